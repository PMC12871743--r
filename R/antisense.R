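#' TPM-normalize a strand-specific count table
#'
#' Converts strand-specific counts to transcripts per million. Per stage,
#' each (gene, strand) entry contributes `count / length` to a common rate
#' pool; TPM is each rate divided by the pooled sum times 1e6, so sense and
#' antisense entries of one locus are separate terms and all TPM values of a
#' stage sum to one million. Sense and antisense share the locus length:
#' the antisense transcripts span the sense locus.
#'
#' @param counts Tibble as returned by [read_stranded_counts()] (columns
#'   `gene_id`, `stage`, `sense_count`, `antisense_count`, `length`,
#'   `observed`).
#' @param stages A [stage_series()].
#' @return A tibble with columns `gene_id`, `stage`, `sense_tpm`,
#'   `antisense_tpm`, `observed` (unobserved cells have `NA` TPM).
#' @export
tpm_normalize <- function(counts, stages = stage_series()) {
  assert_stages(stages, counts$stage)
  if (!"observed" %in% names(counts)) counts$observed <- TRUE
  out <- counts |>
    dplyr::mutate(sense_rate = .data$sense_count / .data$length,
                  antisense_rate = .data$antisense_count / .data$length) |>
    dplyr::group_by(.data$stage) |>
    dplyr::mutate(total_rate = sum(.data$sense_rate[.data$observed]) +
                    sum(.data$antisense_rate[.data$observed])) |>
    dplyr::ungroup()
  if (any(out$total_rate == 0)) {
    bad <- unique(out$stage[out$total_rate == 0])
    stop("stage with zero total counts: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- out |>
    dplyr::mutate(
      sense_tpm = ifelse(.data$observed,
                         .data$sense_rate / .data$total_rate * 1e6, NA_real_),
      antisense_tpm = ifelse(.data$observed,
                             .data$antisense_rate / .data$total_rate * 1e6,
                             NA_real_)
    )
  dplyr::arrange(
    out[, c("gene_id", "stage", "sense_tpm", "antisense_tpm", "observed")],
    .data$gene_id, stage_rank(stages, .data$stage)
  )
}

#' Antisense read ratio per gene and stage
#'
#' The fraction of a locus's strand-assigned signal arising from the
#' antisense strand: `antisense_tpm / (sense_tpm + antisense_tpm)`. A stage
#' is treated as missing when the cell is unobserved or the locus total TPM
#' is at or below `tpm_floor` (published rule: loci with TPM above 10 were
#' retained, lower values treated as missing).
#'
#' @param tpm Tibble from [tpm_normalize()].
#' @param tpm_floor Locus-total TPM floor (default 10).
#' @return A tibble with columns `gene_id`, `stage`, `ratio` (`NA` =
#'   missing).
#' @export
antisense_ratio <- function(tpm, tpm_floor = 10) {
  if (tpm_floor < 0) stop("tpm_floor must be >= 0", call. = FALSE)
  total <- tpm$sense_tpm + tpm$antisense_tpm
  defined <- tpm$observed & !is.na(total) & total > tpm_floor
  tibble::tibble(
    gene_id = tpm$gene_id,
    stage = tpm$stage,
    ratio = ifelse(defined, tpm$antisense_tpm / total, NA_real_)
  )
}

#' Per-gene ratio-trajectory statistics
#'
#' @param ratio Tibble from [antisense_ratio()].
#' @return A tibble with one row per gene: `max_change` (max defined ratio
#'   minus min defined ratio; `NA` with fewer than two defined stages) and
#'   `n_missing`.
#' @export
ratio_gene_stats <- function(ratio) {
  ratio |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      max_change = if (sum(!is.na(.data$ratio)) >= 2) {
        max(.data$ratio, na.rm = TRUE) - min(.data$ratio, na.rm = TRUE)
      } else NA_real_,
      n_missing = sum(is.na(.data$ratio)),
      .groups = "drop"
    )
}

#' Select genes with dynamic antisense ratios
#'
#' Published filter ahead of clustering: keep genes whose antisense read
#' ratio changes by strictly more than `min_change` (ratio units) across the
#' time course, with at most `max_missing` missing stages.
#'
#' @param ratio Tibble from [antisense_ratio()].
#' @param min_change Minimum absolute ratio change (default 0.20).
#' @param max_missing Maximum missing stages (default 1).
#' @return The per-gene statistics tibble restricted to selected genes.
#' @export
select_dynamic_genes <- function(ratio, min_change = 0.20, max_missing = 1L) {
  stats_tbl <- ratio_gene_stats(ratio)
  keep <- !is.na(stats_tbl$max_change) &
    stats_tbl$max_change > min_change &
    stats_tbl$n_missing <= max_missing
  inform_filter("select_dynamic_genes: ", nrow(stats_tbl), " in, ",
                sum(keep), " dynamic")
  stats_tbl[keep, , drop = FALSE]
}

#' Assign antisense activation intervals
#'
#' For each gene, the activation stage is the consecutive defined-stage
#' interval with the largest increase in antisense read ratio (ties broken
#' toward the earliest interval). A gene is called activated only when that
#' maximal increase is positive. The meiosis-specific flag marks genes whose
#' defined ratios at the vegetative (V) and pre-meiotic (P) stages stay at
#' background (at most `background + margin`) and whose called interval
#' starts at P or later.
#'
#' @param ratio Tibble from [antisense_ratio()].
#' @param stages A [stage_series()].
#' @param background Background antisense ratio (default 0.15, the
#'   second-strand artifact floor).
#' @param margin Tolerance above background (default 0.05).
#' @return A tibble with one row per gene: `interval_from`, `interval_to`,
#'   `interval`, `magnitude`, `called`, `meiosis_specific`.
#' @export
assign_activation <- function(ratio, stages = stage_series(),
                              background = 0.15, margin = 0.05) {
  assert_stages(stages, ratio$stage)
  lab <- unclass(stages)
  pre_meiotic <- lab[seq_len(min(2, length(lab)))]  # V and P
  ratio |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(function(tbl, key) {
      ord <- order(stage_rank(stages, tbl$stage))
      tbl <- tbl[ord, ]
      defined <- !is.na(tbl$ratio)
      st <- tbl$stage[defined]
      rr <- tbl$ratio[defined]
      if (length(rr) < 2) {
        return(tibble::tibble(
          gene_id = key$gene_id, interval_from = NA_character_,
          interval_to = NA_character_, interval = NA_character_,
          magnitude = NA_real_, called = FALSE, meiosis_specific = FALSE
        ))
      }
      inc <- diff(rr)
      best <- which.max(inc)  # ties resolve to the earliest interval
      magnitude <- inc[best]
      called <- magnitude > 0
      from <- st[best]; to <- st[best + 1]
      bg_ok <- all(rr[st %in% pre_meiotic] <= background + margin)
      meiosis_specific <- called && bg_ok &&
        stage_rank(stages, from) >= stage_rank(stages, pre_meiotic[length(pre_meiotic)])
      tibble::tibble(
        gene_id = key$gene_id,
        interval_from = if (called) from else NA_character_,
        interval_to = if (called) to else NA_character_,
        interval = if (called) paste0(from, "->", to) else NA_character_,
        magnitude = magnitude,
        called = called,
        meiosis_specific = meiosis_specific
      )
    }) |>
    dplyr::bind_rows()
}

#' Wide gene-by-stage matrix from a long ratio table
#'
#' @param ratio Tibble with columns `gene_id`, `stage` and one value column.
#' @param stages A [stage_series()].
#' @param value Name of the value column (default `"ratio"`).
#' @return A numeric matrix, genes as rows (rownames = gene ids), stages as
#'   columns in series order.
#' @export
ratio_matrix <- function(ratio, stages = stage_series(), value = "ratio") {
  lab <- unclass(stages)
  wide <- tidyr::pivot_wider(ratio[, c("gene_id", "stage", value)],
                             names_from = "stage", values_from = value)
  m <- as.matrix(wide[, intersect(lab, names(wide)), drop = FALSE])
  rownames(m) <- wide$gene_id
  m
}

centroid_distance <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 2) return(2)
  a <- x[keep]; b <- y[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(2)
  1 - stats::cor(a, b)
}

#' Hierarchical clustering with centroid linkage on centered Pearson
#'
#' Agglomerative clustering of per-gene stage trajectories with the
#' semantics of the Cluster 3.0 program: the dissimilarity between two
#' clusters is `1 - r`, the centered Pearson correlation distance between
#' their centroid profiles, and after every merge the centroid is
#' recomputed as the mean member profile over co-defined stages. Centroid
#' linkage on a correlation distance can produce non-monotone merge
#' heights; heights are reported as computed. Rows with zero variance over
#' their defined stages are dropped with a warning, and cluster pairs whose
#' centroids share fewer than two defined stages get the maximal distance 2.
#'
#' @param x Numeric matrix (genes x stages, rownames = gene ids; `NA` =
#'   missing) such as from [ratio_matrix()].
#' @return A `nat_hclust` object with elements `merge` (hclust-style merge
#'   matrix), `height`, `labels`, `dropped`.
#' @seealso [cut_clusters()], [tidy.nat_hclust()]
#' @export
hierarchical_cluster <- function(x) {
  if (is.null(rownames(x))) rownames(x) <- paste0("row", seq_len(nrow(x)))
  row_sd <- apply(x, 1, function(r) stats::sd(r[!is.na(r)]))
  constant <- is.na(row_sd) | row_sd == 0
  if (any(constant)) {
    warning(sum(constant), " constant row(s) dropped before clustering: ",
            paste(utils::head(rownames(x)[constant], 5), collapse = ", "),
            call. = FALSE)
    x <- x[!constant, , drop = FALSE]
  }
  n <- nrow(x)
  if (n < 2) stop("need at least 2 non-constant rows to cluster", call. = FALSE)

  centroids <- x
  sizes <- rep(1L, n)
  # hclust convention: negative = original observation, positive = prior merge
  id <- -seq_len(n)
  active <- rep(TRUE, n)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- centroid_distance(centroids[i, ], centroids[j, ])
    }
  }
  members <- lapply(seq_len(n), function(i) i)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    w <- which(D == min(D), arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE][1, ]  # deterministic ties
    i <- w[1]; j <- w[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- D[i, j]
    members[[i]] <- c(members[[i]], members[[j]])
    centroids[i, ] <- colMeans(x[members[[i]], , drop = FALSE], na.rm = TRUE)
    centroids[i, is.nan(centroids[i, ])] <- NA_real_
    sizes[i] <- sizes[i] + sizes[j]
    id[i] <- step
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    for (k in which(active)) {
      if (k == i) next
      d <- centroid_distance(centroids[i, ], centroids[k, ])
      if (k < i) D[k, i] <- d else D[i, k] <- d
    }
  }
  structure(list(
    merge = merge,
    height = height,
    labels = rownames(x),
    method = "centroid linkage, centered Pearson distance",
    dropped = if (exists("constant")) names(which(constant)) else character(0)
  ), class = "nat_hclust")
}

#' @export
print.nat_hclust <- function(x, ...) {
  cat("<nat_hclust> ", length(x$labels), " leaves, ", x$method, "\n", sep = "")
  if (is.unsorted(x$height)) {
    cat("  note: non-monotone merge heights (inherent to centroid linkage)\n")
  }
  invisible(x)
}

#' Cut a centroid-linkage tree into k clusters
#'
#' Undoes the last `k - 1` merges (cutting by merge order, which is well
#' defined even when centroid-linkage heights are non-monotone) and labels
#' clusters in order of first leaf appearance.
#'
#' @param tree A `nat_hclust` object.
#' @param k Number of clusters.
#' @return A tibble with columns `gene_id` and `cluster`.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must be in 1..", n, call. = FALSE)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep_steps <- seq_len(n - k)
  # map merge-node id -> representative leaf
  node_rep <- integer(n - 1)
  for (s in keep_steps) {
    reps <- vapply(tree$merge[s, ], function(m) {
      if (m < 0) find(-m) else find(node_rep[m])
    }, integer(1))
    parent[reps[2]] <- reps[1]
    node_rep[s] <- reps[1]
  }
  # also record representatives for undone merges so find() stays valid
  if (n - k + 1 <= n - 1) {
    for (s in seq(n - k + 1, n - 1)) {
      m <- tree$merge[s, 1]
      node_rep[s] <- if (m < 0) -m else node_rep[m]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cluster <- match(roots, unique(roots))
  tibble::tibble(gene_id = tree$labels, cluster = cluster)
}

#' Tidy a centroid-linkage tree
#'
#' @param x A `nat_hclust` object.
#' @param k Number of clusters to cut (default 2).
#' @param ... Unused.
#' @return Cluster assignments from [cut_clusters()].
#' @export
tidy.nat_hclust <- function(x, k = 2, ...) {
  cut_clusters(x, k)
}

#' One-row summary of a centroid-linkage tree
#'
#' @param x A `nat_hclust` object.
#' @param ... Unused.
#' @return One-row tibble: number of leaves, merges, height range and
#'   whether merge heights are monotone.
#' @export
glance.nat_hclust <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$labels),
    n_merges = nrow(x$merge),
    min_height = min(x$height),
    max_height = max(x$height),
    monotone_heights = !is.unsorted(x$height)
  )
}

#' Write the merge history of a tree as TSV
#'
#' @param tree A `nat_hclust` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_tree <- function(tree, path) {
  tb <- tibble::tibble(
    node = seq_len(nrow(tree$merge)),
    left = tree$merge[, 1],
    right = tree$merge[, 2],
    height = tree$height
  )
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
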