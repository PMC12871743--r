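#' @keywords internal
#' @noRd
inform_filter <- function(...) {
  if (isTRUE(getOption("meiodsrna.verbose", TRUE))) {
    rlang::inform(paste0(...), class = "meiodsrna_info")
  }
  invisible(NULL)
}

#' Pearson correlation between two reactivity profiles
#'
#' Correlates per-nucleotide reactivities of the same transcript at two
#' stages over positions covered in both profiles. Low r marks strong
#' structural remodeling between the stages. When base identities are
#' supplied and `ac_only` is set, only A/C positions enter (DMS methylates
#' adenine and cytosine). The correlation is reported as undefined (`NA`)
#' rather than zero when fewer than `min_common` positions are co-covered or
#' either vector is constant on the overlap: missing is not dissimilar.
#'
#' @param a,b Numeric reactivity vectors of equal length; `NA` marks missing
#'   coverage.
#' @param min_common Minimum number of co-covered positions (>= 3).
#' @param ac_only Restrict to A/C positions (requires `base`).
#' @param base Optional character vector of base identities (`A`, `C`, `G`,
#'   `U`, `N`) matching the profiles.
#' @return A list with elements `r` (correlation or `NA`) and `n` (number of
#'   positions used).
#' @examples
#' x <- c(0.1, 0.5, 0.9, 0.2, 0.7)
#' pair_correlation(x, x, min_common = 3)$r
#' @export
pair_correlation <- function(a, b, min_common = 50L, ac_only = FALSE,
                             base = NULL) {
  if (length(a) != length(b)) {
    stop("profiles must have equal length (same transcript)", call. = FALSE)
  }
  if (min_common < 3) stop("min_common must be >= 3", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  if (isTRUE(ac_only) && !is.null(base)) {
    keep <- keep & base %in% c("A", "C")
  }
  n <- sum(keep)
  if (n < min_common) return(list(r = NA_real_, n = n))
  x <- a[keep]; y <- b[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(list(r = NA_real_, n = n))
  list(r = stats::cor(x, y), n = n)
}

#' Per-nucleotide reactivity difference between two stages
#'
#' Computes the earlier-minus-later reactivity difference, so a positive
#' value means the position lost reactivity over time -- the direction
#' expected when a nucleotide becomes sequestered in an intermolecular
#' duplex. The difference is defined only where both stages are covered.
#'
#' @param early,late Numeric reactivity vectors of equal length (`NA` =
#'   missing); `early` must precede `late` in the stage series.
#' @param early_stage,late_stage Optional stage labels; when given together
#'   with `stages` their order is checked.
#' @param stages Optional [stage_series()] for the order check.
#' @return Numeric vector of differences, `NA` where either input is
#'   missing.
#' @export
delta_profile <- function(early, late, early_stage = NULL, late_stage = NULL,
                          stages = NULL) {
  if (length(early) != length(late)) {
    stop("profiles must have equal length (same transcript)", call. = FALSE)
  }
  if (!is.null(early_stage) && !is.null(late_stage) && !is.null(stages)) {
    if (stage_rank(stages, early_stage) >= stage_rank(stages, late_stage)) {
      stop("stages out of order: '", early_stage, "' does not precede '",
           late_stage, "'", call. = FALSE)
    }
  }
  early - late
}

#' Median of a per-nucleotide reactivity difference vector
#'
#' The per-transcript summary of unidirectional remodeling: a balanced
#' intramolecular rearrangement (as many gains as losses) has median near
#' zero, while duplex formation suppresses reactivity one-way and drives the
#' median positive. Even-count medians are the mean of the central pair.
#'
#' @param delta Numeric difference vector (`NA` = undefined positions).
#' @param min_common Minimum number of defined values for the median to be
#'   defined.
#' @return The median, or `NA` if fewer than `min_common` values are
#'   defined.
#' @export
median_delta <- function(delta, min_common = 50L) {
  v <- delta[!is.na(delta)]
  if (length(v) < min_common) return(NA_real_)
  stats::median(v)
}

profile_matrix <- function(profile_tbl, stages) {
  pos <- sort(unique(profile_tbl$position))
  lab <- unclass(stages)
  m <- matrix(NA_real_, nrow = length(pos), ncol = length(lab),
              dimnames = list(NULL, lab))
  idx_p <- match(profile_tbl$position, pos)
  idx_s <- match(profile_tbl$stage, lab)
  m[cbind(idx_p, idx_s)] <- profile_tbl$reactivity
  base <- rep(NA_character_, length(pos))
  if ("base" %in% names(profile_tbl)) {
    b <- profile_tbl$base[!is.na(profile_tbl$base)]
    p <- idx_p[!is.na(profile_tbl$base)]
    base[p] <- b
  }
  list(m = m, base = base, positions = pos)
}

#' Remodeling summary for one transcript
#'
#' Evaluates all stage pairs of one transcript: the Pearson r matrix, the
#' matrix of median reactivity differences (rows = earlier stage, columns =
#' later stage, antisymmetric), the minimum off-diagonal r with its stage
#' pair, the maximal earlier-to-later median difference with its pair, and a
#' class label:
#' \describe{
#'   \item{`stable`}{minimum r at or above `stable_min_r`.}
#'   \item{`unidirectional`}{not stable and maximal median difference above
#'     `delta_median_cutoff` -- the dsRNA-formation signature.}
#'   \item{`bidirectional`}{not stable, balanced gains/losses (ordinary
#'     intramolecular remodeling).}
#'   \item{`insufficient`}{no stage pair reaches `min_common` co-covered
#'     positions.}
#' }
#'
#' @param profile_tbl Long tibble for a single transcript with columns
#'   `stage`, `position`, `reactivity` and optionally `base`.
#' @param config A [run_config()].
#' @return A `remodeling_summary` list with elements `transcript_id`,
#'   `r_matrix`, `n_common`, `delta_median`, `min_r`, `min_r_pair`,
#'   `max_delta_median`, `max_delta_pair`, `n_pairs_evaluated`, `class`.
#' @export
summarize_transcript <- function(profile_tbl, config = run_config()) {
  stages <- config$stages
  assert_stages(stages, profile_tbl$stage)
  tid <- unique(profile_tbl$transcript_id)
  if (length(tid) > 1) {
    stop("summarize_transcript expects a single transcript", call. = FALSE)
  }
  if (length(tid) == 0) tid <- NA_character_
  pm <- profile_matrix(profile_tbl, stages)
  lab <- unclass(stages)
  S <- length(lab)
  # bases of all "N" (or absent) carry no A/C information; scan all positions
  use_ac <- config$ac_only && any(pm$base %in% c("A", "C"))
  base <- if (use_ac) pm$base else NULL

  r_mat <- matrix(NA_real_, S, S, dimnames = list(lab, lab))
  n_mat <- matrix(0L, S, S, dimnames = list(lab, lab))
  d_mat <- matrix(NA_real_, S, S, dimnames = list(lab, lab))
  covered <- colSums(!is.na(pm$m)) > 0
  for (i in seq_len(S)) {
    if (covered[i]) {
      diag_r <- pair_correlation(pm$m[, i], pm$m[, i],
                                 min_common = config$min_common,
                                 ac_only = use_ac, base = base)
      r_mat[i, i] <- if (is.na(diag_r$r)) NA_real_ else 1
      n_mat[i, i] <- diag_r$n
      d_mat[i, i] <- if (diag_r$n >= config$min_common) 0 else NA_real_
    }
  }
  for (i in seq_len(S - 1)) {
    for (j in seq(i + 1, S)) {
      pc <- pair_correlation(pm$m[, i], pm$m[, j],
                             min_common = config$min_common,
                             ac_only = use_ac, base = base)
      r_mat[i, j] <- r_mat[j, i] <- pc$r
      n_mat[i, j] <- n_mat[j, i] <- pc$n
      dvec <- delta_profile(pm$m[, i], pm$m[, j])
      if (use_ac) dvec[!(base %in% c("A", "C"))] <- NA_real_
      dm <- median_delta(dvec, min_common = config$min_common)
      d_mat[i, j] <- dm
      d_mat[j, i] <- -dm
    }
  }

  off <- upper.tri(n_mat)
  qualifying <- off & n_mat >= config$min_common
  n_pairs <- sum(qualifying)
  defined_r <- off & !is.na(r_mat)
  if (any(defined_r)) {
    min_r <- min(r_mat[defined_r])
    w <- which(defined_r & r_mat == min_r, arr.ind = TRUE)[1, ]
    min_r_pair <- paste(lab[w[1]], lab[w[2]], sep = ":")
  } else {
    min_r <- NA_real_
    min_r_pair <- NA_character_
  }
  defined_d <- off & !is.na(d_mat)
  if (any(defined_d)) {
    max_dm <- max(d_mat[defined_d])
    w <- which(defined_d & d_mat == max_dm, arr.ind = TRUE)[1, ]
    max_dm_pair <- paste(lab[w[1]], lab[w[2]], sep = ":")
  } else {
    max_dm <- NA_real_
    max_dm_pair <- NA_character_
  }

  cls <- if (n_pairs == 0) {
    "insufficient"
  } else if (!is.na(min_r) && min_r >= config$stable_min_r) {
    "stable"
  } else if (!is.na(max_dm) && max_dm > config$delta_median_cutoff) {
    "unidirectional"
  } else {
    "bidirectional"
  }

  structure(list(
    transcript_id = tid,
    r_matrix = r_mat,
    n_common = n_mat,
    delta_median = d_mat,
    min_r = min_r,
    min_r_pair = min_r_pair,
    max_delta_median = max_dm,
    max_delta_pair = max_dm_pair,
    n_pairs_evaluated = n_pairs,
    class_label = cls
  ), class = "remodeling_summary")
}

#' @export
print.remodeling_summary <- function(x, ...) {
  cat("<remodeling_summary> ", x$transcript_id,
      ": min r = ", signif(x$min_r, 3), " (", x$min_r_pair, ")",
      ", max median ddms = ", signif(x$max_delta_median, 3),
      " (", x$max_delta_pair, "), class = ", x$class_label, "\n", sep = "")
  invisible(x)
}

#' Remodeling summaries for a cohort of transcripts
#'
#' Applies [summarize_transcript()] to every transcript of a long reactivity
#' table and collects the per-transcript statistics into one tibble.
#'
#' @param reactivity Long tibble as returned by [read_reactivity_table()] or
#'   [simulate_reactivity_series()].
#' @param config A [run_config()].
#' @return A tibble with one row per transcript: `transcript_id`, `min_r`,
#'   `min_r_pair`, `max_delta_median`, `max_delta_pair`,
#'   `n_pairs_evaluated`, `class`.
#' @export
summarize_transcripts <- function(reactivity, config = run_config()) {
  out <- reactivity |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::group_map(function(tbl, key) {
      tbl$transcript_id <- key$transcript_id
      s <- summarize_transcript(tbl, config)
      tibble::tibble(
        transcript_id = s$transcript_id,
        min_r = s$min_r,
        min_r_pair = s$min_r_pair,
        max_delta_median = s$max_delta_median,
        max_delta_pair = s$max_delta_pair,
        n_pairs_evaluated = s$n_pairs_evaluated,
        class = s$class_label
      )
    }) |>
    dplyr::bind_rows()
  inform_filter("summarize_transcripts: ", nrow(out), " transcripts, ",
                sum(out$class == "insufficient"), " with insufficient coverage")
  out
}

#' Screen remodeling summaries for dsRNA candidates
#'
#' Applies the two published screens to a cohort of remodeling summaries:
#' genes whose minimum stage-pair correlation falls strictly below each
#' cutoff (default 0.6 and 0.5), and the dsRNA candidate list of genes whose
#' maximal earlier-to-later median reactivity difference strictly exceeds
#' the cutoff (default 0.15).
#'
#' @param summaries Tibble from [summarize_transcripts()].
#' @param r_cutoffs Numeric vector of minimum-r cutoffs (strict `<`).
#' @param delta_cutoff Median-difference cutoff (strict `>`).
#' @return A `structure_screen` object; see [tidy.structure_screen()] and
#'   [glance.structure_screen()].
#' @export
screen_transcripts <- function(summaries, r_cutoffs = c(0.6, 0.5),
                               delta_cutoff = 0.15) {
  r_hits <- lapply(r_cutoffs, function(cut) {
    hits <- summaries[!is.na(summaries$min_r) & summaries$min_r < cut, ]
    dplyr::arrange(hits, .data$min_r)
  })
  names(r_hits) <- paste0("r<", r_cutoffs)
  candidates <- summaries[!is.na(summaries$max_delta_median) &
                            summaries$max_delta_median > delta_cutoff, ]
  candidates <- dplyr::arrange(candidates, dplyr::desc(.data$max_delta_median))
  counts <- tibble::tibble(
    screen = c(names(r_hits), paste0("delta_median>", delta_cutoff)),
    n = c(vapply(r_hits, nrow, integer(1)), nrow(candidates))
  )
  inform_filter("screen_transcripts: ", nrow(summaries), " in; ",
                paste(counts$screen, counts$n, sep = "=", collapse = ", "))
  structure(list(
    summaries = summaries,
    r_hits = r_hits,
    candidates = candidates,
    counts = counts,
    r_cutoffs = r_cutoffs,
    delta_cutoff = delta_cutoff
  ), class = "structure_screen")
}

#' @export
print.structure_screen <- function(x, ...) {
  cat("<structure_screen> ", nrow(x$summaries), " transcripts\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Tidy a structure screen
#'
#' @param x A `structure_screen` object.
#' @param ... Unused.
#' @return The dsRNA candidate tibble (transcripts whose maximal median
#'   reactivity difference exceeds the cutoff), sorted by decreasing
#'   statistic.
#' @export
tidy.structure_screen <- function(x, ...) {
  x$candidates
}

#' One-row summary of a structure screen
#'
#' @param x A `structure_screen` object.
#' @param ... Unused.
#' @return One-row tibble with the cohort size and each screen's hit count.
#' @export
glance.structure_screen <- function(x, ...) {
  wide <- stats::setNames(as.list(x$counts$n), x$counts$screen)
  tibble::as_tibble(c(list(n_transcripts = nrow(x$summaries)), wide))
}

#' Write a remodeling summary table
#'
#' @param summaries Tibble from [summarize_transcripts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_remodeling_summary <- function(summaries, path) {
  readr::write_tsv(summaries, path, na = "NA", progress = FALSE)
  invisible(path)
}
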