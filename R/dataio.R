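#' Read a per-nucleotide reactivity table
#'
#' Reads time-resolved chemical-probing (DMS) reactivities from a TSV with
#' columns `transcript_id`, `stage`, `position` (1-based within the
#' transcript), `base` (`A`, `C`, `G`, `U` or `N`) and `reactivity`
#' (non-negative, or the literal `NA` for positions without coverage).
#' Coordinates are transcript-space: each profile is a per-transcript vector,
#' which is how the downstream structural statistics consume it.
#'
#' @param path Path to the TSV file.
#' @param stages A [stage_series()]; rows with stage labels outside the
#'   series are rejected.
#' @return A tibble with columns `transcript_id`, `stage`, `position`,
#'   `base`, `reactivity` (`NA` = missing), sorted by transcript, stage rank
#'   and position.
#' @seealso [write_reactivity_table()]
#' @export
read_reactivity_table <- function(path, stages = stage_series()) {
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      transcript_id = readr::col_character(),
      stage = readr::col_character(),
      position = readr::col_integer(),
      base = readr::col_character(),
      reactivity = readr::col_double()
    ),
    na = "NA", progress = FALSE
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed reactivity table row at line ", prob$row[1],
         " of ", path, ": expected ", prob$expected[1], call. = FALSE)
  }
  req <- c("transcript_id", "stage", "position", "base", "reactivity")
  if (!all(req %in% names(raw))) {
    stop("reactivity table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  assert_stages(stages, raw$stage)
  if (any(is.na(raw$position)) || any(raw$position < 1)) {
    stop("position must be a 1-based integer", call. = FALSE)
  }
  if (!all(raw$base %in% c("A", "C", "G", "U", "N"))) {
    stop("base must be one of A, C, G, U, N", call. = FALSE)
  }
  if (any(raw$reactivity < 0, na.rm = TRUE)) {
    stop("reactivity must be non-negative where present", call. = FALSE)
  }
  key <- paste(raw$transcript_id, raw$stage, raw$position)
  if (anyDuplicated(key)) {
    stop("duplicate (transcript, stage, position) row: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  dplyr::arrange(raw, .data$transcript_id, stage_rank(stages, .data$stage),
                 .data$position)
}

#' Write a per-nucleotide reactivity table
#'
#' Inverse of [read_reactivity_table()]; rows are emitted in sorted key order
#' so the writer is byte-stable for a given table.
#'
#' @param x Tibble as returned by [read_reactivity_table()].
#' @param path Output TSV path.
#' @param stages A [stage_series()] used for sorting.
#' @return `path`, invisibly.
#' @export
write_reactivity_table <- function(x, path, stages = stage_series()) {
  x <- dplyr::arrange(x, .data$transcript_id, stage_rank(stages, .data$stage),
                      .data$position)
  readr::write_tsv(x[, c("transcript_id", "stage", "position", "base", "reactivity")],
                   path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a strand-specific count table
#'
#' Reads per-gene, per-stage read counts assigned separately to the sense and
#' antisense strand of each locus (TSV columns `gene_id`, `stage`,
#' `sense_count`, `antisense_count`, `length`). The returned table is dense
#' over genes x stages: a (gene, stage) pair absent from the file appears
#' with zero counts and `observed = FALSE`, which downstream code treats as
#' true missingness rather than an observed zero.
#'
#' @param path Path to the TSV file.
#' @param stages A [stage_series()].
#' @return A tibble with columns `gene_id`, `stage`, `sense_count`,
#'   `antisense_count`, `length`, `observed`.
#' @export
read_stranded_counts <- function(path, stages = stage_series()) {
  raw <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      stage = readr::col_character(),
      sense_count = readr::col_double(),
      antisense_count = readr::col_double(),
      length = readr::col_double()
    ),
    progress = FALSE
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed count table row at line ", prob$row[1], " of ", path,
         call. = FALSE)
  }
  assert_stages(stages, raw$stage)
  if (any(raw$sense_count < 0) || any(raw$antisense_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(raw$length <= 0)) stop("gene length must be > 0", call. = FALSE)
  key <- paste(raw$gene_id, raw$stage)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, stage) row: ", key[duplicated(key)][1], call. = FALSE)
  }
  len_tbl <- dplyr::distinct(raw, .data$gene_id, .data$length)
  if (anyDuplicated(len_tbl$gene_id)) {
    stop("inconsistent length for gene ",
         len_tbl$gene_id[duplicated(len_tbl$gene_id)][1], call. = FALSE)
  }
  grid <- tidyr::expand_grid(gene_id = sort(unique(raw$gene_id)),
                             stage = unclass(stages))
  out <- dplyr::left_join(grid, raw[, c("gene_id", "stage", "sense_count",
                                        "antisense_count")],
                          by = c("gene_id", "stage"))
  out$observed <- !is.na(out$sense_count)
  out$sense_count[!out$observed] <- 0
  out$antisense_count[!out$observed] <- 0
  out <- dplyr::left_join(out, len_tbl, by = "gene_id")
  dplyr::arrange(out, .data$gene_id, stage_rank(stages, .data$stage))
}

#' Write a strand-specific count table
#'
#' Only observed (gene, stage) cells are written, so
#' `read_stranded_counts(write_stranded_counts(x))` restores `x` including
#' its missingness pattern.
#'
#' @param x Tibble as returned by [read_stranded_counts()].
#' @param path Output TSV path.
#' @param stages A [stage_series()] used for sorting.
#' @return `path`, invisibly.
#' @export
write_stranded_counts <- function(x, path, stages = stage_series()) {
  obs <- x
  if ("observed" %in% names(obs)) obs <- obs[obs$observed, , drop = FALSE]
  obs <- dplyr::arrange(obs, .data$gene_id, stage_rank(stages, .data$stage))
  readr::write_tsv(obs[, c("gene_id", "stage", "sense_count",
                           "antisense_count", "length")],
                   path, progress = FALSE)
  invisible(path)
}

new_pwm <- function(prob, id, source) {
  stopifnot(is.matrix(prob), nrow(prob) == 4)
  rownames(prob) <- c("A", "C", "G", "T")
  cs <- colSums(prob)
  if (any(abs(cs - 1) > 1e-9)) {
    stop("PWM columns must sum to 1", call. = FALSE)
  }
  structure(prob, id = id, source = source, class = c("pwm", "matrix"))
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", attr(x, "id"), " (", attr(x, "source"), "), width ",
      ncol(x), "\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Read a JASPAR position frequency matrix
#'
#' Parses the JASPAR text PFM format: a `>ID name` header followed by four
#' rows for A, C, G, T, each holding the same number of non-negative counts
#' (with or without the `A [ ... ]` bracket decoration). Counts are converted
#' to column-stochastic probabilities after adding a pseudocount to every
#' cell.
#'
#' @param path Path to the PFM file.
#' @param pseudocount Added to every count before normalization (default 1).
#' @return A `pwm` object: a 4 x W probability matrix with rows A, C, G, T.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 5 || !startsWith(lines[1], ">")) {
    stop("not a JASPAR PFM: expected '>ID name' header plus 4 base rows",
         call. = FALSE)
  }
  id <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]][1]
  rows <- lapply(lines[2:5], function(l) {
    l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
    l <- gsub("\\[|\\]", " ", l)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    if (anyNA(vals)) stop("non-numeric count in PFM row: ", l, call. = FALSE)
    vals
  })
  w <- lengths(rows)
  if (length(unique(w)) != 1) {
    stop("PFM rows have unequal widths: ", paste(w, collapse = ", "),
         call. = FALSE)
  }
  counts <- do.call(rbind, rows)
  if (any(counts < 0)) stop("PFM counts must be non-negative", call. = FALSE)
  if (any(colSums(counts) == 0)) stop("all-zero PFM column", call. = FALSE)
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  new_pwm(prob, id = id, source = "pfm_file")
}

#' Read strand-tagged read 5' ends from BED6
#'
#' Each BED record contributes its 5'-most genomic base: `chromStart` for
#' `+` records, `chromEnd - 1` for `-` records (0-based). Records sharing
#' (chrom, 5' end, strand) are aggregated with summed scores; records
#' without a usable score count 1 each.
#'
#' @param path Path to a BED6 file.
#' @return A tibble with columns `chrom`, `position` (0-based), `strand`,
#'   `count`, sorted by chrom, strand, position.
#' @export
read_5prime_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  str <- as.character(BiocGenerics::strand(gr))
  if (any(!str %in% c("+", "-"))) {
    stop("5'-end BED records must be stranded (+ or -)", call. = FALSE)
  }
  five <- GenomicRanges::resize(gr, width = 1L, fix = "start")
  score <- gr$score
  if (is.null(score)) score <- rep(1, length(gr))
  score[is.na(score)] <- 1
  tb <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(five)),
    position = BiocGenerics::start(five) - 1L,  # GRanges is 1-based
    strand = str,
    count = as.numeric(score)
  )
  out <- dplyr::summarise(
    dplyr::group_by(tb, .data$chrom, .data$position, .data$strand),
    count = sum(.data$count), .groups = "drop"
  )
  dplyr::arrange(out, .data$chrom, .data$strand, .data$position)
}

#' Write read 5' ends as BED6
#'
#' Each (chrom, position, strand, count) entry becomes a single-base BED6
#' record whose score is the aggregated count. Single-base records satisfy
#' the 5'-end convention on both strands.
#'
#' @param ends Tibble with columns `chrom`, `position`, `strand`, `count`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_5prime_bed <- function(ends, path) {
  ends <- dplyr::arrange(ends, .data$chrom, .data$strand, .data$position)
  bed <- tibble::tibble(
    chrom = ends$chrom,
    start = as.integer(ends$position),
    end = as.integer(ends$position) + 1L,
    name = "five_prime_end",
    score = ends$count,
    strand = ends$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' Gene loci are used for strand-aware promoter-region extraction. BED
#' (`.bed`) and GFF3 (`.gff`, `.gff3`; `type == "gene"` records) are
#' supported via `rtracklayer`. Coordinates are returned 0-based half-open.
#'
#' @param path Path to the annotation file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `length`.
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "BED"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "GFF3") {
    gr <- gr[gr$type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$gene_id)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
  }
  str <- as.character(BiocGenerics::strand(gr))
  if (any(!str %in% c("+", "-"))) {
    stop("gene models must be stranded (+ or -)", call. = FALSE)
  }
  tb <- tibble::tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = str
  )
  if (any(tb$start < 0) || any(tb$start >= tb$end)) {
    stop("invalid gene coordinates (need 0 <= start < end)", call. = FALSE)
  }
  tb$length <- tb$end - tb$start
  dplyr::arrange(tb, .data$chrom, .data$start)
}

#' Write gene models as BED6
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  genes <- dplyr::arrange(genes, .data$chrom, .data$start)
  bed <- tibble::tibble(
    chrom = genes$chrom,
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    name = genes$gene_id,
    score = 0L,
    strand = genes$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
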