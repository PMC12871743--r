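IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build a position weight matrix from an IUPAC consensus
#'
#' Each consensus column distributes `1 - (4 - a) * eps` equally over its
#' `a` allowed bases and `eps` over each disallowed base; `N` yields the
#' uniform column. This turns the URS1 (`TCGGCGGCTA`, Ume6p) and MSE
#' (`GNCRCAAAW`, Ndt80p) consensus strings into scannable matrices.
#'
#' @param iupac Consensus string over the IUPAC alphabet.
#' @param eps Probability assigned to each disallowed base (0 < eps <
#'   0.25).
#' @return A `pwm` object (4 x W probability matrix).
#' @examples
#' consensus_to_pwm("GNCRCAAAW")
#' @export
consensus_to_pwm <- function(iupac, eps = 0.01) {
  if (eps <= 0 || eps >= 0.25) stop("eps must be in (0, 0.25)", call. = FALSE)
  chars <- strsplit(toupper(iupac), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  prob <- vapply(chars, function(ch) {
    allowed <- IUPAC_SETS[[ch]]
    col <- rep(eps, 4)
    names(col) <- c("A", "C", "G", "T")
    col[allowed] <- (1 - (4 - length(allowed)) * eps) / length(allowed)
    col
  }, numeric(4))
  new_pwm(matrix(prob, nrow = 4), id = toupper(iupac),
          source = "iupac_consensus")
}

#' URS1 and MSE position weight matrices
#'
#' Convenience constructors for the two cis-elements that mark
#' meiosis-specific antisense promoters: URS1 (Upstream Repressing Sequence
#' 1, Ume6p binding, consensus `TCGGCGGCTA`) at promoters activated in the
#' P to T0 interval, and the MSE (Middle Sporulation Element, Ndt80p
#' binding, consensus `GNCRCAAAW`) at promoters activated in the T0 to T1
#' interval.
#'
#' @param eps Disallowed-base probability, see [consensus_to_pwm()].
#' @return A `pwm` object.
#' @export
urs1_pwm <- function(eps = 0.01) {
  p <- consensus_to_pwm("TCGGCGGCTA", eps)
  attr(p, "id") <- "URS1"
  p
}

#' @rdname urs1_pwm
#' @export
mse_pwm <- function(eps = 0.01) {
  p <- consensus_to_pwm("GNCRCAAAW", eps)
  attr(p, "id") <- "MSE"
  p
}

seq_codes <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- match(chars, c("A", "C", "G", "T", "N"))
  if (anyNA(codes)) {
    stop("sequence contains characters outside A, C, G, T, N", call. = FALSE)
  }
  codes
}

revcomp_chr <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

scan_codes_one <- function(codes, logodds5) {
  W <- ncol(logodds5)
  n <- length(codes)
  if (n < W) return(numeric(0))
  scores <- numeric(n - W + 1)
  for (w in seq_len(W)) {
    scores <- scores + logodds5[codes[w:(n - W + w)], w]
  }
  unname(scores)
}

#' Scan a sequence with a position weight matrix
#'
#' Scores every window of the sequence with the log-odds sum
#' `sum(log2(p_col(base) / background))` against a uniform 0.25 background
#' and reports windows whose score reaches `min_score_fraction` of the
#' maximal attainable score. `N` bases contribute 0 bits (neutral, never
#' -Inf). Minus-strand windows are scored on the reverse complement and
#' reported in forward-strand coordinates.
#'
#' @param sequence Character string over A, C, G, T, N (or a
#'   `Biostrings::DNAString`).
#' @param pwm A `pwm` object.
#' @param min_score_fraction Minimum score / max-score fraction for a hit
#'   (default 0.85).
#' @param strands `"+"`, `"-"` or `"both"`.
#' @return A tibble of hits with columns `start`, `end` (0-based half-open,
#'   forward strand), `strand`, `score` (bits), `score_fraction`, sorted by
#'   coordinate.
#' @export
scan_pwm <- function(sequence, pwm, min_score_fraction = 0.85,
                     strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  sequence <- as.character(sequence)
  W <- ncol(pwm)
  logodds <- log2(unclass(pwm) / 0.25)
  logodds5 <- rbind(logodds, N = rep(0, W))
  max_score <- sum(apply(logodds, 2, max))
  n <- nchar(sequence)
  empty <- tibble::tibble(start = integer(0), end = integer(0),
                          strand = character(0), score = numeric(0),
                          score_fraction = numeric(0))
  if (n < W) return(empty)

  res <- list()
  if (strands %in% c("both", "+")) {
    sc <- scan_codes_one(seq_codes(sequence), logodds5)
    frac <- sc / max_score
    keep <- which(frac >= min_score_fraction)
    if (length(keep) > 0) {
      res[["+"]] <- tibble::tibble(start = keep - 1L, end = keep - 1L + W,
                                   strand = "+", score = sc[keep],
                                   score_fraction = frac[keep])
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp_chr(sequence)
    sc <- scan_codes_one(seq_codes(rc), logodds5)
    frac <- sc / max_score
    keep <- which(frac >= min_score_fraction)
    if (length(keep) > 0) {
      # window at rc offset p (1-based) covers forward [n - p - W + 1, n - p + 1)
      fwd_start <- n - (keep - 1L) - W
      res[["-"]] <- tibble::tibble(start = fwd_start, end = fwd_start + W,
                                   strand = "-", score = sc[keep],
                                   score_fraction = frac[keep])
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$start, .data$strand)
}

extract_flank <- function(genes, genome, length,
                          side = c("downstream", "upstream")) {
  side <- match.arg(side)
  stopifnot(inherits(genome, "DNAStringSet"))
  length <- as.integer(length)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  genes <- dplyr::mutate(genes, start = as.integer(.data$start),
                         end = as.integer(.data$end))
  purrr::pmap_dfr(genes[, c("gene_id", "chrom", "start", "end", "strand")],
                  function(gene_id, chrom, start, end, strand) {
    if (!chrom %in% names(genome)) {
      stop("chromosome not in genome: ", chrom, call. = FALSE)
    }
    clen <- chrom_len[[chrom]]
    if (start < 0 || end > clen) {
      stop("gene ", gene_id, " extends beyond chromosome bounds", call. = FALSE)
    }
    # "downstream" = past the 3' end in the gene's orientation,
    # "upstream" = ahead of the 5' end
    right_of_gene <- (strand == "+") == (side == "downstream")
    if (right_of_gene) {
      r_start <- end
      r_end <- min(end + length, clen)
    } else {
      r_start <- max(start - length, 0)
      r_end <- start
    }
    truncated <- (r_end - r_start) < length
    if (r_end <= r_start) {
      seq <- ""
      truncated <- TRUE
    } else {
      seq <- as.character(Biostrings::subseq(genome[[chrom]],
                                             r_start + 1L, r_end))
      if (strand == "-") seq <- revcomp_chr(seq)
    }
    tibble::tibble(gene_id = gene_id, chrom = chrom,
                   start = as.integer(r_start), end = as.integer(r_end),
                   strand = strand, seq = seq, truncated = truncated)
  })
}

#' Extract strand-aware promoter regions around genes
#'
#' `extract_downstream_regions()` returns the region past each gene's 3'
#' end in the gene's own orientation -- the candidate antisense promoter: a
#' `+` gene yields genomic `[end, end + length)` read forward, a `-` gene
#' yields `[start - length, start)` reverse-complemented.
#' `extract_upstream_regions()` returns the analogous region 5' of the gene
#' (the sense promoter). Regions are truncated at chromosome edges and
#' flagged.
#'
#' @param genes Gene-model tibble (columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand`; 0-based half-open).
#' @param genome A named `Biostrings::DNAStringSet`.
#' @param length Region length in nucleotides (default 1000).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end` (the
#'   genomic span), `strand` (gene strand), `seq` (region sequence in the
#'   gene's reading orientation), `truncated`.
#' @export
extract_downstream_regions <- function(genes, genome, length = 1000L) {
  extract_flank(genes, genome, length, side = "downstream")
}

#' @rdname extract_downstream_regions
#' @export
extract_upstream_regions <- function(genes, genome, length = 1000L) {
  extract_flank(genes, genome, length, side = "upstream")
}

#' Map region-local motif hits to genomic coordinates
#'
#' Scans each extracted region with a PWM and reports hits in genomic
#' forward-strand coordinates, composing the hit strand with the region's
#' orientation. A local hit `[p, p + W)` in a `+`-gene region maps to
#' `[start + p, start + p + W)`; in a `-`-gene region (stored
#' reverse-complemented) it maps to `[end - p - W, end - p)` with its
#' strand flipped.
#'
#' @param regions Region tibble from [extract_downstream_regions()] or
#'   [extract_upstream_regions()].
#' @param pwm A `pwm` object.
#' @param min_score_fraction Hit threshold, see [scan_pwm()].
#' @param strands Strands to scan in region-local orientation.
#' @return A tibble of hits: `gene_id`, `chrom`, `start`, `end` (genomic),
#'   `strand` (genomic), `score`, `score_fraction`, `motif_id`.
#' @export
scan_regions <- function(regions, pwm, min_score_fraction = 0.85,
                         strands = "both") {
  purrr::pmap_dfr(regions[, c("gene_id", "chrom", "start", "end",
                              "strand", "seq")],
                  function(gene_id, chrom, start, end, strand, seq) {
    hits <- scan_pwm(seq, pwm, min_score_fraction, strands)
    if (nrow(hits) == 0) return(NULL)
    if (strand == "+") {
      g_start <- start + hits$start
      g_strand <- hits$strand
    } else {
      g_start <- end - hits$end
      g_strand <- ifelse(hits$strand == "+", "-", "+")
    }
    tibble::tibble(gene_id = gene_id, chrom = chrom, start = g_start,
                   end = g_start + ncol(pwm), strand = g_strand,
                   score = hits$score, score_fraction = hits$score_fraction,
                   motif_id = attr(pwm, "id"))
  })
}

#' Hypergeometric motif enrichment between region sets
#'
#' Counts a region as positive when it carries at least one PWM hit on
#' either strand, forms the 2x2 foreground/background table and tests
#' foreground excess with the one-sided hypergeometric tail. The odds ratio
#' is Haldane-corrected (0.5 added to every cell) when any cell is zero.
#'
#' @param foreground,background Region tibbles (disjoint sets), e.g. the
#'   downstream regions of antisense-active genes vs. all other genes.
#' @param pwm A `pwm` object.
#' @param min_score_fraction Hit threshold, see [scan_pwm()].
#' @return A one-row tibble: `fg_total`, `fg_positive`, `bg_total`,
#'   `bg_positive`, `odds_ratio`, `p_value`.
#' @export
motif_enrichment <- function(foreground, background, pwm,
                             min_score_fraction = 0.85) {
  if (nrow(foreground) == 0 || nrow(background) == 0) {
    stop("foreground and background must be non-empty", call. = FALSE)
  }
  has_hit <- function(regions) {
    vapply(regions$seq, function(s) {
      nrow(scan_pwm(s, pwm, min_score_fraction, "both")) > 0
    }, logical(1), USE.NAMES = FALSE)
  }
  k1 <- sum(has_hit(foreground)); n1 <- nrow(foreground)
  k2 <- sum(has_hit(background)); n2 <- nrow(background)
  # P(X >= k1), X ~ Hypergeom(total positives k1+k2 among n1+n2, draw n1)
  p <- stats::phyper(k1 - 1, k1 + k2, n1 + n2 - k1 - k2, n1,
                     lower.tail = FALSE)
  cells <- c(k1, n1 - k1, k2, n2 - k2)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  tibble::tibble(fg_total = n1, fg_positive = k1, bg_total = n2,
                 bg_positive = k2, odds_ratio = or, p_value = p)
}

#' Call transcription-initiation clusters from read 5' ends
#'
#' Merges same-strand 5'-end positions lying within `merge_window` of their
#' neighbor into initiation clusters, discards clusters with summed read
#' count below `min_count`, and reports the modal position as the cluster
#' representative (ties broken toward the 5'-most position in the
#' transcription direction: lowest coordinate on `+`, highest on `-`).
#'
#' @param ends 5'-end tibble from [read_5prime_bed()] (columns `chrom`,
#'   `position`, `strand`, `count`).
#' @param min_count Minimum summed read count per cluster (default 5).
#' @param merge_window Maximum gap (nt) between neighboring positions of
#'   one cluster (default 20).
#' @return A tibble: `chrom`, `position` (representative), `strand`,
#'   `read_count`, `window_start`, `window_end`.
#' @export
call_tss_clusters <- function(ends, min_count = 5L, merge_window = 20L) {
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  if (merge_window < 0) stop("merge_window must be >= 0", call. = FALSE)
  out <- ends |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::group_map(function(tbl, key) {
      tbl <- tbl[order(tbl$position), ]
      gap_break <- c(0, diff(tbl$position)) > merge_window
      cl <- cumsum(gap_break)
      purrr::map_dfr(split(tbl, cl), function(g) {
        top <- g$count == max(g$count)
        rep_pos <- if (key$strand == "+") min(g$position[top]) else
          max(g$position[top])
        tibble::tibble(chrom = key$chrom, position = rep_pos,
                       strand = key$strand, read_count = sum(g$count),
                       window_start = min(g$position),
                       window_end = max(g$position) + 1L)
      })
    }) |>
    dplyr::bind_rows()
  out <- out[out$read_count >= min_count, , drop = FALSE]
  dplyr::arrange(out, .data$chrom, .data$strand, .data$position)
}

#' Link promoter motifs to antisense transcription start sites
#'
#' For each gene, pairs its downstream-region motif hits with
#' opposite-strand TSS clusters lying within `max_distance` downstream of
#' the motif along the antisense transcription direction. The offset is
#' measured from the motif's downstream edge in that direction: for a `+`
#' gene the antisense transcript runs `-`, so `offset = motif_start -
#' tss_position`; for a `-` gene `offset = tss_position - motif_end + 1`.
#' Only links with `0 <= offset <= max_distance` are kept.
#'
#' @param genes Gene-model tibble.
#' @param motif_hits Genomic motif hits from [scan_regions()] (with
#'   `gene_id`).
#' @param tss TSS clusters from [call_tss_clusters()].
#' @param max_distance Maximum motif-to-TSS distance (default 100).
#' @return A tibble of links: `gene_id`, `motif_id`, `motif_start`,
#'   `motif_end`, `tss_position`, `tss_strand`, `tss_count`, `offset`. The
#'   attribute `linked_fraction` holds the fraction of input genes with at
#'   least one link.
#' @export
link_motifs_to_tss <- function(genes, motif_hits, tss, max_distance = 100L) {
  links <- purrr::pmap_dfr(genes[, c("gene_id", "chrom", "strand")],
                           function(gene_id, chrom, strand) {
    hits <- motif_hits[motif_hits$gene_id == gene_id, , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    anti <- if (strand == "+") "-" else "+"
    cand <- tss[tss$chrom == chrom & tss$strand == anti, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(hits)), function(i) {
      offset <- if (strand == "+") {
        hits$start[i] - cand$position
      } else {
        cand$position - hits$end[i] + 1L
      }
      keep <- offset >= 0 & offset <= max_distance
      if (!any(keep)) return(NULL)
      tibble::tibble(gene_id = gene_id,
                     motif_id = hits$motif_id[i],
                     motif_start = hits$start[i], motif_end = hits$end[i],
                     tss_position = cand$position[keep],
                     tss_strand = anti,
                     tss_count = cand$read_count[keep],
                     offset = offset[keep])
    })
  })
  if (nrow(links) == 0) {
    links <- tibble::tibble(gene_id = character(0), motif_id = character(0),
                            motif_start = integer(0), motif_end = integer(0),
                            tss_position = integer(0),
                            tss_strand = character(0),
                            tss_count = numeric(0), offset = integer(0))
  }
  frac <- length(unique(links$gene_id)) / nrow(genes)
  inform_filter("link_motifs_to_tss: ", nrow(links), " links; ",
                signif(frac, 3), " of genes linked")
  attr(links, "linked_fraction") <- frac
  links
}
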