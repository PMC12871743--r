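#' Row-wise z-scoring of a gene-by-stage matrix
#'
#' Centers and scales each gene's trajectory over its defined stages using
#' the population standard deviation (divisor `n`), so every row has mean 0
#' and standard deviation 1. Rows with zero variance (or fewer than two
#' defined stages) are dropped with a warning.
#'
#' @param m Numeric matrix, genes x stages (`NA` = missing).
#' @return The z-scored matrix, possibly with fewer rows.
#' @export
zscore_rows <- function(m) {
  stats_ok <- apply(m, 1, function(r) {
    v <- r[!is.na(r)]
    length(v) >= 2 && stats::sd(v) > 0
  })
  if (any(!stats_ok)) {
    warning(sum(!stats_ok), " zero-variance row(s) dropped from z-scoring",
            call. = FALSE)
    m <- m[stats_ok, , drop = FALSE]
  }
  t(apply(m, 1, function(r) {
    v <- r[!is.na(r)]
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    (r - mu) / sd_pop
  }))
}

#' Detect pulsed expression in a z-scored trajectory
#'
#' A pulse is a rapid rise followed by an equally rapid fall inside a short
#' stage window (default pre-meiotic P through prophase I T1). The peak is
#' the maximal z value within the window; the rise is peak minus the
#' minimum over stages up to the peak, the fall is peak minus the minimum
#' over stages after the peak through one stage past the window's end. The
#' gene is pulsed when both rise and fall reach `delta` z-units.
#'
#' @param z Named numeric vector of z-scored values (names = stage labels)
#'   or unnamed vector in stage order.
#' @param stages A [stage_series()].
#' @param window Character vector of two stage labels delimiting the pulse
#'   window (default `c("P", "T1")`).
#' @param delta Minimum rise and fall in z-units (default 1).
#' @return A one-row tibble: `pulsed`, `peak_stage`, `rise`, `fall`.
#' @export
detect_pulse <- function(z, stages = stage_series(), window = c("P", "T1"),
                         delta = 1.0) {
  lab <- unclass(stages)
  if (is.null(names(z))) {
    if (length(z) != length(lab)) {
      stop("unnamed z vector must cover every stage", call. = FALSE)
    }
    names(z) <- lab
  }
  assert_stages(stages, names(z))
  assert_stages(stages, window, "window")
  z <- z[lab[lab %in% names(z)]]
  ranks <- stage_rank(stages, names(z))
  w_lo <- stage_rank(stages, window[1])
  w_hi <- stage_rank(stages, window[2])
  if (w_lo > w_hi) stop("window stages out of order", call. = FALSE)
  in_win <- which(ranks >= w_lo & ranks <= w_hi & !is.na(z))
  if (length(in_win) == 0) {
    return(tibble::tibble(pulsed = FALSE, peak_stage = NA_character_,
                          rise = NA_real_, fall = NA_real_))
  }
  peak_i <- in_win[which.max(z[in_win])]
  before <- which(ranks <= ranks[peak_i] & !is.na(z))
  after <- which(ranks > ranks[peak_i] & ranks <= w_hi + 1 & !is.na(z))
  rise <- z[peak_i] - min(z[before])
  fall <- if (length(after) > 0) z[peak_i] - min(z[after]) else NA_real_
  pulsed <- !is.na(rise) && !is.na(fall) && rise >= delta && fall >= delta
  tibble::tibble(pulsed = pulsed, peak_stage = names(z)[peak_i],
                 rise = unname(rise), fall = unname(fall))
}

#' Pulse calls for a cohort of trajectories
#'
#' @param z_matrix Z-scored gene-by-stage matrix (e.g. from
#'   [zscore_rows()]); rownames are gene ids, colnames stage labels.
#' @inheritParams detect_pulse
#' @return A tibble with one row per gene: `gene_id`, `pulsed`,
#'   `peak_stage`, `rise`, `fall`.
#' @export
detect_pulses <- function(z_matrix, stages = stage_series(),
                          window = c("P", "T1"), delta = 1.0) {
  calls <- purrr::map_dfr(seq_len(nrow(z_matrix)), function(i) {
    detect_pulse(z_matrix[i, ], stages, window, delta)
  })
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(z_matrix)), calls)
  inform_filter("detect_pulses: ", nrow(out), " genes in, ",
                sum(out$pulsed), " pulsed")
  out
}

#' Concurrency of sense decline and antisense activation
#'
#' Locates the consecutive-stage interval of maximal sense-TPM decrease and
#' compares it with the gene's antisense activation interval. The two
#' events are concurrent when the intervals are identical or adjacent
#' (neighboring stage boundaries; the mid-meiotic stages are minutes
#' apart, within the alignment resolution of the time course).
#'
#' @param sense_tpm Named numeric vector of sense TPM per stage (`NA` =
#'   missing).
#' @param ratio Named numeric vector of antisense read ratios per stage.
#' @param stages A [stage_series()].
#' @param background,margin Passed to [assign_activation()].
#' @return A one-row tibble: `decline_interval`, `activation_interval`,
#'   `concurrent`, `reason`.
#' @export
sense_antisense_concurrency <- function(sense_tpm, ratio,
                                        stages = stage_series(),
                                        background = 0.15, margin = 0.05) {
  lab <- unclass(stages)
  if (is.null(names(sense_tpm))) names(sense_tpm) <- lab[seq_along(sense_tpm)]
  if (is.null(names(ratio))) names(ratio) <- lab[seq_along(ratio)]
  assert_stages(stages, names(sense_tpm))
  assert_stages(stages, names(ratio))

  s <- sense_tpm[lab[lab %in% names(sense_tpm)]]
  def <- which(!is.na(s))
  decline_idx <- NA_integer_
  if (length(def) >= 2) {
    drops <- s[def[-length(def)]] - s[def[-1]]
    if (max(drops) > 0) decline_idx <- which.max(drops)
  }
  decline_interval <- if (!is.na(decline_idx)) {
    paste0(names(s)[def[decline_idx]], "->", names(s)[def[decline_idx + 1]])
  } else NA_character_

  act <- assign_activation(
    tibble::tibble(gene_id = "g", stage = names(ratio),
                   ratio = unname(ratio)),
    stages = stages, background = background, margin = margin
  )
  activation_interval <- act$interval[1]

  if (is.na(decline_interval) || !isTRUE(act$called[1])) {
    reason <- if (is.na(decline_interval)) "no sense decline" else
      "no antisense activation"
    return(tibble::tibble(decline_interval = decline_interval,
                          activation_interval = activation_interval,
                          concurrent = FALSE, reason = reason))
  }
  d_from <- stage_rank(stages, names(s)[def[decline_idx]])
  a_from <- stage_rank(stages, act$interval_from[1])
  concurrent <- abs(d_from - a_from) <= 1
  tibble::tibble(decline_interval = decline_interval,
                 activation_interval = activation_interval,
                 concurrent = concurrent, reason = NA_character_)
}

#' Annotate sequentially convergent promoter architectures
#'
#' Scans each gene's 1-kb sense-promoter region (upstream, in sense
#' orientation) for the URS1 element and its 1-kb antisense-promoter region
#' (downstream of the 3' end) for the MSE. A locus carrying both is flagged
#' convergent: a temporally ordered pair of opposing promoters (Ume6p-driven
#' sense promoter, Ndt80p-driven antisense promoter) enabling transient
#' sense--antisense overlap.
#'
#' @param genes Gene-model tibble.
#' @param genome A named `Biostrings::DNAStringSet`.
#' @param urs1 PWM for the sense-promoter element (default [urs1_pwm()]).
#' @param mse PWM for the antisense-promoter element (default [mse_pwm()]).
#' @param region_length Promoter region length (default 1000).
#' @param min_score_fraction Hit threshold (default 0.85).
#' @return A tibble with one row per gene: `gene_id`, `urs1_upstream`,
#'   `mse_downstream` (hit counts), `convergent`.
#' @export
annotate_convergent_promoters <- function(genes, genome,
                                          urs1 = urs1_pwm(),
                                          mse = mse_pwm(),
                                          region_length = 1000L,
                                          min_score_fraction = 0.85) {
  up <- extract_upstream_regions(genes, genome, region_length)
  down <- extract_downstream_regions(genes, genome, region_length)
  urs1_hits <- scan_regions(up, urs1, min_score_fraction)
  mse_hits <- scan_regions(down, mse, min_score_fraction)
  n_hits <- function(hits, ids) {
    if (is.null(hits) || nrow(hits) == 0) return(rep(0L, length(ids)))
    tab <- table(hits$gene_id)
    out <- as.integer(tab[ids])
    out[is.na(out)] <- 0L
    out
  }
  out <- tibble::tibble(
    gene_id = genes$gene_id,
    urs1_upstream = n_hits(urs1_hits, genes$gene_id),
    mse_downstream = n_hits(mse_hits, genes$gene_id)
  )
  out$convergent <- out$urs1_upstream > 0 & out$mse_downstream > 0
  inform_filter("annotate_convergent_promoters: ", nrow(out), " genes, ",
                sum(out$convergent), " convergent")
  out
}
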