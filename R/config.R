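#' Run configuration for the dsRNA screen
#'
#' Bundles every tunable threshold of the analysis with its default. Defaults
#' follow the published screen where a value is printed (minimum-r cutoffs 0.6
#' and 0.5, median-ΔDMS cutoff 0.15, TPM floor 10, ratio-change minimum 0.20
#' expressed in ratio units, at most 1 missing stage, antisense background
#' 0.15, motif-to-TSS linkage within 100 bp) and documented package decisions
#' elsewhere (minimum co-covered positions 50, stability threshold on minimum
#' r of 0.8, motif score fraction 0.85, meiosis-specific background margin
#' 0.05).
#'
#' @param stages A [stage_series()].
#' @param min_common Minimum number of co-covered positions for a stage-pair
#'   statistic (correlation or median delta) to be defined.
#' @param r_cutoffs Numeric vector of minimum-r screen cutoffs (strict `<`).
#' @param delta_median_cutoff Median-ΔDMS cutoff for dsRNA candidates
#'   (strict `>`).
#' @param stable_min_r Minimum-r value at or above which a transcript is
#'   classified structurally stable.
#' @param tpm_floor Locus TPM at or below which a stage is treated as missing
#'   in the antisense ratio.
#' @param ratio_change_min Minimum absolute change in antisense read ratio
#'   (ratio units, strict `>`) for a gene to count as dynamic.
#' @param max_missing Maximum number of missing stages tolerated for a
#'   dynamic gene.
#' @param antisense_background Expected background antisense read ratio from
#'   incomplete second-strand digestion (~0.15).
#' @param background_margin Margin above `antisense_background` still treated
#'   as background when calling meiosis-specific activation.
#' @param motif_score_fraction Minimum fraction of a motif's maximal log-odds
#'   score for a scan hit.
#' @param tss_link_max_distance Maximal distance (nt, along the antisense
#'   transcription direction) between a motif's downstream edge and a linked
#'   TSS.
#' @param tss_min_count Minimum summed read count for a TSS cluster.
#' @param tss_merge_window Same-strand 5' ends within this many nt are merged
#'   into one cluster.
#' @param region_length Length (nt) of promoter regions extracted upstream or
#'   downstream of a gene.
#' @param pulse_delta Minimum rise and fall (z-units) for a pulse call.
#' @param pulse_window Stage interval (first and last label) within which a
#'   pulse peak must fall.
#' @param ac_only Restrict reactivity statistics to A/C positions when base
#'   identities are available (DMS probes A and C).
#' @param seed Integer seed used by stochastic steps.
#'
#' @return A named list with class `ds_run_config`.
#' @export
run_config <- function(stages = stage_series(),
                       min_common = 50L,
                       r_cutoffs = c(0.6, 0.5),
                       delta_median_cutoff = 0.15,
                       stable_min_r = 0.8,
                       tpm_floor = 10,
                       ratio_change_min = 0.20,
                       max_missing = 1L,
                       antisense_background = 0.15,
                       background_margin = 0.05,
                       motif_score_fraction = 0.85,
                       tss_link_max_distance = 100L,
                       tss_min_count = 5L,
                       tss_merge_window = 20L,
                       region_length = 1000L,
                       pulse_delta = 1.0,
                       pulse_window = c("P", "T1"),
                       ac_only = TRUE,
                       seed = 1L) {
  stopifnot(inherits(stages, "stage_series"))
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (min_common < 3) stop("min_common must be >= 3", call. = FALSE)
  chk_frac(r_cutoffs, "r_cutoffs")
  if (delta_median_cutoff < 0) stop("delta_median_cutoff must be >= 0", call. = FALSE)
  chk_frac(stable_min_r, "stable_min_r")
  if (tpm_floor < 0) stop("tpm_floor must be >= 0", call. = FALSE)
  chk_frac(ratio_change_min, "ratio_change_min")
  if (max_missing < 0) stop("max_missing must be >= 0", call. = FALSE)
  chk_frac(antisense_background, "antisense_background")
  chk_frac(background_margin, "background_margin")
  chk_frac(motif_score_fraction, "motif_score_fraction")
  if (tss_link_max_distance < 0) stop("tss_link_max_distance must be >= 0", call. = FALSE)
  if (tss_min_count < 1) stop("tss_min_count must be >= 1", call. = FALSE)
  if (tss_merge_window < 0) stop("tss_merge_window must be >= 0", call. = FALSE)
  if (region_length < 1) stop("region_length must be >= 1", call. = FALSE)
  if (pulse_delta <= 0) stop("pulse_delta must be > 0", call. = FALSE)
  assert_stages(stages, pulse_window, "pulse_window")
  structure(list(
    stages = stages,
    min_common = as.integer(min_common),
    r_cutoffs = r_cutoffs,
    delta_median_cutoff = delta_median_cutoff,
    stable_min_r = stable_min_r,
    tpm_floor = tpm_floor,
    ratio_change_min = ratio_change_min,
    max_missing = as.integer(max_missing),
    antisense_background = antisense_background,
    background_margin = background_margin,
    motif_score_fraction = motif_score_fraction,
    tss_link_max_distance = as.integer(tss_link_max_distance),
    tss_min_count = as.integer(tss_min_count),
    tss_merge_window = as.integer(tss_merge_window),
    region_length = as.integer(region_length),
    pulse_delta = pulse_delta,
    pulse_window = as.character(pulse_window),
    ac_only = isTRUE(ac_only),
    seed = as.integer(seed)
  ), class = "ds_run_config")
}

#' @export
print.ds_run_config <- function(x, ...) {
  cat("<ds_run_config>\n")
  cat("  stages:", paste(unclass(x$stages), collapse = " "), "\n")
  for (nm in setdiff(names(x), "stages")) {
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
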