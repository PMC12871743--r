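#' Simulation configuration
#'
#' Bundles every generator parameter with defaults matching the study
#' conditions the pipeline is designed for: 9 ordered stages, ~15% antisense
#' background from incomplete second-strand digestion, antisense activation
#' concentrated (78% of activated genes) in the P->T0 and T0->T1 intervals,
#' unidirectional reactivity suppression inside a T1..T4 window, URS1/MSE
#' elements planted in 1-kb downstream regions with antisense TSSs within
#' 100 bp of the element. Class labels are assigned by exact quota, not
#' Bernoulli draws, so recovery tests have fixed denominators.
#'
#' @param stages A [stage_series()].
#' @param n_transcripts,transcript_length Reactivity cohort size and
#'   per-transcript length (nt).
#' @param fraction_dsrna_targets Fraction of transcripts with planted
#'   intermolecular (dsRNA-like) suppression.
#' @param fraction_intramolecular Fraction with balanced intramolecular
#'   remodeling; the remainder is structurally stable.
#' @param suppression_fraction Multiplicative reactivity reduction `f` in
#'   the suppression window (reactivity is scaled by `1 - f`).
#' @param suppression_window Two stage labels delimiting the suppressed
#'   window (inclusive).
#' @param baseline_median Per-transcript baseline reactivity median; the
#'   drawn gamma baseline is rescaled to hit it exactly.
#' @param baseline_shape Gamma shape of the right-skewed baseline.
#' @param intra_delta Additive shift (+/-) applied to balanced halves of
#'   positions in the intramolecular class.
#' @param noise_sd Per-stage Gaussian reactivity noise sd (truncated at 0).
#' @param missing_rate I.i.d. missing-coverage rate per position and stage.
#' @param n_genes Count-matrix cohort size.
#' @param antisense_background Expected background antisense fraction `b`.
#' @param induced_ratio_level Antisense fraction from the activation
#'   interval onward; must exceed `antisense_background`.
#' @param activated_fraction Fraction of genes with meiosis-specific
#'   antisense activation.
#' @param early_antisense_fraction Fraction with early (V/P) antisense that
#'   decays to background -- dynamic but not meiosis-specific.
#' @param activation_interval_probs Named probability vector over
#'   consecutive-stage intervals (names like `"P->T0"`); must sum to 1.
#' @param dispersion Negative-binomial overdispersion of locus output
#'   (variance = mu + dispersion * mu^2); sense and antisense share the
#'   per-(gene, stage) biological factor, so the strand split behaves like
#'   binomial thinning.
#' @param depth_meanlog,depth_sdlog Lognormal parameters of per-gene
#'   sequencing depth (reads/gene/stage).
#' @param pulse_genes_fraction,rising_fraction,declining_fraction Sense
#'   trajectory class quotas among non-activated, non-early genes.
#' @param gene_length_meanlog,gene_length_sdlog Lognormal gene lengths (nt).
#' @param n_loci Number of gene loci in the genomic simulation.
#' @param gene_length,region_length,locus_spacing Locus geometry (nt).
#' @param antisense_active_fraction Fraction of loci with a planted
#'   antisense promoter (motif + TSS).
#' @param convergent_fraction Fraction of loci with both an upstream URS1
#'   and a downstream MSE (must not exceed half of
#'   `antisense_active_fraction`, the MSE share).
#' @param tss_offset_mean,tss_offset_max Geometric mean and truncation of
#'   the motif-to-TSS offset (nt).
#' @param reads_per_tss 5'-end reads emitted per true TSS.
#' @param tss_jitter_sd Gaussian jitter sd of read 5' ends around the TSS.
#' @param artifact_fraction Fraction of all emitted 5' ends that are
#'   uniformly scattered artifacts.
#' @param seed Integer seed; a fixed seed makes every generator output
#'   reproducible.
#' @return A named list with class `ds_sim_config`.
#' @export
sim_config <- function(stages = stage_series(),
                       n_transcripts = 500L,
                       transcript_length = 200L,
                       fraction_dsrna_targets = 0.08,
                       fraction_intramolecular = 0.12,
                       suppression_fraction = 0.6,
                       suppression_window = c("T1", "T4"),
                       baseline_median = 0.5,
                       baseline_shape = 1.2,
                       intra_delta = 0.3,
                       noise_sd = 0.05,
                       missing_rate = 0.1,
                       n_genes = 1000L,
                       antisense_background = 0.15,
                       induced_ratio_level = 0.45,
                       activated_fraction = 0.30,
                       early_antisense_fraction = 0.09,
                       activation_interval_probs = NULL,
                       dispersion = 0.3,
                       depth_meanlog = log(500),
                       depth_sdlog = 0.8,
                       pulse_genes_fraction = 0.15,
                       rising_fraction = 0.15,
                       declining_fraction = 0.10,
                       gene_length_meanlog = log(1500),
                       gene_length_sdlog = 0.3,
                       n_loci = 100L,
                       gene_length = 1000L,
                       region_length = 1000L,
                       locus_spacing = 1000L,
                       antisense_active_fraction = 0.5,
                       convergent_fraction = 0.2,
                       tss_offset_mean = 40,
                       tss_offset_max = 100L,
                       reads_per_tss = 20L,
                       tss_jitter_sd = 5,
                       artifact_fraction = 0.10,
                       seed = 1L) {
  stopifnot(inherits(stages, "stage_series"))
  lab <- unclass(stages)
  if (is.null(activation_interval_probs)) {
    # 78% of activated genes fall in the P->T0 and T0->T1 intervals, the
    # remainder spread uniformly over the later intervals; none at V->P.
    ints <- stage_intervals(stages)$interval
    p <- stats::setNames(rep(0, length(ints)), ints)
    p["P->T0"] <- 0.39
    p["T0->T1"] <- 0.39
    later <- which(names(p) != "V->P" & p == 0)
    p[later] <- (1 - 0.78) / length(later)
    activation_interval_probs <- p
  }
  fracs <- c(fraction_dsrna_targets = fraction_dsrna_targets,
             fraction_intramolecular = fraction_intramolecular,
             suppression_fraction = suppression_fraction,
             missing_rate = missing_rate,
             antisense_background = antisense_background,
             induced_ratio_level = induced_ratio_level,
             activated_fraction = activated_fraction,
             early_antisense_fraction = early_antisense_fraction,
             pulse_genes_fraction = pulse_genes_fraction,
             rising_fraction = rising_fraction,
             declining_fraction = declining_fraction,
             antisense_active_fraction = antisense_active_fraction,
             convergent_fraction = convergent_fraction,
             artifact_fraction = artifact_fraction)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) {
    stop(paste(names(fracs)[bad], collapse = ", "), " must lie in [0, 1]",
         call. = FALSE)
  }
  if (fraction_dsrna_targets + fraction_intramolecular > 1) {
    stop("reactivity class fractions exceed 1", call. = FALSE)
  }
  if (fraction_dsrna_targets > 0 && suppression_fraction == 0) {
    stop("suppression_fraction must be > 0 when intermolecular targets are requested",
         call. = FALSE)
  }
  assert_stages(stages, suppression_window, "suppression_window")
  if (abs(sum(activation_interval_probs) - 1) > 1e-9) {
    stop("activation_interval_probs must sum to 1", call. = FALSE)
  }
  if (induced_ratio_level <= antisense_background) {
    stop("induced_ratio_level must exceed antisense_background ",
         "(signal would be undetectable)", call. = FALSE)
  }
  if (noise_sd < 0 || tss_jitter_sd < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  max_motif_w <- 10L  # URS1 is the wider of the two planted elements
  if (region_length < max_motif_w + tss_offset_max) {
    stop("region_length must be at least motif width + tss_offset_max",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "ds_sim_config")
}

#' @export
print.ds_sim_config <- function(x, ...) {
  cat("<ds_sim_config> seed ", x$seed, ": ", x$n_transcripts,
      " transcripts, ", x$n_genes, " genes, ", x$n_loci, " loci\n", sep = "")
  invisible(x)
}

quota_assign <- function(n, fractions) {
  # exact-count class assignment; remainder goes to the last class
  counts <- floor(fractions * n)
  counts[length(counts)] <- counts[length(counts)] +
    (round(sum(fractions) * n) - sum(counts))
  rep(names(fractions), counts)
}

#' Simulate time-resolved reactivity profiles
#'
#' Generates per-transcript, per-stage reactivity vectors with three planted
#' behaviors. Every transcript gets a right-skewed gamma baseline rescaled
#' so its median equals `baseline_median` exactly. `stable` transcripts keep
#' the baseline at all stages. `intramolecular` transcripts undergo balanced
#' remodeling inside the suppression window: one half of positions gains
#' `intra_delta`, an equal half loses it, so the per-nucleotide difference
#' median stays 0. `intermolecular` (dsRNA-target) transcripts have all
#' reactivities multiplied by `1 - suppression_fraction` inside the window,
#' the one-way suppression that duplex formation produces. Gaussian noise
#' (truncated at 0) and an i.i.d. missing-coverage mask are applied per
#' stage.
#'
#' @param config A [sim_config()].
#' @return A list with `reactivity` (long tibble: `transcript_id`, `stage`,
#'   `position`, `base` = `"N"`, `reactivity` with `NA` = missing) and
#'   `truth` (tibble: `transcript_id`, `class`).
#' @export
simulate_reactivity_series <- function(config = sim_config()) {
  stopifnot(inherits(config, "ds_sim_config"))
  set.seed(config$seed)
  stages <- config$stages
  lab <- unclass(stages)
  L <- config$transcript_length
  n <- config$n_transcripts
  classes <- quota_assign(n, c(
    intermolecular = config$fraction_dsrna_targets,
    intramolecular = config$fraction_intramolecular,
    stable = 1 - config$fraction_dsrna_targets - config$fraction_intramolecular
  ))
  classes <- sample(classes)
  ids <- sprintf("tx%04d", seq_len(n))
  w <- stage_rank(stages, config$suppression_window)
  in_window <- stage_rank(stages, lab) >= w[1] & stage_rank(stages, lab) <= w[2]

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    baseline <- stats::rgamma(L, shape = config$baseline_shape, rate = 1)
    baseline <- baseline * (config$baseline_median / stats::median(baseline))
    half <- floor(L / 2)
    if (classes[i] == "intramolecular") {
      eligible <- which(baseline >= config$intra_delta)
      down_idx <- sample(eligible, half)
      up_idx <- sample(setdiff(seq_len(L), down_idx), half)
    }
    stage_mats <- lapply(seq_along(lab), function(s) {
      mu <- baseline
      if (in_window[s]) {
        if (classes[i] == "intermolecular") {
          mu <- mu * (1 - config$suppression_fraction)
        } else if (classes[i] == "intramolecular") {
          mu[up_idx] <- mu[up_idx] + config$intra_delta
          mu[down_idx] <- mu[down_idx] - config$intra_delta
        }
      }
      y <- if (config$noise_sd > 0) {
        pmax(0, mu + stats::rnorm(L, 0, config$noise_sd))
      } else mu
      if (config$missing_rate > 0) {
        y[stats::runif(L) < config$missing_rate] <- NA_real_
      }
      y
    })
    rows[[i]] <- tibble::tibble(
      transcript_id = ids[i],
      stage = rep(lab, each = L),
      position = rep(seq_len(L), times = length(lab)),
      base = "N",
      reactivity = unlist(stage_mats)
    )
  }
  list(
    reactivity = dplyr::bind_rows(rows),
    truth = tibble::tibble(transcript_id = ids, class = classes)
  )
}

#' Draw strand-specific counts for one locus state
#'
#' One negative-binomial draw of locus output split across strands: a
#' shared gamma factor (mean 1, variance `dispersion`) scales both
#' strand means, then each strand count is Poisson. Marginally each strand
#' count is NB(mean, dispersion); jointly the strands share the locus-level
#' biological noise, so the antisense fraction behaves like a binomial
#' split of the locus output.
#'
#' @param n Number of draws.
#' @param sense_mean,antisense_mean Expected strand counts.
#' @param dispersion NB overdispersion (0 = Poisson).
#' @return A tibble with columns `sense`, `antisense`.
#' @export
sim_strand_counts <- function(n, sense_mean, antisense_mean, dispersion) {
  g <- if (dispersion > 0) {
    stats::rgamma(n, shape = 1 / dispersion, rate = 1 / dispersion)
  } else rep(1, n)
  tibble::tibble(
    sense = stats::rpois(n, g * sense_mean),
    antisense = stats::rpois(n, g * antisense_mean)
  )
}

#' Simulate a strand-specific count matrix
#'
#' Generates per-gene, per-stage sense/antisense counts. Gene categories
#' are quota-assigned: `activated` genes switch their antisense fraction
#' from the ~15% background to `induced_ratio_level` at a drawn activation
#' interval (concentrated in P->T0 and T0->T1) while their sense output
#' drops across that interval; `early` genes start with induced antisense
#' at V/P that decays to background (dynamic but not meiosis-specific);
#' the rest keep background antisense with pulsed, rising, declining or
#' constant sense trajectories. Counts come from [sim_strand_counts()].
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (tibble in [read_stranded_counts()] layout,
#'   with per-stage library sizes in the `library_size` attribute) and
#'   `truth` (tibble: `gene_id`, `category`, `interval_from`, `interval_to`,
#'   `interval`, `meiosis_specific`, `pulsed`, `dynamic`, `pulse_peak`).
#' @export
simulate_stranded_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "ds_sim_config"))
  set.seed(config$seed + 1L)
  stages <- config$stages
  lab <- unclass(stages)
  S <- length(lab)
  n <- config$n_genes
  b <- config$antisense_background
  lvl <- config$induced_ratio_level

  # quota over all genes: activated, early, then pulse/rising/declining/constant
  base_fracs <- c(activated = config$activated_fraction,
                  early = config$early_antisense_fraction,
                  pulsed = config$pulse_genes_fraction,
                  rising = config$rising_fraction,
                  declining = config$declining_fraction)
  base_fracs <- c(base_fracs, constant = 1 - sum(base_fracs))
  if (base_fracs[["constant"]] < 0) {
    stop("gene category fractions exceed 1", call. = FALSE)
  }
  category <- sample(quota_assign(n, base_fracs))
  ids <- sprintf("g%04d", seq_len(n))

  ints <- stage_intervals(stages)
  n_act <- sum(category == "activated")
  act_intervals <- sample(quota_assign(n_act, config$activation_interval_probs))

  ranks <- stage_rank(stages, lab)
  p_rank <- stage_rank(stages, lab[2])
  depth <- stats::rlnorm(n, config$depth_meanlog, config$depth_sdlog)
  lens <- pmax(200L, round(stats::rlnorm(n, config$gene_length_meanlog,
                                         config$gene_length_sdlog)))
  pulse_peak <- rep(NA_character_, n)

  rows <- vector("list", n)
  truth <- vector("list", n)
  i_act <- 0L
  for (i in seq_len(n)) {
    cat_i <- category[i]
    frac <- rep(b, S)
    mult <- rep(1, S)
    int_from <- NA_character_; int_to <- NA_character_
    if (cat_i == "activated") {
      i_act <- i_act + 1L
      iv <- ints[ints$interval == act_intervals[i_act], ]
      int_from <- iv$from; int_to <- iv$to
      to_rank <- stage_rank(stages, int_to)
      frac[ranks >= to_rank] <- lvl
      # NAT activation drives sense clearance across the same interval
      mult[ranks >= to_rank] <- 0.25
    } else if (cat_i == "early") {
      frac[ranks <= p_rank] <- lvl
    } else if (cat_i == "pulsed") {
      pk <- if (i %% 2 == 0) "P" else "T0"
      pulse_peak[i] <- pk
      mult[lab == pk] <- 6
    } else if (cat_i == "rising") {
      mult <- 0.4 * 1.35^ranks
    } else if (cat_i == "declining") {
      mult <- rev(0.4 * 1.35^ranks)
    }
    # mult shapes the sense trajectory; the antisense mean scales off it so
    # that the expected antisense fraction of locus output equals frac
    sense_mean <- depth[i] * mult
    anti_mean <- sense_mean * frac / (1 - frac)
    draws <- sim_strand_counts(S, sense_mean, anti_mean, config$dispersion)
    rows[[i]] <- tibble::tibble(
      gene_id = ids[i], stage = lab,
      sense_count = draws$sense, antisense_count = draws$antisense,
      length = lens[i], observed = TRUE
    )
    truth[[i]] <- tibble::tibble(
      gene_id = ids[i], category = cat_i,
      interval_from = int_from, interval_to = int_to,
      interval = if (is.na(int_from)) NA_character_ else
        paste0(int_from, "->", int_to),
      meiosis_specific = cat_i == "activated",
      pulsed = cat_i == "pulsed",
      dynamic = cat_i %in% c("activated", "early"),
      pulse_peak = pulse_peak[i]
    )
  }
  counts <- dplyr::bind_rows(rows)
  lib <- counts |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(library_size = sum(.data$sense_count) +
                       sum(.data$antisense_count), .groups = "drop")
  attr(counts, "library_size") <- lib
  list(counts = counts, truth = dplyr::bind_rows(truth))
}

#' Simulate z-scale expression trajectories with planted pulses
#'
#' Emits per-gene stage trajectories already on the z scale: pulsed genes
#' sit at a common low baseline and jump by `amplitude` z-units at a peak
#' stage inside the window (rise and fall of equal size); non-pulsed genes
#' are flat, monotone rising, monotone falling, or V-shaped (rebound)
#' trajectories spanning a comparable z range. Gaussian noise of sd
#' `noise_sd` is added everywhere.
#'
#' @param n Number of genes.
#' @param pulsed_fraction Quota fraction of pulsed genes.
#' @param amplitude Pulse height in z-units (default 2).
#' @param noise_sd Additive noise sd (default 0.2).
#' @param stages A [stage_series()].
#' @param window Pulse-peak window (default `c("P", "T1")`).
#' @param seed Integer seed.
#' @return A list with `z` (gene-by-stage matrix) and `truth` (tibble:
#'   `gene_id`, `pulsed`, `peak_stage`, `shape`).
#' @export
simulate_zscore_tracks <- function(n = 200L, pulsed_fraction = 0.2,
                                   amplitude = 2, noise_sd = 0.2,
                                   stages = stage_series(),
                                   window = c("P", "T1"), seed = 1L) {
  set.seed(seed)
  lab <- unclass(stages)
  S <- length(lab)
  assert_stages(stages, window, "window")
  w_lo <- stage_rank(stages, window[1])
  w_hi <- stage_rank(stages, window[2])
  shapes <- sample(quota_assign(n, c(
    pulsed = pulsed_fraction,
    flat = (1 - pulsed_fraction) * 0.25,
    rising = (1 - pulsed_fraction) * 0.25,
    falling = (1 - pulsed_fraction) * 0.25,
    rebound = (1 - pulsed_fraction) * 0.25
  )))
  peak_choices <- lab[seq(w_lo, w_hi) + 1L]
  z <- matrix(NA_real_, n, S, dimnames = list(sprintf("g%04d", seq_len(n)), lab))
  peak_stage <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    base <- switch(shapes[i],
      pulsed = {
        pk <- sample(peak_choices, 1)
        peak_stage[i] <- pk
        v <- rep(-amplitude / 4, S)
        v[lab == pk] <- amplitude * 3 / 4
        v
      },
      flat = rep(0, S),
      rising = seq(-1.5, 1.5, length.out = S),
      falling = seq(1.5, -1.5, length.out = S),
      rebound = {
        mid <- ceiling(S / 2)
        c(seq(1.5, -1.5, length.out = mid),
          seq(-1.5, 1.5, length.out = S - mid + 1)[-1])
      }
    )
    z[i, ] <- base + stats::rnorm(S, 0, noise_sd)
  }
  list(
    z = z,
    truth = tibble::tibble(gene_id = rownames(z), pulsed = shapes == "pulsed",
                           peak_stage = peak_stage, shape = shapes)
  )
}
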