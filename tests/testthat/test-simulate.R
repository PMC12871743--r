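test_that("simulation config validates fractions, windows and signal levels", {
  expect_error(sim_config(missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(induced_ratio_level = 0.10), "undetectable")
  expect_error(sim_config(fraction_dsrna_targets = 0.1, suppression_fraction = 0),
               "suppression_fraction")
  expect_error(sim_config(region_length = 50), "region_length")
  expect_error(sim_config(suppression_window = c("T1", "Z9")), "unknown")
  cfg <- sim_config()
  expect_equal(sum(cfg$activation_interval_probs), 1, tolerance = 1e-9)
  expect_equal(unname(cfg$activation_interval_probs[c("P->T0", "T0->T1")]),
               c(0.39, 0.39))
})

test_that("zero-noise reactivity classes are exact by construction", {
  cfg <- sim_config(n_transcripts = 12, transcript_length = 80,
                    fraction_dsrna_targets = 0.25, fraction_intramolecular = 0.25,
                    noise_sd = 0, missing_rate = 0, suppression_fraction = 0.6,
                    seed = 61)
  sim <- simulate_reactivity_series(cfg)
  wide <- tidyr::pivot_wider(sim$reactivity,
                             id_cols = c("transcript_id", "position"),
                             names_from = "stage", values_from = "reactivity")
  by_tx <- split(wide, wide$transcript_id)
  for (tx in sim$truth$transcript_id) {
    w <- by_tx[[tx]]
    cls <- sim$truth$class[sim$truth$transcript_id == tx]
    if (cls == "stable") {
      expect_equal(w$T4, w$V)                       # identical across stages
    } else if (cls == "intermolecular") {
      expect_equal(w$T4, 0.4 * w$V)                 # forced (1 - f) scaling
      expect_equal(w$T5, w$V)                       # window ends at T4
    } else {
      expect_equal(median(w$V - w$T4), 0)           # balanced +/- shifts
      expect_equal(sum(w$T4 > w$V), sum(w$T4 < w$V))
    }
    expect_equal(median(w$V), 0.5)                  # rescaled baseline median
  }
})

test_that("generator quotas and truth tables are exact and complete", {
  cfg <- sim_config(n_transcripts = 50, transcript_length = 30,
                    fraction_dsrna_targets = 0.08,
                    fraction_intramolecular = 0.12, seed = 62)
  sim <- simulate_reactivity_series(cfg)
  expect_equal(unname(table(sim$truth$class)["intermolecular"]), 4L)  # quota, not Bernoulli
  expect_equal(unname(table(sim$truth$class)["intramolecular"]), 6L)
  expect_identical(sort(unique(sim$reactivity$transcript_id)),
                   sort(sim$truth$transcript_id))

  simc <- simulate_stranded_counts(sim_config(n_genes = 100, seed = 62))
  expect_equal(nrow(simc$truth), 100)
  expect_identical(sort(unique(simc$counts$gene_id)),
                   sort(simc$truth$gene_id))
  expect_equal(sum(simc$truth$category == "activated"), 30)

  siml <- simulate_motif_tss_locus(sim_config(n_loci = 20, seed = 62))
  expect_equal(nrow(siml$truth), 20)
  expect_equal(sum(siml$truth$active), 10)
})

test_that("expected antisense fractions appear in deep noise-free counts", {
  cfg <- sim_config(n_genes = 40, dispersion = 0, depth_meanlog = log(5e4),
                    depth_sdlog = 0, activated_fraction = 0.5,
                    early_antisense_fraction = 0, pulse_genes_fraction = 0,
                    rising_fraction = 0, declining_fraction = 0, seed = 63)
  sim <- simulate_stranded_counts(cfg)
  rat <- antisense_ratio(tpm_normalize(sim$counts), tpm_floor = 0)
  j <- dplyr::left_join(rat, sim$truth, by = "gene_id")
  bg <- j[j$category == "constant", ]
  expect_equal(mean(bg$ratio), 0.15, tolerance = 0.01)
  act <- j[j$category == "activated" & j$stage == "T6", ]
  expect_equal(mean(act$ratio), 0.45, tolerance = 0.01)
  pre <- j[j$category == "activated" & j$stage == "V", ]
  expect_equal(mean(pre$ratio), 0.15, tolerance = 0.01)
})

test_that("strand counts match negative-binomial moments within 3 SE", {
  set.seed(64)
  n <- 10000
  mu_s <- 80; mu_a <- 20; disp <- 0.3
  draws <- sim_strand_counts(n, mu_s, mu_a, disp)
  for (col in c("sense", "antisense")) {
    mu <- if (col == "sense") mu_s else mu_a
    v <- mu + disp * mu^2                 # NB variance
    se_mean <- sqrt(v / n)
    expect_lt(abs(mean(draws[[col]]) - mu), 3 * se_mean)
    # SE of a sample variance ~ sqrt((kurtosis-ish)/n); use normal-theory bound
    se_var <- v * sqrt(2 / (n - 1)) * 2
    expect_lt(abs(var(draws[[col]]) - v), 3 * se_var)
  }
  # dispersion 0 reduces to Poisson
  p <- sim_strand_counts(n, 30, 10, 0)
  expect_lt(abs(var(p$sense) - 30), 3 * 30 * sqrt(2 / n) * 2)
})

test_that("planted loci obey geometry: offsets truncated, motifs scannable", {
  sim <- simulate_motif_tss_locus(sim_config(n_loci = 40, seed = 65))
  tr <- sim$truth[sim$truth$active, ]
  expect_true(all(tr$offset >= 0 & tr$offset <= 100))
  # TSS strand is opposite the gene strand
  genes <- sim$genes[match(tr$gene_id, sim$genes$gene_id), ]
  expect_true(all(tr$tss_strand != genes$strand))

  # rescanning with each PWM at its maximal score recovers exactly the
  # planted coordinates
  down <- extract_downstream_regions(sim$genes, sim$genome, 1000)
  for (m in c("URS1", "MSE")) {
    pwm <- if (m == "URS1") urs1_pwm() else mse_pwm()
    hits <- scan_regions(down, pwm, min_score_fraction = 0.999)
    want <- tr[tr$motif_id == m, ]
    expect_identical(sort(hits$start), sort(want$motif_start))
    expect_identical(hits$gene_id[order(hits$start)],
                     want$gene_id[order(want$motif_start)])
  }
})

test_that("noise-free locus reads all fall on the planted TSS coordinate", {
  sim <- simulate_motif_tss_locus(sim_config(n_loci = 10, tss_jitter_sd = 0,
                                             artifact_fraction = 0, seed = 66))
  tr <- sim$truth[sim$truth$active, ]
  for (i in seq_len(nrow(tr))) {
    e <- sim$ends[sim$ends$position == tr$tss_position[i] &
                    sim$ends$strand == tr$tss_strand[i], ]
    expect_equal(e$count, 20)  # reads_per_tss, all at one coordinate
  }
  expect_equal(sum(sim$ends$count), nrow(tr) * 20)
  # + strand gene: antisense 5' ends sit genomically below the motif start
  plus <- tr[tr$tss_strand == "-", ]
  expect_true(all(plus$tss_position <= plus$motif_start))
})

test_that("generators are deterministic: same config and seed, identical files", {
  cfg <- sim_config(n_transcripts = 6, transcript_length = 30, n_genes = 20,
                    n_loci = 8, seed = 67)
  d1 <- file.path(tempdir(), "sim_run1"); d2 <- file.path(tempdir(), "sim_run2")
  for (d in c(d1, d2)) {
    r <- simulate_reactivity_series(cfg)
    ct <- simulate_stranded_counts(cfg)
    lo <- simulate_motif_tss_locus(cfg)
    dir.create(d, showWarnings = FALSE)
    write_reactivity_table(r$reactivity, file.path(d, "reactivity.tsv"))
    write_stranded_counts(ct$counts, file.path(d, "counts.tsv"))
    write_locus_simulation(lo, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})
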