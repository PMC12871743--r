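two_stage <- stage_series(c("V", "P"))

counts_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    gene_id = vapply(rows, `[[`, "", 1),
    stage = vapply(rows, `[[`, "", 2),
    sense_count = as.numeric(vapply(rows, `[[`, "", 3)),
    antisense_count = as.numeric(vapply(rows, `[[`, "", 4)),
    length = as.numeric(vapply(rows, `[[`, "", 5)),
    observed = TRUE
  )
}

test_that("TPM normalization scales by length and conserves the per-stage total", {
  ct <- counts_tbl(c("g1", "V", 100, 0, 1000), c("g2", "V", 100, 0, 1000),
                   c("g1", "P", 50, 0, 1000), c("g2", "P", 50, 0, 1000))
  tpm <- tpm_normalize(ct, two_stage)
  expect_equal(tpm$sense_tpm, rep(5e5, 4))

  ct2 <- counts_tbl(c("g1", "V", 100, 0, 2000), c("g2", "V", 100, 0, 1000),
                    c("g1", "P", 100, 0, 2000), c("g2", "P", 100, 0, 1000))
  tpm2 <- tpm_normalize(ct2, two_stage)
  expect_equal(tpm2$sense_tpm[tpm2$gene_id == "g1"],
               tpm2$sense_tpm[tpm2$gene_id == "g2"] / 2)

  set.seed(21)
  st <- stage_series()
  rnd <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:20),
                            stage = unclass(st)) |>
    dplyr::mutate(sense_count = rpois(dplyr::n(), 50),
                  antisense_count = rpois(dplyr::n(), 10),
                  length = rep(sample(500:3000, 20), each = 9),
                  observed = TRUE)
  tpm3 <- tpm_normalize(rnd, st)
  sums <- tapply(tpm3$sense_tpm + tpm3$antisense_tpm, tpm3$stage, sum)
  expect_true(all(abs(sums - 1e6) < 1e-3))

  allzero <- counts_tbl(c("g1", "V", 0, 0, 1000), c("g1", "P", 5, 0, 1000))
  expect_error(tpm_normalize(allzero, two_stage), "zero total")
})

test_that("antisense ratios follow the floor rule and conserve fractions", {
  tpm <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), stage = "V",
    sense_tpm = c(80, 6, 0), antisense_tpm = c(20, 2, 50), observed = TRUE
  )
  r <- antisense_ratio(tpm, tpm_floor = 10)
  expect_equal(r$ratio, c(0.20, NA, 1.0))
  # sense fraction + antisense ratio = 1 wherever defined
  def <- !is.na(r$ratio)
  sense_frac <- tpm$sense_tpm / (tpm$sense_tpm + tpm$antisense_tpm)
  expect_equal(r$ratio[def] + sense_frac[def], rep(1, sum(def)))
})

test_that("raising the TPM floor never converts missing stages to defined", {
  set.seed(22)
  tpm <- tibble::tibble(
    gene_id = rep(sprintf("g%02d", 1:30), each = 3),
    stage = rep(c("V", "P", "T0"), 30),
    sense_tpm = runif(90, 0, 40), antisense_tpm = runif(90, 0, 10),
    observed = runif(90) > 0.1
  )
  floors <- c(0, 5, 10, 20, 40)
  defined <- lapply(floors, function(f) !is.na(antisense_ratio(tpm, f)$ratio))
  for (i in seq_along(floors)[-1]) {
    expect_true(all(defined[[i]] <= defined[[i - 1]]))
  }
})

test_that("dynamic-gene selection applies the change and missingness rules", {
  st <- stage_series()
  mk <- function(id, ratios) tibble::tibble(gene_id = id, stage = unclass(st),
                                            ratio = ratios)
  flat <- mk("flat", rep(0.15, 9))
  up <- mk("up", c(0.10, 0.10, 0.35, 0.35, 0.35, 0.35, 0.35, 0.35, 0.35))
  holey <- mk("holey", c(0.1, NA, 0.6, NA, 0.6, 0.6, 0.6, 0.6, 0.6))
  sel <- select_dynamic_genes(dplyr::bind_rows(flat, up, holey),
                              min_change = 0.20, max_missing = 1)
  expect_identical(sel$gene_id, "up")    # 0.25 > 0.20 in; flat out; 2 missing out
  expect_equal(sel$max_change, 0.25)
  # boundary: change of exactly 0.20 is excluded
  edge <- mk("edge", c(0.10, rep(0.30, 8)))
  expect_equal(nrow(select_dynamic_genes(edge, 0.20, 1)), 0)
})

test_that("activation calls find the largest increase with early tie-breaks", {
  st <- stage_series()
  r1 <- tibble::tibble(gene_id = "g1", stage = unclass(st),
                       ratio = c(0.15, 0.15, 0.45, 0.45, 0.45, 0.45, 0.45, 0.45, 0.45))
  a1 <- assign_activation(r1, st)
  expect_equal(a1$interval, "P->T0")
  expect_equal(a1$magnitude, 0.30)
  expect_true(a1$meiosis_specific)

  # early-high pattern: sharp decrease, no activation, not meiosis-specific
  r2 <- tibble::tibble(gene_id = "g2", stage = unclass(st),
                       ratio = c(0.48, 0.48, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10))
  a2 <- assign_activation(r2, st)
  expect_false(a2$called)
  expect_false(a2$meiosis_specific)

  # tie between two equal increases resolves to the earliest interval
  # (binary-fraction ratios so the two increases are bitwise equal)
  r3 <- tibble::tibble(gene_id = "g3", stage = unclass(st),
                       ratio = c(0.125, 0.125, 0.375, 0.375, 0.625,
                                 0.625, 0.625, 0.625, 0.625))
  expect_equal(assign_activation(r3, st)$interval, "P->T0")

  # activation interval spans consecutive *defined* stages across a gap
  r4 <- tibble::tibble(gene_id = "g4", stage = unclass(st),
                       ratio = c(0.15, 0.15, NA, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(assign_activation(r4, st)$interval, "P->T1")
})

test_that("activation recovery meets the synthetic-truth bounds", {
  sim <- simulate_stranded_counts(sim_config(n_genes = 400, seed = 31))
  rat <- antisense_ratio(tpm_normalize(sim$counts))
  act <- assign_activation(rat)
  j <- dplyr::inner_join(act, sim$truth, by = "gene_id")
  acted <- j[j$category == "activated", ]
  expect_gte(mean(acted$interval.x == acted$interval.y, na.rm = TRUE), 0.90)
  dyn <- select_dynamic_genes(rat)
  jd <- j[j$gene_id %in% dyn$gene_id, ]
  expect_gte(mean(jd$meiosis_specific.x == jd$meiosis_specific.y), 0.95)
})

test_that("centroid clustering merges identical and affine-equivalent rows first", {
  m <- rbind(a = c(1, 2, 3, 4, 3, 2, 1, 1, 1),
             b = c(1, 2, 3, 4, 3, 2, 1, 1, 1),
             c = c(9, 1, 9, 1, 9, 1, 9, 1, 9))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$merge[1, ], c(-2, -1))
  expect_equal(hc$height[1], 0)

  m2 <- rbind(a = c(1, 2, 3, 4, 3, 2, 1, 1, 1),
              b = 2 * c(1, 2, 3, 4, 3, 2, 1, 1, 1) + 3,  # positive affine
              c = c(9, 1, 9, 1, 9, 1, 9, 1, 9))
  hc2 <- hierarchical_cluster(m2)
  expect_equal(hc2$height[1], 0)           # Pearson affine invariance

  expect_warning(hierarchical_cluster(rbind(m, d = rep(1, 9))), "constant")
})

test_that("clustering matches the naive centroid agglomerator on random instances", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(4:6, 1)
    m <- matrix(rnorm(n * 6), n, 6)
    rownames(m) <- paste0("r", seq_len(n))
    got <- hierarchical_cluster(m)
    want <- naive_centroid_cluster(m)
    expect_identical(got$merge, want$merge)
    expect_equal(got$height, want$height, tolerance = 1e-12)
  }
})

test_that("a 2-cut recovers planted step-up and pulse archetypes exactly", {
  set.seed(24)
  step_up <- c(0, 0, 0, 1, 1, 1, 1, 1, 1)
  pulse <- c(0, 1, 0, 0, 0, 0, 0, 0, 0)
  m <- rbind(
    t(vapply(1:3, function(i) step_up + rnorm(9, 0, 0.02), numeric(9))),
    t(vapply(1:3, function(i) pulse + rnorm(9, 0, 0.02), numeric(9)))
  )
  rownames(m) <- paste0("g", 1:6)
  cl <- cut_clusters(hierarchical_cluster(m), 2)
  expect_equal(rand_index_adjusted(cl$cluster, rep(1:2, each = 3)), 1)
  # glance reports the tree shape
  g <- glance(hierarchical_cluster(m))
  expect_equal(g$n_leaves, 6)
  expect_equal(g$n_merges, 5)
})
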