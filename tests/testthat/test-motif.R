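test_that("consensus columns distribute probability over allowed bases", {
  pA <- consensus_to_pwm("A", eps = 0.01)
  expect_equal(unname(pA[, 1]), c(0.97, 0.01, 0.01, 0.01))
  pN <- consensus_to_pwm("N", eps = 0.01)
  expect_equal(unname(pN[, 1]), rep(0.25, 4))
  pR <- consensus_to_pwm("R", eps = 0.01)
  expect_equal(unname(pR[, 1]), c(0.49, 0.01, 0.49, 0.01))
  expect_error(consensus_to_pwm("AXG"), "invalid IUPAC")
  expect_error(consensus_to_pwm("A", eps = 0.3), "eps")
  expect_true(all(abs(colSums(mse_pwm()) - 1) < 1e-9))
})

test_that("a consensus-derived PWM scores its own consensus at fraction 1", {
  hits <- scan_pwm("TCGGCGGCTA", urs1_pwm(), min_score_fraction = 0.99, "+")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 0L)
  expect_equal(hits$score_fraction, 1.0)
  # any realization of a degenerate consensus also reaches fraction 1
  hits2 <- scan_pwm("GACACAAAT", mse_pwm(), min_score_fraction = 0.999, "+")
  expect_equal(hits2$score_fraction, 1.0)
})

test_that("scan scores equal brute-force per-window log-odds on a 2-kb sequence", {
  set.seed(41)
  seq2k <- paste(sample(c("A", "C", "G", "T", "N"), 2000, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
  pwm <- mse_pwm()
  all_hits <- scan_pwm(seq2k, pwm, min_score_fraction = -Inf, "+")
  want <- scan_oracle(seq2k, unclass(pwm))
  expect_equal(all_hits$score, want, tolerance = 1e-12)

  # and on the minus strand via the reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq2k)))
  minus <- scan_pwm(seq2k, pwm, min_score_fraction = -Inf, "-")
  want_rc <- scan_oracle(rc, unclass(pwm))
  expect_equal(sort(minus$score), sort(want_rc), tolerance = 1e-12)
})

test_that("reverse-complementing the sequence mirrors hits with equal scores", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  pwm <- urs1_pwm()
  h1 <- scan_pwm(s, pwm, min_score_fraction = 0.3, "both")
  h2 <- scan_pwm(rc, pwm, min_score_fraction = 0.3, "both")
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-12)
  # a + hit at [p, p+W) mirrors to a - hit at [n-p-W, n-p) and vice versa
  expect_setequal(500 - h1$end[h1$strand == "+"], h2$start[h2$strand == "-"])
  expect_setequal(500 - h1$end[h1$strand == "-"], h2$start[h2$strand == "+"])
})

test_that("scanning a sequence shorter than the motif yields no hits", {
  expect_equal(nrow(scan_pwm("ACGT", urs1_pwm(), 0, "both")), 0)
})

test_that("downstream/upstream regions follow the strand conventions", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), length.out = 6000), collapse = "")))
  genes <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(4000L, 5000L), end = c(5000L, 5800L), strand = c("+", "-")
  )
  down <- extract_downstream_regions(genes[1, ], genome, 1000)
  expect_equal(c(down$start, down$end), c(5000L, 6000L))
  expect_false(down$truncated)

  down_m <- extract_downstream_regions(genes[2, ], genome, 1000)
  expect_equal(c(down_m$start, down_m$end), c(4000L, 5000L))
  fwd <- as.character(Biostrings::subseq(genome[[1]], 4001, 5000))
  expect_equal(down_m$seq,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd))))

  # truncation at the chromosome edge
  near_end <- tibble::tibble(gene_id = "e", chrom = "chr1", start = 4000L,
                             end = 5700L, strand = "+")
  tr <- extract_downstream_regions(near_end, genome, 1000)
  expect_true(tr$truncated)
  expect_equal(nchar(tr$seq), 300)

  out <- tibble::tibble(gene_id = "x", chrom = "chr1", start = 5000L,
                        end = 7000L, strand = "+")
  expect_error(extract_downstream_regions(out, genome, 1000), "bounds")
})

test_that("region-local hits round-trip to genome coordinates and back", {
  set.seed(43)
  chars <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
  # plant URS1 reverse-complemented downstream of a + gene (NAT-strand element)
  planted_at <- 3100
  chars[(planted_at + 1):(planted_at + 10)] <-
    strsplit("TAGCCGCCGA", "")[[1]]  # revcomp of TCGGCGGCTA
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 2000L,
                          end = 3000L, strand = "+")
  regions <- extract_downstream_regions(genes, genome, 1000)
  hits <- scan_regions(regions, urs1_pwm(), 0.95)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, planted_at)
  expect_equal(hits$strand, "-")
  # re-extracting the genomic window recovers the planted element
  window <- as.character(Biostrings::subseq(genome[[1]], hits$start + 1, hits$end))
  expect_equal(window, "TAGCCGCCGA")
})

test_that("enrichment p-values equal exhaustive enumeration", {
  mk_regions <- function(n, with_motif) {
    tibble::tibble(
      gene_id = paste0("r", seq_len(n)),
      seq = vapply(seq_len(n), function(i) {
        s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
        if (i <= with_motif) s <- paste0(s, "TCGGCGGCTA") else s
      }, character(1))
    )
  }
  set.seed(44)
  for (i in 1:20) {
    n_fg <- sample(3:12, 1); n_bg <- sample(5:18, 1)
    k_fg <- sample(0:n_fg, 1); k_bg <- sample(0:n_bg, 1)
    fg <- mk_regions(n_fg, k_fg); bg <- mk_regions(n_bg, k_bg)
    got <- motif_enrichment(fg, bg, urs1_pwm(), 0.95)
    # scanning may only find the planted motifs in these short random seqs
    expect_equal(got$fg_positive, k_fg)
    expect_equal(got$p_value,
                 hyper_tail_oracle(k_fg, n_fg, k_bg, n_bg), tolerance = 1e-12)
  }
  # published-style table: urn 10 success / 90 failure, draw 10, >= 4 successes
  expect_equal(hyper_tail_oracle(4, 10, 6, 90),
               phyper(3, 10, 90, 10, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("odds ratios are 1 at equal rates and finite under Haldane correction", {
  base <- paste(rep("A", 50), collapse = "")
  pos <- paste0(base, "TCGGCGGCTA")
  fg <- tibble::tibble(gene_id = c("a", "b"), seq = c(pos, base))
  bg <- tibble::tibble(gene_id = c("c", "d"), seq = c(pos, base))
  expect_equal(motif_enrichment(fg, bg, urs1_pwm(), 0.95)$odds_ratio, 1)

  fg_all <- tibble::tibble(gene_id = c("a", "b"), seq = c(pos, pos))
  bg_none <- tibble::tibble(gene_id = c("c", "d"), seq = c(base, base))
  got <- motif_enrichment(fg_all, bg_none, urs1_pwm(), 0.95)
  expect_true(is.finite(got$odds_ratio) && got$odds_ratio > 1)
  expect_equal(got$p_value, 1 / choose(4, 2), tolerance = 1e-12)
  expect_error(motif_enrichment(fg_all[0, ], bg_none, urs1_pwm()), "non-empty")
})

test_that("TSS clusters merge, choose modal representatives and filter", {
  mk_ends <- function(pos, count, strand = "-") {
    tibble::tibble(chrom = "chr1", position = as.integer(pos),
                   strand = strand, count = as.numeric(count))
  }
  one <- call_tss_clusters(mk_ends(100, 5), min_count = 5, merge_window = 10)
  expect_equal(one$position, 100)
  expect_equal(one$read_count, 5)

  merged <- call_tss_clusters(mk_ends(c(100, 104), c(3, 2)), 5, 10)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$read_count, 5)
  expect_equal(merged$position, 100)  # mode

  # modal tie on the minus strand resolves to the 5'-most = highest coordinate
  tie <- call_tss_clusters(mk_ends(c(100, 104), c(3, 3)), 5, 10)
  expect_equal(tie$position, 104)
  tie_plus <- call_tss_clusters(mk_ends(c(100, 104), c(3, 3), "+"), 5, 10)
  expect_equal(tie_plus$position, 100)

  two <- call_tss_clusters(mk_ends(c(100, 200), c(3, 3)), 1, 10)
  expect_equal(nrow(two), 2)
  below <- call_tss_clusters(mk_ends(100, 4), min_count = 5, merge_window = 10)
  expect_equal(nrow(below), 0)
})

test_that("motif-TSS links honor the offset convention on both strands", {
  genes <- tibble::tibble(gene_id = c("plus", "minus"), chrom = "chr1",
                          start = c(4000L, 8000L), end = c(5000L, 9000L),
                          strand = c("+", "-"))
  hits <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = "chr1",
    start = c(5100L, 7500L), end = c(5110L, 7510L),
    strand = c("-", "+"), score = 15, score_fraction = 0.99, motif_id = "URS1"
  )
  tss <- tibble::tibble(chrom = "chr1", position = c(5050L, 7559L),
                        strand = c("-", "+"), read_count = 20,
                        window_start = 0L, window_end = 1L)
  links <- link_motifs_to_tss(genes, hits, tss, max_distance = 100)
  expect_equal(nrow(links), 2)
  expect_equal(links$offset[links$gene_id == "plus"], 50)   # 5100 - 5050
  expect_equal(links$offset[links$gene_id == "minus"], 50)  # 7559 - 7510 + 1
  expect_equal(attr(links, "linked_fraction"), 1)

  far <- tss; far$position <- c(4950L, 7700L)
  none <- link_motifs_to_tss(genes, hits, far, max_distance = 100)
  expect_equal(nrow(none), 0)  # offsets 150 and 191 exceed the limit
})
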