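URS1_CONSENSUS <- "TCGGCGGCTA"
MSE_CONSENSUS <- "GNCRCAAAW"

realize_iupac <- function(iupac) {
  chars <- strsplit(iupac, "")[[1]]
  paste(vapply(chars, function(ch) {
    allowed <- IUPAC_SETS[[ch]]
    if (length(allowed) == 1) allowed else sample(allowed, 1)
  }, character(1)), collapse = "")
}

iupac_match_ranges <- function(genome_chars, patterns) {
  subject <- Biostrings::DNAString(paste(genome_chars, collapse = ""))
  out <- list()
  for (pat in patterns) {
    for (p in c(pat, revcomp_chr(pat))) {
      m <- Biostrings::matchPattern(p, subject, fixed = FALSE)
      if (length(m) > 0) {
        out[[length(out) + 1]] <- cbind(BiocGenerics::start(m),
                                        BiocGenerics::end(m))
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, out))
}

# Remove every IUPAC occurrence of the motif patterns (both strands) outside
# the protected windows by redrawing the offending unprotected bases. Keeps
# the planted elements as the only matches, for any seed.
scrub_motifs <- function(genome_chars, patterns, protected = NULL,
                         max_iter = 100L) {
  is_protected <- rep(FALSE, length(genome_chars))
  if (!is.null(protected) && nrow(protected) > 0) {
    for (r in seq_len(nrow(protected))) {
      is_protected[seq(protected[r, 1], protected[r, 2])] <- TRUE
    }
  }
  for (iter in seq_len(max_iter)) {
    hits <- iupac_match_ranges(genome_chars, patterns)
    if (nrow(hits) == 0) return(genome_chars)
    spurious <- FALSE
    for (r in seq_len(nrow(hits))) {
      span <- seq(hits[r, 1], hits[r, 2])
      redraw <- span[!is_protected[span]]
      if (length(redraw) > 0) {
        spurious <- TRUE
        genome_chars[redraw] <- sample(c("A", "C", "G", "T"),
                                       length(redraw), replace = TRUE)
      }
    }
    if (!spurious) return(genome_chars)  # only planted matches remain
  }
  stop("failed to scrub spurious motif occurrences", call. = FALSE)
}

#' Simulate gene loci with planted antisense promoters and TSS reads
#'
#' Builds a uniform-background genome carrying non-overlapping gene loci on
#' both strands. A quota of loci is antisense-active: the exact URS1
#' consensus or a realization of the MSE consensus is planted in the 1-kb
#' region past the gene's 3' end, a true antisense TSS is placed at a
#' geometric offset (mean `tss_offset_mean`, truncated at `tss_offset_max`)
#' downstream of the element in the antisense transcription direction, and
#' `reads_per_tss` strand-tagged 5'-end reads are emitted around the TSS
#' with Gaussian jitter plus uniformly scattered artifact ends. A quota of
#' the MSE-active loci additionally carries a URS1 element in the upstream
#' (sense-promoter) region, forming convergent-promoter loci. Outside the
#' planted sites the genome is scrubbed free of IUPAC occurrences of both
#' elements, so planted coordinates are the only scan hits at stringent
#' thresholds regardless of seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (one-chromosome
#'   `Biostrings::DNAStringSet`), `genes` (gene-model tibble), `ends`
#'   (5'-end tibble as from [read_5prime_bed()]) and `truth` (tibble:
#'   `gene_id`, `active`, `motif_id`, `motif_start`, `motif_end`,
#'   `motif_strand`, `tss_position`, `tss_strand`, `offset`,
#'   `urs1_upstream_start`, `convergent`).
#' @export
simulate_motif_tss_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "ds_sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_loci
  RL <- config$region_length
  GL <- config$gene_length
  slot <- RL + GL + RL + config$locus_spacing
  margin <- 1000L
  genome_len <- margin + n * slot + margin
  genome_chars <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

  strand <- rep(c("+", "-"), length.out = n)
  slot_start <- margin + (seq_len(n) - 1L) * slot
  gene_start <- slot_start + RL          # 0-based
  gene_end <- gene_start + GL
  genes <- tibble::tibble(
    gene_id = sprintf("locus%03d", seq_len(n)),
    chrom = "chr1",
    start = gene_start, end = gene_end,
    strand = strand, length = GL
  )

  active <- sample(quota_assign(n, c(yes = config$antisense_active_fraction,
                                     no = 1 - config$antisense_active_fraction)))
  active <- active == "yes"
  motif_id <- rep(NA_character_, n)
  motif_id[active] <- sample(quota_assign(sum(active),
                                          c(URS1 = 0.5, MSE = 0.5)))
  n_conv <- round(config$convergent_fraction * n)
  mse_loci <- which(active & motif_id == "MSE")
  if (n_conv > length(mse_loci)) {
    stop("convergent_fraction exceeds the MSE-active share of loci",
         call. = FALSE)
  }
  convergent <- rep(FALSE, n)
  convergent[sample(mse_loci, n_conv)] <- TRUE

  draw_offset <- function() {
    repeat {
      o <- stats::rgeom(1, 1 / (config$tss_offset_mean + 1))
      if (o <= config$tss_offset_max) return(o)
    }
  }

  plant <- function(chars, start0, seq_chr) {
    # start0 is 0-based genomic; returns modified character vector
    idx <- seq(start0 + 1L, start0 + nchar(seq_chr))
    chars[idx] <- strsplit(seq_chr, "")[[1]]
    chars
  }

  motif_start <- rep(NA_integer_, n); motif_end <- rep(NA_integer_, n)
  motif_strand <- rep(NA_character_, n)
  tss_position <- rep(NA_integer_, n); tss_strand <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  urs1_up_start <- rep(NA_integer_, n)
  protected <- list()

  for (i in seq_len(n)) {
    if (!active[i]) next
    consensus <- if (motif_id[i] == "URS1") URS1_CONSENSUS else
      realize_iupac(MSE_CONSENSUS)
    W <- nchar(consensus)
    o <- draw_offset()
    if (strand[i] == "+") {
      # antisense transcript runs -, downstream region is [gene_end, +RL)
      ms <- gene_end[i] + config$tss_offset_max +
        sample.int(RL - config$tss_offset_max - W + 1L, 1) - 1L
      motif_strand[i] <- "-"            # element read on the NAT strand
      genome_chars <- plant(genome_chars, ms, revcomp_chr(consensus))
      tss_position[i] <- ms - o
      tss_strand[i] <- "-"
    } else {
      # antisense transcript runs +, downstream region is [start - RL, start)
      region_start <- gene_start[i] - RL
      ms <- region_start + sample.int(RL - config$tss_offset_max - W + 1L, 1) - 1L
      motif_strand[i] <- "+"
      genome_chars <- plant(genome_chars, ms, consensus)
      tss_position[i] <- ms + W - 1L + o
      tss_strand[i] <- "+"
    }
    motif_start[i] <- ms
    motif_end[i] <- ms + W
    offset[i] <- o
    protected[[length(protected) + 1]] <- c(ms + 1L, ms + W)

    if (convergent[i]) {
      # sense-promoter URS1 in the upstream region, on the gene's own strand
      W1 <- nchar(URS1_CONSENSUS)
      if (strand[i] == "+") {
        us <- slot_start[i] + sample.int(RL - W1 + 1L, 1) - 1L
        genome_chars <- plant(genome_chars, us, URS1_CONSENSUS)
      } else {
        us <- gene_end[i] + sample.int(RL - W1 + 1L, 1) - 1L
        genome_chars <- plant(genome_chars, us, revcomp_chr(URS1_CONSENSUS))
      }
      urs1_up_start[i] <- us
      protected[[length(protected) + 1]] <- c(us + 1L, us + W1)
    }
  }

  prot_mat <- if (length(protected) > 0) do.call(rbind, protected) else NULL
  genome_chars <- scrub_motifs(genome_chars,
                               c(URS1_CONSENSUS, MSE_CONSENSUS), prot_mat)

  # strand-tagged read 5' ends: jittered true starts + scattered artifacts
  end_rows <- list()
  for (i in which(active)) {
    jit <- if (config$tss_jitter_sd > 0) {
      round(stats::rnorm(config$reads_per_tss, 0, config$tss_jitter_sd))
    } else rep(0L, config$reads_per_tss)
    pos <- pmin(pmax(tss_position[i] + jit, 0L), genome_len - 1L)
    end_rows[[length(end_rows) + 1]] <- tibble::tibble(
      chrom = "chr1", position = as.integer(pos), strand = tss_strand[i]
    )
  }
  true_ends <- dplyr::bind_rows(end_rows)
  n_true <- nrow(true_ends)
  n_art <- round(config$artifact_fraction /
                   max(1 - config$artifact_fraction, 1e-12) * n_true)
  if (n_art > 0) {
    art <- tibble::tibble(
      chrom = "chr1",
      position = sample.int(genome_len, n_art) - 1L,
      strand = sample(c("+", "-"), n_art, replace = TRUE)
    )
    true_ends <- dplyr::bind_rows(true_ends, art)
  }
  ends <- true_ends |>
    dplyr::count(.data$chrom, .data$position, .data$strand, name = "count") |>
    dplyr::mutate(count = as.numeric(.data$count)) |>
    dplyr::arrange(.data$chrom, .data$strand, .data$position)

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(genome_chars, collapse = ""), "chr1"))

  list(
    genome = genome,
    genes = genes,
    ends = ends,
    truth = tibble::tibble(
      gene_id = genes$gene_id, active = active, motif_id = motif_id,
      motif_start = motif_start, motif_end = motif_end,
      motif_strand = motif_strand, tss_position = tss_position,
      tss_strand = tss_strand, offset = offset,
      urs1_upstream_start = urs1_up_start, convergent = convergent
    )
  )
}

#' Write a simulated locus cohort to disk
#'
#' Emits the file formats the readers accept: genome FASTA, gene models
#' BED6, read 5' ends BED6 and the ground-truth table as TSV. Output is
#' byte-stable for a fixed configuration and seed.
#'
#' @param sim Result of [simulate_motif_tss_locus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_locus_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    ends = file.path(dir, "five_prime_ends.bed"),
    truth = file.path(dir, "locus_truth.tsv")
  )
  Biostrings::writeXStringSet(sim$genome, paths[["genome"]])
  write_gene_models_bed(sim$genes, paths[["genes"]])
  write_5prime_bed(sim$ends, paths[["ends"]])
  readr::write_tsv(sim$truth, paths[["truth"]], na = "NA", progress = FALSE)
  invisible(paths)
}
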