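# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-derivations from first principles, kept free of package internals.

options(meiodsrna.verbose = FALSE)

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

reactivity_lines <- function(rows) {
  c("transcript_id\tstage\tposition\tbase\treactivity",
    vapply(rows, function(r) paste(r, collapse = "\t"), character(1)))
}

# Pearson correlation straight from the covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# sort-and-pick-middle median
median_oracle <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# per-window log-odds scan by explicit double loop
scan_oracle <- function(sequence, prob, background = 0.25) {
  chars <- strsplit(sequence, "")[[1]]
  W <- ncol(prob)
  n <- length(chars)
  if (n < W) return(numeric(0))
  vapply(seq_len(n - W + 1), function(i) {
    s <- 0
    for (w in seq_len(W)) {
      ch <- chars[i + w - 1]
      s <- s + if (ch == "N") 0 else log2(prob[ch, w] / background)
    }
    s
  }, numeric(1))
}

# hypergeometric upper tail by exhaustive enumeration with choose()
hyper_tail_oracle <- function(k_fg, n_fg, k_bg, n_bg) {
  K <- k_fg + k_bg
  N <- n_fg + n_bg
  ks <- k_fg:min(K, n_fg)
  sum(choose(K, ks) * choose(N - K, n_fg - ks)) / choose(N, n_fg)
}

# centroid-linkage agglomeration recomputed from scratch each step
naive_centroid_cluster <- function(x) {
  n <- nrow(x)
  cor_dist <- function(a, b) {
    keep <- !is.na(a) & !is.na(b)
    if (sum(keep) < 2) return(2)
    a <- a[keep]; b <- b[keep]
    if (sd(a) == 0 || sd(b) == 0) return(2)
    1 - pearson_oracle(a, b)
  }
  members <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        ci <- colMeans(x[members[[i]], , drop = FALSE], na.rm = TRUE)
        cj <- colMeans(x[members[[j]], , drop = FALSE], na.rm = TRUE)
        ci[is.nan(ci)] <- NA; cj[is.nan(cj)] <- NA
        d <- cor_dist(ci, cj)
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best[1]
    members[[i]] <- c(members[[i]], members[[j]])
    ids[i] <- step
    members[[j]] <- NULL
    ids <- ids[-j]
  }
  list(merge = merge, height = height)
}

rand_index_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a_comb <- sum_comb(rowSums(tab))
  b_comb <- sum_comb(colSums(tab))
  idx <- sum_comb(as.vector(tab))
  exp_idx <- a_comb * b_comb / choose(n, 2)
  max_idx <- (a_comb + b_comb) / 2
  (idx - exp_idx) / (max_idx - exp_idx)
}
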