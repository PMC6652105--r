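# Independent oracles and small fixture generators shared across tests.

# Direct series summation of the Poisson upper tail P(X >= k), in log space.
poisson_tail_oracle <- function(k, lam) {
  if (k == 0) return(1)
  i <- seq(k, k + max(2000, ceiling(10 * lam + 10 * sqrt(lam))))
  sum(exp(i * log(lam) - lam - lgamma(i + 1)))
}

# Hand application of the Benjamini-Hochberg step-up formula.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force two-sample KS distance: max ECDF difference over all points.
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(t) mean(x <= t), 0)
  Fy <- vapply(pts, function(t) mean(y <= t), 0)
  max(abs(Fx - Fy))
}

# Row-pair overlap check by naive arithmetic (no interval machinery).
naive_overlaps1 <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# O(n*m) all-pairs overlap filter: rows of `a` overlapping >= 1 row of `b`.
naive_overlap_filter <- function(a, b) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (naive_overlaps1(a[i, ], b[j, ])) { keep[i] <- TRUE; break }
    }
  }
  which(keep)
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"), L = 1e5,
                             max_len = 2000) {
  withr::with_seed(seed, {
    start <- floor(runif(n, 0, L - max_len))
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start,
               end = start + 1 + floor(runif(n, 0, max_len - 1)),
               strand = ".",
               stringsAsFactors = FALSE)
  })
}

random_peaks <- function(n, seed, chroms = c("chr1", "chr2"), L = 1e5) {
  df <- random_intervals(n, seed, chroms, L)
  withr::with_seed(seed + 1, {
    df$name <- sprintf("p%03d", seq_len(n))
    df$score <- round(runif(n, 0, 50), 3)
  })
  df
}

# Desk-scale config for fast end-to-end tests.
small_cfg <- function(...) {
  args <- list(n_chroms = 1, chrom_length = 1e6, n_genes = 100,
               n_regulated = 12, bead_sites = 10, library_size = 4e4)
  over <- list(...)
  do.call(sim_config, c(over, args[!names(args) %in% names(over)]))
}
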