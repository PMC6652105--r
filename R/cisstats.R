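#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the
#' p-value is asymptotic by default (the pipeline regime, set sizes ~36 vs
#' thousands). `exact = TRUE` requests the exact null distribution (small
#' samples; used by the test oracles).
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact Use the exact p-value (default `FALSE` = asymptotic).
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) < 1 || length(y) < 1)
    stop("ks_two_sample: both samples must be non-empty")
  kt <- suppressWarnings(ks.test(x, y, exact = exact))
  if (kt$statistic == 0) return(list(D = 0, p = 1))
  list(D = unname(kt$statistic), p = min(1, max(kt$p.value, 0)))
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) statistic with two-sided p. Degenerate inputs
#' (both samples constant) return `t = 0, p = 1` when equal and
#' `p = 0` with a warning when unequal.
#'
#' @param x,y Numeric samples of length >= 2.
#' @param paired Paired test (equal lengths required).
#' @return List with `t` and `p`.
#' @export
welch_t_test <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (!paired && stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    warning("welch_t_test: both samples constant but unequal; p -> 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Compare target-gene fold changes to the background
#'
#' The background is the full FC table (targets included); reports both
#' medians and the two-sample KS comparison of target vs background FC
#' values.
#'
#' @param fc_table FC table from [fold_change()].
#' @param target_genes Character vector of >= 2 gene ids, all present in
#'   the table.
#' @return List: `median_target`, `median_background`, `D`, `p`,
#'   `n_target`, `n_background`.
#' @export
compare_target_to_background <- function(fc_table, target_genes) {
  missing <- setdiff(target_genes, fc_table$gene_id)
  if (length(missing) > 0)
    stop("compare_target_to_background: targets missing from the FC table: ",
         paste(missing, collapse = ", "))
  if (length(target_genes) < 2)
    stop("compare_target_to_background: need >= 2 target genes")
  tf <- fc_table$fc[fc_table$gene_id %in% target_genes]
  bf <- fc_table$fc
  ks <- ks_two_sample(tf, bf)
  list(median_target = median(tf), median_background = median(bf),
       D = ks$D, p = ks$p, n_target = length(tf), n_background = length(bf))
}

#' Permutation-scheme configuration
#'
#' @param n_cycles Number of cycles (default 10).
#' @param n_perm Permutations per cycle (default 100).
#' @param set_size Size of each random gene set (default 36).
#' @param exclude_targets_from_draws Exclude target genes from the random
#'   pool (default `FALSE`: draws come from the full table).
#' @param seed Root seed; each cycle gets an independently derived stream.
#' @return A list of class `perm_config`.
#' @export
perm_config <- function(n_cycles = 10, n_perm = 100, set_size = 36,
                        exclude_targets_from_draws = FALSE, seed = 1) {
  stopifnot(n_cycles >= 1, n_perm >= 1, set_size >= 2)
  structure(list(n_cycles = n_cycles, n_perm = n_perm, set_size = set_size,
                 exclude_targets_from_draws = exclude_targets_from_draws,
                 seed = seed),
            class = "perm_config")
}

#' Cycle-structured permutation scheme for cis-regulatory effect
#'
#' Runs `n_cycles` cycles of `n_perm` permutations. In every permutation
#' the target-set FC values are compared by two-sample KS against the FC
#' of a freshly drawn random set of `set_size` genes (without
#' replacement), giving one `p_empirical`; two further independent random
#' sets are compared to each other, giving one `p_random`. Under no
#' target effect the two collections are exchangeable; a genuine shift in
#' the target set drives `p_empirical` below `p_random`.
#'
#' @param fc_table FC table from [fold_change()].
#' @param target_genes Target gene ids (all present in the table).
#' @param cfg A [perm_config()].
#' @return List of class `perm_result`: matrices `p_empirical` and
#'   `p_random` (`n_cycles` x `n_perm`), `per_cycle` data frame of
#'   medians, and `summary` with `frac_empirical_lt_random` (fraction of
#'   paired draws with p_empirical < p_random) and the pooled KS
#'   comparison (`ks_D`, `ks_p`).
#' @export
permutation_scheme <- function(fc_table, target_genes, cfg = perm_config()) {
  missing <- setdiff(target_genes, fc_table$gene_id)
  if (length(missing) > 0)
    stop("permutation_scheme: targets missing from the FC table: ",
         paste(missing, collapse = ", "))
  fc <- setNames(fc_table$fc, fc_table$gene_id)
  target_fc <- fc[target_genes]
  pool <- if (cfg$exclude_targets_from_draws)
    fc[!names(fc) %in% target_genes] else fc
  if (cfg$set_size > length(pool))
    stop("permutation_scheme: set_size exceeds the available gene pool")
  p_emp <- p_rnd <- matrix(NA_real_, cfg$n_cycles, cfg$n_perm)
  cycle_seeds <- withr::with_seed(cfg$seed,
    sample.int(.Machine$integer.max - 1, cfg$n_cycles))
  for (cy in seq_len(cfg$n_cycles)) {
    withr::with_seed(cycle_seeds[cy], {
      for (pm in seq_len(cfg$n_perm)) {
        r1 <- pool[sample.int(length(pool), cfg$set_size)]
        p_emp[cy, pm] <- ks_two_sample(target_fc, r1)$p
        r2 <- pool[sample.int(length(pool), cfg$set_size)]
        r3 <- pool[sample.int(length(pool), cfg$set_size)]
        p_rnd[cy, pm] <- ks_two_sample(r2, r3)$p
      }
    })
  }
  pooled <- ks_two_sample(as.vector(p_emp), as.vector(p_rnd))
  structure(list(
    p_empirical = p_emp, p_random = p_rnd,
    per_cycle = data.frame(cycle = seq_len(cfg$n_cycles),
                           median_p_empirical = apply(p_emp, 1, median),
                           median_p_random = apply(p_rnd, 1, median)),
    summary = list(
      frac_empirical_lt_random = mean(p_emp < p_rnd),
      median_p_empirical = median(p_emp),
      median_p_random = median(p_rnd),
      ks_D = pooled$D, ks_p = pooled$p),
    cfg = unclass(cfg)), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("perm_result:", nrow(x$p_empirical), "cycles x",
      ncol(x$p_empirical), "permutations;",
      sprintf("frac(p_emp < p_rand) = %.3f", x$summary$frac_empirical_lt_random),
      "\n")
  invisible(x)
}

#' Gaussian kernel density on a fixed grid
#'
#' Evaluates the Gaussian-kernel density estimate of `values` on `grid`;
#' over a sufficiently wide grid the trapezoid integral is ~1.
#'
#' @param values Numeric sample (length >= 2 unless a numeric bandwidth is
#'   given).
#' @param grid Numeric evaluation grid.
#' @param bandwidth Positive number, or `"silverman"` (default) for the
#'   Silverman rule-of-thumb.
#' @return Data frame with `grid` and `density`.
#' @export
kde_summary <- function(values, grid, bandwidth = "silverman") {
  h <- if (is.character(bandwidth)) {
    if (!identical(bandwidth, "silverman"))
      stop("kde_summary: unknown bandwidth rule '", bandwidth, "'")
    bw.nrd0(values)
  } else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0)
    stop("kde_summary: bandwidth must be positive")
  dens <- vapply(grid, function(g) mean(dnorm(g - values, sd = h)), 0)
  data.frame(grid = grid, density = dens)
}
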