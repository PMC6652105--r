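test_that("KS statistic matches the brute-force CDF oracle and exact enumeration", {
  x <- c(1, 5, 9); y <- c(1, 5, 9)
  expect_equal(ks_two_sample(x, y), list(D = 0, p = 1))

  # n = m = 2, complete separation: enumerate all C(4,2) label assignments
  vals <- c(1, 2, 3, 4)
  splits <- combn(4, 2)
  Ds <- apply(splits, 2, function(ix) ks_D_oracle(vals[ix], vals[-ix]))
  obs <- ks_D_oracle(c(1, 2), c(3, 4))
  p_exact_oracle <- mean(Ds >= obs)
  expect_equal(obs, 1)
  expect_equal(p_exact_oracle, 2 / 6, tolerance = 1e-12)
  got <- ks_two_sample(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(got$D, 1)
  expect_equal(got$p, p_exact_oracle, tolerance = 1e-12)

  for (s in 1:50) {
    withr::with_seed(1000 + s, {
      a <- rnorm(30); b <- rnorm(30, mean = runif(1, -1, 1))
    })
    expect_equal(ks_two_sample(a, b)$D, ks_D_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS D is invariant under strictly monotone transforms", {
  withr::with_seed(57, { a <- rlnorm(40); b <- rlnorm(35, 0.5) })
  d0 <- ks_two_sample(a, b)$D
  expect_equal(ks_two_sample(log(a), log(b))$D, d0, tolerance = 1e-12)
  expect_equal(ks_two_sample(a^3, b^3)$D, d0, tolerance = 1e-12)
})

test_that("Welch t matches the direct formula; degenerate inputs handled", {
  expect_equal(welch_t_test(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1))
  welch_oracle <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  for (s in 1:100) {
    withr::with_seed(2000 + s, {
      x <- rnorm(5 + s %% 10); y <- rnorm(7, 0.3)
    })
    expect_equal(welch_t_test(x, y)$t, welch_oracle(x, y), tolerance = 1e-12)
  }
  expect_equal(welch_t_test(c(2, 2, 2), c(2, 2)), list(t = 0, p = 1))
  expect_warning(deg <- welch_t_test(c(2, 2), c(3, 3)), "constant")
  expect_equal(deg$p, 0)
})

test_that("Welch t detects a 1-sigma shift at n = 50", {
  p <- vapply(1:100, function(s) {
    withr::with_seed(3000 + s, welch_t_test(rnorm(50, 1), rnorm(50))$p)
  }, 0)
  expect_gte(mean(p < 0.01), 0.95)
})

test_that("target-vs-background comparison reports medians and KS contrast", {
  fc_table <- data.frame(gene_id = paste0("g", 1:100), fc = rep(2, 100))
  cmp <- compare_target_to_background(fc_table, c("g1", "g2"))
  expect_equal(cmp$D, 0)
  expect_equal(cmp$median_target, cmp$median_background)
  expect_error(compare_target_to_background(fc_table, c("g1", "zz")), "zz")
  expect_error(compare_target_to_background(fc_table, "g1"), ">= 2")
})

test_that("planted 1.2x targets shift the median and reach significance", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config()
    ann <- simulate_annotation(cfg, seed = 5000 + s)
    truth <- simulate_truth(ann, cfg, seed = 5100 + s)
    cm <- simulate_rnaseq(ann, truth, cfg, seed = 5200 + s)
    fc <- fold_change(filter_genes(cm, ann), "quercetin", "DMSO",
                      compute_tests = FALSE)
    cmp <- compare_target_to_background(
      fc, intersect(truth$regulated_gene_ids, fc$gene_id))
    c(cmp$p < 0.05, cmp$median_target, cmp$median_background)
  }, numeric(3))
  expect_gte(mean(hits[1, ]), 0.8)
  expect_lt(abs(mean(hits[2, ]) - 1.2), 0.06)
  expect_lt(abs(mean(hits[3, ]) - 1.0), 0.03)
})

test_that("permutation scheme returns the full cycle structure, reproducibly", {
  withr::with_seed(61, {
    fc_table <- data.frame(gene_id = paste0("g", 1:300), fc = rlnorm(300, 0, 0.3))
  })
  cfg <- perm_config(seed = 5)
  res <- permutation_scheme(fc_table, paste0("g", 1:36), cfg)
  expect_identical(dim(res$p_empirical), c(10L, 100L))
  expect_identical(dim(res$p_random), c(10L, 100L))
  expect_true(all(res$p_empirical > 0 & res$p_empirical <= 1))
  expect_true(all(res$p_random > 0 & res$p_random <= 1))
  expect_identical(nrow(res$per_cycle), 10L)

  again <- permutation_scheme(fc_table, paste0("g", 1:36), cfg)
  expect_identical(res$p_empirical, again$p_empirical)
  expect_identical(res$p_random, again$p_random)
  other <- permutation_scheme(fc_table, paste0("g", 1:36),
                              perm_config(seed = 6))
  expect_false(identical(res$p_empirical, other$p_empirical))

  # degenerate table: all fold changes equal -> every p = 1
  flat <- data.frame(gene_id = paste0("g", 1:100), fc = rep(1.3, 100))
  res_flat <- permutation_scheme(flat, paste0("g", 1:10),
                                 perm_config(n_cycles = 2, n_perm = 10,
                                             set_size = 10, seed = 1))
  expect_true(all(res_flat$p_empirical == 1))
  expect_true(all(res_flat$p_random == 1))

  expect_error(permutation_scheme(fc_table, "zz", cfg), "zz")
  expect_error(permutation_scheme(fc_table[1:10, ], paste0("g", 1:5),
                                  perm_config(set_size = 36)), "set_size")
})

test_that("null targets give marginally exchangeable p_empirical and p_random", {
  # marginally (fresh random target per draw) the two p-value streams are
  # exchangeable; within one scheme run they share the fixed target, so the
  # check draws one pair per seed
  withr::with_seed(67, {
    fc_table <- data.frame(gene_id = paste0("g", 1:500),
                           fc = rlnorm(500, 0, 0.3))
  })
  pairs <- vapply(1:100, function(s) {
    tgt <- withr::with_seed(6500 + s, paste0("g", sample.int(500, 36)))
    res <- permutation_scheme(fc_table, tgt,
                              perm_config(n_cycles = 1, n_perm = 1, seed = s))
    c(res$p_empirical[1, 1], res$p_random[1, 1])
  }, numeric(2))
  expect_gt(ks_two_sample(pairs[1, ], pairs[2, ])$p, 0.01)
  # and their medians agree to first order
  expect_lt(abs(median(pairs[1, ]) - median(pairs[2, ])), 0.2)
})

test_that("planted targets drive p_empirical below p_random monotonically", {
  frac <- vapply(c(1.0, 1.2, 1.5), function(pfc) {
    cfg <- sim_config(planted_fc = pfc)
    ann <- simulate_annotation(cfg, seed = 701)
    truth <- simulate_truth(ann, cfg, seed = 702)
    cm <- simulate_rnaseq(ann, truth, cfg, seed = 703)
    fc <- fold_change(filter_genes(cm, ann), "quercetin", "DMSO",
                      compute_tests = FALSE)
    res <- permutation_scheme(fc,
                              intersect(truth$regulated_gene_ids, fc$gene_id),
                              perm_config(n_cycles = 5, n_perm = 40, seed = 9))
    c(res$summary$frac_empirical_lt_random, res$summary$median_p_empirical)
  }, numeric(2))
  # median p_empirical non-increasing in effect size
  expect_true(all(diff(frac[2, ]) <= 0))
  expect_gt(frac[1, 3], 0.7)
})

test_that("kernel density estimate: closed form, normalization, uniform band", {
  h <- 0.2
  grid <- seq(-2, 2, by = 0.01)
  d <- kde_summary(rep(0.5, 10), grid, bandwidth = h)
  expect_equal(max(d$density), 1 / (h * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(d$density, dnorm(grid, 0.5, h), tolerance = 1e-12)

  u <- withr::with_seed(71, runif(1000))
  wide <- seq(-0.5, 1.5, by = 0.005)
  du <- kde_summary(u, wide)
  trap <- sum(diff(wide) * (head(du$density, -1) + du$density[-1]) / 2)
  expect_lt(abs(trap - 1), 0.02)
  inner <- du$density[wide >= 0.2 & wide <= 0.8]
  expect_true(all(inner > 0.7 & inner < 1.3))

  expect_error(kde_summary(1:10, grid, bandwidth = 0), "positive")
  expect_error(kde_summary(1:10, grid, bandwidth = "scott"), "unknown")
})
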