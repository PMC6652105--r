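mk_cm <- function(counts, condition) {
  m <- as.matrix(counts)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_matrix(m, condition)
}
mk_ann <- function(n, biotype = "protein_coding") {
  data.frame(gene_id = paste0("g", seq_len(n)), chrom = "chr1", strand = "+",
             tss = 1000 * seq_len(n), biotype = rep_len(biotype, n),
             stringsAsFactors = FALSE)
}

test_that("gene filter enforces coding biotype and strict >10 count rule", {
  cm <- mk_cm(rbind(c(10, 10, 10), c(11, 0, 0), c(100, 100, 100)),
              condition = c("a", "a", "b"))
  ann <- mk_ann(3)
  kept <- filter_genes(cm, ann)
  expect_identical(rownames(kept$counts), c("g2", "g3"))  # all-10 gene removed

  ann$biotype[2] <- "lincRNA"
  expect_identical(rownames(filter_genes(cm, ann)$counts), "g3")

  # random matrix equals the naive row-wise predicate
  m <- withr::with_seed(13, matrix(rpois(600, 12), nrow = 100))
  cm2 <- mk_cm(m, condition = rep(c("a", "b"), each = 3))
  ann2 <- mk_ann(100, biotype = rep(c("protein_coding", "lincRNA"), 50))
  naive <- vapply(seq_len(100), function(i)
    ann2$biotype[i] == "protein_coding" && any(m[i, ] > 10), TRUE)
  expect_identical(rownames(filter_genes(cm2, ann2)$counts),
                   paste0("g", which(naive)))
})

test_that("unknown genes are dropped with a warning", {
  cm <- mk_cm(rbind(c(20, 20), c(30, 30)), condition = c("a", "b"))
  expect_warning(out <- filter_genes(cm, mk_ann(1)), "absent")
  expect_identical(rownames(out$counts), "g1")
})

test_that("median-of-ratios size factors: symmetry, worked example, equivariance", {
  cm <- mk_cm(cbind(c(50, 9, 22), c(50, 9, 22), c(50, 9, 22)),
              condition = c("a", "a", "b"))
  expect_equal(unname(size_factors(cm)), c(1, 1, 1))

  doubled <- mk_cm(cbind(c(10, 20, 30), c(20, 40, 60)), condition = c("a", "b"))
  sf <- size_factors(doubled)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # scaling one column by c scales its factor by c relative to the others
  # (the geometric-mean reference absorbs a common c^(1/n))
  m <- withr::with_seed(17, matrix(rpois(300, 50) + 1, nrow = 50))
  cm2 <- mk_cm(m, condition = rep(c("a", "b"), 3))
  scaled <- mk_cm(cbind(m[, 1] * 3, m[, -1]), condition = rep(c("a", "b"), 3))
  sf0 <- size_factors(cm2); sf3 <- size_factors(scaled)
  expect_equal(unname(sf3[1] / sf3[2]), unname(3 * sf0[1] / sf0[2]),
               tolerance = 1e-12)

  all_zero_somewhere <- mk_cm(cbind(c(0, 5), c(5, 0)), condition = c("a", "b"))
  expect_error(size_factors(all_zero_somewhere), "pseudocount")
})

test_that("size factors agree with the DESeq median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  m <- withr::with_seed(19, matrix(rnbinom(1200, mu = 80, size = 5) + 1,
                                   nrow = 200))
  cm <- mk_cm(m, condition = rep(c("a", "b"), 3))
  ours <- unname(size_factors(cm))
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(cm$counts))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("fold change identities: relabeled conditions, zero-count genes", {
  m <- withr::with_seed(23, matrix(rpois(120, 40), nrow = 20))
  m[1, ] <- 0  # zero everywhere -> FC 1 via pseudocount dominance
  cm <- mk_cm(m, condition = rep(c("a", "b"), 3))
  # same samples relabeled: sample 1,3,5 as both treatment and control
  cm_same <- mk_cm(m[, c(1, 3, 5, 1, 3, 5)],
                   condition = rep(c("t", "c"), each = 3))
  fc <- fold_change(cm_same, "t", "c", compute_tests = FALSE)
  expect_true(all(fc$fc == 1))
  fc2 <- fold_change(cm, "a", "b", compute_tests = FALSE)
  expect_equal(fc2$fc[1], 1)
  expect_error(fold_change(cm, "a", "zz"), "unknown condition")
})

test_that("fold change is invariant to uniform depth scaling", {
  m <- withr::with_seed(29, matrix(rpois(300, 60) + 1, nrow = 50))
  cm <- mk_cm(m, condition = rep(c("t", "c"), 3))
  cm4 <- mk_cm(m * 4, condition = rep(c("t", "c"), 3))
  fc1 <- fold_change(cm, "t", "c", pseudocount = 0, compute_tests = FALSE)
  fc4 <- fold_change(cm4, "t", "c", pseudocount = 0, compute_tests = FALSE)
  expect_equal(fc1$fc, fc4$fc, tolerance = 1e-12)
})

test_that("normalization is idempotent up to rounding", {
  m <- withr::with_seed(31, matrix(rnbinom(600, mu = 100, size = 10) + 1,
                                   nrow = 100))
  cm <- mk_cm(m, condition = rep(c("a", "b"), 3))
  sf <- size_factors(cm)
  norm <- mk_cm(round(sweep(m, 2, sf, "/")), condition = rep(c("a", "b"), 3))
  expect_equal(unname(size_factors(norm)), rep(1, 6), tolerance = 0.05)
})

test_that("planted fold change 1.2 is recovered by the expression stage", {
  meds <- vapply(1:3, function(s) {
    cfg <- sim_config()
    ann <- simulate_annotation(cfg, seed = 400 + s)
    truth <- simulate_truth(ann, cfg, seed = 440 + s)
    cm <- simulate_rnaseq(ann, truth, cfg, seed = 480 + s)
    fc <- fold_change(filter_genes(cm, ann), "quercetin", "DMSO",
                      compute_tests = FALSE)
    median(fc$fc[fc$gene_id %in% truth$regulated_gene_ids])
  }, 0)
  expect_lt(abs(mean(meds) - 1.2), 0.05)
})

test_that("differential calling: boundary convention and error contracts", {
  fc_table <- data.frame(gene_id = c("a", "b", "c", "d"),
                         fc = c(2.0, 0.5, 3.0, 1.5),
                         q_value = c(0.01, 0.01, 0.2, 0.01))
  # FC exactly at the closed bounds is included
  expect_setequal(differential_genes(fc_table), c("a", "b"))
  # literal inside reading
  expect_setequal(differential_genes(fc_table, inside = TRUE), c("a", "b", "d"))
  expect_error(differential_genes(data.frame(gene_id = "a", fc = 2)), "p/q")
})

test_that("differential calling has power on strongly planted genes", {
  cfg <- sim_config(n_chroms = 1, chrom_length = 2e6, n_genes = 200,
                    n_regulated = 20, planted_fc = 4, n_replicates = 5)
  ann <- simulate_annotation(cfg, seed = 501)
  truth <- simulate_truth(ann, cfg, seed = 502)
  cm <- simulate_rnaseq(ann, truth, cfg, seed = 503)
  hits <- differential_genes(fold_change(filter_genes(cm, ann),
                                         "quercetin", "DMSO"))
  expect_gte(length(intersect(hits, truth$regulated_gene_ids)) /
               length(truth$regulated_gene_ids), 0.9)
})
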