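mk_genes <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df$biotype <- "protein_coding"
  df
}

test_that("promoter windows are upstream-only, include the TSS, clip at zero", {
  gp <- mk_genes(gene_id = "gp", chrom = "chr1", strand = "+", tss = 10000)
  expect_equal(promoter_windows(gp)[, c("start", "end")],
               data.frame(start = 9500, end = 10001))
  gm <- mk_genes(gene_id = "gm", chrom = "chr1", strand = "-", tss = 10000)
  expect_equal(promoter_windows(gm)[, c("start", "end")],
               data.frame(start = 10000, end = 10501))
  edge <- mk_genes(gene_id = "ge", chrom = "chr1", strand = "+", tss = 100)
  expect_equal(promoter_windows(edge)[, c("start", "end")],
               data.frame(start = 0, end = 101))
  # off-edge length is upstream + 1 on both strands
  expect_equal(with(promoter_windows(gp), end - start), 501)
  expect_equal(with(promoter_windows(gm), end - start), 501)
})

test_that("peak-to-gene association equals the naive all-pairs scan", {
  cfg <- small_cfg(n_genes = 50, n_regulated = 5)
  ann <- simulate_annotation(cfg, seed = 61)
  peaks <- random_peaks(200, seed = 62, chroms = "chr1", L = 1e6)
  got <- peaks_to_genes(peaks, ann)
  prom <- promoter_windows(ann)
  naive <- prom$gene_id[naive_overlap_filter(prom, peaks)]
  expect_setequal(got$genes, naive)
  # per-gene peak lists agree with the naive scan
  for (g in got$genes) {
    w <- prom[prom$gene_id == g, ]
    expect_identical(got$map[[g]],
                     which(vapply(seq_len(nrow(peaks)), function(i)
                       naive_overlaps1(peaks[i, ], w), TRUE)))
  }
  expect_identical(peaks_to_genes(peaks[0, ], ann)$genes, character(0))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # universe 20, set 5, candidates 5, overlap 4:
  # P(X >= 4) = [C(5,4) C(15,1) + C(5,5)] / C(20,5) = 76/15504
  gs <- list(s = paste0("g", 1:5))
  cand <- paste0("g", c(1:4, 10))
  rec <- geneset_enrichment(cand, paste0("g", 1:20), gs)
  oracle <- (choose(5, 4) * choose(15, 1) + choose(5, 5)) / choose(20, 5)
  expect_equal(rec$p_value, oracle, tolerance = 1e-12)
  expect_identical(rec$overlap, 4L)

  # zero overlap: P(X >= 0) = 1
  rec0 <- geneset_enrichment(paste0("g", 11:15), paste0("g", 1:20), gs)
  expect_equal(rec0$p_value, 1)

  expect_error(geneset_enrichment("g1", character(0), gs), "universe")
  expect_error(geneset_enrichment("zz", paste0("g", 1:20), gs), "subset")
})

test_that("hypergeometric p-values are calibrated under random candidate draws", {
  universe <- paste0("g", 1:500)
  gs <- list(s = paste0("g", 1:50))
  p <- vapply(1:1000, function(i) {
    cand <- withr::with_seed(3000 + i,
                             universe[sample.int(500, 36)])
    geneset_enrichment(cand, universe, gs)$p_value
  }, 0)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("PWM scan scores the consensus at the maximum and finds planted hits", {
  m <- e2f_like_pwm()
  cons <- pwm_consensus(m)
  expect_identical(cons, "TTTGGCGCC")
  mx <- chemcis:::pwm_max_score(m)
  hit <- pwm_scan(paste0("ACAC", cons, "ACAC"), m, mx)
  expect_identical(hit$pos, 5L)
  expect_identical(hit$strand, "+")
  expect_equal(hit$score, mx, tolerance = 1e-12)
  # shorter than the motif: no hits
  expect_identical(nrow(pwm_scan("ACGT", m, 0)), 0L)
})

test_that("PWM scan equals a per-offset rescoring oracle on both strands", {
  m <- e2f_like_pwm()
  lo <- log2(m$matrix / 0.25)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score1 <- function(s) sum(vapply(seq_len(nchar(s)), function(j)
    lo[j, substr(s, j, j)], 0))
  seqs <- withr::with_seed(71, vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""), ""))
  for (s in seqs) {
    got <- pwm_scan(s, m, -20)
    L <- nchar(s); M <- nrow(m$matrix)
    oracle <- do.call(rbind, lapply(seq_len(L - M + 1), function(i) {
      sub <- substr(s, i, i + M - 1)
      data.frame(pos = c(i, i), strand = c("+", "-"),
                 score = c(score1(sub), score1(revcomp(sub))))
    }))
    oracle <- oracle[oracle$score >= -20, ]
    oracle <- oracle[order(oracle$pos, oracle$strand), ]
    rownames(oracle) <- NULL
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("PWM scan is strand-symmetric under reverse complement", {
  m <- e2f_like_pwm()
  s <- paste0("AAGG", pwm_consensus(m), "TTCCACGT")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  h1 <- pwm_scan(s, m, 5)
  h2 <- pwm_scan(rc, m, 5)
  M <- nrow(m$matrix)
  # a + hit at pos p maps to a - hit at nchar(s) - M + 2 - p
  expect_setequal(nchar(s) - M + 2 - h1$pos, h2$pos)
  expect_setequal(h2$strand, setdiff(c("+", "-"), h1$strand))
})

test_that("motif enrichment: Fisher tail matches enumeration; null sets give p = 1", {
  m <- e2f_like_pwm()
  cons <- pwm_consensus(m)
  mk <- function(n_hit, n_tot, seed) withr::with_seed(seed, vapply(1:n_tot,
    function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
      if (i <= n_hit) s <- paste0(substr(s, 1, 20), cons,
                                  substr(s, 21 + nchar(cons), 50))
      s
    }, ""))
  tgt <- mk(9, 10, seed = 81)
  bg <- mk(1, 10, seed = 82)
  res <- motif_enrichment(tgt, bg, m)
  expect_identical(c(res$target_hits, res$background_hits), c(9L, 1L))
  # hypergeometric tail: P(X >= 9), margins (10 hits, 10 target of 20)
  oracle <- (choose(10, 9) * choose(10, 1) + choose(10, 10)) / choose(20, 10)
  expect_equal(res$p_value, oracle, tolerance = 1e-12)

  clean <- mk(0, 10, seed = 83)
  same <- motif_enrichment(clean, clean, m)
  expect_equal(same$p_value, 1)
})

test_that("planted-motif promoters are strongly enriched over background", {
  m <- e2f_like_pwm()
  ps <- vapply(1:5, function(s) {
    cfg <- small_cfg(n_regulated = 36, n_genes = 150)
    ann <- simulate_annotation(cfg, seed = 900 + s)
    truth <- simulate_truth(ann, cfg, seed = 950 + s)
    seqs <- simulate_promoter_sequences(ann, truth, cfg, seed = 990 + s)
    tgt <- seqs[truth$regulated_gene_ids]
    bg <- seqs[setdiff(names(seqs), truth$regulated_gene_ids)[1:100]]
    motif_enrichment(tgt, bg, m)$p_value
  }, 0)
  expect_true(all(ps < 1e-6))
})
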