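#!/usr/bin/env Rscript
# Stage 5: the statistical core — target-vs-background FC comparison (KS),
# the 10x100 permutation scheme contrasting P_empirical with P_random, and
# the biotin-equivalence t-tests.
suppressPackageStartupMessages(library(chemcis))

fc <- read.delim("results/run/fc_quercetin.tsv")
fc_bio <- read.delim("results/run/fc_bioquercetin.tsv")
target <- readLines("results/run/candidate_genes.txt")
target <- intersect(target, fc$gene_id)

cmp <- compare_target_to_background(fc, target)
perm <- permutation_scheme(fc, target, perm_config(seed = 21))
tt_qb <- welch_t_test(fc$fc[fc$gene_id %in% target],
                      fc_bio$fc[fc_bio$gene_id %in% target])
tt_bg <- welch_t_test(fc_bio$fc[fc_bio$gene_id %in% target], fc_bio$fc)

grid <- seq(0, 1, by = 0.01)
kde <- data.frame(grid = grid,
                  p_empirical = kde_summary(as.vector(perm$p_empirical), grid)$density,
                  p_random = kde_summary(as.vector(perm$p_random), grid)$density)
write.table(kde, "results/run/permutation_kde.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("median FC: target %.2f vs background %.2f (KS p = %.3g)",
                cmp$median_target, cmp$median_background, cmp$p))
message(sprintf("permutations: %d p_empirical + %d p_random",
                length(perm$p_empirical), length(perm$p_random)))
message(sprintf("frac(P_empirical < P_random) = %.2f",
                perm$summary$frac_empirical_lt_random))
message(sprintf("t-test compound vs biotinylated compound: p = %.2f", tt_qb$p))
message(sprintf("t-test biotinylated compound vs background: p = %.3g", tt_bg$p))
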