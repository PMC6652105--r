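#!/usr/bin/env Rscript
# Stage 3: promoter association of the top compound peaks, gene-set
# enrichment against the synthetic cell-cycle set, and known-motif (E2F-like
# PWM) enrichment of candidate promoters versus background promoters.
suppressPackageStartupMessages(library(chemcis))

ann <- read_annotation("results/run/sim/genes.gtf")
peaks <- read_bed("results/run/quercetin_top.bed")
truth <- jsonlite::read_json("results/run/sim/ground_truth.json",
                             simplifyVector = TRUE)
proms <- read_fasta("results/run/sim/promoters.fa")

assoc <- peaks_to_genes(peaks, ann, upstream = 500)
enr <- geneset_enrichment(assoc$genes, ann$gene_id,
                          list(cell_cycle = truth$regulated_gene_ids))
bg <- withr::with_seed(31,
  proms[sample(setdiff(names(proms), assoc$genes), 100)])
motif <- motif_enrichment(proms[assoc$genes], bg, e2f_like_pwm())

writeLines(assoc$genes, "results/run/candidate_genes.txt")
write.table(enr, "results/run/geneset_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("candidate genes (promoter-associated): ", length(assoc$genes))
message(sprintf("cell-cycle set enrichment p: %.3g", enr$p_value[1]))
message(sprintf("motif enrichment: %.0f%% of targets vs %.0f%% background, p = %.3g",
                100 * motif$target_hit_fraction,
                100 * motif$background_hit_fraction, motif$p_value))
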