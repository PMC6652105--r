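#!/usr/bin/env Rscript
# Stage 4: coding/>10-read filtering, median-of-ratios normalization,
# per-gene fold changes (treatment vs DMSO) and differential calling.
suppressPackageStartupMessages(library(chemcis))

ann <- read_annotation("results/run/sim/genes.gtf")
cm <- read_counts("results/run/sim/counts.tsv")
filtered <- filter_genes(cm, ann)
fc <- fold_change(filtered, "quercetin", "DMSO")
fc_bio <- fold_change(filtered, "bioquercetin", "DMSO")
hits <- differential_genes(fc)

write_fc_table(fc, "results/run/fc_quercetin.tsv")
write_fc_table(fc_bio, "results/run/fc_bioquercetin.tsv")
writeLines(hits, "results/run/differential_genes.txt")
message("genes after filtering: ", nrow(filtered$counts), " / ", nrow(cm$counts))
message(sprintf("size factors: %s",
                paste(sprintf("%.3f", size_factors(filtered)), collapse = " ")))
message("differential genes (FC outside [0.5,2], q<0.05): ", length(hits))
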