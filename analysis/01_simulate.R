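#!/usr/bin/env Rscript
# Stage 1: generate the default-scale synthetic study (genome, gene models,
# three Chem-seq tag libraries, promoter sequences, RNA-seq counts) with
# planted ground truth, and write every artifact under results/run/sim/.
suppressPackageStartupMessages(library(chemcis))

seed <- 1
cfg <- sim_config()
sim <- simulate_chemcis(cfg, seed = seed, outdir = "results/run/sim")

message("genes:            ", nrow(sim$annotation),
        " (", sum(sim$annotation$biotype == "protein_coding"), " coding)")
message("regulated genes:  ", length(sim$truth$regulated_gene_ids))
message("binding sites:    ", nrow(sim$truth$quercetin_site_intervals),
        " in regulated promoters")
message("bead sticky sites:", nrow(sim$truth$bead_site_intervals))
message("tags (compound/bead/input): ",
        sim$tracks$quercetin_bead$total_tags, " / ",
        sim$tracks$bead$total_tags, " / ", sim$tracks$input$total_tags)
message("written: results/run/sim/")
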