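#' Load a simulation config from YAML (or a list of overrides)
#'
#' Unknown keys are rejected; missing keys take the [sim_config()]
#' defaults.
#'
#' @param config `NULL` (all defaults), a path to a YAML file, a plain
#'   list of overrides, or an existing `sim_config`.
#' @return A `sim_config`.
#' @export
load_sim_config <- function(config = NULL) {
  if (is.null(config)) return(sim_config())
  if (is(config, "sim_config")) return(config)
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(formals(sim_config)))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, config)
}

#' Run the full synthetic pipeline
#'
#' Simulate -> Chem-seq peak inference -> promoter association and
#' enrichment -> expression fold changes -> permutation / KS statistics,
#' all under one config and one root seed. Every stage's outputs are
#' written under `outdir` and summarized in a machine-readable
#' `report.json` (parameter echo, per-stage counts, ground-truth recovery,
#' file manifest with checksums; no timestamps, so identical seed and
#' config give byte-identical reports). A stage failure writes the partial
#' report with a `FAILED` marker naming the stage, then raises.
#'
#' @param config See [load_sim_config()].
#' @param outdir Output directory (created).
#' @param seed Root seed for every random stage.
#' @param params Peak-caller parameters ([peak_params()]).
#' @param n_top Size of the ranked top peak lists.
#' @return Invisibly, a list with `report` plus the in-memory stage
#'   objects (`sim`, `chem`, `assoc`, `fc`, `fc_bio`, `perm`, ...).
#' @export
run_all <- function(config = NULL, outdir = tempfile("chemcis_run_"),
                    seed = 1, params = peak_params(), n_top = 1000) {
  cfg <- load_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(pipeline = "chemcis", version = "0.1.0", seed = seed,
                 config = unclass(cfg), peak_params = unclass(params),
                 n_top = n_top, status = "RUNNING", stages = list())
  fail <- function(stage, e) {
    report$status <- "FAILED"
    report$failed_stage <- stage
    report$error <- conditionMessage(e)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  ## --- simulate -------------------------------------------------------
  sim <- run_stage("simulate",
    simulate_chemcis(cfg, seed, outdir = file.path(outdir, "sim")))
  report$stages$simulate <- list(
    n_genes = nrow(sim$annotation),
    n_coding = sum(sim$annotation$biotype == "protein_coding"),
    n_regulated = length(sim$truth$regulated_gene_ids),
    n_quercetin_sites = nrow(sim$truth$quercetin_site_intervals),
    n_bead_sites = nrow(sim$truth$bead_site_intervals),
    tags = list(quercetin_bead = sim$tracks$quercetin_bead$total_tags,
                bead = sim$tracks$bead$total_tags,
                input = sim$tracks$input$total_tags))

  ## --- chemseq peak inference ----------------------------------------
  chem <- run_stage("chemseq",
    run_chemseq_analysis(sim$tracks$quercetin_bead, sim$tracks$bead,
                         sim$tracks$input, params = params, n_top = n_top))
  run_stage("chemseq", {
    write_peaks(chem$quercetin_raw, file.path(outdir, "quercetin_raw.bed"))
    write_peaks(chem$bead_derived, file.path(outdir, "bead_derived.bed"))
    write_peaks(chem$quercetin_final, file.path(outdir, "quercetin_final.bed"))
    write_peaks(chem$quercetin_topN, file.path(outdir, "quercetin_top.bed"))
    write_peaks(chem$bead_topN, file.path(outdir, "bead_top.bed"))
  })
  report$stages$chemseq <- chem$provenance

  ## --- ground-truth recovery -----------------------------------------
  truth_sites <- sim$truth$quercetin_site_intervals
  hit_final <- overlap_any_idx(truth_sites, chem$quercetin_final)
  hit_raw <- overlap_any_idx(truth_sites, chem$quercetin_raw)
  report$truth_recovery <- list(
    n_truth_sites = nrow(truth_sites),
    site_recall = if (nrow(truth_sites) > 0)
      length(hit_final) / nrow(truth_sites) else NA,
    sites_lost_to_exclusion = length(setdiff(hit_raw, hit_final)),
    final_peaks_at_bead_truth = length(
      overlap_any_idx(chem$quercetin_final, sim$truth$bead_site_intervals)),
    final_peak_precision = if (nrow(chem$quercetin_final) > 0)
      length(overlap_any_idx(chem$quercetin_final, truth_sites)) /
        nrow(chem$quercetin_final) else NA)

  ## --- promoter association + enrichment -----------------------------
  assoc <- run_stage("annotate",
    peaks_to_genes(chem$quercetin_topN, sim$annotation,
                   upstream = cfg$promoter_upstream))
  bead_assoc <- run_stage("annotate",
    peaks_to_genes(chem$bead_topN, sim$annotation,
                   upstream = cfg$promoter_upstream))
  genesets <- list(cell_cycle = sim$truth$regulated_gene_ids)
  enr <- run_stage("annotate",
    geneset_enrichment(assoc$genes, sim$annotation$gene_id, genesets))
  motif <- NULL
  if (length(assoc$genes) >= 2) {
    motif <- run_stage("annotate", {
      bg_pool <- setdiff(names(sim$promoters), assoc$genes)
      bg <- withr::with_seed(seed + 30,
        sim$promoters[sample(bg_pool, min(100, length(bg_pool)))])
      motif_enrichment(sim$promoters[assoc$genes], bg, e2f_like_pwm())
    })
  }
  report$stages$annotate <- list(
    n_candidate_genes = length(assoc$genes),
    n_bead_candidate_genes = length(bead_assoc$genes),
    regulated_gene_recall = if (length(sim$truth$regulated_gene_ids) > 0)
      length(intersect(assoc$genes, sim$truth$regulated_gene_ids)) /
        length(sim$truth$regulated_gene_ids) else NA,
    cell_cycle_enrichment_p = enr$p_value[enr$set_name == "cell_cycle"],
    motif = motif)
  run_stage("annotate", {
    writeLines(assoc$genes, file.path(outdir, "candidate_genes.txt"))
    write.table(enr, file.path(outdir, "geneset_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  })

  ## --- expression -----------------------------------------------------
  filtered <- run_stage("expression",
    filter_genes(sim$counts, sim$annotation))
  fc <- run_stage("expression",
    fold_change(filtered, "quercetin", "DMSO"))
  fc_bio <- run_stage("expression",
    fold_change(filtered, "bioquercetin", "DMSO"))
  diff_genes <- run_stage("expression", differential_genes(fc))
  run_stage("expression", {
    write_fc_table(fc, file.path(outdir, "fc_quercetin.tsv"))
    write_fc_table(fc_bio, file.path(outdir, "fc_bioquercetin.tsv"))
    writeLines(diff_genes, file.path(outdir, "differential_genes.txt"))
  })
  report$stages$expression <- list(
    n_filtered_genes = nrow(filtered$counts),
    size_factors = as.list(size_factors(filtered)),
    n_differential = length(diff_genes),
    median_fc = median(fc$fc))

  ## --- cis-regulatory statistics --------------------------------------
  target <- intersect(assoc$genes, fc$gene_id)
  cis <- NULL
  if (length(target) >= 2) {
    cis <- run_stage("cisstats", {
      cmp <- compare_target_to_background(fc, target)
      perm <- permutation_scheme(fc, target,
        perm_config(set_size = min(cfg$n_regulated, length(fc$gene_id) - 1),
                    seed = seed + 20))
      tt_treatments <- welch_t_test(fc$fc[fc$gene_id %in% target],
                                    fc_bio$fc[fc_bio$gene_id %in% target])
      tt_background <- welch_t_test(fc_bio$fc[fc_bio$gene_id %in% target],
                                    fc_bio$fc)
      grid <- seq(0, 1, by = 0.01)
      kde <- data.frame(
        grid = grid,
        p_empirical = kde_summary(as.vector(perm$p_empirical), grid)$density,
        p_random = kde_summary(as.vector(perm$p_random), grid)$density)
      write.table(kde, file.path(outdir, "permutation_kde.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      pv <- data.frame(cycle = rep(seq_len(nrow(perm$p_empirical)),
                                   ncol(perm$p_empirical)),
                       p_empirical = as.vector(perm$p_empirical),
                       p_random = as.vector(perm$p_random))
      write.table(pv, file.path(outdir, "permutation_pvalues.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      list(compare = cmp, perm = perm,
           t_tests = list(quercetin_vs_bioquercetin = tt_treatments,
                          bioquercetin_vs_background = tt_background))
    })
    report$stages$cisstats <- list(
      n_target_genes = length(target),
      compare = cis$compare,
      permutation = c(list(n_cycles = nrow(cis$perm$p_empirical),
                           n_perm = ncol(cis$perm$p_empirical)),
                      cis$perm$summary),
      t_tests = cis$t_tests)
  } else {
    report$stages$cisstats <- list(n_target_genes = length(target),
                                   skipped = "fewer than 2 target genes")
  }

  ## --- manifest + report ----------------------------------------------
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "report.json"]
  report$files <- lapply(setNames(files, substring(files, nchar(outdir) + 2)),
                         function(f) list(md5 = unname(tools::md5sum(f)),
                                          bytes = file.size(f)))
  report$status <- "OK"
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(report = report, sim = sim, chem = chem, assoc = assoc,
                 enrichment = enr, motif = motif, filtered = filtered,
                 fc = fc, fc_bio = fc_bio, diff_genes = diff_genes,
                 cis = cis, outdir = outdir))
}
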