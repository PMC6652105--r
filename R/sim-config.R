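#' Synthetic study configuration
#'
#' Default values define the desk-scale study emulated by the generators: a
#' 2 x 5 Mb genome carrying 1,000 genes of which 36 are regulated by the
#' compound with a planted expression fold change of 1.2, compound binding
#' sites in the promoters of the regulated genes, and sticky bead regions
#' elsewhere. See the methods vignette for the rationale behind each
#' default.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param n_genes Total genes in the annotation.
#' @param frac_noncoding Fraction of genes flagged non-coding.
#' @param n_regulated Number of compound-regulated genes (default 36).
#' @param planted_fc Expression fold change planted on regulated genes in
#'   the treated conditions (default 1.2).
#' @param site_enrichment Multiplicative tag-rate boost at compound binding
#'   sites in the compound-bead library.
#' @param bead_enrichment Tag-rate boost at sticky bead sites (both bead
#'   and compound-bead libraries).
#' @param site_width Width of planted binding / sticky sites in bp.
#' @param bead_sites Number of bead-specific sticky regions.
#' @param bead_sites_avoid_promoters If `TRUE` (default), sticky sites are
#'   placed away from all promoter windows; set `FALSE` to let them collide
#'   with compound sites and stress the exclusion logic.
#' @param background_rate Background tag rate per bp; `NULL` derives it as
#'   `library_size / genome length`.
#' @param library_size Tags per Chem-seq library.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of RNA-seq
#'   gene baseline means.
#' @param nb_dispersion Negative-binomial dispersion of RNA-seq counts
#'   (0 gives Poisson counts).
#' @param n_replicates RNA-seq samples per condition.
#' @param depth_sdlog Log-sd of per-sample RNA-seq depth factors.
#' @param motif_consensus Consensus string planted in regulated promoters.
#' @param motif_plant_fraction Fraction of regulated promoters carrying the
#'   planted consensus.
#' @param promoter_upstream Promoter window size upstream of the TSS in bp.
#' @param min_tss_spacing Minimum distance between adjacent TSSs in bp.
#' @param seed Default random seed for generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2,
                       chrom_length = 5e6,
                       n_genes = 1000,
                       frac_noncoding = 0.1,
                       n_regulated = 36,
                       planted_fc = 1.2,
                       site_enrichment = 8,
                       bead_enrichment = 8,
                       site_width = 300,
                       bead_sites = 50,
                       bead_sites_avoid_promoters = TRUE,
                       background_rate = NULL,
                       library_size = 2e5,
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1.2,
                       nb_dispersion = 0.05,
                       n_replicates = 4,
                       depth_sdlog = 0.1,
                       motif_consensus = "TTTGGCGCC",
                       motif_plant_fraction = 0.8,
                       promoter_upstream = 500,
                       min_tss_spacing = 2000,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_regulated > floor(n_genes * (1 - frac_noncoding)) && n_genes > 0)
      stop("sim_config: n_regulated exceeds the number of coding genes")
    if (planted_fc <= 0) stop("sim_config: planted_fc must be > 0")
    if (site_enrichment < 1 || bead_enrichment < 1)
      stop("sim_config: enrichment factors must be >= 1")
    if (!is.null(background_rate) && background_rate <= 0)
      stop("sim_config: background_rate must be > 0")
    if (library_size <= 0) stop("sim_config: library_size must be > 0")
    if (nb_dispersion < 0) stop("sim_config: nb_dispersion must be >= 0")
    if (n_replicates < 2) stop("sim_config: need >= 2 replicates per condition")
    if (!grepl("^[ACGT]+$", motif_consensus))
      stop("sim_config: motif_consensus must be over {A,C,G,T}")
    if (nchar(motif_consensus) > promoter_upstream + 1)
      stop("sim_config: motif longer than the promoter window")
    if (site_width > promoter_upstream + 1)
      stop("sim_config: site_width exceeds the promoter window")
  })
  invisible(cfg)
}

# Resolve derived quantities: chromosome name/length table and tag rate.
sim_genome <- function(cfg) {
  lens <- setNames(rep(cfg$chrom_length, cfg$n_chroms),
                   paste0("chr", seq_len(cfg$n_chroms)))
  rate <- cfg$background_rate
  if (is.null(rate)) rate <- cfg$library_size / sum(lens)
  list(chrom_lengths = lens, background_rate = rate)
}
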