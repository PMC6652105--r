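#' Simulate a gene annotation
#'
#' TSS positions are uniform per chromosome subject to a minimum spacing
#' (default 2 kb) and an edge margin large enough to fit promoter windows;
#' strands are Bernoulli(0.5); a configurable fraction of genes is flagged
#' non-coding.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return Gene model data frame (`gene_id`, `chrom`, `strand`, `tss`,
#'   `biotype`), ordered by chromosome and TSS.
#' @export
simulate_annotation <- function(cfg, seed = cfg$seed) {
  g <- sim_genome(cfg)
  if (cfg$n_genes == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tss = numeric(0),
                      biotype = character(0), stringsAsFactors = FALSE))
  }
  margin <- cfg$promoter_upstream + 10
  # split genes across chromosomes as evenly as possible
  n_per <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  withr::with_seed(seed, {
    rows <- lapply(seq_len(cfg$n_chroms), function(i) {
      n <- n_per[i]
      if (n == 0) return(NULL)
      L <- g$chrom_lengths[i]
      usable <- L - 2 * margin - (n - 1) * cfg$min_tss_spacing
      if (usable <= 0)
        stop("simulate_annotation: genome too small for ", n,
             " genes at >= ", cfg$min_tss_spacing, " bp spacing")
      # sorted uniforms + deterministic spacing offsets => min spacing holds
      tss <- margin + sort(runif(n, 0, usable)) +
        (seq_len(n) - 1) * cfg$min_tss_spacing
      data.frame(chrom = names(g$chrom_lengths)[i], tss = floor(tss),
                 stringsAsFactors = FALSE)
    })
    ann <- do.call(rbind, rows)
    ann$gene_id <- sprintf("g%04d", seq_len(nrow(ann)))
    ann$strand <- ifelse(runif(nrow(ann)) < 0.5, "+", "-")
    n_nc <- round(cfg$frac_noncoding * nrow(ann))
    ann$biotype <- "protein_coding"
    if (n_nc > 0)
      ann$biotype[sample.int(nrow(ann), n_nc)] <- "lincRNA"
    ann <- ann[, c("gene_id", "chrom", "strand", "tss", "biotype")]
  })
  validate_annotation(ann)
  ann
}

#' Plant ground truth: binding sites, sticky bead regions, regulated genes
#'
#' Picks `n_regulated` coding genes, places one compound binding site of
#' `site_width` bp inside each of their promoter windows, and scatters
#' `bead_sites` sticky regions elsewhere (away from promoters unless
#' `bead_sites_avoid_promoters = FALSE`), disjoint from the binding sites
#' and from each other.
#'
#' @inheritParams simulate_annotation
#' @param annotation Gene models from [simulate_annotation()].
#' @return List of class `ground_truth`: `regulated_gene_ids`,
#'   `quercetin_site_intervals`, `bead_site_intervals`.
#' @export
simulate_truth <- function(annotation, cfg, seed = cfg$seed + 1) {
  g <- sim_genome(cfg)
  coding <- annotation[annotation$biotype == "protein_coding", , drop = FALSE]
  if (nrow(coding) < cfg$n_regulated)
    stop("simulate_truth: fewer coding genes than n_regulated")
  withr::with_seed(seed, {
    reg <- coding[sort(sample.int(nrow(coding), cfg$n_regulated)), , drop = FALSE]
    prom <- promoter_windows(reg, upstream = cfg$promoter_upstream)
    off <- floor(runif(nrow(prom)) *
                   (prom$end - prom$start - cfg$site_width + 1))
    qsites <- data.frame(chrom = prom$chrom,
                         start = prom$start + off,
                         end = prom$start + off + cfg$site_width,
                         name = reg$gene_id, strand = ".",
                         stringsAsFactors = FALSE)
    avoid <- qsites
    if (cfg$bead_sites_avoid_promoters)
      avoid <- rbind(avoid[, c("chrom", "start", "end")],
                     promoter_windows(annotation,
                                      upstream = cfg$promoter_upstream)[
                       , c("chrom", "start", "end")])
    bsites <- place_disjoint_sites(cfg$bead_sites, cfg$site_width,
                                   g$chrom_lengths, avoid)
  })
  structure(list(regulated_gene_ids = reg$gene_id,
                 quercetin_site_intervals = qsites,
                 bead_site_intervals = bsites),
            class = "ground_truth")
}

# Rejection-sample n disjoint intervals of `width` avoiding `avoid`.
place_disjoint_sites <- function(n, width, chrom_lengths, avoid) {
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
  if (n == 0) return(placed)
  chroms <- names(chrom_lengths)
  tries <- 0
  while (nrow(placed) < n) {
    tries <- tries + 1
    if (tries > 200 * n)
      stop("could not place ", n, " disjoint sites; genome too crowded")
    chr <- chroms[sample.int(length(chroms), 1)]
    s <- floor(runif(1, 0, chrom_lengths[[chr]] - width))
    cand <- data.frame(chrom = chr, start = s, end = s + width,
                       stringsAsFactors = FALSE)
    blockers <- rbind(avoid[, c("chrom", "start", "end")],
                      placed[, c("chrom", "start", "end")])
    if (length(overlap_any_idx(cand, blockers)) == 0)
      placed <- rbind(placed, cand)
  }
  placed$name <- sprintf("bead_site_%03d", seq_len(nrow(placed)))
  placed$strand <- "."
  placed[order(placed$chrom, placed$start), ]
}

#' Simulate the three Chem-seq tag libraries
#'
#' Input DNA is a homogeneous Poisson tag process at the background rate.
#' The bead library adds extra tags at `bead_enrichment` times background
#' over sticky sites; the compound-bead library carries both the sticky
#' signal and `site_enrichment`-fold enrichment over the planted compound
#' binding sites.
#'
#' @inheritParams simulate_truth
#' @param truth A `ground_truth` from [simulate_truth()].
#' @return List of three `tag_track`s: `quercetin_bead`, `bead`, `input`.
#' @export
simulate_chemseq <- function(annotation, truth, cfg, seed = cfg$seed + 2) {
  g <- sim_genome(cfg)
  rate <- g$background_rate
  withr::with_seed(seed, {
    input <- poisson_tags(g$chrom_lengths, rate)
    bead <- add_site_tags(poisson_tags(g$chrom_lengths, rate),
                          truth$bead_site_intervals,
                          (cfg$bead_enrichment - 1) * rate)
    quer <- add_site_tags(poisson_tags(g$chrom_lengths, rate),
                          truth$bead_site_intervals,
                          (cfg$bead_enrichment - 1) * rate)
    quer <- add_site_tags(quer, truth$quercetin_site_intervals,
                          (cfg$site_enrichment - 1) * rate)
  })
  list(quercetin_bead = tag_track(quer, g$chrom_lengths),
       bead = tag_track(bead, g$chrom_lengths),
       input = tag_track(input, g$chrom_lengths))
}

poisson_tags <- function(chrom_lengths, rate) {
  setNames(lapply(names(chrom_lengths), function(chr) {
    L <- chrom_lengths[[chr]]
    n <- rpois(1, rate * L)
    floor(runif(n, 0, L))
  }), names(chrom_lengths))
}

add_site_tags <- function(pos, sites, extra_rate) {
  if (extra_rate <= 0 || nrow(sites) == 0) return(pos)
  for (i in seq_len(nrow(sites))) {
    w <- sites$end[i] - sites$start[i]
    n <- rpois(1, extra_rate * w)
    if (n > 0) {
      chr <- sites$chrom[i]
      pos[[chr]] <- c(pos[[chr]], floor(runif(n, sites$start[i], sites$end[i])))
    }
  }
  pos
}

#' Simulate promoter sequences with a planted motif
#'
#' I.i.d. uniform ACGT background over every promoter window; the
#' configured consensus is planted at a random offset in
#' `motif_plant_fraction` of the regulated promoters and in none of the
#' others (chance matches aside).
#'
#' @inheritParams simulate_chemseq
#' @return Named character vector, one sequence per gene (names = gene
#'   ids), each of length `promoter_upstream + 1`.
#' @export
simulate_promoter_sequences <- function(annotation, truth, cfg,
                                        seed = cfg$seed + 3) {
  width <- cfg$promoter_upstream + 1
  motif <- cfg$motif_consensus
  if (nchar(motif) > width)
    stop("simulate_promoter_sequences: motif longer than promoter window")
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(nrow(annotation)), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, "")
    names(seqs) <- annotation$gene_id
    reg <- intersect(truth$regulated_gene_ids, annotation$gene_id)
    n_plant <- round(cfg$motif_plant_fraction * length(reg))
    if (n_plant > 0) {
      planted <- reg[sample.int(length(reg), n_plant)]
      for (gid in planted) {
        off <- sample.int(width - nchar(motif) + 1, 1)
        substr(seqs[[gid]], off, off + nchar(motif) - 1) <- motif
      }
    }
  })
  seqs
}

#' Simulate RNA-seq counts for the three conditions
#'
#' Gene baseline means are log-normal; counts are negative binomial with
#' the configured dispersion. Regulated genes have their mean multiplied by
#' `planted_fc` in the `quercetin` and `bioquercetin` conditions;
#' unregulated genes are identical across conditions. Per-sample depth
#' factors are log-normal.
#'
#' @inheritParams simulate_chemseq
#' @return A [count_matrix()] with conditions `DMSO`, `quercetin`,
#'   `bioquercetin` (`n_replicates` samples each).
#' @export
simulate_rnaseq <- function(annotation, truth, cfg, seed = cfg$seed + 4) {
  conds <- c("DMSO", "quercetin", "bioquercetin")
  n_s <- cfg$n_replicates * length(conds)
  condition <- rep(conds, each = cfg$n_replicates)
  sample_ids <- sprintf("s%02d", seq_len(n_s))
  genes <- annotation$gene_id
  withr::with_seed(seed, {
    base_mu <- rlnorm(length(genes), cfg$baseline_meanlog, cfg$baseline_sdlog)
    depth <- rlnorm(n_s, 0, cfg$depth_sdlog)
    fc <- matrix(1, nrow = length(genes), ncol = n_s)
    reg <- genes %in% truth$regulated_gene_ids
    fc[reg, condition != "DMSO"] <- cfg$planted_fc
    mu <- (base_mu * fc) * rep(depth, each = length(genes))
    counts <- if (cfg$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      rpois(length(mu), mu)
    }
    m <- matrix(as.integer(counts), nrow = length(genes),
                dimnames = list(genes, sample_ids))
  })
  count_matrix(m, condition)
}

#' Generate a complete synthetic study
#'
#' Runs all four generators with seeds derived from one root seed and
#' optionally writes every artifact (annotation GTF, tag BEDs, promoter
#' FASTA, count TSV, ground-truth BED/JSON) to `outdir`.
#'
#' @param cfg A [sim_config()].
#' @param seed Root seed; sub-generators use `seed`, `seed+1`, ...
#' @param outdir Optional output directory.
#' @return List with `annotation`, `truth`, `tracks`, `promoters`,
#'   `counts`, `cfg` and (when written) `files`.
#' @export
simulate_chemcis <- function(cfg = sim_config(), seed = cfg$seed,
                             outdir = NULL) {
  annotation <- simulate_annotation(cfg, seed)
  truth <- simulate_truth(annotation, cfg, seed + 1)
  tracks <- simulate_chemseq(annotation, truth, cfg, seed + 2)
  promoters <- simulate_promoter_sequences(annotation, truth, cfg, seed + 3)
  counts <- simulate_rnaseq(annotation, truth, cfg, seed + 4)
  out <- list(annotation = annotation, truth = truth, tracks = tracks,
              promoters = promoters, counts = counts, cfg = cfg, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- list(
      annotation = file.path(outdir, "genes.gtf"),
      quercetin_bead = file.path(outdir, "tags_quercetin_bead.bed"),
      bead = file.path(outdir, "tags_bead.bed"),
      input = file.path(outdir, "tags_input.bed"),
      promoters = file.path(outdir, "promoters.fa"),
      counts = file.path(outdir, "counts.tsv"),
      truth_sites = file.path(outdir, "truth_quercetin_sites.bed"),
      truth_bead_sites = file.path(outdir, "truth_bead_sites.bed"),
      truth = file.path(outdir, "ground_truth.json"))
    write_annotation(annotation, f$annotation)
    write_tags(tracks$quercetin_bead, f$quercetin_bead)
    write_tags(tracks$bead, f$bead)
    write_tags(tracks$input, f$input)
    write_fasta(promoters, f$promoters)
    write_counts(counts, f$counts)
    write_bed(truth$quercetin_site_intervals, f$truth_sites)
    write_bed(truth$bead_site_intervals, f$truth_bead_sites)
    jsonlite::write_json(
      list(regulated_gene_ids = truth$regulated_gene_ids,
           seed = seed,
           config = unclass(cfg)),
      f$truth, auto_unbox = TRUE, digits = NA, null = "null")
    out$files <- f
  }
  out
}
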