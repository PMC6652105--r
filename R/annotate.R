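#' Promoter window of a gene
#'
#' The promoter is the upstream window ending at (and including) the TSS
#' base: `[max(0, tss - upstream), tss + 1)` on the plus strand and the
#' strand mirror `[tss, tss + upstream + 1)` on the minus strand. Off the
#' chromosome edge the window has length `upstream + 1`.
#'
#' @param genes Gene model data frame (one or more rows).
#' @param upstream Window size upstream of the TSS in bp (default 500).
#' @return Interval data frame with a `gene_id` column.
#' @export
promoter_windows <- function(genes, upstream = 500) {
  stopifnot(upstream > 0)
  validate_annotation(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0, genes$tss - upstream), genes$tss)
  end <- ifelse(plus, genes$tss + 1, genes$tss + upstream + 1)
  data.frame(chrom = genes$chrom, start = start, end = end,
             strand = genes$strand, gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

#' Associate peaks with genes through promoter overlap
#'
#' A gene is associated iff at least one peak overlaps its promoter window;
#' a peak may associate with several genes.
#'
#' @param peaks Peak (interval) data frame.
#' @param annotation Gene model data frame.
#' @param upstream Promoter window size in bp.
#' @return List with `genes` (character vector of associated gene ids, in
#'   annotation order) and `map` (named list gene_id -> integer indices of
#'   the overlapping peaks in `peaks`).
#' @export
peaks_to_genes <- function(peaks, annotation, upstream = 500) {
  prom <- promoter_windows(annotation, upstream)
  if (nrow(peaks) == 0)
    return(list(genes = character(0), map = list()))
  pairs <- overlap_pairs(prom, peaks)
  if (nrow(pairs) == 0)
    return(list(genes = character(0), map = list()))
  map <- lapply(split(pairs[, "subject"], prom$gene_id[pairs[, "query"]]),
                function(ix) sort(unique(ix)))
  genes <- annotation$gene_id[annotation$gene_id %in% names(map)]
  list(genes = genes, map = map[genes])
}
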