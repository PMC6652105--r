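#' Filter a count matrix to expressed coding genes
#'
#' Retains genes that (a) have biotype `protein_coding` in the annotation
#' and (b) exceed `min_count` reads (strictly) in at least one sample.
#' Genes absent from the annotation are dropped with a warning. Input
#' order is preserved.
#'
#' @param cm A [count_matrix()].
#' @param annotation Gene model data frame.
#' @param min_count Strict read-count threshold (default 10: a gene with
#'   all counts equal to 10 is removed).
#' @return Filtered [count_matrix()].
#' @export
filter_genes <- function(cm, annotation, min_count = 10) {
  stopifnot(is(cm, "count_matrix"))
  known <- rownames(cm$counts) %in% annotation$gene_id
  if (any(!known))
    warning("filter_genes: dropping ", sum(!known),
            " gene(s) absent from the annotation")
  biotype <- annotation$biotype[match(rownames(cm$counts), annotation$gene_id)]
  keep <- known & biotype %in% "protein_coding" &
    apply(cm$counts, 1, max) > min_count
  if (!any(keep)) warning("filter_genes: no genes pass the filters")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$condition)
}

#' Median-of-ratios size factors
#'
#' Library normalization in the DESeq style: the reference is the per-gene
#' geometric mean over samples, computed on genes with all-positive
#' counts; each sample's size factor is the median ratio of its counts to
#' the reference.
#'
#' @param cm A [count_matrix()].
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  stopifnot(is(cm, "count_matrix"))
  k <- cm$counts
  pos <- rowSums(k > 0) == ncol(k)
  if (!any(pos))
    stop("size_factors: no gene has positive counts in every sample; ",
         "consider a pseudocount on the matrix")
  logref <- rowMeans(log(k[pos, , drop = FALSE]))
  sf <- apply(k[pos, , drop = FALSE], 2, function(col)
    exp(median(log(col) - logref)))
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("size_factors: degenerate factors")
  sf
}

#' Per-gene fold changes between two conditions
#'
#' Fold change is the ratio of mean normalized counts
#' `(mean_t + pseudocount) / (mean_c + pseudocount)`; when
#' `compute_tests = TRUE` a per-gene Welch t-test on
#' `log2(normalized + pseudocount)` with Benjamini-Hochberg adjustment is
#' attached.
#'
#' @param cm A [count_matrix()] (typically filtered).
#' @param treatment_cond,control_cond Condition labels.
#' @param factors Size factors; default [size_factors()] of `cm`.
#' @param pseudocount Added to the normalized condition means (default
#'   0.5) so fold changes stay finite; a gene with zero counts everywhere
#'   has FC = 1.
#' @param compute_tests Attach Welch-t p/q values (default `TRUE`).
#' @return Data frame (FC table): `gene_id`, `fc`, `log2fc`,
#'   `mean_treatment`, `mean_control`, and with tests `p_value`,
#'   `q_value`.
#' @export
fold_change <- function(cm, treatment_cond, control_cond,
                        factors = size_factors(cm), pseudocount = 0.5,
                        compute_tests = TRUE) {
  stopifnot(is(cm, "count_matrix"))
  for (cond in c(treatment_cond, control_cond))
    if (!cond %in% cm$condition)
      stop("fold_change: unknown condition label '", cond, "'")
  norm <- sweep(cm$counts, 2, factors, "/")
  ti <- cm$condition == treatment_cond
  ci <- cm$condition == control_cond
  mt <- rowMeans(norm[, ti, drop = FALSE])
  mc <- rowMeans(norm[, ci, drop = FALSE])
  fc <- (mt + pseudocount) / (mc + pseudocount)
  out <- data.frame(gene_id = rownames(cm$counts), fc = fc,
                    log2fc = log2(fc), mean_treatment = mt, mean_control = mc,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (compute_tests) {
    lt <- log2(norm[, ti, drop = FALSE] + pseudocount)
    lc <- log2(norm[, ci, drop = FALSE] + pseudocount)
    out$p_value <- vapply(seq_len(nrow(out)), function(i)
      welch_t_test(lt[i, ], lc[i, ])$p, 0)
    out$q_value <- benjamini_hochberg(out$p_value)
  }
  out
}

#' Differentially expressed genes from an FC table
#'
#' Default reading: a gene is differential when its fold change lies
#' outside `[fc_low, fc_high]` (closed bounds included: FC exactly 2 with
#' q < fdr is called) and its adjusted p-value is below `fdr`. The literal
#' "inside the interval" reading is available with `inside = TRUE`.
#'
#' @param fc_table Output of [fold_change()] (must carry `p_value` /
#'   `q_value`).
#' @param fdr FDR threshold (default 0.05).
#' @param fc_low,fc_high Fold-change bounds (defaults 0.5 and 2).
#' @param inside Select genes with FC inside `[fc_low, fc_high]` instead.
#' @return Character vector of gene ids.
#' @export
differential_genes <- function(fc_table, fdr = 0.05, fc_low = 0.5,
                               fc_high = 2.0, inside = FALSE) {
  if (is.null(fc_table$q_value))
    stop("differential_genes: fc_table carries no p/q values; ",
         "run fold_change(compute_tests = TRUE)")
  in_band <- fc_table$fc >= fc_low & fc_table$fc <= fc_high
  sel <- if (inside) in_band else (fc_table$fc <= fc_low | fc_table$fc >= fc_high)
  fc_table$gene_id[sel & fc_table$q_value < fdr]
}

#' Write an FC table as TSV
#' @param fc_table Output of [fold_change()].
#' @param path Output path.
#' @export
write_fc_table <- function(fc_table, path) {
  write.table(fc_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
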