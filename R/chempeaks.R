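#' Consensus of two peak-call sets
#'
#' Keeps the peaks of `calls_a` that overlap (>= 1 bp, strand-blind) at
#' least one peak of `calls_b`; coordinates and scores are taken from
#' `calls_a`. Output is ordered by score descending, ties by
#' (chrom, start).
#'
#' @param calls_a,calls_b Peak data frames.
#' @return Subset of `calls_a`.
#' @export
consensus <- function(calls_a, calls_b) {
  keep <- overlap_any_idx(calls_a, calls_b)
  out <- calls_a[keep, , drop = FALSE]
  out <- out[order(-out$score, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude bead-derived signal from a peak list
#'
#' Returns the peaks of `quercetin_peaks` with zero base-pair overlap
#' against every peak of `bead_peaks`; relative input order is preserved.
#' Together with [consensus()] this partitions the input list.
#'
#' @param quercetin_peaks,bead_peaks Peak data frames.
#' @return Subset of `quercetin_peaks`.
#' @export
exclude_bead_signal <- function(quercetin_peaks, bead_peaks) {
  drop <- overlap_any_idx(quercetin_peaks, bead_peaks)
  out <- if (length(drop) == 0) quercetin_peaks else
    quercetin_peaks[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most significant n peaks
#'
#' @param peaks Peak data frame with a `score` column.
#' @param n Number of peaks to keep (score descending; ties by
#'   chrom, start ascending). `n >= nrow(peaks)` returns the full re-sorted
#'   list.
#' @return Peak data frame with at most `n` rows.
#' @export
select_top_n <- function(peaks, n) {
  stopifnot(n >= 0)
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  out <- peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full Chem-seq inference: dual-caller consensus and bead exclusion
#'
#' Run 1 calls the compound-bead library against the bead library under
#' both caller modes and intersects the two call sets (consensus) to give
#' the raw compound peak list. Run 2 derives the bead-background list by
#' calling against input DNA — by default with the bead library alone as
#' treatment (`run2_treatment = "beads"`); the alternative reading that
#' pools compound-bead and bead tags as treatment is available as
#' `"pooled"`, but note that the pooled treatment contains the
#' compound-specific tags, so every true binding site is then also called
#' in run 2 and removed by the exclusion step. Final peaks are the run-1
#' peaks with zero overlap against the run-2 list.
#'
#' @param q_track,bead_track,input_track `tag_track`s of the compound-bead,
#'   bead-only and input libraries (shared chromosome namespace).
#' @param params [peak_params()]; the mode field is overridden internally
#'   (both modes are always run).
#' @param n_top Size of the ranked top lists (default 1000).
#' @param run2_treatment `"beads"` (default) or `"pooled"`.
#' @return List of class `chemseq_result`: `quercetin_raw`, `bead_derived`,
#'   `quercetin_final`, `quercetin_topN`, `bead_topN`, `provenance`.
#' @export
run_chemseq_analysis <- function(q_track, bead_track, input_track,
                                 params = peak_params(), n_top = 1000,
                                 run2_treatment = c("beads", "pooled")) {
  run2_treatment <- match.arg(run2_treatment)
  p_local <- params; p_local$mode <- "local_lambda"
  p_global <- params; p_global$mode <- "global_lambda"

  q_local <- call_peaks(q_track, bead_track, p_local)
  q_global <- call_peaks(q_track, bead_track, p_global)
  quercetin_raw <- consensus(q_local, q_global)

  run2_track <- if (run2_treatment == "pooled")
    merge_tracks(q_track, bead_track) else bead_track
  b_local <- call_peaks(run2_track, input_track, p_local)
  b_global <- call_peaks(run2_track, input_track, p_global)
  bead_derived <- consensus(b_local, b_global)

  quercetin_final <- exclude_bead_signal(quercetin_raw, bead_derived)
  if (nrow(quercetin_final) == 0)
    message("run_chemseq_analysis: final compound peak list is empty")
  stopifnot(length(overlap_any_idx(quercetin_final, bead_derived)) == 0)

  structure(list(
    quercetin_raw = quercetin_raw,
    bead_derived = bead_derived,
    quercetin_final = quercetin_final,
    quercetin_topN = select_top_n(quercetin_final, n_top),
    bead_topN = select_top_n(bead_derived, n_top),
    provenance = list(params = unclass(params), n_top = n_top,
                      run2_treatment = run2_treatment,
                      n_raw = nrow(quercetin_raw),
                      n_bead_derived = nrow(bead_derived),
                      n_final = nrow(quercetin_final))),
    class = "chemseq_result")
}

#' @export
print.chemseq_result <- function(x, ...) {
  cat("chemseq_result:", x$provenance$n_raw, "raw compound peaks,",
      x$provenance$n_bead_derived, "bead-derived peaks,",
      x$provenance$n_final, "after exclusion\n")
  invisible(x)
}
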