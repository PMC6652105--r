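#' Poisson upper-tail probability
#'
#' Returns `P(X >= k)` for `X ~ Poisson(lam)` — the enrichment significance
#' core of the window caller. Computed via the regularized survivor
#' function (`ppois`); equals 1 when `k = 0`.
#'
#' @param k Non-negative integer count(s).
#' @param lam Positive Poisson mean(s).
#' @return Numeric vector of tail probabilities in (0, 1].
#' @export
poisson_sf <- function(k, lam) {
  if (any(lam <= 0)) stop("poisson_sf: lam must be > 0")
  if (any(k < 0)) stop("poisson_sf: k must be >= 0")
  ppois(k - 1, lam, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard FDR step-up adjustment; input order is preserved in the
#' output.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values (q-values), each in (0, 1].
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("benjamini_hochberg: p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Peak-caller parameters
#'
#' Two scoring modes stand in for the two external callers the consensus
#' layer expects: `global_lambda` scores every window against the
#' depth-scaled genome-wide control rate; `local_lambda` additionally takes
#' the maximum over depth-scaled control rates in centered windows of the
#' `local_windows` scales (MACS-style local background), floored by the
#' global rate.
#'
#' @param window_w Sliding window width in bp.
#' @param step Window stride in bp (must be <= `window_w`).
#' @param merge_gap Significant windows closer than this are merged.
#' @param mode `"global_lambda"` or `"local_lambda"`.
#' @param local_windows Local background scales in bp.
#' @param q_threshold FDR level for window significance.
#' @param lambda_floor Minimum expected tags per window when the control is
#'   locally empty (avoids infinite enrichment).
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(window_w = 300, step = 100, merge_gap = 200,
                        mode = c("local_lambda", "global_lambda"),
                        local_windows = c(1000, 5000, 10000),
                        q_threshold = 0.05, lambda_floor = 0.25) {
  mode <- match.arg(mode)
  stopifnot(step <= window_w, window_w > 0, step > 0, merge_gap >= 0,
            q_threshold > 0, q_threshold < 1, all(local_windows > 0),
            lambda_floor > 0)
  structure(list(window_w = window_w, step = step, merge_gap = merge_gap,
                 mode = mode, local_windows = local_windows,
                 q_threshold = q_threshold, lambda_floor = lambda_floor),
            class = "peak_params")
}

#' Call peaks from a treatment track against a control track
#'
#' Slides windows of `window_w` bp at stride `step` over every chromosome,
#' computes the treatment tag count `k` per window and a depth-normalized
#' control expectation `lambda` (per the chosen mode), scores each window
#' with the Poisson upper tail `P(X >= k)`, adjusts once genome-wide by
#' Benjamini-Hochberg, and merges significant windows separated by at most
#' `merge_gap` bp into peaks.
#'
#' Each peak records the minimum window p-value (and its adjusted q), the
#' tag count and control expectation over the merged interval, fold
#' enrichment (floored expectation), and a summit at the position of
#' maximal local tag density.
#'
#' @param treatment,control `tag_track` objects on a shared chromosome
#'   namespace.
#' @param params A [peak_params()].
#' @param windows If `TRUE`, return the window-level table (`chrom`,
#'   `start`, `end`, `k`, `lam`, `p`, `q`) instead of merged peaks —
#'   useful for calibration diagnostics.
#' @return Peak data frame sorted by score (`-log10 p`) descending, ties
#'   broken by (chrom, start): columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `p_value`, `q_value`, `treatment_tags`,
#'   `expected_tags`, `fold_enrichment`, `summit`, plus the scoring
#'   window's count and expectation (`window_k`, `window_lam`), from which
#'   `p_value` derives.
#' @export
call_peaks <- function(treatment, control, params = peak_params(),
                       windows = FALSE) {
  stopifnot(is(treatment, "tag_track"), is(control, "tag_track"))
  if (treatment$total_tags == 0) stop("call_peaks: empty treatment track")
  if (control$total_tags == 0) stop("call_peaks: empty control track")
  w <- params$window_w
  scale <- treatment$total_tags / control$total_tags
  genome_len <- sum(treatment$chrom_lengths)
  lambda_global <- control$total_tags * scale * w / genome_len

  win <- list()
  for (chr in names(treatment$positions)) {
    L <- treatment$chrom_lengths[[chr]]
    starts <- seq(0, max(0, L - w), by = params$step)
    k <- window_tag_counts(treatment, chr, starts, w)
    ctrl_n <- length(control$positions[[chr]])
    if (ctrl_n == 0)
      warning("call_peaks: control empty on ", chr,
              "; falling back to the global rate")
    lam <- rep(lambda_global, length(starts))
    if (params$mode == "local_lambda" && ctrl_n > 0) {
      lam_w <- window_tag_counts(control, chr, starts, w) * scale
      lam <- pmax(lam, lam_w)
      centers <- starts + w / 2
      for (s in params$local_windows) {
        cnt <- findInterval(centers + s / 2 - 0.5, control$positions[[chr]]) -
          findInterval(centers - s / 2 - 0.5, control$positions[[chr]])
        lam <- pmax(lam, cnt * scale * w / s)
      }
    }
    lam <- pmax(lam, params$lambda_floor)
    win[[chr]] <- data.frame(chrom = chr, start = starts, end = starts + w,
                             k = k, lam = lam, stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, win)
  # clamp deep-tail underflow to the smallest positive double so the
  # downstream (0, 1] contracts hold
  win$p <- pmax(poisson_sf(win$k, win$lam), .Machine$double.xmin)
  win$q <- benjamini_hochberg(win$p)
  if (windows) return(win)
  sig <- win[win$q < params$q_threshold, , drop = FALSE]
  peaks <- merge_windows(sig, treatment, control, scale, params)
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks <- peaks[ord, , drop = FALSE]
  if (nrow(peaks) > 0) {
    peaks$name <- sprintf("peak_%04d", seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
  }
  peaks
}

empty_peaks <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = numeric(0), strand = character(0),
             p_value = numeric(0), q_value = numeric(0),
             treatment_tags = numeric(0), expected_tags = numeric(0),
             fold_enrichment = numeric(0), summit = numeric(0),
             window_k = numeric(0), window_lam = numeric(0),
             stringsAsFactors = FALSE)
}

merge_windows <- function(sig, treatment, control, scale, params) {
  if (nrow(sig) == 0) return(empty_peaks())
  out <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, s$start[-1] - cummax_prev_end(s) > params$merge_gap))
    for (gi in split(seq_len(nrow(s)), grp)) {
      pk_start <- min(s$start[gi])
      pk_end <- max(s$end[gi])
      len <- pk_end - pk_start
      tags <- window_tag_counts(treatment, chr, pk_start, len)
      exp_tags <- window_tag_counts(control, chr, pk_start, len) * scale
      floor_exp <- params$lambda_floor * len / params$window_w
      imin <- gi[which.min(s$p[gi])]
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = pk_start, end = pk_end, name = "",
        score = -log10(max(s$p[imin], .Machine$double.xmin)),
        strand = ".",
        p_value = s$p[imin], q_value = s$q[imin],
        treatment_tags = tags, expected_tags = exp_tags,
        fold_enrichment = tags / max(exp_tags, floor_exp),
        summit = peak_summit(treatment, chr, pk_start, pk_end),
        window_k = s$k[imin], window_lam = s$lam[imin],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# For grouping: running maximum of previous window ends (windows overlap,
# so a plain lag of `end` can understate coverage).
cummax_prev_end <- function(s) {
  if (nrow(s) == 1) return(numeric(0))
  cummax(s$end)[-nrow(s)]
}

# Summit: tag position of maximal local (+/- 25 bp) tag count; ties break
# to the leftmost position. Falls back to the interval midpoint if the
# interval holds no tags.
peak_summit <- function(track, chrom, start, end) {
  p <- track$positions[[chrom]]
  p <- p[p >= start & p < end]
  if (length(p) == 0) return(floor((start + end) / 2))
  cand <- unique(p)
  local <- findInterval(cand + 25.5, p) - findInterval(cand - 25.5, p)
  cand[which.max(local)]
}

#' Write peaks as BED6+ (p, q, fold enrichment, summit as extra columns)
#'
#' @param peaks Peak data frame from [call_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  write_bed(peaks, path,
            extra_cols = c("p_value", "q_value", "fold_enrichment", "summit"))
}
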