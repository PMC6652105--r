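#' Hypergeometric gene-set enrichment
#'
#' For each gene set, tests over-representation of `candidates` within
#' `universe` with the hypergeometric upper tail `P(X >= overlap)`; q is
#' Benjamini-Hochberg across the tested sets. Sets are intersected with
#' the universe before testing.
#'
#' @param candidates Character vector of candidate gene ids (must be a
#'   subset of `universe`).
#' @param universe Character vector of all eligible gene ids.
#' @param genesets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return Data frame with one row per set: `set_name`, `overlap`,
#'   `candidates`, `set_size`, `universe`, `p_value`, `q_value`.
#' @export
geneset_enrichment <- function(candidates, universe, genesets) {
  if (length(universe) == 0) stop("geneset_enrichment: empty universe")
  universe <- unique(universe)
  candidates <- unique(candidates)
  if (!all(candidates %in% universe))
    stop("geneset_enrichment: candidates must be a subset of the universe")
  rows <- lapply(names(genesets), function(nm) {
    s <- intersect(unique(genesets[[nm]]), universe)
    ov <- length(intersect(candidates, s))
    p <- phyper(ov - 1, length(s), length(universe) - length(s),
                length(candidates), lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, candidates = length(candidates),
               set_size = length(s), universe = length(universe),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Position weight matrix
#'
#' @param matrix Numeric L x 4 matrix of per-position base probabilities,
#'   columns A, C, G, T; each row must sum to 1.
#' @param background Length-4 background probabilities (default uniform).
#' @param name Motif name.
#' @return A list of class `pwm`.
#' @export
pwm <- function(matrix, background = rep(0.25, 4), name = "motif") {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == 4, nrow(matrix) >= 4)
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop("pwm: each position must sum to 1")
  if (abs(sum(background) - 1) > 1e-9)
    stop("pwm: background must sum to 1")
  colnames(matrix) <- c("A", "C", "G", "T")
  structure(list(matrix = matrix, background = setNames(background,
                                                        c("A", "C", "G", "T")),
                 name = name), class = "pwm")
}

#' Read a PWM from a 4-column probability text file
#'
#' One row per motif position, columns A C G T; `#` comment lines and a
#' JASPAR-style `>name` header line are tolerated.
#'
#' @param path File path.
#' @return A [pwm()].
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  name <- "motif"
  hdr <- grep("^>", lines)
  if (length(hdr) > 0) name <- sub("^>\\s*", "", lines[hdr[1]])
  lines <- lines[!grepl("^[#>]", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  pwm(m, name = name)
}

#' Consensus string of a PWM (argmax base per position)
#' @param x A [pwm()].
#' @return Character string.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$matrix)[max.col(x$matrix, ties.method = "first")],
        collapse = "")
}

# Maximum achievable log-odds score of a PWM.
pwm_max_score <- function(x) {
  lo <- log2(x$matrix / rep(x$background, each = nrow(x$matrix)))
  sum(apply(lo, 1, max))
}

#' Scan a sequence with a PWM on both strands
#'
#' Log-odds score `sum(log2(p_motif / p_background))` at every offset on
#' both strands; `N` bases score as background (contribute 0). A hit is an
#' offset whose score reaches `score_threshold`.
#'
#' @param sequence Character string over A, C, G, T, N.
#' @param x A [pwm()].
#' @param score_threshold Threshold in log-odds (bits).
#' @return Data frame with `pos` (1-based start of the match on the given
#'   sequence), `strand`, `score`, ordered by position.
#' @export
pwm_scan <- function(sequence, x, score_threshold) {
  L <- nchar(sequence)
  M <- nrow(x$matrix)
  if (L < M)
    return(data.frame(pos = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  lo <- log2(x$matrix / rep(x$background, each = M))
  lo <- cbind(lo, N = 0)
  idx <- match(strsplit(toupper(sequence), "")[[1]],
               c("A", "C", "G", "T", "N"))
  if (any(is.na(idx))) stop("pwm_scan: sequence must be over {A,C,G,T,N}")
  n_off <- L - M + 1
  fwd <- rev <- numeric(n_off)
  # reverse-complement scan: complement base at mirrored motif position
  comp <- c(4L, 3L, 2L, 1L, 5L)
  for (j in seq_len(M)) {
    fwd <- fwd + lo[j, idx[j:(j + n_off - 1)]]
    rev <- rev + lo[M - j + 1, comp[idx[j:(j + n_off - 1)]]]
  }
  fi <- which(fwd >= score_threshold)
  ri <- which(rev >= score_threshold)
  hits <- rbind(
    data.frame(pos = fi, strand = rep("+", length(fi)), score = fwd[fi]),
    data.frame(pos = ri, strand = rep("-", length(ri)), score = rev[ri]))
  hits <- hits[order(hits$pos, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Known-motif enrichment between two sequence sets
#'
#' A sequence is hit-positive if it carries at least one PWM hit at the
#' threshold; enrichment of hit-positive sequences in `target_seqs` over
#' `background_seqs` is tested with a one-sided (greater) Fisher exact test
#' on the 2x2 table.
#'
#' @param target_seqs,background_seqs Character vectors of sequences.
#' @param x A [pwm()].
#' @param score_threshold Log-odds threshold; default 80% of the maximum
#'   achievable score.
#' @return List: `target_hit_fraction`, `background_hit_fraction`,
#'   `target_hits`, `background_hits`, `p_value`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, x,
                             score_threshold = 0.8 * pwm_max_score(x)) {
  stopifnot(length(target_seqs) > 0, length(background_seqs) > 0)
  hit <- function(s) nrow(pwm_scan(s, x, score_threshold)) > 0
  th <- sum(vapply(target_seqs, hit, TRUE))
  bh <- sum(vapply(background_seqs, hit, TRUE))
  tab <- matrix(c(th, length(target_seqs) - th,
                  bh, length(background_seqs) - bh), nrow = 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(target_hit_fraction = th / length(target_seqs),
       background_hit_fraction = bh / length(background_seqs),
       target_hits = th, background_hits = bh, p_value = p)
}

#' The packaged E2F-like example PWM
#'
#' A cell-cycle (E2F-family-like) GC-rich motif used as the default known
#' motif; user-replaceable via [read_pwm()].
#'
#' @return A [pwm()].
#' @export
e2f_like_pwm <- function() {
  read_pwm(system.file("extdata", "e2f_like.pwm", package = "chemcis"))
}
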