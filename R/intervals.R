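#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the convention used throughout the
#' package. An interval of length L contains exactly L bases; abutting
#' intervals do not overlap.
#'
#' @param chrom Character vector of chromosome names (non-empty strings).
#' @param start Integer vector, 0-based inclusive start; must be >= 0.
#' @param end Integer vector, exclusive end; must satisfy `end > start`.
#' @param strand Character vector in `"+"`, `"-"`, `"."` (unstranded).
#' @param ... Further equal-length columns (e.g. `name`, `score`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   plus any extra columns.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom)))
    stop("interval validation: empty chromosome name")
  if (any(df$start < 0))
    stop("interval validation: start < 0")
  if (any(df$end <= df$start))
    stop("interval validation: end <= start (coordinates are half-open)")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("interval validation: strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Test whether two intervals overlap
#'
#' Overlap requires at least one shared base on the same chromosome; strand
#' is ignored. Vectorized over both arguments (recycled).
#'
#' @param a,b Interval data frames (see [genomic_intervals()]); single rows
#'   or equal/recyclable lengths.
#' @return Logical vector.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# Indices of rows in `query` that overlap >= 1 row of `subject`.
# Backed by IRanges::findOverlaps per chromosome namespace.
overlap_any_idx <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) return(integer(0))
  hit <- logical(nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1, end = subject$end[si])
    hit[qi] <- IRanges::overlapsAny(qr, sr)
  }
  which(hit)
}

# All overlapping (query, subject) row pairs as a two-column matrix.
overlap_pairs <- function(query, subject) {
  out <- list()
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0 || length(qi) == 0) next
    qr <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1, end = subject$end[si])
    h <- IRanges::findOverlaps(qr, sr)
    out[[chr]] <- cbind(query = qi[S4Vectors::queryHits(h)],
                        subject = si[S4Vectors::subjectHits(h)])
  }
  if (length(out) == 0) return(cbind(query = integer(0), subject = integer(0)))
  do.call(rbind, out)
}
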