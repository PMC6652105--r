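#' Tag track: per-chromosome sorted tag 5' positions
#'
#' The unit record of a Chem-seq library after alignment: single-base 5'
#' tag positions (0-based), sorted ascending within each chromosome.
#'
#' @param positions Named list of numeric vectors of tag positions, one
#'   element per chromosome (will be sorted).
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @return A list of class `tag_track` with `positions`, `chrom_lengths`
#'   and `total_tags`.
#' @export
tag_track <- function(positions, chrom_lengths) {
  stopifnot(is.list(positions), !is.null(names(positions)),
            all(names(positions) %in% names(chrom_lengths)))
  positions <- lapply(positions, function(p) sort(as.numeric(p)))
  for (chr in names(positions)) {
    p <- positions[[chr]]
    if (length(p) > 0 && (p[1] < 0 || p[length(p)] >= chrom_lengths[[chr]]))
      stop("tag_track: positions outside [0, chrom length) on ", chr)
  }
  structure(list(positions = positions,
                 chrom_lengths = chrom_lengths[names(positions)],
                 total_tags = sum(lengths(positions))),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat("tag_track:", x$total_tags, "tags on",
      length(x$positions), "chromosome(s)\n")
  invisible(x)
}

#' Read/write a tag track as BED of single-base tags
#'
#' Tags are written as 1 bp intervals `[pos, pos+1)`; on read, column 2 is
#' taken as the 5' position.
#'
#' @param path BED file path.
#' @param chrom_lengths Named lengths; if `NULL`, inferred as the maximum
#'   tag end per chromosome.
#' @return `read_tags`: a `tag_track`.
#' @export
read_tags <- function(path, chrom_lengths = NULL) {
  bed <- read_bed(path)
  pos <- split(bed$start, bed$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(bed$end, bed$chrom), max, 0)
  }
  tag_track(pos, chrom_lengths)
}

#' @rdname read_tags
#' @param track A `tag_track`.
#' @export
write_tags <- function(track, path) {
  dfs <- lapply(names(track$positions), function(chr) {
    p <- track$positions[[chr]]
    if (length(p) == 0) return(NULL)
    data.frame(chrom = chr, start = p, end = p + 1, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  if (is.null(df)) df <- data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0))
  write_bed(df, path)
}

# Tag counts of `track` on `chrom` in half-open windows [starts, starts+width).
window_tag_counts <- function(track, chrom, starts, width) {
  p <- track$positions[[chrom]]
  if (is.null(p) || length(p) == 0) return(numeric(length(starts)))
  findInterval(starts + width - 0.5, p) - findInterval(starts - 0.5, p)
}

# Merge the tags of two tracks (used for the pooled run-2 reading).
merge_tracks <- function(a, b) {
  chroms <- union(names(a$positions), names(b$positions))
  lens <- c(a$chrom_lengths, b$chrom_lengths)
  pos <- setNames(lapply(chroms, function(chr) {
    c(a$positions[[chr]], b$positions[[chr]])
  }), chroms)
  tag_track(pos, lens[!duplicated(names(lens))])
}
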