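#' Read a BED file of genomic intervals
#'
#' BED is 0-based half-open, which matches the package's internal
#' convention, so coordinates are taken verbatim. Columns beyond the third
#' (`name`, `score`, `strand`) are kept when present; input order is
#' preserved.
#'
#' @param path Path to a tab-separated BED3/BED6(+) file.
#' @return Interval data frame (possibly zero rows).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(genomic_intervals(character(0), numeric(0), numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", which(nf < 3)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop("BED parse error at line ", bad[1], ": non-numeric coordinate")
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0)
    stop("BED validation error at line ", bad[1],
         ": need 0 <= start < end, got [", start[bad[1]], ", ", end[bad[1]], ")")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(nf >= 4)) df$name <- vapply(fields, `[[`, "", 4)
  if (all(nf >= 5)) df$score <- as.numeric(vapply(fields, `[[`, "", 5))
  if (all(nf >= 6)) df$strand <- vapply(fields, `[[`, "", 6) else df$strand <- "."
  validate_intervals(df)
  df
}

#' Write intervals as BED
#'
#' Emits BED3 by default, adding `name`/`score`/`strand` columns (in BED6
#' order) when present in `x`, plus any `extra_cols` appended after them.
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @param extra_cols Character vector of additional column names in `x` to
#'   append after the first six BED fields.
#' @export
write_bed <- function(x, path, extra_cols = character(0)) {
  validate_intervals(x)
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has6 <- all(c("name", "score") %in% names(x)) || length(extra_cols) > 0
  if (has6 || "name" %in% names(x)) {
    cols <- c(cols, list(
      if (!is.null(x$name)) x$name else ".",
      if (!is.null(x$score)) as.character(x$score) else "0",
      if (!is.null(x$strand)) x$strand else "."))
  }
  for (cc in extra_cols) cols <- c(cols, list(as.character(x[[cc]])))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a GTF-like gene annotation
#'
#' Expects tab-separated records (1-based, fully closed coordinates) whose
#' attribute field carries `gene_id` and optionally `gene_biotype`. Only
#' `gene` feature rows are used when a feature column is present. The TSS is
#' derived per strand (record start for `+`, record end for `-`) and
#' converted to the package's 0-based convention.
#'
#' @param path Path to the annotation file.
#' @return Gene model data frame with columns `gene_id`, `chrom`, `strand`,
#'   `tss` (0-based) and `biotype`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tss = numeric(0),
                      biotype = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop("annotation parse error at line ", which(nf < 9)[1],
         ": fewer than 9 tab-separated fields")
  feature <- vapply(fields, `[[`, "", 3)
  keep <- which(feature == "gene")
  if (length(keep) == 0) keep <- seq_along(fields)
  fields <- fields[keep]
  chrom <- vapply(fields, `[[`, "", 1)
  start1 <- as.numeric(vapply(fields, `[[`, "", 4))
  end1 <- as.numeric(vapply(fields, `[[`, "", 5))
  strand <- vapply(fields, `[[`, "", 7)
  attrs <- vapply(fields, `[[`, "", 9)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop("annotation validation error at line ", keep[bad[1]],
         ": unknown strand symbol '", strand[bad[1]], "'")
  gene_id <- extract_attr(attrs, "gene_id")
  bad <- which(is.na(gene_id))
  if (length(bad) > 0)
    stop("annotation parse error at line ", keep[bad[1]], ": missing gene_id")
  biotype <- extract_attr(attrs, "gene_biotype")
  biotype[is.na(biotype)] <- "protein_coding"
  tss <- ifelse(strand == "+", start1 - 1, end1 - 1)
  gm <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = tss, biotype = biotype, stringsAsFactors = FALSE)
  validate_annotation(gm)
  gm
}

extract_attr <- function(attrs, key) {
  pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(g) {
    if (length(g) >= 2) g[2] else NA_character_
  }, "")
}

validate_annotation <- function(gm) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "biotype") %in% names(gm)))
  if (nrow(gm) == 0) return(invisible(gm))
  if (anyDuplicated(gm$gene_id))
    stop("annotation validation: duplicate gene_id '",
         gm$gene_id[duplicated(gm$gene_id)][1], "'")
  if (any(gm$tss < 0)) stop("annotation validation: tss < 0")
  if (!all(gm$strand %in% c("+", "-")))
    stop("annotation validation: gene strand must be '+' or '-'")
  invisible(gm)
}

#' Write gene models as a GTF-like annotation
#'
#' Inverse of [read_annotation()]: emits one `gene` record per row with
#' 1-based closed coordinates. A nominal gene length is used for the record
#' span; the TSS end of the span is exact so the round trip preserves
#' `tss`, `strand` and `biotype`.
#'
#' @param genes Gene model data frame.
#' @param path Output path.
#' @param gene_length Nominal span of each record in bp.
#' @export
write_annotation <- function(genes, path, gene_length = 1000) {
  validate_annotation(genes)
  tss1 <- genes$tss + 1
  start1 <- ifelse(genes$strand == "+", tss1, pmax(1, tss1 - gene_length + 1))
  end1 <- ifelse(genes$strand == "+", tss1 + gene_length - 1, tss1)
  lines <- paste(genes$chrom, "chemcis", "gene",
                 format_coord(start1), format_coord(end1), ".",
                 genes$strand, ".",
                 paste0("gene_id \"", genes$gene_id,
                        "\"; gene_biotype \"", genes$biotype, "\";"),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a count matrix with condition labels
#'
#' TSV layout: first column `gene_id`, remaining column headers
#' `sample_id:condition`.
#'
#' @param path File path.
#' @return For `read_counts`: a count matrix object (see [count_matrix()]).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- colnames(df)[-1]
  parts <- strsplit(hdr, ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("count matrix header must be 'sample_id:condition', got '",
         hdr[lengths(parts) != 2][1], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- vapply(parts, `[[`, "", 1)
  count_matrix(m, condition = vapply(parts, `[[`, "", 2))
}

#' @rdname read_counts
#' @param cm Count matrix object.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[-1] <- paste0(colnames(cm$counts), ":", cm$condition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count matrix container
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param condition Character vector of condition labels, one per sample.
#' @return A list of class `count_matrix` with elements `counts` and
#'   `condition`.
#' @export
count_matrix <- function(counts, condition) {
  stopifnot(is.matrix(counts), length(condition) == ncol(counts))
  if (any(counts < 0)) stop("count matrix: negative counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix: row and column names required")
  structure(list(counts = counts,
                 condition = setNames(as.character(condition), colnames(counts))),
            class = "count_matrix")
}

#' Read a GMT-like gene-set file
#'
#' Each line: set name, description, then tab-separated gene ids.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("GMT parse error at line ", which(lengths(fields) < 3)[1],
         ": need name, description and >= 1 gene")
  setNames(lapply(fields, function(f) f[-(1:2)]),
           vapply(fields, `[[`, "", 1))
}

#' Read / write FASTA sequences
#'
#' Thin wrappers over Biostrings keeping plain named character vectors at
#' the package surface.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs Named character vector of DNA sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}
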