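## BED-family readers/writers. All coordinates are 0-based half-open on
## disk and in memory; round-trips are bit-exact for canonicalized input.

BED_COLUMNS <- list(
  `3` = c("chrom", "start", "end"),
  `4` = c("chrom", "start", "end", "name"),
  `6` = c("chrom", "start", "end", "name", "mapq", "strand"),
  `7` = c("chrom", "start", "end", "name", "mapq", "strand", "condition")
)

#' Read a BED-family file
#'
#' Accepts 3, 4, 6 or 7 tab-separated columns (the 7-column form is the
#' extended read format: chrom, start, end, name, MAPQ, strand, condition;
#' column 5 holds the MAPQ score in read files). Malformed lines — ragged
#' rows, non-numeric coordinates, `start >= end`, bad strand — are rejected
#' with the offending line number. Coordinates are 0-based half-open.
#'
#' @param path file path.
#' @param genome optional named chromosome lengths; records on unknown
#'   chromosomes or overflowing a chromosome are rejected.
#' @return data.frame with the columns above.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop(sprintf("BED parse error at line %d: ragged row (%d columns, expected %d)",
                 which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1]),
         call. = FALSE)
  nc <- as.character(nf[1])
  if (!nc %in% names(BED_COLUMNS))
    stop(sprintf("BED parse error: unsupported column count %s", nc), call. = FALSE)
  cols <- BED_COLUMNS[[nc]]
  mat <- do.call(rbind, fields)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- cols
  for (col in c("start", "end", "mapq")) {
    if (!col %in% cols) next
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("BED parse error at line %d: non-numeric %s '%s'",
                   bad[1], col, df[[col]][bad[1]]), call. = FALSE)
    df[[col]] <- v
  }
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: start must be < end and >= 0", bad[1]),
         call. = FALSE)
  if ("strand" %in% cols) {
    bad <- which(!df$strand %in% c("+", "-"))
    if (length(bad))
      stop(sprintf("BED parse error at line %d: bad strand '%s'",
                   bad[1], df$strand[bad[1]]), call. = FALSE)
  }
  if (!is.null(genome)) {
    genome <- check_genome(genome)
    bad <- which(!df$chrom %in% names(genome))
    if (length(bad))
      stop(sprintf("BED parse error at line %d: unknown chromosome '%s'",
                   bad[1], df$chrom[bad[1]]), call. = FALSE)
    bad <- which(df$end > genome[df$chrom])
    if (length(bad))
      stop(sprintf("BED parse error at line %d: record overflows chromosome",
                   bad[1]), call. = FALSE)
  }
  df
}

#' Write a BED-family file
#'
#' Writes the columns present (3, 4, 6 or 7 of the extended-BED layout) as
#' tab-separated text without header; inverse of [read_bed()].
#'
#' @param records data.frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  nc <- as.character(ncol(records))
  if (!nc %in% names(BED_COLUMNS) ||
      !identical(names(records), BED_COLUMNS[[nc]]))
    stop("records do not match a supported BED layout", call. = FALSE)
  df <- records
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV
#'
#' Expects a header row of column names and a first column of row names;
#' parsing is strict: ragged rows and non-numeric cells are errors naming
#' the offending row and column. A header-only file yields a zero-row
#' matrix.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  n_col <- length(header)
  if (length(body)) {
    nf <- lengths(body)
    bad <- which(nf != n_col)
    if (length(bad))
      stop(sprintf("matrix parse error at line %d: ragged row", bad[1] + 1L),
           call. = FALSE)
  }
  rown <- vapply(body, `[[`, character(1), 1L)
  coln <- header[-1]
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col - 1L,
                 dimnames = list(rown, coln))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    bad <- which(is.na(v) & body[[i]][-1] != "NA")
    if (length(bad))
      stop(sprintf("matrix parse error: non-numeric cell at row '%s', column '%s'",
                   rown[i], coln[bad[1]]), call. = FALSE)
    vals[i, ] <- v
  }
  vals
}

#' Write a numeric matrix as TSV
#'
#' Header row of column names, first column of row names; inverse of
#' [read_matrix()].
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param rowname_header name of the first header cell (default `"id"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, rowname_header = "id") {
  x <- as.matrix(x)
  df <- data.table::data.table(id = rownames(x) %||% as.character(seq_len(nrow(x))))
  data.table::setnames(df, "id", rowname_header)
  for (j in seq_len(ncol(x))) df[[colnames(x)[j]]] <- x[, j]
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Export a coverage track as bedGraph
#'
#' One line per run of equal-valued adjacent bins; zero-valued runs are
#' skipped.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track$bins)) {
    v <- track$bins[[chr]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- c(0, head(ends, -1))
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", chr,
                       starts[keep] * track$binsize,
                       pmin(ends[keep] * track$binsize, track$genome[[chr]]),
                       r$values[keep]), con)
  }
  invisible(path)
}
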