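## Plain-text readers/writers. All genomic text formats here are 0-based
## half-open on disk (BED/bedGraph native); GRanges in memory are 1-based.

splitLines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "track")]
}

#' Read / write BED intervals
#'
#' BED with 3 mandatory columns plus optional `name` (label) and `cellType`
#' columns (columns 4 and 5).  Malformed lines raise an error naming the
#' line number.
#'
#' @param path file path
#' @return GRanges with metadata columns `name` and `cellType` (NA when the
#'   columns are absent).
#' @export
readBed <- function(path) {
  lines <- splitLines(path)
  if (!length(lines))
    return(GRanges(name = character(0), cellType = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parseOne <- function(f, i) {
    if (length(f) < 3) stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) stop("malformed BED line ", i, ": non-numeric coordinate")
    if (s < 0 || s >= e) stop("malformed BED line ", i, ": need 0 <= start < end")
    c(f[1], s, e, if (length(f) >= 4) f[4] else NA, if (length(f) >= 5) f[5] else NA)
  }
  rec <- mapply(parseOne, fields, seq_along(fields), SIMPLIFY = FALSE)
  m <- do.call(rbind, rec)
  GRanges(m[, 1], IRanges(as.numeric(m[, 2]) + 1, as.numeric(m[, 3])),
          name = m[, 4], cellType = m[, 5])
}

#' @rdname readBed
#' @param gr GRanges (optionally with `name`/`cellType` metadata columns)
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1, scientific = FALSE, trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE))
  if (!is.null(gr$name)) {
    df$name <- gr$name
    if (!is.null(gr$cellType)) df$cellType <- gr$cellType
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write bedGraph signal
#'
#' @param path file path
#' @return GRanges with a numeric `score` column.
#' @export
readBedgraph <- function(path) {
  lines <- splitLines(path)
  if (!length(lines)) return(GRanges(score = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 4)
  if (length(bad)) stop("malformed bedGraph line ", bad[1], ": fewer than 4 fields")
  m <- do.call(rbind, fields)
  s <- suppressWarnings(as.numeric(m[, 2])); e <- suppressWarnings(as.numeric(m[, 3]))
  v <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(s) | is.na(e) | is.na(v) | s < 0 | s >= e)
  if (length(bad)) stop("malformed bedGraph line ", bad[1])
  GRanges(m[, 1], IRanges(s + 1, e), score = v)
}

#' @rdname readBedgraph
#' @param x a [SignalTrack-class] (masked bins are skipped) or a GRanges with
#'   a `score` column
#' @export
writeBedgraph <- function(x, path) {
  if (is(x, "SignalTrack")) {
    gr <- x@bins[!x@mask]
    gr$score <- x@values[!x@mask]
    x <- gr
  }
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = format(start(x) - 1, scientific = FALSE, trim = TRUE),
                   end = format(end(x), scientific = FALSE, trim = TRUE),
                   score = x$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write sparse contact triples
#'
#' Tab-delimited `bin_i bin_j count` triples storing the upper triangle once
#' (i <= j), under a header line `# resolution=<bp> chrom=<name> arm=<p|q|whole>`.
#' Symmetry is materialised on load.
#'
#' @param path file path
#' @param bins optional GRanges of the arm's bins; inferred as a uniform
#'   tiling from the header when omitted.
#' @param nBins optional number of bins (when larger than max index + 1).
#' @return [ContactMatrix-class] (raw, unmasked).
#' @export
readContacts <- function(path, bins = NULL, nBins = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("contact file must start with a '# resolution=... chrom=... arm=...' header")
  hdr <- lines[1]
  getField <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    if (!length(m)) stop("contact header missing ", key)
    sub(paste0(key, "="), "", m)
  }
  res <- as.numeric(getField("resolution"))
  chrom <- getField("chrom"); arm <- getField("arm")
  body <- lines[-1]; body <- body[nzchar(body)]
  if (length(body)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(vapply(fields, length, 0L) != 3)
    if (length(bad)) stop("malformed contact line ", bad[1] + 1L)
    m <- matrix(suppressWarnings(as.numeric(do.call(rbind, fields))), ncol = 3)
    bad <- which(!stats::complete.cases(m))
    if (length(bad)) stop("malformed contact line ", bad[1] + 1L, ": non-numeric field")
    bad <- which(m[, 3] < 0)
    if (length(bad)) stop("negative count at contact line ", bad[1] + 1L)
    bad <- which(m[, 1] > m[, 2])
    if (length(bad)) stop("contact line ", bad[1] + 1L, ": need i <= j (upper triangle)")
  } else m <- matrix(numeric(0), ncol = 3)
  n <- if (!is.null(bins)) length(bins)
       else if (!is.null(nBins)) nBins
       else if (nrow(m)) max(m[, 2]) + 1 else 0
  if (is.null(bins))
    bins <- makeBins(stats::setNames(n * res, chrom), binSize = res)
  mat <- matrix(0, n, n)
  if (nrow(m)) {
    mat[cbind(m[, 1] + 1, m[, 2] + 1)] <- m[, 3]
    mat[cbind(m[, 2] + 1, m[, 1] + 1)] <- m[, 3]
  }
  newContactMatrix(mat, bins)
}

#' @rdname readContacts
#' @param cm [ContactMatrix-class]
#' @export
writeContacts <- function(cm, path) {
  bins <- cm@bins
  chrom <- as.character(seqnames(bins)[1])
  arm <- if (!is.null(bins$arm)) bins$arm[1] else "whole"
  res <- binSize(bins)
  idx <- which(upper.tri(cm@matrix, diag = TRUE) & cm@matrix != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution=%s chrom=%s arm=%s",
                     format(res, scientific = FALSE), chrom, arm), con)
  if (nrow(idx))
    writeLines(sprintf("%d\t%d\t%s", idx[, 1] - 1L, idx[, 2] - 1L,
                       format(cm@matrix[idx], scientific = FALSE, trim = TRUE)),
               con)
  invisible(path)
}
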