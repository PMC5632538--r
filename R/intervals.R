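#' Genomic interval
#'
#' Internal coordinates are 0-based, half-open `[start, end)`; GTF I/O
#' converts at the boundary, BED I/O is native. Strand `"."` is permitted
#' for features where strand is irrelevant (e.g. a QTL window).
#'
#' @param chrom chromosome name (non-empty).
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @return A list with class `genomic_interval`.
#' @examples
#' genomic_interval("chr11", 8900000, 12200000)
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom),
            length(start) == 1L, length(end) == 1L, is.numeric(start),
            is.numeric(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop(sprintf("invalid interval %s:%s-%s (need 0 <= start < end)",
                 chrom, format(start), format(end)))
  if (!strand %in% c("+", "-", "."))
    stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%s-%s(%s)>\n", x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE), x$strand))
  invisible(x)
}

interval_width <- function(x) x$end - x$start

#' Containment / overlap of spans in an interval (vectorized)
#'
#' @param chrom,start,end vectors describing feature spans (0-based
#'   half-open).
#' @param interval a [genomic_interval()].
#' @return Logical vector.
#' @export
span_within <- function(chrom, start, end, interval) {
  chrom == interval$chrom & start >= interval$start & end <= interval$end
}

#' @rdname span_within
#' @export
span_overlaps <- function(chrom, start, end, interval) {
  chrom == interval$chrom & start < interval$end & end > interval$start
}

#' Parse a region string like "chr11:8900000-12200000"
#' @param x a single region string.
#' @return A [genomic_interval()].
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x)
  genomic_interval(m[2], as.numeric(gsub(",", "", m[3])),
                   as.numeric(gsub(",", "", m[4])))
}

#' Read / write a single-interval BED file
#'
#' BED is natively 0-based half-open; no conversion is applied. Only the
#' first interval of the file is returned by the reader.
#' @param path file path.
#' @return `read_bed_interval`: a [genomic_interval()].
#' @export
read_bed_interval <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) stop("empty BED file: ", path)
  f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(f) < 3L) stop("malformed BED line: ", lines[1])
  genomic_interval(f[1], as.numeric(f[2]), as.numeric(f[3]),
                   if (length(f) >= 6L) f[6] else ".")
}

#' @rdname read_bed_interval
#' @param interval a [genomic_interval()].
#' @param name feature name for column 4.
#' @param header optional comment lines to prepend (without trailing newline).
#' @export
write_bed_interval <- function(interval, path, name = "region", header = NULL) {
  line <- paste(interval$chrom,
                format(interval$start, scientific = FALSE, trim = TRUE),
                format(interval$end, scientific = FALSE, trim = TRUE),
                name, 0, interval$strand, sep = "\t")
  writeLines(c(header, line), path)
  invisible(path)
}
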