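#' Read transcript records from a GTF annotation
#'
#' Parses exon features, groups them by `transcript_id`, and converts GTF
#' 1-based inclusive coordinates to the internal 0-based half-open
#' convention. The assembler attributes `coverage` (numeric),
#' `samples` (comma-separated sample ids) and `biotype` are interpreted when
#' present; all other attributes are preserved verbatim in `attrs` and
#' written back by [write_gtf_transcripts()], so a read-write cycle is
#' coordinate- and attribute-exact.
#'
#' @param path GTF file path. Comment lines (`#`) are skipped.
#' @return List of [transcript_record()] objects, ordered by first
#'   appearance in the file.
#' @export
read_gtf_transcripts <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lnums <- which(keep)
  lines <- lines[keep]
  by_tx <- list()
  order_seen <- character()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                   lnums[k], length(f)))
    if (f[3] != "exon") next
    start <- suppressWarnings(as.numeric(f[4]))
    end <- suppressWarnings(as.numeric(f[5]))
    if (is.na(start) || is.na(end) || start < 1 || end < start)
      stop(sprintf("malformed GTF line %d: bad coordinates '%s'-'%s'",
                   lnums[k], f[4], f[5]))
    attrs <- parse_gtf_attributes(f[9])
    if (is.null(attrs[["transcript_id"]]))
      stop(sprintf("GTF line %d: exon without transcript_id attribute", lnums[k]))
    if (is.null(attrs[["gene_id"]]))
      stop(sprintf("GTF line %d: exon without gene_id attribute", lnums[k]))
    tid <- attrs[["transcript_id"]]
    ex <- list(chrom = f[1], source = f[2], start = start - 1, end = end,
               strand = f[7], attrs = attrs)
    if (is.null(by_tx[[tid]])) {
      by_tx[[tid]] <- list(ex)
      order_seen <- c(order_seen, tid)
    } else by_tx[[tid]] <- c(by_tx[[tid]], list(ex))
  }
  lapply(order_seen, function(tid) {
    exs <- by_tx[[tid]]
    first <- exs[[1L]]
    a <- first$attrs
    extra <- a[setdiff(names(a), c("transcript_id", "gene_id", "coverage",
                                   "samples", "biotype"))]
    extra$source <- first$source
    transcript_record(
      transcript_id = tid, gene_id = a[["gene_id"]],
      chrom = first$chrom, strand = first$strand,
      exons = data.frame(start = vapply(exs, `[[`, 0, "start"),
                         end = vapply(exs, `[[`, 0, "end")),
      coverage = if (is.null(a[["coverage"]])) NA_real_
                 else as.numeric(a[["coverage"]]),
      present_in_samples = if (is.null(a[["samples"]])) character()
                           else strsplit(a[["samples"]], ",", fixed = TRUE)[[1]],
      biotype = if (is.null(a[["biotype"]])) "novel_candidate" else a[["biotype"]],
      attrs = extra)
  })
}

parse_gtf_attributes <- function(field) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)\\s+"([^"]*)"', field)[[1]]
  if (m[1] == -1L) return(list())
  toks <- regmatches(field, gregexpr('([A-Za-z_][A-Za-z0-9_]*)\\s+"([^"]*)"',
                                     field))[[1]]
  keys <- sub('\\s+".*$', "", toks)
  vals <- sub('^[^"]*"', "", toks)
  vals <- sub('"$', "", vals)
  setNames(as.list(vals), keys)
}

#' Write transcript records as GTF exon lines
#'
#' Inverse of [read_gtf_transcripts()]: internal 0-based half-open exon
#' coordinates become 1-based inclusive, and interpreted plus pass-through
#' attributes are emitted on every exon line.
#'
#' @param records list of [transcript_record()] objects.
#' @param path output path.
#' @param header optional character vector of `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_gtf_transcripts <- function(records, path, header = NULL) {
  out <- lapply(records, function(r) {
    a <- c(list(transcript_id = r$transcript_id, gene_id = r$gene_id),
           if (!is.na(r$coverage)) list(coverage = format(r$coverage, trim = TRUE)),
           if (length(r$present_in_samples))
             list(samples = paste(r$present_in_samples, collapse = ",")),
           list(biotype = r$biotype),
           r$attrs[setdiff(names(r$attrs), "source")])
    attr_str <- paste0(names(a), ' "', unlist(a), '";', collapse = " ")
    src <- if (!is.null(r$attrs$source)) r$attrs$source else "cernet"
    paste(r$interval$chrom, src, "exon",
          format(r$exons$start + 1, scientific = FALSE, trim = TRUE),
          format(r$exons$end, scientific = FALSE, trim = TRUE),
          ".", r$interval$strand, ".", attr_str, sep = "\t")
  })
  writeLines(c(header, unlist(out)), path)
  invisible(path)
}
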