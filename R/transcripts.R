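#' Assembled transcript record
#'
#' The unit the candidate-lncRNA filter cascade judges: a multi-exon feature
#' with assembler-reported mean coverage, the set of samples it was
#' assembled in, and a biotype.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param exons data.frame with numeric columns `start`, `end` (0-based
#'   half-open); must be non-empty, sorted by start, non-overlapping.
#' @param coverage assembler mean read depth (dimensionless, `>= 0`).
#' @param present_in_samples character vector of sample ids the transcript
#'   was assembled in.
#' @param biotype one of `known_mRNA`, `known_lncRNA`, `known_other`,
#'   `novel_candidate`.
#' @param attrs pass-through list of extra annotation attributes (e.g. GTF
#'   attributes not interpreted by the package, or the `known_overlap` flag).
#' @return A list with class `transcript_record`.
#' @export
transcript_record <- function(transcript_id, gene_id, chrom, strand, exons,
                              coverage = NA_real_,
                              present_in_samples = character(),
                              biotype = "novel_candidate", attrs = list()) {
  stopifnot(is.character(transcript_id), nzchar(transcript_id),
            is.character(gene_id), nzchar(gene_id),
            is.data.frame(exons), nrow(exons) >= 1L,
            all(c("start", "end") %in% names(exons)))
  if (!biotype %in% c("known_mRNA", "known_lncRNA", "known_other",
                      "novel_candidate"))
    stop("unknown biotype: ", biotype)
  exons <- data.frame(start = as.numeric(exons$start),
                      end = as.numeric(exons$end))
  if (is.unsorted(exons$start, strictly = FALSE))
    exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end <= exons$start))
    stop(transcript_id, ": exon with non-positive width")
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop(transcript_id, ": overlapping exons")
  rownames(exons) <- NULL
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    interval = genomic_interval(chrom, min(exons$start), max(exons$end),
                                strand),
    exons = exons, coverage = as.numeric(coverage),
    present_in_samples = unique(as.character(present_in_samples)),
    biotype = biotype, attrs = attrs), class = "transcript_record")
}

#' Spliced length of a transcript (sum of exon widths)
#' @param record a [transcript_record()].
#' @return Integer-valued numeric, `> 0`.
#' @export
transcript_length <- function(record) {
  stopifnot(inherits(record, "transcript_record"))
  sum(record$exons$end - record$exons$start)
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%d-%d(%s) %d exon(s), %d bp, %s>\n",
              x$transcript_id, x$gene_id, x$interval$chrom,
              x$interval$start, x$interval$end, x$interval$strand,
              nrow(x$exons), transcript_length(x), x$biotype))
  invisible(x)
}

#' Flat table view of a transcript list
#' @param records list of [transcript_record()] objects.
#' @return data.frame with one row per transcript (id, gene, span, exon
#'   count, spliced length, coverage, sample count, biotype).
#' @export
transcripts_table <- function(records) {
  stopifnot(is.list(records))
  if (!length(records))
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), n_exons = integer(),
                      length = numeric(), coverage = numeric(),
                      n_samples = integer(), biotype = character()))
  do.call(rbind, lapply(records, function(r) data.frame(
    transcript_id = r$transcript_id, gene_id = r$gene_id,
    chrom = r$interval$chrom, start = r$interval$start, end = r$interval$end,
    strand = r$interval$strand, n_exons = nrow(r$exons),
    length = transcript_length(r), coverage = r$coverage,
    n_samples = length(r$present_in_samples), biotype = r$biotype,
    stringsAsFactors = FALSE)))
}

#' Flag novel candidates whose span overlaps a known non-lncRNA transcript
#'
#' Same-chromosome, same-strand span overlap with any `known_mRNA` or
#' `known_other` record sets `attrs$known_overlap = TRUE` on the candidate;
#' the filter cascade then rejects it under the `known_overlap` criterion.
#'
#' @param records list of [transcript_record()] objects (mixed biotypes).
#' @return The list with candidate records flagged.
#' @export
flag_known_overlap <- function(records) {
  tab <- transcripts_table(records)
  known <- tab[tab$biotype %in% c("known_mRNA", "known_other"), , drop = FALSE]
  for (i in seq_along(records)) {
    if (records[[i]]$biotype != "novel_candidate") next
    r <- tab[i, ]
    hit <- any(known$chrom == r$chrom &
                 (known$strand == r$strand | known$strand == "." |
                    r$strand == ".") &
                 known$start < r$end & known$end > r$start)
    records[[i]]$attrs$known_overlap <- hit
  }
  records
}
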