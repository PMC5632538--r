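#' Assign biotypes from a known-feature map
#'
#' Transcripts whose id appears in `known_ids` adopt the mapped biotype
#' (`known_mRNA`, `known_lncRNA`, `known_other`); all remaining records
#' become `novel_candidate` and are the input of the filter cascade.
#'
#' @param records list of [transcript_record()] objects.
#' @param known_ids named character vector, transcript id -> known biotype.
#' @return The record list with biotypes set.
#' @export
classify_transcripts <- function(records, known_ids = character()) {
  if (length(known_ids)) {
    bad <- setdiff(unique(known_ids), c("known_mRNA", "known_lncRNA",
                                        "known_other"))
    if (length(bad)) stop("invalid known biotype(s): ",
                          paste(bad, collapse = ", "))
  }
  lapply(records, function(r) {
    r$biotype <- if (r$transcript_id %in% names(known_ids))
      unname(known_ids[[r$transcript_id]]) else "novel_candidate"
    r
  })
}

#' Coding-potential heuristic
#'
#' Stand-in for SVM/HMM coding-potential tools: the longest open reading
#' frame (ATG to the first in-frame stop, stop included) is searched in the
#' three forward frames of the spliced transcript; only forward frames are
#' scanned because assembled transcripts are strand-resolved. The score is
#' the longest-ORF length divided by the transcript length; the call is
#' `coding` iff the longest ORF is at least `orf_min_nt` (300 nt) or the
#' score is at least `orf_min_frac` (0.5). ORFs without an in-frame stop are
#' not counted. Sequences shorter than 3 nt are `noncoding` with score 0.
#'
#' @param seq a single DNA sequence string.
#' @param cfg a [ce_config()].
#' @return List with `score` (numeric) and `call` (`"coding"`/`"noncoding"`).
#' @export
coding_potential_score <- function(seq, cfg = ce_config()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) return(list(score = 0, call = "noncoding"))
  longest <- longest_orf_nt(seq)
  score <- longest / n
  call <- if (longest >= cfg$orf_min_nt || score >= cfg$orf_min_frac)
    "coding" else "noncoding"
  list(score = score, call = call)
}

longest_orf_nt <- function(seq) {
  n <- nchar(seq)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(1L + frame, n - 2L, by = 3L)
    if (!length(starts)) next
    codons <- substring(seq, starts, starts + 2L)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (!length(atg) || !length(stp)) next
    # first stop at or after each ATG; ORF spans ATG..stop inclusive
    idx <- findInterval(atg - 1L, stp) + 1L
    ok <- idx <= length(stp)
    if (!any(ok)) next
    len <- (stp[idx[ok]] - atg[ok] + 1L) * 3L
    best <- max(best, len)
  }
  best
}

filter_criteria <- c("length", "exon_count", "coverage", "recurrence",
                     "known_overlap", "coding_potential")

#' Candidate lncRNA filter cascade
#'
#' Judges `novel_candidate` records only. A record survives iff spliced
#' length >= `min_length` AND exon count >= `min_exons` AND assembler
#' coverage >= `min_coverage` AND assembled in >= `min_samples` samples AND
#' it does not overlap a known non-lncRNA transcript AND the
#' coding-potential heuristic calls it noncoding. Every criterion is
#' evaluated for every record, so a failing report lists all violated
#' criteria (in the fixed order length, exon_count, coverage, recurrence,
#' known_overlap, coding_potential) and the outcome is independent of
#' evaluation order.
#'
#' @param records list of [transcript_record()] objects; run
#'   [flag_known_overlap()] first if overlap flags are not already set.
#' @param cfg a [ce_config()].
#' @param seqs named character vector of spliced DNA sequences (for the
#'   coding-potential criterion).
#' @param coding_calls optional named character vector transcript id ->
#'   `"coding"`/`"noncoding"`, overriding the built-in heuristic (e.g. an
#'   external coding-potential tool's calls).
#' @return List with `survivors` (record list, biotypes unchanged) and
#'   `report` (data.frame: transcript_id, passed, failed_criteria as a
#'   comma-joined string, empty when passed).
#' @export
filter_candidates <- function(records, cfg = ce_config(), seqs = NULL,
                              coding_calls = NULL) {
  judged <- Filter(function(r) r$biotype == "novel_candidate", records)
  rows <- lapply(judged, function(r) {
    failed <- character()
    if (transcript_length(r) < cfg$min_length) failed <- c(failed, "length")
    if (nrow(r$exons) < cfg$min_exons) failed <- c(failed, "exon_count")
    if (is.na(r$coverage) || r$coverage < cfg$min_coverage)
      failed <- c(failed, "coverage")
    if (length(r$present_in_samples) < cfg$min_samples)
      failed <- c(failed, "recurrence")
    if (isTRUE(r$attrs$known_overlap)) failed <- c(failed, "known_overlap")
    call <- if (!is.null(coding_calls) &&
                r$transcript_id %in% names(coding_calls)) {
      unname(coding_calls[[r$transcript_id]])
    } else if (!is.null(seqs) && r$transcript_id %in% names(seqs)) {
      coding_potential_score(seqs[[r$transcript_id]], cfg)$call
    } else {
      warning("no sequence or coding call for ", r$transcript_id,
              "; coding-potential criterion skipped")
      "noncoding"
    }
    if (call == "coding") failed <- c(failed, "coding_potential")
    failed <- intersect(filter_criteria, failed)  # canonical order
    data.frame(transcript_id = r$transcript_id,
               passed = !length(failed),
               failed_criteria = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), passed = logical(),
               failed_criteria = character())
  keep <- report$transcript_id[report$passed]
  list(survivors = Filter(function(r) r$transcript_id %in% keep, judged),
       report = report)
}
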