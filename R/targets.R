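#' Pearson product-moment correlation with an undefined-variance marker
#'
#' Returns `NA` (the "undefined" marker, excluded downstream) when either
#' vector has zero variance; errors on length mismatch or fewer than three
#' observations.
#'
#' @param x,y numeric vectors of equal length `>= 3`, finite values.
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  unname(cor(x, y))
}

# all-pairs correlation matrix rows(a) x rows(b); zero-variance rows -> NA
cor_rows <- function(a, b) {
  va <- apply(a, 1L, sd); vb <- apply(b, 1L, sd)
  r <- suppressWarnings(cor(t(a), t(b)))
  r[va == 0, ] <- NA_real_
  r[, vb == 0] <- NA_real_
  r
}

#' Correlation-based trans-target inference for lncRNAs
#'
#' All lncRNA x mRNA pairs whose Pearson correlation across the shared
#' samples satisfies `r >= r_trans` or `r <= -r_trans` (default 0.95).
#' Zero-variance features are skipped; their count is attached as attribute
#' `n_skipped` and reported via a message.
#'
#' @param lnc_em,mrna_em [expression_matrix()] objects sharing >= 3 samples
#'   (typically log-transformed expression).
#' @param cfg a [ce_config()].
#' @return data.frame of edges: a_id (lncRNA), b_id (mRNA), r, n,
#'   edge_class = `lnc_trans`; attribute `n_skipped`.
#' @export
trans_targets <- function(lnc_em, mrna_em, cfg = ce_config()) {
  stopifnot(inherits(lnc_em, "expr_matrix"), inherits(mrna_em, "expr_matrix"))
  shared <- intersect(colnames(lnc_em$values), colnames(mrna_em$values))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  a <- lnc_em$values[, shared, drop = FALSE]
  b <- mrna_em$values[, shared, drop = FALSE]
  r <- cor_rows(a, b)
  n_skipped <- sum(apply(a, 1L, sd) == 0) + sum(apply(b, 1L, sd) == 0)
  if (n_skipped > 0)
    message(n_skipped, " zero-variance feature(s) skipped in trans_targets")
  hit <- which(!is.na(r) & abs(r) >= cfg$r_trans, arr.ind = TRUE)
  edges <- data.frame(
    a_id = rownames(a)[hit[, 1L]], b_id = rownames(b)[hit[, 2L]],
    r = r[hit], n = length(shared), edge_class = "lnc_trans",
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$a_id, edges$b_id), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_skipped") <- n_skipped
  edges
}

#' Scan region for a gene: annotated 3' UTR or downstream fallback
#'
#' Returns the annotated 3' UTR sequence when one exists; otherwise the
#' `utr_fallback_len` (1,000 bp) genomic window downstream of the stop codon
#' in transcription direction, reverse-complemented for minus-strand genes
#' and truncated at the chromosome end with a warning. Genes with neither a
#' UTR nor a stop-codon coordinate are skipped with a warning.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`, and
#'   `stop_pos` (0-based coordinate just past the stop codon on `+`;
#'   the stop codon's start coordinate on `-`; `NA` when unknown).
#' @param utr_seqs named character vector of annotated 3' UTR sequences
#'   (DNA, keyed by gene id).
#' @param genome named character vector of chromosome sequences (DNA).
#' @param cfg a [ce_config()].
#' @return Named character vector of scan-region sequences, one per
#'   resolvable gene.
#' @export
extract_scan_region <- function(genes, utr_seqs = character(),
                                genome = character(), cfg = ce_config()) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "stop_pos") %in% names(genes)))
  out <- character()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    if (g$gene_id %in% names(utr_seqs)) {
      out[[g$gene_id]] <- toupper(utr_seqs[[g$gene_id]])
      next
    }
    if (is.na(g$stop_pos) || !g$chrom %in% names(genome)) {
      warning("gene ", g$gene_id, " has neither a 3' UTR nor a usable ",
              "stop-codon coordinate; skipped")
      next
    }
    chrom_seq <- genome[[g$chrom]]
    clen <- nchar(chrom_seq)
    if (g$strand == "-") {
      lo <- max(0, g$stop_pos - cfg$utr_fallback_len)
      hi <- g$stop_pos
      if (g$stop_pos - cfg$utr_fallback_len < 0)
        warning("gene ", g$gene_id, ": fallback window truncated at ",
                "chromosome start")
      if (hi <= lo) next
      out[[g$gene_id]] <- reverse_complement(substr(chrom_seq, lo + 1, hi))
    } else {
      lo <- g$stop_pos
      hi <- min(clen, g$stop_pos + cfg$utr_fallback_len)
      if (hi < g$stop_pos + cfg$utr_fallback_len)
        warning("gene ", g$gene_id, ": fallback window truncated at ",
                "chromosome end")
      if (hi <= lo) next
      out[[g$gene_id]] <- substr(chrom_seq, lo + 1, hi)
    }
  }
  out
}

#' Seed-weighted miRNA binding-site scan
#'
#' Local alignment of the reversed miRNA against the scan region with
#' scores match +5, G:U wobble +2, mismatch -3, gap open -8, gap extend -2;
#' columns consuming miRNA positions 2-8 from the 5' end (the seed) are
#' weighted x2. Candidate duplex energy comes from a simplified
#' nearest-neighbor stack table (GC/GC stack -3.3, AU/AU -1.1, mixed -2.1,
#' any wobble-containing stack -1.0 kcal/mol). Non-overlapping sites are
#' extracted greedily by descending score and retained iff
#' `align_score > site_score_min` AND `energy < site_energy_max`.
#'
#' @param mirna single miRNA sequence (RNA or DNA letters; T is read as U),
#'   length within `[mirna_len_min, mirna_len_max]` (default 18-26 nt).
#' @param region single DNA scan-region sequence.
#' @param cfg a [ce_config()].
#' @param mirna_id,target_id identifiers copied into the result.
#' @return data.frame of retained sites: mirna_id, target_id, target_start
#'   (0-based), target_end, align_score, energy, alignment strings; ordered
#'   by target_start.
#' @export
scan_mirna_sites <- function(mirna, region, cfg = ce_config(),
                             mirna_id = "mirna", target_id = "target") {
  stopifnot(is.character(mirna), length(mirna) == 1L,
            is.character(region), length(region) == 1L)
  mirna <- dna_to_rna(toupper(mirna))
  region <- toupper(region)
  if (nchar(mirna) < cfg$mirna_len_min || nchar(mirna) > cfg$mirna_len_max)
    stop(sprintf("miRNA length %d outside [%d, %d]", nchar(mirna),
                 cfg$mirna_len_min, cfg$mirna_len_max))
  validate_sequences(c(m = mirna), "RNA")
  validate_sequences(c(r = region), "DNA")
  cand <- .scan_sites_cpp(region, mirna, score_min = cfg$site_score_min)
  keep <- cand[cand$align_score > cfg$site_score_min &
                 cand$energy < cfg$site_energy_max, , drop = FALSE]
  keep <- keep[order(keep$target_start), , drop = FALSE]
  rownames(keep) <- NULL
  cbind(data.frame(mirna_id = rep(mirna_id, nrow(keep)),
                   target_id = rep(target_id, nrow(keep)),
                   stringsAsFactors = FALSE), keep)
}

#' Scan many miRNA / region pairs
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param regions named character vector of DNA scan regions.
#' @param cfg a [ce_config()].
#' @param pairs optional data.frame (`mirna_id`, `target_id`) restricting
#'   the scan; by default every miRNA is scanned against every region.
#' @return Row-bound [scan_mirna_sites()] results over all pairs.
#' @export
scan_all_sites <- function(mirnas, regions, cfg = ce_config(), pairs = NULL) {
  if (is.null(pairs))
    pairs <- expand.grid(mirna_id = names(mirnas), target_id = names(regions),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # validate once, then drive the C++ kernel directly: the all-pairs scan is
  # dominated by pairs with no retained site, which must cost ~nothing in R
  mirnas <- setNames(dna_to_rna(toupper(mirnas)), names(mirnas))
  regions <- setNames(toupper(regions), names(regions))
  validate_sequences(mirnas, "RNA")
  validate_sequences(regions, "DNA")
  bad <- nchar(mirnas) < cfg$mirna_len_min | nchar(mirnas) > cfg$mirna_len_max
  if (any(bad))
    stop("miRNA length outside bounds: ",
         paste(head(names(mirnas)[bad], 3), collapse = ", "))
  out <- vector("list", nrow(pairs))
  n_out <- 0L
  for (k in seq_len(nrow(pairs))) {
    cand <- .scan_sites_cpp(regions[[pairs$target_id[k]]],
                            mirnas[[pairs$mirna_id[k]]],
                            score_min = cfg$site_score_min)
    if (!nrow(cand)) next
    keep <- cand[cand$align_score > cfg$site_score_min &
                   cand$energy < cfg$site_energy_max, , drop = FALSE]
    if (!nrow(keep)) next
    n_out <- n_out + 1L
    out[[n_out]] <- cbind(data.frame(mirna_id = pairs$mirna_id[k],
                                     target_id = pairs$target_id[k],
                                     stringsAsFactors = FALSE),
                          keep[order(keep$target_start), , drop = FALSE])
  }
  res <- if (n_out) do.call(rbind, out[seq_len(n_out)]) else NULL
  if (is.null(res) || !nrow(res))
    return(data.frame(mirna_id = character(), target_id = character(),
                      target_start = integer(), target_end = integer(),
                      align_score = numeric(), energy = numeric(),
                      align_mirna = character(), align_pairs = character(),
                      align_region = character(), stringsAsFactors = FALSE))
  res <- res[order(res$mirna_id, res$target_id, res$target_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
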