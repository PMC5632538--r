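#' Parameters of the synthetic study generator
#'
#' Defaults emulate the design the pipeline targets: 12 ovary samples in
#' four oviposition groups (V/Q/C/R, three queens each), negative-binomial
#' counts with log-normal baselines, 10% planted differential expression
#' per contrast along the V->Q->C->R chain, 50 planted ceRNA triads whose
#' group-level expression coupling induces strong (|r| ~ 0.8-0.95)
#' correlations, miRNA binding sites spliced into 3' UTR and lncRNA
#' sequences, and 5% of features placed fully inside the chr11 ovary-size
#' QTL window.
#'
#' @param ... name = value overrides of the defaults listed below.
#' @return A named list with class `sim_params`.
#' @details
#' Noteworthy defaults and the reasoning behind them:
#' \itemize{
#'   \item `dispersion = 0.05`, `baseline_meanlog = 5`,
#'     `baseline_sdlog = 1.5`: moderately overdispersed bulk RNA-seq with
#'     median baseline counts near 150.
#'   \item `coupling_strength = 0.9`: the fraction of a coupled feature's
#'     group-mean variance driven by its triad partner; implemented so the
#'     group-level correlation between partners is exactly
#'     `sqrt(0.9) ~ 0.95` before counting noise.
#'   \item `triad_amplitude = 2` (log2): standard deviation of the
#'     four-group modulation of triad members; large enough that
#'     between-group variation dominates NB noise, which is what an
#'     |r| >= 0.8 screen on 12 samples can actually detect.
#'   \item `mirna_len_range = c(20, 24)`, but triad (site-carrying) miRNAs
#'     are drawn from 22-24 nt: a full reverse-complement site of an L-nt
#'     miRNA scores 5L + 35 under the seed-doubled scheme, so only
#'     L >= 22 clears the score > 140 retention cutoff.
#' }
#' @export
sim_params <- function(...) {
  p <- list(
    n_mrna = 3000L, n_lncrna = 400L, n_mirna = 100L,
    n_chroms = 16L, chrom_length = 15e6,
    groups = c("V", "Q", "C", "R"), n_reps = 3L,
    baseline_meanlog = 5, baseline_sdlog = 1.5,
    dispersion = 0.05, libsize_sdlog = 0.2,
    de_fraction = 0.10, lfc_range = c(1, 3),
    n_triads = 50L, coupling_strength = 0.9, triad_amplitude = 2,
    sites_per_target = c(1L, 3L),
    utr_len_range = c(200L, 2000L), mirna_len_range = c(20L, 24L),
    mrna_len_range = c(500L, 3000L),
    qtl_fraction = 0.05, seed = 1L)
  override <- list(...)
  if (length(override)) {
    unknown <- setdiff(names(override), names(p))
    if (length(unknown))
      stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
    p[names(override)] <- override
  }
  stopifnot(p$n_mrna >= 0, p$n_lncrna >= 0, p$n_mirna >= 0, p$n_reps >= 2,
            p$de_fraction >= 0, p$de_fraction <= 1,
            p$qtl_fraction >= 0, p$qtl_fraction <= 1,
            p$coupling_strength >= 0, p$coupling_strength <= 1,
            p$dispersion >= 0, length(p$groups) >= 2)
  p$seed <- as.integer(p$seed)
  structure(p, class = "sim_params")
}

# sample uniformly from an integer range; safe when lo == hi (avoids the
# base-R sample(x, 1) scalar pitfall)
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# uniform random sequences as a character vector
random_seqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste(sample(alphabet, len[min(i, length(len))]
                 , replace = TRUE), collapse = ""), character(1))
}

# remove every ATG so the coding-potential heuristic scores 0
scrub_orfs <- function(seq) {
  while (grepl("ATG", seq, fixed = TRUE))
    seq <- sub("ATG", "ACG", seq, fixed = TRUE)
  seq
}

# random exon structure summing to spliced_len, placed so the span fits
place_transcript <- function(chrom, chrom_len, spliced_len, n_exons,
                             window = NULL) {
  w <- rep(spliced_len %/% n_exons, n_exons)
  w[n_exons] <- w[n_exons] + spliced_len %% n_exons
  introns <- if (n_exons > 1) sample(100:5000, n_exons - 1, replace = TRUE)
             else integer()
  span <- spliced_len + sum(introns)
  lo_max <- if (is.null(window)) chrom_len - span else window[2] - span
  lo_min <- if (is.null(window)) 0 else window[1]
  if (lo_max <= lo_min)
    stop("chromosome (or window) too short for a ", span, " bp span")
  start <- floor(runif(1, lo_min, lo_max))
  starts <- start + cumsum(c(0, head(w, -1) + introns))
  data.frame(start = starts, end = starts + w)
}

#' Simulate the genome annotation and QTL interval
#'
#' Features are placed uniformly on `n_chroms` chromosomes except a
#' `qtl_fraction` of the mRNAs and lncRNAs, which are placed fully inside
#' the chr11 QTL window (accidental full containment of non-designated
#' features is re-drawn away, so the planted membership IS the contained
#' set). The annotation also carries seven `novel_candidate` records for
#' the filter cascade: one violator per criterion plus one fully compliant
#' record.
#'
#' Uses the current RNG state; seed via `set.seed()` or run inside
#' [simulate_study()].
#'
#' @param params a [sim_params()].
#' @param cfg a [ce_config()] (QTL window coordinates).
#' @return List: `records` (transcript records), `features` (flat
#'   data.frame with feature_id, class, chrom, start, end, strand, length),
#'   `qtl` (the interval), `qtl_members` (planted contained feature ids).
#' @export
simulate_annotation <- function(params = sim_params(), cfg = ce_config()) {
  qtl <- config_qtl_interval(cfg)
  chroms <- paste0("chr", seq_len(params$n_chroms))
  clen <- setNames(rep_len(params$chrom_length, params$n_chroms), chroms)
  if (!qtl$chrom %in% chroms)
    stop("QTL chromosome ", qtl$chrom, " not among the simulated chromosomes")
  if (clen[[qtl$chrom]] < qtl$end)
    stop("chromosome ", qtl$chrom, " (", clen[[qtl$chrom]],
         " bp) too short for the QTL window")
  ids <- c(sprintf("mrna_%04d", seq_len(params$n_mrna)),
           sprintf("lnc_%04d", seq_len(params$n_lncrna)),
           sprintf("mir_%03d", seq_len(params$n_mirna)))
  class <- rep(c("mRNA", "lncRNA", "miRNA"),
               c(params$n_mrna, params$n_lncrna, params$n_mirna))
  placeable <- which(class != "miRNA")
  n_qtl <- floor(params$qtl_fraction * length(placeable))
  qtl_ids <- if (n_qtl > 0) ids[sample(placeable, n_qtl)] else character()
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cls <- class[i]
    spliced <- switch(cls,
      mRNA = sample_range(params$mrna_len_range[1], params$mrna_len_range[2]),
      lncRNA = sample_range(params$utr_len_range[1], params$utr_len_range[2]),
      miRNA = sample_range(params$mirna_len_range[1], params$mirna_len_range[2]))
    n_ex <- switch(cls, mRNA = sample_range(2L, 8L), lncRNA = sample_range(2L, 4L),
                   miRNA = 1L)
    in_qtl <- ids[i] %in% qtl_ids
    chrom <- if (in_qtl) qtl$chrom else sample(chroms, 1)
    repeat {
      exons <- place_transcript(chrom, clen[[chrom]], spliced, n_ex,
                                window = if (in_qtl) c(qtl$start, qtl$end))
      inside <- chrom == qtl$chrom && min(exons$start) >= qtl$start &&
        max(exons$end) <= qtl$end
      if (in_qtl == inside) break
    }
    records[[i]] <- transcript_record(
      ids[i], paste0(ids[i], "_g"), chrom, sample(c("+", "-"), 1), exons,
      coverage = round(runif(1, 5, 80), 1),
      present_in_samples = paste0("s", 1:(length(params$groups) * params$n_reps)),
      biotype = switch(cls, mRNA = "known_mRNA", lncRNA = "known_lncRNA",
                       miRNA = "known_other"))
  }
  records <- c(records,
               novel_candidate_records(params, chroms, clen, records, qtl))
  features <- transcripts_table(records)
  features <- data.frame(feature_id = features$transcript_id,
                         class = c(class, rep("novel_candidate",
                                              length(records) - length(ids))),
                         chrom = features$chrom, start = features$start,
                         end = features$end, strand = features$strand,
                         length = features$length,
                         stringsAsFactors = FALSE)
  # membership truth is the realized containment over every simulated span
  # (identical to the designated set except in degenerate designs)
  list(records = records, features = features, qtl = qtl,
       qtl_members = sort(features$feature_id[
         span_within(features$chrom, features$start, features$end, qtl)]))
}

# seven filter-cascade fixtures: one violator per criterion + one compliant
novel_candidate_records <- function(params, chroms, clen, known_records,
                                    qtl) {
  all_samples <- paste0("s", 1:(length(params$groups) * params$n_reps))
  ktab <- transcripts_table(known_records)
  clear_of_known <- function(chrom, start, end) {
    !any(ktab$chrom == chrom & ktab$start < end & ktab$end > start) &&
      !span_within(chrom, start, end, qtl)
  }
  # placed away from every known transcript span so no record trips the
  # known_overlap criterion by accident
  mk <- function(id, spliced, n_ex, coverage, samples) {
    repeat {
      chrom <- sample(chroms, 1)
      exons <- place_transcript(chrom, clen[[chrom]], spliced, n_ex)
      if (clear_of_known(chrom, min(exons$start), max(exons$end)))
        return(transcript_record(id, paste0(id, "_g"), chrom, "+", exons,
                                 coverage = coverage,
                                 present_in_samples = samples,
                                 biotype = "novel_candidate"))
    }
  }
  # the known_overlap violator sits on top of a known mRNA outside the QTL
  # window (so planted QTL membership stays exactly the designated set)
  host_ok <- vapply(known_records, function(r)
    r$biotype == "known_mRNA" &&
      !span_within(r$interval$chrom, r$interval$start,
                   r$interval$end + 800, qtl), logical(1))
  if (!any(host_ok))  # degenerate designs (e.g. qtl_fraction = 1)
    host_ok <- vapply(known_records, function(r) r$biotype == "known_mRNA",
                      logical(1))
  if (!any(host_ok)) stop("no known mRNA available to host the overlap decoy")
  host <- known_records[[which(host_ok)[1]]]
  e1_start <- host$exons$start[1]
  ov <- transcript_record(
    "novel_fail_overlap", "novel_fail_overlap_g", host$interval$chrom,
    host$interval$strand,
    data.frame(start = c(e1_start, e1_start + 500),
               end = c(e1_start + 300, e1_start + 800)),
    coverage = 10, present_in_samples = all_samples,
    biotype = "novel_candidate")
  list(mk("novel_fail_length", 150L, 2L, 10, all_samples),
       mk("novel_fail_exon", 500L, 1L, 10, all_samples),
       mk("novel_fail_coverage", 500L, 2L, 1, all_samples),
       mk("novel_fail_recurrence", 500L, 2L, 10, all_samples[1]),
       ov,
       mk("novel_fail_coding", 600L, 2L, 10, all_samples),
       mk("novel_ok", 500L, 2L, 10, all_samples))
}

#' Plant full-complement miRNA binding sites into target sequences
#'
#' For each designated (miRNA, target) pair, 1-3 copies of the reverse
#' complement of the full miRNA (DNA alphabet) overwrite the target
#' sequence at recorded non-overlapping positions, guaranteeing a
#' maximal-score site. Designated miRNAs must be at least 22 nt (shorter
#' full-complement sites cannot clear the score > 140 cutoff; see
#' [sim_params()]).
#'
#' Uses the current RNG state.
#'
#' @param params a [sim_params()] (`sites_per_target` range).
#' @param mirnas named character vector of miRNA sequences (RNA).
#' @param targets named character vector of target sequences (DNA): 3' UTRs
#'   and/or lncRNA transcripts.
#' @param pairs data.frame with columns `mirna_id`, `target_id`.
#' @return List: `targets` (modified sequences), `sites` (data.frame
#'   mirna_id, target_id, position 0-based).
#' @export
plant_sites <- function(params, mirnas, targets, pairs) {
  sites <- data.frame(mirna_id = character(), target_id = character(),
                      position = integer(), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(list(targets = targets, sites = sites))
  for (k in seq_len(nrow(pairs))) {
    mir <- pairs$mirna_id[k]; tgt <- pairs$target_id[k]
    if (!mir %in% names(mirnas)) stop("unknown miRNA id: ", mir)
    if (!tgt %in% names(targets)) stop("unknown target id: ", tgt)
    site_seq <- reverse_complement(mirnas[[mir]])
    slen <- nchar(site_seq)
    if (slen < 22L)
      stop("designated miRNA ", mir, " is ", slen,
           " nt; full-complement sites below 22 nt cannot pass score > 140")
    n_copies <- sample_range(params$sites_per_target[1],
                             params$sites_per_target[2])
    tlen <- nchar(targets[[tgt]])
    if (tlen < n_copies * slen)
      stop("target ", tgt, " (", tlen, " nt) too short to host ",
           n_copies, " site(s) of ", slen, " nt")
    taken <- integer()
    placed <- 0L
    tries <- 0L
    while (placed < n_copies) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("target ", tgt, " too crowded to host ", n_copies, " site(s)")
      pos <- sample.int(tlen - slen + 1L, 1) - 1L  # 0-based
      if (any(abs(taken - pos) < slen)) next
      substr(targets[[tgt]], pos + 1L, pos + slen) <- site_seq
      taken <- c(taken, pos)
      placed <- placed + 1L
      sites <- rbind(sites, data.frame(mirna_id = mir, target_id = tgt,
                                       position = pos,
                                       stringsAsFactors = FALSE))
    }
  }
  list(targets = targets, sites = sites)
}

# centered unit 4-vector orthogonal to each column of `against`
unit_orth <- function(n, against = NULL) {
  repeat {
    e <- rnorm(n)
    e <- e - mean(e)
    if (!is.null(against))
      for (j in seq_len(ncol(against)))
        e <- e - sum(e * against[, j]) * against[, j]
    nrm <- sqrt(sum(e^2))
    if (nrm > 1e-8) return(e / nrm)
  }
}

#' Simulate NB counts for the full study design
#'
#' Count `X_gs ~ NB(mean = s_s * mu_g(group), dispersion phi)` with
#' log-normal library factors `s_s`. DE features shift group means by
#' `2^lfc` along the contrast chain V->Q->C->R (a shift planted for a
#' contrast persists through the later groups unless overwritten by a later
#' planted shift). Triad coupling acts on log2 group means: the miRNA
#' carries a latent centered four-group profile; in a \emph{target} triad
#' the mRNA and the lncRNA move opposite to the miRNA; in a \emph{decoy}
#' triad they move with it (the expression-level signature of effective
#' sponging). `coupling_strength` is the fraction of the driven feature's
#' group-mean variance explained by its driver, so partner group profiles
#' correlate at exactly `±sqrt(coupling_strength)`.
#'
#' Uses the current RNG state.
#'
#' @param params a [sim_params()].
#' @param feature_ids character vector of all features.
#' @param feature_class named class vector (`mRNA`/`lncRNA`/`miRNA`/
#'   `novel_candidate`).
#' @param triads data.frame (lnc_id, mirna_id, mrna_id, role) or NULL.
#' @return List: `counts` (an [expression_matrix()]), `de_sets` (list
#'   contrast -> class -> data.frame(feature_id, sign, lfc)),
#'   `offsets` (log2 group-mean offset matrix, features x groups),
#'   `mu` (true group means), `lib_factors`.
#' @export
simulate_counts <- function(params, feature_ids, feature_class,
                            triads = NULL) {
  groups <- params$groups
  nG <- length(groups)
  nf <- length(feature_ids)
  base <- stats::rlnorm(nf, params$baseline_meanlog, params$baseline_sdlog)
  names(base) <- feature_ids
  offsets <- matrix(0, nf, nG, dimnames = list(feature_ids, groups))

  triad_ids <- if (!is.null(triads))
    unique(c(triads$lnc_id, triads$mirna_id, triads$mrna_id)) else character()

  # planted DE along the chain of adjacent-group contrasts
  de_sets <- list()
  classes <- c("mRNA", "lncRNA", "miRNA")
  for (ci in seq_len(nG - 1L)) {
    ref <- groups[ci]; trt <- groups[ci + 1L]
    cname <- paste0(trt, "_", ref)
    per_class <- list()
    for (cls in classes) {
      pool <- feature_ids[feature_class[feature_ids] == cls &
                            !feature_ids %in% triad_ids]
      n_de <- floor(params$de_fraction * length(pool))
      if (n_de == 0) {
        per_class[[cls]] <- data.frame(feature_id = character(),
                                       sign = integer(), lfc = numeric(),
                                       stringsAsFactors = FALSE)
        next
      }
      chosen <- sample(pool, n_de)
      sign <- sample(c(-1L, 1L), n_de, replace = TRUE)
      lfc <- runif(n_de, params$lfc_range[1], params$lfc_range[2])
      offsets[chosen, seq.int(ci + 1L, nG)] <-
        offsets[chosen, seq.int(ci + 1L, nG)] + sign * lfc
      per_class[[cls]] <- data.frame(feature_id = chosen, sign = sign,
                                     lfc = lfc, stringsAsFactors = FALSE)
    }
    de_sets[[cname]] <- per_class
  }

  # triad coupling on log2 group means
  if (!is.null(triads) && nrow(triads)) {
    A <- params$triad_amplitude * sqrt(nG - 1)  # unit profile -> sd A
    cs <- params$coupling_strength
    for (k in seq_len(nrow(triads))) {
      z <- unit_orth(nG)
      e_mir <- unit_orth(nG, cbind(z))
      u_mir <- sqrt(cs) * z + sqrt(1 - cs) * e_mir
      dir <- if (triads$role[k] == "target") -1 else 1
      e_m <- unit_orth(nG, cbind(u_mir))
      u_m <- sqrt(cs) * dir * u_mir + sqrt(1 - cs) * e_m
      u_l <- if (triads$role[k] == "target") {
        e_l <- unit_orth(nG, cbind(u_mir))
        sqrt(cs) * (-u_mir) + sqrt(1 - cs) * e_l
      } else {
        e_l <- unit_orth(nG, cbind(u_m))
        sqrt(cs) * u_m + sqrt(1 - cs) * e_l
      }
      offsets[triads$mirna_id[k], ] <- A * u_mir
      offsets[triads$mrna_id[k], ] <- A * u_m
      offsets[triads$lnc_id[k], ] <- A * u_l
    }
  }

  mu <- base * 2^offsets
  samples <- paste0("s", seq_len(nG * params$n_reps))
  sample_group <- setNames(rep(groups, each = params$n_reps), samples)
  lib <- setNames(exp(rnorm(length(samples), 0, params$libsize_sdlog)),
                  samples)
  counts <- matrix(0, nf, length(samples),
                   dimnames = list(feature_ids, samples))
  size <- if (params$dispersion > 0) 1 / params$dispersion else Inf
  for (s in samples) {
    m <- lib[[s]] * mu[, sample_group[[s]]]
    counts[, s] <- if (is.finite(size)) rnbinom(nf, mu = m, size = size)
                   else stats::rpois(nf, m)
  }
  list(counts = expression_matrix(counts, sample_group, "counts"),
       de_sets = de_sets, offsets = offsets, mu = mu, lib_factors = lib)
}

#' Generate a complete in-silico study
#'
#' Seeds the RNG from `params$seed` and produces annotation, sequences,
#' planted binding sites, grouped NB counts and the ground-truth table.
#' Identical `(params)` give byte-identical studies.
#'
#' @param params a [sim_params()].
#' @param cfg a [ce_config()].
#' @return A `ce_study`: list with `params`, `records`, `features`, `qtl`,
#'   `counts`, `feature_class`, `mirna_seqs`, `utr_seqs`, `lnc_seqs`,
#'   `novel_seqs`, `categories`, and `truth` (list: de_sets, triads,
#'   planted_sites, qtl_members, offsets, mu).
#' @export
simulate_study <- function(params = sim_params(), cfg = ce_config()) {
  set.seed(params$seed)
  ann <- simulate_annotation(params, cfg)
  feat <- ann$features
  ids_mrna <- feat$feature_id[feat$class == "mRNA"]
  ids_lnc <- feat$feature_id[feat$class == "lncRNA"]
  ids_mir <- feat$feature_id[feat$class == "miRNA"]

  # triads: disjoint members, random roles
  n_triads <- min(params$n_triads, length(ids_lnc), length(ids_mir),
                  length(ids_mrna))
  triads <- if (n_triads > 0) data.frame(
    lnc_id = sample(ids_lnc, n_triads),
    mirna_id = sample(ids_mir, n_triads),
    mrna_id = sample(ids_mrna, n_triads),
    role = ifelse(rbinom(n_triads, 1, 0.5) == 1, "decoy", "target"),
    stringsAsFactors = FALSE)
  else data.frame(lnc_id = character(), mirna_id = character(),
                  mrna_id = character(), role = character(),
                  stringsAsFactors = FALSE)

  # sequences: triad miRNAs 22+ nt (see sim_params), others full range
  mir_len <- sample_range(params$mirna_len_range[1],
                          params$mirna_len_range[2], length(ids_mir))
  names(mir_len) <- ids_mir
  lo22 <- max(22L, params$mirna_len_range[1])
  if (lo22 > params$mirna_len_range[2])
    stop("mirna_len_range excludes the >= 22 nt lengths triad sites require")
  mir_len[triads$mirna_id] <- sample_range(lo22, params$mirna_len_range[2],
                                           nrow(triads))
  mirna_seqs <- setNames(random_seqs(length(ids_mir), mir_len,
                                     c("A", "C", "G", "U")), ids_mir)
  utr_len <- sample_range(params$utr_len_range[1], params$utr_len_range[2],
                          length(ids_mrna))
  utr_seqs <- setNames(random_seqs(length(ids_mrna), utr_len), ids_mrna)
  lnc_len <- feat$length[match(ids_lnc, feat$feature_id)]
  lnc_seqs <- setNames(random_seqs(length(ids_lnc), lnc_len), ids_lnc)

  # novel-candidate sequences: noncoding by construction except the
  # coding-potential violator (one long clean ORF)
  novel_ids <- feat$feature_id[feat$class == "novel_candidate"]
  novel_len <- feat$length[match(novel_ids, feat$feature_id)]
  novel_seqs <- setNames(vapply(random_seqs(length(novel_ids), novel_len),
                                scrub_orfs, character(1), USE.NAMES = FALSE),
                         novel_ids)
  if ("novel_fail_coding" %in% novel_ids) {
    len <- nchar(novel_seqs[["novel_fail_coding"]])
    body <- random_seqs(1, max(0, len - 6),
                        alphabet = c("A", "C", "G", "T"))
    body <- gsub("TAA|TAG|TGA", "TCA", body)  # keep the frame open
    orf <- paste0("ATG", substr(gsub("TAA|TAG|TGA", "TCA", body), 1,
                                len - 6), "TAA")
    novel_seqs[["novel_fail_coding"]] <- orf
  }

  # plant sites for every triad: on the mRNA 3' UTR and on the lncRNA
  pairs <- rbind(data.frame(mirna_id = triads$mirna_id,
                            target_id = triads$mrna_id,
                            stringsAsFactors = FALSE),
                 data.frame(mirna_id = triads$mirna_id,
                            target_id = triads$lnc_id,
                            stringsAsFactors = FALSE))
  planted <- plant_sites(params, mirna_seqs, c(utr_seqs, lnc_seqs), pairs)
  utr_seqs <- planted$targets[ids_mrna]
  lnc_seqs <- planted$targets[ids_lnc]

  feature_class <- setNames(feat$class, feat$feature_id)
  sim <- simulate_counts(params, feat$feature_id, feature_class, triads)

  # synthetic enrichment categories: random blocks plus one triad-loaded set
  categories <- lapply(seq_len(10), function(i)
    sample(ids_mrna, min(50, length(ids_mrna))))
  names(categories) <- sprintf("cat_%02d", seq_len(10))
  if (nrow(triads))
    categories$cat_triad_targets <-
      unique(c(triads$mrna_id,
               sample(ids_mrna, min(20, length(ids_mrna)))))

  truth <- list(de_sets = sim$de_sets, triads = triads,
                planted_sites = planted$sites,
                qtl_members = sort(feat$feature_id[
                  span_within(feat$chrom, feat$start, feat$end, ann$qtl)]),
                offsets = sim$offsets, mu = sim$mu)
  structure(list(params = params, records = ann$records, features = feat,
                 qtl = ann$qtl, counts = sim$counts,
                 feature_class = feature_class, mirna_seqs = mirna_seqs,
                 utr_seqs = utr_seqs, lnc_seqs = lnc_seqs,
                 novel_seqs = novel_seqs, categories = categories,
                 truth = truth, lib_factors = sim$lib_factors),
            class = "ce_study")
}

#' Write a simulated study to disk
#'
#' Emits `annotation.gtf`, `mirna.fa`, `utr.fa`, `lncrna.fa`, `novel.fa`,
#' `counts.tsv`, `groups.tsv`, `qtl.bed`, `categories.tsv` and
#' `truth.json`, each (where the format allows) starting with a comment
#' header carrying the package version, seed and config hash.
#'
#' @param study a `ce_study`.
#' @param dir output directory (created if missing).
#' @param cfg a [ce_config()].
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, cfg = ce_config()) {
  stopifnot(inherits(study, "ce_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(study$params$seed, cfg)
  write_gtf_transcripts(study$records, file.path(dir, "annotation.gtf"),
                        header = hdr)
  write_fasta(study$mirna_seqs, file.path(dir, "mirna.fa"))
  write_fasta(study$utr_seqs, file.path(dir, "utr.fa"))
  write_fasta(study$lnc_seqs, file.path(dir, "lncrna.fa"))
  if (length(study$novel_seqs))
    write_fasta(study$novel_seqs, file.path(dir, "novel.fa"))
  write_counts(study$counts, file.path(dir, "counts.tsv"), header = hdr)
  grp <- study$counts$sample_group
  writeLines(c(hdr, "sample_id\tgroup", paste(names(grp), grp, sep = "\t")),
             file.path(dir, "groups.tsv"))
  write_bed_interval(study$qtl, file.path(dir, "qtl.bed"), name = "qtl",
                     header = hdr)
  cat_rows <- unlist(lapply(names(study$categories), function(nm)
    paste(nm, study$categories[[nm]], sep = "\t")))
  writeLines(c(hdr, "category\tfeature_id", cat_rows),
             file.path(dir, "categories.tsv"))
  truth <- study$truth
  truth$offsets <- NULL; truth$mu <- NULL  # matrices stay in-memory only
  jsonlite::write_json(
    c(list(seed = study$params$seed), truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}

output_header <- function(seed, cfg = ce_config()) {
  sprintf("# cernet %s; seed=%s; config=%s",
          as.character(utils::packageVersion("cernet")), seed,
          config_hash(cfg))
}
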