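#' Median-of-ratios size factors
#'
#' For each sample j, `s_j = median_g X_gj / geomean(X_g.)`, the median over
#' features with all-positive counts of the ratio to the per-feature
#' geometric mean across samples. Factors are reported unscaled (no
#' re-normalization to unit geometric mean).
#'
#' @param em an [expression_matrix()] of kind `counts`.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$kind != "counts") stop("size factors are defined on raw counts")
  x <- em$values
  pos <- rowSums(x > 0) == ncol(x)
  if (!any(pos))
    stop("no feature has positive counts in every sample; ",
         "consider a pseudo-reference fallback (add a pseudo-count)")
  lx <- log(x[pos, , drop = FALSE])
  ref <- rowMeans(lx)                       # log geometric mean
  sf <- apply(exp(lx - ref), 2L, median)
  setNames(sf, colnames(x))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{k >= i} m * p_(k) / k`, clipped at 1 and mapped back to the
#' input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values (same length/order).
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  q[order(o)]
}

#' Negative-binomial Wald test for one two-group contrast
#'
#' A transparent reimplementation of the classic count-based two-group
#' test: counts are normalized by median-of-ratios [size_factors()];
#' per-feature dispersion is estimated by method of moments on normalized
#' counts (`phi = max(0, (var - mean) / mean^2)` with the within-group
#' pooled variance), shrunk halfway toward the mean dispersion over all
#' features and floored at 1e-8; the log2 fold change uses a 0.5
#' pseudo-count; the Wald statistic divides the fold change by a
#' delta-method standard error built from the NB variance `mu + phi mu^2`,
#' with a two-sided normal reference. All features are reported (no
#' independent filtering); BH adjustment is applied within the call.
#'
#' @param em counts [expression_matrix()] containing both groups.
#' @param ctr a [contrast()].
#' @param cfg a [ce_config()] (uses `alpha`, `lfc_pseudo`).
#' @param sf optional named size factors covering the contrast samples;
#'   computed from the two groups when omitted.
#' @return data.frame: feature_id, contrast, base_mean, log2fc, p, q,
#'   direction (`up`/`down`/`ns`; `ns` iff `q >= alpha`).
#' @export
nb_test_contrast <- function(em, ctr, cfg = ce_config(), sf = NULL) {
  stopifnot(inherits(em, "expr_matrix"), inherits(ctr, "ce_contrast"))
  if (em$kind != "counts") stop("nb_test_contrast needs raw counts")
  grp <- em$sample_group
  sA <- names(grp)[grp == ctr$reference]
  sB <- names(grp)[grp == ctr$treatment]
  if (length(sA) < 2L || length(sB) < 2L)
    stop(sprintf("contrast %s: both groups need >= 2 samples", ctr$name))
  sub <- subset_expression(em, samples = c(sA, sB))
  if (is.null(sf)) sf <- size_factors(sub)
  miss <- setdiff(c(sA, sB), names(sf))
  if (length(miss)) stop("size factors missing for sample(s): ",
                         paste(miss, collapse = ", "))
  y <- sweep(sub$values[, c(sA, sB), drop = FALSE], 2L,
             sf[c(sA, sB)], "/")
  yA <- y[, sA, drop = FALSE]; yB <- y[, sB, drop = FALSE]
  nA <- length(sA); nB <- length(sB)
  mA <- rowMeans(yA); mB <- rowMeans(yB)
  vA <- apply(yA, 1L, var); vB <- apply(yB, 1L, var)
  vpool <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mu <- (mA + mB) / 2
  phi_raw <- ifelse(mu > 0, pmax(0, (vpool - mu) / mu^2), 0)
  phi <- pmax(1e-8, 0.5 * phi_raw + 0.5 * mean(phi_raw))
  eps <- cfg$lfc_pseudo
  log2fc <- log2((mB + eps) / (mA + eps))
  varA <- (mA + phi * mA^2) / nA
  varB <- (mB + phi * mB^2) / nB
  se <- sqrt(varA / (mA + eps)^2 + varB / (mB + eps)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(z)), 1)
  dead <- mA == 0 & mB == 0
  p[dead] <- 1
  if (all(colSums(yA) == 0) || all(colSums(yB) == 0))
    warning(sprintf("contrast %s: one group has all-zero counts", ctr$name))
  q <- bh_adjust(p)
  direction <- ifelse(q >= cfg$alpha, "ns", ifelse(log2fc > 0, "up", "down"))
  data.frame(feature_id = rownames(y), contrast = ctr$name,
             base_mean = rowMeans(y), log2fc = log2fc, p = p, q = q,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Run the three oviposition contrasts per RNA class
#'
#' Testing (and BH adjustment, inside [nb_test_contrast()]) is run
#' separately within each RNA class and contrast, mirroring per-class DE
#' tallies.
#'
#' @param em counts [expression_matrix()] over all features.
#' @param feature_class named character vector feature id -> class
#'   (`mRNA`/`lncRNA`/`miRNA`).
#' @param contrasts list of [contrast()]s, default [default_contrasts()].
#' @param cfg a [ce_config()].
#' @return Named nested list `result[[contrast]][[class]]` of
#'   [nb_test_contrast()] data.frames.
#' @export
de_all_contrasts <- function(em, feature_class,
                             contrasts = default_contrasts(),
                             cfg = ce_config()) {
  feature_class <- feature_class[rownames(em$values)]
  if (any(is.na(feature_class))) stop("every feature needs a class")
  # size factors are estimated once per RNA class over all samples (miRNA
  # libraries are normalized independently of the long-RNA libraries)
  class_sf <- lapply(unique(feature_class), function(cls)
    size_factors(subset_expression(
      em, features = names(feature_class)[feature_class == cls])))
  names(class_sf) <- unique(feature_class)
  out <- list()
  for (ctr in contrasts) {
    per_class <- list()
    for (cls in unique(feature_class)) {
      ids <- names(feature_class)[feature_class == cls]
      per_class[[cls]] <- nb_test_contrast(
        subset_expression(em, features = ids), ctr, cfg,
        sf = class_sf[[cls]])
    }
    out[[ctr$name]] <- per_class
  }
  out
}

#' Union of significant features across contrasts
#' @param de nested list from [de_all_contrasts()].
#' @param cfg a [ce_config()].
#' @return Character vector of feature ids with `q < alpha` in any
#'   contrast/class table.
#' @export
de_union <- function(de, cfg = ce_config()) {
  ids <- unlist(lapply(de, function(per_class)
    lapply(per_class, function(tab) tab$feature_id[tab$q < cfg$alpha])),
    use.names = FALSE)
  sort(unique(ids))
}

#' Length- and depth-normalized expression transforms
#'
#' `FPKM_gj = X_gj / (len_g/1e3 * N_j/1e6)` with `N_j` the column sum;
#' `TPM_gj = 1e6 * (X_gj/len_g) / sum_g(X_gj/len_g)`. The stored value is
#' `log10(v + eps) + 1` with `eps = cfg$log_eps` guarding `log10(0)`.
#'
#' @param em counts [expression_matrix()].
#' @param lengths named numeric vector of effective feature lengths in bp
#'   (sum of exon lengths); all `> 0`.
#' @param kind `"FPKM"` or `"TPM"`.
#' @param cfg a [ce_config()].
#' @return An [expression_matrix()] of kind `transformed`.
#' @export
transform_expression <- function(em, lengths, kind = c("FPKM", "TPM"),
                                 cfg = ce_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(em, "expr_matrix"))
  lengths <- lengths[rownames(em$values)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("every feature needs a positive length for ", kind)
  x <- em$values
  v <- if (kind == "FPKM") {
    N <- colSums(x)
    sweep(x / (lengths / 1e3), 2L, N / 1e6, "/")
  } else {
    rate <- x / lengths
    sweep(rate, 2L, colSums(rate), "/") * 1e6
  }
  v[!is.finite(v)] <- 0  # all-zero library guard
  expression_matrix(log10(v + cfg$log_eps) + 1, em$sample_group,
                    "transformed")
}

#' Hierarchical sample clustering (Euclidean, complete linkage)
#'
#' Samples are ordered lexicographically before clustering so the result is
#' invariant to input column order; `stats::hclust` with complete linkage on
#' Euclidean distances over feature vectors. Branch lengths in the Newick
#' string derive from merge heights (ultrametric rendering via
#' [ape::as.phylo()]).
#'
#' @param em a transformed [expression_matrix()] with >= 2 samples.
#' @return List: `hclust` (the merge tree), `newick` (string), `merges`
#'   (data.frame of merge heights and member sets, one row per merge).
#' @export
cluster_samples <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2L) stop("clustering needs >= 2 samples")
  v <- em$values[, order(colnames(em$values)), drop = FALSE]
  hc <- hclust(dist(t(v), method = "euclidean"), method = "complete")
  phy <- ape::as.phylo(hc)
  members <- function(k) {  # tip labels under merge row k
    get <- function(i) if (i < 0) hc$labels[-i] else members(i)
    sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
  }
  merges <- data.frame(
    height = hc$height,
    members = vapply(seq_len(nrow(hc$merge)),
                     function(k) paste(members(k), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  list(hclust = hc, newick = ape::write.tree(phy), merges = merges)
}

#' qPCR relative quantity from the comparative Ct method
#'
#' `quantity = 10^(-dCt / slope)` with `dCt = ct_target - ct_reference`
#' (reference = housekeeping gene), then divided by `calibrator_mean` so the
#' calibrator group (virgin queens) averages exactly 1.
#'
#' @param ct_target,ct_reference numeric Ct values (vectorized).
#' @param slope standard-curve slope (non-zero).
#' @param calibrator_mean mean pre-calibration quantity of the calibrator
#'   group (default 1 = no calibration).
#' @return Numeric vector of relative quantities.
#' @export
qpcr_relative_quantity <- function(ct_target, ct_reference, slope,
                                   calibrator_mean = 1) {
  if (!is.numeric(slope) || length(slope) != 1L || slope == 0)
    stop("slope must be a single non-zero number")
  10^(-(ct_target - ct_reference) / slope) / calibrator_mean
}
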