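#' Co-localize DE features with a QTL interval
#'
#' Differentially expressed features whose genomic span is fully contained
#' in the interval (default semantics; set `cfg$qtl_overlap = TRUE` for
#' any-overlap semantics), split into genes (mRNAs) and lncRNAs. The
#' default window is the ovary-size QTL, chr11:8.9-12.2 Mb.
#'
#' @param features data.frame with columns `feature_id`, `class`
#'   (`mRNA`/`lncRNA`/`miRNA`), `chrom`, `start`, `end` (0-based
#'   half-open spans).
#' @param de_ids character vector of DE feature ids.
#' @param interval a [genomic_interval()]; defaults to the configured QTL.
#' @param cfg a [ce_config()].
#' @return List with `interval`, `genes` (character), `lncrnas`
#'   (character), `members` (data.frame of all accepted features).
#' @export
qtl_colocalize <- function(features, de_ids,
                           interval = NULL, cfg = ce_config()) {
  stopifnot(is.data.frame(features),
            all(c("feature_id", "class", "chrom", "start", "end") %in%
                  names(features)))
  if (is.null(interval)) interval <- config_qtl_interval(cfg)
  if (!interval$chrom %in% features$chrom)
    stop("interval chromosome '", interval$chrom,
         "' absent from the annotation")
  hit <- if (cfg$qtl_overlap)
    span_overlaps(features$chrom, features$start, features$end, interval)
  else
    span_within(features$chrom, features$start, features$end, interval)
  members <- features[hit & features$feature_id %in% de_ids, , drop = FALSE]
  members <- members[order(members$feature_id), , drop = FALSE]
  rownames(members) <- NULL
  list(interval = interval,
       genes = members$feature_id[members$class == "mRNA"],
       lncrnas = members$feature_id[members$class == "lncRNA"],
       members = members)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value per category,
#' `P[X >= overlap]` for `X ~ Hypergeom(N = |universe|, K = |category|,
#' n = |query|)`, BH-adjusted across categories. A generic stand-in for
#' ontology enrichment tools: supply any category -> feature-set map
#' (GO terms, pathways, or synthetic categories).
#'
#' @param query character vector of features of interest (must be a subset
#'   of `universe`).
#' @param universe character vector of all testable features.
#' @param categories named list of character vectors; members outside the
#'   universe are dropped.
#' @return data.frame: category, n_category, overlap, p, q; ordered by
#'   (p, category).
#' @export
enrich_categories <- function(query, universe, categories) {
  query <- unique(query); universe <- unique(universe)
  if (length(setdiff(query, universe)))
    stop("query contains feature(s) outside the universe: ",
         paste(head(setdiff(query, universe), 3), collapse = ", "))
  if (!length(categories))
    return(data.frame(category = character(), n_category = integer(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  if (is.null(names(categories)) || any(!nzchar(names(categories))))
    stop("categories must be a named list")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(categories), function(cat) {
    members <- intersect(unique(categories[[cat]]), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = cat, n_category = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
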