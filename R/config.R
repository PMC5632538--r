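#' Pipeline configuration
#'
#' All tunable thresholds of the pipeline with their defaults. Defaults are
#' the published screening and pairing cutoffs of the analysis the package
#' implements: candidate lncRNAs must be >= 200 bp with >= 2 exons, assembler
#' coverage >= 3 and presence in >= 2 samples; differential expression is
#' called at BH-adjusted p < `alpha`; trans targets require |Pearson r| >=
#' `r_trans` (0.95); network pairing requires |r| > `r_pair` (0.8); miRNA
#' binding sites are retained iff alignment score > `site_score_min` (140)
#' and duplex energy < `site_energy_max` (-10 kcal/mol); genes lacking an
#' annotated 3' UTR are scanned over `utr_fallback_len` (1000 bp) downstream
#' of the stop codon; the ovary-size QTL window defaults to
#' chr11:8,900,000-12,200,000.
#'
#' @param ... name = value overrides of any default listed below.
#'
#' @return A named list with class `ce_config`.
#' @examples
#' cfg <- ce_config(alpha = 0.1)
#' cfg$min_length
#' @export
ce_config <- function(...) {
  cfg <- list(
    min_length       = 200L,    # bp, candidate lncRNA minimum spliced length
    min_exons        = 2L,
    min_coverage     = 3,       # assembler-reported mean read depth
    min_samples      = 2L,      # recurrence across libraries
    alpha            = 0.05,    # BH-adjusted significance cutoff
    r_trans          = 0.95,    # |Pearson r| for lncRNA trans targets
    r_pair           = 0.8,     # |Pearson r| for network pairing (strict >)
    site_score_min   = 140,     # alignment score, strict >
    site_energy_max  = -10,     # kcal/mol, strict <
    utr_fallback_len = 1000L,   # bp downstream of stop codon
    qtl_chrom        = "chr11",
    qtl_start        = 8900000,
    qtl_end          = 12200000,
    qtl_overlap      = FALSE,   # FALSE = full containment semantics
    orf_min_nt       = 300L,    # coding call: longest ORF >= this, or
    orf_min_frac     = 0.5,     #   ORF covering >= this fraction of length
    log_eps          = 0.01,    # epsilon in log10(v + eps) + 1 transform
    lfc_pseudo       = 0.5,     # pseudo-count in log2 fold changes
    require_site     = TRUE,    # miRNA-mRNA edges need site evidence
    mirna_len_min    = 18L,
    mirna_len_max    = 26L,
    rng_seed         = 1L
  )
  override <- list(...)
  if (length(override)) {
    if (is.null(names(override)) || any(names(override) == ""))
      stop("config overrides must be named")
    unknown <- setdiff(names(override), names(cfg))
    if (length(unknown))
      warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[intersect(names(override), names(cfg))] <-
      override[intersect(names(override), names(cfg))]
  }
  cfg <- validate_config(cfg)
  structure(cfg, class = "ce_config")
}

validate_config <- function(cfg) {
  num <- function(key, lo = -Inf, hi = Inf) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo || v > hi)
      stop(sprintf("config key '%s' out of range [%g, %g]: %s",
                   key, lo, hi, paste(v, collapse = ",")))
    v
  }
  cfg$min_length <- as.integer(num("min_length", 0))
  cfg$min_exons <- as.integer(num("min_exons", 1))
  num("min_coverage", 0); cfg$min_samples <- as.integer(num("min_samples", 1))
  num("alpha", 0, 1); num("r_trans", 0, 1); num("r_pair", 0, 1)
  num("site_score_min", 0); num("site_energy_max", -Inf, 0)
  cfg$utr_fallback_len <- as.integer(num("utr_fallback_len", 1))
  num("qtl_start", 0); num("qtl_end", 0)
  if (cfg$qtl_end <= cfg$qtl_start) stop("config: qtl_end must exceed qtl_start")
  cfg$orf_min_nt <- as.integer(num("orf_min_nt", 3))
  num("orf_min_frac", 0, 1); num("log_eps", 0); num("lfc_pseudo", 0)
  cfg$mirna_len_min <- as.integer(num("mirna_len_min", 1))
  cfg$mirna_len_max <- as.integer(num("mirna_len_max", cfg$mirna_len_min))
  for (key in c("qtl_overlap", "require_site"))
    if (!is.logical(cfg[[key]]) || length(cfg[[key]]) != 1L || is.na(cfg[[key]]))
      stop(sprintf("config key '%s' must be TRUE or FALSE", key))
  if (!is.character(cfg$qtl_chrom) || !nzchar(cfg$qtl_chrom))
    stop("config key 'qtl_chrom' must be a non-empty chromosome name")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg
}

#' Read a configuration from a flat key=value file
#'
#' Blank lines and lines starting with `#` are ignored. Unknown keys raise a
#' warning; unparsable values raise an error naming the key. Keys not present
#' keep their [ce_config()] defaults.
#'
#' @param path path to a key=value text file (may be empty).
#' @return A `ce_config` object.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- ce_config()
  override <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("config line without '=': ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(defaults)) {
      warning("ignoring unknown config key: ", key)
      next
    }
    proto <- defaults[[key]]
    parsed <- if (is.logical(proto)) {
      as.logical(toupper(val))
    } else if (is.numeric(proto)) {
      suppressWarnings(as.numeric(val))
    } else val
    if (length(parsed) != 1L || (!is.character(parsed) && is.na(parsed)))
      stop(sprintf("cannot parse value for config key '%s': '%s'", key, val))
    override[[key]] <- parsed
  }
  do.call(ce_config, override)
}

#' Serialize a configuration to a key=value file
#' @param cfg a `ce_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ce_config"))
  fmt <- vapply(cfg, function(v) {
    if (is.logical(v)) ifelse(v, "TRUE", "FALSE")
    else if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE)
    else as.character(v)
  }, character(1))
  writeLines(paste0(names(cfg), "=", fmt), path)
  invisible(path)
}

#' Short hash of the effective configuration
#'
#' Used in output-file headers so runs are attributable to an exact
#' parameterization.
#' @param cfg a `ce_config` object.
#' @return An 8-character hex string.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "ce_config"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 8L)
}

#' QTL interval of a configuration as a genomic interval
#' @param cfg a `ce_config` object.
#' @return A [genomic_interval()].
#' @export
config_qtl_interval <- function(cfg) {
  genomic_interval(cfg$qtl_chrom, cfg$qtl_start, cfg$qtl_end, ".")
}
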