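#' Log expression used for all correlation screens
#'
#' Normalized counts (median-of-ratios within the feature subset) on the
#' log2(y + 1) scale; the substrate for trans-target inference, pairing
#' correlations and role classification.
#'
#' @param em counts [expression_matrix()].
#' @return An [expression_matrix()] of kind `transformed`.
#' @export
log_normalized <- function(em) {
  sf <- size_factors(em)
  y <- sweep(em$values, 2L, sf, "/")
  expression_matrix(log2(y + 1), em$sample_group, "transformed")
}

#' Run the whole pipeline on a simulated study
#'
#' Executes every stage in order — lncRNA filter cascade, per-class
#' differential expression for the three oviposition contrasts, expression
#' transforms and sample clustering, trans-target inference, miRNA site
#' scanning (restricted to DE features by default), ceRNA network assembly
#' with lncRNA role classification, bridge-gene detection, QTL
#' co-localization and category enrichment — and writes all outputs under
#' `out_dir`. Every text output starts with a comment header carrying the
#' package version, seed and configuration hash, and all randomness flows
#' from `seed` alone, so two runs with identical arguments produce
#' byte-identical output trees.
#'
#' @param out_dir output directory.
#' @param params a [sim_params()] for the synthetic study.
#' @param cfg a [ce_config()].
#' @param seed integer; overrides `params$seed`.
#' @param scan_all scan all miRNA/region pairs instead of DE-only (slower).
#' @return Invisibly, a list with the study and every stage result.
#' @export
run_pipeline <- function(out_dir, params = sim_params(), cfg = ce_config(),
                         seed = params$seed, scan_all = FALSE) {
  params$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(params$seed, cfg)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w"); on.exit(close(con), add = TRUE)
    writeLines(hdr, con)
    suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
    path
  }

  study <- simulate_study(params, cfg)
  write_study(study, file.path(out_dir, "simulated"), cfg)

  # -- lncRNA filter cascade on the novel candidates ------------------------
  records <- flag_known_overlap(study$records)
  filt <- filter_candidates(records, cfg, seqs = study$novel_seqs)
  tsv(filt$report, "filter_report.tsv")
  survivors <- vapply(filt$survivors, `[[`, character(1), "transcript_id")

  # -- differential expression ---------------------------------------------
  # surviving novel candidates join the lncRNA testing family
  fclass <- study$feature_class
  fclass[names(fclass) %in% survivors] <- "lncRNA"
  keep <- names(fclass)[fclass %in% c("mRNA", "lncRNA", "miRNA")]
  em <- subset_expression(study$counts, features = keep)
  de <- de_all_contrasts(em, fclass[keep], cfg = cfg)
  for (cname in names(de))
    for (cls in names(de[[cname]]))
      tsv(de[[cname]][[cls]], sprintf("de_%s_%s.tsv", cname, cls))
  de_ids <- de_union(de, cfg)
  tsv(data.frame(sample_id = names(size_factors(em)),
                 size_factor = unname(size_factors(em))),
      "size_factors.tsv")

  # -- transforms and sample clustering ------------------------------------
  lengths <- setNames(study$features$length, study$features$feature_id)
  ids_mrna <- names(fclass)[fclass == "mRNA"]
  ids_lnc <- names(fclass)[fclass == "lncRNA"]
  ids_mir <- names(fclass)[fclass == "miRNA"]
  fpkm <- transform_expression(
    subset_expression(em, features = c(ids_mrna, ids_lnc)), lengths,
    "FPKM", cfg)
  clust <- cluster_samples(fpkm)
  writeLines(c(hdr, clust$newick), file.path(out_dir, "dendrogram.nwk"))

  # -- correlation screens on log-normalized expression --------------------
  expr <- log_normalized(em)
  lnc_expr <- subset_expression(expr, features = ids_lnc)
  mrna_expr <- subset_expression(expr, features = ids_mrna)
  mir_expr <- subset_expression(expr, features = ids_mir)
  trans <- trans_targets(
    subset_expression(lnc_expr, features = intersect(ids_lnc, de_ids)),
    subset_expression(mrna_expr, features = intersect(ids_mrna, de_ids)),
    cfg)
  tsv(trans, "trans_targets.tsv")

  # -- miRNA site scanning --------------------------------------------------
  scan_mir <- if (scan_all) ids_mir else intersect(ids_mir, de_ids)
  scan_tgt <- if (scan_all) c(ids_mrna, ids_lnc)
              else intersect(c(ids_mrna, ids_lnc), de_ids)
  regions <- c(study$utr_seqs, study$lnc_seqs)[
    intersect(scan_tgt, c(names(study$utr_seqs), names(study$lnc_seqs)))]
  sites <- scan_all_sites(study$mirna_seqs[scan_mir], regions, cfg)
  tsv(sites[, c("mirna_id", "target_id", "target_start", "target_end",
                "align_score", "energy")], "mirna_sites.tsv")

  # -- ceRNA network --------------------------------------------------------
  mrna_sites <- sites[sites$target_id %in% ids_mrna, , drop = FALSE]
  lnc_sites <- sites[sites$target_id %in% ids_lnc, , drop = FALSE]
  mm_cand <- mir_mrna_candidates(mrna_sites, mir_expr, mrna_expr)
  lnc_mir <- classify_lncrna_roles(lnc_sites, lnc_expr, mir_expr, mrna_expr,
                                   mm_cand[abs(mm_cand$r) > cfg$r_pair, ,
                                           drop = FALSE], cfg)
  net <- build_network(de_ids, lnc_mir, mm_cand, cfg)
  write_network_sif(net, file.path(out_dir, "network.sif"),
                    file.path(out_dir, "node_attributes.tsv"), header = hdr)
  tsv(find_bridges(net), "bridges.tsv")

  # -- QTL co-localization and enrichment ----------------------------------
  qtl_res <- qtl_colocalize(study$features, de_ids, study$qtl, cfg)
  tsv(qtl_res$members, "qtl_candidates.tsv")
  enr <- enrich_categories(intersect(ids_mrna, de_ids), ids_mrna,
                           study$categories)
  tsv(enr, "enrichment.tsv")
  write_config(cfg, file.path(out_dir, "effective_config.txt"))

  invisible(list(study = study, filter = filt, de = de, de_ids = de_ids,
                 cluster = clust, trans = trans, sites = sites,
                 mir_mrna = mm_cand, lnc_mir = lnc_mir, network = net,
                 bridges = find_bridges(net), qtl = qtl_res,
                 enrichment = enr))
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the synthetic study) and `all` (full
#' pipeline). Flags: `--out-dir` (required), `--config` (key=value file),
#' `--seed` (integer). Mirrors [run_pipeline()]; stage-level subcommands
#' are available programmatically through the exported functions.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Exit status, invisibly (0 on success).
#' @export
cernet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: cernet <simulate|all> --out-dir DIR [--config FILE] [--seed N]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]; args <- args[-1L]
  opt <- list(out_dir = NULL, config = NULL, seed = 1L)
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!key %in% c("--out-dir", "--config", "--seed") || i == length(args))
      stop("unknown or incomplete flag: ", key)
    val <- args[i + 1L]; i <- i + 2L
    if (key == "--out-dir") opt$out_dir <- val
    if (key == "--config") opt$config <- val
    if (key == "--seed") opt$seed <- as.integer(val)
  }
  if (is.null(opt$out_dir)) stop(usage)
  cfg <- if (is.null(opt$config)) ce_config() else load_config(opt$config)
  params <- sim_params(seed = opt$seed)
  message("cernet ", utils::packageVersion("cernet"), " | seed=", opt$seed,
          " | config=", config_hash(cfg))
  if (cmd == "simulate") {
    write_study(simulate_study(params, cfg), opt$out_dir, cfg)
  } else if (cmd == "all") {
    run_pipeline(opt$out_dir, params, cfg, seed = opt$seed)
  } else stop("unknown subcommand '", cmd, "'\n", usage)
  invisible(0L)
}
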