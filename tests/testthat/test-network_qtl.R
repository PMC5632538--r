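grp12 <- setNames(rep(c("V", "Q", "C", "R"), each = 3), paste0("s", 1:12))

# build expression matrices where named features follow given profiles
profile_expr <- function(profiles) {
  m <- do.call(rbind, profiles)
  rownames(m) <- names(profiles)
  colnames(m) <- paste0("s", 1:12)
  expression_matrix(m, grp12, "transformed")
}

test_that("lncRNA role classification follows the target/decoy rule", {
  base <- sin(1:12)
  lnc_t <- profile_expr(list(lnc_a = -base, lnc_b = cos(1:12) * 0.1 + base * 0.05))
  mir <- profile_expr(list(mir_x = base))
  mrna <- profile_expr(list(m_1 = -base))
  sites <- data.frame(mirna_id = c("mir_x", "mir_x"),
                      target_id = c("lnc_a", "lnc_b"),
                      stringsAsFactors = FALSE)
  mm <- data.frame(mirna_id = "mir_x", mrna_id = "m_1", r = -1,
                   site_evidence = TRUE, stringsAsFactors = FALSE)
  roles <- classify_lncrna_roles(sites, lnc_t, mir, mrna, mm)
  # lnc_a: r(lnc, mir) = -1 <= -0.8 -> target
  expect_equal(roles$edge_type[roles$lnc_id == "lnc_a"], "lnc_mir_target")
  # lnc_b: weak r with the miRNA, no strong mRNA partner -> no edge
  expect_false("lnc_b" %in% roles$lnc_id)

  # decoy: r(lnc, mir) ~ 0.1 but r(lnc, targeted mRNA) = +0.9
  set.seed(61)
  u <- rnorm(12); w <- rnorm(12)
  mrna2 <- profile_expr(list(m_1 = 0.5 * u + w))
  lnc2 <- profile_expr(list(lnc_c = 0.45 * u + 1.02 * w))
  mir2 <- profile_expr(list(mir_x = u))
  stopifnot(cor(lnc2$values["lnc_c", ], mir2$values["mir_x", ]) < 0.8,
            cor(lnc2$values["lnc_c", ], mrna2$values["m_1", ]) > 0.8)
  roles2 <- classify_lncrna_roles(
    data.frame(mirna_id = "mir_x", target_id = "lnc_c",
               stringsAsFactors = FALSE), lnc2, mir2, mrna2, mm)
  expect_equal(roles2$edge_type, "lnc_mir_decoy")

  # no site evidence -> no edge regardless of correlation
  roles3 <- classify_lncrna_roles(sites[0, ], lnc_t, mir, mrna, mm)
  expect_equal(nrow(roles3), 0L)
})

test_that("build_network enforces DE membership and admission rules", {
  mm <- data.frame(mirna_id = "mir_1", mrna_id = "m_1", r = 0.9,
                   site_evidence = TRUE, stringsAsFactors = FALSE)
  lm0 <- data.frame(lnc_id = character(), mirna_id = character(),
                    edge_type = character(), r = numeric(),
                    stringsAsFactors = FALSE)
  net <- build_network(c("mir_1", "m_1"), lm0, mm)
  expect_equal(nrow(net$nodes), 2L)
  expect_equal(nrow(net$edges), 1L)
  # mRNA not DE -> empty network
  expect_warning(net2 <- build_network("mir_1", lm0, mm), "empty")
  expect_equal(nrow(net2$edges), 0L)
  # |r| below the pairing threshold -> rejected (strict > 0.8)
  mm$r <- 0.8
  expect_warning(net3 <- build_network(c("mir_1", "m_1"), lm0, mm))
  expect_equal(nrow(net3$edges), 0L)
  # correlation-only admission via require_site = FALSE
  mm$r <- -0.85; mm$site_evidence <- FALSE
  expect_warning(build_network(c("mir_1", "m_1"), lm0, mm), "empty")
  net4 <- build_network(c("mir_1", "m_1"), lm0, mm,
                        ce_config(require_site = FALSE))
  expect_equal(nrow(net4$edges), 1L)
})

test_that("network invariants hold and rebuilding is idempotent", {
  set.seed(62)
  lm <- data.frame(lnc_id = sample(sprintf("lnc_%02d", 1:8), 12, TRUE),
                   mirna_id = sample(sprintf("mir_%02d", 1:5), 12, TRUE),
                   edge_type = sample(c("lnc_mir_target", "lnc_mir_decoy"),
                                      12, TRUE),
                   r = runif(12, -1, 1), stringsAsFactors = FALSE)
  lm <- lm[!duplicated(lm[, 1:2]), ]
  mm <- data.frame(mirna_id = sample(sprintf("mir_%02d", 1:5), 20, TRUE),
                   mrna_id = sample(sprintf("m_%02d", 1:10), 20, TRUE),
                   r = runif(20, -1, 1), site_evidence = TRUE,
                   stringsAsFactors = FALSE)
  mm <- mm[!duplicated(mm[, 1:2]), ]
  de <- c(sprintf("lnc_%02d", 1:6), sprintf("mir_%02d", 1:4),
          sprintf("m_%02d", 1:8))
  net <- suppressWarnings(build_network(de, lm, mm))
  expect_silent(validate_network(net))
  # every node sits in >= 1 edge and endpoint types are compatible
  expect_setequal(net$nodes$id, unique(c(net$edges$a, net$edges$b)))
  # idempotence: rebuilding from the network's own edges reproduces it
  lm2 <- net$edges[net$edges$edge_type != "mir_mrna", ]
  lm2 <- data.frame(lnc_id = lm2$a, mirna_id = lm2$b,
                    edge_type = lm2$edge_type, r = lm2$r,
                    stringsAsFactors = FALSE)
  mm2 <- net$edges[net$edges$edge_type == "mir_mrna", ]
  mm2 <- data.frame(mirna_id = mm2$a, mrna_id = mm2$b, r = mm2$r,
                    site_evidence = mm2$site_evidence,
                    stringsAsFactors = FALSE)
  net2 <- suppressWarnings(build_network(de, lm2, mm2))
  expect_equal(net2$edges, net$edges)
  expect_equal(net2$nodes, net$nodes)
  # monotone in r_pair: raising the threshold never adds edges
  for (thr in c(0.85, 0.9, 0.95)) {
    sub <- suppressWarnings(build_network(de, lm, mm,
                                          ce_config(r_pair = thr)))
    mm_edges <- function(n) paste(n$edges$a, n$edges$b)[
      n$edges$edge_type == "mir_mrna"]
    expect_true(all(mm_edges(sub) %in% mm_edges(net)))
  }
})

test_that("bridge detection equals brute-force neighbor counting", {
  lm0 <- data.frame(lnc_id = character(), mirna_id = character(),
                    edge_type = character(), r = numeric(),
                    stringsAsFactors = FALSE)
  # star: one mRNA linked to three miRNAs
  mm <- data.frame(mirna_id = c("mir_1", "mir_2", "mir_3"),
                   mrna_id = "hub", r = 0.9, site_evidence = TRUE,
                   stringsAsFactors = FALSE)
  net <- build_network(c("mir_1", "mir_2", "mir_3", "hub"), lm0, mm)
  br <- find_bridges(net)
  expect_equal(br$mrna_id, "hub")
  expect_equal(br$mirna_degree, 3L)
  # only degree-1 mRNAs -> empty
  mm1 <- data.frame(mirna_id = c("mir_1", "mir_2"),
                    mrna_id = c("m_1", "m_2"), r = 0.9, site_evidence = TRUE,
                    stringsAsFactors = FALSE)
  net1 <- build_network(c("mir_1", "mir_2", "m_1", "m_2"), lm0, mm1)
  expect_equal(nrow(find_bridges(net1)), 0L)
  # random network vs brute force
  set.seed(63)
  mmr <- unique(data.frame(mirna_id = sample(sprintf("mir_%02d", 1:10), 100,
                                             TRUE),
                           mrna_id = sample(sprintf("m_%02d", 1:20), 100,
                                            TRUE),
                           stringsAsFactors = FALSE))
  mmr$r <- 0.95; mmr$site_evidence <- TRUE
  netr <- build_network(c(sprintf("mir_%02d", 1:10), sprintf("m_%02d", 1:20)),
                        lm0, mmr)
  got <- find_bridges(netr, min_mirna_degree = 2L)
  brute <- sapply(sprintf("m_%02d", 1:20), function(m)
    length(unique(mmr$mirna_id[mmr$mrna_id == m])))
  brute <- sort(brute[brute >= 2], decreasing = TRUE)
  expect_equal(sum(got$mirna_degree), sum(brute))
  expect_setequal(got$mrna_id, names(brute))
  for (m in got$mrna_id)
    expect_equal(got$mirna_degree[got$mrna_id == m], unname(brute[m]))
})

test_that("QTL co-localization follows containment vs overlap semantics", {
  feats <- data.frame(
    feature_id = c("in_gene", "in_lnc", "straddle", "off_chrom", "not_de"),
    class = c("mRNA", "lncRNA", "mRNA", "mRNA", "mRNA"),
    chrom = c("chr11", "chr11", "chr11", "chr10", "chr11"),
    start = c(9000000, 10000000, 8850000, 9000000, 9500000),
    end = c(9010000, 10005000, 8950000, 9010000, 9505000),
    stringsAsFactors = FALSE)
  de <- c("in_gene", "in_lnc", "straddle", "off_chrom")
  res <- qtl_colocalize(feats, de)
  expect_equal(res$genes, "in_gene")
  expect_equal(res$lncrnas, "in_lnc")
  # straddling features enter only under overlap semantics
  res_ov <- qtl_colocalize(feats, de, cfg = ce_config(qtl_overlap = TRUE))
  expect_true("straddle" %in% res_ov$genes)
  expect_false("off_chrom" %in% res_ov$genes)
  expect_error(qtl_colocalize(feats[feats$chrom == "chr10", ], de),
               "absent")
})

test_that("containment/overlap agree with a brute-force check on random spans", {
  set.seed(64)
  iv <- genomic_interval("chr11", 8900000, 12200000)
  n <- 10000
  chrom <- sample(c("chr10", "chr11"), n, TRUE, prob = c(0.3, 0.7))
  start <- floor(runif(n, 8.0e6, 13.0e6))
  width <- floor(runif(n, 1e3, 5e5))
  end <- start + width
  got_in <- span_within(chrom, start, end, iv)
  got_ov <- span_overlaps(chrom, start, end, iv)
  for (k in sample(n, 200)) {  # spot-check the vectorized result elementwise
    expect_identical(got_in[k], chrom[k] == "chr11" &&
                       start[k] >= 8900000 && end[k] <= 12200000)
    expect_identical(got_ov[k], chrom[k] == "chr11" &&
                       !(end[k] <= 8900000 || start[k] >= 12200000))
  }
  # full-vector brute force
  expect_identical(got_in,
                   chrom == "chr11" & start >= 8.9e6 & end <= 12.2e6)
  expect_identical(got_ov,
                   chrom == "chr11" & start < 12.2e6 & end > 8.9e6)
  expect_true(any(got_in) && any(got_ov & !got_in))
})

test_that("enrichment matches hand and enumerated hypergeometric tails", {
  # universe 10, category 5, query 4, overlap 4 -> 5/210
  uni <- sprintf("g%02d", 1:10)
  res <- enrich_categories(uni[1:4], uni, list(cat = uni[1:5]))
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  # query = universe -> p = 1 for every category
  res1 <- enrich_categories(uni, uni, list(a = uni[1:3], b = uni[4:10]))
  expect_true(all(res1$p == 1))
  expect_error(enrich_categories(c(uni[1], "zz"), uni, list(a = uni)),
               "outside the universe")
  # exhaustive enumeration on small universes
  set.seed(65)
  for (i in 1:20) {
    N <- sample(8:20, 1)
    uni <- sprintf("u%02d", seq_len(N))
    K <- sample(2:(N - 2), 1); n <- sample(2:(N - 2), 1)
    cat_set <- sample(uni, K); query <- sample(uni, n)
    k <- length(intersect(cat_set, query))
    res <- enrich_categories(query, uni, list(x = cat_set))
    expect_equal(res$overlap, k)
    expect_equal(res$p, oracle_hyper_tail(k, K, N, n), tolerance = 1e-10)
  }
  # BH across categories
  res2 <- enrich_categories(uni[1:5], uni,
                            list(a = uni[1:5], b = uni[6:10], c = uni[1:2]))
  expect_equal(res2$q, bh_adjust(res2$p), tolerance = 1e-12)
})
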