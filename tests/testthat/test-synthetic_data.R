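# small parameter set shared across generator tests
small_params <- function(...) {
  sim_params(n_mrna = 60L, n_lncrna = 20L, n_mirna = 10L, n_triads = 4L,
             seed = 11L, ...)
}

test_that("simulated annotation places QTL members exactly as recorded", {
  set.seed(1)
  ann <- simulate_annotation(small_params(qtl_fraction = 0.2))
  feat <- ann$features
  # brute-force containment over every simulated span must equal the truth
  brute <- sort(feat$feature_id[
    feat$chrom == "chr11" & feat$start >= 8900000 & feat$end <= 12200000])
  expect_identical(brute, ann$qtl_members)
  expect_gt(length(brute), 0L)

  set.seed(2)
  ann0 <- simulate_annotation(small_params(qtl_fraction = 0))
  f0 <- ann0$features
  expect_identical(character(),
                   f0$feature_id[f0$chrom == "chr11" & f0$start >= 8900000 &
                                   f0$end <= 12200000])

  set.seed(3)
  p1 <- sim_params(n_mrna = 10L, n_lncrna = 0L, n_mirna = 0L, n_triads = 0L,
                   qtl_fraction = 1)
  ann1 <- simulate_annotation(p1)
  f1 <- ann1$features[ann1$features$class == "mRNA", ]
  expect_true(all(f1$chrom == "chr11" & f1$start >= 8900000 &
                    f1$end <= 12200000))

  expect_error(simulate_annotation(small_params(chrom_length = 1e6)),
               "too short")
})

test_that("planted sites are recoverable by exhaustive string search", {
  set.seed(4)
  p <- small_params()
  mirnas <- setNames(random_rna(5, 22), paste0("mir_", 1:5))
  utrs <- setNames(random_dna(5, 800), paste0("t", 1:5))
  pairs <- data.frame(mirna_id = paste0("mir_", 1:5),
                      target_id = paste0("t", 1:5),
                      stringsAsFactors = FALSE)
  res <- plant_sites(p, mirnas, utrs, pairs)
  expect_gte(nrow(res$sites), 5L)
  for (k in seq_len(nrow(res$sites))) {
    s <- res$sites[k, ]
    rc <- reverse_complement(mirnas[[s$mirna_id]])
    # exhaustive search for the reverse complement finds the recorded spot
    hits <- gregexpr(rc, res$targets[[s$target_id]], fixed = TRUE)[[1]] - 1L
    expect_true(s$position %in% hits)
  }
  # zero designated pairs leave the targets untouched
  res0 <- plant_sites(p, mirnas, utrs, pairs[0, ])
  expect_identical(res0$targets, utrs)
  expect_equal(nrow(res0$sites), 0L)
  # too-short target and too-short miRNA raise errors
  expect_error(plant_sites(sim_params(sites_per_target = c(3L, 3L)),
                           mirnas, setNames(random_dna(1, 50), "t1"),
                           pairs[1, ]), "too short")
  expect_error(plant_sites(p, setNames(random_rna(1, 20), "mir_1"),
                           utrs, pairs[1, ]), "22 nt")
})

test_that("simulated counts follow the planted NB model", {
  # Poisson limit: phi -> 0, one group, mu fixed
  set.seed(5)
  p0 <- sim_params(dispersion = 0, libsize_sdlog = 0, n_reps = 3L,
                   groups = c("A", "B"), de_fraction = 0, n_triads = 0L,
                   baseline_meanlog = log(100), baseline_sdlog = 0)
  ids <- paste0("f", 1:2000)
  sim <- simulate_counts(p0, ids, setNames(rep("mRNA", 2000), ids))
  x <- sim$counts$values
  expect_equal(mean(x), 100, tolerance = 0.02)
  expect_equal(var(as.numeric(x)), mean(x), tolerance = 0.1)

  # determinism: same seed, same study
  s1 <- simulate_study(small_params())
  s2 <- simulate_study(small_params())
  expect_identical(s1$counts$values, s2$counts$values)
  expect_identical(s1$utr_seqs, s2$utr_seqs)
  expect_identical(s1$truth$de_sets, s2$truth$de_sets)

  # planted DE shifts group means by exactly the recorded log2FC, and
  # non-DE (non-triad) features have identical group means
  st <- s1
  off <- st$truth$offsets
  for (cname in names(st$truth$de_sets)) {
    trt <- substr(cname, 1, 1); ref <- substr(cname, 3, 3)
    planted <- do.call(rbind, st$truth$de_sets[[cname]])
    if (!nrow(planted)) next
    delta <- off[planted$feature_id, trt] - off[planted$feature_id, ref]
    expect_equal(unname(delta), planted$sign * planted$lfc, tolerance = 1e-12)
  }
  triad_ids <- unlist(st$truth$triads[, c("lnc_id", "mirna_id", "mrna_id")])
  de_ids <- unlist(lapply(st$truth$de_sets, function(x)
    do.call(rbind, x)$feature_id))
  quiet <- setdiff(rownames(off), c(triad_ids, de_ids))
  expect_true(all(off[quiet, ] == 0))
})

test_that("mean-variance of simulated counts recovers the NB dispersion", {
  set.seed(6)
  p <- sim_params(libsize_sdlog = 0, n_reps = 12L,
                  groups = c("A", "B"), de_fraction = 0, n_triads = 0L)
  ids <- paste0("f", 1:3000)
  sim <- simulate_counts(p, ids, setNames(rep("mRNA", 3000), ids))
  x <- sim$counts$values
  m <- rowMeans(x); v <- apply(x, 1, var)
  # regression of (var - mean) on mean^2 recovers phi within 20%
  phi_hat <- sum((v - m) * m^2) / sum(m^4)
  expect_equal(phi_hat, 0.05, tolerance = 0.2)
})

test_that("triad coupling induces strong planted correlations", {
  st <- simulate_study(sim_params(n_mrna = 300L, n_lncrna = 80L,
                                  n_mirna = 40L, n_triads = 20L, seed = 21L))
  expr <- log_normalized(st$counts)$values
  tr <- st$truth$triads
  r_mm <- vapply(seq_len(nrow(tr)), function(k)
    cor(expr[tr$mirna_id[k], ], expr[tr$mrna_id[k], ]), numeric(1))
  expect_gte(mean(abs(r_mm) >= 0.8), 0.9)
  # sign structure: target triads anti-correlate, decoys co-vary
  expect_true(all(sign(r_mm[tr$role == "target"]) == -1))
  expect_true(all(sign(r_mm[tr$role == "decoy"]) == 1))
  r_lm <- vapply(seq_len(nrow(tr)), function(k)
    cor(expr[tr$lnc_id[k], ], expr[tr$mirna_id[k], ]), numeric(1))
  expect_true(all(r_lm[tr$role == "target"] < 0))
})

test_that("study files are written with headers and parse back", {
  st <- simulate_study(small_params())
  dir <- withr::local_tempdir()
  write_study(st, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "annotation.gtf", "mirna.fa", "utr.fa", "lncrna.fa", "counts.tsv",
    "groups.tsv", "qtl.bed", "truth.json", "categories.tsv")))))
  expect_match(readLines(file.path(dir, "counts.tsv"), n = 1), "^# cernet")
  recs <- read_gtf_transcripts(file.path(dir, "annotation.gtf"))
  expect_length(recs, nrow(st$features))
  back <- read_counts(file.path(dir, "counts.tsv"), st$counts$sample_group)
  expect_identical(back$values, st$counts$values)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$qtl_members), st$truth$qtl_members)
  mir <- read_fasta(file.path(dir, "mirna.fa"), "RNA")
  expect_identical(mir, st$mirna_seqs)
})
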