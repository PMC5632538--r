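two_group <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))

test_that("size factors: symmetry, hand example, equivariance, permutation", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  em <- make_expr(m, setNames(c("A", "B"), c("s1", "s2")))
  expect_equal(size_factors(em), c(s1 = 1, s2 = 1))

  m2 <- m; m2[, 2] <- 2 * m2[, 1]
  em2 <- make_expr(m2, setNames(c("A", "B"), c("s1", "s2")))
  # geometric-mean reference: ratios 1/sqrt(2) and sqrt(2), by hand
  expect_equal(size_factors(em2), c(s1 = 1 / sqrt(2), s2 = sqrt(2)))

  set.seed(41)
  m3 <- matrix(rpois(60, 50) + 1, 10, 6,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  em3 <- make_expr(m3, two_group)
  sf <- size_factors(em3)
  # scaling one sample's column by c multiplies its factor by c and divides
  # the rest by c^(1/n) (the geometric reference absorbs c^(1/n))
  c0 <- 3
  m4 <- m3; m4[, 2] <- m4[, 2] * c0
  sf2 <- size_factors(make_expr(m4, two_group))
  expect_equal(sf2[2], sf[2] * c0 * c0^(-1 / 6), tolerance = 1e-12)
  expect_equal(sf2[-2], sf[-2] * c0^(-1 / 6), tolerance = 1e-12)
  # invariant to feature permutation
  perm <- sample(nrow(m3))
  expect_equal(size_factors(make_expr(m3[perm, ], two_group)), sf)
  # error path: no all-positive row
  m5 <- m3; m5[, 1] <- 0
  expect_error(size_factors(make_expr(m5, two_group)), "pseudo-reference")
})

test_that("bh_adjust equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("nb test: null symmetry and planted strong effect", {
  m <- matrix(100, 4, 6, dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  em <- make_expr(m, two_group)
  de <- nb_test_contrast(em, contrast("B_A", "B", "A"))
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$p > 0.99))
  expect_true(all(de$direction == "ns"))
  expect_true(all(de$q >= de$p))

  # planted 8-fold change at low dispersion is detected
  set.seed(43)
  n <- 500
  mu <- rep(50, n); muB <- mu; muB[1:10] <- 400
  cnt <- cbind(matrix(rnbinom(n * 3, mu = rep(mu, 3), size = 100), n, 3),
               matrix(rnbinom(n * 3, mu = rep(muB, 3), size = 100), n, 3))
  dimnames(cnt) <- list(paste0("f", 1:n), paste0("s", 1:6))
  de2 <- nb_test_contrast(make_expr(cnt, two_group),
                          contrast("B_A", "B", "A"))
  expect_true(all(de2$q[1:10] < 0.05))
  expect_true(all(de2$direction[1:10] == "up"))
  expect_true(all(de2$log2fc[1:10] > 2))
})

test_that("expression transforms match hand arithmetic", {
  cfg <- ce_config()
  # count 100, length 1000 bp, column total 1e6 -> FPKM 100 -> log10+1 ~ 3
  m <- matrix(c(100, 1e6 - 100), 2, 1,
              dimnames = list(c("f1", "f2"), "s1"))
  em <- expression_matrix(m, c(s1 = "A"), "counts")
  tr <- transform_expression(em, c(f1 = 1000, f2 = 1000), "FPKM", cfg)
  expect_equal(tr$values["f1", "s1"], log10(100 + 0.01) + 1, tolerance = 1e-12)
  expect_equal(tr$kind, "transformed")

  set.seed(44)
  m2 <- matrix(rpois(30, 200), 5, 6,
               dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  lens <- setNames(sample(200:2000, 5), paste0("f", 1:5))
  tpm <- transform_expression(make_expr(m2, two_group), lens, "TPM", cfg)
  raw_tpm <- 10^(tpm$values - 1) - 0.01
  expect_equal(unname(colSums(raw_tpm)), rep(1e6, 6), tolerance = 1e-6)

  m2[1, ] <- 0
  tr0 <- transform_expression(make_expr(m2, two_group), lens, "FPKM", cfg)
  expect_true(all(tr0$values[1, ] == log10(0.01) + 1))
  expect_error(transform_expression(make_expr(m2, two_group),
                                    setNames(c(0, lens[-1]), names(lens)),
                                    "FPKM", cfg), "positive length")
})

test_that("complete-linkage clustering matches the O(n^3) oracle", {
  m <- matrix(c(0, 0, 0.1, 0, 5, 5, 5.12, 5, 0, 9, 0.14, 9), 2, 6,
              dimnames = list(c("f1", "f2"), paste0("s", 1:6)))
  em <- expression_matrix(m, setNames(rep("A", 6), paste0("s", 1:6)),
                          "transformed")
  got <- cluster_samples(em)
  want <- oracle_complete_linkage(m)
  expect_equal(got$merges$height, want$height, tolerance = 1e-12)
  expect_equal(got$merges$members, want$members)

  # identical samples merge at height zero
  m2 <- matrix(c(1, 2, 1, 2, 8, 9), 2, 3,
               dimnames = list(c("f1", "f2"), c("a", "b", "c")))
  em2 <- expression_matrix(m2, setNames(rep("A", 3), c("a", "b", "c")),
                           "transformed")
  got2 <- cluster_samples(em2)
  expect_equal(got2$merges$height[1], 0)
  expect_equal(got2$merges$members[1], "a,b")
  expect_match(got2$newick, "^\\(")

  # invariant to sample order
  perm <- c(4, 1, 6, 3, 2, 5)
  emp <- expression_matrix(m[, perm],
                           setNames(rep("A", 6), paste0("s", 1:6))[perm],
                           "transformed")
  expect_equal(cluster_samples(emp)$merges, got$merges)
  expect_error(cluster_samples(expression_matrix(
    m[, 1, drop = FALSE], c(s1 = "A"), "transformed")), ">= 2 samples")
})

test_that("qPCR relative quantities follow the standard-curve convention", {
  expect_equal(qpcr_relative_quantity(20, 20, -3.32), 1)
  # dCt = 3.3219, slope = -3.3219 -> 10^1 before calibration
  expect_equal(qpcr_relative_quantity(23.3219, 20, -3.3219), 10,
               tolerance = 1e-9)
  expect_error(qpcr_relative_quantity(20, 18, 0), "non-zero")
  # calibrator group averages exactly 1 after calibration
  ct_t <- c(21.1, 20.9, 21.0); ct_r <- c(20, 20, 20)
  raw <- qpcr_relative_quantity(ct_t, ct_r, -3.32)
  cal <- qpcr_relative_quantity(ct_t, ct_r, -3.32,
                                calibrator_mean = mean(raw))
  expect_equal(mean(cal), 1, tolerance = 1e-12)
})

test_that("de_all_contrasts runs per class and de_union collects hits", {
  set.seed(45)
  grp <- setNames(rep(c("V", "Q", "C", "R"), each = 3), paste0("s", 1:12))
  n <- 60
  mu <- matrix(rep(rlnorm(n, 4, 0.3), 12), n, 12)
  mu[1, grp %in% c("Q", "C", "R")] <- mu[1, 1] * 8  # DE in Q_V only
  cnt <- matrix(rnbinom(n * 12, mu = mu, size = 50), n, 12,
                dimnames = list(c(paste0("lnc_", 1:5), paste0("m_", 6:n)),
                                paste0("s", 1:12)))
  em <- expression_matrix(cnt, grp)
  cls <- setNames(c(rep("lncRNA", 5), rep("mRNA", n - 5)), rownames(cnt))
  de <- de_all_contrasts(em, cls)
  expect_named(de, c("Q_V", "C_Q", "R_C"))
  expect_named(de$Q_V, c("lncRNA", "mRNA"), ignore.order = TRUE)
  expect_equal(nrow(de$Q_V$lncRNA), 5L)
  expect_true("lnc_1" %in% de_union(de))
  expect_equal(de$Q_V$lncRNA$direction[1], "up")
})
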