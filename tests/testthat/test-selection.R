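test_that("Hudson FST matches the closed form on one SNP", {
  # pop1: 10 diploids with sample frequency 0.8; pop2: 10 at 0.2
  g1 <- c(rep(2L, 6), rep(1L, 4))     # 16/20 alleles derived
  g2 <- c(rep(0L, 6), rep(1L, 4))     # 4/20
  d <- make_toy_dataset(matrix(c(g1, g2), 1, 20),
                        populations = rep(c("p1", "p2"), each = 10))
  f <- pairwise_fst(d, "p1", "p2")
  num <- (0.8 - 0.2)^2 - 0.8 * 0.2 / 19 - 0.2 * 0.8 / 19
  den <- 0.8 * (1 - 0.2) + 0.2 * (1 - 0.8)
  expect_equal(f$fst, num / den, tolerance = 1e-12)
  expect_equal(f$fst, 0.5046439628, tolerance = 1e-9)
  expect_equal(f$n_snps, 1L)
})

test_that("FST handles fixed differences, monomorphic sites and missing data", {
  # fixed difference -> FST = 1
  d1 <- make_toy_dataset(matrix(c(2L, 2L, 0L, 0L), 1, 4),
                         populations = c("p1", "p1", "p2", "p2"))
  expect_equal(pairwise_fst(d1, "p1", "p2")$fst, 1)
  # identical frequencies across many SNPs -> clamped at 0
  set.seed(1)
  g <- matrix(rbinom(200 * 8, 2, 0.5), 200, 8)
  g <- cbind(g, g)  # both populations identical sample counts
  d2 <- make_toy_dataset(g, populations = rep(c("p1", "p2"), each = 8))
  expect_equal(pairwise_fst(d2, "p1", "p2")$fst, 0)
  # cross-monomorphic sites are excluded from the SNP count
  d3 <- make_toy_dataset(rbind(c(0L, 0L, 0L, 0L), c(2L, 1L, 0L, 0L)),
                         populations = c("p1", "p1", "p2", "p2"))
  expect_equal(pairwise_fst(d3, "p1", "p2")$n_snps, 1L)
  # a population with < 2 called alleles at every site yields no data
  d4 <- make_toy_dataset(matrix(c(1L, NA), 1, 2),
                         populations = c("p1", "p2"))
  r <- pairwise_fst(d4, "p1", "p2")
  expect_true(r$no_data)
  expect_true(is.na(r$fst))
  expect_error(pairwise_fst(d4, "p1", "zz"), "empty population")
})

test_that("Weir-Cockerham estimator agrees with Hudson at large balanced sizes", {
  set.seed(4)
  n <- 3000
  p1 <- rbeta(n, 2, 2)
  p2 <- rbeta(n, 2, 2)
  g <- cbind(matrix(rbinom(n * 40, 2, p1), n, 40),
             matrix(rbinom(n * 40, 2, p2), n, 40))
  d <- make_toy_dataset(g, populations = rep(c("p1", "p2"), each = 40),
                        pos = seq_len(n) * 100L)
  fh <- pairwise_fst(d, "p1", "p2", estimator = "hudson")$fst
  fw <- pairwise_fst(d, "p1", "p2", estimator = "wc")$fst
  expect_lt(abs(fh - fw), 0.02)
})

test_that("PBS matches the closed form and propagates saturated branches", {
  p <- pbs(0.5, 0.5, 0.1)
  t_half <- -log(0.5)
  t_bc <- -log(0.9)
  expect_equal(p$pbs_a, (2 * t_half - t_bc) / 2, tolerance = 1e-12)
  expect_equal(p$pbs_a, 0.6404669, tolerance = 1e-6)
  expect_equal(p$pbs_b, t_bc / 2, tolerance = 1e-12)
  expect_equal(p$pbs_c, t_bc / 2, tolerance = 1e-12)
  # FST = 0 everywhere -> all branches zero
  expect_equal(unlist(pbs(0, 0, 0)), c(pbs_a = 0, pbs_b = 0, pbs_c = 0))
  # a saturated A-B pair lengthens both its branches and shortens C's
  p1 <- pbs(1, 0.5, 0.5)
  expect_equal(p1$pbs_a, Inf)
  expect_equal(p1$pbs_b, Inf)
  expect_equal(p1$pbs_c, -Inf)
  # two saturated pairs leave the shared focal branch infinite
  p2 <- pbs(1, 1, 0.5)
  expect_equal(p2$pbs_a, Inf)
  expect_error(pbs(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(pbs(-0.1, 0.5, 0.5), "\\[0, 1\\]")
  # negative branches are kept unless floored
  pn <- pbs(0.05, 0.05, 0.6)
  expect_lt(pn$pbs_a, 0)
  expect_equal(pbs(0.05, 0.05, 0.6, floor_zero = TRUE)$pbs_a, 0)
})

test_that("PBS branch lengths satisfy the three-branch identity", {
  set.seed(6)
  f <- matrix(runif(3 * 2000, 0, 0.99), ncol = 3)
  p <- pbs(f[, 1], f[, 2], f[, 3])
  total <- (-log(1 - f[, 1]) - log(1 - f[, 2]) - log(1 - f[, 3])) / 2
  expect_equal(p$pbs_a + p$pbs_b + p$pbs_c, total, tolerance = 1e-12)
})

test_that("pbs_scan is invariant to population order up to relabeling", {
  scan_sim <- simulate_selection_scan(n_genes = 30, snps_per_gene = 25,
                                      n_per_pop = 6, seed = 11)
  s1 <- pbs_scan(scan_sim$data, genes = scan_sim$genes,
                 populations = c("popA", "popB", "popC"))
  s2 <- pbs_scan(scan_sim$data, genes = scan_sim$genes,
                 populations = c("popC", "popA", "popB"))
  expect_equal(s1$pbs_popA, s2$pbs_popA, tolerance = 1e-12)
  expect_equal(s1$pbs_popB, s2$pbs_popB, tolerance = 1e-12)
  expect_equal(s1$pbs_popC, s2$pbs_popC, tolerance = 1e-12)
  # gene intervals derived from site annotation give the same scan
  s3 <- pbs_scan(scan_sim$data, genes = NULL,
                 populations = c("popA", "popB", "popC"))
  s3 <- s3[match(s1$gene, s3$gene), ]
  expect_equal(s1$pbs_popA, s3$pbs_popA, tolerance = 1e-12)
})

test_that("cap_and_call replaces infinities and calls outliers", {
  scan <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    n_snps = c(5L, 5L, 5L, 0L),
    fst_ab = c(0.5, 1, 1, NA), fst_ac = c(0.5, 1, 0.2, NA),
    fst_bc = c(0.1, 1, 0.2, NA),
    pbs_a = c(0.64, Inf, 3.5, NA), pbs_b = c(0.05, Inf, -Inf, NA),
    pbs_c = c(0.05, Inf, 0.2, NA),
    no_data = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE
  )
  names(scan)[6:8] <- c("pbs_pA", "pbs_pB", "pbs_pC")
  attr(scan, "populations") <- c("pA", "pB", "pC")
  r <- cap_and_call(scan, threshold = 3)
  # +Inf capped to the max finite value per population
  expect_equal(r$scan$pbs_pA[2], 3.5)
  # -Inf capped to the min finite value
  expect_equal(r$scan$pbs_pB[3], 0.05)
  expect_equal(r$infinite_replaced[["pA"]], 1L)
  expect_equal(r$infinite_replaced[["pB"]], 2L)
  # outliers are genes strictly above the threshold after capping
  expect_setequal(r$outliers$pA, c("g2", "g3"))
  expect_equal(r$outliers$pB, character(0))
  # g3 outlies only in pA; g2 was capped to 3.5 > 3 in pA alone
  expect_setequal(r$unique_outliers$pA, c("g2", "g3"))
  expect_equal(r$fst_one_genes, "g2")
  # the reported percentile is a quantile of the capped distribution
  expect_equal(r$percentile_value[["pA"]],
               stats::quantile(c(0.64, 3.5, 3.5), 0.998, type = 7,
                               names = FALSE))
  bad <- scan
  bad$pbs_pA <- c(Inf, Inf, Inf, NA)
  expect_error(cap_and_call(bad), "all PBS values infinite")
})

test_that("missense_summary follows presence/exclusive/fixed rules", {
  # three populations, one sample each (two alleles)
  geno <- rbind(c(2L, 0L, 0L),   # fixed in pA, absent elsewhere (gene g1)
                c(2L, 2L, 2L),   # fixed everywhere -> excluded (gene g2)
                c(1L, 1L, 0L),   # shared pA+pB (gene g3)
                c(0L, 0L, 1L))   # only pC (gene g3)
  d <- make_toy_dataset(geno, effect = "missense",
                        gene = c("g1", "g2", "g3", "g3"),
                        populations = c("pA", "pB", "pC"))
  ms <- missense_summary(d)
  a <- ms[ms$population == "pA", ]
  expect_equal(a$n_genes_missense, 2L)       # g1, g3
  expect_equal(a$n_genes_exclusive, 1L)      # g1
  expect_equal(a$n_genes_fixed, 1L)          # g1
  expect_equal(a$n_genes_exclusive_fixed, 1L)
  c_ <- ms[ms$population == "pC", ]
  expect_equal(c_$n_genes_missense, 1L)      # g3
  expect_equal(c_$n_genes_exclusive, 0L)     # g3 also present in pA/pB
  d_no <- make_toy_dataset(matrix(1L, 2, 3), effect = "synonymous",
                           gene = "g1", populations = c("pA", "pB", "pC"))
  expect_error(missense_summary(d_no), "no annotated missense")
})
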