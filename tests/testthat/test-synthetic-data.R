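test_that("simulation_config validates its inputs", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(coding_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(
    effect_probs = c(synonymous = 0.5, missense = 0.4, lof = 0.2)),
    "sum to 1")
  expect_error(simulation_config(
    gerp_mixture = c(constrained = 0.5, intermediate = 0.5, neutral = 0.5)),
    "sum to 1")
  expect_error({
    cfg <- simulation_config()
    cfg$populations$fst <- c(1, 0.1, 0.1)
    validate_simulation_config <- erodr:::validate_simulation_config
    validate_simulation_config(cfg)
  }, "fst")
  expect_error(simulation_config(n_sites = 1e9), "exceeds genome length")
  expect_error(simulation_config(
    scaffolds = data.frame(name = "s1", length = 1e6), n_sites = 100),
    "longest scaffold")
})

test_that("the generator is deterministic given the config", {
  cfg <- small_sim_config(seed = 7, n_sites = 800)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$data$geno, b$data$geno)
  expect_identical(a$data$sites, b$data$sites)
  expect_identical(a$truth$tracts, b$truth$tracts)
  expect_identical(a$truth$freq, b$truth$freq)
})

test_that("simulated dataset has the configured shape and valid contents", {
  cfg <- small_sim_config(seed = 2, n_sites = 1500)
  sim <- simulate_dataset(cfg)
  d <- sim$data
  expect_s3_class(d, "variant_dataset")
  expect_equal(nrow(d$sites), 1500)
  expect_equal(nrow(d$samples), sum(cfg$populations$n_modern) +
                 sum(cfg$populations$n_historical))
  expect_true(all(d$geno %in% c(0L, 1L, 2L)))
  # truth frequencies cover every population
  expect_setequal(colnames(sim$truth$freq), cfg$populations$name)
  # deleterious truth labels agree with the emitted scores
  expect_equal(sim$truth$site_labels$deleterious,
               !is.na(d$sites$gerp) & d$sites$gerp > 4)
  # sites inside no gene have effect "none"
  expect_true(all(d$sites$effect[is.na(d$sites$gene)] == "none"))
  # ancestral allele is always REF or ALT for SNPs
  snp <- !d$sites$is_indel
  expect_true(all(d$sites$aa[snp] == d$sites$ref[snp] |
                    d$sites$aa[snp] == d$sites$alt[snp]))
})

test_that("zero inbreeding targets plant no tracts", {
  cfg <- small_sim_config(seed = 3, n_sites = 500)
  cfg$populations$f_modern <- 0
  cfg$populations$f_historical <- 0
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth$tracts), 0)
  expect_true(all(sim$truth$true_f$f == 0))
})

test_that("planted tracts are non-overlapping and truth F matches them", {
  cfg <- small_sim_config(seed = 4, n_sites = 500)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$tracts
  expect_gt(nrow(tr), 0)
  for (sid in unique(tr$sample)) {
    x <- tr[tr$sample == sid, ]
    x <- x[order(x$scaffold, x$start), ]
    for (sc in unique(x$scaffold)) {
      y <- x[x$scaffold == sc, ]
      if (nrow(y) > 1) expect_true(all(y$start[-1] > y$end[-nrow(y)]))
    }
    planted <- sum(x$end - x$start + 1) / 8e6
    expect_equal(sim$truth$true_f$f[sim$truth$true_f$sample == sid], planted)
  }
  # planted fraction is close to (and never above) the requested target
  f_target <- ifelse(sim$data$samples$era == "modern",
    cfg$populations$f_modern[match(sim$data$samples$population,
                                   cfg$populations$name)],
    cfg$populations$f_historical[match(sim$data$samples$population,
                                       cfg$populations$name)])
  # placement is best-effort on a tiny fragmented genome: never above the
  # target, and close to it on average (truth records the planted value)
  expect_true(all(sim$truth$true_f$f <= f_target + 1e-12))
  expect_lt(mean(f_target - sim$truth$true_f$f), 0.05)
})

test_that("plant_roh forces homozygosity inside tracts and nowhere else", {
  set.seed(11)
  n <- 400
  sites <- data.frame(scaffold = "s1", pos = sort(sample.int(1e6, n)))
  geno <- matrix(1L, n, 2, dimnames = list(NULL, c("a", "b")))
  tracts <- data.frame(sample = "a", scaffold = "s1",
                       start = 2e5, end = 6e5)
  out <- plant_roh(geno, sites, tracts, freq = rep(0.5, n))
  inside <- sites$pos >= 2e5 & sites$pos <= 6e5
  expect_true(all(out[inside, "a"] %in% c(0L, 2L)))
  expect_identical(out[!inside, "a"], geno[!inside, "a"])
  expect_identical(out[, "b"], geno[, "b"])
  # frequency 1 makes every tract genotype homozygous derived
  out1 <- plant_roh(geno, sites, tracts, freq = rep(1, n))
  expect_true(all(out1[inside, "a"] == 2L))
  # empty tract table is a no-op
  expect_identical(plant_roh(geno, sites, tracts[0, ], rep(0.5, n)), geno)
})

test_that("plant_roh rejects invalid tracts", {
  sites <- data.frame(scaffold = "s1", pos = c(10L, 20L))
  geno <- matrix(1L, 2, 1, dimnames = list(NULL, "a"))
  contigs <- data.frame(name = "s1", length = 1000)
  expect_error(plant_roh(geno, sites,
                         data.frame(sample = "a", scaffold = "s1",
                                    start = 5, end = 2000),
                         rep(0.5, 2), contigs), "bounds")
  expect_error(plant_roh(geno, sites,
                         data.frame(sample = "a", scaffold = "s1",
                                    start = c(1, 50), end = c(100, 60)),
                         rep(0.5, 2)), "overlapping")
  expect_error(plant_roh(geno, sites,
                         data.frame(sample = "zz", scaffold = "s1",
                                    start = 1, end = 10),
                         rep(0.5, 2)), "unknown sample")
})

test_that("Balding-Nichols divergence yields the expected Hudson FST", {
  # two populations each drifted F from a shared ancestor have expected
  # Hudson FST equal to F; check the mean estimate over seeds
  fst_hat <- vapply(1:6, function(s) {
    cfg <- simulation_config(
      seed = s,
      scaffolds = data.frame(name = "s1", length = 1e8),
      populations = data.frame(
        name = c("p1", "p2"), n_modern = c(25L, 25L),
        n_historical = c(0L, 0L), fst = c(0.1, 0.1),
        f_modern = c(0, 0), f_historical = c(0, 0)),
      n_sites = 20000L, n_genes = 0L, indel_fraction = 0,
      aa_flip_fraction = 0)
    sim <- simulate_dataset(cfg)
    pairwise_fst(sim$data, "p1", "p2")$fst
  }, numeric(1))
  expect_lt(abs(mean(fst_hat) - 0.1), 0.02)
})

test_that("simulated population frequencies are recoverable from genotypes", {
  cfg <- simulation_config(
    seed = 5,
    scaffolds = data.frame(name = "s1", length = 1e7),
    populations = data.frame(
      name = "p1", n_modern = 100L, n_historical = 0L, fst = 0.1,
      f_modern = 0, f_historical = 0),
    n_sites = 2000L, n_genes = 0L, indel_fraction = 0,
    aa_flip_fraction = 0)
  sim <- simulate_dataset(cfg)
  af <- rowMeans(sim$data$geno) / 2
  # sample frequency tracks the truth within binomial noise at n = 200
  err <- af - sim$truth$freq[, "p1"]
  expect_lt(mean(abs(err)), 0.03)
  expect_lt(stats::quantile(abs(err), 0.99), 0.1)
})

test_that("selection-scan generator plants exactly one drifted gene", {
  scan_sim <- simulate_selection_scan(n_genes = 20, snps_per_gene = 20,
                                      n_per_pop = 8, seed = 3)
  expect_true(scan_sim$selected_gene %in% scan_sim$genes$gene)
  expect_equal(nrow(scan_sim$genes), 20)
  expect_equal(nrow(scan_sim$data$sites), 400)
  expect_equal(unique(scan_sim$data$samples$population),
               c("popA", "popB", "popC"))
  again <- simulate_selection_scan(n_genes = 20, snps_per_gene = 20,
                                   n_per_pop = 8, seed = 3)
  expect_identical(scan_sim$data$geno, again$data$geno)
  expect_identical(scan_sim$selected_gene, again$selected_gene)
})
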