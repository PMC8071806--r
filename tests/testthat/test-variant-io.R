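tiny_bundle_config <- function(seed = 1) {
  simulation_config(
    seed = seed,
    scaffolds = data.frame(name = c("s1", "s2"), length = c(2e5, 2e5)),
    populations = data.frame(
      name = c("pA", "pB"), n_modern = c(3L, 2L), n_historical = c(0L, 1L),
      fst = c(0.1, 0.1), f_modern = c(0.2, 0.2), f_historical = c(0, 0.1)),
    n_sites = 300L, n_genes = 10L,
    roh_lengths = list(short = c(1e4, 3e4), long = c(4e4, 1e5),
                       p_short = 0.6),
    repeat_fraction = 0.05
  )
}

test_that("CpG masking finds every CG dinucleotide and nothing else", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AATTAA", chr2 = "ACGTCG",
                                    chr3 = "CGCG"))
  m <- find_cpg_sites(ref)
  iv <- m$intervals
  expect_false("chr1" %in% iv$scaffold)
  expect_equal(iv$start[iv$scaffold == "chr2"], c(2L, 5L))
  expect_equal(iv$end[iv$scaffold == "chr2"], c(3L, 6L))
  expect_equal(iv$start[iv$scaffold == "chr3"], c(1L, 3L))
  expect_equal(iv$end[iv$scaffold == "chr3"], c(2L, 4L))
})

test_that("BED masks convert 0-based half-open to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("s1\t99\t200\ns2\t0\t10", path)
  m <- read_bed_mask(path)
  expect_equal(m$intervals$start, c(100L, 1L))
  expect_equal(m$intervals$end, c(200L, 10L))
  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_bed_mask(empty)$intervals), 0)
})

test_that("combine_masks unions intervals and excluded scaffolds", {
  m1 <- site_mask(data.frame(scaffold = "s1", start = 1, end = 10),
                  exclude_scaffolds = "sexX")
  m2 <- site_mask(data.frame(scaffold = "s2", start = 5, end = 6),
                  exclude_scaffolds = c("sexX", "sexY"))
  m <- combine_masks(m1, m2)
  expect_equal(nrow(m$intervals), 2)
  expect_setequal(m$exclude_scaffolds, c("sexX", "sexY"))
})

test_that("SNPs within 5 bp of an indel are removed, inclusive boundary", {
  # indel at 105: SNP at 100 lies exactly 5 bp away -> removed
  d1 <- make_toy_dataset(matrix(1L, 2, 1), pos = c(100L, 105L),
                         is_indel = c(FALSE, TRUE))
  f1 <- apply_site_filters(d1)
  expect_equal(nrow(f1$sites), 0)
  lg <- filter_log(f1)
  expect_equal(lg$n_removed[lg$rule == "snps_near_indel"], 1L)
  expect_equal(lg$n_removed[lg$rule == "indel_records"], 1L)
  # indel at 106: SNP at 100 lies 6 bp away -> retained
  d2 <- make_toy_dataset(matrix(1L, 2, 1), pos = c(100L, 106L),
                         is_indel = c(FALSE, TRUE))
  f2 <- apply_site_filters(d2)
  expect_equal(f2$sites$pos, 100L)
  expect_false(any(f2$sites$is_indel))
  # the window is symmetric: SNP downstream of the indel at 5 bp -> removed
  d3 <- make_toy_dataset(matrix(1L, 2, 1), pos = c(100L, 105L),
                         is_indel = c(TRUE, FALSE))
  expect_equal(nrow(apply_site_filters(d3)$sites), 0)
})

test_that("low-depth and low-quality genotypes are set missing", {
  geno <- matrix(c(1L, 1L, 1L, 1L), 2, 2)
  dp <- matrix(c(5, 20, 20, 20), 2, 2)   # 5 < 18/3 for sample 1, site 1
  gq <- matrix(c(99, 99, 29, 30), 2, 2)  # 29 < 30 for sample 2, site 1
  d <- make_toy_dataset(geno, mean_coverage = 18, dp = dp, gq = gq)
  f <- apply_site_filters(d)
  expect_true(is.na(f$geno[1, 1]))
  expect_true(is.na(f$geno[1, 2]))
  expect_equal(f$geno[2, ], c(smp01 = 1L, smp02 = 1L))
  lg <- filter_log(f)
  expect_equal(lg$n_removed[lg$rule == "genotypes_low_depth"], 1L)
  expect_equal(lg$n_removed[lg$rule == "genotypes_low_quality"], 1L)
  # depth filtering without mean coverage is an explicit error
  d_bad <- d
  d_bad$samples$mean_coverage <- NA_real_
  expect_error(apply_site_filters(d_bad), "mean_coverage missing")
})

test_that("masked intervals and excluded scaffolds are removed", {
  geno <- matrix(1L, 6, 1)
  d <- make_toy_dataset(geno, pos = c(10L, 20L, 30L, 10L, 20L, 30L),
                        scaffold = rep(c("s1", "s2"), each = 3),
                        contig_length = c(1000, 1000))
  m <- site_mask(intervals = data.frame(scaffold = "s1", start = 15,
                                        end = 25),
                 exclude_scaffolds = "s2")
  f <- apply_site_filters(d, mask = m)
  expect_equal(f$sites$pos, c(10L, 30L))
  expect_equal(unique(f$sites$scaffold), "s1")
  expect_equal(f$contigs$name, "s1")
  lg <- filter_log(f)
  expect_equal(lg$n_removed[lg$rule == "masked_positions"], 1L)
  expect_equal(lg$n_removed[lg$rule == "excluded_scaffold_sites"], 3L)
})

test_that("filtering is idempotent and order-preserving", {
  sim <- simulate_dataset(small_sim_config(seed = 9, n_sites = 1200))
  m <- site_mask(intervals = data.frame(scaffold = "s1", start = 1e5,
                                        end = 3e5))
  f1 <- apply_site_filters(sim$data, mask = m)
  f2 <- apply_site_filters(f1, mask = m)
  expect_identical(f1$sites, f2$sites)
  expect_identical(f1$geno, f2$geno)
  expect_equal(sum(filter_log(f2)$n_removed), 0)
  # retained sites appear in their original relative order
  key_in <- paste(sim$data$sites$scaffold, sim$data$sites$pos)
  key_out <- paste(f1$sites$scaffold, f1$sites$pos)
  expect_identical(key_out, key_in[key_in %in% key_out])
})

test_that("VCF round trip preserves genotypes and annotations", {
  sim <- simulate_dataset(small_sim_config(seed = 5, n_sites = 600))
  path <- withr::local_tempfile(fileext = ".vcf.gz")
  write_vcf(sim$data, path)
  back <- read_vcf(path, metadata = sim$data$samples)
  expect_identical(back$geno, sim$data$geno)
  expect_identical(back$sites$scaffold, sim$data$sites$scaffold)
  expect_identical(back$sites$pos, as.integer(sim$data$sites$pos))
  expect_identical(back$sites$aa, sim$data$sites$aa)
  expect_identical(back$sites$effect, sim$data$sites$effect)
  expect_identical(back$sites$gene, sim$data$sites$gene)
  expect_identical(back$sites$is_indel, sim$data$sites$is_indel)
  expect_equal(back$sites$gerp, sim$data$sites$gerp, tolerance = 1e-5)
  expect_identical(back$contigs$name, sim$data$contigs$name)
  expect_equal(back$contigs$length, sim$data$contigs$length)
  expect_identical(back$samples$population, sim$data$samples$population)
  # DP survives the round trip
  expect_equal(back$dp, sim$data$dp, ignore_attr = TRUE)
})

test_that("multiallelic records are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=s1,length=1000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "s1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "s1\t20\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/0",
    "s1\t30\t.\tA\tC\t.\tPASS\t.\tGT\t1/1\t./."
  ), path)
  expect_warning(d <- read_vcf(path), "multiallelic")
  expect_equal(d$sites$pos, c(10L, 30L))
  expect_equal(unname(d$geno[, "a"]), c(1L, 2L))
  expect_true(is.na(d$geno[2, "b"]))
})

test_that("the dataset bundle round-trips through its files", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(tiny_bundle_config(), out_dir = dir)
  expect_true(all(file.exists(sim$files)))
  # reference carries the REF alleles at the variant positions
  ref <- Biostrings::readDNAStringSet(sim$files["reference"])
  i <- which(sim$data$sites$scaffold == "s1")[1]
  expect_equal(
    as.character(Biostrings::subseq(ref[["s1"]], sim$data$sites$pos[i],
                                    sim$data$sites$pos[i])),
    substr(sim$data$sites$ref[i], 1, 1))
  # VCF + metadata reproduce the dataset
  back <- read_vcf(sim$files["vcf"], metadata = sim$files["samples"])
  expect_identical(back$geno, sim$data$geno)
  expect_identical(back$samples$era, sim$data$samples$era)
  # gene BED round trip
  genes <- read_gene_bed(sim$files["genes"])
  expect_equal(genes$gene, sim$truth$genes$gene)
  expect_equal(genes$start, sim$truth$genes$start)
  expect_equal(genes$end, sim$truth$genes$end)
  # repeat BED as a mask
  rep_mask <- read_bed_mask(sim$files["repeats"])
  expect_equal(rep_mask$intervals$start, sim$truth$repeats$start)
  # GERP track re-attaches identically (within formatting precision)
  track <- read_gerp_track(sim$files["gerp"])
  stripped <- sim$data
  stripped$sites$gerp <- NA_real_
  re <- attach_gerp(stripped, track)
  expect_equal(re$sites$gerp, sim$data$sites$gerp, tolerance = 1e-5)
})
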