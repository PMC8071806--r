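#' Configuration for the synthetic dataset generator
#'
#' Describes a three-population study design with two sampling eras, planted
#' identity-by-descent (ROH) tracts, Balding-Nichols population divergence,
#' a mixture of conservation-score classes and gene-localized effect
#' categories. Defaults emulate a small, structured rhinoceros-like study:
#' three diverged populations sampled in two eras (19 genomes), coverage
#' 9-29X, and per-group inbreeding targets that rise sharply in the
#' most recently collapsed population.
#'
#' @param seed integer seed; the generator is fully deterministic given the
#'   config and seed.
#' @param scaffolds data.frame (`name`, `length` in bp).
#' @param populations data.frame with one row per population: `name`,
#'   `n_modern`, `n_historical`, `fst` (Balding-Nichols drift in `[0,1)`),
#'   `f_modern`, `f_historical` (target fraction of the genome planted in
#'   ROH tracts for samples of that group, in `[0,1]`).
#' @param beta_shape shape of the symmetric Beta ancestral frequency
#'   distribution over (0,1).
#' @param n_sites total number of variant sites.
#' @param roh_lengths tract-length mixture: list with `short` and `long`
#'   uniform ranges (bp) and `p_short`, covering 100 kb - 10 Mb.
#' @param gerp_mixture named proportions of sites in the `constrained`
#'   (score > 4), `intermediate` and `neutral` (score < 1) classes.
#' @param gerp_ranges uniform score range per class.
#' @param coding_fraction expected fraction of sites inside genes.
#' @param effect_probs per-category probabilities (`synonymous`, `missense`,
#'   `lof`) for sites inside genes; must sum to 1.
#' @param n_genes number of gene models.
#' @param indel_fraction fraction of sites emitted as length-2 indel records
#'   (to exercise the indel-proximity filter).
#' @param coverage_range per-sample mean coverage interval (X).
#' @param missing_rate per-genotype missing probability.
#' @param aa_flip_fraction fraction of SNPs whose ancestral allele is the ALT
#'   allele (exercises polarization).
#' @param aa_missing_fraction fraction of SNPs with unknown ancestral allele.
#' @param repeat_fraction fraction of the genome covered by the emitted
#'   repeat mask (0 disables).
#'
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    scaffolds = data.frame(name = sprintf("scaf%02d", 1:5),
                           length = rep(1e7, 5)),
    populations = data.frame(
      name = c("sumatra", "borneo", "malay_peninsula"),
      n_modern = c(8L, 4L, 3L),
      n_historical = c(0L, 1L, 3L),
      fst = c(0.15, 0.15, 0.15),
      f_modern = c(0.30, 0.28, 0.65),
      f_historical = c(0, 0.25, 0.44)
    ),
    beta_shape = 0.5,
    n_sites = 25000L,
    roh_lengths = list(short = c(1e5, 5e5), long = c(1e6, 5e6),
                       p_short = 0.6),
    gerp_mixture = c(constrained = 0.2, intermediate = 0.2, neutral = 0.6),
    gerp_ranges = list(constrained = c(4, 6), intermediate = c(1, 4),
                       neutral = c(-3, 1)),
    coding_fraction = 0.3,
    effect_probs = c(synonymous = 0.5, missense = 0.4, lof = 0.1),
    n_genes = 200L,
    indel_fraction = 0.02,
    coverage_range = c(9, 29),
    missing_rate = 0,
    aa_flip_fraction = 0.1,
    aa_missing_fraction = 0,
    repeat_fraction = 0) {
  cfg <- structure(
    list(seed = as.integer(seed), scaffolds = scaffolds,
         populations = populations, beta_shape = beta_shape,
         n_sites = as.integer(n_sites), roh_lengths = roh_lengths,
         gerp_mixture = gerp_mixture, gerp_ranges = gerp_ranges,
         coding_fraction = coding_fraction, effect_probs = effect_probs,
         n_genes = as.integer(n_genes), indel_fraction = indel_fraction,
         coverage_range = coverage_range, missing_rate = missing_rate,
         aa_flip_fraction = aa_flip_fraction,
         aa_missing_fraction = aa_missing_fraction,
         repeat_fraction = repeat_fraction),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  p <- cfg$populations
  probs <- c(cfg$gerp_mixture, cfg$effect_probs, cfg$coding_fraction,
             cfg$indel_fraction, cfg$missing_rate, cfg$aa_flip_fraction,
             cfg$aa_missing_fraction, cfg$repeat_fraction,
             cfg$roh_lengths$p_short, p$f_modern, p$f_historical)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$gerp_mixture) - 1) > 1e-8) {
    stop("gerp_mixture proportions must sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$effect_probs) - 1) > 1e-8) {
    stop("effect_probs must sum to 1", call. = FALSE)
  }
  if (any(p$fst < 0 | p$fst >= 1)) {
    stop("population fst must be in [0, 1)", call. = FALSE)
  }
  if (cfg$n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  glen <- sum(as.numeric(cfg$scaffolds$length))
  if (cfg$n_sites > glen) {
    stop("n_sites (", cfg$n_sites, ") exceeds genome length (", glen, ")",
         call. = FALSE)
  }
  max_tract <- max(cfg$roh_lengths$short[2], cfg$roh_lengths$long[2])
  if (max_tract > max(cfg$scaffolds$length)) {
    stop("maximum ROH tract length (", max_tract,
         ") exceeds the longest scaffold", call. = FALSE)
  }
  invisible(cfg)
}

# Balding-Nichols draw: population frequency with mean p and variance
# fst * p * (1 - p)
balding_nichols <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

# sample one tract length from the configured mixture
draw_tract_length <- function(mix) {
  if (stats::runif(1) < mix$p_short) {
    round(stats::runif(1, mix$short[1], mix$short[2]))
  } else {
    round(stats::runif(1, mix$long[1], mix$long[2]))
  }
}

# place non-overlapping tracts totalling ~ target_f * genome length, using
# gap bookkeeping so placement cannot fail while a fitting gap exists
draw_tracts <- function(target_f, scaffolds, mix, min_length = 1e5) {
  glen <- sum(as.numeric(scaffolds$length))
  target_bp <- round(target_f * glen)
  free <- data.frame(scaffold = scaffolds$name, start = 1,
                     end = as.numeric(scaffolds$length),
                     stringsAsFactors = FALSE)
  out <- vector("list", 64L)
  n_out <- 0L
  placed <- 0
  while (placed < target_bp) {
    len <- min(draw_tract_length(mix), target_bp - placed)
    if (len < min_length) break
    gap_len <- free$end - free$start + 1
    cand <- which(gap_len >= len)
    if (!length(cand)) break
    slack <- gap_len[cand] - len + 1
    i <- cand[sample.int(length(cand), 1L, prob = slack)]
    start <- free$start[i] + sample.int(gap_len[i] - len + 1, 1L) - 1
    end <- start + len - 1
    n_out <- n_out + 1L
    out[[n_out]] <- data.frame(scaffold = free$scaffold[i], start = start,
                               end = end, stringsAsFactors = FALSE)
    # split the consumed gap
    left <- right <- NULL
    if (start > free$start[i]) {
      left <- data.frame(scaffold = free$scaffold[i], start = free$start[i],
                         end = start - 1, stringsAsFactors = FALSE)
    }
    if (end < free$end[i]) {
      right <- data.frame(scaffold = free$scaffold[i], start = end + 1,
                          end = free$end[i], stringsAsFactors = FALSE)
    }
    free <- rbind(free[-i, , drop = FALSE], left, right)
    placed <- placed + len
  }
  if (n_out == 0L) {
    return(data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out[seq_len(n_out)])
}

#' Overwrite genotypes inside planted ROH tracts with homozygous calls
#'
#' Inside each tract all of a sample's sites become homozygous: homozygous
#' derived with probability equal to the site's population derived-allele
#' frequency, homozygous ancestral otherwise (this is what identity by
#' descent of the two haplotypes produces under random mating). Sites outside
#' tracts are untouched.
#'
#' @param geno integer matrix of derived dosage (sites x samples).
#' @param sites data.frame with `scaffold` and `pos` for the matrix rows.
#' @param tracts data.frame (`sample`, `scaffold`, `start`, `end`), 1-based
#'   inclusive; must be non-overlapping per sample.
#' @param freq per-site derived-allele frequency: either a single vector
#'   (recycled across samples) or a matrix with one column per sample
#'   (named as in `colnames(geno)`).
#' @param contigs optional contig table used to check tract bounds.
#' @return the genotype matrix with tract sites overwritten.
#' @export
plant_roh <- function(geno, sites, tracts, freq, contigs = NULL) {
  if (nrow(tracts) == 0L) return(geno)
  if (!is.null(contigs)) {
    lens <- contigs$length[match(tracts$scaffold, contigs$name)]
    if (anyNA(lens) || any(tracts$start < 1) || any(tracts$end > lens)) {
      stop("tract outside scaffold bounds", call. = FALSE)
    }
  }
  if (any(tracts$end < tracts$start)) stop("tract end < start", call. = FALSE)
  for (sid in unique(tracts$sample)) {
    tr <- tracts[tracts$sample == sid, , drop = FALSE]
    tr <- tr[order(tr$scaffold, tr$start), , drop = FALSE]
    by_scaf <- split(tr, tr$scaffold)
    if (any(vapply(by_scaf, function(d) {
      nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])
    }, logical(1)))) {
      stop("overlapping tracts for sample ", sid, call. = FALSE)
    }
    j <- match(sid, colnames(geno))
    if (is.na(j)) stop("unknown sample id: ", sid, call. = FALSE)
    q <- if (is.matrix(freq)) freq[, sid] else freq
    for (k in seq_len(nrow(tr))) {
      in_tract <- sites$scaffold == tr$scaffold[k] &
        sites$pos >= tr$start[k] & sites$pos <= tr$end[k]
      n_in <- sum(in_tract)
      if (n_in) {
        geno[in_tract, j] <-
          2L * stats::rbinom(n_in, 1L, q[in_tract])
      }
    }
  }
  geno
}

#' Simulate a complete multi-population variant dataset with known truth
#'
#' Draws ancestral allele frequencies from a symmetric Beta, per-population
#' frequencies from the Balding-Nichols model, genotypes binomially, then
#' plants per-sample ROH tracts (drawn from the configured length mixture
#' until each sample's target inbreeding fraction is reached) by overwriting
#' tract genotypes with homozygous calls. Per-site GERP scores, gene
#' intervals and effect categories, indel records, polarization flips and
#' per-genotype depth are attached. Deterministic given `config` (which
#' carries the seed).
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, the file bundle (reference
#'   FASTA, VCF, BED/TSV sidecars and truth tables) is written via
#'   [write_dataset_bundle()].
#' @return list with elements `data` (a [variant_dataset()]), `truth`
#'   (class `synthetic_truth`: planted tracts, true per-sample F, true
#'   per-population derived frequencies, per-site deleteriousness labels and
#'   the gene/repeat interval tables) and `files` (paths, when written).
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  validate_simulation_config(config)
  set.seed(config$seed)
  scaf <- config$scaffolds
  glen <- sum(as.numeric(scaf$length))
  n <- config$n_sites

  # --- samples -------------------------------------------------------------
  pops <- config$populations
  rows <- list()
  for (i in seq_len(nrow(pops))) {
    for (era in c("modern", "historical")) {
      k <- if (era == "modern") pops$n_modern[i] else pops$n_historical[i]
      if (k > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_%s_%02d", pops$name[i], substr(era, 1, 3),
                       seq_len(k)),
          population = pops$name[i], era = era,
          f_target = if (era == "modern") pops$f_modern[i]
                     else pops$f_historical[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  samples <- do.call(rbind, rows)
  samples$mean_coverage <- round(stats::runif(nrow(samples),
                                              config$coverage_range[1],
                                              config$coverage_range[2]), 1)

  # --- site coordinates ----------------------------------------------------
  per_scaf <- as.vector(stats::rmultinom(1, n, prob = scaf$length))
  site_list <- lapply(seq_len(nrow(scaf)), function(i) {
    if (per_scaf[i] == 0L) return(NULL)
    data.frame(scaffold = scaf$name[i],
               pos = sort(sample.int(scaf$length[i], per_scaf[i])),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)
  sites <- sites[order(sites$scaffold, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL

  # --- alleles -------------------------------------------------------------
  bases <- c("A", "C", "G", "T")
  ref1 <- sample(bases, n, replace = TRUE)
  alt1 <- vapply(ref1, function(b) sample(setdiff(bases, b), 1L), "")
  is_indel <- stats::runif(n) < config$indel_fraction
  sites$ref <- ref1
  sites$alt <- alt1
  # indels: 2-bp REF deletion records, ALT = first REF base
  sites$ref[is_indel] <- paste0(ref1[is_indel],
                                sample(bases, sum(is_indel), replace = TRUE))
  sites$alt[is_indel] <- ref1[is_indel]
  sites$is_indel <- is_indel

  # --- frequencies and genotypes -------------------------------------------
  p_anc <- stats::rbeta(n, config$beta_shape, config$beta_shape)
  p_anc <- pmin(pmax(p_anc, 1e-6), 1 - 1e-6)
  freq <- vapply(seq_len(nrow(pops)), function(i) {
    balding_nichols(p_anc, pops$fst[i])
  }, numeric(n))
  colnames(freq) <- pops$name

  geno <- matrix(NA_integer_, n, nrow(samples),
                 dimnames = list(NULL, samples$id))
  for (j in seq_len(nrow(samples))) {
    q <- freq[, samples$population[j]]
    geno[, j] <- stats::rbinom(n, 2L, q)
  }

  # --- plant ROH tracts ----------------------------------------------------
  tract_list <- list()
  for (j in seq_len(nrow(samples))) {
    if (samples$f_target[j] > 0) {
      tr <- draw_tracts(samples$f_target[j], scaf, config$roh_lengths)
      if (nrow(tr)) {
        tr$sample <- samples$id[j]
        tract_list[[length(tract_list) + 1L]] <- tr
      }
    }
  }
  tracts <- if (length(tract_list)) do.call(rbind, tract_list) else
    data.frame(sample = character(), scaffold = character(),
               start = numeric(), end = numeric(), stringsAsFactors = FALSE)
  freq_by_sample <- freq[, samples$population, drop = FALSE]
  colnames(freq_by_sample) <- samples$id
  geno <- plant_roh(geno, sites, tracts, freq_by_sample, contigs = scaf)
  true_f <- vapply(samples$id, function(sid) {
    tr <- tracts[tracts$sample == sid, , drop = FALSE]
    sum(tr$end - tr$start + 1) / glen
  }, numeric(1))

  # --- GERP scores ---------------------------------------------------------
  cls <- sample(names(config$gerp_mixture), n, replace = TRUE,
                prob = config$gerp_mixture)
  gerp <- numeric(n)
  for (k in names(config$gerp_ranges)) {
    sel <- cls == k
    gerp[sel] <- stats::runif(sum(sel), config$gerp_ranges[[k]][1],
                              config$gerp_ranges[[k]][2])
  }
  gerp[is_indel] <- NA_real_
  sites$gerp <- gerp

  # --- genes and effect categories ----------------------------------------
  gene_len <- config$coding_fraction * glen / max(config$n_genes, 1L)
  genes <- if (config$n_genes > 0) {
    g <- draw_tracts(config$coding_fraction, scaf,
                     list(short = c(0.7 * gene_len, 1.3 * gene_len),
                          long = c(0.7 * gene_len, 1.3 * gene_len),
                          p_short = 1),
                     min_length = 0.5 * gene_len)
    g$gene <- sprintf("gene%04d", seq_len(nrow(g)))
    g
  } else {
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               gene = character(), stringsAsFactors = FALSE)
  }
  sites$gene <- NA_character_
  sites$effect <- "none"
  if (nrow(genes)) {
    hit <- interval_overlap(sites$scaffold, sites$pos, genes)
    sites$gene <- genes$gene[hit]
    in_gene <- !is.na(hit) & !is_indel
    sites$effect[in_gene] <- sample(names(config$effect_probs),
                                    sum(in_gene), replace = TRUE,
                                    prob = config$effect_probs)
  }

  # --- ancestral allele & polarization flips -------------------------------
  sites$aa <- sites$ref
  snp_idx <- which(!is_indel)
  n_flip <- round(config$aa_flip_fraction * length(snp_idx))
  if (n_flip > 0) {
    flip <- sample(snp_idx, n_flip)
    sites$aa[flip] <- sites$alt[flip]
    geno[flip, ] <- 2L - geno[flip, , drop = FALSE]
  }
  n_miss_aa <- round(config$aa_missing_fraction * length(snp_idx))
  if (n_miss_aa > 0) {
    sites$aa[sample(setdiff(snp_idx, which(sites$aa == sites$alt)),
                    n_miss_aa)] <- NA_character_
  }
  sites$aa[is_indel] <- sites$ref[is_indel]

  # --- depth, quality, missingness ----------------------------------------
  dp <- vapply(samples$mean_coverage,
               function(cv) stats::rpois(n, cv), numeric(n))
  colnames(dp) <- samples$id
  gq <- matrix(99L, n, nrow(samples), dimnames = list(NULL, samples$id))
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_integer_
  }

  # --- repeat mask (emitted for filter exercises, not used in generation) --
  repeats <- if (config$repeat_fraction > 0) {
    draw_tracts(config$repeat_fraction, scaf,
                list(short = c(200, 5000), long = c(200, 5000), p_short = 1),
                min_length = 100)
  } else {
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  }

  data <- variant_dataset(
    sites = sites, geno = geno,
    samples = samples[c("id", "population", "era", "mean_coverage")],
    contigs = data.frame(name = scaf$name, length = scaf$length,
                         stringsAsFactors = FALSE),
    dp = dp, gq = gq
  )
  truth <- structure(
    list(tracts = tracts[c("sample", "scaffold", "start", "end")],
         true_f = data.frame(sample = samples$id, f = unname(true_f),
                             stringsAsFactors = FALSE),
         freq = freq,
         site_labels = data.frame(
           scaffold = sites$scaffold, pos = sites$pos,
           deleterious = !is.na(gerp) & gerp > 4,
           effect = sites$effect, gene = sites$gene,
           stringsAsFactors = FALSE),
         genes = genes, repeats = repeats),
    class = "synthetic_truth"
  )
  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_dataset_bundle(data, truth, out_dir,
                                  seed = config$seed + 1L)
  }
  list(data = data, truth = truth, files = files)
}

# first gene interval (row index into `intervals`) overlapping each position,
# NA when none; intervals are 1-based inclusive
interval_overlap <- function(scaffold, pos, intervals) {
  hit <- rep(NA_integer_, length(pos))
  for (sc in unique(intervals$scaffold)) {
    iv <- intervals[intervals$scaffold == sc, , drop = FALSE]
    idx <- which(scaffold == sc)
    if (!length(idx)) next
    ir <- IRanges::IRanges(start = iv$start, end = iv$end)
    qr <- IRanges::IRanges(start = pos[idx], width = 1L)
    ov <- IRanges::findOverlaps(qr, ir, select = "first")
    loc <- which(intervals$scaffold == sc)
    hit[idx] <- loc[ov]
  }
  hit
}

#' Simulate a gene-resolved selection scan with one truly selected gene
#'
#' Generates three populations from a shared Balding-Nichols background
#' drift, except that in one randomly chosen gene the focal population's
#' frequencies are drawn with a much larger drift parameter, mimicking a
#' population-specific sweep. Used to measure the power of the PBS scan
#' against known truth.
#'
#' @param n_genes,snps_per_gene scan size.
#' @param n_per_pop diploid sample size per population.
#' @param background_fst drift for all populations at neutral genes.
#' @param selected_fst drift of the focal population at the selected gene.
#' @param focal_population name of the population carrying the sweep.
#' @param seed integer seed.
#' @param beta_shape ancestral Beta shape.
#' @return list with `data` (a [variant_dataset()]), `genes` (interval
#'   table) and `selected_gene` (the planted outlier's id).
#' @export
simulate_selection_scan <- function(n_genes = 200, snps_per_gene = 50,
                                    n_per_pop = 10, background_fst = 0.05,
                                    selected_fst = 0.6,
                                    focal_population = "popA", seed = 1,
                                    beta_shape = 0.5) {
  set.seed(seed)
  pops <- c("popA", "popB", "popC")
  stopifnot(focal_population %in% pops)
  n <- n_genes * snps_per_gene
  gene_span <- snps_per_gene * 1000L + 10000L
  gene_id <- rep(sprintf("gene%04d", seq_len(n_genes)), each = snps_per_gene)
  gene_start <- (match(gene_id, unique(gene_id)) - 1L) * gene_span + 1L
  pos <- gene_start + (seq_len(n) - 1L) %% snps_per_gene * 1000L
  selected_gene <- sprintf("gene%04d", sample.int(n_genes, 1L))

  p_anc <- pmin(pmax(stats::rbeta(n, beta_shape, beta_shape), 1e-6), 1 - 1e-6)
  freq <- vapply(pops, function(p) balding_nichols(p_anc, background_fst),
                 numeric(n))
  sel <- gene_id == selected_gene
  freq[sel, focal_population] <-
    balding_nichols(p_anc[sel], selected_fst)

  samples <- data.frame(
    id = sprintf("%s_%02d", rep(pops, each = n_per_pop),
                 rep(seq_len(n_per_pop), 3)),
    population = rep(pops, each = n_per_pop),
    era = "modern", mean_coverage = 20,
    stringsAsFactors = FALSE
  )
  geno <- matrix(NA_integer_, n, nrow(samples),
                 dimnames = list(NULL, samples$id))
  for (j in seq_len(nrow(samples))) {
    geno[, j] <- stats::rbinom(n, 2L, freq[, samples$population[j]])
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  sites <- data.frame(
    scaffold = "scaf01", pos = pos, ref = ref,
    alt = vapply(ref, function(b) sample(setdiff(bases, b), 1L), ""),
    is_indel = FALSE, aa = ref, gerp = NA_real_, effect = "none",
    gene = gene_id, stringsAsFactors = FALSE
  )
  genes <- data.frame(
    gene = unique(gene_id), scaffold = "scaf01",
    start = (seq_len(n_genes) - 1L) * gene_span + 1L,
    end = (seq_len(n_genes) - 1L) * gene_span + snps_per_gene * 1000L,
    stringsAsFactors = FALSE
  )
  data <- variant_dataset(
    sites = sites, geno = geno, samples = samples,
    contigs = data.frame(name = "scaf01", length = n_genes * gene_span,
                         stringsAsFactors = FALSE)
  )
  list(data = data, genes = genes, selected_gene = selected_gene)
}
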