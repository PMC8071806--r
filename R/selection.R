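# Per-SNP Hudson FST numerator/denominator from allele frequencies and
# non-missing allele counts. The numerator subtracts within-population
# sampling variance (p(1-p)/(allele count - 1)); the denominator is the
# between-population heterozygosity p1(1-p2) + p2(1-p1).
hudson_components <- function(p1, p2, an1, an2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) - p2 * (1 - p2) / (an2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

# Weir & Cockerham (1984) two-population variance components a, b, c
wc_components <- function(p1, p2, h1, h2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise F_ST between two populations over a set of sites
#'
#' Hudson's estimator (ratio of averages across SNPs, robust at small and
#' unequal sample sizes) by default, with Weir-Cockerham available for
#' sensitivity analysis. Per-SNP negative numerators are retained in the
#' ratio (not truncated); the final estimate is clamped to `[0, 1]`. SNPs
#' with fewer than two non-missing alleles in either population, and SNPs
#' monomorphic across both populations, are dropped.
#'
#' @param data a [variant_dataset()].
#' @param pop1,pop2 population names.
#' @param sites optional integer index of sites to use (e.g., one gene's
#'   SNPs); default all non-indel sites.
#' @param estimator `"hudson"` or `"wc"`.
#' @return list with `fst` (`NA` with `no_data = TRUE` when no SNP
#'   qualifies) and `n_snps`.
#' @export
pairwise_fst <- function(data, pop1, pop2, sites = NULL,
                         estimator = c("hudson", "wc")) {
  stopifnot(inherits(data, "variant_dataset"))
  estimator <- match.arg(estimator)
  if (is.null(sites)) sites <- which(!data$sites$is_indel)
  ids1 <- population_samples(data, pop1)
  ids2 <- population_samples(data, pop2)
  if (!length(ids1) || !length(ids2)) {
    stop("empty population", call. = FALSE)
  }
  g1 <- data$geno[sites, ids1, drop = FALSE]
  g2 <- data$geno[sites, ids2, drop = FALSE]
  an1 <- 2 * rowSums(!is.na(g1))
  an2 <- 2 * rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / an1
  p2 <- rowSums(g2, na.rm = TRUE) / an2
  ok <- an1 >= 2 & an2 >= 2
  poly <- ok & !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  if (!any(poly)) {
    return(list(fst = NA_real_, n_snps = 0L, no_data = TRUE))
  }
  if (estimator == "hudson") {
    hc <- hudson_components(p1[poly], p2[poly], an1[poly], an2[poly])
    fst <- sum(hc$num) / sum(hc$den)
  } else {
    h1 <- rowMeans(g1 == 1L, na.rm = TRUE)
    h2 <- rowMeans(g2 == 1L, na.rm = TRUE)
    wc <- wc_components(p1[poly], p2[poly], h1[poly], h2[poly],
                        an1[poly] / 2, an2[poly] / 2)
    fst <- sum(wc$a) / sum(wc$a + wc$b + wc$c)
  }
  list(fst = min(max(fst, 0), 1), n_snps = sum(poly), no_data = FALSE)
}

#' Population branch statistic from three pairwise F_ST values
#'
#' Branch lengths are `T = -log(1 - F_ST)` (natural log); the focal branch
#' is `PBS_A = (T_AB + T_AC - T_BC) / 2` and cyclic permutations. `F_ST = 1`
#' gives an infinite branch, propagated as `Inf` (handled downstream by
#' [cap_and_call()]). Negative PBS values are permitted unless
#' `floor_zero = TRUE`.
#'
#' @param fst_ab,fst_ac,fst_bc pairwise F_ST values in `[0, 1]`
#'   (vectorized).
#' @param floor_zero truncate negative PBS values at 0.
#' @return data.frame (`pbs_a`, `pbs_b`, `pbs_c`).
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc, floor_zero = FALSE) {
  vals <- c(fst_ab, fst_ac, fst_bc)
  if (any(!is.na(vals) & (vals < 0 | vals > 1))) {
    stop("F_ST values must lie in [0, 1]", call. = FALSE)
  }
  t_ab <- -log(1 - fst_ab)
  t_ac <- -log(1 - fst_ac)
  t_bc <- -log(1 - fst_bc)
  out <- data.frame(
    pbs_a = (t_ab + t_ac - t_bc) / 2,
    pbs_b = (t_ab + t_bc - t_ac) / 2,
    pbs_c = (t_ac + t_bc - t_ab) / 2
  )
  # Inf - Inf from two saturated branches is an infinite focal branch
  for (k in seq_along(out)) out[[k]][is.nan(out[[k]])] <- Inf
  if (floor_zero) for (k in seq_along(out)) out[[k]] <- pmax(out[[k]], 0)
  out
}

#' Per-gene PBS selection scan over three populations
#'
#' Computes per-gene Hudson F_ST (ratio of averages over the gene's SNPs by
#' interval overlap; SNPs in overlapping genes count for each gene) for the
#' three population pairs, converts them to branch lengths and PBS values
#' per population, and flags outliers via [cap_and_call()]. Genes with no
#' usable SNP are flagged `no_data` and excluded from percentile
#' computation.
#'
#' @param data a [variant_dataset()].
#' @param genes gene interval table (`gene`, `scaffold`, `start`, `end`,
#'   1-based inclusive); when `NULL`, intervals are derived from the
#'   dataset's per-site gene annotation.
#' @param populations exactly three population names (default: the dataset's
#'   populations).
#' @param estimator F_ST estimator, see [pairwise_fst()].
#' @param floor_zero see [pbs()].
#' @return data.frame with one row per gene: `gene`, `n_snps`, the three
#'   `fst_*`, and one `pbs_<population>` column per population.
#' @export
pbs_scan <- function(data, genes = NULL, populations = NULL,
                     estimator = c("hudson", "wc"), floor_zero = FALSE) {
  stopifnot(inherits(data, "variant_dataset"))
  estimator <- match.arg(estimator)
  if (is.null(populations)) populations <- unique(data$samples$population)
  if (length(populations) != 3) {
    stop("the PBS scan needs exactly three populations", call. = FALSE)
  }
  if (is.null(genes)) {
    ann <- data$sites$gene
    keep <- !is.na(ann)
    if (!any(keep)) stop("no gene annotation available", call. = FALSE)
    genes <- do.call(rbind, lapply(split(which(keep), ann[keep]),
      function(ix) {
        data.frame(gene = data$sites$gene[ix[1]],
                   scaffold = data$sites$scaffold[ix[1]],
                   start = min(data$sites$pos[ix]),
                   end = max(data$sites$pos[ix]), stringsAsFactors = FALSE)
      }))
  }
  pA <- populations[1]; pB <- populations[2]; pC <- populations[3]
  rows <- lapply(seq_len(nrow(genes)), function(k) {
    in_gene <- which(data$sites$scaffold == genes$scaffold[k] &
                       data$sites$pos >= genes$start[k] &
                       data$sites$pos <= genes$end[k] &
                       !data$sites$is_indel)
    if (!length(in_gene)) {
      return(data.frame(gene = genes$gene[k], n_snps = 0L,
                        fst_ab = NA_real_, fst_ac = NA_real_,
                        fst_bc = NA_real_, pbs_a = NA_real_,
                        pbs_b = NA_real_, pbs_c = NA_real_,
                        no_data = TRUE, stringsAsFactors = FALSE))
    }
    f_ab <- pairwise_fst(data, pA, pB, in_gene, estimator)
    f_ac <- pairwise_fst(data, pA, pC, in_gene, estimator)
    f_bc <- pairwise_fst(data, pB, pC, in_gene, estimator)
    if (f_ab$no_data || f_ac$no_data || f_bc$no_data) {
      return(data.frame(gene = genes$gene[k], n_snps = length(in_gene),
                        fst_ab = f_ab$fst, fst_ac = f_ac$fst,
                        fst_bc = f_bc$fst, pbs_a = NA_real_,
                        pbs_b = NA_real_, pbs_c = NA_real_,
                        no_data = TRUE, stringsAsFactors = FALSE))
    }
    pb <- pbs(f_ab$fst, f_ac$fst, f_bc$fst, floor_zero)
    data.frame(gene = genes$gene[k], n_snps = length(in_gene),
               fst_ab = f_ab$fst, fst_ac = f_ac$fst, fst_bc = f_bc$fst,
               pbs_a = pb$pbs_a, pbs_b = pb$pbs_b, pbs_c = pb$pbs_c,
               no_data = FALSE, stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, rows)
  names(scan)[names(scan) == "pbs_a"] <- paste0("pbs_", pA)
  names(scan)[names(scan) == "pbs_b"] <- paste0("pbs_", pB)
  names(scan)[names(scan) == "pbs_c"] <- paste0("pbs_", pC)
  attr(scan, "populations") <- populations
  scan
}

#' Replace infinite PBS values and call per-population outliers
#'
#' Infinite PBS values (arising from saturated F_ST = 1 branches) are
#' replaced, per population, with that population's maximum finite PBS.
#' Outliers are genes with capped PBS strictly above `threshold` (the
#' operative rule); the `percentile` of each population's capped
#' distribution (linear interpolation between order statistics) is reported
#' alongside. Also reports genes uniquely outlying in exactly one population
#' and genes with F_ST = 1 in all three pairwise comparisons.
#'
#' @param scan result of [pbs_scan()].
#' @param threshold hard PBS outlier threshold (default 3).
#' @param percentile reported reference percentile (default 99.8).
#' @return list with `scan` (capped), `outliers` (named list of gene id
#'   vectors), `unique_outliers`, `percentile_value` (named numeric),
#'   `infinite_replaced` (named counts) and `fst_one_genes`.
#' @export
cap_and_call <- function(scan, threshold = 3, percentile = 99.8) {
  populations <- attr(scan, "populations")
  if (is.null(populations)) {
    populations <- sub("^pbs_", "",
                       grep("^pbs_", names(scan), value = TRUE))
  }
  usable <- !scan$no_data
  pct <- rep(NA_real_, length(populations))
  names(pct) <- populations
  n_inf <- stats::setNames(integer(length(populations)), populations)
  for (p in populations) {
    col <- paste0("pbs_", p)
    v <- scan[[col]]
    inf <- usable & is.infinite(v)
    fin <- usable & is.finite(v)
    if (!any(fin)) {
      stop("all PBS values infinite for population ", p, call. = FALSE)
    }
    n_inf[p] <- sum(inf)
    v[usable & v == Inf] <- max(v[fin])
    v[usable & v == -Inf] <- min(v[fin])
    scan[[col]] <- v
    pct[p] <- stats::quantile(v[usable], percentile / 100, type = 7,
                              names = FALSE)
  }
  outliers <- lapply(populations, function(p) {
    scan$gene[usable & scan[[paste0("pbs_", p)]] > threshold]
  })
  names(outliers) <- populations
  n_out_pops <- rowSums(vapply(populations, function(p) {
    usable & scan[[paste0("pbs_", p)]] > threshold
  }, logical(nrow(scan))))
  unique_outliers <- lapply(populations, function(p) {
    intersect(outliers[[p]], scan$gene[n_out_pops == 1L])
  })
  names(unique_outliers) <- populations
  fst_one <- usable & scan$fst_ab == 1 & scan$fst_ac == 1 & scan$fst_bc == 1
  list(scan = scan, outliers = outliers,
       unique_outliers = unique_outliers, percentile_value = pct,
       threshold = threshold, infinite_replaced = n_inf,
       fst_one_genes = scan$gene[fst_one])
}

#' Per-population missense gene summary
#'
#' For each population: genes with at least one segregating or fixed
#' missense variant, genes whose missense variants occur in no other
#' population, and genes with at least one missense variant fixed
#' (derived frequency 1) in the population. Missense variants fixed across
#' every population are excluded first (they carry no between-population
#' information).
#'
#' @param data a [variant_dataset()] with effect annotations.
#' @param populations populations to summarize (default all).
#' @return data.frame: `population`, `n_genes_missense`,
#'   `n_genes_exclusive`, `n_genes_fixed`, `n_genes_exclusive_fixed`.
#' @export
missense_summary <- function(data, populations = NULL) {
  stopifnot(inherits(data, "variant_dataset"))
  if (is.null(populations)) populations <- unique(data$samples$population)
  dd <- derived_dosage(data)
  at <- which(data$sites$effect == "missense" & !data$sites$is_indel &
                !is.na(data$sites$gene))
  if (!length(at)) stop("no annotated missense sites", call. = FALSE)
  af <- vapply(populations, function(p) {
    pop_derived_freq(dd, population_samples(data, p))[at]
  }, numeric(length(at)))
  fixed_everywhere <- rowSums(!is.na(af) & af == 1) == length(populations)
  at <- at[!fixed_everywhere]
  af <- af[!fixed_everywhere, , drop = FALSE]
  genes <- data$sites$gene[at]
  present <- !is.na(af) & af > 0
  fixed <- !is.na(af) & af == 1
  rows <- lapply(seq_along(populations), function(i) {
    here <- present[, i]
    elsewhere <- rowSums(present[, -i, drop = FALSE]) > 0
    g_here <- unique(genes[here])
    g_excl <- setdiff(g_here, unique(genes[elsewhere]))
    g_fixed <- unique(genes[fixed[, i]])
    data.frame(population = populations[i],
               n_genes_missense = length(g_here),
               n_genes_exclusive = length(g_excl),
               n_genes_fixed = length(g_fixed),
               n_genes_exclusive_fixed = length(intersect(g_excl, g_fixed)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
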