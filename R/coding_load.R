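#' Per-individual coding variant burden
#'
#' Counts, per effect category (loss-of-function, missense, synonymous), the
#' annotated sites where the sample carries at least one derived allele,
#' split by zygosity (heterozygous vs homozygous derived). Sites with a
#' missing genotype for the sample are skipped and reported. Counting
#' carried sites matches per-individual "number of variants" reporting;
#' `count_alleles = TRUE` switches to allele counting (homozygous = 2).
#'
#' @param data a [variant_dataset()] with effect annotations.
#' @param sample sample id.
#' @param count_alleles count derived alleles instead of carried sites.
#' @return data.frame with one row per category: `sample`, `effect`,
#'   `n_total`, `n_hom`, `n_het`, `n_missing_sites`.
#' @export
burden <- function(data, sample, count_alleles = FALSE) {
  stopifnot(inherits(data, "variant_dataset"))
  if (!sample %in% data$samples$id) {
    stop("unknown sample id: ", sample, call. = FALSE)
  }
  annotated <- data$sites$effect %in% c("synonymous", "missense", "lof") &
    !data$sites$is_indel
  if (!any(annotated)) {
    stop("no effect-annotated sites in dataset", call. = FALSE)
  }
  dd <- derived_dosage(data)[, sample]
  rows <- lapply(c("lof", "missense", "synonymous"), function(eff) {
    at <- annotated & data$sites$effect == eff
    d <- dd[at]
    n_missing <- sum(at & is.na(dd))
    het <- sum(d == 1L, na.rm = TRUE)
    hom <- sum(d == 2L, na.rm = TRUE)
    if (count_alleles) {
      data.frame(sample = sample, effect = eff, n_total = het + 2L * hom,
                 n_hom = 2L * hom, n_het = het, n_missing_sites = n_missing,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample = sample, effect = eff, n_total = het + hom,
                 n_hom = hom, n_het = het, n_missing_sites = n_missing,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Per-sample burden table for one effect category
#'
#' @inheritParams burden
#' @param effect category to tabulate (default `"lof"`).
#' @return data.frame with one row per sample: counts total/hom/het.
#' @export
burden_summary <- function(data, effect = "lof", count_alleles = FALSE) {
  rows <- lapply(data$samples$id, function(sid) {
    b <- burden(data, sid, count_alleles)
    b <- b[b$effect == effect, , drop = FALSE]
    data.frame(sample = sid,
               population = data$samples$population[data$samples$id == sid],
               era = data$samples$era[data$samples$id == sid],
               effect = effect, n_total = b$n_total, n_hom = b$n_hom,
               n_het = b$n_het, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# derived allele frequency per site over the non-missing alleles of a
# sample set; NaN when no calls
pop_derived_freq <- function(dd, ids) {
  ct <- allele_counts(dd, ids)
  ct$derived / ct$total
}

#' Population-level summary of loss-of-function variation
#'
#' For one population: segregating LoF sites, genes carrying them, per-gene
#' LoF counts, and the partition into fixed variants (every non-missing
#' genotype homozygous derived), private variants (derived frequency > 0
#' here and 0 in every other population) and private-and-fixed variants.
#'
#' @param data a [variant_dataset()] with effect annotations.
#' @param population population name.
#' @param effect effect category (default `"lof"`).
#' @param min_call_rate optional minimum fraction of called genotypes for a
#'   site to be classifiable as fixed (default 0: any non-missing genotype
#'   suffices, appropriate at very small sample sizes).
#' @return list with `population`, `n_sites` (segregating or fixed derived
#'   sites), `n_genes`, `per_gene` counts, `max_per_gene`, and site index
#'   vectors `fixed`, `private`, `private_fixed`.
#' @export
population_summary <- function(data, population, effect = "lof",
                               min_call_rate = 0) {
  stopifnot(inherits(data, "variant_dataset"))
  ids <- population_samples(data, population)
  if (!length(ids)) stop("empty population: ", population, call. = FALSE)
  other_pops <- setdiff(unique(data$samples$population), population)
  dd <- derived_dosage(data)
  at <- which(data$sites$effect == effect & !data$sites$is_indel)
  m <- dd[at, ids, drop = FALSE]
  n_called <- rowSums(!is.na(m))
  af <- rowSums(m, na.rm = TRUE) / (2 * n_called)
  present <- !is.na(af) & af > 0
  call_rate <- n_called / length(ids)
  fixed <- n_called > 0 & call_rate >= min_call_rate &
    rowSums(m == 2L, na.rm = TRUE) == n_called
  af_other <- vapply(other_pops, function(p) {
    pop_derived_freq(dd, population_samples(data, p))[at]
  }, numeric(length(at)))
  absent_elsewhere <- if (length(other_pops)) {
    rowSums(!is.na(af_other) & af_other > 0) == 0
  } else {
    rep(TRUE, length(at))
  }
  private <- present & absent_elsewhere
  genes <- data$sites$gene[at]
  per_gene <- table(genes[present & !is.na(genes)])
  list(
    population = population, effect = effect,
    n_sites = sum(present),
    n_genes = length(per_gene),
    per_gene = as.data.frame(per_gene, stringsAsFactors = FALSE) |>
      stats::setNames(c("gene", "n_variants")),
    max_per_gene = if (length(per_gene)) max(per_gene) else 0L,
    fixed = at[fixed],
    private = at[private],
    private_fixed = at[fixed & private]
  )
}

#' Translocation risk of a candidate donor
#'
#' The number of loss-of-function variants carried by the donor (derived
#' dosage >= 1) that are entirely absent (derived allele frequency 0 over
#' non-missing calls) from the recipient population -- i.e., the new
#' deleterious variants an assisted-gene-flow translocation of this
#' individual would introduce.
#'
#' @param data a [variant_dataset()] with effect annotations.
#' @param donor donor sample id (must not belong to the recipient).
#' @param recipient_population recipient population name.
#' @param effect effect category (default `"lof"`).
#' @return list with `donor`, `recipient`, `n_new_variants` and `sites`
#'   (data.frame of the introduced sites).
#' @export
translocation_risk <- function(data, donor, recipient_population,
                               effect = "lof") {
  stopifnot(inherits(data, "variant_dataset"))
  if (!donor %in% data$samples$id) {
    stop("unknown sample id: ", donor, call. = FALSE)
  }
  donor_pop <- data$samples$population[data$samples$id == donor]
  if (donor_pop == recipient_population) {
    stop("donor ", donor, " is already a member of population ",
         recipient_population, call. = FALSE)
  }
  rec_ids <- population_samples(data, recipient_population)
  if (!length(rec_ids)) {
    stop("empty recipient population: ", recipient_population, call. = FALSE)
  }
  dd <- derived_dosage(data)
  at <- which(data$sites$effect == effect & !data$sites$is_indel)
  carried <- !is.na(dd[at, donor]) & dd[at, donor] >= 1L
  rec_af <- pop_derived_freq(dd, rec_ids)[at]
  new <- carried & !is.na(rec_af) & rec_af == 0
  idx <- at[new]
  list(donor = donor, recipient = recipient_population,
       n_new_variants = sum(new),
       sites = data$sites[idx, c("scaffold", "pos", "gene"), drop = FALSE])
}

#' Donor-by-recipient translocation risk matrix
#'
#' @inheritParams translocation_risk
#' @return data.frame (`donor`, `donor_population`, `recipient`,
#'   `n_new_variants`), one row per donor x foreign population.
#' @export
translocation_risk_matrix <- function(data, effect = "lof") {
  pops <- unique(data$samples$population)
  rows <- list()
  for (sid in data$samples$id) {
    own <- data$samples$population[data$samples$id == sid]
    for (p in setdiff(pops, own)) {
      r <- translocation_risk(data, sid, p, effect)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = sid, donor_population = own, recipient = p,
        n_new_variants = r$n_new_variants, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate gene flow by copying a donor into a recipient population
#'
#' Returns a dataset in which the donor additionally appears as a member of
#' the recipient population, so that post-gene-flow quantities (e.g., how
#' many previously fixed variants become unfixed/masked) can be recomputed
#' directly.
#'
#' @inheritParams translocation_risk
#' @return a [variant_dataset()] with one added sample.
#' @export
simulate_gene_flow <- function(data, donor, recipient_population) {
  stopifnot(inherits(data, "variant_dataset"))
  j <- match(donor, data$samples$id)
  if (is.na(j)) stop("unknown sample id: ", donor, call. = FALSE)
  if (data$samples$population[j] == recipient_population) {
    stop("donor already belongs to ", recipient_population, call. = FALSE)
  }
  new_id <- paste0(donor, "_translocated")
  geno <- cbind(data$geno, data$geno[, j])
  colnames(geno)[ncol(geno)] <- new_id
  samples <- rbind(data$samples,
                   data.frame(id = new_id,
                              population = recipient_population,
                              era = data$samples$era[j],
                              mean_coverage = data$samples$mean_coverage[j],
                              stringsAsFactors = FALSE))
  variant_dataset(sites = data$sites, geno = geno, samples = samples,
                  contigs = data$contigs)
}
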