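#' GERP-weighted relative mutational load for one individual
#'
#' The load is the conservation-score-weighted average over the individual's
#' derived alleles at constrained sites: the sum over included sites of
#' derived dosage times GERP score, divided by the total number of derived
#' alleles at those sites. Only derived alleles at sites with a score above
#' `score_threshold` are included (the strict-constraint default is 4; a
#' more permissive non-neutral cutoff of 1 can be requested). Sites with a
#' missing genotype for the sample, unknown ancestral allele, no score, or
#' indel records are excluded.
#'
#' @param data a [variant_dataset()].
#' @param sample sample id.
#' @param score_threshold include derived alleles at sites with GERP score
#'   strictly above this value.
#' @param denominator `"included"` (total derived alleles above the
#'   threshold, the default) or `"all_derived"` (all derived alleles
#'   regardless of score, for sensitivity analysis).
#' @return list with `sample`, `relative_load` (`NA` when undefined),
#'   `n_derived_included`, `threshold` and `undefined` flag.
#' @export
relative_load <- function(data, sample, score_threshold = 4,
                          denominator = c("included", "all_derived")) {
  stopifnot(inherits(data, "variant_dataset"))
  denominator <- match.arg(denominator)
  if (!sample %in% data$samples$id) {
    stop("unknown sample id: ", sample, call. = FALSE)
  }
  dd <- derived_dosage(data)[, sample]
  usable <- !data$sites$is_indel & !is.na(dd) & !is.na(data$sites$gerp)
  if (!any(usable)) {
    return(list(sample = sample, relative_load = NA_real_,
                n_derived_included = 0L, threshold = score_threshold,
                undefined = TRUE))
  }
  incl <- usable & data$sites$gerp > score_threshold
  num <- sum(dd[incl] * data$sites$gerp[incl])
  n_incl <- sum(dd[incl])
  den <- if (denominator == "included") n_incl else sum(dd[usable])
  if (den == 0) {
    return(list(sample = sample, relative_load = NA_real_,
                n_derived_included = as.integer(n_incl),
                threshold = score_threshold, undefined = TRUE))
  }
  list(sample = sample, relative_load = num / den,
       n_derived_included = as.integer(n_incl),
       threshold = score_threshold, undefined = FALSE)
}

#' Per-sample relative load table
#'
#' @inheritParams relative_load
#' @return data.frame with one row per sample.
#' @export
load_summary <- function(data, score_threshold = 4,
                         denominator = c("included", "all_derived")) {
  denominator <- match.arg(denominator)
  rows <- lapply(data$samples$id, function(sid) {
    r <- relative_load(data, sid, score_threshold, denominator)
    data.frame(sample = sid,
               population = data$samples$population[data$samples$id == sid],
               era = data$samples$era[data$samples$id == sid],
               relative_load = r$relative_load,
               n_derived_included = r$n_derived_included,
               threshold = r$threshold, undefined = r$undefined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Private and shared deleterious alleles by fixed-depth allele subsampling
#'
#' At every site with a conservation score above `score_threshold` where all
#' populations have at least `n_alleles` non-missing allele calls,
#' `n_alleles` alleles are drawn without replacement from each population's
#' allele pool (equalizing sample sizes across populations to exclude
#' sample-size bias). A population "carries" the derived allele when at
#' least one drawn allele is derived. Sites carried by at least one
#' population are classified as unique to one population, shared by exactly
#' one pair, or shared by all, and category percentages over classified
#' sites are reported.
#'
#' @param data a [variant_dataset()].
#' @param populations populations to compare (default: all populations with
#'   modern samples); at least two required.
#' @param n_alleles alleles drawn per population per site (default 6, i.e.,
#'   three diploid genomes' worth).
#' @param score_threshold GERP cutoff for "deleterious" (default 4).
#' @param seed optional seed making the subsampling reproducible.
#' @param modern_only restrict the allele pools to modern samples.
#' @return list with `table` (data.frame `category`, `percent`, `n_sites`),
#'   `n_sites_used`, `n_alleles`, `threshold`, `seed`.
#' @export
allele_sharing <- function(data, populations = NULL, n_alleles = 6,
                           score_threshold = 4, seed = NULL,
                           modern_only = TRUE) {
  stopifnot(inherits(data, "variant_dataset"))
  if (!is.null(seed)) set.seed(seed)
  meta <- data$samples
  if (modern_only) meta <- meta[meta$era == "modern", , drop = FALSE]
  if (is.null(populations)) populations <- unique(meta$population)
  if (length(populations) < 2) {
    stop("allele sharing needs at least two populations", call. = FALSE)
  }
  dd <- derived_dosage(data)
  scored <- !data$sites$is_indel & !is.na(data$sites$gerp) &
    data$sites$gerp > score_threshold
  counts <- lapply(populations, function(p) {
    ids <- meta$id[meta$population == p]
    allele_counts(dd, ids)
  })
  names(counts) <- populations
  enough <- Reduce(`&`, lapply(counts, function(ct) ct$total >= n_alleles))
  use <- which(scored & enough)
  if (!length(use)) {
    stop("no sites qualify for allele subsampling", call. = FALSE)
  }
  carries <- vapply(populations, function(p) {
    d <- counts[[p]]$derived[use]
    tot <- counts[[p]]$total[use]
    stats::rhyper(length(use), m = d, n = tot - d, k = n_alleles) >= 1L
  }, logical(length(use)))
  n_carry <- rowSums(carries)
  classified <- n_carry >= 1L
  if (!any(classified)) {
    stop("no site carries a derived allele after subsampling", call. = FALSE)
  }
  cats <- c(paste0("unique_", populations),
            utils::combn(populations, 2, paste, collapse = "+"),
            "shared_all")
  label <- character(sum(classified))
  cc <- carries[classified, , drop = FALSE]
  nc <- n_carry[classified]
  label[nc == length(populations)] <- "shared_all"
  one <- nc == 1L
  label[one] <- paste0("unique_", populations[max.col(cc[one, , drop = FALSE])])
  two <- nc == 2L & length(populations) > 2L
  if (any(two)) {
    label[two] <- apply(cc[two, , drop = FALSE], 1, function(z) {
      paste(populations[z], collapse = "+")
    })
  }
  tab <- table(factor(label, levels = cats))
  list(
    table = data.frame(category = names(tab),
                       n_sites = as.integer(tab),
                       percent = 100 * as.integer(tab) / sum(tab),
                       stringsAsFactors = FALSE),
    n_sites_used = sum(classified),
    n_alleles = n_alleles, threshold = score_threshold, seed = seed
  )
}
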