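#' Multi-sample variant dataset
#'
#' The central container used by every analysis stage: an ordered site table,
#' a sites x samples genotype dosage matrix, per-sample metadata and the
#' contig (scaffold) table of the reference the variants were called against.
#'
#' Genotypes are stored as ALT-allele dosage (0, 1, 2 or `NA` for missing).
#' Derived-allele dosage is obtained on demand via [derived_dosage()] using
#' the per-site ancestral allele, so sites with unknown or mismatching
#' ancestral state are transparently excluded from load computations while
#' remaining available for heterozygosity and ROH.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based),
#'   `ref`, `alt`, `is_indel` (logical), `aa` (ancestral allele, `NA` if
#'   unknown), `gerp` (numeric, `NA` if unscored), `effect` (one of
#'   `"synonymous"`, `"missense"`, `"lof"`, `"none"`), `gene` (`NA` outside
#'   genes).
#' @param geno integer matrix (sites x samples) of ALT dosage in `{0,1,2,NA}`;
#'   column names must equal `samples$id`.
#' @param samples data.frame with columns `id`, `population`,
#'   `era` (`"historical"` or `"modern"`) and `mean_coverage` (X).
#' @param contigs data.frame with columns `name` and `length` (bp) for every
#'   retained scaffold; used for ROH bounds and genome length.
#' @param dp,gq optional numeric matrices (same shape as `geno`) of
#'   per-genotype depth and quality, consumed by [apply_site_filters()].
#'
#' @return An object of class `variant_dataset`.
#' @seealso [derived_dosage()], [apply_site_filters()], [simulate_dataset()]
#' @export
variant_dataset <- function(sites, geno, samples, contigs, dp = NULL, gq = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  contigs <- as.data.frame(contigs, stringsAsFactors = FALSE)
  needed <- c("scaffold", "pos", "ref", "alt", "is_indel", "aa", "gerp",
              "effect", "gene")
  missing_cols <- setdiff(needed, names(sites))
  for (col in missing_cols) {
    sites[[col]] <- switch(col,
      is_indel = FALSE,
      aa = NA_character_,
      gerp = NA_real_,
      effect = "none",
      gene = NA_character_,
      stop("site column '", col, "' is required", call. = FALSE)
    )
  }
  sites <- sites[needed]
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno))) colnames(geno) <- samples$id
  obj <- structure(
    list(sites = sites, geno = geno, samples = samples, contigs = contigs,
         dp = dp, gq = gq),
    class = "variant_dataset"
  )
  validate_variant_dataset(obj)
  obj
}

#' @rdname variant_dataset
#' @param x a `variant_dataset`.
#' @export
validate_variant_dataset <- function(x) {
  stopifnot(inherits(x, "variant_dataset"))
  if (nrow(x$sites) != nrow(x$geno)) {
    stop("genotype matrix has ", nrow(x$geno), " rows but ", nrow(x$sites),
         " sites", call. = FALSE)
  }
  if (ncol(x$geno) != nrow(x$samples)) {
    stop("genotype matrix has ", ncol(x$geno), " columns but ",
         nrow(x$samples), " samples", call. = FALSE)
  }
  if (!identical(colnames(x$geno), x$samples$id)) {
    stop("genotype column names do not match sample ids", call. = FALSE)
  }
  if (anyDuplicated(x$samples$id)) stop("duplicated sample ids", call. = FALSE)
  if (nrow(x$sites)) {
    if (any(x$sites$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
    ord <- order(x$sites$scaffold, x$sites$pos)
    if (!identical(ord, seq_len(nrow(x$sites)))) {
      stop("sites must be sorted by (scaffold, pos)", call. = FALSE)
    }
    bad <- x$geno[!is.na(x$geno) & (x$geno < 0L | x$geno > 2L)]
    if (length(bad)) stop("genotype dosages must be in {0, 1, 2, NA}",
                          call. = FALSE)
    unknown <- setdiff(unique(x$sites$scaffold), x$contigs$name)
    if (length(unknown)) {
      stop("sites on scaffolds absent from contig table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (m in c("dp", "gq")) {
    if (!is.null(x[[m]]) && !identical(dim(x[[m]]), dim(x$geno))) {
      stop("'", m, "' matrix must match genotype dimensions", call. = FALSE)
    }
  }
  if (!all(x$samples$era %in% c("historical", "modern"))) {
    stop("era must be 'historical' or 'modern'", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.variant_dataset <- function(x, ...) {
  cat("variant_dataset:", nrow(x$sites), "sites x", nrow(x$samples),
      "samples on", nrow(x$contigs), "scaffolds\n")
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(table(x$samples$population)),
                    as.integer(table(x$samples$population))), collapse = ", "),
      "\n")
  n_indel <- sum(x$sites$is_indel)
  if (n_indel) cat("  indel records:", n_indel, "\n")
  invisible(x)
}

#' Derived-allele dosage matrix
#'
#' Polarizes ALT dosages into derived-allele dosages using the per-site
#' ancestral allele (`AA`). Sites where the ancestral allele is unknown, or
#' matches neither REF nor ALT, yield `NA` for all samples and are thereby
#' excluded from derived-allele (load) computations.
#'
#' @param data a [variant_dataset()].
#' @return integer matrix (sites x samples) of derived dosage.
#' @export
derived_dosage <- function(data) {
  stopifnot(inherits(data, "variant_dataset"))
  out <- data$geno
  anc_is_ref <- !is.na(data$sites$aa) & data$sites$aa == data$sites$ref
  anc_is_alt <- !is.na(data$sites$aa) & data$sites$aa == data$sites$alt
  out[anc_is_alt, ] <- 2L - out[anc_is_alt, , drop = FALSE]
  out[!(anc_is_ref | anc_is_alt), ] <- NA_integer_
  out
}

#' Subset a variant dataset by site index or by samples
#'
#' @param data a [variant_dataset()].
#' @param idx integer or logical index over sites.
#' @return a `variant_dataset` with the selected sites.
#' @export
subset_sites <- function(data, idx) {
  stopifnot(inherits(data, "variant_dataset"))
  variant_dataset(
    sites = data$sites[idx, , drop = FALSE],
    geno = data$geno[idx, , drop = FALSE],
    samples = data$samples,
    contigs = data$contigs,
    dp = if (!is.null(data$dp)) data$dp[idx, , drop = FALSE],
    gq = if (!is.null(data$gq)) data$gq[idx, , drop = FALSE]
  )
}

#' @rdname subset_sites
#' @param ids character vector of sample ids to keep.
#' @export
subset_samples <- function(data, ids) {
  stopifnot(inherits(data, "variant_dataset"))
  keep <- match(ids, data$samples$id)
  if (anyNA(keep)) {
    stop("unknown sample id(s): ", paste(ids[is.na(keep)], collapse = ", "),
         call. = FALSE)
  }
  variant_dataset(
    sites = data$sites,
    geno = data$geno[, keep, drop = FALSE],
    samples = data$samples[keep, , drop = FALSE],
    contigs = data$contigs,
    dp = if (!is.null(data$dp)) data$dp[, keep, drop = FALSE],
    gq = if (!is.null(data$gq)) data$gq[, keep, drop = FALSE]
  )
}

# sample ids belonging to a population (optionally one era)
population_samples <- function(data, population, era = NULL) {
  keep <- data$samples$population == population
  if (!is.null(era)) keep <- keep & data$samples$era == era
  data$samples$id[keep]
}

# derived allele count and non-missing allele count per site for a sample set
allele_counts <- function(dd, sample_ids) {
  m <- dd[, sample_ids, drop = FALSE]
  list(
    derived = rowSums(m, na.rm = TRUE),
    total = 2L * rowSums(!is.na(m))
  )
}

#' Total genome length of the retained scaffolds
#'
#' @param data a [variant_dataset()].
#' @return total scaffold length in bp.
#' @export
genome_length <- function(data) {
  stopifnot(inherits(data, "variant_dataset"))
  sum(as.numeric(data$contigs$length))
}
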