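#' Two-sided pairwise t-tests between groups
#'
#' Welch's unequal-variance t-test (the safer default at small, unequal
#' group sizes; Student's available via `var_equal = TRUE`) for every
#' unordered pair of groups, with no multiple-testing adjustment by default.
#' Groups with fewer than two samples are skipped with a warning.
#'
#' @param values numeric vector of per-sample statistics.
#' @param groups group label per value (population or era).
#' @param var_equal use the pooled-variance Student t-test.
#' @param p_adjust multiple-testing method passed to [stats::p.adjust()]
#'   (default `"none"`, matching unadjusted reporting).
#' @param statistic_name label recorded in the output.
#' @return data.frame with one row per pair: group means/SDs/sizes, `t`,
#'   `df`, `p`, `fold_change` (mean_b / mean_a) and `percent_difference`
#'   (100 x (mean_a - mean_b) / mean_b).
#' @export
pairwise_t_tests <- function(values, groups, var_equal = FALSE,
                             p_adjust = "none", statistic_name = "") {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  lv <- unique(groups)
  rows <- list()
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      a <- values[groups == lv[i]]
      b <- values[groups == lv[j]]
      if (length(a) < 2 || length(b) < 2) {
        warning("skipping ", lv[i], " vs ", lv[j],
                ": fewer than 2 samples in a group")
        next
      }
      tt <- stats::t.test(a, b, var.equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = statistic_name, group_a = lv[i], group_b = lv[j],
        n_a = length(a), n_b = length(b),
        mean_a = mean(a), mean_b = mean(b),
        sd_a = stats::sd(a), sd_b = stats::sd(b),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value,
        fold_change = if (mean(a) != 0) mean(b) / mean(a) else NA_real_,
        percent_difference = if (mean(b) != 0)
          100 * (mean(a) - mean(b)) / mean(b) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && p_adjust != "none") {
    out$p <- stats::p.adjust(out$p, method = p_adjust)
  }
  if (is.null(out)) {
    out <- data.frame(statistic = character(), group_a = character(),
                      group_b = character(), n_a = integer(), n_b = integer(),
                      mean_a = numeric(), mean_b = numeric(),
                      sd_a = numeric(), sd_b = numeric(), t = numeric(),
                      df = numeric(), p = numeric(), fold_change = numeric(),
                      percent_difference = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Signed percent difference of a relative to b
#'
#' `100 * (a - b) / b`: how much higher (positive) or lower (negative) `a`
#' is than the baseline `b`, in percent.
#'
#' @param a,b means to compare; `b` is the baseline and must be non-zero.
#' @return percent difference (vectorized).
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) stop("baseline mean b must be non-zero", call. = FALSE)
  100 * (a - b) / b
}

#' Temporal fold change (modern over historical mean)
#'
#' @param modern,historical group means; `historical` must be positive.
#' @return `modern / historical` (vectorized).
#' @export
fold_change <- function(modern, historical) {
  if (any(historical <= 0)) {
    stop("historical mean must be > 0", call. = FALSE)
  }
  modern / historical
}

#' Run the full genomic-erosion pipeline on one dataset
#'
#' Executes, in order: site filtering, diversity (heterozygosity and F_ROH),
#' GERP load and allele sharing, coding burden with population LoF summaries
#' and the translocation-risk matrix, the per-gene PBS scan with missense
#' summaries, and the group comparisons. One TSV is written per stage plus a
#' combined JSON summary and a run log; stages whose inputs are absent (no
#' GERP scores, no effect annotation, fewer or more than three populations)
#' are skipped with an explicit notice. Deterministic given `seed`.
#'
#' @param data a [variant_dataset()] (already filtered, or pass
#'   `filter = TRUE` to apply default filters first).
#' @param out_dir output directory.
#' @param filter apply [apply_site_filters()] with defaults first.
#' @param mask optional [site_mask()] used when filtering.
#' @param genes optional gene interval table for the PBS scan.
#' @param gerp_threshold GERP cutoff for load and sharing.
#' @param seed seed for the allele-sharing subsampling.
#' @param callable_length callable length for theta (default: retained
#'   genome length).
#' @return (invisibly) a list with every stage result plus `files`.
#' @export
run_pipeline <- function(data, out_dir, filter = FALSE, mask = NULL,
                         genes = NULL, gerp_threshold = 4, seed = 1L,
                         callable_length = NULL) {
  stopifnot(inherits(data, "variant_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- c(sprintf("erodr %s | seed %d",
                         as.character(utils::packageVersion("erodr")), seed))
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                     conditionMessage(e))), log_path)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(seed)
  res <- list()

  if (filter) {
    data <- stage("filter", apply_site_filters(data, mask = mask))
    res$filter_log <- filter_log(data)
    write_tsv(res$filter_log, file.path(out_dir, "filter_report.tsv"))
    note("filter: ", nrow(data$sites), " sites retained")
  }
  if (is.null(callable_length)) callable_length <- genome_length(data)

  res$diversity <- stage("diversity",
                         diversity_summary(data, callable_length))
  write_tsv(res$diversity, file.path(out_dir, "diversity.tsv"))
  note("diversity: ", nrow(res$diversity), " samples")

  pops <- unique(data$samples$population)
  if (any(!is.na(data$sites$gerp))) {
    res$load <- stage("gerp_load", load_summary(data, gerp_threshold))
    write_tsv(res$load, file.path(out_dir, "gerp_load.tsv"))
    if (length(pops) >= 2) {
      res$sharing <- stage("allele_sharing",
                           allele_sharing(data, seed = seed,
                                          score_threshold = gerp_threshold))
      write_tsv(res$sharing$table, file.path(out_dir, "allele_sharing.tsv"))
    }
    note("gerp_load: threshold ", gerp_threshold)
  } else {
    note("gerp_load: skipped (no GERP scores attached)")
  }

  has_eff <- any(data$sites$effect != "none")
  if (has_eff) {
    res$burden <- stage("coding_load", burden_summary(data, "lof"))
    write_tsv(res$burden, file.path(out_dir, "lof_burden.tsv"))
    res$population_lof <- stage("coding_load", lapply(pops, function(p) {
      s <- population_summary(data, p)
      data.frame(population = p, n_sites = s$n_sites, n_genes = s$n_genes,
                 max_per_gene = s$max_per_gene, n_fixed = length(s$fixed),
                 n_private = length(s$private),
                 n_private_fixed = length(s$private_fixed),
                 stringsAsFactors = FALSE)
    }) |> (\(x) do.call(rbind, x))())
    write_tsv(res$population_lof, file.path(out_dir, "population_lof.tsv"))
    res$translocation <- stage("coding_load",
                               translocation_risk_matrix(data))
    write_tsv(res$translocation,
              file.path(out_dir, "translocation_risk.tsv"))
    note("coding_load: ", sum(res$population_lof$n_sites), " LoF records")
  } else {
    note("coding_load: skipped (no effect annotation)")
  }

  if (length(pops) == 3) {
    res$pbs <- stage("selection", {
      scan <- pbs_scan(data, genes = genes, populations = pops)
      cap_and_call(scan)
    })
    write_tsv(res$pbs$scan, file.path(out_dir, "pbs.tsv"))
    if (has_eff) {
      res$missense <- stage("selection", missense_summary(data, pops))
      write_tsv(res$missense, file.path(out_dir, "missense_summary.tsv"))
    }
    note("selection: ", nrow(res$pbs$scan), " genes scanned")
  } else {
    note("selection: skipped (needs exactly three populations)")
  }

  cmp <- list(
    pairwise_t_tests(res$diversity$theta, res$diversity$population,
                     statistic_name = "theta"),
    pairwise_t_tests(res$diversity$froh_100kb, res$diversity$population,
                     statistic_name = "froh_100kb"),
    pairwise_t_tests(res$diversity$froh_2mb, res$diversity$population,
                     statistic_name = "froh_2mb")
  )
  if (!is.null(res$load)) {
    cmp <- c(cmp, list(
      pairwise_t_tests(res$load$relative_load, res$load$population,
                       statistic_name = "relative_load")))
  }
  if (!is.null(res$burden)) {
    cmp <- c(cmp, list(
      pairwise_t_tests(res$burden$n_total, res$burden$population,
                       statistic_name = "n_lof")))
  }
  # temporal (era) contrasts within populations sampled in both eras
  for (p in pops) {
    sub <- res$diversity[res$diversity$population == p, ]
    if (length(unique(sub$era)) == 2) {
      cmp <- c(cmp, list(
        pairwise_t_tests(sub$froh_100kb, sub$era,
                         statistic_name = paste0("froh_100kb@", p)),
        pairwise_t_tests(sub$froh_2mb, sub$era,
                         statistic_name = paste0("froh_2mb@", p)),
        pairwise_t_tests(sub$theta, sub$era,
                         statistic_name = paste0("theta@", p))))
    }
  }
  res$comparisons <- suppressWarnings(do.call(rbind, cmp))
  write_tsv(res$comparisons, file.path(out_dir, "comparisons.tsv"))

  summary <- list(
    seed = seed,
    n_sites = nrow(data$sites),
    n_samples = nrow(data$samples),
    populations = as.list(table(data$samples$population)),
    theta_mean_by_population = as.list(tapply(res$diversity$theta,
                                              res$diversity$population,
                                              mean)),
    froh_2mb_mean_by_population = as.list(tapply(res$diversity$froh_2mb,
                                                 res$diversity$population,
                                                 mean)),
    stages_run = names(res)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(log_lines, log_path)
  res$files <- list.files(out_dir, full.names = TRUE)
  invisible(res)
}
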