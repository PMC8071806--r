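#' Genome-wide heterozygosity (heterozygous sites per 1000 bp)
#'
#' Counts an individual's heterozygous genotypes among called sites and
#' scales by the callable genome length. Missing genotypes are excluded from
#' the numerator; `callable_length` must count all filtered-callable
#' positions (not only variant sites), so when no per-sample callability
#' track is available the total retained scaffold length is the usual
#' approximation.
#'
#' @param data a [variant_dataset()].
#' @param sample sample id.
#' @param callable_length callable genome length in bp (> 0).
#' @return list with `sample`, `het_sites`, `callable_length` and `theta`
#'   (het sites per 1000 bp).
#' @export
genome_heterozygosity <- function(data, sample,
                                  callable_length = genome_length(data)) {
  stopifnot(inherits(data, "variant_dataset"))
  if (!sample %in% data$samples$id) {
    stop("unknown sample id: ", sample, call. = FALSE)
  }
  if (is.na(callable_length) || callable_length <= 0) {
    stop("callable_length must be > 0", call. = FALSE)
  }
  g <- data$geno[!data$sites$is_indel, sample]
  het <- sum(g == 1L, na.rm = TRUE)
  list(sample = sample, het_sites = het, callable_length = callable_length,
       theta = 1000 * het / callable_length)
}

# Maximal homozygous runs on one scaffold's ordered calls.
#
# A run of consecutive called SNPs is valid when every window of
# `window_snps` consecutive SNPs inside it holds at most `max_het`
# heterozygotes; equivalently, no (max_het + 1) heterozygotes fall within
# any window_snps consecutive SNPs. Runs never span inter-SNP gaps larger
# than max_gap. Maximal valid runs are found in one pass from the "bad
# pairs" of heterozygote indices that would violate the window rule:
# a run is valid iff it contains no bad pair, and the rightmost reach of a
# run starting at i is the suffix minimum of (bad-pair end - 1) over bad
# pairs starting at or after i. Runs are then trimmed to their outermost
# homozygous SNPs, filtered by length and SNP count, and overlapping
# trimmed runs merged.
#' Homozygous run detection on position/heterozygosity vectors
#'
#' Low-level worker behind [detect_roh()]; exposed so the detector can be
#' checked against exhaustive-scan oracles on arbitrary toy inputs.
#'
#' @param pos sorted positions (bp) of called SNPs on one scaffold.
#' @param het logical vector: is the call heterozygous.
#' @param window_snps window size in SNPs.
#' @param max_het maximum heterozygotes allowed per window.
#' @param min_length minimum reportable segment length (bp).
#' @param min_snps minimum SNPs spanned by a segment.
#' @param max_gap maximum inter-SNP gap (bp) a segment may bridge.
#' @return data.frame (`start`, `end`, `length`, `n_snps`).
#' @export
find_homozygous_runs <- function(pos, het, window_snps = 50, max_het = 1,
                                 min_length = 1e5, min_snps = 25,
                                 max_gap = 5e5) {
  if (min_length < 1) stop("min_length must be >= 1", call. = FALSE)
  stopifnot(length(pos) == length(het), !is.unsorted(pos))
  empty <- data.frame(start = numeric(), end = numeric(), length = numeric(),
                      n_snps = integer())
  if (!length(pos)) return(empty)

  chunk_id <- cumsum(c(1, diff(pos) > max_gap))
  segs <- list()
  for (ch in unique(chunk_id)) {
    idx <- which(chunk_id == ch)
    p <- pos[idx]
    h <- het[idx]
    m <- length(p)
    het_idx <- which(h)
    # rightmost valid reach for each start index
    reach <- rep(m, m)
    if (length(het_idx) > max_het) {
      a <- het_idx[seq_len(length(het_idx) - max_het)]
      b <- if (max_het > 0) het_idx[-seq_len(max_het)] else het_idx
      bad <- b - a < window_snps
      if (any(bad)) {
        v <- rep(Inf, m)
        v[a[bad]] <- b[bad] - 1L
        reach <- pmin(rev(cummin(rev(v))), m)
      }
    }
    starts <- which(c(TRUE, reach[-1] > reach[-m]))
    for (i in starts) {
      j <- reach[i]
      hom_in <- which(!h[i:j]) + i - 1L
      if (!length(hom_in)) next
      i2 <- hom_in[1]
      j2 <- hom_in[length(hom_in)]
      n_snps <- j2 - i2 + 1L
      len <- p[j2] - p[i2] + 1
      if (n_snps >= min_snps && len >= min_length) {
        segs[[length(segs) + 1L]] <-
          c(start = p[i2], end = p[j2], n = n_snps)
      }
    }
  }
  if (!length(segs)) return(empty)
  segs <- as.data.frame(do.call(rbind, segs))
  segs <- segs[order(segs$start), , drop = FALSE]
  # merge overlapping trimmed runs
  merged <- segs[1, , drop = FALSE]
  if (nrow(segs) > 1) {
    for (k in 2:nrow(segs)) {
      last <- nrow(merged)
      if (segs$start[k] <= merged$end[last]) {
        if (segs$end[k] > merged$end[last]) {
          merged$end[last] <- segs$end[k]
          merged$n[last] <- sum(pos >= merged$start[last] &
                                  pos <= merged$end[last])
        }
      } else {
        merged <- rbind(merged, segs[k, ])
      }
    }
  }
  data.frame(start = merged$start, end = merged$end,
             length = merged$end - merged$start + 1,
             n_snps = as.integer(merged$n))
}

#' Detect runs of homozygosity for one sample
#'
#' A sliding-window heterozygote-density detector: per scaffold, maximal runs
#' of consecutive called SNPs in which every `window_snps`-SNP window
#' contains at most `max_het` heterozygotes are reported, bounded by the
#' outermost homozygous SNPs they contain, subject to a minimum segment
#' length, a minimum SNP count, and a maximum bridgeable inter-SNP gap.
#' Missing genotypes are skipped (they neither break nor support a run).
#'
#' @inheritParams genome_heterozygosity
#' @inheritParams find_homozygous_runs
#' @return data.frame (`sample`, `scaffold`, `start`, `end`, `length`,
#'   `n_snps`), non-overlapping and sorted per scaffold.
#' @export
detect_roh <- function(data, sample, window_snps = 50, max_het = 1,
                       min_length = 1e5, min_snps = 25, max_gap = 5e5) {
  stopifnot(inherits(data, "variant_dataset"))
  if (!sample %in% data$samples$id) {
    stop("unknown sample id: ", sample, call. = FALSE)
  }
  keep <- !data$sites$is_indel & !is.na(data$geno[, sample])
  s <- data$sites[keep, , drop = FALSE]
  g <- data$geno[keep, sample]
  out <- lapply(unique(s$scaffold), function(sc) {
    on_sc <- s$scaffold == sc
    runs <- find_homozygous_runs(s$pos[on_sc], g[on_sc] == 1L,
                                 window_snps = window_snps,
                                 max_het = max_het, min_length = min_length,
                                 min_snps = min_snps, max_gap = max_gap)
    if (!nrow(runs)) return(NULL)
    cbind(data.frame(sample = sample, scaffold = sc,
                     stringsAsFactors = FALSE), runs)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sample = character(), scaffold = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      n_snps = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Fraction of the genome in runs of homozygosity (F_ROH)
#'
#' @param segments data.frame of ROH segments (needs `scaffold`, `start`,
#'   `end`, `length`); must be non-overlapping within scaffolds.
#' @param genome_length total length (bp) of the retained scaffolds.
#' @param min_length minimum segment length (bp) to include; 100 kb captures
#'   all reportable ROH, 2 Mb restricts to long ROH reflecting recent
#'   inbreeding.
#' @return the inbreeding fraction in `[0, 1]`.
#' @export
froh <- function(segments, genome_length, min_length = 1e5) {
  if (genome_length <= 0) stop("genome_length must be > 0", call. = FALSE)
  if (nrow(segments)) {
    segments <- segments[order(segments$scaffold, segments$start), ,
                         drop = FALSE]
    by_scaf <- split(segments, segments$scaffold)
    overlap <- any(vapply(by_scaf, function(d) {
      nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])
    }, logical(1)))
    if (overlap) stop("overlapping ROH segments", call. = FALSE)
  }
  keep <- segments$length >= min_length
  sum(segments$length[keep]) / genome_length
}

#' Per-sample diversity and inbreeding summary
#'
#' Computes heterozygosity and F_ROH at the 100 kb and 2 Mb thresholds for
#' every sample, using the total retained scaffold length as both the
#' callable length for theta (unless overridden) and the denominator for
#' F_ROH.
#'
#' @param data a [variant_dataset()].
#' @param callable_length callable length for theta; defaults to the genome
#'   length.
#' @param ... ROH detector parameters passed to [detect_roh()].
#' @return data.frame with one row per sample: `sample`, `population`,
#'   `era`, `het_sites`, `theta`, `n_roh`, `froh_100kb`, `froh_2mb`.
#' @export
diversity_summary <- function(data, callable_length = genome_length(data),
                              ...) {
  glen <- genome_length(data)
  rows <- lapply(data$samples$id, function(sid) {
    het <- genome_heterozygosity(data, sid, callable_length)
    segs <- detect_roh(data, sid, ...)
    data.frame(
      sample = sid,
      population = data$samples$population[data$samples$id == sid],
      era = data$samples$era[data$samples$id == sid],
      het_sites = het$het_sites, theta = het$theta, n_roh = nrow(segs),
      froh_100kb = froh(segs, glen, 1e5),
      froh_2mb = froh(segs, glen, 2e6),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write per-sample ROH segments as a BED file (0-based half-open)
#'
#' @param segments data.frame from [detect_roh()].
#' @param path output path.
#' @export
write_roh_bed <- function(segments, path) {
  utils::write.table(
    data.frame(segments$scaffold, as.integer(segments$start - 1L),
               as.integer(segments$end), segments$sample),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
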