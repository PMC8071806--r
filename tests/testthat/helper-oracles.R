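# Exhaustive-scan ROH oracle: for every start index, extend the run one SNP
# at a time while every window of `window_snps` consecutive SNPs inside it
# holds <= max_het heterozygotes (checked from cumulative het counts), keep
# maximal runs, trim to outermost homozygous SNPs, filter, and merge by
# interval union. Independent of the bad-pair suffix-min algorithm in the
# package.
oracle_roh <- function(pos, het, window_snps = 50, max_het = 1,
                       min_length = 1e5, min_snps = 25, max_gap = 5e5) {
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
    cs <- c(0, cumsum(h))
    # rightmost j such that the run [i, j] satisfies the window rule
    jmax <- integer(m)
    for (i in seq_len(m)) {
      js <- i:m
      win_lo <- pmax(i - 1L, js - window_snps) # prefix index of window start
      cnt <- cs[js + 1L] - cs[win_lo + 1L]
      viol <- which(cnt > max_het)
      jmax[i] <- if (length(viol)) i + viol[1] - 2L else m
    }
    for (i in seq_len(m)) {
      j <- jmax[i]
      if (j < i) next
      if (i > 1L && jmax[i - 1L] >= j) next # contained in an earlier run
      hom <- which(!h[i:j]) + i - 1L
      if (!length(hom)) next
      i2 <- hom[1]
      j2 <- hom[length(hom)]
      if (j2 - i2 + 1L >= min_snps && p[j2] - p[i2] + 1 >= min_length) {
        segs[[length(segs) + 1L]] <- c(p[i2], p[j2])
      }
    }
  }
  if (!length(segs)) return(empty)
  m <- do.call(rbind, segs)
  red <- IRanges::reduce(IRanges::IRanges(start = m[, 1], end = m[, 2]),
                         min.gapwidth = 0L)
  st <- IRanges::start(red)
  en <- IRanges::end(red)
  n_snps <- vapply(seq_along(st), function(k) {
    sum(pos >= st[k] & pos <= en[k])
  }, integer(1))
  data.frame(start = as.numeric(st), end = as.numeric(en),
             length = as.numeric(en - st + 1), n_snps = n_snps)
}

# textbook Welch t statistic and Welch-Satterthwaite df
oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# random ROH detector instance for property tests
random_roh_instance <- function(max_snps = 500) {
  m <- sample.int(max_snps, 1)
  list(
    pos = sort(sample.int(5e6, m)),
    het = stats::runif(m) < stats::runif(1, 0.02, 0.5),
    window_snps = sample(c(5L, 10L, 20L, 50L), 1),
    max_het = sample(0:2, 1),
    min_length = sample(c(1e3, 1e4, 1e5), 1),
    min_snps = sample(c(2L, 10L, 25L), 1),
    max_gap = sample(c(5e4, 5e5, 5e6), 1)
  )
}
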