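#' Read a multi-sample VCF into a variant dataset
#'
#' Parses a VCF v4.2 (plain or gzipped) written by this package or by a
#' standard caller, using the INFO keys `AA` (ancestral allele), `GERP`
#' (conservation score), `EFF` (effect category) and `GENE` when present,
#' and the per-genotype `DP`/`GQ` FORMAT fields when present. Multiallelic
#' records are dropped with a warning (downstream statistics assume
#' biallelic sites).
#'
#' @param file path to a `.vcf` or `.vcf.gz`.
#' @param metadata optional sample metadata: a data.frame or TSV path with
#'   columns `sample` (or `id`), `population`, `era`, `mean_coverage`.
#' @return a [variant_dataset()].
#' @export
read_vcf <- function(file, metadata = NULL) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  n <- nrow(fix)
  info_chr <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  gerp <- suppressWarnings(as.numeric(info_chr("GERP")))
  eff <- info_chr("EFF")
  eff[is.na(eff)] <- "none"
  aa <- info_chr("AA")
  aa[aa %in% "."] <- NA_character_

  gt <- vcfR::extract.gt(vcf, element = "GT")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- matrix(NA_integer_, n, ncol(gt),
                dimnames = list(NULL, colnames(gt)))
  ok <- !is.na(gt) & a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dos[ok] <- (a1[ok] == "1") + (a2[ok] == "1")

  grab_num <- function(key) {
    if (!grepl(key, vcf@gt[1, "FORMAT"])) return(NULL)
    m <- suppressWarnings(vcfR::extract.gt(vcf, element = key,
                                           as.numeric = TRUE))
    dimnames(m) <- list(NULL, colnames(m))
    m
  }
  dp <- grab_num("DP")
  gq <- grab_num("GQ")

  # contigs from the header; fall back to observed extents
  meta_lines <- vcf@meta
  ctg <- regmatches(meta_lines,
                    regexec("##contig=<ID=([^,>]+),length=([0-9]+)",
                            meta_lines))
  ctg <- ctg[lengths(ctg) == 3]
  contigs <- if (length(ctg)) {
    data.frame(name = vapply(ctg, `[`, "", 2),
               length = as.numeric(vapply(ctg, `[`, "", 3)),
               stringsAsFactors = FALSE)
  } else {
    stats::aggregate(pos ~ scaffold,
                     data.frame(scaffold = fix[, "CHROM"],
                                pos = as.integer(fix[, "POS"])),
                     FUN = max)[, c(1, 2)] |>
      stats::setNames(c("name", "length"))
  }

  samples <- data.frame(id = colnames(gt), population = "unknown",
                        era = "modern", mean_coverage = NA_real_,
                        stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) read_sample_metadata(metadata) else
      as.data.frame(metadata, stringsAsFactors = FALSE)
    if ("sample" %in% names(md) && !"id" %in% names(md)) {
      names(md)[names(md) == "sample"] <- "id"
    }
    i <- match(samples$id, md$id)
    if (anyNA(i)) {
      stop("metadata missing for sample(s): ",
           paste(samples$id[is.na(i)], collapse = ", "), call. = FALSE)
    }
    samples <- md[i, c("id", "population", "era", "mean_coverage")]
  }

  sites <- data.frame(
    scaffold = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    is_indel = nchar(fix[, "REF"]) > 1L | nchar(fix[, "ALT"]) > 1L,
    aa = aa, gerp = gerp, effect = eff, gene = info_chr("GENE"),
    stringsAsFactors = FALSE
  )
  ord <- order(sites$scaffold, sites$pos)
  variant_dataset(sites = sites[ord, , drop = FALSE],
                  geno = dos[ord, , drop = FALSE],
                  samples = samples, contigs = contigs,
                  dp = if (!is.null(dp)) dp[ord, , drop = FALSE],
                  gq = if (!is.null(gq)) gq[ord, , drop = FALSE])
}

#' Write a variant dataset to VCF v4.2 (gzipped)
#'
#' @param data a [variant_dataset()].
#' @param file output path; written gzip-compressed, so use a `.vcf.gz` name.
#' @return `file`, invisibly.
#' @export
write_vcf <- function(data, file) {
  s <- data$sites
  n <- nrow(s)
  info <- character(n)
  add <- function(info, key, val) {
    has <- !is.na(val)
    piece <- paste0(key, "=", val)
    ifelse(has, ifelse(nzchar(info), paste(info, piece, sep = ";"), piece),
           info)
  }
  gerp_chr <- ifelse(is.na(s$gerp), NA_character_,
                     formatC(s$gerp, digits = 6, format = "g"))
  eff_chr <- ifelse(s$effect == "none", NA_character_, s$effect)
  info <- add(info, "AA", s$aa)
  info <- add(info, "GERP", gerp_chr)
  info <- add(info, "EFF", eff_chr)
  info <- add(info, "GENE", s$gene)
  info[!nzchar(info)] <- "."

  fix <- cbind(CHROM = s$scaffold, POS = as.character(s$pos), ID = ".",
               REF = s$ref, ALT = s$alt, QUAL = ".", FILTER = "PASS",
               INFO = info)
  gt_chr <- matrix("./.", n, ncol(data$geno), dimnames = dimnames(data$geno))
  gt_chr[!is.na(data$geno) & data$geno == 0L] <- "0/0"
  gt_chr[!is.na(data$geno) & data$geno == 1L] <- "0/1"
  gt_chr[!is.na(data$geno) & data$geno == 2L] <- "1/1"
  fmt <- "GT"
  if (!is.null(data$dp)) {
    gt_chr[] <- paste(gt_chr, ifelse(is.na(data$dp), ".",
                                     as.character(data$dp)), sep = ":")
    fmt <- paste0(fmt, ":DP")
  }
  if (!is.null(data$gq)) {
    gt_chr[] <- paste(gt_chr, ifelse(is.na(data$gq), ".",
                                     as.character(data$gq)), sep = ":")
    fmt <- paste0(fmt, ":GQ")
  }
  gt <- cbind(FORMAT = rep(fmt, n), gt_chr)

  meta <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", data$contigs$name,
            as.integer(data$contigs$length)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=GERP,Number=1,Type=Float,Description=\"GERP conservation score\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect category\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  )
  out <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                      meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = file)
  invisible(file)
}

#' Sample metadata TSV
#'
#' @param path TSV with columns `sample` (or `id`), `population`, `era`,
#'   `mean_coverage`.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if ("sample" %in% names(md) && !"id" %in% names(md)) {
    names(md)[names(md) == "sample"] <- "id"
  }
  md
}

#' Site masks (CpG, repeats, sex-linked scaffolds)
#'
#' A mask is a set of 1-based inclusive intervals plus a list of scaffolds to
#' exclude entirely (e.g., sex-linked scaffolds identified upstream).
#'
#' @param intervals data.frame (`scaffold`, `start`, `end`), 1-based
#'   inclusive.
#' @param exclude_scaffolds character vector of scaffold names.
#' @return an object of class `site_mask`.
#' @export
site_mask <- function(intervals = NULL, exclude_scaffolds = character()) {
  if (is.null(intervals)) {
    intervals <- data.frame(scaffold = character(), start = numeric(),
                            end = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(intervals = intervals,
                 exclude_scaffolds = exclude_scaffolds),
            class = "site_mask")
}

#' @rdname site_mask
#' @param ... `site_mask` objects to combine.
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  site_mask(
    intervals = do.call(rbind, lapply(masks, `[[`, "intervals")),
    exclude_scaffolds = unique(unlist(lapply(masks, `[[`,
                                             "exclude_scaffolds")))
  )
}

#' Locate CpG dinucleotides in a reference sequence
#'
#' Every position where a C is immediately followed by a G is masked, on both
#' bases of the dinucleotide. Matching is case-insensitive; ambiguous bases
#' (N) never match.
#'
#' @param reference a `Biostrings::DNAStringSet` or path to a FASTA file.
#' @return a [site_mask()] of 2-bp intervals.
#' @export
find_cpg_sites <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  names(reference) <- sub("\\s.*$", "", names(reference))
  hits <- Biostrings::vmatchPattern("CG", reference, fixed = TRUE)
  pieces <- lapply(seq_along(reference), function(i) {
    st <- IRanges::start(hits[[i]])
    if (!length(st)) return(NULL)
    data.frame(scaffold = names(reference)[i], start = st, end = st + 1L,
               stringsAsFactors = FALSE)
  })
  site_mask(intervals = do.call(rbind, pieces))
}

#' Read a BED interval file as a site mask
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED(-like) file with at least 3 columns.
#' @return a [site_mask()].
#' @export
read_bed_mask <- function(path) {
  if (file.size(path) == 0) return(site_mask())
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  site_mask(intervals = data.frame(scaffold = b[[1]], start = b[[2]] + 1L,
                                   end = b[[3]], stringsAsFactors = FALSE))
}

#' Read gene models from a BED-like file
#'
#' @param path BED file with columns scaffold, start, end, gene id.
#' @return data.frame (`gene`, `scaffold`, `start`, `end`), 1-based
#'   inclusive.
#' @export
read_gene_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(gene = b[[4]], scaffold = b[[1]], start = b[[2]] + 1L,
             end = b[[3]], stringsAsFactors = FALSE)
}

#' Read a per-site GERP score track and attach it to a dataset
#'
#' The track is a BED-like TSV (scaffold, 0-based start, end, score) with one
#' row per scored base.
#'
#' @param path track path.
#' @return data.frame (`scaffold`, `pos`, `score`), 1-based.
#' @export
read_gerp_track <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(scaffold = b[[1]], pos = b[[3]], score = b[[4]],
             stringsAsFactors = FALSE)
}

#' @rdname read_gerp_track
#' @param data a [variant_dataset()].
#' @param track data.frame from `read_gerp_track()`.
#' @export
attach_gerp <- function(data, track) {
  key <- paste(track$scaffold, track$pos)
  i <- match(paste(data$sites$scaffold, data$sites$pos), key)
  data$sites$gerp <- track$score[i]
  data
}

#' Apply the study's site and genotype filters
#'
#' Applies, in order: (1) per-genotype depth filter -- calls with depth below
#' `depth_fraction` of that sample's mean coverage are set to missing;
#' (2) per-genotype quality filter -- calls with quality below `min_gq` are
#' set to missing; (3) removal of SNPs within `indel_window` bp (inclusive on
#' both sides) of any indel record, and of the indel records themselves;
#' (4) removal of masked positions (CpG, repeats) and of all sites on
#' excluded (sex-linked) scaffolds, which are also dropped from the contig
#' table. Retained genotypes are never altered, only removed or set missing,
#' so the operation is idempotent and order-preserving.
#'
#' @param data a [variant_dataset()].
#' @param mask optional [site_mask()].
#' @param min_gq minimum genotype quality (default 30); `NULL` disables.
#' @param depth_fraction minimum depth as a fraction of the sample's mean
#'   coverage (default 1/3); `NULL` disables.
#' @param indel_window bp distance around indels within which SNPs are
#'   removed (inclusive).
#' @param exclude_scaffolds extra scaffold names to drop.
#' @return the filtered `variant_dataset`, with a `filter_log` attribute
#'   (data.frame of per-rule removal counts).
#' @export
apply_site_filters <- function(data, mask = NULL, min_gq = 30,
                               depth_fraction = 1 / 3, indel_window = 5,
                               exclude_scaffolds = character()) {
  stopifnot(inherits(data, "variant_dataset"))
  log <- list()
  geno <- data$geno

  if (!is.null(depth_fraction) && !is.null(data$dp)) {
    if (anyNA(data$samples$mean_coverage)) {
      bad <- data$samples$id[is.na(data$samples$mean_coverage)]
      stop("depth filtering requested but mean_coverage missing for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    thr <- matrix(rep(data$samples$mean_coverage * depth_fraction,
                      each = nrow(geno)), nrow = nrow(geno))
    low <- !is.na(data$dp) & data$dp < thr & !is.na(geno)
    log$genotypes_low_depth <- sum(low)
    geno[low] <- NA_integer_
  }
  if (!is.null(min_gq) && !is.null(data$gq)) {
    low <- !is.na(data$gq) & data$gq < min_gq & !is.na(geno)
    log$genotypes_low_quality <- sum(low)
    geno[low] <- NA_integer_
  }

  s <- data$sites
  drop <- rep(FALSE, nrow(s))

  # SNPs within +/- indel_window bp (inclusive) of an indel record
  near_indel <- rep(FALSE, nrow(s))
  if (any(s$is_indel)) {
    for (sc in unique(s$scaffold[s$is_indel])) {
      ip <- sort(s$pos[s$is_indel & s$scaffold == sc])
      on_sc <- which(s$scaffold == sc & !s$is_indel)
      if (!length(on_sc)) next
      p <- s$pos[on_sc]
      k <- findInterval(p, ip)
      d_left <- ifelse(k >= 1L, p - ip[pmax(k, 1L)], Inf)
      d_right <- ifelse(k < length(ip), ip[pmin(k + 1L, length(ip))] - p, Inf)
      near_indel[on_sc] <- pmin(d_left, d_right) <= indel_window
    }
  }
  log$snps_near_indel <- sum(near_indel & !drop)
  drop <- drop | near_indel
  log$indel_records <- sum(s$is_indel & !drop)
  drop <- drop | s$is_indel

  excl <- exclude_scaffolds
  masked <- rep(FALSE, nrow(s))
  if (!is.null(mask)) {
    excl <- unique(c(excl, mask$exclude_scaffolds))
    iv <- mask$intervals
    if (!is.null(iv) && nrow(iv)) {
      hit <- interval_overlap(s$scaffold, s$pos, iv)
      masked <- !is.na(hit)
    }
  }
  log$masked_positions <- sum(masked & !drop)
  drop <- drop | masked
  on_excl <- s$scaffold %in% excl
  log$excluded_scaffold_sites <- sum(on_excl & !drop)
  drop <- drop | on_excl

  out <- variant_dataset(
    sites = s[!drop, , drop = FALSE],
    geno = geno[!drop, , drop = FALSE],
    samples = data$samples,
    contigs = data$contigs[!data$contigs$name %in% excl, , drop = FALSE],
    dp = if (!is.null(data$dp)) data$dp[!drop, , drop = FALSE],
    gq = if (!is.null(data$gq)) data$gq[!drop, , drop = FALSE]
  )
  attr(out, "filter_log") <- data.frame(
    rule = names(log), n_removed = as.integer(unlist(log)),
    stringsAsFactors = FALSE
  )
  out
}

#' @rdname apply_site_filters
#' @export
filter_log <- function(data) attr(data, "filter_log")

# write a data.frame as TSV (no quoting, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a self-contained file bundle
#'
#' Emits a reference FASTA (random background sequence patched with the REF
#' alleles, regenerated deterministically from `seed`), a gzipped VCF with
#' the `AA`/`GERP`/`EFF`/`GENE` INFO keys, gene and repeat BED files
#' (0-based half-open), a per-site GERP score track, the sample metadata TSV
#' and the generator's truth tables.
#'
#' @param data a [variant_dataset()].
#' @param truth the matching `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @param seed seed for the background reference sequence.
#' @return named character vector of file paths.
#' @export
write_dataset_bundle <- function(data, truth, dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(seq_len(nrow(data$contigs)), function(i) {
    chars <- sample(bases, data$contigs$length[i], replace = TRUE)
    on_sc <- which(data$sites$scaffold == data$contigs$name[i])
    for (k in on_sc) {
      ref <- strsplit(data$sites$ref[k], "")[[1]]
      chars[data$sites$pos[k] + seq_along(ref) - 1L] <- ref
    }
    paste(chars, collapse = "")
  })
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  names(ref) <- data$contigs$name
  paths <- c(
    reference = file.path(dir, "reference.fa"),
    vcf = file.path(dir, "variants.vcf.gz"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.bed"),
    repeats = file.path(dir, "repeats.bed"),
    gerp = file.path(dir, "gerp.bed"),
    truth_tracts = file.path(dir, "truth_tracts.tsv"),
    truth_f = file.path(dir, "truth_f.tsv"),
    truth_freq = file.path(dir, "truth_freq.tsv"),
    truth_sites = file.path(dir, "truth_site_labels.tsv")
  )
  Biostrings::writeXStringSet(ref, paths["reference"])
  write_vcf(data, paths["vcf"])
  write_tsv(data$samples, paths["samples"])
  g <- truth$genes
  utils::write.table(
    data.frame(g$scaffold, as.integer(g$start - 1L), as.integer(g$end),
               g$gene),
    paths["genes"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  r <- truth$repeats
  utils::write.table(
    data.frame(r$scaffold, as.integer(r$start - 1L), as.integer(r$end)),
    paths["repeats"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  scored <- !is.na(data$sites$gerp)
  utils::write.table(
    data.frame(data$sites$scaffold[scored],
               as.integer(data$sites$pos[scored] - 1L),
               as.integer(data$sites$pos[scored]),
               formatC(data$sites$gerp[scored], digits = 6, format = "g")),
    paths["gerp"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_tsv(truth$tracts, paths["truth_tracts"])
  write_tsv(truth$true_f, paths["truth_f"])
  write_tsv(cbind(data$sites[c("scaffold", "pos")],
                  as.data.frame(truth$freq)), paths["truth_freq"])
  write_tsv(truth$site_labels, paths["truth_sites"])
  paths
}
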