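# Build a small in-memory dataset from a genotype matrix. Rows are sites in
# position order, columns samples; defaults give one scaffold, REF = A,
# ALT = G, ancestral = REF (so ALT dosage == derived dosage).
make_toy_dataset <- function(geno, pos = NULL, scaffold = "s1",
                             contig_length = NULL, populations = NULL,
                             eras = NULL, mean_coverage = 20,
                             gerp = NA_real_, effect = "none",
                             gene = NA_character_, aa = NULL,
                             is_indel = FALSE, dp = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(colnames(geno))) {
    colnames(geno) <- sprintf("smp%02d", seq_len(ncol(geno)))
  }
  if (is.null(populations)) populations <- rep("pop1", ncol(geno))
  if (is.null(eras)) eras <- rep("modern", ncol(geno))
  if (is.null(contig_length)) contig_length <- max(pos) + 1000
  ref <- rep("A", n)
  alt <- rep("G", n)
  if (is.null(aa)) aa <- ref
  variant_dataset(
    sites = data.frame(scaffold = scaffold, pos = pos, ref = ref, alt = alt,
                       is_indel = rep_len(is_indel, n), aa = rep_len(aa, n),
                       gerp = rep_len(gerp, n),
                       effect = rep_len(effect, n),
                       gene = rep_len(gene, n), stringsAsFactors = FALSE),
    geno = geno,
    samples = data.frame(id = colnames(geno), population = populations,
                         era = eras,
                         mean_coverage = rep_len(mean_coverage, ncol(geno)),
                         stringsAsFactors = FALSE),
    contigs = data.frame(name = unique(scaffold),
                         length = contig_length[seq_along(unique(scaffold))],
                         stringsAsFactors = FALSE),
    dp = dp, gq = gq
  )
}

# compact simulation config for fast tests
small_sim_config <- function(seed = 1, n_sites = 4000, ...) {
  simulation_config(
    seed = seed,
    scaffolds = data.frame(name = c("s1", "s2"), length = c(4e6, 4e6)),
    n_sites = n_sites, n_genes = 30,
    roh_lengths = list(short = c(1e5, 2e5), long = c(2e5, 5e5),
                       p_short = 0.6), ...
  )
}
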