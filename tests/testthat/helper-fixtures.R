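# Shared builders for small in-code fixtures.

# A pileup for one contig from explicit per-population count matrices
# (rows = positions, columns = A, C, G, T).
make_pileup <- function(counts_pop1, counts_pop2, contig_id = "ctg") {
  stopifnot(nrow(counts_pop1) == nrow(counts_pop2))
  pu <- new_contig_pileup(contig_id, nrow(counts_pop1))
  colnames(counts_pop1) <- colnames(counts_pop2) <- c("A", "C", "G", "T")
  pu$counts$pop1 <- counts_pop1
  pu$counts$pop2 <- counts_pop2
  pu
}

# Count matrix with all reads agreeing on one base sequence, given depth.
mono_counts <- function(seq, depth) {
  b <- strsplit(seq, "")[[1]]
  m <- matrix(0L, length(b), 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(b), match(b, c("A", "C", "G", "T")))] <- as.integer(depth)
  m
}

# Reverse-translate a protein with fixed codon choices (deterministic).
reverse_translate <- function(protein) {
  first_codon <- vapply(strsplit(protein, "")[[1]], function(aa) {
    names(oracle_codon_table)[match(aa, oracle_codon_table)]
  }, "")
  paste(first_codon, collapse = "")
}

small_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_contigs = 3L, contig_length = 300L, depth_mean = 10,
                   polymorphic_site_rate = 0.01, fixed_diff_rate = 0.01,
                   error_rate = 0, q_low_fraction = 0,
                   outgroup_protein_divergence = 0, seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, args))
}
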