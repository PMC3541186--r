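# Independent oracles used to check the package's implementations.
# Each is written from first principles and shares no code with R/.

# Brute-force minimal minor-allele count: direct summation of binomial
# terms, no pbinom.
oracle_min_minor_count <- function(D, p = 1e-4, L = 1000, alpha = 0.01,
                                   f_min = 0.05) {
  for (k in 1:D) {
    p_site <- 0
    for (j in k:D)
      p_site <- p_site + choose(D, j) * p^j * (1 - p)^(D - j)
    p_any <- 1 - (1 - p_site)^L
    if (p_any <= alpha && k / D >= f_min) return(k)
  }
  NA_integer_
}

# Two-sided Fisher p by exhaustive enumeration of margin-preserving tables.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  p_obs <- prob(a)
  sum(vapply(xs, prob, 0)[vapply(xs, prob, 0) <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by exhaustive enumeration of draws (tiny N).
oracle_hyper_upper <- function(k, K, N, n) {
  universe <- seq_len(N)
  members <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% members, nrow = n))
  mean(hits >= k)
}

# Independent standard genetic code, written out by amino acid.
oracle_codon_table <- local({
  tab <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  tab
})

oracle_classify_codon_pair <- function(c1, c2) {
  a1 <- oracle_codon_table[[c1]]
  a2 <- oracle_codon_table[[c2]]
  if (a1 == a2) "synonymous"
  else if (xor(a1 == "*", a2 == "*")) "nonsense"
  else "nonsynonymous"
}

# Smith-Waterman local alignment score: match +1, mismatch -2, linear gap
# cost 2 per base, N neutral against everything.
oracle_sw_score <- function(read, contig) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(contig, "")[[1]]
  n <- length(a); m <- length(b)
  sub <- function(x, y) if (x == "N" || y == "N") 0 else if (x == y) 1 else -2
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1, j + 1] <- max(0,
        H[i, j] + sub(a[i], b[j]),
        H[i, j + 1] - 2,
        H[i + 1, j] - 2)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
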