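.translate_seq <- function(seq, from = 1L, to = nchar(seq)) {
  len <- to - from + 1L
  n_codons <- len %/% 3L
  if (n_codons <= 0L) return(character(0))
  starts <- from + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"   # codons containing N or other ambiguity
  unname(aa)
}

#' Per-population consensus sequence from a pileup
#'
#' At each site the population's majority allele is taken; sites whose
#' depth falls below `d_min` keep the reference base and are flagged
#' untrusted, and exact count ties also fall back to the reference base
#' with an ambiguity flag, so the consensus is deterministic. At a fixed
#' difference each population's consensus carries its own allele.
#'
#' @param pileup A `contig_pileup`.
#' @param reference Character scalar, the contig reference sequence.
#' @param thresholds A [call_thresholds()].
#' @return Named list (one element per population), each a list with
#'   `seq`, `untrusted` (logical per site) and `ambiguous` (logical).
#' @export
consensus_per_population <- function(pileup, reference,
                                     thresholds = call_thresholds()) {
  stopifnot(inherits(pileup, "contig_pileup"),
            nchar(reference) == pileup$length)
  ref <- strsplit(reference, "")[[1]]
  out <- list()
  for (pop in pileup$pops) {
    m <- pileup$counts[[pop]]
    d <- rowSums(m)
    major_idx <- max.col(m, ties.method = "first")
    major_count <- m[cbind(seq_len(nrow(m)), major_idx)]
    tie <- rowSums(m == major_count) > 1L & major_count > 0L
    untrusted <- d < thresholds$d_min
    cons <- ref
    use <- !untrusted & !tie
    cons[use] <- DNA_BASES[major_idx[use]]
    out[[pop]] <- list(seq = paste(cons, collapse = ""),
                       untrusted = untrusted,
                       ambiguous = tie & !untrusted)
  }
  out
}

#' Project a contig onto its coding frame via outgroup protein alignment
#'
#' Translates the three forward frames of the contig (inserts are
#' directional, so reverse frames are off by default), aligns each
#' translation locally to the outgroup protein under BLOSUM62, and keeps
#' the best-scoring frame. The aligned region defines the coding interval;
#' contig codons outside it are treated as non-coding and excluded from
#' substitution analysis. The projection is rejected (returns `NULL`) when
#' the best alignment has fewer than `min_aligned` aligned residues or less
#' than `min_identity` identity, which guards against spurious frames.
#'
#' @param seq Character scalar: contig (or consensus) nucleotide sequence.
#' @param outgroup_protein Character scalar: outgroup amino-acid sequence.
#' @param min_identity Identity floor over the aligned region (default 0.4).
#' @param min_aligned Minimum aligned residues (default 30).
#' @param both_strands If `TRUE`, also try the three reverse-complement
#'   frames (for non-directional foreign data).
#' @return `NULL`, or a list of class `coding_projection` with
#'   `frame` (0-2), `strand`, `cds_start`/`cds_end` (1-based contig
#'   coordinates of the aligned codon span), `codon_offset` (codon index in
#'   the frame of the first aligned codon, 1-based), `n_codons`,
#'   `outgroup_map` (integer vector: outgroup residue index per aligned
#'   codon, `NA` at outgroup gaps), `aa_outgroup` (outgroup residue per
#'   aligned codon), `identity`, `score`.
#' @export
project_coding_frame <- function(seq, outgroup_protein,
                                 min_identity = 0.4, min_aligned = 30L,
                                 both_strands = FALSE) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  strands <- if (both_strands) c("+", "-") else "+"
  best <- NULL
  og <- strsplit(outgroup_protein, "")[[1]]
  for (strand in strands) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (frame in 0:2) {
      prot <- .translate_seq(s, from = frame + 1L)
      if (!length(prot)) next
      pstr <- paste(prot, collapse = "")
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pstr), Biostrings::AAString(outgroup_protein),
        type = "local", substitutionMatrix = BLOSUM62,
        gapOpening = 10, gapExtension = 4)
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, frame = frame, strand = strand, aln = aln,
                     prot = prot)
    }
  }
  if (is.null(best)) return(NULL)
  aln <- best$aln
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  n_aligned <- sum(p != "-" & s != "-")
  identity <- if (n_aligned > 0) sum(p == s & p != "-") / n_aligned else 0
  if (n_aligned < min_aligned || identity < min_identity) return(NULL)
  pi <- Biostrings::start(Biostrings::pattern(aln)) - 1L + cumsum(p != "-")
  si <- Biostrings::start(Biostrings::subject(aln)) - 1L + cumsum(s != "-")
  keep <- p != "-"                      # one entry per aligned contig codon
  codon_idx <- pi[keep]
  outgroup_map <- ifelse(s[keep] == "-", NA_integer_, si[keep])
  aa_out <- ifelse(s[keep] == "-", NA_character_, s[keep])
  first_c <- codon_idx[1L]
  last_c <- codon_idx[length(codon_idx)]
  structure(list(
    frame = best$frame, strand = best$strand,
    cds_start = best$frame + 3L * (first_c - 1L) + 1L,
    cds_end = best$frame + 3L * last_c,
    codon_offset = first_c,
    n_codons = last_c - first_c + 1L,
    codon_index = codon_idx,
    outgroup_map = outgroup_map,
    aa_outgroup = aa_out,
    identity = identity, score = best$score),
    class = "coding_projection")
}

# outgroup residue aligned to codon ci (frame codon index), NA if none
.outgroup_aa_at <- function(projection, ci) {
  j <- match(ci, projection$codon_index)
  if (is.na(j)) NA_character_ else projection$aa_outgroup[j]
}

#' Classify a codon substitution as synonymous, non-synonymous or nonsense
#'
#' Both codons are translated under the standard genetic code: identical
#' translations are synonymous, a stop codon on exactly one side is
#' nonsense, and any other difference is non-synonymous. Codons containing
#' ambiguous bases cannot be classified and yield `NA`.
#'
#' @param codon_pop1,codon_pop2 Character scalars of length-3 codons
#'   differing at one or more bases.
#' @return `"synonymous"`, `"nonsynonymous"`, `"nonsense"`, or
#'   `NA_character_` for ambiguous input.
#' @examples
#' classify_substitution("CTG", "CTA")  # synonymous (Leu/Leu)
#' classify_substitution("TAC", "TAA")  # nonsense
#' @export
classify_substitution <- function(codon_pop1, codon_pop2) {
  stopifnot(nchar(codon_pop1) == 3L, nchar(codon_pop2) == 3L)
  if (grepl("[^ACGT]", codon_pop1) || grepl("[^ACGT]", codon_pop2))
    return(NA_character_)
  aa1 <- unname(Biostrings::GENETIC_CODE[codon_pop1])
  aa2 <- unname(Biostrings::GENETIC_CODE[codon_pop2])
  if (aa1 == aa2) "synonymous"
  else if (xor(aa1 == "*", aa2 == "*")) "nonsense"
  else "nonsynonymous"
}

#' Orient an amino-acid substitution by outgroup parsimony
#'
#' The outgroup residue stands in for the ancestral state: if it matches
#' one population's residue, the mutation is assigned to the other
#' population's lineage; if it differs from both (or no outgroup residue is
#' aligned at the position), the substitution cannot be oriented.
#'
#' @param aa_pop1,aa_pop2 Residues of the two populations (must differ).
#' @param aa_outgroup Outgroup residue, or `NA` when unaligned.
#' @return `"pop1"`, `"pop2"`, or `"unoriented"`.
#' @examples
#' orient_substitution("S", "A", "A")  # "pop1"
#' orient_substitution("S", "A", "T")  # "unoriented"
#' @export
orient_substitution <- function(aa_pop1, aa_pop2, aa_outgroup) {
  stopifnot(aa_pop1 != aa_pop2)
  if (is.na(aa_outgroup)) return("unoriented")
  if (aa_outgroup == aa_pop2) "pop1"
  else if (aa_outgroup == aa_pop1) "pop2"
  else "unoriented"
}

#' Is an amino-acid replacement radical?
#'
#' A replacement is radical when the two residues fall in different classes
#' of the six-class physicochemical scheme (see [aa_class_scheme()]), and
#' conservative when they share a class.
#'
#' @param aa1,aa2 One-letter codes of standard amino acids.
#' @param scheme An [aa_class_scheme()].
#' @return Logical.
#' @examples
#' is_radical("D", "E")  # FALSE, both acidic
#' is_radical("K", "E")  # TRUE, basic vs acidic
#' @export
is_radical <- function(aa1, aa2, scheme = aa_class_scheme()) {
  if (!aa1 %in% names(scheme) || !aa2 %in% names(scheme))
    stop("non-standard amino acid: ", aa1, "/", aa2)
  unname(scheme[aa1] != scheme[aa2])
}

#' Analyse fixed differences in coding context
#'
#' Projects each contig's fixed differences onto its coding frame, groups
#' nucleotide changes by codon (a codon hit by two nucleotide changes is a
#' single amino-acid event but counts twice at the nucleotide level),
#' classifies each event as synonymous / non-synonymous / nonsense, orients
#' it by outgroup parsimony and flags radical replacements. Codons
#' containing ambiguous bases, and fixed differences outside the aligned
#' coding interval, are skipped and counted.
#'
#' @param sites Site classification table from [scan_pileups()] (only rows
#'   with class `fixed_difference` are used).
#' @param consensus Named list of per-contig consensus pairs from
#'   [consensus_per_population()].
#' @param projections Named list of `coding_projection` objects (contigs
#'   without an accepted projection are skipped).
#' @param scheme An [aa_class_scheme()].
#' @return A list with `substitutions` (data frame: `contig`,
#'   `codon_index`, `contig_pos`, `n_nuc_changes`, `aa_pop1`, `aa_pop2`,
#'   `aa_outgroup`, `kind`, `lineage`, `radical`) and counts of skipped
#'   events (`n_noncoding`, `n_ambiguous`, `n_unprojected`).
#' @export
analyze_substitutions <- function(sites, consensus, projections,
                                  scheme = aa_class_scheme()) {
  fd <- sites[sites$class == "fixed_difference", , drop = FALSE]
  empty <- data.frame(contig = character(0), codon_index = integer(0),
                      contig_pos = integer(0), n_nuc_changes = integer(0),
                      aa_pop1 = character(0), aa_pop2 = character(0),
                      aa_outgroup = character(0), kind = character(0),
                      lineage = character(0), radical = logical(0))
  n_noncoding <- 0L; n_ambiguous <- 0L; n_unprojected <- 0L
  rows <- list()
  for (cid in unique(fd$contig)) {
    pr <- projections[[cid]]
    sub <- fd[fd$contig == cid, ]
    if (is.null(pr)) { n_unprojected <- n_unprojected + nrow(sub); next }
    cons <- consensus[[cid]]
    s1 <- cons[[1L]]$seq
    s2 <- cons[[2L]]$seq
    in_cds <- sub$pos >= pr$cds_start & sub$pos <= pr$cds_end
    n_noncoding <- n_noncoding + sum(!in_cds)
    sub <- sub[in_cds, , drop = FALSE]
    if (!nrow(sub)) next
    ci <- (sub$pos - pr$frame - 1L) %/% 3L + 1L   # codon index in frame
    for (cx in unique(ci)) {
      pos_in <- sub$pos[ci == cx]
      cstart <- pr$frame + 3L * (cx - 1L) + 1L
      c1 <- substr(s1, cstart, cstart + 2L)
      c2 <- substr(s2, cstart, cstart + 2L)
      kind <- classify_substitution(c1, c2)
      if (is.na(kind)) { n_ambiguous <- n_ambiguous + 1L; next }
      aa1 <- unname(Biostrings::GENETIC_CODE[c1])
      aa2 <- unname(Biostrings::GENETIC_CODE[c2])
      aa_out <- .outgroup_aa_at(pr, cx)
      lineage <- if (kind == "synonymous") NA_character_
                 else orient_substitution(aa1, aa2, aa_out)
      radical <- if (kind == "nonsynonymous" &&
                     aa1 %in% names(scheme) && aa2 %in% names(scheme))
        is_radical(aa1, aa2, scheme) else NA
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cid, codon_index = cx, contig_pos = min(pos_in),
        n_nuc_changes = length(pos_in),
        aa_pop1 = aa1, aa_pop2 = aa2,
        aa_outgroup = if (is.na(aa_out)) NA_character_ else aa_out,
        kind = kind, lineage = lineage, radical = radical)
    }
  }
  list(substitutions = if (length(rows)) do.call(rbind, rows) else empty,
       n_noncoding = n_noncoding, n_ambiguous = n_ambiguous,
       n_unprojected = n_unprojected)
}

#' Detect premature stop codons fixed in one population
#'
#' Translates each population's consensus over the aligned coding interval
#' and reports codons at which exactly one population carries an in-frame
#' stop upstream of the outgroup-aligned C-terminus (a stop at the terminal
#' aligned codon is not premature). The truncation fraction is the share of
#' the aligned protein lost downstream of the stop.
#'
#' @param projection A `coding_projection`.
#' @param consensus A per-contig consensus pair from
#'   [consensus_per_population()].
#' @return Data frame with `codon_index`, `population`,
#'   `truncation_fraction`.
#' @export
detect_premature_stop <- function(projection, consensus) {
  pops <- names(consensus)
  first_c <- projection$codon_offset
  last_c <- first_c + projection$n_codons - 1L
  aa <- lapply(consensus, function(cp)
    .translate_seq(cp$seq, from = projection$frame + 3L * (first_c - 1L) + 1L,
                   to = projection$frame + 3L * last_c))
  n <- projection$n_codons
  out <- data.frame(codon_index = integer(0), population = character(0),
                    truncation_fraction = numeric(0))
  for (k in seq_len(n - 1L)) {      # terminal aligned codon is not premature
    stops <- vapply(aa, function(a) a[k] == "*", TRUE)
    if (sum(stops) == 1L) {
      out <- rbind(out, data.frame(
        codon_index = first_c + k - 1L,
        population = pops[which(stops)],
        truncation_fraction = (n - k) / n))
    }
  }
  out
}

#' Tabulate substitutions by kind, lineage and radical status
#'
#' Produces the bookkeeping of a two-population divergence scan: total
#' fixed nucleotide differences in coding intervals, synonymous vs
#' non-synonymous vs nonsense amino-acid events, the lineage split of the
#' oriented events, and the radical subset by lineage.
#'
#' @param substitutions The `substitutions` data frame from
#'   [analyze_substitutions()].
#' @return A list with `n_nucleotide` (fixed nucleotide differences),
#'   `n_aa_events`, `by_kind`, `lineage_counts` (pop1/pop2/unoriented over
#'   non-synonymous plus nonsense events), `radical_total` and
#'   `radical_by_lineage`, and the full `kind_lineage_radical` table.
#' @export
tabulate_lineage_counts <- function(substitutions) {
  s <- substitutions
  lineage <- factor(ifelse(is.na(s$lineage), "unoriented", s$lineage),
                    levels = c("pop1", "pop2", "unoriented"))
  kind <- factor(s$kind, levels = c("synonymous", "nonsynonymous", "nonsense"))
  radical <- factor(ifelse(is.na(s$radical), "n/a",
                           ifelse(s$radical, "radical", "conservative")),
                    levels = c("radical", "conservative", "n/a"))
  aa_changing <- s$kind %in% c("nonsynonymous", "nonsense")
  list(
    n_nucleotide = sum(s$n_nuc_changes),
    n_aa_events = sum(aa_changing),
    by_kind = table(kind),
    lineage_counts = table(lineage[aa_changing]),
    radical_total = sum(s$radical %in% TRUE),
    radical_by_lineage = table(lineage[s$radical %in% TRUE]),
    kind_lineage_radical = table(kind, lineage, radical))
}
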