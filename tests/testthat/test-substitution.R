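test_that("consensus takes majorities, falls back to reference, and flags ties", {
  ref <- "ACGTACGT"
  m1 <- mono_counts(ref, 5)                      # clean majority
  m2 <- mono_counts(ref, 5)
  m2[3, ] <- c(0L, 3L, 3L, 0L)                   # tie C/G at site 3
  m2[5, ] <- c(2L, 0L, 0L, 0L)                   # below d_min at site 5
  m2[8, ] <- c(6L, 0L, 0L, 0L)                   # fixed T -> A at site 8
  cons <- consensus_per_population(make_pileup(m1, m2), ref)
  expect_identical(cons$pop1$seq, ref)
  expect_identical(substr(cons$pop2$seq, 3, 3), "G")  # reference base kept
  expect_true(cons$pop2$ambiguous[3])
  expect_true(cons$pop2$untrusted[5])
  expect_identical(substr(cons$pop2$seq, 5, 5), "A")  # reference base kept
  expect_identical(substr(cons$pop2$seq, 8, 8), "A")  # own fixed allele
})

test_that("frame selection recovers exact reverse-translations and shifts", {
  set.seed(41)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  protein <- paste(sample(aas, 60, TRUE), collapse = "")
  cds <- reverse_translate(protein)
  pr0 <- project_coding_frame(cds, protein)
  expect_identical(pr0$frame, 0L)
  expect_identical(pr0$cds_start, 1L)
  expect_identical(pr0$cds_end, 180L)
  expect_identical(pr0$identity, 1)

  pr1 <- project_coding_frame(paste0("G", cds), protein)
  expect_identical(pr1$frame, 1L)
  expect_identical(pr1$cds_start, 2L)
})

test_that("non-coding flanks are excluded from the coding interval", {
  cfg <- small_sim_config(n_contigs = 3, contig_length = 240,
                          utr5_length = 50, utr3_length = 55)
  ref <- generate_reference(cfg)
  for (ct in ref$contigs) {
    pr <- project_coding_frame(ct$seq, ct$outgroup_protein)
    expect_false(is.null(pr))
    # the aligned interval must fall inside the true CDS; random UTRs can
    # shorten the local alignment by at most a few terminal codons
    expect_gte(pr$cds_start, ct$cds_start - 3L)
    expect_lte(pr$cds_end, ct$cds_end + 3L)
    expect_identical((pr$cds_start - ct$cds_start) %% 3L, 0L)
    expect_gt(pr$n_codons, 70L)
  }
})

test_that("codon substitution classification matches the genetic-code oracle", {
  expect_identical(classify_substitution("CTG", "CTA"), "synonymous")
  expect_identical(classify_substitution("GAA", "GAC"), "nonsynonymous")
  expect_identical(classify_substitution("TAC", "TAA"), "nonsense")
  expect_identical(classify_substitution("ANG", "AAG"), NA_character_)

  sense <- names(oracle_codon_table)[oracle_codon_table != "*"]
  for (c1 in sense) {
    for (c2 in sense) {
      if (c1 == c2) next
      expect_identical(classify_substitution(c1, c2),
                       oracle_classify_codon_pair(c1, c2))
    }
  }
})

test_that("parsimony orientation assigns the lineage whose residue changed", {
  expect_identical(orient_substitution("S", "A", "A"), "pop1")
  expect_identical(orient_substitution("S", "A", "S"), "pop2")
  expect_identical(orient_substitution("S", "A", "T"), "unoriented")
  expect_identical(orient_substitution("S", "A", NA), "unoriented")
  expect_error(orient_substitution("S", "S", "S"))
})

test_that("radical classification respects the six-class scheme", {
  expect_false(is_radical("D", "E"))   # both acidic
  expect_true(is_radical("K", "E"))    # basic vs acidic
  expect_true(is_radical("A", "P"))    # proline is its own class
  expect_error(is_radical("A", "B"), "non-standard")
})

test_that("is_radical is symmetric and irreflexive", {
  sch <- aa_class_scheme()
  aas <- names(sch)
  for (a in aas) {
    expect_false(is_radical(a, a, sch))
    for (b in aas)
      expect_identical(is_radical(a, b, sch), is_radical(b, a, sch))
  }
})

test_that("fixed differences project to codons with correct kind and lineage", {
  cfg <- small_sim_config(n_contigs = 6, depth_mean = 25,
                          fixed_diff_rate = 0.02, polymorphic_site_rate = 0,
                          nonsyn_fraction = 0.5)
  sim <- simulate_dataset(cfg)
  pus <- sim_pileups(sim)
  scan <- scan_pileups(pus)
  contigs <- setNames(vapply(sim$reference$contigs, `[[`, "", "seq"),
                      vapply(sim$reference$contigs, `[[`, "", "id"))
  og <- setNames(vapply(sim$reference$contigs, `[[`, "", "outgroup_protein"),
                 vapply(sim$reference$contigs, `[[`, "", "id"))
  cons <- sapply(names(pus), function(cid)
    consensus_per_population(pus[[cid]], contigs[[cid]]),
    simplify = FALSE)
  projs <- sapply(names(pus), function(cid)
    project_coding_frame(contigs[[cid]], og[[cid]]), simplify = FALSE)
  res <- analyze_substitutions(scan$sites, cons, projs)
  su <- res$substitutions
  tf <- sim$truth$fixed_diffs
  expect_gt(nrow(su), 0L)
  # every analysed event corresponds to a planted one with matching kind
  for (i in seq_len(nrow(su))) {
    match_row <- tf[tf$contig == su$contig[i] & tf$codon_index == su$codon_index[i], ]
    expect_identical(nrow(match_row), 1L)
    expect_identical(su$kind[i] != "synonymous", match_row$is_nonsynonymous)
    if (su$kind[i] == "nonsynonymous")
      expect_identical(su$lineage[i], match_row$expected_orientation)
  }
  # conservation: kinds partition the classified events
  tab <- tabulate_lineage_counts(su)
  expect_identical(sum(tab$by_kind), nrow(su))
  expect_identical(unname(sum(tab$lineage_counts)), tab$n_aa_events)
})

test_that("a half-diverged outgroup leaves the planted collision fraction unoriented", {
  cfg <- small_sim_config(n_contigs = 8, depth_mean = 25,
                          fixed_diff_rate = 0.02, polymorphic_site_rate = 0,
                          nonsyn_fraction = 1,
                          outgroup_protein_divergence = 0.5)
  sim <- simulate_dataset(cfg)
  pus <- sim_pileups(sim)
  scan <- scan_pileups(pus)
  contigs <- setNames(vapply(sim$reference$contigs, `[[`, "", "seq"),
                      vapply(sim$reference$contigs, `[[`, "", "id"))
  og <- setNames(vapply(sim$reference$contigs, `[[`, "", "outgroup_protein"),
                 vapply(sim$reference$contigs, `[[`, "", "id"))
  cons <- sapply(names(pus), function(cid)
    consensus_per_population(pus[[cid]], contigs[[cid]]), simplify = FALSE)
  projs <- sapply(names(pus), function(cid)
    project_coding_frame(contigs[[cid]], og[[cid]]), simplify = FALSE)
  su <- analyze_substitutions(scan$sites, cons, projs)$substitutions
  su <- su[su$kind == "nonsynonymous", ]
  expect_gt(nrow(su), 10L)
  tf <- sim$truth$fixed_diffs
  # events whose residue the outgroup left untouched recover the planted
  # lineage exactly
  for (i in seq_len(nrow(su))) {
    row <- tf[tf$contig == su$contig[i] & tf$codon_index == su$codon_index[i], ]
    if (row$expected_orientation != "unoriented")
      expect_identical(su$lineage[i], row$expected_orientation)
  }
  # the unoriented fraction tracks the planted collision rate (an outgroup
  # mutated at the residue may still orient by coincidence, ~1/19 of cases,
  # so compare within 4-sigma binomial error plus that slack)
  p_coll <- mean(tf$expected_orientation == "unoriented")
  obs <- mean(su$lineage == "unoriented")
  n <- nrow(su)
  expect_lt(abs(obs - p_coll), 4 * sqrt(p_coll * (1 - p_coll) / n) + 1 / 19)
})

test_that("premature stops are reported with their truncation fraction", {
  set.seed(42)
  aas <- setdiff(names(aa_class_scheme()), "Y")   # avoid near-stop codons
  protein <- paste(sample(aas, 50, TRUE), collapse = "")
  cds <- reverse_translate(protein)
  pr <- project_coding_frame(cds, protein)
  expect_identical(pr$n_codons, 50L)

  mk_cons <- function(seq) list(seq = seq, untrusted = logical(nchar(seq)),
                                ambiguous = logical(nchar(seq)))
  # identical populations: nothing to report
  none <- detect_premature_stop(pr, list(pop1 = mk_cons(cds), pop2 = mk_cons(cds)))
  expect_identical(nrow(none), 0L)

  # plant TAA at codon 21 of pop2
  b <- strsplit(cds, "")[[1]]
  b[(21 - 1) * 3 + 1:3] <- c("T", "A", "A")
  hit <- detect_premature_stop(pr, list(pop1 = mk_cons(cds),
                                        pop2 = mk_cons(paste(b, collapse = ""))))
  expect_identical(hit$codon_index, 21L)
  expect_identical(hit$population, "pop2")
  expect_equal(hit$truncation_fraction, (50 - 21) / 50)

  # a stop at the terminal aligned codon is not premature
  b2 <- strsplit(cds, "")[[1]]
  b2[(50 - 1) * 3 + 1:3] <- c("T", "G", "A")
  last <- detect_premature_stop(pr, list(pop1 = mk_cons(cds),
                                         pop2 = mk_cons(paste(b2, collapse = ""))))
  expect_identical(nrow(last), 0L)
})

test_that("tabulation is empty on empty input and conserves totals", {
  empty <- tabulate_lineage_counts(
    data.frame(contig = character(0), codon_index = integer(0),
               contig_pos = integer(0), n_nuc_changes = integer(0),
               aa_pop1 = character(0), aa_pop2 = character(0),
               aa_outgroup = character(0), kind = character(0),
               lineage = character(0), radical = logical(0)))
  expect_identical(empty$n_nucleotide, 0L)
  expect_true(all(empty$by_kind == 0L))
  expect_identical(empty$radical_total, 0L)
})
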