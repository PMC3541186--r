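test_that("the depth-4 rule requires two minor-allele reads", {
  expect_identical(min_minor_count(4), 2L)
})

test_that("vacuous filters reduce the threshold to a single read", {
  m <- error_model_params(alpha = 1 - 1e-12)
  th <- call_thresholds(f_min = 1 / 4)
  expect_identical(min_minor_count(4, m, th), 1L)
})

test_that("min_minor_count equals the brute-force summation oracle over depths 4..60", {
  got <- min_minor_count(4:60)
  want <- vapply(4:60, oracle_min_minor_count, integer(1))
  expect_identical(got, want)
})

test_that("min_minor_count is undefined below the depth floor", {
  expect_error(min_minor_count(3), "minimum depth")
})

test_that("the point-mass tail variant matches the upper tail at these parameters", {
  up <- min_minor_count(4:40, error_model_params(tail = "upper"))
  pt <- min_minor_count(4:40, error_model_params(tail = "point"))
  expect_identical(up, pt)
})

test_that("min_minor_count responds monotonically to its parameters", {
  base <- min_minor_count(4:80)
  expect_true(all(diff(base) >= 0))  # non-decreasing in depth
  for (D in c(4, 12, 30, 60)) {
    k0 <- min_minor_count(D)
    expect_gte(min_minor_count(D, error_model_params(alpha = 0.001)), k0)
    expect_gte(min_minor_count(D, error_model_params(p_err = 1e-3)), k0)
    expect_gte(min_minor_count(D, error_model_params(contig_len_for_test = 1e5)), k0)
    expect_lte(min_minor_count(D, error_model_params(alpha = 0.2)), k0)
  }
})

test_that("call_site applies the depth-4 rule and the depth floor", {
  poly <- call_site(c(A = 2, C = 2, G = 0, T = 0))
  expect_identical(poly$status, "polymorphic")
  expect_setequal(poly$alleles, c("A", "C"))
  expect_identical(poly$minor_count, 2L)

  mono <- call_site(c(A = 3, C = 1, G = 0, T = 0))
  expect_identical(mono$status, "monomorphic")
  expect_identical(mono$alleles, "A")

  low <- call_site(c(A = 2, C = 1, G = 0, T = 0))
  expect_identical(low$status, "insufficient_depth")
})

test_that("third alleles above threshold are retained in the allele set", {
  tri <- call_site(c(A = 6, C = 3, G = 2, T = 0),
                   thresholds = call_thresholds(f_min = 0.05))
  expect_identical(tri$status, "polymorphic")
  expect_setequal(tri$alleles, c("A", "C", "G"))
})

test_that("cross-population classification covers all site types", {
  poly_ac <- call_site(c(A = 3, C = 2, G = 0, T = 0))
  poly_ac2 <- call_site(c(A = 4, C = 2, G = 0, T = 0))
  poly_ag <- call_site(c(A = 3, C = 0, G = 2, T = 0))
  mono_a5 <- call_site(c(A = 5, C = 0, G = 0, T = 0))
  mono_g6 <- call_site(c(A = 0, C = 0, G = 6, T = 0))
  low_a2 <- call_site(c(A = 2, C = 0, G = 0, T = 0))

  expect_identical(classify_site(poly_ac, poly_ac2)$class, "shared_polymorphism")
  expect_identical(classify_site(poly_ac, poly_ag)$class, "divergent_polymorphism")
  expect_identical(classify_site(poly_ac, mono_a5)$class, "polymorphism_one_morph")
  expect_identical(classify_site(poly_ac, low_a2)$class,
                   "polymorphism_one_morph_unknown_other")
  expect_identical(classify_site(mono_a5, mono_g6)$class, "fixed_difference")
  expect_identical(classify_site(mono_a5, mono_a5)$class, "monomorphic_identical")
  expect_identical(classify_site(mono_a5, low_a2)$class, "undetermined")
  expect_identical(classify_site(low_a2, low_a2)$class, "undetermined")
})

test_that("an all-zero pileup yields no classified sites", {
  pu <- new_contig_pileup("empty", 50)
  res <- scan_contig(pu)
  expect_identical(nrow(res$sites), 0L)
  expect_true(all(res$class_counts == 0L))
})

test_that("a planted fixed difference is found at exactly its site", {
  ref <- strrep("ACGTT", 20)
  m1 <- mono_counts(ref, 5)
  alt <- strsplit(ref, "")[[1]]; alt[37] <- "A"  # C -> A at position 37
  m2 <- mono_counts(paste(alt, collapse = ""), 6)
  res <- scan_contig(make_pileup(m1, m2))
  fixed <- res$sites[res$sites$class == "fixed_difference", ]
  expect_identical(nrow(fixed), 1L)
  expect_identical(fixed$pos, 37L)
  expect_identical(fixed$alleles_pop1, "C")
  expect_identical(fixed$alleles_pop2, "A")
})

test_that("every covered site gets exactly one class and counts add up", {
  cfg <- small_sim_config(n_contigs = 4, depth_mean = 6,
                          polymorphic_site_rate = 0.02,
                          fixed_diff_rate = 0.01, error_rate = 1e-3,
                          q_low_fraction = 0.2)
  pus <- sim_pileups(simulate_dataset(cfg))
  for (pu in pus) {
    res <- scan_contig(pu)
    covered <- sum(rowSums(pu$counts$pop1) + rowSums(pu$counts$pop2) > 0)
    expect_identical(nrow(res$sites), covered)
    expect_identical(sum(res$class_counts), covered)
    expect_true(all(res$sites$class %in% SITE_CLASSES))
  }
})

test_that("scan_contig calls match per-site call_site/classify_site exactly", {
  cfg <- small_sim_config(n_contigs = 2, depth_mean = 8,
                          polymorphic_site_rate = 0.03,
                          fixed_diff_rate = 0.01, error_rate = 2e-3,
                          q_low_fraction = 0.2)
  pus <- sim_pileups(simulate_dataset(cfg))
  for (pu in pus) {
    res <- scan_contig(pu)
    for (r in sample(nrow(res$sites), min(80, nrow(res$sites)))) {
      pos <- res$sites$pos[r]
      c1 <- call_site(pu$counts$pop1[pos, ])
      c2 <- call_site(pu$counts$pop2[pos, ])
      expect_identical(res$sites$class[r], classify_site(c1, c2)$class)
      expect_identical(res$sites$minor_count_pop1[r], c1$minor_count)
      expect_identical(res$sites$minor_count_pop2[r], c2$minor_count)
    }
  }
})

test_that("every emitted polymorphic call survives the brute-force filter", {
  cfg <- small_sim_config(n_contigs = 4, depth_mean = 12,
                          polymorphic_site_rate = 0.02,
                          minor_allele_freq = 0.2,
                          error_rate = 1e-3, q_low_fraction = 0.1)
  pus <- sim_pileups(simulate_dataset(cfg))
  scan <- scan_pileups(pus)
  s <- scan$sites
  for (pop in c("pop1", "pop2")) {
    mc <- s[[paste0("minor_count_", pop)]]
    d <- s[[paste0("depth_", pop)]]
    hit <- mc > 0
    expect_true(all(d[hit] >= 4))
    kmin <- vapply(d[hit], oracle_min_minor_count, integer(1))
    expect_true(all(mc[hit] >= kmin))
    expect_true(all(mc[hit] / d[hit] >= 0.05))
  }
})

test_that("polymorphism calls follow the filter exactly on realized counts", {
  cfg <- small_sim_config(n_contigs = 10, depth_mean = 25,
                          polymorphic_site_rate = 0.01,
                          minor_allele_freq = 0.5,
                          fixed_diff_rate = 0, error_rate = 0,
                          q_low_fraction = 0)
  sim <- simulate_dataset(cfg)
  pus <- sim_pileups(sim)
  scan <- scan_pileups(pus)
  s <- scan$sites
  key <- function(contig, site, pop) paste(contig, site, pop)
  detected <- c(key(s$contig, s$pos, "pop1")[s$minor_count_pop1 > 0],
                key(s$contig, s$pos, "pop2")[s$minor_count_pop2 > 0])
  truth <- sim$truth$polymorphisms
  expect_gt(nrow(truth), 0L)
  # at zero error rate, every detected site is a planted site
  expect_true(all(detected %in% key(truth$contig, truth$site, truth$population)))
  # and each planted site is detected exactly when its realized counts pass
  # the brute-force filter: depth >= 4 and second allele count >= kmin(depth)
  for (i in seq_len(nrow(truth))) {
    counts <- pus[[truth$contig[i]]]$counts[[truth$population[i]]][truth$site[i], ]
    d <- sum(counts)
    should <- d >= 4 && sort(counts, decreasing = TRUE)[2] >= oracle_min_minor_count(d)
    expect_identical(key(truth$contig[i], truth$site[i], truth$population[i]) %in%
                       detected, should)
  }
})

test_that("indel scan is empty on clean data and finds a fixed deletion", {
  set.seed(31)
  contig <- random_dna(120)
  full <- function() align_read_to_contig(contig, contig)
  del <- function() {
    b <- strsplit(contig, "")[[1]]
    align_read_to_contig(paste(b[-(61:63)], collapse = ""), contig)
  }
  # clean: 4 + 4 full-length reads, no indel
  alns <- c(replicate(4, full(), simplify = FALSE),
            replicate(4, full(), simplify = FALSE))
  pops <- rep(c("pop1", "pop2"), each = 4)
  expect_identical(nrow(scan_indels(alns, pops, 120)), 0L)

  # pop2 reads all carry a 3-base deletion
  alns2 <- c(replicate(4, full(), simplify = FALSE),
             replicate(4, del(), simplify = FALSE))
  found <- scan_indels(alns2, pops, 120)
  # gap placement is ambiguous under the DP, so assert count and locality
  expect_identical(nrow(found), 3L)
  expect_true(all(found$pos >= 58 & found$pos <= 66))
  expect_true(all(found$population == "pop2"))
  expect_true(all(found$type == "deletion"))

  # deletion in only half of pop2's reads: not fixed, not reported
  alns3 <- c(replicate(4, full(), simplify = FALSE),
             replicate(2, del(), simplify = FALSE),
             replicate(2, full(), simplify = FALSE))
  expect_identical(nrow(scan_indels(alns3, pops, 120)), 0L)

  # restricted to a coding interval that excludes the deletion
  expect_identical(nrow(scan_indels(alns2, pops, 120,
                                    coding_interval = c(70, 120))), 0L)
})
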