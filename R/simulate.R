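#' Configuration for the two-population EST simulator
#'
#' Describes a simulated study in which two populations (morphs) of one
#' species diverged recently from a common ancestor and were each sampled as
#' a pool of at most `n_individuals_per_pop` diploid individuals, sequenced
#' as low-depth full-length ESTs. The generator plants within-population
#' polymorphic sites, fixed inter-population differences on one lineage or
#' the other, sequencing errors, and sub-Q20 quality values, and records
#' every planted event in a machine-readable truth set so downstream calls
#' can be scored.
#'
#' Defaults mirror a Sanger EST survey of a surface-dwelling and a
#' cave-dwelling fish morph: contigs of about 1 kb, mean per-population
#' depth 6.8, per-base error rate 1e-4, roughly one fixed difference per
#' 6-7 kb of coding sequence with about a quarter of them non-synonymous,
#' and an outgroup protein around 70-80% identical to the ancestral
#' translation.
#'
#' @param n_contigs Number of contigs to simulate.
#' @param contig_length Coding-sequence length per contig in bases; must be
#'   divisible by 3.
#' @param n_individuals_per_pop Diploid individuals per population pool, so
#'   each population holds `2 * n_individuals_per_pop` haplotypes. Default 10
#'   (20 alleles), which motivates the 0.05 minor-allele-frequency floor.
#' @param polymorphic_site_rate Per-base probability that a site is planted
#'   polymorphic within a given population.
#' @param minor_allele_freq Haplotype frequency of the planted minor allele,
#'   in (0, 0.5]; rounded to the nearest achievable haplotype count. Must be
#'   at least `1/(2 * n_individuals_per_pop)`.
#' @param fixed_diff_rate Per-coding-base probability of a fixed
#'   inter-population difference.
#' @param nonsyn_fraction Fraction of fixed differences planted as
#'   non-synonymous codon changes (the rest are synonymous).
#' @param depth_mean Mean reads per contig per population (Poisson).
#' @param error_rate Per-base sequencing/RT error probability. Default 1e-4.
#' @param q_low_fraction Fraction of read bases assigned a quality below 20.
#' @param q_low,q_high The two Phred values of the two-point quality model
#'   (one below the Q20 mask threshold, one at or above it).
#' @param outgroup_protein_divergence Per-residue probability that the
#'   outgroup protein differs from the ancestral translation.
#' @param utr5_length,utr3_length Lengths of non-coding flanks added around
#'   the coding sequence (default 0).
#' @param read_length If `NULL` (default) reads span the whole contig;
#'   otherwise reads of this length start at uniform positions.
#' @param seed Integer seed; the same configuration (including seed) yields
#'   byte-identical output.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_contigs = 5, contig_length = 300, seed = 1)
#' @export
sim_config <- function(n_contigs = 50L,
                       contig_length = 999L,
                       n_individuals_per_pop = 10L,
                       polymorphic_site_rate = 0.002,
                       minor_allele_freq = 0.25,
                       fixed_diff_rate = 1.5e-4,
                       nonsyn_fraction = 0.24,
                       depth_mean = 6.8,
                       error_rate = 1e-4,
                       q_low_fraction = 0.05,
                       q_low = 11L, q_high = 30L,
                       outgroup_protein_divergence = 0.25,
                       utr5_length = 0L, utr3_length = 0L,
                       read_length = NULL,
                       seed = 1L) {
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_individuals_per_pop = as.integer(n_individuals_per_pop),
              polymorphic_site_rate = polymorphic_site_rate,
              minor_allele_freq = minor_allele_freq,
              fixed_diff_rate = fixed_diff_rate,
              nonsyn_fraction = nonsyn_fraction,
              depth_mean = depth_mean,
              error_rate = error_rate,
              q_low_fraction = q_low_fraction,
              q_low = as.integer(q_low), q_high = as.integer(q_high),
              outgroup_protein_divergence = outgroup_protein_divergence,
              utr5_length = as.integer(utr5_length),
              utr3_length = as.integer(utr3_length),
              read_length = if (is.null(read_length)) NULL else as.integer(read_length),
              seed = as.integer(seed))
  rates <- c("polymorphic_site_rate", "fixed_diff_rate", "nonsyn_fraction",
             "error_rate", "q_low_fraction", "outgroup_protein_divergence")
  for (r in rates)
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1)
      stop(r, " must lie in [0, 1]")
  if (cfg$contig_length %% 3L != 0L)
    stop("contig_length must be divisible by 3 (coding contigs)")
  stopifnot(cfg$n_contigs >= 1L, cfg$n_individuals_per_pop >= 1L,
            cfg$depth_mean >= 0, cfg$minor_allele_freq > 0,
            cfg$minor_allele_freq <= 0.5,
            cfg$q_low < 20L, cfg$q_high >= 20L)
  structure(cfg, class = "sim_config")
}

DNA_BASES <- c("A", "C", "G", "T")

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

.translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Generate ancestral coding references and diverged outgroup proteins
#'
#' Draws one ancestral coding sequence per contig (uniform over sense codons,
#' hence free of in-frame stops), optionally flanked by non-coding UTRs, and
#' derives an outgroup protein by mutating each residue of the ancestral
#' translation independently with probability
#' `outgroup_protein_divergence`. Mutated outgroup residue positions are
#' recorded so truth labels can mark substitutions that the outgroup cannot
#' polarize.
#'
#' @param config A [sim_config()].
#' @return An object of class `md_reference`: a list with `contigs` (each
#'   holding `id`, `seq`, `cds_start`, `cds_end`, `protein_id`, `protein`,
#'   `outgroup_protein`, `outgroup_mutated`) and the `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sense <- .sense_codons()
  n_codons <- config$contig_length %/% 3L
  contigs <- vector("list", config$n_contigs)
  for (i in seq_len(config$n_contigs)) {
    codons <- sample(sense, n_codons, replace = TRUE)
    cds <- paste(codons, collapse = "")
    utr5 <- if (config$utr5_length > 0)
      paste(sample(DNA_BASES, config$utr5_length, replace = TRUE), collapse = "") else ""
    utr3 <- if (config$utr3_length > 0)
      paste(sample(DNA_BASES, config$utr3_length, replace = TRUE), collapse = "") else ""
    protein <- .translate_codons(codons)
    mut <- which(stats::runif(n_codons) < config$outgroup_protein_divergence)
    outgroup <- protein
    aa20 <- names(.AA_STANDARD_SET)
    for (j in mut)
      outgroup[j] <- sample(setdiff(aa20, protein[j]), 1L)
    contigs[[i]] <- list(
      id = sprintf("CTG%04d", i),
      seq = paste0(utr5, cds, utr3),
      cds_start = config$utr5_length + 1L,
      cds_end = config$utr5_length + config$contig_length,
      protein_id = sprintf("PROT%04d", i),
      protein = paste(protein, collapse = ""),
      outgroup_protein = paste(outgroup, collapse = ""),
      outgroup_mutated = mut)
  }
  structure(list(contigs = contigs, config = config), class = "md_reference")
}

.AA_STANDARD_SET <- {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  stats::setNames(rep(TRUE, 20L), aas)
}

# enumerate the 9 single-base neighbours of a codon with their substitution kind
.codon_neighbours <- function(codon) {
  ref_aa <- .translate_codons(codon)
  out <- list()
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      alt_aa <- .translate_codons(alt_codon)
      kind <- if (alt_aa == "*") "nonsense"
              else if (alt_aa == ref_aa) "synonymous" else "nonsynonymous"
      out[[length(out) + 1L]] <- list(pos = pos, base = b, kind = kind)
    }
  }
  out
}

#' Plant polymorphisms and fixed differences into haplotype pools
#'
#' Builds `2 * n_individuals_per_pop` haplotypes per population from the
#' ancestral reference and plants (a) within-population polymorphic sites at
#' the configured minor-allele frequency and (b) fixed inter-population
#' differences, each assigned to one lineage (the population whose allele
#' departs from the ancestor). Fixed differences are placed one per codon in
#' the coding region, chosen to be non-synonymous (never nonsense) with
#' probability `nonsyn_fraction` and synonymous otherwise. All planted sites
#' are mutually disjoint. Every event is recorded in the returned truth set,
#' including whether outgroup parsimony is expected to recover the lineage
#' (it cannot when the outgroup protein is itself mutated at that residue).
#'
#' @param reference An `md_reference` from [generate_reference()].
#' @param config The same [sim_config()] used to build the reference.
#' @return An object of class `md_pools`: the reference plus per-contig,
#'   per-population sparse haplotype variant tables and a `truth` list with
#'   data frames `polymorphisms` and `fixed_diffs`.
#' @export
plant_variants <- function(reference, config) {
  stopifnot(inherits(reference, "md_reference"))
  if (config$minor_allele_freq < 1 / (2 * config$n_individuals_per_pop))
    stop("minor_allele_freq ", config$minor_allele_freq,
         " is unreachable with ", 2 * config$n_individuals_per_pop,
         " haplotypes per population")
  set.seed(config$seed + 1L)
  n_hap <- 2L * config$n_individuals_per_pop
  pops <- c("pop1", "pop2")
  pools <- list()
  poly_rows <- list()
  fix_rows <- list()
  for (ct in reference$contigs) {
    L <- nchar(ct$seq)
    base_vec <- strsplit(ct$seq, "")[[1]]
    used <- logical(L)
    variants <- list(pop1 = list(), pop2 = list())

    # fixed differences: one per codon, coding region only
    cds_len <- ct$cds_end - ct$cds_start + 1L
    n_codons <- cds_len %/% 3L
    n_fix <- stats::rbinom(1L, cds_len, config$fixed_diff_rate)
    n_fix <- min(n_fix, n_codons)
    codon_idx <- sort(sample.int(n_codons, n_fix))
    for (ci in codon_idx) {
      cstart <- ct$cds_start + 3L * (ci - 1L)
      codon <- substr(ct$seq, cstart, cstart + 2L)
      nb <- .codon_neighbours(codon)
      want_nonsyn <- stats::runif(1) < config$nonsyn_fraction
      kind_want <- if (want_nonsyn) "nonsynonymous" else "synonymous"
      cand <- Filter(function(x) x$kind == kind_want, nb)
      if (!length(cand))  # e.g. ATG/TGG have no synonymous neighbour
        cand <- Filter(function(x) x$kind == "nonsynonymous", nb)
      pick <- cand[[sample.int(length(cand), 1L)]]
      site <- cstart + pick$pos - 1L
      if (used[site]) next
      used[site] <- TRUE
      lineage <- sample(pops, 1L)
      anc <- base_vec[site]
      variants[[lineage]][[length(variants[[lineage]]) + 1L]] <-
        data.frame(hap = seq_len(n_hap), pos = site, base = pick$base)
      orientable <- !(ci %in% ct$outgroup_mutated)
      fix_rows[[length(fix_rows) + 1L]] <- data.frame(
        contig = ct$id, site = site,
        allele_pop1 = if (lineage == "pop1") pick$base else anc,
        allele_pop2 = if (lineage == "pop2") pick$base else anc,
        is_nonsynonymous = pick$kind == "nonsynonymous",
        lineage = lineage,
        expected_orientation = if (orientable) lineage else "unoriented",
        codon_index = ci)
    }

    # within-population polymorphic sites
    for (pop in pops) {
      n_poly <- stats::rbinom(1L, L, config$polymorphic_site_rate)
      free <- which(!used)
      n_poly <- min(n_poly, length(free))
      sites <- if (n_poly > 0) sample(free, n_poly) else integer(0)
      used[sites] <- TRUE
      for (site in sites) {
        anc <- base_vec[site]
        minor <- sample(setdiff(DNA_BASES, anc), 1L)
        m <- max(1L, as.integer(round(n_hap * config$minor_allele_freq)))
        carriers <- sample.int(n_hap, m)
        variants[[pop]][[length(variants[[pop]]) + 1L]] <-
          data.frame(hap = carriers, pos = site, base = minor)
        poly_rows[[length(poly_rows) + 1L]] <- data.frame(
          contig = ct$id, site = site, population = pop,
          major = anc, minor = minor, minor_count = m,
          n_haplotypes = n_hap, frequency = m / n_hap)
      }
    }

    pools[[ct$id]] <- list(
      pop1 = do.call(rbind, c(variants$pop1,
                              list(data.frame(hap = integer(0), pos = integer(0),
                                              base = character(0))))),
      pop2 = do.call(rbind, c(variants$pop2,
                              list(data.frame(hap = integer(0), pos = integer(0),
                                              base = character(0))))))
  }
  empty_poly <- data.frame(contig = character(0), site = integer(0),
                           population = character(0), major = character(0),
                           minor = character(0), minor_count = integer(0),
                           n_haplotypes = integer(0), frequency = numeric(0))
  empty_fix <- data.frame(contig = character(0), site = integer(0),
                          allele_pop1 = character(0), allele_pop2 = character(0),
                          is_nonsynonymous = logical(0), lineage = character(0),
                          expected_orientation = character(0),
                          codon_index = integer(0))
  truth <- list(
    polymorphisms = if (length(poly_rows)) do.call(rbind, poly_rows) else empty_poly,
    fixed_diffs = if (length(fix_rows)) do.call(rbind, fix_rows) else empty_fix)
  structure(list(reference = reference, pools = pools, truth = truth,
                 n_haplotypes = n_hap, config = config),
            class = "md_pools")
}

#' Simulate reads with qualities from the haplotype pools
#'
#' Draws a Poisson number of reads per contig per population around
#' `depth_mean`; each read copies one uniformly chosen haplotype, receives
#' independent per-base substitution errors at `error_rate` (uniform over
#' the three alternative bases, and logged in the truth set), and a
#' two-point quality string in which a fraction `q_low_fraction` of bases
#' falls below the Q20 mask threshold.
#'
#' @param pools An `md_pools` from [plant_variants()].
#' @param config The same [sim_config()].
#' @return An object of class `md_sim`: reference, truth (now including an
#'   `errors` data frame), and per-population read tables with columns
#'   `read_id`, `contig`, `start`, `seq`, `qual` (Phred+33).
#' @export
simulate_reads <- function(pools, config) {
  stopifnot(inherits(pools, "md_pools"))
  set.seed(config$seed + 2L)
  pops <- c("pop1", "pop2")
  reads <- list(pop1 = list(), pop2 = list())
  err_rows <- list()
  for (ct in pools$reference$contigs) {
    L <- nchar(ct$seq)
    base_vec <- strsplit(ct$seq, "")[[1]]
    rl <- if (is.null(config$read_length)) L else min(config$read_length, L)
    for (pop in pops) {
      vt <- pools$pools[[ct$id]][[pop]]
      n_reads <- stats::rpois(1L, config$depth_mean)
      if (n_reads == 0L) next
      for (r in seq_len(n_reads)) {
        hap <- sample.int(pools$n_haplotypes, 1L)
        start <- if (rl == L) 1L else sample.int(L - rl + 1L, 1L)
        v <- base_vec
        if (nrow(vt)) {
          hv <- vt[vt$hap == hap, ]
          if (nrow(hv)) v[hv$pos] <- hv$base
        }
        v <- v[start:(start + rl - 1L)]
        # contig assignment is carried in the id ("contig|read"), the
        # convention honoured by the file-based pipeline input
        read_id <- sprintf("%s|%s_r%03d", ct$id, pop, r)
        if (config$error_rate > 0) {
          errs <- which(stats::runif(rl) < config$error_rate)
          for (e in errs) {
            obs <- sample(setdiff(DNA_BASES, v[e]), 1L)
            err_rows[[length(err_rows) + 1L]] <- data.frame(
              population = pop, read_id = read_id, contig = ct$id,
              offset = e, contig_pos = start + e - 1L,
              true_base = v[e], obs_base = obs)
            v[e] <- obs
          }
        }
        q <- ifelse(stats::runif(rl) < config$q_low_fraction,
                    config$q_low, config$q_high)
        reads[[pop]][[length(reads[[pop]]) + 1L]] <- data.frame(
          read_id = read_id, contig = ct$id, start = start,
          seq = paste(v, collapse = ""),
          qual = intToUtf8(q + 33L))
      }
    }
  }
  empty_reads <- data.frame(read_id = character(0), contig = character(0),
                            start = integer(0), seq = character(0),
                            qual = character(0))
  empty_err <- data.frame(population = character(0), read_id = character(0),
                          contig = character(0), offset = integer(0),
                          contig_pos = integer(0), true_base = character(0),
                          obs_base = character(0))
  truth <- pools$truth
  truth$errors <- if (length(err_rows)) do.call(rbind, err_rows) else empty_err
  structure(list(reference = pools$reference, truth = truth,
                 reads = list(
                   pop1 = if (length(reads$pop1)) do.call(rbind, reads$pop1) else empty_reads,
                   pop2 = if (length(reads$pop2)) do.call(rbind, reads$pop2) else empty_reads),
                 config = config),
            class = "md_sim")
}

#' Run the full simulator: reference, variants, reads
#'
#' @param config A [sim_config()].
#' @return An `md_sim` object (see [simulate_reads()]).
#' @examples
#' sim <- simulate_dataset(sim_config(n_contigs = 3, contig_length = 300, seed = 7))
#' nrow(sim$truth$fixed_diffs)
#' @export
simulate_dataset <- function(config) {
  simulate_reads(plant_variants(generate_reference(config), config), config)
}

#' Build per-contig pileups directly from simulator output
#'
#' Because the simulator knows where every read starts and that reads are
#' ungapped copies of their haplotype, pileups can be tallied directly
#' without running the aligner: bases below `q_min` are masked to `N` and
#' excluded from counts, exactly as [mask_low_quality()] plus
#' [build_pileup()] would do on the same reads. This exact shortcut makes
#' large calibration runs (hundreds of contigs) fast; the aligner path is
#' exercised separately.
#'
#' @param sim An `md_sim` from [simulate_dataset()].
#' @param thresholds A [call_thresholds()] (only `q_min` is used here).
#' @return A named list of `contig_pileup` objects, one per contig.
#' @export
sim_pileups <- function(sim, thresholds = call_thresholds()) {
  stopifnot(inherits(sim, "md_sim"))
  out <- list()
  for (ct in sim$reference$contigs) {
    L <- nchar(ct$seq)
    pu <- new_contig_pileup(ct$id, L)
    for (pop in c("pop1", "pop2")) {
      rd <- sim$reads[[pop]]
      rd <- rd[rd$contig == ct$id, ]
      if (!nrow(rd)) next
      pu$aligned_read_count[[pop]] <- nrow(rd)
      for (i in seq_len(nrow(rd))) {
        b <- strsplit(rd$seq[i], "")[[1]]
        q <- utf8ToInt(rd$qual[i]) - 33L
        b[q < thresholds$q_min] <- "N"
        pos <- rd$start[i] + seq_along(b) - 1L
        keep <- b %in% DNA_BASES
        if (any(keep)) {
          idx <- cbind(pos[keep], match(b[keep], DNA_BASES))
          pu$counts[[pop]][idx] <- pu$counts[[pop]][idx] + 1L
        }
        if (any(!keep))
          pu$n_masked[[pop]][pos[!keep]] <- pu$n_masked[[pop]][pos[!keep]] + 1L
      }
    }
    out[[ct$id]] <- pu
  }
  out
}

#' Write simulator output as standard files
#'
#' Writes per-population FASTQ (Phred+33), the contig reference FASTA, the
#' outgroup protein FASTA, the ortholog-hit TSV (`contig_id`, `protein_id`)
#' and the truth set as JSON.
#'
#' @param sim An `md_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "md_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    reads_pop1 = file.path(dir, "reads_pop1.fastq"),
    reads_pop2 = file.path(dir, "reads_pop2.fastq"),
    contigs = file.path(dir, "contigs.fasta"),
    outgroup = file.path(dir, "outgroup_proteins.fasta"),
    hits = file.path(dir, "hits.tsv"),
    truth = file.path(dir, "truth.json"))
  for (pop in c("pop1", "pop2")) {
    rd <- sim$reads[[pop]]
    seqs <- Biostrings::DNAStringSet(rd$seq)
    names(seqs) <- rd$read_id
    qs <- Biostrings::QualityScaledDNAStringSet(
      seqs, Biostrings::PhredQuality(rd$qual))
    Biostrings::writeQualityScaledXStringSet(qs, paths[[paste0("reads_", pop)]])
  }
  contigs <- Biostrings::DNAStringSet(
    vapply(sim$reference$contigs, `[[`, "", "seq"))
  names(contigs) <- vapply(sim$reference$contigs, `[[`, "", "id")
  Biostrings::writeXStringSet(contigs, paths$contigs)
  prots <- Biostrings::AAStringSet(
    vapply(sim$reference$contigs, `[[`, "", "outgroup_protein"))
  names(prots) <- vapply(sim$reference$contigs, `[[`, "", "protein_id")
  Biostrings::writeXStringSet(prots, paths$outgroup)
  hits <- data.frame(contig_id = names(contigs),
                     protein_id = names(prots))
  utils::write.table(hits, paths$hits, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
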