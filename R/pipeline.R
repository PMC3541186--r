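#' Configuration of an end-to-end pipeline run
#'
#' Bundles either a simulator configuration or paths to real inputs with
#' all stage parameters. Exactly one of `simulate` or the four input paths
#' (`reads_pop1`, `reads_pop2`, `contigs`, `hits`) must be supplied.
#'
#' @param out_dir Output directory for all stage products.
#' @param simulate Optional [sim_config()]; when given, stage inputs are
#'   generated rather than read from files.
#' @param reads_pop1,reads_pop2 FASTQ paths (Phred+33) per population.
#' @param contigs Contig reference FASTA path.
#' @param outgroup_proteins Outgroup protein FASTA path.
#' @param hits Ortholog-hit TSV path (`contig_id`, `protein_id`).
#' @param annotation Optional annotation TSV path (`gene`, `category`) or
#'   an [annotation_map()] for the enrichment stage.
#' @param category Annotation category tested for enrichment (default
#'   `"eye"`).
#' @param model An [error_model_params()].
#' @param thresholds A [call_thresholds()].
#' @param scheme An [aa_class_scheme()].
#' @param min_score_frac Alignment acceptance floor.
#' @param align For simulated inputs: if `FALSE`, pileups are tallied
#'   directly from the simulator's known read placement ([sim_pileups()])
#'   instead of running trimming/masking/alignment; exact for ungapped
#'   simulated reads and much faster on large runs.
#' @param use_contig_length Use each contig's own length as the
#'   multiple-testing L of the error filter.
#' @param stages Character vector of stages to run, a subset of
#'   `c("prep", "call", "subst", "enrich")`; earlier stages are implied by
#'   later ones.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir,
                       simulate = NULL,
                       reads_pop1 = NULL, reads_pop2 = NULL,
                       contigs = NULL, outgroup_proteins = NULL,
                       hits = NULL, annotation = NULL, category = "eye",
                       model = error_model_params(),
                       thresholds = call_thresholds(),
                       scheme = aa_class_scheme(),
                       min_score_frac = 0.5,
                       align = TRUE,
                       use_contig_length = FALSE,
                       stages = c("prep", "call", "subst", "enrich")) {
  if (is.null(simulate)) {
    need <- list(reads_pop1 = reads_pop1, reads_pop2 = reads_pop2,
                 contigs = contigs, hits = hits)
    missing <- names(need)[vapply(need, is.null, TRUE)]
    if (length(missing))
      stop("without a simulator config, inputs are required: ",
           paste(missing, collapse = ", "))
    for (p in c(unlist(need), outgroup_proteins))
      if (!file.exists(p)) stop("input file not found: ", p)
  } else stopifnot(inherits(simulate, "sim_config"))
  stopifnot(all(stages %in% c("prep", "call", "subst", "enrich")))
  structure(list(out_dir = out_dir, simulate = simulate,
                 reads_pop1 = reads_pop1, reads_pop2 = reads_pop2,
                 contigs = contigs, outgroup_proteins = outgroup_proteins,
                 hits = hits, annotation = annotation, category = category,
                 model = model, thresholds = thresholds, scheme = scheme,
                 min_score_frac = min_score_frac, align = align,
                 use_contig_length = use_contig_length, stages = stages),
            class = "run_config")
}

.log_stage <- function(log_path, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> read preparation -> site calling ->
#' substitution analysis -> enrichment, writing each stage's table under
#' `out_dir` plus a machine-readable `summary.json` and a run log. All
#' randomness flows from the simulator seed; runs with identical
#' configuration are identical.
#'
#' @param config A [run_config()].
#' @return A list of class `md_run` with elements `sim` (or `NULL`),
#'   `pileups`, `kept_contigs`, `scan` (site classifications and counts),
#'   `consensus`, `projections`, `subst`, `tab` (lineage bookkeeping),
#'   `premature_stops`, `enrichment`, `summary`, and `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  .log_stage(log_path, "run: morphdiff ",
             as.character(utils::packageVersion("morphdiff")),
             if (!is.null(config$simulate))
               paste0(" | simulated, seed ", config$simulate$seed)
             else " | file inputs")
  stages <- config$stages
  res <- list(paths = list(), summary = list(), config = config)

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_dataset(config$simulate)
    res$sim <- sim
    sim_dir <- file.path(config$out_dir, "sim")
    res$paths$sim <- write_simulation(sim, sim_dir)
    reads <- sim$reads
    contigs <- stats::setNames(
      vapply(sim$reference$contigs, `[[`, "", "seq"),
      vapply(sim$reference$contigs, `[[`, "", "id"))
    outgroup <- stats::setNames(
      vapply(sim$reference$contigs, `[[`, "", "outgroup_protein"),
      vapply(sim$reference$contigs, `[[`, "", "protein_id"))
    hits <- data.frame(contig_id = names(contigs), protein_id = names(outgroup))
    .log_stage(log_path, "simulate: ", length(contigs), " contigs, ",
               nrow(reads$pop1), "+", nrow(reads$pop2), " reads, ",
               nrow(sim$truth$fixed_diffs), " planted fixed differences, ",
               nrow(sim$truth$polymorphisms), " planted polymorphisms")
  } else {
    reads <- list(pop1 = read_fastq_reads(config$reads_pop1),
                  pop2 = read_fastq_reads(config$reads_pop2))
    ctg <- Biostrings::readDNAStringSet(config$contigs)
    contigs <- stats::setNames(as.character(ctg), names(ctg))
    outgroup <- if (!is.null(config$outgroup_proteins)) {
      og <- Biostrings::readAAStringSet(config$outgroup_proteins)
      stats::setNames(as.character(og), names(og))
    } else NULL
    hits <- utils::read.delim(config$hits, stringsAsFactors = FALSE)
    # file reads carry no contig assignment: align each read to every contig
    # is out of scope; a `contig` column in read ids "contig|read" is honoured
    for (pop in names(reads)) {
      if (!"contig" %in% names(reads[[pop]])) {
        parts <- strsplit(reads[[pop]]$read_id, "|", fixed = TRUE)
        reads[[pop]]$contig <- vapply(parts, `[[`, "", 1L)
      }
    }
  }

  # ---- prep ---------------------------------------------------------------
  if (!is.null(config$simulate) && !config$align) {
    pileups <- sim_pileups(res$sim, config$thresholds)
    n_rej <- 0L
  } else {
    pileups <- prepare_pileups(reads, contigs, config$thresholds,
                               config$min_score_frac)
    n_rej <- attr(pileups, "n_rejected")
  }
  kept <- select_contigs_per_ortholog(pileups, hits)
  pileups <- pileups[kept]
  res$pileups <- pileups
  res$kept_contigs <- kept
  res$paths$pileup <- file.path(config$out_dir, "pileup.tsv")
  write_pileup_tsv(pileups, res$paths$pileup)
  .log_stage(log_path, "prep: ", length(kept), " contigs kept, ",
             n_rej, " reads rejected")
  res$summary$n_contigs <- length(kept)
  res$summary$n_reads_rejected <- n_rej
  if (!any(c("call", "subst", "enrich") %in% stages)) {
    res$summary <- .write_summary(res, config)
    return(structure(res, class = "md_run"))
  }

  # ---- call ---------------------------------------------------------------
  scan <- scan_pileups(pileups, config$model, config$thresholds,
                       config$use_contig_length)
  res$scan <- scan
  res$paths$sites <- file.path(config$out_dir, "sites.tsv")
  utils::write.table(scan$sites, res$paths$sites, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .log_stage(log_path, "call: ", nrow(scan$sites), " covered sites, ",
             scan$class_counts[["fixed_difference"]], " fixed differences, ",
             scan$polymorphic_sites_pop1, "/", scan$polymorphic_sites_pop2,
             " polymorphic sites (pop1/pop2)")
  if (!any(c("subst", "enrich") %in% stages)) {
    res$summary <- .write_summary(res, config)
    return(structure(res, class = "md_run"))
  }

  # ---- subst --------------------------------------------------------------
  consensus <- list(); projections <- list(); stops <- list()
  fd_contigs <- unique(scan$sites$contig[scan$sites$class == "fixed_difference"])
  for (cid in names(pileups)) {
    consensus[[cid]] <- consensus_per_population(pileups[[cid]], contigs[[cid]],
                                                 config$thresholds)
    pid <- hits$protein_id[match(cid, hits$contig_id)]
    og <- if (!is.null(outgroup) && !is.na(pid)) outgroup[[pid]] else NULL
    if (!is.null(og)) {
      pr <- project_coding_frame(contigs[[cid]], og)
      projections[[cid]] <- pr
      if (!is.null(pr)) {
        st <- detect_premature_stop(pr, consensus[[cid]])
        if (nrow(st)) { st$contig <- cid; stops[[length(stops) + 1L]] <- st }
      }
    }
  }
  subst <- analyze_substitutions(scan$sites, consensus, projections,
                                 config$scheme)
  subst$substitutions <- attach_genes(subst$substitutions, hits)
  res$consensus <- consensus
  res$projections <- projections
  res$subst <- subst
  res$premature_stops <- if (length(stops)) do.call(rbind, stops) else
    data.frame(codon_index = integer(0), population = character(0),
               truncation_fraction = numeric(0), contig = character(0))
  res$tab <- tabulate_lineage_counts(subst$substitutions)
  res$paths$substitutions <- file.path(config$out_dir, "substitutions.tsv")
  hdr <- paste0("# aa_class_scheme: ",
                paste(names(config$scheme), unname(config$scheme),
                      sep = "=", collapse = ","))
  writeLines(hdr, res$paths$substitutions)
  suppressWarnings(utils::write.table(
    subst$substitutions, res$paths$substitutions, sep = "\t", quote = FALSE,
    row.names = FALSE, append = TRUE))
  .log_stage(log_path, "subst: ", nrow(subst$substitutions),
             " codon events (", res$tab$n_nucleotide, " nucleotide changes), ",
             res$tab$radical_total, " radical, ",
             nrow(res$premature_stops), " premature stops")
  if (!"enrich" %in% stages || is.null(config$annotation)) {
    res$summary <- .write_summary(res, config)
    return(structure(res, class = "md_run"))
  }

  # ---- enrich -------------------------------------------------------------
  ann <- if (inherits(config$annotation, "annotation_map")) config$annotation
         else read_annotation_map(config$annotation)
  res$enrichment <- eye_enrichment_report(subst$substitutions, ann,
                                          config$category)
  radical_genes <- unique(subst$substitutions$gene[
    subst$substitutions$radical %in% TRUE])
  radical_genes <- intersect(radical_genes, ann$universe)
  res$term_enrichment <- if (length(radical_genes))
    term_enrichment(radical_genes, ann) else NULL
  .log_stage(log_path, "enrich: category '", config$category, "' p = ",
             format(res$enrichment$p_value, digits = 4))
  res$summary <- .write_summary(res, config)
  structure(res, class = "md_run")
}

.write_summary <- function(res, config) {
  s <- res$summary
  if (!is.null(res$scan)) {
    s$class_counts <- as.list(res$scan$class_counts)
    s$polymorphic_sites_pop1 <- res$scan$polymorphic_sites_pop1
    s$polymorphic_sites_pop2 <- res$scan$polymorphic_sites_pop2
    s$fixed_differences <- unname(res$scan$class_counts[["fixed_difference"]])
  }
  if (!is.null(res$tab)) {
    s$fixed_nucleotide_changes_coding <- res$tab$n_nucleotide
    s$aa_events <- res$tab$n_aa_events
    s$by_kind <- as.list(res$tab$by_kind)
    s$lineage_counts <- as.list(res$tab$lineage_counts)
    s$radical_total <- res$tab$radical_total
    s$radical_by_lineage <- as.list(res$tab$radical_by_lineage)
    s$premature_stops <- nrow(res$premature_stops)
  }
  if (!is.null(res$enrichment)) {
    s$enrichment_p <- res$enrichment$p_value
    s$enrichment_category <- config$category
  }
  path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA)
  s
}

#' Score a synthetic run against its truth set
#'
#' Matches the run's calls to the simulator's planted events and reports
#' true positives, false positives, false negatives, sensitivity and
#' precision for each event type: within-population polymorphic sites,
#' fixed differences, lineage assignments of amino-acid events, and radical
#' flags. Planted polymorphisms whose minor-allele frequency lies below the
#' calling floor `f_min` are reported separately as sub-threshold (they are
#' expected false negatives by design).
#'
#' @param run An `md_run` from [run_pipeline()] that used simulated input.
#' @param sim The matching `md_sim` (defaults to `run$sim`).
#' @return A data frame with one row per event type: `tp`, `fp`, `fn`,
#'   `sensitivity`, `precision`, `n_subthreshold`.
#' @export
recovery_report <- function(run, sim = run$sim) {
  if (is.null(sim) || is.null(run$scan))
    stop("recovery_report needs a run on simulated input with the call stage")
  if (!identical(sim$config$seed, run$sim$config$seed))
    stop("truth and run come from different simulations (seed mismatch)")
  th <- sim$truth
  sites <- run$scan$sites
  f_min <- run$config$thresholds$f_min
  key <- function(...) paste(..., sep = ":")

  # polymorphic sites, per population
  det_poly <- c(key(sites$contig, sites$pos, "pop1")[sites$minor_count_pop1 > 0],
                key(sites$contig, sites$pos, "pop2")[sites$minor_count_pop2 > 0])
  true_poly_all <- key(th$polymorphisms$contig, th$polymorphisms$site,
                       th$polymorphisms$population)
  sub_thr <- th$polymorphisms$frequency < f_min
  true_poly <- true_poly_all[!sub_thr]
  row_poly <- .pr_row("polymorphic_site", det_poly, true_poly,
                      n_subthreshold = sum(sub_thr))

  # fixed differences
  det_fix <- key(sites$contig[sites$class == "fixed_difference"],
                 sites$pos[sites$class == "fixed_difference"])
  true_fix <- key(th$fixed_diffs$contig, th$fixed_diffs$site)
  row_fix <- .pr_row("fixed_difference", det_fix, true_fix)

  # lineage calls on amino-acid events
  su <- run$subst$substitutions
  su <- su[su$kind %in% c("nonsynonymous", "nonsense"), , drop = FALSE]
  tf <- th$fixed_diffs[th$fixed_diffs$is_nonsynonymous, , drop = FALSE]
  det_lin <- key(su$contig, su$codon_index, su$lineage)[
    su$lineage %in% c("pop1", "pop2")]
  true_lin <- key(tf$contig, tf$codon_index, tf$expected_orientation)[
    tf$expected_orientation %in% c("pop1", "pop2")]
  row_lin <- .pr_row("lineage_call", det_lin, true_lin)

  # radical flags among truth-matched nonsynonymous events
  exp_rad <- .expected_radical(sim)
  det_rad <- key(su$contig, su$codon_index)[su$radical %in% TRUE]
  true_rad <- key(exp_rad$contig, exp_rad$codon_index)[exp_rad$radical]
  row_rad <- .pr_row("radical_flag", det_rad, true_rad)

  out <- rbind(row_poly, row_fix, row_lin, row_rad)
  rownames(out) <- NULL
  out
}

.pr_row <- function(type, detected, truth, n_subthreshold = 0L) {
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  fn <- length(setdiff(truth, detected))
  data.frame(event_type = type, tp = tp, fp = fp, fn = fn,
             sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             n_subthreshold = n_subthreshold)
}

# recompute, from the reference, whether each planted nonsynonymous fixed
# difference is a radical amino-acid change
.expected_radical <- function(sim, scheme = aa_class_scheme()) {
  tf <- sim$truth$fixed_diffs
  tf <- tf[tf$is_nonsynonymous, , drop = FALSE]
  if (!nrow(tf))
    return(data.frame(contig = character(0), codon_index = integer(0),
                      radical = logical(0)))
  refs <- stats::setNames(sim$reference$contigs,
                          vapply(sim$reference$contigs, `[[`, "", "id"))
  rad <- logical(nrow(tf))
  for (i in seq_len(nrow(tf))) {
    ct <- refs[[tf$contig[i]]]
    cstart <- ct$cds_start + 3L * (tf$codon_index[i] - 1L)
    codon <- strsplit(substr(ct$seq, cstart, cstart + 2L), "")[[1]]
    off <- tf$site[i] - cstart + 1L
    c1 <- codon; c1[off] <- tf$allele_pop1[i]
    c2 <- codon; c2[off] <- tf$allele_pop2[i]
    aa1 <- unname(Biostrings::GENETIC_CODE[paste(c1, collapse = "")])
    aa2 <- unname(Biostrings::GENETIC_CODE[paste(c2, collapse = "")])
    rad[i] <- aa1 != "*" && aa2 != "*" && is_radical(aa1, aa2, scheme)
  }
  data.frame(contig = tf$contig, codon_index = tf$codon_index, radical = rad)
}
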