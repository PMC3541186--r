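#' Site classes distinguished across the two populations
#'
#' @format Character vector of the seven mutually exclusive classes assigned
#'   by [classify_site()].
#' @export
SITE_CLASSES <- c("shared_polymorphism", "divergent_polymorphism",
                  "polymorphism_one_morph",
                  "polymorphism_one_morph_unknown_other",
                  "fixed_difference", "monomorphic_identical",
                  "undetermined")

#' Minimum minor-allele count to survive the error filter
#'
#' For a site of depth `D`, returns the smallest minor-allele occurrence `k`
#' such that the observed minor allele is unlikely to be explained by
#' sequencing errors and reaches the minor-allele-frequency floor. Two
#' conditions must both hold:
#'
#' * Error filter: with per-base error probability `p`, the probability of
#'   at least `k` errors among `D` reads at one position is the binomial
#'   upper tail `P_site(k) = sum_{j>=k} C(D,j) p^j (1-p)^(D-j)`. Since any
#'   of the `L` positions of a contig could produce such a pattern, the
#'   retained quantity is `P_any(k) = 1 - (1 - P_site(k))^L`, and the site
#'   survives only if `P_any(k) <= alpha`.
#' * Frequency floor: `k / D >= f_min`, since a pool of at most 10
#'   individuals (20 alleles) cannot harbour a true allele below 5%.
#'
#' At the defaults (`p = 1e-4`, `L = 1000`, `alpha = 0.01`) a depth-4 site
#' needs two reads of the minor allele, and the requirement grows slowly
#' with depth.
#'
#' @param depth Site depth `D` (scalar or vector); must be at least `d_min`.
#' @param model An [error_model_params()].
#' @param thresholds A [call_thresholds()].
#' @return Integer vector of minimal minor-allele counts (`NA` if no count
#'   up to `depth` satisfies both conditions).
#' @examples
#' min_minor_count(4)   # 2
#' min_minor_count(50)  # grows with depth
#' @export
min_minor_count <- function(depth, model = error_model_params(),
                            thresholds = call_thresholds()) {
  stopifnot(inherits(model, "error_model_params"),
            inherits(thresholds, "call_thresholds"))
  depth <- as.integer(depth)
  if (any(depth < thresholds$d_min))
    stop("min_minor_count is undefined below the minimum depth d_min = ",
         thresholds$d_min)
  vapply(depth, function(D) {
    for (k in seq_len(D)) {
      p_site <- if (model$tail == "upper")
        stats::pbinom(k - 1L, D, model$p_err, lower.tail = FALSE)
      else
        stats::dbinom(k, D, model$p_err)
      p_any <- 1 - (1 - p_site)^model$contig_len_for_test
      if (p_any <= model$alpha && k / D >= thresholds$f_min)
        return(k)
    }
    NA_integer_
  }, integer(1))
}

# kmin for every depth 0..max_depth; NA below d_min
.kmin_table <- function(max_depth, model, thresholds) {
  out <- rep(NA_integer_, max_depth + 1L)
  ds <- seq.int(thresholds$d_min, max_depth)
  if (length(ds) && max_depth >= thresholds$d_min)
    out[ds + 1L] <- min_minor_count(ds, model, thresholds)
  out
}

#' Call one site in one population
#'
#' Computes depth as the sum of the four base counts (masked bases are
#' already excluded), then applies the error filter: the site is
#' `polymorphic` if the second-most-frequent base reaches
#' [min_minor_count()] for its depth, `monomorphic` otherwise, and
#' `insufficient_depth` when depth is below `d_min`. Third and fourth bases
#' at or above the threshold are retained as additional minor alleles.
#'
#' @param counts Numeric vector of length 4 with counts for A, C, G, T (in
#'   that order, or named).
#' @param model An [error_model_params()].
#' @param thresholds A [call_thresholds()].
#' @return A list of class `site_call` with `status`, `depth`,
#'   `major_allele`, `minor_allele` (`NA` if none), `minor_count`, and the
#'   full allele set `alleles`.
#' @examples
#' call_site(c(A = 2, C = 2, G = 0, T = 0))$status  # polymorphic
#' call_site(c(A = 3, C = 1, G = 0, T = 0))$status  # monomorphic
#' @export
call_site <- function(counts, model = error_model_params(),
                      thresholds = call_thresholds()) {
  if (is.null(names(counts))) names(counts) <- DNA_BASES
  counts <- counts[DNA_BASES]
  stopifnot(all(counts >= 0))
  depth <- sum(counts)
  if (depth < thresholds$d_min) {
    return(structure(list(status = "insufficient_depth", depth = depth,
                          major_allele = if (depth > 0)
                            DNA_BASES[which.max(counts)] else NA_character_,
                          minor_allele = NA_character_, minor_count = 0L,
                          alleles = character(0)),
                     class = "site_call"))
  }
  kmin <- min_minor_count(depth, model, thresholds)
  major <- DNA_BASES[which.max(counts)]
  minors <- DNA_BASES[counts >= kmin & DNA_BASES != major & counts > 0]
  if (!is.na(kmin) && length(minors)) {
    mc <- counts[minors]
    minor <- minors[which.max(mc)]
    structure(list(status = "polymorphic", depth = depth,
                   major_allele = major, minor_allele = minor,
                   minor_count = as.integer(max(mc)),
                   alleles = sort(c(major, minors))),
              class = "site_call")
  } else {
    structure(list(status = "monomorphic", depth = depth,
                   major_allele = major, minor_allele = NA_character_,
                   minor_count = 0L, alleles = major),
              class = "site_call")
  }
}

#' Classify one site across the two populations
#'
#' Applies the cross-population typology: both populations polymorphic with
#' identical allele sets is a shared polymorphism and with non-identical
#' sets a divergent polymorphism; one population polymorphic while the
#' other is adequately covered but monomorphic is a one-morph polymorphism,
#' or one-morph-unknown-other when the other population's depth is below
#' `d_min`; both monomorphic at adequate depth with different alleles is a
#' fixed difference; both monomorphic with the same allele is
#' monomorphic-identical; anything else (insufficient depth without a
#' polymorphism, or no coverage) is undetermined.
#'
#' @param call_pop1,call_pop2 `site_call` objects for the same site.
#' @return A list of class `site_classification` with `class`,
#'   `alleles_pop1`, `alleles_pop2`.
#' @export
classify_site <- function(call_pop1, call_pop2) {
  s1 <- call_pop1$status; s2 <- call_pop2$status
  a1 <- call_pop1$alleles; a2 <- call_pop2$alleles
  cls <-
    if (s1 == "polymorphic" && s2 == "polymorphic") {
      if (setequal(a1, a2)) "shared_polymorphism" else "divergent_polymorphism"
    } else if (xor(s1 == "polymorphic", s2 == "polymorphic")) {
      other <- if (s1 == "polymorphic") s2 else s1
      if (other == "monomorphic") "polymorphism_one_morph"
      else "polymorphism_one_morph_unknown_other"
    } else if (s1 == "monomorphic" && s2 == "monomorphic") {
      if (call_pop1$major_allele != call_pop2$major_allele) "fixed_difference"
      else "monomorphic_identical"
    } else "undetermined"
  structure(list(class = cls, alleles_pop1 = a1, alleles_pop2 = a2),
            class = "site_classification")
}

#' Scan a contig pileup and classify every covered site
#'
#' Vectorized site calling over one contig: per population, per-site depth,
#' major allele and qualifying minor alleles are computed from the count
#' matrices, then cross-population classes are assigned as in
#' [classify_site()]. Only sites with at least one counted base in either
#' population are reported.
#'
#' @param pileup A `contig_pileup` (two populations).
#' @param model An [error_model_params()].
#' @param thresholds A [call_thresholds()].
#' @param use_contig_length If `TRUE`, the per-contig multiple-testing
#'   length L of the error model is replaced by this contig's own length.
#' @return A list with `sites` (data frame: `contig`, `pos`, `class`,
#'   `alleles_pop1`, `alleles_pop2`, `depth_pop1`, `depth_pop2`,
#'   `minor_count_pop1`, `minor_count_pop2`) and `class_counts` (named
#'   integer vector over [SITE_CLASSES]).
#' @export
scan_contig <- function(pileup, model = error_model_params(),
                        thresholds = call_thresholds(),
                        use_contig_length = FALSE) {
  stopifnot(inherits(pileup, "contig_pileup"), length(pileup$pops) == 2L)
  if (use_contig_length)
    model$contig_len_for_test <- max(1L, pileup$length)
  m1 <- pileup$counts[[1L]]
  m2 <- pileup$counts[[2L]]
  d1 <- rowSums(m1)
  d2 <- rowSums(m2)
  covered <- which(d1 + d2 > 0)
  empty_sites <- data.frame(contig = character(0), pos = integer(0),
                            class = character(0), alleles_pop1 = character(0),
                            alleles_pop2 = character(0), depth_pop1 = integer(0),
                            depth_pop2 = integer(0), minor_count_pop1 = integer(0),
                            minor_count_pop2 = integer(0))
  if (!length(covered)) {
    cc <- stats::setNames(integer(length(SITE_CLASSES)), SITE_CLASSES)
    return(list(sites = empty_sites, class_counts = cc))
  }
  kmin_tab <- .kmin_table(max(d1, d2), model, thresholds)

  analyse_pop <- function(m, d) {
    kmin <- kmin_tab[d + 1L]               # NA below d_min
    major_idx <- max.col(m, ties.method = "first")
    major_count <- m[cbind(seq_len(nrow(m)), major_idx)]
    is_allele <- m >= ifelse(is.na(kmin), Inf, kmin) & m > 0
    is_allele[cbind(seq_len(nrow(m)), major_idx)] <- d > 0
    m_minor <- m
    m_minor[cbind(seq_len(nrow(m)), major_idx)] <- -1L
    minor_count <- pmax(m_minor[, 1L], m_minor[, 2L], m_minor[, 3L], m_minor[, 4L])
    n_alleles <- rowSums(is_allele)
    poly <- !is.na(kmin) & n_alleles >= 2L
    status <- ifelse(d < thresholds$d_min, "insufficient_depth",
                     ifelse(poly, "polymorphic", "monomorphic"))
    list(status = status, major = DNA_BASES[major_idx],
         minor_count = ifelse(poly, pmax(minor_count, 0L), 0L),
         alleles = is_allele)
  }
  p1 <- analyse_pop(m1, d1)
  p2 <- analyse_pop(m2, d2)

  i <- covered
  s1 <- p1$status[i]; s2 <- p2$status[i]
  same_set <- rowSums(p1$alleles[i, , drop = FALSE] !=
                      p2$alleles[i, , drop = FALSE]) == 0L
  cls <- rep("undetermined", length(i))
  bothp <- s1 == "polymorphic" & s2 == "polymorphic"
  cls[bothp & same_set] <- "shared_polymorphism"
  cls[bothp & !same_set] <- "divergent_polymorphism"
  onep <- xor(s1 == "polymorphic", s2 == "polymorphic")
  other_mono <- ifelse(s1 == "polymorphic", s2, s1) == "monomorphic"
  cls[onep & other_mono] <- "polymorphism_one_morph"
  cls[onep & !other_mono] <- "polymorphism_one_morph_unknown_other"
  bothm <- s1 == "monomorphic" & s2 == "monomorphic"
  cls[bothm & p1$major[i] != p2$major[i]] <- "fixed_difference"
  cls[bothm & p1$major[i] == p2$major[i]] <- "monomorphic_identical"

  allele_str <- function(al, stat, major, d) {
    out <- character(length(stat))
    for (j in seq_along(stat)) {
      out[j] <- if (stat[j] == "insufficient_depth") {
        if (d[j] > 0) major[j] else ""
      } else paste(DNA_BASES[al[j, ]], collapse = "/")
    }
    out
  }
  sites <- data.frame(
    contig = pileup$contig_id, pos = i, class = cls,
    alleles_pop1 = allele_str(p1$alleles[i, , drop = FALSE], s1, p1$major[i], d1[i]),
    alleles_pop2 = allele_str(p2$alleles[i, , drop = FALSE], s2, p2$major[i], d2[i]),
    depth_pop1 = as.integer(d1[i]), depth_pop2 = as.integer(d2[i]),
    minor_count_pop1 = as.integer(p1$minor_count[i]),
    minor_count_pop2 = as.integer(p2$minor_count[i]))
  cc <- stats::setNames(integer(length(SITE_CLASSES)), SITE_CLASSES)
  tab <- table(cls)
  cc[names(tab)] <- as.integer(tab)
  list(sites = sites, class_counts = cc)
}

#' Scan all pileups and pool the classification
#'
#' @param pileups Named list of `contig_pileup` objects.
#' @inheritParams scan_contig
#' @return A list with pooled `sites` and genome-wide `class_counts`, plus
#'   the count of polymorphic sites per population
#'   (`polymorphic_sites_pop1`, `polymorphic_sites_pop2`).
#' @export
scan_pileups <- function(pileups, model = error_model_params(),
                         thresholds = call_thresholds(),
                         use_contig_length = FALSE) {
  res <- lapply(pileups, scan_contig, model = model, thresholds = thresholds,
                use_contig_length = use_contig_length)
  sites <- do.call(rbind, lapply(res, `[[`, "sites"))
  rownames(sites) <- NULL
  cc <- Reduce(`+`, lapply(res, `[[`, "class_counts"))
  if (is.null(cc)) cc <- stats::setNames(integer(length(SITE_CLASSES)), SITE_CLASSES)
  poly1 <- sum(sites$minor_count_pop1 > 0)
  poly2 <- sum(sites$minor_count_pop2 > 0)
  list(sites = sites, class_counts = cc,
       polymorphic_sites_pop1 = poly1, polymorphic_sites_pop2 = poly2)
}

#' Detect population-specific indels from alignments
#'
#' Reports gaps (deletions in reads relative to the contig, and insertions
#' relative to it) that are fixed within one population — every covering
#' read of that population at depth `d_min` or more carries the gap — and
#' absent from every covering read of the other population, which must also
#' reach `d_min`. Optionally restricted to a coding interval.
#'
#' @param alignments List of alignment results from
#'   [align_read_to_contig()].
#' @param populations Character vector parallel to `alignments`.
#' @param contig_length Contig length in bases.
#' @param thresholds A [call_thresholds()].
#' @param coding_interval Optional `c(start, end)` (1-based, inclusive)
#'   restricting reported indels to the coding region.
#' @return Data frame with `pos`, `type` (`"deletion"` / `"insertion"`),
#'   `population`, `n_carrier`, `n_other`. Empty on indel-free data.
#' @export
scan_indels <- function(alignments, populations, contig_length,
                        thresholds = call_thresholds(),
                        coding_interval = NULL) {
  pops <- unique(populations)
  del <- list(); cov <- list(); ins <- list()
  for (p in pops) {
    del[[p]] <- integer(contig_length)
    cov[[p]] <- integer(contig_length)
    ins[[p]] <- integer(contig_length)
  }
  for (j in seq_along(alignments)) {
    a <- alignments[[j]]
    if (is.null(a)) next
    p <- populations[[j]]
    span <- range(a$pairs$contig_pos)
    cov[[p]][span[1]:span[2]] <- cov[[p]][span[1]:span[2]] + 1L
    dpos <- a$pairs$contig_pos[a$pairs$base == "-"]
    del[[p]][dpos] <- del[[p]][dpos] + 1L
    if (!is.null(a$insertions) && nrow(a$insertions)) {
      ip <- a$insertions$contig_pos
      ip <- ip[ip >= 1 & ip <= contig_length]
      ins[[p]][ip] <- ins[[p]][ip] + 1L
    }
  }
  out <- data.frame(pos = integer(0), type = character(0),
                    population = character(0), n_carrier = integer(0),
                    n_other = integer(0))
  if (length(pops) != 2L) return(out)
  p1 <- pops[1]; p2 <- pops[2]
  for (ty in c("deletion", "insertion")) {
    ev <- if (ty == "deletion") del else ins
    for (carrier in pops) {
      other <- setdiff(pops, carrier)
      hit <- which(cov[[carrier]] >= thresholds$d_min &
                   ev[[carrier]] == cov[[carrier]] &
                   cov[[other]] >= thresholds$d_min &
                   ev[[other]] == 0L)
      if (length(hit))
        out <- rbind(out, data.frame(pos = hit, type = ty,
                                     population = carrier,
                                     n_carrier = ev[[carrier]][hit],
                                     n_other = cov[[other]][hit]))
    }
  }
  if (!is.null(coding_interval) && nrow(out))
    out <- out[out$pos >= coding_interval[1] & out$pos <= coding_interval[2], ]
  rownames(out) <- NULL
  out
}
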