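#' Per-contig, per-population pileup container
#'
#' Holds per-site base counts (A, C, G, T) for each population over one
#' contig, together with counts of masked (`N`) bases and the number of
#' aligned reads per population. Masked bases contribute to no allele count,
#' so per-site depth is the row sum of the four base counts.
#'
#' @param contig_id Contig identifier.
#' @param length Contig length in bases.
#' @param pops Population labels (default `"pop1"`, `"pop2"`).
#' @return An object of class `contig_pileup`.
#' @export
new_contig_pileup <- function(contig_id, length, pops = c("pop1", "pop2")) {
  length <- as.integer(length)
  stopifnot(length >= 0L, length(pops) >= 1L)
  mk <- function() matrix(0L, nrow = length, ncol = 4L,
                          dimnames = list(NULL, DNA_BASES))
  structure(list(
    contig_id = contig_id,
    length = length,
    pops = pops,
    counts = stats::setNames(lapply(pops, function(p) mk()), pops),
    n_masked = stats::setNames(
      lapply(pops, function(p) integer(length)), pops),
    aligned_read_count = stats::setNames(
      as.list(integer(length(pops))), pops)),
    class = "contig_pileup")
}

#' @export
print.contig_pileup <- function(x, ...) {
  d <- vapply(x$counts, function(m) mean(rowSums(m)), 0)
  cat("Pileup", x$contig_id, "(", x$length, "bp ) mean depth:",
      paste(sprintf("%s %.2f", names(d), d), collapse = ", "), "\n")
  invisible(x)
}

#' Sliding-window quality trimming of read ends
#'
#' From each end of the read, a window of `trim_window` bases slides inward
#' in `trim_step` increments until its mean quality reaches `q_min`; the cut
#' then advances past any remaining bases of that window that individually
#' fall below `q_min`, so a low-quality run ending inside the first passing
#' window is removed completely. Reads shorter than `min_read_length` after
#' trimming are rejected.
#'
#' @param read Character scalar, the read sequence.
#' @param qualities Integer vector of Phred qualities, one per base.
#' @param thresholds A [call_thresholds()].
#' @return A list with `seq`, `qualities`, `start`/`end` (kept interval,
#'   1-based in the original read) and `rejected` (logical). Rejected reads
#'   have an empty `seq`.
#' @examples
#' th <- call_thresholds()
#' q <- c(rep(10, 60), rep(30, 140))
#' r <- trim_low_quality(strrep("A", 200), q, th)
#' r$start  # 61: the entire low-quality head is removed
#' @export
trim_low_quality <- function(read, qualities, thresholds = call_thresholds()) {
  n <- nchar(read)
  if (length(qualities) != n)
    stop("read and qualities have different lengths (", n, " vs ",
         length(qualities), ")")
  reject <- function() list(seq = "", qualities = integer(0),
                            start = 0L, end = -1L, rejected = TRUE)
  if (n == 0L) return(reject())
  w <- thresholds$trim_window
  s <- thresholds$trim_step
  qm <- thresholds$q_min

  cut_from <- function(q) {
    # returns first kept index when scanning from the left of q
    n <- length(q)
    i <- 1L
    repeat {
      win <- q[i:min(i + w - 1L, n)]
      if (mean(win) >= qm) break
      i <- i + s
      if (i > n) return(n + 1L)
    }
    # advance past leading sub-threshold bases of the passing window
    while (i <= n && q[i] < qm) i <- i + 1L
    i
  }
  left <- cut_from(qualities)
  if (left > n) return(reject())
  right_rev <- cut_from(rev(qualities))
  right <- n - right_rev + 1L
  if (left > right) return(reject())
  len <- right - left + 1L
  if (len < thresholds$min_read_length) return(reject())
  list(seq = substr(read, left, right),
       qualities = qualities[left:right],
       start = left, end = right, rejected = FALSE)
}

#' Mask low-quality bases to N
#'
#' Every base whose Phred quality is strictly below `q_min` is replaced by
#' `N`; length and all other bases are preserved. Masked bases later align
#' neutrally and are excluded from pileup counts.
#'
#' @inheritParams trim_low_quality
#' @return Character scalar, the masked read.
#' @examples
#' mask_low_quality("ACGT", c(19, 20, 35, 2))  # "NCGN"
#' @export
mask_low_quality <- function(read, qualities, thresholds = call_thresholds()) {
  n <- nchar(read)
  if (length(qualities) != n)
    stop("read and qualities have different lengths")
  if (n == 0L) return(read)
  b <- strsplit(read, "")[[1]]
  b[qualities < thresholds$q_min] <- "N"
  paste(b, collapse = "")
}

# scoring used throughout: match +1, mismatch -2, gap open 0,
# gap extension -2 per base; N is neutral (0 against everything)
.dna_sub_matrix <- function() {
  b <- c(DNA_BASES, "N")
  m <- matrix(-2, 5L, 5L, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Align a read to its contig with a stringent local aligner
#'
#' Smith-Waterman local alignment under the scoring scheme match +1,
#' mismatch -2, gap opening 0, gap extension -2 per gap base. `N` bases are
#' scored neutrally (0 against anything) so masked positions align but
#' contribute nothing. An alignment is accepted only if its score reaches
#' half the read's informative (non-`N`) length; reads failing the floor —
#' including reverse-complement reads, since alignment is forward-strand
#' only for directional libraries — are rejected rather than partially
#' counted.
#'
#' @param read Character scalar (already trimmed and masked).
#' @param contig Character scalar, the contig reference sequence.
#' @param min_score_frac Acceptance floor as a fraction of the read's non-`N`
#'   length. Default 0.5.
#' @return `NULL` if rejected, else a list with `score`, `read_start`,
#'   `contig_start`, and `pairs`: a data frame of per-position
#'   correspondences with columns `contig_pos`, `read_pos` (`NA` for a
#'   deletion in the read), and `base` (the read base, `"-"` for deletions,
#'   `"N"` for masked).
#' @export
align_read_to_contig <- function(read, contig, min_score_frac = 0.5) {
  n_informative <- nchar(gsub("N", "", read, fixed = TRUE))
  if (n_informative == 0L) return(NULL)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(contig),
    type = "local", substitutionMatrix = .dna_sub_matrix(),
    gapOpening = 0, gapExtension = 2)
  sc <- Biostrings::score(aln)
  if (sc < min_score_frac * n_informative) return(NULL)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  rp <- Biostrings::start(Biostrings::pattern(aln)) - 1L + cumsum(p != "-")
  cp <- Biostrings::start(Biostrings::subject(aln)) - 1L + cumsum(s != "-")
  keep <- s != "-"  # insertions in the read have no contig coordinate
  list(score = sc,
       read_start = Biostrings::start(Biostrings::pattern(aln)),
       contig_start = Biostrings::start(Biostrings::subject(aln)),
       pairs = data.frame(
         contig_pos = cp[keep],
         read_pos = ifelse(p[keep] == "-", NA_integer_, rp[keep]),
         base = ifelse(p[keep] == "-", "-", p[keep])))
}

#' Build a per-population pileup from aligned reads
#'
#' Tallies, at every contig position, the aligned read bases per population.
#' `N` (masked) bases and deletion gaps are excluded from the A/C/G/T counts;
#' masked bases are tracked separately.
#'
#' @param contig_id Contig identifier.
#' @param contig_length Contig length in bases.
#' @param alignments A list of alignment results from
#'   [align_read_to_contig()] (non-`NULL`).
#' @param populations Character vector parallel to `alignments` giving each
#'   read's population label.
#' @param pops The set of expected population labels.
#' @return A `contig_pileup`.
#' @export
build_pileup <- function(contig_id, contig_length, alignments, populations,
                         pops = c("pop1", "pop2")) {
  if (length(alignments) != length(populations))
    stop("one population label per alignment is required")
  bad <- setdiff(unique(populations), pops)
  if (length(bad))
    stop("unknown population label(s): ", paste(bad, collapse = ", "))
  pu <- new_contig_pileup(contig_id, contig_length, pops)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    if (is.null(a)) next
    pop <- populations[[i]]
    pu$aligned_read_count[[pop]] <- pu$aligned_read_count[[pop]] + 1L
    pr <- a$pairs
    is_base <- pr$base %in% DNA_BASES
    if (any(is_base)) {
      idx <- cbind(pr$contig_pos[is_base], match(pr$base[is_base], DNA_BASES))
      pu$counts[[pop]][idx] <- pu$counts[[pop]][idx] + 1L
    }
    is_n <- pr$base == "N"
    if (any(is_n))
      pu$n_masked[[pop]][pr$contig_pos[is_n]] <-
        pu$n_masked[[pop]][pr$contig_pos[is_n]] + 1L
  }
  pu
}

#' Mean depth of a pileup across populations
#' @param pileup A `contig_pileup`.
#' @return Mean per-site depth summed over populations.
#' @export
pileup_mean_depth <- function(pileup) {
  sum(vapply(pileup$counts, sum, 0)) / pileup$length
}

#' Keep one contig per ortholog hit
#'
#' When several contigs hit the same outgroup protein they represent the
#' same gene, and counting each would inflate polymorphism tallies; only the
#' contig with the largest mean depth is kept per protein. Contigs without a
#' hit are dropped. Depth ties break to the lexicographically smallest
#' contig id so the selection is deterministic.
#'
#' @param pileups Named list of `contig_pileup` objects.
#' @param hits Data frame with columns `contig_id` and `protein_id`.
#' @return Character vector of retained contig ids.
#' @export
select_contigs_per_ortholog <- function(pileups, hits) {
  stopifnot(all(c("contig_id", "protein_id") %in% names(hits)))
  hits <- hits[hits$contig_id %in% names(pileups), , drop = FALSE]
  if (!nrow(hits)) return(character(0))
  depth <- vapply(pileups[hits$contig_id], pileup_mean_depth, 0)
  ord <- order(hits$protein_id, -depth, hits$contig_id)
  hits <- hits[ord, , drop = FALSE]
  sort(hits$contig_id[!duplicated(hits$protein_id)])
}

#' Read FASTQ reads with qualities
#'
#' @param path FASTQ file (Phred+33).
#' @return Data frame with `read_id`, `seq`, and a list-column `qualities`
#'   of integer Phred vectors.
#' @export
read_fastq_reads <- function(path) {
  # Biostrings warns about dropped metadata columns on plain FASTQ input
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  quals <- as(Biostrings::quality(qs), "IntegerList")
  data.frame(read_id = names(qs),
             seq = as.character(qs),
             qualities = I(as.list(quals)))
}

#' Write a set of pileups as a long-format TSV
#'
#' One row per contig x position x population with the four base counts and
#' the masked-base count. Positions are 1-based.
#'
#' @param pileups Named list of `contig_pileup` objects.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_pileup_tsv <- function(pileups, path) {
  rows <- list()
  for (pu in pileups) {
    for (pop in pu$pops) {
      m <- pu$counts[[pop]]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = pu$contig_id, pos = seq_len(pu$length), pop = pop,
        nA = m[, "A"], nC = m[, "C"], nG = m[, "G"], nT = m[, "T"],
        nN = pu$n_masked[[pop]])
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pileups from the long-format TSV written by [write_pileup_tsv()]
#'
#' @param path TSV path.
#' @return Named list of `contig_pileup` objects.
#' @export
read_pileup_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "pop", "nA", "nC", "nG", "nT", "nN")
  stopifnot(all(need %in% names(tab)))
  out <- list()
  for (cid in unique(tab$contig)) {
    sub <- tab[tab$contig == cid, ]
    pops <- unique(sub$pop)
    pu <- new_contig_pileup(cid, max(sub$pos), pops)
    for (pop in pops) {
      ps <- sub[sub$pop == pop, ]
      pu$counts[[pop]][ps$pos, ] <- as.matrix(ps[, c("nA", "nC", "nG", "nT")])
      pu$n_masked[[pop]][ps$pos] <- ps$nN
    }
    out[[cid]] <- pu
  }
  out
}

#' Prepare pileups from reads and contigs (trim, mask, align, tally)
#'
#' Runs the full read-preparation chain for each population: sliding-window
#' end trimming, Q20 masking, stringent local alignment to the read's
#' assigned contig, and pileup construction. Reads failing the trim length
#' floor or the alignment score floor are dropped.
#'
#' @param reads Named list (`pop1`, `pop2`) of read tables as returned by
#'   [read_fastq_reads()] or the simulator (columns `read_id`, `contig`,
#'   `seq`, plus either a `qualities` list-column or a Phred+33 `qual`
#'   string column).
#' @param contigs Named character vector of contig sequences.
#' @param thresholds A [call_thresholds()].
#' @param min_score_frac Alignment acceptance floor (see
#'   [align_read_to_contig()]).
#' @return Named list of `contig_pileup` objects, one per contig with at
#'   least one aligned read; attribute `n_rejected` counts dropped reads.
#' @export
prepare_pileups <- function(reads, contigs, thresholds = call_thresholds(),
                            min_score_frac = 0.5) {
  per_contig <- list()
  n_rejected <- 0L
  for (pop in names(reads)) {
    rd <- reads[[pop]]
    if (!nrow(rd)) next
    quals <- if ("qualities" %in% names(rd)) rd$qualities
             else lapply(rd$qual, function(q) utf8ToInt(q) - 33L)
    for (i in seq_len(nrow(rd))) {
      cid <- rd$contig[i]
      if (!cid %in% names(contigs)) { n_rejected <- n_rejected + 1L; next }
      tr <- trim_low_quality(rd$seq[i], quals[[i]], thresholds)
      if (tr$rejected) { n_rejected <- n_rejected + 1L; next }
      masked <- mask_low_quality(tr$seq, tr$qualities, thresholds)
      a <- align_read_to_contig(masked, contigs[[cid]], min_score_frac)
      if (is.null(a)) { n_rejected <- n_rejected + 1L; next }
      per_contig[[cid]]$alignments <-
        c(per_contig[[cid]]$alignments, list(a))
      per_contig[[cid]]$populations <-
        c(per_contig[[cid]]$populations, pop)
    }
  }
  out <- list()
  for (cid in names(per_contig)) {
    out[[cid]] <- build_pileup(cid, nchar(contigs[[cid]]),
                               per_contig[[cid]]$alignments,
                               per_contig[[cid]]$populations,
                               pops = names(reads))
  }
  if (length(out)) out <- out[order(names(out))]
  attr(out, "n_rejected") <- n_rejected
  out
}
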