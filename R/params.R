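#' Calling thresholds for read cleaning and site calling
#'
#' Bundles the fixed thresholds applied throughout the pipeline: the Phred
#' quality floor used for masking and window trimming, the minimum
#' per-population depth below which a site's status is undetermined, the
#' minor-allele-frequency floor, and the sliding-window trim geometry.
#'
#' The defaults reflect a study design in which at most about 10 individuals
#' per population contributed to the pooled cDNA libraries, so no true allele
#' can segregate below a frequency of 1/20 = 0.05; `f_min` encodes that floor
#' on the read-count frequency.
#'
#' @param q_min Phred quality threshold. Bases with quality strictly below
#'   `q_min` are masked to `N` and window means below `q_min` trigger
#'   end-trimming. Default 20.
#' @param d_min Minimum read depth per population for a site call. Default 4.
#' @param f_min Minimum minor-allele frequency (as a read-count fraction
#'   k/D). Default 0.05.
#' @param trim_window Sliding-window width in bases for end trimming.
#'   Default 30.
#' @param trim_step Step in bases by which the trim window slides inward.
#'   Default 5.
#' @param min_read_length Reads shorter than this after trimming are
#'   discarded. Default 100.
#' @return An object of class `call_thresholds` (a validated list).
#' @examples
#' call_thresholds()
#' call_thresholds(d_min = 6, f_min = 0.1)
#' @export
call_thresholds <- function(q_min = 20L, d_min = 4L, f_min = 0.05,
                            trim_window = 30L, trim_step = 5L,
                            min_read_length = 100L) {
  q_min <- as.integer(q_min)
  d_min <- as.integer(d_min)
  trim_window <- as.integer(trim_window)
  trim_step <- as.integer(trim_step)
  min_read_length <- as.integer(min_read_length)
  stopifnot(d_min >= 1L,
            is.numeric(f_min), f_min > 0, f_min <= 0.5,
            trim_window >= 1L, trim_step >= 1L,
            trim_step <= trim_window,
            min_read_length >= 0L)
  structure(list(q_min = q_min, d_min = d_min, f_min = f_min,
                 trim_window = trim_window, trim_step = trim_step,
                 min_read_length = min_read_length),
            class = "call_thresholds")
}

#' Binomial sequencing-error model parameters
#'
#' Parameters of the error filter used to decide whether the observed minor
#' allele at a site could plausibly be explained by sequencing / reverse
#' transcription errors alone. With per-base error probability `p_err`, the
#' probability that at least `k` of `D` reads at one position carry an error
#' is the binomial upper tail; because an error-driven "polymorphism" may
#' arise at any of the roughly `contig_len_for_test` positions of a contig,
#' the filter works with the probability that at least one position of the
#' contig reaches `k` errors, and discards candidate sites for which that
#' probability exceeds `alpha`.
#'
#' @param p_err Per-base error probability. Default `1e-4`, a deliberately
#'   pessimistic bound dominated by reverse-transcriptase errors (about one
#'   error per 30,000 nucleotides) rather than by the sequencing chemistry.
#' @param contig_len_for_test Number of positions L over which the per-contig
#'   multiple-testing correction is taken. Default 1000, matching a typical
#'   contig length; see `use_contig_length` in [scan_contig()] to use each
#'   contig's own length instead.
#' @param alpha Retention cutoff: a candidate minor allele explainable by
#'   errors with probability greater than `alpha` is discarded. Default 0.01.
#' @param tail If `"upper"` (default) the per-site error probability is
#'   P(at least k errors); `"point"` uses the point mass P(exactly k errors)
#'   instead, for exact replication of implementations written that way. The
#'   two are numerically almost identical at these parameter values.
#' @return An object of class `error_model_params`.
#' @examples
#' error_model_params()
#' @seealso [min_minor_count()]
#' @export
error_model_params <- function(p_err = 1e-4, contig_len_for_test = 1000L,
                               alpha = 0.01, tail = c("upper", "point")) {
  tail <- match.arg(tail)
  contig_len_for_test <- as.integer(contig_len_for_test)
  stopifnot(is.numeric(p_err), p_err > 0, p_err < 1,
            contig_len_for_test >= 1L,
            is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(p_err = p_err, contig_len_for_test = contig_len_for_test,
                 alpha = alpha, tail = tail),
            class = "error_model_params")
}

#' Six-class physicochemical amino-acid scheme
#'
#' Partition of the 20 standard amino acids into six physicochemical classes:
#' hydrophobic, aromatic, polar neutral, acidic, basic, and proline (a
#' singleton class, reflecting its unique backbone geometry). An amino-acid
#' replacement crossing class boundaries is "radical"; one within a class is
#' "conservative".
#'
#' The six class names do not by themselves pin down every assignment
#' (cysteine, glycine and histidine in particular admit several defensible
#' placements), so the membership is explicit, overridable, and echoed into
#' report headers for reproducibility. The default places C and G with the
#' hydrophobics and H with the basics.
#'
#' @param classes Named list mapping class name to a character vector of
#'   one-letter amino-acid codes. Must partition the 20 standard residues.
#' @return An object of class `aa_class_scheme`: a named character vector
#'   mapping each residue to its class name.
#' @examples
#' sch <- aa_class_scheme()
#' sch[["D"]]  # "acidic"
#' @export
aa_class_scheme <- function(classes = list(
    hydrophobic  = c("G", "A", "V", "L", "I", "M", "C"),
    aromatic     = c("F", "Y", "W"),
    polar_neutral = c("S", "T", "N", "Q"),
    acidic       = c("D", "E"),
    basic        = c("K", "R", "H"),
    proline      = "P")) {
  aas <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(aas))
    stop("amino-acid classes overlap: ", paste(aas[duplicated(aas)], collapse = ", "))
  std <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  missing <- setdiff(std, aas)
  if (length(missing))
    stop("amino acids not assigned to any class: ", paste(missing, collapse = ", "))
  extra <- setdiff(aas, std)
  if (length(extra))
    stop("unknown amino-acid codes: ", paste(extra, collapse = ", "))
  map <- rep(names(classes), lengths(classes))
  names(map) <- aas
  structure(map[std], class = "aa_class_scheme")
}

#' Read an amino-acid class scheme from a two-column TSV
#'
#' The file must have columns `aa` (one-letter code) and `class`; it is
#' validated as a total partition of the 20 standard residues.
#'
#' @param path Path to a tab-separated file with header `aa<TAB>class`.
#' @return An `aa_class_scheme` object.
#' @export
read_aa_class_scheme <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("aa", "class") %in% names(tab)))
  aa_class_scheme(split(tab$aa, tab$class))
}

#' @export
print.call_thresholds <- function(x, ...) {
  cat("Call thresholds: Q_min =", x$q_min, "| D_min =", x$d_min,
      "| f_min =", x$f_min, "\n  trim window", x$trim_window,
      "step", x$trim_step, "| min read length", x$min_read_length, "\n")
  invisible(x)
}

#' @export
print.error_model_params <- function(x, ...) {
  cat("Error model: p_err =", format(x$p_err), "| L =", x$contig_len_for_test,
      "| alpha =", x$alpha, "| tail =", x$tail, "\n")
  invisible(x)
}
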