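#' Round half away from zero to a given number of decimals
#' @param x Numeric.
#' @param digits Decimal places (default 1).
#' @return Numeric, rounded half-up.
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditional on both margins, the p-value is the sum of the
#' hypergeometric probabilities of every margin-preserving table whose
#' probability does not exceed that of the observed table (the convention
#' of mainstream statistical software; computed via [stats::fisher.test()]).
#' A table with an empty row or column margin carries no information and
#' returns `p = 1` with a warning.
#'
#' @param tab A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled by row.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(11, 10, 1, 13), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2L, 2L, byrow = TRUE)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin: Fisher test carries no information, p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Annotation map for gene-set enrichment
#'
#' @param annotations Named list: gene id -> character vector of category
#'   labels (may be empty for genes known but unannotated).
#' @param universe Character vector of all genes under consideration; every
#'   annotated gene must belong to it. Defaults to the annotated genes.
#' @return Object of class `annotation_map`.
#' @export
annotation_map <- function(annotations, universe = names(annotations)) {
  stopifnot(is.list(annotations), !is.null(names(annotations)))
  outside <- setdiff(names(annotations), universe)
  if (length(outside))
    stop("annotated genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  structure(list(annotations = annotations, universe = universe),
            class = "annotation_map")
}

#' Read an annotation map from a two-column TSV (gene, category)
#'
#' Multiple rows per gene accumulate categories; a gene with an empty
#' category field is recorded as annotated with no categories.
#'
#' @param path TSV with header columns `gene` and `category`.
#' @return An `annotation_map`.
#' @export
read_annotation_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "category") %in% names(tab)))
  ann <- lapply(split(tab$category, tab$gene),
                function(x) setdiff(unique(x), ""))
  annotation_map(ann)
}

#' Expression-category enrichment report for radical substitutions
#'
#' Builds the per-lineage gene bookkeeping used to ask whether genes hit by
#' radical substitutions on one lineage are enriched for a given annotation
#' category (e.g. "expressed in the eye"). For each lineage (`pop1`,
#' `pop2`, `unoriented`), the distinct genes carrying at least one radical
#' substitution on that lineage are counted, split into genes with and
#' without annotation records, and the annotated ones checked for the
#' category. A gene with radical substitutions on more than one lineage is
#' counted once per lineage. Percentages (of annotated genes and of all
#' genes in the lineage) are rounded half-up to one decimal. The Fisher
#' exact test contrasts the two oriented lineages: annotated genes in the
#' category vs not, pop1 row vs pop2 row.
#'
#' @param substitutions Data frame from [analyze_substitutions()]; only
#'   rows with `radical == TRUE` are used. Must carry a `gene` column (see
#'   [attach_genes()]) or `contig` ids present in `annotation$universe`.
#' @param annotation An [annotation_map()]. Genes absent from
#'   `annotations` count as unannotated.
#' @param category The category label to test.
#' @return A list with `table` (one row per lineage: `n_genes`,
#'   `n_unannotated`, `n_annotated`, `n_in_category`, `pct_of_annotated`,
#'   `pct_of_total`) and `p_value` (two-sided Fisher; `NA` when either
#'   oriented lineage has no annotated genes, since the contrast is then
#'   undefined).
#' @export
eye_enrichment_report <- function(substitutions, annotation, category) {
  stopifnot(inherits(annotation, "annotation_map"))
  s <- substitutions[substitutions$radical %in% TRUE, , drop = FALSE]
  gene_col <- if ("gene" %in% names(s)) "gene" else "contig"
  lineages <- c("pop1", "pop2", "unoriented")
  lin <- ifelse(is.na(s$lineage), "unoriented", s$lineage)
  rows <- lapply(lineages, function(l) {
    genes <- unique(s[[gene_col]][lin == l])
    annotated <- genes[genes %in% names(annotation$annotations)]
    in_cat <- annotated[vapply(annotation$annotations[annotated],
                               function(a) category %in% a, TRUE)]
    data.frame(lineage = l,
               n_genes = length(genes),
               n_unannotated = length(genes) - length(annotated),
               n_annotated = length(annotated),
               n_in_category = length(in_cat),
               pct_of_annotated = if (length(annotated))
                 round_half_up(100 * length(in_cat) / length(annotated)) else NA_real_,
               pct_of_total = if (length(genes))
                 round_half_up(100 * length(in_cat) / length(genes)) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  p <- NA_real_
  a1 <- tab$n_annotated[1]; a2 <- tab$n_annotated[2]
  if (a1 > 0 && a2 > 0) {
    m <- matrix(c(tab$n_in_category[1], a1 - tab$n_in_category[1],
                  tab$n_in_category[2], a2 - tab$n_in_category[2]),
                2L, 2L, byrow = TRUE)
    p <- fisher_exact_2x2(m)
  }
  list(table = tab, p_value = p)
}

#' Attach gene/protein identifiers to a substitution table
#'
#' @param substitutions Data frame with a `contig` column.
#' @param hits Data frame with `contig_id` and `protein_id` (or `gene`).
#' @return The substitution table with a `gene` column appended.
#' @export
attach_genes <- function(substitutions, hits) {
  key <- if ("gene" %in% names(hits)) "gene" else "protein_id"
  substitutions$gene <- hits[[key]][match(substitutions$contig, hits$contig_id)]
  substitutions
}

#' Hypergeometric term enrichment over an annotation map
#'
#' For every category appearing in the map, tests whether the study gene
#' set contains more genes of that category than expected from drawing
#' `|set|` genes without replacement from the universe: the upper-tail
#' hypergeometric probability `P(X >= k)`. No multiple-testing correction
#' is applied by default; the Benjamini-Hochberg adjusted column is added
#' when `adjust = TRUE`.
#'
#' @param gene_set Character vector of genes, a subset of the universe.
#' @param annotation An [annotation_map()].
#' @param adjust Add a BH-adjusted p-value column (default `FALSE`).
#' @return Data frame ordered by p-value with `category`, `k` (in set),
#'   `K` (in universe), `n` (set size), `N` (universe size), `p_value`.
#' @export
term_enrichment <- function(gene_set, annotation, adjust = FALSE) {
  stopifnot(inherits(annotation, "annotation_map"))
  outside <- setdiff(gene_set, annotation$universe)
  if (length(outside))
    stop("genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  gene_set <- unique(gene_set)
  N <- length(annotation$universe)
  n <- length(gene_set)
  cats <- sort(unique(unlist(annotation$annotations, use.names = FALSE)))
  if (!length(cats))
    return(data.frame(category = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0)))
  rows <- lapply(cats, function(cat) {
    members <- names(annotation$annotations)[
      vapply(annotation$annotations, function(a) cat %in% a, TRUE)]
    K <- length(members)
    k <- length(intersect(gene_set, members))
    data.frame(category = cat, k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$category), , drop = FALSE]
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
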