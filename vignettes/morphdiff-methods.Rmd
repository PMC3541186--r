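---
title: "morphdiff: methods, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morphdiff: methods, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphdiff)
```

## The problem

Pooled cDNA libraries from two recently diverged populations of one
species — here generically `pop1` and `pop2`, after the surface-fish and
cavefish morphs this kind of survey was designed for — are sequenced at
shallow depth (a handful of reads per contig per population). Three things
make naive SNP calling on such data misleading:

* depth is so low that a single erroneous read can mimic a polymorphism;
* the pools contain few individuals, so very rare alleles cannot be real;
* reads are single-pass with heterogeneous quality along their length.

`morphdiff` addresses each with an explicit, parameterized rule, then
carries the surviving calls through to protein-level consequences: which
fixed inter-population differences change the protein, on which lineage
each change arose, and whether it crosses physicochemical class
boundaries.

## Read preparation

**Trimming.** A window of `trim_window` bases (default 30) slides inward
from each read end in `trim_step` (default 5) increments until its mean
Phred quality reaches `q_min` (default 20); the cut then advances past any
remaining individual bases of that window still below `q_min`, so a
low-quality run that ends inside the first acceptable window is removed
completely rather than partially. Reads shorter than `min_read_length`
(default 100) afterwards are discarded. The per-base refinement is the
package's own choice: a pure window-mean rule can leave up to
`trim_window − 1` sub-threshold bases attached to the read end, which the
downstream masking would erase anyway; trimming them is cheaper and makes
the window semantics exact at the boundary.

**Masking.** Every remaining base with quality strictly below `q_min`
becomes `N`. Masked bases align neutrally and never contribute to allele
counts, so a quality-20 base is the worst base that can ever support a
call — this is the single quality decision the rest of the pipeline sees,
which is why the simulator's two-point quality model (one value below 20,
one at or above) loses nothing testable.

**Alignment.** Each read is realigned to its assigned contig with a local
(Smith–Waterman) aligner under match +1, mismatch −2, gap opening 0, gap
extension −2 per base; `N` scores 0 against everything. The mismatch and
gap-opening values are the stringent realignment settings the method
calls for; match +1 and extension −2 complete the scheme symmetrically
(a gap base costs what a mismatch costs). An alignment is accepted only
if its score reaches half the read's informative (non-`N`) length. The
floor is taken relative to the *read*, not the aligned region: a floor
relative to aligned length would accept any short perfect subword — for
instance a 10-bp coincidental hit of a reverse-complement read — and
defeat its own purpose. Alignment is forward-strand only because the
cDNA inserts are directional; `both_strands = TRUE` exists for foreign
data. One consequence worth knowing: a true variant in the last couple of
bases of a read is clipped (the local alignment ends before a terminal
mismatch), so terminal positions are slightly under-covered. This is the
intended "did not align properly" behaviour, not a loss of signal the
method ever promised to use.

**Ortholog deduplication.** When several contigs hit the same outgroup
protein they are fragments or alleles of one gene; keeping all of them
would count the same polymorphism repeatedly. Only the contig with the
largest mean depth survives per protein id; ties break to the smaller
contig id so runs are reproducible.

## The calling model

At one site in one population with base counts summing to depth `D`:

* `D < d_min` (default 4): the population's status is *undetermined* at
  this site.
* Otherwise the minor allele (second-most-frequent base) with count `k`
  is accepted iff

  1. `P_any(k) = 1 − (1 − P_site(k))^L ≤ α`, where
     `P_site(k) = P(Binom(D, p_err) ≥ k)` with `p_err = 10⁻⁴` and
     `L = 1000`, `α = 0.01`;
  2. `k / D ≥ f_min = 0.05`.

`min_minor_count(D)` returns the smallest such `k`: 2 at depth 4, still 2
at depth 10, 3 at depth 50. The tail probability `P(≥k)` is used rather
than the point mass `P(=k)` because "could be explained by errors" is a
tail event; at these parameters the two agree for every depth in the
working range (a test asserts this), and `tail = "point"` is available
for exact replication of implementations written the other way.

Parameter meanings and defaults:

| parameter | default | meaning |
|---|---|---|
| `p_err` | 1e-4 | per-base error probability, dominated by reverse transcription (~1/30,000) padded for safety |
| `contig_len_for_test` (L) | 1000 | positions per contig over which an error-driven pattern could arise anywhere; ~ the mean contig length |
| `alpha` | 0.01 | retention cutoff on `P_any` |
| `d_min` | 4 | minimal per-population depth for any call |
| `f_min` | 0.05 | minor-allele read-frequency floor, from ≤10 individuals ⇒ ≤20 alleles per pool |
| `q_min` | 20 | Phred mask/trim threshold |

`L` is fixed at 1000 by default rather than using each contig's true
length; `use_contig_length = TRUE` switches to the per-contig value. The
fixed value keeps the threshold identical across contigs, which makes
genome-wide counts comparable; the difference only matters for contigs
far from 1 kb and depths sitting exactly at a threshold boundary.

**Cross-population classes.** Both populations polymorphic with equal
allele sets → shared polymorphism; with unequal sets → divergent
polymorphism (set inequality, not disjointness — a site {A,C} vs {A,G} is
divergent); exactly one polymorphic and the other monomorphic at adequate
depth → polymorphism in one morph; the other below `d_min` → one morph,
unknown other; both monomorphic at adequate depth with different alleles
→ fixed difference; with the same allele → monomorphic-identical;
everything else → undetermined. The classes are exhaustive and mutually
exclusive over covered sites, and a property test asserts the partition.

A site polymorphic in one morph while the other morph is fixed for an
allele outside the first morph's set still falls in "polymorphism in one
morph"; the allele sets are carried in the output so downstream users can
refine this if their question needs it.

## Coding projection and substitutions

Per-population consensus sequences take the majority base per site,
falling back to the reference contig base (flagged) below `d_min` or at
exact ties, so consensus building is deterministic. The three forward
frames of the contig are translated and locally aligned to the outgroup
protein under BLOSUM62 (gap open 10, extend 4); the best frame wins, and
the projection is rejected below 40% identity or 30 aligned residues.
Those floors are the package's choice — the method itself only says the
outgroup alignment defines the coding region — and they are deliberately
permissive for a ~100-My outgroup while still rejecting wrong frames,
whose identity hovers near the ~6% random-translation baseline.

Fixed differences inside the aligned interval are grouped by codon: a
codon hit by two nucleotide changes is one amino-acid event that counts
twice at the nucleotide level, so nucleotide and amino-acid tallies are
both exact. Each event is synonymous, non-synonymous, or nonsense
(exactly one side a stop) under the standard genetic code; codons
containing `N` are skipped and counted. Non-synonymous events are
oriented by parsimony — outgroup residue equal to one population's
residue puts the mutation on the other population's lineage; equal to
neither (or unaligned) leaves it unoriented. Radical changes are those
crossing the six-class scheme:

hydrophobic {G A V L I M C} · aromatic {F Y W} · polar neutral {S T N Q}
· acidic {D E} · basic {K R H} · proline {P}

The six class names admit several defensible memberships (C, G and H in
particular); the scheme is therefore data, not code — overridable via
`aa_class_scheme()` or a TSV, and echoed into the substitution-table
header of every run so results are interpretable later. Premature stops
are reported when exactly one population's consensus carries an in-frame
stop upstream of the outgroup-aligned C-terminus, with the fraction of
the aligned protein lost; a stop at the terminal aligned codon is not
premature.

## Enrichment

The per-lineage report counts distinct genes with radical substitutions
on each lineage (a gene hit on both lineages appears in both rows — the
rows describe lineages, not a partition of genes), splits them by
annotation availability, and tests the two oriented lineages against each
other with Fisher's exact test on the annotated × in-category table
(two-sided, by summation of all margin-preserving tables no more probable
than the observed one). Percentages are rounded half away from zero at
one decimal. The generic `term_enrichment()` applies upper-tail
hypergeometric tests over a user-supplied gene→category map; no DAG
structure is assumed, and no multiple-testing correction is applied
unless requested (`adjust = TRUE`, Benjamini–Hochberg), since the primary
use is ordering terms.

## The simulator, and what passing its tests means

`sim_config()` describes two populations of `2 × n_individuals_per_pop`
haplotypes derived from a random ancestral coding sequence (uniform sense
codons, so no spurious stops), with optional non-coding flanks. Planted
events are mutually disjoint sites: within-population polymorphisms at a
configured minor-allele frequency (rounded to an achievable haplotype
count, and rejected below `1/(2n)`), and fixed differences placed one per
codon, non-synonymous with probability `nonsyn_fraction` (never nonsense,
so premature-stop detection stays a controlled experiment) and assigned
to a uniformly chosen lineage. The outgroup protein mutates each residue
independently with probability `outgroup_protein_divergence`; truth
records mark events at outgroup-mutated residues as unorientable. Reads
are full-contig-length copies of uniformly chosen haplotypes (a
`read_length` option gives fragments), with a Poisson read count per
contig per population, independent per-base errors at `error_rate`
(logged individually), and a two-point quality model with a fraction
`q_low_fraction` of bases below Q20.

Defaults mirror the study design this pipeline is modelled on: 999-bp
coding contigs (mean contig ≈ 1 kb), mean depth 6.8, error rate `10⁻⁴`,
10 individuals per pool, roughly one fixed difference per 6–7 kb with a
quarter non-synonymous, and a ~25%-diverged outgroup.

What the simulator does **not** emulate — and hence what green tests do
not show about real data: assembly artifacts and chimeric contigs,
vector/adapter contamination, paralog collapse (reads from two loci on
one contig), position- or context-dependent error rates, realistic
quality-score distributions, indels (a clean negative control for the
indel scan, matching the empirical finding of none, but not a test of
indel sensitivity), and any form of selection or linkage structure among
planted sites. Recovery numbers from synthetic runs are statements about
the calling machinery under its own assumptions, not about performance on
a real library.

Determinism: a configuration (including its seed) fixes every byte of
output; the three generator stages use seed, seed+1 and seed+2 so each
stage is independently reproducible.

## Numerical and degenerate-input choices

* Threshold search walks `k = 1 … D`; if nothing satisfies both filter
  conditions the site cannot be called polymorphic at that depth (`NA`).
* Consensus ties and sub-`d_min` sites keep the reference base, flagged
  `ambiguous` / `untrusted`, never a random pick.
* Depth ties in ortholog deduplication break lexicographically.
* Fisher tables with an empty margin return p = 1 with a warning;
  per-lineage reports with no annotated genes in an oriented lineage
  return `NA` rather than a p-value from an undefined contrast.
* Empty reads, empty pileups, empty truth sets and empty substitution
  tables all flow through as empty results, not errors; the test suite
  pins each of these.

## Problem sizes used in validation

The test and acceptance runs use 200-contig (300 bp, mean depth 25,
error-free) simulations for recovery — large enough that ~120 fixed
differences are planted and every sensitivity/precision statement is over
dozens of events — and 500-contig (999 bp, depth 6.8, error rate `10⁻⁴`)
simulations for false-positive calibration, where the filter's design
guarantee (probability ≤ α of any surviving false site per contig) is
checked directly against the per-contig false-call fraction. Smaller runs
exercise the aligner path end to end.

## Known limitations

* Reads must arrive pre-assigned to contigs (the `contig|read` id
  convention); the package realigns but does not assign.
* Allele-frequency reasoning is read-level; no individual genotypes or
  likelihoods are modelled, matching the pooled design.
* Orientation trusts a single outgroup; parallel substitutions and
  reversions over long divergence times make some true lineage
  assignments unknowable, which is why "unoriented" is a first-class
  outcome rather than an error.
* The premature-stop report and the substitution table are restricted to
  the outgroup-aligned interval; genuinely novel C-terminal extensions
  are invisible by construction.
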