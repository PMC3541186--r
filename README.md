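# morphdiff

Polymorphism and fixed-difference analysis for low-depth EST (expressed
sequence tag) data from **two populations of one species** — the setting of
classic surface-fish / cavefish transcriptome comparisons, where pooled
cDNA libraries from each morph are Sanger-sequenced at shallow depth and
the question is which sites vary within a morph, which differ between
morphs, and which protein changes each lineage has accumulated.

## Who it is for

Researchers with (a) per-population reads with base qualities, (b) contig
consensus sequences, (c) outgroup proteins and a contig→protein ortholog
table, who want error-aware SNP calls and polarized amino-acid
substitutions without a reference genome. A built-in simulator generates
two-population datasets with a complete truth set, so every stage can be
validated before touching real data.

## The model

At a site of depth `D` in one population, a minor allele seen `k` times is
accepted as real only if both hold:

1. **Binomial error filter.** With per-base error probability `p` (default
   `10⁻⁴`), the chance of at least `k` errors at one position is the upper
   tail `P_site(k) = Σ_{j≥k} C(D,j) p^j (1−p)^{D−j}`. Because any of the
   `L` positions of a contig (default `L = 1000`) could show such a
   pattern, the site is kept only if
   `P_any(k) = 1 − (1 − P_site(k))^L ≤ α` (default `α = 0.01`).
2. **Frequency floor.** `k/D ≥ f_min` (default 0.05): a pool of at most 10
   diploid individuals (20 alleles) cannot carry a rarer true allele.

At the defaults a depth-4 site needs `k = 2`. Sites with depth < 4 in a
population are *undetermined* for it. Across populations each covered site
is classified as shared polymorphism, divergent polymorphism, polymorphism
in one morph (with or without knowledge of the other), **fixed
difference** (all reads of one morph carry one allele, all reads of the
other a different allele, both at depth ≥ 4), monomorphic-identical, or
undetermined.

Fixed differences are projected onto the coding frame chosen by aligning
the translated contig to its outgroup protein; codon changes are
synonymous, non-synonymous or nonsense; non-synonymous changes are
polarized by outgroup parsimony (outgroup = one morph's residue ⇒ the
other morph's lineage mutated) and scored **radical** when the two
residues fall in different physicochemical classes (hydrophobic /
aromatic / polar neutral / acidic / basic / proline). Gene sets carrying
radical changes are tested for annotation enrichment (e.g. "expressed in
the eye") with Fisher's exact test, and generically with upper-tail
hypergeometric tests.

## Worked example

```r
library(morphdiff)

# the depth-dependent calling threshold
min_minor_count(c(4, 10, 50))
#> [1] 2 2 3

# a simulated two-population study with planted truth
cfg <- sim_config(n_contigs = 5, contig_length = 300, depth_mean = 15,
                  fixed_diff_rate = 0.01, polymorphic_site_rate = 0.005,
                  nonsyn_fraction = 0.5, error_rate = 1e-4, seed = 3)
run <- run_pipeline(run_config(out_dir = tempfile(), simulate = cfg))
run$summary$fixed_differences
#> [1] 10
run$summary$lineage_counts
#> $pop1
#> [1] 4
#> $pop2
#> [1] 2
#> $unoriented
#> [1] 0

recovery_report(run)
#>         event_type tp fp fn sensitivity precision n_subthreshold
#> 1 polymorphic_site  9  0  7      0.5625         1              0
#> 2 fixed_difference 10  0  0      1.0000         1              0
#> 3     lineage_call  6  0  0      1.0000         1              0
#> 4     radical_flag  4  0  0      1.0000         1              0
```

All ten planted fixed differences are recovered, and all six
amino-acid-changing ones are assigned their true lineage. The run writes
`pileup.tsv`, `sites.tsv`, `substitutions.tsv`, `summary.json` and a log
under the output directory. Precision is 1 by design on clean data;
polymorphic-site sensitivity below 1 at mean depth 15 reflects planted
minor alleles whose realized read counts fall under the depth-dependent
threshold — expected behaviour of the filter, not a defect.

The same stages are available from a shell:

```sh
Rscript inst/cli/morphdiff simulate --config cfg.yaml --out sim/ --seed 7
Rscript inst/cli/morphdiff call --pileup sim/pileup.tsv --out calls/ \
    --p-err 1e-4 --alpha 0.01 --contig-len 1000 --min-depth 4 --min-maf 0.05
```

## Vignette

`vignettes/morphdiff-methods.Rmd` describes the statistical model, every
tunable threshold with its default and rationale, what the simulator does
and does not emulate, and the package's numerical and design choices.
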