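# peakperm

Permutation tests for genomic peak co-localization, binned Fisher
co-occurrence, and TMT IP-MS differential enrichment — with synthetic-data
generators that plant known effects so every stage can be validated against
ground truth.

## The problem

Chromatin studies produce sets of binding sites (*peaks*) and ask whether
those sites coincide with annotations (histone marks, other factors) more
than chance would allow, and which proteins physically co-purify with the
factor in quantitative immunoprecipitation–mass spectrometry (IP-MS).
`peakperm` implements the statistical core of both analyses.

**Enrichment.** For a query peak set *Q* and annotation *A* on a genome with
exclusion regions *E*, the statistic is the base-pair overlap
*O* = |⋃Q ∩ ⋃A|. The null is built by length-matched shuffling: each
annotation interval is relocated uniformly into the eligible space *G* \ *E*,
preserving its length, optionally also matching its tiling-array probe
density (for ChIP-chip annotations) to within 0.1. With *N* permutations
giving S₁…S_N, the add-one empirical p-value is

    p = (1 + #{i : Sᵢ ≥ O}) / (N + 1)

(and symmetrically for depletion), so 1000 permutations bottom out at
1/1001 ≈ 0.001. The effect size is log₂(O / mean(S)), with a 1 bp pseudocount
only when needed; Benjamini–Hochberg adjustment is applied once across all
annotations tested against the same query.

**Co-occurrence.** Directed peak-overlap counts (Venn numbers) plus a Fisher
exact test on a genome binning: each bin is flagged as hit by either set and
the 2×2 bin-count table is tested two-tailed by probability mass, reporting
the sample odds ratio *ad/bc*.

**IP-MS.** Co-isolation filtering (> 25% interference excluded), total
normalization (channel totals → grand mean), peptide-to-protein aggregation,
median normalization (channel medians → grand median), then per-protein
pooled-variance Student t-tests of bait vs control channels on log₂
abundances; enriched means p < 0.05 with positive bait log₂ fold change.

See the methods vignette (`vignettes/methods.Rmd`) for the full model,
assumptions, and numerical choices.

## Worked example

```r
library(peakperm)

gen <- simulate_genome(n_chroms = 2, chrom_length = 3e5, seed = 1)
pk  <- simulate_peaks(gen$genome, gen$exclusions, n_query = 150,
                      n_annotation = 150, theta = 0.8, peak_median = 300,
                      seed = 2)
bg  <- simulate_peaks(gen$genome, gen$exclusions, n_annotation = 150,
                      theta = 0, peak_median = 300, seed = 3,
                      query = pk$query)
fit <- enrichment_test(pk$query,
                       list(planted = pk$annotation,
                            background = bg$annotation),
                       gen$genome, exclusions = gen$exclusions,
                       n_permutations = 200, seed = 4)
fit
#> Permutation enrichment test (200 permutations per annotation, seed 4)
#>
#>  annotation observed_bp expected_bp  log2fc direction       p       q
#>     planted       20835      4315.5  2.2700  enriched 0.00498 0.00995
#>  background        4060      4339.7 -0.0961  depleted 0.39300 0.39300
```

The annotation planted at 80% co-localization is recovered at the minimal
attainable p (1/201) while an independent background set sits in the body of
its null. The IP-MS stage works the same way:

```r
sim <- simulate_tmt(n_proteins = 300, n_true_interactors = 5, seed = 7)
ipms_test(sim$matrix)
#> IP-MS differential enrichment: 300 proteins (300 tested), 11 enriched at p < 0.05
#>
#>         protein log2fc       t        p significant
#>            bait   5.02 112.500 3.75e-08        TRUE
#>    interactor01   2.72  24.910 1.54e-05        TRUE
#>    interactor02   3.17  13.180 1.91e-04        TRUE
#>    ...
```

File-based orchestration (`run_simulate()`, `run_enrich()`, `run_coloc()`,
`run_ipms()`) and a command-line dispatcher (`inst/cli/peakperm.R`, with
subcommands `simulate | enrich | coloc | ipms`, YAML config support, and JSON
run manifests) wrap the same functions for pipeline use.

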