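---
title: "Methods: permutation-based genomic co-localization and TMT IP-MS enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based genomic co-localization and TMT IP-MS enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakperm)
```

# The scientific problem

A chromatin study typically produces a set of binding sites (*peaks*) for a
protein of interest and asks two kinds of questions:

1. **Genomic co-localization.** Do these sites coincide with an annotation —
   a histone mark, another factor's sites — more than expected by chance?
2. **Physical interaction.** Which proteins co-purify with the factor in a
   quantitative immunoprecipitation–mass-spectrometry (IP-MS) experiment?

`peakperm` implements the statistical core of both analyses: a
permutation-based enrichment test for interval sets on a genome, a binned
Fisher co-occurrence test, and the normalization/testing pipeline for
multiplexed (TMT) IP-MS data — together with synthetic-data generators that
plant known effects so every stage can be validated against ground truth.

# The permutation null for interval overlap

## Model

Let $Q$ be the query peak set and $A$ an annotation set on a genome $G$ with
an exclusion (blacklist/gap) set $E$. The test statistic is the base-pair
overlap

$$ O = \mathrm{overlap\_bp}(Q, A) = \left| \bigcup Q \cap \bigcup A \right|, $$

the number of bases covered by both sets after merging each. The null
hypothesis is that $A$'s positions are unrelated to $Q$'s: it is simulated by
*length-matched shuffling* — each interval of $A$ is independently relocated
to a uniformly chosen position inside the eligible space $G \setminus E$,
preserving its exact length and never touching an excluded base. Relocated
intervals may overlap each other (real peak sets can, and forbidding it would
bias the null). Placement is genome-wide by default; `same_chrom = TRUE`
restricts each interval to its original chromosome.

For $N$ permutations with shuffled statistics $S_1, \dots, S_N$, the
*add-one* empirical p-value is

$$ p_\text{enriched} = \frac{1 + \#\{i : S_i \ge O\}}{N + 1}, \qquad
   p_\text{depleted} = \frac{1 + \#\{i : S_i \le O\}}{N + 1}, $$

so the smallest attainable p at $N = 1000$ is $1/1001$, which prints as
$0.001$ — the value the method reports when the observed overlap beats every
permutation. The headline p-value is the smaller tail and the reported
direction is that tail's; both tails are kept in the output. The effect size
is

$$ \log_2 \mathrm{FC} = \log_2 \frac{O}{\bar S}, \qquad
   \bar S = \tfrac1N \sum_i S_i, $$

with a 1 bp pseudocount added to *both* numerator and denominator only when
either is zero. Testing several annotations against one query is one family:
Benjamini–Hochberg adjustment is applied across the annotations in a single
step, and the result table is sorted by q, then $|\log_2 \mathrm{FC}|$.

## Probe-density matching for ChIP-chip annotations

Annotations derived from tiling microarrays (ChIP-chip) can only be observed
where probes exist, so a fair null must respect the array design. The *probe
density* of a peak is the fraction of its bases covered by probes. In a
probe-matched shuffle each relocated peak must reproduce its original probe
density to within an absolute tolerance of $0.1$ (a difference of exactly
$0.1$ passes); placements are redrawn per peak until matched or
`max_attempts = 100` draws are spent, keeping the last draw otherwise. A
permutation is acceptable when at least $99\%$ of its peaks matched;
unacceptable permutations are flagged and regenerated (continuing the same
random stream) up to 10 times, keeping the best. Peaks are processed
sequentially, one placement per attempt, so an independent accept/reject
oracle can replay the identical random stream — this reproducibility is part
of the package's acceptance surface.

## Numerical and implementation choices

* Intervals are held in `GenomicRanges::GRanges` (1-based, closed); BED's
  0-based half-open convention is converted exactly at the I/O boundary.
  Merging uses `reduce()`, which also merges bookended intervals.
* Uniform placement is implemented by rejection: draw a base uniformly from
  the eligible space, accept if the interval fits inside its segment. This
  is exactly the uniform law over valid start positions (verified by a
  chi-square test) and is far faster than enumerating valid starts.
* Reproducibility: a master seed generates one sub-seed per permutation, so
  results are independent of evaluation order and bit-identical across runs.
* Probe density is computed from a prefix-sum index of the merged probe
  cover, $O(\log m)$ per query after an $O(m)$ build.

# Binned Fisher co-occurrence

The co-localization report combines directed overlap counts (how many peaks
of $A$ touch $B$ and vice versa — the numbers behind a Venn diagram) with a
Fisher exact test: the genome is cut into consecutive bins of width $w$ (by
default the rounded mean merged-interval length of both sets; the last bin of
each chromosome is truncated), each bin is flagged as hit by $A$ and/or $B$,
and the $2 \times 2$ table of bin counts is tested. The two-tailed p sums the
hypergeometric probabilities of all tables with the observed margins that are
no more probable than the observed one. The reported odds ratio is the sample
cross-product estimate $ad/bc$ (with $0/0 = \mathrm{NaN}$, $x/0 = \infty$),
not the conditional MLE, because it is the quantity practitioners read off
the table.

# The TMT IP-MS pipeline

Quantification proceeds in a fixed order, mirroring standard practice:

1. **Co-isolation filter.** Peptides whose co-isolation interference exceeds
   $25\%$ are excluded (exactly $25\%$ is retained; missing values are
   retained).
2. **Total normalization.** Every channel is scaled so channel totals equal
   the grand mean of the original totals, removing loading differences.
3. **Aggregation.** Peptide rows are summed into protein groups.
4. **Median normalization.** Every channel is divided by its median and
   multiplied by the grand median ("normalized to medium peptide amount" in
   the source protocol is read as the median, the standard location
   estimator in proteomics normalization).
5. **Test.** Per protein, a pooled-variance two-sided Student t-test of bait
   vs control channels on $\log_2$ abundances. A protein is *enriched* when
   $p < 0.05$ and its bait $\log_2$ fold change is positive. No multiple
   testing correction is applied to this call (matching the source
   protocol); a BH column is included for information. Rows with a zero or
   missing value in any channel are not tested on the log scale. Rows whose
   pooled standard error is numerically zero (the criterion `t.test` itself
   uses) get $p = 1$ when the group means agree and the smallest
   representable positive p when they differ, keeping such rows rankable.

A worked example: bait channels $(1, 2, 3)$ vs control $(4, 5, 6)$ on the raw
scale give $t = -3.674$ on 4 degrees of freedom and $p = 0.0213$
($2\,P(T_4 \le -3.674) = 0.02131$; protocol summaries often quote this as
$\approx 0.021$–$0.0214$).

# Synthetic data: what is emulated, and what is not

The generators produce desk-scale data with planted, recorded truth. They
emulate the *statistical structure* of the real inputs — not real genomes,
sequences, or spectra.

* `simulate_genome()` — default 4 chromosomes of 2.5 Mb (a Drosophila-like
  chromosome count at desk scale) with 5% of each chromosome covered by
  disjoint exclusion blocks, one per equal-width slot so coverage is exact.
* `simulate_peaks()` — log-normal peak lengths (median 500 bp, `sdlog` 0.5,
  the right-skewed shape of real peak-width distributions), placed uniformly
  in eligible space. With planting probability $\theta$, an annotation peak
  is instead anchored to a random query peak with at least half its length
  inside it (planted lengths are truncated at twice the host's width so the
  guarantee is always satisfiable). Crucially, $\theta = 0$ data follow
  *exactly* the placement law of the shuffling null, so one-sided empirical
  p-values are exchangeable-uniform — the basis of the type-I calibration
  tests.
* `simulate_probe_map()` — deterministic regular tiling (25 bp probes every
  50 bp by default) with optional gap regions; a stand-in for array designs.
* `simulate_tmt()` — log-normal protein baselines (`meanlog = log(1e6)`,
  `sdlog = 1.5`, spanning the dynamic range of real TMT data), multiplied by
  log-normal channel scale factors (`sdlog = 0.3`) to exercise the
  normalization steps, and mean-corrected log-normal measurement noise with
  a target coefficient of variation (default 0.25). Planted interactors get
  an 8-fold bait/control change; the bait protein itself gets 4 times that.
  The bait's measurement CV defaults to `cv / 10`: the immunoprecipitated
  bait is quantified from many high-intensity peptides, so its relative
  error is far below that of background proteins. This is also what makes
  the bait reliably top-ranked by p — with equal noise, 4-degree-of-freedom
  variance estimates are unstable enough that a lucky low-variance
  interactor would outrank the bait in roughly 1–3% of datasets.

Not emulated: sequence composition, read-level signal, peak calling,
mappability structure, peptide-level missingness patterns, and
between-protein abundance correlation. Channel scale factors are recorded in
the generator's truth because total normalization deterministically
compresses planted fold changes by the planted mass fraction — a property of
the method, not a defect; generator-contract tests divide the recorded
factors out before scoring recovery.

# Worked example

```{r example}
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
```

```{r ipms-example}
sim <- simulate_tmt(n_proteins = 300, n_true_interactors = 5, seed = 7)
ipms_test(sim$matrix)
```

# Problem sizes

The package's own validation runs at desk scale: genomes of $\sim 10$ Mb,
peak sets of 150–2000 intervals, 100–1000 permutations, and TMT matrices of
100–1500 proteins in 3 + 3 channels. At these sizes a 1000-permutation
enrichment test of a 2000-peak annotation completes in seconds on one CPU;
the full calibration suites (hundreds of replicate datasets) complete in
minutes.
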