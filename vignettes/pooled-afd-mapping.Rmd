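---
title: "Mapping quantitative trait loci from pooled sequencing of contrasting sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping quantitative trait loci from pooled sequencing of contrasting sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

`poolscan` maps quantitative trait loci by comparing allele frequencies
between pooled DNA samples of phenotypically extreme variety sets — an
extreme-phenotype variant of bulked segregant analysis for inbred crop
panels. The design assumptions, inherited from the material it targets
(elite selfing cereals genotyped on a fixed SNP array), are:

* every line is fully inbred, so a pool of $n$ lines can only take
  reference allele frequencies that are multiples of $1/n$, and one allele
  call per line is the right counting unit for contingency tables;
* pools are equimolar, so read counts at a variant sample the pool's
  allele frequency binomially given the read total;
* trait values are precomputed variety means (e.g. BLUPs from historical
  trials); the package consumes them and never fits the trait model.

The scan statistic is the **allele frequency difference**

$$\mathrm{AFD} = \widehat{p}_{\mathrm{high}} - \widehat{p}_{\mathrm{low}}
  \in [-1, 1],$$

where $\widehat{p}$ is the reference-allele read fraction in a pool. No
null distribution for the AFD is available without knowing the allele
frequencies of the source population, so the scan thresholds $|\mathrm{AFD}|$
and translates the threshold into a familiar scale instead:
`threshold_significance(0.75, 12)` builds the most favourable implied
line-count table — one pool fixed for the reference allele, the other at
frequency $1 - 0.75$, i.e. $[[12, 0], [3, 9]]$ — and reports $-\log_{10} p$
of the Pearson $\chi^2$ (1 df, no continuity correction), about 3.8. This
is the best case (source frequencies equal, estimates perfect); the
reported level is an upper bound on the evidence an AFD of 0.75 carries.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `set_size` | 12 | lines | balance between phenotypic extremity and the frequency resolution ($1/12$) of a pool |
| `min_distance` | 20 | Euclidean distance on 0/1 allele codes | $20 = \sqrt{400}$: admitted lines differ at $\ge 400$ markers, preventing near-duplicates; meaningful only at array scale (thousands of markers) |
| `min_qual` | 50 | phred | variant-call confidence floor; kept iff qual $\ge 50$ ("less than 50" excluded) |
| `fixed_raf` | 0.01 | frequency | below this in **both** pools the variant is a fixed difference against the reference genome, not a polymorphism between pools |
| `min_reads` | 100 | reads/pool | caps binomial sampling error of $\widehat{p}$ at roughly $0.05$ ($\sqrt{0.25/100}$) |
| `threshold` | 0.75 | AFD | strict inequality; implies $-\log_{10} p \approx 3.8$ at `set_size` 12 |
| `gap_other` | 10 Mbp | bp | QTL independence gap outside centromeres (about 10 cM in a cereal genome) |
| `gap_centromeric` | 400 Mbp | bp | same genetic distance in recombination-poor pericentromeric regions |

## Design choices where the procedure was open

**Fixed-allele rule.** A variant is dropped as "fixed" when its reference
allele frequency is below `fixed_raf` in *both* pools. A variant near zero
in only one pool is maximally informative about the contrast, so dropping
it (the literal "either pool" reading) would discard exactly the signal the
scan looks for; the stricter reading remains available via
`fixed_rule = "either"`.

**Rule order and attribution.** The cascade applies quality, then
fixed-allele, then depth, attributing each exclusion to the first failing
rule. Each rule is a pure per-record predicate, so the *kept set* is
order-independent (tested); only the bookkeeping depends on the order.

**Clustering.** "Independent if separated by at least the gap with no
other associated marker between" is operationalised as single-linkage
chaining: consecutive passing markers join one QTL while their separation
is below the applicable gap. The centromeric gap applies when the span
between the two markers intersects the chromosome's centromere interval
(`centromere_rule = "span"`); a flank-based alternative is provided. The
cluster threshold is on $|\mathrm{AFD}|$, so clusters may mix signs
(`sign_mode = "strict"` splits on sign flips). Peaks tie-break to the
smallest position, making calls deterministic; calls are invariant to
input row order because a canonical (chromosome, position) sort is applied
first.

**Distance with missing genotypes.** Distances are Euclidean on 0/1
allele codes with pairwise-complete markers, rescaled by
$\sqrt{m / m_\mathrm{complete}}$ — the convention of `stats::dist()`. A
pair with no shared complete marker has no defined distance and is an
error, not a silent `NA`.

**Structure-check envelope.** With 12 lines per set the per-marker 2×2
tables are small: the Pearson p-value is discrete and conservative, and
the textbook uniform order statistics with a $\mathrm{Beta}(i, m-i+1)$
pointwise band systematically reject even unstructured selections (only
~30% of sorted p-values fall inside that band in null simulations). The
default therefore compares observed quantiles against the *permutation*
null of each marker's table — set labels exchangeable, margins fixed, so
the high-set reference count is hypergeometric — with a Monte-Carlo
pointwise 95% band (`n_null` = 200 replicates). The uniform construction
is retained behind `null = "uniform"` for large-sample use. Markers
monomorphic within the selected lines are flagged and given $p = 1$.

**Contingency-table conventions.** All 2×2 tests are plain Pearson, 1 df.
No Yates correction: the correction is a small-sample device that breaks
the exact $\chi^2 \to -\log_{10} p$ correspondence this pipeline relies on
for reporting ($\chi^2 = z^2$ identity, tested on a $z$ grid); it is
available behind `correct = TRUE`. Counts are lines, not chromosomes:
in fully homozygous material counting $2n$ alleles would double every cell
and inflate every statistic by 2 without adding information. A zero
marginal makes the statistic 0 ($p = 1$) with a degenerate flag rather
than `NaN`.

**Association t-test.** One-sided pooled-variance t
(df $= n_1 + n_2 - 2$), alternative mean(high allele) > mean(low allele):
the validation question is directional by construction, because the high
allele is *defined* by the pool contrast. `alternative = "two.sided"` is
available.

**Estimated-vs-true agreement.** `identity_r2` takes residuals about the
$y = x$ line, not a fitted slope — bias and attenuation both reduce it —
while the denominator is the spread of the estimates about their own mean.
It can be negative for badly biased estimates; that is a feature, not a
bug. The companion `abs_correlation` is the Pearson correlation of
absolute values, appropriate when the inputs are signed AFDs.

**Collocation.** A gene is collocated with a QTL when its span intersects
the QTL interval extended by the applicable independence gap on each side:
a gene closer than the gap could not have founded an independent QTL. The
gene-to-peak alternative was rejected because the peak is a single read-out
of a noisy maximum; the interval is the stable object.

## The synthetic-data generator

`simulate_panel()` + `simulate_pooled_reads()` emulate the study
conditions the pipeline assumes: a panel of a few hundred inbred
varieties; genotypes drawn independently per marker from founder reference
allele frequencies (default $U(0.05, 0.95)$); a strictly additive trait
$y_i = \sum_k a_k [g_{ik} = \mathrm{ref\text{-}hom}] + N(0, \sigma^2)$;
seven barley-sized chromosomes with broad central centromeres; pooled read
totals Poisson with mean 275 per pool per variant (the exome-capture
coverage regime the 100-read filter was designed for; negative binomial
available for overdispersion), and reference reads binomial with success
probability $p(1-e) + (1-p)e$ under per-read base error $e$. Call quality
is a synthetic constant (60) unless a function is supplied to inject
low-quality records — quality filtering is a pass-through rule, not a
calling model.

Deliberately **not** emulated: linkage disequilibrium (markers are
independent, so a planted QTL is recovered through its causal marker
rather than a haplotype block), capture-efficiency autocorrelation along
the genome, uneven DNA contribution of pool members, and
genotype-by-environment structure in the trait. Passing recovery tests
therefore demonstrate the statistical machinery under the model's own
assumptions, not robustness to these real-data features.

## Problem sizes used in the checks

The test suite exercises: planted-QTL recovery on 20 replicates of a
400-variety panel (1,000 markers, two QTL of effect 15 at founder
frequencies 0.3–0.7, noise SD 10 — effects 1.5× the environmental SD,
read coverage 150×), requiring ≥ 90% of replicates to call a QTL
containing each causal marker with ≤ 0.5 false-positive QTL per replicate;
estimated-vs-true frequency agreement at 100× coverage and base error
0.001 (identity-line $R^2 > 0.9$); null calibration on 5 seeds × 3,000
markers with no planted QTL (fraction of markers beyond $|\mathrm{AFD}| >
0.75$ below $10^{-3}$); and exhaustive-partition oracles for the
clustering rule on instances of up to a dozen passing markers. The
"effect ≥ 1.5 trait SD" recovery condition is read against the
environmental (noise) SD: two loci each carrying 1.5× the *total*
phenotypic SD is arithmetically impossible, since their combined variance
share would exceed one.

## Limitations

* AFD significance is an implied best-case level, not a per-marker test;
  single-marker QTL (like the scan's occasional lone outliers) deserve the
  same skepticism the validation stage applies to them.
* Markers selected *because* their estimated $|\mathrm{AFD}|$ crossed the
  threshold overstate the true differentiation on average (winner's curse);
  the test suite asserts this regression-to-the-mean effect on simulated
  pools, and it is why independent validation of called QTL matters.
* The filtering cascade takes the variant caller's output at face value;
  mapping artefacts that survive upstream filters are out of scope.
* Genetic-map (cM) coordinates are not modelled; the centromere-aware gap
  is a physical-distance proxy.
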