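---
title: "Methods: rifampicin-chase mRNA half-life estimation and rRNA fragmentation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rifampicin-chase mRNA half-life estimation and rRNA fragmentation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifadecay)
```

## The decay model

After rifampicin blocks transcription initiation, the level of a transcript
with half-life $h$ decays as $A(t) = A(0)\,2^{-t/h}$. A two-color array
comparing the sample taken at $t$ minutes against the untreated sample
therefore measures, per gene, a ratio whose expectation is $2^{-t/h}$, and
the replicate-averaged log2 ratio is linear in time:
$y(t) = \log_2\!\big(A(t)/A(0)\big) = -t/h$. `fit_half_lives()` fits
$y(t) = a + m t$ by ordinary least squares with a free intercept and
converts $t_{1/2} = -1/m$ for $m < 0$.

Assumptions worth keeping in mind:

* **First-order decay.** A single exponential per transcript; no delay
  between drug addition and transcription stop, no biphasic decay, no
  re-synthesis. Genes whose kinetics flatten at late times are handled by
  the fallback window (below), not by a richer model.
* **Free intercept.** No synthetic $(0, 0)$ anchor is added at $t_0$: the
  fit uses only the measured ratio points. An intercept off zero absorbs
  residual normalization offsets rather than biasing the slope.
* **Log2 throughout.** Replicate averaging and fitting are done on log2
  ratios (equivalently, a geometric mean of ratios). This makes the result
  symmetric under dye swap; the half-life itself is base-invariant as long
  as slope and conversion use the same base.

## Quality filtering and spike-in normalization

A spot enters the analysis when (i) its flag is $\ge 0$ and (ii) the
signal-to-noise ratio, foreground median over background median, is $\ge 3$
in the Cy5 **or** the Cy3 channel. The OR is deliberate: a gene decayed to
the detection floor at a late timepoint still has a strong $t_0$ channel,
and discarding such spots would censor exactly the fast-decaying genes of
interest. A zero background with positive foreground counts as passing that
channel. The filter is monotone: raising a foreground median can never turn
a passing spot into a failing one.

Because rRNA stability cannot be assumed (the motivating organism fragments
its 23S rRNA), normalization is anchored on exogenous spike-in RNAs present
in both labelling mixes at a 1:1 ratio, printed on 32 spots per control per
array. For each hybridization the factor

$$f = 2^{-\operatorname{mean}(\log_2 r_i)}$$

over the quality-passing control spots recentres those controls at mean
log2 ratio exactly 0 (asserted to $10^{-9}$ in the tests). Every spot's
ratio of medians is multiplied by $f$; arrays whose dyes are swapped
(untreated sample in Cy5) are sign-flipped in log space so that every value
is $\log_2(\text{level}_{t_x}/\text{level}_{t_0})$. Replicates are then
averaged per gene per timepoint; a single passing replicate suffices (the
count is reported so stricter reanalyses can filter on it). Spots with a
missing or non-positive background-corrected ratio are dropped
individually, not per gene.

## The R² gate and the three-point fallback

A fit is accepted only when $R^2 > 0.7$ (strictly) and the slope is
negative. An undefined $R^2$ (constant responses) never passes. Genes
failing on the full window $\{2, 5, 10, 15\}$ min are refitted on
$\{2, 5, 10\}$ under the same gate: transcripts that reach the array's
detection floor before 15 min show a flattened last point that destroys an
otherwise clean linear decay. Genes accepted this way are labelled
`ok_3pt`; the fraction of such genes grows as noise is applied to the last
timepoint specifically, which is the intended behaviour of the fallback.

Genes with no acceptable fit are `censored` when the final slope is
non-negative — reported as no detectable decay rather than an infinite
half-life — and `unresolved` otherwise; both are excluded from means,
medians and downstream group statistics. Summaries (mean, median, histogram
in 1-minute bins $[k, k+1)$) cover accepted estimates only.

### Operon averages and rounding

`operon_half_lives()` takes the arithmetic mean of the accepted member
half-lives, at full precision, and adds a one-decimal reporting column
(standard rounding). When operon averages are recomputed from member values
that were themselves already rounded to one decimal, the recomputed average
can differ from an average taken over unrounded values by up to half a unit
in the last place — a data-precision artifact of the inputs, not of the
averaging. Both the full-precision and the rounded value are therefore
returned.

## Group statistics

The one-way ANOVA across functional categories is computed directly from
the between- and within-group sums of squares,
$F = (SSB/df_B)/(SSW/df_W)$, with the p-value from the F distribution; the
test suite cross-checks it against `stats::aov` and verifies a nominal
type-I error rate (5% ± 1% over 2000 null simulations). The post-hoc test
compares each category with at least two estimated genes against the global
mean half-life treated as a fixed constant — a one-sample two-sided t-test —
because the comparison of interest is "does this category differ from the
overall average", not a pairwise contrast. P-values are Bonferroni-adjusted
by the number of categories actually tested, capped at 1. A two-sample
variant (global mean as a random quantity) is out of scope.

Correlations of half-life with abundance use Pearson's r with the
$t$-transform p-value on $n-2$ degrees of freedom. Abundance (FPKM) is
log10-transformed by default, restricted to genes with FPKM > 0, matching
the logarithmic axis on which such relationships are usually judged; a raw
scale is available via `transform = "raw"`. Whether a published correlation
was computed on the raw or the log scale is often unstated, so the
transform is an explicit, documented choice here.

FPKM itself is $\text{count} \times 10^9 / (\text{length} \times
\text{total})$, where counts are fragments (read pairs; single-end reads
count as one) from uniquely placed alignments with at most 1% mismatches,
and the library size is the sum of counted fragments over annotated genes —
the alternative (all mapped reads in the denominator) rescales every FPKM
by a common factor and leaves all correlations unchanged.

## rRNA fragmentation calling

`map_reads()` places each read, and its reverse complement, at every offset
of every reference (an exhaustive scan via `Biostrings::matchPattern`), and
accepts placements that cover the read's complete length with at most
$\lfloor 0.01 \times \text{read length} \rfloor$ mismatches and no indels —
i.e. ≥ 99% identity. Among the acceptable placements with the fewest
mismatches, one is chosen uniformly at random with the seeded generator.
This random single assignment is one defensible policy for reads that map
equally well to near-identical rRNA gene copies (retaining or discarding
multi-mappers are the alternatives); it keeps per-copy coverage unbiased in
expectation and is reproducible under a fixed seed.

`call_low_coverage_regions()` computes the locus mean coverage $\bar C$
over the **entire** track — low positions included, the literal reading of
"average gene coverage"; an iterated mean that excludes called regions is a
documented option left off by default — and returns the maximal runs of
positions with depth strictly below $0.05\,\bar C$, 1-based inclusive. A
position at exactly 5% of the mean is never called. Runs are not merged
across short high-coverage interruptions. An all-zero track yields a single
whole-locus region flagged degenerate. `compare_regions()` groups regions
across gene copies as equivalent when both start and end differ by at most
2 nt (transitively), labelling groups present in every copy `shared` and
all others `unique`.

One coordinate-arithmetic caveat: with 1-based inclusive coordinates a
region $1717$–$1770$ spans 54 nt. Published region tables occasionally
print 55 nt for such a span (consistent with $1716$–$1770$ on a sister gene
copy); this package reports inclusive lengths, $end - start + 1$,
everywhere and leaves the discrepancy to the coordinates, not the
arithmetic.

## What the synthetic data do and do not emulate

`sim_decay_truth()` draws half-lives log-normally with median 5.7 min and
log-sd 0.4 — centred on the global scale typical of fast-growing bacteria,
with most genes between roughly 2 and 16 min — and log-normal baseline
abundances. `sim_hybridizations()` emulates the full experimental design:
timepoints {2, 5, 10, 15} min, three biological replicates with alternating
dye orientation (dye swap), two 1:1 spike-in controls with 32 spots each,
multiplicative log-normal spot noise on the log2 ratio, a global per-array
scale factor (dye/labelling imbalance that the spike-in factor must remove),
additive backgrounds around 50 intensity units (making the S/N ≥ 3 filter
meaningful), and bad-spot flags (−50) at a configurable rate. Channel
foregrounds are constructed as `scale × abundance + background`, so the
background-corrected ratio of medians equals the simulated ratio exactly and
the zero-noise pipeline is exact to floating point.

Defaults not fixed by the experimental design are engineering choices made
once: spot noise sd 0.2 log2 units and a 2% bad-spot rate (ordinary
two-color array quality), per-array scale sd 0.25 log2 units (typical
labelling imbalance). The generator does **not** simulate scanner
saturation, spatial or print-tip artifacts, probe-sequence effects,
cross-hybridization, or intensity-dependent (curved) dye bias — so passing
recovery tests demonstrates the estimator's correctness under the stated
noise model, not robustness to array pathologies that would call for loess
or spatial normalization (deliberately out of scope).

`sim_rrna_reads()` samples fixed-length reads uniformly from start positions
whose full span avoids every planted fragmentation interval, so the planted
intervals have exactly zero true coverage; substitution errors are opt-in
(default 0, keeping mapping acceptance exact). Two edge effects are
inherent: coverage ramps linearly over the first and last read-length
positions of the locus, and positions adjacent to a planted gap are reached
by fewer valid read placements — so regions called from read-derived
coverage may extend beyond a planted gap by at most read_length − 1
positions, while calls on the exact truth track recover the gaps precisely.
FASTQ output uses a constant Phred quality; quality-aware mapping is not
modelled.

## Problem sizes and numerical choices in the test suite

The suite verifies, among others: exact (1e−9 relative) end-to-end recovery
of half-lives {2, 5, 10, 25} min from noiseless simulations; median
relative error below 5% for 300 genes at spot noise 0.1 log2 units with
three replicates; OLS agreement with `lm()` to 1e−12 on random small point
sets; the ANOVA type-I error over 2000 null simulations of five groups of
ten; and exact recovery of planted gaps from a 1200-nt locus at ~50×
simulated coverage (600 reads of 100 nt). These sizes keep the full suite
in the tens of seconds while leaving each check statistically meaningful;
all simulations are seeded and deterministic.

## Known limitations

* Single-exponential decay only; no delay terms, no Bayesian or nonlinear
  fitting, no per-probe modelling.
* Normalization offers no background-subtraction variants, loess, or
  within-array spatial correction.
* The read mapper is exhaustive and indel-free: adequate for rRNA-length
  references and the ≥ 99% identity rule, but not a general-purpose aligner
  and not indel-aware.
* Multiple-testing correction is Bonferroni only; no Tukey HSD or mixed
  models for the category analysis.
* Censored genes (no detectable decay) are excluded from summaries, which
  biases global means slightly downward if truly stable transcripts exist.
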