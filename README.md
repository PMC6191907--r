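# rifadecay

Genome-wide estimation of bacterial mRNA half-lives from rifampicin-chase
two-color microarray experiments, plus coverage-based detection of rRNA
fragmentation regions.

## The problem

In a rifampicin chase, transcription initiation is blocked and existing
mRNAs decay without replacement. Two-color arrays hybridized with cDNA from
cells sampled t minutes after the chase (t = 2, 5, 10, 15) against the
untreated sample (t0) measure, spot by spot, the relative mRNA level
2^(−t/h) of each gene with half-life h. Because rRNA cannot be assumed
stable (in *Gluconobacter oxydans* the full-length 23S rRNA is itself
fragmented), ratios are anchored instead on exogenous 1:1 spike-in control
RNAs: for every hybridization a factor f = 2^(−mean(log2 r)) over the
quality-passing control spots recentres the controls at mean log2 ratio 0.

For each gene the replicate-averaged log2 ratio y(t) is fitted by ordinary
least squares,

    y(t) = a + m·t,    t1/2 = −1/m   (m < 0),

and the estimate is accepted only when R² > 0.7. Genes failing the gate on
the full four-timepoint window are refitted on the first three sampling
times (t2, t5, t10) under the same gate — short-lived transcripts often hit
the array's detection floor by t15, which wrecks the linear fit without
invalidating the earlier points. Accepted half-lives feed operon averages,
functional-category statistics (one-way ANOVA from sum-of-squares
definitions, post-hoc one-sample t-tests against the global mean with
Bonferroni correction) and correlations with abundance (FPKM) and ORF
length.

Independently, ribosome-associated rRNA reads mapped full-length at ≥ 99%
identity give per-base coverage tracks; maximal runs of positions with depth
strictly below 5% of the locus mean coverage are called as fragmentation
regions and compared across rRNA gene copies (equivalent when start and end
each differ by ≤ 2 nt).

Every input the pipeline consumes — GenePix-style spot tables with flags,
channel medians and ratio of medians; spike-in controls (32 spots each);
reads with planted zero-coverage gaps; fragment-count tables — can be
simulated with known ground truth, so the whole pipeline is testable without
any external data.

## Worked example

```r
library(rifadecay)

truth <- sim_decay_truth(n_genes = 500, seed = 7)        # known half-lives
hybs  <- sim_hybridizations(truth, noise_sd_log2 = 0.1, seed = 8)
profiles <- build_decay_profiles(hybs)                   # spike-in normalized
fit <- fit_half_lives(profiles, gate = 0.7)
fit
#> mRNA half-life fit (R-squared gate > 0.7 )
#>   genes: 500
#>   full-window fits: 500, fallback 3-point fits: 0
#>   censored: 0, unresolved: 0
#>   half-life mean 6.3 min, median 5.8 min
summary(fit)
#> Accepted half-lives: 500 genes (gate R-squared > 0.7)
#>   mean 6.3 min, median 5.8 min, range 1.7-16.9 min
head(fit$estimates, 3)
#>     gene_id       slope   intercept r_squared n_points half_life status
#> 1 GSYN00001 -0.06131455 -0.05507549 0.9940064        4 16.309343 ok_4pt
#> 2 GSYN00002 -0.28804318  0.01315281 0.9999708        4  3.471702 ok_4pt
#> 3 GSYN00003 -0.23383167  0.04982082 0.9999993        4  4.276581 ok_4pt
```

The simulation draws true half-lives log-normally with median 5.7 min, so a
summary mean near 6 min and median near 5.8 min means the pipeline recovers
the planted decay rates through normalization, dye-swap handling, replicate
averaging and the gated fit; `slope` is per minute on the log2 scale and
`half_life = −1/slope`. With the noise terms switched off the recovery is
exact to 1e−9. Downstream, `operon_half_lives()` averages accepted members
per operon, `anova_halflife()` / `category_posthoc()` test functional
categories, `fpkm_table()` and `cor_half_life()` relate half-life to
abundance, and `gap_plan()` → `sim_rrna_reads()` → `map_reads()` →
`call_low_coverage_regions()` → `compare_regions()` run the rRNA
fragmentation analysis.

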