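# tftarget

Predict a transcription factor's direct gene targets from ChIP-seq
binding peaks and perturbation expression data, and infer whether two
factors act **cooperatively** or **competitively** on their shared
targets.

## The problem

A ChIP-seq experiment yields hundreds to thousands of binding peaks for
a factor, but binding alone does not show function. Perturbing the
factor (knockdown or overexpression) and profiling expression shows
function, but not which responses are direct. `tftarget` integrates the
two: genes that are both *bound nearby* and *strongly responsive* rank
as likely direct targets. When two factors are assayed in comparable
experiments, the signs of their expression effects on shared targets
further reveal whether they push those genes in the same direction
(cooperation) or in opposite directions (competition).

## The method

For each peak *p* assigned to a region of interest *g* (any peak whose
center lies within a window *w*, default 100 kb, of the region's
reference point), the peak score is an exponential decay in the
normalized distance Δ = |center − reference| / w:

    S_p = exp(-(0.5 + 4 Δ))

The **regulatory potential** of a region is the sum over its assigned
peaks, S_g = Σ S_p. Regions are ranked by potential (rank R_gb,
descending) and by the magnitude of the signed perturbation statistic
(fold-change or t-statistic; rank R_ge, descending), giving the **rank
product**

    RP_g = R_gb × R_ge / n²  ∈ [1/n², 1]

where n is the number of ranked regions; small RP_g marks likely direct
targets. For two factors *x* and *y*, the **regulatory interaction**

    RI_g = x_ge × y_ge

replaces the single statistic: its rank enters RP_g and its sign labels
each shared target Cooperative (RI > 0) or Competitive (RI < 0). The
per-group ECDFs of the target ranks are then compared with one-sided
two-sample Kolmogorov–Smirnov tests (`stats::ks.test`): the dominant
interaction mode is the group whose ECDF lies significantly above the
other.

## Worked example

The built-in simulator plants a cooperative signal: 5,000 transcripts on
a chromosome-1-sized sequence, 10,000 random peaks near their TSSs, two
standard-normal statistic columns, and 1,000 peak-bearing transcripts
whose second statistic is replaced by 3× the first (so RI = 3x² > 0 for
all of them).

```r
library(tftarget)
sim <- simulate_dataset(sim_config(seed = 42))
dt  <- direct_targets(sim$peaks, sim$regions, sim$stats, mode = "two_factor")
#> 61054 peak-region pairs from 10000 peaks and 5000 regions
#> ranked 4998 regions
head(dt[, c("region_id", "n_peaks", "potential", "stat_x", "stat_y",
            "ri", "rank_product", "group")], 5)
#>   region_id n_peaks potential stat_x stat_y     ri rank_product       group
#> 1      g317      21      4.15 -2.549 -7.646 19.488     5.88e-05 Cooperative
#> 2     g3273      28      6.99  0.758  0.956  0.725     7.12e-05 Cooperative
#> 3     g2199      14      2.50  3.274  9.821 32.149     8.62e-05 Cooperative
#> 4     g4813      17      1.80 -3.311 -9.933 32.885     8.95e-05 Cooperative
#> 5     g3488      19      3.88 -2.592 -7.776 20.154     9.58e-05 Cooperative
```

The top-ranked targets are bound (large potential, rank-product near
1/n²) and carry strong same-sign effects in both factors. Testing
whether the Cooperative group's ECDF of rank products lies above the
Competitive group's:

```r
test_predictions(dt$rank_product, dt$group,
                 compare = c("Cooperative", "Competitive"),
                 alternative = "greater")
#>       group_a     group_b alternative  n_a  n_b ks_statistic  p_value
#> 1 Cooperative Competitive     greater 3007 1991        0.103 7.89e-12
```

D ≈ 0.10 with p ≈ 8e−12: the planted cooperative mode dominates, as it
should. `plot_predictions(dt$rank_product, dt$group)` draws the grouped
ECDF curves. For real data, read peaks with `read_bed()`, regions
(genes/promoters, BED6 with unique names) with `read_bed()`, statistics
with `read_expression()`, and use `direct_targets()` (one factor) or
`combined_targets()` (two factors, shared-target analysis).

## Command line

The same workflows run from a shell via `exec/tftarget`:

```sh
tftarget simulate --n-regions 5000 --n-peaks 10000 --n-biased 1000 \
         --bias-factor 3 --seed 42 --out-dir sim/
tftarget combined --peaks-a sim/peaks_a.bed --peaks-b sim/peaks_b.bed \
         --regions sim/regions.bed --expression sim/expression.tsv \
         --out-dir out/
```

Every run writes a `config.json` echo next to its outputs; exit codes
are 0 (success), 2 (parse error), 3 (contract violation), 4 (empty
result).

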