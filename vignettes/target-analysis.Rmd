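---
title: "Ranking transcription factor targets and inferring combined function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking transcription factor targets and inferring combined function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tftarget)
```

## The model

`tftarget` scores the evidence that a gene (or any region of interest)
is a direct target of a DNA-binding factor by combining two independent
measurements: where the factor binds (ChIP-seq peaks) and what happens
to expression when the factor is perturbed (signed fold-changes or
t-statistics from knockdown/overexpression experiments).

**Binding side.** A peak is assigned to a region when its center lies
within a window $w$ of the region's reference point; each assignment is
scored

$$S_p = e^{-(0.5 + 4\Delta)}, \qquad
  \Delta = \frac{|\text{center} - \text{reference}|}{w} \in [0, 1],$$

and the region's regulatory potential is the sum $S_g = \sum_i S_{p_i}$
over its assigned peaks. The kernel is a monotone exponential decay
chosen to mimic the empirical fall-off of regulatory influence with
distance from the transcription start site: it equals $e^{-0.5} \approx
0.607$ for a peak sitting on the reference point and $e^{-4.5} \approx
0.011$ at the window edge, a roughly 55-fold dynamic range. Potentials
are additive: proximal and distal peaks all contribute, so a region with
many mediocre peaks can outrank one with a single good peak.

**Expression side and the rank product.** Let $n$ be the number of
regions that have at least one peak *and* an expression record. Within
those, the binding rank $R_{gb}$ orders potentials descending and the
expression rank $R_{ge}$ orders the *magnitude* of the signed statistic
descending (strongest change first; the sign is kept aside for
grouping). The rank product

$$RP_g = \frac{R_{gb} \times R_{ge}}{n^2} \in [1/n^2,\, 1]$$

is small exactly when a region is near the top of both orderings; output
tables are sorted by it ascending, most credible target first.

**Two factors.** For factors $x$ and $y$ assayed in comparable
perturbation experiments, the regulatory interaction of a shared target
is the product of the two signed statistics, $RI_g = x_{ge} \cdot
y_{ge}$, under an assumed linear interaction model. Its magnitude enters
the rank product in place of $|{\rm stat}|$; its sign classifies the
target: positive (same-direction effects) is labelled Cooperative,
negative Competitive. `combined_targets()` restricts the analysis to
regions bound by both factors (co-occupancy of the region by default; a
stricter peak-interval-overlap mode via `shared = "overlap"`), and sums
both factors' peak scores into the shared potential.

**Deciding the dominant mode.** Targets are partitioned by RI sign (or
statistic quantiles), and the per-group ECDFs of the final importance
ranks are compared with one-sided two-sample Kolmogorov–Smirnov tests.
If the Cooperative group's ECDF lies significantly above the
Competitive group's, cooperative targets concentrate at better
(smaller) rank products, and cooperation is the dominant mode.

### Which quantity's ECDF is compared

The grouped ECDF/KS machinery accepts any per-target signal, and two
natural choices exist: the rank of the regulatory potential alone, or
the final rank product. We default to the **rank product**. The
reasoning: group labels are a function of the expression statistics
only, so when binding and expression are independent under the null,
potential ranks are identically distributed across groups regardless of
any planted or real expression signal — a potential-only comparison can
detect a group difference only insofar as group membership correlates
with *binding*. The rank product additionally carries the interaction
magnitude, so targets with strong same-direction (or opposing) effects
pull their group's curve upward, which is precisely the effect of
interest. Users who want the potential-only comparison can pass
`rank(-dt$potential)` to `test_predictions()` directly.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window` | 100,000 | bp | association radius and the normalizer of $\Delta$; the conventional regulatory-potential scale for distal elements. Smaller windows (5–10 kb) restrict the analysis to promoters. |
| `ref_point` | `"center"` | – | region reference: interval midpoint, or `"start"` = strand-aware 5′ end (the TSS for gene/transcript regions). Use `"start"` with whole-gene annotations; with symmetric promoter windows the two coincide. |
| `grouping` | quantile (1 factor), sign (2 factors) | – | sign grouping is natural for RI (the sign *is* the direction); tertile quantiles give a single factor a None band so weak responders do not dilute Up/Down. |
| `mode`/`shared` | – | – | `two_factor` ranks by RI; `shared = "region"` calls a target shared when each factor has ≥ 1 peak in its window. |

All coordinates are handled internally in BED 0-based half-open
convention; centers are the floor of the interval midpoint, and the
association window is inclusive at both edges ($\Delta = 1$ is retained
— the kernel is finite and positive there, so exclusion would be an
arbitrary extra rule).

## The simulator

`simulate_dataset()` generates the validation conditions used
throughout the tests: `n_regions = 5000` transcripts with distinct TSSs
drawn uniformly from a 195,471,971 bp chromosome (the size of mouse
chromosome 1, so no genome download is needed), each expanded to a
window-wide promoter centered on its TSS; `n_peaks = 10000` 200-bp
peaks whose centers sit at a uniformly chosen TSS plus a uniform offset
in $[-w, w]$; and two i.i.d. standard-normal statistic columns. The
planted signal replaces `stat_y` with `bias_factor * stat_x` for
`n_biased = 1000` transcripts sampled among those with at least one
nearby peak: `bias_factor = +3` makes every biased transcript
cooperative ($RI = 3x^2 > 0$) with inflated magnitude, $-3$ makes the
same transcripts competitive. The transcript count, bias size and bias
factors are the standard conditions for this design; peak count, peak
width and the normal statistic distribution are the package's own
defaults, chosen to give each transcript a handful of peaks (the mean
is about 12 assignments) and realistic overlap between biased and
unbiased $|RI|$ distributions.

Reproducibility: each stage seeds its own substream derived from the
config seed (`seed`, `seed + 1`, `seed + 2` for regions, peaks,
statistics), so stages are individually deterministic and composable,
and the cooperative and competitive runs of one seed share regions,
peaks, statistics and the biased set exactly — differing only in the
sign flip. This yields the exact mirror property checked in the tests:
rank products coincide and the biased transcripts swap group labels.

What the simulator does *not* emulate: peak-calling noise and width
variation, clustered TSSs and gene-density structure, correlated
biological replicates, heavy-tailed fold-change distributions, and any
nonlinear or assisted-binding interaction. Passing the planted-signal
tests therefore shows that the pipeline propagates a linear
same/opposite-direction signal into the right group and detects it; it
does not certify performance on real ChIP data, where window choice and
annotation quality dominate.

## Numerical and design choices

- **Ranks** use midranks for ties (`rank(..., ties.method =
  "average")`), the convention of the rank-product literature;
  deterministic and permutation-invariant.
- **Rank direction**: rank 1 = strongest signal, so RP is small for good
  targets and bounded in $[1/n^2, 1]$; $n$ counts only the regions
  actually ranked (peaks + expression), keeping the bound tight.
- **Missing expression**: regions with peaks but no expression record
  are dropped with a reported count, never zero-filled — a fabricated 0
  statistic would silently take the worst rank.
- **Duplicate peaks** (identical coordinates) each contribute a score;
  peak names need not be unique, region ids must be (they key the
  expression join). Peaks without names receive synthetic
  `chrom:start-end:line` ids on ingest.
- **KS p-values** come from `stats::ks.test`: exact for small tie-free
  groups, asymptotic otherwise. Midranked data are tie-prone, so the
  ties caveat is surfaced as a message; the D statistic itself is exact
  either way.
- **Determinism**: output tables are sorted by rank product with
  C-locale (radix) id tie-breaks, and `write_table()` prints doubles
  with 17 significant digits so a write/read round-trip reproduces
  values bit-for-bit.
- **Degenerate inputs**: empty BED files parse to empty collections; an
  empty join (no region with both peaks and expression) is a classed
  error (CLI exit 4); all-identical values under quantile grouping are
  rejected rather than silently producing empty extreme groups.

The automated checks run the full 5000-transcript simulation (a few
seconds) plus 100 randomized brute-force comparisons for the interval
engine and 50 for the ranking engine; unit properties use scaled-down
configurations (300–800 transcripts) where the property does not depend
on size.

## Known limitations

- The interaction model is linear; synergistic, saturating or assisted
  binding modes are invisible to $RI$, and co-binding via
  protein–protein contact is indistinguishable from direct DNA binding.
- Peak strength (height/enrichment) is deliberately ignored: only
  distance enters $S_p$, so a weak distal peak and a strong one score
  identically.
- The KS comparison is between two groups at a time and no
  multiple-testing correction is applied across the directional tests;
  with three groups, compare the extremes.
- Real-data use requires the user's own region annotation (BED6 with
  unique names matching the expression table); the package ships no
  genome database.
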