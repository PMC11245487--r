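---
title: "Estimating Pol II elongation kinetics with the ROCC Proxy Rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Pol II elongation kinetics with the ROCC Proxy Rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxyrate)
library(dplyr)
```

## The problem

Immediate early genes (IEGs) are transcriptionally silent until a
stimulus — serum, growth factors, neuronal activity — switches them on
within minutes. As RNA polymerase II (Pol II) waves enter their gene
bodies, the speed of that wave (the elongation rate, bp/min) becomes a
quantity of direct regulatory interest: factors that change it reshape the
whole transcription cycle. Classical rate estimators are poorly suited to
IEGs. DRB-release assays need genes longer than ~25 kb, and wavefront
("leading edge") callers need the front to still be inside the gene at the
sampled timepoints; many IEGs are under 10 kb and are fully traversed
within 5 minutes.

The Rate of Change in Coverage (ROCC) sidesteps the gene-length
constraint. Instead of locating a front, it asks at every fixed-width bin
of a gene: how fast is nascent-transcription coverage rising over the
stimulation time course? Fast elongation fills distal bins earlier, so
per-bin coverage slopes — and their gene-level average, the **Proxy
Rate** — increase with the underlying elongation rate. The Proxy Rate is a
rate *surrogate* in signal/bp/min, deliberately not converted to bp/min.

## The estimator

For gene $g$, coverage $y_{b,t}$ is the mean per-bp normalized
nascent-transcription signal in bin $b$ (50 bp by default) at timepoint
$t$, extracted over the slope-estimation region from 500 bp downstream of
the TSS to 3000 bp past the pA site, in gene orientation. The per-bin ROCC
is the least-squares slope through the origin:

$$\hat s_b \;=\; \frac{\sum_t t\, y_{b,t}}{\sum_t t^2},$$

with the 0 minute sample placed at an effective time of 0.5 min. The
Proxy Rate is the mean absolute slope over the $B$ bins of the region:

$$\mathrm{PR}_g \;=\; \frac{1}{B}\sum_b \lvert \hat s_b \rvert.$$

Two modelling choices deserve comment:

* **Why fix the intercept at zero?** Before stimulation most IEG bins
  carry no signal. An unconstrained two-parameter line fitted to three
  timepoints lets tiny fluctuations at $t=0$ swing the slope wildly; the
  origin constraint keeps empty bins interpretable (slope exactly 0) and
  makes conditions comparable. The cost is that the $t=0$ sample has
  little influence, which is why the complementary **single-timepoint
  variant** exists: $\hat s_b = (y_{b,t}-y_{b,0})/t$ for $t$ = 5 and 10
  min separately, a two-point line on which the 0 minute sample exerts
  maximal influence. Agreement between variants (both are computed by
  `estimate_proxy_rate()`) is the practical check that the intercept
  constraint did not distort a comparison.
* **Why 0.5 min for the 0 minute sample?** The origin fit needs strictly
  positive abscissae; a small positive placement keeps the pre-stimulation
  measurement in the design without letting it dominate. It is a tunable
  (`t0_effective`), and in the limit `t0_effective -> 0` the two-timepoint
  global fit coincides with the single-timepoint slope — a property the
  test suite asserts.

"Mean of absolute slopes" versus "absolute value of the mean slope" is
ambiguous in prose; for induced genes all slopes are nonnegative and the
two coincide, but they differ on noisy bins. The package defaults to
`mean(abs(slope))` and exposes `abs_before_mean = FALSE` for the
alternative, so both readings are computable.

Per-gene kinetic heterogeneity (a short gene finished in one transcription
cycle versus a long gene still filling) is resolved by
`quartile_proxy_rate()`: the gene's `[TSS, pA)` span is split into four
near-equal quartiles (boundaries at `floor(k * length / 4)`, so a 10-kb
gene gives four exact 2.5-kb quartiles) and absolute single-timepoint
slopes are averaged per quartile, assigning each bin by its midpoint so
boundary bins are never double-counted. Quartiles default to the gene span
rather than the slope-estimation region because they describe *the gene's*
kinetics; the alternative is expressible through `region_start`.

## Regions, coordinates and conventions

All coordinates are 0-based half-open (BED convention), so BED inputs are
consumed bit-exactly. Regions are derived in gene-oriented offsets from
the TSS and mirrored about the TSS on the minus strand:

| region | gene-oriented span | default |
|---|---|---|
| promoter-proximal (PP) | `[-pp_up, pp_down)` | −100/+500 bp of TSS |
| gene body (GB) | `[pp_down, length)` | +500 bp to pA |
| 3′ end | `[length, length + ext)` | pA to +3000 bp |
| slope region | GB ∪ 3′ end | +500 to pA + 3000 |

Genes whose body would be empty (`length <= pp_down`) are excluded with a
warning, never silently. The offsets are parameters so that wider layouts
(e.g. 50-kb metagene flanks for background checks) are expressible.

Bin values are per-bp *means*, not sums: a truncated final bin is averaged
over its actual width, and densities of regions with different widths (PP
vs GB) stay comparable across genes. The package's binning is interval
arithmetic, cross-checked in the tests against a per-base brute-force
oracle on hundreds of random tracks.

## Normalization

`normalize_track()` implements RPKM and CPM on count tracks
(`RPKM = count / ((bin/1000) * (total/1e6))`), and `spike_in_factors()`
derives between-sample scaling from exogenous spike-in read counts as
`factor_i = min(counts) / counts_i` — the sample with the fewest spike-in
reads is the reference and applying the factors equalizes expected
spike-in signal. This min/count convention is the field's standard one;
because published factor tables are sometimes produced by external tools
with unstated conventions, factors can always be supplied directly instead
of derived. Replicates are merged (`merge_replicates()`) as the per-base
mean of equally-normalized tracks, with absent chromosomes contributing
zero under a warning.

## Gene classification

`assign_clusters()` reproduces fold-change-threshold IEG classes from a
differential-expression table: an expressed gene with log2 fold change at
least 1, 2, 3 or 4 (inclusive, up-regulation only) belongs to the 2-, 4-,
8- and 16-fold clusters *cumulatively* — a gene at log2FC 4.2 is a member
of all four, and reported cluster sizes nest. Expressed genes within a
1.4-fold band in either direction are non-DE background; remaining
expressed genes (including down-regulated ones) are `other`.
`expression_filter()` applies the inclusive count thresholds (at least
`min_count` reads in at least `min_samples` samples) used upstream of the
fold-change classification. The DE model that produces log2FC values is
out of scope by design; `naive_log2fc()` is a documented plain-ratio
stand-in, not a replacement for one.

## The wavefront simulator

`simulate_wavefront_timecourse()` generates the data structure the
estimator assumes, with known truth: per gene, expected density at
gene-oriented offset $x$ and time $t$ is `basal` (default 0) where
$x > v t$ and `beta` behind the front, times `pileup_gain` past the pA
site to mimic 3′ Pol II accumulation. The wave is deliberately a step
function — the simplest process under which the true rate $v$ is
identifiable from coverage slopes — rather than a kinematic polymerase
simulation. Time 0 emits basal-only signal, matching transcriptionally
inert genes before stimulation. Per-bin within-bin expectations are exact
integrals of the piecewise profile, so a front crossing mid-bin produces
the correct fractional density. Optional noise draws Poisson counts per
bin (mean `noise_scale` at plateau density, scaled by bin-width fraction)
and rescales to density; count noise on short windows of a sequencing
track is well approximated by Poisson, and overdispersed
(negative-binomial) noise is a possible extension. All randomness is local
to a caller-supplied seed, and identical seeds give byte-identical
bedGraph output.

Default study conditions are timepoints {0, 5, 10} minutes, plateau
density 2 signal/bp, 100 expected counts per 50-bp bin at plateau (a
realistic per-bin depth for a deeply sequenced nascent library), and
elongation rates in the 400–4000 bp/min range spanning published Pol II
estimates.

What the simulator does *not* emulate — mappability gaps, library-prep
bias, pausing pile-ups inside the body, gene-to-gene induction delays,
overdispersion — bounds what passing tests show: they demonstrate the
estimator's correctness and rank-recovery under the stated model, not
performance on any particular sequencing dataset.

## Numerical choices

* Quantiles for Tukey summaries (`five_number_summary()`) use linear
  interpolation (R type 7), stated explicitly because box-plot conventions
  differ; whiskers are the most extreme data within 1.5 IQR of the box.
* `condition_log2fc()` adds a pseudocount of 0.01 density units to both
  numerator and denominator — small against typical plateau densities,
  keeps zero-density bins finite, and preserves antisymmetry.
* Kendall's correlation in `correlate_rates()` is tau-a
  (`(C - D) / (n(n-1)/2)`, ties counting toward neither), computed by
  direct pair enumeration; Pearson and Spearman estimates and all p-values
  come from `stats::cor.test()`.
* Quartile and metagene body boundaries use `floor` arithmetic, making
  segment widths differ by at most 1 bp and reconstruction exact.
* Degenerate inputs fail loudly: empty regions, zero library sizes, zero
  spike-in counts, constant benchmark vectors and overlapping track
  intervals are errors; excluded genes and empty quartiles warn.

## Problem sizes

The shipped validation uses genes of 8–12 kb (typical IEG lengths), 50-bp
bins, 50-gene recovery sets and 100-replicate condition contrasts with 20
genes per arm — sizes at which the estimator's behaviour is already
stable, chosen as representative of an IEG-scale analysis.

## A worked run

```{r example}
genes <- make_toy_annotation(10, length_range = c(8000, 12000), seed = 1)
conds <- tibble::tibble(
  condition = c("control", "fast"),
  v = c(1000, 2000), beta = 2,
  noise = "poisson", noise_scale = 100
)
sim <- simulate_wavefront_timecourse(genes, conds, seed = 1)

fits <- lapply(c("control", "fast"), function(cc) {
  estimate_proxy_rate(dplyr::filter(sim$tracks, condition == cc),
                      genes, condition = cc)
})
do.call(rbind, lapply(fits, glance))
```

The condition with the doubled true elongation rate shows the higher
median Proxy Rate; `tidy()` exposes per-gene values and `autoplot()` draws
the Tukey-style comparison.

## Limitations

The Proxy Rate is not an elongation rate in bp/min and should not be
read as one; it supports ordering and contrasting conditions. It inherits
the coverage normalization: comparisons across conditions assume tracks on
a common scale (spike-in or depth normalized). Bins with signal at
baseline that *decreases* on stimulation contribute positive
`mean(abs(slope))` mass; for systems with substantial down-regulation the
`abs_before_mean = FALSE` variant or the single-timepoint slopes (which
keep sign until aggregation) are the appropriate readout. Finally, the
benchmark module treats reference rates as opaque inputs; nothing in the
package re-implements wavefront HMM callers.
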