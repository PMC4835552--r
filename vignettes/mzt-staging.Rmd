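---
title: "Staging embryo transcriptomes across the maternal-to-zygotic transition"
author: "mztclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging embryo transcriptomes across the maternal-to-zygotic transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztclock)
```

## The model

Early embryogenesis is transcribed from two sources with opposite dynamics.
Maternally deposited mRNA is not replenished and decays with first-order
kinetics and gene-specific half-lives,

$$ m_g(t) = m_g(0)\,2^{-t/t_{1/2,g}}, $$

so on the log2 scale every maternal transcript is a straight line in time
with slope $-1/t_{1/2,g}$. Zygotic transcription activates around the MZT;
the package models it as a logistic in time,

$$ z_g(t) = z_g^{\max}\,\sigma\!\big((t - t_{\mathrm{on}})/\tau\big), $$

with midpoint $t_{\mathrm{on}}$ and time scale $\tau$. No functional form
for activation is canonical; the logistic is the minimal smooth monotone
choice with an interpretable midpoint. A third class of stable
(housekeeping) genes is flat in time, so that normalization behaviour is
testable.

Two consequences drive everything in the package:

* **Staging.** Because maternal slopes differ across genes, the *ranking*
  of maternal abundances changes continuously with time. Matching a query's
  ruler-gene ranks against a reference time-course therefore identifies the
  developmental stage, independently of library size.
* **The decay clock.** Between two samples separated by $\Delta t$, a
  decay-only transcript satisfies
  $\log_2\mathrm{FC}_g = -\Delta t / t_{1/2,g}$ exactly. Regressing
  fold-changes on $1/t_{1/2}$ estimates $\Delta t$ with no reference
  time-course at all, and the "extent of reduction" $-\log_2\mathrm{FC}$ is
  strictly decreasing in half-life, giving a Spearman correlation of $-1$
  in the noise-free limit.

## Ruler genes

`compileRuler()` operationalizes the ruler as the maternal genes that are
(i) expressed at the first reference stage (`minFirstStageExpr`, default 1
abundance unit), (ii) non-increasing between every pair of adjacent stages
up to a fractional jitter (`monotoneTolerance`, default 0.05), and (iii)
declining at least `minTotalDecline`-fold (default 2) over the whole
course. No published thresholds exist for this filter, so the defaults are
conservative, every run records them verbatim, and a published ruler list
can be supplied directly in place of the compiled one (`readRuler()` /
`readGeneList()`). Maternal/zygotic classification is an *input* (published
lists via `readGeneClasses()`, or `deriveGeneClasses()` as an explicit
stand-in), never inferred silently.

## Stage estimation

The default similarity between a query profile and a reference stage is the
Spearman rank correlation of $\log_2(x + 0.5)$ over ruler genes. Rank
correlation is scale-free — a library-size multiplier cancels exactly — and
robust to the heavy right tail of RPKM-like data; the pseudocount of 0.5
abundance units keeps zeros finite without distorting expressed genes. A
banded "overlap" metric (fraction of ruler genes within a 2-fold band,
`metric = "overlap"`) is provided as an alternative reading of
profile-overlap staging; it requires a normalized query. Ties at the argmax
resolve to the *earliest* stage: maternal rulers lose resolution late (many
genes fully decayed), which biases late ties.

**Continuous time.** Between stages, the reference is interpolated
log-linearly (geometrically), which reproduces first-order decay *exactly*;
the similarity is then evaluated on a fine time grid (`gridResolution`,
default 0.5 min) and the estimate is the midpoint of the optimal plateau,
snapped to a stage time whenever one attains the maximum (so an exact copy
of a reference column maps to exactly that stage's time). A classic 3-point
parabola through the per-stage similarities is available
(`interpMethod = "parabola"`), but on an irregular, coarse stage grid its
vertex can sit several minutes from the truth even without noise, whereas
the fine-grid search is exact for noise-free queries by construction; the
grid method is therefore the default. Estimates are clamped to the
reference span.

Replicates are estimated independently and summarized by the median
(`consensusEstimate()`), so between-replicate spread and bootstrap
uncertainty (`bootstrapStage()`: ruler genes resampled with replacement,
seed-deterministic) are both available. On noise-free simulated queries the
interpolated time is monotone in the true time and exact to grid
resolution; under multiplicative noise of 0.25 log2-sd with ~200 ruler
genes, single-replicate staging errors are a few minutes — the test suite
and `scripts/acceptance.R` quantify this on every run.

## Normalization

`normalizeToReference()` rescales each sample by a single factor, the
median over ruler genes of reference/query. The reference profile used as
the anchor is, by default, the profile at the sample's *matched* stage
(estimated first with the scale-free rank metric), so that a planted
library-size multiplier is recovered exactly on noise-free data; anchoring
at the first reference stage (`anchor = "first"`) is kept as an option but
would fold the median maternal decline into the factor for late-stage
queries. All-zero ruler rows are excluded from the median and the factors
are recorded in the output `colData`.

## Stage-matched comparison

`stageMatchedProfile()` returns the reference profile at the estimated
stage — the discrete best-stage column verbatim, or the geometric
interpolation at the continuous time. `residualFoldChanges()` then compares
the query against that profile, which removes the part of the
transcriptional difference that is explained by staging.

The recommended protocol for this endpoint, used throughout the tests, is:
pool replicates by their mean, normalize the pooled profile, estimate and
match at the **discrete** best stage (`interpolate = FALSE`), and design the
comparison so conditions sit at reference stage times. Two numerical
reasons: (i) zygotic transcripts rise steeply (≈0.03 log2/min near the
activation midpoint), so even a 1–2 min interpolation error imprints a
systematic sign on every zygotic residual, while the discrete stage is
recovered essentially without error; (ii) normalizing the pooled mean
absorbs, as part of the scale factor, the small upward bias
($\approx \sigma^2\ln 2/2$) that arithmetic replicate means of
log-normally noisy data carry, which per-replicate normalization would
leave in the residuals. With this protocol, a pure timing difference that
drives ~98% of maternal transcripts down and ~100% of zygotic transcripts
up in raw fold-changes leaves residual fractions at ~0.5, and planted
per-gene condition effects of +1 log2 surface in the top few percent of
absolute residuals.

## Global shift statistics

`globalShift()` reports, per class, the median log2 fold-change, the
fractions of genes strictly decreased/increased, and an exact two-sided
sign-test p-value. The sign test is deliberately minimal: the
maternal-down / zygotic-up claim is about direction, not magnitude, and the
exact binomial requires no distributional assumptions. Zero fold-changes
are excluded from the test (ties are undefined under it) and counted
separately; an all-zero class is flagged degenerate rather than assigned a
p-value.

## The decay clock

`estimateDeltaTimeDecay()` fits $\log_2\mathrm{FC}_g$ on $x_g = 1/t_{1/2,g}$
over maternal genes. The default fit is through the origin because the
decay law forces FC $=0$ at $\Delta t = 0$; `fitMode = "free-intercept"`
absorbs a global normalization offset on real data. Genes with
$\log_2\mathrm{FC} > +0.5$ are excluded and counted: apparent induction
violates the decay-only assumption (zygotic re-expression), and the
threshold is recorded in the output. `robust = TRUE` replaces least squares
with a repeated-medians slope (median of per-gene slopes for the
through-origin fit), resistant to a minority of outlying genes. Note the
exclusion rule makes the estimator exactly antisymmetric only on the genes
surviving the filter in both directions. The two clocks — stage mapping and
decay regression — agree on simulated decay-only data; on real data they
need not, since real maternal transcripts can be re-synthesized, and
transcriptional stage need not track nuclear-division stage exactly. The
package reports both without adjudicating.

## The synthetic generator

`simulationConfig()` fixes the study conditions. Defaults, chosen once to
emulate the pre-cellularization *Drosophila* regime:

| parameter | default | units | rationale |
|---|---|---|---|
| `referenceTimes` | 60, 80, 95, 105, 115, 130, 150, 170 | min AED | nuclear-cycle-indexed grid c10–c14D; a documented placeholder — real stage tables are supplied by the user |
| `onsetTime` | 120 | min AED | major zygotic wave around early cycle 14 |
| `activationScale` | 15 | min | activation spread over tens of minutes |
| `halflifeLog2Mean`, `halflifeLog2Sd` | log2(60), 0.8 | log2 min | log-normal half-lives, bulk between ~20 and ~180 min, matching the heterogeneity of published maternal decay tables |
| `baselineLog2Mean`, `baselineLog2Sd` | 5, 2 | log2 abundance | RPKM-like heavy-tailed baselines |
| `noiseDispersion` | 0.25 | log2 sd | replicate noise used throughout the validation suite; no published value exists for this kind of replicate RNA-seq, so this is a convention, stated here |
| `nMaternal`, `nZygotic`, `nStable` | 300, 150, 100 | genes | desk-scale counts preserving the maternal-majority composition |

Noise is multiplicative log-normal on the mean abundance (the analysis
operates on RPKM-like continuous values, and the continuous model keeps
closed-form checks exact); a Poisson count mode with library-size scaling
(`mode = "counts"`) is provided but not the default. The generator is
seed-deterministic end to end: the realized gene table derives from the
config seed, observation noise from the per-call seed, and identical
(config, seed) pairs give bit-identical output.

**What the simulation does and does not show.** Passing recovery tests on
this generator demonstrates that the estimators are correct under their own
assumptions: exact first-order decay, a single smooth activation wave,
independent log-normal noise, and a noise-free reference. Real data violate
all four to some degree — maternal transcripts can be re-synthesized or
degraded in regulated waves, zygotic genes activate in staggered groups,
RNA-seq noise is correlated and count-based, and published references carry
their own noise and batch structure. The simulator also omits spatial
patterning, batch effects and gene–gene correlation entirely. Recovery on
simulation is therefore necessary, not sufficient, evidence for accuracy on
real embryos.

## Numerical conventions and degenerate inputs

* Pseudocount 0.5 abundance units before log2 for staging; decay-clock
  analyses on simulated (strictly positive, continuous) data use a
  negligible pseudocount (`1e-6`) so that closed-form identities hold.
* Geometric interpolation maps zeros to zeros; exact stage hits return the
  column verbatim.
* Constant query profiles (zero rank variance) are an error, not a silent
  `NA`; degenerate correlations (e.g. $\Delta t = 0$, all extents zero)
  are reported as 0 with an explicit `degenerate` flag.
* Times outside the reference span are clamped with a warning; argmax ties
  resolve to the earliest stage.
* Readers validate every type invariant (non-negative values, unique ids,
  rectangular tables, positive half-lives, disjoint class lists) and report
  offending genes/samples by name; every writer round-trips through its
  reader.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run entirely on the generator:
self-mapping over the 8 default stages; 100 query/control pairs at a
planted 35-min offset (noise 0.25 log2-sd, 200 ruler genes) for the stage
clock; 100 simulations of 150 maternal genes for the decay clock plus a
200-draw permutation null; 50 random noisy references against a
brute-force ruler oracle; 10 timing-only simulations of 6 replicates for
the raw/residual shift fractions (reported as means across simulations,
since a single simulation's zygotic fraction carries ~0.05 sampling sd);
and 5 planted-effect simulations of 20 spiked genes. These sizes keep each
check statistically meaningful while the whole suite completes in well
under a minute.

## Limitations

* Single-query mapping only: the package does not align two arbitrary
  time-courses to each other, and has no latent-trajectory model.
* Gene identifiers match by exact string equality (after whitespace
  stripping); symbol aliasing is out of scope.
* Half-lives are an input, never estimated from the data.
* Downstream interpretation (functional enrichment of residuals,
  differential-expression modelling) is out of scope; the residual
  fold-change table is the endpoint.
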