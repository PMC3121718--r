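---
title: "Anchoring brain transcriptional responses to DNA damage: models and methods"
author: "txanchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring brain transcriptional responses to DNA damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txanchor)
```

# The scientific setting

Alkylating genotoxins such as methylazoxymethanol (MAM) leave
O6-methylguanine (O6-mG) adducts in DNA. In tissues with little
O6-mG-methyltransferase (MGMT) repair capacity the lesions persist, and the
question this package addresses is whether, and which, transcriptional
changes track that lesion burden. The experimental template is a
two-laboratory factorial design: wild-type and *Mgmt*-null mice receive a
single dose of MAM or vehicle, brains are profiled on expression arrays at
6, 24, 48 and 168 h post dosing (three arrays per design cell, one array per
animal), and the same animals' O6-mG burdens are quantified by mass
spectrometry in brain and liver.

The analysis has five statistical components, each exported as a module of
this package:

1. **Preprocessing** (`rmaNormalize`): RMA-style background correction,
   quantile normalization and median-polish summarization of probes into
   probeset expression values.
2. **Factorial differential expression with a replication-consistency
   filter** (`runDiffExpr`, `callDE`): per-probeset linear models with
   treatment, genotype, their interaction, and laboratory terms; probesets
   whose effects differ between laboratories are excluded; the rest are
   refitted without laboratory interactions and gated on an FDR-adjusted
   p-value < 0.05 *and* absolute fold change > 1.3.
3. **Lesion anchoring** (`anchorGenes`): Spearman correlation between
   normalized intensity and the animal's O6-mG burden among MAM-treated
   animals, per timepoint; genes with rho > 0.70 at any timepoint are
   "anchored" to DNA damage.
4. **Enrichment** (`hypergeomEnrich`, `buildInteractionMatrix`,
   `treEnrichment`): gene-set overrepresentation of the DE and anchored
   lists, and promoter transcription-factor binding-site (TRE) analysis with
   a >5% prevalence filter and Fisher-type enrichment against a reference
   promoter set.
5. **Adduct statistics** (`rankFit`, `adductStats`): rank-based
   (Wilcoxon-scores) comparison of lesion burdens between genotypes.

A truth-labelled synthetic-data generator (`simulateStudy`) reproduces the
design so that every stage can be validated end to end, and `runPipeline`
orchestrates the whole analysis from one serializable configuration.

# The synthetic study generator

`simulateStudy` draws a probe-level experiment plus matched lesion tables.

**Lesion kinetics.** The study template reports empirical time-courses only,
so the generator adopts the simplest mechanism consistent with them: a
single-pulse, first-order-repair model. The expected burden at time $t$
hours in tissue $s$ for genotype $g$ is

$$\mu_{gs}(t) = B_s \, e^{-\lambda_g t},$$

with initial burdens $B_\text{brain} = 300$ and $B_\text{liver} = 3\times
10^5$ lesions per $10^8$ nucleotides (the liver/brain ratio of $10^3$
matches the reported separation between the tissues), repair rates
$\lambda_\text{wt} = \ln 2/24\ \mathrm{h^{-1}}$ (a 24 h half-life, enough to
drive wild-type brain to the assay floor within the study window) and
$\lambda_\text{ko} = 0$ (no MGMT, no specific repair). Observations carry
mean-preserving lognormal noise with CV 0.2. The assay's minimal detectable
quantity (MDQ) spans 1–2.6 lesions per $10^8$ nucleotides: any draw below
2.6 is reported left-censored at the MDQ midpoint 1.8 with a `censored`
flag, so no emitted value lies between zero and the MDQ. Vehicle animals sit
at the MDQ. This reproduces the qualitative template — flat/low wild-type
brain, persistent knockout burden, declining wild-type liver.

**Expression.** Baseline log2 probeset levels are uniform on (6, 10); each of
the 11 probes of a probeset carries a fixed affinity (sd 0.5 log2 units), so
median polish has genuine probe-level structure, and iid Gaussian noise
(default sd 0.25 log2) is added per probe. Planted signal categories are
disjoint: treatment, genotype and interaction effects add ±1.0 log2 units in
the corresponding cells; "laboratory-inconsistent" probesets receive a
site-by-treatment interaction of the same magnitude (which the consistency
filter should catch); a constant per-site offset (0.3 log2) mimics the batch
effect the laboratory term absorbs. Default fractions are 5% per category —
a sparse-signal regime typical of single-dose toxicogenomics.

**Anchoring implantation.** Anchored probesets couple their MAM-arm
expression to the animal's brain lesion burden through a Gaussian copula on
the within-timepoint lesion ranks: with copula correlation $\rho$
(`anchorStrength`, default 0.9) and amplitude 1 log2 unit, the latent
correlation — and, to within the usual $\tfrac{6}{\pi}\arcsin(\rho/2)$
attenuation, the Spearman correlation — of the summarized expression with the
lesion ranks is approximately $\rho$. Ranks are used precisely so that the
parameter maps onto the rank statistic the anchoring stage computes.

**Pairing.** One animal corresponds to one array and one lesion measurement
per tissue; the half-brain split of the template (RNA from one hemisphere,
DNA from the other) justifies treating expression and lesions as paired
per animal. Expression is generated for brain only; liver enters through the
lesion tables (it is the positive-control tissue for DNA damage, not a
modelled transcriptome).

**What the generator does not emulate.** Probe-specific saturation and
optical background, cross-hybridization, correlated noise between probesets,
probeset-size heterogeneity, and any real regulatory structure among genes.
Passing tests therefore demonstrate that the statistical machinery recovers
the signals it targets under its own assumptions, not that those assumptions
hold on a given real dataset.

# Preprocessing

`backgroundCorrect` models one array's intensities as
$O = S + N$, $S \sim \mathrm{Exp}(\alpha)$, $N \sim \mathcal N(\mu,
\sigma^2)$, and replaces each observation by the posterior mean

$$\mathrm{E}(S \mid O = o) = a + \sigma\,
\frac{\varphi(a/\sigma)}{\Phi(a/\sigma)}, \qquad
a = o - \mu - \sigma^2\alpha,$$

evaluated on the log scale deep in the left tail. Parameters are estimated
per column by the standard heuristic: $\mu$ from the (refined) density mode,
$\sigma$ from the left-tail root mean square about the mode (times
$\sqrt 2$, the half-normal correction), and $\alpha$ as the reciprocal mean
of the right-tail excess. The transform is monotone, so it never reorders
probes; it is validated against a numeric-quadrature oracle of the posterior
mean rather than against any reference binary. A constant column is returned
unchanged — there is nothing to estimate.

`quantileNormalize` maps every column onto the row-wise mean of the sorted
columns. Tied input values receive the mean of the reference values at their
tied ranks, which makes the map well defined and idempotent.
`medianPolishSummarize` runs Tukey's median polish (convergence when the sum
of absolute residuals changes by less than `eps = 0.01`, at most 10 sweeps,
matching common practice) and reports overall-plus-column effects as the
probeset expression. A single-probe block is its own summary. For the usual
case of equal-sized probesets, `rmaNormalize` runs all polish sweeps
vectorized across probesets; late sweeps of blocks that individually
converged early can differ from the one-block-at-a-time reference by less
than the tolerance. Note the median-polish decomposition is not unique:
exact column equivariance holds in exact-arithmetic cases, while converged
fits of perturbed random blocks can settle a few hundredths apart.

Simulated data carry no additive optical background, so pipeline
configurations on synthetic studies disable the background step by default
(`background = FALSE`); it remains available and tested for data that need
it. CEL-file parsing is out of scope — input is a plain probe-level TSV.

# The factorial model and the consistency filter

At each timepoint and probeset the full model is

$$y = \beta_0 + \beta_T T + \beta_G G + \beta_{TG} TG + \beta_L L +
\beta_{LT} LT + \beta_{LG} LG + \beta_{LTG} LTG + \varepsilon$$

with ±1/2 coding for treatment $T$, genotype $G$ and laboratory $L$. This
coding makes every main-effect coefficient the corresponding group contrast
on the log2 scale (e.g. MAM minus vehicle means, averaged over the other
factors) and every interaction coefficient a difference of differences, so
fold changes are simply $\mathrm{sign}(\hat\beta)\,2^{|\hat\beta|}$.

The replication-consistency rule reads "interactions involving the
laboratory" as the three $L\times$ terms jointly in the strict sense: the
model is reduced (dropping the three laboratory interactions but keeping the
main laboratory term) only when *all three* have p > 0.15; otherwise the
probeset's effects differ between laboratories and it is excluded from all
effect families at that timepoint. An optional joint-F variant
(`labTest = "joint"`) tests the three terms with a single 3-df F statistic.
Note that under the strict per-term reading a truly concordant probeset is
reduced with probability $0.85^3 \approx 0.61$ per timepoint — the filter
trades sensitivity for cross-laboratory reproducibility, which is why
recovery of planted effects is assessed on the union over timepoints.

Benjamini–Hochberg adjustment is applied within each (timepoint, effect)
family over the non-excluded probesets, matching an analysis that treats the
four timepoints separately; whether the original analysis pooled effects
within a timepoint is not documented, so the per-family choice is this
package's documented decision. A probeset is declared significant only if
its q-value is below 0.05 *and* its absolute linear fold change exceeds 1.3
— both gates, always. Fold change is model-based (the coefficient as a group
contrast), the definition consistent with the modelling framework. Besides
the three model terms, `runDiffExpr` reports the `treatment_ko` contrast
($\beta_T + \beta_{TG}/2$, MAM vs vehicle within the knockout) — the
analysis that detects a response present only in repair-deficient animals —
while the `interaction` term is the genotype-difference analysis.
Probesets are mapped to genes keeping the smallest-q probeset per gene, and
`combineAnalyses` takes gene-level unions.

# Anchoring

For each candidate probeset and timepoint, `anchorGenes` computes the
Spearman correlation between normalized intensity and brain lesion burden
over all MAM-treated animals of that timepoint, pooling both genotypes (the
anchoring question is whether expression tracks damage, whatever the
genotype that produced it). A candidate is anchored when rho exceeds 0.70 at
one or more timepoints; requiring a single timepoint rather than a combined
statistic is the package's reading of "anchored", recorded here because the
alternative is defensible. The threshold applies to signed rho — a gene
tracking damage negatively is not "anchored" under the default; an
`absolute = TRUE` flag enables the two-sided reading. Censored lesion values
enter at the MDQ midpoint, which is rank-safe because all censored values
tie. Timepoints with fewer than three matched animals are skipped with a
warning, and constant vectors have undefined rank correlation and are never
anchored. Because anchoring is rank-based it is invariant to any strictly
monotone transform of either variable.

# Gene-set and promoter TRE enrichment

Proprietary pathway tools cannot be reproduced, so overrepresentation is
generic: for a list of $n$ genes from a universe of $N$ with a term of size
$K$ and overlap $k$, `hypergeomEnrich` reports the Fisher tail
$P(X \ge k)$ and the EASE variant (the same tail at $k-1$, the conservative
jackknifed score popularized by DAVID), with BH adjustment across terms.
The default universe is every gene represented on the array after filtering.

The TRE stage scans promoter sequences (taken as given; 2000 bp is the
default length the synthetic promoter generator uses, and the length is
recorded in the output) for motifs defined either as IUPAC consensus strings
or as position-weight matrices with a log-odds threshold against a uniform
base background. Scanning is case-insensitive, reports 0-based half-open
forward-strand coordinates, counts overlapping matches, scans the reverse
complement under the default both-strand policy, and never lets a sequence
`N` match a non-N motif position. The interaction matrix over a candidate
gene list records binary presence (at least one hit), dropping motifs found
in no more than 5% of the candidate promoters; enrichment then compares each
retained motif's hit frequency in the candidates against an unfiltered scan
of the reference promoters (default: all genes with promoters) by a
one-sided Fisher test, significant at p < 0.05. Whether the original
promoter tool counted sites once or multiply is not documented; binary
presence is adopted.

# Rank-based adduct statistics

For a two-group genotype comparison, the R-estimate of the shift under
Jaeckel's dispersion with Wilcoxon scores is the Hodges–Lehmann estimator —
the median of all pairwise knockout-minus-wild-type differences — and that
is what `rankFit` computes, with mid-ranks throughout so MDQ-censored ties
are permitted. Its standard error is $\hat\tau\sqrt{1/n_1 + 1/n_2}$, where
$\hat\tau$ is the standard window estimator of the Wilcoxon-scores scale
$1/(\sqrt{12}\int f^2)$ (density of pairwise residual differences at zero,
window at the 0.8 quantile, with degrees-of-freedom and Huber-type
finite-sample corrections). The Wald statistic $TS = (\hat\Delta/SE)^2$ is
referred to $F(1, n-2)$ — $F(1,28)$ for the 30-observation strata the
template reports. Group medians come with the companion standard error
$\hat\tau_S/\sqrt{n}$, $\hat\tau_S$ estimating $1/(2f(\mathrm{med}))$ from
the length of a distribution-free confidence interval for the median. At
n = 15 per group the empirical size of the test at nominal 0.05 is about
0.04 — the window estimator's mild conservatism, documented for this class
of estimators.

# Numerical and design choices, in one place

| Parameter | Default | Where | Why |
|---|---|---|---|
| FDR threshold | 0.05 | `callDE` | standard gate |
| fold-change gate | 1.3 (linear) | `callDE` | the template's second gate |
| consistency alpha | 0.15 | `consistencyFilter` | the filter's documented level |
| anchoring threshold | 0.70 (signed rho) | `anchorGenes` | the anchoring definition |
| TRE prevalence minimum | 5% of candidate promoters | `buildInteractionMatrix` | interaction-matrix rule |
| TRE alpha | 0.05 | `treEnrichment` | significance level |
| median-polish eps / sweeps | 0.01 / 10 | `medianPolishSummarize` | common practice |
| probe noise sd | 0.25 log2 | `effectSpec` | study-condition noise level |
| planted effect | 1.0 log2 | `effectSpec` | fold change 2.0, above the 1.3 gate |
| anchor strength | 0.9 | `effectSpec` | strong coupling, detectable at n = 12 |
| probes per probeset | 11 | `studyDesign` | typical probeset size |
| probesets simulated | 1000 (500 in `pipelineConfig`) | `studyDesign` | large enough for stable FDR behaviour, small enough for fast end-to-end runs |

Degenerate inputs are handled explicitly: constant columns pass through
background correction, single columns skip quantile normalization with a
warning, single-probe probesets summarize to themselves, rank-deficient
designs (a missing cell) raise an error naming the problem, empty candidate
sets anchor to empty sets, and a motif absent from candidates and reference
gets p = 1.

# Validation strategy and problem sizes

Every operation with a closed-form or enumerable answer is tested against an
independent oracle computed in the test itself: hand rank formulas for
Spearman, the step-up definition for BH, exact `choose()` summation for
hypergeometric/EASE/Fisher tails, enumeration of all pairwise differences
for the Hodges–Lehmann shift, all 720 rank permutations for the exact
6-animal anchoring null, a quadrature oracle for the background-correction
posterior mean, and `lm()` for the factorial coefficients. End-to-end
recovery is assessed at the emulated design: 1000 probesets, 96 arrays,
planted 1.0-log2 treatment effects at probe noise 0.25, across 20 seeds
(sensitivity ≥ 0.90 at empirical FDP ≤ 0.10); the consistency filter is
required to exclude ≥ 95% of probesets with a planted 2.0-log2
site-by-treatment interaction; anchoring recovery is measured over 100
seeds of a 6-MAM-animal fixture; and the rank test's size is estimated from
2000 null replicates at n = 15 per group. These sizes are the package's
validation choices: large enough for the stated tolerances, small enough
that the whole suite runs in a few minutes.

# Known limitations

* The laboratory-consistency filter is intentionally strict; on concordant
  data it discards ~39% of probesets per timepoint, so per-timepoint
  sensitivity is materially lower than union sensitivity.
* Variance moderation (empirical Bayes), random animal effects and
  continuous-time modelling are out of scope — each would change the
  inferential machinery the package is meant to mirror.
* Anchoring applies a fixed correlation threshold, not a multiplicity-
  corrected test; with 12 animals per timepoint the null exceedance
  probability of rho > 0.7 is small but not zero, which is why anchoring is
  restricted to DE candidates.
* Enrichment results depend entirely on the supplied gene-set collection
  and promoter sequences; the package ships none.
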