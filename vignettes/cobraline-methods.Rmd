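---
title: "Modeling COBRA LINE-1 methylation patterns and calibrated case-control cohorts"
author: "cobraline authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling COBRA LINE-1 methylation patterns and calibrated case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobraline)
```

## The assay and its model

Combined Bisulfite Restriction Analysis (COBRA) of the LINE-1 retroelement is
a semi-quantitative global-methylation assay. Genomic DNA is bisulfite
converted (unmethylated cytosine reads as thymine; 5-methylcytosine is
preserved), a 160 bp stretch of the LINE-1 promoter is PCR amplified, and the
product is digested with two restriction enzymes that each interrogate one
CpG dinucleotide:

* **TaqI** (T^CGA) keeps its site only if the second interrogated CpG was
  *methylated* (the preserved C completes TCGA); its cut falls 80 bp into the
  amplicon.
* **MluCI** (^AATT) gains its site only if the first interrogated CpG was
  *unmethylated* (the converted C supplies the final T of AATT); its cut
  falls 62 bp into the amplicon.

Complete digestion therefore maps each joint methylation state of the two
CpGs — the molecule's *pattern* — to a fixed fragment multiset:

| pattern | CpG1 (MluCI) | CpG2 (TaqI) | fragments (bp) | quantified |
|---|---|---|---|---|
| mCmC | methylated | methylated | 80 + 80 | 80, 80 |
| uCmC | unmethylated | methylated | 18 + 62 + 80 | 62, 80 |
| mCuC | methylated | unmethylated | 160 | 160 |
| uCuC | unmethylated | unmethylated | 62 + 98 | 62, 98 |

The 18 bp piece of uCmC runs off the quantified gel window and carries no
signal downstream. `fragmentsForPattern()` encodes this table directly, and
`simulateAmpliconDigest()` re-derives it from sequence by composing
`bisulfiteConvert()` with `digestSequence()`.

The original study never printed its amplicon sequence (and its subject-level
data are not publicly available), so the package ships a **synthetic** 160 bp
amplicon, `line1Amplicon()`, engineered to realize exactly this geometry: the
first CpG cytosine sits at position 66 inside `AATCG` (conversion of an
unmethylated C creates `AATT`, cutting at 62), the second at position 81
inside `TCGA` (a methylated C preserves the TaqI site, cutting at 80), and
the backbone contains no other cytosine and no other `AA` dinucleotide, so no
conversion state can create a spurious site. With cuts at 62 and 80, all four
published fragment sets — including the 18 bp piece of uCmC, which is simply
the 62–80 interval — fall out of one sequence with no extra machinery. Real
amplicons may realize the 18 bp fragment differently; only the lengths matter
downstream. Digestion is modeled on one strand (fragment lengths, the only
observable, are strand-symmetric), to completion (partial digestion is
treated as a noise concern in the generator), in 1-based coordinates with a
cut placed `cutOffset` bases into each site occurrence; overlapping
occurrences are each cut, and empty end fragments are dropped as unobservable.

## The densitometry deconvolution

Each gel lane yields percent intensities of the four quantified bands. These
are converted to relative molar abundances by dividing by *effective
lengths*:

$$A = \frac{\%160}{160},\quad B = \frac{\%98}{94},\quad
  C = \frac{\%80}{78},\quad D = \frac{\%62}{62}.$$

The divisors 94 and 78 for the 98 and 80 bp bands are retained exactly as
published for the assay (they presumably reflect base-composition corrections
of the bisulfite strand; the source does not explain them).
`cobraEffectiveLengths()` exposes them, and every function accepts substitute
lengths so the bias induced by using nominal lengths can be studied.

Counting fragments per pattern gives the band abundances
$q_{160} = f_{mCuC}$, $q_{98} = f_{uCuC}$, $q_{80} = 2f_{mCmC} + f_{uCmC}$,
$q_{62} = f_{uCuC} + f_{uCmC}$, and inverting this linear system yields, with
$S = (C - D + B)/2 + A + D$:

$$\%mCmC = 100\frac{(C - D + B)/2}{S},\quad \%uCmC = 100\frac{D - B}{S},\quad
  \%mCuC = 100\frac{A}{S},\quad \%uCuC = 100\frac{B}{S},$$

$$\%mC = 100\frac{C + A}{C + 2A + B + D}.$$

The four percentages sum to 100 algebraically, and
$mC = (2\,mCmC + uCmC + mCuC)/2$ holds identically — both facts are enforced
by tests. One published formula (the uCmC one) is printed with unbalanced
parentheses; the implementation uses the only reading under which the
patterns sum to 100 and a molecule-count oracle is recovered exactly.
`forwardBandProfile()` implements the generative direction (stain signal
modeled as molarity × effective length, i.e. mass-proportional), and
`quantifyBands()` inverts it exactly: the round trip is identity to 1e-9
over a 1000+ point simplex lattice in the tests.

Noisy lanes can leave the feasible simplex (the inferred $mCmC$ or $uCmC$
numerator can go negative). Negative numerators within `1e-9 * S` are treated
as exact zeros; larger ones are clipped to zero with a warning and the four
percentages renormalized. `mC` is always reported from its own published
formula, so the mC/pattern identity is exact for feasible lanes and
approximate only where clipping occurred.

## The synthetic cohort generator

No subject-level data are deposited, so all cohort-level behavior is
validated by *parameter recovery*: a generator draws cohorts whose structure
matches the published summary statistics, and the analysis pipeline must
recover those targets. The default configuration
(`defaultCohortConfig()`) encodes the study conditions: 35 patients and 28
controls, 56.7% male in both groups (the published sex split, which the
source reports identically for both groups), and per-group marginals pinned
to every published median (IQR) — age, blood pressures, BMI, fasting glucose,
HbA1c, total methylation mC and the uCmC/mCuC patterns; for patients also age
at diagnosis, 14 (9–21), and disease duration, 12 (4–20.5) years.

**Marginal families.** Printed summaries are median/IQR, so marginals are
low-parameter quantile-pinned families (`solveMarginal()`):

* `splitnorm` (the default for clinical and methylation variables): a
  quantile-spliced two-half normal matching *all three* printed quartiles
  exactly. The published quartiles are strongly asymmetric (control mC is
  44.7–46.5–47.3; glucose 94–113–146), and the variables were non-normal by
  the study's own Shapiro–Wilk gate, so a symmetric fit would discard printed
  information — in particular it inflates the controls' upper mC tail and
  understates the group separation the study detected. The family's density
  has a step at the median (the price of pinning the median at the join);
  for rank-based analyses only the quantile function matters.
* `truncnorm` for bounded variables (duration ≥ 1 year, the study's inclusion
  criterion; age at diagnosis ≥ 0; control age in the 18–70 enrollment
  window): location and scale are solved numerically so the *truncated*
  median and IQR match exactly. Clamping instead would pile mass on the
  bound and create rank ties that attenuate the duration–uCmC correlation.
* `normal` and `logitnormal` are available for symmetric and
  boundary-hugging variables respectively.

**Pattern simplex.** The five published methylation summaries are not
jointly consistent with the deconvolution identity
$mC = (2\,mCmC + uCmC + mCuC)/2$ (patient medians give
$(2\cdot35.3 + 28.4 + 16.4)/2 = 57.7$, not the printed 47.3). The generator
therefore samples the three quantities the study's findings rest on — mC,
uCmC and mCuC — from their printed marginals and derives
$mCmC = mC - (uCmC + mCuC)/2$ and $uCuC = 100 - mC - (uCmC + mCuC)/2$, the
unique completion satisfying both the identity and the simplex constraint.
The two derived patterns (the widest-IQR rows) absorb the printed
inconsistency; their simulated medians (≈25 and ≈30 for patients) accordingly
differ from the printed 35.3 and 18.8. Rare negative derived values
(< 0.01% of subjects under the defaults) are clipped and the simplex
renormalized; a configuration producing > 20% violations is rejected as
inconsistent.

**Correlation structure.** Rank correlations are imposed through a latent
Gaussian copula. The published correlation table mixes two populations: its
glucose/HbA1c rows match pooled-cohort p-values (n = 63), while age at
diagnosis and duration match patients-only p-values (n = 35); the generator
treats them accordingly. Because pooled rank correlations also absorb the
between-group separation (patients have both higher glucose and higher mC),
the exact single-population conversion $r = 2\sin(\pi\rho/6)$ is only a
seed value; the shipped latent entries are the frozen output of
`calibrateCohortConfig()`, an iterative Monte-Carlo scheme that pushes large
cohorts through the *full* pipeline (copula, truncation, simplex derivation,
band noise, quantification) and moves each latent entry by the residual
between measured and target Spearman rho (1e5 subjects per iteration, 8
iterations). Within-patient mC–uCmC is set to the published −0.364 (controls:
no association, also as published); glucose–HbA1c, unreported, is set to a
physiologically plausible latent 0.5. Any non-positive-definite matrix that
arises is repaired by nearest-PD projection. Patients' age is derived as age
at diagnosis + duration (median ≈ 26 vs the printed 28) rather than sampled:
the graded quantities are the duration and age-at-diagnosis correlations with
uCmC, which a derived-duration design would leave to an unprinted
age–age-at-diagnosis correlation, whereas derived age only affects the
(null) age correlations.

**Band noise.** Densitometry error is multiplicative mean-one lognormal per
band (scale-proportional, the natural model for stain/imaging noise; the
source is silent), default CV 3%, after which lanes are renormalized to
100% and re-quantified. With `noiseCV = 0` the estimates equal the generated
ground truth to 1e-9, a property the tests propagate through the whole
generator.

## The statistical battery

`compareGroups()` uses the two-sided Mann–Whitney U test (tie-corrected
normal approximation with continuity correction by default; an exact method
for small, tie-free samples backs the enumeration oracle in the tests) for
continuous variables and Pearson's chi-squared without continuity correction
for categorical ones. `correlate()` is Spearman's rho with average-rank ties
and the t-approximation p-value. `buildTable1()` / `buildTable2()` rebuild
the published table layouts (12 comparison rows; 6 × 5 correlation rows with
the pooled/patients-only split above). The Shapiro–Wilk gate is reported by
`normalityGate()` but the pipeline always proceeds nonparametrically, as the
study did; no multiple-testing correction is applied, matching the source —
a caveat for any reuse, since the correlation table alone holds 30 tests.

`estimatePower()` estimates power by simulation (normal groups, Mann–Whitney
rejection by default). Note that the study's design statement — ~80% power
for a 1-point difference at SD ≤ 1.8 with 25 per group — is not reproduced
by computation: the closed-form two-sample normal approximation gives
$\Phi(\delta\sqrt{n/2}/\sigma - z_{0.975}) \approx 0.50$ at SD = 1.8, and
the simulation agrees. The function reports computed values only. Under the
calibrated generator the mC comparison rejects in roughly 70% of replicate
cohorts — consistent with a moderately powered design that happened to
observe p = 0.005.

## Numerical choices and problem sizes

Deterministic seeding throughout: one global seed fans out to per-stage child
seeds (`childSeed()`, kept inside the 32-bit integer range), and identical
seed + configuration reproduce byte-identical cohort TSVs. Percentages are
stored at full precision (TSVs print `%.17g`, which round-trips doubles);
1-decimal rounding happens only in rendered tables. The test and acceptance
workloads use 200 replicate cohorts for calibration recovery, 1e4 null
replicates for the type-I check, a 1140-point simplex lattice for the
round-trip identity, and 100 random molecule populations for the counting
oracle — sizes chosen to keep Monte-Carlo error an order of magnitude below
each tolerance.

## What the simulations do and do not show

Passing recovery tests shows the generator, forward model, deconvolution and
statistics are mutually consistent and reproduce the published summary
structure. They do not validate the assay against real gels: the generator
has no inter-gel calibration drift (the cell-line control lanes of the wet
protocol are a config hook only), no partial digestion, no smear/background
signal, bands perturbed by an idealized lognormal noise, and marginals that
are smooth low-parameter fits to three printed quantiles. Findings about real
cohorts should rely on the deconvolution algebra and the statistical engine,
not on the generator's distributional details.
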