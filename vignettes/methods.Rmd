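---
title: "Models and methods behind sitless"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sitless}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitless)
```

`sitless` implements the computational core of a three-regimen crossover
study of sedentary behaviour and metabolic health: participants complete a
sitting regimen (SIT), a sitting-less regimen (SL, sitting replaced by
standing and walking) and an exercise regimen (EXE, one hour of supervised
cycling), and after each regimen undergo a two-step
hyperinsulinaemic-euglycaemic clamp with stable-isotope glucose tracer,
indirect calorimetry, activPAL posture monitoring and a muscle-biopsy
metabolome profile. This vignette records the models, the defaults and why
they were chosen, and what the synthetic-data generator can and cannot stand
in for.

## Steele single-pool tracer kinetics

During the clamp, a d~2~-glucose tracer is infused at a constant
0.04 mg kg^-1^ min^-1^ (converted internally at 182.0 g/mol, i.e.
`r round(sitless::tracer_umol_kg_min(cohort_config()), 4)`
µmol kg^-1^ min^-1^) and enrichment is expressed as the tracer-to-tracee
ratio (TTR) $Z$. For consecutive samples at $t_1, t_2$ with plasma glucose
$C$ (µmol/l) and tracer infusion $F$:

$$
R_a = \frac{F - p_V \, \bar{C} \,(Z_2 - Z_1)/(t_2 - t_1)}{\bar{Z}},
\qquad
R_d = R_a - p_V \, \frac{C_2 - C_1}{t_2 - t_1},
$$

with arithmetic midpoints $\bar{C}, \bar{Z}$ and an effective distribution
volume $p_V = 0.160$ l/kg. This is the classical single-pool non-steady-state
form; the midpoint two-sample discretisation was chosen because it is the
standard formulation in tracer-methodology texts and is exact for linear
segments. Per-phase fluxes are means of interval estimates over the final
30 min of each phase (basal, 10 mU m^-2^ min^-1^ low-dose insulin,
40 mU m^-2^ min^-1^ high-dose insulin), the protocol's steady-state windows;
the coefficient of variation of glucose inside the window is carried as QC.
Derived quantities: EGP $= R_a -$ GIR, hepatic insulin sensitivity as
percentage EGP suppression at low insulin, and non-oxidative glucose
disposal NOGD $= R_d -$ carbohydrate oxidation at high insulin.

Numerical choices: no enrichment smoothing by default (an optional 3-point
moving average sits behind `kinetics_config(smooth = TRUE)`, since whether
the original analysis smoothed is unknowable); intervals with $\bar{Z}
\le 0$ are flagged rather than dropped; the exogenous glucose infusate is
treated as unlabeled, so GIR enters only through the EGP subtraction.

## Indirect calorimetry

Substrate oxidation uses Frayn-type stoichiometry with negligible protein
oxidation — carbohydrate $4.55\,\dot{V}CO_2 - 3.21\,\dot{V}O_2$ g/min, fat
$1.67(\dot{V}O_2 - \dot{V}CO_2)$ g/min — and a Weir-type energy expenditure
$(3.941\,\dot{V}O_2 + 1.106\,\dot{V}CO_2) \times 4.184$ kJ/min. The
carbohydrate equation yields grams of *glucose*, so the internal consistency
test closes energy balance with the glucose heat of combustion
(15.65 kJ/g) rather than the polysaccharide value; with that convention the
two routes agree within 2% across RER 0.75–1.00. Carbohydrate oxidation is
converted to µmol kg^-1^ min^-1^ at 180.16 g/mol for the NOGD subtraction.
Respirometry traces are excluded when the cytochrome-c response exceeds 15%
— strictly above, per the protocol wording; a response of exactly 15% is
kept — and replicate traces aggregate as the mean of kept traces.

## Activity summaries and MET hours

Posture event streams must tile each 24 h day; gaps or overlaps beyond one
second are errors that name the offending interval. Cadence is the
step-weighted mean over stepping time (total steps / stepping minutes),
a convention this package declares since event-level averaging is ambiguous.
Daily energy expenditure uses a compartmental MET model
(1 MET = 3.5 ml O~2~ kg^-1^ min^-1^):

$$
\mathrm{MET\,h} = 1.25\,h_{sed} + 1.4\,h_{stand}
 + h_{step}\left(1.4 + 2.6\,\tfrac{\min(\mathrm{cadence},120)}{120}\right)
 + h_{cycle} \cdot \mathrm{MET}_{ex}.
$$

These coefficients reproduce the study's reported daily energy expenditure
for the sitting (32.0 MET·h) and sitting-less (37.0 MET·h) regimens within
0.6%, which is why they are the package defaults; they live in
`met_model()`, not in code. Sleep counts as sedentary time for energy
expenditure (that is the only reading consistent with the reported values)
and is reported separately from diary intervals. The exercise-day value
(36.6 MET·h) involves a separate session-level calculation that cannot be
reconstructed from the described model (the reconstruction gives ≈35.5), so
the cycling pathway is configurable via `met_model(exercise_met = )` and is
not used as a reference point.

## Metabolomics

Raw intensities are normalised as
$\log_2(\mathrm{raw} / \mathrm{IS} / \mathrm{dry\ weight})$, mirroring the
protocol's internal-standard and dry-tissue-weight normalisation. Zeros and
missing values are imputed per metabolite by half the minimum positive value
(a declared convention; the count is reported), and all-zero metabolites
become flagged constant columns.

Per-metabolite effects come from the blocked linear model
`log2 intensity ~ participant + regimen` with contrasts EXE−SIT, SL−SIT and
EXE−SL. Residual variances are moderated by empirical Bayes: $(d_0, s_0^2)$
are estimated by moment-matching the distribution of $\log s_g^2$ to a
scaled log-F (digamma/trigamma inversion by safeguarded Newton iteration;
when the sample variance of $\log s_g^2$ falls below the theoretical
chi-squared floor, $d_0 = \infty$ and the prior is the pooled mean
variance), the posterior variance is
$\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and the moderated $t$
carries $d_0 + d_g$ degrees of freedom. p values are reported raw and
BH-adjusted per contrast; the implementation is cross-checked against
`limma::eBayes` in the test suite but does not depend on it.

PLS-DA uses NIPALS PLS2 on autoscaled metabolites against a centred one-hot
regimen response, with $A = 2$ components by default (matching the two
displayed components; one-component VIP is available via `vip(model,
ncomp = 1)`). Autoscaling is applied because mixed-magnitude metabolite
intensities would otherwise dominate the weights. VIP scores satisfy
$\mathrm{mean}(VIP^2) = 1$ identically; the top-25 heatmap matrix is
VIP-ordered with ties broken by metabolite id and row-standardised.

Signature concordance correlates per-metabolite signed significance scores
$s_g = \mathrm{sign}(\log_2 FC)\cdot(-\log_{10} p)$ between EXE−SIT and
SL−SIT (Pearson, with p underflow capped at $10^{-300}$). One caveat this
package documents because its own simulations surfaced it: **within a single
cohort the two contrasts share the SIT baseline, so their estimation errors
correlate ≈ 0.5 even when no metabolite responds at all**. A concordance of
that order is therefore not by itself evidence of shared biology; the
independence-null property in the test suite is accordingly evaluated on
signatures from independently generated cohorts, where $r$ scatters around
0 as expected. Exemplar metabolites are those with sign-consistent scores in
both contrasts, ranked by $\min(|s^A|, |s^B|)$ descending (a metabolite must
move clearly in *both* regimens), ties by id — a declared convention.

## Crossover statistics

Parametric outcomes use a one-way within-subject ANOVA with participant as
block (balanced SS decomposition, identical to `aov` on non-degenerate
tables but stable when all values are tied), with paired-t Bonferroni post
hocs (p × 3, capped at 1). Non-parametric outcomes use the Friedman test
(`stats::friedman.test`, average ranks with tie correction) with Dunn's z on
mean ranks. No sphericity correction is applied by default (three levels,
small n); Greenhouse–Geisser sits behind `rm_anova(gg = TRUE)`. Routing
between ANOVA and Friedman is the analyst's choice per outcome, not
automated. Missing regimen values trigger listwise deletion, matching the
per-outcome reduced n of clamp analyses.

The sample-size calculation finds the smallest n whose exact noncentral-t
power reaches the target at the Bonferroni-corrected two-sided level
(noncentrality $\sqrt{n}\,\delta/\sigma_d$). For the study-style
specification ($\sigma_d = 2.48$, $\delta = 2.70$, $\alpha = 0.05/3$,
power 0.8) the search returns `r paired_t_sample_size(2.48, 2.70)$n`;
the published 12 additionally reflects unstated conventions (dropout
allowance, Bonferroni divisor), so the package validates its answer against
a dual oracle — `power.t.test` at the corrected level and a
10^5^-replicate Monte-Carlo power estimate — rather than against that
number. At one residual degree of freedom the t critical value is so large
that even a 10-SD effect is underpowered at n = 2; the floor is only
reached for much larger standardized effects.

## The synthetic-cohort generator

The generator exists so every stage runs and can be verified with no
external data; its defaults *are* the study conditions.

**Physiological truth.** Per-regimen means of high-insulin Rd
(29.4 / 33.1 / 35.2 µmol kg^-1^ min^-1^ for SIT / SL / EXE) and NOGD
(15.7 / 19.9 / 22.3) are the reported group means; carbohydrate-oxidation
truth is their difference. Dispersion is split into a between-participant
offset (SD 2.5) plus a within-person regimen residual (SD 1.75, equivalent
to a within-person SD of paired differences of ≈2.48, the study's
reproducibility figure). The reported cross-sectional SE (≈3.7 at n = 10)
would imply a much larger between-person SD; the package deliberately uses
the smaller within-person-anchored dispersion because crossover inference —
and the recovery checks built on it — rests on within-person contrasts.
Basal EGP (11 ± 1 µmol kg^-1^ min^-1^), 55 ± 8% low-dose suppression and 90%
high-dose suppression are standard values for overweight adults, chosen once
since the study reports suppression only graphically. Body mass is
79 ± 8 kg.

**Clamp series.** Infusion rates and EGP approach their phase targets
exponentially (τ = 20 min), glucose is clamped from 5.4 to 5.2 mmol/l
(τ = 15 min), and the TTR trajectory is obtained by integrating the
single-pool mass balance $Z' = (F - R_a Z)/(p_V C)$ with RK4 at 0.25-min
steps, sampled every 5 min across 180/180/150-min phases. Because the
simulated enrichment obeys the same pool model the estimator inverts, the
Steele equations recover the generating fluxes exactly up to discretisation
(< 0.5% at zero noise) — a closed loop that turns parameter recovery into a
real test. Measurement noise: glucose SD 0.04 mmol/l, TTR CV 1%, gas
exchange SD 0.004 l/min; GIR is pump-controlled and noise-free.

**Activity.** Day-level posture totals are jittered (truncated normal,
relative SD 0.03) and renormalised so each day sums to exactly 24 h; bouts
are interleaved round-robin; stepping bouts carry steps at the regimen
cadence with 2% per-bout jitter. The day-to-day variance is a free
parameter — the study reports only day-level means — and the chosen 3%
produces step-count SEs of the same order as those reported.

**Metabolome.** On the log2 scale, intensity = baseline (uniform 12–20) +
participant effect (SD 0.5) + $\beta_{EXE}\mathbf{1}[EXE] +
\beta_{SL}\mathbf{1}[SL]$ + noise (SD 0.35), where 30% of the 138
metabolites respond ($\beta_{EXE} \sim N(0, 0.5)$, with an amino-acid-like
subset forced negative) and $\beta_{SL} = 0.3\,\beta_{EXE} + N(0, 0.25)$
(dose-like intermediacy: λ outside [0, 1] is rejected). These four numbers
were calibrated once so that the default-cohort concordance r falls in the
0.25–0.55 band around the reported 0.393 while preserving
mean|log2FC(SL−SIT)| < mean|log2FC(EXE−SIT)|; they were then frozen. Raw
intensities multiply in per-sample internal-standard intensities (30
standards, log-normal CV 10%) and dry weights (5 ± 0.5 mg) so the
normalisation step has real work to undo.

**What the generator does not emulate:** correlated metabolite modules,
heavy-tailed or missing-not-at-random intensities, drift or batch effects,
activity-dependent clamp carryover, tracer recycling, or insulin
pharmacokinetics. Passing recovery tests therefore demonstrates that the
estimators invert the stated models correctly at realistic noise — not that
real data meet those models.

## Problem sizes and reproducibility

The test suite runs cohorts of 12 participants (the study size), a
200-participant single-regimen sweep for estimator bias, 200 replicate
cohorts for the concordance independence null, 1000-metabolite null panels
for moderated-t size, and the full 6^5^ permutation null for the Friedman
check — sizes chosen so the whole suite completes in a few minutes while
keeping Monte-Carlo error well below the tolerances asserted.
`scripts/acceptance.R` re-derives the headline quantities from scratch at
any seed; identical configuration and seed reproduce every output
byte-for-byte, and stage seeds are decorrelated through a double Lehmer
scramble so that nearby master seeds give independent cohorts.
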