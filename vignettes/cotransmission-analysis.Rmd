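---
title: "Decomposing purinergic and cholinergic cotransmission from frequency-response curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing purinergic and cholinergic cotransmission from frequency-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cotrans)
```

## The biological problem and the models

Parasympathetic nerves supplying detrusor (bladder wall) smooth muscle
co-release ATP and acetylcholine (ACh). The two transmitters act over
different stimulation-frequency ranges: nerve-evoked ATP release and the
resulting purinergic (P2X-mediated) contraction dominate at low electrical
field stimulation (EFS) frequencies (1–2 Hz), while cholinergic
(muscarinic) contraction dominates above ~4 Hz. Interventions acting on
presynaptic adenosine A~1~ receptors and the downstream
cAMP/PKA pathway suppress the purinergic limb selectively. Quantifying
that selectivity from isolated-strip experiments is the purpose of this
package.

Three curve families carry the analysis.

**Two-component frequency–response curve** (tension or ATP release):

$$Y(f) = Y_{Lf,max}\,\frac{f^m}{f^{*m}_{Lf}+f^m} +
         Y_{Hf,max}\,\frac{f^m}{f^{*m}_{Hf}+f^m}$$

Each Hill-type component rises from zero to its own maximum
$Y_{max}$, reaching half of it at its half-frequency $f^*$; the exponent
$m$ is shared between components, which keeps the model at five
parameters — with typically eight frequency points per curve, a second
exponent is not identifiable and the printed form of the model uses a
single constant. Components are labelled so that
$f^*_{Lf} \le f^*_{Hf}$. Two derived quantities summarise a fit: the
maximal response $T_{max} = Y_{Lf,max} + Y_{Hf,max}$ and the frequency
$f_{1/2}$ at which the curve reaches $T_{max}/2$, obtained by inverting
the fitted curve (`solve_f_half()`).

**One-component curve** (ACh release): the same Hill form with a single
component ($Y_{max}$, $f_{1/2}$, $m$); ACh data show no second component.

**Percentage-reduction curve**: the frequency-dependent percent reduction
of a response by an intervention,

$$T(f) = T_{Lf} - (T_{Lf}-T_{Hf})\,\frac{f^m}{k^m+f^m},$$

which interpolates from the low-frequency plateau $T_{Lf}$ to the
high-frequency plateau $T_{Hf}$, passing exactly through their midpoint at
$f=k$ for any $m$. This parameterisation follows the stated meaning of the
parameters ($T_{Lf}$ and $T_{Hf}$ as the maximal and minimal reductions);
an alternative printed arrangement of the same bracket would force the
high-frequency plateau to zero and contradict that meaning. The two forms
coincide when $T_{Hf}=0$.

## Fitting

All models are estimated by bounded least squares
(`frfit()`): a deterministic grid of data-driven starting values
(amplitudes from the largest observed response, half-frequencies from the
25th/75th frequency percentiles plus a sub-range start for a component
saturating below the tested range, exponents from {0.5, 1, 2, 4}), each
refined with the Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`), up
to 20 starts. The two-component search is additionally seeded at the
one-component optimum with a zero high-frequency amplitude, which
guarantees the nested ordering $SSE_2 \le SSE_1$ required by the model
comparison.

Numerical choices that matter:

* **Identifiability caps.** Parameters whose defining feature lies outside
  the tested frequency range cannot be estimated, only extrapolated, and
  under proportional noise the raw least-squares optimum then wanders
  along a flat amplitude/half-frequency ridge (we observed fitted
  $T_{max}$ inflated by a factor of two under 10 % noise with permissive
  bounds). Half-frequencies are therefore capped at half the largest
  tested frequency, and the reduction curve's $k$ is additionally kept
  above twice the smallest tested frequency so that $T_{Lf}$ stays
  anchored by data. Amplitudes are bounded by 10 times the largest
  observed value, exponents to [0.2, 10]. With these caps the cohort mean
  of fitted $T_{max}$ is within a few percent of the generating value at
  the default noise level.
* **Tie-breaking.** Multi-start solutions whose SSE differ by less than
  0.1 % are numerically indistinguishable; the least-extrapolating one
  (smallest total amplitude) is kept, deterministically.
* **Convergence.** Relative SSE/parameter tolerances of 10^-13^, at most
  500 iterations per start; fits of identical data are bit-reproducible.
* **Degenerate inputs.** All-zero response vectors (a fully blocked
  preparation) return zero-amplitude parameters flagged `degenerate`
  rather than failing, so blocked conditions flow through cohort
  summaries.

One- versus two-component structure is decided by the extra-sum-of-squares
F test (`compare_models()`), the standard nested-least-squares comparison:
$F = \frac{(SSE_1-SSE_2)/(p_2-p_1)}{SSE_2/(n-p_2)}$, two-component
preferred at $\alpha = 0.05$. Calibration of this test (type-I error
$\le 10\%$ at 5 % noise, near-certain detection of clearly separated
components) is exercised on a 12-point design, where the denominator
degrees of freedom make the test usefully powered.

## Assay calibration and release arithmetic

ATP is assayed by luciferin–luciferase bioluminescence. Luminescence is
linear in concentration on a log~10~–log~10~ plot over a wide range, so
`build_calibration(kind = "loglog")` fits the standards in that space;
inverted concentrations below the detection limit (100 fM for the emulated
system) are floored at the limit and flagged rather than dropped or
imputed — the choice is explicit because sub-detection handling is
otherwise ambiguous. ACh is quantified as total choline (AChE-treated
aliquot) minus free choline, each calibrated linearly; negative
differences are retained with a flag so that cohort averages stay
unbiased. Nerve-mediated net release is the during-EFS minus pre-EFS
concentration divided by preparation wet weight (fmol·µL^-1^·mg^-1^);
tension is likewise weight-normalised (mN·mg^-1^).

Percentage reductions are computed **per preparation and then averaged**.
The two orders of operations differ (a mean of per-preparation ratios is
not the ratio of means), and the per-preparation convention is the one
that matches paired experimental reporting.

## The synthetic cohort generator

No raw per-preparation data are deposited for this kind of study, so the
generator (`draw_cohort()`) emulates the paired design: each preparation
is measured under control and again under an intervention, at
{1, 2, 4, 8, 12, 16, 20, 40} Hz — the stimulation range is 1–40 Hz and
the intermediate points are needed for stable five-parameter fits.

The population truth is anchored to the published cohort summaries:

```{r anchors}
pop <- population_truth()
c(t_max = derive_t_max(pop$tension), f_half = solve_f_half(pop$tension))
eval_two_component(pop$atp, 8)    # ATP release at 8 Hz, fmol/uL/mg
eval_one_component(pop$ach, 20)   # ACh release at 20 Hz, fmol/uL/mg
```

The tension parameters (0.969, 0.7, 1.231, 13.75, m = 2) are the exact
solution of three anchors: $T_{max} = 2.2$ mN·mg^-1^, $f_{1/2} = 5.1$ Hz,
and $f_{1/2} = 7.5$ Hz after scaling the purinergic amplitude to 70 %
(the adenosine effect); the purinergic half-frequency is fixed at the
reported 0.7 Hz. The exponent $m = 2$ makes the curves plateau within the
tested range, as the published force–frequency curves do. The ACh curve
(157.5, 10, m = 3) reproduces 140 fmol·µL^-1^·mg^-1^ at 20 Hz with
release negligible (< 1 % of maximum) at 2 Hz, matching the observation
that no nerve-mediated ACh is recorded below 4 Hz.

Interventions act **multiplicatively on component amplitudes only**
(`intervention_preset()`): the parsimonious mechanism consistent with a
uniform proportional suppression of ATP release across frequencies.
Presets for adenosine, CPA, NECA, cAMPS-Rp, DPCPX (alone and with
adenosine), forskolin and TTX are anchored to the corresponding published
percent reductions; scales of 1 encode "no effect", and the TTX preset
abolishes everything — its during-EFS sample is the pre-EFS sample, so net
release is exactly zero, the operational definition of "nerve-mediated".

Variability has two levels: log-normal per-preparation parameter draws
(CV 25 %, mean-preserving, matching the ~30 % between-preparation spread
of the published $T_{max}$ and $f_{1/2}$), and proportional Gaussian
measurement noise (CV 10 %) on every recorded quantity. The error
structure of the original experiments is not reported; proportional
Gaussian noise reproduces the roughly proportional printed SDs and is a
stand-in to be varied in sensitivity analyses. Seeding is per preparation
(derived from one global seed), so cohorts of different sizes share their
first preparations and all outputs are bit-reproducible.

What the generator does **not** emulate: time-dependent drift and run-down
of preparations, correlated errors across frequencies within a sweep, raw
luminescence kinetics, and any intervention effect on curve *shape*
(half-frequencies and exponents are untouched). Passing tests therefore
show that the pipeline recovers known effects under this idealised error
model, not that it is robust to every feature of real recordings.

## Cohort analysis and reporting conventions

`analyze_cohort()` fits every preparation under every condition, derives
$T_{max}$, $f_{1/2}$ and component amplitudes, and summarises:

* tension and ATP intervention effects as the per-preparation percentage
  reduction **averaged over 1 and 2 Hz** (where the purinergic component
  carries ~97–99 % of the response, so ACh is not confounding);
* ACh effects **at 20 Hz**, near its release maximum; a condition without
  ACh records is marked not-recorded rather than failing, and an ACh fit
  whose amplitude is below twice the residual standard error is marked
  not-quantifiable;
* each condition is compared with the **immediately preceding** condition
  in the chain by paired t test; with three or more chained conditions the
  chain p values are Holm-adjusted and a repeated-measures one-way ANOVA
  (condition within preparation) accompanies them. Holm was chosen over
  Bonferroni because it is uniformly more powerful at the same error
  guarantee; which parametric post hoc the original analyses used is not
  stated, so the correction is named in the output. Sphericity
  corrections are omitted (condition counts are small).
* pooled across interventions, the association between low-frequency
  tension reduction and ATP-release reduction is a Pearson correlation
  (`correlate_reductions()`).

Sample sizes for paired designs come from `required_n()`, the smallest n
for a two-sided paired t test at the requested power (noncentral-t
calculation; 80 % power at a unit standardised effect needs n = 10).

## Problem sizes, and what the acceptance analysis shows

The package's own end-to-end run (`scripts/acceptance.R`) simulates an
adenosine cohort of n = 12 preparations plus four further intervention
cohorts of n = 6, analyses them, and reports cohort $T_{max}$ and
$f_{1/2}$, low-frequency tension and ATP reductions, the 20 Hz ACh
change, the fitted reduction-curve plateau, the pooled tension–ATP
reduction correlation and the paired-design sample size. The test suite
additionally uses 20-seed replicate cohorts, 200-replicate model-selection
simulations and 2000-replicate null calibrations; these sizes were chosen
to make Monte-Carlo error small relative to the tolerances tested.

## Known limitations

* **The derived-parameter significance pattern is information-limited.**
  Scaling only the purinergic amplitude necessarily lowers true $T_{max}$
  (by ~13 % under the adenosine preset) while shifting $f_{1/2}$ by
  2.4 Hz. At 10 % measurement noise on an eight-point 1–40 Hz design, the
  Cramér–Rao bound for a single fit is ≈ 0.42 mN·mg^-1^ on $T_{max}$ and
  ≈ 3.3 Hz on $f_{1/2}$; a paired n = 12 cohort therefore detects the
  $f_{1/2}$ shift in only roughly half of replicate cohorts, and
  occasionally flags the $T_{max}$ drop. The published pattern
  ($T_{max}$ unchanged, $f_{1/2}$ clearly increased) is recovered
  qualitatively in most cohorts but not near-universally; reproducing it
  reliably would require either lower measurement noise than the
  generator's default or an intervention model that also compensates the
  high-frequency component.
* $T_{Lf}$ of a fitted reduction profile is an extrapolation to $f = 0$;
  with noisy profiles it can overshoot when the data favour a steep early
  transition, even with the identifiability caps.
* Whether the exponent $m$ should be constrained equal across the control
  and intervention fits of one preparation is not specified anywhere; the
  fits here are independent, which is the weaker assumption.
* The analysis assumes complete paired tables (every preparation measured
  under every condition); missing cells are an error, not imputed.
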