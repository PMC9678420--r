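# cotrans

Decomposition of purinergic and cholinergic cotransmission from
nerve-mediated frequency–response curves.

## What this is for

Parasympathetic nerves supplying detrusor (bladder) smooth muscle
co-release ATP and acetylcholine. Contraction evoked by electrical field
stimulation (EFS) of isolated strips is purinergic at low stimulation
frequencies (1–2 Hz) and cholinergic at higher frequencies, and
interventions on presynaptic adenosine A<sub>1</sub>/cAMP/PKA signalling
suppress the purinergic limb selectively. `cotrans` is for experimenters
analysing this kind of data: it fits the curve models that separate the
two limbs, calibrates the release assays, and produces the paired cohort
summaries and statistics such studies report.

The core models, fitted by multi-start bounded Levenberg–Marquardt least
squares (`frfit()`):

* **Two-component curve** (tension, ATP release):
  `Y(f) = Y_Lf,max · f^m/(f*_Lf^m + f^m) + Y_Hf,max · f^m/(f*_Hf^m + f^m)`,
  with derived maximal response `T_max = Y_Lf,max + Y_Hf,max` and
  half-maximal frequency `f_1/2` (by curve inversion).
* **One-component curve** (ACh release):
  `Y(f) = Y_max · f^m/(f_1/2^m + f^m)`.
* **Percentage-reduction curve** (intervention effect vs frequency):
  `T(f) = T_Lf − (T_Lf − T_Hf) · f^m/(k^m + f^m)`.

One- vs two-component structure is decided by the extra-sum-of-squares F
test (`compare_models()`). Assay support covers log–log bioluminescence
(ATP) and linear choline (ACh) calibration with detection-limit flooring,
choline-difference ACh quantification, and weight-normalised pre/during-EFS
net release. Paired statistics: paired t, repeated-measures one-way ANOVA
with Holm post hocs, Pearson correlation, and paired power/sample-size
calculation. A seeded generator (`draw_cohort()`) simulates paired
control/intervention cohorts with realistic dispersion for end-to-end
testing, since raw per-preparation data for such studies are not deposited.

## Worked example

Simulate a paired adenosine cohort (n = 12 preparations, 1–40 Hz grid)
and analyse it:

```r
library(cotrans)
coh <- draw_cohort("adenosine", n = 12, seed = 4)
an <- analyze_cohort(coh$tension, coh$release)
an
#> Cohort analysis: 12 preparations, conditions: control -> adenosine
#>
#> Force-frequency parameters (T_max, f_1/2):
#>  condition  n t_max_mean t_max_sd t_max_p f_half_mean f_half_sd f_half_p reference
#>    control 12       2.20    0.415      NA        5.70      2.94       NA        NA
#>  adenosine 12       2.09    0.548   0.495        8.92      4.77   0.0181   control
#>
#> Percentage reductions (tension/ATP at low frequency, ACh at 20 Hz):
#>  condition reference  n tension_redn_mean tension_redn_sd tension_p atp_redn_mean atp_redn_sd    atp_p ach_redn_mean ach_redn_sd ach_p ach_recorded
#>  adenosine   control 12              30.8             8.4   2.1e-06          35.4         6.4 3.74e-08         -1.37        26.9 0.732         TRUE
```

Reading the output: the fitted maximal tension `T_max` is unchanged by
adenosine (2.20 → 2.09 mN·mg⁻¹, paired p = 0.50) while the half-maximal
frequency `f_1/2` shifts upwards (5.70 → 8.92 Hz, p = 0.018) — the
signature of a selectively suppressed low-frequency component. Directly
measured, adenosine reduces tension at 1–2 Hz by 30.8 ± 8.4 % and ATP
release by 35.4 ± 6.4 % (both p < 10⁻⁵), with no effect on ACh release at
20 Hz (−1.4 ± 26.9 %, p = 0.73): ATP release is suppressed, ACh release is
spared.

A thin command-line wrapper covers the same pipeline
(`inst/cli/cotrans`): `simulate`, `calibrate`, `fit`, `analyze`, `report`.

```sh
Rscript inst/cli/cotrans simulate --preset adenosine --n 12 --seed 1 --out-dir run1
Rscript inst/cli/cotrans analyze --tension run1/tension.csv --release run1/release.csv --out-dir run1
Rscript inst/cli/cotrans report --dir run1
```

Outputs are plain CSV/JSON (`fits.csv`, `table2.csv`, `table3.csv`,
`correlation.json`, `run_record.json`), byte-identical across reruns with
the same seed, and every summary value is recomputable from the
per-preparation `fits.csv`.

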