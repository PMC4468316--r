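---
title: "Methods: thermoregulatory analysis of graded treadmill exercise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermoregulatory analysis of graded treadmill exercise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoex)
```

## The problem

During graded exercise most metabolic energy is released as heat, and the
body's main defence is evaporation of sweat. Whether constitutionally
different groups of people mount different sweating responses to the *same*
graded stimulus is a question that requires careful normalization: a larger
subject walking the same Bruce-protocol stage performs more external work,
produces more heat, and would sweat more even if their thermoregulatory
sensitivity were identical. `thermoex` implements the full analysis chain for
such a study: breath-by-breath indirect calorimetry and ventilated-capsule
sweat traces in, per-minute energetics and normalized sweat rates out, with
nonparametric per-minute group comparisons that tolerate the progressive
subject dropout inherent in exercise to exhaustion.

The package is organised as a pipeline of small, separately testable stages
(ingest → cohort → anthropometry → energetics → sweat → stats), orchestrated
by `analyze_study()` / `run_pipeline()` and driven by the numbered scripts
under `analysis/`. A synthetic-data module generates complete studies with
the statistical structure the analysis assumes, so every stage — including
the statistics — runs and is tested without any external data.

## The energetics model

**External workload.** On a treadmill at grade $g$ (fraction), belt speed $v$
(m·min⁻¹) and body weight $m$ (kg), the vertical displacement is $g\,v\,m$
(kg·m·min⁻¹) and the external workload is

$$W_e \,[\text{Watt·min}] = \frac{g\,v\,m}{6.12}.$$

The divisor is the conventional kg·m·min⁻¹ → Watt conversion $60/g_0 =
60/9.80665 = 6.118$, printed and used here as 6.12. The default schedule is
the standard Bruce protocol (3-minute stages from 1.7 mph/10% to
6.0 mph/22%, speeds converted at 26.8224 m·min⁻¹ per mph); it is a
configuration object (`bruce_protocol()`) and can be overridden.

**Metabolic energy expenditure.** From oxygen uptake $\dot VO_2$ (litres
within the minute) and the respiratory quotient RQ, the energy equivalent of
oxygen interpolates between the fat-only and carbohydrate-only limits:

$$M_{ee} \,[\text{Watt·min}] = \dot VO_2 \left[\frac{RQ-0.7}{0.3}\,21.13 +
\frac{1-RQ}{0.3}\,19.62\right] \times 16.67.$$

The expression is affine in RQ and linear in $\dot VO_2$; at RQ = 0.7 and
RQ = 1.0 it reproduces the pure-substrate equivalents (19.62 and
21.13 kJ·L⁻¹). Near exhaustion RQ exceeds 1 because of hyperventilation;
values are clamped to $[0.7, 1.0]$ before evaluation by default (the
physiologic convention — outside that range the interpolation leaves its
calibration), with `clamp_rq = FALSE` available for sensitivity analysis.

**Heat production and efficiency.** $H_{prod} = M_{ee} - W_e$ per minute;
metabolic efficiency is $100\,W_e/M_{ee}$ (%). A negative $H_{prod}$
(efficiency above 100%) indicates a data problem and is returned with a
warning rather than silently repaired.

**Temperature-increment load.** One kilocalorie (4186.8 J / 60 s = 69.78
Watt·min) of retained heat raises one kilogram of body water by 1 °C, so the
heat produced beyond resting expenditure in a minute implies

$$T_{inc} \,[^\circ\mathrm{C}] = \frac{H_{prod} - M_{ee}^{rest}}
{69.78 \times \text{body water [kg]}}.$$

Two conventions here were genuinely open and are the package's own choices:

* $T_{inc}$ is treated as **cumulative** (a running sum of per-minute
  increments). The per-minute increments are additive contributions to one
  stored-heat pool, and only the cumulative reading produces the
  monotonically rising load a graded bout implies.
* Per-minute increments can be slightly **negative** in the first instants
  (exercise $H_{prod}$ still near resting $M_{ee}$); they are floored at 0 by
  default (`floor_tinc = FALSE` disables this) so the cumulative value keeps
  its interpretation as an accumulated heat load.
* The resting $M_{ee}$ is Eq.-style evaluation of the minute-0 record: the
  steady-state mean of the final 60 s before exercise start.

## Per-minute aggregation

Instruments report at a nominal 20-s cadence. Exercise minute $m$ collects
samples with $t \in ((m-1)\cdot 60,\ m\cdot 60]$ s (half-open bins; the
binning edge convention is ours, as vendor exports do not define one). A
trailing partial minute is kept only if it contains at least 2 of the 3
expected samples (≥ 40 s of data): exhaustion terminates exercise mid-minute
for most subjects, and discarding all partial minutes would bias
late-exercise means downward. Aggregation is mean-preserving over full
minutes and the identity on per-minute-constant traces — both are tested
properties.

## Cohort rules

Constitutional type probabilities (TE/SE/SY) come from an external diagnostic
tool and are used as given (they need not sum to 1). A subject is classified
to the type with the highest score unless the highest score is below 0.40 or
the gap between the highest and the middle score is below 0.05, in which case
they are excluded (`low_top_score` / `ambiguous_margin`). "Middle" is
interpreted as the median of the three scores; a tied maximum yields a zero
margin and exclusion.

The sweating quality filter removes subjects whose early-exercise sweating
showed an abrupt increase and decrease rather than a steady rise. The
published description is qualitative; the operationalization here is: within
the first half of exercise, a minute-to-minute rise exceeding
$\theta_{rise}$ followed within two minutes by a fall exceeding
$\theta_{fall}$, with both thresholds defaulting to 0.3 mg·cm⁻²·min⁻¹ and
exposed in the configuration. Exclusion precedence is fixed (score rules →
sweat QC → missing VO2) and each excluded subject carries exactly the first
failing reason.

## Sweat-rate conversion and normalization

Local sweat rate (LSR, mg·cm⁻²·min⁻¹, ventilated capsule over 1 cm²) is
extrapolated to a whole-body rate WSR = LSR × BSA(cm²), with BSA from the
Du Bois formula $0.007184\, w^{0.425} h^{0.725}$ (the classical constants;
no alternative formulas are offered). Sweat rates are normalized by the
per-minute sweat-inducing factors $W_e$, $H_{prod}$ and cumulative $T_{inc}$;
minutes where the denominator is ≤ ε (default 10⁻⁶) are masked rather than
divided, because at exercise onset the factors start near zero and the ratio
diverges. Normalization uses the **per-minute** factors, matching the
"for each minute" framing of the analysis; per-bout totals are available from
the totals table for anyone preferring that convention. Per-minute increments
(this minute minus the previous) are computed for all raw and normalized
sweat series; the first exercise minute's increment is undefined unless a
baseline exists, and increments telescope exactly.

## Statistics

Scalar summaries (exercise time, total $W_e$, total $M_{ee}$, efficiency) are
compared across the three types within each sex by one-way ANOVA with Tukey
HSD post hoc (through `stats::aov`/`TukeyHSD`).

Time-indexed outcomes cannot use repeated-measures models because exercise
times differ between subjects; instead, at **each exercise minute** the
subjects still exercising are compared by the Kruskal-Wallis rank-sum test
(tie-corrected, through `stats::kruskal.test`), followed on a significant
omnibus result by the Nemenyi all-pairs post hoc on mean ranks. The Nemenyi
test is implemented in-package: the studentized-range form
$q_{ij} = |\bar R_i - \bar R_j| / \sqrt{\tfrac{N(N+1)}{12}(\tfrac1{n_i} +
\tfrac1{n_j})}$ referred to $Q_{k,\infty}$ when the pooled data are tie-free,
and the chi-square form (the squared standardized difference divided by the
tie-correction factor $C = 1 - \sum(t^3 - t)/(N^3 - N)$, referred to
$\chi^2_{k-1}$) when ties exist; the variant used is recorded in the output,
and both are cross-checked in the test suite against a label-permutation
oracle of the family-wise adjusted p-value.

Pairwise outcomes are encoded as the letters used in time-course figures:
`a` TE ≠ SE, `b` TE ≠ SY, `c` SE ≠ SY, at α = 0.05. Minutes where any group
has fewer than `min_n = 2` subjects are reported untested (late-exercise
comparisons become meaningless as groups thin to a single subject). **No
multiplicity correction is applied across minutes**, consistent with the
per-minute descriptive framing; the comparison table records every omnibus
and pairwise p-value so readers can apply their own.

## The synthetic-data generator

The generator exists so that the full pipeline — including its statistical
operating characteristics — is testable end to end. It emulates:

* **Cohort structure.** Six sex-by-type cells with the analyzed study's
  sizes (62/59/57 males, 46/40/40 females; 304 total) and anthropometric
  means/SDs; sampling is truncated-normal (±4 SD, floored at physiologic
  minima), fat-free mass is derived as weight − fat mass so the composition
  identity holds exactly, and exercise durations are sampled per subject and
  rounded to the nearest 20 s so attrition interacts realistically with
  partial-minute handling. Exercise-time calibration: TE males 11.1 (1.1)
  min, SY males 12.4 (1.4), TE females 9.8 (1.3), SY females 10.4 (1.1);
  SE-cell means are not printed in the source material and are set to 12.0
  (1.3) and 10.0 (1.2) — between the other types, with SE males longer than
  TE males — as the package's own calibration choice.
* **Exclusion bookkeeping.** On top of the 304, exactly 237 extra subjects
  receive score vectors that fail the classification rules (alternating
  low-top and ambiguous-margin constructions) and exactly 9 fail downstream
  (5 with an abrupt sweat spike planted in exercise minute 3, 4 with no
  breath trace), reproducing the 550 → 313 → 304 audit trail
  deterministically.
* **Traces.** VO2 rises mono-exponentially (τ = 30 s) within each stage
  toward a stagewise asymptote climbing to the subject's peak; RQ drifts
  linearly 0.80 → 1.05; LSR is flat until a per-site onset (chest 4 min,
  back 3.5 min) then rises linearly at 0.06 mg·cm⁻²·min⁻¹ per minute times a
  group multiplier TE 1.4 > SY 1.0 > SE 0.7, the ordering the statistics
  must recover. All observed at 20 s with Gaussian noise (VO2 0.05 L·min⁻¹,
  RQ 0.02, LSR 0.02).
* **Fitness ordering.** Peak VO2 is sampled in mL·kg⁻¹·min⁻¹ (TE males 38,
  SE 52, SY 48; females 34/46/44; SD 4), preserving the study's ordering
  (TE lowest). The source table prints VO2max values of 532–758 under a
  mL·kg⁻¹·min⁻¹ label, which is internally inconsistent with that unit; the
  pipeline implements the stated unit and the generator uses physiologic
  values rather than calibrating to the inconsistent printed ones.

What the generator does **not** emulate: core/skin temperature, heart rate,
sweat-gland recruitment, within-subject serial correlation of measurement
noise, device drift, or any correlation between fitness and sweating beyond
the group structure. Passing tests therefore demonstrate that the pipeline's
arithmetic, bookkeeping and inferential machinery behave as specified under
the assumed data-generating process — not that the physiological conclusions
would replicate on new human data.

## Numerical choices and degenerate inputs

* RQ clamped to [0.7, 1.0] (switchable); negative per-minute $T_{inc}$
  floored at 0 (switchable, recorded in the configuration).
* Efficiency at $M_{ee} = 0$ is undefined and returned as `NA`, never 0.
* Normalization mask threshold ε = 10⁻⁶ in denominator units.
* A fully tied Kruskal-Wallis sample returns H = 0, p = 1; a zero-variance
  ANOVA returns a degenerate-case signal rather than an error or a fake p.
* Ties in the Nemenyi test switch the reference distribution (see above);
  the pipeline's sweat data make ties rare but masked minutes common, and
  masked values are dropped before ranking.
* All randomness flows from a single mandatory seed; two runs of the same
  specification produce byte-identical study bundles and reports.

## Problem sizes used in the tests

The unit suites run on small hand-checkable fixtures. The end-to-end suites
use the full 550-subject synthetic study (one realization), a 1000-replicate
null simulation for the type-I error of the per-minute test (n = 20 per
group), and a 500-replicate power simulation for a +2 pooled-SD elevation at
n = 40 per group — sizes chosen to keep Monte-Carlo error well below the
margins being asserted while the whole suite runs in about a minute.

## Known limitations

* The sweat-QC thresholds operationalize a qualitative published rule; on
  real data they should be tuned against visual review of flagged traces.
* $W_e$ for a partial final minute uses the full minute's stage speed/grade,
  slightly overestimating work in the exhaustion minute.
* The Nemenyi chi-square variant is conservative for small samples with many
  ties; the comparison table records the variant used per minute.
* The pipeline's group labels are cohort strata; nothing in the statistics
  track is specific to constitutional typology.
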