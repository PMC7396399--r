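---
title: "Models and methods behind petquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind petquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

petquant implements the full quantitative chain of a first-in-human brain
PET radioligand evaluation: arterial input construction, compartmental and
graphical estimation of the total distribution volume, test–retest
reliability statistics, and whole-body internal dosimetry. This vignette
explains the models, the tunable parameters, the numerical machinery, and
the design decisions — including what the synthetic-data generator does and
does not emulate.

## The kinetic model

The tracer is assumed to exchange between metabolite-corrected arterial
plasma $C_p$ and one or two serial tissue compartments:

$$\frac{dC_1}{dt} = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2, \qquad
  \frac{dC_2}{dt} = k_3 C_1 - k_4 C_2,$$

with $K_1$ in mL·cm$^{-3}$·min$^{-1}$ and $k_2, k_3, k_4$ in min$^{-1}$.
The measured frame value is the *average* of
$C_\mathrm{model} = (1-v_B)(C_1+C_2) + v_B C_{wb}$ over the frame interval,
not a midpoint sample: with 20-s early frames the distinction is material.
$v_B$ is fixed at 0 by default — the study design this package follows
quantified without a blood-volume term — but can be set to a fixed value.

The primary outcome is the total distribution volume,
$V_T = K_1/k_2$ (one-tissue) or $V_T = (K_1/k_2)(1 + k_3/k_4)$
(two-tissue), also estimated as the late-time slope of the Logan plot
$\int_0^t C_T/C_T(t)$ versus $\int_0^t C_p/C_T(t)$ over frames with
mid-time $\ge t^*$.

### Numerical solution

The tissue impulse response of the two-tissue system is a sum of two
exponentials $\phi_1 e^{-\theta_1 t} + \phi_2 e^{-\theta_2 t}$ with
$\theta_{1,2}$ the roots of $s^2 + (k_2+k_3+k_4)s + k_2 k_4$. Tissue curves
are computed by convolving this response with the input on a regular grid
(step 1/60 min) using a recursive update that is *exact* for a
piecewise-linear input; small $\theta \Delta t$ uses series expansions of
the step integrals to avoid cancellation. Frame averages come from the
interpolated cumulative integral at the frame edges. An independent
Runge–Kutta solution (deSolve) serves as the oracle in the test suite and
agrees to $<0.05\%$ per frame; the two routes are never collapsed.

### Fitting, weights, and quality control

Weighted least squares
$\sum_i w_i (y_i - \hat y_i)^2$ is minimized with bounded
Levenberg–Marquardt (minpack.lm) in *log-parameter* space, where the
positive rate constants are well scaled. Defaults:

* weights: $w_i \propto$ frame duration, normalized to mean 1 (`uniform`
  available). Duration weighting is inverse-variance-correct for the
  generator's default additive, duration-scaled noise model.
* bounds: all rates in $[10^{-6}, 5]$.
* initialization: a one-tissue fit seeds the two-tissue fit with
  $k_3 = k_4 = 0.05$; three deterministic log-scale perturbations restart
  the optimizer when the primary start converges onto a parameter bound.
* `AIC` $= N\ln(\mathrm{WRSS}/N) + 2k$ (least-squares form), and the nested
  F-test $F = \frac{(\mathrm{WRSS}_1-\mathrm{WRSS}_2)/(df_1-df_2)}
  {\mathrm{WRSS}_2/df_2}$, compare the two models.
* Logan $t^* = 30$ min, configurable; ordinary least squares on the
  transformed points.

A fit that terminates on a rate-constant bound (typically $k_2$ or $k_4$
collapsing to the lower bound) has no physiological interpretation and an
unbounded $V_T$; it is flagged non-converged and excluded from downstream
tables. In addition every converged fit carries a delta-method percent
standard error of $V_T$ (computed in log space, where
$\log V_T = q_1 - q_2 + \log(1+e^{q_3-q_4})$ is locally linear);
reliability and concordance tables exclude fits with $V_T$ %SE above 50%.
This mirrors routine kinetic-modelling QC: slow two-tissue kinetics in a
123-min window leave $V_T$ only marginally identified, and at realistic
noise a few percent of fits land on a ridge where $V_T$ is arbitrary.

### Detectability of the second compartment

For kinetics at the magnitudes used here, the best one-tissue fit misses
the true two-tissue curve by only a few percent RMS. Model preference by
AIC/F-test therefore degrades quickly as frame noise approaches that
misfit scale: the packaged simulation checks that the generating two-tissue
model is preferred in $>80\%$ of fits at 2% per-frame noise, and the test
documentation notes that the preference fraction collapses at substantially
higher noise. This is a genuine property of the estimation problem, not of
the optimizer.

## Arterial input

The input function is piecewise linear through the metabolite-corrected
plasma knots (linear from (0, 0) to the first sample), with a
mono-exponential tail fitted log-linearly through the last three knots —
kinetic integration extends past the last blood sample to the last frame
mid-time, so an extrapolation rule is part of the definition. A constant
delay parameter exists (default 0). The parent fraction uses a Hill form
$pf(t) = 1 - a t^b/(t^b + c)$ with $pf(0)=1$ enforced structurally; it is
monotone, bounded in $[1-a, 1]$, and robust to fit with the nine metabolite
samples of the study design. The free fraction is the mean of per-replicate
$C_\mathrm{free}/C_\mathrm{total}$ ratios divided by the same quantity on
protein-free controls (membrane-binding correction).

## Reliability statistics

$\mathrm{TRV} = |x_2-x_1|/((x_1+x_2)/2)\times 100$ per subject, summarized
as the across-subject mean and SD per region (not the TRV of means), and
the one-way random-effects ICC
$(\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+(n-1)\mathrm{MSW})$ with $n = 2$
sessions. Negative ICCs are reported as computed. Subjects missing a
session, or whose fit failed QC in a region, are excluded pairwise for that
region only. Note that for a generative model with between-subject variance
$\sigma_b^2$ and within-subject variance $\sigma_w^2$ the population ICC is
$\sigma_b^2/(\sigma_b^2+\sigma_w^2)$, because $E[\mathrm{MSB}] =
n\sigma_b^2 + \sigma_w^2$; the recovery tests use this correctly derived
truth.

## Dosimetry

Organ retention (decay-corrected %ID versus hours) is fitted with
$\sum_i a_i e^{-\lambda_i t}$, $a_i, \lambda_i \ge 0$, the number of terms
(1–3) selected by AIC; $\lambda_i = 0$ describes a plateau, so
extrapolation beyond the last session decays only physically — the
conservative standard. Residence times re-apply physical decay
analytically, $\tau = \sum_i a_i/(\lambda_i + \lambda_\mathrm{phys})/100$
hours with $\lambda_\mathrm{phys} = \ln 2 / T_{1/2}$
($T_{1/2} = 109.77$ min for fluorine-18, so a whole body without excretion
has $\tau = T_{1/2}/\ln 2 = 2.6394$ h). Voided urine is added back to the
bladder VOI curve at each imaging time (measured-data integration, no
dynamic voiding model). Absorbed doses are
$D_\mathrm{target} = \sum_\mathrm{source} \tau_\mathrm{source}
S(\mathrm{target} \leftarrow \mathrm{source})$; the S-value matrix is an
input file and the repository ships only a clearly-labelled synthetic toy
matrix — phantom S-values are deliberately out of scope.

The effective dose applies ICRP-60 tissue weighting factors (stored in an
editable YAML file so ICRP-103 can be swapped in): gonads 0.20; red
marrow, colon, lungs, stomach 0.12; bladder, breasts, liver, esophagus,
thyroid 0.05; skin and bone surface 0.01; remainder 0.05. With an
OLINDA-style adult male organ list, testes stand in for gonads, the thymus
for the esophagus, and the colon is composed as 0.57·ULI + 0.43·LLI (mass
split). The remainder contribution is the mass-weighted mean dose of the
remainder organs, with the ICRP-60 splitting rule — when one remainder
organ exceeds every named organ, half the remainder weight goes to it and
half to the mass-weighted mean of the rest; in the bundled published organ
table the pancreas triggers this rule. These conventions are the reason a
±5% band is the right standard for reproducing a published effective dose:
the exact remainder treatment of legacy dosimetry software is unpublished.

## The synthetic-data generator

The generator emulates the study conditions: a 123-min acquisition with the
34-frame schedule (20 s × 9, 1 min × 3, 3 min × 5, 6 min × 17); arterial
sampling at 1–120 min (14 samples) with metabolite samples at nine times;
a parent fraction of ~0.70 at 60 min; twelve gray-matter regions with
two-tissue kinetics at published test-session magnitudes; test–retest
sessions 5–19 days apart with log-normal between-subject (default CV 10%)
and within-subject (default CV 5%) parameter variation; duration-scaled
Gaussian frame noise (default CV 5% at a 6-min reference frame, SD
$\propto 1/\sqrt{\mathrm{duration}}$; a multiplicative per-frame-CV option
exists); and a 4-session whole-body protocol with liver-dominant uptake,
rising hepatobiliary organs, ~10 %ID urinary excretion, and a remainder
compartment closing the activity balance at exactly 100 %ID.

Two calibration decisions deserve record:

* **Regional parameters.** Published per-region *means* of
  $K_1, k_2, k_3, k_4$ do not compose to the published mean $V_T$ (the
  mean of per-subject ratios is not the ratio of means). The generator
  keeps the published $K_1, k_3, k_4$ means and derives
  $k_2 = K_1 (1 + k_3/k_4)/V_T$ so that each region's macro-parameter
  equals the published mean $V_T$ — the primary outcome anchors the
  calibration.
* **Input truth is the sampled input.** Each session's TACs are simulated
  from the input function *built from that session's generated blood
  samples* under the standard evaluation rule, not from the underlying
  dense analytic curve. Blood-sampling noise thus propagates into the
  outcome measures exactly as in the real analysis chain, and a noiseless
  cohort pushed through the full pipeline returns the generating $V_T$
  identically. The plasma amplitude and decay fractions are calibrated so
  the whole-brain curve peaks near SUV 1.8 around 30 min.

What the generator does **not** emulate: scanner resolution and
point-spread effects (the study mixed two PET systems), partial-volume
effects, attenuation/scatter artifacts, plasma-to-whole-blood ratio
dynamics, delay/dispersion of the arterial line, and realistic
heteroscedastic count statistics beyond the two simple noise models.
Passing tests on synthetic data therefore demonstrate correctness of the
estimation chain and its statistical behaviour under the stated noise
models — not performance on real scanner data.

## Problem sizes and runtime choices

The test suite and acceptance script use cohorts of 3–8 subjects, 100
replicate fits for noisy-recovery and concordance experiments, two 8-subject
cohorts for the time-stability trend, 400-cohort Monte-Carlo loops for the
pure-statistics recoveries, and 1000 random datasets for the formula
oracles. These sizes give stable Monte-Carlo estimates for every asserted
band while keeping a full run to a few minutes; all stochastic routines
take explicit seeds, and generators never disturb the caller's RNG stream.

## Known limitations

* Per-subject results of the underlying study are not reproducible — the
  subject-level data are unpublished; only cohort-level summaries and
  method properties are checked.
* The delay parameter of the input function is accepted but not fitted;
  no dispersion correction is implemented.
* $v_B$ is fixed, not estimated; basis-function and reference-tissue
  estimators are out of scope.
* The bundled S-matrix is synthetic; reproducing published per-organ doses
  from raw residence times requires the user's phantom S-values.
* The retention fitter assumes monotone-decaying (or plateau) kinetics per
  exponential term; organs with pronounced uptake phases rely on the
  sum-of-exponentials flexibility rather than explicit rise terms.
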