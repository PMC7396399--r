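# petquant

Quantitative analysis of first-in-human brain PET radioligand studies:
kinetic quantification of the total distribution volume, test–retest
reliability statistics, and whole-body internal dosimetry. The package was
built around the evaluation of an <sup>18</sup>F-labelled BACE1
(beta-secretase 1) radioligand — a tracer without a reference region, whose
quantification therefore rests on a metabolite-corrected arterial input
function — but every stage is generic for bolus-injection PET tracers with
compartmental kinetics.

## What it computes

**Arterial input.** Measured plasma samples are corrected for
radiometabolites with a Hill-type parent-fraction model
`pf(t) = 1 − a·t^b/(t^b + c)` (so `pf(0) = 1`), interpolated piecewise
linearly, and extrapolated beyond the last sample with a mono-exponential
tail. The plasma free fraction is `f_P = C_free/C_total`, corrected for
membrane binding measured on protein-free controls.

**Kinetics.** Regional time–activity curves (TACs) are fitted with the one-
and two-tissue compartment models

    dC1/dt = K1·Cp − (k2 + k3)·C1 + k4·C2
    dC2/dt = k3·C1 − k4·C2

by weighted nonlinear least squares, and with Logan graphical analysis. The
primary outcome is the total distribution volume, `V_T = K1/k2` (1TCM) or
`V_T = (K1/k2)(1 + k3/k4)` (2TCM), or the late-time Logan slope. Model
selection uses `AIC = N·ln(WRSS/N) + 2k` and the nested F-test; a
time-stability analysis refits on truncated data (63–123 min in 12-min
steps).

**Reliability.** Test–retest variability
`TRV(%) = |PET2 − PET1| / ((PET1 + PET2)/2) × 100` and the one-way
intraclass correlation `ICC = (s_b² − s_w²)/(s_b² + (n−1)·s_w²)` are
computed per region and for AUC-based diagnostics (gray-matter AUC, input
AUC, their ratio, f_P).

**Dosimetry.** Whole-body organ curves in percent injected dose
(`%ID = conc × volume / injected dose × 100`, voided urine added back to
the bladder) are fitted with sums of exponentials; residence times are
`τ = Σ aᵢ/(λᵢ + λ_phys)/100` hours; absorbed doses are the S-value
matrix–vector product; the effective dose applies ICRP-60 tissue weighting
with the standard adult-male surrogates (testes for gonads, thymus for the
esophagus, colon as 0.57·ULI + 0.43·LLI) and the remainder splitting rule.

**Synthetic data.** A generator produces arterial inputs, test–retest
cohorts (12 gray-matter regions, 34-frame 123-min schedule, log-normal
between/within-subject parameter variation, duration-scaled frame noise)
and 4-session whole-body biodistributions with exact activity conservation
— all pure functions of a spec and a seed.

## Worked example

```r
library(petquant)

# noiseless synthetic arterial input at the study's 14 sample times
blood <- gen_input(input_spec(noise_cv = 0), seed = 11)
input <- build_input(blood$plasma, blood$pf_model)

# simulate an anterior-cingulate TAC at the default regional kinetics,
# then recover the parameters
reg <- default_regions()
acc <- kinetic_params(reg$K1[10], reg$k2[10], reg$k3[10], reg$k4[10])
tc  <- simulate_tac(acc, input, frame_schedule(), region_id = "ACC")
fit_compartment(tc, input, model = "2tcm")
#> <kinetic_fit> ACC 2tcm: K1=0.15 k2=0.1551 k3=0.445 k4=0.081 VT=6.28 AIC=-2169

logan_vt(tc, input, t_star = 30)$vt
#> 6.265  (slight underestimation of the compartmental V_T, as expected)

# effective dose from a published per-organ dose table (uSv/MBq)
dd <- read.csv(system.file("extdata", "fih_organ_doses.csv",
                           package = "petquant"), comment.char = "#")
doses <- setNames(dd$mean, dd$organ)
effective_dose(doses[setdiff(names(doses),
                             c("effective_dose", "total_body"))])$effective_dose
#> 25.36  (published cohort value: 24.7 +- 0.8)
```

The recovered `V_T = 6.28` equals the generating macro-parameter exactly on
noiseless data; the Logan slope sits ~0.2% below it. The effective dose of
25.4 µSv/MBq agrees with the published 24.7 ± 0.8 µSv/MBq within the
ambiguity of the unpublished remainder-organ conventions.

A command-line wrapper is installed under `inst/cli/petquant`:

```sh
Rscript inst/cli/petquant simulate cohort --n 8 --seed 7 --out fixtures/
Rscript inst/cli/petquant quantify --dir fixtures/ --out results/
Rscript inst/cli/petquant simulate biodistribution --seed 7 --out wb/
Rscript inst/cli/petquant dose --dir wb --out dose_out/
```

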