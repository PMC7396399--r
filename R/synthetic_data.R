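# Synthetic-data generators: arterial input functions, brain kinetics
# cohorts with test-retest structure, and whole-body biodistributions.
# All generators are pure functions of (spec, seed). Defaults emulate the
# study conditions of a first-in-human brain PET examination of a BACE1
# radioligand: a 123-min acquisition (34 frames), 14 manual arterial
# samples, a parent fraction near 0.70 at 60 min, regional two-tissue
# kinetics at published magnitudes, and a 6.1-h whole-body protocol with
# liver-dominant uptake and ~10 %ID urinary excretion.

# Published test-session two-tissue means per gray-matter region: K1
# (mL/cm^3/min), k3, k4 (1/min), and mean VT (mL/cm^3). k2 is derived from
# the macro-formula k2 = K1*(1 + k3/k4)/VT so that each region's VT equals
# the published mean VT (parameter means alone do not compose to mean VT).
.region_table <- function() {
  df <- data.frame(
    region = c("CERCX", "CAU", "PUT", "THA", "LFC", "LTC",
               "HIP", "LOC", "LPC", "ACC", "PCC", "AMG"),
    K1 = c(0.202, 0.116, 0.159, 0.157, 0.154, 0.163,
           0.162, 0.167, 0.165, 0.150, 0.203, 0.132),
    k3 = c(0.718, 0.561, 0.625, 0.454, 0.595, 0.629,
           0.304, 0.518, 0.607, 0.445, 0.854, 0.540),
    k4 = c(0.085, 0.170, 0.129, 0.079, 0.168, 0.087,
           0.038, 0.110, 0.157, 0.081, 0.065, 0.051),
    vt = c(4.23, 4.56, 5.78, 5.13, 5.16, 5.67,
           5.28, 5.11, 5.23, 6.28, 5.44, 6.00)
  )
  df$k2 <- df$K1 * (1 + df$k3 / df$k4) / df$vt
  df
}

#' Default regional kinetic parameters of the synthetic cohort
#'
#' Twelve gray-matter regions with two-tissue rate constants at the
#' magnitudes of the first-in-human test session; `k2` is derived so the
#' macro-formula V_T matches the published regional mean V_T.
#'
#' @return Data frame with columns `region`, `K1`, `k2`, `k3`, `k4`, `vt`.
#' @export
default_regions <- function() {
  .region_table()[, c("region", "K1", "k2", "k3", "k4", "vt")]
}

#' Arterial input specification
#'
#' The underlying true plasma curve is a linear rise from injection to a
#' peak at `t_peak`, followed by a tri-exponential decay; the parent
#' fraction follows a Hill model calibrated to ~0.70 unmetabolized ligand
#' at 60 min; whole blood is plasma divided by a constant
#' plasma-to-whole-blood ratio.
#'
#' @param peak Plasma peak concentration, kBq/cm^3.
#' @param t_peak Time of the plasma peak, minutes (in \[0.5, 2\]).
#' @param frac,rate Tri-exponential decay fractions (sum 1) and rates
#'   (1/min) after the peak.
#' @param pf_a,pf_b,pf_c Hill parent-fraction parameters (see
#'   [parent_fraction_model()]).
#' @param p_wb_ratio Plasma-to-whole-blood concentration ratio.
#' @param noise_cv Multiplicative measurement noise CV on the blood
#'   samples.
#' @return List of class `input_spec`.
#' @export
input_spec <- function(peak = 9, t_peak = 1,
                       frac = c(0.68, 0.19, 0.13),
                       rate = c(2.5, 0.22, 0.009),
                       pf_a = 0.6, pf_b = 1.5, pf_c = 60^1.5,
                       p_wb_ratio = 1.2, noise_cv = 0.02) {
  stopifnot(t_peak >= 0.5, t_peak <= 2, peak > 0,
            length(frac) == length(rate), all(rate > 0), all(frac > 0))
  structure(list(peak = peak, t_peak = t_peak, frac = frac / sum(frac),
                 rate = rate, pf_a = pf_a, pf_b = pf_b, pf_c = pf_c,
                 p_wb_ratio = p_wb_ratio, noise_cv = noise_cv),
            class = "input_spec")
}

# noiseless plasma concentration of the spec at arbitrary times
.true_plasma <- function(spec, t) {
  out <- numeric(length(t))
  rising <- t >= 0 & t <= spec$t_peak
  out[rising] <- spec$peak * t[rising] / spec$t_peak
  after <- t > spec$t_peak
  if (any(after)) {
    dt <- t[after] - spec$t_peak
    out[after] <- spec$peak *
      colSums(spec$frac * exp(-outer(spec$rate, dt)))
  }
  out
}

#' True (noiseless) input function of an input specification
#'
#' Densely sampled [input_function] of the spec's metabolite-corrected
#' plasma curve; used as ground truth when simulating cohorts.
#'
#' @param spec An [input_spec].
#' @param t_end Last knot, minutes.
#' @return An [input_function].
#' @export
true_input <- function(spec, t_end = 125) {
  kt <- sort(unique(c(seq(0.1, 3, by = 0.1), seq(3.25, 10, by = 0.25),
                      seq(10.5, t_end, by = 0.5))))
  pf <- pf_eval(parent_fraction_model(spec$pf_a, spec$pf_b, spec$pf_c), kt)
  input_function(kt, .true_plasma(spec, kt) * pf)
}

#' Generate arterial blood series at the study sample times
#'
#' Plasma and whole blood at the 14 manual sample times (1, 2, 3, 4, 5, 6,
#' 8, 10, 20, 30, 45, 60, 90, 120 min); parent fractions at the 9
#' metabolite sample times (2, 5, 10, 20, 30, 45, 60, 90, 120 min).
#' Deterministic given the seed.
#'
#' @param spec An [input_spec].
#' @param seed Integer seed.
#' @return List with [blood_series] elements `plasma`, `whole_blood`,
#'   `parent_fraction`, and the generating `pf_model`.
#' @export
gen_input <- function(spec = input_spec(), seed = 1L) {
  t_blood <- c(1, 2, 3, 4, 5, 6, 8, 10, 20, 30, 45, 60, 90, 120)
  t_pf <- c(2, 5, 10, 20, 30, 45, 60, 90, 120)
  pf_model <- parent_fraction_model(spec$pf_a, spec$pf_b, spec$pf_c)
  with_seed(seed, {
    plasma <- .true_plasma(spec, t_blood) *
      rlnorm_cv(length(t_blood), 1, spec$noise_cv)
    wb <- plasma / spec$p_wb_ratio *
      rlnorm_cv(length(t_blood), 1, spec$noise_cv / 2)
    pf <- pf_eval(pf_model, t_pf) +
      stats::rnorm(length(t_pf), 0, 0.5 * spec$noise_cv)
    list(
      plasma = blood_series(t_blood, plasma, "plasma"),
      whole_blood = blood_series(t_blood, wb, "whole_blood"),
      parent_fraction = blood_series(t_pf, pmin(pmax(pf, 0), 1),
                                     "parent_fraction"),
      pf_model = pf_model
    )
  })
}

#' Test-retest cohort specification
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param regions Data frame as from [default_regions()].
#' @param between_subject_cv Log-normal CV of each rate constant across
#'   subjects.
#' @param within_subject_cv Log-normal CV of each rate constant between a
#'   subject's two sessions (biological + procedural session effects); also
#'   applied to the input amplitude and f_P.
#' @param tac_noise_cv Frame-noise CV at a reference 6-min frame, relative
#'   to the curve mean; per-frame SD scales as 1/sqrt(frame duration).
#' @param input_spec An [input_spec] for the arterial model.
#' @param fp_mean Population mean plasma free fraction.
#' @param retest_interval Admissible test-retest interval in days.
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8, regions = default_regions(),
                        between_subject_cv = 0.10, within_subject_cv = 0.05,
                        tac_noise_cv = 0.05, input_spec = petquant::input_spec(),
                        fp_mean = 0.095, retest_interval = c(5, 19),
                        seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (between_subject_cv < 0 || within_subject_cv < 0 || tac_noise_cv < 0) {
    stop("CVs must be >= 0")
  }
  structure(list(n_subjects = n_subjects, regions = regions,
                 between_subject_cv = between_subject_cv,
                 within_subject_cv = within_subject_cv,
                 tac_noise_cv = tac_noise_cv, input_spec = input_spec,
                 fp_mean = fp_mean, retest_interval = retest_interval,
                 seed = seed),
            class = "cohort_spec")
}

#' Add Gaussian frame noise to a time-activity curve
#'
#' Two noise models: `"additive"` (default in [gen_cohort()]) draws
#' zero-mean noise with SD `cv * mean(conc) * sqrt(6 / duration)`, i.e.
#' referenced to a 6-min frame and scaled with counting statistics;
#' `"multiplicative"` draws per-frame noise with SD `cv * conc_i`, i.e. a
#' constant per-frame coefficient of variation.
#'
#' @param tc A [tac].
#' @param cv Noise coefficient of variation (0 disables).
#' @param model `"additive"` or `"multiplicative"`.
#' @return The noisy [tac]. Uses the current RNG stream.
#' @export
add_frame_noise <- function(tc, cv, model = c("additive", "multiplicative")) {
  model <- match.arg(model)
  if (cv <= 0) return(tc)
  sd_i <- if (model == "additive") {
    dur <- tc$frame_end - tc$frame_start
    cv * mean(tc$conc) * sqrt(6 / dur)
  } else {
    cv * abs(tc$conc)
  }
  tc$conc <- tc$conc + stats::rnorm(length(tc$conc), 0, sd_i)
  tc
}

.add_frame_noise <- function(tc, cv) add_frame_noise(tc, cv, "additive")

#' Generate a test-retest cohort of study records
#'
#' Per subject, rate constants are drawn log-normally around the regional
#' population means with `between_subject_cv`; each session re-draws them
#' around the subject's values with `within_subject_cv`. Session TACs are
#' simulated through the two-tissue forward model from the session's true
#' input and perturbed with zero-mean Gaussian frame noise whose SD scales
#' as 1/sqrt(frame duration). Each record carries its generating truth in
#' `attr(record, "truth")`.
#'
#' @param spec A [cohort_spec].
#' @return Named list: `records[[subject]][[session]]` is a
#'   [study_record]; subject names are `S01`, `S02`, ...
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sched <- frame_schedule()
  regions <- spec$regions
  with_seed(spec$seed, {
    out <- list()
    for (i in seq_len(spec$n_subjects)) {
      sid <- sprintf("S%02d", i)
      subj_pars <- lapply(seq_len(nrow(regions)), function(r) {
        c(K1 = rlnorm_cv(1, regions$K1[r], spec$between_subject_cv),
          k2 = rlnorm_cv(1, regions$k2[r], spec$between_subject_cv),
          k3 = rlnorm_cv(1, regions$k3[r], spec$between_subject_cv),
          k4 = rlnorm_cv(1, regions$k4[r], spec$between_subject_cv))
      })
      subj_amp <- rlnorm_cv(1, 1, spec$between_subject_cv)
      subj_fp <- rlnorm_cv(1, spec$fp_mean, 2 * spec$between_subject_cv)
      weight <- stats::rnorm(1, 70, 10)
      interval <- if (spec$within_subject_cv > 0 || spec$tac_noise_cv > 0) {
        sample(spec$retest_interval[1]:spec$retest_interval[2], 1)
      } else spec$retest_interval[1]
      sessions <- list()
      for (session in c("test", "retest")) {
        wcv <- spec$within_subject_cv
        amp <- subj_amp * rlnorm_cv(1, 1, wcv)
        ispec <- spec$input_spec
        ispec$peak <- ispec$peak * amp
        blood_seed <- spec$seed * 10000 + i * 10 +
          (if (session == "test") 1 else 2)
        blood <- gen_input(ispec, seed = blood_seed)
        # the session's true input is the metabolite-corrected input built
        # from the session's own blood samples with the standard evaluation
        # rule, so that input noise propagates into the outcome measures
        # and the noiseless pipeline recovers the generating parameters
        inp <- build_input(blood$plasma, blood$pf_model)
        dose <- max(stats::rnorm(1, 122, 22), 60)
        truth_pars <- list()
        tacs <- lapply(seq_len(nrow(regions)), function(r) {
          p <- subj_pars[[r]]
          p <- p * rlnorm_cv(4, 1, wcv)
          kp <- kinetic_params(p["K1"], p["k2"], p["k3"], p["k4"])
          truth_pars[[regions$region[r]]] <<- kp
          tc <- simulate_tac(kp, inp, sched, region_id = regions$region[r])
          .add_frame_noise(tc, spec$tac_noise_cv)
        })
        names(tacs) <- regions$region
        fp <- subj_fp * rlnorm_cv(1, 1, 3 * wcv)
        rec <- study_record(sid, session, injected_dose = dose, tacs = tacs,
                            blood = blood[c("plasma", "whole_blood",
                                            "parent_fraction")],
                            body_weight = weight, f_P = min(fp, 1))
        attr(rec, "truth") <- list(
          params = truth_pars,
          vt = vapply(truth_pars, vt_from_params, numeric(1)),
          input = inp, pf_model = blood$pf_model,
          interval_days = interval)
        sessions[[session]] <- rec
      }
      out[[sid]] <- sessions
    }
    out
  })
}

#' Generate a whole-body biodistribution over the 4-session protocol
#'
#' Organ %ID curves (decay-corrected) sampled at the bed-pass mid-times of
#' the four whole-body sessions (0-54, 90-144, 210-264, 330-366 min),
#' with liver-dominant uptake, rising hepatobiliary organs (gall bladder,
#' small intestine), urinary excretion of ~10 %ID by 5.8 h, and a
#' remainder compartment that closes the activity balance to exactly
#' 100 %ID at every sample time.
#'
#' @param seed Integer seed.
#' @param noise_cv Multiplicative measurement noise CV per organ sample.
#' @return List with `organs` (named list of [organ_retention], including
#'   `urinary_bladder` as measured in the VOI and `remainder`), `urine`
#'   (data frame of void times in hours and voided %ID), and `t_hours`.
#' @export
gen_biodistribution <- function(seed = 1L, noise_cv = 0.06) {
  t <- c(0.15, 0.45, 0.75, 1.725, 2.175, 3.725, 4.175, 5.8)
  # shape: a * (1 - exp(-r t)) * exp(-lambda t), calibrated to the
  # published peak magnitudes (liver 25 %ID at 0.5 h, lungs 12 %ID at
  # 0.2 h, small intestine rising to ~10.6 %ID, brain 3.5 %ID, ...)
  shapes <- list(
    liver = c(a = 27, r = 8, l = 0.10),
    lungs = c(a = 12.9, r = 20, l = 0.35),
    small_intestine = c(a = 12.2, r = 0.35, l = 0),
    gall_bladder = c(a = 3.0, r = 0.40, l = 0),
    brain = c(a = 3.7, r = 8, l = 0.05),
    stomach = c(a = 4.3, r = 0.8, l = 0.14),
    heart = c(a = 2.7, r = 20, l = 0.30),
    pancreas = c(a = 2.5, r = 20, l = 0.15),
    kidneys = c(a = 2.4, r = 20, l = 0.20),
    spleen = c(a = 1.6, r = 20, l = 0.20),
    red_marrow = c(a = 2.0, r = 2, l = 0),
    urinary_bladder = c(a = 1.0, r = 2, l = 0)
  )
  urine <- data.frame(t = c(1.2, 2.9, 5.3), pid = c(4.2, 3.4, 2.6))
  with_seed(seed, {
    organs <- lapply(names(shapes), function(org) {
      s <- shapes[[org]]
      base <- s["a"] * (1 - exp(-s["r"] * t)) * exp(-s["l"] * t)
      organ_retention(org, t, unname(base) *
                        rlnorm_cv(length(t), 1, noise_cv))
    })
    names(organs) <- names(shapes)
    cum_urine <- vapply(t, function(tt) sum(urine$pid[urine$t <= tt + 1e-9]),
                        numeric(1))
    organ_sum <- Reduce(`+`, lapply(organs, `[[`, "pid"))
    rem <- 100 - organ_sum - cum_urine
    if (any(rem < 0)) stop("activity balance violated; reduce noise_cv")
    organs$remainder <- organ_retention("remainder", t, rem)
    list(organs = organs, urine = urine, t_hours = t)
  })
}
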