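test_that("generators are pure functions of spec and seed", {
  a <- gen_input(seed = 5)
  b <- gen_input(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$plasma$value, gen_input(seed = 6)$plasma$value))
  bd1 <- gen_biodistribution(seed = 4)
  bd2 <- gen_biodistribution(seed = 4)
  expect_identical(bd1, bd2)
  sp <- cohort_spec(n_subjects = 3, seed = 9)
  c1 <- gen_cohort(sp)
  c2 <- gen_cohort(sp)
  expect_identical(c1$S02$retest$tacs$ACC$conc, c2$S02$retest$tacs$ACC$conc)
  # generator calls do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_input(seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated blood series have the study's structure", {
  g <- gen_input(seed = 2)
  expect_equal(g$plasma$t, c(1, 2, 3, 4, 5, 6, 8, 10, 20, 30, 45, 60, 90, 120))
  expect_equal(g$parent_fraction$t, c(2, 5, 10, 20, 30, 45, 60, 90, 120))
  pf60 <- pf_eval(g$pf_model, 60)
  expect_gt(pf60, 0.68); expect_lt(pf60, 0.72)
  # plasma strictly decreasing after its peak (noiseless spec)
  g0 <- gen_input(input_spec(noise_cv = 0), seed = 2)
  v <- g0$plasma$value
  pk <- which.max(v)
  expect_true(all(diff(v[pk:length(v)]) < 0))
})

test_that("default cohort V_T magnitudes track the published regional means", {
  sp <- cohort_spec(n_subjects = 8, seed = 17)
  coh <- gen_cohort(sp)
  reg <- default_regions()
  # mean generating V_T across subjects within +-20% of the published means
  for (r in reg$region) {
    vts <- vapply(coh, function(s) attr(s$test, "truth")$vt[[r]], numeric(1))
    expect_lt(abs(mean(vts) - reg$vt[reg$region == r]) /
                reg$vt[reg$region == r], 0.20)
  }
})

test_that("zero within-subject variance gives ICC of exactly 1 downstream", {
  sp <- cohort_spec(n_subjects = 4, within_subject_cv = 0,
                    tac_noise_cv = 0, seed = 3)
  sp$input_spec$noise_cv <- 0
  coh <- gen_cohort(sp)
  vt_test <- vapply(coh, function(s) attr(s$test, "truth")$vt[["ACC"]],
                    numeric(1))
  vt_retest <- vapply(coh, function(s) attr(s$retest, "truth")$vt[["ACC"]],
                      numeric(1))
  expect_equal(vt_test, vt_retest)
  expect_equal(icc_oneway(cbind(vt_test, vt_retest)), 1)
})

test_that("noiseless cohort returns generating V_T through the full pipeline", {
  sp <- cohort_spec(n_subjects = 3, within_subject_cv = 0,
                    tac_noise_cv = 0, seed = 42)
  sp$input_spec$noise_cv <- 0
  coh <- gen_cohort(sp)
  rec <- coh$S02$test
  truth <- attr(rec, "truth")
  pf <- fit_parent_fraction(rec$blood$parent_fraction)
  inp <- build_input(rec$blood$plasma, pf$model)
  for (r in names(rec$tacs)) {
    f <- fit_compartment(rec$tacs[[r]], inp, model = "2tcm")
    expect_lt(abs(f$vt - truth$vt[[r]]) / truth$vt[[r]], 0.01)
  }
})

test_that("biodistribution conserves activity and hits published anchors", {
  bd <- gen_biodistribution(seed = 8)
  cum_urine <- vapply(bd$t_hours, function(tt) {
    sum(bd$urine$pid[bd$urine$t <= tt + 1e-9])
  }, numeric(1))
  total <- Reduce(`+`, lapply(bd$organs, `[[`, "pid")) + cum_urine
  expect_true(all(total >= 95 & total <= 100 + 1e-9))
  # liver peak in the published band near 0.5 h
  liver <- bd$organs$liver
  expect_gt(max(liver$pid), 20); expect_lt(max(liver$pid), 30)
  expect_lt(abs(liver$t[which.max(liver$pid)] - 0.5), 0.35)
  # ~10 %ID eliminated with urine by 5.8 h
  expect_gt(sum(bd$urine$pid), 8); expect_lt(sum(bd$urine$pid), 12)
  # residence times over all compartments sum to ~T1/2/ln2 (conservation)
  orgs <- bd$organs
  orgs$urinary_bladder <- bladder_with_urine(orgs$urinary_bladder, bd$urine)
  taus <- vapply(orgs, function(o) residence_time(fit_retention(o)),
                 numeric(1))
  target <- (109.77 / 60) / log(2)
  expect_lt(abs(sum(taus) - target) / target, 0.02)
})
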