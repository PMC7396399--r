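test_that("forward model honours degenerate and nested limits", {
  inp <- noiseless_input()
  sched <- default_sched()
  zero <- simulate_tac(kinetic_params(0, 0.1), inp, sched)
  expect_true(all(zero$conc == 0))
  # two-tissue machinery collapses to the one-tissue solution as k3,k4 -> 0
  one <- simulate_tac(kinetic_params(0.15, 0.08), inp, sched)
  near <- simulate_tac(kinetic_params(0.15, 0.08, 1e-10, 1e-10), inp, sched)
  expect_equal(near$conc, one$conc, tolerance = 1e-8)
})

test_that("forward model matches an independent Runge-Kutta oracle", {
  inp <- noiseless_input()
  sched <- default_sched()
  p <- ref_params()
  got <- simulate_tac(p, inp, sched)
  rhs <- function(t, y, parms) {
    cp <- eval_input(inp, t)
    list(c(p$K1 * cp - (p$k2 + p$k3) * y[1] + p$k4 * y[2],
           p$k3 * y[1] - p$k4 * y[2]))
  }
  g <- seq(0, 123, by = 0.01)
  sol <- deSolve::ode(c(0, 0), g, rhs, NULL, method = "rk4")
  ct <- sol[, 2] + sol[, 3]
  cumint <- c(0, cumsum(diff(g) * (ct[-1] + ct[-length(ct)]) / 2))
  oracle <- (approx(g, cumint, sched$end)$y -
               approx(g, cumint, sched$start)$y) / sched$durations
  rel <- abs(got$conc[-1] - oracle[-1]) / oracle[-1]  # frame 1 is ~0
  expect_lt(max(rel), 5e-4)
})

test_that("V_T macro-formulas evaluate the printed relationships", {
  expect_equal(vt_from_params(kinetic_params(0.10, 0.05), "1tcm"), 2.0)
  expect_equal(vt_from_params(ref_params(), "2tcm"), 0.5 * 4.0)
  # one-tissue cerebellum-scale means: the ratio of printed means is 4.129,
  # close to but distinct from the printed mean V_T (which averages
  # per-subject ratios)
  expect_equal(vt_from_params(kinetic_params(0.128, 0.031), "1tcm"),
               4.129, tolerance = 1e-3)
  expect_error(vt_from_params(kinetic_params(0.1, 0.2, 0.3, 0), "2tcm"))
})

test_that("compartment fits recover noiseless generating parameters", {
  inp <- noiseless_input()
  sched <- default_sched()
  p <- ref_params()
  tc <- simulate_tac(p, inp, sched)
  fit <- fit_compartment(tc, inp, model = "2tcm")
  expect_true(fit$converged)
  for (k in c("K1", "k2", "k3", "k4")) {
    expect_lt(abs(fit$params[[k]] - p[[k]]) / p[[k]], 0.01)
  }
  expect_lt(abs(fit$vt - 2.0) / 2.0, 0.005)
  # macro-consistency of the reported V_T
  expect_equal(fit$vt, vt_from_params(fit$params, "2tcm"), tolerance = 1e-10)

  # one-tissue regime at cerebellum-scale parameters
  p1 <- kinetic_params(0.128, 0.031)
  tc1 <- simulate_tac(p1, inp, sched)
  fit1 <- fit_compartment(tc1, inp, model = "1tcm")
  expect_lt(abs(fit1$vt - 0.128 / 0.031) / (0.128 / 0.031), 0.005)

  expect_error(fit_compartment(tac("z", sched$start, sched$end,
                                   rep(0, 34)), inp), "all-zero")
})

test_that("Logan slope estimates V_T on both model classes", {
  inp <- noiseless_input()
  sched <- default_sched()
  tc1 <- simulate_tac(kinetic_params(0.10, 0.05), inp, sched)
  lg1 <- logan_vt(tc1, inp, t_star = 30)
  expect_lt(abs(lg1$vt - 2.0) / 2.0, 0.005)
  expect_gte(lg1$n_points_used, 3)
  tc2 <- simulate_tac(ref_params(), inp, sched)
  lg2 <- logan_vt(tc2, inp, t_star = 30)
  expect_lt(abs(lg2$vt - 2.0) / 2.0, 0.02)
  expect_error(logan_vt(tc2, inp, t_star = 125), "t_star")
  expect_error(logan_vt(tac("z", sched$start, sched$end, rep(0, 34)), inp),
               "non-positive")
})

test_that("model comparison implements the nested F-test", {
  mk <- function(model, wrss, aic, npar) {
    structure(list(model = model, wrss = wrss, aic = aic, n_frames = 34,
                   n_params = npar, converged = TRUE),
              class = "kinetic_fit")
  }
  same <- compare_models(mk("1tcm", 10, 5, 2), mk("2tcm", 10, 9, 4))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_equal(same$f_preferred, "1tcm")
  expect_equal(same$aic_preferred, "1tcm")
  half <- compare_models(mk("1tcm", 10, 5, 2), mk("2tcm", 5, 2, 4))
  expect_equal(half$F, (5 / 2) / (5 / 30))
  expect_equal(half$p, stats::pf(15, 2, 30, lower.tail = FALSE))
  zero <- compare_models(mk("1tcm", 10, 5, 2), mk("2tcm", 0, -60, 4))
  expect_true(zero$wrss2_zero)
  expect_equal(zero$p, 0)
})

test_that("AIC prefers the generating two-tissue model at moderate noise", {
  # at per-frame CV 2% the second compartment is well identified; the
  # preference fraction collapses as noise approaches the 1TCM misfit
  # scale (see the methods vignette)
  inp <- noiseless_input()
  sched <- default_sched()
  reg <- default_regions()
  pref <- vapply(1:36, function(i) {
    r <- ((i - 1) %% 12) + 1
    kp <- kinetic_params(reg$K1[r], reg$k2[r], reg$k3[r], reg$k4[r])
    tc <- simulate_tac(kp, inp, sched)
    tc <- petquant:::with_seed(i, add_frame_noise(tc, 0.02, "multiplicative"))
    f1 <- fit_compartment(tc, inp, "1tcm", weights = "uniform")
    f2 <- fit_compartment(tc, inp, "2tcm", weights = "uniform")
    if (!f2$converged) return(NA)
    compare_models(f1, f2)$aic_preferred == "2tcm"
  }, logical(1))
  expect_gt(mean(pref, na.rm = TRUE), 0.8)
})

test_that("two-tissue WRSS never exceeds one-tissue WRSS when nested", {
  inp <- noiseless_input()
  sched <- default_sched()
  reg <- default_regions()
  for (i in 1:5) {
    r <- 2 * i
    kp <- kinetic_params(reg$K1[r], reg$k2[r], reg$k3[r], reg$k4[r])
    tc <- simulate_tac(kp, inp, sched)
    tc <- petquant:::with_seed(100 + i, add_frame_noise(tc, 0.05))
    f1 <- fit_compartment(tc, inp, "1tcm")
    f2 <- fit_compartment(tc, inp, "2tcm")
    if (f1$converged && f2$converged) {
      expect_lte(f2$wrss, f1$wrss * (1 + 1e-6))
    }
  }
})

test_that("all estimators agree on noiseless two-tissue data", {
  inp <- noiseless_input()
  sched <- default_sched()
  reg <- default_regions()
  for (r in c(1, 5, 10)) {
    kp <- kinetic_params(reg$K1[r], reg$k2[r], reg$k3[r], reg$k4[r])
    truth <- vt_from_params(kp, "2tcm")
    tc <- simulate_tac(kp, inp, sched)
    vt2 <- fit_compartment(tc, inp, "2tcm")$vt
    vt1 <- fit_compartment(tc, inp, "1tcm")$vt
    vtl <- logan_vt(tc, inp)$vt
    expect_lte(vt1, vt2 * 1.02)
    expect_lte(vtl, vt2 * 1.02)
    expect_lt(abs(vt1 - truth) / truth, 0.10)
    expect_lt(abs(vtl - truth) / truth, 0.10)
  }
})

test_that("time-stability analysis is exact on noiseless data", {
  inp <- noiseless_input()
  sched <- default_sched()
  reg <- default_regions()
  gm <- kinetic_params(mean(reg$K1), mean(reg$k2), mean(reg$k3),
                       mean(reg$k4))
  tc <- simulate_tac(gm, inp, sched)
  ts <- time_stability(tc, inp)
  expect_equal(ts$duration_min, c(63, 75, 87, 99, 111, 123))
  expect_equal(ts$pct_diff[6], 0)
  expect_true(all(abs(ts$pct_diff) < 1))
  expect_error(time_stability(tc, inp, durations = c(63, 99)), "longest")
})

test_that("SUV normalization and the default whole-brain peak", {
  tc <- tac("wb", 0, 1, 2.5)
  expect_equal(suv_curve(tc, 125, 50)$suv, 1.0)
  expect_equal(suv_curve(tac("wb", 0, 1, 5.0), 125, 50)$suv, 2.0)
  expect_error(suv_curve(tc, 125, NULL), "body_weight")
  # default synthetic whole-brain curve peaks in the published band
  inp <- noiseless_input()
  reg <- default_regions()
  gm <- kinetic_params(mean(reg$K1), mean(reg$k2), mean(reg$k3),
                       mean(reg$k4))
  s <- suv_curve(simulate_tac(gm, inp, default_sched()), 122, 70)
  expect_gt(max(s$suv), 1.5)
  expect_lt(max(s$suv), 2.1)
  t_peak <- s$t_min[which.max(s$suv)]
  expect_gt(t_peak, 20)
  expect_lt(t_peak, 45)
})
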