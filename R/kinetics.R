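# Compartment-model simulation and fitting, Logan graphical analysis,
# model selection, and time-stability analysis.
#
# State equations (serial two-tissue model):
#   dC1/dt = K1*Cp - (k2 + k3)*C1 + k4*C2
#   dC2/dt = k3*C1 - k4*C2
#   C_model = (1 - vB)*(C1 + C2) + vB*C_wb
# The tissue impulse response is a sum of two exponentials; tissue curves
# are computed by exact convolution of that response with the piecewise-
# linear input on a fine regular grid (recursive filter, exact for a
# piecewise-linear input), then averaged over each frame interval.

#' Compartment-model rate constants
#'
#' @param K1 Plasma-to-tissue delivery, mL/cm^3/min.
#' @param k2 Tissue-to-plasma efflux, 1/min.
#' @param k3,k4 Exchange with the second tissue compartment, 1/min (both 0
#'   for the one-tissue model, both > 0 for the two-tissue model).
#' @param vB Fractional blood volume in \[0, 0.2\] (default 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  p <- c(K1 = K1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(p)) || any(p < 0)) stop("rate constants must be >= 0")
  if (xor(k3 > 0, k4 > 0)) stop("k3 and k4 must both be 0 or both be > 0")
  if (vB < 0 || vB > 0.2) stop("vB must lie in [0, 0.2]")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "kinetic_params")
}

# exact convolution of exp(-alpha*t) with a piecewise-linear curve sampled
# on a regular grid (spacing dt); returns the convolution at the grid nodes
.conv_exp <- function(cp, dt, alpha) {
  n <- length(cp)
  x <- alpha * dt
  if (x < 1e-12) {
    # limit alpha -> 0: running integral of the piecewise-linear curve
    return(c(0, cumsum(dt * (cp[-1] + cp[-n]) / 2)))
  }
  c0 <- cp[-n]
  m <- (cp[-1] - c0) / dt
  if (x < 1e-4) {
    # series forms avoid cancellation for small alpha*dt
    g1 <- dt * (1 - x / 2 + x^2 / 6 - x^3 / 24)
    g2 <- dt^2 * (1 / 2 - x / 6 + x^2 / 24 - x^3 / 120)
  } else {
    em <- -expm1(-x)  # 1 - exp(-alpha*dt), accurately
    g1 <- em / alpha
    g2 <- (dt - g1) / alpha
  }
  r <- exp(-x)
  b <- c0 * g1 + m * g2
  c(0, stats::filter(b, r, method = "recursive"))
}

# decompose the 2TCM impulse response (C1+C2)(t) = phi1*exp(-th1*t) +
# phi2*exp(-th2*t)
.impulse_2tcm <- function(K1, k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  th1 <- (s - disc) / 2
  th2 <- (s + disc) / 2
  if (th2 - th1 < 1e-10) th2 <- th1 + 1e-10  # avoid the repeated-root pole
  phi1 <- K1 * (k3 + k4 - th1) / (th2 - th1)
  phi2 <- K1 * (th2 - k3 - k4) / (th2 - th1)
  list(theta = c(th1, th2), phi = c(phi1, phi2))
}

# simulation grid shared by forward model and fits
.sim_grid <- function(schedule, dt) {
  tend <- max(schedule$end)
  n <- ceiling(tend / dt - 1e-9)
  seq(0, by = dt, length.out = n + 1)
}

# tissue model on the grid -> frame averages
.frame_average <- function(grid, y, schedule) {
  .frame_avg_maker(grid, schedule)(y)
}

# precompute the linear-interpolation weights of the cumulative integral
# at all frame edges on a regular grid; returns a fast y -> frame-averages
# closure for repeated use inside the optimizer
.frame_avg_maker <- function(grid, schedule) {
  dt <- grid[2] - grid[1]
  n <- length(grid)
  edge_val <- function(cumint, e) {
    i <- pmin(pmax(floor(e / dt), 0), n - 2)
    frac <- e / dt - i
    cumint[i + 1] * (1 - frac) + cumint[i + 2] * frac
  }
  s_e <- schedule$start
  e_e <- pmin(schedule$end, grid[n])
  dur <- schedule$durations
  function(y) {
    cumint <- c(0, cumsum(dt * (y[-1] + y[-n]) / 2))
    (edge_val(cumint, e_e) - edge_val(cumint, s_e)) / dur
  }
}

.model_on_grid <- function(params, cp_grid, dt) {
  if (params$k3 > 0) {
    ir <- .impulse_2tcm(params$K1, params$k2, params$k3, params$k4)
    ct <- ir$phi[1] * .conv_exp(cp_grid, dt, ir$theta[1]) +
          ir$phi[2] * .conv_exp(cp_grid, dt, ir$theta[2])
  } else {
    ct <- params$K1 * .conv_exp(cp_grid, dt, params$k2)
  }
  ct
}

#' Simulate a time-activity curve from a compartment model
#'
#' Frame values are interval averages of the model curve (not midpoint
#' samples); with 20-s early frames the distinction is material.
#'
#' @param params A [kinetic_params].
#' @param input An [input_function] (metabolite-corrected plasma).
#' @param schedule A [frame_schedule].
#' @param region_id Label for the returned curve.
#' @param wb_input Optional [input_function] for whole blood, used for the
#'   `vB` term; the plasma input is used when absent.
#' @param dt Simulation grid step, minutes.
#' @return A [tac].
#' @export
simulate_tac <- function(params, input, schedule, region_id = "sim",
                         wb_input = NULL, dt = 1 / 60) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(input, "input_function"),
            inherits(schedule, "frame_schedule"))
  grid <- .sim_grid(schedule, dt)
  cp <- eval_input(input, grid)
  ct <- .model_on_grid(params, cp, dt)
  if (params$vB > 0) {
    cwb <- if (is.null(wb_input)) cp else eval_input(wb_input, grid)
    ct <- (1 - params$vB) * ct + params$vB * cwb
  }
  tac(region_id, schedule$start, schedule$end,
      .frame_average(grid, ct, schedule))
}

#' Total distribution volume from rate constants
#'
#' `V_T = K1/k2` for the one-tissue model and
#' `V_T = (K1/k2) * (1 + k3/k4)` for the two-tissue model.
#'
#' @param params A [kinetic_params] (or list with the rate constants).
#' @param model `"1tcm"` or `"2tcm"`.
#' @return V_T in mL/cm^3.
#' @export
vt_from_params <- function(params, model = c("2tcm", "1tcm")) {
  model <- match.arg(model)
  if (params$k2 <= 0) stop("k2 must be > 0")
  if (model == "1tcm") return(params$K1 / params$k2)
  if (params$k4 <= 0) stop("k4 must be > 0 for the two-tissue model")
  (params$K1 / params$k2) * (1 + params$k3 / params$k4)
}

.weights_for <- function(tc, scheme) {
  w <- switch(scheme,
              uniform = rep(1, length(tc$conc)),
              frame = (tc$frame_end - tc$frame_start),
              stop("unknown weights scheme: ", scheme))
  w / mean(w)
}

#' Fit a compartment model to a time-activity curve
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) minimizing
#' `sum(w_i * (obs_i - model_i)^2)`. Frame-duration weighting
#' (`w_i` proportional to frame length, normalized to mean 1) is the
#' default. The two-tissue fit is seeded from a one-tissue fit with
#' `k3 = k4 = 0.05`; up to three perturbed restarts are attempted before a
#' fit is flagged non-converged. `AIC = N*log(WRSS/N) + 2*k`.
#'
#' @param tc A [tac].
#' @param input An [input_function].
#' @param model `"2tcm"` or `"1tcm"`.
#' @param weights `"frame"` or `"uniform"`.
#' @param init Optional [kinetic_params] starting values.
#' @param lower,upper Bounds for each rate constant (defaults 1e-6 and 5).
#' @param vB Fixed fractional blood volume (default 0, not fitted).
#' @param dt Simulation grid step.
#' @return An object of class `kinetic_fit`: `model`, `params`, `vt`,
#'   `wrss`, `aic`, `n_frames`, `n_params`, `converged`, `vt_se_pct`
#'   (delta-method percent standard error of V_T, a fit-quality
#'   diagnostic), `fitted`.
#' @export
fit_compartment <- function(tc, input, model = c("2tcm", "1tcm"),
                            weights = c("frame", "uniform"), init = NULL,
                            lower = 1e-6, upper = 5, vB = 0, dt = 1 / 60) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(inherits(tc, "tac"), inherits(input, "input_function"))
  if (all(tc$conc == 0)) stop("all-zero TAC: nothing to fit")
  sched <- frame_schedule(tc$frame_end - tc$frame_start)
  w <- .weights_for(tc, weights)
  sw <- sqrt(w)
  grid <- .sim_grid(sched, dt)
  cp <- eval_input(input, grid)
  npar <- if (model == "2tcm") 4L else 2L
  favg <- .frame_avg_maker(grid, sched)

  model_frames <- function(p) {
    ct <- if (npar == 4L) {
      ir <- .impulse_2tcm(p[1], p[2], p[3], p[4])
      ir$phi[1] * .conv_exp(cp, dt, ir$theta[1]) +
        ir$phi[2] * .conv_exp(cp, dt, ir$theta[2])
    } else {
      p[1] * .conv_exp(cp, dt, p[2])
    }
    if (vB > 0) ct <- (1 - vB) * ct + vB * cp
    favg(ct)
  }
  resid_fn <- function(p) {
    r <- sw * (tc$conc - model_frames(p))
    r[!is.finite(r)] <- 1e6
    r
  }

  start <- if (!is.null(init)) {
    if (npar == 4L) c(init$K1, init$k2, init$k3, init$k4) else c(init$K1, init$k2)
  } else if (npar == 2L) {
    # crude delivery guess from the early-uptake ratio
    k1_0 <- max(tc$conc) / max(integrate_input(input, tc$frame_mid[which.max(tc$conc)]), 1e-6)
    c(min(max(k1_0, 1e-3), 2), 0.05)
  } else {
    f1 <- fit_compartment(tc, input, model = "1tcm", weights = weights,
                          vB = vB, dt = dt)
    c(f1$params$K1, f1$params$k2, 0.05, 0.05)
  }
  start <- pmin(pmax(start, lower * 2), upper / 2)

  # deterministic multi-start in log-parameter space (rates are positive
  # and span orders of magnitude); the best of all starts is kept, with an
  # early exit when the fit is numerically perfect
  perturb <- list(c(2, 0.5, 2, 0.5), c(0.5, 2, 0.5, 2), c(3, 1, 0.3, 1))
  scale_wrss <- sum(w * tc$conc^2)
  best <- NULL
  for (attempt in 0:3) {
    p0 <- if (attempt == 0) start else {
      pmin(pmax(start * perturb[[attempt]][seq_len(npar)], lower * 2),
           upper / 2)
    }
    fit <- try(minpack.lm::nls.lm(
      par = log(p0), lower = rep(log(lower), npar),
      upper = rep(log(upper), npar),
      fn = function(q) resid_fn(exp(q)),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    par <- exp(fit$par)
    wrss <- sum(resid_fn(par)^2)
    ok <- fit$info %in% 1:4 && is.finite(wrss)
    interior <- all(par > lower * 2) && all(par < upper * 0.98)
    if (ok && (is.null(best) || wrss < best$wrss)) {
      best <- list(par = par, wrss = wrss, interior = interior)
    }
    # stop early on a numerically perfect fit or an interior optimum from
    # the primary start; bound-stuck solutions trigger the restarts
    if (!is.null(best) &&
        (best$wrss < 1e-12 * scale_wrss || (attempt == 0 && interior))) {
      break
    }
  }

  n <- length(tc$conc)
  # a solution pinned to a rate-constant bound (e.g. k2 or k4 at the lower
  # bound) has no physiological interpretation and an unstable V_T; treat
  # it as non-convergence, mirroring the exclusion of such fits from
  # downstream tables
  if (!is.null(best) && !best$interior && best$wrss >= 1e-12 * scale_wrss) {
    best <- NULL
  }
  if (is.null(best)) {
    return(structure(list(model = model, params = NULL, vt = NA_real_,
                          wrss = NA_real_, aic = NA_real_, n_frames = n,
                          n_params = npar, converged = FALSE,
                          vt_se_pct = NA_real_, fitted = NULL,
                          region_id = tc$region_id),
                     class = "kinetic_fit"))
  }
  p <- best$par
  params <- if (npar == 4L) kinetic_params(p[1], p[2], p[3], p[4], vB) else
    kinetic_params(p[1], p[2], vB = vB)
  vt <- vt_from_params(params, model)
  aic <- n * log(best$wrss / n) + 2 * npar
  vt_se_pct <- .vt_se_pct(p, npar, resid_fn, best$wrss, n)
  structure(list(model = model, params = params, vt = vt, wrss = best$wrss,
                 aic = aic, n_frames = n, n_params = npar, converged = TRUE,
                 vt_se_pct = vt_se_pct, fitted = model_frames(p),
                 region_id = tc$region_id),
            class = "kinetic_fit")
}

# delta-method percent standard error of V_T, computed in log-parameter
# space where V_T is linear: log VT = q1 - q2 (+ log(1 + exp(q3 - q4))).
# Large values signal an unidentifiable macro-parameter (the usual failure
# mode of slow two-tissue kinetics in a finite scan window).
.vt_se_pct <- function(p, npar, resid_fn, wrss, n) {
  if (n <= npar || wrss <= 0) return(0)
  q <- log(p)
  h <- 1e-4
  r0 <- resid_fn(p)
  J <- vapply(seq_len(npar), function(j) {
    qj <- q; qj[j] <- qj[j] + h
    (resid_fn(exp(qj)) - r0) / h
  }, numeric(length(r0)))
  sigma2 <- wrss / (n - npar)
  covq <- try(sigma2 * solve(crossprod(J) + diag(1e-10, npar)),
              silent = TRUE)
  if (inherits(covq, "try-error")) return(Inf)
  g <- if (npar == 4L) {
    s <- (p[3] / p[4]) / (1 + p[3] / p[4])
    c(1, -1, s, -s)
  } else c(1, -1)
  se_log <- sqrt(max(drop(t(g) %*% covq %*% g), 0))
  100 * se_log
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<kinetic_fit> %s %s: NOT CONVERGED\n", x$region_id, x$model))
  } else {
    cat(sprintf(
      "<kinetic_fit> %s %s: K1=%.4g k2=%.4g k3=%.4g k4=%.4g VT=%.4g AIC=%.4g\n",
      x$region_id, x$model, x$params$K1, x$params$k2, x$params$k3,
      x$params$k4, x$vt, x$aic))
  }
  invisible(x)
}

#' Logan graphical analysis
#'
#' Transforms the data to `x(t) = int_0^t Cp / C_T(t)` and
#' `y(t) = int_0^t C_T / C_T(t)` and fits an ordinary least-squares line to
#' the points with frame mid-time at or after `t_star`; the slope estimates
#' V_T. The tissue integral uses trapezoids through (0, 0) and the frame
#' mid-points; the plasma integral uses the continuous input rule.
#'
#' @param tc A [tac].
#' @param input An [input_function].
#' @param t_star Start of the linear segment, minutes (default 30).
#' @return An object of class `logan_fit`: `vt` (slope), `intercept`,
#'   `t_star`, `n_points_used`, `r_squared`.
#' @export
logan_vt <- function(tc, input, t_star = 30) {
  stopifnot(inherits(tc, "tac"), inherits(input, "input_function"))
  mids <- tc$frame_mid
  if (t_star >= max(mids)) stop("t_star is at or beyond the last frame mid-time")
  use <- mids >= t_star
  if (sum(use) < 3) stop("need >= 3 frames with mid-time >= t_star")
  if (any(tc$conc[use] <= 0)) stop("non-positive tissue values on the Logan window")
  tt <- c(0, mids)
  yy <- c(0, tc$conc)
  int_ct <- cumsum(c(0, diff(tt) * (yy[-1] + yy[-length(yy)]) / 2))[-1]
  int_cp <- integrate_input(input, mids)
  x <- int_cp[use] / tc$conc[use]
  y <- int_ct[use] / tc$conc[use]
  cf <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(cf$coefficients[2])
  r2 <- 1 - sum(cf$residuals^2) / sum((y - mean(y))^2)
  structure(list(vt = slope, intercept = unname(cf$coefficients[1]),
                 t_star = t_star, n_points_used = sum(use), r_squared = r2,
                 region_id = tc$region_id),
            class = "logan_fit")
}

#' Compare nested one- and two-tissue fits
#'
#' F-test for the nested pair:
#' `F = ((WRSS1 - WRSS2)/(df1 - df2)) / (WRSS2/df2)` with
#' `df = N - n_params`; AIC preference is `AIC(2TCM) < AIC(1TCM)`.
#'
#' @param fit1 A converged one-tissue `kinetic_fit`.
#' @param fit2 A converged two-tissue `kinetic_fit` of the same data.
#' @param alpha Significance level for the F-test (default 0.05).
#' @return List with `F`, `p`, `df1`, `df2`, `aic_preferred`,
#'   `f_preferred` (each `"1tcm"` or `"2tcm"`), and `wrss2_zero` flag.
#' @export
compare_models <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(fit1$model == "1tcm", fit2$model == "2tcm")
  if (fit1$n_frames != fit2$n_frames) stop("fits are not of the same data")
  n <- fit1$n_frames
  df1 <- n - fit1$n_params
  df2 <- n - fit2$n_params
  if (fit2$wrss == 0) {
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2,
                aic_preferred = "2tcm", f_preferred = "2tcm",
                wrss2_zero = TRUE))
  }
  Fv <- ((fit1$wrss - fit2$wrss) / (df1 - df2)) / (fit2$wrss / df2)
  p <- stats::pf(Fv, df1 - df2, df2, lower.tail = FALSE)
  list(F = Fv, p = p, df1 = df1, df2 = df2,
       aic_preferred = if (fit2$aic < fit1$aic) "2tcm" else "1tcm",
       f_preferred = if (is.finite(p) && p < alpha) "2tcm" else "1tcm",
       wrss2_zero = FALSE)
}

#' Time-stability analysis of V_T
#'
#' Refits the model on data truncated to each duration and reports the
#' percent difference of V_T relative to the full-length estimate.
#'
#' @param tc A [tac] covering the full acquisition.
#' @param input An [input_function].
#' @param durations Truncation lengths in minutes; the longest must equal
#'   the full acquisition length.
#' @param model,weights,... Passed to [fit_compartment()].
#' @return Data frame with columns `duration_min`, `vt`, `pct_diff`,
#'   `converged`.
#' @export
time_stability <- function(tc, input,
                           durations = c(63, 75, 87, 99, 111, 123),
                           model = "2tcm", weights = "frame", ...) {
  full <- max(tc$frame_end)
  if (abs(max(durations) - full) > 1e-6) {
    stop("longest duration must equal the full acquisition length")
  }
  ref_fit <- NULL
  rows <- lapply(sort(durations, decreasing = TRUE), function(d) {
    keep <- tc$frame_end <= d + 1e-9
    sub <- tac(tc$region_id, tc$frame_start[keep], tc$frame_end[keep],
               tc$conc[keep])
    fit <- fit_compartment(sub, input, model = model, weights = weights, ...)
    if (abs(d - full) < 1e-6) ref_fit <<- fit
    data.frame(duration_min = d, vt = fit$vt, converged = fit$converged,
               vt_se_pct = if (is.null(fit$vt_se_pct)) NA_real_ else
                 fit$vt_se_pct)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$duration_min), ]
  vt_full <- out$vt[nrow(out)]
  out$pct_diff <- 100 * (out$vt - vt_full) / vt_full
  rownames(out) <- NULL
  out[, c("duration_min", "vt", "pct_diff", "converged", "vt_se_pct")]
}

#' Standardized uptake value curve
#'
#' `SUV(t) = conc(kBq/cm^3) / (dose(kBq) / weight(g))`, i.e. concentration
#' normalized by injected dose per body mass (unit tissue density):
#' a uniformly distributed tracer gives SUV 1 everywhere.
#'
#' @param tc A [tac].
#' @param injected_dose Injected activity, MBq (> 0).
#' @param body_weight Body weight, kg (> 0).
#' @return Data frame with `t_min` (frame mid-times) and `suv`.
#' @export
suv_curve <- function(tc, injected_dose, body_weight) {
  if (is.null(body_weight) || !is.numeric(body_weight) || body_weight <= 0) {
    stop("body_weight must be a positive number")
  }
  if (!is.numeric(injected_dose) || injected_dose <= 0) {
    stop("injected_dose must be > 0")
  }
  data.frame(t_min = tc$frame_mid,
             suv = tc$conc / (injected_dose * 1000 / (body_weight * 1000)))
}
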