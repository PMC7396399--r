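# Metabolite-corrected arterial input function and plasma free fraction.

#' Hill-type plasma parent-fraction model
#'
#' `pf(t) = 1 - a * t^b / (t^b + c)`, which is 1 at t = 0 (no metabolites at
#' injection), monotone non-increasing, and bounded in \[1 - a, 1\].
#'
#' @param a Amplitude in \[0, 1\]: `1 - a` is the asymptotic parent fraction.
#' @param b Shape (> 0).
#' @param c Scale with units of `minutes^b` (> 0).
#' @return An object of class `parent_fraction_model`, callable through
#'   [pf_eval()].
#' @export
parent_fraction_model <- function(a, b, c) {
  if (a < 0 || a > 1) stop("a must lie in [0, 1]")
  if (b <= 0 || c <= 0) stop("b and c must be > 0")
  structure(list(form = "hill", a = a, b = b, c = c),
            class = "parent_fraction_model")
}

#' Evaluate a parent-fraction model
#' @param model A `parent_fraction_model`.
#' @param t Times in minutes (>= 0).
#' @return Parent fraction in \[0, 1\] at each time.
#' @export
pf_eval <- function(model, t) {
  stopifnot(inherits(model, "parent_fraction_model"))
  tb <- pmax(t, 0)^model$b
  1 - model$a * tb / (tb + model$c)
}

#' Fit the parent-fraction model to measured fractions
#'
#' Least-squares fit of the Hill form to parent-fraction samples, with
#' `pf(0) = 1` enforced structurally by the model form. A series that is
#' identically 1 returns the constant model `a = 0`.
#'
#' @param samples A [blood_series] of kind `parent_fraction` with >= 4
#'   samples.
#' @return List with `model` (a `parent_fraction_model`), `rmse`, and
#'   `converged`.
#' @export
fit_parent_fraction <- function(samples) {
  stopifnot(inherits(samples, "blood_series"))
  if (samples$kind != "parent_fraction") {
    stop("samples must be of kind 'parent_fraction'")
  }
  t <- samples$t; y <- samples$value
  if (length(t) < 4) stop("need at least 4 parent-fraction samples")
  if (all(abs(y - 1) < 1e-12)) {
    return(list(model = parent_fraction_model(0, 1, 1), rmse = 0,
                converged = TRUE))
  }
  a0 <- min(max(1 - min(y), 1e-3), 1)
  # scale start: time at which the drop reaches half its final size
  t_half <- t[which.min(abs((1 - y) - a0 / 2))]
  start <- c(a = a0, b = 1.5, c = max(t_half, 1)^1.5)
  fit <- try(minpack.lm::nls.lm(
    par = start,
    lower = c(0, 0.1, 1e-6), upper = c(1, 10, 1e8),
    fn = function(p) y - (1 - p[1] * t^p[2] / (t^p[2] + p[3]))
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(model = parent_fraction_model(a0, 1.5, start[3]),
                rmse = NA_real_, converged = FALSE))
  }
  p <- fit$par
  model <- parent_fraction_model(p[1], p[2], p[3])
  res <- y - pf_eval(model, t)
  list(model = model, rmse = sqrt(mean(res^2)),
       converged = fit$info %in% 1:4)
}

#' Continuous metabolite-corrected arterial input function
#'
#' Evaluation rule: 0 before `delay`; linear rise from (delay, 0) to the
#' first knot; piecewise linear between knots; mono-exponential tail fitted
#' through the last three knots beyond the last knot. This makes the input
#' evaluable on all of `[0, Inf)` with a finite tail integral.
#'
#' @param knots Knot times in minutes (strictly increasing, > 0).
#' @param values Metabolite-corrected plasma concentration at the knots,
#'   kBq/cm^3 (>= 0).
#' @param delay Constant delay in minutes (default 0).
#' @return An object of class `input_function`.
#' @export
input_function <- function(knots, values, delay = 0) {
  if (length(knots) != length(values) || length(knots) < 3) {
    stop("need >= 3 knots with matching values")
  }
  if (is.unsorted(knots, strictly = TRUE) || any(knots <= 0)) {
    stop("knot times must be strictly increasing and > 0")
  }
  if (any(values < 0)) stop("input values must be >= 0")
  n <- length(knots)
  idx <- (n - 2):n
  tl <- knots[idx]; vl <- values[idx]
  if (all(vl > 0)) {
    # log-linear least squares through the last three knots
    cf <- stats::lm.fit(cbind(1, tl), log(vl))$coefficients
    tail_lambda <- max(-cf[2], 1e-6)  # enforce a decaying, integrable tail
    tail_A <- exp(cf[1] + cf[2] * tl[3])  # fitted value at the last knot
  } else {
    tail_lambda <- 1e-6
    tail_A <- vl[3]
  }
  structure(
    list(knots = knots, values = values, delay = delay,
         tail_A = unname(tail_A), tail_lambda = unname(tail_lambda)),
    class = "input_function"
  )
}

#' Evaluate an input function at arbitrary times
#' @param input An `input_function`.
#' @param t Times in minutes (vectorized).
#' @return Concentration, kBq/cm^3.
#' @export
eval_input <- function(input, t) {
  stopifnot(inherits(input, "input_function"))
  ts <- t - input$delay
  out <- numeric(length(t))
  kt <- input$knots; kv <- input$values
  last <- kt[length(kt)]
  mid <- ts >= 0 & ts <= last
  if (any(mid)) {
    out[mid] <- stats::approx(c(0, kt), c(0, kv), ts[mid], rule = 2)$y
  }
  beyond <- ts > last
  if (any(beyond)) {
    out[beyond] <- input$tail_A * exp(-input$tail_lambda * (ts[beyond] - last))
  }
  pmax(out, 0)
}

#' Integral of an input function from 0 to t
#'
#' Computed on a fine grid with the same evaluation rule as [eval_input()];
#' `t = Inf` returns the full integral including the analytic tail.
#'
#' @param input An `input_function`.
#' @param t Upper limit, minutes (scalar or vector; may be `Inf`).
#' @param dt Grid step for the piecewise-linear part, minutes.
#' @return Integral, kBq/cm^3 x min.
#' @export
integrate_input <- function(input, t, dt = 0.01) {
  last <- input$knots[length(input$knots)] + input$delay
  tail_int_full <- input$tail_A / input$tail_lambda
  one <- function(tt) {
    if (tt <= 0) return(0)
    if (is.infinite(tt)) {
      g <- seq(0, last, by = dt)
      y <- eval_input(input, g)
      return(sum(diff(g) * (y[-1] + y[-length(y)]) / 2) + tail_int_full)
    }
    g <- seq(0, min(tt, last), length.out = max(ceiling(min(tt, last) / dt), 2) + 1)
    y <- eval_input(input, g)
    v <- sum(diff(g) * (y[-1] + y[-length(y)]) / 2)
    if (tt > last) {
      v <- v + tail_int_full * (1 - exp(-input$tail_lambda * (tt - last)))
    }
    v
  }
  vapply(t, one, numeric(1))
}

#' Build the metabolite-corrected arterial input function
#'
#' Multiplies measured plasma concentrations by the modelled parent fraction
#' at each sample time and attaches the tail rule.
#'
#' @param plasma A [blood_series] of kind `plasma` covering (0, 120\] min.
#' @param pf_model A `parent_fraction_model` (or NULL for no correction).
#' @param delay Constant delay in minutes.
#' @return An `input_function`.
#' @export
build_input <- function(plasma, pf_model = NULL, delay = 0) {
  stopifnot(inherits(plasma, "blood_series"))
  if (plasma$kind == "parent_fraction") {
    stop("plasma series required, not parent fractions")
  }
  if (any(plasma$value < 0)) stop("negative plasma values")
  pf <- if (is.null(pf_model)) rep(1, length(plasma$t)) else {
    pf_eval(pf_model, plasma$t)
  }
  input_function(plasma$t, plasma$value * pf, delay = delay)
}

#' Plasma free fraction from an ultrafiltration assay
#'
#' `f_P = mean(sample_free / sample_total) / mean(control_free /
#' control_total)`: per-replicate free/total ratios are averaged first, then
#' the plasma ratio is corrected for membrane binding measured on
#' protein-free control samples.
#'
#' @param assay Data frame with columns `sample_free`, `sample_total`,
#'   `control_free`, `control_total` (one row per replicate; counts > 0 for
#'   totals, free <= total).
#' @return List with `f_P` (corrected, possibly > 1 before clipping),
#'   `f_P_clipped` (capped at 1), `sample_ratio`, `control_ratio`.
#' @export
free_fraction <- function(assay) {
  need <- c("sample_free", "sample_total", "control_free", "control_total")
  miss <- setdiff(need, names(assay))
  if (length(miss)) stop("assay missing column(s): ", paste(miss, collapse = ", "))
  if (any(assay$sample_total <= 0) || any(assay$control_total <= 0)) {
    stop("total counts must be > 0")
  }
  if (any(assay$sample_free > assay$sample_total) ||
      any(assay$control_free > assay$control_total)) {
    stop("free counts cannot exceed total counts")
  }
  sr <- mean(assay$sample_free / assay$sample_total)
  cr <- mean(assay$control_free / assay$control_total)
  if (cr <= 0) stop("control ratio is zero; cannot correct for membrane binding")
  fp <- sr / cr
  list(f_P = fp, f_P_clipped = min(fp, 1), sample_ratio = sr,
       control_ratio = cr)
}
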