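# Core containers and curve utilities shared by all pipeline stages.
# Internal time unit is minutes throughout; file readers convert on the
# way in when headers declare other units.

#' Physical half-life of fluorine-18 in minutes
#' @export
HALF_LIFE_F18_MIN <- 109.77

#' Frame schedule for a dynamic PET acquisition
#'
#' Builds the frame time grid from a vector of frame durations. The default
#' is the 123-min brain protocol of 34 frames: 20 s x 9, 1 min x 3,
#' 3 min x 5, 6 min x 17.
#'
#' @param durations Frame durations in minutes.
#' @return An object of class `frame_schedule` with elements `durations`,
#'   `start`, `end`, and `mid` (all minutes).
#' @examples
#' sched <- frame_schedule()
#' length(sched$mid)      # 34
#' max(sched$end)         # 123
#' @export
frame_schedule <- function(durations = c(rep(1 / 3, 9), rep(1, 3),
                                         rep(3, 5), rep(6, 17))) {
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    stop("frame durations must be positive and finite")
  }
  end <- cumsum(durations)
  start <- c(0, end[-length(end)])
  structure(
    list(durations = durations, start = start, end = end,
         mid = (start + end) / 2),
    class = "frame_schedule"
  )
}

#' Time-activity curve for one region or organ
#'
#' Frame-based, decay-corrected activity concentration versus time. Frames
#' must be sorted and non-overlapping; the model value of a frame is
#' attributed to its mid-time.
#'
#' @param region_id Region/organ label.
#' @param frame_start,frame_end Frame boundaries in minutes.
#' @param conc Decay-corrected activity concentration, kBq/cm^3.
#' @return An object of class `tac`.
#' @export
tac <- function(region_id, frame_start, frame_end, conc) {
  n <- length(frame_start)
  if (n < 1 || length(frame_end) != n || length(conc) != n) {
    stop("frame_start, frame_end and conc must have equal length >= 1")
  }
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_end))) {
    stop("frame times must be finite")
  }
  bad <- which(frame_end <= frame_start)
  if (length(bad)) {
    stop(sprintf("frame_end <= frame_start in frame %d", bad[1]))
  }
  if (n > 1) {
    overlap <- which(frame_start[-1] < frame_end[-n] - 1e-9)
    if (is.unsorted(frame_start) || length(overlap)) {
      stop(sprintf("frames must be sorted and non-overlapping (frame %d)",
                   if (length(overlap)) overlap[1] + 1L else 1L))
    }
  }
  if (any(!is.finite(conc))) stop("conc must be finite")
  structure(
    list(region_id = as.character(region_id),
         frame_start = as.numeric(frame_start),
         frame_end = as.numeric(frame_end),
         frame_mid = (as.numeric(frame_start) + as.numeric(frame_end)) / 2,
         conc = as.numeric(conc)),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> region %s: %d frames, %.3g-%.4g min, peak %.4g kBq/cm^3\n",
              x$region_id, length(x$conc), x$frame_start[1],
              x$frame_end[length(x$frame_end)], max(x$conc)))
  invisible(x)
}

#' Arterial blood sample series
#'
#' @param t Sample times, minutes, strictly increasing and non-negative.
#' @param value Measured values: kBq/cm^3 for `whole_blood`/`plasma`,
#'   a fraction in \[0, 1\] for `parent_fraction`.
#' @param kind One of `"whole_blood"`, `"plasma"`, `"parent_fraction"`.
#' @return An object of class `blood_series`.
#' @export
blood_series <- function(t, value,
                         kind = c("plasma", "whole_blood", "parent_fraction")) {
  kind <- match.arg(kind)
  if (length(t) != length(value) || length(t) < 1) {
    stop("t and value must have equal length >= 1")
  }
  if (any(!is.finite(t)) || any(t < 0) || is.unsorted(t, strictly = TRUE)) {
    stop("sample times must be non-negative and strictly increasing")
  }
  if (any(!is.finite(value))) stop("values must be finite")
  if (kind == "parent_fraction" && (any(value < 0) || any(value > 1))) {
    stop("parent_fraction values must lie in [0, 1]")
  }
  structure(list(t = as.numeric(t), value = as.numeric(value), kind = kind),
            class = "blood_series")
}

#' Subject-session study record
#'
#' Bundles everything measured in one PET session of one subject.
#'
#' @param subject_id Subject label.
#' @param session `"test"` or `"retest"`.
#' @param injected_dose Injected activity, MBq (> 0).
#' @param tacs Named list of [tac] objects (one per region).
#' @param blood Named list of [blood_series] (`plasma`, `whole_blood`,
#'   `parent_fraction`).
#' @param body_weight Body weight in kg, optional.
#' @param f_P Plasma free fraction, optional.
#' @return An object of class `study_record`.
#' @export
study_record <- function(subject_id, session = c("test", "retest"),
                         injected_dose, tacs, blood,
                         body_weight = NULL, f_P = NULL) {
  session <- match.arg(session)
  if (!is.numeric(injected_dose) || injected_dose <= 0) {
    stop("injected_dose must be > 0")
  }
  stopifnot(is.list(tacs), all(vapply(tacs, inherits, TRUE, "tac")))
  structure(
    list(subject_id = as.character(subject_id), session = session,
         injected_dose = injected_dose, tacs = tacs, blood = blood,
         body_weight = body_weight, f_P = f_P),
    class = "study_record"
  )
}

# ---- TAC table I/O ---------------------------------------------------------

#' Read a table of regional time-activity curves
#'
#' Expects delimited text with a header row containing `frame_start_min`,
#' `frame_end_min`, then one column per region (concentration, kBq/cm^3,
#' decay-corrected). Headers `frame_start_s`/`frame_end_s` are accepted and
#' converted from seconds.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @return Named list of [tac] objects, one per region column.
#' @export
read_tac_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "#")
  nm <- names(df)
  scl <- 1
  if (all(c("frame_start_s", "frame_end_s") %in% nm)) {
    scl <- 1 / 60
    start_col <- "frame_start_s"; end_col <- "frame_end_s"
  } else if (all(c("frame_start_min", "frame_end_min") %in% nm)) {
    start_col <- "frame_start_min"; end_col <- "frame_end_min"
  } else {
    stop("TAC table must contain frame_start_min/frame_end_min ",
         "(or *_s) columns; found: ", paste(nm, collapse = ", "))
  }
  regions <- setdiff(nm, c(start_col, end_col))
  if (!length(regions)) stop("TAC table has no region columns")
  for (col in c(start_col, end_col, regions)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d", col,
                   if (is.na(bad)) 1L else bad))
    }
  }
  fs <- df[[start_col]] * scl
  fe <- df[[end_col]] * scl
  bad <- which(fe <= fs)
  if (length(bad)) {
    stop(sprintf("frame_end <= frame_start in row %d", bad[1]))
  }
  out <- lapply(regions, function(r) tac(r, fs, fe, df[[r]]))
  names(out) <- regions
  out
}

#' Write a list of time-activity curves as a delimited table
#'
#' Inverse of [read_tac_table()]; all curves must share one frame grid.
#'
#' @param tacs Named list of [tac] objects.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_tac_table <- function(tacs, path, sep = ",") {
  stopifnot(length(tacs) >= 1)
  ref <- tacs[[1]]
  for (tc in tacs) {
    if (!isTRUE(all.equal(tc$frame_start, ref$frame_start)) ||
        !isTRUE(all.equal(tc$frame_end, ref$frame_end))) {
      stop("all curves must share the same frame schedule")
    }
  }
  df <- data.frame(frame_start_min = ref$frame_start,
                   frame_end_min = ref$frame_end, check.names = FALSE)
  for (nm in names(tacs)) df[[nm]] <- tacs[[nm]]$conc
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a blood sample table
#'
#' Expects columns `t_min`, `value`, `kind` with kind in
#' `whole_blood`/`plasma`/`parent_fraction`.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @return Named list of [blood_series], one element per kind present.
#' @export
read_blood_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("t_min", "value", "kind")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("blood table missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(df, df$kind), function(d) {
    d <- d[order(d$t_min), ]
    blood_series(d$t_min, d$value, kind = d$kind[1])
  })
  out
}

#' Write a set of blood sample series as one table
#' @param blood Named list of [blood_series].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @export
write_blood_table <- function(blood, path, sep = ",") {
  rows <- do.call(rbind, lapply(blood, function(b) {
    data.frame(t_min = b$t, value = b$value, kind = b$kind)
  }))
  utils::write.table(rows, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Curve utilities -------------------------------------------------------

#' Trapezoidal area under a sampled curve
#'
#' Integrates a piecewise-linear curve over `[t0, t1]` with linear
#' interpolation at the endpoints. No extrapolation is performed: the window
#' must lie within the sampled support (frame mid-times for a `tac`, sample
#' times for a `blood_series`).
#'
#' @param curve A [tac], a [blood_series], or a list/data.frame with `t` and
#'   `value` elements.
#' @param t0,t1 Integration window in minutes, `t0 < t1`.
#' @return Integral in concentration x time units (e.g. kBq/cm^3 x min).
#' @export
trapezoid_auc <- function(curve, t0, t1) {
  if (inherits(curve, "tac")) {
    t <- curve$frame_mid; y <- curve$conc
  } else if (inherits(curve, "blood_series")) {
    t <- curve$t; y <- curve$value
  } else {
    t <- curve$t; y <- curve$value
  }
  if (!is.numeric(t0) || !is.numeric(t1) || t0 >= t1) stop("need t0 < t1")
  if (t0 < min(t) - 1e-9 || t1 > max(t) + 1e-9) {
    stop(sprintf("window [%g, %g] outside sampled support [%g, %g]",
                 t0, t1, min(t), max(t)))
  }
  inside <- t > t0 & t < t1
  tt <- c(t0, t[inside], t1)
  yy <- c(stats::approx(t, y, t0)$y, y[inside], stats::approx(t, y, t1)$y)
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Remove or reapply decay correction
#'
#' Study curves are stored decay-corrected to injection time; dose integrals
#' need physical activity. `apply_physical_decay` multiplies values by
#' `exp(-log(2) * t / half_life)`; `remove_physical_decay` is its inverse.
#'
#' @param curve A [tac], [blood_series], or list with `t`/`value`.
#' @param half_life Physical half-life in the same time unit as the curve
#'   (minutes by default convention; fluorine-18 is 109.77 min).
#' @return Same type as the input, with scaled values.
#' @export
apply_physical_decay <- function(curve, half_life = HALF_LIFE_F18_MIN) {
  .decay_scale(curve, half_life, forward = TRUE)
}

#' @rdname apply_physical_decay
#' @export
remove_physical_decay <- function(curve, half_life = HALF_LIFE_F18_MIN) {
  .decay_scale(curve, half_life, forward = FALSE)
}

.decay_scale <- function(curve, half_life, forward) {
  if (!is.numeric(half_life) || half_life <= 0) {
    stop("half_life must be > 0")
  }
  lam <- log(2) / half_life
  if (inherits(curve, "tac")) {
    f <- exp(-lam * curve$frame_mid)
    curve$conc <- curve$conc * if (forward) f else 1 / f
  } else {
    f <- exp(-lam * curve$t)
    curve$value <- curve$value * if (forward) f else 1 / f
  }
  curve
}
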