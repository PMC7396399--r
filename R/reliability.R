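# Test-retest repeatability (TRV) and one-way intraclass correlation (ICC).

#' Test-retest variability
#'
#' `TRV(%) = |PET2 - PET1| / ((PET1 + PET2)/2) * 100`. Symmetric in its
#' arguments and scale-invariant.
#'
#' @param pet1,pet2 Paired measurements (vectorized); their mean must be
#'   positive.
#' @return TRV in percent.
#' @export
trv <- function(pet1, pet2) {
  m <- (pet1 + pet2) / 2
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("session means must be positive and finite")
  }
  abs(pet2 - pet1) / m * 100
}

#' One-way intraclass correlation coefficient
#'
#' `ICC = (s_b^2 - s_w^2) / (s_b^2 + (n-1) * s_w^2)` where `s_b^2` and
#' `s_w^2` are the between- and within-subject mean squares of the one-way
#' random-effects ANOVA decomposition and `n` is the number of sessions per
#' subject (2 here). Negative values are reported as computed, not clipped.
#'
#' @param values Numeric matrix, subjects in rows, the two sessions in
#'   columns; >= 3 subjects.
#' @return ICC (a value in \[-1, 1\] for n = 2).
#' @export
icc_oneway <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 3) stop("need at least 3 subjects")
  if (ncol(values) != 2) stop("expected exactly 2 sessions per subject")
  if (any(!is.finite(values))) stop("values must be finite")
  k <- ncol(values)
  n_subj <- nrow(values)
  subj_means <- rowMeans(values)
  grand <- mean(values)
  ssb <- k * sum((subj_means - grand)^2)
  ssw <- sum((values - subj_means)^2)
  msb <- ssb / (n_subj - 1)
  msw <- ssw / (n_subj * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Reliability table over a test-retest cohort
#'
#' For each metric (a region/estimator combination, an AUC diagnostic, or
#' f_P), computes the across-subject mean and SD of the per-subject TRV and
#' the one-way ICC. Subjects missing either session for a metric are
#' excluded pairwise for that metric only.
#'
#' @param data Data frame with columns `metric`, `subject`, `test`,
#'   `retest`; `NA` in either session drops the subject for that metric.
#' @return Data frame of class `reliability_table` with columns `metric`,
#'   `n_subjects`, `trv_mean`, `trv_sd`, `icc`.
#' @export
reliability_table <- function(data) {
  need <- c("metric", "subject", "test", "retest")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  rows <- lapply(split(data, data$metric), function(d) {
    ok <- is.finite(d$test) & is.finite(d$retest)
    d <- d[ok, ]
    if (nrow(d) < 3) {
      stop(sprintf("metric '%s': fewer than 3 complete test-retest pairs",
                   d$metric[1]))
    }
    tv <- trv(d$test, d$retest)
    data.frame(metric = d$metric[1], n_subjects = nrow(d),
               trv_mean = mean(tv), trv_sd = stats::sd(tv),
               icc = icc_oneway(cbind(d$test, d$retest)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reliability_table", "data.frame")
  out
}

#' Summary row of a reliability table
#'
#' Arithmetic mean over metrics (regions) of the TRV and ICC columns,
#' ignoring missing cells. This is the "mean across regions" row that
#' summarizes a per-region table.
#'
#' @param table A data frame with columns `trv_mean` and `icc` (e.g. from
#'   [reliability_table()]).
#' @return One-row data frame with `metric = "mean"`, `trv_mean`, `icc`,
#'   and the ranges of both columns.
#' @export
summarize_reliability <- function(table) {
  data.frame(metric = "mean",
             trv_mean = mean(table$trv_mean, na.rm = TRUE),
             trv_min = min(table$trv_mean, na.rm = TRUE),
             trv_max = max(table$trv_mean, na.rm = TRUE),
             icc = mean(table$icc, na.rm = TRUE),
             icc_min = min(table$icc, na.rm = TRUE),
             icc_max = max(table$icc, na.rm = TRUE))
}

#' Cohort metric extraction for reliability analysis
#'
#' Assembles the long-format metric table that [reliability_table()]
#' consumes, from per-subject pairs of study records and their kinetic
#' fits. Available metrics: regional V_T per estimator, AUC of the mean
#' gray-matter TAC, AUC of the arterial input, their ratio, and f_P.
#' Non-converged fits give `NA` cells (pairwise exclusion downstream).
#'
#' @param records Named list: `records[[subject]][[session]]` is a
#'   [study_record], sessions `"test"` and `"retest"`.
#' @param fits Named list mirroring `records`:
#'   `fits[[subject]][[session]][[region]]` is a list with elements named
#'   by estimator (`"1tcm"`, `"2tcm"`, `"logan"`) holding fit objects, or
#'   NULL. Optional when only AUC/f_P metrics are requested.
#' @param metrics Character vector choosing among `"vt"`, `"auc"`, `"fp"`.
#' @param auc_window Integration window in minutes for the AUC diagnostics
#'   (default `c(0, 120)`, within both TAC and blood support).
#' @return Long data frame with columns `metric`, `subject`, `test`,
#'   `retest`.
#' @export
cohort_metrics <- function(records, fits = NULL,
                           metrics = c("vt", "auc", "fp"),
                           auc_window = c(0.5, 120)) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  subjects <- names(records)
  complete <- vapply(subjects, function(s) {
    all(c("test", "retest") %in% names(records[[s]]))
  }, logical(1))
  dropped <- subjects[!complete]
  if (length(dropped)) {
    message("excluded from reliability (single session): ",
            paste(dropped, collapse = ", "))
  }
  subjects <- subjects[complete]
  if (!length(subjects)) stop("no complete test-retest subjects")

  rows <- list()
  add <- function(metric, subject, v1, v2) {
    rows[[length(rows) + 1]] <<- data.frame(
      metric = metric, subject = subject,
      test = if (is.null(v1) || !length(v1)) NA_real_ else v1,
      retest = if (is.null(v2) || !length(v2)) NA_real_ else v2)
  }
  vt_of <- function(s, session, region, estimator) {
    f <- fits[[s]][[session]][[region]][[estimator]]
    if (is.null(f)) return(NA_real_)
    if (inherits(f, "kinetic_fit")) {
      # non-converged fits and fits with an unidentifiable V_T (percent
      # standard error above 50%) are excluded pairwise
      if (!f$converged) return(NA_real_)
      if (is.finite(f$vt_se_pct) && f$vt_se_pct > 50) return(NA_real_)
    }
    f$vt
  }

  if ("vt" %in% metrics) {
    if (is.null(fits)) stop("fits required for V_T metrics")
    regions <- names(records[[subjects[1]]]$test$tacs)
    for (region in regions) {
      for (est in names(fits[[subjects[1]]]$test[[region]])) {
        for (s in subjects) {
          add(paste0("VT_", est, "_", region), s,
              vt_of(s, "test", region, est), vt_of(s, "retest", region, est))
        }
      }
    }
  }
  if ("auc" %in% metrics) {
    for (s in subjects) {
      vals <- lapply(c("test", "retest"), function(session) {
        rec <- records[[s]][[session]]
        gm <- rowMeans(vapply(rec$tacs, function(tc) tc$conc,
                              numeric(length(rec$tacs[[1]]$conc))))
        gm_tac <- tac("GM", rec$tacs[[1]]$frame_start,
                      rec$tacs[[1]]$frame_end, gm)
        pf <- fit_parent_fraction(rec$blood$parent_fraction)
        inp <- build_input(rec$blood$plasma, pf$model)
        auc_gm <- trapezoid_auc(gm_tac, auc_window[1], auc_window[2])
        auc_in <- integrate_input(inp, auc_window[2]) -
          integrate_input(inp, auc_window[1])
        c(gm = auc_gm, input = auc_in, ratio = auc_gm / auc_in)
      })
      add("AUC_GM", s, vals[[1]]["gm"], vals[[2]]["gm"])
      add("AUC_input", s, vals[[1]]["input"], vals[[2]]["input"])
      add("AUC_ratio", s, vals[[1]]["ratio"], vals[[2]]["ratio"])
    }
  }
  if ("fp" %in% metrics) {
    for (s in subjects) {
      add("f_P", s, records[[s]]$test$f_P, records[[s]]$retest$f_P)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
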