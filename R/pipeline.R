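# End-to-end orchestration: brain quantification + reliability ("study B"
# style) and whole-body dosimetry ("study A" style). Every intermediate is
# a file; outputs carry a provenance header (settings, seed, version).

.provenance_header <- function(settings) {
  c(sprintf("# petquant %s", as.character(utils::packageVersion("petquant"))),
    sprintf("# generated %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("# settings: %s",
            paste(names(settings), unlist(settings), sep = "=",
                  collapse = " ")))
}

.write_csv_prov <- function(df, path, settings, digits = 10) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_header(settings), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the brain quantification and reliability analysis
#'
#' Fits the one- and two-tissue compartment models and Logan graphical
#' analysis to every region of every subject-session, then assembles the
#' per-region reliability tables (TRV/ICC of V_T per estimator), the AUC
#' diagnostics (gray-matter AUC, input AUC, their ratio, f_P), and a
#' time-stability table of the gray-matter V_T. Subjects with a single
#' session are logged and excluded from reliability. Outputs are CSV files
#' under `outdir` with a provenance header.
#'
#' @param records Cohort as returned by [gen_cohort()] (or assembled from
#'   files): `records[[subject]][[session]]` is a [study_record].
#' @param outdir Output directory (created if needed).
#' @param t_star Logan start time, minutes.
#' @param weights Fit weighting scheme (`"frame"` or `"uniform"`).
#' @param time_stability_durations Truncation grid, minutes, or `NULL` to
#'   skip the time-stability analysis.
#' @param seed Seed recorded in the provenance header (the analysis itself
#'   is deterministic).
#' @return Invisible list with `fits` (data frame), `reliability`
#'   (per-estimator tables), `diagnostics` (AUC/f_P table),
#'   `time_stability`, and the output paths.
#' @export
run_quantification <- function(records, outdir, t_star = 30,
                               weights = "frame",
                               time_stability_durations = c(63, 75, 87, 99,
                                                            111, 123),
                               seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  settings <- list(t_star = t_star, weights = weights, seed = seed)

  fit_rows <- list()
  fits <- list()
  for (sid in names(records)) {
    fits[[sid]] <- list()
    for (session in names(records[[sid]])) {
      rec <- records[[sid]][[session]]
      pf <- fit_parent_fraction(rec$blood$parent_fraction)
      inp <- build_input(rec$blood$plasma, pf$model)
      fits[[sid]][[session]] <- list()
      for (region in names(rec$tacs)) {
        tc <- rec$tacs[[region]]
        f1 <- fit_compartment(tc, inp, model = "1tcm", weights = weights)
        f2 <- fit_compartment(tc, inp, model = "2tcm", weights = weights)
        lg <- logan_vt(tc, inp, t_star = t_star)
        fits[[sid]][[session]][[region]] <-
          list("1tcm" = f1, "2tcm" = f2, "logan" = lg)
        for (f in list(f1, f2)) {
          if (!f$converged) {
            message(sprintf("non-converged %s fit excluded: %s %s %s",
                            f$model, sid, session, region))
          }
          fit_rows[[length(fit_rows) + 1]] <- data.frame(
            subject = sid, session = session, region = region,
            model = f$model,
            K1 = if (f$converged) f$params$K1 else NA_real_,
            k2 = if (f$converged) f$params$k2 else NA_real_,
            k3 = if (f$converged) f$params$k3 else NA_real_,
            k4 = if (f$converged) f$params$k4 else NA_real_,
            VT = f$vt, WRSS = f$wrss, AIC = f$aic,
            converged = f$converged)
        }
        fit_rows[[length(fit_rows) + 1]] <- data.frame(
          subject = sid, session = session, region = region,
          model = "logan", K1 = NA_real_, k2 = NA_real_, k3 = NA_real_,
          k4 = NA_real_, VT = lg$vt, WRSS = NA_real_, AIC = NA_real_,
          converged = TRUE)
      }
    }
  }
  fits_df <- do.call(rbind, fit_rows)
  paths <- list(fits = file.path(outdir, "fits.csv"))
  .write_csv_prov(fits_df, paths$fits, settings)

  # reliability over complete test-retest subjects
  reliability <- NULL
  diagnostics <- NULL
  complete <- Filter(function(sid) {
    all(c("test", "retest") %in% names(records[[sid]]))
  }, names(records))
  if (length(complete) >= 3) {
    long_vt <- cohort_metrics(records[complete], fits[complete],
                              metrics = "vt")
    reliability <- list()
    for (est in c("1tcm", "2tcm", "logan")) {
      sub <- long_vt[grepl(paste0("^VT_", est, "_"), long_vt$metric), ]
      sub$metric <- sub("^VT_[^_]+_", "", sub$metric)
      # regions left with fewer than 3 complete pairs after exclusions are
      # dropped from the table, with a log record
      pairs <- stats::aggregate(
        cbind(ok = is.finite(sub$test) & is.finite(sub$retest)) ~ metric,
        sub, sum)
      thin <- pairs$metric[pairs$ok < 3]
      if (length(thin)) {
        message(sprintf("%s: region(s) dropped from reliability (<3 pairs): %s",
                        est, paste(thin, collapse = ", ")))
        sub <- sub[!sub$metric %in% thin, ]
      }
      if (!nrow(sub)) next
      tab <- reliability_table(sub)
      tab <- rbind(tab,
                   cbind(summarize_reliability(tab)[, c("metric", "trv_mean",
                                                        "icc")],
                         n_subjects = NA, trv_sd = NA)[, names(tab)])
      reliability[[est]] <- tab
      .write_csv_prov(tab, file.path(outdir,
                                     sprintf("reliability_vt_%s.csv", est)),
                      settings)
    }
    diag_long <- cohort_metrics(records[complete], metrics = c("auc", "fp"))
    diagnostics <- reliability_table(diag_long)
    paths$diagnostics <- file.path(outdir, "reliability_diagnostics.csv")
    .write_csv_prov(diagnostics, paths$diagnostics, settings)
  } else {
    warning("fewer than 3 complete test-retest subjects; reliability skipped")
  }

  # time stability of the gray-matter VT (mean regional TAC, test session)
  ts_tab <- NULL
  if (!is.null(time_stability_durations)) {
    rows <- lapply(names(records), function(sid) {
      rec <- records[[sid]][["test"]]
      if (is.null(rec)) rec <- records[[sid]][[1]]
      gm <- rowMeans(vapply(rec$tacs, function(tc) tc$conc,
                            numeric(length(rec$tacs[[1]]$conc))))
      gm_tac <- tac("GM", rec$tacs[[1]]$frame_start,
                    rec$tacs[[1]]$frame_end, gm)
      pf <- fit_parent_fraction(rec$blood$parent_fraction)
      inp <- build_input(rec$blood$plasma, pf$model)
      cbind(subject = sid,
            time_stability(gm_tac, inp,
                           durations = time_stability_durations,
                           weights = weights))
    })
    ts_tab <- do.call(rbind, rows)
    paths$time_stability <- file.path(outdir, "time_stability.csv")
    .write_csv_prov(ts_tab, paths$time_stability, settings)
  }

  invisible(list(fits = fits_df, fit_objects = fits,
                 reliability = reliability, diagnostics = diagnostics,
                 time_stability = ts_tab, paths = paths))
}

#' Run the whole-body dosimetry analysis
#'
#' Adds voided urine back to the bladder curve, fits each organ's
#' decay-corrected retention with a sum of exponentials (AIC-selected
#' order), converts to residence times by re-applying physical decay,
#' multiplies by the S-value matrix, and applies the tissue-weighting
#' scheme for the effective dose.
#'
#' @param biodist Biodistribution as from [gen_biodistribution()]: list
#'   with `organs` (named [organ_retention] list) and `urine`.
#' @param s_matrix_path Path to the S-value CSV (see [read_smatrix()]).
#' @param weights_path Path to the tissue-weighting YAML (default: bundled
#'   ICRP-60 scheme).
#' @param outdir Output directory.
#' @param half_life Physical half-life in minutes.
#' @param seed Seed recorded in provenance.
#' @return Invisible list with `residence_times`, `doses`,
#'   `effective_dose`, `retention_fits`, and output paths.
#' @export
run_dosimetry <- function(biodist, s_matrix_path,
                          weights_path = system.file("extdata",
                                                     "icrp60_weights.yaml",
                                                     package = "petquant"),
                          outdir, half_life = HALF_LIFE_F18_MIN,
                          seed = 1L) {
  if (!length(biodist$organs)) stop("empty organ set")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  settings <- list(smatrix = basename(s_matrix_path),
                   weights = basename(weights_path), seed = seed)
  organs <- biodist$organs
  if ("urinary_bladder" %in% names(organs) && !is.null(biodist$urine)) {
    organs$urinary_bladder <- bladder_with_urine(organs$urinary_bladder,
                                                 biodist$urine)
  }
  rfits <- lapply(organs, fit_retention)
  taus <- vapply(rfits, residence_time, numeric(1), half_life = half_life)
  tau_df <- data.frame(organ = names(taus), residence_time_h = unname(taus),
                       n_exp = vapply(rfits, `[[`, numeric(1), "n_exp"),
                       converged = vapply(rfits, `[[`, logical(1),
                                          "converged"))
  s_matrix <- read_smatrix(s_matrix_path)
  doses <- absorbed_doses(taus, s_matrix)
  scheme <- tissue_weights(weights_path)
  # the effective dose needs the full weighting organ set; with reduced
  # (e.g. toy) S-matrices it is reported as NA
  ed <- tryCatch(effective_dose(doses, scheme)$effective_dose,
                 error = function(e) {
                   message("effective dose not computed: ",
                           conditionMessage(e))
                   NA_real_
                 })
  dose_df <- data.frame(organ = c(names(doses), "effective_dose"),
                        dose = c(unname(doses), ed))
  paths <- list(residence_times = file.path(outdir, "residence_times.csv"),
                doses = file.path(outdir, "dose_report.csv"))
  .write_csv_prov(tau_df, paths$residence_times, settings)
  .write_csv_prov(dose_df, paths$doses, settings)
  invisible(list(residence_times = taus, doses = doses,
                 effective_dose = ed, retention_fits = rfits,
                 scheme = scheme, paths = paths))
}
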