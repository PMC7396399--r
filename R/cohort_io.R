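# File-based exchange of cohorts and biodistributions, so every pipeline
# intermediate can live on disk (one TAC table and one blood table per
# subject-session, plus a metadata table).

#' Write a cohort of study records to a directory
#'
#' Produces `<subject>_<session>_tac.csv`, `<subject>_<session>_blood.csv`
#' and a `subjects.csv` metadata table (subject, session, injected dose,
#' body weight, f_P).
#'
#' @param records Cohort list as from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (sid in names(records)) {
    for (ses in names(records[[sid]])) {
      rec <- records[[sid]][[ses]]
      write_tac_table(rec$tacs,
                      file.path(dir, sprintf("%s_%s_tac.csv", sid, ses)))
      write_blood_table(rec$blood,
                        file.path(dir, sprintf("%s_%s_blood.csv", sid, ses)))
      meta[[length(meta) + 1]] <- data.frame(
        subject = sid, session = ses, injected_dose = rec$injected_dose,
        body_weight = if (is.null(rec$body_weight)) NA else rec$body_weight,
        f_P = if (is.null(rec$f_P)) NA else rec$f_P)
    }
  }
  utils::write.csv(do.call(rbind, meta), file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort of study records from a directory
#'
#' Inverse of [write_cohort()].
#'
#' @param dir Directory containing `subjects.csv` and the per-session
#'   TAC/blood tables.
#' @return Named cohort list: `records[[subject]][[session]]`.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "subjects.csv")
  if (!file.exists(meta_path)) stop("no subjects.csv in ", dir)
  meta <- utils::read.csv(meta_path)
  records <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject[i]; ses <- meta$session[i]
    tacs <- read_tac_table(file.path(dir, sprintf("%s_%s_tac.csv", sid, ses)))
    blood <- read_blood_table(file.path(dir,
                                        sprintf("%s_%s_blood.csv", sid, ses)))
    records[[sid]][[ses]] <- study_record(
      sid, ses, injected_dose = meta$injected_dose[i], tacs = tacs,
      blood = blood,
      body_weight = if (is.na(meta$body_weight[i])) NULL else
        meta$body_weight[i],
      f_P = if (is.na(meta$f_P[i])) NULL else meta$f_P[i])
  }
  records
}

#' Write a whole-body biodistribution to a directory
#'
#' Produces `organs.csv` (organ, t_hours, pid) and `urine.csv`
#' (t_hours, pid per void).
#'
#' @param biodist List as from [gen_biodistribution()].
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_biodistribution <- function(biodist, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- do.call(rbind, lapply(biodist$organs, function(o) {
    data.frame(organ = o$organ, t_hours = o$t, pid = o$pid)
  }))
  utils::write.csv(rows, file.path(dir, "organs.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(t_hours = biodist$urine$t,
                              pid = biodist$urine$pid),
                   file.path(dir, "urine.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' Read a whole-body biodistribution from a directory
#' @param dir Directory with `organs.csv` and optionally `urine.csv`.
#' @return List with `organs`, `urine`, `t_hours` as in
#'   [gen_biodistribution()].
#' @export
read_biodistribution <- function(dir) {
  organs_df <- utils::read.csv(file.path(dir, "organs.csv"))
  organs <- lapply(split(organs_df, organs_df$organ), function(d) {
    d <- d[order(d$t_hours), ]
    organ_retention(d$organ[1], d$t_hours, d$pid)
  })
  urine_path <- file.path(dir, "urine.csv")
  urine <- if (file.exists(urine_path)) {
    u <- utils::read.csv(urine_path)
    data.frame(t = u$t_hours, pid = u$pid)
  } else NULL
  list(organs = organs, urine = urine,
       t_hours = sort(unique(organs_df$t_hours)))
}
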