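#' Generate a synthetic neonatal cohort table with known truth
#'
#' Emulates the study's cohort structure: `n_subjects` infants contribute
#' `n_exams` exams (a subset is scanned twice), gestational age at birth and
#' postmenstrual age at scan are drawn from truncated normals reproducing
#' the study medians and ranges, and postnatal age (PNA = PMA - GA) is
#' non-negative by construction. Per tissue and parameter, values follow the
#' generating line plus a subject-level random intercept and residual noise.
#'
#' Optional flags emulate the study's data losses: exams without a B1 map
#' (no T2 estimate), a T2 exam rejected for motion, and subjects with severe
#' pathology whose rows are flagged `excluded` (with shifted values).
#'
#' @param n_subjects Number of unique subjects.
#' @param n_exams Total exams (`n_exams - n_subjects` subjects get a second
#'   scan).
#' @param gm A `generating_model`.
#' @param seed Integer seed.
#' @param tissues Tissues to tabulate (default: all generating-model rows).
#' @param parameters Parameters to tabulate, subset of `c("T1", "T2")`.
#' @param n_afi_missing Exams lacking a B1 map: their T2 rows get `NA`
#'   values and an `afi_missing` exclusion.
#' @param n_t2_motion_excluded Additional exams whose T2 rows are excluded
#'   for motion.
#' @param n_pathology Subjects flagged as severe pathology: all their rows
#'   are excluded and their values shifted upward (outliers).
#' @param pma_mean,pma_sd,pma_range PMA (weeks) truncated-normal parameters.
#' @param ga_mean,ga_sd,ga_range GA (weeks) truncated-normal parameters.
#' @return A data frame of class `cohort_table` with columns `subject_id`,
#'   `exam_id`, `ga_weeks`, `pma_weeks`, `pna_weeks`, `tissue`, `parameter`,
#'   `value_ms`, `excluded`, `exclude_reason`; the generating truth is in
#'   `attr(, "truth")`.
#' @export
make_cohort <- function(n_subjects = 34, n_exams = 40,
                        gm = generating_model(), seed = 1,
                        tissues = NULL, parameters = c("T1", "T2"),
                        n_afi_missing = 0, n_t2_motion_excluded = 0,
                        n_pathology = 0,
                        pma_mean = 39.7, pma_sd = 3.5, pma_range = c(33.5, 53),
                        ga_mean = 36, ga_sd = 3, ga_range = c(27.8, 42.2)) {
  stopifnot(n_subjects >= 2, n_exams >= n_subjects,
            n_exams <= 2 * n_subjects)
  if (is.null(tissues)) tissues <- gm$tissue_lines$tissue
  parameters <- match.arg(parameters, several.ok = TRUE)
  with_seed(seed, {
    ga <- rnorm_trunc(n_subjects, ga_mean, ga_sd, ga_range[1], ga_range[2])
    pma1 <- numeric(n_subjects)
    for (s in seq_len(n_subjects)) {
      repeat {
        p <- rnorm_trunc(1, pma_mean, pma_sd, pma_range[1], pma_range[2])
        if (p >= ga[s]) { pma1[s] <- p; break }
      }
    }
    n_rep <- n_exams - n_subjects
    rep_subj <- if (n_rep > 0) sample.int(n_subjects, n_rep) else integer()
    exams <- data.frame(subject_id = c(seq_len(n_subjects), rep_subj))
    exams$pma_weeks <- c(pma1, pmin(pma1[rep_subj] +
                                      stats::runif(n_rep, 1, 8), pma_range[2]))
    exams$ga_weeks <- ga[exams$subject_id]
    exams$exam_id <- seq_len(nrow(exams))
    exams$pna_weeks <- exams$pma_weeks - exams$ga_weeks

    path_subj <- if (n_pathology > 0) sample.int(n_subjects, n_pathology)
                 else integer()
    afi_missing <- if (n_afi_missing > 0)
      sample(exams$exam_id, n_afi_missing) else integer()
    t2_motion <- if (n_t2_motion_excluded > 0)
      sample(setdiff(exams$exam_id, afi_missing), n_t2_motion_excluded)
      else integer()

    tl <- gm$tissue_lines[gm$tissue_lines$tissue %in% tissues, ]
    rows <- list()
    intercepts <- list()
    for (pp in parameters) {
      sd_b <- gm$between_subject_sd_ms[[pp]]
      sd_e <- gm$residual_sd_ms[[pp]]
      for (r in seq_len(nrow(tl))) {
        tn <- tl$tissue[r]
        t40 <- if (pp == "T1") tl$t1_40wk_ms[r] else tl$t2_40wk_ms[r]
        dlt <- if (pp == "T1") tl$d1_ms_per_week[r] else tl$d2_ms_per_week[r]
        b <- stats::rnorm(n_subjects, 0, sd_b)
        val <- t40 + dlt * (exams$pma_weeks - 40) + b[exams$subject_id] +
          stats::rnorm(nrow(exams), 0, sd_e)
        path <- exams$subject_id %in% path_subj
        val[path] <- val[path] + 4 * sd_b   # pathological outlier shift
        excl <- path
        reason <- ifelse(path, "pathology", "")
        if (pp == "T2") {
          miss <- exams$exam_id %in% afi_missing
          val[miss] <- NA_real_
          excl <- excl | miss
          reason[miss] <- "afi_missing"
          mot <- exams$exam_id %in% t2_motion
          excl <- excl | mot
          reason[mot & !miss] <- "motion"
        }
        rows[[paste(pp, tn)]] <- data.frame(
          subject_id = exams$subject_id, exam_id = exams$exam_id,
          ga_weeks = exams$ga_weeks, pma_weeks = exams$pma_weeks,
          pna_weeks = exams$pna_weeks, tissue = tn, parameter = pp,
          value_ms = val, excluded = excl, exclude_reason = reason)
        intercepts[[paste(pp, tn)]] <-
          data.frame(parameter = pp, tissue = tn, t40wk_ms = t40,
                     delta_ms_per_week = dlt)
      }
    }
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    class(tbl) <- c("cohort_table", "data.frame")
    attr(tbl, "truth") <- list(
      lines = do.call(rbind, intercepts),
      between_subject_sd_ms = gm$between_subject_sd_ms,
      residual_sd_ms = gm$residual_sd_ms,
      exams = exams, pathology_subjects = path_subj,
      afi_missing_exams = afi_missing, t2_motion_exams = t2_motion,
      seed = seed)
    tbl
  })
}
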