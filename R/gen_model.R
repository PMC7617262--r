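#' Generating model for synthetic neonatal relaxation-time cohorts
#'
#' Per-tissue linear-in-age generating lines
#' `T(pma) = T_40wk + Delta * (pma - 40)` for T1 and T2 at 7 T, with
#' between-subject and residual standard deviations for cohort simulation.
#' The default lines are the package's reference values for the eight
#' tissues of the neonatal relaxometry slice; the variance components are
#' calibrated so simulated confidence-interval widths at around 37 usable
#' exams match the reference intervals (roughly +/- 40 ms for the white
#' matter T1 intercept).
#'
#' @param tissue_lines Data frame with columns `tissue`, `t1_40wk_ms`,
#'   `d1_ms_per_week`, `t2_40wk_ms`, `d2_ms_per_week`.
#' @param between_subject_sd_ms Named vector, SD of the subject-level random
#'   intercept for `T1` and `T2` (ms).
#' @param residual_sd_ms Named vector, residual SD for `T1` and `T2` (ms).
#' @return A list of class `generating_model`.
#' @export
generating_model <- function(tissue_lines = reference_tissue_lines(),
                             between_subject_sd_ms = c(T1 = 50, T2 = 3),
                             residual_sd_ms = c(T1 = 100, T2 = 4)) {
  stopifnot(all(c("tissue", "t1_40wk_ms", "d1_ms_per_week", "t2_40wk_ms",
                  "d2_ms_per_week") %in% names(tissue_lines)),
            all(c("T1", "T2") %in% names(between_subject_sd_ms)),
            all(c("T1", "T2") %in% names(residual_sd_ms)),
            all(tissue_lines$t1_40wk_ms > tissue_lines$t2_40wk_ms))
  structure(list(tissue_lines = tissue_lines,
                 between_subject_sd_ms = between_subject_sd_ms,
                 residual_sd_ms = residual_sd_ms),
            class = "generating_model")
}

#' Reference tissue relaxation lines at 7 T
#'
#' 40-week intercepts (ms) and weekly rates of change for T1 and T2 in the
#' eight tissues, used as the default generating model for synthetic
#' cohorts and phantoms.
#'
#' @return Data frame, one row per tissue.
#' @export
reference_tissue_lines <- function() {
  data.frame(
    tissue = c("cortical_gm", "white_matter", "brainstem", "cerebellum",
               "cerebellar_vermis", "basal_ganglia", "thalamus", "pvfwm"),
    t1_40wk_ms = c(2775, 2933, 2347, 2653, 2436, 2486, 2469, 3165),
    d1_ms_per_week = c(-12, -20, -11, -43, -30, -23, -23, -24),
    t2_40wk_ms = c(98, 119, 83, 99, 86, 90, 90, 146),
    d2_ms_per_week = c(-0.9, -1.8, -1.3, -4.1, -2.3, -2.0, -1.7, -1.3))
}

#' Tissue relaxation times at a given postmenstrual age
#'
#' Evaluates the generating lines `T = T_40wk + Delta * (pma - 40)`.
#' Ages outside the 33-53 week study range warn (extrapolation).
#'
#' @param tissue Tissue name (one of `reference_tissue_lines()$tissue`).
#' @param pma_weeks Postmenstrual age at scan, weeks.
#' @param gm A `generating_model`.
#' @return Named list with `t1_ms` and `t2_ms`.
#' @export
tissue_params <- function(tissue, pma_weeks, gm = generating_model()) {
  tl <- gm$tissue_lines
  row <- tl[tl$tissue == tissue, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown tissue: ", tissue)
  if (any(pma_weeks < 33 | pma_weeks > 53))
    warning("pma outside the 33-53 week range; extrapolating the linear model")
  list(t1_ms = row$t1_40wk_ms + row$d1_ms_per_week * (pma_weeks - 40),
       t2_ms = row$t2_40wk_ms + row$d2_ms_per_week * (pma_weeks - 40))
}
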