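#' Repeated office blood-pressure record
#'
#' Seated automated measurements taken every few minutes; summarization uses
#' only the final five, after the pressure has settled.
#'
#' @param sbp,dbp Systolic / diastolic pressures, mm Hg, in measurement order.
#' @param map Device-reported mean arterial pressures; if omitted, the
#'   oscillometric convention `MAP = DBP + (SBP - DBP)/3` is applied per
#'   measurement.
#' @param arm Which arm was used (informational).
#' @return Data frame of class `bp_record` with columns `sbp`, `dbp`, `map`.
#' @export
bp_record <- function(sbp, dbp, map = NULL, arm = NA_character_) {
  sbp <- as.numeric(sbp)
  dbp <- as.numeric(dbp)
  if (length(sbp) != length(dbp)) {
    stop("`sbp` and `dbp` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) || any(sbp <= dbp)) {
    stop("each measurement needs finite SBP > DBP", call. = FALSE)
  }
  if (is.null(map)) map <- dbp + (sbp - dbp) / 3
  structure(data.frame(sbp = sbp, dbp = dbp, map = as.numeric(map)),
            class = c("bp_record", "data.frame"),
            arm = arm)
}

#' Summarize a blood-pressure record
#'
#' Arithmetic mean of the last five measurements of SBP, DBP and MAP.
#'
#' @param record A [bp_record()] with at least 5 measurements.
#' @return List of class `bp_summary` with `sbp`, `dbp`, `map` (mm Hg) and
#'   `n_measurements`.
#' @export
summarize_bp <- function(record) {
  stopifnot(inherits(record, "bp_record"))
  n <- nrow(record)
  if (n < 5L) {
    stop("blood-pressure summary needs >= 5 measurements, got ", n,
         call. = FALSE)
  }
  idx <- (n - 4L):n
  structure(list(sbp = mean(record$sbp[idx]), dbp = mean(record$dbp[idx]),
                 map = mean(record$map[idx]), n_measurements = n),
            class = "bp_summary")
}

#' Classify hypertension status
#'
#' Hypertensive iff mean SBP >= 135 mm Hg or mean DBP >= 85 mm Hg (inclusive
#' thresholds) or the subject takes antihypertensive medication.
#'
#' @param summary A `bp_summary` (or any list with `sbp` and `dbp`).
#' @param on_meds Logical: on antihypertensive medication.
#' @param sbp_threshold,dbp_threshold Decision thresholds, mm Hg.
#' @return `"hypertensive"` or `"normotensive"`.
#' @export
classify_hypertension <- function(summary, on_meds = FALSE,
                                  sbp_threshold = 135, dbp_threshold = 85) {
  stopifnot(is.finite(summary$sbp), is.finite(summary$dbp))
  if (summary$sbp >= sbp_threshold || summary$dbp >= dbp_threshold ||
      isTRUE(on_meds)) "hypertensive" else "normotensive"
}

#' Assign blood-pressure subgroup
#'
#' Partitions subjects into normotensive (NT), controlled hypertension (CHT:
#' medicated with pressure below both thresholds), uncontrolled without
#' medication (UHT_minus) and uncontrolled despite medication (UHT_plus).
#' "Controlled" reuses the 135/85 mm Hg thresholds of the hypertension
#' definition.
#'
#' @inheritParams classify_hypertension
#' @param status Output of [classify_hypertension()] for this subject.
#' @return One of `"NT"`, `"CHT"`, `"UHT_minus"`, `"UHT_plus"`.
#' @export
assign_subgroup <- function(status, summary, on_meds = FALSE,
                            sbp_threshold = 135, dbp_threshold = 85) {
  status <- match.arg(status, c("normotensive", "hypertensive"))
  if (status == "normotensive") return("NT")
  high <- summary$sbp >= sbp_threshold || summary$dbp >= dbp_threshold
  if (!high) {
    if (!isTRUE(on_meds)) {
      stop("hypertensive status with below-threshold pressure requires medication",
           call. = FALSE)
    }
    return("CHT")
  }
  if (isTRUE(on_meds)) "UHT_plus" else "UHT_minus"
}

#' Grade basal-ganglia perivascular spaces
#'
#' Four-level grading of the PVS count in the slice with the most PVS:
#' grade 0 for <= 10, 1 for 11-25, 2 for 26-40, 3 for >= 41.
#'
#' @param count Nonnegative PVS count(s).
#' @return Integer grade(s) 0-3.
#' @export
pvs_grade <- function(count) {
  count <- as.numeric(count)
  if (any(!is.finite(count)) || any(count < 0)) {
    stop("PVS count must be >= 0", call. = FALSE)
  }
  ifelse(count <= 10, 0L, ifelse(count <= 25, 1L, ifelse(count <= 40, 2L, 3L)))
}

#' cSVD imaging-marker ratings
#'
#' @param fazekas_deep Deep white-matter hyperintensity Fazekas grade, 0-3.
#' @param periventricular_extends_deep Logical: irregular periventricular
#'   hyperintensities extending into the deep WM (Fazekas 3 pattern).
#' @param n_lacunes Number of (asymptomatic) lacunar infarcts.
#' @param n_bg_microbleeds Number of basal-ganglia microbleeds.
#' @param pvs_count_bg Basal-ganglia PVS count in the slice with most PVS.
#' @return List of class `marker_ratings`.
#' @export
marker_ratings <- function(fazekas_deep, periventricular_extends_deep = FALSE,
                           n_lacunes = 0, n_bg_microbleeds = 0,
                           pvs_count_bg = 0) {
  if (!fazekas_deep %in% 0:3) stop("`fazekas_deep` must be 0-3", call. = FALSE)
  if (n_lacunes < 0 || n_bg_microbleeds < 0 || pvs_count_bg < 0) {
    stop("marker counts must be >= 0", call. = FALSE)
  }
  structure(list(fazekas_deep = as.integer(fazekas_deep),
                 periventricular_extends_deep = isTRUE(periventricular_extends_deep),
                 n_lacunes = as.integer(n_lacunes),
                 n_bg_microbleeds = as.integer(n_bg_microbleeds),
                 pvs_count_bg = as.integer(pvs_count_bg)),
            class = "marker_ratings")
}

#' Global cSVD burden score
#'
#' Sum of four independent binary points (maximum 4): white-matter
#' hyperintensities ((early) confluent deep WMH, Fazekas 2-3, or irregular
#' periventricular WMH extending into the deep WM); one or more lacunes; one
#' or more basal-ganglia microbleeds; moderate-to-extensive basal-ganglia PVS
#' (grade >= 1, i.e. count >= 11).
#'
#' @param m A [marker_ratings()].
#' @return List: `total` (0-4) and logical `breakdown` (`wmh`, `lacunes`,
#'   `microbleeds`, `pvs`) for audit.
#' @export
csvd_score <- function(m) {
  stopifnot(inherits(m, "marker_ratings"))
  breakdown <- c(
    wmh = m$fazekas_deep >= 2L || m$periventricular_extends_deep,
    lacunes = m$n_lacunes >= 1L,
    microbleeds = m$n_bg_microbleeds >= 1L,
    pvs = pvs_grade(m$pvs_count_bg) >= 1L
  )
  list(total = as.integer(sum(breakdown)), breakdown = breakdown)
}

#' Score a cohort table
#'
#' Vectorized convenience over a subject-level data frame: adds hypertension
#' status, subgroup, PVS grade and global cSVD score columns. The table must
#' carry summarized `sbp`/`dbp` (means of the last five measurements),
#' `on_antihypertensives`, and the marker-rating columns.
#'
#' @param cohort Data frame with columns `sbp`, `dbp`, `on_antihypertensives`,
#'   `fazekas_deep`, `periventricular_extends_deep`, `n_lacunes`,
#'   `n_bg_microbleeds`, `pvs_count_bg`.
#' @return The table with added `status`, `subgroup`, `pvs_grade_bg`,
#'   `csvd_score` columns.
#' @export
score_cohort <- function(cohort) {
  need <- c("sbp", "dbp", "on_antihypertensives", "fazekas_deep",
            "periventricular_extends_deep", "n_lacunes", "n_bg_microbleeds",
            "pvs_count_bg")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  status <- character(n)
  subgroup <- character(n)
  score <- integer(n)
  for (i in seq_len(n)) {
    s <- list(sbp = cohort$sbp[i], dbp = cohort$dbp[i])
    status[i] <- classify_hypertension(s, cohort$on_antihypertensives[i])
    subgroup[i] <- assign_subgroup(status[i], s, cohort$on_antihypertensives[i])
    score[i] <- csvd_score(marker_ratings(
      cohort$fazekas_deep[i], cohort$periventricular_extends_deep[i],
      cohort$n_lacunes[i], cohort$n_bg_microbleeds[i],
      cohort$pvs_count_bg[i]
    ))$total
  }
  cohort$status <- status
  cohort$subgroup <- subgroup
  cohort$pvs_grade_bg <- pvs_grade(cohort$pvs_count_bg)
  cohort$csvd_score <- score
  cohort
}
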