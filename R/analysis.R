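#' Full-analysis configuration
#'
#' @param exposures Exposure columns: hypertension status and/or the
#'   continuous pressures.
#' @param measures Leakage measures to analyse (`ki`, `vp`).
#' @param rotations Covariates rotated in one at a time on top of age and
#'   sex; `"none"` is the base model.
#' @param base_covariates Always-included adjustment columns.
#' @param alpha Two-sided significance level (default 0.05, uncorrected
#'   across the ROI-by-exposure grid).
#' @param p_adjust `"none"` (default) or `"BH"` to additionally report
#'   Benjamini-Hochberg adjusted p-values across the grid.
#' @param outlier_scope `"subject"` (default): outliers detected on the base
#'   models are excluded study-wide; `"model"`: the rule is applied within
#'   each model separately.
#' @param rule The [outlier_rule()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(exposures = c("status_hypertensive", "sbp", "dbp", "map"),
                            measures = c("ki", "vp"),
                            rotations = c("none", "bmi", "alcohol_use",
                                          "smoking_history", "hematocrit",
                                          "on_antihypertensives",
                                          "cholesterol_medication",
                                          "csvd_score"),
                            base_covariates = c("age", "sex_male"),
                            alpha = 0.05,
                            p_adjust = c("none", "BH"),
                            outlier_scope = c("subject", "model"),
                            rule = outlier_rule()) {
  structure(list(exposures = exposures, measures = measures,
                 rotations = rotations, base_covariates = base_covariates,
                 alpha = alpha, p_adjust = match.arg(p_adjust),
                 outlier_scope = match.arg(outlier_scope), rule = rule),
            class = "analysis_config")
}

# Pivot a long ROI table (subject_id, roi, mean_ki, mean_vp) to wide columns
# <roi>.ki / <roi>.vp, one row per subject.
roi_wide <- function(roi) {
  need <- c("subject_id", "roi", "mean_ki", "mean_vp")
  miss <- setdiff(need, names(roi))
  if (length(miss)) {
    stop("ROI table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(roi$subject_id)
  out <- data.frame(subject_id = ids)
  for (r in unique(roi$roi)) {
    sub <- roi[roi$roi == r, ]
    out[[paste0(r, ".ki")]] <- sub$mean_ki[match(ids, sub$subject_id)]
    out[[paste0(r, ".vp")]] <- sub$mean_vp[match(ids, sub$subject_id)]
  }
  out
}

#' Run the cohort-level analysis
#'
#' Joins the subject table with per-subject ROI leakage summaries, then fits
#' every model of the study design: each leakage measure in each ROI against
#' each exposure, adjusted for age and sex, with each rotating covariate in
#' turn; plus the three-subgroup ANOVA with Tukey post hoc tests and the
#' pooled CHT-vs-UHT comparison per outcome. Subject outliers (deleted
#' studentized residual > 3.5 AND Cook's distance > 1 in a base model) are
#' excluded study-wide by default. The report is deterministic: identical
#' inputs give identical output.
#'
#' @param cohort Subject-level data frame (one row per subject) with
#'   `subject_id`, `age`, `sex_male`, `status` or `status_hypertensive`,
#'   `subgroup`, the pressures and the rotating covariates used.
#' @param roi Long ROI table: `subject_id`, `roi`, `mean_ki`, `mean_vp` (the
#'   `roi_stats.csv` format, or `$roi` of a [simulate_cohort()]).
#' @param config An [analysis_config()].
#' @return List of class `analysis_report`: `regressions` (one row per
#'   model), `subgroup` (ANOVA/Tukey and pooled comparison per outcome),
#'   `exclusions` (log of excluded subjects), `config`.
#' @export
run_full_analysis <- function(cohort, roi, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (!"status_hypertensive" %in% names(cohort) && "status" %in% names(cohort)) {
    cohort$status_hypertensive <- as.integer(cohort$status == "hypertensive")
  }
  if ("on_antihypertensives" %in% names(cohort)) {
    cohort$on_antihypertensives <- as.integer(cohort$on_antihypertensives)
  }
  wide <- roi_wide(roi)
  if (nrow(wide) == 0L || length(unique(roi$roi)) == 0L) {
    stop("ROI table is empty", call. = FALSE)
  }
  tab <- merge(cohort, wide, by = "subject_id", sort = TRUE)
  rois <- unique(roi$roi)
  outcomes <- as.vector(outer(rois, config$measures, paste, sep = "."))
  missing_out <- setdiff(outcomes, names(tab))
  if (length(missing_out)) {
    stop("missing ROI outcome column(s): ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }

  # study-wide outlier pass on the base (age+sex adjusted) models
  exclusions <- data.frame(subject_id = character(0), model = character(0),
                           rstudent = numeric(0), cooks = numeric(0))
  excl_ids <- NULL
  if (config$outlier_scope == "subject") {
    for (oc in outcomes) {
      for (ex in config$exposures) {
        diag <- tryCatch(
          detect_subject_outliers(tab, oc, c(ex, config$base_covariates),
                                  config$rule),
          error = function(e) NULL
        )
        if (!is.null(diag) && any(diag$flagged)) {
          f <- diag[diag$flagged, ]
          exclusions <- rbind(exclusions, data.frame(
            subject_id = f$subject_id, model = paste(oc, "~", ex),
            rstudent = f$rstudent, cooks = f$cooks))
        }
      }
    }
    excl_ids <- unique(exclusions$subject_id)
  }

  rows <- list()
  for (oc in outcomes) {
    for (ex in config$exposures) {
      for (rot in config$rotations) {
        rotating <- if (identical(rot, "none")) NULL else rot
        res <- tryCatch(
          fit_adjusted_regression(
            tab, oc, ex, covariates = config$base_covariates,
            rotating = rotating, rule = config$rule, exclude = excl_ids),
          error = function(e) e
        )
        parts <- strsplit(oc, ".", fixed = TRUE)[[1]]
        rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
          data.frame(roi = paste(parts[-length(parts)], collapse = "."),
                     measure = parts[length(parts)], outcome = oc,
                     exposure = ex, rotation = rot, beta_std = NA_real_,
                     beta_raw = NA_real_, p_value = NA_real_, n_used = NA_integer_,
                     n_excluded = NA_integer_, significant = NA,
                     note = conditionMessage(res))
        } else {
          data.frame(roi = paste(parts[-length(parts)], collapse = "."),
                     measure = parts[length(parts)], outcome = oc,
                     exposure = ex, rotation = rot, beta_std = res$beta_std,
                     beta_raw = res$beta_raw, p_value = res$p_value,
                     n_used = res$n_used,
                     n_excluded = length(res$excluded_ids),
                     significant = res$p_value < config$alpha, note = "")
        }
      }
    }
  }
  reg <- do.call(rbind, rows)
  if (config$p_adjust == "BH") {
    reg$p_bh <- stats::p.adjust(reg$p_value, method = "BH")
  }

  subgroup <- list()
  if ("subgroup" %in% names(tab) &&
      all(c("CHT", "UHT_minus", "UHT_plus") %in% tab$subgroup)) {
    st <- tab[is.null(excl_ids) | !tab$subject_id %in% excl_ids, , drop = FALSE]
    for (oc in outcomes) {
      an <- tryCatch(subgroup_anova_tukey(st, oc), error = function(e) NULL)
      po <- tryCatch(pooled_uht_comparison(st, oc), error = function(e) NULL)
      subgroup[[oc]] <- list(anova_tukey = an, pooled_uht = po)
    }
  }

  structure(list(regressions = reg, subgroup = subgroup,
                 exclusions = exclusions, config = config),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  sig <- x$regressions$significant & x$regressions$rotation == "none"
  cat("<analysis_report> ", nrow(x$regressions), " models; ",
      sum(sig, na.rm = TRUE), " significant base models at alpha = ",
      x$config$alpha, "; ", length(unique(x$exclusions$subject_id)),
      " subject(s) excluded\n", sep = "")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.csv` (one row per regression model), `subgroup.json`,
#' `report.json` (everything), and `exclusions.log`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$regressions, file.path(dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$subgroup, file.path(dir, "subgroup.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(regressions = report$regressions,
         subgroup = report$subgroup,
         exclusions = report$exclusions,
         alpha = report$config$alpha,
         outlier_scope = report$config$outlier_scope),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, dataframe = "rows")
  writeLines(
    if (nrow(report$exclusions)) {
      sprintf("%s excluded (model %s): rstudent=%.3f cooks=%.3f",
              report$exclusions$subject_id, report$exclusions$model,
              report$exclusions$rstudent, report$exclusions$cooks)
    } else "no subjects excluded",
    file.path(dir, "exclusions.log"))
  invisible(dir)
}
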