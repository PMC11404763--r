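#' Subject-outlier rule
#'
#' A data point is an outlier iff its deleted (externally) studentized
#' residual exceeds 3.5 in absolute value AND its Cook's distance exceeds 1
#' (both conditions, by design a conservative rule that fires on points that
#' are simultaneously discrepant and influential).
#'
#' @param studentized_threshold Threshold on |deleted studentized residual|.
#' @param cooks_threshold Threshold on Cook's distance.
#' @return A list of class `outlier_rule`.
#' @export
outlier_rule <- function(studentized_threshold = 3.5, cooks_threshold = 1) {
  stopifnot(studentized_threshold > 0, cooks_threshold > 0)
  structure(list(studentized_threshold = studentized_threshold,
                 cooks_threshold = cooks_threshold),
            class = "outlier_rule")
}

zscore <- function(v, label = "column") {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize constant ", label, call. = FALSE)
  }
  (v - mean(v)) / s
}

# Build the complete-case analysis frame for one model.
model_frame <- function(table, outcome, exposure, covariates, id_col) {
  cols <- c(outcome, exposure, covariates)
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- table[, c(id_col, cols), drop = FALSE]
  df <- df[stats::complete.cases(df[, cols, drop = FALSE]), , drop = FALSE]
  for (cl in cols) df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Compute regression outlier diagnostics
#'
#' Fits an ordinary least-squares model of `outcome` on the predictors and
#' returns per-row deleted (externally) studentized residuals and Cook's
#' distances, flagging rows that violate the [outlier_rule()] (both
#' thresholds exceeded).
#'
#' @param table Data frame with a subject id column.
#' @param outcome,predictors Column names (all treated as numeric).
#' @param rule An [outlier_rule()].
#' @param id_col Subject id column name.
#' @return Data frame: `subject_id`, `rstudent`, `cooks`, `flagged`.
#' @export
detect_subject_outliers <- function(table, outcome, predictors,
                                    rule = outlier_rule(),
                                    id_col = "subject_id") {
  df <- model_frame(table, outcome, predictors[1], predictors[-1], id_col)
  p <- length(predictors) + 1L
  if (nrow(df) < p + 2L) {
    stop("too few complete rows (", nrow(df),
         ") for leave-one-out diagnostics with ", p, " coefficients",
         call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(fml, data = df)
  rs <- stats::rstudent(fit)
  cd <- stats::cooks.distance(fit)
  data.frame(subject_id = df[[id_col]],
             rstudent = unname(rs), cooks = unname(cd),
             flagged = abs(rs) > rule$studentized_threshold &
               cd > rule$cooks_threshold,
             row.names = NULL)
}

#' Adjusted linear regression of a leakage measure
#'
#' Ordinary least squares of a z-scored outcome on z-scored predictors
#' (binary predictors are coded 0/1 before standardization), giving a
#' standardized exposure coefficient comparable across outcomes. Rows with
#' missing values are omitted; subject outliers under the [outlier_rule()]
#' are excluded and the model refit on the remaining, re-standardized rows.
#'
#' @param table Subject-level data frame.
#' @param outcome,exposure Column names.
#' @param covariates Adjustment columns (default age and male sex).
#' @param rotating Optional single extra covariate column (covariate
#'   rotation), or `NULL`.
#' @param rule An [outlier_rule()], or `NULL` to skip outlier exclusion.
#' @param exclude Subject ids to drop before fitting (e.g. study-level
#'   exclusions); when given, the per-model rule is not reapplied.
#' @param id_col Subject id column name.
#' @return List of class `regression_result`: `beta_std`, `se_std`,
#'   `p_value` (two-sided), `beta_raw`, `n_used`, `excluded_ids`, plus the
#'   model description.
#' @export
fit_adjusted_regression <- function(table, outcome, exposure,
                                    covariates = c("age", "sex_male"),
                                    rotating = NULL,
                                    rule = outlier_rule(),
                                    exclude = NULL,
                                    id_col = "subject_id") {
  covs <- unique(c(covariates, rotating))
  if (exposure %in% covs || outcome %in% c(exposure, covs)) {
    stop("outcome, exposure and covariates must be distinct columns",
         call. = FALSE)
  }
  df <- model_frame(table, outcome, exposure, covs, id_col)
  excluded <- character(0)
  if (!is.null(exclude)) {
    excluded <- intersect(df[[id_col]], exclude)
    df <- df[!df[[id_col]] %in% exclude, , drop = FALSE]
  } else if (!is.null(rule)) {
    diag <- detect_subject_outliers(df, outcome, c(exposure, covs), rule,
                                    id_col)
    excluded <- diag$subject_id[diag$flagged]
    df <- df[!df[[id_col]] %in% excluded, , drop = FALSE]
  }
  preds <- c(exposure, covs)
  if (nrow(df) < length(preds) + 3L) {
    stop("too few rows (", nrow(df), ") to fit ", length(preds) + 1L,
         " coefficients", call. = FALSE)
  }
  X <- as.matrix(df[, preds, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- preds[qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sd_y <- stats::sd(df[[outcome]])
  sd_x <- stats::sd(df[[exposure]])
  z <- as.data.frame(lapply(stats::setNames(c(outcome, preds),
                                            c(outcome, preds)),
                            function(cl) zscore(df[[cl]], cl)))
  fit <- stats::lm(stats::reformulate(preds, response = outcome), data = z)
  cf <- summary(fit)$coefficients
  structure(list(
    beta_std = unname(cf[exposure, "Estimate"]),
    se_std = unname(cf[exposure, "Std. Error"]),
    p_value = unname(cf[exposure, "Pr(>|t|)"]),
    beta_raw = unname(cf[exposure, "Estimate"]) * sd_y / sd_x,
    n_used = nrow(df),
    excluded_ids = excluded,
    outcome = outcome, exposure = exposure,
    covariates = covariates, rotating = rotating %||% "none"
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s ~ %s (+%s, rot %s): beta_std=%.3f, p=%.4g, n=%d\n",
              x$outcome, x$exposure, paste(x$covariates, collapse = "+"),
              x$rotating, x$beta_std, x$p_value, x$n_used))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post hoc tests across subgroups
#'
#' @param table Subject-level data frame with a grouping column.
#' @param outcome Outcome column name.
#' @param groups Group labels to compare (default the three hypertensive
#'   subgroups).
#' @param group_col Grouping column name.
#' @param drop_small Drop (with a warning) groups with fewer than 2 members
#'   instead of erroring.
#' @return List: `F`, `p_value`, `tukey` (data frame: `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`), `group_n`.
#' @export
subgroup_anova_tukey <- function(table, outcome,
                                 groups = c("CHT", "UHT_minus", "UHT_plus"),
                                 group_col = "subgroup", drop_small = FALSE) {
  df <- table[table[[group_col]] %in% groups &
                is.finite(as.numeric(table[[outcome]])), , drop = FALSE]
  tab <- table(df[[group_col]])
  small <- names(tab)[tab < 2L]
  if (length(small)) {
    if (!drop_small) {
      stop("group(s) with fewer than 2 members: ",
           paste(small, collapse = ", "), call. = FALSE)
    }
    warning("dropping small group(s): ", paste(small, collapse = ", "))
    df <- df[!df[[group_col]] %in% small, , drop = FALSE]
  }
  if (length(unique(df[[group_col]])) < 2L) {
    stop("need at least 2 groups with >= 2 members", call. = FALSE)
  }
  df$.g <- factor(df[[group_col]])
  df$.y <- as.numeric(df[[outcome]])
  fit <- stats::aov(.y ~ .g, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$.g
  list(F = s[1, "F value"], p_value = s[1, "Pr(>F)"],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       group_n = as.list(table(df$.g)))
}

#' Pooled uncontrolled-hypertension comparison
#'
#' Two-sample two-sided Student t test (equal variances) of the controlled
#' group (CHT) against the pooled uncontrolled groups (UHT- and UHT+).
#'
#' @inheritParams subgroup_anova_tukey
#' @return List: `t`, `p_value`, `mean_cht`, `mean_uht`, `mean_diff`
#'   (CHT - UHT), `direction` (`"CHT lower"` / `"CHT higher"` / `"equal"`),
#'   `n_cht`, `n_uht`.
#' @export
pooled_uht_comparison <- function(table, outcome, group_col = "subgroup") {
  y <- as.numeric(table[[outcome]])
  g <- table[[group_col]]
  cht <- y[g == "CHT" & is.finite(y)]
  uht <- y[g %in% c("UHT_minus", "UHT_plus") & is.finite(y)]
  if (length(cht) < 2L || length(uht) < 2L) {
    stop("CHT and pooled UHT groups must each have >= 2 members",
         call. = FALSE)
  }
  tt <- stats::t.test(cht, uht, var.equal = TRUE)
  d <- mean(cht) - mean(uht)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_cht = mean(cht), mean_uht = mean(uht), mean_diff = d,
       direction = if (d < 0) "CHT lower" else if (d > 0) "CHT higher" else "equal",
       n_cht = length(cht), n_uht = length(uht))
}
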