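#' Central-95% trimmed mean
#'
#' Outlier-corrected ROI mean: values inside the central 95% interval of the
#' ROI's own value distribution are retained and averaged. Two readings of
#' the interval are supported: `"percentile"` (default) keeps values in
#' `[P2.5, P97.5]` with linear-interpolation quantiles (type 7), and `"sd"`
#' keeps values in mean +/- 1.96 sd. Non-finite values are dropped first.
#'
#' @param values Numeric vector with at least one finite value.
#' @param method `"percentile"` or `"sd"`.
#' @return List: `mean` of retained values, `bounds` (lo, hi), `n_retained`,
#'   `n_total` (finite values considered), `method`.
#' @export
trimmed_mean_95 <- function(values, method = c("percentile", "sd")) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite values to summarize", call. = FALSE)
  bounds <- if (method == "percentile") {
    unname(stats::quantile(v, c(0.025, 0.975), type = 7))
  } else {
    m <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s)) s <- 0
    c(m - 1.96 * s, m + 1.96 * s)
  }
  keep <- v >= bounds[1] & v <= bounds[2]
  list(mean = mean(v[keep]), bounds = bounds,
       n_retained = sum(keep), n_total = length(v), method = method)
}

#' ROI specification
#'
#' Maps ROI names to one or more label values of a tissue mask. The default
#' set is the four tissue ROIs of the study design — cortical GM, deep GM,
#' their union (total GM) and total WM — for label conventions
#' cortical_gm = 1, deep_gm = 2, wm = 3. Extra entries (e.g. lobar cortex
#' parcels supplied by the user's segmentation) are plain additional rows.
#'
#' @param ... Named arguments, each a vector of integer labels, e.g.
#'   `roi_spec(total_gm = c(1, 2), cortical_gm = 1)`.
#' @return A named list of class `roi_spec`.
#' @export
roi_spec <- function(...) {
  spec <- list(...)
  if (!length(spec)) {
    spec <- list(total_gm = c(1L, 2L), total_wm = 3L,
                 cortical_gm = 1L, deep_gm = 2L)
  }
  if (is.null(names(spec)) || any(names(spec) == "") ||
      anyDuplicated(names(spec))) {
    stop("ROI names must be present and unique", call. = FALSE)
  }
  structure(lapply(spec, as.integer), class = "roi_spec")
}

#' Summarize leakage maps over regions of interest
#'
#' For each ROI, pools the Ki and vp of its valid-fit voxels and reports
#' their outlier-trimmed means ([trimmed_mean_95()]); Ki and vp are trimmed
#' independently since they are separate physiological measures. ROIs with
#' no valid voxels are flagged missing, not fabricated.
#'
#' @param maps A `leakage_maps` object from [fit_patlak_volume()].
#' @param labels 3D integer label array on the same grid.
#' @param spec A [roi_spec()].
#' @param method Trimming interval method, see [trimmed_mean_95()].
#' @param trim Set `FALSE` to skip outlier correction (plain means).
#' @return Data frame with one row per ROI: `roi`, `mean_ki`, `mean_vp`,
#'   `n_total`, `n_retained_ki`, `n_retained_vp`, `ki_lo`, `ki_hi`, `vp_lo`,
#'   `vp_hi`, `missing`; attribute `trim_method` records the interval choice.
#' @export
summarize_rois <- function(maps, labels, spec = roi_spec(),
                           method = c("percentile", "sd"), trim = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(maps, "leakage_maps"))
  if (!identical(as.integer(dim(labels)), as.integer(maps$dim))) {
    stop("label grid does not match the leakage maps", call. = FALSE)
  }
  if (!inherits(spec, "roi_spec")) spec <- do.call(roi_spec, as.list(spec))
  rows <- lapply(names(spec), function(nm) {
    sel <- (labels %in% spec[[nm]]) & maps$valid
    ki <- maps$ki[sel]
    vp <- maps$vp[sel]
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(roi = nm, mean_ki = NA_real_, mean_vp = NA_real_,
                        n_total = 0L, n_retained_ki = 0L, n_retained_vp = 0L,
                        ki_lo = NA_real_, ki_hi = NA_real_,
                        vp_lo = NA_real_, vp_hi = NA_real_, missing = TRUE))
    }
    if (trim) {
      tk <- trimmed_mean_95(ki, method)
      tv <- trimmed_mean_95(vp, method)
    } else {
      tk <- list(mean = mean(ki), bounds = range(ki), n_retained = n)
      tv <- list(mean = mean(vp), bounds = range(vp), n_retained = n)
    }
    data.frame(roi = nm, mean_ki = tk$mean, mean_vp = tv$mean,
               n_total = n, n_retained_ki = tk$n_retained,
               n_retained_vp = tv$n_retained,
               ki_lo = tk$bounds[1], ki_hi = tk$bounds[2],
               vp_lo = tv$bounds[1], vp_hi = tv$bounds[2], missing = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "trim_method") <- if (trim) method else "none"
  out
}
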