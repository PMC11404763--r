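#' Relaxometry parameters
#'
#' @param r1 Longitudinal relaxivity of the contrast agent in
#'   L·mmol^-1·s^-1. Default 4.5, a literature-typical value for gadobutrol
#'   at high field; override to match the agent and field strength in use.
#' @param hematocrit Hematocrit fraction in `[0, 1)` for blood-to-plasma
#'   conversion (default 0.45).
#' @return A list of class `relaxometry_params`.
#' @export
relaxometry_params <- function(r1 = 4.5, hematocrit = 0.45) {
  if (!is.finite(r1) || r1 <= 0) stop("`r1` must be > 0", call. = FALSE)
  if (!is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    stop("`hematocrit` must be in [0, 1)", call. = FALSE)
  }
  structure(list(r1 = r1, hematocrit = hematocrit),
            class = "relaxometry_params")
}

#' Contrast concentration from pre/post T1 maps
#'
#' Gadolinium shortens T1 in proportion to its concentration:
#' `1/T1_post = 1/T1_pre + r1 * C`, so
#' `C = (1/T1_post - 1/T1_pre) / r1` with T1 in seconds. Negative
#' concentrations (noise) are retained, not clipped, but counted in the QC
#' summary; voxels with nonpositive or non-finite T1 inside the mask are
#' invalidated (NA) and counted.
#'
#' @param pre,post Arrays of T1 in ms on the same grid.
#' @param params A [relaxometry_params()].
#' @param mask Optional logical/0-1 array restricting the conversion; voxels
#'   outside are NA and not QC-counted.
#' @return List: `concentration` (array, mmol/L), `qc` (list with
#'   `n_invalid_t1`, `n_negative_c`, `n_voxels`).
#' @export
concentration_from_t1 <- function(pre, post, params = relaxometry_params(),
                                  mask = NULL) {
  stopifnot(inherits(params, "relaxometry_params"))
  if (!identical(dim(pre), dim(post))) {
    stop("pre and post T1 volumes are on different grids", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, dim(pre) %||% length(pre))
  if (!identical(as.integer(dim(mask) %||% length(mask)),
                 as.integer(dim(pre) %||% length(pre)))) {
    stop("mask dimensions do not match the T1 grid", call. = FALSE)
  }
  m <- mask != 0
  bad <- m & (!is.finite(pre) | !is.finite(post) | pre <= 0 | post <= 0)
  conc <- array(NA_real_, dim(pre) %||% length(pre))
  ok <- m & !bad
  conc[ok] <- (1000 / post[ok] - 1000 / pre[ok]) / params$r1
  list(concentration = conc,
       qc = list(n_voxels = sum(m),
                 n_invalid_t1 = sum(bad),
                 n_negative_c = sum(conc[ok] < 0)))
}

#' Contrast concentration from a dynamic signal series
#'
#' Linearized low-concentration conversion of a baseline-normalized dynamic
#' signal: `dR1(t) = (S(t)/S0 - 1) / (T10_s * k)` with `S0` the mean of the
#' pre-injection baseline samples and `k` a dimensionless sequence scaling
#' constant, then `C = dR1 / r1`. The map is linear and exactly invertible,
#' and baseline samples map to concentration 0 by construction.
#'
#' @param signal Numeric vector (one voxel) or matrix (voxels x time) of
#'   dynamic signal intensities.
#' @param n_baseline Number of leading pre-injection samples (>= 1).
#' @param t10_ms Precontrast T1 in ms (scalar or one per voxel).
#' @param params A [relaxometry_params()].
#' @param k Sequence scaling constant (default 1).
#' @return List: `concentration` (same shape as `signal`, mmol/L), `qc`
#'   (list with `n_invalid_baseline`).
#' @export
concentration_from_dynamic <- function(signal, n_baseline, t10_ms,
                                       params = relaxometry_params(), k = 1) {
  stopifnot(inherits(params, "relaxometry_params"))
  if (n_baseline < 1L) stop("need at least 1 baseline sample", call. = FALSE)
  vec <- is.null(dim(signal))
  S <- if (vec) matrix(signal, nrow = 1L) else as.matrix(signal)
  if (n_baseline >= ncol(S)) {
    stop("`n_baseline` must be smaller than the number of samples", call. = FALSE)
  }
  s0 <- rowMeans(S[, seq_len(n_baseline), drop = FALSE])
  bad <- !is.finite(s0) | s0 <= 0
  t10_s <- rep_len(t10_ms, nrow(S)) / 1000
  dr1 <- (S / s0 - 1) / (t10_s * k)
  conc <- dr1 / params$r1
  conc[bad, ] <- NA_real_
  if (vec) conc <- drop(conc)
  list(concentration = conc, qc = list(n_invalid_baseline = sum(bad)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
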