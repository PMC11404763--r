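#' Integrate the plasma input function
#'
#' Area under the plasma concentration curve from injection (t = 0) to `t`
#' minutes post injection. The VIF is interpreted as a piecewise-linear
#' function of time through its samples and the integral of that interpolant
#' is computed exactly (the limit of a trapezoidal rule on any refinement of
#' the sample grid), so it is additive over subintervals to rounding error.
#'
#' @param vif A [vif_series()] with at least two samples.
#' @param t Time(s) in minutes post injection, within `[0, max sample time]`;
#'   values beyond the last sample raise an error (no silent extrapolation).
#' @return Numeric vector of integrals in mM·min.
#' @export
integrate_vif <- function(vif, t) {
  stopifnot(inherits(vif, "vif_series"))
  s <- vif$t_post_min
  cp <- vif$c_plasma_mM
  if (length(s) < 2L) stop("VIF needs at least 2 samples", call. = FALSE)
  t <- as.numeric(t)
  tmax <- max(s)
  if (any(!is.finite(t)) || any(t < 0) || any(t > tmax)) {
    stop("integration time outside [0, ", format(tmax),
         "] min post injection; refusing to extrapolate", call. = FALSE)
  }
  # knots restricted to [0, tmax], with an interpolated knot at 0
  c0 <- stats::approx(s, cp, xout = 0, rule = 2)$y
  keep <- s > 0
  s2 <- c(0, s[keep])
  c2 <- c(c0, cp[keep])
  cum <- c(0, cumsum(diff(s2) * (c2[-length(c2)] + c2[-1]) / 2))
  idx <- findInterval(t, s2, rightmost.closed = TRUE)
  ct <- stats::approx(s2, c2, xout = t)$y
  cum[idx] + (t - s2[idx]) * (c2[idx] + ct) / 2
}

#' Patlak fit configuration
#'
#' @param cp_threshold_frac Samples with plasma concentration at or below this
#'   fraction of the plasma peak are excluded (default 0.01), which also
#'   drops pre-arrival samples where the Patlak ratios blow up.
#' @param t_min_post Earliest post-injection time (minutes) eligible for the
#'   fit window (default 0).
#' @param use_dynamic,use_t1map Include dynamic and/or late T1-map samples in
#'   the fit window. The sparse protocol's premise is that the two late
#'   T1-map points anchor the slope; both kinds are used by default.
#' @return A list of class `patlak_fit_config`.
#' @export
patlak_fit_config <- function(cp_threshold_frac = 0.01, t_min_post = 0,
                              use_dynamic = TRUE, use_t1map = TRUE) {
  stopifnot(cp_threshold_frac >= 0, t_min_post >= 0)
  structure(list(cp_threshold_frac = cp_threshold_frac,
                 t_min_post = t_min_post,
                 use_dynamic = use_dynamic, use_t1map = use_t1map),
            class = "patlak_fit_config")
}

# Sample-inclusion mask shared by every voxel of a study.
patlak_included <- function(vif, config) {
  cp <- vif$c_plasma_mM
  thr <- config$cp_threshold_frac * max(cp)
  vif$kind != "pre_baseline" &
    vif$t_post_min > 0 &
    vif$t_post_min >= config$t_min_post &
    cp > thr &
    ((config$use_dynamic & vif$kind == "dynamic") |
       (config$use_t1map & vif$kind == "t1map"))
}

#' Patlak transform of a tissue concentration curve
#'
#' Maps a tissue curve and its vascular input function to Patlak coordinates
#' `x(t) = integral(Cp, 0..t) / Cp(t)` (minutes) and `y(t) = Ct(t) / Cp(t)`
#' (dimensionless). On these coordinates an irreversible-uptake tissue obeys
#' `y = Ki x + vp`, so an ordinary least-squares line gives the leakage rate
#' (slope) and the plasma volume fraction (intercept).
#'
#' @param ct Numeric vector of tissue concentrations (mM), one per VIF sample.
#' @param vif A [vif_series()].
#' @param config A [patlak_fit_config()].
#' @return Data frame of class `patlak_points` with columns `t_post_min`,
#'   `kind`, `x`, `y`, `included`.
#' @export
patlak_transform <- function(ct, vif, config = patlak_fit_config()) {
  stopifnot(inherits(vif, "vif_series"), inherits(config, "patlak_fit_config"))
  ct <- as.numeric(ct)
  if (length(ct) != nrow(vif)) {
    stop("tissue curve has ", length(ct), " samples but VIF has ", nrow(vif),
         call. = FALSE)
  }
  incl <- patlak_included(vif, config)
  x <- rep(NA_real_, length(ct))
  y <- rep(NA_real_, length(ct))
  if (any(incl)) {
    cp <- vif$c_plasma_mM[incl]
    x[incl] <- integrate_vif(vif, vif$t_post_min[incl]) / cp
    y[incl] <- ct[incl] / cp
  }
  structure(
    data.frame(t_post_min = vif$t_post_min, kind = vif$kind,
               x = x, y = y, included = incl),
    class = c("patlak_points", "data.frame")
  )
}

#' Ordinary least-squares Patlak fit
#'
#' Fits `y = Ki x + vp` through the included points. At least two included
#' points with distinct `x` are required; otherwise the fit is flagged
#' invalid rather than fabricated.
#'
#' @param points A `patlak_points` data frame from [patlak_transform()], or
#'   any data frame with columns `x`, `y`, `included`.
#' @return List of class `patlak_fit`: `ki` (min^-1), `vp` (fraction), `rms`
#'   residual, `n_points` used, `valid` flag.
#' @export
fit_patlak <- function(points) {
  use <- points$included & is.finite(points$x) & is.finite(points$y)
  xi <- points$x[use]
  yi <- points$y[use]
  n <- length(xi)
  invalid <- list(ki = NA_real_, vp = NA_real_, rms = NA_real_,
                  n_points = n, valid = FALSE)
  if (n < 2L) return(structure(invalid, class = "patlak_fit"))
  mx <- sum(xi) / n
  my <- sum(yi) / n
  dx <- xi - mx
  sxx <- sum(dx * dx)
  if (sxx <= 0) return(structure(invalid, class = "patlak_fit"))
  ki <- sum(dx * (yi - my)) / sxx
  vp <- my - ki * mx
  r <- yi - (vp + ki * xi)
  structure(list(ki = ki, vp = vp, rms = sqrt(sum(r * r) / n),
                 n_points = n, valid = TRUE),
            class = "patlak_fit")
}

#' Voxelwise Patlak fit of a 4D concentration volume
#'
#' Applies [patlak_transform()] and [fit_patlak()] to every voxel inside the
#' mask. The regression is vectorized across voxels (the Patlak abscissa and
#' inclusion window are shared by all voxels of a study) with arithmetic
#' ordered to reproduce the per-voxel [fit_patlak()] result bit for bit;
#' voxels containing non-finite samples fall back to the per-voxel path so
#' partial curves are still fit on their finite points.
#'
#' @param conc4d 4D array (x, y, z, time) of tissue concentration in mM.
#' @param vif A [vif_series()] whose samples match the 4th dimension.
#' @param mask Optional 3D logical/0-1 array of voxels to fit (default: all).
#' @param config A [patlak_fit_config()].
#' @return Object of class `leakage_maps`: list of 3D arrays `ki`, `vp`,
#'   `rms`, `n_points`, `valid`. Voxels outside the mask or with failed fits
#'   have `valid = FALSE` and NA parameters; nothing is silently zeroed.
#' @export
fit_patlak_volume <- function(conc4d, vif, mask = NULL,
                              config = patlak_fit_config()) {
  stopifnot(inherits(vif, "vif_series"))
  d <- dim(conc4d)
  if (is.null(d) || length(d) != 4L) {
    stop("`conc4d` must be a 4D array (x, y, z, time)", call. = FALSE)
  }
  if (d[4] != nrow(vif)) {
    stop("volume has ", d[4], " time points but VIF has ", nrow(vif),
         call. = FALSE)
  }
  sp <- d[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, sp)
  } else {
    if (!identical(as.integer(dim(mask)), as.integer(sp))) {
      stop("mask dimensions do not match the volume grid", call. = FALSE)
    }
    mask <- array(as.logical(mask != 0), sp)
  }
  na3 <- array(NA_real_, sp)
  maps <- list(ki = na3, vp = na3, rms = na3,
               n_points = array(0L, sp), valid = array(FALSE, sp))

  vox <- which(mask)
  if (length(vox)) {
    incl <- patlak_included(vif, config)
    n <- sum(incl)
    Y <- matrix(conc4d, ncol = d[4])[vox, , drop = FALSE]
    if (n >= 2L) {
      cp <- vif$c_plasma_mM[incl]
      xi <- integrate_vif(vif, vif$t_post_min[incl]) / cp
      V <- length(vox)
      Yi <- Y[, incl, drop = FALSE] / rep(cp, each = V)
      finite <- rowSums(!is.finite(Yi)) == 0L
      mx <- sum(xi) / n
      dx <- xi - mx
      sxx <- sum(dx * dx)
      if (sxx <= 0) { # degenerate shared abscissa: every fit is invalid
        maps$n_points[vox] <- n
        vox <- vox[0]
        finite <- logical(0)
      }
      if (any(finite)) {
        Yf <- Yi[finite, , drop = FALSE]
        my <- rowSums(Yf) / n
        num <- rowSums((Yf - my) * rep(dx, each = nrow(Yf)))
        ki <- num / sxx
        vp <- my - ki * mx
        R <- Yf - (vp + outer(ki, xi))
        rms <- sqrt(rowSums(R * R) / n)
        vf <- vox[finite]
        maps$ki[vf] <- ki
        maps$vp[vf] <- vp
        maps$rms[vf] <- rms
        maps$n_points[vf] <- n
        maps$valid[vf] <- TRUE
      }
      # salvage voxels with non-finite samples through the scalar path
      for (v in vox[!finite]) {
        idx <- arrayInd(v, sp)
        pts <- patlak_transform(conc4d[idx[1], idx[2], idx[3], ], vif, config)
        f <- fit_patlak(pts)
        maps$ki[v] <- f$ki
        maps$vp[v] <- f$vp
        maps$rms[v] <- f$rms
        maps$n_points[v] <- f$n_points
        maps$valid[v] <- f$valid
      }
    } else {
      maps$n_points[vox] <- n
    }
  }
  structure(c(maps, list(dim = sp)), class = "leakage_maps")
}

#' @export
print.leakage_maps <- function(x, ...) {
  cat("<leakage_maps> grid ", paste(x$dim, collapse = "x"), "; ",
      sum(x$valid), " valid fits; median Ki ",
      format(stats::median(x$ki[x$valid]), digits = 3), " min^-1, median vp ",
      format(stats::median(x$vp[x$valid]), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write / read leakage maps as NIfTI volumes
#'
#' Writes `ki.nii.gz`, `vp.nii.gz`, `rms.nii.gz` (float32), `n_points.nii.gz`
#' and `valid.nii.gz` (int16) under `dir`.
#'
#' @param maps A `leakage_maps` object.
#' @param dir Output directory (created if needed).
#' @return `write_leakage_maps` returns `dir` invisibly; `read_leakage_maps`
#'   returns a `leakage_maps` object.
#' @export
write_leakage_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "leakage_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(maps$ki, datatype = "float"),
                     file.path(dir, "ki.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$vp, datatype = "float"),
                     file.path(dir, "vp.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$rms, datatype = "float"),
                     file.path(dir, "rms.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(maps$n_points), maps$dim),
                                     datatype = "int16"),
                     file.path(dir, "n_points.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(maps$valid), maps$dim),
                                     datatype = "int16"),
                     file.path(dir, "valid.nii.gz"))
  invisible(dir)
}

#' @rdname write_leakage_maps
#' @export
read_leakage_maps <- function(dir) {
  rd <- function(name) nifti_array(file.path(dir, name))
  ki <- rd("ki.nii.gz")
  np <- rd("n_points.nii.gz")
  valid <- rd("valid.nii.gz")
  structure(list(ki = ki, vp = rd("vp.nii.gz"), rms = rd("rms.nii.gz"),
                 n_points = array(as.integer(np), dim(np)),
                 valid = array(valid != 0, dim(valid)),
                 dim = dim(ki)),
            class = "leakage_maps")
}

# Read a NIfTI volume as a bare numeric array (image metadata dropped).
nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}
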