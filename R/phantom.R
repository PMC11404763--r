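#' Ground-truth tissue region for phantom studies
#'
#' @param label Integer mask value (unique per region).
#' @param name Tissue name, e.g. `"cortical_gm"`, `"deep_gm"`, `"wm"`,
#'   `"sss_blood"`.
#' @param ki_true Leakage rate, min^-1 (>= 0).
#' @param vp_true Plasma volume fraction in `[0, 1]`.
#' @param t10_ms Precontrast T1 in ms (> 0).
#' @return A one-row data frame of class `ground_truth_region`.
#' @export
ground_truth_region <- function(label, name, ki_true, vp_true, t10_ms) {
  stopifnot(length(label) == 1L, length(name) == 1L)
  if (!is.finite(ki_true) || ki_true < 0) stop("`ki_true` must be >= 0", call. = FALSE)
  if (!is.finite(vp_true) || vp_true < 0 || vp_true > 1) {
    stop("`vp_true` must be in [0, 1]", call. = FALSE)
  }
  if (!is.finite(t10_ms) || t10_ms <= 0) stop("`t10_ms` must be > 0", call. = FALSE)
  structure(data.frame(label = as.integer(label), name = as.character(name),
                       ki_true = ki_true, vp_true = vp_true, t10_ms = t10_ms),
            class = c("ground_truth_region", "data.frame"))
}

#' Default phantom regions
#'
#' Literature-typical truths for subtle BBB leakage: cortical grey matter,
#' deep grey matter and white matter with Ki in the 1e-4 to 2e-3 min^-1 range
#' and vp of 1-2.5%.
#'
#' @return Data frame of regions (one per row).
#' @export
default_phantom_regions <- function() {
  rbind(
    ground_truth_region(1L, "cortical_gm", ki_true = 1.5e-3, vp_true = 0.025, t10_ms = 2000),
    ground_truth_region(2L, "deep_gm",     ki_true = 1.0e-3, vp_true = 0.020, t10_ms = 1700),
    ground_truth_region(3L, "wm",          ki_true = 4.0e-4, vp_true = 0.010, t10_ms = 1300)
  )
}

#' Forward Patlak tissue curve
#'
#' Tissue concentration of an irreversible-uptake (Patlak) tissue:
#' `Ct(t) = Ki * integral(Cp, 0..t) + vp * Cp(t)` for t after injection and 0
#' before, evaluated with the same exact piecewise-linear plasma integral used
#' by the fitting code ([integrate_vif()]).
#'
#' @param vif A [vif_series()].
#' @param ki Leakage rate, min^-1 (>= 0).
#' @param vp Plasma volume fraction in `[0, 1]`.
#' @param schedule Optional [acquisition_schedule()]; defaults to the VIF's
#'   own schedule, and must match it sample for sample otherwise.
#' @return Numeric vector of tissue concentrations (mM), one per sample.
#' @export
forward_tissue_curve <- function(vif, ki, vp, schedule = NULL) {
  stopifnot(inherits(vif, "vif_series"))
  if (!is.finite(ki) || ki < 0) stop("`ki` must be >= 0", call. = FALSE)
  if (!is.finite(vp) || vp < 0 || vp > 1) stop("`vp` must be in [0, 1]", call. = FALSE)
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "acquisition_schedule"))
    if (!isTRUE(all.equal(schedule$times_min, vif$time_min))) {
      stop("`schedule` times do not match the VIF samples", call. = FALSE)
    }
  }
  t_post <- vif$t_post_min
  ct <- numeric(length(t_post))
  post <- t_post > 0
  if (any(post)) {
    ct[post] <- ki * integrate_vif(vif, t_post[post]) + vp * vif$c_plasma_mM[post]
  }
  ct
}

#' Simulate a digital phantom study
#'
#' Builds a 4D concentration volume whose voxels follow the forward Patlak
#' model of their region's ground truth plus i.i.d. Gaussian concentration
#' noise, together with the label mask, VIF and truth table. Regions are laid
#' out as contiguous slabs along the first axis, sized proportionally.
#'
#' @param schedule An [acquisition_schedule()].
#' @param regions Data frame of regions as from [default_phantom_regions()];
#'   labels must be unique.
#' @param shape Integer vector of 3 grid dimensions, each >= 4.
#' @param noise_sd Gaussian concentration noise sd in mM (default 0.002,
#'   a realistic level for this class of protocol; set 0 for noise-free).
#' @param vif Optional [vif_series()]; simulated with defaults if missing.
#' @param seed Optional integer seed; identical seeds give identical phantoms.
#' @return Object of class `phantom_study`: list with `concentration` (4D
#'   array, mM), `labels` (3D integer array), `vif`, `truth` (regions data
#'   frame), `schedule`, `noise_sd`, `seed`.
#' @export
simulate_phantom <- function(schedule, regions = default_phantom_regions(),
                             shape = c(10, 10, 10), noise_sd = 0.002,
                             vif = NULL, seed = NULL) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) {
    stop("`shape` must be 3 dimensions, each >= 4", call. = FALSE)
  }
  if (anyDuplicated(regions$label)) {
    stop("region labels must be unique", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(vif)) vif <- simulate_vif(schedule)
  nt <- length(schedule$times_min)
  nr <- nrow(regions)

  # contiguous slabs along x, one per region, proportional to 1/nr each
  cuts <- round(seq(0, shape[1], length.out = nr + 1L))
  labels <- array(0L, shape)
  for (i in seq_len(nr)) {
    if (cuts[i + 1L] > cuts[i]) {
      labels[(cuts[i] + 1L):cuts[i + 1L], , ] <- regions$label[i]
    }
  }

  conc <- array(0, c(shape, nt))
  flat <- matrix(conc, ncol = nt)
  lab_flat <- as.vector(labels)
  for (i in seq_len(nr)) {
    curve <- forward_tissue_curve(vif, regions$ki_true[i], regions$vp_true[i])
    idx <- which(lab_flat == regions$label[i])
    flat[idx, ] <- rep(curve, each = length(idx))
  }
  if (noise_sd > 0) {
    flat <- with_seed(seed, flat + stats::rnorm(length(flat), 0, noise_sd))
  }
  conc <- array(flat, c(shape, nt))

  structure(list(concentration = conc, labels = labels, vif = vif,
                 truth = as.data.frame(regions), schedule = schedule,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat("<phantom_study> grid ", paste(dim(x$labels), collapse = "x"), ", ",
      length(x$schedule$times_min), " time points, ", nrow(x$truth),
      " regions, noise sd ", format(x$noise_sd), " mM\n", sep = "")
  invisible(x)
}

#' Write / read a phantom study on disk
#'
#' Concentration as 4D float32 NIfTI, labels as int16 NIfTI, VIF / truth /
#' schedule as CSV. Labels, truth table and schedule round-trip losslessly;
#' the concentration volume is quantized to float32 by the format.
#'
#' @param study A `phantom_study`.
#' @param dir Output directory (created if needed).
#' @return `write_phantom` returns `dir` invisibly; `read_phantom` returns a
#'   `phantom_study` (without the original noise/seed metadata).
#' @export
write_phantom <- function(study, dir) {
  stopifnot(inherits(study, "phantom_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(study$concentration, datatype = "float"),
                     file.path(dir, "concentration.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(study$labels, datatype = "int16"),
                     file.path(dir, "labels.nii.gz"))
  write_vif_csv(study$vif, file.path(dir, "vif.csv"))
  utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(time_min = study$schedule$times_min,
               kind = study$schedule$kinds,
               injection_min = study$schedule$injection_min),
    file.path(dir, "schedule.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  conc <- nifti_array(file.path(dir, "concentration.nii.gz"))
  labels <- nifti_array(file.path(dir, "labels.nii.gz"))
  vif <- read_vif_csv(file.path(dir, "vif.csv"))
  truth <- utils::read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE)
  structure(list(concentration = conc,
                 labels = array(as.integer(labels), dim(labels)),
                 vif = vif, truth = truth, schedule = attr(vif, "schedule"),
                 noise_sd = NA_real_, seed = NULL),
            class = "phantom_study")
}
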