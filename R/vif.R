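#' Construct a vascular input function series
#'
#' A VIF records the contrast-agent concentration in whole blood and in blood
#' plasma at every sample of an acquisition schedule. In vivo it is measured
#' in a large vessel (here the superior sagittal sinus); plasma concentration
#' is whole-blood concentration divided by (1 - hematocrit).
#'
#' @param schedule An [acquisition_schedule()].
#' @param c_blood_mM Whole-blood concentration (mmol/L) at each schedule sample.
#' @param hematocrit Red-cell volume fraction in `[0, 1)`.
#' @return A data frame of class `vif_series` with columns `time_min`
#'   (since series start), `t_post_min` (since injection), `c_blood_mM`,
#'   `c_plasma_mM`, and attributes `schedule` and `hematocrit`.
#' @export
vif_series <- function(schedule, c_blood_mM, hematocrit) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  if (length(c_blood_mM) != length(schedule$times_min)) {
    stop("`c_blood_mM` must have one value per schedule sample", call. = FALSE)
  }
  c_plasma <- blood_to_plasma(c_blood_mM, hematocrit)
  out <- data.frame(
    time_min = schedule$times_min,
    t_post_min = post_injection_times(schedule),
    kind = schedule$kinds,
    c_blood_mM = as.numeric(c_blood_mM),
    c_plasma_mM = c_plasma
  )
  attr(out, "schedule") <- schedule
  attr(out, "hematocrit") <- hematocrit
  class(out) <- c("vif_series", "data.frame")
  out
}

#' Convert whole-blood to plasma concentration
#'
#' Contrast agent stays in plasma, so the plasma concentration exceeds the
#' whole-blood one by the factor 1/(1 - Hct).
#'
#' @param c_blood Whole-blood concentration(s), mmol/L.
#' @param hematocrit Hematocrit fraction in `[0, 1)`.
#' @return Plasma concentration(s), mmol/L.
#' @export
blood_to_plasma <- function(c_blood, hematocrit) {
  if (!is.numeric(hematocrit) || length(hematocrit) != 1L ||
      !is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    stop("`hematocrit` must be a single value in [0, 1)", call. = FALSE)
  }
  as.numeric(c_blood) / (1 - hematocrit)
}

#' Simulate a vascular input function
#'
#' Generates a literature-shaped plasma input: a gamma-variate first-pass
#' bolus plus a biexponentially decaying recirculation/washout tail, scaled so
#' the whole-blood peak equals `peak_mM`. Concentration is exactly zero at all
#' pre-injection baseline samples and for a short arrival delay after
#' injection, rises to the peak, then decays monotonically.
#'
#' @param schedule An [acquisition_schedule()].
#' @param peak_mM Peak whole-blood concentration in mmol/L (default 3, typical
#'   for a small compact gadolinium bolus).
#' @param decay_params Named list of shape parameters: `arrival_min` bolus
#'   arrival delay after injection; `t_peak_min` time-to-peak of the
#'   first-pass gamma variate; `alpha` gamma shape; `washout_frac` amplitude
#'   of the recirculation tail relative to the first-pass peak;
#'   `tau_rise_min` tail rise constant; `m_fast`, `m_slow` (min^-1) and
#'   `w_fast` the biexponential washout.
#' @param hematocrit Hematocrit fraction in `[0, 1)`; plasma = blood/(1-Hct).
#' @param noise_sd Additive Gaussian noise (mmol/L) on post-arrival blood
#'   samples; default 0 (the VIF is a region-averaged, low-noise measurement).
#' @param seed Optional integer seed; identical seeds give identical series.
#' @return A [vif_series()].
#' @export
simulate_vif <- function(schedule, peak_mM = 3,
                         decay_params = list(), hematocrit = 0.45,
                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  if (!is.numeric(peak_mM) || peak_mM < 0) {
    stop("`peak_mM` must be >= 0", call. = FALSE)
  }
  p <- utils::modifyList(
    list(arrival_min = 0.1, t_peak_min = 0.75, alpha = 3,
         washout_frac = 0.35, tau_rise_min = 0.5,
         m_fast = 0.35, m_slow = 0.015, w_fast = 0.55),
    decay_params
  )
  shape <- function(s) {
    out <- numeric(length(s))
    pos <- s > 0
    sp <- s[pos]
    bolus <- (sp / p$t_peak_min)^p$alpha * exp(p$alpha * (1 - sp / p$t_peak_min))
    tail <- (1 - exp(-sp / p$tau_rise_min)) *
      (p$w_fast * exp(-p$m_fast * sp) + (1 - p$w_fast) * exp(-p$m_slow * sp))
    out[pos] <- bolus + p$washout_frac * tail
    out
  }
  t_post <- post_injection_times(schedule)
  s <- t_post - p$arrival_min
  # normalize on a dense grid so the stated peak holds whatever the samples are
  grid <- seq(0, max(max(s), p$t_peak_min * 4), length.out = 4096L)
  peak_shape <- max(shape(grid))
  c_blood <- if (peak_shape > 0) peak_mM * shape(s) / peak_shape else shape(s) * 0
  if (noise_sd > 0) {
    c_blood <- with_seed(seed, {
      c_blood + ifelse(s > 0, stats::rnorm(length(s), 0, noise_sd), 0)
    })
  }
  vif_series(schedule, c_blood, hematocrit)
}

#' Write / read a VIF as CSV
#'
#' Plain-text interchange format with columns `time_min`, `t_post_min`,
#' `kind`, `c_blood_mM`, `c_plasma_mM` plus a `hematocrit` column repeated on
#' every row so the file is self-contained.
#'
#' @param vif A [vif_series()].
#' @param path File path.
#' @return `write_vif_csv` returns `path` invisibly; `read_vif_csv` returns a
#'   [vif_series()].
#' @export
write_vif_csv <- function(vif, path) {
  stopifnot(inherits(vif, "vif_series"))
  df <- as.data.frame(vif)
  df$hematocrit <- attr(vif, "hematocrit")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vif_csv
#' @export
read_vif_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "t_post_min", "kind", "c_blood_mM", "hematocrit")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("VIF csv missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  inj <- df$time_min[1] - df$t_post_min[1]
  sched <- acquisition_schedule(df$time_min, df$kind, injection_min = inj)
  vif_series(sched, df$c_blood_mM, hematocrit = df$hematocrit[1])
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
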