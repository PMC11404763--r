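#' Acquisition schedule for a sparse DCE-MRI protocol
#'
#' Describes when each sample of a dynamic contrast-enhanced series was
#' acquired and what kind of sample it is. The protocol this models acquires a
#' handful of pre-injection baseline volumes, a short dynamic series for a few
#' minutes after contrast injection, and a small number of late quantitative
#' T1-map samples, the last roughly 25 minutes after the start of injection.
#'
#' @param times_min Numeric vector of sample times in minutes since the start
#'   of the series. Must be strictly increasing and nonnegative.
#' @param kinds Character vector, one of `"pre_baseline"`, `"dynamic"`,
#'   `"t1map"` per sample.
#' @param injection_min Time (minutes since series start) at which contrast
#'   injection starts. All `pre_baseline` samples must precede it and all
#'   other samples must follow it.
#'
#' @return An object of class `acquisition_schedule`: a list with elements
#'   `times_min`, `kinds`, `injection_min` and `n_baseline`.
#' @seealso [default_schedule()], [dense_schedule()]
#' @export
acquisition_schedule <- function(times_min, kinds, injection_min) {
  times_min <- as.numeric(times_min)
  kinds <- as.character(kinds)
  if (length(times_min) != length(kinds)) {
    stop("`times_min` and `kinds` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(times_min)) || any(times_min < 0)) {
    stop("sample times must be finite and >= 0 relative to series start",
         call. = FALSE)
  }
  if (any(diff(times_min) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  ok <- kinds %in% c("pre_baseline", "dynamic", "t1map")
  if (!all(ok)) {
    stop("unknown sample kind(s): ", paste(unique(kinds[!ok]), collapse = ", "),
         call. = FALSE)
  }
  n_baseline <- sum(kinds == "pre_baseline")
  if (n_baseline < 1L) {
    stop("schedule needs at least one pre_baseline sample", call. = FALSE)
  }
  if (!is.numeric(injection_min) || length(injection_min) != 1L ||
      !is.finite(injection_min)) {
    stop("`injection_min` must be a single finite number", call. = FALSE)
  }
  pre <- kinds == "pre_baseline"
  if (any(times_min[pre] >= injection_min)) {
    stop("pre_baseline samples must precede `injection_min`", call. = FALSE)
  }
  if (any(times_min[!pre] < injection_min)) {
    stop("dynamic/t1map samples must not precede `injection_min`", call. = FALSE)
  }
  structure(
    list(times_min = times_min, kinds = kinds,
         injection_min = injection_min, n_baseline = n_baseline),
    class = "acquisition_schedule"
  )
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat("<acquisition_schedule> ", length(x$times_min), " samples (",
      x$n_baseline, " baseline, ", sum(x$kinds == "dynamic"), " dynamic, ",
      sum(x$kinds == "t1map"), " T1-map); injection at ",
      format(x$injection_min), " min; last sample ",
      format(max(post_injection_times(x))), " min post injection\n", sep = "")
  invisible(x)
}

#' Default sparse acquisition schedule
#'
#' Three pre-injection baseline volumes (12 s apart), a dynamic series every
#' 12 s for about 3 minutes after injection, and two late T1-map samples at 5
#' and 25 minutes after the start of injection.
#'
#' @return An [acquisition_schedule()].
#' @export
default_schedule <- function() {
  inj <- 0.6
  baseline <- c(0, 0.2, 0.4)
  dynamic <- inj + seq(0.2, 3, by = 0.2)
  t1maps <- inj + c(5, 25)
  acquisition_schedule(
    times_min = c(baseline, dynamic, t1maps),
    kinds = c(rep("pre_baseline", length(baseline)),
              rep("dynamic", length(dynamic)),
              rep("t1map", length(t1maps))),
    injection_min = inj
  )
}

#' Dense reference schedule
#'
#' A densely sampled comparison design: one sample every `dt_min` minutes from
#' injection out to `t_end_min`, with the same three-volume baseline as
#' [default_schedule()]. Used to benchmark the sparse late-point design.
#'
#' @param dt_min Sampling interval in minutes (default 0.5, i.e. 30 s).
#' @param t_end_min Last sample time in minutes post injection (default 25).
#' @return An [acquisition_schedule()].
#' @export
dense_schedule <- function(dt_min = 0.5, t_end_min = 25) {
  inj <- 0.6
  baseline <- c(0, 0.2, 0.4)
  dynamic <- inj + seq(dt_min, t_end_min, by = dt_min)
  acquisition_schedule(
    times_min = c(baseline, dynamic),
    kinds = c(rep("pre_baseline", 3), rep("dynamic", length(dynamic))),
    injection_min = inj
  )
}

#' Sample times relative to injection start
#'
#' @param schedule An [acquisition_schedule()].
#' @return Numeric vector of times in minutes since injection start (negative
#'   for pre-injection baseline samples).
#' @export
post_injection_times <- function(schedule) {
  stopifnot(inherits(schedule, "acquisition_schedule"))
  schedule$times_min - schedule$injection_min
}
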