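# Shared fixtures and independent oracles, built in code at test time.

test_vif <- function(schedule = default_schedule(), ...) {
  simulate_vif(schedule, ...)
}

# A VIF whose plasma concentration is exactly `value` from injection onward
# (a sample sits at t_post = 0, so the piecewise-linear curve is constant on
# the whole window; hematocrit 0: plasma == blood).
# Closed forms: integral(t) = value * t and, for value 1, x(t) = t.
constant_vif <- function(value = 1, t_end = 10, dt = 0.5) {
  inj <- 0.5
  tt <- c(0, inj + seq(0, t_end, by = dt))
  sched <- acquisition_schedule(tt, c("pre_baseline",
                                      rep("dynamic", length(tt) - 1L)),
                                injection_min = inj)
  cb <- ifelse(post_injection_times(sched) >= 0, value, 0)
  vif_series(sched, cb, hematocrit = 0)
}

# Leave-one-out refit oracle for deleted studentized residuals and Cook's
# distance; deliberately avoids the hat-matrix shortcuts used by stats.
loo_diagnostics <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  n <- nrow(X1)
  p <- ncol(X1)
  beta <- qr.solve(X1, y)
  res <- y - X1 %*% beta
  s2 <- sum(res^2) / (n - p)
  rstud <- cooks <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X1[-i, , drop = FALSE]
    yi <- y[-i]
    bi <- qr.solve(Xi, yi)
    ri <- yi - Xi %*% bi
    s2i <- sum(ri^2) / (nrow(Xi) - p)
    xi <- X1[i, ]
    pred_var <- 1 + drop(t(xi) %*% solve(crossprod(Xi)) %*% xi)
    rstud[i] <- (y[i] - drop(xi %*% bi)) / sqrt(s2i * pred_var)
    db <- beta - bi
    cooks[i] <- drop(t(db) %*% crossprod(X1) %*% db) / (p * s2)
  }
  list(rstudent = rstud, cooks = cooks)
}

# Exhaustive grid-search least-squares Patlak oracle on [0,0.01] x [0,0.1]
# at `step` resolution. For each candidate slope the SSE over the intercept
# grid is expanded analytically, so the search is exact but fast. Agreement
# with OLS is to grid resolution in the slope; the matching intercept moves
# by mean(x) per unit slope step (slope-intercept coupling), so intercept
# agreement is to step * (1 + mean(x)).
grid_search_patlak <- function(x, y, step = 1e-5) {
  kis <- seq(0, 0.01, by = step)
  vps <- seq(0, 0.1, by = step)
  n <- length(y)
  sum_v2 <- n * vps^2
  best <- c(NA, NA)
  best_sse <- Inf
  for (ki in kis) {
    r <- y - ki * x
    sse <- sum_v2 - 2 * vps * sum(r) + sum(r^2)
    j <- which.min(sse)
    if (sse[j] < best_sse) {
      best_sse <- sse[j]
      best <- c(ki, vps[j])
    }
  }
  list(ki = best[1], vp = best[2], sse = best_sse)
}
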