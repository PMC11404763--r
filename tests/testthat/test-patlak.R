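test_that("integrate_vif matches closed forms for constant and linear inputs", {
  # constant 1 mM from injection: integral(10) = 10 mM.min
  vif <- constant_vif()
  expect_equal(integrate_vif(vif, 10), 10, tolerance = 1e-12)
  # linear 0 -> 2 mM over 10 min post-injection: triangle area 10
  sched <- attr(vif, "schedule")
  tp <- post_injection_times(sched)
  cb <- ifelse(tp >= 0, 2 * tp / 10, 0)
  vlin <- vif_series(sched, cb, hematocrit = 0)
  expect_equal(integrate_vif(vlin, 10), 10, tolerance = 1e-12)
  # additive over subintervals
  expect_equal(integrate_vif(vlin, 4) + (integrate_vif(vlin, 9) - integrate_vif(vlin, 4)),
               integrate_vif(vlin, 9))
  # no silent extrapolation
  expect_error(integrate_vif(vlin, 30), "extrapolate")
  expect_error(integrate_vif(vlin, -1), "extrapolate")
})

test_that("integrate_vif matches an adaptive-quadrature oracle on random inputs", {
  set.seed(11)
  for (rep in 1:5) {
    times <- c(0, 0.2, 0.4, sort(stats::runif(16, 0.7, 24)), 25)
    kinds <- c(rep("pre_baseline", 3), rep("dynamic", 17))
    sched <- acquisition_schedule(times, kinds, injection_min = 0.5)
    cb <- ifelse(post_injection_times(sched) > 0, stats::runif(20, 0.1, 5), 0)
    vif <- vif_series(sched, cb, hematocrit = 0.4)
    f <- stats::approxfun(vif$t_post_min, vif$c_plasma_mM)
    for (t in c(5, 12.3, 24.5)) {
      # quadrature segment by segment between kinks, where f is smooth
      knots <- sort(unique(c(0, vif$t_post_min[vif$t_post_min > 0 &
                                                 vif$t_post_min < t], t)))
      oracle <- sum(vapply(seq_len(length(knots) - 1L), function(i) {
        stats::integrate(f, knots[i], knots[i + 1L], rel.tol = 1e-10)$value
      }, numeric(1)))
      expect_equal(integrate_vif(vif, t), oracle, tolerance = 1e-6)
    }
  }
})

test_that("Patlak transform has its closed forms and excludes baseline", {
  vif <- constant_vif(t_end = 25)
  tp <- vif$t_post_min
  # constant Cp = 1: x(t) = t and y(t) = Ct(t)
  ct <- ifelse(tp > 0, 0.02 + 0.001 * tp, 0)
  pts <- patlak_transform(ct, vif)
  inc <- pts$included
  expect_false(any(inc & vif$kind == "pre_baseline"))
  expect_equal(pts$x[inc], tp[inc], tolerance = 1e-12)
  expect_equal(pts$y[inc], ct[inc], tolerance = 1e-12)
  f <- fit_patlak(pts)
  expect_equal(f$ki, 0.001, tolerance = 1e-12)
  expect_equal(f$vp, 0.02, tolerance = 1e-12)
  # ki = 0: y constant at vp
  vif2 <- test_vif()
  ct0 <- forward_tissue_curve(vif2, 0, 0.04)
  p0 <- patlak_transform(ct0, vif2)
  expect_equal(p0$y[p0$included], rep(0.04, sum(p0$included)), tolerance = 1e-12)
  # shape mismatch
  expect_error(patlak_transform(ct[-1], vif), "samples")
})

test_that("forward-model curves give exactly collinear Patlak points", {
  vif <- test_vif()
  ct <- forward_tissue_curve(vif, 0.001, 0.02)
  pts <- patlak_transform(ct, vif)
  fit <- stats::lm(y ~ x, data = pts[pts$included, ])
  expect_lt(max(abs(stats::residuals(fit))), 1e-14)
  expect_equal(unname(stats::coef(fit)[2]), 0.001, tolerance = 1e-9)
})

test_that("fit_patlak recovers an exact line and degenerate cases fail loudly", {
  pts <- data.frame(x = c(1, 10, 25), y = c(0.021, 0.030, 0.045),
                    included = TRUE)
  f <- fit_patlak(pts)
  expect_true(f$valid)
  expect_equal(f$ki, 0.001, tolerance = 1e-12)
  expect_equal(f$vp, 0.02, tolerance = 1e-12)
  expect_equal(f$rms, 0, tolerance = 1e-12)
  # degenerate abscissa
  bad <- data.frame(x = c(2, 2, 2), y = c(1, 2, 3), included = TRUE)
  expect_false(fit_patlak(bad)$valid)
  # fewer than two included points
  expect_false(fit_patlak(data.frame(x = 1, y = 1, included = TRUE))$valid)
})

test_that("noise-free forward + fit round-trips (ki, vp) across the truth range", {
  vif <- test_vif()
  for (ki in c(0, 1e-4, 5e-4, 2e-3, 0.01)) {
    for (vp in c(0, 0.005, 0.02, 0.1)) {
      ct <- forward_tissue_curve(vif, ki, vp)
      f <- fit_patlak(patlak_transform(ct, vif))
      expect_lt(abs(f$ki - ki), 1e-12)
      expect_lt(abs(f$vp - vp), 1e-12)
    }
  }
})

test_that("OLS agrees with the exhaustive grid-search oracle", {
  vif <- test_vif()
  pts0 <- patlak_transform(forward_tissue_curve(vif, 1e-3, 0.02), vif)
  x <- pts0$x[pts0$included]
  set.seed(21)
  for (rep in 1:5) {
    ki <- stats::runif(1, 1e-3, 9e-3)
    vp <- stats::runif(1, 0.01, 0.09)
    y <- ki * x + vp + stats::rnorm(length(x), 0, 5e-4)
    ols <- fit_patlak(data.frame(x = x, y = y, included = TRUE))
    oracle <- grid_search_patlak(x, y, step = 1e-5)
    expect_lt(abs(ols$ki - oracle$ki), 1e-5 + 1e-12)
    expect_lt(abs(ols$vp - oracle$vp), 1e-5 * (1 + mean(x)) + 1e-12)
  }
})

test_that("Patlak estimates are scale-equivariant and vp-shift-equivariant", {
  vif <- test_vif()
  ct <- forward_tissue_curve(vif, 8e-4, 0.015)
  base <- fit_patlak(patlak_transform(ct, vif))
  for (c_scale in c(0.1, 3, 40)) {
    sc_vif <- vif_series(attr(vif, "schedule"), vif$c_blood_mM * c_scale,
                         attr(vif, "hematocrit"))
    sc <- fit_patlak(patlak_transform(ct * c_scale, sc_vif))
    expect_equal(sc$ki, base$ki, tolerance = 1e-10)
    expect_equal(sc$vp, base$vp, tolerance = 1e-10)
  }
  # adding delta * Cp(t) raises vp by exactly delta, ki unchanged
  delta <- 0.013
  shifted <- fit_patlak(patlak_transform(ct + delta * vif$c_plasma_mM, vif))
  expect_equal(shifted$ki, base$ki, tolerance = 1e-12)
  expect_equal(shifted$vp, base$vp + delta, tolerance = 1e-12)
})

test_that("volume fit equals the per-voxel loop bit for bit on a noisy phantom", {
  ph <- simulate_phantom(default_schedule(), shape = c(4, 4, 4),
                         noise_sd = 0.002, seed = 5)
  maps <- fit_patlak_volume(ph$concentration, ph$vif)
  for (v in seq_len(64)) {
    idx <- arrayInd(v, c(4L, 4L, 4L))
    f <- fit_patlak(patlak_transform(
      ph$concentration[idx[1], idx[2], idx[3], ], ph$vif))
    expect_identical(maps$ki[v], f$ki)
    expect_identical(maps$vp[v], f$vp)
    expect_identical(maps$rms[v], f$rms)
    expect_identical(as.integer(maps$n_points[v]), as.integer(f$n_points))
  }
})

test_that("volume fit flags invalid voxels and handles empty masks", {
  ph <- simulate_phantom(default_schedule(), shape = c(4, 4, 4),
                         noise_sd = 0, seed = 1)
  conc <- ph$concentration
  conc[1, 1, 1, ] <- NA_real_          # fully missing voxel
  conc[2, 1, 1, 20] <- NA_real_        # one missing late sample
  maps <- fit_patlak_volume(conc, ph$vif)
  expect_false(maps$valid[1, 1, 1])
  expect_true(is.na(maps$ki[1, 1, 1]))
  # partial curve still fit on its finite points
  expect_true(maps$valid[2, 1, 1])
  expect_equal(maps$n_points[2, 1, 1], maps$n_points[3, 1, 1] - 1L)
  # empty mask: no valid voxels, nothing fabricated
  empty <- fit_patlak_volume(conc, ph$vif, mask = array(FALSE, c(4, 4, 4)))
  expect_equal(sum(empty$valid), 0)
  expect_true(all(is.na(empty$ki)))
  # shape errors
  expect_error(fit_patlak_volume(conc[, , , 1:5], ph$vif), "time points")
  expect_error(fit_patlak_volume(conc, ph$vif, mask = array(TRUE, c(3, 4, 4))),
               "mask")
})

test_that("leakage maps round-trip through NIfTI to float precision", {
  ph <- simulate_phantom(default_schedule(), shape = c(4, 4, 4),
                         noise_sd = 0.002, seed = 9)
  maps <- fit_patlak_volume(ph$concentration, ph$vif)
  dir <- withr::local_tempdir()
  write_leakage_maps(maps, dir)
  back <- read_leakage_maps(dir)
  expect_equal(back$ki, maps$ki, tolerance = 1e-6)
  expect_identical(back$valid, maps$valid)
  expect_identical(back$n_points, array(as.integer(maps$n_points), maps$dim))
})
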