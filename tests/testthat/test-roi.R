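test_that("central-95% trimmed mean matches a sort-and-slice oracle", {
  # constant input: everything retained
  cst <- trimmed_mean_95(rep(1, 4))
  expect_equal(cst$mean, 1)
  expect_equal(cst$n_retained, 4)
  expect_error(trimmed_mean_95(numeric(0)), "finite")
  expect_error(trimmed_mean_95(c(NA, NaN, Inf)), "finite")

  # 0..999 plus one gross outlier: the outlier is excluded
  v <- c(0:999, 1e6)
  tm <- trimmed_mean_95(v)
  expect_false(1e6 >= tm$bounds[1] && 1e6 <= tm$bounds[2])
  expect_gt(tm$mean, 480)
  expect_lt(tm$mean, 520)

  # independent oracle: retain values inside [P2.5, P97.5] from a full sort
  set.seed(14)
  z <- stats::rnorm(1000)
  tm2 <- trimmed_mean_95(z)
  zs <- sort(z)
  q <- function(p) { # type-7 linear interpolation on the sorted sample
    h <- (length(zs) - 1) * p
    lo <- floor(h)
    zs[lo + 1] + (h - lo) * (zs[lo + 2] - zs[lo + 1])
  }
  keep <- zs[zs >= q(0.025) & zs <= q(0.975)]
  expect_equal(tm2$mean, mean(keep), tolerance = 1e-12)
  expect_equal(tm2$n_retained, length(keep))
})

test_that("trimming is idempotent and immune to far-outlier magnitude", {
  set.seed(15)
  v <- stats::rnorm(2000)
  t1 <- trimmed_mean_95(v)
  kept <- v[v >= t1$bounds[1] & v <= t1$bounds[2]]
  t2 <- trimmed_mean_95(kept)
  # distribution-level idempotence: re-trimming moves the mean by less than
  # the sampling uncertainty of the mean itself
  expect_lt(abs(t2$mean - t1$mean), stats::sd(kept) / sqrt(length(kept)))
  # monotone contamination: < 2.5% planted outliers can grow without effect
  base <- stats::rnorm(1000)
  n_out <- 20 # 2% of 1020
  m1 <- trimmed_mean_95(c(base, rep(50, n_out)))$mean
  m2 <- trimmed_mean_95(c(base, rep(5e6, n_out)))$mean
  expect_equal(m1, m2)
})

test_that("the sd-interval reading of the 95% correction is also available", {
  set.seed(16)
  v <- stats::rnorm(500)
  tm <- trimmed_mean_95(v, method = "sd")
  expect_equal(tm$bounds[1], mean(v) - 1.96 * stats::sd(v))
  expect_true(tm$n_retained < length(v))
})

test_that("ROI summaries are exact on uniform phantoms and flag empty ROIs", {
  ph <- simulate_phantom(default_schedule(), shape = c(10, 10, 10),
                         noise_sd = 0)
  maps <- fit_patlak_volume(ph$concentration, ph$vif, mask = ph$labels > 0)
  rs <- summarize_rois(maps, ph$labels)
  expect_equal(attr(rs, "trim_method"), "percentile")
  for (r in c("cortical_gm", "deep_gm")) {
    row <- rs[rs$roi == r, ]
    truth <- ph$truth[ph$truth$name == r, ]
    expect_equal(row$mean_ki, truth$ki_true, tolerance = 1e-10)
    expect_equal(row$mean_vp, truth$vp_true, tolerance = 1e-10)
    expect_equal(row$n_retained_ki, row$n_total)
  }
  # total GM pools cortical and deep GM voxels
  expect_equal(rs$n_total[rs$roi == "total_gm"],
               sum(rs$n_total[rs$roi %in% c("cortical_gm", "deep_gm")]))
  # an ROI whose label is absent is flagged missing, not fabricated
  rs2 <- summarize_rois(maps, ph$labels, roi_spec(ghost = 99L))
  expect_true(rs2$missing[1])
  expect_equal(rs2$n_total[1], 0)
  expect_true(is.na(rs2$mean_ki[1]))
  expect_error(summarize_rois(maps, ph$labels[1:5, , ]), "grid")
})

test_that("trimming recovers the regional mean under planted gross corruption", {
  ph <- simulate_phantom(default_schedule(), shape = c(10, 10, 10),
                         noise_sd = 0)
  maps <- fit_patlak_volume(ph$concentration, ph$vif, mask = ph$labels > 0)
  # contamination must stay within the upper-tail breakdown (2.5%) of a
  # central-95% trim; 2% of the region's voxels here
  sel <- which(ph$labels == 1L)
  set.seed(17)
  bad <- sample(sel, ceiling(0.02 * length(sel)))
  truth <- ph$truth$ki_true[ph$truth$label == 1L]
  maps$ki[bad] <- 100 * truth
  spec <- roi_spec(cortical_gm = 1L)
  trimmed <- summarize_rois(maps, ph$labels, spec)$mean_ki
  plain <- summarize_rois(maps, ph$labels, spec, trim = FALSE)$mean_ki
  expect_lt(abs(trimmed - truth) / truth, 0.02)
  expect_gt(abs(plain - truth) / truth, 0.02)
})
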