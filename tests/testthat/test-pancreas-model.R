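# Whole-pancreas composition: density -> volume, mixtures, thresholds,
# inversion.

calib <- calibration_config()
singles <- size_distribution(1, 1, id = "n1")

test_that("calibration and distribution constructors validate their inputs", {
  expect_error(calibration_config(baseline_volume = 90, reference_volume = 60),
               "baseline_volume < reference_volume")
  expect_error(calibration_config(density_max = 0), "density_max")
  expect_error(size_distribution(c(1, 10), c(0.6, 0.6)), "sum to")
  expect_error(size_distribution(c(10, 10), c(0.5, 0.5)), "distinct")
  expect_error(size_distribution(1, -1), "non-negative")
  expect_warning(
    d <- size_distribution(c(1, 10), c(0.5, 0.5 + 4e-7)),
    "renormalising"
  )
  expect_equal(sum(d$weights), 1)
})

test_that("mixture expansion ratio is the volume-weighted per-size ratio", {
  act <- shell_action(10)
  # degenerate single-component mixture
  expect_equal(mixture_expansion_ratio(singles, act), expansion_ratio(1, act))
  mix <- mixed_distribution()
  expect_equal(mixture_expansion_ratio(mix, shell_action(30)), 33.77152,
               tolerance = 1e-6)
  expect_equal(mixture_expansion_ratio(mix, gradient_action(20)), 38.88303,
               tolerance = 1e-6)
  # shifting beta-cell volume from small to large clusters lowers k_eff
  small_heavy <- size_distribution(c(1, 1000), c(0.8, 0.2))
  large_heavy <- size_distribution(c(1, 1000), c(0.2, 0.8))
  expect_gt(mixture_expansion_ratio(small_heavy, act),
            mixture_expansion_ratio(large_heavy, act))
})

test_that("pancreas volume composes calibration with the expansion ratio", {
  expect_equal(pancreas_volume(0, calib, singles, shell_action(10)), 60)
  expect_equal(pancreas_volume(0.03, calib, singles, shell_action(10)),
               132.9)   # 60 + 0.03*90*(1 + 26)
  n250 <- size_distribution(250, 1)
  expect_equal(pancreas_volume(0.03, calib, n250, shell_action(30)),
               80.09543, tolerance = 1e-6)
  expect_error(pancreas_volume(0.05, calib, singles, shell_action(10)),
               "0.03")
  expect_error(pancreas_volume(-0.01, calib, singles, shell_action(10)))
})

test_that("volume is affine in density with intercept V0 and constant slope", {
  act <- gradient_action(20)
  d <- seq(0, 0.03, by = 0.005)
  v <- pancreas_volume(d, calib, mixed_distribution(), act, 0.5)
  slopes <- diff(v) / diff(d)
  expect_equal(v[1], 60)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-9)
  k <- mixture_expansion_ratio(mixed_distribution(), act, 0.5)
  expect_equal(slopes[1], 90 * (1 + k), tolerance = 1e-9)
})

test_that("volume is monotone in extent, expansion and density", {
  d <- 0.02
  v_t <- vapply(c(1, 5, 10, 20, 30), function(t) {
    pancreas_volume(d, calib, singles, shell_action(t))
  }, numeric(1))
  expect_true(all(diff(v_t) > 0))
  v_lam <- vapply(c(1, 5, 10, 20, 30), function(l) {
    pancreas_volume(d, calib, singles, gradient_action(l))
  }, numeric(1))
  expect_true(all(diff(v_lam) > 0))
  v_f <- vapply(c(0, 0.2, 0.5, 1), function(f) {
    pancreas_volume(d, calib, singles, shell_action(10), f)
  }, numeric(1))
  expect_true(all(diff(v_f) > 0))
})

test_that("volume_curve returns a tidy labelled table", {
  curve <- volume_curve(calib, singles, shell_action(10),
                        density_grid = c(0, 0.03))
  expect_s3_class(curve, "volume_curve")
  expect_equal(curve$volume_ml, c(60, 132.9))
  expect_equal(curve$model, c("shell", "shell"))
  expect_equal(curve$extent_um, c(10, 10))
  expect_equal(attr(curve, "k_eff"), 26)
  # default grid: 0 to density_max in 0.001 steps
  full <- volume_curve(calib, singles, shell_action(10))
  expect_equal(nrow(full), 31)
  expect_true(all(diff(full$volume_ml) > 0))
})

test_that("reference-volume threshold scan matches the atrophy predictions", {
  # single cells: 10/20/30 um shells exceed 90 ml at 3% density; 1 and 5 don't
  for (t in c(10, 20, 30)) {
    expect_true(reaches_reference(calib, singles, shell_action(t))$reaches)
  }
  for (t in c(1, 5)) {
    expect_false(reaches_reference(calib, singles, shell_action(t))$reaches)
  }
  # 250- and 500-cell clusters never reach 90 ml in the shell model
  for (n in c(250, 500)) {
    dn <- size_distribution(n, 1)
    for (t in c(1, 5, 10, 20, 30)) {
      expect_false(reaches_reference(calib, dn, shell_action(t))$reaches)
    }
  }
  # gradient model: 250-cell clusters only at the 30 um decay length
  d250 <- size_distribution(250, 1)
  expect_true(reaches_reference(calib, d250, gradient_action(30))$reaches)
  for (lam in c(1, 5, 10, 20)) {
    expect_false(reaches_reference(calib, d250, gradient_action(lam))$reaches)
  }
  # 500-cell clusters at no decay length
  d500 <- size_distribution(500, 1)
  for (lam in c(1, 5, 10, 20, 30)) {
    expect_false(reaches_reference(calib, d500, gradient_action(lam))$reaches)
  }
  # no expansion cannot bridge the 60 -> 90 ml gap
  res0 <- reaches_reference(calib, singles, shell_action(30), 0)
  expect_false(res0$reaches)
  expect_equal(res0$margin_ml, 62.7 - 90)
})

test_that("density inversion round-trips through the volume model", {
  configs <- list(
    list(dist = singles, action = shell_action(10), f = 1),
    list(dist = mixed_distribution(), action = gradient_action(20), f = 0.5),
    list(dist = size_distribution(250, 1), action = shell_action(30), f = 0.2)
  )
  for (cfg in configs) {
    for (d in c(0, 0.001, 0.015, 0.03)) {
      v <- pancreas_volume(d, calib, cfg$dist, cfg$action, cfg$f)
      expect_equal(
        estimate_density(v, calib, cfg$dist, cfg$action, cfg$f), d,
        tolerance = 1e-12
      )
    }
  }
  expect_equal(estimate_density(60, calib, singles, shell_action(10)), 0)
  expect_equal(estimate_density(96.45, calib, singles, shell_action(10)),
               0.015)
  expect_error(estimate_density(59, calib, singles, shell_action(10)),
               "baseline")
})

test_that("modeled density basis is self-consistent and invertible", {
  calib_m <- calibration_config(density_basis = "modeled")
  act <- shell_action(10)
  v <- pancreas_volume(0.02, calib_m, singles, act)
  # V = V0 / (1 - d (1 + k))
  expect_equal(v, 60 / (1 - 0.02 * 27))
  expect_equal(estimate_density(v, calib_m, singles, act), 0.02,
               tolerance = 1e-12)
  # diverges when the implied beta+acinar load reaches the whole organ
  expect_error(pancreas_volume(0.03, calib_m, singles, shell_action(30)),
               "diverges")
})

test_that("cluster counts conserve total beta-cell volume", {
  expect_equal(cluster_counts(0, calib, mixed_distribution())$count,
               rep(0, 6))
  cc1 <- cluster_counts(0.03, calib, size_distribution(1, 1))
  expect_equal(cc1$count, 5156620156, tolerance = 1e-6)
  mix <- mixed_distribution()
  cc <- cluster_counts(0.03, calib, mix)
  cluster_vols <- vapply(mix$n_cells,
                         function(n) cluster_geometry(n)$volume, numeric(1))
  expect_equal(sum(cc$count * cluster_vols), 0.03 * 90 * UM3_PER_ML)
})
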