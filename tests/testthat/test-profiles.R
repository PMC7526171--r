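test_that("profile evaluation and the composed DGC/PDE totals hit their extrema", {
  p <- default_params()
  flat <- constant_profile(0.4)
  expect_equal(eval_profile(flat, c(0, 31, 149)), rep(0.4, 3))

  # extrema of the printed fits: offset +/- |amplitude|
  pled <- pled_profile()
  t_max <- (pi / 2 - pled$phase) / pled$angular_freq
  expect_equal(eval_profile(pled, t_max), 0.1834 + 0.7579, tolerance = 1e-12)

  pdea <- pdea_profile()
  t_pde_max <- (3 * pi / 2 - pdea$phase) / pdea$angular_freq
  expect_equal(eval_profile(pdea, t_pde_max), 0.361 + 0.3605,
               tolerance = 1e-12)

  expect_equal(dgc_total(t_max, p), 0.7 + 0.9413, tolerance = 1e-12)
  expect_equal(pde_total(t_pde_max, p), 0.2 + 0.7215, tolerance = 1e-12)
  t_pde_min <- (pi / 2 - pdea$phase) / pdea$angular_freq
  expect_equal(pde_total(t_pde_min, p), 0.2 + (0.361 - 0.3605),
               tolerance = 1e-12)
  expect_gt(min(pde_total(seq(0, 150, by = 0.1), p)), 0)

  # 150-min periodicity of both totals
  t <- seq(0, 150, by = 7.5)
  expect_equal(dgc_total(t + 150, p), dgc_total(t, p), tolerance = 1e-12)
  expect_equal(pde_total(t + 150, p), pde_total(t, p), tolerance = 1e-12)
})

test_that("noise-free points are recovered exactly, up to the sign/phase symmetry", {
  profiles <- list(
    pled_profile(),
    pdea_profile(),                       # negative amplitude
    sinusoid_profile(0.5, pi / 75, 5.9, -0.2)  # phase near 2*pi, offset < 0
  )
  for (pr in profiles) {
    pts <- synth_profile_points(pr, n = 12, noise_sd = 0)
    fit <- fit_sinusoid(pts)
    # canonical form: A >= 0, phi in [0, 2*pi)
    expect_gte(fit$profile$amplitude, 0)
    expect_true(fit$profile$phase >= 0 && fit$profile$phase < 2 * pi)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    t <- seq(0, 150, by = 1)
    expect_equal(eval_profile(fit$profile, t), eval_profile(pr, t),
                 tolerance = 1e-6)
    A_canon <- abs(pr$amplitude)
    phi_canon <- (pr$phase + if (pr$amplitude < 0) pi else 0) %% (2 * pi)
    expect_equal(fit$profile$amplitude, A_canon, tolerance = 1e-6)
    expect_equal(fit$profile$phase, phi_canon, tolerance = 1e-6)
  }
})

test_that("free-frequency fitting refines omega from the fixed-frequency start", {
  pr <- sinusoid_profile(0.2, pi / 70, 1.1, 0.7)
  pts <- synth_profile_points(pr, n = 24, noise_sd = 0)
  fit <- fit_sinusoid(pts, fix_freq = NULL)
  expect_equal(fit$profile$angular_freq, pi / 70, tolerance = 1e-6)
  expect_equal(fit$profile$amplitude, 0.2, tolerance = 1e-6)
})

test_that("degenerate point sets are reported, not silently fitted", {
  const <- data.frame(t_min = c(0, 30, 60, 90), level = rep(0.5, 4))
  expect_warning(fit <- fit_sinusoid(const), "undefined")
  expect_true(is.na(fit$r_squared))
  expect_lt(fit$profile$amplitude, 1e-8)

  same_t <- data.frame(t_min = rep(10, 4), level = 1:4)
  expect_error(fit_sinusoid(same_t), "degenerate")
  expect_error(fit_sinusoid(const[1:2, ]), "at least")
})

test_that("noisy recovery of the PleD amplitude stays within the fixture band", {
  pts <- synth_profile_points(pled_profile(), n = 9, noise_sd = 0.02,
                              seed = 123)
  fit <- fit_sinusoid(pts)
  expect_lt(abs(fit$profile$amplitude - 0.1834), 0.05)
  expect_gt(fit$r_squared, 0.9)
})

test_that("the fixture generator is reproducible, restores the RNG, and masking drops points", {
  pr <- pled_profile()
  a <- synth_profile_points(pr, 9, 0.02, seed = 5)
  b <- synth_profile_points(pr, 9, 0.02, seed = 5)
  expect_identical(a, b)

  set.seed(99); before <- runif(3)
  set.seed(99); invisible(synth_profile_points(pr, 9, 0.02, seed = 5))
  expect_identical(runif(3), before)

  # an injected outlier is excluded via mask, mirroring manual curation
  pts <- synth_profile_points(pr, 9, 0)
  pts$level[2] <- pts$level[2] + 0.5
  full <- fit_sinusoid(pts)
  masked <- fit_sinusoid(pts, mask = 2)
  expect_equal(masked$n_used, 8)
  expect_gt(masked$r_squared, full$r_squared)
  expect_equal(masked$profile$amplitude, pr$amplitude, tolerance = 1e-6)
})

test_that("profile points round-trip through CSV", {
  pts <- synth_profile_points(pdea_profile(), 9, 0.01, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_points(pts, path)
  expect_identical(readLines(path)[1], "t_min,level")
  back <- read_profile_points(path)
  expect_equal(back$level, pts$level, tolerance = 1e-12)
})
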