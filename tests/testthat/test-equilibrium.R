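test_that("phosphorelay equilibrium reproduces the common-ratio closed form", {
  p <- default_params()

  # independent arithmetic: r = k1*gf*fPEP / (k_1*fPyr)
  gf <- (75.63 + 0.1 * 10000) / (75.63 + 10000)
  fPEP <- (300 / 350) / (1 + 300 / 350)
  fPyr <- (1500 / 670) / (1 + 1500 / 670)
  r_expect <- 52.4 * gf * fPEP / (67.2 * fPyr)

  eq <- pts_equilibrium(rich_signal(), p)
  expect_equal(eq$r, r_expect, tolerance = 1e-12)
  expect_equal(eq$NPrP, 30 * r_expect / (1 + r_expect), tolerance = 1e-12)
  expect_equal(eq$EIP_tot, 10 * r_expect / (1 + r_expect), tolerance = 1e-12)
  expect_equal(eq$EIIAP, eq$NPrP)

  # printed values: NPr~P 1.6, EI~P 0.5 under the rich condition
  expect_printed(eq$NPrP, 1.6, 0.1)
  expect_printed(eq$EIP_tot, 0.5, 0.1)

  # carbon-limited bold column: NPr~P 4.9
  cl <- pts_equilibrium(nutrient_signal(1000, 2800, 900), p)
  expect_printed(cl$NPrP, 4.9, 0.1)
})

test_that("phosphorelay limits: no donor, no acceptor, and neither", {
  p <- default_params()
  none <- pts_equilibrium(nutrient_signal(100, 0, 1500), p)
  expect_equal(none$r, 0)
  expect_equal(none$NPrP, 0)

  full <- pts_equilibrium(nutrient_signal(100, 300, 0), p)
  expect_equal(full$NPrP, p$NPr_T)
  expect_equal(full$EIP_tot, p$EI_T)

  expect_error(pts_equilibrium(nutrient_signal(100, 0, 0), p),
               "undetermined")
})

test_that("phosphorelay pools scale linearly with totals at fixed signal", {
  p <- default_params()
  sig <- nutrient_signal(500, 800, 1200)
  a <- pts_equilibrium(sig, p, EI_T = 1, NPr_T = 10, EIIA_T = 5)
  b <- pts_equilibrium(sig, p, EI_T = 3, NPr_T = 30, EIIA_T = 15)
  expect_equal(b$r, a$r)
  expect_equal(b$NPrP, 3 * a$NPrP, tolerance = 1e-12)
  expect_equal(b$EIP_tot, 3 * a$EIP_tot, tolerance = 1e-12)
})

test_that("nucleotide balance handles the hydrolysis-only limit and rejects synthetase saturation", {
  p <- default_params()
  off <- nucleotide_equilibrium(list(f_sd = 0, f_hd = 1), 1420.6, p)
  expect_equal(off$ppGpp, 0)
  expect_equal(off$GTP, (15 / 16) * 1420.6, tolerance = 1e-12)

  expect_error(nucleotide_equilibrium(list(f_sd = 1, f_hd = 0), 1420.6, p),
               "no finite equilibrium")
})

test_that("the closed-form equilibrium zeroes the full rhs and closes the guanine balance", {
  p <- default_params()
  set.seed(31)
  for (i in 1:12) {
    sig <- nutrient_signal(runif(1, 1, 1e4), runif(1, 100, 3000),
                           runif(1, 100, 2000))
    eq <- equilibrium_state(sig, p)
    expect_equal(total_guanine(eq), 1420.6, tolerance = 1e-8)
    d <- model_rhs(eq, sig, mean_dgc(p), mean_pde(p), p)
    gross <- p$k_s_GTP * eq[["GMP"]]
    expect_lt(max(abs(d)), 1e-6 * gross)
  }
})

test_that("the PTS calibration sums match the published simulation column", {
  # rows of the enzyme-titration comparison, within +/-0.2 uM
  expect_lt(abs(pts_phospho_sum(0.729, 24.4) - 7), 0.2)
  expect_lt(abs(pts_phospho_sum(0.729, 36.6) - 10.5) , 0.2)
  expect_lt(abs(pts_phospho_sum(0.729, 0) - 0.2), 0.2)
  expect_lt(abs(pts_phospho_sum(0.157, 24.4) - 6.8), 0.2)
  expect_lt(abs(pts_phospho_sum(1.57, 24.4) - 7.2), 0.2)
  expect_lt(abs(pts_phospho_sum(0.729, 12.2) - 3.6), 0.2)

  # independent check of one row: (EI_T + NPr_T) * r/(1+r) at the
  # calibration signal
  gf <- (75.63 + 0.1 * 10000) / (75.63 + 10000)
  fPEP <- (160 / 350) / (1 + 160 / 350)
  fPyr <- (48.5 / 670) / (1 + 48.5 / 670)
  r <- 52.4 * gf * fPEP / (67.2 * fPyr)
  expect_equal(pts_phospho_sum(0.729, 24.4),
               (0.729 + 24.4) * r / (1 + r), tolerance = 1e-12)
})

test_that("the PEP:Pyr sweep is strictly monotone and linear at low saturation", {
  ratios <- c(0.05, 0.1, 0.2, 0.5, 1, 2, 5)
  sw <- pep_pyr_sweep(ratios, Gln = 1000)
  expect_true(all(diff(sw$r) > 0))
  expect_true(all(diff(sw$f_sd) > 0))

  # far below both Kd's the ratio r is proportional to PEP:Pyr
  lin <- pep_pyr_sweep(c(0.01, 0.02), Gln = 1000, anchor = "pyr", pyr = 1)
  expect_equal(lin$r[2] / lin$r[1], 2, tolerance = 1e-3)

  # matched-glutamine carbon comparison: NPr~P rises 2.4 -> 4.9
  both <- rbind(
    pep_pyr_sweep(300 / 1500, Gln = 1000, anchor = "pyr", pyr = 1500),
    pep_pyr_sweep(2800 / 900, Gln = 1000, anchor = "pyr", pyr = 900))
  expect_printed(both$NPrP[1], 2.4, 0.1)
  expect_printed(both$NPrP[2], 4.9, 0.1)
})
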