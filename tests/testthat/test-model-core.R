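test_that("glutamine factor spans (eps, 1] and decreases monotonically", {
  p <- default_params()
  expect_equal(glutamine_factor(0, p), 1)
  # saturating glutamine approaches the residual floor eps
  expect_equal(glutamine_factor(1e12, p), p$eps, tolerance = 1e-9)
  # direct evaluation of (75.63 + 0.1*10000)/(75.63 + 10000)
  expect_equal(glutamine_factor(10000, p),
               (75.63 + 0.1 * 10000) / (75.63 + 10000), tolerance = 1e-12)

  gln <- 10^seq(-2, 6, length.out = 200)
  gf <- glutamine_factor(gln, p)
  expect_true(all(diff(gf) < 0))
  expect_true(all(gf > p$eps & gf <= 1))
  expect_error(glutamine_factor(-1, p), "non-negative")
})

test_that("EI partition obeys the binding equilibria and conserves the pool", {
  p <- default_params()
  sig <- rich_signal()

  # no PEP, no EI.PEP complex
  part0 <- partition_EI(0.5, nutrient_signal(10000, 0, 1500), p)
  expect_equal(part0$EI_PEP, 0)

  # PEP = Kd1 means bound:free = 1:1 in the unphosphorylated pool
  part1 <- partition_EI(0.5, nutrient_signal(0, p$Kd1, 1500), p)
  expect_equal(part1$EI_PEP, part1$EI_free)

  # fractions bound: (300/350)/(1+300/350) and (1500/670)/(1+1500/670)
  part <- partition_EI(0.527, sig, p)
  expect_equal(part$EI_PEP, (10 - 0.527) * (300 / 350) / (1 + 300 / 350),
               tolerance = 1e-12)
  expect_equal(part$EIP_Pyr, 0.527 * (1500 / 670) / (1 + 1500 / 670),
               tolerance = 1e-12)
  expect_equal(part$EI_free + part$EI_PEP + part$EIP_free + part$EIP_Pyr,
               p$EI_T, tolerance = 1e-12)
  # the algebraic dissociation relations hold
  expect_equal(part$EI_free * sig$PEP, p$Kd1 * part$EI_PEP,
               tolerance = 1e-9)
  expect_equal(part$EIP_free * sig$Pyr, p$Kd2 * part$EIP_Pyr,
               tolerance = 1e-9)

  expect_error(partition_EI(11, sig, p), "EI_T")
})

test_that("SpoT partition matches its closed form and is monotone in both inputs", {
  p <- default_params()
  z <- spot_split(0, 5, p)
  expect_equal(z$alpha, 0)
  expect_equal(z$f_sd, 0)
  expect_equal(z$f_hd, 1)

  # alpha = 4 * (1.58/76.58) / (10/11.58)
  s <- spot_split(1.58, 1.58, p)
  expect_equal(s$alpha, 4 * (1.58 / 76.58) / (10 / 11.58), tolerance = 1e-12)
  expect_equal(s$f_sd, s$alpha / (1 + s$alpha), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:25) {
    a <- runif(2, 0, 30)
    sp <- spot_split(a[1], a[2], p)
    expect_equal(sp$f_sd + sp$f_hd, 1, tolerance = 1e-15)
    expect_gt(spot_split(a[1] + 1, a[2], p)$f_sd, sp$f_sd)
    expect_gt(spot_split(a[1], a[2] + 1, p)$f_sd, sp$f_sd)
  }
})

test_that("the right-hand side conserves guanine exactly and vanishes where every flux does", {
  p <- default_params()

  zero <- model_state(0, 0, 0, 0, 0, 0, 0)
  d0 <- model_rhs(zero, nutrient_signal(0, 0, 1500), 1.4, 0.5, p)
  expect_equal(unname(d0), rep(0, 7))

  set.seed(11)
  for (i in 1:100) {
    st <- model_state(runif(1, 0, 0.5), runif(1, 0, 1400), runif(1, 0, 900),
                      runif(1, 0, 100), runif(1, 0, p$EI_T),
                      runif(1, 0, p$NPr_T), runif(1, 0, p$EIIA_T))
    sig <- nutrient_signal(runif(1, 0, 1e4), runif(1, 0, 3000),
                           runif(1, 0, 2000))
    d <- model_rhs(st, sig, runif(1, 0, 2), runif(1, 0, 1), p)
    scale <- max(abs(d))
    expect_lt(abs(2 * d[["cdG"]] + d[["GTP"]] + d[["GMP"]] + d[["ppGpp"]]),
              1e-10 * max(scale, 1))
  }
})

test_that("the published steady-state column is a near-fixed point of the rhs", {
  p <- default_params()
  st <- model_state(cdG = 0.03, GTP = 1221, ppGpp = 118, GMP = 81,
                    EIP_tot = 0.527, NPrP = 1.58, EIIAP = 1.58)
  d <- model_rhs(st, rich_signal(), mean_dgc(p), mean_pde(p), p)

  gross_pp <- p$k_s_ppGpp * spot_split(1.58, 1.58, p)$f_sd *
    1221 / (1221 + p$Km3)
  gross_gtp <- p$k_s_GTP * 81
  gross_pts <- p$k2 * 0.527 * (p$NPr_T - 1.58)
  # residuals from 2-3 digit rounding of the printed values stay below 1%
  # of the gross fluxes through each variable
  expect_lt(abs(d[["ppGpp"]]) / gross_pp, 0.01)
  expect_lt(abs(d[["GTP"]]) / gross_gtp, 0.01)
  expect_lt(abs(d[["NPrP"]]) / gross_pts, 0.01)
})

test_that("state validation blocks unphysical states but tolerates round-off", {
  p <- default_params()
  st <- default_state()
  expect_equal(total_guanine(st), 1420.6)

  bad <- st; bad[["NPrP"]] <- p$NPr_T + 1
  expect_error(model_rhs(bad, rich_signal(), 1, 1, p), "exceeds")
  bad <- st; bad[["cdG"]] <- -0.1
  expect_error(validate_state(bad, p), "negative")
  # a -1e-9 excursion is attributed to the solver and clipped
  tiny <- st; tiny[["cdG"]] <- -1e-9
  expect_equal(validate_state(tiny, p)[["cdG"]], 0)
})
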