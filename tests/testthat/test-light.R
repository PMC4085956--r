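test_that("non-rectangular hyperbola matches its closed form", {
  # quadratic-formula oracle: theta J^2 - (I2+Jmax) J + I2 Jmax = 0
  expect_equal(nonrect_hyperbola(500, 400, 0.7),
               (900 - sqrt(900^2 - 4 * 0.7 * 500 * 400)) / (2 * 0.7))
  expect_equal(nonrect_hyperbola(500, 400, 0.7), 285.7142857,
               tolerance = 1e-8)
  expect_equal(nonrect_hyperbola(0, 400, 0.7), 0)
  expect_equal(nonrect_hyperbola(1e9, 400, 0.7), 400, tolerance = 1e-4)
  # theta -> 0 limit: rectangular hyperbola
  i2 <- 137; jm <- 220
  expect_equal(nonrect_hyperbola(i2, jm, 1e-6), i2 * jm / (i2 + jm),
               tolerance = 1e-3)
})

test_that("electron transport is monotone and bounded", {
  i2 <- seq(0, 2000, by = 50)
  j <- nonrect_hyperbola(i2, 300, 0.7)
  expect_true(all(diff(j) >= -1e-12))
  expect_true(all(j <= pmin(i2, 300) + 1e-9))
  expect_true(all(j >= 0))
  expect_true(all(diff(nonrect_hyperbola(700, seq(50, 500, 50), 0.7)) > 0))
  expect_error(nonrect_hyperbola(100, 200, 0), "theta")
  expect_error(nonrect_hyperbola(100, 200, 1), "theta")
})

test_that("bundle-sheath LET split follows the u = v convention", {
  lp <- c4_light(1000, f_mc = 0.65, let_bsc = 0)
  expect_equal(bsc_let_split(lp, 200)$j_l_b, 0)

  lp5 <- c4_light(1000, f_mc = 0.65, let_bsc = 0.5)
  sp <- bsc_let_split(lp5, 200)
  # LET chain sees half of u*I_b = 50 and v*Jmax_b
  expect_equal(sp$j_l_b,
               nonrect_hyperbola(50, 0.5 * lp5$jmax_b, lp5$theta))

  lp1 <- c4_light(1000, f_mc = 0.65, let_bsc = 1)
  sp1 <- bsc_let_split(lp1, 200)
  expect_equal(sp1$j_l_b, nonrect_hyperbola(100, lp1$jmax_b, lp1$theta))
  expect_equal(sp1$j_cyc_b, 0)
})

test_that("O2 evolution follows the water-splitting stoichiometry", {
  expect_equal(o2_evolution(100)$v_let, 50)
  expect_equal(o2_evolution(100)$v_o2, 25)
  expect_equal(o2_evolution(0)$v_o2, 0)
})

test_that("energy supply conserves light and caps synthesis rates", {
  p <- c4_params()
  for (f in c(0, 0.3, 0.65, 1)) {
    en <- energy_supply(c4_light(1200, f_mc = f, let_bsc = 0.5, params = p))
    expect_equal(en$i_m + en$i_b,
                 1200 * p$light$absorptance * p$light$f_spectral)
  }
  # min(VmaxE, eps*J): both branches
  p2 <- c4_params(list(light = list(vmaxe_nadph = 150, eps_nadph = 0.75)))
  en <- energy_supply(c4_light(500, f_mc = 1, params = p2))
  expect_equal(en$vmax_nadph_m, min(150, 0.75 * en$j_m))
  p3 <- c4_params(list(light = list(vmaxe_nadph = 5)))
  en3 <- energy_supply(c4_light(2000, f_mc = 1, params = p3))
  expect_equal(en3$vmax_nadph_m, 5)

  # no LET in the bundle sheath: no NADPH synthesis, no O2 evolution
  en0 <- energy_supply(c4_light(1500, let_bsc = 0, params = p))
  expect_equal(en0$vmax_nadph_b, 0)
  expect_equal(en0$v_o2_b, 0)
  en1 <- energy_supply(c4_light(1500, let_bsc = 1, params = p))
  expect_gt(en1$vmax_nadph_b, 0)
  expect_gt(en1$v_o2_b, 0)
  expect_lte(en1$j_l_b, en1$j_b + 1e-12)
})

test_that("light parameter validation catches out-of-range values", {
  expect_error(c4_light(-5), "ppfd")
  expect_error(c4_light(100, f_mc = 1.2), "f_mc")
  expect_error(c4_light(100, let_bsc = -0.1), "let_bsc")
})
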