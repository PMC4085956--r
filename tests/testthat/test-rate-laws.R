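test_that("irreversible Michaelis-Menten laws obey their limits", {
  r1 <- reaction("ME", "IRREV_MM", c(S = -1, P = 1),
                 list(vmax = 90, km = c(S = 200)))
  expect_equal(reaction_rate(r1, c(S = 0, P = 0)), 0)
  expect_equal(reaction_rate(r1, c(S = 1e12, P = 0)), 90, tolerance = 1e-6)
  expect_equal(reaction_rate(r1, c(S = 200, P = 0)), 45)

  # two-substrate law at joint half-saturation: Vmax/4
  r2 <- reaction("PEPC", "IRREV_MM", c(S1 = -1, S2 = -1, P = 1),
                 list(vmax = 170, km = c(S1 = 40, S2 = 25)))
  expect_equal(reaction_rate(r2, c(S1 = 40, S2 = 25, P = 0)), 42.5)
  expect_equal(reaction_rate(r2, c(S1 = 0, S2 = 25, P = 0)), 0)

  # non-competitive inhibition halves the rate at I = Ki
  r3 <- reaction("X", "IRREV_MM", c(S = -1),
                 list(vmax = 10, km = c(S = 1), ki = c(I = 100)))
  st <- c(S = 1e9, I = 100)
  expect_equal(reaction_rate(r3, st), 5, tolerance = 1e-6)

  # Hill coefficient 2 steepens the response
  r4 <- reaction("SINK", "IRREV_MM", c(S = -1),
                 list(vmax = 10, km = c(S = 100), hill = c(S = 2)))
  expect_equal(reaction_rate(r4, c(S = 100)), 5)
  expect_lt(reaction_rate(r4, c(S = 10)),
            reaction_rate(reaction("l", "IRREV_MM", c(S = -1),
                                   list(vmax = 10, km = c(S = 100))),
                          c(S = 10)))
})

test_that("every Michaelis-Menten flux is bounded by its Vmax", {
  r <- reaction("R", "IRREV_MM", c(S1 = -1, S2 = -1),
                list(vmax = 65, km = c(S1 = 30, S2 = 500)))
  set.seed(11)
  for (i in 1:50) {
    st <- c(S1 = runif(1, 0, 1e5), S2 = runif(1, 0, 1e5))
    expect_lte(reaction_rate(r, st), 65)
    expect_gte(reaction_rate(r, st), 0)
  }
})

test_that("reversible convenience kinetics respect the equilibrium", {
  r <- reaction("MDH", "REV_MM",
                c(S1 = -1, S2 = -1, P1 = 1, P2 = 1),
                list(vmax = 90, keq = 4,
                     km_s = c(S1 = 30, S2 = 50),
                     km_p = c(P1 = 1500, P2 = 60)))
  # at equilibrium (P1*P2 = keq*S1*S2) the net flux vanishes
  st_eq <- c(S1 = 100, S2 = 50, P1 = 4 * 100, P2 = 50)
  expect_equal(reaction_rate(r, st_eq), 0, tolerance = 1e-12)
  # displaced below equilibrium: forward flux; above: reverse
  expect_gt(reaction_rate(r, c(S1 = 100, S2 = 50, P1 = 10, P2 = 10)), 0)
  expect_lt(reaction_rate(r, c(S1 = 1, S2 = 1, P1 = 5000, P2 = 500)), 0)
  # the forward direction saturates at Vmax; the reverse at Vmax/q with
  # q the Km-scaled equilibrium constant (Haldane relationship)
  q <- 4 * (30 * 50) / (1500 * 60)
  set.seed(7)
  for (i in 1:50) {
    st <- setNames(runif(4, 0, 1e5), c("S1", "S2", "P1", "P2"))
    v <- reaction_rate(r, st)
    expect_lte(v, 90)
    expect_gte(v, -90 / q)
  }
})

test_that("diffusion and mass action laws are linear in the gradient", {
  d <- reaction("T", "DIFFUSION", c(A = -1, B = 1),
                list(g = 0.1, from = "A", to = "B"))
  expect_equal(reaction_rate(d, c(A = 300, B = 100)), 20)
  expect_equal(reaction_rate(d, c(A = 150, B = 150)), 0)
  expect_equal(reaction_rate(d, c(A = 100, B = 300)), -20)
  expect_equal(diffusive_flux(0.1, 300, 100), 20)
  expect_equal(diffusive_flux(0.1, 100, 100), 0)

  m <- reaction("CA", "MASS_ACTION", c(A = -1, B = 1),
                list(k = 50, keq = 10, from = "A", to = "B"))
  expect_equal(reaction_rate(m, c(A = 5, B = 50)), 0)
  expect_gt(reaction_rate(m, c(A = 5, B = 10)), 0)
})

test_that("invalid reaction configurations are rejected", {
  expect_error(reaction("bad", "NOT_A_LAW", c(A = -1)), "should be one of")
  expect_error(reaction("bad", "IRREV_MM", c(A = -1),
                        list(vmax = -5, km = c(A = 10))), "Vmax")
  expect_error(reaction("bad", "IRREV_MM", c(A = -1),
                        list(vmax = 5, km = c(A = 0))), "Km")
  r <- reaction("ok", "IRREV_MM", c(A = -1), list(vmax = 5, km = c(A = 10)))
  expect_error(reaction_rate(r, c(A = -1)), "negative")
  expect_error(reaction_rate(r, c(B = 5)), "missing")
})
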