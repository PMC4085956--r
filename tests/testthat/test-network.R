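test_that("assembled RHS matches an independent brute-force evaluation", {
  # oracle equivalence: fast pre-indexed evaluator vs a plain loop over
  # reactions using the scalar rate function
  net <- c4_network("asp_mal_pepck_me", ppfd = 1200)
  rhs <- build_rhs(net)
  y <- setNames(net$pools$init, net$pools$name)
  set.seed(42)
  for (i in 1:5) {
    state <- y * runif(length(y), 0.2, 3)
    state[net$pools$clamped] <- y[net$pools$clamped]
    bf <- brute_force_rhs(net, state)
    expect_lt(max(abs(rhs(state) - bf$deriv)), 1e-10)
    expect_lt(max(abs(attr(rhs, "rates")(state) - bf$rates)), 1e-10)
  }
})

test_that("single conversion splits derivatives by signed stoichiometry", {
  net <- tiny_ab_network(v_flux = 2, volume = 1)
  rhs <- build_rhs(net)
  d <- rhs(c(A = 10, B = 0, ZERO = 0))
  v <- 2 / 10 * 10   # k * A
  expect_equal(unname(d[["A"]]), -v)
  expect_equal(unname(d[["B"]]), +v)
  # a different volume factor scales concentration change, not flux
  net2 <- tiny_ab_network(v_flux = 2, volume = 0.5)
  d2 <- build_rhs(net2)(c(A = 10, B = 0, ZERO = 0))
  expect_equal(unname(d2[["A"]]), -v / 0.5)
})

test_that("clamped pools have zero derivative by construction", {
  net <- c4_network("nadp_me", ppfd = 1000)
  rhs <- build_rhs(net)
  y <- setNames(net$pools$init, net$pools$name)
  d <- rhs(y * 1.7)
  expect_true(all(d[net$pools$clamped] == 0))
})

test_that("orphan pools and unknown pools are configuration errors", {
  net <- tiny_ab_network()
  net$pools <- rbind(net$pools, data.frame(
    name = "LOST", compartment = "TOY", volume = 1, init = 1,
    clamped = FALSE, carbon = 0, nitrogen = 0))
  expect_error(build_rhs(net), "no active reaction")

  net2 <- tiny_ab_network()
  net2$reactions$BAD <- reaction("BAD", "CONSTANT", c(NOWHERE = 1),
                                 list(flux = 1))
  expect_error(build_rhs(net2), "undeclared")
})

test_that("stoichiometric audit passes for every pathway variant", {
  for (v in c("nadp_me", "asp_mal_me", "asp_mal_pepck",
              "asp_mal_pepck_me", "asp_pepck_only")) {
    aud <- stoich_audit(c4_network(v, ppfd = 1000))
    expect_true(all(aud$pass), info = v)
    expect_true(all(aud$moieties_ok), info = v)
  }
})

test_that("audit flags a carbon-breaking reaction", {
  net <- c4_network("nadp_me", ppfd = 1000)
  # deliberately corrupted stoichiometry: OAA -> PEP without the CO2
  net$reactions$BROKEN <- reaction("BROKEN", "MASS_ACTION",
    c(OAA_m = -1, PEP_m = 1),
    list(k = 0.1, keq = Inf, from = "OAA_m", to = "PEP_m"))
  aud <- stoich_audit(net)
  row <- aud[aud$reaction == "BROKEN", ]
  expect_false(row$pass)
  expect_equal(row$carbon_balance, -1)
  # amino-group transfer balances one-for-one
  asp <- stoich_audit(c4_network("asp_mal_me", ppfd = 1000))
  expect_equal(asp$nitrogen_balance[asp$reaction == "AspAT_M"], 0)
})

test_that("conserved moieties stay constant along trajectories", {
  net <- c4_network("asp_mal_pepck_me", ppfd = 1200)
  tr <- simulate(net, times = seq(0, 200, by = 20))
  for (pair in list(c("ATP_m", "ADP_m"), c("ATP_b", "ADP_b"),
                    c("NADPH_m", "NADP_m"), c("NADPH_b", "NADP_b"),
                    c("GLU_m", "OG2_m"), c("GLU_b", "OG2_b"))) {
    tot <- tr[[pair[1]]] + tr[[pair[2]]]
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
  # non-negativity along the trajectory
  expect_gt(min(as.matrix(tr[, -1])), -1e-9)
})

test_that("variant truth table toggles the right reactions", {
  tab <- variant_table()
  expect_equal(nrow(tab), 5)
  std <- c4_network("nadp_me", ppfd = 1000)
  expect_false(std$reactions$PEPCK$active)
  expect_false(std$reactions$AspAT_M$active)
  expect_true(std$reactions$NADP_ME$active)
  expect_false(std$reactions$MDH_B$active)

  me <- c4_network("asp_mal_me", ppfd = 1000)
  expect_true(me$reactions$MDH_B$active)   # Asp route needs BSC MDH
  expect_false(me$reactions$PEPCK$active)

  pk <- c4_network("asp_mal_pepck", ppfd = 1000)
  expect_true(pk$reactions$PEPCK$active)
  expect_false(pk$reactions$MDH_B$active)

  all_on <- c4_network("asp_mal_pepck_me", ppfd = 1000)
  expect_true(all(vapply(c("PEPCK", "MDH_B", "NADP_ME", "AspAT_M"),
                         function(n) all_on$reactions[[n]]$active, TRUE)))
  expect_equal(all_on$reactions$PEPCK$params$vmax, 60)
  expect_equal(all_on$reactions$NADP_ME$params$vmax, 90)

  only <- c4_network("asp_pepck_only", ppfd = 1000)
  expect_false(only$reactions$NADP_ME$active)
  expect_false(only$reactions$MDH_M$active)
  expect_true(only$reactions$PEPCK$active)
  expect_gt(only$reactions$PEPCK$params$vmax, 0)
})

test_that("rebuilding a variant is idempotent", {
  n1 <- c4_network("asp_mal_pepck", ppfd = 800, f_mc = 0.5)
  n2 <- c4_network("asp_mal_pepck", ppfd = 800, f_mc = 0.5)
  expect_identical(lapply(n1$reactions, function(r) r[c("stoich", "law",
                                                        "active")]),
                   lapply(n2$reactions, function(r) r[c("stoich", "law",
                                                        "active")]))
  expect_identical(n1$pools, n2$pools)
})

test_that("overriding a forced-off enzyme is a configuration error", {
  expect_error(c4_network("nadp_me", overrides = c(PEPCK = 100)),
               "forced off")
  net <- c4_network("asp_mal_pepck_me", overrides = c(PEPCK = 100))
  expect_equal(net$reactions$PEPCK$params$vmax, 100)
})
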