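test_that("assimilation and photorespiration arithmetic", {
  expect_equal(assimilation(40, 4, 1), 37)
  expect_equal(assimilation(0, 0, 1), -1)
  # compensation: vc = vo/2 + Rd gives A = 0
  expect_equal(assimilation(3, 4, 1), 0)
  expect_error(assimilation(-1, 0, 1), "vc")
  expect_equal(photorespiration_rate(0), 0)
  expect_equal(photorespiration_rate(4), 2)
})

test_that("leakiness is the leak share of PEPC flux", {
  expect_equal(leakiness(0, 40), 0)
  expect_equal(leakiness(10, 40), 0.25)
  expect_true(is.na(leakiness(5, 0)))
})

test_that("Rubisco kinetics obey their closed forms", {
  p <- c4_params()
  kc <- p$enzymes$RUBISCO$kc; ko <- p$enzymes$RUBISCO$ko
  # saturating CO2 with ample RuBP approaches Vcmax = 65
  r <- rubisco_rates(co2 = 1e7, o2 = 0, rubp = 1e9, pga = 0, params = p)
  expect_equal(unname(r["vc"]), 65, tolerance = 1e-3)
  # no oxygenation without O2
  expect_equal(unname(r["vo"]), 0)
  # half-saturation: C = Kc (1 + O/Ko) gives vc = 32.5
  o <- 250
  r2 <- rubisco_rates(co2 = kc * (1 + o / ko), o2 = o, rubp = 1e9,
                      pga = 0, params = p)
  expect_equal(unname(r2["vc"]), 32.5, tolerance = 1e-3)
  # specificity identity: vo/vc = (Vomax Kc O) / (Vcmax Ko C)
  r3 <- rubisco_rates(co2 = 30, o2 = 400, rubp = 800, pga = 100,
                      params = p)
  expect_equal(unname(r3["vo"] / r3["vc"]),
               0.25 * kc * 400 / (ko * 30), tolerance = 1e-10)
})

test_that("steady state is reached and independent of the initial state", {
  ss1 <- cached_ss("std1500", "nadp_me", ppfd = 1500)
  expect_true(ss1$converged)
  # double every carbon pool; the conserved cofactor/amino moiety totals
  # define the system and stay put
  net <- c4_network("nadp_me", ppfd = 1500)
  moiety <- grepl("^(ATP|ADP|NADPH|NADP|GLU|OG2)_", net$pools$name)
  doubled <- setNames(ifelse(moiety, 1, 2) * net$pools$init,
                      net$pools$name)
  ss2 <- c4_steady_state(network = net, init = doubled)
  expect_true(ss2$converged)
  expect_lt(abs(ss1$a - ss2$a), 1e-4)
})

test_that("flux-balance residuals vanish at convergence", {
  # oracle: independent stoichiometry-times-flux recomputation
  ss <- cached_ss("std1500", "nadp_me", ppfd = 1500)
  expect_lt(max(abs(residuals(ss))), 1e-3)
  ss2 <- cached_ss("mix1000", "asp_mal_pepck_me", ppfd = 1000)
  expect_lt(max(abs(residuals(ss2))), 1e-3)
})

test_that("in darkness the leaf respires: A(PPFD = 0) = -Rd = -1", {
  dark <- c4_steady_state("nadp_me", ppfd = 0)
  expect_equal(dark$a, -1, tolerance = 1e-4)
  expect_equal(dark$vc, 0, tolerance = 1e-4)
})

test_that("carbon closure: decarboxylation feeds fixation plus leak", {
  # steady state of the BSC gas pools: decarb + Rb + photorespired CO2
  # re-release equals Rubisco carboxylation plus the leak
  for (key in c("std1500", "mix1000")) {
    ss <- ss_cache[[key]]
    lhs <- ss$v_decarb + ss$network$params$drivers$rb + 0.5 * ss$vo
    expect_lt(abs(lhs - (ss$vc + ss$v_leak)), 1e-3)
    # the C4 pump itself balances: PEPC equals total decarboxylation
    expect_lt(abs(ss$v_pepc - ss$v_decarb), 1e-3)
    expect_gte(ss$phi, 0); expect_lt(ss$phi, 1)
    expect_lte(ss$a, ss$vc)
  }
})

test_that("amino-group closure: Asp import equals Ala export", {
  ss <- cached_ss("mix1000", "asp_mal_pepck_me", ppfd = 1000)
  # net ASP flux MC->BSC carries amino groups that return as ALA
  expect_lt(abs(ss$fluxes[["T_ASP"]] + ss$fluxes[["T_ALA"]]), 1e-3)
})

test_that("the CO2-concentrating mechanism elevates bundle-sheath CO2", {
  ss <- cached_ss("std1500", "nadp_me", ppfd = 1500)
  expect_gt(ss$co2_bsc_chl_ubar, ss$drivers$ci)
  # stromal decarboxylation keeps the chloroplast above the cytosol
  expect_gt(ss$co2_bsc_chl_ubar, ss$co2_bsc_cyt_ubar)
})

test_that("result object methods expose the fit", {
  ss <- cached_ss("std1500", "nadp_me", ppfd = 1500)
  expect_output(print(ss), "leakiness")
  expect_output(summary(ss), "Transfer-acid gradients")
  co <- coef(ss)
  expect_named(co, c("a", "vc", "vo", "phi", "v_pr", "v_pepc", "v_leak",
                     "v_decarb", "co2_bsc_cyt_ubar", "co2_bsc_chl_ubar"))
  expect_equal(unname(co["a"]), ss$a)
})

test_that("aspartate share calibration is monotone in the AspAT scale", {
  # below the structural share cap the transfer share rises with the
  # AspAT scale; at large scales it saturates at the cap
  shares <- vapply(c(0.01, 0.03, 0.08), function(s) {
    ss <- c4_steady_state("asp_mal_pepck", ppfd = 2000, params = c4_params(),
                          network = c4_network("asp_mal_pepck", ppfd = 2000,
                                               asp_scale = s))
    fl <- ss$fluxes
    fl[["T_ASP"]] / (fl[["T_ASP"]] + fl[["T_MAL"]])
  }, 0)
  expect_true(all(diff(shares) > 0))
  # degenerate target: zero scale means pure malate transfer
  expect_equal(calibrate_asp_share("asp_mal_me", target = 0)$scale, 0)
  expect_error(calibrate_asp_share("nadp_me"), "does not transfer")
})
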