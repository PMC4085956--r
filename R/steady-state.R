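# Steady-state driver: integrates the stiff ODE system with lsoda over
# geometrically growing horizons until the scaled right-hand-side norm
# falls below the steady-state tolerance, then extracts the derived
# physiological metrics.

#' Diffusive transport flux
#'
#' `flux = g * (C_from - C_to)`; the sign carries the direction.
#'
#' @param g conductance (umol m-2 s-1 uM-1).
#' @param c_from,c_to concentrations (uM).
#' @return flux in umol m-2 s-1.
#' @export
diffusive_flux <- function(g, c_from, c_to) {
  if (any(g < 0)) stop("conductance must be >= 0")
  if (any(c(c_from, c_to) < 0)) stop("concentrations must be >= 0")
  g * (c_from - c_to)
}

#' Bundle-sheath CO2 leakiness
#'
#' The fraction of PEPC carboxylation flux that is lost as CO2
#' retro-diffusion from the bundle sheath back to the mesophyll:
#' `phi = v_leak / v_pepc`.
#'
#' @param v_leak CO2 leak flux (umol m-2 s-1).
#' @param v_pepc PEPC carboxylation flux (umol m-2 s-1).
#' @return leakiness (dimensionless), or `NA` when `v_pepc <= 0`.
#' @export
leakiness <- function(v_leak, v_pepc) {
  ifelse(v_pepc > 0, v_leak / v_pepc, NA_real_)
}

#' Net CO2 assimilation rate
#'
#' `A = vc - 0.5 * vo - Rd`.
#'
#' @param vc,vo RuBP carboxylation and oxygenation rates (umol m-2 s-1).
#' @param rd mitochondrial respiration (umol m-2 s-1).
#' @return A in umol m-2 s-1.
#' @export
assimilation <- function(vc, vo, rd) {
  if (any(vc < 0) || any(vo < 0)) stop("vc and vo must be >= 0")
  vc - 0.5 * vo - rd
}

#' Photorespiratory CO2 release
#'
#' Half the oxygenation rate: one CO2 is released per two
#' phosphoglycolate processed.
#'
#' @param vo RuBP oxygenation rate (umol m-2 s-1).
#' @return v_pr in umol m-2 s-1.
#' @export
photorespiration_rate <- function(vo) 0.5 * vo

.transfer_acids <- c("MAL", "ASP", "ALA", "PYR", "PEP", "PGA", "TP")

#' Solve a C4 pathway variant to steady state
#'
#' Integrates the metabolite balance system `dM/dt = v_in - v_out` with a
#' stiff solver (lsoda) over geometrically growing horizons until
#' `max |dM/dt| / max(M, floor)` drops below `ss_rtol` (default 1e-8 s-1)
#' or `t_max` is reached, then extracts fluxes and the derived metrics:
#' net assimilation `A = vc - 0.5 vo - Rd`, leakiness, photorespiration,
#' bundle-sheath CO2, intercellular metabolite gradients and leaf
#' metabolite pools. Deterministic for fixed inputs; non-convergence is
#' reported via `converged = FALSE`, never silently.
#'
#' Either pass a prebuilt `network` or the variant/driver arguments.
#'
#' @param variant pathway variant name, see [c4_network()].
#' @param ppfd,ci,f_mc,let_bsc,pepc_scale,params,overrides forwarded to
#'   [c4_network()] when `network` is not supplied.
#' @param network optional [c4_network()] (overrides the other arguments).
#' @param init optional named initial state (uM); defaults to the pool
#'   table's initial concentrations. Used for warm starts in scans.
#' @return object of class `c4_steady`; see Details.
#' @details The returned object contains `state` (uM), `fluxes`
#'   (umol m-2 s-1), scalar metrics `a`, `vc`, `vo`, `phi`, `v_pr`,
#'   `v_pepc`, `v_leak`, `v_decarb`, `co2_bsc_cyt_ubar`,
#'   `co2_bsc_chl_ubar`, a `gradients` data.frame (per transfer acid:
#'   concentrations in both cytosols, gradient, gradient per unit A), a
#'   `pools` vector of leaf metabolite contents (umol m-2), `converged`,
#'   `residual` (s-1) and `time` (model s).
#' @examples
#' \donttest{
#' ss <- c4_steady_state("nadp_me", ppfd = 1000)
#' ss$a
#' summary(ss)
#' }
#' @export
c4_steady_state <- function(variant = "nadp_me", ppfd = 1500, ci = NULL,
                            f_mc = NULL, let_bsc = NULL, pepc_scale = 1,
                            params = c4_params(), overrides = NULL,
                            network = NULL, init = NULL) {
  if (is.null(network))
    network <- c4_network(variant, ppfd = ppfd, ci = ci, f_mc = f_mc,
                          let_bsc = let_bsc, pepc_scale = pepc_scale,
                          params = params, overrides = overrides)
  pools <- network$pools
  run <- run_to_steady(network, init = init)
  y <- run$state
  res <- run$residual
  fluxes <- run$fluxes
  fx <- function(nm) if (nm %in% names(fluxes)) fluxes[[nm]] else 0
  vc <- fx("RBC_C"); vo <- fx("RBC_O")
  rd <- network$params$drivers$rd
  a <- assimilation(vc, vo, rd)
  v_pepc <- fx("PEPC")
  v_leak <- fx("T_CO2_LEAK")
  v_decarb <- fx("NADP_ME") + fx("PEPCK")
  per_ubar <- network$params$gas$co2_uM_per_ubar

  grads <- do.call(rbind, lapply(.transfer_acids, function(sp) {
    cm <- y[[paste0(sp, "_m")]]; cb <- y[[paste0(sp, "_b")]]
    data.frame(metabolite = sp, c_mc = cm, c_bsc = cb,
               gradient = cm - cb,
               gradient_per_a = if (a > 0) (cm - cb) / a else NA_real_)
  }))

  # leaf contents per unit area: sum over compartments of conc * volume
  species <- sub("_(m|b|bch)$", "", pools$name)
  pool_totals <- tapply(y[pools$name] * pools$volume, species, sum)

  structure(list(
    variant = network$variant, drivers = network$drivers,
    network = network, state = y, fluxes = fluxes,
    a = a, vc = vc, vo = vo,
    phi = leakiness(v_leak, v_pepc),
    v_pr = photorespiration_rate(vo),
    v_pepc = v_pepc, v_leak = v_leak, v_decarb = v_decarb,
    co2_bsc_cyt_ubar = y[["CO2_b"]] / per_ubar,
    co2_bsc_chl_ubar = y[["CO2_bch"]] / per_ubar,
    gradients = grads, pools = c(pool_totals),
    converged = run$converged, residual = res, time = run$time
  ), class = "c4_steady")
}

#' Integrate a reaction network to steady state
#'
#' Low-level driver shared by [c4_steady_state()] and the toy fixtures:
#' repeated stiff integration over geometrically growing horizons until
#' the scaled derivative norm `max |dM/dt| / max(M, floor)` falls below
#' the steady-state tolerance, or `t_max` is exhausted.
#'
#' @param network any network accepted by [build_rhs()]; solver settings
#'   are taken from `network$params$solver` (see [c4_params()]).
#' @param init optional named initial state (uM).
#' @return list with `state`, `fluxes`, `residual` (s-1), `converged`,
#'   `time` (model s).
#' @export
run_to_steady <- function(network, init = NULL) {
  sol <- network$params$solver
  rhs <- build_rhs(network)
  pools <- network$pools

  y0 <- setNames(pools$init, pools$name)
  if (!is.null(init)) {
    common <- intersect(names(init), names(y0))
    y0[common] <- pmax(init[common], 0)
    y0[pools$clamped] <- pools$init[pools$clamped]
  }

  ode_fn <- function(t, y, parms) list(unname(rhs(y)))
  ss_atol <- if (is.null(sol$ss_atol)) 1e-6 else sol$ss_atol
  ss_norm <- function(y) {
    d <- rhs(y)
    if (all(abs(d) < ss_atol)) return(0)
    max(abs(d) / pmax(y, sol$ss_floor))
  }

  t_now <- 0; y <- y0
  horizon <- sol$t_chunk0
  res <- ss_norm(y)
  while (res > sol$ss_rtol && t_now < sol$t_max) {
    horizon <- min(horizon, sol$t_max - t_now)
    out <- suppressWarnings(
      deSolve::lsoda(y, c(0, horizon), ode_fn, parms = NULL,
                     rtol = sol$rtol, atol = sol$atol,
                     maxsteps = 50000))
    y <- pmax(out[nrow(out), -1], 0)
    names(y) <- pools$name
    y[pools$clamped] <- y0[pools$clamped]
    t_now <- t_now + horizon
    horizon <- horizon * 4
    res <- ss_norm(y)
  }
  list(state = y, fluxes = attr(rhs, "rates")(y), residual = res,
       converged = res <= sol$ss_rtol, time = t_now)
}

#' @export
print.c4_steady <- function(x, digits = 3, ...) {
  cat("C4 steady state, variant '", x$variant, "'",
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat(sprintf("  PPFD %g, Ci %g ubar, f_MC %.2f, LET_BSC %.2f\n",
              x$drivers$ppfd, x$drivers$ci, x$drivers$f_mc,
              x$drivers$let_bsc))
  cat(sprintf("  A = %.*f umol m-2 s-1 (vc %.*f, vo %.*f, Rd %g)\n",
              digits, x$a, digits, x$vc, digits, x$vo, x$drivers$rd))
  cat(sprintf("  leakiness %.*f, photorespiration %.*f, BSC CO2 %.0f ubar\n",
              digits, x$phi, digits, x$v_pr, x$co2_bsc_chl_ubar))
  invisible(x)
}

#' @export
summary.c4_steady <- function(object, ...) {
  print(object, ...)
  cat("\nMajor fluxes (umol m-2 s-1):\n")
  keep <- c("PEPC", "MDH_M", "AspAT_M", "PPDK", "NADP_ME", "PEPCK",
            "T_MAL", "T_ASP", "T_ALA", "T_PYR", "T_PEP", "T_PGA", "T_TP",
            "T_CO2_LEAK", "RBC_C", "RBC_O", "PGA_RED_M", "PGA_RED_B")
  fl <- object$fluxes[names(object$fluxes) %in% keep]
  print(round(fl, 3))
  cat("\nTransfer-acid gradients (uM):\n")
  print(object$gradients, row.names = FALSE)
  cat(sprintf("\nresidual %.2e s-1 at t = %g s\n",
              object$residual, object$time))
  invisible(object)
}

#' @export
coef.c4_steady <- function(object, ...) {
  c(a = object$a, vc = object$vc, vo = object$vo, phi = object$phi,
    v_pr = object$v_pr, v_pepc = object$v_pepc, v_leak = object$v_leak,
    v_decarb = object$v_decarb,
    co2_bsc_cyt_ubar = object$co2_bsc_cyt_ubar,
    co2_bsc_chl_ubar = object$co2_bsc_chl_ubar)
}

#' Flux-balance residuals at a steady state
#'
#' Returns, per unclamped pool, the net areal flux imbalance
#' `sum(nu * v)` in umol m-2 s-1, recomputed by the brute-force loop over
#' reactions (independent of the solver's fast path).
#'
#' @param object a `c4_steady` result.
#' @param ... unused.
#' @return named numeric vector.
#' @export
residuals.c4_steady <- function(object, ...) {
  bf <- brute_force_rhs(object$network, object$state)
  pools <- object$network$pools
  flux_resid <- bf$deriv * pools$volume[match(names(bf$deriv), pools$name)]
  flux_resid[!pools$clamped[match(names(flux_resid), pools$name)]]
}

#' Integrate a variant network over time
#'
#' Runs the stiff integrator from the default (or given) initial state and
#' returns the trajectory — mainly useful for inspecting relaxation to
#' steady state and for conservation checks.
#'
#' @param object a [c4_network()].
#' @param nsim unused (kept for the generic's signature).
#' @param seed unused; the system is deterministic.
#' @param times numeric vector of output times (s).
#' @param init optional named initial state.
#' @param ... unused.
#' @return a data.frame: `time` plus one column per pool (uM).
#' @export
simulate.c4_network <- function(object, nsim = 1, seed = NULL,
                                times = seq(0, 1000, by = 10),
                                init = NULL, ...) {
  rhs <- build_rhs(object)
  pools <- object$pools
  y0 <- setNames(pools$init, pools$name)
  if (!is.null(init)) y0[names(init)] <- init
  sol <- object$params$solver
  out <- deSolve::lsoda(y0, times, function(t, y, p) list(unname(rhs(y))),
                        parms = NULL, rtol = sol$rtol, atol = sol$atol,
                        maxsteps = 50000)
  df <- as.data.frame(out)
  names(df) <- c("time", pools$name)
  df
}

#' @export
plot.c4_steady <- function(x, ...) {
  fl <- x$fluxes
  keep <- fl[abs(fl) > 1e-6]
  op <- graphics::par(mar = c(8, 4, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(keep, las = 2, ylab = "flux (umol m-2 s-1)",
                    main = paste0("variant '", x$variant, "', A = ",
                                  round(x$a, 2)), ...)
  invisible(x)
}
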