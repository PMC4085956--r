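# Rate-law library. Each enzymatic or transport step is described by a
# reaction spec (see `reaction()`), and `reaction_rate()` evaluates its
# flux (umol m-2 s-1) at a given state. Laws:
#
#   IRREV_MM       product of Michaelis terms over >= 1 substrates
#   REV_MM         reversible "convenience" kinetics, Haldane-consistent
#   MASS_ACTION    kf * (A - B/Keq), used for fast near-equilibrium steps
#   DIFFUSION      g * (C_from - C_to)
#   RUBISCO_C/O    RuBP carboxylation / oxygenation with CO2-O2 competition
#   LIGHT_SYNTHESIS  Michaelis term with a Vmax set by the electron
#                    transport chain (min(VmaxE, eps*J)); the effective
#                    Vmax is computed at setup from the drivers
#   CONSTANT       fixed flux (respiration, O2 evolution)
#   CAPPED_MM      Michaelis kinetics additionally capped at a fraction of
#                  the instantaneous Rubisco PGA production (the mesophyll
#                  PGA-reduction share cap); `cap_fun(state)` supplies the cap

#' Construct a reaction specification
#'
#' @param name reaction identifier.
#' @param law one of `"IRREV_MM"`, `"REV_MM"`, `"MASS_ACTION"`,
#'   `"DIFFUSION"`, `"RUBISCO_C"`, `"RUBISCO_O"`, `"LIGHT_SYNTHESIS"`,
#'   `"CONSTANT"`, `"CAPPED_MM"`.
#' @param stoich named numeric vector of signed stoichiometric coefficients
#'   (pool names); rational coefficients are allowed.
#' @param params named list of rate-law constants (`vmax`, `km` named
#'   vector over substrate pools, `keq`, `g`, `k`, `flux`, ...).
#' @param active logical; inactive reactions contribute zero flux.
#' @param exchange logical; exchange steps (respiration, carbon export
#'   sinks) are exempt from the carbon-balance audit.
#' @return a list of class `c4_reaction`.
#' @export
reaction <- function(name, law, stoich, params = list(), active = TRUE,
                     exchange = FALSE) {
  law <- match.arg(law, c("IRREV_MM", "REV_MM", "MASS_ACTION", "DIFFUSION",
                          "RUBISCO_C", "RUBISCO_O", "LIGHT_SYNTHESIS",
                          "CONSTANT", "CAPPED_MM"))
  if (!is.null(params$vmax) && params$vmax < 0)
    stop("reaction '", name, "': Vmax must be >= 0")
  if (!is.null(params$km) && any(params$km <= 0))
    stop("reaction '", name, "': Km must be > 0")
  structure(list(name = name, law = law, stoich = stoich, params = params,
                 active = active, exchange = exchange),
            class = "c4_reaction")
}

mm_term <- function(s, km) s / (s + km)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the flux of a single reaction
#'
#' Reference (scalar) evaluator used by tests and the network audit; the
#' integrator uses an equivalent pre-indexed fast path built by
#' [build_rhs()]. State values are clipped at zero before evaluation so
#' that tiny negative excursions of the integrator cannot produce fluxes
#' with the wrong sign.
#'
#' @param rxn a [reaction()].
#' @param state named numeric vector of pool concentrations (uM).
#' @return flux in umol m-2 s-1.
#' @export
reaction_rate <- function(rxn, state) {
  if (!isTRUE(rxn$active)) return(0)
  if (any(!is.finite(state))) stop("non-finite concentration in state")
  if (any(state < -1e-6)) stop("negative concentration in state")
  p <- rxn$params
  s <- function(nm) {
    if (!nm %in% names(state)) stop("pool '", nm, "' missing from state")
    max(state[[nm]], 0)
  }
  switch(rxn$law,
    IRREV_MM = {
      f <- p$vmax
      for (nm in names(p$km)) {
        h <- if (nm %in% names(p$hill)) p$hill[[nm]] else 1
        f <- f * mm_term(s(nm)^h, p$km[[nm]]^h)
      }
      # non-competitive product/feedback inhibition terms
      for (nm in names(p$ki)) {
        hi <- if (nm %in% names(p$ki_hill)) p$ki_hill[[nm]] else 1
        f <- f / (1 + (s(nm) / p$ki[[nm]])^hi)
      }
      f
    },
    CAPPED_MM = {
      f <- p$vmax
      for (nm in names(p$km)) f <- f * mm_term(s(nm), p$km[[nm]])
      min(f, p$cap_fun(state))
    },
    REV_MM = {
      # convenience kinetics: bounded both ways, equilibrium at
      # P1*P2/(S1*S2) = keq
      a <- vapply(names(p$km_s), function(nm) s(nm) / p$km_s[[nm]], 0)
      b <- vapply(names(p$km_p), function(nm) s(nm) / p$km_p[[nm]], 0)
      q <- p$keq * prod(unlist(p$km_s)) / prod(unlist(p$km_p))
      p$vmax * (prod(a) - prod(b) / q) /
        (prod(1 + a) + prod(1 + b) - 1)
    },
    MASS_ACTION = p$k * (s(p$from) - s(p$to) / p$keq),
    DIFFUSION = p$g * (s(p$from) - s(p$to)),
    RUBISCO_C = {
      C <- s(p$co2); O <- s(p$o2)
      p$vcmax * C / (C + p$kc * (1 + O / p$ko)) *
        mm_term(s(p$rubp), p$km_rubp) / (1 + s(p$pga) / p$ki_pga)
    },
    RUBISCO_O = {
      C <- s(p$co2); O <- s(p$o2)
      (p$vomax_ratio * p$vcmax) * O / (O + p$ko * (1 + C / p$kc)) *
        mm_term(s(p$rubp), p$km_rubp) / (1 + s(p$pga) / p$ki_pga)
    },
    LIGHT_SYNTHESIS = p$vmax_eff * mm_term(s(p$substrate), p$km),
    CONSTANT = p$flux,
    stop("unknown rate law: ", rxn$law)
  )
}
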