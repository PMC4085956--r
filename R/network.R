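# Network assembly: the pool table, the shared reaction set from which all
# pathway variants are carved, the ODE right-hand side, and the
# stoichiometric audit.
#
# Compartment layout: metabolite pools live in the cytosolic space of each
# cell; the chloroplast compartments hold the energy/redox pools, RuBP,
# phosphoglycolate and the gases. Chloroplast enzymes draw metabolites
# from the cell pool and energy from the chloroplast pool (envelope
# translocation lumped); CO2 and O2 keep an explicit cytosol/chloroplast
# split so that cytosolic (PEPCK) and stromal (NADP-ME) CO2 release face
# different diffusion paths to Rubisco and to the leak.

# carbon and amino-nitrogen atom counts per metabolite species
.atoms <- function() {
  c4 <- function(c, n = 0) c(carbon = c, nitrogen = n)
  list(CO2 = c4(1), HCO3 = c4(1), O2 = c4(0), PEP = c4(3), OAA = c4(4),
       MAL = c4(4), PYR = c4(3), ASP = c4(4, 1), ALA = c4(3, 1),
       GLU = c4(5, 1), OG2 = c4(5), PGA = c4(3), TP = c4(3),
       RUBP = c4(5), PGLY = c4(2),
       ATP = c4(0), ADP = c4(0), NADPH = c4(0), NADP = c4(0))
}

#' Pool table of the C4 leaf model
#'
#' One row per metabolite pool: name (species suffixed by location, `_m` /
#' `_b` cytosol of MC / BSC, `_bch` BSC chloroplast; energy pools `_m` /
#' `_b` live in the respective chloroplast), compartment, volume, initial
#' concentration, clamp status and atom counts. `CO2_m` and `O2_m` are
#' boundary pools clamped at the dissolved concentrations implied by the
#' intercellular partial pressures.
#'
#' @param params a [c4_params()] list.
#' @param ci intercellular CO2 (ubar).
#' @param o2_mbar ambient O2 (mbar).
#' @return data.frame of pools.
#' @export
c4_pools <- function(params = c4_params(), ci = params$drivers$ci,
                     o2_mbar = params$drivers$o2_mbar) {
  at <- .atoms()
  ini <- params$init
  row <- function(name, comp, init, clamped = FALSE) {
    sp <- sub("_(m|b|bch)$", "", name)
    data.frame(name = name, compartment = comp,
               volume = unname(params$volumes[comp]),
               init = init, clamped = clamped,
               carbon = at[[sp]][["carbon"]],
               nitrogen = at[[sp]][["nitrogen"]])
  }
  co2_m <- ci * params$gas$co2_uM_per_ubar
  o2_m <- o2_mbar * params$gas$o2_uM_per_mbar
  m <- ini$metabolite
  do.call(rbind, list(
    row("CO2_m", "MC_CYT", co2_m, clamped = TRUE),
    row("O2_m", "MC_CYT", o2_m, clamped = TRUE),
    row("HCO3_m", "MC_CYT", m),
    row("PEP_m", "MC_CYT", m), row("OAA_m", "MC_CYT", m),
    row("MAL_m", "MC_CYT", m), row("PYR_m", "MC_CYT", m),
    row("ASP_m", "MC_CYT", m), row("ALA_m", "MC_CYT", m),
    row("GLU_m", "MC_CYT", ini$glu), row("OG2_m", "MC_CYT", ini$og2),
    row("PGA_m", "MC_CYT", ini$calvin), row("TP_m", "MC_CYT", ini$calvin),
    row("ATP_m", "MC_CHL", ini$atp), row("ADP_m", "MC_CHL", ini$adp),
    row("NADPH_m", "MC_CHL", ini$nadph), row("NADP_m", "MC_CHL", ini$nadp),
    row("CO2_b", "BSC_CYT", co2_m), row("O2_b", "BSC_CYT", o2_m),
    row("OAA_b", "BSC_CYT", m), row("MAL_b", "BSC_CYT", m),
    row("PYR_b", "BSC_CYT", m), row("ASP_b", "BSC_CYT", m),
    row("ALA_b", "BSC_CYT", m),
    row("GLU_b", "BSC_CYT", ini$glu), row("OG2_b", "BSC_CYT", ini$og2),
    row("PEP_b", "BSC_CYT", m), row("PGA_b", "BSC_CYT", ini$calvin),
    row("TP_b", "BSC_CYT", ini$calvin),
    row("CO2_bch", "BSC_CHL", co2_m), row("O2_bch", "BSC_CHL", o2_m),
    row("RUBP_bch", "BSC_CHL", ini$calvin), row("PGLY_bch", "BSC_CHL", m),
    row("ATP_b", "BSC_CHL", ini$atp), row("ADP_b", "BSC_CHL", ini$adp),
    row("NADPH_b", "BSC_CHL", ini$nadph), row("NADP_b", "BSC_CHL", ini$nadp)
  ))
}

# Rubisco carboxylation/oxygenation evaluated directly from a named state;
# used by the mesophyll PGA-reduction cap and exported as rubisco_rates().
.rubisco_pair <- function(rb, state) {
  C <- max(state[["CO2_bch"]], 0); O <- max(state[["O2_bch"]], 0)
  f_r <- state[["RUBP_bch"]]
  f_r <- max(f_r, 0) / (max(f_r, 0) + rb$km_rubp)
  # product (PGA / stromal phosphate) feedback, lumped
  f_r <- f_r / (1 + max(state[["PGA_b"]], 0) / rb$ki_pga)
  vc <- rb$vcmax * C / (C + rb$kc * (1 + O / rb$ko)) * f_r
  vo <- (rb$vomax_ratio * rb$vcmax) * O / (O + rb$ko * (1 + C / rb$kc)) * f_r
  c(vc = vc, vo = vo)
}

#' Rubisco carboxylation and oxygenation rates
#'
#' `vc = Vcmax * C / (C + Kc (1 + O/Ko)) * RuBP/(RuBP + Km)`, and the
#' competing oxygenation with `Vomax = vomax_ratio * Vcmax`, so that
#' `vo/vc = (Vomax Kc O) / (Vcmax Ko C)`.
#'
#' @param co2,o2 dissolved concentrations at the BSC chloroplast (uM).
#' @param rubp RuBP concentration (uM).
#' @param params a [c4_params()] list.
#' @return named vector `c(vc, vo)` in umol m-2 s-1.
#' @export
rubisco_rates <- function(co2, o2, rubp, pga = 0, params = c4_params()) {
  if (any(c(co2, o2, rubp, pga) < 0)) stop("concentrations must be >= 0")
  .rubisco_pair(params$enzymes$RUBISCO,
                c(CO2_bch = co2, O2_bch = o2, RUBP_bch = rubp, PGA_b = pga))
}

#' Full reaction set of the C4 leaf model
#'
#' Builds every reaction of the shared network with the default
#' enzyme capacities; pathway variants deactivate subsets (see
#' [c4_network()]).
#' Light-synthesis capacities and the constant source terms are resolved
#' from `energy` and the respiration split in `params$drivers`.
#'
#' @param params a [c4_params()] list.
#' @param energy a [energy_supply()] result.
#' @return named list of [reaction()] objects.
#' @export
c4_reactions <- function(params = c4_params(),
                         energy = energy_supply(c4_light(1500,
                                                         params = params))) {
  e <- params$enzymes
  tr <- params$transport
  rb <- e$RUBISCO
  s_cap <- params$pga_export_max
  cap_fun <- function(state) {
    v <- .rubisco_pair(rb, state)
    s_cap * (2 * v[["vc"]] + 1.5 * v[["vo"]])
  }
  cap_spec <- list(kind = "rubisco_pga", rb = rb, frac = s_cap)
  # aspartate-share cap: AspAT_M flux held at <= ratio * MDH_M flux
  asp_ratio <- params$asp_flux_target / (1 - params$asp_flux_target)
  mdh <- e$MDH_M
  mdh_rate <- function(state) {
    a1 <- max(state[["OAA_m"]], 0) / mdh$km_oaa
    a2 <- max(state[["NADPH_m"]], 0) / mdh$km_nadph
    b1 <- max(state[["MAL_m"]], 0) / mdh$km_mal
    b2 <- max(state[["NADP_m"]], 0) / mdh$km_nadp
    q <- mdh$keq * (mdh$km_oaa * mdh$km_nadph) / (mdh$km_mal * mdh$km_nadp)
    mdh$vmax * (a1 * a2 - b1 * b2 / q) /
      ((1 + a1) * (1 + a2) + (1 + b1) * (1 + b2) - 1)
  }
  asp_cap_fun <- function(state) max(0, asp_ratio * mdh_rate(state))
  asp_cap_spec <- list(kind = "mdh_share", ratio = asp_ratio, mdh = mdh)
  diff_rxn <- function(name, from, to, g) {
    st <- c(-1, 1); names(st) <- c(from, to)
    reaction(name, "DIFFUSION", st, list(g = g, from = from, to = to))
  }
  rxns <- list(
    # --- mesophyll carboxylation arm -----------------------------------
    CA_M = reaction("CA_M", "MASS_ACTION",
      c(CO2_m = -1, HCO3_m = 1),
      list(k = e$CA_M$k, keq = e$CA_M$keq, from = "CO2_m", to = "HCO3_m")),
    PEPC = reaction("PEPC", "IRREV_MM",
      c(PEP_m = -1, HCO3_m = -1, OAA_m = 1),
      list(vmax = e$PEPC$vmax,
           km = c(PEP_m = e$PEPC$km_pep, HCO3_m = e$PEPC$km_hco3),
           ki = c(MAL_m = e$PEPC$ki_mal, OAA_m = e$PEPC$ki_oaa))),
    MDH_M = reaction("MDH_M", "REV_MM",
      c(OAA_m = -1, NADPH_m = -1, MAL_m = 1, NADP_m = 1),
      list(vmax = e$MDH_M$vmax, keq = e$MDH_M$keq,
           km_s = c(OAA_m = e$MDH_M$km_oaa, NADPH_m = e$MDH_M$km_nadph),
           km_p = c(MAL_m = e$MDH_M$km_mal, NADP_m = e$MDH_M$km_nadp))),
    AspAT_M = reaction("AspAT_M", "CAPPED_MM",
      c(OAA_m = -1, GLU_m = -1, ASP_m = 1, OG2_m = 1),
      list(vmax = e$AspAT_M$vmax,
           km = c(OAA_m = e$AspAT_M$km_oaa, GLU_m = e$AspAT_M$km_glu),
           cap_fun = asp_cap_fun, cap_spec = asp_cap_spec)),
    AlaAT_M = reaction("AlaAT_M", "IRREV_MM",
      c(ALA_m = -1, OG2_m = -1, PYR_m = 1, GLU_m = 1),
      list(vmax = e$AlaAT_M$vmax,
           km = c(ALA_m = e$AlaAT_M$km_ala, OG2_m = e$AlaAT_M$km_og2))),
    PPDK = reaction("PPDK", "IRREV_MM",
      c(PYR_m = -1, ATP_m = -2, PEP_m = 1, ADP_m = 2),
      list(vmax = e$PPDK$vmax,
           km = c(PYR_m = e$PPDK$km_pyr, ATP_m = e$PPDK$km_atp))),
    # anaplerotic PEP/PGA substrate cycle (mutase + enolase vs the
    # glycolytic return): a feedback-inhibited synthesis valve and a slow
    # drain size the C4 carrier pool without pinning PEP to PGA
    PEP_SYN_M = reaction("PEP_SYN_M", "IRREV_MM",
      c(PGA_m = -1, PEP_m = 1),
      list(vmax = e$PEP_SYN_M$vmax, km = c(PGA_m = e$PEP_SYN_M$km_pga),
           ki = c(PEP_m = e$PEP_SYN_M$ki_pep),
           ki_hill = c(PEP_m = e$PEP_SYN_M$ki_hill))),
    PEP_DRAIN_M = reaction("PEP_DRAIN_M", "IRREV_MM",
      c(PEP_m = -1, PGA_m = 1),
      list(vmax = e$PEP_DRAIN_M$vmax,
           km = c(PEP_m = e$PEP_DRAIN_M$km_pep))),
    PK_M = reaction("PK_M", "IRREV_MM",
      c(PEP_m = -1, ADP_m = -1, PYR_m = 1, ATP_m = 1),
      list(vmax = e$PK_M$vmax,
           km = c(PEP_m = e$PK_M$km_pep, ADP_m = e$PK_M$km_adp),
           ki = c(PYR_m = e$PK_M$ki_pyr),
           ki_hill = c(PYR_m = e$PK_M$ki_hill))),
    PYR_OX_M = reaction("PYR_OX_M", "IRREV_MM",
      c(PYR_m = -1),
      list(vmax = e$PYR_OX_M$vmax, km = c(PYR_m = e$PYR_OX_M$km_pyr)),
      exchange = TRUE),
    PGA_RED_M = reaction("PGA_RED_M", "CAPPED_MM",
      c(PGA_m = -1, ATP_m = -1, NADPH_m = -1,
        TP_m = 1, ADP_m = 1, NADP_m = 1),
      list(vmax = e$PGA_RED_M$vmax,
           km = c(PGA_m = e$PGA_RED_M$km_pga, ATP_m = e$PGA_RED_M$km_atp,
                  NADPH_m = e$PGA_RED_M$km_nadph),
           cap_fun = cap_fun, cap_spec = cap_spec)),
    # carbon export to sucrose/starch synthesis: sigmoidal engagement so
    # that the autocatalytic Calvin cycle is not drained while building up
    TP_SINK_M = reaction("TP_SINK_M", "IRREV_MM",
      c(TP_m = -1),
      list(vmax = e$TP_SINK_M$vmax, km = c(TP_m = e$TP_SINK_M$km_tp),
           hill = c(TP_m = e$TP_SINK_M$hill)),
      exchange = TRUE),
    ATP_SYN_M = reaction("ATP_SYN_M", "LIGHT_SYNTHESIS",
      c(ADP_m = -1, ATP_m = 1),
      list(vmax_eff = energy$vmax_atp_m, substrate = "ADP_m", km = 50)),
    NADPH_SYN_M = reaction("NADPH_SYN_M", "LIGHT_SYNTHESIS",
      c(NADP_m = -1, NADPH_m = 1),
      list(vmax_eff = energy$vmax_nadph_m, substrate = "NADP_m", km = 50)),
    RESP_M = reaction("RESP_M", "CONSTANT",
      c(CO2_m = 1), list(flux = params$drivers$rm), exchange = TRUE),

    # --- intercellular diffusion (positive = MC -> BSC) ----------------
    T_MAL = diff_rxn("T_MAL", "MAL_m", "MAL_b", tr$g_met),
    T_ASP = diff_rxn("T_ASP", "ASP_m", "ASP_b", tr$g_met),
    T_ALA = diff_rxn("T_ALA", "ALA_m", "ALA_b", tr$g_met),
    T_PYR = diff_rxn("T_PYR", "PYR_m", "PYR_b", tr$g_met),
    T_PEP = diff_rxn("T_PEP", "PEP_m", "PEP_b", tr$g_met),
    T_PGA = diff_rxn("T_PGA", "PGA_m", "PGA_b", tr$g_met),
    T_TP  = diff_rxn("T_TP", "TP_m", "TP_b", tr$g_met),
    # gas leak (positive = BSC -> MC, the retro-diffusion direction)
    T_CO2_LEAK = diff_rxn("T_CO2_LEAK", "CO2_b", "CO2_m", tr$g_co2),
    T_O2_LEAK  = diff_rxn("T_O2_LEAK", "O2_b", "O2_m", tr$g_o2),

    # --- bundle sheath decarboxylation arm -----------------------------
    AspAT_B = reaction("AspAT_B", "IRREV_MM",
      c(ASP_b = -1, OG2_b = -1, OAA_b = 1, GLU_b = 1),
      list(vmax = e$AspAT_B$vmax,
           km = c(ASP_b = e$AspAT_B$km_asp, OG2_b = e$AspAT_B$km_og2))),
    AlaAT_B = reaction("AlaAT_B", "IRREV_MM",
      c(PYR_b = -1, GLU_b = -1, ALA_b = 1, OG2_b = 1),
      list(vmax = e$AlaAT_B$vmax,
           km = c(PYR_b = e$AlaAT_B$km_pyr, GLU_b = e$AlaAT_B$km_glu))),
    MDH_B = reaction("MDH_B", "REV_MM",
      c(OAA_b = -1, NADPH_b = -1, MAL_b = 1, NADP_b = 1),
      list(vmax = e$MDH_B$vmax, keq = e$MDH_B$keq,
           km_s = c(OAA_b = e$MDH_B$km_oaa, NADPH_b = e$MDH_B$km_nadph),
           km_p = c(MAL_b = e$MDH_B$km_mal, NADP_b = e$MDH_B$km_nadp))),
    NADP_ME = reaction("NADP_ME", "IRREV_MM",
      c(MAL_b = -1, NADP_b = -1, PYR_b = 1, CO2_bch = 1, NADPH_b = 1),
      list(vmax = e$NADP_ME$vmax,
           km = c(MAL_b = e$NADP_ME$km_mal, NADP_b = e$NADP_ME$km_nadp))),
    PEPCK = reaction("PEPCK", "IRREV_MM",
      c(OAA_b = -1, ATP_b = -1, PEP_b = 1, CO2_b = 1, ADP_b = 1),
      list(vmax = e$PEPCK$vmax,
           km = c(OAA_b = e$PEPCK$km_oaa, ATP_b = e$PEPCK$km_atp))),
    T_CO2_ENV = diff_rxn("T_CO2_ENV", "CO2_b", "CO2_bch", tr$g_env),
    T_O2_ENV  = diff_rxn("T_O2_ENV", "O2_bch", "O2_b", tr$g_env),

    # --- Calvin-Benson cycle and photorespiration ----------------------
    RBC_C = reaction("RBC_C", "RUBISCO_C",
      c(RUBP_bch = -1, CO2_bch = -1, PGA_b = 2),
      list(vcmax = rb$vcmax, kc = rb$kc, ko = rb$ko, km_rubp = rb$km_rubp,
           ki_pga = rb$ki_pga, pga = "PGA_b",
           co2 = "CO2_bch", o2 = "O2_bch", rubp = "RUBP_bch")),
    RBC_O = reaction("RBC_O", "RUBISCO_O",
      c(RUBP_bch = -1, O2_bch = -1, PGA_b = 1, PGLY_bch = 1),
      list(vcmax = rb$vcmax, vomax_ratio = rb$vomax_ratio,
           kc = rb$kc, ko = rb$ko, km_rubp = rb$km_rubp,
           ki_pga = rb$ki_pga, pga = "PGA_b",
           co2 = "CO2_bch", o2 = "O2_bch", rubp = "RUBP_bch")),
    PHOTORESP = reaction("PHOTORESP", "IRREV_MM",
      c(PGLY_bch = -2, ATP_b = -1, NADPH_b = -0.5,
        PGA_b = 1, CO2_b = 1, ADP_b = 1, NADP_b = 0.5),
      list(vmax = e$PHOTORESP$vmax,
           km = c(PGLY_bch = e$PHOTORESP$km_pgly))),
    PGA_RED_B = reaction("PGA_RED_B", "IRREV_MM",
      c(PGA_b = -1, ATP_b = -1, NADPH_b = -1,
        TP_b = 1, ADP_b = 1, NADP_b = 1),
      list(vmax = e$PGA_RED_B$vmax,
           km = c(PGA_b = e$PGA_RED_B$km_pga, ATP_b = e$PGA_RED_B$km_atp,
                  NADPH_b = e$PGA_RED_B$km_nadph))),
    RUBP_REGEN = reaction("RUBP_REGEN", "IRREV_MM",
      c(TP_b = -5 / 3, ATP_b = -1, RUBP_bch = 1, ADP_b = 1),
      list(vmax = e$RUBP_REGEN$vmax,
           km = c(TP_b = e$RUBP_REGEN$km_tp, ATP_b = e$RUBP_REGEN$km_atp),
           ki = c(RUBP_bch = e$RUBP_REGEN$ki_rubp))),
    TP_SINK_B = reaction("TP_SINK_B", "IRREV_MM",
      c(TP_b = -1),
      list(vmax = e$TP_SINK_B$vmax, km = c(TP_b = e$TP_SINK_B$km_tp),
           hill = c(TP_b = e$TP_SINK_B$hill)),
      exchange = TRUE),
    ATP_SYN_B = reaction("ATP_SYN_B", "LIGHT_SYNTHESIS",
      c(ADP_b = -1, ATP_b = 1),
      list(vmax_eff = energy$vmax_atp_b, substrate = "ADP_b", km = 50)),
    NADPH_SYN_B = reaction("NADPH_SYN_B", "LIGHT_SYNTHESIS",
      c(NADP_b = -1, NADPH_b = 1),
      list(vmax_eff = energy$vmax_nadph_b, substrate = "NADP_b", km = 50)),
    O2_EVOL_B = reaction("O2_EVOL_B", "CONSTANT",
      c(O2_bch = 1), list(flux = energy$v_o2_b), exchange = TRUE),
    RESP_B = reaction("RESP_B", "CONSTANT",
      c(CO2_b = 1), list(flux = params$drivers$rb), exchange = TRUE)
  )
  rxns
}

#' Assemble the ODE right-hand side
#'
#' For each unclamped pool, `dM/dt = sum(nu * v) / volume` over the active
#' reactions; clamped pools get derivative zero by construction. The
#' returned function is deterministic and closes over a pre-indexed fast
#' evaluator; `attr(f, "rates")` evaluates all reaction fluxes at a state.
#'
#' @param network a [c4_network()] (or any list with `$pools` and
#'   `$reactions` in the same shape).
#' @return function `f(state)` mapping a named concentration vector to its
#'   named time derivative (uM s-1).
#' @export
build_rhs <- function(network) {
  pools <- network$pools
  rxns <- Filter(function(r) isTRUE(r$active), network$reactions)
  if (length(rxns) == 0) stop("network has no active reactions")
  pn <- pools$name
  # configuration checks: referenced pools exist; no orphan unclamped pool
  referenced <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  bad <- setdiff(referenced, pn)
  if (length(bad))
    stop("reactions reference undeclared pools: ",
         paste(bad, collapse = ", "))
  orphans <- setdiff(pn[!pools$clamped], referenced)
  if (length(orphans))
    stop("unclamped pools appear in no active reaction: ",
         paste(orphans, collapse = ", "))

  nr <- length(rxns)
  S <- matrix(0, nrow(pools), nr, dimnames = list(pn, names(rxns)))
  for (j in seq_len(nr)) S[names(rxns[[j]]$stoich), j] <- rxns[[j]]$stoich

  idx <- function(nm) match(nm, pn)
  evals <- lapply(rxns, function(r) {
    p <- r$params
    switch(r$law,
      IRREV_MM = {
        i <- idx(names(p$km)); km <- as.numeric(p$km); vmax <- p$vmax
        h <- rep(1, length(km))
        if (!is.null(p$hill))
          h[match(names(p$hill), names(p$km))] <- as.numeric(p$hill)
        ii <- idx(names(p$ki)); ki <- as.numeric(p$ki)
        hi <- rep(1, length(ii))
        if (!is.null(p$ki_hill))
          hi[match(names(p$ki_hill), names(p$ki))] <- as.numeric(p$ki_hill)
        if (all(h == 1) && !length(ii)) {
          function(y) vmax * prod(y[i] / (y[i] + km))
        } else {
          kmh <- km^h
          function(y) {
            yh <- y[i]^h
            vmax * prod(yh / (yh + kmh)) / prod(1 + (y[ii] / ki)^hi)
          }
        }
      },
      CAPPED_MM = if (p$cap_spec$kind == "rubisco_pga") {
        i <- idx(names(p$km)); km <- as.numeric(p$km); vmax <- p$vmax
        rbp <- p$cap_spec$rb; frac <- p$cap_spec$frac
        ic <- idx("CO2_bch"); io <- idx("O2_bch"); ir <- idx("RUBP_bch")
        ig <- idx("PGA_b")
        vo_max <- rbp$vomax_ratio * rbp$vcmax
        function(y) {
          v <- vmax * prod(y[i] / (y[i] + km))
          f_r <- y[ir] / (y[ir] + rbp$km_rubp) / (1 + y[ig] / rbp$ki_pga)
          vc <- rbp$vcmax * y[ic] / (y[ic] + rbp$kc * (1 + y[io] / rbp$ko)) * f_r
          vo <- vo_max * y[io] / (y[io] + rbp$ko * (1 + y[ic] / rbp$kc)) * f_r
          min(v, frac * (2 * vc + 1.5 * vo))
        }
      } else {
        i <- idx(names(p$km)); km <- as.numeric(p$km); vmax <- p$vmax
        md <- p$cap_spec$mdh; ratio <- p$cap_spec$ratio
        io1 <- idx("OAA_m"); in1 <- idx("NADPH_m")
        im1 <- idx("MAL_m"); ip1 <- idx("NADP_m")
        q <- md$keq * (md$km_oaa * md$km_nadph) / (md$km_mal * md$km_nadp)
        function(y) {
          v <- vmax * prod(y[i] / (y[i] + km))
          a1 <- y[io1] / md$km_oaa; a2 <- y[in1] / md$km_nadph
          b1 <- y[im1] / md$km_mal; b2 <- y[ip1] / md$km_nadp
          vm <- md$vmax * (a1 * a2 - b1 * b2 / q) /
            ((1 + a1) * (1 + a2) + (1 + b1) * (1 + b2) - 1)
          min(v, max(0, ratio * vm))
        }
      },
      REV_MM = {
        si <- idx(names(p$km_s)); pi_ <- idx(names(p$km_p))
        ks <- as.numeric(p$km_s); kp <- as.numeric(p$km_p)
        q <- p$keq * prod(ks) / prod(kp); vmax <- p$vmax
        function(y) {
          a <- y[si] / ks; b <- y[pi_] / kp
          vmax * (prod(a) - prod(b) / q) /
            (prod(1 + a) + prod(1 + b) - 1)
        }
      },
      MASS_ACTION = {
        i1 <- idx(p$from); i2 <- idx(p$to); k <- p$k; keq <- p$keq
        function(y) k * (y[i1] - y[i2] / keq)
      },
      DIFFUSION = {
        i1 <- idx(p$from); i2 <- idx(p$to); g <- p$g
        function(y) g * (y[i1] - y[i2])
      },
      RUBISCO_C = {
        ic <- idx(p$co2); io <- idx(p$o2); ir <- idx(p$rubp)
        ip <- idx(p$pga); kip <- p$ki_pga
        function(y) p$vcmax * y[ic] / (y[ic] + p$kc * (1 + y[io] / p$ko)) *
          y[ir] / (y[ir] + p$km_rubp) / (1 + y[ip] / kip)
      },
      RUBISCO_O = {
        ic <- idx(p$co2); io <- idx(p$o2); ir <- idx(p$rubp)
        ip <- idx(p$pga); kip <- p$ki_pga
        vo_max <- p$vomax_ratio * p$vcmax
        function(y) vo_max * y[io] / (y[io] + p$ko * (1 + y[ic] / p$kc)) *
          y[ir] / (y[ir] + p$km_rubp) / (1 + y[ip] / kip)
      },
      LIGHT_SYNTHESIS = {
        i <- idx(p$substrate); km <- p$km; vm <- p$vmax_eff
        function(y) vm * y[i] / (y[i] + km)
      },
      CONSTANT = {
        fl <- p$flux
        function(y) fl
      },
      stop("unknown rate law: ", r$law)
    )
  })

  vol <- pools$volume
  clamped <- pools$clamped
  align <- function(state) {
    nm <- names(state)
    y <- if (is.null(nm) || identical(nm, pn)) unname(state)
         else unname(state)[match(pn, nm)]
    y[y < 0] <- 0
    y
  }
  rates_fun <- function(state) {
    y <- align(state)
    setNames(vapply(evals, function(f) f(y), 0), names(rxns))
  }
  f <- function(state) {
    y <- align(state)
    v <- vapply(evals, function(f) f(y), 0)
    d <- as.numeric(S %*% v) / vol
    d[clamped] <- 0
    setNames(d, pn)
  }
  attr(f, "rates") <- rates_fun
  attr(f, "stoich_matrix") <- S
  f
}

#' Brute-force flux and derivative evaluation (audit oracle)
#'
#' Evaluates every active reaction with the scalar [reaction_rate()] and
#' accumulates derivatives by looping over stoichiometries. Slow on
#' purpose; this is the independent path against which [build_rhs()] is
#' verified.
#'
#' @param network a [c4_network()].
#' @param state named concentration vector.
#' @return list with `rates` and `deriv`.
#' @export
brute_force_rhs <- function(network, state) {
  pools <- network$pools
  d <- setNames(numeric(nrow(pools)), pools$name)
  rates <- c()
  for (r in network$reactions) {
    if (!isTRUE(r$active)) next
    v <- reaction_rate(r, state)
    rates[r$name] <- v
    for (nm in names(r$stoich)) {
      i <- match(nm, pools$name)
      d[nm] <- d[nm] + r$stoich[[nm]] * v / pools$volume[i]
    }
  }
  d[pools$clamped] <- 0
  list(rates = rates, deriv = d)
}

#' Stoichiometric audit of a reaction network
#'
#' Per active reaction, checks elemental carbon and amino-group balance of
#' the stoichiometry map (exchange reactions exempt) and whether the
#' conserved moiety pairs (ATP+ADP and NADPH+NADP per chloroplast,
#' GLU+OG2 per cell) are preserved. Report-only: returns a data.frame and
#' never throws.
#'
#' @param network a [c4_network()].
#' @return data.frame with one row per active reaction and a `pass` flag.
#' @export
stoich_audit <- function(network) {
  pools <- network$pools
  moieties <- list(
    adenylate_m = c("ATP_m", "ADP_m"), adenylate_b = c("ATP_b", "ADP_b"),
    pyridine_m = c("NADPH_m", "NADP_m"), pyridine_b = c("NADPH_b", "NADP_b"),
    glu_og2_m = c("GLU_m", "OG2_m"), glu_og2_b = c("GLU_b", "OG2_b")
  )
  rows <- lapply(Filter(function(r) isTRUE(r$active), network$reactions),
    function(r) {
      i <- match(names(r$stoich), pools$name)
      carbon <- sum(r$stoich * pools$carbon[i])
      nitrogen <- sum(r$stoich * pools$nitrogen[i])
      moiety_ok <- all(vapply(moieties, function(mp) {
        abs(sum(r$stoich[names(r$stoich) %in% mp])) < 1e-12
      }, TRUE))
      data.frame(reaction = r$name, exchange = r$exchange,
                 carbon_balance = carbon, nitrogen_balance = nitrogen,
                 moieties_ok = moiety_ok,
                 pass = moiety_ok &&
                   (r$exchange || (abs(carbon) < 1e-12 &&
                                     abs(nitrogen) < 1e-12)))
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
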