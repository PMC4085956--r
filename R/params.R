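# Central parameter set. Every kinetic constant used by the network lives
# here so that re-parameterisation is a single-file affair. Units:
#   Vmax                umol m-2 s-1 (leaf area basis)
#   Km, concentrations  uM
#   conductances g      umol m-2 s-1 uM-1
#   compartment volume  L m-2

#' Default parameters of the C4 leaf model
#'
#' Returns the full nested parameter list: compartment volumes, enzyme
#' maximum activities and Michaelis constants, transport conductances,
#' light-reaction constants, gas solubilities and the steady-state solver
#' defaults. Any element can be overridden by passing a named list to
#' `modify`; names use `$`-path notation flattened one level, e.g.
#' `modify = list(enzymes = list(PEPC = list(vmax = 144)))` merges
#' recursively.
#'
#' Maximum activities follow the measured/assumed capacities of
#' NADP-ME-type leaves (malate dehydrogenase 90, PPDK 90, aminotransferases
#' 400, NADP-malic enzyme 90, PEPC 170, Rubisco 65, PEPCK 60, bundle-sheath
#' MDH 60 umol m-2 s-1). Michaelis constants are typical values from C4
#' enzymology compendia; they are deliberately kept in one place because
#' the headline results depend mostly on capacities, stoichiometry and the
#' energy budget, not on individual Km values.
#'
#' @param modify optional named list of overrides, merged recursively.
#' @return a nested list of class `c4_params`.
#' @examples
#' p <- c4_params()
#' p$enzymes$PEPC$vmax
#' p2 <- c4_params(list(light = list(let_bsc = 0.5)))
#' p2$light$let_bsc
#' @export
c4_params <- function(modify = NULL) {
  p <- list(
    volumes = c(MC_CYT = 0.02, MC_CHL = 0.01, BSC_CYT = 0.01, BSC_CHL = 0.01),

    # Henry-law conversions at 25 C (dissolved uM per unit partial pressure)
    gas = list(
      co2_uM_per_ubar = 0.0334,   # ~33.4 mM bar-1
      o2_uM_per_mbar  = 1.26      # ~1.26 mM bar-1
    ),

    enzymes = list(
      # carbonic anhydrase: fast CO2 <-> HCO3- interconversion, MC cytosol
      CA_M     = list(k = 50, keq = 10),
      PEPC     = list(vmax = 170, km_pep = 100, km_hco3 = 25,
                      # weak malate guard; the OAA guard throttles PEPC
                      # only when OAA hoards (mM scale), keeping the
                      # carboxylation from outrunning OAA consumption
                      ki_mal = 1e5, ki_oaa = 3000),
      MDH_M    = list(vmax = 90, km_oaa = 30, km_nadph = 50,
                      km_mal = 1500, km_nadp = 60, keq = 4000),
      MDH_B    = list(vmax = 60, km_oaa = 30, km_nadph = 50,
                      km_mal = 1500, km_nadp = 60, keq = 4000),
      # aminotransferases: irreversible MM in the direction the C4 cycle
      # runs them (MC aminates OAA and deaminates ALA; BSC the converse)
      AspAT_M  = list(vmax = 400, km_oaa = 50, km_glu = 2500),
      AspAT_B  = list(vmax = 400, km_asp = 800, km_og2 = 250),
      AlaAT_M  = list(vmax = 400, km_ala = 800, km_og2 = 250),
      AlaAT_B  = list(vmax = 400, km_pyr = 250, km_glu = 2500),
      PPDK     = list(vmax = 90, km_pyr = 80, km_atp = 150),
      NADP_ME  = list(vmax = 90, km_mal = 450, km_nadp = 8),
      PEPCK    = list(vmax = 60, km_oaa = 100, km_atp = 150),
      RUBISCO  = list(vcmax = 65, kc = 21.7, ko = 570,
                      vomax_ratio = 0.25, km_rubp = 300,
                      # lumped PGA/stromal-phosphate product feedback
                      ki_pga = 8000),
      PGA_RED_M = list(vmax = 120, km_pga = 500, km_nadph = 60,
                       km_atp = 150),
      # anaplerotic PEP/PGA substrate cycle in the MC cytosol: sizes the
      # C4 carrier pool; synthesis shuts off once PEP is replete
      PEP_SYN_M = list(vmax = 10, km_pga = 300, ki_pep = 250, ki_hill = 2),
      PEP_DRAIN_M = list(vmax = 3, km_pep = 1000),
      # pyruvate kinase: connects PEP to the pyruvate/alanine family;
      # shut off by pyruvate so it only sizes a starved pool
      PK_M = list(vmax = 5, km_pep = 200, km_adp = 50,
                  ki_pyr = 300, ki_hill = 2),
      # slow mitochondrial pyruvate oxidation: drains carrier excess
      PYR_OX_M = list(vmax = 9, km_pyr = 4000),
      PGA_RED_B = list(vmax = 180, km_pga = 500, km_nadph = 60,
                       km_atp = 150),
      RUBP_REGEN = list(vmax = 120, km_tp = 120, km_atp = 150,
                        # product feedback standing in for stromal Pi
                        ki_rubp = 3000),
      PHOTORESP  = list(vmax = 40, km_pgly = 150),
      TP_SINK_M  = list(vmax = 35, km_tp = 1500, hill = 2),
      TP_SINK_B  = list(vmax = 35, km_tp = 1500, hill = 2)
    ),

    transport = list(
      g_met = 0.05,   # plasmodesmatal conductance, all transfer acids
      g_co2 = 0.15,   # CO2 leak BSC cytosol <-> MC cytosol
      # O2 conductance on the dissolved-concentration basis; equals ~0.04
      # of g_co2 when both are expressed per unit partial pressure
      g_o2  = 0.15,
      g_env = 0.3     # chloroplast envelope, CO2 and O2
    ),

    light = list(
      absorptance = 0.85,   # leaf absorptance
      f_spectral  = 0.85,   # spectral quality factor
      theta       = 0.7,    # curvature of the electron transport response
      jmax_m      = 320,    # umol e- m-2 s-1, mesophyll
      jmax_b      = 180,    # umol e- m-2 s-1, bundle sheath
      f_mc        = 0.65,   # default light share to mesophyll
      let_bsc     = 0,      # default LET fraction in BSC (u = v)
      eps_atp     = 0.65,   # ATP per e- of mesophyll LET (1.3 per 2 e-)
      eps_nadph   = 0.5,    # NADPH per e- (1 NADPH per 2 e-)
      eps_atp_cyc = 0.65,   # ATP per e- through cyclic flow (per photon
                            # it matches the BSC LET chain: no allocation
                            # penalty for running PSII in the sheath)
      eps_atp_b   = 1.30,   # ATP per e- of bundle-sheath LET
      vmaxe_atp   = 400,    # ATP synthase capacity cap
      vmaxe_nadph = 250     # NADP+ reductase capacity cap
    ),

    drivers = list(
      ci = 150,        # intercellular CO2, ubar
      o2_mbar = 210,   # ambient O2
      rd = 1,          # total mitochondrial respiration
      rm = 0.5, rb = 0.5
    ),

    # Fraction of Calvin-cycle PGA production that can at most be exported
    # to the mesophyll for reduction (PGA/triose-phosphate shuttle cap).
    pga_export_max = 0.75,

    # Aspartate share of C4-acid formation: mesophyll AspAT flux is held at
    # no more than target/(1-target) of the malate-route (MDH) flux,
    # mirroring the carbon-label partition between the two transfer acids.
    asp_flux_target = 0.25,

    init = list(
      metabolite = 50,  # uM, most carbon pools
      calvin = 300,     # uM, RuBP/PGA/TP: start the autocatalytic Calvin
                        # cycle at operating scale so it spins up, not down
      glu = 2000, og2 = 500,
      atp = 1000, adp = 500, nadph = 250, nadp = 250
    ),

    solver = list(
      rtol = 1e-8, atol = 1e-10,
      ss_rtol = 1e-8,       # relative steady-state criterion, s-1
      ss_atol = 1e-6,       # absolute criterion, uM s-1 (asymptotic tails)
      ss_floor = 1,         # uM concentration floor in the relative test
      t_max = 4e4,          # model seconds
      t_chunk0 = 200        # first integration horizon (grows geometrically)
    ),

    # AspAT_M Vmax scale factors realising ~25% aspartate share of the
    # C4-acid transfer at PPFD 2000, Ci 150 (see calibrate_asp_share);
    # regenerate with calibrate_asp_share(), frozen here for speed.
    asp_scale = c(nadp_me = NA_real_,
                  asp_mal_me = 0.125,
                  asp_mal_pepck = 0.125,
                  asp_mal_pepck_me = 0.125,
                  asp_pepck_only = 1)
  )
  if (!is.null(modify)) p <- modifyList(p, modify)
  class(p) <- "c4_params"
  p
}
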