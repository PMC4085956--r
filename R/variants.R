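# Pathway variants: the five model configurations are carved out of the
# shared network by switching enzymes (and the transport steps that only
# they feed) on or off.
#
# variant            transfer acids        decarboxylase(s)   notes
# nadp_me            MAL / PYR             NADP-ME            textbook model
# asp_mal_me         MAL+ASP / PYR+ALA     NADP-ME            needs MDH in BSC
# asp_mal_pepck      MAL+ASP / PYR+ALA+PEP NADP-ME + PEPCK    Asp via PEPCK
# asp_mal_pepck_me   MAL+ASP / PYR+ALA+PEP NADP-ME + PEPCK    both Asp routes
# asp_pepck_only     ASP / ALA+PEP (PYR in) PEPCK             hypothetical

.variant_levels <- c("nadp_me", "asp_mal_me", "asp_mal_pepck",
                     "asp_mal_pepck_me", "asp_pepck_only")

# enzymes switched OFF per variant (everything else stays on)
.variant_off <- list(
  nadp_me          = c("AspAT_M", "AspAT_B", "AlaAT_M", "AlaAT_B",
                       "MDH_B", "PEPCK", "T_ASP", "T_ALA", "T_PEP"),
  asp_mal_me       = c("PEPCK", "T_PEP"),
  asp_mal_pepck    = c("MDH_B"),
  asp_mal_pepck_me = character(0),
  asp_pepck_only   = c("MDH_M", "MDH_B", "NADP_ME", "PPDK", "T_MAL")
)

#' Variant truth table
#'
#' @return data.frame: one row per variant, logical columns per switchable
#'   enzyme.
#' @export
variant_table <- function() {
  enz <- c("MDH_M", "MDH_B", "NADP_ME", "PEPCK", "PPDK",
           "AspAT_M", "AspAT_B", "AlaAT_M", "AlaAT_B")
  out <- data.frame(variant = .variant_levels)
  for (e in enz)
    out[[e]] <- vapply(.variant_levels,
                       function(v) !(e %in% .variant_off[[v]]), TRUE)
  out
}

#' Build a pathway-variant network
#'
#' Assembles the full reaction network for one of the five pathway
#' variants at the given drivers, applies the variant's enzyme switch-offs
#' and the calibrated aspartate-share scaling of mesophyll AspAT, clamps
#' pools that no active reaction touches, and returns everything the
#' steady-state solver needs.
#'
#' @param variant one of `"nadp_me"`, `"asp_mal_me"`, `"asp_mal_pepck"`,
#'   `"asp_mal_pepck_me"`, `"asp_pepck_only"`.
#' @param ppfd incident light (umol m-2 s-1).
#' @param ci intercellular CO2 (ubar).
#' @param f_mc mesophyll light-allocation fraction; default from params.
#' @param let_bsc bundle-sheath LET fraction; default from params.
#' @param pepc_scale multiplier on the PEPC maximum activity.
#' @param asp_scale multiplier on the mesophyll AspAT maximum activity;
#'   `NULL` uses the calibrated default for the variant.
#' @param params a [c4_params()] list.
#' @param overrides named numeric vector of enzyme Vmax overrides, e.g.
#'   `c(PEPCK = 120)`. Overriding an enzyme the variant forces off is a
#'   configuration error.
#' @return list of class `c4_network`.
#' @export
c4_network <- function(variant = "nadp_me", ppfd = 1500, ci = NULL,
                       f_mc = NULL, let_bsc = NULL, pepc_scale = 1,
                       asp_scale = NULL, params = c4_params(),
                       overrides = NULL) {
  variant <- match.arg(variant, .variant_levels)
  if (is.null(ci)) ci <- params$drivers$ci
  if (ci <= 0) stop("ci must be > 0")
  off <- .variant_off[[variant]]
  if (!is.null(overrides)) {
    bad <- intersect(names(overrides), off)
    if (length(bad))
      stop("cannot override enzymes forced off by variant '", variant,
           "': ", paste(bad, collapse = ", "))
    for (nm in names(overrides))
      params$enzymes[[nm]]$vmax <- unname(overrides[[nm]])
  }
  params$enzymes$PEPC$vmax <- params$enzymes$PEPC$vmax * pepc_scale
  if (is.null(asp_scale)) {
    asp_scale <- params$asp_scale[[variant]]
    if (is.na(asp_scale)) asp_scale <- 1
  }
  params$enzymes$AspAT_M$vmax <- params$enzymes$AspAT_M$vmax * asp_scale

  light <- c4_light(ppfd, f_mc = f_mc, let_bsc = let_bsc, params = params)
  energy <- energy_supply(light)
  pools <- c4_pools(params, ci = ci)
  rxns <- c4_reactions(params, energy)
  if (variant == "asp_pepck_only") {
    # aspartate is the sole C4 acid here: the share cap does not apply
    rxns$AspAT_M <- reaction("AspAT_M", "IRREV_MM", rxns$AspAT_M$stoich,
      list(vmax = params$enzymes$AspAT_M$vmax,
           km = c(OAA_m = params$enzymes$AspAT_M$km_oaa,
                  GLU_m = params$enzymes$AspAT_M$km_glu)))
    # pyruvate is the essential amino-group carrier in this variant:
    # keep only a token oxidative drain for pool sizing
    rxns$PYR_OX_M$params$vmax <- 1
  }
  for (nm in off) rxns[[nm]]$active <- FALSE

  # pools untouched by any active reaction are clamped at their initial
  # value (e.g. the aspartate/alanine machinery of the standard model)
  active_pools <- unique(unlist(lapply(Filter(function(r) r$active, rxns),
                                       function(r) names(r$stoich))))
  pools$clamped <- pools$clamped | !(pools$name %in% active_pools)

  structure(list(
    variant = variant, pools = pools, reactions = rxns,
    params = params, light = light, energy = energy,
    drivers = list(ppfd = ppfd, ci = ci, f_mc = light$f_mc,
                   let_bsc = light$let_bsc, rd = params$drivers$rd,
                   pepc_scale = pepc_scale, asp_scale = asp_scale)
  ), class = "c4_network")
}

#' @export
print.c4_network <- function(x, ...) {
  act <- sum(vapply(x$reactions, function(r) isTRUE(r$active), TRUE))
  cat("C4 leaf network, variant '", x$variant, "'\n", sep = "")
  cat(sprintf("  %d pools (%d clamped), %d active reactions\n",
              nrow(x$pools), sum(x$pools$clamped), act))
  cat(sprintf("  PPFD %g, Ci %g ubar, f_MC %.2f, LET_BSC %.2f\n",
              x$drivers$ppfd, x$drivers$ci, x$drivers$f_mc,
              x$drivers$let_bsc))
  invisible(x)
}

#' Calibrate the aspartate share of C4-acid transfer
#'
#' Finds, by deterministic bisection on a single mesophyll-AspAT scale
#' factor, the scaling under which the steady-state aspartate fraction of
#' the MC-to-BSC C4-acid transfer flux (Asp / (Asp + Mal)) matches
#' `target` at the reference condition. The carbon-labelling partition
#' this reproduces puts about a quarter of newly fixed carbon into
#' aspartate and three quarters into malate.
#'
#' @param variant a variant name that transfers both Asp and malate.
#' @param target desired aspartate flux share, default 0.25.
#' @param ppfd,ci reference drivers (defaults: 2000, 150).
#' @param params a [c4_params()] list.
#' @param tol acceptable deviation of the achieved share.
#' @param max_iter bisection iterations.
#' @return list with `scale`, `share`, `iterations`.
#' @export
calibrate_asp_share <- function(variant, target = 0.25, ppfd = 2000,
                                ci = 150, params = c4_params(),
                                tol = 0.02, max_iter = 40) {
  variant <- match.arg(variant, .variant_levels)
  if (variant %in% c("nadp_me", "asp_pepck_only"))
    stop("variant '", variant, "' does not transfer both Asp and malate")
  if (target < 0 || target >= 1) stop("target must lie in [0, 1)")
  if (target == 0) return(list(scale = 0, share = 0, iterations = 0L))

  share_at <- function(scale, state0 = NULL) {
    net <- c4_network(variant, ppfd = ppfd, ci = ci, params = params,
                      asp_scale = scale)
    ss <- c4_steady_state(network = net, init = state0)
    fl <- ss$fluxes
    list(share = fl[["T_ASP"]] / (fl[["T_ASP"]] + fl[["T_MAL"]]),
         state = ss$state)
  }
  lo <- 0; hi <- 1
  r <- share_at(hi)
  if (r$share < target)
    stop("calibration error: share at full AspAT activity (",
         signif(r$share, 3), ") does not bracket target ", target)
  state <- r$state
  it <- 0L; mid <- hi; share <- r$share
  while (it < max_iter && abs(share - target) > tol / 2) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    r <- share_at(mid, state)
    share <- r$share; state <- r$state
    if (share > target) hi <- mid else lo <- mid
  }
  list(scale = mid, share = share, iterations = it)
}
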