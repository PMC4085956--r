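# Light reactions: electron transport in each cell type and the resulting
# ATP/NADPH synthesis capacities. The bundle sheath runs an adjustable mix
# of linear electron transport (LET; NADPH + ATP + O2) and cyclic flow
# (ATP only), controlled by a single fraction u = v = let_bsc applied to
# both the light reaching PSII and the LET share of Jmax.

#' Non-rectangular hyperbola for electron transport
#'
#' Smaller root of `theta*J^2 - (I2 + Jmax)*J + I2*Jmax = 0`: the standard
#' saturating response of whole-chain electron transport to the photon flux
#' absorbed by PSII.
#'
#' @param i2 photosynthetically active radiation absorbed by PSII
#'   (umol m-2 s-1).
#' @param jmax maximal electron transport rate (umol e- m-2 s-1).
#' @param theta empirical curvature factor, in (0, 1).
#' @return electron transport rate J, `0 <= J <= min(i2, jmax)`.
#' @examples
#' nonrect_hyperbola(500, 400, 0.7)  # 285.714...
#' @export
nonrect_hyperbola <- function(i2, jmax, theta) {
  if (any(theta <= 0) || any(theta >= 1))
    stop("theta must lie strictly between 0 and 1")
  if (any(i2 < 0)) stop("i2 must be >= 0")
  if (any(jmax < 0)) stop("jmax must be >= 0")
  b <- i2 + jmax
  disc <- pmax(b * b - 4 * theta * i2 * jmax, 0)
  j <- (b - sqrt(disc)) / (2 * theta)
  # guard the degenerate i2*jmax = 0 case against 0/0 noise
  j[i2 == 0 | jmax == 0] <- 0
  j
}

#' Light-reaction parameter set
#'
#' @param ppfd incident photosynthetic photon flux density (umol m-2 s-1).
#' @param f_mc fraction of absorbed light allocated to mesophyll cells.
#' @param let_bsc proportion u = v of light and Jmax engaged in linear
#'   electron transport in the bundle sheath, in `[0, 1]`.
#' @param params a [c4_params()] list (its `$light` block is used).
#' @return list of class `c4_light` with the resolved constants.
#' @export
c4_light <- function(ppfd, f_mc = NULL, let_bsc = NULL,
                     params = c4_params()) {
  lp <- params$light
  if (is.null(f_mc)) f_mc <- lp$f_mc
  if (is.null(let_bsc)) let_bsc <- lp$let_bsc
  if (ppfd < 0) stop("ppfd must be >= 0")
  if (f_mc < 0 || f_mc > 1) stop("f_mc must lie in [0, 1]")
  if (let_bsc < 0 || let_bsc > 1) stop("let_bsc must lie in [0, 1]")
  lp$f_mc <- NULL
  lp$let_bsc <- NULL
  structure(c(lp, list(ppfd = ppfd, f_mc = f_mc, let_bsc = let_bsc)),
            class = "c4_light")
}

#' Split bundle-sheath light between linear and cyclic electron transport
#'
#' The LET chain receives half of a fraction `u` of the light absorbed by
#' the bundle sheath (the half being the PSII share of absorbed quanta) and
#' a fraction `v` of the bundle-sheath Jmax, with `u = v = let_bsc`. The
#' remaining light and capacity drive cyclic (ATP-only) flow.
#'
#' @param light a [c4_light()] object.
#' @param i_b light absorbed by bundle-sheath cells (umol m-2 s-1).
#' @return list with `j_l_b` (LET) and `j_cyc_b` (cyclic) electron
#'   transport rates.
#' @export
bsc_let_split <- function(light, i_b) {
  if (i_b < 0) stop("i_b must be >= 0")
  u <- light$let_bsc
  i_l_b <- 0.5 * u * i_b
  jmax_l_b <- u * light$jmax_b
  j_l_b <- if (u > 0) nonrect_hyperbola(i_l_b, jmax_l_b, light$theta) else 0
  # cyclic flow is PSI-driven: the remaining quanta feed it without the
  # PSII half-share that applies to the linear chain
  i_cyc <- (1 - u) * i_b
  jmax_cyc <- (1 - u) * light$jmax_b
  j_cyc_b <- if (u < 1) nonrect_hyperbola(i_cyc, jmax_cyc, light$theta) else 0
  list(j_l_b = j_l_b, j_cyc_b = j_cyc_b)
}

#' O2 evolution supported by linear electron transport
#'
#' LET turns over water splitting at `v_LET = J_l / 2` (one NADPH and two
#' ATP per two electrons) and evolves half an O2 per turnover, i.e.
#' `v_O2 = J_l / 4`.
#'
#' @param j_l linear electron transport rate (umol e- m-2 s-1).
#' @return list with `v_let` and `v_o2` (umol m-2 s-1).
#' @export
o2_evolution <- function(j_l) {
  if (any(j_l < 0)) stop("j_l must be >= 0")
  v_let <- 0.5 * j_l
  list(v_let = v_let, v_o2 = 0.5 * v_let)
}

#' Electron transport and energy-supply capacities for both cell types
#'
#' Computes absorbed light per cell, electron transport rates (all-LET in
#' the mesophyll; LET/cyclic split in the bundle sheath), the effective
#' maximal rates of ATP and NADPH synthesis `min(VmaxE, eps * J)`, and O2
#' evolution. Bundle-sheath NADPH synthesis is fed by the LET chain only;
#' bundle-sheath ATP synthesis by total electron flow.
#'
#' @param light a [c4_light()] object.
#' @return list of class `c4_energy` with elements `i_m`, `i_b`, `j_m`,
#'   `j_l_b`, `j_cyc_b`, `j_b`, `vmax_atp_m`, `vmax_nadph_m`,
#'   `vmax_atp_b`, `vmax_nadph_b`, `v_o2_m`, `v_o2_b`.
#' @export
energy_supply <- function(light) {
  absorbed <- light$ppfd * light$absorptance * light$f_spectral
  i_m <- absorbed * light$f_mc
  i_b <- absorbed * (1 - light$f_mc)
  # mesophyll: all electrons through LET; PSII receives half the quanta
  j_m <- nonrect_hyperbola(0.5 * i_m, light$jmax_m, light$theta)
  sp <- bsc_let_split(light, i_b)
  j_b <- sp$j_l_b + sp$j_cyc_b
  structure(list(
    i_m = i_m, i_b = i_b,
    j_m = j_m, j_l_b = sp$j_l_b, j_cyc_b = sp$j_cyc_b, j_b = j_b,
    vmax_atp_m   = min(light$vmaxe_atp, light$eps_atp * j_m),
    vmax_nadph_m = min(light$vmaxe_nadph, light$eps_nadph * j_m),
    vmax_atp_b   = min(light$vmaxe_atp,
                       light$eps_atp_b * sp$j_l_b +
                         light$eps_atp_cyc * sp$j_cyc_b),
    vmax_nadph_b = min(light$vmaxe_nadph, light$eps_nadph * sp$j_l_b),
    v_o2_m = o2_evolution(j_m)$v_o2,
    v_o2_b = o2_evolution(sp$j_l_b)$v_o2
  ), class = "c4_energy")
}
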