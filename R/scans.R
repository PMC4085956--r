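# Parameter scans over steady-state runs: light response, light
# allocation between the cell types, PEPC sensitivity, and the
# transfer-acid gradient snapshot. Every grid point is solved from the
# same default initial state: the network admits more than one steady
# state in pathological corners (a dark, carbon-drained leaf is also
# stationary), and chaining states across grid points can silently hand
# a dead branch from one point to the next.

.all_variants <- function() .variant_levels

.scan_grid_check <- function(grid) {
  if (length(grid) < 3 || any(diff(grid) <= 0))
    stop("scan grid must be strictly increasing with >= 3 points")
}

.ss_row <- function(ss) {
  data.frame(
    a = ss$a, vc = ss$vc, vo = ss$vo, phi = ss$phi, v_pr = ss$v_pr,
    v_pepc = ss$v_pepc, v_leak = ss$v_leak, v_decarb = ss$v_decarb,
    co2_bsc_cyt_ubar = ss$co2_bsc_cyt_ubar,
    co2_bsc_chl_ubar = ss$co2_bsc_chl_ubar,
    mal_pool = unname(ss$pools["MAL"]), asp_pool = unname(ss$pools["ASP"]),
    ala_pool = unname(ss$pools["ALA"]), pyr_pool = unname(ss$pools["PYR"]),
    pep_pool = unname(ss$pools["PEP"]),
    converged = ss$converged, residual = ss$residual)
}

#' Light-response scan
#'
#' Steady states over a PPFD grid for one or more pathway variants at
#' fixed Ci. Non-converged points are flagged in the table, not dropped.
#' The attribute `"best_variant"` records, per PPFD, which variant
#' attains the maximal A.
#'
#' @param variants character vector of variant names (default: all five).
#' @param ppfd increasing PPFD grid (umol m-2 s-1).
#' @param ci intercellular CO2 (ubar).
#' @param let_bsc bundle-sheath LET fraction applied to every variant.
#' @param params a [c4_params()] list.
#' @return data.frame with one row per (variant, PPFD).
#' @export
light_response <- function(variants = .all_variants(),
                           ppfd = seq(0, 2500, by = 50), ci = 150,
                           let_bsc = NULL, params = c4_params()) {
  .scan_grid_check(ppfd)
  rows <- list()
  for (v in variants) {
    for (p in ppfd) {
      ss <- c4_steady_state(v, ppfd = p, ci = ci, let_bsc = let_bsc,
                            params = params)
      rows[[paste(v, p)]] <- cbind(data.frame(variant = v, ppfd = p),
                                   .ss_row(ss))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- vapply(unique(out$ppfd), function(p) {
    sub <- out[out$ppfd == p, ]
    sub$variant[which.max(sub$a)]
  }, "")
  attr(out, "best_variant") <- data.frame(ppfd = unique(out$ppfd),
                                          best = best)
  out
}

#' Light-allocation scan
#'
#' Steady-state A as a function of the mesophyll light share f_MC at
#' fixed PPFD and Ci, for each variant and each bundle-sheath LET
#' fraction. The attribute `"optimum"` holds the argmax f_MC per
#' (variant, LET) pair; flat ties are broken toward the lower f_MC and
#' flagged.
#'
#' @param variants character vector of variant names.
#' @param f_mc increasing allocation grid in `[0, 1]`, step <= 0.05.
#' @param let_bsc numeric vector of LET fractions to scan.
#' @param ppfd,ci fixed drivers (defaults 300, 150).
#' @param params a [c4_params()] list.
#' @return data.frame with one row per (variant, let_bsc, f_mc).
#' @export
allocation_scan <- function(variants = .all_variants(),
                            f_mc = seq(0, 1, by = 0.05),
                            let_bsc = c(0, 0.25, 0.5, 1),
                            ppfd = 300, ci = 150, params = c4_params()) {
  .scan_grid_check(f_mc)
  if (max(diff(f_mc)) > 0.05 + 1e-12)
    stop("f_mc grid step must be <= 0.05")
  rows <- list()
  for (v in variants) for (u in let_bsc) {
    for (f in f_mc) {
      ss <- c4_steady_state(v, ppfd = ppfd, ci = ci, f_mc = f,
                            let_bsc = u, params = params)
      rows[[paste(v, u, f)]] <-
        cbind(data.frame(variant = v, let_bsc = u, f_mc = f), .ss_row(ss))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  key <- unique(out[, c("variant", "let_bsc")])
  opt <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sub <- out[out$variant == key$variant[i] &
                 out$let_bsc == key$let_bsc[i], ]
    amax <- max(sub$a)
    at_max <- sub$f_mc[sub$a >= amax - 1e-9]
    data.frame(variant = key$variant[i], let_bsc = key$let_bsc[i],
               f_mc_opt = min(at_max), a_opt = amax,
               tie = length(at_max) > 1)
  }))
  attr(out, "optimum") <- opt
  out
}

#' PEPC-activity sensitivity scan
#'
#' Scales the PEPC maximum activity and reports leakiness and assimilation
#' relative to the unscaled reference, at high light. A modest reduction
#' in PEPC capacity trims the overcycling that feeds the CO2 leak while
#' barely moving A.
#'
#' @param variant variant name (default the full mixed model).
#' @param scale increasing grid of PEPC multipliers; must contain 1.0.
#' @param ppfd,ci fixed drivers (defaults 2000, 150).
#' @param params a [c4_params()] list.
#' @return data.frame with columns `scale`, `a`, `phi`, and relative
#'   changes `d_a_rel`, `d_phi_rel` versus `scale = 1`.
#' @export
pepc_sensitivity <- function(variant = "asp_mal_pepck_me",
                             scale = seq(0.7, 1, by = 0.05),
                             ppfd = 2000, ci = 150, params = c4_params()) {
  .scan_grid_check(scale)
  if (!any(abs(scale - 1) < 1e-12))
    stop("scale grid must include the reference point 1.0")
  rows <- list()
  for (s in scale) {
    ss <- c4_steady_state(variant, ppfd = ppfd, ci = ci, pepc_scale = s,
                          params = params)
    rows[[as.character(s)]] <- data.frame(scale = s, a = ss$a,
                                          phi = ss$phi,
                                          converged = ss$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ref <- out[abs(out$scale - 1) < 1e-12, ]
  out$d_a_rel <- (out$a - ref$a) / ref$a
  out$d_phi_rel <- (out$phi - ref$phi) / ref$phi
  out
}

#' Transfer-acid gradient snapshot
#'
#' Per-variant steady-state gradients of the transfer acids between the
#' two cytosols, normalized by the CO2 assimilation rate, plus leaf
#' metabolite pools, at high light.
#'
#' @param variants character vector of variant names.
#' @param ppfd,ci fixed drivers (defaults 2000, 150).
#' @param params a [c4_params()] list.
#' @return data.frame with one row per (variant, metabolite).
#' @export
gradient_snapshot <- function(variants = .all_variants(), ppfd = 2000,
                              ci = 150, params = c4_params()) {
  rows <- lapply(variants, function(v) {
    ss <- c4_steady_state(v, ppfd = ppfd, ci = ci, params = params)
    g <- ss$gradients
    g$pool_umol_m2 <- unname(ss$pools[g$metabolite])
    cbind(data.frame(variant = v, a = ss$a, converged = ss$converged), g)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Locate crossovers between two response curves
#'
#' Finds every bracketing interval of a strictly increasing grid where the
#' sign of `y1 - y2` flips and reports the midpoint with the interval
#' half-width attached.
#'
#' @param x increasing grid.
#' @param y1,y2 responses on `x`.
#' @return data.frame with `crossover`, `halfwidth`, `lower`, `upper`
#'   (zero rows when the curves do not cross).
#' @export
find_crossover <- function(x, y1, y2) {
  stopifnot(length(x) == length(y1), length(x) == length(y2))
  d <- y1 - y2
  s <- sign(d)
  flip <- which(s[-1] * s[-length(s)] < 0)
  if (!length(flip))
    return(data.frame(crossover = numeric(0), halfwidth = numeric(0),
                      lower = numeric(0), upper = numeric(0)))
  data.frame(crossover = (x[flip] + x[flip + 1]) / 2,
             halfwidth = (x[flip + 1] - x[flip]) / 2,
             lower = x[flip], upper = x[flip + 1])
}
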