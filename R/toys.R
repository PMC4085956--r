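# Toy reaction networks with closed-form steady states. These are
# first-class fixtures: every solver and RHS component is validated by
# recovering their analytic solutions, independently of the full C4
# network. All toys are deterministic.

.toy_solver <- function() {
  list(rtol = 1e-10, atol = 1e-12, ss_rtol = 1e-10, ss_floor = 1e-3,
       t_max = 1e6, t_chunk0 = 10)
}

.toy_pool <- function(name, init = 0, volume = 1, clamped = FALSE) {
  data.frame(name = name, compartment = "TOY", volume = volume,
             init = init, clamped = clamped, carbon = 0, nitrogen = 0)
}

#' Linear chain toy network
#'
#' `source -> X1 -> X2 -> ... -> Xn -> sink`: constant input `k_in`
#' (umol m-2 s-1) into `X1` and first-order steps with rate constants
#' `k_out[i]` (umol m-2 s-1 uM-1). Flux continuity gives the closed-form
#' steady state `Xi* = k_in / k_out[i]`, attached as `$closed_form`.
#'
#' @param n_pools chain length (>= 1).
#' @param k_in constant input flux.
#' @param k_out first-order rate constants, recycled to length `n_pools`.
#' @param volume compartment volume factor (affects dynamics only, not the
#'   steady state).
#' @return a network list compatible with [build_rhs()] and
#'   [run_to_steady()], with `$closed_form$state` and
#'   `$closed_form$fluxes`.
#' @export
toy_linear_chain <- function(n_pools = 3, k_in = 2, k_out = 0.5,
                             volume = 1) {
  stopifnot(n_pools >= 1, k_in >= 0, all(k_out > 0))
  k_out <- rep_len(k_out, n_pools)
  nm <- paste0("X", seq_len(n_pools))
  pools <- do.call(rbind, lapply(nm, .toy_pool, init = 0, volume = volume))
  rxns <- list(
    SOURCE = reaction("SOURCE", "CONSTANT", c(X1 = 1),
                      list(flux = k_in), exchange = TRUE)
  )
  # first-order steps: the mass-action law needs a formal acceptor for its
  # (here inert, clamped-at-zero) reverse term
  for (i in seq_len(n_pools)) {
    st <- c(-1, if (i < n_pools) 1)
    names(st) <- c(nm[i], if (i < n_pools) nm[i + 1])
    rxns[[paste0("STEP", i)]] <- reaction(
      paste0("STEP", i), "MASS_ACTION", st,
      list(k = k_out[i], keq = Inf, from = nm[i], to = "ZERO"),
      exchange = TRUE)
  }
  pools <- rbind(pools, .toy_pool("ZERO", init = 0, clamped = TRUE))
  state <- setNames(k_in / k_out, nm)
  fluxes <- setNames(rep(k_in, n_pools + 1),
                     c("SOURCE", paste0("STEP", seq_len(n_pools))))
  list(pools = pools, reactions = rxns,
       params = list(solver = .toy_solver()),
       closed_form = list(state = c(state, ZERO = 0), fluxes = fluxes))
}

#' Two-compartment shuttle toy network
#'
#' Miniature of the C4 transfer-acid loop: a constant flux `v` feeds the
#' forward carrier in compartment A, which diffuses to compartment B
#' (conductance `g_f`), converts first-order (`k`) into the return
#' carrier, diffuses back (`g_r`) and drains first-order (`k_sink`). At
#' steady state every flux equals `v` and each diffusive gradient is
#' exactly `v / g`.
#'
#' @param v driving flux (umol m-2 s-1).
#' @param g_f,g_r diffusive conductances.
#' @param k,k_sink first-order conversion and sink constants.
#' @return network list with `$closed_form` as in [toy_linear_chain()].
#' @export
toy_shuttle <- function(v = 10, g_f = 0.1, g_r = 0.1, k = 1, k_sink = 1) {
  stopifnot(v >= 0, g_f > 0, g_r > 0, k > 0, k_sink > 0)
  pools <- rbind(.toy_pool("F_A"), .toy_pool("F_B"),
                 .toy_pool("R_B"), .toy_pool("R_A"),
                 .toy_pool("ZERO", clamped = TRUE))
  rxns <- list(
    SOURCE = reaction("SOURCE", "CONSTANT", c(F_A = 1), list(flux = v),
                      exchange = TRUE),
    DIFF_F = reaction("DIFF_F", "DIFFUSION", c(F_A = -1, F_B = 1),
                      list(g = g_f, from = "F_A", to = "F_B")),
    CONV = reaction("CONV", "MASS_ACTION", c(F_B = -1, R_B = 1),
                    list(k = k, keq = Inf, from = "F_B", to = "ZERO")),
    DIFF_R = reaction("DIFF_R", "DIFFUSION", c(R_B = -1, R_A = 1),
                      list(g = g_r, from = "R_B", to = "R_A")),
    SINK = reaction("SINK", "MASS_ACTION", c(R_A = -1),
                    list(k = k_sink, keq = Inf, from = "R_A", to = "ZERO"),
                    exchange = TRUE)
  )
  f_b <- v / k; f_a <- f_b + v / g_f
  r_a <- v / k_sink; r_b <- r_a + v / g_r
  list(pools = pools, reactions = rxns,
       params = list(solver = .toy_solver()),
       closed_form = list(
         state = c(F_A = f_a, F_B = f_b, R_B = r_b, R_A = r_a, ZERO = 0),
         fluxes = c(SOURCE = v, DIFF_F = v, CONV = v, DIFF_R = v,
                    SINK = v),
         gradients = c(forward = v / g_f, return = v / g_r)))
}
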