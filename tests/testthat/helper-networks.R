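# Shared helpers: small hand-built networks and cached steady states.

# two-pool network with one conversion: A -> B at first order
tiny_ab_network <- function(v_flux = 2, volume = 1) {
  pools <- rbind(
    data.frame(name = "A", compartment = "TOY", volume = volume, init = 10,
               clamped = FALSE, carbon = 1, nitrogen = 0),
    data.frame(name = "B", compartment = "TOY", volume = volume, init = 0,
               clamped = FALSE, carbon = 1, nitrogen = 0),
    data.frame(name = "ZERO", compartment = "TOY", volume = volume, init = 0,
               clamped = TRUE, carbon = 0, nitrogen = 0))
  rxns <- list(
    STEP = reaction("STEP", "MASS_ACTION", c(A = -1, B = 1),
                    list(k = v_flux / 10, keq = Inf, from = "A",
                         to = "ZERO")))
  list(pools = pools, reactions = rxns,
       params = list(solver = list(rtol = 1e-10, atol = 1e-12,
                                   ss_rtol = 1e-10, ss_atol = 1e-9,
                                   ss_floor = 1e-3, t_max = 1e5,
                                   t_chunk0 = 10)))
}

# memoise expensive steady states across test files
ss_cache <- new.env(parent = emptyenv())
cached_ss <- function(key, ...) {
  if (is.null(ss_cache[[key]])) ss_cache[[key]] <- c4_steady_state(...)
  ss_cache[[key]]
}
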