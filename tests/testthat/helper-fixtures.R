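# Shared fixtures: small fibres and desk-scale swarm settings that keep unit
# tests fast while exercising the full update cycle.

straight_fibre <- local({
  cache <- list()
  function(L) {
    key <- as.character(L)
    if (is.null(cache[[key]])) cache[[key]] <<- myofibril_curve(L, Inf)
    cache[[key]]
  }
})

quick_swarm <- function(S = 12L, T_max = 40L, ...) {
  swarm_params(S = S, T_max = T_max, ...)
}

# Minimal simulation-shaped object for metric functions that only need the
# final swarm positions (one row of interior x per configuration) and curve.
fake_sim <- function(curve, interior_matrix) {
  structure(list(curve = curve, swarm_positions = as.matrix(interior_matrix)),
            class = "pso_simulation")
}
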