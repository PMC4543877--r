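## Small network builders used across the tests.

no_edges <- function() {
  data.frame(a = integer(), b = integer(), phi = numeric(),
             w_ab = numeric(), w_ba = numeric())
}

make_network <- function(oscillators, edges = no_edges(), dt = 0.005) {
  structure(list(oscillators = oscillators, edges = edges, dt = dt,
                 condition = "custom", stochastic = FALSE, phase_lead = NA),
            class = "cpg_network")
}

single_osc_network <- function(v = 1, mu = 10, C = 0, gamma = 20, ...) {
  make_network(list(osc_params(v, mu, C, gamma, ...)))
}

## Two oscillators with symmetric bidirectional coupling locking at
## theta2 - theta1 = phi.
pair_network <- function(w = 20, phi = pi / 9, v = 1.4, mu = 10) {
  make_network(
    list(osc_params(v, mu, 0, 20, name = "o1"),
         osc_params(v, mu, 0, 20, name = "o2")),
    data.frame(a = 1L, b = 2L, phi = phi, w_ab = w, w_ba = w))
}

wrap_pi <- function(x) atan2(sin(x), cos(x))
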