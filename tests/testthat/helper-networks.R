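# Shared helpers: small connected networks and hand-made result objects.

# a connected miniature network (default 80 neurons) for simulator tests
tiny_net <- function(seed = 7, n_E = 60, n_I = 20) {
  net <- toy_network(n_E = n_E, n_I = n_I, seed = seed)
  net <- sample_connectivity(net, connectivity_rule(), seed = seed + 1)
  assign_lgn(net, seed = seed + 2)
}

# a fake simulation_result with prescribed spikes, for metric unit tests
fake_result <- function(spike_t, spike_id, n, duration = 7,
                        is_E = rep(TRUE, n)) {
  o <- order(spike_t)
  structure(list(spike_t = spike_t[o], spike_id = as.integer(spike_id[o]),
                 counts_window = tabulate(spike_id, n),
                 n = n, is_E = is_E, scale_n = 1L,
                 duration = duration, dt = 1e-5, seed = 0L,
                 record = integer(0), record_window = c(2, duration),
                 rec_currents = matrix(numeric(0), 0, 5,
                                       dimnames = list(NULL,
                                         c("LGN", "ambient", "L4", "L6", "I"))),
                 traces = NULL),
            class = "simulation_result")
}

# Poisson spike trains at a time-varying rate, by thinning
thinned_spikes <- function(rate_fn, r_max, duration, n = 1) {
  lapply(seq_len(n), function(i) {
    cand <- sort(stats::runif(stats::rpois(1, r_max * duration), 0, duration))
    cand[stats::runif(length(cand)) * r_max < rate_fn(cand)]
  })
}
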