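# Build pre-synaptic -> post-synaptic CSR arrays (0-based) from the
# post-indexed adjacency lists of a network realization, with per-edge
# effective weights and failure probabilities resolved against a weight set.
build_csr <- function(pre, post, w_edge, fail_edge, n_pre) {
  o <- order(pre, method = "radix")
  list(
    ptr = c(0L, cumsum(tabulate(pre, n_pre))),
    tgt = as.integer(post[o] - 1L),
    w = w_edge[o],
    fail = if (is.null(fail_edge)) numeric(length(pre)) else fail_edge[o]
  )
}

resolve_edges <- function(net, w) {
  adj <- net$adjacency
  n <- net$n
  is_E <- net$is_E
  len_E <- lengths(adj$pre_E)
  len_I <- lengths(adj$pre_I)
  post_E <- rep.int(seq_len(n), len_E)
  post_I <- rep.int(seq_len(n), len_I)
  preE <- unlist(adj$pre_E, use.names = FALSE)
  preI <- unlist(adj$pre_I, use.names = FALSE)
  wE <- ifelse(is_E[post_E], w$S_EE, w$S_IE) * unlist(adj$jit_E, use.names = FALSE)
  wI <- ifelse(is_E[post_I], w$S_EI, w$S_II) * unlist(adj$jit_I, use.names = FALSE)
  failE <- ifelse(is_E[post_E], w$fail_EE, 0)  # only E-to-E synapses fail
  cort <- build_csr(c(preE, preI), c(post_E, post_I), c(wE, wI),
                    c(failE, numeric(length(preI))), n)

  # Layer 6: per-postsynaptic-E-cell coupling drawn uniformly in the printed
  # range, co-scaling with the intracortical weight it is indexed to.
  m6E <- if (is.null(w$m6_E)) 1 else w$m6_E
  m6I <- if (is.null(w$m6_I)) 1 else w$m6_I
  s6_E <- (w$S6_EE_range[1] +
             adj$s6_unit * diff(w$S6_EE_range)) * m6E
  len_6 <- lengths(adj$pre_L6)
  post_6 <- rep.int(seq_len(n), len_6)
  pre_6 <- unlist(adj$pre_L6, use.names = FALSE)
  w6 <- ifelse(is_E[post_6], s6_E[post_6], w$S6_IE * m6I) *
    unlist(adj$jit_L6, use.names = FALSE)
  l6 <- build_csr(pre_6, post_6, w6, NULL, net$l6$n)
  l6$fail <- adj$l6_fail_unit * w$fail_L6_max

  len_L <- lengths(net$lgn_input$cells)
  post_L <- rep.int(seq_len(n), len_L)
  pre_L <- unlist(net$lgn_input$cells, use.names = FALSE)
  wL <- ifelse(is_E[post_L], w$S_E_LGN, w$S_I_LGN) *
    unlist(net$lgn_input$jit, use.names = FALSE)
  lgn <- build_csr(pre_L, post_L, wL, NULL, nrow(net$lgn_sheet))

  list(cort = cort, l6 = l6, lgn = lgn)
}

#' Simulate the network
#'
#' Integrates the conductance-based LIF dynamics of every Layer-4Ca neuron:
#' the membrane potential obeys
#' \eqn{dv/dt = -g_R v - g_E(t)(v - V_E) - g_I(t)(v - V_I)}
#' in normalized units (rest 0, threshold 1), with excitatory conductance
#' summed over LGN, ambient, intracortical E and Layer-6 sources
#' (AMPA/NMDA receptor splits for the cortical sources, pure AMPA for LGN and
#' ambient) and inhibitory conductance from intracortical I cells (GABA).
#' On reaching threshold a spike is recorded, the potential resets to 0 and
#' is held for a 2 ms refractory period. E-to-E and Layer-6 spikes undergo
#' independent Bernoulli synaptic failures. Conductance states use exact
#' exponential updates; the membrane uses forward Euler at `dt = 0.01` ms.
#'
#' @param net A connected `network_realization` (see [build_network()]).
#' @param drive External drive, as returned by [make_drive()] (fields `lgn`,
#'   `ambient`, `l6`; any may be `NULL` for silence).
#' @param w Synaptic weight set, see [synaptic_weights()] /
#'   [apply_multipliers()].
#' @param duration Simulated time, seconds. Durations below 7 s trigger a
#'   warning when `warn_short = TRUE` (the standard protocol statistics use
#'   the last 5 s of a 7 s run).
#' @param seed Integer seed (initial conditions and synaptic failure draws).
#' @param record Neuron indices for which source-resolved mean currents are
#'   accumulated over `record_window`.
#' @param record_window Two-element window (seconds) for current averaging
#'   and windowed spike counts; default `c(2, duration)`.
#' @param traces Neuron indices for which `v`, `g_E`, `g_I` time series are
#'   stored (every `trace_stride` steps).
#' @param trace_stride Sampling stride for traces, in steps.
#' @param bio Biophysical parameters, see [biophysics_params()].
#' @param kernels Conductance kernel constants, see [conductance_kernels()].
#' @param g0_E,g0_I Constant clamped conductances added per neuron (scalar or
#'   vector); used by analytic fixtures.
#' @param v0_max Initial membrane potentials are drawn uniformly in
#'   `[0, v0_max]`.
#' @param warn_short Warn when `duration < 7` s.
#' @return An object of class `"simulation_result"` with spike times/ids,
#'   windowed per-neuron spike counts, source-resolved mean currents for the
#'   recorded set (columns LGN, ambient, L4, L6, I; normalized voltage per
#'   second), and optional traces.
#' @export
run_simulation <- function(net, drive, w = synaptic_weights(), duration, seed,
                           record = integer(0), record_window = c(2, duration),
                           traces = integer(0), trace_stride = 10L,
                           bio = biophysics_params(),
                           kernels = conductance_kernels(),
                           g0_E = 0, g0_I = 0, v0_max = 0.5,
                           warn_short = TRUE) {
  stopifnot(inherits(net, "network_realization"))
  if (is.null(net$adjacency) || is.null(net$lgn_input)) {
    stop("network must have sampled connectivity and assigned LGN inputs")
  }
  if (missing(seed)) stop("`seed` is required")
  if (duration <= 0) stop("`duration` must be positive")
  if (warn_short && duration < 7) {
    warning("duration < 7 s: too short for the standard protocol statistics")
  }
  n_steps <- as.integer(round(duration / bio$dt))
  if (abs(n_steps * bio$dt - duration) > 1e-9) {
    stop("`dt` must divide `duration`")
  }
  for (d in drive) {
    if (!is.null(d) && length(d$t) && (d$t[1] < 0 || d$t[length(d$t)] > duration)) {
      stop("drive spike times must lie within [0, duration]")
    }
  }
  record_window[2] <- min(record_window[2], duration)

  edges <- resolve_edges(net, w)
  empty_sp <- function(x) if (is.null(x)) list(t = numeric(0), cell = integer(0)) else x
  lgn_sp <- empty_sp(drive$lgn)
  amb_sp <- empty_sp(drive$ambient)
  l6_sp <- empty_sp(drive$l6)

  gR <- ifelse(net$is_E, bio$g_leak_E, bio$g_leak_I)
  out <- .lif_core(
    n = net$n, dt = bio$dt, n_steps = n_steps,
    isE = as.integer(net$is_E), gR = gR, VE = bio$V_E, VI = bio$V_I,
    ref_steps = as.integer(round(bio$t_refrac / bio$dt)),
    g0E = rep_len(g0_E, net$n), g0I = rep_len(g0_I, net$n),
    tau_d = unname(kernels$tau_d), tau_r = unname(kernels$tau_r),
    rhoA_E = kernels$rho_A_E, rhoA_I = kernels$rho_A_I,
    c_ptr = edges$cort$ptr, c_tgt = edges$cort$tgt,
    c_w = edges$cort$w, c_fail = edges$cort$fail,
    l6_ptr = edges$l6$ptr, l6_tgt = edges$l6$tgt, l6_w = edges$l6$w,
    l6_fail = edges$l6$fail,
    l6_sp_t = l6_sp$t, l6_sp_cell = as.integer(l6_sp$cell - 1L),
    lgn_ptr = edges$lgn$ptr, lgn_tgt = edges$lgn$tgt, lgn_w = edges$lgn$w,
    lgn_sp_t = lgn_sp$t, lgn_sp_cell = as.integer(lgn_sp$cell - 1L),
    amb_t = amb_sp$t, amb_tgt = as.integer(amb_sp$cell - 1L),
    amb_w = w$S_amb,
    rec_idx = as.integer(record - 1L),
    win_lo = record_window[1], win_hi = record_window[2],
    trace_idx = as.integer(traces - 1L), trace_stride = as.integer(trace_stride),
    seed = derive_seed(seed, "sim"), v0_max = v0_max
  )
  rownames(out$rec_currents) <- as.character(record)
  res <- list(
    spike_t = out$spike_t, spike_id = out$spike_id + 1L,
    counts_window = out$count_win,
    n = net$n, is_E = net$is_E, scale_n = net$scale_n,
    duration = duration, dt = bio$dt, seed = seed,
    record = record, record_window = record_window,
    rec_currents = out$rec_currents,
    traces = out$traces
  )
  class(res) <- "simulation_result"
  res
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("LIF simulation: %d neurons, %.3g s at dt = %g ms, %d spikes\n",
              x$n, x$duration, x$dt * 1e3, length(x$spike_t)))
  win <- x$record_window
  cat(sprintf("  window [%.3g, %.3g] s; %d neurons with recorded currents\n",
              win[1], win[2], length(x$record)))
  invisible(x)
}

#' Decompose excitatory currents by source
#'
#' Time- and population-averaged source-resolved currents entering the E and
#' I cells of a patch (normalized voltage per second), and the fractions of
#' total excitatory current contributed by LGN, ambient, intracortical (L4)
#' and Layer-6 sources — the quantities shown in the current-decomposition
#' pie charts. Also assembles the `x`, `y`, `z` triplets used by the
#' compensation algorithm: for E cells, `x` is the LGN + ambient current,
#' `y` the total (cortical + feedforward) excitatory current and `z` the
#' inhibitory current, with `diff_E = y - z`; analogously for I cells.
#'
#' @param result A `simulation_result` whose `record` set covers `patch`.
#' @param patch Neuron indices (may contain both E and I cells).
#' @param window Averaging window; must equal the window recorded during the
#'   run.
#' @return An object of class `"current_summary"`.
#' @export
decompose_currents <- function(result, patch,
                               window = result$record_window) {
  stopifnot(inherits(result, "simulation_result"))
  if (window[1] < 0 || window[2] > result$duration) {
    stop("window outside the simulated interval")
  }
  if (any(abs(window - result$record_window) > 1e-9)) {
    stop("currents were recorded over [",
         paste(result$record_window, collapse = ", "),
         "] s; re-run with the desired `record_window`")
  }
  if (!all(patch %in% result$record)) {
    stop("all patch neurons must be in the result's `record` set")
  }
  rows <- match(patch, result$record)
  cur <- result$rec_currents[rows, , drop = FALSE]
  is_E <- result$is_E[patch]

  type_summary <- function(m) {
    if (nrow(m) == 0) return(NULL)
    avg <- colMeans(m)
    exc <- avg[c("LGN", "ambient", "L4", "L6")]
    list(currents = avg,
         fractions = exc / sum(exc),
         x = unname(avg["LGN"] + avg["ambient"]),
         y = unname(sum(exc)),
         z = unname(avg["I"]),
         diff = unname(sum(exc) - avg["I"]))
  }
  out <- list(
    E = type_summary(cur[is_E, , drop = FALSE]),
    I = type_summary(cur[!is_E, , drop = FALSE]),
    n_E = sum(is_E), n_I = sum(!is_E),
    window = window
  )
  out$diff_E <- if (is.null(out$E)) NA_real_ else out$E$diff
  out$diff_I <- if (is.null(out$I)) NA_real_ else out$I$diff
  class(out) <- "current_summary"
  out
}

#' @export
print.current_summary <- function(x, ...) {
  cat(sprintf("Current decomposition (%d E, %d I cells, window [%g, %g] s)\n",
              x$n_E, x$n_I, x$window[1], x$window[2]))
  for (ty in c("E", "I")) {
    s <- x[[ty]]
    if (is.null(s)) next
    cat(sprintf("  into %s cells: ", ty))
    cat(sprintf("%s %.3g", names(s$currents), s$currents), sep = "; ")
    cat(sprintf("\n    excitatory fractions: %s\n",
                paste(sprintf("%s %.1f%%", names(s$fractions),
                              100 * s$fractions), collapse = ", ")))
  }
  cat(sprintf("  diff_E = %.3g, diff_I = %.3g\n", x$diff_E, x$diff_I))
  invisible(x)
}
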