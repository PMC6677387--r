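#' Biophysical parameters of the leaky integrate-and-fire neurons
#'
#' Membrane parameters of the model neurons in normalized voltage units:
#' rest at 0, spiking threshold at 1, excitatory reversal potential 14/3 and
#' inhibitory reversal potential -2/3. The leak conductance is 50 s^-1 for
#' excitatory cells and 1.33 x 50 s^-1 for inhibitory cells. Integration uses
#' a fixed time step of 0.01 ms and a 2 ms absolute refractory period.
#'
#' @param dt Integration time step in seconds (default `1e-5`, i.e. 0.01 ms).
#' @return A list of class `"biophysics_params"`.
#' @export
biophysics_params <- function(dt = 1e-5) {
  p <- list(
    V_rest = 0, V_th = 1,
    V_E = 14 / 3, V_I = -2 / 3,
    g_leak_E = 50, g_leak_I = 1.33 * 50,
    t_refrac = 2e-3,
    dt = dt
  )
  stopifnot(p$V_I < p$V_rest, p$V_rest < p$V_th, p$V_th < p$V_E, dt > 0)
  class(p) <- "biophysics_params"
  p
}

#' Synaptic coupling weights of the full-size model
#'
#' Mean synaptic coupling constants. Each weight is the *total* conductance
#' (time integral, units of s^-1 x s = dimensionless conductance-time) added
#' to the postsynaptic neuron per presynaptic spike; conductance kernels are
#' therefore normalized to unit area (see [conductance_kernels()]).
#' Derived ratios at the defaults: `S_E_LGN = 2.425 * S_EE`,
#' `S_I_LGN = 3.2 * S_EE`, `S_IE = 0.34 * S_EE`, `S_II = 1.5 * S_EE`.
#'
#' Naming: `S_XY` is the coupling from presynaptic type `Y` onto postsynaptic
#' type `X` (so `S_EI` is inhibition of E cells). Layer-6 weights `S6_EE`
#' (drawn per neuron, uniform over `S6_EE_range`) and `S6_IE` are indexed to
#' their intracortical counterparts and co-scale with them under multipliers.
#'
#' @param jitter_frac Per-synapse multiplicative weight jitter half-width
#'   (uniform, default 0.10, i.e. +/-10%, frozen per realization).
#' @param fail_EE Synaptic failure probability of intracortical E-to-E
#'   synapses. The physiological ceiling is 20%; the default (0.05) is the
#'   calibrated value at which the full-size weight set leaves the reduced
#'   cortices in the supercritical regime that reproduces the uncompensated
#'   rate catastrophe (see the methods vignette).
#' @param fail_L6_max Upper end of the per-source-cell uniform Layer-6 spike
#'   failure probability (default 0.5; each Layer-6 cell gets a frozen failure
#'   rate drawn uniformly in `[0, fail_L6_max]`).
#' @return A list of class `"synaptic_weights"`.
#' @export
synaptic_weights <- function(jitter_frac = 0.10, fail_EE = 0.05, fail_L6_max = 0.5) {
  w <- list(
    S_EE = 0.023,
    S_EI = 0.046,
    S_IE = 0.023 * 0.34,      # 0.00782
    S_II = 0.75 * 2 * 0.023,  # 0.0345
    S_E_LGN = 0.023 * 2.425,  # 0.055775
    S_I_LGN = 0.023 * 3.2,    # 0.0736
    S6_EE_range = c(0.00767, 0.01533),
    S6_IE = 0.003128,
    S_amb = 0.01,
    jitter_frac = jitter_frac,
    fail_EE = fail_EE,
    fail_L6_max = fail_L6_max
  )
  class(w) <- "synaptic_weights"
  w
}

#' Synaptic conductance kernel time constants
#'
#' Difference-of-exponentials kernels, normalized to unit area so that the
#' synaptic weights are total conductance increments per spike. Decay times:
#' AMPA ~3 ms, NMDA ~80 ms, GABA ~5 ms; rise times 0.5 ms (AMPA, GABA) and
#' 2 ms (NMDA). Cortical and Layer-6 excitation is split across AMPA/NMDA
#' receptors (`rho_A_E = 0.8`, `rho_N_E = 0.2` on E cells; 0.67/0.33 on I
#' cells); LGN and ambient excitation is pure AMPA.
#'
#' @return A list of class `"conductance_kernels"` with elements `tau_d`,
#'   `tau_r` (named vectors over AMPA/NMDA/GABA, seconds) and receptor splits.
#' @export
conductance_kernels <- function() {
  k <- list(
    tau_d = c(AMPA = 3e-3, NMDA = 80e-3, GABA = 5e-3),
    tau_r = c(AMPA = 0.5e-3, NMDA = 2e-3, GABA = 0.5e-3),
    rho_A_E = 0.8, rho_N_E = 0.2,
    rho_A_I = 0.67, rho_N_I = 0.33
  )
  class(k) <- "conductance_kernels"
  k
}

#' Evaluate a synaptic conductance kernel
#'
#' Unit-area difference-of-exponentials kernel
#' \eqn{G(s) = (e^{-s/\tau_d} - e^{-s/\tau_r}) / (\tau_d - \tau_r)} for
#' \eqn{s \ge 0} and 0 for \eqn{s < 0} (causality). The simulator never
#' evaluates this sum at run time; it evolves the equivalent two-state
#' exponential system, and equality with the literal convolution is a tested
#' property.
#'
#' @param kernel One of `"AMPA"`, `"NMDA"`, `"GABA"`.
#' @param s Time since presynaptic spike, seconds (vectorized).
#' @param kernels Kernel constants, see [conductance_kernels()].
#' @return Kernel values in s^-1 (per unit synaptic weight).
#' @export
kernel_value <- function(kernel = c("AMPA", "NMDA", "GABA"), s,
                         kernels = conductance_kernels()) {
  kernel <- match.arg(kernel)
  td <- kernels$tau_d[[kernel]]
  tr <- kernels$tau_r[[kernel]]
  out <- (exp(-s / td) - exp(-s / tr)) / (td - tr)
  out[s < 0] <- 0
  out
}

#' External drive parameters
#'
#' Rates of the three external spike sources. Ambient drive is a 350 Hz
#' Poisson pulse train per neuron (independent across neurons). Layer-6
#' spontaneous rates are drawn per cell uniformly in 0.5-10 spikes/s; under
#' drive a Layer-6 cell fires at `f6_max` (~41.4 Hz) at its preferred
#' orientation, falling to `f6_max/4` at the orthogonal orientation by a
#' cosine interpolation. The LGN front end is a rectified sinusoid with
#' background rate `lgn_r_base` and modulation amplitude `lgn_r_mod`
#' (calibrated so the full-size current budget reproduces the reported
#' source decomposition; see the methods vignette).
#'
#' @param lgn_r_base LGN background firing rate, Hz.
#' @param lgn_r_mod LGN modulation amplitude at full contrast, Hz.
#' @return A list of class `"drive_params"`.
#' @export
drive_params <- function(lgn_r_base = 15, lgn_r_mod = 90) {
  d <- list(
    r_ambient = 350,
    lgn_r_base = lgn_r_base,
    lgn_r_mod = lgn_r_mod,
    l6_spont_range = c(0.5, 10),
    f6_max = 41.4,
    f6_ortho_factor = 1 / 4
  )
  class(d) <- "drive_params"
  d
}

# Derive a child RNG seed for a named stage from a master seed, so that each
# stage of a pipeline is independently reproducible. Plain 32-bit arithmetic,
# result in [1, 2^31 - 2].
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h + 1)
}
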