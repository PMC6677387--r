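#' Drifting sinusoidal grating stimulus
#'
#' @param orientation Orientation of the stripes in degrees (taken modulo
#'   180).
#' @param sf Spatial frequency, cycles/deg (0.5-10; the layer's preferred SF
#'   is 2-3 c/d).
#' @param tf Temporal (drift) frequency in Hz, default 4.
#' @param contrast Contrast in `[0, 1]`.
#' @param phase Spatial phase offset in radians.
#' @return An object of class `"grating_stimulus"`.
#' @export
grating_stimulus <- function(orientation, sf = 2.5, tf = 4, contrast = 1,
                             phase = 0) {
  stopifnot(sf > 0, tf > 0, contrast >= 0, contrast <= 1)
  s <- list(orientation = orientation %% 180, sf = sf, tf = tf,
            contrast = contrast, phase = phase)
  class(s) <- "grating_stimulus"
  s
}

# Spatial phase of the grating at given positions (radians). The wave vector
# is perpendicular to the stripes.
grating_spatial_phase <- function(x, y, stim) {
  th <- stim$orientation * pi / 180
  2 * pi * stim$sf * (-sin(th) * x + cos(th) * y) + stim$phase
}

#' Instantaneous firing rate of an LGN cell under a drifting grating
#'
#' Rectified-sinusoid rate model:
#' `rate = max(0, r_base + r_mod * contrast * cos(2 pi tf t - phi))`, with
#' the spatial phase `phi` set by the cell position and OFF cells shifted by
#' half a period relative to co-located ON cells. Deterministic; the spike
#' generators realize it as an inhomogeneous Poisson process.
#'
#' @param cell A one-row data frame (or list) with fields `x`, `y`, `onoff`.
#' @param stim A `grating_stimulus`.
#' @param t Time(s) in seconds (vectorized).
#' @param drive Drive parameters, see [drive_params()].
#' @return Rate(s) in Hz.
#' @export
lgn_rate <- function(cell, stim, t, drive = drive_params()) {
  phi <- grating_spatial_phase(cell$x, cell$y, stim)
  if (identical(cell$onoff, "OFF")) phi <- phi + pi
  pmax(0, drive$lgn_r_base +
         drive$lgn_r_mod * stim$contrast * cos(2 * pi * stim$tf * t - phi))
}

# Internal constructor for spike-train containers: flat (cell, time) arrays
# sorted by time.
source_spikes <- function(t, cell, n_cells, duration, source) {
  o <- order(t, method = "radix")
  out <- list(t = t[o], cell = as.integer(cell[o]), n_cells = n_cells,
              duration = duration, source = source)
  class(out) <- "source_spikes"
  out
}

#' @export
print.source_spikes <- function(x, ...) {
  cat(sprintf("%s spike trains: %d cells, %d spikes over %.3g s\n",
              x$source, x$n_cells, length(x$t), x$duration))
  invisible(x)
}

#' Generate LGN spike trains for a grating
#'
#' Inhomogeneous Poisson realization (by thinning) of [lgn_rate()] for every
#' cell of the LGN sheet.
#'
#' @param cells LGN sheet data frame (e.g. `net$lgn_sheet`) with columns
#'   `id`, `x`, `y`, `onoff`.
#' @param stim A `grating_stimulus`, or `NULL` for background (cells fire at
#'   the base rate).
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param drive Drive parameters.
#' @return A `source_spikes` object (cell ids refer to `cells$id`).
#' @export
generate_lgn_spikes <- function(cells, stim, duration, seed,
                                drive = drive_params()) {
  stopifnot(duration > 0)
  old <- set_local_seed(derive_seed(seed, "lgn-spikes"))
  on.exit(restore_seed(old), add = TRUE)
  if (is.null(stim)) stim <- grating_stimulus(0, contrast = 0)
  r_max <- drive$lgn_r_base + drive$lgn_r_mod * stim$contrast
  phi <- grating_spatial_phase(cells$x, cells$y, stim)
  phi[cells$onoff == "OFF"] <- phi[cells$onoff == "OFF"] + pi
  ts <- vector("list", nrow(cells))
  n_cand <- stats::rpois(nrow(cells), r_max * duration)
  for (i in seq_len(nrow(cells))) {
    cand <- stats::runif(n_cand[i], 0, duration)
    r <- pmax(0, drive$lgn_r_base +
                drive$lgn_r_mod * stim$contrast *
                  cos(2 * pi * stim$tf * cand - phi[i]))
    ts[[i]] <- cand[stats::runif(n_cand[i]) * r_max < r]
  }
  source_spikes(unlist(ts, use.names = FALSE),
                rep(cells$id, lengths(ts)),
                n_cells = max(cells$id), duration = duration, source = "LGN")
}

#' Generate Layer-6 feedback spike trains
#'
#' Background condition: homogeneous Poisson per cell, rates drawn uniformly
#' in 0.5-10 spikes/s. Driven condition: each Layer-6 cell fires at a rate
#' interpolating (cosine in twice the orientation difference) between
#' `f6_max` at its preferred orientation and `f6_max / 4` at the orthogonal
#' orientation.
#'
#' @param net A `network_realization` (Layer-6 pool carries per-cell intended
#'   orientations inherited from the orientation map).
#' @param stim A `grating_stimulus`, or `NULL` for the background condition.
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param drive Drive parameters.
#' @return A `source_spikes` object (cell ids index the Layer-6 pool).
#' @export
generate_layer6_spikes <- function(net, stim, duration, seed,
                                   drive = drive_params()) {
  stopifnot(duration > 0)
  old <- set_local_seed(derive_seed(seed, "l6-spikes"))
  on.exit(restore_seed(old), add = TRUE)
  nl6 <- net$l6$n
  if (is.null(stim) || stim$contrast == 0) {
    rates <- stats::runif(nl6, drive$l6_spont_range[1], drive$l6_spont_range[2])
  } else {
    dth <- (net$l6$wedge_angle - stim$orientation) * pi / 180
    f_min <- drive$f6_max * drive$f6_ortho_factor
    rates <- (f_min + (drive$f6_max - f_min) * (1 + cos(2 * dth)) / 2) *
      stim$contrast
  }
  counts <- stats::rpois(nl6, rates * duration)
  source_spikes(stats::runif(sum(counts), 0, duration),
                rep(seq_len(nl6), counts),
                n_cells = nl6, duration = duration, source = "L6")
}

#' Generate ambient Poisson pulse trains
#'
#' Independent homogeneous Poisson pulse trains, one per target neuron, at
#' the ambient rate (350 Hz), lumping the modulatory background drive.
#'
#' @param n_neurons Number of target neurons (or a `network_realization`).
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param drive Drive parameters.
#' @return A `source_spikes` object (cell ids are target neuron indices).
#' @export
generate_ambient <- function(n_neurons, duration, seed,
                             drive = drive_params()) {
  stopifnot(duration > 0)
  if (inherits(n_neurons, "network_realization")) n_neurons <- n_neurons$n
  old <- set_local_seed(derive_seed(seed, "ambient"))
  on.exit(restore_seed(old), add = TRUE)
  counts <- stats::rpois(n_neurons, drive$r_ambient * duration)
  source_spikes(stats::runif(sum(counts), 0, duration),
                rep(seq_len(n_neurons), counts),
                n_cells = n_neurons, duration = duration, source = "ambient")
}

#' Generate the full external drive for one simulation
#'
#' Bundles LGN, ambient and Layer-6 spike trains for a stimulus condition,
#' with per-source seeds derived from one master seed.
#'
#' @param net A `network_realization`.
#' @param stim A `grating_stimulus`, or `NULL` for the background condition.
#' @param duration Duration in seconds.
#' @param seed Integer master seed.
#' @param drive Drive parameters.
#' @return A list with elements `lgn`, `ambient`, `l6` (each `source_spikes`).
#' @export
make_drive <- function(net, stim, duration, seed, drive = drive_params()) {
  list(
    lgn = generate_lgn_spikes(net$lgn_sheet, stim, duration,
                              derive_seed(seed, "d1"), drive),
    ambient = generate_ambient(net$n, duration, derive_seed(seed, "d2"), drive),
    l6 = generate_layer6_spikes(net, stim, duration,
                                derive_seed(seed, "d3"), drive)
  )
}

#' Export spike trains as a two-column CSV
#'
#' Writes `(neuron_id, time_s)` rows sorted by time.
#'
#' @param spikes A `source_spikes` object or a `simulation_result`.
#' @param path Output file path.
#' @export
write_spikes_csv <- function(spikes, path) {
  if (inherits(spikes, "simulation_result")) {
    df <- data.frame(neuron_id = spikes$spike_id, time_s = spikes$spike_t)
  } else {
    df <- data.frame(neuron_id = spikes$cell, time_s = spikes$t)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
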