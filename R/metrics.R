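spikes_in_window <- function(result, window) {
  keep <- result$spike_t >= window[1] & result$spike_t < window[2]
  list(t = result$spike_t[keep], id = result$spike_id[keep])
}

#' Mean firing rates of a patch
#'
#' Population- and time-averaged firing rates (spikes/s) over a window,
#' reported separately for E and I cells.
#'
#' @param result A `simulation_result`.
#' @param patch Neuron indices (non-empty).
#' @param window Averaging window in seconds, default the last 5 s of the
#'   standard 7 s run.
#' @return A list with `E`, `I` (mean rates; `NA` if the patch has no cells
#'   of that type), and `per_neuron` (named by neuron index).
#' @export
patch_rates <- function(result, patch, window = c(2, 7)) {
  stopifnot(inherits(result, "simulation_result"))
  if (length(patch) == 0) stop("empty patch")
  if (window[2] > result$duration + 1e-9) stop("window outside the run")
  sp <- spikes_in_window(result, window)
  width <- diff(window)
  counts <- tabulate(sp$id, nbins = result$n)[patch]
  rates <- counts / width
  is_E <- result$is_E[patch]
  list(E = if (any(is_E)) mean(rates[is_E]) else NA_real_,
       I = if (any(!is_E)) mean(rates[!is_E]) else NA_real_,
       per_neuron = stats::setNames(rates, patch))
}

#' Circular variance of an orientation tuning curve
#'
#' The standard doubled-angle measure
#' \eqn{CV = 1 - |\sum_k r_k e^{2 i \theta_k}| / \sum_k r_k}: 0 for a
#' perfectly selective neuron, 1 for an unselective one. Invariant to
#' uniform rate rescaling and to rotation of all orientations.
#'
#' @param rates Non-negative response rates at each orientation.
#' @param angles Orientations in degrees, equally spaced over `[0, 180)`
#'   (default inferred from the number of rates).
#' @return CV in `[0, 1]`, or `NA` (with a warning) if all rates are zero.
#' @export
circular_variance <- function(rates, angles = seq(0, 180, length.out = length(rates) + 1)[-(length(rates) + 1)]) {
  stopifnot(length(rates) >= 2, length(rates) == length(angles))
  if (any(rates < 0)) stop("rates must be non-negative")
  tot <- sum(rates)
  if (tot == 0) {
    warning("all-zero rates: circular variance undefined")
    return(NA_real_)
  }
  th <- angles * pi / 180
  1 - Mod(sum(rates * exp(2i * th))) / tot
}

#' Modulation ratio (F1/F0) of a spike train
#'
#' Ratio of the first-harmonic amplitude at the stimulus temporal frequency
#' to the mean rate of the cycle-averaged response. Cells with F1/F0 < 1 are
#' classified complex, >= 1 simple. Invariant to time shifts of the train
#' (the amplitude, not the phase, is reported).
#'
#' @param spike_t Spike times in seconds.
#' @param tf Stimulus temporal frequency in Hz (default 4).
#' @param window Analysis window, at least 4 stimulus cycles.
#' @return A list with `F0`, `F1`, `ratio` and `class` (`"simple"`,
#'   `"complex"`, or `NA` when F0 = 0, flagged `undefined`).
#' @export
modulation_ratio <- function(spike_t, tf = 4, window = c(2, 7)) {
  width <- diff(window)
  if (width * tf < 4) stop("window must contain at least 4 stimulus cycles")
  t <- spike_t[spike_t >= window[1] & spike_t < window[2]]
  F0 <- length(t) / width
  if (F0 == 0) {
    return(list(F0 = 0, F1 = 0, ratio = NA_real_, class = NA_character_,
                undefined = TRUE))
  }
  # F1 amplitude of the rate: 2 |sum exp(-2 pi i f t_k)| / T
  F1 <- 2 * Mod(sum(exp(-2i * pi * tf * t))) / width
  ratio <- F1 / F0
  list(F0 = F0, F1 = F1, ratio = ratio,
       class = if (ratio < 1) "complex" else "simple", undefined = FALSE)
}

#' Cycle-averaged peak firing rate of a patch
#'
#' The response measure of the tuning surfaces: the population PSTH is
#' folded over the stimulus cycle (default 25 ms bins) and the peak bin
#' rate, averaged over the patch neurons, is returned.
#'
#' @param result A `simulation_result` (or a list with `spike_t`,
#'   `spike_id`).
#' @param patch Neuron indices.
#' @param tf Stimulus temporal frequency, Hz.
#' @param window Analysis window in seconds.
#' @param bin Cycle histogram bin width in seconds (default 0.025).
#' @return Peak rate in spikes/s (0 for a silent patch).
#' @export
peak_rate <- function(result, patch, tf = 4, window = c(2, 7), bin = 0.025) {
  sp <- spikes_in_window(result, window)
  keep <- sp$id %in% patch
  if (!any(keep)) return(0)
  period <- 1 / tf
  nb <- max(1L, round(period / bin))
  phase <- (sp$t[keep] - window[1]) %% period
  counts <- tabulate(pmin(floor(phase / period * nb), nb - 1) + 1L, nbins = nb)
  n_cycles <- diff(window) * tf
  max(counts) / (length(patch) * n_cycles * (period / nb))
}

#' Orientation x spatial-frequency tuning surface
#'
#' Assembles, for each wedge, the grid of cycle-peak population rates over a
#' battery of gratings (typically 8 orientations x 8 spatial frequencies),
#' and the measured preference (argmax orientation) per wedge.
#'
#' @param results A list of entries `list(stim =, result =)` covering the
#'   battery (one entry per grating).
#' @param wedges A `wedge_partition` (or a list of neuron index vectors).
#' @param window,bin Passed to [peak_rate()].
#' @return An object of class `"tuning_surface"`: list with `peaks` (array
#'   orientation x sf x wedge), `orientations`, `sfs`, `preferred`
#'   (per-wedge argmax orientation, `NA` for unresponsive wedges), and
#'   `holes` (battery cells with no run).
#' @export
tuning_surface <- function(results, wedges, window = c(2, 7), bin = 0.025) {
  members <- if (inherits(wedges, "wedge_partition")) wedges$members else wedges
  oris <- sort(unique(vapply(results, function(r) r$stim$orientation, numeric(1))))
  sfs <- sort(unique(vapply(results, function(r) r$stim$sf, numeric(1))))
  peaks <- array(NA_real_, c(length(oris), length(sfs), length(members)),
                 dimnames = list(orientation = oris, sf = sfs, wedge = NULL))
  for (entry in results) {
    io <- match(entry$stim$orientation, oris)
    is <- match(entry$stim$sf, sfs)
    for (wi in seq_along(members)) {
      peaks[io, is, wi] <- peak_rate(entry$result, members[[wi]],
                                     tf = entry$stim$tf, window = window,
                                     bin = bin)
    }
  }
  holes <- which(is.na(peaks[, , 1]), arr.ind = TRUE)
  if (nrow(holes) > 0) warning("tuning battery has missing cells (holes flagged)")
  preferred <- vapply(seq_along(members), function(wi) {
    m <- peaks[, , wi]
    if (all(is.na(m)) || all(m == 0, na.rm = TRUE)) return(NA_real_)
    oris[which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, 1]]
  }, numeric(1))
  out <- list(peaks = peaks, orientations = oris, sfs = sfs,
              preferred = preferred, holes = holes)
  class(out) <- "tuning_surface"
  out
}

#' Population spike-count power spectrum and gamma-band summary
#'
#' Bins the population spike count (default 1 ms), subtracts the mean, and
#' averages periodograms over 1 s segments. Gamma-band rhythmicity is
#' summarized as the ratio of the spectral peak in the gamma band (25-90 Hz)
#' to a robust baseline (median power over 20-200 Hz); a homogeneous Poisson
#' population yields a flat spectrum with ratio near 1.
#'
#' @param result A `simulation_result`, or a numeric vector of spike times.
#' @param neurons Optional neuron subset (when `result` is a simulation).
#' @param window Analysis window (>= 1 s).
#' @param bin Bin width in seconds (default 0.001).
#' @param band Gamma band in Hz.
#' @param threshold Peak-to-baseline ratio declaring gamma present.
#' @return An object of class `"spectral_summary"` with `freq`, `power`,
#'   `peak_freq`, `peak_ratio`, `gamma_present`, `low_power` (fewer than 100
#'   spikes).
#' @export
gamma_power <- function(result, neurons = NULL, window = c(2, 7), bin = 1e-3,
                        band = c(25, 90), threshold = 2) {
  if (diff(window) < 1) stop("window must span at least 1 s")
  if (inherits(result, "simulation_result")) {
    sp <- spikes_in_window(result, window)
    t <- if (is.null(neurons)) sp$t else sp$t[sp$id %in% neurons]
  } else {
    t <- result[result >= window[1] & result < window[2]]
  }
  low_power <- length(t) < 100
  seg_len <- round(1 / bin)
  n_seg <- floor(diff(window) / 1)
  counts <- tabulate(pmin(floor((t - window[1]) / bin), n_seg * seg_len - 1) + 1L,
                     nbins = n_seg * seg_len)
  pow <- 0
  for (s in seq_len(n_seg)) {
    x <- counts[((s - 1) * seg_len + 1):(s * seg_len)]
    x <- x - mean(x)
    pow <- pow + Mod(stats::fft(x))^2 / seg_len
  }
  pow <- pow / n_seg
  # light Daniell smoothing stabilizes the peak-to-baseline estimate
  sm <- stats::filter(pow, rep(1 / 3, 3), circular = TRUE)
  pow <- as.numeric(sm)
  freq <- (seq_along(pow) - 1) / (seg_len * bin)
  half <- freq <= 1 / (2 * bin)
  freq <- freq[half]; pow <- pow[half]
  in_band <- freq >= band[1] & freq <= band[2]
  base <- freq >= 20 & freq <= 200
  baseline <- stats::median(pow[base])
  peak_i <- which(in_band)[which.max(pow[in_band])]
  peak_ratio <- if (baseline > 0 && length(peak_i)) pow[peak_i] / baseline else NA_real_
  out <- list(freq = freq, power = pow,
              peak_freq = if (length(peak_i)) freq[peak_i] else NA_real_,
              peak_ratio = peak_ratio,
              gamma_present = isTRUE(peak_ratio >= threshold) && !low_power,
              low_power = low_power, band = band, threshold = threshold)
  class(out) <- "spectral_summary"
  out
}

#' Orientation-preference histograms over the analysis wedges
#'
#' For a battery of 16 equally spaced gratings, determines each neuron's
#' preferred grating (argmax of its mean rate; ties broken toward the lower
#' grating index) and returns, per analysis wedge, the normalized histogram
#' of preferences over its responsive neurons. Silent neurons are excluded
#' and counted.
#'
#' @param results List of entries `list(stim =, result =)`, one per grating,
#'   with orientations `i * 180/16`.
#' @param wedges A `wedge_partition` in analysis mode.
#' @param window Rate window in seconds.
#' @return An object of class `"preference_histograms"`: list with `hist`
#'   (matrix wedge x 16, rows summing to 1), `n_silent`, `n_neurons`, and
#'   `preferred` (per-neuron grating index, `NA` for silent).
#' @export
preference_histograms <- function(results, wedges, window = c(2, 7)) {
  members <- if (inherits(wedges, "wedge_partition")) wedges$members else wedges
  oris <- vapply(results, function(r) r$stim$orientation, numeric(1))
  if (length(results) != 16) stop("expected a battery of 16 gratings")
  ord <- order(oris)
  results <- results[ord]
  n <- results[[1]]$result$n
  rates <- matrix(0, n, 16)
  for (g in 1:16) {
    sp <- spikes_in_window(results[[g]]$result, window)
    rates[, g] <- tabulate(sp$id, nbins = n) / diff(window)
  }
  silent <- rowSums(rates) == 0
  preferred <- ifelse(silent, NA_integer_, max.col(rates, ties.method = "first"))
  hist <- t(vapply(members, function(idx) {
    pref <- preferred[idx]
    pref <- pref[!is.na(pref)]
    if (length(pref) == 0) return(rep(NA_real_, 16))
    tabulate(pref, nbins = 16) / length(pref)
  }, numeric(16)))
  out <- list(hist = hist, preferred = preferred,
              n_silent = vapply(members, function(idx) sum(silent[idx]), numeric(1)),
              n_neurons = lengths(members))
  class(out) <- "preference_histograms"
  out
}

#' Bimodality of a rate distribution (density-valley statistic)
#'
#' Kernel-density based statistic: the two highest density modes are
#' located and the statistic is the relative depth of the deepest valley
#' between them, `(min(p1, p2) - v) / min(p1, p2)`, in `[0, 1]`; 0 for a
#' unimodal sample. Values above `0.5` are treated as bimodal.
#'
#' @param x Numeric sample (e.g. per-neuron firing rates).
#' @return The statistic in `[0, 1]` (0 for degenerate samples).
#' @export
bimodality_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5 || stats::sd(x) == 0) return(0)
  d <- stats::density(x, n = 512)
  y <- d$y
  up <- diff(y) > 0
  modes <- which(c(FALSE, up) & c(!up, FALSE))
  if (length(modes) < 2) return(0)
  top <- modes[order(y[modes], decreasing = TRUE)[1:2]]
  lo <- min(top); hi <- max(top)
  valley <- min(y[lo:hi])
  ref <- min(y[lo], y[hi])
  if (ref <= 0) return(0)
  (ref - valley) / ref
}

#' Firing-rate distribution of a patch
#'
#' Per-neuron mean rates with the silent fraction and the bimodality
#' statistic; optionally filters an accompanying circular-variance sample to
#' neurons firing above `threshold` (the CV panels use only neurons above
#' 5 Hz).
#'
#' @param result A `simulation_result`.
#' @param patch Neuron indices.
#' @param window Rate window in seconds.
#' @param threshold Rate threshold in Hz for the CV filter.
#' @param cv Optional per-neuron circular variances aligned with `patch`.
#' @return A list with `rates`, `silent_fraction`, `bimodality`,
#'   `bimodal` (statistic > 0.5), and `cv_active` (CV values of neurons
#'   above threshold, if `cv` given).
#' @export
rate_distribution <- function(result, patch, window = c(2, 7), threshold = 5,
                              cv = NULL) {
  pr <- patch_rates(result, patch, window)
  rates <- pr$per_neuron
  stat <- bimodality_statistic(rates)
  out <- list(rates = rates,
              silent_fraction = mean(rates == 0),
              bimodality = stat,
              bimodal = stat > 0.5)
  if (!is.null(cv)) {
    stopifnot(length(cv) == length(patch))
    out$cv_active <- cv[rates > threshold]
  }
  out
}
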