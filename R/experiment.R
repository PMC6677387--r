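#' Run the standard stimulus protocol on a network
#'
#' Drives the network with a high-contrast drifting grating (driven
#' condition; the optimal and orthogonal patches are the central-hypercolumn
#' template wedges matching and orthogonal to the grating orientation) and
#' with the background condition (zero contrast, spontaneous Layer-6 rates),
#' each for `duration` seconds, and summarizes the six steering rates and
#' source-resolved currents of the optimal patch over the last
#' `duration - window[1]` seconds.
#'
#' @param net A connected `network_realization`.
#' @param w Synaptic weight set (e.g. [apply_multipliers()] output).
#' @param seed Integer master seed for this trial (drive and integration).
#' @param duration Run length per condition, seconds (default 7).
#' @param window Averaging window, default `c(2, duration)`.
#' @param stim Driven-condition grating (default vertical, 2.5 c/d, 4 Hz,
#'   full contrast).
#' @param drive Drive parameters.
#' @param bio Biophysical parameters.
#' @param conditions Subset of `c("driven", "background")` to run.
#' @param keep_results Keep the full `simulation_result` objects.
#' @return A list of class `"protocol_summary"`: `rates` (a
#'   [rate_summary()]), `currents_opt` and `currents_ortho`
#'   (`current_summary` objects from the driven run), patch indices, and
#'   optionally `results`.
#' @export
run_protocol <- function(net, w = synaptic_weights(), seed, duration = 7,
                         window = c(2, duration),
                         stim = grating_stimulus(90),
                         drive = drive_params(), bio = biophysics_params(),
                         conditions = c("driven", "background"),
                         keep_results = FALSE) {
  if (missing(seed)) stop("`seed` is required")
  opt <- wedge_patch(net, stim$orientation %% 180)
  ortho <- wedge_patch(net, (stim$orientation + 90) %% 180)
  rec <- c(opt, ortho)
  out <- list(opt_patch = opt, ortho_patch = ortho)
  results <- list()

  E_opt <- I_opt <- E_ortho <- I_ortho <- E_bg <- I_bg <- NA_real_
  if ("driven" %in% conditions) {
    dr <- make_drive(net, stim, duration, derive_seed(seed, "drive-driven"),
                     drive)
    res <- run_simulation(net, dr, w, duration,
                          seed = derive_seed(seed, "sim-driven"),
                          record = rec, record_window = window, bio = bio,
                          warn_short = FALSE)
    po <- patch_rates(res, opt, window)
    pq <- patch_rates(res, ortho, window)
    E_opt <- po$E; I_opt <- po$I; E_ortho <- pq$E; I_ortho <- pq$I
    out$currents_opt <- decompose_currents(res, opt, window)
    out$currents_ortho <- decompose_currents(res, ortho, window)
    if (keep_results) results$driven <- res
  }
  if ("background" %in% conditions) {
    dr <- make_drive(net, NULL, duration, derive_seed(seed, "drive-bg"), drive)
    res <- run_simulation(net, dr, w, duration,
                          seed = derive_seed(seed, "sim-bg"),
                          record = rec, record_window = window, bio = bio,
                          warn_short = FALSE)
    pb <- patch_rates(res, opt, window)
    E_bg <- pb$E; I_bg <- pb$I
    if (keep_results) results$background <- res
  }
  out$rates <- rate_summary(E_opt, I_opt, E_ortho, I_ortho, E_bg, I_bg)
  if (keep_results) out$results <- results
  class(out) <- "protocol_summary"
  out
}

#' Protocol closure for the compensation search
#'
#' Wraps a network into a `function(multipliers) -> rate_summary`, the
#' interface consumed by [scan_m_II()] and [compensate()].
#'
#' @param net A connected `network_realization`.
#' @param w_full Full-size weight set to which multipliers are applied.
#' @param seed Integer seed used for every evaluation (frozen so the scan
#'   varies only the multipliers).
#' @param ... Passed to [run_protocol()].
#' @return A function of one `multipliers` argument.
#' @export
network_protocol <- function(net, w_full = synaptic_weights(), seed, ...) {
  force(net); force(w_full); force(seed)
  args <- list(...)
  function(m) {
    do.call(run_protocol,
            c(list(net = net, w = apply_multipliers(w_full, m), seed = seed),
              args))$rates
  }
}

#' Run a reduced-cortex trial from scratch
#'
#' Builds a fresh seeded network at scale 1/n, applies the multipliers, and
#' runs the stimulus protocol — one "trial" of the scaling experiments
#' (different trials use different seeds, hence different networks and
#' initial conditions).
#'
#' @param scale_n Reduction factor.
#' @param m A `multipliers` object (default all ones: uncompensated).
#' @param seed Integer trial seed.
#' @param w_full Full-size weights.
#' @param rule Connectivity rule.
#' @param ... Passed to [run_protocol()].
#' @return A `protocol_summary` (with the network in `$net`).
#' @export
scaled_trial <- function(scale_n, m = multipliers(scale_n = scale_n), seed,
                         w_full = synaptic_weights(),
                         rule = connectivity_rule(), ...) {
  net <- build_network(scale_n, seed, rule)
  out <- run_protocol(net, apply_multipliers(w_full, m), seed = seed, ...)
  out$net <- net
  out
}

config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run a full experiment from a configuration
#'
#' Orchestrates multi-trial scaling experiments: builds networks, applies
#' weights, simulates the protocol, computes rate/current summaries and
#' writes `results.csv` plus a `manifest.json` capturing the configuration.
#' Idempotent per configuration hash: an output directory already holding
#' results for the same configuration is returned as-is. Partial outputs
#' are removed on failure.
#'
#' @param config A list with elements `scale_n`, `seed`, and optionally
#'   `n_trials` (default 1), `multipliers` (list of multiplier values, or
#'   `"table1"` to use the printed regime for that scale; default
#'   uncompensated), `duration` (default 7), `conditions`, and `out_dir`
#'   (default `tempfile()`).
#' @return Invisibly, a list with `results` (data frame) and `out_dir`.
#' @export
run_experiment <- function(config) {
  stopifnot(is.list(config), !is.null(config$scale_n), !is.null(config$seed))
  duration <- config$duration %||% 7
  if (duration <= 0) stop("invalid config: duration must be positive")
  n_trials <- config$n_trials %||% 1L
  out_dir <- config$out_dir %||% tempfile("v1scale-exp-")
  conditions <- config$conditions %||% c("driven", "background")

  m <- if (identical(config$multipliers, "table1")) {
    table1_row(config$scale_n)
  } else if (is.list(config$multipliers)) {
    do.call(multipliers, c(config$multipliers, list(scale_n = config$scale_n)))
  } else {
    multipliers(scale_n = config$scale_n)
  }

  hash <- config_hash(list(scale = config$scale_n, seed = config$seed,
                           trials = n_trials, m = unclass(m),
                           duration = duration, conditions = conditions))
  manifest_path <- file.path(out_dir, "manifest.json")
  results_path <- file.path(out_dir, "results.csv")
  if (file.exists(manifest_path) && file.exists(results_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, hash)) {
      return(invisible(list(results = utils::read.csv(results_path),
                            out_dir = out_dir)))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(c(manifest_path, results_path)), add = TRUE)

  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    trial_seed <- derive_seed(config$seed, paste0("trial", i))
    pr <- scaled_trial(config$scale_n, m, trial_seed, duration = duration,
                       conditions = conditions)
    r <- pr$rates
    rows[[i]] <- data.frame(
      scale_n = config$scale_n, trial = i, seed = trial_seed,
      m_EE = m$m_EE, m_EI = m$m_EI, m_IE = m$m_IE, m_II = m$m_II,
      m_I_LGN = m$m_I_LGN,
      E_opt = r$E_opt, I_opt = r$I_opt, E_ortho = r$E_ortho,
      I_ortho = r$I_ortho, E_bg = r$E_bg, I_bg = r$I_bg, OS = r$OS,
      lgn_fraction = if (!is.null(pr$currents_opt$E)) {
        pr$currents_opt$E$fractions[["LGN"]]
      } else NA_real_,
      diff_E = pr$currents_opt$diff_E %||% NA_real_,
      diff_I = pr$currents_opt$diff_I %||% NA_real_
    )
  }
  results <- do.call(rbind, rows)
  utils::write.csv(results, results_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(package = "v1scale",
         version = as.character(utils::packageVersion("v1scale")),
         config_hash = hash,
         config = list(scale_n = config$scale_n, seed = config$seed,
                       n_trials = n_trials, multipliers = unclass(m)[1:5],
                       duration = duration, conditions = conditions)),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(list(results = results, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
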