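# Full-scale presynaptic in-degree targets and Gaussian kernel widths.
# Densities (cells/deg^2) at full scale: E 48000, I 16000, Layer-6 16000.
# The kernel is p(d) = p0 * exp(-d^2 / (2 sigma^2)); p0 is calibrated
# analytically from the continuum approximation p0 = K / (rho * 2 pi sigma^2)
# so that bulk neurons hit the stated full-scale mean in-degrees. The same
# p(d) is retained at every scale, so in-degrees fall as 1/n with density.

#' Distance-dependent connectivity rule
#'
#' Per ordered type pair, a Gaussian probability-versus-distance kernel and
#' the full-scale target mean in-degree: each E cell receives ~200 E and ~100
#' I intracortical inputs and ~50 Layer-6 inputs; each I cell receives ~775 E,
#' ~100 I and ~100 Layer-6 inputs. The kernel widths are calibrated model
#' parameters (the defaults keep E-to-E excitation wedge-local, let E-to-I
#' drive pool across orientation domains, and give inhibition an intermediate
#' reach; all are of the order of the 125-250 um axonal scales of the layer).
#' Complex-flagged cells (2 or fewer LGN inputs) receive elevated
#' cortico-cortical excitation (`complex_EE_factor` on the E-to-E kernel).
#' Realized in-degrees are narrowed to ~1 binomial standard deviation of
#' their expectation by redrawing (at most `max_redraw` times); neurons left
#' with fewer than 2 inhibitory inputs are also redrawn, since single
#' unlucky draws otherwise dominate the local E/I balance in the smallest
#' cortices.
#'
#' @param sigma_E,sigma_I Kernel widths (cortical degrees) for E-to-E and for
#'   I-to-E/I-to-I connections.
#' @param sigma_IE Kernel width for E-to-I connections (wider by default:
#'   inhibitory cells sample excitation across orientation domains).
#' @param complex_EE_factor Multiplier on the E-to-E kernel for complex cells.
#' @param redraw_sd,max_redraw Redraw tolerance (binomial SDs) and cap.
#' @param min_I_inputs Neurons whose expected I in-degree allows it are
#'   redrawn until they keep at least this many inhibitory inputs.
#' @return A list of class `"connectivity_rule"`.
#' @export
connectivity_rule <- function(sigma_E = 0.060, sigma_I = 0.100,
                              sigma_IE = 0.125,
                              complex_EE_factor = 2,
                              redraw_sd = 1, max_redraw = 50,
                              min_I_inputs = 2L) {
  dens <- c(E = 27000, I = 9000, L6 = 9000) / PATCH_DEG^2
  target <- c(EE = 200, EI = 100, IE = 775, II = 100, L6E = 50, L6I = 100)
  sigma <- c(EE = sigma_E, EI = sigma_I, IE = sigma_IE, II = sigma_I,
             L6E = sigma_E, L6I = sigma_E)
  pre_type <- c(EE = "E", EI = "I", IE = "E", II = "I", L6E = "L6", L6I = "L6")
  p0 <- target / (dens[pre_type] * 2 * pi * sigma^2)
  names(p0) <- names(target)
  rule <- list(target = target, sigma = sigma, p0 = pmin(p0, 0.95),
               pre_type = pre_type,
               complex_EE_factor = complex_EE_factor,
               redraw_sd = redraw_sd, max_redraw = max_redraw,
               min_I_inputs = as.integer(min_I_inputs))
  class(rule) <- "connectivity_rule"
  rule
}

# Draw presynaptic sets for a block of postsynaptic neurons from one
# presynaptic population. prob is an n_post x n_pre matrix of connection
# probabilities; rows are redrawn until the realized in-degree is within
# `redraw_sd` binomial SDs of its expectation (up to max_redraw times).
draw_presynaptic_block <- function(prob, redraw_sd, max_redraw, min_k = 0L) {
  n_post <- nrow(prob); n_pre <- ncol(prob)
  mu <- rowSums(prob)
  sdv <- sqrt(rowSums(prob * (1 - prob)))
  floor_k <- pmin(min_k, ceiling(mu))
  draw <- matrix(stats::runif(n_post * n_pre) < prob, n_post, n_pre)
  k <- rowSums(draw)
  out_of_range <- function(idx) {
    idx[(abs(k[idx] - mu[idx]) > redraw_sd * sdv[idx] & sdv[idx] > 0) |
          k[idx] < floor_k[idx]]
  }
  bad <- out_of_range(seq_len(n_post))
  tries <- 0L
  while (length(bad) > 0 && tries < max_redraw) {
    redo <- matrix(stats::runif(length(bad) * n_pre), length(bad), n_pre) <
      prob[bad, , drop = FALSE]
    draw[bad, ] <- redo
    k[bad] <- rowSums(redo)
    bad <- out_of_range(bad)
    tries <- tries + 1L
  }
  apply(draw, 1, which, simplify = FALSE)
}

pair_probabilities <- function(pos_post, pos_pre, p0, sigma, self = NULL) {
  d2 <- outer(pos_post[, 1], pos_pre[, 1], "-")^2 +
        outer(pos_post[, 2], pos_pre[, 2], "-")^2
  p <- p0 * exp(-d2 / (2 * sigma^2))
  if (!is.null(self)) p[self] <- 0
  pmin(p, 1)
}

#' Sample the synaptic connectivity of a network realization
#'
#' Populates the presynaptic adjacency lists (intracortical E and I inputs and
#' Layer-6 inputs for every neuron) by independent distance-dependent coin
#' tosses under `rule`, with in-degree distributions narrowed to roughly one
#' binomial standard deviation by redrawing. Also freezes the per-synapse
#' weight jitter draws, the per-neuron Layer-6 coupling draw and the
#' per-Layer-6-cell spike-failure draw, so that a realization fully
#' determines a simulation once weights are supplied.
#'
#' @param layout A `network_realization` from [build_layout()].
#' @param rule A `connectivity_rule`.
#' @param seed Integer seed for the connectivity draw.
#' @return The layout with `$adjacency` populated.
#' @export
sample_connectivity <- function(layout, rule = connectivity_rule(), seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(inherits(layout, "network_realization"))
  n <- layout$n
  scale_n <- layout$scale_n
  exp_I_indeg <- rule$target[["EI"]] / scale_n
  if (exp_I_indeg < 1) {
    warning(sprintf(
      "expected I in-degree %.2f < 1 at scale 1/%d: pathological regime",
      exp_I_indeg, scale_n))
  }

  old <- set_local_seed(derive_seed(seed, "connectivity"))
  on.exit(restore_seed(old), add = TRUE)

  idx_E <- which(layout$is_E)
  idx_I <- which(!layout$is_E)
  pre_E <- vector("list", n)
  pre_I <- vector("list", n)
  pre_L6 <- vector("list", n)

  block_size <- 512L
  for (post_set in list(idx_E, idx_I)) {
    post_is_E <- layout$is_E[post_set[1]]
    keyE <- if (post_is_E) "EE" else "IE"
    keyI <- if (post_is_E) "EI" else "II"
    keyL6 <- if (post_is_E) "L6E" else "L6I"
    for (start in seq(1, length(post_set), by = block_size)) {
      blk <- post_set[start:min(start + block_size - 1L, length(post_set))]
      pos_blk <- layout$pos[blk, , drop = FALSE]

      # E inputs (complex cells get elevated E-to-E connectivity)
      pE <- pair_probabilities(pos_blk, layout$pos[idx_E, , drop = FALSE],
                               rule$p0[[keyE]], rule$sigma[[keyE]])
      if (post_is_E) {
        fac <- ifelse(layout$complex[blk], rule$complex_EE_factor, 1)
        pE <- pmin(pE * fac, 1)
        self <- cbind(seq_along(blk), match(blk, idx_E))
        pE[self] <- 0
      }
      sets <- draw_presynaptic_block(pE, rule$redraw_sd, rule$max_redraw)
      pre_E[blk] <- lapply(sets, function(s) idx_E[s])

      # I inputs: neurons with fewer than 2 presynaptic I cells are redrawn
      # (at very small scales single unlucky draws otherwise dominate the
      # local E/I balance)
      pI <- pair_probabilities(pos_blk, layout$pos[idx_I, , drop = FALSE],
                               rule$p0[[keyI]], rule$sigma[[keyI]])
      if (!post_is_E) {
        self <- cbind(seq_along(blk), match(blk, idx_I))
        pI[self] <- 0
      }
      sets <- draw_presynaptic_block(pI, rule$redraw_sd, rule$max_redraw,
                                     min_k = rule$min_I_inputs %||% 2L)
      pre_I[blk] <- lapply(sets, function(s) idx_I[s])

      # Layer-6 inputs
      pL <- pair_probabilities(pos_blk, layout$l6$pos,
                               rule$p0[[keyL6]], rule$sigma[[keyL6]])
      pre_L6[blk] <- draw_presynaptic_block(pL, rule$redraw_sd, rule$max_redraw)
    }
  }

  jit <- function(lst) lapply(lengths(lst), function(k) stats::runif(k, 0.9, 1.1))
  layout$adjacency <- list(
    pre_E = pre_E, pre_I = pre_I, pre_L6 = pre_L6,
    jit_E = jit(pre_E), jit_I = jit(pre_I), jit_L6 = jit(pre_L6),
    s6_unit = stats::runif(n),
    l6_fail_unit = stats::runif(layout$l6$n),
    rule = rule
  )
  layout
}

#' Assign LGN template cells to each neuron
#'
#' Draws, for every neuron, its frozen set of LGN input cells from the ON/OFF
#' template rows matching the neuron's wedge angle (0, 30, ..., 150 degrees)
#' in its own hypercolumn. The number of inputs per neuron was fixed by
#' [build_layout()] (1-6, mean 4; complex-flagged cells have 2 or fewer).
#' Cells are split as evenly as possible between the ON and OFF rows and
#' spread systematically along each row (random start), giving every neuron
#' uniform retinotopic coverage of its template: the cells of a row share
#' the grating phase at the preferred orientation, while at the orthogonal
#' orientation the spread sampling minimizes accidental phase coherence.
#'
#' @param layout A `network_realization`.
#' @param seed Integer seed for the draw.
#' @return The layout with `$lgn_input` populated (list of sheet cell ids per
#'   neuron, plus per-connection weight jitter).
#' @export
assign_lgn <- function(layout, seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(inherits(layout, "network_realization"))
  old <- set_local_seed(derive_seed(seed, "lgn"))
  on.exit(restore_seed(old), add = TRUE)

  sheet <- layout$lgn_sheet
  key <- paste(sheet$hc, sheet$angle)
  on_cells <- split(sheet$id[sheet$onoff == "ON"], key[sheet$onoff == "ON"])
  off_cells <- split(sheet$id[sheet$onoff == "OFF"], key[sheet$onoff == "OFF"])
  # j of the 5 row slots, systematically spread with a random circular start
  pick_spread <- function(slots, j) {
    if (j <= 0) return(integer(0))
    start <- sample.int(5L, 1L) - 1L
    idx <- (start + round((0:(j - 1)) * 5 / j)) %% 5 + 1
    slots[sort(unique(idx))[seq_len(j)]]
  }
  want <- paste(layout$hc, layout$wedge_angle)
  cells <- vector("list", layout$n)
  for (i in seq_len(layout$n)) {
    k <- layout$lgn_count[i]
    a <- (k + sample(0:1, 1)) %/% 2L  # ON count: balanced split, random tie
    cells[[i]] <- sort(c(pick_spread(on_cells[[want[i]]], a),
                         pick_spread(off_cells[[want[i]]], k - a)))
  }
  layout$lgn_input <- list(
    cells = cells,
    jit = lapply(layout$lgn_count, function(k) stats::runif(k, 0.9, 1.1))
  )
  layout
}

#' Realized in-degree of each neuron from one source
#'
#' @param net A connected `network_realization`.
#' @param source One of `"E"`, `"I"`, `"L6"`, `"LGN"`.
#' @return Integer vector of per-neuron in-degrees.
#' @export
in_degree <- function(net, source = c("E", "I", "L6", "LGN")) {
  source <- match.arg(source)
  if (source == "LGN") {
    if (is.null(net$lgn_input)) stop("LGN inputs not assigned")
    return(lengths(net$lgn_input$cells))
  }
  if (is.null(net$adjacency)) stop("connectivity not sampled")
  lengths(net$adjacency[[paste0("pre_", source)]])
}

#' Build a fully connected network realization in one call
#'
#' Convenience wrapper chaining [build_layout()], [sample_connectivity()] and
#' [assign_lgn()] with stage seeds derived from one master seed.
#'
#' @inheritParams build_layout
#' @param rule A `connectivity_rule`.
#' @return A connected `network_realization`.
#' @export
build_network <- function(scale_n, seed, rule = connectivity_rule()) {
  net <- build_layout(scale_n, seed)
  net <- sample_connectivity(net, rule, seed = derive_seed(seed, "conn-stage"))
  assign_lgn(net, seed = derive_seed(seed, "lgn-stage"))
}
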