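# Geometry constants of the modeled cortical patch: 9 hypercolumns covering
# 0.75 x 0.75 deg of visual field at 5 deg eccentricity. E and I cells live on
# separate rectangular lattices (27000 E on 180 x 150, 9000 I on 90 x 100 at
# full scale); the Layer-6 source pool has its own 100 x 90 lattice. Reduced
# cortices are per-axis sublattices of the full lattices, so positions at
# scale 1/n are exactly a subset of the full-scale positions.
PATCH_DEG <- 0.75
HC_DEG <- 0.25
E_NX <- 180L; E_NY <- 150L
I_NX <- 90L;  I_NY <- 100L
L6_NX <- 100L; L6_NY <- 90L
TEMPLATE_ANGLES <- c(0, 30, 60, 90, 120, 150)

lattice_positions <- function(nx, ny, keep_x = 1L, keep_y = 1L) {
  ix <- seq.int(1L, nx, by = keep_x)
  iy <- seq.int(1L, ny, by = keep_y)
  dx <- PATCH_DEG / nx
  dy <- PATCH_DEG / ny
  g <- expand.grid(ix = ix, iy = iy, KEEP.OUT.ATTRS = FALSE)
  cbind(x = (g$ix - 0.5) * dx, y = (g$iy - 0.5) * dy)
}

scale_steps <- function(scale_n) {
  if (scale_n == 2) return(c(2L, 1L))
  r <- sqrt(scale_n)
  if (abs(r - round(r)) > 1e-9) {
    stop("scale_n must be a perfect square or 2 (per-axis sublattice rule)")
  }
  c(as.integer(round(r)), as.integer(round(r)))
}

hypercolumn_index <- function(pos) {
  col <- pmin(floor(pos[, 1] / HC_DEG), 2)
  row <- pmin(floor(pos[, 2] / HC_DEG), 2)
  as.integer(row * 3 + col + 1L)
}

hc_center <- function(hc) {
  hc0 <- hc - 1L
  cbind((hc0 %% 3 + 0.5) * HC_DEG, (hc0 %/% 3 + 0.5) * HC_DEG)
}

# Orientation preference implied by position around the local pinwheel:
# the full 360 deg of angle around the hypercolumn center maps onto
# 180 deg of orientation.
pinwheel_preference <- function(pos, hc) {
  ctr <- hc_center(hc)
  a <- atan2(pos[, 2] - ctr[, 2], pos[, 1] - ctr[, 1])
  (a %% (2 * pi)) * 90 / pi
}

nearest_template_angle <- function(pref) {
  TEMPLATE_ANGLES[(floor(pref / 30 + 0.5) %% 6) + 1]
}

#' Build a seeded network layout at scale 1/n
#'
#' Constructs neuron positions, E/I type labels, hypercolumn and wedge labels,
#' per-neuron LGN input counts and complex-cell flags for a 1/n-cortex, plus
#' the Layer-6 source pool and the LGN template sheet. At full scale the layer
#' holds ~36000 neurons (27000 E, 9000 I) in 9 hypercolumns; a 1/n-cortex
#' keeps a per-axis sublattice with 1/sqrt(n) of the neurons in each direction
#' (for n = 2, one axis only), so positions at scale 1/n are exactly a subset
#' of the full-scale positions. Per-neuron LGN statistics are unchanged across
#' scales: 1-6 LGN inputs, mean 4, with a fixed 30% of E cells flagged complex
#' (2 or fewer LGN inputs, elevated cortical connectivity).
#'
#' @param scale_n Reduction factor n (1, 2 or a perfect square such as 4, 9,
#'   16, 25, 49).
#' @param seed Integer master seed (required; layouts are reproducible).
#' @return An object of class `"network_realization"`.
#' @export
build_layout <- function(scale_n, seed) {
  if (missing(seed)) stop("`seed` is required: network realizations are seeded")
  if (!is.numeric(scale_n) || length(scale_n) != 1 || scale_n <= 0 ||
      abs(scale_n - round(scale_n)) > 1e-9) {
    stop("`scale_n` must be a positive integer")
  }
  scale_n <- as.integer(round(scale_n))
  st <- scale_steps(scale_n)

  pos_E <- lattice_positions(E_NX, E_NY, st[1], st[2])
  pos_I <- lattice_positions(I_NX, I_NY, st[1], st[2])
  pos <- rbind(pos_E, pos_I)
  type <- rep(c("E", "I"), c(nrow(pos_E), nrow(pos_I)))
  n <- nrow(pos)
  hc <- hypercolumn_index(pos)
  pref <- pinwheel_preference(pos, hc)
  wedge_angle <- nearest_template_angle(pref)

  old <- set_local_seed(derive_seed(seed, "layout"))
  on.exit(restore_seed(old), add = TRUE)

  is_E <- type == "E"
  nE <- sum(is_E)
  n_complex <- round(0.3 * nE)
  complex_flag <- rep(FALSE, n)
  complex_flag[sample(which(is_E), n_complex)] <- TRUE

  lgn_count <- integer(n)
  lgn_count[complex_flag] <- sample(1:2, sum(complex_flag), replace = TRUE)
  simple_E <- is_E & !complex_flag
  lgn_count[simple_E] <- sample(4:6, sum(simple_E), replace = TRUE,
                                prob = c(0.25, 3 / 7, 0.25 + 1 / 14))
  lgn_count[!is_E] <- 1L + stats::rbinom(sum(!is_E), 5, 0.6)

  pos_L6 <- lattice_positions(L6_NX, L6_NY, st[1], st[2])
  hc_L6 <- hypercolumn_index(pos_L6)
  pref_L6 <- pinwheel_preference(pos_L6, hc_L6)

  net <- list(
    scale_n = scale_n, seed = seed,
    pos = pos, type = type, n = n, is_E = is_E,
    hc = hc, pref = pref, wedge_angle = wedge_angle,
    complex = complex_flag, lgn_count = lgn_count,
    l6 = list(pos = pos_L6, hc = hc_L6, pref = pref_L6,
              wedge_angle = nearest_template_angle(pref_L6), n = nrow(pos_L6)),
    lgn_sheet = build_lgn_sheet(),
    adjacency = NULL, lgn_input = NULL
  )
  class(net) <- "network_realization"
  net
}

# LGN template sheet: per hypercolumn and per template angle, a row of 5 ON
# cells along the template orientation through the hypercolumn center plus a
# parallel row of 5 OFF cells offset by half a period of the preferred
# spatial frequency, producing Hubel-Wiesel style antiphase ON/OFF subregions.
LGN_ROW_SPACING <- 0.08   # deg between cells: 1/5 period at the preferred
                          # SF, so the 5 cells of a row tile the grating
                          # cycle evenly at the orthogonal orientation
LGN_OFF_OFFSET <- 0.2     # deg, half period at 2.5 cycles/deg
build_lgn_sheet <- function() {
  rows <- list()
  k <- (-2):2
  for (h in 1:9) {
    ctr <- hc_center(h)
    for (a in TEMPLATE_ANGLES) {
      u <- c(cos(a * pi / 180), sin(a * pi / 180))
      wv <- c(-u[2], u[1])
      on_x <- ctr[1] + k * LGN_ROW_SPACING * u[1]
      on_y <- ctr[2] + k * LGN_ROW_SPACING * u[2]
      rows[[length(rows) + 1]] <- data.frame(
        hc = h, angle = a,
        onoff = rep(c("ON", "OFF"), each = 5),
        x = c(on_x, on_x + LGN_OFF_OFFSET * wv[1]),
        y = c(on_y, on_y + LGN_OFF_OFFSET * wv[2])
      )
    }
  }
  sheet <- do.call(rbind, rows)
  sheet$id <- seq_len(nrow(sheet))
  sheet
}

#' Partition a layout into orientation wedges
#'
#' In `"template"` mode returns the 6 disjoint 60-degree sectors per
#' hypercolumn whose neurons share an intended orientation preference (0, 30,
#' ..., 150 degrees), i.e. the wedges tied to the LGN templates. In
#' `"analysis"` mode returns 16 half-overlapping wedges of the central
#' hypercolumn, wedge i centered at i * 180/16 degrees of preference with
#' half-width 11.25 degrees, so every neuron belongs to exactly two adjacent
#' wedges and, under the pinwheel construction, a neuron of wedge i prefers
#' grating i with probability 1/2 and gratings i-1 and i+1 with probability
#' 1/4 each.
#'
#' @param layout A `network_realization`.
#' @param mode `"template"` or `"analysis"`.
#' @return An object of class `"wedge_partition"`: a list with `mode`,
#'   `members` (list of neuron index vectors), and per-wedge metadata
#'   (`angle`, and `hc` in template mode).
#' @export
partition_wedges <- function(layout, mode = c("template", "analysis")) {
  mode <- match.arg(mode)
  if (mode == "template") {
    members <- list(); angle <- numeric(0); hc <- integer(0)
    for (h in 1:9) {
      for (a in TEMPLATE_ANGLES) {
        members[[length(members) + 1]] <-
          which(layout$hc == h & layout$wedge_angle == a)
        angle <- c(angle, a); hc <- c(hc, h)
      }
    }
    out <- list(mode = mode, members = members, angle = angle, hc = hc)
  } else {
    central <- which(layout$hc == 5L)
    if (length(central) < 16) {
      warning("central hypercolumn has fewer than 16 neurons; ",
              "analysis wedges will be poorly sampled")
    }
    pref <- layout$pref[central]
    centers <- (0:15) * 180 / 16
    members <- lapply(centers, function(cc) {
      d <- ((pref - cc + 90) %% 180) - 90
      central[d >= -11.25 & d < 11.25]
    })
    out <- list(mode = mode, members = members, angle = centers)
  }
  class(out) <- "wedge_partition"
  out
}

#' Select an orientation patch of the central hypercolumn
#'
#' Convenience accessor for the optimally / orthogonally driven patches used
#' throughout the protocols: the template wedge of the central hypercolumn
#' whose intended preference matches `angle`.
#'
#' @param layout A `network_realization`.
#' @param angle Intended preference in degrees (one of 0, 30, ..., 150).
#' @param type Restrict to `"E"`, `"I"`, or `"both"`.
#' @return Integer vector of neuron indices.
#' @export
wedge_patch <- function(layout, angle, type = c("both", "E", "I")) {
  type <- match.arg(type)
  idx <- which(layout$hc == 5L & layout$wedge_angle == angle)
  if (type == "E") idx <- idx[layout$is_E[idx]]
  if (type == "I") idx <- idx[!layout$is_E[idx]]
  idx
}

#' @export
print.network_realization <- function(x, ...) {
  cat(sprintf("Layer 4Ca network realization, scale 1/%d (seed %s)\n",
              x$scale_n, format(x$seed)))
  cat(sprintf("  %d neurons (%d E, %d I) in 9 hypercolumns\n",
              x$n, sum(x$is_E), sum(!x$is_E)))
  cat(sprintf("  Layer-6 pool: %d cells; LGN sheet: %d cells\n",
              x$l6$n, nrow(x$lgn_sheet)))
  cat(sprintf("  connectivity: %s; LGN inputs: %s\n",
              if (is.null(x$adjacency)) "not sampled" else "sampled",
              if (is.null(x$lgn_input)) "not assigned" else "assigned"))
  invisible(x)
}

# Scoped RNG helpers: set the R RNG to a derived seed and restore afterwards,
# so package functions do not disturb the caller's RNG state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
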