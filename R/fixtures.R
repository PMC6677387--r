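# Miniature networks with analytically tractable behavior, used by the test
# suite and available to users for sanity checks. Each fixture carries its
# own independent oracle (closed form or fixed-point iteration).

#' Construct a miniature network realization
#'
#' A valid `network_realization` with arbitrary E/I counts placed uniformly
#' at random in the central hypercolumn, compatible with
#' [sample_connectivity()], [assign_lgn()] and [run_simulation()]. Used for
#' toy fixtures and brute-force connectivity oracles.
#'
#' @param n_E,n_I Cell counts.
#' @param seed Integer seed.
#' @param width Side of the square the cells occupy (deg), centered on the
#'   central pinwheel.
#' @param n_l6 Size of the Layer-6 source pool.
#' @return A `network_realization` (with `scale_n = 1`).
#' @export
toy_network <- function(n_E = 75, n_I = 25, seed, width = 0.25, n_l6 = 25) {
  if (missing(seed)) stop("`seed` is required")
  old <- set_local_seed(derive_seed(seed, "toy"))
  on.exit(restore_seed(old), add = TRUE)
  n <- n_E + n_I
  ctr <- PATCH_DEG / 2
  pos <- cbind(x = stats::runif(n, ctr - width / 2, ctr + width / 2),
               y = stats::runif(n, ctr - width / 2, ctr + width / 2))
  type <- rep(c("E", "I"), c(n_E, n_I))
  hc <- rep(5L, n)
  pref <- pinwheel_preference(pos, hc)
  is_E <- type == "E"
  complex_flag <- rep(FALSE, n)
  complex_flag[sample(which(is_E), round(0.3 * n_E))] <- TRUE
  lgn_count <- integer(n)
  lgn_count[complex_flag] <- sample(1:2, sum(complex_flag), replace = TRUE)
  simple_E <- is_E & !complex_flag
  lgn_count[simple_E] <- sample(4:6, sum(simple_E), replace = TRUE,
                                prob = c(0.25, 3 / 7, 0.25 + 1 / 14))
  lgn_count[!is_E] <- 1L + stats::rbinom(n_I, 5, 0.6)
  pos_l6 <- cbind(x = stats::runif(n_l6, ctr - width / 2, ctr + width / 2),
                  y = stats::runif(n_l6, ctr - width / 2, ctr + width / 2))
  hc_l6 <- rep(5L, n_l6)
  pref_l6 <- pinwheel_preference(pos_l6, hc_l6)
  net <- list(
    scale_n = 1L, seed = seed,
    pos = pos, type = type, n = n, is_E = is_E,
    hc = hc, pref = pref, wedge_angle = nearest_template_angle(pref),
    complex = complex_flag, lgn_count = lgn_count,
    l6 = list(pos = pos_l6, hc = hc_l6, pref = pref_l6,
              wedge_angle = nearest_template_angle(pref_l6), n = n_l6),
    lgn_sheet = build_lgn_sheet(),
    adjacency = NULL, lgn_input = NULL
  )
  class(net) <- "network_realization"
  net
}

# Interior (no rectification) solution of the 2-population rate model; the
# independent linear-algebra oracle for the mean-field fixture.
meanfield_linear_solve <- function(x_E, x_I, m, n, p) {
  A <- rbind(c(1 / p$gain_E - p$c_EE * m$m_EE / n, p$c_EI * m$m_EI / n),
             c(-p$c_IE * m$m_IE / n, 1 / p$gain_I + p$c_II * m$m_II / n))
  r <- solve(A, c(x_E, x_I))
  pmax(r, 0)
}

meanfield_fixed_point <- function(x_E, x_I, m, n, p, iter = 5000, damp = 0.2) {
  r <- c(5, 20)
  for (k in seq_len(iter)) {
    new_E <- p$gain_E * max(0, x_E + p$c_EE * m$m_EE / n * r[1] -
                              p$c_EI * m$m_EI / n * r[2])
    new_I <- p$gain_I * max(0, x_I + p$c_IE * m$m_IE / n * r[1] -
                              p$c_II * m$m_II / n * r[2])
    nxt <- (1 - damp) * r + damp * c(new_E, new_I)
    if (max(abs(nxt - r)) < 1e-12) return(nxt)
    r <- nxt
  }
  r
}

make_meanfield_fixture <- function() {
  p <- list(gain_E = 0.3, gain_I = 1.0, c_EE = 2, c_EI = 1.2, c_IE = 3,
            c_II = 0.5)
  # feedforward drives solved so the full-scale fixed point reproduces the
  # full-size model's six steering rates exactly
  targets <- list(opt = c(14.71, 51.15), ortho = c(3.72, 21.48),
                  bg = c(2.93, 11.35))
  x_for <- function(r) c(
    x_E = r[1] / p$gain_E - p$c_EE * r[1] + p$c_EI * r[2],
    x_I = r[2] / p$gain_I - p$c_IE * r[1] + p$c_II * r[2]
  )
  x <- lapply(targets, x_for)
  protocol <- function(m) {
    n <- m$scale_n
    sol <- lapply(x, function(xc)
      meanfield_fixed_point(xc[["x_E"]], xc[["x_I"]], m, n, p))
    rate_summary(sol$opt[1], sol$opt[2], sol$ortho[1], sol$ortho[2],
                 sol$bg[1], sol$bg[2])
  }
  reference <- list(
    E = c(x = unname(x$opt[["x_E"]]), y = p$c_EE * targets$opt[1],
          z = p$c_EI * targets$opt[2]),
    I = c(x = unname(x$opt[["x_I"]]), y = p$c_IE * targets$opt[1],
          z = p$c_II * targets$opt[2])
  )
  diff_targets <- c(diff_E = targets$opt[1] / p$gain_E,
                    diff_I = targets$opt[2] / p$gain_I)
  list(name = "two-population-meanfield", params = p, x = x,
       protocol = protocol, reference = reference,
       diff_targets = diff_targets,
       oracle = function(m, condition = "opt") {
         xc <- x[[condition]]
         meanfield_linear_solve(xc[["x_E"]], xc[["x_I"]], m, m$scale_n, p)
       })
}

#' Named toy fixtures with attached oracles
#'
#' * `"single-neuron-constant-g"`: one E neuron under a constant clamped
#'   excitatory conductance; the oracle returns the closed-form interspike
#'   interval from the linear membrane equation.
#' * `"poisson-population"`: 100 independent homogeneous Poisson trains at
#'   20 Hz; the oracle is the flat-spectrum property (peak-to-baseline ~1).
#' * `"two-population-meanfield"`: threshold-linear E/I rate model whose
#'   full-scale fixed point equals the full-size model's six steering
#'   rates; provides a `protocol(multipliers)` usable with [scan_m_II()]
#'   and [compensate()], with an interior linear-solve oracle.
#' * `"ring-100"`: a 100-neuron toy layout (75 E / 25 I) for brute-force
#'   connectivity expectations.
#'
#' @param name Fixture name; an unknown name raises an error listing the
#'   available fixtures.
#' @param seed Integer seed where the fixture is stochastic.
#' @return A list describing the fixture, including its `oracle`.
#' @export
make_fixture <- function(name, seed = 1L) {
  fixtures <- c("single-neuron-constant-g", "poisson-population",
                "two-population-meanfield", "ring-100")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "))
  }
  switch(name,
    "single-neuron-constant-g" = {
      net <- toy_network(n_E = 1, n_I = 0, seed = seed)
      net$adjacency <- list(pre_E = list(integer(0)), pre_I = list(integer(0)),
                            pre_L6 = list(integer(0)),
                            jit_E = list(numeric(0)), jit_I = list(numeric(0)),
                            jit_L6 = list(numeric(0)),
                            s6_unit = 0.5, l6_fail_unit = numeric(net$l6$n))
      net$lgn_input <- list(cells = list(integer(0)), jit = list(numeric(0)))
      list(name = name, net = net,
           oracle = function(g_bar, bio = biophysics_params()) {
             # dv/dt = A - B v with A = g_bar V_E, B = g_leak + g_bar
             A <- g_bar * bio$V_E
             B <- bio$g_leak_E + g_bar
             if (A / B <= bio$V_th) return(Inf)
             -log(1 - B * bio$V_th / A) / B + bio$t_refrac
           })
    },
    "poisson-population" = {
      sp <- generate_ambient(100, duration = 7,
                             seed = seed, drive = drive_params())
      sp$source <- "poisson-fixture"
      list(name = name, spikes = sp,
           oracle = list(expected_peak_ratio = 1,
                         note = "homogeneous Poisson population has a flat spectrum"))
    },
    "two-population-meanfield" = make_meanfield_fixture(),
    "ring-100" = {
      net <- toy_network(n_E = 75, n_I = 25, seed = seed)
      list(name = name, net = net,
           oracle = function(rule = connectivity_rule(), pair = "EE") {
             # exhaustive expectation of the in-degree over all candidate pairs
             pre_pos <- switch(rule$pre_type[[pair]],
                               E = net$pos[net$is_E, , drop = FALSE],
                               I = net$pos[!net$is_E, , drop = FALSE],
                               L6 = net$l6$pos)
             post_is_E <- pair %in% c("EE", "EI", "L6E")
             post <- if (post_is_E) which(net$is_E) else which(!net$is_E)
             pre <- switch(rule$pre_type[[pair]], E = which(net$is_E),
                           I = which(!net$is_E), L6 = integer(0))
             p <- pair_probabilities(net$pos[post, , drop = FALSE],
                                     pre_pos,
                                     rule$p0[[pair]], rule$sigma[[pair]])
             if (pair == "EE") {
               fac <- ifelse(net$complex[post], rule$complex_EE_factor, 1)
               p <- pmin(p * fac, 1)
             }
             if (pair %in% c("EE", "II")) {
               self <- cbind(match(intersect(post, pre), post),
                             match(intersect(post, pre), pre))
               p[self] <- 0
             }
             rowSums(p)
           })
    })
}
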