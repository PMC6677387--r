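test_that("step 1 solves the current-difference constraint on hand cases", {
  # full scale with currents already on target: identity
  s <- step1_solve(x = 10, y = 100, z = 50, n = 1, target = 60)
  expect_equal(c(s$m_EE, s$m_EI), c(1, 1))
  # amplification branch: 10 + 50 m_EE - 25 = 60
  s <- step1_solve(x = 10, y = 100, z = 50, n = 2, target = 60)
  expect_equal(c(s$m_EE, s$m_EI), c(1.5, 1))
  # attenuation branch: 70 + 10 - 25 m_EI = 60
  s <- step1_solve(x = 70, y = 40, z = 100, n = 4, target = 60)
  expect_equal(c(s$m_EE, s$m_EI), c(1, 0.8))
  # I-cell analogue with m_II held at 1
  sI <- step1_solve_I(x = 20, y = 200, z = 40, n = 2, target = 120)
  expect_equal(sI$m_IE, (120 - 20 + 20) * 2 / 200)
})

test_that("step 1 satisfies its constraint to 1e-12 and pins a multiplier", {
  set.seed(101)
  for (i in 1:200) {
    x <- runif(1, 0, 150); y <- runif(1, 10, 400); z <- runif(1, 10, 400)
    n <- sample(c(1, 2, 4, 9, 16, 25, 49), 1)
    s <- step1_solve(x, y, z, n, target = 60)
    expect_true(isTRUE(s$feasible))
    expect_lt(abs(x + y / n * s$m_EE - z / n * s$m_EI - 60), 1e-12)
    expect_true(s$m_EE == 1 || s$m_EI == 1)  # one multiplier is pinned
    if (s$m_EE >= 1 && s$m_EI >= 1) {
      expect_equal(min(s$m_EE, s$m_EI), 1)   # min()=1 in the amplifying case
    }
  }
})

test_that("all-ones multipliers reproduce the full-size weights exactly", {
  w <- synaptic_weights()
  w1 <- apply_multipliers(w, multipliers())
  for (f in c("S_EE", "S_EI", "S_IE", "S_II", "S_E_LGN", "S_I_LGN")) {
    expect_identical(w1[[f]], w[[f]])
  }
  expect_equal(w1$m6_E, 1)
  expect_equal(w1$m6_I, 1)
  m <- table1_row(16)
  w16 <- apply_multipliers(w, m)
  expect_equal(w16$S_EI, w$S_EI * 2.36)
  expect_equal(w16$m6_I, 1.18)  # Layer-6 couplings co-scale
  expect_error(multipliers(m_EE = -1), "non-negative")
})

test_that("rate acceptance verdict reproduces the printed classifications", {
  full <- rate_summary(14.71, 51.15, 3.72, 21.48, 2.93, 11.35)
  v <- check_acceptance(full)
  expect_true(v$a && v$b && v$c && v$pass)
  expect_equal(v$OS, 14.71 / 3.72, tolerance = 1e-12)
  expect_equal(v$os_class, "strong")

  n25 <- rate_summary(13.17, 47.05, 5.86, NA, 1.79, 8.17)
  v25 <- check_acceptance(n25)
  expect_true(v25$pass)
  expect_equal(round(v25$OS, 2), 2.25)
  expect_equal(v25$os_class, "intermediate")

  zero <- rate_summary(0, 0, 0, 0, 0, 0)
  vz <- check_acceptance(zero)
  expect_false(vz$a || vz$b)
  expect_true(vz$undefined_ratios)
  # zero orthogonal response: infinite OS, strong class
  expect_equal(check_acceptance(rate_summary(14, 50, 0, 0, 2, 8))$os_class,
               "strong")
})

test_that("measured current differences are plain subtractions", {
  cs <- structure(list(
    E = list(currents = c(LGN = 30, ambient = 20, L4 = 45, L6 = 5, I = 35),
             fractions = c(LGN = .3, ambient = .2, L4 = .45, L6 = .05),
             x = 50, y = 100, z = 35, diff = 65),
    I = list(currents = c(LGN = 40, ambient = 20, L4 = 60, L6 = 5, I = 25),
             x = 60, y = 125, z = 25, diff = 100),
    diff_E = 65, diff_I = 100), class = "current_summary")
  expect_equal(unname(measure_diffs(cs)), c(65, 100))
})

test_that("the m_II scan finds acceptable regimes on the mean-field model", {
  fx <- make_fixture("two-population-meanfield")
  cand <- multipliers(scale_n = 1)
  # empty grid degenerates gracefully
  empty <- scan_m_II(cand, grid = numeric(0), protocol = fx$protocol)
  expect_equal(nrow(empty$curves), 0)
  expect_true(is.na(empty$selected))

  sc <- scan_m_II(cand, grid = seq(0.4, 1.2, 0.1), protocol = fx$protocol)
  # E_opt rises with m_II: weaker I self-inhibition lets I suppress E more
  expect_true(all(diff(sc$curves$E_opt) > 0))
  expect_false(is.na(sc$selected))
  m_sel <- cand; m_sel$m_II <- sc$selected
  expect_true(check_acceptance(fx$protocol(m_sel))$pass)
  # failing protocol marks the grid point failed, scan continues
  bad <- function(m) if (m$m_II < 0.5) stop("boom") else fx$protocol(m)
  sc2 <- scan_m_II(cand, grid = c(0.4, 1), protocol = bad)
  expect_true(sc2$curves$failed[1])
  expect_false(sc2$curves$failed[2])
})

test_that("step 2 adjusts targets in the stated directions and fixes points", {
  targets <- c(diff_E = 60, diff_I = 120)
  high <- rate_summary(20, 50, 4, 20, 2, 8)
  expect_lt(step2_adjust(high, targets)[["diff_E"]], 60)
  low <- rate_summary(5, 50, 2, 20, 2, 8)
  expect_gt(step2_adjust(low, targets)[["diff_E"]], 60)
  passing <- rate_summary(14.5, 50, 4, 20, 2.5, 9)
  expect_identical(step2_adjust(passing, targets), targets)
})

test_that("the step-1/step-2 loop converges on the mean-field oracle", {
  fx <- make_fixture("two-population-meanfield")
  # full scale with the exact reference: a no-op (all multipliers 1)
  res <- compensate(fx$reference, n = 1, protocol = fx$protocol,
                    targets = fx$diff_targets)
  expect_true(res$converged)
  expect_equal(res$multipliers$m_EE, 1, tolerance = 1e-6)
  expect_equal(res$multipliers$m_EI, 1, tolerance = 1e-6)
  expect_equal(res$rates$E_opt, 14.71, tolerance = 1e-3)

  # +/-30% perturbed initial targets return to the acceptance box in <= 12
  for (f in c(0.7, 1.3)) {
    res <- compensate(fx$reference, n = 2, protocol = fx$protocol,
                      targets = fx$diff_targets * f)
    expect_true(res$converged)
    expect_lte(length(res$history), 12)
    expect_true(res$rates$E_opt > 13 && res$rates$E_opt < 16)
  }
})

test_that("the mean-field fixed point agrees with its linear-solve oracle", {
  fx <- make_fixture("two-population-meanfield")
  for (n in c(1, 2, 4)) {
    m <- multipliers(1.1, 1.2, 1.3, 0.9, 1, scale_n = n)
    r <- fx$protocol(m)
    oracle <- fx$oracle(m, "opt")
    expect_equal(c(r$E_opt, r$I_opt), unname(oracle), tolerance = 1e-8)
  }
})

test_that("step 3 exchanges cortical for LGN excitation of I cells", {
  w <- synaptic_weights()
  expect_identical(step3_exchange(w, 0, list(per_unit_IE = 40,
                                             per_unit_I_LGN = 25)), w)
  w2 <- step3_exchange(w, 0.001, list(per_unit_IE = 40, per_unit_I_LGN = 25))
  expect_equal(w2$S_IE, w$S_IE - 0.001)
  expect_equal(w2$S_I_LGN, w$S_I_LGN + 0.0016)  # 40 * 0.001 = 25 * delta
  expect_error(step3_exchange(w, 1, list(per_unit_IE = 40,
                                         per_unit_I_LGN = 25)), "exceeds")
  r_bad <- rate_summary(14, 50, 4, 20, 1, 6)  # I_bg/E_bg = 6 > 5
  expect_warning(
    step3_exchange(w, 0.001, list(per_unit_IE = 40, per_unit_I_LGN = 25),
                   rates = r_bad),
    "spontaneous")
})

test_that("the printed compensated regimes carry the stated OS values", {
  tb <- table1_multipliers()
  expect_equal(tb$OS, tb$E_opt / tb$E_ortho, tolerance = 0.005)
  expect_equal(table1_row(49)$m_IE, 7.02)
  expect_error(table1_row(5), "printed")
})
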