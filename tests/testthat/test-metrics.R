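test_that("patch rates average spikes over neurons and time", {
  res <- fake_result(spike_t = seq(2.1, 6.9, length.out = 10),
                     spike_id = rep(1L, 10), n = 2)
  pr <- patch_rates(res, 1, window = c(2, 7))
  expect_equal(unname(pr$per_neuron[1]), 2.0)
  expect_equal(pr$E, 2.0)
  both <- patch_rates(res, 1:2, window = c(2, 7))
  expect_equal(both$E, 1.0)  # silent second neuron halves the mean
  expect_error(patch_rates(res, integer(0)), "empty")
  expect_error(patch_rates(res, 1, window = c(2, 10)), "outside")
})

test_that("circular variance hits its analytic extremes and hand value", {
  expect_equal(circular_variance(rep(3, 8)), 1)
  expect_equal(circular_variance(c(5, 0, 0, 0)), 0)
  expect_equal(circular_variance(c(2, 1), angles = c(0, 90)), 2 / 3)
  expect_warning(cv0 <- circular_variance(c(0, 0, 0, 0)), "undefined")
  expect_true(is.na(cv0))
})

test_that("circular variance is invariant to rate scaling and rotation", {
  set.seed(7)
  for (i in 1:25) {
    r <- runif(8)
    a <- seq(0, 157.5, by = 22.5)
    expect_equal(circular_variance(r, a), circular_variance(5.3 * r, a))
    shift <- runif(1, 0, 180)
    expect_equal(circular_variance(r, a), circular_variance(r, a + shift))
  }
})

test_that("modulation ratio reaches its limits and ignores time shifts", {
  set.seed(8)
  # constant-rate train: ratio -> 0
  flat <- sort(runif(4000, 2, 7))
  expect_lt(modulation_ratio(flat, 4, c(2, 7))$ratio, 0.1)
  # r(t) = r0 (1 + cos 2 pi f t): ratio -> 1 (numerical projection oracle)
  r0 <- 400
  sp <- thinned_spikes(function(t) r0 * (1 + cos(2 * pi * 4 * t)),
                       2 * r0, 7)[[1]]
  mr <- modulation_ratio(sp, 4, c(2, 7))
  expect_equal(mr$ratio, 1, tolerance = 0.05)
  expect_true(mr$class %in% c("simple", "complex"))  # boundary case
  # amplitude is invariant to a time shift of the train
  mr2 <- modulation_ratio(sp + 0.033, 4, c(2 + 0.033, 7 + 0.033))
  expect_equal(mr$ratio, mr2$ratio, tolerance = 0.02)
  # degenerate cases
  expect_true(modulation_ratio(numeric(0), 4, c(2, 7))$undefined)
  expect_error(modulation_ratio(flat, 4, c(2, 2.5)), "cycles")
})

test_that("tuning surfaces recover an injected peak exactly", {
  set.seed(9)
  oris <- seq(0, 157.5, by = 22.5)
  sfs <- c(0.5, 1, 2, 3, 4, 6, 8, 10)
  wedges <- list(1:5, 6:10)
  battery <- list()
  for (o in oris) for (f in sfs) {
    rate <- if (o == 45 && f == 2) 40 else 4
    n_sp <- rpois(1, rate * 5 * 5)
    battery[[length(battery) + 1]] <- list(
      stim = grating_stimulus(o, sf = f, tf = 4),
      result = fake_result(runif(n_sp, 2, 7), sample(1:5, n_sp, TRUE), n = 10))
  }
  ts <- tuning_surface(battery, wedges)
  expect_equal(dim(ts$peaks), c(8, 8, 2))
  best <- which(ts$peaks[, , 1] == max(ts$peaks[, , 1]), arr.ind = TRUE)
  expect_equal(ts$orientations[best[1]], 45)
  expect_equal(ts$sfs[best[2]], 2)
  expect_equal(ts$preferred[1], 45)
  expect_true(is.na(ts$preferred[2]))  # silent wedge has no argmax
})

test_that("population spectra: flat for Poisson, peaked for 50 Hz input", {
  fx <- make_fixture("poisson-population", seed = 10)
  gp <- gamma_power(fx$spikes$t, window = c(2, 7))
  expect_false(gp$gamma_present)
  expect_lt(gp$peak_ratio, fx$oracle$expected_peak_ratio + 1.2)

  set.seed(11)
  mod <- thinned_spikes(function(t) 40 * (1 + 0.9 * cos(2 * pi * 50 * t)),
                        80, 7, n = 100)
  sp <- sort(unlist(mod))
  gp2 <- gamma_power(sp, window = c(2, 7))
  expect_true(gp2$gamma_present)
  expect_lt(abs(gp2$peak_freq - 50), 2)
  expect_error(gamma_power(sp, window = c(2, 2.5)), "1 s")
})

test_that("preference histograms are normalized with deterministic ties", {
  set.seed(12)
  oris <- (0:15) * 180 / 16
  n <- 20
  battery <- lapply(oris, function(o) {
    # neurons 1-10 prefer grating 5 (0-based index 4); 11-15 tie 1 vs 2;
    # neurons 16-20 silent
    rate <- if (o == oris[5]) 12 else 2
    sp_t <- runif(rate * 50, 2, 7)
    sp_id <- sample(1:10, length(sp_t), TRUE)
    tie <- if (o %in% oris[1:2]) runif(250, 2, 7) else numeric(0)
    tie_id <- sample(11:15, length(tie), TRUE)
    list(stim = grating_stimulus(o),
         result = fake_result(c(sp_t, tie), c(sp_id, tie_id), n = n))
  })
  ph <- preference_histograms(battery, list(1:10, 11:20, 16:20))
  expect_equal(rowSums(ph$hist[1:2, ]), c(1, 1))
  expect_equal(unname(ph$hist[1, 5]), 1)       # point mass at the driven grating
  expect_equal(unname(ph$n_silent[3]), 5)
  expect_true(all(is.na(ph$hist[3, ])))        # entirely silent wedge
})

test_that("argmax ties break toward the lower grating index", {
  oris <- (0:15) * 180 / 16
  battery <- lapply(oris, function(o) {
    # one spike per grating: perfect 16-way tie
    list(stim = grating_stimulus(o),
         result = fake_result(3.0, 1L, n = 1))
  })
  ph <- preference_histograms(battery, list(1))
  expect_equal(unname(ph$hist[1, 1]), 1)
})

test_that("rate distributions flag bimodality and count silent cells", {
  set.seed(13)
  uni <- fake_result(runif(3000, 2, 7), sample(1:30, 3000, TRUE), n = 30)
  rd <- patch_rates(uni, 1:30)
  out <- rate_distribution(uni, 1:30)
  expect_equal(out$silent_fraction, 0)
  expect_false(out$bimodal)

  # two-point mixture: 15 silent-ish slow cells, 15 fast cells
  fast <- runif(4000, 2, 7)
  mix <- fake_result(fast, sample(16:30, 4000, TRUE), n = 30)
  out2 <- rate_distribution(mix, 1:30)
  expect_equal(out2$silent_fraction, 0.5)
  expect_true(out2$bimodal)
  # CV filter keeps only active cells
  cv <- runif(30)
  out3 <- rate_distribution(mix, 1:30, threshold = 5, cv = cv)
  expect_equal(out3$cv_active, cv[16:30])
})

test_that("bimodality statistic is 0 for degenerate or unimodal samples", {
  expect_equal(bimodality_statistic(rep(3, 50)), 0)
  expect_equal(bimodality_statistic(numeric(0)), 0)
  set.seed(14)
  expect_lt(bimodality_statistic(rnorm(500)), 0.5)
  expect_gt(bimodality_statistic(c(rnorm(300, 0, 0.2), rnorm(300, 10, 0.2))),
            0.9)
})
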