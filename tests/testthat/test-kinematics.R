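# Segmental CoM, differentiation, marker height/excursion statistics.

test_that("segmental CoM handles the elementary cases", {
  n <- 5
  mk <- marker_set(c("top", "bottom"),
                   x = cbind(rep(0, n), rep(0, n)),
                   y = cbind(rep(0, n), rep(0, n)),
                   z = cbind(rep(1, n), rep(0, n)), fs = 100)
  tab1 <- data.frame(segment = "rod", mass_fraction = 1, com_fraction = 0.5,
                     proximal = "top", distal = "bottom")
  com <- segmental_com(mk, tab1)
  expect_equal(com$z, rep(0.5, n))
  expect_equal(com$ap, rep(0, n))
  # two point segments at x = +/- 0.1 balance to zero
  mk2 <- marker_set(c("a", "b"),
                    x = cbind(rep(0.1, n), rep(-0.1, n)),
                    y = cbind(rep(0, n), rep(0, n)),
                    z = cbind(rep(1, n), rep(1, n)), fs = 100)
  tab2 <- data.frame(segment = c("pa", "pb"), mass_fraction = c(0.5, 0.5),
                     com_fraction = 0, proximal = c("a", "b"),
                     distal = c("a", "b"))
  expect_equal(segmental_com(mk2, tab2)$ap, rep(0, n))
  # missing marker names the segment
  expect_error(segmental_com(mk2, tab1), "missing marker.*rod")
  # mass fractions must sum to 1
  tab_bad <- transform(tab2, mass_fraction = c(0.5, 0.6))
  expect_error(segmental_com(mk2, tab_bad), "sum to 1")
})

test_that("segmental CoM recovers the simulator's ground truth", {
  tr0 <- simulate_trial(noiseless_config(duration = 10))
  com0 <- segmental_com(tr0$recording$markers)
  expect_lt(sqrt(mean((com0$ap - tr0$truth_com$ap)^2)), 1e-3)
  expect_lt(sqrt(mean((com0$ml - tr0$truth_com$ml)^2)), 1e-3)
  # with 0.5 mm marker noise the RMS error stays below 2 mm
  trn <- simulate_trial(quick_config(duration = 10, seed = 17,
                                     marker_noise_sd = 5e-4))
  comn <- segmental_com(trn$recording$markers)
  expect_lt(sqrt(mean((comn$ap - trn$truth_com$ap)^2)), 2e-3)
})

test_that("gap interpolation bridges short gaps and rejects long ones", {
  tr <- simulate_trial(noiseless_config(duration = 5))
  mk <- tr$recording$markers
  mk$x[100:106, "c7"] <- NA # 7-sample gap: interpolated
  com <- segmental_com(mk)
  expect_true(all(is.finite(com$ap)))
  mk$x[200:220, "c7"] <- NA # 21-sample gap: error names the marker
  expect_error(segmental_com(mk), "c7.*gap|gap of 21")
})

test_that("com_acceleration matches analytic second derivatives", {
  fs <- 100
  t <- seq(0, 30, by = 1 / fs)
  # single sinusoid, A = 10 mm at 0.4 Hz
  x <- 0.01 * sin(2 * pi * 0.4 * t)
  acc <- com_acceleration(x, fs)
  ref <- -(2 * pi * 0.4)^2 * x
  interior <- 100:(length(t) - 100)
  rel <- sqrt(mean((acc[interior] - ref[interior])^2)) /
    sqrt(mean(ref[interior]^2))
  expect_lt(rel, 0.01)
  # linear ramp: zero at interior samples
  ramp <- com_acceleration(0.05 * t, fs)
  expect_lt(max(abs(ramp[interior])), 1e-6) # IIR rounding x fs^2 only
  # sum of 0.2 / 0.5 / 1.0 Hz sinusoids within 2% RMS
  f3 <- c(0.2, 0.5, 1.0)
  x3 <- rowSums(sapply(f3, function(f) 0.005 * sin(2 * pi * f * t)))
  ref3 <- rowSums(sapply(f3, function(f) {
    -0.005 * (2 * pi * f)^2 * sin(2 * pi * f * t)
  }))
  acc3 <- com_acceleration(x3, fs)
  rel3 <- sqrt(mean((acc3[interior] - ref3[interior])^2)) /
    sqrt(mean(ref3[interior]^2))
  expect_lt(rel3, 0.02)
  expect_error(com_acceleration(c(1, 2, 3), fs), "too short")
})

test_that("acceleration of noiseless simulated truth is recovered by the chain", {
  tr <- simulate_trial(noiseless_config(duration = 10))
  acc <- com_acceleration(tr$truth_com$ap, fs = 100)
  interior <- 50:950
  rel <- sqrt(mean((acc[interior] - tr$truth_com$acc_ap[interior])^2)) /
    sqrt(mean(tr$truth_com$acc_ap[interior]^2))
  expect_lt(rel, 0.02)
})

test_that("marker movement statistics: path length oracle and invariances", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  n <- length(t)
  osc <- 0.001 * sin(2 * pi * 1 * t) # +/- 1 mm at 1 Hz
  mk <- marker_set(c("still", "osc", "high"),
                   x = cbind(rep(0.5, n), osc, 3 * osc),
                   y = matrix(0, n, 3),
                   z = cbind(rep(0.2, n), rep(1.0, n), rep(1.5, n)),
                   fs = fs)
  hm <- marker_height_excursion(mk, "AP")
  expect_equal(hm$movement[1], 0)             # stationary marker
  expect_equal(hm$movement[2], 0.24, tolerance = 1e-3) # 4 mm x 60 cycles
  expect_equal(hm$mean_height, c(0.2, 1.0, 1.5))
  # independent oracle: plain sum of absolute sampled steps
  expect_equal(hm$movement[3], sum(abs(diff(3 * osc))), tolerance = 1e-12)
  # invariance to time reversal and additive offset
  mk_rev <- marker_set(mk$labels, mk$x[n:1, ], mk$y[n:1, ], mk$z[n:1, ], fs)
  expect_equal(marker_height_excursion(mk_rev, "AP")$movement, hm$movement)
  mk_off <- marker_set(mk$labels, mk$x + 0.3, mk$y, mk$z, fs)
  expect_equal(marker_height_excursion(mk_off, "AP")$movement, hm$movement)
  # range option
  hr <- marker_height_excursion(mk, "AP", movement = "range")
  expect_equal(hr$movement[2], 0.002, tolerance = 1e-6)
  # support height shifts heights only
  hs <- marker_height_excursion(mk, "AP", support_height = 0.1)
  expect_equal(hs$mean_height, hm$mean_height - 0.1)
  expect_error(marker_height_excursion(
    marker_set("a", matrix(0, n, 1), matrix(0, n, 1), matrix(1, n, 1), fs),
    "AP"), "at least 3")
})

test_that("rigid-pendulum markers move strictly more the higher they sit", {
  tr <- simulate_trial(noiseless_config(duration = 10))
  hm <- marker_height_excursion(tr$recording$markers, "AP")
  ord <- order(hm$mean_height)
  expect_true(all(diff(hm$movement[ord]) >= -1e-12))
})
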