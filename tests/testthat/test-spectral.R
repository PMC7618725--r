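test_that("a pure tone localises to the nearest grid frequency in the right region", {
  e <- tone_epochs(40, n_regions = 2, tone_regions = 1)
  tfr <- compute_tfr(e, freqs = c(30, 36, 40, 44), n_cycles = 7)
  mid <- which.min(abs(tfr$time - 2))
  prof <- tfr$power[1, 1, , mid]
  expect_equal(which.max(prof), 3L)        # 40 Hz grid point
  expect_equal(max(tfr$power[1, 2, , ]), 0)
})

test_that("all-zero input yields all-zero power", {
  e <- tone_epochs(40, amplitude = 0)
  tfr <- compute_tfr(e, freqs = c(35, 40), n_cycles = 7)
  expect_true(all(tfr$power == 0))
})

test_that("wavelet power scales with the square of signal amplitude", {
  e1 <- tone_epochs(40, amplitude = 1)
  e2 <- tone_epochs(40, amplitude = 2)
  f <- c(38, 40, 42)
  p1 <- compute_tfr(e1, freqs = f, n_cycles = 7)
  p2 <- compute_tfr(e2, freqs = f, n_cycles = 7)
  mid <- which.min(abs(p1$time - 2))
  expect_equal(p2$power[1, 1, 2, mid] / p1$power[1, 1, 2, mid], 4,
               tolerance = 1e-10)
})

test_that("frequencies above Nyquist and oversized wavelets are rejected", {
  e <- tone_epochs(40, fs = 200)
  expect_error(compute_tfr(e, freqs = c(40, 120)), "Nyquist")
  expect_error(compute_tfr(e, freqs = 1, n_cycles = 400), "support")
})

test_that("percent baseline correction matches its closed form", {
  # constant power: corrected value 0 everywhere
  fs <- 10
  ns <- 60
  p <- array(3, c(1, 1, 1, ns))
  tfr <- tfr_obj(p, freqs = 40, fs = fs)
  bc <- baseline_correct(tfr, c(-0.8, -0.1))
  expect_true(all(abs(bc$power) < 1e-12))
  expect_true(bc$corrected)

  # power doubling relative to baseline: corrected value 1
  p2 <- array(3, c(1, 1, 1, ns))
  tt <- -1 + (seq_len(ns) - 1) / fs
  p2[1, 1, 1, tt >= 0] <- 6
  bc2 <- baseline_correct(tfr_obj(p2, 40, fs), c(-0.8, -0.1))
  expect_equal(bc2$power[1, 1, 1, ns], 1)

  # zero baseline power is degenerate
  expect_error(baseline_correct(tfr_obj(array(0, c(1, 1, 1, ns)), 40, fs)),
               "degenerate")
  # window outside epoch
  expect_error(baseline_correct(tfr_obj(p, 40, fs), c(-9, -8)), "outside")
  # double correction is refused
  expect_error(baseline_correct(bc, c(-0.8, -0.1)), "already")
})

test_that("band binning tiles a 6 s epoch into 60 bins and averages indicators", {
  fs <- 20
  ns <- 6 * fs
  bands <- gas_bands("gamma")
  p <- array(0, c(2, 3, 2, ns))
  tfr <- tfr_obj(p, freqs = c(35, 45), fs = fs, corrected = TRUE)
  bp <- band_bin_power(tfr, bands)
  expect_equal(dim(bp$value), c(2, 3, 1, 60))
  expect_equal(range(bp$bin_edges), c(-1, 5))
  expect_true(all(bp$value == 0))

  # block indicator occupying exactly bin 13 appears only in bin 13
  k <- 13
  idx <- ((k - 1) * 2 + 1):(k * 2)  # 2 samples per 100 ms at fs = 20
  p[1, 2, , idx] <- 1
  bp2 <- band_bin_power(tfr_obj(p, c(35, 45), fs, corrected = TRUE), bands)
  expect_equal(bp2$value[1, 2, 1, k], 1)
  expect_equal(sum(bp2$value != 0), 1)

  # linearity in the input
  bp3 <- band_bin_power(tfr_obj(5 * p, c(35, 45), fs, corrected = TRUE), bands)
  expect_equal(bp3$value, 5 * bp2$value)

  # a band with no grid points errors
  expect_error(band_bin_power(tfr_obj(p, c(35, 45), fs), gas_bands("beta")),
               "no frequency grid points")
})

test_that("energy in the 48-52 Hz gap leaks less than 10% into the bands", {
  in_band <- tone_epochs(40, tone_window = c(1, 3))
  gap <- tone_epochs(50, tone_window = c(1, 3))
  freqs <- band_freq_grid(gas_bands("gamma"))
  resp <- function(e) {
    tfr <- compute_tfr(e, freqs = freqs)
    bp <- band_bin_power(tfr, gas_bands("gamma"))
    mean(bp$value[1, 1, 1, 21:30])    # bins centred in 1-2 s
  }
  expect_lt(resp(gap) / resp(in_band), 0.1)
})

test_that("shifting a burst by one bin shifts its binned signature by one bin", {
  fs <- 200
  mk <- function(onset) {
    ns <- round(7 * fs)
    t0 <- -1.5
    tt <- t0 + (seq_len(ns) - 1) / fs
    pk <- gaspread:::burst_packet(tt, onset, 0.4, 40, 1, 0.3)
    data <- array(0, c(1, 1, ns))
    data[1, 1, pk$idx] <- pk$sig
    parcel_epochs(data, fs, t0, "B", "HC", analysis_window = c(-1, 5))
  }
  freqs <- band_freq_grid(gas_bands("gamma"))
  v1 <- band_bin_power(compute_tfr(mk(1.0), freqs), gas_bands("gamma"))$value[1, 1, 1, ]
  v2 <- band_bin_power(compute_tfr(mk(1.1), freqs), gas_bands("gamma"))$value[1, 1, 1, ]
  expect_equal(v2[6:55 + 1], v1[6:55], tolerance = 1e-9)
})

test_that("chunked band power with per-trial baseline matches the sample-level path", {
  cfg <- tiny_sim_config(n_regions = 3, n_trials = 5, seed = 8)
  e <- simulate_participant_epochs(cfg, "HC", seed = 15)
  bands <- gas_bands("gamma")
  freqs <- band_freq_grid(bands)
  direct <- band_bin_power(
    baseline_correct(compute_tfr(e, freqs), c(-0.8, -0.1)), bands)
  chunked <- compute_band_power(e, bands, baseline_stat = "trial",
                                chunk_size = 2)
  expect_equal(chunked$value, direct$value, tolerance = 1e-10)
  expect_equal(chunked$bin_edges, direct$bin_edges)
})

test_that("the trial-averaged baseline statistic removes the single-trial ratio bias", {
  cfg <- tiny_sim_config(n_regions = 2, n_trials = 40,
                         burst_params = silent_bursts(),
                         beta_osc = no_beta_rhythm(), seed = 12)
  e <- simulate_participant_epochs(cfg, "HC", seed = 33)
  avg_of <- function(stat) {
    bp <- compute_band_power(e, gas_bands("gamma"), baseline_stat = stat,
                             chunk_size = 40)
    v <- collapse_trials(bp)$value[1, , 1, ]
    mean(v[, 11:60])            # bins after the baseline window
  }
  expect_gt(avg_of("trial"), 0.1)       # noisy denominator biases upward
  expect_lt(abs(avg_of("average")), 0.1)
})
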