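test_that("epoch simulation is deterministic and respects the configured grid", {
  cfg <- tiny_sim_config(seed = 7)
  e1 <- simulate_participant_epochs(cfg, "HC", seed = 11, participant_id = "HC01")
  e2 <- simulate_participant_epochs(cfg, "HC", seed = 11, participant_id = "HC01")
  e3 <- simulate_participant_epochs(cfg, "HC", seed = 12, participant_id = "HC02")
  expect_identical(e1$data, e2$data)
  expect_false(identical(e1$data, e3$data))

  d <- dim(e1$data)
  expect_equal(d[1], cfg$n_trials)
  expect_equal(d[2], cfg$n_regions)
  expect_equal(d[3], round((diff(cfg$epoch_window) + 2 * cfg$pad) * cfg$fs))
  expect_true(all(is.finite(e1$data)))
  expect_equal(e1$t0, cfg$epoch_window[1] - cfg$pad)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(tiny_sim_config(fs = 100), "Nyquist")
  expect_error(tiny_sim_config(epoch_window = c(-1, 2)), "tonic")
  expect_error(simulate_participant_epochs(tiny_sim_config(), "patient"))
  bp <- default_burst_params()
  bp$gamma$HC$duration_mean <- -1
  expect_error(tiny_sim_config(burst_params = bp), "positive")
})

test_that("zero-amplitude bursts leave the signal statistically stationary", {
  cfg <- tiny_sim_config(n_regions = 4, n_trials = 10,
                         burst_params = silent_bursts(),
                         beta_osc = no_beta_rhythm(), seed = 5)
  e <- simulate_participant_epochs(cfg, "ALS", seed = 21)
  tt <- e$t0 + (seq_len(dim(e$data)[3]) - 1) / e$fs
  sd_tonic <- sd(e$data[, , tt >= 1 & tt < 3])
  sd_base <- sd(e$data[, , tt >= -1 & tt < 0])
  expect_lt(abs(sd_tonic / sd_base - 1), 0.1)
})

test_that("simulated gamma bursts concentrate their power inside 30-48 Hz", {
  fs <- 250
  tt <- seq(0, 2, by = 1 / fs)
  set.seed(31)
  fracs <- replicate(20, {
    f0 <- runif(1, 32, 46)        # band minus the default 2 Hz margin
    pk <- gaspread:::burst_packet(tt, 0.5, 0.5, f0, 1, runif(1, 0, 2 * pi))
    x <- numeric(length(tt)); x[pk$idx] <- pk$sig
    sp <- Mod(fft(x))^2
    fr <- (seq_along(sp) - 1) / length(sp) * fs
    half <- fr <= fs / 2
    sum(sp[half & fr >= 30 & fr <= 48]) / sum(sp[half])
  })
  expect_true(all(fracs >= 0.8))
})

test_that("ALS group draws more active gamma regions than HC (generator truth)", {
  cfg <- tiny_sim_config(n_regions = 52, n_trials = 20, seed = 9)
  hc <- attr(simulate_participant_epochs(cfg, "HC", seed = 101), "truth")
  als <- attr(simulate_participant_epochs(cfg, "ALS", seed = 102), "truth")
  expect_gt(mean(als$gamma$n_active), mean(hc$gamma$n_active) + 5)
})

test_that("clinical table enforces the progression-rate identity and marginals", {
  cfg <- sim_config(n_hc = 10, n_als = 200, seed = 3)
  set.seed(991)
  latent <- rnorm(200, 20, 4)
  cl <- simulate_clinical_table(cfg, latent, seed = 41)
  als <- cl[cl$group == "ALS", ]
  expect_equal(als$progression_rate,
               (48 - als$ALSFRS_R) / als$symptom_duration, tolerance = 1e-12)
  expect_true(all(als$ALSFRS_R >= 0 & als$ALSFRS_R <= 48))
  expect_true(all(als$symptom_duration > 0))
  expect_true(all(cl$sex %in% c("F", "M")))
  expect_true(all(is.na(cl$ALSFRS_R[cl$group == "HC"])))
  # planted slope links latent spread to progression rate
  expect_gt(cor(latent, als$progression_rate), 0.2)
})

test_that("a zero progression slope leaves no latent-spread association", {
  cfg <- sim_config(n_hc = 0, n_als = 300, gas_progression_slope = 0, seed = 3)
  set.seed(992)
  latent <- rnorm(300, 20, 4)
  cl <- simulate_clinical_table(cfg, latent, seed = 43)
  r <- cor(latent, cl$progression_rate[cl$group == "ALS"])
  expect_lt(abs(r), 3 / sqrt(300) + 0.05)
})

test_that("degenerate clinical configurations error", {
  cfg <- tiny_sim_config()
  cfg$gas_progression_slope <- Inf
  expect_error(simulate_clinical_table(cfg, rnorm(4)), "finite")
  cfg2 <- sim_config(n_hc = 0, n_als = 5)
  expect_error(simulate_clinical_table(cfg2, numeric(0)), "empty")
})

test_that("behavioural metrics share distributions across groups by default", {
  cfg <- sim_config(n_hc = 33, n_als = 42, seed = 1)
  b <- simulate_behavior_table(cfg, seed = 10)
  expect_setequal(unique(b$group), c("HC", "ALS"))
  expect_true(all(b$accuracy > 0 & b$accuracy <= 1))
  expect_true(all(b$grip_length > 0 & b$grip_strength > 0 & b$reaction_time > 0))

  # grip target is 12 N
  big <- simulate_behavior_table(sim_config(n_hc = 1000, n_als = 1000, seed = 2),
                                 seed = 11)
  expect_lt(abs(mean(big$grip_strength) - 12), 0.3)

  # identical per-group seeds with equal sizes give literal copies (t = 0)
  cfg_eq <- sim_config(n_hc = 20, n_als = 20, seed = 4)
  beq <- simulate_behavior_table(cfg_eq, group_seeds = c(5, 5))
  w <- welch_from_summaries(
    mean(beq$grip_length[beq$group == "ALS"]),
    sd(beq$grip_length[beq$group == "ALS"]), 20,
    mean(beq$grip_length[beq$group == "HC"]),
    sd(beq$grip_length[beq$group == "HC"]), 20)
  expect_equal(w$t, 0)
})

test_that("null behaviour cohorts rarely show Bonferroni-significant differences", {
  sig <- vapply(1:50, function(s) {
    cfg <- sim_config(n_hc = 33, n_als = 42, seed = s)
    res <- compare_behavior(simulate_behavior_table(cfg, seed = s))
    any(res$p_bonferroni < 0.05)
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("cohort simulation wires latent gamma spread into the clinical table", {
  cfg <- tiny_sim_config(n_hc = 2, n_als = 3, n_trials = 2, seed = 6)
  co <- simulate_cohort(cfg)
  expect_length(co$epochs, 5)
  expect_equal(length(co$latent_spread), 3)
  expect_equal(nrow(co$clinical), 5)
  expect_identical(names(co$epochs), co$clinical$participant_id)
  # reproducible end to end
  co2 <- simulate_cohort(cfg)
  expect_identical(co$epochs[[1]]$data, co2$epochs[[1]]$data)
  expect_identical(co$clinical, co2$clinical)
})
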