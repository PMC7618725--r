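make_clin <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(group = rep(c("HC", "ALS"), length.out = n),
             age = rnorm(n, 60, 12),
             sex = sample(c("F", "M"), n, replace = TRUE),
             missing_mri = rbinom(n, 1, 0.15))
}

test_that("confounds that are constant or collinear with the design are dropped", {
  tbl <- data.frame(group = rep(c("HC", "ALS"), each = 3),
                    age = c(50, 60, 70, 55, 65, 75),
                    sex = c("M", "M", "M", "F", "F", "F"),  # aliased with group
                    missing_mri = 0)                          # constant
  expect_message(des <- build_design(tbl, "group"), "collinear")
  expect_setequal(des$dropped, c("sex", "missing_mri"))
  expect_equal(colnames(des$X), c("(Intercept)", "group", "age"))
  expect_equal(sum(des$contrast), 1)
})

test_that("OLS contrast t statistics behave like Student t under the null", {
  tbl <- make_clin(75, seed = 2)
  des <- quiet_design(tbl, "group")
  set.seed(3)
  Y <- matrix(rnorm(75 * 1000), 75, 1000)
  fit <- fit_glm(Y, des$X, des$contrast)
  expect_equal(fit$df, 75 - ncol(des$X))
  ks <- suppressWarnings(ks.test(fit$t, function(q) pt(q, fit$df)))
  expect_gt(ks$p.value, 0.01)
})

test_that("location shifts move only the intercept, and perfect fits are capped", {
  tbl <- make_clin(30, seed = 4)
  des <- quiet_design(tbl, "group")
  set.seed(5)
  y <- rnorm(30)
  f1 <- fit_glm(y, des$X, des$contrast)
  f2 <- fit_glm(y + 100, des$X, des$contrast)
  expect_equal(f1$t, f2$t, tolerance = 1e-8)
  expect_equal(unname(f2$beta["(Intercept)", 1] - f1$beta["(Intercept)", 1]),
               100, tolerance = 1e-8)

  # outcome exactly equal to the group indicator: capped, flagged
  X <- cbind(1, rep(0:1, each = 15))
  fperf <- fit_glm(X[, 2], X, c(0, 1))
  expect_true(fperf$capped[1])
  expect_true(is.finite(fperf$t[1]))

  expect_error(fit_glm(y, cbind(1, tbl$age, tbl$age), c(0, 1, 0)),
               "rank deficient")
  expect_error(fit_glm(y[1:2], cbind(1, c(0, 1)), c(0, 1)), "not enough")
})

test_that("sampled permutation p values agree with exhaustive enumeration", {
  n <- 7
  set.seed(6)
  tbl <- data.frame(group = c("HC", "ALS", "HC", "ALS", "HC", "ALS", "ALS"),
                    age = rnorm(n, 60, 10))
  Y <- matrix(rnorm(n * 3), n, 3) +
    outer(as.numeric(tbl$group == "ALS"), c(2, 0, 0.8))
  des <- quiet_design(tbl, "group", confounds = "age")
  ex <- permutation_test(Y, des$X, des$contrast, seed = 1)
  expect_true(attr(ex, "exhaustive"))
  expect_equal(attr(ex, "n_perm"), factorial(n))
  mc <- permutation_test(Y, des$X, des$contrast, n_perm = 4000, seed = 2,
                         max_exhaustive = 0)
  expect_false(attr(mc, "exhaustive"))
  se <- sqrt(ex$p_uncorrected * (1 - ex$p_uncorrected) / 4000)
  expect_true(all(abs(mc$p_uncorrected - ex$p_uncorrected) <= 2 * se + 1e-3))
})

test_that("permutation p values are reproducible, bounded and affine invariant", {
  tbl <- make_clin(20, seed = 7)
  des <- quiet_design(tbl, "group")
  set.seed(8)
  Y <- matrix(rnorm(20 * 6), 20, 6)
  r1 <- permutation_test(Y, des$X, des$contrast, n_perm = 300, seed = 9,
                         max_exhaustive = 0)
  r2 <- permutation_test(Y, des$X, des$contrast, n_perm = 300, seed = 9,
                         max_exhaustive = 0)
  expect_identical(r1$p_uncorrected, r2$p_uncorrected)
  expect_true(all(r1$p_fwe >= r1$p_uncorrected))
  expect_true(all(r1$p_uncorrected >= 1 / 301))
  expect_true(all(r1$p_fwe <= 1))

  # affine rescaling of the outcome leaves t and p unchanged
  r3 <- permutation_test(3 * Y - 2, des$X, des$contrast, n_perm = 300,
                         seed = 9, max_exhaustive = 0)
  expect_equal(r3$t, r1$t, tolerance = 1e-10)
  expect_identical(r3$p_uncorrected, r1$p_uncorrected)

  # a constant outcome gives t = 0 and p = 1
  rc <- permutation_test(rep(4, 20), des$X, des$contrast, n_perm = 200,
                         seed = 1, max_exhaustive = 0)
  expect_equal(rc$t, 0)
  expect_equal(rc$p_uncorrected, 1)

  expect_error(permutation_test(Y, des$X, c(0, 1, 1, 0, 0)[seq_len(ncol(des$X))],
                                n_perm = 200),
               "exactly one")
})

test_that("label permutation is available as an alternative scheme", {
  tbl <- make_clin(16, seed = 10)
  des <- quiet_design(tbl, "group")
  set.seed(11)
  y <- rnorm(16) + 2 * as.numeric(tbl$group == "ALS")
  r <- permutation_test(y, des$X, des$contrast, n_perm = 500, seed = 3,
                        method = "label", max_exhaustive = 0)
  expect_lt(r$p_uncorrected, 0.05)
})

test_that("group contrasts localise a planted tonic-window spread excess", {
  nb <- 60
  centers <- -1 + 0.1 * (1:nb - 0.5)
  mk <- function(id, group, seed) {
    set.seed(seed)
    a <- matrix(rnorm(nb, 5, 0.8), 1, nb)
    if (group == "ALS") a[1, centers >= 1 & centers <= 3] <-
        a[1, centers >= 1 & centers <= 3] + 8
    spread_obj(pmax(a, 0), band_names = "gamma", id = id, group = group)
  }
  spreads <- c(lapply(1:8, function(i) mk(sprintf("HC%02d", i), "HC", i)),
               lapply(1:8, function(i) mk(sprintf("ALS%02d", i), "ALS", 100 + i)))
  clin <- make_clin(16, seed = 12)
  clin$group <- vapply(spreads, `[[`, character(1), "group")
  clin$participant_id <- vapply(spreads, `[[`, character(1), "participant_id")
  res <- suppressMessages(group_contrast_spread(spreads, clin, n_perm = 400,
                                                seed = 5))
  act <- res[res$measure == "activated", ]
  sig <- act[act$p_fwe < 0.05, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$bin_center >= 1 & sig$bin_center <= 3))
  expect_lt(res$p_fwe[res$measure == "gas"], 0.05)

  # shuffled labels leave detections at chance level
  clin_sh <- clin
  set.seed(13)
  clin_sh$group <- sample(clin_sh$group)
  for (i in seq_along(spreads)) spreads[[i]]$group <- clin_sh$group[i]
  res_sh <- suppressMessages(group_contrast_spread(spreads, clin_sh,
                                                   n_perm = 400, seed = 5))
  expect_lte(sum(res_sh$p_fwe < 0.05), 2)

  # a deactivation planted lower in ALS mirrors as a negative t
  spreads2 <- lapply(spreads, function(s) {
    s$group <- clin$group[match(s$participant_id, clin$participant_id)]
    s
  })
  for (i in seq_along(spreads2)) {
    s <- spreads2[[i]]
    base <- matrix(8, 1, nb)
    if (s$group == "ALS") base[1, centers >= 1 & centers <= 3] <- 3
    set.seed(300 + i)
    s$deactivated <- pmax(base + matrix(rnorm(nb, 0, 0.5), 1, nb), 0)
    rownames(s$deactivated) <- "gamma"
    spreads2[[i]] <- s
  }
  res2 <- suppressMessages(group_contrast_spread(spreads2, clin, n_perm = 400,
                                                 seed = 6))
  deact <- res2[res2$measure == "deactivated", ]
  sig2 <- deact[deact$p_fwe < 0.05, ]
  expect_gt(nrow(sig2), 0)
  expect_true(all(sig2$t < 0))
})

test_that("clinical association recovers a planted slope and rejects degenerate input", {
  cfg <- sim_config(n_hc = 0, n_als = 200, gas_progression_slope = 0.5,
                    progression_noise_sd = 0.1, seed = 1)
  for (s in 1:5) {
    set.seed(substream_seed(s, 500))
    latent <- rnorm(200, 20, 4)
    cl <- simulate_clinical_table(cfg, latent, seed = substream_seed(s, 501))
    als <- cl[cl$group == "ALS", ]
    r <- clinical_association(latent, als, "progression_rate",
                              n_perm = 499, seed = s)
    expect_gt(r$beta, 0)
    expect_lt(r$p_uncorrected, 0.05)
  }
  expect_error(clinical_association(rep(3, 200), als, "progression_rate"),
               "constant")
  als2 <- als
  als2$progression_rate <- 1
  expect_error(clinical_association(latent, als2, "progression_rate"),
               "constant")
  expect_warning(
    clinical_association(latent[1:8], als[1:8, ], "progression_rate",
                         n_perm = 100, seed = 1),
    "fewer than 10")
})
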