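#' Morlet wavelet time-frequency power
#'
#' Complex Morlet wavelet decomposition of parcellated epochs, returning
#' linear power (squared magnitude, arbitrary units) per trial x region x
#' frequency x time sample. Cycle counts default to `f/2` clipped to
#' `[4, 12]`. The transform is computed on the padded signal (real padding
#' generated by the simulator when available, reflection padding otherwise)
#' and trimmed to the analysis window, so wavelet edge artifacts never reach
#' the output.
#'
#' @param epochs a [parcel_epochs()] object.
#' @param freqs frequency grid in Hz (default [band_freq_grid()] over all
#'   three canonical bands); all must lie below Nyquist.
#' @param n_cycles wavelet cycles per frequency (scalar or vector).
#' @param window analysis window (s) of the output; defaults to the epochs'
#'   `analysis_window`.
#' @param pad margin (s) of signal required beyond each window edge during
#'   filtering.
#' @return object of class `tfr_power`: list with `power`
#'   (`trials x regions x freqs x times`), `freqs`, `time`, `fs`,
#'   `corrected = FALSE`.
#' @export
compute_tfr <- function(epochs, freqs = band_freq_grid(),
                        n_cycles = NULL, window = NULL, pad = 0.5) {
  stopifnot(inherits(epochs, "parcel_epochs"))
  fs <- epochs$fs
  if (max(freqs) >= fs / 2) {
    stop(sprintf("max frequency %g Hz is at or above Nyquist (%g Hz)",
                 max(freqs), fs / 2))
  }
  if (any(!is.finite(epochs$data))) stop("epochs contain non-finite values")
  n_cycles <- n_cycles %||% default_n_cycles(freqs)
  if (length(n_cycles) == 1) n_cycles <- rep(n_cycles, length(freqs))
  stopifnot(length(n_cycles) == length(freqs))

  w <- window %||% epochs$analysis_window
  d <- dim(epochs$data)
  nt <- d[1]; nr <- d[2]; ns <- d[3]
  tt <- epoch_times(epochs)
  idx <- which(tt >= w[1] - 1e-9 & tt < w[2] - 1e-9)
  if (!length(idx)) stop("analysis window lies outside the epoch")

  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = ns)

  # ensure `pad` seconds of margin around the analysis window, reflecting
  # the signal where real padding is unavailable
  np <- round(pad * fs)
  need_l <- max(0L, np - (idx[1] - 1L))
  need_r <- max(0L, np - (ns - idx[length(idx)]))
  if (need_l > 0) X <- rbind(X[(need_l + 1L):2L, , drop = FALSE], X)
  if (need_r > 0) {
    n0 <- nrow(X)
    X <- rbind(X, X[(n0 - 1L):(n0 - need_r), , drop = FALSE])
  }
  idx <- idx + need_l
  n <- nrow(X)

  Xf <- stats::mvfft(X)
  nf <- length(freqs)
  n_out <- length(idx)
  power <- array(NA_real_, c(nt, nr, nf, n_out))
  for (fi in seq_len(nf)) {
    k <- morlet_kernel(freqs[fi], n_cycles[fi], fs)
    half <- (length(k) - 1L) / 2L
    if (length(k) > n) {
      stop(sprintf("wavelet support at %g Hz (%d samples) exceeds the padded epoch (%d samples)",
                   freqs[fi], length(k), n))
    }
    kfull <- complex(length.out = n)
    kfull[1:(half + 1L)] <- k[(half + 1L):length(k)]
    if (half > 0) kfull[(n - half + 1L):n] <- k[1:half]
    Y <- stats::mvfft(Xf * stats::fft(kfull), inverse = TRUE) / n
    P <- Mod(Y[idx, , drop = FALSE])^2
    power[, , fi, ] <- aperm(array(P, c(n_out, nt, nr)), c(2, 3, 1))
  }

  structure(
    list(power = power, freqs = freqs,
         time = tt[idx - need_l], fs = fs, corrected = FALSE,
         participant_id = epochs$participant_id, group = epochs$group),
    class = "tfr_power"
  )
}

# Unit-energy complex Morlet kernel.
morlet_kernel <- function(f, n_cycles, fs) {
  sd_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sd_t * fs)
  tk <- (-half:half) / fs
  env <- exp(-tk^2 / (2 * sd_t^2))
  (env * exp(2i * pi * f * tk)) / sqrt(sum(env^2))
}

#' Baseline-correct time-frequency power
#'
#' Per-trial, per-region, per-frequency correction against the mean power in
#' a pre-trigger baseline window. The tested default is percent change,
#' `(P - mu_b) / mu_b`; subtractive and dB modes are available.
#'
#' @param tfr a `tfr_power` object with raw (uncorrected) power.
#' @param baseline_window seconds pair inside the epoch, interpreted as the
#'   half-open interval `[b0, b1)`; the default -0.8 to -0.1 s avoids both
#'   the epoch edge and anticipatory activity.
#' @param mode `"percent"` (default), `"subtract"` or `"db"`.
#' @return the `tfr_power` object with corrected power,
#'   `corrected = TRUE` and the baseline metadata attached.
#' @export
baseline_correct <- function(tfr, baseline_window = c(-0.8, -0.1),
                             mode = c("percent", "subtract", "db")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tfr, "tfr_power"))
  if (isTRUE(tfr$corrected)) stop("power is already baseline-corrected")
  # half-open window [b0, b1): the sample set equals the union of the whole
  # 100 ms bins tiling the window, so sample-level and binned corrections
  # agree exactly
  bidx <- tfr$time >= baseline_window[1] - 1e-9 &
    tfr$time < baseline_window[2] - 1e-9
  if (!any(bidx)) stop("baseline window lies outside the epoch")
  d <- dim(tfr$power)
  Pb <- tfr$power[, , , bidx, drop = FALSE]
  mu <- array(rowMeans(matrix(Pb, nrow = prod(d[1:3]))), d[1:3])
  if (mode != "subtract") {
    if (any(!is.finite(mu)) || any(mu <= 0) ||
        min(mu) < 1e-12 * max(mu, 1e-300)) {
      stop("degenerate baseline: mean power is zero or near zero for some region x frequency")
    }
  }
  tfr$power <- switch(mode,
    percent  = tfr$power / c(mu) - 1,
    subtract = tfr$power - c(mu),
    db       = 10 * log10(tfr$power / c(mu))
  )
  tfr$corrected <- TRUE
  tfr$baseline_window <- baseline_window
  tfr$baseline_mode <- mode
  tfr
}

#' Reduce time-frequency power to band power in time bins
#'
#' Averages power over the frequency grid points of each band (band edges
#' inclusive) and over the samples of consecutive fixed-width time bins
#' (default 100 ms) tiling the epoch.
#'
#' @param tfr a `tfr_power` object (normally baseline-corrected).
#' @param bands band list from [gas_bands()].
#' @param bin_width bin width in seconds; must tile the epoch exactly.
#' @return object of class `band_power`: list with `value`
#'   (`trials x regions x bands x bins`), `band_names`, `bin_edges`,
#'   `baseline_window`, `corrected`.
#' @export
band_bin_power <- function(tfr, bands = gas_bands(), bin_width = 0.1) {
  stopifnot(inherits(tfr, "tfr_power"))
  d <- dim(tfr$power)
  nt <- d[1]; nr <- d[2]; n_s <- d[4]
  spb <- round(bin_width * tfr$fs)
  if (abs(spb - bin_width * tfr$fs) > 1e-6 || spb < 1) {
    stop("bin grid is not aligned to the sampling grid")
  }
  nb <- n_s %/% spb
  if (nb * spb != n_s) stop("bin width does not tile the epoch exactly")
  t_start <- tfr$time[1]
  bin_edges <- t_start + (0:nb) * bin_width

  value <- array(NA_real_, c(nt, nr, length(bands), nb))
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    fidx <- which(tfr$freqs >= b$f_lo - 1e-9 & tfr$freqs <= b$f_hi + 1e-9)
    if (!length(fidx)) {
      stop(sprintf("band %s has no frequency grid points", b$name))
    }
    Pf <- tfr$power[, , fidx, , drop = FALSE]
    # mean over band frequencies
    Pa <- aperm(Pf, c(3, 1, 2, 4))
    bm <- array(colMeans(matrix(Pa, nrow = length(fidx))), c(nt, nr, n_s))
    # mean over samples within each bin
    m <- array(matrix(bm, nrow = nt * nr), c(nt * nr, spb, nb))
    binned <- colMeans(aperm(m, c(2, 1, 3)))     # (trials*regions) x bins
    value[, , bi, ] <- array(binned, c(nt, nr, nb))
  }

  structure(
    list(value = value,
         band_names = vapply(bands, `[[`, character(1), "name"),
         bin_edges = bin_edges,
         baseline_window = tfr$baseline_window %||% NULL,
         corrected = isTRUE(tfr$corrected),
         participant_id = tfr$participant_id, group = tfr$group),
    class = "band_power"
  )
}

#' Band power straight from epochs, trial-chunked
#'
#' Composition of [compute_tfr()], baseline correction and band/bin
#' reduction that processes trials in chunks, so the full time-frequency
#' array for a 120-trial participant never has to be held in memory at
#' once. Raw per-frequency power is first averaged within each time bin;
#' because the baseline statistic is constant within a trial x region x
#' frequency, correcting the binned values is algebraically identical to
#' binning sample-level corrected power (the baseline window must align
#' with the bin grid).
#'
#' `baseline_stat` chooses the denominator of the percent change:
#' `"average"` (default) uses each region x frequency's baseline mean
#' pooled over all trials, which stabilises the ratio (a 0.7 s single-trial
#' baseline estimate is noisy enough to bias every out-of-baseline bin
#' upward); `"trial"` uses each trial's own baseline mean, matching
#' [baseline_correct()] exactly.
#'
#' @inheritParams compute_tfr
#' @inheritParams band_bin_power
#' @param baseline_window seconds pair; must be tiled by whole bins.
#' @param mode `"percent"`, `"subtract"` or `"db"`.
#' @param baseline_stat `"average"` or `"trial"` (see Details).
#' @param freq_step wavelet grid pitch in Hz.
#' @param chunk_size trials per chunk.
#' @return a `band_power` object.
#' @export
compute_band_power <- function(epochs, bands = gas_bands(), freq_step = 2,
                               n_cycles = NULL,
                               baseline_window = c(-0.8, -0.1),
                               mode = "percent",
                               baseline_stat = c("average", "trial"),
                               bin_width = 0.1,
                               chunk_size = 16, pad = 0.5, window = NULL) {
  baseline_stat <- match.arg(baseline_stat)
  mode <- match.arg(mode, c("percent", "subtract", "db"))
  freqs <- band_freq_grid(bands, step = freq_step)
  nt <- dim(epochs$data)[1]
  chunks <- split(seq_len(nt), ceiling(seq_len(nt) / chunk_size))

  raw <- NULL  # trials x regions x freqs x bins, uncorrected
  bin_edges <- NULL
  for (tr in chunks) {
    sub <- epochs
    sub$data <- epochs$data[tr, , , drop = FALSE]
    tfr <- compute_tfr(sub, freqs = freqs, n_cycles = n_cycles,
                       window = window, pad = pad)
    spb <- round(bin_width * tfr$fs)
    if (abs(spb - bin_width * tfr$fs) > 1e-6 || spb < 1) {
      stop("bin grid is not aligned to the sampling grid")
    }
    d <- dim(tfr$power)
    nb <- d[4] %/% spb
    if (nb * spb != d[4]) stop("bin width does not tile the epoch exactly")
    m <- array(matrix(tfr$power, nrow = prod(d[1:3])), c(prod(d[1:3]), spb, nb))
    binned <- array(colMeans(aperm(m, c(2, 1, 3))), c(d[1:3], nb))
    if (is.null(raw)) {
      raw <- array(NA_real_, c(nt, d[2], d[3], nb))
      bin_edges <- tfr$time[1] + (0:nb) * bin_width
    }
    raw[tr, , , ] <- binned
  }

  # baseline bins: those lying fully inside the baseline window
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  bbin <- which(lo >= baseline_window[1] - 1e-9 & hi <= baseline_window[2] + 1e-9)
  if (!length(bbin)) stop("baseline window contains no whole time bin")
  d <- dim(raw)
  mu_trial <- array(rowMeans(matrix(raw[, , , bbin, drop = FALSE],
                                    nrow = prod(d[1:3]))), d[1:3])
  mu <- if (baseline_stat == "average") {
    # pooled over trials, broadcast back to trials
    aperm(array(colMeans(matrix(mu_trial, nrow = d[1])), c(d[2], d[3], d[1])),
          c(3, 1, 2))
  } else {
    mu_trial
  }
  if (mode != "subtract" && (any(!is.finite(mu)) || any(mu <= 0))) {
    stop("degenerate baseline: mean power is zero for some region x frequency")
  }
  corr <- switch(mode,
    percent  = raw / c(mu) - 1,
    subtract = raw - c(mu),
    db       = 10 * log10(raw / c(mu))
  )

  # average over each band's frequency grid points
  value <- array(NA_real_, c(d[1], d[2], length(bands), d[4]))
  for (bi in seq_along(bands)) {
    b <- bands[[bi]]
    fidx <- which(freqs >= b$f_lo - 1e-9 & freqs <= b$f_hi + 1e-9)
    if (!length(fidx)) stop(sprintf("band %s has no frequency grid points", b$name))
    Pa <- aperm(corr[, , fidx, , drop = FALSE], c(3, 1, 2, 4))
    value[, , bi, ] <- array(colMeans(matrix(Pa, nrow = length(fidx))),
                             c(d[1], d[2], d[4]))
  }

  structure(
    list(value = value,
         band_names = vapply(bands, `[[`, character(1), "name"),
         bin_edges = bin_edges,
         baseline_window = baseline_window,
         baseline_stat = baseline_stat,
         corrected = TRUE,
         participant_id = epochs$participant_id, group = epochs$group),
    class = "band_power"
  )
}

#' Average band power over trials
#'
#' @param bp a `band_power` object.
#' @return a `band_power` object with a single (trial-averaged) trial.
#' @export
collapse_trials <- function(bp) {
  stopifnot(inherits(bp, "band_power"))
  d <- dim(bp$value)
  avg <- colMeans(matrix(bp$value, nrow = d[1]))
  bp$value <- array(avg, c(1L, d[2], d[3], d[4]))
  bp
}
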