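#' Construct a parcel epochs object
#'
#' Container for one participant's parcellated source-space epochs: a
#' trials x regions x samples array with sampling rate and timing metadata.
#'
#' @param data numeric array `trials x regions x samples`.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample relative to the trigger (s).
#' @param participant_id character id.
#' @param group `"HC"` or `"ALS"`.
#' @param analysis_window epoch limits (s) intended for analysis; samples
#'   outside it are padding available to the time-frequency transform.
#' @return object of class `parcel_epochs`.
#' @export
parcel_epochs <- function(data, fs, t0, participant_id = "P01",
                          group = c("HC", "ALS"), analysis_window = NULL) {
  group <- match.arg(group)
  stopifnot(is.array(data), length(dim(data)) == 3, fs > 0)
  if (any(!is.finite(data))) stop("epoch data contain non-finite values")
  structure(
    list(data = data, fs = fs, t0 = t0, participant_id = participant_id,
         group = group,
         analysis_window = analysis_window %||% c(t0, t0 + dim(data)[3] / fs)),
    class = "parcel_epochs"
  )
}

#' @export
print.parcel_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<parcel_epochs> %s (%s): %d trials x %d regions x %d samples @ %g Hz, t0 = %g s\n",
    x$participant_id, x$group, d[1], d[2], d[3], x$fs, x$t0))
  invisible(x)
}

# Sample times relative to the trigger.
epoch_times <- function(x) x$t0 + (seq_len(dim(x$data)[3]) - 1) / x$fs

# 1/f-shaped Gaussian noise (power spectral slope -1), one column per
# independent channel, each column rescaled to the target SD.
noise_1f <- function(n, ncol, fs, sd) {
  if (sd == 0) return(matrix(0, n, ncol))
  w <- matrix(stats::rnorm(n * ncol), n, ncol)
  f <- c(0, seq_len(n - 1)) / n * fs
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, 1))                 # flat below 1 Hz, 1/f power above
  g[1] <- 0                                 # zero mean
  x <- Re(stats::mvfft(stats::mvfft(w) * g, inverse = TRUE)) / n
  s <- sqrt(colMeans(x^2))
  sweep(x, 2, ifelse(s > 0, s / sd, 1), "/")
}

# A single Hann-windowed sinusoid packet sampled at times tt (s).
burst_packet <- function(tt, onset, duration, freq, amplitude, phase) {
  idx <- which(tt >= onset & tt < onset + duration)
  if (!length(idx)) return(list(idx = integer(0), sig = numeric(0)))
  sig <- amplitude * hann_window(length(idx)) *
    sin(2 * pi * freq * (tt[idx] - onset) + phase)
  list(idx = idx, sig = sig)
}

#' Simulate one participant's parcellated epochs
#'
#' Generates 1/f background noise per region plus band-limited oscillatory
#' structure: an ongoing beta rhythm in a set of motor parcels that
#' desynchronises (amplitude drop) during the movement window, and gamma /
#' high-gamma Hann-windowed sinusoid bursts confined to the tonic grip
#' window in a per-trial random subset of regions. Group differences enter
#' only through `config$burst_params`: the ALS group draws more active
#' regions and longer durations.
#'
#' Epochs are generated with `config$pad` seconds of real signal beyond each
#' epoch edge so downstream filtering can trim edge artifacts.
#'
#' @param config a [sim_config()] object.
#' @param group `"HC"` or `"ALS"`.
#' @param seed integer seed for this participant's RNG stream (see
#'   [substream_seed()]).
#' @param participant_id character id stored in the result.
#' @return a [parcel_epochs()] object; attribute `"truth"` records, per band,
#'   the participant-level expected number of active regions
#'   (`n_active_mean`), the per-trial active region sets (`active_regions`)
#'   and per-trial counts (`n_active`).
#' @export
simulate_participant_epochs <- function(config, group = c("HC", "ALS"),
                                        seed = config$seed,
                                        participant_id = NULL) {
  group <- match.arg(group)
  validate_sim_config(config)
  bands <- gas_bands()
  w <- config$epoch_window
  pad <- config$pad
  fs <- config$fs
  nt <- config$n_trials
  nr <- config$n_regions
  ns <- round((diff(w) + 2 * pad) * fs)
  t0 <- w[1] - pad
  tt <- t0 + (seq_len(ns) - 1) / fs

  truth <- list()
  data <- with_seed(seed, {
    # background: independent 1/f noise per trial x region
    x <- noise_1f(ns, nt * nr, fs, config$noise_sd)
    arr <- aperm(array(x, c(ns, nt, nr)), c(2, 3, 1))

    # ongoing beta rhythm with movement-related desynchronisation
    bo <- config$beta_osc
    if (!is.null(bo) && bo$amplitude > 0 && bo$n_regions > 0) {
      motor <- seq_len(min(bo$n_regions, nr))
      env <- bo$amplitude *
        (1 - bo$erd_depth * ramped_box(tt, bo$erd_window[1], bo$erd_window[2], bo$ramp))
      for (tr in seq_len(nt)) {
        for (r in motor) {
          phase <- stats::runif(1, 0, 2 * pi)
          arr[tr, r, ] <- arr[tr, r, ] + env * sin(2 * pi * bo$freq * tt + phase)
        }
      }
    }

    # band-limited bursts in the tonic window
    for (bn in names(config$burst_params)) {
      p <- config$burst_params[[bn]][[group]]
      bdef <- bands[[bn]]
      f_lo <- bdef$f_lo + config$freq_margin
      f_hi <- bdef$f_hi - config$freq_margin
      n_mean <- max(0, stats::rnorm(1, p$n_active_regions_mean,
                                    0.2 * p$n_active_regions_mean))
      regions_by_trial <- vector("list", nt)
      for (tr in seq_len(nt)) {
        n_act <- min(nr, stats::rpois(1, n_mean))
        act <- sort(sample.int(nr, n_act))
        regions_by_trial[[tr]] <- act
        if (p$amplitude == 0 || n_act == 0) next
        for (r in act) {
          n_b <- max(1L, stats::rpois(1, p$rate))
          for (k in seq_len(n_b)) {
            dur <- stats::rgamma(1, shape = 4, scale = p$duration_mean / 4)
            dur <- clamp(dur, 0.1, diff(p$active_window))
            onset <- stats::runif(1, p$active_window[1],
                                  max(p$active_window[1], p$active_window[2] - dur))
            pk <- burst_packet(tt, onset, dur, stats::runif(1, f_lo, f_hi),
                               p$amplitude, stats::runif(1, 0, 2 * pi))
            arr[tr, r, pk$idx] <- arr[tr, r, pk$idx] + pk$sig
          }
        }
      }
      truth[[bn]] <- list(
        n_active_mean = n_mean,
        active_regions = regions_by_trial,
        n_active = lengths(regions_by_trial)
      )
    }
    arr
  })

  id <- participant_id %||% sprintf("%s%02d", group, 1L)
  out <- parcel_epochs(data, fs, t0, id, group, analysis_window = w)
  attr(out, "truth") <- truth
  out
}
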