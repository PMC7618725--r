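#' Default burst parameters per band and group
#'
#' Gamma and high-gamma activations are simulated as Hann-windowed sinusoid
#' packets confined to the tonic grip window (1--3 s post trigger). The ALS
#' group draws both more active regions and longer burst durations than
#' healthy controls, reproducing the qualitative picture of spatially broader,
#' longer-lasting gamma activations in patients.
#'
#' @return nested list `band -> group -> parameters` with elements
#'   `rate` (expected bursts per active region per trial),
#'   `duration_mean` (s), `amplitude` (a.u., relative to unit noise SD),
#'   `n_active_regions_mean` (expected number of active regions per trial)
#'   and `active_window` (s pair relative to the trigger).
#' @export
default_burst_params <- function() {
  list(
    gamma = list(
      HC  = list(rate = 3, duration_mean = 0.5, amplitude = 2.0,
                 n_active_regions_mean = 7,  active_window = c(1, 3)),
      ALS = list(rate = 3, duration_mean = 0.9, amplitude = 2.0,
                 n_active_regions_mean = 20, active_window = c(1, 3))
    ),
    high_gamma = list(
      HC  = list(rate = 3, duration_mean = 0.4, amplitude = 1.6,
                 n_active_regions_mean = 17, active_window = c(1, 3)),
      ALS = list(rate = 3, duration_mean = 0.7, amplitude = 1.6,
                 n_active_regions_mean = 34, active_window = c(1, 3))
    )
  )
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic cohort
#' generator. Defaults emulate the study conditions of the bilateral grip
#' task: 33 controls and 42 ALS participants, 52 cortical parcels, 120
#' six-second trials (-1 to 5 s around the trigger), a 12 N grip target held
#' for 3 s with a tonic phase at 1--3 s, and an ALS group with spatially
#' broader and longer gamma/high-gamma activations.
#'
#' @param n_hc,n_als cohort sizes.
#' @param n_regions number of cortical parcels (default 52).
#' @param n_trials trials per participant (default 120).
#' @param fs sampling rate in Hz; must exceed twice the highest simulated
#'   frequency.
#' @param epoch_window epoch limits in seconds relative to the trigger.
#' @param pad extra signal generated beyond each epoch edge (s) so that
#'   wavelet filtering can be trimmed free of edge artifacts.
#' @param noise_sd standard deviation of the 1/f background noise (a.u.).
#' @param burst_params nested list as returned by [default_burst_params()].
#' @param beta_osc parameters of the ongoing beta rhythm and its
#'   movement-related desynchronisation (ERD): `freq` (Hz), `amplitude`,
#'   `erd_depth` (fractional amplitude drop), `erd_window` (s),
#'   `n_regions` (number of motor parcels carrying the rhythm), `ramp` (s).
#' @param gas_progression_slope planted effect linking the latent activation
#'   spread of an ALS participant (standardised) to ALSFRS-R progression rate
#'   (points/month per SD of spread).
#' @param progression_noise_sd residual SD of progression rate (points/month).
#' @param behavior_shift optional group shift of behavioural metrics, in SD
#'   units (scalar or named per metric); 0 gives a null group difference.
#' @param freq_margin burst carrier frequencies are drawn uniformly inside
#'   the band shrunk by this margin (Hz), keeping spectral occupancy in-band.
#' @param seed default master seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_hc = 33, n_als = 42,
                       n_regions = 52, n_trials = 120, fs = 250,
                       epoch_window = c(-1, 5), pad = 0.5,
                       noise_sd = 1,
                       burst_params = default_burst_params(),
                       beta_osc = list(freq = 20, amplitude = 1.2,
                                       erd_depth = 0.7, erd_window = c(0, 3),
                                       n_regions = 8, ramp = 0.2),
                       gas_progression_slope = 0.15,
                       progression_noise_sd = 0.25,
                       behavior_shift = 0,
                       freq_margin = 2,
                       seed = 1L) {
  cfg <- list(
    n_hc = n_hc, n_als = n_als, n_regions = n_regions, n_trials = n_trials,
    fs = fs, epoch_window = epoch_window, pad = pad, noise_sd = noise_sd,
    burst_params = burst_params, beta_osc = beta_osc,
    gas_progression_slope = gas_progression_slope,
    progression_noise_sd = progression_noise_sd,
    behavior_shift = behavior_shift, freq_margin = freq_margin,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_regions >= 1, cfg$n_trials >= 1, cfg$fs > 0,
            length(cfg$epoch_window) == 2,
            cfg$epoch_window[1] < cfg$epoch_window[2],
            cfg$pad >= 0, cfg$noise_sd >= 0)
  if (cfg$epoch_window[1] > 1 || cfg$epoch_window[2] < 3) {
    stop("epoch_window must span the 1-3 s tonic grip window")
  }
  bands <- gas_bands()
  fmax <- 0
  for (bn in names(cfg$burst_params)) {
    if (!bn %in% names(bands)) stop("unknown band in burst_params: ", bn)
    for (g in c("HC", "ALS")) {
      p <- cfg$burst_params[[bn]][[g]]
      if (is.null(p)) stop("burst_params$", bn, " lacks group ", g)
      if (p$rate <= 0 || p$duration_mean <= 0) {
        stop("burst rates and durations must be positive")
      }
      if (p$n_active_regions_mean < 0) stop("n_active_regions_mean must be >= 0")
    }
    fmax <- max(fmax, bands[[bn]]$f_hi)
  }
  if (!is.null(cfg$beta_osc) && cfg$beta_osc$amplitude > 0) {
    fmax <- max(fmax, cfg$beta_osc$freq)
  }
  if (cfg$fs <= 2 * fmax) {
    stop(sprintf("fs = %g Hz violates Nyquist for simulated content up to %g Hz",
                 cfg$fs, fmax))
  }
  if (!is.finite(cfg$gas_progression_slope)) {
    stop("gas_progression_slope must be finite")
  }
  invisible(cfg)
}
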