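# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures are stored.

quiet_design <- function(...) suppressMessages(build_design(...))

# burst parameters with all amplitudes set to zero (pure-noise cohort)
silent_bursts <- function() {
  bp <- default_burst_params()
  for (b in names(bp)) for (g in c("HC", "ALS")) bp[[b]][[g]]$amplitude <- 0
  bp
}

no_beta_rhythm <- function() {
  list(freq = 20, amplitude = 0, erd_depth = 0, erd_window = c(0, 3),
       n_regions = 0, ramp = 0.2)
}

tiny_sim_config <- function(n_hc = 2, n_als = 2, n_regions = 6, n_trials = 4,
                            fs = 200, seed = 1, ...) {
  sim_config(n_hc = n_hc, n_als = n_als, n_regions = n_regions,
             n_trials = n_trials, fs = fs, seed = seed, ...)
}

# a band_power object built directly from a value array
band_power_obj <- function(value, band_names = "gamma", t0 = -1,
                           bin_width = 0.1, id = "P01", group = "HC") {
  nb <- dim(value)[4]
  stopifnot(dim(value)[3] == length(band_names))
  structure(
    list(value = value, band_names = band_names,
         bin_edges = t0 + (0:nb) * bin_width,
         baseline_window = c(-0.8, -0.1), baseline_stat = "average",
         corrected = TRUE, participant_id = id, group = group),
    class = "band_power")
}

# a tfr_power object built directly from a power array
tfr_obj <- function(power, freqs, fs, t0 = -1, corrected = FALSE) {
  ns <- dim(power)[4]
  structure(
    list(power = power, freqs = freqs, time = t0 + (seq_len(ns) - 1) / fs,
         fs = fs, corrected = corrected,
         participant_id = "P01", group = "HC"),
    class = "tfr_power")
}

# a spread_series object built directly from count matrices
spread_obj <- function(activated, deactivated = activated * 0,
                       band_names = rownames(activated) %||% "gamma",
                       t0 = -1, bin_width = 0.1, n_regions = 52,
                       id = "P01", group = "HC") {
  nb <- ncol(activated)
  rownames(activated) <- band_names
  rownames(deactivated) <- band_names
  structure(
    list(activated = activated, deactivated = deactivated,
         bin_centers = t0 + bin_width * (seq_len(nb) - 0.5),
         n_regions = n_regions, band_names = band_names,
         participant_id = id, group = group),
    class = "spread_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# epochs containing a pure sinusoid in selected regions, zero elsewhere
tone_epochs <- function(freq, amplitude = 1, n_regions = 2, tone_regions = 1,
                        fs = 200, window = c(-1, 5), pad = 0.5,
                        tone_window = NULL) {
  ns <- round((diff(window) + 2 * pad) * fs)
  t0 <- window[1] - pad
  tt <- t0 + (seq_len(ns) - 1) / fs
  sig <- amplitude * sin(2 * pi * freq * tt)
  if (!is.null(tone_window)) {
    sig[tt < tone_window[1] | tt >= tone_window[2]] <- 0
  }
  data <- array(0, c(1, n_regions, ns))
  for (r in tone_regions) data[1, r, ] <- sig
  parcel_epochs(data, fs, t0, "TONE", "HC", analysis_window = window)
}
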