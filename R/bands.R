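#' Canonical frequency band definitions
#'
#' The three canonical bands used throughout the pipeline: beta (13--30 Hz),
#' gamma (30--48 Hz) and high-gamma (52--80 Hz). The 48--52 Hz gap around the
#' mains line is never covered by any band. Band edges are inclusive when
#' frequencies are assigned to bands, so a grid point at exactly 30 Hz would
#' contribute to both beta and gamma.
#'
#' @param which character vector naming the bands to return, a subset of
#'   `"beta"`, `"gamma"`, `"high_gamma"`.
#' @return a named list of band definitions, each a list with `name`, `f_lo`
#'   and `f_hi` (Hz).
#' @examples
#' gas_bands("gamma")
#' @export
gas_bands <- function(which = c("beta", "gamma", "high_gamma")) {
  all <- list(
    beta       = list(name = "beta",       f_lo = 13, f_hi = 30),
    gamma      = list(name = "gamma",      f_lo = 30, f_hi = 48),
    high_gamma = list(name = "high_gamma", f_lo = 52, f_hi = 80)
  )
  which <- match.arg(which, names(all), several.ok = TRUE)
  all[which]
}

#' Wavelet frequency grid for a set of bands
#'
#' A regular grid (default 2 Hz pitch, anchored at 13 Hz) restricted to the
#' requested bands and excluding the 48--52 Hz mains gap.
#'
#' @param bands list of band definitions from [gas_bands()].
#' @param step grid pitch in Hz.
#' @param gap two-element vector; frequencies strictly inside this open
#'   interval are dropped.
#' @return increasing numeric vector of frequencies in Hz.
#' @export
band_freq_grid <- function(bands = gas_bands(), step = 2, gap = c(48, 52)) {
  f <- seq(13, 80, by = step)
  keep_band <- Reduce(`|`, lapply(bands, function(b) f >= b$f_lo & f <= b$f_hi))
  keep <- keep_band & !(f > gap[1] & f < gap[2])
  fg <- f[keep]
  if (!length(fg)) stop("no grid frequencies fall inside the requested bands")
  fg
}

# Default Morlet cycle count per frequency: f/2 clipped to [4, 24].
# f/2 cycles give a constant ~2 Hz spectral bandwidth, matching the 2 Hz
# grid pitch and keeping mains energy in the 48-52 Hz gap out of the
# adjacent band-edge grid points.
default_n_cycles <- function(freqs) clamp(freqs / 2, 4, 24)
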