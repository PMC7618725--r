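#' Calibrate activation thresholds on the control group
#'
#' For every region x band, pools healthy-control band-power values over all
#' time bins of the epoch (and all HC participants) and sets activation /
#' deactivation cut-offs at the pooled mean plus/minus `sd_mult` pooled
#' sample standard deviations (denominator n - 1). With `level = "average"`
#' (the tested default) each participant contributes their trial-averaged
#' time course, matching the binarization of trial-averaged power used by
#' the pipeline; `level = "trial"` pools raw per-trial values instead.
#'
#' @param bp_list list of `band_power` objects, one per HC participant, all
#'   on identical region/band/bin grids.
#' @param sd_mult threshold multiplier (default 2).
#' @param level pooling level, `"average"` or `"trial"`.
#' @return data.frame of class `threshold_table` with one row per
#'   region x band: `region`, `band`, `center`, `sd`, `upper`, `lower`,
#'   `n_pooled`; attributes record `sd_mult`, `level` and the bin grid.
#' @export
calibrate_thresholds <- function(bp_list, sd_mult = 2,
                                 level = c("average", "trial")) {
  level <- match.arg(level)
  if (length(bp_list) < 2) {
    stop("threshold calibration needs at least two HC participants")
  }
  ref <- bp_list[[1]]
  for (bp in bp_list) {
    stopifnot(inherits(bp, "band_power"))
    if (!identical(bp$band_names, ref$band_names) ||
        !identical(dim(bp$value)[2], dim(ref$value)[2]) ||
        !identical(dim(bp$value)[4], dim(ref$value)[4])) {
      stop("band power grids differ across participants")
    }
  }
  nr <- dim(ref$value)[2]
  nbands <- dim(ref$value)[3]
  pooled <- function(r, b) {
    unlist(lapply(bp_list, function(bp) {
      v <- if (level == "average") collapse_trials(bp)$value else bp$value
      as.vector(v[, r, b, ])
    }), use.names = FALSE)
  }
  rows <- expand.grid(region = seq_len(nr), band_idx = seq_len(nbands))
  stats_mat <- t(mapply(function(r, b) {
    x <- pooled(r, b)
    c(mean(x), stats::sd(x), length(x))
  }, rows$region, rows$band_idx))
  out <- data.frame(
    region = rows$region,
    band = ref$band_names[rows$band_idx],
    center = stats_mat[, 1],
    sd = stats_mat[, 2],
    n_pooled = as.integer(stats_mat[, 3]),
    stringsAsFactors = FALSE
  )
  out$upper <- out$center + sd_mult * out$sd
  out$lower <- out$center - sd_mult * out$sd
  out <- out[, c("region", "band", "center", "sd", "upper", "lower", "n_pooled")]
  attr(out, "sd_mult") <- sd_mult
  attr(out, "level") <- level
  attr(out, "band_names") <- ref$band_names
  attr(out, "bin_edges") <- ref$bin_edges
  class(out) <- c("threshold_table", "data.frame")
  out
}

#' Write / read a threshold table as CSV
#'
#' @param x a `threshold_table`.
#' @param path CSV file path.
#' @return `write_threshold_table` returns `path` invisibly;
#'   `read_threshold_table` returns a `threshold_table`.
#' @export
write_threshold_table <- function(x, path) {
  df <- as.data.frame(x)
  df$sd_mult <- attr(x, "sd_mult")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_table
#' @export
read_threshold_table <- function(path) {
  if (!file.exists(path)) stop("threshold table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sd_mult <- if ("sd_mult" %in% names(df)) df$sd_mult[1] else NA_real_
  df$sd_mult <- NULL
  attr(df, "sd_mult") <- sd_mult
  attr(df, "band_names") <- unique(df$band)
  class(df) <- c("threshold_table", "data.frame")
  df
}

#' Binarize band power into activation states
#'
#' Each trial x region x band x bin cell becomes `+1` (activated) when its
#' value strictly exceeds the upper threshold, `-1` (deactivated) when
#' strictly below the lower threshold, and `0` otherwise. Values exactly on
#' a threshold are state 0, so a degenerate `sd = 0` calibration yields
#' all-zero states rather than an error.
#'
#' @param bp a `band_power` object (per-trial or trial-averaged).
#' @param thresholds a `threshold_table` covering the same regions and bands.
#' @return object of class `activation_map`: list with integer `state`
#'   array (`trials x regions x bands x bins`), `band_names`, `bin_edges`.
#' @export
binarize_activation <- function(bp, thresholds) {
  stopifnot(inherits(bp, "band_power"))
  if (any(!is.finite(bp$value))) stop("band power contains non-finite values")
  d <- dim(bp$value)
  nr <- d[2]; nbands <- d[3]
  U <- matrix(NA_real_, nr, nbands)
  L <- matrix(NA_real_, nr, nbands)
  for (bi in seq_len(nbands)) {
    sel <- thresholds$band == bp$band_names[bi]
    if (sum(sel) < nr) {
      stop("threshold table does not cover all regions for band ",
           bp$band_names[bi])
    }
    th <- thresholds[sel, ]
    th <- th[match(seq_len(nr), th$region), ]
    U[, bi] <- th$upper
    L[, bi] <- th$lower
  }
  Ubig <- aperm(array(U, c(nr, nbands, d[1], d[4])), c(3, 1, 2, 4))
  Lbig <- aperm(array(L, c(nr, nbands, d[1], d[4])), c(3, 1, 2, 4))
  state <- (bp$value > Ubig) - (bp$value < Lbig)
  storage.mode(state) <- "integer"
  structure(
    list(state = state, band_names = bp$band_names, bin_edges = bp$bin_edges,
         participant_id = bp$participant_id, group = bp$group),
    class = "activation_map"
  )
}

#' Region-count spread time courses
#'
#' For every band and time bin, counts the regions in state `+1`
#' (respectively `-1`) within each trial, then averages the counts over
#' trials. With a single (e.g. trial-averaged) "trial" the counts are plain
#' integer region counts.
#'
#' @param actmap an `activation_map`.
#' @return object of class `spread_series`: list with `activated` and
#'   `deactivated` matrices (`bands x bins`, rownames = band names),
#'   `bin_centers`, `n_regions`.
#' @export
spread_timeseries <- function(actmap) {
  stopifnot(inherits(actmap, "activation_map"))
  d <- dim(actmap$state)
  count_state <- function(s) {
    cnt <- colSums(aperm(actmap$state == s, c(2, 1, 3, 4)), dims = 1)
    # cnt: trials x bands x bins -> mean over trials
    m <- colMeans(cnt, dims = 1)
    matrix(m, d[3], d[4], dimnames = list(actmap$band_names, NULL))
  }
  centers <- (actmap$bin_edges[-1] + actmap$bin_edges[-length(actmap$bin_edges)]) / 2
  structure(
    list(activated = count_state(1L), deactivated = count_state(-1L),
         bin_centers = centers, n_regions = d[2],
         band_names = actmap$band_names,
         participant_id = actmap$participant_id, group = actmap$group),
    class = "spread_series"
  )
}

#' Gamma activation spread (GAS)
#'
#' The window mean of a band's activated-region count over the time bins
#' whose centers fall inside the tonic grip window (closed interval,
#' default 1--3 s post trigger).
#'
#' @param spread a `spread_series`.
#' @param window seconds pair (default `c(1, 3)`).
#' @param band band name (default `"gamma"`; `"high_gamma"` gives the
#'   high-gamma analogue).
#' @return object of class `gas_value`: list with `gas`, `window`, `band`,
#'   `n_bins`.
#' @export
compute_gas <- function(spread, window = c(1, 3), band = "gamma") {
  stopifnot(inherits(spread, "spread_series"))
  if (!band %in% spread$band_names) {
    stop("band '", band, "' not present in spread series")
  }
  idx <- which(spread$bin_centers >= window[1] - 1e-9 &
                 spread$bin_centers <= window[2] + 1e-9)
  if (!length(idx)) stop("no bin centers fall inside the GAS window")
  structure(
    list(gas = mean(spread$activated[band, idx]), window = window,
         band = band, n_bins = length(idx)),
    class = "gas_value"
  )
}

#' @export
print.gas_value <- function(x, ...) {
  cat(sprintf("GAS (%s, %g-%g s): %.3f regions over %d bins\n",
              x$band, x$window[1], x$window[2], x$gas, x$n_bins))
  invisible(x)
}

#' Per-region activation proportion over time
#'
#' Fraction of trials in which each region is activated (state `+1`) per
#' time bin for one band; the data behind the activation videos and the
#' regional activation maps.
#'
#' @param actmap an `activation_map`.
#' @param band band name.
#' @return matrix `regions x bins` of proportions in `[0, 1]`.
#' @export
region_activation_proportion <- function(actmap, band = "gamma") {
  bi <- match(band, actmap$band_names)
  if (is.na(bi)) stop("band '", band, "' not present")
  s <- actmap$state[, , bi, , drop = FALSE]
  d <- dim(s)
  arr <- array(s == 1L, c(d[1], d[2], d[4]))
  colMeans(arr, dims = 1)
}
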