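#' Schematic 2-D parcel layout
#'
#' A flat-map stand-in for the cortical surface: each hemisphere is a disc
#' and parcels are placed deterministically on a sunflower (golden-angle)
#' spiral inside it. Sufficient for rendering activation videos and regional
#' maps without any anatomy files.
#'
#' @param n_regions number of parcels (default 52, split half per
#'   hemisphere).
#' @return data.frame with `region`, `name`, `hemisphere` (L/R), `x`, `y`.
#' @export
parcel_layout <- function(n_regions = 52) {
  stopifnot(n_regions >= 1)
  n_l <- ceiling(n_regions / 2)
  hemi <- rep(c("L", "R"), c(n_l, n_regions - n_l))
  golden <- pi * (3 - sqrt(5))
  place <- function(m, cx) {
    k <- seq_len(m)
    r <- sqrt(k / m)
    data.frame(x = cx + r * cos(k * golden), y = r * sin(k * golden))
  }
  xy <- rbind(place(n_l, -1.2),
              if (n_regions > n_l) place(n_regions - n_l, 1.2))
  idx_in_hemi <- c(seq_len(n_l), seq_len(n_regions - n_l))
  data.frame(region = seq_len(n_regions),
             name = sprintf("%s%02d", hemi, idx_in_hemi),
             hemisphere = hemi, x = xy$x, y = xy$y,
             stringsAsFactors = FALSE)
}

#' Group summary of spread time courses
#'
#' Long-format group mean and standard error of the activated and
#' deactivated region counts per band and time bin; the data behind
#' [plot_spread_timecourse()].
#'
#' @param spread_list list of `spread_series`.
#' @param groups optional character vector of group labels per participant;
#'   defaults to each series' own `group` field.
#' @return data.frame with `group`, `band`, `measure`, `bin_center`,
#'   `mean`, `sem`, `n`.
#' @export
spread_group_summary <- function(spread_list, groups = NULL) {
  groups <- groups %||% vapply(spread_list, function(s) s$group %||% "all",
                               character(1))
  stopifnot(length(groups) == length(spread_list))
  s1 <- spread_list[[1]]
  out <- list()
  for (g in unique(groups)) {
    sel <- spread_list[groups == g]
    for (measure in c("activated", "deactivated")) {
      for (bn in s1$band_names) {
        mat <- t(vapply(sel, function(s) s[[measure]][bn, ],
                        numeric(length(s1$bin_centers))))
        mu <- colMeans(mat)
        sem <- if (nrow(mat) > 1) apply(mat, 2, stats::sd) / sqrt(nrow(mat))
               else rep(0, ncol(mat))
        out[[length(out) + 1]] <- data.frame(
          group = g, band = bn, measure = measure,
          bin_center = s1$bin_centers, mean = mu, sem = sem, n = nrow(mat),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Plot group spread time courses
#'
#' Group-mean +/- SEM curves of activated and deactivated region counts per
#' band over the epoch, with the 1--3 s tonic grip window shaded.
#'
#' @inheritParams spread_group_summary
#' @param tonic_window shaded window in seconds.
#' @return a ggplot object.
#' @export
plot_spread_timecourse <- function(spread_list, groups = NULL,
                                   tonic_window = c(1, 3)) {
  df <- spread_group_summary(spread_list, groups)
  ggplot2::ggplot(df, ggplot2::aes(x = bin_center, y = mean,
                                   colour = group, fill = group)) +
    ggplot2::annotate("rect", xmin = tonic_window[1], xmax = tonic_window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(band ~ measure) +
    ggplot2::labs(x = "time relative to trigger (s)",
                  y = "regions (trial-averaged count)",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Render per-bin activation frames
#'
#' Writes one PNG frame per 100 ms time bin showing each parcel on the
#' schematic 2-D layout, coloured by its activation proportion in that bin.
#' A frame directory (rather than an encoded container) keeps the output
#' codec-free and testable.
#'
#' @param actmap an `activation_map`.
#' @param layout parcel layout from [parcel_layout()].
#' @param band band to render.
#' @param out_dir output directory (created if needed).
#' @param width,height frame size in pixels.
#' @return invisible character vector of frame file paths (one per bin).
#' @export
render_activation_frames <- function(actmap, layout = NULL, band = "gamma",
                                     out_dir, width = 480, height = 360) {
  prop <- region_activation_proportion(actmap, band)
  nb <- ncol(prop)
  if (nb == 0) stop("activation map has no time bins")
  layout <- layout %||% parcel_layout(nrow(prop))
  stopifnot(nrow(layout) == nrow(prop))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ramp <- grDevices::colorRampPalette(c("grey85", "orange", "red3"))(101)
  centers <- (actmap$bin_edges[-1] + actmap$bin_edges[-(nb + 1)]) / 2
  paths <- character(nb)
  for (k in seq_len(nb)) {
    paths[k] <- file.path(out_dir, sprintf("frame_%03d.png", k))
    grDevices::png(paths[k], width = width, height = height)
    op <- graphics::par(mar = c(1, 1, 2, 1))
    cols <- ramp[pmin(100, floor(prop[, k] * 100)) + 1]
    plot(layout$x, layout$y, pch = 21, bg = cols, cex = 2.2, axes = FALSE,
         xlab = "", ylab = "", asp = 1,
         main = sprintf("%s activation, t = %.2f s", band, centers[k]))
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(paths)
}
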