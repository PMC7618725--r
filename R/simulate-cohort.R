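#' Simulate the clinical covariate table
#'
#' Builds a participant-level table of demographics and clinical scores whose
#' marginals roughly match the study cohort (ages near 61 y in both groups,
#' more females among controls, ALSFRS-R around 39, symptom durations with a
#' right-skewed distribution around 29 months). For ALS participants the
#' ALSFRS-R progression rate is generated as
#' `0.4 + slope * standardised latent spread + noise`; ALSFRS-R is then
#' back-derived from a drawn symptom duration and the rate recomputed so that
#' the identity `progression_rate = (48 - ALSFRS_R) / symptom_duration` holds
#' exactly. A fine-motor sub-score (sum of two 0--4 items, handwriting and
#' food handling) is planted to correlate negatively with latent spread.
#'
#' @param config a [sim_config()] object; `config$gas_progression_slope`
#'   (points/month per SD of latent spread) and
#'   `config$progression_noise_sd` control the planted association.
#' @param latent_spread numeric vector, one latent activation-spread value
#'   per ALS participant (e.g. the participant-level mean number of active
#'   gamma regions).
#' @param seed integer seed.
#' @return data.frame with one row per participant: `participant_id`,
#'   `group`, `age`, `sex` (F/M), `missing_mri` (0/1), `ALSFRS_R`,
#'   `symptom_duration` (months), `progression_rate` (points/month), `ECAS`,
#'   `UMN_score`, `NfL` (pg/mL), `fine_motor_subscore`; ALS-only fields are
#'   `NA` for controls.
#' @export
simulate_clinical_table <- function(config, latent_spread,
                                    seed = substream_seed(config$seed, 9001L)) {
  slope <- config$gas_progression_slope
  if (!is.finite(slope)) stop("gas_progression_slope must be finite")
  n_als <- length(latent_spread)
  n_hc <- config$n_hc
  if (n_als + n_hc == 0) stop("empty cohort")

  with_seed(seed, {
    z <- if (n_als > 1 && stats::sd(latent_spread) > 0) {
      as.numeric(scale(latent_spread))
    } else {
      rep(0, n_als)
    }

    age_hc <- clamp(stats::rnorm(n_hc, 61.76, 16.42), 25, 90)
    age_als <- clamp(stats::rnorm(n_als, 61.02, 12.65), 25, 90)
    sex_hc <- ifelse(stats::runif(n_hc) < 0.515, "F", "M")
    sex_als <- ifelse(stats::runif(n_als) < 0.333, "F", "M")

    rate_raw <- pmax(0.4 + slope * z +
                       stats::rnorm(n_als, 0, config$progression_noise_sd), 0.01)
    duration <- clamp(stats::rlnorm(n_als, meanlog = 2.97, sdlog = 0.64), 3, 120)
    alsfrs <- clamp(round(48 - rate_raw * duration), 0, 48)
    rate <- (48 - alsfrs) / duration          # identity holds exactly

    ecas_hc <- stats::rnorm(n_hc, 118.78, 9.64)
    ecas_als <- stats::rnorm(n_als, 112.56, 9.22)
    umn <- clamp(round(stats::rnorm(n_als, 10.14, 3.83)), 0, 16)
    nfl <- stats::rlnorm(n_als, meanlog = log(60), sdlog = 0.5)
    fine_motor <- clamp(round(4 - 1.0 * z + stats::rnorm(n_als, 0, 1)), 0, 8)

    data.frame(
      participant_id = c(sprintf("HC%02d", seq_len(n_hc)),
                         sprintf("ALS%02d", seq_len(n_als))),
      group = c(rep("HC", n_hc), rep("ALS", n_als)),
      age = c(age_hc, age_als),
      sex = c(sex_hc, sex_als),
      missing_mri = stats::rbinom(n_hc + n_als, 1, 0.12),
      ALSFRS_R = c(rep(NA_real_, n_hc), alsfrs),
      symptom_duration = c(rep(NA_real_, n_hc), duration),
      progression_rate = c(rep(NA_real_, n_hc), rate),
      ECAS = c(ecas_hc, ecas_als),
      UMN_score = c(rep(NA_real_, n_hc), umn),
      NfL = c(rep(NA_real_, n_hc), nfl),
      fine_motor_subscore = c(rep(NA_real_, n_hc), fine_motor),
      stringsAsFactors = FALSE
    )
  })
}

# Behavioural metric distributions shared by both groups under the null.
behavior_metric_params <- function() {
  list(
    grip_length   = list(mean = 3.00, sd = 0.35),
    grip_strength = list(mean = 12.0, sd = 1.50),   # 12 N grip target
    reaction_time = list(mean = 0.45, sd = 0.08)
  )
}

draw_behavior_group <- function(n, seed, shift = 0) {
  pars <- behavior_metric_params()
  shift_for <- function(metric) {
    if (length(shift) == 1 && is.null(names(shift))) return(shift)
    v <- unname(shift[metric])
    if (length(v) != 1 || is.na(v)) 0 else v
  }
  with_seed(seed, {
    g <- function(metric) {
      p <- pars[[metric]]
      s <- shift_for(metric)
      s <- if (is.na(s)) 0 else s
      pmax(stats::rnorm(n, p$mean + s * p$sd, p$sd), 0.01)
    }
    out <- data.frame(
      grip_length = g("grip_length"),
      grip_strength = g("grip_strength"),
      reaction_time = g("reaction_time")
    )
    s <- shift_for("accuracy")
    s <- if (is.na(s)) 0 else s
    out$accuracy <- stats::plogis(stats::rnorm(n, 2.2 + s * 0.5, 0.5))
    out
  })
}

#' Simulate the behavioural summary table
#'
#' Grip length, grip strength (12 N target), reaction time and accuracy per
#' participant. By default both groups are drawn from identical
#' distributions, so any group difference is a false positive; a nonzero
#' `shift` (in SD units, scalar or named per metric) displaces the ALS group
#' for power checks.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed.
#' @param shift group displacement in SD units applied to the ALS group.
#' @param group_seeds optional length-2 integer vector of per-group seeds
#'   (HC, ALS); defaults to substreams of `seed`.
#' @return data.frame with `participant_id`, `group` and the four metrics.
#' @export
simulate_behavior_table <- function(config,
                                    seed = substream_seed(config$seed, 9002L),
                                    shift = config$behavior_shift,
                                    group_seeds = NULL) {
  gs <- group_seeds %||% c(substream_seed(seed, 1L), substream_seed(seed, 2L))
  hc <- draw_behavior_group(config$n_hc, gs[1], shift = 0)
  als <- draw_behavior_group(config$n_als, gs[2], shift = shift)
  out <- rbind(
    cbind(data.frame(participant_id = sprintf("HC%02d", seq_len(config$n_hc)),
                     group = "HC", stringsAsFactors = FALSE), hc),
    cbind(data.frame(participant_id = sprintf("ALS%02d", seq_len(config$n_als)),
                     group = "ALS", stringsAsFactors = FALSE), als)
  )
  rownames(out) <- NULL
  out
}

#' Simulate a full cohort
#'
#' Draws every participant's epochs from an independent RNG substream of the
#' master seed (participant i uses `substream_seed(seed, i)`), then generates
#' the clinical table — using each ALS participant's latent gamma spread
#' (expected active-region count) as the latent variable behind the planted
#' progression-rate association — and the behavioural table.
#'
#' @param config a [sim_config()] object.
#' @param seed master seed (default `config$seed`).
#' @return list with `epochs` (list of [parcel_epochs()]), `clinical`,
#'   `behavior`, and `truth` (per-participant latent spread per band).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  validate_sim_config(config)
  groups <- c(rep("HC", config$n_hc), rep("ALS", config$n_als))
  ids <- c(sprintf("HC%02d", seq_len(config$n_hc)),
           sprintf("ALS%02d", seq_len(config$n_als)))
  epochs <- vector("list", length(ids))
  names(epochs) <- ids
  latent <- numeric(0)
  truth <- list()
  for (i in seq_along(ids)) {
    ep <- simulate_participant_epochs(config, groups[i],
                                      seed = substream_seed(seed, i),
                                      participant_id = ids[i])
    epochs[[i]] <- ep
    truth[[ids[i]]] <- lapply(attr(ep, "truth"), `[[`, "n_active_mean")
    if (groups[i] == "ALS") {
      latent <- c(latent, attr(ep, "truth")$gamma$n_active_mean %||% 0)
    }
  }
  clinical <- simulate_clinical_table(config, latent_spread = latent,
                                      seed = substream_seed(seed, 9001L))
  behavior <- simulate_behavior_table(config,
                                      seed = substream_seed(seed, 9002L))
  list(epochs = epochs, clinical = clinical, behavior = behavior,
       truth = truth, latent_spread = latent)
}
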