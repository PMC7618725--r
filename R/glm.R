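T_CAP <- 1e6  # cap for t statistics with numerically zero residual variance

#' Build a design matrix with centered confounds
#'
#' Columns: intercept, the predictor of interest, then mean-centered
#' confounds. `group` becomes an ALS indicator (ALS = 1), `sex` a male
#' indicator; both confounds and indicators are centered. Confound columns
#' that are constant in the supplied rows, or collinear with columns already
#' in the design, are dropped with a message (they carry no information and
#' would make the design rank deficient).
#'
#' @param tbl data.frame with one row per participant.
#' @param predictor column name of the regressor of interest, or a numeric
#'   vector of length `nrow(tbl)` (supply `predictor_name`).
#' @param confounds character vector of confound column names.
#' @param predictor_name label used when `predictor` is a vector.
#' @return list with `X` (numeric matrix with named columns), `contrast`
#'   (coefficient-selection vector picking the predictor) and `dropped`
#'   (names of discarded constant confounds).
#' @export
build_design <- function(tbl, predictor = "group",
                         confounds = c("age", "sex", "missing_mri"),
                         predictor_name = NULL) {
  as_num <- function(col, nm) {
    if (nm == "group") return(as.numeric(col == "ALS"))
    if (nm == "sex") return(as.numeric(col == "M"))
    as.numeric(col)
  }
  if (is.character(predictor) && length(predictor) == 1) {
    pname <- predictor
    pcol <- as_num(tbl[[predictor]], predictor)
  } else {
    pname <- predictor_name %||% "predictor"
    pcol <- as.numeric(predictor)
  }
  if (anyNA(pcol)) stop("predictor contains missing values")
  X <- cbind(`(Intercept)` = 1, pcol)
  colnames(X)[2] <- pname
  dropped <- character(0)
  for (cf in confounds) {
    v <- as_num(tbl[[cf]], cf)
    if (anyNA(v)) stop("confound '", cf, "' contains missing values")
    cand <- cbind(X, scale(v, scale = FALSE)[, 1])
    # drop confounds that are constant or collinear with earlier columns
    if (stats::sd(v) == 0 || qr(cand)$rank < ncol(cand)) {
      dropped <- c(dropped, cf)
      next
    }
    X <- cand
    colnames(X)[ncol(X)] <- cf
  }
  if (length(dropped)) {
    message("dropping constant or collinear confound(s): ",
            paste(dropped, collapse = ", "))
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  contrast <- as.numeric(colnames(X) == pname)
  list(X = X, contrast = contrast, dropped = dropped)
}

guarded_t <- function(eff, se) {
  t <- eff / se
  bad <- !is.finite(t) | se <= 1e-12 * (abs(eff) + 1)
  if (any(bad)) {
    t[bad] <- ifelse(abs(eff[bad]) <= 1e-12, 0, sign(eff[bad]) * T_CAP)
  }
  t
}

#' Ordinary least squares fit with a contrast t statistic
#'
#' Fits `y = X b + e` by OLS for one or many outcome columns at once and
#' returns the contrast effect and its t statistic with residual degrees of
#' freedom `n - ncol(X)`. Outcomes with numerically zero residual variance
#' (perfect fit) get a capped, flagged t.
#'
#' @param y outcome vector or `n x m` matrix.
#' @param X design matrix (full column rank).
#' @param contrast coefficient-selection vector of length `ncol(X)`.
#' @return list with `beta` (`p x m` coefficients), `effect`, `se`, `t`,
#'   `df`, and logical `capped` per outcome.
#' @export
fit_glm <- function(y, X, contrast) {
  Y <- as.matrix(y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("outcome rows do not match the design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df <= 0) stop("not enough observations for the design (n <= rank)")
  stopifnot(length(contrast) == p)
  B <- qr.coef(qrX, Y)
  E <- qr.resid(qrX, Y)
  sigma2 <- colSums(E^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  v <- drop(t(contrast) %*% XtXinv %*% contrast)
  eff <- drop(crossprod(contrast, B))
  se <- sqrt(sigma2 * v)
  t <- guarded_t(eff, se)
  list(beta = B, effect = eff, se = se, t = t, df = df,
       capped = abs(t) >= T_CAP)
}

# All n! permutations of 1..n as an (n! x n) matrix (row 1 = identity).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    block <- sub + (sub >= k)
    out[rows, ] <- cbind(rep(k, nrow(sub)), block)
  }
  # put identity first for convenience
  id <- which(apply(out, 1, function(r) all(r == seq_len(n))))[1]
  out[c(id, setdiff(seq_len(nrow(out)), id)), , drop = FALSE]
}

#' Permutation test of a single GLM coefficient
#'
#' Non-parametric inference on one coefficient of an OLS model for a family
#' of outcome elements, with family-wise error control by the max-|t|
#' permutation distribution. The default scheme is Freedman-Lane: the
#' outcome is residualised on the confound columns, residual rows are
#' permuted (the confound fit is kept in place), the full model is refit and
#' the contrast t collected. `method = "label"` permutes whole outcome rows
#' instead. When the total number of row permutations `n!` does not exceed
#' `max_exhaustive`, all permutations are enumerated and p values are exact;
#' otherwise `n_perm` random permutations give Monte-Carlo p values
#' `(1 + #{|t*| >= |t|}) / (1 + n_perm)`.
#'
#' @param y outcome vector or `n x m` matrix (one column per family element).
#' @param X design matrix.
#' @param contrast coefficient-selection vector with exactly one nonzero
#'   entry.
#' @param n_perm number of random permutations (>= 100).
#' @param seed RNG seed.
#' @param method `"freedman_lane"` or `"label"`.
#' @param max_exhaustive switch to exhaustive enumeration when
#'   `n! <= max_exhaustive`.
#' @param family optional description of the correction family.
#' @return data.frame of class `glm_result` with one row per outcome
#'   element: `element`, `beta` (contrast effect), `t`, `p_uncorrected`,
#'   `p_fwe`; attributes `n_perm`, `seed`, `method`, `exhaustive`, `df`,
#'   `family`.
#' @export
permutation_test <- function(y, X, contrast, n_perm = 5000, seed = 1L,
                             method = c("freedman_lane", "label"),
                             max_exhaustive = 20000, family = NULL) {
  method <- match.arg(method)
  Y <- as.matrix(y)
  X <- as.matrix(X)
  if (sum(contrast != 0) != 1) {
    stop("contrast must select exactly one coefficient")
  }
  n <- nrow(X)
  m <- ncol(Y)
  obs <- fit_glm(Y, X, contrast)

  exhaustive <- factorial(n) <= max_exhaustive
  if (exhaustive) {
    perms <- all_permutations(n)
  } else {
    if (n_perm < 100) stop("n_perm must be at least 100")
    perms <- with_seed(seed, t(replicate(n_perm, sample.int(n))))
  }
  B <- nrow(perms)

  qrX <- qr(X)
  XtXinv <- chol2inv(qr.R(qrX))
  pinv <- XtXinv %*% t(X)
  v <- drop(t(contrast) %*% XtXinv %*% contrast)
  df <- n - ncol(X)

  if (method == "freedman_lane") {
    Z <- X[, contrast == 0, drop = FALSE]
    qrZ <- qr(Z)
    E <- qr.resid(qrZ, Y)
    Fhat <- Y - E
  }

  tol <- 1e-12
  abs_obs <- abs(obs$t)
  cnt <- numeric(m)
  cnt_max <- numeric(m)
  for (i in seq_len(B)) {
    pm <- perms[i, ]
    Ys <- if (method == "freedman_lane") Fhat + E[pm, , drop = FALSE]
          else Y[pm, , drop = FALSE]
    Bp <- pinv %*% Ys
    eff <- drop(crossprod(contrast, Bp))
    R <- Ys - X %*% Bp
    se <- sqrt(colSums(R^2) / df * v)
    tp <- abs(guarded_t(eff, se))
    cnt <- cnt + (tp >= abs_obs - tol)
    cnt_max <- cnt_max + (max(tp) >= abs_obs - tol)
  }
  if (exhaustive) {
    p_unc <- cnt / B
    p_fwe <- cnt_max / B
  } else {
    # identity permutation is included implicitly by the +1 convention
    p_unc <- (1 + cnt) / (1 + B)
    p_fwe <- (1 + cnt_max) / (1 + B)
  }
  p_fwe <- pmax(p_fwe, p_unc)

  out <- data.frame(
    element = colnames(Y) %||% sprintf("el%03d", seq_len(m)),
    beta = obs$effect, t = obs$t,
    p_uncorrected = p_unc, p_fwe = p_fwe,
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- B
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  attr(out, "exhaustive") <- exhaustive
  attr(out, "df") <- df
  attr(out, "family") <- family %||% sprintf("%d outcome elements", m)
  class(out) <- c("glm_result", "data.frame")
  out
}

#' Group contrast of spread time courses
#'
#' Compares ALS vs HC on the activated and deactivated region counts for
#' every band and time bin, plus the scalar GAS and its high-gamma analogue,
#' in a single permutation family (max-|t| correction across all elements),
#' adjusting for age, sex and missing-MRI status.
#'
#' @param spread_list list of `spread_series`, one per participant.
#' @param clinical clinical table containing `participant_id`, `group` and
#'   the confounds.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param gas_window GAS window in seconds.
#' @param confounds confound column names.
#' @return a `glm_result` data.frame with extra columns `measure`, `band`
#'   and `bin_center` (`NA` for the scalar GAS elements).
#' @export
group_contrast_spread <- function(spread_list, clinical, n_perm = 1000,
                                  seed = 1L, gas_window = c(1, 3),
                                  confounds = c("age", "sex", "missing_mri")) {
  ids <- vapply(spread_list, `[[`, character(1), "participant_id")
  if (!all(ids %in% clinical$participant_id)) {
    stop("clinical table is missing some participants")
  }
  if (!"group" %in% names(clinical)) stop("clinical table lacks a group column")
  clin <- clinical[match(ids, clinical$participant_id), ]

  s1 <- spread_list[[1]]
  bands <- s1$band_names
  nb <- length(s1$bin_centers)
  cols <- list(); meta <- list()
  for (measure in c("activated", "deactivated")) {
    for (bn in bands) {
      vals <- t(vapply(spread_list, function(s) s[[measure]][bn, ],
                       numeric(nb)))
      colnames(vals) <- sprintf("%s_%s_bin%02d", measure, bn, seq_len(nb))
      cols[[length(cols) + 1]] <- vals
      meta[[length(meta) + 1]] <- data.frame(
        measure = measure, band = bn, bin_center = s1$bin_centers,
        stringsAsFactors = FALSE)
    }
  }
  gas_bandset <- intersect(c("gamma", "high_gamma"), bands)
  for (bn in gas_bandset) {
    g <- vapply(spread_list, function(s) compute_gas(s, gas_window, bn)$gas,
                numeric(1))
    g <- matrix(g, ncol = 1,
                dimnames = list(NULL, sprintf("gas_%s", bn)))
    cols[[length(cols) + 1]] <- g
    meta[[length(meta) + 1]] <- data.frame(
      measure = "gas", band = bn, bin_center = NA_real_,
      stringsAsFactors = FALSE)
  }
  Y <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)

  des <- build_design(clin, "group", confounds)
  res <- permutation_test(Y, des$X, des$contrast, n_perm = n_perm,
                          seed = seed,
                          family = "all bands x bins x {activated, deactivated} + GAS scalars")
  out <- cbind(res, meta)
  for (a in c("n_perm", "seed", "method", "exhaustive", "df", "family")) {
    attr(out, a) <- attr(res, a)
  }
  class(out) <- c("glm_result", "data.frame")
  out
}

#' Association of GAS with a clinical outcome (ALS group)
#'
#' Regresses a clinical outcome on GAS plus confounds within the ALS group
#' and reports a permutation p value for the GAS coefficient. Each outcome
#' is its own family (no correction across outcomes).
#'
#' @param gas numeric vector of GAS values (or list of `gas_value`), one per
#'   ALS participant, aligned with `clinical` rows.
#' @param clinical clinical table restricted to (or containing only rows
#'   for) the same ALS participants.
#' @param outcome outcome column name, e.g. `"progression_rate"`,
#'   `"ALSFRS_R"`, `"ECAS"`, `"UMN_score"`, `"NfL"`, `"fine_motor_subscore"`.
#' @param confounds confound column names (default age and sex).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return a one-row `glm_result` with an `outcome` column.
#' @export
clinical_association <- function(gas, clinical, outcome,
                                 confounds = c("age", "sex"),
                                 n_perm = 5000, seed = 1L) {
  if (is.list(gas)) gas <- vapply(gas, `[[`, numeric(1), "gas")
  if ("group" %in% names(clinical) && all(clinical$group %in% c("HC", "ALS"))) {
    if (any(clinical$group != "ALS")) {
      if (length(gas) == sum(clinical$group == "ALS")) {
        clinical <- clinical[clinical$group == "ALS", ]
      } else {
        stop("clinical table must contain ALS participants only")
      }
    }
  }
  if (length(gas) != nrow(clinical)) {
    stop("one GAS value per ALS participant is required")
  }
  if (length(gas) < 10) warning("fewer than 10 ALS participants")
  if (stats::sd(gas) == 0) stop("GAS regressor is constant")
  y <- as.numeric(clinical[[outcome]])
  if (anyNA(y)) stop("outcome '", outcome, "' contains missing values")
  if (stats::sd(y) == 0) stop("outcome '", outcome, "' is constant")
  des <- build_design(clinical, gas, confounds, predictor_name = "GAS")
  res <- permutation_test(matrix(y, dimnames = list(NULL, outcome)),
                          des$X, des$contrast, n_perm = n_perm, seed = seed,
                          family = sprintf("single outcome: %s", outcome))
  res$outcome <- outcome
  res
}
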