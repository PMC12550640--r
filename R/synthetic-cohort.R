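# Synthetic two-wave adolescent cohorts with the statistical structure the
# downstream models assume: latent anxiety change measured by three
# indicators per wave, behavioral inhibition (BI) as moderator, true
# region-of-interest (ROI) neural signals per modality, and covariate-
# dependent (MAR) missingness.

#' Default generator configuration
#'
#' Returns the full set of generating parameters for the synthetic cohort.
#' Defaults emulate a two-wave community sample of 176 adolescents assessed
#' at ages 13 and 15: anxiety is a latent factor per wave measured by
#' parent SCARED (marker), child SCARED and a binary diagnosis; the latent
#' change factor has mean -0.76 and variance 14.30 SCARED units, with a
#' baseline variance (30) and baseline-change covariance (-14.35) chosen so
#' the implied wave-2 latent variance is ~15.6 SCARED units squared.
#' Neural generating values for the fusion modality reproduce an average
#' standardized increase of ~0.37 (dACC) and ~0.42 (PCC) in error
#' reactivity from 13 to 15.  Missingness is MAR on sex, minority status
#' and BI, with elevated rates for minority-status participants, averaging
#' ~25% per neuroimaging acquisition.
#'
#' @param ... named overrides, possibly nested lists (e.g.
#'   `anxiety = list(mean_delta = 0)` replaces only that entry)
#' @return a `generator_config` list
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_subjects = 176L,
    female_prob = 0.523,
    minority_prob = 0.244,
    bi = list(eta13_corr = 0.3),
    anxiety = list(
      mean_eta13 = 18, var_eta13 = 30,
      mean_delta = -0.76, var_delta = 14.30, cov_eta13_delta = -14.35,
      loadings = c(parent = 1, child = 0.9, dx = NA),   # dx is logistic
      intercepts = c(parent = 0, child = 2, dx = NA),
      resid_vars = c(parent = 20, child = 25)),
    dx_threshold = list(intercept = -2.2, slope = 0.08),
    neural = list(
      eeg = list(
        dacc = list(mean_13 = 0.60, mean_change = 0.10, var_13 = 0.10,
                    var_change = 0.05, cov = -0.01),
        pcc  = list(mean_13 = 0.45, mean_change = 0.12, var_13 = 0.09,
                    var_change = 0.05, cov = -0.01)),
      fmri = list(
        dacc = list(mean_13 = 0.50, mean_change = 0.12, var_13 = 0.12,
                    var_change = 0.06, cov = -0.01),
        pcc  = list(mean_13 = 0.40, mean_change = 0.10, var_13 = 0.10,
                    var_change = 0.05, cov = -0.01)),
      fusion = list(
        dacc = list(mean_13 = 0.50, mean_change = 0.17, var_13 = 0.16,
                    var_change = 0.07, cov = -0.01),
        pcc  = list(mean_13 = 0.40, mean_change = 0.18, var_13 = 0.11,
                    var_change = 0.09, cov = -0.01))),
    noise = list(roi_voxel_sd = 0.05, element_cdr_sd = 0.05,
                 epoch_noise_sd = 10),
    path = list(
      # final moderated path model generating coefficients; outcome is the
      # anxiety change score in SCARED units, predictors z-scored
      intercept = -0.76,
      b_sex = 1.0, b_minority = 0.5, b_bi = 1.5, b_anx13 = -3.0,
      b_dacc13 = 1.29, b_pcc13 = 0.5,
      b_dacc_ch = -4.90, b_pcc_ch = 2.58,
      b_bi_x_dacc13 = 8.77, b_bi_x_pcc13 = 0.5,
      b_bi_x_dacc_ch = 1.0, b_bi_x_pcc_ch = -16.89,
      r2 = 0.81,
      score_cor_within = 0.3, score_cor_13_ch = -0.2),
    blocks = list(
      # population variance contribution of each predictor block in the
      # incremental-validity generator
      r2 = c(block1 = 0.54, block2 = 0.01, block3 = 0.01, block4 = 0.25),
      score_cor_within = 0.3),
    missing = list(
      neural = list(intercept = -1.35, minority = 0.8, sex = 0, bi = 0.15),
      anx_15 = list(intercept = -2.34, minority = 0.8, sex = 0, bi = 0.15),
      anx_13 = list(intercept = -3.10, minority = 0.8, sex = 0, bi = 0.15)),
    geometry = list(
      box_mm = 48, mesh_spacing_mm = 6, voxel_mm = 3,
      dacc_box = list(lower = c(18, 27, 30), upper = c(30, 39, 42)),
      pcc_box  = list(lower = c(18, 6, 21),  upper = c(30, 18, 33))),
    epochs = list(
      srate = 250, window_ms = c(-200, 400), n_trials_error = 30,
      n_trials_correct = 60, ern_latency_ms = 50, ern_width_ms = 15,
      amp_per_unit = -8,
      channels = c("FCz", "Cz", "FC1", "FC2", "Fz", "Pz"),
      cluster = c("FCz", "Cz", "FC1", "FC2"))
  )
  cfg <- utils::modifyList(cfg, list(...))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  assert_prob(cfg$female_prob, "female_prob")
  assert_prob(cfg$minority_prob, "minority_prob")
  a <- cfg$anxiety
  if (a$var_eta13 < 0 || a$var_delta < 0) stop("variances must be >= 0")
  cv <- matrix(c(a$var_eta13, a$cov_eta13_delta,
                 a$cov_eta13_delta, a$var_delta), 2, 2)
  if (min(eigen(cv, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("anxiety (eta13, delta) covariance matrix is not positive ",
         "semidefinite: cov_eta13_delta = ", a$cov_eta13_delta,
         " exceeds sqrt(var_eta13 * var_delta)")
  }
  for (mod in names(cfg$neural)) for (reg in names(cfg$neural[[mod]])) {
    np <- cfg$neural[[mod]][[reg]]
    if (np$var_13 < 0 || np$var_change < 0) stop("neural variances must be >= 0")
    if (abs(np$cov) > sqrt(np$var_13 * np$var_change) + 1e-12) {
      stop("neural covariance exceeds PSD bound for ", mod, "/", reg)
    }
  }
  invisible(cfg)
}

#' Generate a synthetic cohort table and its latent truth
#'
#' Draws latent baseline anxiety and latent change from a bivariate normal,
#' builds the three indicators per wave (continuous indicators truncated to
#' the SCARED 0-82 range and rounded; diagnosis via a logistic link on the
#' latent), and draws true per-subject ROI activations for each modality,
#' region and wave.  Fully observed; see [apply_missingness()].
#'
#' @param config a [generator_config()]
#' @param seed integer seed (all randomness derives from it)
#' @return list with `cohort` (data.frame) and `truth` (data.frame of latent
#'   values and true ROI activations)
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_subjects
  a <- config$anxiety
  sex <- stats::rbinom(n, 1, config$female_prob)        # 1 = female
  minority <- stats::rbinom(n, 1, config$minority_prob)
  # BI correlated with baseline latent anxiety
  r <- config$bi$eta13_corr
  lat_cov <- matrix(c(a$var_eta13, a$cov_eta13_delta,
                      a$cov_eta13_delta, a$var_delta), 2, 2)
  lat <- rmvn(n, c(a$mean_eta13, a$mean_delta), lat_cov)
  eta13 <- lat[, 1]; delta <- lat[, 2]
  z13 <- (eta13 - a$mean_eta13) / sqrt(a$var_eta13)
  bi <- r * z13 + sqrt(1 - r^2) * stats::rnorm(n)
  eta15 <- eta13 + delta
  indicator <- function(eta, which) {
    lam <- a$loadings[[which]]; tau <- a$intercepts[[which]]
    rv <- a$resid_vars[[which]]
    x <- tau + lam * eta + stats::rnorm(n, 0, sqrt(rv))
    round(pmin(pmax(x, 0), 82))
  }
  dxt <- config$dx_threshold
  dx <- function(eta) stats::rbinom(n, 1, stats::plogis(dxt$intercept + dxt$slope * eta))
  cohort <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    sex = sex, minority = minority, bi = bi,
    scared_parent_13 = indicator(eta13, "parent"),
    scared_child_13 = indicator(eta13, "child"),
    dx_13 = dx(eta13),
    scared_parent_15 = indicator(eta15, "parent"),
    scared_child_15 = indicator(eta15, "child"),
    dx_15 = dx(eta15))
  truth <- data.frame(subject_id = cohort$subject_id,
                      eta13 = eta13, delta = delta, eta15 = eta15)
  for (mod in names(config$neural)) for (reg in names(config$neural[[mod]])) {
    np <- config$neural[[mod]][[reg]]
    cv <- matrix(c(np$var_13, np$cov, np$cov, np$var_change), 2, 2)
    draw <- rmvn(n, c(np$mean_13, np$mean_change), cv)
    truth[[paste(mod, reg, "13", sep = "_")]] <- draw[, 1]
    truth[[paste(mod, reg, "15", sep = "_")]] <- draw[, 1] + draw[, 2]
  }
  list(cohort = cohort, truth = truth)
}

mar_prob <- function(par, cohort) {
  lp <- par$intercept + par$minority * cohort$minority +
    par$sex * cohort$sex + par$bi * cohort$bi
  stats::plogis(lp)
}

#' Apply missing-at-random missingness to a cohort and its ROI scores
#'
#' Deletion is driven by a logistic model on the always-observed covariates
#' (sex, minority status, BI) only, so the mechanism is MAR.  Neuroimaging
#' missingness acts at the acquisition level (one indicator per modality
#' and wave): when an EEG or fMRI acquisition is removed the fusion score
#' for that wave is removed too, since it cannot exist without both inputs.
#' Wave-specific anxiety indicators are deleted jointly per wave.
#'
#' @param cohort cohort data.frame from [generate_cohort()]
#' @param scores optional wide score table (see [scores_wide()]) with
#'   columns `<modality>_<region>_<wave>`
#' @param config a [generator_config()]
#' @param seed integer seed
#' @return list with `cohort` and `scores` (the latter `NULL` if not given)
#' @export
apply_missingness <- function(cohort, scores = NULL,
                              config = generator_config(), seed = 1) {
  set.seed(seed)
  mp <- config$missing
  for (nm in c("neural", "anx_15", "anx_13")) {
    pr <- mar_prob(mp[[nm]], cohort)
    if (any(pr >= 1) || any(pr < 0)) stop("configured missing rate outside [0, 1)")
  }
  n <- nrow(cohort)
  miss15 <- stats::runif(n) < mar_prob(mp$anx_15, cohort)
  miss13 <- stats::runif(n) < mar_prob(mp$anx_13, cohort)
  for (col in c("scared_parent_15", "scared_child_15", "dx_15")) {
    cohort[[col]][miss15] <- NA
  }
  for (col in c("scared_parent_13", "scared_child_13", "dx_13")) {
    cohort[[col]][miss13] <- NA
  }
  if (!is.null(scores)) {
    for (wave in c("13", "15")) {
      miss_eeg <- stats::runif(n) < mar_prob(mp$neural, cohort)
      miss_fmri <- stats::runif(n) < mar_prob(mp$neural, cohort)
      for (reg in c("dacc", "pcc")) {
        ce <- paste("eeg", reg, wave, sep = "_")
        cf <- paste("fmri", reg, wave, sep = "_")
        cu <- paste("fusion", reg, wave, sep = "_")
        if (ce %in% names(scores)) scores[[ce]][miss_eeg] <- NA
        if (cf %in% names(scores)) scores[[cf]][miss_fmri] <- NA
        if (cu %in% names(scores)) scores[[cu]][miss_eeg | miss_fmri] <- NA
      }
    }
  }
  list(cohort = cohort, scores = scores)
}

#' Write / read a cohort table as CSV (empty cell = missing)
#' @param cohort cohort data.frame
#' @param path file path
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, na.strings = c("", "NA"))
}
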