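# Two-wave latent change score (LCS) models.
#
# Anxiety: each wave's anxiety is a latent factor with three indicators
# (parent SCARED as marker, child SCARED, binary diagnosis); the wave-2
# latent is the sum of the wave-1 latent and a latent change factor whose
# mean and variance are the quantities of interest.  Unstandardized
# loadings and indicator intercepts are constrained equal across waves
# (measurement invariance; intercept invariance is required on top of
# loading invariance so the mean structure is identified).
#
# Neural: one observed ROI score per wave per modality/region; residual
# variances fixed to 0 so the two-wave single-indicator LCS is identified
# and equals the classical difference score while retaining FIML handling
# of partially missing waves.

anx_vars <- c("scared_parent_13", "scared_child_13", "dx_13",
              "scared_parent_15", "scared_child_15", "dx_15")

#' Two-wave anxiety latent change score model
#'
#' @return an [sem_model()] with latents `eta13`, `delta`, `eta15`;
#'   free parameters: child/diagnosis loadings and intercepts (equal across
#'   waves), mean/variance of `eta13` and `delta` plus their covariance,
#'   and six indicator residual variances (15 parameters, df = 12)
#' @export
build_anxiety_lcs <- function() {
  lam_v <- matrix(0, 6, 3,
                  dimnames = list(anx_vars, c("eta13", "delta", "eta15")))
  lam_f <- lam_v == 1
  lam_l <- array(NA_character_, dim(lam_v))
  lam_v[1, 1] <- 1; lam_v[4, 3] <- 1                     # markers
  lam_v[2, 1] <- lam_v[5, 3] <- 1                        # start values
  lam_f[2, 1] <- lam_f[5, 3] <- TRUE
  lam_l[2, 1] <- lam_l[5, 3] <- "lam_child"
  lam_v[3, 1] <- lam_v[6, 3] <- 0.02
  lam_f[3, 1] <- lam_f[6, 3] <- TRUE
  lam_l[3, 1] <- lam_l[6, 3] <- "lam_dx"
  beta_v <- matrix(0, 3, 3)
  beta_v[3, 1] <- beta_v[3, 2] <- 1                      # eta15 = eta13 + delta
  psi_v <- diag(c(1, 1, 0)); psi_f <- matrix(FALSE, 3, 3)
  psi_f[1, 1] <- psi_f[2, 2] <- psi_f[2, 1] <- psi_f[1, 2] <- TRUE
  psi_l <- array(NA_character_, c(3, 3))
  psi_l[1, 1] <- "var_eta13"; psi_l[2, 2] <- "var_delta"
  psi_l[2, 1] <- psi_l[1, 2] <- "cov_eta13_delta"
  theta_v <- diag(1, 6); theta_f <- diag(6) == 1
  nu_v <- matrix(0, 6, 1); nu_f <- matrix(c(FALSE, TRUE, TRUE), 6, 1)
  nu_l <- matrix(c(NA, "tau_child", "tau_dx"), 6, 1)
  alpha_v <- matrix(0, 3, 1)
  alpha_f <- matrix(c(TRUE, TRUE, FALSE), 3, 1)
  alpha_l <- matrix(c("mean_eta13", "mean_delta", NA), 3, 1)
  sem_model(anx_vars, c("eta13", "delta", "eta15"),
            lambda = par_matrix(lam_v, lam_f, lam_l),
            beta = par_matrix(beta_v),
            psi = par_matrix(psi_v, psi_f, psi_l),
            theta = par_matrix(theta_v, theta_f),
            nu = par_matrix(nu_v, nu_f, nu_l),
            alpha = par_matrix(alpha_v, alpha_f, alpha_l))
}

#' Fit the anxiety LCS with data-driven starting values
#'
#' @param cohort cohort data.frame (columns `scared_parent_13`, ...)
#' @param se compute standard errors
#' @return an `sem_fit`
#' @export
fit_anxiety_lcs <- function(cohort, se = TRUE) {
  model <- build_anxiety_lcs()
  # subjects with no anxiety indicator at either wave carry no information
  cohort <- cohort[rowSums(!is.na(cohort[, anx_vars, drop = FALSE])) > 0,
                   , drop = FALSE]
  if (!nrow(cohort)) stop("no subject has any anxiety indicator data")
  data <- fiml_prepare(cohort, anx_vars)
  y <- data$y
  v1 <- stats::var(y[, 1], na.rm = TRUE)
  m1 <- mean(y[, 1], na.rm = TRUE)
  m4 <- mean(y[, 4], na.rm = TRUE)
  d_obs <- y[, 4] - y[, 1]
  slope <- function(j, i) {
    cc <- stats::complete.cases(y[, c(i, j)])
    if (sum(cc) < 3) return(1)
    stats::cov(y[cc, j], y[cc, i]) / stats::var(y[cc, i])
  }
  start <- c(
    lam_child = slope(2, 1), lam_dx = max(slope(3, 1), 0.001),
    var_eta13 = 0.6 * v1, var_delta = max(stats::var(d_obs, na.rm = TRUE), 1),
    cov_eta13_delta = tryCatch(
      stats::cov(y[, 1], d_obs, use = "complete.obs"), error = function(e) 0),
    theta_1 = 0.4 * v1, theta_2 = 0.4 * stats::var(y[, 2], na.rm = TRUE),
    theta_3 = 0.5 * stats::var(y[, 3], na.rm = TRUE),
    theta_4 = 0.4 * stats::var(y[, 4], na.rm = TRUE),
    theta_5 = 0.4 * stats::var(y[, 5], na.rm = TRUE),
    theta_6 = 0.5 * stats::var(y[, 6], na.rm = TRUE),
    tau_child = mean(y[, 2], na.rm = TRUE) - slope(2, 1) * m1,
    tau_dx = mean(y[, 3], na.rm = TRUE) - slope(3, 1) * m1,
    mean_eta13 = m1, mean_delta = m4 - m1)
  ord <- match(model$pars$free_labels,
               c("lam_child", "lam_dx", "var_eta13", "var_delta",
                 "cov_eta13_delta", "theta[1,1]", "theta[2,2]", "theta[3,3]",
                 "theta[4,4]", "theta[5,5]", "theta[6,6]",
                 "tau_child", "tau_dx", "mean_eta13", "mean_delta"))
  fit_sem(model, data, start = unname(start[ord]), se = se,
          check_identification = FALSE)
}

#' Two-wave single-indicator neural LCS model
#'
#' @param modality `"eeg"`, `"fmri"` or `"fusion"`
#' @param region `"dacc"` or `"pcc"`
#' @return an [sem_model()] on the observed pair
#'   `<modality>_<region>_{13,15}` with latents `level13` and `change`
#' @export
build_neural_lcs <- function(modality = c("eeg", "fmri", "fusion"),
                             region = c("dacc", "pcc")) {
  modality <- match.arg(modality); region <- match.arg(region)
  obs <- paste(modality, region, c("13", "15"), sep = "_")
  lam_v <- matrix(c(1, 1, 0, 1), 2, 2)                    # y13 = l13; y15 = l13 + ch
  psi_f <- matrix(TRUE, 2, 2)
  psi_l <- matrix(c("var_13", "cov_13_change", "cov_13_change", "var_change"),
                  2, 2)
  alpha_f <- matrix(TRUE, 2, 1)
  alpha_l <- matrix(c("mean_13", "mean_change"), 2, 1)
  sem_model(obs, c("level13", "change"),
            lambda = par_matrix(lam_v),
            psi = par_matrix(diag(c(0.5, 0.5)), psi_f, psi_l),
            theta = par_matrix(matrix(0, 2, 2)),
            alpha = par_matrix(matrix(0, 2, 1), alpha_f, alpha_l))
}

#' Fit a neural LCS model
#' @param scores wide score table with `<modality>_<region>_<wave>` columns
#' @inheritParams build_neural_lcs
#' @param se compute standard errors
#' @export
fit_neural_lcs <- function(scores, modality, region, se = TRUE) {
  model <- build_neural_lcs(modality, region)
  # subjects with neither wave observed carry no information for this model
  scores <- scores[rowSums(!is.na(scores[, model$observed, drop = FALSE])) > 0,
                   , drop = FALSE]
  if (!nrow(scores)) stop("no subject has any ", paste(model$observed[1]),
                          " data")
  data <- fiml_prepare(scores, model$observed)
  y <- data$y
  d_obs <- y[, 2] - y[, 1]
  safe_cov <- function(a, b) {
    tryCatch(stats::cov(a, b, use = "complete.obs"), error = function(e) 0)
  }
  start <- c(max(stats::var(y[, 1], na.rm = TRUE), 1e-4),
             safe_cov(y[, 1], d_obs),
             max(stats::var(d_obs, na.rm = TRUE), 1e-4),
             mean(y[, 1], na.rm = TRUE),
             mean(d_obs, na.rm = TRUE))
  names(start) <- c("var_13", "cov_13_change", "var_change",
                    "mean_13", "mean_change")
  if (!is.finite(start["cov_13_change"])) start["cov_13_change"] <- 0
  if (!is.finite(start["var_change"]) || start["var_change"] <= 0) {
    start["var_change"] <- 1e-3
  }
  if (!is.finite(start["mean_change"])) start["mean_change"] <- 0
  fit_sem(model, data, start = unname(start[model$pars$free_labels]), se = se,
          check_identification = FALSE)
}

#' Standardized latent change, relative to the wave-2 latent scale
#'
#' Expresses the change factor's mean and variance on the scale of the
#' implied wave-2 latent, `var(eta15) = var13 + var_change + 2 cov`:
#' `mean_change / sd(eta15)` and `var_change / var(eta15)`.  This makes
#' change estimates comparable across regions and modalities measured in
#' arbitrary units.
#'
#' @param fit an `sem_fit` from [fit_anxiety_lcs()] or [fit_neural_lcs()]
#' @return list: `mean_std`, `var_std`, `var_wave2`
#' @export
lcs_standardized_change <- function(fit) {
  th <- fit$theta
  pick <- function(a, b) if (a %in% names(th)) unname(th[a]) else unname(th[b])
  v13 <- pick("var_13", "var_eta13")
  vch <- pick("var_change", "var_delta")
  cv <- pick("cov_13_change", "cov_eta13_delta")
  mch <- pick("mean_change", "mean_delta")
  v15 <- v13 + vch + 2 * cv
  if (v15 <= 0) stop("implied wave-2 latent variance is not positive")
  list(mean_std = mch / sqrt(v15), var_std = vch / v15, var_wave2 = v15)
}

#' Baseline and change factor scores for all six neural LCS models
#'
#' Fits the six modality-by-region LCS models and extracts regression-
#' method factor scores.  With complete data and zero residual variances
#' the change score equals the observed wave difference exactly; with a
#' missing wave the score is the model-based conditional expectation and
#' is flagged in the `model_based` attribute.
#'
#' @param scores wide score table
#' @param modalities,regions which models to fit
#' @param se compute SEs on the underlying fits
#' @return data.frame of `<modality>_<region>_13` (baseline score) and
#'   `<modality>_<region>_ch` (change score) columns; attribute
#'   `model_based` marks scores computed from a partial pattern; attribute
#'   `fits` carries the six fits
#' @export
estimate_change_scores <- function(scores,
                                   modalities = c("eeg", "fmri", "fusion"),
                                   regions = c("dacc", "pcc"), se = FALSE) {
  out <- data.frame(row.names = seq_len(nrow(scores)))
  if ("subject_id" %in% names(scores)) out$subject_id <- scores$subject_id
  mb <- list()
  fits <- list()
  for (mod in modalities) for (reg in regions) {
    cols <- paste(mod, reg, c("13", "15"), sep = "_")
    if (!all(cols %in% names(scores))) next
    fit <- fit_neural_lcs(scores, mod, reg, se = se)
    fits[[paste(mod, reg, sep = "_")]] <- fit
    # factor_scores drops all-missing rows; re-align on the full table
    keep <- rowSums(!is.na(scores[, cols])) > 0
    fs <- factor_scores(fit, fiml_prepare(scores[keep, cols, drop = FALSE],
                                          cols))
    b <- rep(NA_real_, nrow(scores)); ch <- rep(NA_real_, nrow(scores))
    b[keep] <- fs[, "level13"]; ch[keep] <- fs[, "change"]
    out[[paste(mod, reg, "13", sep = "_")]] <- b
    out[[paste(mod, reg, "ch", sep = "_")]] <- ch
    flag <- keep & rowSums(is.na(scores[, cols])) > 0
    mb[[paste(mod, reg, sep = "_")]] <- flag
  }
  attr(out, "model_based") <- as.data.frame(mb)
  attr(out, "fits") <- fits
  out
}
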