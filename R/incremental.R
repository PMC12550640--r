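# Blockwise incremental validity: sequential semipartial block
# contributions to explained variance in anxiety change, the focused
# moderated path model, and simple-slopes probing.
#
# The block quantities are the semipartial multiple correlations gamma_k of
# each predictor block with the outcome after removing all earlier blocks,
# so gamma_k^2 is the block's increment to R^2.  They are estimated from
# the FIML (saturated-model) joint moments of predictors and outcome: for
# a just-identified model this is the exact maximum-likelihood solution,
# and on complete data the increments agree with hierarchical OLS exactly
# (the normative contract; see ols_hierarchical_r2).

#' Default predictor block specification
#'
#' Block 1: confounders (sex, minority status, BI, baseline anxiety);
#' blocks 2-4: EEG-only, fMRI-only and EEG-fMRI fusion ROI baseline/change
#' scores plus their BI interactions, in that fixed order.
#'
#' @param include_interactions append `_x_bi` product terms to the neural
#'   blocks
#' @return named list of character vectors (class `block_spec`)
#' @export
block_spec <- function(include_interactions = TRUE) {
  neural <- function(mod) {
    sc <- c(paste(mod, "dacc", c("13", "ch"), sep = "_"),
            paste(mod, "pcc", c("13", "ch"), sep = "_"))
    if (include_interactions) c(sc, paste0(sc, "_x_bi")) else sc
  }
  structure(list(block1 = c("sex", "minority", "bi", "anx13"),
                 block2 = neural("eeg"),
                 block3 = neural("fmri"),
                 block4 = neural("fusion")),
            class = "block_spec")
}

#' Append BI-by-score interaction terms
#'
#' Z-scores BI and each score column (observed-case mean/SD), then appends
#' their products as `<score>_x_bi`.  A missing score yields a missing
#' product, never zero.
#'
#' @param data data.frame containing `bi` and the score columns
#' @param score_cols columns to interact with BI
#' @return `data` with product columns appended
#' @export
build_interaction_terms <- function(data, score_cols) {
  missing_cols <- setdiff(c("bi", score_cols), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bi_z <- tryCatch(zscore(data$bi),
                   error = function(e) stop("zero-variance input: bi"))
  for (col in score_cols) {
    z <- tryCatch(zscore(data[[col]]),
                  error = function(e) stop("zero-variance input: ", col))
    data[[paste0(col, "_x_bi")]] <- bi_z * z
  }
  data
}

#' Build the blockwise incremental model
#'
#' @param blocks a [block_spec()] (or any named list of disjoint predictor
#'   sets in the intended entry order)
#' @param outcome name of the outcome column (the anxiety change score)
#' @return a `block_model` specification consumed by [fit_incremental()]
#' @export
build_block_model <- function(blocks = block_spec(), outcome = "anx_ch") {
  vars <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(vars)) stop("predictor blocks must be disjoint")
  if (outcome %in% vars) stop("outcome cannot appear in a block")
  structure(list(blocks = blocks, outcome = outcome), class = "block_model")
}

# R^2 of the outcome on a predictor subset, from a joint covariance matrix.
r2_from_sigma <- function(sigma, outcome, predictors) {
  if (!length(predictors)) return(0)
  sxx <- sigma[predictors, predictors, drop = FALSE]
  sxy <- sigma[predictors, outcome]
  drop(crossprod(sxy, solve(sxx, sxy))) / sigma[outcome, outcome]
}

#' Fit the incremental-validity model
#'
#' Estimates the joint predictor/outcome moments by FIML (EM for the
#' saturated Gaussian model), derives each block's semipartial multiple
#' correlation gamma_k and increment delta-R^2 = gamma_k^2, and tests each
#' increment with the hierarchical F-form test (numerator df = block size),
#' which on complete data is the classical hierarchical-regression test of
#' the same hypothesis.  `se = TRUE` adds a delta-method standard error for
#' each gamma_k (Wishart covariance of the fitted moments).
#'
#' @param model a [build_block_model()] specification
#' @param data data.frame containing outcome and all block predictors
#'   (missing values handled by FIML)
#' @param se compute delta-method SEs for gamma (slower)
#' @param alpha two-sided significance level used to flag blocks
#' @return an `incremental_result`: per-block table plus fitted moments
#' @export
fit_incremental <- function(model, data, se = FALSE, alpha = 0.05) {
  vars <- c(model$outcome, unlist(model$blocks, use.names = FALSE))
  prep <- fiml_prepare(data, vars)
  sat <- fiml_saturated_moments(prep)
  if (!sat$converged) warning("saturated-moment EM did not converge")
  sigma <- sat$sigma
  within_rank_check(sigma, model$blocks)
  n <- sat$n
  k <- length(model$blocks)
  cum_r2 <- numeric(k)
  preds <- character()
  for (b in seq_len(k)) {
    preds <- c(preds, model$blocks[[b]])
    cum_r2[b] <- r2_from_sigma(sigma, model$outcome, preds)
  }
  delta_r2 <- diff(c(0, cum_r2))
  gamma <- sqrt(pmax(delta_r2, 0))
  p_k <- lengths(model$blocks)
  p_cum <- cumsum(p_k)
  fstat <- (delta_r2 / p_k) / ((1 - cum_r2) / (n - 1 - p_cum))
  pval <- stats::pf(fstat, p_k, n - 1 - p_cum, lower.tail = FALSE)
  se_gamma <- rep(NA_real_, k)
  if (se) se_gamma <- gamma_delta_se(sigma, n, model)
  tab <- data.frame(
    block = names(model$blocks),
    n_predictors = unname(p_k),
    gamma = gamma,
    se_gamma = se_gamma,
    delta_r2 = delta_r2,
    cum_r2 = cum_r2,
    statistic = unname(fstat),
    df1 = unname(p_k),
    df2 = unname(n - 1 - p_cum),
    pvalue = unname(pval),
    significant = unname(pval < alpha),
    row.names = NULL)
  structure(list(blocks = tab, r2_total = cum_r2[k], n = n,
                 moments = sat, model = model, alpha = alpha),
            class = "incremental_result")
}

within_rank_check <- function(sigma, blocks) {
  for (b in names(blocks)) {
    s <- sigma[blocks[[b]], blocks[[b]], drop = FALSE]
    ev <- eigen(stats::cov2cor(s), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      warning("near-collinear predictors within ", b, ": ",
              paste(blocks[[b]], collapse = ", "))
    }
  }
}

# Delta-method SE of gamma_k over the half-vectorized joint covariance,
# using the Wishart covariance of covariance estimates (complete-data
# approximation under missingness).
gamma_delta_se <- function(sigma, n, model) {
  vars <- c(model$outcome, unlist(model$blocks, use.names = FALSE))
  sigma <- sigma[vars, vars]
  p <- length(vars)
  lt <- which(lower.tri(sigma, diag = TRUE), arr.ind = TRUE)
  gfun <- function(svec) {
    s <- matrix(0, p, p, dimnames = dimnames(sigma))
    s[lower.tri(s, diag = TRUE)] <- svec
    s <- s + t(s) - diag(diag(s))
    preds <- character(); out <- numeric(length(model$blocks))
    prev <- 0
    for (b in seq_along(model$blocks)) {
      preds <- c(preds, model$blocks[[b]])
      r2 <- r2_from_sigma(s, model$outcome, preds)
      out[b] <- sqrt(max(r2 - prev, 0))
      prev <- r2
    }
    out
  }
  s0 <- sigma[lower.tri(sigma, diag = TRUE)]
  jac <- vapply(seq_along(s0), function(i) {
    h <- 1e-6 * (abs(s0[i]) + 1)
    sp <- s0; sm <- s0
    sp[i] <- s0[i] + h; sm[i] <- s0[i] - h
    (gfun(sp) - gfun(sm)) / (2 * h)
  }, numeric(length(model$blocks)))
  v <- matrix(0, length(s0), length(s0))
  for (a in seq_along(s0)) {
    i <- lt[a, 1]; j <- lt[a, 2]
    for (b2 in seq_len(a)) {
      kk <- lt[b2, 1]; ll <- lt[b2, 2]
      v[a, b2] <- v[b2, a] <-
        (sigma[i, kk] * sigma[j, ll] + sigma[i, ll] * sigma[j, kk]) / n
    }
  }
  sqrt(pmax(diag(jac %*% v %*% t(jac)), 0))
}

#' Hierarchical OLS delta-R^2 (independent oracle)
#'
#' Least-squares R^2 after cumulatively adding each block, on complete
#' data.  This is the normative definition the blockwise model must match.
#'
#' @param data complete-case data.frame
#' @param blocks named list of predictor sets
#' @param outcome outcome column
#' @return list: `cum_r2`, `delta_r2`
#' @export
ols_hierarchical_r2 <- function(data, blocks, outcome) {
  vars <- c(outcome, unlist(blocks, use.names = FALSE))
  if (any(is.na(data[, vars]))) stop("ols_hierarchical_r2 requires complete data")
  cum_r2 <- numeric(length(blocks))
  preds <- character()
  for (b in seq_along(blocks)) {
    preds <- c(preds, blocks[[b]])
    x <- as.matrix(data[, preds, drop = FALSE])
    if (qr(cbind(1, scale(x, scale = FALSE)))$rank < ncol(x) + 1) {
      # redundant columns are allowed (delta-R^2 = 0), a fully singular
      # first block is not
      if (b == 1 && qr(x)$rank == 0) stop("singular design")
    }
    f <- stats::lm(stats::reformulate(preds, response = outcome), data = data)
    cum_r2[b] <- summary(f)$r.squared
  }
  list(cum_r2 = cum_r2, delta_r2 = diff(c(0, cum_r2)))
}

#' Fit the focused moderated path model
#'
#' Regression of the anxiety change score on sex, minority status, BI,
#' baseline anxiety, the selected modality's ROI baseline and change
#' scores, and the BI interactions, estimated by FIML (saturated exogenous
#' moments via EM; the exact ML solution for this just-identified model).
#' All predictors are z-scored before entry, so unstandardized coefficients
#' are in outcome units per predictor SD.  Standard errors come from the
#' observed information of the full just-identified parameter set,
#' numerically differentiated, and are needed for [simple_slopes()].
#'
#' @param data data.frame with covariates, scores and outcome
#' @param modality neural modality entering the model (default fusion)
#' @param outcome outcome column
#' @param extra_covariates optional additional block-1 style covariates
#'   (e.g. maternal education), z-scored and entered alongside the rest
#' @param se compute the observed-information coefficient covariance
#' @return a `path_fit`: coefficient table, vcov, R^2
#' @export
fit_final_path <- function(data, modality = "fusion", outcome = "anx_ch",
                           extra_covariates = character(), se = TRUE) {
  scores <- c(paste(modality, "dacc", c("13", "ch"), sep = "_"),
              paste(modality, "pcc", c("13", "ch"), sep = "_"))
  base <- c("sex", "minority", "bi", "anx13", extra_covariates)
  need <- c(base, scores, outcome)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- data[, need, drop = FALSE]
  for (v in c(base, scores)) df[[v]] <- zscore(df[[v]])
  df <- build_interaction_terms(df, scores)
  predictors <- c(base, scores, paste0(scores, "_x_bi"))
  prep <- fiml_prepare(df, c(predictors, outcome))
  sat <- fiml_saturated_moments(prep)
  sigma <- sat$sigma; mu <- sat$mu
  sxx <- sigma[predictors, predictors]
  sxy <- sigma[predictors, outcome]
  b <- solve(sxx, sxy)
  intercept <- mu[outcome] - sum(b * mu[predictors])
  resid_var <- sigma[outcome, outcome] - drop(crossprod(sxy, b))
  r2 <- 1 - resid_var / sigma[outcome, outcome]
  beta_std <- b * sqrt(diag(sxx)) / sqrt(sigma[outcome, outcome])
  vcov_b <- matrix(NA_real_, length(b), length(b),
                   dimnames = list(predictors, predictors))
  if (se) vcov_b <- path_vcov(prep, sat, predictors, outcome)
  se_b <- sqrt(pmax(diag(vcov_b), 0))
  z <- b / se_b
  tab <- data.frame(
    term = predictors, b = unname(b), beta = unname(beta_std),
    se = unname(se_b), z = unname(z),
    pvalue = 2 * stats::pnorm(-abs(unname(z))),
    ci_lower = unname(b - 1.96 * se_b), ci_upper = unname(b + 1.96 * se_b),
    row.names = NULL)
  structure(list(coefficients = tab, vcov = vcov_b, intercept = intercept,
                 resid_var = resid_var, r2 = r2, n = sat$n,
                 moments = sat, outcome = outcome, modality = modality,
                 data_z = df),
            class = "path_fit")
}

# Observed-information covariance of the regression coefficients: numeric
# Hessian of the FIML log-likelihood over the full just-identified
# parameterization (mu, vech Sigma), then delta method onto b.
path_vcov <- function(prep, sat, predictors, outcome) {
  vars <- c(predictors, outcome)
  p <- length(vars)
  sigma <- sat$sigma[vars, vars]; mu <- sat$mu[vars]
  ltidx <- which(lower.tri(sigma, diag = TRUE))
  pack <- function(m, s) c(m, s[ltidx])
  unpack <- function(th) {
    m <- th[seq_len(p)]
    s <- matrix(0, p, p)
    s[lower.tri(s, diag = TRUE)] <- th[-seq_len(p)]
    s <- s + t(s) - diag(diag(s))
    dimnames(s) <- list(vars, vars)
    list(mu = stats::setNames(m, vars), sigma = s)
  }
  th0 <- pack(mu, sigma)
  negll <- function(th) {
    ms <- unpack(th)
    -as.numeric(fiml_loglik_moments(ms$mu, ms$sigma, prep))
  }
  hess <- num_hessian(negll, th0, h = 1e-4 * (abs(th0) + 1))
  ev <- eigen(hess, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-10 * max(abs(ev$values)))
  vinfo <- ev$vectors %*% ((1 / vals) * t(ev$vectors))
  bfun <- function(th) {
    ms <- unpack(th)
    drop(solve(ms$sigma[predictors, predictors],
               ms$sigma[predictors, outcome]))
  }
  jac <- vapply(seq_along(th0), function(i) {
    h <- 1e-5 * (abs(th0[i]) + 1)
    tp <- th0; tm <- th0
    tp[i] <- th0[i] + h; tm[i] <- th0[i] - h
    (bfun(tp) - bfun(tm)) / (2 * h)
  }, numeric(length(predictors)))
  v <- jac %*% vinfo %*% t(jac)
  dimnames(v) <- list(predictors, predictors)
  symm(v)
}

#' Probe a moderated association at fixed moderator values
#'
#' Conditional slope of the focal predictor at the moderator one SD below
#' the mean, at the mean, and one SD above (the moderator is z-scored, so
#' levels are in SD units): `slope(m) = b_focal + m * b_interaction`, with
#' delta-method standard errors from the coefficient covariance.
#'
#' @param fit a `path_fit` with standard errors
#' @param focal focal predictor term name (e.g. `"fusion_dacc_13"`)
#' @param levels moderator values in SD units
#' @return data.frame: level, slope, se, z, pvalue, ci bounds
#' @export
simple_slopes <- function(fit, focal, levels = c(-1, 0, 1)) {
  inter <- paste0(focal, "_x_bi")
  tab <- fit$coefficients
  if (!focal %in% tab$term) stop("no focal term ", focal)
  if (!inter %in% tab$term) stop("model has no ", inter, " product term")
  bf <- tab$b[tab$term == focal]
  bi <- tab$b[tab$term == inter]
  vv <- fit$vcov[c(focal, inter), c(focal, inter)]
  slope <- bf + levels * bi
  se <- sqrt(vv[1, 1] + levels^2 * vv[2, 2] + 2 * levels * vv[1, 2])
  z <- slope / se
  data.frame(level = levels, slope = slope, se = se, z = z,
             pvalue = 2 * stats::pnorm(-abs(z)),
             ci_lower = slope - 1.96 * se, ci_upper = slope + 1.96 * se)
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Blockwise incremental validity (FIML, n = %d)\n", x$n))
  print(x$blocks, digits = 3)
  cat(sprintf("total R^2 = %.3f\n", x$r2_total))
  invisible(x)
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Moderated path model (%s), n = %d, R^2 = %.3f\n",
              x$modality, x$n, x$r2))
  print(x$coefficients, digits = 3)
  invisible(x)
}
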