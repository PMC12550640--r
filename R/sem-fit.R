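# Fitting, inference, standardization, fit indices and factor scores.

num_gradient <- function(f, x, h = NULL) {
  h <- h %||% (1e-6 * (abs(x) + 1))
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    g[i] <- (f(xp) - f(xm)) / (2 * h[i])
  }
  g
}

num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  h <- h %||% (1e-4 * (abs(x) + 1))
  hess <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
    hess[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    if (i < k) for (j in seq((i + 1), k)) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      hess[i, j] <- hess[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  symm(hess)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

# Data-driven start values: free intercepts at sample means, free residual
# variances at half the sample variance, marker-scaled latent means at the
# marker's sample mean, free loadings at 1 when unset.
sem_start_values <- function(model, data) {
  theta <- model$pars$start
  labs <- model$pars$free_labels
  y <- data$y
  smean <- colMeans(y, na.rm = TRUE)
  svar <- apply(y, 2, stats::var, na.rm = TRUE)
  svar[!is.finite(svar) | svar <= 0] <- 1
  marker_of <- function(j) {
    lam <- model$lambda
    cand <- which(!lam$free[, j] & abs(lam$value[, j] - 1) < 1e-12)
    if (length(cand)) cand[1] else NA_integer_
  }
  for (k in seq_along(model$pars$entries)) {
    e <- model$pars$entries[[k]]
    pos <- match(model$pars$labels[k], labs)
    cur <- theta[pos]
    if (e$matrix == "nu") theta[pos] <- smean[e$i]
    if (e$matrix == "theta" && e$i == e$j && cur == 0) {
      theta[pos] <- 0.5 * svar[e$i]
    }
    if (e$matrix == "lambda" && cur == 0) theta[pos] <- 1
    if (e$matrix == "alpha" && cur == 0) {
      mk <- marker_of(e$i)
      if (!is.na(mk) && !model$nu$free[mk, 1]) {
        theta[pos] <- smean[mk] - model$nu$value[mk, 1]
      }
    }
    if (e$matrix == "psi" && e$i == e$j && cur == 0) {
      mk <- marker_of(e$i)
      theta[pos] <- if (!is.na(mk)) 0.5 * svar[mk] else 0.5
    }
  }
  theta
}

sem_check_identified <- function(model, theta) {
  th <- theta * (1 + 0.013 * seq_along(theta)) + 0.007 * seq_along(theta)
  momvec <- function(t) {
    mom <- model_implied_moments(model, t)
    c(mom$mu, mom$sigma[lower.tri(mom$sigma, diag = TRUE)])
  }
  jac <- vapply(seq_along(th), function(i) {
    h <- 1e-5 * (abs(th[i]) + 1)
    tp <- th; tm <- th
    tp[i] <- th[i] + h; tm[i] <- th[i] - h
    (momvec(tp) - momvec(tm)) / (2 * h)
  }, numeric(length(model$observed) * (length(model$observed) + 3) / 2))
  if (length(th) && qr(jac)$rank < length(th)) {
    stop("model is not identified: the implied-moment Jacobian is rank ",
         qr(jac)$rank, " for ", length(th), " free parameters")
  }
  invisible(TRUE)
}

#' Fit a structural equation model by full-information maximum likelihood
#'
#' Maximizes the casewise Gaussian log-likelihood over each case's observed
#' subvector, so incomplete cases are retained.  Standard errors come from
#' the inverse observed information (numerically differentiated at the
#' optimum); equality constraints are honored exactly because constrained
#' cells share one free parameter.
#'
#' @param model an [sem_model()]
#' @param data data.frame/matrix of observed variables, or a prepared
#'   `fiml_data`
#' @param start optional start vector overriding the data-driven defaults
#' @param se compute standard errors (numeric observed information); can be
#'   switched off in simulation loops where only point estimates are needed
#' @param max_restarts seeded-jitter restarts on non-convergence
#' @param check_identification run the pre-fit implied-moment rank check
#' @return object of class `sem_fit`
#' @export
fit_sem <- function(model, data, start = NULL, se = TRUE,
                    max_restarts = 5, check_identification = TRUE) {
  if (!inherits(data, "fiml_data")) data <- fiml_prepare(data, model$observed)
  npar <- n_free_params(model)
  p <- length(model$observed)
  nmom <- p * (p + 3) / 2
  if (npar > nmom) stop("more free parameters than observed moments")
  theta0 <- start %||% sem_start_values(model, data)
  if (check_identification && npar > 0) sem_check_identified(model, theta0)
  if (data$n <= npar) {
    warning("sample size does not exceed the number of free parameters")
  }
  negll <- function(t) {
    ll <- fiml_loglik(model, t, data)
    -as.numeric(ll)
  }
  best <- NULL
  restarts_used <- 0L
  for (attempt in 0:max_restarts) {
    th_try <- theta0
    if (attempt > 0) {
      with_preserved_rng({
        set.seed(1000L + attempt)
        th_try <- theta0 * stats::runif(npar, 0.7, 1.3) +
          stats::runif(npar, -0.1, 0.1)
      })
    }
    opt <- tryCatch(
      stats::nlminb(th_try, negll,
                    control = list(rel.tol = 1e-10, iter.max = 1000,
                                   eval.max = 4000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    grad <- num_gradient(negll, opt$par)
    ok <- opt$convergence == 0 &&
      max(abs(grad)) < 1e-4 * (1 + abs(opt$objective))
    if (is.null(best) || opt$objective < best$objective - 1e-9 ||
        (ok && !best$ok)) {
      best <- list(opt = opt, ok = ok, objective = opt$objective)
    }
    restarts_used <- attempt
    if (ok) break
  }
  if (is.null(best)) stop("optimization failed on all starts")
  opt <- best$opt
  theta_hat <- opt$par
  names(theta_hat) <- model$pars$free_labels
  ll <- -opt$objective
  vc <- matrix(NA_real_, npar, npar)
  se_vec <- rep(NA_real_, npar)
  se_ok <- FALSE
  if (se && npar > 0) {
    hess <- num_hessian(negll, theta_hat)
    ev <- eigen(hess, symmetric = TRUE)
    if (all(ev$values > 0)) {
      vc <- chol2inv(chol(hess))
      se_ok <- TRUE
    } else {
      vals <- pmax(ev$values, 1e-10 * max(abs(ev$values)))
      vc <- ev$vectors %*% ((1 / vals) * t(ev$vectors))
      warning("observed information not positive definite; ",
              "standard errors from a clipped pseudo-inverse")
    }
    se_vec <- sqrt(pmax(diag(vc), 0))
    dimnames(vc) <- list(model$pars$free_labels, model$pars$free_labels)
  }
  z <- theta_hat / se_vec
  est <- data.frame(
    label = model$pars$free_labels,
    est = unname(theta_hat),
    se = se_vec,
    z = unname(z),
    pvalue = 2 * stats::pnorm(-abs(unname(z))),
    ci_lower = unname(theta_hat - 1.96 * se_vec),
    ci_upper = unname(theta_hat + 1.96 * se_vec),
    row.names = NULL)
  fitted_model <- sem_set_params(model, theta_hat)
  structure(list(
    model = fitted_model,
    estimates = est,
    theta = theta_hat,
    vcov = vc,
    loglik = ll,
    n = data$n,
    npar = npar,
    df = nmom - npar,
    converged = best$ok,
    se_ok = se_ok,
    restarts = restarts_used,
    implied = model_implied_moments(fitted_model),
    data = data), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("FIML fit: %d cases, %d free parameters, df = %d\n",
              x$n, x$npar, x$df))
  cat(sprintf("log-likelihood = %.4f, converged = %s\n",
              x$loglik, x$converged))
  print(x$estimates, digits = 4)
  invisible(x)
}

#' Extract a parameter estimate by label
#' @param fit an `sem_fit`
#' @param label parameter label
#' @export
coef_sem <- function(fit, label = NULL) {
  if (is.null(label)) return(fit$theta)
  if (!label %in% names(fit$theta)) stop("no parameter labeled ", label)
  unname(fit$theta[label])
}

#' Standardized solution
#'
#' Paths are rescaled by implied SD(source)/SD(target); (co)variances of
#' standardized variables become correlations (variances 1), residual
#' variances become proportions of total variance.
#'
#' @param fit a converged `sem_fit`
#' @return list of standardized matrices plus a per-parameter table
#' @export
standardize <- function(fit) {
  model <- fit$model
  p <- length(model$observed); m <- length(model$latent)
  sigma <- fit$implied$sigma
  sd_y <- sqrt(diag(sigma))
  if (any(sd_y <= 0)) {
    stop("zero implied variance for ",
         paste(model$observed[sd_y <= 0], collapse = ", "))
  }
  out <- list()
  if (m > 0) {
    inv <- solve(diag(m) - model$beta$value)
    c_eta <- symm(inv %*% model$psi$value %*% t(inv))
    sd_eta <- sqrt(pmax(diag(c_eta), 0))
    if (any(sd_eta <= 0)) {
      stop("zero implied variance for latent ",
           paste(model$latent[sd_eta <= 0], collapse = ", "))
    }
    out$lambda <- model$lambda$value * outer(1 / sd_y, sd_eta)
    out$beta <- model$beta$value * outer(1 / sd_eta, sd_eta)
    out$psi <- model$psi$value / outer(sd_eta, sd_eta)
    out$alpha <- drop(model$alpha$value) / sd_eta
    out$latent_sd <- stats::setNames(sd_eta, model$latent)
  }
  out$theta <- model$theta$value / outer(sd_y, sd_y)
  out$nu <- drop(model$nu$value) / sd_y
  out$observed_sd <- stats::setNames(sd_y, model$observed)
  # per-free-parameter standardized values
  std_of <- function(e) {
    if (e$matrix == "lambda") return(out$lambda[e$i, e$j])
    if (e$matrix == "beta") return(out$beta[e$i, e$j])
    if (e$matrix == "psi") return(out$psi[e$i, e$j])
    if (e$matrix == "theta") return(out$theta[e$i, e$j])
    if (e$matrix == "alpha") return(out$alpha[e$i])
    if (e$matrix == "nu") return(out$nu[e$i])
    NA_real_
  }
  std_by_label <- vapply(model$pars$entries, std_of, 0)
  tab <- data.frame(label = model$pars$labels, std_est = std_by_label)
  tab <- tab[!duplicated(tab$label), , drop = FALSE]
  out$table <- merge(fit$estimates, tab, by = "label", sort = FALSE)
  out
}

#' Likelihood-based fit indices (plain maximum-likelihood variants)
#'
#' RMSEA, CFI against the independence baseline, and SRMR over standardized
#' covariance residuals.  For a just-identified model (df = 0) the indices
#' are reported as `NA` (not applicable).
#'
#' @param fit an `sem_fit`
#' @return list with `chisq`, `df`, `rmsea`, `srmr`, `cfi`
#' @export
fit_indices <- function(fit) {
  data <- fit$data
  sat <- fiml_saturated_moments(data)
  chisq <- max(2 * (sat$loglik - fit$loglik), 0)
  df <- fit$df
  n <- fit$n
  if (df <= 0) {
    return(list(chisq = chisq, df = df, rmsea = NA_real_, srmr = NA_real_,
                cfi = NA_real_, note = "model is just-identified"))
  }
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  ind <- fiml_independence(data)
  p <- length(fit$model$observed)
  nmom <- p * (p + 3) / 2
  chisq_i <- max(2 * (sat$loglik - ind$loglik), 0)
  df_i <- nmom - ind$df_free
  cfi <- 1 - max(chisq - df, 0) / max(chisq_i - df_i, chisq - df, .Machine$double.eps)
  s <- sat$sigma; sig <- fit$implied$sigma
  d <- sqrt(diag(s))
  res <- (s - sig) / outer(d, d)
  srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
  list(chisq = chisq, df = df, rmsea = rmsea, srmr = srmr, cfi = cfi)
}

#' Regression-method (empirical Bayes) factor scores
#'
#' Conditional expectation of the latent variables given each case's
#' observed subvector under the fitted model, computed per missingness
#' pattern.  A latent with no observed correlate in a case's pattern gets
#' `NA` rather than a silently prior-mean score.
#'
#' @param fit a converged `sem_fit`
#' @param data optional new data (defaults to the fitting data)
#' @return n x n_latent matrix of scores
#' @export
factor_scores <- function(fit, data = NULL) {
  model <- fit$model
  m <- length(model$latent)
  if (m == 0) stop("model has no latent variables")
  data <- if (is.null(data)) fit$data else {
    if (inherits(data, "fiml_data")) data else fiml_prepare(data, model$observed)
  }
  inv <- solve(diag(m) - model$beta$value)
  mean_eta <- drop(inv %*% model$alpha$value)
  c_eta <- symm(inv %*% model$psi$value %*% t(inv))
  cov_ye <- model$lambda$value %*% c_eta    # Cov(y, eta)
  mu_y <- fit$implied$mu
  sigma_y <- fit$implied$sigma
  scores <- matrix(NA_real_, nrow(data$y), m,
                   dimnames = list(rownames(data$y), model$latent))
  for (g in data$patterns) {
    obs <- g$obs
    sig_oo <- sigma_y[obs, obs, drop = FALSE]
    w <- t(cov_ye[obs, , drop = FALSE]) %*%
      chol2inv(chol(symm(sig_oo) + diag(1e-12, length(obs))))
    dev <- sweep(data$y[g$rows, obs, drop = FALSE], 2, mu_y[obs])
    sc <- sweep(dev %*% t(w), 2, mean_eta, "+")
    # latents with no information in this pattern stay NA
    informative <- colSums(abs(cov_ye[obs, , drop = FALSE])) > 1e-12
    sc[, !informative] <- NA_real_
    scores[g$rows, ] <- sc
  }
  scores
}
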