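# Full-information maximum likelihood machinery.  Cases are grouped by
# missingness pattern; each pattern contributes through its sufficient
# statistics (n_g, ybar_g, S_g), so likelihood evaluations never touch the
# raw data again.

#' Group a data matrix by missingness pattern
#'
#' @param data data.frame or matrix of the model's observed variables
#'   (columns may contain `NA`)
#' @param vars variable names to keep, in model order
#' @return a `fiml_data` object: per-pattern observed-index sets and
#'   sufficient statistics.  Cases with no observed values are dropped with
#'   a warning.
#' @export
fiml_prepare <- function(data, vars = colnames(data)) {
  y <- as.matrix(as.data.frame(data)[, vars, drop = FALSE])
  storage.mode(y) <- "double"
  if (any(!is.finite(y) & !is.na(y))) stop("non-finite values in data")
  all_missing <- rowSums(!is.na(y)) == 0
  if (any(all_missing)) {
    warning(sprintf("%d case(s) with no observed values dropped",
                    sum(all_missing)))
    y <- y[!all_missing, , drop = FALSE]
  }
  pat_key <- apply(!is.na(y), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(y)), pat_key)
  patterns <- lapply(groups, function(rows) {
    obs <- which(!is.na(y[rows[1], ]))
    yo <- y[rows, obs, drop = FALSE]
    n_g <- nrow(yo)
    ybar <- colMeans(yo)
    yc <- sweep(yo, 2, ybar)
    s_g <- crossprod(yc) / n_g     # ML (denominator n) within-pattern scatter
    list(obs = obs, n = n_g, ybar = ybar, s = s_g, rows = rows)
  })
  structure(list(patterns = patterns, vars = vars, n = nrow(y), y = y),
            class = "fiml_data")
}

#' FIML log-likelihood of a model at a parameter vector
#'
#' Sum over cases of the Gaussian log-density of each case's observed
#' subvector under the corresponding submatrix of the implied moments.
#' If the implied covariance is not positive definite a finite, heavily
#' penalized value is returned (attribute `penalized` set), so optimizers
#' can retreat rather than crash.
#'
#' @param model an [sem_model()]
#' @param theta optional free-parameter vector
#' @param data a `fiml_data` object from [fiml_prepare()], or raw data
#' @return scalar log-likelihood
#' @export
fiml_loglik <- function(model, theta = NULL, data) {
  if (!inherits(data, "fiml_data")) data <- fiml_prepare(data, model$observed)
  mom <- model_implied_moments(model, theta)
  fiml_loglik_moments(mom$mu, mom$sigma, data)
}

# Likelihood of arbitrary (mu, sigma) against prepared data; the workhorse
# shared by the SEM objective, the saturated model and EM.
fiml_loglik_moments <- function(mu, sigma, data) {
  ev_min <- min(eigen(symm(sigma), symmetric = TRUE, only.values = TRUE)$values)
  if (!is.finite(ev_min) || ev_min < 1e-12) {
    ll <- -1e10 * (1 + abs(min(ev_min, 0)))
    attr(ll, "penalized") <- TRUE
    return(ll)
  }
  ll <- 0
  for (g in data$patterns) {
    k <- length(g$obs)
    mu_g <- mu[g$obs]
    sig_g <- sigma[g$obs, g$obs, drop = FALSE]
    ch <- tryCatch(chol(sig_g), error = function(e) NULL)
    if (is.null(ch)) {
      ll <- -1e10
      attr(ll, "penalized") <- TRUE
      return(ll)
    }
    logdet <- 2 * sum(log(diag(ch)))
    inv <- chol2inv(ch)
    d <- g$ybar - mu_g
    quad <- sum(diag(inv %*% g$s)) + drop(t(d) %*% inv %*% d)
    ll <- ll - 0.5 * g$n * (k * log(2 * pi) + logdet + quad)
  }
  ll
}

#' Saturated-model FIML moments via expectation-maximization
#'
#' Maximum-likelihood mean vector and covariance matrix of an unstructured
#' multivariate normal under arbitrary missingness (the saturated model all
#' structured fits are compared against, and the exact FIML solution for
#' just-identified path models).
#'
#' @param data data.frame/matrix or `fiml_data`
#' @param vars variables to include
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter iteration cap
#' @return list: `mu`, `sigma`, `loglik`, `n`, `iterations`, `converged`
#' @export
fiml_saturated_moments <- function(data, vars = NULL,
                                   tol = 1e-10, max_iter = 5000) {
  if (!inherits(data, "fiml_data")) {
    data <- fiml_prepare(data, vars %||% colnames(data))
  }
  p <- length(data$vars)
  n <- data$n
  # start from available-case moments
  mu <- vapply(seq_len(p), function(j) mean(data$y[, j], na.rm = TRUE), 0)
  v <- vapply(seq_len(p), function(j) {
    s <- stats::var(data$y[, j], na.rm = TRUE)
    if (!is.finite(s) || s <= 0) 1 else s
  }, 0)
  sigma <- diag(v, p)
  complete <- all(vapply(data$patterns, function(g) length(g$obs) == p, TRUE))
  if (complete) {
    # single pattern: closed form
    g <- data$patterns[[1]]
    mu <- g$ybar; sigma <- g$s
    ll <- fiml_loglik_moments(mu, sigma, data)
    names(mu) <- data$vars; dimnames(sigma) <- list(data$vars, data$vars)
    return(list(mu = mu, sigma = symm(sigma), loglik = ll, n = n,
                iterations = 0L, converged = TRUE))
  }
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    t1 <- numeric(p)
    t2 <- matrix(0, p, p)
    for (g in data$patterns) {
      obs <- g$obs; mis <- setdiff(seq_len(p), obs)
      sig_oo <- sigma[obs, obs, drop = FALSE]
      inv_oo <- chol2inv(chol(symm(sig_oo) + diag(1e-10, length(obs))))
      ey <- matrix(0, p, 2)  # col1: sum E[y]; working space
      # observed part
      sum_o <- g$n * g$ybar
      # conditional mean of missing part: a + B y_o
      if (length(mis)) {
        b <- sigma[mis, obs, drop = FALSE] %*% inv_oo
        a <- mu[mis] - b %*% mu[obs]
        mbar <- drop(a + b %*% g$ybar)
        cvar <- sigma[mis, mis, drop = FALSE] -
          b %*% sigma[obs, mis, drop = FALSE]
        sum_m <- g$n * mbar
        # second moments
        s_oo <- g$n * (g$s + tcrossprod(g$ybar))
        s_om <- g$n * (g$s %*% t(b) + tcrossprod(g$ybar, mbar))
        s_mm <- g$n * (b %*% g$s %*% t(b) + tcrossprod(mbar) + cvar)
        t1[obs] <- t1[obs] + sum_o
        t1[mis] <- t1[mis] + sum_m
        t2[obs, obs] <- t2[obs, obs] + s_oo
        t2[obs, mis] <- t2[obs, mis] + s_om
        t2[mis, obs] <- t2[mis, obs] + t(s_om)
        t2[mis, mis] <- t2[mis, mis] + s_mm
      } else {
        t1[obs] <- t1[obs] + sum_o
        t2[obs, obs] <- t2[obs, obs] + g$n * (g$s + tcrossprod(g$ybar))
      }
    }
    mu <- t1 / n
    sigma <- symm(t2 / n - tcrossprod(mu))
    ll <- fiml_loglik_moments(mu, sigma, data)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  names(mu) <- data$vars
  dimnames(sigma) <- list(data$vars, data$vars)
  list(mu = mu, sigma = sigma, loglik = as.numeric(ll_old), n = n,
       iterations = iter, converged = converged)
}

# Independence-model (means + variances only) FIML log-likelihood; the
# baseline for CFI.  Under independence each variable's MLE uses its own
# observed cases, so the solution is closed form.
fiml_independence <- function(data) {
  if (!inherits(data, "fiml_data")) data <- fiml_prepare(data)
  p <- length(data$vars)
  mu <- vapply(seq_len(p), function(j) mean(data$y[, j], na.rm = TRUE), 0)
  v <- vapply(seq_len(p), function(j) {
    yj <- data$y[, j]; yj <- yj[!is.na(yj)]
    sum((yj - mean(yj))^2) / length(yj)
  }, 0)
  ll <- fiml_loglik_moments(mu, diag(v, p), data)
  list(loglik = as.numeric(ll), df_free = 2 * p)
}
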