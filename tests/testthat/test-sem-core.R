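# The FIML SEM engine: implied moments, likelihood, fitting, inference.

test_that("model-implied moments reproduce hand algebra", {
  # saturated: no latents, mu = nu, sigma = theta
  m <- toy_saturated_model()
  m$theta$value <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  m$nu$value <- matrix(c(3, -1), 2, 1)
  mom <- model_implied_moments(m)
  expect_equal(unname(mom$mu), c(3, -1))
  expect_equal(unname(mom$sigma), matrix(c(2, 0.5, 0.5, 1), 2, 2))

  # rank-1: three unit loadings, unit factor variance, zero residuals
  m1 <- sem_model(paste0("y", 1:3), "f",
                  lambda = par_matrix(matrix(1, 3, 1)),
                  psi = par_matrix(matrix(1, 1, 1)),
                  theta = par_matrix(matrix(0, 3, 3)))
  expect_equal(unname(model_implied_moments(m1)$sigma), matrix(1, 3, 3))

  # two-factor toy expanded symbolically: Sigma = Lam Psi Lam' + Theta
  lam <- matrix(c(1, 0.7, 0, 0, 0, 1, 1.3, 0.9), 4, 2)
  psi <- matrix(c(2, 0.6, 0.6, 1.5), 2, 2)
  theta <- diag(c(0.3, 0.4, 0.5, 0.6))
  m2 <- sem_model(paste0("y", 1:4), c("f1", "f2"),
                  lambda = par_matrix(lam), psi = par_matrix(psi),
                  theta = par_matrix(theta))
  expect_equal(unname(model_implied_moments(m2)$sigma),
               lam %*% psi %*% t(lam) + theta)
})

test_that("a structural cycle is reported as singular", {
  beta <- matrix(c(0, 1, 1, 0), 2, 2)   # f1 <-> f2 with unit paths
  m <- sem_model("y1", c("f1", "f2"),
                 lambda = par_matrix(matrix(c(1, 0), 1, 2)),
                 beta = par_matrix(beta),
                 psi = par_matrix(diag(2)))
  expect_error(model_implied_moments(m), "singular")
})

test_that("FIML log-likelihood matches closed forms and a casewise oracle", {
  # one case, one variable, standard normal at the mean
  m <- sem_model("y", theta = par_matrix(matrix(1, 1, 1)),
                 nu = par_matrix(matrix(0, 1, 1)))
  d <- fiml_prepare(data.frame(y = 0))
  expect_equal(fiml_loglik(m, data = d), -0.5 * log(2 * pi), tolerance = 1e-12)

  # complete data: equals the complete-data multivariate normal loglik
  y <- toy_factor_data(n = 80)
  mu <- c(1, 2, 3); sig <- diag(3) + 0.5
  ll_fiml <- fusionern:::fiml_loglik_moments(mu, sig, fiml_prepare(y))
  ll_direct <- sum(apply(y, 1, function(r) {
    -0.5 * (3 * log(2 * pi) + determinant(sig)$modulus[1] +
              t(r - mu) %*% solve(sig) %*% (r - mu))
  }))
  expect_equal(as.numeric(ll_fiml), ll_direct, tolerance = 1e-10)

  # mixed missingness patterns: brute-force case-by-case marginal sum
  y5 <- y[1:5, ]
  y5[1, 2] <- NA; y5[2, c(1, 3)] <- NA; y5[4, 3] <- NA
  ll_g <- fusionern:::fiml_loglik_moments(mu, sig, fiml_prepare(y5))
  ll_b <- 0
  for (i in 1:5) {
    o <- which(!is.na(y5[i, ]))
    s_o <- sig[o, o, drop = FALSE]
    ll_b <- ll_b - 0.5 * (length(o) * log(2 * pi) +
                            determinant(s_o)$modulus[1] +
                            t(y5[i, o] - mu[o]) %*% solve(s_o) %*%
                            (y5[i, o] - mu[o]))
  }
  expect_equal(as.numeric(ll_g), as.numeric(ll_b), tolerance = 1e-10)
})

test_that("log-likelihood is invariant to variable ordering", {
  y <- toy_factor_data(n = 60)
  y[sample(nrow(y), 20), 2] <- NA   # partial patterns only
  mu <- c(1, 2, 3); sig <- diag(3) + 0.5
  perm <- c(3, 1, 2)
  ll1 <- fusionern:::fiml_loglik_moments(mu, sig, fiml_prepare(y))
  ll2 <- fusionern:::fiml_loglik_moments(mu[perm], sig[perm, perm],
                                         fiml_prepare(y[, perm]))
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-12)
})

test_that("saturated fit on complete data equals sample mean and ML covariance", {
  y <- toy_factor_data(n = 120)[, 1:2]
  colnames(y) <- c("a", "b")
  fit <- fit_sem(toy_saturated_model(), y)
  n <- nrow(y)
  expect_equal(fit$df, 0)
  expect_equal(unname(fit$implied$mu), unname(colMeans(y)), tolerance = 1e-6)
  expect_equal(unname(fit$implied$sigma),
               unname(cov(y) * (n - 1) / n), tolerance = 1e-5)
  # fitted moments reproduce sample moments at the just-identified optimum
  sat <- fiml_saturated_moments(y)
  expect_equal(fit$loglik, sat$loglik, tolerance = 1e-8)
})

test_that("EM saturated moments maximize the observed-data likelihood", {
  set.seed(4)
  y <- toy_factor_data(n = 150)
  y[sample(length(y), 100)] <- NA
  sat <- suppressWarnings(fiml_saturated_moments(y))
  expect_true(sat$converged)
  # perturbations can only lower the likelihood
  d <- suppressWarnings(fiml_prepare(y))
  ll0 <- fusionern:::fiml_loglik_moments(sat$mu, sat$sigma, d)
  expect_equal(as.numeric(sat$loglik), as.numeric(ll0))
  for (k in 1:5) {
    mu2 <- sat$mu + rnorm(3, 0, 0.05)
    s2 <- sat$sigma + crossprod(matrix(rnorm(9, 0, 0.05), 3))
    expect_lt(as.numeric(fusionern:::fiml_loglik_moments(mu2, s2, d)),
              as.numeric(ll0))
  }
})

test_that("fit_sem recovers generating parameters and flags the machinery", {
  y <- toy_factor_data(n = 2000, seed = 7)
  y[sample(length(y), 600)] <- NA
  fit <- suppressWarnings(fit_sem(toy_factor_model(), y))
  expect_true(fit$converged)
  est <- fit$estimates
  get <- function(l) est$est[est$label == l]
  expect_equal(get("lambda[2,1]"), 0.8, tolerance = 0.1)
  expect_equal(get("lambda[3,1]"), 1.2, tolerance = 0.1)
  expect_equal(get("alpha[1,1]"), 2, tolerance = 0.15)
  expect_equal(get("psi[1,1]"), 2.25, tolerance = 0.3)
  # CI arithmetic
  expect_equal(est$ci_upper - est$est, 1.96 * est$se, tolerance = 1e-10)
})

test_that("a non-identified model is rejected before fitting", {
  # two free loadings on one indicator pair with free factor variance
  m <- sem_model(c("y1", "y2"), "f",
                 lambda = par_matrix(matrix(1, 2, 1), matrix(TRUE, 2, 1)),
                 psi = par_matrix(matrix(1, 1, 1), matrix(TRUE, 1, 1)),
                 theta = par_matrix(diag(0.5, 2), diag(2) == 1))
  y <- toy_factor_data(n = 50)[, 1:2]
  colnames(y) <- c("y1", "y2")
  expect_error(fit_sem(m, y), "not identified")
})

test_that("standardization follows implied-moment arithmetic", {
  # covariance 3 with SDs 2 and 3 standardizes to correlation 0.5
  m <- toy_saturated_model()
  m$theta$value <- matrix(c(4, 3, 3, 9), 2, 2)
  set.seed(1)
  y <- rmvn(400, c(0, 0), m$theta$value)
  colnames(y) <- c("a", "b")
  fit <- fit_sem(toy_saturated_model(), y, se = FALSE)
  std <- standardize(fit)
  s <- fit$implied$sigma
  expect_equal(std$theta[1, 2], s[1, 2] / sqrt(s[1, 1] * s[2, 2]),
               tolerance = 1e-8)
  # full toy factor model vs direct computation from implied moments
  fit2 <- fit_sem(toy_factor_model(), toy_factor_data(400), se = FALSE)
  std2 <- standardize(fit2)
  sdf <- sqrt(fit2$model$psi$value[1, 1])
  sdy <- sqrt(diag(fit2$implied$sigma))
  expect_equal(unname(std2$lambda[, 1]),
               unname(fit2$model$lambda$value[, 1] * sdf / sdy),
               tolerance = 1e-10)
})

test_that("fit indices behave at their boundary definitions", {
  y <- toy_factor_data(n = 150)
  fit <- fit_sem(toy_factor_model(), y, se = FALSE)
  idx <- fit_indices(fit)
  expect_equal(idx$df, 0)
  expect_true(is.na(idx$rmsea))   # just-identified: not applicable
  # an over-identified model: equal loadings across indicators 2 and 3
  m <- toy_factor_model()
  m$lambda$label[2, 1] <- m$lambda$label[3, 1] <- "lam_eq"
  m <- sem_model(m$observed, m$latent, lambda = m$lambda, psi = m$psi,
                 theta = m$theta, nu = m$nu, alpha = m$alpha)
  fit2 <- fit_sem(m, y, se = FALSE)
  idx2 <- fit_indices(fit2)
  expect_equal(idx2$df, 1)
  expect_gte(idx2$rmsea, 0)
  expect_lte(idx2$cfi, 1)
  expect_gte(idx2$srmr, 0)
})

test_that("regression factor scores match the closed-form complete-data formula", {
  y <- toy_factor_data(n = 100, seed = 3)
  fit <- fit_sem(toy_factor_model(), y, se = FALSE)
  fs <- factor_scores(fit)
  lam <- fit$model$lambda$value
  psi <- fit$model$psi$value[1, 1]
  mu <- fit$implied$mu; sig <- fit$implied$sigma
  alpha <- fit$model$alpha$value[1, 1]
  w <- psi * t(lam) %*% solve(sig)
  manual <- alpha + t(w %*% t(sweep(y, 2, mu)))
  expect_equal(unname(fs[, 1]), unname(drop(manual)), tolerance = 1e-7)
})

test_that("factor scores shrink fully as residual variance dominates", {
  # zero residual variance: score equals the back-transformed observation
  m <- sem_model("y", "f",
                 lambda = par_matrix(matrix(1, 1, 1)),
                 psi = par_matrix(matrix(2, 1, 1)),
                 theta = par_matrix(matrix(1e-12, 1, 1)),
                 alpha = par_matrix(matrix(0.5, 1, 1)))
  fit <- list(model = m, implied = model_implied_moments(m),
              data = fiml_prepare(data.frame(y = c(1, 4))))
  class(fit) <- "sem_fit"
  expect_equal(unname(factor_scores(fit)[, 1]), c(1, 4), tolerance = 1e-5)
  # huge residual variance: score collapses to the latent mean
  m$theta$value[1, 1] <- 1e8
  fit$model <- m; fit$implied <- model_implied_moments(m)
  expect_equal(unname(factor_scores(fit)[, 1]), c(0.5, 0.5), tolerance = 1e-4)
})
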