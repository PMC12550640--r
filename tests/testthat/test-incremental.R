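# Blockwise incremental validity, the OLS oracle, the moderated path model
# and simple slopes.

test_that("interaction terms center, propagate missingness, and reject
           constants", {
  set.seed(1)
  d <- data.frame(bi = rnorm(50), s1 = rnorm(50), s2 = rnorm(50))
  d$s2[7] <- NA
  out <- build_interaction_terms(d, c("s1", "s2"))
  expect_true(all(c("s1_x_bi", "s2_x_bi") %in% names(out)))
  expect_true(is.na(out$s2_x_bi[7]))            # missing, not zero
  # a subject exactly at the BI mean has zero products
  d_sym <- data.frame(bi = c(0, -1, 1, -2, 2), s1 = rnorm(5))
  out2 <- build_interaction_terms(d_sym, "s1")
  expect_equal(out2$s1_x_bi[1], 0, tolerance = 1e-12)
  d$s1 <- 1
  expect_error(build_interaction_terms(d, "s1"), "zero-variance")
  # large-sample moment identity: mean of product of z-scores ~ correlation
  set.seed(2)
  n <- 20000
  bi <- rnorm(n); s <- 0.4 * bi + sqrt(1 - 0.16) * rnorm(n)
  big <- build_interaction_terms(data.frame(bi = bi, s = s), "s")
  expect_equal(mean(big$s_x_bi), 0.4, tolerance = 0.03)
})

test_that("single standardized predictor reduces to the Pearson correlation", {
  set.seed(3)
  n <- 400
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  d <- data.frame(x = x, y = y)
  mod <- build_block_model(list(b1 = "x"), outcome = "y")
  res <- fit_incremental(mod, d)
  expect_equal(res$blocks$gamma[1], abs(cor(x, y)), tolerance = 1e-10)
})

test_that("orthogonal blocks decompose R^2 into squared correlations", {
  set.seed(4)
  n <- 100000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.6 * x1 + 0.3 * x2 + rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, y = y)
  mod <- build_block_model(list(b1 = "x1", b2 = "x2"), outcome = "y")
  res <- fit_incremental(mod, d)
  expect_equal(res$blocks$delta_r2[1], cor(x1, y)^2, tolerance = 1e-3)
  # block 2's semipartial differs from the marginal correlation only by
  # the sample correlation between x1 and x2 (zero in population)
  expect_equal(res$blocks$delta_r2[2], cor(x2, y)^2, tolerance = 0.02)
  expect_equal(sum(res$blocks$delta_r2), res$r2_total, tolerance = 1e-10)
})

test_that("phantom-block increments equal hierarchical OLS to 1e-6", {
  dat <- generate_block_cohort(generator_config(), seed = 11,
                               missing = FALSE)
  dat <- build_interaction_terms(
    dat, grep("^(eeg|fmri|fusion)_", names(dat), value = TRUE))
  mod <- build_block_model()
  res <- fit_incremental(mod, dat)
  oracle <- ols_hierarchical_r2(dat, mod$blocks, "anx_ch")
  expect_lt(max(abs(res$blocks$delta_r2 - oracle$delta_r2)), 1e-6)
  expect_lt(max(abs(res$blocks$cum_r2 - oracle$cum_r2)), 1e-6)
  # increments are the squared gammas and accumulate monotonically
  expect_equal(res$blocks$gamma^2, res$blocks$delta_r2, tolerance = 1e-12)
  expect_true(all(diff(res$blocks$cum_r2) >= -1e-12))
  expect_lte(res$r2_total, 1)
})

test_that("block order changes increments but not the total R^2", {
  dat <- generate_block_cohort(small_config(n = 400L), seed = 13,
                               missing = FALSE)
  dat <- build_interaction_terms(
    dat, grep("^(eeg|fmri|fusion)_", names(dat), value = TRUE))
  blocks <- block_spec()
  r1 <- fit_incremental(build_block_model(blocks), dat)
  r2 <- fit_incremental(build_block_model(rev(blocks)), dat)
  expect_equal(r1$r2_total, r2$r2_total, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(r1$blocks$delta_r2,
                                rev(r2$blocks$delta_r2))))
})

test_that("the OLS oracle matches a brute-force projection computation", {
  set.seed(5)
  n <- 500
  x <- matrix(rnorm(n * 6), n, 6)
  colnames(x) <- paste0("v", 1:6)
  y <- x %*% c(0.5, -0.3, 0.2, 0, 0.1, 0) + rnorm(n)
  d <- data.frame(x, y = drop(y))
  blocks <- list(b1 = c("v1", "v2"), b2 = c("v3", "v4"), b3 = c("v5", "v6"))
  res <- ols_hierarchical_r2(d, blocks, "y")
  yc <- drop(y) - mean(y)
  preds <- character()
  for (b in seq_along(blocks)) {
    preds <- c(preds, blocks[[b]])
    xm <- cbind(1, x[, preds])
    proj <- xm %*% solve(crossprod(xm), t(xm))
    expect_equal(res$cum_r2[b],
                 sum((proj %*% yc)^2) / sum(yc^2), tolerance = 1e-10)
  }
  # duplicating a predictor in a later block adds nothing
  d$v1b <- d$v1
  res2 <- ols_hierarchical_r2(d, c(blocks, list(b4 = "v1b")), "y")
  expect_equal(res2$delta_r2[4], 0, tolerance = 1e-12)
  expect_error(ols_hierarchical_r2(transform(d, y = ifelse(v1 > 0, NA, y)),
                                   blocks, "y"),
               "complete")
})

test_that("null blocks reject at close to the nominal 5% level", {
  # covariate signal in block 1 only; block 2 is pure noise
  set.seed(6)
  reps <- 400
  pvals <- vapply(seq_len(reps), function(i) {
    n <- 176
    x1 <- rnorm(n)
    d <- data.frame(x1 = x1,
                    z1 = rnorm(n), z2 = rnorm(n), z3 = rnorm(n),
                    y = 0.8 * x1 + rnorm(n))
    mod <- build_block_model(list(b1 = "x1", b2 = c("z1", "z2", "z3")),
                             outcome = "y")
    fit_incremental(mod, d)$blocks$pvalue[2]
  }, 0)
  rate <- mean(pvals < 0.05)
  # binomial 2 SE band around 0.05 at 400 replicates
  expect_gt(rate, 0.05 - 2 * sqrt(0.05 * 0.95 / reps))
  expect_lt(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("the moderated path model recovers its generating coefficients", {
  cfg <- generator_config(n_subjects = 4000L)
  dat <- generate_path_cohort(cfg, seed = 21, missing = FALSE)
  fit <- fit_final_path(dat, se = FALSE)
  b <- setNames(fit$coefficients$b, fit$coefficients$term)
  pp <- cfg$path
  expect_equal(unname(b["fusion_dacc_13_x_bi"]), pp$b_bi_x_dacc13,
               tolerance = 0.5)
  expect_equal(unname(b["fusion_pcc_ch_x_bi"]), pp$b_bi_x_pcc_ch,
               tolerance = 0.6)
  expect_equal(unname(b["fusion_dacc_ch"]), pp$b_dacc_ch, tolerance = 0.5)
  expect_equal(fit$r2, pp$r2, tolerance = 0.03)
})

test_that("an extra covariate toggles without changing the interface", {
  dat <- generate_path_cohort(small_config(n = 250L), seed = 23,
                              missing = FALSE)
  set.seed(1); dat$mat_ed <- rnorm(nrow(dat))
  fit <- fit_final_path(dat, extra_covariates = "mat_ed", se = FALSE)
  expect_true("mat_ed" %in% fit$coefficients$term)
  expect_equal(nrow(fit$coefficients), 13)
})

test_that("simple slopes follow the delta-method arithmetic", {
  dat <- generate_path_cohort(small_config(n = 500L), seed = 25,
                              missing = FALSE)
  fit <- fit_final_path(dat, se = TRUE)
  ss <- simple_slopes(fit, "fusion_dacc_13")
  b <- setNames(fit$coefficients$b, fit$coefficients$term)
  # slope(mean) - slope(-1 SD) equals the interaction coefficient
  expect_equal(ss$slope[2] - ss$slope[1],
               unname(b["fusion_dacc_13_x_bi"]), tolerance = 1e-10)
  # zero interaction implies flat slopes
  fit0 <- fit
  fit0$coefficients$b[fit0$coefficients$term == "fusion_dacc_13_x_bi"] <- 0
  ss0 <- simple_slopes(fit0, "fusion_dacc_13")
  expect_equal(ss0$slope[1], ss0$slope[3], tolerance = 1e-12)
  expect_error(simple_slopes(fit, "sex"), "product")
})

test_that("delta-method slope SEs match a parametric bootstrap", {
  # toy fit with a known coefficient covariance
  vc <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
               dimnames = list(c("f", "f_x_bi"), c("f", "f_x_bi")))
  fit <- structure(list(
    coefficients = data.frame(term = c("f", "f_x_bi"), b = c(1.2, -0.7)),
    vcov = vc), class = "path_fit")
  ss <- simple_slopes(fit, "f")
  set.seed(7)
  draws <- rmvn(10000, c(1.2, -0.7), vc)
  for (i in seq_along(ss$level)) {
    boot_se <- sd(draws[, 1] + ss$level[i] * draws[, 2])
    expect_equal(ss$se[i], boot_se, tolerance = 0.02)
  }
})
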