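# Score-level generators for the two model-recovery designs: the final
# moderated path model and the blockwise incremental-validity model.  Both
# generate the variables the models consume directly (covariates, z-scaled
# ROI scores, outcome), with acquisition-level MAR missingness; the
# imaging geometry is exercised elsewhere.

neural_score_cor <- function(within, cor_13_ch) {
  r <- diag(4)  # order: dacc_13, pcc_13, dacc_ch, pcc_ch
  r[1, 2] <- r[2, 1] <- within
  r[3, 4] <- r[4, 3] <- within
  r[1, 3] <- r[3, 1] <- cor_13_ch
  r[2, 4] <- r[4, 2] <- cor_13_ch
  r
}

scan_missing <- function(n, cohort, config) {
  pr <- mar_prob(config$missing$neural, cohort)
  list(eeg13 = stats::runif(n) < pr, eeg15 = stats::runif(n) < pr,
       fmri13 = stats::runif(n) < pr, fmri15 = stats::runif(n) < pr)
}

std_binary <- function(x, p) (x - p) / sqrt(p * (1 - p))

#' Generate a cohort for the moderated path-model recovery design
#'
#' Covariates, z-scaled fusion ROI baseline/change scores (correlated
#' within wave and across waves per config), BI-by-score products, and an
#' outcome built from the configured generating coefficients with residual
#' variance set so the population R^2 equals `config$path$r2`.  With
#' `missing = TRUE`, acquisition-level MAR deletion is applied: a fusion
#' score needs both modalities' acquisitions, and a change score both
#' waves, so fusion change scores are the most often missing.
#'
#' @param config a [generator_config()]
#' @param seed integer seed
#' @param missing apply MAR missingness
#' @return data.frame: sex, minority, bi, anx13, fusion scores, `anx_ch`
#' @export
generate_path_cohort <- function(config = generator_config(), seed = 1,
                                 missing = TRUE) {
  set.seed(seed)
  n <- config$n_subjects
  pp <- config$path
  sex <- stats::rbinom(n, 1, config$female_prob)
  minority <- stats::rbinom(n, 1, config$minority_prob)
  bi <- stats::rnorm(n)
  anx13 <- stats::rnorm(n)
  r <- neural_score_cor(pp$score_cor_within, pp$score_cor_13_ch)
  sc <- rmvn(n, rep(0, 4), r)
  colnames(sc) <- c("fusion_dacc_13", "fusion_pcc_13",
                    "fusion_dacc_ch", "fusion_pcc_ch")
  b_main <- c(pp$b_sex, pp$b_minority, pp$b_bi, pp$b_anx13,
              pp$b_dacc13, pp$b_pcc13, pp$b_dacc_ch, pp$b_pcc_ch)
  b_prod <- c(pp$b_bi_x_dacc13, pp$b_bi_x_pcc13,
              pp$b_bi_x_dacc_ch, pp$b_bi_x_pcc_ch)
  b_sc <- b_main[5:8]
  var_lp <- sum(b_main[1:4]^2) + drop(t(b_sc) %*% r %*% b_sc) +
    drop(t(b_prod) %*% r %*% b_prod)
  resid_sd <- sqrt(var_lp * (1 - pp$r2) / pp$r2)
  lp <- cbind(std_binary(sex, config$female_prob),
              std_binary(minority, config$minority_prob),
              bi, anx13, sc) %*% b_main + (bi * sc) %*% b_prod
  out <- data.frame(sex = sex, minority = minority, bi = bi, anx13 = anx13,
                    sc,
                    anx_ch = pp$intercept + drop(lp) +
                      stats::rnorm(n, 0, resid_sd))
  if (missing) {
    ms <- scan_missing(n, out, config)
    m13 <- ms$eeg13 | ms$fmri13
    mch <- m13 | ms$eeg15 | ms$fmri15
    out$fusion_dacc_13[m13] <- NA; out$fusion_pcc_13[m13] <- NA
    out$fusion_dacc_ch[mch] <- NA; out$fusion_pcc_ch[mch] <- NA
  }
  out
}

#' Generate a cohort for the incremental-validity recovery design
#'
#' Twelve ROI scores (EEG, fMRI and fusion, each dACC/PCC baseline and
#' change) plus covariates and BI products, with the outcome constructed so
#' that each predictor block's population contribution to R^2 equals the
#' configured `config$blocks$r2` sequence exactly.  Modalities are drawn
#' independently of one another (and of the covariates) so that the
#' between-block contributions decompose exactly; within a modality,
#' scores follow the configured correlation structure.
#'
#' @inheritParams generate_path_cohort
#' @return data.frame with covariates, 12 score columns and `anx_ch`
#' @export
generate_block_cohort <- function(config = generator_config(), seed = 1,
                                  missing = TRUE) {
  set.seed(seed)
  n <- config$n_subjects
  bc <- config$blocks
  r2 <- bc$r2
  if (any(r2 < 0) || sum(r2) >= 1) {
    stop("block r2 contributions must be nonnegative and sum below 1")
  }
  sex <- stats::rbinom(n, 1, config$female_prob)
  minority <- stats::rbinom(n, 1, config$minority_prob)
  bi <- stats::rnorm(n)
  anx13 <- stats::rnorm(n)
  r <- neural_score_cor(bc$score_cor_within, -0.2)
  ones <- rep(1, 4)
  block_var <- 2 * drop(t(ones) %*% r %*% ones)   # scores + BI products
  lp <- sqrt(r2[["block1"]] / 4) *
    (std_binary(sex, config$female_prob) +
       std_binary(minority, config$minority_prob) + bi + anx13)
  out <- data.frame(sex = sex, minority = minority, bi = bi, anx13 = anx13)
  for (k in 2:4) {
    mod <- c("eeg", "fmri", "fusion")[k - 1]
    sc <- rmvn(n, rep(0, 4), r)
    colnames(sc) <- c(paste(mod, "dacc", c("13", "ch"), sep = "_"),
                      paste(mod, "pcc", c("13", "ch"), sep = "_"))[c(1, 3, 2, 4)]
    # order columns as dacc_13, pcc_13, dacc_ch, pcc_ch to match r
    colnames(sc) <- paste(mod, c("dacc_13", "pcc_13", "dacc_ch", "pcc_ch"),
                          sep = "_")
    ck <- sqrt(r2[[paste0("block", k)]] / block_var)
    lp <- lp + ck * (rowSums(sc) + rowSums(bi * sc))
    out <- cbind(out, sc)
  }
  out$anx_ch <- drop(lp) + stats::rnorm(n, 0, sqrt(1 - sum(r2)))
  if (missing) {
    ms <- scan_missing(n, out, config)
    del <- function(cols, flag) {
      for (cl in cols) out[[cl]][flag] <<- NA
    }
    del(c("eeg_dacc_13", "eeg_pcc_13"), ms$eeg13)
    del(c("eeg_dacc_ch", "eeg_pcc_ch"), ms$eeg13 | ms$eeg15)
    del(c("fmri_dacc_13", "fmri_pcc_13"), ms$fmri13)
    del(c("fmri_dacc_ch", "fmri_pcc_ch"), ms$fmri13 | ms$fmri15)
    del(c("fusion_dacc_13", "fusion_pcc_13"), ms$eeg13 | ms$fmri13)
    del(c("fusion_dacc_ch", "fusion_pcc_ch"),
        ms$eeg13 | ms$eeg15 | ms$fmri13 | ms$fmri15)
  }
  out
}
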