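# Orchestration: one-command synthetic end-to-end runs and replicated
# parameter-recovery studies.

#' Run the full synthetic pipeline
#'
#' simulate -> ERN peaks -> ROI scores (meshes, volumes, fusion) ->
#' missingness -> anxiety LCS + six neural LCS fits -> change scores ->
#' incremental-validity model -> focused path model with simple slopes.
#' Deterministic given (config, seed).  Stages consuming user-supplied
#' inputs can be bypassed by passing `scores`.
#'
#' @param config a [generator_config()]
#' @param seed integer seed governing all stages
#' @param out_dir optional directory for CSV/JSON artifacts (created if
#'   needed); when `NULL`, nothing is written
#' @param use_geometry run the imaging stage (meshes/volumes/epochs); when
#'   `FALSE` the generator's true ROI activations act as observed scores
#' @param scores optional externally supplied wide score table (skips
#'   simulation of the imaging stage)
#' @param se compute standard errors on the final fits
#' @return a `run_report` list: fits, tables, seeds, per-stage counts, and
#'   an output-file manifest with checksums
#' @export
run_pipeline <- function(config = generator_config(), seed = 1,
                         out_dir = NULL, use_geometry = FALSE,
                         scores = NULL, se = TRUE,
                         models = c("lcs", "incremental", "path")) {
  models <- match.arg(models, several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  gen <- stage("simulate", generate_cohort(config, seed))
  cohort <- gen$cohort; truth <- gen$truth
  peaks <- NULL
  if (is.null(scores)) {
    if (use_geometry) {
      neural <- stage("neural_data",
                      generate_neural_data(truth, config, seed = seed + 1))
      epochs <- stage("epochs", generate_epochs(truth, config, seed = seed + 2))
      peaks <- stage("ern_peaks",
                     ern_peak_table(epochs, config$epochs$cluster))
      tidy <- stage("score", build_roi_score_table(neural, peaks))
      wide <- scores_wide(tidy)
    } else {
      wide <- truth_scores_wide(truth)
    }
    miss <- stage("missingness",
                  apply_missingness(cohort, wide, config, seed = seed + 3))
    cohort <- miss$cohort; wide <- miss$scores
  } else {
    wide <- scores
    cohort <- stage("missingness",
                    apply_missingness(cohort, NULL, config, seed = seed + 3)$cohort)
  }
  anx_fit <- stage("anxiety_lcs", fit_anxiety_lcs(cohort, se = se))
  change <- stage("neural_lcs", estimate_change_scores(wide, se = FALSE))
  neural_fits <- attr(change, "fits")
  obs_anx <- rowSums(!is.na(cohort[, anx_fit$model$observed])) > 0
  anx_scores <- factor_scores(
    anx_fit, fiml_prepare(cohort[obs_anx, ], anx_fit$model$observed))
  modeling <- stage("assemble", {
    df <- cbind(cohort[, c("subject_id", "sex", "minority", "bi")],
                change[, setdiff(names(change), "subject_id")])
    df$anx13 <- df$anx_ch <- NA_real_
    df$anx13[obs_anx] <- anx_scores[, "eta13"]
    df$anx_ch[obs_anx] <- anx_scores[, "delta"]
    df <- build_interaction_terms(
      df, grep("^(eeg|fmri|fusion)_", names(df), value = TRUE))
    df
  })
  inc <- NULL; path <- NULL
  if ("incremental" %in% models) {
    inc <- stage("incremental",
                 fit_incremental(build_block_model(), modeling, se = se))
  }
  if ("path" %in% models) {
    path <- stage("final_path",
                  fit_final_path(modeling, modality = "fusion", se = se))
  }
  slopes <- NULL
  if (se && !is.null(path)) {
    slopes <- list(
      dacc13 = simple_slopes(path, "fusion_dacc_13"),
      pcc_ch = simple_slopes(path, "fusion_pcc_ch"))
  }
  report <- list(
    seeds = c(cohort = seed, neural = seed + 1, epochs = seed + 2,
              missingness = seed + 3),
    n = list(subjects = nrow(cohort),
             scores = sum(!is.na(wide[, -1, drop = FALSE])),
             complete_anxiety = sum(stats::complete.cases(
               cohort[, grep("scared|dx", names(cohort))]))),
    converged = c(anxiety_lcs = anx_fit$converged,
                  vapply(neural_fits, function(f) f$converged, TRUE)),
    anxiety_fit = anx_fit, neural_fits = neural_fits,
    incremental = inc, path = path, simple_slopes = slopes,
    cohort = cohort, scores = wide, modeling = modeling, peaks = peaks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(cohort = file.path(out_dir, "cohort.csv"),
               scores = file.path(out_dir, "scores.csv"),
               anxiety = file.path(out_dir, "anxiety_lcs_estimates.csv"))
    write_cohort_csv(cohort, files["cohort"])
    utils::write.csv(wide, files["scores"], row.names = FALSE, na = "")
    utils::write.csv(anx_fit$estimates, files["anxiety"], row.names = FALSE)
    if (!is.null(inc)) {
      files["blocks"] <- file.path(out_dir, "incremental_blocks.csv")
      utils::write.csv(inc$blocks, files["blocks"], row.names = FALSE)
    }
    if (!is.null(path)) {
      files["path"] <- file.path(out_dir, "path_coefficients.csv")
      utils::write.csv(path$coefficients, files["path"], row.names = FALSE)
    }
    summary_path <- file.path(out_dir, "run_report.json")
    jsonlite::write_json(list(
      seeds = as.list(report$seeds), n = report$n,
      converged = as.list(report$converged),
      config_hash = config_hash(config),
      manifest = lapply(as.list(files), function(f)
        list(file = basename(f), md5 = unname(tools::md5sum(f))))),
      summary_path, auto_unbox = TRUE, digits = NA)
    report$manifest <- c(files, summary = summary_path)
  }
  class(report) <- "run_report"
  report
}

#' Stable hash of a configuration
#' @param config any serializable list
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = 12,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Read a pipeline/generator configuration from YAML or JSON
#' @param path file path (`.yaml`/`.yml` or `.json`)
#' @return a [generator_config()] with file entries overriding defaults
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(generator_config, raw)
}

#' Replicated parameter-recovery study
#'
#' Repeatedly generates a cohort and refits the requested model, with
#' replicate seeds `base_seed + 1 .. base_seed + replicates`.  Convergence
#' failures are recorded and excluded from the summaries.
#'
#' @param design one of `"anxiety_lcs"`, `"neural_lcs"`, `"incremental"`,
#'   `"final_path"`
#' @param replicates number of replicates (>= 2)
#' @param config a [generator_config()]
#' @param base_seed base seed
#' @param se compute SEs per replicate (needed for coverage; slower)
#' @param modality,region neural LCS target (design `"neural_lcs"`)
#' @return list: `summary` data.frame (parameter, generating, mean_est,
#'   sd_est, coverage), `estimates` per-replicate matrix, `n_failed`
#' @export
recovery_study <- function(design = c("anxiety_lcs", "neural_lcs",
                                      "incremental", "final_path"),
                           replicates = 200, config = generator_config(),
                           base_seed = 0, se = FALSE,
                           modality = "fusion", region = "dacc") {
  design <- match.arg(design)
  if (replicates < 2) stop("replicates must be >= 2")
  one <- switch(design,
    anxiety_lcs = function(seed) {
      gen <- generate_cohort(config, seed)
      cohort <- apply_missingness(gen$cohort, NULL, config, seed)$cohort
      fit <- fit_anxiety_lcs(cohort, se = se)
      est <- c(mean_delta = coef_sem(fit, "mean_delta"),
               var_delta = coef_sem(fit, "var_delta"))
      if (se) {
        tab <- fit$estimates
        est <- c(est,
          cover_mean = as.numeric(
            tab$ci_lower[tab$label == "mean_delta"] <= config$anxiety$mean_delta &
            config$anxiety$mean_delta <= tab$ci_upper[tab$label == "mean_delta"]),
          cover_var = as.numeric(
            tab$ci_lower[tab$label == "var_delta"] <= config$anxiety$var_delta &
            config$anxiety$var_delta <= tab$ci_upper[tab$label == "var_delta"]))
      }
      list(est = est, ok = fit$converged)
    },
    neural_lcs = function(seed) {
      gen <- generate_cohort(config, seed)
      wide <- truth_scores_wide(gen$truth)
      wide <- apply_missingness(gen$cohort, wide, config, seed)$scores
      fit <- fit_neural_lcs(wide, modality, region, se = se)
      std <- lcs_standardized_change(fit)
      list(est = c(mean_change = coef_sem(fit, "mean_change"),
                   var_change = coef_sem(fit, "var_change"),
                   std_change = std$mean_std, std_var = std$var_std),
           ok = fit$converged)
    },
    incremental = function(seed) {
      dat <- generate_block_cohort(config, seed)
      dat <- build_interaction_terms(
        dat, grep("^(eeg|fmri|fusion)_", names(dat), value = TRUE))
      inc <- fit_incremental(build_block_model(), dat, se = FALSE)
      list(est = stats::setNames(inc$blocks$delta_r2,
                                 paste0("delta_r2_", 1:4)),
           ok = TRUE)
    },
    final_path = function(seed) {
      dat <- generate_path_cohort(config, seed)
      fit <- fit_final_path(dat, se = se)
      tab <- fit$coefficients
      b <- stats::setNames(tab$b, tab$term)
      sl_d <- b["fusion_dacc_13"] + c(-1, 1) * b["fusion_dacc_13_x_bi"]
      list(est = c(b, slope_dacc13_lo = unname(sl_d[1]),
                   slope_dacc13_hi = unname(sl_d[2])),
           ok = TRUE)
    })
  rows <- list(); failed <- 0L
  for (rep_i in seq_len(replicates)) {
    res <- tryCatch(one(replicate_seed(base_seed, rep_i)),
                    error = function(e) NULL)
    if (is.null(res) || !isTRUE(res$ok)) { failed <- failed + 1L; next }
    rows[[length(rows) + 1]] <- res$est
  }
  if (!length(rows)) stop("no replicate produced a converged fit")
  est <- do.call(rbind, rows)
  gen_vals <- recovery_generating_values(design, config, modality, region)
  params <- colnames(est)
  summary <- data.frame(
    parameter = params,
    generating = unname(gen_vals[params]),
    mean_est = colMeans(est),
    sd_est = apply(est, 2, stats::sd),
    row.names = NULL)
  list(summary = summary, estimates = est, n_failed = failed,
       replicates = replicates, design = design)
}

recovery_generating_values <- function(design, config, modality = "fusion",
                                       region = "dacc") {
  switch(design,
    anxiety_lcs = c(mean_delta = config$anxiety$mean_delta,
                    var_delta = config$anxiety$var_delta),
    neural_lcs = {
      np <- config$neural[[modality]][[region]]
      v15 <- np$var_13 + np$var_change + 2 * np$cov
      c(mean_change = np$mean_change, var_change = np$var_change,
        std_change = np$mean_change / sqrt(v15),
        std_var = np$var_change / v15)
    },
    incremental = stats::setNames(config$blocks$r2, paste0("delta_r2_", 1:4)),
    final_path = {
      pp <- config$path
      c(sex = pp$b_sex, minority = pp$b_minority, bi = pp$b_bi,
        anx13 = pp$b_anx13,
        fusion_dacc_13 = pp$b_dacc13, fusion_dacc_ch = pp$b_dacc_ch,
        fusion_pcc_13 = pp$b_pcc13, fusion_pcc_ch = pp$b_pcc_ch,
        fusion_dacc_13_x_bi = pp$b_bi_x_dacc13,
        fusion_dacc_ch_x_bi = pp$b_bi_x_dacc_ch,
        fusion_pcc_13_x_bi = pp$b_bi_x_pcc13,
        fusion_pcc_ch_x_bi = pp$b_bi_x_pcc_ch,
        slope_dacc13_lo = pp$b_dacc13 - pp$b_bi_x_dacc13,
        slope_dacc13_hi = pp$b_dacc13 + pp$b_bi_x_dacc13)
    })
}
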