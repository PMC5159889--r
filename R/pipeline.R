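# End-to-end analysis: exclusion -> pooled fits for Models 1-5 (plus gender
# variants) -> BIC ranking -> individual fits with the pooled slope ->
# added-variable pairings -> model-free regression.

#' Run the full risk-preference analysis
#'
#' Reproduces the complete analysis on a (real or synthetic) cohort:
#' applies the dominated-choice exclusion rule; fits the five nested
#' risk-tolerance link models (and, optionally, their gender-augmented
#' variants) by pooled clustered MLE; ranks them by BIC; refits alpha at
#' the individual level holding the logistic slope at the pooled estimate
#' of the designated models; computes the added-variable pairings of
#' individual alpha against age (controlling rPPC GMV) and against rPPC
#' GMV (controlling age); and runs the model-free OLS of each participant's
#' lottery-choice proportion on age and rPPC GMV with one-tailed tests in
#' the predicted directions (negative for age, positive for GMV).
#'
#' @param participants Covariate table.
#' @param records Long-format choice records.
#' @param models Which models to fit (subset of 1..5).
#' @param gender_variants Also fit each model with the gender indicator.
#' @param scatter_sigma_model Model whose pooled slope fixes sigma for the
#'   individual fits behind the alpha-vs-GMV scatter (default Model 2).
#' @param partial_sigma_model Model whose pooled slope fixes sigma for the
#'   individual fits behind the residualized partial plots (default
#'   Model 3).
#' @param exclusion_threshold Dominated-choice exclusion threshold.
#' @param ... Passed to [fit_pooled()] (for example `n_restarts`).
#' @return Object of class `risk_analysis_report`: `exclusions`, `fits`,
#'   `coefficient_table`, `bic_table`, `individual_fits`, `partial_plots`,
#'   `model_free`, `meta`.
#' @export
run_full_analysis <- function(participants, records,
                              models = 1:5, gender_variants = TRUE,
                              scatter_sigma_model = 2,
                              partial_sigma_model = 3,
                              exclusion_threshold = 0.5, ...) {
  stop_if_not_records(records)
  n_obs_total <- nrow(records)
  excl <- exclusion_log(records, threshold = exclusion_threshold)
  keep_ids <- excl$participant_id[!excl$exclude]
  if (length(keep_ids) < 2L) {
    stop("fewer than 2 participants remain after exclusion", call. = FALSE)
  }
  records <- records[records$participant_id %in% keep_ids, , drop = FALSE]
  participants <- participants[participants$participant_id %in% keep_ids, ,
                               drop = FALSE]

  specs <- lapply(models, model_spec)
  if (gender_variants) {
    specs <- c(specs, lapply(models, model_spec, gender = TRUE))
  }
  fits <- list()
  for (sp in specs) {
    fits[[sp$name]] <- tryCatch(
      fit_pooled(records, participants, covariates = sp$covariates, ...),
      error = function(e) {
        warning(sprintf("fit of %s failed: %s", sp$name,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))

  base_names <- paste0("Model", models)
  base_ok <- base_names[base_names %in% names(fits)[ok]]
  bic_table <- data.frame(
    model = base_ok,
    log_likelihood = vapply(fits[base_ok],
                            function(f) f$log_likelihood, numeric(1)),
    k = vapply(fits[base_ok], function(f) length(f$coefficients),
               numeric(1)),
    n_obs = vapply(fits[base_ok], function(f) f$n_obs, numeric(1)),
    bic = vapply(fits[base_ok], function(f) f$bic, numeric(1)),
    row.names = NULL)
  bic_table$rank <- bic_rank(bic_table$bic)

  coef_table <- do.call(rbind, lapply(names(fits)[ok], function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm,
               term = names(f$coefficients),
               estimate = unname(f$coefficients),
               se = unname(f$se),
               z = unname(f$z),
               p = unname(f$p_values),
               stars = significance_stars(unname(f$p_values)),
               row.names = NULL)
  }))

  scatter_nm <- paste0("Model", scatter_sigma_model)
  partial_nm <- paste0("Model", partial_sigma_model)
  individual_fits <- partial_plots <- NULL
  if (scatter_nm %in% names(fits)[ok]) {
    sig2 <- fits[[scatter_nm]]$coefficients[["sigma"]]
    individual_fits <- fit_individuals(records, sig2)
  }
  if (partial_nm %in% names(fits)[ok]) {
    sig3 <- fits[[partial_nm]]$coefficients[["sigma"]]
    ind3 <- fit_individuals(records, sig3)
    pp <- merge(ind3, participants, by = "participant_id")
    av_age <- added_variable(pp$alpha_hat, pp$age,
                             pp[, "rppc_gmv", drop = FALSE])
    av_gmv <- added_variable(pp$alpha_hat, pp$rppc_gmv,
                             pp[, "age", drop = FALSE])
    partial_plots <- data.frame(
      participant_id = pp$participant_id,
      alpha_resid_given_gmv = av_age$y_resid,
      age_resid_given_gmv = av_age$x_resid,
      alpha_resid_given_age = av_gmv$y_resid,
      gmv_resid_given_age = av_gmv$x_resid)
    attr(partial_plots, "slopes") <- c(age = av_age$slope,
                                       rppc_gmv = av_gmv$slope)
  }

  props <- vapply(split(records, records$participant_id),
                  proportion_lottery, numeric(1))
  mf_dat <- participants[match(names(props), participants$participant_id), ]
  model_free <- ols_one_tailed(unname(props),
                               mf_dat[, c("age", "rppc_gmv"), drop = FALSE],
                               directions = c(age = -1, rppc_gmv = +1))

  structure(list(
    exclusions = excl,
    fits = fits,
    coefficient_table = coef_table,
    bic_table = bic_table,
    individual_fits = individual_fits,
    partial_plots = partial_plots,
    model_free = model_free,
    meta = list(n_participants = nrow(participants),
                n_obs_total = n_obs_total,
                n_obs = nrow(records),
                n_excluded = sum(excl$exclude),
                package_version = as.character(
                  utils::packageVersion("riskspan")))
  ), class = "risk_analysis_report")
}

# Stars legend: *** <0.001, ** <0.01, * <0.05, '.' <0.06 (borderline).
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*",
                              ifelse(p < 0.06, ".", "")))))
}

#' @export
print.risk_analysis_report <- function(x, ...) {
  cat("Risk-preference analysis report\n")
  cat(sprintf("  %d participants (%d excluded), %d choice records\n",
              x$meta$n_participants, x$meta$n_excluded, x$meta$n_obs))
  cat("\nBIC comparison (lower is better):\n")
  print(x$bic_table, row.names = FALSE)
  cat("\nModel-free regression of lottery-choice proportion:\n")
  print(x$model_free, row.names = FALSE)
  cat("\nStars: *** p<0.001, ** p<0.01, * p<0.05, . p<0.06\n")
  invisible(x)
}

#' Predicted risk tolerance across ages
#'
#' Evaluates a fitted age-containing risk-tolerance link at a grid of ages,
#' holding any other covariates at the sample means stored with the fit.
#'
#' @param fit A `risk_fit` whose link includes `age`.
#' @param ages Ages (years) at which to predict.
#' @param covariate_values Optional named overrides for the non-age
#'   covariates (defaults to the fit's sample means).
#' @return Data frame with `age` and `alpha`.
#' @export
predict_alpha_curve <- function(fit, ages, covariate_values = NULL) {
  stopifnot(inherits(fit, "risk_fit"))
  if (!"age" %in% fit$covariates) {
    stop("fit does not include an age coefficient", call. = FALSE)
  }
  if (any(ages < 0 | ages > 120)) {
    warning("ages outside [0, 120] requested", call. = FALSE)
  }
  others <- setdiff(fit$covariates, "age")
  vals <- fit$covariate_means[others]
  if (!is.null(covariate_values)) {
    vals[names(covariate_values)] <- covariate_values
  }
  newdata <- data.frame(age = ages)
  for (nm in others) newdata[[nm]] <- vals[[nm]]
  link <- fit$coefficients[c("intercept", fit$covariates)]
  alpha <- alpha_from_covariates(link, newdata, floor = fit$alpha_floor)
  data.frame(age = ages, alpha = as.numeric(alpha))
}
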