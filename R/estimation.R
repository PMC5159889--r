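# Pooled maximum-likelihood estimation of the EU/logistic choice model with
# participant-clustered sandwich standard errors.

#' Model specifications for the covariate-linear risk-tolerance link
#'
#' The five nested specifications compared in the analysis differ only in
#' which covariates enter the risk-tolerance link: Model 1 {age}, Model 2
#' {rppc_gmv}, Model 3 {age, rppc_gmv}, Model 4 {rppc_gmv, global_gmv},
#' Model 5 {age, rppc_gmv, global_gmv}. Gender variants add a 0/1 gender
#' indicator to each.
#'
#' @param model Model number, 1--5 (integer or character).
#' @param gender If `TRUE`, append the gender indicator.
#' @return List with `name` and `covariates`.
#' @export
model_spec <- function(model, gender = FALSE) {
  model <- as.character(model)
  sets <- list(`1` = "age",
               `2` = "rppc_gmv",
               `3` = c("age", "rppc_gmv"),
               `4` = c("rppc_gmv", "global_gmv"),
               `5` = c("age", "rppc_gmv", "global_gmv"))
  if (!model %in% names(sets)) {
    stop("`model` must be one of 1..5", call. = FALSE)
  }
  covs <- sets[[model]]
  if (gender) covs <- c(covs, "gender")
  list(name = paste0("Model", model, if (gender) "+gender" else ""),
       covariates = covs)
}

# Build the per-record quantities the likelihood needs, once per fit.
build_model_data <- function(records, participants, covariates) {
  stop_if_not_records(records)
  idx <- match(records$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    stop("records reference participants missing from `participants`",
         call. = FALSE)
  }
  missing <- setdiff(covariates, names(participants))
  if (length(missing)) {
    stop("participants lack covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- cbind(intercept = 1)
  if (length(covariates)) {
    Xc <- as.matrix(participants[idx, covariates, drop = FALSE])
    storage.mode(Xc) <- "double"
    X <- cbind(intercept = 1, Xc)
  } else {
    X <- matrix(1, nrow = nrow(records), ncol = 1,
                dimnames = list(NULL, "intercept"))
  }
  list(X = X,
       y = as.numeric(records$chose_lottery),
       v = records$lottery_amount,
       p = records$lottery_probability,
       s = records$safe_amount,
       logv = log(records$lottery_amount),
       logs = log(records$safe_amount),
       cluster = as.character(records$participant_id),
       covariate_means = if (length(covariates)) {
         colMeans(as.matrix(participants[, covariates, drop = FALSE]))
       } else numeric(0))
}

# Log-likelihood, per-record scores and summed gradient at theta=c(beta,sigma).
# alpha is boxed into [floor, cap]: the floor guards the power-utility
# domain, the cap keeps v^alpha finite far from any plausible optimum.
loglik_parts <- function(theta, md, floor, eps, convention, cap = 20) {
  k <- ncol(md$X)
  beta <- theta[seq_len(k)]
  sigma <- theta[k + 1L]
  lp <- drop(md$X %*% beta)
  active <- lp >= floor & lp <= cap  # where the link (not a bound) is live
  alpha <- pmin(pmax(lp, floor), cap)
  eu_l <- md$p * exp(alpha * md$logv)
  eu_s <- exp(alpha * md$logs)
  d <- eu_l - eu_s
  z <- if (convention == "slope") sigma * d else d / sigma
  z <- pmin(pmax(z, -700), 700)
  pr_l <- stats::plogis(z)
  pr_obs <- ifelse(md$y == 1, pr_l, 1 - pr_l)
  ll <- sum(log(pmax(pr_obs, eps)))
  # d ll / d z per record
  u <- md$y - pr_l
  # d Delta / d alpha
  dd_dalpha <- md$p * exp(alpha * md$logv) * md$logv -
    exp(alpha * md$logs) * md$logs
  if (convention == "slope") {
    dz_dalpha <- sigma * dd_dalpha
    dz_dsigma <- d
  } else {
    dz_dalpha <- dd_dalpha / sigma
    dz_dsigma <- -d / sigma^2
  }
  w_beta <- u * dz_dalpha * active
  scores <- cbind(md$X * w_beta, sigma = u * dz_dsigma)
  colnames(scores) <- c(colnames(md$X), "sigma")
  list(ll = ll, grad = colSums(scores), scores = scores,
       n_floored = sum(!active), pr_obs = pr_obs)
}

#' Cluster-robust sandwich covariance for an MLE
#'
#' Computes the score-sandwich covariance A^-1 B A^-1 where A is the
#' negative Hessian of the log-likelihood at the MLE and B sums the outer
#' products of within-cluster score sums, multiplied by the small-sample
#' factor G/(G-1) for G clusters. With singleton clusters this reduces to
#' the heteroskedasticity-robust sandwich up to the n/(n-1) factor.
#'
#' @param scores n x k matrix of per-observation scores evaluated at the
#'   MLE.
#' @param cluster_ids Length-n cluster labels.
#' @param hessian k x k negative Hessian of the log-likelihood (equivalently
#'   the Hessian of the negative log-likelihood) at the MLE.
#' @return k x k covariance matrix.
#' @export
cluster_robust_vcov <- function(scores, cluster_ids, hessian) {
  scores <- as.matrix(scores)
  if (length(cluster_ids) != nrow(scores)) {
    stop("`cluster_ids` must have one label per score row", call. = FALSE)
  }
  G <- length(unique(cluster_ids))
  if (G < 2L) {
    stop("clustered covariance requires at least 2 clusters", call. = FALSE)
  }
  sg <- rowsum(scores, group = as.character(cluster_ids), reorder = FALSE)
  B <- crossprod(sg)
  Ainv <- tryCatch(solve(hessian),
                   error = function(e) {
                     stop("Hessian is singular; clustered covariance ",
                          "unavailable", call. = FALSE)
                   })
  V <- Ainv %*% B %*% Ainv * G / (G - 1)
  dimnames(V) <- dimnames(hessian)
  (V + t(V)) / 2
}

#' Bayesian Information Criterion
#'
#' BIC = k * ln(n) - 2 * lnL; lower is better. `n` is the number of choice
#' records (the likelihood's observation count), not the number of
#' participants.
#'
#' @param log_likelihood Maximized log-likelihood (nats).
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return BIC value.
#' @export
bic_value <- function(log_likelihood, k, n) {
  stopifnot(n >= 1, k >= 0)
  k * log(n) - 2 * log_likelihood
}

#' Rank models by BIC
#'
#' @param bic Numeric vector of BIC values.
#' @return Integer ranks, 1 = best (lowest BIC).
#' @export
bic_rank <- function(bic) {
  rank(bic, ties.method = "first")
}

#' Pooled maximum-likelihood fit with participant-clustered standard errors
#'
#' Fits the power-utility / logistic choice model to all participants'
#' choices simultaneously, maximizing the joint log-likelihood over the
#' risk-tolerance link coefficients and the common logistic slope, and
#' clustering standard errors on participants to allow arbitrary
#' within-participant correlation. Optimization uses L-BFGS-B with an
#' analytic gradient plus deterministic jittered restarts; ties are broken
#' by highest likelihood, then smallest parameter norm.
#'
#' @param records Choice records (long format).
#' @param participants Covariate table keyed by `participant_id`.
#' @param covariates Character vector of covariates entering the
#'   risk-tolerance link (possibly empty for an intercept-only link).
#' @param start Optional named start values `c(beta..., sigma)`.
#' @param alpha_floor Positivity floor on the linear alpha link.
#' @param sigma_bounds Box bounds on sigma during optimization.
#' @param n_restarts Number of jittered restarts beyond the default start.
#' @param restart_sd Standard deviation of the start jitter.
#' @param restart_seed Seed driving the (deterministic) jitter.
#' @param eps Probability clipping bound in the likelihood.
#' @param convention Choice-rule convention (`"slope"` or `"temperature"`).
#' @param control Passed to [stats::optim()] (`maxit`, `factr`, ...).
#' @return Object of class `risk_fit`: coefficients (link betas and
#'   `sigma`), clustered `vcov`, `log_likelihood`, `bic`, Wald `z` and
#'   two-tailed `p_values`, `n_obs`, `n_clusters`, convergence diagnostics.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 20, seed = 7))
#' fit <- fit_pooled(cohort$records, cohort$participants,
#'                   covariates = "rppc_gmv", n_restarts = 0)
#' coef(fit)
#' @export
fit_pooled <- function(records, participants, covariates = "age",
                       start = NULL, alpha_floor = 0.01,
                       sigma_bounds = c(1e-3, 50), n_restarts = 5,
                       restart_sd = 0.25, restart_seed = 20211L,
                       eps = 1e-12, convention = c("slope", "temperature"),
                       control = list()) {
  convention <- match.arg(convention)
  md <- build_model_data(records, participants, covariates)
  G <- length(unique(md$cluster))
  if (G < 2L) {
    stop("pooled estimation requires at least 2 participants", call. = FALSE)
  }
  k <- ncol(md$X)
  separated <- all(md$y == 1) || all(md$y == 0)
  if (separated) {
    warning("all choices identical (complete separation); parameters are ",
            "not identified and will sit at a bound", call. = FALSE)
  }

  negll <- function(theta) {
    val <- -loglik_parts(theta, md, alpha_floor, eps, convention)$ll
    if (!is.finite(val)) val <- .Machine$double.xmax / 1e10
    val
  }
  neggrad <- function(theta) {
    g <- -loglik_parts(theta, md, alpha_floor, eps, convention)$grad
    g[!is.finite(g)] <- 0
    g
  }

  if (is.null(start)) {
    start <- c(0.5, rep(0, k - 1L), 1)
  }
  stopifnot(length(start) == k + 1L)
  lower <- c(rep(-Inf, k), sigma_bounds[1])
  upper <- c(rep(Inf, k), sigma_bounds[2])
  # covariates enter on very different scales (years vs volume units);
  # scale each slope's search direction and jitter by 1/sd of its column
  parscale <- rep(1, k + 1L)
  if (k > 1L) {
    sds <- apply(md$X[, -1L, drop = FALSE], 2, stats::sd)
    parscale[2:k] <- 1 / pmax(sds, 1e-8)
  }
  control <- utils::modifyList(list(maxit = 500L, parscale = parscale),
                               control)

  starts <- list(start)
  if (n_restarts > 0) {
    jitters <- with_seed(restart_seed,
                         matrix(stats::rnorm(n_restarts * (k + 1L),
                                             sd = restart_sd),
                                nrow = n_restarts))
    for (i in seq_len(n_restarts)) {
      s <- start + jitters[i, ] * parscale
      s[k + 1L] <- min(max(s[k + 1L], sigma_bounds[1] * 2), sigma_bounds[2])
      starts[[i + 1L]] <- s
    }
  }

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, fn = negll, gr = neggrad, method = "L-BFGS-B",
                   lower = lower, upper = upper, control = control),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-10 ||
        (abs(opt$value - best$value) <= 1e-10 &&
         sum(opt$par^2) < sum(best$par^2))) {
      best <- opt
    }
  }
  if (is.null(best)) {
    stop("optimization failed from every start", call. = FALSE)
  }
  if (best$convergence != 0 && !separated) {
    stop("optimizer did not converge: ", best$message %||% best$convergence,
         call. = FALSE)
  }

  theta <- best$par
  names(theta) <- c(colnames(md$X), "sigma")
  parts <- loglik_parts(theta, md, alpha_floor, eps, convention)
  H <- stats::optimHess(theta, fn = negll, gr = neggrad,
                        control = control["parscale"])
  dimnames(H) <- list(names(theta), names(theta))
  at_sigma_bound <- theta["sigma"] <= sigma_bounds[1] * (1 + 1e-6) ||
    theta["sigma"] >= sigma_bounds[2] * (1 - 1e-6)
  boundary <- separated || at_sigma_bound

  V <- if (boundary) {
    matrix(NA_real_, k + 1L, k + 1L,
           dimnames = list(names(theta), names(theta)))
  } else {
    cluster_robust_vcov(parts$scores, md$cluster, H)
  }
  se <- sqrt(pmax(diag(V), 0))
  z <- theta / se
  p <- 2 * stats::pnorm(-abs(z))

  structure(list(
    coefficients = theta,
    vcov = V,
    se = se,
    z = z,
    p_values = p,
    log_likelihood = parts$ll,
    n_obs = nrow(md$X),
    n_clusters = G,
    bic = bic_value(parts$ll, k + 1L, nrow(md$X)),
    covariates = covariates,
    covariate_means = md$covariate_means,
    convention = convention,
    alpha_floor = alpha_floor,
    n_floored = parts$n_floored,
    convergence = list(code = best$convergence,
                       message = best$message %||% "",
                       boundary = boundary,
                       separated = separated,
                       n_starts = length(starts))
  ), class = "risk_fit")
}

#' @export
coef.risk_fit <- function(object, ...) object$coefficients

#' @export
vcov.risk_fit <- function(object, ...) object$vcov

#' @export
logLik.risk_fit <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.risk_fit <- function(x, digits = 4, ...) {
  cat("Pooled EU/logistic risk-preference fit\n")
  cat(sprintf("  observations: %d, clustered on %d participants\n",
              x$n_obs, x$n_clusters))
  tab <- cbind(Estimate = x$coefficients, `Clustered SE` = x$se,
               z = x$z, `Pr(>|z|)` = x$p_values)
  print(round(tab, digits))
  cat(sprintf("  logLik: %.2f   BIC: %.1f\n", x$log_likelihood, x$bic))
  if (x$convergence$boundary) {
    cat("  warning: boundary/separation; inference unavailable\n")
  }
  invisible(x)
}

#' Individual-level risk-tolerance fit
#'
#' Fits alpha for a single participant by one-dimensional likelihood
#' maximization with the logistic slope held fixed at the pooled estimate
#' from the corresponding population-level analysis. The search is bounded;
#' a boundary flag is raised when the bound binds (for example, a
#' participant who always chose the certain amount).
#'
#' @param records Choice records for one participant.
#' @param sigma_fixed Pooled logistic-slope estimate to hold fixed.
#' @param bounds Search interval for alpha.
#' @param eps Probability clipping bound.
#' @param convention Choice-rule convention.
#' @return List: `alpha_hat`, `sigma_fixed`, `log_likelihood`,
#'   `boundary_flag`.
#' @export
fit_individual <- function(records, sigma_fixed, bounds = c(0.01, 4),
                           eps = 1e-12, convention = "slope") {
  stop_if_not_records(records)
  if (nrow(records) == 0L) stop("no records to fit", call. = FALSE)
  if (sigma_fixed <= 0) stop("`sigma_fixed` must be positive", call. = FALSE)
  y <- as.logical(records$chose_lottery)
  logv <- log(records$lottery_amount)
  logs <- log(records$safe_amount)
  pvec <- records$lottery_probability
  ll_at <- function(alpha) {
    eu_l <- pvec * exp(alpha * logv)
    eu_s <- exp(alpha * logs)
    pr <- lottery_choice_probability(eu_s, eu_l, sigma_fixed,
                                     convention = convention)
    sum(log(pmax(ifelse(y, pr, 1 - pr), eps)))
  }
  opt <- stats::optimize(ll_at, interval = bounds, maximum = TRUE,
                         tol = 1e-7)
  alpha_hat <- opt$maximum
  # optimize() never returns the exact endpoints; snap when the likelihood
  # is still climbing into the bound.
  tol <- 1e-3 * diff(bounds)
  boundary <- FALSE
  if (alpha_hat - bounds[1] < tol && ll_at(bounds[1]) >= opt$objective) {
    alpha_hat <- bounds[1]; boundary <- TRUE
  } else if (bounds[2] - alpha_hat < tol &&
             ll_at(bounds[2]) >= opt$objective) {
    alpha_hat <- bounds[2]; boundary <- TRUE
  } else if (alpha_hat - bounds[1] < tol || bounds[2] - alpha_hat < tol) {
    boundary <- TRUE
  }
  list(alpha_hat = alpha_hat,
       sigma_fixed = sigma_fixed,
       log_likelihood = ll_at(alpha_hat),
       boundary_flag = boundary)
}

#' Individual fits for every participant in a cohort
#'
#' @param records Choice records for one or more participants.
#' @param sigma_fixed Pooled logistic-slope estimate to hold fixed.
#' @param ... Passed to [fit_individual()].
#' @return Data frame: `participant_id`, `alpha_hat`, `sigma_fixed`,
#'   `log_likelihood`, `boundary_flag`.
#' @export
fit_individuals <- function(records, sigma_fixed, ...) {
  stop_if_not_records(records)
  ids <- unique(records$participant_id)
  rows <- lapply(ids, function(id) {
    f <- fit_individual(records[records$participant_id == id, ,
                                drop = FALSE], sigma_fixed, ...)
    data.frame(participant_id = id, alpha_hat = f$alpha_hat,
               sigma_fixed = f$sigma_fixed,
               log_likelihood = f$log_likelihood,
               boundary_flag = f$boundary_flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
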