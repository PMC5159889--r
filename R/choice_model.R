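#' Power-utility expected utility of a gamble
#'
#' The behavioural model values a lottery paying `v` with probability `p`
#' as EU = p * v^alpha, where alpha is the risk-tolerance exponent: alpha = 1
#' is risk neutrality over gains, alpha < 1 risk aversion, larger alpha more
#' risk tolerance. The certain option is valued through the same form with
#' p = 1.
#'
#' @param v Monetary amount(s), > 0.
#' @param p Payout probability(ies) in (0, 1].
#' @param alpha Risk-tolerance exponent(s), > 0.
#' @return Expected utility (utils), vectorized over the inputs.
#' @examples
#' expected_utility(5, 1, 0.5)      # sqrt(5)
#' expected_utility(7, 0.5, 1)      # 3.5
#' @export
expected_utility <- function(v, p, alpha) {
  if (anyNA(v) || any(v <= 0)) {
    stop("amounts `v` must be positive", call. = FALSE)
  }
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("probabilities `p` must lie in (0, 1]", call. = FALSE)
  }
  if (anyNA(alpha) || any(alpha <= 0)) {
    stop("`alpha` must be positive", call. = FALSE)
  }
  p * v^alpha
}

#' Evaluate the covariate-linear risk-tolerance link
#'
#' The risk-tolerance exponent is modelled as a linear function of
#' participant covariates, alpha = beta0 + sum_k beta_k x_k. A small
#' positive floor guards the power-utility domain (alpha > 0) while keeping
#' the link itself exactly linear; a `floored` attribute counts how often
#' the floor binds.
#'
#' @param coefficients Named numeric vector with an `intercept` element and
#'   one element per covariate column of `participants` (from
#'   `age`, `rppc_gmv`, `global_gmv`, `gender`, or any numeric column).
#' @param participants Data frame of participant covariates.
#' @param floor Lower bound applied to the linear predictor (default 0.01).
#' @return Numeric vector of alpha values, one per participant, with
#'   attribute `floored` giving the number of floor bindings.
#' @examples
#' alpha_from_covariates(c(intercept = 0.669, age = -0.003),
#'                       data.frame(age = 21))
#' @export
alpha_from_covariates <- function(coefficients, participants, floor = 0.01) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!"intercept" %in% names(coefficients)) {
    stop("`coefficients` must contain an `intercept` element", call. = FALSE)
  }
  covs <- setdiff(names(coefficients), "intercept")
  missing <- setdiff(covs, names(participants))
  if (length(missing)) {
    stop("participants lack covariate(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- rep_len(coefficients[["intercept"]], nrow(participants))
  if (length(covs)) {
    X <- as.matrix(participants[, covs, drop = FALSE])
    storage.mode(X) <- "double"
    lp <- lp + drop(X %*% coefficients[covs])
  }
  if (anyNA(lp) || any(!is.finite(lp))) {
    stop("linear predictor is not finite for some participants",
         call. = FALSE)
  }
  alpha <- pmax(lp, floor)
  attr(alpha, "floored") <- sum(lp < floor)
  alpha
}

#' Logistic choice rule
#'
#' Probability of choosing the lottery given the expected utilities of the
#' two options. Under the default `"slope"` convention the slope sigma
#' multiplies the EU difference, P = 1 / (1 + exp(-sigma * (EU_lottery -
#' EU_safe))); larger sigma means choices track EU differences more
#' deterministically. The `"temperature"` convention divides by sigma
#' instead.
#'
#' @param eu_safe,eu_lottery Expected utilities of the certain and lottery
#'   options.
#' @param sigma Slope of the choice function, > 0.
#' @param convention `"slope"` (default) or `"temperature"`.
#' @return Choice probability(ies) in (0, 1); the exponent is saturated to
#'   avoid overflow.
#' @export
lottery_choice_probability <- function(eu_safe, eu_lottery, sigma,
                                       convention = c("slope",
                                                      "temperature")) {
  convention <- match.arg(convention)
  if (anyNA(sigma) || any(sigma <= 0)) {
    stop("`sigma` must be positive", call. = FALSE)
  }
  d <- eu_lottery - eu_safe
  z <- switch(convention, slope = sigma * d, temperature = d / sigma)
  stats::plogis(pmin(pmax(z, -700), 700))
}

#' Dataset log-likelihood of the choice model
#'
#' Sum over records of the log-probability of the observed choice, with each
#' record's participant-specific alpha evaluated through the covariate link.
#' Probabilities are clipped at `eps` before logging; a `clipped` attribute
#' counts how many records were affected.
#'
#' @param records Choice records (see [build_choice_set()] columns plus
#'   `participant_id` and `chose_lottery`).
#' @param participants Covariate table with `participant_id` plus the link's
#'   covariates.
#' @param coefficients Named link coefficients (see
#'   [alpha_from_covariates()]).
#' @param sigma Logistic slope, > 0.
#' @param floor Alpha positivity floor.
#' @param eps Probability clipping bound.
#' @param convention Choice-rule convention, see
#'   [lottery_choice_probability()].
#' @return Log-likelihood in nats (<= 0), with attributes `clipped` and
#'   `floored`.
#' @export
choice_log_likelihood <- function(records, participants, coefficients,
                                  sigma, floor = 0.01, eps = 1e-12,
                                  convention = "slope") {
  stop_if_not_records(records)
  idx <- match(records$participant_id, participants$participant_id)
  if (anyNA(idx)) {
    stop("records reference participants missing from `participants`",
         call. = FALSE)
  }
  alpha_p <- alpha_from_covariates(coefficients, participants, floor = floor)
  alpha <- alpha_p[idx]
  eu_l <- expected_utility(records$lottery_amount,
                           records$lottery_probability, alpha)
  eu_s <- expected_utility(records$safe_amount, 1, alpha)
  p_lot <- lottery_choice_probability(eu_s, eu_l, sigma,
                                      convention = convention)
  y <- as.logical(records$chose_lottery)
  pr <- ifelse(y, p_lot, 1 - p_lot)
  clipped <- sum(pr < eps)
  if (clipped > 0) {
    warning(sprintf("%d record(s) had observed-choice probability below %g",
                    clipped, eps), call. = FALSE)
  }
  ll <- sum(log(pmax(pr, eps)))
  attr(ll, "clipped") <- clipped
  attr(ll, "floored") <- attr(alpha_p, "floored")
  ll
}
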