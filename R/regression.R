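# Model-free OLS with directional (one-tailed) tests, and residualization
# helpers for partial-regression (added-variable) plots.

#' OLS with one-tailed tests in predicted directions
#'
#' Ordinary least squares of a per-participant outcome (for example the
#' proportion of lottery choices) on covariates, with one-tailed p-values
#' for coefficients whose sign is predicted a priori: for a predicted
#' positive sign p = P(T > t), mirrored for a predicted negative sign.
#' Coefficients without a stated direction get two-tailed p-values.
#'
#' @param y Numeric outcome vector.
#' @param X Data frame of covariates (no intercept column; one is added).
#' @param directions Named numeric vector of predicted signs (+1 / -1) for
#'   the tested coefficients, names matching columns of `X`.
#' @return Data frame with `term`, `estimate`, `se`, `t`, `p`, `tail`.
#' @export
ols_one_tailed <- function(y, X, directions = numeric(0)) {
  stopifnot(is.numeric(y), is.data.frame(X))
  if (nrow(X) != length(y)) {
    stop("`y` and `X` must have matching rows", call. = FALSE)
  }
  if (length(y) <= ncol(X) + 1L) {
    stop("need more observations than parameters", call. = FALSE)
  }
  bad <- setdiff(names(directions), names(X))
  if (length(bad)) {
    stop("directions given for unknown term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dat <- cbind(.y = y, X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  terms <- rownames(sm)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  tval <- sm[, "t value"]
  p <- sm[, "Pr(>|t|)"]
  tail <- rep("two-sided", length(terms))
  for (nm in names(directions)) {
    i <- which(terms == nm)
    if (directions[[nm]] > 0) {
      p[i] <- stats::pt(tval[i], df, lower.tail = FALSE)
      tail[i] <- "one-sided (+)"
    } else {
      p[i] <- stats::pt(tval[i], df, lower.tail = TRUE)
      tail[i] <- "one-sided (-)"
    }
  }
  data.frame(term = terms, estimate = est, se = se, t = tval, p = p,
             tail = tail, row.names = NULL)
}

#' Residualize an outcome on control covariates
#'
#' Returns the residuals of an OLS regression (with intercept) of `y` on
#' the controls. Used to display one covariate's relationship with risk
#' tolerance after regressing out the contribution of the others.
#'
#' @param y Numeric vector.
#' @param controls Data frame of control covariates.
#' @return Residual vector.
#' @export
residualize <- function(y, controls) {
  stopifnot(is.numeric(y), is.data.frame(controls))
  if (length(y) <= ncol(controls) + 1L) {
    stop("need more observations than controls", call. = FALSE)
  }
  X <- if (ncol(controls) == 0L) {
    matrix(1, nrow = length(y), ncol = 1,
           dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = controls)
  }
  if (qr(X)$rank < ncol(X)) {
    stop("control matrix is rank deficient", call. = FALSE)
  }
  stats::lm.fit(X, y)$residuals
}

#' Added-variable (partial regression) pairing
#'
#' Residualizes both the outcome and a focal covariate on the same control
#' set, so that the slope of the residual-on-residual regression equals the
#' focal covariate's multiple-regression coefficient (the Frisch--Waugh
#' identity).
#'
#' @param y Outcome vector.
#' @param x Focal covariate vector.
#' @param controls Data frame of controls (may have zero columns).
#' @return List: `y_resid`, `x_resid`, `slope`.
#' @export
added_variable <- function(y, x, controls) {
  stopifnot(length(x) == length(y))
  y_r <- residualize(y, controls)
  x_r <- residualize(x, controls)
  slope <- sum(x_r * y_r) / sum(x_r^2)
  list(y_resid = y_r, x_resid = x_r, slope = slope)
}
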