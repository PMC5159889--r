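test_that("model specifications enumerate the nested covariate sets", {
  expect_equal(model_spec(1)$covariates, "age")
  expect_equal(model_spec(3)$covariates, c("age", "rppc_gmv"))
  expect_equal(model_spec(5)$covariates,
               c("age", "rppc_gmv", "global_gmv"))
  expect_equal(model_spec(2, gender = TRUE)$covariates,
               c("rppc_gmv", "gender"))
  expect_error(model_spec(7), "1\\.\\.5")
})

test_that("pooled MLE agrees with an exhaustive grid search on a toy set", {
  toy <- toy_cohort(2, alpha0 = 0.6, sigma = 1, seed = 31,
                    choice_set = build_choice_set(
                      amounts = c(6, 16, 44, 120)))
  fit <- fit_pooled(toy$records, toy$participants,
                    covariates = character(0), n_restarts = 2)

  b_grid <- seq(0.1, 1.5, by = 0.01)
  s_grid <- seq(0.2, 3, by = 0.01)
  ll <- function(b, s) as.numeric(
    choice_log_likelihood(toy$records, toy$participants,
                          c(intercept = b), s))
  grid_ll <- suppressWarnings(outer(b_grid, s_grid, Vectorize(ll)))
  best <- which(grid_ll == max(grid_ll), arr.ind = TRUE)[1, ]

  expect_gte(fit$log_likelihood, max(grid_ll) - 1e-8)
  # agreement within the grid's own resolution (0.01 per parameter)
  expect_lt(abs(coef(fit)[["intercept"]] - b_grid[best["row"]]), 0.011)
  expect_lt(abs(coef(fit)[["sigma"]] - s_grid[best["col"]]), 0.011)
})

test_that("individual alpha maximizes the profile likelihood", {
  cs <- build_choice_set()
  part <- data.frame(participant_id = "P001")
  rec <- simulate_choices(part, cs, c(intercept = 0.6), 1, seed = 77)
  ind <- fit_individual(rec, sigma_fixed = 1)
  # recovery at the task's information level for a single participant
  expect_equal(ind$alpha_hat, 0.6, tolerance = 0.15)
  expect_false(ind$boundary_flag)
  # dominance over a dense grid of candidate alphas
  grid <- seq(0.01, 4, length.out = 200)
  ll_grid <- suppressWarnings(vapply(grid, function(a) as.numeric(
    choice_log_likelihood(rec, part, c(intercept = a), 1)), numeric(1)))
  expect_gte(ind$log_likelihood, max(ll_grid) - 1e-6)
})

test_that("all-safe responders hit the lower alpha bound with a flag", {
  cs <- build_choice_set()
  rec <- records_from_choices(cs, rep(0L, nrow(cs)))
  ind <- fit_individual(rec, sigma_fixed = 1)
  expect_equal(ind$alpha_hat, 0.01)
  expect_true(ind$boundary_flag)
})

test_that("fit_individuals returns one row per participant", {
  toy <- toy_cohort(3, seed = 41)
  out <- fit_individuals(toy$records, sigma_fixed = 1)
  expect_equal(nrow(out), 3)
  expect_setequal(out$participant_id, toy$participants$participant_id)
  one <- fit_individual(
    toy$records[toy$records$participant_id == "P002", ], 1)
  expect_equal(out$alpha_hat[out$participant_id == "P002"], one$alpha_hat)
})

test_that("clustered sandwich reduces to known closed forms", {
  withr::with_seed(13, {
    n <- 40; k <- 2
    scores <- matrix(rnorm(n * k), n, k)
    A <- crossprod(matrix(rnorm(n * k), n, k)) / n * 50  # SPD
    # singleton clusters: heteroskedasticity sandwich times n/(n-1)
    V1 <- cluster_robust_vcov(scores, seq_len(n), A)
    Ainv <- solve(A)
    expect_equal(V1, Ainv %*% crossprod(scores) %*% Ainv * n / (n - 1),
                 ignore_attr = TRUE)
    # identical per-cluster score sums: B = G * s s'
    G <- 8
    s <- rnorm(k)
    sc <- matrix(rep(s / 5, each = G * 5), ncol = k)  # 5 rows per cluster
    V2 <- cluster_robust_vcov(sc, rep(seq_len(G), each = 5), A)
    expect_equal(V2, Ainv %*% (G * tcrossprod(s)) %*% Ainv * G / (G - 1),
                 ignore_attr = TRUE)
  })
  expect_error(cluster_robust_vcov(matrix(1:4, 2), c(1, 1), diag(2)),
               "2 clusters")
  expect_error(cluster_robust_vcov(matrix(1:4, 2), c(1, 2),
                                   matrix(0, 2, 2)), "singular")
})

test_that("clustered sandwich matches the established estimator on a GLM", {
  library(sandwich)
  withr::with_seed(42, {
    n <- 200; id <- rep(1:20, each = 10)
    x <- rnorm(n); u <- rnorm(20)[id]
    y <- rbinom(n, 1, plogis(0.5 + x + u))
  })
  g <- glm(y ~ x, family = binomial)
  X <- model.matrix(g)
  p <- fitted(g)
  V <- cluster_robust_vcov(X * (y - p), id,
                           crossprod(X * sqrt(p * (1 - p))))
  expect_equal(V, vcovCL(g, cluster = id, type = "HC0", cadjust = TRUE),
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("clustered SEs track a cluster-bootstrap oracle", {
  G <- 52
  parts <- data.frame(participant_id = sprintf("P%03d", 1:G))
  cs <- small_choice_set()
  rec <- simulate_choices(parts, cs, c(intercept = 0.6), 1, seed = 88)
  fit <- fit_pooled(rec, parts, covariates = character(0), n_restarts = 0)
  se_cl <- fit$se["intercept"]

  boot <- withr::with_seed(89, {
    replicate(400, {
      ids <- sample(parts$participant_id, G, replace = TRUE)
      pieces <- lapply(seq_along(ids), function(j) {
        r <- rec[rec$participant_id == ids[j], ]
        r$participant_id <- sprintf("B%03d", j)
        r
      })
      brec <- do.call(rbind, pieces)
      bfit <- fit_pooled(brec, data.frame(participant_id =
                                            sprintf("B%03d", seq_len(G))),
                         covariates = character(0), n_restarts = 0)
      coef(bfit)[["intercept"]]
    })
  })
  expect_equal(unname(se_cl), sd(boot), tolerance = 0.20)
})

test_that("BIC arithmetic and ranking behave as defined", {
  expect_equal(bic_value(-1500, 3, 3077), 3024.0951311, tolerance = 1e-7)
  expect_equal(bic_value(-250, 0, 100), 500)
  expect_equal(sort(bic_rank(c(3084, 3024, 3031, 3011, 3016))), 1:5)
  expect_equal(bic_rank(c(3084, 3024, 3031, 3011, 3016)),
               c(5, 3, 4, 1, 2))
})

test_that("pooled fit is invariant to record order and cluster labels", {
  toy <- toy_cohort(6, seed = 55)
  f0 <- fit_pooled(toy$records, toy$participants,
                   covariates = character(0), n_restarts = 0)
  perm <- withr::with_seed(56, sample.int(nrow(toy$records)))
  f1 <- fit_pooled(toy$records[perm, ], toy$participants,
                   covariates = character(0), n_restarts = 0)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-7)
  expect_equal(f0$se, f1$se, tolerance = 1e-6)
  # relabel clusters
  relab <- toy$records
  map <- setNames(sprintf("Q%03d", 6:1), toy$participants$participant_id)
  relab$participant_id <- unname(map[relab$participant_id])
  parts2 <- data.frame(participant_id = unname(map))
  f2 <- fit_pooled(relab, parts2, covariates = character(0),
                   n_restarts = 0)
  expect_equal(coef(f0), coef(f2), tolerance = 1e-7)
  expect_equal(f0$se, f2$se, tolerance = 1e-6)
})

test_that("complete separation is flagged rather than silently fit", {
  cs <- small_choice_set()
  parts <- data.frame(participant_id = c("A", "B"))
  rec <- rbind(records_from_choices(cs, rep(1L, nrow(cs)), "A"),
               records_from_choices(cs, rep(1L, nrow(cs)), "B"))
  expect_warning(
    fit <- fit_pooled(rec, parts, covariates = character(0),
                      n_restarts = 0),
    "separation")
  expect_true(fit$convergence$boundary)
  expect_true(all(is.na(fit$vcov)))
})

test_that("one-tailed OLS halves the two-tailed p in the predicted sign", {
  withr::with_seed(7, {
    x <- rnorm(40)
    y <- 2 * x + 1 + rnorm(40, sd = 0.01)
  })
  res <- ols_one_tailed(y, data.frame(x = x), directions = c(x = +1))
  bx <- res[res$term == "x", ]
  expect_equal(bx$estimate, 2, tolerance = 0.01)
  expect_lt(bx$p, 1e-12)

  withr::with_seed(8, {
    x2 <- rnorm(30); y2 <- 0.4 * x2 + rnorm(30)
  })
  two <- summary(lm(y2 ~ x2))$coefficients["x2", "Pr(>|t|)"]
  one_match <- ols_one_tailed(y2, data.frame(x2 = x2),
                              directions = c(x2 = +1))
  one_mismatch <- ols_one_tailed(y2, data.frame(x2 = x2),
                                 directions = c(x2 = -1))
  b <- coef(lm(y2 ~ x2))[["x2"]]
  expect_gt(b, 0)  # estimate's sign matches the + prediction here
  expect_equal(one_match$p[one_match$term == "x2"], two / 2)
  expect_equal(one_mismatch$p[one_mismatch$term == "x2"], 1 - two / 2)

  expect_error(ols_one_tailed(y2, data.frame(a = x2, b = x2)),
               "rank deficient")
  expect_error(ols_one_tailed(y2, data.frame(x2 = x2),
                              directions = c(zz = 1)), "unknown")
})

test_that("residualization obeys the Frisch-Waugh identity", {
  withr::with_seed(12, {
    n <- 60
    ctrl <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
    x <- 0.5 * ctrl$c1 + rnorm(n)
    y <- 1.5 * x - 0.8 * ctrl$c1 + 0.3 * ctrl$c2 + rnorm(n)
  })
  av <- added_variable(y, x, ctrl)
  full <- coef(lm(y ~ x + c1 + c2, data = cbind(ctrl, x = x)))[["x"]]
  expect_equal(av$slope, full, tolerance = 1e-10)

  # orthogonal control: residuals are just the demeaned outcome
  y0 <- rnorm(30)
  ortho <- data.frame(z = rep(c(-1, 1), 15))
  y_orth <- y0 - mean(y0)
  y_orth <- y_orth - sum(y_orth * ortho$z) / sum(ortho$z^2) * ortho$z
  expect_equal(residualize(y_orth, ortho), y_orth - mean(y_orth),
               ignore_attr = TRUE)
  # outcome equal to the control: residuals vanish
  expect_equal(max(abs(residualize(ortho$z, ortho))), 0, tolerance = 1e-12)
})
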