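test_that("design expansion counts mains, interactions and quadratics", {
  cohort <- generate_subject_cohort(cohort_spec(n_young = 10, n_old = 10,
                                                noise_sd = 0, seed = 1))
  d <- build_design(cohort, c("e_local_task", "e_global_task", "mean_rt",
                              "age_group"))
  # 4 mains + C(4,2)=6 interactions + 3 quadratics (binary age^2 dropped)
  expect_equal(ncol(d$X), 13)
  expect_equal(table(d$terms$type)[["main"]], 4)
  expect_equal(table(d$terms$type)[["interaction"]], 6)
  expect_equal(table(d$terms$type)[["quadratic"]], 3)
  expect_false("I(age_group^2)" %in% d$terms$term)

  cohort$flat <- 1
  expect_error(build_design(cohort, c("e_local_task", "flat")), "constant")
})

test_that("OLS matches an explicit normal-equations oracle", {
  set.seed(101)
  for (rep in 1:10) {
    n <- 8; p <- 2
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, c("a", "b")))
    y <- rnorm(n)
    fit <- ols_fit(X, y)
    Xi <- cbind(1, X)
    beta_oracle <- solve(crossprod(Xi), crossprod(Xi, y))
    expect_equal(unname(coef(fit)), as.numeric(beta_oracle),
                 tolerance = 1e-10)
    # SEs from sigma^2 (X'X)^-1
    res <- y - Xi %*% beta_oracle
    s2 <- sum(res^2) / (n - p - 1)
    se_oracle <- sqrt(diag(s2 * solve(crossprod(Xi))))
    expect_equal(unname(fit$coefficients$se), unname(se_oracle),
                 tolerance = 1e-10)
  }
})

test_that("OLS inference agrees with lm/summary/confint", {
  set.seed(5)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X %*% c(0.5, -1, 0) + rnorm(40)
  fit <- ols_fit(X, y)
  ref <- lm(y ~ a + b + c, data = data.frame(y = y, X))
  sm <- summary(ref)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-12)
  expect_equal(unname(fit$coefficients$p),
               unname(sm$coefficients[, 4]), tolerance = 1e-12)
  expect_equal(unname(as.matrix(fit$coefficients[, c("ci_lo", "ci_hi")])),
               unname(confint(ref)), tolerance = 1e-12)
  expect_equal(fit$r2, sm$r.squared, tolerance = 1e-12)
  expect_equal(fit$adj_r2, sm$adj.r.squared, tolerance = 1e-12)
  expect_equal(fit$f_stat, unname(sm$fstatistic[1]), tolerance = 1e-12)
  # the RSS-scale AIC differs from stats::AIC only by a constant in n
  const <- fit$n * (log(2 * pi) + 1)  # absorbed additive terms
  expect_equal(fit$aic + const, AIC(ref), tolerance = 1e-8)
})

test_that("exact linear responses give R2 = 1 and orthogonal columns zero", {
  set.seed(9)
  X <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 + 3 * X[, 1] - X[, 2]
  fit <- ols_fit(X, y)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  x <- rnorm(30)
  z <- residuals(lm(rnorm(30) ~ x))   # orthogonal to x by construction
  fit2 <- ols_fit(cbind(x = x, z = z), 3 * x)
  expect_lt(abs(coef(fit2)[["z"]]), 1e-10)

  expect_error(ols_fit(cbind(a = x, b = 2 * x), rnorm(30)), "singular")
})

test_that("a single informative candidate is retained with its slope", {
  set.seed(33)
  d <- data.frame(x = runif(60), junk = runif(60))
  d$y <- 5 * d$x + rnorm(60, sd = 0.01)
  fit <- stepwise_select(y ~ x + junk, d, quadratics = FALSE,
                         interactions = FALSE)
  expect_true("x" %in% fit$selected)
  expect_false("junk" %in% fit$selected)
  expect_equal(coef(fit)[["x"]], 5, tolerance = 0.05)
})

test_that("stepwise never ends above the full or empty model AIC", {
  set.seed(44)
  for (rep in 1:5) {
    d <- data.frame(a = rnorm(80), b = rnorm(80), g = rbinom(80, 1, 0.5))
    d$y <- 0.5 * d$a + rnorm(80)
    fit <- stepwise_select(y ~ a + b + g, d)
    design <- build_design(d, c("a", "b", "g"))
    full <- ols_fit(design$X, d$y)
    empty <- ols_fit(design$X[, 0, drop = FALSE], d$y)
    expect_lte(fit$fit$aic, full$aic + 1e-8)
    expect_lte(fit$fit$aic, empty$aic + 1e-8)
  }
})

test_that("stepwise recovers the five-term generating model when noise-free", {
  cohort <- generate_subject_cohort(cohort_spec(n_young = 40, n_old = 40,
                                                noise_sd = 0, seed = 3))
  fit <- stepwise_select(dprime ~ e_local_task + e_global_task + mean_rt +
                           n_volumes_removed + age_group, cohort)
  expect_setequal(fit$selected,
                  c("e_local_task", "e_global_task", "mean_rt", "age_group",
                    "e_global_task:age_group"))
  eq <- default_cohort_equations()
  expect_equal(coef(fit)[["e_local_task"]], eq$young[["e_local"]],
               tolerance = 1e-6)
  expect_equal(coef(fit)[["e_global_task"]], eq$young[["e_global"]],
               tolerance = 1e-6)
  expect_equal(coef(fit)[["mean_rt"]], eq$young[["rt"]], tolerance = 1e-6)
})

test_that("hierarchy flag prevents orphan interactions", {
  set.seed(55)
  d <- data.frame(a = runif(100, 0, 1), b = runif(100, 0, 1))
  d$y <- 4 * d$a * d$b + rnorm(100, sd = 0.05)
  fit <- stepwise_select(y ~ a + b, d, hierarchy = TRUE)
  if ("a:b" %in% fit$selected) {
    expect_true(all(c("a", "b") %in% fit$selected))
  }
})

test_that("cohort equation deconstruction follows the interaction algebra", {
  # intercept a, slope b, group g, slope x group c
  set.seed(66)
  n <- 50
  d <- data.frame(x = runif(n), g = rep(0:1, length.out = n))
  d$y <- 1.5 + 2 * d$x + 0.7 * d$g - 1.2 * d$x * d$g
  fit <- stepwise_select(y ~ x + g, d, quadratics = FALSE)
  eqs <- cohort_equations(fit, group = "g")
  expect_equal(eqs$group_0[["(Intercept)"]], 1.5, tolerance = 1e-6)
  expect_equal(eqs$group_0[["x"]], 2, tolerance = 1e-6)
  expect_equal(eqs$group_1[["(Intercept)"]], 1.5 + 0.7, tolerance = 1e-6)
  expect_equal(eqs$group_1[["x"]], 2 - 1.2, tolerance = 1e-6)

  # no interactions -> groups share slopes
  d2 <- data.frame(x = runif(n), g = rep(0:1, length.out = n))
  d2$y <- 1 + 3 * d2$x + 2 * d2$g + rnorm(n, sd = 1e-8)
  fit2 <- stepwise_select(y ~ x + g, d2, quadratics = FALSE)
  eqs2 <- cohort_equations(fit2, group = "g")
  expect_equal(eqs2$group_0[["x"]], eqs2$group_1[["x"]])

  expect_error(cohort_equations(fit, group = "absent"), "group main effect")
})

test_that("predict and residuals are consistent with the fit", {
  cohort <- generate_subject_cohort(cohort_spec(n_young = 30, n_old = 30,
                                                noise_sd = 0.2, seed = 12))
  fit <- stepwise_select(dprime ~ e_local_task + e_global_task + mean_rt +
                           age_group, cohort)
  pred <- predict(fit, cohort)
  expect_equal(pred, fitted(fit), tolerance = 1e-10)
  expect_equal(cohort$dprime - pred, residuals(fit), tolerance = 1e-10)
})

test_that("model fit serializes to JSON with Table-style fields", {
  cohort <- generate_subject_cohort(cohort_spec(n_young = 20, n_old = 20,
                                                noise_sd = 0.1, seed = 2))
  fit <- stepwise_select(dprime ~ e_local_task + e_global_task + mean_rt +
                           age_group, cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_modelfit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n, nrow(cohort))
  expect_equal(unlist(back$coefficients), coef(fit), tolerance = 1e-12)
  expect_true(all(c("se", "t", "p", "ci_lo", "ci_hi", "aic", "adj_r2")
                  %in% names(back)))
})
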