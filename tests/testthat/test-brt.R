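sim_brt_data <- function(n = 500, seed = 1) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n), x5 = rnorm(n), x6 = rnorm(n))
  d$y <- 2 * d$x1
  d
}

test_that("a deterministic single-signal response is learned out of fold", {
  d <- sim_brt_data(500)
  fit <- fit_brt(d, "y", paste0("x", 1:6), fast_hp(), seed = 4)
  expect_gt(fit$cv_correlation, 0.95)
  expect_equal(fit$n_trees_selected %% fit$hyperparams$step_size, 0)
  expect_gt(fit$n_trees_selected, 0)
  imp <- relative_importance(fit)
  expect_equal(imp$covariate[1], "x1")
  expect_gt(imp$relative_importance[1], 90)
})

test_that("fits are deterministic seed for seed", {
  d <- sim_brt_data(240, seed = 2)
  hp <- brt_hyperparams(learning_rate = 0.05, max_trees = 300, cv_folds = 5)
  f1 <- fit_brt(d, "y", paste0("x", 1:6), hp, seed = 9)
  f2 <- fit_brt(d, "y", paste0("x", 1:6), hp, seed = 9)
  expect_identical(f1$n_trees_selected, f2$n_trees_selected)
  expect_identical(f1$cv_deviance_trace, f2$cv_deviance_trace)
  expect_equal(predict(f1), predict(f2), tolerance = 1e-12)
  f3 <- fit_brt(d, "y", paste0("x", 1:6), hp, seed = 10)
  expect_false(identical(f1$folds, f3$folds))
})

test_that("a constant response degenerates gracefully", {
  d <- sim_brt_data(100)
  d$y <- 3.5
  fit <- fit_brt(d, "y", paste0("x", 1:6), fast_hp(), seed = 1)
  expect_equal(unique(predict(fit)), 3.5)
  expect_warning(imp <- relative_importance(fit), "no splits")
  expect_true(all(imp$relative_importance == 0))
  expect_setequal(imp$rank, 1:6)
})

test_that("invalid inputs are rejected with informative errors", {
  d <- sim_brt_data(100)
  d$y[c(3, 7)] <- c(NA, Inf)
  expect_error(fit_brt(d, "y", paste0("x", 1:6), fast_hp()),
               "non-finite response.*3, 7")
  d2 <- sim_brt_data(12)
  expect_error(fit_brt(d2, "y", paste0("x", 1:6), brt_hyperparams()),
               "at least 20 rows")
})

test_that("training deviance is non-increasing along the selected ensemble", {
  d <- sim_brt_data(300, seed = 5)
  d$y <- d$y + rnorm(300, 0, 0.5)
  fit <- fit_brt(d, "y", paste0("x", 1:6), fast_hp(), seed = 2)
  tr <- fit$train_deviance_trace$train_deviance
  expect_true(all(diff(tr) <= 1e-8))
})

test_that("importances are non-negative, sum to 100 and rank a permutation", {
  d <- sim_brt_data(300, seed = 6)
  d$y <- d$y + 0.5 * d$x2 + rnorm(300, 0, 0.3)
  fit <- fit_brt(d, "y", paste0("x", 1:6), fast_hp(), seed = 3)
  imp <- relative_importance(fit)
  expect_true(all(imp$relative_importance >= 0))
  expect_equal(sum(imp$relative_importance), 100, tolerance = 1e-6)
  expect_setequal(imp$rank, seq_along(imp$rank))
  # single-covariate model: that covariate carries all the importance
  fit1 <- fit_brt(d, "y", "x1", fast_hp(), seed = 3)
  imp1 <- relative_importance(fit1)
  expect_equal(imp1$relative_importance, 100, tolerance = 1e-9)
})

test_that("partial dependence recovers additive component shapes", {
  set.seed(8)
  n <- 500
  d <- data.frame(x1 = runif(n, -2, 2), x2 = runif(n, -2, 2),
                  x3 = rnorm(n))
  f1 <- function(x) sin(1.5 * x)
  f2 <- function(x) 0.5 * x
  d$y <- f1(d$x1) + f2(d$x2) + rnorm(n, 0, 0.1)
  fit <- fit_brt(d, "y", c("x1", "x2", "x3"),
                 brt_hyperparams(learning_rate = 0.05, max_trees = 3000,
                                 cv_folds = 5), seed = 6)
  grid <- seq(-1.8, 1.8, length.out = 25)
  pd <- marginal_response(fit, "x1", grid = grid)
  got <- pd$response - mean(pd$response)
  want <- f1(grid) - mean(f1(grid))
  expect_lt(sqrt(mean((got - want)^2)), 0.1)
  # constant model -> flat curve
  dc <- d; dc$y <- 1
  fitc <- fit_brt(dc, "y", c("x1", "x2", "x3"), fast_hp(), seed = 1)
  pdc <- marginal_response(fitc, "x1", grid = grid)
  expect_lt(diff(range(pdc$response)), 1e-12)
  # extrapolation beyond the observed range is flagged
  pde <- marginal_response(fit, "x1", grid = c(-5, 0, 5))
  expect_equal(attr(pde, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("categorical covariates are encoded ordinally and can matter", {
  set.seed(12)
  n <- 300
  d <- data.frame(x1 = rnorm(n),
                  radar_type = sample(c("weather", "vertical-looking"), n,
                                      replace = TRUE))
  d$y <- 2 * (d$radar_type == "vertical-looking") + 0.2 * d$x1
  fit <- fit_brt(d, "y", c("x1", "radar_type"), fast_hp(), seed = 2)
  imp <- relative_importance(fit)
  expect_equal(imp$covariate[1], "radar_type")
  pd <- marginal_response(fit, "radar_type")
  expect_equal(sort(pd$value), c("vertical-looking", "weather"))
  expect_gt(pd$response[pd$value == "vertical-looking"],
            pd$response[pd$value == "weather"])
})
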