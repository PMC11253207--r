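sim_flight <- function(n_per = 100, n_sites = 4, gap = 2.5, site_sd = 0.5,
                       noise_sd = 1, seed = 1, base = 14) {
  set.seed(seed)
  sites <- paste0("s", seq_len(n_sites))
  eff <- rnorm(n_sites, 0, site_sd)
  do.call(rbind, lapply(seq_len(n_sites), function(i) {
    data.frame(
      site_id = sites[i],
      season = rep(c("spring", "autumn"), each = n_per),
      airspeed = base + rep(c(gap, 0), each = n_per) + eff[i] +
        rnorm(2 * n_per, 0, noise_sd),
      groundspeed = base + eff[i] + rnorm(2 * n_per, 0, noise_sd),
      stringsAsFactors = FALSE)
  }))
}

test_that("the LMM season estimate equals the raw mean difference when sites do not vary", {
  d <- sim_flight(n_per = 60, n_sites = 3, site_sd = 0, seed = 11)
  fit <- suppressMessages(lmm_season_effect(d, "airspeed"))
  raw <- mean(d$airspeed[d$season == "spring"]) -
    mean(d$airspeed[d$season == "autumn"])
  expect_equal(fit$estimate, raw, tolerance = 1e-6)
  expect_equal(fit$test, "lmm")
  expect_equal(fit$spring_mean - fit$autumn_mean, raw, tolerance = 1e-12)
})

test_that("an injected 2.5 m/s seasonal airspeed gap is recovered with random site intercepts", {
  d <- sim_flight(n_per = 50, n_sites = 4, gap = 2.5, site_sd = 0.5,
                  noise_sd = 1, seed = 21)  # 400 nights
  fit <- lmm_season_effect(d, "airspeed")
  expect_lt(abs(fit$estimate - 2.5), 0.2)
  expect_lt(fit$p, 0.001)
  expect_true(is.finite(fit$df))
})

test_that("null simulations keep the season effect quiet", {
  rejections <- 0L
  for (i in 1:40) {
    d <- sim_flight(n_per = 30, n_sites = 3, gap = 0, seed = 100 + i)
    fit <- suppressMessages(lmm_season_effect(d, "airspeed"))
    if (fit$p < 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 6)  # ~2 expected at the nominal level
})

test_that("swapping season labels negates the estimate", {
  d <- sim_flight(n_per = 40, n_sites = 3, gap = 1.5, seed = 31)
  f1 <- lmm_season_effect(d, "airspeed")
  d2 <- d
  d2$season <- ifelse(d$season == "spring", "autumn", "spring")
  f2 <- lmm_season_effect(d2, "airspeed")
  expect_equal(f1$estimate, -f2$estimate, tolerance = 1e-6)
})

test_that("a single site downgrades to a Welch t-test with a warning", {
  d <- sim_flight(n_per = 40, n_sites = 1, gap = 2, seed = 41)
  expect_warning(fit <- lmm_season_effect(d, "airspeed"), "single site")
  expect_equal(fit$test, "t")
  expect_lt(fit$p, 0.01)
})

test_that("Bonferroni level is alpha/m; four weather comparisons give 0.0125", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  for (m in c(1, 2, 5, 13)) expect_equal(bonferroni_alpha(0.05, m), 0.05 / m)
})

test_that("seasonal weather t-tests detect a shifted temperature and skip absent variables", {
  set.seed(51)
  n <- 400
  cov <- data.frame(
    season = rep(c("spring", "autumn"), each = n),
    temperature = c(rnorm(n, 16.71, 3), rnorm(n, 21, 3)),
    u = rnorm(2 * n), v_raw = rnorm(2 * n),
    wind_speed = abs(rnorm(2 * n, 4, 1.5)))
  res <- seasonal_weather_tests(cov)
  expect_equal(unique(res$alpha_adjusted), 0.0125)
  tt <- res[res$variable == "temperature", ]
  expect_true(tt$significant)
  expect_lt(tt$estimate, 0)  # spring colder than autumn
  # identical samples give t = 0
  cov0 <- cov; cov0$temperature <- rep(rnorm(n), 2)
  r0 <- seasonal_weather_tests(cov0, variables = "temperature")
  expect_equal(r0$statistic, 0, tolerance = 1e-9)
  expect_warning(seasonal_weather_tests(cov, variables = c("temperature",
                                                           "nonexistent")),
                 "absent")
})

test_that("seasonal speed contrasts reproduce the published worked example", {
  sc <- speed_contrasts(15.1, 15.7, 16.06, 13.6)
  expect_equal(sc$airspeed_pct, 18)
  expect_equal(sc$airspeed_diff_ms, 2.5)
  expect_equal(sc$groundspeed_diff_ms, 0.6)
  expect_equal(sc$groundspeed_pct, 4)
  # equal means -> all zero
  z <- speed_contrasts(10, 10, 10, 10)
  expect_true(all(unlist(z) == 0))
  # hand-computed case
  h <- speed_contrasts(10, 11, 12, 10)
  expect_equal(h$airspeed_diff_ms, 2.0)
  expect_equal(h$airspeed_pct, 20)
  expect_equal(h$groundspeed_diff_ms, 1.0)
  expect_equal(h$groundspeed_pct, 10)
  expect_error(speed_contrasts(10, 11, 12, 0), "positive")
})
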