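test_that("interpolation is linear in geopotential height", {
  p <- data.frame(z_m = c(500, 1500), t_c = c(10, 0))
  expect_equal(interp_to_height(p, 1000)$t_c, 5)
  expect_equal(interp_to_height(p, 500)$t_c, 10)   # exact level identity
  expect_equal(interp_to_height(p, 1500)$t_c, 0)
  # clamped below the lowest level
  low <- interp_to_height(p, 100)
  expect_equal(low$t_c, 10)
  expect_true(attr(low, "clamped"))
  expect_error(interp_to_height(data.frame(z_m = c(1, 1), t_c = c(0, 1)), 1),
               "monotone")
  expect_error(interp_to_height(p[1, ], 1000), "two levels")
})

test_that("dense sampling of a smooth profile interpolates within 0.5%", {
  z <- seq(0, 3000, by = 50)
  truth <- function(z) 20 - 5 * (z / 1000)^2   # curvature stresses linearity
  p <- data.frame(z_m = z, t_c = truth(z))
  for (target in c(137, 512, 1499, 2750)) {
    got <- interp_to_height(p, target)$t_c
    expect_lt(abs(got - truth(target)) / abs(truth(target)), 0.005)
  }
  # affine profiles are reproduced exactly at any target
  pa <- data.frame(z_m = z, t_c = 3 + 0.002 * z, u_ms = -1 + 0.001 * z)
  iv <- interp_to_height(pa, 1234.5)
  expect_equal(iv$t_c, 3 + 0.002 * 1234.5, tolerance = 1e-12)
  expect_equal(iv$u_ms, -1 + 0.001 * 1234.5, tolerance = 1e-12)
})

const_profiles <- function(night, t_c = 10, u = 3, v = -4) {
  hours <- seq(night$sunset, night$sunrise, by = 3600)
  nh <- length(hours)
  data.frame(site_id = "s1",
             timestamp = rep(hours, each = 3),
             pressure_hpa = rep(c(1000, 900, 800), nh),
             t_c = t_c, u_ms = u, v_ms = v, rh_pct = 50, w_pas = 0.01,
             cc = 0.2, z_m = rep(c(100, 1000, 2000), nh))
}

test_that("constant weather yields covariates equal to that constant", {
  site <- vlr_site(elev = 0)
  night <- solar_night(site$latitude, site$longitude, "2018-04-10")
  p <- const_profiles(night, t_c = 12, u = 3, v = 4)
  cv <- nightly_covariates(p, night, site, "spring")
  expect_equal(cv$temperature, 12)
  expect_equal(cv$u, 3)
  expect_equal(cv$v_raw, 4)
  expect_equal(cv$v, 4)           # spring: no flip
  expect_equal(cv$wind_speed, 5)  # 3-4-5 triangle
  expect_true(is.na(cv$d_temperature))  # first night: deltas missing
  expect_equal(cv$ordinal_date, 100L)
})

test_that("autumn flips the sign of v so positive means southward support", {
  site <- vlr_site(elev = 0)
  night <- solar_night(site$latitude, site$longitude, "2018-09-10")
  p <- const_profiles(night, v = -3)  # wind toward the south at 3 m/s
  cv <- nightly_covariates(p, night, site, "autumn")
  expect_equal(cv$v, 3)
  expect_equal(cv$v_raw, -3)
  # flipping twice restores the raw component
  expect_equal(-cv$v, cv$v_raw)
  # wind speed uses the unrotated components
  expect_equal(cv$wind_speed, sqrt(3^2 + 3^2))
})

test_that("deltas chain night over night and stay missing on the first night", {
  site <- vlr_site(elev = 0)
  n1 <- solar_night(site$latitude, site$longitude, "2018-04-10")
  n2 <- solar_night(site$latitude, site$longitude, "2018-04-11")
  p1 <- const_profiles(n1, t_c = 10)
  p2 <- const_profiles(n2, t_c = 14)
  nights <- rbind(n1, n2)
  cv <- season_covariates(rbind(p1, p2), nights, site, "spring")
  expect_true(is.na(cv$d_temperature[1]))
  expect_equal(cv$d_temperature[2], 4)
  expect_equal(cv$d_u[2], 0)
})

test_that("nightly wind speed is the mean of hourly speeds, not the speed of the mean", {
  site <- vlr_site(elev = 0)
  night <- solar_night(site$latitude, site$longitude, "2018-04-10")
  p <- const_profiles(night, u = 5, v = 0)
  # rotate the wind 180 degrees for the second half of the night
  half <- p$timestamp > night$sunset + as.numeric(
    night$sunrise - night$sunset, units = "secs") / 2
  p$u_ms[half] <- -5
  cv <- nightly_covariates(p, night, site, "spring")
  expect_equal(cv$wind_speed, 5)      # every hour blows at 5 m/s
  expect_lt(abs(cv$u), 5)             # components largely cancel
})

test_that("correlation screen flags collinear pairs and reports constants", {
  set.seed(10)
  d <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
  d$dup <- d$a
  d$neg <- -d$b
  d$const <- 1
  scr <- correlation_screen(d, threshold = 0.7)
  pairs <- paste(scr$flagged$var1, scr$flagged$var2)
  expect_true("a dup" %in% pairs)
  expect_true("b neg" %in% pairs)
  expect_equal(scr$flagged$r[scr$flagged$var1 == "b"], -1, tolerance = 1e-12)
  expect_equal(scr$constant, "const")
  # independent columns do not get flagged
  scr2 <- correlation_screen(d[c("a", "b", "c")], threshold = 0.7)
  expect_equal(nrow(scr2$flagged), 0)
  expect_error(correlation_screen(d[1:2, ]), "3 complete rows")
})
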