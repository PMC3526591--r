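# Fickian transport: closed form, chamber solver, D estimation, calibration.

test_that("closed-form profile matches its boundary and initial conditions", {
  p <- diffusion_params(2e-6)
  expect_equal(closed_form_profile(0, c(1, 60, 7200), p), rep(0.5, 3))
  expect_equal(closed_form_profile(c(1, 3, 5), 0, p), rep(0, 3))
  # singular corner: right limit in t
  expect_equal(closed_form_profile(0, 0, p), 0.5)
  expect_error(closed_form_profile(-1, 10, p), "y_mm")
  expect_error(closed_form_profile(1, -10, p), "t_s")
})

test_that("closed-form value agrees with an independent erfc oracle", {
  skip_if_not_installed("pracma")
  p <- diffusion_params(2e-6)
  # D = 2e-6 cm^2/s = 2e-4 mm^2/s; u = y / (2 sqrt(D t))
  cases <- expand.grid(y = c(0.5, 2, 3, 5), t = c(600, 3600, 7200))
  u <- cases$y / (2 * sqrt(2e-4 * cases$t))
  expect_equal(closed_form_profile(cases$y, cases$t, p),
               0.5 * pracma::erfc(u), tolerance = 1e-12)
  # frozen value: half erfc(0.8333...) at y = 2 mm, t = 2 h
  expect_equal(closed_form_profile(2, 7200, p), 0.1192964, tolerance = 1e-6)
})

test_that("profile is within [0, 0.5], decreasing in y, increasing in t", {
  p <- diffusion_params(2e-6)
  y <- seq(0, 5, by = 0.1)
  for (t in c(300, 3600, 7200)) {
    v <- closed_form_profile(y, t, p)
    expect_true(all(v >= 0 & v <= 0.5))
    expect_true(all(diff(v) < 0))
  }
  t <- seq(60, 7200, by = 60)
  expect_true(all(diff(closed_form_profile(2, t, p)) > 0))
})

test_that("closed form satisfies the diffusion PDE on a fine grid", {
  p <- diffusion_params(2e-6)
  D <- 2e-4  # mm^2/s
  resid_at <- function(h, ht) {
    y <- seq(0.5, 3, by = h); t <- seq(1800, 5400, by = ht)
    g <- expand.grid(y = y[c(-1, -length(y))], t = t[c(-1, -length(t))])
    dCdt <- (closed_form_profile(g$y, g$t + ht, p) -
               closed_form_profile(g$y, g$t - ht, p)) / (2 * ht)
    d2Cdy2 <- (closed_form_profile(g$y + h, g$t, p) -
                 2 * closed_form_profile(g$y, g$t, p) +
                 closed_form_profile(g$y - h, g$t, p)) / h^2
    max(abs(dCdt - D * d2Cdy2))
  }
  r_coarse <- resid_at(0.1, 120)
  r_fine <- resid_at(0.05, 60)
  expect_lt(r_fine, r_coarse)          # residual shrinks under refinement
  expect_lt(r_fine, 1e-7)              # and is tiny in absolute terms
})

test_that("gradient_profile matches a numerical derivative of the profile", {
  p <- diffusion_params(2e-6)
  y <- c(0.5, 1, 2, 3); t <- 3600
  h <- 1e-4
  num <- (closed_form_profile(y + h, t, p) -
            closed_form_profile(y - h, t, p)) / (2 * h)
  expect_equal(gradient_profile(y, t, p), num, tolerance = 1e-6)
  expect_true(all(gradient_profile(y, t, p) < 0))
})

test_that("chamber solver conserves mass under no-flux boundaries", {
  for (mi in c("reservoir", "empty")) {
    f <- solve_chamber_1d(t_end_s = 7200, dt_s = 20, dy_mm = 0.1,
                          membrane_initial = mi)
    expect_lt(max(abs(f$mass - f$mass[1])) / f$mass[1], 1e-6)
  }
})

test_that("membrane-gel interface sits at half the reservoir concentration", {
  f <- solve_chamber_1d()
  iface <- eval_field(f, 0, f$t_s[f$t_s >= 600])
  expect_true(all(abs(iface - 0.5) < 0.05))
})

test_that("solver agrees with the semi-infinite closed form in the gel", {
  f <- solve_chamber_1d()
  # spot value from the assay's observation window
  num <- eval_field(f, 2, 7200)
  cf <- closed_form_profile(2, 7200)
  expect_lt(abs(num - cf) / cf, 0.02)
  # membrane hindrance pulls the gel concentration down
  f_slow <- solve_chamber_1d(chamber_geometry(D_factor_membrane = 0.25))
  expect_lt(eval_field(f_slow, 2, 7200), num)
})

test_that("solver converges to the closed form as the reservoir grows", {
  sup_diff <- vapply(c(2, 5, 20), function(Lr) {
    f <- solve_chamber_1d(chamber_geometry(L_reservoir_mm = Lr),
                          dt_s = 20, dy_mm = 0.1, t_end_s = 7200)
    y <- seq(0, 4, by = 0.5)
    g <- expand.grid(y = y, t = c(1800, 3600, 7200))
    max(abs(eval_field(f, g$y, g$t) - closed_form_profile(g$y, g$t)))
  }, numeric(1))
  expect_true(all(diff(sup_diff) <= 1e-12))
})

test_that("explicit scheme runs when stable and refuses when not", {
  dy <- 0.1
  dt_ok <- dy^2 / (2 * 2e-4) * 0.9
  f <- solve_chamber_1d(dt_s = dt_ok, dy_mm = dy, t_end_s = 600,
                        t_save_s = c(0, 600), scheme = "explicit")
  expect_true(all(f$C_norm >= -1e-9 & f$C_norm <= 1 + 1e-9))
  expect_error(
    solve_chamber_1d(dt_s = 60, dy_mm = dy, scheme = "explicit"),
    "CFL")
  expect_error(solve_chamber_1d(dt_s = -1), "positive")
})

test_that("D estimation recovers the generating value from noiseless data", {
  obs <- expand.grid(y_mm = c(2, 3, 5), t_s = seq(600, 7200, by = 600))
  obs$c_norm <- closed_form_profile(obs$y_mm, obs$t_s, diffusion_params(2e-6))
  fit <- fit_diffusion_coefficient(obs)
  expect_lt(abs(fit$D_cm2_s - 2e-6) / 2e-6, 0.001)
  # numeric forward model, self-consistent data
  fld <- solve_chamber_1d(dy_mm = 0.1, dt_s = 30)
  obs$c_norm <- eval_field(fld, obs$y_mm, obs$t_s)
  fit_num <- fit_diffusion_coefficient(obs, model = "numeric")
  expect_lt(abs(fit_num$D_cm2_s - 2e-6) / 2e-6, 0.01)
})

test_that("D estimation is invariant under the diffusive scaling t -> k t, y -> sqrt(k) y", {
  obs <- expand.grid(y_mm = c(2, 3), t_s = seq(1200, 7200, by = 1200))
  obs$c_norm <- closed_form_profile(obs$y_mm, obs$t_s, diffusion_params(2e-6))
  k <- 4
  scaled <- data.frame(y_mm = sqrt(k) * obs$y_mm, t_s = k * obs$t_s,
                       c_norm = obs$c_norm)
  expect_equal(fit_diffusion_coefficient(scaled)$D_cm2_s,
               fit_diffusion_coefficient(obs)$D_cm2_s, tolerance = 1e-4)
})

test_that("ill-posed D fits are refused with a diagnostic", {
  expect_error(fit_diffusion_coefficient(
    data.frame(y_mm = 2, t_s = 600, c_norm = 0.1)), "at least 3")
  expect_error(fit_diffusion_coefficient(
    data.frame(y_mm = c(2, 3, 5), t_s = 600, c_norm = c(0.1, 0.05, 0.01))),
    "distinct positive times")
  expect_error(fit_diffusion_coefficient(
    data.frame(y_mm = c(2, 3, 5), t_s = c(600, 1200, 1800), c_norm = 0)),
    "zero")
})

test_that("calibration reproduces an exact line and inverts it", {
  pts <- data.frame(concentration = c(0.2, 1, 10, 60, 120))
  pts$gray_level <- 3 * pts$concentration + 10
  cal <- fit_calibration(pts)
  expect_equal(cal$slope, 3)
  expect_equal(cal$intercept, 10)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$valid_range, c(0.2, 120))
  expect_equal(as.numeric(suppressWarnings(gray_to_concentration(cal, 10))), 0)
  # out-of-range values are flagged, not rejected
  expect_warning(res <- gray_to_concentration(cal, c(10, 100)), "outside")
  expect_equal(attr(res, "extrapolated"), c(TRUE, FALSE))
  expect_error(fit_calibration(
    data.frame(concentration = c(5, 5), gray_level = c(1, 2))), "distinct")
})

test_that("calibration equals the textbook OLS closed form", {
  set.seed(11)
  x <- runif(20, 0.2, 120)
  y <- 2.5 * x + 8 + rnorm(20, sd = (1 + x / 20))  # heteroscedastic
  cal <- fit_calibration(data.frame(concentration = x, gray_level = y))
  slope_ols <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(cal$slope, slope_ols, tolerance = 1e-12)
  expect_equal(cal$intercept, mean(y) - slope_ols * mean(x), tolerance = 1e-12)
})

test_that("calibration slope CI covers the generating slope", {
  set.seed(12)
  covered <- replicate(50, {
    x <- seq(0.2, 120, length.out = 12)
    y <- 2.5 * x + 8 + rnorm(12, sd = 1 + x / 30)
    fit <- lm(y ~ x)
    ci <- confint(fit)["x", ]
    ci[1] <= 2.5 && 2.5 <= ci[2]
  })
  expect_gte(mean(covered), 0.8)
})
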