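test_that("retention factors follow from retention and dead times", {
  # k = 1 and k = 10 fix the log scale; third case is the closed form
  expect_equal(logk_from_times(2 * 1.3, 1.3), 0)
  expect_equal(logk_from_times(11, 1), 1)
  expect_equal(logk_from_times(3.7, 1.3), log10(2.4 / 1.3))
  expect_equal(logk_from_times(c(11, 21), c(1, 1)), c(1, log10(20)))

  expect_error(logk_from_times(1.0, 1.3), "t_r > t_0 > 0")
  expect_error(logk_from_times(2, 0), "t_r > t_0 > 0")
  expect_error(logk_from_times(2, -1), "t_r > t_0 > 0")
})

test_that("a noiseless linear series is recovered exactly", {
  phi <- seq(0.4, 0.9, by = 0.1)
  f <- fit_isocratic(phi, 2.0774 - 4.3603 * phi, "2", "C18")
  expect_equal(f$logkw, 2.0774, tolerance = 1e-10)
  expect_equal(f$slope_S, -4.3603, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  expect_equal(f$n_points, 6L)
  expect_false(f$degenerate)

  # two points: interpolating line
  f2 <- fit_isocratic(c(0.3, 0.6), c(0.5, -0.4))
  expect_equal(f2$slope_S, -3, tolerance = 1e-12)
  expect_equal(f2$logkw, 1.4, tolerance = 1e-12)
  expect_equal(f2$r2, 1)
})

test_that("noisy fits match the closed-form normal-equations oracle", {
  set.seed(42)
  for (n in 3:10) {
    phi <- sort(runif(n, 0.05, 0.9))
    logk <- 2.1 - 4.9 * phi + rnorm(n, 0, 0.02)
    f <- fit_isocratic(phi, logk)
    o <- ols_oracle(logk, phi)
    expect_equal(f$logkw, o$intercept, tolerance = 1e-10)
    expect_equal(f$slope_S, o$slope, tolerance = 1e-10)
    expect_equal(f$r2, o$R2, tolerance = 1e-10)
  }
})

test_that("adding a constant to log k shifts log kw only", {
  set.seed(7)
  phi <- seq(0.1, 0.7, by = 0.1)
  logk <- 1.5 - 5 * phi + rnorm(7, 0, 0.05)
  f0 <- fit_isocratic(phi, logk)
  f1 <- fit_isocratic(phi, logk + 0.37)
  expect_equal(f1$logkw, f0$logkw + 0.37, tolerance = 1e-10)
  expect_equal(f1$slope_S, f0$slope_S, tolerance = 1e-10)
})

test_that("degenerate and invalid series are handled", {
  expect_error(suppressWarnings(fit_isocratic(c(0.5, 0.5), c(1, 1.1))),
               "distinct phi", class = "simpleError")
  expect_error(fit_isocratic(0.5, 1), "distinct phi")
  expect_error(fit_isocratic(c(0.2, 1.2), c(1, 0)), "volume fraction")

  expect_warning(f <- fit_isocratic(c(0.4, 0.4, 0.6), c(1.0, 1.2, 0.4)),
                 "averaged")
  expect_equal(f$n_points, 2L)
  expect_equal(f$logkw, 1.1 - f$slope_S * 0.4, tolerance = 1e-12)

  flat <- fit_isocratic(c(0.3, 0.5, 0.7), c(0.8, 0.8, 0.8))
  expect_true(flat$degenerate)
  expect_equal(flat$slope_S, 0)
  expect_true(is.na(flat$r2))
})

test_that("prediction evaluates the line and flags extrapolation", {
  phi <- seq(0.4, 0.9, by = 0.1)
  f <- fit_isocratic(phi, 2.0774 - 4.3603 * phi)
  expect_equal(as.numeric(predict_logk(f, 0)), 2.0774, tolerance = 1e-10)
  expect_equal(as.numeric(predict_logk(f, 0.5)), -0.10275, tolerance = 1e-10)
  expect_equal(attr(predict_logk(f, c(0, 0.5, 0.95)), "extrapolated"),
               c(TRUE, FALSE, TRUE))
  flat <- fit_isocratic(c(0.3, 0.6), c(0.9, 0.9))
  expect_equal(as.numeric(predict_logk(flat, 0.123)), 0.9)
})

test_that("tabulated study fits round-trip through predict and refit", {
  tab <- thiosemicarbazide_retention()
  grids <- list(C18 = seq(0.4, 0.9, by = 0.1),
                IAM = seq(0.05, 0.40, by = 0.05),
                Chol = seq(0.3, 0.8, by = 0.1))
  for (sys in names(grids)) {
    kw <- tab[[paste0("logkw_", sys)]]
    mS <- tab[[paste0("minus_S_", sys)]]
    for (i in seq_len(nrow(tab))) {
      f0 <- structure(list(logkw = kw[i], slope_S = -mS[i],
                           phi_range = range(grids[[sys]])),
                      class = "retention_fit")
      f <- fit_isocratic(grids[[sys]], as.numeric(predict_logk(f0, grids[[sys]])))
      expect_equal(f$logkw, kw[i], tolerance = 1e-9)
      expect_equal(-f$slope_S, mS[i], tolerance = 1e-9)
    }
  }
})

test_that("fit_retention handles long tables, times, and percent units", {
  phi <- seq(0.4, 0.9, by = 0.1)
  d <- rbind(
    data.frame(compound_id = "a", system_id = "C18", phi = phi,
               logk = 2.0 - 4.0 * phi),
    data.frame(compound_id = "b", system_id = "C18", phi = phi,
               logk = 1.5 - 3.0 * phi))
  fits <- fit_retention(d)
  expect_equal(nrow(fits), 2L)
  expect_equal(fits$logkw[fits$compound_id == "a"], 2.0, tolerance = 1e-10)
  expect_equal(fits$minus_S[fits$compound_id == "b"], 3.0, tolerance = 1e-10)

  # same data expressed as percent modifier
  d_pct <- d
  d_pct$phi <- d_pct$phi * 100
  fits_pct <- fit_retention(d_pct, phi_as_percent = TRUE)
  expect_equal(fits_pct$logkw, fits$logkw, tolerance = 1e-12)

  # and via retention/dead times: logk = log10((t_r - t_0)/t_0)
  d_t <- d[, c("compound_id", "system_id", "phi")]
  d_t$t_0 <- 1.2
  d_t$t_r <- 1.2 * (1 + 10^d$logk)
  fits_t <- fit_retention(d_t)
  expect_equal(fits_t$logkw, fits$logkw, tolerance = 1e-9)

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_retention_fits(fits, tmp)
  back <- read.csv(tmp)
  expect_equal(back$logkw, round(fits$logkw, 4))
})
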