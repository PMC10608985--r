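tab <- thiosemicarbazide_descriptors()

test_that("an exact line is fitted exactly, with and without exclusions", {
  d <- data.frame(compound_id = as.character(1:6),
                  x = c(0.5, 1, 2, 3, 4, 5))
  d$y <- 2 * d$x + 1
  m <- suppressWarnings(fit_linear_excluding(d, "y", "x"))  # perfect-fit note
  expect_equal(m$slope, 2, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  expect_equal(m$R, 1, tolerance = 1e-12)
  expect_lt(m$p, 1e-12)

  # excluding rows equals fitting the reduced table with no exclusions
  m_ex <- fit_linear_excluding(tab, "logkw_Chol", "logkw_C18", exclude = c(16))
  m_sub <- fit_linear_excluding(tab[tab$compound_id != 16, ],
                                "logkw_Chol", "logkw_C18")
  for (f in c("intercept", "slope", "se_slope", "R2", "F", "p", "n"))
    expect_identical(m_ex[[f]], m_sub[[f]])

  expect_error(fit_linear_excluding(tab, "nope", "logkw_C18"),
               "unknown descriptor column")
  expect_error(fit_linear_excluding(tab, "logkw_IAM", "logkw_C18",
                                    exclude = c(16, 99)),
               "unknown compound id")
  expect_error(fit_linear_excluding(tab[1:4, ], "logkw_IAM", "logkw_C18",
                                    exclude = 1:2), "insufficient data")
})

test_that("the full statistics block matches the closed-form oracle", {
  set.seed(33)
  d <- data.frame(compound_id = as.character(1:12),
                  x = runif(12), stringsAsFactors = FALSE)
  d$y <- 0.7 - 1.3 * d$x + rnorm(12, 0, 0.2)
  m <- fit_linear_excluding(d, "y", "x")
  o <- ols_oracle(d$y, d$x)
  for (f in c("intercept", "slope", "se_intercept", "se_slope", "R", "R2",
              "R2_adj", "F", "p", "s_resid"))
    expect_equal(m[[f]], o[[f]], tolerance = 1e-9)
  # internal consistency of the reported block
  expect_equal(m$R2_adj, 1 - (1 - m$R2) * (m$n - 1) / (m$n - 2), tolerance = 1e-12)
  expect_equal(m$F, m$R2 * (m$n - 2) / (1 - m$R2), tolerance = 1e-9)
})

test_that("cholesterol-vs-C18 regression reproduces the published block", {
  m <- fit_linear_excluding(tab, "logkw_Chol", "logkw_C18", exclude = 16)
  expect_lt(abs(m$intercept - 0.0206), 5e-4)
  expect_equal(m$slope, 1.0959, tolerance = 5e-4)
  expect_equal(m$se_intercept, 0.4552, tolerance = 5e-4)
  expect_equal(m$se_slope, 0.1662, tolerance = 5e-4)
  expect_equal(m$R, 0.8622, tolerance = 5e-4)
  expect_equal(m$R2, 0.74345, tolerance = 5e-4)
  expect_equal(m$R2_adj, 0.7263, tolerance = 5e-4)
  expect_equal(m$F, 43.468, tolerance = 0.05)
  expect_equal(m$s_resid, 0.31982, tolerance = 5e-4)
  expect_identical(m$n, 17L)
  expect_lt(m$p, 1e-5)
})

test_that("AGP binding vs QSAR-predicted binding reproduces the published block", {
  m <- fit_linear_excluding(tab, "logK_AGP", "logK_IRFMN", exclude = c(2, 9))
  expect_equal(m$intercept, -0.7158, tolerance = 5e-4)
  expect_equal(m$slope, 1.1697, tolerance = 5e-4)
  expect_equal(m$se_slope, 0.2313, tolerance = 5e-4)
  expect_equal(m$R, 0.8038, tolerance = 5e-4)
  expect_equal(m$R2, 0.6462, tolerance = 5e-4)
  expect_equal(m$F, 25.57, tolerance = 0.05)
  expect_equal(m$s_resid, 0.1017, tolerance = 5e-4)
  expect_identical(m$n, 16L)
  expect_lt(m$p, 0.00018)
})

test_that("correlation cells are symmetric, self-unit, and exclusion-aware", {
  ex <- list("logP|logkw_C18" = c("4", "16"))
  cm <- correlation_matrix(tab, c("logP", "logkw_C18"), exclude = ex)
  self <- cm[cm$row == cm$col, ]
  expect_true(all(self$r == 1))
  ab <- cm[cm$row == "logP" & cm$col == "logkw_C18", ]
  ba <- cm[cm$row == "logkw_C18" & cm$col == "logP", ]
  expect_equal(ab$r, ba$r, tolerance = 1e-15)
  expect_identical(ab$n, 16L)
  expect_equal(ab$r, 0.84, tolerance = 5e-3)
  expect_identical(format_correlation_cell(ab), "0.84 (4, 16)")

  expect_error(correlation_matrix(tab, "logP", "logkw_C18",
                                  list("logP|logkw_C18" = "99")),
               "unknown compound id")
})

test_that("verified published correlation cells reproduce with their exclusions", {
  # (row descriptor, column descriptor, exclusions, published r) for the
  # cells that are reproducible from the packaged tables
  cases <- list(
    list("logP", "logkw_C18", c(4, 16), 0.84),
    list("ClogP", "logkw_C18", 16, 0.87),
    list("SlogP", "logkw_C18", 16, 0.89),
    list("SlogD", "logkw_C18", 16, 0.89),
    list("MlogP", "logkw_C18", 16, 0.90),
    list("AlogP", "logkw_C18", 16, 0.89),
    list("logP", "logkw_Chol", c(4, 16), 0.84),
    list("ClogP", "logkw_Chol", c(4, 16), 0.84),
    list("SlogP", "logkw_Chol", c(4, 16), 0.82),
    list("SlogD", "logkw_Chol", c(4, 16), 0.82),
    list("MlogP", "logkw_Chol", c(4, 16), 0.81),
    list("AlogP", "logkw_Chol", c(8, 16), 0.82),
    list("logP_MK", "logkw_Chol", c(4, 16), 0.86),
    list("logP", "logK_HSA", c(4, 16), 0.79),
    list("ClogP", "logK_HSA", c(7, 16), 0.72),
    list("logP_MK", "logK_HSA", 16, 0.70),
    list("logP", "logK_AGP", NULL, 0.83),
    list("ClogP", "logK_AGP", 13, 0.92),
    list("SlogP", "logK_AGP", 13, 0.93),
    list("MlogP", "logK_AGP", 13, 0.91),
    list("AlogP", "logK_AGP", 13, 0.83)
  )
  for (cs in cases) {
    ex <- if (is.null(cs[[3]])) list() else
      stats::setNames(list(as.character(cs[[3]])),
                      paste(cs[[1]], cs[[2]], sep = "|"))
    cm <- correlation_matrix(tab, cs[[1]], cs[[2]], ex)
    expect_lt(abs(cm$r - cs[[4]]), 5e-3,
              label = sprintf("r(%s, %s) deviation", cs[[1]], cs[[2]]))
  }
})

test_that("summary statistics match the oracle and the published table", {
  # brute-force order-statistics/moment oracle on an uneven column
  o <- summary_oracle(tab$logk_AGP)
  s <- summary_stats(tab, "logk_AGP")
  expect_equal(s$median, o$median, tolerance = 1e-9)
  expect_equal(s$mean, o$mean, tolerance = 1e-9)
  expect_equal(s$sd, o$sd, tolerance = 1e-9)
  expect_equal(s$range, o$range, tolerance = 1e-9)

  s18 <- summary_stats(tab, "logkw_C18")
  expect_equal(s18$median, 2.698, tolerance = 5e-4)
  expect_equal(s18$mean, 2.700, tolerance = 5e-4)
  expect_equal(s18$range, 1.918, tolerance = 5e-4)

  cst <- data.frame(compound_id = 1:4, v = rep(2.5, 4))
  sc <- summary_stats(cst, "v")
  expect_identical(sc$sd, 0)
  expect_identical(sc$range, 0)
  expect_error(summary_stats(cst, "w"), "unknown descriptor column")
  expect_error(summary_stats(data.frame(compound_id = 1, v = 1), "v"),
               "insufficient data")
})

test_that("outlier detection flags displaced points and ranks by residual", {
  d <- data.frame(compound_id = as.character(1:8), x = 1:8)
  d$y <- 0.5 + 2 * d$x
  expect_length(detect_outliers(d, "y", "x"), 0L)

  d$y[5] <- d$y[5] + 4
  out <- detect_outliers(d, "y", "x")
  expect_identical(as.character(out), "5")

  # on the study table the brute-force studentized ranking puts compound 13
  # on top for the IAM-vs-C18 relation (t = -4.5); no other compound
  # crosses the default 2.5 cutoff
  out13 <- detect_outliers(tab, "logkw_IAM", "logkw_C18")
  expect_identical(as.character(out13), "13")

  jk <- detect_outliers(tab, "logkw_IAM", "logkw_C18", method = "jackknife_r2")
  expect_identical(as.character(jk)[1], "13")

  expect_error(detect_outliers(d[1:3, ], "y", "x"), ">= 4 rows")
})
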