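test_that("the elastance surrogate is the dicrotic pressure over ESVi", {
  expect_equal(est_ees(90, 56), 90 / 56)
  expect_equal(est_ees(100, 50), 2)
  expect_equal(est_ees(64, 64), 1)
  # scale consistency: doubling the pressure doubles the estimate
  expect_equal(est_ees(2 * 87, 41), 2 * est_ees(87, 41))
  expect_error(est_ees(90, 0), "ESVi")
})

make_noiseless <- function(n = 62, seed = 5, coefs, response = "log10BNP") {
  co <- generate_cohort(cohort_spec(n = n, seed = seed))
  c1 <- mean(co$QRSZ)
  c2 <- mean(co$AR_delayed)
  y <- coefs[1] + coefs[2] * co$QRSZ + coefs[3] * co$AR_delayed +
    coefs[4] * (co$QRSZ - c1)^2 + coefs[5] * (co$AR_delayed - c2)^2 +
    coefs[6] * (co$QRSZ - c1) * (co$AR_delayed - c2)
  if (response == "log10BNP") co$BNP <- 10^y else co$estEes <- y
  co
}

test_that("a noiseless synthetic surface is recovered exactly", {
  coefs <- c(1.4, 0.05, 0.004, -0.002, -0.0008, 0.0006)
  co <- make_noiseless(coefs = coefs)
  fit <- suppressWarnings(fit_response_surface(co, "log10BNP"))
  expect_equal(unname(fit$coefficients), coefs, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$c1, mean(co$QRSZ))
  expect_equal(fit$c2, mean(co$AR_delayed))
  # same exactness on the elastance response
  co2 <- make_noiseless(coefs = coefs, response = "estEes")
  fit2 <- suppressWarnings(fit_response_surface(co2, "estEes"))
  expect_equal(unname(fit2$coefficients), coefs, tolerance = 1e-8)
})

test_that("a purely linear response has vanishing quadratic and cross terms", {
  co <- make_noiseless(coefs = c(1, 0.08, 0.003, 0, 0, 0))
  fit <- suppressWarnings(fit_response_surface(co, "log10BNP"))
  expect_equal(unname(fit$beta[c("QRSZ_sq", "AR_sq", "cross")]), rep(0, 3),
               tolerance = 1e-8)
})

test_that("a constant response yields zero betas and zero R-squared", {
  co <- generate_cohort(cohort_spec(n = 30, seed = 2))
  co$BNP <- rep(50, 30)
  fit <- fit_response_surface(co, "log10BNP")
  expect_equal(unname(fit$beta), rep(0, 5))
  expect_equal(fit$r_squared, 0)
})

test_that("collinear designs fail loudly naming the terms", {
  co <- generate_cohort(cohort_spec(n = 30, seed = 2))
  co$AR_delayed <- rep(50, 30) # AR, AR_sq, cross all degenerate
  expect_error(fit_response_surface(co, "log10BNP"), "collinear")
  expect_error(fit_response_surface(co[1:5, ], "log10BNP"), "at least 10")
  co2 <- generate_cohort(cohort_spec(n = 30, seed = 2))
  co2$BNP[3] <- NA
  expect_error(fit_response_surface(co2, "log10BNP"), "missing")
})

test_that("the surface extremum location is recovered by plant-and-recover", {
  # concave surface with its maximum planted at AR = 62 when QRSZ = 10
  b_a2 <- -0.0008
  b_qa <- 0.0005
  co <- generate_cohort(cohort_spec(n = 62, seed = 8))
  c1 <- mean(co$QRSZ); c2 <- mean(co$AR_delayed)
  b_a <- -2 * b_a2 * (62 - c2) - b_qa * (10 - c1)
  co$BNP <- 10^(1.5 + 0.04 * co$QRSZ + b_a * co$AR_delayed +
                  b_a2 * (co$AR_delayed - c2)^2 +
                  b_qa * (co$QRSZ - c1) * (co$AR_delayed - c2))
  fit <- suppressWarnings(fit_response_surface(co, "log10BNP"))
  ex <- extremum_ar_at(fit, 10)
  expect_equal(ex$ar, 62, tolerance = 1e-6)
  expect_identical(ex$type, "maximum")
  expect_false(ex$clipped)

  # convex surface with its minimum planted at AR = 68
  b_a2 <- 0.0009
  b_a <- -2 * b_a2 * (68 - c2)
  co$estEes <- 1.6 - 0.03 * co$QRSZ + b_a * co$AR_delayed +
    b_a2 * (co$AR_delayed - c2)^2
  fite <- suppressWarnings(fit_response_surface(co, "estEes"))
  exe <- extremum_ar_at(fite, 10)
  expect_equal(exe$ar, 68, tolerance = 1e-6)
  expect_identical(exe$type, "minimum")

  # zero cross-term: the vertex does not move with QRSZ
  expect_equal(extremum_ar_at(fite, 0)$ar, extremum_ar_at(fite, 12)$ar)

  # vertex planted outside the observed range is clipped and flagged
  b_a <- -2 * 0.0009 * (180 - c2)
  co$estEes <- 1.6 + b_a * co$AR_delayed + 0.0009 * (co$AR_delayed - c2)^2
  exc <- extremum_ar_at(suppressWarnings(fit_response_surface(co, "estEes")), 10)
  expect_true(exc$clipped)
  expect_equal(exc$ar, max(co$AR_delayed))
})

test_that("both standardization conventions give matching signs", {
  co <- generate_cohort(cohort_spec(n = 62, seed = 13))
  fa <- fit_response_surface(co, "log10BNP", standardize = "after")
  fb <- fit_response_surface(co, "log10BNP", standardize = "before")
  expect_equal(sign(fa$beta), sign(fb$beta))
  # raw coefficients are identical; only the beta scaling differs
  fb2 <- fit_response_surface(co, "log10BNP", standardize = "before")
  expect_equal(fa$coefficients, fb2$coefficients)
})
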