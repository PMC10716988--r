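#' Specification of a synthetic single-ventricle cohort
#'
#' Describes the statistical structure used to generate clinical-style
#' cohorts: a shifted log-normal QRS-duration Z-score (support above the
#' inclusion threshold of 2, calibrated to a target median and interquartile
#' range), a scaled-beta delayed-wall area ratio on (0, 100)%, and two
#' phenomenological second-order response surfaces (for log10 BNP and for
#' estimated end-systolic elastance) with Gaussian noise. Default surface
#' coefficients place an inverse-U BNP maximum at an area ratio of 62% and a
#' U-shaped elastance minimum at 68% (both evaluated at a QRS Z-score of 10),
#' with linear QRS effects of the sign pattern seen clinically.
#'
#' @param n Cohort size.
#' @param seed Integer seed; `generate_cohort()` is reproducible given it.
#' @param qrsz List: `shift` (inclusion threshold), target `median` and
#'   `iqr` (length-2).
#' @param ar List: `mean` and `sd` of the area ratio in percent.
#' @param bnp_surface,ees_surface Lists of raw surface coefficients
#'   (`intercept`, `q`, `a`, `q2`, `a2`, `qa`), the centering constants
#'   (`c1`, `c2`) and the Gaussian noise `sd` (on the log10 scale for BNP, on
#'   the linear scale for the elastance, floored at `ees_floor`).
#' @param ees_floor Lower floor for the generated elastance (mmHg ml^-1 m^2).
#' @param esvi List: target `median` and `iqr` of the indexed end-systolic
#'   volume (ml/m^2), generated log-normally.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 62, seed = 1,
                        qrsz = list(shift = 2, median = 3.8,
                                    iqr = c(2.5, 6.2)),
                        ar = list(mean = 57.2, sd = 20),
                        bnp_surface = list(intercept = 1.5, q = 0.045,
                                           a = 0.00304, q2 = -0.001,
                                           a2 = -0.0006, qa = 0.0005,
                                           c1 = 4.56, c2 = 57.2, sd = 0.20),
                        ees_surface = list(intercept = 1.6, q = -0.05,
                                           a = -0.00536, q2 = 0.002,
                                           a2 = 0.0005, qa = -0.001,
                                           c1 = 4.56, c2 = 57.2, sd = 0.15),
                        ees_floor = 0.05,
                        esvi = list(median = 56, iqr = c(38, 93))) {
  if (n < 3) stop("n must be >= 3")
  if (qrsz$shift < 2) stop("QRSZ support must start at >= 2 (inclusion rule)")
  if (ar$mean <= 0 || ar$mean >= 100) stop("ar$mean must lie in (0, 100)")
  structure(list(n = n, seed = seed, qrsz = qrsz, ar = ar,
                 bnp_surface = bnp_surface, ees_surface = ees_surface,
                 ees_floor = ees_floor, esvi = esvi),
            class = "cohort_spec")
}

# Shifted log-normal parameters matching a target median and IQR width:
#   shift + exp(mu) = median,  exp(mu + k s) - exp(mu - k s) = q3 - q1
# with k = qnorm(0.75); the width equation gives sinh(k s) in closed form.
# Matching all three quantiles would overdetermine (mu, s).
lognormal_from_quantiles <- function(shift, med, iqr) {
  m <- med - shift
  w <- iqr[2] - iqr[1]
  if (!is.finite(m) || m <= 0 || w <= 0) {
    stop("infeasible distribution target: median must exceed the shift and ",
         "the IQR must have positive width")
  }
  k <- stats::qnorm(0.75)
  list(mu = log(m), sigma = asinh(w / (2 * m)) / k)
}

eval_surface <- function(s, q, a) {
  s$intercept + s$q * q + s$a * a + s$q2 * (q - s$c1)^2 +
    s$a2 * (a - s$c2)^2 + s$qa * (q - s$c1) * (a - s$c2)
}

#' Generate a synthetic patient cohort
#'
#' Draws a reproducible cohort with the structure described by a
#' [cohort_spec()]: one row per patient with QRS-duration Z-score, delayed
#' wall area ratio (`AR_delayed`, percent), `BNP` (pg/ml), `estEes`, the
#' consistent catheterization pair (`ESVi`, `AP_dic = estEes * ESVi`), and a
#' rebound-stretch ratio `R_strains` linked monotonically to the BNP level.
#' QRS Z-score and area ratio are drawn independently (their clinical
#' correlation is unreported); the response surfaces act on the drawn values.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with `n` rows and columns `QRSZ`, `AR_delayed`,
#'   `BNP`, `log10BNP`, `estEes`, `ESVi`, `AP_dic`, `R_strains`.
#' @examples
#' head(generate_cohort(cohort_spec(n = 62, seed = 7)))
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n

  ln <- lognormal_from_quantiles(spec$qrsz$shift, spec$qrsz$median,
                                 spec$qrsz$iqr)
  qrsz <- spec$qrsz$shift + stats::rlnorm(n, ln$mu, ln$sigma)

  m <- spec$ar$mean / 100
  v <- (spec$ar$sd / 100)^2
  if (v >= m * (1 - m)) stop("infeasible distribution target: ar$sd too large")
  nu <- m * (1 - m) / v - 1
  ar <- 100 * stats::rbeta(n, m * nu, (1 - m) * nu)

  log10bnp <- eval_surface(spec$bnp_surface, qrsz, ar) +
    stats::rnorm(n, 0, spec$bnp_surface$sd)
  ees <- pmax(spec$ees_floor,
              eval_surface(spec$ees_surface, qrsz, ar) +
                stats::rnorm(n, 0, spec$ees_surface$sd))

  ln_esvi <- lognormal_from_quantiles(0, spec$esvi$median, spec$esvi$iqr)
  esvi <- stats::rlnorm(n, ln_esvi$mu, ln_esvi$sigma)

  r_str <- pmax(0.9, 1 + 0.08 * (log10bnp - 1.5) + stats::rnorm(n, 0, 0.05))

  data.frame(QRSZ = qrsz, AR_delayed = ar, BNP = 10^log10bnp,
             log10BNP = log10bnp, estEes = ees, ESVi = esvi,
             AP_dic = ees * esvi, R_strains = r_str)
}
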