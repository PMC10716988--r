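#' Estimated end-systolic elastance from catheterization indices
#'
#' Single-beat contractility surrogate: dicrotic-notch pressure at the
#' ascending aorta divided by the end-systolic volume indexed for body surface
#' area, `estEes = AP_dic / ESVi`.
#'
#' @param AP_dic Dicrotic notch pressure (mmHg); may be a vector.
#' @param ESVi Indexed end-systolic volume (ml/m^2), > 0.
#' @return Estimated elastance (mmHg ml^-1 m^2).
#' @examples
#' est_ees(90, 56)
#' @export
est_ees <- function(AP_dic, ESVi) {
  if (any(!is.finite(ESVi)) || any(ESVi <= 0)) stop("ESVi must be > 0")
  AP_dic / ESVi
}

surface_terms <- function(qrsz, ar, c1, c2) {
  data.frame(QRSZ = qrsz,
             AR = ar,
             QRSZ_sq = (qrsz - c1)^2,
             AR_sq = (ar - c2)^2,
             cross = (qrsz - c1) * (ar - c2))
}

#' Second-order response-surface fit of a clinical index
#'
#' Ordinary least squares of the chosen response on the five-term second-order
#' polynomial in QRS-duration Z-score and delayed-wall area ratio:
#' `y ~ QRSZ + AR + (QRSZ - c1)^2 + (AR - c2)^2 + (QRSZ - c1)(AR - c2)`,
#' with the centering constants `c1`, `c2` equal to the sample means of the
#' fitted cohort. Standardized coefficients are obtained by z-scoring the
#' response and each constructed regressor (after the centered terms are
#' built; set `standardize = "before"` to z-score QRSZ and AR first and build
#' the terms from the z-scores instead).
#'
#' @param cohort Data frame with columns `QRSZ`, `AR_delayed` (percent) and
#'   the response ingredients (`BNP` in pg/ml for `response = "log10BNP"`, or
#'   `estEes`). [generate_cohort()] produces a suitable table.
#' @param response `"log10BNP"` or `"estEes"`.
#' @param standardize When the z-scoring happens relative to the construction
#'   of the centered quadratic/cross terms (`"after"`, the conventional
#'   standardized coefficient, or `"before"`).
#' @return An object of class `surface_fit`: raw `coefficients` (intercept +
#'   five terms), standardized `beta`, per-term `p_values`, `r_squared`,
#'   centering constants `c1`, `c2`, the observed `ar_range`, `n`, and the
#'   underlying `lm` fit.
#' @export
fit_response_surface <- function(cohort,
                                 response = c("log10BNP", "estEes"),
                                 standardize = c("after", "before")) {
  response <- match.arg(response)
  standardize <- match.arg(standardize)
  need <- c("QRSZ", "AR_delayed", if (response == "log10BNP") "BNP" else "estEes")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  used <- cohort[, need]
  if (anyNA(used)) stop("missing values in ", paste(need, collapse = ", "))
  n <- nrow(cohort)
  if (n < 10) stop("need at least 10 patients")

  y <- if (response == "log10BNP") {
    if (any(cohort$BNP <= 0)) stop("BNP must be > 0 for the log transform")
    log10(cohort$BNP)
  } else {
    cohort$estEes
  }
  c1 <- mean(cohort$QRSZ)
  c2 <- mean(cohort$AR_delayed)
  X <- surface_terms(cohort$QRSZ, cohort$AR_delayed, c1, c2)

  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < ncol(X) + 1) {
    dropped <- setdiff(c("(Intercept)", names(X)),
                       c("(Intercept)", names(X))[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }

  dat <- cbind(y = y, X)
  fit <- stats::lm(y ~ QRSZ + AR + QRSZ_sq + AR_sq + cross, data = dat)
  coefs <- stats::coef(fit)

  sd_y <- stats::sd(y)
  if (sd_y < .Machine$double.eps^0.5) {
    beta <- stats::setNames(rep(0, 5), names(X))
    pvals <- stats::setNames(rep(NA_real_, 5), names(X))
    r2 <- 0
  } else {
    if (standardize == "after") {
      beta <- coefs[names(X)] * vapply(X, stats::sd, numeric(1)) / sd_y
    } else {
      Z <- surface_terms(scale(cohort$QRSZ)[, 1], scale(cohort$AR_delayed)[, 1],
                         0, 0)
      datz <- cbind(y = scale(y)[, 1], Z)
      fitz <- stats::lm(y ~ QRSZ + AR + QRSZ_sq + AR_sq + cross, data = datz)
      beta <- stats::coef(fitz)[names(X)] *
        vapply(Z, stats::sd, numeric(1))
    }
    sm <- summary(fit)
    pvals <- sm$coefficients[names(X), "Pr(>|t|)"]
    r2 <- sm$r.squared
  }

  structure(list(coefficients = coefs, beta = beta, p_values = pvals,
                 r_squared = r2, c1 = c1, c2 = c2, response = response,
                 ar_range = range(cohort$AR_delayed), n = n, lm = fit),
            class = "surface_fit")
}

#' @export
print.surface_fit <- function(x, ...) {
  cat("<surface_fit> response:", x$response, " n =", x$n,
      " R^2 =", round(x$r_squared, 3), "\n")
  cat("  centers: QRSZ", round(x$c1, 2), ", AR", round(x$c2, 1), "%\n")
  tab <- data.frame(beta = round(x$beta, 3), p = signif(x$p_values, 3))
  print(tab)
  invisible(x)
}

#' Area ratio at the extremum of a fitted response surface
#'
#' Vertex of the fitted quadratic in the area ratio at a fixed QRS-duration
#' Z-score: `AR* = c2 - (b_AR + b_cross * (qrsz - c1)) / (2 * b_AR_sq)`. When
#' the vertex falls outside the observed area-ratio range it is clipped to
#' the boundary and flagged.
#'
#' @param fit A `surface_fit` from [fit_response_surface()].
#' @param qrsz QRS-duration Z-score at which to locate the extremum.
#' @return A list with `ar` (percent), `type` (`"maximum"` or `"minimum"`
#'   from the sign of the quadratic coefficient) and `clipped`.
#' @export
extremum_ar_at <- function(fit, qrsz) {
  stopifnot(inherits(fit, "surface_fit"))
  b <- fit$coefficients
  if (!is.finite(b[["AR_sq"]]) || abs(b[["AR_sq"]]) < 1e-12) {
    stop("quadratic area-ratio coefficient is zero; no extremum")
  }
  ar <- fit$c2 - (b[["AR"]] + b[["cross"]] * (qrsz - fit$c1)) /
    (2 * b[["AR_sq"]])
  clipped <- FALSE
  if (ar < fit$ar_range[1]) { ar <- fit$ar_range[1]; clipped <- TRUE }
  if (ar > fit$ar_range[2]) { ar <- fit$ar_range[2]; clipped <- TRUE }
  list(ar = ar, type = if (b[["AR_sq"]] < 0) "maximum" else "minimum",
       clipped = clipped)
}
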