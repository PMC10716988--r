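#' Sweep activation delay against delayed-compartment size
#'
#' Runs one steady-state simulation per combination of activation delay and
#' delayed-compartment volume fraction (by default 19 delays, 0-90 ms in 5-ms
#' steps, times 19 fractions, 5-95% in 5% steps: 361 conditions), extracts
#' per-beat hemodynamic metrics and strain-derived discoordination indices,
#' and expresses cardiac output, effective end-systolic elastance and maximal
#' pressure rise as relative changes against the zero-delay baseline of the
#' same fraction. Conditions that fail to converge are kept as flagged rows of
#' `NA` metrics and do not abort the sweep. Results are independent of
#' execution order; rows are sorted by (`dT_ms`, `fraction`).
#'
#' @param params A [fontan_params()] object (its `delayed_fraction` and
#'   `delay_dT` fields are ignored in favour of the grid).
#' @param dT_ms Vector of activation delays (ms); must contain 0, which
#'   defines the per-fraction baselines.
#' @param fractions Vector of delayed-compartment volume fractions in (0, 1).
#' @param verbose Print one progress line per fraction.
#' @param ... Passed to [simulate_fontan()] (e.g. `dt_ms`).
#' @return A data frame of class `dyssynchrony_sweep` with one row per
#'   condition: metrics from [beat_metrics()], `r_strains_earlier`,
#'   `r_strains_delayed`, `ttp_diff_ms`, and relative changes `dCO_pct`,
#'   `dEes_pct`, `dDpdt_pct` (percent, 0 for all zero-delay rows).
#' @export
run_dyssynchrony_grid <- function(params = fontan_params(),
                                  dT_ms = seq(0, 90, by = 5),
                                  fractions = seq(0.05, 0.95, by = 0.05),
                                  verbose = FALSE, ...) {
  if (length(dT_ms) < 1 || length(fractions) < 1) {
    stop("dT_ms and fractions must be non-empty")
  }
  if (!any(dT_ms == 0)) stop("dT_ms must include the 0 baseline")
  rows <- vector("list", length(dT_ms) * length(fractions))
  k <- 0
  for (f in fractions) {
    base_out <- NA_real_
    base <- NULL
    for (dT in sort(dT_ms)) {
      k <- k + 1
      cond <- tryCatch({
        beat <- simulate_fontan(params, delayed_fraction = f, delay_dT = dT,
                                ...)
        if (dT == 0) base_out <- beat_metrics(beat)$SV_forward
        m <- beat_metrics(beat, baseline_output = base_out)
        st <- beat_strains(beat)
        ev <- beat$events
        cbind(m,
              r_strains_earlier = r_strains(st$earlier, st$time_ms,
                                            ev$vent_onset_earlier,
                                            ev$ao_open, ev$ao_close),
              r_strains_delayed = r_strains(st$delayed, st$time_ms,
                                            ev$vent_onset_earlier,
                                            ev$ao_open, ev$ao_close),
              ttp_diff_ms = time_to_peak_difference(st),
              converged = TRUE)
      }, error = function(e) NULL)
      if (is.null(cond)) {
        cond <- data.frame(EDV = NA_real_, ESV = NA_real_, EF = NA_real_,
                           SV_forward = NA_real_, CO = NA_real_,
                           CI = NA_real_, mean_cvp = NA_real_,
                           mean_atrial = NA_real_, ESP = NA_real_,
                           EDP = NA_real_, SBP = NA_real_, DBP = NA_real_,
                           MAP = NA_real_, dPdt_max = NA_real_,
                           Ees_eff = NA_real_, PVRi = NA_real_,
                           SVRi = NA_real_, reverse_flow_ml = NA_real_,
                           reverse_flow_pct = NA_real_,
                           r_strains_earlier = NA_real_,
                           r_strains_delayed = NA_real_,
                           ttp_diff_ms = NA_real_, converged = FALSE)
      }
      rows[[k]] <- cbind(data.frame(dT_ms = dT, fraction = f), cond)
      if (dT == 0) base <- rows[[k]]
    }
    if (verbose) {
      message(sprintf("fraction %.2f done (baseline CO %.2f L/min)",
                      f, base$CO))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  # relative changes against the same-fraction zero-delay baseline
  rel <- function(col) {
    b <- tab[[col]][match(paste0(tab$fraction, "_0"),
                          paste0(tab$fraction, "_", tab$dT_ms))]
    100 * (tab[[col]] - b) / b
  }
  tab$dCO_pct <- rel("CO")
  tab$dEes_pct <- rel("Ees_eff")
  tab$dDpdt_pct <- rel("dPdt_max")
  tab <- tab[order(tab$dT_ms, tab$fraction), ]
  rownames(tab) <- NULL
  class(tab) <- c("dyssynchrony_sweep", class(tab))
  tab
}

#' Most vulnerable delayed-compartment fraction
#'
#' At a given activation delay, returns the delayed-compartment fraction with
#' the largest reduction (most negative relative change) of the chosen
#' metric. Ties are broken toward the smaller fraction.
#'
#' @param sweep A sweep table from [run_dyssynchrony_grid()].
#' @param dT Activation delay (ms); must be present in the table.
#' @param metric Relative-change column to minimize (default `"dCO_pct"`).
#' @return The fraction (dimensionless, e.g. `0.70`).
#' @export
most_vulnerable_fraction <- function(sweep, dT, metric = "dCO_pct") {
  rows <- sweep[sweep$dT_ms == dT & !is.na(sweep[[metric]]), ]
  if (nrow(rows) == 0) stop("no converged rows at dT = ", dT, " ms")
  rows <- rows[order(rows$fraction), ]
  rows$fraction[which.min(rows[[metric]])]
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank handling of ties, as used to relate candidate
#' dyssynchrony predictors to the simulated contractility change.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `NA` pairs are dropped.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) stop("need at least 3 complete pairs")
  stats::cor(x[keep], y[keep], method = "spearman")
}

#' Rank candidate predictors of contractility loss
#'
#' Computes the Spearman correlation of each candidate discoordination index
#' (relative change in maximal pressure rise, systolic reverse flow,
#' time-to-peak difference, rebound-stretch ratio of the earlier wall) with
#' the relative change in effective end-systolic elastance across all sweep
#' conditions.
#'
#' @param sweep A sweep table from [run_dyssynchrony_grid()].
#' @return A data frame with `predictor`, `rho` and `abs_rho`, sorted by
#'   decreasing `abs_rho`.
#' @export
predictor_correlations <- function(sweep) {
  cand <- c(dDpdt_pct = "dDpdt_pct", reverse_flow_pct = "reverse_flow_pct",
            ttp_diff_ms = "ttp_diff_ms",
            r_strains_earlier = "r_strains_earlier")
  rho <- vapply(cand, function(col) spearman_rho(sweep[[col]], sweep$dEes_pct),
                numeric(1))
  out <- data.frame(predictor = names(cand), rho = unname(rho),
                    abs_rho = abs(unname(rho)))
  out[order(-out$abs_rho), ]
}
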