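#' Length-ratio / area-ratio conversions on a hemispherical ventricle
#'
#' On a hemispherical ventricle whose two wall regions meet along a sagittal
#' plane through the vertex, a wall occupying a fraction `LR` of the
#' base-to-base outline length occupies the surface-area fraction
#' `AR = (1 - cos(pi * LR)) / 2`. [length_ratio_from_area_ratio()] is the
#' exact inverse, `LR = acos(1 - 2 * AR) / pi`.
#'
#' @param LR,AR Dimensionless ratios in `[0, 1]`; may be vectors.
#' @return The converted ratio in `[0, 1]`.
#' @examples
#' area_ratio_from_length_ratio(2 / 3) # 0.75
#' length_ratio_from_area_ratio(0.75)  # 2/3
#' @export
area_ratio_from_length_ratio <- function(LR) {
  if (any(!is.finite(LR)) || any(LR < 0 | LR > 1)) {
    stop("LR must lie in [0, 1]")
  }
  (1 - cos(pi * LR)) / 2
}

#' @rdname area_ratio_from_length_ratio
#' @export
length_ratio_from_area_ratio <- function(AR) {
  if (any(!is.finite(AR)) || any(AR < 0 | AR > 1)) {
    stop("AR must lie in [0, 1]")
  }
  acos(1 - 2 * AR) / pi
}

#' Radius of a hemisphere holding a given volume
#'
#' `r = (3 V / (2 pi))^(1/3)`, the basal radius of the hemispherical
#' ventricular cavity.
#'
#' @param V Cavity volume (ml); may be a vector.
#' @return Radius (cm).
#' @export
hemisphere_radius <- function(V) {
  if (any(!is.finite(V)) || any(V <= 0)) stop("V must be > 0")
  (3 * V / (2 * pi))^(1 / 3)
}

# Position of a material point along the outline at time t, as a fraction of
# the current half-circumference. `u` is the point's end-diastolic outline
# fraction (from the earlier base), `LR0` the earlier wall's end-diastolic
# length fraction and `LR_t` its current one. Within each compartment's arc
# the stretch is uniform, so the map is piecewise linear in u.
material_position <- function(u, LR_t, LR0) {
  if (u <= LR0) {
    u / LR0 * LR_t
  } else {
    LR_t + (u - LR0) / (1 - LR0) * (1 - LR_t)
  }
}

#' Synthesize hemiglobal longitudinal strain curves from compartment volumes
#'
#' Maps the two compartment volume traces onto a hemispherical ventricle cut
#' through the vertex: the outline is a semicircle of length `pi * r(t)` with
#' `r(t)` from the total volume, and the earlier wall occupies the outline
#' length fraction corresponding (via the hemisphere area identity) to its
#' instantaneous volume fraction. The outline is divided into `n_segments`
#' equal material segments at end-diastole; each material point keeps its
#' relative position within its compartment's arc, and a segment straddling
#' the compartment boundary is split there. Hemiglobal strain on each side is
#' the relative length change of the `n_basal` basal segments from that base
#' (the apical cap excluded), in percent, zero at the end-diastolic reference.
#' Negative values denote shortening.
#'
#' @param V_e,V_d Earlier and delayed compartment volume traces (ml).
#' @param time_ms Shared time grid (ms).
#' @param events List of event times as produced by [simulate_fontan()]
#'   (fields `vent_onset_earlier`, `vent_onset_delayed`, `ao_open`,
#'   `ao_close`); the end-diastolic reference sample is the one nearest
#'   `vent_onset_earlier`.
#' @param n_segments Number of material segments over the whole outline.
#' @param n_basal Number of basal segments entering each hemiglobal strain.
#' @return An object of class `strain_traces`: data frame with `time_ms`,
#'   `earlier`, `delayed` (percent strain) plus the `events` and the
#'   end-diastolic sample index as attributes.
#' @export
hemiglobal_strains <- function(V_e, V_d, time_ms, events,
                               n_segments = 7, n_basal = 3) {
  if (length(V_e) != length(time_ms) || length(V_d) != length(time_ms)) {
    stop("V_e, V_d and time_ms must share one grid")
  }
  if (any(V_e <= 0) || any(V_d <= 0)) stop("compartment volumes must be > 0")
  if (n_basal >= n_segments / 2 + 1) stop("n_basal segments must leave an apical cap")
  i_ed <- which.min(abs(time_ms - events$vent_onset_earlier))

  V <- V_e + V_d
  r <- hemisphere_radius(V)
  v_e <- V_e / V                                   # instantaneous volume (area) fraction
  LR <- length_ratio_from_area_ratio(v_e)          # earlier wall length fraction
  LR0 <- LR[i_ed]
  r0 <- r[i_ed]

  u_e <- n_basal / n_segments        # earlier-side material interval [0, u_e]
  u_d <- 1 - n_basal / n_segments    # delayed-side interval [u_d, 1]
  len_e <- material_position(u_e, LR, LR0) * pi * r
  len_d <- (1 - material_position(u_d, LR, LR0)) * pi * r
  earlier <- 100 * (len_e / (u_e * pi * r0) - 1)
  delayed <- 100 * (len_d / ((1 - u_d) * pi * r0) - 1)

  st <- data.frame(time_ms = time_ms, earlier = earlier, delayed = delayed)
  attr(st, "events") <- events
  attr(st, "i_ed") <- i_ed
  class(st) <- c("strain_traces", class(st))
  st
}

#' Systolic rebound-stretch ratio of a strain trace
#'
#' `R_strains = (100 + Strain_ejection) / (100 + Strain_isovolumic)`, where
#' `Strain_isovolumic` is the minimum strain between the activation onset and
#' aortic valve opening and `Strain_ejection` the minimum during ejection
#' (aortic opening to closure). Values above 1 flag a systolic rebound
#' stretch: the early-activated wall is forcedly dilated during ejection after
#' its initial shortening.
#'
#' @param strain Percent strain trace (vector).
#' @param time_ms Time grid (ms).
#' @param onset Activation (QRS) onset time (ms); start of the isovolumic
#'   window, configurable.
#' @param ao_open,ao_close Aortic valve opening / closure times (ms).
#' @return The dimensionless ratio.
#' @examples
#' r_strains_from_values(-10, -20) # 90/80 = 1.125
#' @export
r_strains <- function(strain, time_ms, onset, ao_open, ao_close) {
  if (any(is.na(c(onset, ao_open, ao_close)))) {
    stop("onset, ao_open and ao_close are required")
  }
  ivc <- time_ms >= onset & time_ms <= ao_open
  ej <- time_ms >= ao_open & time_ms <= ao_close
  if (!any(ivc) || !any(ej)) stop("event windows contain no samples")
  r_strains_from_values(min(strain[ej]), min(strain[ivc]))
}

#' @rdname r_strains
#' @param strain_ejection,strain_isovolumic The two window-minimum strain
#'   values (percent).
#' @export
r_strains_from_values <- function(strain_ejection, strain_isovolumic) {
  (100 + strain_ejection) / (100 + strain_isovolumic)
}

#' Time-to-peak-strain difference between the two walls
#'
#' Difference between the times at which the delayed and the earlier
#' hemiglobal strains attain their (first) global minimum, a standard
#' dyssynchrony index. The search starts at the end-diastolic reference
#' sample.
#'
#' @param st A `strain_traces` object from [hemiglobal_strains()], or a data
#'   frame with `time_ms`, `earlier`, `delayed`.
#' @return Delay (ms), positive when the delayed wall peaks later.
#' @export
time_to_peak_difference <- function(st) {
  i0 <- attr(st, "i_ed")
  if (is.null(i0)) i0 <- 1L
  idx <- seq.int(i0, nrow(st))
  t_e <- st$time_ms[idx][which.min(st$earlier[idx])]
  t_d <- st$time_ms[idx][which.min(st$delayed[idx])]
  t_d - t_e
}

#' @export
print.strain_traces <- function(x, ...) {
  cat("<strain_traces>", nrow(x), "samples; earlier peak",
      round(min(x$earlier), 1), "%, delayed peak", round(min(x$delayed), 1),
      "%\n")
  invisible(x)
}

#' Strain curves of a simulated beat
#'
#' Convenience wrapper: extracts the compartment volume traces and event times
#' of a simulated beat and synthesizes the two hemiglobal strain curves.
#'
#' @param beat A `fontan_beat` from [simulate_fontan()].
#' @inheritParams hemiglobal_strains
#' @return A `strain_traces` object.
#' @export
beat_strains <- function(beat, n_segments = 7, n_basal = 3) {
  stopifnot(inherits(beat, "fontan_beat"))
  hemiglobal_strains(beat$traces$V_e, beat$traces$V_d, beat$traces$t_ms,
                     beat$events, n_segments = n_segments, n_basal = n_basal)
}
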