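# Shape predicates used for the qualitative waveform checks.

# Indices of local minima whose prominence (rise to the highest sample on
# both sides) reaches `prominence`.
local_minima <- function(x, prominence = 1) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) > 0) + 1L
  keep <- vapply(cand, function(i) {
    (max(x[1:i]) - x[i]) >= prominence && (max(x[i:n]) - x[i]) >= prominence
  }, logical(1))
  cand[keep]
}

# Number of contiguous supra-threshold episodes of reverse intercompartment
# flow (delayed -> earlier, i.e. -Q_ic > thr) within the systolic window.
reverse_flow_episodes <- function(beat, thr = 5) {
  tr <- beat$traces
  ev <- beat$events
  win <- tr$t_ms >= ev$vent_onset_earlier & tr$t_ms <= ev$ao_close
  above <- (-tr$Q_ic[win]) > thr
  sum(diff(c(FALSE, above)) == 1)
}

# Earlier-wall strain minima count over activation onset .. shortly past
# aortic closure (the relaxation tail delimits a late minimum).
earlier_strain_minima <- function(beat, prominence = 1, tail_ms = 60) {
  st <- beat_strains(beat)
  ev <- beat$events
  win <- st$time_ms >= ev$vent_onset_earlier &
    st$time_ms <= ev$ao_close + tail_ms
  local_minima(st$earlier[win], prominence)
}
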