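test_that("length/area ratio conversions are exact and involutive", {
  expect_identical(area_ratio_from_length_ratio(0), 0)
  expect_equal(area_ratio_from_length_ratio(1), 1)
  expect_equal(area_ratio_from_length_ratio(0.5), 0.5)
  expect_equal(area_ratio_from_length_ratio(2 / 3), 0.75) # cos(120 deg) = -1/2
  expect_equal(length_ratio_from_area_ratio(0.75), 2 / 3)
  expect_equal(length_ratio_from_area_ratio(0.5), 0.5)
  grid <- seq(0, 1, length.out = 201)
  expect_equal(area_ratio_from_length_ratio(length_ratio_from_area_ratio(grid)),
               grid, tolerance = 1e-12)
  expect_true(all(diff(area_ratio_from_length_ratio(grid)) > 0))
  expect_error(area_ratio_from_length_ratio(1.2), "\\[0, 1\\]")
  expect_error(length_ratio_from_area_ratio(-0.1), "\\[0, 1\\]")
})

test_that("hemisphere radius follows the cube-root volume law", {
  expect_equal(hemisphere_radius(2 * pi / 3), 1.0)
  expect_equal(hemisphere_radius(102.0), (3 * 102 / (2 * pi))^(1 / 3))
  expect_equal(hemisphere_radius(8 * 50), 2 * hemisphere_radius(50))
  expect_error(hemisphere_radius(0), "> 0")
})

synthetic_events <- function(t) {
  list(vent_onset_earlier = t[1], vent_onset_delayed = t[1],
       ao_open = t[ceiling(length(t) / 3)],
       ao_close = t[ceiling(2 * length(t) / 3)])
}

test_that("uniform contraction gives the similarity strain on both walls", {
  t <- seq(0, 500, by = 5)
  k <- 1 - 0.5 * (1 - cos(2 * pi * t / 500)) / 2 # 1 -> 0.5 -> 1
  V <- 100 * k
  st <- hemiglobal_strains(0.35 * V, 0.65 * V, t, synthetic_events(t))
  expect_equal(st$earlier, 100 * (k^(1 / 3) - 1), tolerance = 1e-10)
  expect_equal(st$delayed, st$earlier, tolerance = 1e-10)
  expect_equal(min(st$earlier), 100 * (0.5^(1 / 3) - 1)) # -20.63% at k = 1/2
})

test_that("constant volumes give identically zero strain", {
  t <- seq(0, 400, by = 10)
  st <- hemiglobal_strains(rep(30, length(t)), rep(70, length(t)), t,
                           synthetic_events(t))
  expect_equal(st$earlier, rep(0, length(t)))
  expect_equal(st$delayed, rep(0, length(t)))
  expect_error(hemiglobal_strains(rep(-1, 3), rep(70, 3), 1:3,
                                  synthetic_events(1:3)), "> 0")
})

test_that("material segment lengths always tile the semicircular outline", {
  set.seed(4)
  t <- seq(0, 300, by = 10)
  V_e <- 30 + 8 * sin(t / 40) + rnorm(length(t), 0, 0.5)
  V_d <- 70 - 12 * sin(t / 55) + rnorm(length(t), 0, 0.5)
  V <- V_e + V_d
  r <- hemisphere_radius(V)
  LR <- length_ratio_from_area_ratio(V_e / V)
  LR0 <- LR[1]
  bounds <- (0:7) / 7
  pos <- vapply(bounds, fontansim:::material_position, numeric(length(t)),
                LR_t = LR, LR0 = LR0)
  seg_len <- (pos[, -1, drop = FALSE] - pos[, -8, drop = FALSE]) * pi * r
  expect_true(all(seg_len > 0))
  expect_equal(rowSums(seg_len), pi * r, tolerance = 1e-12)
})

test_that("zero-delay strains coincide on both walls throughout systole", {
  # the AV inflow enters through the earlier compartment, so during rapid
  # filling the walls deviate transiently even without an activation delay;
  # over the systolic window (which defines every discoordination index) the
  # two hemiglobal strains must agree
  b <- simulate_fontan(fontan_params(), delayed_fraction = 0.40, delay_dT = 0)
  st <- beat_strains(b)
  ev <- b$events
  sys <- st$time_ms >= ev$vent_onset_earlier & st$time_ms <= ev$ao_close
  expect_lt(max(abs(st$earlier - st$delayed)[sys]), 1.5)
  expect_equal(st$earlier[attr(st, "i_ed")], 0)
  expect_equal(st$delayed[attr(st, "i_ed")], 0)
})

test_that("the rebound-stretch ratio follows its defining arithmetic", {
  expect_identical(r_strains_from_values(-15, -15), 1)
  expect_equal(r_strains_from_values(-10, -20), 90 / 80)
  expect_equal(r_strains_from_values(-20, -10), 80 / 90)
  # windowed version on a constructed trace
  t <- 0:100
  s <- c(seq(0, -20, length.out = 34), seq(-20, -10, length.out = 33),
         seq(-10, -25, length.out = 34))
  rs <- r_strains(s, t, onset = 0, ao_open = 33, ao_close = 66)
  expect_equal(rs, (100 + min(s[34:67])) / (100 + min(s[1:34])))
  expect_error(r_strains(s, t, 0, NA, 66), "required")
})

test_that("monotone shortening never produces a rebound ratio above 1", {
  set.seed(9)
  t <- 0:200
  for (i in 1:20) {
    drop_at <- sample(60:160, 1)
    s <- c(seq(0, runif(1, -30, -5), length.out = drop_at),
           rep(NA, 201 - drop_at))
    s[is.na(s)] <- s[drop_at] # hold after shortening
    rs <- r_strains(s, t, onset = 0, ao_open = sample(20:50, 1),
                    ao_close = sample(150:200, 1))
    expect_lte(rs, 1 + 1e-12)
  }
})

test_that("time-to-peak difference recovers a constructed shift", {
  t <- seq(0, 600, by = 2)
  base <- -20 * exp(-((t - 250) / 90)^2)
  st <- data.frame(time_ms = t, earlier = base,
                   delayed = -20 * exp(-((t - 310) / 90)^2))
  attr(st, "i_ed") <- 1L
  expect_equal(time_to_peak_difference(st), 60)
  st$delayed <- base
  expect_equal(time_to_peak_difference(st), 0)
  # two equal minima: the first occurrence is used
  twomin <- base
  twomin[t >= 450] <- -20 * exp(-((t[t >= 450] - 500) / 40)^2)
  st$earlier <- twomin
  st$delayed <- base
  i_scan <- which(twomin == min(twomin))[1] # independent scan oracle
  expect_equal(time_to_peak_difference(st), t[which.min(base)] - t[i_scan])
})
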