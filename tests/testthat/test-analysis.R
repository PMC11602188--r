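test_that("low-pass filter has unit DC gain and kills 5x-cutoff content", {
  x <- rep(3.7, 1000)
  expect_lt(max(abs(lowpass(x) - 3.7)), 1e-9)
  t <- seq(0, 1, by = 0.001)
  hum <- sin(2 * pi * 50 * t)
  y <- lowpass(hum)
  core <- y[200:800]  # away from edge transients
  expect_lt(max(abs(core)), 0.01)
  expect_error(lowpass(rnorm(10)), "too short")
})

test_that("single-pass gain at the cutoff is the half-power point", {
  expect_equal(filter_gain(10, fs = 1000, cutoff = 10, order = 4, passes = 1),
               1 / sqrt(2), tolerance = 1e-6)
  expect_equal(filter_gain(10, passes = 2), 0.5, tolerance = 1e-6)
  expect_equal(filter_gain(0), 1, tolerance = 1e-9)
})

test_that("filtering is linear (superposition holds numerically)", {
  set.seed(5)
  a <- rnorm(500); b <- rnorm(500)
  expect_equal(lowpass(2 * a + 3 * b), 2 * lowpass(a) + 3 * lowpass(b),
               tolerance = 1e-9)
})

test_that("peak-velocity index lands at the minimum-jerk midpoint", {
  kin <- synthesize_trial(0, 0, duration = 0.5, dt = 0.001)
  ipk <- peak_velocity_index(kin)
  expect_lte(abs(ipk - 251), 1)  # tau = 0.5 is sample 251 of 501
  # degenerate monotone ramp peaks at the end
  ramp <- structure(list(time = seq(0, 0.2, by = 0.001),
                         tip = cbind(seq(0, 0.2, by = 0.001)^2 * 100, 0),
                         left = NULL, right = NULL,
                         tilt = numeric(201)), class = "trial_kinematics")
  expect_equal(peak_velocity_index(ramp, filtered = FALSE), 201)
  expect_equal(which.max(c(1, 5, 5, 2)), 2)  # first-index tie rule
})

test_that("TMD/STA read-out uses the chord and the initial tilt reference", {
  kin <- synthesize_trial(20, 4, initial_tilt = 3)
  expect_equal(tmd_sta_at(kin, 100)[["tmd"]], 20, tolerance = 1e-9)
  expect_equal(tmd_sta_at(kin, length(kin$time))[["sta"]], 4,
               tolerance = 1e-9)
  # at half displacement the linear ramp has accrued half the tilt
  half <- which.min(abs(sqrt(rowSums((kin$tip -
            matrix(kin$tip[1, ], nrow(kin$tip), 2, byrow = TRUE))^2)) - 5))
  expect_equal(tmd_sta_at(kin, half)[["sta"]], 2, tolerance = 1e-3)
  expect_error(tmd_sta_at(kin, 1), "not moved")
  # the velocity read-out agrees on straight paths
  expect_equal(tmd_sta_at(kin, 100, method = "velocity")[["tmd"]], 20,
               tolerance = 1e-9)
})

test_that("trial measures report offset tilt and speed flag", {
  m <- trial_measures(synthesize_trial(0, 6))
  expect_equal(m$sta_offset_deg, 6, tolerance = 1e-6)
  expect_equal(m$sta_deg, 3, tolerance = 1e-6)
  expect_equal(m$flag, "ok")
  expect_gt(m$peak_speed_mms, 300)
  expect_lt(m$peak_speed_mms, 450)
})

test_that("analyze_trials processes a multi-trial table end to end", {
  tabs <- rbind(as_trial_table(synthesize_trial(10, 2), trial = 1),
                as_trial_table(synthesize_trial(-10, -2), trial = 2))
  meas <- analyze_trials(tabs, target_dir = c(10, -10))
  expect_equal(nrow(meas), 2)
  expect_equal(meas$tmd_deg, c(10, -10), tolerance = 1e-6)
  expect_equal(meas$sta_deg, c(1, -1), tolerance = 1e-6)
  expect_error(analyze_trials(tabs[0, ]), "empty")
})

test_that("default segment scheme partitions the adaptation phase", {
  seg <- default_segments()
  expect_equal(nrow(seg), 9)
  expect_equal(seg$first[1], 1)
  expect_equal(seg$last[9], 240)
  expect_true(all(seg$first[-1] == seg$last[-9] + 1))  # no overlap, no gap
})

test_that("segment means average the right trial windows", {
  meas <- data.frame(trial = 1:240, tmd_deg = 1:240, sta_deg = rep(2, 240))
  sm <- segment_means(meas)
  expect_equal(sm$tmd_deg[1], 3)            # mean of 1..5
  expect_equal(sm$tmd_deg[7], mean(31:120)) # normalized 31-120 window
  expect_equal(sm$sta_deg, rep(2, 9))
  expect_equal(sm$n[9], 30)
  expect_error(segment_means(meas[meas$trial > 10, ]), "no trials")
  # permutation within a segment does not change the means
  perm <- meas[sample(nrow(meas)), ]
  expect_equal(segment_means(perm)$tmd_deg, sm$tmd_deg)
})

test_that("trial variability uses the 121-240 window sample SD", {
  meas <- data.frame(trial = 1:240,
                     tmd_deg = rep(c(1, -1), 120),
                     sta_deg = rep(0, 240))
  v <- trial_variability(meas)
  # alternating +-1: sample SD = sqrt(n/(n-1)) at n = 120
  expect_equal(v[["sd_tmd"]], sqrt(120 / 119), tolerance = 1e-9)
  expect_equal(v[["sd_sta"]], 0)
  const <- data.frame(trial = 1:240, tmd_deg = 5, sta_deg = -2)
  expect_equal(unname(trial_variability(const)), c(0, 0))
  expect_error(trial_variability(meas, first = 240, last = 240),
               "at least 2")
})

test_that("summary statistics match their textbook definitions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(paired_t(x, x)$t, 0)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  set.seed(9)
  y <- x + rnorm(5)
  pt <- paired_t(x, y)
  expect_equal(pt$t, mean(x - y) / (sd(x - y) / sqrt(5)), tolerance = 1e-12)
  expect_equal(pt$dof, 4)
  # paired d: mean difference over the SD of the differences
  expect_equal(cohens_d(c(2, 4), c(1, 1), paired = TRUE),
               mean(c(1, 3)) / sd(c(1, 3)))
  expect_equal(cohens_d(x, 3), 0)
  # two-sample pooled-SD definition
  expect_equal(cohens_d(c(0, 2), c(-1, 1)), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), x), "zero-variance")
})

test_that("half-adaptation trial orders faster and slower learning curves", {
  fast <- -30 * (1 - exp(-(1:240) / 10))
  slow <- -30 * (1 - exp(-(1:240) / 40))
  expect_lt(half_adaptation_trial(fast), half_adaptation_trial(slow))
  expect_true(is.na(half_adaptation_trial(rep(0, 240))))
})
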