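test_that("gradual tip schedule ramps 1 deg/trial and caps at 30", {
  spec <- perturbation_spec("gradual")
  expect_equal(tip_rotation_at_trial(1, spec), 1)
  expect_equal(tip_rotation_at_trial(c(15, 30, 31, 240), spec),
               c(15, 30, 30, 30))
  expect_error(tip_rotation_at_trial(0, spec), "1-based")
})

test_that("abrupt and off schedules are constant", {
  expect_equal(tip_rotation_at_trial(c(1, 240), perturbation_spec("abrupt")),
               c(30, 30))
  expect_equal(tip_rotation_at_trial(c(1, 240), perturbation_spec("none")),
               c(0, 0))
})

test_that("tilt perturbation is linear in displacement at 0.6 deg/cm", {
  ccw <- perturbation_spec("none", tilt_sign = +1)
  cw <- perturbation_spec("none", tilt_sign = -1)
  expect_equal(tilt_perturbation_at_displacement(10, ccw), 6)
  expect_equal(tilt_perturbation_at_displacement(0, ccw), 0)
  expect_equal(tilt_perturbation_at_displacement(5, cw), -3)
  expect_error(tilt_perturbation_at_displacement(-1, ccw), "non-negative")
})

test_that("visual map: identity when off, rotation + tilt shift when on", {
  off <- perturbation_spec("none")
  pose <- stick_pose(c(7, 3), 2.5)
  vis <- apply_visual_map(pose, c(0, 0), 1, off)
  expect_equal(vis$tip, pose$tip)
  expect_equal(vis$tilt, pose$tilt)

  # abrupt 30-deg tip rotation moves a 10-cm reach at 0 deg to 30 deg,
  # leaving the tilt unchanged
  tip30 <- perturbation_spec("abrupt", tilt_sign = 0)
  vis2 <- apply_visual_map(stick_pose(c(10, 0), 0), c(0, 0), 1, tip30)
  expect_equal(vis2$tip, 10 * c(cos(pi / 6), sin(pi / 6)), tolerance = 1e-12)
  expect_equal(vis2$tilt, 0)

  # tilt perturbation composes additively with the physical tilt
  tilt_ccw <- perturbation_spec("none", tilt_sign = +1)
  vis3 <- apply_visual_map(stick_pose(c(10, 0), 2), c(0, 0), 1, tilt_ccw)
  expect_equal(vis3$tilt, 8)
  expect_equal(vis3$tip, c(10, 0))
})

test_that("visual map preserves displacement and inverts exactly", {
  spec <- perturbation_spec("gradual", tilt_sign = +1)
  start <- c(1, -2)
  for (i in c(1, 17, 240)) {
    pose <- stick_pose(start + c(6.1, -3.3), 4.2)
    vis <- apply_visual_map(pose, start, i, spec)
    expect_equal(sqrt(sum((vis$tip - start)^2)),
                 sqrt(sum((pose$tip - start)^2)), tolerance = 1e-12)
    back <- invert_visual_map(vis, start, i, spec)
    expect_lt(max(abs(back$tip - pose$tip)), 1e-9)
    expect_lt(abs(back$tilt - pose$tilt), 1e-9)
  }
})

test_that("plane map agrees with the pose-level map at end of movement", {
  spec <- perturbation_spec("gradual", tilt_sign = +1)
  d <- 10
  for (i in c(1, 30, 200)) {
    phys <- plane_state(tmd = -12, sta = -2.4, frame = "physical")
    vis <- plane_map(phys, i, spec, displacement = d)
    th <- phys$tmd * pi / 180
    pose <- stick_pose(d * c(cos(th), sin(th)), phys$sta)
    vpose <- apply_visual_map(pose, c(0, 0), i, spec)
    tmd_pose <- atan2(vpose$tip[2], vpose$tip[1]) * 180 / pi
    expect_equal(vis$tmd, tmd_pose, tolerance = 1e-9)
    expect_equal(vis$sta, vpose$tilt, tolerance = 1e-9)
  }
  expect_error(plane_map(plane_state(0, 0, "visual"), 1, spec), "physical")
})

test_that("all-off plane map just re-tags the frame", {
  off <- perturbation_spec("none")
  s <- plane_state(-7.7, 1.2, "physical")
  v <- plane_map(s, 3, off)
  expect_equal(v$tmd, s$tmd)
  expect_equal(v$sta, s$sta)
  expect_equal(v$frame, "visual")
})

test_that("perturbation spec round-trips through YAML", {
  spec <- perturbation_spec("gradual", tip_max = 30, tip_step = 1,
                            tilt_gain = 0.6, tilt_sign = -1)
  f <- tempfile(fileext = ".yaml")
  write_perturbation_yaml(spec, f)
  back <- read_perturbation_yaml(f)
  expect_equal(back, spec)
  y <- yaml::read_yaml(f)
  expect_named(y, c("tip_mode", "tip_max_deg", "tip_step_deg",
                    "tilt_gain_deg_per_cm", "tilt_sign"))
  unlink(f)
})
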