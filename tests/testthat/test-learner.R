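test_that("prediction errors follow the plane geometry", {
  rel <- linear_relation(slope = 0.2)
  # unperturbed baseline state on the relation: no error
  e0 <- prediction_errors(plane_state(0, 0, "visual"), 0, rel)
  expect_equal(unname(e0), c(0, 0))
  # first CCW tilt-perturbation trial: pure tilt error of -6
  e2 <- prediction_errors(plane_state(0, 6, "visual"), 0, rel)
  expect_equal(unname(e2), c(0, -6))
  # fully compensated tip rotation: the visual stick tilt is abnormal
  e1 <- prediction_errors(plane_state(0, predict(rel, -30), "visual"), 0, rel)
  expect_equal(unname(e1), c(0, -predict(rel, -30)))
  expect_gt(abs(e1[["e_sta"]]), 0)
  expect_error(prediction_errors(plane_state(0, 0, "physical"), 0, rel),
               "visual")
})

test_that("zero error and zero retention loss is a fixed point", {
  rel <- linear_relation(slope = 0.2)
  par <- learner_params(retention_loss = 0)
  s <- plane_state(-3, -0.6, "physical")
  s2 <- update_state(s, c(0, 0), par, rel)
  expect_equal(s2$tmd, s$tmd)
  expect_equal(s2$sta, s$sta)
})

test_that("tilt errors drag both dimensions along the relation", {
  rel <- linear_relation(slope = 0.2)
  par <- learner_params()
  s <- plane_state(0, 0, "physical")
  s2 <- update_state(s, c(0, -6), par, rel)
  expect_lt(s2$tmd, 0)  # CW tip shift accompanies the CW tilt correction
  expect_lt(s2$sta, 0)
  # a flat relation has no along-relation component for tilt errors
  flat <- linear_relation(slope = 0)
  s3 <- update_state(s, c(0, -6), par, flat)
  expect_equal(s3$tmd, 0)
  expect_equal(s3$sta, 0)
})

test_that("every noise-free update is parallel to the relation tangent", {
  rel <- linear_relation(slope = 0.2)
  par <- learner_params(motor_noise_tmd = 0, motor_noise_sta = 0,
                        retention_loss = 0)
  for (expname in c("E1A", "E2CCW", "E3CW")) {
    spec <- make_protocol(expname)$spec
    sim <- simulate_adaptation(100, par, rel, spec)
    tr <- sim$trials
    dm <- diff(tr$intent_tmd)
    da <- diff(tr$intent_sta)
    s <- relation_slope(rel, tr$intent_tmd[-nrow(tr)])
    expect_lt(max(abs(dm * s - da)), 1e-9)
  }
})

test_that("gradual tip rotation is fully compensated when tilt errors are ignored", {
  rel <- linear_relation(slope = 0.2)
  par <- learner_params(eta_sta = 0, motor_noise_tmd = 0,
                        motor_noise_sta = 0, retention_loss = 0)
  spec <- make_protocol("E1A")$spec
  sim <- simulate_adaptation(240, par, rel, spec)
  expect_lt(abs(sim$trials$exec_tmd[240] + 30), 1e-3)
  # the physical state moved along the relation: STA matches g(TMD)
  expect_lt(abs(sim$trials$exec_sta[240] -
                  predict(rel, sim$trials$exec_tmd[240])), 1e-6)
})

test_that("tilt-error correction leaves a residual tip-direction error", {
  rel <- linear_relation(slope = 0.2)
  par <- learner_params(motor_noise_tmd = 0, motor_noise_sta = 0,
                        retention_loss = 0)
  spec <- make_protocol("E1A")$spec
  sim <- simulate_adaptation(240, par, rel, spec)
  final <- sim$trials$exec_tmd[240]
  expect_gt(final, -30)
  expect_lt(final, 0)
  # fixed point of the along-relation recursion for a linear relation:
  # eta_m (m + 30) = s eta_a (g(m + 30) - g(m)) => m = -30 + 30 s^2
  s <- 0.2
  expect_equal(final, -30 + 30 * s^2, tolerance = 1e-3)
})

test_that("abrupt and gradual schedules reach the same steady state", {
  rel <- linear_relation(slope = 0.2)
  par <- learner_params(motor_noise_tmd = 0, motor_noise_sta = 0)
  a <- simulate_adaptation(240, par, rel, make_protocol("E1A")$spec)
  b <- simulate_adaptation(240, par, rel, make_protocol("E1B")$spec)
  expect_equal(a$trials$exec_tmd[240], b$trials$exec_tmd[240],
               tolerance = 1e-6)
})

test_that("simulation is reproducible under a seed", {
  rel <- linear_relation()
  a <- simulate_adaptation(50, learner_params(), rel,
                           make_protocol("E2CCW")$spec, seed = 3)
  b <- simulate_adaptation(50, learner_params(), rel,
                           make_protocol("E2CCW")$spec, seed = 3)
  expect_identical(a$trials, b$trials)
})

test_that("grid simulator matches the scalar simulator without noise", {
  rel <- linear_relation(slope = 0.2)
  spec <- make_protocol("E3CW")$spec
  par <- learner_params(eta_tmd = 0.25, eta_sta = 0.4,
                        retention_loss = 0.05,
                        motor_noise_tmd = 0, motor_noise_sta = 0)
  sim <- simulate_adaptation(120, par, rel, spec)
  grid <- stickreach:::simulate_state_grid(0.25, 0.4, 0.05, 120, rel, spec)
  expect_equal(grid$tmd[, 1], sim$trials$intent_tmd, tolerance = 1e-12)
  expect_equal(grid$sta[, 1], sim$trials$intent_sta, tolerance = 1e-12)
})

test_that("fit_learner recovers noiseless parameters exactly at grid resolution", {
  rel <- linear_relation(slope = 0.2)
  spec <- make_protocol("E1A")$spec
  truth <- learner_params(eta_tmd = 0.3, eta_sta = 0.3,
                          motor_noise_tmd = 0, motor_noise_sta = 0)
  sim <- simulate_adaptation(240, truth, rel, spec)
  fit <- fit_learner(sim$trials$exec_tmd, sim$trials$exec_sta, spec, rel)
  expect_equal(unname(coef(fit)),
               c(0.3, 0.3, 0), tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit)$tmd)), 1e-9)
})

test_that("tilt-error normalization raises a shallow relation's tilt sensitivity", {
  spec <- make_protocol("E2CCW")$spec
  shallow <- linear_relation(0.1)  # g(30) = 3, half the 6-deg reference
  par_plain <- learner_params(motor_noise_tmd = 0, motor_noise_sta = 0)
  par_norm <- learner_params(motor_noise_tmd = 0, motor_noise_sta = 0,
                             tilt_error_norm = TRUE)
  plain <- simulate_adaptation(240, par_plain, shallow, spec)
  norm <- simulate_adaptation(240, par_norm, shallow, spec)
  expect_gt(abs(norm$trials$exec_sta[240]),
            abs(plain$trials$exec_sta[240]))
  # reference slope 0.2 (g(30) = 6): the flag is a no-op there
  ref <- linear_relation(0.2)
  expect_equal(
    simulate_adaptation(100, par_norm, ref, spec)$trials$exec_sta[100],
    simulate_adaptation(100, par_plain, ref, spec)$trials$exec_sta[100],
    tolerance = 1e-12)
  expect_error(stickreach:::eta_sta_effective(par_norm, linear_relation(0)),
               "flat")
})
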