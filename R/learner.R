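#' Learner parameters
#'
#' Free parameters of the trial-by-trial adaptation rule. The learner keeps
#' a planned (TMD, STA) intent; after each trial the visual errors in both
#' dimensions are weighted by their learning rates and the resulting error
#' vector is projected onto the tangent of the baseline TMD-STA
#' relationship, so corrections stay on the stereotyped manifold.
#'
#' @param eta_tmd Learning rate for the task (tip-direction) error, in
#'   \[0, 1\].
#' @param eta_sta Learning rate for the stick-tilt error, in \[0, 1\].
#' @param retention_loss Per-trial decay of the intent toward the baseline
#'   point for the current target, in \[0, 0.2\].
#' @param motor_noise_tmd,motor_noise_sta SD of additive trial-level
#'   execution noise, degrees.
#' @param tilt_error_norm Logical; when `TRUE` the tilt learning rate is
#'   scaled by `6 / |g(30)|`, normalizing tilt-error sensitivity by the
#'   participant's own tilt repertoire (shallower baseline relations then
#'   correct a fixed tilt perturbation more strongly). Default `FALSE`.
#' @return An object of class `learner_params`.
#' @export
learner_params <- function(eta_tmd = 0.3, eta_sta = 0.3,
                           retention_loss = 0,
                           motor_noise_tmd = 1, motor_noise_sta = 1,
                           tilt_error_norm = FALSE) {
  stopifnot(eta_tmd >= 0, eta_tmd <= 1, eta_sta >= 0, eta_sta <= 1,
            retention_loss >= 0, retention_loss <= 0.2,
            motor_noise_tmd >= 0, motor_noise_sta >= 0,
            is.logical(tilt_error_norm), length(tilt_error_norm) == 1)
  structure(
    list(eta_tmd = eta_tmd, eta_sta = eta_sta,
         retention_loss = retention_loss,
         motor_noise_tmd = motor_noise_tmd,
         motor_noise_sta = motor_noise_sta,
         tilt_error_norm = tilt_error_norm),
    class = "learner_params"
  )
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf(
    "Learner: eta_tmd %.3f, eta_sta %.3f, retention loss %.3f, noise SD (%.2f, %.2f) deg%s\n",
    x$eta_tmd, x$eta_sta, x$retention_loss,
    x$motor_noise_tmd, x$motor_noise_sta,
    if (x$tilt_error_norm) ", tilt-error normalization on" else ""))
  invisible(x)
}

#' Visual prediction errors for one trial
#'
#' The task error is the displayed target direction minus the observed
#' visual tip-movement direction. The tilt error is the stick-tilt angle the
#' baseline relationship predicts for the observed visual TMD minus the
#' observed visual STA - a sensory prediction error in the end-effector
#' irrelevant dimension.
#'
#' @param visual A visual-frame [plane_state()].
#' @param target_dir Displayed target direction, degrees.
#' @param relation A `baseline_relation`.
#' @return Named numeric vector `c(e_tmd = , e_sta = )`, degrees.
#' @export
prediction_errors <- function(visual, target_dir, relation) {
  stopifnot(inherits(visual, "plane_state"))
  if (visual$frame != "visual")
    stop("prediction_errors expects a visual-frame state")
  c(e_tmd = target_dir - visual$tmd,
    e_sta = predict(relation, visual$tmd) - visual$sta)
}

# effective tilt learning rate, optionally normalized by the participant's
# tilt at the 30-degree target (reference tilt 6 deg)
eta_sta_effective <- function(params, relation) {
  if (!params$tilt_error_norm) return(params$eta_sta)
  g30 <- abs(predict(relation, 30))
  if (g30 < 1e-6) stop("tilt-error normalization undefined for a flat relation")
  params$eta_sta * 6 / g30
}

#' One application of the constrained-correction update
#'
#' With s the relation slope at the current intent, unit tangent
#' t = (1, s)/sqrt(1 + s^2) and weighted error u = (eta_tmd e_tmd,
#' eta_sta e_sta), the intent moves by the projection (u . t) t along the
#' relation, after decaying toward the baseline point for the target:
#' intent' = b + (1 - lambda)(intent - b) + (u . t) t,
#' b = (target_dir, g(target_dir)).
#'
#' @param intent Physical-frame [plane_state()] (the planned movement).
#' @param errors Numeric `c(e_tmd, e_sta)` as from [prediction_errors()].
#' @param params A [learner_params()].
#' @param relation A `baseline_relation`.
#' @param target_dir Displayed target direction, degrees (default 0).
#' @return The updated physical [plane_state()].
#' @export
update_state <- function(intent, errors, params, relation, target_dir = 0) {
  stopifnot(inherits(intent, "plane_state"), length(errors) == 2)
  if (intent$frame != "physical")
    stop("update_state expects a physical-frame intent")
  s <- relation_slope(relation, intent$tmd)
  nrm <- sqrt(1 + s^2)
  tx <- 1 / nrm; ty <- s / nrm
  u1 <- params$eta_tmd * errors[[1]]
  u2 <- eta_sta_effective(params, relation) * errors[[2]]
  proj <- u1 * tx + u2 * ty
  lam <- params$retention_loss
  b_tmd <- target_dir
  b_sta <- predict(relation, target_dir)
  plane_state(
    tmd = b_tmd + (1 - lam) * (intent$tmd - b_tmd) + proj * tx,
    sta = b_sta + (1 - lam) * (intent$sta - b_sta) + proj * ty,
    frame = "physical"
  )
}

#' Simulate trial-by-trial adaptation of one synthetic participant
#'
#' Runs the constrained-correction learner through an adaptation phase:
#' each trial the intent is executed with additive motor noise, the visual
#' perturbation maps the executed state to the displayed state, prediction
#' errors are formed against the baseline relationship, and the intent is
#' updated along the relation tangent. Errors use end-of-movement visual
#' states, where the tilt perturbation has reached its full value.
#'
#' @param n_trials Number of adaptation trials (default 240).
#' @param params A [learner_params()].
#' @param relation The participant's `baseline_relation`.
#' @param spec A [perturbation_spec()].
#' @param target_dir Displayed target direction during adaptation, degrees
#'   (default 0).
#' @param target_distance Movement distance, cm (default 10).
#' @param seed Optional integer seed for the motor-noise draws.
#' @return An object of class `adaptation_sim` wrapping a data.frame with
#'   one row per trial: `trial`, `intent_tmd`, `intent_sta`, `exec_tmd`,
#'   `exec_sta`, `vis_tmd`, `vis_sta`, `e_tmd`, `e_sta` (all degrees).
#' @export
simulate_adaptation <- function(n_trials = 240, params = learner_params(),
                                relation = linear_relation(),
                                spec = perturbation_spec(),
                                target_dir = 0, target_distance = 10,
                                seed = NULL) {
  stopifnot(n_trials >= 1, inherits(params, "learner_params"),
            inherits(relation, "baseline_relation"),
            inherits(spec, "perturbation_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
  }
  rho <- tip_rotation_at_trial(seq_len(n_trials), spec)
  delta <- tilt_perturbation_at_displacement(target_distance, spec)
  eta_m <- params$eta_tmd
  eta_a <- eta_sta_effective(params, relation)
  lam <- params$retention_loss
  b_tmd <- target_dir
  b_sta <- predict(relation, target_dir)
  noise_m <- if (params$motor_noise_tmd > 0)
    stats::rnorm(n_trials, sd = params$motor_noise_tmd) else numeric(n_trials)
  noise_a <- if (params$motor_noise_sta > 0)
    stats::rnorm(n_trials, sd = params$motor_noise_sta) else numeric(n_trials)

  m <- b_tmd; a <- b_sta  # intent starts at the baseline point
  out <- matrix(NA_real_, n_trials, 8)
  for (i in seq_len(n_trials)) {
    em <- m + noise_m[i]
    ea <- a + noise_a[i]
    vm <- em + rho[i]
    va <- ea + delta
    e_tmd <- target_dir - vm
    e_sta <- predict(relation, vm) - va
    out[i, ] <- c(m, a, em, ea, vm, va, e_tmd, e_sta)
    s <- relation_slope(relation, m)
    nrm2 <- 1 + s^2
    proj <- (eta_m * e_tmd + eta_a * s * e_sta) / nrm2
    m <- b_tmd + (1 - lam) * (m - b_tmd) + proj
    a <- b_sta + (1 - lam) * (a - b_sta) + proj * s
  }
  trials <- data.frame(
    trial = seq_len(n_trials),
    intent_tmd = out[, 1], intent_sta = out[, 2],
    exec_tmd = out[, 3], exec_sta = out[, 4],
    vis_tmd = out[, 5], vis_sta = out[, 6],
    e_tmd = out[, 7], e_sta = out[, 8]
  )
  structure(
    list(trials = trials, params = params, relation = relation,
         spec = spec, target_dir = target_dir,
         target_distance = target_distance, seed = seed),
    class = "adaptation_sim"
  )
}

#' @export
as.data.frame.adaptation_sim <- function(x, ...) x$trials

#' @export
print.adaptation_sim <- function(x, ...) {
  n <- nrow(x$trials)
  last <- x$trials[x$trials$trial >= max(1, n - 29), ]
  cat(sprintf(
    "Adaptation simulation: %d trials | final 30-trial mean physical state TMD %+.2f deg, STA %+.2f deg\n",
    n, mean(last$exec_tmd), mean(last$exec_sta)))
  print(x$spec)
  invisible(x)
}

#' @export
plot.adaptation_sim <- function(x, which = c("trajectory", "plane"), ...) {
  which <- match.arg(which)
  tr <- x$trials
  if (which == "trajectory") {
    graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    graphics::plot(tr$trial, tr$exec_tmd, type = "l",
                   xlab = "adaptation trial", ylab = "physical TMD (deg)", ...)
    graphics::lines(tr$trial, tr$intent_tmd, col = "red")
    graphics::plot(tr$trial, tr$exec_sta, type = "l",
                   xlab = "adaptation trial", ylab = "physical STA (deg)", ...)
    graphics::lines(tr$trial, tr$intent_sta, col = "red")
  } else {
    graphics::plot(tr$exec_tmd, tr$exec_sta, type = "p", pch = 16,
                   col = grDevices::grey(0.7),
                   xlab = "TMD (deg)", ylab = "STA (deg)", ...)
    graphics::lines(tr$intent_tmd, tr$intent_sta, col = "red")
    kt <- x$relation$knots
    graphics::lines(kt$tmd, kt$sta, col = "grey40", lty = 2)
  }
  invisible(x)
}

# Deterministic (zero-noise) state trajectories for a whole grid of
# candidate parameters at once: the 240-step recursion is looped over
# trials and vectorized over grid points. Used by fit_learner.
simulate_state_grid <- function(eta_m, eta_a, lam, n_trials, relation, spec,
                                target_dir = 0, target_distance = 10) {
  g <- length(eta_m)
  stopifnot(length(eta_a) == g, length(lam) == g)
  rho <- tip_rotation_at_trial(seq_len(n_trials), spec)
  delta <- tilt_perturbation_at_displacement(target_distance, spec)
  b_tmd <- target_dir
  b_sta <- predict(relation, target_dir)
  m <- rep(b_tmd, g); a <- rep(b_sta, g)
  M <- matrix(NA_real_, n_trials, g)
  A <- matrix(NA_real_, n_trials, g)
  for (i in seq_len(n_trials)) {
    M[i, ] <- m; A[i, ] <- a
    vm <- m + rho[i]
    va <- a + delta
    e_tmd <- target_dir - vm
    e_sta <- predict(relation, vm) - va
    s <- relation_slope(relation, m)
    proj <- (eta_m * e_tmd + eta_a * s * e_sta) / (1 + s^2)
    m <- b_tmd + (1 - lam) * (m - b_tmd) + proj
    a <- b_sta + (1 - lam) * (a - b_sta) + proj * s
  }
  list(tmd = M, sta = A)
}

#' Recover learner parameters from an observed adaptation series
#'
#' Grid search: for every candidate (eta_tmd, eta_sta, retention_loss) the
#' deterministic (zero-noise) model trajectory is simulated under the same
#' protocol and the summed squared deviation from the observed executed
#' (TMD, STA) series is minimized.
#'
#' @param exec_tmd,exec_sta Observed executed physical series, degrees
#'   (length = number of adaptation trials).
#' @param spec The [perturbation_spec()] the series was collected under.
#' @param relation The participant's `baseline_relation`.
#' @param target_dir Displayed target direction, degrees.
#' @param target_distance Movement distance, cm.
#' @param grid Named list of candidate values for `eta_tmd`, `eta_sta` and
#'   `retention_loss`; the full cross-product is searched.
#' @return An object of class `learner_fit`: best-fitting parameters, the
#'   objective over the grid, and the fitted deterministic series.
#' @export
fit_learner <- function(exec_tmd, exec_sta, spec,
                        relation = linear_relation(),
                        target_dir = 0, target_distance = 10,
                        grid = list(eta_tmd = seq(0.02, 0.6, by = 0.02),
                                    eta_sta = seq(0, 0.6, by = 0.05),
                                    retention_loss = c(0, 0.05, 0.1))) {
  n <- length(exec_tmd)
  stopifnot(n >= 2, length(exec_sta) == n,
            all(c("eta_tmd", "eta_sta", "retention_loss") %in% names(grid)))
  cand <- expand.grid(eta_tmd = grid$eta_tmd, eta_sta = grid$eta_sta,
                      retention_loss = grid$retention_loss,
                      KEEP.OUT.ATTRS = FALSE)
  sim <- simulate_state_grid(cand$eta_tmd, cand$eta_sta,
                             cand$retention_loss, n, relation, spec,
                             target_dir, target_distance)
  sse <- colSums((sim$tmd - exec_tmd)^2) + colSums((sim$sta - exec_sta)^2)
  best <- which.min(sse)
  if (diff(range(sse)) < 1e-12)
    warning("objective is flat over the search grid; parameters are not identified")
  structure(
    list(par = c(eta_tmd = cand$eta_tmd[best],
                 eta_sta = cand$eta_sta[best],
                 retention_loss = cand$retention_loss[best]),
         sse = sse[best],
         grid = cbind(cand, sse = sse),
         fitted = data.frame(trial = seq_len(n),
                             tmd = sim$tmd[, best], sta = sim$sta[, best]),
         observed = data.frame(trial = seq_len(n),
                               tmd = exec_tmd, sta = exec_sta)),
    class = "learner_fit"
  )
}

#' @export
coef.learner_fit <- function(object, ...) object$par

#' @export
print.learner_fit <- function(x, ...) {
  cat(sprintf(
    "Learner fit over %d grid points: eta_tmd %.3f, eta_sta %.3f, retention loss %.3f (SSE %.2f deg^2)\n",
    nrow(x$grid), x$par[["eta_tmd"]], x$par[["eta_sta"]],
    x$par[["retention_loss"]], x$sse))
  invisible(x)
}

#' @export
residuals.learner_fit <- function(object, ...) {
  data.frame(trial = object$observed$trial,
             tmd = object$observed$tmd - object$fitted$tmd,
             sta = object$observed$sta - object$fitted$sta)
}

#' @export
plot.learner_fit <- function(x, ...) {
  graphics::plot(x$observed$trial, x$observed$tmd, pch = 16,
                 col = grDevices::grey(0.7),
                 xlab = "adaptation trial", ylab = "physical TMD (deg)", ...)
  graphics::lines(x$fitted$trial, x$fitted$tmd, col = "red", lwd = 2)
  invisible(x)
}
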