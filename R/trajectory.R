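#' Minimum-jerk displacement profile
#'
#' Straight-line reach of `distance` cm over `duration` s following the
#' quintic r(tau) = d (10 tau^3 - 15 tau^4 + 6 tau^5), tau = t/duration,
#' whose speed is bell-shaped with a single peak of 1.875 d/duration at
#' tau = 1/2.
#'
#' @param distance Movement amplitude d, cm.
#' @param duration Movement time, s.
#' @param dt Sample interval, s (default 0.001, a 1 kHz recording).
#' @return A list with numeric vectors `time` (s), `displacement` (cm) and
#'   `speed` (cm/s), all of length `duration/dt + 1`.
#' @export
min_jerk_profile <- function(distance = 10, duration = 0.5, dt = 0.001) {
  stopifnot(distance > 0, duration > 0, dt > 0, dt < duration)
  time <- seq(0, duration, by = dt)
  tau <- time / duration
  displacement <- distance * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  speed <- distance / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  list(time = time, displacement = displacement, speed = speed)
}

#' Peak tip speed of the minimum-jerk profile
#'
#' Closed form 1.875 d/duration (the quartic speed polynomial peaks at
#' tau = 1/2).
#'
#' @inheritParams min_jerk_profile
#' @param units `"cm_s"` or `"mm_s"`.
#' @return Peak speed.
#' @export
min_jerk_peak_speed <- function(distance = 10, duration = 0.5,
                                units = c("cm_s", "mm_s")) {
  units <- match.arg(units)
  v <- 1.875 * distance / duration
  if (units == "mm_s") v * 10 else v
}

#' Displacement-proportional tilt ramp
#'
#' Within-trial stick tilt grows in proportion to tip displacement,
#' reaching `final_tilt` when the displacement reaches `distance`.
#'
#' @param displacement Non-decreasing displacement series, cm.
#' @param final_tilt Tilt at full displacement, degrees.
#' @param distance Full movement distance, cm.
#' @return Tilt series in degrees.
#' @export
ramped_tilt <- function(displacement, final_tilt, distance = 10) {
  stopifnot(is.numeric(displacement), distance > 0)
  if (any(diff(displacement) < -1e-9))
    stop("displacement series must be non-decreasing")
  final_tilt * displacement / distance
}

#' Peak-speed feedback category
#'
#' Reproduces the apparatus feedback: peak tip speeds below 300 mm/s are
#' flagged `slow`, above 450 mm/s `fast`, otherwise `ok`.
#'
#' @param peak_speed Peak tip speed, mm/s; vectorized.
#' @return Character vector in `{"slow", "ok", "fast"}`.
#' @export
speed_feedback <- function(peak_speed) {
  stopifnot(is.numeric(peak_speed), all(peak_speed >= 0))
  out <- rep("ok", length(peak_speed))
  out[peak_speed < 300] <- "slow"
  out[peak_speed > 450] <- "fast"
  out
}

#' Synthesize one trial of stick kinematics
#'
#' Builds the full sampled kinematics of a reach: the tip follows a
#' minimum-jerk straight path along the intended tip-movement direction
#' (plus optional trial-level direction noise), the stick tilt ramps in
#' proportion to displacement up to the intended final stick-tilt angle
#' (plus optional tilt noise), and the hand paths are derived from the tip
#' and tilt at every sample through the stick geometry.
#'
#' @param tmd Intended tip-movement direction, degrees (physical frame).
#' @param sta Intended stick-tilt angle at movement offset, degrees.
#' @param distance Movement distance, cm (default 10).
#' @param geom A [stick_geometry()].
#' @param duration Movement time, s (default 0.5).
#' @param dt Sample interval, s (default 0.001).
#' @param start Start position of the tip, cm (default origin).
#' @param initial_tilt Stick tilt at movement onset, degrees (default 0,
#'   horizontal).
#' @param noise_sd Length-2 numeric: trial-level SD of additive motor noise
#'   on (tmd, sta) in degrees (default `c(0, 0)`).
#' @param seed Optional integer; when given the noise draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return An object of class `trial_kinematics`: list with `time` (s),
#'   `tip`, `left`, `right` (n x 2 matrices, cm), `tilt` (deg), and the
#'   realized `tmd`/`sta` after noise.
#' @export
synthesize_trial <- function(tmd, sta, distance = 10, geom = stick_geometry(),
                             duration = 0.5, dt = 0.001,
                             start = c(0, 0), initial_tilt = 0,
                             noise_sd = c(0, 0), seed = NULL) {
  stopifnot(length(noise_sd) == 2, all(noise_sd >= 0))
  if (any(noise_sd > 0)) {
    eps <- local_rnorm(2, sd = noise_sd, seed = seed)
    tmd <- tmd + eps[1]
    sta <- sta + eps[2]
  }
  prof <- min_jerk_profile(distance, duration, dt)
  u <- c(cos(deg2rad(tmd)), sin(deg2rad(tmd)))
  tip <- cbind(start[1] + prof$displacement * u[1],
               start[2] + prof$displacement * u[2])
  tilt <- initial_tilt + ramped_tilt(prof$displacement, sta, distance)
  th <- deg2rad(tilt)
  dir_x <- cos(th); dir_y <- sin(th)
  left <- cbind(tip[, 1] - geom$left_to_tip * dir_x,
                tip[, 2] - geom$left_to_tip * dir_y)
  right <- cbind(tip[, 1] - geom$right_to_tip * dir_x,
                 tip[, 2] - geom$right_to_tip * dir_y)
  structure(
    list(time = prof$time, tip = tip, left = left, right = right,
         tilt = tilt, tmd = tmd, sta = sta, distance = distance,
         start = as.numeric(start), initial_tilt = initial_tilt, dt = dt),
    class = "trial_kinematics"
  )
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf(
    "Trial kinematics: %d samples at %g s, TMD %+.2f deg, final STA %+.2f deg, %.1f cm\n",
    length(x$time), x$dt, x$tmd, x$sta, x$distance))
  invisible(x)
}

# draw n normals without disturbing the caller's RNG stream when seeded
local_rnorm <- function(n, sd, seed = NULL) {
  if (is.null(seed)) return(stats::rnorm(n, sd = sd))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Long-format trial table from kinematics
#'
#' @param kin A [synthesize_trial()] result.
#' @param trial Trial number recorded in the table.
#' @return A data.frame with columns `trial`, `t_s`, `effector`
#'   (`tip`/`left`/`right`), `x_cm`, `y_cm`, `tilt_deg`.
#' @export
as_trial_table <- function(kin, trial = 1L) {
  stopifnot(inherits(kin, "trial_kinematics"))
  n <- length(kin$time)
  data.frame(
    trial = rep(as.integer(trial), 3 * n),
    t_s = rep(kin$time, 3),
    effector = rep(c("tip", "left", "right"), each = n),
    x_cm = c(kin$tip[, 1], kin$left[, 1], kin$right[, 1]),
    y_cm = c(kin$tip[, 2], kin$left[, 2], kin$right[, 2]),
    tilt_deg = rep(kin$tilt, 3)
  )
}

#' Write/read trial tables in the package CSV dialect
#'
#' UTF-8 CSV with a mandatory header and columns `trial`, `t_s`, `effector`,
#' `x_cm`, `y_cm`, `tilt_deg`.
#'
#' @param tab A trial table (one or more trials row-bound together).
#' @param file Path to the CSV file.
#' @return `write_trial_csv` returns `file` invisibly; `read_trial_csv`
#'   returns the validated data.frame.
#' @export
write_trial_csv <- function(tab, file) {
  stopifnot(is.data.frame(tab))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trial", "t_s", "effector", "x_cm", "y_cm", "tilt_deg")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("trial CSV is missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(tab$effector), c("tip", "left", "right"))
  if (length(bad))
    stop("trial CSV has unknown effector labels: ", paste(bad, collapse = ", "))
  tab
}

#' Rebuild trial kinematics from a long-format table
#'
#' Inverse of [as_trial_table()] for a single trial.
#'
#' @param tab Trial table data.frame.
#' @param trial Which trial number to extract.
#' @return A `trial_kinematics` list (realized tmd/sta fields are not
#'   recoverable from the table and are set to `NA`).
#' @export
kinematics_from_table <- function(tab, trial = tab$trial[1]) {
  stopifnot(is.data.frame(tab))
  tab <- tab[tab$trial == trial, , drop = FALSE]
  if (nrow(tab) == 0) stop("trial ", trial, " not present in table")
  pick <- function(eff) {
    sub <- tab[tab$effector == eff, , drop = FALSE]
    sub[order(sub$t_s), , drop = FALSE]
  }
  tip <- pick("tip"); left <- pick("left"); right <- pick("right")
  if (!(nrow(tip) == nrow(left) && nrow(tip) == nrow(right)))
    stop("effector series have unequal lengths for trial ", trial)
  structure(
    list(time = tip$t_s,
         tip = cbind(tip$x_cm, tip$y_cm),
         left = cbind(left$x_cm, left$y_cm),
         right = cbind(right$x_cm, right$y_cm),
         tilt = tip$tilt_deg,
         tmd = NA_real_, sta = NA_real_,
         distance = NA_real_,
         start = c(tip$x_cm[1], tip$y_cm[1]),
         initial_tilt = tip$tilt_deg[1],
         dt = if (nrow(tip) > 1) tip$t_s[2] - tip$t_s[1] else NA_real_),
    class = "trial_kinematics"
  )
}
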