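#' Visual perturbation specification
#'
#' Defines the visual remapping applied during the adaptation phase.
#' Two independent components exist:
#' \itemize{
#'   \item A tip rotation about the starting position (end-effector relevant).
#'     `gradual` ramps by `tip_step` degrees per trial up to `tip_max`
#'     (1 deg/trial to 30 deg in the study protocol); `abrupt` applies
#'     `tip_max` from the first trial; `none` leaves the tip unperturbed.
#'   \item A stick-tilt rotation about the tip (end-effector irrelevant),
#'     growing in proportion to the tip's displacement from the start at
#'     `tilt_gain` deg/cm (0.6 deg/cm, i.e. 6 deg at the 10 cm target),
#'     signed by `tilt_sign` (+1 CCW, -1 CW, 0 off).
#' }
#'
#' @param tip_mode One of `"none"`, `"gradual"`, `"abrupt"`.
#' @param tip_max Tip rotation cap in degrees, CCW positive (default 30).
#' @param tip_step Per-trial increment in degrees for `gradual` (default 1).
#' @param tilt_gain Tilt rotation per cm of tip displacement, deg/cm
#'   (default 0.6, non-negative).
#' @param tilt_sign -1, 0 or +1 (+1 = CCW).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(tip_mode = c("none", "gradual", "abrupt"),
                              tip_max = 30, tip_step = 1,
                              tilt_gain = 0.6, tilt_sign = 0) {
  tip_mode <- match.arg(tip_mode)
  stopifnot(is.numeric(tip_max), length(tip_max) == 1, is.finite(tip_max),
            is.numeric(tip_step), length(tip_step) == 1, is.finite(tip_step),
            is.numeric(tilt_gain), length(tilt_gain) == 1, tilt_gain >= 0)
  if (tip_mode == "gradual" && tip_step <= 0)
    stop("'tip_step' must be positive when tip_mode = 'gradual'")
  if (!tilt_sign %in% c(-1, 0, 1))
    stop("'tilt_sign' must be -1, 0 or +1")
  structure(
    list(tip_mode = tip_mode, tip_max = tip_max, tip_step = tip_step,
         tilt_gain = tilt_gain, tilt_sign = tilt_sign),
    class = "perturbation_spec"
  )
}

#' @export
print.perturbation_spec <- function(x, ...) {
  tip <- switch(x$tip_mode,
    none = "tip rotation off",
    gradual = sprintf("tip rotation gradual: %+g deg/trial up to %+g deg",
                      x$tip_step, x$tip_max),
    abrupt = sprintf("tip rotation abrupt: %+g deg", x$tip_max))
  tilt <- if (x$tilt_sign == 0) "tilt rotation off" else
    sprintf("tilt rotation %s: %g deg/cm",
            if (x$tilt_sign > 0) "CCW" else "CW", x$tilt_gain)
  cat("Visual perturbation:", tip, "|", tilt, "\n")
  invisible(x)
}

#' Tip-rotation magnitude on a given adaptation trial
#'
#' @param trial 1-based trial index within the adaptation phase; vectorized.
#' @param spec A [perturbation_spec()].
#' @return Rotation in degrees (CCW positive).
#' @examples
#' spec <- perturbation_spec("gradual")
#' tip_rotation_at_trial(c(1, 30, 240), spec)  # 1 30 30
#' @export
tip_rotation_at_trial <- function(trial, spec) {
  stopifnot(inherits(spec, "perturbation_spec"), is.numeric(trial))
  if (any(trial < 1)) stop("trial indices are 1-based within the adaptation phase")
  switch(spec$tip_mode,
    none = rep(0, length(trial)),
    gradual = pmin(trial * spec$tip_step, spec$tip_max),
    abrupt = rep(spec$tip_max, length(trial)))
}

#' Tilt-rotation magnitude at a given tip displacement
#'
#' Linear in displacement with no cap; the movement ends at the target
#' distance, where the default gain yields the full 6 degrees.
#'
#' @param r Tip displacement from the start in cm (non-negative); vectorized.
#' @param spec A [perturbation_spec()].
#' @return Rotation in degrees, signed by `tilt_sign`.
#' @export
tilt_perturbation_at_displacement <- function(r, spec) {
  stopifnot(inherits(spec, "perturbation_spec"), is.numeric(r))
  if (any(r < 0)) stop("displacement must be non-negative")
  spec$tilt_sign * spec$tilt_gain * r
}

#' Apply the visual perturbation to a physical stick pose
#'
#' The displayed (visual) pose rotates the physical tip about the trial's
#' start position by the tip rotation scheduled for `trial`, and adds the
#' displacement-proportional tilt rotation to the physical tilt.
#' With an all-off spec the map is the identity.
#'
#' @param pose Physical [stick_pose()].
#' @param start Length-2 start position of the trial, cm.
#' @param trial 1-based adaptation trial index.
#' @param spec A [perturbation_spec()].
#' @return The visual [stick_pose()].
#' @export
apply_visual_map <- function(pose, start, trial, spec) {
  stopifnot(inherits(pose, "stick_pose"), is.numeric(start), length(start) == 2)
  rho <- deg2rad(tip_rotation_at_trial(trial, spec))
  v <- pose$tip - start
  rot <- c(cos(rho) * v[1] - sin(rho) * v[2],
           sin(rho) * v[1] + cos(rho) * v[2])
  r <- sqrt(sum(v^2))
  stick_pose(tip = start + rot,
             tilt = pose$tilt + tilt_perturbation_at_displacement(r, spec))
}

#' Invert the visual perturbation map
#'
#' Recovers the physical pose from a displayed pose; exact inverse of
#' [apply_visual_map()] for the same trial and spec (the tip rotation is an
#' isometry about the start, so the displacement driving the tilt term is
#' frame-invariant).
#'
#' @param pose Visual [stick_pose()].
#' @inheritParams apply_visual_map
#' @return The physical [stick_pose()].
#' @export
invert_visual_map <- function(pose, start, trial, spec) {
  stopifnot(inherits(pose, "stick_pose"), is.numeric(start), length(start) == 2)
  rho <- -deg2rad(tip_rotation_at_trial(trial, spec))
  v <- pose$tip - start
  rot <- c(cos(rho) * v[1] - sin(rho) * v[2],
           sin(rho) * v[1] + cos(rho) * v[2])
  r <- sqrt(sum(v^2))
  stick_pose(tip = start + rot,
             tilt = pose$tilt - tilt_perturbation_at_displacement(r, spec))
}

#' A point on the TMD-STA plane
#'
#' A (tip-movement direction, stick-tilt angle) pair tagged with the frame
#' it lives in: `physical` (what the hands do) or `visual` (what is
#' displayed). Cross-frame arithmetic is rejected by consumers.
#'
#' @param tmd Tip-movement direction, degrees CCW from horizontal.
#' @param sta Stick-tilt angle, degrees CCW relative to the initial
#'   horizontal state.
#' @param frame `"physical"` or `"visual"`.
#' @return An object of class `plane_state`.
#' @export
plane_state <- function(tmd, sta, frame = c("physical", "visual")) {
  frame <- match.arg(frame)
  stopifnot(is.numeric(tmd), length(tmd) == 1, is.finite(tmd),
            is.numeric(sta), length(sta) == 1, is.finite(sta))
  structure(list(tmd = tmd, sta = sta, frame = frame), class = "plane_state")
}

#' @export
print.plane_state <- function(x, ...) {
  cat(sprintf("(%s) TMD %+.3f deg, STA %+.3f deg\n", x$frame, x$tmd, x$sta))
  invisible(x)
}

#' Map a physical plane state to its visual counterpart
#'
#' On the TMD-STA plane the tip rotation is a horizontal shift by the
#' scheduled rotation and the tilt rotation a vertical shift by
#' `tilt_sign * tilt_gain * displacement`. By default the state is evaluated
#' at end of movement, where the displacement equals the target distance;
#' pass the peak-velocity displacement for mid-movement read-outs.
#'
#' @param state Physical [plane_state()].
#' @param trial 1-based adaptation trial index.
#' @param spec A [perturbation_spec()].
#' @param displacement Tip displacement (cm) at which the state is evaluated
#'   (default 10, the target distance).
#' @return A visual [plane_state()].
#' @export
plane_map <- function(state, trial, spec, displacement = 10) {
  stopifnot(inherits(state, "plane_state"))
  if (state$frame != "physical")
    stop("plane_map expects a physical-frame state")
  plane_state(
    tmd = state$tmd + tip_rotation_at_trial(trial, spec),
    sta = state$sta + tilt_perturbation_at_displacement(displacement, spec),
    frame = "visual"
  )
}

#' Read/write a perturbation spec as YAML
#'
#' The on-disk keys are `tip_mode`, `tip_max_deg`, `tip_step_deg`,
#' `tilt_gain_deg_per_cm`, `tilt_sign`.
#'
#' @param spec A [perturbation_spec()].
#' @param file Path to a YAML file.
#' @return `write_perturbation_yaml` returns `file` invisibly;
#'   `read_perturbation_yaml` returns a [perturbation_spec()].
#' @export
write_perturbation_yaml <- function(spec, file) {
  stopifnot(inherits(spec, "perturbation_spec"))
  yaml::write_yaml(list(
    tip_mode = spec$tip_mode,
    tip_max_deg = spec$tip_max,
    tip_step_deg = spec$tip_step,
    tilt_gain_deg_per_cm = spec$tilt_gain,
    tilt_sign = spec$tilt_sign
  ), file)
  invisible(file)
}

#' @rdname write_perturbation_yaml
#' @export
read_perturbation_yaml <- function(file) {
  y <- yaml::read_yaml(file)
  need <- c("tip_mode", "tip_max_deg", "tip_step_deg",
            "tilt_gain_deg_per_cm", "tilt_sign")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("perturbation YAML is missing keys: ", paste(missing, collapse = ", "))
  perturbation_spec(tip_mode = y$tip_mode, tip_max = y$tip_max_deg,
                    tip_step = y$tip_step_deg,
                    tilt_gain = y$tilt_gain_deg_per_cm,
                    tilt_sign = y$tilt_sign)
}
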