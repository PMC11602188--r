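#' Stick geometry
#'
#' Describes the rigid virtual stick held with both hands. The tip used to
#' reach targets is the right tip; the left hand holds the left end of the
#' stick and the right hand grips it `grip_separation` cm further along, so
#' the hand-to-tip lever arms are `left_to_tip` (L) and
#' `right_to_tip = left_to_tip - grip_separation` (R).
#'
#' @param left_to_tip Distance from the left hand to the tip, cm (default 40,
#'   the full stick length).
#' @param grip_separation Distance between the hands along the stick, cm
#'   (default 15).
#' @return An object of class `stick_geometry` with elements `left_to_tip`,
#'   `grip_separation` and `right_to_tip`.
#' @examples
#' geom <- stick_geometry()
#' geom$right_to_tip  # 25
#' @export
stick_geometry <- function(left_to_tip = 40, grip_separation = 15) {
  stopifnot(is.numeric(left_to_tip), length(left_to_tip) == 1,
            is.numeric(grip_separation), length(grip_separation) == 1)
  if (!is.finite(left_to_tip) || left_to_tip <= 0)
    stop("'left_to_tip' must be a positive length (cm)")
  if (!is.finite(grip_separation) || grip_separation <= 0)
    stop("'grip_separation' must be a positive length (cm)")
  if (grip_separation >= left_to_tip)
    stop("'grip_separation' must be smaller than 'left_to_tip'")
  structure(
    list(left_to_tip = left_to_tip,
         grip_separation = grip_separation,
         right_to_tip = left_to_tip - grip_separation),
    class = "stick_geometry"
  )
}

#' @export
print.stick_geometry <- function(x, ...) {
  cat("Stick geometry (cm): left hand to tip", x$left_to_tip,
      "| right hand to tip", x$right_to_tip,
      "| grip separation", x$grip_separation, "\n")
  invisible(x)
}

#' Stick pose
#'
#' The physical state of the stick at one instant: tip position and
#' stick-tilt angle. Tilt is measured counter-clockwise from horizontal in
#' degrees; 0 means the stick lies along +x with the tip at its right end.
#'
#' @param tip Numeric length-2 vector, tip position in cm.
#' @param tilt Stick-tilt angle in degrees, CCW positive; normalized into
#'   (-180, 180].
#' @return An object of class `stick_pose`.
#' @export
stick_pose <- function(tip = c(0, 0), tilt = 0) {
  stopifnot(is.numeric(tip), length(tip) == 2, all(is.finite(tip)),
            is.numeric(tilt), length(tilt) == 1, is.finite(tilt))
  structure(list(tip = as.numeric(tip), tilt = wrap_angle(tilt)),
            class = "stick_pose")
}

#' @export
print.stick_pose <- function(x, ...) {
  cat(sprintf("Stick pose: tip (%.3f, %.3f) cm, tilt %.3f deg\n",
              x$tip[1], x$tip[2], x$tilt))
  invisible(x)
}

# map an angle in degrees into (-180, 180]
wrap_angle <- function(deg) {
  w <- deg %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

#' Hand positions from a stick pose
#'
#' Inverse of the display mapping: given the tip position and tilt, place the
#' two hands along the stick behind the tip.
#'
#' @param pose A [stick_pose()].
#' @param geom A [stick_geometry()].
#' @return A list with numeric length-2 elements `left` and `right` (cm).
#' @export
hands_from_pose <- function(pose, geom = stick_geometry()) {
  stopifnot(inherits(pose, "stick_pose"), inherits(geom, "stick_geometry"))
  th <- deg2rad(pose$tilt)
  u <- c(cos(th), sin(th))
  list(left = pose$tip - geom$left_to_tip * u,
       right = pose$tip - geom$right_to_tip * u)
}

#' Stick pose from hand positions
#'
#' Forward display mapping: the stick direction is the unit vector from the
#' left hand to the right hand, and the tip sits `left_to_tip` cm from the
#' left hand along it. The hands must be `grip_separation` cm apart (the
#' apparatus enforces this; modeled as a rigid link).
#'
#' @param left,right Numeric length-2 hand positions in cm.
#' @param geom A [stick_geometry()].
#' @param tol Tolerated violation of the grip separation, cm.
#' @return A [stick_pose()].
#' @export
pose_from_hands <- function(left, right, geom = stick_geometry(), tol = 1e-3) {
  stopifnot(is.numeric(left), length(left) == 2,
            is.numeric(right), length(right) == 2,
            inherits(geom, "stick_geometry"))
  v <- right - left
  sep <- sqrt(sum(v^2))
  if (abs(sep - geom$grip_separation) > tol)
    stop(sprintf(
      "hand separation %.6f cm violates grip separation %.6f cm (tol %g cm)",
      sep, geom$grip_separation, tol))
  tilt <- rad2deg(atan2(v[2], v[1]))
  tip <- left + geom$left_to_tip * v / sep
  stick_pose(tip = tip, tilt = tilt)
}

#' Per-hand displacement between two poses
#'
#' Euclidean distance each hand travels between a start and an end pose.
#' Their sum is the hand-path cost minimized by the baseline strategy; see
#' [hand_path_cost()].
#'
#' @param start,end [stick_pose()] objects.
#' @param geom A [stick_geometry()].
#' @return Named numeric vector `c(left = , right = )` in cm.
#' @export
hand_displacements <- function(start, end, geom = stick_geometry()) {
  h0 <- hands_from_pose(start, geom)
  h1 <- hands_from_pose(end, geom)
  c(left = sqrt(sum((h1$left - h0$left)^2)),
    right = sqrt(sum((h1$right - h0$right)^2)))
}
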