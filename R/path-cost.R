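#' Total hand-path cost of reaching a target with a given stick tilt
#'
#' The cost is the summed Euclidean distance the two hands travel between
#' movement onset and offset when the tip moves `distance` cm in direction
#' `direction` while the stick tilt changes from 0 to `tilt`:
#' \deqn{f(\phi,\theta)=\sqrt{(d\cos\phi-L\cos\theta+L)^2+(d\sin\phi-L\sin\theta)^2}
#'   +\sqrt{(d\cos\phi-R\cos\theta+R)^2+(d\sin\phi-R\sin\theta)^2}}
#' where L and R are the hand-to-tip distances. At `tilt = 0` both hands
#' translate in parallel and the cost is `2 * distance` regardless of
#' direction; tilting the stick toward the target reduces it.
#'
#' @param direction Target direction \eqn{\phi} in degrees (CCW from
#'   horizontal). Vectorized.
#' @param tilt Stick-tilt angle \eqn{\theta} at movement offset, degrees.
#'   Vectorized.
#' @param distance Target distance d in cm (default 10).
#' @param geom A [stick_geometry()].
#' @return Cost in cm, recycled over `direction`/`tilt`.
#' @examples
#' hand_path_cost(20, 0)   # 20: parallel translation costs 2 d everywhere
#' @export
hand_path_cost <- function(direction, tilt, distance = 10,
                           geom = stick_geometry()) {
  stopifnot(is.numeric(direction), is.numeric(tilt),
            is.numeric(distance), distance > 0,
            inherits(geom, "stick_geometry"))
  phi <- deg2rad(direction)
  th <- deg2rad(tilt)
  L <- geom$left_to_tip
  R <- geom$right_to_tip
  d <- distance
  sqrt((d * cos(phi) - L * cos(th) + L)^2 + (d * sin(phi) - L * sin(th))^2) +
    sqrt((d * cos(phi) - R * cos(th) + R)^2 + (d * sin(phi) - R * sin(th))^2)
}

#' Cost-minimizing stick tilt for one target
#'
#' Minimizes [hand_path_cost()] over the tilt angle by bracketed scalar
#' search on \eqn{[-89, 89]} degrees, then polishes the stationary point
#' (zero of the central-difference cost gradient) with a root bracket around
#' the minimizer. The parallel-translation cost (`tilt = 0`) is returned
#' alongside for comparison.
#'
#' @inheritParams hand_path_cost
#' @param direction Target direction in degrees; must satisfy
#'   `abs(direction) < 90`.
#' @return An object of class `stick_optimum`: list with `direction`,
#'   `distance`, `optimal_tilt` (deg), `minimum_cost` (cm), `parallel_cost`
#'   (cm) and `gradient` (cm/deg at the optimum).
#' @export
optimal_tilt <- function(direction, distance = 10, geom = stick_geometry()) {
  stopifnot(length(direction) == 1, is.finite(direction))
  if (abs(direction) >= 90)
    stop("'direction' must lie strictly inside (-90, 90) degrees")
  f <- function(th) hand_path_cost(direction, th, distance, geom)
  opt <- stats::optimize(f, interval = c(-89, 89), tol = 1e-10)
  theta <- opt$minimum
  h <- 1e-4
  grad <- function(th) (f(th + h) - f(th - h)) / (2 * h)
  lo <- max(theta - 0.5, -89)
  hi <- min(theta + 0.5, 89)
  if (grad(lo) < 0 && grad(hi) > 0) {
    root <- stats::uniroot(grad, c(lo, hi), tol = 1e-13)
    theta <- root$root
  }
  g <- grad(theta)
  if (abs(g) > 1e-8)
    stop(sprintf(
      "tilt optimizer failed the stationarity check: |df/dtheta| = %.3e cm/deg at theta = %.6f deg",
      abs(g), theta))
  if (abs(theta) < 1e-9) theta <- 0
  structure(
    list(direction = direction, distance = distance,
         optimal_tilt = theta, minimum_cost = f(theta),
         parallel_cost = hand_path_cost(direction, 0, distance, geom),
         gradient = g),
    class = "stick_optimum"
  )
}

#' @export
print.stick_optimum <- function(x, ...) {
  cat(sprintf(
    "Target %+.1f deg, %.1f cm: optimal tilt %+.4f deg, cost %.4f cm (parallel %.4f cm)\n",
    x$direction, x$distance, x$optimal_tilt, x$minimum_cost, x$parallel_cost))
  invisible(x)
}

#' Predicted baseline TMD-STA relationship from the cost model
#'
#' Evaluates [optimal_tilt()] across a set of target directions, giving the
#' model-side counterpart of the monotone baseline relationship between
#' tip-movement direction and stick-tilt angle.
#'
#' @param directions Numeric vector of target directions in degrees
#'   (default the nine protocol targets 0, +-10, +-20, +-30, +-40).
#' @inheritParams hand_path_cost
#' @return A data.frame with columns `direction_deg`, `optimal_tilt_deg`,
#'   `min_cost_cm`, `parallel_cost_cm`, ordered by direction.
#' @export
predicted_relation <- function(directions = protocol_targets(),
                               distance = 10, geom = stick_geometry()) {
  stopifnot(length(directions) >= 1)
  directions <- sort(directions)
  res <- lapply(directions, optimal_tilt, distance = distance, geom = geom)
  data.frame(
    direction_deg = directions,
    optimal_tilt_deg = vapply(res, `[[`, numeric(1), "optimal_tilt"),
    min_cost_cm = vapply(res, `[[`, numeric(1), "minimum_cost"),
    parallel_cost_cm = vapply(res, `[[`, numeric(1), "parallel_cost")
  )
}

#' The nine baseline target directions
#'
#' @return Numeric vector `c(-40, -30, ..., 40)` degrees.
#' @export
protocol_targets <- function() seq(-40, 40, by = 10)

#' Baseline-optimum prediction table
#'
#' Convenience wrapper around [predicted_relation()] that optionally writes
#' the table as CSV.
#'
#' @inheritParams predicted_relation
#' @param file Optional path; when given the table is written as CSV.
#' @return The prediction data.frame, invisibly when `file` is given.
#' @export
baseline_optimum_table <- function(directions = protocol_targets(),
                                   distance = 10, geom = stick_geometry(),
                                   file = NULL) {
  tab <- predicted_relation(directions, distance, geom)
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
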