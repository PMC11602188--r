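#' Fit the baseline TMD-STA relationship
#'
#' Estimates the monotone mapping g from tip-movement direction to
#' stick-tilt angle that characterizes a participant's baseline reaching.
#' Trials are binned by their nominal target direction; each bin contributes
#' a knot at its mean (TMD, STA). Monotonicity of the STA knots is enforced
#' by weighted isotonic pooling (pool-adjacent-violators, weights = bin
#' counts), so the slope used by the learner is non-negative everywhere.
#' Between knots the relation is piecewise linear; beyond the outermost
#' knots it extrapolates with the nearest segment's slope.
#'
#' @param data A data.frame with numeric columns `target` (nominal target
#'   direction, deg), `tmd` and `sta` (measured angles, deg). At least two
#'   distinct targets are required.
#' @return An object of class `baseline_relation` with a `knots` data.frame
#'   (`tmd`, `sta`, `n`).
#' @seealso [predict.baseline_relation()], [relation_slope()],
#'   [linear_relation()], [relation_from_optimum()]
#' @export
fit_baseline_relation <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("target", "tmd", "sta") %in% names(data)))
  data <- data[stats::complete.cases(data[c("target", "tmd", "sta")]), ]
  targets <- sort(unique(data$target))
  if (length(targets) < 2)
    stop("need baseline trials from at least 2 distinct targets")
  tmd <- vapply(targets, function(tg) mean(data$tmd[data$target == tg]),
                numeric(1))
  sta <- vapply(targets, function(tg) mean(data$sta[data$target == tg]),
                numeric(1))
  n <- vapply(targets, function(tg) sum(data$target == tg), numeric(1))
  ord <- order(tmd)
  tmd <- tmd[ord]; sta <- sta[ord]; n <- n[ord]
  if (any(diff(tmd) <= 0))
    stop("bin mean TMDs are not strictly increasing; targets are not separable")
  sta <- pava(sta, n)
  new_baseline_relation(data.frame(tmd = tmd, sta = sta, n = n))
}

new_baseline_relation <- function(knots) {
  stopifnot(is.data.frame(knots), nrow(knots) >= 2,
            all(diff(knots$tmd) > 0), all(diff(knots$sta) > -1e-12))
  structure(list(knots = knots), class = "baseline_relation")
}

# weighted pool-adjacent-violators: least-squares isotonic fit of y with
# weights w (base isoreg is unweighted, hence unusable for pooled bins)
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; len[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      tot <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) / tot
      wt[k - 1L] <- tot
      len[k - 1L] <- len[k - 1L] + len[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], len[seq_len(k)])
}

#' A linear baseline relation
#'
#' Convenience constructor for g(tmd) = intercept + slope * tmd, represented
#' by two knots spanning `range`.
#'
#' @param slope STA change per degree of TMD (non-negative).
#' @param intercept STA at TMD = 0, degrees.
#' @param range TMD span covered by the knots, degrees.
#' @return A `baseline_relation`.
#' @export
linear_relation <- function(slope = 0.2, intercept = 0, range = c(-50, 50)) {
  stopifnot(slope >= 0, length(range) == 2, range[1] < range[2])
  new_baseline_relation(data.frame(
    tmd = range, sta = intercept + slope * range, n = c(1, 1)))
}

#' Baseline relation predicted by the hand-path-cost model
#'
#' Knots are the cost-optimal tilts of [predicted_relation()] at the given
#' target directions.
#'
#' @inheritParams predicted_relation
#' @return A `baseline_relation`.
#' @export
relation_from_optimum <- function(directions = protocol_targets(),
                                  distance = 10, geom = stick_geometry()) {
  tab <- predicted_relation(directions, distance, geom)
  new_baseline_relation(data.frame(
    tmd = tab$direction_deg, sta = tab$optimal_tilt_deg,
    n = rep(1, nrow(tab))))
}

#' Evaluate the baseline relation
#'
#' Piecewise-linear interpolation over the knots with linear extrapolation
#' using the nearest segment's slope.
#'
#' @param object A `baseline_relation`.
#' @param tmd Tip-movement directions (deg) at which to evaluate; vectorized.
#' @param ... Unused.
#' @return Predicted STA values, degrees.
#' @export
predict.baseline_relation <- function(object, tmd, ...) {
  kt <- object$knots$tmd
  ks <- object$knots$sta
  m <- length(kt)
  seg <- findInterval(tmd, kt, all.inside = TRUE)  # 1..m-1
  sl <- (ks[seg + 1] - ks[seg]) / (kt[seg + 1] - kt[seg])
  ks[seg] + sl * (tmd - kt[seg])
}

#' Local slope of the baseline relation
#'
#' Slope of the active segment; exactly at an interior knot, the mean of the
#' two adjacent segment slopes.
#'
#' @param relation A `baseline_relation`.
#' @param tmd Evaluation points, degrees; vectorized.
#' @return Slope values (deg per deg, non-negative).
#' @export
relation_slope <- function(relation, tmd) {
  stopifnot(inherits(relation, "baseline_relation"))
  kt <- relation$knots$tmd
  ks <- relation$knots$sta
  m <- length(kt)
  segslope <- (ks[-1] - ks[-m]) / (kt[-1] - kt[-m])
  seg <- findInterval(tmd, kt, all.inside = TRUE)
  out <- segslope[seg]
  interior <- match(tmd, kt[-c(1, m)])
  at_knot <- !is.na(interior)
  if (any(at_knot)) {
    k <- interior[at_knot] + 1L  # knot index in 2..m-1
    out[at_knot] <- (segslope[k - 1L] + segslope[k]) / 2
  }
  out
}

#' @export
coef.baseline_relation <- function(object, ...) {
  kt <- object$knots$tmd
  ks <- object$knots$sta
  # overall least-squares slope through the knots, a scalar summary used to
  # compare participants
  c(slope = sum((kt - mean(kt)) * (ks - mean(ks))) / sum((kt - mean(kt))^2))
}

#' @export
print.baseline_relation <- function(x, ...) {
  cat("Baseline TMD-STA relationship:", nrow(x$knots), "knots,",
      sprintf("overall slope %.4f deg/deg\n", coef(x)[["slope"]]))
  k <- x$knots
  cat(paste(sprintf("  TMD %+7.2f -> STA %+7.3f (n=%d)",
                    k$tmd, k$sta, as.integer(k$n)), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.baseline_relation <- function(x, ...,
                                   xlab = "tip-movement direction (deg)",
                                   ylab = "stick-tilt angle (deg)") {
  k <- x$knots
  graphics::plot(k$tmd, k$sta, type = "b", pch = 19,
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  invisible(x)
}

#' Serialize a baseline relation to JSON
#'
#' The wire format is `{"knots": [[tmd_deg, sta_deg], ...]}`.
#'
#' @param relation A `baseline_relation`.
#' @param file Optional path; when given the JSON is written there.
#' @return The JSON string (invisibly when `file` is given).
#' @export
relation_to_json <- function(relation, file = NULL) {
  stopifnot(inherits(relation, "baseline_relation"))
  j <- jsonlite::toJSON(
    list(knots = unname(as.matrix(relation$knots[c("tmd", "sta")]))),
    digits = NA, auto_unbox = TRUE)
  if (!is.null(file)) {
    writeLines(j, file)
    return(invisible(j))
  }
  j
}

#' @rdname relation_to_json
#' @param json A JSON string or path to a JSON file.
#' @export
relation_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (is.null(x$knots)) stop("relation JSON must contain a 'knots' array")
  k <- as.data.frame(x$knots)
  names(k) <- c("tmd", "sta")
  k$n <- 1
  new_baseline_relation(k)
}
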