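#' Zero-phase Butterworth low-pass filter
#'
#' Fourth-order Butterworth applied forward and backward (zero phase, so
#' peak timings are not lag-biased), 10 Hz cutoff by default, matching the
#' standard kinematic preprocessing for 1 kHz recordings.
#'
#' Edge transients are controlled the standard way: the series is extended
#' by odd reflection at both ends and each pass starts from the filter's
#' steady-state initial conditions, so a constant series passes through
#' unchanged.
#'
#' @param x Uniformly sampled numeric series.
#' @param fs Sampling rate, Hz (default 1000).
#' @param cutoff Cutoff frequency, Hz (default 10).
#' @param order Filter order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, fs = 1000, cutoff = 10, order = 4) {
  stopifnot(is.numeric(x), fs > 0, cutoff > 0, cutoff < fs / 2, order >= 1)
  n <- length(x)
  if (n <= 3 * order)
    stop("series too short to filter: need length > 3 * order")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  b <- bf$b; a <- bf$a
  zi <- filter_steady_state(b, a)
  pad <- min(n - 1, 3 * max(length(a), length(b)))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- df2t_filter(b, a, ext, zi * ext[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + n)]
}

# steady-state state vector of the direct-form-II-transposed filter for a
# unit step input: zi = (I - A^T)^{-1} (b[-1] - b[1] a[-1])
filter_steady_state <- function(b, a) {
  m <- length(a) - 1
  A <- matrix(0, m, m)
  A[, 1] <- -a[-1]
  if (m > 1) A[cbind(seq_len(m - 1), seq_len(m - 1) + 1)] <- 1
  solve(diag(m) - A, b[-1] - b[1] * a[-1])
}

# single-pass IIR filter, direct form II transposed, with initial state
df2t_filter <- function(b, a, x, zi) {
  m <- length(b) - 1
  z <- c(zi, 0)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    for (k in seq_len(m)) z[k] <- b[k + 1] * xi + z[k + 1] - a[k + 1] * yi
    y[i] <- yi
  }
  y
}

#' Magnitude response of the low-pass filter
#'
#' Gain of the digital Butterworth filter at given frequencies, for one
#' pass or for the forward-backward (squared-magnitude) application. A
#' single pass has gain 1/sqrt(2) at the cutoff by construction.
#'
#' @param freq Frequencies at which to evaluate, Hz; vectorized.
#' @inheritParams lowpass
#' @param passes 1 (single pass) or 2 (zero-phase forward-backward).
#' @return Gain magnitudes.
#' @export
filter_gain <- function(freq, fs = 1000, cutoff = 10, order = 4, passes = 1) {
  stopifnot(passes %in% c(1, 2))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  w <- 2 * pi * freq / fs
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * seq(0, length(bf$b) - 1))
    abs(sum(bf$b * z) / sum(bf$a * exp(-1i * wi * seq(0, length(bf$a) - 1))))
  }, numeric(1))
  H^passes
}

#' Tip speed of a trial
#'
#' Finite-difference speed of the tip, optionally low-pass filtered.
#'
#' @param kin A `trial_kinematics` object.
#' @param filtered Apply [lowpass()] to the speed series (default TRUE).
#' @param cutoff Filter cutoff, Hz.
#' @return Speed series in cm/s, same length as the trial (first sample
#'   duplicated).
#' @export
tip_speed <- function(kin, filtered = TRUE, cutoff = 10) {
  stopifnot(inherits(kin, "trial_kinematics"))
  dt <- kin$time[2] - kin$time[1]
  n <- nrow(kin$tip)
  # central differences keep the speed series time-symmetric, so the peak
  # of a symmetric bell profile stays at the true midpoint sample
  vx <- c(kin$tip[2, 1] - kin$tip[1, 1],
          (kin$tip[3:n, 1] - kin$tip[1:(n - 2), 1]) / 2,
          kin$tip[n, 1] - kin$tip[n - 1, 1]) / dt
  vy <- c(kin$tip[2, 2] - kin$tip[1, 2],
          (kin$tip[3:n, 2] - kin$tip[1:(n - 2), 2]) / 2,
          kin$tip[n, 2] - kin$tip[n - 1, 2]) / dt
  v <- sqrt(vx^2 + vy^2)
  if (filtered) v <- lowpass(v, fs = 1 / dt, cutoff = cutoff)
  v
}

#' Index of the tip's peak velocity
#'
#' Global maximum of the (filtered) tip speed; the first index wins on
#' exact ties.
#'
#' @inheritParams tip_speed
#' @return Integer sample index.
#' @export
peak_velocity_index <- function(kin, filtered = TRUE, cutoff = 10) {
  which.max(tip_speed(kin, filtered = filtered, cutoff = cutoff))
}

#' TMD and STA read-out at a sample
#'
#' The tip-movement direction is the chord angle from the trial's start
#' position to the tip at the given sample (for the straight paths of this
#' task it coincides with the instantaneous velocity direction, and is
#' robust to noise); `method = "velocity"` gives the instantaneous
#' direction instead. The stick-tilt angle is measured relative to the
#' initial tilt of the trial.
#'
#' @param kin A `trial_kinematics` object.
#' @param index Sample index (e.g. from [peak_velocity_index()]).
#' @param start Start position; defaults to the first tip sample.
#' @param method `"chord"` (default) or `"velocity"`.
#' @return Named numeric `c(tmd = , sta = )`, degrees.
#' @export
tmd_sta_at <- function(kin, index, start = kin$tip[1, ],
                       method = c("chord", "velocity")) {
  stopifnot(inherits(kin, "trial_kinematics"),
            index >= 1, index <= length(kin$time))
  method <- match.arg(method)
  if (method == "chord") {
    v <- kin$tip[index, ] - start
    if (sqrt(sum(v^2)) < 1e-9)
      stop("tip has not moved from the start at this sample")
  } else {
    if (index < 2) stop("velocity direction undefined at the first sample")
    v <- kin$tip[index, ] - kin$tip[index - 1, ]
    if (sqrt(sum(v^2)) < 1e-12)
      stop("tip velocity is zero at this sample")
  }
  c(tmd = rad2deg(atan2(v[2], v[1])),
    sta = kin$tilt[index] - kin$tilt[1])
}

#' Per-trial measures from kinematics
#'
#' Full read-out of one trial: TMD/STA at peak velocity, STA at movement
#' offset (first sample with displacement at or beyond the target distance
#' and speed below 5% of peak; the last sample if none qualifies), peak
#' speed and its feedback flag.
#'
#' @param kin A `trial_kinematics` object.
#' @param trial Trial number.
#' @param phase `"baseline"` or `"adaptation"`.
#' @param target_dir Nominal target direction, degrees.
#' @param target_distance Target distance, cm (default 10).
#' @param cutoff Filter cutoff for the speed series, Hz.
#' @return One-row data.frame with columns `trial`, `phase`, `target_deg`,
#'   `tmd_deg`, `sta_deg`, `sta_offset_deg`, `peak_speed_mms`, `flag`.
#' @export
trial_measures <- function(kin, trial = 1L,
                           phase = c("baseline", "adaptation"),
                           target_dir = 0, target_distance = 10,
                           cutoff = 10) {
  phase <- match.arg(phase)
  v <- tip_speed(kin, filtered = TRUE, cutoff = cutoff)
  ipk <- which.max(v)
  at_pk <- tmd_sta_at(kin, ipk)
  disp <- sqrt((kin$tip[, 1] - kin$tip[1, 1])^2 +
               (kin$tip[, 2] - kin$tip[1, 2])^2)
  off <- which(disp >= target_distance - 1e-9 & v < 0.05 * v[ipk])
  ioff <- if (length(off)) off[1] else length(disp)
  peak_mms <- v[ipk] * 10
  data.frame(
    trial = as.integer(trial), phase = phase, target_deg = target_dir,
    tmd_deg = at_pk[["tmd"]], sta_deg = at_pk[["sta"]],
    sta_offset_deg = kin$tilt[ioff] - kin$tilt[1],
    peak_speed_mms = peak_mms,
    flag = speed_feedback(peak_mms),
    stringsAsFactors = FALSE
  )
}

#' Analyze a long-format trial table
#'
#' Applies [trial_measures()] to every trial in a table read with
#' [read_trial_csv()].
#'
#' @param tab Trial table data.frame (or path to its CSV).
#' @param phase,target_dir,target_distance,cutoff Passed to
#'   [trial_measures()]; `target_dir` may be a vector with one entry per
#'   trial.
#' @return A measures data.frame with one row per trial.
#' @export
analyze_trials <- function(tab, phase = "baseline", target_dir = 0,
                           target_distance = 10, cutoff = 10) {
  if (is.character(tab)) tab <- read_trial_csv(tab)
  trials <- sort(unique(tab$trial))
  if (length(trials) == 0) stop("trial table is empty")
  target_dir <- rep_len(target_dir, length(trials))
  out <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    kin <- kinematics_from_table(tab, trials[i])
    out[[i]] <- trial_measures(kin, trial = trials[i], phase = phase,
                               target_dir = target_dir[i],
                               target_distance = target_distance,
                               cutoff = cutoff)
  }
  do.call(rbind, out)
}

#' Default adaptation-phase trial segments
#'
#' Nine segments: 1-5, 6-10, 11-15, 16-20, 21-25, 26-30, 31-120, 121-210,
#' 211-240 (the historical 30-120 overlap at trial 30 is normalized to
#' 31-120 so segments partition the phase).
#'
#' @return Data.frame with columns `label`, `first`, `last`.
#' @export
default_segments <- function() {
  data.frame(
    label = c("1-5", "6-10", "11-15", "16-20", "21-25", "26-30",
              "31-120", "121-210", "211-240"),
    first = c(1, 6, 11, 16, 21, 26, 31, 121, 211),
    last = c(5, 10, 15, 20, 25, 30, 120, 210, 240),
    stringsAsFactors = FALSE
  )
}

#' Segment means of trial measures
#'
#' Arithmetic mean TMD and STA per trial segment.
#'
#' @param measures Data.frame with columns `trial`, `tmd_deg`, `sta_deg`.
#' @param scheme Segment scheme as from [default_segments()].
#' @return Data.frame `label`, `first`, `last`, `n`, `tmd_deg`, `sta_deg`.
#' @export
segment_means <- function(measures, scheme = default_segments()) {
  stopifnot(all(c("trial", "tmd_deg", "sta_deg") %in% names(measures)),
            all(c("label", "first", "last") %in% names(scheme)))
  out <- scheme
  out$n <- NA_integer_; out$tmd_deg <- NA_real_; out$sta_deg <- NA_real_
  for (i in seq_len(nrow(scheme))) {
    sel <- measures$trial >= scheme$first[i] & measures$trial <= scheme$last[i]
    if (!any(sel))
      stop("segment ", scheme$label[i], " contains no trials")
    out$n[i] <- sum(sel)
    out$tmd_deg[i] <- mean(measures$tmd_deg[sel])
    out$sta_deg[i] <- mean(measures$sta_deg[sel])
  }
  out
}

#' Trial-by-trial variability in a trial window
#'
#' Sample SD of TMD and STA over an inclusive trial window, by default the
#' latter adaptation phase (trials 121-240).
#'
#' @param measures Data.frame with columns `trial`, `tmd_deg`, `sta_deg`.
#' @param first,last Window bounds, inclusive.
#' @return Named numeric `c(sd_tmd = , sd_sta = )`, degrees.
#' @export
trial_variability <- function(measures, first = 121, last = 240) {
  sel <- measures$trial >= first & measures$trial <= last
  if (sum(sel) < 2)
    stop("variability window must contain at least 2 trials")
  c(sd_tmd = stats::sd(measures$tmd_deg[sel]),
    sd_sta = stats::sd(measures$sta_deg[sel]))
}

#' Trial index of half-maximal adaptation
#'
#' First trial at which a centered moving average of the adaptation series
#' reaches half of its final level (mean over the last `final_window`
#' trials). Used to compare how quickly experiment arms adapt.
#'
#' @param x Per-trial adaptation series (e.g. physical TMD), degrees.
#' @param final_window Number of trailing trials defining the final level.
#' @param smooth Moving-average window (odd; default 5).
#' @return Integer trial index, or `NA` if the half level is never reached.
#' @export
half_adaptation_trial <- function(x, final_window = 30, smooth = 5) {
  n <- length(x)
  stopifnot(n > final_window, smooth >= 1, smooth %% 2 == 1)
  final <- mean(x[(n - final_window + 1):n])
  if (abs(final) < 1e-12) return(NA_integer_)
  k <- (smooth - 1) / 2
  xs <- stats::filter(x, rep(1 / smooth, smooth), sides = 2)
  xs[seq_len(k)] <- x[seq_len(k)]
  xs[(n - k + 1):n] <- x[(n - k + 1):n]
  hit <- which(xs / final >= 0.5)
  if (length(hit)) hit[1] else NA_integer_
}

#' Paired t statistic
#'
#' @param x,y Paired numeric series of equal length (n >= 3).
#' @return List with `t`, `dof` and `p` from [stats::t.test()] (paired).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x - y) < 1e-12) {
    if (all(abs(x - y) < 1e-12))
      return(list(t = 0, dof = length(x) - 1, p = 1))
    stop("differences have zero variance")
  }
  res <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), dof = unname(res$parameter),
       p = res$p.value)
}

#' Pearson correlation
#'
#' @param x,y Numeric series of equal length (n >= 3).
#' @return List with `r` and `p` from [stats::cor.test()].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    stop("correlation undefined for a zero-variance series")
  res <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(res$estimate), p = res$p.value)
}

#' Cohen's d
#'
#' Paired (`y` given, `paired = TRUE`): mean difference over the SD of the
#' differences. Two-sample: mean difference over the pooled SD. One-sample
#' (`y` a scalar reference): mean deviation over the SD of `x`.
#'
#' @param x Numeric series.
#' @param y Second series, or a scalar reference value.
#' @param paired Treat `x`/`y` as paired (default FALSE).
#' @return Cohen's d.
#' @export
cohens_d <- function(x, y = 0, paired = FALSE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    s <- stats::sd(d)
    if (s < 1e-12) stop("differences have zero variance")
    return(mean(d) / s)
  }
  if (length(y) == 1) {
    s <- stats::sd(x)
    if (s < 1e-12) stop("series has zero variance")
    return((mean(x) - y) / s)
  }
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp < 1e-12) stop("pooled variance is zero")
  (mean(x) - mean(y)) / sp
}
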