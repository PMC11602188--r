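#' Experiment protocol and perturbation for a study arm
#'
#' Builds the trial protocol of one experiment arm: a 360-trial baseline
#' phase over the nine targets (each appearing exactly 40 times, in blocked
#' pseudo-random order: every consecutive block of nine trials visits each
#' target once) followed by a 240-trial adaptation phase at the 0 degree
#' target, together with the arm's visual perturbation:
#' \describe{
#'   \item{E1A}{gradual tip rotation, 1 deg/trial up to 30 deg CCW; tilt off.}
#'   \item{E1B}{abrupt 30 deg CCW tip rotation; tilt off.}
#'   \item{E2CCW / E2CW}{tip off; tilt rotation +-0.6 deg/cm (full +-6 deg).}
#'   \item{E3CCW / E3CW}{gradual tip rotation combined with the +-6 deg tilt
#'     rotation.}
#' }
#'
#' @param experiment One of `"E1A"`, `"E1B"`, `"E2CCW"`, `"E2CW"`,
#'   `"E3CCW"`, `"E3CW"`.
#' @param seed Integer seed for the baseline target order.
#' @param baseline_trials,adaptation_trials Phase lengths (defaults 360 and
#'   240; `baseline_trials` must be a multiple of nine).
#' @return A list of class `study_protocol`: `experiment`,
#'   `baseline_targets` (length 360), `adaptation_trials`,
#'   `adaptation_target` (0), `targets`, `distance` (10 cm) and `spec`
#'   (a [perturbation_spec()]).
#' @export
make_protocol <- function(experiment = c("E1A", "E1B", "E2CCW", "E2CW",
                                         "E3CCW", "E3CW"),
                          seed = 1L, baseline_trials = 360,
                          adaptation_trials = 240) {
  experiment <- match.arg(experiment)
  targets <- protocol_targets()
  if (baseline_trials %% length(targets) != 0)
    stop("'baseline_trials' must be a multiple of the number of targets (9)")
  spec <- switch(experiment,
    E1A = perturbation_spec("gradual", tip_max = 30, tip_step = 1,
                            tilt_sign = 0),
    E1B = perturbation_spec("abrupt", tip_max = 30, tilt_sign = 0),
    E2CCW = perturbation_spec("none", tilt_gain = 0.6, tilt_sign = +1),
    E2CW = perturbation_spec("none", tilt_gain = 0.6, tilt_sign = -1),
    E3CCW = perturbation_spec("gradual", tip_max = 30, tip_step = 1,
                              tilt_gain = 0.6, tilt_sign = +1),
    E3CW = perturbation_spec("gradual", tip_max = 30, tip_step = 1,
                             tilt_gain = 0.6, tilt_sign = -1))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  blocks <- baseline_trials / length(targets)
  order <- unlist(lapply(seq_len(blocks), function(b) sample(targets)))
  structure(
    list(experiment = experiment,
         baseline_targets = order,
         adaptation_trials = adaptation_trials,
         adaptation_target = 0,
         targets = targets,
         distance = 10,
         spec = spec,
         seed = seed),
    class = "study_protocol"
  )
}

#' @export
print.study_protocol <- function(x, ...) {
  cat(sprintf("Protocol %s: %d baseline trials over %d targets, %d adaptation trials at %g deg\n",
              x$experiment, length(x$baseline_targets), length(x$targets),
              x$adaptation_trials, x$adaptation_target))
  print(x$spec)
  invisible(x)
}

#' Synthetic participant population
#'
#' Draws a heterogeneous population of synthetic participants. Baseline
#' TMD-STA relation slopes come from a normal distribution truncated at
#' zero (defaults mean 0.2, SD 0.07, chosen so reaching the +-30 degree
#' targets tilts the stick about +-6 degrees at movement offset, the scale
#' the tilt perturbation was matched to). Per-participant seeds are derived
#' deterministically from the population seed.
#'
#' @param n Number of participants.
#' @param population_seed Integer seed.
#' @param slope_mean,slope_sd Population distribution of the baseline
#'   relation slope (deg/deg).
#' @param noise_sd_deg Trial-level motor noise SD applied to both TMD and
#'   STA, degrees.
#' @param duration_mean,duration_sd Movement-duration distribution, s.
#' @param params Shared [learner_params()] template; its noise fields are
#'   overridden by `noise_sd_deg`.
#' @return A data.frame of class `population` with one row per participant:
#'   `id`, `slope`, `noise_sd`, `duration`, `seed`.
#' @export
make_population <- function(n, population_seed = 1L,
                            slope_mean = 0.2, slope_sd = 0.07,
                            noise_sd_deg = 1.0,
                            duration_mean = 0.5, duration_sd = 0.03,
                            params = learner_params()) {
  stopifnot(n >= 1, slope_mean >= 0, slope_sd >= 0, noise_sd_deg >= 0)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(population_seed)
  slopes <- stats::rnorm(n, slope_mean, slope_sd)
  while (any(slopes <= 0))  # truncate at zero by redrawing
    slopes[slopes <= 0] <- stats::rnorm(sum(slopes <= 0), slope_mean, slope_sd)
  durations <- pmax(0.3, stats::rnorm(n, duration_mean, duration_sd))
  base <- (as.integer(population_seed) %% 1000000L) * 1000L
  pop <- data.frame(
    id = seq_len(n),
    slope = slopes,
    noise_sd = noise_sd_deg,
    duration = durations,
    seed = base + seq_len(n)
  )
  structure(pop, class = c("population", "data.frame"),
            params = params, population_seed = population_seed)
}

#' Run a full synthetic experiment arm
#'
#' For every participant: baseline trials are executed at intents on the
#' participant's own linear baseline relation at the nominal target (the
#' population is "pre-optimized" - the stereotyped tilt strategy is present
#' from the first trial) with additive motor noise; adaptation trials run
#' the constrained-correction learner under the arm's perturbation. All
#' states are end-of-movement physical plane states; the peak-velocity STA
#' read-out of the linear within-trial tilt ramp is half the offset value.
#'
#' @param population A [make_population()] data.frame.
#' @param protocol A [make_protocol()] object (its `spec` is used).
#' @param params Optional [learner_params()] overriding the population
#'   template (noise fields are still taken per participant).
#' @return An object of class `experiment_run` with elements
#'   `baseline` (data.frame: participant, trial, phase, target_deg,
#'   tmd_deg, sta_deg), `adaptation` (data.frame: participant, trial,
#'   phase, target_deg, intent/exec/vis TMD and STA, errors),
#'   `population`, `protocol` and `manifest` (seeds and configuration).
#' @export
run_experiment <- function(population, protocol, params = NULL) {
  stopifnot(inherits(population, "population"),
            inherits(protocol, "study_protocol"))
  if (is.null(params)) params <- attr(population, "params")
  spec <- protocol$spec
  base_list <- vector("list", nrow(population))
  adapt_list <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    p <- population[i, ]
    relation <- linear_relation(slope = p$slope)
    pp <- learner_params(
      eta_tmd = params$eta_tmd, eta_sta = params$eta_sta,
      retention_loss = params$retention_loss,
      motor_noise_tmd = p$noise_sd, motor_noise_sta = p$noise_sd,
      tilt_error_norm = params$tilt_error_norm)
    nb <- length(protocol$baseline_targets)
    eps <- local_rnorm(2 * nb, sd = p$noise_sd, seed = p$seed)
    tg <- protocol$baseline_targets
    base_list[[i]] <- data.frame(
      participant = p$id,
      trial = seq_len(nb),
      phase = "baseline",
      target_deg = tg,
      tmd_deg = tg + eps[seq_len(nb)],
      sta_deg = p$slope * tg + eps[nb + seq_len(nb)]
    )
    sim <- simulate_adaptation(
      n_trials = protocol$adaptation_trials, params = pp,
      relation = relation, spec = spec,
      target_dir = protocol$adaptation_target,
      target_distance = protocol$distance,
      seed = p$seed + 500000L)
    tr <- sim$trials
    adapt_list[[i]] <- cbind(
      data.frame(participant = p$id, phase = "adaptation",
                 target_deg = protocol$adaptation_target),
      tr)
  }
  structure(
    list(baseline = do.call(rbind, base_list),
         adaptation = do.call(rbind, adapt_list),
         population = population,
         protocol = protocol,
         manifest = list(
           experiment = protocol$experiment,
           population_seed = attr(population, "population_seed"),
           protocol_seed = protocol$seed,
           participant_seeds = population$seed,
           n_participants = nrow(population),
           learner = unclass(params))),
    class = "experiment_run"
  )
}

#' @export
print.experiment_run <- function(x, ...) {
  fin <- final_segment_means(x)
  cat(sprintf(
    "Experiment %s: %d participants | final-segment physical TMD %+.2f deg, STA %+.2f deg (group mean)\n",
    x$protocol$experiment, nrow(x$population),
    mean(fin$tmd_deg), mean(fin$sta_deg)))
  invisible(x)
}

#' Per-participant final-segment means of an experiment run
#'
#' Mean executed physical TMD and STA over the closing trial window of the
#' adaptation phase (default trials 211-240).
#'
#' @param run An [run_experiment()] result.
#' @param first,last Trial window, inclusive.
#' @return Data.frame `participant`, `tmd_deg`, `sta_deg`.
#' @export
final_segment_means <- function(run, first = 211, last = 240) {
  stopifnot(inherits(run, "experiment_run"))
  ad <- run$adaptation
  sel <- ad$trial >= first & ad$trial <= last
  ids <- unique(ad$participant)
  data.frame(
    participant = ids,
    tmd_deg = vapply(ids, function(id)
      mean(ad$exec_tmd[sel & ad$participant == id]), numeric(1)),
    sta_deg = vapply(ids, function(id)
      mean(ad$exec_sta[sel & ad$participant == id]), numeric(1))
  )
}

#' Group-mean adaptation learning curve
#'
#' Mean executed physical TMD (and STA) per trial across participants.
#'
#' @param run An [run_experiment()] result.
#' @return Data.frame `trial`, `tmd_deg`, `sta_deg`.
#' @export
learning_curve <- function(run) {
  stopifnot(inherits(run, "experiment_run"))
  ad <- run$adaptation
  trials <- sort(unique(ad$trial))
  data.frame(
    trial = trials,
    tmd_deg = vapply(trials, function(t)
      mean(ad$exec_tmd[ad$trial == t]), numeric(1)),
    sta_deg = vapply(trials, function(t)
      mean(ad$exec_sta[ad$trial == t]), numeric(1))
  )
}
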