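# random valid stick poses for round-trip properties
random_poses <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    stick_pose(tip = stats::runif(2, -30, 30),
               tilt = stats::runif(1, -179, 179))
  })
}

# exhaustive grid minimizer of the hand-path cost, the independent oracle
# for the bracketed optimizer
grid_optimal_tilt <- function(direction, distance = 10,
                              geom = stick_geometry(),
                              lo = -45, hi = 45, step = 1e-3) {
  th <- seq(lo, hi, by = step)
  cost <- hand_path_cost(direction, th, distance, geom)
  i <- which.min(cost)
  list(tilt = th[i], cost = cost[i])
}
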