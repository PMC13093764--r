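# Independent oracles and fixture builders shared across the test files.
# The oracles are deliberately written as plain double loops / literal
# definitions so they stay independent of the vectorized implementations
# they check.

# group_recording whose analysis window is the full span
make_rec <- function(x, y, species = rep("spA", ncol(as.matrix(x))),
                     strain = rep("s1", ncol(as.matrix(x))),
                     group_type = "single", dt = 0.5, diameter_mm = 140,
                     replicate_id = "test") {
  x <- as.matrix(x); y <- as.matrix(y)
  group_recording(
    x = x, y = y,
    individual_id = sprintf("f%02d", seq_len(ncol(x))),
    species = species, strain = strain, group_type = group_type,
    replicate_id = replicate_id,
    arena = arena_config(diameter_mm = diameter_mm, frame_interval_s = dt,
                         analysis_start_s = 0,
                         analysis_end_s = nrow(x) * dt))
}

# brute-force pairwise visual cue at one frame
oracle_cue_frame <- function(x, y, heading, speed, body_major = 3,
                             clamp = 0.75) {
  n <- length(x)
  out <- numeric(n)
  for (f in seq_len(n)) {
    acc <- 0
    for (i in seq_len(n)) {
      if (i == f) next
      dx <- x[i] - x[f]
      dy <- y[i] - y[f]
      if (dx * cos(heading[f]) + dy * sin(heading[f]) >= 0) {
        d <- max(sqrt(dx^2 + dy^2), clamp)
        acc <- acc + speed[i] * 2 * atan(body_major / (2 * d))
      }
    }
    out[f] <- acc
  }
  out
}

# literal per-frame application of the event definitions
oracle_label_events <- function(states) {
  n <- length(states)
  ev <- character(n)
  for (t in seq_len(n)) {
    if (t < n && states[t] == "stationary" && states[t + 1L] == "walking")
      ev[t] <- "walk"
    else if (t < n && states[t] == "walking" &&
             states[t + 1L] == "stationary")
      ev[t] <- "stop"
    else if (states[t] == "walking")
      ev[t] <- "walking"
    else
      ev[t] <- "stay"
  }
  ev
}

# random positions/headings/speeds for one frame of an n-agent group
random_frame <- function(n = 24, radius = 65) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  list(x = r * cos(th), y = r * sin(th),
       heading = runif(n, 0, 2 * pi),
       speed = rexp(n, rate = 0.25))
}

quick_species <- function(name = "spA", speed = 4, beta = 0, stop_beta = 0)
  species_params(name, walk_speed_mu_mm_s = speed, coupling_beta = beta,
                 stop_coupling = stop_beta)

# full single-recording pipeline used by several tests
run_single_pipeline <- function(rec, config = run_config()) {
  kin <- compute_kinematics(rec, config$cue)
  cue <- compute_cue(rec, kin, config$cue)
  cue <- transform_cue(cue, rec, config$cue)
  st <- compute_states(kin, config$walk_threshold_mm_s,
                       config$min_bout_frames)
  list(kin = kin, cue = cue, states = st,
       aligned = event_aligned_cues(cue, st, rec))
}
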