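#' Ground-truth species parameters for the arena simulator
#'
#' Each simulated fly is a two-state (stationary/walking) Markov agent whose
#' transition probabilities are coupled to its standardized visual cue
#' through a logistic link:
#' `P(stay -> walk) = plogis(qlogis(base_walk_rate) + coupling_beta * z)` and
#' `P(walk -> stay) = plogis(qlogis(base_stop_rate) + stop_coupling * z)`,
#' which keeps probabilities valid at any realized cue. `coupling_beta` is
#' the ground-truth conformity: the log-odds increment of walk onset per sd
#' of cue. Walking agents move at a lognormal speed along their heading with
#' Gaussian turn noise.
#'
#' @param name Species label.
#' @param base_walk_rate Per-frame probability of stay-to-walk at zero
#'   standardized cue, in (0, 1).
#' @param base_stop_rate Per-frame probability of walk-to-stay at zero cue,
#'   in (0, 1).
#' @param coupling_beta Log-odds increment of walk onset per sd of cue
#'   (>= 0 means walking where others move).
#' @param stop_coupling Log-odds increment of stopping per sd of cue
#'   (positive = settles where others are).
#' @param walk_speed_mu_mm_s Median walking speed, mm/s (lognormal scale
#'   parameter, > 0).
#' @param walk_speed_sigma Lognormal shape (sd of log speed, >= 0).
#' @param turn_sd_rad Heading noise per frame while walking, radians.
#' @return An object of class `species_params`.
#' @export
species_params <- function(name, base_walk_rate = 0.05,
                           base_stop_rate = 0.10,
                           coupling_beta = 0, stop_coupling = 0,
                           walk_speed_mu_mm_s = 4,
                           walk_speed_sigma = 0.3,
                           turn_sd_rad = 0.6) {
  stopifnot(base_walk_rate > 0, base_walk_rate < 1,
            base_stop_rate > 0, base_stop_rate < 1,
            walk_speed_mu_mm_s > 0, walk_speed_sigma >= 0,
            turn_sd_rad >= 0)
  structure(list(name = as.character(name),
                 base_walk_rate = base_walk_rate,
                 base_stop_rate = base_stop_rate,
                 coupling_beta = coupling_beta,
                 stop_coupling = stop_coupling,
                 walk_speed_mu_mm_s = walk_speed_mu_mm_s,
                 walk_speed_sigma = walk_speed_sigma,
                 turn_sd_rad = turn_sd_rad),
            class = "species_params")
}

#' Simulation parameters
#'
#' @param species_a A [species_params()].
#' @param species_b Optional second [species_params()]; present = mixed
#'   group (`n_per_species` each), absent = single group.
#' @param n_per_species Individuals per species (24 single / 12+12 mixed by
#'   default, matching a 24-fly arena).
#' @param n_frames Frames retained after burn-in (0.5 s per frame).
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical recording.
#' @param arena An [arena_config()]; the analysis window defaults to the
#'   whole simulated span because the simulator emits stationarized
#'   behavior equivalent to a recording's analysis window.
#' @param burn_in_frames Frames simulated and discarded before recording.
#' @param n_calibration_frames Length of the zero-coupling calibration run
#'   that fixes the cue-standardization constants; defaults to the full
#'   assay window (3600 frames) because at strong coupling the realized
#'   dynamics are sensitive to the standardization center, so the
#'   constants should be estimated as precisely as the recordings they
#'   serve.
#' @param strain_a,strain_b Strain labels per species.
#' @param replicate_id Recording identifier.
#' @param cue A [cue_config()] used for the online cue.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(species_a, species_b = NULL,
                       n_per_species = if (is.null(species_b)) 24L else 12L,
                       n_frames = 3600L, seed = 1L,
                       arena = NULL, burn_in_frames = 100L,
                       n_calibration_frames = 3600L,
                       strain_a = "s1", strain_b = "s1",
                       replicate_id = "sim1",
                       cue = cue_config()) {
  stopifnot(inherits(species_a, "species_params"),
            is.null(species_b) || inherits(species_b, "species_params"),
            n_per_species >= 2L, n_frames >= 10L)
  if (is.null(arena))
    arena <- arena_config(analysis_start_s = 0,
                          analysis_end_s = n_frames * 0.5)
  structure(list(species_a = species_a, species_b = species_b,
                 n_per_species = as.integer(n_per_species),
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 arena = arena, burn_in_frames = as.integer(burn_in_frames),
                 n_calibration_frames = as.integer(n_calibration_frames),
                 strain_a = strain_a, strain_b = strain_b,
                 replicate_id = replicate_id, cue = cue),
            class = "sim_params")
}

# per-agent parameter vectors for the whole group
agent_params <- function(params) {
  sp <- list(params$species_a)
  strains <- params$strain_a
  if (!is.null(params$species_b)) {
    sp <- c(sp, list(params$species_b))
    strains <- c(strains, params$strain_b)
  }
  n <- params$n_per_species
  field <- function(f) rep(vapply(sp, `[[`, numeric(1), f), each = n)
  list(
    n_agents = n * length(sp),
    species = rep(vapply(sp, `[[`, character(1), "name"), each = n),
    strain = rep(strains, each = n),
    logit_walk = stats::qlogis(field("base_walk_rate")),
    logit_stop = stats::qlogis(field("base_stop_rate")),
    beta = field("coupling_beta"),
    stop_beta = field("stop_coupling"),
    log_mu = log(field("walk_speed_mu_mm_s")),
    sigma = field("walk_speed_sigma"),
    turn_sd = field("turn_sd_rad"),
    p_walk0 = field("base_walk_rate"),
    p_stop0 = field("base_stop_rate"))
}

# core dynamics; returns x/y position matrices (n_total_frames x n_agents).
# `constants` are the cue-standardization constants (NULL disables coupling);
# the RNG state is taken as-is, callers seed it.
sim_core <- function(params, ag, n_total, constants, use_coupling) {
  n <- ag$n_agents
  dt <- params$arena$frame_interval_s
  r_wall <- params$arena$diameter_mm / 2 - 1  # 1 mm body margin
  mixed <- !is.null(params$species_b)

  # starting positions clustered near the arena center; in mixed groups the
  # two species start at symmetric +/- y positions (initial location encodes
  # species identity, as in the live assay)
  if (mixed) {
    cy <- rep(c(20, -20), each = params$n_per_species)
    px <- stats::rnorm(n, 0, 5)
    py <- cy + stats::rnorm(n, 0, 5)
  } else {
    rr <- 20 * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    px <- rr * cos(th)
    py <- rr * sin(th)
  }
  heading <- stats::runif(n, 0, 2 * pi)
  walking <- stats::runif(n) < ag$p_walk0 / (ag$p_walk0 + ag$p_stop0)

  x <- matrix(NA_real_, n_total, n)
  y <- matrix(NA_real_, n_total, n)
  x[1L, ] <- px
  y[1L, ] <- py
  speed_real <- numeric(n)

  for (t in 2:n_total) {
    if (use_coupling) {
      cue <- cue_frame(px, py, heading, speed_real, params$cue)
      z <- log_standardize_with(cue, constants)
      p_walk <- stats::plogis(ag$logit_walk + ag$beta * z)
      p_stop <- stats::plogis(ag$logit_stop + ag$stop_beta * z)
    } else {
      p_walk <- ag$p_walk0
      p_stop <- ag$p_stop0
    }
    u <- stats::runif(n)
    walking <- ifelse(walking, u >= p_stop, u < p_walk)

    turn <- stats::rnorm(n, 0, ag$turn_sd)
    sp_draw <- exp(ag$log_mu + ag$sigma * stats::rnorm(n))
    heading <- ifelse(walking, heading + turn, heading)
    step <- ifelse(walking, sp_draw * dt, 0)
    nx <- px + step * cos(heading)
    ny <- py + step * sin(heading)

    # specular (billiard) reflection at the arena wall: the path folds at
    # the wall and keeps its length, so wall contact does not shorten steps
    out <- which(nx^2 + ny^2 > r_wall^2)
    for (j in out) {
      p0x <- px[j]; p0y <- py[j]
      vx <- nx[j] - p0x; vy <- ny[j] - p0y
      for (iter in 1:3) {
        vv <- vx^2 + vy^2
        if (vv == 0) break
        pv <- p0x * vx + p0y * vy
        pp <- p0x^2 + p0y^2 - r_wall^2
        s <- (-pv + sqrt(max(pv^2 - vv * pp, 0))) / vv
        if (s >= 1) break
        qx <- p0x + s * vx; qy <- p0y + s * vy
        uxh <- qx / r_wall; uyh <- qy / r_wall
        dot <- vx * uxh + vy * uyh
        p0x <- qx; p0y <- qy
        vx <- (1 - s) * (vx - 2 * dot * uxh)
        vy <- (1 - s) * (vy - 2 * dot * uyh)
        if ((p0x + vx)^2 + (p0y + vy)^2 <= r_wall^2) break
      }
      ex <- p0x + vx; ey <- p0y + vy
      er <- sqrt(ex^2 + ey^2)
      if (er > r_wall) { ex <- ex * r_wall / er; ey <- ey * r_wall / er }
      nx[j] <- ex; ny[j] <- ey
      if (vx != 0 || vy != 0) heading[j] <- atan2(vy, vx)
    }
    speed_real <- sqrt((nx - px)^2 + (ny - py)^2) / dt
    px <- nx; py <- ny
    x[t, ] <- px
    y[t, ] <- py
  }
  list(x = x, y = y)
}

log_standardize_with <- function(cue, constants) {
  lx <- log(pmax(cue, constants$min_nonzero))
  (lx - constants$log_mean) / constants$log_sd
}

#' Cue-standardization constants from a zero-coupling calibration run
#'
#' Runs the group with all couplings switched off and returns log/z-score
#' constants of the realized raw cue distribution. Using a decoupled
#' calibration pass avoids circularity between the online standardization
#' and the coupled behavior it drives. Unlike the analysis transform, the
#' generative standardization floors the cue at the 1st percentile of the
#' positive calibration values rather than their minimum: the minimum is an
#' extreme order statistic whose run-to-run swings would otherwise inflate
#' the log-scale sd and make the realized coupling strength depend on the
#' calibration seed.
#'
#' @param params A [sim_params()].
#' @return List with `min_nonzero` (the floor), `log_mean`, `log_sd`.
#' @export
calibrate_cue_constants <- function(params) {
  ag <- agent_params(params)
  n_total <- params$burn_in_frames + params$n_calibration_frames
  set.seed(derive_seed(params$seed, 1L))
  pos <- sim_core(params, ag, n_total, constants = NULL,
                  use_coupling = FALSE)
  keep <- (params$burn_in_frames + 1L):n_total
  rec <- group_recording(
    x = pos$x[keep, , drop = FALSE], y = pos$y[keep, , drop = FALSE],
    individual_id = sprintf("c%02d", seq_len(ag$n_agents)),
    species = ag$species, strain = ag$strain,
    group_type = if (is.null(params$species_b)) "single" else "mixed",
    replicate_id = "calibration",
    arena = arena_config(
      diameter_mm = params$arena$diameter_mm,
      frame_interval_s = params$arena$frame_interval_s,
      analysis_start_s = 0,
      analysis_end_s = length(keep) * params$arena$frame_interval_s))
  kin <- compute_kinematics(rec, params$cue)
  cue <- compute_cue(rec, kin, params$cue)
  x <- as.vector(cue$raw)
  pos <- x[x > 0]
  if (!length(pos))
    stop("calibration run produced no positive cue values")
  floor_val <- as.numeric(stats::quantile(pos, 0.01))
  lx <- log(pmax(x, floor_val))
  sdv <- stats::sd(lx)
  if (!is.finite(sdv) || sdv == 0)
    stop("calibration cue values have zero variance")
  list(min_nonzero = floor_val, log_mean = mean(lx), log_sd = sdv)
}

# fold a stream index into the user seed, staying inside 32-bit integers
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream * 97) %% 2147483647)
}

#' Simulate a group recording
#'
#' Runs the agent-based arena model: every frame each agent computes its
#' raw visual cue from the others' current positions and most recent
#' movement (via the same cue model the analysis uses), standardizes it with
#' constants from a zero-coupling calibration pass, and updates its
#' stationary/walking state through the logistic transition model of
#' [species_params()]. Walking agents move at a lognormal speed along their
#' heading with turn noise; headings reflect specularly off the arena wall;
#' starting positions cluster near the center. The first `burn_in_frames`
#' frames are discarded so the retained series is stationarized, mirroring a
#' recording's analysis window.
#'
#' @param params A [sim_params()].
#' @param cue_constants Optional pre-computed standardization constants
#'   (from [calibrate_cue_constants()]) to skip the calibration pass, e.g.
#'   when simulating replicates of one condition.
#' @return A validated `group_recording`; identical seed and parameters
#'   give bit-identical output.
#' @export
simulate_group <- function(params, cue_constants = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (params$n_frames < 2L) stop("n_frames too small")
  ag <- agent_params(params)
  use_coupling <- any(ag$beta != 0) || any(ag$stop_beta != 0)
  if (use_coupling && is.null(cue_constants))
    cue_constants <- calibrate_cue_constants(params)
  n_total <- params$burn_in_frames + params$n_frames
  set.seed(derive_seed(params$seed, 2L))
  pos <- sim_core(params, ag, n_total, constants = cue_constants,
                  use_coupling = use_coupling)
  keep <- (params$burn_in_frames + 1L):n_total
  group_recording(
    x = pos$x[keep, , drop = FALSE], y = pos$y[keep, , drop = FALSE],
    individual_id = sprintf("f%02d", seq_len(ag$n_agents)),
    species = ag$species, strain = ag$strain,
    group_type = if (is.null(params$species_b)) "single" else "mixed",
    replicate_id = params$replicate_id,
    arena = arena_config(
      diameter_mm = params$arena$diameter_mm,
      frame_interval_s = params$arena$frame_interval_s,
      analysis_start_s = 0,
      analysis_end_s = params$n_frames * params$arena$frame_interval_s))
}

#' Default four-species panel for validation
#'
#' Four synthetic species whose median walking speeds (1, 2, 4, 10 mm/s)
#' span the roughly ten-fold activity range seen across sympatric fly
#' species, with the designated host species at an intermediate speed and
#' the highest coupling, and the fastest species at the lowest coupling (the
#' influential-but-insensitive profile). Names are deliberately synthetic.
#'
#' @return Named list of [species_params()]; the host is `syn_host`.
#' @export
default_species_panel <- function() {
  list(
    syn_slow = species_params("syn_slow", walk_speed_mu_mm_s = 1,
                              coupling_beta = 1.2, stop_coupling = 0.4),
    syn_host = species_params("syn_host", walk_speed_mu_mm_s = 2,
                              coupling_beta = 1.5, stop_coupling = 0.4),
    syn_mid = species_params("syn_mid", walk_speed_mu_mm_s = 4,
                             coupling_beta = 1.0, stop_coupling = 0.3),
    syn_fast = species_params("syn_fast", walk_speed_mu_mm_s = 10,
                              coupling_beta = 0.3, stop_coupling = 0.4))
}

#' Write the fixed validation panel of recordings
#'
#' Generates the panel used for end-to-end validation: each of the four
#' panel species in single-species groups, plus the three mixed pairings of
#' the host species with each partner, each condition with 2 pseudo-strains
#' x `n_replicates` replicates. Pseudo-strains jitter the species' median
#' walking speed by +/-10%. One calibration pass per condition fixes the
#' cue-standardization constants shared by its replicates.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-recording seeds are derived from it.
#' @param n_frames Frames per recording.
#' @param n_replicates Replicates per species x strain x condition.
#' @param n_per_species Individuals per species (24 single / 12+12 mixed).
#' @param panel Named list of [species_params()] with a `syn_host` entry.
#' @return The manifest data.frame (also written to
#'   `<out_dir>/manifest.tsv`): file, group_type, species, strains,
#'   replicate, seed, n_frames.
#' @export
make_validation_suite <- function(out_dir, seed = 1L, n_frames = 900L,
                                  n_replicates = 3L, n_per_species = NULL,
                                  panel = default_species_panel()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  strain_scale <- c(a = 0.9, b = 1.1)
  with_strain <- function(sp, s) {
    sp$walk_speed_mu_mm_s <- sp$walk_speed_mu_mm_s * strain_scale[[s]]
    sp
  }
  host <- "syn_host"
  partners <- setdiff(names(panel), host)
  rows <- list()
  counter <- 0L
  run_one <- function(spa, spb, strain, rep_i, label, group_type) {
    counter <<- counter + 1L
    n_single <- if (is.null(n_per_species)) 24L else n_per_species
    n_mix <- if (is.null(n_per_species)) 12L else n_per_species
    p <- sim_params(
      species_a = spa, species_b = spb,
      n_per_species = if (group_type == "single") n_single else n_mix,
      n_frames = n_frames,
      seed = derive_seed(seed, counter * 10L),
      strain_a = strain, strain_b = strain,
      replicate_id = sprintf("%s_%s_r%d", label, strain, rep_i))
    if (rep_i == 1L)
      condition_constants <<- calibrate_cue_constants(p)
    rec <- simulate_group(p, cue_constants = condition_constants)
    fn <- file.path(out_dir, sprintf("%s_%s_r%d.tsv", label, strain, rep_i))
    write_recording(rec, fn)
    rows[[length(rows) + 1L]] <<- data.frame(
      file = basename(fn), group_type = group_type,
      species_a = spa$name,
      species_b = if (is.null(spb)) NA_character_ else spb$name,
      strain = strain, replicate = rep_i, seed = p$seed,
      n_frames = n_frames, stringsAsFactors = FALSE)
  }
  condition_constants <- NULL
  for (nm in names(panel)) for (s in names(strain_scale))
    for (r in seq_len(n_replicates))
      run_one(with_strain(panel[[nm]], s), NULL, s, r,
              sprintf("single_%s", nm), "single")
  for (nm in partners) for (s in names(strain_scale))
    for (r in seq_len(n_replicates))
      run_one(with_strain(panel[[host]], s), with_strain(panel[[nm]], s),
              s, r, sprintf("mixed_%s_%s", host, nm), "mixed")
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
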