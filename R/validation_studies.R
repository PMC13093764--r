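# Seeded simulation studies that validate the pipeline by parameter
# recovery. Each study simulates groups with known ground-truth coupling,
# runs the analysis end to end, and reports the recovered quantity. The
# analysis scripts and the acceptance checks both call these.

study_species <- function(speed = 3, beta = 0, stop_beta = 0, name = "spA")
  species_params(name, base_walk_rate = 0.05, base_stop_rate = 0.10,
                 coupling_beta = beta, stop_coupling = stop_beta,
                 walk_speed_mu_mm_s = speed)

# single-recording analysis: slopes + walk/stay contrast
analyze_single <- function(rec, seed, n_perm = 199L) {
  kin <- compute_kinematics(rec)
  cue <- transform_cue(compute_cue(rec, kin), rec)
  st <- compute_states(kin)
  al <- event_aligned_cues(cue, st, rec)
  sl <- sensitivity_table(rec, kin, cue)
  ct <- tryCatch(event_contrast(al, c("walk", "stay"), n_perm = n_perm,
                                seed = seed),
                 error = function(e) NULL)
  m <- al$means
  walk <- m$mean_transformed_cue[m$event_type == "walk"]
  stay <- m$mean_transformed_cue[m$event_type == "stay"]
  ok <- is.finite(walk) & is.finite(stay)
  list(mean_slope = mean(sl$slope, na.rm = TRUE),
       walk_minus_stay = mean(walk[ok]) - mean(stay[ok]),
       p_walk_stay = if (is.null(ct)) NA_real_ else ct$p_raw)
}

#' Null calibration study: zero coupling
#'
#' Simulates independent (zero-coupling) groups and pushes each through the
#' full pipeline. With no coupling the mean sensitivity slope should be
#' centered on zero and the walk-vs-stay contrast should reject at its
#' nominal level.
#'
#' @param n_seeds Number of simulated groups.
#' @param n_frames Frames per group.
#' @param seed Master seed.
#' @param alpha Nominal level for the rejection-rate summary.
#' @return List: `mean_slope`, `slope_mc_se` (Monte-Carlo standard error of
#'   the mean slope), `rejection_rate`, `n_seeds`, per-seed vectors.
#' @export
study_null_calibration <- function(n_seeds = 200L, n_frames = 3600L,
                                   seed = 1L, alpha = 0.05) {
  sp <- study_species()
  slopes <- numeric(n_seeds)
  pvals <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, 100L + k)
    rec <- simulate_group(sim_params(sp, n_frames = n_frames, seed = sk))
    res <- analyze_single(rec, seed = sk)
    slopes[k] <- res$mean_slope
    pvals[k] <- res$p_walk_stay
  }
  list(mean_slope = mean(slopes),
       slope_mc_se = stats::sd(slopes) / sqrt(n_seeds),
       rejection_rate = mean(pvals <= alpha, na.rm = TRUE),
       n_seeds = n_seeds, slopes = slopes, pvals = pvals)
}

#' Positive-control study: coupled groups show the walk > stay cue pattern
#'
#' @param n_seeds Number of simulated groups.
#' @param beta Ground-truth walk-onset coupling.
#' @param n_frames Frames per group.
#' @param seed Master seed.
#' @return List: `walk_gt_stay_fraction` (seeds where the mean transformed
#'   cue at walk frames exceeds stay frames), `mean_difference`, `n_seeds`,
#'   per-seed differences.
#' @export
study_positive_control <- function(n_seeds = 20L, beta = 1,
                                   n_frames = 3600L, seed = 1L) {
  sp <- study_species(beta = beta, stop_beta = 0.3)
  constants <- calibrate_cue_constants(
    sim_params(sp, n_frames = n_frames, seed = derive_seed(seed, 200L)))
  diffs <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, 200L + k)
    rec <- simulate_group(sim_params(sp, n_frames = n_frames, seed = sk),
                          cue_constants = constants)
    diffs[k] <- analyze_single(rec, seed = sk)$walk_minus_stay
  }
  list(walk_gt_stay_fraction = mean(diffs > 0),
       mean_difference = mean(diffs), n_seeds = n_seeds, diffs = diffs)
}

#' Monotone parameter-recovery study
#'
#' Simulates groups over a grid of ground-truth couplings (all else equal)
#' and checks, per seeded replicate, that the recovered mean sensitivity
#' slopes are in the same rank order as the couplings.
#'
#' Each replicate is paired -- the same seeds drive the group at every
#' coupling value, so shared realization noise cancels out of the
#' within-replicate rank comparison -- and each replicate's slope estimate
#' aggregates several replicate arenas, as in the live assay where every
#' condition is recorded in 3-5 replicate groups and never estimated from
#' a single arena. Aggregation matters at strong coupling, where
#' self-excited activity makes single-arena slope estimates noisy.
#'
#' @param betas Increasing grid of ground-truth couplings.
#' @param n_seeds Replicates (each evaluated at every coupling).
#' @param n_frames Frames per group.
#' @param seed Master seed.
#' @param arenas_per_estimate Arenas averaged into one replicate's slope
#'   estimate.
#' @return List: `rank_agreement_fraction` (replicates whose slopes are
#'   strictly increasing in beta), `mean_slopes` (per beta), `n_seeds`,
#'   `slopes` matrix (seed x beta).
#' @export
study_monotone_recovery <- function(betas = c(0, 0.5, 1, 2), n_seeds = 20L,
                                    n_frames = 3600L, seed = 1L,
                                    arenas_per_estimate = 3L) {
  slopes <- matrix(NA_real_, n_seeds, length(betas))
  colnames(slopes) <- paste0("beta", betas)
  for (b in seq_along(betas)) {
    sp <- study_species(beta = betas[b])
    constants <- if (betas[b] != 0)
      calibrate_cue_constants(
        sim_params(sp, n_frames = n_frames,
                   seed = derive_seed(seed, 300L + 50L * b)))
    for (k in seq_len(n_seeds)) {
      arena_slopes <- vapply(seq_len(arenas_per_estimate), function(g) {
        # arena seeds shared across the beta grid (paired design)
        sk <- derive_seed(seed, 300L + k * 7L + g)
        rec <- simulate_group(
          sim_params(sp, n_frames = n_frames, seed = sk),
          cue_constants = constants)
        analyze_single(rec, seed = sk)$mean_slope
      }, numeric(1))
      slopes[k, b] <- mean(arena_slopes)
    }
  }
  ordered <- apply(slopes, 1L, function(s) all(diff(s) > 0))
  list(rank_agreement_fraction = mean(ordered),
       mean_slopes = colMeans(slopes), n_seeds = n_seeds, slopes = slopes)
}

# one seed of the two-species single/single/mixed design
simulate_pair_condition <- function(sp_a, sp_b, n_frames, sk, constants) {
  list(
    single_a = simulate_group(
      sim_params(sp_a, n_frames = n_frames, seed = derive_seed(sk, 1L),
                 replicate_id = "single_a"),
      cue_constants = constants$single_a),
    single_b = simulate_group(
      sim_params(sp_b, n_frames = n_frames, seed = derive_seed(sk, 2L),
                 replicate_id = "single_b"),
      cue_constants = constants$single_b),
    mixed = simulate_group(
      sim_params(sp_a, sp_b, n_frames = n_frames,
                 seed = derive_seed(sk, 3L), replicate_id = "mixed"),
      cue_constants = constants$mixed))
}

pair_constants <- function(sp_a, sp_b, n_frames, seed) {
  coupled <- any(c(sp_a$coupling_beta, sp_a$stop_coupling,
                   sp_b$coupling_beta, sp_b$stop_coupling) != 0)
  if (!coupled) return(list(single_a = NULL, single_b = NULL, mixed = NULL))
  list(
    single_a = calibrate_cue_constants(
      sim_params(sp_a, n_frames = n_frames, seed = derive_seed(seed, 11L))),
    single_b = calibrate_cue_constants(
      sim_params(sp_b, n_frames = n_frames, seed = derive_seed(seed, 12L))),
    mixed = calibrate_cue_constants(
      sim_params(sp_a, sp_b, n_frames = n_frames,
                 seed = derive_seed(seed, 13L))))
}

speed_table <- function(rec) {
  individual_mean_speeds(rec, compute_kinematics(rec))
}

#' Group-level convergence study
#'
#' Two species with different baseline speeds, mutually coupled (or not):
#' does mixing shrink the interspecific speed difference? For each seed the
#' design is one single-species group per species plus one mixed group;
#' reported is the fraction of seeds with `delta_mixed < delta_single` and
#' the mean reduction.
#'
#' @param n_seeds Seeds (design replicates).
#' @param beta Mutual coupling; 0 gives the null condition, in which every
#'   coupling (including the stop coupling) is switched off so the two
#'   species are fully independent.
#' @param speeds Median walking speeds (mm/s) of the two species.
#' @param n_frames Frames per group.
#' @param seed Master seed.
#' @return List: `convergence_fraction`, `mean_reduction`,
#'   `reduction_mc_se`, `mean_ratio`, `n_seeds`, per-seed `reductions` and
#'   `ratios`.
#' @export
study_convergence <- function(n_seeds = 20L, beta = 1, speeds = c(1, 4),
                              n_frames = 3600L, seed = 1L) {
  stop_beta <- if (beta == 0) 0 else 0.3
  sp_a <- study_species(speed = speeds[1], beta = beta,
                        stop_beta = stop_beta, name = "spA")
  sp_b <- study_species(speed = speeds[2], beta = beta,
                        stop_beta = stop_beta, name = "spB")
  constants <- pair_constants(sp_a, sp_b, n_frames,
                              derive_seed(seed, 400L))
  reductions <- numeric(n_seeds)
  ratios <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, 400L + k)
    recs <- simulate_pair_condition(sp_a, sp_b, n_frames, sk, constants)
    sa <- speed_table(recs$single_a)
    sb <- speed_table(recs$single_b)
    mx <- speed_table(recs$mixed)
    d_single <- abs(mean(sa$mean_speed) - mean(sb$mean_speed))
    d_mixed <- abs(mean(mx$mean_speed[mx$species == "spA"]) -
                     mean(mx$mean_speed[mx$species == "spB"]))
    reductions[k] <- d_single - d_mixed
    ratios[k] <- if (d_single > 0) d_mixed / d_single else NA_real_
  }
  list(convergence_fraction = mean(reductions > 0),
       mean_reduction = mean(reductions),
       reduction_mc_se = stats::sd(reductions) / sqrt(n_seeds),
       mean_ratio = mean(ratios, na.rm = TRUE),
       n_seeds = n_seeds, reductions = reductions, ratios = ratios)
}

#' Asymmetric-conformity study
#'
#' Pairs a fast, weakly coupled species (the influential-but-insensitive
#' profile) with an intermediate-speed, strongly coupled host and asks which
#' changes more when mixed: in each seed the species-level rates of change
#' (strain-matched, relative) are compared and the host should move more
#' than its partner.
#'
#' @param n_seeds Seeds.
#' @param host,partner [species_params()] for the two roles; defaults take
#'   the host and fastest species from [default_species_panel()].
#' @param n_frames Frames per group.
#' @param seed Master seed.
#' @return List: `host_exceeds_fraction` (seeds with `|rate_host| >
#'   |rate_partner|`), mean absolute rates, `n_seeds`, per-seed rates.
#' @export
study_asymmetry <- function(n_seeds = 20L,
                            host = default_species_panel()$syn_host,
                            partner = default_species_panel()$syn_fast,
                            n_frames = 3600L, seed = 1L) {
  constants <- pair_constants(host, partner, n_frames,
                              derive_seed(seed, 500L))
  rate_host <- numeric(n_seeds)
  rate_partner <- numeric(n_seeds)
  for (k in seq_len(n_seeds)) {
    sk <- derive_seed(seed, 500L + k)
    recs <- simulate_pair_condition(host, partner, n_frames, sk, constants)
    singles <- rbind(speed_table(recs$single_a),
                     speed_table(recs$single_b))
    mixed <- speed_table(recs$mixed)
    sc <- species_level_conformity(singles, mixed)
    ps <- sc$per_species
    rate_host[k] <- ps$rate_of_change[ps$species == host$name]
    rate_partner[k] <- ps$rate_of_change[ps$species == partner$name]
  }
  list(host_exceeds_fraction = mean(abs(rate_host) > abs(rate_partner)),
       mean_abs_rate_host = mean(abs(rate_host)),
       mean_abs_rate_partner = mean(abs(rate_partner)),
       n_seeds = n_seeds, rate_host = rate_host,
       rate_partner = rate_partner)
}
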