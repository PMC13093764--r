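#' Per-individual mean locomotive speed
#'
#' The individual is the statistical unit: every downstream comparison works
#' on means of per-individual means, never on frames. One row per
#' individual.
#'
#' @param rec A `group_recording` (already clipped to its analysis window).
#' @param kin The matching `kinematics_series`.
#' @return data.frame: `individual_id`, `species`, `strain`, `group_type`,
#'   `replicate_id`, `mean_speed` (mm/s).
#' @export
individual_mean_speeds <- function(rec, kin) {
  data.frame(
    individual_id = rec$individual_id,
    species = rec$species,
    strain = rec$strain,
    group_type = rec$group_type,
    replicate_id = rec$replicate_id,
    mean_speed = colMeans(kin$speed_mm_s),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Lagged sensitivity of speed to the visual cue
#'
#' Ordinary least squares of `speed[t + lag]` on `cue[t]` over all valid
#' frames; the default lag of one frame (0.5 s) accounts for the delay
#' before a change in visual information is reflected in behavior. The slope
#' (mm/s per sd of cue) is the individual's sensitivity to the visual cue.
#'
#' @param speed Per-frame speed series, mm/s.
#' @param cue Per-frame transformed (standardized) cue series, same length.
#' @param lag_frames Non-negative integer lag applied to the speed series.
#' @return List of class `sensitivity_estimate`: `slope`, `intercept`,
#'   `r_squared`, `lag_frames`, `n_frames`.
#' @export
lagged_sensitivity <- function(speed, cue, lag_frames = 1L) {
  stopifnot(length(speed) == length(cue), lag_frames >= 0L)
  n <- length(speed)
  if (n <= lag_frames + 2L)
    stop("series too short for the requested lag")
  t0 <- seq_len(n - lag_frames)
  x <- cue[t0]
  y <- speed[t0 + lag_frames]
  vx <- stats::var(x)
  if (!is.finite(vx) || vx == 0) stop("cue series has zero variance")
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  vy <- stats::var(y)
  r2 <- if (vy == 0) 1 else stats::cov(x, y)^2 / (vx * vy)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 lag_frames = as.integer(lag_frames),
                 n_frames = length(t0)),
            class = "sensitivity_estimate")
}

#' Per-individual sensitivity table for a recording
#'
#' An individual whose cue series is degenerate (zero variance -- e.g. a
#' fly that spent the whole window stationary facing away from the group,
#' seeing nothing move) gets `NA` estimates and is flagged rather than
#' aborting the run.
#'
#' @param rec A `group_recording`.
#' @param kin The matching `kinematics_series`.
#' @param cue A transformed `cue_series`.
#' @param lag_frames Lag in frames (default 1 = 0.5 s).
#' @return data.frame: `individual_id`, `species`, `strain`, `group_type`,
#'   `replicate_id`, `slope`, `intercept`, `r_squared`, `lag_frames`.
#' @export
sensitivity_table <- function(rec, kin, cue, lag_frames = 1L) {
  est <- lapply(seq_along(rec$individual_id), function(i)
    tryCatch(lagged_sensitivity(kin$speed_mm_s[, i], cue$transformed[, i],
                                lag_frames),
             error = function(e) NULL))
  degenerate <- vapply(est, is.null, logical(1))
  if (any(degenerate))
    warning(sprintf("degenerate cue series, sensitivity set to NA for: %s",
                    paste(rec$individual_id[degenerate], collapse = ", ")))
  pick <- function(f) vapply(est, function(e)
    if (is.null(e)) NA_real_ else e[[f]], numeric(1))
  data.frame(
    individual_id = rec$individual_id,
    species = rec$species,
    strain = rec$strain,
    group_type = rec$group_type,
    replicate_id = rec$replicate_id,
    slope = pick("slope"),
    intercept = pick("intercept"),
    r_squared = pick("r_squared"),
    lag_frames = as.integer(lag_frames),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Species-level conformity: rate of change single-to-mixed
#'
#' For each species the rate of change of mean locomotive speed from
#' single-species to mixed-species groups, strain-matched: every mixed-group
#' strain is baselined against the same strain's single-group mean. The
#' default `"relative"` method reports `(mixed - single) / single` (0 = no
#' change, positive = faster in mixed); `"ratio"` reports `mixed / single`.
#'
#' @param single_means,mixed_means [individual_mean_speeds()] tables from
#'   single- and mixed-species groups; species and strains must match.
#' @param method `"relative"` (default) or `"ratio"`.
#' @return List of class `species_conformity`: `per_strain` (species,
#'   strain, single and mixed means, n, rate_of_change), `per_species`
#'   (species, rate_of_change aggregated over strains), `per_individual`
#'   (each mixed individual's rate against its strain baseline).
#' @export
species_level_conformity <- function(single_means, mixed_means,
                                     method = c("relative", "ratio")) {
  method <- match.arg(method)
  if (!nrow(single_means) || !nrow(mixed_means))
    stop("single and mixed speed tables must be non-empty")
  skey <- paste(single_means$species, single_means$strain, sep = "\r")
  mkey <- paste(mixed_means$species, mixed_means$strain, sep = "\r")
  missing_base <- setdiff(unique(mkey), unique(skey))
  if (length(missing_base))
    stop(sprintf("no single-group baseline for strain(s): %s",
                 paste(gsub("\r", "/", missing_base), collapse = ", ")))
  base_mean <- tapply(single_means$mean_speed, skey, mean)
  if (any(base_mean[unique(mkey)] == 0))
    stop("single-group baseline mean speed is zero")
  rate_fun <- switch(method,
    relative = function(mx, s) (mx - s) / s,
    ratio = function(mx, s) mx / s)

  mix_mean <- tapply(mixed_means$mean_speed, mkey, mean)
  mix_n <- tapply(mixed_means$mean_speed, mkey, length)
  keys <- sort(unique(mkey))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  per_strain <- data.frame(
    species = vapply(parts, `[`, character(1), 1L),
    strain = vapply(parts, `[`, character(1), 2L),
    mean_speed_single = as.numeric(base_mean[keys]),
    mean_speed_mixed = as.numeric(mix_mean[keys]),
    n_single = as.integer(tapply(single_means$mean_speed, skey,
                                 length)[keys]),
    n_mixed = as.integer(mix_n[keys]),
    rate_of_change = rate_fun(as.numeric(mix_mean[keys]),
                              as.numeric(base_mean[keys])),
    stringsAsFactors = FALSE, row.names = NULL)
  per_species <- stats::aggregate(rate_of_change ~ species, per_strain, mean)
  per_individual <- data.frame(
    individual_id = mixed_means$individual_id,
    species = mixed_means$species,
    strain = mixed_means$strain,
    rate_of_change = rate_fun(mixed_means$mean_speed,
                              as.numeric(base_mean[mkey])),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_strain = per_strain, per_species = per_species,
                 per_individual = per_individual, method = method),
            class = "species_conformity")
}

#' Group-level conformity: reduction of the interspecific speed difference
#'
#' Compares the absolute difference of the two species' mean locomotive
#' speeds in single-species groups (`delta_single`) with the difference in
#' mixed-species groups (`delta_mixed`). Convergence means the mixed-group
#' difference shrinks: reduction `delta_single - delta_mixed` > 0, ratio
#' `delta_mixed / delta_single` < 1. A permutation test relabels group type
#' within each species and reports the one-sided p for a positive
#' reduction.
#'
#' @param single_a,single_b,mixed_a,mixed_b [individual_mean_speeds()] rows
#'   for species A and B in single and mixed groups.
#' @param n_perm Number of relabeling permutations.
#' @param seed Integer seed.
#' @return One-row data.frame of class `group_conformity`: species labels,
#'   `delta_single`, `delta_mixed`, `reduction`, `ratio`, `p_reduction`,
#'   `n_perm`, `seed`.
#' @export
group_level_conformity <- function(single_a, single_b, mixed_a, mixed_b,
                                   n_perm = 999L, seed = 1L) {
  for (tab in list(single_a, single_b, mixed_a, mixed_b))
    if (!nrow(tab)) stop("all four speed tables must be non-empty")
  sp_a <- unique(c(single_a$species, mixed_a$species))
  sp_b <- unique(c(single_b$species, mixed_b$species))
  if (length(sp_a) != 1L || length(sp_b) != 1L)
    stop("each table must contain exactly one species")
  delta <- function(sa, sb, ma, mb)
    c(single = abs(mean(sa) - mean(sb)), mixed = abs(mean(ma) - mean(mb)))
  obs <- delta(single_a$mean_speed, single_b$mean_speed,
               mixed_a$mean_speed, mixed_b$mean_speed)
  red_obs <- obs[["single"]] - obs[["mixed"]]

  pool_a <- c(single_a$mean_speed, mixed_a$mean_speed)
  pool_b <- c(single_b$mean_speed, mixed_b$mean_speed)
  na_s <- length(single_a$mean_speed)
  nb_s <- length(single_b$mean_speed)
  set.seed(seed)
  red_perm <- replicate(n_perm, {
    ia <- sample.int(length(pool_a), na_s)
    ib <- sample.int(length(pool_b), nb_s)
    d <- delta(pool_a[ia], pool_b[ib], pool_a[-ia], pool_b[-ib])
    d[["single"]] - d[["mixed"]]
  })
  p <- (1 + sum(red_perm >= red_obs - 1e-12)) / (n_perm + 1)
  structure(data.frame(
    species_a = sp_a, species_b = sp_b,
    delta_single = obs[["single"]], delta_mixed = obs[["mixed"]],
    reduction = red_obs,
    ratio = if (obs[["single"]] > 0) obs[["mixed"]] / obs[["single"]]
            else NA_real_,
    p_reduction = p, n_perm = as.integer(n_perm), seed = as.integer(seed),
    stringsAsFactors = FALSE),
    class = c("group_conformity", "data.frame"))
}

# one-way ANOVA F statistic; returns 0 for zero total variance
oneway_f <- function(values, labels) {
  labels <- factor(labels)
  n <- length(values)
  k <- nlevels(labels)
  grand <- mean(values)
  gm <- tapply(values, labels, mean)
  gn <- tapply(values, labels, length)
  ss_between <- sum(gn * (gm - grand)^2)
  ss_within <- sum((values - gm[labels])^2)
  if (ss_between + ss_within <= 0) return(0)
  if (ss_within == 0) return(Inf)
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Compare sensitivity slopes across species and group types
#'
#' Permutation one-way F tests on individual-level sensitivity slopes:
#' labels (species, then group type) are shuffled across individuals and the
#' observed ANOVA F is compared with its permutation null.
#'
#' @param estimates A [sensitivity_table()]-style data.frame with columns
#'   `slope`, `species`, `group_type`.
#' @param n_perm Number of permutations per factor.
#' @param seed Integer seed.
#' @return data.frame, one row per factor: `factor`, `n_levels`,
#'   `f_statistic`, `p_value`, `n_perm`, `seed`.
#' @export
sensitivity_comparison <- function(estimates, n_perm = 999L, seed = 1L) {
  estimates <- estimates[is.finite(estimates$slope), , drop = FALSE]
  out <- list()
  set.seed(seed)
  for (fac in c("species", "group_type")) {
    labels <- factor(estimates[[fac]])
    if (nlevels(labels) < 2L) next
    if (any(table(labels) < 2L))
      stop(sprintf("every %s stratum needs >= 2 individuals", fac))
    f_obs <- oneway_f(estimates$slope, labels)
    if (f_obs == 0) {
      p <- 1
    } else {
      f_perm <- replicate(n_perm,
                          oneway_f(estimates$slope, sample(labels)))
      p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_perm + 1)
    }
    out[[fac]] <- data.frame(
      factor = fac, n_levels = nlevels(labels), f_statistic = f_obs,
      p_value = p, n_perm = as.integer(n_perm), seed = as.integer(seed),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("need >= 2 levels in species or group_type")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
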