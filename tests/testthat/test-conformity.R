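test_that("individual mean speeds are per-individual frame averages", {
  n_fr <- 20
  kin <- list(speed_mm_s = cbind(rep(3, n_fr),
                                 rep(c(0, 4), n_fr / 2)))
  rec <- make_rec(matrix(0, n_fr, 2), matrix(0, n_fr, 2),
                  species = c("spA", "spA"))
  tab <- individual_mean_speeds(rec, kin)
  expect_equal(tab$mean_speed, c(3, 2))
  expect_equal(tab$species, c("spA", "spA"))
})

test_that("simulated mean speed matches the Markov x lognormal expectation", {
  # with zero coupling the walking fraction is w/(w+s) and the mean walking
  # speed is exp(mu_log + sigma^2/2); recorded mean speed should sit within
  # Monte-Carlo error of their product (wall reflections shave a little)
  sp <- species_params("spA", base_walk_rate = 0.05, base_stop_rate = 0.10,
                       walk_speed_mu_mm_s = 2, walk_speed_sigma = 0.2)
  p <- sim_params(sp, n_frames = 3600, seed = 41)
  rec <- simulate_group(p)
  kin <- compute_kinematics(rec)
  tab <- individual_mean_speeds(rec, kin)
  expected <- (0.05 / 0.15) * exp(log(2) + 0.2^2 / 2)
  mc_sd <- sd(tab$mean_speed) / sqrt(nrow(tab))
  expect_lt(abs(mean(tab$mean_speed) - expected), 3 * mc_sd)
})

test_that("lagged sensitivity recovers exact linear relations", {
  set.seed(42)
  cue <- rnorm(300)
  speed <- c(0, 2 * cue[-300])        # speed[t+1] = 2 * cue[t]
  est <- lagged_sensitivity(speed, cue, lag_frames = 1)
  expect_equal(est$slope, 2, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)

  # lag 0 of a series on itself gives slope 1
  est0 <- lagged_sensitivity(cue, cue, lag_frames = 0)
  expect_equal(est0$slope, 1, tolerance = 1e-12)

  expect_error(lagged_sensitivity(speed, rep(1, 300)), "zero variance")
  expect_error(lagged_sensitivity(speed[1:3], cue[1:3], lag_frames = 2),
               "too short")
})

test_that("lagged sensitivity equals the covariance oracle and lm", {
  set.seed(43)
  for (i in 1:10) {
    n <- 120
    cue <- rnorm(n)
    speed <- pmax(0, 1 + 0.7 * c(0, cue[-n]) + rnorm(n, sd = 0.5))
    est <- lagged_sensitivity(speed, cue, 1)
    x <- cue[1:(n - 1)]
    y <- speed[2:n]
    # brute-force covariance oracle from explicit sums
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxx <- sum((x - mean(x))^2)
    expect_equal(est$slope, sxy / sxx, tolerance = 1e-12)
    fit <- stats::lm(y ~ x)
    expect_equal(est$slope, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(est$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(est$r_squared, summary(fit)$r.squared, tolerance = 1e-10)
  }
})

test_that("null slopes are centered on zero when cue is independent", {
  set.seed(44)
  slopes <- replicate(200, {
    cue <- rnorm(150)
    speed <- rexp(150)
    lagged_sensitivity(speed, cue, 1)$slope
  })
  expect_lt(abs(mean(slopes)), 2 * sd(slopes) / sqrt(200))
})

test_that("species-level conformity is strain-matched and signed", {
  single <- data.frame(
    individual_id = sprintf("s%02d", 1:8),
    species = "spA", strain = rep(c("x", "y"), each = 4),
    mean_speed = rep(c(2, 4), each = 4))
  mixed <- data.frame(
    individual_id = sprintf("m%02d", 1:8),
    species = "spA", strain = rep(c("x", "y"), each = 4),
    mean_speed = rep(c(3, 3), each = 4))
  sc <- species_level_conformity(single, mixed)
  ps <- sc$per_strain
  expect_equal(ps$rate_of_change[ps$strain == "x"], 0.5)    # 2 -> 3
  expect_equal(ps$rate_of_change[ps$strain == "y"], -0.25)  # 4 -> 3
  expect_equal(sc$per_species$rate_of_change, mean(c(0.5, -0.25)))

  # identical means: rate 0
  sc0 <- species_level_conformity(single, transform(
    single, individual_id = sprintf("m%02d", 1:8)))
  expect_equal(sc0$per_strain$rate_of_change, c(0, 0))

  # ratio method
  scr <- species_level_conformity(single, mixed, method = "ratio")
  expect_equal(scr$per_strain$rate_of_change[ps$strain == "x"], 1.5)

  # unmatched strain and zero baseline are errors
  bad <- transform(mixed, strain = "z")
  expect_error(species_level_conformity(single, bad), "baseline")
  zero <- transform(single, mean_speed = 0)
  expect_error(species_level_conformity(zero, mixed), "zero")
})

test_that("conformity rate obeys the exchange identity", {
  # rate(a,b) = -rate(b,a) * mean_b / mean_a for the relative method
  set.seed(45)
  for (i in 1:10) {
    ma <- runif(1, 1, 5)
    mb <- runif(1, 1, 5)
    ta <- data.frame(individual_id = "a1", species = "sp", strain = "x",
                     mean_speed = ma)
    tb <- data.frame(individual_id = "b1", species = "sp", strain = "x",
                     mean_speed = mb)
    r_ab <- species_level_conformity(ta, tb)$per_strain$rate_of_change
    r_ba <- species_level_conformity(tb, ta)$per_strain$rate_of_change
    expect_equal(r_ab, -r_ba * mb / ma, tolerance = 1e-12)
  }
})

test_that("group-level conformity reports deltas, ratio and convergence p", {
  tab <- function(sp, v) data.frame(
    individual_id = sprintf("%s%02d", sp, seq_along(v)), species = sp,
    strain = "x", mean_speed = v)
  g <- group_level_conformity(tab("a", rep(5, 6)), tab("b", rep(1, 6)),
                              tab("a", rep(3.2, 6)), tab("b", rep(2.7, 6)),
                              n_perm = 499, seed = 7)
  expect_equal(g$delta_single, 4)
  expect_equal(g$delta_mixed, 0.5)
  expect_equal(g$reduction, 3.5)
  expect_equal(g$ratio, 0.125)
  expect_lt(g$p_reduction, 0.05)

  # identical species: both deltas zero
  g0 <- group_level_conformity(tab("a", rep(2, 4)), tab("b", rep(2, 4)),
                               tab("a", rep(2, 4)), tab("b", rep(2, 4)),
                               n_perm = 199)
  expect_equal(g0$delta_single, 0)
  expect_equal(g0$delta_mixed, 0)
  expect_true(is.na(g0$ratio))

  expect_error(
    group_level_conformity(tab("a", 1:3), tab("b", 1:3), tab("a", 1:3),
                           tab("b", 1:3)[0, ]),
    "non-empty")
})

test_that("sensitivity comparison: degenerate F, invariance and power", {
  est_eq <- data.frame(slope = rep(0.3, 12),
                       species = rep(c("a", "b"), 6),
                       group_type = rep(c("single", "mixed"), each = 6))
  res <- sensitivity_comparison(est_eq, n_perm = 199, seed = 3)
  expect_equal(res$f_statistic, c(0, 0))
  expect_equal(res$p_value, c(1, 1))

  # power: species slopes shifted by 1 sd at n = 24/species
  set.seed(46)
  hits <- replicate(40, {
    est <- data.frame(
      slope = c(rnorm(24, 0, 1), rnorm(24, 1, 1)),
      species = rep(c("a", "b"), each = 24),
      group_type = "single")
    est$group_type <- rep(c("single", "mixed"), 24)
    sensitivity_comparison(est, n_perm = 199, seed = 9)[1, "p_value"] < 0.05
  })
  expect_gt(mean(hits), 0.8)

  expect_error(
    sensitivity_comparison(data.frame(slope = 1:3,
                                      species = c("a", "a", "b"),
                                      group_type = "single"),
                           n_perm = 99),
    ">= 2 individuals")
})
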