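test_that("state classification thresholds and absorbs short bouts", {
  expect_equal(classify_states(c(0, 0, 5, 5, 0, 0), 2, 1),
               c("stationary", "stationary", "walking", "walking",
                 "stationary", "stationary"))
  # single-frame walking run absorbed into the surrounding stationary state
  expect_equal(classify_states(c(0, 5, 0, 0), 2, 2),
               rep("stationary", 4))
  # hand-traced absorption: runs S2,W1,S1,W3 with min_bout 2 ->
  # W1 absorbed into S (making S4), then S1 was already consumed?  No:
  # left-to-right: S2 kept; W1 < 2 -> absorbed -> S3; S1 < 2 -> absorbed
  # into S (same state) -> S4; W3 kept
  expect_equal(classify_states(c(0, 0, 5, 0, 5, 5, 5), 2, 2),
               c(rep("stationary", 4), rep("walking", 3)))
  expect_equal(classify_states(rep(9, 5), 2, 2), rep("walking", 5))
  expect_error(classify_states(numeric(0)), "empty")
})

test_that("state classification is idempotent on its own output", {
  set.seed(21)
  for (i in 1:20) {
    speed <- rexp(60, 0.3)
    st <- classify_states(speed, 2, 3)
    implied <- ifelse(st == "walking", 4, 0)
    expect_identical(classify_states(implied, 2, 3), st)
  }
})

test_that("event labels match the definitional truth table exhaustively", {
  # every stationary/walking sequence up to length 8 against the literal
  # per-frame definition
  for (n in 1:8) {
    combos <- expand.grid(rep(list(c("stationary", "walking")), n),
                          stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      states <- as.character(combos[r, ])
      expect_identical(label_events(states), oracle_label_events(states))
    }
  }
})

test_that("event labels follow the transition definitions on key cases", {
  expect_equal(label_events(c("stationary", "stationary", "walking",
                              "walking", "stationary")),
               c("stay", "walk", "walking", "stop", "stay"))
  expect_equal(label_events(rep("stationary", 4)), rep("stay", 4))
  # alternating S,W,S,W: every S precedes a walk onset, every W (but the
  # last frame) precedes a stop
  expect_equal(label_events(c("stationary", "walking", "stationary",
                              "walking")),
               c("walk", "stop", "walk", "walking"))
  # final frame can never be walk or stop
  expect_false(label_events(c("walking", "stationary"))[2] %in%
                 c("walk", "stop"))
})

test_that("event counts track state transitions", {
  set.seed(22)
  for (i in 1:20) {
    states <- sample(c("stationary", "walking"), 50, replace = TRUE)
    ev <- label_events(states)
    expect_equal(length(ev), 50)
    n_sw <- sum(states[-50] == "stationary" & states[-1] == "walking")
    n_ws <- sum(states[-50] == "walking" & states[-1] == "stationary")
    expect_equal(sum(ev == "walk"), n_sw)
    expect_equal(sum(ev == "stop"), n_ws)
    expect_lte(abs(sum(ev == "walk") - sum(ev == "stop")), 1)
  }
  # monotone speed ramp: exactly one walk onset, no stop
  ev <- label_events(classify_states(seq(0, 10, length.out = 21), 2, 1))
  expect_equal(sum(ev == "walk"), 1)
  expect_equal(sum(ev == "stop"), 0)
})

test_that("event-aligned cues collect the right frames", {
  # constant cue: every event type has that mean
  n_fr <- 30
  speed <- rep(c(0, 0, 4, 4), length.out = n_fr)
  x <- matrix(cumsum(c(0, speed[-n_fr])) * 0.5, ncol = 1)
  rec <- make_rec(x / 10, matrix(0, n_fr, 1), species = "spA")
  kin <- compute_kinematics(rec)
  kin$speed_mm_s[, 1] <- speed
  st <- compute_states(kin)
  cue <- structure(list(raw = matrix(1, n_fr, 1),
                        transformed = matrix(0.7, n_fr, 1),
                        config = cue_config()), class = "cue_series")
  al <- event_aligned_cues(cue, st, rec)
  got <- al$means[al$means$n_frames > 0, ]
  expect_true(all(abs(got$mean_transformed_cue - 0.7) < 1e-12))

  # a cue stepping up exactly one frame before each walk onset separates
  # walk from stay
  z <- rep(0, n_fr)
  onsets <- which(label_events(st$state[, 1]) == "walk")
  z[onsets] <- 3
  cue$transformed <- matrix(z, ncol = 1)
  al2 <- event_aligned_cues(cue, st, rec)
  m <- al2$means
  expect_gt(m$mean_transformed_cue[m$event_type == "walk"],
            m$mean_transformed_cue[m$event_type == "stay"])

  # an individual with no stop events is flagged empty, not an error
  kin$speed_mm_s[, 1] <- seq(0, 5, length.out = n_fr)
  st2 <- compute_states(kin)
  al3 <- event_aligned_cues(cue, st2, rec)
  stop_row <- al3$means[al3$means$event_type == "stop", ]
  expect_equal(stop_row$n_frames, 0L)
  expect_true(is.na(stop_row$mean_transformed_cue))
})

test_that("sign-flip contrast: exact minimum p, Bonferroni, null behavior", {
  # +1 shift for walk in all n individuals: minimal two-sided p = 2/2^n
  n <- 10
  means <- data.frame(
    individual_id = rep(sprintf("f%02d", 1:n), 2),
    event_type = rep(c("walk", "stay"), each = n),
    n_frames = 5L,
    mean_transformed_cue = c(rep(1, n), rep(0, n)))
  ct <- event_contrast(means, c("walk", "stay"), n_perm = 999, seed = 1)
  expect_equal(ct$estimate, 1)
  expect_equal(ct$p_raw, 2 / 2^n)
  expect_match(ct$method, "exact")

  # Bonferroni multiplies by the family size, capped at 1
  ct4 <- event_contrast(means, c("walk", "stay"), n_contrasts = 4)
  expect_equal(ct4$p_bonferroni, 4 * ct4$p_raw)
  ct_cap <- event_contrast(
    transform(means, mean_transformed_cue = c(rep(0.001, n), rep(0, n)) *
                rep(c(1, -1), length.out = 2 * n)),
    c("walk", "stay"), n_contrasts = 1e6)
  expect_equal(ct_cap$p_bonferroni, 1)

  # identical distributions: difference 0
  null_means <- transform(means, mean_transformed_cue = rep(0.4, 2 * n))
  ct0 <- event_contrast(null_means, c("walk", "stay"))
  expect_equal(ct0$estimate, 0)
  expect_equal(ct0$p_raw, 1)

  expect_error(event_contrast(means[c(1, n + 1), ], c("walk", "stay")),
               ">= 2 individuals")
  expect_warning(event_contrast(means, c("walk", "stay"), n_perm = 50),
                 "n_perm")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(23)
  n <- 12
  pvals <- replicate(200, {
    means <- data.frame(
      individual_id = rep(sprintf("f%02d", 1:n), 2),
      event_type = rep(c("walk", "stay"), each = n),
      n_frames = 5L,
      mean_transformed_cue = rnorm(2 * n))
    event_contrast(means, c("walk", "stay"))$p_raw
  })
  # rejection rate at 5% within 2 binomial MC sd of nominal
  rate <- mean(pvals <= 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})
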