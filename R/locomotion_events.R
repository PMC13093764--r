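#' Classify a speed series into walking and stationary states
#'
#' A frame is walking when its speed is at or above the walking threshold.
#' Runs (bouts) shorter than `min_bout_frames` are then absorbed into the
#' preceding state in a single left-to-right pass (the first run is exempt
#' because it has no predecessor). The default minimum bout of 2 frames
#' (1 s) absorbs single-frame flicker: instantaneous walking speeds
#' fluctuate, so a walker briefly dipping below the threshold would
#' otherwise register a spurious stop-and-restart, which distorts
#' event-aligned statistics. The pass is deterministic.
#'
#' @param speed Non-negative numeric speed series, mm/s.
#' @param walk_threshold_mm_s Walking-speed threshold, mm/s.
#' @param min_bout_frames Minimum run length kept as its own bout; 1 keeps
#'   the raw thresholding.
#' @return Character vector, per frame, of `"stationary"` / `"walking"`.
#' @export
classify_states <- function(speed, walk_threshold_mm_s = 2.0,
                            min_bout_frames = 2L) {
  if (!length(speed)) stop("empty speed series")
  stopifnot(min_bout_frames >= 1L, walk_threshold_mm_s > 0)
  walking <- speed >= walk_threshold_mm_s
  if (min_bout_frames > 1L) {
    r <- rle(walking)
    vals <- r$values
    lens <- r$lengths
    out_v <- vals[1L]
    out_l <- lens[1L]
    for (k in seq_along(vals)[-1L]) {
      v <- vals[k]
      last <- length(out_v)
      if (lens[k] < min_bout_frames) v <- out_v[last]   # absorb short run
      if (v == out_v[last]) {
        out_l[last] <- out_l[last] + lens[k]
      } else {
        out_v <- c(out_v, v)
        out_l <- c(out_l, lens[k])
      }
    }
    walking <- inverse.rle(list(values = out_v, lengths = out_l))
  }
  ifelse(walking, "walking", "stationary")
}

#' Label locomotion events from a state series
#'
#' The frame immediately preceding a stationary-to-walking transition is a
#' "walk" event; the frame immediately preceding a walking-to-stationary
#' transition is a "stop" event. All remaining walking frames are "walking"
#' and all remaining stationary frames are "stay". Every frame gets exactly
#' one label and the final frame can never be "walk" or "stop".
#'
#' @param states Character vector of `"stationary"` / `"walking"`.
#' @return Character vector of `"stay"`, `"walk"`, `"walking"`, `"stop"`.
#' @export
label_events <- function(states) {
  n <- length(states)
  ev <- ifelse(states == "walking", "walking", "stay")
  if (n >= 2L) {
    cur <- states[-n]
    nxt <- states[-1L]
    walk_idx <- which(cur == "stationary" & nxt == "walking")
    stop_idx <- which(cur == "walking" & nxt == "stationary")
    ev[walk_idx] <- "walk"
    ev[stop_idx] <- "stop"
  }
  ev
}

#' Per-individual states and events for a recording
#'
#' Applies [classify_states()] and [label_events()] to every individual's
#' speed series.
#'
#' @param kin A `kinematics_series`.
#' @param walk_threshold_mm_s,min_bout_frames See [classify_states()].
#' @return List of class `state_series` with `state` and `event` character
#'   matrices (`n_frames x n_individuals`) and the parameters used.
#' @export
compute_states <- function(kin, walk_threshold_mm_s = 2.0,
                           min_bout_frames = 2L) {
  state <- apply(kin$speed_mm_s, 2L, classify_states,
                 walk_threshold_mm_s = walk_threshold_mm_s,
                 min_bout_frames = min_bout_frames)
  event <- apply(state, 2L, label_events)
  dim(state) <- dim(kin$speed_mm_s)
  dim(event) <- dim(kin$speed_mm_s)
  structure(list(state = state, event = event,
                 walk_threshold_mm_s = walk_threshold_mm_s,
                 min_bout_frames = min_bout_frames),
            class = "state_series")
}

EVENT_TYPES <- c("stay", "walk", "walking", "stop")

#' Cue values aligned to locomotion events
#'
#' For each individual and event type, collects the transformed cue at every
#' frame carrying that label, and summarizes per-individual means. An
#' individual with no events of some type gets an `NA` mean with
#' `n_frames = 0` (flagged, not an error).
#'
#' @param cue A transformed `cue_series`.
#' @param states A `state_series` frame-aligned with `cue`.
#' @param rec The matching `group_recording`.
#' @return List of class `event_cues` with `means` (data.frame:
#'   `individual_id`, `species`, `strain`, `group_type`, `event_type`,
#'   `n_frames`, `mean_transformed_cue`) and `values` (long data.frame of
#'   the pooled per-frame cue values by individual and event type).
#' @export
event_aligned_cues <- function(cue, states, rec) {
  if (is.null(cue$transformed))
    stop("cue series must be transformed before event alignment")
  n_ind <- length(rec$individual_id)
  ev_flat <- factor(as.vector(states$event), levels = EVENT_TYPES)
  id_flat <- rep(rec$individual_id, each = nrow(cue$transformed))
  z_flat <- as.vector(cue$transformed)

  values <- data.frame(individual_id = id_flat,
                       event_type = as.character(ev_flat),
                       cue = z_flat, stringsAsFactors = FALSE)

  grid <- expand.grid(individual_id = rec$individual_id,
                      event_type = EVENT_TYPES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(id_flat, as.character(ev_flat), sep = "\r")
  n_by <- tapply(z_flat, key, length)
  m_by <- tapply(z_flat, key, mean)
  gkey <- paste(grid$individual_id, grid$event_type, sep = "\r")
  grid$n_frames <- as.integer(ifelse(is.na(n_by[gkey]), 0L, n_by[gkey]))
  grid$mean_transformed_cue <- as.numeric(m_by[gkey])
  idx <- match(grid$individual_id, rec$individual_id)
  means <- data.frame(
    individual_id = grid$individual_id,
    species = rec$species[idx],
    strain = rec$strain[idx],
    group_type = rec$group_type,
    event_type = grid$event_type,
    n_frames = grid$n_frames,
    mean_transformed_cue = grid$mean_transformed_cue,
    stringsAsFactors = FALSE)
  means <- means[order(match(means$individual_id, rec$individual_id),
                       match(means$event_type, EVENT_TYPES)), ]
  rownames(means) <- NULL
  structure(list(means = means, values = values), class = "event_cues")
}

#' Paired event contrast by sign-flip permutation
#'
#' Tests whether the per-individual mean cue differs between two event types
#' using the paired difference of per-individual means. The null is built by
#' sign-flipping each individual's difference; when the number of
#' individuals is small enough all 2^n sign patterns are enumerated exactly
#' (so the smallest attainable two-sided p is 2/2^n), otherwise `n_perm`
#' random flips are drawn. The Bonferroni-adjusted p multiplies the raw p by
#' the number of contrasts in the family, capped at 1.
#'
#' @param aligned An `event_cues` object (or its `means` data.frame).
#' @param pair Character vector of two event types, contrast is
#'   `pair[1] - pair[2]`.
#' @param n_perm Number of random permutations when exact enumeration is not
#'   feasible; values below 100 trigger a warning.
#' @param seed Integer seed for the random permutations.
#' @param n_contrasts Family size for the Bonferroni correction.
#' @return One-row data.frame: `contrast`, `estimate`, `n_individuals`,
#'   `p_raw`, `p_bonferroni`, `method`, `n_perm`, `seed`.
#' @export
event_contrast <- function(aligned, pair = c("walk", "stay"),
                           n_perm = 999L, seed = 1L, n_contrasts = 1L) {
  means <- if (inherits(aligned, "event_cues")) aligned$means else aligned
  stopifnot(length(pair) == 2L, all(pair %in% EVENT_TYPES))
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse permutation p")
  a <- means[means$event_type == pair[1L] & means$n_frames > 0L, ]
  b <- means[means$event_type == pair[2L] & means$n_frames > 0L, ]
  ids <- intersect(a$individual_id, b$individual_id)
  if (length(ids) < 2L)
    stop(sprintf("contrast %s-%s needs >= 2 individuals with both events",
                 pair[1L], pair[2L]))
  d <- a$mean_transformed_cue[match(ids, a$individual_id)] -
       b$mean_transformed_cue[match(ids, b$individual_id)]
  n <- length(d)
  obs <- mean(d)
  exact <- n <= 14L && 2^n <= max(4096L, n_perm + 1L)
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_perm <- as.vector(signs %*% d) / n
    p <- mean(abs(t_perm) >= abs(obs) - 1e-12)
    method <- "exact sign-flip"
    n_used <- 2L^n
  } else {
    set.seed(seed)
    t_perm <- replicate(n_perm,
                        mean(d * sample(c(-1, 1), n, replace = TRUE)))
    p <- (1 + sum(abs(t_perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
    method <- "monte-carlo sign-flip"
    n_used <- as.integer(n_perm)
  }
  data.frame(contrast = paste(pair, collapse = "-"),
             estimate = obs, n_individuals = n,
             p_raw = p, p_bonferroni = min(1, p * n_contrasts),
             method = method, n_perm = n_used, seed = as.integer(seed),
             stringsAsFactors = FALSE)
}
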