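#' Visual-cue configuration
#'
#' Parameters of the visual-cue model. The fly body is approximated as an
#' ellipse (major axis 3.0 mm, minor axis 1.5 mm); the major axis is used as
#' the apparent width in the angular term for every neighbor regardless of
#' its orientation, and the minor axis is stored but does not enter the cue.
#'
#' @param body_major_mm Apparent body width used in the angular term, mm.
#' @param body_minor_mm Body minor axis, mm (stored, unused in the cue).
#' @param distance_clamp_mm Pair distances below this value are clamped
#'   before the angular term, preventing unbounded terms from tracking
#'   jitter at near-contact; default half the minor axis.
#' @param heading_source `"displacement"` (default) derives headings from the
#'   displacement vector even when a tracker heading is on file;
#'   `"file"` uses the recording's heading matrix when present.
#' @param standardize_pool Stratum for the log/z-score transform:
#'   `"stratum"` (species x group type, default) or `"species"` (pooled
#'   across group types).
#' @param stationary_epsilon_mm Displacements below this are treated as
#'   stationary for heading estimation; the last defined heading is carried
#'   forward.
#' @return An object of class `cue_config`.
#' @export
cue_config <- function(body_major_mm = 3.0, body_minor_mm = 1.5,
                       distance_clamp_mm = body_minor_mm / 2,
                       heading_source = c("displacement", "file"),
                       standardize_pool = c("stratum", "species"),
                       stationary_epsilon_mm = 0.25) {
  structure(list(
    body_major_mm = body_major_mm,
    body_minor_mm = body_minor_mm,
    distance_clamp_mm = distance_clamp_mm,
    heading_source = match.arg(heading_source),
    standardize_pool = match.arg(standardize_pool),
    stationary_epsilon_mm = stationary_epsilon_mm
  ), class = "cue_config")
}

carry_forward <- function(v) {
  # last-observation-carried-forward; leading NAs backfilled with the first
  # defined value; all-NA input stays NA
  ok <- !is.na(v)
  if (!any(ok)) return(v)
  idx <- cumsum(ok)
  first <- which(ok)[1L]
  idx[idx == 0L] <- 1L
  v[ok][idx]
}

#' Per-frame speed and heading from a recording
#'
#' Speeds are forward differences of position divided by the frame interval:
#' `speed[t] = |pos[t+1] - pos[t]| / dt`; the last frame carries the previous
#' value so the series stays aligned with the cue. Heading at frame t is the
#' direction of the displacement vector arriving at t (the most recent
#' movement -- the orientation the individual has when it sees the frame-t
#' cue; using the outgoing step instead would leak the individual's next
#' move into its own cue). When the incoming displacement is below the
#' stationary epsilon the last defined heading is carried forward; initial
#' frames with no defined heading are backfilled with the first defined one,
#' and an individual that never moves gets heading 0.
#'
#' @param rec A `group_recording` with at least 2 frames.
#' @param config A [cue_config()].
#' @return List of class `kinematics_series` with `speed_mm_s` and
#'   `heading_rad` matrices (`n_frames x n_individuals`).
#' @export
compute_kinematics <- function(rec, config = cue_config()) {
  n_fr <- rec$n_frames
  if (n_fr < 2L) stop("kinematics need at least 2 frames")
  dt <- rec$arena$frame_interval_s
  n_ind <- length(rec$individual_id)
  dx <- rec$x[-1L, , drop = FALSE] - rec$x[-n_fr, , drop = FALSE]
  dy <- rec$y[-1L, , drop = FALSE] - rec$y[-n_fr, , drop = FALSE]
  step <- sqrt(dx^2 + dy^2)
  speed <- rbind(step, step[n_fr - 1L, ]) / dt

  if (config$heading_source == "file" && !is.null(rec$heading)) {
    heading <- rec$heading
  } else {
    heading <- atan2(dy, dx)
    heading[step < config$stationary_epsilon_mm] <- NA_real_
    # the step from t to t+1 defines the heading AT t+1 (incoming movement)
    heading <- rbind(NA_real_, heading)
    heading <- apply(heading, 2L, carry_forward)
    heading[is.na(heading)] <- 0
    dim(heading) <- c(n_fr, n_ind)
  }
  structure(list(speed_mm_s = speed, heading_rad = heading,
                 frame_interval_s = dt),
            class = "kinematics_series")
}

#' Apparent angular size of a neighbor
#'
#' Visual angle subtended by a body of width `body_major_mm` at distance
#' `distance_mm`: `2 * atan(body_major_mm / (2 * distance_mm))`. Strictly
#' decreasing in distance and bounded in (0, pi). Non-positive or
#' sub-clamp distances are clamped (never an error), so the angle stays
#' finite and below pi.
#'
#' @param distance_mm Distance(s) to the neighbor, mm.
#' @param body_major_mm Apparent body width, mm.
#' @param distance_clamp_mm Lower clamp applied to the distance; 0 disables
#'   clamping except for a hard floor at machine precision.
#' @return Angular size(s) in radians.
#' @export
angular_size <- function(distance_mm, body_major_mm = 3.0,
                         distance_clamp_mm = 0) {
  d <- pmax(distance_mm, distance_clamp_mm, .Machine$double.xmin)
  2 * atan(body_major_mm / (2 * d))
}

#' Forward-sector membership
#'
#' TRUE when the neighbor lies in the focal individual's forward 180-degree
#' sector: the angle between the heading vector and the focal-to-neighbor
#' vector is at most 90 degrees (dot product >= 0; the boundary is
#' inclusive, which makes the sector exactly a half-plane).
#'
#' @param focal_heading Focal heading(s), radians.
#' @param focal_x,focal_y Focal position(s), mm.
#' @param other_x,other_y Neighbor position(s), mm.
#' @return Logical vector.
#' @export
in_forward_sector <- function(focal_heading, focal_x, focal_y,
                              other_x, other_y) {
  (other_x - focal_x) * cos(focal_heading) +
    (other_y - focal_y) * sin(focal_heading) >= 0
}

# cue for every individual at one frame; x, y, heading, speed are vectors
# over individuals. Used by both compute_cue and the simulator.
cue_frame <- function(x, y, heading, speed, config) {
  n <- length(x)
  dx <- outer(x, x, "-")      # dx[i, f] = x[i] - x[f]
  dy <- outer(y, y, "-")
  d <- sqrt(dx^2 + dy^2)
  insec <- sweep(dx, 2L, cos(heading), "*") +
    sweep(dy, 2L, sin(heading), "*") >= 0
  ang <- angular_size(d, config$body_major_mm, config$distance_clamp_mm)
  contrib <- speed * ang * insec   # speed[i] recycles down rows = neighbors
  diag(contrib) <- 0
  colSums(contrib)
}

#' Per-frame visual cue for every individual
#'
#' For each focal individual f and frame t the raw cue is the sum, over all
#' other individuals i in f's forward 180-degree sector, of
#' `speed_i[t] * 2 * atan(body_major / (2 * distance_fi[t]))` -- the summed
#' movement of visible neighbors weighted by their apparent angular size
#' (units mm/s x rad). Neighbors behind the focal contribute nothing.
#'
#' @param rec A `group_recording`.
#' @param kin The matching [compute_kinematics()] result.
#' @param config A [cue_config()].
#' @return List of class `cue_series` with `raw` (`n_frames x
#'   n_individuals`), `transformed` (NULL until [transform_cue()]), and the
#'   config.
#' @export
compute_cue <- function(rec, kin, config = cue_config()) {
  n_fr <- rec$n_frames
  n_ind <- length(rec$individual_id)
  raw <- matrix(0, n_fr, n_ind)
  for (f in seq_len(n_ind)) {
    dx <- rec$x[, -f, drop = FALSE] - rec$x[, f]
    dy <- rec$y[, -f, drop = FALSE] - rec$y[, f]
    d <- sqrt(dx^2 + dy^2)
    insec <- dx * cos(kin$heading_rad[, f]) +
      dy * sin(kin$heading_rad[, f]) >= 0
    ang <- angular_size(d, config$body_major_mm, config$distance_clamp_mm)
    raw[, f] <- rowSums(kin$speed_mm_s[, -f, drop = FALSE] * ang * insec)
  }
  colnames(raw) <- rec$individual_id
  structure(list(raw = raw, transformed = NULL, config = config),
            class = "cue_series")
}

# offset zeros with the minimum non-zero value, log, then z-score;
# returns the transformed vector plus the constants used
log_standardize <- function(x, constants = NULL) {
  if (is.null(constants)) {
    nz <- x[x > 0]
    if (!length(nz))
      stop("all cue values are zero in a standardization stratum; the ",
           "zero-offset is undefined")
    m <- min(nz)
    lx <- log(ifelse(x == 0, m, x))
    mu <- mean(lx)
    sdv <- stats::sd(lx)
    if (!is.finite(sdv) || sdv == 0)
      stop("cue values have zero variance in a standardization stratum")
    constants <- list(min_nonzero = m, log_mean = mu, log_sd = sdv)
  }
  lx <- log(ifelse(x == 0, constants$min_nonzero, x))
  list(z = (lx - constants$log_mean) / constants$log_sd,
       constants = constants)
}

#' Log-transform and standardize raw cues
#'
#' Zero-valued observations are replaced by the minimum non-zero raw cue of
#' their standardization stratum, the series is natural-log transformed, and
#' then z-scored within the stratum (mean 0, sd 1 over all of that stratum's
#' individuals x frames). The default stratum is species x group type; set
#' `standardize_pool = "species"` in the config to pool across group types.
#' Pre-computed constants (see [cue_transform_constants()]) allow pooling the
#' standardization across several recordings.
#'
#' @param cue A `cue_series` from [compute_cue()].
#' @param rec The matching `group_recording`.
#' @param config A [cue_config()].
#' @param constants Optional named list of per-stratum constants
#'   (`min_nonzero`, `log_mean`, `log_sd`) from [cue_transform_constants()].
#' @return The `cue_series` with `transformed` filled in and the constants
#'   attached as `transform_constants`.
#' @export
transform_cue <- function(cue, rec, config = cue$config, constants = NULL) {
  strata <- cue_stratum(rec, config)
  out <- cue$raw
  used <- list()
  for (s in unique(strata)) {
    cols <- which(strata == s)
    res <- log_standardize(as.vector(cue$raw[, cols]), constants[[s]])
    out[, cols] <- res$z
    used[[s]] <- res$constants
  }
  cue$transformed <- out
  cue$transform_constants <- used
  cue
}

cue_stratum <- function(rec, config) {
  if (config$standardize_pool == "species") rec$species
  else paste(rec$species, rec$group_type, sep = ".")
}

#' Pooled standardization constants across recordings
#'
#' Computes per-stratum offset/log/z-score constants over all supplied
#' recordings at once, so that cue values are on a common scale across
#' arenas of the same stratum (as in a species-level standardization over a
#' whole data set).
#'
#' @param cues List of `cue_series`.
#' @param recs List of matching `group_recording`s.
#' @param config A [cue_config()].
#' @return Named list of per-stratum constants, for [transform_cue()].
#' @export
cue_transform_constants <- function(cues, recs, config = cue_config()) {
  strata_values <- list()
  for (k in seq_along(cues)) {
    strata <- cue_stratum(recs[[k]], config)
    for (s in unique(strata)) {
      cols <- which(strata == s)
      strata_values[[s]] <- c(strata_values[[s]],
                              as.vector(cues[[k]]$raw[, cols]))
    }
  }
  lapply(strata_values, function(x) log_standardize(x)$constants)
}

#' Long-format cue table
#'
#' @param cue A transformed `cue_series`.
#' @param rec The matching `group_recording`.
#' @return data.frame with columns `individual_id`, `frame`, `raw_cue`,
#'   `transformed_cue`.
#' @export
cue_table <- function(cue, rec) {
  n_fr <- nrow(cue$raw)
  data.frame(
    individual_id = rep(rec$individual_id, each = n_fr),
    frame = rep(seq_len(n_fr) - 1L, times = length(rec$individual_id)),
    raw_cue = as.vector(cue$raw),
    transformed_cue = if (is.null(cue$transformed)) NA_real_
                      else as.vector(cue$transformed),
    stringsAsFactors = FALSE)
}
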