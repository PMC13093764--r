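#' Pipeline run configuration
#'
#' Collects every tunable parameter of the analysis in one serializable
#' list; unspecified fields take the documented defaults and the full
#' configuration is echoed into every output table so reports are
#' self-describing.
#'
#' @param cue A [cue_config()].
#' @param walk_threshold_mm_s,min_bout_frames State segmentation parameters
#'   (see [classify_states()]).
#' @param lag_frames Sensitivity-regression lag (frames; 1 = 0.5 s).
#' @param contrast_pairs List of event-type pairs to contrast; the family
#'   size sets the Bonferroni factor.
#' @param n_perm Permutations for all built-in tests.
#' @param seed Integer seed for all permutation tests.
#' @param conformity_method `"relative"` or `"ratio"` (see
#'   [species_level_conformity()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cue = cue_config(),
                       walk_threshold_mm_s = 2.0,
                       min_bout_frames = 2L,
                       lag_frames = 1L,
                       contrast_pairs = list(c("walk", "stay"),
                                             c("walk", "walking"),
                                             c("walking", "stop"),
                                             c("stop", "stay")),
                       n_perm = 999L,
                       seed = 1L,
                       conformity_method = "relative") {
  structure(list(cue = cue,
                 walk_threshold_mm_s = walk_threshold_mm_s,
                 min_bout_frames = as.integer(min_bout_frames),
                 lag_frames = as.integer(lag_frames),
                 contrast_pairs = contrast_pairs,
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 conformity_method = conformity_method),
            class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Recognized keys are the arguments of [run_config()] and [cue_config()]
#' (cue keys prefixed `cue_`, e.g. `cue_body_major_mm`); unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cue_keys <- names(formals(cue_config))
  cue_keys <- setdiff(cue_keys, "distance_clamp_mm")  # depends on minor axis
  run_keys <- setdiff(names(formals(run_config)), "cue")
  cue_args <- list()
  run_args <- list()
  for (k in names(raw)) {
    if (startsWith(k, "cue_") &&
        sub("^cue_", "", k) %in% c(cue_keys, "distance_clamp_mm")) {
      cue_args[[sub("^cue_", "", k)]] <- raw[[k]]
    } else if (k %in% run_keys) {
      run_args[[k]] <- raw[[k]]
    } else {
      stop(sprintf("unknown configuration key '%s'", k))
    }
  }
  run_args$cue <- do.call(cue_config, cue_args)
  do.call(run_config, run_args)
}

config_header_lines <- function(config) {
  flat <- c(
    walk_threshold_mm_s = config$walk_threshold_mm_s,
    min_bout_frames = config$min_bout_frames,
    lag_frames = config$lag_frames,
    n_perm = config$n_perm,
    seed = config$seed,
    conformity_method = config$conformity_method,
    body_major_mm = config$cue$body_major_mm,
    body_minor_mm = config$cue$body_minor_mm,
    distance_clamp_mm = config$cue$distance_clamp_mm,
    heading_source = config$cue$heading_source,
    standardize_pool = config$cue$standardize_pool,
    stationary_epsilon_mm = config$cue$stationary_epsilon_mm)
  sprintf("# %s\t%s", names(flat), as.character(flat))
}

stage_wrap <- function(rec_id, stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("recording '%s', stage '%s': %s", rec_id, stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full conformity pipeline over a set of recordings
#'
#' For every recording: clip to the analysis window, compute kinematics,
#' raw cues, the pooled log/z-score transform (standardization constants
#' are computed over all recordings of a stratum together), behavioral
#' states and events, and event-aligned cues. Across recordings it then
#' assembles the per-individual speed and sensitivity tables, the event
#' contrasts per species x group type, and -- when both single and mixed
#' recordings are present -- the species-level and group-level conformity
#' reports for every species pair observed in mixed groups. Deterministic
#' given config (which carries the seed).
#'
#' @param recordings A list of `group_recording` objects and/or paths to
#'   trajectory files readable by [read_recording()].
#' @param config A [run_config()].
#' @return List of class `report_bundle`: `individual_speeds`,
#'   `sensitivity`, `event_means`, `contrasts`, `conformity_species`,
#'   `conformity_group`, `sensitivity_tests`, `log`, `config`.
#' @export
run_pipeline <- function(recordings, config = run_config()) {
  if (!length(recordings)) stop("no recordings supplied")
  recs <- lapply(recordings, function(r) {
    if (is.character(r)) read_recording(r) else r
  })
  ids <- vapply(seq_along(recs), function(k) {
    id <- recs[[k]]$replicate_id
    if (is.null(id) || !nzchar(id)) sprintf("recording%02d", k) else id
  }, character(1))
  if (anyDuplicated(ids)) ids <- sprintf("%s#%d", ids, seq_along(ids))

  log_rows <- list()
  clipped <- list()
  kins <- list()
  cues <- list()
  for (k in seq_along(recs)) {
    rec <- recs[[k]]
    rec <- stage_wrap(ids[k], "validate", validate_recording(rec))
    needs_clip <- rec$arena$analysis_start_s > 0 ||
      rec$n_frames * rec$arena$frame_interval_s > rec$arena$analysis_end_s
    if (needs_clip)
      rec <- stage_wrap(ids[k], "clip", clip_to_analysis_window(rec))
    kin <- stage_wrap(ids[k], "kinematics",
                      compute_kinematics(rec, config$cue))
    cue <- stage_wrap(ids[k], "cue", compute_cue(rec, kin, config$cue))
    clipped[[k]] <- rec
    kins[[k]] <- kin
    cues[[k]] <- cue
  }
  constants <- cue_transform_constants(cues, clipped, config$cue)
  speeds <- list()
  sens <- list()
  ev_means <- list()
  for (k in seq_along(clipped)) {
    rec <- clipped[[k]]
    cue <- stage_wrap(ids[k], "transform",
                      transform_cue(cues[[k]], rec, config$cue, constants))
    st <- stage_wrap(ids[k], "states",
                     compute_states(kins[[k]], config$walk_threshold_mm_s,
                                    config$min_bout_frames))
    al <- stage_wrap(ids[k], "events", event_aligned_cues(cue, st, rec))
    speeds[[k]] <- cbind(individual_mean_speeds(rec, kins[[k]]),
                         recording = ids[k], stringsAsFactors = FALSE)
    sens[[k]] <- cbind(stage_wrap(ids[k], "sensitivity",
                                  sensitivity_table(rec, kins[[k]], cue,
                                                    config$lag_frames)),
                       recording = ids[k], stringsAsFactors = FALSE)
    ev_means[[k]] <- cbind(al$means, recording = ids[k],
                           stringsAsFactors = FALSE)
    log_rows[[k]] <- data.frame(
      recording = ids[k], group_type = rec$group_type,
      n_individuals = length(rec$individual_id), n_frames = rec$n_frames,
      n_walk_events = sum(st$event == "walk"),
      n_stop_events = sum(st$event == "stop"),
      stringsAsFactors = FALSE)
  }
  individual_speeds <- do.call(rbind, speeds)
  sensitivity <- do.call(rbind, sens)
  event_means <- do.call(rbind, ev_means)

  # event contrasts within species x group type, Bonferroni over the family
  contrasts <- list()
  strat <- unique(event_means[c("species", "group_type")])
  fam <- length(config$contrast_pairs)
  for (i in seq_len(nrow(strat))) {
    sub <- event_means[event_means$species == strat$species[i] &
                       event_means$group_type == strat$group_type[i], ]
    for (pair in config$contrast_pairs) {
      ct <- tryCatch(
        event_contrast(sub, pair, n_perm = config$n_perm,
                       seed = config$seed, n_contrasts = fam),
        error = function(e) NULL)  # stratum without both event types
      if (!is.null(ct))
        contrasts[[length(contrasts) + 1L]] <-
          cbind(species = strat$species[i],
                group_type = strat$group_type[i], ct,
                stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL

  conformity_species <- NULL
  conformity_group <- NULL
  singles <- individual_speeds[individual_speeds$group_type == "single", ]
  mixeds <- individual_speeds[individual_speeds$group_type == "mixed", ]
  if (nrow(singles) && nrow(mixeds)) {
    mixed_recs <- unique(mixeds$recording)
    pairs <- unique(do.call(rbind, lapply(mixed_recs, function(r) {
      sp <- sort(unique(mixeds$species[mixeds$recording == r]))
      data.frame(a = sp[1L], b = sp[2L], stringsAsFactors = FALSE)
    })))
    sp_rows <- list()
    gr_rows <- list()
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      in_pair <- vapply(mixed_recs, function(r) {
        setequal(unique(mixeds$species[mixeds$recording == r]), c(a, b))
      }, logical(1))
      mx <- mixeds[mixeds$recording %in% mixed_recs[in_pair], ]
      sg <- singles[singles$species %in% c(a, b), ]
      sc <- species_level_conformity(sg, mx, config$conformity_method)
      sp_rows[[i]] <- cbind(pair = paste(a, b, sep = ":"),
                            sc$per_strain, stringsAsFactors = FALSE)
      gc <- group_level_conformity(
        sg[sg$species == a, ], sg[sg$species == b, ],
        mx[mx$species == a, ], mx[mx$species == b, ],
        n_perm = config$n_perm, seed = config$seed)
      gr_rows[[i]] <- cbind(pair = paste(a, b, sep = ":"), gc,
                            stringsAsFactors = FALSE)
    }
    conformity_species <- do.call(rbind, sp_rows)
    conformity_group <- do.call(rbind, gr_rows)
  }

  sensitivity_tests <- tryCatch(
    sensitivity_comparison(sensitivity, n_perm = config$n_perm,
                           seed = config$seed),
    error = function(e) NULL)

  structure(list(
    individual_speeds = individual_speeds,
    sensitivity = sensitivity,
    event_means = event_means,
    contrasts = contrasts,
    conformity_species = conformity_species,
    conformity_group = conformity_group,
    sensitivity_tests = sensitivity_tests,
    log = do.call(rbind, log_rows),
    config = config), class = "report_bundle")
}

format_table_numbers <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  df
}

#' Write a report bundle to TSV files
#'
#' Each table goes to `<dir>/<name>.tsv` with a header comment block
#' echoing the full configuration; numeric columns use a fixed 10
#' significant-digit format so identical runs are byte-identical.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- config_header_lines(bundle$config)
  written <- character()
  for (nm in c("individual_speeds", "sensitivity", "event_means",
               "contrasts", "conformity_species", "conformity_group",
               "sensitivity_tests", "log")) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(format_table_numbers(tab), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
    written <- c(written, path)
  }
  invisible(written)
}

#' Summarize a report bundle
#'
#' Per-species speed means by group type, species-level conformity rates,
#' group-level convergence ratios (flagged as convergence when the ratio is
#' below 1 with a significant reduction), and mean sensitivity slopes with
#' basic bootstrap confidence intervals.
#'
#' @param bundle A non-empty `report_bundle`.
#' @param n_boot Bootstrap draws for the slope confidence intervals.
#' @param conf Confidence level.
#' @return List of class `report_summary` with `speed`, `sensitivity`,
#'   `conformity` data.frames and a `text` character vector; printed as
#'   plain text.
#' @export
summarize_report <- function(bundle, n_boot = 1000L, conf = 0.95) {
  if (!nrow(bundle$individual_speeds)) stop("empty report bundle")
  sp <- stats::aggregate(mean_speed ~ species + group_type,
                         bundle$individual_speeds, mean)
  boot_ci <- function(x) {
    bs <- replicate(n_boot, mean(sample(x, replace = TRUE)))
    stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }
  set.seed(bundle$config$seed)
  bundle$sensitivity <-
    bundle$sensitivity[is.finite(bundle$sensitivity$slope), , drop = FALSE]
  sens_split <- split(bundle$sensitivity$slope,
                      paste(bundle$sensitivity$species,
                            bundle$sensitivity$group_type, sep = " / "))
  sens <- do.call(rbind, lapply(names(sens_split), function(k) {
    x <- sens_split[[k]]
    ci <- if (length(x) >= 3L) boot_ci(x) else c(NA_real_, NA_real_)
    data.frame(stratum = k, n = length(x), mean_slope = mean(x),
               ci_lo = ci[1L], ci_hi = ci[2L], stringsAsFactors = FALSE)
  }))
  text <- c("== flyconform report summary ==",
            sprintf("recordings: %d (%s)", nrow(bundle$log),
                    paste(sprintf("%s %s", bundle$log$recording,
                                  bundle$log$group_type), collapse = ", ")),
            "-- mean locomotive speed (mm/s, mean of individual means) --",
            sprintf("  %s [%s]: %.3f", sp$species, sp$group_type,
                    sp$mean_speed))
  conf_tab <- NULL
  if (!is.null(bundle$conformity_group)) {
    g <- bundle$conformity_group
    conv <- g$ratio < 1 & g$p_reduction < 0.05
    text <- c(text, "-- group-level conformity --",
              sprintf(
                "  %s: delta single %.3f -> mixed %.3f (ratio %.3f, p=%.4f)%s",
                g$pair, g$delta_single, g$delta_mixed, g$ratio,
                g$p_reduction,
                ifelse(conv, "  [convergence]", "  [no convergence]")))
    conf_tab <- cbind(g, convergence = conv, stringsAsFactors = FALSE)
  }
  if (!is.null(bundle$conformity_species)) {
    s <- bundle$conformity_species
    text <- c(text, "-- species-level conformity (rate of change) --",
              sprintf("  %s %s [%s]: %+.3f", s$pair, s$species, s$strain,
                      s$rate_of_change))
  }
  text <- c(text, "-- sensitivity to visual cue (slope mm/s per sd) --",
            sprintf("  %s: mean %+.4f (n=%d, CI %.4f..%.4f)", sens$stratum,
                    sens$mean_slope, sens$n, sens$ci_lo, sens$ci_hi))
  structure(list(speed = sp, sensitivity = sens, conformity = conf_tab,
                 text = text), class = "report_summary")
}

#' @export
print.report_summary <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}
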