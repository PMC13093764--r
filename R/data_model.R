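#' Arena and recording configuration
#'
#' Describes the circular arena and the analysis window. Defaults follow the
#' standard assay: a 140 mm circular arena, positions sampled every 0.5 s,
#' 60 min recordings of which the final 30 min (1800--3600 s) are analyzed
#' (the first half is an acclimation period).
#'
#' @param diameter_mm Arena diameter in mm (> 0).
#' @param frame_interval_s Time between analysis frames in seconds (> 0).
#' @param analysis_start_s Start of the analysis window in seconds (>= 0).
#' @param analysis_end_s End of the analysis window in seconds
#'   (> `analysis_start_s`). The window is half-open: `[start, end)`.
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(diameter_mm = 140, frame_interval_s = 0.5,
                         analysis_start_s = 1800, analysis_end_s = 3600) {
  stopifnot(is.numeric(diameter_mm), length(diameter_mm) == 1L, diameter_mm > 0)
  stopifnot(is.numeric(frame_interval_s), length(frame_interval_s) == 1L,
            frame_interval_s > 0)
  stopifnot(is.numeric(analysis_start_s), analysis_start_s >= 0)
  stopifnot(is.numeric(analysis_end_s), analysis_end_s > analysis_start_s)
  structure(list(diameter_mm = diameter_mm,
                 frame_interval_s = frame_interval_s,
                 analysis_start_s = analysis_start_s,
                 analysis_end_s = analysis_end_s),
            class = "arena_config")
}

#' Group recording container
#'
#' Holds all trajectories of one arena run plus per-individual metadata.
#' Positions are stored as `n_frames x n_individuals` matrices in mm with the
#' origin at the arena center; frame indices are 0-based and all individuals
#' share the same frames.
#'
#' @param x,y Numeric matrices (`n_frames x n_individuals`) of coordinates in
#'   mm, origin at arena center.
#' @param individual_id Character vector of unique individual identifiers,
#'   one per column of `x`.
#' @param species Character vector of species labels per individual.
#' @param strain Character vector of strain labels per individual.
#' @param group_type `"single"` (one species) or `"mixed"` (two species in
#'   equal numbers).
#' @param replicate_id Identifier of the arena run.
#' @param arena An [arena_config()].
#' @param heading Optional `n_frames x n_individuals` matrix of tracker
#'   headings in radians; headings are normally re-derived from displacement
#'   downstream.
#' @return An object of class `group_recording`.
#' @export
group_recording <- function(x, y, individual_id, species, strain,
                            group_type = c("single", "mixed"),
                            replicate_id = "rep1",
                            arena = arena_config(),
                            heading = NULL) {
  group_type <- match.arg(group_type)
  x <- as.matrix(x); y <- as.matrix(y)
  rec <- structure(list(
    x = x, y = y,
    heading = heading,
    individual_id = as.character(individual_id),
    species = as.character(species),
    strain = as.character(strain),
    group_type = group_type,
    replicate_id = as.character(replicate_id),
    arena = arena,
    n_frames = nrow(x)
  ), class = "group_recording")
  validate_recording(rec)
  rec
}

#' Validate a group recording
#'
#' Checks the structural invariants: matching dimensions, finite coordinates
#' inside the arena (with a small tolerance for tracking jitter at the wall),
#' and the species-count contract for the group type (single = exactly one
#' species; mixed = exactly two species in equal numbers).
#'
#' @param rec A `group_recording`.
#' @param wall_tolerance_mm Allowed overshoot beyond the arena radius, mm.
#' @return `rec`, invisibly. Errors describe the first violated invariant.
#' @export
validate_recording <- function(rec, wall_tolerance_mm = 2) {
  stopifnot(inherits(rec, "group_recording"))
  n_ind <- length(rec$individual_id)
  if (n_ind == 0L) stop("recording contains no individuals")
  if (ncol(rec$x) != n_ind || ncol(rec$y) != n_ind)
    stop("coordinate matrices must have one column per individual")
  if (nrow(rec$x) != rec$n_frames || nrow(rec$y) != rec$n_frames)
    stop("coordinate matrices must have n_frames rows")
  if (length(rec$species) != n_ind || length(rec$strain) != n_ind)
    stop("species and strain must be given for every individual")
  if (anyDuplicated(rec$individual_id))
    stop("individual_id values must be unique")
  if (!all(is.finite(rec$x)) || !all(is.finite(rec$y))) {
    bad <- which(!is.finite(rec$x) | !is.finite(rec$y), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite coordinate for individual '%s' at frame %d",
                 rec$individual_id[bad[2L]], bad[1L] - 1L))
  }
  r_max <- rec$arena$diameter_mm / 2 + wall_tolerance_mm
  rr <- sqrt(rec$x^2 + rec$y^2)
  if (any(rr > r_max)) {
    bad <- which(rr > r_max, arr.ind = TRUE)[1L, ]
    stop(sprintf("individual '%s' outside arena at frame %d (r = %.1f mm)",
                 rec$individual_id[bad[2L]], bad[1L] - 1L, rr[bad[1L], bad[2L]]))
  }
  sp <- unique(rec$species)
  if (rec$group_type == "single" && length(sp) != 1L)
    stop(sprintf("group_type 'single' requires exactly 1 species, found %d",
                 length(sp)))
  if (rec$group_type == "mixed") {
    if (length(sp) != 2L)
      stop(sprintf("group_type 'mixed' requires exactly 2 species, found %d",
                   length(sp)))
    counts <- table(rec$species)
    if (length(unique(counts)) != 1L)
      stop(sprintf("mixed group must have equal species counts, found %s",
                   paste(sprintf("%s=%d", names(counts), counts),
                         collapse = ", ")))
  }
  invisible(rec)
}

format_coord <- function(v) sprintf("%.17g", v)

#' Write a group recording to delimited text
#'
#' Writes the trajectory table (tab-separated, columns `frame`,
#' `individual_id`, `x_mm`, `y_mm`, and `heading_rad` when present) to `path`
#' and the group metadata to `<path>.meta.tsv`. Coordinates are written with
#' 17 significant digits so that [read_recording()] reproduces them
#' bit-exactly. Rows are sorted by individual, then frame; the order is
#' deterministic.
#'
#' @param rec A validated `group_recording`.
#' @param path Output path for the trajectory table.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  n_ind <- length(rec$individual_id)
  n_fr <- rec$n_frames
  df <- data.frame(
    frame = rep(seq_len(n_fr) - 1L, times = n_ind),
    individual_id = rep(rec$individual_id, each = n_fr),
    x_mm = format_coord(as.vector(rec$x)),
    y_mm = format_coord(as.vector(rec$y)),
    stringsAsFactors = FALSE
  )
  if (!is.null(rec$heading)) df$heading_rad <- format_coord(as.vector(rec$heading))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot write trajectory file '%s': %s", path,
                 conditionMessage(e))))
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)

  meta_path <- paste0(path, ".meta.tsv")
  mcon <- file(meta_path, "w")
  on.exit(close(mcon), add = TRUE)
  a <- rec$arena
  hdr <- c(group_type = rec$group_type, replicate_id = rec$replicate_id,
           diameter_mm = a$diameter_mm, frame_interval_s = a$frame_interval_s,
           analysis_start_s = a$analysis_start_s,
           analysis_end_s = a$analysis_end_s)
  writeLines(sprintf("# %s\t%s", names(hdr), as.character(hdr)), mcon)
  utils::write.table(
    data.frame(individual_id = rec$individual_id, species = rec$species,
               strain = rec$strain, stringsAsFactors = FALSE),
    mcon, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_metadata_file <- function(meta_path) {
  lines <- readLines(meta_path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr_lines), "\t", fixed = TRUE))
  keys <- stats::setNames(kv[, 2L], kv[, 1L])
  tab <- utils::read.delim(text = lines[!startsWith(lines, "# ")],
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  list(individuals = tab,
       group_type = unname(keys[["group_type"]]),
       replicate_id = unname(keys[["replicate_id"]]),
       arena = arena_config(
         diameter_mm = as.numeric(keys[["diameter_mm"]]),
         frame_interval_s = as.numeric(keys[["frame_interval_s"]]),
         analysis_start_s = as.numeric(keys[["analysis_start_s"]]),
         analysis_end_s = as.numeric(keys[["analysis_end_s"]])))
}

#' Read a group recording from delimited text
#'
#' Reads the trajectory table written by [write_recording()] (tab- or
#' comma-separated long format with columns `frame`, `individual_id`, `x_mm`,
#' `y_mm` and optional `heading_rad`) together with its metadata, validates
#' the result, re-indexes frames contiguously from 0 and sorts rows by
#' (individual, frame).
#'
#' @param trajectory_file Path to the trajectory table.
#' @param metadata Either a path to a metadata file (default
#'   `<trajectory_file>.meta.tsv`) or a list with elements `individuals`
#'   (data frame: `individual_id`, `species`, `strain`), `group_type`,
#'   `replicate_id` and `arena`.
#' @return A validated `group_recording`.
#' @export
read_recording <- function(trajectory_file,
                           metadata = paste0(trajectory_file, ".meta.tsv")) {
  if (is.character(metadata)) metadata <- read_metadata_file(metadata)
  first <- readLines(trajectory_file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.delim(trajectory_file, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("frame", "individual_id", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    stop(sprintf("trajectory file must have columns %s",
                 paste(need, collapse = ", ")))
  df$individual_id <- as.character(df$individual_id)

  ids <- as.character(metadata$individuals$individual_id)
  frames <- sort(unique(df$frame))
  # completeness: every individual must appear at every frame exactly once
  counts <- table(factor(df$individual_id, levels = ids), df$frame)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf("individual '%s' missing or duplicated at frame %s",
                 ids[bad[1L]], colnames(counts)[bad[2L]]))
  }
  extra <- setdiff(unique(df$individual_id), ids)
  if (length(extra))
    stop(sprintf("individuals in trajectory file but not in metadata: %s",
                 paste(extra, collapse = ", ")))

  ord <- order(match(df$individual_id, ids), df$frame)
  df <- df[ord, , drop = FALSE]
  n_fr <- length(frames)
  x <- matrix(df$x_mm, nrow = n_fr, ncol = length(ids))
  y <- matrix(df$y_mm, nrow = n_fr, ncol = length(ids))
  heading <- if ("heading_rad" %in% names(df))
    matrix(df$heading_rad, nrow = n_fr, ncol = length(ids)) else NULL

  group_recording(
    x = x, y = y, heading = heading,
    individual_id = ids,
    species = metadata$individuals$species,
    strain = metadata$individuals$strain,
    group_type = metadata$group_type,
    replicate_id = metadata$replicate_id,
    arena = metadata$arena)
}

#' Restrict a recording to its analysis window
#'
#' Keeps the frames in `[analysis_start_s, analysis_end_s)` (half-open) and
#' re-zeroes the frame index, so that a 60-min recording with the default
#' window yields exactly the final 30 min (3600 frames at 0.5 s).
#'
#' @param rec A `group_recording`.
#' @return A `group_recording` spanning only the analysis window.
#' @export
clip_to_analysis_window <- function(rec) {
  a <- rec$arena
  i0 <- as.integer(round(a$analysis_start_s / a$frame_interval_s))
  i1 <- as.integer(round(a$analysis_end_s / a$frame_interval_s))
  if (rec$n_frames < i1)
    stop(sprintf(
      "recording has %d frames but the analysis window needs %d (up to %g s)",
      rec$n_frames, i1, a$analysis_end_s))
  keep <- (i0 + 1L):i1
  out <- rec
  out$x <- rec$x[keep, , drop = FALSE]
  out$y <- rec$y[keep, , drop = FALSE]
  if (!is.null(rec$heading)) out$heading <- rec$heading[keep, , drop = FALSE]
  out$n_frames <- length(keep)
  # the clipped recording IS its own analysis window
  out$arena <- arena_config(
    diameter_mm = a$diameter_mm, frame_interval_s = a$frame_interval_s,
    analysis_start_s = 0,
    analysis_end_s = length(keep) * a$frame_interval_s)
  validate_recording(out)
  out
}

#' @export
print.group_recording <- function(x, ...) {
  cat(sprintf(
    "group_recording: %d individuals x %d frames (%s, replicate %s)\n",
    length(x$individual_id), x$n_frames, x$group_type, x$replicate_id))
  cat(sprintf("  species: %s\n",
              paste(sprintf("%s (n=%d)", names(table(x$species)),
                            as.integer(table(x$species))), collapse = ", ")))
  invisible(x)
}
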