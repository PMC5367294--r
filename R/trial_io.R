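#' Marker track
#'
#' One tracking marker's 2-D coordinate series at a fixed frame rate.
#' Frames are 0-based integer indices; missing frames are represented by
#' absent entries (explicit gaps), never by sentinel values, and are never
#' interpolated at construction time. Coordinates are in cm in the shared
#' convention: the target food at the origin, x positive from the bird
#' toward the target, y positive upward.
#'
#' @param marker marker role label, e.g. `"head"`, `"upper_tip"`,
#'   `"lower_tip"`.
#' @param frames strictly increasing integer frame indices (0-based).
#' @param x,y coordinates in cm, same length as `frames`, finite.
#' @param frame_rate frames per second (default 300).
#' @return An object of class `marker_track`.
#' @export
marker_track <- function(marker, frames, x, y, frame_rate = 300) {
  frames <- as.integer(frames)
  if (length(frames) != length(x) || length(frames) != length(y)) {
    stop("frames, x and y must have equal length", call. = FALSE)
  }
  if (length(frames) > 1 && any(diff(frames) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be > 0", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite where present", call. = FALSE)
  }
  structure(
    list(marker = as.character(marker), frames = frames,
         x = as.numeric(x), y = as.numeric(y),
         frame_rate = as.numeric(frame_rate)),
    class = "marker_track"
  )
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("<marker_track '%s': %d frames [%d..%d] @ %g fps>\n",
              x$marker, length(x$frames),
              if (length(x$frames)) min(x$frames) else NA_integer_,
              if (length(x$frames)) max(x$frames) else NA_integer_,
              x$frame_rate))
  invisible(x)
}

# internal: TRUE if the track has internal gaps (missing frames in range)
track_has_gaps <- function(track) {
  n <- length(track$frames)
  n > 1 && any(diff(track$frames) != 1L)
}

#' Single peck trial
#'
#' Metadata and the three marker tracks (head, upper bill tip, lower bill
#' tip) for one peck.
#'
#' @param trial_id unique trial label.
#' @param species `"pigeon"` or `"crow"`.
#' @param individual individual bird label.
#' @param phase one of [phase_levels()].
#' @param session integer session number.
#' @param peck_order integer position of the peck within a trial (pigeons
#'   peck arrays of seeds); use 1 for single-shot pecks.
#' @param target_position integer 1-10 position in the seed array, or `NA`
#'   for single-target trials.
#' @param food_size target food size in cm.
#' @param outcome `"success"` or `"failure"`.
#' @param head,upper_tip,lower_tip [marker_track] objects sharing one
#'   frame rate.
#' @return An object of class `peck_trial`.
#' @export
peck_trial <- function(trial_id, species, individual, phase, session,
                       peck_order, target_position, food_size, outcome,
                       head, upper_tip, lower_tip) {
  species <- match.arg(species, c("pigeon", "crow"))
  outcome <- match.arg(outcome, c("success", "failure"))
  phase <- as.character(as_phase(phase))
  tracks <- list(head = head, upper_tip = upper_tip, lower_tip = lower_tip)
  for (nm in names(tracks)) {
    if (!inherits(tracks[[nm]], "marker_track")) {
      stop("'", nm, "' must be a marker_track", call. = FALSE)
    }
  }
  rates <- vapply(tracks, function(t) t$frame_rate, numeric(1))
  if (length(unique(rates)) != 1) {
    stop("all three tracks must share one frame_rate", call. = FALSE)
  }
  structure(
    list(trial_id = as.character(trial_id), species = species,
         individual = as.character(individual), phase = phase,
         session = as.integer(session), peck_order = as.integer(peck_order),
         target_position = if (is.na(target_position)) NA_integer_
                           else as.integer(target_position),
         food_size = as.numeric(food_size), outcome = outcome,
         head = head, upper_tip = upper_tip, lower_tip = lower_tip),
    class = "peck_trial"
  )
}

#' @export
print.peck_trial <- function(x, ...) {
  cat(sprintf("<peck_trial %s: %s %s, phase %s, outcome %s>\n",
              x$trial_id, x$species, x$individual, x$phase, x$outcome))
  invisible(x)
}

required_track_cols <- c("trial_id", "frame", "marker", "x_cm", "y_cm")
required_trial_cols <- c("trial_id", "species", "individual", "phase",
                         "session", "peck_order", "target_position",
                         "food_size_cm", "outcome")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read peck trials from delimited files
#'
#' Reads the long-format track table (one row per trial, frame and marker)
#' and the trial metadata table, and joins them into a list of
#' [peck_trial] objects. Gaps in the frame series are preserved as missing
#' frames; nothing is interpolated at read time.
#'
#' @param track_path path to `tracks.csv` with columns `trial_id`, `frame`,
#'   `marker` (`head`/`upper_tip`/`lower_tip`), `x_cm`, `y_cm`.
#' @param metadata_path path to `trials.csv` with columns `trial_id`,
#'   `species`, `individual`, `phase`, `session`, `peck_order`,
#'   `target_position`, `food_size_cm`, `outcome`.
#' @param frame_rate frames per second of the recordings (default 300).
#' @return A list of [peck_trial], one per metadata row, in metadata order.
#' @export
read_trials <- function(track_path, metadata_path, frame_rate = 300) {
  tracks <- read.csv(track_path, stringsAsFactors = FALSE)
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  check_columns(tracks, required_track_cols, "track file")
  check_columns(meta, required_trial_cols, "metadata file")
  if (nrow(meta) == 0) return(list())
  dup <- duplicated(tracks[c("trial_id", "marker", "frame")])
  if (any(dup)) {
    d <- tracks[dup, , drop = FALSE][1, ]
    stop(sprintf("duplicate (trial_id, marker, frame) row: (%s, %s, %s)",
                 d$trial_id, d$marker, d$frame), call. = FALSE)
  }
  bad_marker <- setdiff(unique(tracks$marker),
                        c("head", "upper_tip", "lower_tip"))
  if (length(bad_marker) > 0) {
    stop("unknown marker role(s): ", paste(bad_marker, collapse = ", "),
         call. = FALSE)
  }
  no_tracks <- setdiff(meta$trial_id, unique(tracks$trial_id))
  if (length(no_tracks) > 0) {
    stop("metadata trial(s) with no track rows: ",
         paste(no_tracks, collapse = ", "), call. = FALSE)
  }
  by_trial <- split(tracks, tracks$trial_id)
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    tt <- by_trial[[as.character(m$trial_id)]]
    one_track <- function(role) {
      rows <- tt[tt$marker == role, , drop = FALSE]
      if (nrow(rows) == 0) {
        stop(sprintf("trial %s has no '%s' track rows", m$trial_id, role),
             call. = FALSE)
      }
      rows <- rows[order(rows$frame), , drop = FALSE]
      marker_track(role, rows$frame, rows$x_cm, rows$y_cm, frame_rate)
    }
    out[[i]] <- peck_trial(
      trial_id = m$trial_id, species = m$species, individual = m$individual,
      phase = m$phase, session = m$session, peck_order = m$peck_order,
      target_position = m$target_position, food_size = m$food_size_cm,
      outcome = m$outcome,
      head = one_track("head"), upper_tip = one_track("upper_tip"),
      lower_tip = one_track("lower_tip")
    )
  }
  out
}

#' Write peck trials to delimited files
#'
#' Inverse of [read_trials()]: writes the long track table and the trial
#' metadata table. `read_trials(write_trials(x))` reproduces `x` field by
#' field.
#'
#' @param trials list of [peck_trial].
#' @param track_path,metadata_path output CSV paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_trials <- function(trials, track_path, metadata_path) {
  meta <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(trial_id = tr$trial_id, species = tr$species,
               individual = tr$individual, phase = tr$phase,
               session = tr$session, peck_order = tr$peck_order,
               target_position = tr$target_position,
               food_size_cm = tr$food_size, outcome = tr$outcome,
               stringsAsFactors = FALSE)
  }))
  trk <- do.call(rbind, lapply(trials, function(tr) {
    do.call(rbind, lapply(c("head", "upper_tip", "lower_tip"), function(role) {
      t <- tr[[role]]
      data.frame(trial_id = tr$trial_id, frame = t$frames, marker = role,
                 x_cm = t$x, y_cm = t$y, stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(meta)) {
    meta <- data.frame(matrix(nrow = 0, ncol = length(required_trial_cols),
                              dimnames = list(NULL, required_trial_cols)))
    trk <- data.frame(matrix(nrow = 0, ncol = length(required_track_cols),
                             dimnames = list(NULL, required_track_cols)))
  }
  write_results(trk, track_path)
  write_results(meta, metadata_path)
  invisible(list(track_path = track_path, metadata_path = metadata_path))
}

#' Write a tidy result table
#'
#' Writes a data frame as a comma-delimited table with a header row and
#' numbers at full precision (no rounding).
#'
#' @param records data frame (kinematic records, model summaries, ...).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    write.csv(format(records, digits = 17, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, quote = TRUE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("could not write '", path, "': ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
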