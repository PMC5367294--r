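# Event detection and per-peck kinematic parameters.
#
# A peck runs from "head fixation" (a rapid standstill of the head in front
# of the target) to "grasping offset" (the minimum bill aperture after the
# aperture maximum). Grasping onset is the 20% opening of the maximum
# grasping aperture. The four parameters entering the phase models are the
# grasping-onset time from fixation, the head movement distance over the
# peck, and the mean head-reaching velocity and acceleration on the
# fixation-to-onset window.

#' Kinematics extraction options
#'
#' @param cutoff_hz low-pass cutoff for track smoothing (Hz).
#' @param filter_order Butterworth order per pass.
#' @param speed_threshold head-speed threshold defining a standstill
#'   (cm/s). The standstill criterion itself has no canonical published
#'   value; the default of 2 cm/s sustained for `min_still_frames` frames
#'   is a declared convention.
#' @param min_still_frames minimum consecutive sub-threshold frames for a
#'   standstill (default 10 frames = 33 ms at 300 fps).
#' @param onset_rule `"baseline"` measures the 20% opening relative to the
#'   aperture at fixation (the closed bill has nonzero marker separation);
#'   `"absolute"` uses 20% of the maximum aperture itself.
#' @param distance_end end of the movement-distance window: `"offset"`
#'   (default; the whole peck, fixation to grasping offset) or `"onset"`.
#'   Mean velocity and acceleration always use the fixation-to-onset
#'   window. Measuring distance to onset makes it an exact mechanical
#'   mediator of any onset shift, which defeats its use as a covariate in
#'   the onset models; the full-peck window keeps it a pure reach-extent
#'   measure.
#' @param opening_tol minimum rise of the aperture above baseline (cm) for
#'   a grasp to count as an opening.
#' @param baseline_frames frames averaged for the aperture baseline
#'   (default 10; see [detect_grasp_events()]).
#' @param sustain_frames consecutive frames the 20% threshold must be held
#'   (default 3; see [detect_grasp_events()]).
#' @return A list of options for [extract_kinematics()].
#' @export
kinematics_config <- function(cutoff_hz = 5, filter_order = 4,
                              speed_threshold = 2, min_still_frames = 10,
                              onset_rule = c("baseline", "absolute"),
                              distance_end = c("offset", "onset"),
                              opening_tol = 1e-6,
                              baseline_frames = 10, sustain_frames = 3) {
  list(cutoff_hz = cutoff_hz, filter_order = filter_order,
       speed_threshold = speed_threshold,
       min_still_frames = min_still_frames,
       onset_rule = match.arg(onset_rule),
       distance_end = match.arg(distance_end),
       opening_tol = opening_tol,
       baseline_frames = baseline_frames, sustain_frames = sustain_frames)
}

#' Bill aperture series
#'
#' Per-frame Euclidean distance between the upper and lower bill-tip
#' markers.
#'
#' @param upper,lower frame-aligned [marker_track]s of the two bill tips.
#' @return Numeric vector of apertures (cm), one per shared frame, with the
#'   frame indices as the `"frames"` attribute.
#' @export
aperture_series <- function(upper, lower) {
  stopifnot(inherits(upper, "marker_track"), inherits(lower, "marker_track"))
  if (length(upper$frames) != length(lower$frames) ||
      any(upper$frames != lower$frames)) {
    stop("upper and lower tip tracks are not frame-aligned", call. = FALSE)
  }
  ap <- sqrt((upper$x - lower$x)^2 + (upper$y - lower$y)^2)
  attr(ap, "frames") <- upper$frames
  ap
}

# internal: per-frame instantaneous speed (cm/s); speed[i] is the step
# speed into frame i, with the first frame copying the first step
step_speeds <- function(track) {
  d <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  dt <- diff(track$frames) / track$frame_rate
  d / dt
}

#' Detect head fixation
#'
#' Finds the head standstill that anchors a peck: the last interval of at
#' least `min_still_frames` consecutive frames before the global speed peak
#' of the reach whose instantaneous speed stays below `speed_threshold`.
#' Returns the first frame of that interval.
#'
#' @param head smoothed [marker_track] of the head, gap-free.
#' @param speed_threshold standstill speed threshold (cm/s).
#' @param min_still_frames minimum standstill length in frames.
#' @return The fixation frame index (0-based, on the track's frame scale).
#' @export
detect_fixation <- function(head, speed_threshold = 2, min_still_frames = 10) {
  stopifnot(inherits(head, "marker_track"))
  if (track_has_gaps(head)) {
    peckkin_stop("gap", "head track has gaps; cannot detect fixation")
  }
  n <- length(head$frames)
  if (n < min_still_frames + 1) {
    peckkin_stop("no_fixation", "track too short for a standstill interval")
  }
  v <- step_speeds(head)              # v[i] = speed into frame i+1
  speed <- c(v[1], v)                 # per-frame speed, length n
  still <- speed < speed_threshold
  peak <- which.max(speed)
  # standstill candidates must lie before the reach's speed peak; if there
  # is no real reach (all speeds sub-threshold) the whole track qualifies
  if (speed[peak] >= speed_threshold) {
    still[peak:n] <- FALSE
  }
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_still_frames)
  if (length(ok) == 0) {
    peckkin_stop("no_fixation",
                 sprintf("no standstill of >= %d frames below %g cm/s before the speed peak",
                         min_still_frames, speed_threshold))
  }
  head$frames[starts[ok[length(ok)]]]
}

#' Peck events
#'
#' Constructor/validator for the event landmarks of one peck. Enforces the
#' ordering fixation <= onset <= aperture maximum <= offset and
#' `max_aperture >= offset_aperture >= 0`.
#'
#' @param fixation_frame,onset_frame,max_aperture_frame,offset_frame frame
#'   indices of head fixation, grasping onset (20% opening), the aperture
#'   maximum and grasping offset (aperture minimum after the maximum).
#' @param max_aperture,offset_aperture apertures (cm) at the maximum and at
#'   offset; the offset aperture is typically nonzero (held food).
#' @return An object of class `peck_events`.
#' @export
peck_events <- function(fixation_frame, onset_frame, max_aperture_frame,
                        offset_frame, max_aperture, offset_aperture) {
  if (!(fixation_frame <= onset_frame && onset_frame <= max_aperture_frame &&
        max_aperture_frame <= offset_frame)) {
    peckkin_stop("event_order",
                 "event ordering fixation <= onset <= max aperture <= offset violated")
  }
  if (!(max_aperture >= offset_aperture && offset_aperture >= 0)) {
    peckkin_stop("event_order", "apertures violate max >= offset >= 0")
  }
  structure(
    list(fixation_frame = as.integer(fixation_frame),
         onset_frame = as.integer(onset_frame),
         max_aperture_frame = as.integer(max_aperture_frame),
         offset_frame = as.integer(offset_frame),
         max_aperture = max_aperture, offset_aperture = offset_aperture),
    class = "peck_events"
  )
}

#' Detect grasping onset and offset from the aperture profile
#'
#' From the smoothed aperture series and the fixation frame: the maximum
#' grasping aperture is the maximum over `[fixation, end]` (earliest frame
#' on ties); grasping onset is the first frame at or after fixation where
#' the aperture has opened by at least 20% of the maximum opening; grasping
#' offset is the frame of the minimum aperture after the maximum. Under the
#' default `"baseline"` rule the opening is measured relative to the
#' aperture at fixation, since the closed bill has nonzero marker
#' separation; `"absolute"` applies the 20% threshold to the raw aperture.
#'
#' @param aperture numeric aperture series from [aperture_series()]
#'   (computed on smoothed tracks), with frames as attribute or 0-based.
#' @param fixation_frame fixation frame index from [detect_fixation()].
#' @param onset_fraction opening fraction defining onset (default 0.20).
#' @param rule `"baseline"` or `"absolute"` (see above).
#' @param opening_tol minimum opening (cm) below which the peck is
#'   rejected as having no grasp.
#' @param baseline_frames number of frames from fixation over which the
#'   baseline aperture is averaged. The default 1 is the literal
#'   at-fixation baseline; batch extraction widens it (see
#'   [kinematics_config()]) because a single-frame baseline is fragile to
#'   tracking noise at the series edge.
#' @param sustain_frames number of consecutive frames the aperture must
#'   stay at or above the threshold for a crossing to count (guards
#'   against isolated noise excursions; irrelevant for clean monotone
#'   openings).
#' @return A [peck_events] object.
#' @export
detect_grasp_events <- function(aperture, fixation_frame,
                                onset_fraction = 0.20,
                                rule = c("baseline", "absolute"),
                                opening_tol = 1e-6,
                                baseline_frames = 1, sustain_frames = 1) {
  rule <- match.arg(rule)
  frames <- attr(aperture, "frames")
  if (is.null(frames)) frames <- seq_along(aperture) - 1L
  i_fix <- match(fixation_frame, frames)
  if (is.na(i_fix)) {
    stop("fixation_frame not on the aperture frame grid", call. = FALSE)
  }
  n <- length(aperture)
  seg <- i_fix:n
  i_max <- seg[which.max(aperture[seg])]    # earliest frame on ties
  a_max <- aperture[i_max]
  base_idx <- i_fix:min(i_fix + baseline_frames - 1, n)
  a_base <- mean(aperture[base_idx])
  a0 <- if (rule == "baseline") a_base else 0
  if (a_max - a_base <= opening_tol) {
    peckkin_stop("no_opening", "aperture never rises above its fixation baseline")
  }
  thr <- a0 + onset_fraction * (a_max - a0)
  above <- aperture[seg] >= thr
  sustain <- max(1, min(sustain_frames, length(seg)))
  hit <- which(vapply(seq_len(length(seg) - sustain + 1), function(k) {
    all(above[k:(k + sustain - 1)])
  }, logical(1)))[1]
  if (is.na(hit)) {
    peckkin_stop("no_opening", "aperture never reaches the onset threshold")
  }
  i_on <- seg[hit]
  post <- i_max:n
  i_off <- post[which.min(aperture[post])]
  peck_events(frames[i_fix], frames[i_on], frames[i_max], frames[i_off],
              a_max, aperture[i_off])
}

# internal: row indices of a frame window on a track
window_idx <- function(track, start_frame, end_frame) {
  if (start_frame > end_frame) stop("start_frame > end_frame", call. = FALSE)
  i0 <- match(start_frame, track$frames)
  i1 <- match(end_frame, track$frames)
  if (is.na(i0) || is.na(i1)) {
    peckkin_stop("gap", "window endpoints not present on the track")
  }
  idx <- i0:i1
  if (any(diff(track$frames[idx]) != 1L)) {
    peckkin_stop("gap", "gap inside the analysis window")
  }
  idx
}

#' Head movement distance
#'
#' Total length of the head trajectory over a frame window: the sum of
#' per-frame Euclidean displacements.
#'
#' @param head smoothed [marker_track].
#' @param start_frame,end_frame window endpoints (frame indices).
#' @return Path length in cm.
#' @export
movement_distance <- function(head, start_frame, end_frame) {
  idx <- window_idx(head, start_frame, end_frame)
  sum(sqrt(diff(head$x[idx])^2 + diff(head$y[idx])^2))
}

#' Mean head-reaching velocity
#'
#' Arithmetic mean of the instantaneous speeds, each computed from two
#' subsequent frames, over a window (normally fixation to grasping onset).
#' By construction `mean_velocity * window duration = movement_distance`.
#'
#' @inheritParams movement_distance
#' @return Mean speed in cm/s.
#' @export
mean_velocity <- function(head, start_frame, end_frame) {
  idx <- window_idx(head, start_frame, end_frame)
  if (length(idx) < 2) {
    stop("window must span at least 2 frames", call. = FALSE)
  }
  dt <- 1 / head$frame_rate
  mean(sqrt(diff(head$x[idx])^2 + diff(head$y[idx])^2) / dt)
}

#' Mean head-reaching acceleration
#'
#' Arithmetic mean of the instantaneous accelerations, each computed from
#' two subsequent instantaneous velocities, over a window. The mean
#' telescopes to `(v_last - v_first) / duration between them`.
#'
#' @inheritParams movement_distance
#' @return Mean acceleration in cm/s^2.
#' @export
mean_acceleration <- function(head, start_frame, end_frame) {
  idx <- window_idx(head, start_frame, end_frame)
  if (length(idx) < 3) {
    stop("window must span at least 3 frames", call. = FALSE)
  }
  dt <- 1 / head$frame_rate
  v <- sqrt(diff(head$x[idx])^2 + diff(head$y[idx])^2) / dt
  mean(diff(v) / dt)
}

# internal: full per-trial analysis. Returns events, smoothed tracks and
# the retained flag; all detector failures become exclusion reasons.
# When tracks have gaps, events are first located on a linearly
# interpolated copy; a peck whose [fixation, offset] window touches a
# missing frame in any marker is excluded with reason "gap" (markers out of
# frame), otherwise the analysis is redone on the contiguous block of fully
# observed frames containing the window.
analyze_trial <- function(trial, config = kinematics_config()) {
  res <- list(retained = FALSE, reason = NA_character_, events = NULL,
              smoothed = NULL, params = NULL)
  roles <- c("head", "upper_tip", "lower_tip")
  fr <- trial$head$frame_rate

  run <- function(tracks) {
    sm <- lapply(tracks, smooth_track,
                 cutoff = config$cutoff_hz, order = config$filter_order)
    ap <- aperture_series(sm$upper_tip, sm$lower_tip)
    fix <- detect_fixation(sm$head, config$speed_threshold,
                           config$min_still_frames)
    ev <- detect_grasp_events(ap, fix, rule = config$onset_rule,
                              opening_tol = config$opening_tol,
                              baseline_frames = config$baseline_frames,
                              sustain_frames = config$sustain_frames)
    list(smoothed = sm, events = ev)
  }

  out <- tryCatch({
    tracks <- lapply(roles, function(r) trial[[r]])
    names(tracks) <- roles
    all_frames <- sort(unique(unlist(lapply(tracks, `[[`, "frames"))))
    full <- seq(min(all_frames), max(all_frames))
    observed <- lapply(tracks, function(t) full %in% t$frames)
    complete <- Reduce(`&`, observed)
    if (all(complete)) {
      # common gap-free case: all markers observed on the full range
      aligned <- lapply(tracks, function(t) {
        i <- match(full, t$frames)
        marker_track(t$marker, full, t$x[i], t$y[i], fr)
      })
      run(aligned)
    } else {
      # locate events on an interpolated copy, then apply the exclusion rule
      interp <- lapply(tracks, function(t) {
        marker_track(t$marker, full,
                     approx(t$frames, t$x, xout = full, rule = 2)$y,
                     approx(t$frames, t$y, xout = full, rule = 2)$y, fr)
      })
      probe <- run(interp)
      win <- probe$events$fixation_frame:probe$events$offset_frame
      if (!all(complete[match(win, full)])) {
        peckkin_stop("gap", "marker missing inside the fixation-offset window")
      }
      # redo on the contiguous fully observed block containing the window
      r <- rle(complete)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      k <- which(r$values & full[starts] <= min(win) & full[ends] >= max(win))[1]
      blk <- full[starts[k]]:full[ends[k]]
      aligned <- lapply(tracks, function(t) {
        i <- match(blk, t$frames)
        marker_track(t$marker, blk, t$x[i], t$y[i], fr)
      })
      run(aligned)
    }
  }, peckkin_error = function(e) e)

  if (inherits(out, "peckkin_error")) {
    res$reason <- out$reason
    return(res)
  }
  ev <- out$events
  head_sm <- out$smoothed$head
  dist_end <- switch(config$distance_end, onset = ev$onset_frame,
                     offset = ev$offset_frame)
  params <- tryCatch({
    list(onset_s = (ev$onset_frame - ev$fixation_frame) / fr,
         distance_cm = movement_distance(head_sm, ev$fixation_frame, dist_end),
         velocity_cm_s = mean_velocity(head_sm, ev$fixation_frame, ev$onset_frame),
         accel_cm_s2 = mean_acceleration(head_sm, ev$fixation_frame, ev$onset_frame))
  }, error = function(e) e)
  if (inherits(params, "error")) {
    res$reason <- if (inherits(params, "peckkin_error")) params$reason
                  else "window_too_short"
    return(res)
  }
  res$retained <- TRUE
  res$events <- ev
  res$smoothed <- out$smoothed
  res$params <- params
  res
}

#' Extract the kinematic record of one peck
#'
#' Runs the full per-peck pipeline: smoothing, aperture, fixation and grasp
#' event detection, then the four kinematic parameters (movement distance
#' over the window set by `distance_end`; velocity and acceleration on the
#' fixation-to-onset window). Failures are never propagated as errors: any
#' detector failure, too-short window, or a marker gap inside the
#' fixation-to-offset window yields `retained = FALSE` with a reason
#' (mirroring the exclusion of pecks whose markers left the video frame).
#'
#' @param trial a [peck_trial].
#' @param config options from [kinematics_config()].
#' @return One-row data frame with the trial identifiers, `onset_s`,
#'   `distance_cm`, `velocity_cm_s`, `accel_cm_s2`, `retained` and
#'   `exclusion_reason` (parameters are `NA` when not retained).
#' @export
extract_kinematics <- function(trial, config = kinematics_config()) {
  stopifnot(inherits(trial, "peck_trial"))
  a <- analyze_trial(trial, config)
  data.frame(
    trial_id = trial$trial_id, species = trial$species,
    individual = trial$individual, phase = trial$phase,
    session = trial$session, peck_order = trial$peck_order,
    target_position = trial$target_position, outcome = trial$outcome,
    onset_s = if (a$retained) a$params$onset_s else NA_real_,
    distance_cm = if (a$retained) a$params$distance_cm else NA_real_,
    velocity_cm_s = if (a$retained) a$params$velocity_cm_s else NA_real_,
    accel_cm_s2 = if (a$retained) a$params$accel_cm_s2 else NA_real_,
    retained = a$retained,
    exclusion_reason = a$reason,
    stringsAsFactors = FALSE
  )
}

#' Kinematic records for a batch of trials
#'
#' @param trials list of [peck_trial].
#' @param config options from [kinematics_config()].
#' @return Data frame with one row per trial (see [extract_kinematics()]).
#' @export
kinematics_table <- function(trials, config = kinematics_config()) {
  do.call(rbind, lapply(trials, extract_kinematics, config = config))
}

#' Mean and s.d. trajectory across pecks
#'
#' Resamples each retained peck's fixation-to-offset path of one marker to
#' `n_points` by normalized path-length parameterization and returns the
#' pointwise mean and standard deviation of x and y, in target-relative
#' coordinates (food at the origin).
#'
#' @param trials list of [peck_trial] (at least 2 must be retained).
#' @param marker `"head"`, `"upper_tip"` or `"lower_tip"`.
#' @param n_points number of resampling points along the path.
#' @param config options from [kinematics_config()].
#' @return Data frame with columns `point`, `x_mean`, `y_mean`, `x_sd`,
#'   `y_sd` and the number of pecks as attribute `"n_pecks"`.
#' @export
mean_trajectory <- function(trials, marker = c("head", "upper_tip", "lower_tip"),
                            n_points = 100, config = kinematics_config()) {
  marker <- match.arg(marker)
  paths <- list()
  for (tr in trials) {
    a <- analyze_trial(tr, config)
    if (!a$retained) next
    t <- a$smoothed[[marker]]
    idx <- window_idx(t, a$events$fixation_frame, a$events$offset_frame)
    x <- t$x[idx]
    y <- t$y[idx]
    s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    u <- seq(0, 1, length.out = n_points)
    if (s[length(s)] < .Machine$double.eps) {
      xs <- rep(x[1], n_points)
      ys <- rep(y[1], n_points)
    } else {
      sn <- s / s[length(s)]
      xs <- approx(sn, x, xout = u, ties = "ordered")$y
      ys <- approx(sn, y, xout = u, ties = "ordered")$y
    }
    paths[[length(paths) + 1]] <- cbind(xs, ys)
  }
  if (length(paths) < 2) {
    stop("mean_trajectory needs at least 2 retained pecks", call. = FALSE)
  }
  X <- sapply(paths, function(p) p[, 1])
  Y <- sapply(paths, function(p) p[, 2])
  out <- data.frame(point = seq_len(n_points),
                    x_mean = rowMeans(X), y_mean = rowMeans(Y),
                    x_sd = apply(X, 1, sd), y_sd = apply(Y, 1, sd))
  attr(out, "n_pecks") <- length(paths)
  out
}
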