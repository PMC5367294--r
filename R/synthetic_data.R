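# Ground-truth pecking simulator.
#
# Each simulated peck is a sagittal 2-D reach of the head toward a target
# at the origin: a pre-reach standstill (the true head fixation), a
# minimum-jerk displacement profile s(tau) = P (10 tau^3 - 15 tau^4 +
# 6 tau^5) along a gently curved arc, and a raised-cosine bill-aperture
# pulse (from the nonzero resting/offset aperture up to the peak aperture
# and back) that starts when the bill tip comes within a trigger distance
# of the target. The analytic 20% crossing and minimum of that pulse give
# the true grasping onset/offset; success is Bernoulli from a logistic
# model with a per-individual random intercept. Minimum-jerk reach and
# raised-cosine aperture are modelling choices with analytically known
# landmarks, not measured profiles.

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# fraction of the raised-cosine pulse at which the 20% opening occurs:
# 0.5 (1 - cos(2 pi u)) = 0.2  =>  u = acos(0.6) / (2 pi)
onset_pulse_fraction <- function(fraction = 0.20) {
  acos(1 - 2 * fraction) / (2 * pi)
}

#' Species morphometric and kinematic parameters for the simulator
#'
#' Defaults encode the two study species: pigeons with a 2.3 cm bill and a
#' 1 cm artificial extension, crows with a 6.5 cm bill and a 2 cm
#' extension; targets are small food items (sub-cm seed or ~1 cm cheese
#' piece), recorded at 300 frames/s. Reach and grasp durations default to
#' 0.7 s and 0.5 s so that the aperture and speed profiles lie essentially
#' inside the 5 Hz smoothing passband used downstream.
#'
#' @param species `"pigeon"` or `"crow"` (sets all defaults).
#' @param bill_length,extension_length natural bill and artificial
#'   extension length (cm).
#' @param fixation_distance_mean,fixation_distance_sd head-to-target
#'   distance at fixation (cm), truncated-normal across pecks.
#' @param reach_duration mean duration of the head reach (s).
#' @param reach_duration_sd per-peck s.d. of the reach duration (s,
#'   truncated below at 0.3 s); gives reach speed a source of variation
#'   that is independent of reach distance and grasp timing.
#' @param grasp_duration duration of the aperture open-close pulse (s).
#' @param grasp_trigger_frac fraction of the head's path at which the
#'   grasp pulse starts (default 0.5, i.e. near peak reach speed, so the
#'   bill opens during the approach).
#' @param peak_aperture,offset_aperture maximum and resting/offset bill
#'   aperture (cm); the offset aperture is the food-size floor.
#' @param frame_rate frames per second.
#' @param marker_noise_sd i.i.d. Gaussian tracking noise per marker
#'   coordinate per frame (cm).
#' @param approach_angle_deg angle of the fixation point above the
#'   horizontal through the target (degrees).
#' @param arc_height_frac perpendicular bulge of the approach arc as a
#'   fraction of the chord (kept small so the sagittal 2-D projection is
#'   faithful).
#' @param still_duration pre-reach standstill duration (s; the true
#'   fixation interval, >= 60 ms).
#' @param tail_duration extra recording after the grasp pulse (s).
#' @param onset_jitter_sd per-peck Gaussian jitter of the grasp trigger
#'   time (s).
#' @param onset_individual_sd per-individual random shift of the grasp
#'   trigger time (s).
#' @param submovement_sd amplitude (as a fraction of the path, per
#'   harmonic) of smooth random submovement ripples superimposed on the
#'   minimum-jerk displacement profile. Real reaches are not perfectly
#'   stereotyped; these low-frequency ripples (first three half-sine
#'   harmonics of the reach, well inside the smoothing passband) give the
#'   instantaneous speed a source of variation that is not a function of
#'   reach distance or grasp timing.
#' @return A list of class `species_params`.
#' @export
species_params <- function(species = c("pigeon", "crow"),
                           bill_length = NULL, extension_length = NULL,
                           fixation_distance_mean = NULL,
                           fixation_distance_sd = NULL,
                           reach_duration = 0.7, reach_duration_sd = 0.015,
                           grasp_duration = 0.5,
                           grasp_trigger_frac = 0.5,
                           peak_aperture = NULL, offset_aperture = NULL,
                           frame_rate = 300, marker_noise_sd = 0.05,
                           approach_angle_deg = 40, arc_height_frac = 0.08,
                           still_duration = 0.30, tail_duration = 0.08,
                           onset_jitter_sd = 0.010,
                           onset_individual_sd = 0.01,
                           submovement_sd = 0.008) {
  species <- match.arg(species)
  def <- if (species == "pigeon") {
    list(bill_length = 2.3, extension_length = 1.0,
         fixation_distance_mean = 6.5, fixation_distance_sd = 0.8,
         peak_aperture = 1.6, offset_aperture = 0.45)
  } else {
    list(bill_length = 6.5, extension_length = 2.0,
         fixation_distance_mean = 13, fixation_distance_sd = 1.5,
         peak_aperture = 2.0, offset_aperture = 0.6)
  }
  sp <- list(species = species,
             bill_length = bill_length %||% def$bill_length,
             extension_length = extension_length %||% def$extension_length,
             fixation_distance_mean = fixation_distance_mean %||% def$fixation_distance_mean,
             fixation_distance_sd = fixation_distance_sd %||% def$fixation_distance_sd,
             reach_duration = reach_duration,
             reach_duration_sd = reach_duration_sd,
             grasp_duration = grasp_duration,
             grasp_trigger_frac = grasp_trigger_frac,
             peak_aperture = peak_aperture %||% def$peak_aperture,
             offset_aperture = offset_aperture %||% def$offset_aperture,
             frame_rate = frame_rate, marker_noise_sd = marker_noise_sd,
             approach_angle_deg = approach_angle_deg,
             arc_height_frac = arc_height_frac,
             still_duration = still_duration, tail_duration = tail_duration,
             onset_jitter_sd = onset_jitter_sd,
             onset_individual_sd = onset_individual_sd,
             submovement_sd = submovement_sd)
  stopifnot(sp$bill_length > 0, sp$extension_length >= 0, sp$frame_rate > 0,
            sp$fixation_distance_mean > 0, sp$reach_duration > 0,
            sp$grasp_duration > 0, sp$peak_aperture > sp$offset_aperture,
            sp$offset_aperture >= 0, sp$still_duration >= 0.06,
            sp$grasp_trigger_frac > 0, sp$grasp_trigger_frac < 1)
  class(sp) <- "species_params"
  sp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phase-dependent perturbations for the simulator
#'
#' @param onset_shift delay (s) of the grasp trigger, emulating failure to
#'   open an extended bill earlier (positive = later grasping onset).
#' @param distance_shift shift (cm) of the mean fixation distance
#'   (negative = reach initiated closer to the target).
#' @param success_logit_shift shift of the success log-odds.
#' @param after_effect advance (s) of the grasp trigger after removal of
#'   the extension (a motor after-effect; positive = earlier onset).
#' @param extension_on whether the artificial bill extension is attached
#'   (markers sit on the extension tips when present).
#' @return A list of class `phase_effects`.
#' @export
phase_effects <- function(onset_shift = 0, distance_shift = 0,
                          success_logit_shift = 0, after_effect = 0,
                          extension_on = FALSE) {
  structure(list(onset_shift = onset_shift, distance_shift = distance_shift,
                 success_logit_shift = success_logit_shift,
                 after_effect = after_effect,
                 extension_on = isTRUE(extension_on)),
            class = "phase_effects")
}

# inverse of the minimum-jerk displacement profile on [0, 1]
min_jerk_inverse <- function(frac) {
  stopifnot(frac > 0, frac < 1)
  uniroot(function(u) min_jerk(u) - frac, c(0, 1), tol = 1e-12)$root
}

# quadratic Bezier arc from p0 to the origin with total arc length D;
# returns a lookup giving position and unit tangent at arc length s from
# the start
make_arc <- function(D, angle_deg, height_frac, n_dense = 1200) {
  ang <- angle_deg * pi / 180
  chord <- D  # initial guess; rescaled so arc length == D
  for (it in 1:3) {
    p0 <- c(-chord * cos(ang), chord * sin(ang))
    mid <- p0 / 2
    perp <- c(-p0[2], p0[1]) / sqrt(sum(p0^2))
    ctrl <- mid + height_frac * chord * perp
    tt <- seq(0, 1, length.out = n_dense)
    bx <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * ctrl[1]
    by <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * ctrl[2]
    s <- c(0, cumsum(sqrt(diff(bx)^2 + diff(by)^2)))
    chord <- chord * D / s[length(s)]
  }
  total <- s[length(s)]
  list(
    pos = function(arc_s) {
      arc_s <- pmin(pmax(arc_s, 0), total)
      cbind(approx(s, bx, xout = arc_s, ties = "ordered")$y,
            approx(s, by, xout = arc_s, ties = "ordered")$y)
    },
    tangent = function(arc_s) {
      arc_s <- pmin(pmax(arc_s, 0), total)
      eps <- total / n_dense
      a <- pmax(arc_s - eps, 0)
      b <- pmin(arc_s + eps, total)
      dx <- approx(s, bx, xout = b, ties = "ordered")$y -
            approx(s, bx, xout = a, ties = "ordered")$y
      dy <- approx(s, by, xout = b, ties = "ordered")$y -
            approx(s, by, xout = a, ties = "ordered")$y
      nrm <- sqrt(dx^2 + dy^2)
      cbind(dx / nrm, dy / nrm)
    },
    total = total
  )
}

#' Simulate one peck with known ground truth
#'
#' Generates the three marker tracks of a single peck plus a ground-truth
#' record (true fixation and onset frames, path length, mean velocity and
#' acceleration on the fixation-to-onset window, success probability). The
#' head travels along the arc until the bill tip (advanced
#' `bill_length + extension` along the heading) reaches the target; the
#' aperture pulse is triggered when the head has covered
#' `grasp_trigger_frac` of its path, delayed by `onset_shift` and advanced
#' by `after_effect`.
#'
#' @param sp [species_params].
#' @param fx [phase_effects].
#' @param individual_intercept random intercept of this bird on the
#'   success log-odds.
#' @param onset_offset extra trigger-time shift (s), e.g. per-individual
#'   or per-peck jitter supplied by [simulate_experiment()].
#' @param base_success_logit baseline success log-odds (default gives 90%
#'   control success).
#' @param seed optional integer seed (local RNG; same seed, same peck).
#' @param trial_id,individual,phase,session,peck_order,target_position
#'   metadata for the emitted [peck_trial].
#' @return List with elements `trial` ([peck_trial]) and `truth` (one-row
#'   data frame).
#' @export
simulate_peck <- function(sp, fx = phase_effects(), individual_intercept = 0,
                          onset_offset = 0,
                          base_success_logit = qlogis(0.9), seed = NULL,
                          trial_id = "t1", individual = "bird1",
                          phase = "control", session = 1L, peck_order = 1L,
                          target_position = NA) {
  stopifnot(inherits(sp, "species_params"), inherits(fx, "phase_effects"))
  with_seed(seed, {
    fps <- sp$frame_rate
    dt <- 1 / fps
    L <- sp$bill_length + if (fx$extension_on) sp$extension_length else 0
    # truncated-normal fixation distance; the head must start beyond its
    # own stopping point (bill tip on the target => head stops L short)
    dmean <- sp$fixation_distance_mean + fx$distance_shift
    D <- NA_real_
    for (k in 1:200) {
      D <- rnorm(1, dmean, sp$fixation_distance_sd)
      if (D > L + 0.5) break
      D <- NA_real_
    }
    if (is.na(D)) {
      stop("could not draw a fixation distance beyond the bill length",
           call. = FALSE)
    }
    # the head stops with the bill tip on the target: head path length D - L
    P <- D - L
    arc <- make_arc(D, sp$approach_angle_deg, sp$arc_height_frac)
    T_reach <- max(0.3, rnorm(1, sp$reach_duration, sp$reach_duration_sd))
    # grasp pulse triggered when a fixed fraction of the head path is done
    tau_g <- min_jerk_inverse(sp$grasp_trigger_frac)
    t_g <- tau_g * T_reach + fx$onset_shift - fx$after_effect + onset_offset
    g <- sp$grasp_duration
    u_on <- onset_pulse_fraction(0.20)
    t_on <- t_g + u_on * g
    n_still <- round(sp$still_duration * fps)
    t_end <- max(T_reach, t_g + g) + sp$tail_duration
    if (t_g <= 0 || t_on > T_reach) {
      stop("infeasible parameters: grasping onset falls outside the reach window",
           call. = FALSE)
    }
    n_reach <- ceiling(t_end * fps)
    frames <- 0:(n_still + n_reach - 1)
    t_rel <- (frames - n_still) * dt          # time since reach start; <0 in standstill
    tau <- pmin(pmax(t_rel / T_reach, 0), 1)
    # displacement: minimum jerk plus smooth submovement ripples that
    # vanish at both ends of the reach
    amp <- rnorm(3, 0, sp$submovement_sd)
    ripple <- amp[1] * sin(pi * tau) + amp[2] * sin(2 * pi * tau) +
      amp[3] * sin(3 * pi * tau)
    arc_s <- P * pmin(pmax(min_jerk(tau) + ripple, 0), 1)
    head_xy <- arc$pos(arc_s)
    tang <- arc$tangent(arc_s)
    # aperture pulse
    ap <- rep(sp$offset_aperture, length(frames))
    in_pulse <- t_rel >= t_g & t_rel <= t_g + g
    ap[in_pulse] <- sp$offset_aperture +
      (sp$peak_aperture - sp$offset_aperture) *
      0.5 * (1 - cos(2 * pi * (t_rel[in_pulse] - t_g) / g))
    # bill tips: distance L from the head along the heading, split by the
    # aperture: half-angle asin((ap/2)/L) keeps |tip - head| == L exactly
    half <- asin(pmin(ap / 2 / L, 1))
    rot <- function(v, a) cbind(cos(a) * v[, 1] - sin(a) * v[, 2],
                                sin(a) * v[, 1] + cos(a) * v[, 2])
    upper_xy <- head_xy + L * rot(tang, half)
    lower_xy <- head_xy + L * rot(tang, -half)
    # success outcome
    p_succ <- plogis(base_success_logit + fx$success_logit_shift +
                     individual_intercept)
    outcome <- if (rbinom(1, 1, p_succ) == 1) "success" else "failure"
    # ground truth on the noiseless head track, by the definitional
    # finite-difference formulas
    fix_frame <- 0L
    on_frame <- n_still + round(t_on * fps)
    off_frame <- n_still + round((t_g + g) * fps)
    widx <- 1:(on_frame + 1)          # fixation -> onset (velocity, accel)
    stepd <- sqrt(diff(head_xy[widx, 1])^2 + diff(head_xy[widx, 2])^2)
    v <- stepd / dt
    pidx <- 1:(off_frame + 1)         # fixation -> offset (movement distance)
    path_off <- sum(sqrt(diff(head_xy[pidx, 1])^2 + diff(head_xy[pidx, 2])^2))
    truth <- data.frame(
      trial_id = trial_id, species = sp$species, individual = individual,
      phase = phase,
      true_fixation_frame = fix_frame, true_onset_frame = as.integer(on_frame),
      true_offset_frame = as.integer(off_frame),
      true_onset_s = on_frame * dt,
      true_path_cm = path_off,
      true_velocity_cm_s = mean(v),
      true_accel_cm_s2 = mean(diff(v) / dt),
      true_distance_D = D, true_success_p = p_succ,
      individual_intercept = individual_intercept,
      stringsAsFactors = FALSE
    )
    noise <- function(n) rnorm(n, 0, sp$marker_noise_sd)
    n <- length(frames)
    mk <- function(name, xy) {
      marker_track(name, frames, xy[, 1] + noise(n), xy[, 2] + noise(n), fps)
    }
    trial <- peck_trial(trial_id, sp$species, individual, phase, session,
                        peck_order, target_position,
                        food_size = sp$offset_aperture, outcome = outcome,
                        head = mk("head", head_xy),
                        upper_tip = mk("upper_tip", upper_xy),
                        lower_tip = mk("lower_tip", lower_xy))
    list(trial = trial, truth = truth)
  })
}

#' Experiment design for the simulator
#'
#' @param species `"pigeon"` or `"crow"`.
#' @param params [species_params] (defaults to the species defaults).
#' @param individuals number of birds (default 3, the study design).
#' @param pecks_per_phase named integer vector of peck counts over the
#'   seven phases of [phase_levels()].
#' @param effects named list of [phase_effects], one per phase.
#' @param sigma_u s.d. of the per-individual random intercept on the
#'   success log-odds.
#' @param base_success_logit baseline success log-odds (default 90%
#'   control success).
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species = c("pigeon", "crow"),
                       params = species_params(species),
                       individuals = 3,
                       pecks_per_phase = setNames(rep(20, 7), phase_levels()),
                       effects = default_phase_effects(),
                       sigma_u = 0.5,
                       base_success_logit = qlogis(0.9),
                       seed = 1) {
  species <- match.arg(species)
  stopifnot(individuals >= 1, all(phase_levels() %in% names(pecks_per_phase)),
            all(phase_levels() %in% names(effects)))
  if (sum(pecks_per_phase) < 1) stop("design has no pecks", call. = FALSE)
  structure(list(species = species, params = params,
                 individuals = individuals,
                 pecks_per_phase = pecks_per_phase[phase_levels()],
                 effects = effects[phase_levels()], sigma_u = sigma_u,
                 base_success_logit = base_success_logit, seed = seed),
            class = "sim_config")
}

#' Neutral per-phase effects (extension attached, no behavioural change)
#'
#' @return Named list of [phase_effects] over the seven phases, with the
#'   extension attached in the four extension phases and no kinematic or
#'   performance shifts anywhere.
#' @export
default_phase_effects <- function() {
  eff <- lapply(phase_levels(), function(ph) {
    phase_effects(extension_on = ph %in% c("S1", "S2-4", "S5-7", "S8-10"))
  })
  setNames(eff, phase_levels())
}

#' Pigeon-like experiment preset
#'
#' Encodes the qualitative pigeon pattern at study scale (3 birds, 974
#' pecks over the seven phases): a persistent success deficit and delayed
#' grasping onset throughout the extension phases, a continued deficit
#' plus an *advanced* onset (motor after-effect) immediately after
#' removal, and full recovery at follow-up.
#'
#' @param seed integer seed.
#' @return A [sim_config].
#' @export
preset_pigeon_like <- function(seed = 1) {
  counts <- c(control = 118, S1 = 49, `S2-4` = 221, `S5-7` = 218,
              `S8-10` = 231, removal = 84, `follow-up` = 53)
  eff <- list(
    control = phase_effects(),
    S1 = phase_effects(onset_shift = 0.040, success_logit_shift = -2.8,
                       extension_on = TRUE),
    `S2-4` = phase_effects(onset_shift = 0.012, success_logit_shift = -2.8,
                           extension_on = TRUE),
    `S5-7` = phase_effects(onset_shift = 0.012, success_logit_shift = -2.8,
                           extension_on = TRUE),
    `S8-10` = phase_effects(onset_shift = 0.012, success_logit_shift = -2.8,
                            extension_on = TRUE),
    removal = phase_effects(after_effect = 0.040, success_logit_shift = -1.8),
    `follow-up` = phase_effects()
  )
  sim_config("pigeon", individuals = 3, pecks_per_phase = counts,
             effects = eff, sigma_u = 0.3, seed = seed)
}

#' Crow-like experiment preset
#'
#' Encodes the qualitative crow pattern at study scale (3 birds, 378
#' pecks): a transient success deficit and onset delay in the first
#' extension session only, rapid recovery achieved by initiating the reach
#' closer to the target (shorter movement distance through S5-7), and no
#' after-effect on removal.
#'
#' @param seed integer seed.
#' @return A [sim_config].
#' @export
preset_crow_like <- function(seed = 1) {
  counts <- c(control = 80, S1 = 23, `S2-4` = 61, `S5-7` = 65,
              `S8-10` = 88, removal = 30, `follow-up` = 31)
  eff <- list(
    control = phase_effects(),
    S1 = phase_effects(onset_shift = 0.015, success_logit_shift = -3.0,
                       distance_shift = -1.5, extension_on = TRUE),
    `S2-4` = phase_effects(distance_shift = -1.5, extension_on = TRUE),
    `S5-7` = phase_effects(distance_shift = -1.5, extension_on = TRUE),
    `S8-10` = phase_effects(extension_on = TRUE),
    removal = phase_effects(),
    `follow-up` = phase_effects()
  )
  sim_config("crow", individuals = 3, pecks_per_phase = counts,
             effects = eff, sigma_u = 0.3, seed = seed)
}

#' Simulate a full pecking experiment
#'
#' Emits one [peck_trial] per designed peck across the seven phases, with
#' per-individual random intercepts on the success log-odds (Normal(0,
#' sigma_u^2)) and per-individual plus per-peck jitter of the grasp
#' trigger, plus the ground-truth table.
#'
#' @param config a [sim_config] (e.g. [preset_pigeon_like()]).
#' @return List with `trials` (list of [peck_trial]) and `truth`
#'   (data frame, one row per peck, including the per-phase true effect
#'   fields).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    sp <- config$params
    inds <- sprintf("%s%02d", substr(config$species, 1, 1),
                    seq_len(config$individuals))
    u_succ <- rnorm(config$individuals, 0, config$sigma_u)
    u_onset <- rnorm(config$individuals, 0, sp$onset_individual_sd)
    trials <- list()
    truth_rows <- list()
    counter <- 0L
    for (ph in phase_levels()) {
      n_ph <- config$pecks_per_phase[[ph]]
      fx <- config$effects[[ph]]
      session <- match(ph, phase_levels())
      for (j in seq_len(n_ph)) {
        counter <- counter + 1L
        bird <- ((j - 1L) %% config$individuals) + 1L
        is_pigeon <- config$species == "pigeon"
        res <- simulate_peck(
          sp, fx, individual_intercept = u_succ[bird],
          onset_offset = u_onset[bird] + rnorm(1, 0, sp$onset_jitter_sd),
          base_success_logit = config$base_success_logit,
          trial_id = sprintf("%s_%s_%04d", config$species, ph, counter),
          individual = inds[bird], phase = ph, session = session,
          peck_order = if (is_pigeon) ((j - 1L) %% 10L) + 1L else 1L,
          target_position = if (is_pigeon) ((j - 1L) %% 10L) + 1L else NA
        )
        trials[[counter]] <- res$trial
        truth_rows[[counter]] <- res$truth
      }
    }
    list(trials = trials, truth = do.call(rbind, truth_rows))
  })
}
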