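# Orchestration: simulate (or read) -> extract -> fit -> report, with
# plain delimited tables between stages so each stage is re-entrant.

#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config] or preset name) or the pair
#' `track_path`/`metadata_path` must be given.
#'
#' @param outdir output directory (created if needed).
#' @param simulation a [sim_config], or `"pigeon-like"`/`"crow-like"`.
#' @param track_path,metadata_path input CSVs in the [read_trials()]
#'   formats, as the alternative to simulation.
#' @param kinematics options from [kinematics_config()].
#' @param n_quad quadrature nodes for the binomial GLMM.
#' @param ci_method `"nonoverlap"` or `"difference"` (see [phase_cis()]).
#' @param seed integer seed recorded in the manifest and used for
#'   simulation.
#' @param quiet suppress stage log messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, simulation = NULL,
                            track_path = NULL, metadata_path = NULL,
                            kinematics = kinematics_config(), n_quad = 15,
                            ci_method = "nonoverlap", seed = 1,
                            quiet = FALSE) {
  have_sim <- !is.null(simulation)
  have_files <- !is.null(track_path) && !is.null(metadata_path)
  if (have_sim == have_files) {
    stop("give exactly one of 'simulation' or track/metadata paths",
         call. = FALSE)
  }
  if (is.character(simulation)) {
    simulation <- switch(match.arg(simulation, c("pigeon-like", "crow-like")),
                         "pigeon-like" = preset_pigeon_like(seed),
                         "crow-like" = preset_crow_like(seed))
  }
  if (!is.null(simulation)) simulation$seed <- seed
  structure(list(outdir = outdir, simulation = simulation,
                 track_path = track_path, metadata_path = metadata_path,
                 kinematics = kinematics, n_quad = n_quad,
                 ci_method = ci_method, seed = seed, quiet = quiet),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `simulation` may be a
#' preset name or a block with `species`, `individuals`, `sigma_u`,
#' `pecks_per_phase` and per-phase effect blocks.
#'
#' @param path YAML file.
#' @param ... overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (is.list(y$simulation)) {
    s <- y$simulation
    eff <- default_phase_effects()
    for (ph in names(s$effects %||% list())) {
      eff[[ph]] <- do.call(phase_effects, s$effects[[ph]])
    }
    ppp <- unlist(s$pecks_per_phase %||% setNames(rep(20, 7), phase_levels()))
    y$simulation <- sim_config(
      species = s$species %||% "pigeon",
      individuals = s$individuals %||% 3,
      pecks_per_phase = ppp, effects = eff,
      sigma_u = s$sigma_u %||% 0.5,
      seed = y$seed %||% 1
    )
  }
  kin <- do.call(kinematics_config, y$kinematics %||% list())
  args <- list(outdir = y$outdir, simulation = y$simulation,
               track_path = y$track_path, metadata_path = y$metadata_path,
               kinematics = kin, n_quad = y$n_quad %||% 15,
               ci_method = y$ci_method %||% "nonoverlap",
               seed = y$seed %||% 1, quiet = isTRUE(y$quiet))
  do.call(pipeline_config, modifyList(args, list(...)))
}

pipe_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf("[peckkin] %s", sprintf(fmt, ...)))
}

#' Per-phase success summary
#'
#' Success counts and rates per phase and per individual, plus a pooled
#' per-phase rate with a model-based 95% CI from the random-intercept
#' binomial GLMM (response scale).
#'
#' @param trials data frame with at least `phase`, `individual`,
#'   `outcome` columns (e.g. a kinematics table or trial metadata).
#' @return List with `by_individual` and `by_phase` data frames; empty
#'   phases are omitted with a warning.
#' @export
summarize_success <- function(trials) {
  stopifnot(all(c("phase", "individual", "outcome") %in% names(trials)))
  y <- as_binary_response(trials$outcome)
  empty <- setdiff(phase_levels(), unique(as.character(trials$phase)))
  if (length(empty) > 0) {
    warning("phase(s) with no pecks omitted: ", paste(empty, collapse = ", "))
  }
  ph <- droplevels(as_phase(trials$phase))
  by_ind <- aggregate(list(successes = y),
                      list(phase = ph, individual = trials$individual), sum)
  by_ind$n <- aggregate(list(n = rep(1L, length(y))),
                        list(phase = ph, individual = trials$individual),
                        sum)$n
  by_ind$rate <- by_ind$successes / by_ind$n
  by_phase <- aggregate(list(successes = y), list(phase = ph), sum)
  by_phase$n <- as.vector(table(ph)[as.character(by_phase$phase)])
  by_phase$rate <- by_phase$successes / by_phase$n
  ci <- tryCatch({
    d <- data.frame(outcome = y, phase = ph, individual = trials$individual)
    fit <- fit_glmm_binomial(outcome ~ phase, d, "individual")
    pc <- phase_cis(fit)
    data.frame(phase = pc$phase, rate_fit = plogis(pc$estimate),
               lower95 = plogis(pc$lower95), upper95 = plogis(pc$upper95),
               stringsAsFactors = FALSE)
  }, error = function(e) NULL)
  if (!is.null(ci)) {
    by_phase <- merge(by_phase, ci, by = "phase", sort = FALSE)
  }
  by_phase <- by_phase[order(match(by_phase$phase, phase_levels())), ]
  rownames(by_phase) <- NULL
  list(by_individual = by_ind, by_phase = by_phase)
}

#' Run the full pecking-analysis pipeline
#'
#' Stages: `simulate` (or read input files) writes `tracks.csv`,
#' `trials.csv` and, for simulations, `ground_truth.csv`; `extract` writes
#' `kinematics.csv`; `fit` writes `model_summary.csv` and `phase_ci.csv`;
#' `report` writes `success_by_phase.csv`, `mean_trajectory.csv` and the
#' run manifest `manifest.json` (config echo, seed, package version,
#' exclusion counts). Each stage reads the previous stage's files, so the
#' pipeline can be resumed stage by stage.
#'
#' @param config a [pipeline_config] or path to a YAML config.
#' @param stages subset of `c("simulate", "extract", "fit", "report")`.
#' @return Invisibly, a list with the output paths and the fitted-model
#'   objects of the `fit` stage.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "extract", "fit", "report")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    tracks = file.path(out, "tracks.csv"),
    trials = file.path(out, "trials.csv"),
    truth = file.path(out, "ground_truth.csv"),
    kinematics = file.path(out, "kinematics.csv"),
    model_summary = file.path(out, "model_summary.csv"),
    phase_ci = file.path(out, "phase_ci.csv"),
    success = file.path(out, "success_by_phase.csv"),
    trajectory = file.path(out, "mean_trajectory.csv"),
    manifest = file.path(out, "manifest.json")
  )
  result <- list(paths = paths)

  if ("simulate" %in% stages) {
    if (!is.null(config$simulation)) {
      pipe_log(config$quiet, "simulate: %s preset, seed %d",
               config$simulation$species, config$seed)
      sim <- simulate_experiment(config$simulation)
      write_trials(sim$trials, paths$tracks, paths$trials)
      write_results(sim$truth, paths$truth)
    } else {
      pipe_log(config$quiet, "simulate: copying input files")
      trials <- read_trials(config$track_path, config$metadata_path)
      write_trials(trials, paths$tracks, paths$trials)
    }
  }

  if ("extract" %in% stages) {
    pipe_log(config$quiet, "extract: reading %s", paths$tracks)
    trials <- read_trials(paths$tracks, paths$trials)
    kin <- kinematics_table(trials, config$kinematics)
    write_results(kin, paths$kinematics)
    pipe_log(config$quiet, "extract: %d pecks, %d retained",
             nrow(kin), sum(kin$retained))
  }

  if ("fit" %in% stages) {
    kin <- read.csv(paths$kinematics, stringsAsFactors = FALSE)
    ret <- kin[kin$retained, ]
    pipe_log(config$quiet, "fit: success GLMM and onset LMM on %d pecks",
             nrow(ret))
    succ <- success_phase_analysis(kin, n_quad = config$n_quad,
                                   ci_method = config$ci_method)
    ons <- onset_phase_analysis(ret, ci_method = config$ci_method)
    ms <- rbind(
      data.frame(model = "success", term = "phase",
                 estimate = NA_real_, se = NA_real_,
                 chisq = succ$lrt_phase$statistic, df = succ$lrt_phase$df,
                 p = succ$lrt_phase$p_value, stringsAsFactors = FALSE),
      data.frame(model = "onset", term = ons$lrt_terms$term,
                 estimate = c(NA_real_, ons$fit$beta[c("distance_cm", "accel_cm_s2")]),
                 se = c(NA_real_, ons$fit$se_beta[c("distance_cm", "accel_cm_s2")]),
                 chisq = ons$lrt_terms$chisq, df = ons$lrt_terms$df,
                 p = ons$lrt_terms$p, stringsAsFactors = FALSE)
    )
    ms <- rbind(ms, data.frame(
      model = c("success", "onset", "onset"),
      term = c("dispersion", "r2_marginal", "r2_conditional"),
      estimate = c(succ$dispersion, ons$r2["marginal"], ons$r2["conditional"]),
      se = NA_real_, chisq = NA_real_, df = NA_real_, p = NA_real_,
      stringsAsFactors = FALSE
    ))
    write_results(ms, paths$model_summary)
    pc <- rbind(cbind(model = "success", succ$phase_ci),
                cbind(model = "onset", ons$phase_ci))
    write_results(pc, paths$phase_ci)
    result$success_analysis <- succ
    result$onset_analysis <- ons
  }

  if ("report" %in% stages) {
    pipe_log(config$quiet, "report: summaries and manifest")
    kin <- read.csv(paths$kinematics, stringsAsFactors = FALSE)
    ss <- summarize_success(kin)
    write_results(ss$by_phase, paths$success)
    trials <- read_trials(paths$tracks, paths$trials)
    by_phase <- split(trials, vapply(trials, `[[`, "", "phase"))
    traj <- NULL
    for (ph in intersect(phase_levels(), names(by_phase))) {
      mt <- tryCatch(
        mean_trajectory(by_phase[[ph]], marker = "head",
                        config = config$kinematics),
        error = function(e) NULL
      )
      if (!is.null(mt)) traj <- rbind(traj, cbind(phase = ph, mt))
    }
    if (!is.null(traj)) write_results(traj, paths$trajectory)
    excl <- table(factor(kin$retained, levels = c(TRUE, FALSE)))
    manifest <- list(
      package = "peckkin",
      version = as.character(utils::packageVersion("peckkin")),
      seed = config$seed,
      ci_method = config$ci_method, n_quad = config$n_quad,
      kinematics = config$kinematics,
      simulation = if (!is.null(config$simulation)) {
        list(species = config$simulation$species,
             individuals = config$simulation$individuals,
             sigma_u = config$simulation$sigma_u,
             pecks_per_phase = as.list(config$simulation$pecks_per_phase))
      },
      pecks = list(total = nrow(kin), retained = as.integer(excl[["TRUE"]]),
                   excluded = as.integer(excl[["FALSE"]]))
    )
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(result)
}
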