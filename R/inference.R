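# Likelihood-ratio tests, overdispersion, per-phase confidence intervals
# and Nakagawa R-squared for the mixed-model fits.

#' Likelihood-ratio test between nested mixed-model fits
#'
#' @param full,reduced ML fits from [fit_glmm_binomial()] or [fit_lmm()],
#'   on the same data, with the reduced fixed-effect terms nested in the
#'   full model's.
#' @return An object of class `lrt_result`: list with `statistic` (the
#'   chi-squared value, clipped at 0), `df` (difference in fixed-effect
#'   count) and `p_value` (upper chi-squared tail).
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "peckkin_mixfit"), inherits(reduced, "peckkin_mixfit"))
  if (full$method != "ML" || reduced$method != "ML") {
    stop("likelihood-ratio tests require ML fits", call. = FALSE)
  }
  if (full$n_obs != reduced$n_obs) {
    stop("fits are not on the same data (different n)", call. = FALSE)
  }
  if (reduced$n_fixed > full$n_fixed) {
    stop("reduced model has more fixed effects than the full model", call. = FALSE)
  }
  df <- full$n_fixed - reduced$n_fixed
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  # df = 0 (a model compared with itself) is allowed and gives p = NA
  structure(list(statistic = stat, df = df,
                 p_value = if (df >= 1) pchisq(stat, df, lower.tail = FALSE)
                           else NA_real_),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi^2(%d) = %.4f, p = %.4g\n", x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Overdispersion ratio of a binomial mixed model
#'
#' Pearson chi-squared divided by the residual degrees of freedom, the
#' standard check that the binomial variance assumption holds (values near
#' 1: no overdispersion). Fitted values are conditional: random intercepts
#' at their modes. The residual df charge one parameter per fixed effect
#' and one per group.
#'
#' @param fit a [fit_glmm_binomial()] fit.
#' @param aggregate if `TRUE`, observations sharing a fitted probability
#'   and group are pooled into binomial counts before computing Pearson
#'   residuals (proportion-level residuals); default `FALSE` uses
#'   per-observation Bernoulli residuals.
#' @return The dispersion ratio.
#' @export
dispersion <- function(fit, aggregate = FALSE) {
  if (!inherits(fit, "peckkin_glmm")) {
    stop("dispersion is defined for binomial fits", call. = FALSE)
  }
  eta <- drop(fit$X %*% fit$beta) + fit$modes[as.integer(fit$group)]
  p <- plogis(eta)
  if (aggregate) {
    cell <- paste(signif(eta, 12), as.integer(fit$group))
    yy <- tapply(fit$y, cell, sum)
    nn <- tapply(rep(1, fit$n_obs), cell, sum)
    pp <- tapply(p, cell, mean)
    pearson <- sum((yy - nn * pp)^2 / (nn * pp * (1 - pp)))
    rdf <- length(yy) - fit$n_fixed - fit$n_groups
  } else {
    pearson <- sum((fit$y - p)^2 / (p * (1 - p)))
    rdf <- fit$n_obs - fit$n_fixed - fit$n_groups
  }
  if (pearson < 1e-10) return(0)   # perfect fit regardless of df
  if (rdf <= 0) stop("non-positive residual degrees of freedom", call. = FALSE)
  pearson / rdf
}

# internal: representative fixed-effect rows per phase level: phase dummy
# set, every other column at its observed mean
phase_design_rows <- function(fit, phase_var) {
  cn <- colnames(fit$X)
  pref <- paste0(phase_var)
  dummy_cols <- grep(paste0("^", pref), cn)
  if (length(dummy_cols) == 0) {
    stop("'", phase_var, "' is not a fixed factor in the fit", call. = FALSE)
  }
  if (any(cn[dummy_cols] == paste0(pref, "control"))) {
    stop("the phase factor was not coded with 'control' as reference; ",
         "convert it with as_phase() before fitting", call. = FALSE)
  }
  base <- colMeans(fit$X)
  base[dummy_cols] <- 0
  lev_names <- sub(paste0("^", pref), "", cn[dummy_cols])
  levs <- c("control", lev_names)
  rows <- matrix(rep(base, length(levs)), nrow = length(levs), byrow = TRUE,
                 dimnames = list(levs, cn))
  for (k in seq_along(dummy_cols)) rows[k + 1, dummy_cols[k]] <- 1
  rows
}

#' Per-phase estimates with 95% confidence intervals against control
#'
#' Wald 95% CIs of the model's fixed-effect estimate for each experimental
#' phase (at the observed mean of any covariates), mirroring the graphical
#' comparison of per-phase parameters against the control band: a phase is
#' flagged `differs_from_control` when its CI and the control CI do not
#' overlap (default), or when the CI of the difference excludes 0
#' (`method = "difference"`).
#'
#' @param fit a mixed-model fit whose fixed effects include the phase
#'   factor.
#' @param phase_var name of the phase factor (default `"phase"`).
#' @param method `"nonoverlap"` (interval non-overlap, conservative) or
#'   `"difference"` (CI of the contrast with control).
#' @param level confidence level (default 0.95).
#' @return Data frame with `phase`, `estimate`, `lower95`, `upper95`,
#'   `differs_from_control` (link scale for binomial fits).
#' @export
phase_cis <- function(fit, phase_var = "phase",
                      method = c("nonoverlap", "difference"), level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "peckkin_mixfit"))
  rows <- phase_design_rows(fit, phase_var)
  z <- qnorm(1 - (1 - level) / 2)
  est <- drop(rows %*% fit$beta)
  se <- sqrt(pmax(rowSums((rows %*% fit$vcov_beta) * rows), 0))
  lo <- est - z * se
  hi <- est + z * se
  ctrl <- 1
  if (method == "nonoverlap") {
    differs <- (lo > hi[ctrl]) | (hi < lo[ctrl])
  } else {
    d <- sweep(rows, 2, rows[ctrl, ])
    dse <- sqrt(pmax(rowSums((d %*% fit$vcov_beta) * d), 0))
    dest <- est - est[ctrl]
    differs <- (dest - z * dse > 0) | (dest + z * dse < 0)
  }
  differs[ctrl] <- FALSE
  data.frame(phase = rownames(rows), estimate = est,
             lower95 = lo, upper95 = hi,
             differs_from_control = differs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Marginal and conditional R-squared (Nakagawa-Schielzeth)
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional), relative to the total of
#' fixed-effect variance, random-intercept variance and residual variance.
#' For the binomial-logit family the residual variance on the latent scale
#' is `pi^2 / 3`.
#'
#' @param fit a mixed-model fit.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "peckkin_mixfit"))
  # population variance of the fixed-effect predictor, consistent with the
  # ML residual variance (n denominator), so marginal R^2 collapses to the
  # classical R^2 when sigma_u^2 = 0
  eta <- drop(fit$X %*% fit$beta)
  var_f <- mean((eta - mean(eta))^2)
  var_e <- if (inherits(fit, "peckkin_glmm")) pi^2 / 3 else fit$sigma_e2
  denom <- var_f + fit$sigma_u2 + var_e
  if (denom <= 0) stop("zero total variance; R^2 undefined", call. = FALSE)
  c(marginal = var_f / denom,
    conditional = (var_f + fit$sigma_u2) / denom)
}

# internal: drop one term from a formula, keeping the rest
drop_term_formula <- function(formula, term) {
  tl <- attr(terms(formula), "term.labels")
  keep <- setdiff(tl, term)
  rhs <- if (length(keep) == 0) "1" else paste(keep, collapse = " + ")
  stats::reformulate(rhs, response = all.vars(formula)[1])
}

# internal: type-II termwise LRTs (each term dropped respecting
# marginality: main effects tested without their interactions)
termwise_lrt <- function(formula, data, group, family = c("gaussian", "binomial"),
                         n_quad = 15) {
  family <- match.arg(family)
  fitter <- function(f) {
    if (family == "binomial") fit_glmm_binomial(f, data, group, n_quad = n_quad)
    else fit_lmm(f, data, group, method = "ML")
  }
  tl <- attr(terms(formula), "term.labels")
  ord <- attr(terms(formula), "order")
  out <- NULL
  for (i in seq_along(tl)) {
    term <- tl[i]
    if (ord[i] == 1) {
      # main effect: compare within the model excluding interactions
      # containing it
      vars_in <- function(t) strsplit(t, ":", fixed = TRUE)[[1]]
      inter <- tl[ord > 1 & vapply(tl, function(t) term %in% vars_in(t), logical(1))]
      base_terms <- setdiff(tl, inter)
      f_full <- stats::reformulate(base_terms, response = all.vars(formula)[1])
      f_red <- drop_term_formula(f_full, term)
    } else {
      f_full <- formula
      f_red <- drop_term_formula(formula, term)
    }
    res <- lrt(fitter(f_full), fitter(f_red))
    out <- rbind(out, data.frame(term = term, chisq = res$statistic,
                                 df = res$df, p = res$p_value,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Control-phase independence checks
#'
#' For control-phase records of array-pecking birds, fits the three
#' mixed models that justify treating successive pecks as independent
#' events: grasping success (binomial), grasping-onset time and movement
#' distance (Gaussian), each against target position, peck order and their
#' interaction, with the individual as random intercept, and reports a
#' termwise likelihood-ratio test for every term.
#'
#' @param kinematics data frame of retained control-phase records with
#'   columns `outcome`, `onset_s`, `distance_cm`, `target_position`,
#'   `peck_order` and `individual`.
#' @return Named list of data frames (`success`, `onset`, `distance`),
#'   each with `term`, `chisq`, `df`, `p`; a model whose response is
#'   degenerate (constant) is reported as `NULL` with a warning.
#' @export
control_phase_checks <- function(kinematics) {
  need <- c("outcome", "onset_s", "distance_cm", "target_position",
            "peck_order", "individual")
  miss <- setdiff(need, names(kinematics))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- kinematics[stats::complete.cases(kinematics[need]), need, drop = FALSE]
  out <- list(success = NULL, onset = NULL, distance = NULL)
  y <- as_binary_response(d$outcome)
  if (length(unique(y)) < 2) {
    warning("degenerate success response (constant); success model not fitted")
  } else {
    d$success <- y
    out$success <- termwise_lrt(success ~ target_position * peck_order,
                                d, "individual", family = "binomial")
  }
  for (resp in c("onset_s", "distance_cm")) {
    nm <- if (resp == "onset_s") "onset" else "distance"
    if (var(d[[resp]]) < .Machine$double.eps) {
      warning("degenerate ", resp, " response (constant); model not fitted")
    } else {
      f <- stats::reformulate("target_position * peck_order", response = resp)
      out[[nm]] <- termwise_lrt(f, d, "individual", family = "gaussian")
    }
  }
  out
}

#' Success-rate phase analysis
#'
#' The headline performance analysis: a binomial random-intercept GLMM of
#' pecking outcome against experimental phase (individual as random
#' factor), its likelihood-ratio test for the phase effect, the
#' overdispersion ratio, and per-phase 95% CIs compared against control.
#'
#' @param pecks per-peck data frame with columns `outcome`, `phase`,
#'   `individual`.
#' @param n_quad quadrature nodes for the GLMM.
#' @param ci_method passed to [phase_cis()].
#' @return List with `fit`, `lrt_phase`, `dispersion`, `phase_ci`.
#' @export
success_phase_analysis <- function(pecks, n_quad = 15,
                                   ci_method = c("nonoverlap", "difference")) {
  ci_method <- match.arg(ci_method)
  pecks$phase <- as_phase(pecks$phase)
  pecks <- droplevels(pecks[stats::complete.cases(pecks[c("outcome", "phase", "individual")]), ])
  full <- fit_glmm_binomial(outcome ~ phase, pecks, "individual", n_quad)
  null <- fit_glmm_binomial(outcome ~ 1, pecks, "individual", n_quad)
  list(fit = full,
       lrt_phase = lrt(full, null),
       dispersion = dispersion(full),
       phase_ci = phase_cis(full, method = ci_method))
}

#' Grasping-onset phase analysis
#'
#' The headline kinematic analysis: a Gaussian random-intercept LMM of
#' grasping-onset time against experimental phase with movement distance
#' and mean acceleration as covariates (velocity is excluded because it is
#' collinear with distance), termwise likelihood-ratio tests, per-phase
#' 95% CIs against control, and marginal/conditional R-squared.
#'
#' @param pecks per-peck data frame with columns `onset_s`, `phase`,
#'   `distance_cm`, `accel_cm_s2`, `individual` (excluded pecks dropped).
#' @param ci_method passed to [phase_cis()].
#' @return List with `fit`, `lrt_terms`, `phase_ci`, `r2`.
#' @export
onset_phase_analysis <- function(pecks,
                                 ci_method = c("nonoverlap", "difference")) {
  ci_method <- match.arg(ci_method)
  pecks$phase <- as_phase(pecks$phase)
  need <- c("onset_s", "phase", "distance_cm", "accel_cm_s2", "individual")
  pecks <- droplevels(pecks[stats::complete.cases(pecks[need]), ])
  f <- onset_s ~ phase + distance_cm + accel_cm_s2
  fit <- fit_lmm(f, pecks, "individual", method = "ML")
  list(fit = fit,
       lrt_terms = termwise_lrt(f, pecks, "individual", family = "gaussian"),
       phase_ci = phase_cis(fit, method = ci_method),
       r2 = r2_nakagawa(fit))
}
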