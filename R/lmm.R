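# Random-intercept linear mixed model by profiled likelihood.
#
# With a single grouping factor the covariance of group i is
# sigma_e^2 (I + theta J) with theta = sigma_u^2 / sigma_e^2, so beta and
# sigma_e^2 have closed forms given theta (Woodbury identity per group) and
# the fit reduces to a 1-D optimisation of the profile (restricted)
# log-likelihood over theta.

# profile quantities at a given theta; returns beta, sigma_e2 and the
# profile log-likelihood for ML or REML
lmm_profile <- function(theta, X, y, idx, method) {
  p <- ncol(X)
  n <- length(y)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  logdet <- 0
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    yi <- y[ii]
    ni <- length(ii)
    ci <- theta / (1 + theta * ni)
    sx <- colSums(Xi)
    sy <- sum(yi)
    XtVX <- XtVX + crossprod(Xi) - ci * tcrossprod(sx)
    XtVy <- XtVy + drop(crossprod(Xi, yi)) - ci * sx * sy
    logdet <- logdet + log1p(theta * ni)
  }
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -Inf))
  beta <- backsolve(ch, backsolve(ch, XtVy, transpose = TRUE))
  q <- 0
  for (ii in idx) {
    ri <- y[ii] - drop(X[ii, , drop = FALSE] %*% beta)
    ni <- length(ii)
    ci <- theta / (1 + theta * ni)
    q <- q + sum(ri^2) - ci * sum(ri)^2
  }
  if (method == "ML") {
    s2 <- q / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  } else {
    s2 <- q / (n - p)
    # REML adds log det(X' V*^-1 X) with V* = I + theta ZZ' (unscaled)
    ld_xvx <- 2 * sum(log(diag(ch)))
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdet + ld_xvx + (n - p))
  }
  list(beta = beta, sigma_e2 = s2, loglik = ll, XtVX = XtVX)
}

#' Fit a random-intercept linear mixed model
#'
#' Maximum-likelihood (or REML) fit of a Gaussian mixed model with a
#' single random intercept, e.g. grasping-onset time against experimental
#' phase with movement distance and mean acceleration as covariates and
#' the individual as the random factor. The fixed effects and residual
#' variance are profiled out and the variance ratio
#' `theta = sigma_u^2 / sigma_e^2` is optimised in one dimension; a
#' boundary optimum is reported as `sigma_u2 = 0`.
#'
#' @param formula fixed-effects formula, e.g.
#'   `onset_s ~ phase + distance_cm + accel_cm_s2`.
#' @param data data frame.
#' @param group name of the grouping column for the random intercept.
#' @param method `"ML"` (default; required for likelihood-ratio tests) or
#'   `"REML"` (for variance reporting).
#' @return An object of class `c("peckkin_lmm", "peckkin_mixfit")` with
#'   `beta`, `se_beta`, `vcov_beta`, `sigma_u2`, `sigma_e2`, `loglik`,
#'   counts and convergence flag.
#' @export
fit_lmm <- function(formula, data, group, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), group %in% names(data))
  mf <- model.frame(formula, data)
  y <- as.numeric(model.response(mf))
  X <- model.matrix(formula, data)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("response and covariates must be finite", call. = FALSE)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  g <- factor(data[[group]])
  idx <- split(seq_along(y), g)

  obj <- function(lt) -lmm_profile(exp(lt), X, y, idx, method)$loglik
  opt <- optimize(obj, interval = c(-15, 15), tol = 1e-9)
  cand <- list(theta = exp(opt$minimum), nll = opt$objective)
  bound <- -lmm_profile(0, X, y, idx, method)$loglik
  if (bound <= cand$nll + 1e-10) cand <- list(theta = 0, nll = bound)
  prof <- lmm_profile(cand$theta, X, y, idx, method)
  vcov_beta <- prof$sigma_e2 * solve(prof$XtVX)
  beta <- setNames(drop(prof$beta), colnames(X))

  # conditional modes (BLUPs) of the group intercepts
  theta <- cand$theta
  modes <- vapply(idx, function(ii) {
    ri <- y[ii] - drop(X[ii, , drop = FALSE] %*% beta)
    ni <- length(ii)
    theta * sum(ri) / (1 + theta * ni)
  }, numeric(1))

  structure(
    list(beta = beta,
         se_beta = setNames(sqrt(diag(vcov_beta)), colnames(X)),
         vcov_beta = vcov_beta,
         sigma_u2 = theta * prof$sigma_e2, sigma_e2 = prof$sigma_e2,
         loglik = prof$loglik, n_obs = length(y), n_groups = length(idx),
         n_fixed = ncol(X), converged = is.finite(prof$loglik),
         separation = FALSE, method = method, family = "gaussian",
         modes = modes, X = X, y = y, group = g,
         formula = formula, group_name = group),
    class = c("peckkin_lmm", "peckkin_mixfit")
  )
}
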