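# Random-intercept binomial GLMM fitted by maximum likelihood with
# adaptive Gauss-Hermite quadrature.
#
# The marginal likelihood integrates each group's random intercept out of
# the conditional Bernoulli likelihood with a 1-D Gauss-Hermite rule whose
# nodes are recentred at the conditional mode and rescaled by the local
# curvature (Laplace rescaling), so a modest number of nodes (15 by
# default) integrates accurately even for extreme groups.

# Gauss-Hermite nodes/weights for weight exp(-z^2) (Golub-Welsch)
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# conditional mode and curvature of the random intercept of one group
# eta0: fixed-effect linear predictor; y: 0/1; su2: sigma_u^2
glmm_group_mode <- function(eta0, y, su2) {
  b <- 0
  for (it in 1:50) {
    p <- plogis(eta0 + b)
    g <- sum(y - p) - b / su2
    h <- -sum(p * (1 - p)) - 1 / su2
    step <- g / h
    b <- b - step
    if (abs(step) < 1e-12) break
  }
  p <- plogis(eta0 + b)
  list(mode = b, curv = -sum(p * (1 - p)) - 1 / su2)
}

# log marginal likelihood contribution of one group by adaptive GH
glmm_group_loglik <- function(eta0, y, sigma_u, gh) {
  if (sigma_u < 1e-8) {
    return(sum(dbinom(y, 1, plogis(eta0), log = TRUE)))
  }
  su2 <- sigma_u^2
  m <- glmm_group_mode(eta0, y, su2)
  tau <- 1 / sqrt(-m$curv)
  bk <- m$mode + sqrt(2) * tau * gh$nodes
  hk <- vapply(bk, function(b) {
    sum(dbinom(y, 1, plogis(eta0 + b), log = TRUE)) +
      dnorm(b, 0, sigma_u, log = TRUE)
  }, numeric(1))
  log(sqrt(2) * tau) + logsumexp(log(gh$weights) + gh$nodes^2 + hk)
}

# response coercion: factor success/failure, logical, or 0/1 numeric
as_binary_response <- function(y) {
  if (is.character(y)) y <- factor(y)
  if (is.factor(y)) {
    lev <- levels(y)
    if (all(lev %in% c("failure", "success"))) {
      return(as.integer(y == "success"))
    }
    if (length(lev) != 2) stop("response must be binary", call. = FALSE)
    return(as.integer(y == lev[2]))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("response must be binary (0/1)", call. = FALSE)
  as.integer(y)
}

#' Fit a random-intercept binomial GLMM
#'
#' Maximum-likelihood fit of a logit-link binomial mixed model with a
#' single random intercept, e.g. pecking success against experimental
#' phase with the individual bird as the random factor. The random
#' intercept is integrated out by adaptive Gauss-Hermite quadrature;
#' standard errors are Wald, from the observed information at the optimum.
#'
#' @param formula fixed-effects formula, e.g. `outcome ~ phase`. The
#'   response may be 0/1, logical, or a `success`/`failure` factor.
#' @param data data frame.
#' @param group name of the grouping column for the random intercept
#'   (e.g. `"individual"`).
#' @param n_quad number of quadrature nodes (default 15).
#' @param max_restarts bounded random restarts on non-convergence.
#' @return An object of class `c("peckkin_glmm", "peckkin_mixfit")` with
#'   elements `beta`, `se_beta`, `vcov_beta`, `sigma_u2`, `loglik`,
#'   `n_obs`, `n_groups`, `n_fixed`, `converged`, `separation`, `modes`
#'   (conditional modes per group) and the model frame ingredients.
#' @export
fit_glmm_binomial <- function(formula, data, group, n_quad = 15,
                              max_restarts = 3) {
  stopifnot(is.data.frame(data), group %in% names(data))
  mf <- model.frame(formula, data)
  y <- as_binary_response(model.response(mf))
  X <- model.matrix(formula, data)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  g <- factor(data[[group]])
  idx <- split(seq_along(y), g)
  p <- ncol(X)
  gh <- gauss_hermite(n_quad)

  negll <- function(par) {
    beta <- par[1:p]
    sigma_u <- par[p + 1]
    eta <- drop(X %*% beta)
    ll <- 0
    for (ii in idx) {
      ll <- ll + glmm_group_loglik(eta[ii], y[ii], sigma_u, gh)
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  start_beta <- tryCatch(
    coef(glm(y ~ X - 1, family = binomial())),
    error = function(e) rep(0, p)
  )
  start_beta[!is.finite(start_beta)] <- 0
  start <- c(start_beta, 0.5)
  best <- NULL
  for (r in 0:max_restarts) {
    # deterministic restart ladder: shrink betas, grow the variance start
    st <- if (r == 0) start else c(start_beta / (r + 1), 0.5 * 2^r)
    opt <- tryCatch(
      nlminb(st, negll, lower = c(rep(-Inf, p), 0),
             control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective - 1e-8) best <- opt
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) stop("GLMM optimisation failed entirely", call. = FALSE)
  par <- best$par
  beta <- setNames(par[1:p], colnames(X))
  sigma_u <- par[p + 1]
  converged <- best$convergence == 0
  separation <- any(abs(beta) > 15)

  # observed information; at a sigma_u = 0 boundary the curvature in sigma
  # is one-sided, so the variance block is restricted to beta there
  vcov_full <- tryCatch({
    if (sigma_u < 1e-6) {
      H <- optimHess(beta, function(b) negll(c(b, sigma_u)))
      solve(H)
    } else {
      H <- optimHess(par, negll)
      solve(H)[1:p, 1:p, drop = FALSE]
    }
  }, error = function(e) matrix(NA_real_, p, p))
  se_beta <- sqrt(pmax(diag(vcov_full), 0))

  eta <- drop(X %*% beta)
  modes <- vapply(idx, function(ii) {
    if (sigma_u < 1e-8) 0 else glmm_group_mode(eta[ii], y[ii], sigma_u^2)$mode
  }, numeric(1))

  structure(
    list(beta = beta, se_beta = setNames(se_beta, colnames(X)),
         vcov_beta = vcov_full, sigma_u2 = sigma_u^2,
         loglik = -best$objective, n_obs = length(y),
         n_groups = length(idx), n_fixed = p,
         converged = converged, separation = separation,
         method = "ML", family = "binomial",
         modes = modes, X = X, y = y, group = g,
         formula = formula, group_name = group, n_quad = n_quad),
    class = c("peckkin_glmm", "peckkin_mixfit")
  )
}

#' @export
print.peckkin_mixfit <- function(x, ...) {
  fam <- if (inherits(x, "peckkin_glmm")) "binomial (logit)" else "gaussian"
  cat(sprintf("Random-intercept mixed model [%s, %s]\n", fam, x$method))
  cat(sprintf("  n = %d observations, %d groups; logLik = %.4f%s\n",
              x$n_obs, x$n_groups, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  est <- cbind(Estimate = x$beta, `Std.Error` = x$se_beta)
  print(round(est, 4))
  cat(sprintf("  sigma_u^2 = %.4f", x$sigma_u2))
  if (!is.null(x$sigma_e2)) cat(sprintf(", sigma_e^2 = %.4f", x$sigma_e2))
  cat("\n")
  invisible(x)
}
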