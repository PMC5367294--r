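# Shared fixtures and independent oracles, built in code at test time.

# straight-line marker track moving step_cm per frame along +x
straight_track <- function(n, step_cm = 0.1, fps = 300, y = 0,
                           marker = "head") {
  marker_track(marker, 0:(n - 1), x = step_cm * (0:(n - 1)),
               y = rep(y, n), frame_rate = fps)
}

# squared magnitude response of a forward-backward (zero-phase) 4th-order
# Butterworth low-pass: |H(f)|^2 per pass, so amplitude gain = 1/(1+r^8)
# with r = f / f_c -- the analytic oracle for the filter tests
butter_ff_gain <- function(f, fc, order = 4) {
  1 / (1 + (f / fc)^(2 * order))
}

# amplitude of a sinusoid at frequency f in a series (regression on the
# quadrature pair, interior portion only to avoid edge effects)
sin_amplitude <- function(x, f, fs) {
  n <- length(x)
  idx <- seq(round(n / 4), round(3 * n / 4))
  t <- (idx - 1) / fs
  co <- coef(lm(x[idx] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}

# brute-force trapezoidal integration of one group's marginal likelihood
# (independent oracle for the adaptive quadrature)
trapezoid_group_loglik <- function(eta0, y, sigma_u, half_width = 10,
                                   n_grid = 20001) {
  m <- peckkin:::glmm_group_mode(eta0, y, sigma_u^2)
  tau <- 1 / sqrt(-m$curv)
  b <- seq(m$mode - half_width * tau, m$mode + half_width * tau,
           length.out = n_grid)
  h <- vapply(b, function(bb) {
    sum(dbinom(y, 1, plogis(eta0 + bb), log = TRUE)) +
      dnorm(bb, 0, sigma_u, log = TRUE)
  }, numeric(1))
  hm <- max(h)
  w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
  hm + log(sum(w * exp(h - hm)) * (b[2] - b[1]))
}

# binary-response data from a random-intercept logistic model
make_glmm_data <- function(n_groups, n_per, beta0, beta_x = 0, sigma_u,
                           seed) {
  withr_seed <- function(expr) peckkin:::with_seed(seed, expr)
  withr_seed({
    g <- rep(sprintf("g%03d", seq_len(n_groups)), each = n_per)
    u <- rnorm(n_groups, 0, sigma_u)
    x <- rnorm(n_groups * n_per)
    eta <- beta0 + beta_x * x + u[as.integer(factor(g))]
    data.frame(y = rbinom(length(eta), 1, plogis(eta)), x = x,
               individual = g, stringsAsFactors = FALSE)
  })
}

# gaussian data whose group means are exactly centred, so the
# between-group variance estimate is pinned to the boundary and the mixed
# fit must coincide with OLS
make_centred_lmm_data <- function(n_groups = 10, n_per = 30, beta = c(2, 1.5),
                                  sigma_e = 1, seed = 1) {
  peckkin:::with_seed(seed, {
    g <- rep(sprintf("g%02d", seq_len(n_groups)), each = n_per)
    x <- rnorm(n_groups * n_per)
    e <- rnorm(length(x), 0, sigma_e)
    e <- e - ave(e, g)   # exact zero mean residual per group
    data.frame(y = beta[1] + beta[2] * x + e, x = x, individual = g,
               stringsAsFactors = FALSE)
  })
}

# one noise-free simulated peck (shared across kinematics tests)
noisefree_peck <- function(species = "pigeon", seed = 7, fx = phase_effects(),
                           ...) {
  sp <- species_params(species, marker_noise_sd = 0, ...)
  simulate_peck(sp, fx, seed = seed)
}
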