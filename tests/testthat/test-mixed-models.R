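# The GLMM and LMM fitters are checked against independent routes:
# ordinary glm/lm fits where the random-intercept variance is pinned to
# zero, brute-force trapezoidal integration of the marginal likelihood,
# and lme4 (when available) on general data.

test_that("GLMM with a single group collapses to ordinary logistic regression", {
  d <- make_glmm_data(1, 400, beta0 = -0.8, beta_x = 0.7, sigma_u = 0, seed = 4)
  fit <- fit_glmm_binomial(y ~ x, d, "individual")
  ref <- glm(y ~ x, binomial(), d)
  expect_lt(fit$sigma_u2, 1e-10)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("adaptive quadrature matches brute-force integration per group", {
  d <- make_glmm_data(5, 40, beta0 = -0.5, beta_x = 0.4, sigma_u = 0.9,
                      seed = 6)
  beta <- c(-0.5, 0.4)
  sigma_u <- 0.9
  X <- model.matrix(~x, d)
  eta <- drop(X %*% beta)
  gh <- peckkin:::gauss_hermite(15)
  for (g in unique(d$individual)) {
    ii <- which(d$individual == g)
    agq <- peckkin:::glmm_group_loglik(eta[ii], d$y[ii], sigma_u, gh)
    brute <- trapezoid_group_loglik(eta[ii], d$y[ii], sigma_u)
    expect_equal(agq, brute, tolerance = 1e-6)
  }
})

test_that("balanced half-and-half outcomes give a zero intercept", {
  d <- data.frame(y = rep(c(0, 1), times = 60),
                  individual = rep(sprintf("g%d", 1:4), each = 30))
  fit <- fit_glmm_binomial(y ~ 1, d, "individual")
  expect_equal(unname(fit$beta[1]), 0, tolerance = 1e-4)
})

test_that("GLMM recovers known simulation parameters at moderate scale", {
  d <- make_glmm_data(30, 200, beta0 = -1.0, sigma_u = 0.8, seed = 12)
  fit <- fit_glmm_binomial(y ~ 1, d, "individual")
  expect_true(fit$converged)
  expect_gt(fit$beta[1], -1.3)
  expect_lt(fit$beta[1], -0.7)
  expect_gt(sqrt(fit$sigma_u2), 0.5)
  expect_lt(sqrt(fit$sigma_u2), 1.1)
})

test_that("GLMM agrees with lme4 on general data", {
  skip_if_not_installed("lme4")
  d <- make_glmm_data(8, 150, beta0 = -1, beta_x = 0.6, sigma_u = 0.8,
                      seed = 2)
  fit <- fit_glmm_binomial(y ~ x, d, "individual")
  ref <- lme4::glmer(y ~ x + (1 | individual), d, family = binomial,
                     nAGQ = 15)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$se_beta),
               unname(sqrt(diag(as.matrix(vcov(ref))))), tolerance = 1e-3)
})

test_that("estimates are stable in the number of quadrature nodes", {
  d <- make_glmm_data(6, 120, beta0 = -0.6, beta_x = 0.5, sigma_u = 0.7,
                      seed = 9)
  f7 <- fit_glmm_binomial(y ~ x, d, "individual", n_quad = 7)
  f25 <- fit_glmm_binomial(y ~ x, d, "individual", n_quad = 25)
  expect_lt(max(abs(f7$beta - f25$beta)), 1e-4)
})

test_that("LMM with zero between-group variance reduces to OLS", {
  d <- make_centred_lmm_data(seed = 5)
  fit <- fit_lmm(y ~ x, d, "individual")
  ref <- lm(y ~ x, d)
  expect_lt(fit$sigma_u2, 1e-8)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
})

test_that("balanced intercept-only LMM returns the grand mean", {
  d <- peckkin:::with_seed(11, data.frame(
    y = rnorm(120, 5), individual = rep(sprintf("g%d", 1:6), each = 20)
  ))
  fit <- fit_lmm(y ~ 1, d, "individual")
  expect_equal(unname(fit$beta[1]), mean(d$y), tolerance = 1e-8)
})

test_that("LMM recovers a known covariate slope within 10%", {
  d <- peckkin:::with_seed(31, {
    g <- rep(sprintf("g%02d", 1:9), each = 100)
    u <- rnorm(9, 0, 0.5)
    dist <- runif(900, 2, 6)
    data.frame(y = 1 + 3.0 * dist + u[as.integer(factor(g))] + rnorm(900, 0, 1.5),
               distance = dist, individual = g)
  })
  fit <- fit_lmm(y ~ distance, d, "individual")
  expect_equal(unname(fit$beta["distance"]), 3.0, tolerance = 0.10)
})

test_that("LMM agrees with lme4 under ML and REML", {
  skip_if_not_installed("lme4")
  d <- peckkin:::with_seed(3, {
    g <- rep(sprintf("g%d", 1:7), each = 40)
    u <- rnorm(7, 0, 1.2)
    x <- rnorm(280)
    data.frame(y = 2 + x + u[as.integer(factor(g))] + rnorm(280),
               x = x, individual = g)
  })
  for (reml in c(FALSE, TRUE)) {
    fit <- fit_lmm(y ~ x, d, "individual", method = if (reml) "REML" else "ML")
    ref <- lme4::lmer(y ~ x + (1 | individual), d, REML = reml)
    expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-5)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
    expect_equal(fit$sigma_u2, unname(unlist(lme4::VarCorr(ref))),
                 tolerance = 1e-4)
  }
})

test_that("the likelihood-ratio test counts parameters and clips at zero", {
  d <- make_centred_lmm_data(seed = 7)
  fit <- fit_lmm(y ~ x, d, "individual")
  self <- lrt(fit, fit)
  expect_identical(self$statistic, 0)
  expect_identical(self$df, 0L)

  d$phase <- factor(rep(phase_levels(), length.out = nrow(d)),
                    levels = phase_levels())
  full <- fit_lmm(y ~ x + phase, d, "individual")
  res <- lrt(full, fit)
  expect_identical(res$df, 6L)
  expect_gte(res$statistic, 0)

  reml <- fit_lmm(y ~ x, d, "individual", method = "REML")
  expect_error(lrt(full, reml), "ML")
})

test_that("the LRT statistic is invariant to factor coding", {
  d <- make_centred_lmm_data(n_groups = 6, seed = 13)
  d$f <- factor(rep(c("a", "b", "c"), length.out = nrow(d)))
  run <- function(contr) {
    old <- options(contrasts = c(contr, "contr.poly"))
    on.exit(options(old))
    lrt(fit_lmm(y ~ x + f, d, "individual"),
        fit_lmm(y ~ x, d, "individual"))$statistic
  }
  expect_equal(run("contr.treatment"), run("contr.sum"), tolerance = 1e-8)
})

test_that("null-model likelihood-ratio tests hold their 5% level", {
  rej <- vapply(1:500, function(r) {
    d <- peckkin:::with_seed(5000 + r, {
      g <- rep(sprintf("g%d", 1:4), each = 30)
      u <- rnorm(4, 0, 0.5)
      x <- rnorm(120)
      data.frame(y = u[as.integer(factor(g))] + rnorm(120), x = x,
                 individual = g)
    })
    full <- fit_lmm(y ~ x, d, "individual")
    null <- fit_lmm(y ~ 1, d, "individual")
    lrt(full, null)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.08)
})

test_that("Wald CI width shrinks like 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    d <- make_glmm_data(1, n, beta0 = -0.5, sigma_u = 0, seed = 40 + n)
    fit <- fit_glmm_binomial(y ~ 1, d, "individual")
    2 * 1.96 * fit$se_beta[1]
  }, numeric(1))
  # successive quadruplings of n should halve the width
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.15)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.15)
})

test_that("dispersion is near 1 under correct specification and flags overdispersion", {
  # aggregated residuals vanish when fitted cell frequencies are observed
  d0 <- data.frame(
    y = rep(c(1, 0, 1, 0), times = c(30, 30, 45, 15)),
    x = rep(c("a", "a", "b", "b"), times = c(30, 30, 45, 15)),
    individual = "g1"
  )
  fit0 <- fit_glmm_binomial(y ~ x, d0, "individual")
  expect_equal(dispersion(fit0, aggregate = TRUE), 0, tolerance = 1e-6)

  # correctly specified simulations: ratio concentrates near 1
  ratios <- vapply(1:20, function(r) {
    d <- make_glmm_data(5, 80, beta0 = 0.3, sigma_u = 0.5, seed = 600 + r)
    dispersion(fit_glmm_binomial(y ~ 1, d, "individual"))
  }, numeric(1))
  expect_gte(mean(ratios), 0.8)
  expect_lte(mean(ratios), 1.2)

  # unmodelled cell-level heterogeneity inflates the binomial-cell
  # Pearson statistic far beyond its degrees of freedom
  dd <- peckkin:::with_seed(77, {
    g <- rep(sprintf("g%d", 1:4), each = 250)
    xlev <- rep(rep(sprintf("x%02d", 1:10), each = 25), times = 4)
    cell_eff <- rnorm(40, 0, 1.2)          # per (group, x) cell, omitted
    cell_id <- as.integer(factor(paste(g, xlev)))
    data.frame(y = rbinom(1000, 1, plogis(0.5 + cell_eff[cell_id])),
               x = xlev, individual = g)
  })
  fit2 <- fit_glmm_binomial(y ~ x, dd, "individual")
  expect_gt(dispersion(fit2, aggregate = TRUE), 1.5)
})

test_that("phase CIs flag only real departures from control", {
  base <- make_centred_lmm_data(n_groups = 6, n_per = 70, seed = 21)
  base$phase <- factor(rep(phase_levels(), length.out = nrow(base)),
                       levels = phase_levels())
  fit <- fit_lmm(y ~ phase, base, "individual")
  pc <- phase_cis(fit)
  expect_false(pc$differs_from_control[pc$phase == "control"])

  # a 10-SE shift cannot be missed
  se <- fit$se_beta["phaseremoval"]
  shifted <- base
  shifted$y[shifted$phase == "removal"] <-
    shifted$y[shifted$phase == "removal"] + 10 * se
  pc2 <- phase_cis(fit_lmm(y ~ phase, shifted, "individual"))
  expect_true(pc2$differs_from_control[pc2$phase == "removal"])

  # null false-flag rate of the non-overlap rule stays below 5%
  flags <- unlist(lapply(1:200, function(r) {
    d <- make_centred_lmm_data(n_groups = 4, n_per = 35, seed = 900 + r)
    d$phase <- factor(rep(phase_levels(), length.out = nrow(d)),
                      levels = phase_levels())
    p <- phase_cis(fit_lmm(y ~ phase, d, "individual"))
    p$differs_from_control[p$phase != "control"]
  }))
  expect_lte(mean(flags), 0.05)

  expect_error(phase_cis(fit_lmm(y ~ x, base, "individual")), "phase")
})

test_that("Nakagawa R-squared reduces to classical R-squared without random variance", {
  d <- make_centred_lmm_data(seed = 19)
  fit <- fit_lmm(y ~ x, d, "individual")
  r2 <- r2_nakagawa(fit)
  ref <- summary(lm(y ~ x, d))$r.squared
  expect_equal(unname(r2["marginal"]), ref, tolerance = 1e-6)
  expect_gte(r2["conditional"], r2["marginal"])

  fit0 <- fit_lmm(y ~ 1, make_centred_lmm_data(beta = c(2, 0), seed = 23),
                  "individual")
  expect_equal(unname(r2_nakagawa(fit0)["marginal"]), 0, tolerance = 1e-8)
})

test_that("conditional R-squared exceeds marginal when groups differ", {
  d <- peckkin:::with_seed(8, {
    g <- rep(sprintf("g%d", 1:6), each = 50)
    u <- rnorm(6, 0, 2)
    x <- rnorm(300)
    data.frame(y = x + u[as.integer(factor(g))] + rnorm(300), x = x,
               individual = g)
  })
  r2 <- r2_nakagawa(fit_lmm(y ~ x, d, "individual"))
  expect_gt(r2["conditional"], r2["marginal"] + 0.1)
})

test_that("control-phase independence checks behave under null and injected effects", {
  make_control <- function(seed, order_effect = 0) {
    peckkin:::with_seed(seed, {
      n <- 300
      ind <- rep(c("b1", "b2", "b3"), each = n / 3)
      pos <- sample(1:10, n, replace = TRUE)
      ord <- sample(1:10, n, replace = TRUE)
      data.frame(
        individual = ind, target_position = pos, peck_order = ord,
        outcome = ifelse(rbinom(n, 1, 0.9) == 1, "success", "failure"),
        onset_s = 0.7 + order_effect * scale(ord)[, 1] + rnorm(n, 0, 0.02),
        distance_cm = runif(n, 3, 6)
      )
    })
  }
  null <- control_phase_checks(make_control(1))
  expect_named(null, c("success", "onset", "distance"))
  expect_identical(nrow(null$onset), 3L)

  # a 10-SD order effect on onset is unmissable
  inj <- control_phase_checks(make_control(2, order_effect = 0.2))
  expect_lt(inj$onset$p[inj$onset$term == "peck_order"], 1e-3)

  # constant outcomes: warning, success model not fitted
  dg <- make_control(3)
  dg$outcome <- "success"
  expect_warning(res <- control_phase_checks(dg), "degenerate")
  expect_null(res$success)

  # null model p-values are typically unremarkable (gaussian models)
  ps <- unlist(lapply(1:25, function(r) {
    control_phase_checks(make_control(100 + r))$onset$p
  }))
  expect_gte(mean(ps > 0.05), 0.85)
})

test_that("Wald CI coverage is nominal with many groups and degrades at 3 groups", {
  run_cov <- function(n_groups, n_per, seed_base, n_sim) {
    mean(vapply(seq_len(n_sim), function(r) {
      d <- peckkin:::with_seed(seed_base + r, {
        g <- rep(sprintf("g%02d", seq_len(n_groups)), each = n_per)
        u <- rnorm(n_groups, 0, 0.5)
        data.frame(y = rbinom(n_groups * n_per, 1,
                              plogis(1.0 + u[as.integer(factor(g))])),
                   individual = g)
      })
      fit <- fit_glmm_binomial(y ~ 1, d, "individual", n_quad = 7)
      abs(fit$beta[1] - 1.0) <= 1.96 * fit$se_beta[1]
    }, logical(1)))
  }
  # many groups: nominal
  cov30 <- run_cov(30, 10, 7000, 300)
  expect_gte(cov30, 0.90)
  expect_lte(cov30, 0.99)
  # three birds (the study design): Wald intervals undercover; this is a
  # documented small-sample caveat, not a defect to hide
  cov3 <- run_cov(3, 100, 3000, 300)
  expect_gte(cov3, 0.75)
  expect_lte(cov3, 0.95)
})
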