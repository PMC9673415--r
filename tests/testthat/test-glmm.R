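test_that("quadrature log-likelihood matches brute-force integration", {
  tiny <- fixture_tiny()
  cf <- c(mu0 = 0.1, beta2 = -0.3, theta = -0.5, delta2 = 0.2)
  for (s2 in c(0.05, 0.3, 0.8)) {
    ll_bf <- brute_force_loglik(tiny, cf, s2, ref_period = 1)
    ll_q <- glmm_loglik(tiny, cf, s2, nodes = 25, ref_period = 1)
    expect_equal(ll_q, ll_bf, tolerance = 1e-6)
  }
  # Laplace (1 node) is close but not exact; quadrature refines it
  ll1 <- glmm_loglik(tiny, cf, 0.3, nodes = 1, ref_period = 1)
  ll25 <- glmm_loglik(tiny, cf, 0.3, nodes = 25, ref_period = 1)
  expect_lt(abs(ll25 - brute_force_loglik(tiny, cf, 0.3, 1)), abs(ll1 - ll25) + 1e-6)
})

test_that("estimates are stable in the number of quadrature nodes", {
  ag <- fixture_agg(seed = 13, M = 24)
  f9 <- usd_glmm(ag, nodes = 9)
  f15 <- usd_glmm(ag, nodes = 15)
  f25 <- usd_glmm(ag, nodes = 25)
  expect_lt(max(abs(coef(f9) - coef(f25))), 1e-4)
  expect_lt(max(abs(coef(f15) - coef(f25))), 1e-4)
  expect_lt(abs(f9$logLik - f25$logLik), 1e-4)
})

test_that("individual and aggregated fits coincide (binomial sufficiency)", {
  d <- usd_design("DSDu", M = 12, T = 5, n = 20, s = 3)
  p <- sim_params(n = 20, sigma_c2 = 0.3, delta = "linear")
  tr <- simulate_usd_trial(d, p, seed = 17)
  ag <- aggregate_trial(tr)
  fa <- usd_glmm(ag, nodes = 15)
  fi <- usd_glmm(tr, nodes = 15)
  expect_equal(coef(fa), coef(fi), tolerance = 1e-10)
  expect_equal(fa$vcov, fi$vcov, tolerance = 1e-10)
  # log-likelihoods differ exactly by the binomial coefficient constant
  expect_equal(fa$logLik - fi$logLik, fa$loglik_constant, tolerance = 1e-8)
})

test_that("zero cluster variance collapses to a plain probit regression", {
  d <- usd_design("PGD", M = 20, T = 5, n = 40)
  p <- sim_params(n = 40, sigma_c2 = 0, delta = "linear")
  ag <- aggregate_trial(simulate_usd_trial(d, p, seed = 19))
  f <- usd_glmm(ag, nodes = 9)
  expect_true(f$boundary)
  X <- usdpower:::ref_design(5, 3)$build(usdpower:::trial_matrices(ag)$x)
  gl <- suppressWarnings(glm.fit(X, cbind(ag$events, ag$trials - ag$events),
                                 family = binomial("probit")))
  expect_lt(max(abs(f$coefficients - gl$coefficients)), 1e-4)
})

test_that("fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  ag <- fixture_agg(seed = 23, variant = "USDu", sigma_c2 = 0.5, M = 24)
  f <- usd_glmm(ag, nodes = 9)
  df <- data.frame(events = ag$events, trials = ag$trials,
                   cl = factor(ag$cluster),
                   per = factor(ag$period, levels = c(3, 1, 2, 4, 5)),
                   trt = ag$treatment)
  fm <- lme4::glmer(cbind(events, trials - events) ~ per * trt + (1 | cl),
                    data = df, family = binomial("probit"), nAGQ = 9)
  fe <- lme4::fixef(fm)
  # same model, same reference coding, different optimizer and AGQ code
  expect_lt(abs(f$coefficients["mu0"] - fe["(Intercept)"]), 1e-3)
  expect_lt(abs(f$coefficients["theta"] - fe["trt"]), 1e-3)
  expect_lt(max(abs(f$coefficients[c("delta1", "delta2", "delta4", "delta5")] -
                    fe[c("per1:trt", "per2:trt", "per4:trt", "per5:trt")])), 1e-3)
  expect_lt(abs(unname(f$sigma_c2) - unname(unlist(lme4::VarCorr(fm)))), 1e-3)
  # model-based SEs from the two information matrices agree
  se_mine <- sqrt(diag(f$vcov))[names(f$coefficients)]
  se_lme4 <- sqrt(diag(as.matrix(stats::vcov(fm))))
  expect_lt(max(abs(se_mine - se_lme4) / se_lme4), 0.03)
})

test_that("Wald intervals use normal quantiles with infinite df", {
  ci <- usdpower:::wald_ci(c(a = 0), matrix(1, dimnames = list("a", "a")),
                           NULL, 0.95)
  expect_equal(unname(ci[, "lower"]), -1.959964, tolerance = 1e-6)
  expect_equal(unname(ci[, "upper"]), 1.959964, tolerance = 1e-6)
  ci2 <- usdpower:::wald_ci(c(b = 1), matrix(4, dimnames = list("b", "b")),
                            NULL, 0.95)
  expect_equal(unname(ci2[, "lower"]), -2.919928, tolerance = 1e-6)
  expect_equal(unname(ci2[, "upper"]), 4.919928, tolerance = 1e-6)
  # zero SE degenerates to the estimate
  ci0 <- usdpower:::wald_ci(c(c = 2), matrix(0, dimnames = list("c", "c")),
                            NULL, 0.95)
  expect_equal(unname(ci0[, c("lower", "upper")]), c(2, 2))
})

test_that("joint Wald chi-squared behaves algebraically", {
  V <- diag(c(1, 4, 9, 16))
  dimnames(V) <- list(letters[1:4], letters[1:4])
  est <- c(a = 0, b = 0, c = 0, d = 0)
  t0 <- usdpower:::joint_wald(est, V, 1:4, "null block")
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 1)
  # single contrast equals the squared Wald z
  est2 <- c(a = 1.4, b = 0, c = 0, d = 0)
  t1 <- usdpower:::joint_wald(est2, V, 1L, "one df")
  expect_equal(unname(t1$statistic), (1.4 / 1)^2)
  expect_equal(unname(t1$parameter), 1)
  expect_equal(t1$p.value, 2 * pnorm(-1.4), tolerance = 1e-12)
})

test_that("non-identifiable designs are refused with named aliased terms", {
  # pure stepped wedge: no control at the last period
  d <- usd_design("custom", T = 4, n = 10, allocation = c(0, 3, 3, 3, 0))
  p <- sim_params(T = 4, n = 10, beta = 0.1 * (1:4 - 2), delta = rep(0, 4),
                  sigma_c2 = 0.2)
  tr <- simulate_usd_trial(d, p, seed = 29)
  expect_error(usd_glmm(aggregate_trial(tr), ref_period = 2), "aliased")
})

test_that("interaction test demands a converged interaction fit", {
  ag <- fixture_agg(seed = 31, M = 24)
  f <- usd_glmm(ag, nodes = 9)
  expect_s3_class(interaction_test(f), "htest")
  f0 <- usd_glmm(ag, nodes = 9, interaction = FALSE)
  expect_error(interaction_test(f0), "no interaction block")
  fbad <- f
  fbad$converged <- FALSE
  expect_error(interaction_test(fbad), "refused")
  expect_error(confint(fbad), "converge")
})

test_that("sandwich and model-based covariances agree at large M under correct specification", {
  d <- usd_design("PGD", M = 192, sigma_c2 = 0.2)
  p <- sim_params(sigma_c2 = 0.2, delta = "linear")
  seeds <- usdpower:::replicate_seeds(2201, 20)
  ratios <- sapply(seeds, function(s) {
    ag <- aggregate_trial(simulate_usd_trial(d, p, seed = s))
    f <- usd_glmm(ag, nodes = 9, sandwich = TRUE)
    di <- f$delta_idx
    mean(diag(f$vcov_sandwich)[di] / diag(f$vcov)[di])
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})
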