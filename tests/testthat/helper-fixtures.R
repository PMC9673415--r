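# small reusable fixtures; all data generated in code

# a quick aggregated PGD dataset at the study scale
fixture_agg <- function(seed = 7, variant = "PGD", sigma_c2 = 0.2, M = 48,
                        delta = "linear", structure = "exchangeable", r = 0.8) {
  d <- usd_design(variant, M = M, sigma_c2 = sigma_c2)
  p <- sim_params(sigma_c2 = sigma_c2, delta = delta, structure = structure, r = r)
  aggregate_trial(simulate_usd_trial(d, p, seed = seed))
}

# tiny hand-sized aggregated dataset (2 clusters x 2 periods) with fixed counts
fixture_tiny <- function() {
  structure(data.frame(cluster = c(1L, 2L, 1L, 2L),
                       period = c(1L, 1L, 2L, 2L),
                       treatment = c(0L, 1L, 0L, 1L),
                       events = c(3L, 7L, 5L, 2L),
                       trials = 10L),
            class = c("usd_trial_agg", "data.frame"), M = 2L, T = 2L, n = 10L)
}

# brute-force marginal log-likelihood by direct 1-D numerical integration
brute_force_loglik <- function(agg, coefficients, sigma_c2, ref_period = 1) {
  M <- attr(agg, "M"); T <- attr(agg, "T")
  per <- setdiff(seq_len(T), ref_period)
  ll <- 0
  for (i in seq_len(M)) {
    di <- agg[agg$cluster == i, ]
    eta <- coefficients[1] +
      ifelse(di$period == ref_period, 0,
             coefficients[match(paste0("beta", di$period), names(coefficients))]) +
      di$treatment * (coefficients["theta"] +
        ifelse(di$period == ref_period, 0,
               coefficients[match(paste0("delta", di$period), names(coefficients))]))
    eta[is.na(eta)] <- coefficients[1]  # guard; only hit if names missing
    f <- function(b) {
      sapply(b, function(bb) {
        p <- pnorm(eta + bb)
        exp(sum(dbinom(di$events, di$trials, p, log = TRUE))) *
          dnorm(bb, 0, sqrt(sigma_c2))
      })
    }
    ll <- ll + log(integrate(f, -10 * sqrt(sigma_c2), 10 * sqrt(sigma_c2),
                             rel.tol = 1e-12, abs.tol = 0)$value)
  }
  ll
}
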