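#' Treatment-by-period interaction profiles
#'
#' Returns the vector of period-specific deviations `delta_j` of the
#' treatment effect from its average, `theta_j = theta0 + delta_j`.  For
#' `T = 5` periods with reference period 3 the built-in profiles are a
#' linear trend `delta_j = -0.1 (j - 3)`, a symmetric profile
#' `delta_j = -0.1 |j - 3|`, and the null profile `delta_j = 0` used for
#' type-I-error studies.
#'
#' @param kind `"linear"`, `"symmetric"` or `"null"`.
#' @param T number of periods; the non-null built-ins are defined for
#'   `T = 5`.
#' @return Numeric vector of length `T`.
#' @examples
#' interaction_profile("linear")
#' @export
interaction_profile <- function(kind = c("linear", "symmetric", "null"), T = 5) {
  kind <- match.arg(kind)
  T <- check_periods(T)
  if (kind == "null") return(numeric(T))
  if (T != 5)
    stop("built-in non-null profiles are defined for T = 5; supply 'delta' directly otherwise",
         call. = FALSE)
  j <- 1:5
  switch(kind,
         linear = -0.1 * (j - 3),
         symmetric = -0.1 * abs(j - 3))
}

#' Data-generating parameters for a USD trial with binary outcomes
#'
#' Collects the subject-specific (conditional) probit-scale parameters of
#' the data-generating model: given a latent cluster effect `b_ij`, the
#' outcome of subject `k` in cluster `i` at period `j` is Bernoulli with
#' success probability `pnorm(mu0 + b_ij + beta_j + (theta0 + delta_j) x_ij)`.
#' Under the exchangeable structure `b_ij = b_0i ~ N(0, sigma_c2)` is
#' constant over periods; under `"ar1"` the vector `(b_i1, ..., b_iT)` is
#' multivariate normal with variance `sigma_c2` and correlation
#' `r^|j - k|` between periods.
#'
#' Defaults follow the reference study conditions: `T = 5`, `n = 50`,
#' period effects `beta_j = 0.2 (j - 3)`, average treatment effect
#' `theta0 = -0.4`, reference period 3 (`beta_3 = delta_3 = 0`).  The
#' intercept `mu0` defaults to 0, i.e. a 50% event probability at the
#' reference period under control; rejection rates depend mildly on it,
#' so it is exposed as an explicit knob.
#'
#' @param T number of periods.
#' @param n subjects per cluster per period.
#' @param mu0 probit-scale intercept.
#' @param beta length-`T` period effects.
#' @param theta0 average treatment effect.
#' @param delta length-`T` interaction deviations, or a profile name
#'   accepted by [interaction_profile()].
#' @param sigma_c2 latent cluster variance.
#' @param structure `"exchangeable"` or `"ar1"`.
#' @param r AR1 correlation between adjacent periods (used only for
#'   `structure = "ar1"`), in `(-1, 1)`.
#' @return An object of class `"usd_sim_params"`.
#' @examples
#' sim_params(sigma_c2 = 0.2, delta = "linear")
#' @export
sim_params <- function(T = 5, n = 50, mu0 = 0, beta = 0.2 * (seq_len(T) - 3),
                       theta0 = -0.4, delta = "null", sigma_c2 = 0.2,
                       structure = c("exchangeable", "ar1"), r = 0.8) {
  T <- check_periods(T)
  structure <- match.arg(structure)
  if (is.character(delta)) delta <- interaction_profile(delta, T)
  stopifnot(length(beta) == T, length(delta) == T)
  if (sigma_c2 < 0) stop("'sigma_c2' must be nonnegative", call. = FALSE)
  if (structure == "ar1" && abs(r) >= 1)
    stop("AR1 correlation 'r' must lie in (-1, 1)", call. = FALSE)
  if (n < 1 || n != round(n)) stop("'n' must be a positive integer", call. = FALSE)
  structure(list(T = T, n = as.integer(n), mu0 = mu0, beta = as.numeric(beta),
                 theta0 = theta0, delta = as.numeric(delta),
                 theta = theta0 + as.numeric(delta),
                 sigma_c2 = sigma_c2, structure = structure,
                 r = if (structure == "ar1") r else NA_real_),
            class = "usd_sim_params")
}

#' @export
print.usd_sim_params <- function(x, ...) {
  cat(sprintf("Probit DGP: T = %d, n = %d, mu0 = %g, theta0 = %g, sigma_c2 = %g, %s%s\n",
              x$T, x$n, x$mu0, x$theta0, x$sigma_c2, x$structure,
              if (x$structure == "ar1") sprintf(" (r = %g)", x$r) else ""))
  cat("beta: ", paste(signif(x$beta, 4), collapse = " "), "\n")
  cat("delta:", paste(signif(x$delta, 4), collapse = " "), "\n")
  invisible(x)
}

#' Marginal (population-averaged) counterparts of subject-specific parameters
#'
#' With a probit link and a normal latent cluster effect, integrating the
#' cluster effect out attenuates every location parameter by the factor
#' `1 / sqrt(1 + sigma_c2)`; the relationship is exact.  These marginal
#' values are the truths against which marginal-model (GEE) estimates are
#' judged.
#'
#' @param params an `"usd_sim_params"` object.
#' @return List with `mu_M`, `beta_M`, `theta0_M`, `delta_M`, `theta_M`
#'   and the attenuation `factor`.
#' @examples
#' marginal_params(sim_params(sigma_c2 = 0.2))$theta0_M  # -0.4 / sqrt(1.2)
#' @export
marginal_params <- function(params) {
  stopifnot(inherits(params, "usd_sim_params"))
  f <- 1 / sqrt(1 + params$sigma_c2)
  list(mu_M = params$mu0 * f, beta_M = params$beta * f,
       theta0_M = params$theta0 * f, delta_M = params$delta * f,
       theta_M = params$theta * f, factor = f)
}

#' Draw latent cluster effects
#'
#' Exchangeable structure: one `N(0, sigma_c2)` draw per cluster,
#' replicated over periods.  AR1 structure: per cluster a length-`T`
#' multivariate normal with variance `sigma_c2` and correlation
#' `r^|j - k|`, drawn via the Cholesky factor of the correlation matrix.
#'
#' @param M number of clusters.
#' @param T number of periods.
#' @param sigma_c2 latent variance.
#' @param structure `"exchangeable"` or `"ar1"`.
#' @param r AR1 correlation.
#' @param seed optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return Numeric `M x T` matrix of cluster-period effects.
#' @export
draw_random_effects <- function(M, T, sigma_c2,
                                structure = c("exchangeable", "ar1"),
                                r = 0.8, seed = NULL) {
  structure <- match.arg(structure)
  if (sigma_c2 < 0) stop("'sigma_c2' must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (sigma_c2 == 0) return(matrix(0, M, T))
  if (structure == "exchangeable") {
    b0 <- stats::rnorm(M, 0, sqrt(sigma_c2))
    return(matrix(b0, M, T))
  }
  if (abs(r) >= 1) stop("AR1 correlation 'r' must lie in (-1, 1)", call. = FALSE)
  R <- r^abs(outer(seq_len(T), seq_len(T), "-"))
  L <- chol(R)
  Z <- matrix(stats::rnorm(M * T), M, T)
  sqrt(sigma_c2) * (Z %*% L)
}

#' Simulate an individual-level USD trial
#'
#' Draws a complete cross-sectional trial from the probit mixed-model
#' data-generating process: for each cluster-period cell, `n` independent
#' Bernoulli outcomes with conditional success probability
#' `pnorm(mu0 + b_ij + beta_j + theta_j x_ij)`.
#'
#' @param design an `"usd_design"` object (supplies the treatment matrix).
#' @param params an `"usd_sim_params"` object; its `T` and `n` must match
#'   the design.
#' @param seed optional integer seed for reproducibility.
#' @param randomize draw each cluster's switch pattern independently with
#'   probabilities `allocation / M` (the random-allocation reading of a
#'   USD), redrawing in the rare event that a pure pattern ends up empty so
#'   the interaction stays identifiable.  With the default `FALSE` the
#'   design's integer allocation is used as-is.
#' @return A data frame of class `"usd_trial"` with columns `cluster`,
#'   `period`, `subject`, `treatment`, `outcome`, holding `M * T * n`
#'   rows, plus attributes `M`, `T`, `n`.
#' @examples
#' d <- usd_design("PGD", M = 4, T = 5, n = 10)
#' trial <- simulate_usd_trial(d, sim_params(n = 10, sigma_c2 = 0.2), seed = 1)
#' head(trial)
#' @export
simulate_usd_trial <- function(design, params, seed = NULL, randomize = FALSE) {
  stopifnot(inherits(design, "usd_design"), inherits(params, "usd_sim_params"))
  if (design$T != params$T)
    stop("design and parameters disagree on the number of periods", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  M <- design$M; T <- design$T; n <- params$n
  if (randomize) {
    probs <- design$allocation / M
    repeat {
      N <- as.vector(stats::rmultinom(1L, M, probs))
      if (N[1L] > 0L && N[T + 1L] > 0L) break
    }
    x <- usd_patterns(T)[rep(seq_len(T + 1L), N), , drop = FALSE]
  } else {
    x <- treatment_matrix(design)
  }
  b <- draw_random_effects(M, T, params$sigma_c2, params$structure, params$r)
  eta <- params$mu0 + b +
    matrix(params$beta, M, T, byrow = TRUE) +
    x * matrix(params$theta, M, T, byrow = TRUE)
  p <- stats::pnorm(eta)
  # subject index varies fastest, then cluster, then period
  prob <- rep(as.vector(p), each = n)            # (k, i, j)
  y <- stats::rbinom(M * T * n, 1L, prob)
  out <- data.frame(cluster = rep(rep(seq_len(M), each = n), T),
                    period = rep(seq_len(T), each = M * n),
                    subject = rep(seq_len(n), M * T),
                    treatment = rep(as.vector(x), each = n),
                    outcome = y)
  structure(out, class = c("usd_trial", "data.frame"), M = M, T = T, n = n)
}

#' Aggregate an individual-level trial to cluster-period counts
#'
#' Sums outcomes within each cluster-period cell.  Because the linear
#' predictor is constant within a cell, the cell count is a binomial
#' sufficient statistic and aggregated-level model fits coincide with
#' individual-level fits.
#'
#' @param trial a `"usd_trial"` data frame.
#' @return A data frame of class `"usd_trial_agg"` with columns `cluster`,
#'   `period`, `treatment`, `events`, `trials` (one row per cluster-period).
#' @export
aggregate_trial <- function(trial) {
  stopifnot(inherits(trial, "usd_trial"))
  M <- attr(trial, "M"); T <- attr(trial, "T"); n <- attr(trial, "n")
  key <- (trial$period - 1L) * M + trial$cluster
  ev <- as.vector(rowsum(trial$outcome, key))            # sorted by key
  trt <- as.vector(rowsum(trial$treatment, key)) / n     # constant within cell
  ord <- sort(unique(key))
  out <- data.frame(cluster = ((ord - 1L) %% M) + 1L,
                    period = ((ord - 1L) %/% M) + 1L,
                    treatment = as.integer(round(trt)),
                    events = ev,
                    trials = n)
  structure(out, class = c("usd_trial_agg", "data.frame"), M = M, T = T, n = n)
}

# normalize either representation to aggregated counts (used by both engines)
as_aggregated <- function(data) {
  if (inherits(data, "usd_trial_agg")) return(data)
  if (inherits(data, "usd_trial")) return(aggregate_trial(data))
  nm <- names(data)
  if (all(c("cluster", "period", "treatment", "events", "trials") %in% nm)) {
    M <- max(data$cluster); T <- max(data$period)
    return(structure(as.data.frame(data)[c("cluster", "period", "treatment",
                                           "events", "trials")],
                     class = c("usd_trial_agg", "data.frame"),
                     M = M, T = T, n = max(data$trials)))
  }
  if (all(c("cluster", "period", "treatment", "outcome") %in% nm)) {
    M <- max(data$cluster); T <- max(data$period)
    n <- max(table(data$cluster, data$period))
    tr <- structure(as.data.frame(data), class = c("usd_trial", "data.frame"),
                    M = M, T = T, n = n)
    if (!"subject" %in% nm) tr$subject <- stats::ave(tr$outcome, tr$cluster, tr$period, FUN = seq_along)
    return(aggregate_trial(tr))
  }
  stop("unrecognized trial data: expected individual columns (cluster, period, treatment, outcome) or aggregated columns (cluster, period, treatment, events, trials)",
       call. = FALSE)
}

is_individual <- function(data) {
  inherits(data, "usd_trial") ||
    (!inherits(data, "usd_trial_agg") && "outcome" %in% names(data))
}
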