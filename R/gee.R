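# Marginal probit model fitted by generalized estimating equations.
#
# Observations are grouped by cluster; within a cluster all rows (all
# cluster-period cells at the aggregated level, all n*T subjects at the
# individual level) form one exchangeable block with a single working
# correlation alpha.  Aggregated rows are binomial proportions with
# variance mu(1-mu)/trials; individual rows are Bernoulli.  The working
# covariance is V = phi A^{1/2} R(alpha) A^{1/2}; its inverse uses the
# closed form R^{-1} = c1 I + c2 J.

gee_prepare <- function(data, ref_period, interaction) {
  agg_like <- !is_individual(data)
  if (agg_like) {
    d <- as_aggregated(data)
    z <- d$events / d$trials
    w <- d$trials
  } else {
    d <- data
    z <- d$outcome
    w <- rep(1, nrow(d))
  }
  ord <- order(d$cluster, d$period)
  d <- d[ord, ]; z <- z[ord]; w <- w[ord]
  M <- max(d$cluster); T <- max(d$period)
  des <- ref_design(T, ref_period, interaction)
  # design rows in (cluster-major) data order
  per <- des$periods
  p <- length(des$names)
  X <- matrix(0, nrow(d), p)
  X[, 1L] <- 1
  for (q in seq_along(per)) X[d$period == per[q], 1L + q] <- 1
  X[, 2L + length(per)] <- d$treatment
  if (interaction)
    for (q in seq_along(per)) {
      sel <- d$period == per[q]
      X[sel, 2L + length(per) + q] <- d$treatment[sel]
    }
  colnames(X) <- des$names
  list(z = z, w = w, X = X, cl = d$cluster, M = M, T = T, p = p,
       names = des$names, delta_idx = des$delta_idx,
       level = if (agg_like) "aggregated" else "individual")
}

# per-cluster GEE building blocks at coefficients gamma, working alpha, phi
gee_blocks <- function(pr, gamma, alpha, phi) {
  eta <- drop(pr$X %*% gamma)
  mu <- .clamp(stats::pnorm(eta))
  dmu <- stats::dnorm(eta)
  a <- mu * (1 - mu) / pr$w                # variance function
  e <- (pr$z - mu) / sqrt(a)               # scaled residuals
  G <- (dmu / sqrt(a)) * pr$X              # A^{-1/2} D rows
  msz <- tabulate(pr$cl, pr$M)             # rows per cluster
  m1 <- max(msz)
  c1 <- 1 / (1 - alpha)
  # J-coefficient varies with cluster size; sizes are equal here, but keep general
  cs <- rowsum(G, pr$cl)                   # M x p column sums per cluster
  se <- as.vector(rowsum(e, pr$cl))
  c2 <- -alpha / ((1 - alpha) * (1 + (msz - 1) * alpha))
  B <- (crossprod(G) * c1 + crossprod(cs * c2, cs)) / phi
  Umat <- (c1 * rowsum(G * e, pr$cl) + (c2 * se) * cs) / phi
  list(mu = mu, e = e, B = B, Umat = Umat, U = colSums(Umat), msz = msz)
}

# moment estimators of the scale and the exchangeable working correlation
gee_moments <- function(pr, gamma) {
  eta <- drop(pr$X %*% gamma)
  mu <- .clamp(stats::pnorm(eta))
  r <- (pr$z - mu) / sqrt(mu * (1 - mu) / pr$w)
  N <- length(r)
  phi <- sum(r^2) / (N - pr$p)
  S <- as.vector(rowsum(r, pr$cl))
  Q <- as.vector(rowsum(r^2, pr$cl))
  msz <- tabulate(pr$cl, pr$M)
  denom_pairs <- sum(msz * (msz - 1)) / 2 - pr$p
  alpha <- if (denom_pairs > 0) sum(S^2 - Q) / 2 / (denom_pairs * phi) else 0
  lo <- -1 / (max(msz) - 1) + 1e-6
  list(phi = phi, alpha = min(max(alpha, lo), 1 - 1e-6))
}

#' Fit a marginal probit model by GEE
#'
#' Solves the generalized estimating equations for the population-averaged
#' probit mean structure
#' `E(Y) = pnorm(mu_M + beta_Mj + theta_Mj x_ij)` with an exchangeable (or
#' independence) working correlation over all observations of a cluster.
#' Coefficients are updated by Fisher scoring, alternating with moment
#' estimation of the dispersion `phi` (Pearson chi-squared over `N - p`)
#' and the working correlation `alpha` from Pearson residual products.
#' Aggregated cluster-period counts enter as binomial proportions with
#' denominator weights.  Inference uses the Liang-Zeger cluster-robust
#' sandwich covariance.
#'
#' @inheritParams usd_glmm
#' @param working `"exchangeable"` (default) or `"independence"`; with
#'   independence working correlation the estimates coincide with a pooled
#'   probit GLM.
#' @param scale `"moment"` (estimate `phi`; default) or `"fixed"`
#'   (`phi = 1`).
#' @param tol convergence tolerance on the coefficient update.
#' @param max_iter maximum Fisher-scoring iterations.
#' @return An object of class `"usd_gee"` with `coefficients`, `alpha`
#'   (working correlation), `phi` (dispersion), `vcov_sandwich`,
#'   `vcov_model`, `eq_norm` (max abs estimating-function component at the
#'   solution), `converged`, `n_clusters`, plus bookkeeping.
#' @export
usd_gee <- function(data, working = c("exchangeable", "independence"),
                    ref_period = 3, interaction = TRUE,
                    scale = c("moment", "fixed"), tol = 1e-10, max_iter = 100) {
  working <- match.arg(working)
  scale <- match.arg(scale)
  pr <- gee_prepare(data, ref_period, interaction)
  if (pr$M < 2) stop("GEE needs at least 2 clusters", call. = FALSE)
  if (qr(pr$X)$rank < pr$p)
    stop("marginal design is rank deficient", call. = FALSE)
  g0 <- suppressWarnings(stats::glm.fit(pr$X, cbind(round(pr$z * pr$w), round((1 - pr$z) * pr$w)),
                                        family = stats::binomial("probit")))
  gamma <- g0$coefficients
  if (any(!is.finite(gamma)))
    stop("starting probit GLM failed (separation?)", call. = FALSE)
  alpha <- 0; phi <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (scale == "moment" || working == "exchangeable") {
      mom <- gee_moments(pr, gamma)
      if (scale == "moment") phi <- mom$phi
      if (working == "exchangeable") alpha <- mom$alpha
    }
    bl <- gee_blocks(pr, gamma, alpha, phi)
    step <- solve(bl$B, bl$U)
    gamma <- gamma + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  bl <- gee_blocks(pr, gamma, alpha, phi)
  Binv <- chol_solve(bl$B)
  meat <- crossprod(bl$Umat)
  Vs <- Binv %*% meat %*% Binv
  names(gamma) <- pr$names
  dimnames(Vs) <- dimnames(Binv) <- list(pr$names, pr$names)
  structure(list(coefficients = gamma, alpha = alpha, phi = phi,
                 vcov_sandwich = Vs, vcov_model = Binv,
                 eq_norm = max(abs(bl$U)), converged = converged,
                 n_iter = it, n_clusters = pr$M, T = pr$T,
                 working = working, ref_period = ref_period,
                 interaction = interaction, delta_idx = pr$delta_idx,
                 level = pr$level, data = data),
            class = "usd_gee")
}

#' @export
coef.usd_gee <- function(object, ...) object$coefficients

#' Covariance of a fitted marginal model
#'
#' @param object an `"usd_gee"` fit.
#' @param type `"sandwich"` (Liang-Zeger robust, default) or `"model"`
#'   (working-model based).
#' @param ... unused.
#' @export
vcov.usd_gee <- function(object, type = c("sandwich", "model"), ...) {
  type <- match.arg(type)
  if (type == "sandwich") object$vcov_sandwich else object$vcov_model
}

#' Wald confidence intervals for a GEE fit (sandwich standard errors)
#'
#' @inheritParams confint.usd_glmm
#' @param type covariance choice, as in [vcov.usd_gee()].
#' @export
confint.usd_gee <- function(object, parm = NULL, level = 0.95,
                            type = c("sandwich", "model"), ...) {
  if (!object$converged)
    stop("fit did not converge; intervals would be unreliable", call. = FALSE)
  wald_ci(object$coefficients, vcov(object, match.arg(type)), parm, level)
}

#' @export
print.usd_gee <- function(x, ...) {
  cat(sprintf("Marginal probit model by GEE (%s level, %s working correlation)\n",
              x$level, x$working))
  cat(sprintf("M = %d clusters, alpha = %.4f, phi = %.4f%s\n", x$n_clusters,
              x$alpha, x$phi, if (x$converged) "" else " [NOT CONVERGED]"))
  print(signif(coef(x), 5))
  invisible(x)
}

#' @export
summary.usd_gee <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  z <- ci[, "estimate"] / ci[, "se"]
  tab <- cbind(ci, z = z, p = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, table = tab, level = level),
            class = "summary.usd_gee")
}

#' @export
print.summary.usd_gee <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nWald intervals (%g%%, sandwich SE):\n", 100 * x$level))
  print(signif(x$table, 5))
  invisible(x)
}

#' @rdname interaction_test
#' @export
interaction_test.usd_gee <- function(fit, covariance = c("sandwich", "model"), ...) {
  covariance <- match.arg(covariance)
  if (!fit$converged) stop("fit did not converge; test refused", call. = FALSE)
  if (!fit$interaction || !length(fit$delta_idx))
    stop("fit contains no interaction block", call. = FALSE)
  joint_wald(fit$coefficients, vcov(fit, covariance), fit$delta_idx,
             sprintf("GEE joint Wald chi-squared test (%s covariance) for treatment-by-period interaction",
                     covariance))
}

#' Generalized score test for the treatment-by-period interaction
#'
#' Robust (empirical) score test of `delta_j = 0` for all `j`: the
#' main-effects marginal model is fitted by GEE, the estimating function
#' of the interaction block is evaluated at that restricted fit, and the
#' statistic uses the empirical covariance of the per-cluster effective
#' scores (interaction score residualized on the nuisance score), with
#' `T - 1` degrees of freedom.  The working correlation and dispersion
#' are re-estimated under the null.
#'
#' @inheritParams usd_gee
#' @param null_fit optionally, a converged `"usd_gee"` fit of the
#'   main-effects model (`interaction = FALSE`) on the same data; when
#'   supplied, `data` may be omitted.
#' @return An `"htest"` object.
#' @export
gee_score_test <- function(data, working = c("exchangeable", "independence"),
                           ref_period = 3, scale = c("moment", "fixed"),
                           null_fit = NULL, ...) {
  if (is.null(null_fit)) {
    null_fit <- usd_gee(data, working = working, ref_period = ref_period,
                        interaction = FALSE, scale = scale, ...)
  } else {
    stopifnot(inherits(null_fit, "usd_gee"), !null_fit$interaction)
    if (missing(data)) data <- null_fit$data
  }
  if (!null_fit$converged)
    stop("null model did not converge; score test refused", call. = FALSE)
  pr <- gee_prepare(data, null_fit$ref_period, interaction = TRUE)
  gamma_full <- numeric(pr$p)
  nu <- seq_len(pr$p - length(pr$delta_idx))
  gamma_full[nu] <- null_fit$coefficients
  bl <- gee_blocks(pr, gamma_full, null_fit$alpha, null_fit$phi)
  di <- pr$delta_idx
  Bnn <- bl$B[nu, nu, drop = FALSE]
  Bdn <- bl$B[di, nu, drop = FALSE]
  Proj <- Bdn %*% chol_solve(Bnn)
  Ueff <- bl$Umat[, di, drop = FALSE] - bl$Umat[, nu, drop = FALSE] %*% t(Proj)
  Sig <- crossprod(Ueff)
  Ud <- bl$U[di]
  Siginv <- tryCatch(solve(Sig), error = function(e)
    stop("test error: singular empirical score covariance", call. = FALSE))
  stat <- drop(t(Ud) %*% Siginv %*% Ud)
  df <- length(di)
  structure(list(statistic = c(`X-squared` = stat), parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "GEE generalized (robust) score test for treatment-by-period interaction",
                 data.name = "estimating function at the main-effects fit"),
            class = "htest")
}
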