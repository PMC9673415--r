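# ---- shared design machinery (reference-coded probit mean structure) ----

# Gauss-Hermite nodes/weights for weight function exp(-x^2) (Golub-Welsch)
gauss_hermite <- function(K) {
  if (K == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(K - 1L)
  b <- sqrt(i / 2)
  A <- matrix(0, K, K)
  A[cbind(i, i + 1L)] <- b
  A[cbind(i + 1L, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
}

# Reference-coded design for mu0, beta_j (j != ref), theta, delta_j (j != ref).
# Returns parameter names, the non-reference periods, and a builder that maps
# (M x T) treatment matrices to an (M*T x p) design matrix in (i, j) order
# with cluster index varying fastest.
ref_design <- function(T, ref_period, interaction = TRUE) {
  if (ref_period < 1 || ref_period > T)
    stop("'ref_period' must be one of 1..T", call. = FALSE)
  per <- setdiff(seq_len(T), ref_period)
  nm <- c("mu0", sprintf("beta%d", per), "theta",
          if (interaction) sprintf("delta%d", per))
  build <- function(x) {
    M <- nrow(x)
    p <- length(nm)
    X <- matrix(0, M * T, p)
    X[, 1L] <- 1
    for (q in seq_along(per))
      X[(per[q] - 1L) * M + seq_len(M), 1L + q] <- 1
    X[, 2L + length(per)] <- as.vector(x)
    if (interaction)
      for (q in seq_along(per))
        X[(per[q] - 1L) * M + seq_len(M), 2L + length(per) + q] <- x[, per[q]]
    colnames(X) <- nm
    X
  }
  list(names = nm, periods = per, build = build,
       delta_idx = if (interaction) 2L + length(per) + seq_along(per) else integer())
}

# extract (M x T) matrices from an aggregated trial
trial_matrices <- function(agg) {
  M <- attr(agg, "M"); T <- attr(agg, "T")
  idx <- cbind(agg$cluster, agg$period)
  y <- x <- m <- matrix(NA_real_, M, T)
  y[idx] <- agg$events
  x[idx] <- agg$treatment
  m[idx] <- agg$trials
  if (anyNA(y)) stop("incomplete cluster-period panel", call. = FALSE)
  list(y = y, x = x, m = m, M = M, T = T)
}

# binomial probit derivatives w.r.t. the linear predictor at eta (+ b)
.clamp <- function(P) pmin(pmax(P, 1e-12), 1 - 1e-12)

# ---- likelihood machinery ----

# Closure computing the negative AGQ log-likelihood and its gradient for
# par = c(gamma, log sigma_c2). Cells: events y, trials m (M x T), design
# Xmat (M*T x p) in cluster-fastest order.
agq_machinery <- function(y, m, Xmat, K) {
  M <- nrow(y); T <- ncol(y); p <- ncol(Xmat)
  q <- gauss_hermite(K)
  lgw <- log(q$weights) + q$nodes^2

  find_mode <- function(eta, s2) {
    b <- rep(0, M)
    for (it in 1:50) {
      E <- eta + b
      P <- .clamp(stats::pnorm(E)); d <- stats::dnorm(E); dd <- -E * d
      u <- y * d / P - (m - y) * d / (1 - P)
      h <- y * (dd * P - d^2) / P^2 - (m - y) * (dd * (1 - P) + d^2) / (1 - P)^2
      g1 <- -b / s2 + rowSums(u)
      g2 <- pmin(-1 / s2 + rowSums(h), -1e-10)
      step <- g1 / g2
      step <- sign(step) * pmin(abs(step), 3)
      b <- b - step
      if (max(abs(step)) < 1e-10) break
    }
    E <- eta + b
    P <- .clamp(stats::pnorm(E)); d <- stats::dnorm(E); dd <- -E * d
    h <- y * (dd * P - d^2) / P^2 - (m - y) * (dd * (1 - P) + d^2) / (1 - P)^2
    curv <- pmax(1 / s2 - rowSums(h), 1e-10)
    list(b = b, curv = curv)
  }

  # posterior node weights and log-likelihood pieces at par
  nodes_at <- function(par) {
    gam <- par[seq_len(p)]; s2 <- exp(par[p + 1L])
    eta <- matrix(Xmat %*% gam, M, T)
    md <- find_mode(eta, s2)
    tau <- sqrt(2 / md$curv)
    Bk <- md$b + outer(tau, q$nodes)          # M x K
    lf <- matrix(0, M, K)
    for (k in seq_len(K)) {
      P <- .clamp(stats::pnorm(eta + Bk[, k]))
      lf[, k] <- -Bk[, k]^2 / (2 * s2) +
        rowSums(y * log(P) + (m - y) * log1p(-P))
    }
    lw <- sweep(lf, 2L, lgw, "+") + log(tau)
    mx <- apply(lw, 1L, max)
    ll <- mx + log(rowSums(exp(lw - mx))) - 0.5 * log(2 * pi * s2)
    W <- exp(lw - mx); W <- W / rowSums(W)
    list(eta = eta, s2 = s2, Bk = Bk, W = W, ll = ll)
  }

  nll <- function(par) {
    -sum(nodes_at(par)$ll)
  }

  # per-node score blocks; builds gradient, per-cluster scores, Louis info
  score_pass <- function(par, want_info = FALSE) {
    ns <- nodes_at(par)
    s2 <- ns$s2; eta <- ns$eta; Bk <- ns$Bk; W <- ns$W
    Sbar <- matrix(0, M, p + 1L)
    Cm <- matrix(0, p + 1L, p + 1L)
    Agg <- matrix(0, p, p)
    apsi <- 0
    for (k in seq_len(K)) {
      E <- eta + Bk[, k]
      P <- .clamp(stats::pnorm(E)); d <- stats::dnorm(E)
      u <- (y / P - (m - y) / (1 - P)) * d
      Sk <- cbind(crossprod_cells(u, Xmat, M, T, p), (Bk[, k]^2 / s2 - 1) / 2)
      wk <- W[, k]
      Sbar <- Sbar + Sk * wk
      if (want_info) {
        dd <- -E * d
        h <- y * (dd * P - d^2) / P^2 - (m - y) * (dd * (1 - P) + d^2) / (1 - P)^2
        Cm <- Cm + crossprod(Sk * sqrt(wk))
        v <- sqrt(as.vector(-h) * rep(wk, T))
        Agg <- Agg + crossprod(Xmat * v)
        apsi <- apsi + sum(wk * Bk[, k]^2) / (2 * s2)
      }
    }
    out <- list(gradient = -colSums(Sbar), scores = Sbar, ll = sum(ns$ll))
    if (want_info) {
      A <- rbind(cbind(Agg, 0), 0)
      A[p + 1L, p + 1L] <- apsi
      out$info <- A - (Cm - crossprod(Sbar))
    }
    out
  }

  list(nll = nll, grad = function(par) score_pass(par)$gradient,
       score_pass = score_pass, p = p)
}

# per-cluster complete-data score w.r.t. gamma: rows i, columns of Xmat
# u is M x T (dl/deta per cell); exploits the cluster-fastest layout
crossprod_cells <- function(u, Xmat, M, T, p) {
  uv <- as.vector(u)
  S <- matrix(0, M, p)
  for (c in seq_len(p)) {
    z <- uv * Xmat[, c]
    dim(z) <- c(M, T)
    S[, c] <- rowSums(z)
  }
  S
}

# ---- fitting ----

#' Fit a random-intercept probit GLMM to USD trial data
#'
#' Maximum-likelihood fit of the subject-specific analysis model: outcomes
#' are Bernoulli (individual level) or binomial (cluster-period aggregated
#' level) with conditional success probability
#' `pnorm(mu0 + b_i + beta_j + (theta + delta_j) x_ij)` and a normal
#' cluster intercept `b_i ~ N(0, sigma_c2)`.  The cluster integral is
#' approximated by adaptive Gauss-Hermite quadrature centred and scaled at
#' each cluster's conditional mode; `nodes = 1` is the Laplace
#' approximation.  `sigma_c2` is optimized on the log scale, so the
#' estimate is nonnegative; fits that shrink it to the boundary are
#' reported with `boundary = TRUE`.
#'
#' Individual-level and aggregated data give identical estimates because
#' the cluster-period event count is a binomial sufficient statistic; the
#' reported log-likelihood differs only by the binomial coefficient
#' constant of the data representation supplied.
#'
#' @param data a `"usd_trial"` or `"usd_trial_agg"` data frame (or any
#'   data frame with the same columns).
#' @param nodes number of quadrature nodes (default 25; 1 = Laplace).
#' @param ref_period reference period with `beta = delta = 0` (default 3).
#' @param interaction fit the treatment-by-period interaction block
#'   (`TRUE`, the analysis model) or the main-effects-only model.
#' @param sandwich also compute the cluster-robust (sandwich) covariance
#'   from per-cluster score contributions.
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param max_iter maximum optimizer iterations.
#' @return An object of class `"usd_glmm"` with components `coefficients`
#'   (reference-coded fixed effects), `sigma_c2`, `vcov` (model-based,
#'   inverse observed information including the log-variance row),
#'   `vcov_sandwich` (if requested), `logLik`, `converged`, `boundary`,
#'   `n_iter`, `nodes`, plus bookkeeping used by the test and interval
#'   methods.
#' @seealso [interaction_test()], [confint.usd_glmm()]
#' @export
usd_glmm <- function(data, nodes = 25, ref_period = 3, interaction = TRUE,
                     sandwich = FALSE, tol = 1e-10, max_iter = 500) {
  agg <- as_aggregated(data)
  indiv <- is_individual(data)
  tm <- trial_matrices(agg)
  des <- ref_design(tm$T, ref_period, interaction)
  Xmat <- des$build(tm$x)
  p <- length(des$names)
  qrX <- qr(Xmat)
  if (qrX$rank < p) {
    aliased <- des$names[qrX$pivot[(qrX$rank + 1L):p]]
    stop(sprintf("interaction not identifiable from this design: aliased parameters %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }

  mach <- agq_machinery(tm$y, tm$m, Xmat, K = as.integer(nodes))
  g0 <- suppressWarnings(stats::glm.fit(Xmat, cbind(as.vector(tm$y), as.vector(tm$m - tm$y)),
                                        family = stats::binomial("probit")))
  starts <- list(c(g0$coefficients, log(0.1)),
                 c(0.9 * g0$coefficients, log(0.3)))
  lower <- c(rep(-Inf, p), log(1e-10))
  upper <- c(rep(Inf, p), log(100))
  opt <- NULL; converged <- FALSE
  for (st in starts) {
    opt <- stats::optim(st, mach$nll, mach$grad, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
    converged <- opt$convergence == 0L
    if (converged) break
  }
  par <- opt$par
  sigma_c2 <- exp(par[p + 1L])
  boundary <- sigma_c2 < 1e-8
  sp <- mach$score_pass(par, want_info = TRUE)
  info <- sp$info
  if (boundary) {
    V <- matrix(NA_real_, p + 1L, p + 1L)
    V[seq_len(p), seq_len(p)] <- chol_solve(info[seq_len(p), seq_len(p)])
  } else {
    V <- chol_solve(info)
  }
  dimnames(V) <- list(c(des$names, "log_sigma_c2"), c(des$names, "log_sigma_c2"))
  Vs <- NULL
  if (sandwich) {
    Vok <- V
    if (boundary) Vok[p + 1L, ] <- Vok[, p + 1L] <- 0
    meat <- crossprod(sp$scores)
    Vs <- Vok %*% meat %*% Vok
    dimnames(Vs) <- dimnames(V)
  }
  const <- sum(lchoose(tm$m, tm$y))
  ll <- -opt$value + if (indiv) 0 else const
  coefs <- par[seq_len(p)]
  names(coefs) <- des$names
  structure(list(coefficients = coefs, sigma_c2 = sigma_c2,
                 vcov = V, vcov_sandwich = Vs,
                 logLik = ll, loglik_constant = const,
                 converged = converged, boundary = boundary,
                 n_iter = opt$counts[["function"]],
                 nodes = as.integer(nodes), ref_period = ref_period,
                 interaction = interaction, delta_idx = des$delta_idx,
                 M = tm$M, T = tm$T, level = if (indiv) "individual" else "aggregated",
                 data = agg),
            class = "usd_glmm")
}

chol_solve <- function(A) {
  ok <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(ok)) ok <- solve(A)
  (ok + t(ok)) / 2
}

#' Marginal log-likelihood of the probit GLMM at a given parameter point
#'
#' Evaluates the adaptive Gauss-Hermite approximation of the marginal
#' log-likelihood at user-supplied parameter values, without fitting.
#' Useful for checking the quadrature against direct numerical
#' integration.
#'
#' @inheritParams usd_glmm
#' @param coefficients named or positional fixed-effect vector in the
#'   reference coding of [usd_glmm()].
#' @param sigma_c2 cluster variance at which to evaluate.
#' @return The log-likelihood (a scalar); for aggregated data it includes
#'   the binomial coefficient terms.
#' @export
glmm_loglik <- function(data, coefficients, sigma_c2, nodes = 25,
                        ref_period = 3, interaction = TRUE) {
  agg <- as_aggregated(data)
  indiv <- is_individual(data)
  tm <- trial_matrices(agg)
  des <- ref_design(tm$T, ref_period, interaction)
  mach <- agq_machinery(tm$y, tm$m, des$build(tm$x), K = as.integer(nodes))
  const <- sum(lchoose(tm$m, tm$y))
  -mach$nll(c(coefficients, log(sigma_c2))) + if (indiv) 0 else const
}

# ---- methods ----

#' @export
coef.usd_glmm <- function(object, ...) {
  c(object$coefficients, sigma_c2 = object$sigma_c2)
}

#' Covariance of a fitted probit GLMM
#'
#' @param object an `"usd_glmm"` fit.
#' @param type `"model"` for the inverse observed information (default) or
#'   `"sandwich"` for the cluster-robust estimator (available when the
#'   fit was run with `sandwich = TRUE`).
#' @param ... unused.
#' @return Covariance matrix of the fixed effects and `log_sigma_c2`.
#' @export
vcov.usd_glmm <- function(object, type = c("model", "sandwich"), ...) {
  type <- match.arg(type)
  if (type == "model") return(object$vcov)
  if (is.null(object$vcov_sandwich))
    stop("fit was run without sandwich = TRUE", call. = FALSE)
  object$vcov_sandwich
}

#' @export
logLik.usd_glmm <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) + 1L,
            class = "logLik")
}

#' Wald confidence intervals for a probit GLMM
#'
#' Normal-quantile (infinite denominator degrees of freedom) intervals
#' `estimate +/- z * SE` for the fixed effects.
#'
#' @param object an `"usd_glmm"` fit; must have converged.
#' @param parm parameters to include (names or indices; default all fixed
#'   effects).
#' @param level confidence level.
#' @param type covariance to use, as in [vcov.usd_glmm()].
#' @param ... unused.
#' @return Matrix with columns `estimate`, `lower`, `upper`, `se`.
#' @export
confint.usd_glmm <- function(object, parm = NULL, level = 0.95,
                             type = c("model", "sandwich"), ...) {
  if (!object$converged)
    stop("fit did not converge; intervals would be unreliable", call. = FALSE)
  wald_ci(object$coefficients, vcov(object, match.arg(type)), parm, level)
}

wald_ci <- function(est, V, parm, level) {
  nm <- names(est)
  se <- sqrt(pmax(diag(V)[nm], 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(estimate = est, lower = est - z * se, upper = est + z * se, se = se)
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.usd_glmm <- function(x, ...) {
  cat(sprintf("Probit random-intercept GLMM (%s level, %d-node adaptive quadrature)\n",
              x$level, x$nodes))
  cat(sprintf("M = %d clusters, T = %d periods, logLik = %.3f%s\n", x$M, x$T,
              x$logLik, if (x$converged) "" else " [NOT CONVERGED]"))
  print(signif(coef(x), 5))
  if (x$boundary) cat("sigma_c2 at boundary (~0)\n")
  invisible(x)
}

#' @export
summary.usd_glmm <- function(object, level = 0.95, ...) {
  ci <- confint(object, level = level)
  z <- ci[, "estimate"] / ci[, "se"]
  tab <- cbind(ci, z = z, `p` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, table = tab, level = level),
            class = "summary.usd_glmm")
}

#' @export
print.summary.usd_glmm <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nWald intervals (%g%%, model-based SE):\n", 100 * x$level))
  print(signif(x$table, 5))
  if (x$fit$interaction) {
    it <- interaction_test(x$fit)
    cat(sprintf("\nJoint interaction test: chi-squared = %.3f, df = %d, p = %.4g\n",
                it$statistic, it$parameter, it$p.value))
  }
  invisible(x)
}

# ---- interaction test ----

#' Joint test of the treatment-by-period interaction
#'
#' Wald chi-squared test that all interaction contrasts `delta_j`
#' (`j != ref_period`) are zero, with `T - 1` degrees of freedom:
#' `delta' V_delta^{-1} delta` against the upper chi-squared tail.  For
#' GLMM fits the model-based covariance is the default; for GEE fits the
#' sandwich covariance is the default (the robust Wald test).
#'
#' @param fit an `"usd_glmm"` or `"usd_gee"` fit of the interaction model.
#' @param covariance `"model"` or `"sandwich"`.
#' @param ... unused.
#' @return An `"htest"` object.
#' @export
interaction_test <- function(fit, ...) UseMethod("interaction_test")

#' @rdname interaction_test
#' @export
interaction_test.usd_glmm <- function(fit, covariance = c("model", "sandwich"), ...) {
  covariance <- match.arg(covariance)
  if (!fit$converged)
    stop("fit did not converge; test refused", call. = FALSE)
  if (!fit$interaction || !length(fit$delta_idx))
    stop("fit contains no interaction block", call. = FALSE)
  joint_wald(fit$coefficients, vcov(fit, covariance), fit$delta_idx,
             sprintf("GLMM joint Wald chi-squared test (%s covariance) for treatment-by-period interaction",
                     covariance))
}

joint_wald <- function(est, V, idx, method) {
  d <- est[idx]
  Vd <- V[idx, idx, drop = FALSE]
  Vinv <- tryCatch(solve(Vd), error = function(e)
    stop("test error: singular interaction covariance", call. = FALSE))
  stat <- drop(t(d) %*% Vinv %*% d)
  df <- length(idx)
  structure(list(statistic = c(`X-squared` = stat), parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = method, data.name = "fitted interaction block"),
            class = "htest")
}
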