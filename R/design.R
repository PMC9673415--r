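#' Switch patterns of a unidirectional switch design
#'
#' In a unidirectional switch design (USD) with `T` periods, a cluster can
#' follow one of `T + 1` treatment patterns.  Pattern `h` spends the first
#' `T - h` periods on control and the last `h` periods on intervention, so
#' pattern 0 is the pure control arm and pattern `T` the pure intervention
#' arm.  Stepped-wedge, parallel-group and delayed-start designs are all
#' obtained by putting allocation mass on subsets of these patterns.
#'
#' @param T integer number of periods, at least 2.
#' @return An integer matrix with `T + 1` rows (patterns `0..T`, in row
#'   order) and `T` columns; entry `[h + 1, j]` is 1 if pattern `h` is on
#'   intervention in period `j`.
#' @examples
#' usd_patterns(5)
#' @export
usd_patterns <- function(T) {
  T <- check_periods(T)
  P <- matrix(0L, T + 1L, T)
  for (h in seq_len(T)) P[h + 1L, seq.int(T - h + 1L, T)] <- 1L
  dimnames(P) <- list(pattern = 0:T, period = seq_len(T))
  P
}

check_periods <- function(T) {
  if (length(T) != 1L || !is.finite(T) || T < 2 || T != round(T))
    stop("invalid design: 'T' must be a single integer >= 2", call. = FALSE)
  as.integer(T)
}

#' Latent-scale intraclass correlation of a probit random-intercept model
#'
#' For a binary outcome generated by a probit model with a normal cluster
#' intercept of variance `sigma_c2`, the intraclass correlation on the
#' latent scale is `sigma_c2 / (sigma_c2 + 1)` (the residual latent
#' variance of the probit link is 1).
#'
#' @param sigma_c2 nonnegative cluster-intercept variance.
#' @return The ICC, a value in `[0, 1)`.
#' @examples
#' icc_latent(0.2)
#' @export
icc_latent <- function(sigma_c2) {
  if (any(!is.finite(sigma_c2)) || any(sigma_c2 < 0))
    stop("'sigma_c2' must be nonnegative", call. = FALSE)
  sigma_c2 / (sigma_c2 + 1)
}

#' Uniform cluster allocations for PGD, DSD and full-pattern USD
#'
#' Divides `M` clusters equally over the patterns the variant supports:
#' the two pure patterns for a parallel-group design (`"PGD"`), patterns
#' `{0, s, T}` for the three-pattern delayed-start design (`"DSDu"`), and
#' all `T + 1` patterns for the uniform USD (`"USDu"`).
#'
#' @param variant one of `"PGD"`, `"DSDu"`, `"USDu"`.
#' @param M total number of clusters; must be divisible by the number of
#'   supported patterns.
#' @param T number of periods.
#' @param s index of the middle switch pattern for `"DSDu"` (strictly
#'   between 0 and `T`).
#' @return Integer vector of length `T + 1` with names `0..T`: clusters
#'   allocated to each pattern.
#' @examples
#' uniform_allocation("DSDu", M = 48, T = 5, s = 3)
#' @export
uniform_allocation <- function(variant = c("PGD", "DSDu", "USDu"), M, T, s = NULL) {
  variant <- match.arg(variant)
  T <- check_periods(T)
  support <- switch(variant,
    PGD = c(0L, T),
    DSDu = {
      s <- check_middle(s, T)
      c(0L, s, T)
    },
    USDu = 0:T
  )
  M <- as.integer(M)
  k <- length(support)
  if (M %% k != 0L)
    stop(sprintf("allocation error: M = %d is not divisible by %d patterns (remainder %d)",
                 M, k, M %% k), call. = FALSE)
  N <- integer(T + 1L)
  N[support + 1L] <- M %/% k
  names(N) <- 0:T
  N
}

check_middle <- function(s, T) {
  if (is.null(s) || length(s) != 1L || !is.finite(s) || s != round(s) || s <= 0 || s >= T)
    stop("'s' must be an integer strictly between 0 and T", call. = FALSE)
  as.integer(s)
}

#' Allocation probabilities of the optimal delayed-start design
#'
#' Closed-form allocation probabilities that minimise the variance of the
#' estimated average treatment effect (continuous outcome, many clusters,
#' no treatment-by-period interaction) over three-pattern delayed-start
#' designs with patterns `{0, s, T}`.
#'
#' @param n subjects per cluster per period.
#' @param rho intraclass correlation, in `[0, 1)`; see [icc_latent()].
#' @param T number of periods.
#' @param s middle switch pattern index.
#' @return Named numeric vector `c(p0, ps, pT)` summing to 1.
#' @examples
#' optimal_dsd_probs(n = 50, rho = icc_latent(0.2), T = 5, s = 3)
#' @export
optimal_dsd_probs <- function(n, rho, T, s) {
  T <- check_periods(T); s <- check_middle(s, T); check_rho(rho)
  den <- 2 * (1 - rho + n * rho * T)
  p <- c(p0 = (1 - rho + n * rho * s) / den,
         ps = n * rho * T / den,
         pT = (1 - rho + n * rho * (T - s)) / den)
  p
}

#' Allocation probabilities of the optimal full-pattern USD
#'
#' Closed-form optimal probabilities over all `T + 1` switch patterns for
#' estimating the average treatment effect (continuous outcome, large-M
#' approximation, no interaction).  The pure patterns receive
#' `(1 - rho + n rho) / (2 (1 - rho + n rho T))` each and every interior
#' pattern `n rho / (1 - rho + n rho T)`.  At `rho = 0` this collapses to
#' the parallel-group design.
#'
#' @inheritParams optimal_dsd_probs
#' @return Named numeric vector of length `T + 1` (patterns `0..T`)
#'   summing to 1.
#' @examples
#' optimal_usd_probs(n = 50, rho = 1/6, T = 5)
#' @export
optimal_usd_probs <- function(n, rho, T) {
  T <- check_periods(T); check_rho(rho)
  den <- 1 - rho + n * rho * T
  pure <- (1 - rho + n * rho) / (2 * den)
  interior <- n * rho / den
  p <- c(pure, rep(interior, T - 1L), pure)
  names(p) <- 0:T
  p
}

check_rho <- function(rho) {
  if (length(rho) != 1L || !is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)", call. = FALSE)
  rho
}

#' Integer cluster allocation from optimal probabilities
#'
#' Converts optimal allocation probabilities into whole numbers of
#' clusters.  Exact proportions `p_h * M` are fractional, so a rounding
#' convention is needed; three symmetric conventions are provided.
#'
#' `"usdo1"` rounds the interior patterns down and splits the remaining
#' clusters equally between the two pure patterns (at moderate ICC this
#' coincides with rounding the pure patterns up).  `"usdo2"` rounds
#' patterns 1 and `T - 1` up and patterns `2..T-2` down, the pure patterns
#' again taking the equal remainder (pure patterns rounded down relative
#' to `"usdo1"`).  `"dsdo"` expects the three-pattern probabilities
#' `(p0, ps, pT)`: `ps * M` and `pT * M` are rounded to the nearest
#' integer and pattern 0 absorbs the remainder.
#'
#' @param probs probability vector summing to 1: length `T + 1` for the
#'   USD schemes, length 3 (`p0, ps, pT`) for `"dsdo"`.
#' @param M total number of clusters.
#' @param scheme rounding convention, one of `"usdo1"`, `"usdo2"`, `"dsdo"`.
#' @param T number of periods; required for `"dsdo"`, otherwise inferred
#'   from `length(probs) - 1`.
#' @param s middle pattern index for `"dsdo"`.
#' @return Integer allocation vector of length `T + 1` (names `0..T`)
#'   summing to `M`.
#' @examples
#' round_allocation(optimal_usd_probs(50, 1/6, 5), M = 48, scheme = "usdo1")
#' @export
round_allocation <- function(probs, M, scheme = c("usdo1", "usdo2", "dsdo"),
                             T = NULL, s = NULL) {
  scheme <- match.arg(scheme)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("'probs' must sum to 1", call. = FALSE)
  if (scheme == "dsdo") {
    if (length(probs) != 3L)
      stop("scheme error: 'dsdo' expects the three probabilities (p0, ps, pT)",
           call. = FALSE)
    T <- check_periods(T); s <- check_middle(s, T)
    Ns <- round(probs[2L] * M)
    NT <- round(probs[3L] * M)
    N <- integer(T + 1L)
    N[s + 1L] <- Ns
    N[T + 1L] <- NT
    N[1L] <- M - Ns - NT
  } else {
    if (is.null(T)) T <- length(probs) - 1L
    T <- check_periods(T)
    if (length(probs) != T + 1L)
      stop("scheme error: USD schemes expect probabilities for all T + 1 patterns",
           call. = FALSE)
    interior <- probs[2:T] * M
    Nin <- switch(scheme,
      usdo1 = floor(interior),
      usdo2 = { x <- floor(interior)
                x[c(1L, T - 1L)] <- ceiling(interior[c(1L, T - 1L)])
                x })
    rem <- M - sum(Nin)
    if (rem < 0)
      stop(sprintf("allocation error: interior patterns exceed M by %d", -rem),
           call. = FALSE)
    # pure patterns share the remainder; an odd leftover goes to pattern 0
    N <- as.integer(c(ceiling(rem / 2), Nin, floor(rem / 2)))
  }
  if (any(N < 0)) stop("allocation error: negative cluster count", call. = FALSE)
  N <- as.integer(N)
  names(N) <- 0:T
  N
}

#' Construct a unidirectional switch design
#'
#' Builds an executable design: an integer allocation of `M` clusters to
#' the `T + 1` switch patterns, for one of the studied variants or a
#' custom allocation.  Optimal variants (`"DSDo"`, `"USDo1"`, `"USDo2"`)
#' need the ICC, supplied either directly as `rho` or via the latent
#' cluster variance `sigma_c2` (then `rho = sigma_c2 / (sigma_c2 + 1)`).
#'
#' @param variant design variant: `"PGD"`, `"DSDu"`, `"DSDo"`, `"USDu"`,
#'   `"USDo1"`, `"USDo2"` or `"custom"`.
#' @param M total number of clusters.
#' @param T number of periods (default 5).
#' @param n subjects per cluster per period (default 50); used by the
#'   optimal allocations and carried along for simulation.
#' @param sigma_c2,rho cluster variance or ICC for the optimal variants.
#' @param s middle switch pattern for the delayed-start variants
#'   (default 3).
#' @param allocation for `variant = "custom"`, an integer vector of
#'   length `T + 1` of cluster counts per pattern.
#' @return An object of class `"usd_design"`: a list with elements
#'   `variant`, `T`, `M`, `n`, `s`, `rho`, `probs` (allocation
#'   probabilities where defined), `allocation` (integer counts `N_0..N_T`)
#'   and `patterns` (the pattern matrix of [usd_patterns()]).
#' @examples
#' usd_design("USDo1", M = 48, sigma_c2 = 0.2)
#' @export
usd_design <- function(variant = c("PGD", "DSDu", "DSDo", "USDu", "USDo1",
                                   "USDo2", "custom"),
                       M, T = 5, n = 50, sigma_c2 = NULL, rho = NULL,
                       s = 3, allocation = NULL) {
  variant <- match.arg(variant)
  T <- check_periods(T)
  if (is.null(rho) && !is.null(sigma_c2)) rho <- icc_latent(sigma_c2)
  probs <- NULL
  if (variant == "custom") {
    if (is.null(allocation) || length(allocation) != T + 1L)
      stop("custom design needs an 'allocation' of length T + 1", call. = FALSE)
    N <- as.integer(allocation)
    if (any(N < 0)) stop("allocation counts must be nonnegative", call. = FALSE)
    M <- sum(N)
    names(N) <- 0:T
  } else if (variant %in% c("PGD", "DSDu", "USDu")) {
    N <- uniform_allocation(variant, M, T, s = if (variant == "DSDu") s else NULL)
    probs <- N / M
  } else {
    if (is.null(rho))
      stop("optimal variants need 'rho' or 'sigma_c2'", call. = FALSE)
    if (variant == "DSDo") {
      p3 <- optimal_dsd_probs(n, rho, T, s)
      N <- round_allocation(p3, M, "dsdo", T = T, s = s)
      probs <- numeric(T + 1L)
      probs[c(1L, s + 1L, T + 1L)] <- p3
    } else {
      probs <- optimal_usd_probs(n, rho, T)
      N <- round_allocation(probs, M,
                            scheme = if (variant == "USDo1") "usdo1" else "usdo2")
    }
  }
  M <- as.integer(M)
  if (sum(N) != M) stop("allocation does not sum to M", call. = FALSE)
  structure(list(variant = variant, T = T, M = M, n = n,
                 s = if (variant %in% c("DSDu", "DSDo")) s else NA_integer_,
                 rho = if (is.null(rho)) NA_real_ else rho,
                 probs = probs, allocation = N, patterns = usd_patterns(T)),
            class = "usd_design")
}

#' @export
print.usd_design <- function(x, ...) {
  cat(sprintf("Unidirectional switch design: %s (T = %d, M = %d, n = %d)\n",
              x$variant, x$T, x$M, x$n))
  cat("Clusters per switch pattern:\n")
  print(x$allocation)
  rep <- check_identifiability(x)
  cat(sprintf("Treatment-by-period interaction %sidentifiable (%d unique cells, %d free parameters)\n",
              if (rep$identifiable) "" else "NOT ", rep$unique_cell_count,
              rep$free_parameter_count))
  invisible(x)
}

#' Cluster-by-period treatment indicator matrix
#'
#' Expands an allocation into the `M x T` treatment matrix whose row `i`
#' is the pattern followed by cluster `i`.  Clusters are ordered by
#' pattern index (pattern-major); any randomization of cluster labels is
#' left to the trial, not the design.
#'
#' @param design an `"usd_design"` object, or an integer allocation
#'   vector of length `T + 1`.
#' @return Integer matrix of dimension `M x T`.
#' @examples
#' treatment_matrix(usd_design("PGD", M = 4, T = 3))
#' @export
treatment_matrix <- function(design) {
  N <- allocation_of(design)
  T <- length(N) - 1L
  P <- usd_patterns(T)
  X <- P[rep(seq_len(T + 1L), N), , drop = FALSE]
  rownames(X) <- seq_len(nrow(X))
  X
}

allocation_of <- function(design) {
  if (inherits(design, "usd_design")) return(design$allocation)
  N <- as.integer(design)
  if (length(N) < 3L || any(N < 0)) stop("invalid allocation", call. = FALSE)
  names(N) <- seq_along(N) - 1L
  N
}

#' Identifiability of the treatment-by-period interaction
#'
#' The saturated cell-mean structure of a USD has parameters `mu0`,
#' `beta_j` (period effects), `theta_0` and `delta_j` (period-specific
#' treatment effects); under the reference constraints `beta_ref =
#' delta_ref = 0` there are `2T` free parameters.  They are identifiable
#' exactly when every period contains clusters on both arms, which yields
#' `2T` unique (period, arm) cells.  A pure stepped-wedge design has only
#' `2T - 2` cells (no control at the last period, no treatment at the
#' first) and is not identifiable.
#'
#' @inheritParams treatment_matrix
#' @return An object of class `"usd_identifiability"`: list with
#'   `identifiable`, `unique_cell_count`, `free_parameter_count`,
#'   `periods_missing_control`, `periods_missing_treatment`.
#' @examples
#' # stepped wedge with T = 4: patterns 1..3 only
#' check_identifiability(c(0, 4, 4, 4, 0))
#' @export
check_identifiability <- function(design) {
  N <- allocation_of(design)
  T <- length(N) - 1L
  P <- usd_patterns(T)
  present <- N > 0L
  # arm presence per period
  treated <- colSums(P[present, , drop = FALSE] == 1L) > 0L
  control <- colSums(P[present, , drop = FALSE] == 0L) > 0L
  cells <- sum(treated) + sum(control)
  miss_c <- which(!control)
  miss_t <- which(!treated)
  structure(list(identifiable = length(miss_c) == 0L && length(miss_t) == 0L,
                 unique_cell_count = as.integer(cells),
                 free_parameter_count = 2L * T,
                 periods_missing_control = as.integer(miss_c),
                 periods_missing_treatment = as.integer(miss_t)),
            class = "usd_identifiability")
}

#' @export
print.usd_identifiability <- function(x, ...) {
  cat(sprintf("%s: %d unique (period, arm) cells, %d free parameters\n",
              if (x$identifiable) "Identifiable" else "Not identifiable",
              x$unique_cell_count, x$free_parameter_count))
  if (length(x$periods_missing_control))
    cat("Periods with no control arm:", x$periods_missing_control, "\n")
  if (length(x$periods_missing_treatment))
    cat("Periods with no treatment arm:", x$periods_missing_treatment, "\n")
  invisible(x)
}
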