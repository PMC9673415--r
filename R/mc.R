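#' Monte-Carlo standard error of a simulated proportion
#'
#' @param p the proportion (rejection rate, coverage, ...).
#' @param reps number of Monte-Carlo replicates behind it.
#' @return `sqrt(p * (1 - p) / reps)`.
#' @examples
#' mcse_prop(0.05, 1000)  # ~0.007
#' @export
mcse_prop <- function(p, reps) sqrt(p * (1 - p) / reps)

# replicate k's seed depends only on the master seed and k, so replicate
# sets are extensible without reshuffling earlier replicates
replicate_seeds <- function(master, reps) {
  set.seed(master)
  sample.int(2147483646L, reps, replace = TRUE)
}

#' Run one Monte-Carlo study cell
#'
#' Repeatedly simulates a trial from the probit DGP, analyses each
#' replicate with the requested engines, and records estimates, standard
#' errors and interaction-test p-values.  Replicates are seeded from
#' independent substreams of `seed`, so results are deterministic and any
#' execution order gives the same records.  Replicate-level fit failures
#' are recorded with a reason code, never aborting the cell; one retry
#' from a perturbed start is built into the GLMM optimizer.
#'
#' @param design an `"usd_design"`; must be identifiable.
#' @param params an `"usd_sim_params"`.
#' @param reps number of replicates.
#' @param level analyse at the `"aggregated"` (cluster-period counts) or
#'   `"individual"` level.
#' @param methods engines to run: subset of `c("glmm", "gee")`.
#' @param seed master seed.
#' @param nodes quadrature nodes for the GLMM.
#' @param ref_period reference period.
#' @param randomize re-draw the cluster-to-pattern allocation multinomially
#'   in every replicate (see [simulate_usd_trial()]).
#' @return A data frame of class `"usd_mc_records"`, one row per
#'   replicate-method, with columns `rep`, `method`, `converged`,
#'   `excluded` (reason or `NA`), `p_value` (GLMM chi-squared / GEE
#'   generalized score), `p_wald_robust` (GEE only), `sigma_c2`, `alpha`,
#'   `phi`, and `est_*` / `se_*` per fixed effect.
#' @export
mc_run_cell <- function(design, params, reps, level = c("aggregated", "individual"),
                        methods = c("glmm", "gee"), seed = 1, nodes = 25,
                        ref_period = 3, randomize = FALSE) {
  level <- match.arg(level)
  methods <- match.arg(methods, c("glmm", "gee"), several.ok = TRUE)
  idr <- check_identifiability(design)
  if (!idr$identifiable)
    stop("design is not identifiable for the interaction model (periods missing an arm); refusing the cell",
         call. = FALSE)
  seeds <- replicate_seeds(seed, reps)
  pnames <- ref_design(design$T, ref_period)$names
  rows <- vector("list", reps * length(methods))
  ri <- 0L
  for (k in seq_len(reps)) {
    trial <- simulate_usd_trial(design, params, seed = seeds[k],
                                randomize = randomize)
    dat <- if (level == "aggregated") aggregate_trial(trial) else trial
    if ("glmm" %in% methods) {
      ri <- ri + 1L
      rows[[ri]] <- mc_one_glmm(dat, k, nodes, ref_period, pnames)
    }
    if ("gee" %in% methods) {
      ri <- ri + 1L
      rows[[ri]] <- mc_one_gee(dat, k, ref_period, pnames)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  structure(out, class = c("usd_mc_records", "data.frame"),
            level = level, reps = reps, seed = seed, pnames = pnames,
            design = design$variant, sigma_c2 = params$sigma_c2,
            structure_ = params$structure, r = params$r)
}

mc_row_skeleton <- function(k, method, pnames) {
  row <- data.frame(rep = k, method = method, converged = FALSE,
                    excluded = NA_character_, p_value = NA_real_,
                    p_wald_robust = NA_real_, sigma_c2 = NA_real_,
                    alpha = NA_real_, phi = NA_real_,
                    stringsAsFactors = FALSE)
  for (nm in pnames) row[[paste0("est_", nm)]] <- NA_real_
  for (nm in pnames) row[[paste0("se_", nm)]] <- NA_real_
  row
}

mc_one_glmm <- function(dat, k, nodes, ref_period, pnames) {
  row <- mc_row_skeleton(k, "glmm", pnames)
  fit <- tryCatch(usd_glmm(dat, nodes = nodes, ref_period = ref_period),
                  error = function(e) conditionMessage(e))
  if (is.character(fit)) { row$excluded <- paste0("fit_error: ", fit); return(row) }
  if (!fit$converged) { row$excluded <- "non_convergence"; return(row) }
  row$converged <- TRUE
  tst <- tryCatch(interaction_test(fit), error = function(e) NULL)
  if (is.null(tst)) { row$excluded <- "test_error_singular"; row$converged <- FALSE; return(row) }
  row$p_value <- tst$p.value
  row$sigma_c2 <- fit$sigma_c2
  se <- sqrt(pmax(diag(fit$vcov)[pnames], 0))
  for (nm in pnames) {
    row[[paste0("est_", nm)]] <- unname(fit$coefficients[nm])
    row[[paste0("se_", nm)]] <- unname(se[nm])
  }
  row
}

mc_one_gee <- function(dat, k, ref_period, pnames) {
  row <- mc_row_skeleton(k, "gee", pnames)
  fit <- tryCatch(usd_gee(dat, ref_period = ref_period),
                  error = function(e) conditionMessage(e))
  if (is.character(fit)) { row$excluded <- paste0("fit_error: ", fit); return(row) }
  if (!fit$converged) { row$excluded <- "non_convergence"; return(row) }
  sc <- tryCatch(gee_score_test(dat, ref_period = ref_period),
                 error = function(e) NULL)
  wd <- tryCatch(interaction_test(fit), error = function(e) NULL)
  if (is.null(sc) || is.null(wd)) { row$excluded <- "test_error_singular"; return(row) }
  row$converged <- TRUE
  row$p_value <- sc$p.value
  row$p_wald_robust <- wd$p.value
  row$alpha <- fit$alpha
  row$phi <- fit$phi
  se <- sqrt(pmax(diag(fit$vcov_sandwich)[pnames], 0))
  for (nm in pnames) {
    row[[paste0("est_", nm)]] <- unname(fit$coefficients[nm])
    row[[paste0("se_", nm)]] <- unname(se[nm])
  }
  row
}

#' True reference-coded parameter values of a DGP
#'
#' Returns the fixed-effect truths in the reference coding used by the
#' engines, on the subject-specific scale (the GLMM estimand) or the
#' marginal scale (the GEE estimand, attenuated by `1/sqrt(1+sigma_c2)`).
#'
#' @param params an `"usd_sim_params"`.
#' @param scale `"subject_specific"` or `"marginal"`.
#' @param ref_period reference period.
#' @return Named vector matching the engines' coefficient names, plus
#'   `sigma_c2` on the subject-specific scale.
#' @export
true_values <- function(params, scale = c("subject_specific", "marginal"),
                        ref_period = 3) {
  scale <- match.arg(scale)
  f <- if (scale == "marginal") 1 / sqrt(1 + params$sigma_c2) else 1
  T <- params$T
  per <- setdiff(seq_len(T), ref_period)
  mu0 <- params$mu0 + params$beta[ref_period]
  theta <- params$theta0 + params$delta[ref_period]
  v <- c(mu0, params$beta[per] - params$beta[ref_period], theta,
         params$delta[per] - params$delta[ref_period]) * f
  names(v) <- c("mu0", sprintf("beta%d", per), "theta", sprintf("delta%d", per))
  if (scale == "subject_specific") v <- c(v, sigma_c2 = params$sigma_c2)
  v
}

#' Summarize Monte-Carlo records
#'
#' Computes, per engine and parameter, the mean estimate, bias against
#' the engine's own estimand (subject-specific truth for the GLMM,
#' marginal truth for GEE), empirical and mean reported standard errors,
#' and Wald-interval coverage; and per engine the interaction-test
#' rejection rate (type I error under a null DGP, power otherwise).
#' Every proportion carries its Monte-Carlo standard error
#' `sqrt(p(1-p)/R)`.  Non-converged or errored replicates are excluded
#' from the denominators and counted.
#'
#' @param records an `"usd_mc_records"` data frame from [mc_run_cell()].
#' @param params the `"usd_sim_params"` the cell was generated from.
#' @param level confidence level of the coverage intervals.
#' @param alpha test size for the rejection rate.
#' @param ref_period reference period used in the fits.
#' @return A list of class `"usd_mc_summary"`: `estimates` (data frame),
#'   `tests` (data frame with `rejection_rate`, `mcse`, `n_used`,
#'   `n_excluded`).
#' @export
mc_summarize <- function(records, params, level = 0.95, alpha = 0.05,
                         ref_period = 3) {
  stopifnot(is.data.frame(records))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est_tabs <- list(); test_tabs <- list()
  for (meth in unique(records$method)) {
    rec <- records[records$method == meth, , drop = FALSE]
    ok <- rec[is.na(rec$excluded) & rec$converged, , drop = FALSE]
    R <- nrow(ok)
    if (R == 0) stop("all replicates excluded for method ", meth, call. = FALSE)
    truth <- true_values(params,
                         if (meth == "glmm") "subject_specific" else "marginal",
                         ref_period)
    pnames <- setdiff(names(truth), "sigma_c2")
    for (nm in pnames) {
      e <- ok[[paste0("est_", nm)]]
      s <- ok[[paste0("se_", nm)]]
      cover <- mean(truth[nm] >= e - z * s & truth[nm] <= e + z * s)
      est_tabs[[length(est_tabs) + 1L]] <- data.frame(
        method = meth, parameter = nm, truth = unname(truth[nm]),
        mean_estimate = mean(e), bias = mean(e) - unname(truth[nm]),
        bias_mcse = stats::sd(e) / sqrt(R), empirical_se = stats::sd(e),
        mean_se = mean(s), coverage = cover,
        coverage_mcse = mcse_prop(cover, R), n_used = R,
        stringsAsFactors = FALSE)
    }
    if (meth == "glmm" && "sigma_c2" %in% names(truth)) {
      e <- ok$sigma_c2
      est_tabs[[length(est_tabs) + 1L]] <- data.frame(
        method = meth, parameter = "sigma_c2", truth = unname(truth["sigma_c2"]),
        mean_estimate = mean(e), bias = mean(e) - unname(truth["sigma_c2"]),
        bias_mcse = stats::sd(e) / sqrt(R), empirical_se = stats::sd(e),
        mean_se = NA_real_, coverage = NA_real_, coverage_mcse = NA_real_,
        n_used = R, stringsAsFactors = FALSE)
    }
    rej <- mean(ok$p_value < alpha)
    test_tabs[[length(test_tabs) + 1L]] <- data.frame(
      method = meth,
      test = if (meth == "glmm") "wald_chisq_model" else "generalized_score",
      rejection_rate = rej, mcse = mcse_prop(rej, R),
      n_used = R, n_excluded = nrow(rec) - R, stringsAsFactors = FALSE)
    if (meth == "gee") {
      rejw <- mean(ok$p_wald_robust < alpha)
      test_tabs[[length(test_tabs) + 1L]] <- data.frame(
        method = meth, test = "robust_wald", rejection_rate = rejw,
        mcse = mcse_prop(rejw, R), n_used = R, n_excluded = nrow(rec) - R,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(estimates = do.call(rbind, est_tabs),
                 tests = do.call(rbind, test_tabs)),
            class = "usd_mc_summary")
}

#' @export
print.usd_mc_summary <- function(x, ...) {
  cat("Interaction-test rejection rates:\n")
  print(x$tests, row.names = FALSE, digits = 4)
  cat("\nParameter recovery:\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run a grid of Monte-Carlo study cells
#'
#' Iterates over study cells (design variant, cluster variance,
#' correlation structure, interaction profile, analysis level) and
#' returns one tidy summary table.  The configuration is a list — or a
#' path to a YAML/JSON file — with a `cells` list and optional shared
#' defaults `M`, `n`, `T`, `reps`, `seed`, `methods`, `mu0`.  Each cell
#' may override any of them and sets `design`, `sigma_c2`, `structure`
#' (default exchangeable), `r`, `effect` (`linear`/`symmetric`/`null`),
#' `level` and `randomize`.
#'
#' @param config list or path to a YAML or JSON configuration file.
#' @param out optional output directory: writes `summary.csv`,
#'   `records.csv` and `exclusions.log`.
#' @return A tidy data frame with columns `design`, `sigma_c2`,
#'   `structure`, `r`, `effect`, `level`, `method`, `metric`, `value`,
#'   `mcse`; invisibly also writes files when `out` is given.  Per-cell
#'   record frames are attached as attribute `"records"`.
#' @export
mc_run_grid <- function(config, out = NULL) {
  cfg <- read_config(config)
  cells <- cfg$cells
  if (is.null(cells)) cells <- list()
  tidy <- list(); all_records <- list(); exclusions <- character()
  for (ci in seq_along(cells)) {
    cell <- utils::modifyList(cfg[setdiff(names(cfg), "cells")], cells[[ci]])
    cell <- cell_defaults(cell)
    design <- usd_design(cell$design, M = cell$M, T = cell$T, n = cell$n,
                         sigma_c2 = cell$sigma_c2, s = cell$s)
    params <- sim_params(T = cell$T, n = cell$n, mu0 = cell$mu0,
                         theta0 = cell$theta0, delta = cell$effect,
                         sigma_c2 = cell$sigma_c2, structure = cell$structure,
                         r = if (cell$structure == "ar1") cell$r else 0.8)
    rec <- mc_run_cell(design, params, reps = cell$reps, level = cell$level,
                       methods = cell$methods,
                       seed = (cell$seed + 97L * ci) %% 2147483647L,
                       nodes = cell$nodes, randomize = isTRUE(cell$randomize))
    smry <- mc_summarize(rec, params)
    key <- data.frame(design = cell$design, sigma_c2 = cell$sigma_c2,
                      structure = cell$structure,
                      r = if (cell$structure == "ar1") cell$r else NA_real_,
                      effect = cell$effect, level = cell$level,
                      stringsAsFactors = FALSE)
    tt <- smry$tests
    tidy[[length(tidy) + 1L]] <- cbind(key[rep(1, nrow(tt)), , drop = FALSE],
      data.frame(method = tt$method, metric = paste0("rejection_", tt$test),
                 value = tt$rejection_rate, mcse = tt$mcse))
    ee <- smry$estimates
    tidy[[length(tidy) + 1L]] <- cbind(key[rep(1, 2 * nrow(ee)), , drop = FALSE],
      data.frame(method = rep(ee$method, 2),
                 metric = c(paste0("bias_", ee$parameter),
                            paste0("coverage_", ee$parameter)),
                 value = c(ee$bias, ee$coverage),
                 mcse = c(ee$bias_mcse, ee$coverage_mcse)))
    all_records[[ci]] <- cbind(key[rep(1, nrow(rec)), , drop = FALSE],
                               as.data.frame(rec))
    bad <- rec[!is.na(rec$excluded), , drop = FALSE]
    if (nrow(bad))
      exclusions <- c(exclusions,
                      sprintf("cell %d (%s sigma_c2=%g %s): rep %d %s -> %s",
                              ci, cell$design, cell$sigma_c2, cell$level,
                              bad$rep, bad$method, bad$excluded))
  }
  res <- if (length(tidy)) do.call(rbind, tidy) else
    data.frame(design = character(), sigma_c2 = numeric(),
               structure = character(), r = numeric(), effect = character(),
               level = character(), method = character(), metric = character(),
               value = numeric(), mcse = numeric())
  rownames(res) <- NULL
  attr(res, "records") <- all_records
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out, "summary.csv"), row.names = FALSE)
    if (length(all_records))
      utils::write.csv(do.call(rbind, all_records),
                       file.path(out, "records.csv"), row.names = FALSE)
    writeLines(exclusions, file.path(out, "exclusions.log"))
  }
  res
}

cell_defaults <- function(cell) {
  def <- list(M = 48L, n = 50L, T = 5L, s = 3L, reps = 1000L, seed = 20221117L,
              methods = c("glmm", "gee"), mu0 = 0, theta0 = -0.4,
              structure = "exchangeable", r = 0.8, effect = "null",
              level = "aggregated", nodes = 25L, sigma_c2 = 0.2,
              design = "PGD", randomize = FALSE)
  known <- union(names(def), "design")
  unknown <- setdiff(names(cell), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  utils::modifyList(def, cell)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      return(yaml::read_yaml(config))
    return(jsonlite::fromJSON(config, simplifyDataFrame = FALSE))
  }
  stopifnot(is.list(config))
  config
}
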