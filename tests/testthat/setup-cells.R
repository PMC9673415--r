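# Shared Monte-Carlo study cells, computed once per test run and reused by
# the acceptance suite and the property tests.  Study conditions follow the
# simulation design: T = 5 periods, n = 50 subjects per cluster-period,
# M = 48 clusters (M = 192 for the large-sample recovery checks),
# mu0 = 0, theta0 = -0.4, beta_j = 0.2 (j - 3), alpha = 0.05 two-sided,
# and clusters randomly allocated to switch patterns in every replicate
# with probabilities given by the design's allocation (the defining
# random-allocation property of this design family).
# 500 replicates per cell; 9 quadrature nodes (estimates agree with 25
# nodes to 1e-4 on this problem size, see the quadrature-stability test).

acc_reps <- 500L
acc_nodes <- 9L

acc_cell <- function(variant, sigma_c2, effect, structure = "exchangeable",
                     M = 48, reps = acc_reps, seed, methods = c("glmm", "gee")) {
  design <- usd_design(variant, M = M, sigma_c2 = sigma_c2)
  params <- sim_params(sigma_c2 = sigma_c2, delta = effect,
                       structure = structure, r = 0.8)
  rec <- mc_run_cell(design, params, reps = reps, seed = seed,
                     nodes = acc_nodes, methods = methods, randomize = TRUE)
  list(records = rec, params = params, summary = mc_summarize(rec, params))
}

rejection <- function(cell, method, test = NULL) {
  tt <- cell$summary$tests
  if (is.null(test)) test <- if (method == "glmm") "wald_chisq_model" else "generalized_score"
  tt$rejection_rate[tt$method == method & tt$test == test]
}

acc <- list(
  pgd02_null  = acc_cell("PGD",  0.2, "null",   seed = 2001L),
  pgd02_lin   = acc_cell("PGD",  0.2, "linear", seed = 2002L),
  pgd08_lin   = acc_cell("PGD",  0.8, "linear", seed = 2003L),
  usdu05_lin  = acc_cell("USDu", 0.5, "linear", seed = 2004L),
  ar1_pgd02_lin = acc_cell("PGD", 0.2, "linear", structure = "ar1", seed = 2005L),
  m192_lin    = acc_cell("PGD",  0.2, "linear", M = 192, seed = 2006L)
)

# reduced-replicate cells for the design-ordering properties (sigma_c2 = 0.2,
# linear effect); PGD and USDu orderings reuse the 500-replicate cells
acc_order <- lapply(list(DSDu = "DSDu", DSDo = "DSDo", USDu = "USDu",
                         USDo1 = "USDo1", USDo2 = "USDo2"),
                    function(v) acc_cell(v, 0.2, "linear", reps = 150L,
                                         seed = 2007L))
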