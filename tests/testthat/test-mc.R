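test_that("Monte-Carlo standard errors of proportions follow the closed form", {
  expect_equal(mcse_prop(0.05, 1000), sqrt(0.05 * 0.95 / 1000))
  expect_equal(mcse_prop(0.05, 1000), 0.007, tolerance = 0.01)
  expect_equal(mcse_prop(0.5, 1000), sqrt(0.25 / 1000))
  expect_equal(mcse_prop(0.5, 1000), 0.016, tolerance = 0.02)
  expect_equal(mcse_prop(0, 500), 0)
})

test_that("cells are deterministic given the master seed and extensible in reps", {
  d <- usd_design("PGD", M = 8, T = 5, n = 10)
  p <- sim_params(n = 10, sigma_c2 = 0.2, delta = "linear")
  r1 <- mc_run_cell(d, p, reps = 3, seed = 99, nodes = 5)
  r2 <- mc_run_cell(d, p, reps = 3, seed = 99, nodes = 5)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  # the first replicates of a longer run are the same replicates
  r5 <- mc_run_cell(d, p, reps = 5, seed = 99, nodes = 5)
  expect_equal(as.data.frame(r5)[seq_len(nrow(r1)), ], as.data.frame(r1),
               ignore_attr = TRUE)
})

test_that("non-identifiable cells are refused up front", {
  d <- usd_design("custom", T = 5, n = 10, allocation = c(0, 2, 2, 2, 2, 0))
  p <- sim_params(n = 10, sigma_c2 = 0.2)
  expect_error(mc_run_cell(d, p, reps = 2, seed = 1), "not identifiable")
})

test_that("true reference-coded values marginalize correctly", {
  p <- sim_params(sigma_c2 = 0.2, delta = "linear")
  ts <- true_values(p, "subject_specific")
  tm <- true_values(p, "marginal")
  expect_equal(unname(ts["theta"]), -0.4)
  expect_equal(unname(ts["delta5"]), -0.2)
  expect_equal(unname(ts["beta1"]), -0.4)
  expect_equal(unname(ts["sigma_c2"]), 0.2)
  expect_equal(unname(tm["theta"]), -0.4 / sqrt(1.2))
  expect_equal(unname(tm[setdiff(names(tm), "sigma_c2")]),
               unname(ts[setdiff(names(tm), "sigma_c2")]) / sqrt(1.2))
})

test_that("summaries report exact recovery when estimates equal the truth", {
  p <- sim_params(sigma_c2 = 0.2, delta = "null")
  truth <- true_values(p, "subject_specific")
  pnames <- setdiff(names(truth), "sigma_c2")
  rec <- do.call(rbind, lapply(1:4, function(k) {
    row <- usdpower:::mc_row_skeleton(k, "glmm", pnames)
    row$converged <- TRUE
    row$p_value <- 0.5
    row$sigma_c2 <- 0.2
    for (nm in pnames) {
      row[[paste0("est_", nm)]] <- unname(truth[nm])
      row[[paste0("se_", nm)]] <- 0.5
    }
    row
  }))
  s <- mc_summarize(rec, p)
  expect_true(all(abs(s$estimates$bias) < 1e-12))
  expect_true(all(s$estimates$coverage[s$estimates$parameter != "sigma_c2"] == 1))
  expect_equal(s$tests$rejection_rate, 0)
  expect_equal(s$tests$mcse, 0)
})

test_that("summaries error when every replicate was excluded", {
  p <- sim_params(sigma_c2 = 0.2)
  rec <- usdpower:::mc_row_skeleton(1, "glmm",
                                    setdiff(names(true_values(p)), "sigma_c2"))
  rec$excluded <- "non_convergence"
  expect_error(mc_summarize(rec, p), "excluded")
})

test_that("the grid runner produces the tidy layout and is idempotent", {
  cfg <- list(seed = 5, reps = 2, M = 12, n = 10, nodes = 5,
              cells = list(list(design = "PGD", sigma_c2 = 0.2, effect = "null"),
                           list(design = "USDu", sigma_c2 = 0.2, effect = "linear",
                                methods = "gee")))
  res1 <- mc_run_grid(cfg)
  res2 <- mc_run_grid(cfg)
  expect_equal(res1, res2)
  expect_identical(names(res1), c("design", "sigma_c2", "structure", "r",
                                  "effect", "level", "method", "metric",
                                  "value", "mcse"))
  expect_setequal(unique(res1$design), c("PGD", "USDu"))
  expect_true(any(grepl("^rejection_", res1$metric)))
  expect_true(any(grepl("^bias_", res1$metric)))
  # empty cell list is allowed
  empty <- mc_run_grid(list(cells = list()))
  expect_identical(nrow(empty), 0L)
  # unknown keys are rejected at parse time
  expect_error(mc_run_grid(list(cells = list(list(design = "PGD", foo = 1)))),
               "unknown configuration keys")
})

test_that("grid configurations round-trip through YAML and JSON files", {
  cfg <- list(seed = 5, reps = 2, M = 12, n = 10, nodes = 5,
              cells = list(list(design = "PGD", sigma_c2 = 0.2, effect = "null",
                                methods = "gee")))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  out <- tempfile("res")
  ry <- mc_run_grid(yml, out = out)
  rj <- mc_run_grid(jsn)
  expect_equal(ry, rj)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "records.csv")))
  back <- read.csv(file.path(out, "summary.csv"))
  expect_equal(nrow(back), nrow(ry))
})

test_that("the command-line interface prints allocations and writes results", {
  txt <- capture.output(usd_cli(c("design", "--variant", "USDo1", "--M", "48",
                                  "--T", "5", "--n", "50", "--sigma2", "0.2")))
  expect_identical(txt[1], "pattern,clusters")
  expect_identical(txt[2:7], c("0,6", "1,9", "2,9", "3,9", "4,9", "5,6"))
  expect_identical(txt[8], "identifiable,true")
  out <- tempfile("cliout")
  capture.output(usd_cli(c("run", "--design", "PGD", "--sigma2", "0.2",
                           "--effect", "null", "--M", "12", "--n", "10",
                           "--reps", "2", "--seed", "4", "--out", out)))
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_error(usd_cli(c("frobnicate")), "unknown subcommand")
})

test_that("aggregated and individual-level analyses agree on the same replicates", {
  d <- usd_design("PGD", M = 48, sigma_c2 = 0.2)
  p <- sim_params(sigma_c2 = 0.2, delta = "linear")
  ra <- mc_run_cell(d, p, reps = 25, seed = 2401, nodes = 9, level = "aggregated")
  ri <- mc_run_cell(d, p, reps = 25, seed = 2401, nodes = 9, level = "individual")
  pa_glmm <- ra$p_value[ra$method == "glmm"]
  pi_glmm <- ri$p_value[ri$method == "glmm"]
  # GLMM: the cluster-period count is sufficient, so the fits are identical
  expect_equal(pa_glmm, pi_glmm, tolerance = 1e-8)
  # GEE: the two levels give the same rejection decisions up to MC noise
  ra_gee <- mean(ra$p_value[ra$method == "gee"] < 0.05)
  ri_gee <- mean(ri$p_value[ri$method == "gee"] < 0.05)
  expect_lt(abs(ra_gee - ri_gee),
            2 * sqrt(mcse_prop(max(ra_gee, 0.1), 25)^2 + mcse_prop(max(ri_gee, 0.1), 25)^2) + 0.08)
})
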