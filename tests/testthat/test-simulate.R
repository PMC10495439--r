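test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 17, cohort_n = 200, n_decoy_genes = 4,
                    samples_per_cancer = 10)
  expect_identical(simulate_trial_table(cfg), simulate_trial_table(cfg))
  expect_identical(simulate_expression_panel(cfg)$panel$matrix,
                   simulate_expression_panel(cfg)$panel$matrix)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$cohort$clinical, b$cohort$clinical)
  expect_identical(a$cohort$expr, b$cohort$expr)
  # a different seed changes the draw
  cfg2 <- sim_config(seed = 18, cohort_n = 200, n_decoy_genes = 4,
                     samples_per_cancer = 10)
  expect_false(identical(simulate_cohort(cfg2)$cohort$clinical$os_time,
                         a$cohort$clinical$os_time))
})

test_that("noise-free panels invert the planted predictiveness line exactly", {
  cfg <- sim_config(seed = 23, median_noise_sd = 0, within_sd = 0,
                    n_decoy_genes = 5, samples_per_cancer = 5)
  pan <- simulate_expression_panel(cfg)
  med <- median_profile(pan$panel, "MOD1")[, "MOD1"]
  m <- fit_ps_model(med, pan$truth$hrd, gene = "MOD1")
  expect_equal(m$slope, -0.76, tolerance = 1e-9)
  expect_equal(m$intercept, 2.81, tolerance = 1e-9)
  expect_equal(m$loocv_rmse, 0, tolerance = 1e-8)

  # and the screen sees a perfect rank correlation for the planted gene
  pred <- structure(
    data.frame(cancer = names(pan$truth$hrd), endpoint = "OS",
               hrd = unname(pan$truth$hrd)),
    class = c("cancer_predictiveness", "data.frame"))
  scr <- cross_cancer_screen(median_profile(pan$panel), pred, pred)
  expect_equal(abs(scr$rho_os[scr$gene == "MOD1"]), 1)
  expect_true(scr$passes[scr$gene == "MOD1"])
})

test_that("large noise-free trials recover the planted HRD", {
  hits <- vapply(1:6, function(s) {
    cfg <- sim_config(seed = 300 + s, tau = 0, per_arm_n = 10000)
    tt <- simulate_trial_table(cfg)
    pred <- compute_predictiveness(tt$trials, "OS")
    max(abs(pred$hrd[match(names(tt$truth$hrd), pred$cancer)] -
              tt$truth$hrd)) < 0.05
  }, logical(1))
  expect_true(all(hits))
})

test_that("null trials give approximately uniform interaction p-values", {
  ps <- unlist(lapply(1:40, function(s) {
    cfg <- sim_config(seed = 400 + s, preset = "null",
                      hrd_range = c(0, 0), trials_per_cancer = 3,
                      n_cancers = 5)
    compute_predictiveness(simulate_trial_table(cfg)$trials, "OS")$p_interaction
  }))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("cohort censoring hits its target and the null plants nothing", {
  cfg <- sim_config(seed = 29, preset = "null", cohort_n = 2000)
  sim <- simulate_cohort(cfg)
  expect_lt(abs(sim$truth$realized_censor_os - cfg$censor_rate), 0.03)
  expect_lt(abs(sim$truth$realized_censor_pfs - cfg$censor_rate), 0.03)
  # times positive, events 0/1, IHC within range
  cl <- sim$cohort$clinical
  expect_true(all(cl$os_time > 0))
  expect_true(all(cl$pdl1_ihc >= 0 & cl$pdl1_ihc <= 100))
})

test_that("single-arm interaction estimate is consistent for the planted d", {
  cfg <- sim_config(seed = 37, cohort_n = 3000, n_decoy_genes = 2)
  sim <- simulate_cohort(cfg)
  treated <- subset_cohort(
    sim$cohort,
    sim$cohort$clinical$patient_id[sim$cohort$clinical$arm == "ICI"])
  res <- rank_interactions(treated, "CD274", "MOD1", "OS")
  # within the ICI arm the interaction is bPV + bTPV = 0.8
  d_true <- unname(cfg$coef["bPV"] + cfg$coef["bTPV"])
  expect_lt(abs(res$d - d_true), 3 * res$se_d)
})

test_that("truth manifests survive JSON serialization", {
  cfg <- sim_config(seed = 41, samples_per_cancer = 5, n_decoy_genes = 2)
  tt <- simulate_trial_table(cfg)
  path <- tempfile(fileext = ".json")
  write_truth_json(tt$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$hrd), unlist(tt$truth$hrd), tolerance = 1e-12)
  expect_equal(back$seed, tt$truth$seed)
  expect_equal(back$se_trial, tt$truth$se_trial, tolerance = 1e-12)
})

test_that("config validation rejects impossible study conditions", {
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_cancers = 0), "counts")
  expect_error(sim_config(coef = c(bT = 0)), "coef must name")
})
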