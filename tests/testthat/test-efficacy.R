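test_that("PD-L1 strata respect the clinical cutoff boundaries", {
  ch <- make_test_cohort(n_per_arm = 2, seed = 111)
  ch$clinical$pdl1_ihc <- c(0, 1, 49, 50)
  s3 <- stratify_pdl1(ch, "IHC3")
  expect_identical(as.character(unname(s3)), c("<1", "1-50", "1-50", ">=50"))
  s2 <- stratify_pdl1(ch, "IHC2")
  expect_identical(as.character(unname(s2)), c("<1", ">=1", ">=1", ">=1"))
  ch$clinical$pdl1_ihc <- c(4.9, 5, 60, 0)
  s2a <- stratify_pdl1(ch, "IHC2_ALT")
  expect_identical(as.character(unname(s2a)), c("<5", ">=5", ">=5", "<5"))

  # RNA median split on the reference population
  ch$expr["CD274", ch$clinical$patient_id] <- c(1, 2, 3, 4)
  r2 <- stratify_pdl1(ch, "RNA2", reference = "ITT")
  expect_identical(as.character(unname(r2)), c("LOW", "LOW", "HIGH", "HIGH"))

  # missing IHC values are excluded and counted
  ch$clinical$pdl1_ihc <- NA_real_
  s_na <- stratify_pdl1(ch, "IHC2")
  expect_length(s_na, 0)
  expect_equal(attr(s_na, "n_excluded"), 4)
})

test_that("RNA3 uses reference-population quartiles", {
  ch <- make_test_cohort(n_per_arm = 20, seed = 112)
  r3 <- stratify_pdl1(ch, "RNA3", reference = "ITT")
  v <- ch$expr["CD274", names(r3)]
  qs <- quantile(v, c(0.25, 0.75))
  expect_true(all(v[r3 == "LOW"] < qs[1]))
  expect_true(all(v[r3 == "HIGH"] >= qs[2]))
  expect_true(all(v[r3 == "INT"] >= qs[1] & v[r3 == "INT"] < qs[2]))
})

test_that("mirrored arms produce null ICI-vs-chemo rows", {
  ch <- make_test_cohort(n_per_arm = 60, seed = 121, mirror = TRUE)
  strat <- stratify_pdl1(ch, "IHC2", reference = "ITT")
  grid <- efficacy_grid(ch, NULL, strat, "ICI_vs_CHEMO_within_stratum",
                        endpoints = c("OS", "ORR"), groups = "ALL")
  surv <- grid[grid$endpoint == "OS" & grid$estimable, ]
  expect_true(all(abs(log(surv$hr)) < 1e-6))
  orr <- grid[grid$endpoint == "ORR" & grid$estimable, ]
  expect_equal(orr$fisher_p, rep(1, nrow(orr)), tolerance = 1e-9)
  expect_true(all(orr$orr_a == orr$orr_b))
})

test_that("grid rows conserve patients and ORR estimates sit inside their CIs", {
  ch <- make_test_cohort(n_per_arm = 80, seed = 131)
  m <- fit_ps_model(setNames(1:4, paste0("c", 1:4)),
                    setNames(-0.5 * (1:4) + 2, paste0("c", 1:4)),
                    gene = "MOD1")
  sc <- score_and_split(ch, m)
  strat <- stratify_pdl1(ch, "IHC3")
  grid <- efficacy_grid(ch, sc, strat, "ICI_vs_CHEMO_within_stratum",
                        endpoints = "ORR", groups = c("PH", "PL"))
  # conservation: per group, stratum cells partition the analyzable patients
  for (g in c("PH", "PL")) {
    ids <- sc$patient_id[sc$group == g]
    analyzable <- sum(names(strat) %in% ids)
    expect_equal(sum(grid$n_a[grid$group == g] + grid$n_b[grid$group == g]),
                 analyzable)
  }
  est <- grid[grid$estimable, ]
  expect_true(all(est$orr_a >= est$orr_a_lo & est$orr_a <= est$orr_a_hi))
  expect_true(all(est$orr_b >= est$orr_b_lo & est$orr_b <= est$orr_b_hi))

  # empty cells surface as estimable = FALSE, keeping the grid rectangular
  expect_equal(nrow(grid), 2 * nlevels(strat))
})

test_that("swapping stratum labels inverts the hazard ratio", {
  ch <- make_test_cohort(n_per_arm = 80, seed = 141)
  strat <- stratify_pdl1(ch, "IHC2")
  g1 <- efficacy_grid(ch, NULL, strat, "POS_vs_NEG_within_ICI",
                      endpoints = "OS", groups = "ALL")
  # same patient labels, reversed reference level
  swapped <- factor(as.character(strat), levels = c(">=1", "<1"))
  names(swapped) <- names(strat)
  attr(swapped, "n_excluded") <- attr(strat, "n_excluded")
  g2 <- efficacy_grid(ch, NULL, swapped, "POS_vs_NEG_within_ICI",
                      endpoints = "OS", groups = "ALL")
  expect_equal(log(g1$hr), -log(g2$hr), tolerance = 1e-9)
})

test_that("robustness subgrouping partitions the cohort at the stated cutoffs", {
  ch <- make_test_cohort(n_per_arm = 80, seed = 151)
  ch$clinical$tmb[1:2] <- c(15.9, 16.0)   # boundary: >= 16 is high
  m <- fit_ps_model(setNames(1:4, paste0("c", 1:4)),
                    setNames(-0.5 * (1:4) + 2, paste0("c", 1:4)),
                    gene = "MOD1")
  sc <- score_and_split(ch, m)
  grids <- robustness_subgroups(ch, sc, "TMB16", strata_mode = "IHC2",
                                comparison = "POS_vs_NEG_within_ICI",
                                endpoints = "ORR", groups = "ALL")
  lev <- attr(grids, "levels")
  expect_identical(unname(lev[1:2]), c("TMB_LOW", "TMB_HIGH"))
  expect_setequal(names(grids), c("TMB_HIGH", "TMB_LOW"))
  # levels partition the patients with a TMB value
  expect_equal(sum(!is.na(lev)), nrow(ch$clinical))

  grids_tnb <- robustness_subgroups(ch, sc, "TNB_MEDIAN",
                                    strata_mode = "IHC2",
                                    comparison = "POS_vs_NEG_within_ICI",
                                    endpoints = "ORR", groups = "ALL")
  lev_tnb <- attr(grids_tnb, "levels")
  med <- median(ch$clinical$tnb)
  expect_true(all((ch$clinical$tnb >= med) ==
                    (lev_tnb == "TNB_HIGH")))

  ch$clinical$tmb <- NA_real_
  expect_error(robustness_subgroups(ch, sc, "TMB16"), "tmb missing")
})
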