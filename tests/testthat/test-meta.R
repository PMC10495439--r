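test_that("log-HR back-calculation reproduces CIs and rejects bad input", {
  e <- log_hr_from_ci(1.0, 0.5, 2.0)
  expect_equal(e$log_hr, 0)
  expect_equal(e$se_log_hr, log(4) / (2 * 1.959964))

  # a published asymmetric CI is reproduced within rounding when the
  # back-calculated SE is pushed through exp(log_hr +/- z * se)
  e2 <- log_hr_from_ci(0.59, 0.36, 0.98)
  expect_equal(exp(e2$log_hr - 1.959964 * e2$se_log_hr), 0.36,
               tolerance = 0.01)
  expect_equal(exp(e2$log_hr + 1.959964 * e2$se_log_hr), 0.98,
               tolerance = 0.01)

  expect_error(log_hr_from_ci(2.0, 2.0, 2.0), "degenerate")
  expect_error(log_hr_from_ci(-1, 0.5, 2), "positive")
  expect_error(log_hr_from_ci(1, 2, 0.5), "ci_low")
  expect_error(log_hr_from_ci(3, 0.5, 2), "inside")
})

test_that("DerSimonian-Laird pooling matches frozen hand-derived values", {
  est <- function(y, se) structure(list(log_hr = y, se_log_hr = se),
                                   class = "hr_estimate")

  # k = 1 is the identity
  p1 <- pool_random_effects(list(est(-0.5, 0.2)))
  expect_equal(p1$log_hr, -0.5)
  expect_equal(p1$se, 0.2)
  expect_equal(p1$I2, 0)
  expect_equal(p1$Q, 0)

  # zero heterogeneity: pooled se = se / sqrt(k)
  p2 <- pool_random_effects(list(est(-0.5, 0.2), est(-0.5, 0.2)))
  expect_equal(p2$log_hr, -0.5)
  expect_equal(p2$se, 0.2 / sqrt(2))
  expect_equal(p2$tau2, 0)
  expect_equal(p2$I2, 0)

  # two-study fixture, frozen from a hand execution of the DL equations
  # (w = 25, 16; fixed mean -19.4/41; Q, tau2, random-effects mean follow)
  p3 <- pool_random_effects(list(est(-0.2, 0.2), est(-0.9, 0.25)))
  expect_equal(p3$log_hr, -0.5339285714, tolerance = 1e-9)
  expect_equal(p3$se, 0.3496308184, tolerance = 1e-9)
  expect_equal(p3$Q, 4.7804878049, tolerance = 1e-9)
  expect_equal(p3$tau2, 0.19375, tolerance = 1e-9)
  expect_equal(p3$I2, 79.0816326531, tolerance = 1e-7)

  expect_error(pool_random_effects(list()), "non-empty")
})

test_that("DL pooling agrees with an independent meta-analysis engine", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(2:6, 1)
    y <- rnorm(k, -0.3, 0.4)
    se <- runif(k, 0.1, 0.5)
    mine <- pool_random_effects(data.frame(log_hr = y, se_log_hr = se))
    ref <- metafor::rma(yi = y, sei = se, method = "DL")
    expect_equal(mine$log_hr, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mine$se, ref$se, tolerance = 1e-10)
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(mine$I2, ref$I2, tolerance = 1e-6)
  }
})

test_that("pooled estimate stays within inputs and heterogeneity is bounded", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(1:6, 1)
    y <- rnorm(k, 0, 0.6)
    se <- runif(k, 0.05, 0.5)
    p <- pool_random_effects(data.frame(log_hr = y, se_log_hr = se))
    expect_gte(p$log_hr, min(y) - 1e-12)
    expect_lte(p$log_hr, max(y) + 1e-12)
    expect_gte(p$I2, 0); expect_lte(p$I2, 100)
    expect_gte(p$tau2, 0)
    expect_equal(p$hr, exp(p$log_hr))
  }
})

test_that("subgroup-difference test matches the normal oracle and is antisymmetric", {
  mk <- function(y, se) {
    p <- pool_random_effects(data.frame(log_hr = y, se_log_hr = se))
    p
  }
  a <- mk(-0.5, 0.2); b <- mk(0.0, 0.2)
  same <- subgroup_difference_test(a, a)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  r <- subgroup_difference_test(a, b)
  expect_equal(r$z, -0.5 / sqrt(0.08), tolerance = 1e-9)
  expect_equal(r$p, 2 * pnorm(-abs(-0.5 / sqrt(0.08))), tolerance = 1e-12)
  expect_equal(r$z, -1.7678, tolerance = 1e-4)
  expect_equal(r$p, 0.0771, tolerance = 1e-3)

  set.seed(11)
  for (rep in 1:10) {
    x <- mk(rnorm(1), runif(1, 0.1, 0.4))
    y <- mk(rnorm(1), runif(1, 0.1, 0.4))
    f <- subgroup_difference_test(x, y)
    g <- subgroup_difference_test(y, x)
    expect_equal(f$z, -g$z)
    expect_equal(f$p, g$p)
  }
})

make_trials <- function(rows) {
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(trial_id = r$id, cancer = r$cancer, endpoint = "OS",
               subgroup = r$subgroup, hr = r$hr,
               ci_low = r$hr * 0.7, ci_high = r$hr / 0.7,
               stringsAsFactors = FALSE)
  }))
}

test_that("HRD arithmetic, label antisymmetry and subgroup dropping", {
  tr <- make_trials(list(
    list(id = "t1", cancer = "crc", subgroup = "BM_POS", hr = 0.8),
    list(id = "t1", cancer = "crc", subgroup = "BM_NEG", hr = 1.2),
    list(id = "t2", cancer = "mel", subgroup = "BM_POS", hr = 0.9)))
  res <- compute_predictiveness(tr, "OS")
  expect_equal(nrow(res), 1L)
  expect_equal(res$hrd, 0.4, tolerance = 1e-9)
  expect_equal(res$hrd, res$hr_neg - res$hr_pos, tolerance = 1e-12)
  # melanoma lacks the negative subgroup and must be dropped, not silently
  expect_identical(attr(res, "dropped"), "mel")
  expect_setequal(c(res$cancer, attr(res, "dropped")), unique(tr$cancer))

  # swapping the subgroup labels negates HRD
  tr_swap <- tr[tr$cancer == "crc", ]
  tr_swap$subgroup <- ifelse(tr_swap$subgroup == "BM_POS", "BM_NEG", "BM_POS")
  res_swap <- compute_predictiveness(tr_swap, "OS")
  expect_equal(res_swap$hrd, -res$hrd, tolerance = 1e-12)

  expect_error(compute_predictiveness(tr[0, ], "OS"), "non-empty")
})

test_that("cross-endpoint predictiveness correlation is rank-based", {
  mk <- function(hrd) {
    structure(data.frame(cancer = paste0("c", seq_along(hrd)),
                         endpoint = "OS", hrd = hrd),
              class = c("cancer_predictiveness", "data.frame"))
  }
  a <- mk(c(0.1, 0.4, 0.7, 1.0))
  expect_equal(predictiveness_correlation(a, a)$rho, 1)
  b <- mk(rev(c(0.1, 0.4, 0.7, 1.0)))
  b$cancer <- a$cancer
  b$hrd <- rev(a$hrd)
  expect_equal(predictiveness_correlation(a, b)$rho, -1)
  expect_error(predictiveness_correlation(a[1:2, ], a[1:2, ]), "at least 3")
})
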