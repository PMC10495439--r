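test_that("quantile normalization reproduces the hand-worked 2x2 example", {
  m <- matrix(c(1, 3, 4, 2), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  qn <- normalize_expression(m, center = FALSE)
  # sorted columns (1,3) and (2,4) average to (1.5, 3.5); reassign by rank
  expect_equal(unname(qn), matrix(c(1.5, 3.5, 3.5, 1.5), 2),
               tolerance = 1e-12)
  cn <- normalize_expression(m)
  expect_true(all(abs(rowMeans(cn)) < 1e-12))
})

test_that("quantile step equalizes column multisets and is idempotent", {
  set.seed(161)
  m <- matrix(rnorm(200, 5, 2), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  qn <- normalize_expression(m, center = FALSE)
  ref <- sort(qn[, 1])
  for (j in 2:ncol(qn)) expect_equal(sort(qn[, j]), ref, tolerance = 1e-12,
                                     ignore_attr = TRUE)
  # second application changes nothing
  qn2 <- normalize_expression(qn, center = FALSE)
  expect_equal(qn2, qn, tolerance = 1e-12)
  # identical columns: the quantile step is the identity
  mc <- matrix(rep(c(1, 5, 2), 4), 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(normalize_expression(mc, center = FALSE), mc,
               tolerance = 1e-12)
  expect_warning(normalize_expression(m[, 1, drop = FALSE]), "single sample")
})

test_that("signature scores are set means, linear, and coverage-aware", {
  m <- matrix(c(2, 4, 6, 1, 3, 5), 3,
              dimnames = list(c("CD8A", "CD8B", "OTHER"), c("s1", "s2")))
  sets <- list(CD8 = c("CD8A", "CD8B"), GHOST = c("NOPE1", "NOPE2"),
               PARTIAL = c("OTHER", "MISSING"))
  sc <- signature_scores(m, sets)
  expect_equal(unname(sc[, "CD8"]), c(3, 2))
  expect_true(all(is.na(sc[, "GHOST"])))
  cov <- attr(sc, "coverage")
  expect_equal(unname(cov[c("CD8", "GHOST", "PARTIAL")]), c(1, 0, 0.5))
  # constant zero matrix scores zero
  z <- m; z[] <- 0
  expect_true(all(signature_scores(z, sets["CD8"]) == 0))
  # linearity over the same genes
  set.seed(171)
  a <- m; a[] <- rnorm(6); b <- m; b[] <- rnorm(6)
  expect_equal(signature_scores(a + b, sets["CD8"]),
               signature_scores(a, sets["CD8"]) +
                 signature_scores(b, sets["CD8"]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # random matrix equals the direct row-subset mean oracle
  expect_equal(unname(signature_scores(a, sets["CD8"])[, 1]),
               unname(colMeans(a[c("CD8A", "CD8B"), ])), tolerance = 1e-12)
})

test_that("GMT round-trip through the standard parser", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tCD8A\tCD8B", "SET_B\tdesc\tGZMB\tPRF1\tIFNG"),
             path)
  sets <- read_gene_sets(path)
  expect_identical(sets$SET_A, c("CD8A", "CD8B"))
  expect_length(sets$SET_B, 3)
})

planted_clouds <- function(k, n_per = 12, sep = 10, sd = 0.1, seed = 181) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * 5, mean = i * sep, sd = sd), n_per, 5)))
  rownames(x) <- paste0("s", seq_len(k * n_per))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

test_that("consensus clustering recovers planted structure deterministically", {
  # n is kept large enough that the delta-area heuristic is not inflated
  # by unstable small-sample splits
  pc <- planted_clouds(2, n_per = 40)
  cc <- consensus_cluster(pc$x, maxK = 4, reps = 100, seed = 5,
                          distance = "euclidean")
  cm <- cc$consensus[["2"]]
  within <- cm[pc$labels == 1, pc$labels == 1]
  between <- cm[pc$labels == 1, pc$labels == 2]
  expect_gt(min(within), 0.99)
  expect_lt(max(between), 0.01)
  expect_equal(cc$chosen_k, 2L)
  expect_true(all(vapply(cc$consensus, isSymmetric, logical(1))))
  expect_true(all(vapply(cc$consensus,
                         function(m) all(diag(m) == 1), logical(1))))
  expect_true(all(vapply(cc$consensus,
                         function(m) all(m >= 0 & m <= 1), logical(1))))

  p3 <- planted_clouds(3, n_per = 25)
  cc3 <- consensus_cluster(p3$x, maxK = 4, reps = 100, seed = 5,
                           distance = "euclidean")
  expect_equal(adjusted_rand(cc3$assignments[["3"]], p3$labels), 1)
  expect_equal(cc3$chosen_k, 3L)

  # bit-identical reruns under the same seed
  cc_again <- consensus_cluster(pc$x, maxK = 4, reps = 100, seed = 5,
                                distance = "euclidean")
  expect_identical(cc, cc_again)
})

test_that("full-resampling consensus is binary under deterministic linkage", {
  pc <- planted_clouds(2, n_per = 8)
  cc <- consensus_cluster(pc$x, maxK = 3, reps = 25, p_item = 1, seed = 9,
                          distance = "euclidean")
  for (cm in cc$consensus)
    expect_true(all(cm %in% c(0, 1)))
})

make_fractions <- function(n_per = 30, lymph_shift = 0.25, seed = 191) {
  set.seed(seed)
  n <- 2 * n_per
  lymph <- c(rep(0.15 + lymph_shift, n_per), rep(0.15, n_per)) +
    rnorm(n, 0, 0.02)
  stroma <- 0.2 - 0.1 * (lymph > 0.25) + rnorm(n, 0, 0.02)
  lymph <- pmax(0.01, lymph); stroma <- pmax(0.01, stroma)
  cf <- cbind(B_cells = lymph * 0.3, CD8_T_cells = lymph * 0.5,
              NK_cells = lymph * 0.2,
              Endothelium = stroma * 0.4, Fibroblasts = stroma * 0.6,
              Macrophages = 0.1)
  cf <- cbind(cf, Other = pmax(0, 1 - rowSums(cf)))
  rownames(cf) <- paste0("s", seq_len(n))
  list(cf = cf, truth = rep(c("ImmuneEnriched", "NonImmune"), each = n_per))
}

test_that("immune-subtype labels orient to the lymphocyte-rich cluster", {
  fx <- make_fractions()
  lab <- assign_immune_subtype(fx$cf, reps = 100, seed = 3)
  expect_identical(as.vector(lab), fx$truth)
  # orientation is invariant to row order
  perm <- sample(nrow(fx$cf))
  lab2 <- assign_immune_subtype(fx$cf[perm, ], reps = 100, seed = 3)
  expect_identical(as.vector(lab2[rownames(fx$cf)]), fx$truth)
  expect_error(assign_immune_subtype(fx$cf[, c("Macrophages", "Other")],
                                     reps = 10),
               "lymphocyte")
})

test_that("stromal fractions separate groups with a planted shift", {
  set.seed(201)
  n <- 150
  base <- matrix(runif(2 * n * 2, 0.05, 0.15), 2 * n, 2,
                 dimnames = list(NULL, c("Endothelium", "Fibroblasts")))
  base[seq_len(n), ] <- base[seq_len(n), ] + 0.05  # +0.1 stromal total
  st <- stromal_fraction(base)
  expect_equal(st, base[, 1] + base[, 2])
  p <- group_compare(st, rep(c("PL", "PH"), each = n))$p
  expect_lt(p, 0.05)
  expect_error(stromal_fraction(base[, 1, drop = FALSE]), "Fibroblasts")
})
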