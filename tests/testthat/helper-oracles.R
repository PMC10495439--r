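# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Two-sided Fisher p by exact-integer enumeration over all tables with the
# observed margins: the hypergeometric numerators C(r1, x) * C(r2, k - x)
# share one denominator, so table probabilities compare exactly in integer
# arithmetic (numerators stay below 2^53 for totals <= 24).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  if (r1 == 0 || r2 == 0 || k == 0 || b + d == 0) return(1)
  xs <- max(0, k - r2):min(k, r1)
  num <- choose(r1, xs) * choose(r2, k - xs)
  num_obs <- choose(r1, a) * choose(r2, k - a)
  sum(num[num <= num_obs]) / choose(r1 + r2, k)
}

# Newton-Raphson on the Cox partial likelihood for untied event times
# (with no ties the Efron and Breslow corrections coincide with the plain
# partial likelihood).
cox_newton_oracle <- function(time, event, X, tol = 1e-10, maxit = 50) {
  X <- as.matrix(X)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  X <- X[ord, , drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p)
  H <- NULL
  for (it in seq_len(maxit)) {
    w <- as.vector(exp(X %*% beta))
    S0 <- rev(cumsum(rev(w)))
    grad <- rep(0, p); H <- matrix(0, p, p)
    for (i in which(event == 1)) {
      idx <- i:n
      S1 <- colSums(X[idx, , drop = FALSE] * w[idx])
      xbar <- S1 / S0[i]
      grad <- grad + X[i, ] - xbar
      S2 <- crossprod(X[idx, , drop = FALSE] * sqrt(w[idx]))
      H <- H + S2 / S0[i] - tcrossprod(xbar)
    }
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coef = as.vector(beta), se = sqrt(diag(solve(H))))
}

# adjusted Rand index between two partitions
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small two-arm cohort builder for efficacy tests: each arm gets the same
# survival/response data when mirror = TRUE
make_test_cohort <- function(n_per_arm = 60, seed = 42, mirror = FALSE) {
  set.seed(seed)
  n <- 2 * n_per_arm
  base_time <- rexp(n_per_arm, 0.08)
  base_event <- rbinom(n_per_arm, 1, 0.8)
  base_resp <- sample(c("CR", "PR", "SD", "PD", "NE"), n_per_arm, TRUE,
                      prob = c(0.05, 0.2, 0.3, 0.4, 0.05))
  if (mirror) {
    os_time <- rep(base_time, 2); os_event <- rep(base_event, 2)
    response <- rep(base_resp, 2)
  } else {
    os_time <- rexp(n, 0.08); os_event <- rbinom(n, 1, 0.8)
    response <- sample(c("CR", "PR", "SD", "PD", "NE"), n, TRUE,
                       prob = c(0.05, 0.2, 0.3, 0.4, 0.05))
  }
  ihc <- if (mirror) rep(runif(n_per_arm, 0, 100), 2) else runif(n, 0, 100)
  clinical <- data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    arm = rep(c("ICI", "CHEMO"), each = n_per_arm),
    os_time = os_time, os_event = os_event,
    pfs_time = os_time, pfs_event = os_event,
    response = response, pdl1_ihc = ihc,
    tmb = runif(n, 0, 40), tnb = runif(n, 0, 10),
    stringsAsFactors = FALSE)
  expr_row <- if (mirror) rep(rnorm(n_per_arm, 2, 1), 2) else rnorm(n, 2, 1)
  expr <- rbind(CD274 = expr_row,
                MOD1 = if (mirror) rep(rnorm(n_per_arm, 2, 1), 2) else
                  rnorm(n, 2, 1))
  colnames(expr) <- clinical$patient_id
  ici_cohort(clinical, expr)
}
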