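#' Back-calculate a log hazard-ratio estimate from a published HR and 95% CI
#'
#' Published subgroup analyses report a hazard ratio with its 95% confidence
#' interval; pooling requires the estimate on the log scale with a standard
#' error. The SE is recovered from the CI width as
#' \code{(log(ci_high) - log(ci_low)) / (2 * 1.959964)}.
#'
#' @param hr Hazard ratio (positive).
#' @param ci_low,ci_high Bounds of the 95\% confidence interval (positive,
#'   with \code{ci_low <= hr <= ci_high} and \code{ci_low < ci_high}).
#' @param n Optional number of patients behind the estimate.
#' @return An object of class \code{"hr_estimate"}: a list with elements
#'   \code{hr}, \code{ci_low}, \code{ci_high}, \code{log_hr}, \code{se_log_hr}
#'   and \code{n}.
#' @examples
#' log_hr_from_ci(1.0, 0.5, 2.0)   # se = log(4)/3.919928
#' @export
log_hr_from_ci <- function(hr, ci_low, ci_high, n = NA_integer_) {
  .assert(is.numeric(hr) && is.numeric(ci_low) && is.numeric(ci_high) &&
            length(hr) == 1L && length(ci_low) == 1L && length(ci_high) == 1L,
          "hr, ci_low, ci_high must be scalar numerics")
  .assert(is.finite(hr) && is.finite(ci_low) && is.finite(ci_high),
          "hr, ci_low, ci_high must be finite")
  .assert(hr > 0 && ci_low > 0 && ci_high > 0,
          "hazard ratio and CI bounds must be positive")
  .assert(ci_low <= ci_high, "ci_low must not exceed ci_high")
  .assert(ci_low <= hr && hr <= ci_high,
          "hr must lie inside [ci_low, ci_high]")
  se <- (log(ci_high) - log(ci_low)) / (2 * Z975)
  .assert(se > 0, "degenerate CI (zero width): se_log_hr must be positive")
  structure(
    list(hr = hr, ci_low = ci_low, ci_high = ci_high,
         log_hr = log(hr), se_log_hr = se, n = n),
    class = "hr_estimate"
  )
}

#' @export
print.hr_estimate <- function(x, ...) {
  cat(sprintf("HR %.3f (95%% CI %.3f-%.3f), log HR %.4f (SE %.4f)\n",
              x$hr, x$ci_low, x$ci_high, x$log_hr, x$se_log_hr))
  invisible(x)
}

# Coerce a list of hr_estimate (or a data.frame with log_hr/se columns)
# to the (y, se) vectors pooling works on.
.as_loghr_table <- function(estimates) {
  if (is.data.frame(estimates)) {
    .assert(all(c("log_hr", "se_log_hr") %in% names(estimates)),
            "data.frame input needs columns log_hr and se_log_hr")
    return(list(y = estimates$log_hr, se = estimates$se_log_hr))
  }
  if (inherits(estimates, "hr_estimate")) estimates <- list(estimates)
  .assert(is.list(estimates) && length(estimates) >= 1L,
          "estimates must be a non-empty list of hr_estimate objects")
  y <- vapply(estimates, function(e) e$log_hr, numeric(1))
  se <- vapply(estimates, function(e) e$se_log_hr, numeric(1))
  list(y = y, se = se)
}

#' Pool hazard-ratio estimates with a DerSimonian-Laird random-effects model
#'
#' Trial-level log hazard ratios are combined with inverse-variance weights.
#' Between-trial heterogeneity is estimated by the DerSimonian-Laird moment
#' estimator: with fixed-effect weights \eqn{w_i = 1/se_i^2} and
#' fixed-effect mean \eqn{\bar y_F}, \eqn{Q = \sum w_i (y_i - \bar y_F)^2}
#' and \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i))}.
#' Random-effects weights are \eqn{w_i^* = 1/(se_i^2 + \tau^2)}. Percent
#' heterogeneity is \eqn{I^2 = \max(0, (Q - (k-1))/Q) \cdot 100}. A single
#' estimate is returned unchanged with \eqn{Q = 0} and \eqn{I^2 = 0}.
#'
#' @param estimates A non-empty list of \code{\link{log_hr_from_ci}} objects,
#'   or a data.frame with columns \code{log_hr} and \code{se_log_hr}.
#' @return An object of class \code{"pooled_hr"}: list with \code{k},
#'   \code{log_hr}, \code{se}, \code{hr}, \code{ci_low}, \code{ci_high}
#'   (95\%), \code{Q}, \code{tau2}, \code{I2}.
#' @export
pool_random_effects <- function(estimates) {
  tab <- .as_loghr_table(estimates)
  y <- tab$y; se <- tab$se
  k <- length(y)
  .assert(k >= 1L, "at least one estimate is required")
  .assert(all(is.finite(y)) && all(is.finite(se)) && all(se > 0),
          "all standard errors must be positive and finite")
  if (k == 1L) {
    out <- list(k = 1L, log_hr = y, se = se, Q = 0, tau2 = 0, I2 = 0)
  } else {
    w <- 1 / se^2
    ybar_f <- sum(w * y) / sum(w)
    Q <- sum(w * (y - ybar_f)^2)
    tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    mu <- sum(ws * y) / sum(ws)
    out <- list(k = k, log_hr = mu, se = 1 / sqrt(sum(ws)), Q = Q,
                tau2 = tau2, I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0)
  }
  out$hr <- exp(out$log_hr)
  out$ci_low <- exp(out$log_hr - Z975 * out$se)
  out$ci_high <- exp(out$log_hr + Z975 * out$se)
  structure(out, class = "pooled_hr")
}

#' @export
print.pooled_hr <- function(x, ...) {
  cat(sprintf(
    "Pooled HR %.3f (95%% CI %.3f-%.3f) from k = %d trials [DL random effects]\n",
    x$hr, x$ci_low, x$ci_high, x$k))
  cat(sprintf("  Q = %.3f, tau^2 = %.4f, I^2 = %.1f%%\n", x$Q, x$tau2, x$I2))
  invisible(x)
}

#' Interaction test between two pooled subgroup estimates
#'
#' Tests whether the treatment effect differs between the biomarker-positive
#' and biomarker-negative subgroups by the standard subgroup-difference test
#' on pooled log hazard ratios:
#' \eqn{z = (y_{pos} - y_{neg}) / \sqrt{se_{pos}^2 + se_{neg}^2}}, with a
#' two-sided standard-normal p-value.
#'
#' @param pos,neg \code{"pooled_hr"} objects for the two subgroups.
#' @return List with \code{z} and \code{p}.
#' @export
subgroup_difference_test <- function(pos, neg) {
  .assert(inherits(pos, "pooled_hr") && inherits(neg, "pooled_hr"),
          "pos and neg must be pooled_hr objects")
  z <- (pos$log_hr - neg$log_hr) / sqrt(pos$se^2 + neg$se^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}
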