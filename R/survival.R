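#' Kaplan-Meier curves and log-rank comparison of two groups
#'
#' Product-limit survival estimates per group plus the one-degree-of-freedom
#' log-rank test across pooled event times. Median survival is the earliest
#' time at which the estimated survival drops to 0.5 or below; \code{NA}
#' when never reached. With no events in either group the curves are
#' returned and the test is flagged undefined.
#'
#' @param time Positive event/censoring times (months).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param group Two-level grouping vector.
#' @return Object of class \code{"km_logrank"}: list with \code{curves}
#'   (per-group data.frames of \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv}), \code{median} (named numeric), \code{chi2}, \code{p},
#'   \code{undefined}.
#' @export
km_logrank <- function(time, event, group) {
  .assert(is.numeric(time) && all(is.finite(time)) && all(time > 0),
          "times must be positive")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  g <- factor(group)
  .assert(nlevels(g) == 2L, "exactly two groups are required")
  .assert(all(table(g) >= 1L), "each group needs at least one sample")
  sf <- survival::survfit(survival::Surv(time, event) ~ g)
  ss <- summary(sf, censored = TRUE)
  strata <- if (is.null(ss$strata)) {
    factor(rep(levels(g)[1], length(ss$time)))
  } else ss$strata
  curves <- lapply(levels(g), function(lv) {
    idx <- as.character(strata) == paste0("g=", lv)
    data.frame(time = ss$time[idx], n_risk = ss$n.risk[idx],
               n_event = ss$n.event[idx], surv = ss$surv[idx])
  })
  names(curves) <- levels(g)
  med <- vapply(curves, function(cv) {
    hit <- cv$time[cv$surv <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  if (sum(event) == 0) {
    res <- list(chi2 = NA_real_, p = NA_real_, undefined = TRUE)
  } else {
    sd1 <- survival::survdiff(survival::Surv(time, event) ~ g)
    res <- list(chi2 = unname(sd1$chisq),
                p = pchisq(unname(sd1$chisq), df = 1, lower.tail = FALSE),
                undefined = FALSE)
  }
  structure(c(list(curves = curves, median = med), res),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Kaplan-Meier comparison of", paste(names(x$curves), collapse = " vs "), "\n")
  for (nm in names(x$curves))
    cat(sprintf("  %s: n events %d, median %s\n", nm,
                sum(x$curves[[nm]]$n_event),
                ifelse(is.na(x$median[nm]), "not reached",
                       format(x$median[nm]))))
  if (isTRUE(x$undefined)) cat("  log-rank test undefined (no events)\n")
  else cat(sprintf("  log-rank chi2 = %.3f, p = %.4g\n", x$chi2, x$p))
  invisible(x)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron tie correction
#' (delegated to \code{survival::coxph}); standard errors come from the
#' inverse observed information. Per-covariate Wald z, two-sided p, and
#' 95\% hazard-ratio intervals are returned. Non-convergence or a monotone
#' likelihood (separation) yields a flagged, non-estimable fit rather than
#' an error, so downstream consumers can propagate "not estimable".
#'
#' @param data Data frame holding the time, event and covariate columns.
#' @param time_col,event_col Column names of the survival endpoint.
#' @param covariates Character vector of covariate column names; each must
#'   be non-constant. An interaction is written \code{"a:b"} with both main
#'   effects listed.
#' @return Object of class \code{"cox_fit"}: list with \code{coefficients}
#'   (data.frame: term, coef, se, z, p, hr, ci_low, ci_high),
#'   \code{converged}, \code{n}, \code{n_events}.
#' @export
fit_cox <- function(data, time_col, event_col, covariates) {
  .assert(is.data.frame(data), "data must be a data.frame")
  .assert(all(c(time_col, event_col) %in% names(data)),
          "time/event columns not found in data")
  base_terms <- unique(unlist(strsplit(covariates, ":", fixed = TRUE)))
  .assert(all(base_terms %in% names(data)),
          paste("covariate columns missing:",
                paste(setdiff(base_terms, names(data)), collapse = ", ")))
  keep <- complete.cases(data[, c(time_col, event_col, base_terms)])
  d <- data[keep, , drop = FALSE]
  .assert(length(unique(d[[time_col]][d[[event_col]] == 1])) >= 2L,
          "need at least 2 distinct event times")
  for (cv in base_terms) {
    vals <- d[[cv]]
    if (is.numeric(vals) && sd(vals) == 0)
      stop("constant covariate: ", cv, call. = FALSE)
    if (!is.numeric(vals) && length(unique(vals)) < 2L)
      stop("constant covariate: ", cv, call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|singular",
                conditionMessage(w), ignore.case = TRUE))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- cf / se
  converged <- !warned && all(is.finite(cf)) && all(is.finite(se)) &&
    all(se < 100) && all(abs(cf) < 20)
  coefs <- data.frame(
    term = names(cf), coef = unname(cf), se = unname(se), z = unname(z),
    p = unname(2 * pnorm(-abs(z))), hr = unname(exp(cf)),
    ci_low = unname(exp(cf - Z975 * se)),
    ci_high = unname(exp(cf + Z975 * se)),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, converged = converged,
                 n = fit$n, n_events = fit$nevent),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d%s\n",
              x$n, x$n_events,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}
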