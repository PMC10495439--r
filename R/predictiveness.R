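#' Per-cancer PD-L1 predictiveness from trial-level subgroup hazard ratios
#'
#' For each cancer type with at least one trial in both biomarker subgroups,
#' the subgroup hazard ratios are pooled by DerSimonian-Laird random
#' effects and the predictiveness statistic is the hazard-ratio difference
#' \deqn{HRD = (1 - HR_{BM+}) - (1 - HR_{BM-}) = HR_{BM-} - HR_{BM+}}
#' on the hazard-ratio scale (pooling happens on the log scale). Positive
#' HRD means biomarker-positive patients draw more benefit from ICI. The
#' interaction p-value is the subgroup-difference test on pooled log HRs.
#' Cancers lacking either subgroup are dropped and reported in the
#' \code{"dropped"} attribute. Pools whose I-squared exceeds
#' \code{i2_threshold} are flagged (exclusion is left to the caller).
#'
#' @param trials Data frame with columns \code{trial_id}, \code{cancer},
#'   \code{endpoint} ("OS"/"PFS"), \code{subgroup} ("BM_POS"/"BM_NEG"),
#'   \code{hr}, \code{ci_low}, \code{ci_high} and optionally \code{n}.
#' @param endpoint Which endpoint to analyze, \code{"OS"} or \code{"PFS"}.
#' @param i2_threshold Percent I-squared above which either subgroup pool
#'   flags the cancer as heterogeneous (default 75).
#' @return Data frame of class \code{"cancer_predictiveness"} with columns
#'   \code{cancer}, \code{endpoint}, \code{k_pos}, \code{k_neg},
#'   \code{hr_pos}, \code{hr_neg}, \code{hrd}, \code{p_interaction},
#'   \code{i2_pos}, \code{i2_neg}, \code{flagged}; attribute
#'   \code{"dropped"} lists cancers missing a subgroup.
#' @export
compute_predictiveness <- function(trials, endpoint = c("OS", "PFS"),
                                   i2_threshold = 75) {
  endpoint <- match.arg(endpoint)
  .assert(is.data.frame(trials) && nrow(trials) > 0,
          "trials must be a non-empty data.frame")
  req <- c("trial_id", "cancer", "endpoint", "subgroup",
           "hr", "ci_low", "ci_high")
  .assert(all(req %in% names(trials)),
          paste("trials is missing columns:",
                paste(setdiff(req, names(trials)), collapse = ", ")))
  .assert(all(trials$subgroup %in% c("BM_POS", "BM_NEG")),
          "subgroup must be BM_POS or BM_NEG")
  key <- with(trials, paste(trial_id, cancer, endpoint, subgroup))
  .assert(!anyDuplicated(key),
          "duplicate (trial_id, cancer, endpoint, subgroup) rows")
  tr <- trials[trials$endpoint == endpoint, , drop = FALSE]
  .assert(nrow(tr) > 0, paste("no trials for endpoint", endpoint))
  cancers <- sort(unique(tr$cancer))
  rows <- list(); dropped <- character(0)
  for (cn in cancers) {
    sub <- tr[tr$cancer == cn, , drop = FALSE]
    pos <- sub[sub$subgroup == "BM_POS", , drop = FALSE]
    neg <- sub[sub$subgroup == "BM_NEG", , drop = FALSE]
    if (nrow(pos) == 0 || nrow(neg) == 0) {
      dropped <- c(dropped, cn)
      next
    }
    pool1 <- function(df) {
      ests <- lapply(seq_len(nrow(df)), function(i)
        log_hr_from_ci(df$hr[i], df$ci_low[i], df$ci_high[i]))
      pool_random_effects(ests)
    }
    pp <- pool1(pos); pn <- pool1(neg)
    it <- subgroup_difference_test(pp, pn)
    rows[[cn]] <- data.frame(
      cancer = cn, endpoint = endpoint,
      k_pos = pp$k, k_neg = pn$k,
      hr_pos = pp$hr, hr_neg = pn$hr,
      hrd = pn$hr - pp$hr,
      p_interaction = it$p,
      i2_pos = pp$I2, i2_neg = pn$I2,
      flagged = pp$I2 > i2_threshold | pn$I2 > i2_threshold,
      stringsAsFactors = FALSE)
  }
  .assert(length(rows) > 0,
          "no cancer has trials in both biomarker subgroups")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "i2_threshold") <- i2_threshold
  class(out) <- c("cancer_predictiveness", "data.frame")
  out
}

#' @export
print.cancer_predictiveness <- function(x, ...) {
  cat(sprintf("PD-L1 predictiveness (HRD), endpoint %s, %d cancer type(s)\n",
              x$endpoint[1], nrow(x)))
  print(as.data.frame(x), digits = 3)
  dr <- attr(x, "dropped")
  if (length(dr))
    cat("Dropped (missing a biomarker subgroup):", paste(dr, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-endpoint correlation of per-cancer predictiveness
#'
#' Spearman correlation of HRD between two endpoints over the cancers
#' present in both tables (at least 3 shared cancers required).
#'
#' @param a,b \code{"cancer_predictiveness"} tables (e.g. OS and PFS).
#' @return List with \code{rho}, \code{p}, \code{n} shared cancers.
#' @export
predictiveness_correlation <- function(a, b) {
  shared <- intersect(a$cancer, b$cancer)
  .assert(length(shared) >= 3L,
          "need at least 3 cancers shared between endpoints")
  ha <- a$hrd[match(shared, a$cancer)]
  hb <- b$hrd[match(shared, b$cancer)]
  sp <- spearman_cor(ha, hb)
  list(rho = sp$rho, p = sp$p, n = length(shared))
}
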