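#' Stratify patients by PD-L1 expression
#'
#' IHC modes cut the percent of PD-L1-positive tumor cells at the clinical
#' thresholds; RNA modes cut PD-L1 gene expression at percentiles of the
#' reference population. Bins are
#' \itemize{
#'   \item \code{IHC2}: \code{<1} vs \code{>=1} percent;
#'   \item \code{IHC2_ALT}: \code{<5} vs \code{>=5} percent;
#'   \item \code{IHC3}: \code{[0,1)}, \code{[1,50)}, \code{[50,100]};
#'   \item \code{RNA2}: below vs at/above the reference median;
#'   \item \code{RNA3}: below the 25th percentile, between, at/above the
#'     75th percentile.
#' }
#' Patients missing the required field are excluded and counted.
#'
#' @param cohort An \code{"ici_cohort"}.
#' @param mode One of \code{"IHC2"}, \code{"IHC3"}, \code{"IHC2_ALT"},
#'   \code{"RNA2"}, \code{"RNA3"}.
#' @param reference Population defining percentile cutoffs for RNA modes:
#'   \code{"TREATED_ARM"} (default) or \code{"ITT"}.
#' @param pdl1_gene Gene id used for RNA modes (default "CD274").
#' @return Named factor (ordered low to high) over patients with the field
#'   present; attribute \code{"n_excluded"} counts patients missing it.
#' @export
stratify_pdl1 <- function(cohort,
                          mode = c("IHC2", "IHC3", "IHC2_ALT", "RNA2", "RNA3"),
                          reference = c("TREATED_ARM", "ITT"),
                          pdl1_gene = "CD274") {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  .assert(inherits(cohort, "ici_cohort"), "cohort must be an ici_cohort")
  cl <- cohort$clinical
  if (startsWith(mode, "IHC")) {
    .assert("pdl1_ihc" %in% names(cl), "cohort lacks a pdl1_ihc column")
    v <- setNames(cl$pdl1_ihc, cl$patient_id)
  } else {
    v <- .cohort_gene(cohort, pdl1_gene)
    names(v) <- cl$patient_id
  }
  keep <- !is.na(v)
  n_excluded <- sum(!keep)
  v <- v[keep]
  ref_ids <- if (reference == "TREATED_ARM") {
    cl$patient_id[cl$arm == "ICI"]
  } else cl$patient_id
  vref <- v[names(v) %in% ref_ids]
  out <- switch(
    mode,
    IHC2 = factor(ifelse(v >= 1, ">=1", "<1"), levels = c("<1", ">=1")),
    IHC2_ALT = factor(ifelse(v >= 5, ">=5", "<5"), levels = c("<5", ">=5")),
    IHC3 = cut(v, breaks = c(-Inf, 1, 50, Inf), right = FALSE,
               labels = c("<1", "1-50", ">=50")),
    RNA2 = {
      cut_m <- median(vref)
      factor(ifelse(v >= cut_m, "HIGH", "LOW"), levels = c("LOW", "HIGH"))
    },
    RNA3 = {
      qs <- quantile(vref, c(0.25, 0.75))
      factor(ifelse(v >= qs[2], "HIGH", ifelse(v >= qs[1], "INT", "LOW")),
             levels = c("LOW", "INT", "HIGH"))
    })
  names(out) <- names(v)
  attr(out, "n_excluded") <- n_excluded
  attr(out, "mode") <- mode
  out
}

.is_responder <- function(response) response %in% c("CR", "PR")

# one comparison cell: survival HR + log-rank, or ORR + Fisher; a_idx/b_idx
# are logical indices into the clinical table (a = the "exposed" side whose
# HR is reported vs b)
.efficacy_row <- function(cl, a_idx, b_idx, endpoint, group, stratum,
                          comparison, orr_denominator) {
  n_a <- sum(a_idx); n_b <- sum(b_idx)
  row <- data.frame(group = group, stratum = stratum,
                    comparison = comparison, endpoint = endpoint,
                    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    logrank_p = NA_real_,
                    orr_a = NA_real_, orr_a_lo = NA_real_, orr_a_hi = NA_real_,
                    orr_b = NA_real_, orr_b_lo = NA_real_, orr_b_hi = NA_real_,
                    fisher_p = NA_real_,
                    n_a = n_a, n_b = n_b, estimable = FALSE,
                    stringsAsFactors = FALSE)
  if (n_a == 0 || n_b == 0) return(row)
  both <- a_idx | b_idx
  if (endpoint == "ORR") {
    resp <- .is_responder(cl$response)
    if (orr_denominator == "EVALUABLE") {
      ev <- cl$response != "NE"
      a_idx <- a_idx & ev; b_idx <- b_idx & ev
      row$n_a <- n_a <- sum(a_idx); row$n_b <- n_b <- sum(b_idx)
      if (n_a == 0 || n_b == 0) return(row)
    }
    ra <- sum(resp & a_idx); rb <- sum(resp & b_idx)
    cia <- clopper_pearson(ra, n_a)
    cib <- clopper_pearson(rb, n_b)
    row$orr_a <- ra / n_a; row$orr_a_lo <- cia[1]; row$orr_a_hi <- cia[2]
    row$orr_b <- rb / n_b; row$orr_b_lo <- cib[1]; row$orr_b_hi <- cib[2]
    row$fisher_p <- fisher_exact(matrix(c(ra, n_a - ra, rb, n_b - rb),
                                        2, byrow = TRUE))
    row$estimable <- TRUE
    return(row)
  }
  tcol <- if (endpoint == "OS") "os_time" else "pfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  d <- data.frame(time = cl[[tcol]][both], event = cl[[ecol]][both],
                  a = as.integer(a_idx[both]))
  fit <- try(fit_cox(d, "time", "event", "a"), silent = TRUE)
  if (!inherits(fit, "try-error") && fit$converged) {
    cf <- fit$coefficients[1, ]
    row$hr <- cf$hr; row$ci_low <- cf$ci_low; row$ci_high <- cf$ci_high
    row$estimable <- TRUE
  }
  lr <- try(km_logrank(d$time, d$event, d$a), silent = TRUE)
  if (!inherits(lr, "try-error") && !lr$undefined) row$logrank_p <- lr$p
  row
}

#' Biomarker-stratified efficacy grid
#'
#' The study's headline evaluation. For
#' \code{comparison = "POS_vs_NEG_within_ICI"} the cohort is restricted to
#' the ICI arm and, within each predictiveness group, every non-reference
#' PD-L1 stratum is compared against the lowest stratum (hazard ratio with
#' 95\% CI from univariate Cox, log-rank p, and ORR with Clopper-Pearson
#' intervals and Fisher's exact p). For
#' \code{comparison = "ICI_vs_CHEMO_within_stratum"} the arms are compared
#' within each (group x stratum) cell. Cells with an empty side are emitted
#' with \code{estimable = FALSE} so grids stay rectangular.
#'
#' @param cohort An \code{"ici_cohort"}.
#' @param scores Output of \code{\link{score_and_split}} (or NULL to grid
#'   only the "ALL" pseudo-group).
#' @param strata Output of \code{\link{stratify_pdl1}}.
#' @param comparison \code{"POS_vs_NEG_within_ICI"} or
#'   \code{"ICI_vs_CHEMO_within_stratum"}.
#' @param endpoints Subset of \code{c("OS", "PFS", "ORR")}.
#' @param groups Predictiveness groups to grid; default
#'   \code{c("PH", "PL", "ALL")}.
#' @param orr_denominator \code{"ITT"} (default; non-evaluable patients
#'   count as non-responders) or \code{"EVALUABLE"}.
#' @return Data frame of class \code{"efficacy_grid"}; one row per
#'   (group x stratum comparison x endpoint).
#' @export
efficacy_grid <- function(cohort, scores, strata,
                          comparison = c("POS_vs_NEG_within_ICI",
                                         "ICI_vs_CHEMO_within_stratum"),
                          endpoints = c("OS", "PFS", "ORR"),
                          groups = c("PH", "PL", "ALL"),
                          orr_denominator = c("ITT", "EVALUABLE")) {
  comparison <- match.arg(comparison)
  orr_denominator <- match.arg(orr_denominator)
  .assert(all(endpoints %in% c("OS", "PFS", "ORR")), "unknown endpoint")
  cl <- cohort$clinical
  strat <- strata[match(cl$patient_id, names(strata))]
  grp <- if (is.null(scores)) rep(NA_character_, nrow(cl)) else
    scores$group[match(cl$patient_id, scores$patient_id)]
  levs <- levels(strata)
  rows <- list()
  for (g in groups) {
    in_g <- if (g == "ALL") rep(TRUE, nrow(cl)) else (!is.na(grp) & grp == g)
    if (comparison == "POS_vs_NEG_within_ICI") {
      base <- in_g & cl$arm == "ICI" & !is.na(strat)
      for (lev in levs[-1]) {
        a_idx <- base & strat == lev
        b_idx <- base & strat == levs[1]
        for (ep in endpoints)
          rows[[length(rows) + 1L]] <- .efficacy_row(
            cl, a_idx, b_idx, ep, g,
            paste(lev, "vs", levs[1]), comparison, orr_denominator)
      }
    } else {
      base <- in_g & !is.na(strat)
      for (lev in levs) {
        a_idx <- base & strat == lev & cl$arm == "ICI"
        b_idx <- base & strat == lev & cl$arm == "CHEMO"
        for (ep in endpoints)
          rows[[length(rows) + 1L]] <- .efficacy_row(
            cl, a_idx, b_idx, ep, g, lev, comparison, orr_denominator)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("efficacy_grid", "data.frame")
  out
}

#' @export
print.efficacy_grid <- function(x, digits = 3, ...) {
  cat(sprintf("Efficacy grid (%s): %d rows\n", x$comparison[1], nrow(x)))
  show <- as.data.frame(x)
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], signif, digits = digits)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Robustness subgrouping of the efficacy grid
#'
#' Splits the cohort by tumor antigenicity or immune subtype and reruns the
#' efficacy grid within each level: \code{"TMB16"} cuts tumor mutation
#' burden at 16 mut/Mb (at/above is HIGH), \code{"TNB_MEDIAN"} cuts
#' neoantigen burden at the cohort median, \code{"IMMUNE_SUBTYPE"} uses the
#' labels from \code{\link{assign_immune_subtype}} supplied via
#' \code{subtype_labels}.
#'
#' @param cohort An \code{"ici_cohort"}.
#' @param scores Output of \code{\link{score_and_split}}.
#' @param rule \code{"TMB16"}, \code{"TNB_MEDIAN"} or
#'   \code{"IMMUNE_SUBTYPE"}.
#' @param strata_mode Stratification mode passed to
#'   \code{\link{stratify_pdl1}} within each level.
#' @param subtype_labels Named character vector of immune-subtype labels
#'   (required for \code{rule = "IMMUNE_SUBTYPE"}).
#' @param ... Further arguments passed to \code{\link{efficacy_grid}}.
#' @return Named list of \code{"efficacy_grid"} objects, one per level;
#'   attribute \code{"levels"} records the per-patient level assignment.
#' @export
robustness_subgroups <- function(cohort, scores,
                                 rule = c("TMB16", "TNB_MEDIAN",
                                          "IMMUNE_SUBTYPE"),
                                 strata_mode = "IHC2",
                                 subtype_labels = NULL, ...) {
  rule <- match.arg(rule)
  cl <- cohort$clinical
  lev <- switch(rule,
    TMB16 = {
      .assert("tmb" %in% names(cl) && any(!is.na(cl$tmb)),
              "tmb missing for all patients")
      ifelse(is.na(cl$tmb), NA, ifelse(cl$tmb >= 16, "TMB_HIGH", "TMB_LOW"))
    },
    TNB_MEDIAN = {
      .assert("tnb" %in% names(cl) && any(!is.na(cl$tnb)),
              "tnb missing for all patients")
      med <- median(cl$tnb, na.rm = TRUE)
      ifelse(is.na(cl$tnb), NA, ifelse(cl$tnb >= med, "TNB_HIGH", "TNB_LOW"))
    },
    IMMUNE_SUBTYPE = {
      .assert(!is.null(subtype_labels),
              "subtype_labels required for IMMUNE_SUBTYPE rule")
      unname(subtype_labels[match(cl$patient_id, names(subtype_labels))])
    })
  names(lev) <- cl$patient_id
  .assert(any(!is.na(lev)), "grouping field missing for all patients")
  out <- lapply(sort(unique(lev[!is.na(lev)])), function(lv) {
    sub <- subset_cohort(cohort, cl$patient_id[!is.na(lev) & lev == lv])
    strat <- stratify_pdl1(sub, mode = strata_mode)
    efficacy_grid(sub, scores, strat, ...)
  })
  names(out) <- sort(unique(lev[!is.na(lev)]))
  attr(out, "levels") <- lev
  out
}
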