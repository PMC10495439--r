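#' Bundle a genes-by-samples expression panel with its cancer-type map
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns, on the log2(TPM + 0.001) scale.
#' @param sample_cancer Named character vector mapping every sample
#'   (column) to its cancer type.
#' @return Object of class \code{"expression_panel"}.
#' @export
expression_panel <- function(matrix, sample_cancer) {
  .assert(is.matrix(matrix) && is.numeric(matrix),
          "matrix must be a numeric genes x samples matrix")
  .assert(!is.null(rownames(matrix)) && !is.null(colnames(matrix)),
          "matrix needs gene rownames and sample colnames")
  .assert(!anyNA(matrix),
          "missing expression values: apply an imputation policy upstream")
  .assert(all(colnames(matrix) %in% names(sample_cancer)),
          "sample_cancer must cover every sample column")
  structure(list(matrix = matrix,
                 sample_cancer = sample_cancer[colnames(matrix)]),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("Expression panel: %d genes x %d samples, %d cancer type(s)\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$sample_cancer))))
  invisible(x)
}

#' Per-cancer median expression of selected genes
#'
#' For each cancer type, the median (midpoint convention for even counts)
#' of each requested gene over that cancer's samples.
#'
#' @param panel An \code{"expression_panel"}.
#' @param genes Genes to profile; default all genes in the panel.
#' @return Numeric matrix, cancers in rows, genes in columns.
#' @export
median_profile <- function(panel, genes = rownames(panel$matrix)) {
  .assert(inherits(panel, "expression_panel"), "panel must be an expression_panel")
  missing <- setdiff(genes, rownames(panel$matrix))
  .assert(length(missing) == 0,
          paste("genes not in panel:", paste(missing, collapse = ", ")))
  cancers <- sort(unique(panel$sample_cancer))
  out <- vapply(cancers, function(cn) {
    cols <- names(panel$sample_cancer)[panel$sample_cancer == cn]
    apply(panel$matrix[genes, cols, drop = FALSE], 1, median)
  }, numeric(length(genes)))
  # vapply returns genes x cancers; present cancers as rows
  t(base::matrix(out, nrow = length(genes),
                 dimnames = list(genes, cancers)))
}

#' Cross-cancer screen of gene medians against PD-L1 predictiveness
#'
#' For every gene, the Spearman correlation of per-cancer median expression
#' with the HRD statistic, separately for the OS- and PFS-derived
#' predictiveness tables. A gene passes when both endpoint p-values fall
#' below \code{alpha} (unadjusted, per the study convention of no
#' multiplicity correction); Benjamini-Hochberg columns are emitted for
#' reference but never drive the pass flag. Results are sorted by
#' \code{min(p_os, p_pfs)}.
#'
#' @param medians Cancers-by-genes matrix from \code{\link{median_profile}}.
#' @param predictiveness_os,predictiveness_pfs
#'   \code{"cancer_predictiveness"} tables.
#' @param alpha Per-endpoint significance level (default 0.05).
#' @return Data frame with \code{gene}, \code{rho_os}, \code{p_os},
#'   \code{rho_pfs}, \code{p_pfs}, \code{q_os}, \code{q_pfs},
#'   \code{passes}.
#' @export
cross_cancer_screen <- function(medians, predictiveness_os,
                                predictiveness_pfs, alpha = 0.05) {
  .assert(is.matrix(medians) && !is.null(rownames(medians)),
          "medians must be a cancers x genes matrix with cancer rownames")
  one_endpoint <- function(pred) {
    shared <- intersect(rownames(medians), pred$cancer)
    .assert(length(shared) >= 3L,
            "need at least 3 cancers shared between medians and predictiveness")
    hrd <- pred$hrd[match(shared, pred$cancer)]
    res <- t(vapply(colnames(medians), function(gn) {
      sp <- spearman_cor(medians[shared, gn], hrd)
      c(rho = sp$rho, p = sp$p)
    }, c(rho = 0, p = 0)))
    res
  }
  ros <- one_endpoint(predictiveness_os)
  rpf <- one_endpoint(predictiveness_pfs)
  out <- data.frame(
    gene = colnames(medians),
    rho_os = ros[, "rho"], p_os = ros[, "p"],
    rho_pfs = rpf[, "rho"], p_pfs = rpf[, "p"],
    stringsAsFactors = FALSE)
  out$q_os <- stats::p.adjust(out$p_os, method = "BH")
  out$q_pfs <- stats::p.adjust(out$p_pfs, method = "BH")
  out$passes <- !is.na(out$p_os) & !is.na(out$p_pfs) &
    out$p_os < alpha & out$p_pfs < alpha
  out <- out[order(pmin(out$p_os, out$p_pfs), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dichotomize a continuous variable at a cutoff
#'
#' Returns 1 for values at or above the cutoff and 0 below it (the
#' value-at-median goes to 1). \code{cutoff = "median"} resolves the median
#' on the supplied vector.
#'
#' @param values Non-empty numeric vector.
#' @param cutoff Numeric cutoff or \code{"median"} (default).
#' @return Integer 0/1 vector.
#' @examples
#' dichotomize(c(1, 2, 2, 3))  # 0 1 1 1 at median 2
#' @export
dichotomize <- function(values, cutoff = "median") {
  .assert(is.numeric(values) && length(values) >= 1L &&
            all(is.finite(values)), "values must be non-empty finite numerics")
  if (identical(cutoff, "median")) {
    .assert(length(unique(values)) > 1L,
            "all values identical: median dichotomization is degenerate")
    cutoff <- median(values)
  }
  .assert(is.numeric(cutoff) && length(cutoff) == 1L, "invalid cutoff")
  as.integer(values >= cutoff)
}

#' Rank candidate modulators by their Cox interaction with the biomarker
#'
#' Within a (caller-restricted, typically single-arm) cohort, each
#' candidate gene V and the biomarker P are dichotomized at their in-cohort
#' medians and the model
#' \deqn{Hazard = exp(a P + b V + d P V)}
#' is fit by Cox partial likelihood. The interaction coefficient d, its
#' standard error, the standardized Wald \eqn{z = d / se(d)} and two-sided
#' p are reported per candidate. A positive d means high V erodes the
#' beneficial association between the biomarker and survival. Candidates
#' whose fit does not converge (or whose dichotomized covariate is
#' constant) are flagged non-estimable and ranked last. Output is sorted by
#' z descending, ties broken lexicographically by gene id.
#'
#' @param cohort An \code{"ici_cohort"} (restrict to one treatment arm
#'   first, e.g. \code{subset_cohort}).
#' @param biomarker Gene id of the biomarker expression (e.g. "CD274").
#' @param candidates Non-empty character vector of candidate gene ids.
#' @param endpoint \code{"OS"} or \code{"PFS"}.
#' @param dichotomize_covariates Median-dichotomize P and V (default TRUE,
#'   the study convention); FALSE enters them continuously.
#' @return Data frame with \code{gene}, \code{endpoint}, \code{d},
#'   \code{se_d}, \code{z}, \code{p}, \code{estimable}.
#' @export
rank_interactions <- function(cohort, biomarker, candidates,
                              endpoint = c("OS", "PFS"),
                              dichotomize_covariates = TRUE) {
  endpoint <- match.arg(endpoint)
  .assert(inherits(cohort, "ici_cohort"), "cohort must be an ici_cohort")
  .assert(length(candidates) >= 1L, "candidate list must be non-empty")
  tcol <- if (endpoint == "OS") "os_time" else "pfs_time"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  p_raw <- .cohort_gene(cohort, biomarker)
  P <- if (dichotomize_covariates) dichotomize(p_raw) else p_raw
  rows <- lapply(candidates, function(gn) {
    na_row <- data.frame(gene = gn, endpoint = endpoint, d = NA_real_,
                         se_d = NA_real_, z = NA_real_, p = NA_real_,
                         estimable = FALSE, stringsAsFactors = FALSE)
    est <- try({
      v_raw <- .cohort_gene(cohort, gn)
      V <- if (dichotomize_covariates) dichotomize(v_raw) else v_raw
      d <- data.frame(time = cohort$clinical[[tcol]],
                      event = cohort$clinical[[ecol]],
                      P = P, V = V)
      fit <- fit_cox(d, "time", "event", c("P", "V", "P:V"))
      if (!fit$converged) return(na_row)
      cf <- fit$coefficients[fit$coefficients$term == "P:V", ]
      data.frame(gene = gn, endpoint = endpoint, d = cf$coef, se_d = cf$se,
                 z = cf$z, p = cf$p, estimable = TRUE,
                 stringsAsFactors = FALSE)
    }, silent = TRUE)
    if (inherits(est, "try-error")) na_row else est
  })
  out <- do.call(rbind, rows)
  ord <- order(!out$estimable, -ifelse(is.na(out$z), -Inf, out$z), out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
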