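#' Assemble a patient-level trial cohort
#'
#' Binds the clinical table, the expression matrix and optional cell
#' fractions of one trial into a single validated container used by the
#' interaction-ranking, scoring and efficacy stages.
#'
#' @param clinical Data frame with columns \code{patient_id}, \code{arm}
#'   ("ICI"/"CHEMO"), \code{os_time}, \code{os_event}, \code{pfs_time},
#'   \code{pfs_event}, \code{response} ("CR","PR","SD","PD","NE");
#'   optionally \code{pdl1_ihc} (percent, may be NA), \code{tmb} (mut/Mb),
#'   \code{tnb}.
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), patients
#'   in columns (colnames = patient ids covering every clinical row).
#' @param cell_fractions Optional numeric matrix, patients in rows
#'   (rownames = patient ids), cell types in columns, values in [0, 1].
#' @return Object of class \code{"ici_cohort"}.
#' @export
ici_cohort <- function(clinical, expr, cell_fractions = NULL) {
  req <- c("patient_id", "arm", "os_time", "os_event",
           "pfs_time", "pfs_event", "response")
  .assert(is.data.frame(clinical), "clinical must be a data.frame")
  .assert(all(req %in% names(clinical)),
          paste("clinical is missing columns:",
                paste(setdiff(req, names(clinical)), collapse = ", ")))
  .assert(!anyDuplicated(clinical$patient_id), "duplicate patient_id values")
  .assert(all(clinical$arm %in% c("ICI", "CHEMO")), "arm must be ICI or CHEMO")
  .assert(all(clinical$os_time > 0) && all(clinical$pfs_time > 0),
          "survival times must be positive")
  .assert(all(clinical$os_event %in% c(0, 1)) &&
            all(clinical$pfs_event %in% c(0, 1)), "event flags must be 0/1")
  .assert(all(clinical$response %in% c("CR", "PR", "SD", "PD", "NE")),
          "response must be one of CR, PR, SD, PD, NE")
  if ("pdl1_ihc" %in% names(clinical)) {
    ok <- is.na(clinical$pdl1_ihc) |
      (clinical$pdl1_ihc >= 0 & clinical$pdl1_ihc <= 100)
    .assert(all(ok), "pdl1_ihc must be a percent in [0, 100] or NA")
  }
  .assert(is.matrix(expr) && is.numeric(expr), "expr must be a numeric matrix")
  .assert(!is.null(rownames(expr)) && !is.null(colnames(expr)),
          "expr needs gene rownames and patient colnames")
  .assert(all(clinical$patient_id %in% colnames(expr)),
          "every clinical patient needs an expression column")
  .assert(!anyNA(expr), "missing expression values: impute or drop upstream")
  if (!is.null(cell_fractions)) {
    .assert(is.matrix(cell_fractions) && !is.null(rownames(cell_fractions)),
            "cell_fractions must be a matrix with patient rownames")
    .assert(all(cell_fractions >= 0 & cell_fractions <= 1),
            "cell fractions must lie in [0, 1]")
  }
  structure(list(clinical = clinical,
                 expr = expr[, clinical$patient_id, drop = FALSE],
                 cell_fractions = cell_fractions),
            class = "ici_cohort")
}

#' @export
print.ici_cohort <- function(x, ...) {
  cat(sprintf("ICI trial cohort: %d patients (%d ICI / %d CHEMO), %d genes\n",
              nrow(x$clinical), sum(x$clinical$arm == "ICI"),
              sum(x$clinical$arm == "CHEMO"), nrow(x$expr)))
  if (!is.null(x$cell_fractions))
    cat(sprintf("  cell fractions: %d cell types\n", ncol(x$cell_fractions)))
  invisible(x)
}

# expression of one gene, ordered as clinical rows
.cohort_gene <- function(cohort, gene) {
  .assert(gene %in% rownames(cohort$expr),
          paste("gene not present in cohort expression:", gene))
  cohort$expr[gene, cohort$clinical$patient_id]
}

#' Subset a cohort to selected patients
#'
#' @param cohort An \code{"ici_cohort"}.
#' @param patient_ids Character vector of patient ids to keep.
#' @return A new \code{"ici_cohort"} restricted to those patients.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  keep <- cohort$clinical$patient_id %in% patient_ids
  .assert(any(keep), "no patients left after subsetting")
  cf <- cohort$cell_fractions
  if (!is.null(cf)) {
    ids <- intersect(cohort$clinical$patient_id[keep], rownames(cf))
    cf <- cf[ids, , drop = FALSE]
  }
  ici_cohort(cohort$clinical[keep, , drop = FALSE],
             cohort$expr, cf)
}
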