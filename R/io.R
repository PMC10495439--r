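# Tabular I/O: tab-separated, single header row, UTF-8, '.' decimal,
# missing values written/read as "NA".

.read_tsv <- function(path) {
  .assert(file.exists(path), paste("input file not found:", path))
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = "NA")
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  .assert(length(missing) == 0,
          sprintf("%s: missing column(s) %s", path,
                  paste(missing, collapse = ", ")))
}

#' Write a data frame as a TSV file
#'
#' Tab-separated, one header row, "NA" for missing values, no quoting,
#' no row names.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a trial-level hazard-ratio table
#'
#' Expects columns \code{trial_id}, \code{cancer}, \code{endpoint},
#' \code{subgroup}, \code{hr}, \code{ci_low}, \code{ci_high} (and
#' optionally \code{n}); validates value domains and reports offending
#' rows.
#'
#' @param path Path to \code{trials.tsv}.
#' @return Validated data frame.
#' @export
read_trials_tsv <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, c("trial_id", "cancer", "endpoint", "subgroup",
                      "hr", "ci_low", "ci_high"), path)
  bad <- which(!df$endpoint %in% c("OS", "PFS"))
  .assert(length(bad) == 0,
          sprintf("%s: invalid endpoint at data row(s) %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  bad <- which(!df$subgroup %in% c("BM_POS", "BM_NEG"))
  .assert(length(bad) == 0,
          sprintf("%s: invalid subgroup at data row(s) %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  bad <- which(!(df$hr > 0 & df$ci_low > 0 & df$ci_high >= df$ci_low))
  .assert(length(bad) == 0,
          sprintf("%s: invalid hr/CI at data row(s) %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  df
}

#' Read an expression panel and its sample-to-cancer map
#'
#' @param panel_path Genes x samples TSV; first column \code{gene} holds
#'   gene ids, remaining columns are samples.
#' @param map_path Two-column TSV with \code{sample} and \code{cancer}.
#' @return An \code{"expression_panel"}.
#' @export
read_panel_tsv <- function(panel_path, map_path) {
  df <- .read_tsv(panel_path)
  .require_cols(df, "gene", panel_path)
  mat <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  .assert(is.numeric(mat), paste(panel_path, ": non-numeric expression values"))
  rownames(mat) <- df$gene
  mp <- .read_tsv(map_path)
  .require_cols(mp, c("sample", "cancer"), map_path)
  expression_panel(mat, setNames(mp$cancer, mp$sample))
}

#' Write an expression panel to TSV files
#' @param panel An \code{"expression_panel"}.
#' @param panel_path,map_path Output paths.
#' @return \code{panel_path}, invisibly.
#' @export
write_panel_tsv <- function(panel, panel_path, map_path) {
  df <- data.frame(gene = rownames(panel$matrix), panel$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, panel_path)
  write_tsv(data.frame(sample = names(panel$sample_cancer),
                       cancer = unname(panel$sample_cancer)), map_path)
  invisible(panel_path)
}

#' Read a patient-level cohort from clinical/expression (and optional
#' cell-fraction) TSV files
#'
#' @param clinical_path Clinical TSV (see \code{\link{ici_cohort}} for the
#'   required columns).
#' @param expr_path Genes x patients TSV with a leading \code{gene} column.
#' @param fractions_path Optional patients x cell-types TSV with a leading
#'   \code{sample} column.
#' @return An \code{"ici_cohort"}.
#' @export
read_cohort_tsv <- function(clinical_path, expr_path,
                            fractions_path = NULL) {
  cl <- .read_tsv(clinical_path)
  .require_cols(cl, c("patient_id", "arm", "os_time", "os_event",
                      "pfs_time", "pfs_event", "response"), clinical_path)
  ex <- .read_tsv(expr_path)
  .require_cols(ex, "gene", expr_path)
  mat <- as.matrix(ex[, setdiff(names(ex), "gene"), drop = FALSE])
  rownames(mat) <- ex$gene
  cf <- NULL
  if (!is.null(fractions_path)) {
    fr <- .read_tsv(fractions_path)
    .require_cols(fr, "sample", fractions_path)
    cf <- as.matrix(fr[, setdiff(names(fr), "sample"), drop = FALSE])
    rownames(cf) <- fr$sample
  }
  ici_cohort(cl, mat, cf)
}

#' Write a cohort to TSV files
#' @param cohort An \code{"ici_cohort"}.
#' @param clinical_path,expr_path Output paths.
#' @param fractions_path Optional output path for cell fractions.
#' @return \code{clinical_path}, invisibly.
#' @export
write_cohort_tsv <- function(cohort, clinical_path, expr_path,
                             fractions_path = NULL) {
  write_tsv(cohort$clinical, clinical_path)
  write_tsv(data.frame(gene = rownames(cohort$expr), cohort$expr,
                       check.names = FALSE), expr_path)
  if (!is.null(fractions_path) && !is.null(cohort$cell_fractions))
    write_tsv(data.frame(sample = rownames(cohort$cell_fractions),
                         cohort$cell_fractions, check.names = FALSE),
              fractions_path)
  invisible(clinical_path)
}
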