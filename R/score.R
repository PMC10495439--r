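#' Fit the predictiveness-score linear model across cancer types
#'
#' Ordinary least squares of the per-cancer HRD on the per-cancer median
#' expression of the chosen modulator gene:
#' \deqn{PS = \alpha V + \beta.}
#' Leave-one-out cross-validation (an explicit refit per held-out cancer)
#' is reported as a diagnostic RMSE; the deployed model is the all-points
#' fit.
#'
#' @param medians Named numeric vector: per-cancer median expression of the
#'   modulator gene (names = cancers).
#' @param hrd Named numeric vector: per-cancer HRD (names = cancers). Only
#'   cancers present in both vectors are used; at least 3 required.
#' @param gene Gene id recorded in the model (default "V").
#' @return Object of class \code{"ps_model"} with elements \code{gene},
#'   \code{slope}, \code{intercept}, \code{loocv_rmse}, \code{loocv_pred}
#'   (per-cancer held-out predictions), \code{n_points}, \code{data}.
#' @examples
#' m <- setNames(c(1, 2, 3, 4), letters[1:4])
#' fit_ps_model(m, -0.76 * m + 2.81)  # recovers slope -0.76, intercept 2.81
#' @export
fit_ps_model <- function(medians, hrd, gene = "V") {
  .assert(is.numeric(medians) && is.numeric(hrd) &&
            !is.null(names(medians)) && !is.null(names(hrd)),
          "medians and hrd must be named numeric vectors")
  shared <- intersect(names(medians), names(hrd))
  .assert(length(shared) >= 3L, "need at least 3 cancers with both values")
  x <- medians[shared]; y <- hrd[shared]
  .assert(sd(x) > 0, "zero variance in the predictor")
  d <- data.frame(x = x, y = y)
  fit <- lm(y ~ x, data = d)
  loocv_pred <- vapply(seq_along(shared), function(i) {
    f <- lm(y ~ x, data = d[-i, , drop = FALSE])
    unname(predict(f, newdata = d[i, , drop = FALSE]))
  }, numeric(1))
  names(loocv_pred) <- shared
  structure(
    list(gene = gene,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         loocv_rmse = sqrt(mean((y - loocv_pred)^2)),
         loocv_pred = loocv_pred,
         n_points = length(shared),
         data = d),
    class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat(sprintf("Predictiveness score model: PS = %.4g x %s + %.4g\n",
              x$slope, x$gene, x$intercept))
  cat(sprintf("  fitted on %d cancer types; LOOCV RMSE %.4g\n",
              x$n_points, x$loocv_rmse))
  invisible(x)
}

#' @export
coef.ps_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.ps_model <- function(object, ...) {
  res <- residuals(object)
  cat(sprintf("Predictiveness score model on %d cancer types\n",
              object$n_points))
  cat(sprintf("  PS = %.4g x %s + %.4g\n",
              object$slope, object$gene, object$intercept))
  cat(sprintf("  in-sample RMSE %.4g, LOOCV RMSE %.4g\n",
              sqrt(mean(res^2)), object$loocv_rmse))
  invisible(object)
}

#' @export
predict.ps_model <- function(object, newdata, ...) {
  if (missing(newdata)) newdata <- object$data$x
  .assert(is.numeric(newdata), "newdata must be numeric expression values")
  object$slope * newdata + object$intercept
}

#' @export
residuals.ps_model <- function(object, ...) {
  object$data$y - predict(object, object$data$x)
}

#' @export
plot.ps_model <- function(x, ...) {
  plot(x$data$x, x$data$y,
       xlab = paste(x$gene, "median expression"),
       ylab = "HRD", main = "Predictiveness score model", ...)
  abline(x$intercept, x$slope)
  invisible(x)
}

#' Score patients and split into Predictiveness-High / Low
#'
#' Each patient's score is \code{slope * expression + intercept} for the
#' model's gene; the cohort is bifurcated at the median score of the
#' reference population (the treated arm for single-arm analyses, the full
#' intention-to-treat population for arm comparisons). Patients at or above
#' the median are Predictiveness-High (PH). With a negative slope, PH
#' therefore corresponds to low modulator expression.
#'
#' @param cohort An \code{"ici_cohort"} carrying the model's gene.
#' @param model A \code{"ps_model"}.
#' @param reference Population whose median defines the cutoff:
#'   \code{"TREATED_ARM"} (default, arm == "ICI") or \code{"ITT"}.
#' @return Data frame with \code{patient_id}, \code{ps}, \code{group}
#'   ("PH"/"PL"); attributes \code{"cutoff"} and \code{"reference"}.
#' @export
score_and_split <- function(cohort, model,
                            reference = c("TREATED_ARM", "ITT")) {
  reference <- match.arg(reference)
  .assert(inherits(cohort, "ici_cohort"), "cohort must be an ici_cohort")
  .assert(inherits(model, "ps_model"), "model must be a ps_model")
  expr <- .cohort_gene(cohort, model$gene)
  .assert(length(unique(expr)) > 1L,
          "all patients share one expression value: splitting impossible")
  ps <- predict(model, expr)
  ref_ids <- if (reference == "TREATED_ARM") {
    cohort$clinical$patient_id[cohort$clinical$arm == "ICI"]
  } else cohort$clinical$patient_id
  .assert(length(ref_ids) >= 1L, "reference population is empty")
  cutoff <- median(ps[match(ref_ids, cohort$clinical$patient_id)])
  out <- data.frame(patient_id = cohort$clinical$patient_id,
                    ps = unname(ps),
                    group = ifelse(ps >= cutoff, "PH", "PL"),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "reference") <- reference
  out
}
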