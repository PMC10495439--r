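#' Quantile-normalize and gene-center an expression matrix
#'
#' Columns (samples) are forced onto a common reference distribution (the
#' mean of the per-column sorted values, midrank averaging for ties), then
#' every gene is centered to mean zero across samples. With a single
#' sample, only centering is applied and a warning is issued.
#'
#' @param matrix Numeric genes x samples matrix on the log2(TPM + 0.001)
#'   scale.
#' @param center Subtract the per-gene mean after the quantile step
#'   (default TRUE); set FALSE to inspect the quantile-normalized values
#'   themselves.
#' @return Normalized matrix with the same dimnames.
#' @export
normalize_expression <- function(matrix, center = TRUE) {
  .assert(is.matrix(matrix) && is.numeric(matrix),
          "matrix must be a numeric genes x samples matrix")
  .assert(!anyNA(matrix), "missing values are not allowed")
  if (ncol(matrix) < 2) {
    warning("single sample: quantile step skipped, centering only")
    qn <- matrix
  } else {
    qn <- limma::normalizeQuantiles(matrix, ties = TRUE)
    dimnames(qn) <- dimnames(matrix)
  }
  if (center) qn - rowMeans(qn) else qn
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @return Named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  .assert(file.exists(path), paste("GMT file not found:", path))
  fgsea::gmtPathways(path)
}

#' Mean-expression signature scores
#'
#' For each gene set, the unweighted mean of the (normalized) expression of
#' its present genes per sample — the convention used for the IFN-gamma
#' signature, the T-cell-inflamed GEP, and the CD8 score (mean of CD8A and
#' CD8B). Sets with no present gene get an NA column; per-set gene coverage
#' is recorded.
#'
#' @param matrix Normalized genes x samples matrix.
#' @param sets Named list of gene-id vectors (e.g. from
#'   \code{\link{read_gene_sets}}).
#' @return Samples x signatures numeric matrix; attribute
#'   \code{"coverage"} gives the fraction of each set's genes present.
#' @export
signature_scores <- function(matrix, sets) {
  .assert(is.matrix(matrix) && !is.null(rownames(matrix)),
          "matrix must have gene rownames")
  .assert(is.list(sets) && length(sets) >= 1L && !is.null(names(sets)),
          "sets must be a named list of gene vectors")
  .assert(all(vapply(sets, length, integer(1)) >= 1L),
          "every gene set must be non-empty")
  coverage <- numeric(length(sets)); names(coverage) <- names(sets)
  out <- vapply(names(sets), function(nm) {
    present <- intersect(sets[[nm]], rownames(matrix))
    coverage[nm] <<- length(present) / length(sets[[nm]])
    if (length(present) == 0) return(rep(NA_real_, ncol(matrix)))
    colMeans(matrix[present, , drop = FALSE])
  }, numeric(ncol(matrix)))
  out <- base::matrix(out, nrow = ncol(matrix),
                      dimnames = list(colnames(matrix), names(sets)))
  attr(out, "coverage") <- coverage
  out
}

.pair_dist <- function(x, distance) {
  # x: items x features
  if (distance == "pearson") {
    .assert(ncol(x) >= 2L, "pearson distance needs at least 2 features")
    as.dist(1 - cor(t(x)))
  } else {
    dist(x)
  }
}

#' Resampled hierarchical consensus clustering
#'
#' Repeats hierarchical agglomerative clustering on random subsamples of
#' items (and optionally features); the consensus for a sample pair at a
#' given k is the fraction of co-sampled repetitions in which the pair
#' co-clustered. Final assignments cut a hierarchical tree of
#' (1 - consensus). The consensus CDF and its area are reported per k, and
#' \code{chosen_k} is the largest k whose relative delta-area exceeds
#' \code{delta_threshold} (k = 2 when none does).
#'
#' @param features Samples x features numeric matrix (rownames = samples).
#' @param maxK Largest number of clusters tested (default 6; k runs 2..maxK).
#' @param reps Number of resampling repetitions (default 1000).
#' @param p_item Fraction of samples drawn per repetition (default 0.8).
#' @param p_feature Fraction of features drawn per repetition (default 1).
#' @param seed Integer seed controlling the resampling.
#' @param distance \code{"pearson"} (1 - correlation, default) or
#'   \code{"euclidean"}.
#' @param linkage Agglomeration method for \code{\link{hclust}}
#'   (default "average").
#' @param delta_threshold Relative delta-area threshold for choosing k
#'   (default 0.1).
#' @return Object of class \code{"consensus_result"}: list with
#'   \code{consensus} (per-k list of symmetric sample x sample matrices),
#'   \code{assignments} (per-k integer vectors), \code{cdf}, \code{area},
#'   \code{delta_area}, \code{chosen_k}, and the call parameters.
#' @export
consensus_cluster <- function(features, maxK = 6, reps = 1000,
                              p_item = 0.8, p_feature = 1, seed = 1,
                              distance = c("pearson", "euclidean"),
                              linkage = "average", delta_threshold = 0.1) {
  distance <- match.arg(distance)
  .assert(is.matrix(features) && is.numeric(features),
          "features must be a numeric samples x features matrix")
  n <- nrow(features)
  .assert(!is.null(rownames(features)), "features needs sample rownames")
  .assert(maxK >= 2 && n >= maxK + 1, "need at least maxK + 1 samples")
  .assert(reps >= 1, "reps must be >= 1")
  .assert(p_item > 0 && p_item <= 1 && p_feature > 0 && p_feature <= 1,
          "p_item and p_feature must lie in (0, 1]")
  set.seed(seed)
  ks <- 2:maxK
  co <- lapply(ks, function(k) base::matrix(0, n, n))
  names(co) <- as.character(ks)
  sampled <- base::matrix(0, n, n)
  n_item <- max(2L, floor(n * p_item))
  n_feat <- max(1L, floor(ncol(features) * p_feature))
  for (r in seq_len(reps)) {
    items <- sort(sample.int(n, n_item))
    feats <- if (p_feature < 1) sort(sample.int(ncol(features), n_feat)) else
      seq_len(ncol(features))
    sampled[items, items] <- sampled[items, items] + 1
    hc <- hclust(.pair_dist(features[items, feats, drop = FALSE], distance),
                 method = linkage)
    for (k in ks) {
      cls <- cutree(hc, k = k)
      same <- outer(cls, cls, "==")
      kc <- as.character(k)
      co[[kc]][items, items] <- co[[kc]][items, items] + same
    }
  }
  consensus <- lapply(co, function(m) {
    cm <- ifelse(sampled > 0, m / sampled, 0)
    diag(cm) <- 1
    dimnames(cm) <- list(rownames(features), rownames(features))
    cm
  })
  assignments <- lapply(ks, function(k) {
    cm <- consensus[[as.character(k)]]
    hc <- hclust(as.dist(1 - cm), method = linkage)
    setNames(cutree(hc, k = k), rownames(features))
  })
  names(assignments) <- as.character(ks)
  grid <- seq(0, 1, by = 0.01)
  cdf <- lapply(consensus, function(cm) {
    vals <- cm[upper.tri(cm)]
    vapply(grid, function(g) mean(vals <= g), numeric(1))
  })
  area <- vapply(cdf, function(f) sum(diff(grid) * f[-length(f)]), numeric(1))
  delta <- c(area[1],
             diff(area) / pmax(area[-length(area)], .Machine$double.eps))
  names(delta) <- names(area)
  cand <- ks[-1][delta[-1] > delta_threshold]
  chosen_k <- if (length(cand)) max(cand) else 2L
  structure(list(consensus = consensus, assignments = assignments,
                 cdf = cdf, cdf_grid = grid, area = area,
                 delta_area = delta, chosen_k = as.integer(chosen_k),
                 maxK = maxK, reps = reps, p_item = p_item,
                 p_feature = p_feature, seed = seed,
                 distance = distance, linkage = linkage),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "Consensus clustering: %d samples, k = 2..%d, %d reps (p_item %.2f)\n",
    nrow(x$consensus[[1]]), x$maxK, x$reps, x$p_item))
  cat("  delta area:",
      paste(sprintf("k=%s %.3f", names(x$delta_area), x$delta_area),
            collapse = ", "), "\n")
  cat("  chosen k:", x$chosen_k, "\n")
  invisible(x)
}

#' @export
plot.consensus_result <- function(x, ...) {
  plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "consensus index",
       ylab = "CDF", main = "Consensus CDF by k", ...)
  for (i in seq_along(x$cdf))
    lines(x$cdf_grid, x$cdf[[i]], col = i)
  legend("bottomright", legend = paste("k =", names(x$cdf)),
         col = seq_along(x$cdf), lty = 1, bty = "n")
  invisible(x)
}

#' Default lymphocyte cell types for immune-subtype orientation
#' @export
lymphocyte_cell_types <- function() {
  c("B_cells", "CD4_T_cells", "CD8_T_cells", "NK_cells", "T_cells")
}

#' Derived stromal-cell fraction
#'
#' The stromal compartment is the sum of the Endothelium and Fibroblasts
#' fractions.
#'
#' @param cell_fractions Samples x cell-types matrix containing columns
#'   \code{Endothelium} and \code{Fibroblasts}.
#' @return Named numeric vector of stromal fractions.
#' @export
stromal_fraction <- function(cell_fractions) {
  .assert(all(c("Endothelium", "Fibroblasts") %in% colnames(cell_fractions)),
          "cell_fractions needs Endothelium and Fibroblasts columns")
  cell_fractions[, "Endothelium"] + cell_fractions[, "Fibroblasts"]
}

#' Assign Immune-Enriched vs Non-Immune subtypes from cell fractions
#'
#' Consensus-clusters the cell-fraction profiles at k = 2 and labels the
#' cluster with the higher mean lymphocyte sum "ImmuneEnriched", the other
#' "NonImmune".
#'
#' @param cell_fractions Samples x cell-types matrix (rownames = samples),
#'   values in [0, 1]; deconvolution itself happens upstream.
#' @param lymphocytes Cell-type columns summed to orient the labels
#'   (default \code{\link{lymphocyte_cell_types}} intersected with the
#'   available columns; at least one must be present).
#' @param reps,p_item,seed,distance,linkage Passed to
#'   \code{\link{consensus_cluster}}.
#' @return Named character vector sample -> "ImmuneEnriched"/"NonImmune";
#'   attribute \code{"consensus"} keeps the clustering object.
#' @export
assign_immune_subtype <- function(cell_fractions,
                                  lymphocytes = lymphocyte_cell_types(),
                                  reps = 1000, p_item = 0.8, seed = 1,
                                  distance = "pearson",
                                  linkage = "average") {
  .assert(is.matrix(cell_fractions) && !is.null(rownames(cell_fractions)),
          "cell_fractions must be a matrix with sample rownames")
  present <- intersect(lymphocytes, colnames(cell_fractions))
  .assert(length(present) >= 1L,
          "none of the lymphocyte cell types are present in cell_fractions")
  cc <- consensus_cluster(cell_fractions, maxK = 2, reps = reps,
                          p_item = p_item, seed = seed,
                          distance = distance, linkage = linkage)
  cls <- cc$assignments[["2"]]
  lymph <- rowSums(cell_fractions[, present, drop = FALSE])
  mean1 <- mean(lymph[cls == 1]); mean2 <- mean(lymph[cls == 2])
  enriched <- if (mean1 >= mean2) 1L else 2L
  out <- ifelse(cls == enriched, "ImmuneEnriched", "NonImmune")
  names(out) <- rownames(cell_fractions)
  attr(out, "consensus") <- cc
  out
}
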