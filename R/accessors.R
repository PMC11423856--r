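#' Constructor for IntensityExperiment
#'
#' @param intensity non-negative numeric matrix, proteins x samples, with
#'   unique dimnames. Zero means the protein was not detected in the sample.
#' @param n_peptides positive integer vector, one entry per protein: the
#'   number of theoretically observable peptides used by iBAQ.
#' @param colData optional per-sample annotation (clinical covariates).
#' @return an [IntensityExperiment-class] object.
#' @examples
#' m <- matrix(c(100, 0, 40, 10), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' ie <- IntensityExperiment(m, n_peptides = c(4L, 7L))
#' @export
IntensityExperiment <- function(intensity, n_peptides, colData = NULL) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)) || is.null(colnames(intensity)))
    stop("intensity matrix must have protein rownames and sample colnames")
  if (length(n_peptides) != nrow(intensity))
    stop("'n_peptides' must have one entry per protein")
  rd <- S4Vectors::DataFrame(n_peptides = as.integer(n_peptides),
                             row.names = rownames(intensity))
  args <- list(assays = list(intensity = intensity), rowData = rd)
  if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("IntensityExperiment", se)
}

.new_abundance <- function(fot, detected, imputed, colData = NULL) {
  stopifnot(identical(dim(fot), dim(detected)),
            identical(dim(fot), dim(imputed)))
  args <- list(assays = list(fot = fot, detected = detected, imputed = imputed))
  if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("AbundanceExperiment", se)
}

#' @describeIn AbundanceExperiment-class FOT abundance matrix.
#' @param object an `AbundanceExperiment`.
#' @export
fot <- function(object) SummarizedExperiment::assay(object, "fot")

#' @describeIn AbundanceExperiment-class logical detection mask
#'   (pre-imputation value > 0).
#' @export
detected <- function(object) SummarizedExperiment::assay(object, "detected")

#' @describeIn AbundanceExperiment-class logical imputation mask.
#' @export
imputed <- function(object) SummarizedExperiment::assay(object, "imputed")

#' @describeIn IntensityExperiment-class raw intensity matrix.
#' @param object an `IntensityExperiment`.
#' @export
intensities <- function(object) SummarizedExperiment::assay(object, "intensity")

#' @describeIn IntensityExperiment-class theoretical observable peptide
#'   counts per protein.
#' @export
nPeptides <- function(object) {
  stats::setNames(SummarizedExperiment::rowData(object)$n_peptides,
                  rownames(object))
}

setMethod("show", "IntensityExperiment", function(object) {
  cat(sprintf("IntensityExperiment: %d proteins x %d samples\n",
              nrow(object), ncol(object)))
  m <- intensities(object)
  cat(sprintf("  detected entries: %.1f%%\n", 100 * mean(m > 0)))
  callNextMethod()
})

setMethod("show", "AbundanceExperiment", function(object) {
  cat(sprintf("AbundanceExperiment: %d proteins x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  detected: %.1f%%  imputed: %.1f%%\n",
              100 * mean(detected(object)), 100 * mean(imputed(object))))
  callNextMethod()
})

setMethod("show", "ConsensusClustering", function(object) {
  cat(sprintf("ConsensusClustering (k = %d, %d runs)\n",
              object@k, object@nRuns))
  cat(sprintf("  average silhouette: %.3f  min class size: %d\n",
              object@averageSilhouette, object@minClassSize))
  print(table(cluster = object@labels))
})

setMethod("show", "SubtypeClassifier", function(object) {
  cat(sprintf("SubtypeClassifier: %d features, %d trees, mtry = %d\n",
              length(object@features), object@nTrees, object@mtry))
  cat(sprintf("  classes: %s\n", paste(object@classLevels, collapse = ", ")))
  cat(sprintf("  10-fold CV accuracy: %.3f\n", object@cvAccuracy))
})

#' @describeIn SubtypeClassifier-class cross-validated accuracy.
#' @param object a `SubtypeClassifier`.
#' @export
cvAccuracy <- function(object) object@cvAccuracy

#' @describeIn SubtypeClassifier-class ordered predictor panel.
#' @export
classifierFeatureIds <- function(object) object@features

#' @describeIn ConsensusClustering-class cluster labels (integer, named by
#'   sample).
#' @param object a `ConsensusClustering`.
#' @export
clusterLabels <- function(object) object@labels

#' @describeIn ConsensusClustering-class consensus co-clustering matrix.
#' @export
consensusMatrix <- function(object) object@consensus

#' @describeIn ConsensusClustering-class mean silhouette width on
#'   `1 - consensus`.
#' @export
averageSilhouette <- function(object) object@averageSilhouette
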