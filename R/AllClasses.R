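#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Container for raw label-free protein intensities
#'
#' An `IntensityExperiment` holds the raw (search-engine reported) protein
#' intensity matrix of a cohort together with the number of theoretically
#' observable peptides per protein, the two ingredients of iBAQ
#' quantification. It extends
#' [SummarizedExperiment::SummarizedExperiment] with one assay,
#' `"intensity"` (proteins x samples, non-negative, zero = not detected),
#' and a required `rowData` column `n_peptides`.
#'
#' @slot .  See [SummarizedExperiment::SummarizedExperiment] for inherited
#'   slots; clinical covariates live in `colData`.
#' @seealso [IntensityExperiment()], [computeIBAQ()]
#' @export
setClass("IntensityExperiment", contains = "SummarizedExperiment")

setValidity("IntensityExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    m <- SummarizedExperiment::assay(object, "intensity")
    if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "intensities must be non-negative")
  }
  if (!"n_peptides" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'n_peptides' is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated protein identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample identifiers")
  if (length(msg)) msg else TRUE
})

#' Container for normalized protein abundances (FOT)
#'
#' An `AbundanceExperiment` holds per-sample normalized protein abundances
#' (FOT, fraction of total) together with the detection history of every
#' entry. It extends [SummarizedExperiment::SummarizedExperiment] with
#' three aligned assays:
#' \describe{
#'   \item{`fot`}{non-negative abundance fractions (proteins x samples);}
#'   \item{`detected`}{logical, `TRUE` where the protein was identified in
#'     the sample (pre-imputation value > 0);}
#'   \item{`imputed`}{logical, `TRUE` where the value was filled in by the
#'     per-sample minimum/10 rule.}
#' }
#' An entry can never be both detected and imputed.
#'
#' @seealso [computeFOT()], [imputeMissing()], [fot()], [detected()]
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("fot", "detected", "imputed")
  if (!all(need %in% an)) {
    msg <- c(msg, sprintf("assays %s are required",
                          paste(sQuote(need), collapse = ", ")))
  } else {
    f <- SummarizedExperiment::assay(object, "fot")
    d <- SummarizedExperiment::assay(object, "detected")
    i <- SummarizedExperiment::assay(object, "imputed")
    if (any(f < 0, na.rm = TRUE)) msg <- c(msg, "fot values must be non-negative")
    if (!is.logical(d) || !is.logical(i))
      msg <- c(msg, "'detected' and 'imputed' must be logical matrices")
    else {
      if (any(d & i)) msg <- c(msg, "an entry cannot be both detected and imputed")
      if (any(i & !(f > 0))) msg <- c(msg, "imputed entries must carry positive fot")
    }
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated protein identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample identifiers")
  if (length(msg)) msg else TRUE
})

#' Consensus NMF clustering result for one cluster number
#'
#' Aggregates the random-restart consensus matrix at a fixed cluster number
#' `k`, the sample labels extracted from it by average-linkage hierarchical
#' clustering, and silhouette statistics computed on the dissimilarity
#' `1 - consensus`.
#'
#' @slot k integer cluster number.
#' @slot consensus samples x samples co-clustering frequency matrix in
#'   \[0, 1\], symmetric with unit diagonal.
#' @slot labels integer cluster membership (1..k), named by sample.
#' @slot silhouette per-sample silhouette widths on `1 - consensus`.
#' @slot averageSilhouette mean silhouette width.
#' @slot minClassSize size of the smallest cluster.
#' @slot nRuns number of random-restart NMF runs aggregated.
#' @slot baseSeed seed of the first run; run r uses `baseSeed + r - 1`.
#' @export
setClass("ConsensusClustering",
  representation(k = "integer", consensus = "matrix", labels = "integer",
                 silhouette = "numeric", averageSilhouette = "numeric",
                 minClassSize = "integer", nRuns = "integer",
                 baseSeed = "integer"))

setValidity("ConsensusClustering", function(object) {
  msg <- character()
  C <- object@consensus
  if (nrow(C) != ncol(C)) msg <- c(msg, "consensus matrix must be square")
  else {
    if (max(abs(C - t(C))) > 1e-12) msg <- c(msg, "consensus matrix must be symmetric")
    if (any(C < -1e-12) || any(C > 1 + 1e-12))
      msg <- c(msg, "consensus entries must lie in [0, 1]")
    if (max(abs(diag(C) - 1)) > 1e-12)
      msg <- c(msg, "consensus diagonal must be 1")
  }
  if (length(object@labels) != nrow(C))
    msg <- c(msg, "one label per sample required")
  if (length(msg)) msg else TRUE
})

#' Random-forest subtype classifier
#'
#' Wraps a fitted [randomForest::randomForest] model together with the
#' ordered feature panel, the stratified cross-validation layout used for
#' tuning, and the resulting cross-validated accuracy, so that external
#' cohorts can be classified reproducibly.
#'
#' @slot forest the fitted random forest.
#' @slot features ordered protein identifiers used as predictors.
#' @slot classLevels subtype labels the model can emit, hazard-ordered.
#' @slot mtry chosen candidate-features-per-split.
#' @slot nTrees number of trees.
#' @slot seed integer seed governing folds and forests.
#' @slot folds integer fold id (1..10) per training sample, named.
#' @slot cvAccuracy mean held-out accuracy at the chosen `mtry`.
#' @slot cvConfusion held-out confusion matrix (truth x prediction).
#' @slot cvGrid data.frame of the tuning grid with per-`mtry` CV accuracy.
#' @export
setClass("SubtypeClassifier",
  representation(forest = "ANY", features = "character",
                 classLevels = "character", mtry = "integer",
                 nTrees = "integer", seed = "integer", folds = "integer",
                 cvAccuracy = "numeric", cvConfusion = "matrix",
                 cvGrid = "data.frame"))

setValidity("SubtypeClassifier", function(object) {
  msg <- character()
  if (anyDuplicated(object@features)) msg <- c(msg, "duplicated features")
  if (length(object@folds)) {
    tab <- table(object@folds)
    if (max(tab) - min(tab) > ceiling(length(object@folds) / length(tab)))
      msg <- c(msg, "fold sizes implausibly unbalanced")
  }
  if (length(object@cvAccuracy) == 1 &&
      (object@cvAccuracy < 0 || object@cvAccuracy > 1))
    msg <- c(msg, "cvAccuracy must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
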