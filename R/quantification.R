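#' iBAQ quantification
#'
#' Divides each protein's raw intensity by its number of theoretically
#' observable peptides. Zeros (undetected entries) are preserved.
#'
#' @param object an [IntensityExperiment-class].
#' @return numeric matrix of iBAQ values (proteins x samples).
#' @examples
#' m <- matrix(c(100, 0, 40, 10), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' ie <- IntensityExperiment(m, n_peptides = c(4L, 7L))
#' computeIBAQ(ie)  # P1/s1 = 25
#' @export
computeIBAQ <- function(object) {
  stopifnot(is(object, "IntensityExperiment"))
  np <- nPeptides(object)
  bad <- which(is.na(np) | np < 1L)
  if (length(bad)) {
    stop("theoretical peptide count < 1 for protein(s): ",
         paste(names(np)[bad], collapse = ", "))
  }
  intensities(object) / np
}

#' FOT normalization
#'
#' Converts an iBAQ matrix to fraction-of-total (FOT) abundances: each
#' value is divided by the column (per-sample) sum of iBAQs over all
#' identified proteins, so every sample's detected entries sum to 1.
#' Detection is recorded as `input > 0`.
#'
#' @param ibaq non-negative numeric matrix (proteins x samples) with
#'   dimnames, e.g. from [computeIBAQ()].
#' @param colData optional per-sample annotation to carry along.
#' @return an [AbundanceExperiment-class] with all-`FALSE` imputation mask.
#' @export
computeFOT <- function(ibaq, colData = NULL) {
  ibaq <- as.matrix(ibaq)
  if (any(ibaq < 0)) stop("iBAQ values must be non-negative")
  cs <- colSums(ibaq)
  zero <- which(cs == 0)
  if (length(zero)) {
    stop("sample(s) with no identified proteins: ",
         paste(colnames(ibaq)[zero], collapse = ", "))
  }
  f <- sweep(ibaq, 2, cs, "/")
  det <- ibaq > 0
  .new_abundance(f, det, matrix(FALSE, nrow(f), ncol(f), dimnames = dimnames(f)),
                 colData = colData)
}

#' Per-sample minimum/10 missing-value imputation
#'
#' Every undetected entry of a sample is replaced by one tenth of that
#' sample's smallest positive FOT value. Detected values and the detection
#' mask are untouched; the imputation mask records the filled entries. The
#' operation is idempotent. Proteins never detected in any sample are
#' dropped with a warning (their abundance is unknowable in this cohort).
#'
#' @param object an [AbundanceExperiment-class].
#' @return the imputed [AbundanceExperiment-class].
#' @examples
#' f <- matrix(c(0, 0.01, 0.4, 0.2, 0.3, 0.5), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' ae <- computeFOT(f)
#' fot(imputeMissing(ae))[, "s1"]  # A becomes 0.001
#' @export
imputeMissing <- function(object) {
  stopifnot(is(object, "AbundanceExperiment"))
  never <- rowSums(detected(object)) == 0
  if (any(never)) {
    warning(sprintf("dropping %d protein(s) never detected in this cohort",
                    sum(never)))
    object <- object[!never, ]
  }
  f <- fot(object)
  det <- detected(object)
  imp <- imputed(object)
  for (j in seq_len(ncol(f))) {
    pos <- f[, j][f[, j] > 0]
    if (!length(pos)) stop("sample with zero detected proteins: ",
                           colnames(f)[j])
    fill <- !det[, j] & !imp[, j]
    f[fill, j] <- min(pos) / 10
    imp[fill, j] <- TRUE
  }
  .new_abundance(f, det, imp,
                 colData = SummarizedExperiment::colData(object))
}

#' Quantify a cohort end to end
#'
#' Convenience chain `computeIBAQ` -> `computeFOT` -> `imputeMissing`,
#' carrying the clinical annotation through.
#'
#' @param object an [IntensityExperiment-class].
#' @return an imputed [AbundanceExperiment-class].
#' @export
quantifyCohort <- function(object) {
  ib <- computeIBAQ(object)
  ae <- computeFOT(ib, colData = SummarizedExperiment::colData(object))
  imputeMissing(ae)
}
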