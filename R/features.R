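#' Union of each sample's top-N most abundant detected proteins
#'
#' For every sample, the `n` detected proteins with the highest FOT are
#' taken; the union over samples is returned. Ties at the rank-n boundary
#' are all included, so the result is deterministic and invariant to
#' protein order. Samples with fewer than `n` detected proteins contribute
#' all of them.
#'
#' @param object an [AbundanceExperiment-class].
#' @param n positive integer rank cutoff per sample.
#' @return character vector of protein ids (in matrix row order).
#' @export
topNUnion <- function(object, n) {
  stopifnot(is(object, "AbundanceExperiment"))
  .check_scalar(n, "n", positive = TRUE, integerish = TRUE)
  f <- fot(object)
  if (nrow(f) == 0 || ncol(f) == 0) stop("empty abundance matrix")
  det <- detected(object)
  keep <- logical(nrow(f))
  for (j in seq_len(ncol(f))) {
    v <- f[, j]
    v[!det[, j]] <- NA
    obs <- v[!is.na(v)]
    if (!length(obs)) next
    if (length(obs) <= n) {
      keep <- keep | !is.na(v)
    } else {
      thr <- sort(obs, decreasing = TRUE)[n]
      keep <- keep | (!is.na(v) & v >= thr)  # >= keeps boundary ties
    }
  }
  rownames(f)[keep]
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector with strictly positive mean.
#' @return non-negative scalar.
#' @export
computeCV <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("'values' must be a numeric vector of length >= 2")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("coefficient of variation undefined: mean is not positive")
  sd(values) / m
}

# Per-protein summary used by both selectors.
.protein_stats <- function(object) {
  f <- fot(object)
  det <- detected(object)
  n <- ncol(f)
  means <- rowMeans(f)
  sds <- apply(f, 1, sd)
  data.frame(protein_id = rownames(f),
             detect_count = as.integer(rowSums(det)),
             detect_fraction = rowSums(det) / n,
             mean_fot = means,
             cv = ifelse(means > 0, sds / means, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select clustering features: top-N union, detection frequency, CV
#'
#' Reproduces the two-stage selection used ahead of consensus NMF: the
#' union of each sample's `topN` most abundant detected proteins is
#' filtered to proteins detected in strictly more than
#' `minDetectFraction` of samples whose coefficient of variation across
#' all (imputed) samples is strictly greater than `cvThreshold`. At 75
#' samples the 10% rule reproduces "detected in at least 8 samples".
#'
#' @param object an imputed [AbundanceExperiment-class].
#' @param topN per-sample abundance rank cutoff (default 1100).
#' @param minDetectFraction strict lower bound on detection fraction
#'   (default 0.10).
#' @param cvThreshold strict lower bound on the CV (default 1.9).
#' @return a data.frame (class `"FeatureSet"`) with one row per retained
#'   protein and columns `protein_id`, `detect_count`, `detect_fraction`,
#'   `mean_fot`, `cv`; attribute `stage = "clustering"`, attribute
#'   `candidates` holds the pre-filter top-N union size.
#' @export
selectClusteringFeatures <- function(object, topN = 1100,
                                     minDetectFraction = 0.10,
                                     cvThreshold = 1.9) {
  cand <- topNUnion(object, topN)
  stats <- .protein_stats(object)
  stats <- stats[stats$protein_id %in% cand, , drop = FALSE]
  keep <- stats$detect_fraction > minDetectFraction &
    !is.na(stats$cv) & stats$cv > cvThreshold
  out <- stats[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no proteins satisfy the clustering-feature thresholds; ",
         "consider relaxing 'cvThreshold' or 'minDetectFraction'")
  }
  rownames(out) <- NULL
  attr(out, "stage") <- "clustering"
  attr(out, "candidates") <- length(cand)
  class(out) <- c("FeatureSet", class(out))
  out
}

#' Select classifier candidate proteins: top-N union + detection frequency
#'
#' As [selectClusteringFeatures()] but without the CV filter: the union of
#' each sample's `topN` most abundant proteins, restricted to proteins
#' detected in strictly more than `minDetectFraction` of samples.
#' Differential-expression filtering happens later in
#' [classifierFeatures()].
#'
#' @param object an imputed [AbundanceExperiment-class].
#' @param topN per-sample abundance rank cutoff (default 500).
#' @param minDetectFraction strict lower bound on detection fraction
#'   (default 0.25).
#' @return character vector of candidate protein ids.
#' @export
selectClassifierCandidates <- function(object, topN = 500,
                                       minDetectFraction = 0.25) {
  cand <- topNUnion(object, topN)
  det_frac <- rowSums(detected(object)) / ncol(object)
  names(det_frac) <- rownames(object)
  cand[det_frac[cand] > minDetectFraction]
}
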