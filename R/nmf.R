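#' @useDynLib ProteoSubtype, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' KL-divergence multiplicative-update NMF
#'
#' Factorizes a non-negative matrix `V` (features x samples) as `W %*% H`
#' with `W >= 0`, `H >= 0` by the classical multiplicative updates that
#' minimize the generalized Kullback-Leibler divergence (the "brunet"
#' algorithm). `W` and `H` are initialized uniform-random in (0, 1] under
#' the given seed; updates stop when the relative divergence change over a
#' `window`-iteration lag drops below `tol`, or at `maxIter`.
#'
#' @param V non-negative numeric matrix without all-zero rows or columns.
#' @param k factorization rank, `1 <= k <= min(dim(V))`.
#' @param seed integer seed for the random initialization.
#' @param maxIter maximum number of update sweeps (default 2000).
#' @param tol relative divergence-change tolerance (default 1e-6).
#' @param window lag (iterations) over which the change is measured.
#' @return a list of class `"NMFFit"`: `W`, `H`, `k`, `seed`,
#'   `divergence` (final), `trace` (divergence per iteration,
#'   non-increasing), `iterations`.
#' @export
nmfBrunet <- function(V, k, seed, maxIter = 2000, tol = 1e-6, window = 10) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (any(rowSums(V) == 0)) stop("V has all-zero rows; remove them first")
  if (any(colSums(V) == 0)) stop("V has all-zero columns; remove them first")
  .check_scalar(k, "k", positive = TRUE, integerish = TRUE)
  if (k > min(dim(V))) stop("k must not exceed min(dim(V))")
  init <- withr::with_seed(seed, {
    list(W = matrix(pmax(runif(nrow(V) * k), .Machine$double.eps), nrow(V), k),
         H = matrix(pmax(runif(k * ncol(V)), .Machine$double.eps), k, ncol(V)))
  })
  res <- .nmf_brunet_cpp(V, init$W, init$H, as.integer(maxIter), tol,
                         as.integer(window))
  dimnames(res$W) <- list(rownames(V), NULL)
  dimnames(res$H) <- list(NULL, colnames(V))
  structure(list(W = res$W, H = res$H, k = as.integer(k),
                 seed = as.integer(seed),
                 divergence = res$trace[length(res$trace)],
                 trace = res$trace, iterations = res$iterations),
            class = "NMFFit")
}

# Min-max scale each feature row to [0, 1]; constant rows are rejected
# because they carry no clustering information and break the scaling.
.scale_rows_minmax <- function(m) {
  rng <- apply(m, 1, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    stop("constant feature row(s): ",
         paste(rownames(m)[span == 0], collapse = ", "))
  }
  (m - rng[1, ]) / span
}

#' Build the NMF input matrix from selected features
#'
#' Extracts the FOT sub-matrix of the selected proteins and min-max
#' scales each protein to \[0, 1\] across samples, so the KL objective is
#' not dominated by the few most abundant proteins.
#'
#' @param object an imputed [AbundanceExperiment-class].
#' @param features protein ids (e.g. a `FeatureSet`'s `protein_id`).
#' @return numeric matrix, features x samples, values in \[0, 1\].
#' @export
nmfInput <- function(object, features) {
  if (inherits(features, "FeatureSet")) features <- features$protein_id
  missing <- setdiff(features, rownames(object))
  if (length(missing)) {
    stop("features absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "))
  }
  .scale_rows_minmax(fot(object)[features, , drop = FALSE])
}

#' Consensus NMF clustering at a fixed cluster number
#'
#' Runs `nRuns` random-restart NMF factorizations (run r seeded with
#' `baseSeed + r - 1`), assigns each sample per run to the dominant row of
#' `H` (argmax), and averages the resulting 0/1 co-clustering matrices
#' into a consensus matrix. Final labels come from average-linkage
#' hierarchical clustering of the dissimilarity `1 - consensus` cut at
#' `k`; silhouettes are computed on the same dissimilarity (singleton
#' clusters score 0 by convention).
#'
#' @param V non-negative matrix (features x samples), e.g. [nmfInput()].
#' @param k cluster number.
#' @param nRuns number of random restarts (default 50).
#' @param baseSeed integer seed of the first run.
#' @param ... passed to [nmfBrunet()] (`maxIter`, `tol`, `window`).
#' @return a [ConsensusClustering-class] object.
#' @export
consensusCluster <- function(V, k, nRuns = 50, baseSeed = 1, ...) {
  .check_scalar(nRuns, "nRuns", positive = TRUE, integerish = TRUE)
  V <- as.matrix(V)
  # canonical sample order: the random initializations then depend only
  # on the seed and the sample ids, making the whole path equivariant to
  # column permutations of the input
  orig <- colnames(V)
  if (!is.null(orig)) {
    ord <- order(orig)
    V <- V[, ord, drop = FALSE]
  }
  n <- ncol(V)
  consensus <- matrix(0, n, n)
  for (r in seq_len(nRuns)) {
    fit <- nmfBrunet(V, k, seed = as.integer(baseSeed) + r - 1L, ...)
    cl <- apply(fit$H, 2, which.max)
    consensus <- consensus + outer(cl, cl, "==")
  }
  consensus <- consensus / nRuns
  dimnames(consensus) <- list(colnames(V), colnames(V))
  # exact symmetry/diagonal despite float accumulation
  consensus <- (consensus + t(consensus)) / 2
  diag(consensus) <- 1

  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  sil <- cluster::silhouette(labels, dmatrix = 1 - consensus)
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else rep(0, n)
  if (!is.null(orig)) {
    # back to the caller's sample order
    back <- match(orig, colnames(V))
    consensus <- consensus[back, back]
    labels <- labels[back]
    widths <- widths[back]
  }
  new("ConsensusClustering", k = as.integer(k), consensus = consensus,
      labels = stats::setNames(as.integer(labels), colnames(consensus)),
      silhouette = as.numeric(widths),
      averageSilhouette = mean(widths),
      minClassSize = as.integer(min(table(labels))),
      nRuns = as.integer(nRuns), baseSeed = as.integer(baseSeed))
}

#' Choose the cluster number by stability and prognosis
#'
#' A cluster number `k` is eligible when (i) its average silhouette on the
#' consensus dissimilarity exceeds `silhouetteMin`, (ii) its smallest
#' class has at least `minClass` members, and (iii) the k-group log-rank
#' test on overall survival across its labels has `p < prognosticAlpha`.
#' Among eligible `k`, `rule = "finest"` (default) returns the largest
#' eligible `k`: the finest stratification that is still stable,
#' adequately populated and prognostic. Coarser solutions are typically
#' *more* stable by construction (a consensus over random restarts that
#' all agree on splitting off the single cleanest subgroup is perfectly
#' reproducible), so treating stability as a gate rather than an
#' objective avoids collapsing every cohort to two clusters.
#' `rule = "max-silhouette"` instead returns the eligible `k` with the
#' highest average silhouette (ties: smallest `k`). When nothing is
#' eligible the per-k report is still returned with `chosenK = NA`
#' rather than an error, so the diagnostics survive.
#'
#' @param results list of [ConsensusClustering-class] objects (one per k).
#' @param clinical clinical data.frame with `os_years` and `os_event` in
#'   sample order matching the clustering input.
#' @param silhouetteMin minimum average silhouette (default 0.8, strict).
#' @param minClass minimum members per class (default 10).
#' @param prognosticAlpha log-rank significance level (default 0.01).
#' @param rule `"finest"` (largest eligible k, default) or
#'   `"max-silhouette"`.
#' @return a list of class `"KSelection"`: `chosenK` (integer or `NA`),
#'   `labels` (hazard-ordered subtype names "S-I", ... or `NULL`),
#'   `clusterLabels` (the chosen k's raw integer labels), `report`
#'   (data.frame: k, averageSilhouette, minClassSize, logrankP, eligible).
#' @export
selectK <- function(results, clinical, silhouetteMin = 0.8, minClass = 10,
                    prognosticAlpha = 0.01,
                    rule = c("finest", "max-silhouette")) {
  rule <- match.arg(rule)
  stopifnot(length(results) > 0)
  if (!all(c("os_years", "os_event") %in% names(clinical)))
    stop("clinical table must contain 'os_years' and 'os_event'")
  report <- do.call(rbind, lapply(results, function(res) {
    stopifnot(is(res, "ConsensusClustering"))
    if (length(res@labels) != nrow(clinical))
      stop("clinical rows must match clustered samples")
    p <- if (length(unique(res@labels)) < 2 || sum(clinical$os_event) == 0) {
      NA_real_
    } else {
      logrankTest(clinical$os_years, clinical$os_event, res@labels)$p_value
    }
    data.frame(k = res@k, averageSilhouette = res@averageSilhouette,
               minClassSize = res@minClassSize, logrankP = p)
  }))
  report$eligible <- report$averageSilhouette > silhouetteMin &
    report$minClassSize >= minClass &
    !is.na(report$logrankP) & report$logrankP < prognosticAlpha
  rownames(report) <- NULL

  if (!any(report$eligible)) {
    return(structure(list(chosenK = NA_integer_, labels = NULL,
                          clusterLabels = NULL, report = report),
                     class = "KSelection"))
  }
  elig <- report[report$eligible, , drop = FALSE]
  best <- if (rule == "finest") {
    max(elig$k)
  } else {
    elig[order(-elig$averageSilhouette, elig$k), ][1, "k"]
  }
  chosen <- results[[which(report$k == best)]]
  named <- nameSubtypesByHazard(chosen@labels, clinical)
  structure(list(chosenK = as.integer(best), labels = named,
                 clusterLabels = chosen@labels, report = report),
            class = "KSelection")
}

#' Name clusters by ascending overall-survival hazard
#'
#' Assigns the reproducible subtype names "S-I", "S-II", ... to integer
#' cluster labels in order of increasing crude event hazard
#' (events / person-years), so "S-I" is always the best-prognosis cluster.
#'
#' @param labels integer cluster labels, one per clinical row.
#' @param clinical data.frame with `os_years`, `os_event`.
#' @return factor of subtype names, same length and names as `labels`.
#' @export
nameSubtypesByHazard <- function(labels, clinical) {
  stopifnot(length(labels) == nrow(clinical))
  haz <- vapply(split(seq_along(labels), labels), function(i) {
    pt <- sum(clinical$os_years[i])
    if (pt <= 0) Inf else sum(clinical$os_event[i]) / pt
  }, numeric(1))
  ord <- names(sort(haz))
  nm <- .subtype_names(length(ord))
  mapped <- nm[match(as.character(labels), ord)]
  factor(stats::setNames(mapped, names(labels)), levels = nm)
}
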