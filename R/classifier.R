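# Stratified, size-balanced fold assignment: within each class, shuffled
# samples are dealt round-robin across folds. Input must already be in a
# canonical sample order so the partition depends only on ids and seed.
.stratified_folds <- function(labels, nfolds, seed) {
  labels <- factor(labels)
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    offset <- 0L
    for (s in levels(labels)) {
      idx <- sample(which(labels == s))
      folds[idx] <- as.integer((seq_along(idx) + offset - 1L) %% nfolds) + 1L
      offset <- offset + length(idx)  # stagger so folds stay balanced
    }
  })
  folds
}

#' Train the random-forest subtype classifier
#'
#' Fits a random forest on log10 FOT of the feature panel. The
#' candidate-features-per-split parameter (`mtry`) is tuned over the grid
#' {sqrt(p), p/4, p/2} by stratified 10-fold cross-validation; the
#' reported `cvAccuracy` is the mean held-out accuracy at the chosen grid
#' point. The final model is refit on all samples. Everything (folds,
#' forests) is deterministic under the given seed.
#'
#' @param object an imputed [AbundanceExperiment-class].
#' @param labels subtype labels per sample (factor or character).
#' @param features ordered feature panel from [classifierFeatures()].
#' @param seed integer seed (mandatory).
#' @param nTrees trees per forest (default 500).
#' @param nFolds cross-validation folds (default 10).
#' @return a [SubtypeClassifier-class].
#' @export
trainClassifier <- function(object, labels, features, seed, nTrees = 500,
                            nFolds = 10) {
  labels <- factor(labels)
  stopifnot(length(labels) == ncol(object))
  if (!length(features)) stop("empty feature panel")
  if (ncol(object) < nFolds)
    stop("need at least ", nFolds, " samples for ", nFolds, "-fold CV")
  missing <- setdiff(features, rownames(object))
  if (length(missing)) {
    stop("feature(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  }
  # canonical sample order: folds and forests depend only on ids + seed,
  # never on the column order of the input matrix
  ord <- order(colnames(object))
  object <- object[, ord]
  labels <- labels[ord]
  X <- t(log10(fot(object)[features, , drop = FALSE]))
  colnames(X) <- make.names(features)  # RF-safe column names
  p <- length(features)
  grid <- sort(unique(pmax(1L, as.integer(floor(
    c(sqrt(p), p / 4, p / 2))))))
  folds <- .stratified_folds(labels, nFolds, seed)

  cv_one <- function(mtry) {
    preds <- factor(rep(NA_character_, length(labels)),
                    levels = levels(labels))
    for (fo in sort(unique(folds))) {
      tr <- folds != fo
      fit <- withr::with_seed(seed + 1000L * mtry + fo, {
        randomForest::randomForest(X[tr, , drop = FALSE],
                                   droplevels(labels[tr]),
                                   ntree = nTrees, mtry = mtry)
      })
      pr <- predict(fit, X[!tr, , drop = FALSE])
      preds[!tr] <- factor(as.character(pr), levels = levels(labels))
    }
    list(acc = mean(preds == labels), preds = preds)
  }
  cv_res <- lapply(grid, cv_one)
  acc <- vapply(cv_res, `[[`, numeric(1), "acc")
  best <- which.max(acc)  # ties: first (smallest mtry)
  final <- withr::with_seed(seed, {
    randomForest::randomForest(X, labels, ntree = nTrees,
                               mtry = grid[best])
  })
  conf <- table(truth = labels, prediction = cv_res[[best]]$preds)
  new("SubtypeClassifier", forest = final, features = features,
      classLevels = levels(labels), mtry = as.integer(grid[best]),
      nTrees = as.integer(nTrees), seed = as.integer(seed),
      folds = stats::setNames(folds, colnames(object)),
      cvAccuracy = acc[best],
      cvConfusion = unclass(as.matrix(conf)),
      cvGrid = data.frame(mtry = grid, cv_accuracy = acc))
}

#' Classify an external cohort
#'
#' Applies the trained classifier to an externally quantified cohort
#' (same iBAQ/FOT/imputation pipeline). Panel proteins absent from the
#' external matrix are filled with each sample's imputation constant
#' (minimum positive FOT / 10) before log transform; if more than half of
#' the panel is entirely absent the panel is deemed non-transferable and
#' the call errors.
#'
#' @param model a [SubtypeClassifier-class].
#' @param object an imputed [AbundanceExperiment-class] of the external
#'   cohort.
#' @return data.frame: `sample_id`, `label`, one probability column per
#'   class (rows sum to 1).
#' @export
predictSubtypes <- function(model, object) {
  stopifnot(is(model, "SubtypeClassifier"),
            is(object, "AbundanceExperiment"))
  feats <- model@features
  absent <- setdiff(feats, rownames(object))
  if (length(absent) > length(feats) / 2) {
    stop(sprintf(paste0("panel not transferable: %d of %d features absent ",
                        "from the external cohort"),
                 length(absent), length(feats)))
  }
  f <- fot(object)
  fill <- apply(f, 2, function(col) min(col[col > 0]) / 10)
  M <- matrix(rep(fill, each = length(feats)), nrow = length(feats),
              dimnames = list(feats, colnames(f)))
  present <- intersect(feats, rownames(f))
  M[present, ] <- f[present, , drop = FALSE]
  # entries that are 0 (external matrix not imputed) get the sample fill
  for (j in seq_len(ncol(M))) M[M[, j] == 0, j] <- fill[j]
  X <- t(log10(M))
  colnames(X) <- make.names(feats)
  prob <- predict(model@forest, X, type = "prob")
  prob <- prob / rowSums(prob)
  lab <- model@classLevels[max.col(prob, ties.method = "first")]
  out <- data.frame(sample_id = colnames(object),
                    label = factor(lab, levels = model@classLevels),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(prob))
}
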