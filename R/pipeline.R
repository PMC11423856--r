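#' Run the full discovery analysis
#'
#' Executes the discovery chain on a cohort: quantification (when given
#' raw intensities), clustering feature selection, consensus NMF across
#' the `k` range, stability/prognosis selection of `k`, hazard-ordered
#' subtype naming, subtype signatures, classifier feature panel,
#' random-forest training, and the survival analyses (subtype log-rank,
#' multivariate Cox, chemotherapy benefit within TNM II/III). A manifest
#' records stage timings, counts after every filter, and digests of the
#' inputs so reruns are auditable.
#'
#' @param cohort an [IntensityExperiment-class] or an imputed
#'   [AbundanceExperiment-class].
#' @param clinical clinical data.frame (validated by
#'   [validateClinical()]), rows aligned with cohort samples.
#' @param params list of thresholds as in [pipelineDefaults()]; `seed`
#'   must be set.
#' @return list of class `"DiscoveryRun"` with elements `abundance`,
#'   `features`, `kSelection`, `subtypes` (named labels or `NULL` when no
#'   k is eligible), `signatures`, `classifier`, `survival` (log-rank,
#'   Cox table, per-subtype KM, chemo-benefit), `manifest`.
#' @export
runDiscovery <- function(cohort, clinical, params = list()) {
  params <- utils::modifyList(pipelineDefaults(), params)
  if (is.null(params$seed)) stop("'seed' is mandatory")
  validateClinical(clinical)
  if (nrow(clinical) != ncol(cohort))
    stop("clinical rows must match cohort samples")
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  ae <- if (is(cohort, "IntensityExperiment")) {
    suppressWarnings(quantifyCohort(cohort))
  } else if (is(cohort, "AbundanceExperiment")) {
    if (!any(imputed(cohort)) && any(!detected(cohort))) {
      suppressWarnings(imputeMissing(cohort))
    } else cohort
  } else stop("cohort must be an IntensityExperiment or AbundanceExperiment")
  tick("quantification")

  feats <- selectClusteringFeatures(ae, topN = params$clustering_top_n,
                                    minDetectFraction = params$clustering_min_detect,
                                    cvThreshold = params$cv_threshold)
  V <- nmfInput(ae, feats)
  tick("feature_selection")

  cons <- lapply(params$k_range, function(k) {
    consensusCluster(V, k, nRuns = params$n_runs,
                     baseSeed = params$seed + 1000L * k)
  })
  ksel <- selectK(cons, clinical, silhouetteMin = params$silhouette_min,
                  minClass = params$min_class,
                  prognosticAlpha = params$prognostic_alpha)
  tick("consensus_nmf")

  subtypes <- ksel$labels
  signatures <- NULL
  classifier <- NULL
  surv <- NULL
  if (!is.na(ksel$chosenK)) {
    signatures <- subtypeSignatures(
      ae, subtypes,
      fcThresholds = .match_fc_thresholds(params$signature_fc,
                                          levels(subtypes)),
      alpha = params$signature_alpha)
    cand <- selectClassifierCandidates(ae, topN = params$classifier_top_n,
                                       minDetectFraction = params$classifier_min_detect)
    panel <- classifierFeatures(ae, subtypes, cand,
                                fcMin = params$classifier_fc_min,
                                alpha = params$classifier_alpha)
    tick("signatures")
    classifier <- trainClassifier(ae, subtypes, panel,
                                  seed = params$seed,
                                  nTrees = params$n_trees,
                                  nFolds = params$n_folds)
    tick("classifier")

    lr <- logrankTest(clinical$os_years, clinical$os_event, subtypes)
    km <- lapply(split(seq_len(nrow(clinical)), subtypes), function(i) {
      kmEstimate(clinical$os_years[i], clinical$os_event[i])
    })
    cox_cov <- data.frame(subtype = subtypes)
    for (col in c("age", "gender", "smoking", "lnm", "tnm_stage",
                  "valg_stage", "chemotherapy")) {
      if (col %in% names(clinical) &&
          length(unique(clinical[[col]])) > 1) {
        cox_cov[[col]] <- clinical[[col]]
      }
    }
    cox <- tryCatch(coxPH(clinical$os_years, clinical$os_event, cox_cov),
                    error = function(e) e)
    chemo <- if (all(c("tnm_stage", "chemotherapy") %in% names(clinical))) {
      chemoBenefitAnalysis(clinical, subtypes)
    }
    surv <- list(logrank = lr, km = km, cox = cox, chemoBenefit = chemo)
    tick("survival")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ProteoSubtype")),
    seed = params$seed,
    input_digest = .object_digest(list(fot(ae), clinical)),
    config_digest = .object_digest(params),
    n_proteins = nrow(ae), n_samples = ncol(ae),
    n_topn_candidates = attr(feats, "candidates"),
    n_clustering_features = nrow(feats),
    n_classifier_features = if (is.null(classifier)) 0L else
      length(classifier@features),
    chosen_k = ksel$chosenK,
    timings = timings)

  structure(list(abundance = ae, features = feats, kSelection = ksel,
                 subtypes = subtypes, signatures = signatures,
                 classifier = classifier, survival = surv,
                 manifest = manifest),
            class = "DiscoveryRun")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.match_fc_thresholds <- function(fc, levels) {
  if (!is.null(names(fc)) && all(levels %in% names(fc))) return(fc[levels])
  if (length(fc) == length(levels)) return(stats::setNames(fc, levels))
  stop("signature fold-change thresholds do not match the subtype levels")
}

#' Validate the subtyping model on an external cohort
#'
#' Quantifies the external cohort if needed, predicts subtype labels with
#' the trained classifier, and (when more than one sample and more than
#' one predicted class are present) compares overall survival across
#' predicted subtypes by Kaplan-Meier/log-rank.
#'
#' @param model a [SubtypeClassifier-class], e.g. from a discovery run.
#' @param cohort an [IntensityExperiment-class] or imputed
#'   [AbundanceExperiment-class] of the external cohort.
#' @param clinical clinical data.frame for the external samples.
#' @return list: `predictions` (from [predictSubtypes()]), `logrank`
#'   (or `NULL` with a warning when not computable), `km` per predicted
#'   subtype.
#' @export
runValidation <- function(model, cohort, clinical) {
  validateClinical(clinical)
  ae <- if (is(cohort, "IntensityExperiment")) {
    suppressWarnings(quantifyCohort(cohort))
  } else cohort
  if (nrow(clinical) != ncol(ae))
    stop("clinical rows must match cohort samples")
  pred <- predictSubtypes(model, ae)
  lr <- NULL
  km <- NULL
  if (nrow(pred) < 2 || length(unique(pred$label)) < 2) {
    warning("survival comparison skipped: need >= 2 samples in >= 2 ",
            "predicted subtypes")
  } else {
    lr <- logrankTest(clinical$os_years, clinical$os_event,
                      droplevels(pred$label))
    km <- lapply(split(seq_len(nrow(clinical)), droplevels(pred$label)),
                 function(i) kmEstimate(clinical$os_years[i],
                                        clinical$os_event[i]))
  }
  list(predictions = pred, logrank = lr, km = km)
}
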