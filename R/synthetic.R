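#' Design of a synthetic SCLC-like proteomic cohort
#'
#' A `CohortDesign` captures every parameter of the synthetic cohort
#' generator: cohort size, latent subtype structure, the log-normal
#' abundance model with planted multiplicative overexpression signatures,
#' the logistic abundance-dependent dropout model, and the exponential
#' survival model with subtype-specific chemotherapy interactions. The
#' defaults emulate a 75-sample discovery cohort of ~7000 proteins with
#' heavy per-sample missingness, three subtypes with signature fold
#' changes (3, 3, 10), and five-year survival spanning ~75% (best
#' subtype) down to ~4% (worst).
#'
#' @slot nSamples,nProteins cohort dimensions.
#' @slot nSubtypes number of latent subtypes.
#' @slot subtypeProportions probability vector over subtypes (sums to 1).
#' @slot signatureSize planted signature proteins per subtype (disjoint sets).
#' @slot signatureFoldChange multiplicative overexpression per subtype (> 1).
#' @slot signatureLogMean,signatureLogSD natural-log mean/sd of the
#'   *activated* (own-subtype) intensity of signature proteins; the
#'   resting baseline of each marker is this level divided by its
#'   subtype's fold change. Anchoring the activated state rather than the
#'   baseline mirrors marker biology - a 10-fold-overexpressed marker has
#'   a lower resting level, not a higher activated one - and places the
#'   resting state near or below the dropout midpoint, giving markers the
#'   presence/absence behaviour (and hence the high coefficient of
#'   variation) that subtype markers show in label-free FFPE data.
#' @slot baseAbundanceLogMean,baseAbundanceLogSD natural-log mean/sd of the
#'   per-protein baseline intensity.
#' @slot noiseLogSD natural-log sd of multiplicative per-entry sample noise.
#' @slot dropoutMidpoint,dropoutSlope logistic detection-probability model
#'   on latent log intensity: `plogis(slope * (log(x) - midpoint))`. A slope
#'   of 0 with a low midpoint disables dropout.
#' @slot hazardRates per-subtype exponential OS event rate (per year).
#' @slot treatmentLogHR per-subtype log hazard ratio of chemotherapy
#'   (negative = benefit).
#' @slot pfsHazardRates per-subtype exponential progression rate (per year)
#'   used when a fraction of the cohort is ICI-treated.
#' @slot censoringRate exponential censoring rate (per year).
#' @slot followupMaxYears administrative follow-up cap.
#' @slot chemoFraction probability a patient received chemotherapy.
#' @slot iciFraction,iciFirstFraction fraction of patients treated with
#'   immune checkpoint inhibitors, and, among those, fraction treated in
#'   first line.
#' @slot tnmProportions probability vector over TNM stages I-IV.
#' @slot valgLsFraction probability of limited-stage (LS) VALG status.
#' @slot seed default integer seed.
#' @seealso [cohortDesign()], [simulateCohort()]
#' @export
setClass("CohortDesign",
  representation(nSamples = "integer", nProteins = "integer",
                 nSubtypes = "integer", subtypeProportions = "numeric",
                 signatureSize = "integer", signatureFoldChange = "numeric",
                 signatureLogMean = "numeric", signatureLogSD = "numeric",
                 baseAbundanceLogMean = "numeric", baseAbundanceLogSD = "numeric",
                 noiseLogSD = "numeric", dropoutMidpoint = "numeric",
                 dropoutSlope = "numeric", hazardRates = "numeric",
                 treatmentLogHR = "numeric", pfsHazardRates = "numeric",
                 censoringRate = "numeric", followupMaxYears = "numeric",
                 chemoFraction = "numeric", iciFraction = "numeric",
                 iciFirstFraction = "numeric", tnmProportions = "numeric",
                 valgLsFraction = "numeric", seed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  k <- object@nSubtypes
  if (abs(sum(object@subtypeProportions) - 1) > 1e-12)
    msg <- c(msg, "subtypeProportions must sum to 1 (within 1e-12)")
  if (length(object@subtypeProportions) != k)
    msg <- c(msg, "one subtype proportion per subtype required")
  for (nm in c("signatureFoldChange", "hazardRates", "treatmentLogHR",
               "pfsHazardRates")) {
    if (length(slot(object, nm)) != k)
      msg <- c(msg, sprintf("'%s' must have one entry per subtype", nm))
  }
  if (any(object@signatureFoldChange <= 1))
    msg <- c(msg, "signature fold changes must exceed 1")
  if (any(object@hazardRates <= 0) || any(object@pfsHazardRates <= 0))
    msg <- c(msg, "hazard rates must be strictly positive")
  if (object@censoringRate < 0)
    msg <- c(msg, "censoringRate must be non-negative")
  if (abs(sum(object@tnmProportions) - 1) > 1e-12 ||
      length(object@tnmProportions) != 4L)
    msg <- c(msg, "tnmProportions must be 4 probabilities summing to 1")
  if (object@nSubtypes * object@signatureSize > object@nProteins)
    msg <- c(msg, "signature sets exceed the number of proteins")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic cohort design
#'
#' All arguments default to the emulated discovery-cohort conditions; see
#' [CohortDesign-class] for their meaning.
#'
#' @param nSamples,nProteins,nSubtypes cohort dimensions.
#' @param subtypeProportions,signatureSize,signatureFoldChange subtype
#'   structure; fold-change defaults (3, 3, 10).
#' @param baseAbundanceLogMean,baseAbundanceLogSD,noiseLogSD abundance model.
#' @param dropoutMidpoint,dropoutSlope logistic dropout model.
#' @param hazardRates,treatmentLogHR,pfsHazardRates,censoringRate,
#'   followupMaxYears survival model. Hazard defaults give five-year OS of
#'   about 75%, 35% and 4% for the three subtypes.
#' @param chemoFraction,iciFraction,iciFirstFraction treatment assignment.
#' @param tnmProportions,valgLsFraction staging distribution (independent of
#'   subtype).
#' @param seed default seed used by [simulateCohort()].
#' @return a validated [CohortDesign-class] object.
#' @examples
#' d <- cohortDesign(nSamples = 20, nProteins = 500, signatureSize = 10)
#' sim <- simulateCohort(d, seed = 1)
#' table(sim$truth$labels)
#' @export
cohortDesign <- function(nSamples = 75L, nProteins = 7000L, nSubtypes = 3L,
                         subtypeProportions = c(28, 20, 27) / 75,
                         signatureSize = 150L,
                         signatureFoldChange = c(3, 3, 10),
                         baseAbundanceLogMean = log(1e6),
                         baseAbundanceLogSD = 2,
                         signatureLogMean = log(1e6) + 0.6,
                         signatureLogSD = 0.5,
                         noiseLogSD = 0.8,
                         dropoutMidpoint = log(1e6) + 0.5,
                         dropoutSlope = 2.5,
                         hazardRates = c(0.0575, 0.21, 0.66),
                         treatmentLogHR = c(-1.2, 0.7, 0),
                         pfsHazardRates = 2 * hazardRates,
                         censoringRate = 0.08,
                         followupMaxYears = 8,
                         chemoFraction = 0.44,
                         iciFraction = 0,
                         iciFirstFraction = 0.7,
                         tnmProportions = c(13, 19, 28, 13) / 73,
                         valgLsFraction = 0.827,
                         seed = 1L) {
  .check_scalar(nSamples, "nSamples", positive = TRUE, integerish = TRUE)
  .check_scalar(nProteins, "nProteins", positive = TRUE, integerish = TRUE)
  .check_scalar(nSubtypes, "nSubtypes", positive = TRUE, integerish = TRUE)
  .check_scalar(signatureSize, "signatureSize", positive = TRUE,
                integerish = TRUE)
  new("CohortDesign",
      nSamples = as.integer(nSamples), nProteins = as.integer(nProteins),
      nSubtypes = as.integer(nSubtypes),
      subtypeProportions = subtypeProportions,
      signatureSize = as.integer(signatureSize),
      signatureFoldChange = signatureFoldChange,
      signatureLogMean = signatureLogMean, signatureLogSD = signatureLogSD,
      baseAbundanceLogMean = baseAbundanceLogMean,
      baseAbundanceLogSD = baseAbundanceLogSD,
      noiseLogSD = noiseLogSD,
      dropoutMidpoint = dropoutMidpoint, dropoutSlope = dropoutSlope,
      hazardRates = hazardRates, treatmentLogHR = treatmentLogHR,
      pfsHazardRates = pfsHazardRates,
      censoringRate = censoringRate, followupMaxYears = followupMaxYears,
      chemoFraction = chemoFraction, iciFraction = iciFraction,
      iciFirstFraction = iciFirstFraction,
      tnmProportions = tnmProportions, valgLsFraction = valgLsFraction,
      seed = as.integer(seed))
}

# Deterministic disjoint signature index sets, one per subtype.
.assign_signatures <- function(design) {
  total <- design@nSubtypes * design@signatureSize
  idx <- sample.int(design@nProteins, total)
  split(idx, rep(seq_len(design@nSubtypes), each = design@signatureSize))
}

#' Simulate survival outcomes for labelled, treated samples
#'
#' Event times are exponential with hazard
#' `hazardRates[subtype] * exp(treatmentLogHR[subtype] * treatment)`;
#' censoring is an independent exponential at `censoringRate`, capped at
#' `followupMaxYears`. The observed time is the minimum of the three and
#' the event flag records whether the event came first.
#'
#' @param labels integer subtype labels (1..nSubtypes), one per sample.
#' @param treatment logical (or 0/1) treatment flags, same length.
#' @param design a [CohortDesign-class].
#' @param seed integer seed; the call is deterministic given it.
#' @param hazards,loghr optional overrides of the per-subtype event rates
#'   and treatment log hazard ratios (used for PFS simulation).
#' @return data.frame with columns `time` (years) and `event` (logical).
#' @export
simulateSurvival <- function(labels, treatment, design, seed,
                             hazards = design@hazardRates,
                             loghr = design@treatmentLogHR) {
  if (length(labels) != length(treatment))
    stop("'labels' and 'treatment' must have the same length")
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > design@nSubtypes))
    stop("labels must lie in 1..nSubtypes")
  treatment <- as.logical(treatment)
  withr::with_seed(seed, {
    n <- length(labels)
    h <- hazards[labels] * exp(loghr[labels] * as.numeric(treatment))
    t_event <- rexp(n, rate = h)
    t_cens <- if (design@censoringRate > 0) {
      rexp(n, rate = design@censoringRate)
    } else rep(Inf, n)
    t_cens <- pmin(t_cens, design@followupMaxYears)
    data.frame(time = pmin(t_event, t_cens),
               event = t_event <= t_cens)
  })
}

#' Generate a synthetic label-free proteomic cohort
#'
#' Draws latent subtype labels, a per-protein log-normal baseline shared
#' across samples, multiplicative subtype overexpression on disjoint
#' planted signature sets, multiplicative log-normal per-entry noise, and
#' an abundance-dependent logistic dropout that zeroes undetected entries.
#' Clinical covariates, treatment flags and exponential survival outcomes
#' (with subtype-specific treatment interactions) are generated alongside.
#' The same design and seed always reproduce the cohort bit-identically.
#' The proteome (marker identity, baselines, peptide counts) is seeded by
#' the design, so cohorts drawn with different seeds from one design share
#' their biology and can serve as discovery/validation pairs.
#'
#' @param design a [CohortDesign-class].
#' @param seed integer seed (defaults to the design's).
#' @return a list with elements
#'   \describe{
#'     \item{`intensity`}{an [IntensityExperiment-class] whose `colData`
#'       carries the clinical table;}
#'     \item{`clinical`}{the clinical table as a plain data.frame;}
#'     \item{`truth`}{planted ground truth: `labels` (integer subtype per
#'       sample), `signatureProteins` (list of protein-id vectors per
#'       subtype), `hazardRates`, `treatmentLogHR`.}
#'   }
#' @export
simulateCohort <- function(design, seed = design@seed) {
  validObject(design)
  p <- design@nProteins
  k <- design@nSubtypes

  # The proteome - marker identity, per-protein baselines and theoretical
  # peptide counts - is a property of the biology shared by every cohort
  # drawn from the same design, so it is seeded by the design itself.
  # The cohort seed governs sampling: subtype labels, noise, dropout,
  # clinical covariates and outcomes.
  proteome <- withr::with_seed(design@seed, {
    sig_idx <- .assign_signatures(design)
    mu <- rnorm(p, design@baseAbundanceLogMean, design@baseAbundanceLogSD)
    for (s in seq_len(k)) {
      # resting baseline = activated level / fold change
      mu[sig_idx[[s]]] <- rnorm(design@signatureSize,
                                design@signatureLogMean -
                                  log(design@signatureFoldChange[s]),
                                design@signatureLogSD)
    }
    list(sig_idx = sig_idx, mu = mu,
         n_pep = sample(5:50, p, replace = TRUE))
  })
  sig_idx <- proteome$sig_idx
  mu <- proteome$mu

  withr::with_seed(seed, {
    n <- design@nSamples

    labels <- sample.int(k, n, replace = TRUE,
                         prob = design@subtypeProportions)

    protein_ids <- sprintf("PROT%05d", seq_len(p))
    sample_ids <- sprintf("SAMPLE%03d", seq_len(n))

    logx <- matrix(mu, p, n) +
      matrix(rnorm(p * n, 0, design@noiseLogSD), p, n)
    for (s in seq_len(k)) {
      cols <- which(labels == s)
      if (length(cols))
        logx[sig_idx[[s]], cols] <- logx[sig_idx[[s]], cols] +
          log(design@signatureFoldChange[s])
    }

    # logistic detection on latent log intensity; slope 0 keeps everything
    # with log(x) >= midpoint, so a very low midpoint disables dropout
    if (design@dropoutSlope == 0) {
      pdet <- ifelse(logx >= design@dropoutMidpoint, 1, 0)
    } else {
      pdet <- stats::plogis(design@dropoutSlope *
                              (logx - design@dropoutMidpoint))
    }
    det <- matrix(runif(p * n) < pdet, p, n)
    intensity <- exp(logx) * det
    dimnames(intensity) <- list(protein_ids, sample_ids)

    n_pep <- proteome$n_pep

    chemo <- runif(n) < design@chemoFraction
    ici <- runif(n) < design@iciFraction
    ici_line <- ifelse(!ici, "none",
                       ifelse(runif(n) < design@iciFirstFraction,
                              "first", "later"))

    os <- simulateSurvival(labels, chemo, design,
                           seed = sample.int(.Machine$integer.max, 1))
    pfs <- simulateSurvival(labels, rep(FALSE, n), design,
                            seed = sample.int(.Machine$integer.max, 1),
                            hazards = design@pfsHazardRates,
                            loghr = rep(0, k))

    clinical <- data.frame(
      sample_id = sample_ids,
      os_years = os$time, os_event = os$event,
      pfs_years = ifelse(ici, pfs$time, NA_real_),
      pfs_event = ifelse(ici, pfs$event, NA),
      age = pmin(85L, pmax(30L, as.integer(round(rnorm(n, 62, 9))))),
      gender = ifelse(runif(n) < 0.8, "male", "female"),
      smoking = runif(n) < 0.7,
      lnm = runif(n) < 0.6,
      tnm_stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = design@tnmProportions),
      valg_stage = ifelse(runif(n) < design@valgLsFraction, "LS", "ES"),
      chemotherapy = chemo,
      ici_line = ici_line,
      stringsAsFactors = FALSE)

    truth <- list(labels = stats::setNames(labels, sample_ids),
                  signatureProteins = lapply(sig_idx,
                                             function(i) protein_ids[i]),
                  hazardRates = design@hazardRates,
                  treatmentLogHR = design@treatmentLogHR)

    list(intensity = IntensityExperiment(intensity, n_pep,
                                         colData = clinical),
         clinical = clinical,
         truth = truth)
  })
}
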