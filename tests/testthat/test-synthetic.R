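test_that("cohort generation is bit-identical under a fixed seed", {
  d <- small_design()
  a <- simulateCohort(d, seed = 123)
  b <- simulateCohort(d, seed = 123)
  expect_identical(intensities(a$intensity), intensities(b$intensity))
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- simulateCohort(d, seed = 124)
  expect_false(identical(intensities(a$intensity), intensities(c$intensity)))
})

test_that("disabled dropout leaves no missing entries", {
  d <- small_design(dropoutSlope = 0, dropoutMidpoint = -1e6)
  sim <- simulateCohort(d, seed = 5)
  expect_true(all(intensities(sim$intensity) > 0))
})

test_that("design invariants are enforced", {
  expect_error(cohortDesign(subtypeProportions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(cohortDesign(hazardRates = c(0.1, -0.2, 0.3)), "positive")
  expect_error(cohortDesign(nProteins = 100L, signatureSize = 50L),
               "exceed")
  expect_error(cohortDesign(signatureFoldChange = c(1, 3, 10)), "exceed 1")
})

test_that("signature sets are disjoint and labels cover all subtypes", {
  sim <- simulateCohort(small_design(), seed = 2)
  sets <- sim$truth$signatureProteins
  expect_length(unique(unlist(sets)), length(unlist(sets)))
  expect_setequal(unique(sim$truth$labels), 1:3)
  expect_length(sim$truth$labels, 60)
})

test_that("planted fold changes are recovered from the generated matrix", {
  # strong-separation config, dropout off, measured on the raw matrix
  d <- cohortDesign(nSamples = 300L, nProteins = 800L, signatureSize = 30L,
                    dropoutSlope = 0, dropoutMidpoint = -1e6,
                    signatureLogMean = log(1e6), signatureLogSD = 0.5)
  sim <- simulateCohort(d, seed = 77)
  m <- intensities(sim$intensity)
  lab <- sim$truth$labels
  for (s in 1:3) {
    ids <- sim$truth$signatureProteins[[s]]
    own <- lab == s
    ratio <- rowMeans(m[ids, own]) / rowMeans(m[ids, !own])
    fc <- c(3, 3, 10)[s]
    expect_gt(mean(ratio), fc * 0.8)
    expect_lt(mean(ratio), fc * 1.2)
  }
})

test_that("subtype proportions converge to the configured mixture", {
  d <- cohortDesign(nSamples = 5000L, nProteins = 30L, signatureSize = 5L)
  lab <- withr::with_seed(10, sample.int(3, 5000, replace = TRUE,
                                         prob = d@subtypeProportions))
  sim_lab <- simulateCohort(
    cohortDesign(nSamples = 5000L, nProteins = 30L, signatureSize = 5L),
    seed = 10)$truth$labels
  props <- d@subtypeProportions
  emp <- as.numeric(table(sim_lab)) / 5000
  se <- sqrt(props * (1 - props) / 5000)
  expect_true(all(abs(emp - props) < 3 * se))
  expect_equal(as.integer(table(lab)), as.integer(table(sim_lab)))
})

test_that("detection rate rises with protein log-abundance", {
  sim <- simulateCohort(cohortDesign(nSamples = 75L, nProteins = 3000L,
                                     signatureSize = 10L), seed = 6)
  m <- intensities(sim$intensity)
  det_rate <- rowMeans(m > 0)
  # latent abundance proxy: mean of detected values (monotone in mu)
  mu_hat <- log(apply(m, 1, function(r) {
    pos <- r[r > 0]
    if (length(pos)) mean(pos) else NA
  }))
  ok <- !is.na(mu_hat)
  bins <- cut(mu_hat[ok], quantile(mu_hat[ok], seq(0, 1, 0.1)),
              include.lowest = TRUE)
  bin_rate <- tapply(det_rate[ok], bins, mean)
  expect_true(all(diff(bin_rate) > -0.02))  # monotone up to binning noise
})

test_that("survival generator matches the exponential closed form", {
  # hazard 0.0575/yr, no censoring: empirical S(5) ~ exp(-0.2875) ~ 0.75
  d <- cohortDesign(nSamples = 20000L, nProteins = 10L, signatureSize = 2L,
                    hazardRates = c(0.0575, 0.0575, 0.0575),
                    treatmentLogHR = c(0, 0, 0),
                    censoringRate = 0, followupMaxYears = 1e6)
  surv <- simulateSurvival(rep(1L, 20000), rep(FALSE, 20000), d, seed = 42)
  expect_true(all(surv$event))
  expect_equal(mean(surv$time > 5), exp(-0.0575 * 5), tolerance = 0.02)
})

test_that("zero censoring with unbounded follow-up yields all events", {
  d <- small_design(censoringRate = 0, followupMaxYears = 1e9)
  surv <- simulateSurvival(rep(1:3, 20), rep(FALSE, 60), d, seed = 1)
  expect_true(all(surv$event))
})

test_that("Kaplan-Meier curves order by hazard", {
  # two subtypes with hazards h and 3h: the low-hazard curve dominates
  h <- 0.2
  d <- cohortDesign(nSamples = 10000L, nProteins = 10L, signatureSize = 2L,
                    nSubtypes = 2L, subtypeProportions = c(0.5, 0.5),
                    signatureFoldChange = c(3, 3),
                    hazardRates = c(h, 3 * h), treatmentLogHR = c(0, 0),
                    pfsHazardRates = c(h, 3 * h),
                    censoringRate = 0, followupMaxYears = 1e6)
  lab <- rep(1:2, each = 2500)
  surv <- simulateSurvival(lab, rep(FALSE, 5000), d, seed = 9)
  for (tp in c(0.5, 1, 2, 4, 8)) {
    s1 <- survivalAt(surv$time[lab == 1], surv$event[lab == 1], tp)
    s2 <- survivalAt(surv$time[lab == 2], surv$event[lab == 2], tp)
    expect_gt(s1, s2)
    expect_lt(abs(s1 - exp(-h * tp)), 0.02)
  }
})

test_that("clinical table carries the full schema", {
  sim <- simulateCohort(small_design(iciFraction = 0.5), seed = 3)
  cl <- sim$clinical
  expect_true(all(c("sample_id", "os_years", "os_event", "pfs_years",
                    "pfs_event", "age", "gender", "smoking", "lnm",
                    "tnm_stage", "valg_stage", "chemotherapy",
                    "ici_line") %in% names(cl)))
  expect_silent(validateClinical(cl))
  ici <- cl$ici_line != "none"
  expect_true(all(!is.na(cl$pfs_years[ici])))
  expect_true(all(is.na(cl$pfs_years[!ici])))
})
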