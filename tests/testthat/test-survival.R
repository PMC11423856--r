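test_that("Kaplan-Meier matches hand-computed product limits", {
  km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: survival stays at 1 (no event rows)
  km0 <- kmEstimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_equal(nrow(km0), 0)
  expect_equal(survivalAt(c(1, 2, 3), c(FALSE, FALSE, FALSE), 5), 1)
})

test_that("KM agrees with an independent product over risk sets", {
  # mixed 8-subject fixture; censored-at-event-time stays at risk
  times <- c(1, 1, 2, 2, 3, 4, 5, 6)
  events <- c(1, 0, 1, 1, 0, 1, 0, 1)
  km <- kmEstimate(times, events)
  # manual oracle
  surv <- 1
  expected <- c()
  for (t in sort(unique(times[events == 1]))) {
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    surv <- surv * (1 - d / n_risk)
    expected <- c(expected, surv)
  }
  expect_equal(km$survival, expected, tolerance = 1e-12)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(13)
  t <- rexp(40, 0.3)
  km <- kmEstimate(t, rep(TRUE, 40))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$survival[i], mean(t > km$time[i]), tolerance = 1e-12)
  }
})

test_that("log-rank is zero on duplicated groups and matches the oracle", {
  times <- c(1, 2, 3, 4, 1, 2, 3, 4)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1)
  groups <- rep(c("a", "b"), each = 4)  # identical groups
  lr <- logrankTest(times, events, groups)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # three-group fixture vs the independent accumulation oracle
  set.seed(17)
  t3 <- rexp(30, rep(c(0.2, 0.4, 0.8), each = 10))
  e3 <- rbinom(30, 1, 0.8)
  g3 <- rep(1:3, each = 10)
  lr3 <- logrankTest(t3, e3, g3)
  or3 <- logrank_oracle(t3, e3, g3)
  expect_equal(lr3$statistic, or3$statistic, tolerance = 1e-10)
  expect_equal(lr3$df, 2)
  expect_equal(lr3$p_value, or3$p_value, tolerance = 1e-10)
  # invariant under group relabeling
  relab <- c(3, 1, 2)[g3]
  expect_equal(logrankTest(t3, e3, relab)$statistic, lr3$statistic,
               tolerance = 1e-12)
})

test_that("log-rank detects a 3-fold hazard difference", {
  hits <- 0
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      data.frame(t = c(rexp(200, 0.2), rexp(200, 0.6)),
                 g = rep(1:2, each = 200))
    })
    p <- logrankTest(dat$t, rep(TRUE, 400), dat$g)$p_value
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits, 9)
})

test_that("Cox fit matches a brute-force partial-likelihood optimum", {
  # small no-ties fixture, binary covariate
  times <- c(1, 2, 3, 4, 5, 6)
  events <- c(1, 1, 1, 0, 1, 0)
  x <- c(1, 0, 1, 0, 0, 1)
  fit <- coxPH(times, events, data.frame(x = x), ties = "breslow")
  beta_hat <- fit$coef[1]
  oracle <- optimize(cox_nll_oracle, c(-5, 5), times = times,
                     events = events, x = x)$minimum
  expect_equal(beta_hat, oracle, tolerance = 1e-5)
  expect_equal(fit$hazard_ratio[1], exp(beta_hat))
  expect_equal(fit$ci95_low[1], exp(beta_hat - 1.96 * fit$se[1]))
  # Efron equals Breslow when there are no tied event times
  fit_e <- coxPH(times, events, data.frame(x = x), ties = "efron")
  expect_equal(fit_e$coef[1], fit$coef[1], tolerance = 1e-10)
})

test_that("Cox null covariate CI covers 1 about 95% of the time", {
  cover <- 0
  for (seed in 1:20) {
    dat <- withr::with_seed(seed, {
      data.frame(t = rexp(500, 0.3), x = rbinom(500, 1, 0.5))
    })
    fit <- coxPH(dat$t, rep(TRUE, 500), dat["x"])
    cover <- cover + (fit$ci95_low[1] <= 1 && fit$ci95_high[1] >= 1)
  }
  expect_gte(cover, 17)  # ~95%, allow binomial wiggle at 20 reps
})

test_that("Cox input validation rejects constant covariates", {
  expect_error(coxPH(c(1, 2, 3), c(1, 1, 0),
                     data.frame(x = c(2, 2, 2))), "constant")
  expect_error(coxPH(c(1, 2), c(0, 0), data.frame(x = c(1, 2))),
               "at least one event")
})

test_that("chemo-benefit analysis restricts to TNM II/III", {
  cl <- data.frame(
    sample_id = paste0("s", 1:10),
    os_years = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    os_event = rep(c(TRUE, FALSE), 5),
    tnm_stage = c(rep("I", 4), rep("II", 6)),
    chemotherapy = rep(c(TRUE, FALSE), 5))
  lab <- rep("S-I", 10)
  res <- chemoBenefitAnalysis(cl, lab)
  expect_equal(res$n, 6)  # only the 6 TNM II patients enter
  expect_true(res$evaluable)
  # empty arm -> not evaluable, no p-value
  cl2 <- cl
  cl2$chemotherapy <- TRUE
  res2 <- chemoBenefitAnalysis(cl2, lab)
  expect_false(res2$evaluable)
  expect_true(is.na(res2$p_value))
})

test_that("a planted chemo benefit is detected only in the right subtype", {
  hits_s1 <- 0
  false_other <- 0
  for (seed in 1:10) {
    d <- cohortDesign(nSamples = 600L, nProteins = 20L, signatureSize = 3L,
                      treatmentLogHR = c(-1, 0, 0),
                      hazardRates = c(0.3, 0.3, 0.3),
                      censoringRate = 0.05)
    sim <- withr::with_seed(seed * 11L, {
      lab <- sample.int(3, 600, replace = TRUE)
      chemo <- runif(600) < 0.5
      list(lab = lab, chemo = chemo)
    })
    surv <- simulateSurvival(sim$lab, sim$chemo, d, seed = seed * 13L)
    cl <- data.frame(sample_id = seq_len(600), os_years = surv$time,
                     os_event = surv$event,
                     tnm_stage = withr::with_seed(seed, sample(c("II", "III"),
                                                               600, TRUE)),
                     chemotherapy = sim$chemo)
    res <- chemoBenefitAnalysis(cl, sim$lab)
    hits_s1 <- hits_s1 + (res$p_value[res$subtype == "1"] < 0.05)
    false_other <- false_other + any(res$p_value[res$subtype != "1"] < 0.05)
  }
  expect_gte(hits_s1, 8)
  expect_lte(false_other, 2)
})

test_that("first-line ICI analysis filters lines and flags missing PFS", {
  cl <- data.frame(
    sample_id = paste0("s", 1:60),
    os_years = rexp(60, 0.3), os_event = TRUE,
    pfs_years = c(rexp(40, 0.5), rep(NA, 20)),
    pfs_event = c(rep(TRUE, 40), rep(NA, 20)),
    ici_line = c(rep("first", 30), rep("later", 10), rep("none", 20)))
  lab <- rep(c("S-I", "S-II", "S-III"), 20)
  res <- iciAnalysis(cl, lab)
  expect_equal(res$n_first_line, 30)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$n1 == 10 & res$pairwise$n2 == 10))
  # an ICI-treated sample without PFS is a validation error
  cl_bad <- cl
  cl_bad$pfs_years[5] <- NA
  expect_error(iciAnalysis(cl_bad, lab), "missing PFS")
})

test_that("a planted PFS advantage is detected between subtypes", {
  hits <- 0
  for (seed in 1:10) {
    d <- cohortDesign(nSamples = 150L, nProteins = 20L, signatureSize = 3L,
                      pfsHazardRates = c(1.2, 0.6, 1.2),  # 2x median PFS in S2
                      censoringRate = 0.05, iciFraction = 1,
                      iciFirstFraction = 1)
    lab <- withr::with_seed(seed, sample.int(3, 150, replace = TRUE))
    pfs <- simulateSurvival(lab, rep(FALSE, 150), d, seed = seed * 7L,
                            hazards = d@pfsHazardRates, loghr = rep(0, 3))
    cl <- data.frame(sample_id = seq_len(150), os_years = pfs$time,
                     os_event = pfs$event, pfs_years = pfs$time,
                     pfs_event = pfs$event, ici_line = "first")
    res <- iciAnalysis(cl, lab)
    expect_equal(res$n_first_line, 150)
    # subtype 2 vs the others pooled
    p2 <- logrankTest(pfs$time, pfs$event, lab == 2)$p_value
    hits <- hits + (p2 < 0.05)
  }
  expect_gte(hits, 8)
})

test_that("IHC scores multiply, bin and call positivity as published", {
  res <- ihcScore(c(3, 1, 2, 1, 2), c(100, 5, 20.5, 10, 70))
  expect_equal(res$score, c(300, 5, 41, 10, 140))
  expect_equal(as.character(res$bin), c("3+", "0", "2+", "1+", "2+"))
  expect_equal(res$positive, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(ihcScore(4, 50), "intensity")
  expect_error(ihcScore(2, 150), "percentPositive")
})
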