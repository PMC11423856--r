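#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator over the distinct event times, with Greenwood
#' standard errors. Subjects censored at an event time remain at risk for
#' that time (the standard convention).
#'
#' @param times non-negative follow-up times.
#' @param events logical (or 0/1) event indicators.
#' @return data.frame with one row per distinct event time: `time`,
#'   `n_risk`, `n_event`, `survival`, `std_err` (Greenwood SE of the
#'   survival estimate).
#' @examples
#' kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))$survival  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "log")
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep],
             n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep],
             survival = fit$surv[keep],
             std_err = fit$std.err[keep] * fit$surv[keep],
             row.names = NULL)
}

#' Survival probability at a time point
#'
#' Reads the Kaplan-Meier estimate at `at` years (the step function value,
#' i.e. the last event time not exceeding `at`).
#'
#' @param times,events as in [kmEstimate()].
#' @param at time point (years).
#' @return scalar survival probability.
#' @export
survivalAt <- function(times, events, at) {
  km <- kmEstimate(times, events)
  prior <- km$survival[km$time <= at]
  if (!length(prior)) 1 else prior[length(prior)]
}

#' Multi-group log-rank (Mantel-Haenszel) test
#'
#' Accumulates observed-minus-expected events over the distinct event
#' times and forms the chi-square statistic with the full covariance
#' matrix of the group event counts, on `#groups - 1` degrees of freedom.
#' Two-sided p from the chi-square upper tail.
#'
#' @param times,events as in [kmEstimate()].
#' @param groups group membership, at least two non-empty groups.
#' @return list with `statistic`, `df`, `p_value`, `observed`, `expected`
#'   (per group).
#' @export
logrankTest <- function(times, events, groups) {
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least two non-empty groups required")
  if (any(table(g) == 0)) stop("empty group in 'groups'")
  sd_fit <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd_fit$chisq), df = df,
       p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE),
       observed = unname(sd_fit$obs), expected = unname(sd_fit$exp))
}

#' Cox proportional-hazards fit with Wald statistics
#'
#' Partial-likelihood Cox regression; per covariate the hazard ratio
#' `exp(beta)`, its Wald 95% confidence interval
#' `exp(beta +/- 1.96 se)`, and the two-sided Wald p-value are reported.
#' Efron tie handling is the default (year-granular clinical data produce
#' heavy ties); Breslow is selectable.
#'
#' @param times,events as in [kmEstimate()].
#' @param covariates data.frame of covariates; factors are expanded to
#'   treatment contrasts against their first level.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return data.frame with one row per model term: `term`, `coef`, `se`,
#'   `hazard_ratio`, `ci95_low`, `ci95_high`, `wald_p`; the fitted
#'   `coxph` object is attached as attribute `"fit"`.
#' @export
coxPH <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(times))
  if (sum(events) < 1) stop("at least one event required")
  constant <- vapply(covariates, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    stop("constant covariate(s): ",
         paste(names(covariates)[constant], collapse = ", "))
  }
  dat <- cbind(data.frame(.time = times, .event = as.integer(events)),
               covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = ties)
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox model did not converge")
  s <- summary(fit)
  co <- s$coefficients
  data.frame(term = rownames(co),
             coef = co[, "coef"],
             se = co[, "se(coef)"],
             hazard_ratio = exp(co[, "coef"]),
             ci95_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
             ci95_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
             wald_p = co[, "Pr(>|z|)"],
             row.names = NULL) -> out
  attr(out, "fit") <- fit
  out
}

#' Chemotherapy-benefit analysis within TNM II/III
#'
#' Restricts the cohort to TNM stage II and III patients (stages I and IV
#' dominate prognosis on their own) and, within each subtype, compares
#' overall survival between chemotherapy-treated and untreated patients
#' with a two-group log-rank test. Subtypes in which either arm is empty
#' are reported as not evaluable instead of erroring.
#'
#' @param clinical clinical data.frame with `os_years`, `os_event`,
#'   `tnm_stage`, `chemotherapy`.
#' @param labels subtype labels aligned with `clinical` rows.
#' @return data.frame: `subtype`, `n`, `n_chemo`, `n_no_chemo`,
#'   `evaluable`, `p_value`.
#' @export
chemoBenefitAnalysis <- function(clinical, labels) {
  stopifnot(nrow(clinical) == length(labels))
  sel <- clinical$tnm_stage %in% c("II", "III")
  cl <- clinical[sel, , drop = FALSE]
  lab <- factor(labels[sel])
  do.call(rbind, lapply(levels(lab), function(s) {
    rows <- lab == s
    ch <- cl$chemotherapy[rows]
    if (sum(rows) == 0 || length(unique(ch)) < 2) {
      return(data.frame(subtype = s, n = sum(rows),
                        n_chemo = sum(ch), n_no_chemo = sum(!ch),
                        evaluable = FALSE, p_value = NA_real_))
    }
    lr <- logrankTest(cl$os_years[rows], cl$os_event[rows], ch)
    data.frame(subtype = s, n = sum(rows), n_chemo = sum(ch),
               n_no_chemo = sum(!ch), evaluable = TRUE,
               p_value = lr$p_value)
  }))
}

#' Immunotherapy (ICI) cohort analysis
#'
#' Restricts to patients who received immune checkpoint inhibitors in
#' first line and compares ICI progression-free survival (time from first
#' immunotherapy to progressive disease) pairwise between subtypes by
#' log-rank tests. Patients with `ici_line` "none" or "later" never enter
#' the first-line analysis.
#'
#' @param clinical clinical data.frame with `pfs_years`, `pfs_event`,
#'   `ici_line` (values "first", "later", "none").
#' @param labels subtype labels aligned with `clinical` rows.
#' @return list with `n_first_line` and `pairwise` (data.frame: group1,
#'   group2, n1, n2, p_value).
#' @export
iciAnalysis <- function(clinical, labels) {
  stopifnot(nrow(clinical) == length(labels))
  treated <- clinical$ici_line %in% c("first", "later")
  if (any(treated & (is.na(clinical$pfs_years) | is.na(clinical$pfs_event)))) {
    bad <- which(treated & is.na(clinical$pfs_years))
    stop("missing PFS for ICI-treated sample row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  first <- clinical$ici_line == "first"
  cl <- clinical[first, , drop = FALSE]
  lab <- factor(labels[first])
  lv <- levels(droplevels(lab))
  pairs <- if (length(lv) >= 2) utils::combn(lv, 2, simplify = FALSE) else list()
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    rows <- lab %in% pr
    lr <- logrankTest(cl$pfs_years[rows], cl$pfs_event[rows],
                      droplevels(lab[rows]))
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = sum(lab == pr[1]), n2 = sum(lab == pr[2]),
               p_value = lr$p_value)
  }))
  list(n_first_line = sum(first), pairwise = pw)
}

#' Compare overall survival of one subtype across cohorts
#'
#' Convenience wrapper for cross-cohort comparisons (e.g. the same subtype
#' with and without immunotherapy): a log-rank test across an arbitrary
#' group labelling.
#'
#' @param times,events pooled survival data.
#' @param groups cohort/group label per subject.
#' @return as [logrankTest()].
#' @export
compareGroupsOS <- function(times, events, groups) {
  logrankTest(times, events, groups)
}

#' Immunohistochemistry score
#'
#' Score = staining intensity (1 weak, 2 moderate, 3 strong) times the
#' percentage of positive tumor cells, giving 0-300. Scores below 10 bin
#' as "0", 10-40 as "1+", 41-140 (implemented as (40, 140]) as "2+" and
#' above 140 as "3+". A sample is called positive only when its score
#' strictly exceeds 10 - so a score of exactly 10 falls in bin "1+" yet is
#' negative, a deliberate, literal reading of the scoring convention.
#'
#' @param intensity integer vector with values in {1, 2, 3}.
#' @param percentPositive numeric vector in \[0, 100\].
#' @return data.frame: `score` (0-300), `bin` (factor "0", "1+", "2+",
#'   "3+"), `positive` (logical).
#' @examples
#' ihcScore(3, 100)  # 300, "3+", positive
#' ihcScore(1, 5)    # 5, "0", negative
#' @export
ihcScore <- function(intensity, percentPositive) {
  if (!all(intensity %in% c(1, 2, 3)))
    stop("'intensity' must be 1, 2 or 3")
  if (any(percentPositive < 0 | percentPositive > 100))
    stop("'percentPositive' must lie in [0, 100]")
  n <- max(length(intensity), length(percentPositive))
  intensity <- rep_len(intensity, n)
  percentPositive <- rep_len(percentPositive, n)
  score <- intensity * percentPositive
  bin <- ifelse(score < 10, "0",
                ifelse(score <= 40, "1+",
                       ifelse(score <= 140, "2+", "3+")))
  data.frame(score = score,
             bin = factor(bin, levels = c("0", "1+", "2+", "3+")),
             positive = score > 10)
}
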