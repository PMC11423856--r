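# Small in-code fixtures shared across test files.

# Tiny intensity experiment with known arithmetic.
tiny_intensity <- function() {
  m <- matrix(c(100, 0, 50,
                40, 10, 0,
                0, 30, 20), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("s1", "s2", "s3")))
  IntensityExperiment(m, n_peptides = c(4L, 2L, 5L))
}

# Abundance experiment built directly from a FOT-like matrix; zeros are
# undetected.
abundance_from_matrix <- function(m, impute = TRUE) {
  ae <- computeFOT(m)
  if (impute) suppressWarnings(imputeMissing(ae)) else ae
}

# Fast, small cohort design for tests that only need structure, not the
# full emulated scale.
small_design <- function(...) {
  cohortDesign(nSamples = 60L, nProteins = 600L, signatureSize = 25L, ...)
}

# Independent adjusted Rand index (used as an oracle; mclust provides the
# cross-check where available).
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# Independent multi-group log-rank oracle: accumulates the group event
# vector and its full hypergeometric covariance over distinct event times,
# then forms the quadratic form on the first g-1 groups.
logrank_oracle <- function(times, events, groups) {
  g <- factor(groups)
  lv <- levels(g)
  ng <- length(lv)
  O <- E <- numeric(ng)
  Vm <- matrix(0, ng, ng)
  for (t in sort(unique(times[events > 0]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(events[times == t] > 0)
    if (d == 0 || n == 0) next
    nj <- vapply(lv, function(l) sum(at_risk & g == l), numeric(1))
    dj <- vapply(lv, function(l) sum(times == t & events > 0 & g == l),
                 numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      for (i in seq_len(ng)) for (j in seq_len(ng)) {
        delta <- as.numeric(i == j)
        Vm[i, j] <- Vm[i, j] +
          d * (nj[i] / n) * (delta - nj[j] / n) * (n - d) / (n - 1)
      }
    }
  }
  idx <- seq_len(ng - 1)
  z <- (O - E)[idx]
  stat <- drop(t(z) %*% solve(Vm[idx, idx, drop = FALSE]) %*% z)
  list(statistic = stat, df = ng - 1,
       p_value = pchisq(stat, ng - 1, lower.tail = FALSE))
}

# Hand-written Cox negative log partial likelihood (Breslow, no ties in
# the fixtures used) for a single binary covariate; oracle for coxPH.
cox_nll_oracle <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events > 0)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}
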