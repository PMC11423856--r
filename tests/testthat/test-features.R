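test_that("top-N union collects each sample's highest-FOT proteins", {
  # sample1 ranks A > B > C, sample2 ranks C > B > A; n = 2 -> {A, B, C}
  m <- matrix(c(5, 3, 1, 1, 3, 5), 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  ae <- abundance_from_matrix(m, impute = FALSE)
  expect_setequal(topNUnion(ae, 2), c("A", "B", "C"))
  expect_setequal(topNUnion(ae, 10), c("A", "B", "C"))  # n >= proteins
})

test_that("top-N union keeps boundary ties and matches brute force", {
  # 6-protein fixture with a deliberate tie at the rank-2 boundary
  m <- matrix(c(10, 8, 8, 2, 1, 0,
                1, 2, 3, 4, 5, 6), 6, 2,
              dimnames = list(LETTERS[1:6], c("s1", "s2")))
  ae <- abundance_from_matrix(m, impute = FALSE)
  got <- topNUnion(ae, 2)
  # brute force: enumerate per sample all detected proteins whose value is
  # at least the 2nd largest detected value
  brute <- unique(unlist(lapply(1:2, function(j) {
    v <- m[, j][m[, j] > 0]
    names(v)[v >= sort(v, decreasing = TRUE)[2]]
  })))
  expect_setequal(got, brute)
  expect_true(all(c("A", "B", "C") %in% got))  # tie at 8 kept
})

test_that("top-N union is monotone in n", {
  set.seed(5)
  m <- matrix(rexp(200) * rbinom(200, 1, 0.6), 20, 10,
              dimnames = list(paste0("P", 1:20), paste0("s", 1:10)))
  m[1, ] <- 1
  ae <- abundance_from_matrix(m, impute = FALSE)
  prev <- character()
  for (n in c(1, 3, 5, 10, 20)) {
    cur <- topNUnion(ae, n)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("CV is sample sd over mean, matching a two-pass oracle", {
  expect_equal(computeCV(c(4, 4, 4)), 0)
  expect_equal(computeCV(c(1, 3)), sqrt(2) / 2, tolerance = 1e-12)
  set.seed(9)
  x <- rexp(50)
  naive_var <- sum((x - sum(x) / 50)^2) / 49
  expect_equal(computeCV(x), sqrt(naive_var) / mean(x), tolerance = 1e-12)
  expect_error(computeCV(c(-1, -2)), "mean")
})

test_that("clustering feature filters use strict thresholds", {
  # 10 samples; protein detected in exactly 1 of 10 must be excluded at
  # minDetectFraction = 0.10, and CV exactly at threshold must be excluded
  set.seed(21)
  n <- 10
  base <- matrix(rep(c(5, 6, 7, 8), each = n), 4, n, byrow = FALSE,
                 dimnames = list(c("hi1", "hi2", "flat", "rare"),
                                 paste0("s", 1:n)))
  base["hi1", ] <- c(rep(0.001, 5), rep(100, 5))   # huge CV
  base["hi2", ] <- c(rep(100, 5), rep(0.001, 5))
  base["flat", ] <- 50
  base["rare", ] <- c(120, rep(0, n - 1))          # one-sample detection
  ae <- abundance_from_matrix(base)
  fs <- selectClusteringFeatures(ae, topN = 4, minDetectFraction = 0.10,
                                 cvThreshold = 1.0)
  expect_false("rare" %in% fs$protein_id)   # strict > 10%
  expect_false("flat" %in% fs$protein_id)   # CV ~ 0
  expect_true(all(c("hi1", "hi2") %in% fs$protein_id))
  # CV exactly at the threshold is excluded
  cv_hi1 <- fs$cv[fs$protein_id == "hi1"]
  fs2 <- selectClusteringFeatures(ae, topN = 4, minDetectFraction = 0.10,
                                  cvThreshold = cv_hi1)
  expect_false("hi1" %in% fs2$protein_id)
})

test_that("selection matches an independent brute-force filter", {
  set.seed(33)
  sim <- simulateCohort(small_design(), seed = 33)
  ae <- suppressWarnings(quantifyCohort(sim$intensity))
  fs <- selectClusteringFeatures(ae, topN = 100, minDetectFraction = 0.10,
                                 cvThreshold = 1.9)
  # independent oracle written from scratch on the raw assays
  f <- fot(ae); det <- detected(ae)
  union <- unique(unlist(lapply(seq_len(ncol(f)), function(j) {
    v <- f[, j]; v[!det[, j]] <- NA
    obs <- sort(v[!is.na(v)], decreasing = TRUE)
    thr <- if (length(obs) <= 100) min(obs) else obs[100]
    rownames(f)[!is.na(v) & v >= thr]
  })))
  cv <- apply(f, 1, sd) / rowMeans(f)
  frac <- rowMeans(det)
  oracle <- rownames(f)[rownames(f) %in% union & frac > 0.10 & cv > 1.9]
  expect_setequal(fs$protein_id, oracle)
})

test_that("raising thresholds never enlarges the feature set", {
  sim <- simulateCohort(small_design(), seed = 4)
  ae <- suppressWarnings(quantifyCohort(sim$intensity))
  base <- selectClusteringFeatures(ae, topN = 200, minDetectFraction = 0.10,
                                   cvThreshold = 1.5)
  tighter_cv <- selectClusteringFeatures(ae, topN = 200,
                                         minDetectFraction = 0.10,
                                         cvThreshold = 2.2)
  tighter_freq <- selectClusteringFeatures(ae, topN = 200,
                                           minDetectFraction = 0.30,
                                           cvThreshold = 1.5)
  expect_true(all(tighter_cv$protein_id %in% base$protein_id))
  expect_true(all(tighter_freq$protein_id %in% base$protein_id))
})

test_that("classifier candidates apply frequency filter without CV", {
  sim <- simulateCohort(small_design(), seed = 8)
  ae <- suppressWarnings(quantifyCohort(sim$intensity))
  cand <- selectClassifierCandidates(ae, topN = nrow(ae),
                                     minDetectFraction = 0.25)
  frac <- rowMeans(detected(ae))
  expect_setequal(cand, rownames(ae)[frac > 0.25])  # frequency alone governs
  # strict boundary: detected in exactly 2 of 8 samples at threshold 0.25
  m <- matrix(1, 3, 8, dimnames = list(c("A", "B", "edge"), paste0("s", 1:8)))
  m["edge", ] <- c(1, 1, rep(0, 6))
  ae2 <- abundance_from_matrix(m)
  expect_false("edge" %in%
    selectClassifierCandidates(ae2, topN = 3, minDetectFraction = 0.25))
})
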