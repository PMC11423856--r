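#' Subtype signature proteins (one-vs-rest Wilcoxon + fold change)
#'
#' For every subtype each protein is compared against all remaining
#' samples pooled: the fold change is the ratio of arithmetic mean FOT
#' (own subtype over rest) and significance comes from a two-sided
#' Wilcoxon rank-sum test. A protein enters a subtype's signature when
#' its fold change strictly exceeds that subtype's threshold and the raw
#' Wilcoxon p is below `alpha`. With per-subtype thresholds of at least 3
#' and three groups, the resulting signature sets are pairwise disjoint
#' (a protein cannot be >3-fold above the rest-mean of two different
#' groups at once); this is asserted on every run.
#'
#' @param object an imputed [AbundanceExperiment-class].
#' @param labels subtype labels (factor or character) per sample; every
#'   subtype needs at least 2 samples.
#' @param fcThresholds named numeric vector of fold-change thresholds per
#'   subtype; defaults 3 for S-I and S-II, 10 for S-III.
#' @param alpha Wilcoxon significance level (default 0.05, raw p).
#' @param proteins optional restriction of the tested proteins.
#' @return data.frame with columns `subtype`, `protein_id`,
#'   `fold_change`, `p_value`, `adjusted_p` (BH within subtype),
#'   `detect_fraction`, sorted by subtype then descending fold change.
#' @export
subtypeSignatures <- function(object, labels,
                              fcThresholds = c("S-I" = 3, "S-II" = 3,
                                               "S-III" = 10),
                              alpha = 0.05, proteins = rownames(object)) {
  labels <- factor(labels)
  stopifnot(length(labels) == ncol(object))
  small <- names(which(table(labels) < 2))
  if (length(small)) {
    stop("subtype(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  }
  if (is.null(names(fcThresholds))) {
    if (length(fcThresholds) != nlevels(labels))
      stop("'fcThresholds' must be named or have one entry per subtype")
    names(fcThresholds) <- levels(labels)
  }
  miss <- setdiff(levels(labels), names(fcThresholds))
  if (length(miss)) {
    stop("no fold-change threshold for subtype(s): ",
         paste(miss, collapse = ", "))
  }
  f <- fot(object)[proteins, , drop = FALSE]
  det_frac <- rowSums(detected(object)[proteins, , drop = FALSE]) /
    ncol(object)

  out <- do.call(rbind, lapply(levels(labels), function(s) {
    own <- labels == s
    m_own <- rowMeans(f[, own, drop = FALSE])
    m_rest <- rowMeans(f[, !own, drop = FALSE])
    fc <- ifelse(m_rest > 0, m_own / m_rest, Inf)
    pv <- vapply(seq_len(nrow(f)), function(i) {
      suppressWarnings(
        wilcox.test(f[i, own], f[i, !own], exact = FALSE)$p.value)
    }, numeric(1))
    keep <- fc > fcThresholds[[s]] & !is.na(pv) & pv < alpha
    if (!any(keep)) return(NULL)
    res <- data.frame(subtype = s, protein_id = rownames(f)[keep],
                      fold_change = fc[keep], p_value = pv[keep],
                      adjusted_p = p.adjust(pv, "BH")[keep],
                      detect_fraction = det_frac[keep],
                      stringsAsFactors = FALSE)
    res[order(-res$fold_change, res$protein_id), ]
  }))
  if (is.null(out)) {
    out <- data.frame(subtype = character(), protein_id = character(),
                      fold_change = numeric(), p_value = numeric(),
                      adjusted_p = numeric(), detect_fraction = numeric())
  }
  rownames(out) <- NULL
  if (all(fcThresholds >= 3) && nlevels(labels) >= 3 &&
      anyDuplicated(out$protein_id)) {
    stop("internal error: overlapping signature sets despite thresholds >= 3")
  }
  out
}

#' Classifier feature panel (Welch t + BH + fold change)
#'
#' Builds the predictor panel from classifier candidate proteins: for
#' each subtype a one-vs-rest two-sided Welch t-test on log10 FOT,
#' p-values Benjamini-Hochberg adjusted across the candidate panel within
#' each comparison. A protein is retained when any subtype comparison has
#' fold change (arithmetic-mean ratio, own vs rest) above `fcMin` and
#' adjusted p below `alpha`. The panel is ordered by minimum adjusted p,
#' then protein id, so it is deterministic.
#'
#' @param object an imputed [AbundanceExperiment-class].
#' @param labels subtype labels per sample.
#' @param candidates candidate protein ids, e.g. from
#'   [selectClassifierCandidates()].
#' @param fcMin fold-change threshold (default 1.5, strict).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return character vector of protein ids (ordered); attribute
#'   `"stats"` carries the per-protein, per-subtype test table.
#' @export
classifierFeatures <- function(object, labels, candidates, fcMin = 1.5,
                               alpha = 0.05) {
  if (!length(candidates)) stop("empty candidate set")
  labels <- factor(labels)
  stopifnot(length(labels) == ncol(object))
  f <- fot(object)[candidates, , drop = FALSE]
  lf <- log10(f)

  stats_tab <- do.call(rbind, lapply(levels(labels), function(s) {
    own <- labels == s
    m_own <- rowMeans(f[, own, drop = FALSE])
    m_rest <- rowMeans(f[, !own, drop = FALSE])
    fc <- ifelse(m_rest > 0, m_own / m_rest, Inf)
    pv <- vapply(seq_len(nrow(lf)), function(i) {
      x <- lf[i, own]; y <- lf[i, !own]
      if (sd(x) == 0 && sd(y) == 0) return(1)
      suppressWarnings(t.test(x, y)$p.value)
    }, numeric(1))
    data.frame(subtype = s, protein_id = rownames(f),
               fold_change = fc, p_value = pv,
               adjusted_p = p.adjust(pv, "BH"),
               stringsAsFactors = FALSE)
  }))
  hit <- stats_tab$fold_change > fcMin & stats_tab$adjusted_p < alpha
  retained <- unique(stats_tab$protein_id[hit])
  min_adj <- vapply(retained, function(p) {
    min(stats_tab$adjusted_p[stats_tab$protein_id == p & hit])
  }, numeric(1))
  ord <- retained[order(min_adj, retained)]
  attr(ord, "stats") <- stats_tab
  ord
}
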