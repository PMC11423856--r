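#' @importFrom methods new is validObject slot
#' @importFrom stats rnorm runif rexp rbinom sd p.adjust wilcox.test t.test
#'   pchisq setNames optimize quantile
#' @importFrom utils packageVersion head
NULL

# Validate a scalar against simple predicates; used by constructors so error
# messages name the offending argument.
.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                          integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name),
         call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

# Roman-numeral subtype names: "S-I", "S-II", ...
.subtype_names <- function(k) paste0("S-", as.character(utils::as.roman(seq_len(k))))

# md5 digest of an arbitrary R object (serialized to a temp file).
.object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
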