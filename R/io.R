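.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "", comment.char = "")
}

#' Read a protein intensity table
#'
#' Expects a tab-delimited file with a header row of sample ids, a first
#' column of unique protein ids, a column `n_peptides` with the
#' theoretical observable peptide counts, and one numeric column per
#' sample. Empty cells are the missing-value token and become 0
#' (not detected); literal zeros mean the same.
#'
#' @param path file path.
#' @return an [IntensityExperiment-class].
#' @export
readIntensity <- function(path) {
  df <- .read_tsv(path)
  if (!"n_peptides" %in% names(df))
    stop("column 'n_peptides' is required in ", path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated protein id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  np <- df$n_peptides
  samp <- setdiff(names(df)[-1], "n_peptides")
  m <- as.matrix(df[samp])
  if (!is.numeric(m)) {
    badcol <- samp[!vapply(df[samp], is.numeric, logical(1))]
    stop("non-numeric intensity column(s): ", paste(badcol, collapse = ", "))
  }
  m[is.na(m)] <- 0
  rownames(m) <- ids
  IntensityExperiment(m, np)
}

#' Read a FOT abundance table
#'
#' Tab-delimited proteins x samples matrix of FOT values: header row of
#' sample ids, first column of unique protein ids. Empty cells and zeros
#' are treated as not detected. The result is unimputed; run
#' [imputeMissing()] before downstream analysis.
#'
#' @param path file path.
#' @return an [AbundanceExperiment-class].
#' @export
readAbundance <- function(path) {
  df <- .read_tsv(path)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated protein id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(df[-1])
  if (!is.numeric(m)) {
    badcol <- names(df)[-1][!vapply(df[-1], is.numeric, logical(1))]
    stop("non-numeric abundance column(s): ", paste(badcol, collapse = ", "))
  }
  m[is.na(m)] <- 0
  rownames(m) <- ids
  .new_abundance(m, m > 0,
                 matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m)))
}

#' Write a FOT abundance table
#'
#' Inverse of [readAbundance()]: undetected, unimputed entries are
#' written as the empty missing-value token so a write/read round trip
#' reproduces the object.
#'
#' @param object an [AbundanceExperiment-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeAbundance <- function(object, path) {
  f <- fot(object)
  chr <- matrix(format(f, digits = 15, trim = TRUE, scientific = TRUE),
                nrow(f), ncol(f), dimnames = dimnames(f))
  chr[!detected(object) & !imputed(object)] <- ""
  df <- data.frame(protein_id = rownames(f), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.clinical_schema <- list(
  required = c("sample_id", "os_years", "os_event"),
  tnm_levels = c("I", "II", "III", "IV"),
  valg_levels = c("LS", "ES"),
  ici_levels = c("first", "later", "none"))

#' Validate a clinical table
#'
#' Checks id uniqueness, non-negative times, and the stage/treatment
#' enumerations; errors name the offending column and rows.
#'
#' @param clinical data.frame.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validateClinical <- function(clinical) {
  miss <- setdiff(.clinical_schema$required, names(clinical))
  if (length(miss)) {
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  dup <- clinical$sample_id[duplicated(clinical$sample_id)]
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(clinical$os_years < 0, na.rm = TRUE)) {
    stop("negative values in column 'os_years', row(s): ",
         paste(which(clinical$os_years < 0), collapse = ", "))
  }
  check_enum <- function(col, levels) {
    if (!col %in% names(clinical)) return()
    v <- clinical[[col]]
    bad <- which(!is.na(v) & !v %in% levels)
    if (length(bad)) {
      stop(sprintf("invalid value(s) in column '%s', row(s) %s: %s",
                   col, paste(head(bad, 5), collapse = ", "),
                   paste(unique(v[bad]), collapse = ", ")))
    }
  }
  check_enum("tnm_stage", .clinical_schema$tnm_levels)
  check_enum("valg_stage", .clinical_schema$valg_levels)
  check_enum("ici_line", .clinical_schema$ici_levels)
  clinical
}

#' Read a clinical table
#'
#' Tab-delimited, one row per sample, with at least `sample_id`,
#' `os_years`, `os_event`; optional columns `pfs_years`, `pfs_event`,
#' `age`, `gender`, `smoking`, `lnm`, `tnm_stage` (I-IV), `valg_stage`
#' (LS/ES), `chemotherapy`, `ici_line` (first/later/none). Schema
#' violations raise addressed errors before anything downstream runs.
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
readClinical <- function(path) {
  df <- .read_tsv(path)
  for (col in c("os_event", "pfs_event", "smoking", "lnm", "chemotherapy")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  validateClinical(df)
}

#' Write a clinical table
#'
#' @param clinical data.frame (validated).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline configuration
#'
#' YAML file with any of the pipeline thresholds (defaults used for the
#' rest) and a mandatory `seed`. Unknown keys raise an error so typos do
#' not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return named list merged over the defaults of [pipelineDefaults()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- pipelineDefaults()
  unknown <- setdiff(names(cfg), c(names(defaults), "seed"))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("'seed' is mandatory in the pipeline config")
  out <- utils::modifyList(defaults, cfg)
  out$seed <- as.integer(out$seed)
  out
}

#' Default pipeline thresholds
#'
#' @return named list of every tunable stage parameter with its default.
#' @export
pipelineDefaults <- function() {
  list(clustering_top_n = 1100, clustering_min_detect = 0.10,
       cv_threshold = 1.9,
       classifier_top_n = 500, classifier_min_detect = 0.25,
       classifier_fc_min = 1.5, classifier_alpha = 0.05,
       signature_fc = c("S-I" = 3, "S-II" = 3, "S-III" = 10),
       signature_alpha = 0.05,
       k_range = 2:6, n_runs = 50, silhouette_min = 0.8, min_class = 10,
       prognostic_alpha = 0.01,
       n_trees = 500, n_folds = 10,
       seed = NULL)
}
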