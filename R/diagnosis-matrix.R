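#' Binary patient-by-diagnosis matrix with covariates
#'
#' The root input of the pipeline: a sparse binary occurrence matrix
#' (patients in rows, disease codes in columns) plus a per-patient
#' covariate table (age, sex, subtype, and any extras). Disease codes are
#' opaque strings; no vocabulary semantics are attached.
#'
#' @param occurrence a binary matrix or sparse Matrix, patients x diseases,
#'   with unique row (patient) and column (disease) names.
#' @param covariates a data.frame with one row per patient, rownames (or a
#'   `patient_id` column) matching the occurrence rownames.
#' @return an object of class `diagnosis_matrix` with elements
#'   `occurrence` (a `dgCMatrix`), `covariates` (a data.frame),
#'   `patients` and `diseases` (character vectors).
#' @export
diagnosis_matrix <- function(occurrence, covariates = NULL) {
  occ <- methods::as(methods::as(methods::as(occurrence, "dMatrix"),
                                 "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(occ)) || is.null(colnames(occ)))
    stop("occurrence must have patient rownames and disease colnames")
  if (anyDuplicated(rownames(occ))) stop("patient ids must be unique")
  if (anyDuplicated(colnames(occ))) stop("disease codes must be unique")
  if (length(occ@x) && any(occ@x != 1))
    stop("occurrence entries must be binary (0/1)")
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = rownames(occ))
  } else {
    if (!is.null(covariates$patient_id)) {
      rownames(covariates) <- covariates$patient_id
      covariates$patient_id <- NULL
    }
    if (!all(rownames(occ) %in% rownames(covariates)))
      stop("covariates missing for some patients")
    covariates <- covariates[rownames(occ), , drop = FALSE]
  }
  structure(
    list(occurrence = occ, covariates = covariates,
         patients = rownames(occ), diseases = colnames(occ)),
    class = "diagnosis_matrix")
}

#' @export
print.diagnosis_matrix <- function(x, ...) {
  cat("diagnosis_matrix:", length(x$patients), "patients x",
      length(x$diseases), "diseases\n")
  cat("  recorded diagnoses:", length(x$occurrence@x),
      sprintf("(fill %.3f%%)\n",
              100 * length(x$occurrence@x) /
                (length(x$patients) * length(x$diseases))))
  if (ncol(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Disease prevalence (number of patients with a record)
#' @param dm a `diagnosis_matrix`.
#' @return named integer vector of per-disease patient counts.
#' @export
disease_prevalence <- function(dm) {
  stopifnot(inherits(dm, "diagnosis_matrix"))
  stats::setNames(as.integer(Matrix::colSums(dm$occurrence)), dm$diseases)
}

#' Read a diagnosis matrix from long-format TSV files
#'
#' @param diagnoses_tsv path to a TSV with columns `patient_id`,
#'   `disease_code` (one row per recorded diagnosis).
#' @param covariates_tsv optional path to a TSV with a `patient_id` column;
#'   patients present only here are kept as all-zero rows.
#' @return a `diagnosis_matrix`.
#' @export
read_diagnosis_matrix <- function(diagnoses_tsv, covariates_tsv = NULL) {
  dx <- utils::read.delim(diagnoses_tsv, colClasses = "character")
  stopifnot(all(c("patient_id", "disease_code") %in% names(dx)))
  cov <- NULL
  pats <- unique(dx$patient_id)
  if (!is.null(covariates_tsv)) {
    cov <- utils::read.delim(covariates_tsv)
    cov$patient_id <- as.character(cov$patient_id)
    pats <- union(pats, cov$patient_id)
  }
  dis <- sort(unique(dx$disease_code))
  occ <- Matrix::sparseMatrix(
    i = match(dx$patient_id, pats), j = match(dx$disease_code, dis),
    x = 1, dims = c(length(pats), length(dis)),
    dimnames = list(pats, dis), use.last.ij = TRUE)
  diagnosis_matrix(occ, cov)
}

#' Write a diagnosis matrix as long-format TSV files
#' @param dm a `diagnosis_matrix`.
#' @param diagnoses_tsv,covariates_tsv output paths (`covariates_tsv`
#'   optional).
#' @return invisibly, `dm`.
#' @export
write_diagnosis_matrix <- function(dm, diagnoses_tsv, covariates_tsv = NULL) {
  stopifnot(inherits(dm, "diagnosis_matrix"))
  tr <- Matrix::summary(dm$occurrence)
  long <- data.frame(patient_id = dm$patients[tr$i],
                     disease_code = dm$diseases[tr$j])
  long <- long[order(long$patient_id, long$disease_code), ]
  utils::write.table(long, diagnoses_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(covariates_tsv)) {
    cov <- cbind(patient_id = rownames(dm$covariates), dm$covariates)
    utils::write.table(cov, covariates_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dm)
}
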