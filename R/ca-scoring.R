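## ---- correspondence-analysis drug scoring --------------------------------
## Medications are tabulated against the fall outcome; the standardized
## residual matrix of the contingency table is decomposed by SVD and the
## first-dimension row standard coordinates become per-drug scores. A
## patient's drug falling measure is the mean score of their medications.

#' Tabulate medication usage against the fall outcome
#'
#' Builds the medication-by-outcome contingency table: cell `(drug, outcome)`
#' counts the patients with that outcome whose medication list contains the
#' drug. A patient on `m` catalog drugs contributes to `m` rows; drugs used
#' by no patient are dropped.
#'
#' @param patients a data.frame with list column `medications` and binary
#'   column `fall`.
#' @param catalog character vector of catalog drug names (only these are
#'   tabulated).
#' @return An object of class `contingency_table`: list with `row_labels`
#'   (drug names) and `counts`, an `R x 2` integer matrix with columns
#'   `no_fall`, `fall`.
#' @export
build_medication_table <- function(patients, catalog = drug_catalog()$name) {
  if (length(catalog) == 0) stop("catalog must be nonempty", call. = FALSE)
  if (anyNA(patients$fall) || !is_binary01(patients$fall)) {
    stop("every patient needs a binary fall value", call. = FALSE)
  }
  n_per <- lengths(patients$medications)
  drug <- unlist(patients$medications, use.names = FALSE)
  fall <- rep(patients$fall, n_per)
  keep <- drug %in% catalog
  drug <- drug[keep]; fall <- fall[keep]
  if (length(drug) == 0) {
    stop("no catalog medication is used by any patient; cannot build table",
         call. = FALSE)
  }
  used <- catalog[catalog %in% unique(drug)]
  counts <- cbind(
    no_fall = vapply(used, function(d) sum(drug == d & fall == 0L), 0L),
    fall    = vapply(used, function(d) sum(drug == d & fall == 1L), 0L)
  )
  rownames(counts) <- used
  structure(list(row_labels = used, counts = counts),
            class = "contingency_table")
}

#' Correspondence analysis of a medication-by-outcome table
#'
#' Forms the correspondence matrix `P = N / n`, the row and column masses
#' `r = P 1`, `c = t(P) 1`, and the standardized residual
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}`; the SVD of `S` yields singular
#' values and row standard coordinates `D_r^{-1/2} u` for each dimension.
#' The first-dimension row scores are the per-drug values; their sign is
#' fixed so that higher score means higher observed fall share
#' (`orientation` records whether the raw SVD sign was flipped). Total
#' inertia is the sum of squared singular values and `n * inertia`
#' reproduces the Pearson chi-square statistic of the table.
#'
#' @param tab a [build_medication_table()] result, or any list with a
#'   nonnegative two-column `counts` matrix and `row_labels`.
#' @return An object of class `ca_result` with elements `row_scores` (named),
#'   `col_scores`, `singular_values`, `total_inertia`, `chi_square`,
#'   `orientation` (+1/-1), and the ingredients `P`, `r`, `c`, `n`.
#' @export
compute_ca <- function(tab) {
  counts <- tab$counts
  if (ncol(counts) != 2L) stop("counts must have two outcome columns",
                               call. = FALSE)
  if (nrow(counts) < 2L) stop("need at least two medication rows",
                              call. = FALSE)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(counts) == 0)) {
    stop("contingency table has a zero row after filtering", call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    stop("an outcome column is unobserved; both outcome totals must be positive",
         call. = FALSE)
  }
  n <- sum(counts)
  P <- counts / n
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - tcrossprod(r, cm)) %*% diag(1 / sqrt(cm))
  sv <- svd(S)
  ## standard coordinates on the first dimension
  row_scores <- as.numeric(sv$u[, 1L] / sqrt(r))
  col_scores <- as.numeric(sv$v[, 1L] / sqrt(cm))
  ## orientation: higher score must track higher fall share
  fall_share <- counts[, 2L] / rowSums(counts)
  orientation <- 1
  if (sv$d[1L] > 1e-12) {
    cr <- sum((row_scores - mean(row_scores)) *
                (fall_share - mean(fall_share)))
    if (cr < 0) orientation <- -1
  } else {
    row_scores[] <- 0   # independence: no association to orient
    col_scores[] <- 0
  }
  row_scores <- orientation * row_scores
  col_scores <- orientation * col_scores
  names(row_scores) <- tab$row_labels
  total_inertia <- sum(sv$d^2)
  structure(
    list(row_scores = row_scores, col_scores = col_scores,
         singular_values = sv$d, total_inertia = total_inertia,
         chi_square = n * total_inertia, orientation = orientation,
         P = P, r = r, c = cm, n = n),
    class = "ca_result"
  )
}

#' Drug falling measure of one patient
#'
#' The arithmetic mean of the CA row scores over the patient's medications
#' that received a score; `NA` when none did. A vector of medication names
#' may be passed directly.
#'
#' @param patient a one-row patient record with a `medications` list column,
#'   or a character vector of medication names.
#' @param ca a [compute_ca()] result (or any named score vector via
#'   `ca$row_scores`).
#' @return A single numeric measure, or `NA_real_` if the patient has no
#'   scored medication.
#' @examples
#' ca <- list(row_scores = c(A = -0.30, B = 0.20, C = 1.20))
#' drug_falling_measure(c("A", "B", "C"), ca)   # 0.3666...
#' @export
drug_falling_measure <- function(patient, ca) {
  meds <- if (is.character(patient)) patient else patient$medications[[1L]]
  s <- ca$row_scores[meds[meds %in% names(ca$row_scores)]]
  if (length(s) == 0) NA_real_ else mean(s)
}

#' Attach drug falling measures to a cohort
#'
#' Vectorized [drug_falling_measure()]: adds a `drug_measure` column and a
#' logical `measure_missing` flag (no scored medication).
#'
#' @param patients cohort data.frame with a `medications` list column.
#' @param ca a [compute_ca()] result.
#' @return `patients` with columns `drug_measure` and `measure_missing`.
#' @export
add_drug_measure <- function(patients, ca) {
  sc <- ca$row_scores
  patients$drug_measure <- vapply(patients$medications, function(m) {
    s <- sc[m[m %in% names(sc)]]
    if (length(s) == 0) NA_real_ else mean(s)
  }, numeric(1))
  patients$measure_missing <- is.na(patients$drug_measure)
  patients
}

#' Prepare the latent-class analysis table
#'
#' Merges the drug falling measure into the cohort and applies the
#' missing-measure policy: patients with no scored medication are excluded
#' (the default, mirroring a missing-data reduction) or assigned measure 0.
#'
#' @param patients cohort data.frame.
#' @param ca a [compute_ca()] result.
#' @param missing_policy `"exclude"` or `"impute_zero"`.
#' @return A data.frame with the seven indicators, `age`, `gender`,
#'   `n_meds`, `drug_measure` and `fall`, ready for [fit_em()].
#' @export
prepare_lca_data <- function(patients, ca,
                             missing_policy = c("exclude", "impute_zero")) {
  missing_policy <- match.arg(missing_policy)
  d <- add_drug_measure(patients, ca)
  if (missing_policy == "exclude") {
    d <- d[!d$measure_missing, , drop = FALSE]
  } else {
    d$drug_measure[d$measure_missing] <- 0
  }
  keep <- c("id", indicator_names(), "age", "gender", "n_meds",
            "drug_measure", "fall")
  keep <- keep[keep %in% names(d)]
  out <- d[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the drug score table as delimited text
#'
#' Writes one row per scored medication with its user count and CA score,
#' the standard layout of published fall-risk drug score tables.
#'
#' @param ca a [compute_ca()] result.
#' @param tab the [build_medication_table()] the scores came from.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_drug_scores <- function(ca, tab, path) {
  df <- data.frame(name = tab$row_labels,
                   count = rowSums(tab$counts),
                   score = round(unname(ca$row_scores), 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
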