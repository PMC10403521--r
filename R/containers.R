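#' Dosage matrix container
#'
#' Pairs a variants-by-subjects matrix of alternate-allele dosages in
#' [0, 2] with per-variant metadata. Subject alignment to a cohort table is
#' positional and checked by id via [align_dosage()].
#'
#' @param dosage numeric matrix, variants in rows, subjects in columns;
#'   column names are subject ids, row names variant ids.
#' @param info data.frame with one row per variant: `id`, `chr`, `bp`
#'   (1-based), `ref`, `alt`, `imputation_r2`.
#' @return object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosage, info) {
  dosage <- as.matrix(dosage)
  stopifnot(is.data.frame(info), nrow(info) == nrow(dosage),
            all(c("id", "chr", "bp", "ref", "alt", "imputation_r2") %in%
                  names(info)))
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]")
  }
  rownames(dosage) <- info$id
  structure(list(dosage = dosage, info = info), class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix: ", nrow(x$dosage), " variants x ", ncol(x$dosage),
      " subjects\n", sep = "")
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosage)

#' Subset a dosage matrix by variant
#'
#' @param x `dosage_matrix`.
#' @param variants integer/logical/character index into the variants.
#' @return `dosage_matrix` restricted to the selected variants.
#' @export
subset_variants <- function(x, variants) {
  stopifnot(inherits(x, "dosage_matrix"))
  if (is.character(variants)) variants <- match(variants, x$info$id)
  dosage_matrix(x$dosage[variants, , drop = FALSE],
                x$info[variants, , drop = FALSE])
}

#' Check and enforce cohort/dosage subject alignment
#'
#' @param cohort cohort data.frame with `subject_id`.
#' @param dosage `dosage_matrix` whose columns are subject ids.
#' @return the dosage matrix with columns reordered to the cohort order.
#' @export
align_dosage <- function(cohort, dosage) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  ids <- cohort$subject_id
  miss <- setdiff(ids, colnames(dosage$dosage))
  if (length(miss)) {
    stop("subject id mismatch between phenotype table and genotypes: ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  dosage$dosage <- dosage$dosage[, ids, drop = FALSE]
  dosage
}

# Validate the minimal cohort contract used across the scan functions.
check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "status", "exposure") %in% names(cohort)))
  if (any(!cohort$status %in% c(0, 1))) stop("status must be 0/1")
  if (anyNA(cohort$exposure) || any(!cohort$exposure %in% c(0, 1))) {
    stop("exposure must be 0/1 with no missing values")
  }
  if (all(cohort$status == 0) || all(cohort$status == 1)) {
    stop("cohort needs at least one case and one control")
  }
  invisible(cohort)
}
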