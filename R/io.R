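#' Read a dosage VCF into a dosage matrix
#'
#' Reads per-sample alternate-allele dosages from the DS FORMAT field of a
#' VCF (positions 1-based, as in the format). Biallelic records only:
#' multi-allelic records are skipped with a warning and counted in the
#' returned QC attribute. Records without a DS entry fall back to hard
#' calls from GT (count of alternate alleles) with a warning. Imputation
#' quality is taken from the INFO `R2=` key when present (1 otherwise).
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @return a [dosage_matrix()]; attribute `skipped_multiallelic` counts
#'   skipped records.
#' @export
read_dosage_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  ds <- suppressWarnings(
    vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
  gt <- vcfR::extract.gt(v, element = "GT")
  need_gt <- apply(is.na(ds), 1, all)
  if (any(need_gt & !multi)) {
    warning(sum(need_gt & !multi),
            " record(s) without DS: hard-call GT fallback used")
    hard <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(g, "[/|]"), function(al)
               sum(al %in% c("1")), numeric(1)))
    }
    for (i in which(need_gt)) ds[i, ] <- hard(gt[i, ])
  }
  r2 <- rep(1, nrow(fix))
  has_r2 <- grepl("(^|;)R2=", fix$INFO %||% "")
  r2[has_r2] <- as.numeric(sub(".*(?:^|;)R2=([0-9.eE+-]+).*", "\\1",
                               fix$INFO[has_r2], perl = TRUE))
  info <- data.frame(id = fix$ID, chr = fix$CHROM, bp = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, imputation_r2 = r2,
                     stringsAsFactors = FALSE)
  keep <- !multi
  out <- dosage_matrix(ds[keep, , drop = FALSE], info[keep, , drop = FALSE])
  attr(out, "skipped_multiallelic") <- sum(multi)
  out
}

#' Write a dosage matrix as a VCF with DS genotypes
#'
#' Emits a minimal VCFv4.2 with GT (hard call by rounding) and DS per
#' sample, suitable for round-tripping through [read_dosage_vcf()].
#'
#' @param dosage a [dosage_matrix()].
#' @param path output path.
#' @export
write_dosage_vcf <- function(dosage, path) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dosage$dosage)), collapse = "\t")), con)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1]
  for (i in seq_len(nrow(dosage$dosage))) {
    d <- dosage$dosage[i, ]
    cells <- ifelse(is.na(d), "./.:.",
                    paste0(gt_of(d), ":", sprintf("%.10g", d)))
    writeLines(paste(c(dosage$info$chr[i], dosage$info$bp[i],
                       dosage$info$id[i], dosage$info$ref[i],
                       dosage$info$alt[i], ".", "PASS",
                       paste0("R2=", dosage$info$imputation_r2[i]),
                       "GT:DS", cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Header-driven tab-separated table with required columns `id`, `status`
#' (0/1) and the exposure column (default `diabetes`, 0/1); remaining
#' declared covariate columns are carried through. Subjects with missing
#' exposure are dropped and counted (exposure-missing subjects cannot enter
#' an interaction model), mirroring standard exclusion practice.
#'
#' @param path file path.
#' @param exposure name of the exposure column in the file.
#' @param covariates covariate columns to keep (default: all others).
#' @return cohort data.frame (`subject_id`, `status`, `exposure`,
#'   covariates); attribute `n_dropped_missing_exposure`.
#' @export
read_phenotype_table <- function(path, exposure = "diabetes",
                                 covariates = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "status", exposure)
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!tab$status %in% c(0, 1))) stop("status must be 0/1")
  dropped <- sum(is.na(tab[[exposure]]))
  if (dropped > 0) {
    message(dropped, " subject(s) with missing exposure dropped")
    tab <- tab[!is.na(tab[[exposure]]), , drop = FALSE]
  }
  if (any(!tab[[exposure]] %in% c(0, 1))) stop("exposure must be 0/1")
  if (is.null(covariates)) covariates <- setdiff(names(tab), need)
  out <- data.frame(subject_id = as.character(tab$id),
                    status = as.integer(tab$status),
                    exposure = as.integer(tab[[exposure]]),
                    stringsAsFactors = FALSE)
  for (v in covariates) out[[v]] <- tab[[v]]
  attr(out, "n_dropped_missing_exposure") <- dropped
  out
}

#' Write a cohort as a phenotype table
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @param exposure column name to use for the exposure in the file.
#' @export
write_phenotype_table <- function(cohort, path, exposure = "diabetes") {
  out <- cohort
  names(out)[names(out) == "subject_id"] <- "id"
  names(out)[names(out) == "exposure"] <- exposure
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts: given the allele counts, the
#' p-value is the total probability of heterozygote counts at most as
#' probable as the observed one under the Hardy-Weinberg conditional
#' distribution. Continuous dosages are hard-called upstream.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative integer genotype counts.
#' @return two-sided exact p-value.
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2 * n_hom_alt + n_het      # minor-side allele count bookkeeping
  n_b <- 2 * n_hom_ref + n_het
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each possible heterozygote count
  logp <- vapply(hets, function(h) {
    na <- (rare - h) / 2                 # rare-allele homozygotes
    nb <- n - na - h
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' QC thresholds for variant filtering
#'
#' Defaults reflect standard genotyping/imputation practice: variants fail
#' on Hardy-Weinberg deviation in controls at p < 1e-4, call rate below
#' 95% (platforms differ, up to 98% supported), imputation R-squared below
#' 0.8, and - for a common-variant scan - MAF below 1%. All thresholds are
#' strict inequalities in the failing direction.
#'
#' @param hwe_p_min,call_rate_min,imputation_r2_min,maf_common_min
#'   thresholds.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-4, call_rate_min = 0.95,
                          imputation_r2_min = 0.8, maf_common_min = 0.01) {
  structure(list(hwe_p_min = hwe_p_min, call_rate_min = call_rate_min,
                 imputation_r2_min = imputation_r2_min,
                 maf_common_min = maf_common_min),
            class = "qc_thresholds")
}

#' Filter variants on QC thresholds
#'
#' Applies, in order, call rate, Hardy-Weinberg (computed on hard-called
#' genotypes in controls only when a status vector is given), imputation
#' R-squared, and the common-variant MAF bound. Each failing variant is
#' attributed to the first rule it fails, so the per-reason counts in the
#' report sum to the number removed.
#'
#' @param dosage a [dosage_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @param status optional 0/1 vector aligned to the dosage columns; when
#'   present, HWE uses controls only.
#' @return list with `dosage` (surviving subset) and `report` (data.frame
#'   of per-reason counts plus totals). An empty survivor set is allowed
#'   with a warning.
#' @export
qc_filter_variants <- function(dosage, thresholds = qc_thresholds(),
                               status = NULL) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  G <- dosage$dosage
  m <- nrow(G)
  cols <- if (is.null(status)) seq_len(ncol(G)) else which(status == 0)
  reason <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    g <- G[i, ]
    cr <- mean(!is.na(g))
    if (cr < thresholds$call_rate_min) { reason[i] <- "call_rate"; next }
    hc <- pmin(pmax(round(g[cols]), 0), 2)
    hc <- hc[!is.na(hc)]
    cnt <- c(sum(hc == 0), sum(hc == 1), sum(hc == 2))
    hwe_p <- if (sum(cnt) == 0) 1 else
      hwe_exact_test(cnt[1], cnt[2], cnt[3])
    if (hwe_p < thresholds$hwe_p_min) { reason[i] <- "hwe"; next }
    if (dosage$info$imputation_r2[i] < thresholds$imputation_r2_min) {
      reason[i] <- "imputation_r2"; next
    }
    aaf <- mean(g, na.rm = TRUE) / 2
    if (min(aaf, 1 - aaf) < thresholds$maf_common_min) {
      reason[i] <- "maf"; next
    }
  }
  keep <- is.na(reason)
  if (!any(keep)) warning("no variants survive QC")
  tab <- table(factor(reason, c("call_rate", "hwe", "imputation_r2", "maf")))
  report <- data.frame(reason = names(tab), removed = as.integer(tab))
  report <- rbind(report,
                  data.frame(reason = c("total_removed", "surviving"),
                             removed = c(sum(!keep), sum(keep))))
  list(dosage = subset_variants(dosage, which(keep)), report = report)
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Values that parse as numbers are returned numeric.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
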