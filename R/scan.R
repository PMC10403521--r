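#' Single-variant association and interaction tests
#'
#' The per-variant operations behind a genome-wide gene-environment scan of
#' a case-control cohort with a binary exposure. All models are logistic and
#' adjust for the supplied covariates (reference-coded; complete cases per
#' model):
#'
#' * `test_marginal_g`: 1-d.f. Wald test of G in `logit(D) ~ G + covariates`
#'   (the marginal genotype-disease association).
#' * `test_ge_association`: 1-d.f. Wald test of G in
#'   `logit(E) ~ G + covariates` fitted on cases and controls pooled (the
#'   genotype-exposure association).
#' * `test_gxe_1df`: 1-d.f. test of the product term in
#'   `logit(D) ~ G + E + G:E + covariates` (Wald by default; a
#'   likelihood-ratio version is available via `method = "lrt"`).
#' * `test_joint_2df`: 2-d.f. likelihood-ratio test of the full model
#'   against `logit(D) ~ E + covariates`, testing the genetic main effect
#'   and the interaction simultaneously.
#' * `test_joint_3df`: sum of the three 1-d.f. chi-squares (marginal G, G-E
#'   association, GxE) referred to a chi-square with 3 d.f.; the components
#'   are asymptotically independent under the global null.
#'
#' Degenerate variants (monomorphic dosage, collinear product term,
#' separation) are flagged in the returned value rather than raised, so a
#' scan can record the row and continue.
#'
#' @param cohort cohort data.frame (`subject_id`, `status`, `exposure`,
#'   covariates).
#' @param g numeric dosage vector in [0, 2], aligned to the cohort rows.
#' @param covariates character vector of covariate column names; default all
#'   columns except id/status/exposure.
#' @param method for `test_gxe_1df`, `"wald"` (default) or `"lrt"`.
#' @return a list with `chi2`, `p`, and a `flag` string (`"ok"` or the
#'   degeneracy reason); `test_gxe_1df` adds `beta` and `se` for the
#'   interaction coefficient.
#' @name variant_tests
NULL

flagged <- function(flag, extra = list()) {
  c(list(chi2 = NA_real_, p = NA_real_, flag = flag), extra)
}

#' @rdname variant_tests
#' @export
test_marginal_g <- function(cohort, g, covariates = NULL) {
  check_cohort(cohort)
  if (stats::var(g) == 0) return(flagged("monomorphic"))
  b <- build_design(cohort, extras = list(G = g), covariates = covariates)
  fit <- tryCatch(fit_logistic(b$design, cohort$status[b$keep]),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(flagged(if (is.null(fit)) "singular" else "non-converged"))
  }
  w <- wald_test(fit, "G")
  list(chi2 = w$chi2, p = w$p, beta = w$beta, se = w$se, flag = "ok")
}

#' @rdname variant_tests
#' @export
test_ge_association <- function(cohort, g, covariates = NULL) {
  check_cohort(cohort)
  if (stats::var(g) == 0) return(flagged("monomorphic"))
  if (stats::var(cohort$exposure) == 0) return(flagged("constant-exposure"))
  b <- build_design(cohort, extras = list(G = g), covariates = covariates)
  fit <- tryCatch(fit_logistic(b$design, cohort$exposure[b$keep]),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(flagged(if (is.null(fit)) "singular" else "non-converged"))
  }
  w <- wald_test(fit, "G")
  list(chi2 = w$chi2, p = w$p, beta = w$beta, se = w$se, flag = "ok")
}

#' @rdname variant_tests
#' @export
test_gxe_1df <- function(cohort, g, covariates = NULL,
                         method = c("wald", "lrt")) {
  method <- match.arg(method)
  check_cohort(cohort)
  if (stats::var(g) == 0) return(flagged("monomorphic"))
  if (stats::var(cohort$exposure) == 0) return(flagged("constant-exposure"))
  E <- cohort$exposure
  b <- build_design(cohort, extras = list(G = g, E = E, `G:E` = g * E),
                    covariates = covariates)
  fit <- tryCatch(fit_logistic(b$design, cohort$status[b$keep]),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    return(flagged(if (grepl("singular", conditionMessage(fit)))
      "collinear" else "error"))
  }
  if (!fit$converged) return(flagged("non-converged"))
  if (method == "wald") {
    w <- wald_test(fit, "G:E")
    list(chi2 = w$chi2, p = w$p, beta = w$beta, se = w$se, flag = "ok")
  } else {
    bred <- build_design(cohort, extras = list(G = g, E = E),
                         covariates = covariates)
    red <- fit_logistic(bred$design, cohort$status[bred$keep])
    lr <- lrt_test(fit, red, df = 1)
    list(chi2 = lr$chi2, p = lr$p,
         beta = fit$coefficients[["G:E"]], se = fit$se[["G:E"]], flag = "ok")
  }
}

#' @rdname variant_tests
#' @export
test_joint_2df <- function(cohort, g, covariates = NULL) {
  check_cohort(cohort)
  if (stats::var(g) == 0) return(flagged("monomorphic"))
  E <- cohort$exposure
  bfull <- build_design(cohort, extras = list(G = g, E = E, `G:E` = g * E),
                        covariates = covariates)
  bred <- build_design(cohort, extras = list(E = E), covariates = covariates)
  full <- tryCatch(fit_logistic(bfull$design, cohort$status[bfull$keep]),
                   error = function(e) NULL)
  red <- tryCatch(fit_logistic(bred$design, cohort$status[bred$keep]),
                  error = function(e) NULL)
  if (is.null(full) || is.null(red) || !full$converged || !red$converged) {
    return(flagged("non-converged"))
  }
  lr <- lrt_test(full, red, df = 2)
  list(chi2 = lr$chi2, p = lr$p, flag = "ok")
}

#' @rdname variant_tests
#' @param chi2_dg,chi2_eg,chi2_gxe the three 1-d.f. component chi-squares
#'   (for `test_joint_3df` these can be given directly instead of
#'   recomputing).
#' @export
test_joint_3df <- function(cohort = NULL, g = NULL, covariates = NULL,
                           chi2_dg = NULL, chi2_eg = NULL, chi2_gxe = NULL) {
  if (is.null(chi2_dg)) {
    dg <- test_marginal_g(cohort, g, covariates)
    eg <- test_ge_association(cohort, g, covariates)
    ge <- test_gxe_1df(cohort, g, covariates)
    if (dg$flag != "ok" || eg$flag != "ok" || ge$flag != "ok") {
      return(flagged("component-flagged"))
    }
    chi2_dg <- dg$chi2; chi2_eg <- eg$chi2; chi2_gxe <- ge$chi2
  }
  if (anyNA(c(chi2_dg, chi2_eg, chi2_gxe))) return(flagged("component-flagged"))
  chi2 <- chi2_dg + chi2_eg + chi2_gxe
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 3, lower.tail = FALSE),
       flag = "ok")
}

#' Genome-wide scan over a dosage matrix
#'
#' Runs the single-variant test battery for every variant and returns one
#' row per variant. Columns: variant metadata, alternate allele frequency
#' (`aaf`), `chi2_dg`/`p_dg` (marginal genotype-disease), `chi2_eg`/`p_eg`
#' (genotype-exposure), `chi2_gxe`/`p_gxe`/`beta_gxe`/`se_gxe`
#' (interaction), `chi2_2df`/`p_2df`, `chi2_3df`/`p_3df`, and the EDGE
#' screening statistic `edge_stat`/`p_edge` (chi2_dg + chi2_eg on 2 d.f.).
#' A `flag` column records degeneracies per variant.
#'
#' @param cohort cohort data.frame.
#' @param dosage a [dosage_matrix()]; subjects are aligned to the cohort by
#'   id before testing.
#' @param covariates covariate column names (default: all non-core columns).
#' @param tests character subset of
#'   `c("dg", "eg", "gxe", "2df", "3df", "edge")`.
#' @param gxe_method `"wald"` or `"lrt"` for the 1-d.f. interaction test.
#' @return data.frame of class `gxe_scan`, one row per variant.
#' @examples
#' sim <- simulate_cohort(sim_config(n_studies = 2, n_cases = 100,
#'                                   n_controls = 100, n_variants = 3))
#' scan <- scan_variants(sim$cohort, sim$dosage)
#' scan[, c("id", "p_dg", "p_gxe", "p_3df")]
#' @export
scan_variants <- function(cohort, dosage,
                          covariates = NULL,
                          tests = c("dg", "eg", "gxe", "2df", "3df", "edge"),
                          gxe_method = c("wald", "lrt")) {
  check_cohort(cohort)
  gxe_method <- match.arg(gxe_method)
  tests <- match.arg(tests, several.ok = TRUE)
  dosage <- align_dosage(cohort, dosage)
  m <- nrow(dosage$dosage)
  num <- function() rep(NA_real_, m)
  out <- cbind(dosage$info,
               data.frame(aaf = num(),
                          chi2_dg = num(), p_dg = num(),
                          chi2_eg = num(), p_eg = num(),
                          chi2_gxe = num(), p_gxe = num(),
                          beta_gxe = num(), se_gxe = num(),
                          chi2_2df = num(), p_2df = num(),
                          chi2_3df = num(), p_3df = num(),
                          edge_stat = num(), p_edge = num(),
                          flag = rep("ok", m),
                          stringsAsFactors = FALSE))
  for (i in seq_len(m)) {
    g <- dosage$dosage[i, ]
    out$aaf[i] <- mean(g) / 2
    flags <- character(0)
    if ("dg" %in% tests || "3df" %in% tests || "edge" %in% tests) {
      r <- test_marginal_g(cohort, g, covariates)
      out$chi2_dg[i] <- r$chi2; out$p_dg[i] <- r$p
      if (r$flag != "ok") flags <- c(flags, paste0("dg:", r$flag))
    }
    if ("eg" %in% tests || "3df" %in% tests || "edge" %in% tests) {
      r <- test_ge_association(cohort, g, covariates)
      out$chi2_eg[i] <- r$chi2; out$p_eg[i] <- r$p
      if (r$flag != "ok") flags <- c(flags, paste0("eg:", r$flag))
    }
    if ("gxe" %in% tests || "3df" %in% tests) {
      r <- test_gxe_1df(cohort, g, covariates, method = gxe_method)
      out$chi2_gxe[i] <- r$chi2; out$p_gxe[i] <- r$p
      out$beta_gxe[i] <- r$beta %||% NA_real_
      out$se_gxe[i] <- r$se %||% NA_real_
      if (r$flag != "ok") flags <- c(flags, paste0("gxe:", r$flag))
    }
    if ("2df" %in% tests) {
      r <- test_joint_2df(cohort, g, covariates)
      out$chi2_2df[i] <- r$chi2; out$p_2df[i] <- r$p
      if (r$flag != "ok") flags <- c(flags, paste0("2df:", r$flag))
    }
    if ("3df" %in% tests) {
      r <- test_joint_3df(chi2_dg = out$chi2_dg[i], chi2_eg = out$chi2_eg[i],
                          chi2_gxe = out$chi2_gxe[i])
      out$chi2_3df[i] <- r$chi2; out$p_3df[i] <- r$p
    }
    if ("edge" %in% tests) {
      r <- edge_statistic(out$chi2_dg[i], out$chi2_eg[i])
      out$edge_stat[i] <- r$edge_stat; out$p_edge[i] <- r$p_edge
    }
    if (length(flags)) out$flag[i] <- paste(flags, collapse = ";")
  }
  class(out) <- c("gxe_scan", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a scan result table
#'
#' Tab-separated, one row per variant, stable column names as produced by
#' [scan_variants()].
#'
#' @param scan `gxe_scan` data.frame.
#' @param path file path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chr = "character"))
  class(out) <- c("gxe_scan", "data.frame")
  out
}

#' Genotype- and exposure-stratified odds ratios
#'
#' Reproduces the stratified display used to interpret a significant
#' interaction: (i) the odds ratio of exposure on disease within each
#' rounded genotype class (0, 1, 2 copies of the alternate allele), each
#' from a covariate-adjusted logistic fit restricted to that class, and
#' (ii) the per-allele odds ratio of the (continuous) dosage on disease
#' within each exposure stratum. Case/control counts per cell are
#' accumulated from the dosage-implied genotype probabilities (hard-call
#' rounding), exposure-split.
#'
#' @param cohort cohort data.frame.
#' @param g dosage vector aligned to the cohort.
#' @param covariates covariate column names.
#' @return object of class `stratified_or`: list with `by_genotype`
#'   (data.frame: genotype, cases/controls by exposure, OR of E with 95% CI
#'   and p; the first non-empty genotype class is the reference with OR
#'   fixed at 1) and `by_exposure` (data.frame: exposure stratum, per-allele
#'   OR with CI and p). Empty strata are omitted with a warning.
#' @export
stratified_ors <- function(cohort, g, covariates = NULL) {
  check_cohort(cohort)
  gc <- pmin(pmax(round(g), 0), 2)
  by_g <- data.frame(genotype = 0:2,
                     cases_unexposed = NA_real_, controls_unexposed = NA_real_,
                     cases_exposed = NA_real_, controls_exposed = NA_real_,
                     or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                     p = NA_real_)
  first_ok <- NA_integer_
  for (k in 0:2) {
    idx <- gc == k
    row <- k + 1L
    by_g$cases_unexposed[row] <- sum(cohort$status == 1 & cohort$exposure == 0 & idx)
    by_g$controls_unexposed[row] <- sum(cohort$status == 0 & cohort$exposure == 0 & idx)
    by_g$cases_exposed[row] <- sum(cohort$status == 1 & cohort$exposure == 1 & idx)
    by_g$controls_exposed[row] <- sum(cohort$status == 0 & cohort$exposure == 1 & idx)
    sub <- cohort[idx, , drop = FALSE]
    if (sum(idx) == 0) {
      warning("genotype stratum ", k, " is empty; omitted")
      next
    }
    ok <- length(unique(sub$status)) == 2 && length(unique(sub$exposure)) == 2
    if (!ok) next
    b <- build_design(sub, extras = list(E = sub$exposure),
                      covariates = covariates)
    fit <- tryCatch(fit_logistic(b$design, sub$status[b$keep]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    w <- wald_test(fit, "E")
    by_g$or[row] <- exp(w$beta)
    by_g$ci_lo[row] <- exp(w$beta - 1.96 * w$se)
    by_g$ci_hi[row] <- exp(w$beta + 1.96 * w$se)
    by_g$p[row] <- w$p
    if (is.na(first_ok)) first_ok <- row
  }
  by_e <- data.frame(exposure = 0:1, or = NA_real_, ci_lo = NA_real_,
                     ci_hi = NA_real_, p = NA_real_)
  for (e in 0:1) {
    idx <- cohort$exposure == e
    sub <- cohort[idx, , drop = FALSE]
    if (sum(idx) == 0 || length(unique(sub$status)) < 2 ||
        stats::var(g[idx]) == 0) {
      warning("exposure stratum ", e, " degenerate; omitted")
      next
    }
    b <- build_design(sub, extras = list(G = g[idx]), covariates = covariates)
    fit <- tryCatch(fit_logistic(b$design, sub$status[b$keep]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    w <- wald_test(fit, "G")
    by_e$or[e + 1L] <- exp(w$beta)
    by_e$ci_lo[e + 1L] <- exp(w$beta - 1.96 * w$se)
    by_e$ci_hi[e + 1L] <- exp(w$beta + 1.96 * w$se)
    by_e$p[e + 1L] <- w$p
  }
  structure(list(by_genotype = by_g, by_exposure = by_e,
                 reference_row = first_ok),
            class = "stratified_or")
}

#' @export
print.stratified_or <- function(x, ...) {
  cat("OR of exposure on disease, by genotype class:\n")
  print(x$by_genotype, digits = 3, row.names = FALSE)
  cat("\nPer-allele OR on disease, by exposure stratum:\n")
  print(x$by_exposure, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Crude odds ratio from a 2x2 table
#'
#' Cross-product OR with the Woolf (log) confidence interval,
#' `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. With a zero cell the
#' Haldane-Anscombe 0.5 correction is applied to all cells and the result
#' flagged.
#'
#' @param a,b,c,d counts: exposed cases, exposed controls, unexposed cases,
#'   unexposed controls.
#' @return list with `or`, `ci95` (length 2), `p` (two-sided Wald),
#'   `corrected` flag.
#' @examples
#' crude_or_2x2(300, 227, 2605, 3640)  # OR about 1.85
#' @export
crude_or_2x2 <- function(a, b, c, d) {
  stopifnot(all(c(a, b, c, d) >= 0))
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lor <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- lor / se
  list(or = exp(lor),
       ci95 = exp(lor + c(-1.96, 1.96) * se),
       p = 2 * stats::pnorm(-abs(z)),
       corrected = corrected)
}
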