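#' Per-study exposure-disease estimates
#'
#' Fits `logit(D) ~ E + covariates` separately within each study (no study
#' term, since the model is within-study) and returns the log odds ratio
#' and standard error of the exposure per study. Studies that cannot
#' support the model — no cases, no controls, constant exposure, an empty
#' exposure-by-status cell, or a non-converged fit — are excluded and
#' recorded in the `excluded` attribute.
#'
#' @param cohort cohort data.frame with a `study` column.
#' @param covariates covariate column names used within study (default: all
#'   non-core, non-study columns).
#' @return data.frame of class `study_estimates`: `study`, `log_or`, `se`,
#'   `n_cases`, `n_controls`; attribute `excluded` is a named character
#'   vector of reasons.
#' @export
per_study_estimates <- function(cohort, covariates = NULL) {
  check_cohort(cohort)
  stopifnot("study" %in% names(cohort))
  if (is.null(covariates)) {
    covariates <- setdiff(names(cohort),
                          c("subject_id", "status", "exposure", "study"))
  }
  studies <- unique(cohort$study)
  rows <- list()
  excluded <- character(0)
  for (s in studies) {
    sub <- cohort[cohort$study == s, , drop = FALSE]
    cells <- table(factor(sub$status, 0:1), factor(sub$exposure, 0:1))
    reason <- NULL
    if (length(unique(sub$status)) < 2) reason <- "single outcome class"
    else if (length(unique(sub$exposure)) < 2) reason <- "constant exposure"
    else if (any(cells == 0)) reason <- "empty exposure-by-status cell"
    if (is.null(reason)) {
      b <- build_design(sub, extras = list(E = sub$exposure),
                        covariates = covariates)
      fit <- tryCatch(fit_logistic(b$design, sub$status[b$keep]),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) reason <- "fit failed"
      else {
        rows[[s]] <- data.frame(study = s,
                                log_or = fit$coefficients[["E"]],
                                se = fit$se[["E"]],
                                n_cases = sum(sub$status == 1),
                                n_controls = sum(sub$status == 0),
                                stringsAsFactors = FALSE)
      }
    }
    if (!is.null(reason)) {
      excluded[s] <- reason
      message("study ", s, " excluded from meta-analysis: ", reason)
    }
  }
  if (length(rows) == 0) stop("no study yields a usable estimate")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("study_estimates", "data.frame")
  out
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator of the between-study variance tau-squared, truncated at
#' zero: with fixed-effect weights `w = 1/se^2`,
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` where Q is
#' Cochran's heterogeneity statistic.
#'
#' @param estimates data.frame with `log_or` and `se` (k >= 2 rows).
#' @return scalar tau-squared.
#' @export
dl_tau2 <- function(estimates) {
  k <- nrow(estimates)
  if (k < 2) stop("at least two studies required")
  y <- estimates$log_or
  w <- 1 / estimates$se^2
  yw <- sum(w * y) / sum(w)
  Q <- sum(w * (y - yw)^2)
  max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' Hartung-Knapp random-effects meta-analysis
#'
#' Random-effects synthesis with the Hartung-Knapp variance adjustment:
#' random-effects weights `w = 1/(se^2 + tau2)` (tau2 from
#' [dl_tau2()] unless supplied), pooled estimate the weighted mean, and
#' pooled variance `sum(w * (y - pooled)^2) / ((k - 1) * sum(w))` with
#' confidence interval and p-value from a t distribution on k - 1 degrees
#' of freedom. Cochran's Q (fixed-effect weights), its chi-square p-value
#' on k - 1 d.f., and `I2 = max(0, (Q - (k - 1)) / Q)` are attached.
#'
#' @param estimates data.frame with `log_or`, `se` (k >= 2 rows; a `study`
#'   column is carried through if present).
#' @param tau2 optional fixed between-study variance.
#' @return object of class `meta_result`: `log_or`, `se` (HK), `ci95` (log
#'   scale), `or`, `or_ci95`, `p`, `tau2`, `Q`, `Q_p`, `I2`, `k`.
#' @examples
#' est <- data.frame(log_or = c(0.2, 0.35, 0.3), se = c(0.1, 0.12, 0.09))
#' hk_meta(est)
#' @export
hk_meta <- function(estimates, tau2 = NULL) {
  k <- nrow(estimates)
  if (k < 2) stop("at least two studies required")
  y <- estimates$log_or
  v <- estimates$se^2
  wfe <- 1 / v
  yfe <- sum(wfe * y) / sum(wfe)
  Q <- sum(wfe * (y - yfe)^2)
  if (is.null(tau2)) tau2 <- dl_tau2(estimates)
  w <- 1 / (v + tau2)
  pooled <- sum(w * y) / sum(w)
  hk_var <- sum(w * (y - pooled)^2) / ((k - 1) * sum(w))
  se <- sqrt(hk_var)
  tq <- stats::qt(0.975, df = k - 1)
  tval <- pooled / se
  structure(list(log_or = pooled, se = se,
                 ci95 = pooled + c(-1, 1) * tq * se,
                 or = exp(pooled),
                 or_ci95 = exp(pooled + c(-1, 1) * tq * se),
                 p = 2 * stats::pt(-abs(tval), df = k - 1),
                 tau2 = tau2, Q = Q,
                 Q_p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
                 I2 = max(0, (Q - (k - 1)) / Q), k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects (Hartung-Knapp) meta-analysis of %d studies\n", x$k))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or, x$or_ci95[1], x$or_ci95[2], x$p))
  cat(sprintf("  tau2 = %.4f; Q = %.2f (p = %.3g); I2 = %.0f%%\n",
              x$tau2, x$Q, x$Q_p, 100 * x$I2))
  invisible(x)
}

#' Funnel-plot points and outlier flags
#'
#' Emits per-study effect versus precision pairs for a funnel plot, the
#' pooled reference value, and an outlier flag for studies whose
#' standardized deviation from the pooled estimate (using
#' `sqrt(se^2 + tau2)`) exceeds 3 in absolute value.
#'
#' @param estimates data.frame with `log_or`, `se` (and optionally `study`).
#' @return list with `points` (data.frame: study, effect = log_or,
#'   precision = 1/se, z, outlier) and `pooled` (log OR reference; NA with
#'   a single study).
#' @export
funnel_points <- function(estimates) {
  k <- nrow(estimates)
  stopifnot(k >= 1)
  if (k >= 2) {
    m <- hk_meta(estimates)
    pooled <- m$log_or
    tau2 <- m$tau2
  } else {
    pooled <- estimates$log_or[1]
    tau2 <- 0
  }
  z <- (estimates$log_or - pooled) / sqrt(estimates$se^2 + tau2)
  pts <- data.frame(
    study = if ("study" %in% names(estimates)) estimates$study
            else seq_len(k),
    effect = estimates$log_or,
    precision = 1 / estimates$se,
    z = z, outlier = abs(z) > 3,
    stringsAsFactors = FALSE)
  list(points = pts, pooled = pooled)
}

#' Read / write study-estimate tables
#'
#' Tab-separated with columns `study`, `log_or`, `se`, `n_cases`,
#' `n_controls`, allowing meta-analysis of externally supplied estimates.
#'
#' @param estimates `study_estimates` data.frame.
#' @param path file path.
#' @export
write_study_estimates <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_estimates
#' @export
read_study_estimates <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("study", "log_or", "se") %in% names(out)))
  if (any(out$se <= 0)) stop("standard errors must be positive")
  class(out) <- c("study_estimates", "data.frame")
  out
}
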