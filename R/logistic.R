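#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares
#'
#' Minimal, dependency-free logit fitter used by every scan operation. The
#' Bernoulli-logit likelihood is maximised by IRLS with a QR solve of the
#' weighted normal equations. Convergence is declared when the largest
#' absolute score (gradient) component falls below `score_tol` or the
#' relative change in log-likelihood falls below `ll_tol`.
#'
#' @param design numeric design matrix (n x p), including the intercept
#'   column. Must be full column rank; a rank-deficient design is an error
#'   naming the collinear columns.
#' @param outcome binary 0/1 vector of length n with both classes present.
#' @param score_tol convergence tolerance on the maximum absolute score.
#' @param ll_tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter iteration cap.
#'
#' @return object of class `gxe_fit`: list with `coefficients` (named),
#'   `covariance` (inverse observed information), `se`, `log_likelihood`,
#'   `converged`, `separation` (divergence flag), `n_iterations`, `n`.
#'
#' Quasi-complete separation is detected by diverging coefficients (fitted
#' logits exceeding +/-30); the fit is returned flagged non-converged rather
#' than raising, so a genome scan can record the row and move on.
#'
#' @examples
#' fit <- fit_logistic(cbind(1, rnorm(50)), rbinom(50, 1, 0.5))
#' fit$coefficients
#' @export
fit_logistic <- function(design, outcome, score_tol = 1e-8, ll_tol = 1e-10,
                         max_iter = 100L) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  y <- as.numeric(outcome)
  stopifnot(length(y) == nrow(X))
  if (any(!y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (all(y == 0) || all(y == 1)) stop("outcome has a single class")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }

  p <- ncol(X)
  beta <- numeric(p)
  ll_old <- -Inf
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 20) {  # diverging linear predictor: separation
      separation <- TRUE
      break
    }
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    ll <- sum(y * eta - log1p(exp(eta)))
    if (max(abs(score)) < score_tol ||
        abs(ll - ll_old) < ll_tol * (abs(ll_old) + ll_tol)) {
      ll_old <- ll
      converged <- TRUE
      break
    }
    ll_old <- ll
    # Newton step: solve (X'WX) d = score through the weighted QR
    sw <- sqrt(pmax(w, 1e-12))
    qrW <- qr(X * sw)
    d <- qr.coef(qrW, (y - mu) / sw)
    beta <- beta + d
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(pmax(w, 1e-12)))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    covariance = cov,
    se = sqrt(diag(cov)),
    log_likelihood = sum(y * eta - log1p(exp(eta))),
    converged = converged && !separation,
    separation = separation,
    n_iterations = iter,
    n = length(y)
  ), class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("Logistic fit (", x$n, " subjects, ",
      if (x$converged) "converged" else "NOT converged",
      if (x$separation) ", separation suspected" else "",
      ", ", x$n_iterations, " iterations)\n", sep = "")
  tab <- cbind(beta = x$coefficients, se = x$se,
               or = exp(x$coefficients),
               z = x$coefficients / x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Wald test of a single coefficient
#'
#' @param fit `gxe_fit` object.
#' @param term coefficient name.
#' @return list with `chi2` = (beta/se)^2, `p` (chi-square, 1 d.f.), `beta`,
#'   `se`.
#' @export
wald_test <- function(fit, term) {
  beta <- fit$coefficients[[term]]
  se <- fit$se[[term]]
  chi2 <- (beta / se)^2
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       beta = beta, se = se)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,reduced `gxe_fit` objects, reduced nested in full.
#' @param df degrees of freedom of the comparison.
#' @return list with `chi2`, `p`, `df`.
#' @export
lrt_test <- function(full, reduced, df) {
  chi2 <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  list(chi2 = chi2, p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
       df = df)
}

# Expand the cohort covariates into a reference-coded numeric design block.
# Factors/characters get indicator columns dropping the first level; study
# and platform are merged upstream into a single factor. No intercept here.
covariate_design <- function(cohort, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(cohort),
                          c("subject_id", "status", "exposure"))
  }
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  }
  blocks <- lapply(covariates, function(v) {
    x <- cohort[[v]]
    if (is.null(x)) stop("unknown covariate: ", v)
    if (is.character(x) || is.factor(x)) {
      x <- factor(x)
      if (nlevels(x) < 2) return(NULL)
      m <- stats::model.matrix(~x)[, -1, drop = FALSE]
      colnames(m) <- paste0(v, levels(x)[-1])
      m
    } else {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- v
      m
    }
  })
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0) {
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  }
  do.call(cbind, blocks)
}

# Assemble intercept + named extra columns + covariate block, dropping rows
# with missing values (complete-case per model). Returns list(design, keep).
build_design <- function(cohort, extras = list(), covariates = NULL) {
  covs <- covariate_design(cohort, covariates)
  ex <- if (length(extras)) {
    m <- do.call(cbind, lapply(extras, as.numeric))
    colnames(m) <- names(extras)
    m
  } else matrix(numeric(0), nrow = nrow(cohort), ncol = 0)
  X <- cbind(`(Intercept)` = 1, ex, covs)
  keep <- stats::complete.cases(X)
  list(design = X[keep, , drop = FALSE], keep = keep)
}
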