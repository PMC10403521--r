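#' Tail probability of a mixture of chi-squares
#'
#' Upper-tail probability of `Q = sum(lambda_i * chi2_1)` for non-negative
#' weights `lambda`, the null distribution of variance-component score
#' statistics. Methods: `"satterthwaite"` (two-moment scaled chi-square,
#' the default moment-matched approximation), `"liu"` (four-moment match of
#' Liu-Tang-Zhang, better in the far tail), and `"imhof"` (exact inversion
#' of the characteristic function by numerical integration, used as the
#' reference in cross-checks).
#'
#' @param q observed statistic (>= 0).
#' @param lambda mixture weights (eigenvalues), non-negative, not all zero.
#' @param method one of `"satterthwaite"`, `"liu"`, `"imhof"`.
#' @return upper-tail probability in (0, 1].
#' @export
pmixchisq <- function(q, lambda,
                      method = c("satterthwaite", "liu", "imhof")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 1e-12 * max(lambda, 1)]
  if (length(lambda) == 0) stop("all mixture weights are zero")
  if (q <= 0) return(1)
  switch(method,
    satterthwaite = {
      c1 <- sum(lambda); c2 <- sum(lambda^2)
      scale <- c2 / c1
      df <- c1^2 / c2
      stats::pchisq(q / scale, df = df, lower.tail = FALSE)
    },
    liu = {
      c1 <- sum(lambda); c2 <- sum(lambda^2)
      c3 <- sum(lambda^3); c4 <- sum(lambda^4)
      s1 <- c3 / c2^1.5
      s2 <- c4 / c2^2
      if (s1^2 > s2) {
        a <- 1 / (s1 - sqrt(s1^2 - s2))
        delta <- s1 * a^3 - a^2
        df <- a^2 - 2 * delta
      } else {
        delta <- 0
        df <- 1 / s2
      }
      mu_q <- c1; sigma_q <- sqrt(2 * c2)
      mu_x <- df + delta; sigma_x <- sqrt(2) * sqrt(df + 2 * delta)
      stats::pchisq((q - mu_q) / sigma_q * sigma_x + mu_x, df = df,
                    ncp = delta, lower.tail = FALSE)
    },
    imhof = {
      integrand <- function(u) {
        theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
        rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
        sin(theta) / (u * rho)
      }
      # the integrand oscillates with phase speed at most
      # (q + sum(lambda))/2, so integrating piecewise over sub-intervals no
      # longer than one period keeps the adaptive quadrature honest; the
      # pieces alternate in sign and their envelope decays polynomially, so
      # accumulation stops once successive pieces are negligible
      h <- 2 * pi / (0.5 * (q + sum(lambda)))
      val <- 0
      lo <- 0
      tiny <- 0L
      for (piece in seq_len(100000L)) {
        contrib <- stats::integrate(integrand, lower = lo, upper = lo + h,
                                    rel.tol = 1e-9, abs.tol = 1e-13,
                                    stop.on.error = FALSE)$value
        val <- val + contrib
        lo <- lo + h
        tiny <- if (abs(contrib) < 1e-12) tiny + 1L else 0L
        if (tiny >= 3L) break
      }
      min(max(0.5 + val / pi, .Machine$double.xmin), 1)
    })
}

#' Collapse a rare-variant set into a per-subject burden score
#'
#' Sum of alternate-allele dosages across the member variants, optionally
#' weighted. Variants whose sample MAF reaches 1% are rejected from the set
#' with a message, enforcing the rare-variant definition (MAF < 0.01).
#'
#' @param geneset [dosage_matrix()] of the set's member variants.
#' @param weights optional per-variant weights (default 1, the unweighted
#'   burden); `"madsen-browning"` uses `1 / sqrt(maf * (1 - maf))` from the
#'   sample allele frequency.
#' @param maf_max sample-MAF bound above which a member is rejected
#'   (default 0.01, the rare-variant definition; raise it when the sample
#'   is small enough for sampling noise to push a rare variant past 1%).
#' @return numeric burden per subject; attribute `dropped` lists rejected
#'   variant ids.
#' @export
collapse_burden <- function(geneset, weights = NULL, maf_max = 0.01) {
  stopifnot(inherits(geneset, "dosage_matrix"))
  G <- geneset$dosage
  aaf <- rowMeans(G) / 2
  maf <- pmin(aaf, 1 - aaf)
  bad <- maf >= maf_max
  if (any(bad)) {
    message(sum(bad), " variant(s) with MAF above the bound rejected from the set: ",
            paste(rownames(G)[bad], collapse = ", "))
    G <- G[!bad, , drop = FALSE]
    maf <- maf[!bad]
  }
  if (nrow(G) == 0) stop("no rare variants left in the set")
  w <- if (is.null(weights)) rep(1, nrow(G))
  else if (identical(weights, "madsen-browning")) {
    1 / sqrt(pmax(maf, 1e-8) * (1 - pmax(maf, 1e-8)))
  } else rep_len(weights, nrow(G))
  structure(drop(crossprod(G, w)),
            dropped = rownames(geneset$dosage)[bad])
}

# Score test of a single extra column s added to a fitted null logistic
# model: U = s'(y - mu), Var(U) = s'Vs - s'VX (X'VX)^{-1} X'Vs.
score_test_1df <- function(null_fit_design, y, s) {
  fit <- fit_logistic(null_fit_design, y)
  if (!fit$converged) return(flagged("non-converged"))
  mu <- stats::plogis(drop(null_fit_design %*% fit$coefficients))
  v <- mu * (1 - mu)
  U <- sum(s * (y - mu))
  Xv <- null_fit_design * v
  XtVX_inv <- chol2inv(chol(crossprod(null_fit_design, Xv)))
  sVX <- drop(crossprod(s, Xv))
  varU <- sum(s^2 * v) - drop(sVX %*% XtVX_inv %*% sVX)
  if (varU <= 0) return(flagged("degenerate-score-variance"))
  chi2 <- U^2 / varU
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       flag = "ok")
}

#' Fixed burden-by-exposure score test for a rare-variant set
#'
#' Score test of the burden-by-exposure coefficient in
#' `logit(D) ~ burden + E + burden:E + covariates`, the fixed-effect
#' component of the mixed-effects set interaction test.
#'
#' @param cohort cohort data.frame.
#' @param geneset [dosage_matrix()] of the set (aligned by id).
#' @param covariates covariate column names.
#' @return list with `chi2`, `p`, `flag`.
#' @export
misti_fixed_test <- function(cohort, geneset, covariates = NULL,
                             maf_max = 0.01) {
  check_cohort(cohort)
  geneset <- align_dosage(cohort, geneset)
  burden <- as.numeric(collapse_burden(geneset, maf_max = maf_max))
  E <- cohort$exposure
  if (stats::var(burden) == 0) return(flagged("degenerate-burden"))
  if (stats::var(E) == 0) return(flagged("constant-exposure"))
  b <- build_design(cohort, extras = list(burden = burden, E = E),
                    covariates = covariates)
  s <- (burden * E)[b$keep]
  res <- tryCatch(score_test_1df(b$design, cohort$status[b$keep], s),
                  error = function(e) flagged("singular"))
  res
}

#' Variance-component heterogeneity test for per-variant interactions
#'
#' Score test for variant-specific interaction effects modeled as mean-zero
#' random effects. The null model holds the main effects and the fixed
#' burden-by-exposure term (`logit(D) ~ burden + E + burden:E +
#' covariates`); with residuals `r = y - mu` and the matrix `S` of
#' per-variant dosage-by-exposure columns, the statistic is
#' `Q = || S'r ||^2`, whose null distribution is the mixture of chi-squares
#' with weights the eigenvalues of `S'PS`, `P` the projected variance of
#' the residuals. The p-value uses the moment-matched approximation by
#' default; `method = "imhof"` gives the exact eigenvalue inversion.
#'
#' @param cohort cohort data.frame.
#' @param geneset [dosage_matrix()] with at least two member variants.
#' @param covariates covariate column names.
#' @param method passed to [pmixchisq()].
#' @return list with `Q`, `p`, `lambda` (eigenvalues), `flag`.
#' @export
misti_random_test <- function(cohort, geneset, covariates = NULL,
                              method = "satterthwaite", maf_max = 0.01) {
  check_cohort(cohort)
  geneset <- align_dosage(cohort, geneset)
  if (nrow(geneset$dosage) < 2) return(flagged("fewer-than-2-variants"))
  burden <- as.numeric(collapse_burden(geneset, maf_max = maf_max))
  E <- cohort$exposure
  if (stats::var(burden) == 0) return(flagged("degenerate-burden"))
  b <- build_design(cohort, extras = list(burden = burden, E = E,
                                          `burden:E` = burden * E),
                    covariates = covariates)
  X <- b$design
  y <- cohort$status[b$keep]
  fit <- tryCatch(fit_logistic(X, y), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(flagged("null-model-failed"))
  mu <- stats::plogis(drop(X %*% fit$coefficients))
  v <- mu * (1 - mu)
  S <- t(geneset$dosage[, b$keep, drop = FALSE] *
           rep(E[b$keep], each = nrow(geneset$dosage)))
  r <- y - mu
  Q <- sum(drop(crossprod(S, r))^2)
  Xv <- X * v
  XtVX_inv <- chol2inv(chol(crossprod(X, Xv)))
  SvX <- crossprod(S, Xv)                      # m x p
  StPS <- crossprod(S, S * v) - SvX %*% XtVX_inv %*% t(SvX)
  lambda <- eigen(StPS, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  if (sum(lambda) <= 1e-10) {
    return(list(Q = Q, p = 1, chi2 = NA_real_,
                flag = "zero-variance-kernel"))
  }
  list(Q = Q, p = pmixchisq(Q, lambda, method = method), lambda = lambda,
       flag = "ok")
}

#' Fisher combination of the fixed and random component p-values
#'
#' `X = -2 (log p_fixed + log p_random)` referred to a chi-square with 4
#' degrees of freedom. Zero p-values are clamped to the smallest positive
#' double and flagged.
#'
#' @param p_fixed,p_random component p-values in (0, 1].
#' @return list with `X`, `p`, `clamped` flag.
#' @examples
#' fisher_combine(0.1, 0.1)  # p about 0.056
#' @export
fisher_combine <- function(p_fixed, p_random) {
  clamped <- FALSE
  if (p_fixed <= 0) { p_fixed <- .Machine$double.xmin; clamped <- TRUE }
  if (p_random <= 0) { p_random <- .Machine$double.xmin; clamped <- TRUE }
  X <- -2 * (log(p_fixed) + log(p_random))
  list(X = X, p = stats::pchisq(X, df = 4, lower.tail = FALSE),
       clamped = clamped)
}

#' Mixed-effects set-by-exposure interaction test (Fisher combination)
#'
#' Runs the fixed burden-by-exposure score test and the variance-component
#' heterogeneity test for one rare-variant set and combines them with
#' Fisher's method. With 25,000 sets scanned, interactions below
#' `2e-6 = 0.05 / 25000` are conventionally called suggestively
#' significant.
#'
#' @param cohort cohort data.frame.
#' @param geneset [dosage_matrix()] of the set.
#' @param covariates covariate column names.
#' @param method mixture-tail method for the random component.
#' @return one-row data.frame: `set_id` (attribute-driven, NA if unknown),
#'   `n_variants`, `p_fixed`, `p_random`, `p_fisher`, `flag`.
#' @export
misti_test <- function(cohort, geneset, covariates = NULL,
                       method = "satterthwaite", maf_max = 0.01) {
  fx <- misti_fixed_test(cohort, geneset, covariates, maf_max = maf_max)
  rn <- misti_random_test(cohort, geneset, covariates, method = method,
                          maf_max = maf_max)
  flags <- c(if (fx$flag != "ok") paste0("fixed:", fx$flag),
             if (rn$flag != "ok") paste0("random:", rn$flag))
  p_fisher <- if (is.na(fx$p) || is.na(rn$p)) NA_real_
  else fisher_combine(fx$p, rn$p)$p
  data.frame(n_variants = nrow(geneset$dosage),
             p_fixed = fx$p, p_random = rn$p, p_fisher = p_fisher,
             flag = if (length(flags)) paste(flags, collapse = ";") else "ok",
             stringsAsFactors = FALSE)
}

#' Scan rare-variant sets
#'
#' Applies [misti_test()] to every set in a (set_id, variant_id) mapping.
#'
#' @param cohort cohort data.frame.
#' @param dosage [dosage_matrix()] holding all rare variants.
#' @param sets data.frame with columns `set_id`, `variant_id`, or a path to
#'   a two-column whitespace-separated text mapping.
#' @param covariates covariate column names.
#' @return data.frame: `set_id`, `n_variants`, `p_fixed`, `p_random`,
#'   `p_fisher`, `flag`.
#' @export
rare_scan <- function(cohort, dosage, sets, covariates = NULL,
                      maf_max = 0.01) {
  if (is.character(sets)) sets <- read_gene_sets(sets)
  stopifnot(all(c("set_id", "variant_id") %in% names(sets)))
  out <- lapply(split(sets$variant_id, sets$set_id), function(vids) {
    gs <- subset_variants(dosage, intersect(vids, dosage$info$id))
    misti_test(cohort, gs, covariates, maf_max = maf_max)
  })
  res <- do.call(rbind, out)
  res <- cbind(set_id = names(out), res)
  rownames(res) <- NULL
  res
}

#' Read a two-column gene-set mapping
#'
#' @param path whitespace-separated text file with columns set_id and
#'   variant_id (no header).
#' @return data.frame with `set_id`, `variant_id`.
#' @export
read_gene_sets <- function(path) {
  out <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("set_id", "variant_id"))
  out
}
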