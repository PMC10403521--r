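#' EDGE screening statistic
#'
#' Combines the marginal genotype-disease chi-square and the
#' genotype-exposure chi-square into a 2-d.f. screening statistic used to
#' rank variants in step 1 of the two-step scan. Both component tests are
#' independent of the step-2 interaction test under the null, which is what
#' makes the screen valid.
#'
#' @param chi2_dg,chi2_eg 1-d.f. component chi-squares.
#' @return list with `edge_stat = chi2_dg + chi2_eg` and `p_edge` from a
#'   chi-square with 2 d.f.; NA components propagate as NA.
#' @examples
#' edge_statistic(4, 5)  # p = exp(-4.5)
#' @export
edge_statistic <- function(chi2_dg, chi2_eg) {
  s <- chi2_dg + chi2_eg
  list(edge_stat = s,
       p_edge = stats::pchisq(s, df = 2, lower.tail = FALSE))
}

#' Build a weighted-testing bin schedule
#'
#' Sorts variants by their step-1 p-value (ties broken by genomic position,
#' chr then bp ascending, so the schedule is deterministic) and partitions
#' them into bins of geometrically growing size `B * 2^(k-1)`. Bin k
#' receives an alpha budget of `alpha / 2^k` split evenly over its nominal
#' size, giving the per-test threshold `alpha_k = (alpha / 2^k) / (B *
#' 2^(k-1))`. The final bin may hold fewer variants but keeps its full-size
#' denominator, so the total spent budget is at most
#' `alpha * (1/2 + 1/4 + ...) < alpha` at any depth.
#'
#' @param step1_p numeric step-1 p-values (one per variant).
#' @param B size of the first bin (>= 1).
#' @param alpha overall alpha for the screen, in (0, 1).
#' @param ids optional variant ids (default index).
#' @param chr,bp optional position vectors used for deterministic
#'   tie-breaking.
#' @return object of class `bin_schedule`: data.frame with `id`, `step1_p`,
#'   `bin`, `alpha_k` (per-test threshold of the variant's bin), plus
#'   attributes `bins` (data.frame of bin sizes, nominal sizes and
#'   thresholds), `B`, `alpha`.
#' @examples
#' sched <- build_bin_schedule(runif(35), B = 5, alpha = 0.05)
#' attr(sched, "bins")
#' @export
build_bin_schedule <- function(step1_p, B = 5L, alpha = 0.05, ids = NULL,
                               chr = NULL, bp = NULL) {
  m <- length(step1_p)
  stopifnot(m >= 1, B >= 1, alpha > 0, alpha < 1)
  if (is.null(ids)) ids <- seq_len(m)
  if (is.null(chr)) chr <- rep(0L, m)
  if (is.null(bp)) bp <- seq_len(m)
  ord <- order(step1_p, chr, bp)
  sizes <- integer(0); k <- 0L; placed <- 0L
  while (placed < m) {
    k <- k + 1L
    sizes <- c(sizes, B * 2^(k - 1L))
    placed <- placed + sizes[k]
  }
  nominal <- sizes
  # truncate the last bin to the remaining variants, keep its denominator
  sizes[k] <- m - sum(sizes[-k])
  alpha_k <- (alpha / 2^seq_len(k)) / nominal
  bin_of <- rep(seq_len(k), times = sizes)
  out <- data.frame(id = ids[ord], step1_p = step1_p[ord], bin = bin_of,
                    alpha_k = alpha_k[bin_of], stringsAsFactors = FALSE)
  budget <- sum(alpha_k * nominal)
  stopifnot(budget <= alpha + 1e-12)
  structure(out,
            bins = data.frame(bin = seq_len(k), size = sizes,
                              nominal_size = nominal, alpha_k = alpha_k),
            B = B, alpha = alpha, class = c("bin_schedule", "data.frame"))
}

#' Pairwise dosage r-squared and LD group clustering
#'
#' `ld_r2` computes squared Pearson correlation between dosage rows;
#' `ld_groups` single-linkage-clusters variants whose pairwise r-squared
#' meets `r2_min`, returning a group label per variant. Used both for the
#' LD-aware two-step error control and for known-locus pruning.
#'
#' @param dosage numeric matrix, variants x subjects (or a
#'   [dosage_matrix()]).
#' @param r2_min clustering threshold on r-squared.
#' @return `ld_r2`: variants x variants matrix. `ld_groups`: integer vector
#'   of group labels.
#' @export
ld_r2 <- function(dosage) {
  if (inherits(dosage, "dosage_matrix")) dosage <- dosage$dosage
  suppressWarnings(stats::cor(t(dosage))^2)
}

#' @rdname ld_r2
#' @export
ld_groups <- function(dosage, r2_min = 0.2) {
  if (inherits(dosage, "dosage_matrix")) dosage <- dosage$dosage
  m <- nrow(dosage)
  if (m == 1) return(1L)
  r2 <- ld_r2(dosage)
  r2[is.na(r2)] <- 0
  adj <- r2 >= r2_min
  # connected components by repeated expansion (single linkage)
  grp <- rep(NA_integer_, m)
  g <- 0L
  for (i in seq_len(m)) {
    if (!is.na(grp[i])) next
    g <- g + 1L
    frontier <- i
    grp[i] <- g
    while (length(frontier)) {
      nb <- which(adj[frontier[1], ] & is.na(grp))
      grp[nb] <- g
      frontier <- c(frontier[-1], nb)
    }
  }
  grp
}

#' Two-step weighted interaction screen
#'
#' Step 1 ranks variants by a screening p-value (EDGE by default; the pure
#' genotype-disease or genotype-exposure filters are available through
#' `step1`). Step 2 declares a variant significant when its interaction
#' p-value falls below the threshold of its weighted-testing bin. When an
#' LD group assignment is supplied (or a genotype reference to derive one),
#' each bin's denominator is the number of LD-independent groups (pairwise
#' r-squared >= 0.2 single-linkage clusters) among its members instead of
#' the raw member count, so correlated variants do not multiply the
#' correction; without LD information the raw-count schedule is used with a
#' warning.
#'
#' @param scan a [scan_variants()] result carrying `p_gxe` and the step-1
#'   columns.
#' @param B first-bin size.
#' @param alpha overall alpha of the screen.
#' @param ld_group integer vector of LD group labels aligned to the scan
#'   rows, or NULL.
#' @param dosage optional [dosage_matrix()] from which `ld_group` is
#'   derived when not supplied.
#' @param step1 screening statistic: `"edge"`, `"dg"` or `"eg"`.
#' @return list with `significant` (variant ids), `table` (scan rows with
#'   bin, threshold, decision), `schedule` (the [build_bin_schedule()]
#'   result).
#' @export
two_step_screen <- function(scan, B = 5L, alpha = 0.05, ld_group = NULL,
                            dosage = NULL, step1 = c("edge", "dg", "eg")) {
  step1 <- match.arg(step1)
  p1 <- switch(step1, edge = scan$p_edge, dg = scan$p_dg, eg = scan$p_eg)
  usable <- is.finite(p1) & is.finite(scan$p_gxe)
  if (!all(usable)) {
    scan <- scan[usable, , drop = FALSE]
    p1 <- p1[usable]
  }
  if (is.null(ld_group) && !is.null(dosage)) {
    dm <- if (inherits(dosage, "dosage_matrix")) dosage$dosage else dosage
    keep <- match(scan$id, rownames(dm))
    ld_group <- ld_groups(dm[keep, , drop = FALSE])
  }
  sched <- build_bin_schedule(p1, B = B, alpha = alpha, ids = scan$id,
                              chr = scan$chr, bp = scan$bp)
  bins <- attr(sched, "bins")
  ord <- match(sched$id, scan$id)
  tab <- scan[ord, , drop = FALSE]
  tab$bin <- sched$bin
  if (is.null(ld_group)) {
    warning("no LD information supplied; using raw per-bin counts")
    tab$alpha_k <- sched$alpha_k
  } else {
    grp <- ld_group[ord]
    # per bin: members that are LD-redundant with an earlier member do not
    # count as independent tests; the truncated last bin keeps its nominal
    # denominator, so redundancy is subtracted from the nominal size
    n_members <- tapply(grp, sched$bin, length)
    n_eff <- tapply(grp, sched$bin, function(g) length(unique(g)))
    redundant <- as.vector((n_members - n_eff)[as.character(sched$bin)])
    denom <- pmax(bins$nominal_size[sched$bin] - redundant, 1L)
    tab$alpha_k <- (alpha / 2^sched$bin) / denom
  }
  tab$significant <- tab$p_gxe < tab$alpha_k
  list(significant = tab$id[tab$significant], table = tab, schedule = sched)
}

#' Per-family alpha for multiple primary testing approaches
#'
#' When several testing approaches (e.g. 1-d.f. interaction, two-step and
#' 3-d.f. joint test) are run as parallel families, the family-wise rate is
#' split evenly across them. The conventional fixed genome-wide threshold
#' for a single secondary scan is also exposed.
#'
#' @param n_families number of parallel test families.
#' @param alpha overall family-wise error rate.
#' @return list with `per_family` (= alpha / n_families) and `genome_wide`
#'   (5e-8, the fixed threshold used to declare a secondary genome-wide
#'   scan significant).
#' @examples
#' apply_fwer_split(3)$per_family  # 0.0166...
#' @export
apply_fwer_split <- function(n_families = 3L, alpha = 0.05) {
  stopifnot(n_families >= 1)
  list(per_family = alpha / n_families, genome_wide = 5e-8)
}

# chi-square(1) median, fixed so lambda does not depend on quantile-routine
# details
CHI2_1_MEDIAN <- 0.4549364

#' Genomic inflation factor and its 1000/1000 rescaling
#'
#' `genomic_lambda` is the median of the observed 1-d.f. chi-squares
#' divided by the null chi-square(1) median (0.4549364). `lambda_1000`
#' rescales an inflation factor to an equivalent study of 1000 cases and
#' 1000 controls:
#' `1 + (lambda - 1) * (1/n_cases + 1/n_controls) / (2/1000)`,
#' an affine contraction toward 1 whenever the study is larger than
#' 1000/1000.
#'
#' @param chi2 finite 1-d.f. chi-square values (NA dropped); p-values may be
#'   supplied instead via `p` and are converted through the chi-square(1)
#'   quantile.
#' @param p optional p-values (used when `chi2` missing).
#' @return `genomic_lambda`: scalar lambda.
#' @examples
#' lambda_1000(1.008, 31318, 41499)  # about 1.000
#' @export
genomic_lambda <- function(chi2 = NULL, p = NULL) {
  if (is.null(chi2)) {
    stopifnot(!is.null(p))
    chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0) stop("no finite chi-square values")
  stats::median(chi2) / CHI2_1_MEDIAN
}

#' @rdname genomic_lambda
#' @param lambda inflation factor (> 0).
#' @param n_cases,n_controls study sample sizes (> 0).
#' @export
lambda_1000 <- function(lambda, n_cases, n_controls) {
  stopifnot(lambda > 0, n_cases > 0, n_controls > 0)
  1 + (lambda - 1) * (1 / n_cases + 1 / n_controls) / (1 / 1000 + 1 / 1000)
}

#' Inflation report with QQ points
#'
#' @param p p-values of a 1-d.f. test stream.
#' @param n_cases,n_controls sample sizes for the lambda-1000 rescaling.
#' @return object of class `inflation_report`: list with `lambda`,
#'   `lambda_1000`, `n_cases`, `n_controls` and `qq_points` (data.frame of
#'   expected and observed -log10 p, expected quantiles
#'   `-log10((i - 0.5) / m)` for ordered observations).
#' @export
inflation_report <- function(p, n_cases, n_controls) {
  p <- p[is.finite(p)]
  m <- length(p)
  lam <- genomic_lambda(p = p)
  qq <- data.frame(expected = -log10((seq_len(m) - 0.5) / m),
                   observed = -log10(sort(p)))
  structure(list(lambda = lam,
                 lambda_1000 = lambda_1000(lam, n_cases, n_controls),
                 n_cases = n_cases, n_controls = n_controls,
                 qq_points = qq),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("lambda = %.3f; lambda_1000 = %.3f (%d cases / %d controls, %d tests)\n",
              x$lambda, x$lambda_1000, x$n_cases, x$n_controls,
              nrow(x$qq_points)))
  invisible(x)
}

#' Remove variants tagging known susceptibility loci
#'
#' For presentation of joint-test results it is standard to drop variants
#' that merely tag established disease loci: a variant is removed when it
#' lies within +/- `window_bp` of a known anchor AND its dosage r-squared
#' with that anchor exceeds `r2_min` (both conditions required; LD is
#' estimated from a control-genotype reference). Variants with unknown
#' position are retained with a warning.
#'
#' @param scan a scan data.frame with `id`, `chr`, `bp`.
#' @param known data.frame of anchors with `chr`, `bp` (anchor ids optional
#'   in column `id`); anchors must be present in the reference to compute
#'   LD.
#' @param reference [dosage_matrix()] of control genotypes covering the
#'   scan variants and the anchors, used for r-squared.
#' @param window_bp proximity window, inclusive on both ends (default 2 Mb).
#' @param r2_min LD threshold (default 0.2, strict greater-than).
#' @return the scan restricted to surviving variants.
#' @export
prune_known_loci <- function(scan, known, reference, window_bp = 2e6,
                             r2_min = 0.2) {
  stopifnot(inherits(reference, "dosage_matrix"))
  drop <- rep(FALSE, nrow(scan))
  pos_na <- is.na(scan$bp) | is.na(scan$chr)
  if (any(pos_na)) warning(sum(pos_na), " variant(s) with unknown position retained")
  for (j in seq_len(nrow(known))) {
    anchor_id <- if ("id" %in% names(known)) known$id[j] else NA
    near <- !pos_na & scan$chr == known$chr[j] &
      abs(scan$bp - known$bp[j]) <= window_bp
    if (!any(near)) next
    aidx <- if (!is.na(anchor_id)) match(anchor_id, reference$info$id) else
      which(reference$info$chr == known$chr[j] &
              reference$info$bp == known$bp[j])[1]
    if (is.na(aidx)) {
      warning("anchor ", j, " absent from LD reference; proximity-only pruning skipped")
      next
    }
    avec <- reference$dosage[aidx, ]
    vidx <- match(scan$id[near], reference$info$id)
    r2 <- vapply(vidx, function(i) {
      if (is.na(i)) return(NA_real_)
      suppressWarnings(stats::cor(reference$dosage[i, ], avec)^2)
    }, numeric(1))
    hit <- which(near)[!is.na(r2) & r2 > r2_min]
    drop[hit] <- TRUE
  }
  scan[!drop, , drop = FALSE]
}
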