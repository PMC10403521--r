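#' Configuration for the multi-study case-control simulator
#'
#' Defines the generative model behind [simulate_cohort()]: a source
#' population in which genotypes follow Hardy-Weinberg proportions (with
#' optional exchangeable-correlation LD blocks via a Gaussian copula on the
#' haplotype level), a binary exposure drawn from a logistic model whose
#' intercept is solved so the marginal prevalence matches
#' `exposure_prevalence`, and a binary disease outcome drawn from
#' `logit P(D=1) = beta0 + beta_g G + beta_e E + beta_gxe G*E + covariates`.
#' One designated causal variant (`causal_variant`) carries `beta_g`,
#' `beta_gxe` and the exposure-genotype association `gamma_ge`; all other
#' variants are null and exposure-independent, which isolates the signal
#' joint tests and two-step screens are designed to pick up.
#'
#' @param n_studies number of studies in the consortium.
#' @param n_cases,n_controls per-study case and control quotas (recycled to
#'   `n_studies`).
#' @param n_variants number of common variants.
#' @param maf minor/alternate allele frequency per variant in (0, 0.5],
#'   recycled.
#' @param exposure_prevalence marginal exposure prevalence in the source
#'   population, in (0, 1).
#' @param beta0 disease log-odds intercept in the source population.
#' @param beta_g,beta_e,beta_gxe log-odds for the causal variant dosage, the
#'   exposure, and their product.
#' @param gamma_ge log-odds of exposure per causal-variant allele (the G-E
#'   association in the source population).
#' @param causal_variant index of the variant carrying the effects.
#' @param ld_block_size number of consecutive variants per LD block (1 = no
#'   LD).
#' @param ld_rho latent exchangeable correlation inside a block, in [0, 1).
#' @param covariate_effects named log-odds vector for covariates `age`
#'   (per year, centred), `sex`, `pc1`..`pc3` on disease.
#' @param dosage_jitter SD of truncated-Gaussian noise added to integer
#'   genotypes to mimic imputed dosages (clipped to [0, 2]); 0 keeps hard
#'   calls.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_studies = 4, n_cases = 500, n_controls = 500,
                       n_variants = 10, maf = 0.3,
                       exposure_prevalence = 0.10,
                       beta0 = -2.2, beta_g = 0, beta_e = 0.31,
                       beta_gxe = 0, gamma_ge = 0, causal_variant = 1L,
                       ld_block_size = 1L, ld_rho = 0,
                       covariate_effects = c(age = 0.01, sex = 0.1,
                                             pc1 = 0, pc2 = 0, pc3 = 0),
                       dosage_jitter = 0, seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              n_cases = rep_len(as.integer(n_cases), n_studies),
              n_controls = rep_len(as.integer(n_controls), n_studies),
              n_variants = as.integer(n_variants),
              maf = rep_len(as.numeric(maf), n_variants),
              exposure_prevalence = exposure_prevalence,
              beta0 = beta0, beta_g = beta_g, beta_e = beta_e,
              beta_gxe = beta_gxe, gamma_ge = gamma_ge,
              causal_variant = as.integer(causal_variant),
              ld_block_size = as.integer(ld_block_size),
              ld_rho = ld_rho,
              covariate_effects = covariate_effects,
              dosage_jitter = dosage_jitter,
              seed = as.integer(seed))
  stopifnot(cfg$n_studies >= 1, all(cfg$n_cases >= 1),
            all(cfg$n_controls >= 1), cfg$n_variants >= 1)
  if (any(cfg$maf <= 0 | cfg$maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (cfg$exposure_prevalence <= 0 || cfg$exposure_prevalence >= 1) {
    stop("exposure_prevalence must lie in (0, 1)")
  }
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (cfg$ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (cfg$causal_variant < 1 || cfg$causal_variant > cfg$n_variants) {
    stop("causal_variant out of range")
  }
  if (cfg$dosage_jitter < 0) stop("dosage_jitter must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

# Haplotype-level Gaussian copula: one latent factor per block induces
# exchangeable correlation ld_rho between latent normals, thresholded at
# qnorm(maf) to allele indicators. Two independent haplotypes per subject
# sum to the genotype, so Hardy-Weinberg proportions hold marginally.
draw_genotypes <- function(n, maf, block_size, rho) {
  m <- length(maf)
  thr <- stats::qnorm(maf)
  blocks <- split(seq_len(m), ceiling(seq_len(m) / block_size))
  G <- matrix(0L, nrow = m, ncol = n)
  for (hap in 1:2) {
    for (b in blocks) {
      z_common <- stats::rnorm(n)
      z <- sqrt(rho) * matrix(z_common, nrow = length(b), ncol = n,
                              byrow = TRUE) +
        sqrt(1 - rho) * matrix(stats::rnorm(length(b) * n), nrow = length(b))
      G[b, ] <- G[b, ] + (z < thr[b])
    }
  }
  G
}

# Solve the exposure-model intercept so that mean plogis(a + g*G) over the
# realised causal genotypes equals the target prevalence.
solve_exposure_intercept <- function(g_causal, gamma_ge, prevalence) {
  if (gamma_ge == 0) return(stats::qlogis(prevalence))
  f <- function(a) mean(stats::plogis(a + gamma_ge * g_causal)) - prevalence
  stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}

#' Simulate a stratified multi-study case-control cohort with genotypes
#'
#' Implements a nested case-control design by oversampling a source
#' population per study and subsampling cases and controls to the requested
#' quotas, so per-study counts are preserved exactly. Covariates are age
#' (Gaussian, mean 60, SD 10), sex (Bernoulli 0.5) and three Gaussian
#' principal components; `study` is carried as a categorical label.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (data.frame: subject_id, status, exposure,
#'   age, sex, study, pc1-pc3) and `dosage` (a [dosage_matrix()], variants x
#'   subjects, aligned to the cohort by subject id).
#' @examples
#' sim <- simulate_cohort(sim_config(n_studies = 2, n_cases = 50,
#'                                   n_controls = 50, n_variants = 4))
#' table(sim$cohort$status, sim$cohort$study)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cohorts <- vector("list", config$n_studies)
  dosages <- vector("list", config$n_studies)
  ce <- config$covariate_effects
  for (s in seq_len(config$n_studies)) {
    need_ca <- config$n_cases[s]
    need_co <- config$n_controls[s]
    got_ca <- got_co <- 0L
    pieces_c <- list(); pieces_g <- list()
    batch <- 4L * (need_ca + need_co)
    max_draw <- 400L * (need_ca + need_co)
    drawn <- 0L
    while ((got_ca < need_ca || got_co < need_co) && drawn < max_draw) {
      n <- batch
      drawn <- drawn + n
      G <- draw_genotypes(n, config$maf, config$ld_block_size, config$ld_rho)
      gC <- G[config$causal_variant, ]
      a_e <- solve_exposure_intercept(gC, config$gamma_ge,
                                      config$exposure_prevalence)
      E <- stats::rbinom(n, 1, stats::plogis(a_e + config$gamma_ge * gC))
      age <- stats::rnorm(n, 60, 10)
      sex <- stats::rbinom(n, 1, 0.5)
      pc <- matrix(stats::rnorm(3 * n), ncol = 3,
                   dimnames = list(NULL, c("pc1", "pc2", "pc3")))
      eta <- config$beta0 + config$beta_g * gC + config$beta_e * E +
        config$beta_gxe * gC * E +
        ce[["age"]] * (age - 60) + ce[["sex"]] * sex +
        pc %*% c(ce[["pc1"]], ce[["pc2"]], ce[["pc3"]])
      D <- stats::rbinom(n, 1, stats::plogis(drop(eta)))
      df <- data.frame(status = D, exposure = E, age = age, sex = sex,
                       pc1 = pc[, 1], pc2 = pc[, 2], pc3 = pc[, 3])
      take_ca <- which(D == 1)[seq_len(min(sum(D == 1), need_ca - got_ca))]
      take_co <- which(D == 0)[seq_len(min(sum(D == 0), need_co - got_co))]
      take <- c(take_ca, take_co)
      got_ca <- got_ca + length(take_ca)
      got_co <- got_co + length(take_co)
      pieces_c[[length(pieces_c) + 1L]] <- df[take, , drop = FALSE]
      pieces_g[[length(pieces_g) + 1L]] <- G[, take, drop = FALSE]
    }
    if (got_ca < need_ca || got_co < need_co) {
      stop(sprintf(
        "study %d: could not reach %d cases / %d controls after sampling %d subjects (disease or control probability too low)",
        s, need_ca, need_co, drawn))
    }
    cs <- do.call(rbind, pieces_c)
    cs$study <- sprintf("study%02d", s)
    cohorts[[s]] <- cs
    dosages[[s]] <- do.call(cbind, pieces_g)
  }
  cohort <- do.call(rbind, cohorts)
  cohort$subject_id <- sprintf("S%06d", seq_len(nrow(cohort)))
  rownames(cohort) <- NULL
  cohort <- cohort[, c("subject_id", "status", "exposure", "age", "sex",
                       "study", "pc1", "pc2", "pc3")]
  dos <- do.call(cbind, dosages)
  if (config$dosage_jitter > 0) {
    dos <- dos + matrix(stats::rnorm(length(dos), 0, config$dosage_jitter),
                        nrow = nrow(dos))
    dos <- pmin(pmax(dos, 0), 2)
  }
  colnames(dos) <- cohort$subject_id
  info <- data.frame(
    id = sprintf("var%04d", seq_len(config$n_variants)),
    chr = rep("1", config$n_variants),
    bp = 1000000L + 10000L * seq_len(config$n_variants),
    ref = "A", alt = "G",
    imputation_r2 = rep(1, config$n_variants),
    stringsAsFactors = FALSE)
  rownames(dos) <- info$id
  list(cohort = cohort,
       dosage = dosage_matrix(dos, info))
}

#' Configuration for a rare-variant gene set simulation
#'
#' @param n_variants number of rare variants in the set.
#' @param maf_range length-2 interval for per-variant MAF; the upper bound
#'   must be below 0.01 (rare variants are defined as MAF < 1%).
#' @param effect_architecture one of `"null"` (disease untouched by the
#'   set), `"homogeneous-burden-x-e"` (a common burden-by-exposure log-odds
#'   of size `effect_scale`), or `"heterogeneous-gxe"` (per-variant
#'   interaction log-odds drawn i.i.d. N(0, effect_scale^2)).
#' @param effect_scale log-odds magnitude of the chosen architecture.
#' @param seed integer seed.
#' @return object of class `rare_set_config`.
#' @export
rare_set_config <- function(n_variants = 20, maf_range = c(0.001, 0.009),
                            effect_architecture = c("null",
                                                    "homogeneous-burden-x-e",
                                                    "heterogeneous-gxe"),
                            effect_scale = 0, seed = 1L) {
  effect_architecture <- match.arg(effect_architecture)
  if (length(maf_range) != 2 || maf_range[1] <= 0 ||
      maf_range[2] >= 0.01 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.01): rare variants have MAF < 1%")
  }
  structure(list(n_variants = as.integer(n_variants),
                 maf_range = as.numeric(maf_range),
                 effect_architecture = effect_architecture,
                 effect_scale = effect_scale, seed = as.integer(seed)),
            class = "rare_set_config")
}

#' Simulate a rare-variant gene set for an existing cohort
#'
#' Draws independent rare genotypes (binomial with 2 trials at a MAF sampled
#' uniformly inside `maf_range`) for every subject of `cohort`. Under the
#' `"null"` architecture the cohort's disease status is left exactly as
#' generated, so the set is unrelated to disease by construction. Under the
#' effect architectures the disease status is redrawn from a logistic model
#' that keeps the cohort's case fraction as its intercept and adds the
#' rare-variant interaction terms, giving a ground-truth signal for power
#' studies.
#'
#' @param config a [rare_set_config()].
#' @param cohort cohort data.frame from [simulate_cohort()].
#' @return list with `dosage` (a [dosage_matrix()] of the rare set, aligned
#'   to the cohort) and `cohort` (the input cohort; status redrawn only
#'   under a non-null architecture).
#' @export
simulate_rare_geneset <- function(config, cohort) {
  stopifnot(inherits(config, "rare_set_config"))
  set.seed(config$seed)
  n <- nrow(cohort)
  maf <- stats::runif(config$n_variants, config$maf_range[1],
                      config$maf_range[2])
  G <- matrix(stats::rbinom(config$n_variants * n, 2, rep(maf, times = n)),
              nrow = config$n_variants)
  info <- data.frame(id = sprintf("rare%04d", seq_len(config$n_variants)),
                     chr = "2", bp = 5000000L + 500L * seq_len(config$n_variants),
                     ref = "C", alt = "T", imputation_r2 = 1,
                     stringsAsFactors = FALSE)
  colnames(G) <- cohort$subject_id
  rownames(G) <- info$id
  out_cohort <- cohort
  if (config$effect_architecture != "null" && config$effect_scale != 0) {
    E <- cohort$exposure
    b0 <- stats::qlogis(mean(cohort$status))
    if (config$effect_architecture == "homogeneous-burden-x-e") {
      burden <- colSums(G)
      eta <- b0 + config$effect_scale * burden * E
    } else {
      bv <- stats::rnorm(config$n_variants, 0, config$effect_scale)
      eta <- b0 + drop(crossprod(G, bv)) * E
    }
    out_cohort$status <- stats::rbinom(n, 1, stats::plogis(eta))
  }
  list(dosage = dosage_matrix(G, info), cohort = out_cohort)
}
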