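test_that("mixture-of-chi-squares tail matches brute-force simulation", {
  lam <- c(3, 1, 0.5)
  q <- 6
  set.seed(33)
  mc <- mean(replicate(200000, sum(lam * rchisq(3, 1))) > q)
  pe <- pmixchisq(q, lam, "imhof")
  expect_lt(abs(pe - mc), 4 * sqrt(mc * (1 - mc) / 200000))
  # single component reduces to a scaled chi-square exactly
  expect_equal(pmixchisq(4, 2, "imhof"),
               pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(pmixchisq(4, 2, "satterthwaite"),
               pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(pmixchisq(0, c(1, 2)), 1)
})

test_that("moment-matched tail stays within the documented bound of exact", {
  # 50 random Gram-matrix spectra; moderate tail (p roughly 0.03-0.6);
  # documented bound: 15% relative error for the default moment match
  set.seed(1)
  for (r in 1:50) {
    m <- sample(2:15, 1)
    lam <- eigen(crossprod(matrix(rnorm(m * m), m)),
                 only.values = TRUE)$values
    q <- sum(lam) * runif(1, 0.8, 2.5)
    pe <- pmixchisq(q, lam, "imhof")
    ps <- pmixchisq(q, lam, "satterthwaite")
    expect_lt(abs(ps - pe) / pe, 0.15)
  }
})

test_that("burden collapse sums dosages and rejects common variants", {
  G <- rbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0))
  info <- data.frame(id = c("a", "b"), chr = "1", bp = 1:2, ref = "A",
                     alt = "T", imputation_r2 = 1)
  colnames(G) <- paste0("s", 1:4)
  gs <- dosage_matrix(G, info)
  expect_equal(unname(as.numeric(collapse_burden(gs, maf_max = 1))),
               c(2, 1, 1, 0))
  one <- subset_variants(gs, 1)
  expect_equal(unname(as.numeric(collapse_burden(one, maf_max = 1))),
               unname(G[1, ]))
  # a common variant smuggled into a genuinely rare set is dropped
  set.seed(3)
  n <- 400
  G2 <- rbind(r1 = rbinom(n, 2, 0.004), r2 = rbinom(n, 2, 0.004),
              common = rbinom(n, 2, 0.2))
  colnames(G2) <- paste0("s", 1:n)
  info2 <- data.frame(id = rownames(G2), chr = "1", bp = 1:3, ref = "A",
                      alt = "T", imputation_r2 = 1)
  gs2 <- dosage_matrix(G2, info2)
  expect_message(b2 <- collapse_burden(gs2), "rejected")
  expect_equal(attr(b2, "dropped"), "common")
  expect_equal(unname(as.numeric(b2)), unname(colSums(G2[1:2, ])))
})

test_that("uniform weights reproduce unweighted burden ranks", {
  sim <- small_sim(seed = 8)
  rs <- simulate_rare_geneset(rare_set_config(n_variants = 12, seed = 9),
                              sim$cohort)
  u <- as.numeric(collapse_burden(rs$dosage, maf_max = 0.05))
  w <- as.numeric(collapse_burden(rs$dosage, weights = rep(2.5, 12),
                                  maf_max = 0.05))
  expect_equal(rank(u), rank(w))
  mb <- as.numeric(collapse_burden(rs$dosage, weights = "madsen-browning",
                                   maf_max = 0.05))
  expect_equal(length(mb), nrow(sim$cohort))
})

test_that("fixed burden-by-exposure score test matches a brute-force LRT", {
  # 80-subject toy set: the score and LR statistics are asymptotically
  # equivalent; require agreement within 30% of the statistic
  set.seed(44)
  n <- 80
  G <- matrix(rbinom(3 * n, 2, 0.05), nrow = 3)
  colnames(G) <- sprintf("s%03d", 1:n)
  info <- data.frame(id = c("v1", "v2", "v3"), chr = "1", bp = 1:3,
                     ref = "A", alt = "T", imputation_r2 = 1)
  burden <- colSums(G)
  E <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.4 + 0.5 * burden * E))
  cohort <- data.frame(subject_id = colnames(G), status = y, exposure = E)
  r <- misti_fixed_test(cohort, dosage_matrix(G, info), maf_max = 1)
  full <- glm(y ~ burden * E, family = binomial)
  red <- glm(y ~ burden + E, family = binomial)
  lrt <- as.numeric(2 * (logLik(full) - logLik(red)))
  expect_equal(r$flag, "ok")
  expect_lt(abs(r$chi2 - lrt), 0.3 * max(lrt, 1))
})

test_that("random-component statistic needs at least two variants", {
  sim <- small_sim(seed = 10)
  rs <- simulate_rare_geneset(rare_set_config(n_variants = 5, seed = 12),
                              sim$cohort)
  one <- subset_variants(rs$dosage, 1)
  expect_equal(misti_random_test(sim$cohort, one)$flag,
               "fewer-than-2-variants")
})

test_that("removing a monomorphic member leaves set results unchanged", {
  sim <- small_sim(seed = 13)
  rs <- simulate_rare_geneset(rare_set_config(n_variants = 8, seed = 14),
                              sim$cohort)
  G <- rs$dosage$dosage
  G0 <- rbind(G, mono = rep(0, ncol(G)))
  info0 <- rbind(rs$dosage$info,
                 data.frame(id = "mono", chr = "2", bp = 999L, ref = "C",
                            alt = "T", imputation_r2 = 1))
  with_mono <- suppressMessages(
    misti_test(sim$cohort, dosage_matrix(G0, info0), maf_max = 0.05))
  without <- suppressMessages(
    misti_test(sim$cohort, rs$dosage, maf_max = 0.05))
  expect_equal(with_mono$p_fixed, without$p_fixed, tolerance = 1e-10)
  expect_equal(with_mono$p_random, without$p_random, tolerance = 1e-10)
})

test_that("Fisher combination follows the chi-square(4) closed form", {
  expect_equal(fisher_combine(1, 1)$X, 0)
  expect_equal(fisher_combine(1, 1)$p, 1)
  r <- fisher_combine(0.1, 0.1)
  expect_equal(r$X, 9.2103, tolerance = 1e-4)
  expect_equal(r$p, exp(-r$X / 2) * (1 + r$X / 2))
  expect_equal(r$p, 5.61e-2, tolerance = 1e-3)
  z <- fisher_combine(0, 0.5)
  expect_true(z$clamped)
  expect_true(is.finite(z$X))
})

test_that("combined statistic is monotone decreasing in each component p", {
  ps <- c(0.9, 0.5, 0.1, 0.01)
  X1 <- vapply(ps, function(p) fisher_combine(p, 0.3)$X, numeric(1))
  X2 <- vapply(ps, function(p) fisher_combine(0.3, p)$X, numeric(1))
  expect_true(all(diff(X1) > 0))
  expect_true(all(diff(X2) > 0))
})

test_that("null architecture gives calibrated set-test p-values", {
  # under the null the fixed, random and Fisher p-value streams should all
  # be roughly uniform (KS); the exposure prevalence is kept at 0.3 so the
  # carrier-by-exposed cells are populated enough for the asymptotics
  sim <- simulate_cohort(sim_config(n_studies = 1, n_cases = 500,
                                    n_controls = 500, n_variants = 1,
                                    exposure_prevalence = 0.3, seed = 404))
  p_fixed <- p_random <- p_fisher <- numeric(60)
  for (r in 1:60) {
    rs <- simulate_rare_geneset(rare_set_config(n_variants = 15,
                                                maf_range = c(0.003, 0.009),
                                                seed = 500 + r), sim$cohort)
    res <- suppressMessages(misti_test(rs$cohort, rs$dosage))
    p_fixed[r] <- res$p_fixed
    p_random[r] <- res$p_random
    p_fisher[r] <- res$p_fisher
  }
  expect_gt(ks.test(p_fixed, "punif")$p.value, 0.01)
  expect_gt(ks.test(p_random, "punif")$p.value, 0.01)
  expect_gt(ks.test(p_fisher, "punif")$p.value, 0.01)
})

test_that("heterogeneous interactions are caught by the random component", {
  # mean-zero per-variant effects: the burden test is blind by design, the
  # variance component is not
  base <- simulate_cohort(sim_config(n_studies = 1, n_cases = 600,
                                     n_controls = 600, n_variants = 1,
                                     exposure_prevalence = 0.4, seed = 606))
  hit_random <- hit_fixed <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    rs <- simulate_rare_geneset(
      rare_set_config(n_variants = 20, maf_range = c(0.004, 0.009),
                      effect_architecture = "heterogeneous-gxe",
                      effect_scale = 1.2, seed = 700 + r), base$cohort)
    res <- suppressMessages(misti_test(rs$cohort, rs$dosage))
    hit_random <- hit_random + (res$p_random < 0.05)
    hit_fixed <- hit_fixed + (res$p_fixed < 0.05)
  }
  expect_gt(hit_random / n_rep, 0.2)          # clearly above the 5% null rate
  expect_gt(hit_random, hit_fixed)            # the scenario fixed tests miss
})

test_that("homogeneous burden-by-exposure effects give the fixed test power", {
  base <- simulate_cohort(sim_config(n_studies = 1, n_cases = 500,
                                     n_controls = 500, n_variants = 1,
                                     exposure_prevalence = 0.4, seed = 808))
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    rs <- simulate_rare_geneset(
      rare_set_config(n_variants = 20, maf_range = c(0.004, 0.009),
                      effect_architecture = "homogeneous-burden-x-e",
                      effect_scale = 0.5, seed = 900 + r), base$cohort)
    hits <- hits + (suppressMessages(
      misti_fixed_test(rs$cohort, rs$dosage))$p < 0.05)
  }
  expect_gt(hits / n_rep, 0.3)
})

test_that("rare set scan reads a mapping and reports one row per set", {
  sim <- small_sim(seed = 15)
  rs <- simulate_rare_geneset(rare_set_config(n_variants = 10, seed = 16),
                              sim$cohort)
  map <- data.frame(set_id = rep(c("setA", "setB"), each = 5),
                    variant_id = rs$dosage$info$id)
  res <- suppressMessages(rare_scan(sim$cohort, rs$dosage, map))
  expect_equal(sort(res$set_id), c("setA", "setB"))
  expect_true(all(res$n_variants == 5))
  tf <- tempfile()
  write.table(map, tf, row.names = FALSE, col.names = FALSE, quote = FALSE)
  res2 <- suppressMessages(rare_scan(sim$cohort, rs$dosage, tf))
  expect_equal(res2$p_fisher, res$p_fisher)
})
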