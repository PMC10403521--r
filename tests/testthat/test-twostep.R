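test_that("EDGE statistic sums the components on 2 d.f.", {
  z <- edge_statistic(0, 0)
  expect_equal(z$edge_stat, 0)
  expect_equal(z$p_edge, 1)
  r <- edge_statistic(4, 5)
  expect_equal(r$edge_stat, 9)
  expect_equal(r$p_edge, exp(-4.5))       # chi2(2) survival = exp(-x/2)
  expect_true(is.na(edge_statistic(NA, 3)$p_edge))
})

test_that("bin schedule follows the geometric halving arithmetic", {
  set.seed(8)
  sched <- build_bin_schedule(runif(35), B = 5, alpha = 0.05)
  bins <- attr(sched, "bins")
  expect_equal(bins$size, c(5, 10, 20))
  expect_equal(bins$alpha_k, c(0.005, 1.25e-3, 3.125e-4))
  one <- build_bin_schedule(0.5, B = 1, alpha = 0.05)
  expect_equal(attr(one, "bins")$alpha_k, 0.05 / 2)
})

test_that("a truncated last bin keeps its full-size denominator", {
  sched <- build_bin_schedule(runif(8), B = 5, alpha = 0.05)
  bins <- attr(sched, "bins")
  expect_equal(bins$size, c(5, 3))
  expect_equal(bins$nominal_size, c(5, 10))
  expect_equal(bins$alpha_k[2], (0.05 / 4) / 10)
})

test_that("alpha budget never exceeds alpha (geometric-series bound)", {
  for (m in c(1, 7, 64, 1000)) {
    set.seed(m)
    sched <- build_bin_schedule(runif(m), B = 3, alpha = 0.05)
    bins <- attr(sched, "bins")
    expect_lte(sum(bins$alpha_k * bins$nominal_size), 0.05 + 1e-12)
  }
})

test_that("ties in step-1 p are broken by genomic position", {
  p <- c(0.5, 0.5, 0.1)
  s1 <- build_bin_schedule(p, B = 1, alpha = 0.05, ids = c("a", "b", "c"),
                           chr = c(2, 1, 1), bp = c(10, 20, 5))
  expect_equal(s1$id, c("c", "b", "a"))
})

test_that("two-step screen with independent variants matches raw counts", {
  sim <- null_sim_cache()
  scan <- scan_variants(sim$cohort, sim$dosage,
                        tests = c("dg", "eg", "gxe", "edge"))
  grp <- seq_len(nrow(scan))  # all LD-independent
  with_ld <- two_step_screen(scan, B = 5, alpha = 0.05, ld_group = grp)
  raw <- suppressWarnings(two_step_screen(scan, B = 5, alpha = 0.05))
  expect_equal(with_ld$table$alpha_k, raw$table$alpha_k)
  expect_identical(with_ld$significant, raw$significant)
})

test_that("LD clustering shrinks the effective per-bin denominator", {
  sim <- simulate_cohort(sim_config(n_studies = 1, n_cases = 500,
                                    n_controls = 500, n_variants = 20,
                                    ld_block_size = 5, ld_rho = 0.9,
                                    seed = 77))
  grp <- ld_groups(sim$dosage)
  expect_lt(length(unique(grp)), 20)
  scan <- scan_variants(sim$cohort, sim$dosage,
                        tests = c("dg", "eg", "gxe", "edge"))
  scr <- two_step_screen(scan, B = 4, alpha = 0.05, dosage = sim$dosage)
  raw <- suppressWarnings(two_step_screen(scan, B = 4, alpha = 0.05))
  expect_true(all(scr$table$alpha_k >= raw$table$alpha_k))
})

test_that("family-wise alpha split reproduces the printed thresholds", {
  expect_equal(apply_fwer_split(3)$per_family, 0.05 / 3)
  expect_equal(apply_fwer_split(3)$per_family, 1.667e-2, tolerance = 1e-3)
  expect_equal(apply_fwer_split(1)$per_family, 0.05)
  expect_equal(apply_fwer_split(3)$genome_wide, 5e-8)
})

test_that("genomic lambda follows the chi-square(1) median definition", {
  expect_equal(genomic_lambda(rep(0.4549364, 5)), 1, tolerance = 1e-6)
  expect_equal(genomic_lambda(c(0.9098, 0.9098728, 0.91)), 2,
               tolerance = 1e-3)
  expect_error(genomic_lambda(numeric(0)), "no finite")
  # null chi-squares give lambda near 1
  set.seed(4)
  expect_equal(genomic_lambda(rchisq(5000, 1)), 1, tolerance = 0.06)
})

test_that("lambda-1000 rescaling matches the consortium-scale example", {
  expect_equal(lambda_1000(1.008, 31318, 41499), 1.000224, tolerance = 1e-5)
  expect_equal(round(lambda_1000(1.008, 31318, 41499), 3), 1.000)
  expect_equal(lambda_1000(1, 123, 45678), 1)
  expect_equal(lambda_1000(1.37, 1000, 1000), 1.37)
})

test_that("lambda-1000 contracts toward 1 for studies larger than 1000/1000", {
  for (lam in c(0.9, 1.05, 1.4)) {
    l1k <- lambda_1000(lam, 5000, 8000)
    expect_lte(abs(l1k - 1), abs(lam - 1))
    expect_equal(sign(l1k - 1), sign(lam - 1))
  }
})

test_that("QQ expected quantiles are -log10((i - 0.5)/m), decreasing", {
  set.seed(9)
  rep <- inflation_report(runif(100), 50, 50)
  expect_equal(rep$qq_points$expected, -log10((1:100 - 0.5) / 100))
  expect_true(all(diff(rep$qq_points$expected) < 0))
})

test_that("known-locus pruning needs both proximity and LD", {
  set.seed(12)
  n <- 300
  anchor <- rbinom(n, 2, 0.3)
  linked <- ifelse(runif(n) < 0.9, anchor, rbinom(n, 2, 0.3))
  free <- rbinom(n, 2, 0.3)
  G <- rbind(anchor = anchor, near_linked = linked, near_free = free,
             far_linked = anchor)
  info <- data.frame(id = c("anchor", "near_linked", "near_free",
                            "far_linked"),
                     chr = "1", bp = c(10e6, 10e6 + 1.9e6, 10e6 + 1.9e6,
                                       10e6 + 5e6),
                     ref = "A", alt = "G", imputation_r2 = 1)
  colnames(G) <- paste0("s", 1:n)
  ref <- dosage_matrix(G, info)
  scan <- info
  known <- data.frame(id = "anchor", chr = "1", bp = 10e6)
  kept <- prune_known_loci(scan, known, ref)
  # 1.9 Mb + r2 > 0.2 -> removed; 1.9 Mb + low r2 -> kept; 5 Mb -> kept
  expect_false("near_linked" %in% kept$id)
  expect_true("near_free" %in% kept$id)
  expect_true("far_linked" %in% kept$id)
  expect_false("anchor" %in% kept$id)
})

test_that("pruning retains variants with unknown position, with a warning", {
  G <- matrix(rbinom(200, 2, 0.4), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  colnames(G) <- paste0("s", 1:100)
  info <- data.frame(id = c("a", "b"), chr = "1", bp = c(100L, NA),
                     ref = "A", alt = "G", imputation_r2 = 1)
  ref <- dosage_matrix(G, info)
  known <- data.frame(id = "a", chr = "1", bp = 100L)
  expect_warning(kept <- prune_known_loci(info, known, ref),
                 "unknown position")
  expect_true("b" %in% kept$id)
})
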