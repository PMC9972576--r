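small_cfg <- function(...) {
  sim_config(n_probes = c(variance_component = 200, snp_trimodal = 50,
                          age_drift = 50, cell_driven = 40),
             n_qc_gv = 10, ...)
}

test_that("same seed reproduces the cohort, different seeds differ", {
  a <- simulate_cohort(small_cfg(), seed = 5)
  b <- simulate_cohort(small_cfg(), seed = 5)
  d <- simulate_cohort(small_cfg(), seed = 6)
  expect_identical(a$beta, b$beta)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth$probes, b$truth$probes)
  expect_false(identical(a$beta, d$beta))
})

test_that("true ICC of 1 gives identical timepoints up to clipping", {
  cfg <- sim_config(n_probes = c(variance_component = 100, snp_trimodal = 0,
                                 age_drift = 0, cell_driven = 0),
                    n_qc_gv = 0, icc_levels = 1)
  sim <- simulate_cohort(cfg, seed = 2)
  v <- align_pairs(sim$beta, sim$sheet)
  expect_equal(v$t1, v$t2, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("MAF = 0 genotype probes are unimodal with no gap signal", {
  cfg <- sim_config(n_probes = c(variance_component = 0, snp_trimodal = 50,
                                 age_drift = 0, cell_driven = 0),
                    n_qc_gv = 0, maf = c(0, 0))
  sim <- simulate_cohort(cfg, seed = 3)
  g <- gaps_genomewide(sim$beta)
  expect_true(all(g$n_groups == 1))
  expect_false(any(g$is_gap_signal))
})

test_that("generated variance components match the configured model", {
  # empirical between/within variances within 5% at 10^4 probes
  cfg <- sim_config(n_probes = c(variance_component = 10000,
                                 snp_trimodal = 0, age_drift = 0,
                                 cell_driven = 0),
                    n_qc_gv = 0, icc_levels = 0.8, n_subjects = 50)
  sim <- simulate_cohort(cfg, seed = 4)
  v <- align_pairs(sim$beta, sim$sheet)
  diffs <- v$t2 - v$t1                      # Var = 2 * sigma2_e
  sums <- (v$t2 + v$t1) / 2                 # Var = sigma2_b + sigma2_e / 2
  s2e_hat <- mean(apply(diffs, 1, stats::var)) / 2
  s2b_hat <- mean(apply(sums, 1, stats::var)) - s2e_hat / 2
  s2_tot <- cfg$vc_total_sd^2
  expect_lt(abs(s2e_hat - 0.2 * s2_tot) / (0.2 * s2_tot), 0.05)
  expect_lt(abs(s2b_hat - 0.8 * s2_tot) / (0.8 * s2_tot), 0.05)
})

test_that("genotype frequencies follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_probes = c(variance_component = 0, snp_trimodal = 400,
                                 age_drift = 0, cell_driven = 0),
                    n_qc_gv = 0, maf = c(0.3, 0.3), n_subjects = 46)
  sim <- simulate_cohort(cfg, seed = 8)
  g <- sim$truth$genotypes
  n <- length(g)
  p <- 0.3
  expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  obs <- tabulate(as.vector(g) + 1L, 3L) / n
  # each genotype frequency within a 4-sigma binomial band
  for (j in 1:3) {
    se <- sqrt(expected[j] * (1 - expected[j]) / n)
    expect_lt(abs(obs[j] - expected[j]), 4 * se)
  }
  # genotypes constant across timepoints by construction: T1/T2 cluster
  # assignment of any genotype probe matches the subject genotype
  v <- align_pairs(sim$beta, sim$sheet)
  means <- cfg$cluster_means
  assign1 <- apply(abs(outer(v$t1[1, ], means, "-")), 1, which.min) - 1L
  assign2 <- apply(abs(outer(v$t2[1, ], means, "-")), 1, which.min) - 1L
  expect_equal(unname(assign1), unname(assign2))
  expect_equal(unname(assign1), unname(g[1, v$subjects]))
})

test_that("truth tables round-trip through CSV", {
  sim <- simulate_cohort(small_cfg(), seed = 9)
  dir <- withr::local_tempdir()
  write_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$probes, sim$truth$probes)
  expect_equal(back$genotypes, sim$truth$genotypes)
  expect_equal(back$cell_weights, sim$truth$cell_weights, tolerance = 1e-12)
  # truth rows cover the configured probe counts
  expect_equal(nrow(sim$truth$probes), 200 + 50 + 50 + 40 + 10)
})

test_that("cell weights are a simplex and T2 shift matches the config", {
  sim <- simulate_cohort(small_cfg(), seed = 10)
  w <- sim$truth$cell_weights
  expect_true(all(w >= 0))
  expect_equal(unname(rowSums(w)), rep(1, nrow(w)), tolerance = 1e-12)
  w1 <- w[grepl("_T1$", rownames(w)), ]
  w2 <- w[grepl("_T2$", rownames(w)), ]
  shift <- colMeans(w2) - colMeans(w1)
  # configured direction: B and CD4T up, neutrophils down
  expect_gt(shift["B"], 0)
  expect_gt(shift["CD4T"], 0)
  expect_lt(shift["Neu"], 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(icc_levels = c(0.5, 1.2)), "ICC levels")
  expect_error(sim_config(maf = 0.7), "allele frequency")
  expect_error(sim_config(cell_shift = c(0.1, 0, 0, 0, 0, 0)), "sum to 0")
  expect_error(sim_config(reference_high = 0.4, reference_low = 0.2),
               "0.3")
})
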