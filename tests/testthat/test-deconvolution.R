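make_reference <- function(m = 60, c = 6) {
  R <- matrix(0.15, m, c, dimnames = list(sprintf("cg%04d", 1:m),
                                          c("B", "CD4T", "CD8T", "NK",
                                            "Mono", "Neu")[1:c]))
  R[cbind(1:m, rep_len(1:c, m))] <- 0.85
  R
}

test_that("noiseless members of the cone are recovered exactly", {
  R <- make_reference()
  w_true <- c(0.5, 0.3, 0.2, 0, 0, 0)
  est <- deconvolve(as.numeric(R %*% w_true), R)
  expect_lt(max(abs(est$weights_raw - w_true)), 1e-8)
  expect_lt(est$residual_norm, 1e-8)
})

test_that("a response orthogonal to the reference gives zero weights", {
  R <- cbind(a = c(1, 0, 0, 0), b = c(0, 1, 0, 0))
  y <- c(0, 0, 0.3, 0.4)
  est <- deconvolve(y, R)
  expect_equal(unname(est$weights_raw), c(0, 0))
  expect_equal(est$residual_norm, 0.5)
})

test_that("deconvolution is scale consistent on raw weights", {
  set.seed(31)
  R <- make_reference()
  y <- as.numeric(R %*% c(0.1, 0.2, 0.1, 0.1, 0.2, 0.3)) +
    stats::rnorm(nrow(R), sd = 0.01)
  y <- pmax(y, 0)
  w1 <- deconvolve(y, R)$weights_raw
  w2 <- deconvolve(0.5 * y, R)$weights_raw
  expect_equal(w2, 0.5 * w1, tolerance = 1e-8)
})

test_that("duplicated reference CpGs leave estimates unchanged", {
  set.seed(32)
  R <- make_reference(30)
  y <- as.numeric(R %*% c(0.2, 0.2, 0.2, 0.1, 0.1, 0.2)) +
    stats::rnorm(30, sd = 0.005)
  base <- deconvolve(y, R)$weights_raw
  # NNLS minimizes the sum of squares, so duplicating a row re-weights that
  # CpG; duplicating every row leaves the solution unchanged
  dup <- deconvolve(c(y, y), rbind(R, R))$weights_raw
  expect_equal(dup, base, tolerance = 1e-8)
})

test_that("rank-deficient references are rejected naming the column", {
  R <- make_reference(30)
  R[, "Neu"] <- R[, "B"]
  expect_error(deconvolve(stats::runif(30), R), "collinear")
  expect_error(deconvolve(stats::runif(3), make_reference(3, 6)),
               "at least as many CpGs")
})

test_that("Dirichlet mixtures are recovered with small error under noise", {
  set.seed(33)
  R <- make_reference(300)
  n <- 50
  g <- matrix(stats::rgamma(n * 6, shape = rep(c(2, 4, 3, 2, 2, 12), n)),
              n, byrow = TRUE)
  W <- g / rowSums(g)
  Y <- R %*% t(W) + matrix(stats::rnorm(300 * n, sd = 0.01), 300, n)
  colnames(Y) <- sprintf("S%03d", 1:n)
  est <- deconvolve_samples(Y, R)
  W_hat <- as.matrix(est[, colnames(R)])
  expect_lt(sqrt(mean((W_hat - W)^2)), 0.02)
})

test_that("composition comparison detects an encoded shift", {
  set.seed(34)
  cfg <- sim_config(n_probes = c(variance_component = 0, snp_trimodal = 0,
                                 age_drift = 0, cell_driven = 300),
                    n_qc_gv = 0,
                    cell_shift = c(0.05, 0, 0, 0, 0, -0.05))
  sim <- simulate_cohort(cfg, seed = 34)
  est <- deconvolve_samples(sim$beta, sim$reference)
  cmp <- compare_composition(est, sim$sheet)
  expect_equal(nrow(cmp), 6)
  b <- cmp[cmp$cell_type == "B", ]
  expect_lt(b$p_value, 0.05)
  expect_gt(b$mean_diff_paired, 0)
  expect_lt(cmp$mean_diff_paired[cmp$cell_type == "Neu"], 0)
  # paired variant agrees on direction with smaller p on paired shifts
  cmp_p <- compare_composition(est, sim$sheet, paired = TRUE)
  expect_lt(cmp_p$p_value[cmp_p$cell_type == "B"], b$p_value)
  expect_error(compare_composition(est[1:3, ], sim$sheet), ">= 2 samples")
})
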