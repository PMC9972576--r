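test_that("perfect consistency under a constant shift gives ICC 1", {
  res <- icc_consistency(cbind(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(res$icc, 1)
  expect_equal(res$p_value, 0)
  expect_equal(c(res$ci_low, res$ci_high), c(1, 1))
  expect_true(res$degenerate)
})

test_that("no between-subject signal gives non-positive ICC", {
  m <- cbind(c(1, 3, 5), c(6, 2, 4))
  res <- icc_consistency(m)
  expect_lte(res$icc, 0)
  expect_equal(res$icc, oracle_icc(m)$icc, tolerance = 1e-12)
})

test_that("closed form matches the brute-force ANOVA oracle", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    k <- sample(c(2, 2, 2, 3, 4), 1)  # mostly the two-timepoint design
    m <- matrix(stats::rnorm(n * k, 0.5, 0.1), n, k) +
      stats::rnorm(n, sd = 0.1)
    res <- icc_consistency(m)
    orc <- oracle_icc(m)
    expect_lt(abs(res$icc - orc$icc), 1e-10)
    expect_lt(abs(res$f_stat - orc$f), 1e-8)
    expect_lt(abs(res$p_value - orc$p), 1e-10)
  }
})

test_that("degenerate and undersized inputs are flagged", {
  expect_true(is.na(icc_consistency(matrix(0.4, 5, 2))$icc))
  expect_true(is.na(icc_consistency(cbind(c(1, 2), c(1, 2)))$icc))
  # complete-case behavior: NA rows dropped
  m <- cbind(c(1, 3, 5, NA), c(2, 4, 6, 1))
  expect_equal(icc_consistency(m)$n_pairs, 3)
})

test_that("consistency ICC is shift invariant but not scale invariant", {
  set.seed(8)
  m <- matrix(stats::runif(40), 20, 2)
  base <- icc_consistency(m)$icc
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 0.3
  expect_equal(icc_consistency(shifted)$icc, base, tolerance = 1e-10)
  scaled <- m
  scaled[, 2] <- scaled[, 2] * 2
  expect_false(isTRUE(all.equal(icc_consistency(scaled)$icc, base,
                                tolerance = 1e-4)))
})

test_that("genome-wide screen agrees with per-probe computation", {
  set.seed(9)
  t1 <- matrix(stats::runif(200, 0.2, 0.8), 20, 10)
  t2 <- t1 * 0.8 + matrix(stats::runif(200, 0.1, 0.3), 20, 10)
  t1[1, 2] <- NA  # exercise complete-pair handling
  v <- toy_view(t1, t2)
  gw <- icc_genomewide(v)
  for (i in c(1, 5, 20)) {
    single <- icc_consistency(cbind(t1[i, ], t2[i, ]))
    expect_equal(gw$icc[i], single$icc, tolerance = 1e-12)
    expect_equal(gw$p_value[i], single$p_value, tolerance = 1e-12)
    expect_equal(gw$ci_low[i], single$ci_low, tolerance = 1e-10)
    expect_equal(gw$n_pairs[i], single$n_pairs)
  }
  expect_true(gw$low_coverage[1] == (gw$n_pairs[1] < 0.8 * 10))
})

test_that("duplicating T1 as T2 yields ICC 1 genome-wide", {
  set.seed(10)
  t1 <- matrix(stats::runif(300, 0.1, 0.9), 30, 10)
  v <- toy_view(t1, t1)
  gw <- icc_genomewide(v)
  expect_true(all(gw$icc == 1))
  expect_true(all(gw$p_value == 0))
})

test_that("reliability bins follow the published boundaries", {
  expect_equal(as.character(classify_icc(0.9901530462)), "excellent")
  got <- classify_icc(c(0.75, 0.8999999, 0.9, -0.2, 0.49999, 0.5, NA))
  expect_equal(as.character(got),
               c("good", "good", "excellent", "poor", "poor", "moderate",
                 NA))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # NA propagation with m = number tested
  expect_equal(bh_adjust(c(0.01, NA, 0.02, 0.03)),
               c(0.03, NA, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # step-up on a random vector against a direct implementation
  set.seed(11)
  p <- stats::runif(50)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * 50 / seq_len(50))))
  expect_equal(bh_adjust(p)[o], pmin(q, 1))
})

test_that("ICC power increases with true ICC at fixed n", {
  set.seed(12)
  n <- 20; m <- 400
  rej <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    b <- matrix(stats::rnorm(m * n, sd = sqrt(rho)), m, n)
    t1 <- b + matrix(stats::rnorm(m * n, sd = sqrt(1 - rho)), m, n)
    t2 <- b + matrix(stats::rnorm(m * n, sd = sqrt(1 - rho)), m, n)
    v <- toy_view(t1 / 10 + 0.5, t2 / 10 + 0.5)
    mean(icc_genomewide(v)$p_value < 0.05)
  }, 0)
  expect_true(all(diff(rej) > 0))
})
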