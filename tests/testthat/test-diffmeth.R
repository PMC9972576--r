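test_that("design matrix has the expected structure and rank", {
  set.seed(51)
  sheet <- toy_sheet(46)
  cells <- data.frame(sample_id = sheet$sample_id,
                      B = stats::runif(92, 0, 0.2),
                      CD4T = stats::runif(92, 0, 0.3),
                      CD8T = stats::runif(92, 0, 0.2),
                      NK = stats::runif(92, 0, 0.1),
                      Mono = stats::runif(92, 0, 0.1),
                      Neu = stats::runif(92, 0.3, 0.6))
  X <- build_design(sheet, cells)
  expect_equal(dim(X), c(92L, 10L))  # 1+1+1+1+1 + 5 cell columns
  expect_false("Neu" %in% colnames(X))
  expect_equal(qr(X)$rank, 10L)
  # permuting sample order permutes rows identically
  perm <- sample(nrow(sheet))
  Xp <- build_design(sheet[perm, ], cells)
  expect_equal(Xp, X[perm, ])
})

test_that("zero-variance covariates are dropped with a warning", {
  sheet <- toy_sheet(10)
  sheet$sex <- "F"
  expect_warning(X <- build_design(sheet), "sexM")
  expect_false("sexM" %in% colnames(X))
})

test_that("rank-deficient designs are rejected naming the columns", {
  sheet <- toy_sheet(10)
  extra <- data.frame(sample_id = sheet$sample_id,
                      dup = as.numeric(sheet$timepoint == "T2"))
  expect_error(build_design(sheet, extra = extra), "rank deficient.*dup")
})

test_that("per-probe OLS agrees with an independent lm oracle", {
  set.seed(52)
  sheet <- toy_sheet(20)
  X <- build_design(sheet)
  beta <- random_beta(100, 40)
  colnames(beta) <- sheet$sample_id
  beta[3, 5] <- NA  # exercise the complete-case path
  fit <- fit_probes(beta, X)
  for (i in c(1, 3, 50, 100)) {
    ok <- !is.na(beta[i, ])
    lmfit <- stats::lm(beta[i, ok] ~ X[ok, -1])
    expect_lt(max(abs(fit$coefficients[i, ] -
                        unname(stats::coef(lmfit)))), 1e-10)
    expect_lt(abs(fit$sigma2[i] - summary(lmfit)$sigma^2), 1e-12)
    se_lm <- summary(lmfit)$coefficients[, "Std. Error"]
    se_pkg <- fit$stdev_unscaled[i, ] * sqrt(fit$sigma2[i])
    expect_lt(max(abs(se_pkg - unname(se_lm))), 1e-10)
  }
})

test_that("a probe equal to the time column is fitted exactly", {
  sheet <- toy_sheet(10)
  X <- build_design(sheet)
  beta <- matrix(stats::runif(5 * 20), 5, 20,
                 dimnames = list(sprintf("cg%d", 1:5), sheet$sample_id))
  beta[1, ] <- as.numeric(sheet$timepoint == "T2")
  fit <- fit_probes(beta, X)
  expect_equal(unname(fit$coefficients[1, "timepointT2"]), 1,
               tolerance = 1e-10)
  expect_lt(fit$sigma2[1], 1e-20)
})

test_that("variance squeeze matches limma and recovers prior parameters", {
  skip_if_not_installed("limma")
  set.seed(53)
  m <- 3000; dg <- 30; d0 <- 4; s0 <- 0.01
  sig2 <- s0 * d0 / stats::rchisq(m, d0)
  s2 <- sig2 * stats::rchisq(m, dg) / dg
  eb <- squeeze_variances(s2, dg)
  sv <- limma::squeezeVar(s2, dg)
  expect_equal(eb$d0, sv$df.prior, tolerance = 1e-6)
  expect_equal(eb$s0_sq, sv$var.prior, tolerance = 1e-6)
  expect_equal(eb$s2_post, sv$var.post, tolerance = 1e-8)
  expect_lt(abs(eb$d0 - d0) / d0, 0.4)
  expect_lt(abs(eb$s0_sq - s0) / s0, 0.1)
})

test_that("squeeze limits behave as documented", {
  set.seed(54)
  # identical variances: d0 infinite, posterior is the pooled variance
  eb <- squeeze_variances(rep(0.01, 500), 50)
  expect_equal(eb$d0, Inf)
  expect_equal(unique(eb$s2_post), 0.01)
  # huge dispersion: d0 near zero, posterior tracks observed variances
  s2b <- exp(stats::rnorm(2000, sd = 6)) * 1e-4
  eb2 <- squeeze_variances(s2b, 50)
  expect_lt(eb2$d0, 1)
  expect_gt(stats::cor(log(eb2$s2_post), log(s2b)), 0.99)
})

test_that("moderated t interpolates between ordinary and pooled t", {
  set.seed(55)
  sheet <- toy_sheet(23)
  X <- build_design(sheet)
  # heterogeneous residual scales so the prior df estimate is finite
  sds <- exp(stats::rnorm(500, log(0.05), 0.6))
  beta <- pmin(pmax(0.5 + matrix(stats::rnorm(500 * 46), 500, 46) * sds,
                    0), 1)
  rownames(beta) <- sprintf("cg%05d", 1:500)
  colnames(beta) <- sheet$sample_id
  fit <- fit_probes(beta, X)
  mod <- moderate_fit(fit)
  t_ord <- fit$coefficients[, "timepointT2"] /
    (fit$stdev_unscaled[, "timepointT2"] * sqrt(fit$sigma2))
  d0 <- attr(mod, "d0")
  # |t_mod| lies between ordinary t and the t computed with s0 alone
  ratio <- mod$t_mod / t_ord
  expect_true(all(ratio > 0))
  shrunk_more <- fit$sigma2 < attr(mod, "s0_sq")
  expect_true(all(abs(mod$t_mod)[shrunk_more] <= abs(t_ord)[shrunk_more]
                  + 1e-12))
  expect_true(all(abs(mod$t_mod)[!shrunk_more] >= abs(t_ord)[!shrunk_more]
                  - 1e-12))
  expect_true(is.finite(d0) && d0 > 0)
})

test_that("moderated pipeline agrees with limma end to end", {
  skip_if_not_installed("limma")
  set.seed(56)
  sheet <- toy_sheet(20)
  X <- build_design(sheet)
  beta <- random_beta(800, 40)
  colnames(beta) <- sheet$sample_id
  fit <- fit_probes(beta, X)
  mod <- moderate_fit(fit)
  lfit <- limma::eBayes(limma::lmFit(beta, X))
  expect_equal(attr(mod, "d0"), lfit$df.prior, tolerance = 1e-4)
  expect_equal(mod$t_mod, unname(lfit$t[, "timepointT2"]),
               tolerance = 1e-6)
  expect_equal(mod$p_value, unname(lfit$p.value[, "timepointT2"]),
               tolerance = 1e-6)
})

test_that("DMP calls combine BH, threshold and paired delta beta", {
  set.seed(57)
  sheet <- toy_sheet(23)
  X <- build_design(sheet)
  beta <- random_beta(300, 46)
  colnames(beta) <- sheet$sample_id
  # spike a strong time effect
  shift <- as.numeric(sheet$timepoint == "T2") * 0.3
  beta[1, ] <- pmin(0.3 + shift + stats::rnorm(46, sd = 0.01), 1)
  v <- align_pairs(beta, sheet)
  fit <- fit_probes(beta, X)
  dm <- call_dmps(moderate_fit(fit), v)
  expect_true(dm$is_dmp[1])
  expect_equal(dm$delta_beta[1], mean(v$t2[1, ] - v$t1[1, ]),
               tolerance = 1e-12)
  expect_equal(dm$p_adjusted, bh_adjust(dm$p_value))
  # delta_beta equals the paired mean difference used elsewhere
  expect_equal(dm$delta_beta, unname(rowMeans(v$t2 - v$t1)[dm$probe_id]))
})

test_that("set rank test flags extreme sets and respects direction", {
  set.seed(58)
  stats_vec <- stats::setNames(stats::rnorm(2000),
                               sprintf("cg%05d", 1:2000))
  worst <- names(sort(stats_vec))[1:100]  # most negative statistics
  res <- set_rank_test(stats_vec, worst, alternative = "down")
  expect_lt(res$p_value, 1e-20)
  res_up <- set_rank_test(stats_vec, worst, alternative = "up")
  expect_gt(res_up$p_value, 0.999)
  expect_error(set_rank_test(stats_vec, c("nope")), "intersect")
  expect_warning(set_rank_test(stats_vec, names(stats_vec)[1:3]),
                 "< 5 members")
})
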