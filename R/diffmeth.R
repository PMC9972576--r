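#' Build the design matrix for paired differential methylation
#'
#' Columns: intercept, timepoint indicator (T2 = 1), sex (M = 1), smoking
#' (active = 1), disease (UC = 1), and the estimated cell-weight columns
#' with one reference cell type dropped to avoid collinearity with the
#' intercept. Zero-variance covariate columns (e.g. sex in a single-sex
#' cohort) are dropped with a warning; the final matrix must be full rank.
#'
#' @param sheet sample sheet.
#' @param cells optional [deconvolve_samples()] output aligned by
#'   `sample_id`.
#' @param reference_cell cell-weight column to drop (default `"Neu"` if
#'   present, else the last weight column).
#' @param extra optional data.frame of additional numeric covariates keyed
#'   by `sample_id` (e.g. CRP or leukocyte count as the coefficient of
#'   interest).
#' @return numeric design matrix with rownames = sample ids.
#' @export
build_design <- function(sheet, cells = NULL, reference_cell = NULL,
                         extra = NULL) {
  X <- cbind("(Intercept)" = 1,
             timepointT2 = as.numeric(sheet$timepoint == "T2"),
             sexM = as.numeric(sheet$sex == "M"),
             smokingactive = as.numeric(sheet$smoking == "active"),
             diseaseUC = as.numeric(sheet$disease == "UC"))
  rownames(X) <- sheet$sample_id
  if (!is.null(cells)) {
    wcols <- setdiff(names(cells),
                     c("sample_id", "residual_norm",
                       grep("^raw_", names(cells), value = TRUE)))
    if (is.null(reference_cell))
      reference_cell <- if ("Neu" %in% wcols) "Neu" else wcols[length(wcols)]
    wcols <- setdiff(wcols, reference_cell)
    idx <- match(sheet$sample_id, cells$sample_id)
    if (anyNA(idx)) stop("cell estimates missing for some samples",
                         call. = FALSE)
    X <- cbind(X, as.matrix(cells[idx, wcols, drop = FALSE]))
  }
  if (!is.null(extra)) {
    idx <- match(sheet$sample_id, extra$sample_id)
    if (anyNA(idx)) stop("extra covariates missing for some samples",
                         call. = FALSE)
    X <- cbind(X, as.matrix(extra[idx, setdiff(names(extra), "sample_id"),
                                  drop = FALSE]))
  }
  const <- apply(X, 2L, function(col) stats::var(col) == 0)
  const["(Intercept)"] <- FALSE
  if (any(const)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  X
}

#' Per-probe ordinary least squares fit
#'
#' Fits each probe's beta values against the design by OLS. Probes without
#' missing values are fitted in one vectorized pass; probes with missing
#' values are fitted on their complete samples, and probes with fewer than
#' `min_complete` of the samples (or non-positive residual df) are skipped
#' with a flag.
#'
#' @param beta probes x samples matrix (columns matched to design rownames).
#' @param design full-rank design matrix from [build_design()].
#' @param min_complete minimum fraction of non-missing samples per probe.
#' @return `probe_fit` list: `coefficients` (probes x p), `stdev_unscaled`
#'   (probes x p, unscaled coefficient sd), `sigma2` (residual variance),
#'   `df_residual`, `skipped` (logical), `design`.
#' @export
fit_probes <- function(beta, design, min_complete = 0.8) {
  if (is.null(rownames(design)))
    stop("design needs sample rownames", call. = FALSE)
  if (!all(rownames(design) %in% colnames(beta)))
    stop("beta matrix lacks sample(s) present in the design", call. = FALSE)
  beta <- beta[, rownames(design), drop = FALSE]
  nprobe <- nrow(beta); p <- ncol(design); nsamp <- nrow(design)
  if (nsamp <= p) stop("need more samples than design columns", call. = FALSE)

  coefs <- matrix(NA_real_, nprobe, p, dimnames = list(rownames(beta),
                                                       colnames(design)))
  sdu <- matrix(NA_real_, nprobe, p, dimnames = dimnames(coefs))
  sigma2 <- rep(NA_real_, nprobe)
  dfres <- rep(NA_integer_, nprobe)
  skipped <- rep(FALSE, nprobe)

  complete <- rowSums(is.na(beta)) == 0L
  if (any(complete)) {
    qx <- qr(design)
    Y <- t(beta[complete, , drop = FALSE])
    coefs[complete, ] <- t(qr.coef(qx, Y))
    res <- qr.resid(qx, Y)
    dfres[complete] <- nsamp - p
    sigma2[complete] <- colSums(res^2) / (nsamp - p)
    su <- sqrt(diag(chol2inv(qr.R(qx))))
    # chol2inv of qr.R follows the pivoted order
    su <- su[order(qx$pivot)]
    sdu[complete, ] <- matrix(su, sum(complete), p, byrow = TRUE)
  }
  for (i in which(!complete)) {
    ok <- !is.na(beta[i, ])
    if (sum(ok) < max(min_complete * nsamp, p + 1)) {
      skipped[i] <- TRUE
      next
    }
    Xi <- design[ok, , drop = FALSE]
    qi <- qr(Xi)
    if (qi$rank < p) { skipped[i] <- TRUE; next }
    coefs[i, ] <- qr.coef(qi, beta[i, ok])
    ri <- qr.resid(qi, beta[i, ok])
    dfres[i] <- sum(ok) - p
    sigma2[i] <- sum(ri^2) / dfres[i]
    sdu[i, ] <- sqrt(diag(solve(crossprod(Xi))))
  }
  structure(list(coefficients = coefs, stdev_unscaled = sdu, sigma2 = sigma2,
                 df_residual = dfres, skipped = skipped, design = design),
            class = "probe_fit")
}

# Newton solve of trigamma(y) = x, vectorized (monotone decreasing trigamma).
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (iter in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y), na.rm = TRUE) < 1e-10) break
  }
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  y[x < 1e-6] <- 1 / x[x < 1e-6]
  y
}

#' Empirical-Bayes squeeze of residual variances
#'
#' Moment estimation of a scaled inverse-chi-square prior on per-probe
#' residual variances, on the log scale: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior df `d0`
#' solves `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` (infinite when
#' the right-hand side is non-positive, i.e. no excess dispersion), and the
#' prior variance is `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`.
#' Posterior variances are `s2_post = (d0 s0^2 + d_g s2_g) / (d0 + d_g)`.
#'
#' @param s2 per-probe residual variances (>= 100 finite values advised for
#'   stable moment estimation).
#' @param df residual degrees of freedom (scalar or per-probe vector).
#' @return list: `d0`, `s0_sq`, `s2_post`, `df_total` (= `d0 + df`, capped
#'   for infinite `d0`).
#' @export
squeeze_variances <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2L) stop("need >= 2 positive finite variances", call. = FALSE)
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond chi-square sampling noise: the prior is
    # degenerate and the posterior is the pooled variance
    d0 <- Inf
    s0_sq <- mean(s2[ok])
  }
  if (is.finite(d0)) {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  } else {
    s2_post <- rep(s0_sq, length(s2))
  }
  # total df capped at the pooled residual df (the information actually
  # available), so an infinite prior yields a finite reference distribution
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post,
       df_total = pmin(d0 + df, sum(df[ok])))
}

#' Moderated t-statistics for one coefficient
#'
#' Combines a [fit_probes()] fit with the [squeeze_variances()] posterior:
#' `t_mod = coef / (stdev_unscaled * sqrt(s2_post))` on `d0 + d_g` degrees
#' of freedom, two-sided p-values from the t distribution.
#'
#' @param fit a `probe_fit`.
#' @param coef coefficient name (default `"timepointT2"`).
#' @return data.frame: `probe_id`, `coef`, `s2`, `s2_post`, `t_mod`,
#'   `df_total`, `p_value`, plus the `eb` parameters as attributes
#'   `d0`/`s0_sq`.
#' @export
moderate_fit <- function(fit, coef = "timepointT2") {
  stopifnot(inherits(fit, "probe_fit"), coef %in% colnames(fit$coefficients))
  eb <- squeeze_variances(fit$sigma2[!fit$skipped],
                          fit$df_residual[!fit$skipped])
  s2_post <- rep(NA_real_, length(fit$sigma2))
  if (is.finite(eb$d0)) {
    s2_post <- (eb$d0 * eb$s0_sq + fit$df_residual * fit$sigma2) /
      (eb$d0 + fit$df_residual)
  } else {
    s2_post[!fit$skipped] <- eb$s0_sq
  }
  df_total <- pmin(eb$d0 + fit$df_residual,
                   sum(fit$df_residual[!fit$skipped]))
  t_mod <- fit$coefficients[, coef] /
    (fit$stdev_unscaled[, coef] * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(t_mod), df_total)
  out <- data.frame(probe_id = rownames(fit$coefficients),
                    coef = fit$coefficients[, coef],
                    s2 = fit$sigma2, s2_post = s2_post, t_mod = t_mod,
                    df_total = df_total, p_value = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- eb$d0
  attr(out, "s0_sq") <- eb$s0_sq
  out
}

#' Call differentially methylated positions
#'
#' BH-adjusts the moderated p-values and flags probes below the FDR
#' threshold. The unadjusted mean paired difference (`delta_beta`,
#' mean over subjects of T2 - T1) is reported alongside the
#' covariate-adjusted time coefficient.
#'
#' @param moderated output of [moderate_fit()].
#' @param view the [align_pairs()] view used to compute `delta_beta`.
#' @param p_threshold FDR threshold for `is_dmp` (default 0.05).
#' @return `DMResult` data.frame: `probe_id`, `delta_beta`, `coef_time`,
#'   `s2`, `s2_post`, `t_mod`, `df_total`, `p_value`, `p_adjusted`,
#'   `is_dmp`.
#' @export
call_dmps <- function(moderated, view, p_threshold = 0.05) {
  delta <- rowMeans(view$t2 - view$t1, na.rm = TRUE)
  out <- data.frame(probe_id = moderated$probe_id,
                    delta_beta = delta[moderated$probe_id],
                    coef_time = moderated$coef,
                    s2 = moderated$s2, s2_post = moderated$s2_post,
                    t_mod = moderated$t_mod, df_total = moderated$df_total,
                    p_value = moderated$p_value,
                    p_adjusted = bh_adjust(moderated$p_value),
                    stringsAsFactors = FALSE)
  out$is_dmp <- !is.na(out$p_adjusted) & out$p_adjusted < p_threshold
  rownames(out) <- NULL
  out
}

#' Rank test for a CpG set's statistics
#'
#' Wilcoxon rank-sum comparison of the set members' statistics against all
#' other probes in the universe, the standard competitive test for e.g.
#' epigenetic-clock CpG sets among time-associated statistics. Directional
#' alternatives: `"down"` tests for lower statistics in the set (e.g. a
#' hypomethylation-at-T2 pattern), `"up"` for higher, `"mixed"` two-sided.
#'
#' @param statistics named numeric vector (names = probe ids), e.g.
#'   moderated t-statistics.
#' @param set character vector of CpG ids.
#' @param alternative `"mixed"`, `"up"` or `"down"`.
#' @return one-row data.frame: `n_set`, `n_universe`, `statistic`,
#'   `p_value`, `median_rank_set`, `alternative`.
#' @export
set_rank_test <- function(statistics, set,
                          alternative = c("mixed", "up", "down")) {
  alternative <- match.arg(alternative)
  in_set <- names(statistics) %in% set
  if (!any(in_set)) stop("set does not intersect the universe", call. = FALSE)
  exact <- FALSE
  if (sum(in_set) < 5L) {
    warning("set has < 5 members in the universe; using exact test",
            call. = FALSE)
    exact <- TRUE
  }
  alt <- switch(alternative, mixed = "two.sided", up = "greater",
                down = "less")
  wt <- stats::wilcox.test(statistics[in_set], statistics[!in_set],
                           alternative = alt, exact = exact)
  ranks <- rank(statistics)
  data.frame(n_set = sum(in_set), n_universe = length(statistics),
             statistic = unname(wt$statistic), p_value = wt$p.value,
             median_rank_set = stats::median(ranks[in_set]),
             alternative = alternative, stringsAsFactors = FALSE)
}
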