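#' Intra-class correlation, two-way mixed, single measures, consistency
#'
#' Computes ICC(C,1) from an n x k matrix of repeated measurements (rows =
#' subjects, columns = occasions) via the two-way ANOVA decomposition:
#' `MS_R = k * sum((rowmean - grand)^2) / (n-1)`,
#' `MS_C = n * sum((colmean - grand)^2) / (k-1)`,
#' `MS_E = (SS_total - SS_rows - SS_cols) / ((n-1)(k-1))`, and
#' `ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E)`.
#' The null ICC <= 0 is tested one-sided with `F = MS_R / MS_E` on
#' `(n-1, (n-1)(k-1))` degrees of freedom, and the confidence interval uses
#' the F-bound construction `FL = F / qf(1-(1-level)/2, df1, df2)`,
#' `FU = F * qf(1-(1-level)/2, df2, df1)`.
#'
#' Rows with any missing value are dropped (complete-case). Degenerate
#' inputs: zero residual mean square with between-subject signal gives
#' ICC = 1, p = 0, CI (1, 1); a matrix of identical values gives an
#' all-`NA` result. Both are flagged in `degenerate`.
#'
#' @param pairs numeric n x k matrix, n >= 3 complete rows (k = 2 for the
#'   usual two-timepoint design; general k is supported).
#' @param ci_level confidence level (default 0.95).
#' @return one-row data.frame: `icc`, `ci_low`, `ci_high`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `n_pairs`, `degenerate`.
#' @export
icc_consistency <- function(pairs, ci_level = 0.95) {
  pairs <- as.matrix(pairs)
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  n <- nrow(pairs); k <- ncol(pairs)
  na_row <- data.frame(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       f_stat = NA_real_, df1 = NA_real_, df2 = NA_real_,
                       p_value = NA_real_, n_pairs = n, degenerate = TRUE)
  if (n < 3L || k < 2L) return(na_row)
  if (any(!is.finite(pairs))) stop("measurements must be finite", call. = FALSE)
  grand <- mean(pairs)
  rowm <- rowMeans(pairs); colm <- colMeans(pairs)
  ss_rows <- k * sum((rowm - grand)^2)
  ss_cols <- n * sum((colm - grand)^2)
  ss_tot <- sum((pairs - grand)^2)
  ss_err <- max(ss_tot - ss_rows - ss_cols, 0)
  df1 <- n - 1L; df2 <- (n - 1L) * (k - 1L)
  msr <- ss_rows / df1
  mse <- ss_err / df2
  if (ss_tot <= 0) return(na_row)              # all values identical
  if (mse <= 1e-12 * ss_tot / (n * k)) {       # zero residual, signal present
    return(data.frame(icc = 1, ci_low = 1, ci_high = 1, f_stat = Inf,
                      df1 = df1, df2 = df2, p_value = 0, n_pairs = n,
                      degenerate = TRUE))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f <- msr / mse
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  q <- 1 - (1 - ci_level) / 2
  fl <- f / stats::qf(q, df1, df2)
  fu <- f * stats::qf(q, df2, df1)
  data.frame(icc = icc,
             ci_low = (fl - 1) / (fl + k - 1),
             ci_high = (fu - 1) / (fu + k - 1),
             f_stat = f, df1 = df1, df2 = df2, p_value = p, n_pairs = n,
             degenerate = FALSE)
}

#' Genome-wide ICC screen over a paired view
#'
#' Vectorized per-probe ICC(C,1) on raw beta values (no normalization or
#' covariate adjustment, by design: stability is assessed on the measured
#' signal). Each probe uses its complete pairs; probes with fewer than
#' `min_complete` of the maximum pair count are flagged `low_coverage` and
#' excluded from the multiplicity adjustment. Benjamini-Hochberg adjustment
#' is applied across all tested probes.
#'
#' @param view a [align_pairs()] `paired_view`.
#' @param ci_level confidence level for the ICC interval.
#' @param min_complete minimum fraction of complete pairs for a probe to
#'   enter genome-wide summaries (default 0.8).
#' @return data.frame with one row per probe: `probe_id`, `icc`, `ci_low`,
#'   `ci_high`, `f_stat`, `df1`, `df2`, `p_value`, `p_adjusted`, `n_pairs`,
#'   `stability_class`, `degenerate`, `low_coverage`.
#' @export
icc_genomewide <- function(view, ci_level = 0.95, min_complete = 0.8) {
  stopifnot(inherits(view, "paired_view"))
  t1 <- view$t1; t2 <- view$t2
  k <- 2
  ok <- !(is.na(t1) | is.na(t2))
  n <- rowSums(ok)
  if (max(n) < 3L) stop("need >= 3 complete subject pairs", call. = FALSE)
  t1[!ok] <- NA; t2[!ok] <- NA

  rowm <- (t1 + t2) / 2                       # per-subject means
  grand <- rowMeans(rowm, na.rm = TRUE)
  ss_rows <- k * rowSums((rowm - grand)^2, na.rm = TRUE)
  c1 <- rowMeans(t1, na.rm = TRUE); c2 <- rowMeans(t2, na.rm = TRUE)
  ss_cols <- n * ((c1 - grand)^2 + (c2 - grand)^2)
  ss_tot <- rowSums((t1 - grand)^2, na.rm = TRUE) +
    rowSums((t2 - grand)^2, na.rm = TRUE)
  ss_err <- pmax(ss_tot - ss_rows - ss_cols, 0)

  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  msr <- ss_rows / df1
  mse <- ss_err / df2
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  f <- msr / mse
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  q <- 1 - (1 - ci_level) / 2
  fl <- f / stats::qf(q, df1, df2)
  fu <- f * stats::qf(q, df2, df1)
  ci_low <- (fl - 1) / (fl + k - 1)
  ci_high <- (fu - 1) / (fu + k - 1)

  degenerate <- rep(FALSE, length(n))
  # zero residual with between-subject signal: perfect consistency
  perfect <- ss_tot > 0 & mse <= 1e-12 * ss_tot / (n * k) & msr > 0
  icc[perfect] <- 1; ci_low[perfect] <- 1; ci_high[perfect] <- 1
  f[perfect] <- Inf; p[perfect] <- 0; degenerate[perfect] <- TRUE
  # all-identical or too few pairs: undefined
  undef <- ss_tot <= 0 | n < 3
  icc[undef] <- NA; ci_low[undef] <- NA; ci_high[undef] <- NA
  f[undef] <- NA; p[undef] <- NA; degenerate[undef] <- TRUE

  low_coverage <- n < min_complete * max(n)
  p_for_adjust <- p
  p_for_adjust[low_coverage] <- NA
  out <- data.frame(
    probe_id = rownames(view$t1), icc = icc, ci_low = ci_low,
    ci_high = ci_high, f_stat = f, df1 = df1, df2 = df2, p_value = p,
    p_adjusted = bh_adjust(p_for_adjust), n_pairs = n,
    stability_class = classify_icc(icc), degenerate = degenerate,
    low_coverage = low_coverage, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify ICC estimates into reliability bins
#'
#' Koo-Li bins: poor (ICC < 0.5), moderate (0.5 <= ICC < 0.75),
#' good (0.75 <= ICC < 0.9), excellent (ICC >= 0.9). Negative estimates are
#' poor; `NA` stays `NA`.
#'
#' @param icc numeric vector of ICC estimates (negatives allowed).
#' @return factor with levels poor/moderate/good/excellent.
#' @export
classify_icc <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`; `NA` p-values are
#' propagated and the effective number of tests is the number of non-missing
#' values.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, original order preserved.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
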