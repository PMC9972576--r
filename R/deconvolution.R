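#' Reference-based cell-composition estimate for one sample
#'
#' Solves the constrained projection `min_w || y - R w ||^2, w >= 0`
#' (non-negative least squares, Lawson-Hanson via `pracma::lsqnonneg`) of a
#' sample's beta values over the reference CpGs onto a cell-type reference
#' panel. Raw weights are retained and also reported normalized to sum to
#' one (the conventional composition estimate).
#'
#' @param y numeric vector of beta values over the reference CpGs.
#' @param reference m x c matrix of cell-type-specific reference methylation
#'   (m CpGs >= c cell types, columns linearly independent).
#' @return list with `weights_raw`, `weights` (normalized), `residual_norm`.
#' @export
deconvolve <- function(y, reference) {
  reference <- as.matrix(reference)
  if (nrow(reference) < ncol(reference))
    stop("reference needs at least as many CpGs as cell types", call. = FALSE)
  qrr <- qr(reference)
  if (qrr$rank < ncol(reference)) {
    dep <- colnames(reference)[qrr$pivot[-seq_len(qrr$rank)]]
    stop("reference columns are collinear: ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  if (length(y) != nrow(reference))
    stop("length(y) must equal nrow(reference)", call. = FALSE)
  fit <- pracma::lsqnonneg(reference, as.numeric(y))
  w <- fit$x
  names(w) <- colnames(reference)
  s <- sum(w)
  list(weights_raw = w,
       weights = if (s > 0) w / s else w,
       residual_norm = sqrt(max(fit$resid.norm, 0)))
}

#' Cell-composition estimates for all samples of a beta matrix
#'
#' @param beta probes x samples matrix containing the reference CpGs
#'   (matched by rowname).
#' @param reference reference panel, CpGs x cell types.
#' @return data.frame with `sample_id`, one normalized-weight column per
#'   cell type, raw-weight columns (`raw_` prefix) and `residual_norm`.
#' @export
deconvolve_samples <- function(beta, reference) {
  reference <- as.matrix(reference)
  shared <- intersect(rownames(beta), rownames(reference))
  if (length(shared) < ncol(reference))
    stop("too few reference CpGs present in the beta matrix", call. = FALSE)
  R <- reference[shared, , drop = FALSE]
  B <- beta[shared, , drop = FALSE]
  ests <- lapply(seq_len(ncol(B)), function(j) deconvolve(B[, j], R))
  w <- do.call(rbind, lapply(ests, `[[`, "weights"))
  wr <- do.call(rbind, lapply(ests, `[[`, "weights_raw"))
  colnames(wr) <- paste0("raw_", colnames(R))
  out <- data.frame(sample_id = colnames(B), w, wr,
                    residual_norm = vapply(ests, `[[`, 0, "residual_norm"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare estimated cell composition between timepoints
#'
#' Per cell type, a two-sided Mann-Whitney U test of T1 versus T2
#' normalized weights, plus the paired mean difference (T2 - T1 over
#' subjects with both timepoints). A paired Wilcoxon signed-rank
#' alternative is available via `paired = TRUE`.
#'
#' @param estimates output of [deconvolve_samples()].
#' @param sheet sample sheet.
#' @param cell_types columns of `estimates` to test (default: all
#'   non-`raw_` weight columns).
#' @param paired use the paired signed-rank test instead of Mann-Whitney.
#' @return data.frame: `cell_type`, `n_t1`, `n_t2`, `statistic`, `p_value`,
#'   `mean_diff_paired`.
#' @export
compare_composition <- function(estimates, sheet, cell_types = NULL,
                                paired = FALSE) {
  m <- merge(estimates, sheet[, c("sample_id", "subject_id", "timepoint")],
             by = "sample_id")
  if (is.null(cell_types))
    cell_types <- setdiff(names(estimates),
                          c("sample_id", "residual_norm",
                            grep("^raw_", names(estimates), value = TRUE)))
  m1 <- m[m$timepoint == "T1", ]; m2 <- m[m$timepoint == "T2", ]
  if (nrow(m1) < 2L || nrow(m2) < 2L)
    stop("each timepoint needs >= 2 samples", call. = FALSE)
  common <- intersect(m1$subject_id, m2$subject_id)
  i1 <- match(common, m1$subject_id); i2 <- match(common, m2$subject_id)
  rows <- lapply(cell_types, function(ct) {
    if (paired) {
      wt <- stats::wilcox.test(m2[[ct]][i2], m1[[ct]][i1], paired = TRUE,
                               exact = FALSE)
    } else {
      wt <- stats::wilcox.test(m1[[ct]], m2[[ct]], exact = FALSE)
    }
    data.frame(cell_type = ct, n_t1 = nrow(m1), n_t2 = nrow(m2),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               mean_diff_paired = mean(m2[[ct]][i2] - m1[[ct]][i1]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
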