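#' Gap hunting: detect gap-separated clusters in a probe's beta values
#'
#' Sorts the non-missing values and cuts wherever the successive difference
#' exceeds `threshold`; the resulting runs are the groups. Two or more
#' groups constitute a gap signal, the signature of a genotype-driven probe.
#' A gap signal is `outlier_driven` when the combined size of all groups
#' except the largest is below `out_cutoff * n`; such probes are reported
#' but excluded from the predicted-GV set unless `keep_outliers` is set.
#'
#' @param beta_row numeric vector of beta values for one probe
#'   (>= `min_n` non-missing values required).
#' @param threshold minimum gap width in beta units (default 0.05).
#' @param out_cutoff outlier fraction cutoff (default 0.01).
#' @param keep_outliers keep outlier-driven probes in the predicted-GV set.
#' @param min_n minimum non-missing sample count (default 10).
#' @return one-row data.frame: `n_groups`, `group_sizes` (comma-joined),
#'   `threshold`, `is_gap_signal`, `outlier_driven`, `in_predicted_gv`,
#'   `n_used`. All-`NA` input yields an `NA` row.
#' @export
hunt_gaps <- function(beta_row, threshold = 0.05, out_cutoff = 0.01,
                      keep_outliers = FALSE, min_n = 10L) {
  stopifnot(threshold > 0, threshold < 1)
  x <- beta_row[!is.na(beta_row)]
  if (!length(x))
    return(data.frame(n_groups = NA_integer_, group_sizes = NA_character_,
                      threshold = threshold, is_gap_signal = NA,
                      outlier_driven = NA, in_predicted_gv = NA, n_used = 0L))
  if (length(x) < min_n)
    stop("gap hunting needs >= ", min_n, " non-missing values", call. = FALSE)
  sx <- sort(x)
  cuts <- which(diff(sx) > threshold)
  sizes <- diff(c(0L, cuts, length(sx)))
  n_groups <- length(sizes)
  is_gap <- n_groups >= 2L
  outlier <- is_gap && (length(sx) - max(sizes)) < out_cutoff * length(sx)
  data.frame(n_groups = n_groups,
             group_sizes = paste(sizes, collapse = ","),
             threshold = threshold, is_gap_signal = is_gap,
             outlier_driven = outlier,
             in_predicted_gv = is_gap && (keep_outliers || !outlier),
             n_used = length(sx))
}

#' Genome-wide gap scan
#'
#' Applies [hunt_gaps()] to every probe of a beta matrix. Both timepoints
#' are pooled by default (genotypes are time-invariant, so pooling doubles
#' cluster occupancy without changing the group count); restrict `samples`
#' to a single timepoint for a per-timepoint scan.
#'
#' @param beta probes x samples matrix.
#' @param threshold,out_cutoff,keep_outliers,min_n see [hunt_gaps()].
#' @param samples optional character vector of sample ids to use.
#' @return data.frame keyed by `probe_id` with the [hunt_gaps()] columns;
#'   the predicted-GV probe set is `probe_id[in_predicted_gv]`.
#' @export
gaps_genomewide <- function(beta, threshold = 0.05, out_cutoff = 0.01,
                            keep_outliers = FALSE, min_n = 10L,
                            samples = NULL) {
  if (!is.null(samples)) beta <- beta[, samples, drop = FALSE]
  rows <- lapply(seq_len(nrow(beta)), function(i)
    hunt_gaps(beta[i, ], threshold = threshold, out_cutoff = out_cutoff,
              keep_outliers = keep_outliers, min_n = min_n))
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(probe_id = rownames(beta),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
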