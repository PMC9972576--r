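#' @keywords internal
#' Infer a field delimiter from a file extension.
#' ".csv" -> comma, everything else (".tsv", ".txt") -> tab.
.infer_delim <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

.check_unique <- function(x, what) {
  dup <- unique(x[duplicated(x)])
  if (length(dup))
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  invisible(x)
}

# Case-insensitive column lookup; returns canonical-named data.frame.
.require_columns <- function(df, required, optional = character(), what = "file") {
  nm <- tolower(names(df))
  miss <- setdiff(required, nm)
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  keep <- intersect(c(required, optional), nm)
  out <- df[, match(keep, nm), drop = FALSE]
  names(out) <- keep
  out
}

#' Validate a beta-value matrix
#'
#' A beta matrix stores methylation fractions (probes as rows, samples as
#' columns). Values must be `NA` or lie in `[0, 1]`; probe and sample
#' identifiers must be unique.
#'
#' @param values numeric matrix with probe rownames and sample colnames.
#' @return the validated matrix, invisibly usable as a plain matrix.
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs probe rownames and sample colnames", call. = FALSE)
  .check_unique(rownames(values), "probe id")
  .check_unique(colnames(values), "sample id")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf("value out of range [0,1]: %g at probe '%s', sample '%s'",
                 values[bad[1L]], rownames(values)[i[1L]],
                 colnames(values)[i[2L]]), call. = FALSE)
  }
  values
}

#' Read a beta-value matrix from a delimited text file
#'
#' The first column holds CpG probe identifiers; the header row holds sample
#' identifiers. The delimiter is inferred from the extension (`.csv` comma,
#' otherwise tab) unless given explicitly.
#'
#' @param path file path.
#' @param delimiter optional field separator overriding extension-based
#'   detection.
#' @return a numeric probes x samples matrix validated by [beta_matrix()].
#' @export
read_beta_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .infer_delim(path, delimiter)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L) stop("beta matrix file needs probe ids plus >=1 sample",
                          call. = FALSE)
  probes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA" & col != "")
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                     col[bad[1L]], bad[1L], names(vals)[j]), call. = FALSE)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- probes
  beta_matrix(m)
}

#' Write a beta-value matrix
#'
#' @param beta probes x samples matrix.
#' @param path output path; delimiter inferred from extension unless given.
#' @param delimiter optional field separator.
#' @export
write_beta_matrix <- function(beta, path, delimiter = NULL) {
  beta <- beta_matrix(beta)
  sep <- .infer_delim(path, delimiter)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Required columns (case-insensitive): `sample_id`, `subject_id`,
#' `timepoint` (T1/T2), `age_years`, `sex` (F/M), `smoking`
#' (active/non-smoker), `disease` (CD/UC). Optional: `crp_mg_per_l`,
#' `leukocytes_e9_per_l`.
#'
#' @param path CSV/TSV path.
#' @param paired if `TRUE`, require each subject to appear exactly once per
#'   timepoint.
#' @return a data.frame with canonical lower-case column names.
#' @export
read_sample_sheet <- function(path, paired = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = .infer_delim(path),
                          stringsAsFactors = FALSE)
  sheet <- .require_columns(df,
    required = c("sample_id", "subject_id", "timepoint", "age_years", "sex",
                 "smoking", "disease"),
    optional = c("crp_mg_per_l", "leukocytes_e9_per_l"),
    what = "sample sheet")
  validate_sample_sheet(sheet, paired = paired)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame holding sample-sheet columns.
#' @export
validate_sample_sheet <- function(sheet, paired = FALSE) {
  .check_unique(sheet$sample_id, "sample id")
  .check_level <- function(x, allowed, what) {
    bad <- setdiff(unique(as.character(x)), allowed)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                   paste(bad, collapse = ", "),
                   paste(allowed, collapse = "/")), call. = FALSE)
  }
  .check_level(sheet$timepoint, c("T1", "T2"), "timepoint")
  .check_level(sheet$sex, c("F", "M"), "sex")
  .check_level(sheet$smoking, c("active", "non-smoker"), "smoking")
  .check_level(sheet$disease, c("CD", "UC"), "disease")
  for (col in c("crp_mg_per_l", "leukocytes_e9_per_l"))
    if (col %in% names(sheet) && any(sheet[[col]] < 0, na.rm = TRUE))
      stop(col, " must be non-negative", call. = FALSE)
  if (paired) {
    tab <- table(sheet$subject_id, sheet$timepoint)
    bad <- rownames(tab)[apply(tab, 1L, function(r) any(r != 1L))]
    if (length(bad))
      stop("subject(s) without exactly one sample per timepoint: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  sheet
}

#' Read a probe annotation table
#'
#' Required columns: `probe_id`, `chrom`, `pos` (1-based, Illumina manifest
#' convention). Optional: `gene`, `gene_region`, `is_qc_gv`, `annotated_gv`,
#' `dbsnp_id`; missing flag columns default to `FALSE`.
#'
#' @param path CSV/TSV path.
#' @return annotation data.frame.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .infer_delim(path),
                          stringsAsFactors = FALSE)
  ann <- .require_columns(df,
    required = c("probe_id", "chrom", "pos"),
    optional = c("gene", "gene_region", "is_qc_gv", "annotated_gv",
                 "dbsnp_id"),
    what = "probe annotation")
  .check_unique(ann$probe_id, "probe id")
  if (any(ann$pos < 1, na.rm = TRUE))
    stop("annotation positions are 1-based; found pos < 1", call. = FALSE)
  for (flag in c("is_qc_gv", "annotated_gv")) {
    if (!flag %in% names(ann)) ann[[flag]] <- FALSE
    ann[[flag]] <- as.logical(ann[[flag]])
  }
  if (!"gene" %in% names(ann)) ann$gene <- NA_character_
  ann
}

#' Read a variant table
#'
#' CSV format requires columns `variant_id`, `chrom`, `pos` (1-based),
#' `phenotype`. BED-like TSV input (`format = "bed"`: chrom, start, end,
#' variant_id, optional phenotype) is converted from 0-based half-open to
#' 1-based positions (`pos = start + 1`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"bed"`.
#' @return data.frame with `variant_id`, `chrom`, `pos`, `phenotype`.
#' @export
read_variant_table <- function(path, format = c("auto", "csv", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "bed") "bed" else "csv"
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED-like variant file needs >= 4 columns",
                            call. = FALSE)
    out <- data.frame(variant_id = as.character(df[[4L]]),
                      chrom = as.character(df[[1L]]),
                      pos = as.integer(df[[2L]]) + 1L,
                      phenotype = if (ncol(df) >= 5L) as.character(df[[5L]])
                                  else NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = .infer_delim(path),
                            stringsAsFactors = FALSE)
    out <- .require_columns(df,
      required = c("variant_id", "chrom", "pos"),
      optional = "phenotype", what = "variant table")
    if (!"phenotype" %in% names(out)) out$phenotype <- NA_character_
  }
  if (any(out$pos < 1, na.rm = TRUE))
    stop("variant positions are 1-based; found pos < 1", call. = FALSE)
  out
}

#' Read CpG or gene sets
#'
#' Supports GMT (one set per line: name, description, members...) and long
#' two-column format (`set_name`, `member`). Members are de-duplicated
#' within each set.
#'
#' @param path file path; `.gmt` extension selects GMT parsing.
#' @param format `"auto"`, `"long"` or `"gmt"`.
#' @return a named list of character vectors.
#' @export
read_sets <- function(path, format = c("auto", "long", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "gmt") "gmt" else "long"
  if (format == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      if (length(f) < 3L)
        stop("GMT line needs name, description and >=1 member", call. = FALSE)
      unique(f[-(1:2)])
    })
    names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = .infer_delim(path),
                            stringsAsFactors = FALSE)
    df <- .require_columns(df, required = c("set_name", "member"),
                           what = "set file")
    sets <- lapply(split(df$member, df$set_name), unique)
  }
  .check_unique(names(sets), "set name")
  sets
}

#' Align paired samples across two time points
#'
#' Builds a paired view of the beta matrix: one T1 and one T2 column per
#' subject, subjects sorted by `subject_id` so the result is invariant to
#' input row/column order. Subjects missing either timepoint in the matrix
#' are dropped with a warning and returned in `$excluded`.
#'
#' @param beta probes x samples matrix.
#' @param sheet sample sheet data.frame (see [read_sample_sheet()]).
#' @return an object of class `paired_view`: list with probes x subjects
#'   matrices `t1` and `t2`, `subjects`, `sample_ids` (2-column matrix) and
#'   `excluded`.
#' @export
align_pairs <- function(beta, sheet) {
  beta <- beta_matrix(beta)
  sheet <- sheet[sheet$sample_id %in% colnames(beta), , drop = FALSE]
  s1 <- sheet[sheet$timepoint == "T1", ]
  s2 <- sheet[sheet$timepoint == "T2", ]
  subjects <- sort(intersect(s1$subject_id, s2$subject_id))
  excluded <- sort(setdiff(unique(sheet$subject_id), subjects))
  if (!length(subjects))
    stop("no subject has complete T1/T2 samples in the beta matrix",
         call. = FALSE)
  if (length(excluded))
    warning("dropping ", length(excluded),
            " subject(s) missing a timepoint: ",
            paste(utils::head(excluded, 5L), collapse = ", "), call. = FALSE)
  id1 <- s1$sample_id[match(subjects, s1$subject_id)]
  id2 <- s2$sample_id[match(subjects, s2$subject_id)]
  structure(list(
    t1 = beta[, id1, drop = FALSE],
    t2 = beta[, id2, drop = FALSE],
    subjects = subjects,
    sample_ids = cbind(T1 = id1, T2 = id2),
    excluded = excluded
  ), class = "paired_view")
}

#' @export
print.paired_view <- function(x, ...) {
  cat("paired_view:", nrow(x$t1), "probes x", length(x$subjects),
      "subject pairs (", length(x$excluded), "excluded )\n")
  invisible(x)
}
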