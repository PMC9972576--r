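# Independent oracles and fixture builders used across the suite.

# Brute-force ICC(C,1) from a full two-way ANOVA fit (subject + occasion),
# computed through stats::anova rather than the package's closed form.
oracle_icc <- function(pairs) {
  n <- nrow(pairs); k <- ncol(pairs)
  df <- data.frame(y = as.vector(pairs),
                   subject = factor(rep(seq_len(n), k)),
                   occasion = factor(rep(seq_len(k), each = n)))
  av <- stats::anova(stats::lm(y ~ subject + occasion, data = df))
  msr <- av["subject", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  f <- msr / mse
  list(icc = (msr - mse) / (msr + (k - 1) * mse), f = f,
       p = stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE))
}

# Random small beta matrix with probe/sample names.
random_beta <- function(nprobe, nsamp, prefix = "cg") {
  m <- matrix(round(stats::runif(nprobe * nsamp), 6), nprobe, nsamp)
  rownames(m) <- sprintf("%s%05d", prefix, seq_len(nprobe))
  colnames(m) <- sprintf("S%03d", seq_len(nsamp))
  m
}

# Minimal valid sample sheet for n subjects x 2 timepoints.
toy_sheet <- function(n, sample_ids = NULL) {
  subjects <- sprintf("SUBJ%02d", seq_len(n))
  sheet <- data.frame(
    sample_id = c(paste0(subjects, "_T1"), paste0(subjects, "_T2")),
    subject_id = rep(subjects, 2L),
    timepoint = rep(c("T1", "T2"), each = n),
    age_years = rep(40 + seq_len(n), 2L),
    sex = rep(rep_len(c("F", "M"), n), 2L),
    smoking = rep(rep_len(c("non-smoker", "non-smoker", "active"), n), 2L),
    disease = rep(rep_len(c("CD", "CD", "CD", "UC"), n), 2L),
    crp_mg_per_l = stats::rlnorm(2L * n, log(3), 0.5),
    leukocytes_e9_per_l = stats::rlnorm(2L * n, log(7), 0.2),
    stringsAsFactors = FALSE)
  if (!is.null(sample_ids)) sheet$sample_id <- sample_ids
  sheet
}

# Paired view directly from two probe x subject matrices.
toy_view <- function(t1, t2) {
  if (is.null(rownames(t1)))
    rownames(t1) <- rownames(t2) <- sprintf("cg%05d", seq_len(nrow(t1)))
  subjects <- sprintf("SUBJ%02d", seq_len(ncol(t1)))
  colnames(t1) <- paste0(subjects, "_T1")
  colnames(t2) <- paste0(subjects, "_T2")
  structure(list(t1 = t1, t2 = t2, subjects = subjects,
                 sample_ids = cbind(T1 = colnames(t1), T2 = colnames(t2)),
                 excluded = character(0)),
            class = "paired_view")
}
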