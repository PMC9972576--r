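#' Configuration for the synthetic paired-cohort generator
#'
#' Defaults emulate a two-timepoint adult IBD cohort on an EPIC-like array:
#' 46 subjects sampled twice with a uniform integer 2-9 year interval,
#' variance-component probes at four true-ICC levels, Hardy-Weinberg
#' trimodal genotype probes, age-drift probes hypomethylating at T2, and
#' cell-composition-driven probes tied to a six-leukocyte reference panel.
#'
#' @param n_subjects number of subjects (each contributes a T1 and T2 sample).
#' @param n_probes named counts per probe class:
#'   `variance_component`, `snp_trimodal`, `age_drift`, `cell_driven`.
#' @param n_qc_gv number of quality-control genotype probes (trimodal,
#'   flagged `is_qc_gv`).
#' @param icc_levels true ICC levels for variance-component probes (split
#'   evenly across levels).
#' @param vc_total_sd total (between + within) latent sd of a
#'   variance-component probe on the beta scale.
#' @param maf minor-allele frequency for genotype probes; a length-2 vector
#'   gives a uniform range to draw per-probe MAFs from.
#' @param cluster_means genotype cluster beta means (hom-ref, het, hom-alt).
#' @param cluster_sd within-genotype-cluster sd.
#' @param drift_per_year methylation drift per year at T2 for age-drift
#'   probes (negative = hypomethylation over time).
#' @param drift_icc_base latent ICC of the stable component of drift probes.
#' @param noise_sd measurement noise sd for genotype, drift and cell probes.
#' @param cell_types cell-type labels of the reference panel.
#' @param dirichlet_alpha Dirichlet concentration per cell type for T1
#'   weights (scaled so the mean reflects typical adult leukocyte fractions).
#' @param cell_shift additive T2 shift of mean cell weights (same order as
#'   `cell_types`; must sum to ~0).
#' @param reference_high,reference_low methylation level of the
#'   discriminating vs background cell type at a reference CpG (separation
#'   `reference_high - reference_low` >= 0.3 enforced).
#' @param interval_years_range inclusive integer range of the T1->T2
#'   sampling interval in years.
#' @param seed optional RNG seed recorded in the output metadata.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 46,
                       n_probes = c(variance_component = 4000,
                                    snp_trimodal = 500,
                                    age_drift = 500,
                                    cell_driven = 300),
                       n_qc_gv = 59,
                       icc_levels = c(0.2, 0.5, 0.8, 0.95),
                       vc_total_sd = 0.05,
                       maf = c(0.2, 0.5),
                       cluster_means = c(0.05, 0.5, 0.95),
                       cluster_sd = 0.02,
                       drift_per_year = -0.003,
                       drift_icc_base = 0.5,
                       noise_sd = 0.02,
                       cell_types = c("B", "CD4T", "CD8T", "NK", "Mono",
                                      "Neu"),
                       dirichlet_alpha = 25 * c(0.06, 0.16, 0.10, 0.06,
                                                0.08, 0.54),
                       cell_shift = c(0.025, 0.025, 0, 0, 0, -0.05),
                       reference_high = 0.85,
                       reference_low = 0.15,
                       interval_years_range = c(2L, 9L),
                       seed = NULL) {
  cfg <- list(n_subjects = n_subjects, n_probes = n_probes,
              n_qc_gv = n_qc_gv, icc_levels = icc_levels,
              vc_total_sd = vc_total_sd, maf = maf,
              cluster_means = cluster_means, cluster_sd = cluster_sd,
              drift_per_year = drift_per_year,
              drift_icc_base = drift_icc_base, noise_sd = noise_sd,
              cell_types = cell_types, dirichlet_alpha = dirichlet_alpha,
              cell_shift = cell_shift, reference_high = reference_high,
              reference_low = reference_low,
              interval_years_range = as.integer(interval_years_range),
              seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(config$n_subjects >= 2, all(config$n_probes >= 0),
            config$n_qc_gv >= 0)
  need <- c("variance_component", "snp_trimodal", "age_drift", "cell_driven")
  if (!all(need %in% names(config$n_probes)))
    stop("n_probes needs counts for: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(config$icc_levels < 0 | config$icc_levels > 1))
    stop("infeasible config: true ICC levels must lie in [0, 1]",
         call. = FALSE)
  if (any(config$maf < 0 | config$maf > 0.5))
    stop("minor-allele frequency must lie in [0, 0.5]", call. = FALSE)
  if (config$reference_high - config$reference_low < 0.3)
    stop("reference cell-type means must be separated by >= 0.3",
         call. = FALSE)
  if (abs(sum(config$cell_shift)) > 1e-8)
    stop("cell_shift must sum to 0", call. = FALSE)
  if (length(config$dirichlet_alpha) != length(config$cell_types) ||
      length(config$cell_shift) != length(config$cell_types))
    stop("dirichlet_alpha and cell_shift must match cell_types", call. = FALSE)
  config
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

.clip_beta <- function(x) pmin(pmax(x, 0.001), 0.999)

#' Simulate a paired EPIC-like cohort with known ground truth
#'
#' Generates a beta matrix, sample sheet, probe annotation, cell-type
#' reference panel and truth tables per [sim_config()]. Variance-component
#' probes follow a latent Gaussian subject + error model
#' (ICC = sigma2_subject / (sigma2_subject + sigma2_error)) clipped to
#' `[0.001, 0.999]`; genotype probes draw a per-subject genotype from
#' Hardy-Weinberg proportions that is constant across timepoints; age-drift
#' probes add `drift_per_year * interval` at T2; cell-driven probes are
#' reference-panel mixtures of per-sample Dirichlet weights, with T2 weights
#' shifted by `cell_shift`.
#'
#' @param config a [sim_config()] object.
#' @param seed optional seed overriding `config$seed`.
#' @return list with `beta`, `sheet`, `annotation`, `reference`, `truth`
#'   (probe table, genotype matrix, cell-weight matrix, clip fraction) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  subjects <- sprintf("S%03d", seq_len(n))

  ## --- sample sheet -------------------------------------------------------
  interval <- sample(seq(config$interval_years_range[1L],
                         config$interval_years_range[2L]), n, replace = TRUE)
  age_t1 <- round(pmin(pmax(stats::rnorm(n, 44, 15), 18), 80))
  sex <- sample(rep_len(c("F", "M"), n))
  smoking <- ifelse(stats::runif(n) < 0.24, "active", "non-smoker")
  disease <- ifelse(stats::runif(n) < 36 / 46, "CD", "UC")
  crp <- function() round(stats::rlnorm(n, log(2.6), 0.8), 1)
  leu <- function() round(stats::rlnorm(n, log(7), 0.25), 1)
  sheet <- rbind(
    data.frame(sample_id = paste0(subjects, "_T1"), subject_id = subjects,
               timepoint = "T1", age_years = age_t1, sex = sex,
               smoking = smoking, disease = disease, crp_mg_per_l = crp(),
               leukocytes_e9_per_l = leu(), stringsAsFactors = FALSE),
    data.frame(sample_id = paste0(subjects, "_T2"), subject_id = subjects,
               timepoint = "T2", age_years = age_t1 + interval, sex = sex,
               smoking = smoking, disease = disease, crp_mg_per_l = crp(),
               leukocytes_e9_per_l = leu(), stringsAsFactors = FALSE))

  np <- config$n_probes
  blocks <- list(); truth_rows <- list()

  ## --- variance-component probes -----------------------------------------
  if (np[["variance_component"]] > 0) {
    counts <- diff(round(seq(0, np[["variance_component"]],
                             length.out = length(config$icc_levels) + 1L)))
    icc_true <- rep(config$icc_levels, counts)
    m <- length(icc_true)
    ids <- sprintf("cgVC%06d", seq_len(m))
    mu <- stats::runif(m, 0.15, 0.85)
    sd_b <- config$vc_total_sd * sqrt(icc_true)
    sd_e <- config$vc_total_sd * sqrt(1 - icc_true)
    b <- matrix(stats::rnorm(m * n), m, n) * sd_b
    lat <- mu + b
    y1 <- lat + matrix(stats::rnorm(m * n), m, n) * sd_e
    y2 <- lat + matrix(stats::rnorm(m * n), m, n) * sd_e
    blocks$vc <- list(ids = ids, t1 = y1, t2 = y2)
    truth_rows$vc <- data.frame(probe_id = ids, class = "variance_component",
                                true_icc = icc_true, slope = 0, maf = NA_real_,
                                stringsAsFactors = FALSE)
  }

  ## --- genotype (trimodal HWE) probes, incl. QC-GV ------------------------
  geno_mat <- NULL
  sim_geno <- function(m, prefix) {
    ids <- sprintf("cg%s%06d", prefix, seq_len(m))
    maf <- if (length(config$maf) == 2L)
      stats::runif(m, config$maf[1L], config$maf[2L]) else rep(config$maf, m)
    g <- matrix(stats::rbinom(m * n, 2L, rep(maf, n)), m, n)
    mean_g <- matrix(config$cluster_means[g + 1L], m, n)
    y1 <- mean_g + matrix(stats::rnorm(m * n, sd = config$cluster_sd), m, n)
    y2 <- mean_g + matrix(stats::rnorm(m * n, sd = config$cluster_sd), m, n)
    rownames(g) <- ids; colnames(g) <- subjects
    list(ids = ids, t1 = y1, t2 = y2, g = g, maf = maf)
  }
  if (np[["snp_trimodal"]] > 0) {
    sg <- sim_geno(np[["snp_trimodal"]], "SNP")
    blocks$snp <- sg[c("ids", "t1", "t2")]
    geno_mat <- sg$g
    truth_rows$snp <- data.frame(probe_id = sg$ids, class = "snp_trimodal",
                                 true_icc = NA_real_, slope = 0, maf = sg$maf,
                                 stringsAsFactors = FALSE)
  }
  if (config$n_qc_gv > 0) {
    qg <- sim_geno(config$n_qc_gv, "QC")
    blocks$qc <- qg[c("ids", "t1", "t2")]
    geno_mat <- rbind(geno_mat, qg$g)
    truth_rows$qc <- data.frame(probe_id = qg$ids, class = "qc_gv",
                                true_icc = NA_real_, slope = 0, maf = qg$maf,
                                stringsAsFactors = FALSE)
  }

  ## --- age-drift probes ---------------------------------------------------
  if (np[["age_drift"]] > 0) {
    m <- np[["age_drift"]]
    ids <- sprintf("cgAGE%06d", seq_len(m))
    mu <- stats::runif(m, 0.15, 0.85)
    sd_b <- config$vc_total_sd * sqrt(config$drift_icc_base)
    sd_e <- config$vc_total_sd * sqrt(1 - config$drift_icc_base)
    b <- matrix(stats::rnorm(m * n, sd = sd_b), m, n)
    drift <- config$drift_per_year *
      matrix(interval, m, n, byrow = TRUE)
    y1 <- mu + b + matrix(stats::rnorm(m * n, sd = sd_e), m, n)
    y2 <- mu + b + drift + matrix(stats::rnorm(m * n, sd = sd_e), m, n)
    blocks$age <- list(ids = ids, t1 = y1, t2 = y2)
    truth_rows$age <- data.frame(probe_id = ids, class = "age_drift",
                                 true_icc = NA_real_,
                                 slope = config$drift_per_year,
                                 maf = NA_real_, stringsAsFactors = FALSE)
  }

  ## --- cell-driven probes + reference panel -------------------------------
  reference <- NULL; weights <- NULL
  if (np[["cell_driven"]] > 0) {
    m <- np[["cell_driven"]]
    ct <- config$cell_types; C <- length(ct)
    ids <- sprintf("cgCELL%06d", seq_len(m))
    reference <- matrix(config$reference_low, m, C,
                        dimnames = list(ids, ct))
    reference[cbind(seq_len(m), rep_len(seq_len(C), m))] <-
      config$reference_high
    w1 <- .rdirichlet(n, config$dirichlet_alpha)
    w2 <- w1 + matrix(config$cell_shift, n, C, byrow = TRUE)
    w2 <- pmax(w2, 0); w2 <- w2 / rowSums(w2)
    colnames(w1) <- colnames(w2) <- ct
    rownames(w1) <- paste0(subjects, "_T1")
    rownames(w2) <- paste0(subjects, "_T2")
    y1 <- reference %*% t(w1) +
      matrix(stats::rnorm(m * n, sd = config$noise_sd), m, n)
    y2 <- reference %*% t(w2) +
      matrix(stats::rnorm(m * n, sd = config$noise_sd), m, n)
    blocks$cell <- list(ids = ids, t1 = y1, t2 = y2)
    weights <- rbind(w1, w2)
    truth_rows$cell <- data.frame(probe_id = ids, class = "cell_driven",
                                  true_icc = NA_real_, slope = 0,
                                  maf = NA_real_, stringsAsFactors = FALSE)
  }

  ## --- assemble beta matrix ----------------------------------------------
  ids <- unlist(lapply(blocks, `[[`, "ids"), use.names = FALSE)
  raw <- cbind(do.call(rbind, lapply(blocks, `[[`, "t1")),
               do.call(rbind, lapply(blocks, `[[`, "t2")))
  clip_fraction <- mean(raw < 0.001 | raw > 0.999)
  beta <- .clip_beta(raw)
  dimnames(beta) <- list(ids, c(paste0(subjects, "_T1"),
                                paste0(subjects, "_T2")))

  truth_probes <- do.call(rbind, truth_rows)
  rownames(truth_probes) <- NULL

  ## --- annotation: genes with variable probe counts, sequential loci ------
  m_all <- length(ids)
  gene_sizes <- integer(0)
  while (sum(gene_sizes) < m_all)
    gene_sizes <- c(gene_sizes, sample(1:10, 50, replace = TRUE))
  gene_sizes <- gene_sizes[cumsum(gene_sizes) <= m_all]
  if (sum(gene_sizes) < m_all)
    gene_sizes <- c(gene_sizes, m_all - sum(gene_sizes))
  genes <- rep(sprintf("GENE%04d", seq_along(gene_sizes)), gene_sizes)
  chrom <- paste0("chr", rep_len(1:22, m_all))
  pos <- 10000L + 5000L * (seq_len(m_all) - 1L) %/% 22L
  is_qc <- truth_probes$class == "qc_gv"
  # half of the non-QC genotype probes carry a dbSNP annotation; the rest
  # are only discoverable through gap hunting
  annotated <- rep(FALSE, m_all)
  snp_idx <- which(truth_probes$class == "snp_trimodal")
  if (length(snp_idx))
    annotated[snp_idx[seq_len(floor(length(snp_idx) / 2))]] <- TRUE
  annotation <- data.frame(
    probe_id = ids, chrom = chrom, pos = pos, gene = genes,
    gene_region = sample(c("TSS1500", "TSS200", "body", "5'UTR"), m_all,
                         replace = TRUE),
    is_qc_gv = is_qc, annotated_gv = annotated,
    dbsnp_id = ifelse(annotated, sprintf("rs%07d", seq_len(m_all)),
                      NA_character_),
    stringsAsFactors = FALSE)

  list(beta = beta_matrix(beta),
       sheet = validate_sample_sheet(sheet, paired = TRUE),
       annotation = annotation,
       reference = reference,
       truth = list(probes = truth_probes, genotypes = geno_mat,
                    cell_weights = weights, clip_fraction = clip_fraction,
                    seed = config$seed),
       config = config)
}

#' Write / read truth tables
#'
#' Persists the generator's ground truth as plain CSV files
#' (`truth_probes.csv`, `truth_genotypes.csv`, `truth_cell_weights.csv`)
#' keyed by probe and sample id.
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly (for `write_truth`); a truth list (`read_truth`).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$probes, file.path(dir, "truth_probes.csv"),
                   row.names = FALSE)
  if (!is.null(truth$genotypes))
    utils::write.csv(data.frame(probe_id = rownames(truth$genotypes),
                                truth$genotypes, check.names = FALSE),
                     file.path(dir, "truth_genotypes.csv"), row.names = FALSE)
  if (!is.null(truth$cell_weights))
    utils::write.csv(data.frame(sample_id = rownames(truth$cell_weights),
                                truth$cell_weights, check.names = FALSE),
                     file.path(dir, "truth_cell_weights.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  out <- list(probes = utils::read.csv(file.path(dir, "truth_probes.csv"),
                                       stringsAsFactors = FALSE))
  gp <- file.path(dir, "truth_genotypes.csv")
  if (file.exists(gp)) {
    g <- utils::read.csv(gp, check.names = FALSE, stringsAsFactors = FALSE)
    out$genotypes <- as.matrix(g[, -1L, drop = FALSE])
    rownames(out$genotypes) <- g[[1L]]
  }
  wp <- file.path(dir, "truth_cell_weights.csv")
  if (file.exists(wp)) {
    w <- utils::read.csv(wp, check.names = FALSE, stringsAsFactors = FALSE)
    out$cell_weights <- as.matrix(w[, -1L, drop = FALSE])
    rownames(out$cell_weights) <- w[[1L]]
  }
  out
}
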