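#' Assign mutually exclusive probe classes
#'
#' Precedence `qc_gv > annotated_gv > predicted_gv > methylation`:
#' quality-control genotype probes first, then probes annotated to bind a
#' genetic variant, then probes whose beta distribution shows a gap signal
#' (predicted GV), and finally plain methylation probes with no evidence of
#' genetic-variant binding.
#'
#' @param annotation probe annotation with `is_qc_gv` / `annotated_gv`.
#' @param gaps [gaps_genomewide()] output (every gap probe must be
#'   annotated).
#' @return data.frame `probe_id`, `class` (factor with the four levels).
#' @export
assign_probe_classes <- function(annotation, gaps) {
  missing <- setdiff(gaps$probe_id, annotation$probe_id)
  if (length(missing))
    stop("gap-scan probe(s) absent from annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  predicted <- gaps$probe_id[!is.na(gaps$in_predicted_gv) &
                               gaps$in_predicted_gv]
  cls <- rep("methylation", nrow(annotation))
  cls[annotation$probe_id %in% predicted] <- "predicted_gv"
  cls[annotation$annotated_gv] <- "annotated_gv"
  cls[annotation$is_qc_gv] <- "qc_gv"
  data.frame(probe_id = annotation$probe_id,
             class = factor(cls, levels = c("qc_gv", "annotated_gv",
                                            "predicted_gv", "methylation")),
             stringsAsFactors = FALSE)
}

#' Call stable and hyper-stable methylated positions
#'
#' A stably methylated position (SMP) has ICC >= `smp_icc` with a
#' BH-significant ICC test; a hyper-stable methylated position (HSMP) is an
#' SMP with ICC >= `hsmp_icc` and no genetic-variant evidence
#' (class `methylation`). Also returns the probe-class x reliability-bin
#' census crosstab.
#'
#' @param icc_table [icc_genomewide()] output.
#' @param classes [assign_probe_classes()] output.
#' @param smp_icc ICC threshold for SMPs (default 0.75).
#' @param hsmp_icc ICC threshold for HSMPs (default 0.9).
#' @param alpha significance level on the BH-adjusted ICC p-value.
#' @return list: `calls` (per-probe `stability_class`, `is_smp`, `is_hsmp`),
#'   `crosstab` (4 classes x 4 bins), `proportions`.
#' @export
call_stability <- function(icc_table, classes, smp_icc = 0.75,
                           hsmp_icc = 0.9, alpha = 0.05) {
  m <- merge(icc_table, classes, by = "probe_id", sort = FALSE)
  if (nrow(m) != nrow(icc_table))
    stop("icc table and classes must be keyed identically", call. = FALSE)
  sig <- !is.na(m$p_adjusted) & m$p_adjusted < alpha
  m$is_smp <- !is.na(m$icc) & m$icc >= smp_icc & sig
  m$is_hsmp <- m$is_smp & m$icc >= hsmp_icc & m$class == "methylation"
  crosstab <- table(class = m$class, stability = m$stability_class)
  list(calls = m[, c("probe_id", "class", "icc", "p_adjusted",
                     "stability_class", "is_smp", "is_hsmp")],
       crosstab = crosstab,
       proportions = prop.table(crosstab))
}

#' Interrogate a CpG list against the stability and time results
#'
#' Joins the supplied CpG ids (e.g. published disease-associated DMP lists)
#' with the ICC screen, probe classes and optional differential-methylation
#' results, and summarizes the reliability-class breakdown.
#'
#' @param cpg_ids character vector of CpG ids.
#' @param icc_table [icc_genomewide()] output.
#' @param classes optional [assign_probe_classes()] output.
#' @param dm_table optional [call_dmps()] output.
#' @return list: `report` (one row per found probe), `class_proportions`
#'   (sums to 1 over non-`NA` classes), `n_missing`.
#' @export
interrogate_cpg_list <- function(cpg_ids, icc_table, classes = NULL,
                                 dm_table = NULL) {
  cpg_ids <- unique(cpg_ids)
  found <- intersect(cpg_ids, icc_table$probe_id)
  if (!length(found))
    stop("none of the supplied CpGs are in the tested universe",
         call. = FALSE)
  if (length(found) < length(cpg_ids))
    warning(length(cpg_ids) - length(found),
            " CpG(s) not in the tested universe", call. = FALSE)
  rep <- icc_table[match(found, icc_table$probe_id), ]
  if (!is.null(classes))
    rep$class <- classes$class[match(found, classes$probe_id)]
  if (!is.null(dm_table)) {
    idx <- match(found, dm_table$probe_id)
    rep$delta_beta <- dm_table$delta_beta[idx]
    rep$dm_p_adjusted <- dm_table$p_adjusted[idx]
    rep$is_dmp <- dm_table$is_dmp[idx]
  }
  tab <- table(rep$stability_class)
  list(report = rep,
       class_proportions = tab / sum(tab),
       n_missing = length(cpg_ids) - length(found))
}

# strip a leading "chr" so chr6 and 6 compare equal
.norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Annotate probes with the distance to the nearest variant
#'
#' For each probe, the minimum `|probe_pos - variant_pos|` over variants on
#' the same chromosome (both coordinates 1-based inclusive). Probes within
#' strictly less than `window` bases of a variant are flagged; probes on
#' variant-free chromosomes get `NA`. When two variants are equidistant the
#' one at the smaller coordinate is reported. Mixed chromosome-name styles
#' (`chr1` vs `1`) are normalized with a warning.
#'
#' @param annotation probe annotation.
#' @param variants variant table ([read_variant_table()]).
#' @param window flag distance in bases (default 1000, strict `<`).
#' @return data.frame: `probe_id`, `chrom`, `pos`, `nearest_variant`,
#'   `distance`, `within_window`.
#' @export
annotate_gv_vicinity <- function(annotation, variants, window = 1000) {
  pc <- .norm_chrom(annotation$chrom)
  vc <- .norm_chrom(variants$chrom)
  if (xor(any(grepl("^chr", annotation$chrom)),
          any(grepl("^chr", variants$chrom))))
    warning("chromosome naming styles differ; normalizing 'chr' prefixes",
            call. = FALSE)
  dist <- rep(NA_real_, nrow(annotation))
  nearest <- rep(NA_character_, nrow(annotation))
  for (ch in unique(pc)) {
    vi <- which(vc == ch)
    if (!length(vi)) next
    ord <- vi[order(variants$pos[vi], variants$variant_id[vi])]
    vpos <- variants$pos[ord]
    pi <- which(pc == ch)
    idx <- findInterval(annotation$pos[pi], vpos)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(vpos))
    dlo <- abs(annotation$pos[pi] - vpos[lo])
    dhi <- abs(annotation$pos[pi] - vpos[hi])
    # tie -> smaller coordinate, i.e. the left neighbor
    use_lo <- dlo <= dhi
    dist[pi] <- ifelse(use_lo, dlo, dhi)
    nearest[pi] <- variants$variant_id[ifelse(use_lo, ord[lo], ord[hi])]
  }
  data.frame(probe_id = annotation$probe_id, chrom = annotation$chrom,
             pos = annotation$pos, nearest_variant = nearest,
             distance = dist,
             within_window = !is.na(dist) & dist < window,
             stringsAsFactors = FALSE)
}

#' Paired comparison of clinical markers between timepoints
#'
#' Wilcoxon signed-rank tests of CRP and leukocyte count, T2 versus T1,
#' paired by subject. Pairs with zero difference are discarded by the
#' standard signed-rank convention; when every difference is zero the test
#' is reported as p = 1. With fewer than 6 complete pairs the exact test is
#' used with a warning.
#'
#' @param sheet sample sheet with `crp_mg_per_l` / `leukocytes_e9_per_l`.
#' @return data.frame: `variable`, `n_pairs`, `mean_diff`, `statistic`,
#'   `p_value`.
#' @export
clinical_compare <- function(sheet) {
  vars <- intersect(c("crp_mg_per_l", "leukocytes_e9_per_l"), names(sheet))
  if (!length(vars))
    stop("sample sheet has no clinical columns to compare", call. = FALSE)
  s1 <- sheet[sheet$timepoint == "T1", ]
  s2 <- sheet[sheet$timepoint == "T2", ]
  common <- intersect(s1$subject_id, s2$subject_id)
  rows <- lapply(vars, function(v) {
    x1 <- s1[[v]][match(common, s1$subject_id)]
    x2 <- s2[[v]][match(common, s2$subject_id)]
    ok <- !is.na(x1) & !is.na(x2)
    x1 <- x1[ok]; x2 <- x2[ok]
    n <- sum(ok)
    if (n < 2L) stop("need >= 2 complete pairs for ", v, call. = FALSE)
    exact <- FALSE
    if (n < 6L) {
      warning("fewer than 6 complete pairs for ", v, "; using exact test",
              call. = FALSE)
      exact <- TRUE
    }
    if (all(x2 == x1)) {
      stat <- 0; p <- 1  # all differences zero: no evidence of a shift
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(x2, x1, paired = TRUE, exact = exact))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(variable = v, n_pairs = n, mean_diff = mean(x2 - x1),
               statistic = stat, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full stability analysis pipeline
#'
#' Orchestrates: pairing, genome-wide ICC screen, gap scan, cell
#' deconvolution and composition comparison, covariate-adjusted moderated
#' differential methylation, CpG-set rank tests, probe-class assignment and
#' SMP/HSMP census, CpG-list interrogation, variant-vicinity annotation and
#' clinical comparisons. Either supply the inputs, or a [sim_config()] to
#' run on a simulated cohort. Deterministic given `seed`.
#'
#' @param beta,sheet,annotation,reference,variants pipeline inputs (see the
#'   reader functions); `reference` and `variants` optional.
#' @param cpg_sets optional named list of CpG-id sets for the rank test;
#'   when simulating and none are given, the generator's age-drift probes
#'   are used as the known age-associated set.
#' @param interrogate_sets optional named list of CpG-id lists to
#'   interrogate against the ICC/DM results.
#' @param sim_config optional [sim_config()]; generates all inputs.
#' @param seed RNG seed (simulation and any resampling).
#' @param out_dir optional output directory; when given, all stage tables
#'   are written as TSV plus a deterministic `summary.json`.
#' @param smp_icc,hsmp_icc,alpha stability-call parameters.
#' @param gap_threshold,gap_out_cutoff gap-scan parameters.
#' @param verbose log stage progress via `message()`.
#' @return (invisibly) a list with every stage result and the `summary`
#'   list.
#' @export
run_pipeline <- function(beta = NULL, sheet = NULL, annotation = NULL,
                         reference = NULL, variants = NULL,
                         cpg_sets = NULL, interrogate_sets = NULL,
                         sim_config = NULL, seed = NULL, out_dir = NULL,
                         smp_icc = 0.75, hsmp_icc = 0.9, alpha = 0.05,
                         gap_threshold = 0.05, gap_out_cutoff = 0.01,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[methylstab] ", ...)
  truth <- NULL
  if (!is.null(sim_config)) {
    say("simulating cohort")
    sim <- simulate_cohort(sim_config, seed = seed)
    beta <- sim$beta; sheet <- sim$sheet; annotation <- sim$annotation
    reference <- sim$reference; truth <- sim$truth
    if (is.null(cpg_sets)) {
      drift <- truth$probes$probe_id[truth$probes$class == "age_drift"]
      if (length(drift)) cpg_sets <- list(age_clock = drift)
    }
  } else if (!is.null(seed)) set.seed(seed)
  if (is.null(beta) || is.null(sheet) || is.null(annotation))
    stop("beta, sheet and annotation are required (or sim_config)",
         call. = FALSE)

  say("aligning pairs")
  view <- align_pairs(beta, sheet)

  say("ICC screen: ", nrow(beta), " probes x ", length(view$subjects),
      " pairs")
  icc <- icc_genomewide(view)

  say("gap scan")
  gaps <- gaps_genomewide(beta, threshold = gap_threshold,
                          out_cutoff = gap_out_cutoff)

  cells <- NULL; composition <- NULL
  if (!is.null(reference)) {
    say("cell deconvolution")
    cells <- deconvolve_samples(beta, reference)
    composition <- compare_composition(cells, sheet)
  }

  say("differential methylation")
  design <- build_design(sheet, cells = cells)
  fit <- fit_probes(beta, design)
  moderated <- moderate_fit(fit)
  dmps <- call_dmps(moderated, view, p_threshold = alpha)

  set_tests <- NULL
  if (!is.null(cpg_sets)) {
    say("CpG-set rank tests")
    stats_vec <- stats::setNames(moderated$t_mod, moderated$probe_id)
    stats_vec <- stats_vec[!is.na(stats_vec)]
    set_tests <- do.call(rbind, lapply(names(cpg_sets), function(nm) {
      cbind(set_name = nm,
            set_rank_test(stats_vec, cpg_sets[[nm]], alternative = "mixed"))
    }))
  }

  say("probe classes and stability census")
  classes <- assign_probe_classes(annotation, gaps)
  stability <- call_stability(icc, classes, smp_icc = smp_icc,
                              hsmp_icc = hsmp_icc, alpha = alpha)

  interrogation <- NULL
  if (!is.null(interrogate_sets))
    interrogation <- lapply(interrogate_sets, interrogate_cpg_list,
                            icc_table = icc, classes = classes,
                            dm_table = dmps)

  vicinity <- NULL
  if (!is.null(variants)) {
    say("variant vicinity")
    vicinity <- annotate_gv_vicinity(annotation, variants)
  }

  say("clinical comparisons")
  clinical <- tryCatch(clinical_compare(sheet), error = function(e) NULL)

  census <- stability$crosstab
  summary <- list(
    seed = seed,
    n_probes = nrow(beta), n_samples = ncol(beta),
    n_pairs = length(view$subjects), n_excluded = length(view$excluded),
    parameters = list(smp_icc = smp_icc, hsmp_icc = hsmp_icc, alpha = alpha,
                      gap_threshold = gap_threshold,
                      gap_out_cutoff = gap_out_cutoff),
    census = as.data.frame.matrix(census),
    class_counts = as.list(table(classes$class)),
    n_smp = sum(stability$calls$is_smp),
    n_hsmp = sum(stability$calls$is_hsmp),
    n_dmp = sum(dmps$is_dmp),
    n_predicted_gv = sum(gaps$in_predicted_gv, na.rm = TRUE),
    clip_fraction = if (!is.null(truth)) truth$clip_fraction else NULL,
    set_test_p = if (!is.null(set_tests))
      stats::setNames(as.list(set_tests$p_value), set_tests$set_name)
      else NULL,
    clinical_p = if (!is.null(clinical))
      stats::setNames(as.list(clinical$p_value), clinical$variable)
      else NULL)

  result <- list(view = view, icc = icc, gaps = gaps, cells = cells,
                 composition = composition, design = design, fit = fit,
                 dmps = dmps, set_tests = set_tests, classes = classes,
                 stability = stability, interrogation = interrogation,
                 vicinity = vicinity, clinical = clinical, truth = truth,
                 summary = summary)

  if (!is.null(out_dir)) {
    say("writing outputs to ", out_dir)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(icc, "icc.tsv"); wt(gaps, "gaps.tsv"); wt(dmps, "dmp.tsv")
    wt(classes, "classes.tsv"); wt(stability$calls, "stability.tsv")
    wt(as.data.frame.matrix(census), "crosstab.tsv")
    if (!is.null(cells)) wt(cells, "cell_weights.tsv")
    if (!is.null(composition)) wt(composition, "composition_tests.tsv")
    if (!is.null(set_tests)) wt(set_tests, "set_tests.tsv")
    if (!is.null(vicinity)) wt(vicinity, "vicinity.tsv")
    if (!is.null(clinical)) wt(clinical, "clinical.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(result)
}
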