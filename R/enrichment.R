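#' Per-gene probe-count bias weights
#'
#' On methylation arrays, genes covered by more probes are more likely to
#' contain at least one significant probe; the probe count per gene is the
#' bias weight the enrichment test corrects for.
#'
#' @param annotation probe annotation with a populated `gene` column.
#' @return named integer vector: probes per gene (genes with 0 probes are
#'   absent by construction).
#' @export
probe_bias_weights <- function(annotation) {
  g <- annotation$gene
  g <- g[!is.na(g) & nzchar(g)]
  if (!length(g)) stop("annotation has no gene assignments", call. = FALSE)
  tab <- table(g)
  stats::setNames(as.integer(tab), names(tab))
}

# Univariate Wallenius noncentral hypergeometric pmf via its integral
# representation; d = odds*(m1-x) + (m2 - (n-x)) is the total weight of the
# balls remaining after the draw. Substituting t = s^d turns the integrand
# into a smooth Beta-like kernel, which plain quadrature handles reliably.
.wallenius_pmf <- function(x, m1, m2, n, odds) {
  if (x < max(0L, n - m2) || x > min(n, m1)) return(0)
  d <- odds * (m1 - x) + (m2 - (n - x))
  if (d <= 0) return(1)  # every ball drawn: degenerate support point
  lc <- lchoose(m1, x) + lchoose(m2, n - x) + log(d)
  f <- function(s) {
    out <- lc + (d - 1) * log(s) + (n - x) * log1p(-s)
    if (x > 0) out <- out + x * log1p(-s^odds)
    exp(out)
  }
  stats::integrate(f, 0, 1, rel.tol = 1e-9, subdivisions = 1000L)$value
}

#' Upper tail of the Wallenius noncentral hypergeometric distribution
#'
#' `P(X >= x)` when `n` genes are drawn significant from `m1` set genes of
#' weight `odds` and `m2` non-set genes of weight 1. `odds = 1` reduces to
#' the central hypergeometric (`phyper`).
#'
#' @param x observed significant set-gene count.
#' @param m1 set genes in the universe; `m2` non-set genes; `n` significant
#'   genes in total.
#' @param m2,n see above.
#' @param odds weight of a set gene relative to a non-set gene.
#' @return the upper-tail probability.
#' @export
wallenius_upper_tail <- function(x, m1, m2, n, odds = 1) {
  stopifnot(odds > 0)
  if (x <= max(0L, n - m2)) return(1)
  if (odds == 1) return(stats::phyper(x - 1, m1, m2, n, lower.tail = FALSE))
  js <- seq(x, min(n, m1))
  if (!length(js)) return(0)
  min(1, sum(vapply(js, .wallenius_pmf, 0, m1 = m1, m2 = m2, n = n,
                    odds = odds)))
}

#' Probe-bias-corrected gene-set enrichment test
#'
#' Maps probes to genes (a gene is significant when at least one of its
#' probes is significant) and tests the set's significant-gene count
#' against a Wallenius noncentral hypergeometric null whose odds equal the
#' ratio of mean probe counts, set versus non-set genes. This corrects the
#' inflation of the plain Fisher test when selection probability grows with
#' probe coverage; `method = "fisher"` gives the uncorrected one-sided test
#' for comparison.
#'
#' @param significant character vector of significant probe ids (must be a
#'   subset of `universe`).
#' @param universe character vector of all tested probe ids.
#' @param gene_set character vector of gene symbols.
#' @param annotation probe annotation mapping probes to genes.
#' @param weights optional precomputed [probe_bias_weights()].
#' @param method `"wallenius"` (default) or `"fisher"`.
#' @return one-row `EnrichmentResult` data.frame: `set_name`,
#'   `n_genes_universe`, `n_genes_in_set`, `n_significant_genes`,
#'   `n_significant_in_set`, `odds`, `p_value`.
#' @export
test_gene_set <- function(significant, universe, gene_set, annotation,
                          weights = NULL,
                          method = c("wallenius", "fisher")) {
  method <- match.arg(method)
  if (!all(significant %in% universe))
    stop("significant probes must be a subset of the universe", call. = FALSE)
  ann <- annotation[!is.na(annotation$gene) & nzchar(annotation$gene) &
                      annotation$probe_id %in% universe, ]
  if (is.null(weights)) weights <- probe_bias_weights(ann)
  genes_universe <- unique(ann$gene)
  genes_sig <- unique(ann$gene[ann$probe_id %in% significant])
  set_name <- attr(gene_set, "set_name")
  if (is.null(set_name)) set_name <- NA_character_
  set_in <- intersect(gene_set, genes_universe)
  na_row <- data.frame(set_name = set_name, n_genes_universe =
                         length(genes_universe),
                       n_genes_in_set = length(set_in),
                       n_significant_genes = length(genes_sig),
                       n_significant_in_set = NA_integer_, odds = NA_real_,
                       p_value = NA_real_, stringsAsFactors = FALSE)
  if (!length(set_in)) return(na_row)
  m1 <- length(set_in)
  m2 <- length(genes_universe) - m1
  n <- length(genes_sig)
  x <- length(intersect(set_in, genes_sig))
  w <- weights[match(genes_universe, names(weights))]
  in_set <- genes_universe %in% set_in
  odds <- if (m2 > 0) mean(w[in_set]) / mean(w[!in_set]) else 1
  p <- if (method == "fisher")
    stats::phyper(x - 1, m1, m2, n, lower.tail = FALSE)
  else
    wallenius_upper_tail(x, m1, m2, n, odds)
  data.frame(set_name = set_name, n_genes_universe = length(genes_universe),
             n_genes_in_set = m1, n_significant_genes = n,
             n_significant_in_set = x, odds = odds, p_value = p,
             stringsAsFactors = FALSE)
}

#' Enrichment over a list of gene sets with BH adjustment
#'
#' @param significant,universe,annotation,method see [test_gene_set()].
#' @param gene_sets named list of gene symbol vectors.
#' @return data.frame, one row per set, with `p_adjusted` across sets.
#' @export
test_gene_sets <- function(significant, universe, gene_sets, annotation,
                           method = c("wallenius", "fisher")) {
  method <- match.arg(method)
  ann <- annotation[!is.na(annotation$gene) & nzchar(annotation$gene) &
                      annotation$probe_id %in% universe, ]
  weights <- probe_bias_weights(ann)
  rows <- lapply(names(gene_sets), function(nm) {
    gs <- gene_sets[[nm]]
    attr(gs, "set_name") <- nm
    test_gene_set(significant, universe, gs, annotation, weights = weights,
                  method = method)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
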