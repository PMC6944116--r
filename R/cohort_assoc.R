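#' Subgroup samples by UV signature mutation load
#'
#' Partitions samples into `zero` (exactly 0 mutations), `low`
#' (0 < load < 3.6 per Mb), `mid` (3.6 <= load <= 54.6, closed interval),
#' and `high` (load > 54.6) subgroups.
#'
#' @param loads non-negative mutation loads (mutations per Mb).
#' @param boundaries two strictly increasing positive boundaries.
#' @return list with `labels` (factor, levels zero/low/mid/high) and
#'   `counts` (named table).
#' @export
subgroup_by_load <- function(loads, boundaries = c(3.6, 54.6)) {
  if (any(loads < 0)) stop("mutation loads must be non-negative")
  if (length(boundaries) != 2 || diff(boundaries) <= 0 || boundaries[1] <= 0) {
    stop("boundaries must be two strictly increasing positive values")
  }
  labels <- ifelse(loads == 0, "zero",
            ifelse(loads < boundaries[1], "low",
            ifelse(loads <= boundaries[2], "mid", "high")))
  labels <- factor(labels, levels = c("zero", "low", "mid", "high"))
  list(labels = labels, counts = table(labels))
}

#' Spearman correlation between deregulation score and mutation load
#'
#' Rank correlation with mid-ranks for ties; the p value uses the
#' t-distribution approximation on `n - 2` degrees of freedom.
#'
#' @param pds per-sample scores.
#' @param loads per-sample mutation loads, same order.
#' @return list with `rho`, `n`, `p` (`rho`/`p` are `NA` when either
#'   input is constant).
#' @export
correlate_pds_load <- function(pds, loads) {
  if (length(pds) != length(loads)) stop("inputs must be paired")
  n <- length(pds)
  if (n < 10) stop("need >= 10 paired observations")
  if (stats::sd(pds) == 0 || stats::sd(loads) == 0) {
    warning("constant input: correlation undefined")
    return(list(rho = NA_real_, n = n, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(pds, loads, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), n = n, p = ct$p.value)
}

#' Compare deregulation scores between mutation-load subgroups
#'
#' Two-sided rank-sum (Wilcoxon) tests for an ordered set of subgroup
#' pairs, with Benjamini-Hochberg adjustment across the pairs, plus the
#' per-group medians. Pairs with an undersized group are skipped with a
#' warning.
#'
#' @param pds per-sample scores.
#' @param labels subgroup factor from [subgroup_by_load()].
#' @param comparisons list of 2-vectors of group names; default compares
#'   the zero baseline against low/mid/high, and low against mid/high.
#' @param min_n minimum per-group size.
#' @param test `"ranksum"` or `"ttest"`.
#' @return list with `pairs` (data.frame: `group_a`, `group_b`,
#'   `statistic`, `p`, `p_adj`) and `medians` (named).
#' @export
compare_groups <- function(pds, labels,
                           comparisons = list(c("zero", "low"), c("zero", "mid"),
                                              c("zero", "high"), c("low", "mid"),
                                              c("low", "high")),
                           min_n = 3, test = c("ranksum", "ttest")) {
  test <- match.arg(test)
  stopifnot(length(pds) == length(labels))
  medians <- tapply(pds, labels, stats::median)
  rows <- list()
  for (cmp in comparisons) {
    a <- pds[labels == cmp[1]]
    b <- pds[labels == cmp[2]]
    if (length(a) < min_n || length(b) < min_n) {
      warning(sprintf("skipping %s vs %s: group below %d samples",
                      cmp[1], cmp[2], min_n))
      next
    }
    ht <- if (test == "ranksum") {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    } else {
      stats::t.test(a, b)
    }
    rows[[length(rows) + 1]] <- data.frame(
      group_a = cmp[1], group_b = cmp[2],
      statistic = unname(ht$statistic), p = ht$p.value,
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_a = character(), group_b = character(),
               statistic = numeric(), p = numeric())
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  list(pairs = pairs, medians = medians)
}

#' Rank pathway genes by their individual association with mutation load
#'
#' For every gene, computes the single-gene deregulation score and tests
#' it between the low- and high-load subgroups with a two-sided rank-sum
#' test; p values are Benjamini-Hochberg adjusted across genes and genes
#' are ranked by adjusted p, ties broken by absolute median difference.
#'
#' @param expr sample x gene matrix over the pathway panel.
#' @param labels subgroup factor from [subgroup_by_load()] aligned to
#'   rows of `expr`.
#' @param reference_ids baseline sample ids for score orientation.
#' @param groups the two compared subgroups.
#' @param min_n minimum per-group size.
#' @return data.frame ordered by rank: `gene`, `statistic`, `p`, `p_adj`,
#'   `median_diff` (high minus low group median score), `rank`.
#' @export
rank_gene_contributions <- function(expr, labels, reference_ids,
                                    groups = c("low", "high"), min_n = 3) {
  stopifnot(nrow(expr) == length(labels))
  ia <- labels == groups[1]
  ib <- labels == groups[2]
  if (sum(ia) < min_n || sum(ib) < min_n) {
    stop(sprintf("compared groups need >= %d samples each (%s: %d, %s: %d)",
                 min_n, groups[1], sum(ia), groups[2], sum(ib)))
  }
  res <- lapply(colnames(expr), function(g) {
    sg <- single_gene_pds(expr[, g], reference_ids,
                          sample_ids = rownames(expr))
    a <- sg$pds[ia]; b <- sg$pds[ib]
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(gene = g, statistic = unname(ht$statistic), p = ht$p.value,
               median_diff = stats::median(b) - stats::median(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  o <- order(out$p_adj, -abs(out$median_diff))
  out <- out[o, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the cohort association analysis end to end
#'
#' Chains PDS computation (full panel and labelled subsets), subgrouping
#' by mutation load, the PDS-load Spearman correlation, subgroup
#' comparisons, and the per-gene contribution ranking.
#'
#' @param expr sample x gene matrix.
#' @param loads per-sample mutation loads aligned with `expr` rows.
#' @param gene_sets `gene_set_collection` (default: the shipped panel);
#'   subset labels create additional scored gene sets.
#' @param reference_ids baseline samples; default: the zero-load
#'   subgroup.
#' @param strata optional factor (e.g. a clinical covariate) aligned with
#'   `expr` rows; when supplied, the panel-PDS/load correlation is also
#'   recomputed within each stratum as a confounding screen. No covariate
#'   model is fitted.
#' @param cfg run configuration.
#' @return list with `pds` (per gene set), `subgroups`, `correlation`
#'   (full panel), `group_comparison` (full panel), `gene_ranking`, and
#'   `stratified` (per-stratum correlations, when `strata` is given).
#' @export
cohort_association <- function(expr, loads, gene_sets = NULL,
                               reference_ids = NULL, strata = NULL,
                               cfg = default_run_config()) {
  if (is.null(gene_sets)) gene_sets <- read_gene_sets(uvg2_panel_path())
  sg <- subgroup_by_load(loads, cfg$load_boundaries)
  if (is.null(reference_ids)) {
    reference_ids <- rownames(expr)[sg$labels == "zero"]
    if (!length(reference_ids)) {
      stop("no zero-load samples to act as reference; supply reference_ids")
    }
  }
  sets <- as.list(gene_sets)
  subs <- attr(gene_sets, "subsets")
  panel_name <- names(sets)[1]
  panel_genes <- sets[[panel_name]]
  pds <- lapply(names(sets), function(nm) {
    compute_pds(expr, sets[[nm]], reference_ids, pathway = nm,
                var_fraction = cfg$pca_var_fraction, span = cfg$curve_span,
                tol = cfg$curve_tol, max_iter = cfg$curve_max_iter)
  })
  names(pds) <- names(sets)
  main <- pds[[panel_name]]
  corr <- correlate_pds_load(main$pds, loads)
  cmpg <- compare_groups(main$pds, sg$labels)
  ranking <- rank_gene_contributions(
    expr[, intersect(panel_genes, colnames(expr)), drop = FALSE],
    sg$labels, reference_ids)
  stratified <- NULL
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(expr))
    stratified <- lapply(split(seq_len(nrow(expr)), strata), function(idx) {
      if (length(idx) < 10) return(NULL)
      correlate_pds_load(main$pds[idx], loads[idx])
    })
  }
  list(pds = pds, subgroups = sg, correlation = corr,
       group_comparison = cmpg, gene_ranking = ranking,
       reference_ids = reference_ids, stratified = stratified)
}
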