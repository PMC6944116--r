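#' Select differentially expressed genes by fold change and B statistic
#'
#' A gene is selected when its absolute log2 fold change is at least
#' `log2(fc_cutoff)` and its B statistic (log posterior odds of
#' differential expression) exceeds `b_cutoff`. The defaults — a
#' fold-change cutoff of 2 and B > 0 — are the candidate-selection rule
#' used throughout the pipeline.
#'
#' @param stats data.frame from [moderated_stats()] (columns `gene_id`,
#'   `logFC`, `B`).
#' @param fc_cutoff fold-change cutoff on the linear scale, `>= 1`.
#' @param b_cutoff B-statistic cutoff.
#' @return character vector of selected gene ids (input order preserved).
#' @export
select_differential <- function(stats, fc_cutoff = 2, b_cutoff = 0) {
  if (fc_cutoff < 1) stop("fc_cutoff must be >= 1")
  if (nrow(stats) == 0) return(character())
  keep <- abs(stats$logFC) >= log2(fc_cutoff) & stats$B > b_cutoff
  stats$gene_id[keep]
}

#' Remove G2-generic genes from the UV-G2 candidate list
#'
#' Genes on the UV-G2 checkpoint list that also appear on the G2-phase
#' list with a fold change of the same sign and within `similarity_logfc`
#' log2 units are considered generic G2-phase responders rather than
#' checkpoint-specific, and are removed.
#'
#' @param uvg2_set,g2_set character vectors of selected gene ids.
#' @param uvg2_stats,g2_stats stat tables covering every listed gene.
#' @param similarity_logfc log2 window within which same-sign fold changes
#'   count as "similar".
#' @return character vector: the UV-G2 list with G2-similar genes removed.
#' @export
subtract_g2 <- function(uvg2_set, g2_set, uvg2_stats, g2_stats,
                        similarity_logfc = 1) {
  lf_u <- stats::setNames(uvg2_stats$logFC, uvg2_stats$gene_id)
  lf_g <- stats::setNames(g2_stats$logFC, g2_stats$gene_id)
  miss <- c(setdiff(uvg2_set, names(lf_u)), setdiff(g2_set, names(lf_g)))
  if (length(miss)) {
    stop("missing stats for listed gene(s): ", paste(unique(miss), collapse = ", "))
  }
  shared <- intersect(uvg2_set, g2_set)
  same_sign <- sign(lf_u[shared]) == sign(lf_g[shared])
  similar <- abs(lf_u[shared] - lf_g[shared]) < similarity_logfc
  drop <- shared[same_sign & similar]
  setdiff(uvg2_set, drop)
}

#' Intersect candidate lists across platforms
#'
#' Returns the genes selected on both the microarray and the RNA-seq
#' platform, together with the fraction of the RNA-seq list contained in
#' the microarray list (containment 1 means the RNA-seq list is fully
#' confirmed by the arrays).
#'
#' @param microarray_set,rnaseq_set character vectors of gene ids.
#' @return list with `genes` (intersection, microarray order) and
#'   `containment` (fraction of `rnaseq_set` inside `microarray_set`;
#'   `NA` if the RNA-seq list is empty).
#' @export
intersect_platforms <- function(microarray_set, rnaseq_set) {
  inter <- microarray_set[microarray_set %in% rnaseq_set]
  containment <- if (length(rnaseq_set)) {
    mean(rnaseq_set %in% microarray_set)
  } else NA_real_
  list(genes = inter, containment = containment)
}

#' Classify genes as transcriptionally and/or translationally regulated
#'
#' Applies the same fold-change/B selection to the total-mRNA and the
#' polysome-bound contrasts and classifies each gene:
#' `translational_only` (selected on polysomes but not in total mRNA —
#' a change in ribosome loading without a change in transcript level),
#' `transcriptional_only` (selected in total mRNA but not on polysomes —
#' transcript level changes without a corresponding loading change),
#' `both`, or `none`.
#'
#' @param total_stats,polysome_stats stat tables over the same gene
#'   universe (same ids, any order).
#' @param fc_cutoff,b_cutoff selection thresholds.
#' @return list with `class` (named character vector per gene),
#'   `summary`: counts per class plus `frac_polysome_only` (fraction of
#'   polysome-selected genes not selected in total mRNA) and
#'   `frac_total_only` (fraction of total-selected genes not selected on
#'   polysomes).
#' @export
classify_regulation <- function(total_stats, polysome_stats,
                                fc_cutoff = 2, b_cutoff = 0) {
  if (!setequal(total_stats$gene_id, polysome_stats$gene_id) ||
      nrow(total_stats) != nrow(polysome_stats)) {
    stop("total and polysome stats must cover the same gene universe")
  }
  tot <- select_differential(total_stats, fc_cutoff, b_cutoff)
  pol <- select_differential(polysome_stats, fc_cutoff, b_cutoff)
  genes <- total_stats$gene_id
  cls <- rep("none", length(genes))
  cls[genes %in% tot & genes %in% pol] <- "both"
  cls[genes %in% pol & !(genes %in% tot)] <- "translational_only"
  cls[genes %in% tot & !(genes %in% pol)] <- "transcriptional_only"
  names(cls) <- genes
  summary <- list(
    n_total_selected = length(tot),
    n_polysome_selected = length(pol),
    n_both = sum(cls == "both"),
    frac_polysome_only = if (length(pol)) mean(!(pol %in% tot)) else NA_real_,
    frac_total_only = if (length(tot)) mean(!(tot %in% pol)) else NA_real_
  )
  list(class = cls, summary = summary)
}

#' Run the full candidate-selection pipeline
#'
#' Chains the stages used to define the high-confidence UV-G2 checkpoint
#' transcript set: per-contrast moderated statistics, fold-change/B
#' selection of differentially polysome-loaded genes in G2 and UV-G2,
#' subtraction of G2-generic responders from the UV-G2 list, and
#' intersection of the microarray list with the RNA-seq list.
#'
#' @param microarray,rnaseq [expression_dataset()] objects. `rnaseq` may
#'   be `NULL`, in which case the cross-platform step is skipped.
#' @param cfg a [default_run_config()] list.
#' @return list with the per-contrast stat tables (`stats`), the selected
#'   sets per stage (`g2`, `uvg2`, `uvg2_minus_g2`, `rnaseq_uvg2`,
#'   `high_confidence`), the RNA-seq containment fraction, and the
#'   `classify_regulation` outputs for G2 and UV-G2.
#' @export
candidate_pipeline <- function(microarray, rnaseq = NULL, cfg = default_run_config()) {
  p <- cfg$de_proportion
  st <- list(
    g2_pol = moderated_stats(microarray, "G2", "AS", "polysome", proportion = p),
    uvg2_pol = moderated_stats(microarray, "UVG2", "AS", "polysome", proportion = p),
    g2_tot = moderated_stats(microarray, "G2", "AS", "total", proportion = p),
    uvg2_tot = moderated_stats(microarray, "UVG2", "AS", "total", proportion = p)
  )
  g2 <- select_differential(st$g2_pol, cfg$fc_cutoff, cfg$b_cutoff)
  uvg2 <- select_differential(st$uvg2_pol, cfg$fc_cutoff, cfg$b_cutoff)
  uvg2_minus_g2 <- subtract_g2(uvg2, g2, st$uvg2_pol, st$g2_pol,
                               cfg$g2_similarity_logfc)
  rnaseq_uvg2 <- NULL
  high_confidence <- uvg2_minus_g2
  containment <- NA_real_
  if (!is.null(rnaseq)) {
    st$rs_g2_pol <- moderated_stats(rnaseq, "G2", "AS", "polysome", proportion = p)
    st$rs_uvg2_pol <- moderated_stats(rnaseq, "UVG2", "AS", "polysome", proportion = p)
    rs_g2 <- select_differential(st$rs_g2_pol, cfg$fc_cutoff, cfg$b_cutoff)
    rs_uvg2 <- select_differential(st$rs_uvg2_pol, cfg$fc_cutoff, cfg$b_cutoff)
    rnaseq_uvg2 <- subtract_g2(rs_uvg2, rs_g2, st$rs_uvg2_pol, st$rs_g2_pol,
                               cfg$g2_similarity_logfc)
    xp <- intersect_platforms(uvg2_minus_g2, rnaseq_uvg2)
    high_confidence <- xp$genes
    containment <- xp$containment
  }
  regulation <- list(
    g2 = classify_regulation(st$g2_tot, st$g2_pol, cfg$fc_cutoff, cfg$b_cutoff),
    uvg2 = classify_regulation(st$uvg2_tot, st$uvg2_pol, cfg$fc_cutoff, cfg$b_cutoff)
  )
  list(stats = st, g2 = g2, uvg2 = uvg2, uvg2_minus_g2 = uvg2_minus_g2,
       rnaseq_uvg2 = rnaseq_uvg2, high_confidence = high_confidence,
       containment = containment, regulation = regulation)
}
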