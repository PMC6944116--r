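#' Specification for the synthetic polysome-profiling experiment
#'
#' Describes a two-platform (microarray log2 intensities, RNA-seq counts)
#' polysome-profiling experiment over the conditions AS (asynchronous),
#' G2 (synchronized G2 phase) and UVG2 (UV-irradiated, G2
#' checkpoint-arrested), each profiled in total and polysome-bound mRNA
#' fractions with biological replicates. Genes are planted into effect
#' classes:
#'
#' * `translational`: polysome loading shifts in UVG2, total mRNA does not
#'   (the dominant class in the checkpoint response);
#' * `transcriptional`: transcript level shifts in UVG2 and the loading
#'   follows it (total and polysome move together);
#' * `buffered`: transcript level shifts in UVG2 but loading is
#'   translationally buffered (total moves, polysome does not);
#' * `g2_generic`: polysome loading shifts equally in G2 and UVG2 — a
#'   generic G2-phase response the G2-subtraction stage should remove;
#' * the remainder are null genes.
#'
#' @param n_genes number of genes.
#' @param replicates biological replicates per (condition, fraction).
#' @param class_prop named proportions for the four planted classes
#'   (must sum to <= 1).
#' @param effect_logfc named planted log2 fold-change magnitudes per class.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution.
#' @param noise_sd microarray residual sd on the log2 scale.
#' @param rnaseq_dispersion negative-binomial dispersion for RNA-seq counts.
#' @param rnaseq_depth target mean library size for RNA-seq.
#' @param rnaseq_fractions fractions profiled on RNA-seq (the sequencing
#'   arm profiles polysome-bound mRNA only by default).
#' @param seed non-negative integer fixing all randomness.
#' @return a `polysome_sim_spec` list.
#' @export
polysome_sim_spec <- function(n_genes = 2000,
                              replicates = 3,
                              class_prop = c(translational = 0.05,
                                             transcriptional = 0.015,
                                             buffered = 0.02,
                                             g2_generic = 0.015),
                              effect_logfc = c(translational = 2,
                                               transcriptional = 2,
                                               buffered = 2,
                                               g2_generic = 2),
                              baseline_mean = 8, baseline_sd = 1.5,
                              noise_sd = 0.25,
                              rnaseq_dispersion = 0.1,
                              rnaseq_depth = 5e6,
                              rnaseq_fractions = "polysome",
                              seed = 0) {
  classes <- c("translational", "transcriptional", "buffered", "g2_generic")
  stopifnot(all(names(class_prop) %in% classes), all(names(effect_logfc) %in% classes))
  if (sum(class_prop) > 1) stop("class proportions must sum to <= 1")
  if (replicates < 2) stop("need >= 2 replicates per (condition, fraction)")
  if (seed < 0 || seed != round(seed)) stop("seed must be a non-negative integer")
  structure(list(
    n_genes = n_genes, replicates = replicates, class_prop = class_prop,
    effect_logfc = effect_logfc, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, noise_sd = noise_sd,
    rnaseq_dispersion = rnaseq_dispersion, rnaseq_depth = rnaseq_depth,
    rnaseq_fractions = rnaseq_fractions, seed = seed
  ), class = "polysome_sim_spec")
}

# Planted log2 effect of one gene class in a given (condition, fraction).
planted_effect <- function(class, condition, fraction, magnitude) {
  if (condition == "AS" || class == "null") return(0)
  switch(class,
    translational = if (condition == "UVG2" && fraction == "polysome") magnitude else 0,
    transcriptional = if (condition == "UVG2") magnitude else 0,
    buffered = if (condition == "UVG2" && fraction == "total") magnitude else 0,
    g2_generic = if (fraction == "polysome") magnitude else 0,
    0)
}

#' Generate a synthetic polysome-profiling dataset
#'
#' Simulates matched microarray and RNA-seq expression datasets plus a
#' per-gene truth table. Microarray noise is Gaussian on the log2 scale;
#' RNA-seq counts are negative binomial around a mean proportional to the
#' linear-scale abundance. Each planted gene carries its class effect with
#' a random sign (up- or down-regulated), shared across platforms.
#'
#' @param spec a [polysome_sim_spec()].
#' @return list with `microarray` and `rnaseq` [expression_dataset()]s
#'   and `truth`: a data.frame of `gene_id`, `class`, `sign`, and true
#'   log2 effects per (condition, fraction).
#' @export
gen_polysome <- function(spec) {
  stopifnot(inherits(spec, "polysome_sim_spec"))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)

  ng <- spec$n_genes
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  counts <- floor(ng * spec$class_prop)
  cls <- rep("null", ng)
  idx <- seq_len(sum(counts))
  cls[idx] <- rep(names(counts), counts)
  sgn <- ifelse(stats::runif(ng) < 0.5, -1, 1)
  sgn[cls == "null"] <- 0
  baseline <- stats::rnorm(ng, spec$baseline_mean, spec$baseline_sd)

  conditions <- c("AS", "G2", "UVG2")
  fractions <- c("total", "polysome")
  cells <- expand.grid(condition = conditions, fraction = fractions,
                       stringsAsFactors = FALSE)

  # per-gene true log2 effect matrix over cells (before sign)
  eff <- matrix(0, ng, nrow(cells))
  for (j in seq_len(nrow(cells))) {
    mag <- spec$effect_logfc
    eff[, j] <- vapply(seq_len(ng), function(g) {
      if (cls[g] == "null") return(0)
      planted_effect(cls[g], cells$condition[j], cells$fraction[j],
                     mag[[cls[g]]])
    }, numeric(1))
  }
  eff <- eff * sgn

  make_samples <- function(cell_idx) {
    do.call(rbind, lapply(cell_idx, function(j) {
      data.frame(condition = cells$condition[j], fraction = cells$fraction[j],
                 replicate = seq_len(spec$replicates), cell = j,
                 stringsAsFactors = FALSE)
    }))
  }

  # microarray: all six cells
  ma_meta <- make_samples(seq_len(nrow(cells)))
  ma_meta$sample_id <- sprintf("MA_%s_%s_r%d", ma_meta$condition,
                               ma_meta$fraction, ma_meta$replicate)
  ma <- sapply(seq_len(nrow(ma_meta)), function(s) {
    mu <- baseline + eff[, ma_meta$cell[s]]
    stats::rnorm(ng, mu, spec$noise_sd)
  })
  dimnames(ma) <- list(gene_ids, ma_meta$sample_id)

  # rnaseq: configured fractions only
  rs_cells <- which(cells$fraction %in% spec$rnaseq_fractions)
  rs_meta <- make_samples(rs_cells)
  rs_meta$sample_id <- sprintf("RS_%s_%s_r%d", rs_meta$condition,
                               rs_meta$fraction, rs_meta$replicate)
  base_lin <- 2^baseline
  rs <- sapply(seq_len(nrow(rs_meta)), function(s) {
    lin <- base_lin * 2^(eff[, rs_meta$cell[s]] + stats::rnorm(ng, 0, spec$noise_sd / 2))
    mu <- lin / sum(lin) * spec$rnaseq_depth
    stats::rnbinom(ng, mu = mu, size = 1 / spec$rnaseq_dispersion)
  })
  dimnames(rs) <- list(gene_ids, rs_meta$sample_id)

  truth <- data.frame(gene_id = gene_ids, class = cls, sign = sgn,
                      stringsAsFactors = FALSE)
  for (j in seq_len(nrow(cells))) {
    truth[[sprintf("lfc_%s_%s", cells$condition[j], cells$fraction[j])]] <- eff[, j]
  }

  keep <- c("sample_id", "condition", "fraction", "replicate")
  list(
    microarray = expression_dataset(ma, ma_meta[keep], "microarray"),
    rnaseq = expression_dataset(rs, rs_meta[keep], "rnaseq"),
    truth = truth
  )
}

# Save/restore of .Random.seed so generators are pure in (spec, seed)
# without clobbering the caller's RNG stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
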