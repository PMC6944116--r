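#' Specification for the synthetic melanoma-like cohort
#'
#' Emulates a tumor cohort carrying (a) expression of a pathway gene panel
#' driven by a single latent deregulation axis `t in [0,1]` per sample and
#' (b) a UV-signature mutation load (mutations per Mb) stochastically
#' increasing with `t`. Expression follows
#' `x_ig = a_g t_i + q_g t_i^2 + noise` (set `q_g = 0` via
#' `mode = "linear"` for closed-form checks); the mutation count is
#' negative binomial with `log mu = load_intercept + load_slope * t`,
#' divided by `genome_mb` to give a per-Mb load. A configurable fraction
#' of samples carries exactly zero load; these are the lowest-`t` samples
#' and act as the cohort's de facto baseline group.
#'
#' The default `load_slope` is calibrated so that the planted
#' Spearman correlation between `t` and load is about 0.25 at the default
#' cohort size of 352 samples, with subgroup proportions (zero / below
#' 3.6 / 3.6-54.6 / above 54.6 per Mb) resembling a melanoma cohort.
#'
#' @param n_samples cohort size.
#' @param genes character vector of pathway gene ids (default: the
#'   synthetic 43-gene panel shipped with the package).
#' @param mode `"quadratic"` (curved latent trajectory) or `"linear"`.
#' @param loading_range magnitude range for the linear loadings `a_g`.
#' @param quad_range range for the quadratic coefficients `q_g`.
#' @param noise_sd Gaussian expression noise sd.
#' @param shared_factor_sd sd of an optional sample-level shared factor
#'   added to all genes (0 disables; models non-pathway covariation).
#' @param load_intercept,load_slope NB log-mean parameters (counts).
#' @param load_size NB size (inverse dispersion) of the mutation count.
#' @param zero_fraction fraction of exact-zero-load samples, in [0, 1).
#' @param genome_mb genome footprint converting counts to per-Mb load.
#' @param seed non-negative integer.
#' @return a `cohort_sim_spec` list.
#' @export
cohort_sim_spec <- function(n_samples = 352,
                            genes = NULL,
                            mode = c("quadratic", "linear"),
                            loading_range = c(0.6, 1.4),
                            quad_range = c(-0.6, 0.6),
                            noise_sd = 0.25,
                            shared_factor_sd = 0,
                            load_intercept = 6.2,
                            load_slope = 0.7,
                            load_size = 1,
                            zero_fraction = 12 / 352,
                            genome_mb = 38,
                            seed = 0) {
  mode <- match.arg(mode)
  if (is.null(genes)) {
    panel <- read_gene_sets(uvg2_panel_path())
    genes <- panel[[1]]
  }
  if (load_slope < 0) stop("load_slope must be >= 0 (planted association is non-negative)")
  if (zero_fraction < 0 || zero_fraction >= 1) stop("zero_fraction must be in [0, 1)")
  if (seed < 0 || seed != round(seed)) stop("seed must be a non-negative integer")
  structure(list(
    n_samples = n_samples, genes = genes, mode = mode,
    loading_range = loading_range, quad_range = quad_range,
    noise_sd = noise_sd, shared_factor_sd = shared_factor_sd,
    load_intercept = load_intercept, load_slope = load_slope,
    load_size = load_size, zero_fraction = zero_fraction,
    genome_mb = genome_mb, seed = seed
  ), class = "cohort_sim_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `expr` (sample x gene matrix), `loads` (data.frame
#'   `sample_id`, `usm_per_mb`), and `truth` (data.frame `sample_id`,
#'   `t`, `zero_load`).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)

  n <- spec$n_samples
  genes <- spec$genes
  sample_ids <- sprintf("S%03d", seq_len(n))
  t <- stats::runif(n)

  a <- stats::runif(length(genes), spec$loading_range[1], spec$loading_range[2]) *
    ifelse(stats::runif(length(genes)) < 0.5, -1, 1)
  q <- if (spec$mode == "quadratic") {
    stats::runif(length(genes), spec$quad_range[1], spec$quad_range[2])
  } else rep(0, length(genes))

  expr <- outer(t, a) + outer(t^2, q)
  if (spec$noise_sd > 0) {
    expr <- expr + matrix(stats::rnorm(n * length(genes), 0, spec$noise_sd),
                          n, length(genes))
  }
  if (spec$shared_factor_sd > 0) {
    expr <- expr + stats::rnorm(n, 0, spec$shared_factor_sd)
  }
  dimnames(expr) <- list(sample_ids, genes)

  mu <- exp(spec$load_intercept + spec$load_slope * t)
  count <- stats::rnbinom(n, mu = mu, size = spec$load_size)
  load <- count / spec$genome_mb
  nzero <- floor(spec$zero_fraction * n)
  zero <- rep(FALSE, n)
  if (nzero > 0) {
    zero[order(t)[seq_len(nzero)]] <- TRUE
    load[zero] <- 0
  }

  list(
    expr = expr,
    loads = data.frame(sample_id = sample_ids, usm_per_mb = load,
                       stringsAsFactors = FALSE),
    truth = data.frame(sample_id = sample_ids, t = t, zero_load = zero,
                       stringsAsFactors = FALSE)
  )
}
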