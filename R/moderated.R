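#' Invert the trigamma function
#'
#' Newton iteration for the x solving `trigamma(x) = y`, used when
#' moment-matching the scaled inverse-chi-square prior on gene variances.
#'
#' @param y positive numeric vector.
#' @return numeric vector of solutions.
#' @keywords internal
trigamma_inverse <- function(y) {
  out <- y
  lo <- y < 1e-7
  out[lo] <- 1 / sqrt(y[lo])       # trigamma(x) ~ 1/x^2 for large x
  hi <- y > 1e7
  out[hi] <- 1 / y[hi]             # trigamma(x) ~ 1/x for small x... bounded below
  mid <- !lo & !hi
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

#' Shrink gene-wise variances toward a common prior
#'
#' Empirical-Bayes variance moderation. The gene-wise sample variances
#' `s2` (each on `df` residual degrees of freedom) are modelled as scaled
#' F-distributed around a prior variance `s0^2` with prior degrees of
#' freedom `d0`; `(d0, s0^2)` are estimated by matching the mean and
#' variance of `log(s2)` to their theoretical values. The posterior
#' variance for each gene is the df-weighted average
#' `(d0*s0^2 + df*s2) / (d0 + df)`.
#'
#' @param s2 gene-wise sample variances.
#' @param df residual degrees of freedom (scalar; equal across genes).
#' @return list with `var_post`, `var_prior` (s0^2), `df_prior` (d0; may
#'   be `Inf` when the variances are effectively exchangeable).
#' @export
squeeze_variances <- function(s2, df) {
  if (df < 1) stop("residual degrees of freedom must be >= 1")
  s2 <- pmax(s2, 1e-10)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  var_post <- if (is.finite(d0)) (d0 * s0sq + df * s2) / (d0 + df) else rep(s0sq, length(s2))
  list(var_post = var_post, var_prior = s0sq, df_prior = d0)
}

# Estimate the prior variance v0 of true coefficients among DE genes from
# the top |t| quantile (target-quantile matching under the two-component
# mixture), expressed in units of sigma_g^2 like the unscaled variance v.
estimate_v0 <- function(tstat, v, df_total, proportion, v0_lim = NULL) {
  ngenes <- length(tstat)
  ntarget <- ceiling(proportion / 2 * ngenes)
  if (ntarget < 1) return(0)
  p <- max(ntarget / ngenes, proportion)
  at <- abs(tstat)
  o <- order(at, decreasing = TRUE)[seq_len(ntarget)]
  t1 <- at[o]
  v1 <- v[o]
  r <- seq_len(ntarget)
  p0 <- 2 * stats::pt(-t1, df = df_total)
  ptarget <- ((r - 0.5) / ngenes - (1 - p) * p0) / p
  v0 <- numeric(ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df = df_total, lower.tail = FALSE)
    v0[pos] <- v1[pos] * ((t1[pos] / qtarget)^2 - 1)
  }
  v0bar <- mean(v0)
  if (!is.null(v0_lim)) v0bar <- min(max(v0bar, v0_lim[1]), v0_lim[2])
  v0bar
}

# B statistic: log posterior odds of differential expression under the
# two-component normal model with prior DE proportion `proportion` and
# prior coefficient variance v0 (in sigma^2 units).
lods_stat <- function(tstat, v, v0, df_total, proportion) {
  r <- (v + v0) / v
  kernel <- if (is.finite(df_total)) {
    t2 <- tstat^2
    (df_total + 1) / 2 * log((t2 + df_total) / (t2 / r + df_total))
  } else {
    tstat^2 * (1 - 1 / r) / 2
  }
  log(proportion / (1 - proportion)) - log(r) / 2 + kernel
}

#' Log2 counts-per-million with a pseudocount
#'
#' @param counts gene x sample count matrix.
#' @param pseudocount added to counts (and doubled in the library size)
#'   before the CPM transform.
#' @return matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, pseudocount = 0.5) {
  lib <- colSums(counts)
  t(log2(t(counts + pseudocount) / (lib + 2 * pseudocount) * 1e6))
}

#' Moderated differential-expression statistics for one contrast
#'
#' Computes, per gene, the log2 fold change between two conditions within
#' one mRNA fraction, the empirical-Bayes moderated t statistic, and the B
#' statistic (log posterior odds of differential expression). Microarray
#' values are used as-is (log2 intensities); RNA-seq counts are first
#' converted to log2 counts-per-million with a 0.5 pseudocount, after
#' which the same moderated linear model is applied.
#'
#' The moderated t replaces each gene's sample variance by the posterior
#' variance from [squeeze_variances()] and is referred to a t distribution
#' on `df + d0` degrees of freedom. The B statistic follows the standard
#' two-component normal mixture with prior DE proportion `proportion`;
#' the prior variance of DE coefficients is estimated from the upper tail
#' of the moderated t distribution and clamped so the implied prior
#' coefficient standard deviation lies in `coef_sd_lim`.
#'
#' @param ds an [expression_dataset()].
#' @param condition_a,condition_b conditions compared (`a` minus `b`),
#'   e.g. `"UVG2"` vs `"AS"`.
#' @param fraction `"total"` or `"polysome"`.
#' @param proportion prior proportion of differentially expressed genes.
#' @param coef_sd_lim admissible range for the prior coefficient sd.
#' @param prior optional list with `df_prior` and `var_prior` overriding the
#'   moment-matched estimates (e.g. `df_prior = 0` recovers the ordinary
#'   two-sample equal-variance t statistic).
#' @return data.frame with one row per gene: `gene_id`, `logFC`, `t`, `B`,
#'   `sigma` (ordinary residual sd), `df_total`, and the contrast label;
#'   attributes `df_prior`, `var_prior`, `v0`.
#' @export
moderated_stats <- function(ds, condition_a, condition_b, fraction,
                            proportion = 0.01, coef_sd_lim = c(0.1, 4),
                            prior = NULL) {
  validate_expression_dataset(ds)
  meta <- aligned_meta(ds)
  ia <- which(meta$condition == condition_a & meta$fraction == fraction)
  ib <- which(meta$condition == condition_b & meta$fraction == fraction)
  if (length(ia) < 2 || length(ib) < 2) {
    stop(sprintf("need >= 2 replicates per condition in fraction '%s' (found %d '%s', %d '%s')",
                 fraction, length(ia), condition_a, length(ib), condition_b))
  }
  x <- ds$values
  if (ds$platform == "rnaseq") x <- log_cpm(x)
  xa <- x[, ia, drop = FALSE]
  xb <- x[, ib, drop = FALSE]
  na <- length(ia); nb <- length(ib)
  df <- na + nb - 2
  if (df < 1) stop("zero residual degrees of freedom")
  logfc <- rowMeans(xa) - rowMeans(xb)
  ssa <- rowSums((xa - rowMeans(xa))^2)
  ssb <- rowSums((xb - rowMeans(xb))^2)
  s2 <- (ssa + ssb) / df
  v <- 1 / na + 1 / nb
  sq <- squeeze_variances(s2, df)
  if (!is.null(prior)) {
    d0 <- prior$df_prior
    s0sq <- if (is.null(prior$var_prior)) sq$var_prior else prior$var_prior
    sq$df_prior <- d0
    sq$var_prior <- s0sq
    sq$var_post <- if (is.finite(d0)) (d0 * s0sq + df * s2) / (d0 + df) else rep(s0sq, length(s2))
  }
  df_total <- df + sq$df_prior
  tmod <- logfc / sqrt(sq$var_post * v)
  v0_lim <- coef_sd_lim^2 / sq$var_prior
  v0 <- estimate_v0(tmod, rep(v, length(tmod)), df_total, proportion, v0_lim)
  B <- lods_stat(tmod, v, v0, df_total, proportion)
  out <- data.frame(
    gene_id = ds$gene_ids,
    logFC = unname(logfc),
    t = unname(tmod),
    B = unname(B),
    sigma = unname(sqrt(s2)),
    df_total = df_total,
    contrast = sprintf("%s-%s:%s", condition_a, condition_b, fraction),
    stringsAsFactors = FALSE
  )
  attr(out, "df_prior") <- sq$df_prior
  attr(out, "var_prior") <- sq$var_prior
  attr(out, "v0") <- v0
  out
}
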