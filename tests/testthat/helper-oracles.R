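# Independent scalar oracles used to cross-check the vectorized
# implementations. Deliberately written with plain loops and, where
# possible, different numerical methods (uniroot instead of Newton).

# trigamma inverse by bisection/uniroot — independent of the package's
# Newton iteration
oracle_trigamma_inverse <- function(y) {
  stats::uniroot(function(x) trigamma(x) - y, c(1e-6, 1e8), tol = 1e-12)$root
}

# scalar re-implementation of the moderated t / B chain for a two-group
# comparison on a log-scale matrix
oracle_moderated <- function(x, ia, ib, proportion = 0.01,
                             coef_sd_lim = c(0.1, 4)) {
  ng <- nrow(x)
  na <- length(ia); nb <- length(ib)
  df <- na + nb - 2
  logfc <- s2 <- numeric(ng)
  for (g in seq_len(ng)) {
    a <- x[g, ia]; b <- x[g, ib]
    logfc[g] <- mean(a) - mean(b)
    s2[g] <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  }
  s2 <- pmax(s2, 1e-10)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(e))
  } else {
    d0 <- 2 * oracle_trigamma_inverse(evar)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  v <- 1 / na + 1 / nb
  tmod <- numeric(ng)
  for (g in seq_len(ng)) {
    vp <- if (is.finite(d0)) (d0 * s0sq + df * s2[g]) / (d0 + df) else s0sq
    tmod[g] <- logfc[g] / sqrt(vp * v)
  }
  dft <- df + d0
  # v0 from the top-|t| target quantiles, scalar loop
  ntarget <- ceiling(proportion / 2 * ng)
  p <- max(ntarget / ng, proportion)
  ord <- order(abs(tmod), decreasing = TRUE)[seq_len(ntarget)]
  v0s <- numeric(ntarget)
  for (i in seq_len(ntarget)) {
    t1 <- abs(tmod[ord[i]])
    p0 <- 2 * stats::pt(-t1, df = dft)
    ptarget <- ((i - 0.5) / ng - (1 - p) * p0) / p
    if (ptarget > p0) {
      qt1 <- stats::qt(ptarget / 2, df = dft, lower.tail = FALSE)
      v0s[i] <- v * ((t1 / qt1)^2 - 1)
    }
  }
  v0 <- mean(v0s)
  lim <- coef_sd_lim^2 / s0sq
  v0 <- min(max(v0, lim[1]), lim[2])
  B <- numeric(ng)
  r <- (v + v0) / v
  for (g in seq_len(ng)) {
    t2 <- tmod[g]^2
    kern <- if (is.finite(dft)) {
      (dft + 1) / 2 * log((t2 + dft) / (t2 / r + dft))
    } else t2 * (1 - 1 / r) / 2
    B[g] <- log(proportion / (1 - proportion)) - log(r) / 2 + kern
  }
  list(logFC = logfc, t = tmod, B = B, d0 = d0, s0sq = s0sq, v0 = v0)
}

# Tukey HSD adjusted p for each group vs the control, computed directly
# from the studentized range distribution (independent of stats::TukeyHSD)
oracle_tukey_vs_control <- function(values, groups, control) {
  groups <- as.character(groups)
  gl <- unique(groups)
  k <- length(gl)
  ni <- sapply(gl, function(g) sum(groups == g))
  mi <- sapply(gl, function(g) mean(values[groups == g]))
  N <- length(values)
  sse <- 0
  for (g in gl) sse <- sse + sum((values[groups == g] - mi[g])^2)
  dfe <- N - k
  mse <- sse / dfe
  out <- numeric(0)
  for (g in setdiff(gl, control)) {
    q <- abs(mi[g] - mi[control]) / sqrt(mse / 2 * (1 / ni[g] + 1 / ni[control]))
    out[g] <- stats::ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE)
  }
  out
}

# brute-force Spearman with mid-ranks and t-approximation p value
oracle_spearman <- function(x, y) {
  n <- length(x)
  midrank <- function(v) {
    r <- numeric(n)
    for (i in seq_len(n)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# brute-force candidate-set rules
oracle_select <- function(stats_df, fc_cutoff, b_cutoff) {
  out <- character(0)
  for (i in seq_len(nrow(stats_df))) {
    if (abs(stats_df$logFC[i]) >= log2(fc_cutoff) && stats_df$B[i] > b_cutoff) {
      out <- c(out, stats_df$gene_id[i])
    }
  }
  out
}

oracle_subtract <- function(uvg2_set, g2_set, lfc_u, lfc_g, window) {
  out <- character(0)
  for (g in uvg2_set) {
    drop <- FALSE
    if (g %in% g2_set) {
      if (sign(lfc_u[g]) == sign(lfc_g[g]) && abs(lfc_u[g] - lfc_g[g]) < window) {
        drop <- TRUE
      }
    }
    if (!drop) out <- c(out, g)
  }
  out
}

# small two-group expression fixture on the microarray scale
make_two_group_ds <- function(ng = 50, na = 3, nb = 3, effect = NULL,
                              noise_sd = 0.3, seed = 3) {
  set.seed(seed)
  mu <- stats::rnorm(ng, 8, 1)
  if (is.null(effect)) effect <- c(stats::rnorm(ceiling(ng / 5), 0, 1.5),
                                   rep(0, ng - ceiling(ng / 5)))
  x <- cbind(matrix(stats::rnorm(ng * na, mu + effect, noise_sd), ng),
             matrix(stats::rnorm(ng * nb, mu, noise_sd), ng))
  rownames(x) <- sprintf("g%03d", seq_len(ng))
  colnames(x) <- c(sprintf("A%d", seq_len(na)), sprintf("B%d", seq_len(nb)))
  meta <- data.frame(
    sample_id = colnames(x),
    condition = rep(c("UVG2", "AS"), c(na, nb)),
    fraction = "polysome",
    replicate = c(seq_len(na), seq_len(nb))
  )
  expression_dataset(x, meta, "microarray")
}

# hand-built well-summary row for screen-scoring tests
ws_row <- function(pert, line, tp, n_cells = 800, f4n = 0.3, mean_foci = 4,
                   transduced_frac = NA, n_used = n_cells, well = NULL) {
  data.frame(
    well = if (is.null(well)) sprintf("%s_%s_%s", line, pert, tp) else well,
    perturbation = pert, line = line, timepoint = tp, n_cells = n_cells,
    n_used = n_used, f2n = 1 - 0.15 - f4n, fS = 0.15, f4n = f4n,
    evaluable = TRUE, mean_foci = mean_foci,
    transduced_frac = transduced_frac, stringsAsFactors = FALSE
  )
}
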