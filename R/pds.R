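#' Reduce pathway expression to its leading principal components
#'
#' Restricts the cohort expression matrix to one gene set, standardizes
#' each gene to zero mean and unit variance across samples (making the
#' downstream score invariant to gene-wise affine rescaling), and keeps
#' the leading principal components up to a cumulative explained-variance
#' fraction, with a floor of two dimensions so the principal curve always
#' has room to bend.
#'
#' @param expr sample x gene expression matrix.
#' @param genes gene ids to use (default: all columns).
#' @param var_fraction cumulative variance fraction to retain.
#' @param min_genes minimum usable genes.
#' @return list with `scores` (sample x k), `k`, `sdev` (all component
#'   sds), `genes_used`.
#' @export
pds_reduce <- function(expr, genes = colnames(expr), var_fraction = 0.9,
                       min_genes = 3) {
  genes <- intersect(genes, colnames(expr))
  x <- expr[, genes, drop = FALSE]
  if (nrow(x) < 10) stop("need >= 10 samples")
  vars <- apply(x, 2, stats::var)
  if (any(vars == 0)) {
    warning("dropping zero-variance gene(s): ",
            paste(genes[vars == 0], collapse = ", "))
    x <- x[, vars > 0, drop = FALSE]
  }
  if (ncol(x) < min_genes) stop("fewer than ", min_genes, " usable genes")
  xs <- scale(x)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  cumfrac <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- max(2L, which(cumfrac >= var_fraction)[1])
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # canonical component signs (largest-|loading| gene positive) so results
  # do not depend on the SVD's arbitrary sign choices
  for (j in seq_len(k)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  list(scores = scores, k = k, sdev = pc$sdev, genes_used = colnames(x))
}

# Project points onto a polyline; returns per-point arc-length position
# and squared distance. curve_pts must be ordered; n_seg = nrow - 1.
# The terminal segments are extrapolated (open-ended) so that points
# lying beyond the curve ends receive distinct positions instead of
# piling up at the endpoints; positions are then shifted so the smallest
# is 0 and total_length spans all projections.
project_to_polyline <- function(points, curve_pts) {
  n <- nrow(points)
  m <- nrow(curve_pts)
  if (m == 1) {
    d2 <- rowSums(sweep(points, 2, curve_pts[1, ])^2)
    return(list(lambda = rep(0, n), dist2 = d2, total_length = 0))
  }
  seg_start <- curve_pts[-m, , drop = FALSE]
  seg_vec <- curve_pts[-1, , drop = FALSE] - seg_start
  seg_len2 <- rowSums(seg_vec^2)
  seg_len <- sqrt(seg_len2)
  cum_len <- c(0, cumsum(seg_len))
  best_d2 <- rep(Inf, n)
  best_lambda <- rep(0, n)
  for (s in seq_len(m - 1)) {
    if (seg_len2[s] < 1e-24) next
    rel <- sweep(points, 2, seg_start[s, ])
    tt <- (rel %*% seg_vec[s, ])[, 1] / seg_len2[s]
    lo <- if (s == 1) -Inf else 0
    hi <- if (s == m - 1) Inf else 1
    tt <- pmin(pmax(tt, lo), hi)
    proj <- outer(tt, seg_vec[s, ]) # n x k
    d2 <- rowSums((rel - proj)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lambda[upd] <- cum_len[s] + tt[upd] * seg_len[s]
  }
  shift <- min(best_lambda, 0)
  best_lambda <- best_lambda - shift
  list(lambda = best_lambda, dist2 = best_d2,
       total_length = max(best_lambda, cum_len[length(cum_len)] - shift))
}

# local-averaging smoother of y against the rank order of lambda;
# span = fraction of points in the window
smooth_against <- function(lambda, y, span) {
  n <- length(lambda)
  o <- order(lambda)
  half <- max(1L, floor(span * n / 2))
  ys <- y[o]
  cs <- cumsum(ys)
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  sm <- (cs[hi] - ifelse(lo > 1, cs[lo - 1], 0)) / (hi - lo + 1)
  out <- numeric(n)
  out[o] <- sm
  out
}

#' Fit a principal curve by the projection-expectation iteration
#'
#' Fits a one-dimensional curve through a point cloud: the curve is
#' initialized at the first principal-component segment, then the fit
#' alternates between (a) projecting every point onto the current
#' polyline to obtain its arc-length position and (b) smoothing each
#' coordinate against the arc-length ordering with a local-averaging
#' smoother, until the mean squared projection distance stabilizes. The
#' fit is deterministic given the input (no randomness); points are
#' processed in a canonical order (initial position, then coordinates as
#' tie-breaks), so the result is invariant to the input row order.
#'
#' @param points sample x k matrix (k >= 1).
#' @param span smoother span as a fraction of the sample count.
#' @param tol relative change in mean squared projection distance below
#'   which the iteration stops.
#' @param max_iter maximum iterations.
#' @return a `principal_curve_fit`: list with `curve_pts` (ordered curve
#'   points), `lambda` (per-sample arc length), `total_length`,
#'   `converged`, `iterations`, `final_change`, `mse`.
#' @export
fit_principal_curve <- function(points, span = 0.3, tol = 1e-4, max_iter = 50) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 10) stop("need >= 10 points to fit a principal curve")
  k <- ncol(points)
  ctr <- colMeans(points)
  xc <- sweep(points, 2, ctr)
  sv <- svd(xc, nu = 0, nv = 1)
  v1 <- sv$v[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1 # canonical direction
  lambda <- (xc %*% v1)[, 1]

  # canonical processing order (initial position, coordinates as
  # tie-breaks): the fit is then invariant to the input row order
  ord <- do.call(order, c(list(lambda),
                          lapply(seq_len(k), function(j) points[, j])))
  inv <- order(ord)
  points <- points[ord, , drop = FALSE]
  xc <- xc[ord, , drop = FALSE]
  lambda <- lambda[ord]

  total_span <- diff(range(lambda))
  if (total_span < 1e-12) {
    # degenerate cloud: all samples at one point
    return(structure(list(curve_pts = matrix(ctr, 1, k), lambda = rep(0, n),
                          total_length = 0, converged = TRUE, iterations = 0L,
                          final_change = 0, mse = mean(rowSums(xc^2))),
                     class = "principal_curve_fit"))
  }

  # exactly collinear cloud: the principal curve is the first-PC segment
  # and the arc-length position is the projection coordinate (closed form)
  resid_ss <- sum(xc^2) - sum(lambda^2)
  if (resid_ss <= 1e-12 * sum(xc^2)) {
    lam <- (lambda - min(lambda))[inv]
    ends <- rbind(ctr + min(lambda) * v1, ctr + max(lambda) * v1)
    return(structure(list(curve_pts = ends, lambda = lam,
                          total_length = diff(range(lambda)),
                          converged = TRUE, iterations = 0L,
                          final_change = 0, mse = resid_ss / n),
                     class = "principal_curve_fit"))
  }

  # initial curve: PC1 segment discretized at the projected positions
  make_curve <- function(coords, lambda) {
    o <- order(lambda)
    pts <- coords[o, , drop = FALSE]
    keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                               pts[-nrow(pts), , drop = FALSE])^2) > 1e-20)
    pts[keep, , drop = FALSE]
  }
  coords <- sweep(outer(lambda, v1), 2, ctr, `+`)
  curve_pts <- make_curve(coords, lambda)
  pr <- project_to_polyline(points, curve_pts)
  mse <- mean(pr$dist2)
  converged <- FALSE
  change <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    sm <- vapply(seq_len(k), function(j) {
      smooth_against(pr$lambda, points[, j], span)
    }, numeric(n))
    curve_pts <- make_curve(sm, pr$lambda)
    pr <- project_to_polyline(points, curve_pts)
    mse_new <- mean(pr$dist2)
    change <- abs(mse - mse_new) / max(mse, 1e-12)
    mse <- mse_new
    if (change < tol) { converged <- TRUE; break }
  }
  structure(list(curve_pts = curve_pts, lambda = pr$lambda[inv],
                 total_length = pr$total_length, converged = converged,
                 iterations = it, final_change = change, mse = mse),
            class = "principal_curve_fit")
}

#' Turn a fitted principal curve into pathway deregulation scores
#'
#' Orients the curve so that the reference samples (the cohort's
#' baseline, by default the zero-mutation-load subgroup) sit at the low
#' end — the curve is flipped when the reference median arc length
#' exceeds the overall median — and returns each sample's normalized arc
#' length `PDS = lambda / L` in [0, 1]. A degenerate curve of zero
#' length yields all-zero scores.
#'
#' @param fit a [fit_principal_curve()] result.
#' @param sample_ids sample identifiers aligned with the fitted points.
#' @param reference_ids non-empty subset of `sample_ids` acting as the
#'   low-deregulation anchor.
#' @param pathway pathway name carried into the result.
#' @return a `pds_result`: data.frame `sample_id`, `pds` plus attributes
#'   `pathway`, `flipped`, `converged`, `iterations`.
#' @export
pds_score <- function(fit, sample_ids, reference_ids, pathway = "pathway") {
  if (length(reference_ids) == 0) {
    stop("reference set is empty: designate reference (baseline) samples")
  }
  if (!all(reference_ids %in% sample_ids)) {
    stop("reference id(s) not in cohort: ",
         paste(setdiff(reference_ids, sample_ids), collapse = ", "))
  }
  lam <- fit$lambda
  L <- fit$total_length
  if (L <= 0) {
    pds <- rep(0, length(lam))
    flipped <- FALSE
  } else {
    ref <- sample_ids %in% reference_ids
    flipped <- stats::median(lam[ref]) > stats::median(lam)
    if (flipped) lam <- L - lam
    pds <- lam / L
  }
  out <- data.frame(sample_id = sample_ids, pds = pds, stringsAsFactors = FALSE)
  attr(out, "pathway") <- pathway
  attr(out, "flipped") <- flipped
  attr(out, "converged") <- fit$converged
  attr(out, "iterations") <- fit$iterations
  class(out) <- c("pds_result", "data.frame")
  out
}

#' Compute the pathway deregulation score for one gene set
#'
#' Convenience wrapper chaining [pds_reduce()], [fit_principal_curve()]
#' and [pds_score()].
#'
#' @param expr sample x gene matrix.
#' @param genes gene set to score.
#' @param reference_ids baseline sample ids.
#' @param pathway pathway name.
#' @param var_fraction,span,tol,max_iter see the stage functions.
#' @return a `pds_result` (see [pds_score()]); attribute `k` records the
#'   retained dimensions.
#' @export
compute_pds <- function(expr, genes = colnames(expr), reference_ids,
                        pathway = "pathway", var_fraction = 0.9, span = 0.3,
                        tol = 1e-4, max_iter = 50) {
  red <- pds_reduce(expr, genes, var_fraction = var_fraction)
  fit <- fit_principal_curve(red$scores, span = span, tol = tol,
                             max_iter = max_iter)
  out <- pds_score(fit, rownames(expr), reference_ids, pathway = pathway)
  attr(out, "k") <- red$k
  attr(out, "genes_used") <- red$genes_used
  out
}

#' Single-gene deregulation score
#'
#' One-dimensional special case of the PDS: the gene's expression is
#' min-max normalized to [0, 1] and oriented so the reference samples'
#' median sits at the low end.
#'
#' @param x expression of one gene across samples (named by sample id, or
#'   supply `sample_ids`).
#' @param reference_ids baseline sample ids.
#' @param sample_ids sample identifiers (default `names(x)`).
#' @return a `pds_result` data.frame (`sample_id`, `pds`).
#' @export
single_gene_pds <- function(x, reference_ids, sample_ids = names(x)) {
  if (is.null(sample_ids)) stop("sample ids are required")
  if (length(reference_ids) == 0) {
    stop("reference set is empty: designate reference (baseline) samples")
  }
  rng <- range(x)
  if (diff(rng) <= 0) {
    warning("constant gene: all scores set to 0")
    pds <- rep(0, length(x))
    flipped <- FALSE
  } else {
    pds <- (x - rng[1]) / diff(rng)
    ref <- sample_ids %in% reference_ids
    flipped <- stats::median(pds[ref]) > stats::median(pds)
    if (flipped) pds <- 1 - pds
  }
  out <- data.frame(sample_id = sample_ids, pds = unname(pds),
                    stringsAsFactors = FALSE)
  attr(out, "flipped") <- flipped
  class(out) <- c("pds_result", "data.frame")
  out
}
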