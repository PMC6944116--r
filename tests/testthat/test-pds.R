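test_that("dimension reduction standardizes genes and enforces the k floor", {
  set.seed(30)
  n <- 40
  t <- runif(n)
  expr <- outer(t, c(1, -2, 0.5, 1.5)) # rank-1
  dimnames(expr) <- list(sprintf("s%02d", 1:n), paste0("g", 1:4))
  red <- pds_reduce(expr, var_fraction = 0.9)
  expect_equal(red$k, 2) # floor despite rank-1 data
  expect_lt(red$sdev[2] / red$sdev[1], 1e-6)
  # gene-wise affine rescaling leaves the reduced scores unchanged
  resc <- sweep(sweep(expr, 2, c(2, 3, 0.5, 10), `*`), 2, c(1, -5, 2, 0), `+`)
  red2 <- pds_reduce(resc, var_fraction = 0.9)
  expect_equal(abs(red2$scores), abs(red$scores), tolerance = 1e-8)
  # zero-variance gene dropped with warning; too few genes is an error
  expr0 <- cbind(expr, g5 = 1)
  expect_warning(pds_reduce(expr0), "zero-variance")
  expect_error(pds_reduce(expr[, 1:2]), "usable genes")
})

test_that("collinear clouds reduce to the first-PC closed form", {
  set.seed(31)
  t <- runif(50)
  pts <- outer(t, c(1, 2, -1))
  fit <- fit_principal_curve(pts)
  proj <- (pts %*% c(1, 2, -1))[, 1] / sqrt(6)
  lam_norm <- (proj - min(proj)) / diff(range(proj))
  got <- fit$lambda / fit$total_length
  err <- min(max(abs(got - lam_norm)), max(abs(got - (1 - lam_norm))))
  expect_lt(err, 1e-8) # up to the arbitrary direction of the segment
  expect_true(fit$converged)
})

test_that("the curve fit is deterministic and permutation-equivariant", {
  co <- gen_cohort(cohort_sim_spec(n_samples = 60, seed = 17))
  ref <- co$truth$sample_id[co$truth$zero_load]
  a <- compute_pds(co$expr, reference_ids = ref)
  b <- compute_pds(co$expr, reference_ids = ref)
  expect_identical(a, b)
  # dimension reduction is permutation-equivariant
  set.seed(2)
  perm <- sample(nrow(co$expr))
  ra <- pds_reduce(co$expr)
  rb <- pds_reduce(co$expr[perm, ])
  m <- match(rownames(ra$scores), rownames(rb$scores))
  expect_equal(rb$scores[m, ], ra$scores, tolerance = 1e-6)
  # the curve fit is exactly invariant to the row order of its input
  fa <- fit_principal_curve(ra$scores)
  fb <- fit_principal_curve(ra$scores[perm, , drop = FALSE])
  expect_equal(fb$lambda, fa$lambda[perm], tolerance = 1e-12)
  expect_identical(fb$total_length, fa$total_length)
  # duplicated point set refits identically
  expect_identical(fit_principal_curve(ra$scores), fa)
})

test_that("a degenerate point cloud yields all-zero scores", {
  pts <- matrix(2, 12, 3)
  fit <- fit_principal_curve(pts)
  expect_equal(fit$total_length, 0)
  sc <- pds_score(fit, sprintf("s%d", 1:12), reference_ids = "s1")
  expect_equal(sc$pds, rep(0, 12))
})

test_that("orientation puts the reference cluster at the low end", {
  set.seed(33)
  a <- matrix(rnorm(60, 0, 0.1), 20, 3)
  b <- matrix(rnorm(60, 3, 0.1), 20, 3)
  pts <- rbind(a, b)
  ids <- sprintf("s%02d", 1:40)
  fit <- fit_principal_curve(pts)
  # anchored in cluster A
  s1 <- pds_score(fit, ids, reference_ids = ids[1:20])
  expect_lt(median(s1$pds[1:20]), median(s1$pds[21:40]))
  # anchored in cluster B flips the curve
  s2 <- pds_score(fit, ids, reference_ids = ids[21:40])
  expect_lt(median(s2$pds[21:40]), median(s2$pds[1:20]))
  expect_error(pds_score(fit, ids, character(0)), "reference")
  expect_error(pds_score(fit, ids, "nope"), "nope")
})

test_that("noiseless planted gradients are recovered in exact rank order", {
  for (mode in c("linear", "quadratic")) {
    co <- gen_cohort(cohort_sim_spec(n_samples = 70, noise_sd = 0, mode = mode,
                                     zero_fraction = 0.05, seed = 5))
    ref <- co$truth$sample_id[co$truth$zero_load]
    p <- compute_pds(co$expr, reference_ids = ref)
    expect_equal(cor(p$pds, co$truth$t, method = "spearman"), 1)
    expect_true(all(p$pds >= 0 & p$pds <= 1))
  }
})

test_that("scores are stable under leave-one-out refits", {
  co <- gen_cohort(cohort_sim_spec(seed = 21))
  ref <- co$truth$sample_id[co$truth$zero_load]
  full <- compute_pds(co$expr, reference_ids = ref)
  set.seed(1)
  drop <- sample(setdiff(rownames(co$expr), ref), 1)
  sub <- compute_pds(co$expr[rownames(co$expr) != drop, ], reference_ids = ref)
  shared <- sub$sample_id
  d <- abs(sub$pds - full$pds[match(shared, full$sample_id)])
  expect_lt(median(d), 0.05)
})

test_that("single-gene scores are oriented min-max rescalings", {
  x <- c(s1 = 1, s2 = 3, s3 = 2, s4 = 5)
  sg <- single_gene_pds(x, reference_ids = "s1")
  expect_equal(sg$pds, c(0, 0.5, 0.25, 1))
  # reference at the maximum flips the orientation
  sg2 <- single_gene_pds(x, reference_ids = "s4")
  expect_equal(sg2$pds, 1 - c(0, 0.5, 0.25, 1))
  expect_warning(sg3 <- single_gene_pds(c(a = 1, b = 1, c = 1), "a"), "constant")
  expect_equal(sg3$pds, c(0, 0, 0))
})

test_that("single-gene scores agree with the padded curve pipeline", {
  set.seed(35)
  x <- rnorm(40)
  names(x) <- sprintf("s%02d", 1:40)
  ref <- names(sort(x))[1:4]
  sg <- single_gene_pds(x, reference_ids = ref)
  padded <- cbind(scale(x)[, 1], 0)
  fit <- fit_principal_curve(padded)
  curve <- pds_score(fit, names(x), reference_ids = ref)
  expect_equal(cor(sg$pds, curve$pds, method = "spearman"), 1)
})
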