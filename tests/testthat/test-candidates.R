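fixture_stats <- function(lfc, B, ids = sprintf("g%d", seq_along(lfc))) {
  data.frame(gene_id = ids, logFC = lfc, B = B, stringsAsFactors = FALSE)
}

test_that("fold-change/B selection applies both rules", {
  st <- fixture_stats(log2(c(2.5, 3, 1.5)), c(1.2, -0.5, 2))
  expect_identical(select_differential(st, 2, 0), "g1")
  expect_identical(select_differential(fixture_stats(numeric(0), numeric(0)), 2, 0),
                   character(0))
  # down-regulation counts through |logFC|
  st2 <- fixture_stats(c(-1.5, -0.5), c(1, 1))
  expect_identical(select_differential(st2, 2, 0), "g1")
  expect_error(select_differential(st, 0.5, 0), "fc_cutoff")
})

test_that("selection is monotone in both cutoffs", {
  set.seed(20)
  for (i in 1:20) {
    st <- fixture_stats(rnorm(50, 0, 1.5), rnorm(50, 0, 2))
    base <- select_differential(st, 2, 0)
    expect_true(all(select_differential(st, 3, 0) %in% base))
    expect_true(all(select_differential(st, 2, 1) %in% base))
  }
})

test_that("G2 subtraction removes same-sign similar fold changes only", {
  u <- fixture_stats(c(2.1, 2.0, -1.8), c(2, 2, 2), c("a", "b", "c"))
  g <- fixture_stats(c(2.0, -1.9, -1.7), c(2, 2, 2), c("a", "b", "c"))
  # a: same sign, |2.1-2.0| < 1 -> removed; b: opposite sign -> kept;
  # c: same sign, |diff| < 1 -> removed
  expect_identical(subtract_g2(c("a", "b", "c"), c("a", "b", "c"), u, g, 1),
                   "b")
  # disjoint lists pass through untouched
  expect_identical(subtract_g2(c("a", "b"), "c", u, g, 1), c("a", "b"))
  expect_error(subtract_g2(c("a", "zz"), "c", u, g, 1), "zz")
})

test_that("subtraction and intersection match brute-force set rules", {
  set.seed(21)
  for (i in 1:30) {
    ids <- sprintf("g%d", 1:60)
    u <- fixture_stats(rnorm(60, 0, 2), rep(1, 60), ids)
    g <- fixture_stats(rnorm(60, 0, 2), rep(1, 60), ids)
    us <- sample(ids, 25)
    gs <- sample(ids, 20)
    got <- subtract_g2(us, gs, u, g, 1)
    want <- oracle_subtract(us, gs, setNames(u$logFC, ids),
                            setNames(g$logFC, ids), 1)
    expect_setequal(got, want)
    a <- sample(ids, 30); b <- sample(ids, 15)
    expect_setequal(intersect_platforms(a, b)$genes, intersect(a, b))
  }
})

test_that("cross-platform containment is reported", {
  big <- sprintf("g%d", 1:20)
  expect_equal(intersect_platforms(big, big[3:7])$containment, 1)
  expect_identical(intersect_platforms(big, big[3:7])$genes, big[3:7])
  out <- intersect_platforms(big[1:5], c("x", "y"))
  expect_equal(out$containment, 0)
  expect_length(out$genes, 0)
})

test_that("regulation classes follow the two-way selection", {
  tot <- fixture_stats(c(log2(1.1), log2(3), log2(4)), c(-1, 2, 2),
                       c("a", "b", "c"))
  pol <- fixture_stats(c(log2(3), log2(1.2), log2(4)), c(2, -1, 2),
                       c("a", "b", "c"))
  cl <- classify_regulation(tot, pol, 2, 0)
  expect_identical(unname(cl$class[c("a", "b", "c")]),
                   c("translational_only", "transcriptional_only", "both"))
  expect_equal(cl$summary$frac_polysome_only, 1 / 2)
  expect_equal(cl$summary$frac_total_only, 1 / 2)
  # all genes passing both gives zero exclusive fractions
  allpass <- fixture_stats(c(2, 2), c(1, 1), c("a", "b"))
  cl2 <- classify_regulation(allpass, allpass)
  expect_equal(cl2$summary$frac_polysome_only, 0)
  expect_equal(cl2$summary$n_both, 2)
  expect_error(classify_regulation(tot, fixture_stats(1, 1, "zz")),
               "universe")
})

test_that("the pipeline composition equals an end-to-end brute-force filter", {
  sim <- gen_polysome(polysome_sim_spec(n_genes = 500, seed = 13))
  cfg <- default_run_config()
  res <- candidate_pipeline(sim$microarray, sim$rnaseq, cfg)
  # brute force over the same stat tables
  g2 <- oracle_select(res$stats$g2_pol, cfg$fc_cutoff, cfg$b_cutoff)
  uvg2 <- oracle_select(res$stats$uvg2_pol, cfg$fc_cutoff, cfg$b_cutoff)
  sub <- oracle_subtract(uvg2, g2,
                         setNames(res$stats$uvg2_pol$logFC, res$stats$uvg2_pol$gene_id),
                         setNames(res$stats$g2_pol$logFC, res$stats$g2_pol$gene_id),
                         cfg$g2_similarity_logfc)
  expect_setequal(res$g2, g2)
  expect_setequal(res$uvg2_minus_g2, sub)
  rs <- oracle_subtract(
    oracle_select(res$stats$rs_uvg2_pol, cfg$fc_cutoff, cfg$b_cutoff),
    oracle_select(res$stats$rs_g2_pol, cfg$fc_cutoff, cfg$b_cutoff),
    setNames(res$stats$rs_uvg2_pol$logFC, res$stats$rs_uvg2_pol$gene_id),
    setNames(res$stats$rs_g2_pol$logFC, res$stats$rs_g2_pol$gene_id),
    cfg$g2_similarity_logfc)
  expect_setequal(res$high_confidence, intersect(sub, rs))
})

test_that("null simulations select at a low rate that shrinks with the DE prior", {
  fracs01 <- fracs001 <- numeric(10)
  for (s in 1:10) {
    spec <- polysome_sim_spec(n_genes = 400, class_prop = c(translational = 0),
                              seed = 100 + s)
    sim <- gen_polysome(spec)
    st1 <- moderated_stats(sim$microarray, "UVG2", "AS", "polysome",
                           proportion = 0.01)
    st2 <- moderated_stats(sim$microarray, "UVG2", "AS", "polysome",
                           proportion = 0.001)
    fracs01[s] <- length(select_differential(st1, 2, 0)) / 400
    fracs001[s] <- length(select_differential(st2, 2, 0)) / 400
  }
  expect_lt(mean(fracs01), 0.02)      # false positives stay near nominal
  expect_lt(sd(fracs01), 0.02)        # and stable across seeds
  expect_true(all(fracs001 <= fracs01)) # smaller prior, fewer selections
})

test_that("selection power grows with the planted effect size", {
  power <- sapply(c(1.2, 2, 3), function(eff) {
    hits <- sapply(1:15, function(s) {
      spec <- polysome_sim_spec(
        n_genes = 300, class_prop = c(translational = 0.1),
        effect_logfc = c(translational = eff), noise_sd = 0.6, seed = 200 + s)
      sim <- gen_polysome(spec)
      st <- moderated_stats(sim$microarray, "UVG2", "AS", "polysome")
      sel <- select_differential(st, 2, 0)
      planted <- sim$truth$gene_id[sim$truth$class == "translational"]
      mean(planted %in% sel)
    })
    mean(hits)
  })
  expect_true(all(diff(power) > 0))
  expect_gt(power[3], 0.9)
})
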