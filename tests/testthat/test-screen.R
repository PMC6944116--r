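test_that("DNA-content classification handles pure and scaled inputs", {
  # every cell exactly at the 2n mode
  res <- classify_dna_content(rep(500, 300))
  expect_equal(unname(res$fractions), c(1, 0, 0))
  # scale invariance: multiplying intensities leaves fractions unchanged
  set.seed(8)
  x <- draw_dna_intensity(2000, frac4n = 0.4, s_weight = 0.15,
                          mode_2n = 500, sd = 0.08)
  a <- classify_dna_content(x)
  b <- classify_dna_content(x * 7.3)
  expect_equal(a$fractions, b$fractions)
  expect_equal(b$mode_2n / a$mode_2n, 7.3, tolerance = 1e-6)
})

test_that("a planted 30% 4n population is recovered within three points", {
  set.seed(9)
  x <- draw_dna_intensity(5000, frac4n = 0.30, s_weight = 0.15,
                          mode_2n = 500, sd = 0.08)
  res <- classify_dna_content(x)
  expect_lt(abs(res$fractions[["f4n"]] - 0.30), 0.03)
  expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
})

test_that("wells below the cell floor are flagged unevaluable", {
  res <- classify_dna_content(rep(500, 150), floor = 200)
  expect_false(res$evaluable)
  expect_true(all(is.na(res$fractions)))
  expect_equal(res$n_cells, 150)
})

test_that("focus statistics: null groups give p near 1 and fold change 1", {
  ws <- do.call(rbind, c(
    lapply(1:4, function(w) ws_row("NT", "L1", "UV24", mean_foci = 4 + c(0.1, -0.1, 0.05, -0.05)[w],
                                   well = paste0("nt", w))),
    lapply(1:3, function(w) ws_row("A", "L1", "UV24", mean_foci = 4 + c(0.1, -0.1, 0)[w],
                                   well = paste0("a", w)))
  ))
  out <- foci_stats(ws)
  expect_equal(out$fold_change, 1, tolerance = 0.02)
  expect_gt(out$p_adj, 0.9)
})

test_that("two-group Tukey p equals the pooled two-sample t-test p", {
  set.seed(12)
  ws <- rbind(
    do.call(rbind, lapply(1:4, function(w) ws_row("NT", "L1", "UV24", mean_foci = rnorm(1, 4, 0.5),
                                                  well = paste0("nt", w)))),
    do.call(rbind, lapply(1:4, function(w) ws_row("A", "L1", "UV24", mean_foci = rnorm(1, 6, 0.5),
                                                  well = paste0("a", w))))
  )
  out <- foci_stats(ws)
  tt <- stats::t.test(ws$mean_foci[ws$perturbation == "A"],
                      ws$mean_foci[ws$perturbation == "NT"], var.equal = TRUE)
  expect_equal(out$p_adj, tt$p.value, tolerance = 1e-4)
})

test_that("single-replicate perturbations report a missing p value", {
  set.seed(13)
  ws <- rbind(
    do.call(rbind, lapply(1:3, function(w) ws_row("NT", "L1", "UV24", mean_foci = rnorm(1, 4, 0.3),
                                                  well = paste0("nt", w)))),
    ws_row("A", "L1", "UV24", mean_foci = 8, well = "a1"),
    do.call(rbind, lapply(1:2, function(w) ws_row("B", "L1", "UV24", mean_foci = rnorm(1, 4, 0.3),
                                                  well = paste0("b", w))))
  )
  out <- foci_stats(ws)
  expect_true(is.na(out$p_adj[out$perturbation == "A"]))
  expect_false(is.na(out$p_adj[out$perturbation == "B"]))
  expect_error(foci_stats(ws[ws$perturbation != "NT", ]), "control")
})

make_gene_summaries <- function(gene, line, viability_fc = 1, f4n24_shift = 0,
                                f4n40_shift = 0, nt_cells = 800) {
  nt24 <- 0.6; nt40 <- 0.3
  rbind(
    ws_row("NT", line, "noUV", n_cells = nt_cells, f4n = 0.25, well = paste0(line, "ntn")),
    ws_row("NT", line, "UV24", n_cells = nt_cells, f4n = nt24, well = paste0(line, "nt24")),
    ws_row("NT", line, "UV40", n_cells = nt_cells, f4n = nt40, well = paste0(line, "nt40")),
    ws_row(gene, line, "noUV", n_cells = nt_cells, f4n = 0.25, well = paste0(line, "gn")),
    ws_row(gene, line, "UV24", n_cells = nt_cells * viability_fc,
           f4n = nt24 + f4n24_shift, well = paste0(line, "g24")),
    ws_row(gene, line, "UV40", n_cells = nt_cells * viability_fc,
           f4n = nt40 + f4n40_shift, well = paste0(line, "g40"))
  )
}

null_foci <- function(gene, line) {
  data.frame(perturbation = gene, fold_change = 1, p_adj = 1, n_wells = 3,
             line = line, timepoint = c("UV24", "UV40"), stringsAsFactors = FALSE)
}

test_that("control-level phenotypes score zero and tier none", {
  ws <- rbind(make_gene_summaries("A", "L1"), make_gene_summaries("A", "L2"))
  ft <- rbind(null_foci("A", "L1"), null_foci("A", "L2"))
  sc <- score_sirna(ws, ft)
  expect_equal(sc$total, c(0, 0))
  expect_true(all(sc$tier == "none"))
})

test_that("siRNA scoring is monotone in each phenotype axis", {
  base <- score_sirna(rbind(make_gene_summaries("A", "L1"),
                            make_gene_summaries("A", "L2")),
                      rbind(null_foci("A", "L1"), null_foci("A", "L2")))
  stronger_viab <- score_sirna(rbind(make_gene_summaries("A", "L1", viability_fc = 0.4),
                                     make_gene_summaries("A", "L2")),
                               rbind(null_foci("A", "L1"), null_foci("A", "L2")))
  stronger_exit <- score_sirna(rbind(make_gene_summaries("A", "L1", f4n40_shift = 0.25),
                                     make_gene_summaries("A", "L2")),
                               rbind(null_foci("A", "L1"), null_foci("A", "L2")))
  ft_up <- rbind(data.frame(perturbation = "A", fold_change = 3, p_adj = 0.001,
                            n_wells = 3, line = "L1", timepoint = "UV24"),
                 null_foci("A", "L2"))
  stronger_foci <- score_sirna(rbind(make_gene_summaries("A", "L1"),
                                     make_gene_summaries("A", "L2")), ft_up)
  for (sc in list(stronger_viab, stronger_exit, stronger_foci)) {
    expect_true(all(sc$total >= base$total))
    expect_gt(sum(sc$total), sum(base$total))
  }
})

test_that("two-line tier rules match the published boundaries", {
  mk <- function(t1, t2) data.frame(gene = "A", line = c("L1", "L2"),
                                    total = c(t1, t2))
  # siRNA rule: >= 10 in both -> high, >= 10 in one -> low
  expect_equal(unique(uvg2pipe:::tier_two_lines(mk(12, 11), 10, FALSE)), "high")
  expect_equal(unique(uvg2pipe:::tier_two_lines(mk(12, 4), 10, FALSE)), "low")
  expect_equal(unique(uvg2pipe:::tier_two_lines(mk(9, 4), 10, FALSE)), "none")
  # overexpression rule: > 2 in both -> high, > 3 in one -> low
  expect_equal(unique(uvg2pipe:::tier_two_lines(mk(3, 3), 2, TRUE, 3)), "high")
  expect_equal(unique(uvg2pipe:::tier_two_lines(mk(4, 1), 2, TRUE, 3)), "low")
  expect_equal(unique(uvg2pipe:::tier_two_lines(mk(3, 1), 2, TRUE, 3)), "none")
  # symmetry in cell-line order
  expect_equal(unique(uvg2pipe:::tier_two_lines(mk(4, 12), 10, FALSE)),
               unique(uvg2pipe:::tier_two_lines(mk(12, 4), 10, FALSE)))
})

oe_summaries <- function(gene, line, ratio, n_used = 800) {
  rbind(
    ws_row("NT", line, "noUV", transduced_frac = 0.6, well = paste0(line, "ntn")),
    ws_row("NT", line, "UV24", f4n = 0.6, transduced_frac = 0.6, well = paste0(line, "nt24")),
    ws_row("NT", line, "UV40", transduced_frac = 0.6, well = paste0(line, "nt40")),
    ws_row(gene, line, "noUV", transduced_frac = 0.6, n_used = n_used, well = paste0(line, "gn")),
    ws_row(gene, line, "UV24", f4n = 0.6, transduced_frac = 0.6, n_used = n_used, well = paste0(line, "g24")),
    ws_row(gene, line, "UV40", transduced_frac = 0.6 * ratio, n_used = n_used, well = paste0(line, "g40"))
  )
}

test_that("overexpression viability flag follows the 25% drop rule", {
  sc70 <- score_overexpression(rbind(oe_summaries("A", "L1", 0.70),
                                     oe_summaries("A", "L2", 0.70)))
  expect_true(all(sc70$viability_flag))
  sc80 <- score_overexpression(rbind(oe_summaries("A", "L1", 0.80),
                                     oe_summaries("A", "L2", 0.80)))
  expect_false(any(sc80$viability_flag))
  # under the transduced-cell floor in every timepoint -> unevaluable
  scu <- score_overexpression(rbind(oe_summaries("A", "L1", 0.70, n_used = 100),
                                    oe_summaries("A", "L2", 0.70, n_used = 100)))
  expect_true(all(scu$tier == "unevaluable"))
})
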