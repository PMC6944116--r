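#' Classify DNA content of the cells in one well
#'
#' Fits a constrained two-mode mixture to the log2 integrated nuclear
#' stain intensities: Gaussian 2n and 4n modes with the 4n mode fixed at
#' exactly twice the 2n intensity (one log2 unit above), plus a uniform
#' S-phase bridge between the modes. The 2n location, common mode sd and
#' component weights are estimated by EM. Cells are then assigned by
#' threshold: within `margin` log2 units above the 2n mode (or anywhere
#' below it) they are 2n; within `margin` below the 4n mode (or above it)
#' they are 4n; in between they are S phase. The classification is
#' invariant to rescaling of the intensity units.
#'
#' @param intensity positive numeric vector of integrated intensities.
#' @param margin log2 distance from a mode counted as that mode.
#' @param floor minimum number of cells; below it the well is flagged
#'   unevaluable and `NA` fractions are returned.
#' @param max_iter,tol EM controls.
#' @return list with `fractions` (named: `f2n`, `fS`, `f4n`), `mode_2n`
#'   (intensity units), `evaluable`, `n_cells`, and the per-cell `phase`
#'   factor (NULL when unevaluable).
#' @export
classify_dna_content <- function(intensity, margin = 0.15, floor = 200,
                                 max_iter = 50, tol = 1e-6) {
  n <- length(intensity)
  if (n < floor) {
    return(list(fractions = c(f2n = NA_real_, fS = NA_real_, f4n = NA_real_),
                mode_2n = NA_real_, evaluable = FALSE, n_cells = n,
                phase = NULL))
  }
  if (any(intensity <= 0)) stop("intensities must be positive")
  x <- log2(intensity)

  # EM on {N(mu, sd), Unif(mu, mu+1), N(mu+1, sd)}
  mu <- stats::quantile(x, 0.25, names = FALSE)
  sd <- 0.1
  w <- c(0.4, 0.2, 0.4)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu, sd)
    d2 <- w[2] * stats::dunif(x, mu, mu + 1)
    d3 <- w[3] * stats::dnorm(x, mu + 1, sd)
    tot <- d1 + d2 + d3
    tot[tot < 1e-300] <- 1e-300
    r1 <- d1 / tot; r2 <- d2 / tot; r3 <- d3 / tot
    ll <- sum(log(tot))
    w <- c(mean(r1), mean(r2), mean(r3))
    denom <- sum(r1) + sum(r3)
    mu <- (sum(r1 * x) + sum(r3 * (x - 1))) / denom
    sd <- sqrt((sum(r1 * (x - mu)^2) + sum(r3 * (x - mu - 1)^2)) / denom)
    sd <- max(sd, 1e-3)
    if (abs(ll - ll_old) < tol * abs(ll_old)) break
    ll_old <- ll
  }

  phase <- ifelse(x <= mu + margin, "2n", ifelse(x >= mu + 1 - margin, "4n", "S"))
  phase <- factor(phase, levels = c("2n", "S", "4n"))
  fr <- as.numeric(table(phase)) / n
  list(fractions = c(f2n = fr[1], fS = fr[2], f4n = fr[3]),
       mode_2n = 2^mu, evaluable = TRUE, n_cells = n, phase = phase)
}

#' Summarize a per-cell screen table by well
#'
#' Computes, per well: cell count, DNA-content phase fractions (via
#' [classify_dna_content()]), mean RPA foci per cell, and in
#' overexpression mode the transduced fraction and transduced cell count.
#'
#' @param cells per-cell data.frame from [gen_screen()] (or equivalent:
#'   columns `well`, `perturbation`, `line`, `timepoint`, `intensity`,
#'   `foci`, optionally `transduced`).
#' @param cell_floor minimum cells per well for DNA-content evaluation.
#' @param margin S-phase margin passed to [classify_dna_content()].
#' @return data.frame with one row per well.
#' @export
summarize_wells <- function(cells, cell_floor = 200, margin = 0.15) {
  stopifnot(all(c("well", "perturbation", "line", "timepoint",
                  "intensity", "foci") %in% names(cells)))
  oe <- "transduced" %in% names(cells)
  wells <- unique(cells$well)
  out <- lapply(wells, function(w) {
    cw <- cells[cells$well == w, , drop = FALSE]
    use <- if (oe) cw[cw$transduced, , drop = FALSE] else cw
    dc <- classify_dna_content(use$intensity, margin = margin, floor = cell_floor)
    data.frame(
      well = w, perturbation = cw$perturbation[1], line = cw$line[1],
      timepoint = cw$timepoint[1], n_cells = nrow(cw),
      n_used = nrow(use),
      f2n = dc$fractions[["f2n"]], fS = dc$fractions[["fS"]],
      f4n = dc$fractions[["f4n"]], evaluable = dc$evaluable,
      mean_foci = mean(use$foci),
      transduced_frac = if (oe) mean(cw$transduced) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' RPA-focus fold changes and Tukey HSD adjusted p values
#'
#' Treats the well mean focus count as the analysis unit, fits a one-way
#' layout across perturbations within one (line, timepoint) stratum, and
#' reports for each perturbation its focus fold change relative to the
#' non-targeting control together with the Tukey HSD adjusted p value of
#' the perturbation-vs-control comparison (studentized-range family
#' correction over all pairwise comparisons).
#'
#' @param well_summaries output of [summarize_wells()] for one line and
#'   one timepoint (checked).
#' @param control name of the control perturbation.
#' @return data.frame per non-control perturbation: `perturbation`,
#'   `fold_change`, `p_adj` (NA when a group has a single well),
#'   `n_wells`.
#' @export
foci_stats <- function(well_summaries, control = "NT") {
  ws <- well_summaries
  if (length(unique(ws$line)) != 1 || length(unique(ws$timepoint)) != 1) {
    stop("foci_stats expects a single (line, timepoint) stratum")
  }
  if (!control %in% ws$perturbation) stop("control wells ('", control, "') missing")
  n_ctrl <- sum(ws$perturbation == control)
  if (n_ctrl < 3) stop("need >= 3 control replicate wells (found ", n_ctrl, ")")
  ws$perturbation <- factor(ws$perturbation)
  ws$perturbation <- stats::relevel(ws$perturbation, ref = control)
  fit <- stats::aov(mean_foci ~ perturbation, data = ws)
  tuk <- stats::TukeyHSD(fit)$perturbation
  ctrl_mean <- mean(ws$mean_foci[ws$perturbation == control])
  perts <- setdiff(levels(ws$perturbation), control)
  res <- lapply(perts, function(p) {
    nm1 <- paste0(p, "-", control)
    nm2 <- paste0(control, "-", p)
    padj <- if (nm1 %in% rownames(tuk)) tuk[nm1, "p adj"]
            else if (nm2 %in% rownames(tuk)) tuk[nm2, "p adj"] else NA_real_
    nw <- sum(ws$perturbation == p)
    if (nw < 2) padj <- NA_real_
    data.frame(perturbation = p,
               fold_change = mean(ws$mean_foci[ws$perturbation == p]) / ctrl_mean,
               p_adj = padj, n_wells = nw, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default screen-scoring rubric
#'
#' Point allocation for the five siRNA phenotype axes (each 0 / 2 / 4
#' points: weak / strong effect) and the overexpression axes. With five
#' axes at up to 4 points, a full-phenotype gene scores well above the
#' high-confidence tier boundary (total >= 10 in both cell lines); the
#' overexpression tier boundaries are > 2 (both lines) and > 3 (one
#' line). Axis thresholds are deviations from the non-targeting control:
#' cell-count fold change (UV-sensitized viability loss), 4n-fraction
#' shifts at 24 h (delayed checkpoint entry) and 40 h (blocked exit), and
#' significant RPA-focus increases or decreases.
#'
#' @return nested list of thresholds and points.
#' @export
default_screen_rubric <- function() {
  list(
    viability = list(strong = 0.5, weak = 0.75, points = c(weak = 2, strong = 4)),
    entry24 = list(strong = 0.2, weak = 0.1, points = c(weak = 2, strong = 4)),
    exit40 = list(strong = 0.2, weak = 0.1, points = c(weak = 2, strong = 4)),
    foci_up = list(alpha = 0.05, strong = 2, weak = 1.5, points = c(weak = 2, strong = 4)),
    foci_down = list(alpha = 0.05, strong = 0.5, weak = 2 / 3, points = c(weak = 2, strong = 4)),
    sirna_high_total = 10,
    oe = list(viability_drop = 0.25, viability_points = 2,
              cycle_shift = 0.1, cycle_points_24 = 1, cycle_points_40 = 2,
              high_total = 2, low_total = 3)
  )
}

# points for a graded two-threshold axis; `x` on the scale where larger =
# stronger phenotype (already oriented)
axis_points <- function(x, weak, strong, points) {
  if (is.na(x)) return(0)
  if (x >= strong) points[["strong"]] else if (x >= weak) points[["weak"]] else 0
}

#' Score the siRNA screen
#'
#' Combines the per-well summaries and focus statistics of one gene into
#' integer subscores on five axes — UV-sensitized viability loss, delayed
#' 4n accumulation at 24 h, retained 4n at 40 h, significant focus
#' increase, significant focus decrease — and totals them per cell line.
#' Confidence tiers follow the two-line rule: `high` when the total
#' reaches the tier boundary (>= 10 by default) in both cell lines, `low`
#' when in exactly one, `none` otherwise.
#'
#' @param well_summaries [summarize_wells()] output across lines and
#'   timepoints (siRNA mode).
#' @param foci_table rbind of [foci_stats()] results per (line,
#'   timepoint), with columns `line`, `timepoint` added.
#' @param rubric scoring rubric, see [default_screen_rubric()].
#' @param control control perturbation name.
#' @return data.frame per (gene, line) with axis subscores, `total`, and
#'   a per-gene `tier` column (`high`/`low`/`none`).
#' @export
score_sirna <- function(well_summaries, foci_table, rubric = default_screen_rubric(),
                        control = "NT") {
  ws <- well_summaries
  genes <- setdiff(unique(ws$perturbation), c(control, "PLK1"))
  lines <- unique(ws$line)
  grp_mean <- function(df, col) if (nrow(df)) mean(df[[col]], na.rm = TRUE) else NA_real_

  rows <- list()
  for (line in lines) {
    nt <- ws[ws$perturbation == control & ws$line == line, ]
    for (g in genes) {
      gd <- ws[ws$perturbation == g & ws$line == line, ]
      sub <- c(viability = 0, entry24 = 0, exit40 = 0, foci_up = 0, foci_down = 0)
      flags <- character()
      # viability: worst post-UV cell-count fold change vs NT
      fc_cells <- vapply(c("UV24", "UV40"), function(tp) {
        grp_mean(gd[gd$timepoint == tp, ], "n_cells") /
          grp_mean(nt[nt$timepoint == tp, ], "n_cells")
      }, numeric(1))
      if (all(is.na(fc_cells))) flags <- c(flags, "viability:missing")
      vfc <- suppressWarnings(min(fc_cells, na.rm = TRUE))
      if (is.finite(vfc)) {
        r <- rubric$viability
        # orient: smaller fold change = stronger phenotype
        sub["viability"] <- axis_points(1 - vfc, 1 - r$weak, 1 - r$strong, r$points)
      }
      # checkpoint entry at 24 h: 4n deficit vs NT
      d24 <- grp_mean(nt[nt$timepoint == "UV24" & nt$evaluable, ], "f4n") -
        grp_mean(gd[gd$timepoint == "UV24" & gd$evaluable, ], "f4n")
      if (is.na(d24)) flags <- c(flags, "entry24:missing")
      sub["entry24"] <- axis_points(d24, rubric$entry24$weak,
                                    rubric$entry24$strong, rubric$entry24$points)
      # checkpoint exit at 40 h: 4n excess vs NT
      d40 <- grp_mean(gd[gd$timepoint == "UV40" & gd$evaluable, ], "f4n") -
        grp_mean(nt[nt$timepoint == "UV40" & nt$evaluable, ], "f4n")
      if (is.na(d40)) flags <- c(flags, "exit40:missing")
      sub["exit40"] <- axis_points(d40, rubric$exit40$weak,
                                   rubric$exit40$strong, rubric$exit40$points)
      # focus axes: best supported post-UV effect
      ft <- foci_table[foci_table$perturbation == g & foci_table$line == line &
                         foci_table$timepoint %in% c("UV24", "UV40"), ]
      sig <- ft[!is.na(ft$p_adj) & ft$p_adj < rubric$foci_up$alpha, ]
      if (nrow(sig)) {
        up <- max(sig$fold_change)
        dn <- min(sig$fold_change)
        ru <- rubric$foci_up
        sub["foci_up"] <- axis_points(up, ru$weak, ru$strong, ru$points)
        rd <- rubric$foci_down
        sub["foci_down"] <- axis_points(1 / dn, 1 / rd$weak, 1 / rd$strong, rd$points)
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, line = line, t(sub), total = sum(sub),
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$tier <- tier_two_lines(res, threshold = rubric$sirna_high_total,
                             strict = FALSE)
  res
}

# two-line tier rule; strict=TRUE uses ">" (overexpression), else ">="
tier_two_lines <- function(scores, threshold, strict, low_threshold = threshold) {
  pass <- if (strict) scores$total > threshold else scores$total >= threshold
  pass_low <- if (strict) scores$total > low_threshold else scores$total >= low_threshold
  vapply(scores$gene, function(g) {
    p <- pass[scores$gene == g]
    pl <- pass_low[scores$gene == g]
    if (length(p) >= 2 && all(p)) "high"
    else if (any(pl)) "low"
    else "none"
  }, character(1))
}

#' Score the overexpression screen
#'
#' For each gene and cell line, flags a UV-sensitized viability effect
#' when the transduced fraction at 40 h post-UV drops by more than 25%
#' relative to the unirradiated control, and adds a cell-cycle axis from
#' 4n-fraction shifts. Tiers follow the overexpression rule: `high` when
#' the total exceeds 2 in both lines, `low` when it exceeds 3 in one
#' line, `none` otherwise; genes with fewer transduced cells than the
#' floor at every timepoint are `unevaluable`.
#'
#' @param well_summaries [summarize_wells()] output (overexpression mode;
#'   DNA-content fractions computed over transduced cells).
#' @param rubric rubric list, see [default_screen_rubric()].
#' @param control control perturbation name (empty vector / cells-only).
#' @param transduced_floor minimum transduced cells for evaluability.
#' @return data.frame per (gene, line) with `viability_flag`,
#'   `viability_points`, `cycle_points`, `total`, and per-gene `tier`.
#' @export
score_overexpression <- function(well_summaries, rubric = default_screen_rubric(),
                                 control = "NT", transduced_floor = 500) {
  ws <- well_summaries
  oe <- rubric$oe
  genes <- setdiff(unique(ws$perturbation), c(control, "PLK1"))
  lines <- unique(ws$line)
  grp_mean <- function(df, col) if (nrow(df)) mean(df[[col]], na.rm = TRUE) else NA_real_

  rows <- list()
  for (line in lines) {
    nt <- ws[ws$perturbation == control & ws$line == line, ]
    for (g in genes) {
      gd <- ws[ws$perturbation == g & ws$line == line, ]
      trans_by_tp <- vapply(c("noUV", "UV24", "UV40"), function(tp) {
        sum(gd$n_used[gd$timepoint == tp])
      }, numeric(1))
      evaluable <- any(trans_by_tp >= transduced_floor)
      tf0 <- grp_mean(gd[gd$timepoint == "noUV", ], "transduced_frac")
      tf40 <- grp_mean(gd[gd$timepoint == "UV40", ], "transduced_frac")
      ratio <- tf40 / tf0
      vflag <- !is.na(ratio) && ratio < (1 - oe$viability_drop)
      vpts <- if (vflag) oe$viability_points else 0
      d24 <- abs(grp_mean(gd[gd$timepoint == "UV24" & gd$evaluable, ], "f4n") -
                   grp_mean(nt[nt$timepoint == "UV24" & nt$evaluable, ], "f4n"))
      d40 <- abs(grp_mean(gd[gd$timepoint == "UV40" & gd$evaluable, ], "f4n") -
                   grp_mean(nt[nt$timepoint == "UV40" & nt$evaluable, ], "f4n"))
      cpts <- 0
      if (evaluable) {
        if (!is.na(d24) && d24 >= oe$cycle_shift) cpts <- cpts + oe$cycle_points_24
        if (!is.na(d40) && d40 >= oe$cycle_shift) cpts <- cpts + oe$cycle_points_40
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, line = line, viability_flag = vflag,
        viability_points = vpts, cycle_points = cpts, total = vpts + cpts,
        evaluable = evaluable, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$tier <- tier_two_lines(res, threshold = oe$high_total, strict = TRUE,
                             low_threshold = oe$low_total)
  uneval <- vapply(res$gene, function(g) !any(res$evaluable[res$gene == g]),
                   logical(1))
  res$tier[uneval] <- "unevaluable"
  res
}
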