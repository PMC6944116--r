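#' Phenotype archetype for a screened perturbation
#'
#' Describes how one perturbation (siRNA pool or overexpression construct)
#' deviates from the non-targeting control in the high-content readouts:
#' UV-sensitized viability, DNA-content (4n) fraction shifts at 24 h and
#' 40 h after irradiation, and RPA-focus rate multipliers.
#'
#' @param viability multiplier on cell number at the post-UV timepoints
#'   (1 = control-like; 0.2 = severe UV-sensitized killing).
#' @param d4n_24,d4n_40 additive shifts of the 4n DNA-content fraction at
#'   24 h and 40 h post-UV (negative at 24 h = delayed checkpoint entry;
#'   positive at 40 h = blocked checkpoint exit).
#' @param foci_24,foci_40 multipliers on the mean RPA foci per cell at
#'   24 h and 40 h post-UV.
#' @param transduced_drop overexpression mode only: fractional drop of the
#'   transduced percentage at UV40 relative to no-UV (0.3 = 30% drop).
#' @param lines which cell lines express the phenotype (default both).
#' @return a named list (archetype).
#' @export
screen_archetype <- function(viability = 1, d4n_24 = 0, d4n_40 = 0,
                             foci_24 = 1, foci_40 = 1,
                             transduced_drop = 0, lines = NULL) {
  stopifnot(viability > 0, foci_24 > 0, foci_40 > 0)
  list(viability = viability, d4n_24 = d4n_24, d4n_40 = d4n_40,
       foci_24 = foci_24, foci_40 = foci_40,
       transduced_drop = transduced_drop, lines = lines)
}

#' Specification for the synthetic high-content screen
#'
#' Emulates the per-cell output of a high-content imaging screen: nuclear
#' DNA stain integrated intensity (a 2n/4n mixture with an S-phase bridge)
#' and RPA focus counts per cell, for each perturbation across cell lines,
#' wells and timepoints (`noUV`, `UV24`, `UV40`). The control DNA-content
#' profile reproduces the checkpoint kinetics: 4n accumulation at 24 h
#' post-UV and recovery (2n return) by 40 h.
#'
#' @param archetypes named list of [screen_archetype()]s, one per
#'   perturbation. A non-targeting control `NT` is always added.
#' @param lines cell line identifiers.
#' @param wells_per_perturbation replicate wells per perturbation.
#' @param nt_wells replicate wells for the non-targeting control.
#' @param cells_per_well expected cells per control well (Poisson).
#' @param mode_2n 2n integrated-intensity mode (arbitrary units); the 4n
#'   mode is exactly twice this.
#' @param intensity_sd lognormal sd (log2 units) around each mode.
#' @param s_weight baseline S-phase (bridge) weight.
#' @param frac4n control 4n fraction by timepoint.
#' @param foci_mean control mean RPA foci per cell by timepoint.
#' @param foci_size negative-binomial size (inverse dispersion) for foci.
#' @param transduced_frac overexpression mode: baseline transduced fraction.
#' @param toxic_control include a `PLK1` toxic positive-control well set.
#' @param seed non-negative integer.
#' @return a `screen_sim_spec` list.
#' @export
screen_sim_spec <- function(archetypes = list(),
                            lines = c("lineA", "lineB"),
                            wells_per_perturbation = 3,
                            nt_wells = 4,
                            cells_per_well = 800,
                            mode_2n = 500,
                            intensity_sd = 0.08,
                            s_weight = 0.15,
                            frac4n = c(noUV = 0.25, UV24 = 0.60, UV40 = 0.30),
                            foci_mean = c(noUV = 1, UV24 = 8, UV40 = 4),
                            foci_size = 2,
                            transduced_frac = 0.6,
                            toxic_control = TRUE,
                            seed = 0) {
  for (a in archetypes) {
    stopifnot(a$viability > 0)
    stopifnot(all(frac4n + c(0, a$d4n_24, a$d4n_40) >= 0))
  }
  if (seed < 0 || seed != round(seed)) stop("seed must be a non-negative integer")
  structure(list(
    archetypes = archetypes, lines = lines,
    wells_per_perturbation = wells_per_perturbation, nt_wells = nt_wells,
    cells_per_well = cells_per_well, mode_2n = mode_2n,
    intensity_sd = intensity_sd, s_weight = s_weight, frac4n = frac4n,
    foci_mean = foci_mean, foci_size = foci_size,
    transduced_frac = transduced_frac, toxic_control = toxic_control,
    seed = seed
  ), class = "screen_sim_spec")
}

#' Draw synthetic integrated DNA-stain intensities
#'
#' Samples per-cell integrated nuclear stain intensities from a 2n/4n
#' lognormal mixture with the 4n mode at exactly twice the 2n mode plus a
#' uniform S-phase bridge between the modes (on the log2 scale).
#'
#' @param n number of cells.
#' @param frac4n 4n (G2/M) fraction.
#' @param s_weight S-phase bridge weight.
#' @param mode_2n 2n mode in intensity units.
#' @param sd lognormal sd (log2 units) around each mode.
#' @return numeric vector of intensities.
#' @export
draw_dna_intensity <- function(n, frac4n, s_weight, mode_2n, sd) {
  f4 <- min(max(frac4n, 0), 1 - s_weight)
  f2 <- 1 - s_weight - f4
  comp <- sample.int(3, n, replace = TRUE, prob = c(f2, s_weight, f4))
  m <- log2(mode_2n)
  x <- numeric(n)
  x[comp == 1] <- stats::rnorm(sum(comp == 1), m, sd)
  x[comp == 2] <- stats::runif(sum(comp == 2), m, m + 1)
  x[comp == 3] <- stats::rnorm(sum(comp == 3), m + 1, sd)
  2^x
}

#' Generate a synthetic per-cell screen table
#'
#' @param spec a [screen_sim_spec()].
#' @param mode `"sirna"` or `"oe"` (overexpression adds a `transduced`
#'   column and applies `transduced_drop` at UV40).
#' @return data.frame with one row per cell: `well`, `perturbation`,
#'   `line`, `timepoint`, `intensity`, `foci`, and `transduced` in
#'   overexpression mode.
#' @export
gen_screen <- function(spec, mode = c("sirna", "oe")) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  mode <- match.arg(mode)
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)

  perts <- c("NT", names(spec$archetypes))
  if (spec$toxic_control && mode == "sirna") perts <- c(perts, "PLK1")
  tps <- c("noUV", "UV24", "UV40")
  rows <- list()
  for (line in spec$lines) {
    for (pert in perts) {
      arch <- if (pert %in% names(spec$archetypes)) {
        spec$archetypes[[pert]]
      } else if (pert == "PLK1") {
        screen_archetype(viability = 0.25)
      } else screen_archetype()
      active <- is.null(arch$lines) || line %in% arch$lines
      if (!active) arch <- screen_archetype()
      nw <- if (pert == "NT") spec$nt_wells else spec$wells_per_perturbation
      for (w in seq_len(nw)) {
        for (tp in tps) {
          viab <- if (tp == "noUV") 1 else arch$viability
          ncell <- stats::rpois(1, spec$cells_per_well * viab)
          if (ncell == 0) next
          f4 <- spec$frac4n[[tp]] +
            switch(tp, noUV = 0, UV24 = arch$d4n_24, UV40 = arch$d4n_40)
          fm <- spec$foci_mean[[tp]] *
            switch(tp, noUV = 1, UV24 = arch$foci_24, UV40 = arch$foci_40)
          intensity <- draw_dna_intensity(ncell, f4, spec$s_weight,
                                          spec$mode_2n, spec$intensity_sd)
          foci <- stats::rnbinom(ncell, mu = fm, size = spec$foci_size)
          rec <- data.frame(
            well = sprintf("%s_%s_%s_w%d", line, pert, tp, w),
            perturbation = pert, line = line, timepoint = tp,
            intensity = intensity, foci = foci, stringsAsFactors = FALSE
          )
          if (mode == "oe") {
            tf <- spec$transduced_frac *
              (if (tp == "UV40") 1 - arch$transduced_drop else 1)
            rec$transduced <- stats::runif(ncell) < tf
          }
          rows[[length(rows) + 1]] <- rec
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
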