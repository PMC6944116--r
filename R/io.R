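#' Construct an expression dataset
#'
#' Bundles a gene x sample expression matrix with per-sample metadata
#' describing the experimental cell each column comes from: cell-cycle
#' condition (`AS` asynchronous, `G2` synchronized G2 phase, `UVG2`
#' UV-irradiated G2 checkpoint-arrested), mRNA fraction (`total` cellular
#' mRNA or `polysome`-bound mRNA from sucrose-gradient fractionation), and
#' biological replicate number.
#'
#' @param values numeric gene x sample matrix. Log2 intensities for
#'   `platform = "microarray"`; non-negative integer counts for
#'   `platform = "rnaseq"`.
#' @param sample_meta data.frame with one row per column of `values` and
#'   columns `sample_id`, `condition`, `fraction`, `replicate`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `sample_meta`, `platform`.
#' @export
expression_dataset <- function(values, sample_meta, platform = c("microarray", "rnaseq")) {
  platform <- match.arg(platform)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix must have gene ids as rownames")
  if (is.null(colnames(values))) stop("expression matrix must have sample ids as colnames")
  ds <- structure(list(
    values = values,
    gene_ids = rownames(values),
    sample_ids = colnames(values),
    sample_meta = as.data.frame(sample_meta),
    platform = platform
  ), class = "expression_dataset")
  validate_expression_dataset(ds)
  ds
}

VALID_CONDITIONS <- c("AS", "G2", "UVG2")
VALID_FRACTIONS <- c("total", "polysome")

#' Validate an expression dataset
#'
#' Checks the structural invariants: matching dimensions, unique gene ids,
#' known condition/fraction labels, positive integer replicates, no missing
#' values, and (for RNA-seq) non-negative integer counts.
#'
#' @param ds an `expression_dataset`.
#' @return `ds`, invisibly; stops with an informative error otherwise.
#' @export
validate_expression_dataset <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  v <- ds$values
  meta <- ds$sample_meta
  req <- c("sample_id", "condition", "fraction", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("sample_meta is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(v) != length(ds$gene_ids)) stop("gene_ids length does not match matrix rows")
  if (ncol(v) != length(ds$sample_ids)) stop("sample_ids length does not match matrix columns")
  dup <- ds$gene_ids[duplicated(ds$gene_ids)]
  if (length(dup)) stop("duplicate gene_ids: ", paste(unique(dup), collapse = ", "))
  extra <- setdiff(ds$sample_ids, meta$sample_id)
  if (length(extra)) stop("sample_meta is missing sample id(s): ", paste(extra, collapse = ", "))
  dup_s <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup_s)) stop("duplicate sample ids in metadata: ", paste(unique(dup_s), collapse = ", "))
  bad_c <- setdiff(unique(meta$condition), VALID_CONDITIONS)
  if (length(bad_c)) stop("unknown condition label(s): ", paste(bad_c, collapse = ", "))
  bad_f <- setdiff(unique(meta$fraction), VALID_FRACTIONS)
  if (length(bad_f)) stop("unknown fraction label(s): ", paste(bad_f, collapse = ", "))
  if (any(!is.finite(meta$replicate)) || any(meta$replicate < 1) ||
      any(meta$replicate != round(meta$replicate))) {
    stop("replicate must be a positive integer")
  }
  if (anyNA(v)) stop("expression matrix contains missing values; imputation is not supported")
  if (ds$platform == "rnaseq") {
    if (any(v < 0)) stop("rnaseq counts must be non-negative")
    if (any(v != round(v))) {
      bad <- which(v != round(v), arr.ind = TRUE)[1, ]
      stop(sprintf("rnaseq counts must be integers; value %g at gene '%s', sample '%s'",
                   v[bad[1], bad[2]], rownames(v)[bad[1]], colnames(v)[bad[2]]))
    }
  }
  invisible(ds)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset (%s): %d genes x %d samples\n",
              x$platform, length(x$gene_ids), length(x$sample_ids)))
  tab <- table(x$sample_meta$condition, x$sample_meta$fraction)
  print(tab)
  invisible(x)
}

# Metadata rows aligned to the column order of the matrix.
aligned_meta <- function(ds) {
  ds$sample_meta[match(ds$sample_ids, ds$sample_meta$sample_id), , drop = FALSE]
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix file is a delimited table whose header row holds sample ids
#' and whose first column holds gene ids; the metadata table is keyed by
#' sample id. Row and column order are preserved.
#'
#' @param path path to the expression matrix (TSV by default).
#' @param meta_path path to the sample metadata table with columns
#'   `sample_id`, `condition`, `fraction`, `replicate`.
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param sep field separator; tab by default, use `","` for CSV.
#' @return a validated [expression_dataset()].
#' @export
read_expression <- function(path, meta_path, platform = c("microarray", "rnaseq"),
                            sep = "\t") {
  platform <- match.arg(platform)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           row.names = 1, stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  expression_dataset(as.matrix(tab), meta, platform = platform)
}

#' Write an expression dataset to disk
#'
#' @param ds an `expression_dataset`.
#' @param path output path for the matrix.
#' @param meta_path output path for the sample metadata.
#' @param sep field separator.
#' @return invisibly, the paths written.
#' @export
write_expression <- function(ds, path, meta_path, sep = "\t") {
  validate_expression_dataset(ds)
  df <- data.frame(gene_id = ds$gene_ids, ds$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(ds$sample_meta, meta_path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then members. When the description field carries a
#' `subset=LABEL` token, the label is attached to the set (used here for
#' the checkpoint / repair / MASTL-axis subsets of the pathway panel).
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: named list of character vectors with a
#'   `subsets` attribute (named character vector, possibly NA).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  sets <- list()
  subsets <- character()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) stop(sprintf("empty line at line %d of %s", i, path))
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop(sprintf("line %d: gene set '%s' is empty", i, f[1]))
    nm <- f[1]
    if (nm %in% names(sets)) stop(sprintf("line %d: duplicate gene set name '%s'", i, nm))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("line %d: gene set '%s' is empty", i, nm))
    if (anyDuplicated(members)) {
      stop(sprintf("line %d: duplicate members in set '%s'", i, nm))
    }
    sets[[nm]] <- members
    sub <- regmatches(f[2], regexpr("subset=[^;[:space:]]+", f[2]))
    subsets[nm] <- if (length(sub)) sub("subset=", "", sub) else NA_character_
  }
  structure(sets, subsets = subsets, class = "gene_set_collection")
}

#' Write gene sets to a GMT file
#'
#' @param sets a `gene_set_collection` or named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions; subset labels are
#'   emitted as `subset=LABEL` when present on the collection.
#' @return invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  subs <- attr(sets, "subsets")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else if (!is.null(subs) && !is.na(subs[nm])) {
      paste0("subset=", subs[nm])
    } else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default run configuration
#'
#' Central home for the pipeline's tunable constants: the candidate
#' selection thresholds (fold change 2 and B > 0), the G2-subtraction
#' fold-change similarity window, the mutation-load subgroup boundaries
#' (3.6 and 54.6 mutations per Mb), the PDS dimension-reduction variance
#' fraction and curve-fit tolerances, and the screen-scoring rubric.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    fc_cutoff = 2,            # fold-change selection cutoff (linear scale)
    b_cutoff = 0,             # B-statistic cutoff (log posterior odds)
    de_proportion = 0.01,     # prior proportion of DE genes for the B statistic
    g2_similarity_logfc = 1,  # same-sign log2FC window for G2 subtraction
    load_boundaries = c(3.6, 54.6),  # mutations/Mb subgroup boundaries
    pca_var_fraction = 0.9,
    curve_tol = 1e-4,
    curve_max_iter = 50L,
    curve_span = 0.3,
    s_phase_margin = 0.15,    # log2 distance from a DNA-content mode counted as that mode
    cell_floor = 200L,        # minimum cells per well for DNA-content analysis
    transduced_floor = 500L,  # minimum transduced cells for overexpression cell-cycle calls
    rubric = default_screen_rubric(),
    seed = 0L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  num <- c("fc_cutoff", "b_cutoff", "de_proportion", "g2_similarity_logfc",
           "pca_var_fraction", "curve_tol", "s_phase_margin")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || !all(is.finite(cfg[[f]]))) {
      stop("config field '", f, "' must be finite numeric")
    }
  }
  lb <- cfg$load_boundaries
  if (length(lb) != 2 || any(!is.finite(lb)) || lb[1] <= 0 || diff(lb) <= 0) {
    stop("load_boundaries must be two strictly increasing positive values")
  }
  if (cfg$fc_cutoff < 1) stop("fc_cutoff must be >= 1")
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) stop("seed must be a non-negative integer")
  invisible(cfg)
}

#' Read a run configuration from YAML or JSON
#'
#' Fields not present in the file keep their defaults.
#'
#' @param path a `.yaml`/`.yml` or `.json` file of overrides.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  over <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(default_run_config, over)
}

#' Write a run configuration
#'
#' @param cfg a `run_config`.
#' @param path output path (`.yaml` or `.json` decides the format).
#' @return invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Path to the synthetic 43-gene UV-G2 checkpoint panel
#'
#' A synthetic stand-in panel of 43 gene symbols with checkpoint / repair /
#' MASTL-axis subset labels, shipped as a GMT file. The membership is
#' illustrative, not a reproduction of any published supplementary table.
#'
#' @return file path to the GMT file.
#' @export
uvg2_panel_path <- function() {
  system.file("extdata", "uvg2_panel_synthetic.gmt", package = "uvg2pipe",
              mustWork = TRUE)
}
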