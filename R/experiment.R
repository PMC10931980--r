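#' Time-course experiment container
#'
#' Bundles an abundance matrix (features in rows, samples in columns; FPKM
#' for expression, arbitrary units for metabolites) with its sample design.
#' The design carries one row per sample with the condition label, hours
#' since treatment start, replicate index, and a derived light/dark flag.
#'
#' @param values Numeric matrix, features x samples, non-negative. Row names
#'   are feature ids, column names sample ids.
#' @param design Data frame with columns `sample_id`, `condition`, `time_h`,
#'   `replicate`. Extra columns are kept.
#' @param photoperiod Two hours `c(on, off)` delimiting the light window of
#'   each 24-h day; default 16 h light : 8 h dark.
#'
#' @return An object of class `tc_experiment`: a list with elements
#'   `values`, `design` (tibble, with a derived logical `light` column) and
#'   `photoperiod`.
#' @export
tc_experiment <- function(values, design, photoperiod = c(0, 16)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry feature row names and sample column names.")
  }
  design <- as_tibble(design)
  req <- c("sample_id", "condition", "time_h", "replicate")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols)) {
    abort(paste0("design is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  only_mat <- setdiff(colnames(values), design$sample_id)
  only_des <- setdiff(design$sample_id, colnames(values))
  if (length(only_mat) || length(only_des)) {
    abort(paste0(
      "sample ids in matrix and design do not match 1:1.",
      if (length(only_mat)) paste0(" Matrix only: ",
                                   paste(only_mat, collapse = ", "), ".") else "",
      if (length(only_des)) paste0(" Design only: ",
                                   paste(only_des, collapse = ", "), ".") else ""
    ))
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    abort(paste0("negative abundance at [",
                 rownames(values)[neg[1, 1]], ", ",
                 colnames(values)[neg[1, 2]], "] (",
                 nrow(neg), " cell(s) total); abundances must be >= 0."))
  }
  if (any(design$time_h < 0)) abort("time_h must be >= 0.")
  key <- paste(design$condition, design$time_h, design$replicate)
  if (anyDuplicated(key)) {
    abort("(condition, time_h, replicate) must be unique across samples.")
  }
  # align design to matrix column order
  design <- design[match(colnames(values), design$sample_id), ]
  design$light <- in_light(design$time_h, photoperiod)
  structure(
    list(values = values, design = design, photoperiod = photoperiod),
    class = "tc_experiment"
  )
}

#' @export
print.tc_experiment <- function(x, ...) {
  cat("<tc_experiment> ", nrow(x$values), " features x ",
      ncol(x$values), " samples\n", sep = "")
  cat("  conditions: ", paste(unique(x$design$condition), collapse = ", "),
      "\n  time points (h): ",
      paste(sort(unique(x$design$time_h)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.tc_experiment <- function(x) dim(x$values)

#' Long-format view of a time-course experiment
#'
#' @param x A [tc_experiment()].
#' @param ... Unused.
#' @return Tibble with one row per (feature, sample) and the design columns.
#' @export
#' @exportS3Method tibble::as_tibble
as_tibble.tc_experiment <- function(x, ...) {
  tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  ) %>%
    left_join(x$design, by = "sample_id")
}

#' Subset an experiment to one or more conditions
#'
#' @param exp A [tc_experiment()].
#' @param conditions Character vector of condition labels to keep.
#' @return A `tc_experiment` restricted to the matching samples.
#' @export
filter_condition <- function(exp, conditions) {
  stopifnot(inherits(exp, "tc_experiment"))
  keep <- exp$design$condition %in% conditions
  if (!any(keep)) abort("no samples match the requested condition(s).")
  tc_experiment(exp$values[, exp$design$sample_id[keep], drop = FALSE],
                exp$design[keep, setdiff(names(exp$design), "light")],
                photoperiod = exp$photoperiod)
}

#' Per-time-point replicate means for one condition
#'
#' @param exp A [tc_experiment()].
#' @param condition Single condition label; may be omitted when the
#'   experiment holds only one condition.
#' @return Features x time-points matrix of replicate means; column names
#'   are the time points in hours, ascending.
#' @export
timepoint_means <- function(exp, condition = NULL) {
  stopifnot(inherits(exp, "tc_experiment"))
  des <- exp$design
  if (is.null(condition)) {
    if (length(unique(des$condition)) > 1L) {
      abort("experiment holds several conditions; pass `condition`.")
    }
  } else {
    des <- des[des$condition == condition, ]
    if (!nrow(des)) abort(paste0("condition not found: ", condition))
  }
  tps <- sort(unique(des$time_h))
  out <- vapply(tps, function(tp) {
    ids <- des$sample_id[des$time_h == tp]
    rowMeans(exp$values[, ids, drop = FALSE])
  }, numeric(nrow(exp$values)))
  out <- matrix(out, nrow = nrow(exp$values),
                dimnames = list(rownames(exp$values), tps))
  out
}

#' Read an expression (or metabolite) matrix with its sample sheet
#'
#' Both files are tab-delimited. The matrix has feature ids in the first
#' column and one column per sample; the sample sheet has columns
#' `sample_id`, `condition`, `time_h`, `replicate`.
#'
#' @param matrix_path,design_path Paths to the two TSV files.
#' @param photoperiod Light window, see [tc_experiment()].
#' @return A validated [tc_experiment()].
#' @export
read_expression <- function(matrix_path, design_path, photoperiod = c(0, 16)) {
  # base reader: strtod parsing is correctly rounded, so matrices written
  # by write_experiment() round-trip bit-exactly
  mat_df <- utils::read.delim(matrix_path, check.names = FALSE,
                              colClasses = "character")
  if (ncol(mat_df) < 2L) abort("matrix file must have >= 1 sample column.")
  values <- vapply(mat_df[, -1, drop = FALSE], as.numeric,
                   numeric(nrow(mat_df)))
  values <- matrix(values, nrow = nrow(mat_df),
                   dimnames = list(mat_df[[1]], colnames(mat_df)[-1]))
  design <- readr::read_tsv(design_path, show_col_types = FALSE,
                            progress = FALSE)
  tc_experiment(values, design, photoperiod = photoperiod)
}

#' Write an experiment as a matrix TSV plus sample-sheet TSV
#'
#' Values are written with R's shortest round-trip representation, so a
#' [read_expression()] of the output reproduces the matrix exactly.
#'
#' @param exp A [tc_experiment()].
#' @param matrix_path,design_path Output paths.
#' @return `exp`, invisibly.
#' @export
write_experiment <- function(exp, matrix_path, design_path) {
  stopifnot(inherits(exp, "tc_experiment"))
  num <- apply(exp$values, 2, function(col) sprintf("%.17g", col))
  out <- dplyr::bind_cols(
    tibble(feature = rownames(exp$values)),
    as_tibble(matrix(num, nrow(exp$values),
                     dimnames = dimnames(exp$values)))
  )
  readr::write_tsv(out, matrix_path, progress = FALSE)
  readr::write_tsv(
    exp$design[, setdiff(names(exp$design), "light")], design_path,
    progress = FALSE
  )
  invisible(exp)
}

#' Log-transform abundances
#'
#' Elementwise `log2(value + pseudocount)`; the conventional normalization
#' for FPKM-scale expression.
#'
#' @param exp A [tc_experiment()] or a non-negative numeric matrix.
#' @param pseudocount Positive offset added before the log; default 1.
#' @return The transformed matrix.
#' @export
log_transform <- function(exp, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0.")
  values <- if (inherits(exp, "tc_experiment")) exp$values else exp
  if (any(values < 0)) abort("values must be non-negative.")
  log2(values + pseudocount)
}

#' Dark-to-light growth-rate ratio
#'
#' Ratio of elongation rate in darkness to that in light (V_D/V_L), the
#' summary used to quantify rhythmic leaf growth.
#'
#' @param rates_dark,rates_light Positive rates, recycled elementwise.
#' @return Numeric vector of ratios.
#' @export
growth_rate_ratio <- function(rates_dark, rates_light) {
  if (any(rates_dark <= 0) || any(rates_light <= 0)) {
    abort("rates must be positive.")
  }
  rates_dark / rates_light
}
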