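# B-spline soft-binning weights for one variable: each observation spreads
# unit mass over `bins` basis functions of the given spline order (the
# estimator of Daub et al. used by the original CLR work)
bspline_weights <- function(x, bins = 6, order = 3) {
  n <- length(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(NULL)  # constant variable
  top <- bins - order + 1
  z <- (x - rng[1]) / (rng[2] - rng[1]) * top
  z <- pmin(z, top * (1 - 1e-9))  # keep the right endpoint inside the basis
  knots <- c(rep(0, order), seq_len(bins - order), rep(top, order))
  splines::splineDesign(knots, z, ord = order)
}

mi_from_weights <- function(wx, wy) {
  n <- nrow(wx)
  pxy <- crossprod(wx, wy) / n
  px <- colMeans(wx)
  py <- colMeans(wy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

mi_hard_bins <- function(x, y, bins) {
  n <- length(x)
  bx <- ceiling(rank(x, ties.method = "first") * bins / n)
  by <- ceiling(rank(y, ties.method = "first") * bins / n)
  pxy <- table(bx, by) / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
}

#' Mutual information between two profiles
#'
#' Plug-in mutual information (nats) from a discretized joint density.
#' The default estimator spreads each observation over third-order
#' B-spline basis functions (soft binning), which is smooth in the data
#' and non-negative by construction; `"bins"` switches to equal-frequency
#' hard binning.
#'
#' @param x,y Equal-length numeric vectors, n >= 8.
#' @param estimator `"bspline"` (default) or `"bins"`.
#' @param bins Number of bins (default 6).
#' @param order Spline order for the default estimator.
#' @return Mutual information in nats; 0 for a constant vector.
#' @export
mutual_information <- function(x, y, estimator = c("bspline", "bins"),
                               bins = 6, order = 3) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) abort("`x`/`y` length mismatch.")
  if (length(x) < 8L) abort("mutual information needs n >= 8.")
  if (sd(x) == 0 || sd(y) == 0) return(0)
  if (estimator == "bins") return(mi_hard_bins(x, y, bins))
  wx <- bspline_weights(x, bins, order)
  wy <- bspline_weights(y, bins, order)
  mi_from_weights(wx, wy)
}

#' Pairwise mutual-information matrix
#'
#' @param mat Features x samples matrix.
#' @inheritParams mutual_information
#' @return Symmetric features x features MI matrix (diagonal 0).
#' @export
mi_matrix <- function(mat, estimator = c("bspline", "bins"), bins = 6,
                      order = 3) {
  estimator <- match.arg(estimator)
  n <- nrow(mat)
  out <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (estimator == "bspline") {
    ws <- purrr::map(seq_len(n), function(i) bspline_weights(mat[i, ], bins, order))
    for (i in seq_len(n - 1)) {
      if (is.null(ws[[i]])) next
      for (j in (i + 1):n) {
        if (is.null(ws[[j]])) next
        out[i, j] <- out[j, i] <- mi_from_weights(ws[[i]], ws[[j]])
      }
    }
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (sd(mat[i, ]) == 0 || sd(mat[j, ]) == 0) next
        out[i, j] <- out[j, i] <- mi_hard_bins(mat[i, ], mat[j, ], bins)
      }
    }
  }
  out
}

#' CLR background z-scores
#'
#' For gene i, each pairwise MI is standardized against the mean and
#' standard deviation of gene i's off-diagonal MI values and floored at 0
#' (the context likelihood of relatedness background correction).
#'
#' @param mi Square symmetric MI matrix (diagonal ignored).
#' @return Matrix `z` with `z[i, j]` = gene i's background z-score for
#'   pair (i, j); rows with zero background sd are all 0.
#' @export
clr_zscores <- function(mi) {
  if (!is.matrix(mi) || nrow(mi) != ncol(mi)) abort("`mi` must be square.")
  if (max(abs(mi - t(mi))) > 1e-9) abort("`mi` must be symmetric (1e-9).")
  n <- nrow(mi)
  z <- matrix(0, n, n, dimnames = dimnames(mi))
  for (i in seq_len(n)) {
    off <- mi[i, -i]
    s <- sd(off)
    if (is.na(s) || s == 0) next
    z[i, ] <- pmax(0, (mi[i, ] - mean(off)) / s)
    z[i, i] <- 0
  }
  z
}

#' Combined CLR edge score
#'
#' Euclidean combination `f = sqrt(z_i^2 + z_j^2)` of the two endpoint
#' background z-scores; an edge is conventionally retained when f exceeds
#' 4.5 (strictly).
#'
#' @param z_i,z_j Non-negative z-scores (vectorized).
#' @return Numeric f.
#' @export
clr_score <- function(z_i, z_j) {
  if (any(z_i < 0) || any(z_j < 0)) abort("z-scores must be >= 0.")
  sqrt(z_i^2 + z_j^2)
}

#' Infer a TF -> target network with CLR
#'
#' Computes pairwise mutual information over the analysis genes (TFs plus
#' targets) on log2(value + 1) profiles, standardizes each gene's MI
#' against its own background, combines endpoint z-scores as
#' `f = sqrt(z_tf^2 + z_target^2)`, and keeps TF -> target pairs with
#' `f > threshold` (strict).
#'
#' @param exp A [tc_experiment()]; by default all conditions' samples are
#'   used as observations.
#' @param tf_ids Character vector of transcription-factor feature ids
#'   (non-empty).
#' @param target_ids Candidate targets; defaults to all non-TF features.
#' @param threshold Edge cutoff on f (default 4.5; pass -1 to rank all
#'   pairs).
#' @param condition Optional single condition to restrict the profiles.
#' @inheritParams mutual_information
#' @return Tibble of class `grn_edges`, columns `tf`, `target`, `mi`,
#'   `z_tf`, `z_target`, `f`, sorted by decreasing f; estimator settings
#'   in attribute `metadata`.
#' @export
build_grn <- function(exp, tf_ids, target_ids = NULL, threshold = 4.5,
                      condition = NULL, estimator = c("bspline", "bins"),
                      bins = 6) {
  stopifnot(inherits(exp, "tc_experiment"))
  estimator <- match.arg(estimator)
  if (!length(tf_ids)) abort("`tf_ids` must be non-empty.")
  if (!is.null(condition)) exp <- filter_condition(exp, condition)
  feats <- rownames(exp$values)
  bad <- setdiff(tf_ids, feats)
  if (length(bad)) abort(paste0("unknown TF id(s): ",
                                paste(head(bad, 5), collapse = ", ")))
  if (is.null(target_ids)) target_ids <- setdiff(feats, tf_ids)
  bad <- setdiff(target_ids, feats)
  if (length(bad)) abort(paste0("unknown target id(s): ",
                                paste(head(bad, 5), collapse = ", ")))
  genes <- union(tf_ids, target_ids)
  prof <- log2(exp$values[genes, , drop = FALSE] + 1)
  mi <- mi_matrix(prof, estimator = estimator, bins = bins)
  z <- clr_zscores(mi)
  edges <- tidyr::expand_grid(tf = tf_ids, target = target_ids) %>%
    filter(.data$tf != .data$target) %>%
    mutate(
      mi = mi[cbind(.data$tf, .data$target)],
      z_tf = z[cbind(.data$tf, .data$target)],
      z_target = z[cbind(.data$target, .data$tf)],
      f = clr_score(.data$z_tf, .data$z_target)
    ) %>%
    filter(.data$f > threshold) %>%
    arrange(dplyr::desc(.data$f))
  attr(edges, "metadata") <- list(estimator = estimator, bins = bins,
                                  threshold = threshold,
                                  n_samples = ncol(prof))
  class(edges) <- c("grn_edges", class(edges))
  edges
}
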