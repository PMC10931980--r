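#' Pearson correlation between biological replicates
#'
#' For every (condition, time point) cell with at least two replicates,
#' correlates each replicate pair on the log2(value + 1) scale across all
#' features. Cells with fewer than two replicates are skipped with a
#' warning.
#'
#' @param exp A [tc_experiment()].
#' @return Tibble with columns `condition`, `time_h`, `rep_a`, `rep_b`,
#'   `r`. The mean squared correlation over all pairs is attached as
#'   attribute `mean_r_squared`.
#' @export
replicate_correlation <- function(exp) {
  stopifnot(inherits(exp, "tc_experiment"))
  lv <- log_transform(exp)
  des <- exp$design
  cells <- distinct(des, .data$condition, .data$time_h)
  rows <- purrr::pmap(cells, function(condition, time_h) {
    sub <- des[des$condition == condition & des$time_h == time_h, ]
    if (nrow(sub) < 2L) {
      warn(paste0("cell (", condition, ", ", time_h,
                  " h) has < 2 replicates; skipped."))
      return(NULL)
    }
    pr <- combn(seq_len(nrow(sub)), 2)
    purrr::map(seq_len(ncol(pr)), function(k) {
      a <- sub[pr[1, k], ]; b <- sub[pr[2, k], ]
      tibble(condition = condition, time_h = time_h,
             rep_a = a$replicate, rep_b = b$replicate,
             r = cor(lv[, a$sample_id], lv[, b$sample_id]))
    }) %>% bind_rows()
  }) %>% bind_rows()
  attr(rows, "mean_r_squared") <- mean(rows$r^2)
  rows
}

#' Principal component analysis of samples on z-scored features
#'
#' Each feature's log2(value + 1) profile is standardized across samples
#' (constant features dropped with a warning) before the samples are
#' projected onto principal components.
#'
#' @param exp A [tc_experiment()].
#' @param log2p1 Standardize the log2(value + 1) matrix (default) rather
#'   than raw abundances.
#' @return Object of class `pca_result`: list with `scores` (tibble of
#'   sample design columns plus PCs) and `explained` (variance fractions,
#'   non-increasing, summing to <= 1).
#' @export
pca_scores <- function(exp, log2p1 = TRUE) {
  stopifnot(inherits(exp, "tc_experiment"))
  if (ncol(exp$values) < 2L) abort("PCA needs at least 2 samples.")
  v <- if (log2p1) log_transform(exp) else exp$values
  sds <- apply(v, 1, sd)
  if (any(sds == 0)) {
    warn(paste0(sum(sds == 0), " constant feature(s) dropped before PCA."))
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!nrow(v)) abort("no non-constant features left for PCA.")
  z <- (v - rowMeans(v)) / sds
  fit <- prcomp(t(z), center = FALSE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x)
  scores <- dplyr::bind_cols(exp$design, scores)
  structure(list(scores = scores, explained = explained, rotation = fit$rotation),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " samples, PC1 ",
      sprintf("%.1f%%", 100 * x$explained[1]), " of variance\n", sep = "")
  invisible(x)
}

#' @rdname pca_scores
#' @param x A `pca_result`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.pca_result <- function(x, ...) x$scores

#' @rdname pca_scores
#' @export
#' @exportS3Method generics::glance
glance.pca_result <- function(x, ...) {
  tibble(n_components = length(x$explained),
         pc1_var = x$explained[1],
         pc2_var = if (length(x$explained) > 1) x$explained[2] else NA_real_)
}

#' Cluster temporal expression patterns
#'
#' Partitions features by their fold-change (or abundance) profiles,
#' k-means with multiple restarts by default; Ward hierarchical clustering
#' is available and also serves as the fallback when k-means yields an
#' empty cluster.
#'
#' @param mat Features x time matrix of finite values (typically log2
#'   fold-changes).
#' @param k Number of clusters (default 15, the usual granularity for a
#'   48-h DEG panel).
#' @param seed RNG seed; fixed seed gives a deterministic partition.
#' @param method `"kmeans"` (default) or `"hclust"` (Ward.D2 + cutree).
#' @param nstart Restarts for k-means.
#' @return Tibble with columns `feature`, `cluster` (1..k, every cluster
#'   non-empty).
#' @export
cluster_patterns <- function(mat, k = 15, seed = 1L,
                             method = c("kmeans", "hclust"), nstart = 25) {
  method <- match.arg(method)
  if (!is.matrix(mat) || !all(is.finite(mat))) {
    abort("`mat` must be a numeric matrix of finite values.")
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("f", seq_len(nrow(mat)))
  if (k > nrow(mat)) abort("`k` exceeds the number of features.")
  assign_hclust <- function() {
    hc <- hclust(dist(mat), method = "ward.D2")
    cutree(hc, k = k)
  }
  cl <- if (method == "hclust") {
    assign_hclust()
  } else {
    set.seed(seed)
    fit <- tryCatch(
      suppressWarnings(kmeans(mat, centers = k, nstart = nstart,
                              iter.max = 100)),
      error = function(e) NULL
    )
    if (is.null(fit) || length(unique(fit$cluster)) < k) assign_hclust()
    else fit$cluster
  }
  tibble(feature = rownames(mat), cluster = as.integer(cl))
}

#' Over-representation test for user-supplied gene sets
#'
#' Hypergeometric upper-tail probability of the observed overlap between a
#' gene set of interest and each annotation term, with Benjamini-Hochberg
#' adjustment across terms.
#'
#' @param gene_set Character vector of genes of interest (subset of
#'   `universe`).
#' @param annotation_map Named list: term id -> character vector of genes.
#' @param universe Character vector of all background genes.
#' @return Tibble with `term`, `overlap`, `set_size`, `term_size`,
#'   `universe`, `p`, `q`, sorted by `p`.
#' @export
enrich <- function(gene_set, annotation_map, universe) {
  if (!length(universe)) abort("`universe` must be non-empty.")
  universe <- unique(universe)
  gene_set <- intersect(unique(gene_set), universe)
  if (!length(annotation_map)) abort("`annotation_map` must be non-empty.")
  n_uni <- length(universe)
  n_set <- length(gene_set)
  res <- purrr::imap(annotation_map, function(genes, term) {
    tg <- intersect(unique(genes), universe)
    ov <- length(intersect(gene_set, tg))
    tibble(
      term = term, overlap = ov, set_size = n_set,
      term_size = length(tg), universe = n_uni,
      p = phyper(ov - 1, length(tg), n_uni - length(tg), n_set,
                 lower.tail = FALSE)
    )
  }) %>% bind_rows()
  res$q <- p.adjust(res$p, method = "BH")
  arrange(res, .data$p)
}
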