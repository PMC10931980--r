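#' Correlate gene expression with metabolite abundance
#'
#' Pairs the two experiments on shared (condition, time point) cells,
#' takes per-cell replicate means, and computes Pearson (or Spearman)
#' correlation per gene x metabolite pair with the t-transform p-value
#' `t = r * sqrt((n - 2)/(1 - r^2))`. Significance stars follow the usual
#' convention: `**` for p < 0.01, `*` for 0.01 <= p < 0.05 (strict
#' boundaries), none otherwise. A BH-adjusted `q` across the whole grid is
#' reported alongside.
#'
#' @param expr_exp,metab_exp [tc_experiment()]s sharing >= 3 (condition,
#'   time) cells.
#' @param genes,metabolites Feature subsets (defaults: all).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble `gene`, `metabolite`, `r`, `p`, `q`, `stars`,
#'   `degenerate` (TRUE when either profile had zero variance and the
#'   pair was skipped).
#' @export
gene_metabolite_correlation <- function(expr_exp, metab_exp, genes = NULL,
                                        metabolites = NULL,
                                        method = c("pearson", "spearman")) {
  stopifnot(inherits(expr_exp, "tc_experiment"),
            inherits(metab_exp, "tc_experiment"))
  method <- match.arg(method)
  if (is.null(genes)) genes <- rownames(expr_exp$values)
  if (is.null(metabolites)) metabolites <- rownames(metab_exp$values)
  cells <- inner_join(
    distinct(expr_exp$design, .data$condition, .data$time_h),
    distinct(metab_exp$design, .data$condition, .data$time_h),
    by = c("condition", "time_h")
  ) %>% arrange(.data$condition, .data$time_h)
  n <- nrow(cells)
  if (n < 3L) abort("need >= 3 shared (condition, time) cells.")
  cell_means <- function(exp, feats) {
    vapply(seq_len(n), function(k) {
      ids <- exp$design$sample_id[
        exp$design$condition == cells$condition[k] &
          exp$design$time_h == cells$time_h[k]]
      rowMeans(exp$values[feats, ids, drop = FALSE])
    }, numeric(length(feats)))
  }
  gm <- matrix(cell_means(expr_exp, genes), nrow = length(genes),
               dimnames = list(genes, NULL))
  mm <- matrix(cell_means(metab_exp, metabolites), nrow = length(metabolites),
               dimnames = list(metabolites, NULL))
  grid <- tidyr::expand_grid(gene = genes, metabolite = metabolites)
  res <- purrr::pmap(grid, function(gene, metabolite) {
    x <- gm[gene, ]; y <- mm[metabolite, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(gene = gene, metabolite = metabolite, r = NA_real_,
                    p = NA_real_, degenerate = TRUE))
    }
    r <- cor(x, y, method = method)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    tibble(gene = gene, metabolite = metabolite, r = r,
           p = 2 * pt(-abs(tt), df = n - 2), degenerate = FALSE)
  }) %>% bind_rows()
  ok <- !res$degenerate
  res$q <- NA_real_
  res$q[ok] <- bh_adjust(res$p[ok])
  res$stars <- dplyr::case_when(
    is.na(res$p) ~ "",
    res$p < 0.01 ~ "**",
    res$p < 0.05 ~ "*",
    TRUE ~ ""
  )
  res
}

#' Assemble the tripartite TF-target-metabolite network
#'
#' Joins CLR regulatory edges with significant gene-metabolite
#' correlations into one typed network. Node flags carry the circadian
#' verdict (circadian in any condition of `rhythm_calls`) and the DAM
#' verdict.
#'
#' @param grn_edges A [build_grn()] result.
#' @param correlations A [gene_metabolite_correlation()] result (may be
#'   empty).
#' @param rhythm_calls Optional [call_circadian()] result.
#' @param dam_records Optional [dam_call()] result.
#' @param alpha Keep correlation edges with p < `alpha` (default 0.05).
#' @return Object of class `tripartite_network`: list of `nodes` (tibble
#'   `id`, `type` in tf/target_gene/metabolite, `rhythmic`, `dam`) and
#'   `edges` (tibble `from`, `to`, `type` in regulates/correlates,
#'   `weight`), both deterministically ordered.
#' @export
assemble_network <- function(grn_edges, correlations = NULL,
                             rhythm_calls = NULL, dam_records = NULL,
                             alpha = 0.05) {
  corr_keep <- if (!is.null(correlations) && nrow(correlations)) {
    filter(correlations, !is.na(.data$p), .data$p < alpha)
  } else {
    tibble(gene = character(), metabolite = character(), r = numeric())
  }
  tfs <- unique(grn_edges$tf)
  tgt <- setdiff(unique(c(grn_edges$target, corr_keep$gene)), tfs)
  mets <- unique(corr_keep$metabolite)
  rhy_set <- if (!is.null(rhythm_calls)) {
    unique(rhythm_calls$feature[rhythm_calls$circadian])
  } else character()
  dam_set <- if (!is.null(dam_records)) {
    unique(dam_records$metabolite[dam_records$is_dam])
  } else character()
  nodes <- bind_rows(
    tibble(id = sort(tfs), type = "tf"),
    tibble(id = sort(tgt), type = "target_gene"),
    tibble(id = sort(mets), type = "metabolite")
  ) %>%
    mutate(rhythmic = .data$id %in% rhy_set, dam = .data$id %in% dam_set)
  edges <- bind_rows(
    tibble(from = grn_edges$tf, to = grn_edges$target, type = "regulates",
           weight = grn_edges$f),
    tibble(from = corr_keep$gene, to = corr_keep$metabolite,
           type = "correlates", weight = corr_keep$r)
  ) %>% arrange(.data$type, .data$from, .data$to)
  dangling <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(dangling)) {
    abort(paste0("edge endpoint(s) missing from node table: ",
                 paste(head(dangling, 5), collapse = ", ")))
  }
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat("<tripartite_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$type == "tf"), " TF, ",
      sum(x$nodes$type == "target_gene"), " target, ",
      sum(x$nodes$type == "metabolite"), " metabolite), ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @rdname assemble_network
#' @param x A `tripartite_network`.
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.tripartite_network <- function(x, ...) x$edges

#' @rdname assemble_network
#' @export
#' @exportS3Method generics::glance
glance.tripartite_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_tf = sum(x$nodes$type == "tf"),
         n_targets = sum(x$nodes$type == "target_gene"),
         n_metabolites = sum(x$nodes$type == "metabolite"))
}

#' Export a tripartite network
#'
#' `"sif"` writes the simple interaction format (`source TAB type TAB
#' target`, isolated nodes on their own lines); `"graphml"` writes GraphML
#' through igraph with node/edge attributes preserved.
#'
#' @param net A [assemble_network()] result.
#' @param path Output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(inherits(net, "tripartite_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- paste(net$edges$from, net$edges$type, net$edges$to, sep = "\t")
    isolated <- setdiff(net$nodes$id, c(net$edges$from, net$edges$to))
    writeLines(c(lines, isolated), path)
  } else {
    g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                       vertices = net$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network file written by [export_network()]
#'
#' @param path Input file.
#' @param format `"sif"` or `"graphml"`.
#' @return A `tripartite_network`; SIF carries no node attributes, so
#'   flags default to FALSE and node types are inferred from edge roles.
#' @export
read_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ed <- purrr::keep(parts, ~ length(.x) == 3L)
    iso <- unlist(purrr::keep(parts, ~ length(.x) == 1L))
    edges <- tibble(
      from = vapply(ed, `[[`, character(1), 1),
      type = vapply(ed, `[[`, character(1), 2),
      to = vapply(ed, `[[`, character(1), 3),
      weight = NA_real_
    ) %>% select("from", "to", "type", "weight")
    met <- unique(edges$to[edges$type == "correlates"])
    tfs <- unique(edges$from[edges$type == "regulates"])
    ids <- unique(c(edges$from, edges$to, iso))
    nodes <- tibble(id = ids) %>%
      mutate(type = dplyr::case_when(
        .data$id %in% tfs ~ "tf",
        .data$id %in% met ~ "metabolite",
        TRUE ~ "target_gene"
      ), rhythmic = FALSE, dam = FALSE) %>%
      arrange(factor(.data$type, c("tf", "target_gene", "metabolite")),
              .data$id)
    edges <- arrange(edges, .data$type, .data$from, .data$to)
    structure(list(nodes = nodes, edges = edges),
              class = "tripartite_network")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    vd <- igraph::as_data_frame(g, what = "vertices")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- tibble(id = vd$name, type = vd$type,
                    rhythmic = as.logical(vd$rhythmic),
                    dam = as.logical(vd$dam)) %>%
      arrange(factor(.data$type, c("tf", "target_gene", "metabolite")),
              .data$id)
    edges <- tibble(from = ed$from, to = ed$to, type = ed$type,
                    weight = ed$weight) %>%
      arrange(.data$type, .data$from, .data$to)
    structure(list(nodes = nodes, edges = edges),
              class = "tripartite_network")
  }
}
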