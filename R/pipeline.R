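# stage tables go out as TSV with floats at 6 significant digits
write_stage_tsv <- function(df, path) {
  df <- mutate(df, across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(df, path, progress = FALSE)
  nrow(df)
}

default_thresholds <- function() {
  list(cv_min = 0.3, r_min = 0.9, q_rhythm = 0.01,
       lfc_deg = 1, q_deg = 0.05,
       vip_min = 1, fc_up = 2, fc_down = 0.5,
       clr_threshold = 4.5, alpha_corr = 0.05)
}

#' Assemble and validate a pipeline configuration
#'
#' A configuration names either a `simulation` block (arguments for
#' [sim_config()]) or an `inputs` block (paths to expression/metabolome
#' TSVs, a sample sheet each, and a TF list), plus optional per-stage
#' threshold overrides and a master seed. Exactly one of the two blocks
#' must be present.
#'
#' @param config A named list, or the path to a YAML file holding one.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    abort("config must contain exactly one of `simulation` or `inputs`.")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  thr <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  bad <- names(thr)[!vapply(thr, function(v) is.numeric(v) && v >= 0,
                            logical(1))]
  if (length(bad)) abort(paste0("invalid threshold(s): ",
                                paste(bad, collapse = ", ")))
  if (thr$cv_min > 5 || thr$r_min > 1 || thr$q_rhythm > 1 || thr$q_deg > 1 ||
      thr$alpha_corr > 1 || thr$fc_down > thr$fc_up) {
    abort("threshold out of legal range.")
  }
  config$thresholds <- thr
  config$conditions <- utils::modifyList(
    list(wt = "WT", mut = "MUT", treated = "MUT_GA"),
    config$conditions %||% list()
  )
  config$grn_max_targets <- config$grn_max_targets %||% 150L
  config$corr_max_genes <- config$corr_max_genes %||% 25L
  config$corr_max_metabolites <- config$corr_max_metabolites %||% 50L
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate/load, circadian
#' calling, differential expression with restoration classes, pattern
#' clustering, metabolite DAM calling, CLR network inference, and
#' gene-metabolite integration — writing every stage table as TSV into
#' `out_dir` together with the echoed configuration and a JSON summary of
#' per-stage counts, parameters, seed and versions. Re-running with an
#' identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()], a plain list, or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return The summary, invisibly (a named list).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  thr <- cfg$thresholds
  cn <- cfg$conditions
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  # --- data -----------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim_args <- cfg$simulation
    sim_args$seed <- as.integer(sim_args$seed %||% cfg$seed)
    sc <- stage("simulate", do.call(sim_config, sim_args))
    sim <- stage("simulate", generate_experiment(sc))
    met <- stage("simulate", generate_metabolome(sc, sim))
    exp <- sim$experiment
    mexp <- met$experiment
    tf_ids <- sim$truth$genes$gene[sim$truth$genes$is_tf]
    annotations <- select(met$truth, "metabolite", "klass")
    truth <- c(sim$truth[c("genes", "edges")],
               list(metabolites = met$truth))
    write_truth(truth, file.path(out_dir, "truth.tsv"))
  } else {
    inp <- cfg$inputs
    exp <- stage("load", read_expression(inp$expression, inp$design))
    mexp <- if (!is.null(inp$metabolome)) {
      stage("load", read_expression(inp$metabolome, inp$metab_design))
    }
    tf_ids <- if (!is.null(inp$tf_list)) readLines(inp$tf_list) else character()
    annotations <- if (!is.null(inp$annotations)) {
      readr::read_tsv(inp$annotations, show_col_types = FALSE, progress = FALSE)
    }
  }
  write_experiment(exp, file.path(out_dir, "expression.tsv"),
                   file.path(out_dir, "design.tsv"))
  counts$n_genes <- nrow(exp$values)
  counts$n_samples <- ncol(exp$values)

  # --- rhythms --------------------------------------------------------
  calls <- stage("rhythms", call_circadian(
    exp, cv_min = thr$cv_min, r_min = thr$r_min, q_max = thr$q_rhythm))
  counts$n_rhythm_rows <- write_stage_tsv(
    calls, file.path(out_dir, "rhythm_calls.tsv"))
  counts$n_circadian <- sum(calls$circadian)
  conserved <- stage("rhythms", conserved_circadian(calls))
  counts$n_conserved <- write_stage_tsv(
    tibble(feature = conserved), file.path(out_dir, "conserved.tsv"))
  pg <- phase_groups(calls, light_window = exp$photoperiod)
  write_stage_tsv(attr(pg, "summary"),
                  file.path(out_dir, "phase_group_summary.tsv"))

  # --- differential expression ---------------------------------------
  e_wt <- filter_condition(exp, cn$wt)
  e_mut <- filter_condition(exp, cn$mut)
  e_trt <- filter_condition(exp, cn$treated)
  deg_wm <- stage("degs", deg_call(e_wt, e_mut, lfc_min = thr$lfc_deg,
                                   q_max = thr$q_deg))
  deg_tm <- stage("degs", deg_call(e_trt, e_mut, lfc_min = thr$lfc_deg,
                                   q_max = thr$q_deg))
  counts$n_deg_rows <- write_stage_tsv(deg_wm,
                                       file.path(out_dir, "deg_wt_mut.tsv"))
  write_stage_tsv(deg_tm, file.path(out_dir, "deg_trt_mut.tsv"))
  degs <- unique(deg_wm$feature[deg_wm$is_deg])
  counts$n_deg <- length(degs)
  restor <- stage("degs", classify_restoration(deg_wm, deg_tm))
  counts$n_restored <- sum(restor$direction_class != "other")
  write_stage_tsv(restor, file.path(out_dir, "restoration.tsv"))

  # --- expression-pattern clustering ---------------------------------
  if (length(degs) >= 16L) {
    lfc_mat <- deg_wm %>%
      filter(.data$feature %in% degs) %>%
      select("feature", "time_h", "log2fc") %>%
      tidyr::pivot_wider(names_from = "time_h", values_from = "log2fc")
    m <- as.matrix(lfc_mat[, -1])
    rownames(m) <- lfc_mat$feature
    clus <- stage("cluster", cluster_patterns(m, k = 15, seed = cfg$seed))
    counts$n_clustered <- write_stage_tsv(
      clus, file.path(out_dir, "clusters.tsv"))
  }

  # --- metabolites ----------------------------------------------------
  if (!is.null(mexp)) {
    dams <- stage("dams", dam_call(
      mexp, contrast = c(cn$mut, cn$wt), treatment = cn$treated,
      annotations = annotations, vip_min = thr$vip_min,
      fc_up = thr$fc_up, fc_down = thr$fc_down))
    counts$n_metabolites <- write_stage_tsv(
      dams, file.path(out_dir, "dams.tsv"))
    counts$n_dam <- sum(dams$is_dam, na.rm = TRUE)
    if (counts$n_dam > 0 && "klass" %in% names(dams)) {
      write_stage_tsv(dam_class_summary(filter(dams, .data$is_dam)),
                      file.path(out_dir, "dam_class_summary.tsv"))
    }
  }

  # --- regulatory network --------------------------------------------
  grn <- NULL
  if (length(tf_ids)) {
    cand <- setdiff(rownames(exp$values), tf_ids)
    pref <- intersect(cand, union(degs, conserved))
    rest <- setdiff(cand, pref)
    vx <- apply(log2(exp$values + 1), 1, var)
    ordered_targets <- c(pref[order(-vx[pref])], rest[order(-vx[rest])])
    targets <- head(ordered_targets, cfg$grn_max_targets)
    grn <- stage("grn", build_grn(exp, tf_ids, targets,
                                  threshold = thr$clr_threshold))
    counts$n_grn_edges <- write_stage_tsv(
      grn, file.path(out_dir, "grn_edges.tsv"))
  }

  # --- integration ----------------------------------------------------
  if (!is.null(mexp) && !is.null(grn)) {
    corr_genes <- head(intersect(conserved, degs), cfg$corr_max_genes)
    if (!length(corr_genes)) corr_genes <- head(degs, cfg$corr_max_genes)
    corr_mets <- head(dams$metabolite[dams$is_dam],
                      cfg$corr_max_metabolites)
    if (length(corr_genes) && length(corr_mets)) {
      corr <- stage("integrate", gene_metabolite_correlation(
        exp, mexp, genes = corr_genes, metabolites = corr_mets))
      counts$n_correlations <- write_stage_tsv(
        corr, file.path(out_dir, "correlations.tsv"))
      net <- stage("integrate", assemble_network(
        grn, corr, rhythm_calls = calls, dam_records = dams,
        alpha = thr$alpha_corr))
      export_network(net, file.path(out_dir, "network.sif"), "sif")
      export_network(net, file.path(out_dir, "network.graphml"), "graphml")
      counts$n_network_nodes <- nrow(net$nodes)
      counts$n_network_edges <- nrow(net$edges)
    }
  }

  # --- summary --------------------------------------------------------
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  summary <- list(
    counts = counts,
    parameters = thr,
    seed = cfg$seed,
    versions = list(
      rhythmics = as.character(utils::packageVersion("rhythmics")),
      r = R.version.string
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(summary)
}
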