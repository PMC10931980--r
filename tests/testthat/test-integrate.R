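make_paired_experiments <- function(seed = 47, n_genes = 30,
                                    n_metabolites = 20, frac_coupled = 0.5,
                                    noise_cv = 0.1) {
  cfg <- sim_config(n_genes = n_genes, n_metabolites = n_metabolites,
                    frac_coupled = frac_coupled, frac_rhythmic = 0.6,
                    noise_cv = noise_cv, seed = seed)
  sim <- generate_experiment(cfg)
  met <- generate_metabolome(cfg, sim)
  list(cfg = cfg, sim = sim, met = met)
}

test_that("gene-metabolite correlation matches the closed-form oracle", {
  px <- make_paired_experiments(seed = 8)
  corr <- gene_metabolite_correlation(px$sim$experiment, px$met$experiment)
  # 3 conditions x 4 shared time points = 12 cells
  expect_equal(nrow(corr), 30 * 20)

  # direct covariance-formula oracle for a few pairs
  cells <- expand.grid(time_h = c(12, 20, 36, 42),
                       condition = c("WT", "MUT", "MUT_GA"),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$condition, cells$time_h), ]
  cell_mean <- function(exp, feat) {
    vapply(seq_len(nrow(cells)), function(k) {
      ids <- exp$design$sample_id[exp$design$condition == cells$condition[k] &
                                    exp$design$time_h == cells$time_h[k]]
      mean(exp$values[feat, ids])
    }, numeric(1))
  }
  set.seed(1)
  some <- corr[sample(nrow(corr), 5), ]
  for (k in seq_len(nrow(some))) {
    x <- cell_mean(px$sim$experiment, some$gene[k])
    y <- cell_mean(px$met$experiment, some$metabolite[k])
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(some$r[k], r_manual, tolerance = 1e-3)
    tt <- r_manual * sqrt((12 - 2) / (1 - r_manual^2))
    expect_equal(some$p[k], 2 * pt(-abs(tt), 10), tolerance = 1e-3)
  }
})

test_that("correlation edge cases: identity, negation, degenerate profiles", {
  tpm <- c(12, 20, 36, 42)
  des <- expand.grid(time_h = tpm, replicate = 1:2)
  des$condition <- "WT"
  des$sample_id <- paste0("s", seq_len(nrow(des)))
  prof <- c(1, 5, 2, 8)
  gvals <- matrix(rep(prof, 2), 1, dimnames = list("gene1", des$sample_id))
  des_m <- des
  des_m$sample_id <- paste0("m", seq_len(nrow(des)))
  mvals <- rbind(
    same = rep(prof, 2),
    neg = rep(max(prof) + min(prof) - prof, 2),
    flat = rep(3, 8)
  )
  colnames(mvals) <- des_m$sample_id
  ge <- tc_experiment(gvals, des[, c("sample_id", "condition", "time_h",
                                     "replicate")])
  me <- tc_experiment(mvals, des_m[, c("sample_id", "condition", "time_h",
                                       "replicate")])
  corr <- gene_metabolite_correlation(ge, me)
  expect_equal(corr$r[corr$metabolite == "same"], 1, tolerance = 1e-12)
  expect_equal(corr$stars[corr$metabolite == "same"], "**")
  expect_equal(corr$r[corr$metabolite == "neg"], -1, tolerance = 1e-12)
  expect_true(corr$degenerate[corr$metabolite == "flat"])

  # < 3 shared cells errors
  keep <- des$time_h %in% c(12, 20)
  ge2 <- tc_experiment(gvals[, keep, drop = FALSE],
                       des[keep, c("sample_id", "condition", "time_h",
                                   "replicate")])
  me2 <- tc_experiment(mvals[, keep, drop = FALSE],
                       des_m[keep, c("sample_id", "condition", "time_h",
                                     "replicate")])
  expect_error(gene_metabolite_correlation(ge2, me2), "3 shared")
})

test_that("correlation is invariant to replicate ordering", {
  px <- make_paired_experiments(seed = 53, n_genes = 10, n_metabolites = 8)
  c1 <- gene_metabolite_correlation(px$sim$experiment, px$met$experiment)
  perm <- rev(seq_len(ncol(px$met$experiment$values)))
  me_p <- tc_experiment(
    px$met$experiment$values[, perm],
    px$met$experiment$design[perm, c("sample_id", "condition", "time_h",
                                     "replicate")]
  )
  c2 <- gene_metabolite_correlation(px$sim$experiment, me_p)
  j <- dplyr::inner_join(c1, c2, by = c("gene", "metabolite"))
  expect_equal(j$r.x, j$r.y, tolerance = 1e-12)
})

test_that("network assembly links only passing records and exports round-trip", {
  grn <- tibble::tibble(tf = c("tf1", "tf1"), target = c("gA", "gB"),
                        mi = c(1, 0.8), z_tf = c(5, 4), z_target = c(3, 2),
                        f = sqrt(c(34, 20)))
  corr <- tibble::tibble(gene = c("gA", "gB"), metabolite = c("m1", "m2"),
                         r = c(0.99, 0.2), p = c(0.001, 0.6),
                         q = c(0.002, 0.6), stars = c("**", ""),
                         degenerate = FALSE)
  net <- assemble_network(grn, corr, alpha = 0.05)
  expect_equal(nrow(net$nodes), 4)  # tf1, gA, gB, m1 (m2's edge fails alpha)
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$from[net$edges$type == "regulates"] == "tf1"))

  # empty correlations -> GRN-only network
  net0 <- assemble_network(grn, corr[0, ])
  expect_equal(sum(net0$nodes$type == "metabolite"), 0)
  expect_equal(nrow(net0$edges), 2)

  # one TF, one target, one correlated metabolite -> 3 nodes, 2 edges
  net1 <- assemble_network(grn[1, ], corr[1, ])
  expect_equal(nrow(net1$nodes), 3)
  expect_equal(nrow(net1$edges), 2)

  # exports round-trip node/edge sets in both dialects
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, sif, "sif")
  export_network(net, gml, "graphml")
  expect_equal(length(grep("\t", readLines(sif))), nrow(net$edges))
  back_sif <- read_network(sif, "sif")
  expect_setequal(back_sif$nodes$id, net$nodes$id)
  expect_setequal(paste(back_sif$edges$from, back_sif$edges$to),
                  paste(net$edges$from, net$edges$to))
  back_gml <- read_network(gml, "graphml")
  expect_equal(back_gml$nodes$id, net$nodes$id)
  expect_equal(back_gml$nodes$type, net$nodes$type)
  expect_equal(back_gml$edges[, c("from", "to", "type")],
               net$edges[, c("from", "to", "type")])
  expect_equal(back_gml$edges$weight, net$edges$weight, tolerance = 1e-9)
})

test_that("full synthetic integration keeps referential integrity", {
  px <- make_paired_experiments(seed = 59, n_genes = 40, n_metabolites = 15)
  tfs <- px$sim$truth$genes$gene[px$sim$truth$genes$is_tf]
  grn <- build_grn(px$sim$experiment, tfs, threshold = 2)
  calls <- call_circadian(px$sim$experiment)
  dams <- dam_call(px$met$experiment, contrast = c("MUT", "WT"),
                   treatment = "MUT_GA")
  corr <- gene_metabolite_correlation(
    px$sim$experiment, px$met$experiment,
    genes = unique(c(grn$tf, grn$target)))
  net <- assemble_network(grn, corr, rhythm_calls = calls,
                          dam_records = dams)
  # every edge endpoint exists and edge types match endpoint types
  expect_true(all(net$edges$from %in% net$nodes$id))
  expect_true(all(net$edges$to %in% net$nodes$id))
  typ <- setNames(net$nodes$type, net$nodes$id)
  reg <- net$edges[net$edges$type == "regulates", ]
  expect_true(all(typ[reg$from] == "tf"))
  cor_e <- net$edges[net$edges$type == "correlates", ]
  expect_true(all(typ[cor_e$to] == "metabolite"))
  # every correlate edge traces back to a passing correlation record
  for (k in seq_len(nrow(cor_e))) {
    rec <- corr[corr$gene == cor_e$from[k] &
                  corr$metabolite == cor_e$to[k], ]
    expect_lt(rec$p, 0.05)
  }
  # node flags trace to upstream verdicts
  rhy_nodes <- net$nodes$id[net$nodes$rhythmic]
  expect_true(all(rhy_nodes %in% calls$feature[calls$circadian]))
})
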