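tp11 <- c(0, 4, 8, 12, 16, 20, 24, 30, 36, 42, 48)

make_pair <- function(profile_a, profile_b, noise_sd = 0.02, seed = 51) {
  set.seed(seed)
  nf <- function(n) exp(rnorm(n, 0, noise_sd))
  list(
    a = toy_experiment(profile_a, condition = "A", noise_fun = nf),
    b = toy_experiment(profile_b, condition = "B", noise_fun = nf)
  )
}

test_that("deg_call applies the fold-change/q rule on the stated scales", {
  pr <- make_pair(list(g1 = rep(3, 11), g2 = rep(5, 11)),
                  list(g1 = rep(1, 11), g2 = rep(5, 11)))
  deg <- deg_call(pr$a, pr$b)
  g1 <- dplyr::filter(deg, feature == "g1")
  expect_equal(g1$log2fc, rep(1, 11), tolerance = 0.05)  # log2(4/2) = 1
  expect_true(all(g1$is_deg))
  g2 <- dplyr::filter(deg, feature == "g2")
  expect_equal(g2$log2fc, rep(0, 11), tolerance = 0.05)
  expect_false(any(g2$is_deg))

  # identical groups: all zero log2fc, nothing called
  same <- make_pair(list(g1 = rep(7, 11)), list(g1 = rep(7, 11)),
                    noise_sd = 0)
  deg0 <- deg_call(same$a, same$b)
  expect_true(all(deg0$log2fc == 0))
  expect_false(any(deg0$is_deg))

  # unmatched time points error
  short <- toy_experiment(list(g1 = rep(1, 5)), times = c(0, 4, 8, 12, 16),
                          condition = "B")
  expect_error(deg_call(pr$a, short), "features|time points")
})

test_that("deg_call is antisymmetric under group swap", {
  cfg <- sim_config(n_genes = 60, noise_cv = 0.1, seed = 23)
  sim <- generate_experiment(cfg)
  a <- filter_condition(sim$experiment, "WT")
  b <- filter_condition(sim$experiment, "MUT")
  ab <- deg_call(a, b)
  ba <- deg_call(b, a)
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_identical(ab$is_deg, ba$is_deg)
})

test_that("planted genotype offsets are recovered as DEGs", {
  cfg <- sim_config(n_genes = 300, frac_rhythmic = 0.3, frac_deg = 0.3,
                    offset_range = c(2, 2.5), noise_cv = 0.1, seed = 29)
  sim <- generate_experiment(cfg)
  deg <- deg_call(filter_condition(sim$experiment, "WT"),
                  filter_condition(sim$experiment, "MUT"))
  verdict <- dplyr::distinct(deg, feature, is_deg)
  j <- dplyr::inner_join(verdict, sim$truth$genes,
                         by = c(feature = "gene"))
  planted <- abs(j$condition_offset) > 0
  expect_gte(mean(j$is_deg[planted]), 0.9)
  expect_lte(mean(j$is_deg[!planted]), 0.05)
})

test_that("restoration classes follow the planted offset direction", {
  cfg <- sim_config(n_genes = 200, frac_deg = 0.4, offset_range = c(2, 3),
                    restore_rate = 0.15, noise_cv = 0.1, seed = 31)
  sim <- generate_experiment(cfg)
  wt <- filter_condition(sim$experiment, "WT")
  mut <- filter_condition(sim$experiment, "MUT")
  trt <- filter_condition(sim$experiment, "MUT_GA")
  deg_wm <- deg_call(wt, mut)
  deg_tm <- deg_call(trt, mut)
  cls <- classify_restoration(deg_wm, deg_tm)
  j <- dplyr::inner_join(cls, sim$truth$genes, by = c(feature = "gene"))
  # gene lower in mutant (offset < 0): WT > MUT and GA raises it back
  down_off <- j$condition_offset < 0 & j$direction_class != "other"
  up_off <- j$condition_offset > 0 & j$direction_class != "other"
  expect_gte(mean(j$direction_class[down_off] == "up_restored"), 0.9)
  expect_gte(mean(j$direction_class[up_off] == "down_restored"), 0.9)
  expect_true(all(j$direction_class[j$condition_offset == 0] == "other"))
})

test_that("OPLS-DA VIP satisfies its normalization identity and ranks the discriminant", {
  set.seed(61)
  n <- 24; p <- 30
  y <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  x[, 7] <- x[, 7] + ifelse(y == "A", 2, -2)
  fit <- fit_oplsda(x, y)
  expect_equal(sum(fit$vip^2), fit$p, tolerance = 1e-6)
  expect_equal(names(which.max(fit$vip)), "m7")
  td <- tidy(fit)
  expect_setequal(names(td), c("variable", "weight", "loading", "vip"))
  expect_equal(glance(fit)$p, p)

  # identical class-correlated variables all get VIP 1
  x2 <- matrix(rep(ifelse(y == "A", 1, -1), 5), n, 5,
               dimnames = list(NULL, paste0("v", 1:5)))
  x2 <- x2 + matrix(rnorm(n * 5, 0, 1e-6), n, 5)
  suppressWarnings(fit2 <- fit_oplsda(x2, y))
  expect_equal(unname(fit2$vip), rep(1, 5), tolerance = 1e-3)

  expect_error(fit_oplsda(x, rep("A", n)), "two classes")
})

test_that("dam_call applies the inclusive VIP/fold-change conjunction", {
  set.seed(71)
  cfg <- sim_config(n_genes = 100, n_metabolites = 40, frac_coupled = 0.5,
                    frac_deg = 0.5, offset_range = c(2, 3), noise_cv = 0.1,
                    seed = 37)
  sim <- generate_experiment(cfg)
  met <- generate_metabolome(cfg, sim)
  anns <- dplyr::select(met$truth, metabolite, klass)
  dams <- dam_call(met$experiment, contrast = c("MUT", "WT"),
                   treatment = "MUT_GA", annotations = anns)
  expect_setequal(
    dams$metabolite[dams$is_dam],
    dams$metabolite[!is.na(dams$vip) & dams$vip >= 1 &
                      (dams$fold_change >= 2 | dams$fold_change <= 0.5)]
  )
  # conjunction: high fold change with low VIP is not a DAM
  low_vip <- dams[!is.na(dams$vip) & dams$vip < 1, ]
  expect_false(any(low_vip$is_dam))
  expect_true("klass" %in% names(dams))

  # sample order invariance
  perm <- sample(ncol(met$experiment$values))
  exp_p <- tc_experiment(
    met$experiment$values[, perm],
    met$experiment$design[perm, c("sample_id", "condition", "time_h",
                                  "replicate")]
  )
  dams_p <- dam_call(exp_p, contrast = c("MUT", "WT"), treatment = "MUT_GA")
  expect_equal(dams$fold_change, dams_p$fold_change, tolerance = 1e-12)
  expect_identical(dams$is_dam, dams_p$is_dam)
})

test_that("coupled metabolites with planted response are flagged with correct direction", {
  # a minority of coupled responders among flat metabolites, so VIP (a
  # relative importance measure) can separate them from the background
  cfg <- sim_config(n_genes = 100, n_metabolites = 40, frac_coupled = 0.35,
                    frac_deg = 1, offset_range = c(2, 2.5), noise_cv = 0.05,
                    restore_rate = 0.15, seed = 41)
  sim <- generate_experiment(cfg)
  met <- generate_metabolome(cfg, sim)
  dams <- dam_call(met$experiment, contrast = c("MUT", "WT"),
                   treatment = "MUT_GA")
  j <- dplyr::inner_join(dams, met$truth, by = "metabolite") %>%
    dplyr::inner_join(sim$truth$genes, by = c(driver = "gene"))
  # metabolites driven by genes with a big negative offset sit lower in the
  # mutant and are raised by treatment
  dn <- j[j$condition_offset < -1.5, ]
  expect_gte(mean(dn$is_dam), 0.9)
  expect_gte(mean(dn$ga_direction == "up_by_GA"), 0.9)
  up <- j[j$condition_offset > 1.5, ]
  expect_gte(mean(up$ga_direction == "down_by_GA"), 0.9)
})

test_that("rhythmic metabolite rule needs consistent sign across both cycles", {
  tpm <- c(12, 20, 36, 42)
  des <- expand.grid(time_h = tpm, replicate = 1:3)
  des$condition <- "WT"
  des$sample_id <- paste0("s", seq_len(nrow(des)))
  prof <- function(v) rep(v, times = 3)
  vals <- rbind(
    dark_up = prof(c(1, 3, 1, 3)),
    incoherent = prof(c(1, 3, 3, 1)),
    flat = prof(c(2, 2, 2, 2))
  )
  colnames(vals) <- des$sample_id
  set.seed(81)
  vals <- vals * exp(matrix(rnorm(length(vals), 0, 0.01), nrow(vals)))
  exp <- tc_experiment(vals, des[, c("sample_id", "condition", "time_h",
                                     "replicate")])
  r <- rhythmic_dam(exp)
  expect_true(r$rhythmic[r$metabolite == "dark_up"])
  expect_true(r$dark_over_light[r$metabolite == "dark_up"])
  expect_false(r$rhythmic[r$metabolite == "incoherent"])
  expect_false(r$rhythmic[r$metabolite == "flat"])

  expect_error(rhythmic_dam(filter_condition(exp, "WT") |>
                              (\(e) {
                                keep <- e$design$time_h != 42
                                tc_experiment(
                                  e$values[, keep],
                                  e$design[keep, c("sample_id", "condition",
                                                   "time_h", "replicate")])
                              })()),
               "missing time point")

  # propagation from dark-phase drivers at scale
  cfg <- sim_config(n_genes = 60, n_metabolites = 30, frac_coupled = 1,
                    frac_rhythmic = 1, frac_deg = 0, noise_cv = 0.1, seed = 43)
  sim <- generate_experiment(cfg)
  met <- generate_metabolome(cfg, sim)
  r2 <- rhythmic_dam(met$experiment)
  j <- dplyr::inner_join(r2, met$truth, by = "metabolite") %>%
    dplyr::inner_join(
      dplyr::select(sim$truth$genes, gene, amplitude_true, phase_true),
      by = c(driver = "gene"))
  # truth: driver mean in dark vs light at the metabolome time points
  expected_dark <- vapply(seq_len(nrow(j)), function(i) {
    f <- function(t) 1 + j$amplitude_true[i] *
      cos(2 * pi * (t - j$phase_true[i]) / 24)
    mean(f(c(20, 42))) > mean(f(c(12, 36)))
  }, logical(1))
  concl <- j$rhythmic
  expect_gte(mean(j$dark_over_light[concl] == expected_dark[concl]), 0.9)
})

test_that("class summary reproduces printed-percentage arithmetic", {
  flav <- tibble::tibble(klass = rep(c("tricin", "other flavonoid"),
                                     c(14, 3)))
  s <- dam_class_summary(flav)
  expect_equal(s$pct[s$klass == "tricin"], 82.4)
  expect_equal(s$pct_label[s$klass == "tricin"], "82.4%")

  mix <- tibble::tibble(klass = rep(c("flavonoid", "phenolic acid", "lipid"),
                                    c(17, 11, 27)))
  s2 <- dam_class_summary(mix)
  expect_equal(s2$pct[s2$klass == "flavonoid"], 30.9)
  expect_equal(s2$pct_label[s2$klass == "phenolic acid"], "20%")
  expect_lte(abs(sum(s2$pct) - 100), 0.3)  # partition sums to ~100

  none <- tibble::tibble(klass = character())
  expect_error(dam_class_summary(none), "empty")
  s3 <- dam_class_summary(tibble::tibble(klass = "x"), total = 5)
  expect_equal(s3$pct, 20)
})
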