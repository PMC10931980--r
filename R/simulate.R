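#' Simulation configuration
#'
#' Describes a synthetic diel time-course experiment with three conditions —
#' wild type (`WT`), a hormone-deficient mutant (`MUT`), and the treated
#' mutant (`MUT_GA`) — sampled on the 11-point / 48-h transcriptome design
#' (2 replicates) and the 4-point metabolome design (3 replicates) under a
#' 16 h light : 8 h dark cycle.
#'
#' Fraction parameters are converted to counts deterministically by
#' rounding half-up, so planted truth counts are reproducible.
#'
#' @param n_genes Number of genes.
#' @param frac_rhythmic Fraction of genes carrying a 24-h cosine rhythm.
#' @param frac_tf Fraction of genes designated transcription factors.
#' @param n_edges Number of planted TF -> target regulatory edges.
#' @param frac_deg Fraction of genes with a genotype-dependent level offset
#'   (the GA-responsive set).
#' @param amplitude_range Relative cosine amplitude range, within (0, 1).
#' @param baseline_range Baseline abundance range (FPKM scale), log-uniform.
#' @param offset_range Range of |log2| mutant-vs-WT offsets for responsive
#'   genes; signs are drawn at random.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise.
#' @param restore_rate Per-hour exponential decay rate of the mutant offset
#'   under treatment (how fast `MUT_GA` converges to `WT`).
#' @param coupling Strength of the TF -> target link on the log2 latent
#'   scale (1 = target inherits the TF's centred latent profile 1:1).
#' @param n_metabolites,frac_coupled Metabolome size and the fraction of
#'   metabolites driven by a pathway gene.
#' @param seed Integer RNG seed; equal seeds give byte-identical output.
#' @param timepoints_expr,timepoints_metab Sampling times in hours.
#' @param reps_expr,reps_metab Replicates per (condition, time) cell.
#' @param photoperiod Light window per 24 h.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000,
                       frac_rhythmic = 0.3,
                       frac_tf = 0.1,
                       n_edges = 0,
                       frac_deg = 0.3,
                       amplitude_range = c(0.4, 0.8),
                       baseline_range = c(5, 100),
                       offset_range = c(1, 3),
                       noise_cv = 0.1,
                       restore_rate = 0.1,
                       coupling = 1,
                       n_metabolites = 50,
                       frac_coupled = 0.4,
                       seed = 1L,
                       timepoints_expr = c(0, 4, 8, 12, 16, 20, 24, 30, 36, 42, 48),
                       timepoints_metab = c(12, 20, 36, 42),
                       reps_expr = 2L,
                       reps_metab = 3L,
                       photoperiod = c(0, 16)) {
  cfg <- as.list(environment())
  for (f in c("frac_rhythmic", "frac_tf", "frac_deg", "frac_coupled")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(paste0("`", f, "` must lie in [0, 1]."))
    }
  }
  if (any(amplitude_range <= 0) || any(amplitude_range >= 1)) {
    abort("`amplitude_range` must lie within (0, 1).")
  }
  if (any(baseline_range <= 0)) abort("`baseline_range` must be positive.")
  if (!length(timepoints_expr) || !length(timepoints_metab)) {
    abort("time-point lists must be non-empty.")
  }
  if (any(timepoints_expr < 0) || any(timepoints_metab < 0)) {
    abort("time points must be non-negative.")
  }
  if (reps_expr < 1 || reps_metab < 1) abort("replicate counts must be >= 1.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (n_edges > 0 && round_half_up(frac_tf * n_genes) < 1) {
    abort("`n_edges` > 0 requires at least one TF (frac_tf * n_genes >= 1).")
  }
  if (any(timepoints_metab < min(timepoints_expr)) ||
      any(timepoints_metab > max(timepoints_expr))) {
    abort("metabolome time points must lie within the expression time range.")
  }
  structure(cfg, class = "sim_config")
}

# latent log2 profile of one gene in one condition at times t.
# offset decays toward 0 under treatment; rhythmic genes carry the cosine.
latent_log2 <- function(t, baseline, rhythmic, amplitude, phase, offset,
                        treated, restore_rate) {
  off_t <- if (treated) offset * exp(-restore_rate * t) else rep(offset, length(t))
  l <- log2(baseline) + off_t
  if (rhythmic) l <- l + log2(1 + amplitude * cos(2 * pi * (t - phase) / 24))
  l
}

# permutation of a vector that is safe for length-1 input
# (sample(5L) would expand to sample.int(5))
shuffle <- function(x) x[sample.int(length(x))]

sim_conditions <- function() {
  # condition label, whether the genotype offset applies, whether it decays
  tibble(
    condition = c("WT", "MUT", "MUT_GA"),
    has_offset = c(FALSE, TRUE, TRUE),
    treated = c(FALSE, FALSE, TRUE)
  )
}

#' Generate a synthetic three-condition expression time course
#'
#' Plants 24-h cosine rhythms, genotype level offsets that decay under
#' treatment, and TF -> target regulatory links, then corrupts the expected
#' abundances with mean-one multiplicative lognormal noise. A rhythmic gene
#' in condition c has expectation
#' `baseline * 2^offset_c(t) * (1 + A * cos(2*pi*(t - phase)/24))`;
#' non-rhythmic genes omit the cosine factor. Targets of a planted edge
#' additionally inherit `coupling` times their TF's centred latent log2
#' profile, so mutual information between TF and target exceeds background.
#'
#' TFs (and metabolite driver genes, see [generate_metabolome()]) are drawn
#' preferentially from the rhythmic set: a perfectly flat regulator carries
#' no information to its targets.
#'
#' @param config A [sim_config()].
#' @return List with `experiment` (a [tc_experiment()] holding all three
#'   conditions) and `truth`, itself a list of tibbles: `genes` (per-gene
#'   rhythmic flag, phase, amplitude, baseline, log2 offset, TF flag) and
#'   `edges` (planted `tf`, `target` pairs).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))

  n_rhy <- round_half_up(config$frac_rhythmic * n)
  rhythmic <- logical(n)
  rhythmic[sample.int(n, n_rhy)] <- TRUE

  n_tf <- round_half_up(config$frac_tf * n)
  tf_pool <- c(shuffle(which(rhythmic)), shuffle(which(!rhythmic)))
  is_tf <- logical(n)
  is_tf[tf_pool[seq_len(n_tf)]] <- TRUE

  n_deg <- round_half_up(config$frac_deg * n)
  offset <- numeric(n)
  deg_idx <- sample.int(n, n_deg)
  offset[deg_idx] <- runif(n_deg, config$offset_range[1], config$offset_range[2]) *
    sample(c(-1, 1), n_deg, replace = TRUE)

  phase <- ifelse(rhythmic, runif(n, 0, 24), NA_real_)
  amplitude <- ifelse(
    rhythmic,
    runif(n, config$amplitude_range[1], config$amplitude_range[2]),
    NA_real_
  )
  baseline <- exp(runif(n, log(config$baseline_range[1]),
                        log(config$baseline_range[2])))

  edges <- tibble(tf = character(), target = character())
  if (config$n_edges > 0) {
    tf_ids <- which(is_tf)
    tgt_ids <- which(!is_tf)
    if (!length(tgt_ids)) abort("no non-TF genes left to serve as targets.")
    combos_needed <- config$n_edges
    pairs <- unique(tibble(
      tf = tf_ids[sample.int(length(tf_ids), combos_needed * 4, replace = TRUE)],
      target = tgt_ids[sample.int(length(tgt_ids), combos_needed * 4,
                                  replace = TRUE)]
    ))
    pairs <- pairs[pairs$tf != pairs$target, ]
    if (nrow(pairs) < combos_needed) {
      abort("could not place the requested number of distinct edges.")
    }
    pairs <- pairs[seq_len(combos_needed), ]
    edges <- tibble(tf = genes[pairs$tf], target = genes[pairs$target])
  }

  conds <- sim_conditions()
  tps <- config$timepoints_expr
  design <- tidyr::expand_grid(
    condition = conds$condition,
    time_h = tps,
    replicate = seq_len(config$reps_expr)
  ) %>%
    mutate(sample_id = paste0(.data$condition, "_t", .data$time_h,
                              "_r", .data$replicate))

  # latent log2 profile per gene per condition at the sampled times
  sigma <- sqrt(log(1 + config$noise_cv^2))
  values <- matrix(NA_real_, n, nrow(design),
                   dimnames = list(genes, design$sample_id))
  latents <- list()
  for (ci in seq_len(nrow(conds))) {
    cond <- conds$condition[ci]
    lat <- t(vapply(seq_len(n), function(g) {
      latent_log2(tps, baseline[g], rhythmic[g], amplitude[g], phase[g],
                  if (conds$has_offset[ci]) offset[g] else 0,
                  conds$treated[ci], config$restore_rate)
    }, numeric(length(tps))))
    # regulatory coupling: target inherits the TF's centred latent profile
    if (nrow(edges)) {
      for (e in seq_len(nrow(edges))) {
        tfi <- match(edges$tf[e], genes)
        tgi <- match(edges$target[e], genes)
        lat[tgi, ] <- lat[tgi, ] + config$coupling * (lat[tfi, ] - mean(lat[tfi, ]))
      }
    }
    latents[[cond]] <- lat
    for (r in seq_len(config$reps_expr)) {
      ids <- design$sample_id[design$condition == cond & design$replicate == r]
      noise <- if (sigma > 0) {
        exp(matrix(rnorm(n * length(tps), -sigma^2 / 2, sigma), n))
      } else {
        matrix(1, n, length(tps))
      }
      values[, ids] <- 2^lat * noise
    }
  }

  truth_genes <- tibble(
    gene = genes, rhythmic = rhythmic, phase_true = phase,
    amplitude_true = amplitude, baseline = baseline,
    condition_offset = offset, is_tf = is_tf
  )
  exp <- tc_experiment(values, design[, c("sample_id", "condition",
                                          "time_h", "replicate")],
                       photoperiod = config$photoperiod)
  list(
    experiment = exp,
    truth = list(genes = truth_genes, edges = edges, latents = latents)
  )
}

#' Generate a synthetic metabolome coupled to an expression simulation
#'
#' Coupled metabolites track their driver gene's latent (noise-free)
#' profile evaluated at the metabolome time points, so dark-vs-light
#' contrasts and treatment restoration propagate from the transcriptome;
#' uncoupled metabolites are flat plus noise. Class labels echo the
#' composition typical of a maize leaf secondary-metabolite panel.
#'
#' @param config The [sim_config()] used for [generate_experiment()].
#' @param sim The list returned by [generate_experiment()].
#' @return List with `experiment` (metabolite [tc_experiment()]) and
#'   `truth`: tibble with `metabolite`, `driver` (driving gene or `NA`),
#'   `klass`, `baseline`.
#' @export
generate_metabolome <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  m <- config$n_metabolites
  mets <- sprintf("m%03d", seq_len(m))
  genes <- sim$truth$genes

  n_cpl <- round_half_up(config$frac_coupled * m)
  driver <- rep(NA_character_, m)
  if (n_cpl > 0) {
    pool <- c(shuffle(genes$gene[genes$rhythmic]),
              shuffle(genes$gene[!genes$rhythmic]))
    driver[sample.int(m, n_cpl)] <- pool[seq_len(n_cpl)]
  }

  classes <- c("flavonoid", "phenolic acid", "lipid", "amino acid",
               "organic acid", "alkaloid")
  klass <- classes[1 + (seq_len(m) - 1) %% length(classes)]
  klass <- sample(klass)  # shuffle so class is independent of coupling

  baseline <- exp(runif(m, log(config$baseline_range[1]),
                        log(config$baseline_range[2])))

  conds <- sim_conditions()
  tpe <- config$timepoints_expr
  tpm <- config$timepoints_metab
  design <- tidyr::expand_grid(
    condition = conds$condition,
    time_h = tpm,
    replicate = seq_len(config$reps_metab)
  ) %>%
    mutate(sample_id = paste0("M_", .data$condition, "_t", .data$time_h,
                              "_r", .data$replicate))

  sigma <- sqrt(log(1 + config$noise_cv^2))
  values <- matrix(NA_real_, m, nrow(design),
                   dimnames = list(mets, design$sample_id))
  for (cond in conds$condition) {
    lat_expr <- sim$truth$latents[[cond]]
    for (j in seq_len(m)) {
      if (is.na(driver[j])) {
        lat <- rep(log2(baseline[j]), length(tpm))
      } else {
        di <- match(driver[j], genes$gene)
        drl <- lat_expr[di, ]
        # re-centre on the driver's WT mean (not the per-condition mean),
        # so genotype offsets and their treatment restoration propagate
        # into the metabolite alongside the diel oscillation
        ref <- mean(sim$truth$latents[["WT"]][di, ])
        lat <- log2(baseline[j]) +
          stats::approx(tpe, drl - ref, xout = tpm)$y
      }
      for (r in seq_len(config$reps_metab)) {
        ids <- design$sample_id[design$condition == cond &
                                  design$replicate == r]
        noise <- if (sigma > 0) exp(rnorm(length(tpm), -sigma^2 / 2, sigma))
        else rep(1, length(tpm))
        values[j, ids] <- 2^lat * noise
      }
    }
  }

  truth <- tibble(metabolite = mets, driver = driver, klass = klass,
                  baseline = baseline)
  exp <- tc_experiment(values, design[, c("sample_id", "condition",
                                          "time_h", "replicate")],
                       photoperiod = config$photoperiod)
  list(experiment = exp, truth = truth)
}

#' Serialize planted truth as a flat TSV
#'
#' Long format (`feature`, `field`, `value`) so regulatory edges, per-gene
#' parameters and metabolite drivers share one file.
#'
#' @param truth The `truth` element of [generate_experiment()] (optionally
#'   with the metabolite truth appended under `metabolites`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  g <- truth$genes
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      mutate(g, across(-"gene", as.character)),
      -"gene", names_to = "field", values_to = "value"
    ) %>% rename(feature = "gene"),
    if (!is.null(truth$edges) && nrow(truth$edges)) {
      tibble(feature = truth$edges$tf, field = "edge_target",
             value = truth$edges$target)
    },
    if (!is.null(truth$metabolites)) {
      tidyr::pivot_longer(
        mutate(truth$metabolites, across(-"metabolite", as.character)),
        -"metabolite", names_to = "field", values_to = "value"
      ) %>% rename(feature = "metabolite")
    }
  )
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}
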