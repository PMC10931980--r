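#' Call differentially expressed genes between two conditions
#'
#' Per matched time point: the log2 fold-change is
#' `log2((mean_A + 1)/(mean_B + 1))` on the abundance scale (the
#' pseudocount tames zero FPKM), the p-value is a Welch t-test on
#' log2(value + 1) replicate values, and q is Benjamini-Hochberg adjusted
#' across features within the time point. A feature is a DEG when at least
#' one time point shows |log2FC| >= `lfc_min` and q < `q_max`.
#'
#' @param exp_a,exp_b Single-condition [tc_experiment()]s with identical
#'   features and time points and >= 2 replicates per cell.
#' @param lfc_min,q_max Calling thresholds (defaults 1 and 0.05).
#' @param pseudocount Offset used on both scales (default 1).
#' @return Tibble with one row per (feature, time point): `feature`,
#'   `time_h`, `log2fc`, `p`, `q`, `sig`, plus the per-feature verdict
#'   `is_deg` repeated along its rows. Attribute `contrast` records the
#'   condition labels as "A_vs_B".
#' @export
deg_call <- function(exp_a, exp_b, lfc_min = 1, q_max = 0.05,
                     pseudocount = 1) {
  stopifnot(inherits(exp_a, "tc_experiment"), inherits(exp_b, "tc_experiment"))
  if (!identical(rownames(exp_a$values), rownames(exp_b$values))) {
    abort("experiments must share the same features in the same order.")
  }
  tps_a <- sort(unique(exp_a$design$time_h))
  tps_b <- sort(unique(exp_b$design$time_h))
  if (!identical(tps_a, tps_b)) abort("time points do not match between groups.")
  la <- log2(exp_a$values + pseudocount)
  lb <- log2(exp_b$values + pseudocount)
  res <- purrr::map(tps_a, function(tp) {
    ia <- exp_a$design$sample_id[exp_a$design$time_h == tp]
    ib <- exp_b$design$sample_id[exp_b$design$time_h == tp]
    if (length(ia) < 2L || length(ib) < 2L) {
      abort(paste0("need >= 2 replicates per cell (time ", tp, " h)."))
    }
    ma <- rowMeans(exp_a$values[, ia, drop = FALSE])
    mb <- rowMeans(exp_b$values[, ib, drop = FALSE])
    p <- vapply(seq_len(nrow(la)), function(i) {
      xa <- la[i, ia]; xb <- lb[i, ib]
      if (sd(xa) == 0 && sd(xb) == 0) {
        if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      } else {
        tryCatch(t.test(xa, xb)$p.value, error = function(e) 1)
      }
    }, numeric(1))
    tibble(
      feature = rownames(la), time_h = tp,
      log2fc = unname(log2((ma + pseudocount) / (mb + pseudocount))),
      p = p, q = bh_adjust(p)
    )
  }) %>% bind_rows()
  res <- res %>%
    mutate(sig = abs(.data$log2fc) >= lfc_min & .data$q < q_max) %>%
    group_by(.data$feature) %>%
    mutate(is_deg = any(.data$sig)) %>%
    ungroup()
  attr(res, "contrast") <- paste0(unique(exp_a$design$condition)[1], "_vs_",
                                  unique(exp_b$design$condition)[1])
  res
}

#' Classify restoration direction of treatment-responsive genes
#'
#' Combines the genotype contrast (WT vs mutant) with the treatment
#' contrast (treated mutant vs mutant). A gene lower in the mutant whose
#' expression the treatment raises back toward WT at the genotype-
#' significant time points is `up_restored`; the mirror case is
#' `down_restored`; everything else (including non-DEGs) is `other`.
#'
#' @param deg_wt_mut [deg_call()] result for WT vs mutant.
#' @param deg_trt_mut [deg_call()] result for treated-mutant vs mutant,
#'   same features and time points.
#' @return Tibble `feature`, `direction_class`.
#' @export
classify_restoration <- function(deg_wt_mut, deg_trt_mut) {
  sig_tp <- deg_wt_mut %>%
    filter(.data$sig) %>%
    select("feature", "time_h", wt_lfc = "log2fc")
  if (!nrow(sig_tp)) {
    return(tibble(feature = unique(deg_wt_mut$feature),
                  direction_class = "other"))
  }
  joined <- inner_join(
    sig_tp,
    select(deg_trt_mut, "feature", "time_h", trt_lfc = "log2fc"),
    by = c("feature", "time_h")
  ) %>%
    group_by(.data$feature) %>%
    summarise(wt_dir = sign(mean(.data$wt_lfc)),
              trt_dir = sign(mean(.data$trt_lfc)),
              .groups = "drop") %>%
    mutate(direction_class = dplyr::case_when(
      .data$wt_dir > 0 & .data$trt_dir > 0 ~ "up_restored",
      .data$wt_dir < 0 & .data$trt_dir < 0 ~ "down_restored",
      TRUE ~ "other"
    ))
  tibble(feature = unique(deg_wt_mut$feature)) %>%
    left_join(select(joined, "feature", "direction_class"), by = "feature") %>%
    mutate(direction_class = dplyr::coalesce(.data$direction_class, "other"))
}

#' Fit a two-class OPLS-DA model
#'
#' NIPALS orthogonal projections to latent structures discriminant
#' analysis with one orthogonal-signal-correction component followed by
#' one predictive PLS component, on a centred unit-variance-scaled matrix.
#'
#' @param x Samples x variables numeric matrix (typically log-transformed
#'   abundances).
#' @param classes Two-level factor/character vector of length `nrow(x)`.
#' @param scale Centre and unit-variance scale columns (default TRUE);
#'   constant variables are dropped with a warning.
#' @param n_orth Number of orthogonal components (default 1).
#' @return Object of class `opls_da` with predictive weights/scores/
#'   loadings, the orthogonal counterparts, and per-variable VIP scores
#'   (first predictive component, so sum(VIP^2) equals the number of
#'   retained variables).
#' @export
fit_oplsda <- function(x, classes, scale = TRUE, n_orth = 1) {
  if (!is.matrix(x)) x <- as.matrix(x)
  cls <- as.factor(classes)
  if (nlevels(cls) != 2L) abort("OPLS-DA needs exactly two classes.")
  if (min(table(cls)) < 1L) abort("each class needs >= 1 sample.")
  y <- ifelse(cls == levels(cls)[2], 1, -1)
  y <- y - mean(y)
  keep <- rep(TRUE, ncol(x))
  if (scale) {
    sds <- apply(x, 2, sd)
    keep <- sds > 0
    if (any(!keep)) {
      warn(paste0(sum(!keep), " constant variable(s) dropped from OPLS-DA."))
    }
    x <- scale(x[, keep, drop = FALSE])
  } else {
    x <- scale(x[, keep, drop = FALSE], scale = FALSE)
  }
  p_used <- ncol(x)
  if (!p_used) abort("no non-constant variables left.")
  ssx_total <- sum(x^2)
  unit <- function(v) v / sqrt(sum(v^2))

  orth <- list()
  for (a in seq_len(n_orth)) {
    w <- unit(drop(crossprod(x, y)))
    t_p <- drop(x %*% w)
    p_l <- drop(crossprod(x, t_p)) / sum(t_p^2)
    w_o <- p_l - drop(crossprod(w, p_l)) * w
    if (sqrt(sum(w_o^2)) < 1e-12) break  # nothing orthogonal to remove
    w_o <- unit(w_o)
    t_o <- drop(x %*% w_o)
    p_o <- drop(crossprod(x, t_o)) / sum(t_o^2)
    x <- x - tcrossprod(t_o, p_o)
    orth[[a]] <- list(w = w_o, t = t_o, p = p_o)
  }

  w1 <- unit(drop(crossprod(x, y)))
  t1 <- drop(x %*% w1)
  p1 <- drop(crossprod(x, t1)) / sum(t1^2)
  q1 <- drop(crossprod(y, t1)) / sum(t1^2)
  vip <- sqrt(p_used) * abs(w1)  # single predictive component

  structure(list(
    weights = w1, scores = t1, loadings = p1, q = q1,
    orthogonal = orth, vip = setNames(vip, colnames(x)),
    variables = colnames(x), kept = keep, classes = cls,
    r2x_pred = sum(t1^2) * sum(p1^2) / ssx_total,
    r2y = 1 - sum((y - t1 * q1)^2) / sum(y^2),
    n = nrow(x), p = p_used
  ), class = "opls_da")
}

#' @export
print.opls_da <- function(x, ...) {
  cat("<opls_da> ", x$n, " samples x ", x$p, " variables, 1 predictive + ",
      length(x$orthogonal), " orthogonal component(s)\n", sep = "")
  cat("  R2Y = ", sprintf("%.3f", x$r2y), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_oplsda
#' @param x An `opls_da` fit (for the tidiers).
#' @param ... Unused.
#' @export
#' @exportS3Method generics::tidy
tidy.opls_da <- function(x, ...) {
  tibble(variable = x$variables, weight = unname(x$weights),
         loading = unname(x$loadings), vip = unname(x$vip))
}

#' @rdname fit_oplsda
#' @export
#' @exportS3Method generics::glance
glance.opls_da <- function(x, ...) {
  tibble(n = x$n, p = x$p, n_orth = length(x$orthogonal),
         r2x_pred = x$r2x_pred, r2y = x$r2y)
}

#' VIP scores from an OPLS-DA contrast
#'
#' Convenience wrapper: fits [fit_oplsda()] on log2(value + 1),
#' unit-variance-scaled abundances of the two sample groups and returns
#' variable importance in projection from the predictive component.
#'
#' @param mat Metabolites x samples abundance matrix.
#' @param classes Two-level labels, one per sample (column).
#' @param ... Passed to [fit_oplsda()].
#' @return Tibble `metabolite`, `vip` (dropped constant metabolites carry
#'   `NA`).
#' @export
opls_vip <- function(mat, classes, ...) {
  fit <- fit_oplsda(t(log2(mat + 1)), classes, ...)
  tibble(metabolite = rownames(mat)) %>%
    left_join(tibble(metabolite = fit$variables, vip = unname(fit$vip)),
              by = "metabolite")
}

#' Flag rhythmically accumulating metabolites
#'
#' With the 4-point diel metabolome design (light at 12 and 36 h, dark at
#' 20 and 42 h), a metabolite accumulates rhythmically when the sign of
#' (dark mean - light mean) is identical in both diurnal cycles (20 vs 12
#' and 42 vs 36) and a pooled dark-vs-light Welch t-test gives p < 0.05.
#'
#' @param metab_exp Metabolite [tc_experiment()]; samples from all its
#'   conditions are pooled.
#' @param light_times,dark_times Paired cycle time points (defaults
#'   c(12, 36) and c(20, 42)).
#' @param alpha Significance level for the pooled test (default 0.05).
#' @return Tibble `metabolite`, `rhythmic`, `dark_over_light`, `p`.
#' @export
rhythmic_dam <- function(metab_exp, light_times = c(12, 36),
                         dark_times = c(20, 42), alpha = 0.05) {
  stopifnot(inherits(metab_exp, "tc_experiment"))
  des <- metab_exp$design
  needed <- c(light_times, dark_times)
  missing_tp <- setdiff(needed, unique(des$time_h))
  if (length(missing_tp)) {
    abort(paste0("metabolome design is missing time point(s): ",
                 paste(missing_tp, collapse = ", "), " h."))
  }
  mean_at <- function(tp) {
    rowMeans(metab_exp$values[, des$sample_id[des$time_h == tp],
                              drop = FALSE])
  }
  d1 <- mean_at(dark_times[1]) - mean_at(light_times[1])
  d2 <- mean_at(dark_times[2]) - mean_at(light_times[2])
  dark_ids <- des$sample_id[des$time_h %in% dark_times]
  light_ids <- des$sample_id[des$time_h %in% light_times]
  p <- vapply(seq_len(nrow(metab_exp$values)), function(i) {
    xd <- metab_exp$values[i, dark_ids]
    xl <- metab_exp$values[i, light_ids]
    if (sd(xd) == 0 && sd(xl) == 0) return(1)
    tryCatch(t.test(xd, xl)$p.value, error = function(e) 1)
  }, numeric(1))
  tibble(
    metabolite = rownames(metab_exp$values),
    rhythmic = sign(d1) == sign(d2) & sign(d1) != 0 & p < alpha,
    dark_over_light = sign(d1) == sign(d2) & d1 > 0,
    p = p
  )
}

#' Call differentially accumulated metabolites
#'
#' A metabolite is a DAM when its OPLS-DA VIP for the contrast is >=
#' `vip_min` and its raw group-mean fold change is >= `fc_up` or <=
#' `fc_down` (all thresholds inclusive). When a treatment condition is
#' given, each metabolite is also classified by treatment response:
#' `up_by_GA` when it sits lower in the mutant than WT and the treatment
#' raises it, `down_by_GA` for the mirror pattern, `none` otherwise.
#'
#' @param metab_exp Metabolite [tc_experiment()] containing the contrast
#'   conditions (and the treatment condition, if requested).
#' @param contrast Length-2 character vector `c(group1, group2)`; the fold
#'   change is mean(group1)/mean(group2) over all matched samples.
#' @param treatment Optional condition label of the treated group used for
#'   direction classification (requires both contrast conditions present).
#' @param annotations Optional tibble `metabolite`, `klass` merged onto
#'   the result.
#' @param vip_min,fc_up,fc_down Thresholds (defaults 1, 2, 0.5).
#' @return Tibble with `metabolite`, `klass`, `vip`, `fold_change`,
#'   `is_dam`, `ga_direction`, `rhythmic`, `dark_over_light`.
#' @export
dam_call <- function(metab_exp, contrast = c("MUT", "WT"),
                     treatment = "MUT_GA", annotations = NULL,
                     vip_min = 1, fc_up = 2, fc_down = 0.5) {
  stopifnot(inherits(metab_exp, "tc_experiment"))
  des <- metab_exp$design
  for (cond in contrast) {
    if (!cond %in% des$condition) abort(paste0("condition not found: ", cond))
  }
  ids1 <- des$sample_id[des$condition == contrast[1]]
  ids2 <- des$sample_id[des$condition == contrast[2]]
  m1 <- rowMeans(metab_exp$values[, ids1, drop = FALSE])
  m2 <- rowMeans(metab_exp$values[, ids2, drop = FALSE])
  if (any(m2 == 0)) abort("zero denominator group mean; cannot form fold change.")
  sub <- filter_condition(metab_exp, contrast)
  vip <- opls_vip(sub$values, sub$design$condition)
  out <- vip %>%
    mutate(
      fold_change = m1 / m2,
      is_dam = !is.na(.data$vip) & .data$vip >= vip_min &
        (.data$fold_change >= fc_up | .data$fold_change <= fc_down)
    )
  if (!is.null(treatment) && treatment %in% des$condition) {
    mt <- rowMeans(
      metab_exp$values[, des$sample_id[des$condition == treatment],
                       drop = FALSE]
    )
    # contrast[1] is the mutant-like group, contrast[2] the WT-like group
    out$ga_direction <- dplyr::case_when(
      m1 < m2 & mt > m1 ~ "up_by_GA",
      m1 > m2 & mt < m1 ~ "down_by_GA",
      TRUE ~ "none"
    )
  } else {
    out$ga_direction <- "none"
  }
  rhy <- tryCatch(rhythmic_dam(metab_exp), error = function(e) NULL)
  if (!is.null(rhy)) {
    out <- left_join(out, select(rhy, "metabolite", "rhythmic",
                                 "dark_over_light"),
                     by = "metabolite")
  } else {
    out$rhythmic <- NA
    out$dark_over_light <- NA
  }
  if (!is.null(annotations)) {
    out <- left_join(out, annotations, by = "metabolite")
  }
  out
}

#' Per-class counts and percentages of a metabolite subset
#'
#' Percentages are rounded half-up to one decimal; `pct_label` drops a
#' trailing ".0" so 11 of 55 prints as "20%".
#'
#' @param df Data frame with a `klass` column, one row per metabolite in
#'   the subset of interest.
#' @param total Denominator (defaults to `nrow(df)`).
#' @return Tibble `klass`, `n`, `pct`, `pct_label`, descending by count.
#' @export
dam_class_summary <- function(df, total = nrow(df)) {
  if (!nrow(df)) abort("empty subset: nothing to summarise.")
  if (!"klass" %in% names(df)) abort("`df` must have a `klass` column.")
  df %>%
    dplyr::count(.data$klass, name = "n") %>%
    mutate(
      pct = round_half_up(100 * .data$n / total, 1),
      pct_label = ifelse(.data$pct == round(.data$pct),
                         sprintf("%g%%", .data$pct),
                         sprintf("%.1f%%", .data$pct))
    ) %>%
    arrange(dplyr::desc(.data$n))
}
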