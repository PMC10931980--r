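#' Cosine molecular-timetable screen
#'
#' Fits a feature's per-time-point mean profile against 24-h cosine
#' templates over a grid of candidate peak phases. `R` is the maximal
#' Pearson correlation with any template; `CV` (sd/mean of the per-time
#' means, population denominator) proxies relative amplitude. Circadian
#' features are conventionally required to satisfy CV >= 0.3 and R >= 0.9.
#'
#' @param means Numeric vector of per-time-point replicate means.
#' @param times Time points in hours (same length as `means`, >= 5
#'   distinct values).
#' @param period Oscillation period in hours (default 24).
#' @param phase_step Candidate phase spacing in hours (default 1, giving
#'   the 24 hourly phase groups).
#' @return One-row tibble: `phase_zt` (argmax phase, ties to the smallest
#'   candidate), `R`, `cv`, `amplitude_rel` (least-squares relative
#'   amplitude of the winning template), `degenerate` (TRUE when the
#'   profile is constant and `R` is returned as 0).
#' @export
cosine_screen <- function(means, times, period = 24, phase_step = 1) {
  if (length(means) != length(times)) abort("`means`/`times` length mismatch.")
  if (length(unique(times)) < 5L) abort("need >= 5 distinct time points.")
  mu <- mean(means)
  if (mu <= 0) abort("mean abundance must be positive to compute CV.")
  cv <- sqrt(mean((means - mu)^2)) / mu
  if (sd(means) == 0) {
    return(tibble(phase_zt = NA_real_, R = 0, cv = cv,
                  amplitude_rel = 0, degenerate = TRUE))
  }
  phases <- seq(0, period - phase_step, by = phase_step)
  templates <- vapply(phases, function(ph) cos(2 * pi * (times - ph) / period),
                      numeric(length(times)))
  rs <- suppressWarnings(as.vector(cor(means, templates)))
  rs[is.na(rs)] <- -Inf  # constant template (cannot happen for >=5 distinct t)
  best <- which(rs >= max(rs) - 1e-12)[1]
  tmpl <- templates[, best]
  b <- cov(means, tmpl) / var(tmpl)
  a <- mu - b * mean(tmpl)
  tibble(phase_zt = phases[best], R = rs[best], cv = cv,
         amplitude_rel = if (a > 0) b / a else NA_real_,
         degenerate = FALSE)
}

# ---------------------------------------------------------------------------
# JTK_CYCLE-style rank test internals
#
# For a candidate peak lag phi the reference waveform cos(2*pi*(t-phi)/P) is
# evaluated at each sample's time; the test statistic is the Kendall-type
# S = sum over reference-comparable pairs of sign(x_i - x_j)*sign(ref_i -
# ref_j). Ties in the reference (inevitable with repeated times and the
# cosine's symmetry) partition samples into ordered groups, making S a
# shifted Jonckheere-Terpstra statistic; its exact null distribution for a
# given tie pattern is the q-multinomial coefficient, computed by
# convolving Mann-Whitney (Gaussian binomial) distributions.
# ---------------------------------------------------------------------------

# counts of the Mann-Whitney U statistic for group sizes (m, n):
# coefficients of the Gaussian binomial [m+n choose n]_q, by interleaved
# polynomial multiplication by (1 - q^(m+i)) and division by (1 - q^i)
mw_counts <- function(m, n) {
  if (m == 0 || n == 0) return(1)
  co <- 1
  for (i in seq_len(n)) {
    a <- m + i
    len <- length(co) + a
    nxt <- numeric(len)
    nxt[seq_along(co)] <- co
    nxt[(a + 1):len] <- nxt[(a + 1):len] - co
    # divide by (1 - q^i): cumulative recurrence c[j] += c[j - i]
    if (len > i) for (j in (i + 1):len) nxt[j] <- nxt[j] + nxt[j - i]
    # exact division leaves degree m*i at step i
    co <- nxt[seq_len(m * i + 1)]
  }
  co
}

# exact null distribution of J (number of concordances between a tied
# reference with group sizes `sizes` and an untied exchangeable ranking),
# as a probability vector over J = 0..M with M = sum_{i<j} n_i n_j
jt_null <- function(sizes) {
  sizes <- sizes[sizes > 0]
  dist <- 1
  mcum <- sizes[1]
  if (length(sizes) > 1) for (g in sizes[-1]) {
    u <- mw_counts(mcum, g)
    # open convolution
    nd <- numeric(length(dist) + length(u) - 1)
    for (i in seq_along(dist)) {
      idx <- i:(i + length(u) - 1)
      nd[idx] <- nd[idx] + dist[i] * u
    }
    dist <- nd
    mcum <- mcum + g
  }
  dist / sum(dist)
}

# two-sided tail table: p_abs[s+1] = P(|S| >= s) for s = 0..M, S = 2J - M
jtk_tail_table <- function(sizes) {
  pj <- jt_null(sizes)
  M <- length(pj) - 1L
  s_abs <- abs(2 * seq(0, M) - M)
  p_abs <- numeric(M + 1L)
  for (s in 0:M) p_abs[s + 1L] <- sum(pj[s_abs >= s])
  list(M = M, p_abs = pmin(p_abs, 1))
}

# normal approximation with continuity correction for n > jtk_exact_limit
jtk_normal_p <- function(s_obs, sizes) {
  N <- sum(sizes)
  varJ <- (N^2 * (2 * N + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72
  if (varJ <= 0) return(1)
  z <- (abs(s_obs) - 1) / (2 * sqrt(varJ))
  min(1, 2 * pnorm(-max(z, 0)))
}

# per-lag reference structures for one sampling design (shared across genes)
jtk_references <- function(times, period, lag_step, pair_idx) {
  lags <- seq(0, period - lag_step, by = lag_step)
  purrr::map(lags, function(lag) {
    ref <- round(cos(2 * pi * (times - lag) / period), 9)
    sref <- sign(ref[pair_idx[, 1]] - ref[pair_idx[, 2]])
    sizes <- sort(as.integer(table(ref)))
    list(lag = lag, sref = sref, sizes = sizes,
         n_comparable = sum(sref != 0))
  })
}

jtk_exact_limit <- 30L

# test one profile against prebuilt references; tails cached by tie pattern
jtk_profile <- function(x, refs, pair_idx, n, cache) {
  sx <- sign(x[pair_idx[, 1]] - x[pair_idx[, 2]])
  if (all(sx == 0)) {
    return(list(p = 1, best_lag = NA_real_, tau = 0, p_by_lag = NULL))
  }
  s_lag <- vapply(refs, function(rf) sum(sx * rf$sref), numeric(1))
  p_lag <- vapply(seq_along(refs), function(k) {
    rf <- refs[[k]]
    if (n <= jtk_exact_limit) {
      key <- paste(rf$sizes, collapse = ",")
      tab <- cache[[key]]
      if (is.null(tab)) {
        tab <- jtk_tail_table(rf$sizes)
        cache[[key]] <- tab
      }
      tab$p_abs[min(abs(s_lag[k]), tab$M) + 1L]
    } else {
      jtk_normal_p(s_lag[k], rf$sizes)
    }
  }, numeric(1))
  # the two-sided p ties a lag with its antiphase; prefer the concordant
  # (positive-S) lag, then the smaller lag, so the reported peak matches
  # the waveform's phase
  cand <- which(p_lag <= min(p_lag) + 1e-14)
  best <- cand[order(-s_lag[cand], cand)][1]
  list(
    p = min(1, length(refs) * p_lag[best]),
    best_lag = refs[[best]]$lag,
    tau = s_lag[best] / refs[[best]]$n_comparable,
    p_by_lag = setNames(p_lag, vapply(refs, `[[`, numeric(1), "lag"))
  )
}

#' JTK_CYCLE-style nonparametric rhythmicity test
#'
#' Compares all replicate observations of one feature against phase-lagged
#' 24-h cosine references via a Kendall-type statistic. Per lag, the
#' two-sided p-value comes from the exact null distribution of the
#' statistic given the reference's tie pattern (by convolution) for up to
#' 30 samples, and from a normal approximation with continuity correction
#' above that. The reported p is Bonferroni-corrected over the lag grid.
#' Because the two-sided statistic ties each lag with its antiphase, the
#' reported `best_lag` is the concordant one (largest S) among the
#' minimum-p lags, then the smallest such lag.
#'
#' `tau` is the statistic divided by the number of reference-comparable
#' pairs, so an observation series perfectly concordant with a (possibly
#' tied) reference scores 1. Tied observations are handled as zero-sign
#' pairs in the statistic; the exact null assumes continuous data.
#'
#' @param x Observations (replicates kept separate), length >= 8.
#' @param times Sampling time of each observation, hours.
#' @param period Period in hours (default 24).
#' @param lag_step Lag grid spacing in hours (default 2).
#' @return One-row tibble: `jtk_p`, `best_lag`, `jtk_tau`.
#' @export
jtk_cycle <- function(x, times, period = 24, lag_step = 2) {
  n <- length(x)
  if (n < 8L) abort("jtk_cycle needs >= 8 observations.")
  if (length(times) != n) abort("`x`/`times` length mismatch.")
  pair_idx <- t(combn(n, 2))
  refs <- jtk_references(times, period, lag_step, pair_idx)
  cache <- new.env(parent = emptyenv())
  res <- jtk_profile(x, refs, pair_idx, n, cache)
  tibble(jtk_p = res$p, best_lag = res$best_lag, jtk_tau = res$tau)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) p_(j) * m / j`, capped at 1,
#' returned in input order. Thin validated wrapper over
#' [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1] and be non-missing.")
  }
  p.adjust(pvals, method = "BH")
}

#' Call circadian features per condition
#'
#' Applies the dual criterion per feature and condition: the cosine screen
#' on per-time-point replicate means (CV >= `cv_min` and R >= `r_min`,
#' both inclusive) and the JTK-style test on all replicate observations
#' with Benjamini-Hochberg adjustment across features within the condition
#' (q < `q_max`, strict). `combine = "or"` relaxes the verdict to the
#' union of the two criteria.
#'
#' Features whose screen fails numerically (e.g. all-zero profiles) are
#' retained as non-circadian with `degenerate = TRUE`.
#'
#' @param exp A [tc_experiment()]; all its conditions are processed.
#' @param period,phase_step,lag_step See [cosine_screen()] and
#'   [jtk_cycle()].
#' @param cv_min,r_min,q_max Calling thresholds (defaults 0.3, 0.9, 0.01).
#' @param combine `"and"` (default) or `"or"`.
#' @return Tibble of class `rhythm_calls`: one row per (feature,
#'   condition) with `phase_zt`, `R`, `cv`, `amplitude_rel`, `jtk_p`,
#'   `jtk_q`, `jtk_tau`, `best_lag`, `circadian`, `degenerate`.
#' @export
call_circadian <- function(exp, period = 24, phase_step = 1, lag_step = 2,
                           cv_min = 0.3, r_min = 0.9, q_max = 0.01,
                           combine = c("and", "or")) {
  stopifnot(inherits(exp, "tc_experiment"))
  combine <- match.arg(combine)
  conds <- unique(exp$design$condition)
  out <- purrr::map(conds, function(cond) {
    sub <- filter_condition(exp, cond)
    tm <- timepoint_means(sub)
    tps <- as.numeric(colnames(tm))
    stimes <- sub$design$time_h
    n <- length(stimes)
    pair_idx <- t(combn(n, 2))
    refs <- jtk_references(stimes, period, lag_step, pair_idx)
    cache <- new.env(parent = emptyenv())
    rows <- purrr::map(seq_len(nrow(tm)), function(i) {
      cs <- tryCatch(
        cosine_screen(tm[i, ], tps, period = period, phase_step = phase_step),
        error = function(e) tibble(phase_zt = NA_real_, R = 0, cv = 0,
                                   amplitude_rel = NA_real_, degenerate = TRUE)
      )
      jt <- jtk_profile(sub$values[i, ], refs, pair_idx, n, cache)
      mutate(cs, feature = rownames(tm)[i],
             jtk_p = jt$p, jtk_tau = jt$tau, best_lag = jt$best_lag)
    }) %>% bind_rows()
    rows$condition <- cond
    rows$jtk_q <- bh_adjust(rows$jtk_p)
    rows
  }) %>% bind_rows()
  pass_cos <- out$cv >= cv_min & out$R >= r_min & !out$degenerate
  pass_jtk <- out$jtk_q < q_max
  out$circadian <- if (combine == "and") pass_cos & pass_jtk
  else pass_cos | pass_jtk
  out <- select(out, "feature", "condition", "phase_zt", "R", "cv",
                "amplitude_rel", "jtk_p", "jtk_q", "jtk_tau", "best_lag",
                "circadian", "degenerate")
  class(out) <- c("rhythm_calls", class(out))
  out
}

#' Features circadian in every condition
#'
#' @param calls A [call_circadian()] result covering >= 2 conditions.
#' @return Character vector of conserved circadian feature ids.
#' @export
conserved_circadian <- function(calls) {
  conds <- unique(calls$condition)
  if (length(conds) < 2L) abort("need calls for >= 2 conditions.")
  calls %>%
    filter(.data$circadian) %>%
    dplyr::count(.data$feature) %>%
    filter(.data$n == length(conds)) %>%
    pull(.data$feature)
}

#' Hourly phase groups and light/dark peak classification
#'
#' Circadian features are binned into 24 hourly groups by rounding their
#' estimated peak phase; a group inside the light window peaks in light.
#'
#' @param calls A [call_circadian()] result (non-circadian rows ignored).
#' @param light_window Hours `c(on, off)`, default 16L:8D.
#' @return Tibble `feature`, `condition`, `group` (0..23), `peak_light`,
#'   with a `summary` attribute (per-condition light/dark counts and the
#'   dark-peaking percentage).
#' @export
phase_groups <- function(calls, light_window = c(0, 16)) {
  g <- calls %>%
    filter(.data$circadian, !is.na(.data$phase_zt)) %>%
    mutate(group = round_half_up(.data$phase_zt) %% 24,
           peak_light = in_light(.data$group, light_window)) %>%
    select("feature", "condition", "group", "peak_light")
  smry <- g %>%
    group_by(.data$condition) %>%
    summarise(n_light = sum(.data$peak_light),
              n_dark = sum(!.data$peak_light),
              pct_dark = round_half_up(100 * mean(!.data$peak_light), 1),
              .groups = "drop")
  attr(g, "summary") <- smry
  g
}

#' Amplitude and circular phase shifts between two conditions
#'
#' For features circadian in both conditions, reports the signed amplitude
#' difference and the circular phase difference mapped into (-12, 12].
#'
#' @param calls_a,calls_b Single-condition slices of a [call_circadian()]
#'   result (A is the reference).
#' @return Tibble `feature`, `d_amplitude`, `d_phase`.
#' @export
amplitude_phase_delta <- function(calls_a, calls_b) {
  a <- filter(calls_a, .data$circadian)
  b <- filter(calls_b, .data$circadian)
  inner_join(
    select(a, "feature", amp_a = "amplitude_rel", ph_a = "phase_zt"),
    select(b, "feature", amp_b = "amplitude_rel", ph_b = "phase_zt"),
    by = "feature"
  ) %>%
    mutate(
      d_amplitude = .data$amp_b - .data$amp_a,
      d_phase = ((.data$ph_b - .data$ph_a + 12) %% 24) - 12,
      d_phase = ifelse(.data$d_phase == -12, 12, .data$d_phase)
    ) %>%
    select("feature", "d_amplitude", "d_phase")
}
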