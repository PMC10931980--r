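# shared small fixtures, built in code

# minimal single-condition experiment: `profiles` is a named list of
# per-time-point expected values; replicates get identical values unless
# noise_fun is given
toy_experiment <- function(profiles, times = c(0, 4, 8, 12, 16, 20, 24, 30, 36, 42, 48),
                           reps = 2, condition = "WT", noise_fun = NULL) {
  design <- expand.grid(time_h = times, replicate = seq_len(reps))
  design$condition <- condition
  design$sample_id <- paste0(condition, "_t", design$time_h, "_r", design$replicate)
  vals <- do.call(rbind, lapply(profiles, function(p) {
    stopifnot(length(p) == length(times))
    rep(p, times = reps)
  }))
  if (!is.null(noise_fun)) vals <- vals * noise_fun(length(vals))
  rownames(vals) <- names(profiles)
  colnames(vals) <- design$sample_id
  tc_experiment(vals, design[, c("sample_id", "condition", "time_h", "replicate")])
}

cosine_profile <- function(baseline, amplitude, phase, times) {
  baseline * (1 + amplitude * cos(2 * pi * (times - phase) / 24))
}

# brute-force Kendall-type S between x and a reference with possible ties
brute_S <- function(x, ref) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(x[i] - x[j]) * sign(ref[i] - ref[j])
  }
  s
}

# enumerate the exact two-sided null of S for small n by full permutation
enumerate_null_p <- function(s_obs, ref) {
  n <- length(ref)
  perms <- gtools_permutations(n)
  svals <- apply(perms, 1, function(ord) brute_S(seq_len(n)[ord], ref))
  mean(abs(svals) >= abs(s_obs))
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  k <- 1
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[k, ] <- c(i, rest[sub[r, ]])
      k <- k + 1
    }
  }
  out
}

# area under the precision-recall curve for a ranking (ties broken by order)
aupr <- function(scores, labels) {
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(lab)
  sum(prec * c(rec[1], diff(rec)))
}
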