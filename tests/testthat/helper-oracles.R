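# Independent oracles, kept deliberately naive and separate from the
# implementation code paths they check.

# One-sided rank-sum p-value by exhaustive enumeration over index subsets:
# the probability, under exchangeability, that a random size-n1 subset of
# the combined midranks has sum >= the observed target rank sum.
oracle_wilcox_p <- function(target, bg) {
  x <- c(target, bg)
  if (max(x) == min(x)) return(0.5)
  r <- rank(x)
  n1 <- length(target)
  w <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(x), n1)
  sums <- apply(idx, 2L, function(i) sum(r[i]))
  mean(sums >= w - 1e-9)
}

# Rank-mean quantile normalization, written the long way: reference
# distribution = row means of column-sorted values; each value replaced by
# the reference at its midrank (ties averaged over their positions).
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "average")
    # interpolate reference for fractional midranks
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (ref[lo] + ref[hi]) / 2
  }
  out
}

# Spearman via the classical tie-free closed form 1 - 6*sum(d^2)/(n(n^2-1)).
oracle_spearman_tiefree <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force re-implementation of the s0 percentile sweep (same rule,
# independent code): candidates = percentiles 0,5,...,100 of s; windows =
# quantile bins of s; minimize sd/mean of within-window mad(d).
oracle_choose_s0 <- function(r, s) {
  n <- length(s)
  cand <- unname(quantile(s, seq(0, 1, 0.05)))
  ngroups <- min(100, max(2, floor(n / 5)))
  br <- unique(quantile(s, seq(0, 1, length.out = ngroups + 1)))
  grp <- cut(s, br, include.lowest = TRUE)
  cvs <- sapply(cand, function(a) {
    d <- r / (s + a)
    v <- tapply(d, grp, mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(if (sd(v) == 0) 0 else Inf)
    sd(v) / mean(v)
  })
  cand[which.min(cvs)]
}

# Small, fast simulation parameter sets used across test files.
tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_features = 40L, n_background = 60L, probes_per_set = 3L,
         n_subjects = 2L, n_males = 3L, n_females = 3L,
         de_features = 2L, seed = 421L),
    list(...))
  do.call(sim_params, args)
}

small_params <- function(...) {
  args <- utils::modifyList(
    list(n_features = 120L, n_background = 120L, probes_per_set = 4L,
         n_subjects = 3L, n_males = 5L, n_females = 6L,
         de_features = 3L, seed = 99L),
    list(...))
  do.call(sim_params, args)
}
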