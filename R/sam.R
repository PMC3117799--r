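# Two-class unpaired SAM: modified t-scores with an exchangeability
# constant s0, permutation expected order statistics, delta-sweep FDR
# estimation and SAM-style q-values.

# Coerce group labels to a two-level factor; the SECOND level is the "up"
# direction (females, for the M/F cohort design).
as_sam_groups <- function(groups) {
  g <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  g
}

# Core statistic on a features x samples matrix given the level-2 column
# index set. Returns numerator r (mean2 - mean1), pooled scatter s, and
# d = r / (s + s0). A feature with r = 0 and s + s0 = 0 scores 0.
sam_stat <- function(X, idx2, s0 = 0) {
  n <- ncol(X)
  n2 <- length(idx2)
  n1 <- n - n2
  X2sum <- rowSums(X[, idx2, drop = FALSE])
  Xtot <- rowSums(X)
  m2 <- X2sum / n2
  m1 <- (Xtot - X2sum) / n1
  sq2 <- rowSums(X[, idx2, drop = FALSE]^2)
  sqtot <- rowSums(X^2)
  rss <- (sq2 - n2 * m2^2) + ((sqtot - sq2) - n1 * m1^2)
  rss[rss < 0] <- 0 # numerical guard
  s <- sqrt((1 / n1 + 1 / n2) * rss / (n1 + n2 - 2))
  r <- m2 - m1
  denom <- s + s0
  d <- ifelse(denom == 0, ifelse(r == 0, 0, sign(r) * Inf), r / denom)
  list(d = d, s = s, r = r)
}

#' SAM modified t-scores
#'
#' For each feature, `d = (mean2 - mean1) / (s + s0)` where `s` is the
#' pooled standard error
#' `sqrt((1/n1 + 1/n2) * (rss1 + rss2) / (n1 + n2 - 2))` and `s0` is the
#' exchangeability constant damping scores of low-variance features. The
#' second factor level is the positive direction (with an M/F cohort and
#' levels `c("M", "F")`, positive scores are up-regulated in females).
#' With `s0 = 0` the score equals the classical equal-variance two-sample
#' t statistic.
#'
#' @param expr log2 probe-set matrix (features x samples).
#' @param groups two-level factor (or vector) aligned with the columns.
#' @param s0 exchangeability constant (default 0; see [choose_s0()]).
#' @return named numeric vector of per-feature scores.
#' @export
sam_scores <- function(expr, groups, s0 = 0) {
  check_matrix(expr)
  g <- as_sam_groups(groups)
  if (length(g) != ncol(expr)) stop("groups must match the matrix columns")
  st <- sam_stat(expr, which(g == levels(g)[2L]), s0 = s0)
  stats::setNames(st$d, rownames(expr))
}

#' Choose the SAM exchangeability constant s0
#'
#' Tusher-style tuning: candidate values are the percentiles
#' 0, 5, ..., 100 of the per-feature scatter `s`; for each candidate the
#' features are binned into quantile windows of `s` and the candidate
#' minimizing the coefficient of variation of the within-window median
#' absolute deviation of `d` is selected. Deterministic; ties resolve to
#' the smallest candidate. When every `s` is identical the 5th percentile
#' (that common value) is returned.
#'
#' @param r per-feature numerator (group mean difference).
#' @param s per-feature pooled scatter (same length, >= 10 features).
#' @return scalar s0.
#' @export
choose_s0 <- function(r, s) {
  if (length(r) != length(s)) stop("r and s must have equal length")
  n <- length(s)
  if (n < 10L) stop("need at least 10 features to tune s0")
  if (max(s) == min(s)) {
    message("all per-feature scatters identical; s0 fixed at their 5th percentile")
    return(unname(stats::quantile(s, 0.05)))
  }
  candidates <- unname(stats::quantile(s, seq(0, 1, by = 0.05)))
  ngroups <- min(100L, max(2L, floor(n / 5)))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = ngroups + 1L)))
  grp <- cut(s, breaks = br, include.lowest = TRUE)
  cv <- vapply(candidates, function(a) {
    d <- r / (s + a)
    v <- tapply(d, grp, stats::mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) return(if (stats::sd(v) == 0) 0 else Inf)
    stats::sd(v) / mean(v)
  }, numeric(1L))
  candidates[which.min(cv)]
}

# Distinct two-group label splits as a matrix of level-2 column index sets
# (n2 x B). Enumerates all C(n, n2) splits when that count is at most
# n_perm; otherwise samples distinct splits uniformly.
sample_splits <- function(n, n2, n_perm, seed) {
  total <- choose(n, n2)
  if (total <= n_perm) {
    message("only ", total, " distinct label splits; enumerating all of them")
    return(utils::combn(n, n2))
  }
  with_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- matrix(0L, nrow = n2, ncol = n_perm)
    b <- 0L
    while (b < n_perm) {
      idx <- sort(sample.int(n, n2))
      key <- paste(idx, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        b <- b + 1L
        out[, b] <- idx
      }
    }
    out
  })
}

#' Permutation null for SAM scores
#'
#' Recomputes the score vector under permuted group labels (distinct label
#' splits, enumerated exhaustively when fewer than `n_perm` exist, sampled
#' uniformly without replacement otherwise) and sorts each permutation's
#' scores. The expected score at rank r is the mean over permutations of
#' the r-th order statistic.
#'
#' @param expr log2 probe-set matrix.
#' @param groups two-level factor aligned with the columns.
#' @param s0 exchangeability constant (the one used for the observed scores).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the label sampling.
#' @return list with `d_expected` (ascending rank order), `perms` (matrix
#'   of sorted permuted scores, features x permutations), `n_perm` and
#'   `seed`.
#' @export
permutation_null <- function(expr, groups, s0 = 0, n_perm = 1000L, seed = 17L) {
  check_matrix(expr)
  g <- as_sam_groups(groups)
  if (length(g) != ncol(expr)) stop("groups must match the matrix columns")
  n2 <- sum(g == levels(g)[2L])
  splits <- sample_splits(ncol(expr), n2, n_perm, seed)
  B <- ncol(splits)
  # vectorized over permutations: indicator matrix W (samples x B)
  W <- matrix(0, nrow = ncol(expr), ncol = B)
  W[cbind(as.vector(splits), rep(seq_len(B), each = n2))] <- 1
  n <- ncol(expr)
  n1 <- n - n2
  X2 <- expr^2
  sum2 <- expr %*% W          # per-perm group-2 sums
  sq2 <- X2 %*% W
  tot <- rowSums(expr)
  sqtot <- rowSums(X2)
  m2 <- sum2 / n2
  m1 <- (tot - sum2) / n1
  rss <- (sq2 - n2 * m2^2) + ((sqtot - sq2) - n1 * m1^2)
  rss[rss < 0] <- 0
  s <- sqrt((1 / n1 + 1 / n2) * rss / (n1 + n2 - 2))
  r <- m2 - m1
  denom <- s + s0
  d <- ifelse(denom == 0, ifelse(r == 0, 0, sign(r) * Inf), r / denom)
  perms <- apply(d, 2L, sort)
  list(d_expected = rowMeans(perms), perms = perms,
       n_perm = B, seed = seed)
}

#' Delta-sweep thresholding, FDR estimation and q-values
#'
#' Sweeps the SAM threshold delta over the observed deviations
#' `|d - d_expected|`. At a given delta, the upper cut is the smallest
#' observed score whose deviation above the expected score exceeds delta
#' (on the positive side of the expected curve), and symmetrically for the
#' lower cut; features beyond a cut are called. The estimated FDR at delta
#' is the average number of permuted scores beyond the cuts per
#' permutation, divided by the observed call count; it is exactly 0 when no
#' permuted score in any permutation exceeds the cuts, i.e. when every
#' called feature is more extreme than the entire permutation null — the
#' situation in which a q-value of 0 is reported. (`count_stat = "median"`
#' pools the counts by their median instead; that variant declares FDR 0
#' whenever half the permutations show no exceedance, which produces a
#' false singleton call on about half of null datasets.) The chosen delta
#' is the smallest one with estimated FDR at most `fdr_target`; a feature's
#' q-value is the minimum estimated FDR over all deltas at which it is
#' called (1 when it is never called).
#'
#' @param d observed scores (named).
#' @param d_expected expected order statistics (ascending), from
#'   [permutation_null()].
#' @param perms sorted permuted score matrix from [permutation_null()].
#' @param fdr_target nominal FDR (default 0.05).
#' @param count_stat how permuted exceedance counts are pooled across
#'   permutations for the FDR numerator: `"mean"` (default) or `"median"`.
#' @return list with `significant` (feature ids), `delta` (chosen value,
#'   `Inf` when no delta meets the target with calls), `fdr` (estimated FDR
#'   at the chosen delta), `qvalue` (per feature, in input order),
#'   `cut_up`, `cut_low` and the full `delta_table`.
#' @export
sam_threshold <- function(d, d_expected, perms, fdr_target = 0.05,
                          count_stat = c("mean", "median")) {
  count_stat <- match.arg(count_stat)
  nf <- length(d)
  if (length(d_expected) != nf || nrow(perms) != nf) {
    stop("d, d_expected and perms must come from matching runs")
  }
  ord <- order(d)
  dd <- d[ord]
  diffs <- dd - d_expected
  deltas <- sort(unique(c(0, abs(diffs))))
  ndelta <- length(deltas)

  cut_up <- rep(Inf, ndelta)
  cut_low <- rep(-Inf, ndelta)
  up_ok <- d_expected > 0
  low_ok <- d_expected < 0
  for (k in seq_len(ndelta)) {
    iu <- which(diffs > deltas[k] & up_ok)
    if (length(iu) > 0L) cut_up[k] <- dd[iu[1L]]
    il <- which(-diffs > deltas[k] & low_ok)
    if (length(il) > 0L) cut_low[k] <- dd[il[length(il)]]
  }

  n_called <- vapply(seq_len(ndelta), function(k) {
    sum(d >= cut_up[k] | d <= cut_low[k])
  }, numeric(1L))

  # permuted exceedance counts: columns of `perms` are sorted ascending, so
  # counts for all deltas come from one findInterval pass per permutation
  B <- ncol(perms)
  counts <- matrix(0, nrow = ndelta, ncol = B)
  for (b in seq_len(B)) {
    v <- perms[, b]
    ge_up <- nf - findInterval(cut_up, v, left.open = TRUE)
    le_low <- findInterval(cut_low, v)
    counts[, b] <- ge_up + le_low
  }
  pooled_count <- if (count_stat == "mean") {
    rowMeans(counts)
  } else {
    apply(counts, 1L, stats::median)
  }
  fdr <- ifelse(n_called > 0, pmin(1, pooled_count / n_called), 0)

  chosen <- which(fdr <= fdr_target)[1L]
  if (is.na(chosen)) {
    delta_hat <- Inf
    sig <- character(0L)
    fdr_hat <- NA_real_
    cu <- Inf
    cl <- -Inf
  } else {
    delta_hat <- deltas[chosen]
    cu <- cut_up[chosen]
    cl <- cut_low[chosen]
    sig <- names(d)[d >= cu | d <= cl]
    fdr_hat <- fdr[chosen]
  }

  qvalue <- rep(1, nf)
  names(qvalue) <- names(d)
  for (k in seq_len(ndelta)) {
    called_k <- d >= cut_up[k] | d <= cut_low[k]
    if (any(called_k)) {
      qvalue[called_k] <- pmin(qvalue[called_k], fdr[k])
    }
  }

  list(significant = sig, delta = delta_hat, fdr = fdr_hat, qvalue = qvalue,
       cut_up = cu, cut_low = cl,
       delta_table = data.frame(delta = deltas, cut_up = cut_up,
                                cut_low = cut_low, n_called = n_called,
                                fdr = fdr))
}

#' Drop significant features never detected in any cohort sample
#'
#' @param significant character vector of feature ids.
#' @param d `detection_table` covering the cohort samples.
#' @return the subset of `significant` with at least one detection call.
#' @export
detection_filter <- function(significant, d) {
  stopifnot(inherits(d, "detection_table"))
  if (length(significant) == 0L) return(character(0L))
  known <- intersect(significant, rownames(d$calls))
  detected <- rownames(d$calls)[rowSums(d$calls) > 0L]
  significant[significant %in% detected | !(significant %in% known)]
}

#' Linear-scale fold change between groups
#'
#' Ratio of group mean linear intensities, second level over first (female
#' over male for an M/F cohort). Log2 input is converted back to linear.
#'
#' @param expr probe-set matrix.
#' @param groups two-level factor aligned with the columns.
#' @return named per-feature ratio; NA where the first-group mean is zero.
#' @export
fold_change <- function(expr, groups) {
  check_matrix(expr)
  g <- as_sam_groups(groups)
  if (length(g) != ncol(expr)) stop("groups must match the matrix columns")
  lin <- as_linear(expr, get_scale(expr))
  m1 <- rowMeans(lin[, g == levels(g)[1L], drop = FALSE])
  m2 <- rowMeans(lin[, g == levels(g)[2L], drop = FALSE])
  stats::setNames(ifelse(m1 == 0, NA_real_, m2 / m1), rownames(expr))
}

#' Two-class unpaired SAM analysis
#'
#' Orchestrates the full procedure: per-feature modified t-scores with a
#' tuned (or supplied) exchangeability constant, permutation expected
#' scores, delta/FDR thresholding with q-values, linear fold changes and an
#' optional detection-call filter on the significant set.
#'
#' @param expr log2 probe-set matrix (features x samples).
#' @param groups two-level factor; second level is the positive direction.
#' @param fdr_target nominal FDR for the significant set (default 0.05).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for permutation sampling.
#' @param s0 exchangeability constant; tuned by [choose_s0()] when NULL.
#' @param detection optional `detection_table`; when given, significant
#'   features with zero detection calls are removed.
#' @param count_stat FDR numerator pooling, see [sam_threshold()].
#' @return object of class `sam_result`.
#' @export
sam <- function(expr, groups, fdr_target = 0.05, n_perm = 1000L, seed = 17L,
                s0 = NULL, detection = NULL,
                count_stat = c("mean", "median")) {
  check_matrix(expr)
  g <- as_sam_groups(groups)
  st <- sam_stat(expr, which(g == levels(g)[2L]), s0 = 0)
  if (is.null(s0)) s0 <- choose_s0(st$r, st$s)
  d <- stats::setNames(sam_stat(expr, which(g == levels(g)[2L]), s0 = s0)$d,
                       rownames(expr))
  null <- permutation_null(expr, g, s0 = s0, n_perm = n_perm, seed = seed)
  thr <- sam_threshold(d, null$d_expected, null$perms, fdr_target = fdr_target,
                       count_stat = count_stat)
  fc <- fold_change(expr, g)
  significant <- thr$significant
  removed <- character(0L)
  if (!is.null(detection)) {
    kept <- detection_filter(significant, detection)
    removed <- setdiff(significant, kept)
    significant <- kept
  }
  structure(list(d = d, d_expected = null$d_expected, s0 = s0,
                 fold_change = fc, qvalue = thr$qvalue,
                 significant = significant, removed_undetected = removed,
                 delta = thr$delta, fdr = thr$fdr,
                 cut_up = thr$cut_up, cut_low = thr$cut_low,
                 delta_table = thr$delta_table,
                 fdr_target = fdr_target, n_perm = null$n_perm, seed = seed),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat("SAM (two-class unpaired):", length(x$d), "features,",
      x$n_perm, "permutations, s0 =", signif(x$s0, 4), "\n")
  cat("  delta =", signif(x$delta, 4), " estimated FDR =",
      signif(x$fdr, 4), "\n")
  cat("  significant at FDR", x$fdr_target, ":", length(x$significant),
      "feature(s)\n")
  if (length(x$significant) > 0L) {
    cat("   ", paste(x$significant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate a SAM result
#'
#' @param x `sam_result`.
#' @param ... unused.
#' @return data.frame with feature, score, expected score (by rank), fold
#'   change, q-value and the significance call, sorted by score.
#' @export
as.data.frame.sam_result <- function(x, ...) {
  ord <- order(x$d)
  data.frame(feature = names(x$d)[ord],
             score = unname(x$d[ord]),
             expected = x$d_expected,
             fold_change = unname(x$fold_change[names(x$d)[ord]]),
             qvalue = unname(x$qvalue[names(x$d)[ord]]),
             significant = names(x$d)[ord] %in% x$significant,
             stringsAsFactors = FALSE)
}

#' Complete-linkage clustering of samples on significant features
#'
#' Agglomerative clustering of the sample columns on the Euclidean distance
#' over the given features' log2 intensities, with complete linkage — the
#' layout used for the differential-expression heat map.
#'
#' @param expr log2 probe-set matrix.
#' @param features features to cluster on (default: all rows; >= 2).
#' @return list with `hclust` (the merge tree), `order` (leaf sample ids)
#'   and `heights` (non-decreasing merge heights).
#' @export
cluster_features <- function(expr, features = rownames(expr)) {
  check_matrix(expr)
  if (length(features) < 2L) stop("need at least 2 features to cluster on")
  if (ncol(expr) < 2L) stop("need at least 2 samples to cluster")
  hc <- stats::hclust(stats::dist(t(expr[features, , drop = FALSE])),
                      method = "complete")
  list(hclust = hc, order = colnames(expr)[hc$order], heights = hc$height)
}
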