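# --- Ranking and correlation primitives -------------------------------------

#' Highest-expressing features by across-sample mean intensity
#'
#' @param expr probe-set matrix.
#' @param n number of features to return (positive, at most the row count).
#' @return character vector of the n features with highest mean intensity,
#'   in descending order; ties broken lexicographically by feature id.
#' @export
top_n_features <- function(expr, n) {
  check_matrix(expr)
  if (n <= 0) stop("n must be positive")
  if (n > nrow(expr)) stop("n exceeds the number of features")
  means <- rowMeans(expr)
  ord <- order(-means, rownames(expr), method = "radix")
  rownames(expr)[ord][seq_len(n)]
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties). A constant
#' input vector has no rank ordering; the correlation is undefined and NA
#' is returned with a warning.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return correlation in `[-1, 1]`, or NA for degenerate input.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# Per-feature mean profile of a set of sample columns, restricted to
# `features` (order preserved).
mean_profile <- function(expr, sample_ids, features) {
  rowMeans(expr[features, sample_ids, drop = FALSE])
}

#' Pairwise Spearman correlation map between fractions
#'
#' For each pair of fractions, correlates the per-feature mean intensities
#' (over the fraction's samples) restricted to a reference feature list.
#' Optionally appends the pooled cellular contaminant profile ("LWR", the
#' per-feature mean over all RBC/WBC/LEU samples).
#'
#' @param expr probe-set matrix covering all samples involved.
#' @param samples sample metadata for the matrix columns.
#' @param features reference feature list (e.g. from [top_n_features()]);
#'   features missing from the matrix are dropped with a message.
#' @param fractions fraction labels to compare (default the five plasma
#'   fractions present in the data).
#' @param include_lwr append the pooled cellular profile as a row/column
#'   named `"LWR"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
fraction_correlation_map <- function(expr, samples, features,
                                     fractions = NULL, include_lwr = FALSE,
                                     method = c("spearman", "pearson")) {
  method <- match.arg(method)
  check_matrix(expr)
  validate_samples(samples)
  check_matrix_samples(expr, samples)
  samples <- samples[samples$sample_id %in% colnames(expr), ]
  if (is.null(fractions)) {
    fractions <- intersect(PLASMA_FRACTIONS, unique(samples$fraction))
  }
  missing <- setdiff(features, rownames(expr))
  if (length(missing) > 0L) {
    message(length(missing), " reference feature(s) missing from the matrix; dropped")
    features <- setdiff(features, missing)
  }
  profiles <- lapply(stats::setNames(nm = fractions), function(fr) {
    ids <- samples$sample_id[samples$fraction == fr]
    if (length(ids) == 0L) stop("no samples for fraction ", fr)
    mean_profile(expr, ids, features)
  })
  if (include_lwr) {
    ids <- samples$sample_id[samples$fraction %in% CELLULAR_FRACTIONS]
    if (length(ids) == 0L) stop("include_lwr = TRUE but no cellular samples present")
    profiles$LWR <- mean_profile(expr, ids, features)
  }
  k <- length(profiles)
  out <- diag(1, k)
  dimnames(out) <- list(names(profiles), names(profiles))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- if (method == "spearman") {
        spearman_cor(profiles[[i]], profiles[[j]])
      } else {
        stats::cor(profiles[[i]], profiles[[j]])
      }
      out[i, j] <- out[j, i] <- r
    }
  }
  out
}

# --- Paired comparisons and replicate stability -----------------------------

#' Paired t-test of per-feature mean intensities between two fractions
#'
#' Pairs by feature: for each feature the mean log2 intensity over each
#' fraction's samples is computed and the two paired vectors compared with
#' a two-sided paired Student's t-test.
#'
#' @param expr log2 probe-set matrix.
#' @param samples sample metadata.
#' @param fraction_a,fraction_b fraction labels.
#' @param features features to compare (at least 2).
#' @return list with `t`, `p`, `mean_diff` (b minus a) and `n` features.
#' @export
paired_intensity_test <- function(expr, samples, fraction_a, fraction_b,
                                  features) {
  check_matrix(expr)
  validate_samples(samples)
  check_matrix_samples(expr, samples)
  if (length(features) < 2L) stop("need at least 2 paired features")
  ids_a <- samples$sample_id[samples$fraction == fraction_a]
  ids_b <- samples$sample_id[samples$fraction == fraction_b]
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop("both fractions must have samples in the matrix")
  }
  a <- mean_profile(expr, ids_a, features)
  b <- mean_profile(expr, ids_b, features)
  diffs <- b - a
  if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) {
      return(list(t = 0, p = 1, mean_diff = 0, n = length(features)))
    }
    # constant nonzero shift: zero variance of differences, underflow-safe p
    return(list(t = sign(mean(diffs)) * Inf, p = .Machine$double.xmin,
                mean_diff = mean(diffs), n = length(features)))
  }
  tt <- stats::t.test(b, a, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = mean(diffs), n = length(features))
}

#' Replicate stability: pairwise rank correlations per intensity stratum
#'
#' Within one fraction's replicate samples, computes the Spearman
#' correlation between every pair of replicate columns, restricted to the
#' top-n features of each stratum (ranked by across-replicate mean).
#'
#' @param expr probe-set matrix for one fraction's replicates (>= 2 columns).
#' @param sizes strictly increasing stratum sizes, each at most the feature
#'   count (e.g. `c(20, 50, 200, 534)`).
#' @return list with `values` (data.frame: size, rep_a, rep_b, rho) and
#'   `means` (named mean correlation per stratum).
#' @export
replicate_stability <- function(expr, sizes) {
  check_matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 replicate samples")
  if (any(diff(sizes) <= 0)) stop("stratum sizes must be strictly increasing")
  if (any(sizes > nrow(expr)) || any(sizes <= 0)) {
    stop("stratum sizes must lie in [1, number of features]")
  }
  pairs <- utils::combn(colnames(expr), 2L)
  rows <- lapply(sizes, function(n) {
    feats <- top_n_features(expr, n)
    rho <- vapply(seq_len(ncol(pairs)), function(k) {
      spearman_cor(expr[feats, pairs[1L, k]], expr[feats, pairs[2L, k]])
    }, numeric(1L))
    data.frame(size = n, rep_a = pairs[1L, ], rep_b = pairs[2L, ], rho = rho,
               stringsAsFactors = FALSE)
  })
  values <- do.call(rbind, rows)
  means <- tapply(values$rho, values$size, mean)
  list(values = values, means = means[as.character(sizes)])
}

# --- Coefficient of variation ------------------------------------------------

#' Per-feature coefficient of variation across samples
#'
#' CV = sd/mean of linear-scale intensities across the matrix columns.
#' Log2-scale input is converted back to linear first. Zero-mean features
#' have an undefined CV and are returned as NA.
#'
#' @param expr probe-set matrix.
#' @param scale intensity scale of `expr` (defaults to its attribute, else
#'   log2).
#' @return named numeric vector of CVs.
#' @export
feature_cv <- function(expr, scale = get_scale(expr)) {
  check_matrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples to estimate a CV")
  lin <- as_linear(expr, scale)
  mu <- rowMeans(lin)
  sdev <- apply(lin, 1L, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdev / mu)
  stats::setNames(cv, rownames(expr))
}

#' Compare per-feature CVs between two fractions
#'
#' Computes the linear-scale CV of each common feature within each
#' fraction's replicates and contrasts the paired CV distributions with a
#' two-sided t-test. Zero-mean features are dropped with a warning.
#'
#' @param expr_a,expr_b probe-set matrices for the two fractions (>= 2
#'   samples each).
#' @param features common features to compare.
#' @return list with `cv_a`, `cv_b`, `t`, `p` and `n` features used.
#' @export
fraction_cv_compare <- function(expr_a, expr_b, features) {
  cv_a <- feature_cv(expr_a[features, , drop = FALSE],
                     scale = get_scale(expr_a))
  cv_b <- feature_cv(expr_b[features, , drop = FALSE],
                     scale = get_scale(expr_b))
  bad <- is.na(cv_a) | is.na(cv_b)
  if (any(bad)) {
    warning(sum(bad), " zero-mean feature(s) dropped from the CV comparison")
    cv_a <- cv_a[!bad]
    cv_b <- cv_b[!bad]
  }
  if (stats::sd(cv_a - cv_b) == 0) {
    # identical CV profiles (e.g. all zero variance): no difference
    return(list(cv_a = cv_a, cv_b = cv_b, t = 0, p = 1, n = length(cv_a)))
  }
  tt <- stats::t.test(cv_a, cv_b, paired = TRUE)
  list(cv_a = cv_a, cv_b = cv_b, t = unname(tt$statistic), p = tt$p.value,
       n = length(cv_a))
}
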