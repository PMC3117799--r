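#' Partition cohort-detected features by contaminant-catalogue membership
#'
#' A feature is "in circulation" when detected in at least
#' `ceiling(rate * n_samples)` of the cohort samples (default rate 0.5, the
#' at-least-9-of-18 criterion). Circulating features are then split into
#' `s_plus_l` (also in the contaminant catalogue) and `s_only` (circulation
#' only).
#'
#' @param d `detection_table` for the cohort samples.
#' @param catalog `contaminant_catalog` built from the cellular fractions.
#' @param rate detection proportion in (0, 1] (default 0.5).
#' @param sample_ids cohort samples to use (default: all columns of `d`).
#' @return object of class `class_partition`: list with `s_plus_l`,
#'   `s_only`, `circulating` and `rate`.
#' @export
partition_classes <- function(d, catalog, rate = 0.5,
                              sample_ids = colnames(d$calls)) {
  stopifnot(inherits(d, "detection_table"))
  if (length(sample_ids) == 0L) stop("empty cohort")
  circulating <- detected_set(d, sample_ids, rate = rate)
  members <- if (inherits(catalog, "contaminant_catalog")) catalog$members
             else as.character(catalog)
  structure(list(s_plus_l = intersect(circulating, members),
                 s_only = setdiff(circulating, members),
                 circulating = circulating, rate = rate),
            class = "class_partition")
}

#' @export
print.class_partition <- function(x, ...) {
  cat("Detected-in-circulation partition (rate ", x$rate, "):\n", sep = "")
  cat("  +S/+L (also in contaminants):", length(x$s_plus_l), "\n")
  cat("  +S/-L (circulation only):    ", length(x$s_only), "\n")
  invisible(x)
}

#' Compare intensity distributions of the +S/+L and +S/-L classes
#'
#' Pools the per-feature, per-sample log2 intensities of each class and
#' contrasts the two distributions with a two-sided t-test.
#'
#' @param expr log2 probe-set matrix for the cohort.
#' @param part `class_partition`.
#' @return list with class means, `t`, `p` and the pooled value vectors.
#' @export
class_intensity_compare <- function(expr, part) {
  check_matrix(expr)
  stopifnot(inherits(part, "class_partition"))
  if (length(part$s_plus_l) < 2L || length(part$s_only) < 2L) {
    stop("both classes need at least 2 features")
  }
  x <- as.vector(expr[part$s_plus_l, , drop = FALSE])
  y <- as.vector(expr[part$s_only, , drop = FALSE])
  tt <- stats::t.test(x, y)
  list(mean_s_plus_l = mean(x), mean_s_only = mean(y),
       t = unname(tt$statistic), p = tt$p.value,
       values_s_plus_l = x, values_s_only = y)
}

#' Compare CV distributions of the +S/+L and +S/-L classes
#'
#' Computes each feature's linear-scale CV across all cohort samples and
#' contrasts the two classes' CV distributions with a two-sided t-test.
#' The standard deviation is available as an alternate variability
#' statistic.
#'
#' @param expr log2 probe-set matrix for the cohort (>= 2 samples).
#' @param part `class_partition`.
#' @param stat `"cv"` (default) or `"sd"` of linear-scale intensities.
#' @return list with per-class statistic vectors, their means, `t` and `p`.
#' @export
class_cv_compare <- function(expr, part, stat = c("cv", "sd")) {
  stat <- match.arg(stat)
  check_matrix(expr)
  stopifnot(inherits(part, "class_partition"))
  if (ncol(expr) < 2L) stop("need at least 2 cohort samples")
  if (length(part$s_plus_l) < 2L || length(part$s_only) < 2L) {
    stop("both classes need at least 2 features")
  }
  value_of <- function(ids) {
    sub <- expr[ids, , drop = FALSE]
    if (stat == "cv") {
      v <- feature_cv(sub, scale = get_scale(expr))
    } else {
      v <- apply(as_linear(sub, get_scale(expr)), 1L, stats::sd)
    }
    bad <- is.na(v)
    if (any(bad)) {
      warning(sum(bad), " zero-mean feature(s) dropped")
      v <- v[!bad]
    }
    v
  }
  x <- value_of(part$s_plus_l)
  y <- value_of(part$s_only)
  if (stats::sd(c(x, y)) == 0) {
    # all features equally (in)variable: no class difference
    return(list(stat = stat, cv_s_plus_l = x, cv_s_only = y,
                mean_s_plus_l = mean(x), mean_s_only = mean(y), t = 0, p = 1))
  }
  tt <- stats::t.test(x, y)
  list(stat = stat, cv_s_plus_l = x, cv_s_only = y,
       mean_s_plus_l = mean(x), mean_s_only = mean(y),
       t = unname(tt$statistic), p = tt$p.value)
}
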