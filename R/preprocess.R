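# --- GC-stratified background machinery ------------------------------------

# Background probe row indices grouped by GC count.
background_bins <- function(m, annotation) {
  ann <- annotation[match(rownames(m), annotation$probe_id), ]
  bg <- which(ann$probe_class == "background")
  if (length(bg) == 0L) stop("no background probes present in the matrix")
  split(bg, ann$gc_count[bg])
}

# For each requested GC count, the available background bin to use:
# exact match, else nearest available GC (ties toward the lower GC).
match_gc_bins <- function(gc_wanted, bin_gcs) {
  vapply(gc_wanted, function(g) {
    d <- abs(bin_gcs - g)
    bin_gcs[order(d, bin_gcs)[1L]]
  }, numeric(1L))
}

#' GC-stratified background subtraction
#'
#' For each sample, subtracts from every target probe the median intensity
#' of the anti-genomic background probes sharing its GC count, clamping
#' results at zero. Target probes whose GC count has no background probes
#' fall back to the nearest available GC bin (with a warning). Background
#' probe rows are dropped from the output.
#'
#' @param m linear-scale probe matrix including background probe rows.
#' @param annotation probe annotation.
#' @return linear-scale matrix of background-corrected target probes.
#' @export
gc_background_subtract <- function(m, annotation) {
  check_matrix(m)
  validate_annotation(annotation)
  bins <- background_bins(m, annotation)
  bin_gcs <- as.numeric(names(bins))
  # per-sample median background intensity per GC bin
  med <- t(vapply(bins, function(rows) {
    apply(m[rows, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(m))))
  rownames(med) <- names(bins)

  ann <- annotation[match(rownames(m), annotation$probe_id), ]
  tgt <- which(ann$probe_class == "target")
  gc_tgt <- ann$gc_count[tgt]
  used_gc <- match_gc_bins(gc_tgt, bin_gcs)
  n_fallback <- sum(used_gc != gc_tgt)
  if (n_fallback > 0L) {
    warning(n_fallback, " target probe(s) had no GC-matched background probes; ",
            "nearest GC bin used")
  }
  out <- m[tgt, , drop = FALSE] - med[as.character(used_gc), , drop = FALSE]
  out[out < 0] <- 0
  set_scale(out, "linear")
}

# --- Wilcoxon rank-sum detection p-value ------------------------------------

# One-sided p-value that `target` values exceed `bg` values, using midranks.
# Exact by enumeration of rank assignments when the combined n <= max_exact;
# tie-corrected normal approximation (with continuity correction) otherwise.
# Fully degenerate input (all values identical) returns 0.5 by symmetry.
wilcox_greater_p <- function(target, bg, max_exact = 20L) {
  n1 <- length(target)
  n2 <- length(bg)
  if (n1 == 0L) stop("probe set with zero probes")
  if (n2 == 0L) stop("empty background pool")
  x <- c(target, bg)
  if (max(x) == min(x)) return(0.5)
  n <- n1 + n2
  r <- rank(x)
  w <- sum(r[seq_len(n1)])
  if (n <= max_exact) {
    r2 <- as.integer(round(2 * r)) # midranks are multiples of 1/2
    sums <- colSums(utils::combn(r2, n1))
    return(mean(sums >= as.integer(round(2 * w))))
  }
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(0.5)
  z <- (w - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Per-probe-set detection calls via one-sided Wilcoxon rank-sum tests
#'
#' For each probe set and sample, tests whether the set's target probe
#' intensities exceed the anti-genomic background probes pooled over the
#' set's GC bins in that sample. Exact p-values by enumeration when the
#' combined sample size is at most 20; tie-corrected normal approximation
#' above. A feature is called detected when p < `alpha`.
#'
#' @param m raw (pre-subtraction) linear probe matrix with background rows.
#' @param annotation probe annotation.
#' @param alpha detection threshold on the p-value (default 0.06).
#' @return object of class `detection_table`: list with `pvalues` and
#'   `calls` matrices (probe sets x samples) and `alpha`.
#' @export
detection_call <- function(m, annotation, alpha = 0.06) {
  check_matrix(m)
  validate_annotation(annotation)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  bins <- background_bins(m, annotation)
  bin_gcs <- as.numeric(names(bins))
  ann <- annotation[match(rownames(m), annotation$probe_id), ]
  tgt <- which(ann$probe_class == "target")
  sets <- split(tgt, ann$probeset_id[tgt])
  set_ids <- names(sets)
  # pooled background rows per probe set (over its probes' GC bins)
  pool <- lapply(sets, function(rows) {
    gcs <- unique(match_gc_bins(ann$gc_count[rows], bin_gcs))
    unlist(bins[as.character(gcs)], use.names = FALSE)
  })
  pv <- matrix(NA_real_, nrow = length(sets), ncol = ncol(m),
               dimnames = list(set_ids, colnames(m)))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    for (i in seq_along(sets)) {
      pv[i, j] <- wilcox_greater_p(col[sets[[i]]], col[pool[[i]]])
    }
  }
  ord <- order(set_ids, method = "radix")
  pv <- pv[ord, , drop = FALSE]
  structure(list(pvalues = pv, calls = pv < alpha, alpha = alpha),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  cat("Detection table:", nrow(x$pvalues), "probe sets x",
      ncol(x$pvalues), "samples (alpha =", x$alpha, ")\n")
  cat("  detected calls:", sum(x$calls), "of", length(x$calls), "\n")
  invisible(x)
}

# --- Transform / normalize / summarize --------------------------------------

#' Offset log2 transform
#'
#' `value -> log2(value + offset)`. The small constant keeps zero-clamped
#' background-corrected intensities finite on the log scale.
#'
#' @param m linear-scale matrix (non-negative).
#' @param offset positive constant added before the log (default 16).
#' @return log2-scale matrix.
#' @export
offset_log2 <- function(m, offset = 16) {
  check_matrix(m)
  if (offset <= 0) stop("offset must be positive")
  if (any(m < 0)) stop("negative intensities: background subtraction clamps at 0 upstream")
  set_scale(log2(m + offset), "log2")
}

#' Quantile normalization
#'
#' Classic rank-mean quantile normalization: each column's sorted values are
#' replaced by the across-column mean of sorted values, reassigned by the
#' original ranks; ties receive the mean of their tied positions' reference
#' values. After normalization every column has an identical sorted vector.
#'
#' @param m log2-scale matrix with at least 2 columns.
#' @return normalized matrix on the same scale.
#' @export
quantile_normalize <- function(m) {
  check_matrix(m)
  if (ncol(m) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  set_scale(out, get_scale(m))
}

#' Median summarization of probe sets
#'
#' Collapses target probe rows to one row per probe set, taking the
#' per-sample median across the set's probes. Probe sets present in the
#' annotation but absent from the matrix are dropped with a warning.
#'
#' @param m log2-scale matrix of target probes.
#' @param annotation probe annotation.
#' @return probe-set matrix (rows in lexicographic probe-set order).
#' @export
median_summarize <- function(m, annotation) {
  check_matrix(m)
  validate_annotation(annotation)
  ann <- annotation[match(rownames(m), annotation$probe_id), ]
  if (any(ann$probe_class != "target")) {
    stop("median_summarize expects target probe rows only")
  }
  sets <- split(seq_len(nrow(m)), ann$probeset_id)
  all_sets <- unique(annotation$probeset_id[annotation$probe_class == "target"])
  absent <- setdiff(all_sets, names(sets))
  if (length(absent) > 0L) {
    warning(length(absent), " probe set(s) absent from the matrix were dropped")
  }
  out <- t(vapply(sets, function(rows) {
    apply(m[rows, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(m))))
  colnames(out) <- colnames(m)
  out <- out[order(rownames(out), method = "radix"), , drop = FALSE]
  set_scale(out, get_scale(m))
}

#' Full probe-level preprocessing workflow
#'
#' Runs detection calls on the raw matrix, then GC background subtraction,
#' offset log2 transform, quantile normalization (in `"normalized"` mode
#' only; fraction-level analyses use `"non_normalized"` mode to preserve
#' each fraction's intensity distribution) and median summarization.
#'
#' @param raw linear-scale probe matrix including background probes.
#' @param annotation probe annotation.
#' @param mode `"normalized"` (cohort analyses, all samples normalized
#'   together) or `"non_normalized"` (fractionation analyses).
#' @param samples optional sample metadata; when given, matrix columns are
#'   required to be described in it.
#' @param alpha detection threshold (default 0.06).
#' @param offset constant added before the log2 transform (default 16).
#' @return list with `expr` (log2 probe-set matrix) and `detection`
#'   (a `detection_table` with matching features and samples).
#' @export
preprocess <- function(raw, annotation,
                       mode = c("normalized", "non_normalized"),
                       samples = NULL, alpha = 0.06, offset = 16) {
  mode <- match.arg(mode)
  check_matrix(raw)
  if (!is.null(samples)) {
    validate_samples(samples)
    check_matrix_samples(raw, samples)
  }
  detection <- detection_call(raw, annotation, alpha = alpha)
  m <- gc_background_subtract(raw, annotation)
  m <- offset_log2(m, offset = offset)
  if (mode == "normalized") m <- quantile_normalize(m)
  expr <- median_summarize(m, annotation)
  det_idx <- match(rownames(expr), rownames(detection$pvalues))
  detection$pvalues <- detection$pvalues[det_idx, , drop = FALSE]
  detection$calls <- detection$calls[det_idx, , drop = FALSE]
  list(expr = expr, detection = detection)
}
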