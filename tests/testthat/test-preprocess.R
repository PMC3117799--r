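# Hand-built 3-target-probe toy with two GC bins; background medians are
# computed by hand in the expectations.
toy_bg_matrix <- function() {
  annotation <- data.frame(
    probe_id = c("a:p1", "a:p2", "b:p1", "bg1", "bg2", "bg3", "bg4"),
    probeset_id = c("a", "a", "b", NA, NA, NA, NA),
    probe_class = c(rep("target", 3), rep("background", 4)),
    gc_count = c(10L, 12L, 10L, 10L, 10L, 10L, 12L),
    is_human = c(rep(TRUE, 3), rep(FALSE, 4)),
    stringsAsFactors = FALSE
  )
  m <- matrix(c(100, 50, 70, 60, 80, 90, 40,   # sample s1
                30, 200, 10, 20, 22, 24, 150), # sample s2
              ncol = 2,
              dimnames = list(annotation$probe_id, c("s1", "s2")))
  attr(m, "scale") <- "linear"
  list(annotation = annotation, m = m)
}

test_that("GC background subtraction matches hand-computed medians and clamps", {
  toy <- toy_bg_matrix()
  out <- gc_background_subtract(toy$m, toy$annotation)
  # s1: GC10 median = median(60,80,90) = 80; GC12 median = 40
  expect_equal(unname(out["a:p1", "s1"]), 100 - 80)
  expect_equal(unname(out["a:p2", "s1"]), 50 - 40)
  expect_equal(unname(out["b:p1", "s1"]), 0)       # 70 - 80 clamped
  # s2: GC10 median = 22; GC12 median = 150
  expect_equal(unname(out["a:p1", "s2"]), 30 - 22)
  expect_equal(unname(out["a:p2", "s2"]), 200 - 150)
  expect_equal(unname(out["b:p1", "s2"]), 0)       # 10 - 22 clamped
  expect_equal(nrow(out), 3L) # background rows dropped
})

test_that("a target GC bin with no background probes falls back to the nearest bin", {
  toy <- toy_bg_matrix()
  toy$annotation$gc_count[toy$annotation$probe_id == "a:p2"] <- 15L
  expect_warning(out <- gc_background_subtract(toy$m, toy$annotation),
                 "nearest GC bin")
  # nearest available bin to 15 is 12 (bg4)
  expect_equal(unname(out["a:p2", "s1"]), 50 - 40)
  no_bg <- toy$annotation[toy$annotation$probe_class == "target", ]
  expect_error(gc_background_subtract(toy$m[1:3, ], no_bg), "no background")
})

test_that("subtraction is monotone in target intensity and never negative", {
  toy <- toy_bg_matrix()
  out1 <- gc_background_subtract(toy$m, toy$annotation)
  m2 <- toy$m
  m2["a:p1", ] <- m2["a:p1", ] + 5
  out2 <- gc_background_subtract(m2, toy$annotation)
  expect_true(all(out2["a:p1", ] >= out1["a:p1", ]))
  expect_true(all(out1 >= 0) && all(out2 >= 0))
})

test_that("detection p-values match the enumeration oracle, including ties", {
  # 4 targets all above 4 backgrounds: exact p = 1/70
  p <- mircalib:::wilcox_greater_p(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_equal(p, 1 / 70)
  # opposite tail: targets all below background
  p_low <- mircalib:::wilcox_greater_p(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_gte(p_low, 0.5)
  # full tie degeneracy: p = 0.5, not detected
  expect_equal(mircalib:::wilcox_greater_p(rep(5, 4), rep(5, 4)), 0.5)
  # exhaustive check against the independent oracle for all configurations
  # with combined n <= 12, with and without ties
  set.seed(7)
  for (n1 in 2:4) {
    for (n2 in 2:(12 - n1)) {
      x <- sample(1:6, n1, replace = TRUE) + stats::runif(n1, 0, 0.01)
      y <- sample(1:6, n2, replace = TRUE) + stats::runif(n2, 0, 0.01)
      expect_equal(mircalib:::wilcox_greater_p(x, y), oracle_wilcox_p(x, y),
                   info = sprintf("n1=%d n2=%d tie-free", n1, n2))
      xt <- sample(1:3, n1, replace = TRUE)
      yt <- sample(1:3, n2, replace = TRUE)
      expect_equal(mircalib:::wilcox_greater_p(xt, yt), oracle_wilcox_p(xt, yt),
                   info = sprintf("n1=%d n2=%d tied", n1, n2))
    }
  }
})

test_that("detection p-value decreases as target intensities rise", {
  bg <- c(3, 5, 7, 9, 11, 2, 4, 6, 8, 10, 1, 12, 13, 14, 15, 16, 17, 18)
  shifts <- c(0, 2, 5, 10, 20)
  ps <- vapply(shifts, function(s) {
    mircalib:::wilcox_greater_p(c(6, 7, 8, 9) + s, bg)
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("detection_call pools probe-set replicates against GC-matched background", {
  toy <- toy_bg_matrix()
  det <- detection_call(toy$m, toy$annotation, alpha = 0.06)
  expect_equal(dim(det$pvalues), c(2L, 2L))
  expect_identical(det$calls, det$pvalues < 0.06)
  # probe set "a" pools GC bins {10, 12}: verify against the oracle
  expect_equal(unname(det$pvalues["a", "s1"]),
               oracle_wilcox_p(c(100, 50), c(60, 80, 90, 40)))
  expect_equal(unname(det$pvalues["b", "s2"]),
               oracle_wilcox_p(10, c(20, 22, 24)))
  expect_error(detection_call(toy$m, toy$annotation, alpha = 1.2), "alpha")
})

test_that("offset log2 transform hits its closed forms and rejects negatives", {
  m <- matrix(c(0, 16, 240, 48), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- offset_log2(m)
  expect_equal(unname(out[, 1]), c(4, 5))
  expect_equal(unname(out["a", "s2"]), 8)
  expect_identical(attr(out, "scale"), "log2")
  m[1, 1] <- -1
  expect_error(offset_log2(m), "negative")
})

test_that("quantile normalization matches the rank-mean oracle", {
  m <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  out <- quantile_normalize(m)
  expect_equal(unname(out), matrix(c(1.5, 3.5, 1.5, 3.5), 2),
               ignore_attr = TRUE)
  # random matrices vs the independent oracle
  set.seed(11)
  for (k in 1:5) {
    r <- matrix(rnorm(20), 5, 4,
                dimnames = list(paste0("f", 1:5), paste0("s", 1:4)))
    expect_equal(unname(quantile_normalize(r)),
                 unname(oracle_quantile_normalize(r)), ignore_attr = TRUE)
  }
})

test_that("quantile normalization is idempotent, rank-preserving and fixes columns", {
  set.seed(12)
  m <- matrix(rexp(60), 15, 4,
              dimnames = list(paste0("f", 1:15), paste0("s", 1:4)))
  out <- quantile_normalize(m)
  # defining property: identical sorted columns
  sorted <- apply(out, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # idempotence and within-column rank preservation
  expect_equal(unname(quantile_normalize(out)), unname(out),
               ignore_attr = TRUE)
  for (j in 1:4) expect_equal(rank(out[, j]), rank(m[, j]))
  # already-identical columns are a fixed point
  fp <- matrix(rep(c(1, 5, 9), 3), 3,
               dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_equal(unname(quantile_normalize(fp)), unname(fp),
               ignore_attr = TRUE)
  one <- m[, 1, drop = FALSE]
  expect_warning(same <- quantile_normalize(one), "single sample")
  expect_equal(same, one, ignore_attr = TRUE)
})

test_that("median summarization collapses probe sets per sample", {
  ann <- data.frame(
    probe_id = c("a:1", "a:2", "b:1", "b:2", "b:3"),
    probeset_id = c("a", "a", "b", "b", "b"),
    probe_class = "target", gc_count = 10L, is_human = TRUE,
    stringsAsFactors = FALSE
  )
  m <- matrix(c(4, 6, 1, 2, 9), ncol = 1, dimnames = list(ann$probe_id, "s1"))
  m <- cbind(s1 = m[, 1], s2 = c(10, 10, 5, 7, 6))
  out <- median_summarize(m, ann)
  expect_equal(unname(out["a", ]), c(5, 10))
  expect_equal(unname(out["b", ]), c(2, 6))
  # degenerate one-probe sets: identity
  ann1 <- ann[c(1, 3), ]; ann1$probeset_id <- c("a", "b")
  out1 <- median_summarize(m[c(1, 3), ], ann1)
  expect_equal(unname(out1), unname(m[c(1, 3), ]), ignore_attr = TRUE)
  # sets absent from the matrix are dropped with a warning
  expect_warning(median_summarize(m[1:2, , drop = FALSE], ann), "absent")
})

test_that("pipeline modes differ only by the quantile step", {
  p <- tiny_params()
  sim <- simulate_fractions(p)
  pp_raw <- preprocess(sim$matrix, sim$annotation, mode = "non_normalized",
                       samples = sim$samples)
  pp_qn <- preprocess(sim$matrix, sim$annotation, mode = "normalized",
                      samples = sim$samples)
  # detection identical (computed on raw input in both modes)
  expect_identical(pp_raw$detection$pvalues, pp_qn$detection$pvalues)
  # non-normalized columns keep distinct distributions; normalized
  # probe-level quantiles are equalized upstream of summarization
  expect_false(isTRUE(all.equal(pp_raw$expr, pp_qn$expr)))
  # feature/sample labels shared between outputs
  expect_identical(rownames(pp_raw$expr), rownames(pp_raw$detection$pvalues))
  expect_identical(colnames(pp_raw$expr), colnames(pp_raw$detection$pvalues))
})

test_that("zero-noise pipeline reproduces the closed-form summarized values", {
  p <- tiny_params(noise_sigma_log2 = 0, bio_sigma_log2 = 0)
  sim <- simulate_fractions(p)
  pp <- preprocess(sim$matrix, sim$annotation, mode = "non_normalized",
                   samples = sim$samples)
  # a circulating feature in a plasma sample: subtraction recovers the
  # abundance exactly, so the summarized value is log2(abundance + 16)
  circ <- sim$truth$circulating[1:5]
  s1 <- sim$samples$sample_id[sim$samples$fraction == "S1"][1]
  expect_equal(unname(pp$expr[circ, s1]),
               unname(log2(sim$truth$abundance[circ] + 16)))
})
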