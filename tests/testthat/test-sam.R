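rand_expr <- function(nf, n1, n2, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nf * (n1 + n2), mean = 6), nf,
              dimnames = list(sprintf("f%03d", seq_len(nf)),
                              paste0("s", seq_len(n1 + n2))))
  attr(m, "scale") <- "log2"
  list(expr = m, groups = factor(rep(c("M", "F"), c(n1, n2)),
                                 levels = c("M", "F")))
}

test_that("sam score matches its closed form and is damped by s0", {
  m <- matrix(c(1, 2, 3, 4), nrow = 1,
              dimnames = list("f1", paste0("s", 1:4)))
  g <- factor(c("M", "M", "F", "F"), levels = c("M", "F"))
  # s = sqrt((1/2 + 1/2) * (0.5 + 0.5) / 2) = sqrt(0.5); d = 2 / sqrt(0.5)
  expect_equal(unname(sam_scores(m, g, s0 = 0)), 2 / sqrt(0.5))
  # identical group means: d = 0
  m0 <- matrix(c(1, 3, 1, 3), nrow = 1, dimnames = list("f1", paste0("s", 1:4)))
  expect_equal(unname(sam_scores(m0, g)), 0)
  # s0 > 0 strictly shrinks |d| when the mean difference is nonzero
  expect_lt(abs(sam_scores(m, g, s0 = 1)), abs(sam_scores(m, g, s0 = 0)))
  expect_error(sam_scores(m[, 1:3, drop = FALSE], factor(c("M", "M", "F"))),
               "at least 2")
})

test_that("sam score with s0 = 0 equals the classical pooled t statistic", {
  for (k in 1:100) {
    nf <- sample(3:8, 1)
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    re <- rand_expr(nf, n1, n2, seed = 1000 + k)
    d <- sam_scores(re$expr, re$groups, s0 = 0)
    for (i in seq_len(nf)) {
      tt <- stats::t.test(re$expr[i, re$groups == "F"],
                          re$expr[i, re$groups == "M"], var.equal = TRUE)
      expect_equal(unname(d[i]), unname(tt$statistic), tolerance = 1e-10)
    }
  }
})

test_that("s0 tuning reproduces the independent percentile-sweep oracle", {
  set.seed(42)
  re <- rand_expr(50, 4, 4)
  re$expr[1:10, ] <- re$expr[1:10, ] * 3 # spread the scatter distribution
  st <- mircalib:::sam_stat(re$expr, which(re$groups == "F"), s0 = 0)
  expect_equal(choose_s0(st$r, st$s), oracle_choose_s0(st$r, st$s))
  # degenerate: identical scatters fall back to their 5th percentile
  r <- rnorm(20); s <- rep(0.7, 20)
  expect_message(s0 <- choose_s0(r, s), "identical")
  expect_equal(s0, 0.7)
})

test_that("permutation null is deterministic and exhausts small designs", {
  re <- rand_expr(20, 2, 2, seed = 3)
  # C(4,2) = 6 distinct splits: exhaustive enumeration
  expect_message(null <- permutation_null(re$expr, re$groups, n_perm = 1000),
                 "6 distinct")
  expect_equal(null$n_perm, 6L)
  # oracle: recompute expected order statistics from all index splits
  splits <- utils::combn(4, 2)
  perms <- sapply(seq_len(ncol(splits)), function(b) {
    sort(mircalib:::sam_stat(re$expr, splits[, b], s0 = 0)$d)
  })
  expect_equal(null$d_expected, unname(rowMeans(perms)))
  # sampled case: identical seeds give identical nulls
  re2 <- rand_expr(30, 5, 5, seed = 4)
  n1 <- permutation_null(re2$expr, re2$groups, n_perm = 50, seed = 9)
  n2 <- permutation_null(re2$expr, re2$groups, n_perm = 50, seed = 9)
  expect_identical(n1$d_expected, n2$d_expected)
  # degenerate input: identical samples give an identically-zero null
  flat <- matrix(5, 10, 6, dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  g <- factor(rep(c("M", "F"), each = 3), levels = c("M", "F"))
  nullf <- permutation_null(flat, g, n_perm = 10)
  expect_true(all(nullf$d_expected == 0))
})

test_that("delta sweep calls planted effects and controls the null", {
  set.seed(8)
  re <- rand_expr(100, 6, 6, seed = 12)
  re$expr[1:3, re$groups == "F"] <- re$expr[1:3, re$groups == "F"] + 3
  fit <- sam(re$expr, re$groups, fdr_target = 0.05, n_perm = 200, seed = 2)
  expect_true(all(c("f001", "f002", "f003") %in% fit$significant))
  expect_true(all(fit$qvalue[c("f001", "f002", "f003")] <= 0.05))
  expect_true(all(fit$qvalue >= 0 & fit$qvalue <= 1))
  expect_lte(fit$fdr, 0.05)
  # null data: empty or near-empty significant set
  re0 <- rand_expr(100, 6, 6, seed = 13)
  fit0 <- sam(re0$expr, re0$groups, fdr_target = 0.05, n_perm = 200, seed = 2)
  expect_lte(length(fit0$significant), 2L)
})

test_that("q-values decrease with the deviation from the expected score", {
  re <- rand_expr(80, 5, 5, seed = 21)
  re$expr[1:5, re$groups == "F"] <- re$expr[1:5, re$groups == "F"] + 2
  fit <- sam(re$expr, re$groups, n_perm = 100, seed = 3)
  ord <- order(fit$d)
  up <- fit$d_expected > 0
  # within the positive side of the expected curve, a larger observed score
  # is called at every delta a smaller one is, so q never increases with d
  q_up <- fit$qvalue[ord][up]
  expect_true(all(diff(q_up) <= 1e-12))
})

test_that("detection filter removes only features never detected anywhere", {
  calls <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE), nrow = 3,
                  dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  d <- structure(list(pvalues = ifelse(calls, 0.01, 0.5), calls = calls,
                      alpha = 0.06), class = "detection_table")
  expect_equal(detection_filter(c("a", "b", "c"), d), c("a", "b"))
  expect_equal(detection_filter(c("a", "b"), d), c("a", "b"))
  expect_equal(detection_filter(character(0), d), character(0))
})

test_that("fold change is the female/male linear mean ratio", {
  m <- matrix(log2(c(10, 10, 18, 18,   # f1: 10 vs 18
                     8, 8, 8, 8)),     # f2: equal means
              nrow = 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  attr(m, "scale") <- "log2"
  g <- factor(c("M", "M", "F", "F"), levels = c("M", "F"))
  fc <- fold_change(m, g)
  expect_equal(unname(fc), c(1.8, 1))
  # uniform +1 log2 shift in females doubles every ratio
  m2 <- m; m2[, g == "F"] <- m2[, g == "F"] + 1
  attr(m2, "scale") <- "log2"
  expect_equal(unname(fold_change(m2, g)), c(3.6, 2))
  # zero male mean is undefined
  mz <- matrix(c(0, 0, 4, 4), nrow = 1, dimnames = list("f1", paste0("s", 1:4)))
  attr(mz, "scale") <- "linear"
  expect_true(is.na(fold_change(mz, g)))
})

test_that("complete-linkage clustering matches hand-computed merge heights", {
  # 3 samples on a line at 0, 1, 10: merge {0,1} at height 1, then the pair
  # joins 10 at the complete-linkage height 10 (the farthest member)
  two <- rbind(f1 = c(0, 1, 10), f2 = c(0, 0, 0))
  colnames(two) <- c("x", "y", "z")
  cl2 <- cluster_features(two)
  expect_equal(cl2$heights, c(1, 10))
  expect_setequal(cl2$order, c("x", "y", "z"))
  # identical samples merge first at height 0
  m3 <- matrix(c(5, 5, 9), nrow = 1, dimnames = list("f1", c("x", "y", "z")))
  cl3 <- cluster_features(rbind(m3, f2 = c(5, 5, 9)))
  expect_equal(cl3$heights[1], 0)
  # merge heights are non-decreasing (ultrametric property) and label
  # permutation leaves them unchanged
  set.seed(19)
  big <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  clb <- cluster_features(big)
  expect_true(all(diff(clb$heights) >= -1e-12))
  shuf <- big[, sample(10)]
  expect_equal(sort(cluster_features(shuf)$heights), sort(clb$heights))
})

test_that("sam results expose a tidy table aligned with the score order", {
  re <- rand_expr(30, 4, 4, seed = 2)
  fit <- sam(re$expr, re$groups, n_perm = 50, seed = 1)
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), 30L)
  expect_true(!is.unsorted(tab$score))
  expect_equal(tab$expected, fit$d_expected)
  expect_output(print(fit), "SAM")
})
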