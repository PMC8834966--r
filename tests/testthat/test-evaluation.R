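brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

test_that("roc_auc equals brute-force concordant-pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)  # perfect
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 0, 0, 0, 1)), 0.5)  # all tied
  set.seed(91)
  for (rep in 1:50) {
    n <- sample(5:30, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) next
    scores <- sample(round(runif(n), 1))  # coarse grid to force ties
    expect_equal(roc_auc(scores, labels), brute_auc(scores, labels))
  }
  expect_warning(roc_auc(1:3, c(1, 1, 1)), "degenerate")
})

test_that("random scores give AUC 0.5 in expectation", {
  set.seed(92)
  labels <- rep(c(TRUE, FALSE), 10)
  aucs <- replicate(1e4, roc_auc(runif(20), labels))
  expect_equal(mean(aucs), 0.5, tolerance = 0.01)
})

test_that("p-values ascending reproduce statistic-descending AUC", {
  set.seed(93)
  labels <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(.4, .6))
  stat <- runif(20)
  pval <- exp(-5 * abs(stat))  # strictly decreasing in |stat|
  expect_equal(roc_auc(abs(stat), labels), roc_auc(-pval, labels))
})

test_that("precision at half counts true pairs in the selected half", {
  # 4 true pairs, 3 of them in the top 10
  labels <- c(rep(TRUE, 4), rep(FALSE, 16))
  scores <- c(20, 19, 18, 5, 17:2)  # truths ranked 1st, 2nd, 3rd and 14th
  expect_equal(precision_at_half(scores, labels), 0.3)
  # all interacting except one, all selected
  lab2 <- c(rep(TRUE, 19), FALSE)
  expect_equal(precision_at_half(rev(seq_len(20)), lab2), 1)
  # random scores: precision matches connectance in expectation
  set.seed(94)
  lab3 <- sample(c(rep(TRUE, 7), rep(FALSE, 13)))
  precs <- replicate(1e4, precision_at_half(runif(20), lab3))
  expect_equal(mean(precs), 7 / 20, tolerance = 0.02)
  # deterministic tie-break towards lower index
  expect_equal(precision_at_half(rep(1, 20), lab3),
               sum(lab3[1:10]) / 10)
})

test_that("top_k_species sorts by mean abundance with index tie-break", {
  means <- c(0.9, 0.1, 0.5, 0.05, 0.3, 0.2, 0.01, 0.02, 0.03, 0.04)
  s <- matrix(rep(means, each = 4), 4, 10)
  expect_equal(top_k_species(s, 5), c(1L, 3L, 5L, 6L, 2L))
  expect_equal(top_k_species(s, 10), order(-means, 1:10))
  expect_error(top_k_species(s, 11), "exceeds")
  # permutation consistency
  set.seed(95)
  perm <- sample(10)
  expect_equal(sort(perm[top_k_species(s[, perm], 5)]),
               sort(top_k_species(s, 5)))
})

test_that("evaluation_task flattens the top-5 submatrix row-major", {
  set.seed(96)
  s <- matrix(runif(700), 100, 7)
  truth <- matrix(runif(49) < 0.4, 7, 7); diag(truth) <- FALSE
  res <- correlation_infer(s, "pearson")
  task <- evaluation_task(s, truth, res, "stat")
  expect_length(task$scores, 20)
  sel <- task$species
  expect_equal(sel, sort(top_k_species(s, 5)))
  k <- 0
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    k <- k + 1
    expect_equal(task$scores[k], abs(res$stat[sel[i], sel[j]]))
    expect_equal(task$labels[k], truth[sel[i], sel[j]])
  }
})

test_that("summarize_records computes medians, differences and MW tests", {
  rec <- data.frame(
    model_id = rep(c("Dprime", "Mprime"), each = 5),
    method = "pearson", classifier = "stat",
    auc = c(rep(0.9, 5), rep(0.5, 5)))
  st <- summarize_records(rec, "auc")
  expect_equal(sort(st$medians$median), c(0.5, 0.9))
  expect_equal(st$diff + t(st$diff), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(abs(st$diff[1, 2]), 0.4)
  expect_true(all(st$signif[row(st$signif) != col(st$signif)]))
  # identical groups: zero difference, not significant
  rec2 <- rec; rec2$auc <- rep(0.7, 10)
  st2 <- summarize_records(rec2, "auc")
  expect_true(all(st2$diff == 0))
  expect_false(any(st2$signif, na.rm = TRUE))
})
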