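test_that("confusion counts enumerate the four cells and validate input", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               c(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unname(perfect[c("FP", "FN")]), c(0L, 0L))
  expect_error(confusion(integer(), integer()), "empty")
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "mismatch")
})

test_that("metrics match hand-computed values and degenerate cases yield 0", {
  m <- classification_metrics(c(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(unname(m["F1"]), 0.5)
  expect_equal(unname(m["MCC"]), 0)
  expect_equal(unname(m["sensitivity"]), 0.5)
  expect_equal(unname(m["specificity"]), 0.5)
  expect_equal(unname(classification_metrics(c(TP = 5, FP = 0, TN = 5, FN = 0))),
               c(1, 1, 1, 1))
  # all-negative predictor on mixed truth
  m2 <- classification_metrics(confusion(c(1, 1, 0), c(0, 0, 0)), quiet = TRUE)
  expect_equal(unname(m2[c("sensitivity", "specificity")]), c(0, 1))
  w <- capture_warnings(classification_metrics(c(TP = 0, FP = 0, TN = 3, FN = 0)))
  expect_true(any(grepl("zero denominator", w)))
})

test_that("identity predictions score 1 and MCC is label-swap symmetric", {
  set.seed(77)
  for (i in 1:20) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(unname(classification_metrics(confusion(y, y), quiet = TRUE)),
                 c(1, 1, 1, 1))
    p <- rbinom(40, 1, 0.5)
    m1 <- classification_metrics(confusion(y, p), quiet = TRUE)["MCC"]
    m2 <- classification_metrics(confusion(1 - y, 1 - p), quiet = TRUE)["MCC"]
    expect_equal(unname(m1), unname(m2))
  }
})

test_that("PR-AUC matches exhaustive threshold enumeration and analytic cases", {
  expect_equal(pr_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(pr_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)  # = prevalence
  # 6-point toy, frozen against independent exhaustive enumeration (29/36)
  expect_equal(pr_auc(c(1, 0, 1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)),
               29 / 36)
  expect_error(pr_auc(c(1, 1, 1), c(0.1, 0.2, 0.3)), "both classes")
})

test_that("PR-AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  y <- rbinom(60, 1, 0.3)
  s <- runif(60)
  base <- pr_auc(y, s)
  expect_equal(pr_auc(y, exp(3 * s)), base)
  expect_equal(pr_auc(y, rank(s)), base)
})

test_that("concordance regions match direct set algebra and sum to the union", {
  r <- concordance(list(A = c("1", "2"), B = c("2", "3")),
                   as.character(1:4))
  counts <- setNames(r$regions$count, r$regions$methods)
  expect_equal(unname(counts["A"]), 1L)
  expect_equal(unname(counts["B"]), 1L)
  expect_equal(unname(counts["A&B"]), 1L)
  expect_equal(r$missed_by_all, 1L)
  expect_equal(r$union_size, 3L)

  same <- concordance(list(A = c("1", "2"), B = c("1", "2")), c("1", "2"))
  expect_equal(setNames(same$regions$count, same$regions$methods)[["A&B"]], 2L)

  set.seed(123)
  pos <- sprintf("p%04d", 1:1500)
  sets <- list(dom = sample(pos, 1000), xgb = sample(pos, 1000),
               ext = sample(pos, 1000))
  r3 <- concordance(sets, pos)
  oracle <- oracle_regions(sets, pos)
  got <- setNames(r3$regions$count, r3$regions$methods)
  expect_equal(got[names(oracle)], oracle)
  expect_equal(sum(r3$regions$count), r3$union_size)
  expect_equal(r3$union_size + r3$missed_by_all, r3$n_positives)
  expect_error(concordance(list(A = "zzz"), pos), "outside")
})

test_that("evaluate_methods ties metrics and concordance to a common truth", {
  y <- setNames(c(1, 1, 1, 0, 0), paste0("p", 1:5))
  preds <- list(
    good = data.frame(id = paste0("p", 1:5), label = c(1, 1, 1, 0, 0)),
    meh = data.frame(id = paste0("p", 1:5), label = c(1, 0, 0, 0, 1)))
  ev <- evaluate_methods(y, preds)
  expect_equal(ev$metrics$F1[ev$metrics$method == "good"], 1)
  expect_equal(ev$concordance$n_positives, 3L)
  expect_equal(ev$concordance$missed_by_all, 0L)
})
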