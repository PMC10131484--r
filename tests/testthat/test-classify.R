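# brute-force all-pairs concordance oracle (ties count 1/2)
auc_oracle <- function(scores, labels, direction) {
  x <- if (direction == "lower-is-positive") -scores else scores
  pos <- x[labels]; neg <- x[!labels]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("AUC equals all-pairs concordance on hand cases", {
  r <- roc_auc(c(0.2, 0.4, 0.9, 1.0), c(TRUE, TRUE, FALSE, FALSE),
               "lower-is-positive")
  expect_equal(r$auc, 1.0)
  r <- roc_auc(c(0.2, 0.9, 0.9, 1.0), c(TRUE, TRUE, FALSE, FALSE),
               "lower-is-positive")
  expect_equal(r$auc, 3.5 / 4)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "positive and 1 negative")
})

test_that("ROC curve is anchored and its trapezoid equals the AUC", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    sc <- sample(round(rnorm(n), sample(1:3, 1)))   # induce ties
    lb <- runif(n) < 0.4
    if (!any(lb) || all(lb)) next
    dir <- sample(c("lower-is-positive", "higher-is-positive"), 1)
    r <- roc_auc(sc, lb, dir)
    expect_equal(unlist(r$curve[1, c("fpr", "tpr")], use.names = FALSE),
                 c(0, 0))
    expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")],
                        use.names = FALSE), c(1, 1))
    trap <- sum(diff(r$curve$fpr) * (head(r$curve$tpr, -1) +
                                     tail(r$curve$tpr, -1)) / 2)
    expect_equal(r$auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC matches the pairwise oracle on 500 random instances", {
  set.seed(101)
  for (i in 1:500) {
    n <- sample(4:200, 1)
    sc <- round(rnorm(n), sample(0:2, 1))
    lb <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(lb) || all(lb)) { lb[1] <- !lb[1]; lb[2] <- !lb[2] }
    dir <- if (i %% 2) "lower-is-positive" else "higher-is-positive"
    expect_equal(roc_auc(sc, lb, dir)$auc, auc_oracle(sc, lb, dir),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:20) {
    sc <- rnorm(80); lb <- runif(80) < 0.5
    if (!any(lb) || all(lb)) next
    ref <- suppressMessages(
      pROC::auc(pROC::roc(lb, sc, direction = ">", quiet = TRUE)))
    expect_equal(roc_auc(sc, lb, "lower-is-positive")$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(9)
  sc <- rnorm(100); lb <- runif(100) < 0.5
  a <- roc_auc(sc, lb, "higher-is-positive")$auc
  for (f in list(function(x) x^3, function(x) exp(x),
                 function(x) 5 * x - 2))
    expect_equal(roc_auc(f(sc), lb, "higher-is-positive")$auc, a,
                 tolerance = 1e-12)
})

test_that("random labels give chance-level AUC on average", {
  set.seed(21)
  aucs <- vapply(1:100, function(i) {
    sc <- rnorm(60)
    lb <- sample(rep(c(TRUE, FALSE), 30))
    roc_auc(sc, lb, "lower-is-positive")$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.05 / 0.5)
})

test_that("threshold selection maximizes Youden's J over midpoints", {
  r <- roc_auc(c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0),
               c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
               "lower-is-positive")
  t <- select_threshold(r)
  expect_equal(t$threshold, 0.55)
  expect_equal(t$j, 1)

  r <- roc_auc(c(0.2, 0.9, 0.9, 1.0), c(TRUE, TRUE, FALSE, FALSE),
               "lower-is-positive")
  t <- select_threshold(r)
  expect_equal(t$threshold, 0.55)
  expect_equal(t$sensitivity, 0.5)
  expect_equal(t$specificity, 1.0)

  # identically distributed classes: no cutoff beats J = 0
  r <- roc_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
               "lower-is-positive")
  expect_true(select_threshold(r)$degenerate)
  r0 <- roc_auc(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE),
                "lower-is-positive")
  expect_error(select_threshold(r0), "identical")
})

test_that("threshold recovery on the two-Gaussian benchmark", {
  set.seed(31)
  sc <- c(rnorm(200, 0.40, 0.10), rnorm(200, 1.00, 0.10))
  lb <- rep(c(TRUE, FALSE), each = 200)
  t <- select_threshold(roc_auc(sc, lb, "lower-is-positive"))
  expect_gt(t$threshold, 0.60)
  expect_lt(t$threshold, 0.80)
})

test_that("class assignment partitions the line with strict boundaries", {
  expect_equal(as.character(assign_class(c(0.5, 1.30, 1.18, 0.66, 1.0))),
               c("MODY-like", "HH-like", "WT-like", "WT-like", "WT-like"))
  set.seed(2)
  sc <- c(rnorm(200), 0.66, 1.18)
  cls <- assign_class(sc)
  expect_false(anyNA(cls))            # exactly one class per score
  expect_error(assign_class(Inf), "finite")
  expect_error(assign_class(1, thresholds = c(2, 1)))
})

test_that("allele-frequency consistency flags common non-WT-like variants", {
  out <- af_consistency(c("a", "b", "c"), score = c(1.0, 0.2, 0.2),
                        allele_frequency = c(1e-3, 1e-3, 1e-6))
  expect_equal(out$discordant, c(FALSE, TRUE, FALSE))
  out <- af_consistency("d", 0.2, NA)
  expect_false(out$discordant)        # unknown frequency: never flagged
})
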