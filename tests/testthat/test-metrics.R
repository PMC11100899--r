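test_that("confusion counts are exact and match brute-force pairwise counting", {
  cc <- confusion(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
                  c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 3L, TN = 7L, FP = 0L, FN = 0L))

  flipped <- confusion(c(0, 1), c(1, 0))
  expect_equal(flipped$TP + flipped$TN, 0L)

  set.seed(31)
  pred <- sample(0:1, 50, replace = TRUE)
  truth <- sample(0:1, 50, replace = TRUE)
  cc <- confusion(pred, truth)
  brute <- c(TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (i in 1:50) {
    key <- if (pred[i] == 1 && truth[i] == 1) "TP"
    else if (pred[i] == 1) "FP"
    else if (truth[i] == 1) "FN"
    else "TN"
    brute[key] <- brute[key] + 1L
  }
  expect_equal(unlist(unclass(cc))[names(brute)], brute)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 50L)

  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
})

test_that("F1 is the harmonic mean of reported precision/recall pairs", {
  # screening-study worked examples at two decimal places
  pairs <- list(c(0.50, 0.93, 0.65),
                c(0.47, 0.92, 0.62),
                c(0.22, 1.00, 0.36),
                c(0.29, 0.98, 0.45),
                c(0.31, 0.94, 0.47))
  for (p in pairs) {
    expect_equal(round(f1_from_pr(p[1], p[2]), 2), p[3])
  }
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(f1_from_pr(0, 0), 0)
})

test_that("undefined precision and recall surface as NA flags, never silent zeros", {
  no_pred_hits <- confusion(rep(0L, 5), c(1, 1, 0, 0, 0))
  expect_true(is.na(precision_score(no_pred_hits)))
  expect_equal(recall_score(no_pred_hits), 0)
  expect_true(is.na(f1_score(no_pred_hits)))

  no_true_hits <- confusion(c(1, 0, 0), c(0, 0, 0))
  expect_true(is.na(recall_score(no_true_hits)))
})

test_that("F1 respects its min-side bound", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(1, 0.05, 1)
    r <- runif(1, 0.05, 1)
    f <- f1_from_pr(p, r)
    expect_lte(f, 2 * min(p, r) + 1e-12)
    expect_gte(f, min(p, r) - 1e-12)
  }
})

test_that("ROC-AUC equals the O(n^2) pair-concordance probability", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 60
    scores <- round(runif(n), 1)  # coarse scores force ties
    truth <- rbinom(n, 1, 0.4)
    if (length(unique(truth)) < 2) next
    auc <- roc_curve(scores, truth)$auc
    pos <- scores[truth == 1]
    neg <- scores[truth == 0]
    conc <- 0
    for (a in pos) for (b in neg) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
    expect_equal(auc, conc / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("ROC-AUC agrees with an independent implementation and is monotone-invariant", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- rnorm(200)
  truth <- rbinom(200, 1, 0.3)
  auc <- roc_curve(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-10)
  # strictly monotone transforms leave the AUC unchanged
  expect_equal(roc_curve(exp(scores), truth)$auc, auc, tolerance = 1e-12)
  expect_equal(roc_curve(10 * scores - 2, truth)$auc, auc, tolerance = 1e-12)
})

test_that("separable scores give perfect curves; label-independent scores hover at chance", {
  truth <- c(rep(1, 10), rep(0, 30))
  scores <- c(seq(0.9, 0.99, length.out = 10), seq(0.1, 0.5, length.out = 30))
  expect_equal(roc_curve(scores, truth)$auc, 1)
  expect_equal(pr_curve(scores, truth)$auc, 1)

  set.seed(77)
  n <- 4000
  truth <- rbinom(n, 1, 0.5)
  scores <- runif(n)
  expect_equal(roc_curve(scores, truth)$auc, 0.5, tolerance = 0.05)

  expect_error(roc_curve(runif(5), rep(1, 5)), "positive and one negative")
})

test_that("PEP bins reproduce hand counts and the aggregate equals recall", {
  # three energy bins below a -8 threshold, hand-tallied
  energies <- c(-9.014, -9.006, -8.504, -8.502, -8.499, -8.101, -7.9)
  predicted <- c(1L, 0L, 1L, 1L, 1L, 0L, 1L)
  pep <- pep_curve(energies, predicted, threshold = -8, granularity = 0.01)
  expect_equal(pep$bins$energy, c(-9.01, -8.50, -8.10))
  expect_equal(pep$bins$pep, c(1 / 2, 3 / 3, 0))
  expect_equal(pep$bins$n, c(2L, 3L, 1L))
  # the last record (-7.9) is not a hit and never enters

  # aggregate PEP = recall on the same records (denominator is TP + FN)
  truth <- as.integer(energies < -8)
  cc <- confusion(predicted, truth)
  expect_equal(pep$aggregate, recall_score(cc))

  # count-weighted mean of per-bin PEP is the aggregate, exactly
  expect_equal(sum(pep$bins$pep * pep$bins$n) / sum(pep$bins$n),
               pep$aggregate)

  # a predict-everything model has PEP 1 in every bin
  all_hit <- pep_curve(energies, rep(1L, 7), threshold = -8)
  expect_true(all(all_hit$bins$pep == 1))

  expect_error(pep_curve(c(-1, -2), c(1L, 0L), threshold = -10), "no true hits")
})

test_that("energy binning rounds half away from zero at 0.01 kcal/mol", {
  expect_equal(nfscreen:::round_to_granularity(-8.125, 0.01), -8.13)
  expect_equal(nfscreen:::round_to_granularity(-8.124, 0.01), -8.12)
  expect_equal(nfscreen:::round_to_granularity(8.125, 0.01), 8.13)
})
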