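# Confusion counts, scalar metrics, ROC/AUC, PR/AUPR and the repeated
# experiment harness.

test_that("confusion counts tally with ties classified positive", {
  cc <- confusion_at_threshold(c(0.9, 0.2), c(1, 0))
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")]),
               c(TP = 1, FP = 0, TN = 1, FN = 0))
  # probability exactly at the threshold counts as positive
  cc <- confusion_at_threshold(c(0.5, 0.5), c(1, 0))
  expect_equal(cc$TP, 1)
  expect_equal(cc$FP, 1)
  cc <- confusion_at_threshold(0.4, 1)
  expect_equal(cc$FN, 1)
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 1)
  expect_error(confusion_at_threshold(c(0.1, 0.2), 1),
               class = "essnet_invalid_input")
})

test_that("scalar metrics follow the four formulas; zero denominators are NA", {
  m <- scalar_metrics(structure(list(TP = 3, FN = 1, FP = 1, TN = 5),
                                class = "confusion_counts"))
  expect_equal(unname(m), c(0.75, 5 / 6, 0.75, 0.8))

  perfect <- scalar_metrics(structure(list(TP = 7, FN = 0, FP = 0, TN = 9),
                                      class = "confusion_counts"))
  expect_equal(unname(perfect), rep(1, 4))

  expect_message(
    m <- scalar_metrics(structure(list(TP = 0, FN = 2, FP = 0, TN = 3),
                                  class = "confusion_counts")),
    regexp = "ppv")
  expect_true(is.na(m[["ppv"]]))
  expect_false(is.na(m[["accuracy"]]))
})

test_that("ROC/AUC handles separation, ties and the hand-counted example", {
  perfect <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  all_tied <- roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(all_tied$auc, 0.5)
  # 3 concordant of 4 positive/negative pairs
  ex <- roc_auc(c(0.8, 0.6, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(ex$auc, 0.75)

  # curve contract: starts (0,0), ends (1,1), both axes non-decreasing
  expect_equal(as.numeric(ex$points[1, c("fpr", "tpr")]), c(0, 0))
  expect_equal(as.numeric(ex$points[nrow(ex$points), c("fpr", "tpr")]),
               c(1, 1))
  expect_true(all(diff(ex$points$fpr) >= 0))
  expect_true(all(diff(ex$points$tpr) >= 0))

  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), class = "essnet_invalid_input")
})

test_that("trapezoidal AUC equals the pairwise oracle on random instances", {
  withr::with_seed(99, {
    for (i in 1:60) {
      n <- sample(4:50, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))       # both classes present
      probs <- round(runif(n), sample(1:3, 1))       # coarse grid forces ties
      expect_equal(roc_auc(probs, labels)$auc, pairwise_auc(probs, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("Sn/Sp at the threshold coincide with the matching ROC point", {
  withr::with_seed(17, {
    probs <- runif(80)
    labels <- rbinom(80, 1, 0.5)
    m <- suppressMessages(scalar_metrics(confusion_at_threshold(probs, labels)))
    roc <- roc_auc(probs, labels)$points
    at <- utils::tail(which(roc$threshold >= 0.5), 1)  # last point with t>=0.5
    expect_equal(roc$tpr[at], m[["sensitivity"]])
    expect_equal(1 - roc$fpr[at], m[["specificity"]])
  })
})

test_that("PR/AUPR uses step-wise summation", {
  perfect <- pr_aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$aupr, 1)
  # single positive ranked last among 4
  expect_equal(pr_aupr(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 0, 1))$aupr, 0.25)
  # curve passes through precision 1 at recall 1
  pr <- pr_aupr(c(0.9, 0.1), c(1, 0))
  expect_true(any(pr$points$recall == 1 & pr$points$precision == 1))
  expect_error(pr_aupr(c(0.3, 0.2), c(0, 0)), class = "essnet_invalid_input")
})

test_that("metrics_report bundles consistent values", {
  withr::with_seed(4, {
    probs <- runif(60)
    labels <- rbinom(60, 1, 0.5)
  })
  rep <- metrics_report(probs, labels)
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$auc, roc_auc(probs, labels)$auc)
  expect_equal(rep$aupr, pr_aupr(probs, labels)$aupr)
  expect_equal(rep$accuracy,
               suppressMessages(
                 scalar_metrics(confusion_at_threshold(probs, labels))
               )[["accuracy"]])
})

test_that("repeated experiments are deterministic and aggregate correctly", {
  corp <- tiny_corpus(genes_per_species = 150, seed = 55)
  bal <- balance_by_downsampling(corp$records, seed = 8)
  feats <- feature_matrix(bal)
  cfg <- fast_mlp_config(max_epochs = 10L, patience = 3L)

  one <- suppressMessages(
    repeated_experiment(bal, feats, "random", n_repetitions = 1,
                        base_seed = 21, model_config = cfg))
  expect_equal(one$aggregate$sd, rep(0, 6))
  expect_equal(one$aggregate$mean[one$aggregate$metric == "auc"],
               one$reports[[1]]$test$auc)

  again <- suppressMessages(
    repeated_experiment(bal, feats, "random", n_repetitions = 1,
                        base_seed = 21, model_config = cfg))
  expect_identical(one$aggregate, again$aggregate)
  expect_identical(one$reports[[1]]$test$auc, again$reports[[1]]$test$auc)

  # aggregate means are order-invariant reductions of the reports
  two <- suppressMessages(
    repeated_experiment(bal, feats, "random", n_repetitions = 2,
                        base_seed = 21, model_config = cfg))
  per_rep <- vapply(two$reports, function(r) r$test$auc, numeric(1))
  expect_equal(two$aggregate$mean[two$aggregate$metric == "auc"],
               mean(per_rep))
  expect_equal(two$auc$test_auc, per_rep)
})
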