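# Confusion-matrix metrics (Sn, Sp, PPV, accuracy), ROC/AUC and
# precision-recall/AUPR, plus the repeated split-train-evaluate harness.
# Essential is the positive class throughout.

#' Confusion counts at a probability threshold
#'
#' A record is predicted essential iff its probability is greater than or
#' equal to the threshold (ties classify as positive).
#'
#' @param probs Numeric vector of essential-class probabilities.
#' @param labels 0/1 (or logical) labels, 1 = essential.
#' @param threshold Classification threshold, default 0.5.
#' @return A `confusion_counts` object with TP, FP, TN, FN.
#' @export
confusion_at_threshold <- function(probs, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(probs) != length(labels)) {
    stop_invalid_input("probs (%d) and labels (%d) differ in length",
                       length(probs), length(labels))
  }
  pred <- probs >= threshold
  structure(list(TP = sum(pred & labels == 1),
                 FP = sum(pred & labels == 0),
                 TN = sum(!pred & labels == 0),
                 FN = sum(!pred & labels == 1),
                 threshold = threshold),
            class = "confusion_counts")
}

#' Scalar classification metrics from confusion counts
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(FP+TN),
#' positive predictive value PPV = TP/(TP+FP) and accuracy
#' (TP+TN)/(TP+FN+TN+FP). A metric whose denominator is zero is reported as
#' `NA` (undefined, distinct from 0) and noted via a message.
#'
#' @param counts A `confusion_counts` object.
#' @return Named numeric vector (sensitivity, specificity, ppv, accuracy).
#' @export
scalar_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- c(sensitivity = ratio(counts$TP, counts$TP + counts$FN),
           specificity = ratio(counts$TN, counts$FP + counts$TN),
           ppv = ratio(counts$TP, counts$TP + counts$FP),
           accuracy = ratio(counts$TP + counts$TN,
                            counts$TP + counts$FN + counts$TN + counts$FP))
  if (anyNA(out)) {
    message("undefined metric(s) (zero denominator): ",
            paste(names(out)[is.na(out)], collapse = ", "))
  }
  out
}

#' ROC curve and area under it
#'
#' The curve is built by sweeping every distinct score as a threshold; ties
#' are grouped, so trapezoidal integration of the curve equals the pairwise
#' concordance probability P(score_pos > score_neg) + 0.5 P(tie) exactly.
#'
#' @param probs Numeric scores (higher = more essential).
#' @param labels 0/1 or logical labels; both classes must be present.
#' @return List with `points` (data frame fpr/tpr/threshold, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(probs) != length(labels)) {
    stop_invalid_input("probs and labels differ in length")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop_invalid_input("ROC requires both classes (got %d positive, %d negative)",
                       n_pos, n_neg)
  }
  ord <- order(probs, decreasing = TRUE)
  p_sorted <- probs[ord]
  l_sorted <- labels[ord]
  # one curve point per distinct score (last index of each tie group)
  last_of_group <- c(p_sorted[-length(p_sorted)] != p_sorted[-1], TRUE)
  cum_tp <- cumsum(l_sorted == 1)[last_of_group]
  cum_fp <- cumsum(l_sorted == 0)[last_of_group]
  points <- data.frame(fpr = c(0, cum_fp / n_neg),
                       tpr = c(0, cum_tp / n_pos),
                       threshold = c(Inf, p_sorted[last_of_group]))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Precision-recall curve and area under it
#'
#' Points are computed at every distinct score threshold; the area uses the
#' step-wise (interpolation-free) summation sum over thresholds of
#' (recall_k - recall_{k-1}) * precision_k.
#'
#' @inheritParams roc_auc
#' @return List with `points` (data frame recall/precision/threshold) and
#'   `aupr`.
#' @export
pr_aupr <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(probs) != length(labels)) {
    stop_invalid_input("probs and labels differ in length")
  }
  n_pos <- sum(labels == 1)
  if (n_pos == 0) {
    stop_invalid_input("precision-recall requires at least one positive label")
  }
  ord <- order(probs, decreasing = TRUE)
  p_sorted <- probs[ord]
  l_sorted <- labels[ord]
  last_of_group <- c(p_sorted[-length(p_sorted)] != p_sorted[-1], TRUE)
  cum_tp <- cumsum(l_sorted == 1)[last_of_group]
  n_pred <- which(last_of_group)
  points <- data.frame(recall = cum_tp / n_pos,
                       precision = cum_tp / n_pred,
                       threshold = p_sorted[last_of_group])
  aupr <- sum(diff(c(0, points$recall)) * points$precision)
  list(points = points, aupr = aupr)
}

#' Full metrics report for one evaluation
#'
#' @inheritParams confusion_at_threshold
#' @return A `metrics_report`: confusion counts, the four scalar metrics,
#'   ROC points and AUC, PR points and AUPR, and the threshold used.
#' @export
metrics_report <- function(probs, labels, threshold = 0.5) {
  counts <- confusion_at_threshold(probs, labels, threshold)
  scal <- suppressMessages(scalar_metrics(counts))
  roc <- roc_auc(probs, labels)
  pr <- pr_aupr(probs, labels)
  structure(list(counts = counts,
                 sensitivity = scal[["sensitivity"]],
                 specificity = scal[["specificity"]],
                 ppv = scal[["ppv"]],
                 accuracy = scal[["accuracy"]],
                 roc = roc$points, auc = roc$auc,
                 pr = pr$points, aupr = pr$aupr,
                 threshold = threshold,
                 aupr_convention = "step-wise summation, no interpolation"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report: AUC %.3f | AUPR %.3f | Sn %.3f | Sp %.3f | PPV %.3f | Acc %.3f (threshold %.2f)\n",
    x$auc, x$aupr, x$sensitivity, x$specificity, x$ppv, x$accuracy,
    x$threshold))
  invisible(x)
}

scalar_metric_names <- c("auc", "aupr", "sensitivity", "specificity", "ppv",
                         "accuracy")

report_scalars <- function(report) {
  vapply(scalar_metric_names, function(m) report[[m]], numeric(1))
}

# Split, standardize, train and evaluate once. `features` rows are matched to
# records by gene_id rowname. Returns labeled test and validation reports.
run_one_experiment <- function(records, features, policy, split_seed,
                               model_config, fractions) {
  split <- if (policy == "random") {
    random_split(records, fractions, split_seed)
  } else {
    cluster_aware_split(records, fractions, split_seed)
  }
  xy <- function(part) {
    df <- split[[part]]
    list(x = features[df$gene_id, , drop = FALSE],
         y = as.integer(df$essential))
  }
  tr <- xy("train"); va <- xy("validation"); te <- xy("test")
  std <- fit_standardizer(tr$x)
  cfg <- model_config
  cfg$seed <- stage_seed(split_seed, "model-init")
  model <- build_model(cfg)
  model <- train_mlp(model,
                     apply_standardizer(std, tr$x), tr$y,
                     apply_standardizer(std, va$x), va$y)
  list(test = metrics_report(predict_proba(model,
                                           apply_standardizer(std, te$x)),
                             te$y),
       validation = metrics_report(predict_proba(model,
                                                 apply_standardizer(std, va$x)),
                                   va$y),
       split = split, model = model, standardizer = std)
}

#' Repeated split/train/evaluate experiment
#'
#' Repetition k splits the corpus with seed `base_seed + k`, trains the
#' classifier and evaluates on the held-out test partition (validation-set
#' metrics are reported alongside, labeled). Aggregates are the mean and
#' standard deviation of each scalar metric over repetitions, plus the raw
#' per-repetition AUC list.
#'
#' @param records A balanced corpus data frame (see
#'   [balance_by_downsampling()]).
#' @param features Feature matrix with rownames matching `records$gene_id`
#'   (computed internally when `NULL`).
#' @param policy `"random"` or `"cluster_aware"` splitting.
#' @param n_repetitions Number of repetitions (default 10).
#' @param base_seed Integer; repetition k uses split seed `base_seed + k`.
#' @param model_config An `mlp_config`.
#' @param fractions Train/validation/test fractions.
#' @param keep_models If TRUE, keep each repetition's trained model.
#' @return List with `reports` (per repetition: test and validation
#'   `metrics_report`s), `aggregate` (data frame of per-metric mean and sd on
#'   the test partition), `auc` (data frame of test and validation AUC per
#'   repetition) and `policy`.
#' @export
repeated_experiment <- function(records, features = NULL,
                                policy = c("random", "cluster_aware"),
                                n_repetitions = 10L, base_seed = 1L,
                                model_config = mlp_config(),
                                fractions = c(0.8, 0.1, 0.1),
                                keep_models = FALSE) {
  policy <- match.arg(policy)
  validate_corpus(records)
  if (is.null(features)) {
    features <- feature_matrix(records)
  }
  reports <- vector("list", n_repetitions)
  for (k in seq_len(n_repetitions)) {
    res <- tryCatch(
      run_one_experiment(records, features, policy, base_seed + k,
                         model_config, fractions),
      error = function(e) {
        stop(errorCondition(
          sprintf("repetition %d (%s): %s", k, policy, conditionMessage(e)),
          class = class(e)))
      })
    reports[[k]] <- if (keep_models) res else res[c("test", "validation")]
  }
  test_scalars <- t(vapply(reports, function(r) report_scalars(r$test),
                           numeric(length(scalar_metric_names))))
  aggregate <- data.frame(
    metric = scalar_metric_names,
    mean = colMeans(test_scalars, na.rm = TRUE),
    sd = if (n_repetitions == 1) 0 else
      apply(test_scalars, 2, stats::sd, na.rm = TRUE),
    row.names = NULL)
  auc <- data.frame(
    repetition = seq_len(n_repetitions),
    test_auc = test_scalars[, "auc"],
    validation_auc = vapply(reports, function(r) r$validation$auc,
                            numeric(1)))
  list(reports = reports, aggregate = aggregate, auc = auc, policy = policy,
       base_seed = base_seed)
}
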