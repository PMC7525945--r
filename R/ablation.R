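# Feature-importance methodology: Pearson correlation screening, grouping of
# highly correlated feature pairs (|r| > 0.9), and leave-one-unit-out
# ablation measured as the AUC drop under a paired stratified 5-fold
# cross-validation (the same folds are reused for the baseline and for every
# ablated run).

#' Pairwise Pearson correlation matrix of a feature table
#'
#' Correlations involving a constant (zero-variance) feature are reported as
#' 0 and flagged with a warning; the diagonal is 1.
#'
#' @param features Numeric matrix (records x features).
#' @return Symmetric correlation matrix with feature names as dimnames.
#' @export
correlation_matrix <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3) {
    stop_invalid_input("correlation needs at least 3 records, got %d",
                       nrow(features))
  }
  cm <- suppressWarnings(stats::cor(features))
  if (anyNA(cm)) {
    constant <- colnames(cm)[apply(is.na(cm), 2, all) |
                               apply(features, 2, stats::sd) == 0]
    warning(sprintf("constant feature(s), correlation reported as 0: %s",
                    paste(utils::head(constant, 5), collapse = ", ")),
            call. = FALSE)
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Group features into ablation units by correlation
#'
#' Every unordered feature pair with |r| above the threshold becomes one
#' unit; features occurring in more than one qualifying pair are merged
#' transitively into a single unit. All remaining features become singleton
#' units. Units are disjoint by construction.
#'
#' @param matrix Correlation matrix from [correlation_matrix()].
#' @param threshold Absolute-correlation threshold (default 0.9, strict).
#' @return Named list of character vectors (the features of each unit), in
#'   feature-layout order of their first member.
#' @export
correlated_units <- function(matrix, threshold = 0.9) {
  feats <- colnames(matrix)
  parent <- seq_along(feats)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  hits <- which(abs(matrix) > threshold & upper.tri(matrix), arr.ind = TRUE)
  for (k in seq_len(nrow(hits))) {
    ri <- find(hits[k, 1]); ci <- find(hits[k, 2])
    if (ri != ci) parent[max(ri, ci)] <- min(ri, ci)
  }
  roots <- vapply(seq_along(feats), find, 1L)
  units <- split(feats, roots)
  units <- units[order(as.integer(names(units)))]
  names(units) <- vapply(units, paste, "", collapse = "+")
  units
}

#' Leave-one-unit-out ablation study
#'
#' The baseline is the mean test-fold AUC of the full-feature classifier over
#' a seeded class-stratified k-fold cross-validation. Each ablation unit is
#' then removed (both members of a correlated pair are removed together,
#' since removing only one would be compensated by its correlate) and the
#' classifier retrained with the reduced input width on exactly the same
#' folds. The AUC drop (baseline - ablated; positive = performance loss) is
#' reported per unit, sorted descending.
#'
#' Within each fold a small class-stratified slice of the training portion is
#' held out as the validation set driving early stopping.
#'
#' @param features Numeric feature matrix (records x features).
#' @param labels 0/1 or logical labels (1 = essential); classes should be
#'   balanced.
#' @param units List of character vectors from [correlated_units()] (may be
#'   a subset to restrict the study).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment and training.
#' @param model_config An `mlp_config`; its `input_dim` is adapted per run.
#' @param validation_fraction Fraction of the training portion held out for
#'   early stopping (default 0.1).
#' @return Data frame (unit, baseline_auc, ablated_auc, delta), sorted by
#'   delta descending.
#' @export
ablation_study <- function(features, labels, units, folds = 5L, seed = 1L,
                           model_config = mlp_config(),
                           validation_fraction = 0.1) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  unknown <- setdiff(unlist(units), colnames(features))
  if (length(unknown) > 0) {
    stop_config("ablation unit references unknown feature(s): %s",
                paste(utils::head(unknown, 5), collapse = ", "))
  }
  fold_id <- stratified_folds(labels, folds, stage_seed(seed, "cv-folds"))
  cv_auc <- function(x) {
    aucs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr_idx <- which(fold_id != f)
      te_idx <- which(fold_id == f)
      val_n <- max(2L, round(validation_fraction * length(tr_idx)))
      val_pick <- with_local_seed(stage_seed(seed, sprintf("cv-val-%d", f)), {
        pos <- tr_idx[labels[tr_idx] == 1]
        neg <- tr_idx[labels[tr_idx] == 0]
        c(sample(pos, max(1L, round(val_n / 2))),
          sample(neg, max(1L, round(val_n / 2))))
      })
      fit_idx <- setdiff(tr_idx, val_pick)
      std <- fit_standardizer(x[fit_idx, , drop = FALSE])
      cfg <- model_config
      cfg$input_dim <- ncol(x)
      cfg$seed <- stage_seed(seed, sprintf("cv-model-%d", f))
      model <- train_mlp(build_model(cfg),
                         apply_standardizer(std, x[fit_idx, , drop = FALSE]),
                         labels[fit_idx],
                         apply_standardizer(std, x[val_pick, , drop = FALSE]),
                         labels[val_pick])
      probs <- predict_proba(model,
                             apply_standardizer(std, x[te_idx, , drop = FALSE]))
      aucs[f] <- roc_auc(probs, labels[te_idx])$auc
    }
    mean(aucs)
  }
  baseline <- cv_auc(features)
  unit_names <- names(units) %||%
    vapply(units, paste, "", collapse = "+")
  ablated <- vapply(seq_along(units), function(i) {
    if (length(units[[i]]) == 0) return(baseline)   # empty unit: identity
    keep <- setdiff(colnames(features), units[[i]])
    cv_auc(features[, keep, drop = FALSE])
  }, numeric(1))
  out <- data.frame(unit = unit_names,
                    baseline_auc = baseline,
                    ablated_auc = ablated,
                    delta = baseline - ablated,
                    row.names = NULL)
  out[order(out$delta, decreasing = TRUE), , drop = FALSE]
}

# Class-stratified fold assignment: within each class, records are shuffled
# and dealt round-robin to folds.
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  with_local_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Write a correlation matrix as delimited text
#'
#' @param matrix Correlation matrix.
#' @param path Output path (tab-separated, with a `feature` id column).
#' @export
write_correlation_matrix <- function(matrix, path) {
  df <- data.frame(feature = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
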