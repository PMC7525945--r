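# Class balancing by down-sampling and train/validation/test partitioning,
# either fully random (class-stratified) or orthology-cluster-aware so that
# homologous genes never straddle the train/test boundary.

check_fractions <- function(fractions) {
  if (length(fractions) != 3 || any(!is.finite(fractions)) ||
      any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop_config("split fractions must be three positive numbers summing to 1")
  }
  fractions
}

#' Balance classes by down-sampling the majority class
#'
#' The majority class is down-sampled uniformly at random without replacement
#' to the minority-class size, so the result has equal class counts. Record
#' content is never modified, only membership; original record order is kept.
#'
#' @param records Corpus data frame with logical column `essential`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return The balanced corpus.
#' @export
balance_by_downsampling <- function(records, seed) {
  validate_corpus(records)
  n_pos <- sum(records$essential)
  n_neg <- sum(!records$essential)
  if (n_pos == 0 || n_neg == 0) {
    stop_invalid_input("both classes must be present to balance (%d essential, %d non-essential)",
                       n_pos, n_neg)
  }
  if (n_pos == n_neg) {
    return(records)
  }
  majority <- which(records$essential == (n_pos > n_neg))
  minority_n <- min(n_pos, n_neg)
  keep_major <- with_local_seed(seed, sample(majority, minority_n))
  keep <- sort(c(which(records$essential != (n_pos > n_neg)), keep_major))
  records[keep, , drop = FALSE]
}

new_dataset_split <- function(train, validation, test, policy, fractions,
                              seed) {
  ids <- c(train$gene_id, validation$gene_id, test$gene_id)
  stopifnot(!anyDuplicated(ids))
  structure(list(train = train, validation = validation, test = test,
                 policy = policy, fractions = fractions,
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split (%s, seed %d): train %d / validation %d / test %d\n",
              x$policy, x$seed, nrow(x$train), nrow(x$validation),
              nrow(x$test)))
  invisible(x)
}

#' Random class-stratified train/validation/test split
#'
#' Records are shuffled by the seed and partitioned per class: each class
#' contributes floor(f * n_class) records to train and validation and the
#' remainder to test, so the class balance of every partition matches the
#' corpus within one record per class.
#'
#' @param records Corpus data frame.
#' @param fractions Train/validation/test fractions (positive, summing to 1).
#' @param seed Integer seed.
#' @return A `dataset_split` object.
#' @export
random_split <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  validate_corpus(records)
  check_fractions(fractions)
  if (nrow(records) < 10) {
    stop_invalid_input("need at least 10 records to split, got %d",
                       nrow(records))
  }
  part <- character(nrow(records))
  with_local_seed(seed, {
    for (cls in unique(records$essential)) {
      idx <- which(records$essential == cls)
      idx <- sample(idx)
      n <- length(idx)
      n_tr <- floor(fractions[1] * n)
      n_va <- floor(fractions[2] * n)
      part[idx[seq_len(n_tr)]] <- "train"
      part[idx[n_tr + seq_len(n_va)]] <- "validation"
      part[idx[seq(n_tr + n_va + 1, length.out = n - n_tr - n_va)]] <- "test"
    }
  })
  new_dataset_split(records[part == "train", , drop = FALSE],
                    records[part == "validation", , drop = FALSE],
                    records[part == "test", , drop = FALSE],
                    "random", fractions, seed)
}

#' Orthology-cluster-aware train/validation/test split
#'
#' Whole clusters -- never individual genes -- are assigned greedily to the
#' partitions: clusters are taken largest first (shuffled by the seed within
#' equal sizes) and each is placed into the partition with the largest
#' remaining gene-count deficit relative to its target (train preferred on
#' ties). Every cluster therefore lies entirely within one partition, so no
#' pair of homologous genes can appear on both sides of the train/test
#' boundary. Realized fractions may deviate from the targets; a cluster
#' larger than the whole train target is forced into train with a warning.
#'
#' @inheritParams random_split
#' @return A `dataset_split` object with policy `"cluster_aware"`.
#' @export
cluster_aware_split <- function(records, fractions = c(0.8, 0.1, 0.1),
                                seed = 1L) {
  validate_corpus(records)
  check_fractions(fractions)
  if (any(is.na(records$cluster_id))) {
    stop_invalid_input("every record needs a cluster_id; run attach_clusters() first")
  }
  n <- nrow(records)
  targets <- c(train = floor(fractions[1] * n),
               validation = floor(fractions[2] * n))
  targets <- c(targets, test = n - sum(targets))
  cl_sizes <- table(records$cluster_id)
  cl_names <- with_local_seed(seed, sample(names(cl_sizes)))
  cl_names <- cl_names[order(cl_sizes[cl_names], decreasing = TRUE)]
  oversized <- names(cl_sizes)[cl_sizes > targets["train"]]
  if (length(oversized) > 0) {
    warning(sprintf("cluster(s) larger than the train target forced into train: %s",
                    paste(oversized, collapse = ", ")), call. = FALSE)
  }
  assign_to <- stats::setNames(character(length(cl_names)), cl_names)
  filled <- c(train = 0L, validation = 0L, test = 0L)
  for (cl in cl_names) {
    p <- if (cl %in% oversized) "train" else
      names(filled)[which.max(targets - filled)]   # ties resolve to train
    assign_to[cl] <- p
    filled[p] <- filled[p] + cl_sizes[[cl]]
  }
  part <- unname(assign_to[records$cluster_id])
  message(sprintf("cluster-aware split realized fractions: %.3f/%.3f/%.3f (targets %.3f/%.3f/%.3f)",
                  filled["train"] / n, filled["validation"] / n,
                  filled["test"] / n, fractions[1], fractions[2],
                  fractions[3]))
  new_dataset_split(records[part == "train", , drop = FALSE],
                    records[part == "validation", , drop = FALSE],
                    records[part == "test", , drop = FALSE],
                    "cluster_aware", fractions, seed)
}

#' Split manifest as a data frame
#'
#' @param split A `dataset_split`.
#' @return Data frame with gene_id, partition, cluster_id and the split seed,
#'   sufficient to reproduce the experiment exactly.
#' @export
split_manifest <- function(split) {
  stopifnot(inherits(split, "dataset_split"))
  do.call(rbind, lapply(c("train", "validation", "test"), function(p) {
    df <- split[[p]]
    if (nrow(df) == 0) return(NULL)
    data.frame(gene_id = df$gene_id, partition = p,
               cluster_id = df$cluster_id, seed = split$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Write a split manifest as tab-separated text
#'
#' @param split A `dataset_split`.
#' @param path Output path.
#' @export
write_split_manifest <- function(split, path) {
  utils::write.table(split_manifest(split), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fit a per-feature standardizer on the training partition
#'
#' Location is the per-feature train mean and scale the per-feature train
#' standard deviation (1 for constant features). Fitting is restricted to
#' the training partition by contract: statistics computed on validation or
#' test data would leak information into training.
#'
#' @param x Numeric feature matrix of the training partition.
#' @param fitted_on Partition name; anything other than `"train"` is
#'   rejected.
#' @return A `standardizer` object.
#' @export
fit_standardizer <- function(x, fitted_on = "train") {
  if (!identical(fitted_on, "train")) {
    stop_state("standardizer must be fitted on the training partition, not '%s'",
               fitted_on)
  }
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale, fitted_on = fitted_on),
            class = "standardizer")
}

#' Apply a fitted standardizer to a feature matrix
#'
#' @param std A `standardizer` from [fit_standardizer()].
#' @param x Numeric feature matrix with the same columns the standardizer
#'   was fitted on.
#' @return The transformed matrix.
#' @export
apply_standardizer <- function(std, x) {
  if (!inherits(std, "standardizer")) {
    stop_state("not a fitted standardizer")
  }
  x <- as.matrix(x)
  if (ncol(x) != length(std$center)) {
    stop_invalid_input("feature dimension %d does not match standardizer (%d)",
                       ncol(x), length(std$center))
  }
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}
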