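#' Repeated stratified patient-level splits
#'
#' Splits subjects into training and validation sets `repetitions` times
#' independently (Monte-Carlo cross-validation, as opposed to disjoint
#' k-fold partitions, which [kfold_splits()] provides). Stratification is by
#' subject label: each repetition draws `round(val_fraction * n_c)` (at
#' least 1) validation subjects per class without replacement. Splitting is
#' on a patient basis, so no subject can contribute recordings to both
#' sides.
#'
#' @param labels named integer vector: subject id -> class label.
#' @param repetitions number of independent splits (default 10).
#' @param val_fraction validation fraction (default 0.20).
#' @return A `split_plan`: list with `repetitions` entries, each holding
#'   `train` and `validation` subject-id character vectors.
#' @export
repeated_stratified_splits <- function(labels, repetitions = 10,
                                       val_fraction = 0.20) {
  subjects <- names(labels)
  if (is.null(subjects) || any(subjects == "")) {
    stop("labels must be named by subject id", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    stop(sprintf("every class needs at least 2 subjects; class %s has %d",
                 names(counts)[which.min(counts)], min(counts)),
         call. = FALSE)
  }
  splits <- lapply(seq_len(repetitions), function(r) {
    val <- unlist(lapply(names(counts), function(cl) {
      ids <- subjects[labels == cl]
      n_val <- max(1L, round(val_fraction * length(ids)))
      sample(ids, n_val)
    }), use.names = FALSE)
    list(train = setdiff(subjects, val), validation = sort(val))
  })
  structure(list(splits = splits, repetitions = repetitions,
                 val_fraction = val_fraction, labels = labels),
            class = "split_plan")
}

#' Disjoint stratified k-fold partition
#'
#' True k-fold alternative to [repeated_stratified_splits()]: each class's
#' subjects are shuffled once and dealt into `k` folds; repetition `i` uses
#' fold `i` as validation.
#'
#' @param labels named integer vector: subject id -> class label.
#' @param k number of folds (default 10).
#' @return A `split_plan` with `k` entries.
#' @export
kfold_splits <- function(labels, k = 10) {
  subjects <- names(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class needs at least k subjects for k-fold", call. = FALSE)
  }
  fold_of <- integer(length(labels))
  names(fold_of) <- subjects
  for (cl in names(counts)) {
    ids <- sample(subjects[labels == cl])
    fold_of[ids] <- rep_len(seq_len(k), length(ids))
  }
  splits <- lapply(seq_len(k), function(i) {
    val <- subjects[fold_of[subjects] == i]
    list(train = setdiff(subjects, val), validation = sort(val))
  })
  structure(list(splits = splits, repetitions = k, val_fraction = 1 / k,
                 labels = labels), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d repetitions, %.0f%% validation, %d subjects\n",
              x$repetitions, 100 * x$val_fraction, length(x$labels)))
  invisible(x)
}

# Mann-Whitney AUC of scores for positives vs negatives (ties count 1/2)
pairwise_auc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n1 <- length(scores_pos); n0 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics for one evaluation
#'
#' The metric suite used throughout: one-vs-one AUROC (the pairwise AUC of
#' class `i`'s probability on samples of classes `i` and `j`, averaged over
#' all ordered class pairs present), balanced accuracy (mean per-class
#' recall), and support-weighted F1, precision and recall. AUROC is `NA`
#' when probabilities are not supplied or fewer than two classes occur in
#' the truth.
#'
#' @param truth true labels.
#' @param pred predicted labels.
#' @param prob optional `n x num_classes` probability matrix with columns
#'   ordered by class `0, 1, ...` (or named by class).
#' @param classes class domain; defaults to the classes present in truth or
#'   predictions.
#' @return Named numeric vector: `auroc`, `balanced_accuracy`, `f1`,
#'   `precision`, `recall`.
#' @export
compute_metrics <- function(truth, pred, prob = NULL, classes = NULL) {
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  present <- classes[classes %in% truth]

  recall_c <- vapply(present, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1))
  prec_c <- vapply(present, function(cl) {
    denom <- sum(pred == cl)
    if (denom == 0) 0 else sum(pred == cl & truth == cl) / denom
  }, numeric(1))
  f1_c <- ifelse(prec_c + recall_c == 0, 0,
                 2 * prec_c * recall_c / (prec_c + recall_c))
  support <- vapply(present, function(cl) sum(truth == cl), numeric(1))
  wts <- support / sum(support)

  auroc <- NA_real_
  if (!is.null(prob) && length(present) >= 2) {
    if (!is.null(colnames(prob))) {
      col_of <- function(cl) which(colnames(prob) == as.character(cl))
    } else {
      col_of <- function(cl) which(classes == cl)
    }
    pairs <- expand.grid(i = present, j = present)
    pairs <- pairs[pairs$i != pairs$j, ]
    aucs <- mapply(function(i, j) {
      pairwise_auc(prob[truth == i, col_of(i)], prob[truth == j, col_of(i)])
    }, pairs$i, pairs$j)
    auroc <- mean(aucs)
  }
  c(auroc = auroc,
    balanced_accuracy = mean(recall_c),
    f1 = sum(wts * f1_c),
    precision = sum(wts * prec_c),
    recall = sum(wts * recall_c))
}

#' Summarize metrics over repetitions
#'
#' Unweighted mean and sample (n-1) standard deviation per metric; a single
#' repetition reports SD 0 by convention.
#'
#' @param entries list of named metric vectors (from [compute_metrics()]),
#'   or a matrix with one row per repetition.
#' @return List with `mean` and `sd` named vectors and the entry matrix.
#' @export
summarize_folds <- function(entries) {
  m <- if (is.matrix(entries)) entries else do.call(rbind, entries)
  if (nrow(m) == 0) stop("no entries to summarize", call. = FALSE)
  mu <- colMeans(m)
  dev <- if (nrow(m) == 1) {
    stats::setNames(rep(0, ncol(m)), colnames(m))
  } else {
    apply(m, 2, stats::sd)
  }
  list(mean = mu, sd = dev, entries = m)
}

#' Check a split plan for patient-level leakage
#'
#' @param plan a `split_plan`.
#' @return Number of subjects appearing in both train and validation of any
#'   repetition (0 for a sound plan).
#' @export
split_leakage_count <- function(plan) {
  sum(vapply(plan$splits, function(s) {
    length(intersect(s$train, s$validation))
  }, numeric(1)))
}
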