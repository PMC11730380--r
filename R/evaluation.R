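# Cross-validation protocols and ranking metrics.
#
# Goal 1: known unordered interacting pairs are partitioned into k folds;
# each fold's pairs are removed (both triangles) from the training network,
# and scoring candidates are the held-out positives plus every
# never-interacting pair.  Goal 2: drugs are partitioned into k folds; each
# fold's drugs are removed entirely and scored cold-start against the
# training drugs.  No negative sampling is performed: the full imbalanced
# candidate set is evaluated, which is why AUPR is the primary metric.

#' Partition known interacting pairs into folds (goal 1)
#'
#' @param network Binary symmetric interaction matrix.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `ddi_folds`: `mode = "goal1"`, `pairs` (two-column
#'   index matrix of the unordered known pairs, `i < j`), `fold` (fold id
#'   per pair), `k`, `seed`.
#' @export
split_goal1 <- function(network, k = 5, seed = 1) {
  validate_network(network, require_edge = TRUE)
  idx <- which(upper.tri(network) & network == 1)
  n <- nrow(network)
  pairs <- cbind(row(network)[idx], col(network)[idx])
  if (nrow(pairs) < k) stop("fewer known pairs (", nrow(pairs),
                            ") than folds (", k, ")")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), nrow(pairs)))
  structure(list(mode = "goal1", pairs = pairs, fold = fold, k = k,
                 seed = seed, n = n),
            class = "ddi_folds")
}

#' Partition drugs into folds (goal 2)
#'
#' @param ids Drug identifiers (a catalog or the dimnames of a network).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Object of class `ddi_folds`: `mode = "goal2"`, `ids`, `fold`
#'   (fold id per drug), `k`, `seed`.
#' @export
split_goal2 <- function(ids, k = 5, seed = 1) {
  if (is.matrix(ids)) ids <- rownames(ids)
  ids <- as.character(ids)
  if (length(ids) < k) stop("fewer drugs than folds")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), length(ids)))
  structure(list(mode = "goal2", ids = ids, fold = fold, k = k, seed = seed),
            class = "ddi_folds")
}

#' Train/validation/test drug split for case studies
#'
#' The named preset used for cold-start case studies: 66.67% of drugs for
#' training, 16.67% for validation (hyperparameter checks) and the rest as
#' simulated new drugs.
#'
#' @param ids Drug identifiers.
#' @param seed Integer seed.
#' @return List with character vectors `train`, `validation`, `test`.
#' @export
case_study_split <- function(ids, seed = 1) {
  if (is.matrix(ids)) ids <- rownames(ids)
  ids <- as.character(ids)
  n <- length(ids)
  if (n < 6) stop("need at least 6 drugs for the 4:1:1 split")
  set.seed(seed)
  perm <- sample(ids)
  n_train <- round(n * 2 / 3)
  n_val <- round(n / 6)
  list(train = perm[seq_len(n_train)],
       validation = perm[n_train + seq_len(n_val)],
       test = perm[(n_train + n_val + 1):n])
}

#' @export
print.ddi_folds <- function(x, ...) {
  units <- if (x$mode == "goal1") nrow(x$pairs) else length(x$ids)
  cat("<ddi_folds> ", x$mode, ": ", units, " units in ", x$k,
      " folds (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Confusion counts at a score threshold
#'
#' Scores at or above the threshold are predicted positive.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1 or logical).
#' @param threshold Decision threshold.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(scores) == 0) stop("empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  pred <- scores >= threshold
  c(tp = sum(pred & labels == 1L), fp = sum(pred & labels == 0L),
    tn = sum(!pred & labels == 0L), fn = sum(!pred & labels == 1L))
}

#' Threshold classification metrics from confusion counts
#'
#' Recall = TP/(TP+FN), Precision = TP/(TP+FP),
#' F1 = 2PR/(P+R), Accuracy = (TP+TN)/total.  A zero denominator yields 0
#' with a warning.
#'
#' @param counts Named vector from [confusion_counts()] (or four scalars
#'   `tp, fp, tn, fn`).
#' @return Named numeric vector `c(recall, precision, f1, accuracy)`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0")
      0
    } else num / den
  }
  recall <- safe(tp, tp + fn, "recall")
  precision <- safe(tp, tp + fp, "precision")
  f1 <- safe(2 * precision * recall, precision + recall, "F1")
  accuracy <- safe(tp + tn, tp + tn + fp + fn, "accuracy")
  c(recall = recall, precision = precision, f1 = f1, accuracy = accuracy)
}

#' Area under the ROC curve
#'
#' Rank-statistic form: the probability that a random positive outscores a
#' random negative, ties counted half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over descending unique score thresholds
#' (average-precision style, no interpolation between points): tied scores
#' enter as one threshold group.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; at least one positive required.
#' @return AUPR in (0, 1\].
#' @export
aupr_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0) stop("AUPR needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last_in_group <- c(diff(s) != 0, TRUE)   # collapse tied thresholds
  tp <- tp[last_in_group]
  fp <- fp[last_in_group]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

# default decision threshold: the score whose predicted-positive count
# equals the count implied by the training interaction density
prevalence_threshold <- function(scores, train_density) {
  k <- max(1L, min(length(scores), round(train_density * length(scores))))
  sort(scores, decreasing = TRUE)[k]
}

#' Cross-validated evaluation of the prediction model
#'
#' Runs the k-fold protocol for the chosen goal (see the module notes
#' above), fits one model per fold and reports the six metrics per fold
#' with mean and standard deviation.  The decision threshold for the four
#' count metrics defaults to the score at which the predicted-positive
#' count matches the count implied by the training interaction density;
#' override with `threshold`.
#'
#' @inheritParams ddi_fit
#' @param k Number of folds.
#' @param threshold Optional fixed decision threshold.
#' @param ... Further arguments passed to [ddi_fit()] (e.g. `lambda`,
#'   `theta`, `sigma`, `max_iter`).
#' @return Object of class `ddi_cv`: `metrics` (data frame, one row per
#'   fold plus `mean` and `sd`), `goal`, `k`, `seed`, `threshold_rule`.
#' @export
ddi_crossval <- function(features, network, goal = 1, k = 5, seed = 1,
                         threshold = NULL, ...) {
  ids <- validate_inputs(features, network)
  n <- length(ids)
  metric_names <- c("recall", "precision", "f1", "accuracy", "auc", "aupr")
  rows <- matrix(NA_real_, k, length(metric_names),
                 dimnames = list(NULL, metric_names))
  thresholds <- numeric(k)
  if (goal == 1) {
    folds <- split_goal1(network, k, seed)
    all_density <- sum(network) / 2 / choose(n, 2)
    for (f in seq_len(k)) {
      held <- folds$pairs[folds$fold == f, , drop = FALSE]
      J_train <- network
      J_train[held] <- 0
      J_train[held[, c(2, 1), drop = FALSE]] <- 0
      model <- ddi_fit(features, J_train, goal = 1, seed = seed + f, ...)
      Ssym <- (model$S + t(model$S)) / 2
      cand <- upper.tri(network) & J_train == 0
      sc <- Ssym[cand]
      lab <- network[cand]
      train_density <- sum(J_train) / 2 / choose(n, 2)
      thr <- if (is.null(threshold)) prevalence_threshold(sc, train_density)
             else threshold
      thresholds[f] <- thr
      cm <- classification_metrics(confusion_counts(sc, lab, thr))
      rows[f, ] <- c(cm, auc = auc_score(sc, lab), aupr = aupr_score(sc, lab))
    }
  } else if (goal == 2) {
    folds <- split_goal2(ids, k, seed)
    for (f in seq_len(k)) {
      test_ids <- folds$ids[folds$fold == f]
      train_ids <- setdiff(ids, test_ids)
      tr <- catalog_index(ids, train_ids)
      J_train <- network[tr, tr]
      H_train <- lapply(features, function(H) H[tr, , drop = FALSE])
      model <- ddi_fit(H_train, J_train, goal = 2, seed = seed + f, ...)
      sc <- numeric(0); lab <- integer(0)
      for (d in test_ids) {
        hstar <- lapply(features, function(H) H[d, ])
        names(hstar) <- model$feature_names
        jstar <- predict_new_drug(model, hstar)
        sc <- c(sc, unname(jstar))
        lab <- c(lab, network[d, train_ids])
      }
      train_density <- sum(J_train) / 2 / choose(length(train_ids), 2)
      thr <- if (is.null(threshold)) prevalence_threshold(sc, train_density)
             else threshold
      thresholds[f] <- thr
      cm <- classification_metrics(confusion_counts(sc, lab, thr))
      rows[f, ] <- c(cm, auc = auc_score(sc, lab), aupr = aupr_score(sc, lab))
    }
  } else stop("goal must be 1 or 2")
  metrics <- as.data.frame(rows)
  metrics <- rbind(metrics, colMeans(rows), apply(rows, 2, stats::sd))
  metrics <- cbind(fold = c(as.character(seq_len(k)), "mean", "sd"), metrics)
  structure(list(metrics = metrics, goal = goal, k = k, seed = seed,
                 thresholds = thresholds,
                 threshold_rule = if (is.null(threshold))
                   "training-prevalence count" else "fixed"),
            class = "ddi_cv")
}

#' @export
print.ddi_cv <- function(x, ...) {
  cat("<ddi_cv> goal ", x$goal, ", ", x$k, "-fold (seed ", x$seed, ")\n",
      sep = "")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a cross-validation report
#'
#' @param cv A [ddi_crossval()] result.
#' @param csv,json Optional output paths.
#' @return `cv`, invisibly.
#' @export
write_cv_report <- function(cv, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    utils::write.csv(cv$metrics, csv, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(goal = cv$goal, k = cv$k, seed = cv$seed,
           threshold_rule = cv$threshold_rule, metrics = cv$metrics),
      json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(cv)
}

#' Hyperparameter grid search
#'
#' Sweeps `lambda`, `theta` (and for goal 1 also `sigma`) over the supplied
#' value grid, running [ddi_crossval()] for each combination; goal 2 fixes
#' `sigma = 0`.
#'
#' @inheritParams ddi_crossval
#' @param values Candidate values for each tunable weight (default
#'   `10^(-5:-1)`).
#' @param metric Column of the CV report to rank by.
#' @return Data frame of combinations with their mean metric values, sorted
#'   best-first.
#' @export
tune_ddi <- function(features, network, goal = 1, values = 10^(-5:-1),
                     k = 5, seed = 1, metric = "aupr", ...) {
  grid <- if (goal == 1) {
    expand.grid(lambda = values, theta = values, sigma = values)
  } else {
    expand.grid(lambda = values, theta = values, sigma = 0)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cv <- ddi_crossval(features, network, goal = goal, k = k, seed = seed,
                       lambda = grid$lambda[i], theta = grid$theta[i],
                       sigma = grid$sigma[i], ...)
    mrow <- cv$metrics[cv$metrics$fold == "mean", ]
    cbind(grid[i, , drop = FALSE], mrow[, -1, drop = FALSE])
  })
  out <- do.call(rbind, res)
  out[order(-out[[metric]]), , drop = FALSE]
}
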