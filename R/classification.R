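#' Predict a label by k-nearest-neighbour majority vote
#'
#' Euclidean distance on the supplied feature space. Distance ties at the k-th
#' position are broken by stable training order; vote ties are broken by the
#' smallest summed distance to the query among the tied labels, then by label
#' lexicographic order.
#'
#' @param train_expr Numeric training matrix, samples in rows, features in
#'   columns.
#' @param train_labels Label per training sample.
#' @param query Numeric feature vector (or 1-row matrix).
#' @param k Number of neighbours (default 11); must be positive and no larger
#'   than the training set.
#' @return The predicted label (character scalar).
#' @export
knn_predict <- function(train_expr, train_labels, query, k = 11) {
  train_expr <- as.matrix(train_expr)
  if (k <= 0) stop("k must be positive")
  if (k > nrow(train_expr)) stop("k exceeds the number of training samples")
  query <- as.numeric(query)
  if (length(query) != ncol(train_expr)) stop("feature dimensions do not match")
  d <- sqrt(colSums((t(train_expr) - query)^2))
  nn <- order(d)[seq_len(k)]              # order() is stable: training order
  lab <- as.character(train_labels)[nn]
  votes <- table(lab)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    sums <- vapply(top, function(l) sum(d[nn][lab == l]), numeric(1))
    top <- top[sums == min(sums)]
    if (length(top) > 1) top <- sort(top)[1]
  }
  top
}

#' Leave-one-out cross-validation report for a feature set
#'
#' Each sample is predicted by KNN trained on the remaining n-1 samples;
#' accuracy, per-class sensitivity and specificity, and the predicted-by-true
#' contingency table are assembled over all n predictions. Samples are put in
#' a canonical order (by sample id) before prediction so the report is
#' invariant to input ordering.
#'
#' @param expr A `normalized_expression` object or miRNA x sample matrix.
#' @param labels Class label per sample.
#' @param feature_set miRNA identifiers to use as features.
#' @param k Number of neighbours (default 11).
#' @return An object of class `classifier_report`: `feature_set`, `k`,
#'   `accuracy`, `sensitivity` and `specificity` (named per class),
#'   `contingency` (predicted x true), `predictions`, `n_samples`.
#' @export
loocv_report <- function(expr, labels, feature_set = NULL, k = 11) {
  m <- if (inherits(expr, "normalized_expression")) expr$log2cpm else as.matrix(expr)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m))
  if (is.null(feature_set)) feature_set <- rownames(m)
  missing_ids <- setdiff(feature_set, rownames(m))
  if (length(missing_ids))
    stop("features not in expression matrix: ",
         paste(missing_ids, collapse = ", "))
  if (any(table(labels) < 2))
    stop("every class needs at least 2 members; offending: ",
         paste(names(which(table(labels) < 2)), collapse = ", "))

  feat <- t(m[feature_set, , drop = FALSE])   # samples x features
  ord <- order(rownames(feat))                # canonical order by sample id
  feat <- feat[ord, , drop = FALSE]
  labels <- labels[ord]
  n <- nrow(feat)
  if (k > n - 1) stop("k exceeds the LOOCV training-set size")

  pred <- vapply(seq_len(n), function(i) {
    knn_predict(feat[-i, , drop = FALSE], labels[-i], feat[i, ], k = k)
  }, character(1))

  classes <- sort(unique(labels))
  contingency <- table(factor(pred, levels = classes),
                       factor(labels, levels = classes),
                       dnn = c("predicted", "true"))
  acc <- sum(diag(contingency)) / n
  sens <- diag(contingency) / colSums(contingency)
  spec <- vapply(classes, function(cl) {
    neg <- labels != cl
    sum(pred[neg] != cl) / sum(neg)
  }, numeric(1))
  structure(list(feature_set = feature_set, k = k, accuracy = acc,
                 sensitivity = sens, specificity = spec,
                 contingency = contingency,
                 predictions = stats::setNames(pred, rownames(feat)),
                 n_samples = n),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("LOOCV KNN (k=%d, %d features, n=%d): accuracy %.3f\n",
              x$k, length(x$feature_set), x$n_samples, x$accuracy))
  cat("sensitivity: ",
      paste(sprintf("%s=%.3f", names(x$sensitivity), x$sensitivity),
            collapse = ", "), "\n", sep = "")
  print(x$contingency)
  invisible(x)
}

#' Rank candidate miRNAs and trace cumulative classification curves
#'
#' Step 1: each candidate is LOOCV-evaluated as a single feature. Step 2:
#' candidates are sorted in descending order of the chosen criterion (ties:
#' higher accuracy, then higher mean sensitivity, then id lexicographic).
#' Step 3: each prefix of the sorted list is LOOCV-evaluated as a cumulative
#' feature set.
#'
#' @param expr A `normalized_expression` object or miRNA x sample matrix.
#' @param labels Class label per sample.
#' @param candidate_set Candidate miRNA identifiers (e.g. the FDR-significant
#'   set).
#' @param k Number of neighbours (default 11).
#' @param criterion Ranking criterion, `"accuracy"` or `"sensitivity"` (mean
#'   per-class sensitivity for multi-class tasks; for two-class tasks the
#'   positive class, `"cancer"` if present, is used).
#' @return An object of class `marker_ranking`: `individual` (data frame,
#'   sorted), `cumulative` (data frame, one row per prefix) and `reports`
#'   (the cumulative `classifier_report`s).
#' @export
rank_and_accumulate <- function(expr, labels, candidate_set, k = 11,
                                criterion = c("accuracy", "sensitivity")) {
  criterion <- match.arg(criterion)
  if (!length(candidate_set)) stop("candidate_set must be non-empty")
  labels <- as.character(labels)

  crit_sens <- function(rep) {
    if ("cancer" %in% names(rep$sensitivity)) rep$sensitivity[["cancer"]]
    else mean(rep$sensitivity)
  }
  indiv <- lapply(candidate_set, function(id) {
    rep <- loocv_report(expr, labels, id, k = k)
    data.frame(mirna_id = id, accuracy = rep$accuracy,
               sensitivity = crit_sens(rep),
               specificity = mean(rep$specificity),
               stringsAsFactors = FALSE)
  })
  indiv <- do.call(rbind, indiv)
  key <- if (criterion == "accuracy") indiv$accuracy else indiv$sensitivity
  o <- order(-key, -indiv$accuracy, -indiv$sensitivity, indiv$mirna_id)
  indiv <- indiv[o, , drop = FALSE]
  indiv$rank <- seq_len(nrow(indiv))
  rownames(indiv) <- NULL

  reports <- lapply(seq_len(nrow(indiv)), function(j) {
    loocv_report(expr, labels, indiv$mirna_id[seq_len(j)], k = k)
  })
  cumulative <- data.frame(
    n_features = seq_len(nrow(indiv)),
    added_mirna = indiv$mirna_id,
    cum_accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    cum_sensitivity = vapply(reports, crit_sens, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(individual = indiv, cumulative = cumulative,
                 reports = reports, criterion = criterion, k = k),
            class = "marker_ranking")
}

#' @export
print.marker_ranking <- function(x, ...) {
  best <- which.max(x$cumulative$cum_accuracy)
  cat(sprintf("marker ranking (%d candidates, criterion=%s, k=%d)\n",
              nrow(x$individual), x$criterion, x$k))
  cat(sprintf("best cumulative accuracy %.3f at %d feature(s)\n",
              x$cumulative$cum_accuracy[best], best))
  invisible(x)
}

#' Bootstrap selection of the number of neighbours k
#'
#' For each bootstrap replicate, samples are resampled with replacement and
#' the out-of-bag samples form the evaluation set. Per k the mean out-of-bag
#' accuracy and the mean proportion of neighbours voting for the winning
#' label are recorded. The chosen k is the smallest k whose mean accuracy is
#' within one bootstrap standard error of the maximum.
#'
#' @param expr A `normalized_expression` object or miRNA x sample matrix.
#' @param labels Class label per sample.
#' @param feature_set Features to use (default: all).
#' @param k_grid Candidate k values (default odd 1..21).
#' @param B Number of bootstrap replicates (default 200).
#' @param seed Integer seed for the resampling.
#' @return List with `chosen_k`, and `per_k` (data frame: `k`,
#'   `mean_accuracy`, `se_accuracy`, `mean_vote_proportion`).
#' @export
select_k_bootstrap <- function(expr, labels, feature_set = NULL,
                               k_grid = seq(1, 21, by = 2), B = 200,
                               seed = 1) {
  m <- if (inherits(expr, "normalized_expression")) expr$log2cpm else as.matrix(expr)
  labels <- as.character(labels)
  if (is.null(feature_set)) feature_set <- rownames(m)
  feat <- t(m[feature_set, , drop = FALSE])
  n <- nrow(feat)
  stopifnot(B >= 1, all(k_grid >= 1), all(k_grid < n))
  classes <- unique(labels)

  acc <- matrix(NA_real_, nrow = B, ncol = length(k_grid))
  vote <- matrix(NA_real_, nrow = B, ncol = length(k_grid))
  discarded <- 0
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (!all(classes %in% labels[idx]) || !length(oob)) {
        discarded <- discarded + 1
        next
      }
      tr <- feat[idx, , drop = FALSE]; trl <- labels[idx]
      d <- vapply(oob, function(i)
        sqrt(colSums((t(tr) - feat[i, ])^2)), numeric(nrow(tr)))
      for (j in seq_along(k_grid)) {
        kk <- min(k_grid[j], nrow(tr))
        res <- vapply(seq_along(oob), function(ii) {
          nn <- order(d[, ii])[seq_len(kk)]
          votes <- table(trl[nn])
          top <- names(votes)[votes == max(votes)]
          if (length(top) > 1) {
            sums <- vapply(top, function(l)
              sum(d[nn, ii][trl[nn] == l]), numeric(1))
            top <- top[sums == min(sums)]
            if (length(top) > 1) top <- sort(top)[1]
          }
          c(correct = as.numeric(top == labels[oob[ii]]),
            prop = max(votes) / kk)
        }, numeric(2))
        acc[b, j] <- mean(res["correct", ])
        vote[b, j] <- mean(res["prop", ])
      }
    }
  })
  if (discarded > B / 2)
    stop("more than half of the bootstrap replicates lacked a class")
  if (discarded > 0)
    warning(discarded, " bootstrap replicate(s) lacked a class and were discarded")

  mean_acc <- colMeans(acc, na.rm = TRUE)
  se_acc <- apply(acc, 2, function(z) stats::sd(z, na.rm = TRUE) /
                    sqrt(sum(!is.na(z))))
  se_acc[is.na(se_acc)] <- 0            # single usable replicate

  best <- which.max(mean_acc)
  ok <- mean_acc >= mean_acc[best] - se_acc[best]
  chosen <- k_grid[which(ok)[1]]
  list(chosen_k = chosen,
       per_k = data.frame(k = k_grid, mean_accuracy = mean_acc,
                          se_accuracy = se_acc,
                          mean_vote_proportion = colMeans(vote, na.rm = TRUE)))
}

#' Collapse three-group labels to the two-group (cancer vs control) task
#'
#' @param labels Labels in `{PC, BTC, HC}`.
#' @return Character vector: `"cancer"` for PC/BTC, `"control"` for HC.
#' @export
two_group_collapse <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("PC", "BTC", "HC"))
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  ifelse(labels == "HC", "control", "cancer")
}
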