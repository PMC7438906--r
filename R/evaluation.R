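# Evaluation: confusion-matrix metrics, ROC/AUC, repeated stratified
# cross-validation, and the DeLong comparison of paired ROC curves.

#' Confusion counts from paired truth/prediction vectors
#'
#' @param truth Integer 0/1 (or logical) true labels, 1 = positive.
#' @param estimate Predicted 0/1 labels (or `"ACP"`/`"non-ACP"`).
#' @return A tibble with columns `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, estimate) {
  truth <- as.integer(truth)
  if (is.character(estimate) || is.factor(estimate)) {
    estimate <- as.integer(as.character(estimate) == "ACP")
  }
  estimate <- as.integer(estimate)
  stopifnot(length(truth) == length(estimate),
            all(truth %in% 0:1), all(estimate %in% 0:1))
  tibble::tibble(
    TP = sum(truth == 1 & estimate == 1),
    FP = sum(truth == 0 & estimate == 1),
    TN = sum(truth == 0 & estimate == 0),
    FN = sum(truth == 1 & estimate == 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy
#' Acc = (TP+TN)/total, and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When a
#' marginal of the confusion table is zero the MCC is undefined; the
#' conventional value 0 is reported with `mcc_undefined = TRUE`.
#'
#' @param counts A one-row data frame (or named list/vector) with
#'   `TP`, `FP`, `TN`, `FN`; alternatively pass `truth`/`estimate` to
#'   have the counts computed with [confusion_counts()].
#' @param truth,estimate Optional label vectors used when `counts` is
#'   missing.
#' @return A one-row tibble: `Sn`, `Sp`, `Acc`, `MCC`,
#'   `mcc_undefined`.
#' @export
#' @examples
#' classification_metrics(list(TP = 10, FP = 0, TN = 10, FN = 0))
classification_metrics <- function(counts = NULL, truth = NULL,
                                   estimate = NULL) {
  if (is.null(counts)) {
    counts <- confusion_counts(truth, estimate)
  }
  counts <- as.list(counts)
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  total <- tp + fp + tn + fn
  if (!isTRUE(total > 0)) {
    stop("confusion counts are all zero", call. = FALSE)
  }
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / total
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  undefined <- denom2 == 0
  mcc <- if (undefined) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  tibble::tibble(Sn = sn, Sp = sp, Acc = acc, MCC = mcc,
                 mcc_undefined = undefined)
}

#' Area under the ROC curve
#'
#' AUC via the Mann-Whitney identity using midranks, i.e. tied scores
#' get 0.5 credit: the probability that a random positive scores above
#' a random negative.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Integer 0/1 true labels; both classes required.
#' @return A single number in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps thresholds over the distinct scores in descending order.
#'
#' @inheritParams roc_auc
#' @return A tibble of class `pepstack_roc` with columns `threshold`,
#'   `fpr`, `tpr`, starting at (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("a ROC curve needs both classes present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last occurrence of each score level
  out <- tibble::tibble(
    threshold = c(Inf, s[keep]),
    tpr = c(0, cumsum(y)[keep] / n1),
    fpr = c(0, cumsum(1 - y)[keep] / n0)
  )
  class(out) <- c("pepstack_roc", class(out))
  out
}

#' DeLong comparison of two correlated ROC curves
#'
#' Nonparametric test of the AUC difference between two classifiers
#' scored on the same instances, using the placement-value covariance
#' estimator and a two-sided normal reference. A degenerate variance
#' (e.g. identical score vectors) yields p = 1 with
#' `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Paired score vectors on the same records.
#' @param labels Integer 0/1 true labels.
#' @return A list of class `delong_test` (also supported by
#'   [generics::tidy()]): `auc_a`, `auc_b`, `delta`, `se`,
#'   `statistic`, `p_value`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length",
         call. = FALSE)
  }
  pos <- labels == 1
  neg <- labels == 0
  m <- sum(pos); n <- sum(neg)
  if (m == 0 || n == 0) {
    stop("the DeLong test needs both classes present", call. = FALSE)
  }
  placements <- function(s) {
    x <- s[pos]; y <- s[neg]
    # V10[i]: fraction of negatives below positive i (ties 0.5);
    # V01[j]: fraction of positives above negative j
    v10 <- vapply(x, function(xi)
      (sum(y < xi) + 0.5 * sum(y == xi)) / n, numeric(1))
    v01 <- vapply(y, function(yj)
      (sum(x > yj) + 0.5 * sum(x == yj)) / m, numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / m + s01 / n
  var_delta <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  delta <- pa$auc - pb$auc
  degenerate <- !is.finite(var_delta) || var_delta < 1e-16
  if (degenerate) {
    z <- 0; p <- 1; se <- 0
  } else {
    se <- sqrt(var_delta)
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = se,
         statistic = z, p_value = p, degenerate = degenerate),
    class = "delong_test"
  )
}

#' @export
print.delong_test <- function(x, ...) {
  cat("DeLong comparison of paired ROC curves\n")
  cat(sprintf("  AUC A = %.4f, AUC B = %.4f, difference = %+.4f\n",
              x$auc_a, x$auc_b, x$delta))
  if (x$degenerate) {
    cat("  degenerate variance: p = 1\n")
  } else {
    cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$statistic,
                x$p_value))
  }
  invisible(x)
}

#' @export
tidy.delong_test <- function(x, ...) {
  tibble::tibble(auc_a = x$auc_a, auc_b = x$auc_b, delta = x$delta,
                 se = x$se, statistic = x$statistic,
                 p_value = x$p_value, degenerate = x$degenerate)
}

#' Better/equal/worse comparison triplets from pairwise ROC tests
#'
#' Condenses per-dataset pairwise ROC comparisons into, for each
#' ordered method pair (A, B), the number of datasets where A is
#' significantly better (p < alpha and AUC_A > AUC_B), statistically
#' tied (p >= alpha), or significantly worse, formatted "b/e/w".
#'
#' @param comparisons A tibble with one row per (dataset, method pair):
#'   columns `dataset`, `method_a`, `method_b`, `auc_a`, `auc_b`,
#'   `p_value`. Each unordered pair may appear once per dataset; the
#'   reversed ordering is filled in by antisymmetry.
#' @param alpha Significance level (default 0.05, i.e. 0.95
#'   confidence).
#' @return A tibble: `method_a`, `method_b`, `better`, `equal`,
#'   `worse`, `triplet`.
#' @export
comparison_triplets <- function(comparisons, alpha = 0.05) {
  need <- c("dataset", "method_a", "method_b", "auc_a", "auc_b",
            "p_value")
  stopifnot(all(need %in% names(comparisons)))
  if (anyNA(comparisons[need])) {
    stop("comparison table contains missing cells", call. = FALSE)
  }
  both <- dplyr::bind_rows(
    comparisons[need],
    dplyr::rename(comparisons[need], method_a = "method_b",
                  method_b = "method_a", auc_a = "auc_b",
                  auc_b = "auc_a")
  )
  both <- dplyr::distinct(both, .data$dataset, .data$method_a,
                          .data$method_b, .keep_all = TRUE)
  out <- dplyr::summarise(
    dplyr::group_by(both, .data$method_a, .data$method_b),
    better = sum(.data$p_value < alpha & .data$auc_a > .data$auc_b),
    equal = sum(.data$p_value >= alpha),
    worse = sum(.data$p_value < alpha & .data$auc_a <= .data$auc_b),
    .groups = "drop"
  )
  dplyr::mutate(out, triplet = paste(.data$better, .data$equal,
                                     .data$worse, sep = "/"))
}

# pooled-counts metrics for one repeat of k-fold CV
.pooled_metrics <- function(truth, score, threshold) {
  counts <- confusion_counts(truth, as.integer(score >= threshold))
  met <- classification_metrics(counts)
  met$AUC <- roc_auc(score, truth)
  met
}

#' Repeated stratified k-fold cross-validation of the stacked model
#'
#' Re-draws stratified folds each repeat from a per-repeat seed,
#' trains the full two-stage stack on each training split and scores
#' the held-out fold. Within a repeat the fold confusion counts are
#' pooled before computing metrics (micro-averaging); the AUC pools
#' all out-of-fold scores. Feature encodings are computed once up
#' front since they do not depend on the training labels.
#'
#' @param data Labeled peptide tibble.
#' @param k Folds (each class must have at least `k` members).
#' @param repeats Number of random re-partitions (the stability
#'   protocol runs 30).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param bank,stage1_mode,stage2,grid,threshold,nrounds Passed to the
#'   trainer; see [pepstack()].
#' @return An object of class `pepstack_cv`: list with `metrics` (one
#'   row per repeat: Sn, Sp, Acc, MCC, AUC), `summary` (per-metric
#'   mean and population sd), `scores` (per-record out-of-fold scores
#'   of the first repeat), and the call parameters.
#' @export
cv_pepstack <- function(data, k = 5L, repeats = 1L, seed = 1L,
                        bank = NULL,
                        stage1_mode = c("in_sample", "out_of_fold"),
                        stage2 = "svm", grid = svm_grid(),
                        threshold = 0.5, nrounds = 100L) {
  stage1_mode <- match.arg(stage1_mode)
  data <- .as_peptide_tbl(data)
  stopifnot("label" %in% names(data))
  labels <- as.integer(data$label)
  if (min(table(labels)) < k) {
    stop("each class needs at least k = ", k, " records", call. = FALSE)
  }
  if (is.null(bank)) {
    bank <- if ("pssm" %in% names(data)) encoder_bank()
            else suppressWarnings(encoder_bank(profiles = FALSE))
  }
  features <- encode_with_bank(data, bank)
  per_repeat <- vector("list", repeats)
  first_scores <- NULL
  for (r in seq_len(repeats)) {
    rep_seed <- as.integer(seed) + r
    set.seed(rep_seed)
    folds <- .stratified_folds(labels, k)
    score <- numeric(length(labels))
    for (f in seq_len(k)) {
      hold <- folds == f
      train_feat <- lapply(features, function(x) x[!hold, , drop = FALSE])
      fit <- .fit_stack(train_feat, labels[!hold], bank, stage1_mode,
                        stage2, grid, threshold, rep_seed + 1000L * f,
                        as.integer(nrounds))
      test_feat <- lapply(features, function(x) x[hold, , drop = FALSE])
      meta <- vapply(seq_along(test_feat), function(m) {
        .gbt_predict(fit$stage1[[m]], test_feat[[m]])
      }, numeric(sum(hold)))
      meta <- matrix(meta, nrow = sum(hold),
                     dimnames = list(NULL, names(features)))
      score[hold] <- .stage2_score(fit$stage2$model, fit$stage2$learner,
                                   meta)
    }
    per_repeat[[r]] <- .pooled_metrics(labels, score, threshold)
    if (r == 1L) first_scores <- score
  }
  metrics <- dplyr::bind_rows(per_repeat)
  metrics$repeat_id <- seq_len(repeats)
  long <- tidyr::pivot_longer(
    metrics[c("repeat_id", "Sn", "Sp", "Acc", "MCC", "AUC")],
    cols = -"repeat_id", names_to = "metric", values_to = "value"
  )
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value),
    # population sd; a single repeat reports sd = 0 by convention
    sd = sqrt(mean((.data$value - mean(.data$value))^2)),
    .groups = "drop"
  )
  structure(
    list(metrics = tibble::as_tibble(metrics), summary = summ,
         scores = tibble::tibble(id = data$id, label = labels,
                                 score = first_scores),
         k = k, repeats = repeats, seed = seed,
         stage1_mode = stage1_mode, stage2 = stage2),
    class = "pepstack_cv"
  )
}

#' @export
print.pepstack_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold stratified cross-validation (%s stage 1, %s stage 2)\n",
              x$repeats, x$k, x$stage1_mode, x$stage2))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-4s %.4f (sd %.4f)\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' @export
tidy.pepstack_cv <- function(x, ...) x$metrics

#' @export
glance.pepstack_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(k = x$k, repeats = x$repeats), wide)
}
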