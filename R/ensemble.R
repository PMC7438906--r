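# The two-stage stacked classifier: one gradient-boosted tree model
# per feature encoding whose positive-class scores form the
# meta-feature vector, and a second-layer classifier (by default an
# RBF SVM tuned by grid search) producing the final ACP/non-ACP call.

.MODEL_VERSION <- "pepstack-model-1"

# ---- stage 1: per-encoder gradient-boosted trees ----------------------

.fit_gbt <- function(x, y, nrounds, seed) {
  set.seed(seed)
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", nthread = 1L,
                  seed = seed),
    data = dm, nrounds = nrounds, verbose = 0
  )
}

.gbt_predict <- function(model, x) {
  predict(model, xgboost::xgb.DMatrix(x, nthread = 1L))
}

# stratified fold ids, deterministic given the RNG state
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Fit the first layer of the stacked model
#'
#' Trains one gradient-boosted tree model per feature encoding and
#' assembles the meta-feature matrix whose column m is model m's
#' positive-class probability. `mode = "in_sample"` scores the training
#' rows with the model trained on all of them (the construction used
#' when the stack was introduced); `mode = "out_of_fold"` scores each
#' row from an internal stratified 5-fold model trained without it
#' (avoiding the label leakage of in-sample stacking) and then refits
#' every model on all rows for deployment.
#'
#' @param features Named list of numeric feature matrices with equal
#'   row counts, one per encoder (see [encode_with_bank()]).
#' @param labels Integer 0/1 vector, 1 = ACP; both classes required.
#' @param mode `"in_sample"` or `"out_of_fold"`.
#' @param seed Integer seed controlling fold draws and model fits.
#' @param nrounds Boosting rounds per model (default 100, the usual
#'   gradient-boosting library default).
#' @param output `"probability"` (default; preserves each channel's
#'   confidence) or `"label"` (hard 0/1 stage-1 calls at threshold
#'   0.5).
#' @return A list with `models` (fitted boosters) and `meta`
#'   (n x k meta-feature matrix, columns named by encoder).
#' @export
fit_stage1 <- function(features, labels,
                       mode = c("in_sample", "out_of_fold"),
                       seed = 1L, nrounds = 100L,
                       output = c("probability", "label")) {
  mode <- match.arg(mode)
  output <- match.arg(output)
  stopifnot(is.list(features), length(features) >= 1)
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(all(vapply(features, nrow, integer(1)) == n))
  if (length(unique(labels)) < 2L) {
    stop("stage-1 training needs both classes present", call. = FALSE)
  }
  k <- length(features)
  meta <- matrix(NA_real_, n, k, dimnames = list(NULL, names(features)))
  fold_audit <- NULL
  if (mode == "out_of_fold") {
    n_folds <- min(5L, min(table(labels)))
    if (n_folds < 2L) {
      stop("out_of_fold stacking needs at least 2 records per class",
           call. = FALSE)
    }
    set.seed(seed)
    folds <- .stratified_folds(labels, n_folds)
    fold_audit <- folds
    for (m in seq_len(k)) {
      x <- features[[m]]
      for (f in seq_len(n_folds)) {
        hold <- folds == f
        fit <- .fit_gbt(x[!hold, , drop = FALSE], labels[!hold],
                        nrounds, seed + 31L * m + f)
        meta[hold, m] <- .gbt_predict(fit, x[hold, , drop = FALSE])
      }
    }
  }
  models <- lapply(seq_len(k), function(m) {
    .fit_gbt(features[[m]], labels, nrounds, seed + 31L * m)
  })
  names(models) <- names(features)
  if (mode == "in_sample") {
    for (m in seq_len(k)) {
      meta[, m] <- .gbt_predict(models[[m]], features[[m]])
    }
  }
  if (output == "label") meta[] <- as.numeric(meta >= 0.5)
  list(models = models, meta = meta, mode = mode, output = output,
       folds = fold_audit)
}

# ---- stage 2: grid-searched second-layer classifier -------------------

#' Default RBF grid for the second-layer SVM
#'
#' The classical log2 grid: cost C over 2^-5..2^15 and gamma over
#' 2^-15..2^3, both in steps of 2^2.
#'
#' @return A data frame with columns `cost` and `gamma`.
#' @export
svm_grid <- function() {
  expand.grid(cost = 2^seq(-5, 15, by = 2),
              gamma = 2^seq(-15, 3, by = 2),
              KEEP.OUT.ATTRS = FALSE)
}

# score in [0, 1] from each second-layer learner
.stage2_fit <- function(x, y, learner, cost = 1, gamma = 1 / ncol(x)) {
  ydf <- data.frame(x)
  switch(learner,
    svm = e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = cost, gamma = gamma, scale = FALSE),
    logistic = suppressWarnings(
      stats::glm(y ~ ., data = cbind(ydf, y = y), family = stats::binomial())
    ),
    naive_bayes = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    decision_tree = rpart::rpart(
      y ~ ., data = cbind(ydf, y = factor(y, levels = c(0, 1))),
      method = "class"
    ),
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("the random_forest second layer needs the randomForest ",
             "package", call. = FALSE)
      }
      randomForest::randomForest(x, factor(y, levels = c(0, 1)))
    },
    adaboost = .fit_adaboost(x, y),
    stop("unknown second-layer learner: ", learner, call. = FALSE)
  )
}

.stage2_score <- function(fit, learner, x) {
  xdf <- data.frame(x)
  switch(learner,
    # signed margin through a logistic link: deterministic, monotone,
    # in [0, 1]; 0.5 corresponds to the separating hyperplane
    svm = {
      dv <- attr(predict(fit, x, decision.values = TRUE),
                 "decision.values")
      d <- dv[, 1]
      # libsvm orients the margin toward the first class label it saw;
      # flip so positive means class "1"
      if (startsWith(colnames(dv)[1], "0/")) d <- -d
      1 / (1 + exp(-d))
    },
    logistic = unname(stats::predict(fit, newdata = xdf,
                                     type = "response")),
    naive_bayes = unname(predict(fit, x, type = "raw")[, "1"]),
    decision_tree = unname(predict(fit, newdata = xdf)[, "1"]),
    random_forest = unname(predict(fit, x, type = "prob")[, "1"]),
    adaboost = .predict_adaboost(fit, x)
  )
}

# discrete SAMME boosting with decision stumps; the classical AdaBoost
# formulation used for the second-layer comparison experiments
.fit_adaboost <- function(x, y, n_stumps = 50L) {
  df <- data.frame(x)
  yy <- ifelse(y == 1, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (t in seq_len(n_stumps)) {
    fit <- rpart::rpart(
      yf ~ ., data = cbind(df, yf = factor(yy, levels = c(-1, 1))),
      weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                     minsplit = 2, xval = 0)
    )
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    if (err >= 0.5 || err <= 1e-12) {
      if (err <= 1e-12) {
        stumps[[t]] <- fit
        alphas[t] <- 10  # perfect stump dominates
      }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[t]] <- fit
    alphas[t] <- alpha
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

.predict_adaboost <- function(fit, x) {
  df <- data.frame(x)
  if (length(fit$stumps) == 0) return(rep(0.5, nrow(df)))
  score <- rowSums(vapply(seq_along(fit$stumps), function(t) {
    p <- ifelse(predict(fit$stumps[[t]], df, type = "class") == "1",
                1, -1)
    fit$alphas[t] * p
  }, numeric(nrow(df))))
  1 / (1 + exp(-2 * score))
}

#' Fit the second layer on the meta-feature matrix
#'
#' By default an RBF-kernel SVM whose cost and gamma are chosen by
#' exhaustive grid search under internal stratified 5-fold accuracy
#' (ties resolved toward the earliest grid point). Alternative
#' second-layer learners are available for classifier-comparison
#' experiments.
#'
#' @param meta n x k meta-feature matrix from [fit_stage1()].
#' @param labels Integer 0/1 vector.
#' @param learner `"svm"` (default), `"logistic"`, `"naive_bayes"`,
#'   `"decision_tree"`, `"random_forest"` or `"adaboost"`.
#' @param grid Data frame of `cost`/`gamma` combinations searched for
#'   the SVM (default [svm_grid()]); ignored by other learners.
#' @param seed Integer seed for the internal fold draw.
#' @return A list with the fitted `model`, `learner`, `best_params`
#'   (chosen cost/gamma and internal CV accuracy) and the full `search`
#'   tibble.
#' @export
fit_stage2 <- function(meta, labels, learner = "svm",
                       grid = svm_grid(), seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(nrow(meta) == length(labels))
  meta <- as.matrix(meta)
  if (all(apply(meta, 2, function(col) diff(range(col)) < 1e-12))) {
    warning("meta-feature matrix has constant columns only; the second ",
            "layer cannot separate the classes", call. = FALSE)
  }
  search <- NULL
  best <- list(cost = NA_real_, gamma = NA_real_,
               cv_accuracy = NA_real_)
  if (learner == "svm") {
    n_folds <- min(5L, min(table(labels)))
    if (nrow(grid) == 1L || n_folds < 2L) {
      best <- list(cost = grid$cost[1], gamma = grid$gamma[1],
                   cv_accuracy = NA_real_)
      search <- tibble::tibble(cost = grid$cost, gamma = grid$gamma,
                               accuracy = NA_real_)
    } else {
      set.seed(seed)
      folds <- .stratified_folds(labels, n_folds)
      acc <- vapply(seq_len(nrow(grid)), function(g) {
        correct <- 0L
        for (f in seq_len(n_folds)) {
          hold <- folds == f
          fit <- .stage2_fit(meta[!hold, , drop = FALSE], labels[!hold],
                             "svm", cost = grid$cost[g],
                             gamma = grid$gamma[g])
          pred <- as.integer(as.character(
            predict(fit, meta[hold, , drop = FALSE])))
          correct <- correct + sum(pred == labels[hold])
        }
        correct / length(labels)
      }, numeric(1))
      search <- tibble::tibble(cost = grid$cost, gamma = grid$gamma,
                               accuracy = acc)
      g_best <- which.max(acc)  # first maximum: earliest grid point
      best <- list(cost = grid$cost[g_best], gamma = grid$gamma[g_best],
                   cv_accuracy = acc[g_best])
    }
    model <- .stage2_fit(meta, labels, "svm", cost = best$cost,
                         gamma = best$gamma)
  } else {
    set.seed(seed)
    model <- .stage2_fit(meta, labels, learner)
  }
  list(model = model, learner = learner, best_params = best,
       search = search)
}

# ---- the full stack ---------------------------------------------------

# minimum sequence length required by every encoder in a bank
.bank_min_length <- function(bank) {
  need <- vapply(seq_len(nrow(bank)), function(i) {
    p <- bank$params[[i]]
    switch(bank$encoder[i],
           kmer = p$k,
           dr = , distance_pair = 1L,
           ac = , cc = , acc = , pdt = p$dmax + 1L,
           pc_pseaac = , sc_pseaac = ,
           pc_pseaac_general = , sc_pseaac_general = p$lambda + 1L,
           top_ngram = 1L,
           pdt_profile = , dt = , ac_pssm = , cc_pssm = , acc_pssm = ,
           pssm_dt = , pssm_rt = p$dmax + 1L,
           1L)
  }, numeric(1))
  as.integer(max(need))
}

.fit_stack <- function(features, labels, bank, stage1_mode, stage2,
                       grid, threshold, seed, nrounds,
                       stage1_output = "probability") {
  s1 <- fit_stage1(features, labels, mode = stage1_mode,
                   seed = seed, nrounds = nrounds,
                   output = stage1_output)
  s2 <- fit_stage2(s1$meta, labels, learner = stage2, grid = grid,
                   seed = seed + 1L)
  structure(
    list(bank = bank, stage1 = s1$models, stage1_mode = stage1_mode,
         stage1_output = stage1_output,
         dims = vapply(features, ncol, integer(1)),
         stage2 = s2, meta = s1$meta, labels = labels,
         threshold = threshold, seed = seed, nrounds = nrounds,
         min_length = .bank_min_length(bank),
         version = .MODEL_VERSION),
    class = "pepstack"
  )
}

#' Train the stacked anticancer-peptide classifier
#'
#' Encodes the dataset with every encoder in the bank, fits one
#' gradient-boosted tree model per encoding ([fit_stage1()]), and
#' feeds the resulting k-dimensional meta-feature vectors to a
#' grid-searched second-layer classifier ([fit_stage2()]).
#'
#' @param data Labeled peptide tibble (`id`, `sequence`, `label`; a
#'   `pssm` list-column if the bank contains profile encoders).
#' @param bank An [encoder_bank()]. Default: the 19-encoder bank when a
#'   `pssm` column is present, otherwise the 11 sequence-only encoders.
#' @param stage1_mode `"in_sample"` (score training rows with the
#'   models trained on them, the stack's original construction) or
#'   `"out_of_fold"` (recommended when honest training-set
#'   meta-features matter). See [fit_stage1()].
#' @param stage2 Second-layer learner; see [fit_stage2()].
#' @param grid SVM search grid (default [svm_grid()]).
#' @param threshold Decision threshold on the stage-2 positive score.
#' @param seed Integer seed making training fully reproducible.
#' @param nrounds Boosting rounds for each stage-1 model.
#' @param stage1_output `"probability"` (default) or `"label"`; see
#'   [fit_stage1()].
#' @return An object of class `pepstack`. Use [predict.pepstack()],
#'   [generics::tidy()], [generics::glance()].
#' @export
#' @examples
#' d <- simulate_peptides(n_pos = 30, n_neg = 30, seed = 1)
#' fit <- pepstack(d, bank = encoder_bank(c("kmer", "pc_pseaac")),
#'                 seed = 1)
#' predict(fit, d[1:4, ])
pepstack <- function(data, bank = NULL,
                     stage1_mode = c("in_sample", "out_of_fold"),
                     stage2 = "svm", grid = svm_grid(),
                     threshold = 0.5, seed = 1L, nrounds = 100L,
                     stage1_output = c("probability", "label")) {
  stage1_mode <- match.arg(stage1_mode)
  stage1_output <- match.arg(stage1_output)
  data <- .as_peptide_tbl(data)
  if (!"label" %in% names(data)) {
    stop("training data must carry a 'label' column (1 = ACP)",
         call. = FALSE)
  }
  if (nrow(data) == 0) {
    stop("cannot train on an empty dataset", call. = FALSE)
  }
  if (is.null(bank)) {
    bank <- if ("pssm" %in% names(data)) encoder_bank()
            else suppressWarnings(encoder_bank(profiles = FALSE))
  }
  min_len <- .bank_min_length(bank)
  short <- nchar(data$sequence) < min_len
  if (any(short)) {
    stop("sequence(s) shorter than the bank minimum length (", min_len,
         "): ", paste(utils::head(data$id[short], 5), collapse = ", "),
         call. = FALSE)
  }
  features <- encode_with_bank(data, bank)
  .fit_stack(features, as.integer(data$label), bank, stage1_mode,
             stage2, grid, threshold, as.integer(seed),
             as.integer(nrounds), stage1_output)
}

#' Predict with a trained stacked classifier
#'
#' Encodes each record with the model's encoder bank, scores every
#' encoding with its stage-1 model, and feeds the k-vector to the
#' second layer. Records that are too short for the bank (or miss a
#' required PSSM) are not fatal: they get `NA` score with a reason, and
#' the remaining records are predicted normally.
#'
#' @param object A [pepstack()] model.
#' @param new_data Peptide tibble (or character vector of sequences).
#' @param threshold Decision threshold; defaults to the one stored in
#'   the model.
#' @param ... Unused.
#' @return A tibble in input order: `id`, `score` (positive-class
#'   score in \[0, 1\]), `label` (`"ACP"`/`"non-ACP"`), `note`
#'   (`NA` or the per-record failure reason).
#' @export
predict.pepstack <- function(object, new_data, threshold = NULL, ...) {
  new_data <- .as_peptide_tbl(new_data)
  threshold <- threshold %||% object$threshold
  n <- nrow(new_data)
  note <- rep(NA_character_, n)
  short <- nchar(new_data$sequence) < object$min_length
  note[short] <- paste0("sequence shorter than bank minimum (",
                        object$min_length, ")")
  needs_pssm <- any(object$bank$family == "profile")
  if (needs_pssm) {
    if (!"pssm" %in% names(new_data)) {
      stop("this model's bank includes profile encoders; new_data needs ",
           "a 'pssm' list-column", call. = FALSE)
    }
    no_pssm <- vapply(new_data$pssm, is.null, logical(1))
    note[no_pssm & is.na(note)] <- "missing PSSM"
  }
  ok <- is.na(note)
  score <- rep(NA_real_, n)
  if (any(ok)) {
    sub <- new_data[ok, , drop = FALSE]
    features <- encode_with_bank(sub, object$bank)
    meta <- vapply(seq_along(features), function(m) {
      .gbt_predict(object$stage1[[m]], features[[m]])
    }, numeric(nrow(sub)))
    meta <- matrix(meta, nrow = nrow(sub),
                   dimnames = list(NULL, names(features)))
    if (identical(object$stage1_output, "label")) {
      meta[] <- as.numeric(meta >= 0.5)
    }
    score[ok] <- .stage2_score(object$stage2$model,
                               object$stage2$learner, meta)
  }
  if (any(!ok)) {
    warning(sum(!ok), " record(s) could not be scored; see the 'note' ",
            "column", call. = FALSE)
  }
  tibble::tibble(
    id = new_data$id,
    score = score,
    label = ifelse(is.na(score), NA_character_,
                   ifelse(score >= threshold, "ACP", "non-ACP")),
    note = note
  )
}

#' Stage-1 meta-features for new records
#'
#' @param object A [pepstack()] model.
#' @param new_data Peptide tibble.
#' @return A tibble: `id` plus one column of stage-1 scores per
#'   encoder, in bank order.
#' @export
meta_features <- function(object, new_data) {
  stopifnot(inherits(object, "pepstack"))
  new_data <- .as_peptide_tbl(new_data)
  features <- encode_with_bank(new_data, object$bank)
  meta <- vapply(seq_along(features), function(m) {
    .gbt_predict(object$stage1[[m]], features[[m]])
  }, numeric(nrow(new_data)))
  meta <- matrix(meta, nrow = nrow(new_data),
                 dimnames = list(NULL, names(features)))
  if (identical(object$stage1_output, "label")) {
    meta[] <- as.numeric(meta >= 0.5)
  }
  dplyr::bind_cols(tibble::tibble(id = new_data$id),
                   tibble::as_tibble(meta))
}

#' @export
print.pepstack <- function(x, ...) {
  cat("Stacked peptide classifier\n")
  cat("  encoders: k =", nrow(x$bank), "(",
      paste(table(factor(x$bank$family,
                         c("composition", "autocorrelation", "pseaac",
                           "profile"))), collapse = "/"), ")\n")
  cat("  stage 1:", x$stage1_mode, "gradient-boosted trees,",
      x$nrounds, "rounds\n")
  cat("  stage 2:", x$stage2$learner)
  if (x$stage2$learner == "svm") {
    cat(sprintf(" (C = %g, gamma = %g)", x$stage2$best_params$cost,
                x$stage2$best_params$gamma))
  }
  cat("\n  trained on", length(x$labels), "peptides (",
      sum(x$labels == 1), "ACP /", sum(x$labels == 0), "non-ACP )\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-encoder summary of a trained stack
#'
#' One row per encoder: family, feature dimension, and the training
#' AUC of its meta-feature column (how well that channel alone ranks
#' the training labels).
#'
#' @param x A [pepstack()] model.
#' @param ... Unused.
#' @return A tibble with columns `encoder`, `family`, `dim`,
#'   `meta_auc`.
#' @export
tidy.pepstack <- function(x, ...) {
  dims <- x$dims
  aucs <- vapply(seq_len(ncol(x$meta)), function(m) {
    roc_auc(x$meta[, m], x$labels)
  }, numeric(1))
  tibble::tibble(encoder = x$bank$encoder, family = x$bank$family,
                 dim = unname(dims), meta_auc = aucs)
}

#' One-row summary of a trained stack
#'
#' @param x A [pepstack()] model.
#' @param ... Unused.
#' @return A tibble: `k`, `stage1_mode`, `stage2`, `cost`, `gamma`,
#'   `stage2_cv_accuracy`, `n`, `seed`.
#' @export
glance.pepstack <- function(x, ...) {
  tibble::tibble(
    k = nrow(x$bank), stage1_mode = x$stage1_mode,
    stage2 = x$stage2$learner,
    cost = x$stage2$best_params$cost,
    gamma = x$stage2$best_params$gamma,
    stage2_cv_accuracy = x$stage2$best_params$cv_accuracy,
    n = length(x$labels), seed = x$seed
  )
}

# ---- serialization ----------------------------------------------------

#' Save / load a trained stacked classifier
#'
#' Stage-1 boosters are stored in their raw serialized form so the
#' model survives package reloads; a version tag is checked on load
#' and mismatched versions are refused.
#'
#' @param object A [pepstack()] model.
#' @param path File path (`.rds`).
#' @return `save_pepstack()` returns `path` invisibly; `load_pepstack()`
#'   returns the model.
#' @export
save_pepstack <- function(object, path) {
  stopifnot(inherits(object, "pepstack"))
  object$stage1 <- lapply(object$stage1, xgboost::xgb.save.raw)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_pepstack
#' @export
load_pepstack <- function(path) {
  object <- readRDS(path)
  if (!identical(object$version, .MODEL_VERSION)) {
    stop("refusing to load model with version '", object$version,
         "' (expected '", .MODEL_VERSION, "')", call. = FALSE)
  }
  object$stage1 <- lapply(object$stage1, xgboost::xgb.load.raw)
  class(object) <- "pepstack"
  object
}
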