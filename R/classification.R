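#' Standard OMI feature sets
#'
#' `"omi+morphology"`: the ten OMI variables (NAD(P)H and FAD lifetime
#' components and fractions, intensities, redox ratio) plus area,
#' eccentricity and solidity.  `"lifetime-only"`: only the NAD(P)H and
#' FAD lifetime-derived variables.
#'
#' @param name Feature-set name.
#' @return Character vector of column names.
#' @export
omi_feature_set <- function(name = c("omi+morphology", "lifetime-only")) {
  name <- match.arg(name)
  omi <- c("nadph_tau_m", "nadph_tau1", "nadph_tau2", "nadph_alpha1_pct",
           "nadph_intensity", "fad_tau_m", "fad_tau1", "fad_tau2",
           "fad_alpha1_pct", "redox_ratio")
  lifetime <- c("nadph_tau_m", "nadph_tau1", "nadph_tau2",
                "nadph_alpha1_pct", "fad_tau_m", "fad_tau1", "fad_tau2",
                "fad_alpha1_pct")
  switch(name,
         "omi+morphology" = c(omi, "area_um2", "eccentricity", "solidity"),
         "lifetime-only" = lifetime)
}

#' Stratified train/test split
#'
#' Random split of the rows into disjoint, exhaustive train and test sets,
#' stratified so that each label's (or label-by-group stratum's) class
#' proportions are preserved to within one row.  Deterministic for a
#' fixed seed.
#'
#' @param table Data frame with a label column.
#' @param label Name of the class-label column.
#' @param train_frac Fraction of rows in the training set (0 < f < 1);
#'   default 0.7 for a 70/30 split.
#' @param seed Integer seed.
#' @param stratify_by Optional additional stratification column (e.g.
#'   donor).
#' @return List with `train` and `test` data frames; attribute `"seed"`.
#' @export
split_data <- function(table, label = "condition", train_frac = 0.7,
                       seed = 1, stratify_by = NULL) {
  if (!label %in% names(table)) stop("label column not found")
  if (train_frac <= 0 || train_frac >= 1)
    stop("'train_frac' must lie strictly between 0 and 1")
  strata <- as.character(table[[label]])
  if (!is.null(stratify_by))
    strata <- paste(strata, as.character(table[[stratify_by]]), sep = "|")
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n_tr <- round(length(idx) * train_frac)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train <- table[sort(train_idx), , drop = FALSE]
  test <- table[-sort(train_idx), , drop = FALSE]
  lv <- unique(table[[label]])
  if (!all(lv %in% train[[label]]) || !all(lv %in% test[[label]]))
    stop("a class is absent from the train or test set; ",
         "use more data or a different split fraction")
  structure(list(train = train, test = test), seed = seed,
            train_frac = train_frac)
}

#' Train the random-forest activation classifier
#'
#' Fits a random forest (500 trees by default) predicting the activation
#' label from single-cell OMI features, matching the study design where
#' the dish condition is the ground-truth label.
#'
#' @param train Training data frame.
#' @param feature_set Character vector of feature columns, or a name
#'   accepted by [omi_feature_set()].
#' @param label Name of the class-label column.
#' @param seed Integer seed.
#' @param ntree Number of trees.
#' @return A list of class `omi_classifier`: `model`
#'   (randomForest), `features`, `label`, `seed`.
#' @export
train_activation_classifier <- function(train, feature_set = "omi+morphology",
                                        label = "condition", seed = 1,
                                        ntree = 500) {
  if (length(feature_set) == 1 &&
      feature_set %in% c("omi+morphology", "lifetime-only"))
    feature_set <- omi_feature_set(feature_set)
  missing_cols <- setdiff(feature_set, names(train))
  if (length(missing_cols))
    stop("feature columns not in table: ",
         paste(missing_cols, collapse = ", "))
  X <- train[, feature_set, drop = FALSE]
  bad <- names(X)[!vapply(X, is.numeric, logical(1)) |
                    vapply(X, anyNA, logical(1))]
  if (length(bad))
    stop("non-numeric or missing values in features: ",
         paste(bad, collapse = ", "))
  y <- factor(train[[label]])
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                   importance = FALSE)
  structure(list(model = rf, features = feature_set, label = label,
                 seed = seed),
            class = "omi_classifier")
}

#' Evaluate a trained classifier on held-out cells
#'
#' Computes the ROC curve and AUC from predicted class probabilities, the
#' confusion matrix at the 0.5 probability threshold, and normalized
#' feature importances (Gini decrease, scaled to sum to 1).
#'
#' @param classifier An `omi_classifier`.
#' @param test Held-out data frame containing the feature and label
#'   columns.
#' @return A list of class `omi_classifier_report`: `auc`, `roc`
#'   (data.frame `fpr`, `tpr`, threshold-ordered), `confusion` (true x
#'   predicted counts), `importance` (named, sums to 1), `n_test`,
#'   `positive_class`.
#' @export
evaluate_classifier <- function(classifier, test) {
  y <- factor(test[[classifier$label]],
              levels = levels(classifier$model$y))
  if (nlevels(droplevels(y)) < 2)
    stop("test set contains a single class; AUC undefined")
  prob <- stats::predict(classifier$model,
                         test[, classifier$features, drop = FALSE],
                         type = "prob")
  pos <- colnames(prob)[ncol(prob)]
  roc_obj <- pROC::roc(response = y, predictor = prob[, pos],
                       levels = levels(y), direction = "<", quiet = TRUE)
  pred <- factor(ifelse(prob[, pos] >= 0.5, pos,
                        setdiff(levels(y), pos)[1]),
                 levels = levels(y))
  imp <- classifier$model$importance[, "MeanDecreaseGini"]
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(list(
    auc = as.numeric(pROC::auc(roc_obj)),
    roc = data.frame(fpr = rev(1 - roc_obj$specificities),
                     tpr = rev(roc_obj$sensitivities)),
    confusion = table(true = y, predicted = pred),
    importance = imp,
    n_test = nrow(test),
    positive_class = pos),
    class = "omi_classifier_report")
}

#' @export
print.omi_classifier_report <- function(x, ...) {
  cat(sprintf("<omi_classifier_report> AUC = %.3f (positive: %s, n = %d)\n",
              x$auc, x$positive_class, x$n_test))
  print(x$confusion)
  invisible(x)
}
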