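# Stratified k-fold cross-validation and the confusion-matrix metric set
# (accuracy, precision, recall/sensitivity, specificity, FPR, AUC), with
# per-fold and mean reporting.

#' Stratified k-fold assignment
#'
#' Every class is shuffled and dealt round-robin across the folds, so
#' per-class counts across folds differ by at most one and each round uses
#' k-1 folds for training and one for validation.
#'
#' @param labels class label per sample.
#' @param k number of folds (default 10).
#' @param seed RNG seed for the shuffles.
#' @return integer fold index (1..k) per sample, with the labels attached
#'   as an attribute.
#' @export
stratified_kfold <- function(labels, k = 10, seed = NULL) {
  labels <- as.character(labels)
  stopifnot(k >= 2)
  counts <- table(labels)
  small <- counts[counts < k]
  if (length(small)) {
    stop("class(es) with fewer members than k = ", k, ": ",
         paste(names(small), " (", small, ")", sep = "", collapse = ", "))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    offset <- 0L
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      # rotate the dealing start so residual samples spread across folds
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  })
  structure(fold, labels = labels, k = k)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("undefined ", what, " (zero denominator); reported as NA")
    return(NA_real_)
  }
  num / den
}

#' Confusion-matrix metrics
#'
#' Accuracy plus one-vs-rest per-class sensitivity (= recall), specificity,
#' precision and false-positive rate, macro- or micro-averaged over classes
#' and reported in percent. Undefined ratios (empty denominators) become NA
#' with a warning, never silent zeros.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes label vocabulary (default: union of observed labels).
#' @param average `"macro"` (unweighted class mean) or `"micro"` (pooled
#'   counts).
#' @return one-row data.frame: accuracy, precision, recall, sensitivity,
#'   specificity, fpr (all percent).
#' @export
confusion_metrics <- function(y_true, y_pred, classes = NULL,
                              average = c("macro", "micro")) {
  average <- match.arg(average)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  n <- length(y_true)
  acc <- mean(y_true == y_pred)
  tp <- fp <- tn <- fn <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp[i] <- sum(y_true == cl & y_pred == cl)
    fp[i] <- sum(y_true != cl & y_pred == cl)
    fn[i] <- sum(y_true == cl & y_pred != cl)
    tn[i] <- n - tp[i] - fp[i] - fn[i]
  }
  if (average == "macro") {
    sens <- mean(mapply(safe_ratio, tp, tp + fn,
                        MoreArgs = list(what = "sensitivity")))
    spec <- mean(mapply(safe_ratio, tn, tn + fp,
                        MoreArgs = list(what = "specificity")))
    prec <- mean(mapply(safe_ratio, tp, tp + fp,
                        MoreArgs = list(what = "precision")))
    fpr <- mean(mapply(safe_ratio, fp, fp + tn,
                       MoreArgs = list(what = "FPR")))
  } else {
    sens <- safe_ratio(sum(tp), sum(tp + fn), "sensitivity")
    spec <- safe_ratio(sum(tn), sum(tn + fp), "specificity")
    prec <- safe_ratio(sum(tp), sum(tp + fp), "precision")
    fpr <- safe_ratio(sum(fp), sum(fp + tn), "FPR")
  }
  data.frame(accuracy = 100 * acc, precision = 100 * prec,
             recall = 100 * sens, sensitivity = 100 * sens,
             specificity = 100 * spec, fpr = 100 * fpr)
}

#' Area under the ROC curve (rank / Mann-Whitney form)
#'
#' Probability that a positive outscores a negative, ties counted half
#' (midranks). Multiclass input with a score matrix is macro-averaged
#' one-vs-rest.
#'
#' @param y_true labels; binary, or multiclass with a score matrix.
#' @param scores numeric score vector (binary) or samples x classes matrix
#'   with named columns.
#' @param positive the positive label for the binary case (default: the
#'   larger level).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y_true, scores, positive = NULL) {
  y_true <- as.character(y_true)
  if (is.matrix(scores)) {
    classes <- colnames(scores)
    if (is.null(classes)) stop("multiclass scores need column names")
    present <- classes[classes %in% y_true]
    if (length(present) < 2) stop("need at least two observed classes")
    vals <- vapply(present, function(cl) {
      auc(ifelse(y_true == cl, "pos", "neg"), scores[, cl],
          positive = "pos")
    }, numeric(1))
    return(mean(vals))
  }
  classes <- sort(unique(y_true))
  if (length(classes) != 2) {
    stop("binary AUC needs exactly two observed classes, got ",
         length(classes))
  }
  if (is.null(positive)) positive <- classes[2]
  pos <- y_true == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores)  # midranks for ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated training and evaluation of the stage classifier
#'
#' Stratified k-fold rotation: for every fold one model is trained from
#' scratch on the other k-1 folds (`epochs_per_fold` epochs each, so the
#' default 10 x 15 accounts 150 training epochs overall) and evaluated on
#' the held-out fold. Reports one metric row per fold plus their arithmetic
#' mean, in percent.
#'
#' @param x input array (H, W, depth, N).
#' @param labels class label per sample.
#' @param config an [mcnn_config()] (its `n_classes` must cover the labels).
#' @param k folds (default 10).
#' @param seed seed controlling fold assignment and per-fold training.
#' @param epochs_per_fold training epochs per fold (default 15).
#' @param fold_modality optional per-fold annotation tags (bookkeeping
#'   only, e.g. which folds held PET cases), recycled to k.
#' @param verbose print per-fold progress.
#' @return object of class `metrics_report`: `folds` data.frame (one row
#'   per fold + mean row), `fold_assignment`, `total_epochs`, `history`
#'   per fold.
#' @export
cross_validate <- function(x, labels, config, k = 10, seed = 1L,
                           epochs_per_fold = 15L, fold_modality = NULL,
                           verbose = FALSE) {
  labels <- as.character(labels)
  stopifnot(length(labels) == dim(x)[4])
  seeds <- derive_seeds(seed, k + 1L)
  fold <- stratified_kfold(labels, k = k, seed = seeds[k + 1L])
  classes <- sort(unique(labels))
  if (length(classes) > config$n_classes) {
    stop("labels carry ", length(classes), " classes but the model is ",
         "configured for ", config$n_classes)
  }
  rows <- vector("list", k)
  histories <- vector("list", k)
  total_epochs <- 0L
  auc_vals <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    cfg <- config
    cfg$seed <- seeds[f]
    model <- build_mcnn(cfg, class_labels =
                          c(classes, rep("", cfg$n_classes -
                                           length(classes))))
    model <- train_mcnn(model, x[, , , tr, drop = FALSE], labels[tr],
                        x_val = x[, , , !tr, drop = FALSE],
                        y_val = labels[!tr],
                        epochs = epochs_per_fold)
    pr <- predict(model, x[, , , !tr, drop = FALSE])
    met <- confusion_metrics(labels[!tr], pr$class, classes = classes)
    auc_vals[f] <- 100 * auc(labels[!tr],
                             pr$probabilities[, classes, drop = FALSE])
    met$auc <- auc_vals[f]
    rows[[f]] <- cbind(data.frame(fold = as.character(f)), met)
    histories[[f]] <- model$history
    total_epochs <- total_epochs + model$trained_epochs
    if (verbose) {
      message(sprintf("fold %2d: accuracy %.1f%%", f, met$accuracy))
    }
  }
  folds <- do.call(rbind, rows)
  mean_row <- cbind(data.frame(fold = "mean"),
                    as.data.frame(t(colMeans(folds[, -1]))))
  report <- structure(list(folds = rbind(folds, mean_row),
                           fold_assignment = fold,
                           fold_modality = if (!is.null(fold_modality))
                             rep_len(fold_modality, k) else NULL,
                           total_epochs = total_epochs,
                           histories = histories, k = k, seed = seed),
                      class = "metrics_report")
  report
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(format_metrics_table(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Format a metrics report as a fixed-width table
#'
#' Folds 1..k followed by the mean row, metrics in percent.
#'
#' @param report a `metrics_report`.
#' @param digits decimal places.
#' @export
format_metrics_table <- function(report, digits = 2) {
  df <- report$folds
  num <- vapply(df[-1], function(col) formatC(col, format = "f",
                                              digits = digits, width = 9),
                character(nrow(df)))
  header <- c(sprintf("%-8s", "fold"),
              sprintf("%9s", names(df)[-1]))
  body <- apply(cbind(sprintf("%-8s", ifelse(df$fold == "mean",
                                             "Mean value", df$fold)),
                      num), 1, paste, collapse = " ")
  c(paste(header, collapse = " "), body)
}

#' Write a metrics report (and optional ROC points) as CSV
#'
#' @param report a `metrics_report`.
#' @param path CSV path for the fold table.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report$folds, path, row.names = FALSE)
  invisible(path)
}
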