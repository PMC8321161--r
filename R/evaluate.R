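#' Classification metrics
#'
#' Accuracy, per-class precision/recall/F1, macro F1 and the confusion matrix
#' for a multi-class prediction. Precision is the fraction of predicted
#' positives that are true positives; recall the fraction of actual positives
#' recovered; F1 their harmonic mean. Classes absent from both truth and
#' prediction contribute 0 to the macro average and are flagged.
#'
#' @param truth,predicted equal-length label vectors.
#' @param class_names label universe; defaults to the union of observed labels.
#' @param average `"macro"` (unweighted class mean) or `"weighted"`
#'   (support-weighted).
#' @return list with `accuracy`, `per_class` data.frame, `f1` (averaged),
#'   `confusion` matrix (rows = truth), `absent_classes`.
#' @export
compute_metrics <- function(truth, predicted,
                            class_names = sort(unique(c(truth, predicted))),
                            average = c("macro", "weighted")) {
  average <- match.arg(average)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  truth <- factor(as.character(truth), levels = class_names)
  predicted <- factor(as.character(predicted), levels = class_names)
  if (anyNA(truth) || anyNA(predicted))
    stop("labels outside class_names")
  confusion <- table(truth = truth, predicted = predicted)
  tp <- diag(confusion)
  support <- rowSums(confusion)
  pred_n <- colSums(confusion)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  absent <- class_names[support == 0 & pred_n == 0]
  w <- if (average == "macro") rep(1 / length(class_names), length(class_names))
       else support / sum(support)
  list(accuracy = sum(tp) / length(truth),
       per_class = data.frame(class = class_names,
                              precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = as.numeric(f1),
                              support = as.integer(support),
                              row.names = NULL),
       f1 = sum(w * f1),
       average = average,
       confusion = confusion,
       absent_classes = absent)
}

feature_columns <- function(features) {
  grep("^[dg]_\\d+$", names(features), value = TRUE)
}

fit_svm <- function(x, y, config) {
  e1071::svm(x = x, y = factor(y, levels = config$class_names),
             kernel = config$kernel, cost = config$cost, scale = FALSE)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject in turn, all of that subject's samples form the held-out
#' fold; a feature normalizer and an SVM are fitted on the remaining subjects'
#' samples, and the held-out samples are predicted. Predictions are pooled
#' over folds before computing accuracy, F1 and the confusion matrix, so
#' subjects with unequal sample counts are weighted by their samples.
#'
#' @param features feature table from [extract_feature_matrix()] (metadata
#'   columns `subject_id`, `label` plus `d_*`/`g_*` feature columns).
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost SVM regularization constant C (default 1).
#' @param normalization `"minmax"` or `"zscore"`, fitted per fold on the
#'   training rows only.
#' @param f1_average `"macro"` or `"weighted"`.
#' @return object of class `losocv_report`: pooled `accuracy`, `f1`,
#'   `confusion`, `per_class`, per-fold detail in `folds`, `warnings`, and a
#'   `config` echo.
#' @export
losocv <- function(features, kernel = "linear", cost = 1,
                   normalization = c("minmax", "zscore"),
                   f1_average = c("macro", "weighted")) {
  normalization <- match.arg(normalization)
  f1_average <- match.arg(f1_average)
  subjects <- unique(features$subject_id)
  if (length(subjects) < 2L)
    stop("LOSOCV requires at least 2 subjects")
  class_names <- sort(unique(features$label))
  fcols <- feature_columns(features)
  if (!length(fcols)) stop("no feature columns (d_*/g_*) found")
  x_all <- as.matrix(features[, fcols])
  config <- list(kernel = kernel, cost = cost, normalization = normalization,
                 f1_average = f1_average, class_names = class_names)

  warnings <- character(0)
  folds <- lapply(subjects, function(subj) {
    test_rows <- features$subject_id == subj
    x_train <- x_all[!test_rows, , drop = FALSE]
    y_train <- features$label[!test_rows]
    missing_cls <- setdiff(class_names, unique(y_train))
    if (length(missing_cls))
      warnings <<- c(warnings, sprintf(
        "fold %s: training data missing class(es) %s",
        subj, paste(missing_cls, collapse = ", ")))
    norm <- fit_normalizer(x_train, method = normalization)
    model <- fit_svm(predict(norm, x_train), y_train, config)
    pred <- predict(model, predict(norm, x_all[test_rows, , drop = FALSE]))
    list(subject = subj,
         truth = features$label[test_rows],
         predicted = as.character(pred),
         normalizer = norm)
  })

  truth <- unlist(lapply(folds, `[[`, "truth"))
  predicted <- unlist(lapply(folds, `[[`, "predicted"))
  m <- compute_metrics(truth, predicted, class_names, average = f1_average)
  structure(list(accuracy = m$accuracy, f1 = m$f1,
                 per_class = m$per_class, confusion = m$confusion,
                 folds = folds, n_samples = length(truth),
                 warnings = warnings, config = config),
            class = "losocv_report")
}

#' @export
print.losocv_report <- function(x, ...) {
  cat(sprintf("<losocv_report> %d folds, %d pooled samples\n",
              length(x$folds), x$n_samples))
  cat(sprintf("  accuracy: %.4f   F1 (%s): %.4f\n",
              x$accuracy, x$config$f1_average, x$f1))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report a `losocv_report`.
#' @param path output JSON path; the confusion matrix is embedded and also
#'   written as `<path>.confusion.tsv`.
#' @export
write_report <- function(report, path) {
  out <- list(accuracy = report$accuracy,
              f1 = report$f1,
              n_samples = report$n_samples,
              per_class = report$per_class,
              confusion = as.data.frame.matrix(report$confusion),
              warnings = report$warnings,
              config = report$config[c("kernel", "cost", "normalization",
                                       "f1_average")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(as.data.frame.matrix(report$confusion),
                     paste0(path, ".confusion.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Run the full single-frame recognition pipeline
#'
#' Chains sampling, feature extraction and LOSOCV evaluation: restructure the
#' landmark table under a sampling scheme, extract distance/gradient features
#' on the chosen graph, and evaluate with a subject-held-out SVM.
#'
#' @param tab landmark table of labelled video sequences.
#' @param scheme sampling scheme, see [restructure()].
#' @param graph a `segment_graph`, or `"facs"`/`"full"` to build the default.
#' @param ... passed to [losocv()].
#' @return a `losocv_report`.
#' @export
run_pipeline <- function(tab, scheme = "mid", graph = "facs", ...) {
  if (is.character(graph))
    graph <- switch(match.arg(graph, c("facs", "full")),
                    facs = build_facs_graph(),
                    full = build_full_face_graph())
  samples <- restructure(tab, scheme)
  features <- extract_feature_matrix(samples$samples, graph)
  losocv(features, ...)
}
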