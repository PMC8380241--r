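#' Cross-validation confusion matrix
#'
#' Counts human-truth versus network-output label pairs. Internal
#' orientation: rows are the human/truth classes, columns the network
#' output classes (displays may transpose; the stored orientation is what
#' the metric functions assume).
#'
#' @param truth human/ground-truth labels.
#' @param predicted network output labels, same length.
#' @param taxonomy class labels fixing row/column order.
#' @return object of class `confusion_matrix`: integer matrix with
#'   attribute `n_total`.
#' @export
confusion_matrix <- function(truth, predicted, taxonomy = PHENOTYPE_CLASSES) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  assert_phenotype(truth, taxonomy)
  assert_phenotype(predicted, taxonomy)
  tab <- table(factor(truth, levels = taxonomy),
               factor(predicted, levels = taxonomy))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(truth = taxonomy, predicted = taxonomy))
  structure(m, n_total = length(truth), class = c("confusion_matrix", "matrix"))
}

#' Per-class precision, FDR, sensitivity and FNR
#'
#' For each class c: precision = 100 * TP / (TP + FP) (of everything the
#' network called c, how much was c), sensitivity = 100 * TP / (TP + FN)
#' (of everything truly c, how much the network found), with the false
#' discovery and false negative rates as their complements to 100. A class
#' never predicted has undefined precision (NA, not 0); a class with no
#' true members has undefined sensitivity.
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with one row per class: precision, false_discovery_rate,
#'   sensitivity, false_negative_rate (percent; NA where undefined).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- diag(cm)
  pred_tot <- colSums(cm)   # TP + FP
  true_tot <- rowSums(cm)   # TP + FN
  precision <- ifelse(pred_tot > 0, 100 * tp / pred_tot, NA_real_)
  sensitivity <- ifelse(true_tot > 0, 100 * tp / true_tot, NA_real_)
  data.frame(class = rownames(cm), precision = precision,
             false_discovery_rate = 100 - precision,
             sensitivity = sensitivity,
             false_negative_rate = 100 - sensitivity,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall accuracy and misclassification rate
#'
#' @param cm a [confusion_matrix()].
#' @return list(accuracy, misclassification), in percent.
#' @export
overall_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- attr(cm, "n_total")
  if (is.null(n) || n == 0) stop("empty confusion matrix")
  acc <- 100 * sum(diag(cm)) / n
  list(accuracy = acc, misclassification = 100 - acc)
}

#' Render a confusion-matrix report
#'
#' Machine-readable long-format report: the 9x9 counts plus per-class and
#' overall metrics, percentages to one decimal place.
#'
#' @param cm a [confusion_matrix()].
#' @param transpose display with human scores horizontal (the published
#'   figure orientation) instead of the internal rows-are-truth layout.
#' @return data.frame report; printing is side-effect free.
#' @export
render_confusion_report <- function(cm, transpose = FALSE) {
  pc <- per_class_metrics(cm)
  ov <- overall_metrics(cm)
  counts <- if (transpose) t(unclass(cm)) else unclass(cm)
  long <- as.data.frame(as.table(counts), stringsAsFactors = FALSE)
  names(long) <- c(if (transpose) c("predicted", "truth") else
                   c("truth", "predicted"), "count")
  list(counts = counts, long = long,
       per_class = transform(pc,
                             precision = round(precision, 1),
                             false_discovery_rate = round(false_discovery_rate, 1),
                             sensitivity = round(sensitivity, 1),
                             false_negative_rate = round(false_negative_rate, 1)),
       overall = lapply(ov, round, 1))
}

#' Stratified train/test split
#'
#' Randomly assigns records to training and unseen testing groups (the
#' published design uses 60%/40%). With stratification the split is drawn
#' independently within each class so per-class proportions match the
#' target within one record; classes with fewer than 2 records go to the
#' training set with a warning.
#'
#' @param records list (or vector/data.frame) of records.
#' @param labels class labels used for stratification (required when
#'   `stratify`).
#' @param fraction training fraction in (0, 1).
#' @param stratify logical.
#' @param seed integer seed.
#' @return list(train = indices, test = indices): a disjoint, exhaustive
#'   partition of `seq_along(labels)`.
#' @export
split_train_test <- function(records = NULL, labels = NULL, fraction = 0.60,
                             stratify = TRUE, seed = 1L) {
  if (is.null(labels)) {
    if (is.list(records) && !is.null(records[[1]]$label))
      labels <- vapply(records, function(r) r$label, character(1))
    else stop("labels required")
  }
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0,1)")
  n <- length(labels)
  withr_seed(seed, {
    if (!stratify) {
      n_train <- round(fraction * n)
      train <- sort(sample.int(n, n_train))
    } else {
      train <- integer(0)
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < 2L) {
          warning("class '", cl, "' has < 2 records; assigned to train")
          train <- c(train, idx)
        } else {
          k <- round(fraction * length(idx))
          k <- min(max(k, 1L), length(idx) - 1L)  # keep both sides non-empty
          train <- c(train, sample(idx, k))
        }
      }
      train <- sort(train)
    }
  })
  list(train = train, test = setdiff(seq_len(n), train))
}
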