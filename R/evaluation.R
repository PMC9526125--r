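#' Token-level extraction metrics
#'
#' Computes per-measurement precision, recall and F1 over aligned per-token
#' predicted and gold label vectors, and their unweighted (macro) mean over
#' measurement labels — the null label never enters the average, and labels
#' absent from both gold and predictions are excluded (set
#' `include_absent = TRUE` to count them as zero instead). Macro averaging
#' makes the score insensitive to how often each measurement occurs.
#'
#' @param predicted,gold Character vectors of token labels, same length.
#' @param schema A `cmr_schema`.
#' @param include_absent Count labels missing from both sides as F1 = 0.
#' @return A `cmr_eval` object: `per_label` tibble (`label`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `support`), `macro_f1`, `n_tokens`.
#' @export
evaluate_tokens <- function(predicted, gold, schema, include_absent = FALSE) {
  if (length(predicted) != length(gold)) {
    abort(sprintf("prediction/gold length mismatch: %d vs %d", length(predicted), length(gold)))
  }
  labels <- schema$measurement_types$label
  counts <- label_confusion(predicted, gold, labels)
  per <- counts %>%
    mutate(precision = ifelse(.data$tp + .data$fp == 0, 0, .data$tp / (.data$tp + .data$fp)),
           recall = ifelse(.data$tp + .data$fn == 0, 0, .data$tp / (.data$tp + .data$fn)),
           f1 = ifelse(2 * .data$tp + .data$fp + .data$fn == 0, 0,
                       2 * .data$tp / (2 * .data$tp + .data$fp + .data$fn)),
           support = .data$tp + .data$fn)
  active <- per$support > 0 | per$tp + per$fp > 0
  used <- if (include_absent) per else per[active, ]
  macro <- if (nrow(used)) mean(used$f1) else NA_real_
  structure(list(per_label = per, macro_f1 = macro, n_tokens = length(gold),
                 included_labels = used$label),
            class = "cmr_eval")
}

label_confusion <- function(predicted, gold, labels) {
  purrr::map(labels, function(lab) {
    tibble(label = lab,
           tp = sum(predicted == lab & gold == lab),
           fp = sum(predicted == lab & gold != lab),
           fn = sum(predicted != lab & gold == lab))
  }) %>% bind_rows()
}

#' @export
print.cmr_eval <- function(x, ...) {
  cat(sprintf("<cmr_eval> macro-F1 %.4f over %d labels (%d tokens)\n",
              x$macro_f1, length(x$included_labels), x$n_tokens))
  print(x$per_label, ...)
  invisible(x)
}

#' @export
tidy.cmr_eval <- function(x, ...) x$per_label

#' @export
glance.cmr_eval <- function(x, ...) {
  tibble(macro_f1 = x$macro_f1, n_labels = length(x$included_labels),
         n_tokens = x$n_tokens)
}

#' Bootstrap confidence interval for macro-F1
#'
#' Percentile bootstrap resampling whole reports with replacement (reports,
#' not tokens, are the sampling unit, respecting within-report correlation of
#' token labels). Deterministic given the seed.
#'
#' @param predicted,gold Aligned token label vectors.
#' @param report_ids Report id per token (grouping for the resample).
#' @param schema A `cmr_schema`.
#' @param B Number of bootstrap resamples.
#' @param seed Seed.
#' @param conf Confidence level.
#' @return List `lo`, `hi`, `point`, `B`.
#' @export
bootstrap_macro_f1 <- function(predicted, gold, report_ids, schema, B = 1000L,
                               seed = 1L, conf = 0.95) {
  stopifnot(length(predicted) == length(gold), length(gold) == length(report_ids))
  labels <- schema$measurement_types$label
  rids <- unique(report_ids)
  if (length(rids) == 1) warn("single report: bootstrap interval is degenerate")
  # per-report confusion counts, then resample by summing counts
  arr <- array(0L, dim = c(length(rids), length(labels), 3),
               dimnames = list(rids, labels, c("tp", "fp", "fn")))
  for (r in seq_along(rids)) {
    sel <- report_ids == rids[r]
    cc <- label_confusion(predicted[sel], gold[sel], labels)
    arr[r, , ] <- as.matrix(cc[, c("tp", "fp", "fn")])
  }
  macro_from_counts <- function(tp, fp, fn) {
    f1 <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
    active <- (tp + fn) > 0 | (tp + fp) > 0
    if (!any(active)) return(NA_real_)
    mean(f1[active])
  }
  point <- macro_from_counts(colSums(arr[, , 1, drop = FALSE]),
                             colSums(arr[, , 2, drop = FALSE]),
                             colSums(arr[, , 3, drop = FALSE]))
  stats <- with_seed(seed, {
    purrr::map_dbl(seq_len(B), function(b) {
      take <- sample.int(length(rids), replace = TRUE)
      tp <- colSums(arr[take, , 1, drop = FALSE])
      fp <- colSums(arr[take, , 2, drop = FALSE])
      fn <- colSums(arr[take, , 3, drop = FALSE])
      macro_from_counts(tp, fp, fn)
    })
  })
  qs <- quantile(stats, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE, names = FALSE)
  list(lo = qs[1], hi = qs[2], point = point, B = B)
}

#' One-vs-rest ROC curves per measurement
#'
#' For each measurement label, treats its per-token score column as the
#' predictor of whether the token carries that gold label, and computes the
#' ROC curve and AUC (via pROC). Labels without gold positives (or without
#' negatives) have no defined AUC and are reported as missing.
#'
#' @param scores Token score matrix with label column names.
#' @param gold Gold token labels (length `nrow(scores)`).
#' @param schema A `cmr_schema`.
#' @return A `cmr_roc` object: `per_label` tibble (`label`, `auc`, `n_pos`)
#'   and `curves` (tibble `label`, `fpr`, `tpr`).
#' @export
roc_per_label <- function(scores, gold, schema) {
  if (!requireNamespace("pROC", quietly = TRUE)) abort("roc_per_label() needs the pROC package")
  labels <- schema$measurement_types$label
  per <- list(); curves <- list()
  for (lab in labels) {
    y <- as.integer(gold == lab)
    n_pos <- sum(y)
    if (n_pos == 0 || n_pos == length(y) || !lab %in% colnames(scores)) {
      per[[lab]] <- tibble(label = lab, auc = NA_real_, n_pos = n_pos)
      next
    }
    r <- pROC::roc(response = y, predictor = scores[, lab], quiet = TRUE,
                   direction = "<", levels = c(0, 1))
    per[[lab]] <- tibble(label = lab, auc = as.numeric(pROC::auc(r)), n_pos = n_pos)
    curves[[lab]] <- tibble(label = lab, fpr = rev(1 - r$specificities),
                            tpr = rev(r$sensitivities))
  }
  structure(list(per_label = bind_rows(per), curves = bind_rows(curves)),
            class = "cmr_roc")
}

#' @export
print.cmr_roc <- function(x, ...) {
  cat("<cmr_roc> per-measurement one-vs-rest AUC\n")
  print(x$per_label, ...)
  invisible(x)
}

#' @export
tidy.cmr_roc <- function(x, ...) x$per_label

#' Annotation-efficiency learning curve
#'
#' Trains one model per training-set size on nested subsets of the training
#' reports (smaller subsets are contained in larger ones, drawn once per seed)
#' and reports the maximum macro-F1 over epochs on a fixed evaluation set —
#' how extraction quality grows with labeling effort. The tokenizer vocabulary
#' is built once from the full (unlabeled) training text.
#'
#' @param reports,annotations Training corpus.
#' @param eval_reports,eval_annotations Fixed evaluation corpus.
#' @param sizes Increasing vector of training-set sizes (reports).
#' @param schema A `cmr_schema`.
#' @param config A [train_config()].
#' @param repr_mode Numerical representation mode.
#' @param seed Seed for the nested subset draw.
#' @return A `cmr_learning_curve`: tibble `size`, `macro_f1`, `best_epoch`.
#' @export
learning_curve <- function(reports, annotations, eval_reports, eval_annotations,
                           sizes, schema = default_schema(),
                           config = train_config(), repr_mode = "original",
                           seed = 1L) {
  if (any(sizes < 1)) abort("training-set sizes must be >= 1")
  if (any(sizes > nrow(reports))) abort("size exceeds corpus size")
  sizes <- sort(unique(as.integer(sizes)))
  ord <- with_seed(seed, sample(nrow(reports)))  # nested subsets: prefixes
  tr <- transform_corpus(reports, annotations, repr_mode)
  ev <- transform_corpus(eval_reports, eval_annotations, repr_mode)
  tokenizer <- build_tokenizer(tr$reports$text)
  eval_windows <- corpus_windows(ev$reports, ev$annotations, tokenizer, schema,
                                 max_len = config$encoder$max_len)
  rows <- purrr::map(sizes, function(sz) {
    sub <- ord[seq_len(sz)]
    tw <- corpus_windows(tr$reports[sub, ], tr$annotations, tokenizer, schema,
                         max_len = config$encoder$max_len)
    model <- train_extractor(tw, schema, tokenizer, config, dev_windows = eval_windows)
    tibble(size = sz,
           macro_f1 = max(model$history$dev_macro_f1, na.rm = TRUE),
           best_epoch = model$best_epoch)
  })
  structure(list(curve = bind_rows(rows), sizes = sizes, seed = seed),
            class = "cmr_learning_curve")
}

#' @export
print.cmr_learning_curve <- function(x, ...) {
  cat("<cmr_learning_curve>\n")
  print(x$curve, ...)
  invisible(x)
}

#' @export
tidy.cmr_learning_curve <- function(x, ...) x$curve
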