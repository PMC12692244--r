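#' Confusion counts
#'
#' K x K confusion matrix plus the per-class one-vs-rest TP/FP/FN/TN counts
#' derived from it.
#'
#' @param truth,predicted label vectors of equal length, members of
#'   `classes`.
#' @param classes class order.
#' @return List of class `confusion_counts` with `matrix` (truth in rows)
#'   and `per_class` (data frame of TP/FP/FN/TN).
#' @export
confusion_counts <- function(truth, predicted, classes = sort(unique(c(truth, predicted)))) {
  if (length(truth) != length(predicted)) stop("length mismatch")
  ti <- match(truth, classes); pi <- match(predicted, classes)
  if (anyNA(ti) || anyNA(pi)) stop("labels outside the class set")
  K <- length(classes)
  m <- matrix(0L, K, K, dimnames = list(truth = classes, predicted = classes))
  for (i in seq_along(ti)) m[ti[i], pi[i]] <- m[ti[i], pi[i]] + 1L
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- sum(m) - tp - fp - fn
  structure(list(matrix = m,
                 per_class = data.frame(class = classes, TP = tp, FP = fp,
                                        FN = fn, TN = tn, row.names = NULL)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Overall accuracy on the pooled counts, per-class precision, recall and
#' F1 (one-vs-rest), and their macro (unweighted class mean) averages.
#' Classes with a zero denominator get metric 0 and are flagged.
#'
#' @param counts a [confusion_counts()].
#' @return List of class `eval_report` with `accuracy`, `per_class` (data
#'   frame), `macro` (named vector), and `flagged` classes.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  pc <- counts$per_class
  n <- sum(counts$matrix)
  if (n == 0) stop("empty input")
  safe <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe(pc$TP, pc$TP + pc$FP)
  recall <- safe(pc$TP, pc$TP + pc$FN)
  f1 <- safe(2 * precision * recall, precision + recall)
  flagged <- pc$class[(pc$TP + pc$FP) == 0 | (pc$TP + pc$FN) == 0 |
                        (precision + recall) == 0]
  structure(list(
    accuracy = sum(diag(counts$matrix)) / n,
    per_class = data.frame(class = pc$class, precision = precision,
                           recall = recall, f1 = f1, row.names = NULL),
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    flagged = as.character(flagged), n = n
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.4f, macro F1 = %.4f\n",
              x$n, x$accuracy, x$macro["f1"]))
  invisible(x)
}

#' Sliced evaluation of a trained network
#'
#' The two slicings drift studies report: `by_day` reports the variety task restricted to
#' each storage day's test scans; `by_variety` reports the storage-period
#' task restricted to each variety's test scans. A pooled report over all
#' test scans is included.
#'
#' @param network a trained [fit_network()] network (with class orders and
#'   band indices attached).
#' @param table test [spectra_table()], disjoint (by egg) from training.
#' @param slicing `"by_day"` or `"by_variety"`.
#' @return List with `pooled` (an `eval_report`) and `slices` (named list of
#'   `eval_report`s keyed by day or variety).
#' @export
evaluate_sliced <- function(network, table, slicing = c("by_day", "by_variety")) {
  slicing <- match.arg(slicing)
  stopifnot(inherits(network, "ctse_net"), inherits(table, "spectra_table"))
  if (is.null(network$bands)) stop("network has not been trained on a band set")
  fl <- variant_flags(network$variant)
  if (slicing == "by_day" && !fl$task1) stop("variant lacks the variety head")
  if (slicing == "by_variety" && !fl$task2) stop("variant lacks the period head")
  pr <- predict(network, table$reflectance[, network$bands, drop = FALSE])
  if (slicing == "by_day") {
    truth <- table$variety
    pred <- network$classes1[pr$pred1]
    classes <- network$classes1
    key <- table$day
  } else {
    truth <- as.character(table$day)
    pred <- as.character(network$classes2[pr$pred2])
    classes <- as.character(network$classes2)
    key <- table$variety
  }
  slices <- list()
  for (k in sort(unique(key))) {
    idx <- key == k
    if (!any(idx)) stop("empty slice: ", k)
    slices[[as.character(k)]] <-
      classification_metrics(confusion_counts(truth[idx], pred[idx], classes))
  }
  list(pooled = classification_metrics(confusion_counts(truth, pred, classes)),
       slices = slices)
}

#' Tabulate sliced evaluations across runs
#'
#' Binds per-run sliced evaluations into one long data frame and summarises
#' accuracy and macro F1 per variant and slice as mean and sd over run
#' seeds — the layout of the model-comparison and ablation tables.
#'
#' @param runs list of runs; each a list with fields `variant`, `seed` and
#'   `eval` (the result of [evaluate_sliced()]).
#' @return List with `per_run` and `summary` data frames.
#' @export
compare_runs <- function(runs) {
  if (length(runs) < 1) stop("no runs supplied")
  rows <- list()
  for (r in runs) {
    sl <- c(list(pooled = r$eval$pooled), r$eval$slices)
    for (nm in names(sl)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = r$variant, seed = r$seed, slice = nm,
        accuracy = sl[[nm]]$accuracy, f1 = unname(sl[[nm]]$macro["f1"]))
    }
  }
  per_run <- do.call(rbind, rows)
  agg <- function(x) c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0)
  sp <- split(per_run, list(per_run$variant, per_run$slice), drop = TRUE)
  summary <- do.call(rbind, lapply(sp, function(g) {
    a <- agg(g$accuracy); f <- agg(g$f1)
    data.frame(variant = g$variant[1], slice = g$slice[1], n_seeds = nrow(g),
               accuracy_mean = a["mean"], accuracy_sd = a["sd"],
               f1_mean = f["mean"], f1_sd = f["sd"], row.names = NULL)
  }))
  rownames(summary) <- NULL
  list(per_run = per_run, summary = summary[order(summary$slice, summary$variant), ])
}
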