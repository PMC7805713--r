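# Evaluation protocol: weighted metrics, per-subject personalized models,
# TD/ASD group and combined models, repeated random 80/20 splits, and
# summary tables.

#' Class-support-weighted classification metrics
#'
#' Computes the 7-class confusion matrix, per-class precision, recall and F1,
#' and their averages weighted by true-class support — the convention used to
#' counter the strong imbalance in engagement levels. The support-weighted
#' mean of per-class recall ("weighted accuracy") algebraically equals plain
#' accuracy; both names are reported.
#'
#' @param y_true,y_pred equal-length integer vectors of classes 0-6.
#' @return list with `accuracy`, `f1` (weighted), `per_class` (data frame of
#'   support/precision/recall/f1 per class) and `confusion` (7 x 7 table,
#'   true classes in rows).
#' @export
weighted_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must be non-empty and of equal length")
  }
  stopifnot(all(y_true %in% 0:6), all(y_pred %in% 0:6))
  conf <- table(true = factor(y_true, levels = 0:6),
                pred = factor(y_pred, levels = 0:6))
  tp <- diag(conf)
  support <- rowSums(conf)
  predn <- colSums(conf)
  recall <- ifelse(support > 0, tp / support, 0)
  precision <- ifelse(predn > 0, tp / predn, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  # support-weighted recall collapses to plain accuracy; computed as such
  wacc <- sum(tp) / sum(support)
  wf1 <- sum(f1 * support) / sum(support)
  list(accuracy = wacc, f1 = wf1,
       per_class = data.frame(class = 0:6, support = as.integer(support),
                              precision = precision, recall = recall, f1 = f1),
       confusion = conf)
}

eval_split_metrics <- function(model, parts) {
  m_of <- function(ds) {
    if (length(ds) == 0) return(list(acc = NA_real_, f1 = NA_real_))
    p <- predict(model, ds)
    wm <- weighted_metrics(ds$y, p)
    list(acc = wm$accuracy, f1 = wm$f1)
  }
  tr <- m_of(parts$train); va <- m_of(parts$validation); te <- m_of(parts$test)
  losses <- c(NA_real_, NA_real_)
  if (model$kind == "cnn" && !is.null(model$history)) {
    h <- model$history
    best <- which.min(if (all(is.na(h$val_loss))) h$train_loss else h$val_loss)
    losses <- c(h$train_loss[best], h$val_loss[best])
  }
  data.frame(train_accuracy = tr$acc, train_loss = losses[1],
             val_accuracy = va$acc, val_loss = losses[2],
             test_accuracy = te$acc, test_f1 = te$f1)
}

#' Evaluate classifiers on one subject's dataset
#'
#' Repeats `reps` random train/validation/test splits (default fractions
#' 0.8/0.2 with 10% of the train windows as validation), fits each requested
#' classifier kind on each split, and reports the mean weighted metrics per
#' kind. Fresh seeds (`seed`, `seed + 1`, ...) are drawn per repetition and
#' logged. Per-repetition rows and the index partitions of every split are
#' attached as attributes `"per_rep"` and `"partitions"` for audits.
#'
#' @param dataset a `windowed_dataset` from a single subject.
#' @param kinds classifier kinds to evaluate.
#' @param reps number of repeated splits.
#' @param seed base integer seed.
#' @param test_fraction,val_fraction split fractions.
#' @param epochs optional CNN epoch override.
#' @param spec optional [cnn_spec()] override.
#' @return data frame of class `eval_report`, one row per kind.
#' @export
evaluate_subject <- function(dataset, kinds = MODEL_KINDS, reps = 10, seed = 1,
                             test_fraction = 0.2, val_fraction = 0.1,
                             epochs = NULL, spec = NULL) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  kinds <- match.arg(kinds, MODEL_KINDS, several.ok = TRUE)
  if (length(dataset) < 10) {
    stop("too few windows (", length(dataset), ") to split for evaluation")
  }
  per_rep <- NULL
  partitions <- vector("list", reps)
  for (r in seq_len(reps)) {
    rep_seed <- seed + r - 1L
    parts <- split_windows(dataset, test_fraction = test_fraction,
                           val_fraction = val_fraction, seed = rep_seed)
    partitions[[r]] <- parts$indices
    for (k in kinds) {
      model <- fit_engagement_model(parts$train, kind = k,
                                    validation = parts$validation,
                                    seed = rep_seed, epochs = epochs,
                                    spec = spec)
      row <- eval_split_metrics(model, parts)
      row$kind <- k; row$rep <- r; row$seed <- rep_seed
      per_rep <- rbind(per_rep, row)
    }
  }
  agg <- do.call(rbind, lapply(kinds, function(k) {
    d <- per_rep[per_rep$kind == k, ]
    data.frame(id = dataset$subject_id, group = dataset$group, kind = k,
               n_windows = length(dataset),
               train_accuracy = mean(d$train_accuracy),
               train_loss = mean(d$train_loss),
               val_accuracy = mean(d$val_accuracy),
               val_loss = mean(d$val_loss),
               test_accuracy = mean(d$test_accuracy),
               test_f1 = mean(d$test_f1),
               reps = reps, seed = seed,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  attr(agg, "per_rep") <- per_rep
  attr(agg, "partitions") <- partitions
  class(agg) <- c("eval_report", "data.frame")
  agg
}

#' Evaluate a pooled group classifier
#'
#' Pools all windows of the supplied datasets before splitting, then runs the
#' same repeated-split protocol as [evaluate_subject()]. With a single
#' dataset this reduces exactly to the per-subject evaluation.
#'
#' @param datasets list of `windowed_dataset`s (one or more subjects).
#' @param grouping label for the pooled model (e.g. `"TD"`, `"ASD"`,
#'   `"combined"`).
#' @inheritParams evaluate_subject
#' @return data frame of class `eval_report`, one row per kind.
#' @export
evaluate_group <- function(datasets, grouping = "combined", kinds = MODEL_KINDS,
                           reps = 10, seed = 1, test_fraction = 0.2,
                           val_fraction = 0.1, epochs = NULL, spec = NULL) {
  if (length(datasets) == 0) stop("empty group")
  pooled <- if (length(datasets) == 1) datasets[[1]] else {
    pool_windows(datasets, subject_id = grouping, group = grouping)
  }
  pooled$subject_id <- grouping
  pooled$group <- grouping
  evaluate_subject(pooled, kinds = kinds, reps = reps, seed = seed,
                   test_fraction = test_fraction, val_fraction = val_fraction,
                   epochs = epochs, spec = spec)
}

#' Audit the partitions of an evaluation report
#'
#' Verifies that for every repetition the train/validation/test index sets
#' are pairwise disjoint and together exhaust the dataset.
#'
#' @param report an `eval_report` (from [evaluate_subject()] or
#'   [evaluate_group()]).
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
audit_partitions <- function(report) {
  parts <- attr(report, "partitions")
  if (is.null(parts)) stop("report carries no partition record")
  n <- report$n_windows[1]
  for (r in seq_along(parts)) {
    p <- parts[[r]]
    all_idx <- c(p$train, p$validation, p$test)
    if (anyDuplicated(all_idx) > 0) {
      stop("partition audit failed: overlapping partitions in repetition ", r)
    }
    if (!setequal(all_idx, seq_len(n))) {
      stop("partition audit failed: partitions not exhaustive in repetition ", r)
    }
  }
  invisible(TRUE)
}

#' Summary table with group means
#'
#' Collates per-subject (or per-group) report rows and appends one mean row
#' per group, computed as the unweighted arithmetic mean of the constituent
#' rows and rounded to `digits` decimals (4 matches the per-subject
#' convention of the reference tables, 2 the classifier-comparison one).
#'
#' @param reports an `eval_report`, a list of them, or any data frame with a
#'   `group` column and numeric metric columns.
#' @param digits decimals for rounding, applied to all numeric columns.
#' @param mean_over additional overall mean row label, or `NULL` to omit.
#' @return data frame: the input rows (rounded) followed by group-mean rows.
#' @export
summary_table <- function(reports, digits = 4, mean_over = NULL) {
  df <- if (is.data.frame(reports)) reports else do.call(rbind, reports)
  stopifnot(nrow(df) >= 1)
  num <- vapply(df, is.numeric, logical(1))
  mean_row <- function(rows, label) {
    out <- rows[1, , drop = FALSE]
    for (c in setdiff(names(df)[num], "id")) out[[c]] <- mean(rows[[c]])
    out[!num] <- NA
    if ("id" %in% names(out)) out$id <- label
    if ("group" %in% names(out)) out$group <- label
    out
  }
  extra <- NULL
  if ("group" %in% names(df)) {
    for (g in unique(stats::na.omit(df$group))) {
      extra <- rbind(extra, mean_row(df[df$group == g, , drop = FALSE], g))
    }
  }
  if (!is.null(mean_over)) extra <- rbind(mean_row(df, mean_over), extra)
  out <- rbind(df, extra)
  num_out <- vapply(out, is.numeric, logical(1))
  out[num_out] <- lapply(out[num_out], round, digits = digits)
  rownames(out) <- NULL
  out
}

#' Reference result tables from the original cohort
#'
#' The published performance and demographic tables of the 18-child cohort
#' (13 typically developing, 5 with ASD) the method was developed on, shipped
#' as plain CSV: per-subject demographics, per-subject personalized CNN
#' metrics, group-classifier metrics and the five-classifier comparison.
#' Used to verify that the package's aggregation arithmetic reproduces the
#' published group means.
#'
#' @return list of data frames: `demographics`, `personalized`, `groups`,
#'   `comparison`.
#' @export
study_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "lmaengage",
                                  mustWork = TRUE)
  list(
    demographics = utils::read.csv(path("cohort_demographics.csv"),
                                   stringsAsFactors = FALSE),
    personalized = utils::read.csv(path("personalized_model_metrics.csv"),
                                   stringsAsFactors = FALSE),
    groups = utils::read.csv(path("group_model_metrics.csv"),
                             stringsAsFactors = FALSE),
    comparison = utils::read.csv(path("classifier_comparison.csv"),
                                 stringsAsFactors = FALSE)
  )
}
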