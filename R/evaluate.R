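#' Per-class evaluation ratios
#'
#' `sensitivity()` is the ratio of true positives to all objects of the
#' class (TP / (TP + FN)). `specificity_paper()` follows the reporting
#' convention used throughout this package's tables: the ratio of true
#' positives to all objects predicted into the class (TP / (TP + FP)) —
#' what is conventionally called precision. The standard
#' true-negative-based definition is available as
#' `specificity_standard()` (TN / (TN + FP)) under its own name to avoid
#' silent confusion. Undefined ratios (empty class / no positive
#' predictions) return `NA`, not 0.
#'
#' @param tp,fn,fp,tn Confusion counts.
#' @return A number in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' sensitivity(45, 1)        # 0.978...
#' specificity_paper(12, 1)  # 0.923...
#' @export
sensitivity <- function(tp, fn) {
  ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
}

#' @rdname sensitivity
#' @export
specificity_paper <- function(tp, fp) {
  ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
}

#' @rdname sensitivity
#' @export
specificity_standard <- function(tn, fp) {
  ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
}

#' Mean predictability
#'
#' The summary metric of the nine-task tables: the unweighted mean of the
#' per-class sensitivities over all non-empty classes — including, where
#' present, the X (not-applicable) class — expressed as a percentage.
#' Classes with no objects are excluded from the mean.
#'
#' @param correct Correctly predicted count per class.
#' @param size Class size per class (same length).
#' @return A percentage in `[0, 100]`.
#' @examples
#' mean_predictability(c(45, 45), c(46, 46))  # 97.83
#' @export
mean_predictability <- function(correct, size) {
  stopifnot(length(correct) == length(size))
  if (any(correct > size)) abort("correct cannot exceed size",
                                 class = "glyco_validation_error")
  keep <- size > 0
  if (!any(keep)) abort("all classes are empty", class = "glyco_validation_error")
  100 * mean(correct[keep] / size[keep])
}

confusion_counts <- function(truth, pred, classes) {
  table(factor(truth, classes), factor(pred, classes), dnn = c("true", "pred"))
}

#' Confusion-based per-task report
#'
#' Builds, for each task, the true-by-predicted confusion matrix over the
#' task's full class alphabet and summarises it with per-class size, correct
#' predictions, [sensitivity()], [specificity_paper()] and the task's
#' [mean_predictability()].
#'
#' @param truth,pred Either data frames carrying (a subset of) the nine
#'   label columns of [task_names()], or, for a single task, plain character
#'   vectors together with `task`.
#' @param task Task name when `truth`/`pred` are vectors.
#' @return An object of class `task_report`: list with `summary` (tibble:
#'   task, class, size, correct, sensitivity, specificity),
#'   `mean_predictability` (tibble: task, mean_predictability) and
#'   `confusions` (named list of matrices). `tidy()` returns the summary,
#'   `glance()` the mean predictabilities.
#' @examples
#' task_report(c("A", "B", "B"), c("A", "B", "A"), task = "ano_r")
#' @export
task_report <- function(truth, pred, task = NULL) {
  alphabets <- glyco_tasks()
  if (is.atomic(truth)) {
    stopifnot(!is.null(task))
    truth <- tibble(!!task := as.character(truth))
    pred <- tibble(!!task := as.character(pred))
  }
  tasks <- intersect(task_names(), intersect(names(truth), names(pred)))
  if (length(tasks) == 0) abort("no common task columns",
                                class = "glyco_validation_error")
  confusions <- lapply(setNames(tasks, tasks), function(t) {
    if (anyNA(truth[[t]])) {
      abort(paste0("missing true labels for task ", t),
            class = "glyco_validation_error")
    }
    classes <- union(alphabets[[t]], unique(c(truth[[t]], pred[[t]])))
    confusion_counts(truth[[t]], pred[[t]], classes)
  })
  summary <- purrr::map_dfr(tasks, function(t) {
    cm <- confusions[[t]]
    tibble(
      task = t, class = rownames(cm),
      size = as.integer(rowSums(cm)), correct = as.integer(diag(cm)),
      sensitivity = unname(sensitivity(diag(cm), rowSums(cm) - diag(cm))),
      specificity = unname(specificity_paper(diag(cm), colSums(cm) - diag(cm)))
    )
  })
  mp <- summary |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(mean_predictability = mean_predictability(.data$correct,
                                                               .data$size)) |>
    dplyr::mutate(task = factor(.data$task, task_names())) |>
    dplyr::arrange(.data$task) |>
    dplyr::mutate(task = as.character(.data$task))
  structure(list(summary = summary, mean_predictability = mp,
                 confusions = confusions),
            class = "task_report")
}

#' @export
print.task_report <- function(x, digits = 2, ...) {
  s <- x$summary
  fmt <- function(v) ifelse(is.na(v), "---", sprintf(paste0("%.", digits, "f"), v))
  out <- data.frame(task = s$task, class = s$class, size = s$size,
                    correct = s$correct,
                    sensitivity = fmt(s$sensitivity),
                    specificity = fmt(s$specificity))
  print(out, row.names = FALSE)
  cat("\nmean predictability (%):\n")
  mp <- x$mean_predictability
  cat(paste0("  ", mp$task, ": ", sprintf("%.2f", mp$mean_predictability),
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
tidy.task_report <- function(x, ...) x$summary

#' @export
glance.task_report <- function(x, ...) x$mean_predictability

#' Per-class sensitivity plot of a report
#'
#' @param object A `task_report`.
#' @param ... Unused.
#' @return A ggplot of per-class sensitivities faceted by task.
#' @export
autoplot.task_report <- function(object, ...) {
  s <- dplyr::filter(object$summary, .data$size > 0)
  ggplot2::ggplot(s, ggplot2::aes(.data$class, .data$sensitivity)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "class", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Evaluate a fitted model on labelled records
#'
#' Dispatches on the model type: single-task fits ([train_rf()],
#' [train_cart()]) are scored on their task, a [train_cpgnn()] network on
#' all nine tasks.
#'
#' @param model A `glyco_rf`, `glyco_cart` or `cpgnn` fit.
#' @param records Labelled `glyco_records`.
#' @return A [task_report()].
#' @export
evaluate_model <- function(model, records) {
  records <- validate_records(records)
  if (inherits(model, "cpgnn")) {
    pred <- predict(model, records)
    return(task_report(records, pred[task_names()]))
  }
  task <- model$task
  if (is.null(task)) abort("model carries no task name",
                           class = "glyco_validation_error")
  if (anyNA(records[[task]])) {
    abort(paste0("records missing labels for task ", task, ": ",
                 paste(records$id[is.na(records[[task]])], collapse = ", ")),
          class = "glyco_validation_error")
  }
  task_report(records[[task]], predict(model, records), task = task)
}

#' Combine reports into a method-comparison table
#'
#' @param ... Named `task_report` objects (e.g. `rf_train = ...`,
#'   `rf_test = ...`), or a single named list of them.
#' @return A tibble with one row per task and one mean-predictability column
#'   per report.
#' @export
compare_reports <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && is.list(reports[[1]]) &&
      !inherits(reports[[1]], "task_report")) {
    reports <- reports[[1]]
  }
  stopifnot(length(names(reports)) == length(reports))
  out <- tibble(task = task_names())
  for (nm in names(reports)) {
    mp <- glance(reports[[nm]])
    out[[nm]] <- mp$mean_predictability[match(out$task, mp$task)]
  }
  dplyr::filter(out, rowSums(!is.na(out[-1])) > 0)
}
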