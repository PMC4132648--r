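#' Stage distribution by diagnostic label
#'
#' Tabulates, for each diagnostic label, the proportion of its subjects at
#' each model stage; each label's column sums to one.
#'
#' @param stages a [stage_subjects()] result or an integer vector of stages.
#' @param labels per-subject diagnostic labels.
#' @param n_events number of events N (stages run 0..N); inferred from a
#'   `stage_assignment` input.
#' @return (N+1) x L matrix of proportions with stage row names and label
#'   column names.
#' @export
stage_distribution <- function(stages, labels, n_events = NULL) {
  if (inherits(stages, "stage_assignment")) {
    if (is.null(n_events)) n_events <- stages$n_events
    stages <- stages$stage
  }
  if (is.null(n_events)) n_events <- max(stages)
  stopifnot(length(stages) == length(labels), all(stages >= 0L),
            all(stages <= n_events))
  labels <- as.factor(labels)
  tab <- table(factor(stages, levels = 0:n_events), labels)
  prop <- sweep(unclass(tab), 2L, pmax(colSums(tab), 1L), "/")
  dimnames(prop) <- list(stage = 0:n_events, label = levels(labels))
  prop
}

#' Classify subjects by thresholding their model stage
#'
#' Sweeps every threshold t = 0..N+1, classifying subjects with stage >= t as
#' positive (converters), and reports sensitivity, specificity and balanced
#' accuracy — the mean of sensitivity and specificity, which does not depend
#' on prevalence — at each threshold. The returned report uses the
#' balanced-accuracy-maximising threshold (lowest on ties, favouring
#' sensitivity). The area under the ROC curve is computed from the sweep by
#' the trapezoid rule, which equals the Mann-Whitney rank statistic with
#' half-credit for ties.
#'
#' @param stages integer vector of baseline stages (or a
#'   `stage_assignment`).
#' @param outcome binary outcome per subject: 1/TRUE for converters (or AD),
#'   0/FALSE for stable (or CN). Both classes must be present.
#' @param n_events number of events N; inferred when possible.
#' @return object of class `classification_report`: list with
#'   `threshold_stage`, `sensitivity`, `specificity`, `balanced_accuracy`
#'   (percent), `auc`, `n_positive`, `n_negative`, and `sweep` (data frame
#'   over all thresholds).
#' @export
classify_by_stage <- function(stages, outcome, n_events = NULL) {
  if (inherits(stages, "stage_assignment")) {
    if (is.null(n_events)) n_events <- stages$n_events
    stages <- stages$stage
  }
  if (is.null(n_events)) n_events <- max(stages)
  outcome <- as.integer(as.logical(outcome))
  stopifnot(length(stages) == length(outcome))
  n_pos <- sum(outcome == 1L)
  n_neg <- sum(outcome == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    .stopf("both converter and stable subjects are required")
  }
  thresholds <- 0:(n_events + 1L)
  sweep_df <- do.call(rbind, lapply(thresholds, function(t) {
    pred <- stages >= t
    sens <- 100 * sum(pred & outcome == 1L) / n_pos
    spec <- 100 * sum(!pred & outcome == 0L) / n_neg
    data.frame(threshold = t, sensitivity = sens, specificity = spec,
               balanced_accuracy = (sens + spec) / 2,
               tpr = sens / 100, fpr = 1 - spec / 100)
  }))
  best <- which.max(sweep_df$balanced_accuracy)  # first max = lowest threshold
  # trapezoid over ROC points; thresholds descend fpr from 1 to 0
  o <- order(sweep_df$fpr, sweep_df$tpr)
  fpr <- c(0, sweep_df$fpr[o], 1)
  tpr <- c(0, sweep_df$tpr[o], 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(threshold_stage = sweep_df$threshold[best],
                 sensitivity = sweep_df$sensitivity[best],
                 specificity = sweep_df$specificity[best],
                 balanced_accuracy = sweep_df$balanced_accuracy[best],
                 auc = auc, n_positive = n_pos, n_negative = n_neg,
                 sweep = sweep_df[, c("threshold", "sensitivity",
                                      "specificity", "balanced_accuracy")]),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("Stage-threshold classification (n+ = %d, n- = %d)\n",
                     "  threshold stage %d: balanced accuracy %.1f%% ",
                     "(sens %.1f%%, spec %.1f%%), AUC %.3f\n"),
              x$n_positive, x$n_negative, x$threshold_stage,
              x$balanced_accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Write a classification report and its threshold sweep
#'
#' @param x a `classification_report`.
#' @param dir output directory; writes `report.json` and
#'   `threshold_sweep.csv`.
#' @export
write_classification_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(x)[c("threshold_stage", "sensitivity",
                                    "specificity", "balanced_accuracy",
                                    "auc", "n_positive", "n_negative")],
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(x$sweep, file.path(dir, "threshold_sweep.csv"),
                   row.names = FALSE)
  invisible(dir)
}
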