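#' Fit an event-based model of disease progression
#'
#' The event-based model describes disease progression as a fixed sequence
#' in which biomarkers switch from a normal to an abnormal distribution.
#' Fitting proceeds in three steps: (1) for each biomarker a two-component
#' constrained normal mixture is fitted to all subjects
#' ([fit_event_distributions()]), giving the per-measurement likelihoods
#' under "event occurred" and "event not occurred"; (2) the
#' maximum-likelihood ordering of the events is found by multi-start greedy
#' ascent over permutations ([most_likely_sequence()]), marginalising each
#' subject's unknown stage with a uniform prior; (3) optionally, the
#' posterior over orderings is sampled by MCMC ([mcmc_sequences()]) to
#' quantify positional uncertainty. No biomarker cut points and no a priori
#' staging are involved at any step.
#'
#' @param data a [biomarker_dataset()], or a numeric matrix / data frame of
#'   biomarker values (subjects x biomarkers).
#' @param diagnosis per-subject labels in CN/MCI/AD; required when `data` is
#'   not already a `biomarker_dataset`.
#' @param direction per-biomarker abnormality direction (see
#'   [biomarker_dataset()]); used only when `data` is raw values.
#' @param mcmc if `TRUE` (default), sample the sequence posterior.
#' @param n_starts greedy restarts for the sequence search.
#' @param n_samples,burn_in MCMC retained and burn-in sample counts. For
#'   exploratory runs the defaults (10000/1000) give a stable picture of the
#'   positional variance; production runs may use much longer chains.
#' @param seed integer seed governing restarts and MCMC.
#' @return object of class `ebm`: list with `dataset`, `distributions`,
#'   `likelihoods`, `order` (maximum-likelihood sequence), `loglik`,
#'   `posterior` (a `sequence_posterior` or `NULL`), `staging` (baseline
#'   [stage_subjects()] result), `seed`, `call`.
#' @examples
#' sc <- simulation_scenario(n_events = 5, n_cn = 40, n_mci = 40, n_ad = 20,
#'                           separation = 3)
#' cohort <- generate_cohort(sc, seed = 1)
#' fit <- ebm(cohort$dataset, n_samples = 500, burn_in = 100, seed = 1)
#' fit
#' coef(fit)
#' predict(fit)[1:5]
#' @export
ebm <- function(data, diagnosis = NULL, direction = "increase", mcmc = TRUE,
                n_starts = 10L, n_samples = 10000L, burn_in = 1000L,
                seed = 1L) {
  ds <- if (inherits(data, "biomarker_dataset")) data else {
    if (is.null(diagnosis)) .stopf("'diagnosis' is required with raw values")
    biomarker_dataset(data, diagnosis, direction = direction)
  }
  dists <- fit_event_distributions(ds)
  lt <- event_likelihoods(ds, dists)
  ord <- most_likely_sequence(lt, n_starts = n_starts, seed = seed)
  post <- NULL
  if (mcmc) {
    post <- mcmc_sequences(lt, init = as.integer(ord), n_samples = n_samples,
                           burn_in = burn_in, seed = .substream_seed(seed, 104729L))
    if (post$ml_loglik > attr(ord, "loglik")) {
      ord <- structure(post$ml_sequence, loglik = post$ml_loglik,
                       degenerate = attr(ord, "degenerate"))
    }
  }
  staging <- stage_subjects(lt, as.integer(ord), visit = ds$visit)
  structure(list(dataset = ds, distributions = dists, likelihoods = lt,
                 order = as.integer(ord), loglik = attr(ord, "loglik"),
                 degenerate = isTRUE(attr(ord, "degenerate")),
                 posterior = post, staging = staging, seed = seed,
                 call = match.call()),
            class = "ebm")
}

#' @export
print.ebm <- function(x, ...) {
  N <- length(x$order)
  cat(sprintf("Event-based model: %d events, %d subjects\n",
              N, nrow(x$dataset$values)))
  cat("  ML sequence:",
      paste(x$dataset$biomarker_names[x$order], collapse = " -> "), "\n")
  cat(sprintf("  logLik: %.4f\n", x$loglik))
  if (!is.null(x$posterior)) {
    cat(sprintf("  MCMC: %d samples, acceptance %.1f%%\n",
                x$posterior$n_samples, 100 * x$posterior$acceptance_rate))
  }
  if (x$degenerate) cat("  note: ordering is fully degenerate (flat likelihood)\n")
  invisible(x)
}

#' @export
summary.ebm <- function(object, ...) {
  pv_diag <- if (!is.null(object$posterior)) {
    pv <- object$posterior$positional_variance
    pv[cbind(object$order, seq_along(object$order))]
  }
  out <- list(order = object$order,
              event_names = object$dataset$biomarker_names[object$order],
              loglik = object$loglik,
              mixtures = as.data.frame(object$distributions),
              positional_certainty = pv_diag,
              stage_table = table(stage = object$staging$stage),
              n_subjects = nrow(object$dataset$values))
  class(out) <- "summary.ebm"
  out
}

#' @export
print.summary.ebm <- function(x, ...) {
  cat(sprintf("Event-based model fit (%d subjects, %d events), logLik %.4f\n",
              x$n_subjects, length(x$order), x$loglik))
  cat("\nMaximum-likelihood event sequence:\n")
  seq_df <- data.frame(position = seq_along(x$order), event = x$event_names)
  if (!is.null(x$positional_certainty)) {
    seq_df$posterior_at_position <- round(x$positional_certainty, 3)
  }
  print(seq_df, row.names = FALSE)
  cat("\nFitted event distributions:\n")
  print(x$mixtures, digits = 4, row.names = FALSE)
  cat("\nBaseline stage distribution:\n")
  print(x$stage_table)
  invisible(x)
}

#' @export
coef.ebm <- function(object, ...) {
  df <- as.data.frame(object$distributions)
  m <- as.matrix(df[, c("mu_normal", "sd_normal", "mu_abnormal",
                        "sd_abnormal", "weight_normal")])
  rownames(m) <- df$biomarker
  m
}

#' @export
logLik.ebm <- function(object, ...) {
  # free parameters: 5 per mixture; the ordering is a discrete structure
  structure(object$loglik, df = 5L * length(object$order),
            nobs = nrow(object$dataset$values), class = "logLik")
}

#' Stage subjects with a fitted event-based model
#'
#' @param object an [ebm()] fit.
#' @param newdata optional [biomarker_dataset()] (or values matrix) of new
#'   subjects measured on the same biomarkers; defaults to the training
#'   subjects.
#' @param type `"stage"` for the integer stage vector, `"posterior"` for the
#'   full J x (N+1) stage posterior, `"assignment"` for the
#'   [stage_subjects()] object.
#' @param ... ignored.
#' @return per the chosen `type`.
#' @export
predict.ebm <- function(object, newdata = NULL,
                        type = c("stage", "posterior", "assignment"), ...) {
  type <- match.arg(type)
  sa <- if (is.null(newdata)) object$staging else {
    ds <- if (inherits(newdata, "biomarker_dataset")) newdata else {
      biomarker_dataset(newdata, rep("MCI", nrow(as.matrix(newdata))),
                        direction = object$dataset$direction)
    }
    if (!identical(ds$biomarker_names, object$dataset$biomarker_names)) {
      .stopf("newdata biomarkers must match the fitted model")
    }
    stage_subjects(event_likelihoods(ds, object$distributions), object$order,
                   visit = ds$visit)
  }
  switch(type, stage = sa$stage, posterior = sa$posterior, assignment = sa)
}

#' Plot method for event-based model fits
#'
#' Draws the positional variance diagram of the MCMC sequence posterior
#' (rows ordered by the maximum-likelihood sequence, greyscale 0 = white to
#' 1 = black).
#'
#' @param x an [ebm()] fit (with `mcmc = TRUE`).
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.ebm <- function(x, main = "Positional variance diagram", ...) {
  if (is.null(x$posterior)) {
    .stopf("no MCMC posterior stored; refit with mcmc = TRUE")
  }
  .plot_pvd(x$posterior$positional_variance, x$order,
            x$dataset$biomarker_names, main)
}

#' Simulate cohorts from a fitted event-based model
#'
#' Draws synthetic datasets from the fitted mixture components under the
#' maximum-likelihood sequence: each simulated subject receives a uniform
#' random stage and biomarker values from the corresponding components.
#'
#' @param object an [ebm()] fit.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param n_subjects subjects per simulated dataset (default: training size).
#' @param ... ignored.
#' @return list of `nsim` lists, each with `dataset` and `truth` as in
#'   [generate_cohort()].
#' @export
simulate.ebm <- function(object, nsim = 1, seed = NULL, n_subjects = NULL, ...) {
  if (is.null(n_subjects)) n_subjects <- nrow(object$dataset$values)
  co <- coef(object)
  N <- length(object$order)
  sc <- simulation_scenario(
    n_events = N, sequence_truth = object$order,
    mu_normal = co[, "mu_normal"], sd_normal = co[, "sd_normal"],
    mu_abnormal = co[, "mu_abnormal"], sd_abnormal = co[, "sd_abnormal"],
    direction = unname(object$dataset$direction),
    n_cn = 0L, n_mci = n_subjects, n_ad = 0L,
    contamination = 0, misdiagnosis = 0,
    stage_dist_mci = rep(1 / (N + 1), N + 1),
    biomarker_names = object$dataset$biomarker_names)
  .with_seed(seed, lapply(seq_len(nsim), function(i) generate_cohort(sc)))
}
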