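#' Assign model stages to subjects under a fixed event sequence
#'
#' For each subject, evaluates the likelihood of every stage k = 0..N under
#' the given sequence (events at positions <= k abnormal, the rest normal,
#' uniform stage prior) and assigns the maximum-likelihood stage. Ties take
#' the lowest stage, so severity is never inflated. The full normalised stage
#' posterior is returned alongside the point assignment; stage 0 means no
#' events have occurred and stage N means all have.
#'
#' @param lt a [event_likelihoods()] table.
#' @param order integer permutation: the (maximum-likelihood) event sequence.
#' @param visit optional per-subject visit label carried into the result.
#' @return object of class `stage_assignment`: list with `stage` (integer
#'   vector, 0..N), `posterior` (J x (N+1) matrix, rows summing to one),
#'   `subject_id`, `visit`, `order`, `n_events`.
#' @export
stage_subjects <- function(lt, order, visit = NULL) {
  stopifnot(inherits(lt, "likelihood_tables"))
  N <- ncol(lt$log_like_event)
  ord <- .assert_permutation(order, N)
  S <- .stage_loglik_matrix(lt, ord)           # J x (N+1), k = 0..N
  lse <- .row_logsumexp(S)
  post <- exp(S - lse)
  stage <- max.col(post, ties.method = "first") - 1L  # lowest stage on ties
  colnames(post) <- paste0("k", 0:N)
  if (is.null(visit)) visit <- rep("baseline", nrow(S))
  structure(list(stage = stage, posterior = post,
                 subject_id = lt$subject_id, visit = rep_len(visit, nrow(S)),
                 order = ord, n_events = N),
            class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  cat(sprintf("Stage assignment: %d subjects, stages 0..%d\n",
              length(x$stage), x$n_events))
  print(table(stage = x$stage))
  invisible(x)
}

#' @export
as.data.frame.stage_assignment <- function(x, ...) {
  data.frame(subject_id = x$subject_id, visit = x$visit, stage = x$stage,
             max_posterior = x$posterior[cbind(seq_along(x$stage), x$stage + 1L)],
             posterior = apply(x$posterior, 1L, function(p)
               paste(sprintf("%.6g", p), collapse = ";")),
             row.names = NULL)
}

# Half-width of the sequence-uncertainty band at stage k: the smallest
# window w such that the positional-variance mass of the event at position k
# within positions k-w..k+w reaches band_mass. Stage 0 has no event: band 0.
.stage_band <- function(pv, ord, k, band_mass) {
  if (k == 0L) return(0L)
  N <- ncol(pv)
  ev <- ord[k]
  for (w in 0:(N - 1L)) {
    lo <- max(1L, k - w); hi <- min(N, k + w)
    if (sum(pv[ev, lo:hi]) >= band_mass) return(w)
  }
  N - 1L
}

#' Longitudinal consistency of stage assignments
#'
#' Compares each subject's follow-up stage with the baseline stage. A stage
#' that increases or stays constant is always consistent (disease progresses
#' monotonically); a decrease is flagged inconsistent only when it exceeds
#' the sequence-uncertainty band at the baseline stage. The band half-width
#' at stage k is the smallest number of contiguous positions around k over
#' which the positional-variance mass of the event at position k reaches
#' `band_mass` — an operational stand-in for the visual uncertainty band of
#' the fitted sequence, labelled as such in output.
#'
#' @param baseline,followup [stage_subjects()] results with matching
#'   subjects (matched by `subject_id`).
#' @param pv positional variance matrix (event x position), e.g. from
#'   [mcmc_sequences()].
#' @param band_mass positional-variance mass defining the band (default
#'   0.95).
#' @return data frame with columns `subject_id`, `baseline`, `followup`,
#'   `band`, `consistent`.
#' @export
longitudinal_consistency <- function(baseline, followup, pv, band_mass = 0.95) {
  stopifnot(inherits(baseline, "stage_assignment"),
            inherits(followup, "stage_assignment"))
  m <- match(baseline$subject_id, followup$subject_id)
  if (anyNA(m)) {
    .stopf("subject(s) missing from follow-up: %s",
           paste(baseline$subject_id[is.na(m)], collapse = ", "))
  }
  bl <- baseline$stage
  fu <- followup$stage[m]
  band <- vapply(bl, function(k) .stage_band(pv, baseline$order, k, band_mass), 0L)
  data.frame(subject_id = baseline$subject_id, baseline = bl, followup = fu,
             band = band, consistent = !(fu < bl & (bl - fu) > band),
             row.names = NULL)
}

#' Export a stage table to CSV
#'
#' Writes subject, visit, stage, maximum posterior and the full stage
#' posterior (semicolon-separated) — a layout any survival package can
#' consume after joining time-to-event columns.
#'
#' @param x a `stage_assignment`.
#' @param path output CSV path.
#' @export
write_stage_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
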