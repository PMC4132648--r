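#' Bootstrap cross-validation of the maximum-likelihood sequence
#'
#' Re-estimates the full model on bootstrap resamples of the subjects: each
#' replicate resamples J subjects with replacement, refits every biomarker's
#' event distribution, rebuilds the likelihood tables and reruns the greedy
#' sequence search. The B maximum-likelihood sequences are aggregated into a
#' positional variance matrix. Because each replicate sees only a resample of
#' the data, these diagrams tend to overestimate ordering uncertainty
#' relative to the MCMC posterior on the full data.
#'
#' A resample with fewer than two CN- or two AD-labelled subjects cannot
#' support the constrained mixture fit and is redrawn (with a message); more
#' than 50 percent redraws overall is an error.
#'
#' @param ds a [biomarker_dataset()].
#' @param B number of bootstrap replicates (>= 1; 100 for full runs).
#' @param seed master integer seed. Each replicate consumes an independent
#'   substream derived from it, so changing `B` does not reshuffle earlier
#'   replicates.
#' @param n_starts greedy restarts per replicate.
#' @param stratify if `TRUE`, resample within each diagnostic group
#'   separately (off by default; the plain bootstrap resamples all subjects).
#' @return object of class `bootstrap_result`: list with `B`,
#'   `ml_sequences` (list of integer permutations), `positional_variance`,
#'   `n_redraws`, `seed`, `event_names`.
#' @export
bootstrap_sequences <- function(ds, B = 100L, seed = 1L, n_starts = 5L,
                                stratify = FALSE) {
  stopifnot(inherits(ds, "biomarker_dataset"), B >= 1L)
  B <- as.integer(B)
  J <- nrow(ds$values)
  N <- ncol(ds$values)
  ml_sequences <- vector("list", B)
  n_redraws <- 0L
  for (b in seq_len(B)) {
    sb <- .substream_seed(seed, b)
    fit_b <- .with_seed(sb, {
      repeat {
        idx <- if (stratify) {
          unlist(lapply(split(seq_len(J), ds$diagnosis),
                        function(g) sample(g, length(g), replace = TRUE)),
                 use.names = FALSE)
        } else {
          sample.int(J, J, replace = TRUE)
        }
        dx <- ds$diagnosis[idx]
        ok <- sum(dx == "CN") >= 2L && sum(dx == "AD") >= 2L &&
          all(apply(ds$values[idx, , drop = FALSE], 2L, stats::sd) > 0)
        if (ok) break
        n_redraws <- n_redraws + 1L
        message(sprintf("bootstrap replicate %d redrawn (unusable resample)", b))
        if (n_redraws > B / 2) {
          .stopf("more than half of the bootstrap draws were unusable")
        }
      }
      # fresh subject keys: resampling with replacement duplicates subjects
      rs <- biomarker_dataset(ds$values[idx, , drop = FALSE],
                              ds$diagnosis[idx],
                              subject_id = paste0("b", seq_len(J)),
                              direction = ds$direction)
      dists <- fit_event_distributions(rs)
      lt <- event_likelihoods(rs, dists)
      most_likely_sequence(lt, n_starts = n_starts, seed = sb)
    })
    ml_sequences[[b]] <- as.integer(fit_b)
  }
  samples <- do.call(rbind, ml_sequences)
  structure(list(B = B, ml_sequences = ml_sequences,
                 positional_variance = .positional_variance_matrix(samples, ds$biomarker_names),
                 n_redraws = n_redraws, seed = seed,
                 event_names = ds$biomarker_names),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap sequence validation: B = %d replicates (%d redraws)\n",
              x$B, x$n_redraws))
  cat(sprintf("  diagonal mass (vs. modal order): %.3f\n",
              mean(diag(x$positional_variance[x$ml_sequences[[1L]], ]))))
  invisible(x)
}

#' @rdname plot.sequence_posterior
#' @export
plot.bootstrap_result <- function(x, main = "Positional variance (bootstrap)", ...) {
  # order rows by the modal sequence across replicates (greedy by position)
  pv <- x$positional_variance
  N <- nrow(pv)
  taken <- logical(N)
  ml <- integer(N)
  for (p in seq_len(N)) {
    cand <- order(pv[, p], decreasing = TRUE)
    ml[p] <- cand[!taken[cand]][1L]
    taken[ml[p]] <- TRUE
  }
  .plot_pvd(pv, ml, x$event_names, main)
}

#' Per-replicate maximum-likelihood sequence table
#'
#' @param x a `bootstrap_result`.
#' @return data frame with columns `replicate`, `position`, `biomarker`.
#' @export
bootstrap_sequence_table <- function(x) {
  stopifnot(inherits(x, "bootstrap_result"))
  N <- length(x$ml_sequences[[1L]])
  data.frame(replicate = rep(seq_len(x$B), each = N),
             position = rep(seq_len(N), x$B),
             biomarker = x$event_names[unlist(x$ml_sequences)],
             row.names = NULL)
}
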