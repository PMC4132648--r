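# Sequence likelihood, greedy search and MCMC over event orderings.
#
# An event sequence is an integer permutation `ord` of 1..N: ord[p] is the
# biomarker (event) occupying position p. A subject at stage k has exactly
# the first k events in `ord` abnormal.

# J x (N+1) matrix of per-subject stage log-likelihoods under `ord`
# (columns k = 0..N), excluding the uniform stage prior. Column k holds
# sum_{i<=k} log p(x|E) + sum_{i>k} log p(x|not E) over positions i.
.stage_loglik_matrix <- function(lt, ord) {
  le <- lt$log_like_event[, ord, drop = FALSE]
  ln <- lt$log_like_noevent[, ord, drop = FALSE]
  CA <- .row_cumsum(le)
  CB <- .row_cumsum(ln)
  totB <- CB[, ncol(CB)]
  unname(cbind(totB, CA + (totB - CB)))
}

#' Log-likelihood of the data under an event sequence
#'
#' Evaluates the total data log-likelihood of a candidate event ordering:
#' each subject's likelihood is the average over all N+1 latent stages
#' (uniform stage prior) of the product of abnormal-component densities for
#' events at or before the stage and normal-component densities after it.
#' Computation is entirely in the log domain (log-sum-exp over stages,
#' cumulative log-sums over positions), costing O(J N) per sequence.
#'
#' @param lt a [event_likelihoods()] table.
#' @param order integer permutation of the N biomarker indices;
#'   `order[p]` is the event at position `p`.
#' @return scalar log-likelihood.
#' @export
log_likelihood_sequence <- function(lt, order) {
  stopifnot(inherits(lt, "likelihood_tables"))
  N <- ncol(lt$log_like_event)
  ord <- .assert_permutation(order, N)
  if (any(!is.finite(lt$log_like_event)) || any(!is.finite(lt$log_like_noevent))) {
    .stopf("likelihood tables contain non-finite entries")
  }
  S <- .stage_loglik_matrix(lt, ord)
  sum(.row_logsumexp(S)) - nrow(S) * log(N + 1)
}

#' Maximum-likelihood event sequence by multi-start greedy ascent
#'
#' From each of `n_starts` random initial permutations, repeatedly evaluates
#' all N(N-1)/2 pairwise position swaps, moves to the best strictly-improving
#' one (ties broken by the lexicographically first pair), and stops at a local
#' optimum; the best local optimum across starts is returned. Deterministic
#' given `seed`.
#'
#' @param lt a [event_likelihoods()] table.
#' @param n_starts number of random restarts (>= 1).
#' @param seed integer seed for the restart permutations; `NULL` uses the
#'   ambient RNG stream.
#' @return integer permutation with attributes `loglik` (its log-likelihood)
#'   and `degenerate` (`TRUE` when every swap from the first start left the
#'   likelihood exactly unchanged, i.e. the ordering is unidentifiable).
#' @export
most_likely_sequence <- function(lt, n_starts = 10L, seed = NULL) {
  stopifnot(inherits(lt, "likelihood_tables"), n_starts >= 1L)
  N <- ncol(lt$log_like_event)
  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  best_ord <- NULL
  best_ll <- -Inf
  degenerate <- FALSE
  .with_seed(seed, {
    for (s in seq_len(n_starts)) {
      ord <- if (N == 1L) 1L else sample.int(N)
      ll <- log_likelihood_sequence(lt, ord)
      first_sweep <- TRUE
      repeat {
        if (N == 1L) break
        cand_ll <- apply(pairs, 1L, function(pq) {
          o <- ord
          o[pq] <- o[rev(pq)]
          log_likelihood_sequence(lt, o)
        })
        if (s == 1L && first_sweep && all(cand_ll == ll)) degenerate <- TRUE
        first_sweep <- FALSE
        k <- which.max(cand_ll)     # first index among ties = lexicographic
        if (cand_ll[k] <= ll) break # strict improvement required
        ord[pairs[k, ]] <- ord[rev(pairs[k, ])]
        ll <- cand_ll[k]
      }
      if (ll > best_ll) {
        best_ll <- ll
        best_ord <- ord
      }
    }
  })
  structure(as.integer(best_ord), loglik = best_ll, degenerate = degenerate)
}

# Event-by-position frequency matrix from an M x N matrix of sampled
# permutations (rows are samples; entries are event indices).
.positional_variance_matrix <- function(samples, event_names = NULL) {
  M <- nrow(samples); N <- ncol(samples)
  pos <- rep(seq_len(N), each = M)
  counts <- tabulate(as.integer(samples) + N * (pos - 1L), nbins = N * N)
  pv <- matrix(counts / M, N, N)  # rows: event, cols: position
  dimnames(pv) <- list(event = event_names, position = NULL)
  pv
}

#' Positional variance matrix of a sample of sequences
#'
#' Entry (event, position) is the fraction of sampled sequences placing that
#' event at that position; rows and columns each sum to one.
#'
#' @param samples an M x N integer matrix of sampled permutations (one row
#'   per sample), or a [mcmc_sequences()] / [bootstrap_sequences()] result.
#' @param event_names optional row names.
#' @return N x N doubly stochastic matrix.
#' @export
positional_variance <- function(samples, event_names = NULL) {
  if (inherits(samples, c("sequence_posterior", "bootstrap_result"))) {
    return(samples$positional_variance)
  }
  .positional_variance_matrix(as.matrix(samples), event_names)
}

#' MCMC sampling of the sequence posterior
#'
#' Metropolis sampling over permutations: each step proposes swapping two
#' uniformly chosen positions (a symmetric proposal, so the acceptance
#' probability is the bare likelihood ratio `min(1, exp(delta log-lik))`).
#' Samples recorded after `burn_in` steps summarise the posterior over
#' orderings; the positional variance matrix gives the marginal
#' event-by-position frequencies.
#'
#' @param lt a [event_likelihoods()] table.
#' @param init initial permutation, typically the greedy optimum from
#'   [most_likely_sequence()].
#' @param n_samples retained post-burn-in samples (>= 1).
#' @param burn_in discarded initial steps.
#' @param seed integer seed; `NULL` uses the ambient stream.
#' @return object of class `sequence_posterior`: list with `samples`
#'   (n_samples x N matrix), `log_liks`, `ml_sequence`, `ml_loglik`,
#'   `positional_variance`, `acceptance_rate`, `seed`, `n_samples`,
#'   `burn_in`, `event_names`.
#' @export
mcmc_sequences <- function(lt, init = NULL, n_samples = 10000L,
                           burn_in = 1000L, seed = NULL) {
  stopifnot(inherits(lt, "likelihood_tables"), n_samples >= 1L, burn_in >= 0L)
  N <- ncol(lt$log_like_event)
  if (is.null(init)) init <- seq_len(N)
  ord <- .assert_permutation(init, N)
  ll <- log_likelihood_sequence(lt, ord)
  ml_ord <- ord; ml_ll <- ll
  total <- burn_in + n_samples
  samples <- matrix(0L, n_samples, N)
  log_liks <- numeric(n_samples)
  n_accept <- 0L
  .with_seed(seed, {
    for (t in seq_len(total)) {
      if (N > 1L) {
        pq <- sample.int(N, 2L)
        cand <- ord
        cand[pq] <- cand[rev(pq)]
        cand_ll <- log_likelihood_sequence(lt, cand)
        if (cand_ll >= ll || stats::runif(1L) < exp(cand_ll - ll)) {
          ord <- cand; ll <- cand_ll
          n_accept <- n_accept + 1L
          if (ll > ml_ll) { ml_ll <- ll; ml_ord <- ord }
        }
      }
      if (t > burn_in) {
        samples[t - burn_in, ] <- ord
        log_liks[t - burn_in] <- ll
      }
    }
  })
  if (N > 1L && n_accept == 0L) {
    warning("MCMC accepted no proposals over the entire run", call. = FALSE)
  }
  structure(list(samples = samples, log_liks = log_liks,
                 ml_sequence = as.integer(ml_ord), ml_loglik = ml_ll,
                 positional_variance = .positional_variance_matrix(samples, lt$biomarker_names),
                 acceptance_rate = if (N > 1L) n_accept / total else 1,
                 seed = seed, n_samples = n_samples, burn_in = burn_in,
                 event_names = lt$biomarker_names),
            class = "sequence_posterior")
}

#' @export
print.sequence_posterior <- function(x, ...) {
  cat(sprintf("Sequence posterior: %d MCMC samples (%d burn-in), acceptance %.1f%%\n",
              x$n_samples, x$burn_in, 100 * x$acceptance_rate))
  cat("  ML sequence:",
      paste(x$event_names[x$ml_sequence], collapse = " -> "), "\n")
  cat(sprintf("  ML logLik: %.4f\n", x$ml_loglik))
  invisible(x)
}

# Shared positional variance diagram renderer (greyscale: 0 white, 1 black),
# rows ordered by the maximum-likelihood sequence.
.plot_pvd <- function(pv, ml_sequence, event_names, main) {
  N <- nrow(pv)
  if (is.null(event_names)) event_names <- paste0("bm", seq_len(N))
  disp <- pv[ml_sequence, , drop = FALSE]  # row p: event at ML position p
  op <- graphics::par(mar = c(4, 8, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(x = seq_len(N), y = seq_len(N),
                  z = t(disp[N:1, , drop = FALSE]),
                  col = grDevices::gray(seq(1, 0, length.out = 256)),
                  zlim = c(0, 1), axes = FALSE, xlab = "Sequence position",
                  ylab = "", main = main)
  graphics::axis(1, at = seq_len(N))
  graphics::axis(2, at = N:1, labels = event_names[ml_sequence], las = 2,
                 cex.axis = 0.8)
  graphics::box()
  invisible(disp)
}

#' Positional variance diagram
#'
#' Plots the event-by-position frequency matrix with rows ordered by the
#' maximum-likelihood sequence, greyscale from 0 (white) to 1 (black). A
#' strong ordering shows a dark diagonal; grey blocks mark events whose
#' position is uncertain.
#'
#' @param x a `sequence_posterior`.
#' @param main plot title.
#' @param ... ignored.
#' @export
plot.sequence_posterior <- function(x, main = "Positional variance (MCMC)", ...) {
  .plot_pvd(x$positional_variance, x$ml_sequence, x$event_names, main)
}

#' Serialise a sequence posterior to a directory
#'
#' Writes `ml_sequence.json` (biomarker names in maximum-likelihood order),
#' `positional_variance.csv` (named rows and columns) and `metadata.json`
#' (seed, sample counts, acceptance rate).
#'
#' @param x a `sequence_posterior` or `bootstrap_result`.
#' @param dir output directory (created if needed).
#' @export
write_sequence_posterior <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- x$event_names
  if (is.null(nm)) nm <- paste0("bm", seq_len(ncol(x$positional_variance)))
  ml <- if (!is.null(x$ml_sequence)) x$ml_sequence else x$ml_sequences[[1L]]
  jsonlite::write_json(nm[ml], file.path(dir, "ml_sequence.json"))
  pv <- x$positional_variance
  rownames(pv) <- nm
  colnames(pv) <- paste0("pos", seq_len(ncol(pv)))
  utils::write.csv(pv, file.path(dir, "positional_variance.csv"))
  meta <- list(seed = x$seed, n_samples = x$n_samples, burn_in = x$burn_in,
               B = x$B, acceptance_rate = x$acceptance_rate)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       file.path(dir, "metadata.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
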