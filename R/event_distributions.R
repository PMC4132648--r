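#' Fit the constrained two-component normal mixture for one biomarker
#'
#' Models a biomarker's values across *all* subjects as a mixture of a
#' "normal" (not-yet-abnormal) and an "abnormal" normal component. Because a
#' sporadic-disease control group is contaminated by presymptomatic cases and
#' the patient group contains misdiagnoses, the components are fitted to the
#' pooled data rather than to the labelled groups; the diagnostic labels enter
#' only through (i) the initialisation and (ii) a weak constraint that keeps
#' the fit away from physically unrealistic solutions: the normal component's
#' standard deviation may not exceed the sample SD of the CN-labelled values,
#' and the abnormal component's may not exceed the sample SD of the
#' AD-labelled values.
#'
#' The fit is expectation-maximisation with the SD constraint enforced by
#' projection at each M-step (the constrained M-step remains the exact
#' maximiser of the EM surrogate, so the observed-data log-likelihood is
#' non-decreasing across iterations). Initialisation is deterministic: normal
#' component from the CN-labelled moments, abnormal from the AD-labelled
#' moments, mixing weight from the CN fraction.
#'
#' @param values numeric vector of one biomarker's measurements for all
#'   subjects.
#' @param cn_mask,ad_mask logical vectors flagging CN- and AD-labelled
#'   subjects (each needs at least two members with nonzero spread).
#' @param direction `"increase"` or `"decrease"`: the side on which the
#'   abnormal component must lie.
#' @param biomarker_name stored in the result for bookkeeping.
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @return object of class `event_distribution`: list with `mu_normal`,
#'   `sd_normal`, `mu_abnormal`, `sd_abnormal`, `weight_normal`, `direction`,
#'   `biomarker_name`, the SD bounds, the per-iteration log-likelihood trace
#'   and iteration count.
#' @export
fit_event_distribution <- function(values, cn_mask, ad_mask,
                                   direction = c("increase", "decrease"),
                                   biomarker_name = "biomarker",
                                   max_iter = 10000L, tol = 1e-8) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) .stopf("values must be finite")
  if (sum(cn_mask) < 2L || sum(ad_mask) < 2L) {
    .stopf("need at least 2 CN-labelled and 2 AD-labelled values")
  }
  if (stats::sd(values) == 0) .stopf("degenerate input: all values identical")
  sn_max <- stats::sd(values[cn_mask])
  sa_max <- stats::sd(values[ad_mask])
  if (sn_max == 0 || sa_max == 0) {
    .stopf("zero spread within the CN- or AD-labelled group")
  }

  mu_n <- mean(values[cn_mask]); sd_n <- sn_max
  mu_a <- mean(values[ad_mask]); sd_a <- sa_max
  w <- sum(cn_mask) / length(values)
  w <- min(max(w, 1e-3), 1 - 1e-3)

  mix_loglik <- function(mu_n, sd_n, mu_a, sd_a, w) {
    sum(log(pmax(w * stats::dnorm(values, mu_n, sd_n) +
                   (1 - w) * stats::dnorm(values, mu_a, sd_a), .DENSITY_FLOOR)))
  }

  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dn <- w * stats::dnorm(values, mu_n, sd_n)
    da <- (1 - w) * stats::dnorm(values, mu_a, sd_a)
    tot <- pmax(dn + da, .DENSITY_FLOOR)
    r <- dn / tot  # responsibility of the normal component
    rn <- sum(r); ra <- sum(1 - r)
    if (rn < 1e-10 || ra < 1e-10) {
      .stopf("mixture fit degenerated: one component lost all responsibility")
    }
    mu_n <- sum(r * values) / rn
    mu_a <- sum((1 - r) * values) / ra
    sd_n <- min(sqrt(sum(r * (values - mu_n)^2) / rn), sn_max)
    sd_a <- min(sqrt(sum((1 - r) * (values - mu_a)^2) / ra), sa_max)
    if (sd_n < 1e-10 || sd_a < 1e-10) {
      .stopf("constraint infeasible: a component's spread collapsed to zero")
    }
    w <- rn / length(values)
    ll <- mix_loglik(mu_n, sd_n, mu_a, sd_a, w)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }

  # Component identity must respect the declared direction of abnormality.
  swapped <- (direction == "increase" && mu_a < mu_n) ||
    (direction == "decrease" && mu_a > mu_n)
  if (swapped) {
    warning(sprintf("components for '%s' converged on the wrong side; relabelling",
                    biomarker_name), call. = FALSE)
    tmp <- c(mu_n, sd_n); mu_n <- mu_a; sd_n <- sd_a
    mu_a <- tmp[1]; sd_a <- tmp[2]; w <- 1 - w
    sd_n <- min(sd_n, sn_max); sd_a <- min(sd_a, sa_max)
  }

  structure(list(biomarker_name = biomarker_name,
                 mu_normal = mu_n, sd_normal = sd_n,
                 mu_abnormal = mu_a, sd_abnormal = sd_a,
                 weight_normal = w, direction = direction,
                 sd_bound_normal = sn_max, sd_bound_abnormal = sa_max,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = length(trace)),
            class = "event_distribution")
}

#' @export
print.event_distribution <- function(x, ...) {
  cat(sprintf("Event distribution '%s' (%s):\n", x$biomarker_name, x$direction))
  cat(sprintf("  normal:   N(%.4g, %.4g)   abnormal: N(%.4g, %.4g)\n",
              x$mu_normal, x$sd_normal, x$mu_abnormal, x$sd_abnormal))
  cat(sprintf("  weight_normal = %.3f, logLik = %.3f (%d EM iterations)\n",
              x$weight_normal, x$loglik, x$n_iter))
  invisible(x)
}

#' Fit event distributions for every biomarker in a dataset
#'
#' @param ds a [biomarker_dataset()].
#' @param ... passed to [fit_event_distribution()].
#' @return object of class `distribution_set`: a named list of
#'   `event_distribution` records, one per biomarker, in dataset column order.
#' @export
fit_event_distributions <- function(ds, ...) {
  stopifnot(inherits(ds, "biomarker_dataset"))
  cn <- ds$diagnosis == "CN"
  ad <- ds$diagnosis == "AD"
  fits <- lapply(ds$biomarker_names, function(bm) {
    fit_event_distribution(ds$values[, bm], cn, ad,
                           direction = ds$direction[[bm]],
                           biomarker_name = bm, ...)
  })
  names(fits) <- ds$biomarker_names
  structure(fits, class = "distribution_set")
}

#' @export
print.distribution_set <- function(x, ...) {
  cat(sprintf("Distribution set: %d biomarkers\n", length(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.distribution_set <- function(x, ...) {
  data.frame(biomarker = vapply(x, `[[`, "", "biomarker_name"),
             mu_normal = vapply(x, `[[`, 0, "mu_normal"),
             sd_normal = vapply(x, `[[`, 0, "sd_normal"),
             mu_abnormal = vapply(x, `[[`, 0, "mu_abnormal"),
             sd_abnormal = vapply(x, `[[`, 0, "sd_abnormal"),
             weight_normal = vapply(x, `[[`, 0, "weight_normal"),
             direction = vapply(x, `[[`, "", "direction"),
             row.names = NULL)
}

#' Per-subject event likelihood tables
#'
#' Evaluates, for every subject j and biomarker i, the densities
#' p(x_ij | event occurred) under the abnormal component and
#' p(x_ij | event not occurred) under the normal component. The mixing weight
#' plays no role here: the sequence likelihood conditions on event status, and
#' the uniform stage prior replaces the weight. Densities are floored at
#' 1e-300 before logging so every entry is finite and strictly positive.
#'
#' @param ds a [biomarker_dataset()].
#' @param dists a `distribution_set` covering every biomarker in `ds`.
#' @return object of class `likelihood_tables`: list with J x N matrices
#'   `like_event`, `like_noevent` and their logs `log_like_event`,
#'   `log_like_noevent`, plus `biomarker_names` and `subject_id`.
#' @export
event_likelihoods <- function(ds, dists) {
  stopifnot(inherits(ds, "biomarker_dataset"), inherits(dists, "distribution_set"))
  missing_bm <- setdiff(ds$biomarker_names, names(dists))
  if (length(missing_bm)) {
    .stopf("distribution set lacks biomarker(s): %s",
           paste(missing_bm, collapse = ", "))
  }
  J <- nrow(ds$values); N <- ncol(ds$values)
  le <- ln <- matrix(0, J, N, dimnames = list(NULL, ds$biomarker_names))
  for (bm in ds$biomarker_names) {
    d <- dists[[bm]]
    le[, bm] <- pmax(stats::dnorm(ds$values[, bm], d$mu_abnormal, d$sd_abnormal),
                     .DENSITY_FLOOR)
    ln[, bm] <- pmax(stats::dnorm(ds$values[, bm], d$mu_normal, d$sd_normal),
                     .DENSITY_FLOOR)
  }
  structure(list(like_event = le, like_noevent = ln,
                 log_like_event = log(le), log_like_noevent = log(ln),
                 biomarker_names = ds$biomarker_names,
                 subject_id = ds$subject_id),
            class = "likelihood_tables")
}

#' Construct likelihood tables from density matrices
#'
#' Builds a `likelihood_tables` object directly from J x N matrices of
#' densities under the event / no-event hypotheses, for use with custom
#' (non-mixture) event distributions. Entries are floored at 1e-300.
#'
#' @param like_event,like_noevent J x N matrices of strictly positive
#'   densities.
#' @param biomarker_names,subject_id optional names; defaults derived from
#'   the matrices.
#' @return a `likelihood_tables` object as from [event_likelihoods()].
#' @export
likelihood_tables <- function(like_event, like_noevent,
                              biomarker_names = NULL, subject_id = NULL) {
  like_event <- as.matrix(like_event)
  like_noevent <- as.matrix(like_noevent)
  if (!identical(dim(like_event), dim(like_noevent))) {
    .stopf("the two density matrices must have identical dimensions")
  }
  if (anyNA(like_event) || anyNA(like_noevent) ||
      any(like_event < 0) || any(like_noevent < 0)) {
    .stopf("densities must be non-negative and complete")
  }
  if (is.null(biomarker_names)) {
    biomarker_names <- colnames(like_event)
    if (is.null(biomarker_names)) biomarker_names <- paste0("bm", seq_len(ncol(like_event)))
  }
  if (is.null(subject_id)) subject_id <- paste0("s", seq_len(nrow(like_event)))
  le <- pmax(like_event, .DENSITY_FLOOR)
  ln <- pmax(like_noevent, .DENSITY_FLOOR)
  colnames(le) <- colnames(ln) <- biomarker_names
  structure(list(like_event = le, like_noevent = ln,
                 log_like_event = log(le), log_like_noevent = log(ln),
                 biomarker_names = biomarker_names, subject_id = subject_id),
            class = "likelihood_tables")
}

#' Mixture-based cut point for a biomarker
#'
#' Finds the biomarker value between the two component means at which a
#' measurement is equally likely to be normal or abnormal under the fitted
#' mixture, i.e. the root of
#' `weight_normal * phi(x; mu_normal, sd_normal) =
#'  (1 - weight_normal) * phi(x; mu_abnormal, sd_abnormal)`.
#' The cut point is descriptive only — the event-based model itself never
#' thresholds. When labelled values are supplied, the achieved sensitivity
#' (percent of AD-labelled values on the abnormal side of the cut point) and
#' specificity (percent of CN-labelled values on the normal side) are
#' reported.
#'
#' @param dist an `event_distribution`.
#' @param values,cn_mask,ad_mask optional labelled data for the
#'   sensitivity/specificity report.
#' @return list with `cutpoint` and, when labelled data were given,
#'   `sensitivity` and `specificity` in percent.
#' @export
compute_cutpoint <- function(dist, values = NULL, cn_mask = NULL, ad_mask = NULL) {
  stopifnot(inherits(dist, "event_distribution"))
  if (dist$mu_normal == dist$mu_abnormal && dist$sd_normal == dist$sd_abnormal) {
    .stopf("components are identical; no cut point exists")
  }
  w <- min(max(dist$weight_normal, 1e-12), 1 - 1e-12)
  f <- function(x) {
    (log(w) + stats::dnorm(x, dist$mu_normal, dist$sd_normal, log = TRUE)) -
      (log(1 - w) + stats::dnorm(x, dist$mu_abnormal, dist$sd_abnormal, log = TRUE))
  }
  lo <- min(dist$mu_normal, dist$mu_abnormal)
  hi <- max(dist$mu_normal, dist$mu_abnormal)
  if (lo == hi || f(lo) * f(hi) > 0) {
    .stopf(paste0("no posterior-0.5 crossing between the component means ",
                  "(normal N(%.4g, %.4g), abnormal N(%.4g, %.4g), weight %.3f)"),
           dist$mu_normal, dist$sd_normal, dist$mu_abnormal, dist$sd_abnormal, w)
  }
  x_star <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  out <- list(cutpoint = x_star)
  if (!is.null(values)) {
    abn_side <- if (dist$direction == "increase") values >= x_star else values <= x_star
    if (!is.null(ad_mask)) out$sensitivity <- 100 * mean(abn_side[ad_mask])
    if (!is.null(cn_mask)) out$specificity <- 100 * mean(!abn_side[cn_mask])
  }
  out
}

#' Serialise a distribution set to JSON
#'
#' One record per biomarker with all five mixture parameters plus direction;
#' values survive a round trip to at least 12 significant digits.
#'
#' @param dists a `distribution_set`.
#' @param path output JSON path.
#' @export
write_distribution_set <- function(dists, path) {
  stopifnot(inherits(dists, "distribution_set"))
  recs <- lapply(unclass(dists), function(d) {
    d[c("biomarker_name", "mu_normal", "sd_normal", "mu_abnormal",
        "sd_abnormal", "weight_normal", "direction")]
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a distribution set from JSON
#'
#' @param path JSON path written by [write_distribution_set()].
#' @return a `distribution_set`.
#' @export
read_distribution_set <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- lapply(recs, function(d) {
    structure(list(biomarker_name = d$biomarker_name,
                   mu_normal = d$mu_normal, sd_normal = d$sd_normal,
                   mu_abnormal = d$mu_abnormal, sd_abnormal = d$sd_abnormal,
                   weight_normal = d$weight_normal, direction = d$direction,
                   sd_bound_normal = NA_real_, sd_bound_abnormal = NA_real_,
                   loglik = NA_real_, loglik_trace = numeric(0), n_iter = NA_integer_),
              class = "event_distribution")
  })
  names(fits) <- vapply(fits, `[[`, "", "biomarker_name")
  structure(fits, class = "distribution_set")
}
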