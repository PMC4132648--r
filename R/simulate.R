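#' Define a synthetic cohort scenario
#'
#' Describes a generative cohort with a known ground-truth event sequence and
#' per-subject stages, mirroring the structure of a sporadic-disease study:
#' a control (CN) group contaminated by presymptomatic cases (a third of
#' apparently healthy elderly individuals carry presymptomatic biomarker
#' abnormality), a patient (AD) group with a modest misdiagnosis fraction
#' drawn from stage 0, and an intermediate (MCI) group concentrated around
#' the middle stages.
#'
#' Default stage distributions mirror the cross-sectional stage histograms
#' such a cohort shows: uncontaminated CN subjects sit at stage 0;
#' contaminated (presymptomatic) CN subjects carry only early events —
#' three quarters of them at stages 1-3, the rest at stages 4-6; MCI
#' subjects follow a triangular bump over stages 1..N-1 peaking mid-course;
#' correctly diagnosed AD subjects sit mostly at the final stage (60
#' percent), with the remainder tapering over the three stages before it.
#' All distributions are overridable.
#'
#' @param n_events number of biomarker events N (default 14).
#' @param sequence_truth ground-truth event ordering (default identity).
#' @param mu_normal,sd_normal,mu_abnormal,sd_abnormal per-event component
#'   parameters, recycled to length N. `mu_abnormal = NULL` derives the
#'   abnormal mean from `separation` pooled SDs away from the normal mean in
#'   the declared direction.
#' @param separation component separation in pooled-SD units used when
#'   `mu_abnormal` is `NULL` (default 2).
#' @param direction per-event abnormality direction, recycled.
#' @param n_cn,n_mci,n_ad diagnostic group sizes (defaults 100/130/70).
#' @param contamination fraction of CN-labelled subjects drawn from nonzero
#'   stages (default 1/3).
#' @param misdiagnosis fraction of AD-labelled subjects drawn from stage 0
#'   (default 0.1).
#' @param stage_dist_cn_contaminated,stage_dist_mci,stage_dist_ad optional
#'   length-(N+1) probability vectors over stages 0..N overriding the
#'   defaults above.
#' @param biomarker_names optional names (default `bm1..bmN`).
#' @return object of class `simulation_scenario`.
#' @seealso [generate_cohort()], [generate_followup()]
#' @export
simulation_scenario <- function(n_events = 14L,
                                sequence_truth = seq_len(n_events),
                                mu_normal = 0, sd_normal = 1,
                                mu_abnormal = NULL, sd_abnormal = 1,
                                separation = 2,
                                direction = "increase",
                                n_cn = 100L, n_mci = 130L, n_ad = 70L,
                                contamination = 1 / 3, misdiagnosis = 0.1,
                                stage_dist_cn_contaminated = NULL,
                                stage_dist_mci = NULL,
                                stage_dist_ad = NULL,
                                biomarker_names = NULL) {
  N <- as.integer(n_events)
  stopifnot(N >= 1L, n_cn >= 0L, n_mci >= 0L, n_ad >= 0L,
            contamination >= 0, contamination <= 1,
            misdiagnosis >= 0, misdiagnosis <= 1)
  sequence_truth <- .assert_permutation(sequence_truth, N)
  mu_normal <- rep_len(mu_normal, N)
  sd_normal <- rep_len(sd_normal, N)
  sd_abnormal <- rep_len(sd_abnormal, N)
  direction <- rep_len(direction, N)
  stopifnot(all(direction %in% c("increase", "decrease")),
            all(sd_normal > 0), all(sd_abnormal > 0))
  if (is.null(mu_abnormal)) {
    pooled <- sqrt((sd_normal^2 + sd_abnormal^2) / 2)
    mu_abnormal <- mu_normal +
      ifelse(direction == "increase", 1, -1) * separation * pooled
  } else {
    mu_abnormal <- rep_len(mu_abnormal, N)
  }
  norm1 <- function(p) p / sum(p)
  if (is.null(stage_dist_cn_contaminated)) {
    # presymptomatic controls: early events only (mostly stages 1-3)
    p <- numeric(N + 1L)
    k1 <- pmin(1:3, N); k2 <- pmin(4:6, N)
    p[unique(k1) + 1L] <- 0.75 / length(unique(k1))
    if (N > 3L) p[setdiff(unique(k2), unique(k1)) + 1L] <-
        0.25 / length(setdiff(unique(k2), unique(k1)))
    stage_dist_cn_contaminated <- norm1(p)
  }
  if (is.null(stage_dist_mci)) {
    peak <- round(N / 2)
    tri <- pmax(0, sapply(0:N, function(k) {
      if (k < 1 || k > N - 1 || N < 2) 0
      else 1 - abs(k - peak) / max(peak, N - 1 - peak + 1)
    }))
    if (sum(tri) == 0) tri <- c(0, rep(1, N))
    stage_dist_mci <- norm1(tri)
  }
  if (is.null(stage_dist_ad)) {
    # most patients have all events; the rest taper over the last stages
    p <- numeric(N + 1L)
    p[N + 1L] <- 0.6
    tail_stages <- seq.int(max(1L, N - 3L), max(1L, N - 1L))
    p[tail_stages + 1L] <- 0.4 * c(0.25, 0.25, 0.5)[seq_along(tail_stages)]
    stage_dist_ad <- norm1(p)
  }
  for (p in list(stage_dist_cn_contaminated, stage_dist_mci, stage_dist_ad)) {
    stopifnot(length(p) == N + 1L, all(p >= 0), abs(sum(p) - 1) < 1e-9)
  }
  if (is.null(biomarker_names)) biomarker_names <- paste0("bm", seq_len(N))
  structure(list(n_events = N, sequence_truth = sequence_truth,
                 mu_normal = mu_normal, sd_normal = sd_normal,
                 mu_abnormal = mu_abnormal, sd_abnormal = sd_abnormal,
                 direction = stats::setNames(direction, biomarker_names),
                 n_cn = as.integer(n_cn), n_mci = as.integer(n_mci),
                 n_ad = as.integer(n_ad),
                 contamination = contamination, misdiagnosis = misdiagnosis,
                 stage_dist_cn_contaminated = stage_dist_cn_contaminated,
                 stage_dist_mci = stage_dist_mci,
                 stage_dist_ad = stage_dist_ad,
                 biomarker_names = biomarker_names),
            class = "simulation_scenario")
}

# Draw biomarker vectors for given true stages under a scenario.
.draw_values <- function(sc, stages) {
  N <- sc$n_events
  J <- length(stages)
  pos_of_event <- order(sc$sequence_truth)  # position of each biomarker
  vals <- matrix(0, J, N, dimnames = list(NULL, sc$biomarker_names))
  for (i in seq_len(N)) {
    abnormal <- pos_of_event[i] <= stages
    vals[, i] <- ifelse(abnormal,
                        stats::rnorm(J, sc$mu_abnormal[i], sc$sd_abnormal[i]),
                        stats::rnorm(J, sc$mu_normal[i], sc$sd_normal[i]))
  }
  vals
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each subject: draw the diagnostic label's true stage (CN subjects are
#' at stage 0 except for the contaminated fraction; AD subjects follow the
#' late-stage distribution except for the misdiagnosed fraction, placed at
#' stage 0; MCI subjects follow the mid-stage distribution), then draw every
#' biomarker from its abnormal component if its sequence position is at or
#' before the stage and from its normal component otherwise. Noise is
#' independent across biomarkers given the stage — exactly the
#' conditional-independence assumption of the model.
#'
#' @param sc a [simulation_scenario()].
#' @param seed integer seed; `NULL` uses the ambient stream.
#' @return list with `dataset` (a [biomarker_dataset()]), `truth` (data
#'   frame: `subject_id`, `diagnosis`, `stage`), and `sequence`
#'   (the ground-truth ordering).
#' @export
generate_cohort <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "simulation_scenario"))
  N <- sc$n_events
  .with_seed(seed, {
    dx <- c(rep("CN", sc$n_cn), rep("MCI", sc$n_mci), rep("AD", sc$n_ad))
    J <- length(dx)
    stages <- integer(J)
    for (j in seq_len(J)) {
      stages[j] <- switch(dx[j],
        CN = if (stats::runif(1) < sc$contamination) {
          sample(0:N, 1L, prob = sc$stage_dist_cn_contaminated)
        } else 0L,
        MCI = sample(0:N, 1L, prob = sc$stage_dist_mci),
        AD = if (stats::runif(1) < sc$misdiagnosis) 0L else {
          sample(0:N, 1L, prob = sc$stage_dist_ad)
        })
    }
    vals <- .draw_values(sc, stages)
    ds <- biomarker_dataset(vals, dx, direction = sc$direction)
    list(dataset = ds,
         truth = data.frame(subject_id = ds$subject_id, diagnosis = dx,
                            stage = stages, row.names = NULL),
         sequence = sc$sequence_truth)
  })
}

#' Generate a follow-up visit for a synthetic cohort
#'
#' Advances each subject's true stage by a non-negative increment (capped at
#' N) and redraws all biomarkers at the new stage, producing a follow-up
#' dataset with the same schema and an advanced visit label.
#'
#' @param cohort a [generate_cohort()] result.
#' @param sc the [simulation_scenario()] used to generate it.
#' @param increment per-subject stage increments: a single value, a vector,
#'   or a function `n -> integer vector` drawing them.
#' @param visit visit label for the follow-up rows (default `"m12"`).
#' @param seed integer seed.
#' @return list with `dataset` and `truth` in the same layout as
#'   [generate_cohort()].
#' @export
generate_followup <- function(cohort, sc, increment = 1L, visit = "m12",
                              seed = NULL) {
  stopifnot(inherits(sc, "simulation_scenario"))
  truth <- cohort$truth
  J <- nrow(truth)
  .with_seed(seed, {
    inc <- if (is.function(increment)) increment(J) else rep_len(increment, J)
    if (any(inc < 0)) .stopf("stage increments must be non-negative")
    new_stage <- pmin(truth$stage + as.integer(inc), sc$n_events)
    vals <- .draw_values(sc, new_stage)
    ds <- biomarker_dataset(vals, truth$diagnosis,
                            subject_id = truth$subject_id,
                            direction = sc$direction, visit = visit)
    list(dataset = ds,
         truth = data.frame(subject_id = truth$subject_id,
                            diagnosis = truth$diagnosis, stage = new_stage,
                            row.names = NULL))
  })
}

#' Kendall rank correlation between two event sequences
#'
#' Scores a recovered ordering against the truth by the Kendall tau between
#' the positions each sequence assigns to the events (1 = identical order,
#' -1 = fully reversed).
#'
#' @param seq_a,seq_b integer permutations of the same length.
#' @return scalar in `[-1, 1]`.
#' @export
sequence_kendall_tau <- function(seq_a, seq_b) {
  N <- length(seq_a)
  .assert_permutation(seq_a, N)
  .assert_permutation(seq_b, N)
  if (N < 2L) return(1)
  stats::cor(order(seq_a), order(seq_b), method = "kendall")
}
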