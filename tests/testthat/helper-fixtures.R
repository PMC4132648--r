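# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# Random positive likelihood tables (log-normal entries).
random_tables <- function(J, N, seed, sdlog = 1) {
  set.seed(seed)
  likelihood_tables(matrix(exp(rnorm(J * N, 0, sdlog)), J, N),
                    matrix(exp(rnorm(J * N, 0, sdlog)), J, N))
}

# All permutations of 1..n as rows of a matrix.
perms_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- perms_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# Literal nested-loop evaluation of the sequence likelihood in linear space:
# for each subject, average over stages k = 0..N of the product of event
# densities at positions <= k and no-event densities after.
loglik_bruteforce <- function(lt, ord) {
  J <- nrow(lt$like_event); N <- ncol(lt$like_event)
  sum(log(sapply(seq_len(J), function(j) {
    mean(sapply(0:N, function(k) {
      pre <- if (k > 0) prod(lt$like_event[j, ord[seq_len(k)]]) else 1
      post <- if (k < N) prod(lt$like_noevent[j, ord[(k + 1):N]]) else 1
      pre * post
    }))
  })))
}

# Distribution set holding the exact generating parameters of a scenario
# (the oracle distributions for staging tests).
oracle_distributions <- function(sc) {
  fits <- lapply(seq_len(sc$n_events), function(i) {
    structure(list(biomarker_name = sc$biomarker_names[i],
                   mu_normal = sc$mu_normal[i], sd_normal = sc$sd_normal[i],
                   mu_abnormal = sc$mu_abnormal[i],
                   sd_abnormal = sc$sd_abnormal[i],
                   weight_normal = 0.5, direction = unname(sc$direction[i]),
                   sd_bound_normal = NA_real_, sd_bound_abnormal = NA_real_,
                   loglik = NA_real_, loglik_trace = numeric(0),
                   n_iter = NA_integer_),
              class = "event_distribution")
  })
  names(fits) <- sc$biomarker_names
  structure(fits, class = "distribution_set")
}

# Small well-separated scenario used by several inference tests.
small_scenario <- function(n_events = 5, separation = 3, n_cn = 40,
                           n_mci = 50, n_ad = 30) {
  simulation_scenario(n_events = n_events, separation = separation,
                      n_cn = n_cn, n_mci = n_mci, n_ad = n_ad)
}

# Fit-to-sequence pipeline on a generated cohort; returns the recovered
# ordering (integer permutation).
recover_sequence <- function(cohort, n_starts = 5, seed = 1) {
  dists <- suppressWarnings(fit_event_distributions(cohort$dataset))
  lt <- event_likelihoods(cohort$dataset, dists)
  as.integer(most_likely_sequence(lt, n_starts = n_starts, seed = seed))
}

# Write a small cohort CSV + schema YAML into dir; returns paths.
write_cohort_fixture <- function(dir, sc = small_scenario(), seed = 1) {
  cohort <- generate_cohort(sc, seed = seed)
  csv <- file.path(dir, "cohort.csv")
  schema <- write_biomarker_table(cohort$dataset, csv)
  schema_path <- file.path(dir, "schema.yaml")
  yaml::write_yaml(schema, schema_path)
  list(csv = csv, schema = schema_path, cohort = cohort)
}
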