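test_that("sequence likelihood matches closed forms in tiny cases", {
  # one subject, one biomarker: average of the two stage likelihoods
  lt <- likelihood_tables(matrix(0.3), matrix(0.8))
  expect_equal(log_likelihood_sequence(lt, 1L), log((0.3 + 0.8) / 2),
               tolerance = 1e-12)

  # identical tables: every permutation gives the same value
  lt2 <- likelihood_tables(matrix(0.4, 6, 4), matrix(0.4, 6, 4))
  lls <- apply(perms_of(4), 1, function(p) log_likelihood_sequence(lt2, p))
  expect_equal(max(lls) - min(lls), 0, tolerance = 1e-12)

  expect_error(log_likelihood_sequence(lt2, c(1, 2, 3, 3)), "permutation")
})

test_that("log-domain evaluation matches the nested-loop linear-space oracle", {
  for (s in 1:10) {
    lt <- random_tables(J = 5, N = 3, seed = s)
    for (p in list(c(1L, 2L, 3L), c(3L, 1L, 2L), c(2L, 3L, 1L))) {
      ref <- loglik_bruteforce(lt, p)
      expect_equal(log_likelihood_sequence(lt, p), ref,
                   tolerance = 1e-10 * abs(ref))
    }
  }
})

test_that("greedy ascent finds the exhaustive argmax on small problems", {
  for (s in 1:10) {
    set.seed(s)
    N <- sample(2:5, 1)
    lt <- random_tables(J = 40, N = N, seed = s + 100)
    allp <- perms_of(N)
    lls <- apply(allp, 1, function(p) log_likelihood_sequence(lt, p))
    ml <- most_likely_sequence(lt, n_starts = 5, seed = s)
    expect_equal(attr(ml, "loglik"), max(lls), tolerance = 1e-12)
    expect_identical(as.integer(ml), as.integer(allp[which.max(lls), ]))
  }
})

test_that("two-event data favouring one order recovers it", {
  # subjects abnormal in biomarker 1 but not 2: event 1 must come first
  le <- cbind(rep(1.0, 10), rep(0.05, 10))
  ln <- cbind(rep(0.05, 10), rep(1.0, 10))
  lt <- likelihood_tables(le, ln)
  expect_gt(log_likelihood_sequence(lt, c(1L, 2L)),
            log_likelihood_sequence(lt, c(2L, 1L)))
  expect_identical(as.integer(most_likely_sequence(lt, n_starts = 3, seed = 1)),
                   c(1L, 2L))
})

test_that("flat likelihood tables are flagged as degenerate", {
  lt <- likelihood_tables(matrix(0.5, 8, 4), matrix(0.5, 8, 4))
  ml <- most_likely_sequence(lt, n_starts = 2, seed = 1)
  expect_true(attr(ml, "degenerate"))
})

test_that("the ML sequence likelihood is invariant to subject row order", {
  lt <- random_tables(J = 30, N = 4, seed = 9)
  set.seed(1)
  shuf <- sample(30)
  lt2 <- likelihood_tables(lt$like_event[shuf, ], lt$like_noevent[shuf, ])
  ml1 <- most_likely_sequence(lt, n_starts = 4, seed = 2)
  ml2 <- most_likely_sequence(lt2, n_starts = 4, seed = 2)
  expect_equal(attr(ml1, "loglik"), attr(ml2, "loglik"), tolerance = 1e-10)
})

test_that("MCMC sampling is reproducible and doubly stochastic", {
  lt <- random_tables(J = 15, N = 4, seed = 3)
  a <- mcmc_sequences(lt, init = 1:4, n_samples = 500, burn_in = 100, seed = 5)
  b <- mcmc_sequences(lt, init = 1:4, n_samples = 500, burn_in = 100, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_identical(a$ml_sequence, b$ml_sequence)
  pv <- a$positional_variance
  expect_equal(unname(rowSums(pv)), rep(1, 4), tolerance = 1e-9)
  expect_equal(unname(colSums(pv)), rep(1, 4), tolerance = 1e-9)
  expect_gte(a$ml_loglik, max(a$log_liks))
})

test_that("strong separation concentrates the posterior on the true order", {
  sc <- small_scenario(separation = 3)
  cohort <- generate_cohort(sc, seed = 21)
  dists <- suppressWarnings(fit_event_distributions(cohort$dataset))
  lt <- event_likelihoods(cohort$dataset, dists)
  ml <- most_likely_sequence(lt, n_starts = 5, seed = 21)
  post <- mcmc_sequences(lt, init = as.integer(ml), n_samples = 3000,
                         burn_in = 500, seed = 21)
  diag_mass <- mean(post$positional_variance[cbind(post$ml_sequence,
                                                   seq_len(5))])
  expect_gt(diag_mass, 0.9)
  expect_equal(sequence_kendall_tau(post$ml_sequence, cohort$sequence), 1)
})

test_that("posterior serialisation writes the expected artifacts", {
  lt <- random_tables(J = 10, N = 3, seed = 2)
  post <- mcmc_sequences(lt, init = 1:3, n_samples = 200, burn_in = 50, seed = 1)
  dir <- withr::local_tempdir()
  write_sequence_posterior(post, dir)
  expect_true(file.exists(file.path(dir, "ml_sequence.json")))
  pv <- as.matrix(read.csv(file.path(dir, "positional_variance.csv"),
                           row.names = 1))
  expect_equal(unname(pv), unname(post$positional_variance), tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$n_samples, 200)
})
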