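test_that("constrained EM recovers a well-separated two-mode mixture", {
  set.seed(101)
  comp <- rbinom(500, 1, 0.5)
  x <- ifelse(comp == 1, rnorm(500, 4, 1), rnorm(500, 0, 1))
  d <- fit_event_distribution(x, comp == 0, comp == 1, "increase")
  expect_lt(abs(d$mu_normal - 0), 0.2)
  expect_lt(abs(d$mu_abnormal - 4), 0.2)
  expect_lt(abs(d$weight_normal - 0.5), 0.1)
  # constraint satisfied
  expect_lte(d$sd_normal, sd(x[comp == 0]) + 1e-12)
  expect_lte(d$sd_abnormal, sd(x[comp == 1]) + 1e-12)
  # EM log-likelihood is monotone non-decreasing
  expect_true(all(diff(d$loglik_trace) > -1e-8))
})

test_that("SD constraint binds when the labelled group is tight", {
  set.seed(7)
  # low mode is wide, but the CN label marks only a tight subcluster
  low <- rnorm(150, 0, 1)
  tight <- rnorm(30, 0, 0.1)
  high <- rnorm(100, 4, 1)
  x <- c(low, tight, high)
  cn <- c(rep(FALSE, 150), rep(TRUE, 30), rep(FALSE, 100))
  ad <- c(rep(FALSE, 180), rep(TRUE, 100))
  d <- fit_event_distribution(x, cn, ad, "increase")
  expect_lte(d$sd_normal, sd(x[cn]) + 1e-12)
  expect_equal(d$sd_normal, sd(x[cn]), tolerance = 1e-8)  # pinned at bound
})

test_that("two components never fit worse than one (nesting)", {
  set.seed(5)
  x <- rnorm(200, 1, 2)
  cn <- seq_along(x) <= 80
  ad <- seq_along(x) > 120
  d <- fit_event_distribution(x, cn, ad, "increase")
  # single-normal ML log-likelihood (MLE variance uses 1/n)
  ll1 <- sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
  expect_gte(d$loglik, ll1 - 1e-6)
})

test_that("mixture parameter recovery is stable over seeded replicates", {
  errs <- sapply(1:20, function(s) {
    set.seed(s)
    comp <- rbinom(500, 1, 0.5)
    x <- ifelse(comp == 1, rnorm(500, 4, 1), rnorm(500, 0, 1))
    d <- fit_event_distribution(x, comp == 0, comp == 1, "increase")
    expect_lte(d$sd_normal, sd(x[comp == 0]) + 1e-12)
    expect_lte(d$sd_abnormal, sd(x[comp == 1]) + 1e-12)
    c(abs(d$mu_normal), abs(d$mu_abnormal - 4),
      abs(d$sd_normal - 1), abs(d$sd_abnormal - 1))
  })
  expect_lt(median(errs), 0.15)
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_event_distribution(rep(1, 20), rep(c(TRUE, FALSE), 10),
                                      rep(c(FALSE, TRUE), 10), "increase"),
               "identical")
  expect_error(fit_event_distribution(rnorm(20), c(TRUE, rep(FALSE, 19)),
                                      rep(TRUE, 20), "increase"),
               "at least 2")
})

test_that("event likelihood tables evaluate the raw component densities", {
  vals <- matrix(c(2, 1, 0), 3, 1, dimnames = list(NULL, "m"))
  ds <- biomarker_dataset(vals, c("AD", "MCI", "CN"))
  d <- structure(list(biomarker_name = "m", mu_normal = 0, sd_normal = 1,
                      mu_abnormal = 2, sd_abnormal = 1, weight_normal = 0.7,
                      direction = "increase"), class = "event_distribution")
  dl <- structure(list(m = d), class = "distribution_set")
  lt <- event_likelihoods(ds, dl)
  # at the abnormal mean the event density is the normal peak
  expect_equal(unname(lt$like_event[1, 1]), 1 / sqrt(2 * pi), tolerance = 1e-12)
  # at the midpoint of equal-SD components the two densities agree
  expect_equal(unname(lt$like_event[2, 1]), unname(lt$like_noevent[2, 1]), tolerance = 1e-12)
  # mixing weight plays no role and all entries are strictly positive
  expect_true(all(lt$like_event > 0 & lt$like_noevent > 0))
  # extreme value is floored, not zero or -Inf
  ds2 <- biomarker_dataset(matrix(1e6, 1, 1, dimnames = list(NULL, "m")), "CN")
  lt2 <- event_likelihoods(ds2, dl)
  expect_true(is.finite(lt2$log_like_event[1, 1]))
  expect_gt(lt2$like_event[1, 1], 0)

  bad <- ds; bad$biomarker_names <- "other"; colnames(bad$values) <- "other"
  expect_error(event_likelihoods(bad, dl), "lacks")
})

test_that("cut points solve the posterior-0.5 equation", {
  d <- structure(list(biomarker_name = "m", mu_normal = 0, sd_normal = 1,
                      mu_abnormal = 4, sd_abnormal = 1, weight_normal = 0.5,
                      direction = "increase"), class = "event_distribution")
  expect_equal(compute_cutpoint(d)$cutpoint, 2, tolerance = 1e-9)

  # unequal weights shift the cut point toward the abnormal mean
  d75 <- d; d75$weight_normal <- 0.75
  cp <- compute_cutpoint(d75)$cutpoint
  expect_gt(cp, 2)
  # grid-scan oracle of the posterior crossing
  grid <- seq(0, 4, by = 1e-4)
  post <- 0.25 * dnorm(grid, 4, 1) /
    (0.75 * dnorm(grid, 0, 1) + 0.25 * dnorm(grid, 4, 1))
  oracle <- grid[which.min(abs(post - 0.5))]
  expect_equal(cp, oracle, tolerance = 1e-3)

  # sensitivity / specificity on labelled values
  set.seed(2)
  x <- c(rnorm(100, 0, 1), rnorm(100, 4, 1))
  cn <- rep(c(TRUE, FALSE), each = 100)
  res <- compute_cutpoint(d, values = x, cn_mask = cn, ad_mask = !cn)
  expect_gt(res$sensitivity, 90)
  expect_gt(res$specificity, 90)

  same <- d; same$mu_abnormal <- 0
  expect_error(compute_cutpoint(same), "identical|crossing")
})

test_that("distribution sets survive a JSON round trip", {
  sc <- small_scenario()
  cohort <- generate_cohort(sc, seed = 4)
  dists <- suppressWarnings(fit_event_distributions(cohort$dataset))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_distribution_set(dists, tmp)
  back <- read_distribution_set(tmp)
  for (bm in names(dists)) {
    for (f in c("mu_normal", "sd_normal", "mu_abnormal", "sd_abnormal",
                "weight_normal")) {
      expect_equal(back[[bm]][[f]], dists[[bm]][[f]], tolerance = 1e-12)
    }
  }
})
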