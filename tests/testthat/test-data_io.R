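test_that("dataset construction validates labels, names and completeness", {
  vals <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("ABETA", "TAU")))
  ds <- biomarker_dataset(vals, c("CN", "MCI", "AD"))
  expect_identical(dim(ds), c(3L, 2L))
  expect_identical(ds$biomarker_names, c("ABETA", "TAU"))

  expect_error(biomarker_dataset(vals, c("CN", "Dementia", "AD")), "Dementia")
  vals_na <- vals; vals_na[2, 1] <- NA
  expect_error(biomarker_dataset(vals_na, c("CN", "MCI", "AD")), "complete")
  expect_error(biomarker_dataset(vals, c("CN", "MCI", "AD"),
                                 subject_id = c("a", "a", "b")), "duplicate")
  dup <- vals; colnames(dup) <- c("x", "x")
  expect_error(biomarker_dataset(dup, c("CN", "MCI", "AD")), "unique")
})

test_that("CSV reading honours the schema, strict and lenient modes", {
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "t.csv")
  writeLines(c("id,dx,ABETA,TAU",
               "s1,CN,210,60",
               "s2,MCI,150,90",
               "s3,AD,120,140"), csv)
  schema <- list(id = "id", diagnosis = "dx", biomarkers = c("ABETA", "TAU"))
  ds <- read_biomarker_table(csv, schema)
  expect_identical(dim(ds), c(3L, 2L))
  expect_equal(ds$values[, "TAU"], c(60, 90, 140))
  expect_identical(ds$subject_id, c("s1", "s2", "s3"))

  # schema from a YAML file behaves identically
  sy <- file.path(tmp, "schema.yaml")
  yaml::write_yaml(schema, sy)
  expect_equal(read_biomarker_table(csv, sy)$values, ds$values)

  writeLines(c("id,dx,ABETA,TAU",
               "s1,CN,210,60",
               "s2,MCI,150,",
               "s3,AD,120,140"), csv)
  expect_error(read_biomarker_table(csv, schema, mode = "strict"), "row")
  expect_warning(ds2 <- read_biomarker_table(csv, schema, mode = "lenient"),
                 "dropped 1")
  expect_identical(dim(ds2), c(2L, 2L))

  writeLines(c("id,dx,ABETA,TAU", "s1,Dementia,210,60"), csv)
  expect_error(read_biomarker_table(csv, schema), "Dementia")
})

test_that("write/read round trip reproduces values exactly", {
  sc <- small_scenario()
  cohort <- generate_cohort(sc, seed = 11)
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "c.csv")
  schema <- write_biomarker_table(cohort$dataset, csv)
  back <- read_biomarker_table(csv, schema)
  expect_equal(unname(back$values), unname(cohort$dataset$values), tolerance = 0)
  expect_identical(back$diagnosis, cohort$dataset$diagnosis)
  expect_identical(back$direction, cohort$dataset$direction)
})

test_that("preprocessing applies log and percent-of-TIV transforms", {
  vals <- matrix(c(100, 50, 6.0, 5.5), 2, 2,
                 dimnames = list(NULL, c("TAU", "HIPPO")))
  ds <- biomarker_dataset(vals, c("CN", "AD"),
                          covariates = data.frame(TIV = c(1500, 1400)))
  out <- preprocess_biomarkers(ds, log_transform = "TAU",
                               tiv_normalize = "HIPPO", tiv = "TIV")
  expect_equal(unname(out$values[1, "TAU"]), log(100), tolerance = 1e-12)
  expect_equal(unname(out$values[1, "TAU"]), 4.6052, tolerance = 1e-4)
  expect_equal(unname(out$values[1, "HIPPO"]), 0.40, tolerance = 1e-12)  # 100*6/1500

  # empty transform sets: identical object
  expect_identical(preprocess_biomarkers(ds), ds)

  neg <- ds; neg$values[1, "TAU"] <- -1
  expect_error(preprocess_biomarkers(neg, log_transform = "TAU"), "non-positive")
  expect_error(preprocess_biomarkers(ds, tiv_normalize = "HIPPO", tiv = "nope"),
               "not found")
})

test_that("preprocessing commutes with row subsetting", {
  sc <- small_scenario()
  cohort <- generate_cohort(sc, seed = 3)
  ds <- cohort$dataset
  ds$values <- abs(ds$values) + 1  # make log-transformable
  keep <- c(2, 5, 9, 40)
  a <- preprocess_biomarkers(subset_rows(ds, keep), log_transform = "bm1")
  b <- subset_rows(preprocess_biomarkers(ds, log_transform = "bm1"), keep)
  expect_equal(a$values, b$values, tolerance = 0)
})

test_that("subgroup selection applies the strict 192 pg/ml and APOE4 rules", {
  vals <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  ds <- biomarker_dataset(vals, c("CN", "MCI", "AD", "CN"),
                          covariates = data.frame(ABETA = c(150, 192, 250, 100),
                                                  APOE4 = c(1, 0, 1, 0)))
  amy <- select_subgroup(ds, "amyloid+")
  expect_identical(amy$subject_id, c("s1", "s4"))  # 192 itself excluded
  apoe <- select_subgroup(ds, "apoe+")
  expect_identical(apoe$subject_id, c("s1", "s3"))
  both <- select_subgroup(ds, "amyloid+apoe+")
  expect_identical(both$subject_id, "s1")
  expect_identical(select_subgroup(ds, "whole"), ds)

  # idempotence
  expect_identical(select_subgroup(amy, "amyloid+")$values, amy$values)

  no_cov <- biomarker_dataset(vals, c("CN", "MCI", "AD", "CN"))
  expect_error(select_subgroup(no_cov, "amyloid+"), "requires covariate")
})
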