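#' Construct a biomarker dataset
#'
#' Bundles a subjects-by-biomarkers matrix of continuous measurements with the
#' per-subject diagnostic labels and optional covariates and visit labels that
#' the event-based model consumes. Missing biomarker values are not supported:
#' the model requires a complete measurement vector per subject.
#'
#' @param values numeric matrix or data frame, J subjects by N biomarkers,
#'   with unique column names. No missing entries.
#' @param diagnosis character or factor of length J with levels among
#'   `"CN"`, `"MCI"`, `"AD"` (cognitively normal, mild cognitive impairment,
#'   Alzheimer's disease).
#' @param subject_id optional vector of length J of subject identifiers;
#'   defaults to `s1..sJ`.
#' @param direction per-biomarker direction of abnormality: `"increase"` if
#'   disease raises the value (e.g. CSF tau, ventricular volume), `"decrease"`
#'   if disease lowers it (e.g. CSF amyloid-beta, hippocampal volume). A
#'   single value is recycled; a named vector is matched to biomarker names.
#' @param covariates optional data frame of per-subject covariates (age, sex,
#'   education, APOE4 carrier flag, raw CSF amyloid-beta, total intracranial
#'   volume, ...), J rows.
#' @param visit optional per-row visit label; `"baseline"` is the default.
#' @return An object of class `biomarker_dataset`: a list with elements
#'   `values`, `diagnosis`, `subject_id`, `direction`, `covariates`, `visit`,
#'   `biomarker_names`.
#' @seealso [read_biomarker_table()], [preprocess_biomarkers()],
#'   [select_subgroup()]
#' @export
biomarker_dataset <- function(values, diagnosis, subject_id = NULL,
                              direction = "increase", covariates = NULL,
                              visit = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("bm", seq_len(ncol(values)))
  }
  J <- nrow(values)
  N <- ncol(values)
  if (J < 1L || N < 1L) .stopf("dataset needs at least one subject and one biomarker")
  if (anyDuplicated(colnames(values))) .stopf("biomarker names must be unique")
  if (anyNA(values) || any(!is.finite(values))) {
    .stopf("biomarker values must be complete and finite (missing data unsupported)")
  }
  diagnosis <- as.character(diagnosis)
  if (length(diagnosis) != J) .stopf("'diagnosis' must have one label per subject")
  bad <- setdiff(unique(diagnosis), c("CN", "MCI", "AD"))
  if (length(bad)) {
    .stopf("unknown diagnosis label(s): %s (allowed: CN, MCI, AD)",
           paste(bad, collapse = ", "))
  }
  if (is.null(subject_id)) subject_id <- paste0("s", seq_len(J))
  subject_id <- as.character(subject_id)
  if (length(subject_id) != J) .stopf("'subject_id' must have length %d", J)
  if (is.null(visit)) visit <- rep("baseline", J)
  visit <- as.character(rep_len(visit, J))
  if (anyDuplicated(paste(subject_id, visit, sep = "\r"))) {
    .stopf("duplicate (subject, visit) pairs are not allowed")
  }
  if (is.null(names(direction))) {
    direction <- stats::setNames(rep_len(direction, N), colnames(values))
  } else {
    missing_dir <- setdiff(colnames(values), names(direction))
    if (length(missing_dir)) {
      .stopf("no direction declared for biomarker(s): %s",
             paste(missing_dir, collapse = ", "))
    }
    direction <- direction[colnames(values)]
  }
  if (!all(direction %in% c("increase", "decrease"))) {
    .stopf("direction values must be 'increase' or 'decrease'")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != J) .stopf("'covariates' must have %d rows", J)
  }
  structure(list(values = values, diagnosis = diagnosis,
                 subject_id = subject_id, direction = direction,
                 covariates = covariates, visit = visit,
                 biomarker_names = colnames(values)),
            class = "biomarker_dataset")
}

#' @export
print.biomarker_dataset <- function(x, ...) {
  cat(sprintf("Biomarker dataset: %d subjects x %d biomarkers\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(factor(x$diagnosis, levels = c("CN", "MCI", "AD")))
  cat(sprintf("  diagnosis: CN %d / MCI %d / AD %d\n", tab[1], tab[2], tab[3]))
  cat("  biomarkers:", paste(x$biomarker_names, collapse = ", "), "\n")
  if (!is.null(x$covariates)) {
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.biomarker_dataset <- function(x) dim(x$values)

# Row subset of a dataset, keeping all per-subject metadata aligned.
#' Subset a biomarker dataset by row
#'
#' @param ds a [biomarker_dataset()].
#' @param i row (subject) index vector.
#' @return the subset as a `biomarker_dataset`.
#' @export
subset_rows <- function(ds, i) {
  stopifnot(inherits(ds, "biomarker_dataset"))
  biomarker_dataset(ds$values[i, , drop = FALSE], ds$diagnosis[i],
                    subject_id = ds$subject_id[i], direction = ds$direction,
                    covariates = if (!is.null(ds$covariates)) ds$covariates[i, , drop = FALSE],
                    visit = ds$visit[i])
}

#' Read a biomarker table from CSV
#'
#' Reads a CSV with a header row and a schema mapping columns to roles, and
#' returns a validated [biomarker_dataset()]. Row order is preserved. Rows
#' with a missing or non-numeric biomarker value are an error in `"strict"`
#' mode and are dropped with a warning in `"lenient"` mode.
#'
#' @param path path to a CSV file (UTF-8, header row).
#' @param schema a list (or path to a YAML/JSON file encoding one) with
#'   elements: `id` (column name), `diagnosis` (column name), `biomarkers`
#'   (character vector of column names), and optionally `visit` (column
#'   name), `covariates` (character vector of column names), `direction`
#'   (named character vector or single value, see [biomarker_dataset()]).
#' @param mode `"strict"` (default) or `"lenient"` handling of incomplete
#'   biomarker rows.
#' @return a `biomarker_dataset`.
#' @export
read_biomarker_table <- function(path, schema, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  schema <- .load_schema(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(schema$id, schema$diagnosis, schema$biomarkers,
              schema$visit, schema$covariates)
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    .stopf("schema names column(s) absent from '%s': %s", path,
           paste(absent, collapse = ", "))
  }
  vals <- df[, schema$biomarkers, drop = FALSE]
  num <- vapply(vals, function(col) suppressWarnings(as.numeric(col)), numeric(nrow(df)))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(NULL, schema$biomarkers))
  bad_row <- apply(num, 1L, function(r) anyNA(r) | any(!is.finite(r)))
  if (any(bad_row)) {
    if (mode == "strict") {
      .stopf("missing or non-numeric biomarker value in row(s): %s",
             paste(which(bad_row), collapse = ", "))
    }
    warning(sprintf("dropped %d row(s) with incomplete biomarker values",
                    sum(bad_row)), call. = FALSE)
  }
  keep <- !bad_row
  dx <- as.character(df[[schema$diagnosis]])[keep]
  bad_dx <- which(!dx %in% c("CN", "MCI", "AD"))
  if (length(bad_dx)) {
    .stopf("unknown diagnosis label '%s' in row %d", dx[bad_dx[1]], bad_dx[1])
  }
  covs <- if (length(schema$covariates)) df[keep, schema$covariates, drop = FALSE]
  biomarker_dataset(num[keep, , drop = FALSE], dx,
                    subject_id = as.character(df[[schema$id]])[keep],
                    direction = if (is.null(schema$direction)) "increase" else unlist(schema$direction),
                    covariates = covs,
                    visit = if (!is.null(schema$visit)) as.character(df[[schema$visit]])[keep])
}

.load_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L) {
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE)) {
      jsonlite::read_json(schema, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(schema)
    }
  }
  if (!is.list(schema) || is.null(schema$id) || is.null(schema$diagnosis) ||
      is.null(schema$biomarkers)) {
    .stopf("schema must provide 'id', 'diagnosis' and 'biomarkers'")
  }
  if (!is.null(schema$direction)) {
    dn <- unlist(schema$direction)
    schema$direction <- dn
  }
  schema
}

#' Write a biomarker dataset to CSV
#'
#' Canonical CSV export: id, diagnosis, visit, covariates, then biomarker
#' columns at full double precision, so that a write/read round trip
#' reproduces the values exactly.
#'
#' @param ds a [biomarker_dataset()].
#' @param path output CSV path.
#' @return invisibly, the schema list matching the written file (usable with
#'   [read_biomarker_table()]).
#' @export
write_biomarker_table <- function(ds, path) {
  stopifnot(inherits(ds, "biomarker_dataset"))
  df <- data.frame(id = ds$subject_id, dx = ds$diagnosis, visit = ds$visit,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(ds$covariates)) df <- cbind(df, ds$covariates)
  vals <- as.data.frame(ds$values)
  for (j in seq_along(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  df <- cbind(df, vals)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(list(id = "id", diagnosis = "dx", visit = "visit",
                 covariates = if (!is.null(ds$covariates)) names(ds$covariates),
                 biomarkers = ds$biomarker_names,
                 direction = as.list(ds$direction)))
}

#' Preprocess biomarker columns
#'
#' Applies the standard per-biomarker transforms: natural-log transform of
#' skewed positive markers (e.g. CSF total and phosphorylated tau, to improve
#' normality) and normalisation of regional volumes by total intracranial
#' volume (TIV), stored as percent of TIV (100 x volume / TIV). All other
#' columns are untouched; the transforms are per-row, so preprocessing
#' commutes with subject subsetting.
#'
#' @param ds a [biomarker_dataset()].
#' @param log_transform character vector of biomarker names to replace by
#'   their natural logarithm; values must be strictly positive.
#' @param tiv_normalize named character vector: names are biomarker (volume)
#'   columns, values the covariate column holding each subject's TIV. An
#'   unnamed vector uses `tiv` for every listed biomarker.
#' @param tiv default TIV covariate column name, used when `tiv_normalize`
#'   is unnamed.
#' @return the transformed `biomarker_dataset`.
#' @export
preprocess_biomarkers <- function(ds, log_transform = character(),
                                  tiv_normalize = character(), tiv = "TIV") {
  stopifnot(inherits(ds, "biomarker_dataset"))
  vals <- ds$values
  unknown <- setdiff(log_transform, colnames(vals))
  if (length(unknown)) .stopf("log_transform names unknown biomarker(s): %s",
                              paste(unknown, collapse = ", "))
  for (bm in log_transform) {
    if (any(vals[, bm] <= 0)) {
      .stopf("biomarker '%s' has non-positive values; cannot log transform", bm)
    }
    vals[, bm] <- log(vals[, bm])
  }
  if (length(tiv_normalize)) {
    if (is.null(names(tiv_normalize))) {
      tiv_normalize <- stats::setNames(rep(tiv, length(tiv_normalize)), tiv_normalize)
    }
    unknown <- setdiff(names(tiv_normalize), colnames(vals))
    if (length(unknown)) .stopf("tiv_normalize names unknown biomarker(s): %s",
                                paste(unknown, collapse = ", "))
    for (bm in names(tiv_normalize)) {
      tc <- tiv_normalize[[bm]]
      if (is.null(ds$covariates) || !tc %in% names(ds$covariates)) {
        .stopf("TIV column '%s' not found among covariates", tc)
      }
      tv <- ds$covariates[[tc]]
      if (anyNA(tv) || any(tv <= 0)) .stopf("TIV column '%s' must be positive and complete", tc)
      vals[, bm] <- 100 * vals[, bm] / tv
    }
  }
  out <- ds
  out$values <- vals
  out
}

#' Select a population subgroup
#'
#' Row subsets matching the standard subgrouping rules: `"amyloid+"` keeps
#' subjects whose raw CSF amyloid-beta 1-42 is strictly below 192 pg/ml (the
#' autopsy-derived cut point), `"apoe+"` keeps APOE4 allele carriers,
#' `"amyloid+apoe+"` requires both, `"whole"` keeps every subject.
#'
#' @param ds a [biomarker_dataset()].
#' @param rule one of `"whole"`, `"amyloid+"`, `"apoe+"`, `"amyloid+apoe+"`.
#' @param amyloid_col covariate column with the raw (untransformed) CSF
#'   amyloid-beta value in pg/ml.
#' @param apoe_col covariate column with the APOE4 carrier flag (logical or
#'   0/1).
#' @return the subset as a `biomarker_dataset`.
#' @export
select_subgroup <- function(ds, rule = c("whole", "amyloid+", "apoe+", "amyloid+apoe+"),
                            amyloid_col = "ABETA", apoe_col = "APOE4") {
  stopifnot(inherits(ds, "biomarker_dataset"))
  rule <- match.arg(rule)
  if (rule == "whole") return(ds)
  need_amyloid <- rule %in% c("amyloid+", "amyloid+apoe+")
  need_apoe <- rule %in% c("apoe+", "amyloid+apoe+")
  keep <- rep(TRUE, nrow(ds$values))
  if (need_amyloid) {
    if (is.null(ds$covariates) || !amyloid_col %in% names(ds$covariates)) {
      .stopf("subgroup '%s' requires covariate '%s'", rule, amyloid_col)
    }
    keep <- keep & (ds$covariates[[amyloid_col]] < 192)
  }
  if (need_apoe) {
    if (is.null(ds$covariates) || !apoe_col %in% names(ds$covariates)) {
      .stopf("subgroup '%s' requires covariate '%s'", rule, apoe_col)
    }
    keep <- keep & (as.logical(ds$covariates[[apoe_col]]))
  }
  subset_rows(ds, which(keep))
}
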