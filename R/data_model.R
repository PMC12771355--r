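# Study data model and CSV I/O.
#
# Long-format exchange schema (`pairs.csv`):
#   patient_id,timepoint,method,co_l_min[,height_cm,weight_kg]
# with method in {test, reference}. Timepoints are labelled 1..5 (or any
# positive integers), never 0-based. Missing values are empty cells.

.PAIR_COLS <- c("patient_id", "timepoint", "method", "co_l_min")

#' Assemble a paired study dataset from a long-format CSV
#'
#' Reads paired cardiac-output measurements and assembles one
#' (test, reference) observation per patient x timepoint. When biometrics are
#' available (embedded `height_cm`/`weight_kg` columns or a separate
#' biometrics table) the CO values are indexed to body surface area via the
#' Mosteller formula; otherwise the `co_l_min` column is taken to be
#' already-indexed values. Rows whose partner method is missing are retained
#' in a side table of orphans with a warning, never silently dropped.
#'
#' @param path Path to the long-format CSV (see schema above).
#' @param biometrics Optional data frame with columns `patient_id`,
#'   `height_cm`, `weight_kg` (and optionally `age_yr`, `asa_class`);
#'   overrides embedded columns.
#' @return An object of class `study_dataset`: a list with
#'   `observations` (data frame: `patient_id`, `timepoint`, `ci_test`,
#'   `ci_ref`, `difference`, `mean_pair`), `patients` (biometrics or ids),
#'   and `orphans` (unpaired rows).
#' @export
read_pairs <- function(path, biometrics = NULL) {
  if (!file.exists(path)) stop("read_pairs: file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.PAIR_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_pairs: schema error, missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  assemble_pairs(raw, biometrics = biometrics)
}

#' Assemble pairs from an in-memory long table
#'
#' Workhorse behind [read_pairs()]; accepts the long data frame directly.
#'
#' @param long Data frame with the `pairs.csv` columns.
#' @param biometrics Optional biometrics data frame (see [read_pairs()]).
#' @return A `study_dataset`; see [read_pairs()].
#' @export
assemble_pairs <- function(long, biometrics = NULL) {
  long <- long[!is.na(long$co_l_min), , drop = FALSE]
  if (!all(long$method %in% c("test", "reference"))) {
    bad <- setdiff(unique(long$method), c("test", "reference"))
    stop("assemble_pairs: unknown method label(s): ",
         paste(bad, collapse = ", "), " (expected 'test'/'reference')")
  }
  if (any(long$co_l_min <= 0)) {
    stop("assemble_pairs: cardiac output values must be positive")
  }
  key <- paste(long$patient_id, long$timepoint, long$method, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- long[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "assemble_pairs: integrity error, duplicate (patient %s, timepoint %s, method %s)",
      dup$patient_id, dup$timepoint, dup$method))
  }

  # biometrics: explicit table wins over embedded columns
  if (is.null(biometrics) && all(c("height_cm", "weight_kg") %in% names(long))) {
    biometrics <- unique(long[, c("patient_id", "height_cm", "weight_kg")])
    if (anyDuplicated(biometrics$patient_id)) {
      stop("assemble_pairs: inconsistent height/weight within a patient")
    }
  }

  co2ci <- function(df) {
    if (is.null(biometrics)) return(df$co_l_min)
    i <- match(df$patient_id, biometrics$patient_id)
    if (anyNA(i)) {
      stop("assemble_pairs: patient(s) without biometrics: ",
           paste(unique(df$patient_id[is.na(i)]), collapse = ", "))
    }
    bsa <- mosteller_bsa(biometrics$height_cm[i], biometrics$weight_kg[i])
    cardiac_index(df$co_l_min, bsa)
  }

  tst <- long[long$method == "test", , drop = FALSE]
  ref <- long[long$method == "reference", , drop = FALSE]
  ktst <- paste(tst$patient_id, tst$timepoint, sep = "\r")
  kref <- paste(ref$patient_id, ref$timepoint, sep = "\r")
  common <- intersect(ktst, kref)

  it <- match(common, ktst)
  ir <- match(common, kref)
  ci_test <- co2ci(tst[it, , drop = FALSE])
  ci_ref <- co2ci(ref[ir, , drop = FALSE])
  obs <- data.frame(
    patient_id = tst$patient_id[it],
    timepoint = tst$timepoint[it],
    ci_test = ci_test,
    ci_ref = ci_ref,
    difference = ci_test - ci_ref,
    mean_pair = (ci_test + ci_ref) / 2,
    stringsAsFactors = FALSE
  )
  obs <- obs[order(obs$patient_id, obs$timepoint), , drop = FALSE]
  rownames(obs) <- NULL

  orphans <- rbind(
    tst[!(ktst %in% common), .PAIR_COLS, drop = FALSE],
    ref[!(kref %in% common), .PAIR_COLS, drop = FALSE]
  )
  rownames(orphans) <- NULL
  if (nrow(orphans) > 0) {
    warning(sprintf("assemble_pairs: %d unpaired observation(s) retained as orphans",
                    nrow(orphans)), call. = FALSE)
  }

  patients <- if (is.null(biometrics)) {
    data.frame(patient_id = unique(long$patient_id), stringsAsFactors = FALSE)
  } else {
    biometrics
  }
  structure(
    list(observations = obs, patients = patients, orphans = orphans),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Paired method-comparison dataset\n")
  cat(sprintf("  patients:     %d\n", nrow(x$patients)))
  cat(sprintf("  paired obs:   %d\n", nrow(x$observations)))
  cat(sprintf("  orphan rows:  %d\n", nrow(x$orphans)))
  invisible(x)
}

#' Write a paired dataset back to the long-format CSV
#'
#' Inverse of [read_pairs()] for the paired part: each observation becomes a
#' `test` and a `reference` row carrying the cardiac-index values in
#' `co_l_min` (the schema column; when no biometrics are attached index and
#' output coincide). Full-precision values are written so that a read/write
#' round trip reproduces `difference` and `mean_pair` bit-exactly.
#'
#' @param dataset A `study_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(dataset, path) {
  obs <- dataset$observations
  long <- data.frame(
    patient_id = rep(obs$patient_id, 2L),
    timepoint = rep(obs$timepoint, 2L),
    method = rep(c("test", "reference"), each = nrow(obs)),
    co_l_min = c(obs$ci_test, obs$ci_ref),
    stringsAsFactors = FALSE
  )
  long <- long[order(long$patient_id, long$timepoint, long$method), ]
  # %.17g survives the decimal round trip bit-exactly for doubles
  long$co_l_min <- sprintf("%.17g", long$co_l_min)
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expected pair count after attrition
#'
#' `n_patients * n_timepoints - n_lost` complete measurement sets.
#'
#' @param n_patients,n_timepoints,n_lost Non-negative integers;
#'   `n_lost <= n_patients * n_timepoints`.
#' @return Integer pair count.
#' @examples
#' pair_count(55, 5, 2)  # 273
#' @export
pair_count <- function(n_patients, n_timepoints, n_lost) {
  if (n_patients < 0 || n_timepoints < 0 || n_lost < 0) {
    stop("pair_count: arguments must be non-negative")
  }
  if (n_lost > n_patients * n_timepoints) {
    stop("pair_count: n_lost exceeds the number of scheduled sets")
  }
  as.integer(n_patients * n_timepoints - n_lost)
}

#' Per-timepoint cardiac-index summary fixture
#'
#' The packaged 5 x 2 grid of per-timepoint (n, mean, sd) cardiac-index
#' summaries for the test device and the echo reference in the validation
#' cohort (55 patients, 5 perioperative timepoints, 2 sets lost).
#'
#' @return Data frame with columns `timepoint`, `method` (`test`/`reference`),
#'   `n`, `mean`, `sd`.
#' @export
fixture_table2 <- function() {
  path <- system.file("extdata", "table2_cardiac_index.csv", package = "coagree")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Cohort biometrics summary fixture
#'
#' Summary statistics (mean, sd, range) of age, weight, height and BMI for
#' the validation cohort, plus the ASA physical-status counts.
#'
#' @return List with data frames `continuous` and `asa`.
#' @export
fixture_table1 <- function() {
  list(
    continuous = utils::read.csv(
      system.file("extdata", "table1_characteristics.csv", package = "coagree"),
      stringsAsFactors = FALSE),
    asa = utils::read.csv(
      system.file("extdata", "table1_asa.csv", package = "coagree"),
      stringsAsFactors = FALSE)
  )
}

#' Published agreement summary fixture
#'
#' The printed Bland-Altman summary (bias, precision, limits of agreement,
#' mean percentage error) for cardiac index and for raw cardiac output, used
#' by verdict-logic and reconstruction tests.
#'
#' @return Data frame with columns `quantity`, `cardiac_index`,
#'   `cardiac_output`.
#' @export
fixture_table3 <- function() {
  utils::read.csv(
    system.file("extdata", "table3_agreement.csv", package = "coagree"),
    stringsAsFactors = FALSE)
}

#' Pseudo-observations encoding the per-timepoint summary grid
#'
#' Expands the [fixture_table2()] cell means into one pseudo paired
#' observation per timepoint, optionally replicated by the per-timepoint n so
#' that the plain mean of differences equals the n-weighted mean across
#' timepoints. This reproduces the cohort-level bias (0.02 at two decimals)
#' from published summaries alone; second moments are not representable this
#' way (each pseudo-pair sits at its cell mean).
#'
#' @param expand If `TRUE` (default) replicate each timepoint's pseudo-pair
#'   `n` times; if `FALSE` return 5 rows with an `n` weight column.
#' @return Data frame with `patient_id`, `timepoint`, `ci_test`, `ci_ref`,
#'   `difference`, `mean_pair` (plus `n` when `expand = FALSE`).
#' @export
table2_pseudo_pairs <- function(expand = TRUE) {
  t2 <- fixture_table2()
  tst <- t2[t2$method == "test", ]
  ref <- t2[t2$method == "reference", ]
  i <- match(tst$timepoint, ref$timepoint)
  cells <- data.frame(
    patient_id = sprintf("cell%d", tst$timepoint),
    timepoint = tst$timepoint,
    ci_test = tst$mean,
    ci_ref = ref$mean[i],
    n = tst$n,
    stringsAsFactors = FALSE
  )
  cells$difference <- cells$ci_test - cells$ci_ref
  cells$mean_pair <- (cells$ci_test + cells$ci_ref) / 2
  if (!expand) return(cells)
  out <- cells[rep(seq_len(nrow(cells)), cells$n), ]
  out$n <- NULL
  rownames(out) <- NULL
  out
}
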