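# Cohort schema, CSV input/output, and the Results-style tabulation.
#
# One row per respondent. Prevalences are always computed against the FULL
# cohort size (including excluded and instrument-missing records) -- every
# published percentage reproduces from counts only under that denominator
# (e.g. 805/12,668 = 6.35%, 658/12,668 = 5.19%).

COHORT_COLUMNS <- c("id", "prior_dx",
                    paste0("bhs", 1:4), paste0("bdi", 1:9),
                    "mde_core1", "mde_core2", "mde_other_count",
                    "ideation", "plan", "prior_attempt", "sex", "age")

LOGICAL_COLUMNS <- c("prior_dx", "mde_core1", "mde_core2",
                     "ideation", "plan", "prior_attempt")

#' An empty record in the standard cohort schema
#'
#' All instrument items and flags missing, \code{prior_dx = FALSE}. Useful
#' for building worked examples and test fixtures.
#'
#' @param id record identifier.
#' @return one-row data.frame in the cohort schema.
#' @export
blank_record <- function(id = "r1") {
  rec <- as.data.frame(setNames(rep(list(NA), length(COHORT_COLUMNS)),
                                COHORT_COLUMNS))
  rec$id <- id
  rec$prior_dx <- FALSE
  for (col in setdiff(LOGICAL_COLUMNS, "prior_dx")) rec[[col]] <- NA
  rec$sex <- NA_character_
  rec
}

#' Validate a cohort data.frame against the standard schema
#'
#' Checks column presence, id uniqueness, flag and item ranges. Raises an
#' error naming the offending column and row on the first violation.
#'
#' @param cohort data.frame to validate.
#' @return the cohort, invisibly, on success.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols))
    stop(sprintf("cohort is missing required columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyNA(cohort$id) || any(cohort$id == ""))
    stop("cohort ids must be non-missing and non-empty", call. = FALSE)
  dup <- unique(cohort$id[duplicated(cohort$id)])
  if (length(dup))
    stop(sprintf("duplicate record ids: %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  if (anyNA(cohort$prior_dx))
    stop(sprintf("prior_dx is missing for record(s) %s",
                 paste(utils::head(cohort$id[is.na(cohort$prior_dx)], 5),
                       collapse = ", ")), call. = FALSE)
  for (col in LOGICAL_COLUMNS) {
    v <- cohort[[col]]
    if (!is.logical(v) && !all(is.na(v) | v %in% c(0, 1)))
      stop(sprintf("column %s must be logical or 0/1", col), call. = FALSE)
  }
  check_items <- function(cols, vmin, vmax, label) {
    for (col in cols) {
      v <- cohort[[col]]
      bad <- which(!is.na(v) & (v < vmin | v > vmax | v != floor(v)))
      if (length(bad))
        stop(sprintf("%s: value %s in column %s outside %d..%d (record %s, row %d)",
                     label, format(v[bad[1]]), col, vmin, vmax,
                     cohort$id[bad[1]], bad[1]), call. = FALSE)
    }
  }
  check_items(paste0("bhs", 1:4), 0, 3, "BHS")
  check_items(paste0("bdi", 1:9), 1, 4, "BDI-9")
  oc <- cohort$mde_other_count
  bad <- which(!is.na(oc) & (oc < 0 | oc > 7 | oc != floor(oc)))
  if (length(bad))
    stop(sprintf("mde_other_count outside 0..7 (record %s, row %d)",
                 cohort$id[bad[1]], bad[1]), call. = FALSE)
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads the standard one-row-per-respondent CSV (empty cells are missing
#' values) and validates it strictly; schema violations are reported with the
#' offending column and file line (header is line 1).
#'
#' @param path path to the CSV file.
#' @return validated cohort data.frame.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df$id <- as.character(df$id)
  for (col in LOGICAL_COLUMNS) df[[col]] <- as.logical(df[[col]])
  tryCatch(validate_cohort(df), error = function(e) {
    msg <- conditionMessage(e)
    # translate data.frame row to file line (header occupies line 1)
    m <- regmatches(msg, regexec("row ([0-9]+)", msg))[[1]]
    if (length(m) == 2)
      msg <- sub("row [0-9]+", sprintf("line %d", as.integer(m[2]) + 1L), msg)
    stop(sprintf("%s: %s", path, msg), call. = FALSE)
  })
  df
}

#' Write a cohort CSV
#'
#' Writes the standard cohort schema with empty cells for missing values,
#' producing a file that [read_cohort()] accepts unchanged.
#'
#' @param cohort validated cohort data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[COHORT_COLUMNS]
  for (col in LOGICAL_COLUMNS) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Tabulate triage categories over a cohort
#'
#' Applies one protocol to every record and counts the eight terminal
#' categories. The denominator for every prevalence is the full cohort size
#' N; prevalences are count / N x 100, rounded half away from zero to two
#' decimals at presentation only. Aggregates (kept as attributes and
#' accessible via [definitive_and_potential()]) always use raw counts:
#' \itemize{
#'   \item definitive care need: immediate referrals by BHS (>= 6) plus by
#'     BDI-9 (>= 25);
#'   \item potential care need: the BDI-9 19--24 group awaiting MDE
#'     assessment;
#'   \item BDI-indicated: all records routed into the BDI-9 stage (including
#'     those whose BDI-9 was missing).
#' }
#'
#' @param cohort cohort data.frame (or a cohort already triaged by
#'   [triage_cohort()] under the same protocol).
#' @param protocol a \code{protocol_spec} or shipped protocol name.
#' @return object of class \code{cohort_table}: a data.frame with columns
#'   \code{category}, \code{count}, \code{prevalence}, with attributes
#'   \code{protocol}, \code{n}, \code{definitive}, \code{potential},
#'   \code{bdi_indicated} and \code{mde_split} (sub-classification counts for
#'   assessed records, when any DSM-5 flags were present).
#' @export
tabulate_cohort <- function(cohort, protocol) {
  protocol <- as_protocol(protocol)
  if (!"category" %in% names(cohort)) cohort <- triage_cohort(cohort, protocol)
  n <- nrow(cohort)
  counts <- table(factor(cohort$category, levels = TRIAGE_CATEGORIES))
  stopifnot(sum(counts) == n)  # partition: every record in exactly one category
  tab <- data.frame(category = TRIAGE_CATEGORIES,
                    count = as.integer(counts),
                    prevalence = round_half_away(as.integer(counts) / n * 100, 2),
                    stringsAsFactors = FALSE)
  mde_split <- table(factor(cohort$mde_subresult, levels = MDE_SUBRESULTS))
  structure(tab,
            class = c("cohort_table", "data.frame"),
            protocol = protocol$name,
            n = n,
            definitive = as.integer(counts[["IMMEDIATE_REFERRAL_BHS"]] +
                                    counts[["IMMEDIATE_REFERRAL_BDI"]]),
            potential = as.integer(counts[["MDE_ASSESSMENT_INDICATED"]]),
            bdi_indicated = as.integer(counts[["BDI_MISSING"]] +
                                       counts[["BDI_BELOW_ASSESS"]] +
                                       counts[["MDE_ASSESSMENT_INDICATED"]] +
                                       counts[["IMMEDIATE_REFERRAL_BDI"]]),
            mde_split = if (sum(mde_split) > 0) mde_split else NULL)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort triage table -- protocol %s, N = %s\n",
              attr(x, "protocol"), format(attr(x, "n"), big.mark = ",")))
  df <- as.data.frame(x)
  df$prevalence <- sprintf("%.2f%%", df$prevalence)
  print(df, row.names = FALSE)
  dp <- definitive_and_potential(x)
  cat(sprintf("definitive care need: %d   potential care need: %d   BDI-indicated: %d\n",
              dp[["definitive"]], dp[["potential"]], attr(x, "bdi_indicated")))
  if (!is.null(attr(x, "mde_split"))) {
    cat("MDE sub-classification of assessed records:\n")
    print(attr(x, "mde_split"))
  }
  invisible(x)
}

#' Definitive and potential psychiatric-care counts of a cohort table
#'
#' Definitive = immediate referrals by BHS plus by BDI-9; potential = the
#' BDI-9 19--24 group (tallied without requiring DSM-5 flags, matching the
#' headline accounting; any MDE sub-split is reported additionally on the
#' table and never replaces this aggregation).
#'
#' @param table a \code{cohort_table}.
#' @return named integer vector \code{c(definitive = , potential = )}.
#' @export
definitive_and_potential <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  c(definitive = attr(table, "definitive"),
    potential = attr(table, "potential"))
}
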