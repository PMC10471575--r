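# Item-level scoring of the two screening instruments.
#
# BHS-4: four hopelessness items on a 0-3 Likert scale ("not typical" ...
# "very typical"), total 0-12. Hopelessness is a strong independent predictor
# of suicide risk; totals of 6 or more flag acute risk.
#
# BDI-9: nine depression items on a 1-4 intensity scale, total 9-36, with
# severity bands none (9-13) / mild (14-18) / moderate (19-24) / severe (>=25).
# The raw 1-4 coding is kept as published (not rebased to 0-3) so the printed
# band boundaries apply verbatim.
#
# A single missing item invalidates the whole instrument total: cohorts are
# accounted with whole-instrument missingness, so no prorating or imputation
# is done.

BDI9_SEVERITY_LEVELS <- c("NO_DEPRESSION", "MILD", "MODERATE", "SEVERE")

# Shared scorer: x is a length-n_items vector or an (n x n_items) matrix /
# data.frame of item scores. Present values must be integers in
# [vmin, vmax]; any missing item makes the total NA.
score_items <- function(x, n_items, vmin, vmax, label) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != n_items)
      stop(sprintf("%s response must have exactly %d items, got %d",
                   label, n_items, length(x)), call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1)
  } else if (ncol(x) != n_items) {
    stop(sprintf("%s response matrix must have %d columns, got %d",
                 label, n_items, ncol(x)), call. = FALSE)
  }
  storage.mode(x) <- "double"
  bad <- !is.na(x) & (x < vmin | x > vmax | x != floor(x))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("%s item %d has value %s outside %d..%d (record %d)",
                 label, w[["col"]], format(x[w[["row"]], w[["col"]]]),
                 vmin, vmax, w[["row"]]), call. = FALSE)
  }
  total <- rowSums(x)          # NA whenever any item is missing
  as.integer(total)
}

#' Score a 4-item Beck Hopelessness Scale response
#'
#' Sums the four item scores (each 0--3) into the BHS total (0--12). An
#' incomplete response -- any missing item -- yields \code{NA}: the instrument
#' is treated as missing as a whole, matching how survey cohorts account for
#' instrument non-completion.
#'
#' @param items numeric vector of length 4, or an n x 4 matrix/data.frame of
#'   item scores; \code{NA} marks a missing item.
#' @return integer total(s) in 0..12, \code{NA} for incomplete responses.
#' @examples
#' score_bhs(c(2, 1, 2, 1))   # 6, the referral cutoff
#' score_bhs(c(2, 1, NA, 1))  # NA
#' @seealso [score_bdi9()], [classify_bhs()]
#' @export
score_bhs <- function(items) score_items(items, 4L, 0L, 3L, "BHS")

#' Score a 9-item Beck Depression Inventory response
#'
#' Sums the nine item scores (each 1--4) into the BDI-9 total (9--36). Any
#' missing item makes the total \code{NA}.
#'
#' @param items numeric vector of length 9, or an n x 9 matrix/data.frame.
#' @return integer total(s) in 9..36, \code{NA} for incomplete responses.
#' @examples
#' score_bdi9(rep(1, 9))            # 9, scale floor
#' score_bdi9(c(3, rep(2, 8)))      # 19, the MDE-assessment cutoff
#' @seealso [bdi9_severity()], [classify_bdi()]
#' @export
score_bdi9 <- function(items) score_items(items, 9L, 1L, 4L, "BDI-9")

#' Map a BDI-9 total to its depression severity band
#'
#' Bands partition the whole 9..36 range: 9--13 no depression, 14--18 likely
#' mild, 19--24 likely moderate, 25 and above likely severe.
#'
#' @param total integer vector of BDI-9 totals in 9..36 (\code{NA} passes
#'   through).
#' @return factor with levels \code{NO_DEPRESSION}, \code{MILD},
#'   \code{MODERATE}, \code{SEVERE}.
#' @examples
#' bdi9_severity(c(13, 19, 25))
#' @export
bdi9_severity <- function(total) {
  stopifnot(is.numeric(total))
  out_of_range <- !is.na(total) & (total < 9 | total > 36)
  if (any(out_of_range))
    stop(sprintf("BDI-9 total %s outside 9..36: not a scored complete response",
                 format(total[out_of_range][1])), call. = FALSE)
  cut(total, breaks = c(8, 13, 18, 24, 36), labels = BDI9_SEVERITY_LEVELS)
}

#' Shipped instrument definitions
#'
#' Reads the versioned instrument configuration (item texts, value ranges,
#' severity bands) that protocols reference by name ("BHS4", "BDI9"). The
#' published Hungarian 9-item depression form prints identical wording for
#' items 4 and 6; the duplication is carried verbatim as a documented erratum
#' -- only totals enter the scoring, so it has no numerical effect.
#'
#' @param path path to an instruments YAML file; defaults to the copy shipped
#'   with the package.
#' @return named list with elements \code{version} and \code{instruments}.
#' @export
instrument_definitions <- function(path = system.file("extdata", "instruments.yaml",
                                                      package = "depscreen")) {
  defs <- yaml::read_yaml(path)
  stopifnot(all(c("BHS4", "BDI9") %in% names(defs$instruments)))
  defs
}
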