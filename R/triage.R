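# The staged decision tree: BHS gate -> BDI-9 stage -> DSM-5 MDE check.
#
# Three shipped protocols differ only in which BHS totals end screening
# before the BDI-9 stage: P1 stops at 0-1, P2 at 0-2, P3 at 0-3. BHS >= 6
# refers immediately to a psychiatrist under every protocol.

TRIAGE_CATEGORIES <- c(
  "EXCLUDED_PRIOR_PSYCHIATRIC",
  "MISSING_BHS",
  "NO_FURTHER_EVALUATION",
  "BDI_MISSING",
  "BDI_BELOW_ASSESS",
  "MDE_ASSESSMENT_INDICATED",
  "IMMEDIATE_REFERRAL_BHS",
  "IMMEDIATE_REFERRAL_BDI"
)

MDE_SUBRESULTS <- c(
  "MDE_NON_SUICIDAL_GP_TREATABLE",
  "MDE_SUICIDAL_PSYCHIATRIST",
  "NOT_MDE_CONSIDER_REFERRAL"
)

# category -> recommended action at the screening stage
CATEGORY_ACTIONS <- c(
  EXCLUDED_PRIOR_PSYCHIATRIC = "none",
  MISSING_BHS                = "none",
  NO_FURTHER_EVALUATION      = "none",
  BDI_MISSING                = "none",
  BDI_BELOW_ASSESS           = "none",
  MDE_ASSESSMENT_INDICATED   = "assess-MDE",
  IMMEDIATE_REFERRAL_BHS     = "refer-psychiatrist",
  IMMEDIATE_REFERRAL_BDI     = "refer-psychiatrist"
)

# MDE sub-classification -> treatment-stage action
SUBRESULT_ACTIONS <- c(
  MDE_NON_SUICIDAL_GP_TREATABLE = "GP-treatment",
  MDE_SUICIDAL_PSYCHIATRIST     = "psychiatrist-treatment",
  NOT_MDE_CONSIDER_REFERRAL     = "monitor-3-months"
)

#' Construct a triage protocol specification
#'
#' A protocol fixes the three BHS zones (stop / BDI-indicated / refer) and the
#' BDI-9 cutoffs. The zones must partition 0..12: totals up to
#' \code{bhs_stop_max} end screening, totals from \code{bhs_stop_max + 1} to
#' \code{bhs_refer_min - 1} trigger the BDI-9 stage, and totals of
#' \code{bhs_refer_min} (6) or more trigger immediate psychiatric referral.
#'
#' @param name protocol label (e.g. "P1").
#' @param bhs_stop_max highest BHS total that ends screening (1, 2 or 3 for
#'   the shipped protocols).
#' @param bhs_refer_min lowest BHS total that refers immediately (6).
#' @param bdi_assess_lo,bdi_assess_hi inclusive BDI-9 band indicating MDE
#'   assessment (19--24).
#' @param bdi_refer_min lowest BDI-9 total that refers immediately (25).
#' @return object of class \code{protocol_spec}.
#' @examples
#' protocol_spec("P1", bhs_stop_max = 1)
#' @export
protocol_spec <- function(name, bhs_stop_max, bhs_refer_min = 6L,
                          bdi_assess_lo = 19L, bdi_assess_hi = 24L,
                          bdi_refer_min = 25L) {
  stopifnot(is.character(name), length(name) == 1)
  vals <- c(bhs_stop_max, bhs_refer_min, bdi_assess_lo, bdi_assess_hi,
            bdi_refer_min)
  stopifnot(all(vals == floor(vals)))
  if (bhs_stop_max < 0 || bhs_stop_max >= bhs_refer_min)
    stop("bhs_stop_max must be nonnegative and below bhs_refer_min",
         call. = FALSE)
  if (bhs_refer_min > 12)
    stop("bhs_refer_min must lie in the BHS range 0..12", call. = FALSE)
  if (!(9 <= bdi_assess_lo && bdi_assess_lo <= bdi_assess_hi &&
        bdi_assess_hi + 1 == bdi_refer_min && bdi_refer_min <= 36))
    stop("BDI bands must be ordered 9 <= assess_lo <= assess_hi < refer_min <= 36",
         call. = FALSE)
  structure(list(name = name,
                 bhs_stop_max = as.integer(bhs_stop_max),
                 bhs_refer_min = as.integer(bhs_refer_min),
                 bdi_assess_lo = as.integer(bdi_assess_lo),
                 bdi_assess_hi = as.integer(bdi_assess_hi),
                 bdi_refer_min = as.integer(bdi_refer_min)),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(
    "<protocol %s>  BHS stop 0-%d | BDI-9 for %d-%d | refer >= %d;  BDI-9 assess %d-%d, refer >= %d\n",
    x$name, x$bhs_stop_max, x$bhs_stop_max + 1, x$bhs_refer_min - 1,
    x$bhs_refer_min, x$bdi_assess_lo, x$bdi_assess_hi, x$bdi_refer_min))
  invisible(x)
}

#' The three shipped screening protocols
#'
#' Loads P1 (the original algorithm: BHS 0--1 stops), P2 (BHS 0--2 stops,
#' BDI-9 for 3--5) and P3 (BHS 0--3 stops, BDI-9 for 4--5) from the shipped
#' protocol configuration.
#'
#' @param path path to a protocols YAML file; defaults to the shipped copy.
#' @return named list of \code{protocol_spec} objects.
#' @export
protocols <- function(path = system.file("extdata", "protocols.yaml",
                                         package = "depscreen")) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg$protocols), function(nm) {
    p <- cfg$protocols[[nm]]
    protocol_spec(nm, p$bhs_stop_max, p$bhs_refer_min,
                  p$bdi_assess_lo, p$bdi_assess_hi, p$bdi_refer_min)
  })
  names(out) <- names(cfg$protocols)
  out
}

as_protocol <- function(protocol) {
  if (inherits(protocol, "protocol_spec")) return(protocol)
  if (is.character(protocol) && length(protocol) == 1) {
    ps <- protocols()
    if (!protocol %in% names(ps))
      stop(sprintf("unknown protocol '%s'; shipped protocols: %s",
                   protocol, paste(names(ps), collapse = ", ")), call. = FALSE)
    return(ps[[protocol]])
  }
  stop("protocol must be a protocol_spec or the name of a shipped protocol",
       call. = FALSE)
}

#' Classify a BHS total into its protocol zone
#'
#' @param bhs_total integer vector of BHS totals (0..12); \code{NA} for a
#'   missing instrument (the caller routes missings to their own category).
#' @param protocol a \code{protocol_spec} or shipped protocol name.
#' @return factor with levels \code{STOP}, \code{BDI_INDICATED}, \code{REFER}.
#' @examples
#' classify_bhs(c(1, 2, 6), "P1")  # STOP, BDI_INDICATED, REFER
#' classify_bhs(2, "P2")           # STOP
#' @export
classify_bhs <- function(bhs_total, protocol) {
  protocol <- as_protocol(protocol)
  stopifnot(is.numeric(bhs_total))
  bad <- !is.na(bhs_total) & (bhs_total < 0 | bhs_total > 12)
  if (any(bad))
    stop(sprintf("BHS total %s outside 0..12", format(bhs_total[bad][1])),
         call. = FALSE)
  out <- ifelse(bhs_total <= protocol$bhs_stop_max, "STOP",
         ifelse(bhs_total >= protocol$bhs_refer_min, "REFER", "BDI_INDICATED"))
  factor(out, levels = c("STOP", "BDI_INDICATED", "REFER"))
}

#' Classify a BDI-9 total within the BDI stage
#'
#' Totals below the assessment band end screening, totals inside it indicate
#' a DSM-5 MDE assessment, and totals at or above the referral cutoff (25)
#' indicate immediate psychiatric referral.
#'
#' @param bdi_total integer vector of BDI-9 totals (9..36); \code{NA} for a
#'   missing instrument.
#' @param protocol protocol carrying the BDI cutoffs (all shipped protocols
#'   share 19--24 / >= 25); defaults to the standard cutoffs.
#' @return factor with levels \code{STOP}, \code{ASSESS_MDE}, \code{REFER}.
#' @examples
#' classify_bdi(c(18, 22, 25))  # STOP, ASSESS_MDE, REFER
#' @export
classify_bdi <- function(bdi_total, protocol = protocol_spec("default", 1L)) {
  protocol <- as_protocol(protocol)
  stopifnot(is.numeric(bdi_total))
  bad <- !is.na(bdi_total) & (bdi_total < 9 | bdi_total > 36)
  if (any(bad))
    stop(sprintf("BDI-9 total %s outside 9..36", format(bdi_total[bad][1])),
         call. = FALSE)
  out <- ifelse(bdi_total < protocol$bdi_assess_lo, "STOP",
         ifelse(bdi_total >= protocol$bdi_refer_min, "REFER", "ASSESS_MDE"))
  factor(out, levels = c("STOP", "ASSESS_MDE", "REFER"))
}

#' Evaluate DSM-5 major depressive episode criteria with suicide-risk split
#'
#' An MDE is present when at least one of the two core symptoms (depressed
#' mood, loss of interest) and at least four additional symptoms are present.
#' An MDE with any suicidality qualifier -- current ideation, a plan, or a
#' previous attempt -- needs treatment by a psychiatrist; a non-suicidal MDE
#' can be treated in the general medical practice; when criteria are not met,
#' referral should be considered, or close monitoring with repeat screening
#' after three months.
#'
#' @param core_depressed_mood,core_loss_of_interest logical: the two core
#'   symptoms.
#' @param other_symptom_count integer 0..7: additional DSM-5 symptoms present.
#' @param suicidal_ideation,suicide_plan,prior_attempt logical qualifiers.
#' @param allow_incomplete if \code{TRUE}, records with missing required flags
#'   return \code{NA} instead of raising an error.
#' @return factor with levels \code{MDE_NON_SUICIDAL_GP_TREATABLE},
#'   \code{MDE_SUICIDAL_PSYCHIATRIST}, \code{NOT_MDE_CONSIDER_REFERRAL}.
#' @examples
#' evaluate_mde(TRUE, FALSE, 4)                       # GP-treatable MDE
#' evaluate_mde(TRUE, TRUE, 5, prior_attempt = TRUE)  # psychiatrist
#' evaluate_mde(FALSE, FALSE, 7)                      # not MDE
#' @export
evaluate_mde <- function(core_depressed_mood, core_loss_of_interest,
                         other_symptom_count,
                         suicidal_ideation = FALSE, suicide_plan = FALSE,
                         prior_attempt = FALSE, allow_incomplete = FALSE) {
  n <- max(lengths(list(core_depressed_mood, core_loss_of_interest,
                        other_symptom_count)))
  core1 <- rep_len(as.logical(core_depressed_mood), n)
  core2 <- rep_len(as.logical(core_loss_of_interest), n)
  other <- rep_len(as.numeric(other_symptom_count), n)
  ide   <- rep_len(as.logical(suicidal_ideation), n)
  plan  <- rep_len(as.logical(suicide_plan), n)
  att   <- rep_len(as.logical(prior_attempt), n)
  bad <- !is.na(other) & (other < 0 | other > 7 | other != floor(other))
  if (any(bad))
    stop(sprintf("other_symptom_count %s outside 0..7", format(other[bad][1])),
         call. = FALSE)

  mde <- (core1 | core2) & other >= 4
  suicidal <- ide | plan | att
  # a record is incomplete when the flags needed to decide it are missing
  incomplete <- is.na(core1) | is.na(core2) | is.na(other) |
    (!is.na(mde) & mde & (is.na(ide) | is.na(plan) | is.na(att) | is.na(suicidal)))
  if (any(incomplete) && !allow_incomplete)
    stop("MDE assessment incomplete: required symptom or suicidality flags are missing",
         call. = FALSE)
  out <- ifelse(incomplete, NA_character_,
         ifelse(!mde, "NOT_MDE_CONSIDER_REFERRAL",
         ifelse(suicidal, "MDE_SUICIDAL_PSYCHIATRIST",
                "MDE_NON_SUICIDAL_GP_TREATABLE")))
  factor(out, levels = MDE_SUBRESULTS)
}

# Vectorised core of the decision tree over pre-scored totals. Evaluation
# order is fixed: prior-diagnosis exclusion -> BHS missingness -> BHS zones ->
# BDI missingness -> BDI zones. Returns a character vector of categories.
assign_categories <- function(prior_dx, bhs_total, bdi_total, protocol) {
  protocol <- as_protocol(protocol)
  bhs_branch <- classify_bhs(bhs_total, protocol)
  bdi_branch <- classify_bdi(bdi_total, protocol)
  ifelse(prior_dx, "EXCLUDED_PRIOR_PSYCHIATRIC",
  ifelse(is.na(bhs_total), "MISSING_BHS",
  ifelse(bhs_branch == "STOP", "NO_FURTHER_EVALUATION",
  ifelse(bhs_branch == "REFER", "IMMEDIATE_REFERRAL_BHS",
  ifelse(is.na(bdi_total), "BDI_MISSING",
  ifelse(bdi_branch == "STOP", "BDI_BELOW_ASSESS",
  ifelse(bdi_branch == "REFER", "IMMEDIATE_REFERRAL_BDI",
         "MDE_ASSESSMENT_INDICATED")))))))
}

#' Triage a whole cohort under one protocol
#'
#' Scores both instruments for every record, walks the decision tree, and
#' returns the cohort with triage columns appended: \code{bhs_total},
#' \code{bdi_total}, \code{category}, \code{action}, \code{mde_subresult}
#' (filled only for MDE-assessment records whose DSM-5 flags are complete)
#' and \code{risk_note} ("very-high-suicide-risk" for BHS totals of 9 or
#' more, which warrant psychiatric admission rather than plain referral).
#'
#' @param cohort data.frame in the standard cohort schema (see
#'   [read_cohort()]).
#' @param protocol a \code{protocol_spec} or shipped protocol name.
#' @return the cohort data.frame with triage columns appended; \code{category}
#'   is a factor over the eight terminal categories.
#' @seealso [triage_record()], [tabulate_cohort()]
#' @export
triage_cohort <- function(cohort, protocol) {
  protocol <- as_protocol(protocol)
  validate_cohort(cohort)
  bhs_total <- score_bhs(cohort[paste0("bhs", 1:4)])
  bdi_total <- score_bdi9(cohort[paste0("bdi", 1:9)])
  prior <- as.logical(cohort$prior_dx)
  category <- assign_categories(prior, bhs_total, bdi_total, protocol)

  sub <- evaluate_mde(cohort$mde_core1, cohort$mde_core2,
                      cohort$mde_other_count, cohort$ideation, cohort$plan,
                      cohort$prior_attempt, allow_incomplete = TRUE)
  sub[category != "MDE_ASSESSMENT_INDICATED"] <- NA

  action <- unname(CATEGORY_ACTIONS[category])
  has_sub <- !is.na(sub)
  action[has_sub] <- unname(SUBRESULT_ACTIONS[as.character(sub[has_sub])])

  cohort$bhs_total <- bhs_total
  cohort$bdi_total <- bdi_total
  cohort$category <- factor(category, levels = TRIAGE_CATEGORIES)
  cohort$action <- action
  cohort$mde_subresult <- sub
  cohort$risk_note <- ifelse(!prior & !is.na(bhs_total) & bhs_total >= 9,
                             "very-high-suicide-risk", NA_character_)
  cohort
}

#' Triage a single respondent
#'
#' Convenience wrapper around [triage_cohort()] for one record; useful for
#' worked examples and spot checks.
#'
#' @param record one-row data.frame in the cohort schema, or a list coercible
#'   to one.
#' @param protocol a \code{protocol_spec} or shipped protocol name.
#' @return list with elements \code{category}, \code{action},
#'   \code{mde_subresult}, \code{bhs_total}, \code{bdi_total},
#'   \code{risk_note}.
#' @examples
#' rec <- blank_record("r1")
#' rec[paste0("bhs", 1:4)] <- c(1, 1, 1, 1)
#' rec[paste0("bdi", 1:9)] <- c(4, 4, 4, 3, 3, 3, 2, 2, 2)
#' triage_record(rec, "P1")$category   # IMMEDIATE_REFERRAL_BDI
#' @export
triage_record <- function(record, protocol) {
  if (!is.data.frame(record)) record <- as.data.frame(record)
  if (nrow(record) != 1)
    stop("triage_record expects exactly one record", call. = FALSE)
  out <- tryCatch(triage_cohort(record, protocol), error = function(e)
    stop(sprintf("record '%s': %s", record$id[1], conditionMessage(e)),
         call. = FALSE))
  list(category = as.character(out$category),
       action = out$action,
       mde_subresult = as.character(out$mde_subresult),
       bhs_total = out$bhs_total,
       bdi_total = out$bdi_total,
       risk_note = out$risk_note)
}
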