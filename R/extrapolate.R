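# Rescaling cohort counts to target populations.
#
# The two reference targets are an average general medical practice of 1,600
# registered adults and the Hungarian population over 25 years of age
# (7,288,433 in 2018). Estimates are round-half-away-from-zero of
# count x target / N; aggregates are extrapolated from their raw summed
# counts (aggregate-then-round), with the round-then-sum alternative kept for
# reconciliation because some component-wise published figures arise that way.

#' Construct a population target
#'
#' @param name label for the target (e.g. "gmp", "national").
#' @param size positive integer population size.
#' @return object of class \code{population_target}.
#' @examples
#' population_target("gmp", 1600)
#' population_target("national", 7288433)
#' @export
population_target <- function(name, size) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(size), length(size) == 1, size >= 1,
            size == floor(size))
  structure(list(name = name, size = as.integer(size)),
            class = "population_target")
}

#' The two reference population targets
#'
#' An average general medical practice (1,600 adults) and the Hungarian 25+
#' population in 2018 (7,288,433). Sizes are ordinary config values, so other
#' years or populations can be substituted.
#'
#' @return named list of \code{population_target} objects.
#' @export
default_targets <- function() {
  list(gmp = population_target("gmp", 1600),
       national = population_target("national", 7288433))
}

#' Extrapolate one category count to a target population
#'
#' Returns the observed proportion \code{count / denominator} scaled to the
#' target size and rounded half away from zero to an integer. Zero maps to
#' zero and \code{count = denominator} maps to the target size exactly.
#'
#' @param count observed category count (0..denominator).
#' @param denominator full-sample size N.
#' @param target_size target population size.
#' @return integer estimate(s); vectorised over \code{count}.
#' @examples
#' extrapolate_count(1097, 12668, 1600)     # 139
#' extrapolate_count(1097, 12668, 7288433)  # 631150
#' @export
extrapolate_count <- function(count, denominator, target_size) {
  stopifnot(is.numeric(count), is.numeric(denominator),
            is.numeric(target_size),
            length(denominator) == 1, length(target_size) == 1)
  if (denominator < 1 || denominator != floor(denominator))
    stop("denominator must be a positive integer", call. = FALSE)
  if (target_size < 1 || target_size != floor(target_size))
    stop("target_size must be a positive integer", call. = FALSE)
  if (any(is.na(count)) || any(count < 0) || any(count > denominator) ||
      any(count != floor(count)))
    stop("count must be an integer in 0..denominator", call. = FALSE)
  as.integer(round_half_away(as.numeric(count) * as.numeric(target_size) /
                               denominator))
}

#' Extrapolate a whole cohort table to a target population
#'
#' Applies [extrapolate_count()] to every category count and, independently,
#' to each raw aggregate (definitive, potential, BDI-indicated) -- aggregates
#' are extrapolated from their summed counts, never by summing rounded
#' category estimates. The sum of rounded category estimates is also
#' recorded so reports can flag the (bounded) discrepancy between the two
#' conventions.
#'
#' @param table a \code{cohort_table}.
#' @param target a \code{population_target}.
#' @return object of class \code{population_estimate}: the table data.frame
#'   with an \code{estimate} column appended, plus attributes \code{target},
#'   \code{definitive}, \code{potential}, \code{bdi_indicated} (each an
#'   aggregate-then-round estimate), \code{definitive_componentwise}
#'   (round-then-sum of the two referral categories) and
#'   \code{sum_of_rounded} (sum of category estimates).
#' @export
extrapolate_table <- function(table, target) {
  stopifnot(inherits(table, "cohort_table"),
            inherits(target, "population_target"))
  n <- attr(table, "n")
  est <- extrapolate_count(table$count, n, target$size)
  out <- as.data.frame(table)
  out$estimate <- est
  refer_rows <- out$category %in% c("IMMEDIATE_REFERRAL_BHS",
                                    "IMMEDIATE_REFERRAL_BDI")
  structure(out,
            class = c("population_estimate", "data.frame"),
            protocol = attr(table, "protocol"),
            n = n,
            target = target,
            definitive = extrapolate_count(attr(table, "definitive"), n,
                                           target$size),
            potential = extrapolate_count(attr(table, "potential"), n,
                                          target$size),
            bdi_indicated = extrapolate_count(attr(table, "bdi_indicated"), n,
                                              target$size),
            definitive_componentwise = sum(est[refer_rows]),
            sum_of_rounded = sum(est))
}

#' @export
print.population_estimate <- function(x, ...) {
  tg <- attr(x, "target")
  cat(sprintf("Population estimate -- protocol %s, target %s (%s), N = %s\n",
              attr(x, "protocol"), tg$name, format(tg$size, big.mark = ","),
              format(attr(x, "n"), big.mark = ",")))
  df <- as.data.frame(x)
  df$prevalence <- sprintf("%.2f%%", df$prevalence)
  print(df, row.names = FALSE)
  cat(sprintf("definitive: %s   potential: %s   (component-wise definitive: %s)\n",
              format(attr(x, "definitive"), big.mark = ","),
              format(attr(x, "potential"), big.mark = ","),
              format(attr(x, "definitive_componentwise"), big.mark = ",")))
  invisible(x)
}
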