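# Small numeric helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest value at the given number of decimal digits, with
#' exact halves moved away from zero (so 0.5 -> 1, -0.5 -> -1). This is the
#' rounding convention used for all reported prevalences and population
#' estimates; note that base \code{round()} rounds half to even instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep (default 0).
#' @return numeric vector of the same length as \code{x}.
#' @examples
#' round_half_away(0.5)        # 1
#' round_half_away(-1.5)       # -2
#' round_half_away(8.6596, 2)  # 8.66
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Integer apportionment by the largest-remainder method
#'
#' Splits an integer total across cells proportionally to \code{weights},
#' flooring the exact quotas and handing the leftover units to the cells with
#' the largest fractional remainders (ties broken by cell order). Used to fill
#' blueprint cells that the published marginals do not pin down.
#'
#' @param total nonnegative integer to apportion.
#' @param weights positive numeric weights, one per cell.
#' @return integer vector summing exactly to \code{total}, named like
#'   \code{weights}.
#' @export
largest_remainder <- function(total, weights) {
  stopifnot(length(total) == 1, total >= 0, total == floor(total),
            is.numeric(weights), all(weights >= 0), sum(weights) > 0)
  q <- total * weights / sum(weights)
  f <- floor(q)
  rem <- as.integer(total - sum(f))
  if (rem > 0) {
    idx <- order(q - f, decreasing = TRUE)[seq_len(rem)]
    f[idx] <- f[idx] + 1
  }
  out <- as.integer(f)
  names(out) <- names(weights)
  out
}

# Evaluate code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}
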