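# Fixture builders and an independent brute-force triage oracle.

# A record with given BHS/BDI totals realised as concrete item vectors
# (greedy fill), plus optional flags.
make_record <- function(id = "r1", bhs_total = NULL, bdi_total = NULL,
                        prior = FALSE, mde_core1 = NA, mde_core2 = NA,
                        mde_other = NA, ideation = NA, plan = NA,
                        attempt = NA) {
  fill_items <- function(total, n, vmin, vmax) {
    x <- rep(vmin, n)
    left <- total - n * vmin
    for (i in seq_len(n)) {
      add <- min(left, vmax - vmin)
      x[i] <- vmin + add
      left <- left - add
    }
    stopifnot(left == 0)
    x
  }
  rec <- blank_record(id)
  rec$prior_dx <- prior
  if (!is.null(bhs_total)) rec[paste0("bhs", 1:4)] <- fill_items(bhs_total, 4, 0, 3)
  if (!is.null(bdi_total)) rec[paste0("bdi", 1:9)] <- fill_items(bdi_total, 9, 1, 4)
  rec$mde_core1 <- mde_core1
  rec$mde_core2 <- mde_core2
  rec$mde_other_count <- mde_other
  rec$ideation <- ideation
  rec$plan <- plan
  rec$prior_attempt <- attempt
  rec
}

bind_records <- function(...) {
  out <- do.call(rbind, list(...))
  out$id <- sprintf("r%03d", seq_len(nrow(out)))
  out
}

# Independent truth-table reimplementation of the decision tree, written as
# plain nested conditionals over scalar totals (no shared code with the
# package's vectorised path).
oracle_triage <- function(prior, bhs_total, bdi_total, stop_max) {
  if (isTRUE(prior)) return("EXCLUDED_PRIOR_PSYCHIATRIC")
  if (is.na(bhs_total)) return("MISSING_BHS")
  if (bhs_total >= 6) return("IMMEDIATE_REFERRAL_BHS")
  if (bhs_total <= stop_max) return("NO_FURTHER_EVALUATION")
  if (is.na(bdi_total)) return("BDI_MISSING")
  if (bdi_total >= 25) return("IMMEDIATE_REFERRAL_BDI")
  if (bdi_total >= 19) return("MDE_ASSESSMENT_INDICATED")
  "BDI_BELOW_ASSESS"
}
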