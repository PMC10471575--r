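ps <- protocols()

test_that("shipped protocols carry the published cutoffs", {
  expect_named(ps, c("P1", "P2", "P3"))
  expect_equal(vapply(ps, `[[`, integer(1), "bhs_stop_max"),
               c(P1 = 1L, P2 = 2L, P3 = 3L))
  for (p in ps) {
    expect_equal(p$bhs_refer_min, 6L)
    expect_equal(p$bdi_assess_lo, 19L)
    expect_equal(p$bdi_assess_hi, 24L)
    expect_equal(p$bdi_refer_min, 25L)
  }
  expect_error(protocol_spec("bad", 7), "below bhs_refer_min")
  expect_error(protocol_spec("bad", 1, bdi_assess_hi = 25), "ordered")
})

test_that("BHS zone classification follows each protocol's stop cutoff", {
  expect_equal(as.character(classify_bhs(1, ps$P1)), "STOP")
  expect_equal(as.character(classify_bhs(2, ps$P1)), "BDI_INDICATED")
  expect_equal(as.character(classify_bhs(2, ps$P2)), "STOP")
  expect_equal(as.character(classify_bhs(3, ps$P3)), "STOP")
  expect_equal(as.character(classify_bhs(4, ps$P3)), "BDI_INDICATED")
  for (p in ps) expect_equal(as.character(classify_bhs(6, p)), "REFER")
  # zones partition 0..12 for every protocol
  for (p in ps) {
    z <- classify_bhs(0:12, p)
    expect_false(anyNA(z))
    expect_equal(sum(z == "STOP"), p$bhs_stop_max + 1)
    expect_equal(sum(z == "REFER"), 12 - p$bhs_refer_min + 1)
  }
  expect_error(classify_bhs(13, ps$P1), "outside 0\\.\\.12")
})

test_that("BDI stage classification uses the 19/25 cutoffs", {
  expect_equal(as.character(classify_bdi(18)), "STOP")
  expect_equal(as.character(classify_bdi(22)), "ASSESS_MDE")
  expect_equal(as.character(classify_bdi(25)), "REFER")
  z <- classify_bdi(9:36)
  expect_equal(as.vector(table(z)), c(10L, 6L, 12L))
  expect_error(classify_bdi(8), "outside 9\\.\\.36")
})

test_that("MDE evaluation applies the core-plus-four rule and suicidality split", {
  expect_equal(as.character(evaluate_mde(TRUE, FALSE, 4)),
               "MDE_NON_SUICIDAL_GP_TREATABLE")
  expect_equal(as.character(evaluate_mde(FALSE, FALSE, 7)),
               "NOT_MDE_CONSIDER_REFERRAL")
  expect_equal(as.character(evaluate_mde(TRUE, TRUE, 5, prior_attempt = TRUE)),
               "MDE_SUICIDAL_PSYCHIATRIST")
  expect_equal(as.character(evaluate_mde(TRUE, FALSE, 3)),
               "NOT_MDE_CONSIDER_REFERRAL")
  # a plan alone qualifies as suicidality
  expect_equal(as.character(evaluate_mde(FALSE, TRUE, 6, suicide_plan = TRUE)),
               "MDE_SUICIDAL_PSYCHIATRIST")
  expect_error(evaluate_mde(NA, TRUE, 4), "incomplete")
  expect_true(is.na(evaluate_mde(NA, TRUE, 4, allow_incomplete = TRUE)))
  expect_error(evaluate_mde(TRUE, TRUE, 8), "outside 0\\.\\.7")
})

test_that("single-record triage follows the fixed evaluation order", {
  expect_equal(triage_record(make_record(bhs_total = 12, prior = TRUE), "P1")$category,
               "EXCLUDED_PRIOR_PSYCHIATRIC")
  expect_equal(triage_record(blank_record(), "P1")$category, "MISSING_BHS")
  expect_equal(triage_record(make_record(bhs_total = 0), "P1")$category,
               "NO_FURTHER_EVALUATION")
  out <- triage_record(make_record(bhs_total = 4, bdi_total = 27), "P1")
  expect_equal(out$category, "IMMEDIATE_REFERRAL_BDI")
  expect_equal(out$action, "refer-psychiatrist")
  expect_equal(triage_record(make_record(bhs_total = 3), "P1")$category,
               "BDI_MISSING")
  # very high risk note on BHS >= 9
  expect_equal(triage_record(make_record(bhs_total = 9), "P1")$risk_note,
               "very-high-suicide-risk")
  expect_true(is.na(triage_record(make_record(bhs_total = 6), "P1")$risk_note))
})

test_that("MDE subresult appears exactly when assessment-band flags are complete", {
  rec <- make_record(bhs_total = 3, bdi_total = 20, mde_core1 = TRUE,
                     mde_core2 = FALSE, mde_other = 5, ideation = FALSE,
                     plan = FALSE, attempt = FALSE)
  out <- triage_record(rec, "P1")
  expect_equal(out$category, "MDE_ASSESSMENT_INDICATED")
  expect_equal(out$mde_subresult, "MDE_NON_SUICIDAL_GP_TREATABLE")
  expect_equal(out$action, "GP-treatment")
  # incomplete flags: category stands, no subresult
  out2 <- triage_record(make_record(bhs_total = 3, bdi_total = 20), "P1")
  expect_equal(out2$category, "MDE_ASSESSMENT_INDICATED")
  expect_true(is.na(out2$mde_subresult))
  expect_equal(out2$action, "assess-MDE")
  # subresult never leaks outside the assessment band
  out3 <- triage_record(make_record(bhs_total = 3, bdi_total = 30,
                                    mde_core1 = TRUE, mde_core2 = TRUE,
                                    mde_other = 7, ideation = TRUE,
                                    plan = TRUE, attempt = TRUE), "P1")
  expect_equal(out3$category, "IMMEDIATE_REFERRAL_BDI")
  expect_true(is.na(out3$mde_subresult))
})

test_that("triage agrees with the brute-force oracle on all enumerable inputs", {
  grid <- expand.grid(prior = c(FALSE, TRUE),
                      bhs = c(NA, 0:12),
                      bdi = c(NA, 9:36))
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_record(sprintf("g%04d", i),
                bhs_total = if (is.na(grid$bhs[i])) NULL else grid$bhs[i],
                bdi_total = if (is.na(grid$bdi[i])) NULL else grid$bdi[i],
                prior = grid$prior[i])))
  for (pn in names(ps)) {
    got <- as.character(triage_cohort(recs, pn)$category)
    want <- vapply(seq_len(nrow(grid)), function(i)
      oracle_triage(grid$prior[i], grid$bhs[i], grid$bdi[i],
                    ps[[pn]]$bhs_stop_max), character(1))
    expect_identical(got, want, label = sprintf("oracle agreement under %s", pn))
    # partition: every record lands in exactly one (non-missing) category
    expect_false(anyNA(got))
  }
})

test_that("relaxing the stop cutoff only moves records into no-further-evaluation", {
  grid <- expand.grid(bhs = 0:12, bdi = 9:36)
  recs <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    make_record(sprintf("m%04d", i), bhs_total = grid$bhs[i],
                bdi_total = grid$bdi[i])))
  cat1 <- as.character(triage_cohort(recs, "P1")$category)
  cat2 <- as.character(triage_cohort(recs, "P2")$category)
  cat3 <- as.character(triage_cohort(recs, "P3")$category)
  check_pair <- function(a, b) {
    moved <- a != b
    # all changes land in NO_FURTHER_EVALUATION and originate in BDI-derived categories
    expect_true(all(b[moved] == "NO_FURTHER_EVALUATION"))
    expect_true(all(a[moved] %in% c("BDI_MISSING", "BDI_BELOW_ASSESS",
                                    "MDE_ASSESSMENT_INDICATED",
                                    "IMMEDIATE_REFERRAL_BDI")))
  }
  check_pair(cat1, cat2)
  check_pair(cat2, cat3)
  # BHS-referral set is identical across protocols
  expect_identical(cat1 == "IMMEDIATE_REFERRAL_BHS",
                   cat3 == "IMMEDIATE_REFERRAL_BHS")
})
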