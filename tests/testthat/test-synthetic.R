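bp <- default_blueprint()

test_that("default blueprint reproduces the published calibration cells", {
  expect_equal(bp$total_n, 12668L)
  cells <- setNames(bp$cells$n, bp$cells$name)
  expect_equal(cells[["prior_dx"]], 805L)
  expect_equal(cells[["bhs_missing"]], 658L)
  expect_equal(cells[["bhs_refer"]], 1097L)
  expect_equal(cells[["z01"]], 6992L)
  # zone sums reproduce every published BHS aggregate
  zone2 <- sum(cells[grep("^z2_", names(cells))])
  zone3 <- sum(cells[grep("^z3_", names(cells))])
  zone45 <- sum(cells[grep("^z45_", names(cells))])
  expect_equal(cells[["z01"]] + zone2, 8169L)            # BHS 0-2
  expect_equal(cells[["z01"]] + zone2 + zone3, 8996L)    # BHS 0-3
  expect_equal(zone2 + zone3 + zone45, 3116L)            # BHS 2-5
  expect_equal(zone3 + zone45, 1939L)                    # BHS 3-5
  expect_equal(zone45, 1112L)                            # BHS 4-5
  # published BDI bands within BHS 3-5 and 4-5
  expect_equal(cells[["z3_assess"]] + cells[["z45_assess"]], 235L)
  expect_equal(cells[["z3_refer"]] + cells[["z45_refer"]], 178L)
  expect_equal(cells[["z45_assess"]], 190L)
  expect_equal(cells[["z45_refer"]], 137L)
  # 491 BDI non-completers allocated inside BHS 2-5
  expect_equal(sum(cells[grep("bdi_missing$", names(cells))]), 491L)
  expect_equal(sum(cells), 12668L)
  # unpinned cells are flagged free
  expect_true(all(bp$cells$free[grep("^z2_|bdi_missing$", bp$cells$name)]))
})

test_that("generated cohorts reproduce every published count under all protocols", {
  cohort <- generate_cohort(bp, seed = 42)
  expect_equal(nrow(cohort), 12668)
  expect_silent(validate_cohort(cohort))
  expected <- list(
    P1 = c(EXCLUDED_PRIOR_PSYCHIATRIC = 805, MISSING_BHS = 658,
           NO_FURTHER_EVALUATION = 6992, IMMEDIATE_REFERRAL_BHS = 1097),
    P2 = c(EXCLUDED_PRIOR_PSYCHIATRIC = 805, MISSING_BHS = 658,
           NO_FURTHER_EVALUATION = 8169, MDE_ASSESSMENT_INDICATED = 235,
           IMMEDIATE_REFERRAL_BDI = 178, IMMEDIATE_REFERRAL_BHS = 1097),
    P3 = c(EXCLUDED_PRIOR_PSYCHIATRIC = 805, MISSING_BHS = 658,
           NO_FURTHER_EVALUATION = 8996, MDE_ASSESSMENT_INDICATED = 190,
           IMMEDIATE_REFERRAL_BDI = 137, IMMEDIATE_REFERRAL_BHS = 1097))
  for (pn in names(expected)) {
    tab <- tabulate_cohort(cohort, pn)
    got <- setNames(tab$count, tab$category)
    for (cat in names(expected[[pn]]))
      expect_equal(got[[cat]], expected[[pn]][[cat]],
                   label = sprintf("%s %s", pn, cat))
    expect_equal(sum(tab$count), 12668)
  }
  # BDI-indicated groups match the published zone sums
  expect_equal(attr(tabulate_cohort(cohort, "P1"), "bdi_indicated"), 3116L)
  expect_equal(attr(tabulate_cohort(cohort, "P2"), "bdi_indicated"), 1939L)
  expect_equal(attr(tabulate_cohort(cohort, "P3"), "bdi_indicated"), 1112L)
})

test_that("marginals are blueprint-determined: seeds change order, not tables", {
  small <- bp
  small$cells$n <- largest_remainder(600, bp$cells$n)
  small$total_n <- 600L
  c1 <- generate_cohort(small, seed = 1)
  c2 <- generate_cohort(small, seed = 2)
  t1 <- tabulate_cohort(c1, "P2")
  t2 <- tabulate_cohort(c2, "P2")
  expect_equal(t1$count, t2$count)
  expect_false(identical(c1$bhs1, c2$bhs1))  # different item realisations
  # same seed is fully reproducible
  expect_identical(generate_cohort(small, seed = 1), c1)
})

test_that("item scores land in their cell's declared total range", {
  small <- bp
  small$cells$n <- largest_remainder(800, bp$cells$n)
  small$total_n <- 800L
  cohort <- generate_cohort(small, seed = 9)
  tri <- triage_cohort(cohort, "P1")
  for (i in seq_len(nrow(small$cells))) {
    cl <- small$cells[i, ]
    if (is.na(cl$bhs_lo) || cl$n == 0) next
    in_cell <- !is.na(tri$bhs_total) & tri$bhs_total >= cl$bhs_lo &
      tri$bhs_total <= cl$bhs_hi & tri$prior_dx == cl$prior_dx
    expect_gte(sum(in_cell), cl$n)  # cell members are present in range
  }
  # degenerate cell: totals forced to 0 admit a unique composition
  one <- structure(list(total_n = 5L,
                        cells = data.frame(name = "zero", n = 5L,
                                           prior_dx = FALSE, bhs_lo = 0L,
                                           bhs_hi = 0L, bdi_lo = NA_integer_,
                                           bdi_hi = NA_integer_, free = FALSE),
                        mde = NULL),
                   class = "cohort_blueprint")
  five <- generate_cohort(one, seed = 3)
  expect_true(all(five[paste0("bhs", 1:4)] == 0))
})

test_that("infeasible cells and malformed blueprints are rejected", {
  bad <- bp
  bad$cells$bhs_lo[3] <- 10L
  bad$cells$bhs_hi[3] <- 9L
  expect_error(validate_blueprint(bad), "bhs_refer.*infeasible")
  bad2 <- bp
  bad2$cells$n[1] <- bad2$cells$n[1] + 1L
  expect_error(validate_blueprint(bad2), "sum to")
})

test_that("stochastic cell counts fluctuate around blueprint proportions", {
  n <- 12668
  p_refer <- 1097 / 12668
  refer_idx <- which(bp$cells$name == "bhs_refer")
  draws <- vapply(1:200, function(s)
    draw_cell_counts(bp, n, seed = 1000 + s)[refer_idx], numeric(1))
  se_mean <- sqrt(n * p_refer * (1 - p_refer) / 200)
  expect_lt(abs(mean(draws) - 1097), 3 * se_mean)
  expect_gt(stats::sd(draws), 0)  # genuinely stochastic, unlike generate_cohort
  expect_error(draw_cell_counts(bp, 0, seed = 1), "at least 1")
})

test_that("stochastic cohorts are schema-valid and reproducible", {
  co <- sample_stochastic_cohort(bp, n = 1500, seed = 5)
  expect_equal(nrow(co), 1500)
  expect_silent(validate_cohort(co))
  expect_identical(co, sample_stochastic_cohort(bp, n = 1500, seed = 5))
  # concentrating all mass on one cell puts every record there
  onecell <- bp
  onecell$cells$n <- ifelse(bp$cells$name == "z01", bp$total_n, 0L)
  co2 <- sample_stochastic_cohort(onecell, n = 50, seed = 6)
  expect_true(all(tabulate_cohort(co2, "P1")$count[
    tabulate_cohort(co2, "P1")$category == "NO_FURTHER_EVALUATION"] == 50))
})

test_that("blueprints round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_blueprint(bp, path)
  back <- read_blueprint(path)
  expect_equal(back$total_n, bp$total_n)
  expect_equal(back$cells$n, bp$cells$n)
  expect_equal(back$cells$bhs_lo, bp$cells$bhs_lo)
  expect_equal(back$cells$bdi_hi, bp$cells$bdi_hi)
})

test_that("requested MDE flags fill the assessment band consistently", {
  bpm <- default_blueprint(mde = list(p_mde = 0.5, p_suicidal = 0.3))
  small <- bpm
  small$cells$n <- largest_remainder(1000, bpm$cells$n)
  small$total_n <- 1000L
  co <- generate_cohort(small, seed = 8)
  tri <- triage_cohort(co, "P1")
  assessed <- tri[tri$category == "MDE_ASSESSMENT_INDICATED", ]
  expect_gt(nrow(assessed), 0)
  expect_false(anyNA(assessed$mde_subresult))  # flags complete -> sub-split present
  expect_true(all(as.character(assessed$mde_subresult) %in%
                    c("MDE_NON_SUICIDAL_GP_TREATABLE",
                      "MDE_SUICIDAL_PSYCHIATRIST",
                      "NOT_MDE_CONSIDER_REFERRAL")))
})
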