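test_that("PRR point estimate reproduces published values and sentinels", {
  expect_equal(round_half_up(prr(1046, 2076, 4, 92), 2), 11.59)
  expect_equal(prr(5, 50, 5, 50), 1.0)
  expect_identical(prr(0, 60, 8, 99), 0)          # unreported for exposure drug
  expect_true(is.na(prr(956, 2076, 0, 92)))        # unreported for comparator
  expect_true(is.na(prr(0, 60, 0, 99)))            # unreported everywhere
  expect_error(prr(5, 0, 1, 10), "positive")
  expect_error(prr(11, 10, 1, 10), "exceed")
})

test_that("delta-method CI reproduces published bounds and a closed-form case", {
  ci <- prr_ci(1046, 2076, 4, 92)
  expect_equal(round_half_up(ci$lower, 2), 4.44)
  expect_equal(round_half_up(ci$upper, 2), 30.25)
  ci2 <- prr_ci(727, 2076, 3, 92)
  expect_equal(round_half_up(ci2$lower, 2), 3.52)
  expect_equal(round_half_up(ci2$upper, 2), 32.74)
  # symmetric table: PRR = 1, se = sqrt(0.18)
  ci3 <- prr_ci(10, 100, 10, 100)
  expect_equal(ci3$lower, exp(-1.96 * sqrt(0.18)), tolerance = 1e-12)
  expect_equal(round(ci3$lower, 4), 0.4354)
  expect_equal(round(ci3$upper, 4), 2.2969)
  # undefined when either affected count is zero
  expect_true(all(is.na(prr_ci(0, 60, 9, 99))))
  expect_true(all(is.na(prr_ci(9, 60, 0, 99))))
})

test_that("PRR reciprocity, CI coverage of the point and monotonicity hold", {
  set.seed(11)
  for (i in 1:200) {
    a0 <- sample(5:400, 1)
    b0 <- sample(5:400, 1)
    a1 <- sample(1:a0, 1)
    b1 <- sample(1:b0, 1)
    expect_equal(prr(a1, a0, b1, b0) * prr(b1, b0, a1, a0), 1, tolerance = 1e-12)
    ci <- prr_ci(a1, a0, b1, b0)
    point <- prr(a1, a0, b1, b0)
    expect_true(ci$lower <= point && point <= ci$upper)
    if (a1 < a0) {
      expect_gte(prr(a1 + 1, a0, b1, b0), point)
    }
  }
})

test_that("two-tailed Fisher p reproduces published rows and is symmetric", {
  expect_equal(round(fisher_exact_two_tailed(3, 60, 5, 99), 2), 1.00)
  expect_equal(round(fisher_exact_two_tailed(0, 60, 9, 99), 3), 0.027)
  expect_equal(fisher_exact_two_tailed(1, 2, 1, 2), 1)
  set.seed(13)
  for (i in 1:50) {
    a0 <- sample(2:40, 1); b0 <- sample(2:40, 1)
    a1 <- sample(0:a0, 1); b1 <- sample(0:b0, 1)
    expect_equal(
      fisher_exact_two_tailed(a1, a0, b1, b0),
      fisher_exact_two_tailed(b1, b0, a1, a0),
      tolerance = 1e-12
    )
  }
})

test_that("affected-case counting is case-level and tolerates empty cohorts", {
  cohort <- make_reports(
    report_row("R1", reactions = c("ANXIETY", "ANXIETY", "HEADACHE")),
    report_row("R2", reactions = "HEADACHE"),
    report_row("R3", reactions = "ANXIETY")
  )
  expect_equal(count_affected(cohort, "ANXIETY"), 2)
  expect_equal(count_affected(cohort, "HEADACHE"), 2)
  expect_equal(count_affected(cohort, "ABSENT"), 0)
  expect_equal(count_affected(cohort[0, ], "ANXIETY"), 0)
})

test_that("top_events ranks by count with lexicographic ties and truncates", {
  cohort <- make_reports(
    report_row("R1", reactions = c("B TERM", "A TERM", "C TERM")),
    report_row("R2", reactions = c("B TERM", "A TERM")),
    report_row("R3", reactions = "C TERM")
  )
  top <- top_events(cohort, 10)
  expect_identical(top$event, c("A TERM", "B TERM", "C TERM"))
  expect_identical(top$affected, c(2L, 2L, 2L))
  expect_equal(nrow(top_events(cohort, 2)), 2)
  expect_equal(nrow(top_events(cohort[0, ], 5)), 0)
})

test_that("gender composition reproduces the published cohort rows", {
  fin <- gender_composition(2076, 60, 1750808, 2818346)
  expect_equal(round(fin$pct_male, 1), 97.2)
  expect_equal(round_half_up(fin$or_mf, 2), 55.70)
  expect_lt(fin$p_value, 1e-300)
  min <- gender_composition(92, 99, 1750808, 2818346)
  expect_equal(round(min$pct_male, 1), 48.2)
  expect_equal(round_half_up(min$or_mf, 2), 1.50)
  expect_equal(round(min$p_value, 4), 0.0058)
  self <- gender_composition(10, 20, 10, 20)
  expect_equal(self$or_mf, 1)
  expect_true(is.na(gender_composition(5, 0, 10, 20)$or_mf))
})

test_that("compare_drugs assembles published rows end to end", {
  cohorts <- alopecia_fixture_cohorts("male")
  cmp <- compare_drugs(cohorts$finasteride, cohorts$minoxidil)
  expect_s3_class(cmp, "prr_comparison")
  expect_equal(nrow(cmp), 16) # union of the two top-10 lists
  anx <- cmp[cmp$event == "ANXIETY", ]
  expect_equal(round(100 * anx$prop_a, 2), 32.32)
  expect_equal(round(100 * anx$prop_b, 2), 1.09)
  expect_equal(round_half_up(anx$prr, 2), 29.74)
  expect_identical(anx$stars, "***")

  cohorts_f <- alopecia_fixture_cohorts("female")
  counts_f <- alopecia_event_counts("female")
  cmp_f <- compare_drugs(cohorts_f$finasteride, cohorts_f$minoxidil,
                         events = counts_f$event)
  expect_equal(nrow(cmp_f), 20)
  # the default union of top-10 lists loses two tied terms to the
  # lexicographic tie-break in this stratum
  cmp_def <- compare_drugs(cohorts_f$finasteride, cohorts_f$minoxidil)
  expect_equal(nrow(cmp_def), 18)
  expect_true(all(cmp_def$event %in% counts_f$event))
  ab <- cmp_f[cmp_f$event == "ABORTION INDUCED", ]
  expect_equal(ab$prr, 9.07, tolerance = 0.01)
  expect_identical(ab$stars, "**")

  # an event absent from both cohorts: undefined PRR, p = 1
  cmp_abs <- compare_drugs(cohorts$finasteride, cohorts$minoxidil,
                           events = "NEVER REPORTED")
  expect_true(is.na(cmp_abs$prr))
  expect_equal(cmp_abs$p_value, 1)

  # sex strata must agree
  expect_error(
    compare_drugs(cohorts$finasteride, cohorts_f$minoxidil),
    "sex stratum"
  )
})

test_that("significance stars follow the 0.05/0.01/0.001 thresholds", {
  expect_identical(
    significance_stars(c(0.0005, 0.005, 0.04, 0.05, 0.2)),
    c("***", "**", "*", "", "")
  )
})

test_that("rendered tables show N/A, 0.00 and formatted p-values as printed", {
  expect_identical(format_prr(c(NA, 0, 11.588632)), c("N/A", "0.00", "11.59"))
  expect_identical(format_p_value(c(8.31432e-12, 0.24, 1, 0.077, 1e-310)),
                   c("8.31e-12", "0.24", "1.00", "0.077", "0"))
  cohorts <- alopecia_fixture_cohorts("female")
  cmp <- compare_drugs(cohorts$finasteride, cohorts$minoxidil)
  rendered <- render_comparison(cmp)
  palp <- rendered[rendered$event == "PALPITATIONS", ]
  expect_identical(palp$prr_ci, "0.00")
  swell <- rendered[rendered$event == "SWELLING FACE", ]
  expect_identical(swell$p_value, "0.027*")
})

test_that("comparison CSV export is long-format and numerically faithful", {
  cohorts <- alopecia_fixture_cohorts("male")
  cmp <- compare_drugs(cohorts$finasteride, cohorts$minoxidil)
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(cmp, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 2 * nrow(cmp))
  ed <- back[back$event == "ERECTILE DYSFUNCTION" & back$drug == "FINASTERIDE", ]
  expect_equal(ed$affected, 1046)
  expect_equal(ed$prr, 11.588632, tolerance = 1e-6)
})
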