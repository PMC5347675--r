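test_that("normalize_term uppercases, trims and collapses whitespace, idempotently", {
  expect_identical(normalize_term("  Alopecia   Areata "), "ALOPECIA AREATA")
  expect_identical(normalize_term("erectile dysfunction"), "ERECTILE DYSFUNCTION")
  expect_identical(normalize_term("ALOPECIA"), "ALOPECIA")
  raw <- c("  a  b ", "Mixed\tCase", "x", "UPPER  LOWER")
  once <- normalize_term(raw)
  expect_identical(normalize_term(once), once)
})

test_that("JSON-lines parsing maps openFDA fields, sex codes and set semantics", {
  lines <- c(
    jsonl_record(id = "R1", sex = "1",
                 reactions = list("ERECTILE DYSFUNCTION")),
    jsonl_record(id = "R2", sex = NULL, reactions = list("HEADACHE")),
    jsonl_record(id = "R3", sex = "0", reactions = list("HEADACHE")),
    jsonl_record(id = "R4", sex = "2",
                 reactions = list("nausea", " Nausea ", "RASH"))
  )
  reports <- parse_reports(lines, format = "jsonl")
  expect_equal(nrow(reports), 4)
  expect_identical(reports$sex, c("male", "unknown", "unknown", "female"))
  expect_identical(reports$reactions[[1]], "ERECTILE DYSFUNCTION")
  # duplicate reaction collapses after normalization
  expect_setequal(reports$reactions[[4]], c("NAUSEA", "RASH"))
  expect_identical(reports$receipt_date[1], as.Date("2010-05-01"))
  expect_identical(reports$drugs[[1]], "FINASTERIDE")
  expect_identical(reports$indications[[1]], "ANDROGENETIC ALOPECIA")
})

test_that("malformed records are collected and reaction-less reports dropped", {
  lines <- c(
    jsonl_record(id = "R1"),
    "{not json at all",
    jsonl_record(id = "R3", reactions = list())
  )
  expect_warning(
    expect_warning(reports <- parse_reports(lines, format = "jsonl"),
                   "no parseable reactions"),
    "malformed"
  )
  expect_equal(nrow(reports), 1)
  expect_identical(reports$report_id, "R1")
  expect_length(attr(reports, "problems"), 1)
})

test_that("flat CSV rows are reassembled per report and round-trip the writer", {
  csv <- paste(
    "report_id,receipt_date,sex,drug,indication,reaction",
    "R1,2010-05-01,1,FINASTERIDE,ANDROGENETIC ALOPECIA,ERECTILE DYSFUNCTION",
    "R1,2010-05-01,1,FINASTERIDE,ANDROGENETIC ALOPECIA,ANXIETY",
    "R1,2010-05-01,1,MINOXIDIL,,ANXIETY",
    "R2,2012-01-02,2,MINOXIDIL,ALOPECIA,HEADACHE",
    sep = "\n"
  )
  reports <- parse_reports(csv, format = "csv")
  expect_equal(nrow(reports), 2)
  r1 <- reports[reports$report_id == "R1", ]
  expect_setequal(r1$reactions[[1]], c("ERECTILE DYSFUNCTION", "ANXIETY"))
  expect_setequal(r1$drugs[[1]], c("FINASTERIDE", "MINOXIDIL"))
  expect_true(is.na(r1$indications[[1]][r1$drugs[[1]] == "MINOXIDIL"]))

  path <- withr::local_tempfile(fileext = ".csv")
  write_reports_csv(reports, path)
  again <- parse_reports(path, format = "csv")
  again <- again[order(again$report_id), ]
  expect_identical(again$report_id, reports$report_id)
  expect_identical(again$sex, reports$sex)
  expect_identical(lapply(again$reactions, sort), lapply(reports$reactions, sort))
})

test_that("JSON-lines writer round-trips through the parser", {
  reports <- make_reports(
    report_row("R1"),
    report_row("R2", sex = "unknown", reactions = c("HEADACHE", "RASH")),
    report_row("R3", sex = "female", drugs = c("MINOXIDIL", "ASPIRIN"),
               indications = c("ALOPECIA", NA))
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_reports_jsonl(reports, path)
  again <- parse_reports(path, format = "jsonl")
  expect_identical(again$report_id, reports$report_id)
  expect_identical(again$sex, reports$sex)
  expect_identical(again$receipt_date, reports$receipt_date)
  expect_identical(again$drugs, reports$drugs)
  expect_identical(again$indications, reports$indications)
  expect_identical(lapply(again$reactions, sort), lapply(reports$reactions, sort))
})

test_that("the default alopecia indication list holds exactly the 8 query terms", {
  terms <- default_alopecia_terms()
  expect_length(terms, 8)
  expect_true(all(c("ALOPECIA TOTALIS", "DIFFUSE ALOPECIA",
                    "ANDROGENETIC ALOPECIA") %in% terms))
  expect_false("HYPERTENSION" %in% terms)
  expect_identical(terms, normalize_term(terms))
})

test_that("cohort construction filters on sex, window, per-drug indication and exclusions", {
  reports <- make_reports(
    report_row("in_window"),
    report_row("unknown_sex", sex = "unknown"),
    report_row("female", sex = "female"),
    report_row("before", date = "2003-12-31"),
    report_row("window_start", date = "2004-01-01"),
    report_row("window_end", date = "2014-07-01"),
    report_row("last_day", date = "2014-06-30"),
    report_row("offlabel", indications = "BENIGN PROSTATIC HYPERPLASIA"),
    # qualifying indication only on the co-medication entry: must not count
    report_row("comed_indication", drugs = c("FINASTERIDE", "MINOXIDIL"),
               indications = c(NA, "ALOPECIA")),
    report_row("dual_exposure", drugs = c("FINASTERIDE", "MINOXIDIL"),
               indications = c("ALOPECIA", "ALOPECIA"))
  )
  cohort <- build_cohort(reports, "FINASTERIDE", "male",
                         exclude_drugs = "MINOXIDIL")
  expect_setequal(cohort$report_id, c("in_window", "window_start", "last_day"))
  expect_identical(attr(cohort, "drug"), "FINASTERIDE")

  # without the exclusion the dual-exposure report qualifies
  no_excl <- build_cohort(reports, "FINASTERIDE", "male")
  expect_true("dual_exposure" %in% no_excl$report_id)
  # empty result is a valid cohort
  empty <- build_cohort(reports, "UNSEEN DRUG", "male")
  expect_equal(nrow(empty), 0)
})

test_that("male, female and unknown-sex reports partition the drug-matching set", {
  set.seed(7)
  n <- 60
  reports <- do.call(make_reports, lapply(seq_len(n), function(i) {
    report_row(paste0("R", i),
               sex = sample(c("male", "female", "unknown"), 1),
               date = sample(c("2010-01-01", "2016-01-01"), 1),
               indications = sample(c("ALOPECIA", "HYPERTENSION"), 1))
  }))
  male <- build_cohort(reports, "FINASTERIDE", "male")
  female <- build_cohort(reports, "FINASTERIDE", "female")
  in_window <- reports$receipt_date < as.Date("2014-07-01")
  matches <- vapply(reports$indications, function(x)
    any(!is.na(x) & x == "ALOPECIA"), logical(1)) & in_window
  unknown <- reports$report_id[matches & reports$sex == "unknown"]
  expect_length(intersect(male$report_id, female$report_id), 0)
  expect_setequal(
    c(male$report_id, female$report_id, unknown),
    reports$report_id[matches]
  )
  # idempotence: rebuilding from the cohort's own reports keeps membership
  again <- build_cohort(male, "FINASTERIDE", "male")
  expect_setequal(again$report_id, male$report_id)
})

test_that("drug matching is case-insensitive and honours synonyms", {
  reports <- make_reports(
    report_row("R1", drugs = "Finasteride"),
    report_row("R2", drugs = "PROPECIA")
  )
  expect_equal(nrow(build_cohort(reports, "finasteride", "male")), 1)
  both <- build_cohort(reports, "FINASTERIDE", "male", synonyms = "PROPECIA")
  expect_setequal(both$report_id, c("R1", "R2"))
})
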