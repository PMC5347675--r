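# Handcrafted report rows for ingest and cohort tests.
make_reports <- function(...) {
  rows <- list(...)
  tibble::tibble(
    report_id = vapply(rows, `[[`, character(1), "id"),
    receipt_date = as.Date(vapply(rows, `[[`, character(1), "date")),
    sex = vapply(rows, `[[`, character(1), "sex"),
    drugs = lapply(rows, function(r) r$drugs),
    indications = lapply(rows, function(r) r$indications),
    reactions = lapply(rows, function(r) r$reactions)
  )
}

report_row <- function(id, date = "2010-05-01", sex = "male",
                       drugs = "FINASTERIDE",
                       indications = "ANDROGENETIC ALOPECIA",
                       reactions = "ERECTILE DYSFUNCTION") {
  list(id = id, date = date, sex = sex, drugs = drugs,
       indications = indications, reactions = reactions)
}

# openFDA-style JSON line built independently of the package writer.
jsonl_record <- function(id = "R1", date = "20100501", sex = "1",
                         drugs = list(list(medicinalproduct = "FINASTERIDE",
                                           drugindication = "ANDROGENETIC ALOPECIA")),
                         reactions = list("ERECTILE DYSFUNCTION")) {
  patient <- list(
    drug = drugs,
    reaction = lapply(reactions, function(r) list(reactionmeddrapt = r))
  )
  if (!is.null(sex)) patient <- c(list(patientsex = sex), patient)
  jsonlite::toJSON(
    list(safetyreportid = id, receiptdate = date, patient = patient),
    auto_unbox = TRUE
  )
}
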