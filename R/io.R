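#' Write reports as openFDA-style JSON lines
#'
#' Emits one JSON object per report in the same schema subset that
#' [parse_reports()] consumes, so generated collections round-trip.
#'
#' @param reports Report tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports_jsonl <- function(reports, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")
  lines <- vapply(seq_len(nrow(reports)), function(i) {
    drugs <- purrr::map2(
      reports$drugs[[i]], reports$indications[[i]],
      function(d, ind) {
        entry <- list(medicinalproduct = d)
        if (!is.na(ind)) entry$drugindication <- ind
        entry
      }
    )
    rec <- list(
      safetyreportid = reports$report_id[i],
      receiptdate = format(reports$receipt_date[i], "%Y%m%d"),
      patient = list(
        patientsex = unname(sex_code[reports$sex[i]]),
        drug = drugs,
        reaction = lapply(reports$reactions[[i]],
                          function(r) list(reactionmeddrapt = r))
      )
    )
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write reports as flat CSV
#'
#' One row per report x drug entry x reaction, the flat dialect
#' [parse_reports()] reassembles by `report_id`.
#'
#' @inheritParams write_reports_jsonl
#' @return `path`, invisibly.
#' @export
write_reports_csv <- function(reports, path) {
  rows <- purrr::pmap(reports, function(report_id, receipt_date, sex, drugs,
                                        indications, reactions, ...) {
    grid <- expand.grid(d = seq_along(drugs), r = seq_along(reactions))
    tibble(
      report_id = report_id,
      receipt_date = format(receipt_date, "%Y-%m-%d"),
      sex = c(male = "1", female = "2", unknown = "0")[[sex]],
      drug = drugs[grid$d],
      indication = indications[grid$d],
      reaction = reactions[grid$r]
    )
  })
  readr::write_csv(dplyr::bind_rows(rows), path, na = "")
  invisible(path)
}
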