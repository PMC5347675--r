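#' Normalize an adverse-event or indication term
#'
#' MedDRA preferred terms and drug names arrive from report streams with
#' inconsistent case and spacing. Normalization upper-cases the term, strips
#' leading/trailing whitespace, and collapses internal whitespace runs to a
#' single space. The operation is idempotent.
#'
#' @param raw Character vector of raw terms.
#' @return Character vector of normalized terms.
#' @examples
#' normalize_term("  Alopecia   Areata ")
#' @export
normalize_term <- function(raw) {
  toupper(stringr::str_squish(as.character(raw)))
}

# openFDA patientsex codes: 1 = male, 2 = female, anything else (incl. 0 or
# absent) carries no usable sex information.
decode_sex <- function(code) {
  code <- as.character(code)
  out <- rep("unknown", length(code))
  out[!is.na(code) & code == "1"] <- "male"
  out[!is.na(code) & code == "2"] <- "female"
  out
}

# openFDA receipt dates are CCYYMMDD strings; tolerate ISO dates too.
parse_receipt_date <- function(x) {
  x <- as.character(x)
  iso <- grepl("-", x, fixed = TRUE)
  out <- rep(as.Date(NA), length(x))
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[!iso] <- as.Date(x[!iso], format = "%Y%m%d")
  out
}

new_report_tbl <- function(report_id, receipt_date, sex, drugs, indications,
                           reactions) {
  tibble(
    report_id = as.character(report_id),
    receipt_date = receipt_date,
    sex = sex,
    drugs = drugs,
    indications = indications,
    reactions = reactions
  )
}

#' Parse spontaneous adverse-event reports
#'
#' Reads a report collection into a tidy one-row-per-report tibble. Two
#' on-disk dialects are supported:
#'
#' * `"jsonl"`: one JSON object per line, a subset of the openFDA drug-event
#'   schema (`safetyreportid`, `receiptdate`, `patient.patientsex`,
#'   `patient.drug[].medicinalproduct`, `patient.drug[].drugindication`,
#'   `patient.reaction[].reactionmeddrapt`).
#' * `"csv"`: flat rows with columns `report_id`, `receipt_date`, `sex`,
#'   `drug`, `indication`, `reaction` (one row per report x drug x reaction),
#'   reassembled by `report_id`.
#'
#' All reaction, drug and indication strings pass through [normalize_term()].
#' Duplicate reactions within a report collapse to one (case-level set
#' semantics). Reports with no parseable reaction are dropped with a warning.
#' Malformed JSON lines are collected, reported in a single warning, and
#' attached to the result as `attr(x, "problems")`; they are not fatal.
#'
#' @param source Path to the input file, or a character vector of lines
#'   (JSON-lines) / literal CSV text.
#' @param format `"jsonl"` or `"csv"`.
#' @return A tibble with columns `report_id`, `receipt_date`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), and list-columns `drugs`,
#'   `indications` (parallel character vectors per report; `NA` indication
#'   where the drug entry carries none) and `reactions` (character set).
#' @export
parse_reports <- function(source, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  switch(format,
    jsonl = parse_reports_jsonl(source),
    csv = parse_reports_csv(source)
  )
}

read_source_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

parse_reports_jsonl <- function(source) {
  lines <- read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  records <- vector("list", length(lines))
  problems <- character()
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) NULL
    )
    if (is.null(rec) || is.null(rec$safetyreportid)) {
      problems <- c(problems, sprintf("line %d: malformed record", i))
      next
    }
    records[[i]] <- rec
  }
  records <- records[!vapply(records, is.null, logical(1))]

  n <- length(records)
  reactions <- vector("list", n)
  drugs <- vector("list", n)
  indications <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[[i]]
    rx <- vapply(
      rec$patient$reaction %||% list(),
      function(r) as.character(r$reactionmeddrapt %||% NA_character_),
      character(1)
    )
    rx <- unique(normalize_term(rx[!is.na(rx) & nzchar(rx)]))
    reactions[[i]] <- rx
    dg <- rec$patient$drug %||% list()
    drugs[[i]] <- normalize_term(vapply(
      dg, function(d) as.character(d$medicinalproduct %||% NA_character_),
      character(1)
    ))
    ind <- vapply(
      dg, function(d) as.character(d$drugindication %||% NA_character_),
      character(1)
    )
    ind[!is.na(ind)] <- normalize_term(ind[!is.na(ind)])
    indications[[i]] <- ind
  }

  out <- new_report_tbl(
    report_id = vapply(records, function(r) as.character(r$safetyreportid), character(1)),
    receipt_date = parse_receipt_date(
      vapply(records, function(r) as.character(r$receiptdate %||% NA_character_), character(1))
    ),
    sex = decode_sex(
      vapply(records, function(r) as.character(r$patient$patientsex %||% NA_character_), character(1))
    ),
    drugs = drugs, indications = indications, reactions = reactions
  )
  finish_parsed_reports(out, problems)
}

parse_reports_csv <- function(source) {
  df <- suppressMessages(readr::read_csv(
    source,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  ))
  required <- c("report_id", "receipt_date", "sex", "drug", "indication", "reaction")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("CSV input lacks required columns: %s", paste(missing, collapse = ", ")))
  }
  df <- dplyr::mutate(
    df,
    drug = normalize_term(.data$drug),
    indication = dplyr::if_else(
      is.na(.data$indication) | !nzchar(trimws(.data$indication)),
      NA_character_, normalize_term(.data$indication)
    ),
    reaction = dplyr::if_else(
      is.na(.data$reaction) | !nzchar(trimws(.data$reaction)),
      NA_character_, normalize_term(.data$reaction)
    )
  )
  grouped <- dplyr::group_by(df, .data$report_id)
  out <- dplyr::summarise(
    grouped,
    receipt_date = parse_receipt_date(dplyr::first(.data$receipt_date)),
    sex = decode_sex(dplyr::first(.data$sex)),
    pairs = list(dplyr::distinct(dplyr::pick("drug", "indication"))),
    reactions = list(unique(.data$reaction[!is.na(.data$reaction)])),
    .groups = "drop"
  )
  res <- new_report_tbl(
    report_id = out$report_id,
    receipt_date = out$receipt_date,
    sex = out$sex,
    drugs = purrr::map(out$pairs, "drug"),
    indications = purrr::map(out$pairs, "indication"),
    reactions = out$reactions
  )
  finish_parsed_reports(res, character())
}

finish_parsed_reports <- function(reports, problems) {
  empty <- lengths(reports$reactions) == 0
  if (any(empty)) {
    warn(sprintf(
      "dropping %d report(s) with no parseable reactions: %s",
      sum(empty), paste(head(reports$report_id[empty], 5), collapse = ", ")
    ))
    reports <- reports[!empty, ]
  }
  if (length(problems) > 0) {
    warn(sprintf(
      "%d malformed record(s) skipped; see attr(x, \"problems\")",
      length(problems)
    ))
  }
  attr(reports, "problems") <- problems
  reports
}

#' Adverse-event query terms for alopecia indications
#'
#' The eight MedDRA preferred terms used to restrict report cohorts to drug
#' entries indicated for alopecia.
#'
#' @return Character vector of 8 normalized indication terms.
#' @export
default_alopecia_terms <- function() {
  c(
    "ALOPECIA", "ALOPECIA AREATA", "ALOPECIA EFFLUVIUM", "ALOPECIA SCARRING",
    "ALOPECIA TOTALIS", "ALOPECIA UNIVERSALIS", "ANDROGENETIC ALOPECIA",
    "DIFFUSE ALOPECIA"
  )
}

#' Default receipt-date window for cohort construction
#'
#' Half-open window `[2004-01-01, 2014-07-01)`, i.e. reports received from
#' January 2004 through June 2014.
#'
#' @return Date vector of length 2 (start, end).
#' @export
default_date_window <- function() {
  as.Date(c("2004-01-01", "2014-07-01"))
}

#' Build a sex-stratified drug/indication case cohort
#'
#' Filters a report tibble down to the reports that (i) have the requested
#' sex, (ii) have a receipt date inside the half-open window
#' `[start, end)`, (iii) carry at least one drug entry whose generic name
#' matches `drug` (or a supplied synonym) *and whose own indication term* is
#' in `indication_terms`, and (iv) carry no drug entry matching
#' `exclude_drugs`. Reports with unknown sex never enter a cohort. The
#' indication must be annotated on the matching drug's entry, mirroring the
#' per-drug `drugindication` field of openFDA records; an indication on a
#' co-medication does not qualify.
#'
#' @param reports Report tibble as returned by [parse_reports()] or
#'   [generate_reports()].
#' @param drug Normalized generic name of the exposure drug.
#' @param sex `"male"` or `"female"`.
#' @param indication_terms Character vector of qualifying indication terms.
#' @param date_window Date vector `c(start, end)`; half-open `[start, end)`.
#' @param exclude_drugs Drug names whose presence anywhere on the report
#'   disqualifies it (e.g. the comparator, to keep arms disjoint).
#' @param synonyms Additional names accepted as the exposure drug
#'   (case-insensitive exact match); default none.
#' @return The retained reports as a `case_cohort` tibble; attributes `drug`,
#'   `sex`, `indication_terms` and `date_window` record the query. An empty
#'   cohort is valid.
#' @export
build_cohort <- function(reports, drug, sex = c("male", "female"),
                         indication_terms = default_alopecia_terms(),
                         date_window = default_date_window(),
                         exclude_drugs = character(),
                         synonyms = character()) {
  sex <- match.arg(sex)
  stopifnot(length(indication_terms) >= 1)
  date_window <- as.Date(date_window)
  if (length(date_window) != 2 || is.na(date_window[1]) || is.na(date_window[2]) ||
      date_window[1] >= date_window[2]) {
    abort("`date_window` must be two dates with start < end")
  }
  names_ok <- normalize_term(c(drug, synonyms))
  indication_terms <- normalize_term(indication_terms)
  exclude_drugs <- normalize_term(exclude_drugs)

  keep_sex <- reports$sex == sex
  keep_date <- !is.na(reports$receipt_date) &
    reports$receipt_date >= date_window[1] &
    reports$receipt_date < date_window[2]

  # Flatten the per-report drug entries once; vectorized matching is much
  # cheaper than mapping over list-column elements.
  n_entries <- lengths(reports$drugs)
  idx <- rep.int(seq_len(nrow(reports)), n_entries)
  d <- normalize_term(unlist(reports$drugs, use.names = FALSE))
  ind <- unlist(reports$indications, use.names = FALSE)
  match_entry <- d %in% names_ok & !is.na(ind) & ind %in% indication_terms
  excl_entry <- d %in% exclude_drugs
  keep_drug <- keep_excl <- rep(FALSE, nrow(reports))
  if (length(idx) > 0) {
    keep_drug[unique(idx[match_entry])] <- TRUE
    keep_excl[unique(idx[excl_entry])] <- TRUE
  }

  out <- reports[keep_sex & keep_date & keep_drug & !keep_excl, ]
  if (anyDuplicated(out$report_id) > 0) {
    abort("duplicate report_id in cohort input")
  }
  new_case_cohort(out, drug = normalize_term(drug), sex = sex,
                  indication_terms = indication_terms,
                  date_window = date_window)
}

new_case_cohort <- function(x, drug, sex, indication_terms, date_window) {
  structure(
    x,
    drug = drug, sex = sex,
    indication_terms = indication_terms, date_window = date_window,
    class = c("case_cohort", class(tibble()))
  )
}

#' @export
print.case_cohort <- function(x, ...) {
  cat(sprintf(
    "<case_cohort> drug=%s sex=%s n=%d reports, window [%s, %s)\n",
    attr(x, "drug"), attr(x, "sex"), nrow(x),
    attr(x, "date_window")[1], attr(x, "date_window")[2]
  ))
  NextMethod()
}
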