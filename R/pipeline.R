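# Stage runners: thin orchestration over the module functions, driven by a
# plain-text (YAML) config. Each stage is re-runnable from on-disk
# intermediates, so a shell pipeline can chain synth -> disprop, etc.

#' Read a pipeline run configuration
#'
#' YAML file with stage-specific keys; see the individual `run_*` functions
#' for the keys each stage reads. A `seed` key seeds all randomness.
#'
#' @param path YAML config path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

config_spec <- function(config) {
  drugs <- dplyr::bind_rows(lapply(config$drugs, as_tibble))
  event_probs <- dplyr::bind_rows(lapply(config$event_probs, as_tibble))
  args <- list(drugs = drugs, event_probs = event_probs,
               seed = config$seed %||% 1L)
  for (key in c("indication_pool", "background_event_pool", "p_background",
                "date_window")) {
    if (!is.null(config[[key]])) args[[key]] <- config[[key]]
  }
  do.call(synthetic_cohort_spec, args)
}

#' Generate a synthetic report corpus on disk
#'
#' Writes `reports.jsonl` (the openFDA-style dialect [parse_reports()]
#' consumes) and `truth.csv` holding the analytic reporting-probability
#' ratios ([expected_prr()]) for every tested event and sex. Deterministic
#' for a fixed config seed.
#'
#' @param config List (or path read by [read_run_config()]) with keys
#'   `drugs`, `event_probs`, optional `indication_pool`,
#'   `background_event_pool`, `p_background`, `date_window`, `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
run_synth <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  spec <- config_spec(config)
  ensure_dir(out_dir)
  reports <- generate_reports(spec)
  reports_path <- file.path(out_dir, "reports.jsonl")
  write_reports_jsonl(reports, reports_path)
  truth <- tidyr::expand_grid(
    event = unique(spec$event_probs$event),
    sex = c("male", "female")
  )
  truth$expected_prr <- purrr::map2_dbl(
    truth$event, truth$sex,
    function(e, s) expected_prr(spec, e, s)
  )
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(truth, truth_path, na = "NA")
  invisible(c(reports = reports_path, truth = truth_path))
}

#' Run the disproportionality stage
#'
#' Parses the input reports, builds the requested drug/comparator cohorts per
#' sex stratum, and writes a gender-composition table
#' (`gender_composition.csv`), one comparison CSV and one rendered text table
#' per stratum, and a run log recording the count surviving each filter step.
#'
#' @param config List with keys `input` (path), `format` (`"jsonl"`/`"csv"`),
#'   `drug`, `comparator`, optional `drug_synonyms`, `comparator_synonyms`,
#'   `indication_terms`, `date_window`, `sex` (vector of strata, default
#'   both), `top_n`, `reference_male`/`reference_female` (background counts
#'   for the gender table).
#' @param out_dir Output directory.
#' @return Invisibly, a named list of written paths.
#' @export
run_disprop <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("input", "drug", "comparator")) {
    if (is.null(config[[key]])) abort(sprintf("config key `%s` is required", key))
  }
  if (!file.exists(config$input)) {
    abort(sprintf("input file not found: %s", config$input))
  }
  ensure_dir(out_dir)
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  reports <- parse_reports(config$input, format = config$format %||% "jsonl")
  say("parsed reports: %d", nrow(reports))
  say("reports with unknown sex (excluded from cohorts): %d",
      sum(reports$sex == "unknown"))

  indication_terms <- config$indication_terms %||% default_alopecia_terms()
  window <- as.Date(unlist(config$date_window %||% as.character(default_date_window())))
  strata <- config$sex %||% c("male", "female")
  top_n <- config$top_n %||% 10

  paths <- list()
  gender_rows <- list()
  for (sex in strata) {
    cohort_a <- build_cohort(
      reports, config$drug, sex,
      indication_terms = indication_terms, date_window = window,
      exclude_drugs = config$comparator,
      synonyms = config$drug_synonyms %||% character()
    )
    cohort_b <- build_cohort(
      reports, config$comparator, sex,
      indication_terms = indication_terms, date_window = window,
      exclude_drugs = config$drug,
      synonyms = config$comparator_synonyms %||% character()
    )
    say("[%s] %s cohort: %d; %s cohort: %d", sex,
        config$drug, nrow(cohort_a), config$comparator, nrow(cohort_b))
    if (nrow(cohort_a) == 0 || nrow(cohort_b) == 0) {
      warn(sprintf("empty cohort in %s stratum; writing empty table", sex))
      readr::write_csv(
        tibble(event = character(), drug = character(), affected = integer(),
               total = integer(), proportion = numeric(), prr = numeric(),
               ci_lower = numeric(), ci_upper = numeric(),
               p_value = numeric(), stars = character()),
        file.path(out_dir, sprintf("comparison_%s.csv", sex))
      )
      next
    }
    comparison <- compare_drugs(cohort_a, cohort_b, top_n = top_n)
    csv_path <- file.path(out_dir, sprintf("comparison_%s.csv", sex))
    write_comparison_csv(comparison, csv_path)
    txt_path <- file.path(out_dir, sprintf("comparison_%s.txt", sex))
    rendered <- render_comparison(comparison)
    writeLines(
      c(sprintf("# %s vs %s, %s cases (seed %s)",
                config$drug, config$comparator, sex,
                as.character(config$seed %||% "none")),
        utils::capture.output(print(as.data.frame(rendered), row.names = FALSE))),
      txt_path
    )
    paths[[sprintf("comparison_%s", sex)]] <- csv_path
  }

  if (all(c("male", "female") %in% strata)) {
    ref_m <- config$reference_male %||% alopecia_gender_counts()$male[1]
    ref_f <- config$reference_female %||% alopecia_gender_counts()$female[1]
    for (d in c(config$drug, config$comparator)) {
      other <- setdiff(c(config$drug, config$comparator), d)
      n_m <- nrow(build_cohort(reports, d, "male",
                               indication_terms = indication_terms,
                               date_window = window, exclude_drugs = other))
      n_f <- nrow(build_cohort(reports, d, "female",
                               indication_terms = indication_terms,
                               date_window = window, exclude_drugs = other))
      if (n_m + n_f > 0) {
        gender_rows[[d]] <- dplyr::mutate(
          gender_composition(n_m, n_f, ref_m, ref_f),
          drug = d, .before = 1
        )
      }
    }
    if (length(gender_rows) > 0) {
      gpath <- file.path(out_dir, "gender_composition.csv")
      readr::write_csv(dplyr::bind_rows(gender_rows), gpath)
      paths$gender_composition <- gpath
    }
  }

  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths$log <- log_path
  invisible(paths)
}

#' Run the drug-gene network stage
#'
#' Reads a drug-gene association TSV and a PPI edge TSV, builds the
#' drug-centered network, and writes the edge list, node metric table,
#' per-degree metric profiles and log-log power-law fit parameters.
#'
#' @param config List with keys `drug_gene_file`, `ppi_file`, `network_drug`.
#' @param out_dir Output directory.
#' @return Invisibly, the network object.
#' @export
run_network <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("drug_gene_file", "ppi_file", "network_drug")) {
    if (is.null(config[[key]])) abort(sprintf("config key `%s` is required", key))
  }
  fags <- read_drug_gene_tsv(config$drug_gene_file, drug = config$network_drug)
  if (length(fags) == 0) {
    abort(sprintf("no genes associated with %s in %s",
                  config$network_drug, config$drug_gene_file))
  }
  ppi <- read_ppi_tsv(config$ppi_file)
  network <- build_network(config$network_drug, fags, ppi)
  ensure_dir(out_dir)
  write_network(network, out_dir)

  fits <- list()
  for (metric in c("tc", "betweenness")) {
    profile <- degree_profile(network, metric)
    readr::write_tsv(profile,
                     file.path(out_dir, sprintf("profile_%s.tsv", metric)))
    usable <- profile[profile$value > 0, ]
    if (nrow(usable) >= 2 && length(unique(usable$degree)) >= 2) {
      fit <- fit_power_law(profile)
      fits[[metric]] <- tibble(metric = metric, a = fit$a, b = fit$b,
                               r_squared = fit$r_squared,
                               n_points = fit$n_points)
    }
  }
  if (length(fits) > 0) {
    readr::write_csv(dplyr::bind_rows(fits),
                     file.path(out_dir, "power_law_fits.csv"))
  }
  invisible(network)
}

#' Run the gene-set enrichment stage
#'
#' Reads a GMT collection and a query gene list (one symbol per line) and
#' writes the over-representation table.
#'
#' @param config List with keys `gmt_file`, `query_file`, optional
#'   `universe_file`.
#' @param out_dir Output directory.
#' @return Invisibly, the enrichment result.
#' @export
run_enrich <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("gmt_file", "query_file")) {
    if (is.null(config[[key]])) abort(sprintf("config key `%s` is required", key))
  }
  universe <- if (!is.null(config$universe_file)) {
    readLines(config$universe_file, warn = FALSE)
  }
  collection <- read_gmt(config$gmt_file, universe = universe)
  query <- readLines(config$query_file, warn = FALSE)
  query <- trimws(query[nzchar(trimws(query))])
  result <- enrich(query, collection)
  ensure_dir(out_dir)
  write_enrichment_csv(result, file.path(out_dir, "enrichment.csv"))
  invisible(result)
}
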