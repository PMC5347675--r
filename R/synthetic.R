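#' Specify a synthetic two-drug report collection
#'
#' Defines the generative model behind [generate_reports()]: two (or more)
#' drug arms with configurable size and sex composition, sex-specific
#' per-event reporting probabilities (so the true reporting-probability ratio
#' — the quantity the PRR estimates — is known analytically), a missing-sex
#' rate, off-label indications, and a pool of background reactions ensuring
#' every report carries at least one reaction.
#'
#' @param drugs Tibble with one row per arm and columns `drug`, `n_reports`,
#'   `p_male`, `p_sex_missing`, `p_offlabel_indication`.
#' @param event_probs Tibble with columns `drug`, `event`, `p_male`,
#'   `p_female`: the probability that a report in that arm lists the event,
#'   by (latent) sex.
#' @param indication_pool Non-alopecia indication terms drawn for off-label
#'   reports.
#' @param background_event_pool Reaction terms sampled as noise.
#' @param p_background Per-term inclusion probability for background events.
#' @param date_window Receipt dates are uniform over this half-open window.
#' @param seed Integer seed; identical specs generate identical collections.
#' @return A `synthetic_cohort_spec` object.
#' @export
synthetic_cohort_spec <- function(
    drugs = tibble(
      drug = c("FINASTERIDE", "MINOXIDIL"),
      n_reports = 2000L,
      p_male = 0.5,
      p_sex_missing = 0.02,
      p_offlabel_indication = 0.05
    ),
    event_probs = tibble(
      drug = rep(c("FINASTERIDE", "MINOXIDIL"), each = 2),
      event = rep(c("ERECTILE DYSFUNCTION", "ABORTION INDUCED"), 2),
      p_male = c(0.40, 0, 0.05, 0),
      p_female = c(0, 0.16, 0, 0.02)
    ),
    indication_pool = c("HYPERTENSION", "BENIGN PROSTATIC HYPERPLASIA"),
    background_event_pool = c("HEADACHE", "NAUSEA", "FATIGUE", "DIZZINESS",
                              "RASH", "PRURITUS"),
    p_background = 0.05,
    date_window = default_date_window(),
    seed = 1L) {
  drugs <- as_tibble(drugs)
  event_probs <- as_tibble(event_probs)
  need <- c("drug", "n_reports", "p_male", "p_sex_missing", "p_offlabel_indication")
  if (!all(need %in% names(drugs))) {
    abort(sprintf("`drugs` needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!all(c("drug", "event", "p_male", "p_female") %in% names(event_probs))) {
    abort("`event_probs` needs columns drug, event, p_male, p_female")
  }
  probs <- c(
    drugs$p_male, drugs$p_sex_missing, drugs$p_offlabel_indication,
    event_probs$p_male, event_probs$p_female, p_background
  )
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  if (any(drugs$n_reports < 1)) abort("each arm needs n_reports >= 1")
  if (nrow(event_probs) == 0) abort("event_probs must be non-empty")
  if (length(background_event_pool) == 0) {
    abort("background_event_pool must be non-empty")
  }
  if (!all(event_probs$drug %in% drugs$drug)) {
    abort("event_probs refers to drugs absent from `drugs`")
  }
  structure(
    list(
      drugs = dplyr::mutate(drugs, drug = normalize_term(.data$drug),
                            n_reports = as.integer(.data$n_reports)),
      event_probs = dplyr::mutate(event_probs,
                                  drug = normalize_term(.data$drug),
                                  event = normalize_term(.data$event)),
      indication_pool = normalize_term(indication_pool),
      background_event_pool = normalize_term(background_event_pool),
      p_background = p_background,
      date_window = as.Date(date_window),
      seed = as.integer(seed)
    ),
    class = "synthetic_cohort_spec"
  )
}

#' @export
print.synthetic_cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort_spec> %d arm(s), %d event prob(s), seed %d\n",
    nrow(x$drugs), nrow(x$event_probs), x$seed
  ))
  invisible(x)
}

#' Generate a seeded synthetic report collection
#'
#' Draws `n_reports` reports per drug arm. Latent sex is Bernoulli
#' (`p_male`), then masked to `"unknown"` with probability `p_sex_missing`
#' (events are still driven by the latent sex, as in real reports where sex
#' exists but was not recorded). Each tested event enters a report
#' independently with its sex-specific probability; background terms enter
#' with probability `p_background` each; a report that drew no reaction
#' receives one uniformly chosen background term, since spontaneous reports
#' always carry at least one reaction. The drug entry's indication is drawn
#' from the alopecia term list with probability `1 - p_offlabel_indication`,
#' otherwise from `indication_pool`. Output is deterministic given the spec
#' (including its seed); the session RNG state is left untouched.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return A report tibble in the same shape as [parse_reports()] returns.
#' @export
generate_reports <- function(spec) {
  if (!inherits(spec, "synthetic_cohort_spec")) {
    abort("`spec` must be a synthetic_cohort_spec")
  }
  withr::with_seed(spec$seed, {
    arms <- lapply(seq_len(nrow(spec$drugs)), function(i) {
      generate_arm(spec, spec$drugs[i, ])
    })
  })
  dplyr::bind_rows(arms)
}

generate_arm <- function(spec, arm) {
  n <- arm$n_reports
  drug <- arm$drug
  ev <- spec$event_probs[spec$event_probs$drug == drug, ]

  sex_true <- ifelse(runif(n) < arm$p_male, "male", "female")
  sex_obs <- ifelse(runif(n) < arm$p_sex_missing, "unknown", sex_true)

  ndays <- as.integer(spec$date_window[2] - spec$date_window[1])
  dates <- spec$date_window[1] + floor(runif(n) * ndays)

  male <- sex_true == "male"
  hit <- matrix(FALSE, n, nrow(ev))
  for (j in seq_len(nrow(ev))) {
    p <- ifelse(male, ev$p_male[j], ev$p_female[j])
    hit[, j] <- runif(n) < p
  }
  bg_pool <- spec$background_event_pool
  bg <- matrix(runif(n * length(bg_pool)) < spec$p_background, n)

  terms <- c(ev$event, bg_pool)
  mat <- cbind(hit, bg)
  reactions <- apply(mat, 1, function(row) terms[row], simplify = FALSE)
  empty <- lengths(reactions) == 0
  if (any(empty)) {
    rescue <- bg_pool[sample.int(length(bg_pool), sum(empty), replace = TRUE)]
    reactions[empty] <- as.list(rescue)
  }

  offlabel <- runif(n) < arm$p_offlabel_indication
  alopecia <- default_alopecia_terms()
  ind <- alopecia[sample.int(length(alopecia), n, replace = TRUE)]
  if (any(offlabel)) {
    pool <- spec$indication_pool
    ind[offlabel] <- pool[sample.int(length(pool), sum(offlabel), replace = TRUE)]
  }

  new_report_tbl(
    report_id = sprintf("%s-%06d", gsub("[^A-Z0-9]", "", drug), seq_len(n)),
    receipt_date = dates,
    sex = sex_obs,
    drugs = as.list(rep(drug, n)),
    indications = as.list(ind),
    reactions = reactions
  )
}

#' Analytic reporting-probability ratio of a synthetic spec
#'
#' The ground truth that the PRR estimates on data from
#' [generate_reports()]: the ratio of the two arms' sex-specific event
#' probabilities.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param event Event term.
#' @param sex `"male"` or `"female"`.
#' @param drug_a,drug_b Arm names; default the spec's first and second arms.
#' @return The true ratio, or `NA` when the comparator probability is zero
#'   (undefined, matching the PRR sentinel).
#' @export
expected_prr <- function(spec, event, sex = c("male", "female"),
                         drug_a = NULL, drug_b = NULL) {
  sex <- match.arg(sex)
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  drug_a <- normalize_term(drug_a %||% spec$drugs$drug[1])
  drug_b <- normalize_term(drug_b %||% spec$drugs$drug[2])
  event <- normalize_term(event)
  col <- if (sex == "male") "p_male" else "p_female"
  pick <- function(d) {
    row <- spec$event_probs[spec$event_probs$drug == d &
                              spec$event_probs$event == event, ]
    if (nrow(row) == 0) {
      abort(sprintf("event %s has no probability for drug %s", event, d))
    }
    row[[col]][1]
  }
  pa <- pick(drug_a)
  pb <- pick(drug_b)
  if (pb == 0) return(NA_real_)
  pa / pb
}

#' Reconstruct report cohorts from printed marginal counts
#'
#' Builds a deterministic report collection whose per-event affected-case
#' counts and cohort totals reproduce a printed comparison table exactly:
#' within each arm, the event with count k is assigned to the k
#' earliest-numbered reports, so overlapping events co-occur on the lowest
#' report ids and every marginal count round-trips through
#' [count_affected()]. Reports left with no event receive a report-specific
#' filler reaction (reports always carry at least one reaction); fillers are
#' unique per report so they never enter event rankings.
#'
#' @param counts Tibble with columns `event`, `a1`, `b1` (affected counts in
#'   the two arms).
#' @param a0,b0 Total case counts of the two arms.
#' @param drug_a,drug_b Drug names of the two arms.
#' @param sex Sex recorded on every report.
#' @param indication Indication term recorded on every drug entry.
#' @param receipt_date Receipt date recorded on every report.
#' @return A report tibble covering both arms.
#' @export
fixture_from_counts <- function(counts, a0, b0,
                                drug_a = "FINASTERIDE", drug_b = "MINOXIDIL",
                                sex = c("male", "female"),
                                indication = "ALOPECIA",
                                receipt_date = as.Date("2010-01-01")) {
  sex <- match.arg(sex)
  counts <- as_tibble(counts)
  stopifnot(all(c("event", "a1", "b1") %in% names(counts)))
  if (any(counts$a1 < 0) || any(counts$b1 < 0) ||
      any(counts$a1 > a0) || any(counts$b1 > b0)) {
    abort("infeasible counts: need 0 <= a1 <= a0 and 0 <= b1 <= b0")
  }
  events <- normalize_term(counts$event)
  build_arm <- function(drug, n, k, prefix) {
    reactions <- lapply(seq_len(n), function(i) events[k >= i])
    none <- lengths(reactions) == 0
    # one distinct filler per report so fillers never enter event rankings
    reactions[none] <- as.list(sprintf("UNSPECIFIED REACTION %s%05d",
                                       prefix, which(none)))
    new_report_tbl(
      report_id = sprintf("%s%05d", prefix, seq_len(n)),
      receipt_date = rep(receipt_date, n),
      sex = rep(sex, n),
      drugs = as.list(rep(normalize_term(drug), n)),
      indications = as.list(rep(normalize_term(indication), n)),
      reactions = reactions
    )
  }
  dplyr::bind_rows(
    build_arm(drug_a, a0, counts$a1, "A"),
    build_arm(drug_b, b0, counts$b1, "B")
  )
}
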