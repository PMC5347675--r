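check_contingency <- function(a1, a0, b1, b0) {
  n <- max(length(a1), length(a0), length(b1), length(b0))
  ok <- function(x) length(x) %in% c(1L, n) && all(!is.na(x)) &&
    all(x >= 0) && all(x == trunc(x))
  if (!ok(a1) || !ok(a0) || !ok(b1) || !ok(b0)) {
    abort("contingency counts must be non-negative integers of compatible length")
  }
  if (any(a0 <= 0) || any(b0 <= 0)) abort("cohort totals a0 and b0 must be positive")
  if (any(a1 > a0) || any(b1 > b0)) abort("affected counts cannot exceed cohort totals")
  invisible(n)
}

#' Proportional reporting ratio
#'
#' The PRR for an adverse event compares the reporting proportion of the
#' event between an exposure drug and a comparator:
#' `PRR = (a1/a0) / (b1/b0)`, where `a1` of `a0` exposure-drug cases and
#' `b1` of `b0` comparator cases report the event.
#'
#' Degenerate cells map to sentinels rather than errors: when the event is
#' unreported for the exposure drug (`a1 = 0`, `b1 > 0`) the PRR is exactly
#' `0`; when it is unreported for the comparator (`b1 = 0`) the ratio is
#' undefined and `NA` is returned (rendered "N/A" in tables).
#'
#' @param a1,a0 Affected and total case counts for the exposure drug.
#' @param b1,b0 Affected and total case counts for the comparator.
#' @return Numeric vector: the PRR, `0`, or `NA` (undefined).
#' @examples
#' prr(1046, 2076, 4, 92) # 11.59 to two decimals
#' @export
prr <- function(a1, a0, b1, b0) {
  check_contingency(a1, a0, b1, b0)
  out <- (a1 / a0) / (b1 / b0)
  out[b1 == 0] <- NA_real_ # undefined, including a1 = b1 = 0
  out[a1 == 0 & b1 > 0] <- 0
  out
}

#' Delta-method 95% confidence interval for the PRR
#'
#' On the log scale the PRR has approximate standard error
#' `sqrt(1/a1 + 1/b1 - 1/a0 - 1/b0)`, giving
#' `exp(log(PRR) -+ 1.96 * se)` as the 95% interval. The interval is
#' undefined (both bounds `NA`) whenever `a1 = 0` or `b1 = 0`.
#'
#' @inheritParams prr
#' @return A tibble with columns `lower` and `upper`.
#' @examples
#' prr_ci(1046, 2076, 4, 92) # (4.44, 30.25) to two decimals
#' @export
prr_ci <- function(a1, a0, b1, b0) {
  check_contingency(a1, a0, b1, b0)
  point <- (a1 / a0) / (b1 / b0)
  radicand <- 1 / a1 + 1 / b1 - 1 / a0 - 1 / b0
  defined <- a1 > 0 & b1 > 0
  if (any(radicand[defined] < 0)) {
    abort("negative variance estimate; counts violate a1 <= a0, b1 <= b0")
  }
  se <- sqrt(ifelse(defined, radicand, NA_real_))
  lower <- ifelse(defined, exp(log(point) - 1.96 * se), NA_real_)
  upper <- ifelse(defined, exp(log(point) + 1.96 * se), NA_real_)
  tibble(lower = lower, upper = upper)
}

#' Two-tailed Fisher exact test on reported-case counts
#'
#' Tests the null hypothesis of equal reporting (PRR = 1) between the two
#' drugs. The 2x2 table is laid out exactly as comparison tables print it —
#' cells `(a1, a0)` for the exposure drug row and `(b1, b0)` for the
#' comparator row, i.e. affected cases against total cases. The two-tailed
#' p-value sums the hypergeometric probabilities of all tables with the same
#' margins whose probability does not exceed that of the observed table
#' (within relative tolerance 1e-7), clipped at 1.
#'
#' @inheritParams prr
#' @return Numeric vector of p-values in `[0, 1]`.
#' @examples
#' fisher_exact_two_tailed(0, 60, 9, 99) # 0.027 to three decimals
#' @export
fisher_exact_two_tailed <- function(a1, a0, b1, b0) {
  n <- check_contingency(a1, a0, b1, b0)
  a1 <- rep_len(a1, n); a0 <- rep_len(a0, n)
  b1 <- rep_len(b1, n); b0 <- rep_len(b0, n)
  vapply(seq_len(n), function(i) {
    m <- matrix(c(a1[i], a0[i], b1[i], b0[i]), nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }, numeric(1))
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Count cohort cases reporting an event
#'
#' Case-level counting: each report contributes at most once regardless of
#' duplicate reaction entries.
#'
#' @param cohort A `case_cohort` (or any report tibble with a `reactions`
#'   list-column).
#' @param event_term Normalized event term.
#' @return Integer count of distinct affected reports.
#' @export
count_affected <- function(cohort, event_term) {
  stopifnot(length(event_term) == 1)
  if (nrow(cohort) == 0) return(0L)
  idx <- rep.int(seq_len(nrow(cohort)), lengths(cohort$reactions))
  hits <- idx[unlist(cohort$reactions, use.names = FALSE) == event_term]
  length(unique(hits))
}

#' Most commonly reported adverse events in a cohort
#'
#' Ranks event terms by affected-case count (case-level, deduplicated within
#' report), descending; ties break lexicographically by term. Returns fewer
#' than `n` rows when the cohort has fewer distinct terms.
#'
#' @param cohort A `case_cohort` or report tibble.
#' @param n Number of top events to return.
#' @return Tibble with columns `event` and `affected`, ordered by rank.
#' @export
top_events <- function(cohort, n = 10) {
  stopifnot(n >= 1)
  if (nrow(cohort) == 0) {
    return(tibble(event = character(), affected = integer()))
  }
  idx <- rep.int(seq_len(nrow(cohort)), lengths(cohort$reactions))
  long <- dplyr::distinct(tibble(
    report = idx,
    event = unlist(cohort$reactions, use.names = FALSE)
  ))
  counts <- dplyr::count(long, .data$event, name = "affected")
  counts <- dplyr::arrange(counts, dplyr::desc(.data$affected), .data$event)
  head(counts, n)
}

#' Gender composition of a cohort against a reference population
#'
#' Summarizes the male/female split of a drug cohort and contrasts it with a
#' reference population (e.g. the whole report database) through the
#' male-to-female odds ratio `OR = (male/female) / (ref_male/ref_female)`;
#' values above 1 indicate a cohort more male-dominated than the reference.
#' Significance comes from the two-tailed Fisher exact test on the 2x2 of
#' `(male, female)` vs `(ref_male, ref_female)`.
#'
#' @param male,female Case counts in the cohort.
#' @param ref_male,ref_female Case counts in the reference population.
#' @return One-row tibble: `male`, `female`, `pct_male` (percent),
#'   `or_mf` (`NA` when `female = 0`), `p_value`.
#' @examples
#' gender_composition(2076, 60, 1750808, 2818346)
#' @export
gender_composition <- function(male, female, ref_male, ref_female) {
  stopifnot(
    length(male) == 1, length(female) == 1,
    male >= 0, female >= 0, male + female > 0,
    ref_male > 0, ref_female > 0
  )
  or_mf <- if (female == 0) NA_real_ else (male / female) / (ref_male / ref_female)
  p <- stats::fisher.test(
    matrix(c(male, female, ref_male, ref_female), nrow = 2, byrow = TRUE)
  )$p.value
  tibble(
    male = male, female = female,
    pct_male = 100 * male / (male + female),
    or_mf = or_mf, p_value = p
  )
}

#' Compare adverse-event reporting between two drug cohorts
#'
#' Assembles one row per event from the component statistics: affected-case
#' counts ([count_affected()]), reporting proportions, PRR ([prr()]),
#' delta-method 95% CI ([prr_ci()]), two-tailed Fisher exact p
#' ([fisher_exact_two_tailed()]) and significance stars (thresholds
#' 0.05 / 0.01 / 0.001). By default the event list is the union of both
#' cohorts' top-`top_n` terms, sorted alphabetically.
#'
#' @param cohort_a Exposure-drug cohort.
#' @param cohort_b Comparator cohort; must share the sex stratum of
#'   `cohort_a`.
#' @param events Optional character vector of event terms; default the union
#'   of both cohorts' top-`top_n` lists.
#' @param top_n Size of each cohort's top list used for the default `events`.
#' @return A `prr_comparison` tibble with columns `event`, `a1`, `a0`, `b1`,
#'   `b0`, `prop_a`, `prop_b` (fractions), `prr` (`NA` when undefined),
#'   `ci_lower`, `ci_upper`, `p_value`, `stars`; attributes `drug_a`,
#'   `drug_b`, `sex`.
#' @export
compare_drugs <- function(cohort_a, cohort_b, events = NULL, top_n = 10) {
  sex_a <- attr(cohort_a, "sex")
  sex_b <- attr(cohort_b, "sex")
  if (!is.null(sex_a) && !is.null(sex_b) && !identical(sex_a, sex_b)) {
    abort("cohorts must share the same sex stratum")
  }
  if (is.null(events)) {
    events <- sort(union(top_events(cohort_a, top_n)$event,
                         top_events(cohort_b, top_n)$event))
  }
  if (length(events) == 0) {
    abort("no events to compare: both cohorts are empty and `events` is NULL")
  }
  events <- normalize_term(events)
  a0 <- nrow(cohort_a)
  b0 <- nrow(cohort_b)
  if (a0 == 0 || b0 == 0) abort("both cohorts must contain at least one report")
  a1 <- unname(vapply(events, function(e) count_affected(cohort_a, e), integer(1)))
  b1 <- unname(vapply(events, function(e) count_affected(cohort_b, e), integer(1)))
  ci <- prr_ci(a1, a0, b1, b0)
  p <- fisher_exact_two_tailed(a1, a0, b1, b0)
  out <- tibble(
    event = events,
    a1 = a1, a0 = a0, b1 = b1, b0 = b0,
    prop_a = a1 / a0, prop_b = b1 / b0,
    prr = prr(a1, a0, b1, b0),
    ci_lower = ci$lower, ci_upper = ci$upper,
    p_value = p,
    stars = significance_stars(p)
  )
  structure(
    out,
    drug_a = attr(cohort_a, "drug") %||% "drug A",
    drug_b = attr(cohort_b, "drug") %||% "drug B",
    sex = sex_a %||% sex_b,
    class = c("prr_comparison", class(tibble()))
  )
}
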