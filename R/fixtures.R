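# Published FAERS alopecia-cohort summary counts (2004-01 .. 2014-06 window),
# shipped so every comparison table can be reconstructed without the live API.

#' Gender composition counts of the alopecia case cohorts
#'
#' Male/female report counts for the whole FAERS background and the two
#' alopecia drug cohorts over the 2004-2014 study window.
#'
#' @return Tibble with columns `cohort`, `male`, `female`.
#' @export
alopecia_gender_counts <- function() {
  tibble(
    cohort = c("all_faers", "finasteride", "minoxidil"),
    male = c(1750808L, 2076L, 92L),
    female = c(2818346L, 60L, 99L)
  )
}

#' Published affected-case counts for the finasteride vs minoxidil comparison
#'
#' Per-event affected-case counts among alopecia cases, by sex stratum.
#' The male stratum has 16 events over cohorts of 2076 (finasteride) and 92
#' (minoxidil) cases; the female stratum has 20 events over 60 and 99 cases.
#' Each stratum's event list is the union of the two drugs' top-10 most
#' reported events.
#'
#' @param sex `"male"` or `"female"`.
#' @return Tibble with columns `event`, `a1` (finasteride affected), `b1`
#'   (minoxidil affected) and attributes `a0`, `b0` (cohort totals).
#' @export
alopecia_event_counts <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (sex == "male") {
    counts <- tibble(
      event = c(
        "ANXIETY", "CHORIORETINOPATHY", "COGNITIVE DISORDER", "DEPRESSION",
        "DERMATITIS CONTACT", "DIZZINESS", "EJACULATION DISORDER",
        "ERECTILE DYSFUNCTION", "FATIGUE", "HEADACHE", "HYPOESTHESIA",
        "LIBIDO DECREASED", "LOSS OF LIBIDO", "SEMEN VOLUME DECREASED",
        "SEXUAL DYSFUNCTION", "SKIN DISORDER"
      ),
      a1 = c(671L, 3L, 607L, 727L, 8L, 67L, 173L, 1046L, 232L, 84L, 40L,
             496L, 305L, 192L, 956L, 25L),
      b1 = c(1L, 6L, 0L, 3L, 6L, 5L, 1L, 4L, 2L, 6L, 4L, 1L, 1L, 1L, 0L, 3L)
    )
    a0 <- 2076L
    b0 <- 92L
  } else {
    counts <- tibble(
      event = c(
        "ABORTION INDUCED", "ABORTION SPONTANEOUS", "ARTHRALGIA", "ARTHRITIS",
        "DERMATITIS CONTACT", "DIZZINESS", "ENDOMETRIAL HYPERTROPHY",
        "FATIGUE", "MENORRHAGIA", "MENSTRUATION IRREGULAR", "NAUSEA",
        "PALPITATIONS", "PATERNAL DRUGS AFFECTING FETUS",
        "PHALANGEAL AGENESIS", "PRURITUS", "SWELLING FACE", "TACHYCARDIA",
        "UTERINE CERVIX STENOSIS", "VISUAL ACUITY REDUCED", "WEIGHT INCREASED"
      ),
      a1 = c(11L, 8L, 3L, 3L, 2L, 2L, 4L, 3L, 4L, 4L, 2L, 0L, 5L, 3L, 1L,
             0L, 0L, 4L, 0L, 0L),
      b1 = c(2L, 2L, 9L, 0L, 9L, 8L, 0L, 5L, 1L, 1L, 7L, 8L, 0L, 0L, 5L,
             9L, 6L, 0L, 5L, 5L)
    )
    a0 <- 60L
    b0 <- 99L
  }
  structure(counts, a0 = a0, b0 = b0)
}

#' Published top-10 adverse events, finasteride male stratum
#'
#' The one published top-10 ordering that is strictly descending in
#' affected-case counts (the other strata contain count ties whose printed
#' order is not reproducible from counts alone).
#'
#' @return Character vector of 10 normalized event terms in rank order.
#' @export
finasteride_male_top10 <- function() {
  c(
    "ERECTILE DYSFUNCTION", "SEXUAL DYSFUNCTION", "DEPRESSION", "ANXIETY",
    "COGNITIVE DISORDER", "LIBIDO DECREASED", "LOSS OF LIBIDO", "FATIGUE",
    "SEMEN VOLUME DECREASED", "EJACULATION DISORDER"
  )
}

#' Reconstruct a published comparison stratum as report cohorts
#'
#' Convenience wrapper: rebuilds the report collection for one sex stratum
#' from [alopecia_event_counts()] via [fixture_from_counts()] and returns the
#' two built cohorts.
#'
#' @param sex `"male"` or `"female"`.
#' @return List with elements `finasteride` and `minoxidil` (case cohorts).
#' @export
alopecia_fixture_cohorts <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  counts <- alopecia_event_counts(sex)
  reports <- fixture_from_counts(
    counts,
    a0 = attr(counts, "a0"), b0 = attr(counts, "b0"),
    drug_a = "FINASTERIDE", drug_b = "MINOXIDIL", sex = sex
  )
  list(
    finasteride = build_cohort(reports, "FINASTERIDE", sex),
    minoxidil = build_cohort(reports, "MINOXIDIL", sex)
  )
}

#' Packaged gene sets of the finasteride network enrichment
#'
#' The five reproductive-toxicity categories (two GO terms, three KEGG
#' pathways) with their published member gene lists, as a GMT-backed
#' collection. The universe defaults to the union of the members unless
#' overridden.
#'
#' @param universe Optional universe of gene symbols.
#' @return A [gene_set_collection()].
#' @export
finasteride_gene_sets <- function(universe = NULL) {
  read_gmt(
    system.file("extdata", "finasteride_reprotox_gene_sets.gmt",
                package = "prrsignal", mustWork = TRUE),
    universe = universe
  )
}
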