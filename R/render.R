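#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used for the
#' rendered PRR and CI columns; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

format_fixed <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Format a PRR point estimate for display
#'
#' Two decimals half-up; the undefined sentinel (`NA`, comparator count zero)
#' renders as `"N/A"` and an exact zero (exposure count zero) as `"0.00"`.
#'
#' @param prr Numeric vector from [prr()].
#' @return Character vector.
#' @export
format_prr <- function(prr) {
  ifelse(is.na(prr), "N/A", format_fixed(prr, 2))
}

#' Format a p-value for display
#'
#' Values below `1e-300` (including underflow to zero) render as `"0"`;
#' values below 0.01 use scientific notation with 3 significant digits;
#' larger values print with enough fixed decimals for 2 significant digits.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return("NA")
    if (x < 1e-300) return("0")
    if (x < 0.01) {
      mant <- formatC(x, format = "e", digits = 2)
      return(sub("e([+-])0?(\\d+)", "e\\1\\2", mant))
    }
    if (x < 0.095) return(formatC(signif(x, 2), format = "fg"))
    formatC(x, format = "f", digits = 2)
  }, character(1))
}

#' Render a drug comparison as a display table
#'
#' Formats a [compare_drugs()] result the way published comparison tables
#' print: two rows per event (exposure drug then comparator) with proportions
#' as percentages to two decimals, PRR and CI to two decimals half-up
#' (`"N/A"` for undefined rows, no CI when either affected count is zero),
#' and the p-value with significance stars on the exposure row.
#'
#' @param comparison A `prr_comparison` tibble.
#' @return Tibble of character columns `event`, `drug`, `affected`, `total`,
#'   `proportion`, `prr_ci`, `p_value`.
#' @export
render_comparison <- function(comparison) {
  stopifnot(inherits(comparison, "prr_comparison"))
  drug_a <- attr(comparison, "drug_a")
  drug_b <- attr(comparison, "drug_b")
  rows <- purrr::pmap(comparison, function(event, a1, a0, b1, b0, prop_a,
                                           prop_b, prr, ci_lower, ci_upper,
                                           p_value, stars, ...) {
    prr_cell <- format_prr(prr)
    if (!is.na(ci_lower)) {
      prr_cell <- sprintf("%s (%s - %s)", prr_cell,
                          format_fixed(ci_lower, 2), format_fixed(ci_upper, 2))
    }
    tibble(
      event = c(event, ""),
      drug = c(drug_a, drug_b),
      affected = c(a1, b1),
      total = c(a0, b0),
      proportion = paste0(format_fixed(100 * c(prop_a, prop_b), 2), "%"),
      prr_ci = c(prr_cell, ""),
      p_value = c(paste0(format_p_value(p_value), stars), "")
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a drug comparison to CSV
#'
#' Long-format machine-readable export: one row per event x drug with the
#' full-precision statistics repeated on both rows of each event.
#'
#' @param comparison A `prr_comparison` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  stopifnot(inherits(comparison, "prr_comparison"))
  long <- tibble(
    event = rep(comparison$event, each = 2),
    drug = rep(c(attr(comparison, "drug_a"), attr(comparison, "drug_b")),
               nrow(comparison)),
    affected = as.vector(rbind(comparison$a1, comparison$b1)),
    total = as.vector(rbind(comparison$a0, comparison$b0)),
    proportion = as.vector(rbind(comparison$prop_a, comparison$prop_b)),
    prr = rep(comparison$prr, each = 2),
    ci_lower = rep(comparison$ci_lower, each = 2),
    ci_upper = rep(comparison$ci_upper, each = 2),
    p_value = rep(comparison$p_value, each = 2),
    stars = rep(comparison$stars, each = 2)
  )
  readr::write_csv(long, path, na = "")
  invisible(path)
}
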