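#' Tidy a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return One row per parameter (`a`, `b`) with `estimate`.
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' One-row summary of a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return Tibble with `a`, `b`, `r.squared`, `n.points`.
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, r.squared = x$r_squared, n.points = x$n_points)
}

#' Node-level tidy view of a drug-gene network
#'
#' @param x A `drug_gene_network`.
#' @param ... Unused.
#' @return The [node_metrics()] tibble.
#' @export
tidy.drug_gene_network <- function(x, ...) {
  node_metrics(x)
}

#' One-row summary of a drug-gene network
#'
#' @param x A `drug_gene_network`.
#' @param ... Unused.
#' @return Tibble with node/edge/FAG/IAG counts.
#' @export
glance.drug_gene_network <- function(x, ...) {
  tibble(
    drug = x$drug,
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_fags = length(x$fags),
    n_iags = length(x$iags)
  )
}

#' Tidy view of a drug comparison
#'
#' @param x A `prr_comparison`.
#' @param ... Unused.
#' @return A plain tibble of the comparison rows.
#' @export
tidy.prr_comparison <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a drug comparison
#'
#' @param x A `prr_comparison`.
#' @param ... Unused.
#' @return Tibble with the cohort sizes and significant-event counts.
#' @export
glance.prr_comparison <- function(x, ...) {
  tibble(
    drug_a = attr(x, "drug_a"),
    drug_b = attr(x, "drug_b"),
    sex = attr(x, "sex") %||% NA_character_,
    n_events = nrow(x),
    n_a = if (nrow(x)) x$a0[1] else NA_integer_,
    n_b = if (nrow(x)) x$b0[1] else NA_integer_,
    n_significant = sum(x$p_value < 0.05)
  )
}
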