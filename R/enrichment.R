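#' Assemble a gene-set collection
#'
#' Bundles named gene sets with the annotation universe used by [enrich()].
#' When `universe` is not supplied it defaults to the union of all set
#' members — the reference-set behavior of common over-representation
#' servers. Members outside a supplied universe are dropped from their sets.
#'
#' @param sets Named list of character vectors (category id -> members).
#' @param universe Optional character vector of gene symbols.
#' @param names Optional named character vector of human-readable category
#'   names (defaults to the ids).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, names = NULL) {
  if (length(sets) == 0 || is.null(base::names(sets)) ||
      anyDuplicated(base::names(sets)) > 0) {
    abort("`sets` must be a non-empty list with unique names")
  }
  sets <- lapply(sets, function(s) unique(trimws(as.character(s))))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- unique(trimws(as.character(universe)))
    sets <- lapply(sets, intersect, universe)
  }
  display <- setNames(base::names(sets), base::names(sets))
  if (!is.null(names)) display[base::names(names)] <- names
  structure(
    list(sets = sets, names = display, universe = universe),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: category id, description, then members.
#'
#' @param path GMT file path.
#' @param universe Optional universe passed to [gene_set_collection()].
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  # recover the description column for display names
  lines <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  lines <- lines[lengths(lines) >= 2]
  desc <- setNames(
    vapply(lines, `[[`, character(1), 2),
    vapply(lines, `[[`, character(1), 1)
  )
  gene_set_collection(sets, universe = universe, names = desc)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric with `N` genes in the universe, `K` of
#' them in the category, and `n` drawn (the query size): the
#' over-representation p-value of an overlap of size `k`.
#'
#' @param k Observed overlap count.
#' @param K Category size.
#' @param n Query size.
#' @param N Universe size.
#' @return Numeric vector of probabilities.
#' @examples
#' hypergeometric_upper_tail(3, 4, 5, 10) # 66/252
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    abort("need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: with the p-values sorted
#' ascending, `q(i) = min over j >= i of p(j) * m / j`, clipped at 1, and
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests every category of a collection for over-representation of a query
#' gene list, restricted to the collection's universe. Categories with no
#' overlap are not tested. Each tested row reports the overlap, the
#' enrichment ratio `R = k / (n K / N)` (observed over expected overlap, the
#' "OR of enrichment" convention of WebGestalt-style reports), the sample
#' odds ratio of the underlying 2x2, the raw hypergeometric upper-tail p and
#' its Benjamini-Hochberg adjustment across the tested categories.
#'
#' @param query Character vector of gene symbols.
#' @param collection A [gene_set_collection()].
#' @return An `enrichment_result` tibble sorted by adjusted then raw p:
#'   columns `category_id`, `name`, `k`, `n`, `K`, `N`, `overlap_genes`
#'   (list), `enrichment_ratio`, `odds_ratio`, `p_raw`, `p_adjusted`.
#' @export
enrich <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(trimws(as.character(query)))
  q <- intersect(query, collection$universe)
  if (length(q) == 0) {
    abort(sprintf(
      "query does not intersect the universe (%d query genes, %d universe genes); check symbol conventions",
      length(query), length(collection$universe)
    ))
  }
  N <- length(collection$universe)
  n <- length(q)
  rows <- purrr::imap(collection$sets, function(members, id) {
    overlap <- intersect(q, members)
    tibble(
      category_id = id,
      name = unname(collection$names[[id]]),
      k = length(overlap),
      n = n,
      K = length(members),
      N = N,
      overlap_genes = list(sort(overlap))
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$k >= 1, ]
  if (nrow(out) == 0) {
    warn("no category overlaps the query")
    return(structure(
      dplyr::mutate(out, enrichment_ratio = numeric(0), odds_ratio = numeric(0),
                    p_raw = numeric(0), p_adjusted = numeric(0)),
      class = c("enrichment_result", class(tibble()))
    ))
  }
  out$enrichment_ratio <- out$k / (out$n * out$K / out$N)
  out$odds_ratio <- with(out, (k / (n - k)) / ((K - k) / (N - K - n + k)))
  out$p_raw <- hypergeometric_upper_tail(out$k, out$K, out$n, out$N)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out <- dplyr::arrange(out, .data$p_adjusted, .data$p_raw, .data$category_id)
  structure(out, class = c("enrichment_result", class(tibble())))
}

#' Write an enrichment result to CSV
#'
#' Columns mirror published over-representation tables: the category, its
#' overlapping genes (semicolon-separated), the enrichment ratio (labelled
#' OR), and raw/adjusted p-values.
#'
#' @param result An `enrichment_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment_csv <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  flat <- dplyr::mutate(
    as_tibble(result),
    overlap_genes = vapply(.data$overlap_genes, paste, character(1),
                           collapse = ";")
  )
  readr::write_csv(flat, path)
  invisible(path)
}
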