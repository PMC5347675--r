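#' Build a drug-centered drug-gene network
#'
#' Starts from the genes with direct drug-association evidence (FAGs,
#' "drug-associated genes") and recruits their first neighbors from a
#' protein-protein interaction edge list; the recruited genes are the
#' indirectly associated genes (IAGs). The resulting graph is simple and
#' undirected: one edge from the drug node to every FAG, plus every PPI edge
#' with at least one FAG endpoint. PPI edges between two IAGs are not
#' retained (first-neighbor recruitment without closure), and self-loops and
#' duplicate edges are dropped.
#'
#' @param drug Drug node identifier.
#' @param fags Character vector of directly associated gene symbols.
#' @param ppi_edges Two-column data frame (or matrix) of undirected gene-gene
#'   interaction pairs.
#' @return A `drug_gene_network`: list with elements `graph` (igraph),
#'   `drug`, `fags`, `iags`.
#' @export
build_network <- function(drug, fags, ppi_edges) {
  fags <- unique(trimws(as.character(fags)))
  fags <- fags[nzchar(fags)]
  if (length(fags) == 0) abort("`fags` must contain at least one gene symbol")
  ppi <- as.data.frame(ppi_edges)
  if (nrow(ppi) > 0 && ncol(ppi) < 2) abort("`ppi_edges` needs two columns")
  drug <- trimws(as.character(drug))
  if (drug %in% fags) abort("the drug identifier collides with a gene symbol")

  if (nrow(ppi) > 0) {
    from <- trimws(as.character(ppi[[1]]))
    to <- trimws(as.character(ppi[[2]]))
    keep <- (from %in% fags | to %in% fags) & from != to &
      nzchar(from) & nzchar(to)
    from <- from[keep]
    to <- to[keep]
  } else {
    from <- to <- character()
  }
  edges <- rbind(
    cbind(rep(drug, length(fags)), fags),
    cbind(from, to)
  )
  # canonical order within each pair, then dedupe
  swap <- edges[, 1] > edges[, 2]
  edges[swap, ] <- edges[swap, 2:1]
  edges <- unique(edges)

  iags <- setdiff(unique(c(from, to)), c(fags, drug))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = c(drug, fags, iags))
  )
  structure(
    list(graph = g, drug = drug, fags = fags, iags = iags),
    class = "drug_gene_network"
  )
}

#' @export
print.drug_gene_network <- function(x, ...) {
  cat(sprintf(
    "<drug_gene_network> drug=%s: %d FAGs, %d IAGs, %d nodes, %d edges\n",
    x$drug, length(x$fags), length(x$iags),
    igraph::vcount(x$graph), igraph::ecount(x$graph)
  ))
  invisible(x)
}

as_igraph_network <- function(network) {
  if (inherits(network, "drug_gene_network")) network$graph
  else if (inherits(network, "igraph")) network
  else abort("`network` must be a drug_gene_network or igraph graph")
}

#' Topological coefficient of network nodes
#'
#' For a node n with degree k(n), consider every other node m sharing at
#' least one neighbor with n, and let J(n, m) be the number of shared
#' neighbors plus 1 if n and m are directly linked. The topological
#' coefficient is `TC(n) = mean(J(n, m)) / k(n)` (the Cytoscape convention).
#' Nodes with no qualifying partner, or degree zero, have no defined value
#' (`NA`). Defined values lie in (0, 1]; in scale-free networks TC decreases
#' with degree roughly as a power law.
#'
#' @param network A `drug_gene_network` or igraph graph.
#' @param nodes Node names; default all nodes.
#' @return Named numeric vector of TC values (`NA` where undefined).
#' @export
topological_coefficient <- function(network, nodes = NULL) {
  g <- as_igraph_network(network)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  diag(a) <- 0
  all_names <- igraph::V(g)$name
  nodes <- nodes %||% all_names
  missing <- setdiff(nodes, all_names)
  if (length(missing) > 0) {
    abort(sprintf("nodes not in network: %s", paste(missing, collapse = ", ")))
  }
  shared <- a %*% a # shared-neighbor counts between every node pair
  deg <- rowSums(a)
  out <- vapply(nodes, function(v) {
    k <- deg[[v]]
    if (k == 0) return(NA_real_)
    partners <- all_names[shared[v, ] > 0 & all_names != v]
    if (length(partners) == 0) return(NA_real_)
    j <- shared[v, partners] + a[v, partners]
    mean(j) / k
  }, numeric(1))
  setNames(out, nodes)
}

#' Pair-normalized betweenness centrality
#'
#' Shortest-path betweenness of every node, normalized by the number of
#' ordered node pairs excluding the node itself, `2 / ((N - 1) (N - 2))` for
#' an undirected graph on N nodes, so values lie in `[0, 1]`. Graphs with
#' fewer than 3 nodes have no mediated pairs and return all zeros.
#'
#' @param network A `drug_gene_network` or igraph graph.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(network) {
  g <- as_igraph_network(network)
  n <- igraph::vcount(g)
  if (n < 3) {
    return(setNames(rep(0, n), igraph::V(g)$name))
  }
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(b), igraph::V(g)$name)
}

#' Node metric table for a drug-gene network
#'
#' One row per node with its role (`drug`, `FAG` or `IAG`), degree,
#' topological coefficient and normalized betweenness.
#'
#' @param network A `drug_gene_network`.
#' @return Tibble with columns `node`, `role`, `degree`, `tc`, `betweenness`.
#' @export
node_metrics <- function(network) {
  stopifnot(inherits(network, "drug_gene_network"))
  g <- network$graph
  name <- igraph::V(g)$name
  role <- dplyr::case_when(
    name == network$drug ~ "drug",
    name %in% network$fags ~ "FAG",
    TRUE ~ "IAG"
  )
  tibble(
    node = name,
    role = role,
    degree = as.integer(igraph::degree(g)),
    tc = unname(topological_coefficient(network)),
    betweenness = unname(betweenness_centrality(network))
  )
}

#' Per-degree averages of a node metric
#'
#' Prepares the scatter data for the scale-free diagnostics: the mean of a
#' node metric (topological coefficient or betweenness) over all nodes of
#' each degree, after dropping nodes where the metric is undefined. Pairs
#' with zero mean are retained here and excluded by [fit_power_law()].
#'
#' @param network A `drug_gene_network` or igraph graph.
#' @param metric `"tc"` or `"betweenness"`.
#' @return Tibble with columns `degree` and `value`, ascending in degree.
#' @export
degree_profile <- function(network, metric = c("tc", "betweenness")) {
  metric <- match.arg(metric)
  g <- as_igraph_network(network)
  value <- switch(metric,
    tc = unname(topological_coefficient(g)),
    betweenness = unname(betweenness_centrality(g))
  )
  df <- tibble(degree = as.integer(igraph::degree(g)), value = value)
  df <- df[!is.na(df$value), ]
  if (nrow(df) == 0) return(tibble(degree = integer(), value = numeric()))
  out <- dplyr::summarise(dplyr::group_by(df, .data$degree),
                          value = mean(.data$value), .groups = "drop")
  dplyr::arrange(out, .data$degree)
}

#' Fit a power law by least squares on the log-log scale
#'
#' Fits `y = a * x^b` by ordinary least squares of `log(y)` on `log(x)`;
#' `r_squared` is the coefficient of determination on the fitted (log-log)
#' scale. Points with non-positive y (or x) are excluded before fitting.
#' Degenerate constant-y input fits a zero-slope model exactly and reports
#' `r_squared = 1`.
#'
#' @param points Data frame with columns `x` (or `degree`) and `y` (or
#'   `value`), or a numeric vector `x` with `y` supplied separately.
#' @param y Optional numeric vector when `points` is a vector.
#' @return A `power_law_fit`: list with `a`, `b`, `r_squared`, `n_points`,
#'   and the fitted `model`.
#' @export
fit_power_law <- function(points, y = NULL) {
  if (is.null(y)) {
    df <- as.data.frame(points)
    names(df)[match(c("degree", "value"), names(df), nomatch = 0)] <- c("x", "y")
    if (!all(c("x", "y") %in% names(df))) {
      abort("`points` needs columns x/y (or degree/value)")
    }
  } else {
    df <- data.frame(x = as.numeric(points), y = as.numeric(y))
  }
  df <- df[!is.na(df$x) & !is.na(df$y) & df$x > 0 & df$y > 0, ]
  if (nrow(df) < 2 || length(unique(df$x)) < 2) {
    abort("need at least 2 points with distinct positive x and positive y")
  }
  fit <- lm(log(y) ~ log(x), data = df)
  res <- stats::residuals(fit)
  tss <- sum((log(df$y) - mean(log(df$y)))^2)
  rss <- sum(res^2)
  r2 <- if (tss < 1e-12) {
    if (rss < 1e-12) 1 else 0
  } else {
    1 - rss / tss
  }
  structure(
    list(
      a = unname(exp(coef(fit)[1])),
      b = unname(coef(fit)[2]),
      r_squared = r2,
      n_points = nrow(df),
      data = as_tibble(df),
      model = fit
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> y = %.4g * x^%.4g, R^2 = %.4f (n = %d)\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Export a drug-gene network to TSV files
#'
#' Writes `edges.tsv` (two columns, one row per undirected edge) and
#' `nodes.tsv` (the [node_metrics()] table) under `dir`.
#'
#' @param network A `drug_gene_network`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "drug_gene_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  el <- igraph::as_edgelist(network$graph)
  edges_path <- file.path(dir, "edges.tsv")
  nodes_path <- file.path(dir, "nodes.tsv")
  readr::write_tsv(tibble(from = el[, 1], to = el[, 2]), edges_path)
  readr::write_tsv(node_metrics(network), nodes_path)
  invisible(c(edges = edges_path, nodes = nodes_path))
}

#' Read a drug-gene association TSV
#'
#' Two-column TSV (`drug`, `gene`), optionally with extra evidence columns
#' (ignored), emulating a PharmGKB/DrugBank association export.
#'
#' @param path File path.
#' @param drug Optional drug name to filter on.
#' @return Character vector of associated gene symbols.
#' @export
read_drug_gene_tsv <- function(path, drug = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2) abort(sprintf("%s: expected >= 2 tab-separated columns", path))
  names(df)[1:2] <- c("drug", "gene")
  if (!is.null(drug)) {
    df <- df[normalize_term(df$drug) == normalize_term(drug), ]
  }
  unique(trimws(df$gene))
}

#' Read a protein-protein interaction edge TSV
#'
#' Two-column TSV of gene symbols, one undirected interaction per row,
#' emulating a BioGRID physical-interaction extract.
#'
#' @param path File path.
#' @return Tibble with columns `from` and `to`.
#' @export
read_ppi_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (ncol(df) < 2) abort(sprintf("%s: expected >= 2 tab-separated columns", path))
  tibble(from = trimws(df[[1]]), to = trimws(df[[2]]))
}
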