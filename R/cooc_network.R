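#' Build a document-level co-occurrence network
#'
#' Nodes are canonical terms (optionally restricted to some categories) with
#' occurrence = number of documents containing the term; an edge's link
#' strength is the number of documents co-mentioning both endpoints
#' (VOSviewer-style, binary per document); a node's total link strength is
#' the sum of its incident link strengths.
#'
#' @param index an `hs_mentions` index from [tag_corpus()].
#' @param min_occurrence keep only terms occurring in at least this many
#'   documents (default 1).
#' @param categories optional character vector of lexicon categories to
#'   include; default all.
#' @return object of class `hs_cooc`: list with data frames `nodes`
#'   (`term`, `category`, `occurrence`, `total_link_strength`) and `edges`
#'   (`source`, `target`, `link_strength`).
#' @export
build_graph <- function(index, min_occurrence = 1, categories = NULL) {
  if (!nrow(index)) hs_compute_error("cannot build a graph from an empty mention index")
  if (!is.null(categories)) index <- index[index$category %in% categories, , drop = FALSE]
  if (!nrow(index)) hs_compute_error("no mentions left after category filtering")
  terms <- unique(index[, c("category", "term")])
  terms$key <- paste(terms$category, terms$term)
  dup <- duplicated(terms$term) | duplicated(terms$term, fromLast = TRUE)
  terms$term[dup] <- paste(terms$category[dup], terms$term[dup], sep = ":")
  ids <- unique(index$id)
  # binary document x term incidence
  m <- Matrix::sparseMatrix(i = match(index$id, ids),
                            j = match(paste(index$category, index$term), terms$key),
                            x = 1, dims = c(length(ids), nrow(terms)))
  m@x[] <- 1
  occ <- Matrix::colSums(m)
  keep <- occ >= min_occurrence
  if (!any(keep)) hs_compute_error("no terms meet min_occurrence")
  m <- m[, keep, drop = FALSE]
  terms <- terms[keep, , drop = FALSE]
  occ <- occ[keep]
  co <- as.matrix(Matrix::crossprod(m))
  diag(co) <- 0
  ut <- which(upper.tri(co) & co > 0, arr.ind = TRUE)
  edges <- data.frame(source = terms$term[ut[, 1]], target = terms$term[ut[, 2]],
                      link_strength = co[ut], stringsAsFactors = FALSE)
  nodes <- data.frame(term = terms$term, category = terms$category,
                      occurrence = as.integer(occ),
                      total_link_strength = as.integer(rowSums(co)),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges), class = "hs_cooc")
}

# hs_cooc -> igraph with link_strength edge weights
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = graph$nodes$term)
  igraph::E(g)$link_strength <- graph$edges$link_strength
  g
}

#' Node centralities with eigenvector fallback
#'
#' Degree centrality `deg(v)/(N-1)`, betweenness centrality on unweighted
#' shortest paths normalized to \[0, 1\], and eigenvector centrality by power
#' iteration on the link-strength-weighted adjacency matrix (tolerance 1e-8,
#' at most 1000 iterations, scaled so the maximum is 1). When the iteration
#' fails to converge, or the graph is disconnected so no dominant eigenvector
#' is defined, eigenvector values are replaced by degree centrality and the
#' `method` flag records the fallback.
#'
#' @param graph an `hs_cooc` network.
#' @return data frame `term`, `degree`, `betweenness`, `eigenvector`,
#'   `method` (`"power_iteration"` or `"degree_fallback"`).
#' @export
centralities <- function(graph) {
  n <- nrow(graph$nodes)
  if (n < 2) hs_validation_error("centralities need at least 2 nodes")
  g <- as_igraph(graph)
  deg <- igraph::degree(g) / (n - 1)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = TRUE)
  adj <- igraph::as_adjacency_matrix(g, attr = "link_strength", sparse = FALSE)
  ev <- power_iteration(adj)
  connected <- igraph::is_connected(g)
  if (!connected || !ev$converged) {
    eig <- deg / max(deg)
    method <- "degree_fallback"
  } else {
    eig <- ev$vector / max(ev$vector)
    method <- "power_iteration"
  }
  data.frame(term = graph$nodes$term, degree = as.numeric(deg),
             betweenness = as.numeric(btw), eigenvector = as.numeric(eig),
             method = method, stringsAsFactors = FALSE, row.names = NULL)
}

# power iteration for the dominant eigenvector of a nonnegative symmetric
# matrix; sup-norm convergence test
power_iteration <- function(adj, tol = 1e-8, max_iter = 1000) {
  n <- nrow(adj)
  if (all(adj == 0)) return(list(vector = rep(0, n), converged = FALSE))
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    y <- as.numeric(adj %*% x)
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(list(vector = x, converged = FALSE))
    y <- y / nrm
    if (max(abs(y - x)) < tol) return(list(vector = y, converged = TRUE))
    x <- y
  }
  list(vector = x, converged = FALSE)
}

#' Frequency vs total link strength fit
#'
#' Ordinary least squares of total link strength on term occurrence count;
#' returns the coefficient of determination.
#'
#' @param graph an `hs_cooc` network.
#' @return R-squared of the fit.
#' @export
frequency_tls_correlation <- function(graph) {
  nd <- graph$nodes
  if (nrow(nd) < 3) hs_validation_error("need at least 3 nodes")
  if (var(nd$occurrence) == 0 || var(nd$total_link_strength) == 0)
    hs_compute_error("zero variance in occurrence or total link strength")
  # simple regression: the coefficient of determination is the squared
  # Pearson correlation, computed directly to stay exact on perfect fits
  cor(nd$occurrence, nd$total_link_strength)^2
}

#' Export a co-occurrence network
#'
#' `write_graphml()` writes GraphML (via igraph); `write_edges_csv()` writes
#' `source,target,link_strength`; `write_nodes_csv()` writes the node table
#' joined with [centralities()].
#'
#' @param graph an `hs_cooc` network.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  g <- as_igraph(graph)
  igraph::V(g)$category <- graph$nodes$category
  igraph::V(g)$occurrence <- graph$nodes$occurrence
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edges_csv <- function(graph, path) {
  utils::write.csv(graph$edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_nodes_csv <- function(graph, path) {
  cen <- centralities(graph)
  out <- merge(graph$nodes, cen, by = "term", sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
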