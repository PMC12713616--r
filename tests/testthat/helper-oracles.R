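# Fabricate an hs_mentions index from a list of per-document entity vectors
# (entities may repeat for multiple occurrences).
make_index <- function(entity_lists, category = "polymer") {
  ids <- sprintf("d%03d", seq_along(entity_lists))
  rows <- do.call(rbind, lapply(seq_along(entity_lists), function(i) {
    ents <- entity_lists[[i]]
    if (!length(ents)) return(NULL)
    tab <- table(ents)
    data.frame(id = ids[i], category = category, term = names(tab),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(id = character(), category = character(),
                       term = character(), count = integer())
  rows <- rows[order(rows$id, rows$category, rows$term), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("hs_mentions", "data.frame")
  attr(rows, "n_docs") <- length(entity_lists)
  attr(rows, "doc_ids") <- ids
  rows
}

# Brute-force co-occurrence oracle: document-pair counting by explicit loops.
oracle_graph <- function(entity_lists) {
  terms <- sort(unique(unlist(entity_lists)))
  occ <- sapply(terms, function(t) sum(vapply(entity_lists, function(d) t %in% d, logical(1))))
  edges <- list()
  for (a in seq_along(terms)) for (b in seq_along(terms)) {
    if (a >= b) next
    w <- sum(vapply(entity_lists,
                    function(d) terms[a] %in% d && terms[b] %in% d, logical(1)))
    if (w > 0) edges[[length(edges) + 1L]] <-
        data.frame(source = terms[a], target = terms[b], link_strength = w,
                   stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(), target = character(), link_strength = integer())
  tls <- sapply(terms, function(t)
    sum(edges$link_strength[edges$source == t | edges$target == t]))
  list(terms = terms, occurrence = occ, edges = edges, tls = tls)
}

# Brute-force betweenness oracle: enumerate every shortest path between every
# node pair (BFS distances + DFS enumeration), accumulate fractional pass-through
# counts, normalize by (n-1)(n-2)/2.
oracle_betweenness <- function(terms, edges) {
  n <- length(terms)
  adj <- lapply(terms, function(t)
    c(edges$target[edges$source == t], edges$source[edges$target == t]))
  names(adj) <- terms
  bfs_dist <- function(s) {
    d <- setNames(rep(Inf, n), terms); d[s] <- 0
    q <- s
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (v in adj[[u]]) if (d[v] == Inf) { d[v] <- d[u] + 1; q <- c(q, v) }
    }
    d
  }
  all_paths <- function(s, t, d) {
    # all shortest s->t paths, following strictly decreasing distance to s
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1L]] <<- rev(acc); return(invisible()) }
      for (u in adj[[v]]) if (d[u] == d[v] - 1) walk(u, c(acc, u))
    }
    walk(t, t)
    paths
  }
  btw <- setNames(rep(0, n), terms)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- terms[i]; t <- terms[j]
    d <- bfs_dist(s)
    if (!is.finite(d[t]) || d[t] == 0) next
    paths <- all_paths(s, t, d)
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) setdiff(p, c(s, t))))
    if (length(inner)) {
      tab <- table(inner)
      btw[names(tab)] <- btw[names(tab)] + as.numeric(tab) / length(paths)
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw * 0
}

# small single-document corpus for tagging tests
one_doc <- function(abstract, title = "t") {
  out <- data.frame(id = "d1", title = title, abstract = abstract,
                    year = 2020L, countries = "", source = "test",
                    stringsAsFactors = FALSE)
  class(out) <- c("hs_corpus", "data.frame")
  attr(out, "n_docs") <- 1L
  out
}

# bootstrap / ordering scenario shared by scoring tests: three polymers with
# strictly ordered frequency, discourse negativity, and impact density
scenario_corpus <- function(n, seed) {
  generate_corpus(synthetic_corpus_spec(
    n_docs = n,
    entity_probs = c(PS = 0.30, PE = 0.15, PLA = 0.05, TiO2 = 0.10, toxicity = 0.20),
    entity_sentiment = list(PS = c(0.10, 0.80, 0.10),
                            PE = c(0.35, 0.45, 0.20),
                            PLA = c(0.80, 0.10, 0.10)),
    entity_impact_boost = c(PS = 0.8, PE = 0.5, PLA = 0.1),
    seed = seed))
}
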