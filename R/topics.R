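hs_stopwords <- c(
  "a", "an", "and", "are", "as", "at", "be", "between", "by", "for", "from",
  "has", "have", "in", "is", "it", "its", "of", "on", "or", "that", "the",
  "this", "these", "those", "to", "was", "were", "which", "with", "we", "our",
  "their", "they", "been", "than", "but", "not", "no", "also", "such", "can",
  "may", "into", "during", "through", "using", "used", "both", "each", "more",
  "most", "other", "some", "when", "while", "where", "after", "before")

tokenize <- function(text) {
  toks <- stringi::stri_split_fixed(normalize_text(text)$norm, " ")
  lapply(toks, function(tt) tt[nchar(tt) >= 2 & !tt %in% hs_stopwords])
}

#' Document-term matrix
#'
#' Unigram bag-of-words over lowercased, punctuation-stripped tokens with a
#' small shipped stopword list. The TF-IDF variant uses the smoothed inverse
#' document frequency `ln((1 + N) / (1 + df)) + 1` and L2 row normalization,
#' so a term present in every document gets idf exactly 1.
#'
#' @param corpus an `hs_corpus` (title + abstract are vectorized together).
#' @param type `"tfidf"` (default) or `"counts"`.
#' @return sparse `dgCMatrix`, documents x vocabulary.
#' @export
vectorize <- function(corpus, type = c("tfidf", "counts")) {
  type <- match.arg(type)
  toks <- tokenize(paste(corpus$title, corpus$abstract))
  vocab <- sort(unique(unlist(toks)))
  if (!length(vocab)) hs_compute_error("empty vocabulary")
  i <- rep(seq_along(toks), lengths(toks))
  j <- match(unlist(toks), vocab)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(toks), length(vocab)),
                            dimnames = list(corpus$id, vocab))
  if (type == "counts") return(m)
  n <- nrow(m)
  df <- Matrix::colSums(m > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  m <- m %*% Matrix::Diagonal(x = idf)
  nrm <- sqrt(Matrix::rowSums(m^2))
  nrm[nrm == 0] <- 1
  out <- Matrix::Diagonal(x = 1 / nrm) %*% m
  dimnames(out) <- list(corpus$id, vocab)
  out
}

#' Reduce a document-term matrix by truncated SVD
#'
#' Exact singular value decomposition truncated to the leading `d`
#' components; component variances are non-increasing by construction.
#'
#' @param m document-term matrix.
#' @param d target dimensionality (`1 <= d <= min(dim(m))`).
#' @return numeric matrix of document embeddings (`U_d D_d`, n x d) with the
#'   singular values attached as attribute `"singular_values"`.
#' @export
reduce <- function(m, d) {
  if (d < 1 || d > min(dim(m)))
    hs_validation_error(sprintf("d must lie in [1, %d]", min(dim(m))))
  sv <- svd(as.matrix(m), nu = d, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(d)], nrow = d)
  rownames(emb) <- rownames(m)
  attr(emb, "singular_values") <- sv$d[seq_len(d)]
  emb
}

# Davies-Bouldin index: mean over clusters of the worst
# (scatter_i + scatter_j) / centroid distance ratio
davies_bouldin <- function(emb, labels) {
  labs <- sort(unique(labels))
  cent <- t(vapply(labs, function(l) colMeans(emb[labels == l, , drop = FALSE]),
                   numeric(ncol(emb))))
  scat <- vapply(seq_along(labs), function(i) {
    pts <- emb[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  dmat <- as.matrix(dist(cent))
  mean(vapply(seq_along(labs), function(i) {
    r <- (scat[i] + scat[-i]) / dmat[i, -i]
    max(r)
  }, numeric(1)))
}

#' Cluster document embeddings
#'
#' Seeded k-means (10 restarts, best within-cluster sum of squares kept) with
#' silhouette and Davies-Bouldin quality metrics. Identical seeds give
#' identical labels.
#'
#' @param emb document embeddings (rows = documents).
#' @param k number of clusters (>= 2, <= number of documents).
#' @param seed integer seed.
#' @param nstart k-means restarts (default 10).
#' @return list with integer `labels` in `0 .. k-1`, `k`, `silhouette`
#'   (mean silhouette width), `davies_bouldin`, `inertia` (total
#'   within-cluster sum of squares), and `seed`.
#' @export
cluster_topics <- function(emb, k, seed = 1L, nstart = 10) {
  if (k < 2) hs_validation_error("k must be >= 2 (quality metrics undefined otherwise)")
  if (nrow(emb) < k) hs_validation_error("need at least k documents")
  if (nrow(unique(as.data.frame(emb))) < k)
    hs_compute_error("degenerate input: fewer distinct points than clusters")
  set.seed(seed)
  km <- kmeans(emb, centers = k, nstart = nstart, iter.max = 100)
  sil <- cluster::silhouette(km$cluster, dist(emb))
  list(labels = as.integer(km$cluster) - 1L, k = k,
       silhouette = mean(sil[, "sil_width"]),
       davies_bouldin = davies_bouldin(emb, km$cluster),
       inertia = km$tot.withinss, seed = as.integer(seed))
}

#' Fit the thematic layer end to end
#'
#' TF-IDF vectorization, truncated SVD, and seeded k-means, with `d` clamped
#' to the matrix dimensions for small corpora.
#'
#' @param corpus an `hs_corpus`.
#' @param d reduced dimensionality (default 100).
#' @param k cluster count (default 14).
#' @param seed integer seed.
#' @return list of class `hs_topics`: `labels` (0-based), `k`, `d`,
#'   `silhouette`, `davies_bouldin`, `vocabulary_size`, `seed`.
#' @export
topic_model <- function(corpus, d = 100, k = 14, seed = 1L) {
  m <- vectorize(corpus, "tfidf")
  d <- min(d, dim(m) - 1L)
  d <- max(1L, min(d))
  emb <- reduce(m, d)
  cl <- cluster_topics(emb, k = k, seed = seed)
  structure(list(labels = cl$labels, k = k, d = d,
                 silhouette = cl$silhouette,
                 davies_bouldin = cl$davies_bouldin,
                 vocabulary_size = ncol(m), seed = as.integer(seed)),
            class = "hs_topics")
}
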