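#' Scoring configuration
#'
#' @param weights length-3 nonnegative weights for the sentiment, impact and
#'   centrality components of the base score; must sum to 1. Default
#'   `c(S = 0.4, I = 0.4, C = 0.2)`.
#' @param bootstrap_reps bootstrap replicates (default 200).
#' @param seed integer seed for resampling.
#' @param centrality_measure which centrality feeds the centrality component:
#'   `"degree"` (default), `"eigenvector"`, or `"betweenness"`.
#' @return list of class `hs_score_config`.
#' @export
score_config <- function(weights = c(S = 0.4, I = 0.4, C = 0.2),
                         bootstrap_reps = 200, seed = 1L,
                         centrality_measure = c("degree", "eigenvector", "betweenness")) {
  if (length(weights) != 3 || any(weights < 0))
    hs_validation_error("weights must be 3 nonnegative numbers")
  if (abs(sum(weights) - 1) > 1e-9)
    hs_validation_error("component weights must sum to 1")
  structure(list(weights = unname(weights), bootstrap_reps = bootstrap_reps,
                 seed = as.integer(seed),
                 centrality_measure = match.arg(centrality_measure)),
            class = "hs_score_config")
}

#' Frequency percentage of a polymer
#'
#' Share of the corpus mentioning the polymer, `100 * n_p / n_corpus`,
#' reported to 3 decimals.
#'
#' @param n_p number of documents mentioning the polymer.
#' @param n_corpus corpus size.
#' @return percentage, rounded to 3 decimals.
#' @export
frequency_percentage <- function(n_p, n_corpus) {
  if (any(n_corpus == 0)) hs_validation_error("n_corpus must be positive")
  if (any(n_p < 1) || any(n_p > n_corpus))
    hs_validation_error("n_p must satisfy 1 <= n_p <= n_corpus")
  round(100 * n_p / n_corpus, 3)
}

#' Normalized frequency F
#'
#' Each polymer's frequency percentage divided by the maximum across
#' polymers, so the most-studied polymer gets F = 1.
#'
#' @param pcts numeric vector of frequency percentages.
#' @return numeric vector of `F` values in \[0, 1\].
#' @export
normalize_frequency <- function(pcts) {
  if (!length(pcts)) hs_validation_error("no percentages supplied")
  mx <- max(pcts)
  if (mx <= 0) hs_validation_error("maximum percentage must be positive")
  pcts / mx
}

#' Frequency weight w = 0.7 + 0.3 F
#'
#' Bounds every score to at least 70% of its base before the confidence
#' penalty, so rare polymers are down-weighted but never erased.
#'
#' @param F_p normalized frequency in \[0, 1\].
#' @return weight in \[0.7, 1\].
#' @export
frequency_weight <- function(F_p) {
  if (any(F_p < 0 | F_p > 1)) hs_validation_error("F must lie in [0, 1]")
  0.7 + 0.3 * F_p
}

#' Confidence penalty sigma = 1 - 1/(1 + 0.05 n)
#'
#' Saturating replication penalty: 0 at n = 0, strictly increasing, limit 1.
#'
#' @param n_p number of supporting documents (>= 0).
#' @return confidence in \[0, 1).
#' @export
confidence <- function(n_p) {
  if (any(n_p < 0)) hs_validation_error("n_p must be nonnegative")
  1 - 1 / (1 + 0.05 * n_p)
}

#' Base score B = a_S S + a_I I + a_C C
#'
#' @param S,I,C unit-interval sentiment, impact and centrality components.
#' @param config an [score_config()]; its `weights` default to
#'   `(0.4, 0.4, 0.2)`.
#' @return base score in \[0, 1\].
#' @export
base_score <- function(S, I, C, config = score_config()) {
  comp <- c(S, I, C)
  if (any(comp < 0 | comp > 1)) hs_validation_error("components must lie in [0, 1]")
  w <- config$weights
  w[1] * S + w[2] * I + w[3] * C
}

#' Final Harmfulness Score H = B (0.7 + 0.3 F) sigma(n)
#'
#' @param B base score in \[0, 1\].
#' @param F_p normalized frequency in \[0, 1\].
#' @param n_p supporting document count.
#' @return Harmfulness Score in \[0, 1\]; always `<= B`.
#' @export
final_score <- function(B, F_p, n_p) {
  if (any(B < 0 | B > 1)) hs_validation_error("B must lie in [0, 1]")
  B * frequency_weight(F_p) * confidence(n_p)
}

#' Per-polymer impact component
#'
#' Per-document impact density: the fraction of a polymer's documents that
#' co-mention at least one impact descriptor, max-normalized across polymers
#' so the densest polymer gets I = 1.
#'
#' @param index an `hs_mentions` index.
#' @return data frame `polymer`, `n_docs`, `impact_rate`, `I`.
#' @export
impact_component <- function(index) {
  pm <- mention_matrix(index, "polymer")
  if (!ncol(pm)) hs_validation_error("no polymer mentions in the index")
  has_impact <- rowSums(mention_matrix(index, "impact")) > 0
  n_docs <- colSums(pm)
  keep <- n_docs > 0
  pm <- pm[, keep, drop = FALSE]; n_docs <- n_docs[keep]
  r <- as.numeric(crossprod(pm, as.numeric(has_impact))) / n_docs
  I <- if (max(r) > 0) r / max(r) else rep(0, length(r))
  data.frame(polymer = colnames(pm), n_docs = as.integer(n_docs),
             impact_rate = r, I = I, stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-polymer centrality component
#'
#' Selected centrality of each polymer node, max-normalized over the polymer
#' subset. Polymers absent from the graph are excluded with a warning.
#'
#' @param cent centrality table from [centralities()].
#' @param polymers character vector of polymer node names.
#' @param measure `"degree"` (default), `"eigenvector"`, or `"betweenness"`.
#' @return data frame `polymer`, `C`.
#' @export
centrality_component <- function(cent, polymers,
                                 measure = c("degree", "eigenvector", "betweenness")) {
  measure <- match.arg(measure)
  hit <- polymers %in% cent$term
  if (!any(hit)) hs_validation_error("no polymers present in the graph")
  if (any(!hit))
    warning(sprintf("excluding polymer(s) absent from graph: %s",
                    paste(polymers[!hit], collapse = ", ")))
  polymers <- polymers[hit]
  v <- cent[[measure]][match(polymers, cent$term)]
  C <- if (max(v) > 0) v / max(v) else rep(1, length(v))
  data.frame(polymer = polymers, C = C, stringsAsFactors = FALSE)
}

#' Rank a score table
#'
#' Descending Harmfulness Score; ties broken by descending paper count, then
#' lexicographic polymer id. The input row order is irrelevant.
#'
#' @param rows data frame with columns `harmfulness_score`, `paper_count`,
#'   `polymer`.
#' @return the table, reordered.
#' @export
rank_scores <- function(rows) {
  out <- rows[order(-rows$harmfulness_score, -rows$paper_count, rows$polymer), ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' `G1 = sqrt(n(n-1))/(n-2) * m3 / m2^(3/2)` with central sample moments.
#'
#' @param values numeric vector, at least 3 values with nonzero variance.
#' @return skewness.
#' @export
score_skewness <- function(values) {
  n <- length(values)
  if (n < 3) hs_validation_error("skewness needs at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) hs_compute_error("skewness undefined for zero variance")
  m3 <- mean((values - m)^3)
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
}

#' Score a corpus end to end
#'
#' Runs the whole pipeline: tagging, sentiment scoring, per-polymer
#' components, co-occurrence network centralities, and aggregation into the
#' Harmfulness Score table (ranked).
#'
#' @param corpus an `hs_corpus`.
#' @param lexicons lexicons for tagging.
#' @param sent_config an [sentiment_config()].
#' @param config an [score_config()].
#' @param min_occurrence node threshold for the entity network.
#' @return ranked data frame of class `hs_scores` with Table-style columns
#'   `polymer`, `harmfulness_score`, `base_score`, `frequency_weight` (the
#'   normalized frequency F), `confidence`, `sentiment_component`,
#'   `impact_component`, `centrality_component`, `paper_count`,
#'   `frequency_percentage`, `eigenvector_centrality`,
#'   `betweenness_centrality`.
#' @export
score_corpus <- function(corpus, lexicons = default_lexicons(),
                         sent_config = sentiment_config(),
                         config = score_config(),
                         min_occurrence = 1) {
  index <- tag_corpus(corpus, lexicons)
  scores <- score_sentiment(corpus, sent_config)
  sent <- polymer_sentiment_component(scores, index, sent_config)
  imp <- impact_component(index)
  graph <- build_graph(index, min_occurrence = min_occurrence,
                       categories = c("polymer", "enp", "impact"))
  cent <- centralities(graph)
  cc <- centrality_component(cent, sent$polymer, measure = config$centrality_measure)
  polymers <- Reduce(intersect, list(sent$polymer, imp$polymer, cc$polymer))
  if (!length(polymers)) hs_compute_error("no polymer survived all components")
  S <- sent$S[match(polymers, sent$polymer)]
  I <- imp$I[match(polymers, imp$polymer)]
  C <- cc$C[match(polymers, cc$polymer)]
  n_p <- sent$n_docs[match(polymers, sent$polymer)]
  pct <- frequency_percentage(n_p, nrow(corpus))
  F_p <- normalize_frequency(pct)
  B <- config$weights[1] * S + config$weights[2] * I + config$weights[3] * C
  H <- final_score(B, F_p, n_p)
  ei <- cent$eigenvector[match(polymers, cent$term)]
  bt <- cent$betweenness[match(polymers, cent$term)]
  out <- data.frame(polymer = polymers, harmfulness_score = H, base_score = B,
                    frequency_weight = F_p, confidence = confidence(n_p),
                    sentiment_component = S, impact_component = I,
                    centrality_component = C, paper_count = n_p,
                    frequency_percentage = pct, eigenvector_centrality = ei,
                    betweenness_centrality = bt, stringsAsFactors = FALSE)
  out <- rank_scores(out)
  class(out) <- c("hs_scores", "data.frame")
  out
}

#' Score a pre-computed component table
#'
#' Components-only mode: runs only the scoring arithmetic on a table that
#' already holds the per-polymer components (such as the packaged reference
#' table), without a corpus. The normalized frequency is taken from the
#' `frequency_weight` column when present, otherwise recomputed from
#' `frequency_percentage` (or from `paper_count` and `n_corpus`); the
#' confidence is always recomputed from `paper_count`; the base score column
#' is used as printed unless `recompute_base = TRUE`, in which case it is
#' rebuilt from the component columns with the configured weights.
#'
#' @param table data frame with at least `polymer`, `paper_count`, and either
#'   `base_score` or the three component columns.
#' @param config an [score_config()].
#' @param n_corpus corpus size, needed only when no frequency column exists.
#' @param recompute_base rebuild the base score from components?
#' @return ranked `hs_scores` data frame (same schema as [score_corpus()]).
#' @export
score_components <- function(table, config = score_config(), n_corpus = NULL,
                             recompute_base = FALSE) {
  tb <- as.data.frame(table)
  if (is.null(tb$polymer) || is.null(tb$paper_count))
    hs_validation_error("table needs 'polymer' and 'paper_count' columns")
  pct <- if (!is.null(tb$frequency_percentage)) tb$frequency_percentage
         else if (!is.null(n_corpus)) frequency_percentage(tb$paper_count, n_corpus)
         else hs_validation_error("need 'frequency_percentage' or n_corpus")
  F_p <- if (!is.null(tb$frequency_weight)) tb$frequency_weight
         else normalize_frequency(pct)
  B <- if (!recompute_base && !is.null(tb$base_score)) tb$base_score
       else {
         need <- c("sentiment_component", "impact_component", "centrality_component")
         if (!all(need %in% names(tb)))
           hs_validation_error("component columns required to rebuild the base score")
         config$weights[1] * tb$sentiment_component +
           config$weights[2] * tb$impact_component +
           config$weights[3] * tb$centrality_component
       }
  out <- data.frame(polymer = tb$polymer,
                    harmfulness_score = final_score(B, F_p, tb$paper_count),
                    base_score = B, frequency_weight = F_p,
                    confidence = confidence(tb$paper_count),
                    sentiment_component = tb$sentiment_component,
                    impact_component = tb$impact_component,
                    centrality_component = tb$centrality_component,
                    paper_count = tb$paper_count, frequency_percentage = pct,
                    stringsAsFactors = FALSE)
  if (!is.null(tb$eigenvector_centrality)) out$eigenvector_centrality <- tb$eigenvector_centrality
  if (!is.null(tb$betweenness_centrality)) out$betweenness_centrality <- tb$betweenness_centrality
  out <- rank_scores(out)
  class(out) <- c("hs_scores", "data.frame")
  out
}

#' Leave-one-out rank stability
#'
#' Drops one polymer, renormalizes F against the new maximum frequency
#' percentage, recomputes the frequency weight and Harmfulness Score of every
#' remaining polymer, and reports all pairwise rank inversions relative to
#' the original ordering.
#'
#' @param rows an `hs_scores` table.
#' @param drop polymer id to remove.
#' @return list with `table` (recomputed scores, ranked), `inversions`
#'   (data frame of inverted pairs) and `n_inversions`.
#' @export
leave_one_out <- function(rows, drop) {
  if (!drop %in% rows$polymer)
    hs_validation_error(sprintf("polymer '%s' not present", drop))
  keep <- rows[rows$polymer != drop, , drop = FALSE]
  F2 <- normalize_frequency(keep$frequency_percentage)
  H2 <- final_score(keep$base_score, F2, keep$paper_count)
  old_rank <- rank(-keep$harmfulness_score, ties.method = "first")
  new_rank <- rank(-H2, ties.method = "first")
  inv <- which(outer(old_rank, old_rank, "<") & outer(new_rank, new_rank, ">"),
               arr.ind = TRUE)
  inversions <- data.frame(higher = keep$polymer[inv[, 1]],
                           lower = keep$polymer[inv[, 2]],
                           stringsAsFactors = FALSE)
  tab <- keep
  tab$frequency_weight <- F2
  tab$harmfulness_score <- H2
  list(table = rank_scores(tab), inversions = inversions,
       n_inversions = nrow(inversions))
}

#' Bootstrap the Harmfulness Scores
#'
#' Resamples documents with replacement and recomputes the per-polymer score
#' for every replicate (tagging and sentiment are per-document deterministic,
#' so per-document features are computed once and the aggregation stages of
#' the pipeline are re-run on each resample). Identical seeds give identical
#' intervals. A polymer unmentioned in a replicate is recorded as absent
#' (`NA`) for that replicate.
#'
#' @param corpus an `hs_corpus`.
#' @param reps number of replicates (>= 1).
#' @param seed integer seed.
#' @param lexicons,sent_config,config as in [score_corpus()].
#' @param level confidence level of the percentile intervals (default 0.95).
#' @return list with `ci` (data frame `polymer`, `estimate`, `lower`,
#'   `upper`, `width`, `n_reps_present`) and `replicates` (reps x polymer
#'   matrix of scores).
#' @export
bootstrap_scores <- function(corpus, reps = 200, seed = 1L,
                             lexicons = default_lexicons(),
                             sent_config = sentiment_config(),
                             config = score_config(), level = 0.95) {
  if (reps < 1) hs_validation_error("reps must be >= 1")
  index <- tag_corpus(corpus, lexicons)
  scores <- score_sentiment(corpus, sent_config)
  pm <- mention_matrix(index, "polymer")
  if (!ncol(pm)) hs_validation_error("no polymer mentions in the corpus")
  ent <- cbind(pm,
               mention_matrix(index, "enp"),
               mention_matrix(index, "impact"))
  has_impact <- rowSums(mention_matrix(index, "impact")) > 0
  comp <- scores$compound
  n <- nrow(corpus)
  polymers <- colnames(pm)
  point <- replicate_scores(seq_len(n), pm, ent, has_impact, comp, sent_config, config)
  set.seed(seed)
  mat <- matrix(NA_real_, nrow = reps, ncol = length(polymers),
                dimnames = list(NULL, polymers))
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    mat[r, ] <- replicate_scores(idx, pm, ent, has_impact, comp, sent_config, config)
  }
  a <- (1 - level) / 2
  ci <- data.frame(
    polymer = polymers,
    estimate = point,
    lower = apply(mat, 2, quantile, probs = a, na.rm = TRUE),
    upper = apply(mat, 2, quantile, probs = 1 - a, na.rm = TRUE),
    n_reps_present = colSums(!is.na(mat)),
    stringsAsFactors = FALSE, row.names = NULL)
  ci$width <- ci$upper - ci$lower
  list(ci = ci, replicates = mat)
}

# one bootstrap replicate: aggregation stages of the scoring pipeline over
# the documents selected by idx
replicate_scores <- function(idx, pm, ent, has_impact, comp, sent_config, config) {
  pm_r <- pm[idx, , drop = FALSE]
  n_p <- colSums(pm_r)
  out <- rep(NA_real_, ncol(pm))
  present <- n_p > 0
  if (sum(present) < 1) return(out)
  # sentiment component (harm-oriented min-max over present polymers)
  means <- as.numeric(crossprod(pm_r[, present, drop = FALSE], comp[idx])) / n_p[present]
  h <- if (sent_config$orientation == "harm") -means else means
  rng <- range(h)
  S <- if (diff(rng) < .Machine$double.eps^0.5) rep(0.5, length(h))
       else (h - rng[1]) / diff(rng)
  # impact component
  r_imp <- as.numeric(crossprod(pm_r[, present, drop = FALSE],
                                as.numeric(has_impact[idx]))) / n_p[present]
  I <- if (max(r_imp) > 0) r_imp / max(r_imp) else rep(0, length(r_imp))
  # centrality component: degree in the replicate's entity co-mention graph
  ent_r <- ent[idx, , drop = FALSE]
  co <- crossprod(ent_r)
  diag(co) <- 0
  deg <- rowSums(as.matrix(co) > 0)[colnames(pm)[present]]
  C <- if (max(deg) > 0) deg / max(deg) else rep(1, length(deg))
  pct <- 100 * n_p[present] / length(idx)
  F_p <- pct / max(pct)
  B <- config$weights[1] * S + config$weights[2] * I + config$weights[3] * C
  out[present] <- B * (0.7 + 0.3 * F_p) * confidence(n_p[present])
  out
}

#' Packaged reference score table
#'
#' The published per-polymer score table for the 18 most prevalent
#' microplastic polymers (all Harmfulness Score columns), shipped for
#' regression tests and components-only scoring.
#'
#' @return data frame in the [score_corpus()] schema.
#' @export
reference_scores <- function() {
  path <- system.file("extdata", "polymer_scores_reference.csv",
                      package = "harmscore", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a score table as CSV
#'
#' Mirrors the reference table's columns, values rounded to 3 decimals.
#'
#' @param scores an `hs_scores` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "paper_count"
  out[num] <- lapply(out[num], round, digits = 3)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
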