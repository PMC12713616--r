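#' Specification of a synthetic abstract corpus
#'
#' Describes a corpus of template-sentence abstracts with controlled
#' statistical structure: per-entity mention probabilities, an optional
#' co-mention amplifier, a positive/negative/neutral sentiment mixture, and a
#' publication-year range. Synthetic abstracts are template sentences, not
#' natural language; sentiment is injected through affect words from the
#' scorer's own valence lexicon so the mixture is exactly controllable.
#'
#' @param n_docs number of documents (>= 1).
#' @param entity_probs named numeric vector: canonical lexicon term ->
#'   per-document mention probability in \[0, 1\].
#' @param cooccur_boost joint-mention amplifier (>= 1). Implemented as a
#'   Gaussian-copula common factor with correlation `1 - 1/boost`, which
#'   raises the probability of joint mentions while keeping every marginal
#'   mention probability exactly at `entity_probs`.
#' @param sentiment_mix length-3 vector `(positive, negative, neutral)`;
#'   renormalized when it sums to within 0.01 of 1 (tolerates printed
#'   rounding), rejected otherwise.
#' @param year_range inclusive integer year interval.
#' @param seed integer random seed.
#' @param entity_sentiment optional named list: entity -> its own length-3
#'   sentiment mix; documents mentioning such entities draw their class from
#'   the average of the applicable mixes.
#' @param entity_impact_boost optional named numeric vector: polymer ->
#'   probability that a document mentioning it gains an extra
#'   impact-descriptor sentence.
#' @return list of class `hs_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_docs, entity_probs,
                                  cooccur_boost = 1,
                                  sentiment_mix = c(0.655, 0.242, 0.104),
                                  year_range = c(1961L, 2025L),
                                  seed = 1L,
                                  entity_sentiment = NULL,
                                  entity_impact_boost = NULL) {
  if (n_docs < 1) hs_validation_error("n_docs must be >= 1")
  if (is.null(names(entity_probs)) || any(!nzchar(names(entity_probs))))
    hs_validation_error("entity_probs must be a named vector")
  if (any(entity_probs < 0 | entity_probs > 1))
    hs_validation_error("entity probabilities must lie in [0, 1]")
  if (cooccur_boost < 1) hs_validation_error("cooccur_boost must be >= 1")
  norm_mix <- function(m, what) {
    if (length(m) != 3 || any(m < 0))
      hs_validation_error(sprintf("%s must be 3 nonnegative fractions", what))
    if (abs(sum(m) - 1) > 0.01)
      hs_validation_error(sprintf("%s must sum to 1 (got %.4f)", what, sum(m)))
    m / sum(m)
  }
  sentiment_mix <- norm_mix(sentiment_mix, "sentiment_mix")
  if (!is.null(entity_sentiment))
    entity_sentiment <- lapply(entity_sentiment, norm_mix, what = "entity_sentiment mix")
  structure(list(n_docs = as.integer(n_docs), entity_probs = entity_probs,
                 cooccur_boost = cooccur_boost, sentiment_mix = sentiment_mix,
                 year_range = as.integer(year_range), seed = as.integer(seed),
                 entity_sentiment = entity_sentiment,
                 entity_impact_boost = entity_impact_boost),
            class = "hs_corpus_spec")
}

# sentence templates; deliberately free of valence-lexicon words and of
# controlled-vocabulary terms other than the injected entity
entity_sentence <- function(category, term) {
  switch(category,
         polymer = sprintf("Samples contained %s debris.", term),
         enp = sprintf("The material was combined with %s additives.", term),
         morphology = sprintf("Debris occurred in %s form.", term),
         impact = sprintf("Researchers reported %s in the system.", term),
         technique = sprintf("Characterization employed %s.", term),
         country = sprintf("Field sites were located in %s.", term),
         sprintf("The survey mentions %s.", term))
}

sentiment_sentence <- function(class) {
  switch(class,
         positive = "The findings are promising and beneficial for remediation.",
         negative = "The authors describe harmful and hazardous outcomes.",
         neutral = "The measurements were recorded and archived.")
}

#' Generate a synthetic corpus
#'
#' Builds `n_docs` template abstracts. Each entity is mentioned with its
#' configured probability (joint mentions amplified by `cooccur_boost` while
#' marginals are preserved); one affect sentence carries the document's drawn
#' sentiment class; the same spec and seed always produce an identical
#' corpus.
#'
#' @param spec an [synthetic_corpus_spec()].
#' @param lexicons lexicons used to resolve each entity's category; defaults
#'   to [default_lexicons()].
#' @return `hs_corpus` data frame with attributes `truth` (the spec) and
#'   `classes` (the drawn sentiment class per document).
#' @export
generate_corpus <- function(spec, lexicons = default_lexicons()) {
  stopifnot(inherits(spec, "hs_corpus_spec"))
  set.seed(spec$seed)
  ents <- names(spec$entity_probs)
  cat_of <- vapply(ents, function(e) {
    for (lx in lexicons) if (e %in% names(lx$entries)) return(lx$category)
    "other"
  }, character(1))
  n <- spec$n_docs
  k <- length(ents)
  rho <- if (spec$cooccur_boost > 1) 1 - 1 / spec$cooccur_boost else 0
  z <- rnorm(n)
  lat <- rho * z + sqrt(1 - rho^2) * matrix(rnorm(n * k), n, k)
  mention <- sweep(pnorm(lat), 2, spec$entity_probs, "<")
  colnames(mention) <- ents

  # extra impact sentences for boosted polymers
  impact_pool <- c("toxicity", "oxidative stress", "bioaccumulation", "pollution")
  extra_impact <- vector("list", n)
  if (!is.null(spec$entity_impact_boost)) {
    for (p in names(spec$entity_impact_boost)) {
      if (!p %in% ents) next
      hit <- mention[, p] & runif(n) < spec$entity_impact_boost[[p]]
      if (any(hit)) {
        terms <- sample(impact_pool, sum(hit), replace = TRUE)
        idx <- which(hit)
        for (j in seq_along(idx))
          extra_impact[[idx[j]]] <- c(extra_impact[[idx[j]]], terms[j])
      }
    }
  }

  # per-document sentiment class
  mix <- matrix(spec$sentiment_mix, n, 3, byrow = TRUE)
  if (!is.null(spec$entity_sentiment)) {
    for (i in seq_len(n)) {
      ov <- intersect(names(spec$entity_sentiment), ents[mention[i, ]])
      if (length(ov)) {
        mm <- do.call(rbind, spec$entity_sentiment[ov])
        mix[i, ] <- colMeans(mm)
      }
    }
  }
  u <- runif(n)
  cls <- ifelse(u < mix[, 1], "positive",
                ifelse(u < mix[, 1] + mix[, 2], "negative", "neutral"))

  years <- sample(seq(spec$year_range[1], spec$year_range[2]), n, replace = TRUE)

  abstracts <- vapply(seq_len(n), function(i) {
    sent <- c(sprintf("This synthetic survey describes observations from %d.", years[i]))
    on <- which(mention[i, ])
    if (length(on))
      sent <- c(sent, vapply(on, function(j) entity_sentence(cat_of[j], ents[j]),
                             character(1)))
    if (!is.null(extra_impact[[i]]))
      sent <- c(sent, vapply(extra_impact[[i]],
                             function(t) entity_sentence("impact", t), character(1)))
    sent <- c(sent, sentiment_sentence(cls[i]))
    paste(sent, collapse = " ")
  }, character(1))

  countries <- vapply(seq_len(n), function(i) {
    cc <- ents[mention[i, ] & cat_of == "country"]
    paste(cc, collapse = ";")
  }, character(1))

  out <- data.frame(
    id = sprintf("syn%05d", seq_len(n)),
    title = sprintf("Synthetic abstract record %d", seq_len(n)),
    abstract = abstracts,
    year = as.integer(years),
    countries = countries,
    source = "synthetic",
    stringsAsFactors = FALSE)
  class(out) <- c("hs_corpus", "data.frame")
  attr(out, "excluded") <- 0L
  attr(out, "truth") <- spec
  attr(out, "classes") <- cls
  out
}
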