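#' Sentiment configuration
#'
#' Thresholds and normalization constant for the rule-based valence scorer.
#' A document's compound polarity is classified positive when it is at or
#' above `tau_pos`, negative at or below `tau_neg`, neutral in between
#' (boundaries inclusive).
#'
#' @param tau_pos positive threshold (default 0.25).
#' @param tau_neg negative threshold (default -0.25).
#' @param alpha normalization constant of the compound map
#'   `v / sqrt(v^2 + alpha)` (default 15).
#' @param orientation `"harm"` (more negative discourse gives a larger
#'   sentiment component) or `"raw"`.
#' @return list of class `hs_sentiment_config`.
#' @export
sentiment_config <- function(tau_pos = 0.25, tau_neg = -0.25, alpha = 15,
                             orientation = c("harm", "raw")) {
  if (!(tau_neg < 0 && 0 < tau_pos))
    hs_validation_error("thresholds must satisfy tau_neg < 0 < tau_pos")
  if (alpha <= 0) hs_validation_error("alpha must be positive")
  structure(list(tau_pos = tau_pos, tau_neg = tau_neg, alpha = alpha,
                 orientation = match.arg(orientation)),
            class = "hs_sentiment_config")
}

#' Valence lexicon of the rule-based scorer
#'
#' A compact lexicon of evaluative words in scientific discourse with raw
#' valences on the usual -4..+4 scale, plus negation and intensifier word
#' lists. Deliberately disjoint from the impact controlled vocabulary
#' (`toxicity`, `degradation`, ...) so the sentiment and impact components of
#' the Harmfulness Score measure different signals: affect words here are
#' evaluative ("harmful", "beneficial"), impact terms are topical.
#'
#' @return list with data frame `words` (`word`, `valence`), character vector
#'   `negations`, and data frame `modifiers` (`word`, `boost`).
#' @export
valence_lexicon <- function() {
  words <- data.frame(
    word = c(
      # positive
      "beneficial", "benefit", "promising", "effective", "efficient",
      "improved", "improve", "improvement", "enhanced", "enhance", "safe",
      "safely", "novel", "green", "clean", "renewable", "recyclable",
      "successful", "success", "robust", "advantage", "advantageous",
      "favorable", "favourable", "excellent", "superior", "valuable",
      "useful", "benign", "good", "better", "best", "remarkable",
      "outstanding", "biocompatible", "feasible", "viable", "optimal",
      "protect", "protective",
      # negative
      "harmful", "harm", "hazardous", "hazard", "toxic", "dangerous",
      "danger", "adverse", "detrimental", "damage", "damaging", "risk",
      "risky", "threat", "threaten", "contaminated", "contamination",
      "contaminate", "concern", "concerning", "alarming", "lethal", "death",
      "mortality", "impaired", "impair", "disrupt", "disruption",
      "inflammation", "inflammatory", "severe", "severely", "poor", "worse",
      "worst", "negative", "problem", "problematic", "fail", "failure",
      "loss", "deteriorate", "deterioration"),
    valence = c(
      1.9, 1.7, 1.8, 1.7, 1.5,
      1.4, 1.4, 1.4, 1.3, 1.3, 1.9,
      1.8, 1.2, 1.1, 1.6, 1.5, 1.4,
      1.8, 1.8, 1.3, 1.5, 1.6,
      1.7, 1.7, 2.7, 2.0, 1.7,
      1.6, 1.5, 1.9, 1.6, 2.3, 1.9,
      2.5, 1.4, 1.1, 1.2, 1.6,
      1.4, 1.4,
      -2.1, -1.9, -2.6, -2.2, -2.4, -2.4,
      -2.2, -1.6, -2.0, -1.8, -1.9, -1.1,
      -1.3, -1.9, -1.8, -1.7, -1.5,
      -1.6, -1.1, -1.3, -2.0, -2.9, -2.9,
      -2.2, -1.6, -1.5, -1.5, -1.5,
      -1.4, -1.4, -1.8, -1.9, -1.5, -1.8,
      -2.6, -1.4, -1.2, -1.4, -1.9, -1.9,
      -1.3, -1.6, -1.6),
    stringsAsFactors = FALSE)
  list(
    words = words,
    negations = c("not", "no", "never", "without", "neither", "nor", "cannot"),
    modifiers = data.frame(
      word = c("very", "extremely", "highly", "significantly", "remarkably",
               "particularly", "especially", "slightly", "somewhat", "marginally"),
      boost = c(rep(0.293, 7), rep(-0.293, 3)),
      stringsAsFactors = FALSE))
}

# raw valence sum of one token vector (negation flip within the previous
# 3 tokens; intensifier/diminisher boost from the immediately preceding token)
valence_sum <- function(tokens, lex) {
  v <- lex$words$valence[match(tokens, lex$words$word)]
  hits <- which(!is.na(v))
  if (!length(hits)) return(0)
  total <- 0
  neg <- tokens %in% lex$negations
  boost <- lex$modifiers$boost[match(tokens, lex$modifiers$word)]
  for (i in hits) {
    vi <- v[i]
    if (i > 1 && !is.na(boost[i - 1]))
      vi <- vi + sign(vi) * boost[i - 1]
    lo <- max(1, i - 3)
    if (i > 1 && any(neg[lo:(i - 1)])) vi <- vi * -0.74
    total <- total + vi
  }
  total
}

#' Compound polarity of free text
#'
#' Sums valence-lexicon word scores over the tokenized text, flipping
#' valence under a negation within the previous three tokens (factor -0.74)
#' and boosting under an immediately preceding intensifier (+/- 0.293), then
#' normalizes to \[-1, 1\] as `v / sqrt(v^2 + alpha)`. Text with no lexicon
#' words (including empty text) scores exactly 0.
#'
#' @param text character vector.
#' @param config an [sentiment_config()].
#' @param lexicon valence lexicon, defaults to [valence_lexicon()].
#' @return numeric vector of compound polarities in \[-1, 1\].
#' @export
compound_score <- function(text, config = sentiment_config(),
                           lexicon = valence_lexicon()) {
  norm <- normalize_text(text)$norm
  toks <- stringi::stri_split_fixed(norm, " ")
  sums <- vapply(toks, valence_sum, numeric(1), lex = lexicon)
  sums / sqrt(sums^2 + config$alpha)
}

#' Classify a compound polarity
#'
#' @param compound numeric vector in \[-1, 1\].
#' @param config an [sentiment_config()].
#' @return factor with levels `positive`, `negative`, `neutral`.
#' @export
classify <- function(compound, config = sentiment_config()) {
  if (any(is.na(compound)) || any(compound < -1 | compound > 1))
    hs_validation_error("compound polarity must lie in [-1, 1]")
  cls <- ifelse(compound >= config$tau_pos, "positive",
                ifelse(compound <= config$tau_neg, "negative", "neutral"))
  factor(cls, levels = c("positive", "negative", "neutral"))
}

#' Score a corpus
#'
#' Scores title + abstract of every document and classifies it with the
#' configured thresholds.
#'
#' @param corpus an `hs_corpus` data frame.
#' @param config an [sentiment_config()].
#' @param lexicon valence lexicon.
#' @return data frame `id`, `compound`, `class` of class `hs_sentiment`.
#' @export
score_sentiment <- function(corpus, config = sentiment_config(),
                            lexicon = valence_lexicon()) {
  comp <- compound_score(paste(corpus$title, corpus$abstract), config, lexicon)
  out <- data.frame(id = corpus$id, compound = comp,
                    class = classify(comp, config), stringsAsFactors = FALSE)
  class(out) <- c("hs_sentiment", "data.frame")
  out
}

#' Corpus sentiment class fractions
#'
#' @param scores an `hs_sentiment` data frame (or factor of classes).
#' @return named numeric vector `(positive, negative, neutral)` summing to 1.
#' @export
corpus_distribution <- function(scores) {
  cls <- if (is.data.frame(scores)) scores$class else scores
  if (!length(cls)) hs_validation_error("no sentiment scores to summarize")
  cls <- factor(cls, levels = c("positive", "negative", "neutral"))
  tab <- table(cls)
  setNames(as.numeric(tab) / length(cls), names(tab))
}

#' Per-polymer sentiment component
#'
#' For each polymer, averages the compound polarity over the documents that
#' mention it; under the default harm orientation the negated mean
#' (`h = -mean(compound)`) is min-max normalized across polymers so the most
#' negatively discussed polymer gets S = 1. When all polymer means coincide,
#' every S is 0.5.
#'
#' @param scores an `hs_sentiment` data frame.
#' @param index an `hs_mentions` index over the same corpus.
#' @param config an [sentiment_config()] (used for `orientation`).
#' @return data frame `polymer`, `n_docs`, `mean_compound`, `S`.
#' @export
polymer_sentiment_component <- function(scores, index,
                                        config = sentiment_config()) {
  pm <- mention_matrix(index, "polymer")
  if (!ncol(pm)) hs_validation_error("no polymer mentions in the index")
  comp <- scores$compound[match(rownames(pm), scores$id)]
  n_docs <- colSums(pm)
  if (any(n_docs == 0)) {
    warning(sprintf("excluding polymer(s) with zero documents: %s",
                    paste(colnames(pm)[n_docs == 0], collapse = ", ")))
    pm <- pm[, n_docs > 0, drop = FALSE]
    n_docs <- n_docs[n_docs > 0]
  }
  means <- as.numeric(crossprod(pm, comp)) / n_docs
  h <- if (config$orientation == "harm") -means else means
  rng <- range(h)
  S <- if (diff(rng) < .Machine$double.eps^0.5) rep(0.5, length(h))
       else (h - rng[1]) / diff(rng)
  data.frame(polymer = colnames(pm), n_docs = as.integer(n_docs),
             mean_compound = means, S = S, stringsAsFactors = FALSE,
             row.names = NULL)
}
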