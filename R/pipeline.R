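#' Run the full scoring pipeline and write its outputs
#'
#' Reads a corpus, runs tagging, sentiment, network, scoring and bootstrap,
#' and writes the diagnostics bundle to `out_dir`: `scores.csv` (reference
#' table schema), `network.graphml`, `sentiment.csv`, `bootstrap_ci.csv`, and
#' `manifest.json` (configuration, seed, package version). All outputs are
#' computed before anything is written, so a failing stage leaves no partial
#' bundle. In components-only mode `input` is a pre-computed component table
#' (CSV) and only the scoring arithmetic runs (no corpus stages).
#'
#' @param input path to the corpus (or component table) file.
#' @param out_dir output directory (created if needed).
#' @param format corpus format (`"csv"`, `"ris"`, `"bibtex"`).
#' @param seed integer seed for the bootstrap.
#' @param components_only run only the scoring arithmetic on a component
#'   table?
#' @param lexicons,sent_config,config pipeline configuration.
#' @param bootstrap_reps bootstrap replicates; 0 disables the bootstrap.
#' @param min_occurrence network node threshold.
#' @return invisibly, the ranked score table.
#' @export
run_score <- function(input, out_dir, format = "csv", seed = 1L,
                      components_only = FALSE,
                      lexicons = default_lexicons(),
                      sent_config = sentiment_config(),
                      config = score_config(),
                      bootstrap_reps = config$bootstrap_reps,
                      min_occurrence = 1) {
  if (components_only) {
    if (!file.exists(input)) hs_io_error(sprintf("cannot read '%s': no such file", input))
    tab <- utils::read.csv(input, stringsAsFactors = FALSE)
    scores <- score_components(tab, config = config)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_scores(scores, file.path(out_dir, "scores.csv"))
    write_manifest(out_dir, list(mode = "components_only", input = input, seed = seed))
    return(invisible(scores))
  }
  corpus <- read_records(input, format = format)
  index <- tag_corpus(corpus, lexicons)
  sentiment <- score_sentiment(corpus, sent_config)
  graph <- build_graph(index, min_occurrence = min_occurrence,
                       categories = c("polymer", "enp", "impact"))
  scores <- score_corpus(corpus, lexicons = lexicons, sent_config = sent_config,
                         config = config, min_occurrence = min_occurrence)
  boot <- if (bootstrap_reps > 0)
    bootstrap_scores(corpus, reps = bootstrap_reps, seed = seed,
                     lexicons = lexicons, sent_config = sent_config,
                     config = config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_scores(scores, file.path(out_dir, "scores.csv"))
  write_graphml(graph, file.path(out_dir, "network.graphml"))
  utils::write.csv(sentiment, file.path(out_dir, "sentiment.csv"), row.names = FALSE)
  if (!is.null(boot))
    utils::write.csv(boot$ci, file.path(out_dir, "bootstrap_ci.csv"), row.names = FALSE)
  write_manifest(out_dir, list(mode = "full", input = input, format = format,
                               seed = seed,
                               sentiment = unclass(sent_config),
                               score = unclass(config),
                               bootstrap_reps = bootstrap_reps,
                               min_occurrence = min_occurrence))
  invisible(scores)
}

#' Generate and write a synthetic corpus
#'
#' Writes `corpus.csv` (reader dialect) and `truth.json` (the generating
#' entity probabilities, co-occurrence boost, sentiment mixture and seed) to
#' `out_dir`; the manifest suffices to regenerate the corpus bit-identically.
#'
#' @param spec an [synthetic_corpus_spec()].
#' @param out_dir output directory.
#' @return invisibly, the generated corpus.
#' @export
run_simulate <- function(spec, out_dir) {
  corpus <- generate_corpus(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_records(corpus, file.path(out_dir, "corpus.csv"))
  jsonlite::write_json(
    list(n_docs = spec$n_docs,
         entity_probs = as.list(spec$entity_probs),
         cooccur_boost = spec$cooccur_boost,
         sentiment_mix = spec$sentiment_mix,
         year_range = spec$year_range,
         seed = spec$seed,
         entity_sentiment = spec$entity_sentiment,
         entity_impact_boost = as.list(spec$entity_impact_boost)),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(corpus)
}

write_manifest <- function(out_dir, config) {
  jsonlite::write_json(
    list(package = "harmscore",
         version = as.character(utils::packageVersion("harmscore")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         config = config),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
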