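#' Build a controlled-vocabulary lexicon
#'
#' @param category one of `"polymer"`, `"enp"`, `"morphology"`, `"impact"`,
#'   `"technique"`, `"country"`.
#' @param entries named list mapping each canonical term to a character
#'   vector of surface synonyms (the canonical itself need not be repeated).
#' @param case_sensitive optional logical vector named by surface; by default
#'   a surface is matched case-sensitively when it is 4 characters or fewer
#'   and contains an uppercase letter (abbreviations such as PS, GO, TiO2),
#'   and case-insensitively otherwise.
#' @return object of class `hs_lexicon`.
#' @export
lexicon <- function(category, entries, case_sensitive = NULL) {
  cats <- c("polymer", "enp", "morphology", "impact", "technique", "country")
  if (!category %in% cats)
    hs_validation_error(sprintf("unknown lexicon category '%s'", category))
  if (anyDuplicated(names(entries)))
    hs_validation_error("canonical terms must be unique within a category")
  surfaces <- unlist(lapply(names(entries), function(cn) {
    s <- unique(c(cn, entries[[cn]]))
    setNames(rep(cn, length(s)), s)
  }))
  if (anyDuplicated(names(surfaces)))
    hs_validation_error(sprintf(
      "surface(s) %s map to more than one canonical term in category '%s'",
      paste(unique(names(surfaces)[duplicated(names(surfaces))]), collapse = ", "),
      category))
  structure(list(category = category, entries = entries,
                 case_sensitive = case_sensitive),
            class = "hs_lexicon")
}

default_case_rule <- function(surface) {
  nchar(surface) <= 4 & surface != stringi::stri_trans_tolower(surface)
}

# Flatten lexicons into the surface table tagging iterates over,
# longest surface first so multiword terms mask their substrings.
surface_table <- function(lexicons) {
  rows <- lapply(lexicons, function(lx) {
    surf <- unlist(lapply(names(lx$entries), function(cn) {
      s <- unique(c(cn, lx$entries[[cn]]))
      setNames(rep(cn, length(s)), s)
    }))
    cs <- default_case_rule(names(surf))
    if (!is.null(lx$case_sensitive)) {
      ov <- intersect(names(lx$case_sensitive), names(surf))
      cs[match(ov, names(surf))] <- lx$case_sensitive[ov]
    }
    data.frame(category = lx$category, canonical = unname(surf),
               surface = names(surf), case_sensitive = cs,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab[order(-nchar(tab$surface), tab$surface), , drop = FALSE]
}

#' Default controlled vocabularies
#'
#' Ships the six lexicons the toolkit mines: the 18 polymer abbreviations with
#' their full-name synonyms, common engineered nanoparticles (ENPs),
#' morphology descriptors, environmental/biological impact descriptors
#' (including harm terms such as oxidative stress and genotoxicity),
#' characterization techniques, and high-output countries.
#'
#' @return named list of `hs_lexicon` objects
#'   (`polymer`, `enp`, `morphology`, `impact`, `technique`, `country`).
#' @export
default_lexicons <- function() {
  polymer <- lexicon("polymer", list(
    PS   = "polystyrene",
    PE   = "polyethylene",
    PP   = "polypropylene",
    PET  = c("polyethylene terephthalate", "poly(ethylene terephthalate)"),
    PA   = c("polyamide", "nylon"),
    PVC  = c("polyvinyl chloride", "poly(vinyl chloride)"),
    PUR  = c("polyurethane", "PU"),
    PLA  = c("polylactic acid", "poly(lactic acid)", "polylactide"),
    PC   = "polycarbonate",
    PMMA = c("polymethyl methacrylate", "poly(methyl methacrylate)"),
    ABS  = "acrylonitrile butadiene styrene",
    PTFE = c("polytetrafluoroethylene", "teflon"),
    EVA  = c("ethylene-vinyl acetate", "ethylene vinyl acetate"),
    HDPE = c("high-density polyethylene", "high density polyethylene"),
    LDPE = c("low-density polyethylene", "low density polyethylene"),
    POM  = c("polyoxymethylene", "polyacetal"),
    PBT  = "polybutylene terephthalate",
    PEEK = c("polyether ether ketone", "polyetheretherketone")
  ))
  enp <- lexicon("enp", list(
    TiO2   = c("TiO_2", "titanium dioxide"),
    ZnO    = "zinc oxide",
    AgNP   = c("AgNPs", "silver nanoparticle", "silver nanoparticles"),
    SiO2   = c("SiO_2", "silicon dioxide", "silica"),
    GO     = c("graphene oxide", "graphene"),
    CNT    = c("CNTs", "carbon nanotube", "carbon nanotubes"),
    Fe3O4  = c("Fe_3_O_4", "magnetite"),
    Fe2O3  = c("Fe_2_O_3", "hematite"),
    CuO    = "copper oxide",
    PbS    = c("lead sulfide", "lead sulphide"),
    Al2O3  = c("Al_2_O_3", "aluminum oxide", "aluminium oxide", "alumina"),
    sulfur = "sulphur"
  ))
  morphology <- lexicon("morphology", list(
    particle = character(), film = character(),
    fiber = "fibre", microfiber = "microfibre",
    fragment = character(), foam = character(), line = character(),
    sphere = character(), bead = character(), pellet = character(),
    crystalline = character()
  ))
  impact <- lexicon("impact", list(
    microplastic = character(), pollution = "pollutant",
    effect = character(), impact = character(), degradation = character(),
    treatment = character(), adsorption = character(), toxicity = character(),
    wastewater = character(), sustainable = "sustainability",
    `oxidative stress` = character(), cytotoxicity = character(),
    genotoxicity = character(), bioaccumulation = character()
  ))
  technique <- lexicon("technique", list(
    FTIR = "fourier transform infrared",
    SEM = "scanning electron microscopy",
    Raman = "raman spectroscopy",
    pyrolysis = character(),
    XRD = "x-ray diffraction",
    `fluorescence microscopy` = character(),
    digestion = character(),
    `machine learning` = character(),
    PCA = "principal component analysis",
    `neural network` = "neural networks"
  ))
  country <- lexicon("country", list(
    China = character(), India = character(),
    `United States` = c("USA", "United States of America"),
    Germany = character(), Italy = character(), Spain = character(),
    `South Korea` = "Republic of Korea", Canada = character(),
    Australia = character(), Japan = character(), Iran = character(),
    Egypt = character(), Brazil = character(),
    `United Kingdom` = "UK", France = character()
  ))
  list(polymer = polymer, enp = enp, morphology = morphology,
       impact = impact, technique = technique, country = country)
}

# regex for one surface: non-alphanumeric boundaries + optional plural "s"
surface_pattern <- function(surface) {
  esc <- stringi::stri_replace_all_regex(surface, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1")
  paste0("(?<![\\p{L}\\p{N}])", esc, "s?(?![\\p{L}\\p{N}])")
}

#' Tag documents against controlled vocabularies
#'
#' Longest-match-first, word-boundary occurrence counting of every lexicon
#' surface over title + abstract. Matched spans are masked so a multiword
#' surface (e.g. "polyethylene terephthalate") hides its substrings
#' ("polyethylene") from shorter surfaces. Surfaces flagged case-sensitive
#' (short abbreviations such as PS or GO) are matched against the
#' original-case text, so "PSD" never yields a PS hit.
#'
#' @param corpus an `hs_corpus` data frame (or any data frame with `id`,
#'   `title`, `abstract` columns).
#' @param lexicons list of `hs_lexicon` objects; defaults to
#'   [default_lexicons()].
#' @return Mention index of class `hs_mentions`: a long data frame with
#'   columns `id`, `category`, `term`, `count` (occurrence counts, rows only
#'   for count >= 1), with attributes `n_docs` and `doc_ids`.
#' @export
tag_corpus <- function(corpus, lexicons = default_lexicons()) {
  stab <- surface_table(lexicons)
  texts <- normalize_text(paste(corpus$title, corpus$abstract))$original
  n <- length(texts)
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(stab))) {
    pat <- surface_pattern(stab$surface[i])
    ci <- !stab$case_sensitive[i]
    counts <- stringi::stri_count_regex(texts, pat,
                                        opts_regex = stringi::stri_opts_regex(case_insensitive = ci))
    hit <- counts > 0L
    if (any(hit)) {
      key <- paste0(stab$category[i], "\r", stab$canonical[i])
      prev <- if (!is.null(acc[[key]])) acc[[key]] else integer(n)
      prev[hit] <- prev[hit] + counts[hit]
      acc[[key]] <- prev
      texts[hit] <- stringi::stri_replace_all_regex(
        texts[hit], pat, "\u0001",
        opts_regex = stringi::stri_opts_regex(case_insensitive = ci))
    }
  }
  keys <- ls(acc)
  rows <- lapply(keys, function(k) {
    ct <- acc[[k]]
    idx <- which(ct > 0L)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(id = corpus$id[idx], category = parts[1], term = parts[2],
               count = ct[idx], stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), category = character(),
               term = character(), count = integer(), stringsAsFactors = FALSE)
  out <- out[order(out$id, out$category, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hs_mentions", "data.frame")
  attr(out, "n_docs") <- nrow(corpus)
  attr(out, "doc_ids") <- corpus$id
  out
}

#' @rdname tag_corpus
#' @param record a single-row corpus data frame (one document).
#' @export
tag_document <- function(record, lexicons = default_lexicons()) {
  tag_corpus(record[1, , drop = FALSE], lexicons)
}

#' Per-term document counts and percentages
#'
#' @param index an `hs_mentions` index from [tag_corpus()].
#' @param n_docs corpus size the percentages are relative to; defaults to the
#'   size recorded on the index.
#' @return data frame with `category`, `term`, `doc_count`, `mention_count`,
#'   and `pct` (document percentage, 2 decimals).
#' @export
category_frequencies <- function(index, n_docs = attr(index, "n_docs")) {
  if (is.null(n_docs) || n_docs < 1) hs_validation_error("n_docs must be >= 1")
  if (!nrow(index))
    return(data.frame(category = character(), term = character(),
                      doc_count = integer(), mention_count = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  key <- interaction(index$category, index$term, drop = TRUE)
  agg <- data.frame(
    category = tapply(index$category, key, `[`, 1),
    term = tapply(index$term, key, `[`, 1),
    doc_count = as.integer(tapply(index$id, key, function(x) length(unique(x)))),
    mention_count = as.integer(tapply(index$count, key, sum)),
    stringsAsFactors = FALSE)
  agg$pct <- round(100 * agg$doc_count / n_docs, 2)
  agg <- agg[order(agg$category, -agg$doc_count, agg$term), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Document-by-term presence matrix for one category
#'
#' @param index an `hs_mentions` index.
#' @param category lexicon category to extract.
#' @param counts if `TRUE` return occurrence counts instead of 0/1 presence.
#' @return integer matrix, rows = documents (all docs in the tagged corpus),
#'   columns = canonical terms seen in that category.
#' @export
mention_matrix <- function(index, category, counts = FALSE) {
  ids <- attr(index, "doc_ids")
  sub <- index[index$category == category, , drop = FALSE]
  terms <- sort(unique(sub$term))
  m <- matrix(0L, nrow = length(ids), ncol = length(terms),
              dimnames = list(ids, terms))
  if (nrow(sub)) {
    ij <- cbind(match(sub$id, ids), match(sub$term, terms))
    m[ij] <- if (counts) as.integer(sub$count) else 1L
  }
  m
}

#' Read or write lexicons as YAML or JSON
#'
#' The schema is a list of objects with fields `category`, `entries`
#' (canonical -> synonyms), and optional `case_sensitive` overrides.
#'
#' @param lexicons named list of `hs_lexicon` objects.
#' @param path file path; format inferred from the `.yaml`/`.yml` or `.json`
#'   extension.
#' @return `write_lexicons()`: `path` invisibly; `read_lexicons()`: named
#'   list of `hs_lexicon` objects.
#' @export
write_lexicons <- function(lexicons, path) {
  obj <- lapply(lexicons, function(lx) {
    list(category = lx$category,
         entries = lapply(lx$entries, as.list),
         case_sensitive = as.list(lx$case_sensitive))
  })
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lexicons
#' @export
read_lexicons <- function(path) {
  if (!file.exists(path)) hs_io_error(sprintf("cannot read '%s': no such file", path))
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path)
  out <- lapply(obj, function(o) {
    cs <- if (length(o$case_sensitive)) unlist(o$case_sensitive) else NULL
    lexicon(o$category, lapply(o$entries, function(e) unlist(e, use.names = FALSE)),
            case_sensitive = cs)
  })
  setNames(out, vapply(out, function(lx) lx$category, character(1)))
}
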