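#' Read bibliographic records
#'
#' Reads abstract records from CSV, RIS, or BibTeX into a corpus data frame
#' with one row per document. Records without an abstract are dropped and
#' counted; duplicates (same DOI when present, otherwise same normalized
#' title + year) collapse to the first occurrence.
#'
#' The CSV dialect is UTF-8 with a header row and columns
#' `id,title,abstract,year,country` (`country` may hold several
#' `;`-separated names; an optional `doi` column sharpens deduplication).
#' RIS entries use the `TY/TI/AB/PY/CY` tags; BibTeX entries use the
#' `title`/`abstract`/`year` fields.
#'
#' @param path path to the input file.
#' @param format one of `"csv"`, `"ris"`, `"bibtex"`.
#' @return A data frame of class `hs_corpus` with columns `id`, `title`,
#'   `abstract`, `year` (integer, `NA` when absent), `countries`
#'   (`;`-separated string) and `source`. The number of records excluded for
#'   lacking an abstract is attached as attribute `"excluded"` and reported
#'   via a message.
#' @export
read_records <- function(path, format = c("csv", "ris", "bibtex")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) hs_usage_error(
                       sprintf("unknown format '%s' (use csv, ris or bibtex)", format[1])))
  if (!file.exists(path)) hs_io_error(sprintf("cannot read '%s': no such file", path))
  raw <- switch(format,
                csv = read_records_csv(path),
                ris = read_records_ris(path),
                bibtex = read_records_bibtex(path))
  as_corpus(raw, source = format)
}

read_records_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 encoding = "UTF-8", check.names = FALSE),
                 error = function(e) hs_io_error(sprintf("failed to parse '%s': %s",
                                                         path, conditionMessage(e))))
  need <- c("title", "abstract")
  if (!all(need %in% names(df)))
    hs_io_error(sprintf("CSV must contain columns %s", paste(need, collapse = ", ")))
  data.frame(
    id = if ("id" %in% names(df)) as.character(df$id) else rep(NA_character_, nrow(df)),
    title = as.character(df$title),
    abstract = as.character(df$abstract),
    year = if ("year" %in% names(df)) suppressWarnings(as.integer(df$year)) else NA_integer_,
    countries = if ("country" %in% names(df)) as.character(df$country) else "",
    doi = if ("doi" %in% names(df)) as.character(df$doi) else NA_character_,
    stringsAsFactors = FALSE
  )
}

# minimal RIS tag reader: entries delimited by ER  -, fields as "XX  - value"
read_records_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- list(); cur <- list()
  flush <- function(cur) {
    if (!length(cur)) return(NULL)
    data.frame(
      id = if (!is.null(cur$ID)) cur$ID else NA_character_,
      title = if (!is.null(cur$TI)) cur$TI else if (!is.null(cur$T1)) cur$T1 else "",
      abstract = if (!is.null(cur$AB)) cur$AB else "",
      year = if (!is.null(cur$PY))
        suppressWarnings(as.integer(sub("^([0-9]{4}).*", "\\1", cur$PY))) else NA_integer_,
      countries = if (!is.null(cur$CY)) cur$CY else "",
      doi = if (!is.null(cur$DO)) cur$DO else NA_character_,
      stringsAsFactors = FALSE)
  }
  last_tag <- NULL
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Z][A-Z0-9])  - ?(.*)$", ln))[[1]]
    if (length(m)) {
      tag <- m[2]; val <- m[3]
      if (tag == "ER") { recs[[length(recs) + 1L]] <- flush(cur); cur <- list(); last_tag <- NULL }
      else {
        cur[[tag]] <- if (is.null(cur[[tag]])) val else paste(cur[[tag]], val, sep = "; ")
        last_tag <- tag
      }
    } else if (!is.null(last_tag) && nzchar(trimws(ln))) {
      # continuation line of a wrapped field
      cur[[last_tag]] <- paste(cur[[last_tag]], trimws(ln))
    }
  }
  if (length(cur)) recs[[length(recs) + 1L]] <- flush(cur)
  if (!length(recs)) hs_io_error(sprintf("no RIS entries found in '%s'", path))
  do.call(rbind, recs)
}

# minimal BibTeX reader: @type{key, field = {value}|"value", ...}
read_records_bibtex <- function(path) {
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  starts <- gregexpr("@[A-Za-z]+\\s*\\{", txt)[[1]]
  if (starts[1] == -1) hs_io_error(sprintf("no BibTeX entries found in '%s'", path))
  chunks <- mapply(function(s, e) substr(txt, s, e),
                   starts, c(starts[-1] - 1L, nchar(txt)))
  recs <- lapply(chunks, function(chunk) {
    km <- regmatches(chunk, regexec("@[A-Za-z]+\\s*\\{\\s*([^,}\\s]+)", chunk,
                                    perl = TRUE))[[1]]
    key <- if (length(km) == 2) km[2] else ""
    field <- function(name) {
      # brace-delimited first, then quoted, then bare
      pats <- c(sprintf("(?si)\\b%s\\s*=\\s*\\{([^{}]*)\\}", name),
                sprintf('(?si)\\b%s\\s*=\\s*"([^"]*)"', name),
                sprintf("(?si)\\b%s\\s*=\\s*([^,}\\s]+)", name))
      for (p in pats) {
        m <- regmatches(chunk, regexec(p, chunk, perl = TRUE))[[1]]
        if (length(m) == 2) return(gsub("\\s+", " ", trimws(m[2])))
      }
      NA_character_
    }
    ti <- field("title"); ab <- field("abstract")
    data.frame(
      id = if (nzchar(key)) key else NA_character_,
      title = if (is.na(ti)) "" else ti,
      abstract = if (is.na(ab)) "" else ab,
      year = suppressWarnings(as.integer(field("year"))),
      countries = { cy <- field("country"); if (is.na(cy)) "" else cy },
      doi = field("doi"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# Normalize a raw record table into an hs_corpus: drop empty abstracts,
# deduplicate, assign ids, validate years.
as_corpus <- function(df, source = "unknown") {
  df$abstract <- trimws(df$abstract)
  df$title <- trimws(df$title)
  keep <- !is.na(df$abstract) & nzchar(df$abstract)
  excluded <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) hs_io_error("empty corpus: no records with a non-empty abstract survive")
  bad_year <- !is.na(df$year) & (df$year < 1900 | df$year > 2100)
  if (any(bad_year)) df$year[bad_year] <- NA_integer_
  # dedup: DOI when present, else normalized title + year
  key <- ifelse(!is.na(df$doi) & nzchar(df$doi),
                paste0("doi:", tolower(df$doi)),
                paste0("ty:", normalize_text(df$title)$norm, "|", ifelse(is.na(df$year), "", df$year)))
  df <- df[!duplicated(key), , drop = FALSE]
  miss <- is.na(df$id) | !nzchar(df$id) | duplicated(df$id)
  if (any(miss)) df$id[miss] <- sprintf("doc%05d", which(miss))
  out <- data.frame(id = df$id, title = df$title, abstract = df$abstract,
                    year = df$year, countries = df$countries,
                    source = source, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hs_corpus", "data.frame")
  attr(out, "excluded") <- excluded
  if (excluded > 0)
    message(sprintf("read_records: excluded %d record(s) without an abstract", excluded))
  out
}

#' Write a corpus to CSV
#'
#' Writes the same UTF-8 header dialect `read_records()` consumes
#' (`id,title,abstract,year,country`), so `read_records(write_records(x))`
#' round-trips id, title, abstract, and year.
#'
#' @param corpus an `hs_corpus` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(corpus, path) {
  df <- data.frame(id = corpus$id, title = corpus$title, abstract = corpus$abstract,
                   year = corpus$year, country = corpus$countries,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Normalize free text for matching
#'
#' Produces two aligned views of the input: a lowercased copy with
#' punctuation collapsed to spaces (for general case-insensitive matching)
#' and an original-case copy (for case-sensitive matching of short
#' abbreviations such as PS or PET). In both views the hyphenated spellings
#' "micro-plastic(s)" and "nano-plastic(s)" collapse to their solid forms.
#'
#' @param text character vector.
#' @return list with character vectors `norm` (lowercase, punctuation
#'   stripped) and `original` (case preserved, hyphen-collapsed).
#' @export
normalize_text <- function(text) {
  text <- ifelse(is.na(text), "", text)
  orig <- stringi::stri_replace_all_regex(text, "(?i)\\b(micro|nano)-(plastic)", "$1$2")
  low <- stringi::stri_trans_tolower(orig)
  low <- stringi::stri_replace_all_regex(low, "[^\\p{L}\\p{N}]+", " ")
  low <- trimws(stringi::stri_replace_all_regex(low, "\\s+", " "))
  list(norm = low, original = orig)
}
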