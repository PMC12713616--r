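test_that("CSV records parse, and abstract-less records are excluded with a count", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,title,abstract,year,country",
               "a1,First study,Microplastics in rivers,2019,China",
               "a2,Second study,Polystyrene beads in soil,2021,India;Spain"), f)
  corp <- read_records(f, "csv")
  expect_s3_class(corp, "hs_corpus")
  expect_equal(nrow(corp), 2L)
  expect_equal(corp$year, c(2019L, 2021L))
  expect_equal(attr(corp, "excluded"), 0L)

  writeLines(c("id,title,abstract,year,country",
               "a1,Kept,Some abstract,2019,",
               "a2,Dropped,,2020,"), f)
  expect_message(corp2 <- read_records(f, "csv"), "excluded 1")
  expect_equal(nrow(corp2), 1L)
  expect_equal(attr(corp2, "excluded"), 1L)
})

test_that("RIS entries parse and an entry without AB is excluded", {
  f <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TY  - JOUR", "TI  - With abstract", "AB  - Body text here",
               "PY  - 2018", "CY  - Canada", "ER  -",
               "TY  - JOUR", "TI  - No abstract", "PY  - 2019", "ER  -"), f)
  expect_message(corp <- read_records(f, "ris"), "excluded 1")
  expect_equal(nrow(corp), 1L)
  expect_equal(corp$title, "With abstract")
  expect_equal(corp$year, 2018L)
  # a file whose only entry lacks AB leaves an empty corpus
  writeLines(c("TY  - JOUR", "TI  - No abstract", "ER  -"), f)
  expect_error(suppressMessages(read_records(f, "ris")), "empty corpus")
})

test_that("BibTeX title/abstract/year fields are read", {
  f <- withr::local_tempfile(fileext = ".bib")
  writeLines(c("@article{smith2020,",
               "  title = {Polymer fate in soils},",
               "  abstract = {We study polymer fate.},",
               "  year = {2020}", "}",
               "@article{lee2021,",
               '  title = "Nanoplastics",',
               '  abstract = "Small particles.",',
               "  year = 2021", "}"), f)
  corp <- read_records(f, "bibtex")
  expect_equal(nrow(corp), 2L)
  expect_equal(corp$id, c("smith2020", "lee2021"))
  expect_equal(corp$year, c(2020L, 2021L))
  expect_equal(corp$abstract[2], "Small particles.")
})

test_that("duplicates collapse on normalized title + year, DOI taking precedence", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- c("id,title,abstract,year,country",
            sprintf("r%d,Unique title %d,Abstract %d,2020,", 1:7, 1:7, 1:7),
            "r8,Shared Title!,Abstract 8,2021,",
            "r9,shared title,Abstract 9,2021,",
            "r10,SHARED TITLE,Abstract 10,2021,")
  writeLines(rows, f)
  corp <- read_records(f, "csv")
  expect_equal(nrow(corp), 8L)   # 10 records, 3 share a title+year

  # same title+year but distinct DOIs stay separate
  writeLines(c("id,title,abstract,year,country,doi",
               "x1,Same,A,2020,,10.1/a",
               "x2,Same,B,2020,,10.1/b"), f)
  expect_equal(nrow(read_records(f, "csv")), 2L)
})

test_that("reader errors are explicit", {
  expect_error(read_records("/nonexistent/file.csv", "csv"), "no such file")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,title,abstract\n", f)
  expect_error(read_records(f, "unknown_format"), "unknown format")
})

test_that("write_records round-trips id, title, abstract, and year", {
  f <- withr::local_tempfile(fileext = ".csv")
  corp <- generate_corpus(synthetic_corpus_spec(25, c(PS = 0.4, toxicity = 0.3), seed = 5))
  write_records(corp, f)
  back <- read_records(f, "csv")
  expect_equal(back$id, corp$id)
  expect_equal(back$title, corp$title)
  expect_equal(back$abstract, corp$abstract)
  expect_equal(back$year, corp$year)
})

test_that("normalize_text lowercases, strips punctuation, keeps case copy, joins hyphens", {
  r <- normalize_text("Polystyrene (PS) beads")
  expect_equal(r$norm, "polystyrene ps beads")
  expect_equal(r$original, "Polystyrene (PS) beads")
  expect_equal(normalize_text("")$norm, "")
  expect_equal(normalize_text("micro-plastics")$norm, "microplastics")
  expect_equal(normalize_text("Nano-Plastic load")$original, "NanoPlastic load")
})

test_that("generator is deterministic and respects zero probabilities", {
  spec <- synthetic_corpus_spec(50, c(PS = 0.3, PE = 0, toxicity = 0.2), seed = 7)
  a <- generate_corpus(spec)
  b <- generate_corpus(spec)
  expect_identical(a, b)
  expect_false(any(grepl("PE debris", a$abstract, fixed = TRUE)))
  # different seed differs
  c2 <- generate_corpus(synthetic_corpus_spec(50, c(PS = 0.3, PE = 0, toxicity = 0.2), seed = 8))
  expect_false(identical(a$abstract, c2$abstract))
})

test_that("generator spec validation rejects bad inputs", {
  expect_error(synthetic_corpus_spec(0, c(PS = 0.2)), "n_docs")
  expect_error(synthetic_corpus_spec(10, c(PS = 1.2)), "\\[0, 1\\]")
  expect_error(synthetic_corpus_spec(10, c(0.2)), "named")
  expect_error(synthetic_corpus_spec(10, c(PS = 0.2), sentiment_mix = c(0.5, 0.3, 0.3)),
               "sum to 1")
  # the printed-rounding mix (sums to 1.001) is accepted and renormalized
  sp <- synthetic_corpus_spec(10, c(PS = 0.2), sentiment_mix = c(0.655, 0.242, 0.104))
  expect_equal(sum(sp$sentiment_mix), 1, tolerance = 1e-12)
})

test_that("empirical mention rates converge to configured probabilities across seeds", {
  n <- 400; p <- 0.15
  ok <- vapply(1:100, function(s) {
    corp <- generate_corpus(synthetic_corpus_spec(n, c(PS = p), seed = s))
    phat <- mean(grepl("Samples contained PS debris", corp$abstract, fixed = TRUE))
    abs(phat - p) < 3 * sqrt(p * (1 - p) / n)
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("cooccur_boost amplifies joint mentions but preserves marginals", {
  n <- 4000
  base <- generate_corpus(synthetic_corpus_spec(n, c(PS = 0.3, PE = 0.3),
                                                cooccur_boost = 1, seed = 31))
  boosted <- generate_corpus(synthetic_corpus_spec(n, c(PS = 0.3, PE = 0.3),
                                                   cooccur_boost = 4, seed = 31))
  ps <- function(x) grepl("PS debris", x$abstract, fixed = TRUE)
  pe <- function(x) grepl("PE debris", x$abstract, fixed = TRUE)
  expect_gt(mean(ps(boosted) & pe(boosted)), mean(ps(base) & pe(base)))
  se <- 3 * sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(ps(boosted)) - 0.3), se)
  expect_lt(abs(mean(pe(boosted)) - 0.3), se)
})
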