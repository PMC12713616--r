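test_that("frequency percentage and normalized frequency reproduce published arithmetic", {
  n_corpus <- 100713
  expect_equal(frequency_percentage(7594, n_corpus), 7.540)
  expect_equal(frequency_percentage(10205, n_corpus), 10.133)
  expect_equal(frequency_percentage(21, n_corpus), 0.021)
  F_ps <- normalize_frequency(c(PS = 7.540, PE = 10.133))[["PS"]]
  expect_equal(F_ps, 7.540 / 10.133, tolerance = 1e-12)
  expect_equal(frequency_weight(0.744), 0.9232, tolerance = 1e-12)
  expect_error(frequency_percentage(5, 0), "positive")
  expect_error(frequency_percentage(0, 10), "n_p")
  expect_error(normalize_frequency(numeric()), "no percentages")
  expect_error(frequency_weight(1.2), "\\[0, 1\\]")
})

test_that("confidence is the saturating replication penalty", {
  expect_equal(confidence(0), 0)
  expect_equal(confidence(20), 0.5)
  expect_equal(round(confidence(21), 3), 0.512)
  expect_equal(round(confidence(2403), 3), 0.992)
  expect_equal(round(confidence(131), 3), 0.868)
  n <- 0:500
  expect_true(all(diff(confidence(n)) > 0))
  expect_true(all(confidence(n) < 1))
  expect_error(confidence(-1), "nonnegative")
})

test_that("base and final score formulas match printed table rows", {
  # PS row: components 0.770 / 0.874 / 1 -> base 0.857(4)
  expect_equal(base_score(0.770, 0.874, 1), 0.8576, tolerance = 1e-12)
  expect_lt(abs(base_score(0.770, 0.874, 1) - 0.857), 0.002)
  # PS final: printed base x weight(0.744) x printed confidence
  expect_equal(final_score(0.857, 0.744, 7594), 0.857 * 0.9232 * confidence(7594),
               tolerance = 1e-12)
  expect_equal(round(final_score(0.857, 0.744, 7594), 3), 0.789)
  # PEEK, the rarest polymer, is dominated by the confidence penalty
  expect_equal(round(final_score(0.638, 0.002, 21), 3), 0.229)
  expect_error(base_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(final_score(1.5, 0.5, 10), "\\[0, 1\\]")
  # custom weights are honored
  cfg <- score_config(weights = c(S = 1, I = 0, C = 0))
  expect_equal(base_score(0.3, 0.9, 0.9, cfg), 0.3)
  expect_error(score_config(weights = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("H never exceeds B and is monotone in each argument", {
  set.seed(4)
  B <- runif(200); F_p <- runif(200); n_p <- sample(1:5000, 200, TRUE)
  H <- final_score(B, F_p, n_p)
  expect_true(all(H <= B + 1e-15))
  expect_true(all(H >= 0))
  expect_true(all(final_score(B, pmin(F_p + 0.1, 1), n_p) >= H))
  expect_true(all(final_score(B, F_p, n_p + 50) >= H))
  expect_true(all(final_score(pmin(B + 0.05, 1), F_p, n_p) >= H))
})

test_that("impact component equals a hand-counted co-mention density", {
  # PA: 2 docs, 1 with impact -> rate 0.5; PB: 1 doc with impact -> rate 1
  idx <- make_index(list("PA", "PA", "PB"))
  imp_idx <- make_index(list("toxicity", character(), "toxicity"),
                        category = "impact")
  both <- rbind(as.data.frame(idx), as.data.frame(imp_idx))
  both$id[both$category == "impact"] <- c("d001", "d003")
  class(both) <- c("hs_mentions", "data.frame")
  attr(both, "n_docs") <- 3L
  attr(both, "doc_ids") <- sprintf("d%03d", 1:3)
  out <- impact_component(both)
  expect_equal(out$impact_rate[out$polymer == "PA"], 0.5)
  expect_equal(out$impact_rate[out$polymer == "PB"], 1.0)
  expect_equal(out$I[out$polymer == "PA"], 0.5)
  expect_equal(out$I[out$polymer == "PB"], 1.0)
  expect_error(impact_component(make_index(list("toxicity"), category = "impact")),
               "no polymer mentions")
})

test_that("centrality component max-normalizes the chosen measure over polymers", {
  cent <- data.frame(term = c("PS", "PE", "TiO2"),
                     degree = c(0.8, 0.4, 1.0),
                     eigenvector = c(1.0, 0.5, 0.9),
                     betweenness = c(0.3, 0.1, 0.6))
  cc <- centrality_component(cent, c("PS", "PE"))
  expect_equal(setNames(cc$C, cc$polymer), c(PS = 1.0, PE = 0.5))
  cc2 <- centrality_component(cent, c("PS", "PE"), measure = "betweenness")
  expect_equal(setNames(cc2$C, cc2$polymer), c(PS = 1.0, PE = 1 / 3))
  expect_warning(cc3 <- centrality_component(cent, c("PS", "PLA")), "absent")
  expect_equal(cc3$polymer, "PS")
  expect_error(centrality_component(cent, "PLA"), "no polymers present")
})

test_that("ranking orders by score, then paper count, then id, regardless of input order", {
  rows <- data.frame(polymer = c("PC", "PA", "PB", "PD"),
                     harmfulness_score = c(0.5, 0.9, 0.5, 0.5),
                     paper_count = c(10L, 5L, 30L, 10L))
  set.seed(8)
  for (i in 1:5) {
    shuf <- rows[sample(nrow(rows)), ]
    expect_equal(rank_scores(shuf)$polymer, c("PA", "PB", "PC", "PD"))
  }
})

test_that("skewness matches closed forms and the e1071 type-2 oracle", {
  expect_equal(score_skewness(c(1, 2, 3)), 0)
  expect_gt(score_skewness(c(1, 1, 1, 10)), 0)
  expect_lt(score_skewness(c(-10, 1, 1, 1)), 0)
  set.seed(12)
  v <- rexp(100)
  expect_equal(score_skewness(v), e1071::skewness(v, type = 2), tolerance = 1e-12)
  expect_error(score_skewness(c(1, 2)), "at least 3")
  expect_error(score_skewness(rep(2, 5)), "zero variance")
})

test_that("score_components reproduces every printed Harmfulness Score from table columns", {
  ref <- reference_scores()
  out <- score_components(ref)
  m <- match(ref$polymer, out$polymer)
  expect_true(all(abs(out$harmfulness_score[m] - ref$harmfulness_score) < 0.002))
  # and the ranking of the recomputed table preserves the published order
  expect_equal(out$polymer, ref$polymer)
  expect_error(score_components(data.frame(polymer = "PS")), "paper_count")
  expect_error(score_components(data.frame(polymer = "PS", paper_count = 5)),
               "frequency_percentage")
})

test_that("leave-one-out renormalizes F and finds no inversion for stable drops", {
  ref <- reference_scores()
  loo <- leave_one_out(score_components(ref), "PE")
  # PE held the maximum frequency; dropping it rescales every F upward
  expect_true(all(loo$table$frequency_weight >=
                  ref$frequency_weight[match(loo$table$polymer, ref$polymer)] - 1e-12))
  expect_equal(max(loo$table$frequency_weight), 1)
  expect_equal(loo$n_inversions, 0L)
  loo2 <- leave_one_out(score_components(ref), "PS")
  expect_equal(loo2$n_inversions, 0L)
  expect_error(leave_one_out(score_components(ref), "XYZ"), "not present")
})

test_that("score_corpus produces a coherent ranked table on a synthetic corpus", {
  corp <- scenario_corpus(1500, seed = 2)
  tab <- score_corpus(corp)
  expect_s3_class(tab, "hs_scores")
  expect_true(all(tab$harmfulness_score <= tab$base_score + 1e-12))
  expect_true(all(tab$harmfulness_score >= 0 & tab$harmfulness_score <= 1))
  expect_equal(max(tab$frequency_weight), 1)
  expect_true(all(diff(tab$harmfulness_score) <= 1e-12))
  # the scenario makes PS most frequent, most negative, most impact-laden
  expect_equal(tab$polymer[1], "PS")
  expect_equal(tab$polymer, c("PS", "PE", "PLA"))
})

test_that("score ordering is reproduced across independent seeds", {
  for (s in 1:5) {
    tab <- score_corpus(scenario_corpus(1500, seed = s))
    expect_equal(tab$polymer, c("PS", "PE", "PLA"),
                 label = sprintf("ordering at seed %d", s))
  }
})

test_that("bootstrap is seed-deterministic and point estimates match the full pipeline", {
  corp <- scenario_corpus(400, seed = 10)
  b1 <- bootstrap_scores(corp, reps = 25, seed = 5)
  b2 <- bootstrap_scores(corp, reps = 25, seed = 5)
  expect_identical(b1, b2)
  b3 <- bootstrap_scores(corp, reps = 25, seed = 6)
  expect_false(identical(b1$replicates, b3$replicates))
  expect_true(all(b1$ci$lower <= b1$ci$estimate + 1e-12))
  expect_true(all(b1$ci$estimate <= b1$ci$upper + 1e-12))
  tab <- score_corpus(corp)
  est <- setNames(b1$ci$estimate, b1$ci$polymer)
  expect_equal(est[tab$polymer], setNames(tab$harmfulness_score, tab$polymer),
               tolerance = 1e-12)
  expect_error(bootstrap_scores(corp, reps = 0), "reps")
})

test_that("bootstrap intervals narrow as the corpus grows", {
  small <- bootstrap_scores(scenario_corpus(400, seed = 21), reps = 60, seed = 99)
  large <- bootstrap_scores(scenario_corpus(3200, seed = 22), reps = 60, seed = 99)
  shared <- intersect(small$ci$polymer, large$ci$polymer)
  ws <- setNames(small$ci$width, small$ci$polymer)[shared]
  wl <- setNames(large$ci$width, large$ci$polymer)[shared]
  expect_true(all(wl < ws))
})

test_that("write_scores rounds every numeric column except the paper count", {
  ref <- score_components(reference_scores())
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores(ref, f)
  back <- read.csv(f)
  expect_equal(back$harmfulness_score, round(ref$harmfulness_score, 3))
  expect_equal(back$paper_count, ref$paper_count)
})
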