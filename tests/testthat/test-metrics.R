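test_that("lawfulness counts profile violations per statement", {
  fix <- lawfulness_fixture()
  res <- lawfulness(fix)
  expect_equal(res$n_statements, 10L)
  expect_length(res$violations, 1)
  expect_equal(res$score, 0.9)
  expect_match(res$violations, "undeclared class")
  # score + violation rate = 1 exactly
  expect_equal(res$score + length(res$violations) / res$n_statements, 1)
  # empty ontology scores 1 by convention
  expect_equal(lawfulness(phido:::triple_df())$score, 1)
})

test_that("richness is the used share of the axiom inventory", {
  inv10 <- c("SubClassOf", paste0("Type", 1:9))
  fix <- paste(
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "<http://x#A> a owl:Class .",
    "<http://x#B> a owl:Class .",
    "<http://x#B> rdfs:subClassOf <http://x#A> .",
    sep = "\n")
  expect_equal(richness(fix, inv10), 0.1)
  expect_equal(richness(phido:::triple_df(), inv10), 0)
  # the full schema uses many but not all recognised types
  r <- richness(build_schema())
  expect_gt(r, 0); expect_lt(r, 1)
  used <- phido:::axiom_types_used(phido:::schema_to_triples(build_schema()))
  expect_equal(richness(build_schema(), used), 1)
  expect_error(richness(build_schema(), character()), "non-empty")
})

test_that("interpretability and clarity follow the toy lexicon", {
  # labels Gene, Blue, Cell: senses 1, 2, 4 in the bundled lexicon
  fix <- lawfulness_fixture()
  lex <- toy_lexicon()
  expect_equal(lex("gene"), 1L)
  expect_equal(lex("blue"), 2L)
  expect_equal(lex("cell"), 4L)
  expect_equal(lex("zzqx"), 0L)
  expect_equal(interpretability(fix), 1)
  expect_equal(clarity(fix), (1 + 1/2 + 1/4) / 3)
  # 3 of 4 words known
  fix2 <- sub("\"Cell\"", "\"Cell Zzqx\"", fix)
  expect_equal(interpretability(fix2), 0.75)
  # unknown words clamp to one sense in clarity
  expect_equal(clarity(fix2), (1 + 1/2 + 1/4 + 1) / 4)
  # no labels at all: convention 1 on fragment fallback all unknown? the
  # fallback tokenizes IRI fragments, so craft an empty ontology instead
  expect_equal(interpretability(phido:::triple_df()), 1)
})

test_that("consistency is the satisfiable-class fraction", {
  expect_equal(consistency(consistency_fixture()), 0.75)
  expect_equal(consistency(build_schema()), 1)
  expect_equal(consistency(phido:::triple_df()), 1)
})

test_that("comprehensiveness caps relative size at one", {
  fix <- consistency_fixture()       # 4 classes
  expect_equal(comprehensiveness(fix, reference_size = 4), 1)
  expect_equal(comprehensiveness(fix, reference_size = 400), 0.01)
  expect_equal(comprehensiveness(fix, reference_size = 2), 1)
  expect_equal(comprehensiveness(phido:::triple_df(), 100), 0)
  expect_error(comprehensiveness(fix, 0), "positive")
})

test_that("compose reproduces the published composite arithmetic", {
  # syntactic branch from its two sub-scores
  c1 <- compose_semiotic(lawfulness = 1.00, richness = 0.38,
                         semantic = 0.94, pragmatic = 0.00)
  expect_equal(c1$rounded$syntactic, 0.69)
  # overall from the three branch scores
  c2 <- compose_semiotic(syntactic = 0.69, semantic = 0.94, pragmatic = 0.00)
  expect_equal(c2$rounded$overall, 0.54)
  # identity ontology composes to 1 under default weights
  c3 <- compose_semiotic(lawfulness = 1, richness = 1, interpretability = 1,
                         consistency = 1, clarity = 1, comprehensiveness = 1)
  expect_equal(unlist(c3[c("syntactic", "semantic", "pragmatic",
                           "overall")]),
               c(syntactic = 1, semantic = 1, pragmatic = 1, overall = 1))
  expect_error(compose_semiotic(syntactic = 1.2, semantic = 0, pragmatic = 0),
               "\\[0, 1\\]")
  expect_error(compose_semiotic(lawfulness = 1, semantic = 1, pragmatic = 1),
               "richness")
})

test_that("compose is monotone non-decreasing in every sub-score", {
  set.seed(11)
  nm <- c("lawfulness", "richness", "interpretability", "consistency",
          "clarity", "comprehensiveness")
  for (rep in 1:20) {
    base <- as.list(setNames(runif(6), nm))
    o1 <- do.call(compose_semiotic, base)$overall
    k <- sample(6, 1)
    bumped <- base
    bumped[[k]] <- min(1, base[[k]] + runif(1, 0, 1 - base[[k]]))
    o2 <- do.call(compose_semiotic, bumped)$overall
    expect_gte(o2, o1 - 1e-12)
  }
})

test_that("z-scores standardize against a benchmark", {
  rep <- list(scores = list(overall = 0.54, lawfulness = 1))
  class(rep) <- "semiotic_report"
  z <- metric_zscores(rep, list(overall = list(mean = 0.54, sd = 0.2)))
  expect_equal(unname(z["overall"]), 0)
  z2 <- metric_zscores(rep, list(lawfulness = list(mean = 0.8, sd = 0.1)))
  expect_equal(unname(z2["lawfulness"]), 2)
  expect_length(metric_zscores(rep, list()), 0)
  expect_error(metric_zscores(rep, list(overall = list(mean = 0, sd = 0))),
               "positive")
})

test_that("the full report on the built schema is clean and recomposable", {
  rep <- semiotic_report(build_schema())
  s <- rep$scores
  expect_equal(s$lawfulness, 1)
  expect_equal(s$consistency, 1)
  expect_true(all(unlist(s) >= 0 & unlist(s) <= 1))
  recomposed <- compose_semiotic(
    lawfulness = s$lawfulness, richness = s$richness,
    interpretability = s$interpretability, consistency = s$consistency,
    clarity = s$clarity, comprehensiveness = s$comprehensiveness)
  expect_equal(recomposed$overall, s$overall)
  expect_equal(s$syntactic, mean(c(s$lawfulness, s$richness)))
  expect_equal(s$pragmatic, s$comprehensiveness)
  # the JSON report round-trips the raw numbers
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$scores$overall, s$overall)
})
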