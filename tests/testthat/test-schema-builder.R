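test_that("the built schema matches the published inventory", {
  s <- build_schema()
  expect_length(data_properties(s), 5)
  expect_setequal(names(data_properties(s)),
                  c("hasUtterancePriority", "hasUtteranceString",
                    "hasBeenSaid", "hasUtteranceExamples", "hasFocus"))
  expect_length(subclasses(s, "Participant Utterance"), 18)
  expect_length(subclasses(s, "System Utterance"), 29)
  # the four level roots, with Speech Task under Task and the two
  # utterance branches
  roots <- names(Filter(function(cl) length(cl$parents) == 0, s$classes))
  expect_setequal(roots, c("Discussion", "Goal", "Task", "Utterance"))
  expect_true("Speech Task" %in% subclasses(s, "Task"))
  kids <- names(Filter(function(cl) "Utterance" %in% cl$parents, s$classes))
  expect_setequal(kids, c("Participant Utterance", "System Utterance"))
  expect_setequal(subclasses(s, "Communication Goal"),
                  c("Acclimate", "Conclude", "Communicate Benefit",
                    "Communicate Effectiveness", "Communicate Harms",
                    "Communicate Uncertainty", "Pursuit Before Exit"))
  expect_true(all(c("Pleasantry Task", "Salutation", "Valediction",
                    "Proposition Task", "Initiate Discussion",
                    "Transition to Topic", "Interview Participant",
                    "Discuss Health Topic", "Question and Answering Task")
                  %in% subclasses(s, "Task")))
  expect_true("Health Information" %in% subclasses(s, "System Utterance"))
})

test_that("speech-act annotations match the printed tables", {
  s <- build_schema()
  act <- function(nm) s$classes[[nm]]$speech_act
  # both assertive and representative kept distinct, exactly as printed
  expect_equal(act("Participant Introduction"), "assertive")
  expect_equal(act("Confirmation"), "representative")
  expect_equal(act("Disconfirmation"), "expressive")
  expect_equal(act("Question"), "directive")
  expect_equal(act("Divergent Question"), "directive")
  expect_equal(act("Unintelligible"), "none")
  expect_equal(act("Prattle"), "none")
  expect_equal(act("Agenda"), "commissive")
  expect_equal(act("Topic Transition"), "commissive")
  expect_equal(act("Disclaimer"), "representative")
  expect_equal(act("Concluding Farewell"), "expressive")
  expect_equal(act("Interview Question"), "directive")
  expect_equal(act("System Introduction"), "representative")
  # multi-parent classes
  expect_setequal(s$classes[["Negative Personal Status"]]$parents,
                  c("Negative Utterance", "Personal Status"))
  expect_setequal(s$classes[["Positive Personal Status"]]$parents,
                  c("Personal Status", "Positive Utterance"))
})

test_that("property declarations carry the inverse/sub-property structure", {
  s <- build_schema()
  expect_equal(s$properties[["follows"]]$inverse_of, "precedes")
  expect_equal(s$properties[["precedes"]]$inverse_of, "follows")
  expect_true(s$properties[["utteranceLink"]]$symmetric)
  for (p in c("follows", "precedes", "speechSegue"))
    expect_equal(s$properties[[p]]$sub_property_of, "utteranceLink")
  expect_equal(s$properties[["belongsToSpeechTask"]]$inverse_of,
               "hasUtterance")
  expect_equal(s$properties[["hasUtterance"]]$inverse_of,
               "belongsToSpeechTask")
  expect_length(object_properties(s), 8)
})

test_that("validate_schema reports the rule and entity for each violation", {
  expect_identical(nrow(validate_schema(build_schema())), 0L)

  # self-inverse property
  s <- phido_schema(
    list(phido_class("Utterance")),
    list(phido_property("follows", "object", "Utterance", "Utterance",
                        inverse_of = "follows")))
  v <- validate_schema(s)
  expect_equal(nrow(v), 1L)
  expect_equal(v$rule, "inverse must be mutual and distinct")

  # one-sided inverse
  s2 <- phido_schema(
    list(phido_class("Utterance")),
    list(phido_property("follows", "object", "Utterance", "Utterance",
                        inverse_of = "precedes"),
         phido_property("precedes", "object", "Utterance", "Utterance")))
  expect_equal(validate_schema(s2)$rule, "inverse must be mutual and distinct")

  # hierarchy cycle A -> B -> A
  s3 <- phido_schema(list(phido_class("A", "B"), phido_class("B", "A")))
  expect_true("hierarchy cycle" %in% validate_schema(s3)$rule)

  # missing speech act on a leaf utterance class
  s4 <- phido_schema(list(phido_class("Utterance"),
                          phido_class("Participant Utterance", "Utterance"),
                          phido_class("Acceptance", "Participant Utterance",
                                      "none")))
  expect_true("missing speech act" %in% validate_schema(s4)$rule)

  expect_identical(nrow(validate_schema(phido_schema())), 0L)
})

test_that("cycle detection agrees with an independent DAG oracle", {
  skip_if_not_installed("igraph")
  set.seed(421)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    nodes <- paste0("C", seq_len(n))
    # random parent assignments, sometimes cyclic
    edges <- list()
    classes <- lapply(nodes, function(nd) {
      parents <- sample(setdiff(nodes, nd),
                        sample(0:min(2, n - 1), 1))
      for (p in parents) edges[[length(edges) + 1L]] <<- c(nd, p)
      phido_class(nd, parents)
    })
    s <- phido_schema(classes)
    has_cycle <- "hierarchy cycle" %in% validate_schema(s)$rule
    if (length(edges)) {
      g <- igraph::graph_from_edgelist(do.call(rbind, edges))
      expect_equal(has_cycle, !igraph::is_dag(g))
    } else {
      expect_false(has_cycle)
    }
  }
})

test_that("duplicate class names are rejected at construction", {
  expect_error(phido_schema(list(phido_class("A"), phido_class("A"))),
               "duplicate class name")
})
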