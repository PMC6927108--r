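# Shared fixtures, all built in code.

# a two-task script: salutation then valediction in one goal
two_task_script <- function() {
  as_dialogue_script(list(
    title = "two tasks",
    goals = list(list(goal = "Acclimate",
                      tasks = list(list(kind = "salutation"),
                                   list(kind = "valediction"))))))
}

# minimal discussion script: salutation, one discuss topic, valediction
mini_script <- function(items = 1L, answers = NULL) {
  discuss <- list(kind = "discuss_health_topic",
                  health_items = as.list(sprintf("Fact number %d about the vaccine.",
                                                 seq_len(items))))
  if (!is.null(answers)) discuss$answers <- answers
  as_dialogue_script(list(
    title = "mini",
    goals = list(
      list(goal = "Acclimate", tasks = list(list(kind = "salutation"))),
      list(goal = "Communicate Benefit", tasks = list(discuss)),
      list(goal = "Conclude", tasks = list(list(kind = "valediction"))))))
}

hpv_script_path <- function()
  system.file("extdata", "hpv_counseling.yaml", package = "phido")

# drive a session with a policy, checking the single-focus invariant after
# every step; returns the final state
run_checked <- function(session, policy, seed = policy$seed,
                        max_turns = 500L, tau = 0.5, retry_budget = 2L) {
  state <- dialogue_state(session, tau = tau, retry_budget = retry_budget)
  rng <- phido:::rng_stream(seed)
  budget <- policy$question_budget
  while (!state$ended && state$turn < max_turns) {
    state <- if (!is.null(state$awaiting)) {
      cands <- lapply(state$awaiting, function(i) session$instances[[i]])
      resp <- respond(policy, cands, rng, question_budget = budget)
      budget <- resp$question_budget
      step(state, resp$text)
    } else step(state)
    nfocus <- sum(vapply(state$session$instances, `[[`, logical(1), "focus"))
    expect_equal(nfocus, if (state$ended) 0L else 1L,
                 info = sprintf("focus count broke at turn %d", state$turn))
  }
  state
}

event_classes <- function(x) {
  ev <- if (inherits(x, "phido_transcript")) x$events else x$transcript
  vapply(ev, function(e) e$class %||% NA_character_, character(1))
}
event_kinds <- function(x) {
  ev <- if (inherits(x, "phido_transcript")) x$events else x$transcript
  vapply(ev, `[[`, character(1), "kind")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Turtle fixture with exactly 10 statements, one of them a profile
# violation (subclass axiom over an undeclared class)
lawfulness_fixture <- function() {
  paste(
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix : <http://example.org/fix#> .",
    ":A a owl:Class .",
    ":A rdfs:label \"Gene\" .",
    ":B a owl:Class .",
    ":B rdfs:label \"Blue\" .",
    ":B rdfs:subClassOf :A .",
    ":C a owl:Class .",
    ":C rdfs:label \"Cell\" .",
    ":C rdfs:subClassOf :Missing .",
    ":p a owl:ObjectProperty .",
    ":p rdfs:domain :A .",
    sep = "\n")
}

# four classes, one made unsatisfiable by a disjointness clash
consistency_fixture <- function() {
  paste(
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix : <http://example.org/fix#> .",
    ":A a owl:Class .",
    ":B a owl:Class .",
    ":C a owl:Class .",
    ":D a owl:Class .",
    ":B rdfs:subClassOf :A .",
    ":B owl:disjointWith :A .",
    sep = "\n")
}
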