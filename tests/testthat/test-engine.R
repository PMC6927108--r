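salutation_session <- function() link_tasks(two_task_script())

test_that("next_candidates follows priority then id, and segues when needed", {
  sess <- salutation_session()
  st <- dialogue_state(sess)
  # expected candidates after the opening greeting
  st2 <- step(st)
  cand_classes <- unname(vapply(st2$awaiting,
                                function(i) sess$instances[[i]]$class_name,
                                character(1)))
  expect_equal(cand_classes, c("Reciprocal Greet", "Unintelligible"))

  # brute-force ordering oracle on a synthetic candidate set
  sess2 <- sess
  fake <- names(sess$instances)[1:3]
  for (k in 1:3) sess2$instances[[fake[k]]]$priority <- c(2L, 0L, 1L)[k]
  sess2$edges <- rbind(sess2$edges,
                       data.frame(source = "hub", kind = "precedes",
                                  target = fake))
  sess2$instances$hub <- list(id = "hub", class_name = "Inform",
                              string = "x", examples = character(),
                              priority = 0L, been_said = FALSE, focus = FALSE)
  st3 <- dialogue_state(sess2); st3$focus_id <- "hub"
  got <- next_candidates(st3)
  pri <- vapply(fake, function(i) sess2$instances[[i]]$priority, integer(1))
  expect_equal(got, fake[order(pri, fake)])
})

test_that("a dangling focus is reported, a terminal farewell is not", {
  sess <- salutation_session()
  st <- dialogue_state(sess)
  st$focus_id <- names(Filter(function(i)
    i$class_name == "System Introduction", sess$instances))[1]
  # introduction segues onward: fine
  expect_length(next_candidates(st), 1)
  # strip the segue: dangling
  sess2 <- sess
  sess2$edges <- sess2$edges[sess2$edges$source != st$focus_id, ]
  st2 <- dialogue_state(sess2); st2$focus_id <- st$focus_id
  expect_error(next_candidates(st2), "dangling graph")
  st3 <- dialogue_state(sess)
  st3$focus_id <- names(Filter(function(i)
    i$class_name == "Concluding Farewell", sess$instances))[1]
  expect_length(next_candidates(st3), 0)
})

test_that("classification scores by token-set Jaccard with threshold tau", {
  sess <- salutation_session()
  st <- step(dialogue_state(sess))
  cands <- lapply(st$awaiting, function(i) sess$instances[[i]])
  # verbatim example: score 1
  res <- classify_input("hello", cands, sess$schema, tau = 0.5)
  expect_equal(res$matched_class, "Reciprocal Greet")
  expect_equal(res$score, 1)
  # disjoint-alphabet gibberish: zero overlap
  res2 <- classify_input("zzqx qqv", cands, sess$schema, tau = 0.5)
  expect_equal(res2$matched_class, "Unintelligible")
  expect_equal(res2$score, 0)
  # hand-computed 2-of-4-union-token case: |{hello, how} n ...| etc.
  # example "hello how are you" vs input "hello how": J = 2/4 = 0.5
  res3 <- classify_input("hello how", cands, sess$schema, tau = 0.5)
  expect_equal(res3$score, 0.5)
  expect_equal(res3$matched_class, "Reciprocal Greet")
  res4 <- classify_input("hello how", cands, sess$schema, tau = 0.51)
  expect_equal(res4$matched_class, "Unintelligible")
  # no participant candidates at all
  sys_only <- list(sess$instances[[names(Filter(function(i)
    i$class_name == "System Greet", sess$instances))[1]]])
  expect_error(classify_input("x", sys_only, sess$schema),
               "no expected participant utterance")
})

test_that("the salutation trace follows the golden sequence", {
  sess <- salutation_session()
  st <- dialogue_state(sess)
  st <- step(st)                 # greet
  st <- step(st, "hello")        # reciprocal greet
  st <- step(st)                 # introduction (+ segue)
  st <- step(st)                 # farewell
  st <- step(st, "goodbye")      # reciprocal farewell
  st <- step(st)                 # concluding farewell + end
  kinds <- event_kinds(st)
  classes <- event_classes(st)
  say <- classes[kinds == "system_say"]
  expect_equal(say, c("System Greet", "System Introduction",
                      "System Farewell", "Concluding Farewell"))
  expect_equal(classes[kinds == "classified_as"],
               c("Reciprocal Greet", "Reciprocal Farewell"))
  expect_equal(kinds[length(kinds)], "session_end")
  expect_true(st$ended)
  # stepping an ended session is an error
  expect_error(step(st), "already ended")
})

test_that("await/classify alternation is legal over a full run", {
  sess <- compile_script(hpv_script_path())
  tr <- run_session(sess, participant_policy("cooperative"), seed = 5,
                    max_turns = 400)
  kinds <- event_kinds(tr)
  prev <- c("", kinds[-length(kinds)])
  expect_true(all(prev[kinds == "classified_as"] == "await_input" |
                    prev[kinds == "classified_as"] == "segue"))
  aw <- which(kinds == "await_input")
  expect_true(all(kinds[aw - 1] %in% c("system_say", "segue")))
})

test_that("the retry automaton ends the session after the budget is spent", {
  sess <- salutation_session()
  # hand-traced: say, gib(1), say, gib(2), say, gib(3) -> end with budget 2
  st <- dialogue_state(sess, retry_budget = 2L)
  st <- step(st)
  st <- step(st, "zzqx qqvv")
  expect_equal(sum(event_kinds(st) == "repeat_requested"), 1)
  expect_false(st$ended)
  st <- step(st)                # request repeat spoken
  st <- step(st, "zzqx qqvv")
  st <- step(st)
  st <- step(st, "zzqx qqvv")
  kinds <- event_kinds(st)
  expect_equal(sum(kinds == "repeat_requested"), 3)
  expect_true(st$ended)
  expect_equal(kinds[length(kinds)], "session_end")
  # budget 0: first gibberish ends the session
  st0 <- step(dialogue_state(sess, retry_budget = 0L))
  st0 <- step(st0, "zzqx")
  expect_true(st0$ended)
})

test_that("input is rejected when the system holds the focus", {
  sess <- salutation_session()
  expect_error(step(dialogue_state(sess), "hello"), "System Utterance")
})

test_that("hasBeenSaid is monotone and focus stays unique over random runs", {
  set.seed(99)
  for (rep in 1:4) {
    sc <- generate_script(n_goals = sample(2:7, 1),
                          items_per_topic = sample(1:2, 1), seed = rep)
    sess <- link_tasks(sc)
    persona <- sample(c("cooperative", "repeater", "confused", "questioner",
                        "refuser"), 1)
    state <- dialogue_state(sess)
    rng <- phido:::rng_stream(rep)
    pol <- participant_policy(persona, seed = rep)
    budget <- pol$question_budget
    said_before <- character()
    while (!state$ended && state$turn < 300) {
      state <- if (!is.null(state$awaiting)) {
        cands <- lapply(state$awaiting, function(i) sess$instances[[i]])
        resp <- respond(pol, cands, rng, budget)
        budget <- resp$question_budget
        step(state, resp$text)
      } else step(state)
      said_now <- names(Filter(function(i) i$been_said,
                               state$session$instances))
      expect_true(all(said_before %in% said_now))
      said_before <- said_now
      expect_equal(sum(vapply(state$session$instances, `[[`, logical(1),
                              "focus")),
                   if (state$ended) 0L else 1L)
    }
  }
})

test_that("questions detour through answering and resume the discussion", {
  ans <- list("how long does protection last" = "More than ten years.")
  sc <- mini_script(items = 2, answers = ans)
  # give the goal an explicit QA task sharing the answers
  sc$goals[[2]]$tasks <- c(sc$goals[[2]]$tasks,
                           list(list(kind = "question_answering",
                                     content = list(answers = ans))))
  sess <- link_tasks(sc)
  tr <- run_session(sess, participant_policy("questioner",
                                             question_budget = 1, seed = 3),
                    max_turns = 300)
  kinds <- event_kinds(tr); classes <- event_classes(tr)
  expect_true(tr$ended)
  said <- classes[kinds == "system_say"]
  expect_true("Answer" %in% said)          # the mapped answer was spoken
  expect_equal(sum(classes == "Question" & kinds == "classified_as"), 1)
  # both health facts still delivered after the detour
  expect_equal(sum(said == "Health Information"), 2)
  expect_equal(said[length(said)], "Concluding Farewell")
})

test_that("transcripts are reproducible and bounded by max_turns", {
  sess <- compile_script(hpv_script_path())
  a <- run_session(sess, participant_policy("refuser", seed = 4),
                   max_turns = 400)
  b <- run_session(sess, participant_policy("refuser", seed = 4),
                   max_turns = 400)
  expect_identical(a$events, b$events)
  one <- run_session(sess, participant_policy("cooperative"), seed = 1,
                     max_turns = 1)
  expect_equal(one$turns, 1L)
  expect_false(one$ended)
  expect_true(all(vapply(one$events, `[[`, numeric(1), "turn") == 1))
})

test_that("transcripts serialize to one JSON event per line", {
  sess <- salutation_session()
  tr <- run_session(sess, participant_policy("cooperative"), seed = 2,
                    max_turns = 50)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transcript(tr, path)
  lines <- readLines(path)
  expect_length(lines, length(tr$events))
  ev <- jsonlite::fromJSON(lines[1])
  expect_setequal(names(ev), c("turn", "kind", "id", "class", "text"))
  expect_equal(ev$kind, "system_say")
})
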