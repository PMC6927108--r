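test_that("scripts load from YAML and JSON with validation", {
  sc <- load_script(hpv_script_path())
  expect_s3_class(sc, "dialogue_script")
  expect_length(sc$goals, 7)
  expect_equal(vapply(sc$goals, `[[`, character(1), "kind"),
               c("Acclimate", "Communicate Benefit",
                 "Communicate Effectiveness", "Communicate Harms",
                 "Communicate Uncertainty", "Pursuit Before Exit",
                 "Conclude"))
  # JSON round-trips through write_script
  json <- write_script(sc, format = "json")
  expect_equal(load_script(json, format = "json")$goals, sc$goals)

  minimal <- as_dialogue_script(list(goals = list(list(
    goal = "Communicate Benefit",
    tasks = list(list(kind = "discuss_health_topic",
                      health_items = list("One fact.")))))))
  expect_s3_class(minimal, "dialogue_script")
})

test_that("script ordering and content rules are enforced with paths", {
  bad_val_first <- list(goals = list(list(
    goal = "Conclude",
    tasks = list(list(kind = "valediction"), list(kind = "salutation")))))
  expect_error(as_dialogue_script(bad_val_first),
               "must be the (first|last) task")

  expect_error(as_dialogue_script(list(goals = list())), "at least one goal")
  expect_error(as_dialogue_script(list(goals = list(list(
    goal = "Acclimate", tasks = list())))), "at least one task")
  err <- tryCatch(as_dialogue_script(list(goals = list(list(
    goal = "Acclimate", tasks = list(list(kind = "lecture")))))),
    error = function(e) conditionMessage(e))
  expect_match(err, "goals\\[1\\].tasks\\[1\\]")
  expect_match(err, "salutation.*question_answering")
  expect_error(as_dialogue_script(list(goals = list(list(
    goal = "Communicate Benefit",
    tasks = list(list(kind = "discuss_health_topic")))))),
    "at least one health item")
  expect_error(as_dialogue_script(list(goals = list(list(
    goal = "Chat", tasks = list(list(kind = "salutation")))))),
    "unknown goal kind")
})

# expected class multiset and class-level edges per template (golden)
template_golden <- list(
  salutation = list(
    classes = c("System Greet", "Reciprocal Greet", "Unintelligible",
                "Request Repeat", "System Introduction"),
    edges = c("System Greet>Reciprocal Greet", "System Greet>Unintelligible",
              "Unintelligible>Request Repeat",
              "Request Repeat>Reciprocal Greet",
              "Request Repeat>Unintelligible",
              "Reciprocal Greet>System Introduction")),
  valediction = list(
    classes = c("System Farewell", "Reciprocal Farewell", "Unintelligible",
                "Request Repeat", "Concluding Farewell"),
    edges = c("System Farewell>Reciprocal Farewell",
              "System Farewell>Unintelligible",
              "Unintelligible>Request Repeat",
              "Request Repeat>Reciprocal Farewell",
              "Request Repeat>Unintelligible",
              "Reciprocal Farewell>Concluding Farewell")),
  initiate_discussion = list(
    classes = c("Disclaimer", "Confirmation", "Unintelligible",
                "Request Repeat", "Overview", "Topic Options"),
    edges = c("Disclaimer>Confirmation", "Disclaimer>Unintelligible",
              "Unintelligible>Request Repeat", "Request Repeat>Confirmation",
              "Request Repeat>Unintelligible", "Confirmation>Overview",
              "Overview>Topic Options")),
  transition_to_topic = list(
    classes = c("Topic Transition", "Confirmation", "Disconfirmation",
                "Unintelligible", "Request Repeat"),
    edges = c("Topic Transition>Confirmation",
              "Topic Transition>Disconfirmation",
              "Topic Transition>Unintelligible",
              "Unintelligible>Request Repeat", "Request Repeat>Confirmation",
              "Request Repeat>Disconfirmation",
              "Request Repeat>Unintelligible")))

test_that("template fragments match their golden class multisets and edges", {
  for (kind in names(template_golden)) {
    frag <- instantiate_task(kind, list(), id_prefix = "t")
    got_classes <- sort(unname(vapply(frag$instances, `[[`, character(1),
                                      "class_name")))
    expect_equal(got_classes, sort(template_golden[[kind]]$classes),
                 info = kind)
    cls <- function(id) frag$instances[[id]]$class_name
    got_edges <- sort(sprintf("%s>%s",
                              unname(vapply(frag$edges$source, cls,
                                            character(1))),
                              unname(vapply(frag$edges$target, cls,
                                            character(1)))))
    expect_equal(got_edges, sort(template_golden[[kind]]$edges), info = kind)
    # single system entry, no utterance marked said at build time
    expect_false(any(vapply(frag$instances, `[[`, logical(1), "been_said")))
  }
})

test_that("discuss_health_topic chains one block per health item", {
  frag <- instantiate_task("discuss_health_topic",
                           list(health_items = list("a", "b", "c")), "d")
  classes <- vapply(frag$instances, `[[`, character(1), "class_name")
  expect_equal(sum(classes == "Health Information"), 3)
  expect_equal(sum(classes == "Confirm Health Information"), 3)
  expect_equal(sum(classes == "Question"), 3)
  expect_length(frag$disconfirms, 3)
  # expected candidate set after each confirm prompt
  chi <- names(classes)[classes == "Confirm Health Information"][1]
  after <- frag$edges$target[frag$edges$source == chi]
  expect_setequal(vapply(after, function(i) frag$instances[[i]]$class_name,
                         character(1)),
                  c("Confirmation", "Request System Repeat", "Question",
                    "Disconfirmation", "Unintelligible"))
  # Request System Repeat replays the same health fact
  rsr <- names(classes)[classes == "Request System Repeat"][1]
  hi1 <- names(classes)[classes == "Health Information"][1]
  expect_true(any(frag$edges$source == rsr & frag$edges$target == hi1))
})

test_that("question_answering routes every question to No Answer when no answers exist", {
  frag <- instantiate_task("question_answering", list(answers = list()), "q")
  classes <- vapply(frag$instances, `[[`, character(1), "class_name")
  expect_equal(sum(classes == "Answer"), 0)
  expect_equal(sum(classes == "No Answer"), 1)
  qq <- names(classes)[classes == "Question"][1]
  after <- vapply(frag$edges$target[frag$edges$source == qq],
                  function(i) frag$instances[[i]]$class_name, character(1))
  expect_true(all(after == "No Answer"))
})

test_that("missing content slots name the slot and kind", {
  expect_error(instantiate_task("interview_participant", list(), "t"),
               "interview_questions")
  expect_error(instantiate_task("discuss_health_topic", list(), "t"),
               "health_items")
  expect_error(instantiate_task("lecture", list(), "t"), "unknown task kind")
})

test_that("link_tasks wires the happy path, focus and segues", {
  sess <- link_tasks(two_task_script())
  seg <- sess$edges[sess$edges$kind == "speechSegue", ]
  expect_equal(nrow(seg), 1L)
  expect_equal(sess$instances[[seg$source]]$class_name,
               "System Introduction")
  expect_equal(sess$instances[[seg$target]]$class_name, "System Farewell")
  focus <- vapply(sess$instances, `[[`, logical(1), "focus")
  expect_equal(sum(focus), 1L)
  expect_equal(sess$instances[[names(which(focus))]]$class_name,
               "System Greet")
  expect_false(any(vapply(sess$instances, `[[`, logical(1), "been_said")))
  # every instance belongs to exactly one task
  expect_setequal(names(sess$task_membership), names(sess$instances))
})

test_that("disconfirmation sites segue to the pursuit goal's first task", {
  sess <- compile_script(hpv_script_path())
  pursuit_tasks <- names(Filter(function(t)
    sess$goals[[t$goal_id]]$kind == "Pursuit Before Exit", sess$tasks))
  pursuit_members <- names(sess$task_membership)[
    sess$task_membership %in% pursuit_tasks]
  pursuit_entry_class <- "Topic Transition"
  dcs <- names(Filter(function(i) i$class_name == "Disconfirmation",
                      sess$instances))
  outside <- setdiff(dcs, pursuit_members)
  qa_tasks <- names(Filter(function(t) t$kind == "question_answering",
                           sess$tasks))
  outside <- outside[!sess$task_membership[outside] %in% qa_tasks]
  for (dc in outside) {
    tgt <- sess$edges$target[sess$edges$source == dc &
                             sess$edges$kind == "speechSegue"]
    expect_length(tgt, 1)
    expect_true(sess$task_membership[[tgt]] %in% pursuit_tasks)
    expect_equal(sess$instances[[tgt]]$class_name, pursuit_entry_class)
  }
  # refusing inside the pursuit task capitulates instead of looping
  inside <- intersect(dcs, pursuit_members)
  for (dc in inside) {
    nxt <- sess$edges$target[sess$edges$source == dc &
                             sess$edges$kind == "precedes"]
    expect_equal(sess$instances[[nxt]]$class_name, "Capitulate")
  }
})

test_that("follows/precedes inverse closure holds by exhaustive check", {
  sess <- compile_script(hpv_script_path())
  expect_lte(length(sess$instances), 200)
  pe <- sess$edges[sess$edges$kind == "precedes", ]
  fe <- follows_edges(sess)
  ids <- names(sess$instances)
  for (a in ids) {
    prec_of_a <- sort(pe$target[pe$source == a])
    foll_back <- sort(fe$source[fe$target == a])
    expect_equal(prec_of_a, foll_back, info = a)
  }
  expect_equal(nrow(pe), nrow(fe))
})

test_that("sessions round-trip through both serializations", {
  sess <- link_tasks(mini_script(items = 2,
                                 answers = list("how long" = "Ten years.")))
  for (dial in c("turtle", "rdfxml")) {
    back <- load_session(serialize_session(sess, dialect = dial))
    expect_true(session_equal(sess, back), info = dial)
  }
  # independent XML-level triple count agrees with the in-memory count
  xml <- serialize_session(sess, dialect = "rdfxml")
  stmts <- xml2::xml_find_all(
    xml2::read_xml(xml), "/rdf:RDF/rdf:Description/*",
    ns = c(rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#"))
  expect_length(stmts, nrow(phido:::session_to_triples(sess)))
})

test_that("loading a session with a dangling edge target fails", {
  sess <- link_tasks(two_task_script())
  txt <- serialize_session(sess, dialect = "turtle")
  broken <- paste0(txt, sprintf(
    "\n<https://w3id.org/phido/session#%s>\n    <https://w3id.org/phido#precedes> <https://w3id.org/phido/session#ghost> .\n",
    sess$entry))
  expect_error(load_session(broken), "unknown instance")
})
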