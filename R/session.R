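# Session graphs (A-Box): utterance instances wired by `precedes` edges
# inside a speech task and `speechSegue` edges between tasks. The seven
# task templates below are the normative reconstruction of the speech-task
# flows; their node-class multisets and edge sets are frozen as golden
# fixtures in the test suite.

DEFAULT_EXAMPLES <- list(
  "Reciprocal Greet" = c("hello", "hi there", "hello how are you",
                         "good morning"),
  "Reciprocal Farewell" = c("goodbye", "bye bye", "see you later",
                            "goodbye and thank you"),
  "Confirmation" = c("yes", "yes i understand", "okay got it",
                     "sure that makes sense"),
  "Disconfirmation" = c("no", "i disagree", "no i do not want that",
                        "i am not interested"),
  "Request System Repeat" = c("can you repeat that",
                              "please say that again", "repeat that please"),
  "Question" = c("i have a question", "can i ask a question",
                 "what about the vaccine"),
  "Positive Personal Status" = c("i am doing well", "i feel great today",
                                 "doing fine thanks"),
  "Negative Personal Status" = c("i am not doing well", "i feel bad today",
                                 "not so great"),
  "Unintelligible" = "(unintelligible)"
)

DEFAULT_STRINGS <- list(
  greeting = "Hello! How are you today?",
  introduction = paste("I am a counseling assistant here to talk with you",
                       "about the HPV vaccine."),
  farewell = "That is everything I had for today. Goodbye!",
  concluding_farewell = "Take care, and talk to your provider soon. Goodbye.",
  request_repeat = "I'm sorry, I didn't catch that. Could you repeat it?",
  disclaimer = paste("Please note I may not cover every concern; ask your",
                     "health care provider about anything I cannot answer."),
  overview = "Today we will talk about the HPV vaccine and what it does.",
  topic_options = "We can discuss benefits, effectiveness, or side effects.",
  transition = "Let's move on to the next topic.",
  confirm_health_information = "Does that make sense to you?",
  acknowledgment = "Thank you, I appreciate you sharing that.",
  no_answer = paste("I don't have an answer for that one; please ask your",
                    "health care provider."),
  question_options = "Do you have any more questions?",
  capitulate = "I understand. We can stop here if you prefer."
)

# ---- fragment construction --------------------------------------------------

new_fragment <- function() {
  env <- new.env(parent = emptyenv())
  env$instances <- list(); env$edges <- list()
  env$counter <- 0L
  env
}

frag_inst <- function(frag, prefix, class_name, string = NA_character_,
                      examples = character(), priority = 0L) {
  frag$counter <- frag$counter + 1L
  id <- sprintf("%s_u%02d_%s", prefix, frag$counter,
                camel_fragment(class_name))
  frag$instances[[id]] <- list(id = id, class_name = class_name,
                               string = string,
                               examples = as.character(examples),
                               priority = as.integer(priority),
                               been_said = FALSE, focus = FALSE)
  id
}

frag_edge <- function(frag, from, to, kind = "precedes")
  frag$edges[[length(frag$edges) + 1L]] <- list(source = from, kind = kind,
                                                target = to)

examples_for <- function(class_name, content) {
  ov <- content$examples[[class_name]]
  if (!is.null(ov)) return(as.character(unlist(ov)))
  DEFAULT_EXAMPLES[[class_name]] %||%
    stop_phido(sprintf("no utterance examples available for class '%s'",
                       class_name), "phido_template_error")
}

slot <- function(content, name, default = NULL) {
  v <- content[[name]] %||% default
  if (is.null(v))
    stop_phido(sprintf("task content is missing required slot '%s'", name),
               "phido_template_error")
  v
}

# Unintelligible fallback + Request Repeat loop shared by all templates:
# wires src -> {candidates..., Unintelligible}; Unintelligible -> Request
# Repeat -> {candidates..., Unintelligible} and returns the repeat node id.
add_retry_loop <- function(frag, prefix, content, src, candidate_ids) {
  un <- frag_inst(frag, prefix, "Unintelligible",
                  examples = examples_for("Unintelligible", content),
                  priority = 9L)
  rr <- frag_inst(frag, prefix, "Request Repeat",
                  string = slot(content, "request_repeat",
                                DEFAULT_STRINGS$request_repeat))
  for (cand in candidate_ids) frag_edge(frag, src, cand)
  frag_edge(frag, src, un)
  frag_edge(frag, un, rr)
  for (cand in candidate_ids) frag_edge(frag, rr, cand)
  frag_edge(frag, rr, un)
  rr
}

#' Instantiate one speech-task template
#'
#' Builds the utterance subgraph for a task kind, filled with the content
#' slots. Edges are `precedes` unless recorded in the fragment's special
#' roles (Disconfirmation exits, Question exits, terminal exits), which
#' [link_tasks()] turns into `speechSegue` wiring.
#'
#' @param kind one of the seven task kinds (see `TASK_KINDS`).
#' @param content named list of content slots for the kind.
#' @param id_prefix string prefixed to every generated instance id.
#' @return a list with `instances`, `edges`, `entry`, `exits`,
#'   `disconfirms`, `questions` (with per-site resume targets) and
#'   `task_class` (the speech-task class the fragment instantiates).
#' @export
instantiate_task <- function(kind, content = list(), id_prefix = "t") {
  frag <- new_fragment()
  entry <- NULL; exits <- character()
  disconfirms <- character()
  questions <- list()   # question node id -> resume id or "EXIT"
  task_class <- switch(kind,
    salutation = "Salutation", valediction = "Valediction",
    initiate_discussion = "Initiate Discussion",
    transition_to_topic = "Transition to Topic",
    interview_participant = "Interview Participant",
    discuss_health_topic = "Discuss Health Topic",
    question_answering = "Question and Answering Task",
    stop_phido(sprintf("unknown task kind '%s'; allowed: %s", kind,
                       paste(TASK_KINDS, collapse = ", ")),
               "phido_template_error"))

  if (kind == "salutation") {
    g <- frag_inst(frag, id_prefix, "System Greet",
                   string = slot(content, "greeting", DEFAULT_STRINGS$greeting))
    rg <- frag_inst(frag, id_prefix, "Reciprocal Greet",
                    examples = examples_for("Reciprocal Greet", content))
    add_retry_loop(frag, id_prefix, content, g, rg)
    si <- frag_inst(frag, id_prefix, "System Introduction",
                    string = slot(content, "introduction",
                                  DEFAULT_STRINGS$introduction))
    frag_edge(frag, rg, si)
    entry <- g; exits <- si

  } else if (kind == "valediction") {
    sf <- frag_inst(frag, id_prefix, "System Farewell",
                    string = slot(content, "farewell",
                                  DEFAULT_STRINGS$farewell))
    rf <- frag_inst(frag, id_prefix, "Reciprocal Farewell",
                    examples = examples_for("Reciprocal Farewell", content))
    add_retry_loop(frag, id_prefix, content, sf, rf)
    cf <- frag_inst(frag, id_prefix, "Concluding Farewell",
                    string = slot(content, "concluding_farewell",
                                  DEFAULT_STRINGS$concluding_farewell))
    frag_edge(frag, rf, cf)
    entry <- sf   # Concluding Farewell is terminal: no exits

  } else if (kind == "initiate_discussion") {
    d <- frag_inst(frag, id_prefix, "Disclaimer",
                   string = slot(content, "disclaimer",
                                 DEFAULT_STRINGS$disclaimer))
    conf <- frag_inst(frag, id_prefix, "Confirmation",
                      examples = examples_for("Confirmation", content))
    add_retry_loop(frag, id_prefix, content, d, conf)
    ov <- frag_inst(frag, id_prefix, "Overview",
                    string = slot(content, "overview",
                                  DEFAULT_STRINGS$overview))
    topts <- unlist(content$topic_options, use.names = FALSE)
    to <- frag_inst(frag, id_prefix, "Topic Options",
                    string = if (length(topts))
                      paste("We can talk about:",
                            paste(topts, collapse = "; "))
                    else DEFAULT_STRINGS$topic_options)
    frag_edge(frag, conf, ov); frag_edge(frag, ov, to)
    entry <- d; exits <- to

  } else if (kind == "transition_to_topic") {
    tt <- frag_inst(frag, id_prefix, "Topic Transition",
                    string = slot(content, "transition",
                                  DEFAULT_STRINGS$transition))
    conf <- frag_inst(frag, id_prefix, "Confirmation",
                      examples = examples_for("Confirmation", content))
    dc <- frag_inst(frag, id_prefix, "Disconfirmation",
                    examples = examples_for("Disconfirmation", content),
                    priority = 1L)
    rr <- add_retry_loop(frag, id_prefix, content, tt, conf)
    frag_edge(frag, tt, dc); frag_edge(frag, rr, dc)
    entry <- tt; exits <- conf; disconfirms <- dc

  } else if (kind == "interview_participant") {
    qs <- as.character(unlist(slot(content, "interview_questions"),
                              use.names = FALSE))
    prev_ack <- NULL
    for (k in seq_along(qs)) {
      iq <- frag_inst(frag, id_prefix, "Interview Question", string = qs[[k]])
      if (!is.null(prev_ack)) frag_edge(frag, prev_ack, iq)
      pps <- frag_inst(frag, id_prefix, "Positive Personal Status",
                       examples = examples_for("Positive Personal Status",
                                               content))
      nps <- frag_inst(frag, id_prefix, "Negative Personal Status",
                       examples = examples_for("Negative Personal Status",
                                               content), priority = 1L)
      add_retry_loop(frag, id_prefix, content, iq, c(pps, nps))
      ack <- frag_inst(frag, id_prefix, "Acknowledgment",
                       string = slot(content, "acknowledgment",
                                     DEFAULT_STRINGS$acknowledgment))
      frag_edge(frag, pps, ack); frag_edge(frag, nps, ack)
      if (k == 1L) entry <- iq
      prev_ack <- ack
    }
    exits <- prev_ack

  } else if (kind == "discuss_health_topic") {
    items <- as.character(unlist(slot(content, "health_items"),
                                 use.names = FALSE))
    answers <- content$answers %||% list()
    q_examples <- unique(c(names(answers),
                           examples_for("Question", content)))
    his <- character(length(items)); confs <- character(length(items))
    qqs <- character(length(items))
    for (k in seq_along(items)) {
      hi <- frag_inst(frag, id_prefix, "Health Information",
                      string = items[[k]])
      chi <- frag_inst(frag, id_prefix, "Confirm Health Information",
                       string = slot(content, "confirm_prompt",
                                     DEFAULT_STRINGS$confirm_health_information))
      frag_edge(frag, hi, chi)
      conf <- frag_inst(frag, id_prefix, "Confirmation",
                        examples = examples_for("Confirmation", content))
      rsr <- frag_inst(frag, id_prefix, "Request System Repeat",
                       examples = examples_for("Request System Repeat",
                                               content), priority = 1L)
      qq <- frag_inst(frag, id_prefix, "Question", examples = q_examples,
                      priority = 2L)
      dc <- frag_inst(frag, id_prefix, "Disconfirmation",
                      examples = examples_for("Disconfirmation", content),
                      priority = 3L)
      rr <- add_retry_loop(frag, id_prefix, content, chi,
                           c(conf, rsr, qq, dc))
      frag_edge(frag, rsr, hi)      # replay the same health fact
      his[k] <- hi; confs[k] <- conf; qqs[k] <- qq
      disconfirms <- c(disconfirms, dc)
      if (k == 1L) entry <- hi
    }
    for (k in seq_along(items)) {
      resume <- if (k < length(items)) his[k + 1L] else "EXIT"
      if (k < length(items)) frag_edge(frag, confs[k], his[k + 1L])
      questions[[qqs[k]]] <- resume
    }
    exits <- confs[length(items)]

  } else if (kind == "question_answering") {
    answers <- content$answers %||% list()
    q_examples <- unique(c(names(answers),
                           examples_for("Question", content)))
    qq <- frag_inst(frag, id_prefix, "Question", examples = q_examples)
    for (j in seq_along(answers))
      frag_edge(frag, qq,
                frag_inst(frag, id_prefix, "Answer",
                          string = as.character(answers[[j]]),
                          examples = names(answers)[j],
                          priority = j - 1L))
    na_ <- frag_inst(frag, id_prefix, "No Answer",
                     string = slot(content, "no_answer",
                                   DEFAULT_STRINGS$no_answer),
                     priority = length(answers))
    frag_edge(frag, qq, na_)
    qopt <- frag_inst(frag, id_prefix, "Question Options",
                      string = slot(content, "question_options",
                                    DEFAULT_STRINGS$question_options))
    for (ans in setdiff(names(frag$instances), qq))
      if (frag$instances[[ans]]$class_name %in% c("Answer", "No Answer"))
        frag_edge(frag, ans, qopt)
    dc <- frag_inst(frag, id_prefix, "Disconfirmation",
                    examples = examples_for("Disconfirmation", content),
                    priority = 1L)
    rr <- add_retry_loop(frag, id_prefix, content, qopt, qq)
    frag_edge(frag, qopt, dc); frag_edge(frag, rr, dc)
    entry <- qq; exits <- dc
  }

  list(instances = frag$instances,
       edges = if (length(frag$edges)) do.call(rbind, lapply(frag$edges,
                 as.data.frame)) else
                 data.frame(source = character(), kind = character(),
                            target = character()),
       entry = entry, exits = exits, disconfirms = disconfirms,
       questions = questions, task_class = task_class)
}

# ---- linking ----------------------------------------------------------------

#' Compile a dialogue script into a session graph
#'
#' Instantiates every task template and wires the fragments with
#' `speechSegue` edges: on-path tasks chain in script order; tasks inside a
#' Pursuit Before Exit goal and question-answering tasks sit off-path,
#' reachable through Disconfirmation and Question segues. Each
#' Disconfirmation/Question site records a resume target so the engine can
#' return after the detour. The initial focus is placed on the first system
#' utterance of the first task.
#'
#' @param script a `dialogue_script` (see [load_script()]).
#' @param schema the ontology schema instances must conform to.
#' @return a `phido_session`.
#' @export
link_tasks <- function(script, schema = build_schema()) {
  goals <- list(); tasks <- list(); instances <- list()
  edges <- list(); membership <- character()
  frag_meta <- list()

  for (gi in seq_along(script$goals)) {
    g <- script$goals[[gi]]
    gid <- sprintf("goal_%d_%s", gi, camel_fragment(g$kind))
    goals[[gid]] <- list(id = gid, kind = g$kind,
                         discussion_id = "discussion_1")
    for (ti in seq_along(g$tasks)) {
      t <- g$tasks[[ti]]
      tid <- sprintf("g%d_t%d_%s", gi, ti, t$kind)
      frag <- instantiate_task(t$kind, t$content, id_prefix = tid)
      tasks[[tid]] <- list(id = tid, kind = t$kind,
                           class_name = frag$task_class, goal_id = gid)
      instances <- c(instances, frag$instances)
      if (nrow(frag$edges)) edges[[length(edges) + 1L]] <- frag$edges
      membership[names(frag$instances)] <- tid
      frag_meta[[tid]] <- frag
    }
  }

  task_ids <- names(tasks)
  goal_kind_of <- function(tid) goals[[tasks[[tid]]$goal_id]]$kind
  off_path <- vapply(task_ids, function(tid)
    goal_kind_of(tid) == "Pursuit Before Exit" ||
      tasks[[tid]]$kind == "question_answering", logical(1))
  on_path <- task_ids[!off_path]

  add_edge <- function(from, kind, to)
    edges[[length(edges) + 1L]] <<- data.frame(source = from, kind = kind,
                                               target = to)

  val_task <- task_ids[vapply(task_ids, function(tid)
    tasks[[tid]]$kind == "valediction", logical(1))]
  val_entry <- if (length(val_task)) frag_meta[[val_task[1]]]$entry else NULL

  # happy-path chain and per-task exit target (used as resume addresses)
  exit_target <- character()
  for (k in seq_along(on_path)) {
    tid <- on_path[k]
    nxt <- if (k < length(on_path)) frag_meta[[on_path[k + 1L]]]$entry
           else val_entry   # NULL when the script has no valediction
    is_val <- length(val_task) > 0L && tid == val_task[1]
    if (!is.null(nxt) && !is_val) {
      exit_target[tid] <- nxt
      for (ex in frag_meta[[tid]]$exits)
        if (length(ex)) add_edge(ex, "speechSegue", nxt)
    }
  }
  for (tid in task_ids[off_path]) {
    ex_t <- val_entry %||% frag_meta[[tid]]$entry
    if (!is.null(ex_t)) exit_target[tid] <- ex_t
  }

  pursuit_tasks <- task_ids[vapply(task_ids, function(tid)
    goal_kind_of(tid) == "Pursuit Before Exit", logical(1))]
  pursuit_entry <- if (length(pursuit_tasks))
    frag_meta[[pursuit_tasks[1]]]$entry else NULL

  resume <- character(); return_exits <- character()

  for (tid in task_ids) {
    frag <- frag_meta[[tid]]
    in_pursuit <- goal_kind_of(tid) == "Pursuit Before Exit"
    et <- function(tid) {
      v <- exit_target[tid]
      if (length(v) == 0L || is.na(v)) val_entry else unname(v)
    }
    res_of <- function(raw) if (identical(raw, "EXIT")) et(tid) else raw

    for (dc in frag$disconfirms) {
      if (in_pursuit) {
        # a second refusal: capitulate, then head for the farewell
        cap_id <- paste0(tid, "_u99_Capitulate")
        instances[[cap_id]] <- list(id = cap_id, class_name = "Capitulate",
                                    string = DEFAULT_STRINGS$capitulate,
                                    examples = character(), priority = 0L,
                                    been_said = FALSE, focus = FALSE)
        membership[cap_id] <- tid
        add_edge(dc, "precedes", cap_id)
        if (!is.null(val_entry)) add_edge(cap_id, "speechSegue", val_entry)
      } else if (!is.null(pursuit_entry)) {
        add_edge(dc, "speechSegue", pursuit_entry)
        rt <- et(tid)
        if (!is.null(rt)) resume[dc] <- rt
      } else if (!is.null(val_entry)) {
        add_edge(dc, "speechSegue", val_entry)
      }
    }
    if (in_pursuit || tasks[[tid]]$kind == "question_answering") {
      for (ex in frag$exits) {
        return_exits <- c(return_exits, ex)
        fb <- et(tid)
        if (!is.null(fb)) add_edge(ex, "speechSegue", fb)
      }
    }
    # Question sites route to a question-answering task in the same goal
    if (length(frag$questions)) {
      gid <- tasks[[tid]]$goal_id
      qa_in_goal <- task_ids[vapply(task_ids, function(x)
        tasks[[x]]$kind == "question_answering" &&
          tasks[[x]]$goal_id == gid, logical(1))]
      qa_entry <- if (length(qa_in_goal)) frag_meta[[qa_in_goal[1]]]$entry
                  else NULL
      for (qn in names(frag$questions)) {
        if (!is.null(qa_entry)) {
          add_edge(qn, "speechSegue", qa_entry)
          resume[qn] <- res_of(frag$questions[[qn]])
        } else if (!is.null(val_entry)) {
          add_edge(qn, "speechSegue", res_of(frag$questions[[qn]]))
        }
      }
    }
  }

  entry <- frag_meta[[task_ids[1]]]$entry
  instances[[entry]]$focus <- TRUE
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(source = character(), kind = character(),
               target = character())
  rownames(edges) <- NULL

  session <- structure(list(
    title = script$title,
    instances = instances,
    edges = edges,
    task_membership = membership,
    tasks = tasks, goals = goals,
    discussion_id = "discussion_1",
    entry = entry,
    resume = resume, return_exits = unique(return_exits),
    schema = schema), class = "phido_session")
  check_session(session)
  session
}

#' @rdname link_tasks
#' @param x path to a script document, document text, or `dialogue_script`.
#' @param ... passed to [load_script()].
#' @export
compile_script <- function(x, schema = build_schema(), ...) {
  script <- if (inherits(x, "dialogue_script")) x else load_script(x, ...)
  link_tasks(script, schema)
}

check_session <- function(session) {
  ids <- names(session$instances)
  for (inst in session$instances) {
    if (!inst$class_name %in% names(session$schema$classes) ||
        !is_utterance_class(session$schema, inst$class_name))
      stop_phido(sprintf(
        "instance '%s' references unknown utterance class '%s'",
        inst$id, inst$class_name), "phido_session_error")
    if (is_system_class(session$schema, inst$class_name) &&
        (is.na(inst$string) || !nzchar(inst$string)))
      stop_phido(sprintf(
        "system utterance instance '%s' has empty hasUtteranceString",
        inst$id), "phido_session_error")
  }
  dangling <- setdiff(c(session$edges$source, session$edges$target), ids)
  if (length(dangling))
    stop_phido(sprintf("edge references unknown instance(s): %s",
                       paste(dangling, collapse = ", ")),
               "phido_session_error")
  nfocus <- sum(vapply(session$instances, `[[`, logical(1), "focus"))
  if (nfocus != 1L)
    stop_phido(sprintf("session must start with exactly 1 focused instance, found %d",
                       nfocus), "phido_session_error")
  invisible(session)
}

is_system_class <- function(schema, class_name)
  class_name == "System Utterance" ||
  "System Utterance" %in% ancestors(schema, class_name)

is_participant_class <- function(schema, class_name)
  class_name == "Participant Utterance" ||
  "Participant Utterance" %in% ancestors(schema, class_name)

#' Derived follows edges
#'
#' The graph stores `precedes` edges; `follows` is their inverse closure:
#' `follows(b, a)` holds exactly when `precedes(a, b)` is stored.
#'
#' @param session a `phido_session`.
#' @return data.frame with columns `source`, `kind = "follows"`, `target`.
#' @export
follows_edges <- function(session) {
  pe <- session$edges[session$edges$kind == "precedes", , drop = FALSE]
  data.frame(source = pe$target, kind = "follows", target = pe$source)
}

#' @export
print.phido_session <- function(x, ...) {
  cat(sprintf("<phido_session> \"%s\": %d instances, %d edges, %d tasks, %d goals\n",
              x$title, length(x$instances), nrow(x$edges), length(x$tasks),
              length(x$goals)))
  invisible(x)
}

# ---- session serialization --------------------------------------------------

SESSION_PROPS <- c(resume = "hasResumeTarget", return_exit = "isReturnExit",
                   title = "sessionTitle")

session_to_triples <- function(session) {
  base <- session$schema$iri_base
  piri <- function(name) paste0(base, "#", name)
  ciri <- function(label) schema_iri(session$schema, label)
  iri <- function(id) paste0(base, "/session#", id)
  ts <- list(tr(paste0(base, "/session"), q("rdf:type"), q("owl:Ontology")),
             lit(paste0(base, "/session"), q("rdfs:label"), session$title))
  d <- iri(session$discussion_id)
  ts[[length(ts) + 1L]] <- tr(d, q("rdf:type"), ciri("Vaccine Counseling"))
  for (g in session$goals) {
    ts[[length(ts) + 1L]] <- tr(iri(g$id), q("rdf:type"), ciri(g$kind))
    ts[[length(ts) + 1L]] <- tr(d, piri("hasGoal"), iri(g$id))
  }
  for (t in session$tasks) {
    ts[[length(ts) + 1L]] <- tr(iri(t$id), q("rdf:type"),
                                ciri(t$class_name))
    ts[[length(ts) + 1L]] <- tr(iri(t$goal_id), piri("hasSpeechTask"),
                                iri(t$id))
  }
  for (inst in session$instances) {
    s <- iri(inst$id)
    ts[[length(ts) + 1L]] <- tr(s, q("rdf:type"), ciri(inst$class_name))
    if (!is.na(inst$string))
      ts[[length(ts) + 1L]] <- lit(s, piri("hasUtteranceString"),
                                   inst$string)
    for (ex in inst$examples)
      ts[[length(ts) + 1L]] <- lit(s, piri("hasUtteranceExamples"), ex)
    ts[[length(ts) + 1L]] <- lit(s, piri("hasUtterancePriority"),
                                 inst$priority, "integer")
    ts[[length(ts) + 1L]] <- lit(s, piri("hasBeenSaid"),
                                 tolower(inst$been_said), "boolean")
    ts[[length(ts) + 1L]] <- lit(s, piri("hasFocus"),
                                 tolower(inst$focus), "boolean")
    ts[[length(ts) + 1L]] <- tr(s, piri("belongsToSpeechTask"),
                                iri(session$task_membership[[inst$id]]))
    if (inst$id %in% names(session$resume))
      ts[[length(ts) + 1L]] <- tr(s, piri(SESSION_PROPS[["resume"]]),
                                  iri(session$resume[[inst$id]]))
    if (inst$id %in% session$return_exits)
      ts[[length(ts) + 1L]] <- lit(s, piri(SESSION_PROPS[["return_exit"]]),
                                   "true", "boolean")
  }
  for (k in seq_len(nrow(session$edges)))
    ts[[length(ts) + 1L]] <- tr(iri(session$edges$source[k]),
                                piri(session$edges$kind[k]),
                                iri(session$edges$target[k]))
  bind_triples(ts)
}

#' Serialize a session graph (A-Box)
#'
#' @param session a `phido_session`.
#' @param path optional output file.
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @return document text, invisibly when `path` is given.
#' @export
serialize_session <- function(session, path = NULL,
                              dialect = c("turtle", "rdfxml")) {
  if (length(dialect) == 1L && !dialect %in% c("turtle", "rdfxml"))
    stop_phido(sprintf(
      "unknown dialect '%s'; supported dialects: turtle, rdfxml", dialect),
      "phido_dialect_error")
  dialect <- match.arg(dialect)
  tt <- session_to_triples(session)
  text <- if (dialect == "turtle")
    write_turtle_text(tt, paste0(session$schema$iri_base, "/session"))
  else write_rdfxml_text(tt)
  if (!is.null(path)) { writeLines(text, path); return(invisible(text)) }
  text
}

#' Load a serialized session graph
#'
#' @param x path or document text (Turtle or RDF/XML).
#' @param schema the schema the instances reference.
#' @return a `phido_session`.
#' @export
load_session <- function(x, schema = build_schema()) {
  tt <- read_triples(x)
  base <- schema$iri_base
  piri <- function(name) paste0(base, "#", name)
  sess_ns <- paste0(base, "/session#")
  id_of <- function(iri) sub("^.*#", "", iri)
  label_by_camel <- setNames(names(schema$classes),
                             vapply(names(schema$classes), camel_fragment,
                                    character(1)))
  class_of <- function(type_iri) {
    lbl <- label_by_camel[[sub("^.*#", "", type_iri)]]
    lbl %||% stop_phido(sprintf(
      "instance references unknown class <%s>", type_iri),
      "phido_session_error")
  }
  types <- tt[tt$predicate == q("rdf:type") &
              startsWith(tt$subject, sess_ns), , drop = FALSE]
  goals <- list(); tasks <- list(); instances <- list()
  membership <- character(); resume <- character()
  return_exits <- character(); discussion_id <- "discussion_1"
  task_class_labels <- c("Speech Task", subclasses(schema, "Speech Task"))
  goal_labels <- c("Communication Goal",
                   subclasses(schema, "Communication Goal"))
  for (k in seq_len(nrow(types))) {
    s <- types$subject[k]; id <- id_of(s)
    cls <- class_of(types$object[k])
    if (cls %in% c("Vaccine Counseling", "Discussion")) {
      discussion_id <- id
    } else if (cls %in% goal_labels) {
      goals[[id]] <- list(id = id, kind = cls, discussion_id = discussion_id)
    } else if (cls %in% task_class_labels) {
      kind <- TASK_KINDS[match(cls, c("Salutation", "Valediction",
                                      "Initiate Discussion",
                                      "Transition to Topic",
                                      "Interview Participant",
                                      "Discuss Health Topic",
                                      "Question and Answering Task"))]
      tasks[[id]] <- list(id = id, kind = kind, class_name = cls,
                          goal_id = NA_character_)
    } else if (is_utterance_class(schema, cls)) {
      sv <- obj1(tt, s, piri("hasUtteranceString"))
      instances[[id]] <- list(
        id = id, class_name = cls,
        string = sv %||% NA_character_,
        examples = triples_of(tt, s, piri("hasUtteranceExamples"))$object,
        priority = as.integer(obj1(tt, s, piri("hasUtterancePriority")) %||% 0),
        been_said = identical(obj1(tt, s, piri("hasBeenSaid")), "true"),
        focus = identical(obj1(tt, s, piri("hasFocus")), "true"))
      membership[id] <- id_of(obj1(tt, s, piri("belongsToSpeechTask")) %||%
                                NA_character_)
      rt <- obj1(tt, s, piri(SESSION_PROPS[["resume"]]))
      if (!is.null(rt)) resume[id] <- id_of(rt)
      if (identical(obj1(tt, s, piri(SESSION_PROPS[["return_exit"]])),
                    "true"))
        return_exits <- c(return_exits, id)
    }
  }
  hst <- tt[tt$predicate == piri("hasSpeechTask"), , drop = FALSE]
  for (k in seq_len(nrow(hst))) {
    tid <- id_of(hst$object[k])
    if (!is.null(tasks[[tid]])) tasks[[tid]]$goal_id <- id_of(hst$subject[k])
  }
  ek <- tt$predicate %in% c(piri("precedes"), piri("speechSegue"))
  ee <- tt[ek, , drop = FALSE]
  edges <- data.frame(source = vapply(ee$subject, id_of, character(1),
                                      USE.NAMES = FALSE),
                      kind = sub("^.*#", "", ee$predicate),
                      target = vapply(ee$object, id_of, character(1),
                                      USE.NAMES = FALSE))
  title_row <- obj1(tt, paste0(base, "/session"), q("rdfs:label"))
  entry <- names(instances)[vapply(instances, `[[`, logical(1), "focus")]
  session <- structure(list(
    title = title_row %||% "untitled counseling script",
    instances = instances[order(names(instances))],
    edges = edges[order(edges$source, edges$kind, edges$target), ,
                  drop = FALSE],
    task_membership = membership,
    tasks = tasks, goals = goals,
    discussion_id = discussion_id,
    entry = if (length(entry)) entry[[1]] else NA_character_,
    resume = resume, return_exits = unique(return_exits),
    schema = schema), class = "phido_session")
  rownames(session$edges) <- NULL
  check_session(session)
  session
}

#' Compare two session graphs for structural equality
#'
#' Order-insensitive on instances, data values, edges and groupings.
#'
#' @param a,b `phido_session` objects.
#' @return logical scalar.
#' @export
session_equal <- function(a, b) {
  canon <- function(s) {
    ed <- s$edges[order(s$edges$source, s$edges$kind, s$edges$target), ]
    rownames(ed) <- NULL
    res <- if (length(s$resume)) s$resume[order(names(s$resume))]
           else setNames(character(), character())
    list(instances = s$instances[order(names(s$instances))],
         edges = ed,
         membership = s$task_membership[order(names(s$task_membership))],
         task = lapply(s$tasks[order(names(s$tasks))],
                       function(t) t[c("id", "kind", "class_name", "goal_id")]),
         goals = lapply(s$goals[order(names(s$goals))],
                        function(g) g[c("id", "kind")]),
         resume = res,
         return_exits = sort(s$return_exits))
  }
  isTRUE(all.equal(canon(a), canon(b)))
}
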