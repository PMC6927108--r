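# The transition mechanism: walk the session graph from the focused
# instance, speak system utterances, classify participant input against the
# expected utterance instances, and keep exactly one hasFocus holder alive
# until the session ends.

#' Create a fresh dialogue state over a session graph
#'
#' @param session a `phido_session`.
#' @param tau similarity threshold for input classification (token-set
#'   Jaccard, default 0.5).
#' @param retry_budget misunderstandings tolerated per Request Repeat site
#'   before the session is ended (default 2).
#' @return a `dialogue_state`.
#' @export
dialogue_state <- function(session, tau = 0.5, retry_budget = 2L) {
  stopifnot(inherits(session, "phido_session"), tau >= 0, tau <= 1)
  structure(list(session = session, focus_id = session$entry,
                 tau = tau, retry_budget = as.integer(retry_budget),
                 retries = integer(), turn = 0L, transcript = list(),
                 awaiting = NULL, return_stack = character(),
                 ended = FALSE),
            class = "dialogue_state")
}

#' @export
print.dialogue_state <- function(x, ...) {
  cat(sprintf("<dialogue_state> turn %d, focus %s%s\n", x$turn,
              if (x$ended) "<none>" else x$focus_id,
              if (x$ended) " (ended)" else ""))
  invisible(x)
}

event <- function(kind, turn, id = NA_character_, class = NA_character_,
                  text = NA_character_)
  list(kind = kind, turn = turn, id = id, class = class, text = text)

inst_of <- function(state, id) state$session$instances[[id]]

edge_targets <- function(session, from, kind) {
  e <- session$edges
  e$target[e$source == from & e$kind == kind]
}

order_by_priority <- function(session, ids) {
  if (!length(ids)) return(character())
  pr <- vapply(ids, function(i) session$instances[[i]]$priority, integer(1))
  ids[order(pr, ids)]
}

#' Query the utterances that follow the focus
#'
#' All instances one `precedes` edge away from the focus (those that
#' `follow` it), ordered by hasUtterancePriority ascending with ties broken
#' by instance id; when there are none, the speechSegue target(s). A focus
#' with neither, other than a terminal Concluding Farewell, is a dangling
#' graph.
#'
#' @param state a `dialogue_state`.
#' @return character vector of instance ids (empty at the terminal node).
#' @export
next_candidates <- function(state) {
  session <- state$session
  foll <- order_by_priority(session,
                            edge_targets(session, state$focus_id, "precedes"))
  if (length(foll)) return(foll)
  seg <- order_by_priority(session,
                           edge_targets(session, state$focus_id,
                                        "speechSegue"))
  if (length(seg)) return(seg)
  if (inst_of(state, state$focus_id)$class_name == "Concluding Farewell")
    return(character())
  stop_phido(sprintf(
    "dangling graph: instance '%s' has no followers and no speechSegue",
    state$focus_id), "phido_engine_error")
}

#' Classify participant input against expected utterance instances
#'
#' Scores each Participant Utterance candidate by the maximum token-set
#' Jaccard similarity between the (lower-cased, punctuation-stripped) input
#' and the candidate's hasUtteranceExamples. The best-scoring candidate is
#' matched when its score reaches `tau`; otherwise the input is
#' Unintelligible. Deterministic for fixed input.
#'
#' @param text participant input.
#' @param candidates list of utterance instances (as stored in a session).
#' @param schema schema used to restrict candidates to participant classes.
#' @param tau similarity threshold in [0, 1].
#' @return list with `matched_class`, `matched_id` (NA when unmatched),
#'   `score` and `candidate_scores`.
#' @export
classify_input <- function(text, candidates, schema = build_schema(),
                           tau = 0.5) {
  part <- Filter(function(i) is_participant_class(schema, i$class_name),
                 candidates)
  if (!length(part))
    stop_phido("no expected participant utterance at this point",
               "phido_engine_error")
  scored <- Filter(function(i) i$class_name != "Unintelligible", part)
  if (!length(scored))
    return(list(matched_class = "Unintelligible", matched_id = NA_character_,
                score = 0, candidate_scores = numeric()))
  scores <- vapply(scored, function(i) {
    if (!length(i$examples)) return(0)
    max(vapply(i$examples, jaccard_similarity, numeric(1), b = text))
  }, numeric(1))
  names(scores) <- vapply(scored, `[[`, character(1), "id")
  ord <- order(-scores,
               vapply(scored, `[[`, integer(1), "priority"),
               names(scores))
  best <- ord[1]
  if (scores[best] >= tau)
    list(matched_class = scored[[best]]$class_name,
         matched_id = names(scores)[best], score = unname(scores[best]),
         candidate_scores = scores)
  else
    list(matched_class = "Unintelligible", matched_id = NA_character_,
         score = unname(scores[best]), candidate_scores = scores)
}

# move focus flag to `to` (or clear it when to is NULL)
set_focus <- function(state, to) {
  state$session$instances[[state$focus_id]]$focus <- FALSE
  if (!is.null(to)) {
    state$session$instances[[to]]$focus <- TRUE
    state$focus_id <- to
  } else state$focus_id <- NA_character_
  state
}

mark_said <- function(state, id) {
  state$session$instances[[id]]$been_said <- TRUE
  state
}

end_session <- function(state, events, turn) {
  state <- set_focus(state, NULL)
  state$ended <- TRUE
  events[[length(events) + 1L]] <- event("session_end", turn)
  list(state = state, events = events)
}

# pick an Answer follower of a question-answering entry for the given input:
# best example match at or above tau, else the No Answer default
select_answer <- function(state, qa_entry, input) {
  session <- state$session
  foll <- order_by_priority(session, edge_targets(session, qa_entry,
                                                  "precedes"))
  answers <- foll[vapply(foll, function(i)
    session$instances[[i]]$class_name == "Answer", logical(1))]
  noans <- foll[vapply(foll, function(i)
    session$instances[[i]]$class_name == "No Answer", logical(1))]
  if (length(answers)) {
    sc <- vapply(answers, function(i)
      max(c(0, vapply(session$instances[[i]]$examples, jaccard_similarity,
                      numeric(1), b = input))), numeric(1))
    if (max(sc) >= state$tau) return(answers[which.max(sc)])
  }
  if (length(noans)) noans[[1]] else foll[[1]]
}

#' Advance the dialogue by one step
#'
#' A step at a system-utterance focus emits the utterance (system_say),
#' marks it said, and moves the focus to its follower or segue target,
#' emitting await_input when the follower slot expects the participant. A
#' step at a participant slot classifies the supplied input: a match passes
#' the focus through the matched instance to its follower in the same step;
#' an unintelligible input requests a repeat and burns one retry at that
#' Request Repeat site; an exhausted retry budget ends the session. Exactly
#' one instance holds hasFocus afterwards (none once the session has ended).
#'
#' @param state a `dialogue_state`.
#' @param input participant input; required exactly when the previous step
#'   emitted await_input.
#' @return the updated `dialogue_state`; the events of this step are
#'   appended to `state$transcript`.
#' @export
step <- function(state, input = NULL) {
  if (state$ended)
    stop_phido("session has already ended", "phido_engine_error")
  session <- state$session
  turn <- state$turn + 1L
  events <- list()
  finish <- function(st) {
    st$turn <- turn
    st$transcript <- c(st$transcript, events)
    st
  }

  if (is.null(state$awaiting)) {
    # ---- system side ----
    inst <- inst_of(state, state$focus_id)
    if (!is.null(input))
      stop_phido(sprintf(
        "input supplied while focus '%s' is a System Utterance",
        inst$id), "phido_engine_error")
    events[[length(events) + 1L]] <- event("system_say", turn, inst$id,
                                           inst$class_name, inst$string)
    state <- mark_said(state, inst$id)
    cand <- next_candidates(state)
    if (!length(cand)) {          # terminal Concluding Farewell
      res <- end_session(state, events, turn)
      events <- res$events
      return(finish(res$state))
    }
    direct <- edge_targets(session, state$focus_id, "precedes")
    via_segue <- !length(direct)
    first <- cand[[1]]
    if (is_participant_class(session$schema,
                             inst_of(state, first)$class_name) &&
        !via_segue) {
      state <- set_focus(state, first)
      state$awaiting <- cand
      events[[length(events) + 1L]] <-
        event("await_input", turn, first,
              paste(vapply(cand, function(i)
                inst_of(state, i)$class_name, character(1)),
                collapse = " | "))
    } else {
      if (via_segue)
        events[[length(events) + 1L]] <- event("segue", turn, first,
                                               inst_of(state, first)$class_name)
      state <- set_focus(state, first)
      if (is_participant_class(session$schema,
                               inst_of(state, first)$class_name)) {
        # segue landed on a participant slot (question-answering entry):
        # the slot itself is the expected utterance
        state$awaiting <- state$focus_id
        events[[length(events) + 1L]] <-
          event("await_input", turn, first,
                inst_of(state, first)$class_name)
      }
    }
    return(finish(state))
  }

  # ---- participant side ----
  if (is.null(input))
    stop_phido("participant input required at this step",
               "phido_engine_error")
  cand_ids <- state$awaiting
  cands <- lapply(cand_ids, function(i) session$instances[[i]])
  res <- classify_input(input, cands, session$schema, state$tau)
  state$awaiting <- NULL

  if (res$matched_class == "Unintelligible") {
    un_id <- cand_ids[vapply(cands, function(i)
      i$class_name == "Unintelligible", logical(1))]
    rr_id <- if (length(un_id))
      edge_targets(session, un_id[[1]], "precedes") else character()
    site <- if (length(rr_id)) rr_id[[1]] else state$focus_id
    state$retries[site] <- (if (site %in% names(state$retries))
      state$retries[[site]] else 0L) + 1L
    events[[length(events) + 1L]] <- event("repeat_requested", turn,
                                           site, "Unintelligible", input)
    if (state$retries[[site]] > state$retry_budget) {
      events[[length(events) + 1L]] <- event("segue", turn, NA_character_,
                                             "session end")
      res2 <- end_session(state, events, turn)
      events <- res2$events
      return(finish(res2$state))
    }
    if (length(un_id)) state <- mark_said(state, un_id[[1]])
    state <- set_focus(state, site)
    return(finish(state))
  }

  m <- res$matched_id
  mclass <- res$matched_class
  events[[length(events) + 1L]] <- event("classified_as", turn, m, mclass,
                                         input)
  state <- mark_said(state, m)
  state <- set_focus(state, m)

  seg <- edge_targets(session, m, "speechSegue")
  foll <- order_by_priority(session, edge_targets(session, m, "precedes"))

  is_question <- mclass == "Question" ||
    "Question" %in% ancestors(session$schema, mclass)
  if (is_question && length(seg)) {
    # detour into question answering: remember where to resume, then pick
    # the answer for this input right away
    if (m %in% names(session$resume))
      state$return_stack <- c(state$return_stack, session$resume[[m]])
    qa_entry <- seg[[1]]
    events[[length(events) + 1L]] <- event("segue", turn, qa_entry,
                                           inst_of(state, qa_entry)$class_name)
    ans <- select_answer(state, qa_entry, input)
    state <- set_focus(state, ans)
    return(finish(state))
  }
  if (is_question && !length(seg) && length(foll)) {
    # question asked at the question-answering entry itself
    ans <- select_answer(state, m, input)
    state <- set_focus(state, ans)
    return(finish(state))
  }

  if (length(foll)) {                       # ordinary follower
    state <- set_focus(state, foll[[1]])
    return(finish(state))
  }

  if (m %in% session$return_exits && length(state$return_stack)) {
    back <- state$return_stack[length(state$return_stack)]
    state$return_stack <- state$return_stack[-length(state$return_stack)]
    events[[length(events) + 1L]] <- event("segue", turn, back,
                                           inst_of(state, back)$class_name)
    state <- set_focus(state, back)
    return(finish(state))
  }

  if (length(seg)) {
    if (m %in% names(session$resume) &&
        (mclass == "Disconfirmation" ||
         "Negative Utterance" %in% ancestors(session$schema, mclass)))
      state$return_stack <- c(state$return_stack, session$resume[[m]])
    events[[length(events) + 1L]] <- event("segue", turn, seg[[1]],
                                           inst_of(state, seg[[1]])$class_name)
    state <- set_focus(state, seg[[1]])
    return(finish(state))
  }

  res2 <- end_session(state, events, turn)
  events <- res2$events
  finish(res2$state)
}

#' Run a full counseling session with a participant policy
#'
#' Alternates [step()] with policy-generated participant input until the
#' session ends or `max_turns` is reached. Bit-for-bit reproducible for a
#' fixed (session, policy, seed) triple.
#'
#' @param session a `phido_session`.
#' @param policy a [participant_policy()].
#' @param seed integer seed for the policy's private RNG stream.
#' @param max_turns upper bound on engine steps (>= 1).
#' @param tau,retry_budget engine parameters, see [dialogue_state()].
#' @return a `phido_transcript`: list with `events`, `ended`, `turns` and
#'   the final `state`.
#' @export
run_session <- function(session, policy = participant_policy("cooperative"),
                        seed = policy$seed, max_turns = 500L, tau = 0.5,
                        retry_budget = 2L) {
  stopifnot(max_turns >= 1L)
  state <- dialogue_state(session, tau = tau, retry_budget = retry_budget)
  rng <- rng_stream(seed)
  budget <- policy$question_budget
  while (!state$ended && state$turn < max_turns) {
    if (!is.null(state$awaiting)) {
      cands <- lapply(state$awaiting, function(i) session$instances[[i]])
      resp <- respond(policy, cands, rng, question_budget = budget)
      budget <- resp$question_budget
      state <- step(state, resp$text)
    } else {
      state <- step(state)
    }
  }
  structure(list(events = state$transcript, ended = state$ended,
                 turns = state$turn, state = state),
            class = "phido_transcript")
}

#' @export
print.phido_transcript <- function(x, ...) {
  cat(sprintf("<phido_transcript> %d events over %d turns%s\n",
              length(x$events), x$turns,
              if (x$ended) ", session ended" else ""))
  for (e in utils::head(x$events, 12))
    cat(sprintf("  [%02d] %-16s %s\n", e$turn, e$kind,
                if (!is.na(e$text)) e$text else e$class %||% ""))
  if (length(x$events) > 12) cat("  ...\n")
  invisible(x)
}

#' Write a transcript as JSON lines
#'
#' One engine event per line: turn, kind, utterance id, class and text.
#'
#' @param transcript a `phido_transcript` (or its `events` list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  events <- if (inherits(transcript, "phido_transcript"))
    transcript$events else transcript
  lines <- vapply(events, function(e)
    jsonlite::toJSON(e[c("turn", "kind", "id", "class", "text")],
                     auto_unbox = TRUE, null = "null", na = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
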