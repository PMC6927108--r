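# Synthetic participants and synthetic counseling scripts. Personas stand
# in for live study participants so every engine path (cooperative flow,
# repeats, refusals, questions, unintelligible input) can be exercised
# deterministically from a seed.

PERSONAS <- c("cooperative", "repeater", "confused", "questioner", "refuser")

# consonant-cluster alphabet disjoint from any utterance example: token-set
# Jaccard against real text is 0 by construction, so classification as
# Unintelligible is certain, not probabilistic
GIBBERISH_TOKENS <- c("zzqx", "qqvv", "xkzz", "vqxq", "zxqv", "qzzk")

#' Define a synthetic participant policy
#'
#' @param persona one of `"cooperative"`, `"repeater"`, `"confused"`,
#'   `"questioner"`, `"refuser"`.
#' @param p_question probability of asking a question where one is expected
#'   (questioner; default 1 so a question budget is spent deterministically).
#' @param p_disconfirm probability of refusing at a Disconfirmation site
#'   (refuser).
#' @param p_gibberish probability of answering with gibberish (confused).
#' @param p_repeat probability of asking the system to repeat itself where
#'   possible (repeater).
#' @param question_budget questions the persona may ask over a session.
#' @param seed seed of the policy's private RNG stream.
#' @return a `participant_policy`.
#' @export
participant_policy <- function(persona = PERSONAS, p_question = NULL,
                               p_disconfirm = NULL, p_gibberish = NULL,
                               p_repeat = NULL, question_budget = 2L,
                               seed = 1L) {
  persona <- match.arg(persona)
  defaults <- switch(persona,
    cooperative = c(q = 0, d = 0, g = 0, r = 0),
    repeater    = c(q = 0, d = 0, g = 0, r = 0.5),
    confused    = c(q = 0, d = 0, g = 1, r = 0),
    questioner  = c(q = 1, d = 0, g = 0, r = 0),
    refuser     = c(q = 0, d = 0.8, g = 0, r = 0))
  p <- list(p_question = p_question %||% defaults[["q"]],
            p_disconfirm = p_disconfirm %||% defaults[["d"]],
            p_gibberish = p_gibberish %||% defaults[["g"]],
            p_repeat = p_repeat %||% defaults[["r"]])
  for (nm in names(p))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop_phido(sprintf("%s must lie in [0, 1]", nm), "phido_policy_error")
  if (persona == "cooperative" && any(unlist(p) > 0))
    stop_phido("cooperative persona admits no perturbation probabilities",
               "phido_policy_error")
  structure(c(list(persona = persona), p,
              list(question_budget = as.integer(question_budget),
                   seed = as.integer(seed))),
            class = "participant_policy")
}

gibberish <- function(rng, n = 3L)
  paste(stream_sample(rng, GIBBERISH_TOKENS, n, replace = TRUE),
        collapse = " ")

#' Generate a participant reply for the expected candidate set
#'
#' The cooperative baseline answers with the first example of the
#' highest-priority expected Participant Utterance; personas perturb it at
#' the sites where their utterance class is among the candidates.
#'
#' @param policy a [participant_policy()].
#' @param candidates list of expected utterance instances (non-empty).
#' @param rng an RNG stream created by the caller (one per session).
#' @param question_budget remaining question allowance.
#' @return list with `text` and the updated `question_budget`.
#' @export
respond <- function(policy, candidates, rng = rng_stream(policy$seed),
                    question_budget = policy$question_budget) {
  if (!length(candidates))
    stop_phido("no candidates to respond to", "phido_policy_error")
  classes <- vapply(candidates, `[[`, character(1), "class_name")
  first_example_of <- function(class_name) {
    k <- which(classes == class_name)[1]
    candidates[[k]]$examples[[1]]
  }
  cooperative <- function() {
    ok <- which(classes != "Unintelligible")
    if (!length(ok)) return(gibberish(rng))
    # compliant reply first; a polite "no more" next (ends question loops);
    # a question only when nothing else is expected
    tiers <- list(
      ok[!classes[ok] %in% c("Disconfirmation", "Question",
                             "Divergent Question")],
      ok[classes[ok] == "Disconfirmation"],
      ok)
    pick_from <- tiers[[which(vapply(tiers, length, integer(1)) > 0)[1]]]
    pr <- vapply(candidates[pick_from], `[[`, integer(1), "priority")
    candidates[[pick_from[which.min(pr)]]]$examples[[1]]
  }
  text <- NULL
  if (policy$persona == "confused" && policy$p_gibberish > 0 &&
      stream_runif(rng) <= policy$p_gibberish) {
    text <- gibberish(rng)
  } else if (policy$persona == "questioner" && question_budget > 0L &&
             "Question" %in% classes &&
             stream_runif(rng) <= policy$p_question) {
    text <- first_example_of("Question")
    question_budget <- question_budget - 1L
  } else if (policy$persona == "refuser" && "Disconfirmation" %in% classes &&
             stream_runif(rng) <= policy$p_disconfirm) {
    text <- first_example_of("Disconfirmation")
  } else if (policy$persona == "repeater" &&
             "Request System Repeat" %in% classes &&
             stream_runif(rng) <= policy$p_repeat) {
    text <- first_example_of("Request System Repeat")
  }
  list(text = text %||% cooperative(), question_budget = question_budget)
}

DEFAULT_VOCABULARY <- c("protects", "against", "cancer", "infection",
                        "effective", "safe", "soreness", "mild", "fever",
                        "doses", "schedule", "immunity", "teens", "adults",
                        "studies", "coverage", "common", "rare", "benefit",
                        "response")

#' Generate a synthetic counseling script
#'
#' Deterministic for a fixed seed. The script always opens with a
#' salutation and closes with a valediction; communication goals follow the
#' introductory-to-concluding ordering, with Pursuit Before Exit kept
#' off-path; health items are sentences drawn from the vocabulary.
#'
#' @param n_goals number of communication goals (1..7).
#' @param items_per_topic health items per discussion topic (>= 1).
#' @param vocabulary words used to assemble health items and answers.
#' @param seed integer seed.
#' @return a `dialogue_script` that passes [load_script()] validation.
#' @export
generate_script <- function(n_goals = 4L, items_per_topic = 2L,
                            vocabulary = DEFAULT_VOCABULARY, seed = 1L) {
  if (n_goals < 1L || n_goals > 7L)
    stop_phido("n_goals must lie between 1 and 7 (the defined communication goals)",
               "phido_script_error")
  stopifnot(items_per_topic >= 1L)
  rng <- rng_stream(seed)
  order7 <- c("Acclimate", "Communicate Benefit", "Communicate Effectiveness",
              "Communicate Harms", "Communicate Uncertainty",
              "Pursuit Before Exit", "Conclude")
  kinds <- if (n_goals == 1L) "Acclimate"
           else if (n_goals == 2L) c("Acclimate", "Conclude")
           else c("Acclimate", order7[seq_len(n_goals - 2L) + 1L], "Conclude")
  # keep the ordering convention: pursuit sits just before the conclusion
  kinds <- c(setdiff(kinds, c("Pursuit Before Exit", "Conclude")),
             intersect(kinds, "Pursuit Before Exit"),
             intersect(kinds, "Conclude"))
  item_sentence <- function() {
    w <- stream_sample(rng, vocabulary, 3L)
    sprintf("The vaccine is %s and %s against %s.", w[1], w[2], w[3])
  }
  answer_pair <- function(topic) {
    w <- stream_sample(rng, vocabulary, 2L)
    q <- sprintf("how %s is the vaccine for %s", w[1], w[2])
    setNames(list(sprintf("It is considered %s for %s.", w[1], w[2])), q)
  }
  goals <- lapply(seq_along(kinds), function(k) {
    kind <- kinds[k]
    tasks <- if (kind == "Acclimate") {
      list(list(kind = "salutation"),
           list(kind = "initiate_discussion",
                topic_options = as.list(stream_sample(rng, vocabulary, 2L))),
           list(kind = "interview_participant",
                interview_questions = list("How are you feeling today?")))
    } else if (kind == "Conclude") {
      list(list(kind = "valediction"))
    } else if (kind == "Pursuit Before Exit") {
      list(list(kind = "transition_to_topic",
                transition = paste("I hear you. May I share one more point",
                                   "before we finish?")))
    } else {
      ans <- answer_pair(kind)
      list(list(kind = "transition_to_topic",
                transition = sprintf("Let's talk about %s.",
                                     tolower(sub("Communicate ", "", kind)))),
           list(kind = "discuss_health_topic",
                health_items = as.list(replicate(items_per_topic,
                                                 item_sentence())),
                answers = ans),
           list(kind = "question_answering", answers = ans))
    }
    list(goal = kind, tasks = tasks)
  })
  if (n_goals == 1L)
    goals[[1]]$tasks <- c(goals[[1]]$tasks, list(list(kind = "valediction")))
  if (!any(kinds == "Conclude") && n_goals > 1L)
    goals[[length(goals)]]$tasks <- c(goals[[length(goals)]]$tasks,
                                      list(list(kind = "valediction")))
  as_dialogue_script(list(
    title = sprintf("synthetic counseling script (seed %d)", seed),
    goals = goals))
}
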