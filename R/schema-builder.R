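#' Class descriptor for the dialogue ontology
#'
#' @param name class label, verbatim (spaces allowed); unique in a schema.
#' @param parents character vector of parent class labels (empty for roots).
#'   Multiple parents are allowed.
#' @param speech_act Searle speech-act annotation, one of
#'   `"assertive"`, `"representative"`, `"directive"`, `"commissive"`,
#'   `"expressive"`, `"declaration"`, `"none"`. `"none"` is reserved for
#'   non-utterance classes and for utterance classes whose act is not
#'   defined (unintelligible or nonsensical speech, and abstract grouping
#'   classes).
#' @param annotation free-text definition stored as a comment annotation.
#' @param note optional editorial note annotation.
#' @return a list of class `phido_class`.
#' @export
phido_class <- function(name, parents = character(), speech_act = "none",
                        annotation = "", note = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  acts <- c("assertive", "representative", "directive", "commissive",
            "expressive", "declaration", "none")
  if (!speech_act %in% acts)
    stop_phido(sprintf("unknown speech act '%s' for class '%s'",
                       speech_act, name), "phido_schema_error")
  structure(list(name = name, parents = sort(unique(as.character(parents))),
                 speech_act = speech_act,
                 annotation = as.character(annotation),
                 note = note),
            class = "phido_class")
}

#' Property descriptor for the dialogue ontology
#'
#' @param name property name (camelCase, verbatim).
#' @param kind `"object"` or `"data"`.
#' @param domain domain class label.
#' @param range range class label (object properties) or one of
#'   `"string"`, `"boolean"`, `"integer"` (data properties).
#' @param inverse_of optional name of the inverse property (must be mutual).
#' @param sub_property_of optional name of the parent property.
#' @param symmetric logical; only meaningful for object properties.
#' @return a list of class `phido_property`.
#' @export
phido_property <- function(name, kind, domain, range, inverse_of = NULL,
                           sub_property_of = NULL, symmetric = FALSE) {
  stopifnot(kind %in% c("object", "data"))
  if (kind == "data" && !range %in% c("string", "boolean", "integer"))
    stop_phido(sprintf("data property '%s' has non-literal range '%s'",
                       name, range), "phido_schema_error")
  structure(list(name = name, kind = kind, domain = domain, range = range,
                 inverse_of = inverse_of, sub_property_of = sub_property_of,
                 symmetric = isTRUE(symmetric)),
            class = "phido_property")
}

#' Assemble an ontology schema (T-Box)
#'
#' @param classes list of [phido_class()] descriptors.
#' @param properties list of [phido_property()] descriptors.
#' @param iri_base namespace; entity IRIs are `<iri_base>#<CamelCaseLabel>`.
#' @return object of class `phido_schema`.
#' @seealso [build_schema()] for the full patient-counseling schema.
#' @export
phido_schema <- function(classes = list(), properties = list(),
                         iri_base = "https://w3id.org/phido") {
  names(classes) <- vapply(classes, `[[`, character(1), "name")
  names(properties) <- vapply(properties, `[[`, character(1), "name")
  if (anyDuplicated(names(classes)))
    stop_phido(sprintf("duplicate class name(s): %s",
                       paste(unique(names(classes)[duplicated(names(classes))]),
                             collapse = ", ")), "phido_schema_error")
  structure(list(iri_base = iri_base,
                 classes = classes[order(names(classes))],
                 properties = properties[order(names(properties))]),
            class = "phido_schema")
}

# ---- the reconstructed patient-counseling inventory ------------------------

# Participant utterance rows with their printed Searle acts. Grouping rows
# without a printed act carry "none"; Negative Personal Status is listed
# twice in the source table (representative under Negative Utterance,
# expressive under Personal Status) and is kept once, expressive, with a
# note recording the dual printing.
participant_classes <- function() {
  pu <- "Participant Utterance"
  list(
    phido_class("Acceptance", pu, "expressive",
                "Participant accepts a proposal or recommendation."),
    phido_class("Negative Utterance", pu, "none",
                "Grouping class for negatively valenced participant speech."),
    phido_class("Disconfirmation", "Negative Utterance", "expressive",
                "Participant rejects or disagrees with what was said."),
    phido_class("Negative Personal Status",
                c("Negative Utterance", "Personal Status"), "expressive",
                "Participant reports an unfavourable personal state.",
                note = paste("Listed under both Negative Utterance",
                             "(representative) and Personal Status",
                             "(expressive) in the source inventory.")),
    phido_class("Participant Farewell", pu, "expressive",
                "Participant-initiated farewell."),
    phido_class("Participant Introduction", pu, "assertive",
                "Participant introduces themself."),
    phido_class("Personal Status", pu, "none",
                "Grouping class for reports about the participant's state."),
    phido_class("Positive Personal Status",
                c("Personal Status", "Positive Utterance"), "expressive",
                "Participant reports a favourable personal state."),
    phido_class("Positive Utterance", pu, "none",
                "Grouping class for positively valenced participant speech."),
    phido_class("Confirmation", "Positive Utterance", "representative",
                "Participant confirms or agrees."),
    phido_class("Prattle", pu, "none",
                "Nonsensical or off-task speech; no speech act assigned."),
    phido_class("Question", pu, "directive",
                "Participant asks a question about the current topic."),
    phido_class("Divergent Question", "Question", "directive",
                "Participant question that departs from the current topic."),
    phido_class("Reciprocal Farewell", pu, "expressive",
                "Participant returns the system's farewell."),
    phido_class("Reciprocal Greet", pu, "expressive",
                "Participant returns the system's greeting."),
    phido_class("Request System", pu, "directive",
                "Participant directs the system to act."),
    phido_class("Request System Repeat", "Request System", "directive",
                "Participant asks the system to repeat itself."),
    phido_class("Unintelligible", pu, "none",
                "Speech the system could not discern; no speech act assigned.")
  )
}

system_classes <- function() {
  su <- "System Utterance"
  list(
    phido_class("Acknowledgment", su, "expressive",
                "System acknowledges what the participant said."),
    phido_class("Agenda", su, "commissive",
                "System states the agenda of the discussion."),
    phido_class("Answer", su, "representative",
                "System answers a participant question."),
    phido_class("No Answer", "Answer", "representative",
                "Default response when no answer is available."),
    phido_class("Apology", su, "expressive", "System apologises."),
    phido_class("Capitulate", su, "expressive",
                "System yields after the participant declines to continue."),
    phido_class("Compassionate Utterance", su, "none",
                "Grouping class for empathic system speech."),
    phido_class("Condolence", "Compassionate Utterance", "expressive",
                "System expresses sympathy."),
    phido_class("Happy For", "Compassionate Utterance", "expressive",
                "System expresses shared joy."),
    phido_class("Confirm Health Information", su, "directive",
                "System asks whether the participant understood the fact."),
    phido_class("System Declaration", su, "none",
                "Grouping class for declarative system announcements."),
    phido_class("Disclaimer", "System Declaration", "representative",
                "System states the limits of the counseling session."),
    phido_class("Topic Transition", "System Declaration", "commissive",
                "System announces a switch to another topic."),
    phido_class("System Farewell", su, "expressive",
                "System-initiated farewell."),
    phido_class("Concluding Farewell", "System Farewell", "expressive",
                "Final farewell that closes the session."),
    phido_class("System Greet", su, "expressive",
                "Opening greeting by the system."),
    phido_class("Inform", su, "representative",
                "System communicates a piece of information."),
    phido_class("Inquire Personal", su, "directive",
                "System asks about the participant personally."),
    phido_class("Interview Question", su, "directive",
                "System question used to probe participant context."),
    phido_class("Option", su, "none",
                "Grouping class for option prompts offered to the user."),
    phido_class("Clarification Options", "Option", "directive",
                "System offers options to clarify an utterance."),
    phido_class("Question Options", "Option", "directive",
                "System asks whether the participant has more questions."),
    phido_class("Topic Options", "Option", "directive",
                "System lists topics the participant may choose from."),
    phido_class("Overview", su, "commissive",
                "System previews the discussion ahead."),
    phido_class("Request", su, "directive",
                "System requests an action from the participant."),
    phido_class("Request Repeat", su, "directive",
                "System asks the participant to repeat themself."),
    phido_class("Satisfaction Prompt", su, "directive",
                "System asks whether the participant is satisfied."),
    phido_class("System Introduction", su, "representative",
                "System introduces itself and its role."),
    phido_class("Health Information", su, "representative",
                paste("A single health fact spoken by the agent during a",
                      "health-topic discussion."),
                note = paste("Not part of the tabulated utterance inventory;",
                             "required by the Discuss Health Topic flow."))
  )
}

structural_classes <- function() {
  list(
    phido_class("Discussion", character(),
                annotation = "Root: an entire counseling encounter."),
    phido_class("Vaccine Counseling", "Discussion",
                annotation = "A counseling discussion about vaccination."),
    phido_class("Goal", character(),
                annotation = "Root: an objective of the discussion."),
    phido_class("Communication Goal", "Goal",
                annotation = "A goal achieved by communicating with the user."),
    phido_class("Acclimate", "Communication Goal",
                annotation = "Help the user adapt to talking with an agent."),
    phido_class("Conclude", "Communication Goal",
                annotation = "End the discussion."),
    phido_class("Communicate Benefit", "Communication Goal",
                annotation = "Convey perceived benefits (Health Belief Model)."),
    phido_class("Communicate Effectiveness", "Communication Goal",
                annotation = "Convey effectiveness (Health Belief Model)."),
    phido_class("Communicate Harms", "Communication Goal",
                annotation = "Convey perceived harms (Health Belief Model)."),
    phido_class("Communicate Uncertainty", "Communication Goal",
                annotation = "Convey uncertainty (Health Belief Model)."),
    phido_class("Pursuit Before Exit", "Communication Goal",
                annotation = "Nudge a hesitant user before ending the session."),
    phido_class("Task", character(),
                annotation = "Root: a generic activity."),
    phido_class("Speech Task", "Task",
                annotation = "An atomic conversational objective."),
    phido_class("Pleasantry Task", "Speech Task",
                annotation = "Exchange of pleasantries."),
    phido_class("Salutation", "Pleasantry Task",
                annotation = "Opening greeting exchange."),
    phido_class("Valediction", "Pleasantry Task",
                annotation = "Closing farewell exchange."),
    phido_class("Proposition Task", "Speech Task",
                annotation = "Communicating an idea with user feedback."),
    phido_class("Initiate Discussion", "Proposition Task",
                annotation = "Introduce the theme of the session."),
    phido_class("Transition to Topic", "Proposition Task",
                annotation = "Switch the discussion to a different topic."),
    phido_class("Interview Participant", "Proposition Task",
                annotation = "Probe the participant for contextual information."),
    phido_class("Discuss Health Topic", "Proposition Task",
                annotation = "Communicate one health fact and confirm uptake."),
    phido_class("Question and Answering Task", "Speech Task",
                annotation = "Answer participant questions."),
    phido_class("Utterance", character(),
                annotation = "Root: any piece of speech by either party."),
    phido_class("Participant Utterance", "Utterance",
                annotation = "Utterances expected and spoken by the user."),
    phido_class("System Utterance", "Utterance",
                annotation = "Utterances vocalised by the agent.")
  )
}

phido_properties <- function() {
  list(
    phido_property("utteranceLink", "object", "Utterance", "Utterance",
                   symmetric = TRUE),
    phido_property("follows", "object", "Utterance", "Utterance",
                   inverse_of = "precedes", sub_property_of = "utteranceLink"),
    phido_property("precedes", "object", "Utterance", "Utterance",
                   inverse_of = "follows", sub_property_of = "utteranceLink"),
    phido_property("speechSegue", "object", "Utterance", "Utterance",
                   sub_property_of = "utteranceLink"),
    phido_property("belongsToSpeechTask", "object", "Utterance",
                   "Speech Task", inverse_of = "hasUtterance"),
    phido_property("hasUtterance", "object", "Speech Task", "Utterance",
                   inverse_of = "belongsToSpeechTask"),
    phido_property("hasGoal", "object", "Discussion", "Goal"),
    phido_property("hasSpeechTask", "object", "Communication Goal",
                   "Speech Task"),
    phido_property("hasUtterancePriority", "data", "Utterance", "integer"),
    phido_property("hasUtteranceString", "data", "Utterance", "string"),
    phido_property("hasBeenSaid", "data", "Utterance", "boolean"),
    phido_property("hasUtteranceExamples", "data", "Utterance", "string"),
    phido_property("hasFocus", "data", "Utterance", "boolean")
  )
}

#' Build the patient health-information dialogue schema
#'
#' Constructs the full T-Box: the four level roots (Discussion, Goal, Task,
#' Utterance), the seven communication goals, the speech-task hierarchy,
#' the Searle-annotated participant and system utterance inventories, eight
#' object properties and the five utterance data properties
#' (hasUtterancePriority, hasUtteranceString, hasBeenSaid,
#' hasUtteranceExamples, hasFocus).
#'
#' @param iri_base namespace IRI for the ontology.
#' @return a `phido_schema`.
#' @examples
#' s <- build_schema()
#' length(data_properties(s))          # 5
#' length(subclasses(s, "Participant Utterance"))  # 18
#' @export
build_schema <- function(iri_base = "https://w3id.org/phido") {
  phido_schema(c(structural_classes(), participant_classes(),
                 system_classes()),
               phido_properties(), iri_base = iri_base)
}

# ---- queries ----------------------------------------------------------------

#' @rdname schema-queries
#' @export
class_names <- function(schema) names(schema$classes)

#' Schema queries
#'
#' `subclasses()` returns the strict descendants of a class;
#' `ancestors()` its strict ancestors; `data_properties()` /
#' `object_properties()` the property descriptors of each kind;
#' `is_utterance_class()` tests descent from Utterance.
#'
#' @param schema a `phido_schema`.
#' @param class_name a class label present in the schema.
#' @name schema-queries
#' @export
subclasses <- function(schema, class_name) {
  kids <- function(p) names(Filter(function(cl) p %in% cl$parents,
                                   schema$classes))
  out <- character(); frontier <- class_name
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, kids)))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt); frontier <- nxt
  }
  sort(out)
}

#' @rdname schema-queries
#' @export
ancestors <- function(schema, class_name) {
  out <- character(); frontier <- class_name
  while (length(frontier)) {
    ps <- unique(unlist(lapply(frontier, function(n)
      schema$classes[[n]]$parents %||% character())))
    ps <- setdiff(ps, out)
    out <- c(out, ps); frontier <- ps
  }
  sort(out)
}

#' @rdname schema-queries
#' @export
data_properties <- function(schema)
  Filter(function(p) p$kind == "data", schema$properties)

#' @rdname schema-queries
#' @export
object_properties <- function(schema)
  Filter(function(p) p$kind == "object", schema$properties)

#' @rdname schema-queries
#' @export
is_utterance_class <- function(schema, class_name)
  class_name %in% names(schema$classes) &&
  (class_name == "Utterance" || "Utterance" %in% ancestors(schema, class_name))

# classes allowed to carry speech_act "none": non-utterance classes, the two
# uncaptured-speech classes, and grouping rows printed without an act.
none_act_allowed <- function(schema, name) {
  if (!is_utterance_class(schema, name) ||
      name %in% c("Utterance", "Participant Utterance", "System Utterance"))
    return(TRUE)
  name %in% c("Unintelligible", "Prattle", "Negative Utterance",
              "Personal Status", "Positive Utterance",
              "Compassionate Utterance", "System Declaration", "Option")
}

# depth-first cycle search over the parent relation
hierarchy_cycles <- function(schema) {
  colour <- setNames(rep(0L, length(schema$classes)), names(schema$classes))
  cyc <- character()
  visit <- function(n) {
    colour[n] <<- 1L
    for (p in schema$classes[[n]]$parents) {
      if (!p %in% names(colour)) next
      if (colour[p] == 1L) cyc <<- c(cyc, paste(n, "->", p))
      else if (colour[p] == 0L) visit(p)
    }
    colour[n] <<- 2L
  }
  for (n in names(colour)) if (colour[n] == 0L) visit(n)
  cyc
}

#' Validate a schema against its structural rules
#'
#' Checks name uniqueness, parent existence and acyclicity, speech-act
#' assignment, mutual-and-distinct inverse declarations, sub-property and
#' domain/range references. Reports violations; never throws.
#'
#' @param schema a `phido_schema`.
#' @return data.frame with columns `entity`, `rule`, `message`; zero rows
#'   when the schema is valid.
#' @export
validate_schema <- function(schema) {
  v <- list()
  bad <- function(entity, rule, message)
    v[[length(v) + 1L]] <<- data.frame(entity = entity, rule = rule,
                                       message = message)
  for (cl in schema$classes) {
    miss <- setdiff(cl$parents, names(schema$classes))
    if (length(miss))
      bad(cl$name, "unknown parent",
          sprintf("class '%s' lists unknown parent(s) %s", cl$name,
                  paste(miss, collapse = ", ")))
    if (cl$speech_act == "none" && !none_act_allowed(schema, cl$name))
      bad(cl$name, "missing speech act",
          sprintf("utterance class '%s' must carry a speech act", cl$name))
  }
  for (cyc in hierarchy_cycles(schema))
    bad(cyc, "hierarchy cycle", sprintf("class hierarchy cycle at %s", cyc))
  pn <- names(schema$properties)
  for (p in schema$properties) {
    if (!is.null(p$inverse_of)) {
      q <- schema$properties[[p$inverse_of]]
      if (identical(p$inverse_of, p$name))
        bad(p$name, "inverse must be mutual and distinct",
            sprintf("property '%s' declares itself as its inverse", p$name))
      else if (is.null(q) || !identical(q$inverse_of, p$name))
        bad(p$name, "inverse must be mutual and distinct",
            sprintf("inverse of '%s' is not mutual", p$name))
    }
    if (!is.null(p$sub_property_of) && !p$sub_property_of %in% pn)
      bad(p$name, "unknown super-property",
          sprintf("property '%s' references unknown super-property '%s'",
                  p$name, p$sub_property_of))
    if (!p$domain %in% names(schema$classes))
      bad(p$name, "unknown domain",
          sprintf("property '%s' has unknown domain '%s'", p$name, p$domain))
    if (p$kind == "object" && !p$range %in% names(schema$classes))
      bad(p$name, "unknown range",
          sprintf("property '%s' has unknown range '%s'", p$name, p$range))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(entity = character(), rule = character(),
                  message = character())
}

#' @export
print.phido_schema <- function(x, ...) {
  cat(sprintf("<phido_schema> %d classes, %d object / %d data properties\n",
              length(x$classes), length(object_properties(x)),
              length(data_properties(x))))
  cat("  iri_base:", x$iri_base, "\n")
  invisible(x)
}

#' Compare two schemas for structural equality
#'
#' Order-insensitive equality on classes, properties, annotations and the
#' namespace; used by the serialization round-trip checks.
#'
#' @param a,b `phido_schema` objects.
#' @return logical scalar.
#' @export
schema_equal <- function(a, b) {
  norm <- function(s) {
    s$classes <- lapply(s$classes, function(cl) {
      cl$note <- cl$note %||% NULL
      cl[c("name", "parents", "speech_act", "annotation", "note")]
    })
    s$properties <- lapply(s$properties, function(p)
      p[c("name", "kind", "domain", "range", "inverse_of",
          "sub_property_of", "symmetric")])
    s[c("iri_base", "classes", "properties")]
  }
  isTRUE(all.equal(norm(a), norm(b)))
}
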