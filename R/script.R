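# Declarative counseling scripts: an ordered list of communication goals,
# each holding ordered speech tasks with their content slots. YAML is the
# primary format, JSON is accepted; the shape is documented by
# inst/extdata/dialogue-script.schema.json.

GOAL_KINDS <- c("Acclimate", "Communicate Benefit", "Communicate Effectiveness",
                "Communicate Harms", "Communicate Uncertainty",
                "Pursuit Before Exit", "Conclude")

TASK_KINDS <- c("salutation", "valediction", "initiate_discussion",
                "transition_to_topic", "interview_participant",
                "discuss_health_topic", "question_answering")

script_error <- function(path, msg)
  stop_phido(sprintf("%s: %s", path, msg), "phido_script_error")

#' Load and validate a dialogue script
#'
#' @param x path to a YAML/JSON document, or the document text itself.
#' @param format `"auto"` (default), `"yaml"` or `"json"`.
#' @return a validated `dialogue_script` object.
#' @examples
#' load_script(system.file("extdata", "hpv_counseling.yaml",
#'                         package = "phido"))
#' @export
load_script <- function(x, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  is_path <- length(x) == 1L && !grepl("\n", x) && file.exists(x)
  text <- if (is_path) paste(readLines(x, warn = FALSE), collapse = "\n")
          else paste(x, collapse = "\n")
  if (format == "auto") {
    format <- if (is_path && grepl("\\.json$", x)) "json"
              else if (grepl("^\\s*\\{", text)) "json" else "yaml"
  }
  doc <- if (format == "json") jsonlite::fromJSON(text, simplifyVector = FALSE)
         else yaml::yaml.load(text)
  as_dialogue_script(doc)
}

#' Construct a dialogue script from an R list
#'
#' @param doc list with `title` and `goals`; each goal has `goal` (one of the
#'   seven communication-goal kinds) and `tasks`; each task has `kind` (one
#'   of the seven task kinds) plus its content slots.
#' @return a `dialogue_script`.
#' @export
as_dialogue_script <- function(doc) {
  if (is.null(doc$goals) || length(doc$goals) == 0L)
    script_error("goals", "a script needs at least one goal")
  goals <- lapply(seq_along(doc$goals), function(gi) {
    g <- doc$goals[[gi]]
    gpath <- sprintf("goals[%d]", gi)
    kind <- g$goal %||% script_error(paste0(gpath, ".goal"),
                                     "missing goal kind")
    if (!kind %in% GOAL_KINDS)
      script_error(paste0(gpath, ".goal"),
                   sprintf("unknown goal kind '%s'; allowed: %s", kind,
                           paste(GOAL_KINDS, collapse = ", ")))
    if (is.null(g$tasks) || length(g$tasks) == 0L)
      script_error(paste0(gpath, ".tasks"), "a goal needs at least one task")
    tasks <- lapply(seq_along(g$tasks), function(ti) {
      t <- g$tasks[[ti]]
      tpath <- sprintf("%s.tasks[%d]", gpath, ti)
      tkind <- t$kind %||% script_error(paste0(tpath, ".kind"),
                                        "missing task kind")
      if (!tkind %in% TASK_KINDS)
        script_error(paste0(tpath, ".kind"),
                     sprintf("unknown task kind '%s'; allowed: %s", tkind,
                             paste(TASK_KINDS, collapse = ", ")))
      # normalise parser differences: unnamed lists of scalars become
      # character vectors (YAML and JSON then agree)
      content <- lapply(t[setdiff(names(t), "kind")], function(v) {
        if (is.list(v) && length(v) && is.null(names(v)) &&
            all(vapply(v, function(x) is.atomic(x) && length(x) == 1L,
                       logical(1))))
          unlist(v)
        else v
      })
      if (tkind == "discuss_health_topic") {
        items <- unlist(content$health_items, use.names = FALSE)
        if (length(items) == 0L)
          script_error(paste0(tpath, ".health_items"),
                       "discuss_health_topic needs at least one health item")
        content$health_items <- as.character(items)
      }
      list(kind = tkind, content = content)
    })
    list(kind = kind, tasks = tasks)
  })
  script <- structure(list(title = doc$title %||% "untitled counseling script",
                           goals = goals),
                      class = "dialogue_script")
  validate_script_order(script)
  script
}

# salutation at most once, first overall; valediction at most once, last
validate_script_order <- function(script) {
  flat <- list()
  for (gi in seq_along(script$goals))
    for (ti in seq_along(script$goals[[gi]]$tasks))
      flat[[length(flat) + 1L]] <- list(
        kind = script$goals[[gi]]$tasks[[ti]]$kind,
        path = sprintf("goals[%d].tasks[%d]", gi, ti))
  kinds <- vapply(flat, `[[`, character(1), "kind")
  sal <- which(kinds == "salutation"); val <- which(kinds == "valediction")
  if (length(sal) > 1L)
    script_error(flat[[sal[2]]]$path, "salutation may appear at most once")
  if (length(sal) == 1L && sal != 1L)
    script_error(flat[[sal]]$path, "salutation must be the first task")
  if (length(val) > 1L)
    script_error(flat[[val[2]]]$path, "valediction may appear at most once")
  if (length(val) == 1L && val != length(kinds))
    script_error(flat[[val]]$path, "valediction must be the last task")
  invisible(script)
}

#' @export
print.dialogue_script <- function(x, ...) {
  cat(sprintf("<dialogue_script> \"%s\": %d goal(s)\n", x$title,
              length(x$goals)))
  for (g in x$goals)
    cat(sprintf("  %-26s %s\n", g$kind,
                paste(vapply(g$tasks, `[[`, character(1), "kind"),
                      collapse = ", ")))
  invisible(x)
}

#' Serialize a dialogue script
#'
#' @param script a `dialogue_script`.
#' @param path optional output file.
#' @param format `"yaml"` or `"json"`.
#' @return document text, invisibly when `path` is given.
#' @export
write_script <- function(script, path = NULL, format = c("yaml", "json")) {
  format <- match.arg(format)
  doc <- list(title = script$title,
              goals = lapply(script$goals, function(g)
                c(list(goal = g$kind),
                  list(tasks = lapply(g$tasks, function(t)
                    c(list(kind = t$kind), t$content))))))
  text <- if (format == "yaml") yaml::as.yaml(doc)
          else jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(text, path); return(invisible(text)) }
  text
}
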