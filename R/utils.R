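`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tokenize free text for similarity matching
#'
#' Lower-cases, strips punctuation and splits on whitespace. Used both by
#' the input classifier and by the label-word extraction of the metric
#' suite (which additionally splits camel case before calling this).
#'
#' @param text character scalar.
#' @return character vector of distinct tokens (possibly empty).
#' @keywords internal
tokenize <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character())
  x <- tolower(text)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  unique(toks[nzchar(toks)])
}

#' Token-set Jaccard similarity between two strings
#'
#' @param a,b character scalars.
#' @return similarity in [0, 1]; 0 when either token set is empty.
#' @keywords internal
jaccard_similarity <- function(a, b) {
  ta <- tokenize(a); tb <- tokenize(b)
  if (length(ta) == 0L || length(tb) == 0L) return(0)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

# Split a label or CamelCase IRI fragment into lower-case words.
label_words <- function(label) {
  x <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", label)
  tokenize(x)
}

# Deterministic label -> IRI fragment (spaces removed, words capitalised).
camel_fragment <- function(label) {
  parts <- strsplit(label, " ", fixed = TRUE)[[1]]
  paste0(vapply(parts, function(p) {
    if (!nzchar(p)) return("")
    paste0(toupper(substr(p, 1, 1)), substr(p, 2, nchar(p)))
  }, character(1)), collapse = "")
}

# A self-contained RNG stream: draws never touch (or depend on) the global
# .Random.seed, so simulator output is reproducible regardless of caller
# RNG state.
rng_stream <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  env$seed <- as.integer(seed)
  env
}

with_stream <- function(stream, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  if (is.null(stream$state)) set.seed(stream$seed)
  else assign(".Random.seed", stream$state, envir = globalenv())
  out <- force(expr)
  stream$state <- get(".Random.seed", globalenv())
  out
}

stream_runif <- function(stream, n = 1L) with_stream(stream, runif(n))
stream_sample <- function(stream, x, size = 1L, replace = FALSE) {
  with_stream(stream, x[sample.int(length(x), size, replace = replace)])
}

stop_phido <- function(msg, class) {
  stop(structure(class = c(class, "phido_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
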