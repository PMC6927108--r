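# RDF layer. Everything is a plain triple table:
#   data.frame(subject, predicate, object, type = "iri"|"literal", datatype)
# IRIs are stored in full; `datatype` is NA for IRIs and one of
# string/boolean/integer for literals. No RDF library exists in this R
# stack, so the Turtle grammar subset the package needs is implemented
# here; RDF/XML rides on xml2/libxml2.

NS <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  xsd  = "http://www.w3.org/2001/XMLSchema#"
)
q <- function(x) {   # "rdf:type" -> full IRI
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  paste0(NS[[p[1]]], p[2])
}
XSD_OF <- c(string = "string", boolean = "boolean", integer = "integer")

triple_df <- function(subject = character(), predicate = character(),
                      object = character(), type = character(),
                      datatype = character()) {
  data.frame(subject = subject, predicate = predicate, object = object,
             type = type, datatype = datatype)
}

tr <- function(s, p, o, type = "iri", datatype = NA_character_)
  triple_df(s, p, o, type, datatype)

lit <- function(s, p, value, datatype = "string")
  triple_df(s, p, as.character(value), "literal", datatype)

bind_triples <- function(lst) {
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

# ---- schema <-> triples -----------------------------------------------------

schema_iri <- function(schema, label)
  paste0(schema$iri_base, "#", camel_fragment(label))

SPEECH_ACT_PROP <- "hasSpeechActType"
NOTE_PROP <- "hasEditorialNote"

schema_to_triples <- function(schema) {
  base <- schema$iri_base
  piri <- function(name) paste0(base, "#", name)
  ts <- list(tr(base, q("rdf:type"), q("owl:Ontology")))
  for (ap in c(SPEECH_ACT_PROP, NOTE_PROP)) {
    ts[[length(ts) + 1L]] <- tr(piri(ap), q("rdf:type"),
                                q("owl:AnnotationProperty"))
    ts[[length(ts) + 1L]] <- lit(piri(ap), q("rdfs:label"), ap)
  }
  for (cl in schema$classes) {
    iri <- schema_iri(schema, cl$name)
    ts[[length(ts) + 1L]] <- tr(iri, q("rdf:type"), q("owl:Class"))
    ts[[length(ts) + 1L]] <- lit(iri, q("rdfs:label"), cl$name)
    for (p in cl$parents)
      ts[[length(ts) + 1L]] <- tr(iri, q("rdfs:subClassOf"),
                                  schema_iri(schema, p))
    if (cl$speech_act != "none")
      ts[[length(ts) + 1L]] <- lit(iri, piri(SPEECH_ACT_PROP), cl$speech_act)
    if (nzchar(cl$annotation))
      ts[[length(ts) + 1L]] <- lit(iri, q("rdfs:comment"), cl$annotation)
    if (!is.null(cl$note))
      ts[[length(ts) + 1L]] <- lit(iri, piri(NOTE_PROP), cl$note)
  }
  for (p in schema$properties) {
    iri <- piri(p$name)
    kind <- if (p$kind == "object") "owl:ObjectProperty"
            else "owl:DatatypeProperty"
    ts[[length(ts) + 1L]] <- tr(iri, q("rdf:type"), q(kind))
    ts[[length(ts) + 1L]] <- lit(iri, q("rdfs:label"), p$name)
    ts[[length(ts) + 1L]] <- tr(iri, q("rdfs:domain"),
                                schema_iri(schema, p$domain))
    rng <- if (p$kind == "object") schema_iri(schema, p$range)
           else q(paste0("xsd:", XSD_OF[[p$range]]))
    ts[[length(ts) + 1L]] <- tr(iri, q("rdfs:range"), rng)
    if (!is.null(p$inverse_of))
      ts[[length(ts) + 1L]] <- tr(iri, q("owl:inverseOf"),
                                  piri(p$inverse_of))
    if (!is.null(p$sub_property_of))
      ts[[length(ts) + 1L]] <- tr(iri, q("rdfs:subPropertyOf"),
                                  piri(p$sub_property_of))
    if (p$symmetric)
      ts[[length(ts) + 1L]] <- tr(iri, q("rdf:type"),
                                  q("owl:SymmetricProperty"))
  }
  bind_triples(ts)
}

triples_of <- function(tt, s = NULL, p = NULL) {
  keep <- rep(TRUE, nrow(tt))
  if (!is.null(s)) keep <- keep & tt$subject == s
  if (!is.null(p)) keep <- keep & tt$predicate == p
  tt[keep, , drop = FALSE]
}
obj1 <- function(tt, s, p) {
  o <- triples_of(tt, s, p)$object
  if (length(o)) o[[1]] else NULL
}

triples_to_schema <- function(tt) {
  onto <- tt$subject[tt$predicate == q("rdf:type") &
                     tt$object == q("owl:Ontology")]
  if (length(onto) != 1L)
    stop_phido("document does not declare exactly one owl:Ontology",
               "phido_parse_error")
  base <- onto[[1]]
  piri <- function(name) paste0(base, "#", name)
  frag <- function(iri) sub("^.*#", "", iri)
  label_of <- function(iri) obj1(tt, iri, q("rdfs:label")) %||% frag(iri)

  class_iris <- sort(tt$subject[tt$predicate == q("rdf:type") &
                                tt$object == q("owl:Class")])
  classes <- lapply(class_iris, function(iri) {
    parents <- vapply(triples_of(tt, iri, q("rdfs:subClassOf"))$object,
                      label_of, character(1), USE.NAMES = FALSE)
    phido_class(label_of(iri), parents,
                speech_act = obj1(tt, iri, piri(SPEECH_ACT_PROP)) %||% "none",
                annotation = obj1(tt, iri, q("rdfs:comment")) %||% "",
                note = obj1(tt, iri, piri(NOTE_PROP)))
  })

  prop_rows <- tt[tt$predicate == q("rdf:type") &
                  tt$object %in% c(q("owl:ObjectProperty"),
                                   q("owl:DatatypeProperty")), , drop = FALSE]
  props <- lapply(sort(unique(prop_rows$subject)), function(iri) {
    kind <- if (q("owl:ObjectProperty") %in%
                prop_rows$object[prop_rows$subject == iri]) "object"
            else "data"
    rng_iri <- obj1(tt, iri, q("rdfs:range"))
    rng <- if (kind == "object") label_of(rng_iri)
           else names(XSD_OF)[match(sub("^.*#", "", rng_iri), XSD_OF)]
    inv <- obj1(tt, iri, q("owl:inverseOf"))
    sup <- obj1(tt, iri, q("rdfs:subPropertyOf"))
    phido_property(frag(iri), kind,
                   domain = label_of(obj1(tt, iri, q("rdfs:domain"))),
                   range = rng,
                   inverse_of = if (!is.null(inv)) frag(inv),
                   sub_property_of = if (!is.null(sup)) frag(sup),
                   symmetric = any(triples_of(tt, iri, q("rdf:type"))$object ==
                                   q("owl:SymmetricProperty")))
  })
  phido_schema(classes, props, iri_base = base)
}

# ---- Turtle -----------------------------------------------------------------

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}
ttl_unescape <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

ttl_term <- function(iri, prefixes) {
  for (k in seq_along(prefixes)) {
    ns <- prefixes[[k]]
    if (startsWith(iri, ns)) {
      local <- substring(iri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", local) || local == "")
        return(paste0(names(prefixes)[k], ":", local))
    }
  }
  paste0("<", iri, ">")
}

ttl_object <- function(row, prefixes) {
  if (row$type == "iri") return(ttl_term(row$object, prefixes))
  dt <- row$datatype
  if (identical(dt, "boolean") || identical(dt, "integer")) return(row$object)
  paste0("\"", ttl_escape(row$object), "\"")
}

write_turtle_text <- function(tt, base = NULL) {
  prefixes <- NS
  if (!is.null(base)) prefixes <- c(prefixes, c(`:` = paste0(base, "#")))
  names(prefixes)[names(prefixes) == ":"] <- ""
  hdr <- vapply(seq_along(prefixes), function(i)
    sprintf("@prefix %s: <%s> .", names(prefixes)[i], prefixes[i]),
    character(1))
  body <- character()
  for (s in unique(tt$subject)) {
    rows <- tt[tt$subject == s, , drop = FALSE]
    po <- vapply(seq_len(nrow(rows)), function(i) {
      pred <- if (rows$predicate[i] == q("rdf:type")) "a"
              else ttl_term(rows$predicate[i], prefixes)
      paste0("    ", pred, " ", ttl_object(rows[i, ], prefixes))
    }, character(1))
    body <- c(body,
              paste0(ttl_term(s, prefixes), "\n",
                     paste(po, collapse = " ;\n"), " ."))
  }
  paste0(paste(hdr, collapse = "\n"), "\n\n",
         paste(body, collapse = "\n\n"), "\n")
}

ttl_tokenize <- function(text) {
  tokens <- list(); i <- 1L; n <- nchar(text)
  chr <- function(k) substr(text, k, k)
  push <- function(kind, value)
    tokens[[length(tokens) + 1L]] <<- list(kind = kind, value = value)
  while (i <= n) {
    c0 <- chr(i)
    if (grepl("[ \t\r\n]", c0)) { i <- i + 1L; next }
    if (c0 == "#") { while (i <= n && chr(i) != "\n") i <- i + 1L; next }
    if (c0 == "<") {
      j <- regexpr(">", substring(text, i + 1L), fixed = TRUE)
      if (j < 0) stop_phido("unterminated IRI in Turtle input",
                            "phido_parse_error")
      push("iri", substr(text, i + 1L, i + j - 1L)); i <- i + j + 1L; next
    }
    if (c0 == "\"") {
      j <- i + 1L; buf <- character()
      while (j <= n) {
        cj <- chr(j)
        if (cj == "\\") { buf <- c(buf, substr(text, j, j + 1L)); j <- j + 2L }
        else if (cj == "\"") break
        else { buf <- c(buf, cj); j <- j + 1L }
      }
      if (j > n) stop_phido("unterminated literal in Turtle input",
                            "phido_parse_error")
      push("literal", ttl_unescape(paste(buf, collapse = "")))
      i <- j + 1L
      if (substr(text, i, i + 1L) == "^^") {
        i <- i + 2L
        m <- regmatches(substring(text, i),
                        regexpr("^(<[^>]*>|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*)",
                                substring(text, i)))
        if (!length(m)) stop_phido("malformed datatype in Turtle input",
                                   "phido_parse_error")
        push("datatype", gsub("^<|>$", "", m))
        i <- i + nchar(m)
      } else if (chr(i) == "@") {  # language tag: keep literal, drop tag
        m <- regmatches(substring(text, i),
                        regexpr("^@[A-Za-z0-9-]+", substring(text, i)))
        i <- i + nchar(m)
      }
      next
    }
    if (c0 %in% c(".", ";", ",")) { push("punct", c0); i <- i + 1L; next }
    if (c0 %in% c("[", "]", "(", ")"))
      stop_phido("blank nodes and collections are not supported",
                 "phido_parse_error")
    m <- regmatches(substring(text, i),
                    regexpr("^[^ \t\r\n;,.#]+", substring(text, i)))
    if (!length(m) || !nzchar(m))
      stop_phido(sprintf("unexpected character '%s' in Turtle input", c0),
                 "phido_parse_error")
    if (m %in% c("@prefix", "@base")) push("directive", m)
    else if (m == "a") push("a", m)
    else if (m %in% c("true", "false")) push("boolean", m)
    else if (grepl("^[+-]?[0-9]+$", m)) push("integer", m)
    else if (grepl(":", m, fixed = TRUE)) push("pname", m)
    else stop_phido(sprintf("unrecognised Turtle token '%s'", m),
                    "phido_parse_error")
    i <- i + nchar(m)
  }
  tokens
}

parse_turtle <- function(text) {
  toks <- ttl_tokenize(text)
  prefixes <- list(); out <- list(); i <- 1L
  n <- length(toks)
  peek <- function() if (i <= n) toks[[i]] else NULL
  take <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  expand <- function(tok) {
    if (tok$kind == "iri") return(tok$value)
    if (tok$kind == "a") return(q("rdf:type"))
    if (tok$kind == "pname") {
      p <- sub(":.*$", "", tok$value); local <- sub("^[^:]*:", "", tok$value)
      if (p == "") p <- "_default"
      ns <- prefixes[[p]] %||% stop_phido(
        sprintf("undeclared prefix '%s:'", p), "phido_parse_error")
      return(paste0(ns, local))
    }
    stop_phido("expected an IRI term", "phido_parse_error")
  }
  read_object <- function() {
    tok <- take()
    if (tok$kind %in% c("iri", "pname", "a"))
      return(list(object = expand(tok), type = "iri",
                  datatype = NA_character_))
    if (tok$kind == "boolean")
      return(list(object = tok$value, type = "literal", datatype = "boolean"))
    if (tok$kind == "integer")
      return(list(object = tok$value, type = "literal", datatype = "integer"))
    if (tok$kind == "literal") {
      dt <- "string"
      nxt <- peek()
      if (!is.null(nxt) && nxt$kind == "datatype") {
        take()
        short <- sub("^.*#", "", nxt$value)
        dt <- if (short %in% XSD_OF) short else "string"
      }
      return(list(object = tok$value, type = "literal", datatype = dt))
    }
    stop_phido("expected an object term", "phido_parse_error")
  }
  while (i <= n) {
    tok <- peek()
    if (tok$kind == "directive") {
      take()
      if (tok$value == "@prefix") {
        pn <- take(); iri <- take(); dot <- take()
        key <- sub(":$", "", pn$value)
        if (key == "") key <- "_default"
        prefixes[[key]] <- iri$value
      } else { take(); take() }
      next
    }
    subj <- expand(take())
    repeat {
      pred <- expand(take())
      repeat {
        o <- read_object()
        out[[length(out) + 1L]] <- triple_df(subj, pred, o$object, o$type,
                                             o$datatype)
        sep <- take()
        if (sep$kind != "punct")
          stop_phido("expected '.', ';' or ',' in Turtle input",
                     "phido_parse_error")
        if (sep$value != ",") break
      }
      if (sep$value == ".") break
      # ';' may be followed directly by '.' (trailing semicolon)
      if (!is.null(peek()) && peek()$kind == "punct" &&
          peek()$value == ".") { take(); break }
    }
  }
  if (length(out)) bind_triples(out) else triple_df()
}

# ---- RDF/XML ----------------------------------------------------------------

write_rdfxml_text <- function(tt, base = NULL) {
  # every predicate namespace must be declared on the root element
  pred_ns <- unique(sub("#[^#]*$", "#", tt$predicate))
  extra <- setdiff(pred_ns, unname(NS))
  extra_names <- if (length(extra)) paste0("ns", seq_along(extra))
                 else character()
  names(extra) <- extra_names
  allns <- c(NS, extra)
  attrs <- setNames(as.list(unname(allns)),
                    paste0("xmlns:", names(allns)))
  doc <- do.call(xml2::xml_new_root, c(list("rdf:RDF"), attrs))
  pname_of <- function(pred) {
    hit <- which(vapply(allns, function(ns) startsWith(pred, ns),
                        logical(1)))[1]
    paste0(names(allns)[hit], ":", substring(pred, nchar(allns[hit]) + 1L))
  }
  for (s in unique(tt$subject)) {
    node <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    rows <- tt[tt$subject == s, , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      pname <- pname_of(rows$predicate[k])
      if (rows$type[k] == "iri")
        xml2::xml_add_child(node, pname, "rdf:resource" = rows$object[k])
      else {
        kid <- xml2::xml_add_child(node, pname, rows$object[k])
        if (!rows$datatype[k] %in% c(NA, "string"))
          xml2::xml_set_attr(kid, "rdf:datatype",
                             paste0(NS[["xsd"]], rows$datatype[k]))
      }
    }
  }
  as.character(doc)
}

parse_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  nsmap <- xml2::xml_ns(doc)
  out <- list()
  for (node in xml2::xml_children(doc)) {
    subj <- xml2::xml_attr(node, "about")
    if (is.na(subj)) next
    tname <- node_full_name(node, nsmap)
    # typed node element (<owl:Class rdf:about=...>) => rdf:type triple
    if (!is.na(tname) && tname != q("rdf:Description"))
      out[[length(out) + 1L]] <- tr(subj, q("rdf:type"), tname)
    for (kid in xml2::xml_children(node)) {
      pred <- node_full_name(kid, nsmap)
      if (is.na(pred))
        stop_phido("property element without a namespace in RDF/XML input",
                   "phido_parse_error")
      res <- xml2::xml_attr(kid, "resource")
      if (!is.na(res))
        out[[length(out) + 1L]] <- tr(subj, pred, res)
      else {
        dt_attr <- xml2::xml_attr(kid, "datatype")
        dt <- if (is.na(dt_attr)) "string" else {
          short <- sub("^.*#", "", dt_attr)
          if (short %in% XSD_OF) short else "string"
        }
        out[[length(out) + 1L]] <- lit(subj, pred, xml2::xml_text(kid), dt)
      }
    }
  }
  if (length(out)) bind_triples(out) else triple_df()
}

# full IRI of an element's qualified name, resolved against the document's
# namespace map (element-local xmlns declarations are collected there too)
node_full_name <- function(node, nsmap) {
  qn <- xml2::xml_name(node, ns = nsmap)
  if (!grepl(":", qn, fixed = TRUE)) return(NA_character_)
  pfx <- sub(":.*$", "", qn)
  local <- sub("^[^:]*:", "", qn)
  uri <- unname(nsmap[pfx])
  if (is.na(uri)) NA_character_ else paste0(uri, local)
}

# ---- public surface ---------------------------------------------------------

#' Serialize a schema to OWL2
#'
#' @param schema a `phido_schema`.
#' @param path optional file to write.
#' @param dialect `"turtle"` or `"rdfxml"`.
#' @return the document text, invisibly when `path` is given.
#' @export
serialize_schema <- function(schema, path = NULL,
                             dialect = c("turtle", "rdfxml")) {
  if (length(dialect) == 1L && !dialect %in% c("turtle", "rdfxml"))
    stop_phido(sprintf(
      "unknown dialect '%s'; supported dialects: turtle, rdfxml", dialect),
      "phido_dialect_error")
  dialect <- match.arg(dialect)
  tt <- schema_to_triples(schema)
  text <- if (dialect == "turtle") write_turtle_text(tt, schema$iri_base)
          else write_rdfxml_text(tt, schema$iri_base)
  if (!is.null(path)) { writeLines(text, path); return(invisible(text)) }
  text
}

#' Read RDF triples from Turtle or RDF/XML
#'
#' @param x a file path or the document text itself.
#' @param dialect `"auto"` (default), `"turtle"` or `"rdfxml"`.
#' @return the triple table (subject, predicate, object, type, datatype).
#' @export
read_triples <- function(x, dialect = c("auto", "turtle", "rdfxml")) {
  dialect <- match.arg(dialect)
  text <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "\n") else
    paste(x, collapse = "\n")
  if (dialect == "auto")
    dialect <- if (grepl("^\\s*(<\\?xml|<rdf:RDF)", text)) "rdfxml"
               else "turtle"
  if (dialect == "turtle") parse_turtle(text) else parse_rdfxml(text)
}

#' Parse an OWL2 document back into a schema
#'
#' Inverse of [serialize_schema()]: round-trips classes, parents, speech-act
#' annotations, comments and property declarations.
#'
#' @inheritParams read_triples
#' @return a `phido_schema`.
#' @export
parse_schema <- function(x, dialect = c("auto", "turtle", "rdfxml")) {
  triples_to_schema(read_triples(x, dialect))
}
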