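## Reading and writing the knowledge base.
##
## The canonical plain-text dialect is shaped like the Manchester-syntax
## fragments of the published class definitions, one block per class, so
## those definitions work as literal fixtures. OWL files (Turtle / RDF-XML)
## can be read (not written); the readers cover the constructs the ontology
## actually uses: named classes, rdfs:subClassOf, only/some restrictions,
## union-of-atoms fillers, labels/synonyms/descriptions and annotation
## properties. Any class outside the ontology's namespace becomes a MIREOT
## external term reference.

BDO_NS <- "http://purl.org/skeletome/bonedysplasia#"

EXTERNAL_NS <- c(
  HP      = "http://purl.org/obo/owl/HP#",
  PATO    = "http://purl.org/obo/owl/PATO#",
  FMA     = "http://purl.org/org/sig/ont/fma#",
  NCI     = "http://ncicb.nci.nih.gov/xml/owl/EVS/Thesaurus.owl#",
  REAMS   = "http://d-reams.org/ontology#",
  UO      = "http://purl.org/obo/owl/UO#",
  OMIM    = "http://purl.org/omim#",
  MeSH    = "http://purl.org/mesh#",
  UniProt = "http://purl.org/uniprot#",
  UMLS    = "http://purl.org/umls#"
)

quote_str <- function(x) {
  paste0("\"", gsub("\"", "\\\\\"", gsub("\\\\", "\\\\\\\\", x)), "\"")
}

unquote_str <- function(x) {
  x <- sub("^\"", "", sub("\"$", "", trimws(x)))
  gsub("\\\\(.)", "\\1", x)
}

## ---------------------------------------------------------------------------
## Canonical dialect: writer

#' Serialize a knowledge base to the canonical text dialect
#'
#' Deterministic: metadata first, external terms sorted by id, then one
#' block per class sorted by id. `load_kb(write_kb(kb, path))` reproduces
#' the knowledge base structurally ([kb_equal()]).
#'
#' @param kb A `bd_kb`.
#' @return A character scalar holding the document.
#' @export
serialize_kb <- function(kb) {
  stopifnot(inherits(kb, "bd_kb"))
  out <- c("# canonical knowledge base", "Ontology:")
  md <- kb$metadata
  out <- c(out,
           paste0("  dc:title ", quote_str(md$title)),
           paste0("  dc:creator ", quote_str(md$creator)),
           paste0("  dc:contributor ", quote_str(md$contributor)),
           paste0("  dc:publisher ", quote_str(md$publisher)),
           paste0("  version ", quote_str(md$version)),
           "")
  for (id in sort(names(kb$external))) {
    ref <- kb$external[[id]]
    out <- c(out,
             paste0("ExternalTerm: ", id),
             paste0("  Source: ", ref$source),
             paste0("  Label: ", quote_str(ref$label)))
    if (nzchar(ref$parent_hint))
      out <- c(out, paste0("  Parent: ", ref$parent_hint))
    out <- c(out, "")
  }
  for (id in sort(names(kb$classes))) {
    cls <- kb$classes[[id]]
    out <- c(out,
             paste0("Class: ", id),
             paste0("  Pillar: ", cls$pillar),
             paste0("  Label: ", quote_str(cls$label)))
    for (al in cls$alt_labels)
      out <- c(out, paste0("  AltLabel: ", quote_str(al)))
    if (nzchar(cls$description))
      out <- c(out, paste0("  Description: ", quote_str(cls$description)))
    for (p in sort(cls$parents))
      out <- c(out, paste0("  Parent: ", p))
    for (a in cls$axioms)
      out <- c(out, paste0("  SubClassOf: ", serialize_class_expression(a)))
    for (k in sort(names(cls$annotations)))
      out <- c(out, paste0("  Annotation: ", k, " ",
                           quote_str(cls$annotations[[k]])))
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write a knowledge base to a file
#'
#' @param kb A `bd_kb`.
#' @param path Output file path.
#' @param format Only `"canonical"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path, format = "canonical") {
  format <- match.arg(format, "canonical")
  txt <- serialize_kb(kb)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Canonical dialect: parser

parse_canonical <- function(lines) {
  ## returns list(metadata=, externals=list, classes=list of raw blocks)
  metadata <- list(title = "", creator = "", contributor = "",
                   publisher = "", version = "")
  externals <- list()
  classes <- list()
  block <- NULL

  flush_block <- function() {
    if (is.null(block)) return(invisible())
    if (block$type == "external") {
      externals[[length(externals) + 1L]] <<- block
    } else if (block$type == "class") {
      classes[[length(classes) + 1L]] <<- block
    } else {
      metadata <<- utils::modifyList(metadata, block$fields)
    }
    block <<- NULL
  }

  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    if (grepl("^[[:space:]]*(#|$)", raw)) next
    if (grepl("^Ontology:", raw)) {
      flush_block()
      block <- list(type = "ontology", fields = list())
      next
    }
    m <- regmatches(raw, regexec("^ExternalTerm:[[:space:]]+(\\S+)[[:space:]]*$",
                                 raw))[[1]]
    if (length(m) == 2L) {
      flush_block()
      block <- list(type = "external", id = m[2], source = NA_character_,
                    label = "", parent_hint = "")
      next
    }
    m <- regmatches(raw, regexec("^Class:[[:space:]]+(\\S+)[[:space:]]*$",
                                 raw))[[1]]
    if (length(m) == 2L) {
      flush_block()
      block <- list(type = "class", id = m[2], pillar = NA_character_,
                    label = NULL, alt_labels = character(0),
                    description = "", parents = character(0),
                    axioms = list(), annotations = character(0))
      next
    }
    m <- regmatches(raw, regexec("^[[:space:]]+([A-Za-z:_]+)[[:space:]]+(.*)$",
                                 raw))[[1]]
    if (length(m) != 3L || is.null(block))
      stop("canonical parse failure at line ", ln, ": ", raw, call. = FALSE)
    key <- sub(":$", "", m[2])
    val <- trimws(m[3])
    if (block$type == "ontology") {
      slot <- c("dc:title" = "title", "dc:creator" = "creator",
                "dc:contributor" = "contributor",
                "dc:publisher" = "publisher", "version" = "version")[m[2]]
      if (is.na(slot))
        stop("canonical parse failure at line ", ln,
             ": unknown metadata key ", m[2], call. = FALSE)
      block$fields[[unname(slot)]] <- unquote_str(val)
    } else if (block$type == "external") {
      switch(key,
             Source = { block$source <- val },
             Label = { block$label <- unquote_str(val) },
             Parent = { block$parent_hint <- val },
             stop("canonical parse failure at line ", ln,
                  ": unknown external key ", key, call. = FALSE))
    } else {
      switch(key,
             Pillar = { block$pillar <- val },
             Label = { block$label <- unquote_str(val) },
             AltLabel = { block$alt_labels <- c(block$alt_labels,
                                                unquote_str(val)) },
             Description = { block$description <- unquote_str(val) },
             Parent = { block$parents <- c(block$parents, val) },
             SubClassOf = {
               parsed <- parse_class_expression(val)
               if (inherits(parsed, "bd_expr")) {
                 if (parsed$kind != "atom")
                   stop("canonical parse failure at line ", ln,
                        ": a plain SubClassOf value must be a named class",
                        call. = FALSE)
                 block$parents <- c(block$parents, parsed$id)
               } else {
                 block$axioms <- c(block$axioms, parsed)
               }
             },
             Annotation = {
               am <- regmatches(val, regexec("^(\\S+)[[:space:]]+(.*)$",
                                             val))[[1]]
               if (length(am) != 3L)
                 stop("canonical parse failure at line ", ln, call. = FALSE)
               ann <- stats::setNames(unquote_str(am[3]), am[2])
               block$annotations <- c(block$annotations, ann)
             },
             stop("canonical parse failure at line ", ln,
                  ": unknown class key ", key, call. = FALSE))
    }
  }
  flush_block()
  list(metadata = metadata, externals = externals, classes = classes)
}

## ---------------------------------------------------------------------------
## Assembly shared by all loaders

## Infer the pillar of a raw class block from its ancestry when the block
## does not carry an explicit pillar (OWL input).
infer_pillars <- function(blocks) {
  parent_of <- lapply(blocks, `[[`, "parents")
  names(parent_of) <- vapply(blocks, `[[`, character(1), "id")
  find_pillar <- function(id, seen = character(0)) {
    if (is_root_id(id)) return(KB_ROOTS[[id]])
    if (id %in% seen) return(NA_character_)
    ps <- parent_of[[id]]
    if (is.null(ps)) return(NA_character_)
    for (p in ps) {
      pil <- find_pillar(p, c(seen, id))
      if (!is.na(pil)) return(pil)
    }
    NA_character_
  }
  for (i in seq_along(blocks)) {
    if (is.na(blocks[[i]]$pillar %||% NA_character_)) {
      pil <- find_pillar(blocks[[i]]$id)
      if (is.na(pil))
        stop("cannot infer pillar of class ", blocks[[i]]$id, call. = FALSE)
      blocks[[i]]$pillar <- pil
    }
  }
  blocks
}

assemble_kb <- function(parsed) {
  kb <- empty_kb(title = parsed$metadata$title,
                 creator = parsed$metadata$creator,
                 contributor = parsed$metadata$contributor,
                 publisher = parsed$metadata$publisher,
                 version = parsed$metadata$version)
  for (b in parsed$externals) {
    if (is.na(b$source)) b$source <- external_source_of(b$id)
    kb <- add_external_ref(kb, external_ref(b$id, b$source, b$label,
                                            b$parent_hint))
  }
  blocks <- infer_pillars(parsed$classes)
  for (b in blocks) {
    cls <- class_def(b$id, b$pillar, label = b$label %||% b$id,
                     alt_labels = b$alt_labels, description = b$description,
                     parents = b$parents, axioms = b$axioms,
                     annotations = b$annotations)
    if (is_root_id(cls$id)) {
      if (!identical(cls$pillar, KB_ROOTS[[cls$id]]))
        stop("root class ", cls$id, " declared with pillar ", cls$pillar,
             call. = FALSE)
      kb$classes[[cls$id]] <- cls
    } else {
      kb$classes[[cls$id]] <- cls   # low level; checks follow
    }
  }
  cyc <- cyclic_class_ids(kb)
  if (length(cyc))
    stop("subclass cycle among: ", paste(cyc, collapse = ", "), call. = FALSE)
  v <- check_tbox(kb)
  warn <- attr(v, "warnings")
  if (nrow(v))
    warn <- c(warn, sprintf("%s/%s: %s (%s)", v$subject, v$relation,
                            v$kind, v$message))
  attr(kb, "load_warnings") <- warn
  kb
}

#' Load a knowledge base
#'
#' Reads the canonical text dialect, or an OWL file in Turtle or RDF/XML.
#' The subclass graph is checked (a cycle is an error); axioms violating the
#' relation registry's domain/range vocabulary are reported in
#' `attr(result, "load_warnings")` and loading continues.
#'
#' @param path Input file.
#' @param format `"canonical"` (default), `"turtle"`, or `"rdfxml"`.
#' @return A `bd_kb`.
#' @export
load_kb <- function(path, format = c("canonical", "turtle", "rdfxml")) {
  format <- match.arg(format)
  parsed <- switch(format,
                   canonical = parse_canonical(readLines(path, warn = FALSE)),
                   turtle = parse_turtle(readLines(path, warn = FALSE)),
                   rdfxml = parse_rdfxml(path))
  assemble_kb(parsed)
}

## ---------------------------------------------------------------------------
## External-term table (TSV)

#' Read / write the external-term table
#'
#' TSV with columns `id`, `source`, `label`, `parent_hint`.
#'
#' @param path File path.
#' @return `read_external_terms()` returns a list of [external_ref()]
#'   objects.
#' @export
read_external_terms <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(df)), function(i)
    external_ref(df$id[i], df$source[i], df$label[i],
                 df$parent_hint[i] %||% ""))
}

#' @rdname read_external_terms
#' @param kb A `bd_kb` whose external terms are written.
#' @export
write_external_terms <- function(kb, path) {
  ids <- sort(names(kb$external))
  df <- data.frame(
    id = ids,
    source = vapply(ids, function(i) kb$external[[i]]$source, character(1)),
    label = vapply(ids, function(i) kb$external[[i]]$label, character(1)),
    parent_hint = vapply(ids, function(i) kb$external[[i]]$parent_hint,
                         character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## URI mapping shared by the OWL readers

uri_to_id <- function(uri) {
  if (startsWith(uri, BDO_NS)) return(substring(uri, nchar(BDO_NS) + 1L))
  for (src in names(EXTERNAL_NS)) {
    ns <- EXTERNAL_NS[[src]]
    if (startsWith(uri, ns))
      return(paste0(src, ":", substring(uri, nchar(ns) + 1L)))
  }
  NA_character_
}

id_is_external <- function(id) grepl(":", id, fixed = TRUE)

## Convert collected per-class raw axioms (relation, quant, atom ids) into
## bd_axiom objects, merging only/some pairs.
raw_axioms_to_bd <- function(rax) {
  axs <- lapply(rax, function(r)
    axiom(r$relation, r$quant,
          if (length(r$atoms) == 1L) expr_atom(r$atoms)
          else do.call(expr_or, lapply(r$atoms, expr_atom))))
  merge_only_some(axs)
}

## Build the parsed-block structure from per-URI property lists.
owl_to_blocks <- function(nodes, metadata) {
  externals <- list()
  classes <- list()
  for (id in names(nodes)) {
    nd <- nodes[[id]]
    if (id_is_external(id)) {
      externals[[length(externals) + 1L]] <- list(
        id = id, source = external_source_of(id),
        label = nd$label %||% id,
        parent_hint = if (length(nd$parents)) nd$parents[[1L]] else "")
    } else {
      classes[[length(classes) + 1L]] <- list(
        id = id, pillar = NA_character_,
        label = nd$label %||% id,
        alt_labels = nd$alt_labels %||% character(0),
        description = nd$description %||% "",
        parents = Filter(Negate(id_is_external),
                         nd$parents %||% character(0)),
        axioms = raw_axioms_to_bd(nd$axioms %||% list()),
        annotations = nd$annotations %||% character(0))
    }
  }
  list(metadata = metadata, externals = externals, classes = classes)
}

## ---------------------------------------------------------------------------
## RDF/XML reader (xml2)

parse_rdfxml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  metadata <- list(title = "", creator = "", contributor = "",
                   publisher = "", version = "")
  onto <- xml2::xml_find_first(doc, ".//owl:Ontology", ns)
  if (!inherits(onto, "xml_missing")) {
    get1 <- function(xp) {
      n <- xml2::xml_find_first(onto, xp, ns)
      if (inherits(n, "xml_missing")) "" else xml2::xml_text(n)
    }
    metadata$title <- get1("./dc:title")
    metadata$creator <- get1("./dc:creator")
    metadata$contributor <- get1("./dc:contributor")
    metadata$publisher <- get1("./dc:publisher")
    metadata$version <- get1("./owl:versionInfo")
  }
  nodes <- list()
  touch <- function(id) {
    if (is.null(nodes[[id]]))
      nodes[[id]] <<- list(label = NULL, alt_labels = character(0),
                           description = "", parents = character(0),
                           axioms = list(), annotations = character(0))
    invisible()
  }
  about_attr <- function(node) xml2::xml_attr(node, "about")
  resource_attr <- function(node) xml2::xml_attr(node, "resource")

  parse_filler_atoms <- function(node) {
    ## node: the allValuesFrom/someValuesFrom element
    res <- resource_attr(node)
    if (!is.na(res)) return(uri_to_id(res))
    cls <- xml2::xml_find_first(node, "./owl:Class", ns)
    if (inherits(cls, "xml_missing"))
      stop("rdfxml parse failure: unsupported restriction filler",
           call. = FALSE)
    members <- xml2::xml_find_all(cls, "./owl:unionOf/owl:Class", ns)
    if (!length(members))
      stop("rdfxml parse failure: empty union filler", call. = FALSE)
    vapply(members, function(mem) uri_to_id(about_attr(mem)), character(1))
  }

  for (cl in xml2::xml_find_all(doc, "./owl:Class", ns)) {
    uri <- about_attr(cl)
    id <- uri_to_id(uri)
    if (is.na(id)) next
    touch(id)
    for (child in xml2::xml_children(cl)) {
      nm <- xml2::xml_name(child, ns)
      if (nm == "rdfs:label") {
        nodes[[id]]$label <- trimws(gsub("[[:space:]]+", " ",
                                         xml2::xml_text(child)))
      } else if (nm == "skos:altLabel") {
        nodes[[id]]$alt_labels <- c(nodes[[id]]$alt_labels,
                                    trimws(xml2::xml_text(child)))
      } else if (nm == "skos:description") {
        nodes[[id]]$description <- trimws(gsub("[[:space:]]+", " ",
                                               xml2::xml_text(child)))
      } else if (nm == "rdfs:subClassOf") {
        res <- resource_attr(child)
        if (!is.na(res)) {
          pid <- uri_to_id(res)
          if (!is.na(pid))
            nodes[[id]]$parents <- c(nodes[[id]]$parents, pid)
          next
        }
        restr <- xml2::xml_find_first(child, "./owl:Restriction", ns)
        if (inherits(restr, "xml_missing")) next
        prop <- xml2::xml_find_first(restr, "./owl:onProperty", ns)
        rel_uri <- resource_attr(prop)
        rel <- uri_to_id(rel_uri)
        for (quant_el in c("owl:allValuesFrom", "owl:someValuesFrom")) {
          q <- xml2::xml_find_first(restr, paste0("./", quant_el), ns)
          if (inherits(q, "xml_missing")) next
          quant <- if (quant_el == "owl:allValuesFrom") "only" else "some"
          nodes[[id]]$axioms <- c(nodes[[id]]$axioms,
                                  list(list(relation = rel, quant = quant,
                                            atoms = parse_filler_atoms(q))))
        }
      } else if (grepl("^bdo:", nm)) {
        key <- sub("^bdo:", "", nm)
        ann <- stats::setNames(xml2::xml_text(child), key)
        nodes[[id]]$annotations <- c(nodes[[id]]$annotations, ann)
      }
    }
  }
  owl_to_blocks(nodes, metadata)
}

## ---------------------------------------------------------------------------
## Turtle reader (subset)

ttl_tokenize <- function(lines) {
  text <- paste(lines, collapse = "\n")
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value)
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      j <- regexpr("\n", substr(text, i, n), fixed = TRUE)
      i <- if (j == -1L) n + 1L else i + j
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(ch, ch); i <- i + 1L; next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j == -1L) stop("turtle parse failure: unterminated IRI",
                         call. = FALSE)
      push("iri", substr(text, i + 1L, i + j - 2L))
      i <- i + j
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      val <- character(0)
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { val <- c(val, substr(text, j + 1L, j + 1L)); j <- j + 2L; next }
        if (cj == "\"") break
        val <- c(val, cj); j <- j + 1L
      }
      if (j > n) stop("turtle parse failure: unterminated string",
                      call. = FALSE)
      push("string", paste(val, collapse = ""))
      i <- j + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^@?[A-Za-z0-9_:.-]+", substr(text, i, n)))
    if (!length(m))
      stop("turtle parse failure: unexpected character '", ch, "'",
           call. = FALSE)
    ## a trailing '.' ends the statement, not the name
    while (endsWith(m, ".")) m <- substr(m, 1L, nchar(m) - 1L)
    if (!nzchar(m)) { push(".", "."); i <- i + 1L; next }
    type <- if (startsWith(m, "@")) "directive"
            else if (m == "a") "a"
            else if (grepl(":", m, fixed = TRUE)) "pname"
            else "name"
    push(type, m)
    i <- i + nchar(m)
  }
  tokens
}

parse_turtle <- function(lines) {
  tokens <- ttl_tokenize(lines)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  nxt <- function() { t <- peek(); pos <<- pos + 1L; t }
  expect <- function(type) {
    t <- nxt()
    if (is.null(t) || t$type != type)
      stop("turtle parse failure: expected ", type, call. = FALSE)
    t
  }
  prefixes <- list()
  resolve <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type == "pname") {
      sp <- regmatches(tok$value,
                       regexec("^([A-Za-z0-9_-]*):(.*)$", tok$value))[[1]]
      base <- prefixes[[sp[2]]]
      if (is.null(base))
        stop("turtle parse failure: unknown prefix '", sp[2], "'",
             call. = FALSE)
      return(paste0(base, sp[3]))
    }
    stop("turtle parse failure: expected IRI or prefixed name",
         call. = FALSE)
  }

  triples <- list()
  emit <- function(s, p, o)
    triples[[length(triples) + 1L]] <<- list(s = s, p = p, o = o)
  bnode_n <- 0L

  parse_object <- function() {
    t <- peek()
    if (is.null(t)) stop("turtle parse failure: missing object",
                         call. = FALSE)
    if (t$type == "string") { nxt(); return(list(kind = "lit", value = t$value)) }
    if (t$type == "[") {
      nxt()
      bnode_n <<- bnode_n + 1L
      bid <- paste0("_:b", bnode_n)
      parse_pred_obj_list(bid)
      expect("]")
      return(list(kind = "node", value = bid))
    }
    if (t$type == "(") {
      nxt()
      members <- list()
      while (!is.null(peek()) && peek()$type != ")")
        members <- c(members, list(parse_object()))
      expect(")")
      return(list(kind = "coll", value = members))
    }
    tok <- nxt()
    list(kind = "node", value = resolve(tok))
  }

  parse_pred_obj_list <- function(subj) {
    repeat {
      t <- peek()
      if (is.null(t) || t$type %in% c(".", "]")) return(invisible())
      pred <- if (t$type == "a") { nxt(); "rdf:type" } else resolve(nxt())
      repeat {
        obj <- parse_object()
        emit(subj, pred, obj)
        if (!is.null(peek()) && peek()$type == ",") { nxt(); next }
        break
      }
      if (!is.null(peek()) && peek()$type == ";") { nxt(); next }
      return(invisible())
    }
  }

  while (!is.null(peek())) {
    t <- peek()
    if (t$type == "directive") {
      nxt()
      if (t$value == "@prefix") {
        pn <- expect("pname")
        iri <- expect("iri")
        expect(".")
        prefixes[[sub(":$", "", pn$value)]] <- iri$value
      } else stop("turtle parse failure: unsupported directive ", t$value,
                  call. = FALSE)
      next
    }
    subj <- resolve(nxt())
    parse_pred_obj_list(subj)
    expect(".")
  }

  ttl_to_blocks(triples)
}

ttl_to_blocks <- function(triples) {
  ## index triples by subject
  by_subj <- list()
  for (tr in triples)
    by_subj[[tr$s]] <- c(by_subj[[tr$s]], list(tr))
  prop_local <- function(p) {
    id <- uri_to_id(p)
    if (!is.na(id) && !id_is_external(id)) return(id)
    ## well-known vocabulary URIs
    map <- c("http://www.w3.org/2000/01/rdf-schema#label" = "rdfs:label",
             "http://www.w3.org/2000/01/rdf-schema#subClassOf" = "rdfs:subClassOf",
             "http://www.w3.org/2004/02/skos/core#altLabel" = "skos:altLabel",
             "http://www.w3.org/2004/02/skos/core#description" = "skos:description",
             "http://www.w3.org/2002/07/owl#onProperty" = "owl:onProperty",
             "http://www.w3.org/2002/07/owl#allValuesFrom" = "owl:allValuesFrom",
             "http://www.w3.org/2002/07/owl#someValuesFrom" = "owl:someValuesFrom",
             "http://www.w3.org/2002/07/owl#unionOf" = "owl:unionOf",
             "http://www.w3.org/2002/07/owl#versionInfo" = "owl:versionInfo",
             "http://purl.org/dc/terms/title" = "dc:title",
             "http://purl.org/dc/terms/creator" = "dc:creator",
             "http://purl.org/dc/terms/contributor" = "dc:contributor",
             "http://purl.org/dc/terms/publisher" = "dc:publisher",
             "rdf:type" = "rdf:type")
    unname(map[p]) %||% NA_character_
  }
  obj_id <- function(o) {
    if (o$kind != "node") return(NA_character_)
    uri_to_id(o$value)
  }
  restriction_axiom <- function(bid) {
    props <- by_subj[[bid]] %||% list()
    rel <- NULL; quant <- NULL; atoms <- NULL
    for (tr in props) {
      p <- prop_local(tr$p)
      if (identical(p, "owl:onProperty")) rel <- obj_id(tr$o)
      if (identical(p, "owl:allValuesFrom") ||
          identical(p, "owl:someValuesFrom")) {
        quant <- if (identical(p, "owl:allValuesFrom")) "only" else "some"
        if (tr$o$kind == "node" && startsWith(tr$o$value, "_:")) {
          uprops <- by_subj[[tr$o$value]] %||% list()
          for (utr in uprops) {
            if (identical(prop_local(utr$p), "owl:unionOf")) {
              atoms <- vapply(utr$o$value, function(mem)
                uri_to_id(mem$value), character(1))
            }
          }
        } else {
          atoms <- obj_id(tr$o)
        }
      }
    }
    if (is.null(rel) || is.null(quant) || is.null(atoms))
      stop("turtle parse failure: incomplete restriction", call. = FALSE)
    list(relation = rel, quant = quant, atoms = atoms)
  }

  metadata <- list(title = "", creator = "", contributor = "",
                   publisher = "", version = "")
  nodes <- list()
  for (subj in names(by_subj)) {
    if (startsWith(subj, "_:")) next
    props <- by_subj[[subj]]
    is_ontology <- any(vapply(props, function(tr)
      identical(prop_local(tr$p), "rdf:type") && tr$o$kind == "node" &&
        identical(tr$o$value, "http://www.w3.org/2002/07/owl#Ontology"),
      logical(1)))
    if (is_ontology) {
      for (tr in props) {
        p <- prop_local(tr$p)
        if (is.na(p) || tr$o$kind != "lit") next
        slot <- c("dc:title" = "title", "dc:creator" = "creator",
                  "dc:contributor" = "contributor",
                  "dc:publisher" = "publisher",
                  "owl:versionInfo" = "version")[p]
        if (!is.na(slot)) metadata[[slot]] <- tr$o$value
      }
      next
    }
    id <- uri_to_id(subj)
    if (is.na(id)) next
    nd <- list(label = NULL, alt_labels = character(0), description = "",
               parents = character(0), axioms = list(),
               annotations = character(0))
    for (tr in props) {
      p <- prop_local(tr$p)
      if (is.na(p)) next
      if (p == "rdfs:label" && tr$o$kind == "lit") {
        nd$label <- trimws(gsub("[[:space:]]+", " ", tr$o$value))
      } else if (p == "skos:altLabel" && tr$o$kind == "lit") {
        nd$alt_labels <- c(nd$alt_labels, trimws(tr$o$value))
      } else if (p == "skos:description" && tr$o$kind == "lit") {
        nd$description <- trimws(gsub("[[:space:]]+", " ", tr$o$value))
      } else if (p == "rdfs:subClassOf") {
        if (tr$o$kind == "node" && startsWith(tr$o$value, "_:")) {
          nd$axioms <- c(nd$axioms, list(restriction_axiom(tr$o$value)))
        } else {
          pid <- obj_id(tr$o)
          if (!is.na(pid)) nd$parents <- c(nd$parents, pid)
        }
      } else if (p == "rdf:type") {
        ## class declaration; nothing to record
      } else if (!id_is_external(p) && tr$o$kind == "lit" &&
                 p %in% ANNOTATION_KEYS) {
        nd$annotations <- c(nd$annotations, stats::setNames(tr$o$value, p))
      }
    }
    nodes[[id]] <- nd
  }
  owl_to_blocks(nodes, metadata)
}
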