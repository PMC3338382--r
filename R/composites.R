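## Entity-quality phenotype composites.
##
## Phenotype descriptions are decomposed into an anatomical target and a
## quality: an anatomical composite groups anatomical entities (with optional
## anatomical coordinates such as proximal/distal), a quality composite groups
## qualities with qualifiers (e.g. "mildly bowed"), and a phenotypic
## composite ties exactly one target (anatomical entity, anatomical
## composite, or parts that are themselves phenotypic composites) to exactly
## one quality (a quality term or a quality composite).

new_composite_id <- function(kb, prefix) next_counter_id(kb, prefix, sep = "_")

resolve_part <- function(kb, id, what) {
  id <- normalize_term_id(id)
  if (!kb_has_term(kb, id))
    stop("unresolvable ", what, " reference: ", id)
  id
}

or_of <- function(ids) {
  if (length(ids) == 1L) expr_atom(ids) else
    do.call(expr_or, lapply(ids, expr_atom))
}

#' Create an anatomical composite
#'
#' Adds a class under `Anatomical_Composite` holding its parts via
#' `has_part only P and has_part some P` and its anatomical coordinates via
#' `has_anatomical_coordinate` (same universal+existential pattern).
#'
#' @param kb A `bd_kb`.
#' @param parts Character vector (non-empty) of anatomical entity references
#'   (FMA external terms) and/or anatomical composite ids.
#' @param coordinates Character vector of anatomical-coordinate references
#'   (may be empty).
#' @param label Human-readable label.
#' @param description Optional description.
#' @param id Optional explicit id; default allocates the next `AC_` counter.
#' @return The updated knowledge base; the new class id is available as
#'   `attr(result, "last_id")`.
#' @export
make_anatomical_composite <- function(kb, parts, coordinates = character(0),
                                      label, description = "", id = NULL) {
  stopifnot(inherits(kb, "bd_kb"))
  if (!length(parts)) stop("an anatomical composite needs at least one part")
  parts <- vapply(parts, resolve_part, character(1), kb = kb, what = "part")
  coordinates <- vapply(coordinates, resolve_part, character(1),
                        kb = kb, what = "coordinate")
  id <- id %||% new_composite_id(kb, "AC")
  axioms <- list(axiom("has_part", "only_and_some", or_of(parts)))
  if (length(coordinates))
    axioms <- c(axioms, list(axiom("has_anatomical_coordinate",
                                   "only_and_some", or_of(coordinates))))
  kb <- add_class(kb, class_def(id, "anatomical_composite", label = label,
                                description = description,
                                parents = "Anatomical_Composite",
                                axioms = axioms))
  attr(kb, "last_id") <- id
  kb
}

#' Create a quality composite
#'
#' Adds a class under `Quality_Composite` holding its qualities via
#' `has_part` and its qualifiers via `has_qualifier` (both as
#' universal+existential pairs).
#'
#' @param kb A `bd_kb`.
#' @param qualities Character vector (non-empty) of quality references (PATO
#'   external terms).
#' @param qualifiers Character vector of qualifier references (may be empty).
#' @param label Human-readable label.
#' @param description Optional description.
#' @param id Optional explicit id; default allocates the next `QC_` counter.
#' @return The updated knowledge base; new id in `attr(result, "last_id")`.
#' @export
make_quality_composite <- function(kb, qualities, qualifiers = character(0),
                                   label, description = "", id = NULL) {
  stopifnot(inherits(kb, "bd_kb"))
  if (!length(qualities)) stop("a quality composite needs at least one quality")
  qualities <- vapply(qualities, resolve_part, character(1),
                      kb = kb, what = "quality")
  qualifiers <- vapply(qualifiers, resolve_part, character(1),
                       kb = kb, what = "qualifier")
  id <- id %||% new_composite_id(kb, "QC")
  axioms <- list(axiom("has_part", "only_and_some", or_of(qualities)))
  if (length(qualifiers))
    axioms <- c(axioms, list(axiom("has_qualifier", "only_and_some",
                                   or_of(qualifiers))))
  kb <- add_class(kb, class_def(id, "quality_composite", label = label,
                                description = description,
                                parents = "Quality_Composite",
                                axioms = axioms))
  attr(kb, "last_id") <- id
  kb
}

#' Create a phenotypic composite
#'
#' Adds a class under `Phenotypic_Composite` linking exactly one target to
#' exactly one quality, mirroring the disjunctive structure of the
#' phenotypic-composite root definition: the target is either an anatomical
#' entity reference or an anatomical composite (linked via `describes`), or a
#' set of phenotypic composites (linked via `has_part`); the quality is a
#' quality reference or a quality composite (linked via `has_quality`). All
#' links use the universal+existential axiom pattern.
#'
#' @param kb A `bd_kb`.
#' @param target A single anatomical entity reference or anatomical composite
#'   id, or a character vector of phenotypic composite ids.
#' @param quality A single quality reference or quality composite id.
#' @param label Human-readable label; default follows the
#'   `"<quality label> of <target label>"` convention.
#' @param description Optional description.
#' @param id Optional explicit id; default allocates the next `PC_` counter.
#' @return The updated knowledge base; new id in `attr(result, "last_id")`.
#' @export
make_phenotypic_composite <- function(kb, target, quality, label = NULL,
                                      description = "", id = NULL) {
  stopifnot(inherits(kb, "bd_kb"))
  if (!length(target)) stop("a phenotypic composite needs a target")
  target <- vapply(target, resolve_part, character(1), kb = kb,
                   what = "target")
  quality <- resolve_part(kb, quality, "quality")
  target_pillar <- function(x) {
    cls <- kb$classes[[x]]
    if (!is.null(cls)) cls$pillar else paste0("external:",
                                              kb$external[[x]]$source)
  }
  kinds <- vapply(target, target_pillar, character(1))
  if (length(target) > 1L || all(kinds == "phenotypic_composite")) {
    if (!all(kinds == "phenotypic_composite"))
      stop("a multi-part target must consist of phenotypic composite ids")
    target_axiom <- axiom("has_part", "only_and_some", or_of(target))
  } else if (kinds %in% c("anatomical_composite", "external:FMA")) {
    target_axiom <- axiom("describes", "only_and_some", target)
  } else {
    stop("target must be an anatomical entity, an anatomical composite, ",
         "or phenotypic composite ids")
  }
  qcls <- kb$classes[[quality]]
  q_ok <- (!is.null(qcls) && qcls$pillar == "quality_composite") ||
    (is.null(qcls) && kb$external[[quality]]$source == "PATO")
  if (!q_ok)
    stop("quality must be a PATO reference or a quality composite")
  if (is.null(label)) {
    tl <- term_label(kb, target[[1L]])
    ql <- term_label(kb, quality)
    label <- paste(ql, "of", tolower(tl))
  }
  id <- id %||% new_composite_id(kb, "PC")
  kb <- add_class(kb, class_def(
    id, "phenotypic_composite", label = label, description = description,
    parents = "Phenotypic_Composite",
    axioms = list(target_axiom,
                  axiom("has_quality", "only_and_some", quality))))
  attr(kb, "last_id") <- id
  kb
}

#' Label of a term (own class or external reference)
#' @param kb A `bd_kb`.
#' @param id Term id.
#' @return The stored label, or the id itself when unknown.
#' @export
term_label <- function(kb, id) {
  cls <- kb$classes[[id]]
  if (!is.null(cls)) return(cls$label)
  ref <- kb$external[[id]]
  if (!is.null(ref)) return(ref$label)
  id
}

## ---------------------------------------------------------------------------
## Lexicons and dictionary matching

#' Read an annotation lexicon
#'
#' A lexicon is a TSV file with columns `surface_form`, `term_id`, `kind`
#' (`entity`, `quality`, `qualifier`, or any other tag such as `dysplasia` /
#' `phenotype` for text annotation). Several rows may share a `term_id`
#' (label + synonyms + morphological alternates).
#'
#' @param path TSV file path.
#' @return A `data.frame` with those three character columns.
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.delim(path, header = TRUE, sep = "\t",
                           quote = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("surface_form", "term_id", "kind")
  if (!all(need %in% names(lex)))
    stop("lexicon must have columns: ", paste(need, collapse = ", "))
  lex[need]
}

as_lexicon <- function(lexicon) {
  if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
  stopifnot(is.data.frame(lexicon),
            all(c("surface_form", "term_id", "kind") %in% names(lexicon)))
  lexicon$surface_form <- normalize_label(lexicon$surface_form)
  lexicon
}

normalize_label <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

## Left-to-right, longest-match, case-insensitive, non-overlapping dictionary
## matching on word boundaries. Offsets are 0-based half-open on the
## normalized text (whitespace collapsed to single spaces).
lexicon_match <- function(text, lexicon) {
  lexicon <- as_lexicon(lexicon)
  norm <- gsub("[[:space:]]+", " ", trimws(text))
  empty <- data.frame(start = integer(0), end = integer(0),
                      term_id = character(0), surface = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (!nzchar(norm) || !nrow(lexicon)) {
    attr(empty, "text") <- norm
    return(empty)
  }
  hits <- list()
  for (i in seq_len(nrow(lexicon))) {
    surf <- lexicon$surface_form[i]
    if (!nzchar(surf)) next
    pat <- paste0("(?<![A-Za-z0-9])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surf),
                  "(?![A-Za-z0-9])")
    m <- gregexpr(pat, norm, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    hits[[length(hits) + 1L]] <- data.frame(
      start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
      term_id = lexicon$term_id[i], surface = surf,
      kind = lexicon$kind[i], stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    attr(empty, "text") <- norm
    return(empty)
  }
  all_hits <- do.call(rbind, hits)
  ## greedy selection: smallest start, then longest span, then term id
  all_hits <- all_hits[order(all_hits$start, -(all_hits$end - all_hits$start),
                             all_hits$term_id), , drop = FALSE]
  sel <- list()
  cursor <- 0L
  for (i in seq_len(nrow(all_hits))) {
    if (all_hits$start[i] >= cursor) {
      sel[[length(sel) + 1L]] <- all_hits[i, , drop = FALSE]
      cursor <- all_hits$end[i]
    }
  }
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  attr(out, "text") <- norm
  out
}

#' Decompose a phenotype label into entity-quality candidates
#'
#' Splits a phenotype label (e.g. `"Mitral valve prolapse"`) into candidate
#' (anatomical entity, quality, qualifier) tuples using longest-span lexicon
#' matches. Morphological variants ("prolapsed" vs "prolapse") are handled by
#' lexicon alternates, not by a lemmatizer. Matching is stable under
#' whitespace and case normalization of the label.
#'
#' @param label The phenotype label.
#' @param lexicon A lexicon `data.frame` (or TSV path) with `kind` values
#'   `entity`, `quality`, `qualifier`.
#' @return A `data.frame` with columns `entity`, `quality`, `qualifier`
#'   (term ids, `NA` for an absent qualifier), ordered by match position;
#'   zero rows when no entity-quality pair is found. The normalized tokens
#'   not covered by any match are attached as `attr(, "unmatched")`.
#' @examples
#' lex <- data.frame(
#'   surface_form = c("mitral valve", "prolapse", "prolapsed"),
#'   term_id = c("FMA:Mitral_valve", "PATO:PATO_0100001", "PATO:PATO_0100001"),
#'   kind = c("entity", "quality", "quality"))
#' decompose_term("Mitral valve prolapse", lex)
#' @export
decompose_term <- function(label, lexicon) {
  hits <- lexicon_match(normalize_label(label), lexicon)
  norm <- attr(hits, "text")
  entities <- hits[hits$kind == "entity", , drop = FALSE]
  qualities <- hits[hits$kind == "quality", , drop = FALSE]
  qualifiers <- hits[hits$kind == "qualifier", , drop = FALSE]
  qualifier_id <- if (nrow(qualifiers)) qualifiers$term_id[1L] else NA_character_
  out <- data.frame(entity = character(0), quality = character(0),
                    qualifier = character(0), stringsAsFactors = FALSE)
  if (nrow(entities) && nrow(qualities)) {
    grid <- expand.grid(e = seq_len(nrow(entities)),
                        q = seq_len(nrow(qualities)))
    grid <- grid[order(pmin(entities$start[grid$e], qualities$start[grid$q]),
                       grid$e, grid$q), , drop = FALSE]
    out <- data.frame(entity = entities$term_id[grid$e],
                      quality = qualities$term_id[grid$q],
                      qualifier = qualifier_id, stringsAsFactors = FALSE)
  }
  covered <- rep(FALSE, nchar(norm))
  for (i in seq_len(nrow(hits)))
    if (hits$start[i] < hits$end[i])
      covered[(hits$start[i] + 1L):hits$end[i]] <- TRUE
  tokens <- regmatches(norm, gregexpr("[A-Za-z0-9]+", norm))[[1]]
  starts <- as.integer(gregexpr("[A-Za-z0-9]+", norm)[[1]]) - 1L
  unmatched <- tokens[!vapply(seq_along(tokens), function(i)
    all(covered[(starts[i] + 1L):(starts[i] + nchar(tokens[i]))]),
    logical(1))]
  attr(out, "unmatched") <- unmatched
  out
}
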