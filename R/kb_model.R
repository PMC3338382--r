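#' @keywords internal
"_PACKAGE"

## Pillars of the knowledge base. "external" is reserved for MIREOT term
## references, which live in kb$external rather than kb$classes.
PILLARS <- c(
  "dysplasia", "gene", "gene_mutation", "protein",
  "phenotypic_composite", "anatomical_composite", "quality_composite"
)

## Structural roots: one per pillar. The five disease/genotype/phenotype roots
## correspond to the ontology's top-level concepts; the two composite roots
## anchor the entity-quality model.
KB_ROOTS <- c(
  Bone_Dysplasia       = "dysplasia",
  Gene                 = "gene",
  Gene_Mutation        = "gene_mutation",
  Protein              = "protein",
  Phenotypic_Composite = "phenotypic_composite",
  Anatomical_Composite = "anatomical_composite",
  Quality_Composite    = "quality_composite"
)

## Upper-level (BFO/OGMS) grounding of each pillar, kept as metadata tags:
## it carries no computational behaviour in this package.
PILLAR_UPPER_TAGS <- c(
  dysplasia            = "OGMS:OGMS_0000047",
  gene                 = "SNAP:MaterialEntity",
  gene_mutation        = "SNAP:SpecificallyDependentContinuant",
  phenotypic_composite = "OGMS:OGMS_0000023"
)

## Object-property registry: relation -> domain pillar(s).
RELATION_DOMAINS <- list(
  characterized_by          = "dysplasia",
  mode_of_inheritance       = "dysplasia",
  has_locus                 = "gene_mutation",
  mutation_type             = "gene_mutation",
  is_encoded_by             = "protein",
  describes                 = "phenotypic_composite",
  has_quality               = "phenotypic_composite",
  has_qualifier             = "quality_composite",
  has_anatomical_coordinate = "anatomical_composite",
  has_part                  = c("phenotypic_composite", "anatomical_composite",
                                "quality_composite")
)

RELATIONS <- names(RELATION_DOMAINS)

## External subtree roots admitted in each relation's range, alongside the
## internal pillars listed in RELATION_RANGE_PILLARS below.
RELATION_RANGE_ROOTS <- list(
  characterized_by          = c("REAMS:Abnormality", "HP:HP_0000118"),
  mode_of_inheritance       = "HP:HP_0000005",
  has_locus                 = character(0),
  mutation_type             = "NCI:Mutation_Abnormality",
  is_encoded_by             = character(0),
  describes                 = "FMA:Anatomical_entity",
  has_quality               = "PATO:PATO_0001241",
  has_qualifier             = c("PATO:PATO_0000068", "PATO:PATO_0001241"),
  has_anatomical_coordinate = c("FMA:Primary_anatomical_coordinate",
                                "FMA:Secondary_anatomical_coordinate")
)

RELATION_RANGE_PILLARS <- list(
  characterized_by          = c("gene_mutation", "phenotypic_composite"),
  mode_of_inheritance       = character(0),
  has_locus                 = "gene",
  mutation_type             = character(0),
  is_encoded_by             = "gene",
  describes                 = "anatomical_composite",
  has_quality               = "quality_composite",
  has_qualifier             = character(0),
  has_anatomical_coordinate = character(0)
)

## has_part range depends on the owning composite pillar.
HAS_PART_RANGE_PILLARS <- list(
  phenotypic_composite = "phenotypic_composite",
  anatomical_composite = "anatomical_composite",
  quality_composite    = "quality_composite"
)
HAS_PART_RANGE_ROOTS <- list(
  phenotypic_composite = character(0),
  anatomical_composite = "FMA:Anatomical_entity",
  quality_composite    = "PATO:PATO_0001241"
)

## Annotation-property vocabulary: cross-reference keys carried by genes and
## dysplasias, plus the gene-mutation datatype properties.
ANNOTATION_KEYS <- c(
  "omim_no", "uniprot_id", "mesh_id", "umls_cui", "ref_seq",
  "entrezgene_id", "accession_no", "chromosomal_locus",
  "encoding", "offset", "count", "original_content", "mutated_content"
)

EXTERNAL_SOURCES <- c("HP", "PATO", "FMA", "NCI", "REAMS", "UO",
                      "OMIM", "MeSH", "UniProt", "UMLS")

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## Term ids

#' Normalize a term identifier
#'
#' Internal gene (`G`), gene-mutation (`GM`) and protein (`P`) identifiers use
#' an incremental scheme: prefix plus a zero-padded integer. The canonical pad
#' width is 7 digits, but published renderings vary between 5 and 8 digits, so
#' identifiers such as `"GM000001"` are accepted and normalized to
#' `"GM0000001"`. All other identifiers pass through unchanged.
#'
#' @param id Character vector of term identifiers.
#' @return Character vector of the same length with canonical identifiers.
#' @examples
#' normalize_term_id(c("GM000001", "G0000047", "HP:HP_0000238"))
#' @export
normalize_term_id <- function(id) {
  stopifnot(is.character(id))
  m <- regmatches(id, regexec("^(GM|G|P)([0-9]{5,8})$", id))
  vapply(seq_along(id), function(i) {
    if (length(m[[i]]) == 3L) {
      paste0(m[[i]][2L], sprintf("%07d", as.integer(m[[i]][3L])))
    } else {
      id[i]
    }
  }, character(1))
}

is_valid_term_id <- function(id) {
  is.character(id) && length(id) == 1L && !is.na(id) && nzchar(id) &&
    !grepl("[[:space:]\"()]", id)
}

external_source_of <- function(id) sub(":.*$", "", id)

## ---------------------------------------------------------------------------
## Class definitions

#' Create a class definition
#'
#' A class definition is the unit record of the knowledge base: an identifier,
#' the pillar it belongs to, human-readable labels, its parents in the
#' subclass DAG, restriction axioms, and annotation-property values.
#'
#' @param id Term identifier (normalized with [normalize_term_id()]).
#' @param pillar One of `r paste0('"', PILLARS, '"', collapse = ", ")`.
#' @param label Human-readable label (`rdfs:label`); defaults to the id.
#' @param alt_labels Character vector of synonyms (`skos:altLabel`).
#' @param description Free-text description (`skos:description`).
#' @param parents Character vector of parent class ids.
#' @param axioms List of [axiom()] objects.
#' @param annotations Named character vector; names must come from the
#'   annotation-property vocabulary (`omim_no`, `uniprot_id`, `mesh_id`,
#'   `umls_cui`, `ref_seq`, `entrezgene_id`, `accession_no`,
#'   `chromosomal_locus`, and the gene-mutation datatype properties
#'   `encoding`, `offset`, `count`, `original_content`, `mutated_content`).
#' @return An object of class `bd_class`.
#' @export
class_def <- function(id, pillar, label = id, alt_labels = character(0),
                      description = "", parents = character(0),
                      axioms = list(), annotations = character(0)) {
  if (!is_valid_term_id(id)) stop("invalid term id: ", deparse(id))
  id <- normalize_term_id(id)
  pillar <- match.arg(pillar, PILLARS)
  stopifnot(is.character(label), length(label) == 1L,
            is.character(alt_labels), is.character(description),
            is.character(parents))
  parents <- normalize_term_id(parents)
  if (length(annotations)) {
    if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
      stop("annotations must be a named character vector")
    bad <- setdiff(names(annotations), ANNOTATION_KEYS)
    if (length(bad))
      stop("unknown annotation key(s): ", paste(bad, collapse = ", "))
    annotations <- vapply(annotations, as.character, character(1))
  } else {
    annotations <- stats::setNames(character(0), character(0))
  }
  axioms <- lapply(axioms, function(a) {
    if (!inherits(a, "bd_axiom")) stop("axioms must be bd_axiom objects")
    a
  })
  structure(
    list(id = id, pillar = pillar, label = label,
         alt_labels = alt_labels, description = description,
         parents = unique(parents), axioms = axioms,
         annotations = annotations),
    class = "bd_class"
  )
}

#' @export
print.bd_class <- function(x, ...) {
  cat(sprintf("<%s> %s [%s]\n", x$id, x$label, x$pillar))
  if (length(x$parents))
    cat("  parents: ", paste(x$parents, collapse = ", "), "\n", sep = "")
  for (a in x$axioms)
    cat("  SubClassOf: ", serialize_class_expression(a), "\n", sep = "")
  if (length(x$annotations))
    cat("  annotations: ",
        paste(names(x$annotations), shQuote(x$annotations), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## External term references (MIREOT)

#' Create an external term reference
#'
#' External ontology terms (Human Phenotype Ontology, PATO, FMA, NCI
#' thesaurus, REAMS, ...) are referenced by minimal records rather than being
#' imported wholesale, following the MIREOT convention: identifier, source,
#' label and an optional parent hint used for subtree-membership checks.
#'
#' @param id Term id carrying the source prefix, e.g. `"HP:HP_0000238"`.
#' @param source Source ontology, one of
#'   `r paste0('"', EXTERNAL_SOURCES, '"', collapse = ", ")`.
#' @param label Human-readable label (non-empty).
#' @param parent_hint Id of the term's parent in its source ontology, or `""`.
#' @return An object of class `bd_external_ref`.
#' @export
external_ref <- function(id, source, label, parent_hint = "") {
  if (!is_valid_term_id(id)) stop("invalid term id: ", deparse(id))
  source <- match.arg(source, EXTERNAL_SOURCES)
  if (!identical(external_source_of(id), source))
    stop("id prefix of ", id, " does not match source ", source)
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.character(parent_hint), length(parent_hint) == 1L)
  structure(list(id = id, source = source, label = label,
                 parent_hint = parent_hint),
            class = "bd_external_ref")
}

#' @export
print.bd_external_ref <- function(x, ...) {
  cat(sprintf("<%s> %s (external: %s)\n", x$id, x$label, x$source))
  invisible(x)
}

## ---------------------------------------------------------------------------
## The knowledge base

#' Create an empty knowledge base
#'
#' The empty knowledge base contains only the structural roots (one per
#' pillar: `Bone_Dysplasia`, `Gene`, `Gene_Mutation`, `Protein`,
#' `Phenotypic_Composite`, `Anatomical_Composite`, `Quality_Composite`), the
#' fixed relation registry, and Dublin Core metadata.
#'
#' @param title,creator,contributor,publisher,version Metadata strings.
#' @return An object of class `bd_kb`.
#' @examples
#' kb <- empty_kb(title = "toy nosology")
#' kb_stats(kb)$total
#' @export
empty_kb <- function(title = "", creator = "", contributor = "",
                     publisher = "", version = "") {
  classes <- lapply(names(KB_ROOTS), function(id) {
    class_def(id, KB_ROOTS[[id]], label = gsub("_", " ", id))
  })
  names(classes) <- names(KB_ROOTS)
  structure(
    list(classes = classes,
         external = list(),
         metadata = list(title = title, creator = creator,
                         contributor = contributor, publisher = publisher,
                         version = version),
         pillar_tags = as.list(PILLAR_UPPER_TAGS),
         bookkeeping = NULL),
    class = "bd_kb"
  )
}

is_root_id <- function(id) id %in% names(KB_ROOTS)

#' @export
print.bd_kb <- function(x, ...) {
  s <- kb_stats(x)
  cat("Knowledge base")
  if (nzchar(x$metadata$title)) cat(": ", x$metadata$title, sep = "")
  cat("\n  own-defined classes: ", s$total,
      " (", paste(sprintf("%s %d", names(s$per_pillar), s$per_pillar),
                  collapse = ", "), ")\n", sep = "")
  cat("  groups under Bone_Dysplasia: ", s$n_groups, "\n", sep = "")
  cat("  external term references: ", length(x$external), "\n", sep = "")
  invisible(x)
}

kb_class <- function(kb, id) kb$classes[[id]]
kb_has_class <- function(kb, id) !is.null(kb$classes[[id]])
kb_has_term <- function(kb, id) kb_has_class(kb, id) || !is.null(kb$external[[id]])

#' List class ids in a knowledge base
#'
#' @param kb A `bd_kb`.
#' @param pillar Optional pillar filter.
#' @param include_roots Keep the structural root classes? Default `FALSE`.
#' @return Character vector of class ids.
#' @export
class_ids <- function(kb, pillar = NULL, include_roots = FALSE) {
  ids <- names(kb$classes)
  if (!include_roots) ids <- ids[!is_root_id(ids)]
  if (!is.null(pillar)) {
    pillar <- match.arg(pillar, PILLARS)
    keep <- vapply(ids, function(i) kb$classes[[i]]$pillar == pillar,
                   logical(1))
    ids <- ids[keep]
  }
  unname(ids)
}

#' Add an external term reference to a knowledge base
#'
#' @param kb A `bd_kb`.
#' @param ref A [external_ref()] object.
#' @return The updated knowledge base.
#' @export
add_external_ref <- function(kb, ref) {
  stopifnot(inherits(kb, "bd_kb"), inherits(ref, "bd_external_ref"))
  if (kb_has_class(kb, ref$id))
    stop("id ", ref$id, " already names an own-defined class")
  kb$external[[ref$id]] <- ref
  kb
}

#' Add a class to a knowledge base
#'
#' Registers a class definition. The class id must be fresh, all parents must
#' already exist, the relation of every axiom must be applicable to the
#' class's pillar (Table-level domain check), and the subclass graph must
#' remain acyclic.
#'
#' @param kb A `bd_kb`.
#' @param cls A [class_def()] object.
#' @return The updated knowledge base.
#' @export
add_class <- function(kb, cls) {
  stopifnot(inherits(kb, "bd_kb"), inherits(cls, "bd_class"))
  if (kb_has_term(kb, cls$id)) stop("duplicate id: ", cls$id)
  if (cls$id %in% cls$parents) stop("cycle introduced: ", cls$id,
                                    " lists itself as a parent")
  missing_parents <- cls$parents[!vapply(cls$parents, kb_has_class,
                                         logical(1), kb = kb)]
  if (length(missing_parents))
    stop("dangling parent(s): ", paste(missing_parents, collapse = ", "))
  check_axiom_domains(cls)
  check_label_unique(kb, cls)
  kb$classes[[cls$id]] <- cls
  if (!is_dag(kb)) stop("cycle introduced by ", cls$id)  # defensive
  kb
}

#' Replace the parents of a class
#'
#' The editorial "move a disease between groups" operation: the parent list is
#' replaced wholesale and the DAG invariant re-checked.
#'
#' @param kb A `bd_kb`.
#' @param id Class to move.
#' @param new_parents Character vector of new parent ids (all must exist).
#' @return The updated knowledge base.
#' @export
move_class <- function(kb, id, new_parents) {
  stopifnot(inherits(kb, "bd_kb"))
  id <- normalize_term_id(id)
  if (!kb_has_class(kb, id)) stop("unknown class: ", id)
  new_parents <- normalize_term_id(new_parents)
  missing <- new_parents[!vapply(new_parents, kb_has_class, logical(1), kb = kb)]
  if (length(missing))
    stop("dangling parent(s): ", paste(missing, collapse = ", "))
  old <- kb$classes[[id]]$parents
  kb$classes[[id]]$parents <- unique(new_parents)
  if (!is_dag(kb)) {
    kb$classes[[id]]$parents <- old
    stop("cycle introduced when moving ", id)
  }
  kb
}

#' Update fields of an existing class
#'
#' @param kb A `bd_kb`.
#' @param id Class id.
#' @param axioms,label,alt_labels,description,annotations Fields to replace;
#'   `NULL` leaves the stored value unchanged.
#' @return The updated knowledge base.
#' @export
update_class <- function(kb, id, axioms = NULL, label = NULL,
                         alt_labels = NULL, description = NULL,
                         annotations = NULL) {
  stopifnot(inherits(kb, "bd_kb"))
  id <- normalize_term_id(id)
  cls <- kb$classes[[id]]
  if (is.null(cls)) stop("unknown class: ", id)
  new <- class_def(
    id = cls$id, pillar = cls$pillar,
    label = label %||% cls$label,
    alt_labels = alt_labels %||% cls$alt_labels,
    description = description %||% cls$description,
    parents = cls$parents,
    axioms = axioms %||% cls$axioms,
    annotations = annotations %||% cls$annotations
  )
  check_axiom_domains(new)
  kb$classes[[id]] <- new
  kb
}

check_axiom_domains <- function(cls) {
  for (a in cls$axioms) {
    for (rel in axiom_relations(a)) {
      dom <- RELATION_DOMAINS[[rel]]
      if (is.null(dom)) stop("unknown relation: ", rel)
      if (!cls$pillar %in% dom)
        stop("relation ", rel, " is not applicable to pillar ", cls$pillar,
             " (class ", cls$id, ")")
    }
  }
  invisible(cls)
}

check_label_unique <- function(kb, cls) {
  for (other in kb$classes) {
    if (other$pillar == cls$pillar && !is_root_id(other$id) &&
        identical(other$label, cls$label) && !identical(other$id, cls$id))
      stop("label ", shQuote(cls$label), " already used in pillar ",
           cls$pillar, " by ", other$id)
  }
  invisible(cls)
}

## ---------------------------------------------------------------------------
## DAG queries

parent_map <- function(kb) lapply(kb$classes, `[[`, "parents")

children_map <- function(kb) {
  kids <- stats::setNames(vector("list", length(kb$classes)),
                          names(kb$classes))
  for (id in names(kb$classes)) {
    for (p in kb$classes[[id]]$parents)
      kids[[p]] <- c(kids[[p]], id)
  }
  kids
}

#' Is the subclass graph acyclic?
#'
#' @param kb A `bd_kb`.
#' @return `TRUE` if the subclass graph is a DAG.
#' @export
is_dag <- function(kb) {
  stopifnot(inherits(kb, "bd_kb"))
  length(cyclic_class_ids(kb)) == 0L
}

## Ids of classes that can reach themselves through parent edges.
cyclic_class_ids <- function(kb) {
  parents <- parent_map(kb)
  state <- stats::setNames(integer(length(parents)), names(parents))
  in_cycle <- character(0)
  visit <- function(id, stack) {
    if (state[[id]] == 2L) return(invisible())
    if (id %in% stack) {
      in_cycle <<- union(in_cycle, stack[seq(match(id, stack), length(stack))])
      return(invisible())
    }
    stack <- c(stack, id)
    for (p in parents[[id]]) if (!is.null(parents[[p]])) visit(p, stack)
    state[[id]] <<- 2L
    invisible()
  }
  for (id in names(parents)) visit(id, character(0))
  sort(in_cycle)
}

#' Subclasses of a class
#'
#' @param kb A `bd_kb`.
#' @param id Class id.
#' @param direct If `TRUE`, only immediate children; otherwise the transitive
#'   closure (excluding `id` itself).
#' @return Character vector of class ids, sorted.
#' @export
subclasses <- function(kb, id, direct = FALSE) {
  stopifnot(inherits(kb, "bd_kb"))
  id <- normalize_term_id(id)
  if (!kb_has_class(kb, id)) stop("unknown class: ", id)
  kids <- children_map(kb)
  if (direct) return(sort(unique(unlist(kids[id])) %||% character(0)))
  seen <- character(0)
  frontier <- kids[[id]] %||% character(0)
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  sort(unique(seen))
}

#' Ancestors of a class (transitive parents)
#'
#' @param kb A `bd_kb`.
#' @param id Class id.
#' @return Character vector of ancestor ids (excluding `id`), sorted.
#' @export
superclasses <- function(kb, id) {
  stopifnot(inherits(kb, "bd_kb"))
  id <- normalize_term_id(id)
  if (!kb_has_class(kb, id)) stop("unknown class: ", id)
  seen <- character(0)
  frontier <- kb$classes[[id]]$parents
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(lapply(frontier, function(p)
      if (kb_has_class(kb, p)) kb$classes[[p]]$parents else character(0)),
      use.names = FALSE)
  }
  sort(unique(seen))
}

#' Depth of a dysplasia class in the disease hierarchy
#'
#' The number of subclass edges on the longest path from the `Bone_Dysplasia`
#' root down to the class. Groups sit at depth 1; most dysplasias at depth 2;
#' historically subsumed diseases at depth 3.
#'
#' @param kb A `bd_kb`.
#' @param id A dysplasia-pillar class id.
#' @return Integer depth (`0` for the root itself).
#' @export
depth <- function(kb, id) {
  stopifnot(inherits(kb, "bd_kb"))
  id <- normalize_term_id(id)
  cls <- kb$classes[[id]]
  if (is.null(cls)) stop("unknown class: ", id)
  if (cls$pillar != "dysplasia") stop(id, " is not a dysplasia-pillar class")
  if (id == "Bone_Dysplasia") return(0L)
  memo <- new.env(parent = emptyenv())
  rec <- function(x) {
    if (x == "Bone_Dysplasia") return(0L)
    if (exists(x, envir = memo, inherits = FALSE)) return(memo[[x]])
    ps <- kb$classes[[x]]$parents
    ps <- ps[vapply(ps, function(p) {
      c2 <- kb$classes[[p]]
      !is.null(c2) && c2$pillar == "dysplasia"
    }, logical(1))]
    d <- -1L
    for (p in ps) {
      dp <- rec(p)
      if (dp >= 0L && dp + 1L > d) d <- dp + 1L
    }
    memo[[x]] <- d
    d
  }
  d <- rec(id)
  if (d < 0L) stop(id, " is not under Bone_Dysplasia")
  d
}

#' Next free incremental identifier for a pillar
#'
#' Genes, gene mutations and proteins are named by an incremental scheme:
#' `G0000001`, `GM0000001`, `P0000001`. Returns the smallest unused id in
#' canonical 7-digit form.
#'
#' @param kb A `bd_kb`.
#' @param pillar One of `"gene"`, `"gene_mutation"`, `"protein"`.
#' @return A fresh term id.
#' @examples
#' next_id(empty_kb(), "gene")  # "G0000001"
#' @export
next_id <- function(kb, pillar) {
  stopifnot(inherits(kb, "bd_kb"))
  pillar <- match.arg(pillar, c("gene", "gene_mutation", "protein"))
  prefix <- c(gene = "G", gene_mutation = "GM", protein = "P")[[pillar]]
  next_counter_id(kb, prefix, sep = "")
}

## Shared allocator: also used for PC_/AC_/QC_ composite ids.
next_counter_id <- function(kb, prefix, sep = "") {
  pat <- paste0("^", prefix, sep, "([0-9]{5,8})$")
  ids <- names(kb$classes)
  hits <- regmatches(ids, regexec(pat, ids))
  used <- sort(unique(vapply(hits[lengths(hits) == 2L],
                             function(h) as.integer(h[2L]), integer(1))))
  n <- 1L
  for (u in used) {
    if (u == n) n <- n + 1L else if (u > n) break
  }
  paste0(prefix, sep, sprintf("%07d", n))
}

## ---------------------------------------------------------------------------
## Summary statistics

#' Leaf dysplasias of a knowledge base
#'
#' Dysplasia-pillar classes with no dysplasia-pillar subclasses (the disease
#' level, as opposed to the group level).
#'
#' @param kb A `bd_kb`.
#' @return Character vector of class ids, sorted.
#' @export
leaf_dysplasias <- function(kb) {
  ids <- class_ids(kb, "dysplasia")
  kids <- children_map(kb)
  keep <- vapply(ids, function(i) {
    ch <- kids[[i]] %||% character(0)
    !any(vapply(ch, function(x) kb$classes[[x]]$pillar == "dysplasia",
                logical(1)))
  }, logical(1))
  sort(ids[keep])
}

#' Structural statistics of a knowledge base
#'
#' Counts own-defined classes (the structural roots are excluded), per pillar;
#' the number of disease groups (direct subclasses of `Bone_Dysplasia`); and,
#' over leaf dysplasias, the fraction whose `characterized_by` filler contains
#' at least one gene-mutation atom and the fraction containing at least one
#' phenotype atom (an HP/REAMS external term or a phenotypic composite).
#'
#' @param kb A `bd_kb`.
#' @return A list with elements `total`, `per_pillar` (named integer vector),
#'   `n_groups`, `n_leaf_dysplasias`, `frac_mutation_linked`,
#'   `frac_phenotype_linked` (the fractions are `NA` when there are no leaf
#'   dysplasias).
#' @export
kb_stats <- function(kb) {
  stopifnot(inherits(kb, "bd_kb"))
  ids <- class_ids(kb)
  pillars <- vapply(ids, function(i) kb$classes[[i]]$pillar, character(1))
  per <- stats::setNames(integer(length(PILLARS)), PILLARS)
  tab <- table(pillars)
  per[names(tab)] <- as.integer(tab)
  leaves <- leaf_dysplasias(kb)
  mut <- phe <- NA_real_
  if (length(leaves)) {
    linked <- vapply(leaves, function(d) {
      atoms <- characterized_by_atoms(kb, d)
      c(mut = any(vapply(atoms, function(a) atom_is_mutation(kb, a),
                         logical(1))),
        phe = any(vapply(atoms, function(a) atom_is_phenotype(kb, a),
                         logical(1))))
    }, logical(2))
    mut <- mean(linked["mut", ])
    phe <- mean(linked["phe", ])
  }
  list(total = length(ids),
       per_pillar = per,
       n_groups = length(subclasses(kb, "Bone_Dysplasia", direct = TRUE)),
       n_leaf_dysplasias = length(leaves),
       frac_mutation_linked = mut,
       frac_phenotype_linked = phe)
}

## Atoms appearing in the union of a class's characterized_by fillers.
characterized_by_atoms <- function(kb, id) {
  cls <- kb$classes[[id]]
  if (is.null(cls)) stop("unknown class: ", id)
  out <- character(0)
  for (a in cls$axioms) {
    if (a$kind == "disjunct") next
    if (a$relation == "characterized_by")
      out <- c(out, expression_atoms(a$filler))
  }
  unique(out)
}

atom_is_mutation <- function(kb, a) {
  cls <- kb$classes[[a]]
  !is.null(cls) && cls$pillar == "gene_mutation"
}

atom_is_phenotype <- function(kb, a) {
  cls <- kb$classes[[a]]
  if (!is.null(cls)) return(cls$pillar == "phenotypic_composite")
  ref <- kb$external[[a]]
  !is.null(ref) && ref$source %in% c("HP", "REAMS")
}

## ---------------------------------------------------------------------------
## Structural equality (ignores bookkeeping, ordering)

#' Structural equality of two knowledge bases
#'
#' Compares metadata, class definitions (up to ordering of parents, axioms and
#' annotations) and external term references. Generator bookkeeping is
#' ignored.
#'
#' @param a,b `bd_kb` objects.
#' @return `TRUE` or `FALSE`.
#' @export
kb_equal <- function(a, b) {
  stopifnot(inherits(a, "bd_kb"), inherits(b, "bd_kb"))
  if (!identical(a$metadata, b$metadata)) return(FALSE)
  if (!setequal(names(a$classes), names(b$classes))) return(FALSE)
  if (!setequal(names(a$external), names(b$external))) return(FALSE)
  for (id in names(a$classes)) {
    ca <- a$classes[[id]]; cb <- b$classes[[id]]
    if (!identical(ca$pillar, cb$pillar) || !identical(ca$label, cb$label) ||
        !setequal(ca$alt_labels, cb$alt_labels) ||
        !identical(ca$description, cb$description) ||
        !setequal(ca$parents, cb$parents))
      return(FALSE)
    an_a <- ca$annotations[order(names(ca$annotations))]
    an_b <- cb$annotations[order(names(cb$annotations))]
    if (!identical(an_a, an_b)) return(FALSE)
    ax_a <- sort(vapply(ca$axioms, serialize_class_expression, character(1)))
    ax_b <- sort(vapply(cb$axioms, serialize_class_expression, character(1)))
    if (!identical(ax_a, ax_b)) return(FALSE)
  }
  for (id in names(a$external)) {
    ra <- a$external[[id]]; rb <- b$external[[id]]
    if (!identical(ra[c("id", "source", "label", "parent_hint")],
                   rb[c("id", "source", "label", "parent_hint")]))
      return(FALSE)
  }
  TRUE
}

## ---------------------------------------------------------------------------
## Subtree membership across internal classes and MIREOT parent hints

## TRUE: id is one of / descends from `roots`. FALSE: provably not.
## NA: the chain runs into an unresolvable external hint.
descends_from <- function(kb, id, roots) {
  if (!length(roots)) return(FALSE)
  seen <- character(0)
  frontier <- id
  unresolved <- FALSE
  while (length(frontier)) {
    if (any(frontier %in% roots)) return(TRUE)
    seen <- c(seen, frontier)
    nxt <- character(0)
    for (x in frontier) {
      cls <- kb$classes[[x]]
      if (!is.null(cls)) {
        nxt <- c(nxt, cls$parents)
      } else {
        ref <- kb$external[[x]]
        if (is.null(ref)) {
          unresolved <- TRUE
        } else if (nzchar(ref$parent_hint)) {
          if (!kb_has_term(kb, ref$parent_hint) &&
              !ref$parent_hint %in% roots)
            unresolved <- TRUE
          nxt <- c(nxt, ref$parent_hint)
        }
      }
    }
    frontier <- setdiff(unique(nxt), seen)
  }
  if (unresolved) NA else FALSE
}
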