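## Structural TBox checking and closed-world ABox checking.
##
## The class level is checked structurally: relation domains against the
## pillar of the owning class, range membership of every filler atom
## (internal pillar or external subtree via MIREOT parent hints), reference
## resolvability, and acyclicity of the subclass DAG. The instance level is
## checked under closed-world constraint semantics: a `some` restriction
## requires at least one asserted link to a suitably typed individual, an
## `only` restriction requires every asserted link of that relation to point
## at a suitably typed individual. This deliberately replaces open-world
## description-logic reasoning: for desk-scale validation of patient records,
## constraint semantics over asserted links is what is wanted.

violation <- function(subject, relation, kind, message) {
  data.frame(subject = subject, relation = relation, kind = kind,
             message = message, stringsAsFactors = FALSE)
}

VIOLATION_KINDS <- c("some_unsatisfied", "only_violated", "domain_mismatch",
                     "range_mismatch", "dag_cycle", "unknown_ref")

finish_violations <- function(parts, warnings) {
  out <- if (length(parts)) do.call(rbind, parts) else
    violation(character(0), character(0), character(0), character(0))
  out <- out[order(out$subject, out$relation, out$kind, out$message), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bd_violations", "data.frame")
  attr(out, "warnings") <- unique(warnings)
  out
}

#' @export
print.bd_violations <- function(x, ...) {
  if (!nrow(x)) {
    cat("No violations.\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x)
  }
  w <- attr(x, "warnings")
  if (length(w)) cat("Warnings:\n", paste(" -", w, collapse = "\n"), "\n")
  invisible(x)
}

## Range vocabulary for a relation, given the owning pillar.
relation_range <- function(relation, owner_pillar) {
  if (relation == "has_part") {
    list(pillars = HAS_PART_RANGE_PILLARS[[owner_pillar]] %||% character(0),
         roots = HAS_PART_RANGE_ROOTS[[owner_pillar]] %||% character(0))
  } else {
    list(pillars = RELATION_RANGE_PILLARS[[relation]] %||% character(0),
         roots = RELATION_RANGE_ROOTS[[relation]] %||% character(0))
  }
}

## TRUE / FALSE / NA (NA = unresolvable external hint chain).
atom_in_range <- function(kb, atom, range) {
  cls <- kb$classes[[atom]]
  if (!is.null(cls)) {
    if (cls$pillar %in% range$pillars) return(TRUE)
    ## an internal class can also sit under an admitted external root
    ## (not used by the core model, but harmless to allow)
    return(descends_from(kb, atom, range$roots))
  }
  descends_from(kb, atom, range$roots)
}

#' Check the class level of a knowledge base
#'
#' Structural TBox check: the subclass graph must be acyclic, every parent
#' and filler atom resolvable, every axiom's relation applicable to the
#' owning class's pillar, and every filler atom inside the relation's range
#' (internal pillar membership or external subtree membership through MIREOT
#' parent hints). Unresolvable parent-hint chains degrade to warnings, not
#' violations.
#'
#' @param kb A `bd_kb`.
#' @return A `bd_violations` data frame (columns `subject`, `relation`,
#'   `kind`, `message`), sorted, empty when the knowledge base is clean;
#'   warnings in `attr(, "warnings")`.
#' @export
check_tbox <- function(kb) {
  stopifnot(inherits(kb, "bd_kb"))
  parts <- list()
  warnings <- character(0)
  add <- function(v) parts[[length(parts) + 1L]] <<- v

  for (id in cyclic_class_ids(kb))
    add(violation(id, "subclass_of", "dag_cycle",
                  "class participates in a subclass cycle"))

  for (id in sort(names(kb$classes))) {
    cls <- kb$classes[[id]]
    for (p in cls$parents) {
      if (!kb_has_class(kb, p))
        add(violation(id, "subclass_of", "unknown_ref",
                      paste0("unknown parent ", p)))
    }
    for (a in cls$axioms) {
      flat <- if (a$kind == "disjunct") unlist(a$branches, recursive = FALSE)
              else list(a)
      for (ax in flat) {
        rel <- ax$relation
        dom <- RELATION_DOMAINS[[rel]]
        if (is.null(dom)) {
          add(violation(id, rel, "unknown_ref",
                        paste0("unknown relation ", rel)))
          next
        }
        if (!cls$pillar %in% dom) {
          add(violation(id, rel, "domain_mismatch",
                        paste0("relation ", rel, " does not apply to pillar ",
                               cls$pillar)))
          next
        }
        range <- relation_range(rel, cls$pillar)
        for (atom in unique(expression_atoms(ax$filler))) {
          if (!kb_has_term(kb, atom)) {
            add(violation(id, rel, "unknown_ref",
                          paste0("unresolvable filler atom ", atom)))
            next
          }
          ok <- atom_in_range(kb, atom, range)
          if (is.na(ok)) {
            warnings <- c(warnings,
                          paste0(id, "/", rel, ": cannot resolve external ",
                                 "ancestry of ", atom))
          } else if (!ok) {
            add(violation(id, rel, "range_mismatch",
                          paste0("filler atom ", atom,
                                 " outside the range of ", rel)))
          }
        }
      }
    }
  }
  finish_violations(parts, warnings)
}

## ---------------------------------------------------------------------------
## Individuals

#' Create an individual (instance-level assertion)
#'
#' @param id Individual identifier.
#' @param types Character vector (non-empty) of asserted class/term ids.
#' @param links A `data.frame` with columns `relation`, `target` (target
#'   individual ids), or `NULL`.
#' @param data Named list of datatype-property values.
#' @return A `bd_individual`.
#' @export
individual <- function(id, types, links = NULL, data = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(types), length(types) >= 1L)
  if (is.null(links))
    links <- data.frame(relation = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(links),
            all(c("relation", "target") %in% names(links)))
  structure(list(id = id, types = normalize_term_id(types),
                 links = links[c("relation", "target")], data = data),
            class = "bd_individual")
}

#' @export
print.bd_individual <- function(x, ...) {
  cat(sprintf("individual %s : %s\n", x$id, paste(x$types, collapse = ", ")))
  for (i in seq_len(nrow(x$links)))
    cat("  ", x$links$relation[i], " -> ", x$links$target[i], "\n", sep = "")
  invisible(x)
}

## Restriction axioms applicable to an individual: those of its asserted
## internal classes and of all their ancestors.
applicable_axioms <- function(kb, ind) {
  out <- list()
  classes <- character(0)
  for (t in ind$types) {
    if (kb_has_class(kb, t)) classes <- c(classes, t, superclasses(kb, t))
  }
  for (cl in unique(classes)) out <- c(out, kb$classes[[cl]]$axioms)
  out
}

## Does a type term satisfy a filler atom? Equal or descendant.
type_matches_atom <- function(kb, type, atom) {
  if (identical(type, atom)) return(TRUE)
  descends_from(kb, type, atom)
}

## Does an individual satisfy a filler expression? TRUE/FALSE/NA.
individual_satisfies <- function(kb, target_ind, filler) {
  if (filler$kind == "atom") {
    res <- vapply(target_ind$types, function(t)
      type_matches_atom(kb, t, filler$id), logical(1))
    if (any(res, na.rm = TRUE)) return(TRUE)
    if (anyNA(res)) return(NA)
    return(FALSE)
  }
  res <- vapply(filler$children, function(ch)
    individual_satisfies(kb, target_ind, ch), logical(1))
  if (filler$kind == "or") {
    if (any(res, na.rm = TRUE)) TRUE else if (anyNA(res)) NA else FALSE
  } else {
    if (any(!res, na.rm = TRUE)) FALSE else if (anyNA(res)) NA else TRUE
  }
}

#' Check instance data against class restrictions (closed world)
#'
#' For every individual and every restriction axiom of its asserted classes
#' (including inherited axioms): a `some` component requires at least one
#' link of that relation to an individual typed by the filler; an `only`
#' component requires every link of that relation to target an individual
#' typed by the filler. Disjunctive axioms are satisfied when at least one
#' branch is fully satisfied. Typing is subsumption-aware (internal subclass
#' closure, external parent-hint chains); unresolvable hints degrade to
#' warnings.
#'
#' @param kb A `bd_kb`.
#' @param individuals A list of [individual()] objects.
#' @return A `bd_violations` data frame, sorted; empty when all constraints
#'   hold.
#' @export
check_abox <- function(kb, individuals) {
  stopifnot(inherits(kb, "bd_kb"), is.list(individuals))
  by_id <- stats::setNames(individuals,
                           vapply(individuals, `[[`, character(1), "id"))
  parts <- list()
  warnings <- character(0)
  add <- function(v) parts[[length(parts) + 1L]] <<- v

  check_restriction <- function(ind, ax) {
    ## returns c(some_ok, only_ok) with NA propagation
    rel <- ax$relation
    ls <- ind$links[ind$links$relation == rel, , drop = FALSE]
    sat <- vapply(ls$target, function(tid) {
      tgt <- by_id[[tid]]
      if (is.null(tgt)) return(NA)
      individual_satisfies(kb, tgt, ax$filler)
    }, logical(1))
    some_ok <- if (ax$kind %in% c("some", "only_and_some")) {
      if (any(sat, na.rm = TRUE)) TRUE
      else if (anyNA(sat)) NA else FALSE
    } else TRUE
    only_ok <- if (ax$kind %in% c("only", "only_and_some")) {
      if (any(!sat, na.rm = TRUE)) FALSE
      else if (anyNA(sat)) NA else TRUE
    } else TRUE
    c(some_ok, only_ok)
  }

  for (ind in individuals[order(vapply(individuals, `[[`, character(1), "id"))]) {
    for (t in ind$types) {
      if (!kb_has_term(kb, t))
        add(violation(ind$id, "type", "unknown_ref",
                      paste0("unknown asserted type ", t)))
    }
    for (i in seq_len(nrow(ind$links))) {
      rel <- ind$links$relation[i]
      if (!rel %in% RELATIONS)
        add(violation(ind$id, rel, "unknown_ref",
                      paste0("unknown link relation ", rel)))
      if (is.null(by_id[[ind$links$target[i]]]))
        add(violation(ind$id, rel, "unknown_ref",
                      paste0("link target ", ind$links$target[i],
                             " is not a known individual")))
    }
    for (ax in applicable_axioms(kb, ind)) {
      if (ax$kind == "disjunct") {
        branch_ok <- vapply(ax$branches, function(b) {
          oks <- vapply(b, function(a2) check_restriction(ind, a2),
                        logical(2))
          if (any(!oks, na.rm = TRUE)) FALSE
          else if (anyNA(oks)) NA else TRUE
        }, logical(1))
        if (any(branch_ok, na.rm = TRUE)) next
        if (anyNA(branch_ok)) {
          warnings <- c(warnings, paste0(ind$id,
                        ": disjunctive axiom undecidable (unresolved hints)"))
        } else {
          add(violation(ind$id, "(disjunction)", "some_unsatisfied",
                        "no branch of the disjunctive axiom is satisfied"))
        }
        next
      }
      oks <- check_restriction(ind, ax)
      fill <- serialize_expr(ax$filler)
      if (is.na(oks[1])) {
        warnings <- c(warnings, paste0(ind$id, "/", ax$relation,
                                       ": some-check undecidable"))
      } else if (!oks[1]) {
        add(violation(ind$id, ax$relation, "some_unsatisfied",
                      paste0("no ", ax$relation, " link to an individual of ",
                             fill)))
      }
      if (is.na(oks[2])) {
        warnings <- c(warnings, paste0(ind$id, "/", ax$relation,
                                       ": only-check undecidable"))
      } else if (!oks[2]) {
        add(violation(ind$id, ax$relation, "only_violated",
                      paste0("a ", ax$relation, " link targets an individual",
                             " outside ", fill)))
      }
    }
  }
  finish_violations(parts, warnings)
}

## ---------------------------------------------------------------------------
## Closed-world membership classification

## Is every term of `terms` covered by the characterized_by only-filler of
## dysplasia `d`? A dysplasia without characterized_by axioms is
## unconstrained (vacuously compatible) -- that is what an absent universal
## restriction means.
terms_compatible_with_dysplasia <- function(kb, terms, d) {
  allowed <- characterized_by_only_atoms(kb, d)
  if (is.null(allowed)) return(TRUE)       # no axiom: unconstrained
  if (!length(terms)) return(TRUE)         # universal over the empty set
  for (t in terms) {
    hit <- FALSE
    for (a in allowed) {
      m <- type_matches_atom(kb, t, a)
      if (isTRUE(m) || is.na(m)) { hit <- TRUE; break }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

## Union of only/only_and_some characterized_by filler atoms; NULL when the
## class carries no such axiom.
characterized_by_only_atoms <- function(kb, d) {
  cls <- kb$classes[[d]]
  atoms <- NULL
  for (a in cls$axioms) {
    if (a$kind == "disjunct") next
    if (a$relation == "characterized_by" &&
        a$kind %in% c("only", "only_and_some"))
      atoms <- c(atoms %||% character(0), expression_atoms(a$filler))
  }
  if (is.null(atoms)) NULL else unique(atoms)
}

#' Closed-world membership classification of a patient individual
#'
#' Lists the dysplasia classes whose `characterized_by` universal filler
#' covers every phenotype/mutation the patient is linked to. This is
#' closed-world compatibility filtering, not description-logic realization:
#' a dysplasia without a `characterized_by` axiom is unconstrained and a
#' patient without links is compatible with every dysplasia (a universal
#' restriction over an empty link set holds vacuously). Matching is
#' subsumption-aware.
#'
#' @param kb A `bd_kb`.
#' @param patient A [individual()] whose `characterized_by` links carry the
#'   observed phenotypes/mutations, or a plain character vector of term ids.
#' @param individuals Optional list of individuals used to resolve link
#'   targets to their asserted types; a link target with no matching
#'   individual is taken as a term id directly.
#' @return Sorted character vector of compatible dysplasia class ids
#'   (excluding the `Bone_Dysplasia` root).
#' @export
classify_membership <- function(kb, patient, individuals = list()) {
  stopifnot(inherits(kb, "bd_kb"))
  if (inherits(patient, "bd_individual")) {
    by_id <- stats::setNames(individuals,
                             vapply(individuals, `[[`, character(1), "id"))
    ls <- patient$links[patient$links$relation == "characterized_by", ,
                        drop = FALSE]
    terms <- unlist(lapply(ls$target, function(tid) {
      tgt <- by_id[[tid]]
      if (is.null(tgt)) tid else tgt$types
    }), use.names = FALSE) %||% character(0)
  } else {
    terms <- as.character(patient)
  }
  terms <- normalize_term_id(unique(terms))
  ds <- class_ids(kb, "dysplasia")
  keep <- vapply(ds, function(d)
    terms_compatible_with_dysplasia(kb, terms, d), logical(1))
  sort(ds[keep])
}
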