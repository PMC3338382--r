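# Independent oracles and fixture builders shared across the test files.
# The oracles deliberately use different algorithms from the package code
# (fixpoint closures and exhaustive enumeration instead of recursive
# traversal) so that agreement is informative.

printed_kb <- function() {
  load_kb(system.file("extdata", "printed_definitions.kb",
                      package = "bdokit"))
}

## ---------------------------------------------------------------------------
## Graph oracles

# Edge data.frame (child -> parent) of the subclass graph.
kb_edges <- function(kb) {
  rows <- lapply(names(kb$classes), function(id) {
    ps <- kb$classes[[id]]$parents
    if (!length(ps)) return(NULL)
    data.frame(child = id, parent = ps, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(child = character(0),
                                         parent = character(0)))))
}

# Cycle detection by brute-force reachability: a class is cyclic iff it can
# reach itself through parent edges (fixpoint expansion, no recursion).
oracle_cyclic_ids <- function(kb) {
  edges <- kb_edges(kb)
  reach <- function(start) {
    seen <- character(0)
    frontier <- edges$parent[edges$child == start]
    while (length(frontier)) {
      frontier <- setdiff(frontier, seen)
      if (start %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
      frontier <- edges$parent[edges$child %in% frontier]
    }
    FALSE
  }
  ids <- names(kb$classes)
  sort(ids[vapply(ids, reach, logical(1))])
}

# Transitive subclasses by BFS over child edges.
oracle_subclasses <- function(kb, id) {
  edges <- kb_edges(kb)
  seen <- character(0)
  frontier <- edges$child[edges$parent == id]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- edges$child[edges$parent %in% frontier]
  }
  sort(unique(seen))
}

# All root-to-class path lengths in the dysplasia hierarchy, by exhaustive
# path enumeration.
oracle_depths <- function(kb, id) {
  if (id == "Bone_Dysplasia") return(0L)
  ps <- kb$classes[[id]]$parents
  ps <- ps[vapply(ps, function(p) {
    cl <- kb$classes[[p]]
    !is.null(cl) && cl$pillar == "dysplasia"
  }, logical(1))]
  unlist(lapply(ps, function(p) oracle_depths(kb, p) + 1L))
}

## ---------------------------------------------------------------------------
## Ancestor closure (fixpoint), spanning classes and external parent hints.
## Returns list(anc = named list of ancestor sets, complete = named logical:
## FALSE when the chain hits an unresolvable reference).

oracle_closure <- function(kb) {
  direct <- list()
  complete <- logical(0)
  for (id in names(kb$classes)) {
    direct[[id]] <- kb$classes[[id]]$parents
    complete[[id]] <- TRUE
  }
  for (id in names(kb$external)) {
    h <- kb$external[[id]]$parent_hint
    direct[[id]] <- if (nzchar(h)) h else character(0)
    complete[[id]] <- TRUE
  }
  anc <- direct
  repeat {
    changed <- FALSE
    for (id in names(anc)) {
      add <- unlist(lapply(anc[[id]], function(p) anc[[p]]))
      new <- union(anc[[id]], add)
      if (length(new) > length(anc[[id]])) {
        anc[[id]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (id in names(anc)) {
    unresolved <- anc[[id]][!anc[[id]] %in% names(direct)]
    if (length(unresolved)) complete[[id]] <- FALSE
  }
  list(anc = anc, complete = complete)
}

# TRUE/FALSE/NA subtree membership driven by the closure.
oracle_under <- function(clo, id, roots) {
  if (!length(roots)) return(FALSE)
  if (id %in% roots) return(TRUE)
  if (!id %in% names(clo$anc)) return(NA)
  if (any(roots %in% clo$anc[[id]])) return(TRUE)
  if (!clo$complete[[id]] ||
      any(!clo$anc[[id]] %in% names(clo$anc))) return(NA)
  FALSE
}

## ---------------------------------------------------------------------------
## Brute-force TBox oracle: enumerate every (class, axiom conjunct, atom).
## Emits (subject, relation, kind) triples for comparison.

oracle_relation_range <- function(relation, owner_pillar) {
  ranges <- list(
    characterized_by = list(p = c("gene_mutation", "phenotypic_composite"),
                            r = c("REAMS:Abnormality", "HP:HP_0000118")),
    mode_of_inheritance = list(p = character(0), r = "HP:HP_0000005"),
    has_locus = list(p = "gene", r = character(0)),
    mutation_type = list(p = character(0), r = "NCI:Mutation_Abnormality"),
    is_encoded_by = list(p = "gene", r = character(0)),
    describes = list(p = "anatomical_composite", r = "FMA:Anatomical_entity"),
    has_quality = list(p = "quality_composite", r = "PATO:PATO_0001241"),
    has_qualifier = list(p = character(0),
                         r = c("PATO:PATO_0000068", "PATO:PATO_0001241")),
    has_anatomical_coordinate = list(
      p = character(0),
      r = c("FMA:Primary_anatomical_coordinate",
            "FMA:Secondary_anatomical_coordinate")))
  if (relation == "has_part") {
    list(p = owner_pillar,
         r = switch(owner_pillar,
                    anatomical_composite = "FMA:Anatomical_entity",
                    quality_composite = "PATO:PATO_0001241",
                    character(0)))
  } else ranges[[relation]]
}

oracle_domains <- function() {
  list(characterized_by = "dysplasia", mode_of_inheritance = "dysplasia",
       has_locus = "gene_mutation", mutation_type = "gene_mutation",
       is_encoded_by = "protein", describes = "phenotypic_composite",
       has_quality = "phenotypic_composite",
       has_qualifier = "quality_composite",
       has_anatomical_coordinate = "anatomical_composite",
       has_part = c("phenotypic_composite", "anatomical_composite",
                    "quality_composite"))
}

# Flatten an axiom into plain (relation, kind, atoms) conjuncts.
flatten_axiom <- function(a) {
  if (a$kind == "disjunct")
    unlist(a$branches, recursive = FALSE)
  else list(a)
}

oracle_tbox <- function(kb) {
  clo <- oracle_closure(kb)
  domains <- oracle_domains()
  out <- list()
  emit <- function(subject, relation, kind)
    out[[length(out) + 1L]] <<- c(subject, relation, kind)
  for (id in oracle_cyclic_ids(kb))
    emit(id, "subclass_of", "dag_cycle")
  for (id in names(kb$classes)) {
    cls <- kb$classes[[id]]
    for (p in cls$parents)
      if (is.null(kb$classes[[p]])) emit(id, "subclass_of", "unknown_ref")
    for (a in cls$axioms) {
      for (ax in flatten_axiom(a)) {
        dom <- domains[[ax$relation]]
        if (is.null(dom)) { emit(id, ax$relation, "unknown_ref"); next }
        if (!cls$pillar %in% dom) {
          emit(id, ax$relation, "domain_mismatch"); next
        }
        rng <- oracle_relation_range(ax$relation, cls$pillar)
        for (atom in unique(expression_atoms(ax$filler))) {
          known <- !is.null(kb$classes[[atom]]) ||
            !is.null(kb$external[[atom]])
          if (!known) { emit(id, ax$relation, "unknown_ref"); next }
          icls <- kb$classes[[atom]]
          ok <- if (!is.null(icls) && icls$pillar %in% rng$p) TRUE
                else oracle_under(clo, atom, rng$r)
          if (isFALSE(ok)) emit(id, ax$relation, "range_mismatch")
        }
      }
    }
  }
  triples_df(out)
}

triples_df <- function(out) {
  df <- if (length(out)) {
    as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  } else {
    data.frame(V1 = character(0), V2 = character(0), V3 = character(0))
  }
  names(df) <- c("subject", "relation", "kind")
  df[order(df$subject, df$relation, df$kind), , drop = FALSE]
}

violation_triples <- function(v) {
  df <- data.frame(subject = v$subject, relation = v$relation,
                   kind = v$kind, stringsAsFactors = FALSE)
  df[order(df$subject, df$relation, df$kind), , drop = FALSE]
}

expect_same_triples <- function(actual, expected) {
  a <- actual; e <- expected
  rownames(a) <- rownames(e) <- NULL
  expect_equal(a, e)
}

## ---------------------------------------------------------------------------
## Brute-force ABox oracle

oracle_abox <- function(kb, individuals) {
  clo <- oracle_closure(kb)
  by_id <- stats::setNames(individuals,
                           vapply(individuals, `[[`, character(1), "id"))
  type_sat <- function(types, atom) {
    res <- vapply(types, function(t) {
      if (identical(t, atom)) TRUE else oracle_under(clo, t, atom)
    }, logical(1))
    if (any(res, na.rm = TRUE)) TRUE else if (anyNA(res)) NA else FALSE
  }
  expr_sat <- function(types, filler) {
    if (filler$kind == "atom") return(type_sat(types, filler$id))
    res <- vapply(filler$children, function(ch) expr_sat(types, ch),
                  logical(1))
    if (filler$kind == "or") {
      if (any(res, na.rm = TRUE)) TRUE else if (anyNA(res)) NA else FALSE
    } else {
      if (any(!res, na.rm = TRUE)) FALSE else if (anyNA(res)) NA else TRUE
    }
  }
  restr_ok <- function(ind, ax) {
    ls <- ind$links[ind$links$relation == ax$relation, , drop = FALSE]
    sat <- vapply(ls$target, function(tid) {
      tgt <- by_id[[tid]]
      if (is.null(tgt)) return(NA)
      expr_sat(tgt$types, ax$filler)
    }, logical(1))
    some <- if (ax$kind %in% c("some", "only_and_some")) {
      if (any(sat, na.rm = TRUE)) TRUE else if (anyNA(sat)) NA else FALSE
    } else TRUE
    only <- if (ax$kind %in% c("only", "only_and_some")) {
      if (any(!sat, na.rm = TRUE)) FALSE else if (anyNA(sat)) NA else TRUE
    } else TRUE
    c(some, only)
  }
  out <- list()
  emit <- function(subject, relation, kind)
    out[[length(out) + 1L]] <<- c(subject, relation, kind)
  for (ind in individuals) {
    for (t in ind$types)
      if (is.null(kb$classes[[t]]) && is.null(kb$external[[t]]))
        emit(ind$id, "type", "unknown_ref")
    for (i in seq_len(nrow(ind$links))) {
      rel <- ind$links$relation[i]
      if (!rel %in% c("characterized_by", "mode_of_inheritance", "has_locus",
                      "mutation_type", "is_encoded_by", "describes",
                      "has_quality", "has_qualifier",
                      "has_anatomical_coordinate", "has_part"))
        emit(ind$id, rel, "unknown_ref")
      if (is.null(by_id[[ind$links$target[i]]]))
        emit(ind$id, rel, "unknown_ref")
    }
    ## applicable axioms: asserted classes plus all their ancestors
    cls_set <- character(0)
    for (t in ind$types) {
      if (!is.null(kb$classes[[t]]))
        cls_set <- union(cls_set,
                         c(t, intersect(clo$anc[[t]], names(kb$classes))))
    }
    for (cl in cls_set) {
      for (a in kb$classes[[cl]]$axioms) {
        if (a$kind == "disjunct") {
          br <- vapply(a$branches, function(b) {
            oks <- unlist(lapply(b, function(a2) restr_ok(ind, a2)))
            if (any(!oks, na.rm = TRUE)) FALSE
            else if (anyNA(oks)) NA else TRUE
          }, logical(1))
          if (!any(br, na.rm = TRUE) && !anyNA(br))
            emit(ind$id, "(disjunction)", "some_unsatisfied")
          next
        }
        oks <- restr_ok(ind, a)
        if (isFALSE(oks[1])) emit(ind$id, a$relation, "some_unsatisfied")
        if (isFALSE(oks[2])) emit(ind$id, a$relation, "only_violated")
      }
    }
  }
  triples_df(out)
}

## ---------------------------------------------------------------------------
## Random structure generators (fixed seeds are set by the callers)

random_expression <- function(atoms, depth = 2) {
  if (depth == 0 || runif(1) < 0.4) return(expr_atom(sample(atoms, 1)))
  n <- sample(2:3, 1)
  kids <- lapply(seq_len(n), function(i)
    random_expression(atoms, depth - 1))
  ## avoid same-kind children collapsing differently than generated
  do.call(if (runif(1) < 0.5) expr_and else expr_or, kids)
}

random_axiom_set <- function() {
  rels <- sample(c("characterized_by", "mode_of_inheritance", "has_locus",
                   "mutation_type", "is_encoded_by", "describes",
                   "has_quality", "has_qualifier",
                   "has_anatomical_coordinate", "has_part"),
                 sample(1:3, 1))
  atoms <- c("Gene", "GM0000001", "HP:HP_0000238", "PATO:PATO_0001354",
             "FMA:Femur", "AC_0000001")
  structure(lapply(rels, function(r)
    axiom(r, sample(c("only", "some", "only_and_some"), 1),
          random_expression(atoms, depth = sample(0:2, 1)))),
    class = "bd_axiom_set")
}

random_mutation_encoding <- function() {
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  len <- sample(1:3, 1)
  nt <- function() paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                         collapse = "")
  form <- sample(1:3, 1)
  prot <- paste0(sample(aa, 1), sample(1:2000, 1), sample(aa, 1))
  nuc <- paste0(sample(1:9999, 1), " ", nt(), "-", nt())
  switch(form, paste0(prot, ", ", nuc), nuc, prot)
}

## A perturbed KB with a known mixture of valid and invalid structure,
## inserted below the reference definitions (low level, bypassing add_class,
## the way a hand-edited file could arrive).
random_dirty_kb <- function(base) {
  kb <- base
  n_ops <- sample(4:8, 1)
  mut_ids <- c("GM0000001", "GM0000361")
  phe_ids <- c("HP:HP_0000238", "HP:HP_0002938", "HP:HP_0002968",
               "HP:HP_0003505")
  for (i in seq_len(n_ops)) {
    op <- sample(c("valid_dysplasia", "bad_domain", "bad_range",
                   "unknown_atom", "dangling_parent", "cycle_pair"), 1)
    id <- sprintf("T%03d_%d", i, sample(1e4, 1))
    if (op == "valid_dysplasia") {
      atoms <- c(sample(mut_ids, 1), sample(phe_ids, sample(1:3, 1)))
      kb$classes[[id]] <- class_def(
        id, "dysplasia", parents = "Bone_Dysplasia",
        axioms = list(axiom("characterized_by", "only",
                            do.call(expr_or, lapply(atoms, expr_atom)))))
    } else if (op == "bad_domain") {
      kb$classes[[id]] <- class_def(
        id, "gene", parents = "Gene",
        axioms = list(axiom("characterized_by", "only", "HP:HP_0000238")))
    } else if (op == "bad_range") {
      kb$classes[[id]] <- class_def(
        id, "dysplasia", parents = "Bone_Dysplasia",
        axioms = list(axiom("characterized_by", "only",
                            expr_or(expr_atom("G0000001"),
                                    expr_atom(sample(phe_ids, 1))))))
    } else if (op == "unknown_atom") {
      kb$classes[[id]] <- class_def(
        id, "dysplasia", parents = "Bone_Dysplasia",
        axioms = list(axiom("characterized_by", "only",
                            paste0("ZZ:missing_", i))))
    } else if (op == "dangling_parent") {
      kb$classes[[id]] <- class_def(
        id, "dysplasia", parents = paste0("NoSuchParent_", i))
    } else if (op == "cycle_pair") {
      a <- paste0(id, "_a"); b <- paste0(id, "_b")
      kb$classes[[a]] <- class_def(a, "dysplasia", parents = b)
      kb$classes[[b]] <- class_def(b, "dysplasia", parents = a)
    }
  }
  kb
}

## A random set of individuals over the reference definitions, with a
## mixture of complete and broken link structures.
random_abox <- function(kb) {
  inds <- list()
  gene_i <- individual("i_gene", "G0000001")
  mis_i <- individual("i_missense", "NCI:Missense_Mutation")
  wrong_i <- individual("i_wrong", "HP:HP_0000238")
  inds <- c(inds, list(gene_i, mis_i, wrong_i))
  n <- sample(3:6, 1)
  for (j in seq_len(n)) {
    form <- sample(c("complete", "no_locus", "wrong_locus", "extra_bad_only",
                     "dangling"), 1)
    links <- data.frame(relation = character(0), target = character(0),
                        stringsAsFactors = FALSE)
    add_link <- function(rel, tgt)
      rbind(links, data.frame(relation = rel, target = tgt,
                              stringsAsFactors = FALSE))
    if (form != "no_locus")
      links <- add_link("has_locus",
                        if (form == "wrong_locus") "i_wrong" else "i_gene")
    links <- add_link("mutation_type", "i_missense")
    if (form == "extra_bad_only")
      links <- add_link("has_locus", "i_wrong")
    if (form == "dangling")
      links <- add_link("mutation_type", paste0("ghost_", j))
    inds <- c(inds, list(
      individual(sprintf("i_m%02d", j),
                 sample(c("GM0000001", "GM0000361"), 1), links = links)))
  }
  inds
}

## ---------------------------------------------------------------------------
## Small cohorts for the rule miner

toy_cohort <- function() {
  cs <- list()
  for (i in 1:8)
    cs <- c(cs, list(patient_case(paste0("c", i),
                                  phenotypes = c("p1", "p2",
                                                 if (i %% 2) "p3"),
                                  diagnosis = "X")))
  for (i in 9:10)
    cs <- c(cs, list(patient_case(paste0("c", i),
                                  phenotypes = c("p4", if (i == 9) "p1"),
                                  diagnosis = "Y")))
  cs
}

# Exhaustive rule enumeration over all antecedent subsets up to the cap.
oracle_rules <- function(cases, min_support, min_confidence,
                         max_antecedent = 3L) {
  n <- length(cases)
  phen_sets <- lapply(cases, `[[`, "phenotypes")
  diags <- vapply(cases, `[[`, character(1), "diagnosis")
  items <- sort(unique(unlist(phen_sets)))
  rows <- list()
  for (k in seq_len(min(max_antecedent, length(items)))) {
    for (A in utils::combn(items, k, simplify = FALSE)) {
      nA <- sum(vapply(phen_sets, function(s) all(A %in% s), logical(1)))
      if (nA == 0) next
      for (X in sort(unique(diags[!is.na(diags)]))) {
        joint <- sum(vapply(seq_len(n), function(i)
          !is.na(diags[i]) && diags[i] == X && all(A %in% phen_sets[[i]]),
          logical(1)))
        if (joint == 0) next
        supp <- joint / n
        conf <- joint / nA
        if (supp >= min_support - 1e-9 && conf >= min_confidence - 1e-9)
          rows[[length(rows) + 1L]] <- list(antecedent = A, consequent = X,
                                            support = supp,
                                            confidence = conf)
      }
    }
  }
  rows
}

rules_key <- function(rules_df) {
  if (!nrow(rules_df)) return(character(0))
  sort(vapply(seq_len(nrow(rules_df)), function(i)
    paste(paste(rules_df$antecedent[[i]], collapse = ","),
          rules_df$consequent[i],
          format(rules_df$support[i], digits = 10),
          format(rules_df$confidence[i], digits = 10), sep = " => "),
    character(1)))
}

rules_key_list <- function(rows) {
  sort(vapply(rows, function(r)
    paste(paste(r$antecedent, collapse = ","), r$consequent,
          format(r$support, digits = 10),
          format(r$confidence, digits = 10), sep = " => "),
    character(1)))
}
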