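## Decision-support analytics: phenotype profiles, overlap, disorder ranking,
## association-rule mining refined by class axioms, and dictionary annotation
## of clinical text.

#' Create a patient case
#'
#' @param id Case identifier.
#' @param phenotypes Character vector of phenotype term ids.
#' @param mutations Character vector of gene-mutation term ids.
#' @param diagnosis Dysplasia class id (ground truth when known), or `NA`.
#' @return A `bd_case`.
#' @export
patient_case <- function(id, phenotypes = character(0),
                         mutations = character(0),
                         diagnosis = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id,
                 phenotypes = sort(unique(normalize_term_id(as.character(phenotypes)))),
                 mutations = sort(unique(normalize_term_id(as.character(mutations)))),
                 diagnosis = if (is.na(diagnosis)) NA_character_
                             else normalize_term_id(diagnosis)),
            class = "bd_case")
}

#' Read / write patient cases as JSON
#'
#' Cases are exchanged as a JSON array of objects with fields `id`,
#' `phenotypes`, `mutations`, `diagnosis` (`null` when unknown).
#'
#' @param path File path.
#' @return `read_cases()` returns a list of `bd_case` objects.
#' @export
read_cases <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(x) {
    patient_case(id = x$id,
                 phenotypes = unlist(x$phenotypes) %||% character(0),
                 mutations = unlist(x$mutations) %||% character(0),
                 diagnosis = if (is.null(x$diagnosis)) NA_character_
                             else x$diagnosis)
  })
}

#' @rdname read_cases
#' @param cases List of `bd_case` objects.
#' @export
write_cases <- function(cases, path) {
  out <- lapply(cases, function(x) {
    list(id = x$id, phenotypes = as.list(x$phenotypes),
         mutations = as.list(x$mutations),
         diagnosis = if (is.na(x$diagnosis)) NULL else x$diagnosis)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Profiles and overlap

#' Phenotype profile of a dysplasia
#'
#' The phenotype-kind atoms of the union of the class's `characterized_by`
#' fillers: HP/REAMS external terms and phenotypic composites. Gene-mutation
#' atoms are excluded.
#'
#' @param kb A `bd_kb`.
#' @param dysplasia Dysplasia class id.
#' @return Sorted character vector of phenotype term ids.
#' @export
phenotype_profile <- function(kb, dysplasia) {
  stopifnot(inherits(kb, "bd_kb"))
  dysplasia <- normalize_term_id(dysplasia)
  atoms <- characterized_by_atoms(kb, dysplasia)
  sort(atoms[vapply(atoms, function(a) atom_is_phenotype(kb, a),
                    logical(1))]) %||% character(0)
}

#' Phenotype overlap between two dysplasias
#'
#' @param kb A `bd_kb`.
#' @param d1,d2 Dysplasia class ids.
#' @return The size of the intersection of the two phenotype profiles
#'   (symmetric).
#' @export
profile_overlap <- function(kb, d1, d2) {
  length(intersect(phenotype_profile(kb, d1), phenotype_profile(kb, d2)))
}

#' Phenotype-overlap distribution around a focus dysplasia
#'
#' All other dysplasias sharing at least one profile phenotype with the
#' focus, with the overlap count - the chart behind "disorders with
#' correlated phenotypes".
#'
#' @param kb A `bd_kb`.
#' @param focus Dysplasia class id.
#' @return A `data.frame` with columns `dysplasia`, `overlap`, sorted by
#'   decreasing overlap then id.
#' @export
overlap_distribution <- function(kb, focus) {
  stopifnot(inherits(kb, "bd_kb"))
  focus <- normalize_term_id(focus)
  fp <- phenotype_profile(kb, focus)
  ds <- setdiff(class_ids(kb, "dysplasia"), focus)
  ov <- vapply(ds, function(d)
    length(intersect(fp, phenotype_profile(kb, d))), integer(1))
  keep <- ov > 0L
  out <- data.frame(dysplasia = ds[keep], overlap = unname(ov[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overlap, out$dysplasia), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Disorder ranking

#' Rank disorders for a phenotype set
#'
#' Default scorer: Jaccard similarity between the patient phenotype set and
#' each dysplasia's phenotype profile. The alternative `"rules"` scorer sums
#' the confidences of fired association rules per consequent (normalized to
#' `[0, 1]` over all fired rules); it requires `rules`, typically the output
#' of [refine_rules()]. Ties are broken by term id; only disorders with a
#' positive score are returned. Mutations asserted in cases are accepted but
#' not used by either scorer.
#'
#' @param kb A `bd_kb`.
#' @param phenotypes Non-empty character vector of phenotype term ids.
#' @param method `"jaccard"` (default) or `"rules"`.
#' @param rules Association rules `data.frame` (for `method = "rules"`).
#' @return A `data.frame` with columns `dysplasia`, `score`, and a list
#'   column `evidence` holding the matched phenotypes, sorted by decreasing
#'   score then id.
#' @export
rank_disorders <- function(kb, phenotypes, method = c("jaccard", "rules"),
                           rules = NULL) {
  stopifnot(inherits(kb, "bd_kb"))
  method <- match.arg(method)
  phenotypes <- unique(normalize_term_id(as.character(phenotypes)))
  if (!length(phenotypes)) stop("phenotype set must be non-empty")
  ds <- class_ids(kb, "dysplasia")
  if (method == "jaccard") {
    rows <- lapply(ds, function(d) {
      prof <- phenotype_profile(kb, d)
      if (!length(prof)) return(NULL)
      hit <- sort(intersect(phenotypes, prof))
      score <- length(hit) / length(union(phenotypes, prof))
      if (score <= 0) return(NULL)
      list(dysplasia = d, score = score, evidence = hit)
    })
  } else {
    if (is.null(rules)) stop("method = 'rules' needs a rules data.frame")
    fired <- vapply(seq_len(nrow(rules)), function(i)
      all(rules$antecedent[[i]] %in% phenotypes), logical(1))
    fr <- rules[fired, , drop = FALSE]
    total <- sum(fr$confidence)
    rows <- lapply(ds, function(d) {
      sel <- fr[fr$consequent == d, , drop = FALSE]
      if (!nrow(sel) || total <= 0) return(NULL)
      list(dysplasia = d, score = sum(sel$confidence) / total,
           evidence = sort(unique(unlist(sel$antecedent))))
    })
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- data.frame(dysplasia = character(0), score = numeric(0))
    out$evidence <- list()
    return(out)
  }
  out <- data.frame(
    dysplasia = vapply(rows, `[[`, character(1), "dysplasia"),
    score = vapply(rows, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  out$evidence <- lapply(rows, `[[`, "evidence")
  out <- out[order(-out$score, out$dysplasia), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Association rule mining

#' Mine phenotype-to-diagnosis association rules
#'
#' Apriori-complete enumeration of rules `{phenotype subset} -> diagnosis`
#' over diagnosed patient cases, with antecedent size capped. Support of a
#' rule is the fraction of all cases containing the antecedent and carrying
#' the diagnosis; confidence is that count divided by the number of cases
#' containing the antecedent.
#'
#' @param cases List of `bd_case` objects; at least one must be diagnosed.
#' @param min_support Minimum rule support in `(0, 1]`.
#' @param min_confidence Minimum rule confidence in `(0, 1]`.
#' @param max_antecedent Antecedent size cap (default 3).
#' @return A `data.frame` with list column `antecedent` (sorted term ids),
#'   and columns `consequent`, `support`, `confidence`, ordered by
#'   consequent then antecedent.
#' @export
mine_rules <- function(cases, min_support, min_confidence,
                       max_antecedent = 3L) {
  stopifnot(is.list(cases), length(cases) >= 1L,
            min_support > 0, min_support <= 1,
            min_confidence > 0, min_confidence <= 1)
  diags <- vapply(cases, `[[`, character(1), "diagnosis")
  if (all(is.na(diags))) stop("no diagnosed cases")
  n <- length(cases)
  eps <- 1e-9
  phen_sets <- lapply(cases, `[[`, "phenotypes")
  items <- sort(unique(unlist(phen_sets)))

  count_antecedent <- function(A)
    sum(vapply(phen_sets, function(s) all(A %in% s), logical(1)))
  count_joint <- function(A, X)
    sum(vapply(seq_len(n), function(i)
      !is.na(diags[i]) && diags[i] == X && all(A %in% phen_sets[[i]]),
      logical(1)))

  ## level-wise frequent antecedents (pruned by antecedent support)
  min_count <- min_support * n - eps
  frequent <- list()
  level <- lapply(items, identity)
  level <- Filter(function(A) count_antecedent(A) >= min_count, level)
  k <- 1L
  while (length(level) && k <= max_antecedent) {
    frequent <- c(frequent, level)
    if (k == max_antecedent) break
    pool <- sort(unique(unlist(level)))
    keys <- vapply(level, paste, character(1), collapse = "\r")
    nxt <- list()
    if (length(pool) >= k + 1L) {
      cand <- utils::combn(pool, k + 1L, simplify = FALSE)
      for (A in cand) {
        subs <- utils::combn(A, k, simplify = FALSE)
        if (!all(vapply(subs, paste, character(1), collapse = "\r") %in% keys))
          next
        if (count_antecedent(A) >= min_count)
          nxt <- c(nxt, list(A))
      }
    }
    level <- nxt
    k <- k + 1L
  }

  rows <- list()
  for (A in frequent) {
    nA <- count_antecedent(A)
    for (X in sort(unique(diags[!is.na(diags)]))) {
      joint <- count_joint(A, X)
      if (joint == 0L) next
      support <- joint / n
      confidence <- joint / nA
      if (support >= min_support - eps && confidence >= min_confidence - eps)
        rows[[length(rows) + 1L]] <- list(antecedent = A, consequent = X,
                                          support = support,
                                          confidence = confidence)
    }
  }
  if (!length(rows)) {
    out <- data.frame(consequent = character(0), support = numeric(0),
                      confidence = numeric(0))
    out$antecedent <- list()
    return(out[c("antecedent", "consequent", "support", "confidence")])
  }
  key <- vapply(rows, function(r) paste(r$antecedent, collapse = "|"),
                character(1))
  cons <- vapply(rows, `[[`, character(1), "consequent")
  ord <- order(cons, key)
  out <- data.frame(consequent = cons[ord],
                    support = vapply(rows, `[[`, numeric(1), "support")[ord],
                    confidence = vapply(rows, `[[`, numeric(1),
                                        "confidence")[ord],
                    stringsAsFactors = FALSE)
  out$antecedent <- lapply(rows[ord], `[[`, "antecedent")
  out[c("antecedent", "consequent", "support", "confidence")]
}

#' Refine association rules against class axioms
#'
#' Keeps only the rules whose every antecedent phenotype is compatible with
#' the consequent dysplasia's `characterized_by` universal filler
#' (subsumption-aware; a consequent without such an axiom is unconstrained).
#' The operation never adds rules and is idempotent.
#'
#' @param kb A `bd_kb`.
#' @param rules Output of [mine_rules()].
#' @return The filtered rules `data.frame`.
#' @export
refine_rules <- function(kb, rules) {
  stopifnot(inherits(kb, "bd_kb"), is.data.frame(rules))
  if (!nrow(rules)) return(rules)
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    d <- rules$consequent[i]
    if (!kb_has_class(kb, d)) stop("unknown consequent dysplasia: ", d)
    terms_compatible_with_dysplasia(kb, rules$antecedent[[i]], d)
  }, logical(1))
  out <- rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Text annotation

#' Annotate clinical text with lexicon terms
#'
#' Dictionary annotation: case-insensitive, left-to-right, longest-match,
#' non-overlapping spans on word boundaries. Offsets are 0-based half-open
#' positions on the normalized text (whitespace runs collapsed to single
#' spaces), returned as `attr(result, "text")`.
#'
#' @param text The clinical summary.
#' @param lexicon Lexicon `data.frame` (or TSV path) mapping surface forms to
#'   term ids; see [read_lexicon()].
#' @return A `data.frame` with columns `start`, `end`, `term_id`, `surface`.
#' @export
annotate_text <- function(text, lexicon) {
  hits <- lexicon_match(text, lexicon)
  out <- hits[c("start", "end", "term_id", "surface")]
  attr(out, "text") <- attr(hits, "text")
  out
}
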