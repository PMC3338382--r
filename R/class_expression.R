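## Class expressions and restriction axioms.
##
## The grammar mirrors the Manchester-syntax fragments used in the disease
## class definitions: atoms, `and`/`or` with the usual precedence
## (`and` binds tighter), parentheses, and `REL only EXPR` / `REL some EXPR`
## restrictions. A universal+existential pair on the same relation and filler
## normalizes to a single axiom of kind "only_and_some". A disjunction of
## restriction conjunctions (used by the phenotypic-composite root) is stored
## as an axiom of kind "disjunct" with branches.

#' Build a class-expression atom
#' @param id Term id the atom references.
#' @return A `bd_expr` of kind `"atom"`.
#' @export
expr_atom <- function(id) {
  if (!is_valid_term_id(id)) stop("invalid term id: ", deparse(id))
  structure(list(kind = "atom", id = normalize_term_id(id)),
            class = "bd_expr")
}

new_bool_expr <- function(kind, children) {
  children <- lapply(children, function(x) {
    if (!inherits(x, "bd_expr")) stop("children must be bd_expr objects")
    x
  })
  ## flatten nested nodes of the same kind
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  if (length(flat) < 2L) stop(kind, " expression needs at least 2 children")
  structure(list(kind = kind, children = flat), class = "bd_expr")
}

#' Boolean combinations of class expressions
#' @param ... `bd_expr` objects (at least two once flattened).
#' @return A `bd_expr` of kind `"and"` / `"or"`.
#' @export
expr_and <- function(...) new_bool_expr("and", list(...))

#' @rdname expr_and
#' @export
expr_or <- function(...) new_bool_expr("or", list(...))

#' Atoms referenced by a class expression
#' @param expr A `bd_expr`.
#' @return Character vector of term ids, in depth-first order.
#' @export
expression_atoms <- function(expr) {
  stopifnot(inherits(expr, "bd_expr"))
  if (expr$kind == "atom") return(expr$id)
  unlist(lapply(expr$children, expression_atoms), use.names = FALSE)
}

#' Build a restriction axiom
#'
#' @param relation One of the registry relations
#'   (`r paste0('\x60', RELATIONS, '\x60', collapse = ", ")`).
#' @param kind `"only"`, `"some"`, or `"only_and_some"` (the
#'   universal+existential pair on the same filler).
#' @param filler A `bd_expr` (or a term id, promoted to an atom).
#' @return A `bd_axiom`.
#' @examples
#' axiom("has_locus", "only_and_some", "G0000001")
#' @export
axiom <- function(relation, kind = c("only", "some", "only_and_some"),
                  filler) {
  if (!relation %in% RELATIONS) stop("unknown relation: ", relation)
  kind <- match.arg(kind)
  if (is.character(filler)) filler <- expr_atom(filler)
  stopifnot(inherits(filler, "bd_expr"))
  structure(list(relation = relation, kind = kind, filler = filler),
            class = "bd_axiom")
}

#' Build a disjunctive axiom
#'
#' A disjunction of restriction conjunctions, e.g. the phenotypic-composite
#' root's "(has_part ...) or (describes ...)" alternatives.
#'
#' @param branches A list; each element is a list of `bd_axiom` objects
#'   (one conjunction branch).
#' @return A `bd_axiom` of kind `"disjunct"`.
#' @export
axiom_disjunct <- function(branches) {
  stopifnot(is.list(branches), length(branches) >= 2L)
  branches <- lapply(branches, function(b) {
    if (inherits(b, "bd_axiom")) b <- list(b)
    stopifnot(length(b) >= 1L)
    lapply(b, function(a) {
      if (!inherits(a, "bd_axiom") || a$kind == "disjunct")
        stop("disjunct branches must contain plain restriction axioms")
      a
    })
  })
  structure(list(relation = NA_character_, kind = "disjunct",
                 branches = branches),
            class = "bd_axiom")
}

axiom_relations <- function(a) {
  if (a$kind == "disjunct")
    unique(unlist(lapply(a$branches, function(b)
      vapply(b, `[[`, character(1), "relation"))))
  else a$relation
}

## All atoms referenced by an axiom's filler(s).
axiom_atoms <- function(a) {
  if (a$kind == "disjunct")
    unique(unlist(lapply(a$branches, function(b)
      unlist(lapply(b, function(x) expression_atoms(x$filler))))))
  else unique(expression_atoms(a$filler))
}

## ---------------------------------------------------------------------------
## Tokenizer

ce_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[[:space:]]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      tokens[[length(tokens) + 1L]] <- list(type = ch, value = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[A-Za-z0-9_:.#/-]+", substr(text, i, n)))
    if (length(m) == 0L)
      stop(sprintf("class-expression syntax error at position %d: unexpected '%s'",
                   i, ch), call. = FALSE)
    type <- if (m %in% c("and", "or", "only", "some")) m else "ident"
    tokens[[length(tokens) + 1L]] <- list(type = type, value = m, pos = i)
    i <- i + nchar(m)
  }
  tokens
}

## ---------------------------------------------------------------------------
## Recursive-descent parser
##
## EXPR := AND ('or' AND)*
## AND  := PRIM ('and' PRIM)*
## PRIM := RESTRICTION | ident | '(' EXPR ')'
## RESTRICTION := relation ('only'|'some') FILLER
## FILLER := ident | '(' EXPR ')'      (must be a pure class expression)
##
## The raw parse tree may mix restriction leaves with class-expression nodes;
## normalization afterwards decides whether the input is a plain expression
## or an axiom set, and rejects mixtures.

ce_parser_env <- function(tokens, text) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env$text <- text
  env
}

ce_peek <- function(p) if (p$pos <= length(p$tokens)) p$tokens[[p$pos]] else NULL
ce_next <- function(p) { t <- ce_peek(p); p$pos <- p$pos + 1L; t }
ce_fail <- function(p, msg) {
  t <- ce_peek(p)
  at <- if (is.null(t)) nchar(p$text) + 1L else t$pos
  stop(sprintf("class-expression syntax error at position %d: %s", at, msg),
       call. = FALSE)
}

ce_parse_expr <- function(p) {
  terms <- list(ce_parse_and(p))
  while (!is.null(t <- ce_peek(p)) && t$type == "or") {
    ce_next(p)
    terms <- c(terms, list(ce_parse_and(p)))
  }
  if (length(terms) == 1L) terms[[1L]]
  else list(node = "or", children = terms)
}

ce_parse_and <- function(p) {
  terms <- list(ce_parse_prim(p))
  while (!is.null(t <- ce_peek(p)) && t$type == "and") {
    ce_next(p)
    terms <- c(terms, list(ce_parse_prim(p)))
  }
  if (length(terms) == 1L) terms[[1L]]
  else list(node = "and", children = terms)
}

ce_parse_prim <- function(p) {
  t <- ce_peek(p)
  if (is.null(t)) ce_fail(p, "unexpected end of input")
  if (t$type == "(") {
    ce_next(p)
    inner <- ce_parse_expr(p)
    t2 <- ce_next(p)
    if (is.null(t2) || t2$type != ")") ce_fail(p, "expected ')'")
    return(inner)
  }
  if (t$type != "ident") ce_fail(p, paste0("unexpected '", t$value, "'"))
  nxt <- if (p$pos + 1L <= length(p$tokens)) p$tokens[[p$pos + 1L]] else NULL
  if (!is.null(nxt) && nxt$type %in% c("only", "some")) {
    ce_next(p)  # relation
    if (!t$value %in% RELATIONS)
      stop(sprintf("unknown relation '%s' at position %d", t$value, t$pos),
           call. = FALSE)
    quant <- ce_next(p)$type
    filler <- ce_parse_filler(p)
    return(list(node = "restriction", relation = t$value, quant = quant,
                filler = filler))
  }
  ce_next(p)
  list(node = "atom", id = t$value)
}

ce_parse_filler <- function(p) {
  t <- ce_peek(p)
  if (is.null(t)) ce_fail(p, "missing restriction filler")
  if (t$type == "(") {
    ce_next(p)
    inner <- ce_parse_expr(p)
    t2 <- ce_next(p)
    if (is.null(t2) || t2$type != ")") ce_fail(p, "expected ')'")
    return(inner)
  }
  if (t$type != "ident") ce_fail(p, "restriction filler must be a class expression")
  ce_next(p)
  list(node = "atom", id = t$value)
}

tree_has_restriction <- function(t) {
  if (t$node == "restriction") return(TRUE)
  if (t$node %in% c("and", "or"))
    return(any(vapply(t$children, tree_has_restriction, logical(1))))
  FALSE
}

tree_to_expr <- function(t) {
  if (t$node == "restriction")
    stop("restriction not allowed inside a restriction filler", call. = FALSE)
  if (t$node == "atom") return(expr_atom(t$id))
  do.call(if (t$node == "and") expr_and else expr_or,
          lapply(t$children, tree_to_expr))
}

tree_to_axioms <- function(t) {
  ## t is a raw tree containing restrictions: interpret as an axiom
  ## conjunction at top level.
  items <- if (t$node == "and") t$children else list(t)
  axioms <- list()
  for (it in items) {
    if (it$node == "restriction") {
      axioms <- c(axioms, list(axiom(it$relation, it$quant,
                                     tree_to_expr(it$filler))))
    } else if (it$node == "or" && tree_has_restriction(it)) {
      branches <- lapply(it$children, function(br) {
        if (!tree_has_restriction(br))
          stop("cannot mix restrictions and plain class expressions in 'or'",
               call. = FALSE)
        merge_only_some(tree_to_branch(br))
      })
      axioms <- c(axioms, list(axiom_disjunct(branches)))
    } else {
      stop("cannot mix restrictions and plain class expressions in 'and'",
           call. = FALSE)
    }
  }
  merge_only_some(axioms)
}

tree_to_branch <- function(t) {
  items <- if (t$node == "and") t$children else list(t)
  lapply(items, function(it) {
    if (it$node != "restriction")
      stop("disjunction branches must be conjunctions of restrictions",
           call. = FALSE)
    axiom(it$relation, it$quant, tree_to_expr(it$filler))
  })
}

## Merge `REL only F` + `REL some F` (equal relation and filler) into a
## single only_and_some axiom, kept at the position of the first member.
merge_only_some <- function(axioms) {
  n <- length(axioms)
  if (n < 2L) return(axioms)
  keys <- vapply(axioms, function(a) {
    if (a$kind == "disjunct") NA_character_
    else paste(a$relation, serialize_expr(a$filler))
  }, character(1))
  used <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (used[i]) next
    a <- axioms[[i]]
    if (a$kind %in% c("only", "some") && !is.na(keys[i])) {
      want <- if (a$kind == "only") "some" else "only"
      j <- which(!used & seq_len(n) > i & keys == keys[i] &
                   vapply(axioms, function(x) identical(x$kind, want),
                          logical(1)))
      if (length(j)) {
        used[j[1L]] <- TRUE
        a <- axiom(a$relation, "only_and_some", a$filler)
      }
    }
    used[i] <- TRUE
    out <- c(out, list(a))
  }
  out
}

#' Parse a Manchester-style class expression
#'
#' Parses the restricted grammar used in the disease class definitions:
#' atoms, `and`/`or`, parentheses, and `REL only EXPR` / `REL some EXPR`
#' restrictions. A universal+existential pair on the same relation and filler
#' (`has_locus only Gene and has_locus some Gene`) normalizes to a single
#' axiom of kind `"only_and_some"`. A disjunction of parenthesized
#' restriction conjunctions becomes a `"disjunct"` axiom.
#'
#' @param text The expression string.
#' @return A `bd_expr` when the input is a plain class expression, or a
#'   `bd_axiom_set` (list of `bd_axiom`) when it contains restrictions.
#' @examples
#' parse_class_expression("has_locus only Gene and has_locus some Gene")
#' parse_class_expression("characterized_by only (GM000001 or HP:HP_0000238)")
#' parse_class_expression("Gene")
#' @export
parse_class_expression <- function(text) {
  tokens <- ce_tokenize(text)
  if (!length(tokens))
    stop("class-expression syntax error at position 1: empty expression",
         call. = FALSE)
  p <- ce_parser_env(tokens, text)
  tree <- ce_parse_expr(p)
  if (!is.null(ce_peek(p))) ce_fail(p, "trailing input")
  if (!tree_has_restriction(tree)) {
    ## normalize internal ids inside the expression
    return(tree_to_expr(tree))
  }
  structure(tree_to_axioms(tree), class = "bd_axiom_set")
}

## ---------------------------------------------------------------------------
## Serialization

serialize_expr <- function(expr) {
  if (expr$kind == "atom") return(expr$id)
  parts <- vapply(expr$children, function(ch) {
    s <- serialize_expr(ch)
    ## 'and' binds tighter than 'or': parenthesize an or-child of an and-node
    if (expr$kind == "and" && ch$kind == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$kind, " "))
}

serialize_axiom <- function(a) {
  if (a$kind == "disjunct") {
    return(paste(vapply(a$branches, function(b) {
      paste0("(", paste(vapply(b, serialize_axiom, character(1)),
                        collapse = " and "), ")")
    }, character(1)), collapse = " or "))
  }
  filler <- serialize_expr(a$filler)
  if (a$filler$kind != "atom") filler <- paste0("(", filler, ")")
  switch(a$kind,
         only = paste(a$relation, "only", filler),
         some = paste(a$relation, "some", filler),
         only_and_some = paste(a$relation, "only", filler, "and",
                               a$relation, "some", filler))
}

#' Serialize a class expression or axiom (set)
#'
#' Deterministic inverse of [parse_class_expression()]:
#' `parse_class_expression(serialize_class_expression(x))` reproduces `x`.
#'
#' @param x A `bd_expr`, `bd_axiom`, or `bd_axiom_set`.
#' @return A single string.
#' @export
serialize_class_expression <- function(x) {
  if (inherits(x, "bd_expr")) return(serialize_expr(x))
  if (inherits(x, "bd_axiom")) return(serialize_axiom(x))
  if (inherits(x, "bd_axiom_set"))
    return(paste(vapply(x, serialize_axiom, character(1)),
                 collapse = " and "))
  stop("cannot serialize object of class ", paste(class(x), collapse = "/"))
}

#' @export
print.bd_expr <- function(x, ...) {
  cat(serialize_class_expression(x), "\n")
  invisible(x)
}

#' @export
print.bd_axiom <- function(x, ...) {
  cat(serialize_class_expression(x), "\n")
  invisible(x)
}

#' @export
print.bd_axiom_set <- function(x, ...) {
  for (a in x) cat(serialize_class_expression(a), "\n")
  invisible(x)
}
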