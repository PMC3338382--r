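## HGVS-derived gene-mutation encoding.
##
## A mutation is recorded at two levels: a protein-level substitution
## (three-letter reference amino acid, position, alternate amino acid) and a
## nucleotide-level substitution (1-based offset, original and mutated
## content, count = number of affected nucleotides). Either part may be
## absent, but not both. The worked reference instance is
## "GLY380ARG, 1138 G-A": a missense change GLY -> ARG at residue 380 caused
## by a G -> A substitution at nucleotide offset 1138 (count 1).

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Create a gene-mutation record
#'
#' @param protein_change `NULL`, or a list with elements `ref_aa`, `position`,
#'   `alt_aa` (three-letter amino-acid codes, 1-based residue position).
#' @param offset 1-based nucleotide offset within the reference used by the
#'   source (coordinate system is recorded opaquely, not converted), or `NA`.
#' @param original_content,mutated_content Nucleotide strings over `ACGT`
#'   (empty when the nucleotide part is absent).
#' @param locus Optional gene class id.
#' @param mutation_type Optional external term id under the
#'   `NCI:Mutation_Abnormality` subtree.
#' @return A `bd_mutation` record; `count` is derived as
#'   `nchar(original_content)`.
#' @export
mutation_record <- function(protein_change = NULL, offset = NA_integer_,
                            original_content = "", mutated_content = "",
                            locus = NA_character_,
                            mutation_type = NA_character_) {
  if (!is.null(protein_change)) {
    stopifnot(is.list(protein_change),
              all(c("ref_aa", "position", "alt_aa") %in% names(protein_change)))
    protein_change$ref_aa <- toupper(protein_change$ref_aa)
    protein_change$alt_aa <- toupper(protein_change$alt_aa)
    if (!protein_change$ref_aa %in% AA3)
      stop("malformed amino-acid code: ", protein_change$ref_aa)
    if (!protein_change$alt_aa %in% AA3)
      stop("malformed amino-acid code: ", protein_change$alt_aa)
    protein_change$position <- as.integer(protein_change$position)
    if (is.na(protein_change$position) || protein_change$position < 1L)
      stop("protein position must be a positive integer")
  }
  original_content <- toupper(original_content)
  mutated_content <- toupper(mutated_content)
  has_nt <- nzchar(original_content) || nzchar(mutated_content) || !is.na(offset)
  if (has_nt) {
    if (!grepl("^[ACGT]+$", original_content))
      stop("original content must be a nucleotide string over ACGT")
    if (!grepl("^[ACGT]+$", mutated_content))
      stop("mutated content must be a nucleotide string over ACGT")
    offset <- as.integer(offset)
    if (is.na(offset) || offset < 1L)
      stop("offset must be a positive integer")
  }
  if (is.null(protein_change) && !has_nt)
    stop("mutation record needs a protein part or a nucleotide part")
  structure(
    list(protein_change = protein_change,
         offset = if (has_nt) offset else NA_integer_,
         original_content = original_content,
         mutated_content = mutated_content,
         count = nchar(original_content),
         locus = locus, mutation_type = mutation_type),
    class = "bd_mutation"
  )
}

#' Parse a gene-mutation encoding
#'
#' Accepts the dialect `AAA<pos>BBB, <offset> <orig>-<mut>` with either part
#' optional (but at least one present); separators between the two parts may
#' be a comma and/or whitespace; amino-acid codes are case-insensitive.
#' `count` is derived as the length of the original content.
#'
#' @param text The encoding, e.g. `"GLY380ARG, 1138 G-A"`.
#' @return A `bd_mutation` record (without locus/type).
#' @examples
#' parse_mutation_encoding("GLY380ARG, 1138 G-A")
#' parse_mutation_encoding("1138 G-A")
#' @export
parse_mutation_encoding <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  prot_re <- "([A-Za-z]{3})([0-9]+)([A-Za-z]{3})"
  nt_re <- "([0-9]+)[[:space:]]+([A-Za-z]+)-([A-Za-z]+)"
  full <- paste0("^", prot_re, "[[:space:]]*(?:,[[:space:]]*|[[:space:]]+)",
                 nt_re, "$")
  m <- regmatches(s, regexec(full, s))[[1]]
  if (length(m) == 7L) {
    return(mutation_record(
      protein_change = list(ref_aa = m[2], position = as.integer(m[3]),
                            alt_aa = m[4]),
      offset = as.integer(m[5]), original_content = m[6],
      mutated_content = m[7]))
  }
  m <- regmatches(s, regexec(paste0("^", nt_re, "$"), s))[[1]]
  if (length(m) == 4L) {
    return(mutation_record(offset = as.integer(m[2]),
                           original_content = m[3], mutated_content = m[4]))
  }
  m <- regmatches(s, regexec(paste0("^", prot_re, "$"), s))[[1]]
  if (length(m) == 4L) {
    return(mutation_record(
      protein_change = list(ref_aa = m[2], position = as.integer(m[3]),
                            alt_aa = m[4])))
  }
  stop("malformed mutation encoding: ", shQuote(text), call. = FALSE)
}

#' Serialize a gene-mutation record
#'
#' Canonical form: `AAA<pos>BBB, <offset> <orig>-<mut>`, upper case, with the
#' protein part and/or nucleotide part omitted when absent.
#'
#' @param rec A `bd_mutation` record.
#' @return A single string.
#' @examples
#' serialize_mutation(parse_mutation_encoding("gly380arg,1138 g-a"))
#' @export
serialize_mutation <- function(rec) {
  stopifnot(inherits(rec, "bd_mutation"))
  prot <- if (!is.null(rec$protein_change)) {
    with(rec$protein_change, paste0(ref_aa, position, alt_aa))
  } else NULL
  nt <- if (nzchar(rec$original_content)) {
    paste0(rec$offset, " ", rec$original_content, "-", rec$mutated_content)
  } else NULL
  paste(c(prot, nt), collapse = ", ")
}

#' @export
print.bd_mutation <- function(x, ...) {
  cat("<gene mutation> ", serialize_mutation(x), "\n", sep = "")
  if (nzchar(x$original_content))
    cat("  offset ", x$offset, ", count ", x$count, ", ",
        x$original_content, " -> ", x$mutated_content, "\n", sep = "")
  if (!is.na(x$locus)) cat("  locus: ", x$locus, "\n", sep = "")
  if (!is.na(x$mutation_type)) cat("  type: ", x$mutation_type, "\n", sep = "")
  invisible(x)
}

#' Register a gene mutation class in the knowledge base
#'
#' Creates a gene-mutation class under the `Gene_Mutation` root with the
#' axiom pattern of the reference definitions: `has_locus only G and
#' has_locus some G`, `mutation_type only T and mutation_type some T`, and
#' the encoding carried as annotation properties (`encoding`, `offset`,
#' `count`, `original_content`, `mutated_content`).
#'
#' @param kb A `bd_kb`.
#' @param mutation_id Id for the new class (e.g. from
#'   `next_id(kb, "gene_mutation")`).
#' @param record A `bd_mutation` record.
#' @param gene_id Id of an existing gene-pillar class.
#' @param type_ref Id of an external term under `NCI:Mutation_Abnormality`
#'   (added to the knowledge base beforehand via [add_external_ref()]).
#' @param label Optional label; defaults to the mutation id.
#' @return The updated knowledge base.
#' @export
attach_mutation <- function(kb, mutation_id, record, gene_id, type_ref,
                            label = mutation_id) {
  stopifnot(inherits(kb, "bd_kb"), inherits(record, "bd_mutation"))
  mutation_id <- normalize_term_id(mutation_id)
  gene_id <- normalize_term_id(gene_id)
  gene <- kb$classes[[gene_id]]
  if (is.null(gene) || gene$pillar != "gene")
    stop("has_locus range violation: ", gene_id, " is not a gene class")
  if (!isTRUE(descends_from(kb, type_ref,
                            c("NCI:Mutation_Abnormality"))))
    stop("mutation_type range violation: ", type_ref,
         " is not under NCI:Mutation_Abnormality")
  ann <- c(encoding = serialize_mutation(record))
  if (nzchar(record$original_content)) {
    ann <- c(ann,
             offset = as.character(record$offset),
             count = as.character(record$count),
             original_content = record$original_content,
             mutated_content = record$mutated_content)
  }
  cls <- class_def(
    id = mutation_id, pillar = "gene_mutation", label = label,
    parents = "Gene_Mutation",
    axioms = list(axiom("has_locus", "only_and_some", gene_id),
                  axiom("mutation_type", "only_and_some", type_ref)),
    annotations = ann
  )
  add_class(kb, cls)
}
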