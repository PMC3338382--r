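## Synthetic nosology and patient-cohort generator.
##
## Emulates the structural statistics of the real ontology: 40 disease
## groups under Bone_Dysplasia, leaf dysplasias at depth 2 with a fraction
## nested at depth 3 (historically subsumed diseases), genes / gene mutations
## / proteins wired via has_locus and is_encoded_by, and characterized_by
## axioms linking >70% of leaves to gene mutations and ~80% to phenotypes
## drawn from a synthetic HP-like phenotype pool with a random parent forest
## (so subsumption-aware matching is exercised). No real HP/OMIM content is
## shipped. Generation is a pure function of the configuration, seed
## included.

with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic nosology generator
#'
#' Defaults reproduce the structural shape of the real nosology at a scale
#' suited to desk-top testing: 40 groups, 3 leaf dysplasias per group, a
#' 100-phenotype pool with per-leaf profiles of size 8, 70% of leaves linked
#' to gene mutations and 80% to phenotypes, and a tenth of the leaves nested
#' at hierarchy depth 3.
#'
#' @param n_groups Number of disease groups (direct subclasses of
#'   `Bone_Dysplasia`).
#' @param dysplasias_per_group Integer range (length-2) of leaves per group.
#' @param n_genes,n_mutations,n_proteins Genotype pillar sizes.
#' @param phenotype_pool_size Size of the synthetic HP-like phenotype pool.
#' @param profile_size Integer range (length-2) of phenotypes per linked
#'   leaf.
#' @param frac_with_mutation Fraction of leaves with gene-mutation atoms in
#'   their `characterized_by` filler.
#' @param frac_with_phenotype Fraction of leaves with phenotype atoms.
#' @param depth3_fraction Fraction of leaves nested under another dysplasia
#'   (depth 3).
#' @param seed Integer seed; generation is a pure function of the config.
#' @param exact_leaves Optional exact total leaf count, overriding random
#'   per-group sizes (used by [paper_scale_config()]).
#' @return A `bd_fixture_config` list.
#' @export
fixture_config <- function(n_groups = 40L,
                           dysplasias_per_group = c(3L, 3L),
                           n_genes = 60L, n_mutations = 90L,
                           n_proteins = 50L,
                           phenotype_pool_size = 100L,
                           profile_size = c(8L, 8L),
                           frac_with_mutation = 0.70,
                           frac_with_phenotype = 0.80,
                           depth3_fraction = 0.10,
                           seed = 42L,
                           exact_leaves = NULL) {
  cfg <- list(n_groups = as.integer(n_groups),
              dysplasias_per_group = as.integer(dysplasias_per_group),
              n_genes = as.integer(n_genes),
              n_mutations = as.integer(n_mutations),
              n_proteins = as.integer(n_proteins),
              phenotype_pool_size = as.integer(phenotype_pool_size),
              profile_size = as.integer(profile_size),
              frac_with_mutation = frac_with_mutation,
              frac_with_phenotype = frac_with_phenotype,
              depth3_fraction = depth3_fraction,
              seed = as.integer(seed),
              exact_leaves = if (is.null(exact_leaves)) NULL
                             else as.integer(exact_leaves))
  stopifnot(cfg$n_groups >= 1L, length(cfg$dysplasias_per_group) == 2L,
            all(cfg$dysplasias_per_group >= 1L),
            cfg$n_genes >= 1L, cfg$n_mutations >= 1L, cfg$n_proteins >= 0L,
            cfg$phenotype_pool_size >= 1L, length(cfg$profile_size) == 2L,
            all(cfg$profile_size >= 1L),
            cfg$profile_size[2] <= cfg$phenotype_pool_size,
            cfg$frac_with_mutation >= 0, cfg$frac_with_mutation <= 1,
            cfg$frac_with_phenotype >= 0, cfg$frac_with_phenotype <= 1,
            cfg$depth3_fraction >= 0, cfg$depth3_fraction <= 1)
  structure(cfg, class = "bd_fixture_config")
}

#' Configuration matching the real ontology's class counts
#'
#' 515 dysplasia classes (40 groups + 475 leaves), 254 genes, 361 gene
#' mutations, 224 proteins.
#'
#' @param seed Integer seed.
#' @return A `bd_fixture_config`.
#' @export
paper_scale_config <- function(seed = 42L) {
  fixture_config(n_groups = 40L, dysplasias_per_group = c(11L, 12L),
                 n_genes = 254L, n_mutations = 361L, n_proteins = 224L,
                 phenotype_pool_size = 400L, profile_size = c(4L, 12L),
                 seed = seed, exact_leaves = 475L)
}

NCI_MUTATION_TYPES <- c("NCI:Missense_Mutation", "NCI:Nonsense_Mutation",
                        "NCI:Splice_Site_Mutation", "NCI:Frameshift_Mutation",
                        "NCI:Silent_Mutation")

## sample() treats a length-1 numeric as 1:n; guard against that
sample_range <- function(lo, hi) {
  if (lo >= hi) lo else sample(seq(lo, hi), 1L)
}

random_mutation_record <- function() {
  len <- sample(1:2, 1L)
  mutation_record(
    protein_change = list(ref_aa = sample(AA3, 1L),
                          position = sample(1:1500, 1L),
                          alt_aa = sample(AA3, 1L)),
    offset = sample(1:5000, 1L),
    original_content = paste(sample(c("A", "C", "G", "T"), len,
                                    replace = TRUE), collapse = ""),
    mutated_content = paste(sample(c("A", "C", "G", "T"), len,
                                   replace = TRUE), collapse = ""))
}

#' Generate a synthetic nosology
#'
#' Builds a knowledge base with the configured group count, leaf dysplasias
#' (a fraction nested one level deeper), synthetic phenotype pool, genes,
#' gene mutations (with grammar-valid encodings) and proteins, wired with
#' the standard axiom patterns. The result always passes [check_tbox()] and
#' is byte-identical across runs with the same configuration. Ground-truth
#' bookkeeping is stored in `kb$bookkeeping` so [kb_stats()] can be tested
#' exactly.
#'
#' @param config A [fixture_config()].
#' @return A `bd_kb`.
#' @examples
#' kb <- generate_nosology(fixture_config(n_groups = 2, seed = 1))
#' kb_stats(kb)$n_groups
#' @export
generate_nosology <- function(config = fixture_config()) {
  stopifnot(inherits(config, "bd_fixture_config"))
  with_seed(config$seed, {
    kb <- empty_kb(title = "Synthetic skeletal dysplasia nosology",
                   creator = "bdokit synthetic generator",
                   version = "1.0")

    ## external scaffolding
    kb <- add_external_ref(kb, external_ref("HP:HP_0000118", "HP",
                                            "Phenotypic abnormality"))
    kb <- add_external_ref(kb, external_ref("REAMS:Abnormality", "REAMS",
                                            "Radiographic abnormality"))
    kb <- add_external_ref(kb, external_ref("HP:HP_0000005", "HP",
                                            "Mode of inheritance"))
    kb <- add_external_ref(kb, external_ref(
      "HP:HP_0000006", "HP", "Autosomal dominant inheritance",
      parent_hint = "HP:HP_0000005"))
    kb <- add_external_ref(kb, external_ref(
      "HP:HP_0000007", "HP", "Autosomal recessive inheritance",
      parent_hint = "HP:HP_0000005"))
    kb <- add_external_ref(kb, external_ref("NCI:Mutation_Abnormality", "NCI",
                                            "Mutation abnormality"))
    for (ty in NCI_MUTATION_TYPES)
      kb <- add_external_ref(kb, external_ref(
        ty, "NCI", gsub("_", " ", sub("^NCI:", "", ty)),
        parent_hint = "NCI:Mutation_Abnormality"))

    ## synthetic HP-like phenotype pool with a random parent forest
    pool <- sprintf("HP:HP_9%06d", seq_len(config$phenotype_pool_size))
    for (i in seq_along(pool)) {
      parent <- if (i > 1L && stats::runif(1) < 0.3)
        pool[sample(i - 1L, 1L)] else "HP:HP_0000118"
      kb <- add_external_ref(kb, external_ref(
        pool[i], "HP", sprintf("Synthetic phenotype %03d", i),
        parent_hint = parent))
    }

    ## genes
    genes <- sprintf("G%07d", seq_len(config$n_genes))
    for (i in seq_along(genes)) {
      kb <- add_class(kb, class_def(
        genes[i], "gene", label = sprintf("SYNG%03d", i),
        alt_labels = sprintf("SYNTHG%03d", i),
        parents = "Gene",
        annotations = c(omim_no = sprintf("6%05d", i),
                        chromosomal_locus = sprintf("%dq%d",
                                                    sample(1:22, 1L),
                                                    sample(10:40, 1L)))))
    }

    ## gene mutations (encodings drawn from the nomenclature grammar)
    mutations <- sprintf("GM%07d", seq_len(config$n_mutations))
    for (i in seq_along(mutations)) {
      rec <- random_mutation_record()
      kb <- attach_mutation(kb, mutations[i], rec,
                            gene_id = sample(genes, 1L),
                            type_ref = sample(NCI_MUTATION_TYPES, 1L))
    }

    ## proteins
    for (i in seq_len(config$n_proteins)) {
      kb <- add_class(kb, class_def(
        sprintf("P%07d", i), "protein", label = sprintf("SYNP%03d", i),
        parents = "Protein",
        axioms = list(axiom("is_encoded_by", "only_and_some",
                            sample(genes, 1L)))))
    }

    ## disease hierarchy
    sizes <- if (!is.null(config$exact_leaves)) {
      base <- config$exact_leaves %/% config$n_groups
      sizes <- rep(base, config$n_groups)
      extra <- config$exact_leaves - sum(sizes)
      if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      sizes
    } else if (config$dysplasias_per_group[1] >= config$dysplasias_per_group[2]) {
      rep(config$dysplasias_per_group[1], config$n_groups)
    } else {
      sample(seq(config$dysplasias_per_group[1],
                 config$dysplasias_per_group[2]),
             config$n_groups, replace = TRUE)
    }
    groups <- sprintf("BDG_%03d", seq_len(config$n_groups))
    for (g in seq_along(groups)) {
      kb <- add_class(kb, class_def(
        groups[g], "dysplasia", label = sprintf("Synthetic group %03d", g),
        parents = "Bone_Dysplasia"))
    }
    d_idx <- 0L
    nodes_by_group <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      for (j in seq_len(sizes[g])) {
        d_idx <- d_idx + 1L
        id <- sprintf("BD_%07d", d_idx)
        parent <- groups[g]
        prior <- nodes_by_group[[g]]
        if (length(prior) && stats::runif(1) < config$depth3_fraction)
          parent <- prior[sample(length(prior), 1L)]
        kb <- add_class(kb, class_def(
          id, "dysplasia", label = sprintf("Synthetic dysplasia %04d", d_idx),
          parents = parent))
        nodes_by_group[[g]] <- c(prior, id)
      }
    }

    ## characterized_by axioms on the leaves: exact fractions, so the
    ## generated ontology always meets the stated linkage bounds
    leaves <- leaf_dysplasias(kb)
    profiles <- stats::setNames(vector("list", length(leaves)), leaves)
    n_leaf <- length(leaves)
    mut_linked <- seq_len(n_leaf) %in%
      sample(n_leaf, ceiling(config$frac_with_mutation * n_leaf))
    phe_linked <- seq_len(n_leaf) %in%
      sample(n_leaf, ceiling(config$frac_with_phenotype * n_leaf))
    for (i in seq_along(leaves)) {
      atoms <- character(0)
      if (mut_linked[i]) {
        atoms <- c(atoms, sample(mutations, sample(1:3, 1L)))
      }
      if (phe_linked[i]) {
        k <- sample_range(config$profile_size[1], config$profile_size[2])
        prof <- sort(sample(pool, k))
        profiles[[i]] <- prof
        atoms <- c(atoms, prof)
      }
      ax <- list()
      if (length(atoms))
        ax <- c(ax, list(axiom("characterized_by", "only", or_of(atoms))))
      if (stats::runif(1) < 0.5) {
        moi <- sample(c("HP:HP_0000006", "HP:HP_0000007"), 1L)
        ax <- c(ax, list(axiom("mode_of_inheritance", "only_and_some", moi)))
      }
      if (length(ax)) kb <- update_class(kb, leaves[i], axioms = ax)
    }

    kb$bookkeeping <- list(
      config = config,
      n_groups = length(groups),
      n_dysplasia_classes = length(groups) + d_idx,
      n_leaves = length(leaves),
      n_genes = length(genes),
      n_mutations = length(mutations),
      n_proteins = config$n_proteins,
      phenotype_pool = pool,
      leaf_profiles = profiles,
      frac_mutation_linked = mean(mut_linked),
      frac_phenotype_linked = mean(phe_linked))
    kb
  })
}

#' Generate a synthetic patient cohort
#'
#' Each case samples a true dysplasia uniformly among leaves with a
#' non-empty phenotype profile, keeps each profile phenotype independently
#' with probability `1 - dropout`, adds `n_spurious` phenotypes drawn
#' uniformly from the off-profile pool, and records the true dysplasia as
#' the diagnosis. One mutation atom of the true dysplasia (when present) is
#' carried over into the case's mutation list.
#'
#' @param kb A `bd_kb` with phenotype-linked dysplasias.
#' @param n Number of cases.
#' @param dropout Per-phenotype drop probability in `[0, 1]`.
#' @param n_spurious Number of off-profile phenotypes added per case.
#' @param seed Integer seed.
#' @return A list of `bd_case` objects.
#' @export
generate_cases <- function(kb, n, dropout = 0.2, n_spurious = 2L,
                           seed = 1L) {
  stopifnot(inherits(kb, "bd_kb"), n >= 1L,
            dropout >= 0, dropout <= 1, n_spurious >= 0L)
  leaves <- leaf_dysplasias(kb)
  profs <- lapply(leaves, function(d) phenotype_profile(kb, d))
  names(profs) <- leaves
  has_prof <- lengths(profs) > 0L
  if (!any(has_prof)) stop("no dysplasia has a non-empty phenotype profile")
  pool <- phenotype_pool(kb)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      d <- sample(leaves[has_prof], 1L)
      prof <- profs[[d]]
      keep <- prof[stats::runif(length(prof)) >= dropout]
      off <- setdiff(pool, prof)
      spur <- if (n_spurious > 0L && length(off))
        sample(off, min(n_spurious, length(off))) else character(0)
      muts <- characterized_by_atoms(kb, d)
      muts <- muts[vapply(muts, function(a) atom_is_mutation(kb, a),
                          logical(1))]
      patient_case(sprintf("case_%04d", i),
                   phenotypes = c(keep, spur),
                   mutations = if (length(muts)) muts[1L] else character(0),
                   diagnosis = d)
    })
  })
}

#' Phenotype pool of a knowledge base
#'
#' All external terms that qualify as phenotype atoms (HP/REAMS sources under
#' their phenotypic-abnormality roots).
#'
#' @param kb A `bd_kb`.
#' @return Sorted character vector of term ids.
#' @export
phenotype_pool <- function(kb) {
  ids <- names(kb$external)
  keep <- vapply(ids, function(i) {
    ref <- kb$external[[i]]
    ref$source %in% c("HP", "REAMS") &&
      !i %in% c("HP:HP_0000118", "REAMS:Abnormality") &&
      isTRUE(descends_from(kb, i, c("HP:HP_0000118", "REAMS:Abnormality")))
  }, logical(1))
  sort(ids[keep])
}
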