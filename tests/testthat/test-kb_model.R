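test_that("identifier normalization canonicalizes the incremental scheme", {
  expect_equal(normalize_term_id(c("GM000001", "GM0000001", "G0000047",
                                   "P00001", "GM00000001")),
               c("GM0000001", "GM0000001", "G0000047", "P0000001",
                 "GM0000001"))
  # non-incremental identifiers pass through
  expect_equal(normalize_term_id(c("HP:HP_0000238", "PC_0000004", "Gene")),
               c("HP:HP_0000238", "PC_0000004", "Gene"))
})

test_that("subclass insertion mirrors the craniosynostosis example", {
  kb <- empty_kb()
  kb <- add_class(kb, class_def("Craniosynostosis_Group", "dysplasia",
                                parents = "Bone_Dysplasia"))
  kb <- add_class(kb, class_def("Pfeiffer_FGFR2", "dysplasia",
                                label = "Pfeiffer syndrome FGFR2-related",
                                parents = "Craniosynostosis_Group"))
  kb <- add_class(kb, class_def("Antley_Bixler_FGFR2", "dysplasia",
                                parents = "Pfeiffer_FGFR2"))
  kb <- add_class(kb, class_def("Jackson_Weiss", "dysplasia",
                                label = "Jackson-Weiss syndrome",
                                parents = "Pfeiffer_FGFR2"))
  expect_setequal(subclasses(kb, "Pfeiffer_FGFR2", direct = TRUE),
                  c("Antley_Bixler_FGFR2", "Jackson_Weiss"))
  # historically subsumed diseases sit at depth 3
  expect_equal(depth(kb, "Jackson_Weiss"), 3L)
  expect_equal(depth(kb, "Pfeiffer_FGFR2"), 2L)
  expect_equal(depth(kb, "Bone_Dysplasia"), 0L)
  # leaves have no children
  expect_length(subclasses(kb, "Jackson_Weiss", direct = TRUE), 0L)
})

test_that("add_class rejects duplicates, dangling parents and self-cycles", {
  kb <- empty_kb()
  kb <- add_class(kb, class_def("D1", "dysplasia",
                                parents = "Bone_Dysplasia"))
  expect_error(add_class(kb, class_def("D1", "dysplasia",
                                       parents = "Bone_Dysplasia")),
               "duplicate")
  expect_error(add_class(kb, class_def("D2", "dysplasia",
                                       parents = "NotThere")),
               "dangling")
  expect_error(add_class(kb, class_def("D3", "dysplasia", parents = "D3")),
               "cycle")
  expect_error(add_class(kb, class_def(
    "G1x", "gene", parents = "Gene",
    axioms = list(axiom("characterized_by", "only", "D1")))),
    "not applicable")
})

test_that("random insertions keep the DAG invariant (DFS oracle)", {
  set.seed(101)
  kb <- empty_kb()
  ids <- "Bone_Dysplasia"
  for (i in 1:100) {
    id <- sprintf("D%03d", i)
    kb <- add_class(kb, class_def(
      id, "dysplasia",
      parents = sample(ids, sample(1:min(2, length(ids)), 1))))
    ids <- c(ids, id)
  }
  expect_true(is_dag(kb))
  expect_length(oracle_cyclic_ids(kb), 0L)
  # moving a disease between groups re-checks the invariant
  kb2 <- move_class(kb, "D050", "Bone_Dysplasia")
  expect_true(is_dag(kb2))
  expect_error(move_class(kb, "D001", subclasses(kb, "D001")[1]),
               "cycle")
})

test_that("transitive subclasses equal BFS reachability on a generated KB", {
  kb <- generate_nosology(fixture_config(n_groups = 6, seed = 5))
  for (id in c("Bone_Dysplasia", sample(class_ids(kb, "dysplasia"), 5)))
    expect_equal(subclasses(kb, id), oracle_subclasses(kb, id))
})

test_that("hierarchy depths are 2 or 3 and match path enumeration", {
  kb <- generate_nosology(fixture_config(n_groups = 10, seed = 11,
                                         depth3_fraction = 0.3))
  leaves <- leaf_dysplasias(kb)
  ds <- vapply(leaves, function(l) depth(kb, l), integer(1))
  expect_true(all(ds %in% c(2L, 3L)))
  for (l in sample(leaves, 10))
    expect_equal(depth(kb, l), max(oracle_depths(kb, l)))
  expect_error(depth(kb, "Gene"), "not a dysplasia")
})

test_that("incremental identifier allocation is minimal, unique, monotone", {
  kb <- empty_kb()
  expect_equal(next_id(kb, "gene"), "G0000001")
  for (i in 1:47)
    kb <- add_class(kb, class_def(sprintf("G%07d", i), "gene",
                                  parents = "Gene"))
  expect_equal(next_id(kb, "gene"), "G0000048")
  expect_error(next_id(kb, "dysplasia"))
  # 500 sequential allocations stay unique
  seen <- character(0)
  kb2 <- empty_kb()
  for (i in 1:500) {
    id <- next_id(kb2, "gene_mutation")
    expect_false(id %in% seen)
    seen <- c(seen, id)
    kb2$classes[[id]] <- class_def(id, "gene_mutation",
                                   parents = "Gene_Mutation")
  }
  expect_equal(seen, sprintf("GM%07d", 1:500))
})

test_that("kb_stats matches generator bookkeeping exactly", {
  cfg <- fixture_config(n_groups = 8, seed = 19)
  kb <- generate_nosology(cfg)
  s <- kb_stats(kb)
  bk <- kb$bookkeeping
  expect_equal(s$n_groups, bk$n_groups)
  expect_equal(unname(s$per_pillar["dysplasia"]), bk$n_dysplasia_classes)
  expect_equal(unname(s$per_pillar["gene"]), bk$n_genes)
  expect_equal(unname(s$per_pillar["gene_mutation"]), bk$n_mutations)
  expect_equal(unname(s$per_pillar["protein"]), bk$n_proteins)
  expect_equal(s$n_leaf_dysplasias, bk$n_leaves)
  expect_equal(s$frac_mutation_linked, bk$frac_mutation_linked)
  expect_equal(s$frac_phenotype_linked, bk$frac_phenotype_linked)
  expect_equal(s$total, bk$n_dysplasia_classes + bk$n_genes +
                 bk$n_mutations + bk$n_proteins)
})

test_that("an empty knowledge base reports zero counts", {
  s <- kb_stats(empty_kb())
  expect_equal(s$total, 0L)
  expect_true(all(s$per_pillar == 0L))
  expect_equal(s$n_groups, 0L)
  expect_true(is.na(s$frac_mutation_linked))
  expect_true(is.na(s$frac_phenotype_linked))
})

test_that("annotation keys are restricted to the shared vocabulary", {
  expect_error(class_def("X", "gene", annotations = c(nonsense = "1")),
               "unknown annotation key")
  cd <- class_def("X", "gene",
                  annotations = c(omim_no = "100800",
                                  uniprot_id = "P22607"))
  expect_equal(cd$annotations[["omim_no"]], "100800")
})

test_that("labels are unique within a pillar", {
  kb <- empty_kb()
  kb <- add_class(kb, class_def("D1", "dysplasia", label = "Same",
                                parents = "Bone_Dysplasia"))
  expect_error(add_class(kb, class_def("D2", "dysplasia", label = "Same",
                                       parents = "Bone_Dysplasia")),
               "already used")
  # same label in another pillar is fine
  expect_silent(add_class(kb, class_def("G0000001", "gene", label = "Same",
                                        parents = "Gene")))
})
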