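test_that("the reference definitions load with full structure", {
  kb <- printed_kb()
  s <- kb_stats(kb)
  expect_equal(s$total, 8L)  # Achondroplasia, G/GM/GM, AC, QC, PC, PC
  expect_equal(unname(s$per_pillar["gene_mutation"]), 2L)
  expect_length(attr(kb, "load_warnings"), 0L)
  # the phenotypic-composite root keeps its disjunctive definition
  pc <- kb$classes[["Phenotypic_Composite"]]
  expect_length(pc$axioms, 2L)
  expect_true(all(vapply(pc$axioms, function(a) a$kind, character(1)) ==
                    "disjunct"))
  # metadata block preserved verbatim
  expect_equal(kb$metadata$title,
               "Bone dysplasia knowledge model: reference definitions")
})

test_that("an empty document yields roots and metadata only", {
  f <- withr::local_tempfile(fileext = ".kb")
  writeLines(c("Ontology:", "  dc:title \"nothing here\""), f)
  kb <- load_kb(f)
  expect_equal(kb_stats(kb)$total, 0L)
  expect_equal(kb$metadata$title, "nothing here")
  expect_setequal(names(kb$classes),
                  c("Bone_Dysplasia", "Gene", "Gene_Mutation", "Protein",
                    "Phenotypic_Composite", "Anatomical_Composite",
                    "Quality_Composite"))
})

test_that("writer output is deterministic and round-trips", {
  kb <- generate_nosology(fixture_config(n_groups = 5, seed = 3))
  f1 <- withr::local_tempfile(fileext = ".kb")
  f2 <- withr::local_tempfile(fileext = ".kb")
  write_kb(kb, f1)
  write_kb(kb, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(kb_equal(kb, load_kb(f1)))
})

test_that("round-trip equality holds across 50 random generated KBs", {
  f <- withr::local_tempfile(fileext = ".kb")
  for (seed in 1:50) {
    kb <- generate_nosology(fixture_config(
      n_groups = 3, dysplasias_per_group = c(1L, 3L),
      n_genes = 4L, n_mutations = 6L, n_proteins = 2L,
      phenotype_pool_size = 12L, profile_size = c(2L, 4L), seed = seed))
    write_kb(kb, f)
    kb2 <- load_kb(f)
    expect_true(kb_equal(kb, kb2))
    # the validator judges original and round-tripped KB identically
    expect_same_triples(violation_triples(check_tbox(kb)),
                        violation_triples(check_tbox(kb2)))
  }
})

test_that("cycles abort the load; domain problems become warnings", {
  f <- withr::local_tempfile(fileext = ".kb")
  writeLines(c("Ontology:",
               "  dc:title \"cyclic\"",
               "Class: A",
               "  Pillar: dysplasia",
               "  Label: \"A\"",
               "  Parent: B",
               "Class: B",
               "  Pillar: dysplasia",
               "  Label: \"B\"",
               "  Parent: A"), f)
  expect_error(load_kb(f), "cycle")

  writeLines(c("Ontology:",
               "  dc:title \"bad domain\"",
               "Class: G0000001",
               "  Pillar: gene",
               "  Label: \"FGFR3\"",
               "  Parent: Gene",
               "  SubClassOf: characterized_by only HP:HP_0000118"), f)
  kb <- load_kb(f)
  expect_true(any(grepl("domain_mismatch", attr(kb, "load_warnings"))))
  expect_true(kb_has_class <- !is.null(kb$classes[["G0000001"]]))
})

test_that("turtle and rdfxml loaders agree with the canonical loader", {
  kc <- load_kb(system.file("extdata", "genotype_subset.kb",
                            package = "bdokit"), "canonical")
  kt <- load_kb(system.file("extdata", "genotype_subset.ttl",
                            package = "bdokit"), "turtle")
  kx <- load_kb(system.file("extdata", "genotype_subset.owl",
                            package = "bdokit"), "rdfxml")
  expect_true(kb_equal(kc, kt))
  expect_true(kb_equal(kc, kx))
  expect_equal(nrow(check_tbox(kt)), 0L)
  # only/some restriction pairs merge on OWL ingestion
  gm <- kt$classes[["GM0000001"]]
  expect_setequal(vapply(gm$axioms, function(a) a$kind, character(1)),
                  "only_and_some")
  expect_equal(gm$annotations[["encoding"]], "GLY380ARG, 1138 G-A")
  # dublin-core metadata maps across formats
  expect_equal(kx$metadata$title,
               "Bone dysplasia knowledge model: genotype subset")
  expect_equal(kx$metadata$version, "1.5")
})

test_that("external-term table round-trips as TSV", {
  kb <- printed_kb()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_external_terms(kb, f)
  refs <- read_external_terms(f)
  expect_length(refs, length(kb$external))
  byid <- stats::setNames(refs, vapply(refs, `[[`, character(1), "id"))
  expect_equal(byid[["HP:HP_0000238"]]$parent_hint, "HP:HP_0000118")
  expect_equal(byid[["NCI:Missense_Mutation"]]$source, "NCI")
})
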