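test_that("the reference definitions are TBox-clean", {
  v <- check_tbox(printed_kb())
  expect_equal(nrow(v), 0L)
  expect_length(attr(v, "warnings"), 0L)
})

test_that("a protein atom inside characterized_by is a range violation", {
  kb <- printed_kb()
  kb <- add_class(kb, class_def("P0000001x", "protein", parents = "Protein"))
  bad <- parse_class_expression(
    "characterized_by only (GM0000001 or P0000001x)")
  kb <- update_class(kb, "Achondroplasia", axioms = bad)
  v <- check_tbox(kb)
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "range_mismatch")
  expect_equal(v$subject, "Achondroplasia")
  expect_equal(v$relation, "characterized_by")
})

test_that("TBox checking equals the brute-force oracle on 100 dirty KBs", {
  base <- printed_kb()
  set.seed(2024)
  for (rep in 1:100) {
    kb <- random_dirty_kb(base)
    expect_same_triples(violation_triples(check_tbox(kb)), oracle_tbox(kb))
  }
})

test_that("a complete mutation individual satisfies the published axioms", {
  kb <- printed_kb()
  inds <- list(
    individual("m1", "GM0000001",
               links = data.frame(relation = c("has_locus", "mutation_type"),
                                  target = c("g1", "t1"))),
    individual("g1", "G0000001"),
    individual("t1", "NCI:Missense_Mutation"))
  expect_equal(nrow(check_abox(kb, inds)), 0L)
  # removing the locus link breaks exactly the existentials
  inds2 <- inds
  inds2[[1]]$links <- inds[[1]]$links[-1, , drop = FALSE]
  v <- check_abox(kb, inds2)
  expect_true(all(v$kind == "some_unsatisfied"))
  expect_true(all(v$relation == "has_locus"))
  # one existential per has_locus axiom (own class + inherited root)
  expect_equal(nrow(v), 2L)
})

test_that("ABox checking equals the brute-force oracle on 100 random ABoxes", {
  kb <- printed_kb()
  set.seed(555)
  for (rep in 1:100) {
    inds <- random_abox(kb)
    expect_same_triples(violation_triples(check_abox(kb, inds)),
                        oracle_abox(kb, inds))
  }
})

test_that("adding a link never fixes an unrelated existential (metamorphic)", {
  kb <- printed_kb()
  set.seed(31)
  for (rep in 1:20) {
    inds <- random_abox(kb)
    v1 <- check_abox(kb, inds)
    ## add a link on a fresh relation to the first mutation individual
    i <- which(vapply(inds, function(x) grepl("^i_m", x$id), logical(1)))[1]
    inds[[i]]$links <- rbind(inds[[i]]$links,
                             data.frame(relation = "mutation_type",
                                        target = "i_missense",
                                        stringsAsFactors = FALSE))
    v2 <- check_abox(kb, inds)
    before <- violation_triples(v1)
    after <- violation_triples(v2)
    ## some-violations on other relations are unchanged
    keep <- function(df) df[df$kind == "some_unsatisfied" &
                              df$relation != "mutation_type", , drop = FALSE]
    expect_same_triples(keep(after), keep(before))
  }
})

test_that("membership classification is closed-world subset compatibility", {
  kb <- printed_kb()
  inds <- list(individual("p1", "HP:HP_0000238"),
               individual("p2", "GM0000001"))
  patient <- individual(
    "patient", "Bone_Dysplasia",
    links = data.frame(relation = c("characterized_by", "characterized_by"),
                       target = c("p1", "p2")))
  hits <- classify_membership(kb, patient, inds)
  expect_true("Achondroplasia" %in% hits)

  # a patient with no links is compatible with every dysplasia
  blank <- individual("blank", "Bone_Dysplasia")
  expect_equal(classify_membership(kb, blank),
               sort(class_ids(kb, "dysplasia")))

  # a phenotype outside the universal filler excludes the dysplasia
  kb2 <- add_external_ref(kb, external_ref("HP:HP_0009999", "HP",
                                           "Unrelated phenotype",
                                           parent_hint = "HP:HP_0000118"))
  expect_false("Achondroplasia" %in%
                 classify_membership(kb2, c("HP:HP_0009999")))
})

test_that("classification equals a brute-force subset test on fixtures", {
  kb <- generate_nosology(fixture_config(n_groups = 5, seed = 77))
  cases <- generate_cases(kb, 20, dropout = 0.3, n_spurious = 0, seed = 4)
  for (cs in cases[1:10]) {
    got <- classify_membership(kb, cs$phenotypes)
    ds <- class_ids(kb, "dysplasia")
    want <- sort(Filter(function(d) {
      allowed <- unique(unlist(lapply(kb$classes[[d]]$axioms, function(a) {
        if (!inherits(a, "bd_axiom") || a$kind == "disjunct") return(NULL)
        if (a$relation != "characterized_by") return(NULL)
        expression_atoms(a$filler)
      })))
      if (is.null(allowed)) return(TRUE)   # unconstrained
      clo <- oracle_closure(kb)
      all(vapply(cs$phenotypes, function(t)
        t %in% allowed ||
          isTRUE(any(vapply(allowed, function(a)
            isTRUE(oracle_under(clo, t, a)), logical(1)))),
        logical(1)))
    }, ds))
    expect_equal(got, want)
  }
})

test_that("subsumption-aware matching accepts descendants of filler atoms", {
  kb <- printed_kb()
  kb <- add_external_ref(kb, external_ref(
    "HP:HP_0000240", "HP", "More specific hydrocephalus",
    parent_hint = "HP:HP_0000238"))
  expect_true("Achondroplasia" %in%
                classify_membership(kb, "HP:HP_0000240"))
})
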