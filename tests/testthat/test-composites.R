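# Constructors are checked against the published composite instances:
# AC_0000001 "Proximal femur", QC_0000001 "Oval translucency",
# PC_0000004 "Translucency of proximal femur", PC_0000005 "Oval translucency
# of proximal femur".

axioms_of <- function(kb, id)
  sort(vapply(kb$classes[[id]]$axioms, serialize_class_expression,
              character(1)))

strip_composites <- function(kb) {
  for (id in c("AC_0000001", "QC_0000001", "PC_0000004", "PC_0000005"))
    kb$classes[[id]] <- NULL
  kb
}

test_that("constructors regenerate the published composite axioms", {
  ref <- printed_kb()
  kb <- strip_composites(ref)

  kb <- make_anatomical_composite(kb, parts = "FMA:Femur",
                                  coordinates = "FMA:Proximal",
                                  label = "Proximal femur")
  expect_equal(attr(kb, "last_id"), "AC_0000001")
  expect_equal(axioms_of(kb, "AC_0000001"), axioms_of(ref, "AC_0000001"))

  kb <- make_quality_composite(kb, qualities = "PATO:PATO_0001354",
                               qualifiers = "PATO:PATO_0000947",
                               label = "Oval translucency")
  expect_equal(attr(kb, "last_id"), "QC_0000001")
  expect_equal(axioms_of(kb, "QC_0000001"), axioms_of(ref, "QC_0000001"))

  kb <- make_phenotypic_composite(kb, target = "AC_0000001",
                                  quality = "PATO:PATO_0001354",
                                  label = "Translucency of proximal femur",
                                  id = "PC_0000004")
  expect_equal(axioms_of(kb, "PC_0000004"), axioms_of(ref, "PC_0000004"))

  kb <- make_phenotypic_composite(kb, target = "AC_0000001",
                                  quality = "QC_0000001",
                                  label = "Oval translucency of proximal femur",
                                  id = "PC_0000005")
  expect_equal(axioms_of(kb, "PC_0000005"), axioms_of(ref, "PC_0000005"))
  expect_equal(nrow(check_tbox(kb)), 0L)
})

test_that("composites without coordinates/qualifiers stay minimal", {
  kb <- strip_composites(printed_kb())
  kb <- make_anatomical_composite(kb, parts = "FMA:Femur", label = "Femur part")
  ac <- kb$classes[[attr(kb, "last_id")]]
  expect_length(ac$axioms, 1L)
  expect_equal(ac$axioms[[1]]$relation, "has_part")
  kb <- make_quality_composite(kb, qualities = "PATO:PATO_0001354",
                               label = "Bare translucency")
  qc <- kb$classes[[attr(kb, "last_id")]]
  expect_length(qc$axioms, 1L)
})

test_that("constructor preconditions hold", {
  kb <- printed_kb()
  expect_error(make_anatomical_composite(kb, parts = character(0),
                                         label = "x"), "at least one part")
  expect_error(make_anatomical_composite(kb, parts = "FMA:NoSuchPart",
                                         label = "x"), "unresolvable")
  expect_error(make_quality_composite(kb, qualities = character(0),
                                      label = "x"), "at least one quality")
  expect_error(make_phenotypic_composite(kb, target = "HP:HP_0000238",
                                         quality = "PATO:PATO_0001354",
                                         label = "x"),
               "target must be")
  expect_error(make_phenotypic_composite(kb, target = "AC_0000001",
                                         quality = "HP:HP_0000238",
                                         label = "x"),
               "quality must be")
})

test_that("random composites are validator-clean, nesting included", {
  set.seed(9)
  kb <- printed_kb()
  for (i in 1:10) {
    kb <- make_anatomical_composite(kb, parts = "FMA:Femur",
                                    coordinates = "FMA:Proximal",
                                    label = sprintf("AC gen %d", i))
    ac <- attr(kb, "last_id")
    kb <- make_phenotypic_composite(kb, target = ac,
                                    quality = "PATO:PATO_0001354",
                                    label = sprintf("PC gen %d", i))
  }
  pcs <- grep("^PC_", names(kb$classes), value = TRUE)
  kb <- make_phenotypic_composite(kb, target = sample(pcs, 2),
                                  quality = "QC_0000001",
                                  label = "nested composite")
  nested <- kb$classes[[attr(kb, "last_id")]]
  expect_equal(nested$axioms[[1]]$relation, "has_part")
  expect_equal(nrow(check_tbox(kb)), 0L)
})

mk_lexicon <- function() {
  data.frame(
    surface_form = c("mitral valve", "prolapse", "prolapsed", "femur",
                     "translucent", "translucency", "oval", "mildly"),
    term_id = c("FMA:Mitral_valve", "PATO:PATO_0100001",
                "PATO:PATO_0100001", "FMA:Femur", "PATO:PATO_0001354",
                "PATO:PATO_0001354", "PATO:PATO_0000947",
                "PATO:PATO_0100002"),
    kind = c("entity", "quality", "quality", "entity", "quality", "quality",
             "qualifier", "qualifier"),
    stringsAsFactors = FALSE)
}

test_that("entity-quality decomposition recovers the worked example", {
  out <- decompose_term("Mitral valve prolapse", mk_lexicon())
  expect_equal(nrow(out), 1L)
  expect_equal(out$entity, "FMA:Mitral_valve")
  expect_equal(out$quality, "PATO:PATO_0100001")
  expect_length(attr(out, "unmatched"), 0L)
})

test_that("decomposition is stable under whitespace/case normalization", {
  a <- decompose_term("  MITRAL   Valve   PROLAPSED ", mk_lexicon())
  b <- decompose_term("mitral valve prolapsed", mk_lexicon())
  expect_equal(a, b)
})

test_that("unmatched labels give empty candidates; leftovers are reported", {
  out <- decompose_term("entirely unknown words", mk_lexicon())
  expect_equal(nrow(out), 0L)
  expect_true(length(attr(out, "unmatched")) >= 2L)
  out2 <- decompose_term("oval translucent femur thing", mk_lexicon())
  expect_equal(out2$entity, "FMA:Femur")
  expect_equal(out2$quality, "PATO:PATO_0001354")
  expect_equal(out2$qualifier, "PATO:PATO_0000947")
  expect_equal(attr(out2, "unmatched"), "thing")
})

test_that("decompose-then-compose reproduces a label-compatible composite", {
  lex <- mk_lexicon()
  kb <- printed_kb()
  labels <- c("translucent femur", "oval translucent femur")
  for (lab in labels) {
    cand <- decompose_term(lab, lex)
    expect_gte(nrow(cand), 1L)
    kb2 <- make_phenotypic_composite(kb, target = "FMA:Femur",
                                     quality = cand$quality[1])
    pc <- kb2$classes[[attr(kb2, "last_id")]]
    # every token of the synthesized label appears in the source label's
    # lexicon closure (quality-of-target convention)
    expect_match(pc$label, "of", fixed = TRUE)
    expect_equal(nrow(check_tbox(kb2)), 0L)
  }
})
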