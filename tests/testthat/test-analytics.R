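test_that("phenotype profiles keep phenotype atoms and drop mutations", {
  kb <- printed_kb()
  prof <- phenotype_profile(kb, "Achondroplasia")
  expect_true(all(c("HP:HP_0000238", "HP:HP_0002938", "HP:HP_0002968",
                    "HP:HP_0003505") %in% prof))
  expect_false(any(c("GM0000001", "GM0000361") %in% prof))
  # no characterized_by axiom means an empty profile
  kb <- add_class(kb, class_def("BareDysplasia", "dysplasia",
                                parents = "Bone_Dysplasia"))
  expect_length(phenotype_profile(kb, "BareDysplasia"), 0L)
  expect_error(phenotype_profile(kb, "NotAClass"), "unknown class")
})

test_that("profiles equal a brute-force filler scan on generated KBs", {
  kb <- generate_nosology(fixture_config(n_groups = 4, seed = 21))
  clo <- oracle_closure(kb)
  for (d in sample(leaf_dysplasias(kb), 8)) {
    atoms <- unique(unlist(lapply(kb$classes[[d]]$axioms, function(a) {
      if (a$kind == "disjunct" || a$relation != "characterized_by")
        return(NULL)
      expression_atoms(a$filler)
    })))
    want <- sort(Filter(function(a) {
      ref <- kb$external[[a]]
      (!is.null(ref) && ref$source %in% c("HP", "REAMS")) ||
        (!is.null(kb$classes[[a]]) &&
           kb$classes[[a]]$pillar == "phenotypic_composite")
    }, atoms %||% character(0)))
    expect_equal(phenotype_profile(kb, d), want)
  }
})

test_that("overlap is symmetric, self-overlap is the profile size", {
  kb <- generate_nosology(fixture_config(n_groups = 4, seed = 33))
  ds <- leaf_dysplasias(kb)
  for (i in 1:5) {
    d1 <- sample(ds, 1); d2 <- sample(ds, 1)
    expect_equal(profile_overlap(kb, d1, d2), profile_overlap(kb, d2, d1))
    expect_equal(profile_overlap(kb, d1, d1),
                 length(phenotype_profile(kb, d1)))
    expect_equal(profile_overlap(kb, d1, d2),
                 length(intersect(phenotype_profile(kb, d1),
                                  phenotype_profile(kb, d2))))
  }
})

test_that("overlap distribution is consistent with pairwise overlaps", {
  kb <- generate_nosology(fixture_config(n_groups = 6, seed = 8))
  focus <- leaf_dysplasias(kb)[1]
  dist <- overlap_distribution(kb, focus)
  expect_true(all(dist$overlap > 0))
  expect_false(focus %in% dist$dysplasia)
  for (i in seq_len(min(5, nrow(dist))))
    expect_equal(dist$overlap[i],
                 profile_overlap(kb, focus, dist$dysplasia[i]))
  # sorted by decreasing overlap, ties by id
  expect_true(all(diff(dist$overlap) <= 0))
  # a focus with an empty profile has an empty distribution
  kb <- add_class(kb, class_def("EmptyD", "dysplasia",
                                parents = "Bone_Dysplasia"))
  expect_equal(nrow(overlap_distribution(kb, "EmptyD")), 0L)
})

test_that("an exact profile match ranks first with score 1", {
  kb <- printed_kb()
  prof <- phenotype_profile(kb, "Achondroplasia")
  rk <- rank_disorders(kb, prof)
  expect_equal(rk$dysplasia[1], "Achondroplasia")
  expect_lt(abs(rk$score[1] - length(prof) /
                  length(union(prof, phenotype_profile(kb, "Achondroplasia")))),
            1e-12)
  # input order is irrelevant (set semantics)
  rk2 <- rank_disorders(kb, rev(prof))
  expect_equal(rk, rk2)
  expect_error(rank_disorders(kb, character(0)), "non-empty")
})

test_that("Jaccard scores equal exhaustive recomputation", {
  kb <- generate_nosology(fixture_config(n_groups = 5, seed = 13))
  cases <- generate_cases(kb, 5, seed = 2)
  for (cs in cases) {
    rk <- rank_disorders(kb, cs$phenotypes)
    expect_true(all(rk$score > 0 & rk$score <= 1))
    for (i in seq_len(min(3, nrow(rk)))) {
      prof <- phenotype_profile(kb, rk$dysplasia[i])
      expect_equal(rk$score[i],
                   length(intersect(cs$phenotypes, prof)) /
                     length(union(cs$phenotypes, prof)))
    }
    # deterministic tie-break: score desc then id
    expect_equal(order(-rk$score, rk$dysplasia), seq_len(nrow(rk)))
  }
})

test_that("the hand-countable cohort yields the expected rule", {
  cases <- toy_cohort()   # 8 of 10 cases: {p1,p2,...} diagnosed X
  rules <- mine_rules(cases, min_support = 0.5, min_confidence = 0.7,
                      max_antecedent = 2)
  key <- vapply(seq_len(nrow(rules)), function(i)
    paste(paste(rules$antecedent[[i]], collapse = ","),
          rules$consequent[i], sep = "->"), character(1))
  i <- match("p1,p2->X", key)
  expect_false(is.na(i))
  expect_equal(rules$support[i], 0.8)
  expect_equal(rules$confidence[i], 1)      # p1+p2 occur together only in X
  j <- match("p1->X", key)
  expect_equal(rules$support[j], 0.8)
  expect_equal(rules$confidence[j], 8 / 9)  # p1 occurs in 9 cases
  # an impossible support threshold gives an empty rule set
  expect_equal(nrow(mine_rules(cases, 1.0, 0.1)), 0L)
  expect_error(mine_rules(list(patient_case("u", "p1")), 0.1, 0.1),
               "no diagnosed")
})

test_that("the miner is Apriori-complete against exhaustive enumeration", {
  set.seed(88)
  phen <- paste0("p", 1:6)
  for (rep in 1:15) {
    n <- sample(5:15, 1)
    cases <- lapply(seq_len(n), function(i)
      patient_case(paste0("c", i),
                   phenotypes = sample(phen, sample(1:4, 1)),
                   diagnosis = sample(c("X", "Y", "Z", NA), 1)))
    if (all(vapply(cases, function(x) is.na(x$diagnosis), logical(1))))
      next
    ms <- sample(c(0.1, 0.2, 0.3), 1)
    mc <- sample(c(0.5, 0.7, 0.9), 1)
    got <- mine_rules(cases, ms, mc, max_antecedent = 3)
    want <- oracle_rules(cases, ms, mc, max_antecedent = 3)
    expect_equal(rules_key(got), rules_key_list(want))
  }
})

test_that("axiom refinement keeps compatible rules and drops the rest", {
  kb <- printed_kb()
  rules <- data.frame(consequent = c("Achondroplasia", "Achondroplasia"),
                      support = c(0.5, 0.5), confidence = c(0.9, 0.9),
                      stringsAsFactors = FALSE)
  rules$antecedent <- list(c("HP:HP_0000238", "HP:HP_0002938"),
                           c("HP:HP_0000238", "HP:HP_0009999x"))
  kb <- add_external_ref(kb, external_ref("HP:HP_0009999x", "HP",
                                          "Off-profile phenotype",
                                          parent_hint = "HP:HP_0000118"))
  out <- refine_rules(kb, rules)
  expect_equal(nrow(out), 1L)
  expect_equal(out$antecedent[[1]], c("HP:HP_0000238", "HP:HP_0002938"))
  # never grows, idempotent
  expect_equal(refine_rules(kb, out), out)
})

test_that("refinement equals the subset-filter oracle on generated cohorts", {
  kb <- generate_nosology(fixture_config(n_groups = 4, seed = 6))
  cases <- generate_cases(kb, 30, dropout = 0.1, n_spurious = 1, seed = 9)
  rules <- mine_rules(cases, min_support = 0.02, min_confidence = 0.5)
  out <- refine_rules(kb, rules)
  clo <- oracle_closure(kb)
  keep <- vapply(seq_len(nrow(rules)), function(i) {
    d <- rules$consequent[i]
    allowed <- unique(unlist(lapply(kb$classes[[d]]$axioms, function(a) {
      if (a$kind == "disjunct" || a$relation != "characterized_by")
        return(NULL)
      expression_atoms(a$filler)
    })))
    if (is.null(allowed)) return(TRUE)
    all(vapply(rules$antecedent[[i]], function(t)
      t %in% allowed || any(vapply(allowed, function(a)
        isTRUE(oracle_under(clo, t, a)), logical(1))), logical(1)))
  }, logical(1))
  expect_equal(rules_key(out), rules_key(rules[keep, , drop = FALSE]))
})

test_that("confidence-weighted rule voting is exposed as a second scorer", {
  kb <- generate_nosology(fixture_config(n_groups = 4, seed = 26))
  cases <- generate_cases(kb, 40, dropout = 0.1, n_spurious = 0, seed = 3)
  rules <- refine_rules(kb, mine_rules(cases, 0.02, 0.5))
  cs <- cases[[1]]
  rk <- rank_disorders(kb, cs$phenotypes, method = "rules", rules = rules)
  if (nrow(rk)) {
    expect_true(all(rk$score > 0 & rk$score <= 1))
    expect_lt(abs(sum(rk$score) - 1), 1e-9)
  }
  expect_error(rank_disorders(kb, cs$phenotypes, method = "rules"),
               "needs a rules")
})

mk_text_lexicon <- function() {
  data.frame(
    surface_form = c("achondroplasia", "hydrocephalus",
                     "lumbar hyperlordosis", "macrocephaly"),
    term_id = c("Achondroplasia", "HP:HP_0000238", "HP:HP_0002938",
                "HP:HP_0000256"),
    kind = c("dysplasia", "phenotype", "phenotype", "phenotype"),
    stringsAsFactors = FALSE)
}

test_that("clinical text annotation finds hand-marked spans", {
  txt <- "Suspected achondroplasia with hydrocephalus and lumbar hyperlordosis."
  out <- annotate_text(txt, mk_text_lexicon())
  expect_equal(out$term_id,
               c("Achondroplasia", "HP:HP_0000238", "HP:HP_0002938"))
  norm <- attr(out, "text")
  for (i in seq_len(nrow(out)))
    expect_equal(tolower(substr(norm, out$start[i] + 1, out$end[i])),
                 out$surface[i])
  expect_equal(nrow(annotate_text("", mk_text_lexicon())), 0L)
})

test_that("annotation is longest-match, non-overlapping, boundary-aware", {
  lex <- data.frame(surface_form = c("lumbar", "lumbar hyperlordosis"),
                    term_id = c("T:short", "T:long"),
                    kind = "phenotype", stringsAsFactors = FALSE)
  out <- annotate_text("lumbar hyperlordosis", lex)
  expect_equal(out$term_id, "T:long")
  # no match inside a longer word
  out2 <- annotate_text("haslumbarword", lex)
  expect_equal(nrow(out2), 0L)
})

test_that("concatenating all surface forms recovers every term once", {
  lex <- mk_text_lexicon()
  txt <- paste(lex$surface_form, collapse = "; ")
  out <- annotate_text(txt, lex)
  expect_equal(sort(out$term_id), sort(lex$term_id))
  expect_equal(nrow(out), nrow(lex))
})
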