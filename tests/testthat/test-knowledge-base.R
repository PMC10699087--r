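test_that("loading assembles reactions, gates, inputs and outputs from the tables", {
  kb <- make_kb(
    c("K_P+_S_[(r1)]", "P_P-_S_[(r1)]"),
    cont_df(c("K_P+_S_[(r1)]", "<G>", "<G>", "[Out]"),
            c("!", "OR", "OR", "!"),
            c("<G>", "[I1]", "S_[(r1)]-{P}", "S_[(r1)]-{P}")))
  expect_s3_class(kb, "rxn_kb")
  expect_length(kb$reactions, 2L)
  expect_identical(kb$gates$G$op, "OR")
  expect_identical(kb$gates$G$members, c("[I1]", "S_[(r1)]-{P}"))
  expect_identical(kb$inputs, "I1")
  expect_identical(kb$outputs, "Out")
  expect_true(kb_accepted(validate_knowledge_base(kb)))
})

test_that("an empty contingency table yields an unconstrained knowledge base", {
  kb <- make_kb("K_P+_S_[(r1)]")
  expect_length(kb$reactions, 1L)
  expect_identical(nrow(kb$contingencies), 0L)
  expect_length(kb$inputs, 0L)
})

test_that("leading '!' header names and the printed table dialect are accepted", {
  dir <- withr::local_tempdir()
  writeLines(c("!UID\t!Reaction\t!Reference", "1\tK_P+_S_[(r1)]\tnote"),
             file.path(dir, "ReactionList.tsv"))
  writeLines(c("!UID\t!Target\t!Contingency\t!Modifier",
               "175\tK_P+_S_[(r1)]\tx\t[miniX]"),
             file.path(dir, "ContingencyList.tsv"))
  kb <- load_knowledge_base(dir)
  expect_identical(kb$contingencies$uid, 175L)
  expect_identical(kb$contingencies$kind, "x")
  expect_identical(kb$contingencies$modifier, "[miniX]")
  expect_identical(kb$rxn_meta$reference, "note")
})

test_that("structural errors are rejected at load or reported by the validator", {
  expect_error(
    make_kb(c("K_P+_S_[(r1)]", "K_P+_S_[(r1)]")), "duplicate reaction")
  expect_error(
    make_kb("K_P+_S_[(r1)]",
            cont_df(c("K_P+_S_[(r1)]", "K_P+_S_[(r1)]"), c("!", "x"),
                    c("[I]", "[J]"))[c(1, 1), ]), "UID")
  expect_error(
    make_kb("K_P+_S_[(r1)]",
            cont_df("K_P+_S_[(r1)]", "AND", "[I]")), "gate target")

  # dangling target: reported, not thrown
  kb <- make_kb("K_P+_S_[(r1)]", cont_df("K_P+_X_[(r9)]", "!", "[I]"))
  rep <- validate_knowledge_base(kb)
  expect_false(kb_accepted(rep))
  expect_identical(rep$issues$code[rep$issues$severity == "error"],
                   "dangling-target")

  # gate cycle: <A> contains <B> contains <A>
  kb <- make_kb("K_P+_S_[(r1)]",
                cont_df(c("<A>", "<A>", "<B>", "<B>", "K_P+_S_[(r1)]"),
                        c("OR", "OR", "OR", "OR", "!"),
                        c("<B>", "[I]", "<A>", "[I]", "<A>")))
  rep <- validate_knowledge_base(kb)
  expect_true("gate-cycle" %in% rep$issues$code)
  expect_false(kb_accepted(rep))
})

test_that("warnings flag unproducible states and unused components", {
  kb <- make_kb("K_P+_S_[(r1)]",
                cont_df("K_P+_S_[(r1)]", "!", "S_[(r1)]-{ub48}"))
  rep <- validate_knowledge_base(kb)
  expect_true(kb_accepted(rep))
  expect_true("nonproducible-state" %in% rep$issues$code)

  kb2 <- make_kb("K_P+_S_[(r1)]", cont_df("K_P+_S_[(r1)]", "!", "Z_[(q)]-{P}"))
  rep2 <- validate_knowledge_base(kb2)
  expect_true("unused-component" %in% rep2$issues$code)
})

test_that("a generated knowledge base round-trips write -> load structurally", {
  kb <- random_network(synth_config(n_components = 4, n_reactions = 8,
                                    seed = 11))
  dir <- withr::local_tempdir()
  write_knowledge_base(kb, dir)
  kb2 <- load_knowledge_base(dir)
  expect_true(boolkit:::kb_equal(kb, kb2))
  # and the reloaded copy compiles to the same node set
  expect_identical(enumerate_nodes(kb), enumerate_nodes(kb2))
})

test_that("contingency kind '0' is retained but compiles to nothing", {
  kb <- make_kb(c("K_P+_S_[(r1)]", "P_P-_S_[(r1)]"),
                cont_df(c("K_P+_S_[(r1)]", "[Out]"), c("0", "!"),
                        c("S_[(r1)]-{P}", "S_[(r1)]-{P}")))
  expect_identical(sum(kb$contingencies$kind == "0"), 1L)
  model <- build_update_rules(kb)
  expect_identical(format_expression(model$rules[["K_P+_S_[(r1)]"]]),
                   "AND(K, S)")
})
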