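test_that("node enumeration covers reactions, states with neutral partners, components", {
  kb <- make_kb("AKT_P+_NLRP3_[(S5)]")
  nodes <- enumerate_nodes(kb)
  expect_setequal(nodes$key[nodes$kind == "reaction"], "AKT_P+_NLRP3_[(S5)]")
  expect_setequal(nodes$key[nodes$kind == "state"],
                  c("NLRP3_[(S5)]-{0}", "NLRP3_[(S5)]-{P}"))
  expect_setequal(nodes$key[nodes$kind == "component"], c("AKT", "NLRP3"))
  expect_identical(sum(nodes$kind %in% c("input", "output")), 0L)
})

test_that("node counts on random networks match the component tally", {
  for (seed in 1:20) {
    kb <- random_network(synth_config(n_components = 3, n_reactions = 6,
                                      seed = seed))
    nodes <- enumerate_nodes(kb)
    state_keys <- unique(unlist(lapply(
      c(unlist(lapply(kb$reactions, `[[`, "consumed")),
        unlist(lapply(kb$reactions, `[[`, "produced")),
        boolkit:::kb_modifier_state_keys(kb)),
      function(k) vapply(c(list(parse_state(k)),
                           neutral_partners(parse_state(k))),
                         render_state, character(1)))))
    expect_identical(nrow(nodes),
                     length(kb$reactions) + length(state_keys) +
                       length(kb$components) + length(kb$inputs) +
                       length(kb$outputs))
    expect_false(anyDuplicated(nodes$key) > 0L)
  }
})

test_that("gate inlining substitutes definitions recursively", {
  kb <- nlrp3_cached()$kb
  inh <- inline_gates(kb, "<AKTinhib>")
  expect_identical(format_expression(inh), "OR([MK2206], [AKTK179M])")
  act <- inline_gates(kb, "<AKTactive>")
  expect_identical(
    format_expression(act),
    "AND(AKT_[PH]--PI_[head], OR([SC79], AND(AKT_[(T308)]-{P}, AKT_[(S473)]-{P})))")
})

test_that("inlining a single-member NOT gate reduces to NOT of the literal", {
  kb <- make_kb("K_P+_S_[(r1)]",
                cont_df(c("<X>", "K_P+_S_[(r1)]"), c("NOT", "x"),
                        c("S_[(r1)]-{P}", "<X>")))
  model <- build_update_rules(kb)
  rule <- format_expression(model$rules[["K_P+_S_[(r1)]"]])
  expect_identical(rule, "AND(K, S, NOT(NOT(S_[(r1)]-{P})))")
})

test_that("gate inlining is semantics-preserving on exhaustive member assignments", {
  kb <- nlrp3_cached()$kb
  for (gate in c("AKTactive", "Kefflux", "CentrosomalNLRP3", "Signal1")) {
    inlined <- inline_gates(kb, sprintf("<%s>", gate))
    lits <- boolkit:::expr_literals(inlined)
    expect_lte(length(lits), 10L)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(lits)))
    for (i in seq_len(nrow(grid))) {
      vals <- stats::setNames(as.logical(grid[i, ]), lits)
      direct <- boolkit:::interp_modifier(kb, sprintf("<%s>", gate),
                                          as.list(vals))
      expect_identical(eval_expression(inlined, vals), direct)
    }
  }
})

test_that("unconstrained reactions compile to component-presence rules", {
  kb <- make_kb("K_P+_S_[(r1)]")
  model <- build_update_rules(kb)
  expect_identical(format_expression(model$rules[["K_P+_S_[(r1)]"]]),
                   "AND(K, S)")
  # production dominates consumption in the state rules
  expect_identical(
    format_expression(model$rules[["S_[(r1)]-{P}"]]),
    "AND(S, OR(K_P+_S_[(r1)], S_[(r1)]-{P}))")
  expect_identical(
    format_expression(model$rules[["S_[(r1)]-{0}"]]),
    "AND(S, S_[(r1)]-{0}, NOT(K_P+_S_[(r1)]))")
  expect_identical(format_expression(model$rules[["K"]]), "TRUE")
})

test_that("fixture rules wire contingencies, synthesis producers and outputs", {
  cc <- nlrp3_cached()
  jnk <- format_expression(cc$model$rules[["JNK1_P+_NLRP3_[(S198)]"]])
  expect_match(jnk, "^AND\\(JNK1, NLRP3, OR\\(\\[LPS\\]", fixed = FALSE)
  # translation is a producer of the neutral Ser5 state
  s50 <- format_expression(cc$model$rules[["NLRP3_[(S5)]-{0}"]])
  expect_match(s50, "Ribo_trsl_NLRP3", fixed = TRUE)
  expect_match(s50, "PP2Aca_P-_NLRP3_[(S5)]", fixed = TRUE)
  # gates are fully inlined: no gate literal survives anywhere
  for (rule in cc$model$rules) {
    expect_false(any(grepl("^<", boolkit:::expr_literals(rule))))
  }
})

test_that("the model is bipartite: reactions never read reactions, states never read states", {
  cc <- nlrp3_cached()
  nodes <- cc$model$nodes
  kind_of <- stats::setNames(nodes$kind, nodes$key)
  for (i in seq_len(nrow(nodes))) {
    lits <- boolkit:::expr_literals(cc$model$rules[[i]])
    kinds <- unname(kind_of[lits])
    if (nodes$kind[i] == "reaction") {
      expect_false("reaction" %in% kinds)
    } else if (nodes$kind[i] == "state") {
      others <- lits[lits != nodes$key[i]]
      expect_true(all(kind_of[others] %in% c("reaction", "component")))
    }
  }
})

test_that("monotone production: an active producer forces its product on", {
  for (seed in 1:10) {
    kb <- random_network(synth_config(n_components = 3, n_reactions = 5,
                                      seed = seed))
    model <- build_update_rules(kb)
    set.seed(seed)
    asg <- stats::setNames(sample(c(TRUE, FALSE), nrow(model$nodes), TRUE),
                           model$nodes$key)
    for (r in kb$reactions) {
      asg2 <- asg
      asg2[r$text] <- TRUE
      asg2[unique(unlist(lapply(kb$reactions, `[[`, "components")))] <- TRUE
      nxt <- sim_step(model, asg2)
      for (p in r$produced) expect_true(nxt[[p]])
    }
  }
})

test_that("contingencies on never-produced non-neutral states abort compilation", {
  kb <- make_kb("K_P+_S_[(r1)]",
                cont_df("K_P+_S_[(r1)]", "x", "S_[(r1)]-{ub63}"))
  expect_error(build_update_rules(kb), "no producing reaction")
})

test_that("neutral/modified duality holds along fixture trajectories", {
  cc <- nlrp3_cached()
  res <- run_cached("S-LPS+Nig")
  traj <- res$trajectory
  mods <- cc$model$nodes$key[cc$model$nodes$kind == "state"]
  mods <- mods[grepl("-\\{", mods)]
  res_of <- sub("-\\{[^}]+\\}$", "", mods)
  comp_of <- sub("_.*$", "", mods)
  for (res_key in unique(res_of)) {
    members <- mods[res_of == res_key]
    comp <- comp_of[res_of == res_key][1]
    for (t in 2:ncol(traj)) {
      if (traj[comp, t] && traj[comp, t - 1L]) {
        expect_true(any(traj[members, t]))
      }
    }
  }
})
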