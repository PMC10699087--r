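test_that("the fixture's regulatory graph carries the expected causal edges", {
  kb <- nlrp3_cached()$kb
  g <- build_regulatory_graph(kb)
  el <- igraph::as_edgelist(g)
  cat_e <- igraph::edge_attr(g, "category")

  has_edge <- function(from, to, category) {
    any(el[, 1] == from & el[, 2] == to & cat_e == category)
  }
  expect_true(has_edge("NLRP3_[(S198)]-{P}",
                       "BRCC36_[bd]_ppi+_NLRP3_[nb36]", "required"))
  expect_true(has_edge("BRCC36_[G5]--G5_[dub]",
                       "BRCC36_ub63-_NLRP3_[(lrr)]", "inhibitory"))
  expect_true(has_edge("AKT_P+_NLRP3_[(S5)]", "NLRP3_[(S5)]-{P}",
                       "production"))
  expect_true(has_edge("PP2Aca_P-_NLRP3_[(S5)]", "NLRP3_[(S5)]-{P}",
                       "consumption"))
  expect_true(has_edge("Ribo_trsl_NLRP3", "NLRP3", "synthesis-degradation"))
  expect_true(has_edge("[LPS]", "<Signal1>", "membership"))

  cats <- igraph::vertex_attr(g, "category")
  expect_setequal(unique(cats[startsWith(igraph::V(g)$name, "<")]),
                  c("boolean-AND", "boolean-OR", "boolean-NOT"))
})

test_that("neutral states are excluded from the regulatory graph", {
  kb <- nlrp3_cached()$kb
  g <- build_regulatory_graph(kb)
  nm <- igraph::V(g)$name
  # neutral-state nodes appear only when a contingency references them
  neutral <- nm[endsWith(nm, "--0")]
  expect_length(neutral, 0L)
  produced_neutrals <- nm[endsWith(nm, "-{0}") &
                            igraph::vertex_attr(g, "category") == "state"]
  # Ser806/Tyr861/Ser295/Ser5/lrr-{0} appear as required modifiers; none
  # may appear as a production or consumption endpoint
  el <- igraph::as_edgelist(g)
  cat_e <- igraph::edge_attr(g, "category")
  eff <- cat_e %in% c("production", "consumption")
  expect_false(any(el[eff, 2] %in% produced_neutrals))
})

test_that("required+inhibitory edge count equals the strict contingency rows", {
  for (kb in list(nlrp3_cached()$kb,
                  random_network(synth_config(seed = 5)))) {
    g <- build_regulatory_graph(kb)
    cat_e <- igraph::edge_attr(g, "category")
    rows <- kb$contingencies
    n_strict <- sum(rows$kind %in% c("!", "x"))
    expect_identical(sum(cat_e %in% c("required", "inhibitory")), n_strict)
  }
})

test_that("a KB with one unconstrained reaction has no contingency edges", {
  g <- build_regulatory_graph(make_kb("K_P+_S_[(r1)]"))
  cat_e <- igraph::edge_attr(g, "category")
  expect_false(any(cat_e %in% c("required", "inhibitory", "membership")))
  expect_identical(sum(cat_e == "production"), 1L)
})

test_that("graph files are parseable, deterministic and format-checked", {
  kb <- random_network(synth_config(seed = 3))
  g <- build_regulatory_graph(kb)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  write_regulatory_graph(g, f1, "graphml")
  write_regulatory_graph(g, f2, "graphml")
  expect_identical(readLines(f1), readLines(f2))
  back <- igraph::read_graph(f1, format = "graphml")
  expect_identical(igraph::vcount(back), igraph::vcount(g))
  expect_identical(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::vertex_attr(back, "category"),
                  igraph::vertex_attr(g, "category"))

  fd <- withr::local_tempfile(fileext = ".dot")
  write_regulatory_graph(g, fd, "dot")
  lines <- readLines(fd)
  expect_match(lines[1], "^digraph")
  expect_identical(sum(grepl("->", lines, fixed = TRUE)),
                   as.integer(igraph::ecount(g)))
  expect_error(write_regulatory_graph(g, fd, "gexf"), "arg")
})

test_that("an empty knowledge base yields an empty graph file", {
  kb <- make_kb(character(0))
  g <- build_regulatory_graph(kb)
  expect_identical(as.integer(igraph::vcount(g)), 0L)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_regulatory_graph(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_identical(as.integer(igraph::vcount(back)), 0L)
})
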