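#' Build the regulatory graph of a knowledge base
#'
#' The regulatory graph shows the causal information flow: reactions
#' produce and consume elemental states (and synthesise or degrade
#' components), and states, inputs and Boolean gates regulate reactions
#' and outputs through required (`!`) or inhibitory (`x`) edges. Neutral
#' (unmodified, unbound) states are excluded from the visualisation.
#'
#' Node categories: `reaction`, `state`, `component`, `boolean-AND`,
#' `boolean-OR`, `boolean-NOT`, `input-output`. Edge categories:
#' `production`, `consumption`, `synthesis-degradation`, `required`,
#' `inhibitory`, `membership` (gate members to their gate).
#'
#' @param kb A validated `rxn_kb` object.
#' @return An [igraph::igraph] with vertex/edge attribute `category`.
#' @export
build_regulatory_graph <- function(kb) {
  stopifnot(inherits(kb, "rxn_kb"))
  modifiers <- registry_modifiers(kb$registry)
  nodes <- list()     # key -> category
  edges <- list()     # list of c(from, to, category)
  add_node <- function(key, category) {
    if (is.null(nodes[[key]])) nodes[[key]] <<- category
  }
  add_edge <- function(from, to, category) {
    edges[[length(edges) + 1L]] <<- c(from, to, category)
  }
  # non-neutral sibling states per locus, for rendering neutral
  # modifiers as NOT constructs (neutral states are excluded from the
  # graph; "unmodified/unbound" reads as NOT of the perturbed states)
  sibling_states <- function(s) {
    same_locus <- function(t) {
      if (inherits(s, "modification_state") &&
          inherits(t, "modification_state")) {
        identical(t$component, s$component) &&
          identical(t$residue$name, s$residue$name) && !is_neutral_state(t)
      } else if (inherits(s, "free_state") && inherits(t, "bond_state")) {
        ep <- sprintf("%s_[%s]", s$component, s$domain$name)
        keyA <- sprintf("%s_[%s]", t$endpointA$component,
                        t$endpointA$domain$name)
        keyB <- sprintf("%s_[%s]", t$endpointB$component,
                        t$endpointB$domain$name)
        ep %in% c(keyA, keyB)
      } else {
        FALSE
      }
    }
    all_states <- unlist(lapply(kb$reactions, function(r) {
      c(r$consumed_states, r$produced_states)
    }), recursive = FALSE)
    keys <- unique(vapply(Filter(same_locus, all_states), render_state,
                          character(1)))
    sort(keys)
  }

  node_of_modifier <- function(m) {
    # returns the graph key for a modifier, adding its node if needed
    if (grepl("^<.+>$", m)) {
      nm <- sub("^<(.+)>$", "\\1", m)
      g <- kb$gates[[nm]]
      key <- sprintf("<%s>", nm)
      if (is.null(nodes[[key]])) {
        add_node(key, paste0("boolean-", g$op))
        for (mem in g$members) {
          add_edge(node_of_modifier(mem), key, "membership")
        }
      }
      key
    } else if (grepl("^\\[.+\\]$", m)) {
      add_node(m, "input-output")
      m
    } else {
      s <- parse_state(m, modifiers)
      key <- render_state(s)
      if (is_neutral_state(s)) {
        if (is.null(nodes[[key]])) {
          add_node(key, "boolean-NOT")
          for (sib in sibling_states(s)) {
            add_node(sib, "state")
            add_edge(sib, key, "membership")
          }
        }
        key
      } else {
        add_node(key, "state")
        key
      }
    }
  }

  for (r in kb$reactions) {
    add_node(r$text, "reaction")
    for (s in r$produced_states) {
      if (!is_neutral_state(s)) {
        key <- render_state(s); add_node(key, "state")
        add_edge(r$text, key, "production")
      }
    }
    for (s in r$consumed_states) {
      if (!is_neutral_state(s)) {
        key <- render_state(s); add_node(key, "state")
        add_edge(r$text, key, "consumption")
      }
    }
    for (comp in c(r$synthesises, r$degrades)) {
      if (!is.na(comp)) {
        add_node(comp, "component")
        add_edge(r$text, comp, "synthesis-degradation")
      }
    }
  }

  rows <- kb_constraints(kb)
  for (i in seq_len(nrow(rows))) {
    if (!rows$kind[i] %in% c("!", "x")) next
    target <- rows$target[i]
    if (grepl("^\\[.+\\]$", target)) {
      add_node(target, "input-output")
    } else {
      add_node(target, "reaction")
    }
    from <- node_of_modifier(rows$modifier[i])
    add_edge(from, target,
             if (rows$kind[i] == "!") "required" else "inhibitory")
  }

  keys <- sort(names(nodes))
  g <- igraph::make_empty_graph(n = length(keys), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = keys)
  g <- igraph::set_vertex_attr(g, "category",
                               value = unlist(nodes[keys], use.names = FALSE))
  if (length(edges)) {
    em <- do.call(rbind, edges)
    ord <- order(em[, 1], em[, 2], em[, 3])
    em <- em[ord, , drop = FALSE]
    g <- igraph::add_edges(g, t(em[, 1:2, drop = FALSE]),
                           category = em[, 3])
  }
  g
}

#' Write a regulatory graph to GraphML or DOT
#'
#' Categories are emitted as plain attributes (key `category`), not as
#' style directives; rendering is a viewer concern. Nodes are ordered by
#' key, so two writes of the same graph are byte-identical.
#'
#' @param graph An igraph as returned by [build_regulatory_graph()].
#' @param file Output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `file`, invisibly.
#' @export
write_regulatory_graph <- function(graph, file,
                                   format = c("graphml", "dot")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, file, format = "graphml")
  } else {
    con <- file(file, "w", encoding = "UTF-8")
    on.exit(close(con))
    esc <- function(x) gsub("\"", "\\\"", x, fixed = TRUE)
    writeLines("digraph regulatory {", con)
    vs <- igraph::V(graph)
    nm <- igraph::vertex_attr(graph, "name")
    cat_v <- igraph::vertex_attr(graph, "category")
    for (i in order(nm)) {
      writeLines(sprintf("  \"%s\" [category=\"%s\"];", esc(nm[i]),
                         esc(cat_v[i])), con)
    }
    if (igraph::ecount(graph)) {
      el <- igraph::as_edgelist(graph)
      cat_e <- igraph::edge_attr(graph, "category")
      ord <- order(el[, 1], el[, 2], cat_e)
      for (i in ord) {
        writeLines(sprintf("  \"%s\" -> \"%s\" [category=\"%s\"];",
                           esc(el[i, 1]), esc(el[i, 2]), esc(cat_e[i])), con)
      }
    }
    writeLines("}", con)
  }
  invisible(file)
}
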