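#' @title Bipartite Boolean model compilation
#' @description
#' A knowledge base compiles into a bipartite Boolean model: one node per
#' elemental reaction, per elemental state (neutral and non-neutral), per
#' component, per input and per contingency-defined output, each with a
#' single update expression. Reaction rules read states; state rules read
#' reactions; gates are inlined away.
#' @name bbm-compilation
NULL

b_const <- function(value) list(op = "const", value = isTRUE(value))
b_lit <- function(key) list(op = "lit", key = key)
b_not <- function(e) list(op = "not", args = list(e))

b_nary <- function(op, args) {
  args <- args[!vapply(args, is.null, logical(1))]
  # flatten nested runs of the same operator
  flat <- list()
  for (a in args) {
    if (identical(a$op, op)) flat <- c(flat, a$args) else
      flat[[length(flat) + 1L]] <- a
  }
  # constant folding: absorbing and identity elements
  is_const <- vapply(flat, function(a) a$op == "const", logical(1))
  vals <- vapply(flat[is_const], `[[`, logical(1), "value")
  if (op == "and" && any(!vals)) return(b_const(FALSE))
  if (op == "or" && any(vals)) return(b_const(TRUE))
  flat <- flat[!is_const]
  if (!length(flat)) return(b_const(op == "and"))  # AND()=TRUE, OR()=FALSE
  if (length(flat) == 1L) return(flat[[1]])
  list(op = op, args = flat)
}
b_and <- function(...) b_nary("and", list(...))
b_or <- function(...) b_nary("or", list(...))
b_and_list <- function(args) b_nary("and", args)
b_or_list <- function(args) b_nary("or", args)

expr_literals <- function(e) {
  switch(e$op,
         lit = e$key,
         const = character(0),
         unique(unlist(lapply(e$args, expr_literals))))
}

#' Evaluate a Boolean update expression
#'
#' @param expr Expression tree as stored in a compiled model's `rules`.
#' @param values Named logical vector supplying every literal.
#' @return Logical scalar.
#' @export
eval_expression <- function(expr, values) {
  switch(expr$op,
         const = expr$value,
         lit = {
           v <- values[[expr$key]]
           if (is.null(v) || is.na(v)) {
             stop(sprintf("no value for node '%s'", expr$key), call. = FALSE)
           }
           v
         },
         not = !eval_expression(expr$args[[1]], values),
         and = all(vapply(expr$args, eval_expression, logical(1),
                          values = values)),
         or = any(vapply(expr$args, eval_expression, logical(1),
                         values = values)),
         stop(sprintf("unknown operator '%s'", expr$op), call. = FALSE))
}

#' Format an update expression
#'
#' @param expr Expression tree.
#' @return A readable single-line string.
#' @export
format_expression <- function(expr) {
  switch(expr$op,
         const = if (expr$value) "TRUE" else "FALSE",
         lit = expr$key,
         not = sprintf("NOT(%s)", format_expression(expr$args[[1]])),
         sprintf("%s(%s)", toupper(expr$op),
                 paste(vapply(expr$args, format_expression, character(1)),
                       collapse = ", ")))
}

#' Enumerate the node set of the bipartite Boolean model
#'
#' The node set contains every reaction, every state appearing as a
#' reaction effect or contingency modifier plus its neutral partner(s),
#' one node per component, every input, and one output node per bracketed
#' name used as a contingency target.
#'
#' @param kb An `rxn_kb` object.
#' @return A data.frame with columns `kind`
#'   (`reaction`/`state`/`component`/`input`/`output`) and `key`
#'   (canonical string; inputs and outputs are bracketed).
#' @export
enumerate_nodes <- function(kb) {
  stopifnot(inherits(kb, "rxn_kb"))
  modifiers <- registry_modifiers(kb$registry)
  state_keys <- unique(c(
    unlist(lapply(kb$reactions, `[[`, "consumed")),
    unlist(lapply(kb$reactions, `[[`, "produced")),
    kb_modifier_state_keys(kb)
  ))
  # canonicalise and close under neutral partners
  states <- lapply(state_keys, parse_state, modifiers = modifiers)
  partners <- unlist(lapply(states, neutral_partners), recursive = FALSE)
  all_keys <- unique(vapply(c(states, partners), render_state, character(1)))

  blocks <- list(
    reaction = names(kb$reactions),
    state = sort(all_keys),
    component = names(kb$components),
    input = if (length(kb$inputs)) sprintf("[%s]", kb$inputs),
    output = if (length(kb$outputs)) sprintf("[%s]", kb$outputs)
  )
  out <- do.call(rbind, lapply(names(blocks), function(kind) {
    keys <- blocks[[kind]]
    if (!length(keys)) return(NULL)
    data.frame(kind = kind, key = keys, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(kind = character(0), key = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Inline gate references in a contingency modifier
#'
#' Replaces every `<gate>` reference by its definition, recursively,
#' yielding an expression over states, inputs and outputs only. `NOT`
#' over a neutral-state reference is permitted (it reads "unmodified").
#'
#' @param kb An `rxn_kb` object with an acyclic gate graph.
#' @param expr A modifier string (state, `[input]` or `<gate>`) or an
#'   expression tree containing gate-reference literals.
#' @return A gate-free expression tree.
#' @export
inline_gates <- function(kb, expr) {
  if (length(gate_cycles(kb))) {
    stop("gate-reference graph is cyclic", call. = FALSE)
  }
  modifiers <- registry_modifiers(kb$registry)
  rec <- function(m) {
    if (is.list(m) && !is.null(m$op)) {
      if (m$op == "lit") return(rec(m$key))
      if (m$op == "const") return(m)
      m$args <- lapply(m$args, rec)
      return(m)
    }
    if (grepl("^<.+>$", m)) {
      nm <- sub("^<(.+)>$", "\\1", m)
      g <- kb$gates[[nm]]
      if (is.null(g)) stop(sprintf("undefined gate <%s>", nm), call. = FALSE)
      members <- lapply(g$members, rec)
      return(switch(g$op,
                    AND = b_and_list(members),
                    OR = b_or_list(members),
                    NOT = b_not(members[[1]])))
    }
    if (grepl("^\\[.+\\]$", m)) return(b_lit(m))
    b_lit(render_state(parse_state(m, modifiers)))
  }
  rec(expr)
}

# producer / consumer reaction maps keyed by state
state_reaction_maps <- function(kb) {
  producers <- list(); consumers <- list()
  addto <- function(map, key, rxn) {
    map[[key]] <- c(map[[key]], rxn); map
  }
  rows <- kb_constraints(kb)
  for (r in kb$reactions) {
    for (s in r$produced) producers <- addto(producers, s, r$text)
    for (s in r$consumed) consumers <- addto(consumers, s, r$text)
    if (!is.na(r$degrades)) {
      # contingent degradation consumes the target states it requires
      req <- rows[rows$target == r$text & rows$kind == "!", , drop = FALSE]
      keys <- unique(unlist(lapply(req$modifier, modifier_states, kb = kb)))
      modifiers <- registry_modifiers(kb$registry)
      for (key in keys) {
        s <- parse_state(key, modifiers)
        if (inherits(s, "elemental_state") &&
            r$degrades %in% state_components(s)) {
          key <- render_state(s)
          consumers <- addto(consumers, key, r$text)
        }
      }
    }
  }
  list(producers = producers, consumers = consumers)
}

#' Compile a knowledge base into a bipartite Boolean model
#'
#' Builds one update rule per node:
#' \itemize{
#'   \item reaction: AND of component presence, required (`!`)
#'     modifiers, and negated inhibitory (`x`) modifiers; source states
#'     act through the state layer (production/consumption), not the
#'     reaction rule;
#'   \item state: component presence AND (production OR unconsumed
#'     persistence); production dominates consumption, so an active
#'     producer keeps the state TRUE regardless of consumers;
#'   \item neutral state: as above, with reverse reactions and every
#'     synthesis of the component among its producers;
#'   \item component: constant TRUE without synthesis reactions,
#'     otherwise synthesis OR (self AND no active degradation);
#'   \item output: the conjunction of its inlined contingency rows;
#'   \item input: identity (holds its value unless clamped).
#' }
#' State semantics are existential over the molecule pool: a state node
#' means "some molecules carry this state", so a modified state and its
#' neutral partner may be TRUE simultaneously.
#'
#' @param kb A validated `rxn_kb` object (no validation errors).
#' @return An object of class `boolean_model` with fields `nodes`,
#'   `rules` (named expression trees), `clampable` (input node keys).
#' @export
build_update_rules <- function(kb) {
  stopifnot(inherits(kb, "rxn_kb"))
  if (length(gate_cycles(kb))) {
    stop("gate-reference graph is cyclic", call. = FALSE)
  }
  nodes <- enumerate_nodes(kb)
  modifiers <- registry_modifiers(kb$registry)
  rows <- kb_constraints(kb)

  produced_any <- unique(unlist(lapply(kb$reactions, `[[`, "produced")))
  for (key in kb_modifier_state_keys(kb)) {
    s <- parse_state(key, modifiers)
    if (inherits(s, "elemental_state") && !is_neutral_state(s) &&
        !render_state(s) %in% produced_any) {
      stop(sprintf(
        "state '%s' is referenced by a contingency but has no producing reaction and is not neutral",
        key), call. = FALSE)
    }
  }

  maps <- state_reaction_maps(kb)
  synth_of <- vapply(kb$reactions, `[[`, character(1), "synthesises")
  deg_of <- vapply(kb$reactions, `[[`, character(1), "degrades")

  contingency_expr <- function(target_key) {
    sel <- rows[rows$target == target_key, , drop = FALSE]
    parts <- list()
    for (i in seq_len(nrow(sel))) {
      if (sel$kind[i] == "!") {
        parts[[length(parts) + 1L]] <- inline_gates(kb, sel$modifier[i])
      } else if (sel$kind[i] == "x") {
        parts[[length(parts) + 1L]] <- b_not(inline_gates(kb, sel$modifier[i]))
      }  # kind "0" compiles to nothing
    }
    parts
  }

  rules <- vector("list", nrow(nodes))
  names(rules) <- nodes$key
  for (i in seq_len(nrow(nodes))) {
    key <- nodes$key[i]
    rules[[i]] <- switch(
      nodes$kind[i],
      reaction = {
        # source states do not gate the reaction node: under pool
        # semantics the reaction acts on whatever fraction of the pool
        # carries the source state, and folding sources into the rule
        # couples the reaction and state layers into artefactual
        # synchronous oscillations (see the methods vignette)
        r <- kb$reactions[[key]]
        comps <- unique(c(r$components,
                          if (!is.na(r$degrades)) r$degrades))
        b_and_list(c(lapply(comps, b_lit), contingency_expr(key)))
      },
      state = {
        s <- parse_state(key, modifiers)
        comps <- state_components(s)
        prods <- unique(maps$producers[[key]])
        cons <- unique(maps$consumers[[key]])
        persist <- if (length(cons)) {
          b_and(b_lit(key), b_not(b_or_list(lapply(cons, b_lit))))
        } else {
          b_lit(key)
        }
        b_and_list(c(lapply(comps, b_lit),
                     list(b_or(b_or_list(lapply(prods, b_lit)), persist))))
      },
      component = {
        synths <- names(synth_of)[!is.na(synth_of) & synth_of == key]
        degs <- names(deg_of)[!is.na(deg_of) & deg_of == key]
        if (!length(synths)) {
          b_const(TRUE)
        } else {
          persist <- if (length(degs)) {
            b_and(b_lit(key), b_not(b_or_list(lapply(degs, b_lit))))
          } else {
            b_lit(key)
          }
          b_or(b_or_list(lapply(synths, b_lit)), persist)
        }
      },
      input = b_lit(key),
      output = b_and_list(contingency_expr(key))
    )
  }

  # every literal must name a declared node
  declared <- nodes$key
  for (i in seq_along(rules)) {
    missing <- setdiff(expr_literals(rules[[i]]), declared)
    if (length(missing)) {
      stop(sprintf("rule for '%s' references undeclared node(s): %s",
                   names(rules)[i], paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }

  model <- structure(
    list(nodes = nodes, rules = rules,
         clampable = nodes$key[nodes$kind == "input"]),
    class = "boolean_model"
  )
  model$step_fun <- compile_step_function(model)
  model
}

# translate the rule set into one generated R function for fast stepping
compile_step_function <- function(model) {
  idx <- stats::setNames(seq_along(model$nodes$key), model$nodes$key)
  code_of <- function(e) {
    switch(e$op,
           const = if (e$value) "TRUE" else "FALSE",
           lit = sprintf("x[%dL]", idx[[e$key]]),
           not = sprintf("!(%s)", code_of(e$args[[1]])),
           and = paste0("(", paste(vapply(e$args, code_of, character(1)),
                                   collapse = " && "), ")"),
           or = paste0("(", paste(vapply(e$args, code_of, character(1)),
                                  collapse = " || "), ")"))
  }
  lines <- vapply(seq_along(model$rules), function(i) {
    sprintf("v[%dL] <- %s", i, code_of(model$rules[[i]]))
  }, character(1))
  body <- paste0("function(x) {\n v <- logical(", length(model$rules), "L)\n",
                 paste(lines, collapse = "\n"), "\n v\n}")
  eval(parse(text = body)[[1]], envir = baseenv())
}

#' @export
print.boolean_model <- function(x, ...) {
  tab <- table(x$nodes$kind)
  cat(sprintf("<boolean_model: %d nodes (%s)>\n", nrow(x$nodes),
              paste(sprintf("%s %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}
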