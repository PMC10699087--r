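#' @title Random networks and the reference interpreter
#' @description
#' The generator emits random reaction-contingency networks with the
#' structural motifs the simulator semantics must handle:
#' kinase/phosphatase pairs, bond formation and dissociation,
#' (de)ubiquitylation, proteolytic truncation, input-gated
#' transcription/translation/degradation, strict contingencies and
#' nested gates. The companion reference interpreter evaluates the
#' update semantics directly from the knowledge base, without compiled
#' rule expressions, and serves as the oracle for the compiler and
#' simulator.
#' @name synthetic-networks
NULL

#' Configuration for the random-network generator
#'
#' @param n_components Number of substrate components (>= 1).
#' @param n_reactions Total number of reactions to emit (>= 1).
#' @param p_contingency Probability that a reaction receives a strict
#'   contingency row.
#' @param p_gate Probability that a contingency modifier is a nested
#'   gate rather than a single state or input.
#' @param max_gate_depth Maximum gate nesting depth.
#' @param p_synthesis Probability that a component receives a
#'   transcription/translation/degradation triple.
#' @param n_inputs Number of declared inputs.
#' @param seed Integer seed; generation is a pure function of the
#'   configuration including the seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_components = 4L, n_reactions = 8L,
                         p_contingency = 0.6, p_gate = 0.3,
                         max_gate_depth = 2L, p_synthesis = 0.3,
                         n_inputs = 2L, seed = 1L) {
  stopifnot(n_components >= 1L, n_reactions >= 1L, n_inputs >= 1L,
            p_contingency >= 0, p_contingency <= 1,
            p_gate >= 0, p_gate <= 1, p_synthesis >= 0, p_synthesis <= 1,
            max_gate_depth >= 1L)
  structure(list(n_components = as.integer(n_components),
                 n_reactions = as.integer(n_reactions),
                 p_contingency = p_contingency, p_gate = p_gate,
                 max_gate_depth = as.integer(max_gate_depth),
                 p_synthesis = p_synthesis, n_inputs = as.integer(n_inputs),
                 seed = as.integer(seed)),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a random reaction-contingency network
#'
#' The result always passes [validate_knowledge_base()] with zero
#' errors: every contingency state modifier is producible in the network
#' or neutral, the gate graph is acyclic by construction, and at least
#' one input and one output are present.
#'
#' @param config A [synth_config()].
#' @return An `rxn_kb` object.
#' @export
random_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    comps <- sprintf("C%d", seq_len(config$n_components))
    inputs <- sprintf("[I%d]", seq_len(config$n_inputs))
    residues <- c("r1", "r2")
    domains <- c("d1", "d2")
    rc <- function(x) x[sample.int(length(x), 1L)]

    texts <- character(0)
    add <- function(txt) {
      if (!txt %in% texts) texts <<- c(texts, txt)
    }

    # synthesis/turnover triples under the reaction budget
    for (comp in comps) {
      if (length(texts) + 3L > config$n_reactions) break
      if (stats::runif(1) < config$p_synthesis) {
        add(sprintf("Pol_trsc_%s", comp))
        add(sprintf("Ribo_trsl_%s", comp))
        add(sprintf("Prot_deg_%s", comp))
      }
    }

    guard <- 0L
    while (length(texts) < config$n_reactions && guard < 10000L) {
      guard <- guard + 1L
      kind <- rc(c("P+", "P+", "P-", "ppi+", "ppi+", "ppi-", "ub63+",
                   "ub63-", "cut"))
      if (kind %in% c("P+", "ub63+", "cut")) {
        add(sprintf("%s_%s_%s_[(%s)]", rc(comps), kind, rc(comps),
                    rc(residues)))
      } else if (kind == "P-") {
        fwd <- grep("_P\\+_", texts, value = TRUE)
        if (!length(fwd)) next
        target <- sub("^[^_]+_P\\+_", "", rc(fwd))
        add(sprintf("%s_P-_%s", rc(comps), target))
      } else if (kind == "ub63-") {
        fwd <- grep("_ub63\\+_", texts, value = TRUE)
        if (!length(fwd)) next
        target <- sub("^[^_]+_ub63\\+_", "", rc(fwd))
        add(sprintf("%s_ub63-_%s", rc(comps), target))
      } else if (kind == "ppi+") {
        add(sprintf("%s_[%s]_ppi+_%s_[%s]", rc(comps), rc(domains),
                    rc(comps), rc(domains)))
      } else if (kind == "ppi-") {
        fwd <- grep("_ppi\\+_", texts, value = TRUE)
        if (!length(fwd)) next
        add(sub("_ppi+_", "_ppi-_", rc(fwd), fixed = TRUE))
      }
    }
    texts <- texts[seq_len(min(length(texts), config$n_reactions))]

    registry <- reaction_type_registry()
    rxns <- lapply(texts, parse_reaction, registry = registry)
    producible <- unique(unlist(lapply(rxns, `[[`, "produced")))
    producible <- producible[!is.na(producible)]
    leaf_pool <- c(producible, inputs)

    cont <- list()
    uid <- 0L
    gate_n <- 0L
    add_row <- function(target, kind, modifier) {
      uid <<- uid + 1L
      cont[[length(cont) + 1L]] <<- data.frame(
        UID = uid, Target = target, Contingency = kind, Modifier = modifier,
        stringsAsFactors = FALSE)
    }
    make_gate <- function(depth) {
      gate_n <<- gate_n + 1L
      name <- sprintf("G%d", gate_n)
      op <- rc(c("AND", "OR", "OR", "NOT"))
      n_members <- if (op == "NOT") 1L else 2L
      for (i in seq_len(n_members)) {
        nested <- depth < config$max_gate_depth &&
          stats::runif(1) < config$p_gate
        member <- if (nested) make_gate(depth + 1L) else rc(leaf_pool)
        add_row(sprintf("<%s>", name), op, member)
      }
      sprintf("<%s>", name)
    }

    # input-gated transcription: the priming motif
    for (txt in grep("_trsc_", texts, value = TRUE)) {
      add_row(txt, "!", rc(inputs))
    }
    for (txt in texts) {
      if (grepl("_trsc_", txt)) next
      if (stats::runif(1) < config$p_contingency && length(leaf_pool)) {
        kind <- rc(c("!", "!", "x", "0"))
        modifier <- if (stats::runif(1) < config$p_gate) {
          make_gate(1L)
        } else {
          rc(leaf_pool)
        }
        add_row(txt, kind, modifier)
      }
    }
    # at least one input must be mentioned and one output defined
    if (!any(vapply(cont, function(d) d$Modifier %in% inputs, logical(1)))) {
      add_row(texts[1], "!", inputs[1])
    }
    add_row("[Out1]", "!",
            if (length(producible)) rc(producible) else inputs[1])

    rdf <- data.frame(UID = seq_along(texts), Reaction = texts,
                      Reference = "", stringsAsFactors = FALSE)
    cdf <- do.call(rbind, cont)
    load_knowledge_base(rdf, cdf, registry = registry)
  })
}

# evaluate a contingency modifier directly against an assignment
interp_modifier <- function(kb, modifier, values) {
  if (grepl("^<.+>$", modifier)) {
    g <- kb$gates[[sub("^<(.+)>$", "\\1", modifier)]]
    member_vals <- vapply(g$members, interp_modifier, logical(1),
                          kb = kb, values = values)
    switch(g$op, AND = all(member_vals), OR = any(member_vals),
           NOT = !member_vals[[1]])
  } else if (grepl("^\\[.+\\]$", modifier)) {
    v <- values[[modifier]]
    if (is.null(v)) stop(sprintf("no node for %s", modifier), call. = FALSE)
    v
  } else {
    key <- render_state(parse_state(modifier, registry_modifiers(kb$registry)))
    values[[key]]
  }
}

#' Reference interpreter for the bipartite Boolean semantics
#'
#' Computes a synchronous trajectory by evaluating the update semantics
#' node by node directly from the knowledge base at every step:
#' reactions fire when their components, source states and required
#' modifiers hold and no inhibitory modifier does; states follow
#' production-dominant pool semantics; components without synthesis are
#' constitutive; outputs re-evaluate their contingencies; inputs hold
#' (or take their clamp). No compiled rule expressions are involved, so
#' this serves as an independent oracle for [build_update_rules()] and
#' [sim_step()].
#'
#' @param kb A validator-clean `rxn_kb`.
#' @param initial Named logical assignment over [enumerate_nodes()]'s
#'   keys.
#' @param clamps Named logical vector over input keys (bracketed).
#' @param n_steps Number of synchronous steps.
#' @return A `bool_trajectory` matrix with `n_steps + 1` columns.
#' @export
reference_interpret <- function(kb, initial, clamps = NULL, n_steps = 50L) {
  stopifnot(inherits(kb, "rxn_kb"), n_steps >= 0L)
  nodes <- enumerate_nodes(kb)
  if (is.null(clamps)) clamps <- stats::setNames(logical(0), character(0))
  modifiers <- registry_modifiers(kb$registry)
  rows <- kb_constraints(kb)

  # index maps derived once per call, directly from the knowledge base
  canon <- function(k) render_state(parse_state(k, modifiers))
  meta <- lapply(seq_len(nrow(nodes)), function(i) {
    key <- nodes$key[i]
    switch(
      nodes$kind[i],
      input = list(),
      reaction = list(comps = kb$reactions[[key]]$components,
                      rows = rows[rows$target == key, , drop = FALSE]),
      state = {
        s <- parse_state(key, modifiers)
        prod <- cons <- character(0)
        for (r in kb$reactions) {
          if (key %in% r$produced) prod <- c(prod, r$text)
          if (key %in% r$consumed) cons <- c(cons, r$text)
          if (!is.na(r$degrades) && r$degrades %in% state_components(s)) {
            # contingent degradation consumes the target states it requires
            sel <- rows[rows$target == r$text & rows$kind == "!", ,
                        drop = FALSE]
            req <- unlist(lapply(sel$modifier, modifier_states, kb = kb))
            if (length(req) &&
                key %in% vapply(req, canon, character(1), USE.NAMES = FALSE)) {
              cons <- c(cons, r$text)
            }
          }
        }
        list(comps = state_components(s), prod = prod, cons = cons)
      },
      component = {
        synths <- names(Filter(function(r) identical(r$synthesises, key),
                               kb$reactions))
        degs <- names(Filter(function(r) identical(r$degrades, key),
                             kb$reactions))
        list(synths = synths, degs = degs)
      },
      output = list(rows = rows[rows$target == key, , drop = FALSE]))
  })

  eval_rows <- function(sel, cur) {
    ok <- TRUE
    for (j in seq_len(nrow(sel))) {
      mv <- interp_modifier(kb, sel$modifier[j], cur)
      if (sel$kind[j] == "!" && !mv) { ok <- FALSE; break }
      if (sel$kind[j] == "x" && mv) { ok <- FALSE; break }
    }
    ok
  }

  cur <- as.list(initial[nodes$key])
  if (length(clamps)) cur[names(clamps)] <- as.list(unname(clamps))
  traj <- matrix(NA, nrow(nodes), n_steps + 1L,
                 dimnames = list(nodes$key, 0:n_steps))
  traj[, 1] <- unlist(cur[nodes$key])

  for (step in seq_len(n_steps)) {
    nxt <- vector("list", nrow(nodes))
    names(nxt) <- nodes$key
    for (i in seq_len(nrow(nodes))) {
      key <- nodes$key[i]
      m <- meta[[i]]
      nxt[[i]] <- switch(
        nodes$kind[i],
        input = if (key %in% names(clamps)) clamps[[key]] else cur[[key]],
        reaction = all(unlist(cur[m$comps])) && eval_rows(m$rows, cur),
        state = {
          all(unlist(cur[m$comps])) &&
            (any(unlist(cur[m$prod])) ||
               (cur[[key]] && !any(unlist(cur[m$cons]))))
        },
        component = {
          if (!length(m$synths)) TRUE else {
            any(unlist(cur[m$synths])) ||
              (cur[[key]] && !any(unlist(cur[m$degs])))
          }
        },
        output = nrow(m$rows) > 0L && eval_rows(m$rows, cur))
    }
    cur <- nxt
    traj[, step + 1L] <- unlist(cur[nodes$key])
  }
  structure(traj, clamps = clamps, class = "bool_trajectory")
}
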