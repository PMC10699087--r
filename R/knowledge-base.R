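#' @title Reaction-contingency knowledge bases
#' @description
#' A knowledge base couples a list of typed elemental reactions with a
#' table of contingencies: required (`!`), inhibitory (`x`) or no-effect
#' (`0`) constraints whose modifier is an elemental state, a bracketed
#' system input, or a named Boolean gate (`<name>`), itself defined by
#' contingency rows with kind `AND`/`OR`/`NOT`. Bracketed names used as
#' contingency targets define system outputs.
#' @name knowledge-base
NULL

strip_bang <- function(x) sub("^[!]+", "", x)

read_table_arg <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    df <- utils::read.delim(x, stringsAsFactors = FALSE,
                            colClasses = "character",
                            check.names = FALSE, quote = "")
    names(df) <- strip_bang(names(df))
    df
  } else if (is.data.frame(x)) {
    x <- as.data.frame(lapply(x, as.character), stringsAsFactors = FALSE,
                       check.names = FALSE)
    names(x) <- strip_bang(names(x))
    x
  } else {
    stop("expected a file path or a data.frame", call. = FALSE)
  }
}

#' Load a knowledge base from its tabular sources
#'
#' @param reactions A directory containing `ReactionList.tsv`,
#'   `ContingencyList.tsv` and optionally `ReactionTypes.tsv`; or the
#'   reaction table itself (TSV path or data.frame with columns `UID`,
#'   `Reaction` and optionally `Reference`; leading `!` on header names
#'   is stripped).
#' @param contingencies Contingency table (TSV path or data.frame with
#'   columns `UID`, `Target`, `Contingency`, `Modifier` and optionally
#'   `Reference`). Ignored when `reactions` is a directory.
#' @param registry Reaction-type registry; defaults to the directory's
#'   `ReactionTypes.tsv` when present, else [reaction_type_registry()].
#' @return An object of class `rxn_kb`.
#' @export
load_knowledge_base <- function(reactions, contingencies = NULL,
                                registry = NULL) {
  if (is.character(reactions) && length(reactions) == 1L &&
      dir.exists(reactions)) {
    dir <- reactions
    reactions <- file.path(dir, "ReactionList.tsv")
    contingencies <- file.path(dir, "ContingencyList.tsv")
    reg_path <- file.path(dir, "ReactionTypes.tsv")
    if (is.null(registry) && file.exists(reg_path)) {
      registry <- read_reaction_types(reg_path)
    }
  }
  if (is.null(registry)) registry <- reaction_type_registry()

  rdf <- read_table_arg(reactions)
  if (!"Reaction" %in% names(rdf)) {
    stop("reaction table must have a 'Reaction' column", call. = FALSE)
  }
  rdf <- rdf[nzchar(trimws(rdf$Reaction)), , drop = FALSE]

  if (is.null(contingencies)) {
    cdf <- data.frame(UID = character(0), Target = character(0),
                      Contingency = character(0), Modifier = character(0),
                      stringsAsFactors = FALSE)
  } else {
    cdf <- read_table_arg(contingencies)
  }
  need <- c("UID", "Target", "Contingency", "Modifier")
  if (nrow(cdf) && !all(need %in% names(cdf))) {
    stop("contingency table must have columns UID, Target, Contingency, Modifier",
         call. = FALSE)
  }

  rxns <- lapply(rdf$Reaction, parse_reaction, registry = registry)
  names(rxns) <- vapply(rxns, `[[`, character(1), "text")
  if (anyDuplicated(names(rxns))) {
    stop(sprintf("duplicate reaction: %s",
                 names(rxns)[duplicated(names(rxns))][1]), call. = FALSE)
  }
  rxn_meta <- data.frame(
    uid = if ("UID" %in% names(rdf)) rdf$UID else as.character(seq_along(rxns)),
    reaction = names(rxns),
    reference = if ("Reference" %in% names(rdf)) rdf$Reference
                else character(length(rxns)),
    stringsAsFactors = FALSE
  )

  cont <- data.frame(
    uid = if (nrow(cdf)) suppressWarnings(as.integer(cdf$UID)) else integer(0),
    target = if (nrow(cdf)) trimws(cdf$Target) else character(0),
    kind = if (nrow(cdf)) trimws(cdf$Contingency) else character(0),
    modifier = if (nrow(cdf)) trimws(cdf$Modifier) else character(0),
    reference = if (nrow(cdf) && "Reference" %in% names(cdf)) cdf$Reference
                else character(nrow(cdf)),
    stringsAsFactors = FALSE
  )
  if (anyNA(cont$uid)) stop("contingency UID must be an integer", call. = FALSE)
  if (anyDuplicated(cont$uid)) {
    stop(sprintf("duplicate contingency UID: %s",
                 cont$uid[duplicated(cont$uid)][1]), call. = FALSE)
  }
  bad_kind <- !cont$kind %in% c("!", "x", "0", "AND", "OR", "NOT")
  if (any(bad_kind)) {
    stop(sprintf("unknown contingency kind '%s' (UID %d)",
                 cont$kind[bad_kind][1], cont$uid[bad_kind][1]), call. = FALSE)
  }
  gate_kind <- cont$kind %in% c("AND", "OR", "NOT")
  gate_target <- grepl("^<.+>$", cont$target)
  if (any(gate_kind & !gate_target)) {
    i <- which(gate_kind & !gate_target)[1]
    stop(sprintf("contingency kind %s requires a gate target (UID %d)",
                 cont$kind[i], cont$uid[i]), call. = FALSE)
  }

  # assemble gate definitions, preserving member order
  gates <- list()
  for (i in which(gate_kind)) {
    nm <- sub("^<(.+)>$", "\\1", cont$target[i])
    if (is.null(gates[[nm]])) {
      gates[[nm]] <- list(name = nm, op = cont$kind[i],
                          members = character(0))
    } else if (!identical(gates[[nm]]$op, cont$kind[i])) {
      stop(sprintf("gate <%s> defined with conflicting operators", nm),
           call. = FALSE)
    }
    gates[[nm]]$members <- c(gates[[nm]]$members, cont$modifier[i])
  }
  for (g in gates) {
    if (g$op == "NOT" && length(g$members) != 1L) {
      stop(sprintf("NOT gate <%s> must have exactly one member", g$name),
           call. = FALSE)
    }
    if (g$op %in% c("AND", "OR") && length(g$members) < 2L) {
      stop(sprintf("%s gate <%s> needs at least two members", g$op, g$name),
           call. = FALSE)
    }
  }

  kb <- structure(
    list(reactions = rxns, contingencies = cont, gates = gates,
         registry = registry, rxn_meta = rxn_meta),
    class = "rxn_kb"
  )
  kb_finalise(kb)
}

# rows that constrain a reaction or output (not gate definitions)
kb_constraints <- function(kb) {
  kb$contingencies[kb$contingencies$kind %in% c("!", "x", "0"), , drop = FALSE]
}

# every state string referenced by a modifier, descending through gates
modifier_states <- function(kb, modifier, seen = character(0)) {
  if (grepl("^<.+>$", modifier)) {
    nm <- sub("^<(.+)>$", "\\1", modifier)
    if (nm %in% seen) return(character(0))  # cycle; validator reports it
    g <- kb$gates[[nm]]
    if (is.null(g)) return(character(0))
    return(unique(unlist(lapply(g$members, modifier_states, kb = kb,
                                seen = c(seen, nm)))))
  }
  if (grepl("^\\[.+\\]$", modifier)) return(character(0))
  modifier
}

kb_modifier_state_keys <- function(kb) {
  rows <- kb_constraints(kb)
  keys <- unique(unlist(lapply(rows$modifier, modifier_states, kb = kb)))
  modifiers <- registry_modifiers(kb$registry)
  vapply(keys, function(k) {
    s <- try(parse_state(k, modifiers), silent = TRUE)
    if (inherits(s, "try-error")) k else render_state(s)
  }, character(1), USE.NAMES = FALSE)
}

kb_bracketed_names <- function(modifier, kb, seen = character(0)) {
  if (grepl("^<.+>$", modifier)) {
    nm <- sub("^<(.+)>$", "\\1", modifier)
    if (nm %in% seen) return(character(0))
    g <- kb$gates[[nm]]
    if (is.null(g)) return(character(0))
    return(unique(unlist(lapply(g$members, kb_bracketed_names, kb = kb,
                                seen = c(seen, nm)))))
  }
  if (grepl("^\\[.+\\]$", modifier)) sub("^\\[(.+)\\]$", "\\1", modifier)
  else character(0)
}

# derive per-component locus inventory, synthesis effects, inputs/outputs
kb_finalise <- function(kb) {
  modifiers <- registry_modifiers(kb$registry)
  inventory <- list()
  add_locus <- function(component, loc) {
    if (is.null(loc)) {
      if (is.null(inventory[[component]])) {
        inventory[[component]] <<- list(residues = character(0),
                                        domains = character(0))
      }
      return(invisible())
    }
    cur <- inventory[[component]]
    if (is.null(cur)) cur <- list(residues = character(0), domains = character(0))
    slot <- if (loc$kind == "residue") "residues" else "domains"
    cur[[slot]] <- unique(c(cur[[slot]], loc$name))
    inventory[[component]] <<- cur
  }
  add_state <- function(s) {
    if (inherits(s, "modification_state")) add_locus(s$component, s$residue)
    else if (inherits(s, "bond_state")) {
      add_locus(s$endpointA$component, s$endpointA$domain)
      add_locus(s$endpointB$component, s$endpointB$domain)
    } else if (inherits(s, "free_state")) add_locus(s$component, s$domain)
  }

  for (r in kb$reactions) {
    add_locus(r$subjectA$component, r$subjectA$locus)
    add_locus(r$subjectB$component, r$subjectB$locus)
    for (s in c(r$consumed_states, r$produced_states)) add_state(s)
    if (!is.na(r$synthesises)) add_locus(r$synthesises, NULL)
    if (!is.na(r$degrades)) add_locus(r$degrades, NULL)
  }
  for (key in kb_modifier_state_keys(kb)) {
    s <- try(parse_state(key, modifiers), silent = TRUE)
    if (!inherits(s, "try-error") && inherits(s, "elemental_state")) add_state(s)
  }

  # synthesis reactions produce every neutral state of their target
  neutral_keys_of <- function(component) {
    inv <- inventory[[component]]
    if (is.null(inv)) return(character(0))
    c(if (length(inv$residues))
        sprintf("%s_[(%s)]-{0}", component, inv$residues),
      if (length(inv$domains))
        sprintf("%s_[%s]--0", component, inv$domains))
  }
  for (nm in names(kb$reactions)) {
    r <- kb$reactions[[nm]]
    if (!is.na(r$synthesises)) {
      keys <- neutral_keys_of(r$synthesises)
      kb$reactions[[nm]]$produced <- keys
      kb$reactions[[nm]]$produced_states <-
        lapply(keys, parse_state, modifiers = modifiers)
    }
  }

  rows <- kb_constraints(kb)
  outputs <- unique(sub("^\\[(.+)\\]$", "\\1",
                        rows$target[grepl("^\\[.+\\]$", rows$target)]))
  mentioned <- unique(unlist(lapply(rows$modifier, kb_bracketed_names, kb = kb)))
  inputs <- setdiff(mentioned, outputs)

  kb$components <- inventory
  kb$inputs <- sort(inputs)
  kb$outputs <- sort(outputs)
  kb
}

#' @export
print.rxn_kb <- function(x, ...) {
  cat(sprintf(
    "<rxn_kb: %d reactions, %d contingency rows (%d gates), %d components, %d inputs, %d outputs>\n",
    length(x$reactions), nrow(x$contingencies), length(x$gates),
    length(x$components), length(x$inputs), length(x$outputs)))
  invisible(x)
}

#' Write a knowledge base back to its tabular format
#'
#' Emits `ReactionList.tsv`, `ContingencyList.tsv` and
#' `ReactionTypes.tsv` (UTF-8, tab-separated) into `dir`, in the dialect
#' accepted by [load_knowledge_base()].
#'
#' @param kb An `rxn_kb` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_knowledge_base <- function(kb, dir) {
  stopifnot(inherits(kb, "rxn_kb"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(data.frame(UID = kb$rxn_meta$uid, Reaction = kb$rxn_meta$reaction,
                Reference = kb$rxn_meta$reference, stringsAsFactors = FALSE),
     "ReactionList.tsv")
  wr(data.frame(UID = kb$contingencies$uid, Target = kb$contingencies$target,
                Contingency = kb$contingencies$kind,
                Modifier = kb$contingencies$modifier,
                Reference = kb$contingencies$reference,
                stringsAsFactors = FALSE),
     "ContingencyList.tsv")
  wr(data.frame(Type = kb$registry$type, Class = kb$registry$class,
                SourcePattern = kb$registry$source,
                ProductPattern = kb$registry$product, stringsAsFactors = FALSE),
     "ReactionTypes.tsv")
  invisible(dir)
}

# structural equality (used by round-trip tests)
kb_equal <- function(a, b) {
  norm <- function(d) { rownames(d) <- NULL; d }
  identical(sort(names(a$reactions)), sort(names(b$reactions))) &&
    identical(norm(a$contingencies[c("uid", "target", "kind", "modifier")]),
              norm(b$contingencies[c("uid", "target", "kind", "modifier")])) &&
    identical(lapply(a$gates[order(names(a$gates))], `[`, c("op", "members")),
              lapply(b$gates[order(names(b$gates))], `[`, c("op", "members"))) &&
    identical(a$registry, b$registry)
}

gate_cycles <- function(kb) {
  # names of gates participating in a reference cycle
  bad <- character(0)
  for (start in names(kb$gates)) {
    stack <- list(list(name = start, path = character(0)))
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$name %in% cur$path) { bad <- c(bad, start); break }
      g <- kb$gates[[cur$name]]
      if (is.null(g)) next
      refs <- g$members[grepl("^<.+>$", g$members)]
      for (m in refs) {
        stack[[length(stack) + 1L]] <-
          list(name = sub("^<(.+)>$", "\\1", m), path = c(cur$path, cur$name))
      }
    }
  }
  unique(bad)
}

#' Validate a knowledge base
#'
#' Collects errors (dangling contingency targets, gate cycles, unknown
#' reaction types, gate-definition kinds on non-gate targets, duplicate
#' UIDs) and warnings (contingency states never produced by any reaction
#' and not neutral, consumed states without a producer, outputs without a
#' defining contingency, components never appearing in a reaction) into a
#' report. An empty error list means the knowledge base is accepted for
#' compilation.
#'
#' @param kb An `rxn_kb` object.
#' @return An object of class `kb_validation` with a data.frame `issues`
#'   (`severity`, `code`, `message`, `uid`).
#' @export
validate_knowledge_base <- function(kb) {
  stopifnot(inherits(kb, "rxn_kb"))
  issues <- list()
  add <- function(severity, code, message, uid = NA_integer_) {
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, code = code, message = message,
      uid = as.integer(uid), stringsAsFactors = FALSE)
  }

  if (anyDuplicated(kb$contingencies$uid)) {
    for (u in unique(kb$contingencies$uid[duplicated(kb$contingencies$uid)])) {
      add("error", "duplicate-uid", sprintf("duplicate contingency UID %d", u), u)
    }
  }

  for (r in kb$reactions) {
    if (!r$rtype %in% kb$registry$type) {
      add("error", "unknown-rtype",
          sprintf("reaction '%s' uses unregistered type '%s'", r$text, r$rtype))
    }
  }

  rows <- kb_constraints(kb)
  for (i in seq_len(nrow(rows))) {
    tg <- rows$target[i]
    if (grepl("^\\[.+\\]$", tg)) next
    if (grepl("^<.+>$", tg)) {
      nm <- sub("^<(.+)>$", "\\1", tg)
      if (is.null(kb$gates[[nm]])) {
        add("error", "dangling-target",
            sprintf("contingency targets undefined gate <%s>", nm), rows$uid[i])
      }
      next
    }
    if (!tg %in% names(kb$reactions)) {
      add("error", "dangling-target",
          sprintf("contingency targets unknown reaction '%s'", tg), rows$uid[i])
    }
  }
  gd <- kb$contingencies[kb$contingencies$kind %in% c("AND", "OR", "NOT"), ,
                         drop = FALSE]
  for (i in seq_len(nrow(gd))) {
    if (!grepl("^<.+>$", gd$target[i])) {
      add("error", "gate-def-target",
          sprintf("kind %s on non-gate target '%s'", gd$kind[i], gd$target[i]),
          gd$uid[i])
    }
  }
  for (nm in gate_cycles(kb)) {
    add("error", "gate-cycle", sprintf("gate <%s> participates in a cycle", nm))
  }
  # gate members must resolve
  for (g in kb$gates) {
    refs <- g$members[grepl("^<.+>$", g$members)]
    for (m in refs) {
      rn <- sub("^<(.+)>$", "\\1", m)
      if (is.null(kb$gates[[rn]])) {
        add("error", "dangling-target",
            sprintf("gate <%s> references undefined gate <%s>", g$name, rn))
      }
    }
  }

  produced <- unique(unlist(lapply(kb$reactions, `[[`, "produced")))
  modifiers <- registry_modifiers(kb$registry)
  is_neutral_key <- function(key) {
    s <- try(parse_state(key, modifiers), silent = TRUE)
    !inherits(s, "try-error") && inherits(s, "elemental_state") &&
      is_neutral_state(s)
  }
  for (key in kb_modifier_state_keys(kb)) {
    ok <- key %in% produced || is_neutral_key(key)
    if (!ok) {
      add("warning", "nonproducible-state",
          sprintf("contingency state '%s' is never produced and is not neutral",
                  key))
    }
  }
  consumed <- unique(unlist(lapply(kb$reactions, `[[`, "consumed")))
  for (key in setdiff(consumed, produced)) {
    if (!is_neutral_key(key)) {
      add("warning", "nonproducible-state",
          sprintf("consumed state '%s' has no producing reaction", key))
    }
  }
  for (o in kb$outputs) {
    if (!any(rows$target == sprintf("[%s]", o))) {
      add("warning", "orphan-output",
          sprintf("output [%s] has no defining contingency", o))
    }
  }
  in_reactions <- unique(unlist(lapply(kb$reactions, function(r) {
    c(r$components, r$synthesises, r$degrades)
  })))
  in_reactions <- in_reactions[!is.na(in_reactions)]
  for (comp in setdiff(names(kb$components), in_reactions)) {
    add("warning", "unused-component",
        sprintf("component '%s' appears in no reaction", comp))
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), code = character(0),
               message = character(0), uid = integer(0),
               stringsAsFactors = FALSE)
  structure(list(issues = issues), class = "kb_validation")
}

#' @export
print.kb_validation <- function(x, ...) {
  ne <- sum(x$issues$severity == "error")
  nw <- sum(x$issues$severity == "warning")
  cat(sprintf("<kb_validation: %d error(s), %d warning(s)>\n", ne, nw))
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues))) {
      cat(sprintf("  %s [%s] %s\n", x$issues$severity[i], x$issues$code[i],
                  x$issues$message[i]))
    }
  }
  invisible(x)
}

#' Does a validation report accept the knowledge base?
#'
#' @param report A `kb_validation` object.
#' @return `TRUE` when the report contains no errors.
#' @export
kb_accepted <- function(report) {
  stopifnot(inherits(report, "kb_validation"))
  !any(report$issues$severity == "error")
}
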