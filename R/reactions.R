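#' Default reaction-type registry
#'
#' Reaction types are data, not code: each row declares a type name, its
#' class (`state-change`, `synthesis` or `degradation`) and, for
#' state-change types, the source and product pattern applied at the
#' subjects' loci. Patterns are either residue-modifier tokens
#' (`-{0}`, `-{P}`, ...) or the bond tokens `free`/`bond`.
#'
#' The shipped registry: `P+`/`P-` (de)phosphorylation, `ub48+` and
#' `ub63+`/`ub63-` (de)polyubiquitylation, `cut` proteolytic truncation,
#' `ppi+`/`ppi-` bond formation/dissociation, `i` lipid binding (an alias
#' of `ppi+`), `trsc`/`trsl` transcription and translation, `deg`
#' degradation, and the nucleotide cycle `aBind` (empty to ATP), `aHy`
#' (ATP to ADP) and `aEx` (ADP to ATP).
#'
#' @return A data.frame with columns `type`, `class`, `source`, `product`.
#' @export
reaction_type_registry <- function() {
  rt <- function(type, class, source, product) {
    data.frame(type = type, class = class, source = source,
               product = product, stringsAsFactors = FALSE)
  }
  rbind(
    rt("P+",    "state-change", "-{0}",    "-{P}"),
    rt("P-",    "state-change", "-{P}",    "-{0}"),
    rt("ub48+", "state-change", "-{0}",    "-{ub48}"),
    rt("ub63+", "state-change", "-{0}",    "-{ub63}"),
    rt("ub63-", "state-change", "-{ub63}", "-{0}"),
    rt("cut",   "state-change", "-{0}",    "-{truncated}"),
    rt("ppi+",  "state-change", "free",    "bond"),
    rt("ppi-",  "state-change", "bond",    "free"),
    rt("i",     "state-change", "free",    "bond"),
    rt("aBind", "state-change", "-{0}",    "-{ATP}"),
    rt("aHy",   "state-change", "-{ATP}",  "-{ADP}"),
    rt("aEx",   "state-change", "-{ADP}",  "-{ATP}"),
    rt("trsc",  "synthesis",    "",        "mRNA"),
    rt("trsl",  "synthesis",    "",        ""),
    rt("deg",   "degradation",  "",        "")
  )
}

#' Read a reaction-type registry from a TSV file
#'
#' Expected columns: `Type`, `Class`, `SourcePattern`, `ProductPattern`.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A registry data.frame as for [reaction_type_registry()].
#' @export
read_reaction_types <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df) <- sub("^X\\.", "", names(df))  # stripped "!Type" headers
  need <- c("Type", "Class", "SourcePattern", "ProductPattern")
  if (!all(need %in% names(df))) {
    stop("registry file must have columns Type, Class, SourcePattern, ProductPattern",
         call. = FALSE)
  }
  data.frame(type = df$Type, class = df$Class,
             source = df$SourcePattern, product = df$ProductPattern,
             stringsAsFactors = FALSE)
}

registry_modifiers <- function(registry) {
  toks <- unlist(regmatches(c(registry$source, registry$product),
                            gregexpr("(?<=-\\{)[^{}]+(?=\\})",
                                     c(registry$source, registry$product),
                                     perl = TRUE)))
  unique(c("0", toks))
}

mod_token <- function(pattern) sub("^-\\{(.+)\\}$", "\\1", pattern)

#' Parse an elemental reaction string
#'
#' A reaction string has the form `A[_locus]_type_B[_locus]`, with `_` as
#' the field separator (component names therefore contain no underscore).
#' The consumed and produced elemental-state sets are derived from the
#' type's effect pattern instantiated at the subjects' loci: e.g.
#' `AKT_P+_NLRP3_[(S5)]` consumes `NLRP3_[(S5)]-{0}` and produces
#' `NLRP3_[(S5)]-{P}`, while `ppi+` consumes the two free domains and
#' produces the bond. For `trsc` the synthesised component is the target
#' name suffixed `mRNA`; for `trsl` it is the target itself (its neutral
#' states are attached when the knowledge base is assembled, since they
#' depend on the component's full locus inventory). Translation acts on
#' the target's transcript, so the `mRNA` component is a participant.
#'
#' @param text Reaction string.
#' @param registry Reaction-type registry (see [reaction_type_registry()]).
#' @return An object of class `elemental_reaction` with fields `text`
#'   (canonical string), `subjectA`, `rtype`, `subjectB`, `consumed`,
#'   `produced` (canonical state keys), `components`, and for
#'   synthesis/degradation types `synthesises`/`degrades`.
#' @export
parse_reaction <- function(text, registry = reaction_type_registry()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  toks <- strsplit(text, "_", fixed = TRUE)[[1]]
  if (length(toks) < 3L) {
    stop(sprintf("cannot parse reaction '%s'", text), call. = FALSE)
  }
  is_locus_tok <- grepl("^\\[.*\\]$", toks)
  if (is_locus_tok[1]) {
    stop(sprintf("reaction '%s' must start with a component name", text),
         call. = FALSE)
  }
  ia <- if (length(toks) >= 2L && is_locus_tok[2]) 2L else 1L
  itype <- ia + 1L
  if (itype > length(toks)) {
    stop(sprintf("cannot parse reaction '%s'", text), call. = FALSE)
  }
  rtype <- toks[itype]
  row <- registry[registry$type == rtype, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown reaction type '%s' in '%s'", rtype, text),
         call. = FALSE)
  }
  ib <- itype + 1L
  if (ib > length(toks) || is_locus_tok[ib]) {
    stop(sprintf("reaction '%s' lacks a second subject", text), call. = FALSE)
  }
  extra <- if (ib < length(toks)) (ib + 1L):length(toks) else integer(0)
  if (length(extra) > 1L || (length(extra) == 1L && !is_locus_tok[extra])) {
    stop(sprintf("trailing fields in reaction '%s'", text), call. = FALSE)
  }

  compA <- toks[1]
  check_token(compA, sprintf("component name in '%s'", text))
  locA <- if (ia == 2L) parse_locus_token(toks[2], text) else NULL
  compB <- toks[ib]
  check_token(compB, sprintf("component name in '%s'", text))
  locB <- if (length(extra) == 1L) parse_locus_token(toks[extra], text) else NULL

  cls <- row$class
  consumed <- produced <- list()
  components <- unique(c(compA, compB))
  synthesises <- degrades <- NA_character_

  if (cls == "state-change") {
    if (identical(row$source, "free") || identical(row$source, "bond")) {
      if (is.null(locA) || locA$kind != "domain" ||
          is.null(locB) || locB$kind != "domain") {
        stop(sprintf("'%s' requires both subjects at domain resolution in '%s'",
                     rtype, text), call. = FALSE)
      }
      bond <- new_bond_state(compA, locA, compB, locB)
      frees <- neutral_partners(bond)
      if (identical(row$source, "free")) {
        consumed <- frees; produced <- list(bond)
      } else {
        consumed <- list(bond); produced <- frees
      }
    } else {
      if (is.null(locB) || locB$kind != "residue") {
        stop(sprintf("'%s' requires the target at residue resolution in '%s'",
                     rtype, text), call. = FALSE)
      }
      consumed <- list(new_modification_state(compB, locB, mod_token(row$source)))
      produced <- list(new_modification_state(compB, locB, mod_token(row$product)))
    }
  } else if (cls == "synthesis") {
    if (!is.null(locB)) {
      stop(sprintf("synthesis target must be a bare component in '%s'", text),
           call. = FALSE)
    }
    if (identical(row$product, "mRNA")) {
      synthesises <- paste0(compB, "mRNA")
      components <- unique(compA)
    } else {
      synthesises <- compB
      # translation consumes nothing; it acts on the transcript
      components <- unique(c(compA, paste0(compB, "mRNA")))
    }
  } else if (cls == "degradation") {
    if (!is.null(locB)) {
      stop(sprintf("degradation target must be a bare component in '%s'", text),
           call. = FALSE)
    }
    degrades <- compB
  } else {
    stop(sprintf("unknown reaction class '%s'", cls), call. = FALSE)
  }

  ckeys <- vapply(consumed, render_state, character(1))
  pkeys <- vapply(produced, render_state, character(1))
  if (length(intersect(ckeys, pkeys))) {
    stop(sprintf("consumed and produced states overlap in '%s'", text),
         call. = FALSE)
  }

  canon <- paste0(
    compA, if (!is.null(locA)) format(locA) else "",
    "_", rtype, "_",
    compB, if (!is.null(locB)) format(locB) else ""
  )

  structure(
    list(text = canon,
         subjectA = list(component = compA, locus = locA),
         rtype = rtype, rclass = cls,
         subjectB = list(component = compB, locus = locB),
         consumed = ckeys, produced = pkeys,
         consumed_states = consumed, produced_states = produced,
         components = components,
         synthesises = synthesises, degrades = degrades),
    class = "elemental_reaction"
  )
}

#' @export
format.elemental_reaction <- function(x, ...) x$text

#' @export
print.elemental_reaction <- function(x, ...) {
  cat(sprintf("<elemental_reaction %s (%s)>\n", x$text, x$rclass))
  if (length(x$consumed)) cat("  consumes:", paste(x$consumed, collapse = ", "), "\n")
  if (length(x$produced)) cat("  produces:", paste(x$produced, collapse = ", "), "\n")
  if (!is.na(x$synthesises)) cat("  synthesises:", x$synthesises, "\n")
  if (!is.na(x$degrades)) cat("  degrades:", x$degrades, "\n")
  invisible(x)
}
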