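#' @title Elemental states and loci
#' @description
#' An elemental state is a site-specific fact about one or two components:
#' a modification at a residue (`NLRP3_[(S5)]-{P}`), a bond between two
#' domains (`NEK7_[clobe]--NLRP3_[HD2LRR]`), or a free domain
#' (`NLRP3_[HD2LRR]--0`). States are the atoms of both the knowledge base
#' and the compiled Boolean model; a state says nothing about any other
#' site of the same molecule.
#' @name elemental-states
NULL

#' Construct a locus
#'
#' A locus names a site on a component: either an interaction domain
#' (rendered `_[name]`) or a modification residue (rendered `_[(name)]`).
#'
#' @param name Site name; non-empty, no brackets or whitespace.
#' @param kind `"domain"` or `"residue"`.
#' @return An object of class `locus` with fields `kind` and `name`.
#' @export
locus <- function(name, kind = c("domain", "residue")) {
  kind <- match.arg(kind)
  check_token(name, "locus name")
  structure(list(kind = kind, name = name), class = "locus")
}

#' @export
format.locus <- function(x, ...) {
  if (x$kind == "residue") sprintf("_[(%s)]", x$name) else sprintf("_[%s]", x$name)
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus %s %s>\n", x$kind, x$name))
  invisible(x)
}

check_token <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x) ||
      grepl("[][(){}<>[:space:]]", x)) {
    stop(sprintf("invalid %s: '%s'", what,
                 paste(as.character(x), collapse = ",")), call. = FALSE)
  }
  invisible(x)
}

#' Default modifier registry
#'
#' Modifier tokens that may decorate a residue, including the neutral
#' marker `0`. The set mirrors the chemistry used by the reaction-type
#' registry: phosphate, K48-/K63-linked polyubiquitin, proteolytic
#' truncation and nucleotide occupancy.
#'
#' @return Character vector of modifier tokens.
#' @export
rxn_modifiers <- function() {
  c("0", "P", "ub48", "ub63", "truncated", "ATP", "ADP")
}

new_modification_state <- function(component, residue, modifier) {
  structure(
    list(component = component, residue = residue, modifier = modifier),
    class = c("modification_state", "elemental_state")
  )
}

new_bond_state <- function(compA, domA, compB, domB) {
  # canonical ordering: lexicographic on "component_[domain]"
  keyA <- sprintf("%s_[%s]", compA, domA$name)
  keyB <- sprintf("%s_[%s]", compB, domB$name)
  if (keyA > keyB) {
    tmp <- list(compA, domA); compA <- compB; domA <- domB
    compB <- tmp[[1]]; domB <- tmp[[2]]
  }
  structure(
    list(endpointA = list(component = compA, domain = domA),
         endpointB = list(component = compB, domain = domB)),
    class = c("bond_state", "elemental_state")
  )
}

new_free_state <- function(component, domain) {
  structure(list(component = component, domain = domain),
            class = c("free_state", "elemental_state"))
}

new_input_ref <- function(name) {
  check_token(name, "input/output name")
  structure(list(name = name), class = "input_ref")
}

new_gate_ref <- function(name) {
  check_token(name, "gate name")
  structure(list(name = name), class = "gate_ref")
}

parse_locus_token <- function(tok, text) {
  name <- if (grepl("^\\[\\(.+\\)\\]$", tok)) {
    list(sub("^\\[\\((.+)\\)\\]$", "\\1", tok), "residue")
  } else if (grepl("^\\[.+\\]$", tok)) {
    list(sub("^\\[(.+)\\]$", "\\1", tok), "domain")
  } else {
    NULL
  }
  if (is.null(name) || grepl("[][(){}<>[:space:]]", name[[1]])) {
    stop(sprintf("malformed locus '%s' in '%s'", tok, text), call. = FALSE)
  }
  locus(name[[1]], name[[2]])
}

split_component_locus <- function(txt, text) {
  # "Comp_[dom]" / "Comp_[(res)]" / bare "Comp"
  m <- regmatches(txt, regexec("^([^_]+)_(\\[.*\\])$", txt))[[1]]
  if (length(m) == 3L) {
    check_token(m[2], sprintf("component name in '%s'", text))
    list(component = m[2], locus = parse_locus_token(m[3], text))
  } else {
    check_token(txt, sprintf("component name in '%s'", text))
    list(component = txt, locus = NULL)
  }
}

#' Parse an elemental state, input or gate reference
#'
#' Understands the four state syntaxes (`Comp_[(res)]-{mod}` modification,
#' `A_[x]--B_[y]` bond, `A_[x]--0` free domain) plus bracketed system
#' boundary names (`[Input]`) and angle-bracketed gate references
#' (`<Gate>`). Bond states are canonicalised so that
#' `parse_state("A_[x]--B_[y]")` and `parse_state("B_[y]--A_[x]")` are
#' identical.
#'
#' @param text State string.
#' @param modifiers Allowed modifier tokens (see [rxn_modifiers()]).
#' @return An `elemental_state`, `input_ref` or `gate_ref` object.
#' @examples
#' parse_state("NLRP3_[(S5)]-{P}")
#' parse_state("NEK7_[clobe]--NLRP3_[HD2LRR]")
#' @export
parse_state <- function(text, modifiers = rxn_modifiers()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty state string", call. = FALSE)

  if (grepl("^\\[.+\\]$", text)) {
    return(new_input_ref(sub("^\\[(.+)\\]$", "\\1", text)))
  }
  if (grepl("^<.+>$", text)) {
    return(new_gate_ref(sub("^<(.+)>$", "\\1", text)))
  }
  if (grepl("--", text, fixed = TRUE)) {
    parts <- strsplit(text, "--", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop(sprintf("malformed bond state '%s'", text), call. = FALSE)
    }
    a <- split_component_locus(parts[1], text)
    if (is.null(a$locus) || a$locus$kind != "domain") {
      stop(sprintf("bond endpoint must be at domain resolution in '%s'", text),
           call. = FALSE)
    }
    if (identical(parts[2], "0")) {
      return(new_free_state(a$component, a$locus))
    }
    b <- split_component_locus(parts[2], text)
    if (is.null(b$locus) || b$locus$kind != "domain") {
      stop(sprintf("bond endpoint must be at domain resolution in '%s'", text),
           call. = FALSE)
    }
    return(new_bond_state(a$component, a$locus, b$component, b$locus))
  }
  m <- regmatches(text, regexec("^(.+)-\\{([^{}]*)\\}$", text))[[1]]
  if (length(m) == 3L) {
    sub <- split_component_locus(m[2], text)
    if (is.null(sub$locus) || sub$locus$kind != "residue") {
      stop(sprintf("modification requires residue resolution in '%s'", text),
           call. = FALSE)
    }
    if (!m[3] %in% modifiers) {
      stop(sprintf("unknown modifier '{%s}' in '%s'", m[3], text), call. = FALSE)
    }
    return(new_modification_state(sub$component, sub$locus, m[3]))
  }
  stop(sprintf("cannot parse state '%s'", text), call. = FALSE)
}

#' Render a state, input or gate reference to its canonical string
#'
#' Inverse of [parse_state()]: `render_state(parse_state(s))` equals the
#' canonical form of `s`.
#'
#' @param x Object from [parse_state()].
#' @return Canonical string.
#' @export
render_state <- function(x) {
  if (inherits(x, "modification_state")) {
    sprintf("%s%s-{%s}", x$component, format(x$residue), x$modifier)
  } else if (inherits(x, "bond_state")) {
    sprintf("%s_[%s]--%s_[%s]",
            x$endpointA$component, x$endpointA$domain$name,
            x$endpointB$component, x$endpointB$domain$name)
  } else if (inherits(x, "free_state")) {
    sprintf("%s_[%s]--0", x$component, x$domain$name)
  } else if (inherits(x, "input_ref")) {
    sprintf("[%s]", x$name)
  } else if (inherits(x, "gate_ref")) {
    sprintf("<%s>", x$name)
  } else {
    stop("not a state, input or gate reference", call. = FALSE)
  }
}

#' @export
format.elemental_state <- function(x, ...) render_state(x)

#' @export
print.elemental_state <- function(x, ...) {
  cat(sprintf("<%s %s>\n", class(x)[1], render_state(x)))
  invisible(x)
}

#' @export
print.input_ref <- function(x, ...) {
  cat(sprintf("<input/output ref %s>\n", render_state(x)))
  invisible(x)
}

#' @export
print.gate_ref <- function(x, ...) {
  cat(sprintf("<gate ref %s>\n", render_state(x)))
  invisible(x)
}

#' Is a state neutral?
#'
#' Neutral states are the unperturbed partners: a residue carrying
#' modifier `0`, or a free (unbound) domain.
#'
#' @param x An elemental state object.
#' @return Logical scalar.
#' @export
is_neutral_state <- function(x) {
  (inherits(x, "modification_state") && identical(x$modifier, "0")) ||
    inherits(x, "free_state")
}

#' Components referenced by a state
#'
#' @param x Elemental state object.
#' @return Character vector of component names (length 1 or 2, unique).
#' @export
state_components <- function(x) {
  if (inherits(x, "bond_state")) {
    unique(c(x$endpointA$component, x$endpointB$component))
  } else if (inherits(x, "elemental_state")) {
    x$component
  } else {
    character(0)
  }
}

#' Neutral partner state(s)
#'
#' Every non-neutral state has one or two neutral partners: a modified
#' residue has the `-{0}` state of the same residue; a bond has the free
#' state of each endpoint. Neutral states are their own partners.
#'
#' @param x Elemental state object.
#' @return List of elemental state objects.
#' @export
neutral_partners <- function(x) {
  if (inherits(x, "modification_state")) {
    list(new_modification_state(x$component, x$residue, "0"))
  } else if (inherits(x, "bond_state")) {
    fs <- list(new_free_state(x$endpointA$component, x$endpointA$domain),
               new_free_state(x$endpointB$component, x$endpointB$domain))
    keys <- vapply(fs, render_state, character(1))
    fs[!duplicated(keys)]
  } else if (inherits(x, "free_state")) {
    list(x)
  } else {
    list()
  }
}
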