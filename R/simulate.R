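#' @title Synchronous simulation
#' @description
#' The bipartite Boolean model is simulated with a synchronous update:
#' every non-clamped node takes its rule's value evaluated on the
#' previous assignment, clamped inputs hold their clamp value. Attractors
#' are detected by hashing visited assignments and returning on the first
#' revisit.
#' @name bool-simulation
NULL

is_neutral_key <- function(key) {
  endsWith(key, "-{0}") | endsWith(key, "--0")
}

#' Build an initial assignment for a model
#'
#' Two artificial starting points are supported for off-state discovery:
#' `"neutral"` (components present, neutral states TRUE, everything else
#' FALSE; reactions take their rule's value at the first step) and
#' `"all-on"` (everything TRUE except inputs). `"all-off"` is provided
#' for degenerate tests.
#'
#' @param model A `boolean_model`.
#' @param start One of `"neutral"`, `"all-on"`, `"all-off"`.
#' @return Named logical vector over the model's nodes.
#' @export
initial_assignment <- function(model, start = c("neutral", "all-on", "all-off")) {
  start <- match.arg(start)
  nodes <- model$nodes
  v <- switch(start,
              "all-on" = nodes$kind != "input",
              "all-off" = rep(FALSE, nrow(nodes)),
              "neutral" = ifelse(
                nodes$kind == "state", is_neutral_key(nodes$key),
                nodes$kind == "component"))
  stats::setNames(as.logical(v), nodes$key)
}

check_clamps <- function(model, clamps) {
  if (is.null(clamps)) return(stats::setNames(logical(0), character(0)))
  stopifnot(is.logical(clamps), !is.null(names(clamps)))
  bad <- setdiff(names(clamps), model$clampable)
  if (length(bad)) {
    stop(sprintf("cannot clamp non-input node(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  clamps
}

#' Perform one synchronous update step
#'
#' @param model A `boolean_model`.
#' @param assignment Named logical vector over all nodes.
#' @param clamps Optional named logical vector over input nodes; clamped
#'   inputs take the clamp value instead of their rule's.
#' @return The next assignment (named logical vector).
#' @export
sim_step <- function(model, assignment, clamps = NULL) {
  clamps <- check_clamps(model, clamps)
  stopifnot(length(assignment) == nrow(model$nodes))
  v <- model$step_fun(as.logical(assignment))
  if (length(clamps)) {
    v[match(names(clamps), model$nodes$key)] <- unname(clamps)
  }
  stats::setNames(v, model$nodes$key)
}

#' Simulate synchronously until an attractor is reached
#'
#' Iterates from `initial`, hashing visited assignments, and returns on
#' the first revisit. A revisit of the immediately preceding assignment
#' is a point attractor; otherwise the cycle length is the distance
#' between the two visits.
#'
#' @param model A `boolean_model`.
#' @param initial Named logical assignment (clamp values are imposed on
#'   it before the first step).
#' @param clamps Optional named logical vector over input nodes.
#' @param max_steps Maximum number of steps before giving up (an error of
#'   class `boolkit_nonconvergence`, carrying the trajectory so far, is
#'   raised).
#' @return A list with `trajectory` (a `bool_trajectory`: logical matrix,
#'   nodes x time, columns labelled by step) and `attractor` (class
#'   `bool_attractor`: `kind` `"point"`/`"cycle"`, `states` matrix,
#'   `entry_step`).
#' @export
simulate_to_attractor <- function(model, initial, clamps = NULL,
                                  max_steps = 500L) {
  stopifnot(max_steps >= 1L)
  clamps <- check_clamps(model, clamps)
  cur <- initial
  if (length(clamps)) cur[names(clamps)] <- unname(clamps)

  seen <- new.env(parent = emptyenv(), hash = TRUE)
  states <- list(cur)
  assign(paste(as.integer(cur), collapse = ""), 1L, envir = seen)
  for (step in seq_len(max_steps)) {
    nxt <- sim_step(model, cur, clamps)
    h <- paste(as.integer(nxt), collapse = "")
    prev <- seen[[h]]
    if (!is.null(prev)) {
      traj <- do.call(cbind, states)
      dimnames(traj) <- list(model$nodes$key, seq_len(ncol(traj)) - 1L)
      traj <- structure(traj, clamps = clamps, class = "bool_trajectory")
      att_states <- traj[, prev:ncol(traj), drop = FALSE]
      attractor <- structure(
        list(kind = if (ncol(att_states) == 1L) "point" else "cycle",
             states = att_states, entry_step = prev - 1L),
        class = "bool_attractor")
      return(list(trajectory = traj, attractor = attractor))
    }
    states[[length(states) + 1L]] <- nxt
    assign(h, length(states), envir = seen)
    cur <- nxt
  }
  traj <- do.call(cbind, states)
  dimnames(traj) <- list(model$nodes$key, seq_len(ncol(traj)) - 1L)
  cond <- structure(
    class = c("boolkit_nonconvergence", "error", "condition"),
    list(message = sprintf("no attractor within %d steps", max_steps),
         call = sys.call(-1), trajectory = traj))
  stop(cond)
}

#' @export
print.bool_trajectory <- function(x, ...) {
  cat(sprintf("<bool_trajectory: %d nodes x %d steps>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' @export
print.bool_attractor <- function(x, ...) {
  cat(sprintf("<bool_attractor: %s (%d state(s)), entered at step %d>\n",
              x$kind, ncol(x$states), x$entry_step))
  invisible(x)
}

#' Find the natural off state of a model
#'
#' Simulates from an artificial initial assignment with all inputs FALSE
#' until a point attractor is reached; that fixed point is the baseline
#' from which every treatment scenario starts. The canonical artificial
#' start is the `"neutral"` assignment (see [initial_assignment()] and
#' the methods vignette for why `"all-on"` does not relax networks with
#' irreversibly produced states).
#'
#' @param model A `boolean_model`.
#' @param start Artificial start, `"neutral"` (default) or `"all-on"`.
#' @param max_steps Step budget for the relaxation.
#' @return The off state as a named logical assignment.
#' @export
natural_off_state <- function(model, start = c("neutral", "all-on"),
                              max_steps = 500L) {
  start <- match.arg(start)
  res <- simulate_to_attractor(model, initial_assignment(model, start),
                               clamps = NULL, max_steps = max_steps)
  if (res$attractor$kind != "point") {
    cond <- structure(
      class = c("boolkit_cyclic_off_state", "error", "condition"),
      list(message = "relaxation from the artificial start reached a cyclic attractor, not a point off state",
           call = sys.call(-1), attractor = res$attractor))
    stop(cond)
  }
  res$attractor$states[, 1]
}

#' Define a clamped-input scenario
#'
#' @param name Scenario label.
#' @param inputs Character vector of input names to clamp TRUE (without
#'   brackets).
#' @param variants Character vector of model-variant flags applied to the
#'   knowledge base before compilation (see [apply_variant()]).
#' @param max_steps Step budget.
#' @return An object of class `bool_scenario`.
#' @export
scenario <- function(name, inputs = character(0), variants = character(0),
                     max_steps = 500L) {
  stopifnot(is.character(name), length(name) == 1L)
  structure(list(name = name, inputs = as.character(inputs),
                 variants = as.character(variants),
                 max_steps = as.integer(max_steps)),
            class = "bool_scenario")
}

#' Read a scenario definition from a YAML file
#'
#' Recognised keys: `name`, `inputs` (list), `variants` (list),
#' `max_steps`.
#'
#' @param path Path to a YAML file.
#' @return A `bool_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  scenario(name = y$name %||% tools::file_path_sans_ext(basename(path)),
           inputs = unlist(y$inputs) %||% character(0),
           variants = unlist(y$variants) %||% character(0),
           max_steps = y$max_steps %||% 500L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.bool_scenario <- function(x, ...) {
  cat(sprintf("<bool_scenario %s: inputs {%s}%s>\n", x$name,
              paste(x$inputs, collapse = ", "),
              if (length(x$variants))
                sprintf(", variants {%s}", paste(x$variants, collapse = ", "))
              else ""))
  invisible(x)
}

#' Run a clamped-input scenario from the natural off state
#'
#' Applies the scenario's variant flags to the knowledge base, compiles
#' it, finds the natural off state, clamps the scenario inputs TRUE,
#' simulates to the attractor and classifies every output node as `ON`
#' (TRUE in every attractor state), `OFF` (FALSE in every) or
#' `OSCILLATING`.
#'
#' @param kb An `rxn_kb` object.
#' @param scn A `bool_scenario`.
#' @param model Optional precompiled model for `kb` (only used when the
#'   scenario carries no variant flags).
#' @param off_state Optional precomputed off state for `model`.
#' @return An object of class `scenario_result` with fields `scenario`,
#'   `off_state`, `trajectory`, `attractor`, `readouts`.
#' @export
run_scenario <- function(kb, scn, model = NULL, off_state = NULL) {
  stopifnot(inherits(kb, "rxn_kb"), inherits(scn, "bool_scenario"))
  if (length(scn$variants)) {
    kb <- apply_variant(kb, scn$variants)
    model <- NULL
    off_state <- NULL
  }
  if (is.null(model)) model <- build_update_rules(kb)
  if (is.null(off_state)) off_state <- natural_off_state(model)

  keys <- sprintf("[%s]", scn$inputs)
  missing <- setdiff(keys, model$clampable)
  if (length(missing)) {
    stop(sprintf("scenario '%s' clamps unknown input(s): %s", scn$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  clamps <- stats::setNames(rep(TRUE, length(keys)), keys)
  res <- simulate_to_attractor(model, off_state, clamps,
                               max_steps = scn$max_steps)

  out_keys <- model$nodes$key[model$nodes$kind == "output"]
  readouts <- vapply(out_keys, function(k) {
    vals <- res$attractor$states[k, ]
    if (all(vals)) "ON" else if (!any(vals)) "OFF" else "OSCILLATING"
  }, character(1))

  structure(
    list(scenario = scn, off_state = off_state, trajectory = res$trajectory,
         attractor = res$attractor, readouts = readouts,
         model = model),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result %s: %s attractor, %d step trajectory>\n",
              x$scenario$name, x$attractor$kind, ncol(x$trajectory)))
  on <- names(x$readouts)[x$readouts == "ON"]
  osc <- names(x$readouts)[x$readouts == "OSCILLATING"]
  cat("  outputs ON:", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
  if (length(osc)) cat("  oscillating:", paste(osc, collapse = ", "), "\n")
  invisible(x)
}

#' Attractor value of a node in a scenario result
#'
#' @param result A `scenario_result`.
#' @param key Node key.
#' @return `"ON"`, `"OFF"` or `"OSCILLATING"`.
#' @export
attractor_value <- function(result, key) {
  stopifnot(inherits(result, "scenario_result"))
  if (!key %in% rownames(result$attractor$states)) {
    stop(sprintf("unknown node '%s'", key), call. = FALSE)
  }
  vals <- result$attractor$states[key, ]
  if (all(vals)) "ON" else if (!any(vals)) "OFF" else "OSCILLATING"
}

#' Write a scenario result as JSON
#'
#' Serialises the off-state hash (first 16 hex digits of the packed
#' assignment), the attractor kind and length, the clamped inputs and
#' the readout map.
#'
#' @param result A `scenario_result`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_scenario_result <- function(result, file) {
  stopifnot(inherits(result, "scenario_result"))
  bits <- paste(as.integer(result$off_state), collapse = "")
  hash <- sprintf("%08x", sum(utf8ToInt(bits) * seq_len(nchar(bits))) %% .Machine$integer.max)
  payload <- list(
    scenario = result$scenario$name,
    inputs = result$scenario$inputs,
    variants = result$scenario$variants,
    off_state_hash = hash,
    attractor = list(kind = result$attractor$kind,
                     length = ncol(result$attractor$states),
                     entry_step = result$attractor$entry_step),
    readouts = as.list(result$readouts)
  )
  jsonlite::write_json(payload, file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Step at which each node first becomes TRUE
#'
#' @param trajectory A `bool_trajectory` matrix.
#' @return Named integer vector; `NA` for nodes never TRUE. Step indices
#'   follow the trajectory's column labels (the initial assignment is
#'   step 0).
#' @export
first_true_step <- function(trajectory) {
  steps <- as.integer(colnames(trajectory))
  apply(trajectory, 1L, function(row) {
    i <- which(row)[1]
    if (is.na(i)) NA_integer_ else steps[i]
  })
}

#' Export a trajectory as a 0/1 matrix file
#'
#' Writes a CSV whose first column is the node key and whose remaining
#' columns are the 0/1 values per time step. With
#' `sort = "activation-order"` rows are ordered by the step at which they
#' first become TRUE (never-TRUE rows last, ties broken by declaration
#' order), mirroring the activation-sequence sorting of trajectory
#' heat maps.
#'
#' @param trajectory A `bool_trajectory` (or several column-bound
#'   trajectories).
#' @param file Output path.
#' @param sort `"activation-order"` or `"declaration-order"`.
#' @return The ordered integer matrix, invisibly.
#' @export
export_trajectory <- function(trajectory, file,
                              sort = c("activation-order",
                                       "declaration-order")) {
  sort <- match.arg(sort)
  stopifnot(ncol(trajectory) >= 1L)
  mat <- trajectory * 1L
  if (sort == "activation-order") {
    first <- first_true_step(trajectory)
    ord <- order(ifelse(is.na(first), Inf, first), seq_len(nrow(mat)))
    mat <- mat[ord, , drop = FALSE]
  }
  df <- data.frame(node = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("node", colnames(mat))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(mat)
}
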