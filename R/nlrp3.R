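#' @title The curated NLRP3 inflammasome network
#' @description
#' A reaction-contingency model of NLRP3 inflammasome priming
#' (NFkB-dependent transcription under Signal 1), posttranslational
#' licensing (Ser5/Ser198/Ser295/Ser806/Tyr861 phosphorylation and
#' LRR-domain K63 (de)ubiquitylation), triggering (a chain of
#' input/output placeholders connecting type I-III triggers to
#' centrosomal PI(4)P or exposed cardiolipin), assembly (NACHT
#' oligomerisation, PYD and CARD filaments, caspase-1 processing),
#' output (IL-1beta/IL-18 maturation and gasdermin D pores), the
#' non-canonical caspase-4/5 axis, and turnover (proteasomal and
#' autophagosomal degradation). Shipped as plain TSV tables installed
#' with the package.
#' @name nlrp3-network
NULL

#' Load the built-in NLRP3 inflammasome knowledge base
#'
#' @param path Directory holding the fixture tables; defaults to the
#'   copy installed with the package, which can be copied and edited.
#' @return An `rxn_kb` object (validates with zero errors).
#' @export
load_nlrp3_network <- function(path = system.file("extdata", "nlrp3",
                                                  package = "boolkit")) {
  if (!nzchar(path) || !dir.exists(path)) {
    stop("NLRP3 fixture directory not found", call. = FALSE)
  }
  load_knowledge_base(path)
}

#' Model-variant flags
#'
#' Variants patch specific rules of the knowledge base before
#' compilation:
#' \describe{
#'   \item{`mcc950-blocks-abind`}{MCC950 bound to the NOD additionally
#'     blocks ATP binding to the empty NBD (adds an inhibitory
#'     contingency on the `aBind` reaction); in the baseline rules
#'     MCC950 only blocks ADP-to-ATP exchange, which newly synthesised
#'     NLRP3 bypasses by binding ATP directly.}
#'   \item{`t346m-bypasses-centrosome`}{The open-conformation CAPS
#'     mutation T346M also lifts the centrosomal-localisation
#'     requirement on NEK7 binding (adds `[nlrp3T346M]` as a disjunct of
#'     the `<CentrosomalNLRP3>` gate), reflecting that a
#'     PI(4)P-binding-independent open conformation should not need
#'     PI(4)P transport.}
#' }
#'
#' @return Character vector of known flags.
#' @export
nlrp3_variants <- function() {
  c("mcc950-blocks-abind", "t346m-bypasses-centrosome")
}

#' Apply model-variant flags to a knowledge base
#'
#' @param kb An `rxn_kb` object.
#' @param flags Character vector of flags (see [nlrp3_variants()]).
#' @return The patched `rxn_kb`.
#' @export
apply_variant <- function(kb, flags) {
  stopifnot(inherits(kb, "rxn_kb"))
  for (flag in flags) {
    next_uid <- max(c(0L, kb$contingencies$uid)) + 1L
    if (flag == "mcc950-blocks-abind") {
      kb$contingencies <- rbind(kb$contingencies, data.frame(
        uid = next_uid, target = "NLRP3_aBind_NLRP3_[(NBD)]", kind = "x",
        modifier = "MCC950_[bd]--NLRP3_[NOD]",
        reference = "variant: MCC950 also blocks ATP binding",
        stringsAsFactors = FALSE))
    } else if (flag == "t346m-bypasses-centrosome") {
      if (is.null(kb$gates[["CentrosomalNLRP3"]])) {
        stop("knowledge base has no <CentrosomalNLRP3> gate", call. = FALSE)
      }
      kb$contingencies <- rbind(kb$contingencies, data.frame(
        uid = next_uid, target = "<CentrosomalNLRP3>", kind = "OR",
        modifier = "[nlrp3T346M]",
        reference = "variant: open conformation bypasses PI(4)P transport",
        stringsAsFactors = FALSE))
      kb$gates[["CentrosomalNLRP3"]]$members <-
        c(kb$gates[["CentrosomalNLRP3"]]$members, "[nlrp3T346M]")
    } else {
      stop(sprintf("unknown variant flag '%s'", flag), call. = FALSE)
    }
  }
  kb_finalise(kb)
}

#' The in-silico experiment catalogue
#'
#' Scenarios covering the baseline stimulus matrix (LPS and/or
#' nigericin), the Pam3csk4 + imiquimod combination, intracellular LPS
#' (non-canonical route), mitochondrial permeability transition (MMPT),
#' the MCC950/G5/okadaic-acid inhibitors, the CAPS mutations D305G and
#' T346M (with and without rule variants), the LRR-truncated miniNLRP3,
#' and potassium-efflux suppression by external KCl.
#'
#' @return Named list of [scenario()] objects.
#' @export
scenario_catalogue <- function() {
  sc <- list(
    scenario("S-none"),
    scenario("S-LPS", "LPS"),
    scenario("S-Nig", "Nigericin"),
    scenario("S-LPS+Nig", c("LPS", "Nigericin")),
    scenario("S-Pam+Imq", c("Pam3csk4", "Imiquimod")),
    scenario("S-extLPS", "LPS"),
    scenario("S-intLPS", "intLPS"),
    scenario("S-dualLPS", c("LPS", "intLPS")),
    scenario("S-MMPT", "MMPT"),
    scenario("S-LPS+MMPT", c("LPS", "MMPT")),
    scenario("S-MCC-A", c("LPS", "Nigericin", "MCC950")),
    scenario("S-MCC-B", c("LPS", "Nigericin", "MCC950"),
             variants = "mcc950-blocks-abind"),
    scenario("S-G5", c("LPS", "Nigericin", "G5")),
    scenario("S-OKA", c("LPS", "Nigericin", "OKA")),
    scenario("S-D305G", "nlrp3D305G"),
    scenario("S-LPS+D305G", c("LPS", "nlrp3D305G")),
    scenario("S-T346M-A", c("LPS", "nlrp3T346M")),
    scenario("S-T346M-B", c("LPS", "nlrp3T346M"),
             variants = "t346m-bypasses-centrosome"),
    scenario("S-mini-Nig", c("LPS", "Nigericin", "miniNLRP3")),
    scenario("S-mini-MMPT", c("LPS", "MMPT", "miniNLRP3")),
    scenario("S-extK-Nig", c("LPS", "Nigericin", "extK")),
    scenario("S-extK-Imq", c("LPS", "Imiquimod", "extK"))
  )
  stats::setNames(sc, vapply(sc, `[[`, character(1), "name"))
}

nlrp3_readout_nodes <- function() {
  c(speck = "ASC_[pydA]--NLRP3_[pydB]",
    casp1_active = "Caspase1_[(pro)]-{truncated}",
    il1b_release = "[IL1Brelease]",
    il18_release = "[IL18release]",
    pyroptosis = "[Pyroptosis]",
    bacterial_killing = "[BacterialKilling]")
}

#' Classify a scenario result into an activation call
#'
#' Readouts are taken from the attractor: `speck` is the ASC-NLRP3 PYD
#' bond, `casp1_active` the truncated caspase-1 state, and the release,
#' pyroptosis and bacterial-killing readouts are the corresponding
#' output nodes. The summary is `FULL_ACTIVATION` exactly when speck,
#' active caspase-1 and IL-1beta release are all ON; `PORE_ONLY` when
#' pyroptosis occurs without a speck (the non-canonical caspase-4/5
#' gasdermin D route, e.g. intracellular LPS without priming);
#' `PRIMED_ONLY`/`TRIGGERED_ONLY` flag the partial states of a nucleated
#' speck without cytokine release, and caspase-1 processing without a
#' speck, respectively (neither arises in the shipped catalogue);
#' otherwise `NO_ACTIVATION`. Oscillating readouts are surfaced as an
#' `OSCILLATING` summary, never coerced to ON or OFF.
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @return An object of class `activation_call` with the six logical
#'   readouts and a `summary` string.
#' @export
classify_outcome <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  nodes <- nlrp3_readout_nodes()
  vals <- vapply(nodes, function(k) attractor_value(result, k), character(1))
  if (any(vals == "OSCILLATING")) {
    call <- as.list(stats::setNames(rep(NA, length(nodes)), names(nodes)))
    call$summary <- "OSCILLATING"
  } else {
    on <- vals == "ON"
    call <- as.list(on)
    call$summary <-
      if (on[["speck"]] && on[["casp1_active"]] && on[["il1b_release"]]) {
        "FULL_ACTIVATION"
      } else if (on[["pyroptosis"]] && !on[["speck"]]) {
        "PORE_ONLY"
      } else if (on[["speck"]] && !on[["il1b_release"]]) {
        "PRIMED_ONLY"
      } else if (on[["casp1_active"]] && !on[["speck"]]) {
        "TRIGGERED_ONLY"
      } else {
        "NO_ACTIVATION"
      }
  }
  call$scenario <- result$scenario$name
  structure(call, class = "activation_call")
}

#' @export
print.activation_call <- function(x, ...) {
  cat(sprintf("<activation_call %s: %s>\n", x$scenario, x$summary))
  flags <- unlist(x[names(nlrp3_readout_nodes())])
  cat(" ", paste(sprintf("%s=%s", names(flags), flags), collapse = " "), "\n")
  invisible(x)
}

#' Run the full scenario catalogue and tabulate the outcomes
#'
#' Compiles the baseline model once and reuses its natural off state for
#' every variant-free scenario; variant scenarios are recompiled from
#' the patched knowledge base.
#'
#' @param kb Knowledge base; defaults to the built-in NLRP3 network.
#' @param scenarios List of scenarios; defaults to [scenario_catalogue()].
#' @return A data.frame with one row per scenario: inputs, variants, the
#'   six readouts and the summary call.
#' @export
scenario_truth_table <- function(kb = load_nlrp3_network(),
                                 scenarios = scenario_catalogue()) {
  model <- build_update_rules(kb)
  off <- natural_off_state(model)
  rows <- lapply(scenarios, function(scn) {
    res <- if (length(scn$variants)) {
      run_scenario(kb, scn)
    } else {
      run_scenario(kb, scn, model = model, off_state = off)
    }
    call <- classify_outcome(res)
    data.frame(scenario = scn$name,
               inputs = paste(scn$inputs, collapse = "+"),
               variants = paste(scn$variants, collapse = "+"),
               speck = call$speck, casp1_active = call$casp1_active,
               il1b_release = call$il1b_release,
               il18_release = call$il18_release,
               pyroptosis = call$pyroptosis,
               bacterial_killing = call$bacterial_killing,
               summary = call$summary, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
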