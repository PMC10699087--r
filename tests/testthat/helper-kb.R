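# tiny knowledge bases built in code, plus a cached copy of the NLRP3
# fixture so the compiled model and off state are computed once per run

make_kb <- function(reactions, cont = NULL, registry = NULL) {
  rdf <- data.frame(UID = seq_along(reactions), Reaction = reactions,
                    stringsAsFactors = FALSE)
  load_knowledge_base(rdf, cont, registry = registry)
}

cont_df <- function(target, kind, modifier) {
  data.frame(UID = seq_along(target), Target = target, Contingency = kind,
              Modifier = modifier, stringsAsFactors = FALSE)
}

.nlrp3_cache <- new.env(parent = emptyenv())

nlrp3_cached <- function() {
  if (is.null(.nlrp3_cache$model)) {
    .nlrp3_cache$kb <- load_nlrp3_network()
    .nlrp3_cache$model <- build_update_rules(.nlrp3_cache$kb)
    .nlrp3_cache$off <- natural_off_state(.nlrp3_cache$model)
  }
  .nlrp3_cache
}

run_cached <- function(name) {
  cc <- nlrp3_cached()
  scn <- scenario_catalogue()[[name]]
  if (length(scn$variants)) {
    run_scenario(cc$kb, scn)
  } else {
    run_scenario(cc$kb, scn, model = cc$model, off_state = cc$off)
  }
}
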