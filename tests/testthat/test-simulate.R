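test_that("a synchronous step is deterministic and respects clamps", {
  cc <- nlrp3_cached()
  asg <- initial_assignment(cc$model, "neutral")
  a <- sim_step(cc$model, asg)
  b <- sim_step(cc$model, asg)
  expect_identical(a, b)

  clamped <- sim_step(cc$model, asg, clamps = c("[LPS]" = TRUE))
  expect_true(clamped[["[LPS]"]])
  expect_error(sim_step(cc$model, asg, clamps = c("NLRP3" = TRUE)),
               "non-input")
  expect_error(sim_step(cc$model, asg, clamps = c("[Pyroptosis]" = TRUE)),
               "non-input")
})

test_that("components without synthesis become TRUE from an all-off start", {
  cc <- nlrp3_cached()
  off0 <- initial_assignment(cc$model, "all-off")
  nxt <- sim_step(cc$model, off0)
  expect_true(nxt[["AKT"]])
  expect_true(nxt[["ASC"]])
  expect_false(nxt[["NLRP3"]])   # synthesised, so not constitutive
})

test_that("clamping LPS switches the priming reactions on at the next step", {
  cc <- nlrp3_cached()
  asg <- cc$off
  asg[["[LPS]"]] <- TRUE   # clamp imposed on the off state
  nxt <- sim_step(cc$model, asg, clamps = c("[LPS]" = TRUE))
  expect_true(nxt[["Pol_trsc_NLRP3"]])
  expect_true(nxt[["Tbk1_P+_AKT_[(T308)]"]])
  expect_false(cc$off[["Pol_trsc_NLRP3"]])
})

test_that("a one-node negation model yields a two-cycle", {
  model <- structure(list(
    nodes = data.frame(kind = "state", key = "a", stringsAsFactors = FALSE),
    rules = list(a = boolkit:::b_not(boolkit:::b_lit("a"))),
    clampable = character(0)), class = "boolean_model")
  model$step_fun <- boolkit:::compile_step_function(model)
  res <- simulate_to_attractor(model, c(a = FALSE))
  expect_identical(res$attractor$kind, "cycle")
  expect_identical(ncol(res$attractor$states), 2L)
  expect_identical(res$attractor$entry_step, 0L)
})

test_that("non-convergence raises a typed error carrying the trajectory", {
  model <- structure(list(
    nodes = data.frame(kind = "state", key = "a", stringsAsFactors = FALSE),
    rules = list(a = boolkit:::b_not(boolkit:::b_lit("a"))),
    clampable = character(0)), class = "boolean_model")
  model$step_fun <- boolkit:::compile_step_function(model)
  # force the budget below the cycle-closing revisit
  err <- tryCatch(simulate_to_attractor(model, c(a = FALSE), max_steps = 1L),
                  boolkit_nonconvergence = function(e) e)
  expect_s3_class(err, "boolkit_nonconvergence")
  expect_identical(ncol(err$trajectory), 2L)
})

test_that("the natural off state is an idempotent fixed point with outputs off", {
  cc <- nlrp3_cached()
  expect_identical(sim_step(cc$model, cc$off), cc$off)
  outs <- cc$model$nodes$key[cc$model$nodes$kind == "output"]
  expect_false(any(cc$off[outs]))
  expect_false(cc$off[["NLRP3"]])
  expect_false(cc$off[["[IL1Brelease]"]])
  expect_false(cc$off[["[Pyroptosis]"]])
})

test_that("a constitutive modification cycle is fully occupied in the off state", {
  kb <- make_kb(c("K_P+_S_[(r1)]", "P_P-_S_[(r1)]"))
  model <- build_update_rules(kb)
  off <- natural_off_state(model)
  expect_true(off[["S_[(r1)]-{P}"]])
  expect_true(off[["S_[(r1)]-{0}"]])
})

test_that("clamped inputs never change value along a trajectory", {
  cc <- nlrp3_cached()
  res <- run_cached("S-LPS+Nig")
  for (key in c("[LPS]", "[Nigericin]")) {
    expect_true(all(res$trajectory[key, ]))
  }
  off_res <- run_cached("S-none")
  expect_identical(off_res$attractor$states[, 1], cc$off)
})

test_that("scenario results expose readouts derived only from the attractor", {
  res <- run_cached("S-LPS+Nig")
  expect_identical(res$readouts[["[IL1Brelease]"]], "ON")
  expect_identical(res$readouts[["[BacterialKilling]"]], "ON")
  expect_identical(attractor_value(res, "NLRP3"), "ON")
  res0 <- run_cached("S-none")
  expect_true(all(res0$readouts == "OFF"))
  expect_error(run_scenario(nlrp3_cached()$kb, scenario("bad", "NoSuchInput")),
               "unknown input")
})

test_that("trajectory export sorts rows by activation order", {
  res <- run_cached("S-LPS")
  file <- withr::local_tempfile(fileext = ".csv")
  mat <- export_trajectory(res$trajectory, file)
  df <- utils::read.csv(file, check.names = FALSE)
  expect_identical(nrow(df), nrow(res$trajectory))
  expect_identical(ncol(df), ncol(res$trajectory) + 1L)
  expect_true(all(as.matrix(df[, -1]) %in% c(0L, 1L)))
  # rows already TRUE at step 0 come first, never-TRUE rows last
  first <- first_true_step(res$trajectory)[df$node]
  first <- ifelse(is.na(first), Inf, first)
  expect_false(is.unsorted(first))
  # the clamped stimulus is among the earliest activations
  expect_lte(first[["[LPS]"]], 0)

  tiny <- res$trajectory[, 1, drop = FALSE]
  file2 <- withr::local_tempfile(fileext = ".csv")
  mat2 <- export_trajectory(tiny, file2, sort = "declaration-order")
  expect_identical(ncol(mat2), 1L)
})

test_that("scenario results serialise to JSON with attractor and readouts", {
  res <- run_cached("S-LPS+Nig")
  f <- withr::local_tempfile(fileext = ".json")
  write_scenario_result(res, f)
  back <- jsonlite::read_json(f)
  expect_identical(back$scenario, "S-LPS+Nig")
  expect_identical(back$attractor$kind, "point")
  expect_identical(back$readouts[["[IL1Brelease]"]], "ON")
  expect_match(back$off_state_hash, "^[0-9a-f]+$")
})

test_that("scenario YAML files round-trip through read_scenario", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: demo", "inputs:", "  - LPS", "  - Nigericin",
               "variants:", "  - mcc950-blocks-abind", "max_steps: 100"),
             path)
  scn <- read_scenario(path)
  expect_identical(scn$name, "demo")
  expect_identical(scn$inputs, c("LPS", "Nigericin"))
  expect_identical(scn$variants, "mcc950-blocks-abind")
  expect_identical(scn$max_steps, 100L)
})
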