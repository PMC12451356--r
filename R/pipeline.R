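#' Pipeline run configuration
#'
#' Bundles every stage configuration plus the single global seed all
#' random draws flow from.
#'
#' @param seed global seed.
#' @param preset phantom resolution preset (see [phantomConfig()]).
#' @param phantom_cfg,beams,dose_cfg,spot_cfg,presc,siss stage configs
#'   (defaults built from the other arguments when NULL).
#' @param wishlist a [WishList-class] (default [npcWishList()]).
#' @param ntcp_models list of [ntcpModel()].
#' @param setup_mm,range_pct uncertainty settings for both scenario sets.
#' @param out_dir output directory (NULL = no files written).
#' @return list of class "run_config"
#' @export
runConfig <- function(seed = 1L, preset = "desk",
                      phantom_cfg = NULL, beams = beamConfig(),
                      dose_cfg = doseModelConfig(),
                      spot_cfg = spotPlacementConfig(),
                      presc = prescriptionConfig(),
                      wishlist = NULL,
                      ntcp_models = defaultNtcpModels(),
                      siss = sissConfig(),
                      setup_mm = 3, range_pct = 3,
                      out_dir = NULL) {
  if (is.null(phantom_cfg)) phantom_cfg <- phantomConfig(seed = seed, preset = preset)
  if (is.null(wishlist)) wishlist <- npcWishList(presc, beams)
  structure(list(seed = as.integer(seed), preset = preset,
                 phantom_cfg = phantom_cfg, beams = beams,
                 dose_cfg = dose_cfg, spot_cfg = spot_cfg, presc = presc,
                 wishlist = wishlist, ntcp_models = ntcp_models,
                 siss = siss, setup_mm = setup_mm, range_pct = range_pct,
                 out_dir = out_dir),
            class = "run_config")
}

#' Generate the IMPT and IMPT+TB plans for one phantom
#'
#' Runs the full planning chain twice with identical wish-list, beams and
#' scenarios: spot placement, avoidance filtering, transmission
#' duplication, per-scenario influence computation, lexicographic
#' optimization and sparsity-induced spot selection — once restricted to
#' the IMPT candidates and once on the union of IMPT and transmission
#' candidates. Influence matrices are computed once on the union and the
#' IMPT variant uses the corresponding column subset, so both variants see
#' numerically identical dose models.
#'
#' @param phantom a [VoxelPhantom-class] (after [deriveStructures()]).
#' @param config a [runConfig()].
#' @param opt_scenarios optional [ScenarioSet-class] (built from config
#'   when NULL).
#' @param verbose print stage progress.
#' @return list(impt =, impt_tb = [PlanSolution-class], candidates =
#'   [SpotSet-class], influences = list of [InfluenceMatrix-class],
#'   structure_rows = list).
#' @export
planImptAndTb <- function(phantom, config = runConfig(),
                          opt_scenarios = NULL, verbose = FALSE) {
  if (is.null(opt_scenarios)) {
    opt_scenarios <- buildOptimizationScenarios(config$setup_mm, config$range_pct)
  }
  say <- function(...) if (verbose) message(...)
  say("placing spots")
  sp <- placeImptSpots(phantom, config$beams, cfg = config$spot_cfg,
                       dose_cfg = config$dose_cfg)
  sp <- filterAvoidance(sp, phantom, config$beams$avoidance_structures,
                        config$dose_cfg)
  cand <- duplicateAsTransmission(sp, config$spot_cfg)

  say("computing influence matrices (", nrow(scenarioTable(opt_scenarios)),
      " scenarios)")
  infl <- influenceForScenarios(phantom, cand, opt_scenarios, config$dose_cfg,
                                verbose = verbose)
  srows <- structureRows(phantom, infl[[1]])

  tab <- cand@spots
  impt_idx <- which(!tab$is_transmission)
  solve_variant <- function(idx, label) {
    say("optimizing ", label)
    mats <- lapply(infl, function(x) x@mat[, idx, drop = FALSE])
    spots_v <- subsetSpots(cand, idx)
    dense <- solveLexicographic(config$wishlist, mats, srows, spots_v)
    sissSelect(dense, mats, config$wishlist, srows, spots_v,
               sparsity = config$siss)
  }
  impt <- solve_variant(impt_idx, "IMPT")
  impt_tb <- solve_variant(seq_len(nrow(tab)), "IMPT+TB")
  # expand IMPT weights back to the union candidate index for comparison
  w_full <- numeric(nrow(tab)); w_full[impt_idx] <- impt@weights
  impt@weights <- w_full
  impt@active <- impt_idx[impt@active]
  impt@spots <- cand
  list(impt = impt, impt_tb = impt_tb, candidates = cand,
       influences = infl, structure_rows = srows)
}

#' Run the full planning-and-evaluation pipeline
#'
#' phantom -> derived structures -> spots -> influences (optimization +
#' evaluation scenarios) -> IMPT solve -> IMPT+TB solve -> per-plan
#' evaluation -> paired comparison. When `out_dir` is set in the config,
#' all artifacts are written (phantom NIfTIs, spot CSV, plan JSONs,
#' evaluation and comparison CSVs and a manifest with config hash, seed
#' and file checksums); re-running the same configuration reproduces
#' identical outputs.
#'
#' @param config a [runConfig()].
#' @param verbose print stage progress.
#' @return list(phantom, plans, evaluations, comparison, manifest, files).
#' @export
runPipeline <- function(config = runConfig(), verbose = FALSE) {
  set.seed(config$seed)
  phantom <- deriveStructures(generatePhantom(config$phantom_cfg))
  plans <- planImptAndTb(phantom, config, verbose = verbose)

  eval_sc <- buildEvaluationScenarios(config$setup_mm, config$range_pct)
  evaluations <- list(
    autoIMPT = evaluatePlan(phantom, plans$impt, eval_sc, config$presc,
                            config$dose_cfg, config$ntcp_models),
    autoIMPT_TB = evaluatePlan(phantom, plans$impt_tb, eval_sc, config$presc,
                               config$dose_cfg, config$ntcp_models))

  pid <- sprintf("phantom_%03d", config$seed)
  cohort <- cohortMetricTable(lapply(evaluations, function(e) {
    stats::setNames(list(e), pid)
  }))
  comparison <- summarizeCohort(cohort)

  manifest <- list(
    seed = config$seed, preset = config$preset,
    config_hash = .hash_obj(config[setdiff(names(config), "out_dir")]),
    n_candidates = nrow(plans$candidates@spots),
    n_active = list(autoIMPT = length(plans$impt@active),
                    autoIMPT_TB = length(plans$impt_tb@active)),
    tb_fraction = plans$impt_tb@tb_fraction,
    scenario_counts = list(optimization = length(plans$influences),
                           evaluation = nrow(scenarioTable(eval_sc))))

  files <- character(0)
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    writePhantom(phantom, file.path(od, "phantom"))
    writeSpots(plans$candidates, file.path(od, "spots.csv"))
    writePlan(plans$impt, file.path(od, "plan_impt.json"))
    writePlan(plans$impt_tb, file.path(od, "plan_impt_tb.json"))
    for (v in names(evaluations)) {
      utils::write.csv(metricTable(evaluations[[v]]),
                       file.path(od, sprintf("evaluation_%s.csv", v)),
                       row.names = FALSE)
    }
    utils::write.csv(comparison, file.path(od, "comparison.csv"),
                     row.names = FALSE)
    files <- c("spots.csv", "plan_impt.json", "plan_impt_tb.json",
               sprintf("evaluation_%s.csv", names(evaluations)),
               "comparison.csv")
    manifest$file_md5 <- as.list(tools::md5sum(file.path(od, files)))
    names(manifest$file_md5) <- files
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- file.path(od, c(files, "manifest.json"))
  }
  list(phantom = phantom, plans = plans, evaluations = evaluations,
       comparison = comparison, manifest = manifest, files = files)
}

#' Deliberately detuned wish-list ("clinical-like" baseline)
#'
#' A baseline protocol that stops optimizing once targets are covered and
#' hot spots controlled — it keeps the hard constraints and coverage
#' objectives of [npcWishList()] but drops the organ-at-risk and dose-bath
#' minimization stages, mimicking a planner who stops when the clinical
#' goals are met. Used as the comparison arm in cohort demonstrations; it
#' is a labelled surrogate, not a replication of manual planning.
#'
#' @inheritParams npcWishList
#' @return a [WishList-class]
#' @export
clinicalSurrogateWishList <- function(presc = prescriptionConfig(),
                                      beams = beamConfig()) {
  wl <- npcWishList(presc, beams)
  ob <- wl@objectives[wl@objectives$priority <= 3, , drop = FALSE]
  wishList(wl@constraints, ob, slack = wl@slack, name = "clinical_surrogate")
}
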