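#' Prescription configuration
#'
#' Dose prescription and target-coverage goals: 70.00 Gy(RBE) to the
#' primary target and 54.25 Gy(RBE) to the elective targets in 35
#' fractions; nominal D98% goal 95% of prescription, voxel-wise-minimum
#' D98% goal 94%, near-maximum (D2%) goal 107%.
#'
#' @param d_high primary prescription, Gy(RBE).
#' @param d_elect elective prescription, Gy(RBE).
#' @param n_fractions fraction count.
#' @param goal_d98_pct,goal_d98_vwmin_pct,goal_d2_pct coverage goals in
#'   percent of prescription.
#' @return list of class "prescription_config"
#' @export
prescriptionConfig <- function(d_high = 70.00, d_elect = 54.25,
                               n_fractions = 35, goal_d98_pct = 95,
                               goal_d98_vwmin_pct = 94, goal_d2_pct = 107) {
  if (d_high <= 0 || d_elect <= 0) .stopf("prescriptions must be positive")
  if (goal_d98_pct <= 0 || goal_d98_vwmin_pct <= 0 || goal_d2_pct <= 0) {
    .stopf("goal percentages must be positive")
  }
  structure(list(d_high = d_high, d_elect = d_elect,
                 n_fractions = n_fractions, goal_d98_pct = goal_d98_pct,
                 goal_d98_vwmin_pct = goal_d98_vwmin_pct,
                 goal_d2_pct = goal_d2_pct),
            class = "prescription_config")
}

#' Absolute dose thresholds for the coverage goals
#'
#' Converts the percentage goals into absolute Gy values per target dose
#' level, rounded to one decimal as conventionally printed: with the
#' default prescription, 66.5 / 65.8 / 74.9 Gy for the primary target and
#' 51.5 / 51.0 Gy for the elective targets.
#'
#' @param presc a [prescriptionConfig()].
#' @return list(ctv7000 =, ctv5425 =) of named numeric vectors (d98,
#'   d98_vwmin, d2).
#' @export
goalThresholds <- function(presc = prescriptionConfig()) {
  mk <- function(d) c(
    d98 = round(presc$goal_d98_pct / 100 * d, 1),
    d98_vwmin = round(presc$goal_d98_vwmin_pct / 100 * d, 1),
    d2 = round(presc$goal_d2_pct / 100 * d, 1))
  list(ctv7000 = mk(presc$d_high), ctv5425 = mk(presc$d_elect))
}

# doses within a structure, descending
.struct_doses <- function(dose, mask) {
  if (!any(mask)) .stopf("empty structure mask")
  sort(dose[mask], decreasing = TRUE)
}

#' DVH metric of a dose distribution in a structure
#'
#' Supported metric specs: `"Dx%"` (minimum dose to the hottest x% of the
#' structure volume), `"Dvcm3"` (hottest v cm^3), `"Dmean"`, `"VxGy"`
#' (absolute volume in cm^3 receiving at least x Gy). Dx% uses the
#' inclusive "receives >= d" convention on the linearly interpolated
#' cumulative DVH of the sorted voxel doses; absolute volumes below one
#' voxel extrapolate to the maximum voxel dose.
#'
#' @param dose numeric dose array/vector (Gy).
#' @param mask logical mask, same shape.
#' @param metric metric spec string, e.g. "D98%", "D0.03cm3", "Dmean",
#'   "V5Gy".
#' @param voxel_volume_cm3 voxel volume (needed for Dvcm3 and VxGy).
#' @return metric value (Gy, or cm^3 for VxGy).
#' @export
dvhMetric <- function(dose, mask, metric, voxel_volume_cm3 = NULL) {
  d <- .struct_doses(dose, mask)
  n <- length(d)
  if (metric == "Dmean") return(mean(d))
  m <- regmatches(metric, regexec("^D([0-9.]+)%$", metric))[[1]]
  if (length(m)) {
    x <- as.numeric(m[2])
    if (x <= 0 || x > 100) .stopf("Dx%% needs x in (0, 100]")
    v <- x / 100 * n
    return(stats::approx(seq_len(n), d, xout = max(1, v), rule = 2)$y)
  }
  m <- regmatches(metric, regexec("^D([0-9.]+)cm3$", metric))[[1]]
  if (length(m)) {
    if (is.null(voxel_volume_cm3)) .stopf("Dvcm3 requires voxel_volume_cm3")
    vcm <- as.numeric(m[2])
    if (vcm > n * voxel_volume_cm3) {
      .stopf("requested volume %.3g cm^3 exceeds structure volume %.3g cm^3",
             vcm, n * voxel_volume_cm3)
    }
    v <- vcm / voxel_volume_cm3
    return(stats::approx(seq_len(n), d, xout = max(1, v), rule = 2)$y)
  }
  m <- regmatches(metric, regexec("^V([0-9.]+)Gy$", metric))[[1]]
  if (length(m)) {
    if (is.null(voxel_volume_cm3)) .stopf("VxGy requires voxel_volume_cm3")
    return(sum(d >= as.numeric(m[2])) * voxel_volume_cm3)
  }
  .stopf("unknown metric spec '%s'", metric)
}

#' Paddick conformity index at the 95% isodose
#'
#' CI = |target n PIV|^2 / (|target| * |PIV|) with PIV the set of voxels
#' receiving at least `isodose_frac` x prescription; 0 when the PIV is
#' empty.
#'
#' @param dose numeric dose array.
#' @param target logical target mask.
#' @param prescription prescription dose (Gy) of this target.
#' @param isodose_frac isodose level as a fraction of prescription
#'   (default 0.95).
#' @return conformity index in [0, 1].
#' @export
conformityIndex <- function(dose, target, prescription, isodose_frac = 0.95) {
  if (prescription <= 0) .stopf("prescription must be positive")
  if (!any(target)) .stopf("empty target mask")
  piv <- dose >= isodose_frac * prescription
  n_piv <- sum(piv)
  if (n_piv == 0) return(0)
  sum(piv & target)^2 / (sum(target) * n_piv)
}

#' Logistic NTCP model
#'
#' Normal-tissue complication probability as a logistic function of organ
#' dose summaries: NTCP = 100 / (1 + exp(-(b0 + sum_i b_i f_i(D_i)))) in
#' percent, with D_i the mean dose of one or more structures (averaged
#' when several are named) and f_i identity or square root.
#'
#' @param endpoint label, e.g. "xerostomia".
#' @param grade toxicity grade threshold label, e.g. ">=2".
#' @param intercept b0.
#' @param terms list of term lists: list(structures = character(),
#'   transform = "linear"|"sqrt", coef = numeric).
#' @return list of class "ntcp_model"
#' @export
ntcpModel <- function(endpoint, grade, intercept, terms) {
  structure(list(endpoint = endpoint, grade = grade,
                 intercept = intercept, terms = terms),
            class = "ntcp_model")
}

#' Evaluate an NTCP model on structure mean doses
#'
#' @param mean_doses named numeric vector of structure mean doses (Gy).
#' @param model an [ntcpModel()].
#' @return probability in percent.
#' @export
ntcp <- function(mean_doses, model) {
  lp <- model$intercept
  for (tm in model$terms) {
    miss <- setdiff(tm$structures, names(mean_doses))
    if (length(miss)) {
      .stopf("NTCP model '%s' needs mean dose of '%s'",
             model$endpoint, paste(miss, collapse = "', '"))
    }
    d <- mean(mean_doses[tm$structures])
    f <- switch(tm$transform, linear = d, sqrt = sqrt(d),
                .stopf("unknown transform '%s'", tm$transform))
    lp <- lp + tm$coef * f
  }
  100 * stats::plogis(lp)
}

#' Synthetic default NTCP models
#'
#' Logistic xerostomia and dysphagia models (grade >= 2 and >= 3) in the
#' style of published head-and-neck protocols, with hand-set coefficients:
#' they are plausibility stand-ins for demonstration, not validated
#' clinical models, and are meant to be replaced via [readNtcpModels()].
#'
#' @return named list of [ntcpModel()] objects.
#' @export
defaultNtcpModels <- function() {
  list(
    xerostomia_geq2 = ntcpModel("xerostomia", ">=2", -2.30, list(
      list(structures = c("parotid_l", "parotid_r"), transform = "sqrt",
           coef = 0.33))),
    xerostomia_geq3 = ntcpModel("xerostomia", ">=3", -3.70, list(
      list(structures = c("parotid_l", "parotid_r"), transform = "sqrt",
           coef = 0.30))),
    dysphagia_geq2 = ntcpModel("dysphagia", ">=2", -4.00, list(
      list(structures = "oral_cavity", transform = "linear", coef = 0.03),
      list(structures = "pcm_superior", transform = "linear", coef = 0.025))),
    dysphagia_geq3 = ntcpModel("dysphagia", ">=3", -6.20, list(
      list(structures = "oral_cavity", transform = "linear", coef = 0.03),
      list(structures = "pcm_superior", transform = "linear", coef = 0.025)))
  )
}

#' Read NTCP models from YAML
#'
#' @param path YAML file with a list of models (endpoint, grade,
#'   intercept, terms with structures/transform/coef).
#' @return named list of [ntcpModel()] objects.
#' @export
readNtcpModels <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(y$models, function(m) {
    ntcpModel(m$endpoint, m$grade, m$intercept,
              lapply(m$terms, function(tm) {
                list(structures = unlist(tm$structures),
                     transform = tm$transform, coef = tm$coef)
              }))
  })
  names(out) <- vapply(y$models, function(m) m$id, character(1))
  out
}

# evaluation metric schema: structure -> metrics per dose basis
.metric_schema <- function() {
  list(
    list(structure = "ctv7000", metric = "D98%", basis = c("nominal", "vwmin")),
    list(structure = "ctv7000", metric = "D2%", basis = "nominal"),
    list(structure = "ctv5425", metric = "D98%", basis = c("nominal", "vwmin")),
    list(structure = "ctv5425", metric = "D2%", basis = "nominal"),
    list(structure = "brainstem", metric = "D0.03cm3", basis = c("nominal", "vwmax")),
    list(structure = "brainstem_surface", metric = "D0.03cm3", basis = c("nominal", "vwmax")),
    list(structure = "spinal_cord", metric = "D0.03cm3", basis = c("nominal", "vwmax")),
    list(structure = "spinal_cord_surface", metric = "D0.03cm3", basis = c("nominal", "vwmax")),
    list(structure = "chiasm", metric = "D0.03cm3", basis = c("nominal", "vwmax")),
    list(structure = "optic_nerve_l", metric = "D0.03cm3", basis = c("nominal", "vwmax")),
    list(structure = "optic_nerve_r", metric = "D0.03cm3", basis = c("nominal", "vwmax")),
    list(structure = "brain_minus_ctv7000", metric = "D0.03cm3", basis = "nominal"),
    list(structure = "brain_minus_ctv7000", metric = "D3cm3", basis = "vwmax"),
    list(structure = "brain_minus_ctv7000", metric = "V10Gy", basis = "nominal"),
    list(structure = "mandible", metric = "D2%", basis = c("nominal", "vwmax")),
    list(structure = "parotid_l", metric = "Dmean", basis = "nominal"),
    list(structure = "parotid_r", metric = "Dmean", basis = "nominal"),
    list(structure = "oral_cavity", metric = "Dmean", basis = "nominal"),
    list(structure = "pcm_superior", metric = "Dmean", basis = "nominal"),
    list(structure = "body_minus_ctvs", metric = "V2Gy", basis = "nominal"),
    list(structure = "body_minus_ctvs", metric = "V5Gy", basis = "nominal"),
    list(structure = "body_minus_ctvs", metric = "Dmean", basis = "nominal")
  )
}

#' Full plan evaluation
#'
#' Computes the evaluation metric set from a plan's dose distributions:
#' nominal DVH metrics for all structures, voxel-wise-minimum D98% for the
#' targets and voxel-wise-maximum near-maximum metrics for serial
#' structures (vw-min/vw-max built from the evaluation scenario doses),
#' Paddick conformity indices at the 95% isodose of each target's own
#' prescription level, dose-bath volumes, the maximum dose per beam, and
#' NTCP values.
#'
#' @param phantom a [VoxelPhantom-class] (after [deriveStructures()]).
#' @param plan a [PlanSolution-class].
#' @param eval_scenarios a [ScenarioSet-class] (evaluation kind).
#' @param presc a [prescriptionConfig()].
#' @param dose_cfg a [doseModelConfig()].
#' @param ntcp_models list of [ntcpModel()] (NULL to skip).
#' @param nominal_influence optional precomputed nominal
#'   [InfluenceMatrix-class] for the plan's candidate spots.
#' @return a [PlanEvaluation-class].
#' @export
evaluatePlan <- function(phantom, plan, eval_scenarios,
                         presc = prescriptionConfig(),
                         dose_cfg = doseModelConfig(),
                         ntcp_models = defaultNtcpModels(),
                         nominal_influence = NULL) {
  vv <- voxelVolumeCm3(phantom)
  act <- plan@active
  w_act <- plan@weights[act]
  sp_act <- subsetSpots(plan@spots, act)

  nominal_row <- data.frame(id = "nominal", sx = 0, sy = 0, sz = 0,
                            range_factor = 1, stringsAsFactors = FALSE)
  if (is.null(nominal_influence)) {
    infl_nom <- computeInfluence(phantom, sp_act, nominal_row, dose_cfg)
    dose_nom <- doseFromWeights(infl_nom, w_act)
    beam_doses <- doseByBeam(infl_nom, sp_act, w_act)
  } else {
    dose_nom <- doseFromWeights(nominal_influence, plan@weights)
    beam_doses <- doseByBeam(nominal_influence, plan@spots, plan@weights)
  }

  tab <- scenarioTable(eval_scenarios)
  scen_doses <- lapply(seq_len(nrow(tab)), function(i) {
    doseFromWeights(computeInfluence(phantom, sp_act, tab[i, ], dose_cfg), w_act)
  })
  ext <- voxelwiseExtrema(scen_doses)

  pick <- function(basis) switch(basis, nominal = dose_nom,
                                 vwmin = ext$vw_min, vwmax = ext$vw_max)
  rows <- list()
  for (it in .metric_schema()) {
    if (!it$structure %in% structureNames(phantom)) next
    mask <- structureMask(phantom, it$structure)
    for (bs in it$basis) {
      val <- dvhMetric(pick(bs), mask, it$metric, vv)
      unit <- if (grepl("^V", it$metric)) "cm3" else "Gy"
      rows[[length(rows) + 1L]] <- data.frame(
        structure = it$structure, metric = it$metric, basis = bs,
        value = val, unit = unit, stringsAsFactors = FALSE)
    }
  }
  # conformity indices on each target's own prescription
  for (ci in list(c("ctv7000", presc$d_high), c("ctv5425", presc$d_elect))) {
    if (!ci[1] %in% structureNames(phantom)) next
    rows[[length(rows) + 1L]] <- data.frame(
      structure = ci[1], metric = "CI95", basis = "nominal",
      value = conformityIndex(dose_nom, structureMask(phantom, ci[1]),
                              as.numeric(ci[2])),
      unit = "", stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, rows)

  pbm <- data.frame(
    beam_index = as.integer(names(beam_doses)),
    max_dose = vapply(beam_doses, max, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(pbm) <- NULL

  ntcp_df <- data.frame(endpoint = character(), grade = character(),
                        value_pct = numeric(), stringsAsFactors = FALSE)
  if (length(ntcp_models)) {
    need <- unique(unlist(lapply(ntcp_models, function(m) {
      unlist(lapply(m$terms, `[[`, "structures"))
    })))
    need <- intersect(need, structureNames(phantom))
    means <- vapply(need, function(nm) {
      mean(dose_nom[structureMask(phantom, nm)])
    }, numeric(1))
    ntcp_df <- do.call(rbind, lapply(ntcp_models, function(m) {
      data.frame(endpoint = m$endpoint, grade = m$grade,
                 value_pct = ntcp(means, m), stringsAsFactors = FALSE)
    }))
    rownames(ntcp_df) <- NULL
  }

  new("PlanEvaluation", metrics = metrics, ntcp = ntcp_df,
      per_beam_max = pbm,
      meta = list(prescription = unclass(presc),
                  goal_thresholds = goalThresholds(presc),
                  n_eval_scenarios = nrow(tab),
                  tb_fraction = plan@tb_fraction))
}

#' @rdname accessors
#' @export
setMethod("metricTable", "PlanEvaluation", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("ntcpTable", "PlanEvaluation", function(x) x@ntcp)
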