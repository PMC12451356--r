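#' @import methods
#' @importFrom Matrix sparseMatrix colSums t
NULL

#' VoxelPhantom: voxel grid with stopping-power map and structure masks
#'
#' Container for a synthetic (or imported) patient model: a regular voxel
#' grid carrying a relative-stopping-power (RSP) map (water = 1.0), a binary
#' body mask, and named binary structure masks (targets, organs at risk,
#' avoidance volumes, derived structures).
#'
#' Invariants enforced by the validity method: all arrays share the grid
#' shape; every structure mask is contained in the body mask; RSP is zero
#' outside the body and positive inside; the primary target \code{ctv7000}
#' never overlaps the \code{brainstem} (abutting is allowed).
#'
#' @slot grid integer(3), voxels per axis.
#' @slot spacing numeric(3), voxel size in mm per axis.
#' @slot origin numeric(3), world coordinate (mm) of the centre of voxel
#'   (1,1,1).
#' @slot rsp numeric 3D array, relative stopping power per voxel.
#' @slot body logical 3D array, patient outline.
#' @slot structures named list of logical 3D arrays.
#' @slot seed integer seed the phantom was generated from (NA if imported).
#' @slot meta list of free-form metadata (config echo, volumes, hash).
#'
#' @aliases VoxelPhantom
#' @exportClass VoxelPhantom
setClass("VoxelPhantom",
  representation(
    grid = "integer", spacing = "numeric", origin = "numeric",
    rsp = "array", body = "array", structures = "list",
    seed = "integer", meta = "list"
  )
)

setValidity("VoxelPhantom", function(object) {
  msg <- character()
  g <- object@grid
  if (length(g) != 3L || any(g < 1L)) msg <- c(msg, "grid must be 3 positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be 3 positive numbers (mm)")
  }
  if (!identical(dim(object@rsp), g)) msg <- c(msg, "rsp dims != grid")
  if (!identical(dim(object@body), g)) msg <- c(msg, "body dims != grid")
  body <- object@body
  if (any(object@rsp[!body] != 0)) msg <- c(msg, "rsp must be 0 outside body")
  if (any(object@rsp[body] <= 0)) msg <- c(msg, "rsp must be > 0 inside body")
  for (nm in names(object@structures)) {
    m <- object@structures[[nm]]
    if (!identical(dim(m), g)) {
      msg <- c(msg, sprintf("structure '%s' dims != grid", nm))
    } else if (any(m & !body)) {
      msg <- c(msg, sprintf("structure '%s' not contained in body", nm))
    }
  }
  st <- object@structures
  if (!is.null(st$ctv7000) && !is.null(st$brainstem) &&
      any(st$ctv7000 & st$brainstem)) {
    msg <- c(msg, "ctv7000 overlaps brainstem (abutting allowed, overlap forbidden)")
  }
  if (length(msg)) msg else TRUE
})

#' SpotSet: catalog of candidate pencil-beam spots
#'
#' One row per deliverable spot: beam index and gantry angle, lateral
#' position in the beam's-eye-view (u: in-plane, v: superior-inferior, mm
#' relative to the isocenter), nominal energy (MeV), water-equivalent
#' range-shifter thickness (cm), and a transmission flag. Transmission
#' spots always carry the transmission energy and no range shifter.
#'
#' @slot spots data.frame with columns spot_id, beam_index, gantry_angle,
#'   u, v, energy, shifter_wet_cm, is_transmission, target.
#' @slot isocenter numeric(3) world coordinates (mm).
#' @slot meta list (placement config echo, removal reports).
#'
#' @aliases SpotSet
#' @exportClass SpotSet
setClass("SpotSet",
  representation(spots = "data.frame", isocenter = "numeric", meta = "list")
)

setValidity("SpotSet", function(object) {
  msg <- character()
  need <- c("spot_id", "beam_index", "gantry_angle", "u", "v",
            "energy", "shifter_wet_cm", "is_transmission")
  miss <- setdiff(need, names(object@spots))
  if (length(miss)) msg <- c(msg, paste("missing columns:", paste(miss, collapse = ", ")))
  if (!length(miss) && nrow(object@spots)) {
    s <- object@spots
    if (any(s$energy <= 0)) msg <- c(msg, "energies must be positive")
    tb <- s$is_transmission
    if (any(tb & s$shifter_wet_cm != 0)) {
      msg <- c(msg, "transmission spots must have no range shifter")
    }
    if (any(duplicated(s$spot_id))) msg <- c(msg, "spot_id must be unique")
  }
  if (length(object@isocenter) != 3L) msg <- c(msg, "isocenter must be length 3")
  if (length(msg)) msg else TRUE
})

#' ScenarioSet: setup/range error scenarios
#'
#' An ordered collection of treatment error scenarios, each a rigid
#' isocenter shift (mm) plus a multiplicative range (density) factor
#' applied to the stopping-power map.
#'
#' @slot scenarios data.frame with columns id, sx, sy, sz (mm) and
#'   range_factor.
#' @slot kind "optimization" or "evaluation".
#'
#' @aliases ScenarioSet
#' @exportClass ScenarioSet
setClass("ScenarioSet",
  representation(scenarios = "data.frame", kind = "character")
)

setValidity("ScenarioSet", function(object) {
  msg <- character()
  need <- c("id", "sx", "sy", "sz", "range_factor")
  if (!all(need %in% names(object@scenarios))) {
    msg <- c(msg, paste("scenarios needs columns", paste(need, collapse = ", ")))
  } else {
    if (any(object@scenarios$range_factor <= 0)) msg <- c(msg, "range_factor must be > 0")
    if (any(duplicated(object@scenarios$id))) msg <- c(msg, "scenario ids must be unique")
  }
  if (!object@kind %in% c("optimization", "evaluation")) {
    msg <- c(msg, "kind must be 'optimization' or 'evaluation'")
  }
  if (length(msg)) msg else TRUE
})

#' WishList: prioritized planning protocol
#'
#' Hard constraints plus an ordered list of objectives for lexicographic
#' multi-criteria optimization. Constraint metrics: \code{max_dose},
#' \code{mean_dose}, \code{per_beam_max_dose}. Objective types:
#' \code{max_dose}, \code{mean_dose}, \code{mean_underdose} (one-sided
#' deficit below \code{goal}). Robust items are enforced/scored over all
#' optimization scenarios (voxel-wise-minimum semantics for underdose).
#'
#' @slot constraints data.frame(structure, metric, bound, robust).
#' @slot objectives data.frame(priority, structure, type, goal, robust,
#'   sufficient). \code{structure} may list several names separated by
#'   "+" (the objective then acts on the union).
#' @slot slack numeric >= 1, multiplicative slack used when freezing an
#'   attained objective before optimizing the next priority.
#' @slot meta list (name, provenance).
#'
#' @aliases WishList
#' @exportClass WishList
setClass("WishList",
  representation(constraints = "data.frame", objectives = "data.frame",
                 slack = "numeric", meta = "list")
)

setValidity("WishList", function(object) {
  msg <- character()
  cn <- object@constraints
  ob <- object@objectives
  if (nrow(cn)) {
    if (!all(c("structure", "metric", "bound", "robust") %in% names(cn))) {
      msg <- c(msg, "constraints need structure, metric, bound, robust")
    } else {
      if (any(!cn$metric %in% c("max_dose", "mean_dose", "per_beam_max_dose"))) {
        msg <- c(msg, "unknown constraint metric")
      }
      if (any(cn$bound <= 0)) msg <- c(msg, "constraint bounds must be > 0")
    }
  }
  if (nrow(ob)) {
    if (!all(c("priority", "structure", "type", "goal", "robust", "sufficient") %in% names(ob))) {
      msg <- c(msg, "objectives need priority, structure, type, goal, robust, sufficient")
    } else {
      if (any(!ob$type %in% c("max_dose", "mean_dose", "mean_underdose"))) {
        msg <- c(msg, "unknown objective type")
      }
      p <- sort(ob$priority)
      if (any(duplicated(p)) || !identical(p, seq_along(p))) {
        msg <- c(msg, "priorities must be unique and contiguous starting at 1")
      }
      if (any(ob$type == "mean_underdose" & !is.finite(ob$goal))) {
        msg <- c(msg, "mean_underdose objectives need a finite goal")
      }
    }
  }
  if (length(object@slack) != 1L || object@slack < 1) msg <- c(msg, "slack must be >= 1")
  if (length(msg)) msg else TRUE
})

#' PlanSolution: optimized spot weights and achieved objective values
#'
#' @slot weights numeric, non-negative weight per candidate spot (same
#'   order as the candidate SpotSet).
#' @slot spots SpotSet of candidates the weights refer to.
#' @slot achieved data.frame(priority, structure, type, value) of attained
#'   objective values, in priority order (final re-solve if SISS ran).
#' @slot active integer indices of spots with weight above the prune
#'   threshold.
#' @slot tb_fraction numeric, |active transmission spots| / |active spots|.
#' @slot log character vector, solver log lines.
#' @slot meta list (scenario hash, wish-list name, solver settings).
#'
#' @aliases PlanSolution
#' @exportClass PlanSolution
setClass("PlanSolution",
  representation(weights = "numeric", spots = "SpotSet",
                 achieved = "data.frame", active = "integer",
                 tb_fraction = "numeric", log = "character", meta = "list")
)

setValidity("PlanSolution", function(object) {
  msg <- character()
  if (any(object@weights < -1e-9)) msg <- c(msg, "weights must be non-negative")
  if (length(object@weights) != nrow(object@spots@spots)) {
    msg <- c(msg, "one weight per candidate spot required")
  }
  if (length(msg)) msg else TRUE
})

#' PlanEvaluation: dose/volume, robustness, conformity and NTCP metrics
#'
#' @slot metrics data.frame(structure, metric, basis, value, unit) where
#'   basis is "nominal", "vwmin" or "vwmax".
#' @slot ntcp data.frame(endpoint, grade, value_pct).
#' @slot per_beam_max data.frame(beam_index, max_dose).
#' @slot meta list (prescriptions, scenario counts).
#'
#' @aliases PlanEvaluation
#' @exportClass PlanEvaluation
setClass("PlanEvaluation",
  representation(metrics = "data.frame", ntcp = "data.frame",
                 per_beam_max = "data.frame", meta = "list")
)

setMethod("show", "VoxelPhantom", function(object) {
  cat("VoxelPhantom:", paste(object@grid, collapse = " x "), "voxels @",
      paste(object@spacing, collapse = "x"), "mm\n")
  cat("  body voxels:", sum(object@body),
      sprintf("(%.1f cm^3)", sum(object@body) * prod(object@spacing) / 1000), "\n")
  cat("  structures:", paste(names(object@structures), collapse = ", "), "\n")
  if (!is.na(object@seed)) cat("  seed:", object@seed, "\n")
})

setMethod("show", "SpotSet", function(object) {
  s <- object@spots
  cat("SpotSet:", nrow(s), "spots,",
      sum(s$is_transmission), "transmission,",
      length(unique(s$beam_index)), "beams\n")
})

setMethod("show", "ScenarioSet", function(object) {
  cat("ScenarioSet (", object@kind, "): ", nrow(object@scenarios),
      " scenarios\n", sep = "")
})

setMethod("show", "WishList", function(object) {
  cat("WishList:", nrow(object@constraints), "hard constraints,",
      nrow(object@objectives), "prioritized objectives, slack",
      object@slack, "\n")
})

setMethod("show", "PlanSolution", function(object) {
  cat("PlanSolution:", length(object@active), "active /",
      length(object@weights), "candidate spots")
  if (length(object@tb_fraction) && !is.na(object@tb_fraction)) {
    cat(sprintf(", TB fraction %.1f%%", 100 * object@tb_fraction))
  }
  cat("\n")
  if (nrow(object@achieved)) {
    cat("  achieved objectives:\n")
    a <- object@achieved
    for (i in seq_len(nrow(a))) {
      cat(sprintf("   P%d %s %s = %.4g\n", a$priority[i], a$structure[i],
                  a$type[i], a$value[i]))
    }
  }
})

setMethod("show", "PlanEvaluation", function(object) {
  cat("PlanEvaluation:", nrow(object@metrics), "dose/volume metrics,",
      nrow(object@ntcp), "NTCP endpoints\n")
})
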