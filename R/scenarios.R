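#' Construct the robust-optimization scenario set
#'
#' Scenarios combine rigid isocenter shifts with a multiplicative range
#' (stopping-power) factor. The optimization set is the standard
#' {nominal + 6 cardinal shifts of `setup_mm`} x {range factors
#' 1 - r, 1, 1 + r}: 21 scenarios at the default 3 mm / 3 % settings.
#' Degenerate settings collapse it: 0 mm and 0 % give the single nominal
#' scenario.
#'
#' @param setup_mm isotropic setup error magnitude (mm), default 3.
#' @param range_pct range uncertainty in percent, default 3.
#' @return a [ScenarioSet-class] of kind "optimization" (nominal first,
#'   deterministic ordering).
#' @export
buildOptimizationScenarios <- function(setup_mm = 3, range_pct = 3) {
  if (setup_mm < 0 || range_pct < 0) .stopf("error magnitudes must be >= 0")
  shifts <- rbind(c(0, 0, 0))
  if (setup_mm > 0) {
    shifts <- rbind(shifts,
      setup_mm * rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  }
  rf <- unique(c(1, 1 - range_pct / 100, 1 + range_pct / 100))
  sc <- expand.grid(shift = seq_len(nrow(shifts)), rf = rf)
  df <- data.frame(
    id = sprintf("opt_%02d", seq_len(nrow(sc))),
    sx = shifts[sc$shift, 1], sy = shifts[sc$shift, 2], sz = shifts[sc$shift, 3],
    range_factor = sc$rf, stringsAsFactors = FALSE)
  # nominal (zero shift, factor 1) first
  nom <- which(df$sx == 0 & df$sy == 0 & df$sz == 0 & df$range_factor == 1)
  df <- rbind(df[nom, ], df[-nom, ])
  df$id <- sprintf("opt_%02d", seq_len(nrow(df)))
  rownames(df) <- NULL
  new("ScenarioSet", scenarios = df, kind = "optimization")
}

#' Construct the robustness-evaluation scenario set
#'
#' The evaluation set pairs 14 shift directions (6 cardinal + 8 body
#' diagonals, all normalized to `setup_mm`) with the two shifted range
#' factors 1 - r and 1 + r: 28 scenarios at the default 3 mm / 3 %
#' settings. The nominal scenario is deliberately not a member; voxel-wise
#' min/max surfaces are built from error scenarios only.
#'
#' @inheritParams buildOptimizationScenarios
#' @return a [ScenarioSet-class] of kind "evaluation".
#' @export
buildEvaluationScenarios <- function(setup_mm = 3, range_pct = 3) {
  if (setup_mm <= 0 || range_pct <= 0) .stopf("error magnitudes must be > 0")
  card <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  diag8 <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  shifts <- setup_mm * rbind(card, diag8)
  rf <- c(1 - range_pct / 100, 1 + range_pct / 100)
  sc <- expand.grid(shift = seq_len(nrow(shifts)), rf = rf)
  df <- data.frame(
    id = sprintf("eval_%02d", seq_len(nrow(sc))),
    sx = shifts[sc$shift, 1], sy = shifts[sc$shift, 2], sz = shifts[sc$shift, 3],
    range_factor = sc$rf, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  new("ScenarioSet", scenarios = df, kind = "evaluation")
}

#' @rdname accessors
#' @export
setMethod("scenarioTable", "ScenarioSet", function(x) x@scenarios)

#' Voxel-wise extrema over scenario doses
#'
#' Element-wise minimum and maximum over a list of congruent dose grids —
#' the voxel-wise min (vw-min) and voxel-wise max (vw-max) dose surfaces
#' used for robustness evaluation.
#'
#' @param doses list of numeric arrays (or vectors) with identical dims.
#' @return list(vw_min =, vw_max =) with the shared dims.
#' @export
voxelwiseExtrema <- function(doses) {
  if (!length(doses)) .stopf("need at least one scenario dose")
  d1 <- doses[[1]]
  for (d in doses) {
    if (!identical(dim(d), dim(d1)) || length(d) != length(d1)) {
      .stopf("scenario dose grids are not congruent")
    }
  }
  vmin <- d1; vmax <- d1
  for (d in doses[-1]) {
    vmin <- pmin(vmin, d)
    vmax <- pmax(vmax, d)
  }
  list(vw_min = vmin, vw_max = vmax)
}
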