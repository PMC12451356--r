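#' InfluenceMatrix: per-scenario linear map from spot weights to voxel dose
#'
#' Sparse matrix of dose per unit spot weight (Gy(RBE)) with rows indexed
#' by the body voxels of the phantom (linear grid indices kept in
#' `voxel_idx`) and one column per candidate spot.
#'
#' @slot mat dgCMatrix, body voxels x spots, all entries >= 0.
#' @slot voxel_idx integer linear grid indices of the rows.
#' @slot grid integer(3) grid shape (for reconstructing dose arrays).
#' @slot scenario_id character.
#' @slot spot_hash character, md5 of the spot catalog the columns refer to.
#'
#' @aliases InfluenceMatrix
#' @exportClass InfluenceMatrix
setClass("InfluenceMatrix",
  representation(mat = "dgCMatrix", voxel_idx = "integer", grid = "integer",
                 scenario_id = "character", spot_hash = "character")
)

setValidity("InfluenceMatrix", function(object) {
  msg <- character()
  if (nrow(object@mat) != length(object@voxel_idx)) {
    msg <- c(msg, "one row per voxel index required")
  }
  if (length(object@mat@x) && min(object@mat@x) < 0) {
    msg <- c(msg, "influence entries must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

# beam-frame unit vectors for a gantry angle (degrees).
# 0 deg: beam travels anterior -> posterior (+y); clockwise from superior.
.beam_frame <- function(angle_deg) {
  a <- angle_deg * pi / 180
  list(e_d = c(sin(a), cos(a), 0),
       e_u = c(cos(a), -sin(a), 0),
       e_v = c(0, 0, 1))
}

# nearest-voxel rsp lookup for world points (n x 3); 0 outside grid
.rsp_at <- function(pts, phantom) {
  g <- phantom@grid
  i <- round((pts[, 1] - phantom@origin[1]) / phantom@spacing[1]) + 1
  j <- round((pts[, 2] - phantom@origin[2]) / phantom@spacing[2]) + 1
  k <- round((pts[, 3] - phantom@origin[3]) / phantom@spacing[3]) + 1
  ok <- i >= 1 & i <= g[1] & j >= 1 & j <= g[2] & k >= 1 & k <= g[3]
  out <- numeric(nrow(pts))
  if (any(ok)) {
    lin <- (k[ok] - 1) * g[1] * g[2] + (j[ok] - 1) * g[1] + i[ok]
    out[ok] <- phantom@rsp[lin]
  }
  out
}

# water-equivalent-thickness profile along one ray.
# Returns t grid (mm, in beam depth coordinate), cumulative WET (cm,
# already scaled by the scenario range factor), and whether any sample
# lies inside the body.
.ray_wet <- function(phantom, iso, frame, u0, v0, shift, range_factor,
                     t_lim, step_mm) {
  tg <- seq(t_lim[1], t_lim[2], by = step_mm)
  base <- iso - shift + u0 * frame$e_u + v0 * frame$e_v
  pts <- cbind(base[1] + tg * frame$e_d[1],
               base[2] + tg * frame$e_d[2],
               base[3] + tg * frame$e_d[3])
  rsp <- .rsp_at(pts, phantom)
  list(t = tg, wet = cumsum(rsp) * step_mm / 10 * range_factor,
       hit = any(rsp > 0), rsp = rsp)
}

.interp_wet <- function(ray, d) {
  n <- length(ray$t)
  idx <- findInterval(d, ray$t, all.inside = TRUE)
  h <- ray$t[2] - ray$t[1]
  fr <- pmin(1, pmax(0, (d - ray$t[idx]) / h))
  ray$wet[idx] * (1 - fr) + ray$wet[pmin(idx + 1L, n)] * fr
}

#' Compute a dose-influence matrix for one scenario
#'
#' Analytic pencil-beam dose deposition: for every spot, the water
#' equivalent depth is accumulated by ray tracing through the scenario's
#' scaled stopping-power map along the spot's central axis (the ray is
#' shifted by the scenario's isocenter displacement and WET scales with the
#' range factor), the depth-dose curve is evaluated at each voxel's depth
#' and multiplied by an isotropic lateral Gaussian and the RBE factor.
#' Deposition is truncated at `lateral_cutoff_sigma` for sparsity. A spot
#' whose axis misses the body entirely yields a zero column and a warning.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param spots a [SpotSet-class].
#' @param scenario one row of a scenario table (id, sx, sy, sz,
#'   range_factor), e.g. `scenarioTable(s)[i, ]`.
#' @param cfg a [doseModelConfig()].
#' @return an [InfluenceMatrix-class].
#' @export
computeInfluence <- function(phantom, spots, scenario, cfg = doseModelConfig()) {
  sp_tab <- spots@spots
  body_idx <- which(phantom@body)
  nvox <- length(body_idx)
  nspot <- nrow(sp_tab)
  shift <- c(scenario$sx, scenario$sy, scenario$sz)
  rf <- scenario$range_factor
  iso <- spots@isocenter
  step_mm <- min(phantom@spacing) / 2

  trip_i <- vector("list", nspot)
  trip_x <- vector("list", nspot)

  if (nspot > 0) {
    coords <- .mask_coords(phantom@body, phantom)
    # beam-frame coordinates of the (shifted) voxels
    half_diag <- sqrt(sum((phantom@grid * phantom@spacing)^2)) / 2
    for (b in unique(sp_tab$beam_index)) {
      rows_b <- which(sp_tab$beam_index == b)
      frame <- .beam_frame(sp_tab$gantry_angle[rows_b[1]])
      rel <- sweep(coords, 2, iso - shift, "-")
      d_all <- rel %*% frame$e_d
      u_all <- rel %*% frame$e_u
      v_all <- rel %*% frame$e_v
      t_lim <- c(-half_diag - max(abs(shift)), half_diag + max(abs(shift)))
      ray_key <- paste(round(sp_tab$u[rows_b], 4), round(sp_tab$v[rows_b], 4))
      for (rk in unique(ray_key)) {
        srows <- rows_b[ray_key == rk]
        u0 <- sp_tab$u[srows[1]]; v0 <- sp_tab$v[srows[1]]
        ray <- .ray_wet(phantom, iso, frame, u0, v0, shift, rf, t_lim, step_mm)
        if (!ray$hit) {
          warning(sprintf("spot axis (beam %d, u=%.1f, v=%.1f) misses the body; zero column",
                          b, u0, v0))
          next
        }
        wet_end <- max(ray$wet)
        for (s in srows) {
          E <- sp_tab$energy[s]
          shw <- sp_tab$shifter_wet_cm[s]
          R_res <- rangeFromEnergy(E, cfg) - shw
          sig_ref <- lateralSigma(E, min(R_res, wet_end), shw, cfg)
          cut <- cfg$lateral_cutoff_sigma * sig_ref
          cand <- which(abs(u_all - u0) <= cut & abs(v_all - v0) <= cut)
          if (!length(cand)) next
          r2 <- (u_all[cand] - u0)^2 + (v_all[cand] - v0)^2
          keep <- r2 <= cut^2
          cand <- cand[keep]; r2 <- r2[keep]
          if (!length(cand)) next
          wet_i <- .interp_wet(ray, d_all[cand])
          dd <- depthDose(E, pmax(wet_i, 0) + shw, cfg)
          nz <- dd > 0
          if (!any(nz)) next
          cand <- cand[nz]; r2 <- r2[nz]; wet_i <- wet_i[nz]; dd <- dd[nz]
          sig <- lateralSigma(E, pmax(wet_i, 0), shw, cfg)
          val <- cfg$rbe * dd * exp(-r2 / (2 * sig^2)) / (2 * pi * sig^2) * 100
          trip_i[[s]] <- cand
          trip_x[[s]] <- val
        }
      }
    }
  }

  lens <- lengths(trip_i)
  mat <- Matrix::sparseMatrix(
    i = as.integer(unlist(trip_i, use.names = FALSE)),
    j = rep.int(seq_len(nspot), lens),
    x = as.numeric(unlist(trip_x, use.names = FALSE)),
    dims = c(nvox, nspot))
  new("InfluenceMatrix", mat = methods::as(mat, "CsparseMatrix"),
      voxel_idx = body_idx, grid = phantom@grid,
      scenario_id = as.character(scenario$id),
      spot_hash = .hash_obj(sp_tab))
}

#' Influence matrices for every scenario of a set
#'
#' @param phantom a [VoxelPhantom-class].
#' @param spots a [SpotSet-class].
#' @param scenarios a [ScenarioSet-class].
#' @param cfg a [doseModelConfig()].
#' @param verbose print progress.
#' @return named list of [InfluenceMatrix-class], one per scenario id.
#' @export
influenceForScenarios <- function(phantom, spots, scenarios,
                                  cfg = doseModelConfig(), verbose = FALSE) {
  tab <- scenarioTable(scenarios)
  out <- vector("list", nrow(tab))
  names(out) <- tab$id
  for (i in seq_len(nrow(tab))) {
    if (verbose) message("influence: scenario ", tab$id[i])
    out[[i]] <- computeInfluence(phantom, spots, tab[i, ], cfg)
  }
  out
}

#' Dose grid from spot weights
#'
#' @param influence an [InfluenceMatrix-class].
#' @param weights numeric weight per spot (>= 0).
#' @return 3D dose array (Gy(RBE)) on the phantom grid.
#' @export
doseFromWeights <- function(influence, weights) {
  stopifnot(length(weights) == ncol(influence@mat))
  v <- as.numeric(influence@mat %*% weights)
  .grid_array(v, influence@voxel_idx, influence@grid)
}

#' Per-beam dose grids from spot weights
#'
#' @param influence an [InfluenceMatrix-class].
#' @param spots the [SpotSet-class] the columns refer to.
#' @param weights numeric weight per spot.
#' @return named list of 3D dose arrays, one per beam index.
#' @export
doseByBeam <- function(influence, spots, weights) {
  tab <- spots@spots
  out <- list()
  for (b in sort(unique(tab$beam_index))) {
    w <- weights
    w[tab$beam_index != b] <- 0
    out[[as.character(b)]] <- doseFromWeights(influence, w)
  }
  out
}
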