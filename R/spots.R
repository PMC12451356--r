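#' Beam configuration
#'
#' Six-field head-and-neck beam arrangement with range shifters on the
#' four oblique-posterior fields and a per-beam dose cap. The
#' `structure_beam_map` restricts which beams may carry spots for a given
#' target: by default the left elective lobe is only irradiated by beams
#' 1-3 and the right lobe by beams 4-6, preventing unnecessary irradiation
#' of traversed healthy tissue.
#'
#' @param angles gantry angles in degrees, default c(50,100,160,200,260,310).
#' @param shifter_beams indices of beams carrying a range shifter (default
#'   2:5).
#' @param shifter_wet_cm water-equivalent shifter thickness, default 3.
#' @param per_beam_dose_cap maximum dose (Gy(RBE)) any voxel may receive
#'   from a single beam, default 47.0.
#' @param structure_beam_map named list: structure -> integer beam subset.
#' @param avoidance_structures structure names spots must not pass through.
#' @return list of class "beam_config"
#' @export
beamConfig <- function(angles = c(50, 100, 160, 200, 260, 310),
                       shifter_beams = 2:5,
                       shifter_wet_cm = 3,
                       per_beam_dose_cap = 47.0,
                       structure_beam_map = list(ctv5425_left = 1:3,
                                                 ctv5425_right = 4:6),
                       avoidance_structures = "avoid_dental") {
  if (any(angles < 0 | angles >= 360)) .stopf("angles must be in [0, 360)")
  if (per_beam_dose_cap <= 0) .stopf("per-beam cap must be > 0")
  if (length(shifter_beams) && any(!shifter_beams %in% seq_along(angles))) {
    .stopf("shifter_beams out of range")
  }
  structure(list(angles = angles, shifter_beams = shifter_beams,
                 shifter_wet_cm = shifter_wet_cm,
                 per_beam_dose_cap = per_beam_dose_cap,
                 structure_beam_map = structure_beam_map,
                 avoidance_structures = avoidance_structures),
            class = "beam_config")
}

#' Spot placement configuration
#'
#' @param lateral_spacing_mm lateral grid pitch in the beam's-eye-view.
#' @param energy_layer_wet_cm energy layer spacing in cm water-equivalent
#'   depth.
#' @param target_margin_mm margin added around targets for spot coverage.
#' @param transmission_energy MeV used when duplicating spots as
#'   transmission candidates, default 244.
#' @return list of class "spot_placement_config"
#' @export
spotPlacementConfig <- function(lateral_spacing_mm = 18,
                                energy_layer_wet_cm = 2.2,
                                target_margin_mm = 5,
                                transmission_energy = 244) {
  if (lateral_spacing_mm <= 0 || energy_layer_wet_cm <= 0) {
    .stopf("spacings must be positive")
  }
  if (target_margin_mm < 0) .stopf("margin must be >= 0")
  structure(list(lateral_spacing_mm = lateral_spacing_mm,
                 energy_layer_wet_cm = energy_layer_wet_cm,
                 target_margin_mm = target_margin_mm,
                 transmission_energy = transmission_energy),
            class = "spot_placement_config")
}

#' Place candidate IMPT spots
#'
#' For every beam, a lateral spot grid covers the beam's-eye-view
#' projection of the targets assigned to that beam (plus margin), and for
#' every ray that intersects the (margin-dilated) target, energy layers
#' span the target's water-equivalent depth interval at the configured
#' layer spacing. Spot energies are chosen so that each Bragg peak sits at
#' its layer's depth after traversing the beam's range shifter; peaks
#' therefore lie inside target + margin by construction. The
#' `structure_beam_map` of the beam configuration restricts targets to
#' their allowed beams.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param beams a [beamConfig()].
#' @param targets character structure names to cover (default primary +
#'   both elective lobes).
#' @param cfg a [spotPlacementConfig()].
#' @param dose_cfg a [doseModelConfig()] (range-energy relation).
#' @return a [SpotSet-class]; isocenter = centre of mass of the first
#'   target.
#' @export
placeImptSpots <- function(phantom, beams = beamConfig(),
                           targets = c("ctv7000", "ctv5425_left", "ctv5425_right"),
                           cfg = spotPlacementConfig(),
                           dose_cfg = doseModelConfig()) {
  for (tg in targets) {
    if (!tg %in% structureNames(phantom)) .stopf("unknown target '%s'", tg)
  }
  iso <- colMeans(.mask_coords(structureMask(phantom, targets[1]), phantom))
  step_mm <- min(phantom@spacing) / 2
  half_diag <- sqrt(sum((phantom@grid * phantom@spacing)^2)) / 2
  t_lim <- c(-half_diag, half_diag)
  ls <- cfg$lateral_spacing_mm

  rows <- list()
  for (tg in targets) {
    allowed <- beams$structure_beam_map[[tg]]
    if (is.null(allowed)) allowed <- seq_along(beams$angles)
    mask <- structureMask(phantom, tg)
    if (cfg$target_margin_mm > 0) {
      mask <- .dilate_mask(mask, phantom@spacing, cfg$target_margin_mm) & phantom@body
    }
    tcoords <- .mask_coords(mask, phantom)
    placed_any <- FALSE
    for (b in allowed) {
      frame <- .beam_frame(beams$angles[b])
      shw <- if (b %in% beams$shifter_beams) beams$shifter_wet_cm else 0
      rel <- sweep(tcoords, 2, iso, "-")
      u_t <- as.numeric(rel %*% frame$e_u)
      v_t <- as.numeric(rel %*% frame$e_v)
      # lateral grid nodes that carry at least one projected target voxel
      iu <- round((u_t - min(u_t)) / ls)
      iv <- round((v_t - min(v_t)) / ls)
      nodes <- unique(cbind(iu, iv))
      u_nodes <- min(u_t) + nodes[, 1] * ls
      v_nodes <- min(v_t) + nodes[, 2] * ls
      tg_lin <- which(mask)
      for (q in seq_len(nrow(nodes))) {
        u0 <- u_nodes[q]; v0 <- v_nodes[q]
        ray <- .ray_wet(phantom, iso, frame, u0, v0, c(0, 0, 0), 1, t_lim, step_mm)
        if (!ray$hit) next
        # samples inside the (dilated) target along this ray
        base <- iso + u0 * frame$e_u + v0 * frame$e_v
        pts <- cbind(base[1] + ray$t * frame$e_d[1],
                     base[2] + ray$t * frame$e_d[2],
                     base[3] + ray$t * frame$e_d[3])
        g <- phantom@grid
        i <- round((pts[, 1] - phantom@origin[1]) / phantom@spacing[1]) + 1
        j <- round((pts[, 2] - phantom@origin[2]) / phantom@spacing[2]) + 1
        k <- round((pts[, 3] - phantom@origin[3]) / phantom@spacing[3]) + 1
        ok <- i >= 1 & i <= g[1] & j >= 1 & j <= g[2] & k >= 1 & k <= g[3]
        lin <- rep(NA_integer_, nrow(pts))
        lin[ok] <- (k[ok] - 1L) * g[1] * g[2] + (j[ok] - 1L) * g[1] + i[ok]
        in_t <- !is.na(lin) & lin %in% tg_lin
        if (!any(in_t)) next
        wrange <- range(ray$wet[in_t])
        layers <- seq(wrange[1], wrange[2], by = cfg$energy_layer_wet_cm)
        if (utils::tail(layers, 1) < wrange[2] - 1e-9) layers <- c(layers, wrange[2])
        energies <- ((layers + shw) / dose_cfg$alpha)^(1 / dose_cfg$p)
        rows[[length(rows) + 1L]] <- data.frame(
          beam_index = b, gantry_angle = beams$angles[b],
          u = u0, v = v0, energy = energies, shifter_wet_cm = shw,
          is_transmission = FALSE, target = tg, stringsAsFactors = FALSE)
        placed_any <- TRUE
      }
    }
    if (!placed_any) .stopf("target '%s' is invisible from every allowed beam", tg)
  }
  tab <- do.call(rbind, rows)
  # merge coincident spots placed for different targets
  key <- paste(tab$beam_index, round(tab$u, 3), round(tab$v, 3),
               round(tab$energy, 3))
  tab <- tab[!duplicated(key), , drop = FALSE]
  tab <- tab[order(tab$beam_index, tab$u, tab$v, tab$energy), , drop = FALSE]
  tab$spot_id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("SpotSet", spots = tab[, c("spot_id", "beam_index", "gantry_angle",
                                 "u", "v", "energy", "shifter_wet_cm",
                                 "is_transmission", "target")],
      isocenter = as.numeric(iso),
      meta = list(placement = unclass(cfg)))
}

#' Remove spots whose entrance ray crosses an avoidance volume
#'
#' A spot is removed when any ray sample proximal to its Bragg peak (the
#' segment between patient entry and the peak depth) lies inside one of
#' the named avoidance masks. Transmission spots have their peak beyond
#' the patient, so their whole in-patient path counts as entrance.
#'
#' @param spots a [SpotSet-class].
#' @param phantom a [VoxelPhantom-class].
#' @param avoidance character structure names.
#' @param dose_cfg a [doseModelConfig()].
#' @return the filtered [SpotSet-class]; a removal report is stored in
#'   `meta$avoidance_removed`.
#' @export
filterAvoidance <- function(spots, phantom, avoidance,
                            dose_cfg = doseModelConfig()) {
  if (!length(avoidance)) {
    spots@meta$avoidance_removed <- integer(0)
    return(spots)
  }
  avoid <- Reduce(`|`, lapply(avoidance, function(nm) structureMask(phantom, nm)))
  tab <- spots@spots
  iso <- spots@isocenter
  step_mm <- min(phantom@spacing) / 2
  half_diag <- sqrt(sum((phantom@grid * phantom@spacing)^2)) / 2
  t_lim <- c(-half_diag, half_diag)
  g <- phantom@grid
  avoid_lin <- which(avoid)
  drop <- logical(nrow(tab))
  ray_cache <- new.env(parent = emptyenv())
  for (s in seq_len(nrow(tab))) {
    key <- paste(tab$beam_index[s], round(tab$u[s], 4), round(tab$v[s], 4))
    if (is.null(ray_cache[[key]])) {
      frame <- .beam_frame(tab$gantry_angle[s])
      ray <- .ray_wet(phantom, iso, frame, tab$u[s], tab$v[s],
                      c(0, 0, 0), 1, t_lim, step_mm)
      base <- iso + tab$u[s] * frame$e_u + tab$v[s] * frame$e_v
      pts <- cbind(base[1] + ray$t * frame$e_d[1],
                   base[2] + ray$t * frame$e_d[2],
                   base[3] + ray$t * frame$e_d[3])
      i <- round((pts[, 1] - phantom@origin[1]) / phantom@spacing[1]) + 1
      j <- round((pts[, 2] - phantom@origin[2]) / phantom@spacing[2]) + 1
      k <- round((pts[, 3] - phantom@origin[3]) / phantom@spacing[3]) + 1
      ok <- i >= 1 & i <= g[1] & j >= 1 & j <= g[2] & k >= 1 & k <= g[3]
      lin <- rep(NA_integer_, nrow(pts))
      lin[ok] <- (k[ok] - 1L) * g[1] * g[2] + (j[ok] - 1L) * g[1] + i[ok]
      ray_cache[[key]] <- list(wet = ray$wet, in_avoid = !is.na(lin) & lin %in% avoid_lin)
    }
    rc <- ray_cache[[key]]
    R_res <- rangeFromEnergy(tab$energy[s], dose_cfg) - tab$shifter_wet_cm[s]
    proximal <- rc$wet <= R_res
    drop[s] <- any(rc$in_avoid & proximal)
  }
  removed <- tab$spot_id[drop]
  tab <- tab[!drop, , drop = FALSE]
  rownames(tab) <- NULL
  spots@spots <- tab
  spots@meta$avoidance_removed <- removed
  validObject(spots)
  spots
}

#' Duplicate spots as transmission-beam candidates
#'
#' Every selected IMPT spot is duplicated with its energy replaced by the
#' transmission energy (default 244 MeV) and no range shifter. Duplicates
#' sharing (beam, lateral position) collapse to a single transmission
#' candidate, so each ray contributes at most one transmission spot.
#'
#' @param spots a [SpotSet-class] of IMPT candidates.
#' @param cfg a [spotPlacementConfig()] (transmission energy).
#' @return a [SpotSet-class] containing the original spots plus the
#'   transmission candidates (spot ids extended).
#' @export
duplicateAsTransmission <- function(spots, cfg = spotPlacementConfig()) {
  tab <- spots@spots
  if (!nrow(tab)) .stopf("cannot duplicate an empty spot set")
  tb <- tab[!duplicated(paste(tab$beam_index, round(tab$u, 3), round(tab$v, 3))), ,
            drop = FALSE]
  tb$energy <- cfg$transmission_energy
  tb$shifter_wet_cm <- 0
  tb$is_transmission <- TRUE
  tb$spot_id <- max(tab$spot_id) + seq_len(nrow(tb))
  out <- rbind(tab, tb)
  rownames(out) <- NULL
  spots@spots <- out
  validObject(spots)
  spots
}

#' @rdname accessors
#' @export
setMethod("spotTable", "SpotSet", function(x) x@spots)

#' Subset a spot set by row indices
#'
#' @param spots a [SpotSet-class]
#' @param idx integer row indices to keep
#' @return the subset [SpotSet-class] (spot ids preserved)
#' @export
subsetSpots <- function(spots, idx) {
  spots@spots <- spots@spots[idx, , drop = FALSE]
  rownames(spots@spots) <- NULL
  validObject(spots)
  spots
}
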