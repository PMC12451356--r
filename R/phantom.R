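#' Phantom generation configuration
#'
#' Builds the configuration for [generatePhantom()]. Defaults emulate the
#' nasopharynx planning geometry the pipeline targets: a primary target
#' (ctv7000) abutting the brainstem, bilateral elective targets (ctv5425,
#' split into left/right lobes), serial organs at risk (brainstem, spinal
#' cord, optic nerves, chiasm), parallel organs at risk (parotids, oral
#' cavity, superior pharyngeal constrictor), brain, mandible and a dental
#' avoidance volume.
#'
#' @param seed integer seed; the phantom is bit-reproducible from it.
#' @param preset resolution preset: "mini" (12 mm), "desk" (8 mm, default),
#'   "fine" (4 mm) or "clinical" (2 mm). Overridden by `spacing`/`grid`.
#' @param spacing numeric(3) voxel size in mm (optional override).
#' @param grid integer(3) grid shape (optional override).
#' @param ctv7000_volume_bounds admissible primary-target volume (cm^3);
#'   default is the study population range 27.3-408.7.
#' @param ctv5425_volume_bounds admissible elective-target volume (cm^3);
#'   default 256.6-565.3.
#' @param ctv7000_volume_draw range (cm^3) the seeded generator samples the
#'   primary target volume from (kept inside the bounds).
#' @param ctv5425_volume_draw sampling range for the elective target volume.
#' @param ctv_oar_gap mm gap between ctv7000 and the brainstem surface;
#'   0 (default) = abutting.
#' @param heterogeneity logical; if TRUE, bone (mandible, RSP 1.5) and an
#'   air sinus (RSP 0.2) are inserted, otherwise RSP is uniform 1.0 in body.
#' @param jitter relative magnitude of the seeded anatomical jitter.
#' @return a list of class "phantom_config"
#' @export
phantomConfig <- function(seed = 1L,
                          preset = c("desk", "mini", "fine", "clinical"),
                          spacing = NULL, grid = NULL,
                          ctv7000_volume_bounds = c(27.3, 408.7),
                          ctv5425_volume_bounds = c(256.6, 565.3),
                          ctv7000_volume_draw = c(100, 260),
                          ctv5425_volume_draw = c(300, 460),
                          ctv_oar_gap = 0,
                          heterogeneity = FALSE,
                          jitter = 0.04) {
  preset <- match.arg(preset)
  if (is.null(spacing)) {
    spacing <- switch(preset,
      mini = c(12, 12, 12), desk = c(8, 8, 8),
      fine = c(4, 4, 4), clinical = c(2, 2, 2))
  }
  if (is.null(grid)) grid <- as.integer(ceiling(264 / spacing))
  if (ctv_oar_gap < 0) .stopf("ctv_oar_gap must be >= 0")
  stopifnot(length(spacing) == 3, all(spacing > 0), length(grid) == 3)
  structure(list(
    seed = as.integer(seed), preset = preset,
    spacing = as.numeric(spacing), grid = as.integer(grid),
    ctv7000_volume_bounds = ctv7000_volume_bounds,
    ctv5425_volume_bounds = ctv5425_volume_bounds,
    ctv7000_volume_draw = ctv7000_volume_draw,
    ctv5425_volume_draw = ctv5425_volume_draw,
    ctv_oar_gap = ctv_oar_gap,
    heterogeneity = isTRUE(heterogeneity),
    jitter = jitter
  ), class = "phantom_config")
}

#' Generate a seeded synthetic nasopharynx-like phantom
#'
#' Procedurally composes the anatomy from ellipsoids and tubes with seeded
#' jitter on positions, shapes and target volumes; no image realism is
#' attempted. The primary target is placed so that its posterior surface
#' sits `ctv_oar_gap` mm anterior of the brainstem surface (abutting when
#' 0); voxels shared with the brainstem are removed from the target so the
#' two masks never overlap. The elective target excludes the primary
#' target, the brainstem and the spinal cord by construction.
#'
#' @param config a [phantomConfig()] list.
#' @return a [VoxelPhantom-class] with structures ctv7000, ctv5425 (+ left/
#'   right lobes), brainstem, spinal_cord, parotid_l/r, oral_cavity,
#'   optic_nerve_l/r, chiasm, brain, mandible, pcm_superior, avoid_dental.
#' @export
generatePhantom <- function(config = phantomConfig()) {
  stopifnot(inherits(config, "phantom_config"))
  g <- config$grid; sp <- config$spacing
  extent <- g * sp
  origin <- sp / 2 - extent / 2          # grid centred on world 0
  ctr <- c(0, 0, 0)

  rng <- local({ set.seed(config$seed); list(
    j = function(n = 1) 1 + config$jitter * stats::runif(n, -1, 1),
    u = function(lo, hi) stats::runif(1, lo, hi),
    sh = function(n = 1, mm = 4) stats::runif(n, -mm, mm)
  )})

  ell <- function(center, semi) .ellipsoid_mask(g, sp, origin, center, semi)
  seg <- function(p0, p1, r) .segment_tube_mask(g, sp, origin, p0, p1, r)
  vol <- function(m) sum(m) * prod(sp) / 1000   # cm^3

  # --- body ---------------------------------------------------------------
  body <- ell(ctr, c(78, 95, 122) * rng$j(3))

  # --- serial structures ---------------------------------------------------
  # tubular structures keep a partial-volume floor on their radius so
  # they stay non-empty on coarse grids
  r_floor <- 0.75 * max(sp)
  bs_r <- max(9 * rng$j(), r_floor)
  bs_y <- 30 + rng$sh(1, 2)
  brainstem <- .tube_mask(g, sp, origin, c(0 + rng$sh(1, 1.5), bs_y),
                          c(bs_r, bs_r), c(-15, 65)) & body
  cord_r <- pmax(c(7 * rng$j(), 7 * rng$j()), r_floor)
  cord <- .tube_mask(g, sp, origin, c(0, bs_y + 3), cord_r,
                     c(origin[3] - 1, -15)) & body

  # --- primary target, abutting the brainstem ------------------------------
  v7 <- rng$u(config$ctv7000_volume_draw[1], config$ctv7000_volume_draw[2])
  base7 <- c(1.05, 0.88, 1.0) * rng$j(3)
  scale7 <- (v7 * 1000 / (4 / 3 * pi * prod(base7)))^(1 / 3)
  semi7 <- base7 * scale7
  # posterior surface of target touches anterior surface of brainstem;
  # a 2 mm geometric overlap (removed by subtraction) guarantees abutment
  y7 <- (bs_y - bs_r) - semi7[2] + 2 - config$ctv_oar_gap
  ctv7000_geo <- ell(c(0 + rng$sh(1, 1.5), y7, 5 + rng$sh(1, 3)), semi7)
  ctv7000 <- ctv7000_geo & body & !brainstem & !cord

  # --- elective targets (left/right lobes) ---------------------------------
  v54 <- rng$u(config$ctv5425_volume_draw[1], config$ctv5425_volume_draw[2])
  base54 <- c(0.92, 1.0, 1.3) * rng$j(3)
  scale54 <- (v54 / 2 * 1000 / (4 / 3 * pi * prod(base54)))^(1 / 3)
  semi54 <- base54 * scale54
  mk_lobe <- function(side) {
    c0 <- c(side * (40 + rng$sh(1, 2)), 8 + rng$sh(1, 2), -32 + rng$sh(1, 3))
    ell(c0, semi54) & body & !ctv7000 & !brainstem & !cord
  }
  ctv5425_left <- mk_lobe(+1)            # +x = patient left
  ctv5425_right <- mk_lobe(-1)
  ctv5425 <- ctv5425_left | ctv5425_right

  # --- parallel OARs --------------------------------------------------------
  parotid_l <- ell(c(+60, 18, 2) + rng$sh(3, 2), c(13, 19, 23) * rng$j(3)) & body
  parotid_r <- ell(c(-60, 18, 2) + rng$sh(3, 2), c(13, 19, 23) * rng$j(3)) & body
  oral_cavity <- ell(c(0, -48, -28) + rng$sh(3, 2), c(27, 22, 20) * rng$j(3)) & body
  pcm_superior <- .tube_mask(g, sp, origin, c(0, 14),
                             pmax(c(10, 8) * rng$j(2), r_floor),
                             c(-40, -14)) & body & !ctv7000

  # --- optic system ---------------------------------------------------------
  on_r_eff <- max(3, 0.6 * max(sp))      # keep thin nerves non-empty at coarse grids
  zopt <- 42 + rng$sh(1, 2)
  optic_nerve_l <- seg(c(+24, -52, zopt), c(+4, -16, zopt), on_r_eff) & body
  optic_nerve_r <- seg(c(-24, -52, zopt), c(-4, -16, zopt), on_r_eff) & body
  chiasm <- ell(c(0, -14, zopt), pmax(c(9, 7, 6) * rng$j(3), r_floor)) & body

  # --- brain, mandible, avoidance -------------------------------------------
  brain <- ell(c(0, 6, 78), c(64, 74, 52) * rng$j(3)) & body
  mandible <- ell(c(0, -50, -45), pmax(c(44, 16, 12) * rng$j(3), r_floor)) & body
  avoid_dental <- ell(c(0, -58, -40), pmax(c(12, 8, 8), r_floor)) & body

  structures <- list(
    ctv7000 = ctv7000, ctv5425 = ctv5425,
    ctv5425_left = ctv5425_left, ctv5425_right = ctv5425_right,
    brainstem = brainstem, spinal_cord = cord,
    parotid_l = parotid_l, parotid_r = parotid_r,
    oral_cavity = oral_cavity, pcm_superior = pcm_superior,
    optic_nerve_l = optic_nerve_l, optic_nerve_r = optic_nerve_r,
    chiasm = chiasm, brain = brain, mandible = mandible,
    avoid_dental = avoid_dental
  )

  for (nm in names(structures)) {
    if (!any(structures[[nm]])) {
      .stopf("structure '%s' is empty at the requested resolution", nm)
    }
  }
  vb <- config$ctv7000_volume_bounds
  if (vol(ctv7000) < vb[1] || vol(ctv7000) > vb[2]) {
    .stopf("ctv7000 volume %.1f cm^3 outside bounds [%.1f, %.1f] at this resolution",
           vol(ctv7000), vb[1], vb[2])
  }
  vb54 <- config$ctv5425_volume_bounds
  if (vol(ctv5425) < vb54[1] || vol(ctv5425) > vb54[2]) {
    .stopf("ctv5425 volume %.1f cm^3 outside bounds [%.1f, %.1f] at this resolution",
           vol(ctv5425), vb54[1], vb54[2])
  }

  rsp <- array(0, dim = g)
  rsp[body] <- 1.0
  if (config$heterogeneity) {
    rsp[mandible] <- 1.5
    sinus <- ell(c(0, -40, 22), c(16, 12, 10)) & body
    rsp[sinus] <- 0.2
  }

  ph <- new("VoxelPhantom",
    grid = g, spacing = sp, origin = origin,
    rsp = rsp, body = body, structures = structures,
    seed = config$seed,
    meta = list(config = unclass(config),
                volumes_cm3 = vapply(structures, vol, numeric(1))))
  validObject(ph)
  ph
}

#' Add derived evaluation structures
#'
#' Adds the set-subtraction structures used in plan evaluation
#' (body_minus_ctvs = body without both targets, brain_minus_ctv7000) and
#' the outward "surface" shells of the brainstem and spinal cord (a
#' morphological dilation of thickness `shell_mm` restricted to the body,
#' excluding the core). On grids coarser than `shell_mm` the shell is one
#' voxel thick.
#'
#' @param phantom a [VoxelPhantom-class]
#' @param shell_mm shell thickness in mm (default 3)
#' @return the phantom with structures body_minus_ctvs, brain_minus_ctv7000,
#'   brainstem_surface, spinal_cord_surface added.
#' @export
deriveStructures <- function(phantom, shell_mm = 3) {
  st <- phantom@structures
  for (need in c("ctv7000", "ctv5425", "brainstem", "spinal_cord", "brain")) {
    if (is.null(st[[need]])) .stopf("missing base structure '%s'", need)
  }
  body <- phantom@body
  st$body_minus_ctvs <- body & !(st$ctv7000 | st$ctv5425)
  st$brain_minus_ctv7000 <- st$brain & !st$ctv7000
  st$brainstem_surface <-
    .dilate_mask(st$brainstem, phantom@spacing, shell_mm) & body & !st$brainstem
  st$spinal_cord_surface <-
    .dilate_mask(st$spinal_cord, phantom@spacing, shell_mm) & body & !st$spinal_cord
  # high-dose envelope around the targets; the per-beam dose cap is
  # enforced here during optimization (single-beam maxima arise on the
  # target-crossing ray segments) and verified body-wide at evaluation
  st$ctv_ring <- .dilate_mask(st$ctv7000 | st$ctv5425, phantom@spacing,
                              2.5 * max(phantom@spacing)) & body
  # optimization target volumes: coverage is optimized outside the serial
  # structures and their shells, where hard constraints forbid full dose
  # (the standard planning concession at target/serial-organ interfaces)
  serial <- st$brainstem | st$brainstem_surface | st$spinal_cord |
    st$spinal_cord_surface
  st$ctv7000_opt <- st$ctv7000 & !serial
  st$ctv5425_opt <- st$ctv5425 & !serial
  phantom@structures <- st
  phantom@meta$shell_mm <- shell_mm
  validObject(phantom)
  phantom
}

#' @rdname accessors
#' @export
setMethod("structureNames", "VoxelPhantom", function(x) names(x@structures))

#' @rdname accessors
#' @export
setMethod("structureMask", "VoxelPhantom", function(x, name) {
  if (identical(name, "body")) return(x@body)
  m <- x@structures[[name]]
  if (is.null(m)) .stopf("unknown structure '%s'", name)
  m
})

#' @rdname accessors
#' @export
setMethod("bodyMask", "VoxelPhantom", function(x) x@body)

#' @rdname accessors
#' @export
setMethod("rspMap", "VoxelPhantom", function(x) x@rsp)

#' @rdname accessors
#' @export
setMethod("gridSpacing", "VoxelPhantom", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelVolumeCm3", "VoxelPhantom", function(x) prod(x@spacing) / 1000)

#' @rdname accessors
#' @export
setMethod("structureVolumeCm3", "VoxelPhantom", function(x, name) {
  sum(structureMask(x, name)) * voxelVolumeCm3(x)
})

#' @rdname accessors
#' @export
setMethod("addStructure", "VoxelPhantom", function(x, name, value) {
  stopifnot(is.logical(value), identical(dim(value), x@grid))
  x@structures[[name]] <- value & x@body
  validObject(x)
  x
})
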