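test_that("spot grids cover the targets and respect the beam map", {
  ph <- mini_phantom()
  sp <- mini_spots()
  tab <- spotTable(sp)
  impt <- tab[!tab$is_transmission, ]
  expect_true(all(sort(unique(impt$beam_index)) == 1:6))
  # left/right elective lobes restricted to their beam subsets
  expect_true(all(impt$beam_index[impt$target == "ctv5425_left"] %in% 1:3))
  expect_true(all(impt$beam_index[impt$target == "ctv5425_right"] %in% 4:6))
  # the primary target may use all six beams
  expect_setequal(unique(impt$beam_index[impt$target == "ctv7000"]), 1:6)
  # shifter assignment follows the beam configuration
  expect_true(all(impt$shifter_wet_cm[impt$beam_index %in% 2:5] == 3))
  expect_true(all(impt$shifter_wet_cm[impt$beam_index %in% c(1, 6)] == 0))
})

test_that("IMPT Bragg peaks sit inside target + margin", {
  ph <- mini_phantom()
  cfg <- mini_spot_cfg()
  dose_cfg <- doseModelConfig()
  sp <- mini_spots()
  tab <- spotTable(sp)
  impt <- tab[!tab$is_transmission & tab$target == "ctv7000", ]
  # distance oracle: the geometric peak position of every spot must lie
  # within margin + one voxel diagonal of a target voxel centre
  tgt_xyz <- protonMCO:::.mask_coords(structureMask(ph, "ctv7000"), ph)
  vox_diag <- sqrt(sum(gridSpacing(ph)^2))
  dist_to_target <- vapply(seq_len(nrow(impt)), function(i) {
    frame <- protonMCO:::.beam_frame(impt$gantry_angle[i])
    ray <- protonMCO:::.ray_wet(ph, sp@isocenter, frame, impt$u[i], impt$v[i],
                                c(0, 0, 0), 1, c(-250, 250), 2)
    R_res <- rangeFromEnergy(impt$energy[i], dose_cfg) - impt$shifter_wet_cm[i]
    tpk <- ray$t[which.max(ray$wet >= R_res)]
    p <- sp@isocenter + impt$u[i] * frame$e_u + impt$v[i] * frame$e_v +
      tpk * frame$e_d
    min(sqrt((tgt_xyz[, 1] - p[1])^2 + (tgt_xyz[, 2] - p[2])^2 +
             (tgt_xyz[, 3] - p[3])^2))
  }, numeric(1))
  expect_true(all(dist_to_target <= cfg$target_margin_mm + vox_diag + 1e-9))
})

test_that("halving the lateral spacing quadruples spots per layer", {
  ph <- mini_phantom()
  n_rays <- function(ls) {
    sp <- placeImptSpots(ph, targets = "ctv7000",
                         cfg = spotPlacementConfig(ls, 3))
    tab <- spotTable(sp)
    nrow(unique(tab[, c("beam_index", "u", "v")]))
  }
  ratio <- n_rays(12) / n_rays(24)
  expect_gt(ratio, 2.8); expect_lt(ratio, 5.5)
})

test_that("avoidance filtering removes exactly the rays crossing the mask", {
  ph <- mini_phantom()
  sp <- placeImptSpots(ph, targets = "ctv7000", cfg = mini_spot_cfg())
  # empty avoidance set is the identity
  expect_identical(spotTable(filterAvoidance(sp, ph, character(0))),
                   spotTable(sp))
  # avoidance covering the whole body removes every spot
  ph2 <- addStructure(ph, "all_body", bodyMask(ph))
  expect_equal(nrow(spotTable(filterAvoidance(sp, ph2, "all_body"))), 0L)
})

test_that("an anterior slab blocks exactly the rays that cross it", {
  # slab body with a small central target and an anterior slab on one side
  g <- as.integer(c(24, 24, 24)); spc <- c(4, 4, 4)
  body <- array(TRUE, dim = g); rsp <- array(1, dim = g)
  tgt <- array(FALSE, dim = g); tgt[11:14, 11:14, 11:14] <- TRUE
  slab <- array(FALSE, dim = g); slab[1:8, 3:5, 1:24] <- TRUE  # anterior (low y)
  ph <- new("VoxelPhantom", grid = g, spacing = spc,
            origin = spc / 2 - g * spc / 2, rsp = rsp, body = body,
            structures = list(t = tgt, slab = slab), seed = NA_integer_,
            meta = list())
  beams <- beamConfig(angles = 0, shifter_beams = integer(0),
                      structure_beam_map = list(), avoidance_structures = "slab")
  sp <- placeImptSpots(ph, beams, targets = "t",
                       cfg = spotPlacementConfig(6, 1.5, target_margin_mm = 0))
  filtered <- filterAvoidance(sp, ph, "slab")
  # oracle: beam at 0 deg travels +y; a ray crosses the slab iff its x
  # coordinate (u maps to x for angle 0) falls in the slab's x range
  ax <- protonMCO:::.axis_coords(ph)
  iso <- sp@isocenter
  slab_x <- range(ax$x[1:8])
  tab <- spotTable(sp)
  spot_x <- iso[1] + tab$u * cos(0)          # e_u = +x at gantry 0
  should_block <- spot_x >= slab_x[1] - 2 & spot_x <= slab_x[2] + 2
  expect_setequal(setdiff(tab$spot_id, spotTable(filtered)$spot_id),
                  tab$spot_id[should_block])
})

test_that("transmission duplication contract holds", {
  ph <- mini_phantom()
  sp <- mini_spots()
  tab <- spotTable(sp)
  tb <- tab[tab$is_transmission, ]
  impt <- tab[!tab$is_transmission, ]
  expect_true(all(tb$energy == 244))
  expect_true(all(tb$shifter_wet_cm == 0))
  # one transmission candidate per distinct (beam, lateral position)
  expect_equal(nrow(tb),
               nrow(unique(impt[, c("beam_index", "u", "v")])))
  # IMPT candidate records are a subset of the union set
  expect_true(all(impt$spot_id %in% tab$spot_id))
  # 2n duplication for all-distinct lateral positions
  one <- impt[!duplicated(paste(impt$beam_index, impt$u, impt$v)), ]
  one$spot_id <- seq_len(nrow(one))
  ss <- new("SpotSet", spots = one, isocenter = sp@isocenter, meta = list())
  expect_equal(nrow(spotTable(duplicateAsTransmission(ss))), 2L * nrow(one))
  # merge rule: same ray, two energies -> 3 candidates
  two <- one[c(1, 1), ]; two$energy <- c(100, 140); two$spot_id <- 1:2
  ss2 <- new("SpotSet", spots = two, isocenter = sp@isocenter, meta = list())
  expect_equal(nrow(spotTable(duplicateAsTransmission(ss2))), 3L)
})

test_that("transmission Bragg peaks lie beyond the body on every ray", {
  ph <- mini_phantom()
  sp <- mini_spots()
  tab <- spotTable(sp)
  tb <- tab[tab$is_transmission, ]
  dose_cfg <- doseModelConfig()
  R244 <- rangeFromEnergy(244, dose_cfg)
  wet_max <- vapply(seq_len(nrow(tb)), function(i) {
    frame <- protonMCO:::.beam_frame(tb$gantry_angle[i])
    ray <- protonMCO:::.ray_wet(ph, sp@isocenter, frame, tb$u[i], tb$v[i],
                                c(0, 0, 0), 1, c(-250, 250), 3)
    max(ray$wet)
  }, numeric(1))
  expect_true(all(wet_max < R244))
})
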