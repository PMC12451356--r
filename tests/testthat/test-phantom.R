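test_that("phantom generation is bit-reproducible from the seed", {
  a <- generatePhantom(phantomConfig(seed = 7L, preset = "mini"))
  b <- generatePhantom(phantomConfig(seed = 7L, preset = "mini"))
  expect_identical(a@rsp, b@rsp)
  expect_identical(a@body, b@body)
  expect_identical(a@structures, b@structures)
  c <- generatePhantom(phantomConfig(seed = 8L, preset = "mini"))
  expect_false(identical(a@structures$ctv7000, c@structures$ctv7000))
})

test_that("synthesized target volumes stay inside the configured bounds", {
  for (seed in 1:30) {
    ph <- generatePhantom(phantomConfig(seed = seed, preset = "mini"))
    v7 <- structureVolumeCm3(ph, "ctv7000")
    v54 <- structureVolumeCm3(ph, "ctv5425")
    expect_gte(v7, 27.3); expect_lte(v7, 408.7)
    expect_gte(v54, 256.6); expect_lte(v54, 565.3)
  }
})

test_that("primary target abuts but never overlaps the brainstem", {
  ph <- mini_phantom()
  ctv <- structureMask(ph, "ctv7000")
  bs <- structureMask(ph, "brainstem")
  expect_false(any(ctv & bs))
  # distance oracle: minimum pairwise voxel-centre distance <= one voxel diagonal
  a <- protonMCO:::.mask_coords(ctv, ph)
  b <- protonMCO:::.mask_coords(bs, ph)
  dmin <- min(apply(b, 1, function(p) {
    min(sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - p[3])^2))
  }))
  expect_lte(dmin, sqrt(sum(gridSpacing(ph)^2)) + 1e-9)
})

test_that("a positive target-brainstem gap separates the surfaces", {
  ph <- generatePhantom(phantomConfig(seed = 5L, preset = "mini", ctv_oar_gap = 15))
  a <- protonMCO:::.mask_coords(structureMask(ph, "ctv7000"), ph)
  b <- protonMCO:::.mask_coords(structureMask(ph, "brainstem"), ph)
  dmin <- min(apply(b, 1, function(p) {
    min(sqrt((a[, 1] - p[1])^2 + (a[, 2] - p[2])^2 + (a[, 3] - p[3])^2))
  }))
  expect_gt(dmin, gridSpacing(ph)[1])   # clearly separated
})

test_that("structure masks live inside the body and rsp is consistent", {
  ph <- mini_phantom()
  body <- bodyMask(ph)
  for (nm in structureNames(ph)) {
    expect_false(any(structureMask(ph, nm) & !body), info = nm)
  }
  expect_true(all(rspMap(ph)[body] > 0))
  expect_true(all(rspMap(ph)[!body] == 0))
})

test_that("derived structures satisfy the set identities", {
  ph <- mini_phantom()
  body <- bodyMask(ph)
  bmc <- structureMask(ph, "body_minus_ctvs")
  c7 <- structureMask(ph, "ctv7000")
  c54 <- structureMask(ph, "ctv5425")
  expect_identical(bmc | c7 | c54, body)
  expect_false(any(bmc & c7)); expect_false(any(bmc & c54))
  expect_false(any(c7 & c54))
  # voxel-count identity against direct mask counting
  expect_identical(sum(bmc), sum(body) - sum(c7 | c54))
  # shells are disjoint from their cores
  expect_false(any(structureMask(ph, "brainstem_surface") &
                   structureMask(ph, "brainstem")))
  expect_false(any(structureMask(ph, "spinal_cord_surface") &
                   structureMask(ph, "spinal_cord")))
  expect_gt(sum(structureMask(ph, "brainstem_surface")), 0)
})

test_that("unsatisfiable volume bounds fail naming the structure", {
  cfg <- phantomConfig(seed = 1L, preset = "mini",
                       ctv7000_volume_bounds = c(27.3, 50),
                       ctv7000_volume_draw = c(100, 260))
  expect_error(generatePhantom(cfg), "ctv7000")
})

test_that("deriveStructures demands its base structures", {
  ph <- generatePhantom(phantomConfig(seed = 2L, preset = "mini"))
  ph@structures$brain <- NULL
  expect_error(deriveStructures(ph), "brain")
})

test_that("heterogeneity inserts change rsp only inside the body", {
  ph <- generatePhantom(phantomConfig(seed = 4L, preset = "mini",
                                      heterogeneity = TRUE))
  expect_true(any(rspMap(ph) > 1))       # bone
  expect_true(any(rspMap(ph)[bodyMask(ph)] < 1))  # air sinus
  expect_true(all(rspMap(ph)[!bodyMask(ph)] == 0))
})
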