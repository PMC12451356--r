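test_that("range-energy relation follows the power law", {
  cfg <- doseModelConfig()
  # frozen value computed independently: 0.0022 * exp(1.77 * log(244))
  expect_equal(rangeFromEnergy(244, cfg), 0.0022 * exp(1.77 * log(244)),
               tolerance = 1e-12)
  expect_equal(rangeFromEnergy(244, cfg), 36.9, tolerance = 0.01)
  # doubling the energy scales the range by 2^p
  expect_equal(rangeFromEnergy(200, cfg) / rangeFromEnergy(100, cfg), 2^1.77,
               tolerance = 1e-12)
  expect_true(all(diff(rangeFromEnergy(seq(50, 250, 5), cfg)) > 0))
  expect_error(rangeFromEnergy(-5, cfg), "positive")
})

test_that("depth dose is a plateau plus Bragg peak with hard distal cutoff", {
  cfg <- doseModelConfig()
  E <- 120
  R <- rangeFromEnergy(E, cfg)
  sB <- cfg$bragg_width_mm / 10
  z <- seq(0, R + 10, by = 0.01)
  d <- depthDose(E, z, cfg)
  expect_true(all(d >= 0))
  # argmax within one peak width of the range (dense grid search oracle)
  zmax <- z[which.max(d)]
  expect_gte(zmax, R - sB); expect_lte(zmax, R + sB)
  # zero beyond the cutoff; far tail within 1e-6 of zero relative to peak
  expect_equal(depthDose(E, R + 5 * sB, cfg), 0, tolerance = 1e-6)
  expect_true(all(depthDose(E, z[z > R + 3 * sB], cfg) == 0))
  # plateau-to-peak ratio < 1
  expect_lt(depthDose(E, 0.1, cfg), max(d))
  expect_error(depthDose(E, -1, cfg), "wet_depth")
})

test_that("transmission spot dose inside the patient sits on a flat plateau", {
  cfg <- doseModelConfig()
  z <- seq(0.5, 25, by = 0.1)       # typical head-and-neck path lengths, cm
  d <- depthDose(244, z, cfg)
  # non-increasing within 2 %
  expect_true(all(diff(d) <= 0 | abs(diff(d)) / max(d) < 0.02))
  expect_lt((max(d) - min(d)) / max(d), 0.02)
})

test_that("lateral sigma is monotone in depth and widened by the shifter", {
  cfg <- doseModelConfig()
  z <- seq(0, 15, by = 0.5)
  E <- ((15 + 3) / cfg$alpha)^(1 / cfg$p)  # peak at 15 cm after 3 cm shifter
  s0 <- lateralSigma(E, z, 0, cfg)
  s3 <- lateralSigma(E, z, 3, cfg)
  expect_true(all(diff(s0) >= 0))
  expect_true(all(s3 > s0))
  expect_equal(lateralSigma(E, 0, 0, cfg), cfg$sigma0_mm)
  # at equal depth the 244 MeV spot is never wider than the in-target spot
  for (depth in c(5, 10, 15)) {
    E_in <- (depth / cfg$alpha)^(1 / cfg$p)
    expect_lte(lateralSigma(244, depth, 0, cfg),
               lateralSigma(E_in, depth, 0, cfg))
  }
})

test_that("transmission penumbra beats the range-shifted penumbra at depth", {
  cfg <- doseModelConfig()
  for (depth in seq(0, 15, by = 1)) {
    E_in <- ((depth + 3) / cfg$alpha)^(1 / cfg$p)
    expect_lt(penumbra8020(244, depth, 0, cfg),
              penumbra8020(E_in, depth, 3, cfg))
  }
  # numeric profile-width oracle: for a Gaussian the 80-20 width is
  # (sqrt(2 log(1/0.2)) - sqrt(2 log(1/0.8))) * sigma
  w <- penumbra8020(244, 10, 0, cfg)
  s <- lateralSigma(244, 10, 0, cfg)
  expect_equal(w / s, sqrt(-2 * log(0.2)) - sqrt(-2 * log(0.8)), tolerance = 5e-3)
})

# --- influence matrix ------------------------------------------------------

slab_phantom <- function(spacing = c(4, 4, 4), n = 40L) {
  g <- as.integer(c(n, n, n))
  body <- array(TRUE, dim = g)
  rsp <- array(1, dim = g)
  new("VoxelPhantom", grid = g, spacing = spacing,
      origin = spacing / 2 - g * spacing / 2,
      rsp = rsp, body = body,
      structures = list(), seed = NA_integer_, meta = list())
}

single_spot <- function(energy, angle = 0, shifter = 0) {
  new("SpotSet",
      spots = data.frame(spot_id = 1L, beam_index = 1L, gantry_angle = angle,
                         u = 0, v = 0, energy = energy, shifter_wet_cm = shifter,
                         is_transmission = FALSE, target = "t",
                         stringsAsFactors = FALSE),
      isocenter = c(0, 0, 0), meta = list())
}

nominal_row <- data.frame(id = "nominal", sx = 0, sy = 0, sz = 0,
                          range_factor = 1, stringsAsFactors = FALSE)

test_that("influence matrices are non-negative, linear and sparse by cutoff", {
  ph <- mini_phantom()
  sp <- subsetSpots(mini_spots(), 1:25)
  infl <- computeInfluence(ph, sp, nominal_row)
  M <- infl@mat
  expect_true(all(M@x >= 0))
  expect_true(all(is.finite(M@x)))
  # dose linearity is exact
  w1 <- runif(ncol(M)); w2 <- runif(ncol(M))
  expect_equal(doseFromWeights(infl, w1 + w2),
               doseFromWeights(infl, w1) + doseFromWeights(infl, w2),
               tolerance = 1e-12)
  # empty spot set -> zero columns
  infl0 <- computeInfluence(ph, subsetSpots(sp, integer(0)), nominal_row)
  expect_equal(ncol(infl0@mat), 0L)
})

test_that("a +3% range scenario pulls the Bragg peak proximally by 1/1.03", {
  ph <- slab_phantom(spacing = c(2, 2, 2), n = 80L)   # 16 cm slab
  sp <- single_spot(((10) / 0.0022)^(1 / 1.77))        # peak at 10 cm
  cfg <- doseModelConfig()
  d_nom <- doseFromWeights(computeInfluence(ph, sp, nominal_row, cfg), 1)
  over_row <- nominal_row; over_row$range_factor <- 1.03; over_row$id <- "rp"
  d_over <- doseFromWeights(computeInfluence(ph, sp, over_row, cfg), 1)
  # beam travels +y through the slab; peak depth along the central axis
  ax <- d_nom[40, , 40]; axo <- d_over[40, , 40]
  y <- protonMCO:::.axis_coords(ph)$y
  entry <- y[1] - 1                                   # slab entry face
  depth_nom <- y[which.max(ax)] - entry
  depth_over <- y[which.max(axo)] - entry
  expect_equal(depth_over / depth_nom, 1 / 1.03, tolerance = 0.03)
})

test_that("a pure lateral shift scenario translates the dose grid", {
  ph <- slab_phantom(spacing = c(3, 3, 3), n = 30L)
  sp <- single_spot((8 / 0.0022)^(1 / 1.77))
  shift_row <- data.frame(id = "sx", sx = 3, sy = 0, sz = 0, range_factor = 1)
  d0 <- doseFromWeights(computeInfluence(ph, sp, nominal_row), 1)
  d1 <- doseFromWeights(computeInfluence(ph, sp, shift_row), 1)
  # exactly one voxel of translation along x (interior compared)
  err_a <- max(abs(d1[2:29, 2:29, 2:29] - d0[1:28, 2:29, 2:29]))
  err_b <- max(abs(d1[1:28, 2:29, 2:29] - d0[2:29, 2:29, 2:29]))
  expect_lt(min(err_a, err_b), 1e-9 + 1e-6 * max(d0))
})

test_that("a spot axis that misses the body yields a zero column and warning", {
  ph <- mini_phantom()
  sp <- single_spot(150)
  sp@spots$u <- 500   # far outside the body
  sp@isocenter <- colMeans(protonMCO:::.mask_coords(structureMask(ph, "ctv7000"), ph))
  expect_warning(infl <- computeInfluence(ph, sp, nominal_row), "misses the body")
  expect_equal(sum(infl@mat), 0)
})
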