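# Shared fixtures. Heavy objects are built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small phantom used by most unit tests
mini_phantom <- function(seed = 11L) {
  fixture(paste0("phantom_", seed), function() {
    deriveStructures(generatePhantom(phantomConfig(seed = seed, preset = "mini")))
  })
}

mini_spot_cfg <- function() spotPlacementConfig(lateral_spacing_mm = 24,
                                                energy_layer_wet_cm = 3.2)

mini_spots <- function(seed = 11L) {
  fixture(paste0("spots_", seed), function() {
    ph <- mini_phantom(seed)
    sp <- placeImptSpots(ph, cfg = mini_spot_cfg())
    sp <- filterAvoidance(sp, ph, "avoid_dental")
    duplicateAsTransmission(sp, mini_spot_cfg())
  })
}

# complete two-variant planning run at the test scale (used by several
# acceptance properties; computed once)
mini_plan_run <- function(seed = 11L) {
  fixture(paste0("run_", seed), function() {
    ph <- mini_phantom(seed)
    cfg <- runConfig(seed = seed, preset = "mini",
                     spot_cfg = spotPlacementConfig(26, 3.4))
    plans <- planImptAndTb(ph, cfg)
    c(plans, list(phantom = ph, config = cfg))
  })
}

# random small lexicographic instances for oracle comparisons
random_lex_instance <- function(n_spots, n_vox, n_obj = 2, n_scen = 1) {
  infl <- lapply(seq_len(n_scen), function(s) {
    # dense positive entries keep the simplex oracle away from degenerate
    # bases while exercising the same formulation
    M <- matrix(stats::runif(n_vox * n_spots, 0.05, 1), n_vox, n_spots)
    Matrix::Matrix(M, sparse = TRUE)
  })
  names(infl) <- c("nominal", if (n_scen > 1) sprintf("err%d", seq_len(n_scen - 1)))
  # two disjoint structures: a "target" and an "oar"
  half <- floor(n_vox / 2)
  structures <- list(target = seq_len(half), oar = (half + 1):n_vox)
  cns <- data.frame(structure = "oar", metric = "max_dose",
                    bound = stats::runif(1, 2, 4), robust = n_scen > 1,
                    stringsAsFactors = FALSE)
  types <- c("mean_underdose", sample(c("max_dose", "mean_dose"), n_obj - 1,
                                      replace = TRUE))
  obs <- data.frame(
    priority = seq_len(n_obj),
    structure = c("target", rep("oar", n_obj - 1)),
    type = types,
    goal = c(stats::runif(1, 3, 6), rep(0, n_obj - 1)),
    robust = c(n_scen > 1, rep(FALSE, n_obj - 1)),
    sufficient = FALSE, stringsAsFactors = FALSE)
  list(influences = infl, structures = structures,
       wishlist = wishList(cns, obs, slack = 1.03))
}
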