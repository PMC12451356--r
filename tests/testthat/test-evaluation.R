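test_that("goal thresholds reproduce the printed absolute values", {
  th <- goalThresholds(prescriptionConfig())
  expect_equal(unname(th$ctv7000["d98"]), 66.5)
  expect_equal(unname(th$ctv7000["d98_vwmin"]), 65.8)
  expect_equal(unname(th$ctv7000["d2"]), 74.9)
  expect_equal(unname(th$ctv5425["d98"]), 51.5)
  expect_equal(unname(th$ctv5425["d98_vwmin"]), 51.0)
})

test_that("DVH metrics on constructed distributions match hand values", {
  mask <- array(TRUE, dim = c(10, 10, 1))
  uni <- array(60, dim = c(10, 10, 1))
  expect_equal(dvhMetric(uni, mask, "D98%"), 60)
  expect_equal(dvhMetric(uni, mask, "D2%"), 60)
  expect_equal(dvhMetric(uni, mask, "Dmean"), 60)
  # 100-voxel linear ramp 1..100: D50% = 51 under the ">= d" convention
  ramp <- array(as.numeric(1:100), dim = c(10, 10, 1))
  expect_equal(dvhMetric(ramp, mask, "D50%"), 51)
  expect_equal(dvhMetric(ramp, mask, "D2%"), 99)
  expect_equal(dvhMetric(ramp, mask, "D100%"), 1)
  # VxGy with everything below threshold
  expect_equal(dvhMetric(uni, mask, "V61Gy", voxel_volume_cm3 = 0.5), 0)
  expect_equal(dvhMetric(ramp, mask, "V51Gy", voxel_volume_cm3 = 0.5), 25)
  # absolute-volume metric: interpolation on the hot tail
  expect_equal(dvhMetric(ramp, mask, "D1cm3", voxel_volume_cm3 = 1), 100)
  # sub-voxel request extrapolates to the hottest voxel
  expect_equal(dvhMetric(ramp, mask, "D0.03cm3", voxel_volume_cm3 = 0.5), 100)
  expect_error(dvhMetric(ramp, mask, "D51cm3", voxel_volume_cm3 = 0.5),
               "exceeds")
  expect_error(dvhMetric(ramp, array(FALSE, dim = dim(mask)), "Dmean"),
               "empty")
})

test_that("DVH metrics match an exhaustive sort oracle on random doses", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(40:120, 1)
    mask <- array(FALSE, dim = c(8, 8, 4))
    mask[sample(length(mask), n)] <- TRUE
    dose <- array(runif(length(mask), 0, 80), dim = dim(mask))
    d <- sort(dose[mask], decreasing = TRUE)
    for (x in c(2, 50, 98)) {
      v <- x / 100 * n
      oracle <- if (v <= 1) d[1] else {
        lo <- floor(v); hi <- ceiling(v)
        if (lo == hi) d[lo] else d[lo] + (v - lo) * (d[hi] - d[lo])
      }
      expect_equal(dvhMetric(dose, mask, sprintf("D%d%%", x)), oracle,
                   tolerance = 1e-12)
    }
    # hot-tail ordering on the same dose
    expect_gte(dvhMetric(dose, mask, "D2%"), dvhMetric(dose, mask, "Dmean") - 1e-12)
    # Dx% non-increasing in x
    dx <- vapply(c(2, 10, 50, 90, 98), function(x) {
      dvhMetric(dose, mask, sprintf("D%d%%", x))
    }, numeric(1))
    expect_true(all(diff(dx) <= 1e-12))
  }
})

test_that("conformity index matches brute-force set counting", {
  g <- c(10, 10, 3)
  tgt <- array(FALSE, dim = g); tgt[3:7, 3:7, 2] <- TRUE   # 25 voxels
  # PIV identical to the target -> CI 1
  dose <- array(0, dim = g); dose[tgt] <- 70
  expect_equal(conformityIndex(dose, tgt, 70), 1)
  # worked example: |T| = 100, |PIV| = 100, overlap 50 -> CI 0.25
  t2 <- array(FALSE, dim = c(20, 10, 1)); t2[1:10, , 1] <- TRUE
  d2 <- array(0, dim = dim(t2)); d2[6:15, , 1] <- 70
  expect_equal(conformityIndex(d2, t2, 70), 50^2 / (100 * 100))
  # empty PIV -> 0
  expect_equal(conformityIndex(array(0, dim = g), tgt, 70), 0)
  # random masks vs direct counting
  set.seed(5)
  for (rep in 1:8) {
    dose <- array(runif(prod(g), 0, 80), dim = g)
    tgt_r <- array(runif(prod(g)) < 0.3, dim = g)
    if (!any(tgt_r)) next
    piv <- dose >= 0.95 * 70
    oracle <- if (!any(piv)) 0 else sum(piv & tgt_r)^2 / (sum(tgt_r) * sum(piv))
    expect_equal(conformityIndex(dose, tgt_r, 70), oracle)
  }
  expect_error(conformityIndex(dose, array(FALSE, dim = g), 70), "empty")
})

test_that("NTCP logistic evaluates the closed form and is monotone", {
  m <- ntcpModel("toy", ">=2", -2, list(
    list(structures = "parotid_l", transform = "linear", coef = 0.05)))
  # independent evaluation: 100 / (1 + exp(1)) at Dmean = 20
  expect_equal(ntcp(c(parotid_l = 20), m), 100 / (1 + exp(1)), tolerance = 1e-9)
  expect_equal(ntcp(c(parotid_l = 20), m), 26.894, tolerance = 1e-3)
  # intercept only
  m0 <- ntcpModel("toy", ">=2", -1.5, list())
  expect_equal(ntcp(numeric(0), m0), 100 * stats::plogis(-1.5))
  # strict monotonicity in a positive-coefficient dose term
  vals <- vapply(seq(0, 60, 5), function(d) ntcp(c(parotid_l = d), m), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 100))
  expect_error(ntcp(c(other = 1), m), "parotid_l")
})

test_that("a zero-weight plan evaluates to zero dose everywhere", {
  ph <- mini_phantom()
  sp <- subsetSpots(mini_spots(), 1:5)
  plan <- new("PlanSolution", weights = rep(0, 5), spots = sp,
              achieved = data.frame(), active = integer(0),
              tb_fraction = NA_real_, log = character(), meta = list())
  ev <- evaluatePlan(ph, plan, buildEvaluationScenarios(),
                     ntcp_models = defaultNtcpModels())
  mt <- metricTable(ev)
  expect_true(all(mt$value == 0))
  expect_true(all(ev@per_beam_max$max_dose == 0))
  # NTCP at zero dose collapses to the intercept
  expect_equal(ntcpTable(ev)$value_pct[1],
               100 * stats::plogis(defaultNtcpModels()[[1]]$intercept))
})

test_that("shipped NTCP YAML matches the constructor defaults", {
  path <- system.file("extdata", "ntcp", "ntcp_models_synthetic.yaml",
                      package = "protonMCO")
  skip_if(path == "", "extdata not installed")
  models <- readNtcpModels(path)
  ref <- defaultNtcpModels()
  expect_setequal(names(models), names(ref))
  for (nm in names(ref)) {
    expect_equal(ntcp(c(parotid_l = 20, parotid_r = 30, oral_cavity = 15,
                        pcm_superior = 40), models[[nm]]),
                 ntcp(c(parotid_l = 20, parotid_r = 30, oral_cavity = 15,
                        pcm_superior = 40), ref[[nm]]))
  }
})
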