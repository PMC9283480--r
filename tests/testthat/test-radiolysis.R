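# Effective G(HO.): gas saturation, Gd3+ enhancement, scavenger competition,
# Fenton budget.

test_that("source presets carry the measured baseline yields", {
  expect_equal(ir_source("GR")$g_ho_base, 0.280)
  expect_equal(ir_source("XR")$g_ho_base, 0.200)
  expect_equal(ir_source("E")$g_ho_base, 0.280)
  expect_identical(ir_source("E")$particle, "electron")
  expect_error(radiation_source("hot", "photon", 662, 1.5), "low-LET")
})

test_that("N2O doubles G(HO.) and N2 leaves it unchanged", {
  gr <- ir_source("GR")
  expect_equal(effective_g_ho(gr, solution_conditions())$value_umol_per_J,
               0.280)
  expect_equal(effective_g_ho(gr, solution_conditions(gas = "N2O"))$value_umol_per_J,
               0.56)
  expect_equal(effective_g_ho(gr, solution_conditions(gas = "N2"))$value_umol_per_J,
               0.280)
})

test_that("N2O doubling holds at every Gd concentration", {
  gr <- ir_source("GR")
  for (gd in c(0, 10, 137, 500, 2000)) {
    g_water <- effective_g_ho(gr, solution_conditions(gd_concentration_uM = gd))
    g_n2o <- effective_g_ho(gr, solution_conditions(gas = "N2O",
                                                    gd_concentration_uM = gd))
    expect_equal(g_n2o$value_umol_per_J, 2 * g_water$value_umol_per_J)
  }
})

test_that("Gd enhancement hits the measured maxima and is 0 without Gd", {
  expect_identical(gd_enhancement(0), 0)
  expect_equal(gd_enhancement(500, gd_curve("GR")), 0.20)
  expect_equal(gd_enhancement(200, gd_curve("XR")), 0.33)
  expect_equal(effective_g_ho("GR",
               solution_conditions(gd_concentration_uM = 500))$value_umol_per_J,
               0.280 * 1.20)
})

test_that("Gd curve is continuous and its maximum equals the anchored one", {
  for (src in c("GR", "XR")) {
    cv <- gd_curve(src)
    grid <- seq(0, 2000, by = 1)
    v <- gd_enhancement(grid, cv)
    expect_true(all(is.finite(v)))
    expect_true(all(v >= -1))
    expect_lt(max(abs(diff(v))), 0.02)  # no jumps on a 1 uM grid
    expect_equal(max(v), max(cv$anchor_factors), tolerance = 1e-12)
    # shape: rises from 0, then declines at the high end
    expect_gt(v[which(grid == 200)], 0)
    expect_lt(v[length(v)], max(v))
  }
})

test_that("concentrations beyond the anchors warn and clamp", {
  expect_warning(v <- gd_enhancement(3000), "anchored range")
  expect_equal(v, gd_enhancement(2000))
})

test_that("scavenging fractions sum to one and respect k*c symmetry", {
  one <- scavenging_fractions(list(scavenger_preset("coumarin", 5e-4)))
  expect_equal(unname(one), 1.0)
  # equal scavenging powers: 1.05e10 * 5e-4 == 1.05e9 * 5e-3
  two <- scavenging_fractions(list(
    scavenger_preset("coumarin", 5e-4),
    scavenger("other", 5e-3, 1.05e9)))
  expect_equal(unname(two), c(0.5, 0.5))
  set.seed(7)
  panel <- lapply(1:6, function(i) scavenger(paste0("s", i),
                                             stats::runif(1, 1e-4, 1),
                                             stats::runif(1, 1e6, 1e10)))
  fr <- scavenging_fractions(panel)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(fr >= 0))
  # adding a zero-concentration scavenger changes nothing
  fr2 <- scavenging_fractions(c(panel, list(scavenger("zero", 0, 1e9))))
  expect_equal(fr2[names(fr)], fr)
})

test_that("degenerate competition errors", {
  expect_error(scavenging_fractions(list(scavenger("z", 0, 1e9))),
               "degenerate")
  expect_error(scavenging_fractions(list()), "at least one")
})

test_that("oxidising fraction removes quencher shares only", {
  expect_equal(oxidising_fraction(list()), 1.0)
  # pure quencher takes everything
  expect_equal(oxidising_fraction(list(scavenger_preset("tBuOH", 0.524))), 0)
  # pure converter leaves the budget intact
  expect_equal(oxidising_fraction(list(scavenger_preset("NaN3", 0.05))), 1)
  mixed <- list(scavenger("q", 1e-3, 1e9, ho_fate = "quench"),
                scavenger("c", 1e-3, 1e9, ho_fate = "convert_to_oxidant"))
  expect_equal(oxidising_fraction(mixed), 0.5)
})

test_that("coumarin preset carries the probe rate constant", {
  expect_equal(scavenger_preset("coumarin", 5e-4)$rate_constant_ho, 1.05e10)
  expect_error(scavenger_preset("unobtainium", 1), "unknown")
})

test_that("Fenton budget is zero at zero inputs and monotone in each", {
  expect_identical(fenton_ho_budget(0, 75, 5), 0)
  expect_identical(fenton_ho_budget(50, 0, 5), 0)
  expect_identical(fenton_ho_budget(50, 75, 0), 0)
  b1 <- fenton_ho_budget(50, 75, 5)
  expect_gte(fenton_ho_budget(50, 75, 10), b1)
  expect_gte(fenton_ho_budget(100, 75, 5), b1)
  expect_gte(fenton_ho_budget(50, 150, 5), b1)
})

test_that("Fenton defaults reproduce the observed trans jump through inversion", {
  # the 50 mM H2O2 / 75 uM Fe / 5 min budget, read back through the
  # monoexponential at the water G(HO.), must land on the 16.7% -> 48.4% jump
  budget_uM <- fenton_ho_budget(50, 75, 5)
  d_eq <- budget_uM / 0.28
  after <- radiation_activate(isomer_state(0.167), d_eq)$trans_fraction
  expect_equal(after, 0.484, tolerance = 1e-3)
})
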