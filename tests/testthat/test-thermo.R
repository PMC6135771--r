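# Folding thermodynamics estimators.

test_that("classification thresholds split folded / intermediate / unfolded", {
  lab <- classifyState(c(7, 4, 3, 2, 1, 0))
  expect_identical(as.character(lab),
                   c("folded", "folded", "intermediate", "intermediate",
                     "unfolded", "unfolded"))
  expect_error(classifyState(3, foldedMin = 2, unfoldedMax = 4), "strictly")
  expect_error(classifyState(-1), "negative")
})

test_that("deltaG reproduces the closed forms and is antisymmetric", {
  # reduced units: Pf = 0.8, Pu = 0.2 -> -ln 4
  expect_equal(deltaG(0.8, 0.2, 1, kB = 1), -log(4), tolerance = 1e-12)
  expect_identical(deltaG(0.4, 0.4, 300), 0)
  expect_equal(deltaG(0.2, 0.5, 300), -deltaG(0.5, 0.2, 300))
  expect_error(deltaG(0.5, 0, 300), "folded")
  # folded-fraction estimator at the GB1m3 measurement point
  dg <- deltaGFromFoldedFraction(0.86, 298)
  expect_equal(signif(dg, 2), -1.1)
  expect_equal(dg, -gasConstantKcal() * 298 * log(0.86 / 0.14),
               tolerance = 1e-12)
})

test_that("deltaU differences sub-ensemble means per component", {
  lab <- classifyState(c(7, 7, 0, 0))
  en <- data.frame(total = c(-10, -10, -1, -1),
                   a = c(-6, -6, -1, -1), b = c(-4, -4, 0, 0))
  du <- deltaU(en, lab)
  expect_equal(du$total, -9)
  expect_equal(unname(du$components), c(-5, -4))
  expect_equal(sum(du$components), du$total)
  # identical distributions in both states: zero everywhere
  en2 <- data.frame(total = c(-3, -3, -3, -3), a = rep(-3, 4))
  expect_equal(deltaU(en2, lab)$total, 0)
  expect_error(deltaU(en, classifyState(c(7, 7, 7, 7))), "folded-dominated")
  # antisymmetry under relabeling
  swap <- factor(c("unfolded", "unfolded", "folded", "folded"),
                 levels = levels(lab))
  expect_equal(deltaU(en, swap)$total, -du$total)
})

test_that("electrostatic component combination follows the sum rule", {
  # printed per-term folding energies: Elec + GB
  hp5a <- combineComponents(c(Elec = 12.2, GB = -9.7),
                            list(elec_gb = c("Elec", "GB")))
  gb1p <- combineComponents(c(Elec = -14.9, GB = 7.9),
                            list(elec_gb = c("Elec", "GB")))
  expect_equal(unname(hp5a), 2.5)
  expect_equal(unname(gb1p), -7.0)
  expect_error(combineComponents(c(a = 1), list(x = c("a", "zz"))),
               "unknown component")
})

test_that("deltaS applies (dU - dG)/T with the cal/mol/K convention", {
  expect_equal(deltaS(-9.9, -0.44, 270), -35.03704, tolerance = 1e-5)
  expect_identical(deltaS(-3, -3, 100), 0)
  expect_lt(deltaS(-5, -1, 300), 0)  # dU < dG => dS < 0
  expect_equal(deltaS(-2, -1, 2, unit = "reduced"), -0.5)
})

test_that("melting temperature interpolates dG(T) and reports bounds", {
  # exact ladder hit
  tm <- meltingTemperature(c(300, 340), c(0.4, 0.2), c(0.4, 0.6))
  expect_equal(tm$Tm, 300)
  # symmetric linear dG crossing: -0.5 at 300 K, +0.5 at 340 K
  pf <- c(exp(0.5 / 300) / (1 + exp(0.5 / 300)),
          exp(-0.5 / 340) / (1 + exp(-0.5 / 340)))
  tm2 <- meltingTemperature(c(300, 340), pf, 1 - pf, kB = 1)
  expect_equal(tm2$Tm, 320, tolerance = 0.5)
  # never folded -> "<Tmin"; always folded -> ">Tmax"
  expect_identical(
    meltingTemperature(c(270, 300), c(0.1, 0.05), c(0.7, 0.8))$bound,
    "<270")
  expect_identical(
    meltingTemperature(c(270, 300), c(0.9, 0.8), c(0.05, 0.1))$bound,
    ">300")
  # multiple crossings: lowest returned with a warning
  expect_warning(
    tm3 <- meltingTemperature(c(1, 2, 3, 4), c(0.6, 0.4, 0.6, 0.4),
                              c(0.4, 0.6, 0.4, 0.6)),
    "multiple")
  expect_lt(tm3$Tm, 2)
})

test_that("half-split SE is |half difference| / 2, NA when undefined", {
  expect_equal(halfSplitSE(mean, c(1, 1, 3, 3)), 1)
  expect_equal(halfSplitSE(mean, rep(2, 10)), 0)
  # estimates of -0.3 and -0.5 -> SE 0.1
  vals <- c(rep(-0.3, 4), rep(-0.5, 4))
  expect_equal(halfSplitSE(mean, vals), 0.1)
  # undefined on a half -> NA, not zero
  f <- function(x) if (all(x > 0)) mean(x) else stop("empty state")
  expect_true(is.na(halfSplitSE(f, c(-1, -1, 2, 2))))
})

test_that("full analysis matches the zipper oracle in two-state mode", {
  zm <- zipperPreset("GB1p-like")
  run <- runREX(zipperSamplerModel(zm), buildLadder(1.0, 2.5, 6),
                rexConfig(15000, 10, seed = 41))
  th <- analyzeThermo(run)
  tab <- thermoTable(th)
  expect_true(all(tab$mode == "two_state"))
  for (i in seq_len(nrow(tab))) {
    ex <- zipperExact(zm, tab$temperature[i])
    expect_lt(abs(tab$Pf[i] - ex$Pf), 3 * max(tab$se_Pf[i], 0.01) + 0.02)
    if (ex$Pf < 0.05) next  # dG/dU too noisy where a state is barely populated
    expect_lt(abs(tab$dG[i] - ex$dG), 3 * max(tab$se_dG[i], 0.07) + 0.07)
    expect_lt(abs(tab$dU[i] - ex$dU), 3 * max(tab$se_dU[i], 0.07) + 0.07)
    # entropy identity is exact by construction
    expect_equal(tab$dS[i], (tab$dU[i] - tab$dG[i]) / tab$temperature[i],
                 tolerance = 1e-12)
  }
  # sampled Tm within one ladder spacing of the exact crossing
  exTm <- zipperExactTm(zm)
  spacing <- diff(temperatures(run))[1]
  expect_lt(abs(meltingPoint(th) - exTm), spacing)
})

test_that("folded-dominated mode triggers when the unfolded state is absent", {
  zm <- zipperPreset("GB1m3-like")
  run <- runREX(zipperSamplerModel(zm), buildLadder(1.0, 2.0, 4),
                rexConfig(6000, 10, seed = 43))
  th <- analyzeThermo(run)
  tab <- thermoTable(th)
  low <- tab[1, ]
  expect_identical(low$mode, "folded_dominated")
  # Pu set to 1 - Pf; dU and dS flagged unavailable
  expect_equal(low$Pu, 1 - low$Pf, tolerance = 1e-12)
  expect_true(is.na(low$dU) && is.na(low$dS))
  expect_equal(low$dG, -1 * low$temperature * log(low$Pf / (1 - low$Pf)),
               tolerance = 1e-10)
  # reduced-unit run: Tm bound beyond the ladder top (preset melts ~4.3)
  expect_identical(meltingPoint(th), ">2")
})

test_that("a single-temperature run yields only a Tm bound", {
  zm <- zipperPreset("GB1p-like")
  run <- runREX(zipperSamplerModel(zm), temperatureLadder(1.0),
                rexConfig(4000, 10, seed = 44))
  th <- analyzeThermo(run)
  expect_true(is.na(th@Tm))
  expect_match(meltingPoint(th), "^[<>]")
})

test_that("estimator error shrinks as sampling grows (zipper consistency)", {
  zm <- zipperPreset("HP5A-like")
  ex <- zipperExact(zm, 1.3)
  meanErr <- function(n) mean(vapply(45:47, function(seed) {
    run <- runREX(zipperSamplerModel(zm), temperatureLadder(c(1.3, 1.9)),
                  rexConfig(n, 10, seed = seed))
    obs <- productionWindow(run)
    abs(mean(obs$nhb[obs$temperature == 1.3] >= 4) - ex$Pf)
  }, 0))
  # 16x the sweeps: mean error over seeds should clearly shrink
  expect_lt(meanErr(32000L), meanErr(2000L))
})
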