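# Synthetic-data layer: topologies, CG energy, fixtures, zipper oracle.

test_that("hairpin topologies carry the native registry and sequences", {
  seqs <- c(GB1p = "GEWTYDDATKTFTVTE", HP5A = "KKYTWNPATGKATVQE",
            GB1m3 = "KKWTYNPATGKFTVQE")
  for (nm in names(seqs)) {
    top <- buildHairpinTopology(nm)
    expect_identical(peptideSequence(top), seqs[[nm]])
    expect_identical(nrow(hbondRegistry(top)), 7L)
    expect_length(sidechainPairs(top), 2L)
    expect_identical(top@loopResidues, c(6L, 11L))
    expect_identical(top@terminiResidues, c(1L, 16L))
    # every registry entry references existing beads
    expect_true(all(hbondRegistry(top) >= 1 &
                    hbondRegistry(top) <= nrow(beads(top))))
    expect_true(validObject(top))
  }
  # registry pairs sit at the expected residues (literature 42-55 etc.)
  top <- buildHairpinTopology("GB1p")
  b <- beads(top)
  reg <- hbondRegistry(top)
  donors <- sort(unique(b$residue[reg[, 1L]]))
  acceptors <- sort(unique(b$residue[reg[, 2L]]))
  expect_identical(donors, c(2L, 4L, 6L, 10L, 11L, 13L, 15L))
  expect_identical(acceptors, c(2L, 4L, 6L, 7L, 11L, 13L, 15L))
  # sidechain pairs at the Trp/Val and Tyr/Phe homolog positions
  scRes <- lapply(sidechainPairs(top), function(p)
    sort(b$residue[c(p$a[1L], p$b[1L])]))
  expect_identical(scRes, list(c(3L, 14L), c(5L, 12L)))
})

test_that("unknown peptide names raise an error listing the valid ones", {
  expect_error(buildHairpinTopology("trpzip2"), "GB1p.*HP5A.*GB1m3")
})

test_that("native fixture satisfies every contact criterion; extended none", {
  for (nm in c("GB1p", "HP5A", "GB1m3")) {
    top <- buildHairpinTopology(nm)
    nat <- buildNativeFixture(top)
    ext <- buildExtendedFixture(top)
    expect_identical(countNativeHbonds(nat, top), 7L)
    expect_identical(countSidechainContacts(nat, top), 2L)
    expect_identical(countNativeHbonds(ext, top), 0L)
    expect_identical(countSidechainContacts(ext, top), 0L)
    expect_lt(loopDistance(nat, top), loopDistance(ext, top))
  }
})

test_that("CG energy decomposition sums to the total and hits the wells", {
  top <- topoGB1p
  p <- cgParameters(epsHb = 0.8, epsSc = 1.5, lambdaLoop = 0.5)
  nat <- buildNativeFixture(top)
  en <- cgEnergy(nat, top, p)
  expect_equal(sum(en$components), en$total)
  # every registry pair inside the well plateau: exactly -7 eps_hb
  expect_equal(unname(en$components["hbond_contact"]), -7 * 0.8,
               tolerance = 1e-10)
  expect_equal(unname(en$components["sidechain_contact"]), -2 * 1.5,
               tolerance = 1e-10)
  # extended chain: all contact terms zero
  ee <- cgEnergy(buildExtendedFixture(top), top, p)
  expect_identical(unname(ee$components["hbond_contact"]), 0)
  expect_identical(unname(ee$components["sidechain_contact"]), 0)
  # zero-coupling limit
  p0 <- cgParameters(epsHb = 0, epsSc = 0)
  e0 <- cgEnergy(nat, top, p0)
  expect_equal(e0$total,
               sum(e0$components[c("bonded", "excluded_volume")]))
})

test_that("compiled CG energy matches the pure-R oracle on random frames", {
  set.seed(101)
  p <- cgPreset("GB1p-like")
  pq <- cgParameters(epsHb = 0.6, epsSc = 1.2, lambdaLoop = 0.4,
                     hbCoop = 0.5, qScale = 0.3)
  for (i in 1:8) {
    ca <- randomCA(topoGB1p, sd = runif(1, 0.1, 2),
                   fromNative = i %% 2 == 0)
    for (par in list(p, pq)) {
      cpp <- cgEnergy(ca, topoGB1p, par)$components
      ref <- cgEnergyR(ca, topoGB1p, par)
      expect_equal(cpp, ref, tolerance = 1e-10)
    }
  }
})

test_that("overlapping beads give a finite repulsion, never NaN", {
  ca <- caTrace(buildExtendedFixture(topoGB1p), topoGB1p)
  ca[8, ] <- ca[5, ]  # exact overlap of a nonbonded pair
  en <- cgEnergy(ca, topoGB1p, cgParameters(qScale = 1))
  expect_true(all(is.finite(en$components)))
  expect_gt(en$components["excluded_volume"], 0)
})

test_that("zipper exact solution matches brute-force state enumeration", {
  set.seed(7)
  for (rep in 1:4) {
    om <- runif(8, 0, 5); om[8] <- max(om[8], 1)
    eps <- runif(1, 0.2, 2)
    zm <- zipperModel(epsilon = eps, degeneracy = om)
    Tk <- runif(1, 0.3, 3)
    z <- zipperExact(zm, Tk)
    # independent enumeration
    w <- om * exp((0:7) * eps / Tk)
    expect_equal(unname(z$populations), w / sum(w), tolerance = 1e-12)
    expect_equal(z$Pf, sum(w[5:8]) / sum(w), tolerance = 1e-12)
    expect_equal(z$Pu, sum(w[1:2]) / sum(w), tolerance = 1e-12)
    expect_equal(z$dG, -Tk * log(z$Pf / z$Pu), tolerance = 1e-12)
    # entropy identity holds to round-off
    expect_equal(z$dS, (z$dU - z$dG) / Tk, tolerance = 1e-12)
  }
})

test_that("two-level zipper melts exactly at E0 / (kB ln g)", {
  zm <- zipperModel(epsilon = 1 / 7,
                    degeneracy = c(exp(2), 0, 0, 0, 0, 0, 0, 1))
  expect_equal(zipperExactTm(zm), 0.5, tolerance = 1e-8)
  z <- zipperExact(zm, 0.5)
  expect_equal(z$dG, 0, tolerance = 1e-10)
  # ground state dominates as T -> 0
  expect_gt(zipperExact(zm, 0.01)$Pf, 1 - 1e-10)
  expect_error(zipperExact(zm, -1), "positive")
})

test_that("zipper MC sampler reproduces the exact populations", {
  set.seed(11)
  for (rep in 1:3) {
    om <- exp(runif(8, 0, 3)); om[8] <- max(om[8], 1)
    eps <- runif(1, 0.3, 1.5)
    zm <- zipperModel(epsilon = eps, degeneracy = om)
    Tk <- runif(1, 0.6, 1.8)
    # R step function, modest chain
    N <- 0L
    ns <- integer(20000)
    for (s in seq_along(ns)) {
      N <- zipperMcStep(N, zm, Tk)
      ns[s] <- N
    }
    emp <- tabulate(ns + 1L, 8) / length(ns)
    ex <- zipperExact(zm, Tk)
    pf <- mean(ns >= 4)
    se <- sqrt(ex$Pf * (1 - ex$Pf) / 1000)  # generous effective n
    expect_lt(abs(pf - ex$Pf), 3 * se + 0.02)
    # empirical detailed balance: flux N -> N+1 equals N+1 -> N
    up <- sum(ns[-1] - ns[-length(ns)] == 1)
    dn <- sum(ns[-1] - ns[-length(ns)] == -1)
    expect_lt(abs(up - dn) / max(1, up + dn), 0.1)
  }
})

test_that("two-level zipper sampler crosses the gap (support-restricted walk)", {
  zm <- zipperModel(epsilon = 1 / 7,
                    degeneracy = c(exp(2), 0, 0, 0, 0, 0, 0, 1))
  set.seed(3)
  ns <- integer(4000)
  N <- 0L
  for (s in seq_along(ns)) { N <- zipperMcStep(N, zm, 0.5); ns[s] <- N }
  expect_setequal(unique(ns), c(0L, 7L))
  expect_gt(mean(ns == 7), 0.2)  # both levels visited heavily at Tm
})

test_that("flat zipper landscape gives uniform occupancy", {
  zm <- zipperModel(epsilon = 0, degeneracy = rep(1, 8))
  set.seed(5)
  res <- hairpinREX:::.zipper_segment_cpp(0L, 1, 0, rep(1, 8), 80000L)
  emp <- tabulate(res$records + 1L, 8) / 80000
  se <- 3 * sqrt(0.125 * 0.875 / 2000)  # correlated chain: generous SE
  expect_true(all(abs(emp - 0.125) < se))
})

test_that("preset folded-population ordering matches the peptide series", {
  # zipper presets: exact
  pf <- vapply(c("GB1m3-like", "GB1p-like", "HP5A-like"), function(nm)
    zipperExact(zipperPreset(nm), 1.0)$Pf, 0)
  expect_true(pf[1] > pf[2] && pf[2] > pf[3])
  # CG presets are exercised statistically in the acceptance suite
})
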