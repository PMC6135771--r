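# Metropolis kernel, temperature ladders, replica exchange.

test_that("exponential ladder has exact endpoints and geometric spacing", {
  lad <- buildLadder(270, 400, 16)
  tt <- temperatures(lad)
  expect_identical(tt[1], 270)
  expect_identical(tt[16], 400)
  expect_equal(tt[2], 270 * (400 / 270)^(1 / 15), tolerance = 1e-12)
  expect_equal(tt[2], 277.17, tolerance = 1e-4)
  # ratios constant
  expect_equal(diff(log(tt)), rep(log(400 / 270) / 15, 15),
               tolerance = 1e-12)
  # degenerate equal-endpoint ladder
  expect_equal(temperatures(buildLadder(270, 270, 16)), rep(270, 16))
  expect_error(buildLadder(270, 400, 1), "2 replicas")
  expect_error(buildLadder(-1, 400, 4), "positive")
})

test_that("Metropolis acceptance follows min(1, exp(-dE/kT))", {
  set.seed(2)
  # dE <= 0 always accepted
  expect_true(all(vapply(1:50, function(i)
    metropolisAccept(-runif(1), 1), TRUE)))
  # dE = kT: long-run acceptance ~ 1/e
  n <- 10000
  acc <- mean(vapply(seq_len(n), function(i)
    metropolisAccept(1, 1), TRUE))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  # T -> infinity: accept everything
  expect_true(all(vapply(1:50, function(i)
    metropolisAccept(100, 1e12), TRUE)))
})

test_that("exchange probability is the detailed-balance criterion", {
  expect_identical(exchangeProbability(1, 1, 5, -3), 1)
  expect_identical(exchangeProbability(2, 0.5, 4, 4), 1)
  expect_equal(exchangeProbability(1.0, 0.5, 1.0, 2.0), exp(-0.5),
               tolerance = 1e-12)
  # symmetric under swapping pair labels
  expect_equal(exchangeProbability(0.7, 1.3, 2, 5),
               exchangeProbability(1.3, 0.7, 5, 2))
  expect_error(exchangeProbability(-1, 1, 0, 0), "positive")
})

test_that("CG move proposals preserve the constraints they claim", {
  set.seed(9)
  top <- topoGB1p
  ca <- caTrace(buildNativeFixture(top), top)
  # zero-amplitude local move leaves coordinates unchanged
  expect_equal(proposeMove(ca, top, c(1, 0, 0), c(0, 0, 0)), ca)
  # crankshaft preserves all bond lengths
  bl <- function(x) sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2))
  for (i in 1:20) {
    prop <- proposeMove(ca, top, c(0, 1, 0), c(0, 0.9, 0))
    expect_equal(bl(prop), bl(ca), tolerance = 1e-10)
  }
  # pivot rotates one side rigidly: all pairwise distances within each
  # side preserved
  for (i in 1:10) {
    prop <- proposeMove(ca, top, c(0, 0, 1), c(0, 0, 0.6))
    expect_equal(bl(prop), bl(ca), tolerance = 1e-9)
    moved <- which(rowSums(abs(prop - ca)) > 1e-12)
    if (length(moved) >= 2) {
      d0 <- dist(ca[moved, ]); d1 <- dist(prop[moved, ])
      expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
    }
  }
})

test_that("single-temperature MC on a harmonic potential gives <x^2> = kT/k", {
  k <- 2.5
  model <- harmonicModel(k = k, stepSize = 1.5)
  for (Tk in c(0.7, 1.6)) {
    run <- runMC(model, Tk, rexConfig(nSweeps = 40000, seed = 17))
    x <- productionWindow(run)$x
    v <- mean(x^2)
    expected <- Tk / k
    # 3 SE with an effective sample size from the autocorrelation time
    neff <- length(x) / (2 * max(1, sum(acf(x^2, plot = FALSE,
                                            lag.max = 200)$acf)))
    se <- sd(x^2) / sqrt(neff)
    expect_lt(abs(v - expected), 3 * se)
  }
})

test_that("two-replica exchange acceptance matches the canonical average", {
  b1 <- 1 / 0.8; b2 <- 1 / 2.0
  model <- harmonicModel(k = 1, stepSize = 2)
  run <- runREX(model, temperatureLadder(c(0.8, 2.0)),
                rexConfig(nSweeps = 30000, exchangeInterval = 5, seed = 23))
  obs <- mean(exchangeAttempts(run)$accepted)
  expected <- harmonicExchangeExpectation(b1, b2)
  n <- nrow(exchangeAttempts(run))
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(obs - expected), 3 * se + 0.01)
})

test_that("replica-exchange bookkeeping invariants hold", {
  zm <- zipperPreset("GB1p-like")
  model <- zipperSamplerModel(zm)
  lad <- buildLadder(1.0, 2.5, 6)
  cfg <- rexConfig(nSweeps = 3000, exchangeInterval = 10, seed = 5)
  run <- runREX(model, lad, cfg)
  rec <- rexRecord(run)
  # replica -> temperature is a permutation at every block (class validity
  # enforces it; assert explicitly anyway)
  traj <- rec@tempTrajectory
  expect_true(all(apply(traj, 1, function(r)
    identical(sort(as.integer(r)), 1:6))))
  # demultiplexing conservation: rows = replicas x sweeps
  expect_identical(nrow(observables(run)), 6L * 3000L)
  expect_true(all(table(observables(run)$tempIndex) == 3000L))
  # acceptance rates in [0, 1]
  expect_true(all(acceptanceRates(run) >= 0 & acceptanceRates(run) <= 1))
  # seed determinism: bit-identical record and observables
  run2 <- runREX(model, lad, cfg)
  expect_identical(observables(run), observables(run2))
  expect_identical(exchangeAttempts(run), exchangeAttempts(run2))
  expect_identical(rec@tempTrajectory, rexRecord(run2)@tempTrajectory)
  # different seed changes the stream
  run3 <- runREX(model, lad, rexConfig(3000, 10, seed = 6))
  expect_false(identical(observables(run), observables(run3)))
})

test_that("two replicas at equal temperature always exchange", {
  model <- harmonicModel()
  run <- runREX(model, temperatureLadder(c(1, 1)),
                rexConfig(nSweeps = 500, exchangeInterval = 5, seed = 1))
  expect_true(all(exchangeAttempts(run)$accepted))
})

test_that("single replica reduces to plain MC and zipper REX hits the oracle", {
  zm <- zipperPreset("HP5A-like")
  m <- zipperSamplerModel(zm)
  one <- runREX(m, temperatureLadder(1.2), rexConfig(20000, 10, seed = 9))
  expect_identical(nrow(exchangeAttempts(one)), 0L)
  pf <- mean(productionWindow(one)$nhb >= 4)
  ex <- zipperExact(zm, 1.2)
  expect_lt(abs(pf - ex$Pf), 3 * sqrt(ex$Pf * (1 - ex$Pf) / 500) + 0.02)
})

test_that("non-finite model energies abort with a diagnostic", {
  bad <- list(kind = "bad", describe = "bad",
              init = function(i) list(x = 0, energy = 0),
              sweep = function(state, beta, n)
                list(state = list(x = 0, energy = NaN),
                     records = matrix(0, n, 1,
                                      dimnames = list(NULL, "total")),
                     nAccept = 0L, nProposed = n))
  class(bad) <- "rexModel"
  expect_error(runREX(bad, temperatureLadder(c(1, 2)),
                      rexConfig(10, 5, seed = 1)),
               "non-finite energy in replica")
})

test_that("production window keeps the configured trailing fraction", {
  m <- harmonicModel()
  run <- runMC(m, 1, rexConfig(nSweeps = 1000, productionFraction = 0.6,
                               seed = 2))
  pw <- productionWindow(run)
  expect_identical(range(pw$step), c(401, 1000))
  expect_error(rexConfig(100, productionFraction = 0), "productionFraction")
  expect_error(rexConfig(100, exchangeInterval = 0), "exchangeInterval")
})
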