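# Free-energy profiles, surfaces, minimal paths, PCA.

test_that("1D profiles are -kT ln p, min-shifted, with masked empty bins", {
  # uniform over two bins -> flat zero
  fe <- feProfile1D(c(0, 0, 1, 1), kT = 1)
  expect_equal(unname(surfaceGrid(fe)), c(0, 0))
  # p = (0.8, 0.2) -> F = (0, ln 4)
  fe2 <- feProfile1D(c(rep(0, 8), rep(1, 2)), kT = 1)
  expect_equal(unname(surfaceGrid(fe2)), c(0, log(4)), tolerance = 1e-12)
  # masked bins never enter the minimum
  fe3 <- feProfile1D(c(0, 0, 3), kT = 2)
  expect_true(surfaceMask(fe3)[2] && surfaceMask(fe3)[3])
  expect_equal(min(surfaceGrid(fe3), na.rm = TRUE), 0)
  # contour levels are integer multiples of kT
  expect_equal(contourLevels(fe2) / 1, round(contourLevels(fe2) / 1))
  expect_error(feProfile1D(numeric(0), kT = 1))
})

test_that("2D surfaces factorize for independent coordinates and marginalize", {
  set.seed(51)
  x <- sample(0:3, 4000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  y <- sample(0:2, 4000, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  kT <- 0.7
  s2 <- feSurface2D(x, y, kT)
  fx <- feProfile1D(x, kT); fy <- feProfile1D(y, kT)
  # separability: F(x,y) - Fx(x) - Fy(y) constant over unmasked bins
  dev <- surfaceGrid(s2) - outer(surfaceGrid(fx), rep(0, 3), `+`) -
    outer(rep(0, 4), surfaceGrid(fy), `+`)
  dev <- dev[!surfaceMask(s2)]
  expect_lt(diff(range(dev)), 0.35)  # sampling noise only
  # marginalizing the 2D counts over y reproduces the 1D profile exactly
  cx <- rowSums(s2@counts)
  feMarg <- -kT * log(cx / sum(cx))
  expect_equal(feMarg - min(feMarg), unname(surfaceGrid(fx)),
               tolerance = 1e-12)
  # single occupied bin
  s1 <- feSurface2D(2, 5, kT = 1)
  expect_equal(sum(!surfaceMask(s1)), 1L)
  expect_equal(surfaceGrid(s1)[!surfaceMask(s1)], 0)
})

test_that("surfaces are invariant under sample duplication", {
  set.seed(52)
  x <- rnorm(500); y <- rnorm(500)
  a <- feSurface2D(x, y, kT = 1, xBinSpec = list(width = 0.5),
                   yBinSpec = list(width = 0.5))
  b <- feSurface2D(rep(x, 2), rep(y, 2), kT = 1,
                   xBinSpec = list(width = 0.5, min = min(x), max = max(x)),
                   yBinSpec = list(width = 0.5, min = min(y), max = max(y)))
  expect_equal(surfaceGrid(a), surfaceGrid(b), tolerance = 1e-12)
  # equivalently via weights
  cw <- feProfile1D(x, kT = 1, binSpec = list(width = 0.5))
  dw <- feProfile1D(x, kT = 1, binSpec = list(width = 0.5),
                    weights = rep(2, length(x)))
  expect_equal(surfaceGrid(cw), surfaceGrid(dw), tolerance = 1e-12)
})

test_that("bottleneck path matches exhaustive threshold enumeration", {
  set.seed(53)
  for (trial in 1:100) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    F <- matrix(round(runif(nx * ny), 3), nx, ny)
    F <- F - min(F)
    surf <- new("FESurface",
                axes = list(list(name = "x", breaks = 0:nx + 0.5,
                                 mids = 1:nx),
                            list(name = "y", breaks = 0:ny + 0.5,
                                 mids = 1:ny)),
                F = F, mask = matrix(FALSE, nx, ny), kT = 1,
                counts = exp(-F), contourLevels = numeric())
    start <- c(1L, 1L); end <- c(nx, ny)
    got <- minimalEnergyPath(surf, start, end)
    expect_equal(got$bottleneck, bruteBottleneck(F, start, end),
                 tolerance = 1e-9)
    # path is 8-connected, starts and ends correctly, stays unmasked
    expect_equal(got$path[1, ], c(row = 1, col = 1))
    expect_equal(unname(got$path[nrow(got$path), ]), c(nx, ny))
    steps <- diff(got$path)
    expect_true(all(abs(steps) <= 1))
  }
})

test_that("path is deterministic and passes through forced saddles", {
  # two basins separated by a wall with one low saddle
  F <- matrix(5, 5, 5)
  F[, 1] <- 0; F[, 5] <- 0       # two deep basins (columns)
  F[3, 3] <- 1; F[, 3][c(1, 2, 4, 5)] <- 5
  F[, 2] <- 0.5; F[, 4] <- 0.5
  surf <- new("FESurface",
              axes = list(list(name = "x", breaks = 0:5 + 0.5, mids = 1:5),
                          list(name = "y", breaks = 0:5 + 0.5, mids = 1:5)),
              F = F - min(F), mask = matrix(FALSE, 5, 5), kT = 1,
              counts = exp(-F), contourLevels = numeric())
  got <- minimalEnergyPath(surf, c(3L, 1L), c(3L, 5L))
  expect_true(any(got$path[, 1] == 3 & got$path[, 2] == 3))  # the saddle
  # start = end -> single-bin path
  triv <- minimalEnergyPath(surf, c(2L, 2L), c(2L, 2L))
  expect_identical(nrow(triv$path), 1L)
  # identical reruns give identical paths (documented determinism)
  expect_identical(minimalEnergyPath(surf, c(3L, 1L), c(3L, 5L))$path,
                   got$path)
  # disconnected masked grid errors
  mask <- matrix(FALSE, 5, 5); mask[, 3] <- TRUE
  surf2 <- new("FESurface", axes = surf@axes, F = ifelse(mask, NA, F - min(F)),
               mask = mask, kT = 1, counts = exp(-F),
               contourLevels = numeric())
  expect_error(minimalEnergyPath(surf2, c(3L, 1L), c(3L, 5L)),
               "no connected path")
})

test_that("minimal total-F tie-break agrees with an independent shortest path", {
  skip_if_not_installed("igraph")
  set.seed(54)
  for (trial in 1:20) {
    nx <- 5; ny <- 5
    F <- matrix(runif(nx * ny, 0, 3), nx, ny); F <- F - min(F)
    surf <- new("FESurface",
                axes = list(list(name = "x", breaks = 0:nx + 0.5,
                                 mids = 1:nx),
                            list(name = "y", breaks = 0:ny + 0.5,
                                 mids = 1:ny)),
                F = F, mask = matrix(FALSE, nx, ny), kT = 1,
                counts = exp(-F), contourLevels = numeric())
    got <- minimalEnergyPath(surf, c(1L, 1L), c(nx, ny))
    # restrict to bins at or below the bottleneck; igraph shortest path on
    # node-weighted graph (edge weight = F of the target node)
    B <- got$bottleneck + 1e-9
    ok <- which(F <= B)
    idx <- matrix(seq_len(nx * ny), nx, ny)
    edges <- c(); w <- c()
    for (v in ok) {
      i <- (v - 1) %% nx + 1; j <- (v - 1) %/% nx + 1
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
        u <- idx[ii, jj]
        if (F[u] <= B) {
          edges <- c(edges, v, u); w <- c(w, F[u])
        }
      }
    }
    g <- igraph::make_graph(edges, n = nx * ny, directed = TRUE)
    d <- igraph::distances(g, v = 1, to = nx * ny, weights = w,
                           mode = "out")
    expect_equal(got$totalF, as.numeric(d) + F[1, 1], tolerance = 1e-9)
  }
})

test_that("Kabsch superposition recovers planted rigid transforms", {
  set.seed(55)
  cloud <- matrix(rnorm(3 * 20), 20, 3)
  # self-superposition: identity, RMSD 0
  self <- kabschSuperpose(cloud, cloud)
  expect_equal(self$rotation, diag(3), tolerance = 1e-10)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  # known 90 degree rotation about z + shift
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- sweep(cloud %*% t(R90), 2, c(2, -1, 4), `+`)
  fit <- kabschSuperpose(moved, cloud)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation %*% R90, diag(3), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # reflections are not admitted: mirrored cloud keeps RMSD > 0
  mirror <- cloud; mirror[, 1] <- -mirror[, 1]
  fitM <- kabschSuperpose(mirror, cloud)
  expect_gt(fitM$rmsd, 0.1)
  expect_equal(det(fitM$rotation), 1, tolerance = 1e-9)
  # degenerate input
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line), "collinear")
  expect_error(kabschSuperpose(cloud[1:2, ], cloud[1:2, ]), "3 points")
})

test_that("joint PCA recovers a planted deformation direction", {
  set.seed(56)
  base <- caTrace(buildNativeFixture(topoGB1p), topoGB1p)
  dir1 <- plantDirection(base)
  frames <- lapply(rnorm(80, sd = 2), function(a) base + a * dir1)
  pca <- jointPCA(list(GB1p = frames))
  # PC1 aligned with the planted 3N-direction
  v <- eigenvalues(pca)
  expect_gt(v[1] / sum(v[v > 1e-12]), 0.95)
  pc1 <- matrix(pca@eigenvectors[, 1], 16, 3, byrow = TRUE)
  cosine <- abs(sum(pc1 * dir1))
  expect_gt(cosine, 0.99)
  # projections' covariance is diagonal with the top eigenvalues
  cv <- cov(projections(pca))
  expect_equal(unname(diag(cv)), v[1:2], tolerance = 1e-8)
  expect_lt(abs(cv[1, 2]), 1e-8)
  # single frame repeated: all eigenvalues 0
  pca0 <- jointPCA(list(a = replicate(5, base, simplify = FALSE)))
  expect_lt(max(eigenvalues(pca0)), 1e-12)
})

test_that("PCA and FE surfaces are invariant under rigid motion of inputs", {
  set.seed(57)
  base <- caTrace(buildNativeFixture(topoGB1p), topoGB1p)
  frames <- lapply(1:40, function(i) base + matrix(rnorm(48, sd = 0.7),
                                                   16, 3))
  movedFrames <- lapply(frames, rigidTransform, angle = 0.9,
                        axis = c(1, 1, 0), shift = c(10, 0, -5))
  p1 <- jointPCA(list(a = frames))
  p2 <- jointPCA(list(a = movedFrames))
  expect_equal(eigenvalues(p1)[1:5], eigenvalues(p2)[1:5],
               tolerance = 1e-6)
  s1 <- pcaFESurface(p1, kT = 0.5)
  s2 <- pcaFESurface(p2, kT = 0.5)
  g1 <- surfaceGrid(s1); g2 <- surfaceGrid(s2)
  # grids agree up to the sign ambiguity of the PCs
  agree <- function(a, b) isTRUE(all.equal(a, b, tolerance = 1e-6))
  flips <- list(g2, g2[rev(seq_len(nrow(g2))), ],
                g2[, rev(seq_len(ncol(g2)))],
                g2[rev(seq_len(nrow(g2))), rev(seq_len(ncol(g2)))])
  expect_true(any(vapply(flips, agree, TRUE, a = g1)))
  # mismatched atom counts error
  expect_error(jointPCA(list(a = frames, b = list(base[1:10, ]))),
               "mismatched")
})

test_that("joint analyses keep peptide labels and per-label surfaces", {
  set.seed(58)
  base <- caTrace(buildNativeFixture(topoGB1p), topoGB1p)
  fa <- lapply(1:30, function(i) base + matrix(rnorm(48, sd = 0.4), 16, 3))
  fb <- lapply(1:20, function(i) base + matrix(rnorm(48, sd = 1.5), 16, 3))
  pca <- jointPCA(list(GB1p = fa, HP5A = fb))
  expect_identical(table(pca@labels)[["GB1p"]], 30L)
  sA <- pcaFESurface(pca, kT = 0.5, label = "GB1p")
  sB <- pcaFESurface(pca, kT = 0.5, label = "HP5A")
  # shared grid: same axes
  expect_equal(surfaceAxes(sA)[[1]]$breaks, surfaceAxes(sB)[[1]]$breaks)
  expect_error(pcaFESurface(pca, kT = 0.5, label = "nope"), "no frames")
})

test_that("loop-distance densities normalize per state and find planted modes", {
  set.seed(59)
  loop <- c(rnorm(400, 4.5, 0.3),
            c(rnorm(300, 8, 0.5), rnorm(300, 13, 0.5)))
  labels <- classifyState(c(rep(7, 400), rep(0, 600)))
  dens <- loopDistanceDistributions(loop, labels, binWidth = 0.5)
  for (d in dens)
    expect_equal(sum(d$density) * 0.5, 1, tolerance = 1e-9)
  # bimodal unfolded input: two local maxima near the planted modes
  u <- dens$unfolded
  locmax <- u$mid[which(diff(sign(diff(c(-Inf, u$density, -Inf)))) == -2)]
  locmax <- locmax[u$density[match(locmax, u$mid)] > 0.1]
  expect_gte(length(locmax), 2L)
  expect_true(any(abs(locmax - 8) < 1) && any(abs(locmax - 13) < 1))
  # all-folded input: unfolded density omitted with a warning
  expect_warning(
    one <- loopDistanceDistributions(rnorm(50, 4.5, 0.2),
                                     classifyState(rep(7, 50))),
    "unfolded")
  expect_named(one, "folded")
})

test_that("two-state barrier separates cooperative from downhill profiles", {
  kT <- 1
  # constructed bimodal profile over N = 0..7
  pops <- exp(-c(0, 0.4, 2.5, 2.0, 1.2, 0.3, 0.1, 0.05))
  nhb <- rep(0:7, round(pops * 1000))
  fe <- feProfile1D(nhb, kT)
  tb <- twoStateBarrier(fe)
  expect_gt(tb$barrier, 1.5)
  # monotone downhill profile: no barrier
  pops2 <- exp(-(7:0) * 0.8)
  fe2 <- feProfile1D(rep(0:7, round(pops2 * 1000)), kT)
  expect_equal(twoStateBarrier(fe2)$barrier, 0)
})
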