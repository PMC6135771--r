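# Shared test fixtures and independent (pure-R) oracles.

topoGB1p <- buildHairpinTopology("GB1p")

# random, mildly perturbed CA conformations spanning folded to unfolded
randomCA <- function(topology, sd = 1, fromNative = TRUE) {
  base <- if (fromNative) caTrace(buildNativeFixture(topology), topology)
          else caTrace(buildExtendedFixture(topology), topology)
  base + matrix(rnorm(length(base), sd = sd), nrow(base), 3L)
}

# pure-R mirror of the compiled CG energy; same parameter list, independent
# arithmetic.  Serves as the oracle for the C++ kernel.
cgEnergyR <- function(ca, topology, params, hbCutoff = 2.6, scCutoff = 6.5) {
  par <- hairpinREX:::.cgParList(topology, params, hbCutoff, scCutoff)
  n <- nrow(ca)
  sw <- function(r, on, off)
    ifelse(r <= on, 1, ifelse(r >= off, 0,
      0.5 * (1 + cos(pi * (r - on) / (off - on)))))
  # bonded
  bl <- sqrt(rowSums((ca[-1, ] - ca[-n, ])^2))
  bonded <- sum(par$bondK * (bl - par$bondR0)^2)
  for (i in 2:(n - 1)) {
    a <- ca[i - 1, ] - ca[i, ]; b <- ca[i + 1, ] - ca[i, ]
    th <- acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
    lam <- if (i >= par$loopLo && i <= par$loopHi) par$lambdaLoop else 1
    bonded <- bonded + par$angleK * lam * (th - par$theta0[i])^2
  }
  for (k in seq_along(par$dihStart)) {
    i <- par$dihStart[k]
    phi <- hairpinREX:::.dihedral(ca[i, ], ca[i + 1, ], ca[i + 2, ],
                                  ca[i + 3, ])
    bonded <- bonded + par$dihedralK * par$lambdaLoop *
      (1 - cos(phi - par$phi0[k]))
  }
  # excluded volume
  ev <- 0
  for (i in 1:(n - 3)) for (j in (i + 3):n) {
    r <- sqrt(sum((ca[i, ] - ca[j, ])^2))
    if (r < par$evSigma) ev <- ev + par$evK * (par$evSigma - r)^2
  }
  # contacts on framed beads
  xyz <- frameFromCA(ca, topology)
  bd <- beads(topology)
  beadAt <- function(res, role) xyz[which(bd$residue == res & bd$role == role), ]
  s <- numeric(length(par$donorRes))
  for (k in seq_along(par$donorRes)) {
    r <- sqrt(sum((beadAt(par$donorRes[k], "HN") -
                   beadAt(par$acceptorRes[k], "O"))^2))
    s[k] <- sw(r, par$hbOn, par$hbOff)
  }
  hb <- -par$epsHb * sum(s)
  if (par$hbCoop != 0 && length(par$zipOrder) >= 2) {
    z <- par$zipOrder
    hb <- hb - par$hbCoop * sum(s[z[-length(z)]] * s[z[-1]])
  }
  sc <- 0
  for (k in seq_along(par$scA)) {
    r <- sqrt(sum((beadAt(par$scA[k], "SC") - beadAt(par$scB[k], "SC"))^2))
    sc <- sc - par$epsSc * sw(r, par$scOn, par$scOff)
  }
  chg <- 0
  if (par$qScale != 0) {
    q <- par$charge
    for (i in 1:(n - 2)) for (j in (i + 2):n) {
      if (q[i] == 0 || q[j] == 0) next
      r <- max(0.5, sqrt(sum((ca[i, ] - ca[j, ])^2)))
      chg <- chg + par$qScale * q[i] * q[j] * exp(-r / par$debye) / r
    }
  }
  c(bonded = bonded, excluded_volume = ev, hbond_contact = hb,
    sidechain_contact = sc, screened_charge = chg)
}

# rigid transform helper
rigidTransform <- function(xyz, angle = 0.7, axis = c(0, 0, 1),
                           shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, `+`)
}

# internal deformation direction orthogonal to all rigid motions of the
# reference (net translation and infinitesimal rotations projected out),
# so superposition cannot absorb any of it
plantDirection <- function(base) {
  raw <- matrix(rnorm(length(base)), nrow(base), 3L)
  ctr <- sweep(base, 2, colMeans(base))
  rigid <- cbind(
    as.numeric(matrix(rep(c(1, 0, 0), each = nrow(base)), ncol = 3)),
    as.numeric(matrix(rep(c(0, 1, 0), each = nrow(base)), ncol = 3)),
    as.numeric(matrix(rep(c(0, 0, 1), each = nrow(base)), ncol = 3)),
    as.numeric(cbind(0, -ctr[, 3], ctr[, 2])),
    as.numeric(cbind(ctr[, 3], 0, -ctr[, 1])),
    as.numeric(cbind(-ctr[, 2], ctr[, 1], 0)))
  q <- qr.Q(qr(rigid))
  v <- as.numeric(raw)
  v <- v - q %*% crossprod(q, v)
  v <- v / sqrt(sum(v^2))
  matrix(v, nrow(base), 3L)
}

# canonical-average exchange acceptance for two harmonic oscillators at
# inverse temperatures b1, b2: E[min(1, exp((b1-b2)(U1-U2)))] with
# U_i = k x_i^2 / 2 and x_i Gaussian, by dense grid quadrature over
# (x1, x2) standard normals
harmonicExchangeExpectation <- function(b1, b2) {
  z <- seq(-8, 8, length.out = 801)
  w <- dnorm(z); w <- w / sum(w)
  u1 <- z^2 / (2 * b1)   # U in units where k = 1: x ~ N(0, 1/(k b))
  u2 <- z^2 / (2 * b2)
  A <- exp((b1 - b2) * outer(u1, u2, `-`))
  A[A > 1] <- 1
  as.numeric(t(w) %*% A %*% w)
}

# exhaustive minimal-bottleneck oracle on small grids: enumerate candidate
# bottleneck levels, check 8-connectivity below each, then shortest total F
# by Dijkstra on the thresholded grid (independent of the package's
# implementation).
bruteBottleneck <- function(F, start, end) {
  nx <- nrow(F); ny <- ncol(F)
  lin <- function(b) (b[2] - 1) * nx + b[1]
  nbrs <- function(v) {
    i <- (v - 1) %% nx + 1; j <- (v - 1) %/% nx + 1
    out <- integer()
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny)
        out <- c(out, (jj - 1) * nx + ii)
    }
    out
  }
  connectedBelow <- function(thr) {
    ok <- as.numeric(F) <= thr
    s <- lin(start); e <- lin(end)
    if (!ok[s] || !ok[e]) return(FALSE)
    seen <- rep(FALSE, nx * ny); seen[s] <- TRUE; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v == e) return(TRUE)
      for (w in nbrs(v)) if (ok[w] && !seen[w]) {
        seen[w] <- TRUE; queue <- c(queue, w)
      }
    }
    FALSE
  }
  for (thr in sort(unique(as.numeric(F))))
    if (connectedBelow(thr)) return(thr)
  Inf
}
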