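#' Kabsch least-squares rigid superposition
#'
#' Optimal proper rotation and translation mapping \code{moving} onto
#' \code{reference} in the least-squares sense (SVD construction with the
#' determinant correction, so reflections are never returned).
#'
#' @param moving,reference numeric matrices (n x 3), equal n >= 3,
#'   non-collinear.
#' @return list: \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3; transformed = moving %*% t(rotation) + translation),
#'   \code{rmsd}, \code{transformed}.
#' @export
kabschSuperpose <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference) || ncol(moving) != 3L ||
      ncol(reference) != 3L)
    stop("coordinate sets must be equal-size n x 3 matrices")
  n <- nrow(moving)
  if (n < 3L) stop("need at least 3 points for superposition")
  cm <- colMeans(moving); cr <- colMeans(reference)
  P <- sweep(moving, 2L, cm); Q <- sweep(reference, 2L, cr)
  svP <- svd(P)$d; svQ <- svd(Q)$d
  if (svP[2L] < 1e-8 * max(svP) || svQ[2L] < 1e-8 * max(svQ))
    stop("degenerate (collinear) point set; superposition undefined")
  H <- crossprod(P, Q)          # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- P %*% t(R)
  transformed <- sweep(transformed, 2L, cr, `+`)
  rmsd <- sqrt(mean(rowSums((transformed - reference)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
       rmsd = rmsd, transformed = transformed)
}

## normalise heterogeneous ensemble input to a list of (n_atoms x 3)
## matrices
.frameList <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[1L]), function(i) x[i, , ]))
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(lapply(x, function(f)
    if (is(f, "Frame")) f@coords else as.matrix(f)))
  stop("unsupported ensemble input")
}

#' Joint principal component analysis of superposed ensembles
#'
#' Pools CA-trace frames from one or more labelled ensembles (e.g. GB1p
#' and HP5A production frames at one temperature), superposes every frame
#' onto the pooled mean structure (two align/recompute-mean iterations
#' after an initial alignment to the first frame), diagonalizes the
#' covariance of the flattened coordinates, and projects every frame onto
#' the top principal components.  Component signs are canonicalized
#' (positive third moment of the scores) so repeated analyses of rigidly
#' transformed inputs agree exactly.  Projections of the mean structure are
#' the origin by construction, and per-frame labels are retained so
#' per-peptide landscapes can be built from one shared PC basis.
#'
#' @param ensembles named list; each element is a frames x atoms x 3
#'   array, a list of (atoms x 3) matrices, or a single matrix.  All
#'   frames must share the atom count.
#' @param nComponents number of components to keep (default 2).
#' @return a \linkS4class{PCAResult}.
#' @export
jointPCA <- function(ensembles, nComponents = 2L) {
  if (!is.list(ensembles) || is.null(names(ensembles)) ||
      any(!nzchar(names(ensembles))))
    stop("ensembles must be a named list")
  frames <- list(); labels <- character()
  for (nm in names(ensembles)) {
    fl <- .frameList(ensembles[[nm]])
    frames <- c(frames, fl)
    labels <- c(labels, rep(nm, length(fl)))
  }
  nAtoms <- nrow(frames[[1L]])
  if (any(vapply(frames, nrow, 1L) != nAtoms))
    stop("mismatched atom counts across frames")
  nF <- length(frames)

  alignAll <- function(ref) lapply(frames, function(f) {
    fit <- tryCatch(kabschSuperpose(f, ref), error = function(e) NULL)
    if (is.null(fit)) f else fit$transformed
  })
  aligned <- alignAll(frames[[1L]])
  for (it in 1:2) {
    m <- Reduce(`+`, aligned) / nF
    frames <- aligned
    aligned <- alignAll(m)
  }
  meanStruct <- Reduce(`+`, aligned) / nF

  X <- t(vapply(aligned, function(f) as.numeric(t(f)),
                numeric(3L * nAtoms)))
  Xc <- sweep(X, 2L, colMeans(X))
  C <- crossprod(Xc) / max(1L, nF - 1L)
  eig <- eigen(C, symmetric = TRUE)
  k <- min(nComponents, ncol(eig$vectors))
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  proj <- Xc %*% V
  # canonical sign: positive third moment of the scores (first-frame sign
  # as tie-break), so results do not depend on the input frame orientation
  for (j in seq_len(k)) {
    s3 <- sum(proj[, j]^3)
    flip <- if (abs(s3) > 1e-8 * max(1, sum(proj[, j]^2))^1.5) s3 < 0
            else proj[1L, j] < 0
    if (isTRUE(flip)) {
      proj[, j] <- -proj[, j]
      V[, j] <- -V[, j]
    }
  }
  colnames(proj) <- paste0("PC", seq_len(k))
  new("PCAResult", meanStructure = meanStruct,
      eigenvalues = pmax(eig$values, 0), eigenvectors = V,
      projections = proj, labels = labels)
}

#' Free-energy surface over principal components
#'
#' Applies \code{\link{feSurface2D}} to the PC1/PC2 projections,
#' optionally restricted to one peptide label (while keeping the shared
#' joint-PCA bin grid when \code{commonGrid} is TRUE).
#'
#' @param pca a \linkS4class{PCAResult}.
#' @param kT thermal energy.
#' @param label optional single label to subset frames.
#' @param nBins bins per axis (default 50: bin width = range/50).
#' @param commonGrid when subsetting by label, keep the bin range of the
#'   full projection cloud.
#' @return an \linkS4class{FESurface}.
#' @export
pcaFESurface <- function(pca, kT, label = NULL, nBins = 50L,
                         commonGrid = TRUE) {
  # snap scores to 1e-9 before binning so round-off jitter (e.g. from a
  # rigid transform of the input ensemble) cannot flip edge samples
  pr <- round(pca@projections, 9)
  if (ncol(pr) < 2L) stop("need at least two components")
  full <- pr
  if (!is.null(label)) {
    keep <- pca@labels == label
    if (!any(keep)) stop("no frames with label '", label, "'")
    pr <- pr[keep, , drop = FALSE]
  }
  src <- if (commonGrid) full else pr
  spec <- function(col) {
    r <- range(src[, col])
    w <- round(diff(r) / nBins, 9)
    if (w <= 0) w <- 1
    list(width = w, min = r[1L], max = r[2L] + w * 1e-6)
  }
  feSurface2D(pr[, 1L], pr[, 2L], kT,
              xBinSpec = spec(1L), yBinSpec = spec(2L),
              xName = "PC1", yName = "PC2")
}
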