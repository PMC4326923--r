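#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds samples in `dims` dimensions from a symmetric distance matrix by
#' double-centering the squared distances and taking the top eigenpairs
#' (via [stats::cmdscale()]). Axes are ordered by eigenvalue, and each
#' axis' sign is fixed deterministically so that its first nonzero
#' coordinate is positive.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal and
#'   non-negative entries.
#' @param dims embedding dimension (default 2).
#' @return list with `points` (samples x dims) and `eig` (all
#'   eigenvalues, descending).
#' @export
classicalMds <- function(d, dims = 2) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8))
    stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be non-negative")
  if (any(abs(diag(dm)) > 1e-8)) stop("diagonal must be zero")
  fit <- stats::cmdscale(dm, k = dims, eig = TRUE)
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < dims) {
    pad <- matrix(0, nrow(dm), dims - if (is.null(pts)) 0 else ncol(pts))
    pts <- cbind(pts, pad)
  }
  for (j in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1L], j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  list(points = pts, eig = fit$eig)
}

#' MDS of an AgingExperiment's samples
#'
#' Convenience wrapper: Euclidean distances between samples on the
#' log2(RPKM + 1) matrix over all genes, embedded by [classicalMds()],
#' with per-age centroids and confidence radii from [groupCentroids()].
#'
#' @param ae an [AgingExperiment-class].
#' @param dims embedding dimension.
#' @param assay assay used for the distances.
#' @param confidence quantile for the per-group radius.
#' @return list with `points`, `eig`, `centroids`, `radii`, `ages`.
#' @export
mdsSamples <- function(ae, dims = 2, assay = "logrpkm",
                       confidence = 0.95) {
  x <- assayMatrix(ae, assay)
  emb <- classicalMds(stats::dist(t(x)), dims = dims)
  cen <- groupCentroids(emb$points, ageWeeks(ae), confidence = confidence)
  c(emb, cen, list(ages = ageWeeks(ae)))
}

#' Group centroids and confidence radii in an ordination
#'
#' The centroid of each group is the arithmetic mean of its members'
#' coordinates; the confidence radius is the `confidence` quantile of the
#' within-group distances to the centroid (a data-driven stand-in for a
#' confidence circle). Singleton groups get radius `NA` and are flagged.
#'
#' @param points numeric matrix of coordinates, samples x dims.
#' @param groups group label per sample (e.g. age in weeks).
#' @param confidence quantile level in (0, 1].
#' @return list with `centroids` (groups x dims), `radii` (named numeric,
#'   `NA` for singletons) and `singleton` (named logical).
#' @export
groupCentroids <- function(points, groups, confidence = 0.95) {
  points <- as.matrix(points)
  if (length(groups) != nrow(points))
    stop("one group label per row of 'points' is required")
  lev <- sort(unique(groups))
  cen <- matrix(NA_real_, length(lev), ncol(points),
                dimnames = list(as.character(lev), colnames(points)))
  radii <- stats::setNames(rep(NA_real_, length(lev)), as.character(lev))
  singleton <- stats::setNames(rep(FALSE, length(lev)), as.character(lev))
  for (i in seq_along(lev)) {
    ix <- which(groups == lev[i])
    cen[i, ] <- colMeans(points[ix, , drop = FALSE])
    if (length(ix) < 2L) { singleton[i] <- TRUE; next }
    dd <- sqrt(rowSums(sweep(points[ix, , drop = FALSE], 2L,
                             cen[i, ])^2))
    radii[i] <- unname(stats::quantile(dd, probs = confidence))
  }
  list(centroids = cen, radii = radii, singleton = singleton)
}
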