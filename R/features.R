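#' Clip intensity outliers at k standard deviations
#'
#' Mean and standard deviation (population, n denominator) are computed on
#' the raw masked intensities; values outside mu +/- k*sigma are set to the
#' nearer bound. Order and count are preserved.
#'
#' @param intensities numeric vector (>= 2 values).
#' @param k clipping bound in sigma-multiples (default 4).
#' @return The clipped vector, with attributes \code{mu} and \code{sigma}.
#' @export
clipOutliers <- function(intensities, k = 4) {
  if (length(intensities) < 2) stop("need at least 2 intensity values")
  mu <- mean(intensities)
  sigma <- sqrt(mean((intensities - mu)^2))
  out <- pmin(pmax(intensities, mu - k * sigma), mu + k * sigma)
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  out
}

#' Normalize intensities to the interval [0, 1]
#'
#' \code{(i - min(i)) / (max(i) - min(i))}: attains 0 and 1, and is
#' invariant under positive affine transforms of the input.
#'
#' @param clipped numeric vector with max > min.
#' @return Vector in [0, 1].
#' @export
normalizeIntensity <- function(clipped) {
  lo <- min(clipped); hi <- max(clipped)
  if (hi <= lo) stop("degenerate intensity range")
  (clipped - lo) / (hi - lo)
}

#' Average normalized intensity over the lamina
#'
#' Sum of normalized intensities divided by the lamina voxel count;
#' independent of voxel size by construction.
#'
#' @param inorm normalized intensities of the mask voxels.
#' @return Scalar in [0, 1].
#' @export
averageNormalizedIntensity <- function(inorm) {
  if (!length(inorm)) stop("empty mask")
  sum(inorm) / length(inorm)
}

#' Skewness of the normalized lamina intensity distribution
#'
#' Third standardized moment, mean(((i - mean) / sigma)^3), with sigma the
#' population standard deviation. Implemented streaming-style from raw
#' moments (sums of i, i^2, i^3), so it can be accumulated from a histogram
#' without revisiting the voxel list.
#'
#' @param inorm normalized intensities of the mask voxels.
#' @return The skewness (dimensionless).
#' @export
intensitySkewness <- function(inorm) {
  n <- length(inorm)
  if (!n) stop("empty mask")
  s1 <- sum(inorm); s2 <- sum(inorm^2); s3 <- sum(inorm^3)
  m <- s1 / n
  var <- s2 / n - m^2
  if (var <= 0) stop("zero intensity variance")
  m3 <- s3 / n - 3 * m * s2 / n + 2 * m^3
  m3 / var^1.5
}

#' Per-voxel Gaussian curvature of the lamina surface
#'
#' Implicit-surface (isophote) curvature computed from the gray-scale
#' volume at the mask voxels. First and second Gaussian-derivative
#' responses are taken at scale \code{sigmaG}; the surface normal is the
#' dominant eigenvector of the gradient structure tensor averaged at scale
#' \code{sigmaW} (robust against noise on the thin shell); the shape
#' operator is the Hessian restricted to the tangent plane, divided by the
#' gradient magnitude. Its eigenvalues are the principal curvatures
#' kappa1 >= kappa2 and K = kappa1 * kappa2. The sign convention follows
#' the isophote normal oriented along the intensity gradient; K is
#' independent of that orientation. Voxels whose gradient magnitude is
#' below \code{gradientFloor} times the mask maximum are excluded (the
#' ratio 0/0 at the exact shell ridge is otherwise unstable under noise)
#' and counted.
#'
#' @param volume the isotropic [VoxelGrid3D-class] (smoothing is provided
#'   by the derivative filters themselves).
#' @param mask a [LaminaMask-class] on the same grid.
#' @param params a [MeasurementParams-class].
#' @return A [CurvatureField-class]; curvatures in nm^-1 / nm^-2.
#' @export
curvatureField <- function(volume, mask, params = measurementParams()) {
  stopifnot(is(volume, "VoxelGrid3D"), is(mask, "LaminaMask"),
            is(params, "MeasurementParams"))
  if (!isIsotropic(volume)) stop("volume must be isotropic")
  m <- voxelValues(mask)
  if (!identical(dim(voxelValues(volume)), dim(m)))
    stop("volume/mask shape mismatch")
  idx <- which(m)
  if (!length(idx)) stop("empty mask")
  v <- voxelValues(volume)
  sg <- params@sigmaG; sw <- params@sigmaW
  ## gradient and Hessian in voxel units
  gz <- .gaussDeriv3d(v, sg, c(1, 0, 0))
  gy <- .gaussDeriv3d(v, sg, c(0, 1, 0))
  gx <- .gaussDeriv3d(v, sg, c(0, 0, 1))
  hzz <- .gaussDeriv3d(v, sg, c(2, 0, 0))
  hyy <- .gaussDeriv3d(v, sg, c(0, 2, 0))
  hxx <- .gaussDeriv3d(v, sg, c(0, 0, 2))
  hzy <- .gaussDeriv3d(v, sg, c(1, 1, 0))
  hzx <- .gaussDeriv3d(v, sg, c(1, 0, 1))
  hyx <- .gaussDeriv3d(v, sg, c(0, 1, 1))
  ## gradient structure tensor, averaged at sigmaW
  sigW <- rep(sw, 3)
  tzz <- .gaussBlur3d(gz * gz, sigW)[idx]
  tyy <- .gaussBlur3d(gy * gy, sigW)[idx]
  txx <- .gaussBlur3d(gx * gx, sigW)[idx]
  tzy <- .gaussBlur3d(gz * gy, sigW)[idx]
  tzx <- .gaussBlur3d(gz * gx, sigW)[idx]
  tyx <- .gaussBlur3d(gy * gx, sigW)[idx]
  gz <- gz[idx]; gy <- gy[idx]; gx <- gx[idx]
  gmag <- sqrt(gz^2 + gy^2 + gx^2)
  floorAbs <- params@gradientFloor * max(gmag)
  keep <- gmag > floorAbs & gmag > 0
  if (!any(keep)) stop("all mask voxels have degenerate gradients")
  excluded <- sum(!keep)
  sel <- function(x) x[keep]
  gz <- sel(gz); gy <- sel(gy); gx <- sel(gx); gmag <- sel(gmag)
  tzz <- sel(tzz); tyy <- sel(tyy); txx <- sel(txx)
  tzy <- sel(tzy); tzx <- sel(tzx); tyx <- sel(tyx)
  hzz <- hzz[idx][keep]; hyy <- hyy[idx][keep]; hxx <- hxx[idx][keep]
  hzy <- hzy[idx][keep]; hzx <- hzx[idx][keep]; hyx <- hyx[idx][keep]
  ## dominant eigenvector of the tensor by power iteration, seeded with the
  ## local gradient (PSD tensor; the normal eigenvalue dominates on a shell)
  nz <- gz / gmag; ny <- gy / gmag; nx <- gx / gmag
  for (it in 1:25) {
    wz <- tzz * nz + tzy * ny + tzx * nx
    wy <- tzy * nz + tyy * ny + tyx * nx
    wx <- tzx * nz + tyx * ny + txx * nx
    nrm <- sqrt(wz^2 + wy^2 + wx^2)
    bad <- nrm < 1e-300
    nz <- ifelse(bad, nz, wz / nrm)
    ny <- ifelse(bad, ny, wy / nrm)
    nx <- ifelse(bad, nx, wx / nrm)
  }
  ## orient along the gradient
  sgn <- sign(nz * gz + ny * gy + nx * gx)
  sgn[sgn == 0] <- 1
  nz <- nz * sgn; ny <- ny * sgn; nx <- nx * sgn
  ## orthonormal tangent basis (t1, t2): t1 = n x a, a the axis least
  ## aligned with n
  pickZ <- abs(nz) <= pmin(abs(ny), abs(nx))
  pickY <- !pickZ & abs(ny) <= abs(nx)
  az <- as.numeric(pickZ)
  ay <- as.numeric(pickY)
  ax <- as.numeric(!pickZ & !pickY)
  t1z <- ny * ax - nx * ay
  t1y <- nx * az - nz * ax
  t1x <- nz * ay - ny * az
  nrm1 <- sqrt(t1z^2 + t1y^2 + t1x^2)
  t1z <- t1z / nrm1; t1y <- t1y / nrm1; t1x <- t1x / nrm1
  t2z <- ny * t1x - nx * t1y
  t2y <- nx * t1z - nz * t1x
  t2x <- nz * t1y - ny * t1z
  ## Hessian quadratic forms on the tangent basis
  H <- function(az_, ay_, ax_, bz, by, bx)
    hzz * az_ * bz + hyy * ay_ * by + hxx * ax_ * bx +
    hzy * (az_ * by + ay_ * bz) +
    hzx * (az_ * bx + ax_ * bz) +
    hyx * (ay_ * bx + ax_ * by)
  a11 <- -H(t1z, t1y, t1x, t1z, t1y, t1x) / gmag
  a12 <- -H(t1z, t1y, t1x, t2z, t2y, t2x) / gmag
  a22 <- -H(t2z, t2y, t2x, t2z, t2y, t2x) / gmag
  mid <- (a11 + a22) / 2
  disc <- sqrt(pmax(((a11 - a22) / 2)^2 + a12^2, 0))
  s <- spacingNm(volume)[1]
  k1 <- (mid + disc) / s
  k2 <- (mid - disc) / s
  new("CurvatureField", K = k1 * k2, kappa1 = k1, kappa2 = k2,
      index = idx[keep], excludedCount = as.integer(excluded),
      sigmaG = sg, sigmaW = sw, spacing = s)
}

#' Surface area of the convex hull of a mask, in nm^2
#'
#' The hull of the voxel centres is used (internal structure of the mask is
#' ignored by hull idempotence). The area is evaluated by Cauchy's
#' projection formula for convex bodies -- four times the mean area of the
#' hull's planar shadows -- averaged over a deterministic Fibonacci grid of
#' projection directions; each shadow is the 2D convex hull of the
#' projected candidate points. Candidates are reduced beforehand to the
#' per-column extreme voxels, which preserves the hull exactly. Accuracy is
#' a fraction of a percent, far below the half-voxel centre-vs-boundary
#' convention.
#'
#' @param mask a [LaminaMask-class] spanning >= 4 non-coplanar voxels.
#' @param nDirections number of projection directions.
#' @return Hull surface area in nm^2.
#' @export
convexHullArea <- function(mask, nDirections = 800) {
  stopifnot(is(mask, "LaminaMask"))
  pts <- which(voxelValues(mask), arr.ind = TRUE)  # (z, y, x) voxel indices
  if (nrow(pts) < 4) stop("mask too small for a 3D hull")
  ## keep only the min/max z voxel of every (y, x) column: a hull vertex is
  ## extreme within its own column, so this reduction preserves the hull
  key <- pts[, 2] + (max(pts[, 2]) + 1) * pts[, 3]
  ord <- order(key, pts[, 1])
  p <- pts[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  last <- !duplicated(k, fromLast = TRUE)
  p <- unique(rbind(p[first, , drop = FALSE], p[last, , drop = FALSE]))
  ## non-degeneracy: rank of centred points must be 3
  pc <- sweep(p, 2, colMeans(p))
  if (qr(pc)$rank < 3) stop("degenerate mask: voxels are coplanar or collinear")
  u <- .fibonacciDirections(nDirections)
  areas <- numeric(nDirections)
  for (i in seq_len(nDirections)) {
    d <- u[i, ]
    a <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v1 <- c(d[2] * a[3] - d[3] * a[2],
            d[3] * a[1] - d[1] * a[3],
            d[1] * a[2] - d[2] * a[1])
    v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(d[2] * v1[3] - d[3] * v1[2],
            d[3] * v1[1] - d[1] * v1[3],
            d[1] * v1[2] - d[2] * v1[1])
    px <- pc %*% v1
    py <- pc %*% v2
    h <- grDevices::chull(px, py)
    xs <- px[h]; ys <- py[h]
    areas[i] <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  }
  4 * mean(areas) * spacingNm(mask)^2
}

## Deterministic quasi-uniform directions on the sphere (Fibonacci lattice).
.fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Normalized average absolute Gaussian curvature (K_naaGc)
#'
#' Mean |K| over the lamina voxels multiplied by the convex hull area of
#' the mask: a dimensionless, voxel-size-independent shape descriptor that
#' equals 4*pi for a perfect sphere of any radius.
#'
#' @param field a [CurvatureField-class].
#' @param hullAreaNm2 convex hull area from [convexHullArea()], nm^2.
#' @return Scalar K_naaGc (>= 0).
#' @export
normalizedCurvature <- function(field, hullAreaNm2) {
  stopifnot(is(field, "CurvatureField"))
  if (!length(field@K)) stop("empty curvature field")
  if (hullAreaNm2 <= 0) stop("hull area must be > 0")
  hullAreaNm2 * mean(abs(field@K))
}

#' Measure the three lamina shape features of one cell
#'
#' Runs segmentation and then the full measurement chain: clip intensity
#' outliers on the masked isotropic intensities, normalize to [0, 1],
#' average normalized intensity and skewness, Gaussian curvature field, and
#' the hull-normalized absolute curvature. Returns one feature row.
#'
#' @param grid the recorded [VoxelGrid3D-class].
#' @param optics an [OpticsConfig-class].
#' @param segParams a [SegmentationParams-class].
#' @param measParams a [MeasurementParams-class].
#' @param cellId identifier copied into the row.
#' @return A one-row \code{data.frame}: cell_id, i_average, i_skewness,
#'   K_naaGc, mask_voxels, A_CH_nm2, excluded_voxels, usable.
#' @export
measureCell <- function(grid, optics = opticsConfig(),
                        segParams = segmentationParams(),
                        measParams = measurementParams(),
                        cellId = "cell") {
  mask <- segmentLamina(grid, optics, segParams)
  iso <- attr(mask, "iso")
  measureSegmentedCell(iso, mask, measParams, cellId)
}

#' Measure features from an already segmented cell
#'
#' @param iso the isotropized intensity [VoxelGrid3D-class].
#' @param mask the [LaminaMask-class] on the same grid.
#' @param measParams a [MeasurementParams-class].
#' @param cellId identifier copied into the row.
#' @return A one-row \code{data.frame} (see [measureCell()]).
#' @export
measureSegmentedCell <- function(iso, mask, measParams = measurementParams(),
                                 cellId = "cell") {
  qc <- qcMask(mask)
  ints <- voxelValues(iso)[voxelValues(mask)]
  inorm <- normalizeIntensity(clipOutliers(ints, measParams@clipK))
  field <- curvatureField(iso, mask, measParams)
  hull <- convexHullArea(mask)
  data.frame(cell_id = cellId,
             i_average = averageNormalizedIntensity(inorm),
             i_skewness = intensitySkewness(inorm),
             K_naaGc = normalizedCurvature(field, hull),
             mask_voxels = voxelCount(mask),
             A_CH_nm2 = hull,
             excluded_voxels = field@excludedCount,
             usable = qc$usable,
             stringsAsFactors = FALSE)
}

#' Projected spatial maps of intensity and curvature
#'
#' Masked normalized intensity and |K| are summed along the projection axis
#' and divided by the per-column mask voxel count, collapsing the 3D lamina
#' onto a single cross-section per cell. Columns with no mask voxels are
#' NA. The curvature map is typically displayed on a log scale.
#'
#' @param iso isotropized intensity grid.
#' @param mask lamina mask.
#' @param field [CurvatureField-class] for the same mask.
#' @param axis projection axis: 1 = z, 2 = y, 3 = x.
#' @return list with matrices \code{intensity} and \code{curvature}.
#' @export
spatialMaps <- function(iso, mask, field, axis = 2) {
  stopifnot(axis %in% 1:3)
  m <- voxelValues(mask)
  if (!any(m)) stop("empty mask")
  ints <- voxelValues(iso)[m]
  inorm <- normalizeIntensity(clipOutliers(ints))
  d <- dim(m)
  iArr <- array(0, d); iArr[which(m)] <- inorm
  kArr <- array(0, d); kArr[field@index] <- abs(field@K)
  kMask <- array(FALSE, d); kMask[field@index] <- TRUE
  proj <- function(a, ax) apply(a, setdiff(1:3, ax), sum)
  cnt <- proj(m + 0, axis)
  kcnt <- proj(kMask + 0, axis)
  iMap <- proj(iArr, axis) / ifelse(cnt > 0, cnt, NA)
  kMap <- proj(kArr, axis) / ifelse(kcnt > 0, kcnt, NA)
  list(intensity = iMap, curvature = kMap)
}

#' Intensity-curvature joint histogram and correlation
#'
#' Pearson correlation between normalized intensity and |K| over the
#' lamina voxels, plus the 2D histogram of the pairs (bin counts sum to the
#' number of voxels).
#'
#' @param inorm normalized intensities at the curvature-field voxels.
#' @param absK absolute Gaussian curvatures, same length.
#' @param bins number of bins per dimension.
#' @return list: \code{rho}, \code{histogram} (bins x bins matrix),
#'   \code{intensity_breaks}, \code{curvature_breaks}.
#' @export
intensityCurvatureCorrelation <- function(inorm, absK, bins = 64) {
  if (length(inorm) != length(absK)) stop("length mismatch")
  if (length(inorm) < 2) stop("need at least 2 voxels")
  if (stats::sd(inorm) == 0 || stats::sd(absK) == 0)
    stop("zero variance in intensity or curvature")
  bi <- seq(min(inorm), max(inorm), length.out = bins + 1)
  bk <- seq(min(absK), max(absK), length.out = bins + 1)
  ci <- findInterval(inorm, bi, rightmost.closed = TRUE)
  ck <- findInterval(absK, bk, rightmost.closed = TRUE)
  h <- matrix(0L, bins, bins)
  tab <- table(factor(ci, levels = 1:bins), factor(ck, levels = 1:bins))
  h[] <- as.integer(tab)
  list(rho = stats::cor(inorm, absK), histogram = h,
       intensity_breaks = bi, curvature_breaks = bk)
}
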