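#' Heavily smoothed image for local thresholding
#'
#' Separable Gaussian smoothing with a lateral sigma applied in both
#' in-plane axes and an axial sigma along z (the order of application is
#' immaterial by separability). Sigmas are given in nm and converted to
#' voxels via the grid spacing; defaults correspond to 1 voxel laterally
#' (~1/6 of the lateral PSF extent) and 15 voxels axially (~3/4 of the
#' axial PSF extent) at 60 nm pitch.
#'
#' @param grid a sampling-isotropic [VoxelGrid3D-class].
#' @param sigmaL lateral smoothing sigma, nm.
#' @param sigmaA axial smoothing sigma, nm.
#' @return The smoothed grid (\code{i_blur}).
#' @export
smoothAnisotropic <- function(grid, sigmaL = 60, sigmaA = 900) {
  stopifnot(is(grid, "VoxelGrid3D"))
  if (sigmaL < 0 || sigmaA < 0) stop("sigmas must be non-negative")
  if (!isIsotropic(grid)) stop("grid must be isotropically sampled")
  s <- spacingNm(grid)[1]
  a <- .gaussBlur3d(voxelValues(grid), c(sigmaA / s, sigmaL / s, sigmaL / s))
  VoxelGrid3D(a, spacingNm(grid),
              c(provenance(grid),
                sprintf("smoothed sigmaL %.0f nm, sigmaA %.0f nm", sigmaL, sigmaA)))
}

#' Derive the local-threshold constants from the smoothed image
#'
#' The transition intensity between foreground and background is set to a
#' fraction of the smoothed-image maximum, \code{Ic = icFraction *
#' max(i_blur)} (default 1/3 -- set below the mid-intensity because Poisson
#' noise is larger, on an absolute scale, at high intensities), and the
#' offset follows as \code{beta = Ic * (1 - alpha)}. With the defaults
#' alpha = 0.9 and icFraction = 1/3, beta = max(i_blur)/30. Because beta
#' scales with the image maximum, the resulting mask is invariant under a
#' positive rescaling of the input intensities.
#'
#' @param iBlur the smoothed [VoxelGrid3D-class].
#' @param alpha scaling constant in (0, 1).
#' @param icFraction transition intensity as a fraction of max(i_blur).
#' @return named numeric: \code{alpha}, \code{beta}, \code{Ic}.
#' @export
deriveThresholdParams <- function(iBlur, alpha = 0.9, icFraction = 1/3) {
  stopifnot(is(iBlur, "VoxelGrid3D"))
  mx <- max(voxelValues(iBlur))
  if (mx <= 0) stop("degenerate smoothed image: max(i_blur) must be > 0")
  ic <- icFraction * mx
  c(alpha = alpha, beta = ic * (1 - alpha), Ic = ic)
}

#' Unsharp-masked image
#'
#' Emphasizes the thin bright shell by subtracting the scaled-and-offset
#' smoothed image: \code{i_isotropic - (alpha * i_blur + beta)}. The result
#' is real-valued and may be negative; its zero crossing is the locally
#' adaptive segmentation boundary.
#'
#' @param iIsotropic the isotropized [VoxelGrid3D-class].
#' @param iBlur the smoothed grid from [smoothAnisotropic()].
#' @param alpha,beta threshold constants (see [deriveThresholdParams()]).
#' @return The unsharp-masked grid.
#' @export
unsharpMask <- function(iIsotropic, iBlur, alpha, beta) {
  stopifnot(is(iIsotropic, "VoxelGrid3D"), is(iBlur, "VoxelGrid3D"))
  if (!identical(dim(voxelValues(iIsotropic)), dim(voxelValues(iBlur))) ||
      any(spacingNm(iIsotropic) != spacingNm(iBlur)))
    stop("shape/spacing mismatch between i_isotropic and i_blur")
  a <- voxelValues(iIsotropic) - (alpha * voxelValues(iBlur) + beta)
  VoxelGrid3D(a, spacingNm(iIsotropic),
              c(provenance(iIsotropic),
                sprintf("unsharp mask alpha %.3f beta %.4g", alpha, beta)))
}

#' Threshold the unsharp-masked image at zero
#'
#' A voxel belongs to the lamina iff its unsharp-masked value is >= 0 (ties
#' assigned to the lamina; with real-valued images the tie case is not
#' critical).
#'
#' @param iUm the unsharp-masked [VoxelGrid3D-class].
#' @return A [LaminaMask-class].
#' @export
thresholdMask <- function(iUm) {
  stopifnot(is(iUm, "VoxelGrid3D"))
  if (!isIsotropic(iUm)) stop("mask must live on an isotropic grid")
  LaminaMask(voxelValues(iUm) >= 0, spacingNm(iUm)[1])
}

#' Digital sphere structuring element
#'
#' All integer offsets within Euclidean distance \code{radius} of the
#' origin. Radius 2.7 voxels gives exactly 81 offsets (162 nm at 60 nm
#' pitch), the closing element used throughout.
#'
#' @param radius radius in voxels (>= 0).
#' @return Integer matrix of offsets, one (dz, dy, dx) row each; symmetric
#'   under negation and containing the origin.
#' @export
digitalSphere <- function(radius = 2.7) {
  if (radius < 0) stop("radius must be >= 0")
  r <- floor(radius)
  g <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  g <- g[rowSums(g^2) <= radius^2 + 1e-12, , drop = FALSE]
  storage.mode(g) <- "integer"
  rownames(g) <- NULL
  g
}

#' Morphological closing of a lamina mask
#'
#' Dilation followed by erosion with the same structuring element; fills
#' small punctures in the segmented shell while keeping the enclosed
#' nuclear interior open. Outside the stack counts as background for the
#' dilation and as foreground for the erosion, so the closing is extensive
#' (result contains the input) and idempotent.
#'
#' @param mask a [LaminaMask-class].
#' @param se structuring element from [digitalSphere()].
#' @return The closed [LaminaMask-class].
#' @export
closeMask <- function(mask, se = digitalSphere(2.7)) {
  stopifnot(is(mask, "LaminaMask"))
  m <- voxelValues(mask)
  if (!any(m) || nrow(se) == 1L) return(mask)
  m <- .morph3d(.morph3d(m, se, "dilate"), se, "erode")
  LaminaMask(m, spacingNm(mask))
}

#' Segment the nuclear lamina from a recorded stack
#'
#' The full segmentation chain: isotropic resampling, lateral blur
#' compensation, heavy anisotropic smoothing, per-image threshold
#' derivation, unsharp masking, zero thresholding, and morphological
#' closing. Every parameter actually used is recorded in the returned
#' attributes.
#'
#' @param grid the recorded [VoxelGrid3D-class] (anisotropic allowed).
#' @param optics an [OpticsConfig-class] (PSF sigmas for blur compensation).
#' @param params a [SegmentationParams-class].
#' @param targetSpacing isotropic pitch in nm (default: smallest input pitch).
#' @return A [LaminaMask-class] with attributes \code{iso} (the
#'   blur-corrected isotropic grid), \code{iBlur}, \code{threshold} (alpha,
#'   beta, Ic), and \code{params}.
#' @export
segmentLamina <- function(grid, optics = opticsConfig(),
                          params = segmentationParams(),
                          targetSpacing = min(spacingNm(grid))) {
  stopifnot(is(grid, "VoxelGrid3D"), is(params, "SegmentationParams"))
  iso <- resampleIsotropic(grid, targetSpacing)
  iso <- applyLateralBlur(iso, blurCorrectionSigma(optics@sigmaR, optics@sigmaZ))
  iBlur <- smoothAnisotropic(iso, params@sigmaL, params@sigmaA)
  if (is.na(params@beta)) {
    th <- deriveThresholdParams(iBlur, params@alpha, params@icFraction)
  } else {
    th <- c(alpha = params@alpha, beta = params@beta,
            Ic = params@beta / (1 - params@alpha))
  }
  um <- unsharpMask(iso, iBlur, th[["alpha"]], th[["beta"]])
  mask <- closeMask(thresholdMask(um), digitalSphere(params@closingRadius))
  attr(mask, "iso") <- iso
  attr(mask, "iBlur") <- iBlur
  attr(mask, "threshold") <- th
  attr(mask, "params") <- params
  mask
}

#' Quality control of a segmented mask
#'
#' A mask is usable when its largest 26-connected foreground component
#' holds at least \code{minLargestFraction} of the mask voxels and the
#' 6-connected background splits into at least two components (i.e. an
#' enclosed nuclear interior exists).
#'
#' @param mask a [LaminaMask-class].
#' @param minLargestFraction required share of the largest component.
#' @return list: \code{usable}, \code{largest_component_fraction},
#'   \code{has_enclosed_cavity}, \code{n_foreground_components}.
#' @export
qcMask <- function(mask, minLargestFraction = 0.9) {
  stopifnot(is(mask, "LaminaMask"))
  m <- voxelValues(mask)
  if (!any(m))
    return(list(usable = FALSE, largest_component_fraction = 0,
                has_enclosed_cavity = FALSE, n_foreground_components = 0L))
  fg <- .labelComponents(m, 26)
  frac <- fg$sizes[1] / sum(m)
  bg <- .labelComponents(!m, 6)
  cavity <- length(bg$sizes) >= 2L
  list(usable = frac >= minLargestFraction && cavity,
       largest_component_fraction = frac,
       has_enclosed_cavity = cavity,
       n_foreground_components = length(fg$sizes))
}
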