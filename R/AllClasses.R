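#' @import methods
NULL

## Axis order is (z, y, x) for every 3D array in this package: page order of
## a confocal stack maps to the first dimension. Spacing vectors follow the
## same order, (dz, dy, dx), in nanometres. This is asserted at I/O time.

#' VoxelGrid3D: a 3D scalar intensity field with physical voxel spacing
#'
#' The carrier for every volumetric image in the pipeline: the recorded
#' stack, the isotropized image, the heavily smoothed image used for local
#' thresholding, and the unsharp-masked residual. Values are non-negative
#' integers on ingest and become real-valued after isotropization.
#'
#' @slot values 3D numeric array, axis order (z, y, x).
#' @slot spacing numeric(3), voxel pitch (dz, dy, dx) in nm; all > 0.
#' @slot provenance character vector, free-text processing history.
#' @export
setClass("VoxelGrid3D",
  representation(values = "array", spacing = "numeric",
                 provenance = "character"))

setValidity("VoxelGrid3D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array (z, y, x)")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite numbers (dz, dy, dx) in nm")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid3D
#'
#' @param values 3D numeric array in (z, y, x) order.
#' @param spacing numeric(3), (dz, dy, dx) in nm.
#' @param provenance optional character vector of processing notes.
#' @return A [VoxelGrid3D-class] object.
#' @export
VoxelGrid3D <- function(values, spacing, provenance = character()) {
  new("VoxelGrid3D", values = values, spacing = as.numeric(spacing),
      provenance = as.character(provenance))
}

#' LaminaMask: binary 3D voxel set marking lamina membership
#'
#' The output of thresholding the unsharp-masked image (and of the
#' subsequent morphological closing). Always lives on an isotropic grid.
#'
#' @slot values 3D logical array, axis order (z, y, x).
#' @slot spacing single positive number, the isotropic voxel size in nm.
#' @export
setClass("LaminaMask",
  representation(values = "array", spacing = "numeric"))

setValidity("LaminaMask", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L || !is.logical(object@values))
    msg <- c(msg, "values must be a 3D logical array")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive isotropic voxel size in nm")
  if (length(msg)) msg else TRUE
})

#' Construct a LaminaMask
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param spacing isotropic voxel size in nm.
#' @return A [LaminaMask-class] object.
#' @export
LaminaMask <- function(values, spacing) {
  storage.mode(values) <- "logical"
  new("LaminaMask", values = values, spacing = as.numeric(spacing))
}

#' OpticsConfig: confocal acquisition parameters and the Gaussian PSF model
#'
#' The point spread function of the confocal system is modelled as an
#' anisotropic 3D Gaussian with lateral width \code{sigmaR} and axial width
#' \code{sigmaZ} (both nm, \code{sigmaR <= sigmaZ}).
#'
#' @slot lambda emission wavelength in nm.
#' @slot na numerical aperture.
#' @slot magnification objective magnification.
#' @slot sigmaR lateral PSF Gaussian sigma, nm.
#' @slot sigmaZ axial PSF Gaussian sigma, nm.
#' @export
setClass("OpticsConfig",
  representation(lambda = "numeric", na = "numeric",
                 magnification = "numeric",
                 sigmaR = "numeric", sigmaZ = "numeric"))

setValidity("OpticsConfig", function(object) {
  msg <- character()
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@na <= 0 || object@na >= 1.6)
    msg <- c(msg, "numerical aperture must be in (0, 1.6)")
  if (object@sigmaR <= 0 || object@sigmaZ <= 0)
    msg <- c(msg, "PSF sigmas must be > 0")
  if (object@sigmaR > object@sigmaZ)
    msg <- c(msg, "sigmaR must not exceed sigmaZ (lateral blur compensation would be imaginary)")
  if (length(msg)) msg else TRUE
})

#' Construct an OpticsConfig
#'
#' Defaults describe a 63x / NA 1.32 oil objective imaging GFP emission
#' (509 nm) with a Gaussian PSF of sigma 62 nm laterally, 190 nm axially.
#'
#' @param lambda emission wavelength, nm.
#' @param na numerical aperture.
#' @param magnification objective magnification.
#' @param sigmaR,sigmaZ PSF Gaussian widths, nm.
#' @return An [OpticsConfig-class] object.
#' @export
opticsConfig <- function(lambda = 509, na = 1.32, magnification = 63,
                         sigmaR = 62, sigmaZ = 190) {
  new("OpticsConfig", lambda = lambda, na = na,
      magnification = magnification, sigmaR = sigmaR, sigmaZ = sigmaZ)
}

#' SegmentationParams: the unsharp-masking "magic numbers"
#'
#' The locally adaptive threshold is \code{alpha * i_blur + beta}; the
#' transition intensity is \code{Ic = beta / (1 - alpha)}. By default
#' \code{beta} is derived per image as \code{Ic = max(i_blur) * icFraction}
#' with \code{icFraction = 1/3}, so that with \code{alpha = 0.9},
#' \code{beta = max(i_blur)/30}. A fixed \code{beta} override is available
#' for reproducing runs with a frozen threshold.
#'
#' @slot sigmaL lateral smoothing sigma, nm (default 60).
#' @slot sigmaA axial smoothing sigma, nm (default 900 = 15 voxels at 60 nm).
#' @slot alpha dimensionless, in (0, 1).
#' @slot icFraction fraction of max(i_blur) defining the transition intensity.
#' @slot beta fixed offset override (NA_real_ = derive per image).
#' @slot closingRadius structuring-element radius in voxels.
#' @export
setClass("SegmentationParams",
  representation(sigmaL = "numeric", sigmaA = "numeric", alpha = "numeric",
                 icFraction = "numeric", beta = "numeric",
                 closingRadius = "numeric"))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!is.na(object@beta) && object@beta <= 0)
    msg <- c(msg, "beta override must be > 0")
  if (object@icFraction <= 0 || object@icFraction >= 1)
    msg <- c(msg, "icFraction must be in (0, 1)")
  if (object@sigmaL < 0 || object@sigmaA < 0)
    msg <- c(msg, "smoothing sigmas must be >= 0")
  if (object@closingRadius < 0)
    msg <- c(msg, "closingRadius must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct SegmentationParams
#'
#' @param sigmaL lateral smoothing sigma in nm.
#' @param sigmaA axial smoothing sigma in nm.
#' @param alpha scaling of the smoothed image in the local threshold.
#' @param icFraction transition intensity as a fraction of max(i_blur).
#' @param beta optional fixed offset; NA derives it from icFraction.
#' @param closingRadius closing structuring-element radius in voxels.
#' @return A [SegmentationParams-class] object.
#' @export
segmentationParams <- function(sigmaL = 60, sigmaA = 900, alpha = 0.9,
                               icFraction = 1/3, beta = NA_real_,
                               closingRadius = 2.7) {
  new("SegmentationParams", sigmaL = sigmaL, sigmaA = sigmaA, alpha = alpha,
      icFraction = icFraction, beta = as.numeric(beta),
      closingRadius = closingRadius)
}

#' MeasurementParams: scales for intensity and curvature measurement
#'
#' @slot clipK outlier clipping bound in sigma-multiples (default 4).
#' @slot sigmaG Gaussian derivative scale, voxels (default 3, ~180 nm).
#' @slot sigmaW gradient-structure-tensor averaging scale, voxels (default 7, ~420 nm).
#' @slot gradientFloor relative gradient-magnitude floor below which voxels
#'   are excluded from curvature estimation (fraction of the max gradient
#'   magnitude over the mask).
#' @export
setClass("MeasurementParams",
  representation(clipK = "numeric", sigmaG = "numeric", sigmaW = "numeric",
                 gradientFloor = "numeric"))

setValidity("MeasurementParams", function(object) {
  msg <- character()
  if (object@clipK <= 0) msg <- c(msg, "clipK must be > 0")
  if (!(object@sigmaW > object@sigmaG && object@sigmaG > 0))
    msg <- c(msg, "require sigmaW > sigmaG > 0")
  if (object@gradientFloor < 0 || object@gradientFloor >= 1)
    msg <- c(msg, "gradientFloor must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct MeasurementParams
#'
#' @param clipK clipping bound, sigma-multiples.
#' @param sigmaG derivative filter scale, voxels.
#' @param sigmaW tensor averaging scale, voxels.
#' @param gradientFloor relative degenerate-gradient exclusion threshold.
#' @return A [MeasurementParams-class] object.
#' @export
measurementParams <- function(clipK = 4, sigmaG = 3, sigmaW = 7,
                              gradientFloor = 0.01) {
  new("MeasurementParams", clipK = clipK, sigmaG = sigmaG, sigmaW = sigmaW,
      gradientFloor = gradientFloor)
}

#' CurvatureField: per-lamina-voxel Gaussian curvature
#'
#' Principal curvatures kappa1 >= kappa2 (nm^-1) and their product, the
#' Gaussian curvature K (nm^-2), evaluated at the retained mask voxels.
#' \code{index} holds the linear indices of those voxels in the source
#' volume; voxels whose gradient magnitude fell below the floor are counted
#' in \code{excludedCount}.
#'
#' @slot K numeric, Gaussian curvature per retained voxel, nm^-2.
#' @slot kappa1,kappa2 numeric, principal curvatures, nm^-1.
#' @slot index integer, linear indices of retained voxels.
#' @slot excludedCount integer, degenerate-gradient voxels dropped.
#' @slot sigmaG,sigmaW numeric, the scales used (voxels).
#' @slot spacing numeric, isotropic voxel size in nm.
#' @export
setClass("CurvatureField",
  representation(K = "numeric", kappa1 = "numeric", kappa2 = "numeric",
                 index = "integer", excludedCount = "integer",
                 sigmaG = "numeric", sigmaW = "numeric", spacing = "numeric"))

setValidity("CurvatureField", function(object) {
  msg <- character()
  n <- length(object@K)
  if (length(object@kappa1) != n || length(object@kappa2) != n ||
      length(object@index) != n)
    msg <- c(msg, "K, kappa1, kappa2, index must have equal length")
  if (n && any(object@kappa1 + 1e-12 < object@kappa2))
    msg <- c(msg, "kappa1 must be >= kappa2")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of a synthetic lamina phantom
#'
#' Describes a thin (sub-resolution) ellipsoidal shell with optional
#' invaginations (inward Gaussian-profile dents) and intensity hotspots
#' (multiplicative patches), to be blurred by an anisotropic Gaussian PSF
#' and corrupted by Poisson noise.
#'
#' @slot semiAxes numeric(3), ellipsoid semi-axes (a, b, c) along (x, y, z), nm.
#' @slot shellThickness shell thickness, nm (sub-resolution, 30-100 nm scale).
#' @slot invaginations list of \code{list(direction, depth, width)}:
#'   unit direction (x, y, z), dent depth nm, dent arc width nm.
#' @slot hotspots list of \code{list(direction, amplitude, extent)}:
#'   anchor unit direction, multiplicative amplitude, angular extent rad.
#' @slot basePhotons expected photon count at the blurred-shell peak.
#' @slot optics an [OpticsConfig-class] providing the PSF sigmas.
#' @slot spacing numeric(3), acquisition voxel pitch (dz, dy, dx), nm.
#' @slot fieldShape integer(3), stack dimensions (nz, ny, nx).
#' @slot seed RNG seed for the Poisson acquisition.
#' @export
setClass("PhantomSpec",
  representation(semiAxes = "numeric", shellThickness = "numeric",
                 invaginations = "list", hotspots = "list",
                 basePhotons = "numeric", optics = "OpticsConfig",
                 spacing = "numeric", fieldShape = "integer",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@semiAxes) != 3L || any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be three positive lengths (nm)")
  if (object@shellThickness <= 0 ||
      object@shellThickness >= min(object@semiAxes) / 4)
    msg <- c(msg, "shellThickness must be positive and < min(semiAxes)/4")
  if (object@basePhotons <= 0) msg <- c(msg, "basePhotons must be > 0")
  for (h in object@hotspots)
    if (h$amplitude <= 0) msg <- c(msg, "hotspot amplitudes must be > 0")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive numbers (dz, dy, dx)")
  if (length(object@fieldShape) != 3L || any(object@fieldShape < 4L))
    msg <- c(msg, "fieldShape must be three dimensions >= 4")
  ## field must contain the blurred shell plus a 3*sigmaZ margin
  halfExtent <- (object@fieldShape - 1L) * object@spacing / 2
  need <- rev(object@semiAxes) + object@shellThickness / 2 +
    3 * object@optics@sigmaZ          # rev: semiAxes are (x,y,z), field (z,y,x)
  if (any(halfExtent < need))
    msg <- c(msg, "fieldShape too small for the blurred shell plus 3*sigmaZ margin")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param semiAxes ellipsoid semi-axes (x, y, z) in nm.
#' @param shellThickness shell thickness in nm.
#' @param invaginations list of list(direction, depth, width).
#' @param hotspots list of list(direction, amplitude, extent).
#' @param basePhotons expected peak photon count after PSF blur.
#' @param optics an OpticsConfig.
#' @param spacing acquisition voxel pitch (dz, dy, dx) in nm.
#' @param fieldShape stack dimensions (nz, ny, nx).
#' @param seed RNG seed used by [imagePhantom()].
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(semiAxes = c(1500, 1350, 1200), shellThickness = 80,
                        invaginations = list(), hotspots = list(),
                        basePhotons = 1000, optics = opticsConfig(),
                        spacing = c(162.8, 60, 60),
                        fieldShape = c(24L, 68L, 72L), seed = 1L) {
  new("PhantomSpec", semiAxes = as.numeric(semiAxes),
      shellThickness = shellThickness,
      invaginations = invaginations, hotspots = hotspots,
      basePhotons = basePhotons, optics = optics,
      spacing = as.numeric(spacing), fieldShape = as.integer(fieldShape),
      seed = as.integer(seed))
}
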