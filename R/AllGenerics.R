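#' Raw voxel values of a grid or mask
#' @param x a VoxelGrid3D or LaminaMask.
#' @return The 3D array of values ((z, y, x) order).
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' Physical voxel spacing in nm
#' @param x a VoxelGrid3D or LaminaMask.
#' @return numeric(3) (dz, dy, dx) for grids; a single number for masks.
#' @export
setGeneric("spacingNm", function(x) standardGeneric("spacingNm"))

#' Processing history of a grid
#' @param x a VoxelGrid3D.
#' @return character vector of processing notes.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Number of foreground voxels of a mask
#' @param x a LaminaMask.
#' @return integer count of TRUE voxels.
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))

#' Is a grid isotropic in sampling?
#' @param x a VoxelGrid3D.
#' @return TRUE if dz == dy == dx exactly.
#' @export
setGeneric("isIsotropic", function(x) standardGeneric("isIsotropic"))

#' @rdname voxelValues
setMethod("voxelValues", "VoxelGrid3D", function(x) x@values)
#' @rdname voxelValues
setMethod("voxelValues", "LaminaMask", function(x) x@values)

#' @rdname spacingNm
setMethod("spacingNm", "VoxelGrid3D", function(x) x@spacing)
#' @rdname spacingNm
setMethod("spacingNm", "LaminaMask", function(x) x@spacing)

#' @rdname provenance
setMethod("provenance", "VoxelGrid3D", function(x) x@provenance)

#' @rdname voxelCount
setMethod("voxelCount", "LaminaMask", function(x) sum(x@values))

#' @rdname isIsotropic
setMethod("isIsotropic", "VoxelGrid3D", function(x) {
  x@spacing[1] == x@spacing[2] && x@spacing[2] == x@spacing[3]
})

setMethod("show", "VoxelGrid3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid3D: %d x %d x %d voxels (z,y,x), spacing %.1f x %.1f x %.1f nm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@values), max(object@values)))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = " | "), "\n")
})

setMethod("show", "LaminaMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("LaminaMask: %d x %d x %d voxels, %.1f nm isotropic, %d foreground voxels\n",
              d[1], d[2], d[3], object@spacing, sum(object@values)))
})

setMethod("show", "OpticsConfig", function(object) {
  cat(sprintf("OpticsConfig: lambda %.0f nm, NA %.2f, M %.0fx, PSF sigma (r, z) = (%.0f, %.0f) nm\n",
              object@lambda, object@na, object@magnification,
              object@sigmaR, object@sigmaZ))
})

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf("SegmentationParams: sigmaL %.0f nm, sigmaA %.0f nm, alpha %.2f, Ic fraction %.3f, beta %s, closing %.1f voxels\n",
              object@sigmaL, object@sigmaA, object@alpha, object@icFraction,
              if (is.na(object@beta)) "per-image" else sprintf("%.4g", object@beta),
              object@closingRadius))
})

setMethod("show", "MeasurementParams", function(object) {
  cat(sprintf("MeasurementParams: clipK %.0f, sigmaG %.0f vox, sigmaW %.0f vox, gradient floor %.1e\n",
              object@clipK, object@sigmaG, object@sigmaW, object@gradientFloor))
})

setMethod("show", "CurvatureField", function(object) {
  cat(sprintf("CurvatureField: %d voxels (%d excluded), sigmaG %.0f, sigmaW %.0f, mean |K| = %.3e nm^-2\n",
              length(object@K), object@excludedCount, object@sigmaG,
              object@sigmaW, mean(abs(object@K))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: semi-axes (%.0f, %.0f, %.0f) nm, shell %.0f nm, %d invagination(s), %d hotspot(s)\n",
              object@semiAxes[1], object@semiAxes[2], object@semiAxes[3],
              object@shellThickness, length(object@invaginations),
              length(object@hotspots)))
  cat(sprintf("  field %d x %d x %d at (%.1f, %.1f, %.1f) nm, %.0f peak photons, seed %d\n",
              object@fieldShape[1], object@fieldShape[2], object@fieldShape[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@basePhotons, object@seed))
})
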