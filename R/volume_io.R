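#' Read a single-channel multi-page TIFF stack
#'
#' Pages map to the z axis; the returned array is in (z, y, x) order. Voxel
#' spacing is taken from \code{spacing} if given, otherwise from the JSON
#' sidecar written by [writeStack()] (\code{<path>.json}). Integer stacks
#' round-trip bit-exactly; float stacks are stored as an affine-scaled
#' 32-bit image whose scale/offset live in the sidecar.
#'
#' @param path path to a grayscale multi-page TIFF.
#' @param spacing optional numeric(3), (dz, dy, dx) in nm; overrides the sidecar.
#' @return A [VoxelGrid3D-class].
#' @export
readStack <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  side <- .readSidecar(path)
  if (is.null(spacing)) {
    if (is.null(side$spacing_nm))
      stop("no spacing given and no sidecar found for ", path)
    spacing <- side$spacing_nm
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (dz, dy, dx) in nm")
  scaled <- !is.null(side$scale)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !scaled)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("multi-channel unsupported: expected single-channel grayscale pages")
  d <- c(length(pages), dim(pages[[1]]))
  a <- array(if (scaled) 0 else 0L, d)     # integer ingest stays integer
  for (i in seq_len(d[1])) a[i, , ] <- pages[[i]]
  if (scaled) a <- a * side$scale + side$offset
  prov <- if (!is.null(side$provenance)) as.character(side$provenance)
          else sprintf("read %s", basename(path))
  VoxelGrid3D(a, spacing, prov)
}

.sidecarPath <- function(path) paste0(path, ".json")

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(list())
  jsonlite::fromJSON(sp)
}

#' Write a stack (or mask) as multi-page TIFF plus JSON sidecar
#'
#' Integer-valued grids in [0, 65535] are written as 16-bit samples
#' (lossless); other grids as affine-rescaled 32-bit samples whose
#' scale/offset are recorded in the sidecar (values restored to ~1e-7
#' relative precision of the range). Masks are written 8-bit, encoded as
#' \{0, 255\} by default or \{0, 1\} with \code{mask01 = TRUE}; either
#' round-trips through [readMask()].
#'
#' @param grid a [VoxelGrid3D-class] or [LaminaMask-class].
#' @param path output TIFF path; the sidecar goes to \code{<path>.json}.
#' @param mask01 store mask foreground as 1 instead of 255.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(grid, path, mask01 = FALSE) {
  if (is(grid, "LaminaMask")) {
    a <- voxelValues(grid) * if (mask01) 1L else 255L
    pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 255)
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 8),
                   error = function(e) stop("cannot write ", path, ": ",
                                            conditionMessage(e)))
    side <- list(spacing_nm = rep(spacingNm(grid), 3), kind = "mask",
                 mask_encoding = if (mask01) "01" else "0255")
  } else {
    a <- voxelValues(grid)
    intlike <- all(a >= 0) && all(a <= 65535) && all(a == round(a))
    if (intlike) {
      pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / 65535)
      bits <- 16
      side <- list(spacing_nm = spacingNm(grid), kind = "stack",
                   provenance = provenance(grid))
    } else {
      lo <- min(a); hi <- max(a)
      scale <- if (hi > lo) hi - lo else 1
      w <- (a - lo) / scale
      pages <- lapply(seq_len(dim(a)[1]), function(i) w[i, , ])
      bits <- 32
      side <- list(spacing_nm = spacingNm(grid), kind = "stack",
                   scale = scale, offset = lo, provenance = provenance(grid))
    }
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits),
                   error = function(e) stop("cannot write ", path, ": ",
                                            conditionMessage(e)))
  }
  jsonlite::write_json(side, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a binary mask written by [writeStack()]
#'
#' @param path TIFF path.
#' @param spacing optional isotropic voxel size in nm (overrides sidecar).
#' @return A [LaminaMask-class].
#' @export
readMask <- function(path, spacing = NULL) {
  side <- .readSidecar(path)
  if (is.null(spacing)) {
    if (is.null(side$spacing_nm)) stop("no spacing given and no sidecar for ", path)
    spacing <- side$spacing_nm[1]
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  a <- array(FALSE, d)
  for (i in seq_len(d[1])) a[i, , ] <- pages[[i]] > 0
  LaminaMask(a, spacing)
}

#' Lateral and axial PSF extents from the optics
#'
#' Lateral extent is computed as lambda/NA and truncated to integer nm;
#' axial extent as 4*lambda/NA^2, rounded to the nearest nm (half away from
#' zero). For GFP emission through a 1.32 NA oil objective this gives
#' 385 nm laterally and 1169 nm axially; the segmentation smoothing scales
#' sigmaL and sigmaA are chosen as fractions of these extents.
#'
#' @param optics an [OpticsConfig-class].
#' @return named numeric: \code{lateral} and \code{axial} extents in nm.
#' @export
psfExtents <- function(optics) {
  stopifnot(is(optics, "OpticsConfig"))
  if (optics@na == 0) stop("numerical aperture must be nonzero")
  c(lateral = trunc(optics@lambda / optics@na),
    axial = .roundHalfAway(4 * optics@lambda / optics@na^2))
}

#' Report a length in integer nanometres
#'
#' Rounds half away from zero; the convention used for every derived nm
#' quantity this package prints.
#'
#' @param x length(s) in nm.
#' @return integer nm.
#' @export
reportNm <- function(x) .roundHalfAway(x)
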