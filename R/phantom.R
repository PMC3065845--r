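## Synthetic lamina phantoms: ideal emitter density, simulated acquisition,
## and two-population generation with known ground truth.

## Radial distance (nm) from each voxel to the (possibly invaginated)
## shell mid-surface, plus the multiplicative hotspot field. Shared by
## renderShell() and phantomTruthMask(). Works on any grid geometry.
.shellGeometry <- function(spec, d, spacing) {
  co <- .coordArrays(d, spacing)
  r <- sqrt(co$X^2 + co$Y^2 + co$Z^2)
  r[r < 1e-9] <- 1e-9
  ux <- co$X / r; uy <- co$Y / r; uz <- co$Z / r
  amp <- 1
  for (h in spec@hotspots) {
    if (h$amplitude == 1) next
    w <- h$direction / sqrt(sum(h$direction^2))
    cosang <- pmin(pmax(ux * w[1] + uy * w[2] + uz * w[3], -1), 1)
    ang <- acos(cosang)
    amp <- amp * (1 + (h$amplitude - 1) * exp(-ang^2 / (2 * h$extent^2)))
  }
  list(dist = .shellGeometryAt(spec, co$X, co$Y, co$Z), amp = amp)
}

#' Render the noise-free ground-truth emitter density of a phantom
#'
#' An ellipsoidal shell of the stated thickness, with invaginations carved
#' as inward Gaussian-profile dents of the mid-surface and hotspots applied
#' as multiplicative intensity patches. The shell cross-profile is a box of
#' width \code{shellThickness} antialiased linearly over one voxel, so
#' sub-resolution shells render without aliasing. Deterministic: no RNG.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [VoxelGrid3D-class] of emitter density on the acquisition grid.
#' @export
renderShell <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@fieldShape
  geom <- .shellGeometry(spec, d, spec@spacing)
  h <- max(spec@spacing)                      # antialiasing width: one voxel
  prof <- pmin(1, pmax(0, ((spec@shellThickness + h) / 2 - abs(geom$dist)) / h))
  prof <- array(prof * geom$amp, d)
  VoxelGrid3D(prof, spec@spacing,
              sprintf("phantom shell: semi-axes (%.0f, %.0f, %.0f) nm, thickness %.0f nm",
                      spec@semiAxes[1], spec@semiAxes[2], spec@semiAxes[3],
                      spec@shellThickness))
}

#' Ground-truth lamina mask of a phantom on an isotropic grid
#'
#' Marks voxels within \code{dilateNm} of the shell volume
#' (|distance to mid-surface| <= thickness/2 + dilateNm), computed on the
#' isotropic grid that [resampleIsotropic()] would produce for the
#' phantom's acquisition geometry, so it is directly comparable with
#' pipeline masks. \code{dilateNm} accounts for PSF-induced widening of the
#' segmented shell; the default is the half-width at which a Gaussian-
#' blurred shell profile falls to 1/3 of its peak (the default transition
#' intensity), sigma being the axial PSF width.
#'
#' @param spec a [PhantomSpec-class].
#' @param targetSpacing isotropic pitch in nm.
#' @param dilateNm widening of the true shell, nm.
#' @return A [LaminaMask-class].
#' @export
phantomTruthMask <- function(spec, targetSpacing = min(spec@spacing),
                             dilateNm = spec@optics@sigmaZ * sqrt(2 * log(3))) {
  stopifnot(is(spec, "PhantomSpec"))
  dIn <- spec@fieldShape
  dOut <- as.integer(floor((dIn - 1) * spec@spacing / targetSpacing) + 1)
  ## the resampled grid keeps voxel (1,1,1) at the original origin but may
  ## trim a fraction of a voxel at the far faces, so the shell centre (the
  ## ORIGINAL field centre) is offset from the new grid centre
  shift <- ((dIn - 1) * spec@spacing - (dOut - 1) * targetSpacing) / 2
  co <- .coordArrays(dOut, rep(targetSpacing, 3))
  dist <- .shellGeometryAt(spec, co$X + shift[3], co$Y + shift[2],
                           co$Z + shift[1])
  LaminaMask(abs(dist) <= spec@shellThickness / 2 + dilateNm,
             targetSpacing)
}

## Distance to mid-surface at explicit physical coordinates.
.shellGeometryAt <- function(spec, X, Y, Z) {
  r <- sqrt(X^2 + Y^2 + Z^2)
  r[r < 1e-9] <- 1e-9
  ux <- X / r; uy <- Y / r; uz <- Z / r
  ax <- spec@semiAxes
  rSurf <- 1 / sqrt((ux / ax[1])^2 + (uy / ax[2])^2 + (uz / ax[3])^2)
  for (inv in spec@invaginations) {
    v <- inv$direction / sqrt(sum(inv$direction^2))
    if (inv$depth == 0) next
    cosang <- pmin(pmax(ux * v[1] + uy * v[2] + uz * v[3], -1), 1)
    ang <- acos(cosang)
    rAnchor <- 1 / sqrt(sum((v / ax)^2))
    sigAng <- inv$width / rAnchor
    rSurf <- rSurf - inv$depth * exp(-ang^2 / (2 * sigAng^2))
  }
  r - rSurf
}

#' Simulate the confocal acquisition of a phantom
#'
#' Convolves the ground-truth emitter density with the separable
#' anisotropic Gaussian PSF (sigmaR laterally, sigmaZ axially, unit-sum
#' kernels so expected photons are conserved), scales the result so its
#' peak equals \code{basePhotons}, and draws one Poisson sample per voxel
#' using the seed stored in the PhantomSpec (the caller's RNG state is
#' restored afterwards).
#'
#' @param truth the noise-free render from [renderShell()].
#' @param spec the originating [PhantomSpec-class].
#' @return An integer-valued [VoxelGrid3D-class].
#' @export
imagePhantom <- function(truth, spec) {
  stopifnot(is(truth, "VoxelGrid3D"), is(spec, "PhantomSpec"))
  lambda <- blurredPhantom(truth, spec)
  v <- voxelValues(lambda)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(spec@seed)
  noisy <- array(stats::rpois(length(v), v), dim(v))
  VoxelGrid3D(noisy, spec@spacing,
              c(provenance(lambda), sprintf("Poisson noise, seed %d", spec@seed)))
}

#' Noise-free blurred phantom (the Poisson mean of [imagePhantom()])
#'
#' @param truth the render from [renderShell()].
#' @param spec the originating [PhantomSpec-class].
#' @return A [VoxelGrid3D-class] of expected photon counts.
#' @export
blurredPhantom <- function(truth, spec) {
  v <- voxelValues(truth)
  sp <- spec@spacing
  sig <- c(spec@optics@sigmaZ / sp[1], spec@optics@sigmaR / sp[2],
           spec@optics@sigmaR / sp[3])
  v <- .gaussBlur3d(v, sig)
  v <- v / max(v) * spec@basePhotons
  VoxelGrid3D(v, sp, c(provenance(truth),
                       sprintf("PSF blur sigma (r, z) = (%.0f, %.0f) nm, peak %.0f photons",
                               spec@optics@sigmaR, spec@optics@sigmaZ,
                               spec@basePhotons)))
}

## Field dimensions that contain the blurred shell plus a 3*sigmaZ margin.
.fieldFor <- function(semiAxes, thickness, optics, spacing) {
  need <- rev(semiAxes) + thickness / 2 + 3 * optics@sigmaZ   # (z, y, x)
  as.integer(ceiling(2 * need / spacing) + 2L)
}

## Random unit vector.
.runitvec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic cell population with known ground truth
#'
#' Two morphological classes mirror the biological contrast the features
#' are designed to capture. \code{"control"} cells are near-ellipsoidal
#' shells with one mild intensity hotspot (amplitude 1.2-1.6) and at most
#' one shallow dent (depth <= 200 nm). \code{"apoptotic"} cells carry 2-4
#' deep invaginations (depth 450-750 nm, width 500-800 nm) and two strong
#' hotspots (amplitude 2.2-3.2). Per-cell semi-axes are jittered by +/-8%
#' around (1500, 1350, 1200) nm and peak photon counts drawn from
#' [800, 1500]. All per-cell randomness derives deterministically from the
#' master seed (cell i uses seed + 7919 * i), so equal seeds give identical
#' populations.
#'
#' @param n number of cells (0 allowed).
#' @param classLabel "control" or "apoptotic".
#' @param seed master RNG seed.
#' @param baseSpec template [PhantomSpec-class] supplying optics, spacing,
#'   thickness and base semi-axes.
#' @return A list of \code{n} elements, each with \code{spec},
#'   \code{stack} (noisy acquisition) and \code{truth} (noise-free render).
#' @export
generatePopulation <- function(n, classLabel = c("control", "apoptotic"),
                               seed = 1L,
                               baseSpec = phantomSpec()) {
  classLabel <- match.arg(classLabel)
  if (n < 0) stop("n must be >= 0")
  if (n == 0) return(list())
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cellSeed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    set.seed(cellSeed)
    axes <- baseSpec@semiAxes * stats::runif(3, 0.92, 1.08)
    photons <- stats::runif(1, 800, 1500)
    if (classLabel == "control") {
      hot <- list(list(direction = .runitvec(),
                       amplitude = stats::runif(1, 1.2, 1.6),
                       extent = stats::runif(1, 0.4, 0.6)))
      inv <- if (stats::runif(1) < 0.3)
        list(list(direction = .runitvec(),
                  depth = stats::runif(1, 100, 200),
                  width = stats::runif(1, 400, 600)))
      else list()
    } else {
      hot <- lapply(1:2, function(j)
        list(direction = .runitvec(),
             amplitude = stats::runif(1, 2.2, 3.2),
             extent = stats::runif(1, 0.3, 0.5)))
      inv <- lapply(seq_len(sample(2:4, 1)), function(j)
        list(direction = .runitvec(),
             depth = stats::runif(1, 450, 750),
             width = stats::runif(1, 500, 800)))
    }
    spec <- phantomSpec(semiAxes = axes,
                        shellThickness = baseSpec@shellThickness,
                        invaginations = inv, hotspots = hot,
                        basePhotons = photons, optics = baseSpec@optics,
                        spacing = baseSpec@spacing,
                        fieldShape = .fieldFor(axes, baseSpec@shellThickness,
                                               baseSpec@optics,
                                               baseSpec@spacing),
                        seed = cellSeed)
    truth <- renderShell(spec)
    out[[i]] <- list(spec = spec, truth = truth,
                     stack = imagePhantom(truth, spec))
  }
  out
}
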