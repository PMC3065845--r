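# Shared fixtures, built in code at test time.

# Dice coefficient between two logical arrays.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Analytic spherical-shell volume (Gaussian cross profile, radius R voxels,
# profile width sigma voxels) with a thin ideal mask at the mid-surface.
# Isophotes are exact spheres, so mean K over the mask must be ~1/R^2.
sphereShellFixture <- function(R, sigma = 2, margin = 14, spacing = 60) {
  n <- 2 * (R + margin) + 1
  cc <- (n + 1) / 2
  x <- seq_len(n) - cc
  X <- array(rep(x, each = n * n), c(n, n, n))
  Y <- array(rep(x, each = n), c(n, n, n))
  Z <- array(x, c(n, n, n))
  r <- sqrt(X^2 + Y^2 + Z^2)
  list(vol = VoxelGrid3D(exp(-(r - R)^2 / (2 * sigma^2)), rep(spacing, 3)),
       mask = LaminaMask(abs(r - R) <= 0.5, spacing),
       r = r)
}

# The standard test phantom: a mildly eccentric shell with one invagination
# and one hotspot, at a chosen lateral pitch. Geometry is fixed; only the
# acquisition grid adapts to the pitch.
stdPhantom <- function(lateralNm = 60, seed = 7L) {
  axes <- c(1500, 1350, 1200)
  sp <- c(162.8, lateralNm, lateralNm)
  phantomSpec(
    semiAxes = axes, shellThickness = 80,
    invaginations = list(list(direction = c(1, 0.2, 0.1), depth = 550,
                              width = 600)),
    hotspots = list(list(direction = c(-0.3, 1, 0.2), amplitude = 2.5,
                         extent = 0.45)),
    basePhotons = 1200, spacing = sp,
    fieldShape = lamina3d:::.fieldFor(axes, 80, opticsConfig(), sp),
    seed = seed)
}

# A small, fast phantom for unit tests (sub-2 s through the full chain).
smallPhantom <- function(seed = 3L, invaginations = list(),
                         hotspots = list(), basePhotons = 1500) {
  axes <- c(1000, 950, 900)
  sp <- c(162.8, 60, 60)
  phantomSpec(semiAxes = axes, shellThickness = 80,
              invaginations = invaginations, hotspots = hotspots,
              basePhotons = basePhotons, spacing = sp,
              fieldShape = lamina3d:::.fieldFor(axes, 80, opticsConfig(), sp),
              seed = seed)
}

# Hollow voxelized spherical shell mask (no intensity volume).
shellMask <- function(R, thick = 1, n = 2 * R + 9, spacing = 60) {
  cc <- (n + 1) / 2
  x <- seq_len(n) - cc
  X <- array(rep(x, each = n * n), c(n, n, n))
  Y <- array(rep(x, each = n), c(n, n, n))
  Z <- array(x, c(n, n, n))
  r <- sqrt(X^2 + Y^2 + Z^2)
  LaminaMask(abs(r - R) <= thick / 2, spacing)
}
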