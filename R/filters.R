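## Internal separable filtering / resampling / morphology primitives.
## All operate on plain 3D arrays in (z, y, x) order, sigma in voxels.
## Boundary rule for all filters: symmetric reflection (mirror), because
## lamina signal can approach stack faces.

.KERNEL_TRUNCATE <- 4

## Sampled, unit-sum Gaussian smoothing kernel.
.gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(.KERNEL_TRUNCATE * sigma)))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## Sampled Gaussian derivative kernel (correlation convention), normalized
## so the response to 1, x, x^2/2 is exactly 0/1/0 (order 1) or 0/0/1
## (order 2): curvature of quadratic surfaces is then estimated exactly.
.gaussDerivKernel <- function(sigma, order) {
  stopifnot(sigma > 0, order %in% 0:2)
  r <- max(order + 1L, as.integer(ceiling(.KERNEL_TRUNCATE * sigma)))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- x / sigma^2 * g          # correlation: response slope sum(x * k)
    k <- k - mean(k)
    return(k / sum(x * k))
  }
  k <- (x^2 / sigma^4 - 1 / sigma^2) * g
  k <- k - mean(k)
  k / sum(x^2 / 2 * k)
}

## Indices implementing symmetric reflection for positions 1-r .. n+r.
.reflectIndex <- function(n, r) {
  i <- seq.int(1L - r, n + r)
  m <- (i - 1L) %% (2L * n)
  m <- ifelse(m >= n, 2L * n - 1L - m, m)
  m + 1L
}

## Correlate a 3D array with a 1D kernel along one axis (1 = z, 2 = y, 3 = x).
.filterAxis <- function(a, k, axis) {
  nk <- length(k)
  if (nk == 1L) return(a * k)
  r <- (nk - 1L) %/% 2L
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  n <- dp[1]
  m <- prod(dp[-1])
  dim(ap) <- c(n, m)
  padded <- ap[.reflectIndex(n, r), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_len(nk))
    out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
  dim(out) <- dp
  aperm(out, order(perm))
}

## Separable Gaussian blur, sigmas in voxels per axis (z, y, x); 0 = skip.
.gaussBlur3d <- function(a, sigmas) {
  for (ax in 1:3)
    if (sigmas[ax] > 0) a <- .filterAxis(a, .gaussKernel(sigmas[ax]), ax)
  a
}

## Gaussian derivative of the volume: orders (z, y, x) in {0, 1, 2},
## a single scale sigma (voxels). Voxel units.
.gaussDeriv3d <- function(a, sigma, orders) {
  for (ax in 1:3)
    a <- .filterAxis(a, .gaussDerivKernel(sigma, orders[ax]), ax)
  a
}

## Linear interpolation of a 3D array along one axis at fractional 1-based
## input positions. Exact on signals linear along that axis.
.interpAxis <- function(a, axis, positions) {
  d <- dim(a)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  dim(ap) <- c(n, prod(dp[-1]))
  lo <- pmin(pmax(floor(positions), 1), n)
  hi <- pmin(lo + 1, n)
  f <- positions - lo
  out <- ap[lo, , drop = FALSE] * (1 - f) + ap[hi, , drop = FALSE] * f
  dim(out) <- c(length(positions), dp[-1])
  aperm(out, order(perm))
}

## Morphological dilation/erosion of a logical array by a set of integer
## offsets ((z, y, x) rows). Outside the array counts as background for
## dilation and foreground for erosion, so a closing is extensive and does
## not erode at stack faces.
.morph3d <- function(m, offsets, op = c("dilate", "erode")) {
  op <- match.arg(op)
  d <- dim(m)
  r <- max(abs(offsets))
  if (r == 0L) return(m)
  padval <- op == "erode"
  dp <- d + 2L * r
  pad <- array(padval, dp)
  pad[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] <- m
  acc <- NULL
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    slab <- pad[(r + 1 + o[1]):(r + d[1] + o[1]),
                (r + 1 + o[2]):(r + d[2] + o[2]),
                (r + 1 + o[3]):(r + d[3] + o[3])]
    acc <- if (is.null(acc)) slab
           else if (op == "dilate") acc | slab else acc & slab
  }
  acc
}

## Neighbourhood offsets for connectivity 6 or 26, as linear-index offsets
## of an array padded by one voxel on every face.
.neighbourOffsets <- function(dimPadded, connectivity) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g[, 1] + g[, 2] * dimPadded[1] + g[, 3] * dimPadded[1] * dimPadded[2]
}

## Connected-component labelling of a logical 3D array by vectorized
## frontier BFS. Returns component sizes (decreasing) and the label array.
.labelComponents <- function(m, connectivity = 26) {
  d <- dim(m)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  offs <- .neighbourOffsets(dp, connectivity)
  labels <- array(0L, dp)
  todo <- which(pad)
  sizes <- integer(0)
  lab <- 0L
  seen <- array(FALSE, dp)
  for (seed in todo) {
    if (seen[seed]) next
    lab <- lab + 1L
    seen[seed] <- TRUE
    labels[seed] <- lab
    frontier <- seed
    size <- 1L
    while (length(frontier)) {
      cand <- as.vector(outer(frontier, offs, `+`))
      cand <- cand[pad[cand] & !seen[cand]]
      cand <- unique(cand)
      seen[cand] <- TRUE
      labels[cand] <- lab
      size <- size + length(cand)
      frontier <- cand
    }
    sizes[lab] <- size
  }
  inner <- labels[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  dim(inner) <- d
  ord <- order(sizes, decreasing = TRUE)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  inner[inner > 0] <- relabel[inner[inner > 0]]
  list(sizes = sort(sizes, decreasing = TRUE), labels = inner)
}

## Coordinate arrays (physical nm, relative to the field centre) for a grid
## of dimensions d ((z, y, x)) and spacing (dz, dy, dx).
.coordArrays <- function(d, spacing) {
  centre <- (d - 1) * spacing / 2
  zc <- (seq_len(d[1]) - 1) * spacing[1] - centre[1]
  yc <- (seq_len(d[2]) - 1) * spacing[2] - centre[2]
  xc <- (seq_len(d[3]) - 1) * spacing[3] - centre[3]
  list(Z = array(zc, d),
       Y = array(rep(yc, each = d[1]), d),
       X = array(rep(xc, each = d[1] * d[2]), d))
}

## Round half away from zero (reporting convention for nm quantities).
.roundHalfAway <- function(x) trunc(x + sign(x) * 0.5)
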