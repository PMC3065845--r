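test_that("anisotropic smoothing is separable and normalized", {
  set.seed(6)
  a <- array(runif(20 * 20 * 20), c(20, 20, 20))
  g <- VoxelGrid3D(a, rep(60, 3))
  expect_identical(voxelValues(smoothAnisotropic(g, 0, 0)), a)

  cst <- VoxelGrid3D(array(3.7, c(10, 10, 10)), rep(60, 3))
  expect_equal(voxelValues(smoothAnisotropic(cst, 60, 300)),
               array(3.7, c(10, 10, 10)), tolerance = 1e-12)

  # lateral-first equals axial-first (separability)
  v <- voxelValues(g)
  lat <- lamina3d:::.gaussBlur3d(v, c(0, 1, 1))
  both1 <- lamina3d:::.gaussBlur3d(lat, c(5, 0, 0))
  axi <- lamina3d:::.gaussBlur3d(v, c(5, 0, 0))
  both2 <- lamina3d:::.gaussBlur3d(axi, c(0, 1, 1))
  expect_lt(sqrt(mean((both1 - both2)^2)), 1e-10)
})

test_that("threshold constants follow the max(i_blur) rule", {
  ib <- VoxelGrid3D(array(seq(0, 30, length.out = 27), c(3, 3, 3)),
                    rep(60, 3))
  th <- deriveThresholdParams(ib, alpha = 0.9, icFraction = 1/3)
  expect_equal(unname(th["Ic"]), 10)
  expect_equal(unname(th["beta"]), 1)
  # alpha = 0 reduces Eq to a global threshold at Ic
  th0 <- deriveThresholdParams(ib, alpha = 0, icFraction = 1/3)
  expect_equal(unname(th0["beta"]), unname(th0["Ic"]))
  # round-trip: beta/(1 - alpha) recovers Ic exactly
  expect_equal(unname(th["beta"]) / (1 - unname(th["alpha"])),
               unname(th["Ic"]))
  expect_error(deriveThresholdParams(
    VoxelGrid3D(array(0, c(2, 2, 2)), rep(60, 3))), "degenerate")
})

test_that("unsharp masking follows the subtraction algebra", {
  set.seed(7)
  a <- array(runif(5 * 5 * 5), c(5, 5, 5))
  g <- VoxelGrid3D(a, rep(60, 3))
  b <- VoxelGrid3D(array(runif(125), c(5, 5, 5)), rep(60, 3))
  expect_identical(voxelValues(unsharpMask(g, b, 0, 0)), a)

  cVal <- 6
  cst <- VoxelGrid3D(array(cVal, c(4, 4, 4)), rep(60, 3))
  um <- unsharpMask(cst, cst, 0.9, cVal / 30)
  expect_equal(voxelValues(um), array(cVal / 15, c(4, 4, 4)),
               tolerance = 1e-12)

  # 1D two-level profile: the sign change sits between the two levels
  prof <- array(rep(c(rep(10, 10), rep(100, 10)), each = 1), c(20, 3, 3))
  gp <- VoxelGrid3D(prof, rep(60, 3))
  bp <- smoothAnisotropic(gp, 0, 300)
  th <- deriveThresholdParams(bp)
  ump <- unsharpMask(gp, bp, th["alpha"], th["beta"])
  line <- voxelValues(ump)[, 2, 2]
  expect_true(all(line[1:8] < 0))     # low plateau is background
  expect_true(all(line[13:20] > 0))   # high plateau is foreground
  expect_error(unsharpMask(g, VoxelGrid3D(array(0, c(4, 4, 4)), rep(60, 3)),
                           0.9, 1), "mismatch")
})

test_that("zero thresholding assigns ties to the lamina", {
  u <- VoxelGrid3D(array(c(-1, 0, 2, -3, 4, 0, -2, 1), c(2, 2, 2)),
                   rep(60, 3))
  m <- thresholdMask(u)
  expect_identical(as.vector(voxelValues(m)),
                   c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  neg <- thresholdMask(VoxelGrid3D(array(-abs(rnorm(8)) - 1, c(2, 2, 2)),
                                   rep(60, 3)))
  expect_equal(voxelCount(neg), 0)
  # complement symmetry away from exact zeros
  v <- array(rnorm(27), c(3, 3, 3))
  m1 <- voxelValues(thresholdMask(VoxelGrid3D(v, rep(60, 3))))
  m2 <- voxelValues(thresholdMask(VoxelGrid3D(-v, rep(60, 3))))
  nz <- v != 0
  expect_true(all(m1[nz] != m2[nz]))
})

test_that("digital sphere contains the documented voxel counts", {
  expect_identical(nrow(digitalSphere(2.7)), 81L)
  expect_identical(nrow(digitalSphere(0)), 1L)
  expect_identical(nrow(digitalSphere(1)), 7L)
  se <- digitalSphere(2.7)
  # symmetric under negation and contains the origin
  expect_true(any(rowSums(abs(se)) == 0))
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(key(se), key(-se))
})

test_that("closing is extensive, idempotent, and fills punctures", {
  em <- LaminaMask(array(FALSE, c(8, 8, 8)), 60)
  expect_equal(voxelCount(closeMask(em)), 0)

  set.seed(8)
  se <- digitalSphere(1.8)
  for (i in 1:3) {
    m <- LaminaMask(array(runif(14^3) > 0.7, c(14, 14, 14)), 60)
    cl <- closeMask(m, se)
    expect_true(all(voxelValues(m) <= voxelValues(cl)))       # extensive
    cl2 <- closeMask(cl, se)
    expect_identical(voxelValues(cl2), voxelValues(cl))       # idempotent
  }

  # spherical shell with a 2-voxel puncture: closing repairs the hole and
  # keeps the interior cavity (background component count stays 2)
  sh <- shellMask(9, thick = 2.2, n = 27)
  v <- voxelValues(sh)
  v[14, 14, 22:24] <- FALSE                   # puncture through the shell
  punct <- LaminaMask(v, 60)
  expect_equal(length(lamina3d:::.labelComponents(!v, 6)$sizes), 1L)
  healed <- closeMask(punct, digitalSphere(2.7))
  bg <- lamina3d:::.labelComponents(!voxelValues(healed), 6)
  expect_equal(length(bg$sizes), 2L)
})

test_that("end-to-end segmentation finds the phantom shell deterministically", {
  sp <- smallPhantom(seed = 21L)
  img <- imagePhantom(renderShell(sp), sp)
  m1 <- segmentLamina(img)
  m2 <- segmentLamina(img)
  expect_identical(voxelValues(m1), voxelValues(m2))
  truth <- phantomTruthMask(sp)
  expect_gte(dice(voxelValues(m1), voxelValues(truth)), 0.8)
  # the dark interior is excluded from the mask
  co <- lamina3d:::.coordArrays(dim(voxelValues(m1)), rep(60, 3))
  r <- sqrt((co$X / sp@semiAxes[1])^2 + (co$Y / sp@semiAxes[2])^2 +
            (co$Z / sp@semiAxes[3])^2)
  expect_equal(sum(voxelValues(m1)[r < 0.5]), 0)
})

test_that("the mask is invariant under intensity rescaling", {
  sp <- smallPhantom(seed = 22L)
  img <- imagePhantom(renderShell(sp), sp)
  m1 <- segmentLamina(img)
  img5 <- VoxelGrid3D(voxelValues(img) * 5, spacingNm(img))
  m5 <- segmentLamina(img5)
  expect_identical(voxelValues(m1), voxelValues(m5))
})

test_that("QC distinguishes closed shells, empty masks, and open half-shells", {
  closed <- shellMask(8, thick = 2.2, n = 25)
  qc <- qcMask(closed)
  expect_true(qc$usable)
  expect_true(qc$has_enclosed_cavity)

  expect_false(qcMask(LaminaMask(array(FALSE, c(6, 6, 6)), 60))$usable)

  # two disjoint half-shells: no enclosed cavity, two components
  v <- voxelValues(shellMask(8, thick = 2.2, n = 25))
  gap <- 11:15                       # equatorial band removed
  v[gap, , ] <- FALSE
  half <- qcMask(LaminaMask(v, 60))
  expect_false(half$usable)
  expect_false(half$has_enclosed_cavity)
  expect_gte(half$n_foreground_components, 2L)
})
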