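test_that("outlier clipping uses population statistics of the raw values", {
  x <- c(0, 0, 0, 0, 100)                    # mu = 20, sigma = 40
  cl <- clipOutliers(x, 4)
  expect_equal(attr(cl, "mu"), 20)
  expect_equal(attr(cl, "sigma"), 40)
  expect_equal(as.numeric(cl), x)            # 100 < 20 + 160: nothing clips

  y <- c(rep(10, 50), 10 + 4 * 100)          # compute bound from raw stats
  muY <- mean(y); sdY <- sqrt(mean((y - muY)^2))
  clY <- clipOutliers(c(y, 1e6), 4)
  expect_equal(as.numeric(clY[length(clY)]),
               mean(c(y, 1e6)) + 4 * sqrt(mean((c(y, 1e6) -
                                                mean(c(y, 1e6)))^2)))
  expect_error(clipOutliers(5), "at least 2")
})

test_that("intensity normalization is affine-invariant and spans [0, 1]", {
  expect_equal(normalizeIntensity(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(normalizeIntensity(c(3, 7)), c(0, 1))
  set.seed(9)
  v <- runif(100)
  expect_equal(normalizeIntensity(v), normalizeIntensity(2.5 * v + 7),
               tolerance = 1e-12)
  expect_error(normalizeIntensity(rep(2, 5)), "degenerate")
})

test_that("average normalized intensity is the plain mask mean", {
  expect_equal(averageNormalizedIntensity(c(0, 1)), 0.5)
  expect_equal(averageNormalizedIntensity(rep(0.37, 10)), 0.37)
  set.seed(10)
  u <- runif(1e5)
  expect_lt(abs(averageNormalizedIntensity(u) - 0.5), 0.005)
  expect_error(averageNormalizedIntensity(numeric(0)), "empty")
})

test_that("skewness matches brute-force evaluation and its symmetries", {
  # brute force on the 3-element set {0, 0, 1}
  x <- c(0, 0, 1)
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  expect_equal(intensitySkewness(x), mean(((x - m) / s)^3), tolerance = 1e-12)
  # symmetric distributions have zero skewness
  expect_lt(abs(intensitySkewness(c(0.1, 0.3, 0.5, 0.7, 0.9))), 1e-12)
  # reflecting about 0.5 flips the sign
  set.seed(11)
  v <- rbeta(1000, 2, 5)
  expect_equal(intensitySkewness(1 - v), -intensitySkewness(v),
               tolerance = 1e-9)
  expect_error(intensitySkewness(rep(0.2, 4)), "zero")
})

test_that("streaming skewness equals brute force on random masked data", {
  set.seed(12)
  for (n in c(10, 1000, 10000)) {
    v <- runif(n)^2
    m <- mean(v); s <- sqrt(mean((v - m)^2))
    brute <- mean(((v - m) / s)^3)
    expect_equal(intensitySkewness(v), brute, tolerance = 1e-10)
  }
})

test_that("curvature recovers sphere, plane, and monkey-saddle geometry", {
  # blurred spherical shell: mean K over the mid-surface mask ~ 1/R^2
  R <- 20
  s <- sphereShellFixture(R, spacing = 60)
  cf <- curvatureField(s$vol, s$mask)
  expect_lt(abs(mean(cf@K) * (R * 60)^2 - 1) , 0.1)
  expect_true(all(cf@kappa1 >= cf@kappa2))
  expect_equal(cf@K, cf@kappa1 * cf@kappa2, tolerance = 1e-12)

  # flat slab: |K| vanishes on the interior face
  n <- 33
  z <- array(rep(seq_len(n), n * n) , c(n, n, n))  # ramp along z
  vol <- VoxelGrid3D(z / n, rep(1, 3))
  slab <- array(FALSE, c(n, n, n))
  slab[16:17, 9:25, 9:25] <- TRUE
  cfS <- curvatureField(vol, LaminaMask(slab, 1))
  expect_lt(max(abs(cfS@K)), 1e-4)

  # monkey saddle z = (x^3 - 3xy^2)/s: K < 0 near (not at) the flat point
  n <- 41; cc <- 21
  x <- (seq_len(n) - cc)
  X <- array(rep(x, each = n * n), c(n, n, n))
  Y <- array(rep(x, each = n), c(n, n, n))
  Z <- array(x, c(n, n, n))
  h <- (X^3 - 3 * X * Y^2) / 150
  f <- Z - h
  volM <- VoxelGrid3D(f, rep(1, 3))
  rho <- sqrt(X^2 + Y^2)
  maskM <- abs(f) <= 0.5 & rho >= 3 & rho <= 6
  cfM <- curvatureField(volM, LaminaMask(maskM, 1),
                        measurementParams(sigmaG = 2, sigmaW = 3))
  expect_lt(mean(cfM@K), 0)
  expect_gt(mean(cfM@K < 0), 0.95)
})

test_that("convex hull area matches closed forms for cuboid and sphere", {
  # filled cuboid: hull of voxel centres is the (a-1)(b-1)(c-1) box
  v <- array(FALSE, c(14, 12, 10))
  v[3:12, 3:10, 3:8] <- TRUE                 # 10 x 8 x 6 voxels
  A <- convexHullArea(LaminaMask(v, 60))
  expected <- 2 * (9 * 7 + 7 * 5 + 9 * 5) * 60^2
  expect_lt(abs(A - expected) / expected, 0.02)

  # hull ignores internal structure: a shell and the ball with the same
  # outer radius have the same hull
  sh <- shellMask(8, thick = 2.2, n = 25)                  # r in [6.9, 9.1]
  ball <- shellMask(4.55, thick = 9.1, n = 25)             # r in [0, 9.1]
  expect_lt(abs(convexHullArea(sh) - convexHullArea(ball)) /
              convexHullArea(ball), 0.005)

  # solid sphere of voxel centres: 4 pi R^2 within 3% at R >= 15 (the
  # half-voxel centre-vs-boundary offset is part of the convention)
  for (R in c(18, 25)) {
    m <- shellMask(R / 2, thick = R, n = 2 * R + 7)        # ball r <= R
    expect_lt(abs(convexHullArea(m) - 4 * pi * (R * 60)^2) /
                (4 * pi * (R * 60)^2), 0.03)
  }
  expect_error(convexHullArea(LaminaMask(array(c(TRUE, TRUE, rep(FALSE, 6)),
                                               c(2, 2, 2)), 60)), "small|degenerate")
})

test_that("K_naaGc equals 4 pi for spheres and reacts to invaginations", {
  s <- sphereShellFixture(18, spacing = 60)
  cf <- curvatureField(s$vol, s$mask)
  kn <- normalizedCurvature(cf, convexHullArea(s$mask))
  expect_lt(abs(kn - 4 * pi) / (4 * pi), 0.1)
  # all-zero K gives 0
  cf0 <- cf; cf0@K <- rep(0, length(cf@K))
  expect_equal(normalizedCurvature(cf0, 1e6), 0)
})

test_that("measured features respond to shape and intensity structure", {
  smooth <- smallPhantom(seed = 31L)
  dent <- smallPhantom(seed = 31L,
                       invaginations = list(list(direction = c(0, 0, 1),
                                                 depth = 450, width = 500)))
  fSmooth <- measureCell(imagePhantom(renderShell(smooth), smooth))
  fDent <- measureCell(imagePhantom(renderShell(dent), dent))
  expect_gt(fDent$K_naaGc, fSmooth$K_naaGc)

  hot <- smallPhantom(seed = 31L,
                      hotspots = list(list(direction = c(0, 1, 0),
                                           amplitude = 3, extent = 0.4)))
  fHot <- measureCell(imagePhantom(renderShell(hot), hot))
  expect_gt(abs(fHot$i_skewness), abs(fSmooth$i_skewness))

  # determinism of the full chain
  img <- imagePhantom(renderShell(smooth), smooth)
  expect_identical(measureCell(img), measureCell(img))
})

test_that("spatial maps localize hotspots and flag empty projections", {
  sp <- smallPhantom(seed = 32L,
                     hotspots = list(list(direction = c(1, 0, 0),
                                          amplitude = 4, extent = 0.35)))
  img <- imagePhantom(renderShell(sp), sp)
  mask <- segmentLamina(img)
  iso <- attr(mask, "iso")
  field <- curvatureField(iso, mask)
  maps <- spatialMaps(iso, mask, field, axis = 1)   # project along z
  expect_identical(dim(maps$intensity), dim(voxelValues(mask))[2:3])
  # hotspot at +x: the intensity map maximum sits in the +x half
  mx <- which(maps$intensity == max(maps$intensity, na.rm = TRUE),
              arr.ind = TRUE)
  expect_gt(mx[1, 2], dim(maps$intensity)[2] / 2)
  expect_error(spatialMaps(iso, LaminaMask(array(FALSE, dim(voxelValues(mask))),
                                           spacingNm(mask)), field), "empty")

  # near-uniform shell intensity: the projected map is roughly constant
  s <- sphereShellFixture(12, spacing = 60)
  n <- dim(voxelValues(s$vol))[1]
  ramp <- array(rep(seq_len(n) / n, n * n), c(n, n, n))    # breaks constancy
  volU <- VoxelGrid3D(array(1 + 0.01 * ramp, c(n, n, n)), rep(60, 3))
  cfS <- curvatureField(s$vol, s$mask)
  mapsS <- spatialMaps(volU, s$mask, cfS, axis = 1)
  vals <- mapsS$intensity[!is.na(mapsS$intensity)]
  expect_lt(stats::sd(vals) / mean(vals), 0.2)
})

test_that("intensity-curvature correlation behaves at the extremes", {
  set.seed(13)
  u <- runif(5000)
  r <- intensityCurvatureCorrelation(u, 3 * u)
  expect_equal(r$rho, 1, tolerance = 1e-12)
  expect_equal(sum(r$histogram), 5000)

  a <- runif(1e5); b <- runif(1e5)
  expect_lt(abs(intensityCurvatureCorrelation(a, b)$rho), 0.01)
  expect_error(intensityCurvatureCorrelation(u, rep(1, 5000)), "variance")
})
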