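test_that("regularized Heaviside/Dirac pair has the right symmetries and derivative", {
  expect_equal(heavisideEps(0, 1.5), 0.5)
  expect_equal(heavisideEps(3.7, 1) + heavisideEps(-3.7, 1), 1)
  h <- 1e-4
  fd <- (heavisideEps(0.5 + h, 1.5) - heavisideEps(0.5 - h, 1.5)) / (2 * h)
  expect_equal(diracEps(0.5, 1.5), fd, tolerance = 1e-6)
  # the arctan Dirac has heavy tails: its mass over +/- 1000 eps is within
  # 1e-3 of 1 (over +/- 100 eps about 6e-3 is still outside)
  for (eps in c(0.5, 1.5)) {
    grid <- seq(-1000 * eps, 1000 * eps, length.out = 400001)
    mass <- sum(diracEps(grid, eps)) * (grid[2] - grid[1])
    expect_lt(abs(mass - 1), 1e-3)
  }
})

test_that("region means equal the per-pixel weighted-mean oracle", {
  img <- matrix(0, 32, 32); img[, 1:16] <- 200; img[, 17:32] <- 50
  phi <- matrix(-30, 32, 32); phi[, 1:16] <- 30  # sharp: |phi| >> eps
  cm <- regionMeans(img, phi, eps = 1.5)
  expect_equal(cm[["c_i"]], 200, tolerance = 0.5)
  expect_equal(cm[["c_o"]], 50, tolerance = 0.5)

  const <- matrix(90, 16, 16)
  cmc <- regionMeans(const, matrix(rnorm(256), 16, 16), eps = 1.5)
  expect_equal(unname(cmc), c(90, 90))

  for (s in 1:100) {
    set.seed(s)
    ri <- matrix(runif(256, 0, 255), 16, 16)
    rp <- matrix(rnorm(256, 0, 5), 16, 16)
    expect_equal(unname(regionMeans(ri, rp, 1.5)),
                 bruteRegionMeans(ri, rp, 1.5), tolerance = 1e-10)
  }
})

test_that("a matched two-constant image leaves the zero level set stationary", {
  img <- matrix(50, 32, 32)
  img[diskMask(c(32, 32), c(15.5, 15.5), 9) == 1] <- 200
  phi <- levelsetFromCircle(c(row = 15.5, col = 15.5, radius = 9), c(32, 32))
  cfg <- cvConfig(mu = 0, nu = 0)
  out <- phi
  for (i in 1:10) out <- cvStep(img, out, cfg)
  # the field steepens but no pixel changes side
  expect_identical(out > 0, phi > 0)
})

test_that("a pure area penalty shrinks the smoothed interior area", {
  set.seed(2)
  phi <- levelsetFromCircle(c(row = 12, col = 12, radius = 7), c(24, 24))
  img <- matrix(runif(576, 0, 255), 24, 24)
  cfg <- cvConfig(mu = 0, nu = 0.5, lambdaIn = 0, lambdaOut = 0)
  out <- cvStep(img, phi, cfg)
  expect_lt(sum(heavisideEps(out, cfg@eps)), sum(heavisideEps(phi, cfg@eps)))
})

test_that("the Chan-Vese update matches a termwise straight-line oracle", {
  set.seed(8)
  img <- matrix(runif(64, 0, 10), 8, 8)  # small scale keeps updates uncapped
  phi <- matrix(rnorm(64, 0, 2), 8, 8)
  cfg <- cvConfig(mu = 1, nu = 1, lambdaIn = 1, lambdaOut = 1, dt = 1,
                  eps = 1)
  got <- cvStep(img, phi, cfg)

  # independent evaluation: explicit loops, textbook formulas
  H <- matrix(0, 8, 8); D <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    H[i, j] <- 0.5 * (1 + (2 / pi) * atan(phi[i, j] / 1))
    D[i, j] <- (1 / pi) * 1 / (1 + phi[i, j]^2)
  }
  ci <- sum(img * H) / sum(H)
  co <- sum(img * (1 - H)) / sum(1 - H)
  at <- function(m, i, j) m[min(max(i, 1), 8), min(max(j, 1), 8)]
  gx <- gy <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    gx[i, j] <- (at(phi, i, j + 1) - at(phi, i, j - 1)) / 2
    gy[i, j] <- (at(phi, i + 1, j) - at(phi, i - 1, j)) / 2
  }
  nx <- ny <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    mag <- max(sqrt(gx[i, j]^2 + gy[i, j]^2), 1e-8)
    nx[i, j] <- gx[i, j] / mag; ny[i, j] <- gy[i, j] / mag
  }
  want <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    kap <- (at(nx, i, j + 1) - at(nx, i, j - 1)) / 2 +
           (at(ny, i + 1, j) - at(ny, i - 1, j)) / 2
    f <- kap - 1 - (img[i, j] - ci)^2 + (img[i, j] - co)^2
    want[i, j] <- phi[i, j] + min(max(D[i, j] * f, -1), 1)
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the entropy-weighted step reduces to the plain step at unit weights", {
  set.seed(12)
  img <- matrix(runif(256, 0, 255), 16, 16)
  phi <- levelsetFromCircle(c(row = 8, col = 8, radius = 5), c(16, 16))
  cfg <- cvConfig(mu = 0, nu = 0, lambdaIn = 1, lambdaOut = 1)
  expect_identical(ecvStep(img, phi, cfg, weights = c(1, 1)),
                   cvStep(img, phi, cfg))
  # zero interior weight: the update is driven by the exterior term only
  cm <- regionMeans(img, phi, cfg@eps)
  onlyOut <- phi + pmin(pmax(
    cfg@dt * diracEps(phi, cfg@eps) * (img - cm[["c_o"]])^2, -1), 1)
  expect_equal(ecvStep(img, phi, cfg, weights = c(0, 1)), onlyOut)
})

test_that("global Chan-Vese converges on a noise-free two-constant image", {
  shape <- c(96, 96)
  truth <- diskMask(shape, c(48, 48), 26)
  img <- matrix(40, 96, 96); img[truth == 1] <- 210
  phi0 <- levelsetFromCircle(c(row = 44, col = 50, radius = 15), shape)
  r <- runCV(img, phi0, cvConfig(maxIters = 300), model = "cv")
  expect_gte(diceCoefficient((r$phi > 0) * 1, truth), 0.99)
})
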