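test_that("the narrow band is exactly the |phi| < width set", {
  phi <- levelsetFromCircle(c(row = 30, col = 30, radius = 10), c(64, 64))
  band <- curveBand(phi, 1.5)
  d <- sqrt((band[, 1] - 30)^2 + (band[, 2] - 30)^2)
  expect_true(all(abs(d - 10) < 1.5))

  wide <- curveBand(phi, 1000)
  expect_equal(nrow(wide), 64 * 64)

  set.seed(31)
  rphi <- matrix(rnorm(400, 0, 3), 20, 20)
  got <- curveBand(rphi, 2.5)
  want <- NULL
  for (i in 1:20) for (j in 1:20)
    if (abs(rphi[i, j]) < 2.5) want <- rbind(want, c(i - 1, j - 1))
  expect_equal(unname(got), unname(want))

  expect_error(curveBand(abs(rphi) + 1, 2), "contour collapse")
})

test_that("the adaptive window grows until its entropy clears the threshold", {
  cfg <- evolutionConfig(winInit = 2L, winMax = 9)
  const <- matrix(100, 40, 40)
  expect_equal(adaptiveWindow(const, c(20, 20), cfg)$halfSize, 9)

  # a window already above threshold stays at winInit
  set.seed(41)
  noisy <- matrix(runif(1600, 0, 255), 40, 40)
  expect_equal(adaptiveWindow(noisy, c(20, 20), cfg)$halfSize, 2L)

  # ramp texture: first size whose histogram entropy clears 0.5 nats,
  # found by exhaustive scan
  ramp <- matrix(rep(seq(0, 255, length.out = 40), each = 40), 40, 40)
  got <- adaptiveWindow(ramp, c(20, 20), cfg)$halfSize
  scan <- NA
  for (hs in 2:9) {
    rows <- (20 - hs):(20 + hs) + 1; cols <- rows
    if (bruteEntropy(as.vector(ramp[rows, cols]), 32) >= 0.5) {
      scan <- hs; break
    }
  }
  if (is.na(scan)) scan <- 9
  expect_equal(got, scan)
})

test_that("local means match brute force and reduce to global means", {
  img <- matrix(160, 21, 21); img[, 1:10] <- 40
  phi <- matrix(-5, 21, 21); phi[, 1:10] <- 5
  win <- localWindow(c(10, 9), 4, c(21, 21))
  uv <- localMeans(img, phi, win, eps = 0.1)
  expect_equal(uv[["u_j"]], 40, tolerance = 0.5)
  expect_equal(uv[["v_j"]], 160, tolerance = 0.5)

  # whole-image window equals the global region means exactly
  set.seed(51)
  ri <- matrix(runif(441, 0, 255), 21, 21)
  rp <- matrix(rnorm(441, 0, 4), 21, 21)
  whole <- localWindow(c(10, 10), 40, c(21, 21))
  expect_equal(unname(localMeans(ri, rp, whole, 1.5)),
               unname(regionMeans(ri, rp, 1.5)))

  # random 9x9 windows against a per-pixel sum oracle
  for (s in 1:100) {
    set.seed(100 + s)
    wi <- matrix(runif(81, 0, 255), 9, 9)
    wp <- matrix(rnorm(81, 0, 3), 9, 9)
    win9 <- localWindow(c(4, 4), 4, c(9, 9))
    uv <- localMeans(wi, wp, win9, 1.5)
    nu <- de <- nv <- dv <- 0
    for (i in 1:9) for (j in 1:9) {
      h <- 0.5 * (1 + (2 / pi) * atan(wp[i, j] / 1.5))
      nu <- nu + wi[i, j] * h; de <- de + h
      nv <- nv + wi[i, j] * (1 - h); dv <- dv + (1 - h)
    }
    expect_equal(unname(uv), c(nu / de, nv / dv), tolerance = 1e-10)
  }

  # one-sided window signals NA
  expect_true(all(is.na(localMeans(img, abs(phi), win, 1.5))))
})

test_that("the local force vanishes on matched windows and matches the printed expression", {
  cfg <- evolutionConfig(winInit = 3L, winMax = 3)
  # constant window: u_j = v_j = I everywhere, both residuals vanish at
  # every pixel and both entropy weights floor equally -> exactly zero
  img <- matrix(80, 15, 15)
  phi <- matrix(-8, 15, 15); phi[, 1:7] <- 8
  f <- localForce(img, phi, c(7, 6), cfg)
  expect_lt(abs(f), 1e-12)

  # fixed 7x7 fixture against termwise evaluation
  set.seed(61)
  wi <- matrix(runif(49, 0, 255), 7, 7)
  wp <- matrix(rnorm(49, 0, 2), 7, 7)
  got <- localForce(wi, wp, c(3, 3), cfg)
  H <- 0.5 * (1 + (2 / pi) * atan(wp / cfg@eps))
  u <- sum(wi * H) / sum(H)
  v <- sum(wi * (1 - H)) / sum(1 - H)
  eIn <- max(bruteEntropy(wi[wp > 0], 32), 0.05)
  eOut <- max(bruteEntropy(wi[wp <= 0], 32), 0.05)
  want <- 0
  for (i in 1:7) for (j in 1:7) {
    d <- (1 / pi) * cfg@eps / (cfg@eps^2 + wp[i, j]^2)
    want <- want + d * (eIn * (wi[i, j] - u)^2 - eOut * (wi[i, j] - v)^2)
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("Gaussian regularization preserves constants and interior ramps, and relaxes rough fields", {
  const <- matrix(3, 20, 20)
  expect_equal(gaussianRegularize(const, 1.5), const, tolerance = 1e-12)

  # unit impulse: center picks up the normalized kernel's central weight
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  out <- gaussianRegularize(imp, 2)
  g <- dnorm(-8:8, sd = 2); g <- g / sum(g)
  expect_equal(out[17, 17], g[9]^2)

  # linear ramp: interior pixels unchanged (symmetric kernel)
  ramp <- matrix(rep(0:29, each = 30), 30, 30)
  sm <- gaussianRegularize(ramp, 1)
  K <- 4
  expect_equal(sm[(K + 1):(30 - K), (K + 1):(30 - K)],
               ramp[(K + 1):(30 - K), (K + 1):(30 - K)], tolerance = 1e-9)

  # Dirichlet energy strictly decreases for non-constant fields
  dirichlet <- function(m) {
    sum((m[-1, ] - m[-nrow(m), ])^2) + sum((m[, -1] - m[, -ncol(m)])^2)
  }
  for (s in 1:5) {
    set.seed(70 + s)
    f <- matrix(rnorm(400), 20, 20)
    expect_lt(dirichlet(gaussianRegularize(f, 1)), dirichlet(f))
  }
})

test_that("with a whole-image window and unit weights the local force reduces to the global one", {
  set.seed(81)
  img <- matrix(runif(256, 0, 10), 16, 16)
  phi <- levelsetFromCircle(c(row = 8, col = 8, radius = 5), c(16, 16))
  cfg <- evolutionConfig(nu = 0, winInit = 32L, winMax = 32,
                         fixedWeights = TRUE, bandWidth = 100, eps = 1.5,
                         dt = 0.05)
  Floc <- smlvForce(img, phi, cfg)
  nBand <- nrow(curveBand(phi, 100))
  D <- diracEps(phi, cfg@eps)
  cm <- regionMeans(img, phi, cfg@eps)
  Fglob <- D * (-(img - cm[["c_i"]])^2 + (img - cm[["c_o"]])^2)
  expect_equal(Floc / (nBand * D), Fglob, tolerance = 1e-8)
})

test_that("an evolution step degenerates correctly on constant images", {
  phi <- levelsetFromCircle(c(row = 10, col = 10, radius = 6), c(21, 21))
  const <- matrix(99, 21, 21)
  # nu = 0: zero data force, the step is pure Gaussian smoothing
  cfg0 <- evolutionConfig(nu = 0, winInit = 2L, winMax = 3)
  expect_equal(smlvStep(const, phi, cfg0),
               gaussianRegularize(pmin(pmax(phi, -9), 9), cfg0@xi),
               tolerance = 1e-12)
  # nu > 0 only: smoothed interior area shrinks (pre-regularization)
  cfg1 <- evolutionConfig(nu = 0.5, winInit = 2L, winMax = 3)
  F <- smlvForce(const, phi, cfg1)
  phi2 <- phi + pmin(pmax(cfg1@dt * F, -1), 1)
  expect_lt(sum(heavisideEps(phi2, cfg1@eps)),
            sum(heavisideEps(phi, cfg1@eps)))
})

test_that("runSMLV honors maxIters = 0 and keeps the field bounded", {
  ph <- makeLVPhantom(phantomSpec(shape = c(64L, 64L), rEndo = 8,
                                  rEpi = 14))
  phi0 <- levelsetFromCircle(c(row = 31.5, col = 31.5, radius = 14),
                             c(64, 64))
  r0 <- runSMLV(ph$image, phi0, evolutionConfig(maxIters = 0L))
  expect_identical(r0$phi, phi0)
  expect_equal(r0$iterations, 0L)

  r <- runSMLV(ph$image, phi0, evolutionConfig(maxIters = 30L))
  expect_true(all(is.finite(r$phi)))
  expect_lte(max(abs(r$phi)), 9 + 1e-9)
})

test_that("the local model beats the global model under bias and noise", {
  spec <- phantomSpec(shape = c(96L, 96L), rEndo = 12, rEpi = 20,
                      biasAmplitude = 0.4, noiseSigma = 10, seed = 5L)
  ph <- makeLVPhantom(spec)
  init <- selectLVPair(detectCircles(ph$image))
  cfg <- evolutionConfig()
  evo <- function(circle, run) {
    phi0 <- levelsetFromCircle(circle, c(96, 96))
    run(ph$image, phi0)
  }
  pe <- evo(init@endocardial, function(i, p) runSMLV(i, p, cfg))
  pp <- evo(init@epicardial, function(i, p) runSMLV(i, p, cfg))
  epi <- (pp$phi > 0) * 1
  endo <- (pe$phi > 0) * epi
  dSmlv <- diceCoefficient(epi * (1 - endo), ph$myo_mask)
  # the global model gets a generous budget of its own
  ccfg <- cvConfig(maxIters = 400L)
  ce <- evo(init@endocardial, function(i, p) runCV(i, p, ccfg))
  cp <- evo(init@epicardial, function(i, p) runCV(i, p, ccfg))
  cepi <- (cp$phi > 0) * 1
  cendo <- (ce$phi > 0) * cepi
  dCv <- diceCoefficient(cepi * (1 - cendo), ph$myo_mask)
  expect_gte(dSmlv, 0.95)
  expect_gt(dSmlv, dCv)
})
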