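# Scan-time inversion: crossing quadratic, segment boundaries, object->
# scan mapping and image reconstruction.

test_that("the crossing quadratic degenerates correctly", {
  cfg <- studyCfg()
  v <- Velocity2(900, 350, "C2")
  a0 <- Accel2(0, 0, "C2")
  z <- solveCrossingFrame(0, 0, v, a0, cfg)
  expect_equal(z$yPrime, 0)
  expect_true(z$valid)
  # zero acceleration: closed linear form
  th <- tiltAngle(cfg) * pi / 180
  d <- pixelPitch(cfg); f <- lineRate(cfg)
  s <- solveCrossingFrame(7, 31, v, a0, cfg)
  expect_equal(s$yPrime,
               d * f * sin(th) * (31 * sin(th) + 7 * cos(th)) / 350)
})

test_that("a decelerating object that never reaches the line is invalid", {
  cfg <- studyCfg()
  v <- Velocity2(0, 100, "C2")
  a <- Accel2(0, -2000, "C2")
  # stopping distance V^2/(2|a|) = 2.5 um; a far point is unreachable
  far <- solveCrossingFrame(0, 200, v, a, cfg)
  expect_false(far$valid)
  near <- solveCrossingFrame(0, 1, v, a, cfg)
  expect_true(near$valid)
})

test_that("analytic crossing matches brute-force time stepping", {
  cfg <- studyCfg()
  th <- tiltAngle(cfg) * pi / 180
  dx <- equivalentPixelSize(cfg)
  set.seed(21)
  for (rep in 1:5) {
    vy0 <- runif(1, 400, 1200)
    ay <- runif(1, -2000, 4000)
    vx0 <- runif(1, -40, 40)
    prof <- MotionProfile(Velocity2(vx0, vy0, "C1"),
                          data.frame(duration = 2000, ax = 0, ay = ay))
    ok <- tryCatch({trajectoryVelocity(prof, 2000 / 1230, 1230); TRUE},
                   error = function(e) FALSE)
    if (!ok) next
    v2 <- velocityToScanFrame(Velocity2(vx0, vy0, "C1"), cfg)
    a2 <- accelToScanFrame(Accel2(0, ay, "C1"), cfg)
    tab <- oracleTable(prof, cfg, 1500)
    x <- runif(60, 0, 80); y <- runif(60, 0, 250)
    an <- solveCrossingFrame(x, y, v2, a2, cfg)
    orc <- oracleCrossing(tab, x * dx, y * dx)
    use <- an$valid & orc$valid
    expect_gt(mean(use), 0.8)
    expect_lt(max(abs(an$yPrime[use] - orc$ypp[use])), 0.5)
  }
})

test_that("the lateral coordinate follows the drift formula", {
  cfg <- studyCfg()
  vC1 <- Velocity2(0, 900, "C1"); aC1 <- Accel2(0, 0, "C1")
  expect_equal(lateralScanCoordinate(12, 55, vC1, aC1, cfg), 12)
  # doubled line rate halves the per-frame drift at fixed y' in frames
  v <- Velocity2(30, 900, "C1")
  cfg2 <- SensorConfig(lineRate = 2460)
  d1 <- lateralScanCoordinate(0, 100, v, aC1, cfg) - 0
  d2 <- lateralScanCoordinate(0, 100, v, aC1, cfg2) - 0
  expect_equal(d1 / d2, 2)
  expect_error(lateralScanCoordinate(0, -5, v, aC1, cfg), "non-negative")
})

test_that("segment boundaries integrate the measured velocities", {
  cfg <- studyCfg()
  th <- tiltAngle(cfg) * pi / 180
  f <- lineRate(cfg); d <- pixelPitch(cfg)
  # single gap, zero acceleration: closed form b = V'T/(f d sin^2)
  feats <- data.frame(featureId = 1:2, x1 = 0, y1 = c(1, 101),
                      x2 = 0, y2 = c(41, 141), yMid = c(1, 101),
                      ssd = 0, vxp = 900, vyp = c(350, 350),
                      vx = 0, vy = 977)
  acc <- data.frame(yStart = 1, yEnd = 101, axp = 0, ayp = 0,
                    ax = 0, ay = 0)
  kin <- new("KinematicsTable", features = feats, accelerations = acc,
             config = cfg)
  b <- computeSegmentBoundaries(kin, cfg, frameOffset = 0L)
  expect_equal(b@scanDistance[2] - b@scanDistance[1], 350 * 100 / f)
  expect_equal(b@intercepts, b@scanDistance / (d * sin(th)^2))
  expect_true(all(diff(b@intercepts) > 0))
})

test_that("boundaries agree with fine-step numerical integration", {
  cfg <- studyCfg()
  f <- lineRate(cfg)
  feats <- data.frame(featureId = 1:3, x1 = 0, y1 = c(10, 60, 120),
                      x2 = 0, y2 = c(50, 100, 160),
                      yMid = c(10, 60, 120), ssd = 0,
                      vxp = 900, vyp = c(300, 380, 330), vx = 0, vy = 0)
  acc <- data.frame(yStart = c(10, 60), yEnd = c(60, 120),
                    axp = 0, ayp = f * diff(feats$vyp) / diff(feats$yMid),
                    ax = 0, ay = 0)
  kin <- new("KinematicsTable", features = feats, accelerations = acc,
             config = cfg)
  b <- computeSegmentBoundaries(kin, cfg)
  # Euler integration of the piecewise-linear scan speed; the boundary
  # frames are 0-based (yMid - 1 at zero frame offset)
  dt <- 1e-5
  tt <- seq(0, 125 / f, by = dt)
  vAt <- approx(c(0, (feats$yMid - 1) / f, 1), c(300, feats$vyp, 330),
                tt, rule = 2)$y
  S <- cumsum(vAt * dt)
  SAt <- approx(tt, S, (feats$yMid - 1) / f)$y
  expect_equal(b@scanDistance - b@scanDistance[1], SAt - SAt[1],
               tolerance = 1e-3)
})

test_that("segment assignment respects the closed upper boundary", {
  cfg <- studyCfg()
  th <- tiltAngle(cfg) * pi / 180
  # boundaries sit at the feature crossings; the implicit b_y0 = 0 region
  # before the first boundary is segment 0
  pr <- data.frame(startFrame = c(0, 100, 200), v = 350, a = 0,
                   vxObj = 0, axObj = 0,
                   cumS = c(0, 28.4553, 56.9106),
                   cumLat = 0)
  b <- new("SegmentBoundaries", featureFrames = c(100, 200),
           scanDistance = pr$cumS[2:3],
           intercepts = pr$cumS[2:3] / (2.2 * sin(th)^2), profile = pr)
  expect_equal(assignAcceleration(0, 0, b, cfg), 0)
  # a point exactly on an intercept belongs to the earlier segment
  u1 <- b@intercepts[1]
  expect_equal(assignAcceleration(0, u1, b, cfg), 0)
  expect_equal(assignAcceleration(0, u1 + 1e-9, b, cfg), 1)
  # beyond the last boundary: the last segment's acceleration applies
  expect_equal(assignAcceleration(0, 10 * u1, b, cfg), 1)
  # exhaustive-check oracle on random points
  set.seed(9)
  x <- runif(50, 0, 60); y <- runif(50, 0, 400)
  got <- assignAcceleration(x, y, b, cfg)
  u <- y + x * cos(th) / sin(th)
  want <- vapply(u, function(ui)
    min(sum(b@intercepts < ui), length(b@intercepts) - 1), numeric(1))
  expect_equal(as.numeric(got), want)
})

test_that("single-segment mapping equals the crossing quadratic", {
  cfg <- studyCfg()
  v2 <- Velocity2(850, 320, "C2")
  a2 <- Accel2(0, 0, "C2")
  vObj <- velocityToObjectFrame(v2, cfg)
  pr <- data.frame(startFrame = 0, v = 320, a = 0, vxObj = vObj@vx,
                   axObj = 0, cumS = 0, cumLat = 0)
  b <- new("SegmentBoundaries", featureFrames = 0, scanDistance = 0,
           intercepts = 0, profile = pr)
  x <- c(0, 10, 33); y <- c(5, 40, 120)
  mp <- mapObjectToScan(x, y, b, cfg)
  an <- solveCrossingFrame(x, y, v2, a2, cfg)
  expect_equal(mp$ypp, an$yPrime, tolerance = 1e-9)
})

test_that("multi-segment mapping matches the time-stepping oracle", {
  cfg <- studyCfg()
  dx <- equivalentPixelSize(cfg)
  prof <- MotionProfile(Velocity2(12, 700, "C1"),
                        data.frame(duration = c(160, 55, 120),
                                   ax = c(0, 30, 0),
                                   ay = studyAccels()))
  b <- exactBoundaries(prof, cfg, frames = c(0, 160, 215))
  tab <- oracleTable(prof, cfg, 330)
  set.seed(13)
  x <- runif(300, 0, 80); y <- runif(300, 0, 260)
  mp <- mapObjectToScan(x, y, b, cfg)
  orc <- oracleCrossing(tab, x * dx, y * dx)
  use <- mp$valid & orc$valid & orc$ypp < 320
  expect_gt(sum(use), 150)
  expect_lt(max(abs(mp$ypp[use] - orc$ypp[use])), 0.5)
  expect_lt(max(abs(mp$xpp[use] - orc$xpp[use])), 0.5)
})

test_that("the mapping is continuous across segment boundaries", {
  cfg <- studyCfg()
  prof <- defaultMotionProfile()
  b <- exactBoundaries(prof, cfg, frames = c(0, 160, 215))
  y <- seq(0, 250, by = 0.5)
  mp <- mapObjectToScan(rep(20, length(y)), y, b, cfg)
  ok <- mp$valid
  expect_true(all(diff(mp$ypp[ok]) > 0))
  expect_lt(max(abs(diff(mp$ypp[ok]))), 1)  # no jumps between neighbours
})

test_that("at 90 degrees the reconstruction is a transpose-and-scale", {
  cfg <- SensorConfig(tiltAngle = 90, lineLength = 30L)
  # one sensor pixel advances per frame when V_y' = d f
  v <- Velocity2(0, pixelPitch(cfg) * lineRate(cfg), "C2")
  fgm <- matrix(rnorm(40 * 30), 40, 30)
  rec <- reconstructImage(fgm, NULL, cfg, model = "uniform_velocity",
                          velocity = v, frameOffset = 0L)
  img <- reconImage(rec)
  expect_equal(img[1:40, ], fgm, tolerance = 1e-9)
})

test_that("degenerate constant-velocity kinematics make all models agree", {
  cfg <- studyCfg()
  feats <- data.frame(featureId = 1:3, x1 = 10, y1 = c(20, 60, 100),
                      x2 = 25, y2 = c(60, 100, 140),
                      yMid = c(40, 80, 120), ssd = 0,
                      vxp = 900, vyp = 340, vx = 0, vy = 950)
  acc <- data.frame(yStart = c(40, 80), yEnd = c(80, 120),
                    axp = 0, ayp = 0, ax = 0, ay = 0)
  kin <- new("KinematicsTable", features = feats, accelerations = acc,
             config = cfg)
  fgm <- matrix(rnorm(260 * 88), 260, 88)
  rV <- reconstructImage(fgm, kin, cfg, model = "variable_acceleration",
                         frameOffset = 20L)
  rU <- reconstructImage(fgm, kin, cfg, model = "uniform_velocity",
                         frameOffset = 20L)
  expect_lt(max(abs(reconImage(rV) - reconImage(rU))), 1e-6)
})

test_that("a uniform-flow capture round-trips above 0.9 similarity", {
  # reconstruction contract in isolation: the true uniform velocity is
  # supplied, so the only losses are resampling blur
  cfg <- studyCfg()
  vy <- 800
  prof <- MotionProfile(Velocity2(0, vy, "C1"),
                        data.frame(duration = 500, ax = 0, ay = 0))
  sim <- acquireDualLineScan(studyPhantom(), prof, cfg, zeroNoise(),
                             seed = 1)
  fg1 <- extractForeground(sim$stream1)
  rec <- reconstructImage(fg1, NULL, cfg, model = "uniform_velocity",
                          velocity = velocityToScanFrame(
                            Velocity2(0, vy, "C1"), cfg))
  ref <- downsamplePhantom(sim$truth$phantom, equivalentPixelSize(cfg))
  reg <- registerToReference(reconImage(rec), ref)
  expect_gte(ssim(reg$aligned, ref), 0.9)
})

test_that("a circular phantom reconstructs with unit aspect ratio", {
  cfg <- studyCfg()
  sim <- studySim(seed = 1, noise = zeroNoise())
  fg1 <- extractForeground(sim$stream1)
  fg2 <- extractForeground(sim$stream2)
  kin <- suppressMessages(estimateKinematics(fg1, fg2, cfg))
  rec <- reconstructImage(fg1, kin, cfg, model = "variable_acceleration")
  ref <- downsamplePhantom(sim$truth$phantom, equivalentPixelSize(cfg))
  reg <- registerToReference(reconImage(rec), ref)
  axisRatio <- function(M) {
    W <- abs(M); s <- sum(W)
    mr <- sum(row(M) * W) / s; mc <- sum(col(M) * W) / s
    crr <- sum((row(M) - mr)^2 * W) / s
    ccc <- sum((col(M) - mc)^2 * W) / s
    crc <- sum((row(M) - mr) * (col(M) - mc) * W) / s
    ev <- eigen(matrix(c(crr, crc, crc, ccc), 2))$values
    sqrt(ev[1] / ev[2])
  }
  expect_lt(abs(axisRatio(reg$aligned) - 1), 0.05)
})

test_that("empty kinematics require an explicit velocity", {
  cfg <- studyCfg()
  fgm <- matrix(0, 50, 88)
  expect_error(reconstructImage(fgm, NULL, cfg,
                                model = "variable_acceleration"),
               "uniform_velocity")
  rec <- reconstructImage(fgm, NULL, cfg, model = "uniform_velocity",
                          velocity = Velocity2(900, 350, "C2"))
  expect_s4_class(rec, "ReconstructionGrid")
  expect_equal(pixelSize(rec), equivalentPixelSize(cfg))
})
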