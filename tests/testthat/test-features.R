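# MSER ring detection, corner extraction/screening, SSD matching and
# velocity/acceleration estimation.

test_that("dynamic-range compression rescales only above the cap", {
  img <- matrix(seq(0, 255, length.out = 64), 8)
  out <- compressDynamicRange(img, 190)
  expect_equal(max(out), 190)
  expect_equal(out, img * (190 / 255))
  expect_identical(compressDynamicRange(img, 300), img)  # cap >= max
  flat <- matrix(7, 4, 4)
  expect_identical(compressDynamicRange(flat, 5), flat)
  # rank order preserved
  expect_identical(order(out), order(img))
})

test_that("MSER finds nothing on a uniform image", {
  expect_length(detectMSER(matrix(128, 40, 40)), 0)
})

test_that("MSER recovers a dark disk on a bright field", {
  img <- matrix(200, 48, 48)
  ctr <- 24.5
  disk <- (row(img) - ctr)^2 + (col(img) - ctr)^2 <= 8^2
  img[disk] <- 40
  regs <- detectMSER(img, mserParams(minArea = 20, maxArea = 1000))
  expect_gte(length(regs), 1)
  cover <- vapply(regs, function(r) {
    idx <- (r$pixels[, 2] - 1) * nrow(img) + r$pixels[, 1]
    sum(disk[idx]) / sum(disk)
  }, numeric(1))
  expect_gte(max(cover), 0.9)
})

test_that("MSER separates nested bright/dark rings", {
  n <- 81; ctr <- 41
  r <- sqrt((row(matrix(0, n, n)) - ctr)^2 +
              (col(matrix(0, n, n)) - ctr)^2)
  img <- matrix(120, n, n)
  img[r <= 30] <- 120 + 60 * cos(pi * r[r <= 30] / 7.5)
  regs <- detectMSER(img, mserParams(minArea = 30, maxArea = 3000))
  expect_gte(length(regs), 2)
  bb <- t(vapply(regs, function(rr)
    c(min(rr$pixels[, 1]), max(rr$pixels[, 1]),
      min(rr$pixels[, 2]), max(rr$pixels[, 2])), numeric(4)))
  # at least one strictly nested pair of bounding boxes
  nested <- FALSE
  for (i in seq_len(nrow(bb))) for (j in seq_len(nrow(bb)))
    if (i != j && bb[i, 1] > bb[j, 1] && bb[i, 2] < bb[j, 2] &&
        bb[i, 3] > bb[j, 3] && bb[i, 4] < bb[j, 4]) nested <- TRUE
  expect_true(nested)
})

test_that("corners sit at the ordinate extremes of a region", {
  rect <- list(list(pixels = cbind(rep(2:7, each = 7), rep(3:9, 6)),
                    id = 1L))
  co <- extractCorners(rect)
  expect_equal(co$x, c(6, 6))
  expect_equal(co$y, c(2, 7))
  expect_equal(co$end, c("top", "bottom"))
  # single-pixel region: both corners coincide
  one <- extractCorners(list(list(pixels = cbind(5L, 8L), id = 1L)))
  expect_equal(one$x, c(8, 8))
  expect_equal(one$y, c(5, 5))
  # rasterised circle: corners near centre_x, centre_y +- r
  n <- 41; ctr <- 21; r <- 12
  px <- which((row(matrix(0, n, n)) - ctr)^2 +
                (col(matrix(0, n, n)) - ctr)^2 <= r^2, arr.ind = TRUE)
  cc <- extractCorners(list(list(pixels = px, id = 1L)))
  expect_equal(cc$x, c(ctr, ctr), tolerance = 0.05)
  expect_equal(cc$y, c(ctr - r, ctr + r))
})

test_that("corner score is the absolute kernel response", {
  k <- defaultCornerKernel()
  expect_equal(scoreCorner(matrix(0, 9, 9), k), 0)
  expect_equal(scoreCorner(k, k), sum(k^2))
  step <- rbind(matrix(10, 4, 9), matrix(0, 1, 9), matrix(-10, 4, 9))
  expect_gt(scoreCorner(step, k), scoreCorner(matrix(5, 9, 9), k))
  expect_error(scoreCorner(matrix(0, 3, 3), k), "shape")
})

test_that("corner screening keeps the strongest within the separation", {
  one <- data.frame(x = 1, y = 5, strength = 2)
  expect_identical(screenCorners(one), one)
  two <- data.frame(x = c(1, 2), y = c(10, 11), strength = c(5, 9))
  expect_equal(screenCorners(two, minSeparation = 3)$strength, 9)
  set.seed(4)
  rnd <- data.frame(x = runif(40, 1, 50), y = runif(40, 1, 200),
                    strength = runif(40))
  kept <- screenCorners(rnd, minSeparation = 8)
  expect_true(all(diff(sort(kept$y)) >= 8))
})

test_that("SSD matching recovers an exact shift and the global optimum", {
  set.seed(7)
  img1 <- matrix(runif(60 * 40, 0, 255), 60, 40)
  di <- 9; dj <- 3
  img2 <- matrix(0, 80, 50)
  img2[(1:60) + di, (1:40) + dj] <- img1
  m <- ssdMatch(20, 30, img1, img2, H = 20, W = 20,
                searchRows = 25:55, searchCols = 12:34)
  expect_equal(m$y2, 30 + di)
  expect_equal(m$x2, 20 + dj)
  expect_equal(m$ssd, 0)
  # restricted search equals exhaustive search when the shift is inside
  ex <- ssdMatch(20, 30, img1, img2, H = 20, W = 20,
                 searchRows = 11:70, searchCols = 11:40,
                 subpixel = FALSE)
  expect_equal(ex$y2, 30 + di)
  expect_equal(ex$x2, 20 + dj)
  # translation consistency: shifting both images leaves the offset fixed
  s1 <- img1[6:55, 6:40]; s2 <- img2[6:75, 6:50]
  m2 <- ssdMatch(15, 25, s1, s2, H = 20, W = 20,
                 searchRows = 20:50, searchCols = 8:30)
  expect_equal(m2$y2 - 25, m$y2 - 30)
  expect_equal(m2$x2 - 15, m$x2 - 20)
})

test_that("features whose template leaves the image are dropped", {
  img <- matrix(runif(400), 20, 20)
  expect_message(
    out <- ssdMatch(2, 2, img, img, H = 20, W = 20,
                    searchRows = 5:15, searchCols = 5:15),
    "border")
  expect_null(out)
})

test_that("pair velocity follows the dual-line lag relations", {
  cfg <- SensorConfig(pixelPitch = 2.2, sensorGap = 13.2,
                      lineRate = 1230)
  v <- estimateVelocity(list(x1 = 10, y1 = 50, x2 = 10, y2 = 60), cfg)
  expect_equal(v@vx, 0)
  expect_equal(v@vy, 1623.6)
  expect_equal(v@frame, "C2")
  expect_error(
    estimateVelocity(list(x1 = 10, y1 = 50, x2 = 10, y2 = 50), cfg),
    "later")
})

test_that("velocity estimates invert the frame rotation exactly", {
  # simulate one noiseless uniform capture and check rotation
  # consistency: the recovered scan-frame velocity maps back to the
  # object frame
  cfg <- studyCfg()
  vy <- 850
  prof <- MotionProfile(Velocity2(0, vy, "C1"),
                        data.frame(duration = 500, ax = 0, ay = 0))
  sim <- acquireDualLineScan(studyPhantom(), prof, cfg, zeroNoise(),
                             seed = 1)
  fg1 <- extractForeground(sim$stream1)
  fg2 <- extractForeground(sim$stream2)
  kin <- suppressMessages(estimateKinematics(fg1, fg2, cfg))
  feats <- featureTable(kin)
  expect_gte(nrow(feats), 3)
  th <- tiltAngle(cfg) * pi / 180
  expect_equal(median(feats$vyp), vy * sin(th), tolerance = 0.02)
  expect_equal(median(feats$vxp), vy * cos(th), tolerance = 0.02)
  expect_equal(median(feats$vy), vy, tolerance = 0.02)
  expect_lt(abs(median(feats$vx)), 0.03 * vy)
})

test_that("finite-difference accelerations follow the lag arithmetic", {
  cfg <- SensorConfig(lineRate = 1230)
  f <- data.frame(y1 = c(10, 20), yMid = c(10, 20),
                  vxp = c(100, 100), vyp = c(400, 500))
  a <- estimateAccelerations(f, cfg)
  expect_equal(a$ayp, 1230 * 100 / 10)   # 12300
  expect_equal(a$axp, 0)
  # equal consecutive velocities give zero acceleration
  f2 <- data.frame(y1 = c(5, 9), yMid = c(5, 9),
                   vxp = c(80, 80), vyp = c(300, 300))
  expect_equal(unlist(estimateAccelerations(f2, cfg)[, c("axp", "ayp")]),
               c(axp = 0, ayp = 0))
  dup <- data.frame(y1 = c(5, 5), yMid = c(5, 5),
                    vxp = c(1, 2), vyp = c(3, 4))
  expect_warning(aa <- estimateAccelerations(dup, cfg), "duplicate")
  expect_true(is.na(aa$ayp))
})

test_that("a kinematics table has K velocities and K-1 accelerations", {
  sim <- studySim(seed = 3)
  fg1 <- extractForeground(sim$stream1)
  fg2 <- extractForeground(sim$stream2)
  kin <- suppressMessages(estimateKinematics(fg1, fg2, cfg <- studyCfg()))
  k <- nrow(featureTable(kin))
  expect_gte(k, 2)
  expect_equal(nrow(accelerationTable(kin)), k - 1)
  expect_true(all(featureTable(kin)$y2 > featureTable(kin)$y1))
  expect_error(new("KinematicsTable", features = featureTable(kin),
                   accelerations = accelerationTable(kin)[-1, ],
                   config = cfg), "K-1")
})

test_that("three-segment velocimetry recovers speeds and accel signs", {
  cfg <- studyCfg()
  th <- tiltAngle(cfg) * pi / 180
  sim <- studySim(seed = 5, noise = zeroNoise())
  fg1 <- extractForeground(sim$stream1)
  fg2 <- extractForeground(sim$stream2)
  kin <- suppressMessages(estimateKinematics(fg1, fg2, cfg))
  feats <- featureTable(kin)
  off <- frameOffset(fg1)
  vf <- sim$truth$velocityByFrame
  vyT <- vapply(seq_len(nrow(feats)), function(i)
    mean(approx(vf$frame, vf$vy,
                seq(feats$y1[i], feats$y2[i], by = 0.5) - 1 + off,
                rule = 2)$y) * sin(th), numeric(1))
  bnd <- sim$truth$segmentBoundaryFrames
  fr <- feats$yMid - 1 + off
  seg <- findInterval(fr, bnd[1:2]) + 1
  for (s in 1:3) {
    i <- seg == s
    expect_gte(sum(i), 2)
    expect_equal(median(feats$vyp[i]), median(vyT[i]), tolerance = 0.05)
    slope <- unname(coef(lm(feats$vyp[i] ~ fr[i]))[2])
    expect_equal(sign(slope), sign(studyAccels()[s]))
  }
})

test_that("kinematics tables round-trip through CSV", {
  sim <- studySim(seed = 3)
  cfg <- studyCfg()
  kin <- suppressMessages(estimateKinematics(
    extractForeground(sim$stream1), extractForeground(sim$stream2), cfg))
  p <- tempfile(fileext = ".csv")
  writeKinematics(kin, p)
  back <- readKinematics(p, cfg)
  expect_equal(featureTable(back)$vyp, featureTable(kin)$vyp)
  expect_equal(accelerationTable(back)$ayp, accelerationTable(kin)$ayp,
               tolerance = 1e-9)
})
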