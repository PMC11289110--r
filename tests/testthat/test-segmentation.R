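test_that("binarization is strict at the threshold", {
  z <- matrix(0, 4, 4)
  expect_equal(nCystPixels(binarizeProbabilities(z)), 0L)

  half <- matrix(0.5, 4, 4)
  expect_equal(nCystPixels(binarizeProbabilities(half, 0.5)), 0L)

  cb <- matrix(c(0.4, 0.6), 4, 4)
  m <- binarizeProbabilities(cb, 0.5)
  expect_identical(maskMatrix(m), matrix(c(FALSE, TRUE), 4, 4))

  expect_error(binarizeProbabilities(z, 0), "in \\(0, 1\\)")
  expect_error(binarizeProbabilities(z, 1), "in \\(0, 1\\)")
  expect_error(binarizeProbabilities(matrix(1.2, 2, 2)), "\\[0, 1\\]")
})

test_that("the warm-restart schedule restarts at the 10- and 30-epoch boundaries", {
  lr <- cosineAnnealingSchedule(1:70, lr0 = 1e-4, t0 = 10L, tMult = 2L)
  expect_equal(lr[1], 1e-4)
  expect_equal(lr[11], 1e-4)   # restart after the 10-epoch cycle
  expect_equal(lr[31], 1e-4)   # restart after the following 20-epoch cycle
  expect_lt(lr[10], 1e-5)      # cosine tail near the end of a cycle
  expect_true(all(diff(lr[1:10]) < 0))
  expect_true(all(diff(lr[11:30]) < 0))
  expect_true(all(diff(lr[31:70]) < 0))
})

test_that("network gradients match numerical differentiation", {
  nn <- asNamespace("cystwise")
  set.seed(14)
  w <- nn$.initNet(c(2L, 3L, 4L))
  # perturb the zero-initialized head so gradients reach every layer
  w[["out.W"]][] <- stats::rnorm(length(w[["out.W"]]), 0, 0.05)
  x <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(stats::runif(64) > 0.5, 8, 8)
  fwd <- nn$.netForward(w, x, keepCache = TRUE)
  bce <- nn$.bceLogits(fwd$logits, y)
  G <- nn$.netBackward(w, fwd, bce$dz)
  f <- function(wts) nn$.bceLogits(nn$.netForward(wts, x)$logits, y)$loss
  for (nm in c("enc1a.W", "enc2b.b", "botb.W", "dec1a.W", "out.W", "out.b")) {
    i <- sample(length(w[[nm]]), 1)
    eps <- 1e-5
    wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
    wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
    num <- (f(wp) - f(wm)) / (2 * eps)
    expect_equal(G[[nm]][i], num, tolerance = 1e-5)
  }
})

test_that("backends satisfy the predictor contract on any RGB input", {
  sc <- generateScene(easySceneConfig(2L))
  for (backend in list(thresholdBackend(),
                       new("ReferenceNet",
                           weights = asNamespace("cystwise")$.initNet(c(2L, 3L, 4L)),
                           channels = c(2L, 3L, 4L),
                           channelMeans = c(0.485, 0.456, 0.406),
                           channelStds = c(0.229, 0.224, 0.225)))) {
    p <- predictProbabilities(backend, sc@image)
    expect_equal(dim(p), dim(sc@image)[1:2])
    expect_true(all(p >= 0 & p <= 1))
    # deterministic inference
    expect_identical(p, predictProbabilities(backend, sc@image))
  }
})

test_that("the untrained-baseline backend localizes lumens on easy scenes", {
  sc <- generateScene(easySceneConfig(19L))
  prob <- predictProbabilities(thresholdBackend(), sc@image)
  m <- matchCysts(binarizeProbabilities(prob), sc@gtMask)
  expect_equal(m@ms, 0L)  # every lumen found by darkness alone
})

test_that("training validates its inputs", {
  sets <- easySceneSet(1:2)
  expect_error(trainReferenceModel(list(), sets, trainConfig()), "empty")
  blank <- list(list(image = array(0.5, c(16, 16, 3)),
                     mask = matrix(FALSE, 16, 16)))
  expect_error(trainReferenceModel(sets, blank, trainConfig()),
               "no cyst pixels")
})

test_that("training honors early stopping and returns the best-epoch weights", {
  small <- function(seed) {
    sc <- generateScene(sceneConfig(width = 32L, height = 32L, nCysts = 1L,
                                    areaMeanlog = log(40), areaSdlog = 0.2,
                                    areaRange = c(25, 70),
                                    micronsPerPixel = 1, margin = 3L,
                                    seed = seed))
    list(image = sc@image, mask = sc@gtMask)
  }
  trainSet <- lapply(1:6, small)
  valSet <- lapply(7:8, small)
  cfg <- trainConfig(maxEpochs = 15L, patience = 3L, seed = 5L)
  fit <- trainReferenceModel(trainSet, valSet, cfg, channels = c(2L, 3L, 4L))
  h <- fit$history
  expect_lte(nrow(h), cfg@maxEpochs)
  expect_lte(nrow(h), fit$bestEpoch + cfg@patience)
  expect_equal(fit$bestValIoU, max(h$valIoU))
  expect_equal(h$lr, cosineAnnealingSchedule(h$epoch, cfg@learningRate,
                                             cfg@t0, cfg@tMult))
  # returned backend reproduces the best epoch's validation IoU
  tp <- fp <- fn <- 0
  for (s in valSet) {
    pm <- maskMatrix(binarizeProbabilities(
      predictProbabilities(fit$backend, s$image), cfg@threshold))
    y <- maskMatrix(s$mask)
    tp <- tp + sum(pm & y); fp <- fp + sum(pm & !y); fn <- fn + sum(!pm & y)
  }
  expect_equal(tp / (tp + fp + fn), fit$bestValIoU, tolerance = 1e-12)
})

test_that("training is reproducible under its seed", {
  trainSet <- easySceneSet(1:4)
  valSet <- easySceneSet(31:32)
  cfg <- trainConfig(maxEpochs = 2L, seed = 9L)
  a <- trainReferenceModel(trainSet, valSet, cfg, channels = c(2L, 3L, 4L))
  b <- trainReferenceModel(trainSet, valSet, cfg, channels = c(2L, 3L, 4L))
  expect_identical(a$history, b$history)
  expect_identical(a$backend@weights, b$backend@weights)
})

test_that("checkpoints round-trip through disk", {
  nn <- asNamespace("cystwise")
  set.seed(3)
  net <- new("ReferenceNet", weights = nn$.initNet(c(2L, 3L, 4L)),
             channels = c(2L, 3L, 4L),
             channelMeans = c(0.485, 0.456, 0.406),
             channelStds = c(0.229, 0.224, 0.225))
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  back <- loadCheckpoint(f)
  expect_identical(back@weights, net@weights)
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(predictProbabilities(back, img),
                   predictProbabilities(net, img))
})
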