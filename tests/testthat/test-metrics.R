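test_that("pixel confusion and metrics follow their definitions", {
  g <- matrix(FALSE, 10, 10); g[2:6, 2:5] <- TRUE   # 20 cyst pixels
  same <- pixelConfusion(CystMask(g), CystMask(g))
  expect_equal(same, c(TP = 20, FP = 0, FN = 0))
  expect_equal(unname(pixelMetrics(same)), c(1, 1, 1))

  # gt = {a, b}, pred = {b, c}: one shared pixel
  gt <- matrix(FALSE, 2, 2); gt[1, 1] <- TRUE; gt[1, 2] <- TRUE
  pr <- matrix(FALSE, 2, 2); pr[1, 2] <- TRUE; pr[2, 1] <- TRUE
  conf <- pixelConfusion(CystMask(pr), CystMask(gt))
  expect_equal(conf, c(TP = 1, FP = 1, FN = 1))
  m <- pixelMetrics(conf)
  expect_equal(unname(m), c(1 / 3, 1 / 2, 1 / 2))

  # both empty: all metrics undefined
  e <- pixelMetrics(pixelConfusion(CystMask(matrix(FALSE, 3, 3)),
                                   CystMask(matrix(FALSE, 3, 3))))
  expect_true(all(is.na(e)))

  expect_error(pixelConfusion(CystMask(matrix(FALSE, 2, 2)),
                              CystMask(matrix(FALSE, 3, 3))), "same shape")
})

test_that("the pixel-wise IoU identity holds whenever defined", {
  set.seed(41)
  for (i in 1:50) {
    conf <- pixelConfusion(CystMask(randomBlobMask(24, 24, sample(0:4, 1))),
                           CystMask(randomBlobMask(24, 24, sample(1:4, 1))))
    m <- pixelMetrics(conf)
    if (!anyNA(m) && m[["Pr"]] + m[["Re"]] > 0)
      expect_equal(m[["IoU"]],
                   m[["Pr"]] * m[["Re"]] /
                     (m[["Pr"]] + m[["Re"]] - m[["Pr"]] * m[["Re"]]),
                   tolerance = 1e-12)
  }
})

test_that("the five overlap configurations resolve to the stated DT/MS/WR", {
  H <- 20L; W <- 20L
  disc <- function(cy, cx, r) {
    g <- matrix(FALSE, H, W)
    rr <- max(1, cy - r):min(H, cy + r); cc <- max(1, cx - r):min(W, cx + r)
    g[rr, cc] <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2) <= r^2
    g
  }
  counts <- function(pred, gt)
    matchCounts(matchCysts(CystMask(pred), CystMask(gt)))

  # exact match
  expect_equal(counts(disc(10, 10, 4), disc(10, 10, 4)),
               c(DT = 1L, MS = 0L, WR = 0L))
  # partial overlap
  expect_equal(counts(disc(10, 12, 4), disc(10, 9, 4)),
               c(DT = 1L, MS = 0L, WR = 0L))
  # two predictions over one ground-truth cyst: one DT, surplus is WR
  twoPred <- disc(8, 8, 2) | disc(13, 13, 2)
  expect_equal(counts(twoPred, disc(10, 10, 6)),
               c(DT = 1L, MS = 0L, WR = 1L))
  # one prediction over two ground-truth cysts: one DT, the other MS
  twoGt <- disc(10, 6, 3) | disc(10, 15, 3)
  expect_equal(counts(disc(10, 10, 8), twoGt),
               c(DT = 1L, MS = 1L, WR = 0L))
  # disjoint: a miss and a wrong
  expect_equal(counts(disc(4, 4, 2), disc(15, 15, 3)),
               c(DT = 0L, MS = 1L, WR = 1L))
  # no predictions at all
  expect_equal(counts(matrix(FALSE, H, W), twoGt),
               c(DT = 0L, MS = 2L, WR = 0L))
})

test_that("DT/MS/WR conservation holds on random perturbed scenes", {
  for (s in 1:10) {
    sc <- generateScene(easySceneConfig(60L + s))
    p <- perturbMask(sc@gtMask,
                     perturbConfig(dropRate = 0.3, spuriousRate = 2,
                                   splitRate = 0.3, seed = s),
                     micronsPerPixel = 1)
    m <- matchCysts(p$pred, sc@gtMask)
    expect_equal(m@dt + m@ms, nComponents(labelComponents(sc@gtMask)))
    expect_equal(m@dt + m@wr, nComponents(labelComponents(p$pred)))
    expect_equal(m@dt, nrow(matchedPairs(m)))
    expect_lte(m@dt, min(m@dt + m@ms, m@dt + m@wr))
  }
})

test_that("greedy matching attains the maximum on star-overlap instances", {
  set.seed(43)
  tried <- 0
  while (tried < 60) {
    inst <- randomStarInstance()
    pred <- labelComponents(CystMask(inst$pred))
    gt <- labelComponents(CystMask(inst$gt))
    if (nComponents(pred) > 6 || nComponents(gt) > 6) next
    tried <- tried + 1
    m <- matchCysts(pred, gt)
    ov <- matrix(FALSE, max(nComponents(pred), 1), max(nComponents(gt), 1))
    pl <- componentLabels(pred); gl <- componentLabels(gt)
    both <- pl > 0 & gl > 0
    if (any(both)) ov[cbind(pl[both], gl[both])] <- TRUE
    expect_equal(m@dt, oracleMaxMatching(ov))
  }
})

test_that("matching is monotone in the IoU threshold", {
  sc <- generateScene(easySceneConfig(77L))
  p <- perturbMask(sc@gtMask, perturbConfig(splitRate = 0.5,
                                            boundaryJitter = 1L, seed = 2))
  taus <- c(0, 0.1, 0.3, 0.5, 0.7)
  dts <- vapply(taus, function(t)
    matchCysts(p$pred, sc@gtMask, matchConfig("iou", t))@dt, integer(1))
  expect_true(all(diff(dts) <= 0))
  # tau = 0 IoU rule equals the >= 1 pixel rule
  expect_equal(dts[1], matchCysts(p$pred, sc@gtMask, matchConfig("pixel"))@dt)
})

test_that("cyst-wise metric arithmetic and undefined flagging", {
  expect_equal(unname(cystMetrics(c(DT = 1, MS = 1, WR = 0))),
               c(0.5, 1.0, 0.5))
  expect_equal(unname(cystMetrics(c(DT = 3, MS = 0, WR = 3))),
               c(0.5, 0.5, 1.0))
  expect_true(all(is.na(cystMetrics(c(DT = 0, MS = 0, WR = 0)))))
  partial <- cystMetrics(c(DT = 0, MS = 2, WR = 0))
  expect_true(is.na(partial[["Pr_cyst"]]))
  expect_equal(partial[["Re_cyst"]], 0)
})

test_that("perfect prediction yields six unit metrics", {
  sc <- generateScene(easySceneConfig(55L))
  pm <- pixelMetrics(pixelConfusion(sc@gtMask, sc@gtMask))
  cm <- cystMetrics(matchCysts(sc@gtMask, sc@gtMask))
  expect_equal(unname(c(pm, cm)), rep(1, 6))
})

test_that("zone assignment uses left-closed boundaries with an open top zone", {
  z <- zoneConfig()
  expect_equal(assignZone(30, z), 1L)
  expect_equal(assignZone(34.7, z), 2L)    # boundary belongs to the upper zone
  expect_equal(assignZone(78, z), 3L)
  expect_equal(assignZone(1900, z), 6L)
  expect_error(assignZone(0, z), "positive")
  expect_error(zoneConfig(boundaries = c(5, 3)), "ascending")
})

test_that("quantile boundaries induce equal-cardinality zones", {
  b <- computeZoneBoundaries(1:12, 6L)
  expect_length(b, 5L)
  zones <- assignZone(1:12, zoneConfig(boundaries = b, micronsPerPixel = 1))
  expect_true(all(table(zones) == 2))

  expect_warning(computeZoneBoundaries(rep(7, 10), 6L), "degenerate")
  expect_identical(computeZoneBoundaries(1:5, 1L), numeric(0))
  expect_error(computeZoneBoundaries(1:3, 6L), "at least")
})

test_that("zone attribution uses actual size for DT/MS and predicted size for WR", {
  z <- zoneConfig(micronsPerPixel = 1)  # areas in px = areas in um^2
  H <- 40L
  g <- matrix(FALSE, H, H); g[2:8, 2:8] <- TRUE          # gt area 49 -> zone 2
  p <- matrix(FALSE, H, H); p[2:12, 2:12] <- TRUE        # pred area 121 -> zone 4
  p[30:33, 30:37] <- TRUE                                # WR blob area 32 -> zone 1
  m <- matchCysts(CystMask(p), CystMask(g))
  za <- zoneAttribution(m, z)
  expect_equal(za$DT[2], 1L)     # the DT pair sits in the gt zone
  expect_equal(sum(za$DT), 1L)
  expect_equal(za$WR[1], 1L)     # the wrong blob sits in its predicted zone
  # conservation across zones
  expect_equal(colSums(za[, c("DT", "MS", "WR")]),
               c(DT = m@dt, MS = m@ms, WR = m@wr))
})

test_that("detected-pair IoU distribution reports correct fractions", {
  sc <- generateScene(easySceneConfig(88L))
  ident <- matchCysts(sc@gtMask, sc@gtMask)
  d <- dtIouDistribution(ident)
  expect_true(all(d$iou == 1))

  d2 <- structure(list(iou = c(0.1, 0.5, 0.9),
                       cumulative = c(1, 2, 3) / 3),
                  class = "dtIouDistribution")
  expect_equal(fractionAbove(d2, 0.2), 2 / 3)
  expect_equal(fractionAbove(d2, c(0, 0.95)), c(1, 0))

  expect_length(dtIouDistribution(list())$iou, 0L)
})

test_that("jitter-only perturbation keeps detected-pair IoUs high for thick cysts", {
  sc <- generateScene(easySceneConfig(23L))
  p <- perturbMask(sc@gtMask, perturbConfig(boundaryJitter = 1L, seed = 4))
  m <- matchCysts(p$pred, sc@gtMask)
  expect_equal(m@ms + m@wr, 0L)
  expect_true(all(matchedPairs(m)$iou > 0.5))
})
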