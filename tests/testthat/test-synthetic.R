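test_that("scene generation honors the requested cyst count and is deterministic", {
  cfg0 <- sceneConfig(width = 96L, height = 96L, nCysts = 0L,
                      micronsPerPixel = 1, seed = 2)
  expect_equal(nCystPixels(generateScene(cfg0)@gtMask), 0L)

  cfg <- sceneConfig(width = 192L, height = 192L, nCysts = 5L,
                     areaRange = c(30, 300), micronsPerPixel = 1, seed = 4)
  sc <- generateScene(cfg)
  comps <- labelComponents(sc@gtMask)
  expect_equal(nComponents(comps), 5L)

  sc2 <- generateScene(cfg)
  expect_identical(sc@image, sc2@image)
  expect_identical(maskMatrix(sc@gtMask), maskMatrix(sc2@gtMask))
})

test_that("the ground-truth mask equals the rasterization of the stored geometries", {
  sc <- generateScene(easySceneConfig(9L))
  ann <- AnnotationSet("x", lapply(sc@geometries, `[[`, "polygon"))
  again <- rasterizeAnnotations(ann, dim(sc@image)[2], dim(sc@image)[1])
  expect_identical(maskMatrix(sc@gtMask), maskMatrix(again))
})

test_that("scene renders the expected channel structure", {
  sc <- generateScene(easySceneConfig(13L))
  gt <- maskMatrix(sc@gtMask)
  red <- sc@image[, , 1]; green <- sc@image[, , 2]; blue <- sc@image[, , 3]
  # lumens dark in red relative to surrounding tissue
  expect_lt(mean(red[gt]), 0.3 * mean(red[!gt & red > 0.2]))
  # green is low-level noise, uncorrelated with the mask
  expect_lt(mean(green), 0.2)
  # nuclei make blue bright somewhere near rims but dark inside lumens
  expect_lt(mean(blue[gt]), 0.15)
  expect_gt(max(blue), 0.8)
})

test_that("empirical cyst-area median tracks the configured target", {
  areas <- unlist(lapply(1:30, function(s) {
    sc <- generateScene(sceneConfig(width = 512L, height = 512L,
                                    micronsPerPixel = 0.5, seed = 400 + s))
    vapply(sc@geometries, `[[`, numeric(1), "areaUm2")
  }))
  expect_gt(length(areas), 50)
  expect_lt(abs(stats::median(areas) - 78) / 78, 0.20)
  expect_true(all(areas >= 30 & areas <= 2000))
})

test_that("placement failure is reported with the achieved count", {
  tiny <- sceneConfig(width = 48L, height = 48L, nCysts = 12L,
                      areaMeanlog = log(800), areaSdlog = 0.1,
                      areaRange = c(500, 2000), micronsPerPixel = 1, seed = 1)
  expect_error(generateScene(tiny), class = "cystwisePlacementError")
  expect_error(generateScene(tiny), "achieved")
})

test_that("perturbation identity, total drop, and logging behave as specified", {
  sc <- generateScene(easySceneConfig(6L))
  gt <- sc@gtMask
  n <- nComponents(labelComponents(gt))

  idp <- perturbMask(gt, perturbConfig(seed = 1))
  expect_identical(maskMatrix(idp$pred), maskMatrix(gt))
  expect_true(all(idp$log$components$action == "kept"))

  dr <- perturbMask(gt, perturbConfig(dropRate = 1, seed = 1))
  expect_equal(nCystPixels(dr$pred), 0L)
  expect_equal(nrow(dr$log$components), n)
  expect_true(all(dr$log$components$action == "dropped"))

  sp <- perturbMask(gt, perturbConfig(spuriousRate = 3, spuriousExact = TRUE,
                                      seed = 2), micronsPerPixel = 1)
  expect_equal(nrow(sp$log$spurious), 3L)
  # spurious blobs are disjoint from ground truth: components increase by 3
  expect_equal(nComponents(labelComponents(sp$pred)), n + 3L)
  expect_equal(sum(maskMatrix(sp$pred) & maskMatrix(gt)), nCystPixels(gt))
})

test_that("a split produces two fragments that both overlap the parent cyst", {
  sc <- generateScene(easySceneConfig(8L))
  comps <- labelComponents(sc@gtMask)
  n <- nComponents(comps)
  sp <- perturbMask(sc@gtMask, perturbConfig(splitIds = 1L, seed = 3))
  expect_equal(sp$log$components$action[1], "split")
  expect_equal(nComponents(labelComponents(sp$pred)), n + 1L)
  # fragments are subsets of the parent, so they overlap it by construction
  expect_true(all(maskMatrix(sp$pred) <= maskMatrix(sc@gtMask)))
})

test_that("small boundary jitter preserves component count for thick cysts", {
  for (s in c(5L, 17L)) {
    sc <- generateScene(easySceneConfig(s))
    n <- nComponents(labelComponents(sc@gtMask))
    jt <- perturbMask(sc@gtMask, perturbConfig(boundaryJitter = 2L, seed = s))
    # easy-regime cysts have radius >= 4 px > 2*jitter and margin 6 px
    expect_equal(nComponents(labelComponents(jt$pred)), n)
  }
})

test_that("perturbation is deterministic under its seed", {
  sc <- generateScene(easySceneConfig(3L))
  cfg <- perturbConfig(dropRate = 0.3, spuriousRate = 2, splitRate = 0.4,
                       boundaryJitter = 1L, seed = 77)
  a <- perturbMask(sc@gtMask, cfg)
  b <- perturbMask(sc@gtMask, cfg)
  expect_identical(maskMatrix(a$pred), maskMatrix(b$pred))
  expect_identical(a$log, b$log)
})

test_that("written datasets flow back through the standard readers", {
  dir <- file.path(tempdir(), "cw-ds")
  unlink(dir, recursive = TRUE)
  cfg <- sceneConfig(width = 96L, height = 96L, nCysts = 2L,
                     areaRange = c(30, 200), micronsPerPixel = 1)
  cat <- generateDataset(dir, nTubules = 2L, imagesPerTubule = 2L,
                         config = cfg, seed = 5)
  expect_equal(nrow(cat), 4L)
  expect_error(generateDataset(dir, config = cfg), "not empty")

  back <- readCatalog(file.path(dir, "catalog.csv"))
  expect_equal(back$image_id, cat$image_id)
  for (i in seq_len(nrow(back))) {
    img <- readImageRGB(file.path(dir, back$image_path[i]))
    expect_equal(dim(img), c(96, 96, 3))
    msk <- readMask(file.path(dir, "masks", paste0(back$image_id[i], ".png")))
    ann <- readLabelme(file.path(dir, back$annotation_path[i]))
    rast <- rasterizeAnnotations(ann, 96, 96)
    expect_identical(maskMatrix(rast), maskMatrix(msk))
  }
  unlink(dir, recursive = TRUE)
})
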