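test_that("connected components respect connectivity and match the propagation oracle", {
  # two diagonal pixels: joined under 8-connectivity, split under 4
  diag2 <- matrix(FALSE, 4, 4); diag2[1, 1] <- TRUE; diag2[2, 2] <- TRUE
  expect_equal(nComponents(labelComponents(CystMask(diag2, 8L))), 1L)
  expect_equal(nComponents(labelComponents(CystMask(diag2, 4L))), 2L)

  # a plus sign is one component even under 4-connectivity
  plus <- matrix(FALSE, 5, 5); plus[3, 2:4] <- TRUE; plus[2:4, 3] <- TRUE
  expect_equal(nComponents(labelComponents(CystMask(plus, 4L))), 1L)

  # empty mask
  expect_equal(nComponents(labelComponents(CystMask(matrix(FALSE, 3, 3)))), 0L)

  set.seed(11)
  for (i in 1:20) {
    grid <- randomSpeckleMask(18, 15, stats::runif(1, 0.2, 0.6))
    for (conn in c(4L, 8L)) {
      got <- labelComponents(CystMask(grid, conn))
      ref <- oracleLabel(grid, conn)
      expect_equal(max(componentLabels(got), 0L), max(ref, 0L))
      # same partition (labels may be permuted): compare co-membership
      if (max(ref) > 0) {
        gv <- componentLabels(got)[grid]; rv <- ref[grid]
        expect_equal(as.integer(table(gv, rv) > 0) |> sum(), max(ref))
      }
      # areas sum to the true-pixel count
      expect_equal(sum(componentAreas(got)), sum(grid))
    }
  }
})

test_that("4-connected labeling agrees with EBImage::bwlabel component counts", {
  set.seed(5)
  for (i in 1:10) {
    grid <- randomBlobMask(40, 40, sample(1:5, 1))
    got <- nComponents(labelComponents(CystMask(grid, 4L)))
    ref <- max(EBImage::bwlabel(matrix(as.numeric(grid), nrow(grid))))
    expect_equal(got, ref)
  }
})

test_that("mask PNG round trip is exact", {
  set.seed(3)
  grid <- randomBlobMask(33, 47, 4)
  f <- withr::local_tempfile(fileext = ".png")
  writeMask(CystMask(grid), f)
  back <- readMask(f)
  expect_identical(maskMatrix(back), grid)
})

test_that("CystMask validates its grid and connectivity", {
  expect_error(CystMask(matrix(c(TRUE, NA), 1)), "NA")
  expect_error(CystMask(matrix(FALSE, 2, 2), connectivity = 6L), "4 or 8")
  # numeric 0/255 input is interpreted as a mask
  m <- CystMask(matrix(c(0, 255, 255, 0), 2, 2))
  expect_equal(nCystPixels(m), 2L)
})

test_that("Labelme parsing keeps polygons, rejects other shapes, flags bad JSON", {
  mkJson <- function(shapes) {
    f <- tempfile(fileext = ".json")
    jsonlite::write_json(list(version = "5.0.0", shapes = shapes,
                              imagePath = "img.png"),
                         f, auto_unbox = TRUE)
    f
  }
  expect_length(readLabelme(mkJson(list()))@polygons, 0L)

  tri <- list(list(label = "cyst",
                   points = list(c(1, 2), c(5, 2), c(3, 6)),
                   shape_type = "polygon"))
  ann <- readLabelme(mkJson(tri))
  expect_length(ann@polygons, 1L)
  expect_equal(nrow(ann@polygons[[1]]), 3L)
  expect_equal(ann@polygons[[1]][3, ], c(x = 3, y = 6))

  rect <- list(list(label = "cyst", points = list(c(1, 1), c(4, 4)),
                    shape_type = "rectangle"))
  expect_error(readLabelme(mkJson(rect)), "unsupported shape")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"not-shapes\": []}", bad)
  expect_error(readLabelme(bad), "shapes")
  writeLines("{broken", bad)
  expect_error(readLabelme(bad), "malformed")
})

test_that("Labelme writing round-trips polygons exactly", {
  polys <- list(cbind(x = c(2, 9, 9, 2), y = c(2, 2, 8, 8)),
                cbind(x = c(12.5, 17.25, 14), y = c(3, 5, 9.75)))
  ann <- AnnotationSet("img1", polys)
  f <- withr::local_tempfile(fileext = ".json")
  writeLabelme(ann, f, imageHeight = 20, imageWidth = 20)
  back <- readLabelme(f)
  expect_equal(length(back@polygons), 2L)
  for (i in 1:2)
    expect_equal(unname(back@polygons[[i]]), unname(polys[[i]]))
})

test_that("rasterization follows the pixel-center rule and matches a point-in-polygon oracle", {
  # axis-aligned square with corners (0,0)..(10,10): centers 0.5..9.5 inside
  sq <- AnnotationSet("sq", list(cbind(c(0, 0, 10, 10), c(0, 10, 10, 0))))
  m <- rasterizeAnnotations(sq, 20, 20)
  expect_equal(nCystPixels(m), 100L)
  expect_equal(nComponents(labelComponents(m)), 1L)

  # oracle: mgcv::in.out over all pixel centers, off-lattice polygons
  set.seed(21)
  for (i in 1:8) {
    n <- sample(3:7, 1)
    ang <- sort(stats::runif(n, 0, 2 * pi))
    cx <- stats::runif(1, 8, 16); cy <- stats::runif(1, 8, 16)
    r <- stats::runif(n, 3, 7)
    poly <- cbind(x = cx + r * cos(ang), y = cy + r * sin(ang))
    got <- maskMatrix(rasterizeAnnotations(AnnotationSet("p", list(poly)),
                                           24, 24))
    ctr <- expand.grid(row = seq_len(24), col = seq_len(24))
    inside <- mgcv::in.out(rbind(poly, poly[1, ]),
                           cbind(ctr$col - 0.5, ctr$row - 0.5))
    ref <- matrix(FALSE, 24, 24)
    ref[cbind(ctr$row, ctr$col)] <- inside
    expect_identical(got, ref)
  }

  # empty set and disjoint union
  expect_equal(nCystPixels(rasterizeAnnotations(AnnotationSet("e"), 10, 10)), 0L)
  two <- AnnotationSet("t", list(cbind(c(1, 1, 5, 5), c(1, 5, 5, 1)),
                                 cbind(c(10, 10, 14, 14), c(10, 14, 14, 10))))
  expect_equal(nComponents(labelComponents(rasterizeAnnotations(two, 20, 20))), 2L)

  # polygon fully outside contributes nothing, with a warning
  out <- AnnotationSet("o", list(cbind(c(30, 30, 35), c(30, 35, 30))))
  expect_warning(m2 <- rasterizeAnnotations(out, 20, 20), "outside")
  expect_equal(nCystPixels(m2), 0L)
})

test_that("rasterization is deterministic from file bytes", {
  sq <- AnnotationSet("sq", list(cbind(c(1.2, 1.2, 8.7, 8.7),
                                       c(1.4, 8.1, 8.1, 1.4))))
  f <- withr::local_tempfile(fileext = ".json")
  writeLabelme(sq, f)
  m1 <- rasterizeAnnotations(readLabelme(f), 12, 12)
  m2 <- rasterizeAnnotations(readLabelme(f), 12, 12)
  expect_identical(maskMatrix(m1), maskMatrix(m2))
})

test_that("catalog I/O validates structure and round-trips", {
  cat <- syntheticCatalog(nTubules = 6L, imagesPerTubule = 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  writeCatalog(cat, f)
  back <- readCatalog(f)
  expect_equal(back$image_id, cat$image_id)
  expect_equal(back$z_index, cat$z_index)
  expect_equal(length(unique(tubuleKeys(back))), 6L)

  dup <- rbind(cat, cat[1, ])
  expect_error(validateCatalog(dup), "duplicate image_id")
  expect_error(validateCatalog(cat[, -3]), "missing column")
})
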