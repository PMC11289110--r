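`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent oracles used to validate the implementation. These are
# deliberately naive (label propagation, shift-based min/max filters,
# exhaustive matching enumeration) and share no code with the package
# internals.

# connected-component count/labeling by iterative min-label propagation
oracleLabel <- function(grid, connectivity = 8L) {
  H <- nrow(grid); W <- ncol(grid)
  lab <- matrix(0L, H, W)
  lab[grid] <- seq_len(sum(grid))
  offs <- if (connectivity == 8L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  shift <- function(m, dr, dc, fill = Inf) {
    out <- matrix(fill, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  lab2 <- ifelse(grid, lab, Inf)
  repeat {
    nxt <- lab2
    for (o in offs) nxt <- pmin(nxt, shift(lab2, o[1], o[2]))
    nxt[!grid] <- Inf
    if (identical(nxt, lab2)) break
    lab2 <- nxt
  }
  ids <- sort(unique(lab2[is.finite(lab2)]))
  out <- matrix(0L, H, W)
  for (i in seq_along(ids)) out[lab2 == ids[i]] <- i
  out
}

# shift a logical matrix, padding with FALSE
.shiftLogical <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.oracleDiscOffsets <- function(k) {
  r <- (k - 1) / 2
  ri <- floor(r)
  offs <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  offs[offs$dr^2 + offs$dc^2 <= r^2, , drop = FALSE]
}

# sliding-window max (dilate) / min (erode) with a circular element,
# outside-of-image = background; composites run on a padded canvas
oracleMorph <- function(grid, op, k) {
  offs <- .oracleDiscOffsets(k)
  ri <- max(abs(offs$dr), 0)
  H <- nrow(grid); W <- ncol(grid)
  pad <- matrix(FALSE, H + 2 * ri, W + 2 * ri)
  pad[(ri + 1):(ri + H), (ri + 1):(ri + W)] <- grid
  dil <- function(m) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (i in seq_len(nrow(offs)))
      out <- out | .shiftLogical(m, offs$dr[i], offs$dc[i])
    out
  }
  ero <- function(m) {
    out <- matrix(TRUE, nrow(m), ncol(m))
    for (i in seq_len(nrow(offs)))
      out <- out & .shiftLogical(m, offs$dr[i], offs$dc[i])
    out
  }
  res <- switch(op,
                dilate = dil(pad), erode = ero(pad),
                open = dil(ero(pad)), close = ero(dil(pad)))
  res[(ri + 1):(ri + H), (ri + 1):(ri + W)]
}

# flood the background from the border (complement connectivity of an
# 8-connected foreground is 4); holes = unreached background
oracleFillHoles <- function(grid, bgConnectivity = 4L) {
  bg <- !grid
  reach <- matrix(FALSE, nrow(grid), ncol(grid))
  reach[1, ] <- bg[1, ]; reach[nrow(bg), ] <- bg[nrow(bg), ]
  reach[, 1] <- reach[, 1] | bg[, 1]
  reach[, ncol(bg)] <- reach[, ncol(bg)] | bg[, ncol(bg)]
  offs <- if (bgConnectivity == 4L)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
            c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    nxt <- reach
    for (o in offs) nxt <- nxt | (.shiftLogical(reach, o[1], o[2]) & bg)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  grid | (bg & !reach)
}

# exhaustive maximum one-to-one matching size over an overlap incidence
# matrix (predicted x ground truth), for small instances
oracleMaxMatching <- function(overlap) {
  nP <- nrow(overlap); nG <- ncol(overlap)
  if (nP == 0 || nG == 0) return(0L)
  best <- 0L
  recurse <- function(p, usedG, size) {
    if (size + (nP - p + 1) <= best) return()
    if (p > nP) { best <<- max(best, size); return() }
    recurse(p + 1, usedG, size)                    # leave pred p unmatched
    for (g in seq_len(nG)) {
      if (!usedG[g] && overlap[p, g]) {
        usedG[g] <- TRUE
        recurse(p + 1, usedG, size + 1L)
        usedG[g] <- FALSE
      }
    }
  }
  recurse(1L, logical(nG), 0L)
  best
}

# random blob mask: a few discs of random radius on an H x W grid
randomBlobMask <- function(H, W, nBlobs, rRange = c(2, 6)) {
  grid <- matrix(FALSE, H, W)
  for (i in seq_len(nBlobs)) {
    r <- stats::runif(1, rRange[1], rRange[2])
    cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
    rr <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    cc <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    blob <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2) <= r^2
    grid[rr, cc] <- grid[rr, cc] | blob
  }
  grid
}

# random speckle mask with given density
randomSpeckleMask <- function(H, W, density = 0.4) {
  matrix(stats::runif(H * W) < density, H, W)
}

# an instance whose overlap graph is a union of stars: each ground-truth
# disc gets 0..3 predicted fragments inside it (star centered on gt), and
# some predictions are isolated; returns the two masks
randomStarInstance <- function(H = 48L, W = 48L, nGt = NULL) {
  if (is.null(nGt)) nGt <- sample(0:4, 1)
  gt <- matrix(FALSE, H, W)
  pred <- matrix(FALSE, H, W)
  slots <- expand.grid(r = c(8, 24, 40), c = c(8, 24, 40))
  slots <- slots[sample(nrow(slots)), ]
  used <- 0
  for (i in seq_len(nGt)) {
    used <- used + 1
    if (used > nrow(slots)) break
    cy <- slots$r[used]; cx <- slots$c[used]
    rr <- (cy - 6):(cy + 6); cc <- (cx - 6):(cx + 6)
    disc <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2) <= 36
    gt[rr, cc] <- gt[rr, cc] | disc
    for (f in seq_len(sample(0:3, 1))) {
      fy <- cy + sample(-3:3, 1); fx <- cx + sample(-3:3, 1)
      fr <- (fy - 2):(fy + 2); fc <- (fx - 2):(fx + 2)
      fd <- outer(fr - fy, fc - fx, function(a, b) a^2 + b^2) <= 4
      pred[fr, fc] <- pred[fr, fc] | fd
    }
  }
  nIso <- sample(0:2, 1)
  for (i in seq_len(nIso)) {
    used <- used + 1
    if (used > nrow(slots)) break
    cy <- slots$r[used]; cx <- slots$c[used]
    rr <- (cy - 2):(cy + 2); cc <- (cx - 2):(cx + 2)
    disc <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2) <= 4
    pred[rr, cc] <- pred[rr, cc] | disc
  }
  list(pred = pred, gt = gt)
}

# the easy synthetic regime used for learning checks: 128 x 128 close-ups
# of the tubule wall (tissue fills the frame), 1 um/px, 3-4 well-separated
# mid-sized high-contrast lumens
easySceneConfig <- function(seed) {
  sceneConfig(width = 128L, height = 128L, nCysts = 3L + (seed %% 2L),
              areaMeanlog = log(300), areaSdlog = 0.4,
              areaRange = c(120, 500), micronsPerPixel = 1,
              bandFraction = 0.75, seed = seed)
}

easySceneSet <- function(seeds) {
  lapply(seeds, function(s) {
    sc <- generateScene(easySceneConfig(s))
    list(image = sc@image, mask = sc@gtMask)
  })
}
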