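# Internal 3D morphology on plain logical arrays, frontier-BFS based so
# cost scales with the region, not the volume. All operations accept a
# connectivity of 6, 18 or 26 neighbours (face / face+edge / full cube).
# Single-slice volumes fall out naturally: out-of-slice neighbours are out
# of bounds, so 26-connectivity degenerates to 8-connectivity in-plane.

.neighborOffsets <- function(connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  keep <- ord > 0 & ord <= switch(as.character(connectivity),
                                  "6" = 1L, "18" = 2L, "26" = 3L)
  unname(off[keep, , drop = FALSE])
}

# In-bounds neighbour linear indices of the voxels in `idx` (deduplicated).
.neighborsOf <- function(idx, d, off) {
  f <- length(idx)
  if (f == 0L) return(integer(0))
  k <- nrow(off)
  co <- arrayInd(idx, d)
  x <- rep(co[, 1], times = k) + rep(off[, 1], each = f)
  y <- rep(co[, 2], times = k) + rep(off[, 2], each = f)
  z <- rep(co[, 3], times = k) + rep(off[, 3], each = f)
  ok <- x >= 1L & x <= d[1] & y >= 1L & y <= d[2] & z >= 1L & z <= d[3]
  nb <- (z[ok] - 1L) * (d[1] * d[2]) + (y[ok] - 1L) * d[1] + x[ok]
  nb[!duplicated(nb)]
}

# Flood fill: all voxels of `mask` reachable from `seeds` (linear indices).
# Returns a logical array.
.floodFrom <- function(mask, seeds, connectivity = 26L) {
  d <- dim(mask)
  off <- .neighborOffsets(connectivity)
  reached <- array(FALSE, d)
  frontier <- seeds[mask[seeds] & !duplicated(seeds)]
  reached[frontier] <- TRUE
  while (length(frontier) > 0L) {
    nb <- .neighborsOf(frontier, d, off)
    nb <- nb[mask[nb] & !reached[nb]]
    reached[nb] <- TRUE
    frontier <- nb
  }
  reached
}

# Connected component of `mask` containing `seed` (1-based voxel coord).
.connectedComponent <- function(mask, seed, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(seed) == 3L, all(seed >= 1L), all(seed <= d))
  if (!mask[seed[1], seed[2], seed[3]])
    stop("seed voxel is not inside the mask")
  s <- (seed[3] - 1L) * (d[1] * d[2]) + (seed[2] - 1L) * d[1] + seed[1]
  .floodFrom(mask, as.integer(s), connectivity)
}

# Fill interior holes of `mask` up to `maxHoleSize` voxels. A hole is a
# connected component of the complement that does not touch the array
# border; complement connectivity is the complementary one (6 for 26).
# Works on the bounding box of the mask (+1 voxel), so cost scales with
# the region.
.fillHoles <- function(mask, maxHoleSize = Inf, connectivity = 26L) {
  if (maxHoleSize <= 0 || !any(mask)) return(mask)
  d <- dim(mask)
  co <- arrayInd(which(mask), d)
  lo <- pmax(apply(co, 2, min) - 1L, 1L)
  hi <- pmin(apply(co, 2, max) + 1L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  bgConn <- if (connectivity == 6L) 26L else 6L
  # singleton axes (e.g. a single slice) have no faces inside the grid:
  # a region enclosed in-plane is a hole in the 2D sense
  border <- array(FALSE, ds)
  if (ds[1] > 1L) border[c(1L, ds[1]), , ] <- TRUE
  if (ds[2] > 1L) border[, c(1L, ds[2]), ] <- TRUE
  if (ds[3] > 1L) border[, , c(1L, ds[3])] <- TRUE
  seeds <- which(border & !sub)
  outside <- if (length(seeds) > 0L) .floodFrom(!sub, seeds, bgConn)
             else array(FALSE, ds)
  holes <- !sub & !outside
  nHoles <- sum(holes)
  if (nHoles > 0) {
    if (nHoles <= maxHoleSize) {
      sub <- sub | holes             # each component is at most nHoles
    } else {
      remaining <- holes
      while (any(remaining)) {
        s <- arrayInd(which(remaining)[1L], ds)[1L, ]
        comp <- .connectedComponent(remaining, as.integer(s), bgConn)
        if (sum(comp) <= maxHoleSize) sub <- sub | comp
        remaining <- remaining & !comp
      }
    }
  }
  out <- mask
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  out
}
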