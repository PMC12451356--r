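# Internal geometry and hashing helpers.
#
# Coordinate convention (used everywhere): voxel indices are 1-based;
# the world coordinate of voxel centre (i,j,k) is origin + (c(i,j,k)-1) *
# spacing, in mm. Axes: +x = patient left, +y = posterior, +z = superior.
# Gantry angle 0 deg = beam travelling anterior -> posterior (+y); angles
# increase clockwise viewed from superior.

.axis_coords <- function(phantom) {
  g <- phantom@grid; sp <- phantom@spacing; o <- phantom@origin
  list(x = o[1] + (seq_len(g[1]) - 1) * sp[1],
       y = o[2] + (seq_len(g[2]) - 1) * sp[2],
       z = o[3] + (seq_len(g[3]) - 1) * sp[3])
}

# world coords (n x 3) of the TRUE voxels of a logical array
.mask_coords <- function(mask, phantom) {
  idx <- which(mask)
  ax <- .axis_coords(phantom)
  g <- phantom@grid
  i <- (idx - 1L) %% g[1] + 1L
  j <- ((idx - 1L) %/% g[1]) %% g[2] + 1L
  k <- (idx - 1L) %/% (g[1] * g[2]) + 1L
  cbind(ax$x[i], ax$y[j], ax$z[k])
}

# logical array: ellipsoid with centre (mm) and semi-axes (mm)
.ellipsoid_mask <- function(grid, spacing, origin, center, semi) {
  ax <- list(x = origin[1] + (seq_len(grid[1]) - 1) * spacing[1],
             y = origin[2] + (seq_len(grid[2]) - 1) * spacing[2],
             z = origin[3] + (seq_len(grid[3]) - 1) * spacing[3])
  dx2 <- ((ax$x - center[1]) / semi[1])^2
  dy2 <- ((ax$y - center[2]) / semi[2])^2
  dz2 <- ((ax$z - center[3]) / semi[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(q <= 1, dim = grid)
}

# vertical tube (axis parallel z) with elliptical cross-section
.tube_mask <- function(grid, spacing, origin, center_xy, radius_xy, z_range) {
  ax <- list(x = origin[1] + (seq_len(grid[1]) - 1) * spacing[1],
             y = origin[2] + (seq_len(grid[2]) - 1) * spacing[2],
             z = origin[3] + (seq_len(grid[3]) - 1) * spacing[3])
  dx2 <- ((ax$x - center_xy[1]) / radius_xy[1])^2
  dy2 <- ((ax$y - center_xy[2]) / radius_xy[2])^2
  inplane <- outer(dx2, dy2, "+") <= 1
  zin <- ax$z >= z_range[1] & ax$z <= z_range[2]
  arr <- array(FALSE, dim = grid)
  arr[, , zin] <- inplane
  arr
}

# tube along an arbitrary segment p0 -> p1 with radius r (mm)
.segment_tube_mask <- function(grid, spacing, origin, p0, p1, r) {
  ax <- list(x = origin[1] + (seq_len(grid[1]) - 1) * spacing[1],
             y = origin[2] + (seq_len(grid[2]) - 1) * spacing[2],
             z = origin[3] + (seq_len(grid[3]) - 1) * spacing[3])
  # bounding box, then exact distance-to-segment on candidates
  lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
  ii <- which(ax$x >= lo[1] & ax$x <= hi[1])
  jj <- which(ax$y >= lo[2] & ax$y <= hi[2])
  kk <- which(ax$z >= lo[3] & ax$z <= hi[3])
  arr <- array(FALSE, dim = grid)
  if (!length(ii) || !length(jj) || !length(kk)) return(arr)
  pts <- as.matrix(expand.grid(x = ax$x[ii], y = ax$y[jj], z = ax$z[kk]))
  d <- p1 - p0
  L2 <- sum(d^2)
  t <- if (L2 > 0) pmin(1, pmax(0, ((pts[, 1] - p0[1]) * d[1] +
                                    (pts[, 2] - p0[2]) * d[2] +
                                    (pts[, 3] - p0[3]) * d[3]) / L2)) else 0
  px <- p0[1] + t * d[1]; py <- p0[2] + t * d[2]; pz <- p0[3] + t * d[3]
  ok <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2 + (pts[, 3] - pz)^2 <= r^2
  sub <- array(ok, dim = c(length(ii), length(jj), length(kk)))
  arr[ii, jj, kk] <- sub
  arr
}

# binary dilation by a euclidean ball of radius r_mm (shift-and-OR).
# A radius below the largest voxel pitch still yields the 6-neighbour
# shell so that "surface" structures are non-empty on coarse grids.
.dilate_mask <- function(mask, spacing, r_mm) {
  r <- max(r_mm, max(spacing) * 1.0001)
  steps <- lapply(spacing, function(s) seq(-floor(r / s), floor(r / s)))
  offs <- as.matrix(expand.grid(steps[[1]], steps[[2]], steps[[3]]))
  keep <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
               (offs[, 3] * spacing[3])^2) <= r
  offs <- offs[keep, , drop = FALSE]
  g <- dim(mask)
  out <- array(FALSE, dim = g)
  for (q in seq_len(nrow(offs))) {
    o <- offs[q, ]
    sx <- seq(max(1, 1 - o[1]), min(g[1], g[1] - o[1]))
    sy <- seq(max(1, 1 - o[2]), min(g[2], g[2] - o[2]))
    sz <- seq(max(1, 1 - o[3]), min(g[3], g[3] - o[3]))
    out[sx + o[1], sy + o[2], sz + o[3]] <-
      out[sx + o[1], sy + o[2], sz + o[3]] | mask[sx, sy, sz]
  }
  out
}

# md5 of an R object via canonical serialization (version 2, no header refs)
.hash_obj <- function(x) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# linear voxel indices -> dose array
.grid_array <- function(values, idx, grid) {
  a <- array(0, dim = grid)
  a[idx] <- values
  a
}
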