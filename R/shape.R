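#' Shape features of a binary ROI
#'
#' Morphological descriptors of the ROI mask, computed on the original image
#' grid only:
#'
#' * `VoxelVolume` — voxel count times voxel volume (mm^3);
#' * `SurfaceArea` — area (mm^2) of an iso-surface mesh extracted by
#'   marching tetrahedra at level 0.5 from the mask after a 3x3x3 mean
#'   pre-filter (the smoothing places mesh vertices sub-voxel, which removes
#'   most of the staircase-area bias of a binary surface);
#' * `Sphericity` — \eqn{\pi^{1/3} (6V)^{2/3} / A}, 1 for a perfect ball;
#' * `Maximum3DDiameter` — largest pairwise distance between surface voxels
#'   (mm).
#'
#' @param mask 0/1 array.
#' @param spacing voxel spacing, mm.
#' @return Named numeric vector `VoxelVolume`, `SurfaceArea`, `Sphericity`,
#'   `Maximum3DDiameter`.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_volume_array(mask)
  vox <- which(mask > 0)
  if (!length(vox)) abort("mask is empty")
  vol <- length(vox) * prod(spacing)
  area <- mesh_surface_area(box_smooth3(mask), spacing)
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  c(VoxelVolume = vol, SurfaceArea = area, Sphericity = sph,
    Maximum3DDiameter = max_diameter(mask, spacing))
}

# 3x3x3 box mean filter with zero padding
box_smooth3 <- function(x) {
  n <- dim(x)
  p <- array(0, n + 2L)
  p[2:(n[1] + 1L), 2:(n[2] + 1L), 2:(n[3] + 1L)] <- x
  sm <- array(0, n)
  for (dx in 0:2) for (dy in 0:2) for (dz in 0:2) {
    sm <- sm + p[(1:n[1]) + dx, (1:n[2]) + dy, (1:n[3]) + dz]
  }
  sm / 27
}

# iso-surface area by marching tetrahedra (6 tetrahedra per cube, linear
# interpolation of the crossing point on each edge)
mesh_surface_area <- function(vol, spacing = c(1, 1, 1), level = 0.5) {
  d <- dim(vol)
  p <- array(0, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vol
  dp <- dim(p)
  nx <- dp[1] - 1L; ny <- dp[2] - 1L; nz <- dp[3] - 1L
  off <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0,
                  0, 0, 1, 1, 0, 1, 1, 1, 1, 0, 1, 1), ncol = 3, byrow = TRUE)
  idx <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny),
                               k = seq_len(nz)))
  V <- matrix(0, nrow(idx), 8)
  for (c in 1:8) {
    V[, c] <- p[cbind(idx[, 1] + off[c, 1], idx[, 2] + off[c, 2],
                      idx[, 3] + off[c, 3])]
  }
  s <- rowSums(V > level)
  keep <- s > 0 & s < 8
  idx <- idx[keep, , drop = FALSE]
  V <- V[keep, , drop = FALSE]
  if (!nrow(idx)) return(0)
  tets <- matrix(c(1, 6, 2, 7, 1, 2, 3, 7, 1, 3, 4, 7,
                   1, 4, 8, 7, 1, 8, 5, 7, 1, 5, 6, 7), ncol = 4, byrow = TRUE)
  tri_area <- function(P1, P2, P3) {
    u <- P2 - P1; v <- P3 - P1
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  total <- 0
  for (t in 1:6) {
    corners <- tets[t, ]
    tv <- V[, corners, drop = FALSE] > level
    code <- tv[, 1] + 2L * tv[, 2] + 4L * tv[, 3] + 8L * tv[, 4]
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (!length(sel)) next
      P <- lapply(1:4, function(c) {
        sweep(sweep(idx[sel, , drop = FALSE], 2, off[corners[c], ], "+"),
              2, spacing, "*")
      })
      Vv <- lapply(1:4, function(c) V[sel, corners[c]])
      cross_pt <- function(a, b) {
        tt <- (level - Vv[[a]]) / (Vv[[b]] - Vv[[a]])
        P[[a]] + tt * (P[[b]] - P[[a]])
      }
      inside <- which(bitwAnd(cs, c(1L, 2L, 4L, 8L)) > 0)
      ni <- length(inside)
      if (ni == 1L || ni == 3L) {
        odd <- if (ni == 1L) inside else setdiff(1:4, inside)
        oth <- setdiff(1:4, odd)
        total <- total + sum(tri_area(cross_pt(odd, oth[1]),
                                      cross_pt(odd, oth[2]),
                                      cross_pt(odd, oth[3])))
      } else {
        a <- inside[1]; b <- inside[2]; cd <- setdiff(1:4, inside)
        q1 <- cross_pt(a, cd[1]); q2 <- cross_pt(a, cd[2])
        q3 <- cross_pt(b, cd[2]); q4 <- cross_pt(b, cd[1])
        total <- total + sum(tri_area(q1, q2, q3)) + sum(tri_area(q1, q3, q4))
      }
    }
  }
  total
}

# maximum pairwise distance between boundary voxel centres
max_diameter <- function(mask, spacing) {
  d <- dim(mask)
  inside <- mask > 0
  # boundary: in-mask voxels with at least one face neighbour outside
  nb <- array(0, d)
  for (ax in 1:3) {
    for (sgn in c(1L, -1L)) {
      sh <- shift_array(inside + 0, sgn * as.integer(1:3 == ax))
      sh[is.na(sh)] <- 0
      nb <- nb + sh
    }
  }
  bdry <- which(inside & nb < 6)
  co <- arrayInd(bdry, d)
  co <- sweep(co, 2, spacing, "*")
  if (nrow(co) == 1L) return(0)
  # max distance via squared-norm expansion
  sq <- rowSums(co^2)
  G <- tcrossprod(co)
  d2 <- outer(sq, sq, "+") - 2 * G
  sqrt(max(d2))
}
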