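#' Texture feature matrices
#'
#' Implements the four texture families used by the prognostic models, per
#' the standard (IBSI-style) matrix definitions on a fixed-bin-width
#' quantised ROI:
#'
#' * **GLCM** ([glcm_features()]) — symmetric, normalised gray-level
#'   co-occurrence matrices at distance 1 over all 13 3-D direction classes
#'   (4 in-plane directions for single-slice input); per-direction features
#'   are averaged. `MCC` is \eqn{\sqrt{\lambda_2}} of the matrix
#'   \eqn{Q(i,j) = \sum_k p(i,k)p(j,k) / (p_x(i) p_y(k))}; a single-level
#'   ROI has `MCC = 1` by convention.
#' * **GLSZM** ([glszm_features()]) — zones are maximal 26-connected
#'   (8-connected for a single slice) components of equal gray level.
#' * **GLDM** ([gldm_features()]) — dependence of a voxel is 1 + the number
#'   of 26-neighbours (8 for a single slice) with identical level
#'   (\eqn{\alpha = 0}); neighbours outside the ROI do not count.
#' * **NGTDM** ([ngtdm_features()]) — \eqn{s_i} sums \eqn{|i - \bar A|} over
#'   voxels of level \eqn{i}, where \eqn{\bar A} is the mean level of the
#'   voxel's valid (in-ROI) neighbours; voxels with no valid neighbour are
#'   excluded.
#'
#' @param q a `quantized_roi` from [discretize()].
#' @return Named numeric vector of features for the family.
#' @name texture_features
NULL

# unique positive neighbour offsets: 13 in 3-D, 4 for a single slice
neighbor_offsets <- function(dims) {
  if (dims[3] == 1L) {
    matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 0, 1, -1, 0), ncol = 3, byrow = TRUE)
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
    keep <- g[, 1] > 0 |
      (g[, 1] == 0 & g[, 2] > 0) |
      (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
    unname(g[keep, , drop = FALSE])
  }
}

# shift a 3-D array by an offset, padding with NA
shift_array <- function(a, d) {
  dm <- dim(a)
  out <- array(NA, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- seq_len(dm[ax] + d[ax])
    }
    if (!length(src[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' @rdname texture_features
#' @export
glcm_features <- function(q) {
  lev <- q$levels
  ng <- q$ng
  offs <- neighbor_offsets(dim(lev))
  per_dir <- list()
  for (r in seq_len(nrow(offs))) {
    sh <- shift_array(lev, offs[r, ])
    keep <- !is.na(lev) & !is.na(sh)
    if (!any(keep)) next
    i <- lev[keep]; j <- sh[keep]
    # symmetric co-occurrence, counted in both pair orders
    counts <- matrix(
      tabulate(i + (j - 1L) * ng, nbins = ng * ng) +
        tabulate(j + (i - 1L) * ng, nbins = ng * ng),
      ng, ng)
    p <- counts / sum(counts)
    per_dir[[length(per_dir) + 1L]] <- glcm_stats(p)
  }
  if (!length(per_dir)) {
    return(c(MCC = 1, JointEnergy = 1, JointEntropy = 0, Contrast = 0,
             Correlation = 1, Idm = 1))
  }
  colMeans(do.call(rbind, per_dir))
}

glcm_stats <- function(p) {
  ng <- nrow(p)
  ii <- row(p); jj <- col(p)
  px <- rowSums(p)
  mu <- sum(ii * p)
  sig2 <- sum((ii - mu)^2 * p)
  corr <- if (sig2 > 1e-12) (sum(ii * jj * p) - mu^2) / sig2 else 1
  pos <- p > 0
  c(
    MCC = glcm_mcc(p),
    JointEnergy = sum(p^2),
    JointEntropy = -sum(p[pos] * log2(p[pos])),
    Contrast = sum((ii - jj)^2 * p),
    Correlation = corr,
    Idm = sum(p / (1 + (ii - jj)^2))
  )
}

glcm_mcc <- function(p) {
  px <- rowSums(p)
  present <- which(px > 0)
  if (length(present) <= 1L) return(1)
  pp <- p[present, present, drop = FALSE]
  px <- rowSums(pp)
  # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) px(k));  symmetric p => py = px
  A <- sweep(pp, 2, px, "/")      # p(i,k)/px(k)
  Q <- sweep(pp %*% t(A), 1, px, "/")
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(ev[2], 0))
}

#' @rdname texture_features
#' @export
glszm_features <- function(q) {
  lev <- q$levels
  vox <- which(!is.na(lev))
  nv <- length(vox)
  vid <- array(NA_integer_, dim(lev))
  vid[vox] <- seq_len(nv)
  offs <- neighbor_offsets(dim(lev))
  efrom <- eto <- list()
  for (r in seq_len(nrow(offs))) {
    sh_lev <- shift_array(lev, offs[r, ])
    sh_vid <- shift_array(vid, offs[r, ])
    keep <- !is.na(lev) & !is.na(sh_lev) & lev == sh_lev
    if (!any(keep)) next
    efrom[[length(efrom) + 1L]] <- vid[keep]
    eto[[length(eto) + 1L]] <- sh_vid[keep]
  }
  if (length(efrom)) {
    g <- igraph::graph_from_edgelist(
      cbind(unlist(efrom), unlist(eto)), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_len(nv)
  }
  zone_level <- tapply(lev[vox], comp, function(x) x[1])
  zone_size <- tabulate(comp)
  zone_size <- zone_size[zone_size > 0]
  nz <- length(zone_size)
  i <- as.numeric(zone_level)
  j <- as.numeric(zone_size)
  gl_counts <- tapply(rep(1, nz), i, sum)
  sz_counts <- tapply(rep(1, nz), j, sum)
  c(
    LAHGLE = sum(i^2 * j^2) / nz,
    GLNN = sum(gl_counts^2) / nz^2,
    SZNN = sum(sz_counts^2) / nz^2,
    SmallAreaEmphasis = sum(1 / j^2) / nz,
    LargeAreaEmphasis = sum(j^2) / nz,
    ZonePercentage = nz / nv
  )
}

#' @rdname texture_features
#' @export
gldm_features <- function(q) {
  lev <- q$levels
  vox <- which(!is.na(lev))
  nv <- length(vox)
  offs <- neighbor_offsets(dim(lev))
  eq <- array(0L, dim(lev))
  for (r in seq_len(nrow(offs))) {
    for (sgn in c(1, -1)) {
      sh <- shift_array(lev, sgn * offs[r, ])
      eq <- eq + (!is.na(lev) & !is.na(sh) & lev == sh)
    }
  }
  dep <- eq[vox] + 1L
  i <- as.numeric(lev[vox])
  j <- as.numeric(dep)
  pj <- tapply(rep(1, nv), j, sum) / nv
  c(
    LDHGLE = sum(i^2 * j^2) / nv,
    LargeDependenceEmphasis = sum(j^2) / nv,
    SmallDependenceEmphasis = sum(1 / j^2) / nv,
    DependenceEntropy = -sum(pj * log2(pj))
  )
}

#' @rdname texture_features
#' @export
ngtdm_features <- function(q) {
  lev <- q$levels
  dm <- dim(lev)
  offs <- neighbor_offsets(dm)
  val <- lev; val[is.na(val)] <- 0
  inroi <- !is.na(lev)
  nsum <- array(0, dm)
  ncnt <- array(0, dm)
  for (r in seq_len(nrow(offs))) {
    for (sgn in c(1, -1)) {
      shv <- shift_array(val, sgn * offs[r, ])
      shm <- shift_array(inroi + 0, sgn * offs[r, ])
      shv[is.na(shv)] <- 0
      shm[is.na(shm)] <- 0
      nsum <- nsum + shv * shm
      ncnt <- ncnt + shm
    }
  }
  use <- inroi & ncnt > 0
  ii <- lev[use]
  abar <- nsum[use] / ncnt[use]
  nvt <- length(ii)
  ng <- q$ng
  n_i <- tabulate(ii, nbins = ng)
  s_i <- vapply(seq_len(ng), function(g) sum(abs(g - abar)[ii == g]), 0)
  p_i <- n_i / nvt
  present <- which(p_i > 0)
  ngp <- length(present)
  coars_den <- sum(p_i * s_i)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  if (ngp > 1) {
    pr <- expand.grid(a = present, b = present)
    pa <- p_i[pr$a]; pb <- p_i[pr$b]
    contrast <- sum(pa * pb * (pr$a - pr$b)^2) / (ngp * (ngp - 1)) *
      sum(s_i) / nvt
    bus_den <- sum(abs(pr$a * pa - pr$b * pb))
    busyness <- if (bus_den > 0) coars_den / bus_den else 0
    complexity <- sum(abs(pr$a - pr$b) *
                        (pa * s_i[pr$a] + pb * s_i[pr$b]) / (pa + pb)) / nvt
    str_den <- sum(s_i)
    strength <- if (str_den > 0) sum((pa + pb) * (pr$a - pr$b)^2) / str_den
                else 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
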