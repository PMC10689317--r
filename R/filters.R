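#' Derived-image filters for radiomics
#'
#' Applies one of the image filters from which first-order and texture
#' features are extracted in addition to the original image:
#'
#' * `"squareroot"` — elementwise \eqn{\sqrt{|x|}} (positive sign
#'   convention);
#' * `"lbp"` — slice-wise 2-D local binary pattern codes (radius 1,
#'   8 samples, uniform patterns: code = number of set bits for uniform
#'   patterns, 9 otherwise);
#' * `"wavelet-LLL"` … `"wavelet-HHH"` — one of the 8 sub-bands of a
#'   one-level 3-D stationary (undecimated) wavelet decomposition with the
#'   coiflet-1 kernel. The letter order is (x, y, z): the first letter is the
#'   filter applied along the first array dimension. The filter bank is
#'   normalised so that the 8 sub-band energies sum to the input energy.
#'
#' `wavelet_subbands()` computes all 8 sub-bands in one pass, which
#' [extract_features()] uses to avoid repeated convolutions.
#'
#' @param volume `image_volume` or 3-D array.
#' @param filter_name one of `"squareroot"`, `"lbp"`,
#'   `"wavelet-LLL"` … `"wavelet-HHH"`.
#' @return `apply_filter()`: a 3-D array (the filtered image);
#'   `wavelet_subbands()`: a named list of 8 arrays `LLL` … `HHH`.
#' @export
apply_filter <- function(volume, filter_name) {
  arr <- as_volume_array(volume)
  if (length(dim(arr)) != 3L) abort("volume must be 3-D")
  if (filter_name == "squareroot") return(sqrt(abs(arr)))
  if (filter_name == "lbp") return(lbp_slices(arr))
  if (grepl("^wavelet-[LH]{3}$", filter_name)) {
    band <- sub("^wavelet-", "", filter_name)
    return(wavelet_subbands(arr)[[band]])
  }
  abort(sprintf("unknown filter '%s'", filter_name))
}

# coiflet-1 analysis filters, scaled by 1/sqrt(2) so that the one-level
# undecimated bank conserves energy exactly (|H|^2 + |G|^2 = 1)
coif1_filters <- function() {
  h <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
         0.852572020212255, 0.337897662457809, -0.072732619512854)
  g <- rev(h) * c(1, -1, 1, -1, 1, -1) # QMF: g[k] = (-1)^k h[L-1-k]
  list(lo = h / sqrt(2), hi = g / sqrt(2))
}

# circular convolution along one axis with an arbitrary (uncentred) kernel
conv_axis_periodic <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, d)
  for (j in seq_along(kernel)) {
    sh <- j - 1L
    idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
    out <- out + kernel[j] * switch(axis,
      arr[idx, , , drop = FALSE],
      arr[, idx, , drop = FALSE],
      arr[, , idx, drop = FALSE]
    )
  }
  out
}

#' @rdname apply_filter
#' @export
wavelet_subbands <- function(volume) {
  arr <- as_volume_array(volume)
  f <- coif1_filters()
  ax1 <- list(L = conv_axis_periodic(arr, f$lo, 1L),
              H = conv_axis_periodic(arr, f$hi, 1L))
  out <- list()
  for (b1 in c("L", "H")) {
    ax2 <- list(L = conv_axis_periodic(ax1[[b1]], f$lo, 2L),
                H = conv_axis_periodic(ax1[[b1]], f$hi, 2L))
    for (b2 in c("L", "H")) {
      for (b3 in c("L", "H")) {
        out[[paste0(b1, b2, b3)]] <-
          conv_axis_periodic(ax2[[b2]], switch(b3, L = f$lo, H = f$hi), 3L)
      }
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

# slice-wise uniform LBP, radius 1, 8 samples on the circle (bilinear
# interpolation at the diagonal sample points, replicate padding at borders)
lbp_slices <- function(arr) {
  d <- dim(arr)
  out <- array(0, d)
  angles <- 2 * pi * (0:7) / 8
  dx <- cos(angles)
  dy <- sin(angles)
  for (k in seq_len(d[3])) {
    out[, , k] <- lbp_slice(arr[, , k, drop = TRUE], dx, dy)
  }
  out
}

lbp_slice <- function(sl, dx, dy) {
  nx <- nrow(sl); ny <- ncol(sl)
  # replicate-pad by 1 pixel
  p <- matrix(0, nx + 2L, ny + 2L)
  p[2:(nx + 1L), 2:(ny + 1L)] <- sl
  p[1, ] <- p[2, ]; p[nx + 2L, ] <- p[nx + 1L, ]
  p[, 1] <- p[, 2]; p[, ny + 2L] <- p[, ny + 1L]
  cx <- matrix(seq_len(nx) + 1L, nx, ny)
  cy <- matrix(rep(seq_len(ny) + 1L, each = nx), nx, ny)
  bits <- vector("list", 8)
  for (s in 1:8) {
    sx <- cx + dx[s]
    sy <- cy + dy[s]
    x0 <- pmin(pmax(floor(sx), 1), nx + 1L)
    y0 <- pmin(pmax(floor(sy), 1), ny + 1L)
    fx <- sx - x0; fy <- sy - y0
    v <- (1 - fx) * (1 - fy) * p[cbind(as.vector(x0), as.vector(y0))] +
      fx * (1 - fy) * p[cbind(as.vector(x0 + 1), as.vector(y0))] +
      (1 - fx) * fy * p[cbind(as.vector(x0), as.vector(y0 + 1))] +
      fx * fy * p[cbind(as.vector(x0 + 1), as.vector(y0 + 1))]
    bits[[s]] <- matrix(as.numeric(v >= sl - 1e-12), nx, ny)
  }
  nset <- Reduce(`+`, bits)
  trans <- matrix(0, nx, ny)
  for (s in 1:8) {
    nxt <- if (s == 8) 1 else s + 1
    trans <- trans + abs(bits[[s]] - bits[[nxt]])
  }
  ifelse(trans <= 2, nset, 9)
}
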