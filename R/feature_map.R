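#' High-resolution sliding-window radiomics feature map
#'
#' Computes a named radiomic feature pixel-by-pixel: for every in-ROI pixel
#' visited at the given step, the `window` x `window` in-plane patch centred
#' there is clipped at the image borders, restricted to patch-and-ROI
#' voxels, and the feature is evaluated on that restricted set (first-order
#' directly on the intensities; texture features after per-patch fixed-bin
#' discretisation with the origin at the patch minimum, so each patch is
#' self-contained). The value is assigned to the centre pixel. Patches whose
#' in-ROI fraction falls below `min_roi_fraction`, or with fewer than 2
#' voxels, are left undefined.
#'
#' A large window makes the per-patch statistics accurate while `step = 1`
#' keeps the map at full image resolution; the window should not exceed the
#' smallest in-plane ROI bounding-box edge (a warning is issued, not an
#' error).
#'
#' @param volume `image_volume` or 3-D array.
#' @param mask 0/1 ROI array on the same grid.
#' @param feature feature name `<family>_<feature>`, e.g.
#'   `"firstorder_Variance"` or `"glszm_LAHGLE"` (families as in
#'   [texture_features]).
#' @param window odd patch edge length in pixels (>= 3), default 21.
#' @param step pixel stride between evaluated centres (default 1).
#' @param min_roi_fraction minimum in-ROI fraction of the (clipped) patch.
#' @param bin_width discretisation bin width for texture features.
#' @param global_origin discretise patches against the global in-ROI minimum
#'   instead of each patch's own minimum.
#' @param slices slice indices to map (default: all slices with ROI pixels).
#' @return A `feature_map`: `values` (3-D array aligned to the source, `NA`
#'   where undefined), `feature`, and the configuration echo.
#' @export
compute_feature_map <- function(volume, mask, feature = "firstorder_Variance",
                                window = 21, step = 1,
                                min_roi_fraction = 0.25, bin_width = 5,
                                global_origin = FALSE, slices = NULL) {
  arr <- as_volume_array(volume)
  if (!all(dim(arr) == dim(mask))) abort("mask grid does not match the volume")
  if (window < 3 || window %% 2 == 0) abort("`window` must be odd and >= 3")
  if (step < 1) abort("`step` must be >= 1")
  d <- dim(arr)
  half <- (window - 1L) %/% 2L
  eval_fun <- resolve_map_feature(feature)
  origin <- if (global_origin) min(arr[mask > 0]) else NULL

  roi_slices <- which(apply(mask, 3, function(m) any(m > 0)))
  if (is.null(slices)) slices <- roi_slices else slices <- intersect(slices, seq_len(d[3]))
  # warn when the window exceeds the smallest in-plane ROI bounding edge
  bb <- vapply(roi_slices, function(k) {
    m <- mask[, , k] > 0
    min(diff(range(which(rowSums(m) > 0))), diff(range(which(colSums(m) > 0)))) + 1L
  }, 0L)
  if (length(bb) && window > min(bb)) {
    warn(sprintf("window (%d) exceeds the smallest in-plane ROI bounding edge (%d)",
                 window, min(bb)))
  }

  values <- array(NA_real_, d)
  for (k in slices) {
    sl <- arr[, , k]
    mk <- mask[, , k] > 0
    if (!any(mk)) next
    centers <- which(mk, arr.ind = TRUE)
    keep <- (centers[, 1] - 1L) %% step == 0 & (centers[, 2] - 1L) %% step == 0
    centers <- centers[keep, , drop = FALSE]
    for (r in seq_len(nrow(centers))) {
      ci <- centers[r, 1]; cj <- centers[r, 2]
      i0 <- max(1L, ci - half); i1 <- min(d[1], ci + half)
      j0 <- max(1L, cj - half); j1 <- min(d[2], cj + half)
      pm <- mk[i0:i1, j0:j1]
      n_in <- sum(pm)
      if (n_in < 2L || n_in / length(pm) < min_roi_fraction) next
      pv <- sl[i0:i1, j0:j1]
      values[ci, cj, k] <- eval_fun(pv, pm, bin_width, origin)
    }
  }
  structure(list(values = values, feature = feature,
                 config = list(window = window, step = step,
                               min_roi_fraction = min_roi_fraction,
                               bin_width = bin_width,
                               global_origin = global_origin)),
            class = "feature_map")
}

# returns function(patch_values_matrix, patch_mask_matrix, bin_width, origin)
resolve_map_feature <- function(feature) {
  parts <- strsplit(feature, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    abort("`feature` must be of the form <family>_<name>, e.g. firstorder_Variance")
  }
  family <- parts[1]; name <- parts[2]
  if (family == "firstorder") {
    return(function(pv, pm, bw, origin) {
      fv <- first_order_features(pv[pm], bin_width = bw)
      if (!name %in% names(fv)) abort(sprintf("unknown first-order feature '%s'", name))
      unname(fv[name])
    })
  }
  fam_fun <- switch(family,
    glcm = glcm_features, glszm = glszm_features,
    gldm = gldm_features, ngtdm = ngtdm_features,
    abort(sprintf("unknown feature family '%s'", family))
  )
  function(pv, pm, bw, origin) {
    a <- array(pv, c(dim(pv), 1L))
    m <- array(pm + 0, c(dim(pm), 1L))
    q <- discretize(a, m, bin_width = bw, origin = origin)
    fv <- fam_fun(q)
    if (!name %in% names(fv)) abort(sprintf("unknown %s feature '%s'", family, name))
    unname(fv[name])
  }
}

#' @export
print.feature_map <- function(x, ...) {
  nd <- sum(!is.na(x$values))
  cat(sprintf("<feature_map> %s: %d defined pixels, window %d, step %d\n",
              x$feature, nd, x$config$window, x$config$step))
  invisible(x)
}

#' Render a feature map over its source image
#'
#' Produces a deterministic RGB rendering of one slice: grayscale background
#' from the source image with colour-mapped feature values inside the
#' defined mask (viridis ramp). Optionally written as PNG (via
#' [png::writePNG()], no graphics device required) and as NIfTI of the raw
#' map values (`NaN` outside the defined mask).
#'
#' @param map a `feature_map`.
#' @param volume the source `image_volume` (grids must match).
#' @param slice slice index (default: defined slice with most map pixels).
#' @param range colour-scale limits; defaults to the min/max of the defined
#'   map values.
#' @param path_png,path_nifti optional output paths.
#' @return Invisibly, a list with the RGB array (`height x width x 3`), the
#'   slice index and the colour range used.
#' @export
overlay_map <- function(map, volume, slice = NULL, range = NULL,
                        path_png = NULL, path_nifti = NULL) {
  arr <- as_volume_array(volume)
  if (!all(dim(arr) == dim(map$values))) abort("map and volume grids are misaligned")
  counts <- apply(!is.na(map$values), 3, sum)
  if (is.null(slice)) slice <- which.max(counts)
  vals <- map$values[, , slice]
  defined <- !is.na(vals)
  rng <- range %||% (if (any(defined)) base::range(vals[defined]) else c(0, 1))
  bg <- arr[, , slice]
  bgn <- (bg - min(bg)) / max(max(bg) - min(bg), 1e-12)
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis")) / 255)
  rgb <- array(0, c(dim(bg), 3L))
  for (c in 1:3) rgb[, , c] <- bgn
  if (any(defined)) {
    span <- max(rng[2] - rng[1], 1e-12)
    idx <- pmin(pmax(floor((vals[defined] - rng[1]) / span * 255) + 1L, 1L), 256L)
    for (c in 1:3) {
      ch <- rgb[, , c]
      ch[defined] <- pal[idx, c]
      rgb[, , c] <- ch
    }
  }
  # image row 1 at the top of the rendering
  rendered <- aperm(rgb[, rev(seq_len(ncol(bg))), , drop = FALSE], c(2, 1, 3))
  if (!is.null(path_png)) png::writePNG(rendered, path_png)
  if (!is.null(path_nifti)) {
    raw <- map$values
    raw[is.na(raw)] <- NaN
    write_volume(image_volume(raw, if (inherits(volume, "image_volume"))
      volume$spacing else c(1, 1, 1)), path_nifti)
  }
  invisible(list(rgb = rendered, slice = slice, range = rng))
}

#' @describeIn compute_feature_map ggplot rendering of one slice of the map.
#' @param object a `feature_map`.
#' @param ... unused.
#' @export
autoplot.feature_map <- function(object, slice = NULL, ...) {
  counts <- apply(!is.na(object$values), 3, sum)
  if (is.null(slice)) slice <- which.max(counts)
  vals <- object$values[, , slice]
  df <- tidyr::expand_grid(x = seq_len(nrow(vals)), y = seq_len(ncol(vals)))
  df$value <- vals[cbind(df$x, df$y)]
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$value)),
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$feature) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s (window %d, step %d), slice %d",
                      object$feature, object$config$window,
                      object$config$step, slice),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
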