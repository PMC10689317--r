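#' Feature extraction configuration
#'
#' @param bin_width gray-level discretisation bin width (intensity units),
#'   applied to the original and every filtered image alike (can be set per
#'   call if a filtered image needs its own width).
#' @param filters character vector of derived images to add to the original:
#'   any of `"squareroot"`, `"lbp"`, `"wavelet"` (all 8 sub-bands).
#' @param families texture/first-order families to compute: subset of
#'   `"firstorder"`, `"glcm"`, `"glszm"`, `"gldm"`, `"ngtdm"`.
#' @param shape include shape features (original mask only).
#' @return A `feature_config` list.
#' @export
feature_config <- function(bin_width = 5,
                           filters = c("squareroot", "lbp", "wavelet"),
                           families = c("firstorder", "glcm", "glszm",
                                        "gldm", "ngtdm"),
                           shape = TRUE) {
  bad <- setdiff(filters, c("squareroot", "lbp", "wavelet"))
  if (length(bad)) abort(sprintf("unknown filter(s): %s",
                                 paste(bad, collapse = ", ")))
  bad <- setdiff(families, c("firstorder", "glcm", "glszm", "gldm", "ngtdm"))
  if (length(bad)) abort(sprintf("unknown family(ies): %s",
                                 paste(bad, collapse = ", ")))
  structure(list(bin_width = bin_width, filters = filters,
                 families = families, shape = shape),
            class = "feature_config")
}

# intensity (first-order + texture) features of one image under one mask
intensity_features <- function(arr, mask, config) {
  out <- numeric(0)
  vals <- arr[mask > 0]
  if ("firstorder" %in% config$families) {
    fo <- first_order_features(vals, bin_width = config$bin_width)
    out <- c(out, setNames(fo, paste0("firstorder_", names(fo))))
  }
  tex_fams <- intersect(config$families, c("glcm", "glszm", "gldm", "ngtdm"))
  if (length(tex_fams)) {
    q <- discretize(arr, mask, bin_width = config$bin_width)
    for (fam in tex_fams) {
      fv <- switch(fam,
        glcm = glcm_features(q),
        glszm = glszm_features(q),
        gldm = gldm_features(q),
        ngtdm = ngtdm_features(q)
      )
      out <- c(out, setNames(fv, paste0(fam, "_", names(fv))))
    }
  }
  out
}

#' Extract the full radiomic feature vector of one image
#'
#' Computes shape features (original mask only) plus first-order and texture
#' features on the original image and each configured derived image. Feature
#' names follow the `<filter>_<family>_<feature>` convention, e.g.
#' `wavelet-LHL_glszm_LAHGLE` or `lbp_firstorder_Variance`.
#'
#' @param volume `image_volume` or 3-D array.
#' @param mask 0/1 array on the same grid.
#' @param config a [feature_config()].
#' @param spacing voxel spacing (mm); taken from `volume` when it is an
#'   `image_volume`.
#' @return A one-row tibble, one column per feature, all values finite.
#' @export
extract_features <- function(volume, mask, config = feature_config(),
                             spacing = NULL) {
  arr <- as_volume_array(volume)
  if (is.null(spacing)) {
    spacing <- if (inherits(volume, "image_volume")) volume$spacing else c(1, 1, 1)
  }
  if (!all(dim(arr) == dim(mask))) abort("mask grid does not match the volume")
  images <- list(original = arr)
  if ("squareroot" %in% config$filters) {
    images$squareroot <- apply_filter(arr, "squareroot")
  }
  if ("lbp" %in% config$filters) {
    images$lbp <- apply_filter(arr, "lbp")
  }
  if ("wavelet" %in% config$filters) {
    wb <- wavelet_subbands(arr)
    names(wb) <- paste0("wavelet-", names(wb))
    images <- c(images, wb)
  }
  out <- numeric(0)
  if (isTRUE(config$shape)) {
    sf <- shape_features(mask, spacing)
    out <- c(out, setNames(sf, paste0("original_shape_", names(sf))))
  }
  for (nm in names(images)) {
    fv <- intensity_features(images[[nm]], mask, config)
    out <- c(out, setNames(fv, paste0(nm, "_", names(fv))))
  }
  if (anyDuplicated(names(out))) abort("internal error: feature name collision")
  if (any(!is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    abort(sprintf("non-finite feature value(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  as_tibble(as.list(out))
}

#' Extract features for every subject of a cohort
#'
#' Runs [extract_features()] on each subject's named volumes and binds the
#' results into a subjects-by-features tibble keyed by `id`. With more than
#' one image per subject, feature names are prefixed by the image name
#' (`PDw_wavelet-LHL_glszm_LAHGLE`); identical volumes under different names
#' therefore yield identical per-feature values.
#'
#' @param cohort a `radiomics_cohort` (or any list with `subjects`).
#' @param config a [feature_config()].
#' @param volumes_fun function mapping a subject record to its named list of
#'   `image_volume`s (default: the MR volumes in `subject$volumes`).
#' @return Tibble with `id` plus one column per feature.
#' @export
extract_cohort_features <- function(cohort, config = feature_config(),
                                    volumes_fun = function(s) s$volumes) {
  rows <- purrr::map(cohort$subjects, function(s) {
    vols <- volumes_fun(s)
    multi <- length(vols) > 1L
    feats <- purrr::imap(vols, function(v, nm) {
      cfg <- config
      # shape depends on the mask only: compute it once per subject
      if (multi && nm != names(vols)[1]) cfg$shape <- FALSE
      ft <- extract_features(v, s$roi, cfg, spacing = s$spacing)
      if (multi) names(ft) <- paste0(nm, "_", names(ft))
      ft
    })
    dplyr::bind_cols(tibble(id = s$id), feats)
  })
  dplyr::bind_rows(rows)
}
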