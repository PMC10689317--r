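test_that("variance map of a constant image is identically zero", {
  vol <- array(10, c(20, 20, 1))
  mask <- array(0L, c(20, 20, 1))
  mask[5:16, 5:16, 1] <- 1L
  map <- compute_feature_map(vol, mask, "firstorder_Variance",
                             window = 5, min_roi_fraction = 0)
  vals <- map$values[!is.na(map$values)]
  expect_gt(length(vals), 0)
  expect_true(all(vals == 0))
})

test_that("non-overlapping tiling equals direct per-tile extraction", {
  set.seed(9)
  w <- 5
  vol <- array(rnorm(30 * 30, 50, 12), c(30, 30, 1))
  mask <- array(1L, c(30, 30, 1))
  map <- compute_feature_map(vol, mask, "glszm_LAHGLE", window = w, step = w,
                             min_roi_fraction = 0)
  centers <- which(!is.na(map$values), arr.ind = TRUE)
  expect_gt(nrow(centers), 4)
  half <- (w - 1) / 2
  for (r in seq_len(nrow(centers))) {
    ci <- centers[r, 1]; cj <- centers[r, 2]
    i0 <- max(1, ci - half); i1 <- min(30, ci + half)
    j0 <- max(1, cj - half); j1 <- min(30, cj + half)
    patch <- array(vol[i0:i1, j0:j1, 1], c(i1 - i0 + 1, j1 - j0 + 1, 1))
    pmask <- array(1L, dim(patch))
    direct <- glszm_features(discretize(patch, pmask, 5))["LAHGLE"]
    expect_equal(map$values[ci, cj, 1], unname(direct))
  }
})

test_that("map values equal direct patch computation at random pixels", {
  set.seed(10)
  vol <- array(rnorm(26 * 26, 100, 20), c(26, 26, 1))
  mask <- array(0L, c(26, 26, 1))
  mask[4:23, 4:23, 1] <- 1L
  w <- 7; half <- 3
  map <- compute_feature_map(vol, mask, "firstorder_Variance", window = w,
                             step = 1, min_roi_fraction = 0)
  defined <- which(!is.na(map$values), arr.ind = TRUE)
  pick <- defined[sample(nrow(defined), 100), , drop = FALSE]
  for (r in seq_len(nrow(pick))) {
    ci <- pick[r, 1]; cj <- pick[r, 2]
    i0 <- max(1, ci - half); i1 <- min(26, ci + half)
    j0 <- max(1, cj - half); j1 <- min(26, cj + half)
    sel <- vol[i0:i1, j0:j1, 1][mask[i0:i1, j0:j1, 1] > 0]
    expect_equal(map$values[ci, cj, 1], mean((sel - mean(sel))^2))
  }
})

core_rim_phantom <- function(seed) {
  set.seed(seed)
  d <- c(28, 28, 1)
  vol <- array(rnorm(prod(d), 50, 1), d) # low-variance everywhere
  mask <- array(0L, d)
  mask[5:24, 5:24, 1] <- 1L
  core <- array(FALSE, d)
  core[11:18, 11:18, 1] <- TRUE
  rim <- mask > 0 & !core
  vol[rim] <- rnorm(sum(rim), 50, 10) # high-variance rim
  list(vol = vol, mask = mask, core = core, rim = rim)
}

test_that("variance map separates a high-variance rim from a quiet core", {
  wins <- vapply(1:10, function(seed) {
    p <- core_rim_phantom(seed)
    map <- compute_feature_map(p$vol, p$mask, "firstorder_Variance",
                               window = 5, min_roi_fraction = 0)
    mean(map$values[p$rim & !is.na(map$values)]) >
      mean(map$values[p$core & !is.na(map$values)])
  }, TRUE)
  expect_true(all(wins))
})

test_that("smaller windows track region boundaries more sharply", {
  # deterministic two-region phantom: flat left half, alternating +/-10
  # right half; the variance map must step up across the boundary within a
  # transition zone whose width grows with the window
  d <- c(40, 21, 1)
  vol <- array(0, d)
  for (i in 21:40) vol[i, , 1] <- ifelse((i + seq_len(21)) %% 2 == 0, 10, -10)
  mask <- array(1L, d)
  trans_width <- function(w) {
    map <- compute_feature_map(vol, mask, "firstorder_Variance",
                               window = w, min_roi_fraction = 0)
    prof <- map$values[, 11, 1]
    hi <- max(prof)
    sum(prof > 0.05 * hi & prof < 0.95 * hi)
  }
  widths <- vapply(c(5, 9, 13), trans_width, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("window larger than the ROI bounding box warns but still runs", {
  vol <- array(rnorm(100), c(10, 10, 1))
  mask <- array(0L, c(10, 10, 1))
  mask[4:7, 4:7, 1] <- 1L
  expect_warning(
    map <- compute_feature_map(vol, mask, "firstorder_Variance",
                               window = 9, min_roi_fraction = 0),
    "bounding edge")
  expect_gt(sum(!is.na(map$values)), 0)
})

test_that("overlay rendering is deterministic with NaN outside the mask", {
  p <- core_rim_phantom(3)
  map <- compute_feature_map(p$vol, p$mask, "firstorder_Variance",
                             window = 5, min_roi_fraction = 0)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.png"); f2 <- file.path(dir, "b.png")
  nii <- file.path(dir, "raw.nii.gz")
  r1 <- overlay_map(map, image_volume(p$vol), path_png = f1, path_nifti = nii)
  r2 <- overlay_map(map, image_volume(p$vol), path_png = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  raw <- read_volume(nii)
  expect_true(all(is.nan(raw$data[is.na(map$values)])))
  expect_equal(r1$range, range(map$values, na.rm = TRUE))
})
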