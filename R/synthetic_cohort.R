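#' Synthetic cohort configuration
#'
#' Bundles every knob of the phantom-cohort simulator: grid geometry, texture
#' heterogeneity, pharmacokinetic ground truth, the DCE acquisition, and the
#' proportional-hazards survival mechanism. The same configuration plus seed
#' always reproduces the same cohort.
#'
#' Survival times are drawn from an exponential proportional-hazards model
#' whose linear predictor depends on the *true* per-subject heterogeneity
#' covariates (texture contrast and mean K-trans, both standardised by the
#' declared population mean/sd), so recovery of image-derived risk signal is
#' a genuine end-to-end test.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param vol_dim integer length-3 volume grid.
#' @param spacing voxel spacing, mm.
#' @param roi_semiaxes ellipsoid ROI semi-axes, voxels.
#' @param texture list: `smoothness` (Gaussian correlation length of the
#'   random field, voxels), `contrast_mean`/`contrast_sd` (population
#'   distribution of the per-subject in-ROI intensity SD, truncated at
#'   `contrast_min`), `base` named baseline intensities per sequence,
#'   `background` intensity outside the ROI.
#' @param pk list of population pharmacokinetic truth: `ktrans_mean`/`_sd`
#'   (min^-1), `ve_mean`/`_sd`, `vp_mean`/`_sd` (fractions), `spatial_cv`
#'   (within-tumour coefficient of variation of the parameter fields).
#' @param dce_times DCE sampling times, minutes, starting at 0.
#' @param noise_sd additive Gaussian noise SD on simulated tissue
#'   concentration (mM).
#' @param hazard list: `h0` baseline rate (events/month), `beta` named
#'   coefficients over the standardised truth covariates `texture`, `ktrans`.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 60,
                          vol_dim = c(32L, 32L, 32L),
                          spacing = c(1, 1, 1),
                          roi_semiaxes = c(9, 7, 6),
                          texture = list(),
                          pk = list(),
                          dce_times = seq(0, 5, length.out = 30),
                          noise_sd = 0.02,
                          hazard = list(),
                          censor_rate = 0.4,
                          seed = 1L) {
  texture <- utils::modifyList(list(
    smoothness = 2, contrast_mean = 20, contrast_sd = 8, contrast_min = 1,
    base = c(PDw = 100, CET1w = 120), background = 10
  ), texture)
  pk <- utils::modifyList(list(
    ktrans_mean = 0.2, ktrans_sd = 0.08,
    ve_mean = 0.4, ve_sd = 0.1,
    vp_mean = 0.05, vp_sd = 0.02,
    spatial_cv = 0.2
  ), pk)
  hazard <- utils::modifyList(list(
    h0 = 0.02, beta = c(texture = 0.8, ktrans = 0.8)
  ), hazard)
  if (n_subjects < 2) abort("`n_subjects` must be at least 2.")
  if (censor_rate < 0 || censor_rate >= 1) abort("`censor_rate` must be in [0, 1).")
  if (hazard$h0 <= 0) abort("baseline hazard `h0` must be positive.")
  if (dce_times[1] != 0 || is.unsorted(dce_times, strictly = TRUE)) {
    abort("`dce_times` must start at 0 and be strictly increasing.")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), vol_dim = as.integer(vol_dim),
    spacing = spacing, roi_semiaxes = roi_semiaxes, texture = texture,
    pk = pk, dce_times = dce_times, noise_sd = noise_sd, hazard = hazard,
    censor_rate = censor_rate, seed = as.integer(seed)
  ), class = "cohort_config")
}

# deterministic per-stage, per-subject seed derived from the master seed;
# kept below 2^31 - 1 so set.seed() accepts it
derive_seed <- function(seed, stage, index = 0L) {
  as.integer((abs(as.numeric(seed)) * 7919 + stage * 104729 + index * 131) %%
               2147483646) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# smooth standardized Gaussian random field restricted to the ROI
gaussian_field <- function(dim, smoothness, roi = NULL) {
  f <- smooth_gaussian(array(rnorm(prod(dim)), dim), smoothness)
  ref <- if (is.null(roi)) f else f[roi > 0]
  s <- sd(ref)
  if (!is.finite(s) || s == 0) s <- 1
  (f - mean(ref)) / s
}

#' Generate one phantom subject
#'
#' Builds the image part of a synthetic subject: an ellipsoidal tumour ROI
#' whose in-ROI intensities are a smooth Gaussian random field with
#' subject-specific contrast (the in-ROI intensity SD), constant background
#' outside, plus per-voxel pharmacokinetic truth fields. Survival is attached
#' separately by [simulate_cohort()].
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index (`<= n_subjects`).
#' @return A list with elements `id`, `volumes` (named `image_volume`s `PDw`,
#'   `CET1w`), `roi` (0/1 array), `truth` (per-subject latent covariates and
#'   per-voxel PK fields), and `spacing`.
#' @export
generate_phantom <- function(config, subject_index) {
  if (subject_index < 1 || subject_index > config$n_subjects) {
    abort("`subject_index` out of range for this configuration.")
  }
  d <- config$vol_dim
  roi <- ellipsoid_mask(d, config$roi_semiaxes)
  tx <- config$texture
  pk <- config$pk
  with_seed(derive_seed(config$seed, 1L, subject_index), {
    contrast <- max(rnorm(1, tx$contrast_mean, tx$contrast_sd), tx$contrast_min)
    ktrans_mean <- max(rnorm(1, pk$ktrans_mean, pk$ktrans_sd), 0.02)
    ve_mean <- min(max(rnorm(1, pk$ve_mean, pk$ve_sd), 0.05), 0.9)
    vp_mean <- min(max(rnorm(1, pk$vp_mean, pk$vp_sd), 0.005), 0.2)

    volumes <- lapply(names(tx$base), function(seq_name) {
      f <- gaussian_field(d, tx$smoothness, roi)
      img <- array(tx$background, d)
      img[roi > 0] <- tx$base[[seq_name]] + contrast * f[roi > 0]
      image_volume(img, config$spacing)
    })
    names(volumes) <- names(tx$base)

    mod_field <- function(center, lo, hi) {
      g <- gaussian_field(d, tx$smoothness, roi)
      pmin(pmax(center * (1 + pk$spatial_cv * g), lo), hi)
    }
    ktrans <- mod_field(ktrans_mean, 1e-3, Inf)
    ve <- mod_field(ve_mean, 0.01, 0.95)
    vp <- mod_field(vp_mean, 1e-3, 0.3)
    # keep total extracellular + plasma fraction physical
    tot <- ve + vp
    over <- tot > 1
    if (any(over)) {
      ve[over] <- ve[over] / tot[over] * 0.99
      vp[over] <- vp[over] / tot[over] * 0.99
    }
    in_roi <- volumes[[1]]$data[roi > 0]
    list(
      id = sprintf("S%03d", subject_index),
      volumes = volumes,
      roi = roi,
      truth = list(
        contrast = contrast,
        roi_variance = mean((in_roi - mean(in_roi))^2),
        ktrans_mean = ktrans_mean, ve_mean = ve_mean, vp_mean = vp_mean,
        ktrans = ktrans, ve = ve, vp = vp
      ),
      spacing = config$spacing
    )
  })
}

#' Simulate a DCE concentration series from the extended Tofts model
#'
#' Forward-simulates per-voxel tissue concentration
#' \deqn{C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)
#'   e^{-k_{ep}(t-\tau)} d\tau, \quad k_{ep} = K^{trans}/v_e,}
#' treating the arterial input function as piecewise linear between samples,
#' for which the convolution integral has a closed form evaluated recursively
#' (numerically exact, stable for any `kep`). Additive Gaussian noise of the
#' stated SD is applied; `noise_sd = 0` yields the noiseless curves.
#'
#' @param truth list with 3-D arrays (or scalars) `ktrans` (min^-1), `ve`,
#'   `vp` (fractions).
#' @param aif plasma concentration sampled at `times` (mM).
#' @param times acquisition times in minutes, strictly increasing from 0.
#' @param noise_sd Gaussian noise SD (mM).
#' @param roi optional 0/1 array restricting simulated voxels (others 0).
#' @param seed optional seed for the noise draw.
#' @return A `dce_series`: list of `data` (4-D array, x,y,z,time), `times`,
#'   `aif`.
#' @export
simulate_dce <- function(truth, aif, times, noise_sd = 0, roi = NULL,
                         seed = NULL) {
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing and start at 0.")
  }
  if (length(aif) != length(times) || any(!is.finite(aif)) || any(aif < 0)) {
    abort("`aif` must be finite, nonnegative, one value per time point.")
  }
  kt <- as_volume_array(truth$ktrans)
  ve <- as_volume_array(truth$ve)
  vp <- as_volume_array(truth$vp)
  if (!is.array(kt)) {
    kt <- array(kt, c(1, 1, 1)); ve <- array(ve, c(1, 1, 1))
    vp <- array(vp, c(1, 1, 1))
  }
  d <- dim(kt)
  if (any(ve == 0 & kt > 0)) {
    abort("`ve` = 0 with positive K-trans gives an undefined k-ep.")
  }
  vox <- if (is.null(roi)) seq_along(kt) else which(roi > 0)
  ktv <- as.numeric(kt[vox]); vev <- as.numeric(ve[vox]); vpv <- as.numeric(vp[vox])
  kep <- ifelse(ktv > 0, ktv / vev, 0)
  nt <- length(times)
  conc <- matrix(0, length(vox), nt)
  intg <- numeric(length(vox)) # running convolution integral per voxel
  conc[, 1] <- vpv * aif[1]
  for (n in seq_len(nt - 1L)) {
    dt <- times[n + 1L] - times[n]
    c0 <- aif[n]; slope <- (aif[n + 1L] - aif[n]) / dt
    x <- kep * dt
    e <- exp(-x)
    # phi1 = (1 - e^-x)/kep, phi2 = (dt - phi1)/kep with series fallback
    small <- x < 1e-6
    phi1 <- ifelse(small, dt * (1 - x / 2 + x^2 / 6), (1 - e) / ifelse(kep > 0, kep, 1))
    phi1[small & kep == 0] <- dt
    phi2 <- ifelse(kep > 0, (dt - phi1) / ifelse(kep > 0, kep, 1), dt^2 / 2)
    seg <- c0 * phi1 + slope * phi2
    intg <- intg * e + seg
    conc[, n + 1L] <- vpv * aif[n + 1L] + ktv * intg
  }
  if (noise_sd > 0) {
    noise_fun <- function() {
      conc + matrix(rnorm(length(conc), 0, noise_sd), nrow(conc))
    }
    conc <- if (is.null(seed)) noise_fun() else with_seed(seed, noise_fun())
  }
  data <- array(0, c(d, nt))
  flat <- matrix(data, prod(d), nt)
  flat[vox, ] <- conc
  structure(list(data = array(flat, c(d, nt)), times = times, aif = aif),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series> %d x %d x %d voxels, %d time points (0-%.2f min)\n",
              d[1], d[2], d[3], d[4], max(x$times)))
  invisible(x)
}

#' Draw survival outcomes from an exponential proportional-hazards model
#'
#' Event times follow \eqn{T = -\log(U) / (h_0 e^{\beta^T z})} (inverse
#' transform of an exponential with subject-specific rate). Independent
#' exponential censoring times are calibrated by root finding so the expected
#' censored fraction matches `censor_rate`; `censor_rate = 0` disables
#' censoring.
#'
#' @param z numeric matrix (subjects x covariates) of true risk covariates.
#' @param h0 baseline hazard, events/month.
#' @param beta coefficient vector, one per column of `z`.
#' @param censor_rate target censored fraction in `[0, 1)`.
#' @param seed optional RNG seed.
#' @return Tibble with columns `time_months`, `event` (1 = progression) and
#'   `true_lp` (the linear predictor).
#' @export
generate_survival <- function(z, h0, beta, censor_rate = 0, seed = NULL) {
  if (h0 <= 0) abort("`h0` must be positive.")
  z <- as.matrix(z)
  lp <- as.numeric(z %*% beta)
  rate <- h0 * exp(lp)
  draw <- function() {
    t_event <- rexp(length(rate), rate)
    if (censor_rate > 0) {
      # P(censored | rates) = mean mu/(lambda + mu) for exponential censoring
      f <- function(mu) mean(mu / (rate + mu)) - censor_rate
      mu <- uniroot(f, lower = 1e-10, upper = 1e6 * max(rate),
                    tol = 1e-12)$root
      t_cens <- rexp(length(rate), mu)
    } else {
      t_cens <- rep(Inf, length(rate))
    }
    tibble(
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      true_lp = lp
    )
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_subjects` phantoms, their DCE series (shared population AIF),
#' and survival outcomes tied to the true heterogeneity covariates
#' (standardised texture contrast and mean K-trans).
#'
#' @param config a [cohort_config()].
#' @return A `radiomics_cohort`: list with `subjects` (list of subject
#'   records, each with `dce` and `survival` attached), `survival` (tibble
#'   id/time_months/event), `truth` (tibble of latent covariates), `config`.
#' @export
simulate_cohort <- function(config) {
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    s <- generate_phantom(config, i)
    aif <- population_aif(config$dce_times)
    s$dce <- simulate_dce(s$truth[c("ktrans", "ve", "vp")], aif,
                          config$dce_times, noise_sd = config$noise_sd,
                          roi = s$roi,
                          seed = derive_seed(config$seed, 2L, i))
    s
  })
  tx <- config$texture; pk <- config$pk
  z <- cbind(
    texture = (vapply(subjects, function(s) s$truth$contrast, 0) -
                 tx$contrast_mean) / tx$contrast_sd,
    ktrans = (vapply(subjects, function(s) s$truth$ktrans_mean, 0) -
                pk$ktrans_mean) / pk$ktrans_sd
  )
  beta <- config$hazard$beta[colnames(z)]
  surv <- generate_survival(z, config$hazard$h0, beta,
                            censor_rate = config$censor_rate,
                            seed = derive_seed(config$seed, 3L))
  surv <- dplyr::mutate(surv,
                        id = vapply(subjects, function(s) s$id, ""),
                        .before = 1)
  for (i in seq_along(subjects)) {
    subjects[[i]]$survival <- list(time_months = surv$time_months[i],
                                   event = surv$event[i])
  }
  truth <- tibble(
    id = surv$id,
    contrast = z[, "texture"] * tx$contrast_sd + tx$contrast_mean,
    ktrans_mean = z[, "ktrans"] * pk$ktrans_sd + pk$ktrans_mean,
    ve_mean = vapply(subjects, function(s) s$truth$ve_mean, 0),
    vp_mean = vapply(subjects, function(s) s$truth$vp_mean, 0),
    true_lp = surv$true_lp
  )
  structure(list(subjects = subjects,
                 survival = dplyr::select(surv, "id", "time_months", "event"),
                 truth = truth, config = config),
            class = "radiomics_cohort")
}

#' @export
print.radiomics_cohort <- function(x, ...) {
  cat(sprintf("<radiomics_cohort> %d subjects, %d events, %d x %d x %d grid\n",
              length(x$subjects), sum(x$survival$event),
              x$config$vol_dim[1], x$config$vol_dim[2], x$config$vol_dim[3]))
  invisible(x)
}

#' Write / read a cohort on disk
#'
#' Serialises a cohort to NIfTI volumes (`.nii.gz`; 4-D for the DCE series
#' with a JSON sidecar of acquisition times and AIF), survival and truth
#' CSVs, and a JSON config echo. `read_cohort()` round-trips the images and
#' tables losslessly.
#'
#' @param cohort a `radiomics_cohort`.
#' @param out_dir output directory (created if missing).
#' @return A manifest tibble (columns `id`, `kind`, `path`).
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!length(cohort$subjects)) abort("cohort is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(id, kind, path) {
    rows[[length(rows) + 1L]] <<- tibble(id = id, kind = kind, path = path)
  }
  for (s in cohort$subjects) {
    for (nm in names(s$volumes)) {
      p <- file.path(out_dir, sprintf("%s_%s.nii.gz", s$id, nm))
      write_volume(s$volumes[[nm]], p)
      add(s$id, nm, p)
    }
    p <- file.path(out_dir, sprintf("%s_mask.nii.gz", s$id))
    write_volume(image_volume(s$roi + 0, s$spacing), p)
    add(s$id, "mask", p)
    if (!is.null(s$dce)) {
      p <- file.path(out_dir, sprintf("%s_dce.nii.gz", s$id))
      img <- RNifti::asNifti(s$dce$data)
      RNifti::pixdim(img) <- c(s$spacing, 1)
      RNifti::writeNifti(img, p)
      add(s$id, "dce", p)
      sidecar <- file.path(out_dir, sprintf("%s_dce.json", s$id))
      jsonlite::write_json(
        list(times_min = s$dce$times, times_sec = s$dce$times * 60,
             aif_mM = s$dce$aif),
        sidecar, digits = NA, auto_unbox = TRUE)
      add(s$id, "dce_times", sidecar)
    }
  }
  surv_path <- file.path(out_dir, "survival.csv")
  utils::write.csv(cohort$survival, surv_path, row.names = FALSE)
  add(NA_character_, "survival", surv_path)
  truth_path <- file.path(out_dir, "truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  add(NA_character_, "truth", truth_path)
  cfg_path <- file.path(out_dir, "config.json")
  cfg <- cohort$config
  cfg$texture$base <- as.list(cfg$texture$base)
  cfg$hazard$beta <- as.list(cfg$hazard$beta)
  jsonlite::write_json(unclass(cfg), cfg_path, digits = NA, auto_unbox = TRUE)
  add(NA_character_, "config", cfg_path)
  dplyr::bind_rows(rows)
}

#' @rdname write_cohort
#' @param manifest the manifest tibble returned by `write_cohort()`.
#' @export
read_cohort <- function(manifest) {
  surv <- as_tibble(utils::read.csv(
    manifest$path[manifest$kind == "survival"][1]))
  ids <- unique(manifest$id[!is.na(manifest$id)])
  subjects <- lapply(ids, function(id) {
    sub <- manifest[!is.na(manifest$id) & manifest$id == id, ]
    mask <- read_volume(sub$path[sub$kind == "mask"][1])
    vols <- sub[!sub$kind %in% c("mask", "dce", "dce_times"), ]
    volumes <- setNames(lapply(vols$path, read_volume), vols$kind)
    rec <- list(id = id, volumes = volumes, roi = mask$data,
                spacing = mask$spacing)
    if (any(sub$kind == "dce")) {
      arr <- as.array(RNifti::readNifti(sub$path[sub$kind == "dce"][1]))
      attributes(arr) <- list(dim = dim(arr))
      side <- jsonlite::read_json(sub$path[sub$kind == "dce_times"][1],
                                  simplifyVector = TRUE)
      rec$dce <- structure(list(data = arr, times = side$times_min,
                                aif = side$aif_mM), class = "dce_series")
    }
    i <- match(id, surv$id)
    rec$survival <- list(time_months = surv$time_months[i],
                         event = surv$event[i])
    rec
  })
  structure(list(subjects = subjects, survival = surv, truth = NULL,
                 config = NULL), class = "radiomics_cohort")
}
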