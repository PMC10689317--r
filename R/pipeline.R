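#' Study configuration for the end-to-end pipeline
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param features a [feature_config()] for the MR volumes.
#' @param dce_features a [feature_config()] for the pharmacokinetic
#'   parameter maps; the default bin width of 0.01 reflects their intensity
#'   scale (fractions and rate constants of order 0.01-1) the way width 5
#'   reflects MR gray values.
#' @param split_ratio train fraction (7:3 by default).
#' @param redundancy_threshold Pearson redundancy / decorrelation threshold.
#' @param vif_limit VIF flag threshold.
#' @param alpha backward-elimination retention p-value.
#' @param nfolds LASSO cross-validation folds.
#' @param horizon NRI assessment horizon (months).
#' @param map_feature feature rendered in the example feature maps.
#' @param map_window,map_step sliding-window settings for the maps.
#' @param n_map_subjects subjects to render maps for.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `study_config` list.
#' @export
study_config <- function(cohort = cohort_config(),
                         features = feature_config(),
                         dce_features = feature_config(bin_width = 0.01),
                         split_ratio = 0.7,
                         redundancy_threshold = 0.8,
                         vif_limit = 5,
                         alpha = 0.05,
                         nfolds = 10,
                         horizon = 24,
                         map_feature = "firstorder_Variance",
                         map_window = 21,
                         map_step = 1,
                         n_map_subjects = 2,
                         seed = 1L) {
  stopifnot(split_ratio > 0, split_ratio < 1, redundancy_threshold > 0,
            vif_limit > 0, alpha > 0, nfolds >= 3, horizon > 0)
  structure(list(cohort = cohort, features = features,
                 dce_features = dce_features,
                 split_ratio = split_ratio,
                 redundancy_threshold = redundancy_threshold,
                 vif_limit = vif_limit, alpha = alpha, nfolds = nfolds,
                 horizon = horizon, map_feature = map_feature,
                 map_window = map_window, map_step = map_step,
                 n_map_subjects = n_map_subjects, seed = as.integer(seed)),
            class = "study_config")
}

#' Run the full synthetic study end-to-end
#'
#' Executes the whole design on a simulated cohort: cohort generation,
#' per-subject extended-Tofts pharmacokinetic map fitting, radiomic feature
#' extraction from the MR volumes and the four PK parameter maps,
#' event-stratified 7:3 split, construction of the MR-based (multi-sequence),
#' DCE-based (multi-parameter, with Pearson redundancy filtering) and
#' combined models, their evaluation (C-index, risk stratification with
#' Kaplan-Meier/log-rank, NRI of the combined model against both), and
#' example sliding-window feature maps.
#'
#' Stage outputs are cached in `out_dir/cache` keyed by a hash of the
#' relevant configuration, so a rerun with the same config reuses them; the
#' report is bit-identical either way. A manifest records every seed and
#' threshold used.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (`NULL` for no on-disk outputs).
#' @param cache reuse cached stage outputs when present.
#' @return A `study_bundle` list: `features` (tibble with split labels),
#'   `models`, `evaluation`, `maps`, `manifest`.
#' @export
run_study <- function(config, out_dir = NULL, cache = TRUE) {
  use_disk <- !is.null(out_dir)
  if (use_disk) dir.create(file.path(out_dir, "cache"),
                           showWarnings = FALSE, recursive = TRUE)
  cached <- function(key, fun) {
    if (!use_disk || !cache) return(fun())
    path <- file.path(out_dir, "cache", paste0(key, ".rds"))
    if (file.exists(path)) return(readRDS(path))
    val <- fun()
    saveRDS(val, path)
    val
  }
  stage <- function(name, key_obj, fun) {
    tryCatch(cached(paste0(name, "-", rlang::hash(key_obj)), fun),
             error = function(e) {
               abort(sprintf("stage '%s' failed: %s", name,
                             conditionMessage(e)))
             })
  }

  cohort <- stage("cohort", config$cohort,
                  function() simulate_cohort(config$cohort))

  pk <- stage("pk", config$cohort, function() {
    lapply(cohort$subjects, function(s) {
      maps <- fit_extended_tofts(s$dce, s$roi, clip = TRUE)
      pk_maps_to_volumes(maps, spacing = s$spacing)
    })
  })

  feats <- stage("features", list(config$cohort, config$features,
                                  config$dce_features), function() {
    mr <- extract_cohort_features(cohort, config$features)
    ids <- vapply(cohort$subjects, `[[`, "", "id")
    dce <- extract_cohort_features(
      cohort, config$dce_features,
      volumes_fun = function(s) {
        pk[[match(s$id, ids)]][c("ktrans", "kep", "ve", "vp")]
      })
    names(dce)[-1] <- paste0("DCE_", names(dce)[-1])
    dplyr::left_join(mr, dce, by = "id")
  })

  data <- dplyr::left_join(cohort$survival, feats, by = "id")
  data <- split_cohort(data, ratio = config$split_ratio, seed = config$seed)
  train <- dplyr::filter(data, .data$split == "train")
  test <- dplyr::filter(data, .data$split == "test")

  mr_cols <- grep("^(PDw|CET1w)_", names(data), value = TRUE)
  dce_cols <- grep("^DCE_", names(data), value = TRUE)

  models <- stage("models", list(config, feats), function() {
    mr_model <- train_radiomics_model(
      dplyr::select(train, dplyr::any_of(survival_cols),
                    dplyr::all_of(mr_cols)),
      nfolds = config$nfolds, seed = config$seed, alpha = config$alpha,
      vif_limit = config$vif_limit)
    dce_model <- train_radiomics_model(
      dplyr::select(train, dplyr::any_of(survival_cols),
                    dplyr::all_of(dce_cols)),
      redundancy_threshold = config$redundancy_threshold,
      nfolds = config$nfolds, seed = config$seed, alpha = config$alpha,
      vif_limit = config$vif_limit)
    combined <- build_combined_model(
      mr_model, train, dce_cols, threshold = config$redundancy_threshold,
      nfolds = config$nfolds, seed = config$seed, alpha = config$alpha)
    list(mr = mr_model, dce = dce_model, combined = combined)
  })

  evaluation <- stage("evaluation", list(config, feats), function() {
    eval_one <- function(model, name) {
      scores_tr <- dplyr::mutate(
        dplyr::select(train, "id", "time_months", "event"),
        score = predict(model, train)$score)
      scores_te <- dplyr::mutate(
        dplyr::select(test, "id", "time_months", "event"),
        score = predict(model, test)$score)
      strat <- stratify_and_test(model, test)
      tibble(
        model = name,
        cindex_train = concordance_index(scores_tr, n_boot = 0)$cindex,
        ci = list(concordance_index(scores_te, seed = config$seed)),
        logrank_test = list(strat$logrank),
        km = list(strat$km)
      )
    }
    res <- dplyr::bind_rows(eval_one(models$mr, "MR"),
                            eval_one(models$dce, "DCE"),
                            eval_one(models$combined, "combined"))
    safe_nri <- function(new, old) {
      tryCatch(nri(new, old, test, horizon = config$horizon,
                   seed = config$seed),
               error = function(e) {
                 warn(sprintf("NRI unavailable: %s", conditionMessage(e)))
                 tibble(nri = NA_real_, lower = NA_real_, upper = NA_real_,
                        n_event = 0L, n_nonevent = 0L, n_excluded = 0L,
                        up_event = 0L, down_event = 0L, up_nonevent = 0L,
                        down_nonevent = 0L)
               })
    }
    nri_mr <- safe_nri(models$combined, models$mr)
    nri_dce <- safe_nri(models$combined, models$dce)
    list(models = res, nri_vs_mr = nri_mr, nri_vs_dce = nri_dce)
  })

  maps <- stage("maps", list(config$cohort, config$map_feature,
                             config$map_window, config$map_step), function() {
    ids <- vapply(cohort$subjects,
                  `[[`, "", "id")[seq_len(min(config$n_map_subjects,
                                              length(cohort$subjects)))]
    lapply(ids, function(id) {
      s <- cohort$subjects[[match(id, vapply(cohort$subjects, `[[`, "", "id"))]]
      suppressWarnings(compute_feature_map(
        s$volumes[[1]], s$roi, feature = config$map_feature,
        window = config$map_window, step = config$map_step))
    }) |> setNames(ids)
  })

  manifest <- list(
    seed = config$seed,
    stage_seeds = list(phantom = "seed + per-subject offset (stage 1)",
                       dce_noise = "stage 2", survival = "stage 3",
                       split = "stage 4", lasso_folds = "stage 5",
                       bootstrap = "stages 6-7"),
    thresholds = list(redundancy = config$redundancy_threshold,
                      vif = config$vif_limit, alpha = config$alpha,
                      nfolds = config$nfolds, horizon = config$horizon),
    cohort = list(n_subjects = config$cohort$n_subjects,
                  vol_dim = config$cohort$vol_dim,
                  censor_rate = config$cohort$censor_rate,
                  hazard = config$cohort$hazard),
    features = unclass(config$features),
    map = list(feature = config$map_feature, window = config$map_window,
               step = config$map_step)
  )

  bundle <- structure(list(data = data, models = models,
                           evaluation = evaluation, maps = maps,
                           cohort = cohort, manifest = manifest,
                           config = config),
                      class = "study_bundle")
  if (use_disk) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  ev <- x$evaluation$models
  for (i in seq_len(nrow(ev))) {
    ci <- ev$ci[[i]]
    cat(sprintf("  %-9s C-index train %.3f / test %.3f (95%% CI %.3f-%.3f)\n",
                ev$model[i], ev$cindex_train[i], ci$cindex, ci$lower, ci$upper))
  }
  cat(sprintf("  NRI combined vs MR: %.3f; vs DCE: %.3f\n",
              x$evaluation$nri_vs_mr$nri, x$evaluation$nri_vs_dce$nri))
  invisible(x)
}

# serialise the report bundle as JSON + CSV (+ PNG maps)
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev <- bundle$evaluation
  report <- list(
    manifest = bundle$manifest,
    models = lapply(seq_len(nrow(ev$models)), function(i) {
      ci <- ev$models$ci[[i]]
      lr <- ev$models$logrank_test[[i]]
      m <- bundle$models[[c("MR" = "mr", "DCE" = "dce",
                            "combined" = "combined")[ev$models$model[i]]]]
      list(model = ev$models$model[i],
           features = as.list(round(m$coefficients, 6)),
           cutoff = m$cutoff, lambda = m$lambda,
           cindex_train = ev$models$cindex_train[i],
           cindex_test = ci$cindex,
           cindex_ci = c(ci$lower, ci$upper),
           logrank_p = if (!is.null(lr)) lr$p else NA)
    }),
    nri = list(vs_mr = as.list(ev$nri_vs_mr), vs_dce = as.list(ev$nri_vs_dce))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, na = "null")
  utils::write.csv(
    dplyr::select(bundle$data, dplyr::any_of(survival_cols)),
    file.path(out_dir, "split.csv"), row.names = FALSE)
  km_all <- dplyr::bind_rows(lapply(seq_len(nrow(ev$models)), function(i) {
    dplyr::mutate(as_tibble(ev$models$km[[i]]), model = ev$models$model[i])
  }))
  utils::write.csv(km_all, file.path(out_dir, "km_curves.csv"),
                   row.names = FALSE)
  for (id in names(bundle$maps)) {
    s <- bundle$cohort$subjects[[
      match(id, vapply(bundle$cohort$subjects, `[[`, "", "id"))]]
    overlay_map(bundle$maps[[id]], s$volumes[[1]],
                path_png = file.path(out_dir, sprintf("map_%s.png", id)),
                path_nifti = file.path(out_dir, sprintf("map_%s.nii.gz", id)))
  }
  invisible(out_dir)
}

#' Per-subject figure panels
#'
#' Renders, for each mapped subject, a panel of PNGs: the MR volumes, the
#' sliding-window feature map overlay, and the four pharmacokinetic
#' parameter maps (K-trans and k-ep in min^-1, v-e and v-p as fractions —
#' the units are embedded in the file names). Rendering is raster-based
#' (no graphics device) and deterministic.
#'
#' @param bundle a `study_bundle` from [run_study()].
#' @param out_dir output directory.
#' @param slice slice to render (default: middle slice of the ROI).
#' @return Tibble manifest of written files (`id`, `panel`, `path`).
#' @export
make_figures <- function(bundle, out_dir, slice = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  gray_png <- function(arr2d, path) {
    a <- (arr2d - min(arr2d)) / max(max(arr2d) - min(arr2d), 1e-12)
    png::writePNG(t(a[, rev(seq_len(ncol(a)))]), path)
  }
  ids <- names(bundle$maps)
  for (id in ids) {
    s <- bundle$cohort$subjects[[
      match(id, vapply(bundle$cohort$subjects, `[[`, "", "id"))]]
    k <- slice %||% round(mean(which(apply(s$roi, 3, sum) > 0)))
    for (nm in names(s$volumes)) {
      p <- file.path(out_dir, sprintf("%s_%s.png", id, nm))
      gray_png(s$volumes[[nm]]$data[, , k], p)
      rows[[length(rows) + 1L]] <- tibble(id = id, panel = nm, path = p)
    }
    p <- file.path(out_dir, sprintf("%s_map_%s.png", id,
                                    bundle$manifest$map$feature))
    overlay_map(bundle$maps[[id]], s$volumes[[1]], slice = k, path_png = p)
    rows[[length(rows) + 1L]] <- tibble(id = id, panel = "feature_map",
                                        path = p)
    maps <- fit_extended_tofts(s$dce, s$roi, clip = TRUE)
    vols <- pk_maps_to_volumes(maps, spacing = s$spacing)
    units <- c(ktrans = "per-min", kep = "per-min", ve = "fraction",
               vp = "fraction")
    for (nm in names(units)) {
      p <- file.path(out_dir, sprintf("%s_%s_%s.png", id, nm, units[[nm]]))
      gray_png(vols[[nm]]$data[, , k], p)
      rows[[length(rows) + 1L]] <- tibble(id = id, panel = nm, path = p)
    }
  }
  dplyr::bind_rows(rows)
}
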