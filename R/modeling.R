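survival_cols <- c("id", "time_months", "event", "split")

feature_cols <- function(data) setdiff(names(data), survival_cols)

check_survival_data <- function(data) {
  if (!all(c("time_months", "event") %in% names(data))) {
    abort("data must contain `time_months` and `event` columns")
  }
  if (any(data$time_months <= 0)) abort("survival times must be positive")
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0/1")
  invisible(data)
}

#' Clean a feature table
#'
#' Drops features with any missing value, zero variance (constant columns)
#' or exactly duplicated values (one representative of each duplicate set is
#' retained, in column order). Survival bookkeeping columns (`id`,
#' `time_months`, `event`, `split`) are passed through untouched. The
#' operation is idempotent.
#'
#' @param data tibble of features (plus optional survival columns).
#' @return The cleaned tibble, with attribute `dropped`: a named character
#'   vector of dropped features and the reason.
#' @export
clean_features <- function(data) {
  feats <- feature_cols(data)
  dropped <- character(0)
  keep <- character(0)
  seen <- list()
  for (f in feats) {
    x <- data[[f]]
    if (anyNA(x)) {
      dropped[f] <- "missing values"
    } else if (sd(x) == 0 || !all(is.finite(x))) {
      dropped[f] <- "constant or non-finite"
    } else {
      dup <- FALSE
      for (k in keep) {
        if (isTRUE(all.equal(data[[k]], x, tolerance = 0))) {
          dropped[f] <- sprintf("duplicate of %s", k)
          dup <- TRUE
          break
        }
      }
      if (!dup) keep <- c(keep, f)
    }
  }
  if (!length(keep)) abort("all features were dropped during cleaning")
  out <- dplyr::select(data, dplyr::any_of(survival_cols), dplyr::all_of(keep))
  attr(out, "dropped") <- dropped
  out
}

#' Pearson redundancy filter
#'
#' Greedy correlation pruning in column order: a feature is dropped when its
#' absolute Pearson correlation with an already-kept (earlier) feature
#' exceeds `threshold`. Scale-invariant; the column-order tie-break makes
#' runs reproducible.
#'
#' @param data tibble of features (plus optional survival columns).
#' @param threshold absolute correlation above which the later feature of a
#'   pair is deemed redundant (default 0.8).
#' @return Filtered tibble with attribute `dropped` naming removed features.
#' @export
pearson_redundancy_filter <- function(data, threshold = 0.8) {
  feats <- feature_cols(data)
  if (length(feats) < 2L) return(data)
  cm <- abs(stats::cor(as.matrix(data[feats])))
  keep <- character(0)
  dropped <- character(0)
  for (f in feats) {
    if (length(keep) && any(cm[f, keep] > threshold)) {
      against <- keep[which.max(cm[f, keep])]
      dropped[f] <- sprintf("|r| = %.3f with %s", max(cm[f, keep]), against)
    } else {
      keep <- c(keep, f)
    }
  }
  out <- dplyr::select(data, dplyr::any_of(survival_cols), dplyr::all_of(keep))
  attr(out, "dropped") <- dropped
  out
}

#' Event-stratified train/test split
#'
#' Randomly allocates subjects to a training and a test set at the given
#' ratio, stratified by event status so the event fraction differs by at
#' most one subject between parts. Deterministic given the seed.
#'
#' @param data survival tibble (`time_months`, `event`, features).
#' @param ratio training fraction (default 0.7, the usual 7:3 split).
#' @param seed RNG seed.
#' @return The tibble with a `split` column of `"train"` / `"test"`.
#' @export
split_cohort <- function(data, ratio = 0.7, seed = 1L) {
  check_survival_data(data)
  n <- nrow(data)
  if (n < 10) abort("need at least 10 subjects to split")
  assign_split <- function() {
    split <- rep("test", n)
    for (ev in unique(data$event)) {
      idx <- which(data$event == ev)
      n_train <- round(ratio * length(idx))
      split[sample(idx, n_train)] <- "train"
    }
    split
  }
  split <- with_seed(derive_seed(seed, 4L), assign_split())
  for (retry in 1:10) {
    ev_train <- sum(data$event[split == "train"])
    ev_test <- sum(data$event[split == "test"])
    if (ev_train >= 1 && ev_test >= 1) break
    warn("a split part has no events; reshuffling")
    split <- with_seed(derive_seed(seed, 4L, retry), assign_split())
  }
  dplyr::mutate(data, split = split)
}

# event-stratified fold assignment for CV (no fold without events when
# events >= nfolds)
stratified_folds <- function(event, nfolds) {
  foldid <- integer(length(event))
  for (ev in unique(event)) {
    idx <- sample(which(event == ev))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' LASSO-Cox feature selection
#'
#' L1-penalised Cox regression over the standardised feature matrix with the
#' penalty chosen by `nfolds`-fold cross-validation (event-stratified folds)
#' under the minimum partial-likelihood-deviance criterion; the features with
#' nonzero coefficients at \eqn{\lambda_{min}} are returned.
#'
#' @param data survival tibble (train set).
#' @param nfolds CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param features optional subset of feature columns to consider.
#' @return List: `features` (selected names), `lambda_min`, `cvfit` (the
#'   `cv.glmnet` object, `NULL` when selection was trivial).
#' @export
lasso_cox_select <- function(data, nfolds = 10, seed = 1L, features = NULL) {
  check_survival_data(data)
  feats <- features %||% feature_cols(data)
  if (sum(data$event) < 2) abort("need at least 2 events for LASSO-Cox")
  if (length(feats) < 2L) {
    return(list(features = feats, lambda_min = NA_real_, cvfit = NULL))
  }
  x <- scale(as.matrix(data[feats]))
  y <- survival::Surv(data$time_months, data$event)
  nfolds_eff <- max(3L, min(nfolds, sum(data$event)))
  res <- with_seed(derive_seed(seed, 5L), {
    foldid <- stratified_folds(data$event, nfolds_eff)
    glmnet::cv.glmnet(x, y, family = "cox", alpha = 1,
                      foldid = foldid, standardize = FALSE)
  })
  co <- as.matrix(coef(res, s = "lambda.min"))
  list(features = rownames(co)[co[, 1] != 0],
       lambda_min = res$lambda.min, cvfit = res)
}

#' Backward feature elimination by Cox p-values
#'
#' Iteratively refits the multivariate Cox model and removes the single
#' feature with the largest Wald p-value while any p-value is at or above
#' `alpha`; stops when all remaining features are significant or one feature
#' remains. A non-convergent fit (monotone likelihood) drops the feature
#' with the most extreme coefficient, with a warning. Deterministic given
#' the input.
#'
#' @param data survival tibble (train set).
#' @param features starting feature names.
#' @param alpha retention threshold on the Wald p-value (default 0.05).
#' @return Character vector of retained features (possibly length 1).
#' @export
backward_eliminate <- function(data, features, alpha = 0.05) {
  check_survival_data(data)
  feats <- features
  while (length(feats) > 1L) {
    fit <- cox_fit_quiet(data, feats)
    if (!fit$ok) {
      drop <- feats[which.max(replace(abs(fit$coef), is.na(fit$coef), Inf))]
      warn(sprintf("Cox fit did not converge; dropping '%s'", drop))
      feats <- setdiff(feats, drop)
      next
    }
    p <- fit$p
    if (all(p < alpha, na.rm = TRUE)) break
    worst <- feats[which.max(replace(p, is.na(p), Inf))]
    feats <- setdiff(feats, worst)
  }
  feats
}

cox_fit_quiet <- function(data, feats, ties = "breslow") {
  x <- as.matrix(data[feats])
  colnames(x) <- feats
  y <- survival::Surv(data$time_months, data$event)
  ok <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(y ~ x, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
        ok <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- coef(fit)
  names(cf) <- feats
  if (any(!is.finite(cf)) || any(abs(cf) > 15)) ok <- FALSE
  sm <- summary(fit)$coefficients
  p <- sm[, "Pr(>|z|)"]
  names(p) <- feats
  list(fit = fit, coef = cf, p = p, ok = ok)
}

#' Variance inflation factors
#'
#' Computes \eqn{VIF_j = 1/(1 - R_j^2)} by regressing each feature on all
#' the others; values above `limit` (default 5) indicate multicollinearity.
#' Exactly collinear features get an infinite VIF.
#'
#' @param data tibble containing the features.
#' @param features feature names (>= 2).
#' @param limit flag threshold (default 5).
#' @return Tibble with columns `feature`, `vif`, `flagged`.
#' @export
vif_check <- function(data, features, limit = 5) {
  if (length(features) < 2L) {
    return(tibble(feature = features, vif = rep(1, length(features)),
                  flagged = FALSE))
  }
  x <- as.matrix(data[features])
  vifs <- vapply(seq_along(features), function(j) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  tibble(feature = features, vif = vifs, flagged = vifs > limit)
}

#' Fit the multivariate Cox prognostic model
#'
#' Fits a Cox proportional-hazards model (Breslow tie handling) on
#' train-standardised features and stores everything needed to score new
#' subjects: coefficients, the standardisation parameters, and the
#' training-median cutoff of the linear predictor used for risk
#' stratification. Monotone likelihood (perfect separation) triggers a
#' ridge-penalised refit, flagged in the result.
#'
#' @param data survival tibble (train set).
#' @param features feature names to fit.
#' @param lambda optional selection penalty to record as provenance.
#' @param provenance free-text note on how the features were chosen.
#' @return A `radiomics_cox_model`.
#' @export
fit_cox <- function(data, features, lambda = NA_real_, provenance = "") {
  check_survival_data(data)
  if (!length(features)) abort("no features to fit")
  if (sum(data$event) < 2) abort("need at least 2 events")
  x <- as.matrix(data[features])
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  sdata <- data
  sdata[features] <- as.data.frame(xs)
  fit <- cox_fit_quiet(sdata, features)
  penalized <- FALSE
  if (!fit$ok) {
    penalized <- TRUE
    y <- survival::Surv(data$time_months, data$event)
    if (length(features) >= 2L) {
      g <- glmnet::glmnet(xs, y, family = "cox", alpha = 0,
                          lambda = 0.05, standardize = FALSE)
      cf <- setNames(as.numeric(coef(g)), features)
    } else {
      # single-feature monotone likelihood: fall back to a bounded coefficient
      cf <- setNames(pmin(pmax(fit$coef, -15), 15), features)
    }
    fit$coef <- cf
  }
  lp <- as.numeric(xs %*% fit$coef)
  structure(list(
    features = features,
    coefficients = fit$coef,
    center = center,
    scale = scl,
    cutoff = median(lp),
    lambda = lambda,
    penalized = penalized,
    fit = if (fit$ok) fit$fit else NULL,
    n = nrow(data),
    n_event = sum(data$event),
    provenance = provenance
  ), class = "radiomics_cox_model")
}

#' @export
print.radiomics_cox_model <- function(x, ...) {
  cat(sprintf("<radiomics_cox_model> %d feature(s), %d subjects (%d events)%s\n",
              length(x$features), x$n, x$n_event,
              if (x$penalized) ", ridge-penalised fallback" else ""))
  print(round(x$coefficients, 4))
  cat(sprintf("risk cutoff (training median): %.4f\n", x$cutoff))
  invisible(x)
}

#' Score subjects with a fitted model
#'
#' @param object a `radiomics_cox_model`.
#' @param new_data tibble containing the model's feature columns.
#' @param ... unused.
#' @return Tibble with `score` (linear predictor on the training
#'   standardisation) and `risk_group` (`"high"` iff score strictly exceeds
#'   the training-median cutoff; ties go to `"low"`). An `id` column is
#'   carried through when present.
#' @export
predict.radiomics_cox_model <- function(object, new_data, ...) {
  if ("MR_prediction" %in% object$features &&
      !"MR_prediction" %in% names(new_data) && !is.null(object$mr_model)) {
    new_data <- dplyr::mutate(new_data,
      MR_prediction = predict(object$mr_model, new_data)$score)
  }
  miss <- setdiff(object$features, names(new_data))
  if (length(miss)) {
    abort(sprintf("new_data lacks feature(s): %s", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(new_data[object$features])
  xs <- scale(x, center = object$center, scale = object$scale)
  score <- as.numeric(xs %*% object$coefficients)
  out <- tibble(
    score = score,
    risk_group = factor(ifelse(score > object$cutoff, "high", "low"),
                        levels = c("low", "high"))
  )
  if ("id" %in% names(new_data)) out <- dplyr::bind_cols(
    tibble(id = new_data$id), out)
  out
}

#' Train a radiomics prognostic model end-to-end
#'
#' The full selection chain on a training set: cleaning, optional Pearson
#' redundancy filtering, LASSO-Cox selection at \eqn{\lambda_{min}} (10-fold
#' CV), backward elimination by Wald p-value, a VIF multicollinearity check
#' (flagged features are reported, not dropped — mirroring the diagnostic
#' role of the check), and the final multivariate Cox fit with
#' training-median risk cutoff.
#'
#' @param data training survival tibble.
#' @param redundancy_threshold Pearson pre-filter threshold, or `NULL` to
#'   skip the pre-filter.
#' @param nfolds,seed CV folds and seed for [lasso_cox_select()].
#' @param alpha backward-elimination retention threshold.
#' @param vif_limit VIF flag threshold.
#' @return A `radiomics_cox_model` with a `vif` tibble and `dropped`
#'   bookkeeping attached.
#' @export
train_radiomics_model <- function(data, redundancy_threshold = NULL,
                                  nfolds = 10, seed = 1L, alpha = 0.05,
                                  vif_limit = 5) {
  data <- clean_features(data)
  steps <- c(sprintf("cleaned (%d dropped)", length(attr(data, "dropped"))))
  if (!is.null(redundancy_threshold)) {
    data <- pearson_redundancy_filter(data, redundancy_threshold)
    steps <- c(steps, sprintf("redundancy filter |r| > %g (%d dropped)",
                              redundancy_threshold,
                              length(attr(data, "dropped"))))
  }
  sel <- lasso_cox_select(data, nfolds = nfolds, seed = seed)
  if (!length(sel$features)) {
    warn("LASSO selected no features; keeping the single best by univariate p")
    feats <- feature_cols(data)
    p <- vapply(feats, function(f) cox_fit_quiet(data, f)$p, 0)
    sel$features <- feats[which.min(p)]
  }
  steps <- c(steps, sprintf("LASSO-Cox lambda.min = %.4g (%d selected)",
                            sel$lambda_min, length(sel$features)))
  feats <- backward_eliminate(data, sel$features, alpha = alpha)
  steps <- c(steps, sprintf("backward elimination at p < %g (%d retained)",
                            alpha, length(feats)))
  model <- fit_cox(data, feats, lambda = sel$lambda_min,
                   provenance = paste(steps, collapse = "; "))
  model$vif <- vif_check(data, feats, limit = vif_limit)
  if (any(model$vif$flagged)) {
    warn(sprintf("VIF above %g for: %s", vif_limit,
                 paste(model$vif$feature[model$vif$flagged], collapse = ", ")))
  }
  model
}

#' Combine an MR model with DCE-MR features
#'
#' Builds the fusion model: (1) Pearson redundancy filtering within the DCE
#' features; (2) removal of DCE features highly correlated (|r| >
#' `threshold`) with the MR model's linear predictor, so the DCE block
#' contributes information divergent from the MR model; (3) pooling of the
#' remaining DCE features with the MR model prediction as covariates;
#' (4) LASSO-Cox selection and backward elimination; (5) the final Cox fit.
#' If every DCE feature is eliminated, the MR model is returned unchanged,
#' flagged `combined_fallback`.
#'
#' @param mr_model a trained `radiomics_cox_model` (the MR-based model).
#' @param data training tibble holding the DCE feature columns, the MR
#'   model's feature columns, and survival.
#' @param dce_features names of the DCE feature columns in `data`.
#' @param threshold correlation threshold for both decorrelation steps.
#' @param nfolds,seed,alpha passed to selection, as in
#'   [train_radiomics_model()].
#' @return A `radiomics_cox_model` whose covariates include
#'   `MR_prediction`; or the MR model (flagged) when no DCE signal survives.
#' @export
build_combined_model <- function(mr_model, data, dce_features,
                                 threshold = 0.8, nfolds = 10, seed = 1L,
                                 alpha = 0.05) {
  check_survival_data(data)
  mr_pred <- predict(mr_model, data)$score
  dce <- dplyr::select(data, dplyr::any_of(survival_cols),
                       dplyr::all_of(dce_features))
  dce <- clean_features(dce)
  dce <- pearson_redundancy_filter(dce, threshold)
  feats <- feature_cols(dce)
  # decorrelate against the MR model's prediction
  r <- vapply(feats, function(f) abs(stats::cor(dce[[f]], mr_pred)), 0)
  feats <- feats[r <= threshold]
  if (!length(feats)) {
    warn("all DCE features were decorrelated away; returning the MR model")
    mr_model$combined_fallback <- TRUE
    return(mr_model)
  }
  pool <- dplyr::bind_cols(
    dplyr::select(dce, dplyr::any_of(survival_cols), dplyr::all_of(feats)),
    tibble(MR_prediction = mr_pred))
  sel <- lasso_cox_select(pool, nfolds = nfolds, seed = seed)
  cand <- sel$features
  if (!length(cand)) cand <- "MR_prediction"
  kept <- backward_eliminate(pool, cand, alpha = alpha)
  model <- fit_cox(pool, kept, lambda = sel$lambda_min,
                   provenance = sprintf(
                     "combined: %d DCE features after decorrelation; LASSO + backward elimination",
                     length(feats)))
  model$vif <- vif_check(pool, kept)
  model$mr_model <- mr_model
  model
}
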