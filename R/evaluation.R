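#' Harrell's concordance index with bootstrap confidence interval
#'
#' Counts concordant pairs over all usable pairs: a pair is usable when the
#' subject with the shorter observed time had an event (or both times are
#' tied with at least one event under the standard tie rules); the pair is
#' concordant when that subject also has the higher risk score, and score
#' ties count 1/2. The 95% CI is the percentile interval over bootstrap
#' resamples of subjects.
#'
#' @param data tibble with the three columns below.
#' @param time,event,score column names (tidy-eval, defaults
#'   `time_months`, `event`, `score`).
#' @param n_boot bootstrap resamples for the CI (default 1000; 0 skips it).
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return One-row tibble: `cindex`, `lower`, `upper`, `n`, `n_pairs`.
#' @export
concordance_index <- function(data, time = "time_months", event = "event",
                              score = "score", n_boot = 1000, conf = 0.95,
                              seed = 1L) {
  t <- data[[time]]; e <- data[[event]]; s <- data[[score]]
  ci <- harrell_c(t, e, s)
  if (is.na(ci$c)) abort("no comparable pairs")
  lower <- upper <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(derive_seed(seed, 6L), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(t), replace = TRUE)
        harrell_c(t[idx], e[idx], s[idx])$c
      }, 0)
    })
    qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                   na.rm = TRUE, names = FALSE)
    lower <- qs[1]; upper <- qs[2]
  }
  tibble(cindex = ci$c, lower = lower, upper = upper,
         n = length(t), n_pairs = ci$pairs)
}

# vectorised pairwise Harrell counting: a pair is usable when the subject
# with the strictly earlier observed time had an event; concordant when that
# subject also has the higher score, score ties credited 1/2; tied observed
# times are not usable
harrell_c <- function(t, e, s) {
  n <- length(t)
  ti <- matrix(t, n, n); tj <- t(ti)
  ei <- matrix(e, n, n)
  si <- matrix(s, n, n); sj <- t(si)
  usable <- ti < tj & ei == 1
  num <- sum(usable & si > sj) + 0.5 * sum(usable & si == sj)
  den <- sum(usable)
  if (den == 0) return(list(c = NA_real_, pairs = 0))
  list(c = num / den, pairs = den)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; censored subjects leave
#' the risk set without producing a step. Thin tidy wrapper over
#' [survival::survfit()].
#'
#' @param data survival tibble.
#' @param time,event column names.
#' @return Tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (and `group` when called via
#'   [stratify_and_test()]).
#' @export
km_curve <- function(data, time = "time_months", event = "event") {
  fit <- survival::survfit(
    survival::Surv(data[[time]], data[[event]]) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                n_censor = fit$n.censor, survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' @param data survival tibble.
#' @param group column name of a two-level grouping factor.
#' @param time,event column names.
#' @return One-row tibble: `chisq`, `df`, `p`.
#' @export
log_rank <- function(data, group = "risk_group", time = "time_months",
                     event = "event") {
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) < 2L) abort("log-rank needs two non-empty groups")
  fit <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ g)
  df <- length(fit$n) - 1
  tibble(chisq = fit$chisq, df = df,
         p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Risk stratification by the training-median cutoff
#'
#' Scores a dataset with a fitted model, splits it at the model's stored
#' training-median cutoff into low/high risk groups, and runs Kaplan-Meier
#' curves plus the two-group log-rank test. A degenerate single-group split
#' is reported without a test.
#'
#' @param model a `radiomics_cox_model`.
#' @param data tibble with the model's features and survival columns.
#' @return List: `scores` (tibble with `score`, `risk_group`), `km` (tibble
#'   of per-group curves), `logrank` (tibble or `NULL` when degenerate),
#'   `cutoff`.
#' @export
stratify_and_test <- function(model, data) {
  check_survival_data(data)
  pred <- predict(model, data)
  scored <- dplyr::bind_cols(
    dplyr::select(data, dplyr::any_of(c("id", "time_months", "event"))),
    dplyr::select(pred, "score", "risk_group"))
  km <- dplyr::group_by(scored, .data$risk_group) |>
    dplyr::group_modify(~ km_curve(.x)) |>
    dplyr::ungroup() |>
    dplyr::rename(group = "risk_group")
  class(km) <- c("km_curve", class(km))
  lr <- NULL
  if (nlevels(droplevels(scored$risk_group)) == 2L) {
    lr <- log_rank(scored)
  } else {
    warn("all subjects fall in one risk group; log-rank test skipped")
  }
  list(scores = scored, km = km, logrank = lr, cutoff = model$cutoff)
}

#' Net reclassification improvement between two models
#'
#' Two-category NRI at a fixed horizon using each model's median-cutoff risk
#' groups. Subjects are classed as events if they progressed at or before
#' the horizon and as non-events if followed beyond it; subjects censored
#' before the horizon are excluded (their status is unknown — the exclusion
#' count is reported).
#' \deqn{NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) -
#'   P(up|nonevent)]}
#' where "up" means the new model reclassifies a subject into the high-risk
#' group. The CI is a percentile bootstrap. NRI is antisymmetric in the two
#' models. The index is reported together with the reclassification counts;
#' like any NRI it can mislead under a poorly calibrated risk function and
#' should be read alongside the C-index.
#'
#' @param model_new,model_old fitted `radiomics_cox_model`s scoring the same
#'   subjects.
#' @param data tibble with both models' features and survival columns.
#' @param horizon months at which event status is assessed.
#' @param n_boot bootstrap resamples (default 1000; 0 skips the CI).
#' @param seed RNG seed.
#' @return One-row tibble: `nri`, `lower`, `upper`, `n_event`, `n_nonevent`,
#'   `n_excluded`, `up_event`, `down_event`, `up_nonevent`, `down_nonevent`.
#' @export
nri <- function(model_new, model_old, data, horizon, n_boot = 1000,
                seed = 1L) {
  check_survival_data(data)
  g_new <- predict(model_new, data)$risk_group
  g_old <- predict(model_old, data)$risk_group
  status <- ifelse(data$time_months > horizon, 0L,
                   ifelse(data$event == 1, 1L, NA_integer_))
  keep <- !is.na(status)
  if (!any(status[keep] == 1L)) abort("no events before the horizon")
  calc <- function(gn, go, st) {
    up <- gn == "high" & go == "low"
    down <- gn == "low" & go == "high"
    ev <- st == 1L
    ne <- st == 0L
    (mean(up[ev]) - mean(down[ev])) + (mean(down[ne]) - mean(up[ne]))
  }
  gn <- g_new[keep]; go <- g_old[keep]; st <- status[keep]
  value <- calc(gn, go, st)
  lower <- upper <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(derive_seed(seed, 7L), {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample(length(st), replace = TRUE)
        if (!any(st[idx] == 1L) || !any(st[idx] == 0L)) return(NA_real_)
        calc(gn[idx], go[idx], st[idx])
      }, 0)
    })
    qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    lower <- qs[1]; upper <- qs[2]
  }
  ev <- st == 1L; ne <- st == 0L
  tibble(
    nri = value, lower = lower, upper = upper,
    n_event = sum(ev), n_nonevent = sum(ne), n_excluded = sum(!keep),
    up_event = sum(gn[ev] == "high" & go[ev] == "low"),
    down_event = sum(gn[ev] == "low" & go[ev] == "high"),
    up_nonevent = sum(gn[ne] == "high" & go[ne] == "low"),
    down_nonevent = sum(gn[ne] == "low" & go[ne] == "high")
  )
}

#' @describeIn km_curve ggplot step curves (per group when present).
#' @param object a `km_curve` tibble.
#' @param ... unused.
#' @export
autoplot.km_curve <- function(object, ...) {
  has_group <- "group" %in% names(object)
  pad <- function(df) {
    dplyr::bind_rows(tibble(time = 0, survival = 1), df)
  }
  df <- if (has_group) {
    dplyr::group_by(object, .data$group) |>
      dplyr::group_modify(~ pad(.x)) |> dplyr::ungroup()
  } else {
    pad(object)
  }
  p <- if (has_group) {
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                     colour = .data$group))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival))
  }
  p + ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Progression-free survival") +
    ggplot2::theme_minimal()
}
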