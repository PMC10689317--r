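test_that("C-index is 1 for perfect concordance and 0 for perfect discordance", {
  d <- tibble::tibble(time_months = c(1, 2, 3), event = c(1, 1, 1),
                      score = c(3, 2, 1))
  expect_equal(concordance_index(d, n_boot = 0)$cindex, 1)
  d$score <- c(1, 2, 3)
  expect_equal(concordance_index(d, n_boot = 0)$cindex, 0)
})

test_that("C-index equals exhaustive pair enumeration under censoring", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    d <- tibble::tibble(
      time_months = round(rexp(n, 0.05), 1),
      event = rbinom(n, 1, 0.6),
      score = sample(rnorm(n - 2), n, replace = TRUE)) # some score ties
    if (sum(d$event) == 0) d$event[1] <- 1
    expect_equal(concordance_index(d, n_boot = 0)$cindex,
                 oracle_cindex(d$time_months, d$event, d$score))
  }
})

test_that("an uninformative score concordances near one half", {
  set.seed(24)
  d <- tibble::tibble(time_months = rexp(500, 0.05),
                      event = rbinom(500, 1, 0.7),
                      score = rnorm(500))
  ci <- concordance_index(d, n_boot = 0)
  expect_lt(abs(ci$cindex - 0.5), 0.05)
})

test_that("bootstrap CI brackets the point estimate", {
  d <- sim_dataset(n = 80, seed = 25)
  d$score <- d$inf1 + d$inf2
  ci <- concordance_index(d, n_boot = 200, seed = 1)
  expect_true(ci$lower <= ci$cindex && ci$cindex <= ci$upper)
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  d <- tibble::tibble(time_months = c(1, 2), event = c(1, 1))
  km <- km_curve(d)
  expect_equal(km$survival, c(0.5, 0))
  # censored subjects shrink the risk set without a step
  d2 <- tibble::tibble(time_months = c(1, 1.5, 2, 3), event = c(1, 0, 1, 1))
  km2 <- km_curve(d2)
  hand <- oracle_km(d2$time_months, d2$event)
  expect_equal(km2$survival[km2$n_event > 0], hand$survival)
  # all censored: flat at 1
  d3 <- tibble::tibble(time_months = 1:4, event = rep(0, 4))
  expect_true(all(km_curve(d3)$survival == 1))
})

test_that("KM curves are non-increasing and start from 1", {
  set.seed(26)
  d <- tibble::tibble(time_months = rexp(100, 0.04),
                      event = rbinom(100, 1, 0.6))
  km <- km_curve(d)
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_true(all(km$survival <= 1))
})

test_that("KM tracks the closed-form exponential survival curve", {
  set.seed(27)
  d <- tibble::tibble(time_months = rexp(2000, 0.05), event = 1)
  km <- km_curve(d)
  mid <- km$time < quantile(d$time_months, 0.8)
  expect_lt(max(abs(km$survival[mid] - exp(-0.05 * km$time[mid]))), 0.04)
})

test_that("log-rank is null on identical groups and matches hand arithmetic", {
  d <- tibble::tibble(time_months = rep(c(1, 2, 3), 2),
                      event = rep(1, 6),
                      risk_group = rep(c("low", "high"), each = 3))
  lr <- log_rank(d)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  # 6-subject worked example: observed minus expected by hand
  d2 <- tibble::tibble(time_months = c(1, 2, 3, 4, 5, 6),
                       event = c(1, 1, 1, 1, 1, 0),
                       risk_group = c("a", "a", "a", "b", "b", "b"))
  # at times 1..5: O_a = (1,1,1,0,0); E_a computed from risk sets
  # risk sets: n=(6,5,4,3,2), n_a=(3,2,1,0,0) -> E_a = sum(n_a/n) = 1.65
  # V = sum n_a*n_b*(n-d)/(n^2*(n-1)) with d=1 each
  na <- c(3, 2, 1, 0, 0); nn <- c(6, 5, 4, 3, 2)
  oa <- 3; ea <- sum(na / nn)
  vv <- sum(na * (nn - na) / nn^2)
  expect_equal(log_rank(d2)$chisq, (oa - ea)^2 / vv, tolerance = 1e-10)
})

test_that("log-rank type-I error is near nominal under the null", {
  rejections <- vapply(1:500, function(seed) {
    set.seed(seed + 9000)
    d <- tibble::tibble(time_months = rexp(60, 0.05),
                        event = rbinom(60, 1, 0.7),
                        risk_group = rep(c("low", "high"), 30))
    log_rank(d)$p < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("stratification applies the training-median cutoff with ties low", {
  d <- sim_dataset(n = 100, seed = 28)
  m <- fit_cox(d, c("inf1", "inf2"))
  # training split is exactly 50/50 at the median for even n
  pred <- predict(m, d)
  expect_equal(sum(pred$risk_group == "high"), 50)
  st <- stratify_and_test(m, d)
  expect_true(all(c("scores", "km", "logrank") %in% names(st)))
  expect_equal(st$cutoff, m$cutoff)
  expect_true(all(st$scores$risk_group[st$scores$score <= m$cutoff] == "low"))
})

test_that("an effectful cohort stratifies significantly most of the time", {
  hits <- vapply(1:20, function(seed) {
    d <- sim_dataset(n = 200, n_inf = 2, n_noise = 0, beta = 1, seed = seed + 100)
    d <- split_cohort(d, seed = seed)
    train <- dplyr::filter(d, split == "train")
    test <- dplyr::filter(d, split == "test")
    m <- fit_cox(train, c("inf1", "inf2"))
    st <- stratify_and_test(m, test)
    !is.null(st$logrank) && st$logrank$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("NRI worked example and antisymmetry hold", {
  # fabricate two models as fixed score tables via direct group arithmetic:
  # 10 events: 4 up / 1 down; 10 non-events: 3 down / 1 up -> NRI = 0.5
  d <- tibble::tibble(
    time_months = c(rep(5, 10), rep(50, 10)),
    event = c(rep(1, 10), rep(0, 10)))
  old_high <- c(rep(FALSE, 4), TRUE, rep(FALSE, 2), rep(TRUE, 3),  # events
                rep(TRUE, 3), FALSE, rep(FALSE, 3), rep(TRUE, 3))  # non-events
  new_high <- c(rep(TRUE, 4), FALSE, rep(FALSE, 2), rep(TRUE, 3),
                rep(FALSE, 3), TRUE, rep(FALSE, 3), rep(TRUE, 3))
  mk <- function(f) {
    m <- list(features = f, coefficients = setNames(1, f),
              center = setNames(0, f), scale = setNames(1, f), cutoff = 0.5)
    class(m) <- "radiomics_cox_model"
    m
  }
  m_new <- mk("s_new"); m_old <- mk("s_old")
  d$s_new <- as.numeric(new_high); d$s_old <- as.numeric(old_high)
  res <- nri(m_new, m_old, d, horizon = 24, n_boot = 0)
  expect_equal(res$nri, 0.5)
  expect_equal(res$up_event, 4)
  expect_equal(res$down_nonevent, 3)
  # identical models: zero
  expect_equal(nri(m_new, m_new, d, horizon = 24, n_boot = 0)$nri, 0)
  # antisymmetry
  rev <- nri(m_old, m_new, d, horizon = 24, n_boot = 0)
  expect_equal(rev$nri, -res$nri)
})

test_that("subjects censored before the horizon are excluded from the NRI", {
  d <- tibble::tibble(
    time_months = c(5, 10, 40, 50, 12),
    event = c(1, 0, 0, 1, 1),
    s_new = c(1, 1, 0, 1, 1), s_old = c(0, 0, 0, 1, 1))
  mk <- function(f) {
    m <- list(features = f, coefficients = setNames(1, f),
              center = setNames(0, f), scale = setNames(1, f), cutoff = 0.5)
    class(m) <- "radiomics_cox_model"
    m
  }
  res <- nri(mk("s_new"), mk("s_old"), d, horizon = 24, n_boot = 0)
  expect_equal(res$n_excluded, 1) # the subject censored at 10 months
  expect_equal(res$n_event, 2)    # events at 5 and 12 months
  expect_equal(res$n_nonevent, 2) # followed past the horizon (40, 50 months)
})

test_that("a better-informed model earns a positive NRI", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed + 700)
    n <- 200
    z <- matrix(rnorm(n), n, 1)
    surv <- generate_survival(z, h0 = 0.04, beta = 1.2, censor_rate = 0.2,
                              seed = seed)
    d <- dplyr::bind_cols(dplyr::select(surv, -true_lp),
                          tibble::tibble(truth = z[, 1],
                                         noisy = z[, 1] + rnorm(n, 0, 2)))
    mk <- function(f, cut) {
      m <- list(features = f, coefficients = setNames(1, f),
                center = setNames(0, f), scale = setNames(1, f),
                cutoff = cut)
      class(m) <- "radiomics_cox_model"
      m
    }
    res <- nri(mk("truth", median(d$truth)), mk("noisy", median(d$noisy)),
               d, horizon = 24, n_boot = 0)
    res$nri > 0
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})
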