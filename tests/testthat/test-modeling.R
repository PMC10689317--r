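test_that("cleaning drops constant, missing and duplicated features once", {
  d <- tibble::tibble(
    time_months = c(1, 2, 3, 4), event = c(1, 0, 1, 1),
    a = c(1, 2, 3, 4), const = 5, with_na = c(1, NA, 3, 4),
    dup_of_a = c(1, 2, 3, 4))
  out <- clean_features(d)
  expect_named(out, c("time_months", "event", "a"))
  dropped <- attr(out, "dropped")
  expect_setequal(names(dropped), c("const", "with_na", "dup_of_a"))
  # idempotence
  out2 <- clean_features(out)
  expect_identical(names(out2), names(out))
})

test_that("redundancy filter drops later features above |r| = 0.8", {
  set.seed(11)
  d <- tibble::tibble(a = rnorm(50))
  d$b <- 2 * d$a
  d$c <- rnorm(50)
  out <- pearson_redundancy_filter(d)
  expect_named(out, c("a", "c"))
  # scale invariance
  d2 <- d
  d2$c <- d2$c * 1000
  expect_identical(names(pearson_redundancy_filter(d2)), c("a", "c"))
})

test_that("independent features at n = 500 survive the redundancy filter", {
  set.seed(12)
  d <- tibble::as_tibble(matrix(rnorm(500 * 10), 500, 10),
                         .name_repair = ~ paste0("f", 1:10))
  out <- pearson_redundancy_filter(d)
  expect_equal(ncol(out), 10)
})

test_that("split is event-stratified, sized and deterministic", {
  d <- sim_dataset(n = 100, seed = 13)
  s1 <- split_cohort(d, ratio = 0.7, seed = 21)
  s2 <- split_cohort(d, ratio = 0.7, seed = 21)
  expect_identical(s1$split, s2$split)
  expect_equal(sum(s1$split == "train"), 70)
  ev_frac_train <- mean(d$event[s1$split == "train"])
  ev_frac_test <- mean(d$event[s1$split == "test"])
  # stratification keeps event fractions within one subject of equality
  expect_lt(abs(sum(d$event[s1$split == "train"]) - 0.7 * sum(d$event)), 1)
  expect_lt(abs(ev_frac_train - ev_frac_test), 0.05)
})

test_that("LASSO-Cox selects the informative features most of the time", {
  hits <- vapply(1:20, function(seed) {
    d <- sim_dataset(n = 200, n_inf = 2, n_noise = 48, beta = 1, seed = seed)
    sel <- lasso_cox_select(d, seed = seed)
    all(c("inf1", "inf2") %in% sel$features)
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("a duplicated informative feature does not inflate the selection", {
  d <- sim_dataset(n = 150, n_inf = 2, n_noise = 10, beta = 1, seed = 31)
  d$inf1_copy <- d$inf1
  sel <- lasso_cox_select(d, seed = 31)
  expect_true(any(c("inf1", "inf1_copy") %in% sel$features))
})

test_that("backward elimination removes appended noise and keeps signal", {
  removed <- vapply(1:20, function(seed) {
    d <- sim_dataset(n = 150, n_inf = 2, n_noise = 1, beta = 1, seed = seed)
    kept <- backward_eliminate(d, c("inf1", "inf2", "noise1"))
    !"noise1" %in% kept
  }, TRUE)
  expect_gte(mean(removed), 0.9)
  # strongly informative features are all retained
  d <- sim_dataset(n = 400, n_inf = 3, n_noise = 0, beta = 1, seed = 77)
  expect_setequal(backward_eliminate(d, c("inf1", "inf2", "inf3")),
                  c("inf1", "inf2", "inf3"))
  # determinism
  d2 <- sim_dataset(n = 80, n_inf = 2, n_noise = 5, beta = 0.5, seed = 5)
  feats <- paste0("noise", 1:5)
  expect_identical(backward_eliminate(d2, feats),
                   backward_eliminate(d2, feats))
})

test_that("VIF matches brute-force R-squared regressions", {
  set.seed(14)
  x <- matrix(rnorm(100 * 5), 100, 5)
  colnames(x) <- paste0("f", 1:5)
  x[, 5] <- x[, 1] + 0.5 * x[, 2] + rnorm(100, 0, 0.3)
  d <- tibble::as_tibble(x)
  rep <- vif_check(d, colnames(x))
  for (j in 1:5) {
    r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
    expect_equal(rep$vif[j], 1 / (1 - r2), tolerance = 1e-10)
  }
  # near-collinear pair is flagged
  d$f6 <- d$f1 + rnorm(100, 0, 0.01)
  rep2 <- vif_check(d, c("f1", "f6"))
  expect_true(all(rep2$flagged))
})

test_that("Cox fit recovers a doubled hazard within 3 SE", {
  set.seed(15)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  surv <- generate_survival(matrix(x), h0 = 0.03, beta = log(2),
                            censor_rate = 0, seed = 16)
  d <- dplyr::bind_cols(dplyr::select(surv, -true_lp),
                        tibble::tibble(grp = x))
  m <- fit_cox(d, "grp")
  # coefficients are per SD; undo the standardisation
  beta_raw <- unname(m$coefficients / m$scale)
  se <- unname(summary(m$fit)$coefficients[, "se(coef)"] / m$scale)
  expect_lt(abs(beta_raw - log(2)), 3 * se)
})

test_that("predictions are invariant to affine rescaling of a feature", {
  d <- sim_dataset(n = 120, n_inf = 2, n_noise = 0, seed = 17)
  m1 <- fit_cox(d, c("inf1", "inf2"))
  d2 <- dplyr::mutate(d, inf1 = 10 * inf1 + 3)
  m2 <- fit_cox(d2, c("inf1", "inf2"))
  expect_equal(predict(m1, d)$score, predict(m2, d2)$score,
               tolerance = 1e-6)
})

test_that("null coefficients give approximately uniform Wald p-values", {
  ps <- vapply(1:200, function(seed) {
    set.seed(seed + 4000)
    x <- matrix(rnorm(60), 60, 1)
    surv <- generate_survival(x, h0 = 0.05, beta = 0, censor_rate = 0,
                              seed = seed)
    d <- dplyr::bind_cols(dplyr::select(surv, -true_lp),
                          tibble::tibble(f = x[, 1]))
    m <- fit_cox(d, "f")
    summary(m$fit)$coefficients[, "Pr(>|z|)"]
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("combined model collapses to the MR model when DCE duplicates it", {
  d <- sim_dataset(n = 150, n_inf = 2, n_noise = 5, beta = 1, seed = 18)
  mr <- train_radiomics_model(
    dplyr::select(d, -dplyr::starts_with("noise")), seed = 18)
  pred <- predict(mr, d)$score
  d$dce1 <- pred
  d$dce2 <- 2 * pred + 1
  expect_warning(
    comb <- build_combined_model(mr, d, c("dce1", "dce2"), seed = 18),
    "returning the MR model")
  expect_true(isTRUE(comb$combined_fallback))
  expect_identical(comb$coefficients, mr$coefficients)
})

test_that("the MR prediction survives selection when it dominates", {
  d <- sim_dataset(n = 200, n_inf = 2, n_noise = 3, beta = 1, seed = 19)
  mr <- train_radiomics_model(
    dplyr::select(d, -dplyr::starts_with("noise")), seed = 19)
  # DCE features: pure noise, independent of hazard
  set.seed(20)
  d$dce1 <- rnorm(200); d$dce2 <- rnorm(200)
  comb <- build_combined_model(mr, d, c("dce1", "dce2"), seed = 19)
  expect_true("MR_prediction" %in% comb$features)
})

test_that("model tidiers expose coefficients and training metadata", {
  d <- sim_dataset(n = 150, n_inf = 2, n_noise = 2, seed = 22)
  m <- train_radiomics_model(d, seed = 22)
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  expect_equal(nrow(td), length(m$features))
  gl <- glance(m)
  expect_equal(gl$n, 150)
  expect_equal(gl$n_features, length(m$features))
  expect_false(is.na(gl$lambda))
})
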