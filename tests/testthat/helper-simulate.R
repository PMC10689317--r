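# covariate-level survival datasets for modeling/evaluation tests:
# `n_inf` informative standard-normal features with coefficient `beta` each,
# plus `n_noise` pure-noise features, exponential PH outcomes
sim_dataset <- function(n = 200, n_inf = 2, n_noise = 20, beta = 1,
                        h0 = 0.02, censor_rate = 0.3, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * n_inf), n, n_inf)
  colnames(z) <- paste0("inf", seq_len(n_inf))
  noise <- matrix(rnorm(n * n_noise), n, n_noise)
  if (n_noise > 0) colnames(noise) <- paste0("noise", seq_len(n_noise))
  surv <- generate_survival(z, h0 = h0, beta = rep(beta, n_inf),
                            censor_rate = censor_rate, seed = seed + 1000)
  dplyr::bind_cols(
    tibble::tibble(id = sprintf("S%04d", seq_len(n))),
    dplyr::select(surv, -true_lp),
    tibble::as_tibble(z),
    if (n_noise > 0) tibble::as_tibble(noise) else NULL)
}
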