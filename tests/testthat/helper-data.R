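# small reproducible designs and datasets built in code

rand_design <- function(n, k, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k)
  colnames(X) <- paste0("x", seq_len(k))
  X
}

# linear data with known coefficients; noise_sd = 0 gives exact recovery
linear_data <- function(n, betas, beta0 = 0, noise_sd = 0, seed = 1) {
  X <- rand_design(n, length(betas), seed)
  set.seed(seed + 1000)
  y <- beta0 + drop(X %*% betas) + rnorm(n, 0, noise_sd)
  list(x = X, y = y)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

eq1_coef <- c("(Intercept)" = 2.587, PSA = -0.007, DM = 0.163, MW = 0.010)
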