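# explicit leave-one-out oracle used in several tests
loo_oracle <- function(X, y) {
  n <- length(y)
  press <- sum(vapply(seq_len(n), function(i) {
    fit <- lm(y ~ ., data = data.frame(y = y[-i], X[-i, , drop = FALSE]))
    (y[i] - predict(fit, data.frame(X)[i, , drop = FALSE]))^2
  }, numeric(1)))
  1 - press / sum((y - mean(y))^2)
}

test_that("leave-one-out Q2 is exact for noiseless data and matches the refit oracle", {
  d0 <- linear_data(15, c(2, -1), noise_sd = 0, seed = 1)
  expect_equal(loo_q2(d0$x, d0$y), 1, tolerance = 1e-10)

  d <- linear_data(12, c(1, 0.5), noise_sd = 0.8, seed = 2)
  expect_equal(loo_q2(d$x, d$y), loo_oracle(d$x, d$y), tolerance = 1e-10)
})

test_that("Q2 never exceeds R2 and goes negative on pure noise", {
  q2s <- numeric(200)
  for (i in 1:200) {
    set.seed(i)
    X <- rand_design(40, 3, seed = i)
    y <- rnorm(40)
    fit <- qsar_mlr(X, y)
    q2s[i] <- loo_q2(fit)
    expect_lte(q2s[i], fit$r2)
  }
  expect_lte(mean(q2s), 0)
})

test_that("external validation reports both R2 flavours and guards degeneracy", {
  d <- linear_data(20, c(1, 1), noise_sd = 0.1, seed = 3)
  fit <- qsar_mlr(d$x, d$y)
  # perfect prediction
  ext <- external_r2(fit, d$x, drop(cbind(1, d$x) %*% coef(fit)))
  expect_equal(ext$r2_test, 1, tolerance = 1e-12)

  # 5-point toy table checked by hand-computed squared Pearson correlation
  obs <- c(5.2, 6.1, 6.8, 7.0, 5.9)
  Xt <- cbind(x1 = c(0.1, 0.9, 1.5, 1.8, 0.6), x2 = rep(0, 5))
  m <- structure(list(coefficients = c("(Intercept)" = 5, x1 = 1, x2 = 0),
                      y = obs), class = "qsar_mlr")
  pred <- 5 + Xt[, "x1"]
  ext2 <- external_r2(m, Xt, obs)
  r_hand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(ext2$r2_test, r_hand^2, tolerance = 1e-12)
  expect_equal(ext2$r2_pred, 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  expect_equal(ext2$n_ext, 5)

  constant_m <- structure(list(coefficients = c("(Intercept)" = 5, x1 = 0, x2 = 0),
                               y = obs), class = "qsar_mlr")
  expect_error(external_r2(constant_m, Xt, obs),
               class = "qsar_undefined_correlation_error")
})

test_that("VIF matches the auxiliary-regression oracle and its special cases", {
  # mutually orthogonal centered columns (orthogonal polynomial basis)
  X <- unclass(poly(1:30, 4))
  colnames(X) <- paste0("o", 1:4)
  expect_equal(unname(vif(X)), rep(1, 4), tolerance = 1e-8)

  expect_equal(unname(vif(matrix(rnorm(20), dimnames = list(NULL, "only")))), 1)

  # near-collinear pair blows up and equals the explicit oracle
  set.seed(5)
  x1 <- rnorm(50)
  X2 <- cbind(a = x1, b = x1 + rnorm(50, 0, 0.01), c = rnorm(50))
  v <- vif(X2)
  expect_gt(v[["a"]], 10)
  oracle <- vapply(1:3, function(j) {
    r2j <- summary(lm(X2[, j] ~ X2[, -j]))$r.squared
    1 / (1 - r2j)
  }, numeric(1))
  expect_lt(max(abs(unname(v) - oracle) / oracle), 1e-6)

  # invariance under column rescaling
  X3 <- X2
  X3[, "b"] <- X3[, "b"] * 1e3 + 5
  expect_equal(unname(vif(X3)), unname(v), tolerance = 1e-6)

  # exact collinearity is a value (Inf) with a flag, not an error
  X4 <- cbind(p = x1, q = 2 * x1, r = rnorm(50))
  v4 <- vif(X4)
  expect_true(is.infinite(v4[["p"]]))
  expect_true(all(c("p", "q") %in% attr(v4, "exact_collinear")))
})

test_that("VIF agrees with the car reference implementation", {
  set.seed(6)
  X <- rand_design(40, 3, seed = 6)
  X[, 2] <- X[, 2] + 0.6 * X[, 1]
  y <- rnorm(40)
  ours <- vif(X)
  theirs <- car::vif(lm(y ~ x1 + x2 + x3, data = data.frame(X, y = y)))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("y-scrambling collapses the correlation and is seed-reproducible", {
  ds <- split_dataset(generate_dataset(default_paperlike_spec(seed = 2)), 0.8, 1)
  fit <- qsar_mlr(ds, descriptors = c("PSA", "DM", "MW"))
  r1 <- y_randomization(fit, n_perm = 30, seed = 9)
  r2 <- y_randomization(fit, n_perm = 30, seed = 9)
  expect_identical(r1, r2)
  expect_lt(r1$mean_r2_rand, fit$r2)
  expect_equal(mean(r1$per_perm_r2), r1$mean_r2_rand, tolerance = 1e-12)
  expect_length(r1$per_perm_r2, 30)

  # injected identity permutation reproduces the baseline fit exactly
  rid <- y_randomization(fit, permutations = list(seq_len(fit$n)))
  expect_equal(rid$per_perm_r2, fit$r2, tolerance = 1e-12)
})

test_that("the cRp2 correction reduces correctly at its edges", {
  expect_equal(crp2(0.64, 0), 0.64, tolerance = 1e-12)
  expect_equal(crp2(0.64, 0.64), 0)
  expect_warning(v <- crp2(0.5, 0.7), class = "qsar_randomization_warning")
  expect_equal(v, 0)
})

test_that("the acceptance gate passes the reported statistics and flags single failures", {
  g <- gt_gate(r2 = 0.64, q2 = 0.56, n_ext = 10, f_pvalue = 1e-4)
  expect_true(all(g))
  g2 <- gt_gate(r2 = 0.59, q2 = 0.56, n_ext = 10, f_pvalue = 1e-4)
  expect_false(g2[["r2"]])
  expect_false(g2[["overall"]])
  expect_true(all(g2[c("n_ext", "r2_minus_q2", "q2", "p")]))
  g3 <- gt_gate(r2 = 0.86, q2 = 0.55, n_ext = 10, f_pvalue = 1e-4)
  expect_false(g3[["r2_minus_q2"]])
  expect_true(all(g3[c("r2", "n_ext", "q2", "p")]))
})

test_that("validate_model assembles a coherent report", {
  ds <- split_dataset(generate_dataset(default_paperlike_spec(seed = 4)), 0.8, 2)
  fit <- qsar_mlr(ds, descriptors = c("PSA", "DM", "MW"))
  rep <- validate_model(fit, ds, n_perm = 20, seed = 3)
  expect_s3_class(rep, "qsar_validation")
  expect_lte(rep$q2_cv, rep$r2)
  expect_true(all(rep$vif >= 1))
  expect_equal(rep$n_ext, 10)
  expect_equal(rep$r2_minus_q2, rep$r2 - rep$q2_cv)
})
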