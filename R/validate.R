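#' Leave-one-out cross-validated Q2
#'
#' Computes Q2 = 1 - PRESS/TSS, where PRESS accumulates the squared
#' prediction error of each compound when it is left out of the fit and TSS
#' is taken about the full-training mean. The deleted residuals are obtained
#' from the hat-matrix shortcut e_i / (1 - h_ii) and cross-checked internally
#' against explicit refits of all n leave-one-out models; the two routes must
#' agree to 1e-10.
#'
#' @param x a fitted [qsar_mlr()] model, or a descriptor matrix.
#' @param y training activities (when `x` is a matrix).
#' @return Q2 as a single number.
#' @export
loo_q2 <- function(x, y = NULL) {
  model <- if (inherits(x, "qsar_mlr")) x else qsar_mlr.default(x, y)
  n <- model$n
  if (n < model$k + 3L)
    qsar_stop("leave-one-out requires n >= k + 3", "qsar_size_error")
  h <- leverage(model$x)
  if (any(h > 1 - 1e-10)) {
    bad <- which(h > 1 - 1e-10)[1L]
    qsar_stop(sprintf("leave-one-out fold is singular when dropping record %s",
                      names(h)[bad] %||% bad), "qsar_fold_error")
  }
  e_loo <- model$residuals / (1 - h)

  # independent route: refit without each record in turn
  D <- cbind(1, model$x)
  e_refit <- vapply(seq_len(n), function(i) {
    fit <- stats::lm.fit(D[-i, , drop = FALSE], model$y[-i])
    model$y[i] - sum(D[i, ] * fit$coefficients)
  }, numeric(1L))
  if (max(abs(e_loo - e_refit)) > 1e-10)
    qsar_stop("internal inconsistency between hat-matrix and refit LOO residuals",
              "qsar_numerical_error")

  tss <- sum((model$y - mean(model$y))^2)
  1 - sum(e_loo^2) / tss
}

#' External (test-set) validation
#'
#' Predicts the held-out compounds and reports the squared Pearson
#' correlation between observed and predicted activity (the primary R2_test),
#' the predictive-R2 variant 1 - sum((y - yhat)^2) / sum((y - ybar_train)^2),
#' and the test RMSE.
#'
#' @param model a fitted [qsar_mlr()] model.
#' @param newdata test-set descriptors (matrix, data frame or [qsar_dataset];
#'   for a dataset, test-role records are used and `y` defaults to their
#'   activities).
#' @param y observed test activities.
#' @return list with `r2_test`, `r2_pred`, `rmse_test`, `n_ext`.
#' @export
external_r2 <- function(model, newdata, y = NULL) {
  if (inherits(newdata, "qsar_dataset")) {
    te <- dataset_rows(newdata, "test")
    if (is.null(y)) y <- te$y
    newdata <- te$x
  }
  pred <- predict(model, newdata)
  y <- as.numeric(y)
  if (!length(y))
    qsar_stop("empty test set", "qsar_size_error")
  if (length(y) != length(pred))
    qsar_stop("test observations and predictions differ in length", "qsar_size_error")
  if (stats::sd(pred) == 0 || stats::sd(y) == 0)
    qsar_stop("correlation undefined: constant predictions or observations",
              "qsar_undefined_correlation_error")
  list(r2_test = stats::cor(y, pred)^2,
       r2_pred = 1 - sum((y - pred)^2) / sum((y - mean(model$y))^2),
       rmse_test = sqrt(mean((y - pred)^2)),
       n_ext = length(y))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j comes from regressing descriptor j
#' (with intercept) on all other descriptors. A single-descriptor design has
#' VIF 1 by definition. Exact collinearity yields `Inf` (a value, not an
#' error) and is flagged in the `"exact_collinear"` attribute.
#'
#' @param x a fitted [qsar_mlr()] model or a descriptor matrix.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(x) {
  X <- if (inherits(x, "qsar_mlr")) x$x else as.matrix(x)
  k <- ncol(X)
  nms <- colnames(X) %||% paste0("x", seq_len(k))
  if (k == 1L)
    return(stats::setNames(1, nms))
  out <- numeric(k)
  for (j in seq_len(k)) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2j <- if (tss > 0) 1 - rss / tss else 0
    out[j] <- if (r2j > 1 - 1e-12) Inf else 1 / (1 - r2j)
  }
  out <- stats::setNames(out, nms)
  if (any(is.infinite(out)))
    attr(out, "exact_collinear") <- nms[is.infinite(out)]
  out
}

#' y-randomization correction statistic
#'
#' cRp2 = R * sqrt(R2 - mean r2_rand) with R = +sqrt(R2), the correction of
#' the training R2 for the chance correlation measured by the mean fit R2 of
#' models refitted on scrambled activities. Reduces to R2 when the scrambled
#' models carry no signal and to 0 when they match the real model; if the
#' scrambled mean reaches R2 the statistic is reported as 0 with a warning.
#'
#' @param r2 training R2 of the real model.
#' @param r2_rand_mean mean fit R2 over the scrambled models.
#' @return cRp2 as a single number.
#' @examples
#' crp2(0.64, 0.09)  # 0.5933...
#' @export
crp2 <- function(r2, r2_rand_mean) {
  stopifnot(is_number(r2), is_number(r2_rand_mean))
  if (r2_rand_mean >= r2) {
    if (r2_rand_mean > r2)
      qsar_warn("mean randomized r2 exceeds the model R2; cRp2 set to 0",
                "qsar_randomization_warning")
    return(0)
  }
  sqrt(r2) * sqrt(r2 - r2_rand_mean)
}

#' y-randomization (y-scrambling) test
#'
#' Refits the model on `n_perm` random permutations of the activity vector
#' (descriptors untouched; the identity permutation is rejected and redrawn)
#' and records each scrambled model's fit r2 and leave-one-out Q2. A real
#' structure-activity correlation should collapse under scrambling: the mean
#' scrambled r2 stays near its chance level k/(n-1), the mean scrambled Q2
#' goes negative, and the correction [crp2()] stays above 0.5.
#'
#' @param model a fitted [qsar_mlr()] model.
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for the permutation stream.
#' @param permutations optional list of integer permutations to use verbatim
#'   instead of random draws (testing hook).
#' @return an object of class `qsar_yrand`: `n_perm`, `per_perm_r2`,
#'   `per_perm_q2`, `mean_r2_rand`, `mean_q2_rand`, `crp2`, `baseline_r2`,
#'   `seed`.
#' @export
y_randomization <- function(model, n_perm = 100L, seed = 1L,
                            permutations = NULL) {
  stopifnot(inherits(model, "qsar_mlr"))
  if (!is_number(n_perm) || n_perm < 1L)
    qsar_stop("n_perm must be a positive integer", "qsar_config_error")
  n_perm <- as.integer(n_perm)
  n <- model$n
  if (is.null(permutations)) {
    permutations <- with_seed(seed, {
      lapply(seq_len(n_perm), function(i) {
        repeat {
          p <- sample.int(n)
          if (!identical(p, seq_len(n))) return(p)
        }
      })
    })
  } else n_perm <- length(permutations)

  r2s <- numeric(n_perm)
  q2s <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    m_i <- qsar_mlr.default(model$x, model$y[permutations[[i]]])
    r2s[i] <- m_i$r2
    q2s[i] <- loo_q2(m_i)
  }
  mean_r2 <- mean(r2s)
  structure(list(n_perm = n_perm, per_perm_r2 = r2s, per_perm_q2 = q2s,
                 mean_r2_rand = mean_r2, mean_q2_rand = mean(q2s),
                 crp2 = crp2(model$r2, mean_r2),
                 baseline_r2 = model$r2, seed = seed),
            class = "qsar_yrand")
}

#' @export
print.qsar_yrand <- function(x, ...) {
  cat(sprintf("y-randomization: %d scrambled models (seed %s)\n", x$n_perm,
              format(x$seed)))
  cat(sprintf("  mean r2(rand) = %.3f, mean Q2(rand) = %.3f (baseline R2 = %.3f)\n",
              x$mean_r2_rand, x$mean_q2_rand, x$baseline_r2))
  cat(sprintf("  cRp2 = %.3f (accept when > 0.5)\n", x$crp2))
  invisible(x)
}

#' Acceptance gate for a QSAR model
#'
#' Applies the conventional minimum requirements for an acceptable model:
#' training R2 at least 0.6, at least 5 external test compounds, R2 - Q2 at
#' most 0.3, Q2 above 0.5, and regression p-value below 0.05. Thresholds are
#' configurable.
#'
#' @param r2 training R2.
#' @param q2 leave-one-out Q2.
#' @param n_ext external test-set size.
#' @param f_pvalue p-value of the regression F test.
#' @param thresholds named list overriding any of `r2_min` (0.6),
#'   `n_ext_min` (5), `r2_q2_max` (0.3), `q2_min` (0.5), `p_max` (0.05).
#' @return named logical vector of verdicts (`r2`, `n_ext`, `r2_minus_q2`,
#'   `q2`, `p`) plus `overall`, their conjunction; the thresholds used are
#'   attached as attribute `"thresholds"`.
#' @export
gt_gate <- function(r2, q2, n_ext, f_pvalue, thresholds = list()) {
  th <- utils::modifyList(list(r2_min = 0.6, n_ext_min = 5, r2_q2_max = 0.3,
                               q2_min = 0.5, p_max = 0.05), thresholds)
  v <- c(r2 = r2 >= th$r2_min,
         n_ext = n_ext >= th$n_ext_min,
         r2_minus_q2 = (r2 - q2) <= th$r2_q2_max,
         q2 = q2 > th$q2_min,
         p = f_pvalue < th$p_max)
  structure(c(v, overall = all(v)), thresholds = th)
}

#' Full validation report
#'
#' Runs internal (leave-one-out), external, y-randomization and collinearity
#' validation of a fitted model and applies the acceptance gate.
#'
#' @param model a fitted [qsar_mlr()] model.
#' @param newdata test-set descriptors (or a [qsar_dataset] with test-role
#'   records).
#' @param y observed test activities (taken from the dataset if omitted).
#' @param n_perm permutations for [y_randomization()].
#' @param seed seed for the permutation stream.
#' @param thresholds gate thresholds, see [gt_gate()].
#' @return an object of class `qsar_validation` collecting `q2_cv`, the
#'   external metrics, `vif`, the randomization report and the gate verdicts.
#' @export
validate_model <- function(model, newdata, y = NULL, n_perm = 100L,
                           seed = 1L, thresholds = list()) {
  ext <- external_r2(model, newdata, y)
  q2 <- loo_q2(model)
  rand <- y_randomization(model, n_perm = n_perm, seed = seed)
  gate <- gt_gate(model$r2, q2, ext$n_ext, model$f_pvalue, thresholds)
  structure(list(r2 = model$r2, q2_cv = q2, r2_minus_q2 = model$r2 - q2,
                 r2_test = ext$r2_test, r2_pred = ext$r2_pred,
                 rmse_test = ext$rmse_test, n_ext = ext$n_ext,
                 f_stat = model$f_stat, f_pvalue = model$f_pvalue,
                 vif = vif(model), randomization = rand, gate = gate),
            class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  cat("QSAR validation report\n")
  cat(sprintf("  R2 = %.3f, Q2(LOO) = %.3f, R2 - Q2 = %.3f\n",
              x$r2, x$q2_cv, x$r2_minus_q2))
  cat(sprintf("  external: R2_test = %.3f (predictive %.3f), RMSE = %.3f, n = %d\n",
              x$r2_test, x$r2_pred, x$rmse_test, x$n_ext))
  cat(sprintf("  F = %.2f (p = %.3g)\n", x$f_stat, x$f_pvalue))
  cat("  VIF:", paste(sprintf("%s = %.2f", names(x$vif), x$vif), collapse = ", "), "\n")
  print(x$randomization)
  verdicts <- x$gate[setdiff(names(x$gate), "overall")]
  cat("  gate:", paste(sprintf("%s %s", names(verdicts),
                               ifelse(verdicts, "PASS", "FAIL")), collapse = ", "),
      sprintf("-> overall %s\n", ifelse(x$gate[["overall"]], "PASS", "FAIL")))
  invisible(x)
}
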