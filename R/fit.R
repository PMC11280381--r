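#' Fit a multiple linear regression QSAR model
#'
#' Fits the activity model pIC50 = b0 + b1 x1 + ... + bK xK by ordinary least
#' squares with an intercept, solved through a QR decomposition (the normal
#' equations are never formed). The returned object carries the fit
#' statistics conventional in QSAR reporting: the coefficient of
#' determination R2 = 1 - RSS/TSS, RMSE = sqrt(RSS/n), the residual standard
#' deviation sqrt(RSS/(n-K-1)) used to studentize residuals, the Fisher
#' statistic F = (R2/K) / ((1-R2)/(n-K-1)) with its p-value, and standardized
#' coefficients beta_j * sd(x_j)/sd(y) (population standard deviations).
#'
#' @param x a [qsar_dataset] (training-role records are used) or a numeric
#'   descriptor matrix with column names.
#' @param ... passed to methods.
#' @return an object of class `qsar_mlr` with methods for [print()],
#'   [summary()], [coef()], [predict()], [residuals()], [fitted()],
#'   [simulate()] and [plot()].
#' @examples
#' ds <- generate_dataset(default_paperlike_spec(seed = 1))
#' fit <- qsar_mlr(ds, descriptors = c("PSA", "DM", "MW"))
#' summary(fit)
#' @export
qsar_mlr <- function(x, ...) UseMethod("qsar_mlr")

#' @rdname qsar_mlr
#' @param descriptors descriptor names to use; default all descriptors in the
#'   dataset.
#' @export
qsar_mlr.qsar_dataset <- function(x, descriptors = NULL, ...) {
  tr <- dataset_rows(x, "train")
  descriptors <- descriptors %||% colnames(tr$x)
  missing <- setdiff(descriptors, colnames(tr$x))
  if (length(missing))
    qsar_stop(sprintf("descriptor(s) not in dataset: %s",
                      paste(missing, collapse = ", ")), "qsar_key_error")
  fit <- qsar_mlr.default(tr$x[, descriptors, drop = FALSE], tr$y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname qsar_mlr
#' @param y numeric vector of training activities (default method).
#' @export
qsar_mlr.default <- function(x, y, ...) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  k <- ncol(X)
  if (length(y) != n)
    qsar_stop("x and y dimensions disagree", "qsar_size_error")
  if (n < k + 2L)
    qsar_stop(sprintf("need at least k + 2 = %d training compounds, got %d",
                      k + 2L, n), "qsar_size_error")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    qsar_stop("non-finite values in training data", "qsar_validation_error")

  D <- cbind("(Intercept)" = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    aliased <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    qsar_stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                      paste(aliased, collapse = ", ")), "qsar_singular_error")
  }
  beta <- qr.coef(qrD, y)
  fitted <- drop(D %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= .Machine$double.eps * max(1, sum(y^2))) {
    qsar_warn("response is constant; R2 reported as 0", "qsar_degenerate_warning")
    r2 <- 0
  } else r2 <- 1 - rss / tss
  df_res <- n - k - 1L
  residual_sd <- sqrt(rss / df_res)
  f_stat <- if (r2 < 1) (r2 / k) / ((1 - r2) / df_res) else Inf
  f_pvalue <- stats::pf(f_stat, k, df_res, lower.tail = FALSE)

  sdy <- sd_pop(y)
  std_coef <- if (sdy > 0)
    beta[-1L] * apply(X, 2L, sd_pop) / sdy
  else stats::setNames(rep(NA_real_, k), colnames(X))

  structure(list(coefficients = beta, n = n, k = k, r2 = r2,
                 rmse = sqrt(rss / n), residual_sd = residual_sd,
                 f_stat = f_stat, f_pvalue = f_pvalue,
                 standardized_coefficients = std_coef,
                 fitted.values = stats::setNames(fitted, rownames(X)),
                 residuals = stats::setNames(resid, rownames(X)),
                 x = X, y = y, qr = qrD, call = match.call()),
            class = "qsar_mlr")
}

#' @export
coef.qsar_mlr <- function(object, ...) object$coefficients

#' @export
residuals.qsar_mlr <- function(object, ...) object$residuals

#' @export
fitted.qsar_mlr <- function(object, ...) object$fitted.values

#' Predict activity for new compounds
#'
#' Evaluates intercept + sum(coefficient * descriptor value). `newdata` may
#' be a matrix, a data frame, a [qsar_dataset], or a single named numeric
#' vector/list; it must expose every model descriptor by name (extra columns
#' and any column order are fine).
#'
#' @param object a fitted [qsar_mlr()] model.
#' @param newdata descriptor values for the compounds to predict.
#' @param ... unused.
#' @return named numeric vector of predicted pIC50.
#' @export
predict.qsar_mlr <- function(object, newdata, ...) {
  if (missing(newdata)) return(fitted(object))
  wanted <- names(coef(object))[-1L]
  if (inherits(newdata, "qsar_dataset")) newdata <- newdata$descriptors
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- matrix(newdata, nrow = 1L, dimnames = list(NULL, names(newdata)))
  if (is.list(newdata) && !is.data.frame(newdata))
    newdata <- as.data.frame(newdata)
  newdata <- as.matrix(newdata)
  missing_d <- setdiff(wanted, colnames(newdata))
  if (length(missing_d))
    qsar_stop(sprintf("missing descriptor(s): %s", paste(missing_d, collapse = ", ")),
              "qsar_key_error")
  X <- newdata[, wanted, drop = FALSE]
  storage.mode(X) <- "double"
  drop(cbind(1, X) %*% coef(object))
}

#' Standardized regression coefficients
#'
#' Returns beta_j * sd(x_j)/sd(y) with population (1/n) standard deviations,
#' the scale-free contributions used to rank descriptor importance. For a
#' single-descriptor model this equals the Pearson correlation between the
#' descriptor and the activity.
#'
#' @param model a fitted [qsar_mlr()] model.
#' @return named numeric vector of standardized coefficients, with the
#'   descriptor ranking (by absolute value, decreasing) attached as attribute
#'   `"ranking"`.
#' @export
standardized_coefficients <- function(model) {
  stopifnot(inherits(model, "qsar_mlr"))
  b <- model$standardized_coefficients
  if (anyNA(b))
    qsar_stop("response has zero variance; standardized coefficients undefined",
              "qsar_degenerate_error")
  structure(b, ranking = names(b)[order(-abs(b))])
}

#' @export
print.qsar_mlr <- function(x, digits = 4, ...) {
  cat("Linear QSAR model (OLS)\n")
  co <- coef(x)
  eq <- paste0(format(co[1L], digits = digits),
               paste0(sprintf(" %s %s %s", ifelse(co[-1L] < 0, "-", "+"),
                              format(abs(co[-1L]), digits = digits),
                              names(co)[-1L]), collapse = ""))
  cat("  pIC50 =", eq, "\n")
  cat(sprintf("  n = %d, K = %d, R2 = %.3f, RMSE = %.3f, F = %.2f (p = %.3g)\n",
              x$n, x$k, x$r2, x$rmse, x$f_stat, x$f_pvalue))
  invisible(x)
}

#' @export
summary.qsar_mlr <- function(object, ...) {
  sb <- object$standardized_coefficients
  structure(list(model = object,
                 coefficients = coef(object),
                 standardized = sb,
                 ranking = if (!anyNA(sb)) names(sb)[order(-abs(sb))] else NULL),
            class = "summary.qsar_mlr")
}

#' @export
print.summary.qsar_mlr <- function(x, ...) {
  print(x$model)
  if (!is.null(x$ranking)) {
    cat("  standardized coefficients:\n")
    for (nm in x$ranking)
      cat(sprintf("    %-12s %+.4f\n", nm, x$standardized[[nm]]))
    cat("  contribution order:", paste(x$ranking, collapse = " > "), "\n")
  }
  invisible(x)
}

#' @export
simulate.qsar_mlr <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() fitted(object) + stats::rnorm(object$n, 0, object$residual_sd)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_seed(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(names(fitted(object)),
                                       paste0("sim_", seq_len(nsim)))))
}

#' @export
plot.qsar_mlr <- function(x, ...) {
  graphics::plot(fitted(x), x$y, xlab = "Predicted pIC50",
                 ylab = "Observed pIC50",
                 main = sprintf("Training fit (R2 = %.2f)", x$r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
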