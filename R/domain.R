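#' Leverage (hat) values
#'
#' Computes h_i = x_i' (X'X)^-1 x_i for each query row against the training
#' design, with the design augmented by an intercept column (so training
#' leverages sum to K+1 and the centroid of the training descriptors has
#' leverage exactly 1/n). Solved through the QR decomposition of the
#' augmented design rather than by inverting X'X.
#'
#' @param x_train training descriptor matrix (or a fitted [qsar_mlr()] model,
#'   whose training matrix is used).
#' @param x_query rows to evaluate; defaults to the training rows.
#' @return named numeric vector of leverages.
#' @export
leverage <- function(x_train, x_query = NULL) {
  X <- if (inherits(x_train, "qsar_mlr")) x_train$x else as.matrix(x_train)
  Q <- if (is.null(x_query)) X else {
    q <- if (inherits(x_query, "qsar_dataset")) x_query$descriptors else as.matrix(x_query)
    if (!is.null(colnames(X)) && !is.null(colnames(q))) {
      missing_d <- setdiff(colnames(X), colnames(q))
      if (length(missing_d))
        qsar_stop(sprintf("query is missing descriptor(s): %s",
                          paste(missing_d, collapse = ", ")), "qsar_key_error")
      q <- q[, colnames(X), drop = FALSE]
    }
    q
  }
  D <- cbind(1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    qsar_stop("training design is singular; leverages undefined", "qsar_singular_error")
  R <- qr.R(qrD)[, order(qrD$pivot), drop = FALSE]
  # h_i = || R^-T d_i ||^2  since X'X = R'R
  tmp <- forwardsolve(t(R), t(cbind(1, Q)))
  stats::setNames(colSums(tmp^2), rownames(Q))
}

#' Leverage threshold of the applicability domain
#'
#' The conventional cutoff h* = 3 (K + 1) / n, where K is the number of model
#' descriptors and n the number of training compounds. A threshold of 1 or
#' more is vacuous (every leverage is at most 1 for training compounds) and
#' triggers a warning.
#'
#' @param k number of descriptors (K >= 1).
#' @param n number of training compounds.
#' @return h* as a single number.
#' @examples
#' leverage_threshold(3, 40)  # 0.3
#' @export
leverage_threshold <- function(k, n) {
  if (!is_number(k) || !is_number(n) || k < 1 || n < 1)
    qsar_stop("k and n must be positive", "qsar_domain_error")
  h_star <- 3 * (k + 1) / n
  if (h_star >= 1)
    qsar_warn(sprintf("leverage threshold %.3f >= 1 is vacuous", h_star),
              "qsar_vacuous_threshold_warning")
  h_star
}

#' Williams classification of compounds
#'
#' Classifies compounds against the two applicability-domain cutoffs: a
#' compound with leverage above `h_star` is a structural outlier, one with
#' absolute standardized residual above `residual_limit` a response outlier
#' (`"both"` when both cutoffs are exceeded, `"inside"` otherwise).
#' Compounds without an observed activity (standardized residual `NA`, e.g.
#' designed candidates) are classified on leverage alone.
#'
#' @param leverage numeric vector of leverages.
#' @param sdr standardized residuals (`NA` allowed), recycled if length 1.
#' @param h_star leverage cutoff.
#' @param residual_limit standardized-residual cutoff (default 3).
#' @return character vector of categories: `"inside"`,
#'   `"structural_outlier"`, `"response_outlier"` or `"both"`.
#' @export
williams_classify <- function(leverage, sdr = NA_real_, h_star,
                              residual_limit = 3) {
  sdr <- rep_len(sdr, length(leverage))
  lev_out <- leverage > h_star
  res_out <- !is.na(sdr) & abs(sdr) > residual_limit
  ifelse(lev_out & res_out, "both",
         ifelse(lev_out, "structural_outlier",
                ifelse(res_out, "response_outlier", "inside")))
}

#' Leverage-based applicability domain
#'
#' Builds the Williams-plot table for a fitted model: per-compound leverage
#' against the training design, standardized residuals (raw residual divided
#' by the model's residual standard deviation) for compounds with an observed
#' activity, and the domain category from [williams_classify()]. With a
#' dataset argument, training, test and candidate records are all assessed;
#' test and candidate residuals use the training-fit residual scale, and
#' candidates (no activity) are classified on leverage alone.
#'
#' @param model a fitted [qsar_mlr()] model.
#' @param dataset optional [qsar_dataset] to assess; default is the model's
#'   own training data.
#' @param h_star leverage cutoff; default [leverage_threshold()] with the
#'   model's K and n. The value used is always recorded in the report, so a
#'   stricter or looser cutoff can be imposed explicitly.
#' @param residual_limit standardized-residual cutoff (default 3).
#' @param studentized if `TRUE`, use internally studentized residuals
#'   (dividing each training residual additionally by sqrt(1 - h_i)) instead
#'   of the plain standardized residuals.
#' @return an object of class `qsar_ad`: the Williams table (`id`, `role`,
#'   `leverage`, `sdr`, `category`) plus `h_star` and `residual_limit`.
#' @export
applicability_domain <- function(model, dataset = NULL, h_star = NULL,
                                 residual_limit = 3, studentized = FALSE) {
  stopifnot(inherits(model, "qsar_mlr"))
  h_star <- h_star %||% leverage_threshold(model$k, model$n)
  if (is.null(dataset)) {
    ids <- rownames(model$x) %||% sprintf("T%02d", seq_len(model$n))
    h <- leverage(model$x)
    resid <- model$residuals
    role <- rep("train", model$n)
  } else {
    ids <- dataset$ids
    h <- leverage(model$x, dataset$descriptors)
    resid <- dataset$pic50 - predict(model, dataset)
    role <- dataset$role
  }
  # a numerically perfect fit has no residual scale: residuals at rounding
  # level get SDR 0 rather than 0/0 noise
  eps <- sqrt(.Machine$double.eps) * max(1, abs(model$y))
  sdr <- if (model$residual_sd > eps) resid / model$residual_sd
         else ifelse(abs(resid) <= eps, 0, sign(resid) * Inf)
  if (studentized) {
    tr <- role == "train"
    sdr[tr] <- sdr[tr] / sqrt(pmax(1 - h[tr], .Machine$double.eps))
  }
  tab <- data.frame(id = ids, role = role, leverage = unname(h),
                    sdr = unname(sdr),
                    category = williams_classify(h, sdr, h_star, residual_limit),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, h_star = h_star,
                 residual_limit = residual_limit),
            class = "qsar_ad")
}

#' @export
print.qsar_ad <- function(x, ...) {
  cat(sprintf("Applicability domain (h* = %.3f, |SDR| <= %g)\n",
              x$h_star, x$residual_limit))
  print(table(role = x$table$role, category = x$table$category))
  invisible(x)
}

#' Williams plot
#'
#' Standardized residual against leverage with the h* and residual-limit
#' cutoffs drawn in. Compounds without an observed activity (candidates) are
#' drawn at SDR 0 with an open triangle, since only their leverage is
#' defined.
#'
#' @param x a `qsar_ad` report from [applicability_domain()].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.qsar_ad <- function(x, ...) {
  tab <- x$table
  sdr <- ifelse(is.na(tab$sdr), 0, tab$sdr)
  pch <- ifelse(is.na(tab$sdr), 2L, ifelse(tab$role == "test", 17L, 16L))
  ylim <- range(c(sdr, -x$residual_limit - 0.5, x$residual_limit + 0.5))
  xlim <- range(c(tab$leverage, x$h_star * 1.1, 0))
  graphics::plot(tab$leverage, sdr, pch = pch, xlab = "Leverage h",
                 ylab = "Standardized residual", xlim = xlim, ylim = ylim,
                 main = "Williams plot", ...)
  graphics::abline(v = x$h_star, lty = 2)
  graphics::abline(h = c(-1, 1) * x$residual_limit, lty = 3)
  invisible(x)
}
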