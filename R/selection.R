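#' Descriptor-selection settings
#'
#' Thresholds for pruning uninformative descriptor columns and for the greedy
#' correlation-based subset selection. The defaults target a parsimonious
#' three-descriptor model: variance at or below `variance_floor` marks a
#' constant column; candidate descriptors must correlate with the activity at
#' `|r| >= activity_r_min` and may not correlate with an already accepted
#' descriptor beyond `pairwise_r_max`.
#'
#' @param variance_floor columns with variance `<=` this are dropped (default
#'   `1e-10`, i.e. numerically constant).
#' @param pairwise_r_max maximum allowed absolute Pearson correlation between
#'   two selected descriptors (default 0.9).
#' @param activity_r_min minimum absolute Pearson correlation with the
#'   activity for a descriptor to be eligible (default 0.1).
#' @param max_descriptors maximum size of the selected subset (default 3).
#' @return a `qsar_selection_config` list.
#' @export
selection_config <- function(variance_floor = 1e-10, pairwise_r_max = 0.9,
                             activity_r_min = 0.1, max_descriptors = 3L) {
  stopifnot(is_number(variance_floor), variance_floor >= 0,
            is_number(pairwise_r_max), pairwise_r_max > 0, pairwise_r_max <= 1,
            is_number(activity_r_min), activity_r_min >= 0, activity_r_min < 1,
            is_number(max_descriptors), max_descriptors >= 1)
  structure(list(variance_floor = variance_floor,
                 pairwise_r_max = pairwise_r_max,
                 activity_r_min = activity_r_min,
                 max_descriptors = as.integer(max_descriptors)),
            class = "qsar_selection_config")
}

#' Prune constant and duplicate descriptors
#'
#' Removes descriptor columns that carry no information: columns whose
#' variance is at or below the configured floor ("zero variance"), and exact
#' duplicates of an earlier column ("duplicate"; the first column in file
#' order is kept). Each removal is logged with the rule that fired.
#'
#' @param ds a [qsar_dataset].
#' @param config a [selection_config()].
#' @return a list with elements `dataset` (the pruned [qsar_dataset]) and
#'   `log` (data frame with columns `descriptor`, `rule`).
#' @export
prune_descriptors <- function(ds, config = selection_config()) {
  X <- ds$descriptors
  if (ncol(X) < 1L)
    qsar_stop("dataset has no descriptors", "qsar_prune_error")
  vars <- apply(X, 2L, stats::var)
  drop_const <- vars <= config$variance_floor
  dup_of <- rep(NA_integer_, ncol(X))
  for (j in seq_len(ncol(X))[-1L]) {
    for (i in seq_len(j - 1L)) {
      if (!drop_const[i] && is.na(dup_of[i]) && identical(X[, i], X[, j])) {
        dup_of[j] <- i
        break
      }
    }
  }
  drop_dup <- !is.na(dup_of) & !drop_const
  log <- data.frame(
    descriptor = colnames(X)[drop_const | drop_dup],
    rule = c(rep("zero variance", sum(drop_const)),
             rep("duplicate", sum(drop_dup)))[order(c(which(drop_const), which(drop_dup)))],
    stringsAsFactors = FALSE)
  keep <- !(drop_const | drop_dup)
  if (!any(keep)) {
    cond <- errorCondition("all descriptors removed by pruning",
                           removal_log = log,
                           class = c("qsar_prune_error", "qsar_error"))
    stop(cond)
  }
  ds$descriptors <- X[, keep, drop = FALSE]
  list(dataset = ds, log = log)
}

#' Greedy correlation-based descriptor selection
#'
#' Ranks descriptors by their absolute Pearson correlation with the activity
#' (computed on training records only) and accepts them in rank order,
#' skipping any descriptor that correlates too weakly with the activity or
#' too strongly with an already accepted descriptor, until
#' `max_descriptors` are chosen. Ties in the ranking are broken by column
#' order. Zero-variance columns are ineligible.
#'
#' @param ds a [qsar_dataset] with training activities.
#' @param config a [selection_config()].
#' @return character vector of selected descriptor names, with the activity
#'   correlations attached as attribute `"activity_r"`.
#' @export
select_descriptors <- function(ds, config = selection_config()) {
  tr <- dataset_rows(ds, "train")
  if (nrow(tr$x) < 3L)
    qsar_stop("need at least 3 training records for selection", "qsar_size_error")
  X <- tr$x
  y <- tr$y
  vars <- apply(X, 2L, stats::var)
  r_act <- rep(0, ncol(X))
  ok <- vars > 0
  r_act[ok] <- suppressWarnings(as.vector(stats::cor(X[, ok, drop = FALSE], y)))
  r_act[!is.finite(r_act)] <- 0
  names(r_act) <- colnames(X)
  ord <- order(-abs(r_act), seq_along(r_act))  # ties by column order
  chosen <- integer(0)
  for (j in ord) {
    if (length(chosen) >= config$max_descriptors) break
    if (abs(r_act[j]) < config$activity_r_min) next
    if (length(chosen)) {
      rp <- suppressWarnings(abs(stats::cor(X[, j], X[, chosen, drop = FALSE])))
      rp[!is.finite(rp)] <- 0
      if (any(rp > config$pairwise_r_max)) next
    }
    chosen <- c(chosen, j)
  }
  if (!length(chosen))
    qsar_stop("no descriptor meets the selection thresholds",
              "qsar_selection_error")
  structure(colnames(X)[chosen], activity_r = r_act[chosen])
}
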