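#' Run the full QSAR pipeline
#'
#' Executes the whole workflow in order — data loading or synthesis,
#' descriptor pruning and selection, train/test split, model fitting,
#' validation, applicability-domain assessment and (optionally) candidate
#' screening — and writes every report to `output_dir`: `model.json`,
#' `validation.json` and `validation.csv`, `williams.csv` (columns `id`,
#' `role`, `leverage`, `sdr`, `category`), `screening.csv` when candidates
#' are supplied, and `run_log.txt` recording every threshold and seed
#' actually applied (selected descriptors, h*, gate thresholds). Identical
#' configuration and seeds produce byte-identical reports.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with entries:
#' \describe{
#'   \item{data}{`list(file=, activity_col=, id_col=, role_col=)` — or}
#'   \item{synthetic}{`list(seed=)` for the default generator spec, or a
#'     [synthetic_spec()]; exactly one of `data`/`synthetic` must be given.}
#'   \item{split}{`list(fraction = 0.8, seed = 1)`.}
#'   \item{selection}{arguments for [selection_config()].}
#'   \item{validation}{`list(n_perm = 100, seed = 1, thresholds = list())`.}
#'   \item{domain}{`list(h_star = NULL, residual_limit = 3)`.}
#'   \item{screening}{`list(candidates = "table4_candidates" or a file path,
#'     reference_pic50 = ...)`; omit to skip screening.}
#' }
#'
#' @param config named list or YAML file path.
#' @param output_dir directory for the run artifacts (created if missing).
#' @return invisibly, a list with the fitted model, validation report, AD
#'   report, screening table and the paths written.
#' @export
run_qsar_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    qsar_stop("config must be a named list or a YAML file path", "qsar_config_error")
  if (is.null(config$data) == is.null(config$synthetic))
    qsar_stop("exactly one of config$data and config$synthetic must be set",
              "qsar_config_error")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stale <- file.path(output_dir, "_STALE")
  writeLines("run in progress; outputs incomplete", stale)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, qsar_error = function(e) {
      writeLines(c(sprintf("run failed at stage '%s': %s", name,
                           conditionMessage(e)), log_lines), stale)
      stop(errorCondition(sprintf("stage '%s': %s", name, conditionMessage(e)),
                          stage = name,
                          class = c("qsar_pipeline_error", class(e))))
    })
  }

  ds <- stage("data", {
    if (!is.null(config$data)) {
      d <- config$data
      note("data: file %s (activity column %s)", d$file,
           d$activity_col %||% "pIC50")
      read_compound_table(d$file, id_col = d$id_col %||% "id",
                          activity_col = d$activity_col %||% "pIC50",
                          ic50_col = d$ic50_col, unit_col = d$unit_col,
                          role_col = d$role_col)
    } else {
      spec <- if (inherits(config$synthetic, "qsar_synth_spec")) config$synthetic
              else default_paperlike_spec(seed = config$synthetic$seed %||% 1L)
      note("data: synthetic, n = %d, seed = %d", spec$n, spec$seed)
      generate_dataset(spec)
    }
  })

  sel_cfg <- do.call(selection_config, config$selection %||% list())
  sel <- stage("selection", {
    pruned <- prune_descriptors(ds, sel_cfg)
    for (i in seq_len(nrow(pruned$log)))
      note("prune: removed %s (%s)", pruned$log$descriptor[i], pruned$log$rule[i])
    names <- as.character(select_descriptors(pruned$dataset, sel_cfg))
    note("selection: %s (thresholds: pairwise |r| <= %g, activity |r| >= %g, max %d)",
         paste(names, collapse = ", "), sel_cfg$pairwise_r_max,
         sel_cfg$activity_r_min, sel_cfg$max_descriptors)
    list(dataset = pruned$dataset, names = names)
  })

  split_cfg <- config$split %||% list()
  ds_split <- stage("split", {
    fr <- split_cfg$fraction %||% 0.8
    sd <- split_cfg$seed %||% 1L
    note("split: fraction %g, seed %d", fr, sd)
    split_dataset(sel$dataset, fr, sd)
  })

  model <- stage("fit", qsar_mlr(ds_split, descriptors = sel$names))

  val_cfg <- config$validation %||% list()
  val <- stage("validation",
    validate_model(model, ds_split, n_perm = val_cfg$n_perm %||% 100L,
                   seed = val_cfg$seed %||% 1L,
                   thresholds = val_cfg$thresholds %||% list()))
  th <- attr(val$gate, "thresholds")
  note("gate thresholds: R2 >= %g, n_ext >= %g, R2-Q2 <= %g, Q2 > %g, p < %g",
       th$r2_min, th$n_ext_min, th$r2_q2_max, th$q2_min, th$p_max)

  dom_cfg <- config$domain %||% list()
  ad <- stage("domain",
    applicability_domain(model, ds_split, h_star = dom_cfg$h_star,
                         residual_limit = dom_cfg$residual_limit %||% 3))
  note("domain: h* = %.4f, |SDR| limit = %g", ad$h_star, ad$residual_limit)

  screening <- NULL
  if (!is.null(config$screening)) {
    screening <- stage("screening", {
      sc <- config$screening
      cand <- if (!is.null(sc$candidates) && file.exists(sc$candidates %||% ""))
        read_compound_table(sc$candidates, role_col = NULL)
      else load_fixture(sc$candidates %||% "table4_candidates")
      scr_cfg <- screening_config(reference_pic50 = sc$reference_pic50 %||% 7.259)
      cand_ad <- applicability_domain(model, cand, h_star = dom_cfg$h_star)
      note("screening: %d candidates, reference pIC50 = %g",
           length(cand$ids), scr_cfg$reference_pic50)
      screen_candidates(model, cand, scr_cfg, ad = cand_ad)
    })
  }

  paths <- stage("report", {
    p <- c(model = file.path(output_dir, "model.json"),
           validation_json = file.path(output_dir, "validation.json"),
           validation_csv = file.path(output_dir, "validation.csv"),
           williams = file.path(output_dir, "williams.csv"),
           log = file.path(output_dir, "run_log.txt"))
    jsonlite::write_json(list(
      coefficients = as.list(coef(model)),
      n = model$n, k = model$k, r2 = model$r2, rmse = model$rmse,
      residual_sd = model$residual_sd, f_stat = model$f_stat,
      f_pvalue = model$f_pvalue,
      standardized_coefficients = as.list(model$standardized_coefficients),
      descriptors = sel$names),
      p[["model"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(list(
      r2 = val$r2, q2_cv = val$q2_cv, r2_minus_q2 = val$r2_minus_q2,
      r2_test = val$r2_test, r2_pred = val$r2_pred,
      rmse_test = val$rmse_test, n_ext = val$n_ext,
      f_stat = val$f_stat, f_pvalue = val$f_pvalue,
      vif = as.list(val$vif),
      randomization = list(n_perm = val$randomization$n_perm,
                           mean_r2_rand = val$randomization$mean_r2_rand,
                           mean_q2_rand = val$randomization$mean_q2_rand,
                           crp2 = val$randomization$crp2,
                           seed = val$randomization$seed),
      gate = as.list(val$gate), gate_thresholds = th),
      p[["validation_json"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    gate_df <- data.frame(metric = names(val$gate),
                          pass = as.logical(val$gate))
    utils::write.csv(gate_df, p[["validation_csv"]], row.names = FALSE)
    utils::write.csv(ad$table, p[["williams"]], row.names = FALSE)
    if (!is.null(screening)) {
      p[["screening"]] <- file.path(output_dir, "screening.csv")
      utils::write.csv(as.data.frame(screening), p[["screening"]],
                       row.names = FALSE)
    }
    writeLines(log_lines, p[["log"]])
    p
  })

  unlink(stale)
  invisible(list(dataset = ds_split, descriptors = sel$names, model = model,
                 validation = val, domain = ad, screening = screening,
                 paths = paths))
}
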