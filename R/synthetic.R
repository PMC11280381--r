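#' Specification of a synthetic descriptor-activity dataset
#'
#' Describes a dataset in which a few informative descriptors drive the
#' activity through a linear model with Gaussian noise, surrounded by
#' independent nuisance descriptors plus optional constant and duplicate
#' columns (the degenerate columns a real descriptor table contains and the
#' pruning stage must remove). Informative descriptors are drawn from a
#' correlated multivariate normal distribution.
#'
#' @param n number of compounds.
#' @param betas coefficients of the informative descriptors.
#' @param beta0 intercept of the activity model.
#' @param descriptor_names,descriptor_means,descriptor_sds names, means and
#'   standard deviations of the informative descriptors.
#' @param inter_correlation correlation matrix of the informative
#'   descriptors (symmetric positive definite).
#' @param noise_sd standard deviation of the activity noise.
#' @param k_noise number of independent standard-normal nuisance descriptors.
#' @param n_constant_cols,n_duplicate_cols degenerate columns to append.
#' @param seed integer seed; generation is fully determined by it.
#' @return a `qsar_synth_spec` list.
#' @seealso [default_paperlike_spec()], [generate_dataset()]
#' @export
synthetic_spec <- function(n, betas, beta0 = 0,
                           descriptor_names = paste0("X", seq_along(betas)),
                           descriptor_means = rep(0, length(betas)),
                           descriptor_sds = rep(1, length(betas)),
                           inter_correlation = diag(length(betas)),
                           noise_sd = 1, k_noise = 0L,
                           n_constant_cols = 0L, n_duplicate_cols = 0L,
                           seed = 1L) {
  k <- length(betas)
  stopifnot(is_number(n), n >= 1, k >= 1,
            length(descriptor_names) == k,
            length(descriptor_means) == k, length(descriptor_sds) == k,
            is_number(noise_sd), noise_sd >= 0,
            k_noise >= 0, n_constant_cols >= 0, n_duplicate_cols >= 0)
  inter_correlation <- as.matrix(inter_correlation)
  if (!isTRUE(all.equal(inter_correlation, t(inter_correlation))) ||
      inherits(try(chol(inter_correlation), silent = TRUE), "try-error"))
    qsar_stop("inter_correlation must be symmetric positive definite",
              "qsar_spec_error")
  structure(list(n = as.integer(n), betas = as.numeric(betas), beta0 = beta0,
                 descriptor_names = descriptor_names,
                 descriptor_means = as.numeric(descriptor_means),
                 descriptor_sds = as.numeric(descriptor_sds),
                 inter_correlation = inter_correlation,
                 noise_sd = noise_sd, k_noise = as.integer(k_noise),
                 n_constant_cols = as.integer(n_constant_cols),
                 n_duplicate_cols = as.integer(n_duplicate_cols),
                 seed = as.integer(seed)),
            class = "qsar_synth_spec")
}

#' Default study-like synthetic specification
#'
#' The stand-in for the modelled descriptor table: 50 compounds and ~50
#' descriptors of which three (polar surface area PSA in square Angstrom,
#' dipole moment DM in Debye, molecular weight MW in g/mol) drive the
#' activity with coefficients (-0.007, +0.163, +0.010) about an intercept of
#' 2.587, plus 45 nuisance descriptors, one constant and one duplicate
#' column. Descriptor location/scale (means 90, 3.4, 380; sds 20, 1.1, 22)
#' and the driver correlation structure (PSA against the others -0.5, DM-MW
#' +0.5) are chosen so that generated activities fall predominantly in the
#' observed pIC50 range (about 5.3-7.3) and collinearity stays mild
#' (variance inflation around 1.4-2). The activity noise (sd 0.34 pIC50
#' units) is calibrated so the median training R2 at n = 50 is about 0.64.
#'
#' @param seed integer seed for [generate_dataset()].
#' @return a [synthetic_spec()].
#' @export
default_paperlike_spec <- function(seed = 1L) {
  synthetic_spec(
    n = 50L,
    betas = c(-0.007, 0.163, 0.010),
    beta0 = 2.587,
    descriptor_names = c("PSA", "DM", "MW"),
    descriptor_means = c(90, 3.4, 380),
    descriptor_sds = c(20, 1.1, 22),
    inter_correlation = matrix(c(1, -0.5, -0.5,
                                 -0.5, 1, 0.5,
                                 -0.5, 0.5, 1), 3L, 3L),
    noise_sd = 0.34,
    k_noise = 45L,
    n_constant_cols = 1L,
    n_duplicate_cols = 1L,
    seed = seed)
}

#' Generate a synthetic dataset
#'
#' Draws the informative descriptors from the specified correlated
#' multivariate normal, the activity as beta0 + X beta + Normal(0,
#' noise_sd^2), appends the nuisance/constant/duplicate columns, and returns
#' everything as a [qsar_dataset] (all records labelled `"train"`; use
#' [split_dataset()] afterwards). Byte-identical for identical spec and
#' seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a [qsar_dataset] with the generating parameters attached as
#'   attribute `"generating_spec"`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "qsar_synth_spec"))
  k <- length(spec$betas)
  with_seed(spec$seed, {
    L <- chol(spec$inter_correlation)
    Z <- matrix(stats::rnorm(spec$n * k), spec$n, k) %*% L
    X <- sweep(sweep(Z, 2L, spec$descriptor_sds, "*"),
               2L, spec$descriptor_means, "+")
    colnames(X) <- spec$descriptor_names
    cols <- list(X)
    if (spec$k_noise > 0L) {
      N <- matrix(stats::rnorm(spec$n * spec$k_noise), spec$n, spec$k_noise)
      colnames(N) <- sprintf("ND%02d", seq_len(spec$k_noise))
      cols <- c(cols, list(N))
    }
    if (spec$n_constant_cols > 0L) {
      C <- matrix(1, spec$n, spec$n_constant_cols)
      colnames(C) <- sprintf("CONST%d", seq_len(spec$n_constant_cols))
      cols <- c(cols, list(C))
    }
    if (spec$n_duplicate_cols > 0L) {
      src <- utils::tail(seq_len(k + spec$k_noise),
                         spec$n_duplicate_cols)
      full <- do.call(cbind, cols)
      Dp <- full[, src, drop = FALSE]
      colnames(Dp) <- sprintf("DUP%d", seq_len(spec$n_duplicate_cols))
      cols <- c(cols, list(Dp))
    }
    full <- do.call(cbind, cols)
    y <- spec$beta0 + drop(X %*% spec$betas) +
      stats::rnorm(spec$n, 0, spec$noise_sd)
    ds <- qsar_dataset(full, pic50 = y)
    attr(ds, "generating_spec") <- spec
    ds
  })
}

fixture_names <- c("eq1_model", "table4_candidates", "table5_druglikeness",
                   "table6_admet", "table8_activities")

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "qsarlm")
  if (!nzchar(p))
    qsar_stop(sprintf("fixture file %s not installed", file), "qsar_lookup_error")
  p
}

#' Load an in-package fixture
#'
#' Ships the published reference values used throughout the examples and
#' tests:
#' * `"eq1_model"` — the reported three-descriptor activity model (intercept
#'   2.587; PSA -0.007, DM +0.163, MW +0.010) as a `qsar_mlr`-classed object
#'   that can predict but carries reported rather than refitted statistics
#'   (R2 0.64, Q2 0.56, RMSE 0.35, F 21.54 at n = 40). Note the published
#'   coefficients are rounded to at most 3 decimals, so predictions carry a
#'   systematic offset of roughly +0.2 to +0.4 pIC50 units relative to the
#'   published candidate predictions.
#' * `"table4_candidates"` — the 11 designed candidates (PSA, DM, MW) as a
#'   candidate-role [qsar_dataset]; the published predicted pIC50 and
#'   leverage values are attached as attribute `"printed"`.
#' * `"table5_druglikeness"` — logP, MW, H-bond acceptor/donor counts for
#'   the five retained candidates.
#' * `"table6_admet"` — their externally predicted absorption, distribution,
#'   metabolism, excretion and toxicity values.
#' * `"table8_activities"` — the ordered 50 observed pIC50 values of the
#'   modelled series (the structures themselves are not machine-readable and
#'   are not shipped).
#'
#' @param name one of the fixture names above.
#' @return see description; unknown names raise a lookup error listing the
#'   valid names.
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% fixture_names)
    qsar_stop(sprintf("unknown fixture '%s'; valid names: %s",
                      paste(name, collapse = ","),
                      paste(fixture_names, collapse = ", ")),
              "qsar_lookup_error")
  switch(name,
    eq1_model = {
      co <- c("(Intercept)" = 2.587, PSA = -0.007, DM = 0.163, MW = 0.010)
      structure(list(coefficients = co, n = 40L, k = 3L, r2 = 0.64,
                     rmse = 0.35, residual_sd = NA_real_,
                     f_stat = 21.54, f_pvalue = 1e-4,
                     standardized_coefficients = NULL,
                     reported = list(q2_cv = 0.56, r2_test = 0.72),
                     x = NULL, y = NULL, call = NULL),
                class = c("qsar_mlr_reported", "qsar_mlr"))
    },
    table4_candidates = {
      df <- utils::read.csv(fixture_path("table4_candidates.csv"))
      ds <- qsar_dataset(as.matrix(df[c("PSA", "DM", "MW")]), ids = df$id,
                         role = "candidate")
      attr(ds, "printed") <- df[c("id", "pIC50_printed", "leverage_printed",
                                  "domain_printed")]
      ds
    },
    table5_druglikeness = utils::read.csv(fixture_path("table5_druglikeness.csv")),
    table6_admet = utils::read.csv(fixture_path("table6_admet.csv")),
    table8_activities = utils::read.csv(fixture_path("table8_activities.csv"))$pIC50)
}

#' @export
print.qsar_mlr_reported <- function(x, ...) {
  NextMethod()
  cat("  (reported reference model: statistics as published, not refitted)\n")
  invisible(x)
}

#' ADMET profiles of the published candidates
#'
#' Merges the drug-likeness and pharmacokinetic fixtures into one
#' [admet_profile()] per candidate, ready for [lipinski_profile()],
#' [bbb_cns_classify()] and [admet_gate()].
#'
#' @return named list of `qsar_admet` profiles (M1, M2, M6, M9, M10).
#' @export
fixture_admet_profiles <- function() {
  t5 <- load_fixture("table5_druglikeness")
  t6 <- load_fixture("table6_admet")
  stopifnot(identical(t5$id, t6$id))
  profs <- lapply(seq_len(nrow(t5)), function(i)
    admet_profile(logp = t5$logP[i], mw = t5$MW[i], hba = t5$HBA[i],
                  hbd = t5$HBD[i], caco2 = t6$caco2[i], hia = t6$hia[i],
                  logbb = t6$logbb[i], logps = t6$logps[i],
                  cyp2d6_inhibitor = t6$cyp2d6_inhibitor[i] == "Yes",
                  total_clearance = t6$total_clearance[i],
                  ames_toxic = t6$ames_toxicity[i] == "Yes",
                  ld50 = t6$ld50[i],
                  hepatotoxic = t6$hepatotoxicity[i] == "Yes",
                  skin_sensitizer = t6$skin_sensitization[i] == "Yes"))
  stats::setNames(profs, t5$id)
}
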