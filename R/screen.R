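#' Screening thresholds
#'
#' Bundles the reference activity and the rule-based drug-likeness and
#' pharmacokinetic cutoffs used by the screening stage. Defaults follow the
#' usual conventions: Lipinski bounds MW <= 500 g/mol, logP <= 5, H-bond
#' donors <= 5, H-bond acceptors <= 10, with at most two violations allowed;
#' blood-brain partition logBB > 0.3 for permeant and < -1 for poor
#' diffusion; CNS permeability logPS > -2 for penetrant and < -3 for
#' blocked; intestinal absorption above 80%; Caco-2 permeability above 0.9.
#' The default reference activity 7.259 (pIC50) is the most potent training
#' compound, which designed candidates are expected to beat.
#'
#' @param reference_pic50 reference activity for the improved-vs-reference
#'   flag.
#' @param mw_max,logp_max,hbd_max,hba_max Lipinski bounds (inclusive).
#' @param max_lipinski_violations violations tolerated before failing
#'   (default 2; set to 1 for the classical rule).
#' @param logbb_permeant,logbb_poor,logps_penetrant,logps_blocked strict
#'   cutoffs of the brain-penetration classes.
#' @param hia_min,caco2_min absorption cutoffs (strict).
#' @return a `qsar_screening_config` list.
#' @export
screening_config <- function(reference_pic50 = 7.259,
                             mw_max = 500, logp_max = 5, hbd_max = 5,
                             hba_max = 10, max_lipinski_violations = 2L,
                             logbb_permeant = 0.3, logbb_poor = -1,
                             logps_penetrant = -2, logps_blocked = -3,
                             hia_min = 80, caco2_min = 0.9) {
  if (logbb_poor >= logbb_permeant || logps_blocked >= logps_penetrant)
    qsar_stop("lower class cutoffs must lie below upper cutoffs", "qsar_config_error")
  structure(list(reference_pic50 = reference_pic50, mw_max = mw_max,
                 logp_max = logp_max, hbd_max = hbd_max, hba_max = hba_max,
                 max_lipinski_violations = as.integer(max_lipinski_violations),
                 logbb_permeant = logbb_permeant, logbb_poor = logbb_poor,
                 logps_penetrant = logps_penetrant, logps_blocked = logps_blocked,
                 hia_min = hia_min, caco2_min = caco2_min),
            class = "qsar_screening_config")
}

#' ADMET profile of a compound
#'
#' Collects externally predicted drug-likeness and pharmacokinetic values
#' for one compound. These values are inputs to the rule engine; the package
#' never computes them from structure.
#'
#' @param logp octanol-water partition coefficient.
#' @param mw molecular weight, g/mol.
#' @param hba,hbd hydrogen-bond acceptor and donor counts.
#' @param caco2 log Caco-2 permeability.
#' @param hia human intestinal absorption, percent (0-100).
#' @param logbb log blood-brain partition coefficient.
#' @param logps log CNS permeability-surface-area product.
#' @param cyp2d6_inhibitor logical, predicted CYP2D6 inhibition.
#' @param total_clearance total clearance value.
#' @param ames_toxic logical, AMES mutagenicity.
#' @param ld50 rat acute-toxicity LD50.
#' @param hepatotoxic,skin_sensitizer logical toxicity flags.
#' @return a `qsar_admet` list.
#' @export
admet_profile <- function(logp, mw, hba, hbd, caco2 = NA_real_,
                          hia = NA_real_, logbb = NA_real_, logps = NA_real_,
                          cyp2d6_inhibitor = NA, total_clearance = NA_real_,
                          ames_toxic = NA, ld50 = NA_real_,
                          hepatotoxic = NA, skin_sensitizer = NA) {
  if (!is.na(hia) && (hia < 0 || hia > 100))
    qsar_stop("HIA must be a percentage in [0, 100]", "qsar_validation_error")
  if (hba < 0 || hbd < 0)
    qsar_stop("H-bond counts must be non-negative", "qsar_validation_error")
  structure(list(logp = logp, mw = mw, hba = hba, hbd = hbd, caco2 = caco2,
                 hia = hia, logbb = logbb, logps = logps,
                 cyp2d6_inhibitor = isTRUE(cyp2d6_inhibitor),
                 total_clearance = total_clearance,
                 ames_toxic = isTRUE(ames_toxic), ld50 = ld50,
                 hepatotoxic = isTRUE(hepatotoxic),
                 skin_sensitizer = isTRUE(skin_sensitizer)),
            class = "qsar_admet")
}

#' Lipinski rule-of-five check
#'
#' Counts violations of the four oral drug-likeness bounds (all inclusive:
#' a compound sitting exactly on a bound does not violate it) and passes the
#' compound when the count does not exceed the configured maximum.
#'
#' @param profile a [admet_profile()].
#' @param config a [screening_config()].
#' @return list with `violations` (integer), `pass` (logical) and `detail`
#'   (named logical vector of individual violations).
#' @export
lipinski_profile <- function(profile, config = screening_config()) {
  detail <- c(mw = profile$mw > config$mw_max,
              logp = profile$logp > config$logp_max,
              hbd = profile$hbd > config$hbd_max,
              hba = profile$hba > config$hba_max)
  v <- sum(detail)
  list(violations = as.integer(v),
       pass = v <= config$max_lipinski_violations,
       detail = detail)
}

#' Blood-brain barrier and CNS classification
#'
#' Three-way classification on each axis with strict cutoffs: logBB above
#' 0.3 is BBB-permeant and below -1 poor; logPS above -2 is CNS-penetrant
#' and below -3 blocked; values between the cutoffs are intermediate.
#'
#' @param profile a [admet_profile()].
#' @param config a [screening_config()].
#' @return list with `bbb` (`"permeant"`, `"intermediate"`, `"poor"`) and
#'   `cns` (`"penetrant"`, `"intermediate"`, `"blocked"`).
#' @export
bbb_cns_classify <- function(profile, config = screening_config()) {
  bbb <- if (profile$logbb > config$logbb_permeant) "permeant"
         else if (profile$logbb < config$logbb_poor) "poor"
         else "intermediate"
  cns <- if (profile$logps > config$logps_penetrant) "penetrant"
         else if (profile$logps < config$logps_blocked) "blocked"
         else "intermediate"
  list(bbb = bbb, cns = cns)
}

#' Pharmacokinetic and toxicity gate
#'
#' Applies the six pass/fail rules: intestinal absorption above the HIA
#' cutoff, Caco-2 permeability above its cutoff, no CYP2D6 inhibition, no
#' AMES mutagenicity, no hepatotoxicity, no skin sensitization. The overall
#' verdict is their conjunction.
#'
#' @param profile a [admet_profile()].
#' @param config a [screening_config()].
#' @return named logical vector (`hia`, `caco2`, `cyp2d6`, `ames`,
#'   `hepatotoxicity`, `skin_sensitization`, `overall`).
#' @export
admet_gate <- function(profile, config = screening_config()) {
  v <- c(hia = profile$hia > config$hia_min,
         caco2 = profile$caco2 > config$caco2_min,
         cyp2d6 = !profile$cyp2d6_inhibitor,
         ames = !profile$ames_toxic,
         hepatotoxicity = !profile$hepatotoxic,
         skin_sensitization = !profile$skin_sensitizer)
  c(v, overall = all(v))
}

#' Rank designed candidates by predicted activity
#'
#' Predicts pIC50 for each candidate, flags whether it improves on the
#' reference activity, attaches the applicability-domain verdict when an AD
#' report is supplied, and ranks candidates by predicted activity
#' (descending; ties broken by id).
#'
#' @param model a fitted [qsar_mlr()] model.
#' @param candidates a [qsar_dataset] (or descriptor matrix/data frame)
#'   carrying every model descriptor.
#' @param config a [screening_config()].
#' @param ad optional `qsar_ad` report whose table contains the candidates.
#' @return a `qsar_screening` data frame with columns `id`,
#'   `predicted_pic50`, `improved`, `leverage`, `in_domain`, `rank`.
#' @export
screen_candidates <- function(model, candidates, config = screening_config(),
                              ad = NULL) {
  ids <- if (inherits(candidates, "qsar_dataset")) candidates$ids
         else rownames(candidates) %||% sprintf("M%d", seq_len(nrow(candidates)))
  if (!length(ids)) {
    out <- data.frame(id = character(), predicted_pic50 = numeric(),
                      improved = logical(), leverage = numeric(),
                      in_domain = logical(), rank = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("qsar_screening", "data.frame")
    return(out)
  }
  pred <- predict(model, candidates)
  lev <- in_dom <- rep(NA, length(ids))
  if (!is.null(ad)) {
    m <- match(ids, ad$table$id)
    lev <- ad$table$leverage[m]
    in_dom <- ad$table$category[m] == "inside"
  }
  out <- data.frame(id = ids, predicted_pic50 = unname(pred),
                    improved = unname(pred) > config$reference_pic50,
                    leverage = lev, in_domain = in_dom,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$predicted_pic50, out$id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("qsar_screening", "data.frame")
  out
}

#' @export
print.qsar_screening <- function(x, digits = 3, ...) {
  cat(sprintf("Candidate screening: %d compounds\n", nrow(x)))
  df <- as.data.frame(x)
  df$predicted_pic50 <- round(df$predicted_pic50, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
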