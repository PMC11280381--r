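#' Compound dataset container
#'
#' A `qsar_dataset` holds an ordered set of compounds: identifiers, an
#' optional structure string per compound, a numeric descriptor matrix, the
#' observed activity as pIC50 (missing for designed candidates), and a role
#' label (`"train"`, `"test"` or `"candidate"`) used by the pipeline stages.
#'
#' @param descriptors numeric matrix (compounds x descriptors) with column
#'   names; all values must be finite.
#' @param pic50 numeric activity vector, one value per compound. `NA` is
#'   allowed only for candidate records: training and test compounds must
#'   carry an observed activity.
#' @param ids character vector of unique compound labels. Defaults to
#'   `C01, C02, ...`.
#' @param role per-compound role, recycled if length one.
#' @param smiles optional character vector of structure strings.
#' @return An object of class `qsar_dataset`.
#' @seealso [read_compound_table()], [split_dataset()], [generate_dataset()]
#' @export
qsar_dataset <- function(descriptors, pic50 = NULL, ids = NULL,
                         role = "train", smiles = NULL) {
  descriptors <- as.matrix(descriptors)
  if (!is.numeric(descriptors))
    qsar_stop("descriptor matrix must be numeric", "qsar_validation_error")
  n <- nrow(descriptors)
  if (is.null(colnames(descriptors)))
    qsar_stop("descriptor columns must be named", "qsar_validation_error")
  if (anyDuplicated(colnames(descriptors)))
    qsar_stop("descriptor names must be unique", "qsar_validation_error")
  if (any(!is.finite(descriptors)))
    qsar_stop("descriptor values must be finite", "qsar_validation_error")
  ids <- ids %||% rownames(descriptors) %||% sprintf("C%02d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n)
    qsar_stop("ids length does not match number of compounds", "qsar_validation_error")
  if (anyDuplicated(ids))
    qsar_stop(sprintf("duplicate compound id: %s", ids[duplicated(ids)][1L]),
              "qsar_validation_error")
  role <- rep_len(as.character(role), n)
  if (!all(role %in% c("train", "test", "candidate")))
    qsar_stop("role must be one of train, test, candidate", "qsar_validation_error")
  if (is.null(pic50)) pic50 <- rep(NA_real_, n)
  pic50 <- as.numeric(pic50)
  if (length(pic50) != n)
    qsar_stop("pic50 length does not match number of compounds", "qsar_validation_error")
  miss <- is.na(pic50) & role != "candidate"
  if (any(miss))
    qsar_stop(sprintf("missing activity for non-candidate compound(s): %s",
                      paste(ids[miss], collapse = ", ")),
              "qsar_validation_error")
  rownames(descriptors) <- ids
  structure(list(ids = ids, descriptors = descriptors, pic50 = pic50,
                 role = role, smiles = smiles),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat(sprintf("<qsar_dataset> %d compounds x %d descriptors\n",
              length(x$ids), ncol(x$descriptors)))
  tab <- table(factor(x$role, levels = c("train", "test", "candidate")))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  k <- ncol(x$descriptors)
  shown <- paste(utils::head(colnames(x$descriptors), 6L), collapse = ", ")
  cat("  descriptors:", shown, if (k > 6L) sprintf("... (%d more)", k - 6L) else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.qsar_dataset <- function(x, ...) {
  data.frame(id = x$ids, role = x$role, x$descriptors,
             pIC50 = x$pic50, check.names = FALSE, row.names = NULL)
}

#' Descriptor names of a dataset or model
#' @param x a `qsar_dataset` or `qsar_mlr` object.
#' @return character vector of descriptor names (model: excludes intercept).
#' @export
descriptor_names <- function(x) {
  if (inherits(x, "qsar_dataset")) return(colnames(x$descriptors))
  if (inherits(x, "qsar_mlr")) return(names(coef(x))[-1L])
  qsar_stop("no descriptor names for this object", "qsar_validation_error")
}

# subset rows of a dataset by role, keeping classes
dataset_rows <- function(ds, role) {
  keep <- ds$role %in% role
  list(x = ds$descriptors[keep, , drop = FALSE],
       y = ds$pic50[keep], ids = ds$ids[keep])
}

#' Convert IC50 to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50, so a compound
#' inhibiting at 1000 nM (1 micromolar) has pIC50 = 6. Vectorised over
#' `value`.
#'
#' @param value positive IC50 value(s).
#' @param unit unit of `value`: `"nM"`, `"uM"` (also accepted: `"µM"`) or `"M"`.
#' @return pIC50 value(s).
#' @examples
#' ic50_to_pic50(1000, "nM")  # 6
#' ic50_to_pic50(55, "nM")    # 7.2596...
#' @export
ic50_to_pic50 <- function(value, unit = c("nM", "uM", "M")) {
  unit <- sub("µ", "u", unit[1L])
  unit <- match.arg(unit, c("nM", "uM", "M"))
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0))
    qsar_stop("IC50 must be a positive finite value", "qsar_domain_error")
  scale <- c(nM = 1e-9, uM = 1e-6, M = 1)[[unit]]
  -log10(value * scale)
}

#' Read a compound table
#'
#' Reads a delimited compound table (comma-separated, `.` decimal, header row
#' required) into a [qsar_dataset]. Every column other than the id, role,
#' structure and activity columns is treated as a numeric descriptor; a cell
#' that does not parse as a number is reported with its row and column.
#' Activities may be given as pIC50, or as IC50 plus a unit column (converted
#' via [ic50_to_pic50()]); when both are present they must agree to 1e-6.
#'
#' With `format = "sdf"` an SD file is read through the ChemmineR package and
#' descriptors are taken from named data fields.
#'
#' @param path file to read.
#' @param format `"csv"` (default) or `"sdf"`.
#' @param id_col,activity_col,ic50_col,unit_col,smiles_col,role_col column
#'   names; set to `NULL` for absent columns. Records without an activity
#'   value must be labelled `"candidate"` in the role column.
#' @return a [qsar_dataset].
#' @export
read_compound_table <- function(path, format = c("csv", "sdf"),
                                id_col = "id", activity_col = "pIC50",
                                ic50_col = NULL, unit_col = NULL,
                                smiles_col = NULL, role_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    qsar_stop(sprintf("file not found: %s", path), "qsar_parse_error")
  if (format == "sdf") return(read_sdf_table(path, activity_col))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!id_col %in% names(raw))
    qsar_stop(sprintf("missing id column '%s'", id_col), "qsar_parse_error")
  ids <- raw[[id_col]]
  if (anyDuplicated(ids))
    qsar_stop(sprintf("duplicate compound id: %s", ids[duplicated(ids)][1L]),
              "qsar_validation_error")
  special <- c(id_col, activity_col, ic50_col, unit_col, smiles_col, role_col)
  desc_cols <- setdiff(names(raw), special)
  if (!length(desc_cols))
    qsar_stop("no descriptor columns found", "qsar_parse_error")

  parse_num <- function(cells, col, allow_na = FALSE) {
    out <- suppressWarnings(as.numeric(cells))
    bad <- if (allow_na) !is.na(cells) & cells != "" & is.na(out)
           else is.na(out) | !is.finite(out)
    if (any(bad))
      qsar_stop(sprintf("cannot parse '%s' as a number (row %d, column '%s')",
                        cells[which(bad)[1L]], which(bad)[1L], col),
                "qsar_parse_error")
    if (allow_na) out[cells == ""] <- NA_real_
    out
  }
  X <- vapply(desc_cols, function(cl) parse_num(raw[[cl]], cl), numeric(nrow(raw)))
  X <- matrix(X, nrow = nrow(raw), dimnames = list(NULL, desc_cols))

  role <- if (!is.null(role_col)) raw[[role_col]] else "train"
  pic50 <- if (!is.null(activity_col) && activity_col %in% names(raw))
    parse_num(raw[[activity_col]], activity_col, allow_na = TRUE)
  else rep(NA_real_, nrow(raw))
  if (!is.null(ic50_col) && ic50_col %in% names(raw)) {
    ic50 <- parse_num(raw[[ic50_col]], ic50_col, allow_na = TRUE)
    if (is.null(unit_col) || !unit_col %in% names(raw))
      qsar_stop("a unit column is required when IC50 values are given",
                "qsar_parse_error")
    conv <- rep(NA_real_, length(ic50))
    has <- !is.na(ic50)
    conv[has] <- vapply(which(has), function(i)
      ic50_to_pic50(ic50[i], raw[[unit_col]][i]), numeric(1L))
    both <- has & !is.na(pic50)
    if (any(off <- both & abs(conv - pic50) > 1e-6))
      qsar_stop(sprintf(
        "IC50 and pIC50 disagree for compound %s (converted %.6f vs stated %.6f)",
        ids[which(off)[1L]], conv[which(off)[1L]], pic50[which(off)[1L]]),
        "qsar_validation_error")
    pic50[is.na(pic50)] <- conv[is.na(pic50)]
  }
  smiles <- if (!is.null(smiles_col) && smiles_col %in% names(raw))
    raw[[smiles_col]] else NULL
  qsar_dataset(X, pic50 = pic50, ids = ids, role = role, smiles = smiles)
}

# SDF input: structures plus named data fields as descriptors (ChemmineR)
read_sdf_table <- function(path, activity_col) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    qsar_stop("reading SDF requires the ChemmineR package", "qsar_parse_error")
  sdf <- ChemmineR::read.SDFset(path)
  blocks <- ChemmineR::datablock(sdf)
  ids <- ChemmineR::sdfid(sdf)
  keys <- unique(unlist(lapply(blocks, names)))
  get <- function(b, k) if (k %in% names(b)) suppressWarnings(as.numeric(b[[k]])) else NA_real_
  M <- t(vapply(blocks, function(b) vapply(keys, get, numeric(1L), b = b),
                numeric(length(keys))))
  colnames(M) <- keys
  pic50 <- if (!is.null(activity_col) && activity_col %in% keys) M[, activity_col] else NULL
  desc <- M[, setdiff(keys, activity_col), drop = FALSE]
  if (any(!is.finite(desc)))
    qsar_stop("missing or non-numeric descriptor field in SDF data block",
              "qsar_parse_error")
  qsar_dataset(desc, pic50 = pic50, ids = ids,
               role = if (is.null(pic50)) "candidate" else "train")
}

#' Write a compound table
#'
#' Writes a [qsar_dataset] back to CSV with full numeric precision (15
#' significant digits), so that a read/write cycle round-trips values.
#'
#' @param ds a [qsar_dataset].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_compound_table <- function(ds, path) {
  df <- as.data.frame(ds)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "", format(v, digits = 15, trim = TRUE, scientific = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Seeded train/test split
#'
#' Randomly assigns non-candidate compounds to training and test roles. The
#' training size is `fraction * n` rounded half-up, and the assignment is a
#' deterministic function of `seed`. Candidate records are left untouched.
#'
#' @param ds a [qsar_dataset].
#' @param train_fraction fraction of non-candidate compounds used for
#'   training, in (0, 1].
#' @param seed integer seed controlling the assignment.
#' @param require_test if `TRUE` (default) a split leaving an empty test set
#'   is a configuration error; set to `FALSE` to allow `train_fraction = 1`
#'   when no external validation is intended.
#' @return the dataset with updated roles.
#' @export
split_dataset <- function(ds, train_fraction = 0.8, seed = 1L,
                          require_test = TRUE) {
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction > 1)
    qsar_stop("train_fraction must be in (0, 1]", "qsar_config_error")
  pool <- which(ds$role != "candidate")
  n <- length(pool)
  if (n < 2L)
    qsar_stop("need at least 2 non-candidate compounds to split", "qsar_size_error")
  n_train <- as.integer(floor(train_fraction * n + 0.5))  # round half-up
  if (n_train < 1L)
    qsar_stop("split leaves an empty training set", "qsar_config_error")
  if (n_train >= n && require_test)
    qsar_stop("split leaves an empty test set but external validation is required",
              "qsar_config_error")
  train_idx <- with_seed(seed, sample(pool, n_train))
  role <- ds$role
  role[pool] <- "test"
  role[train_idx] <- "train"
  ds$role <- role
  ds
}
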