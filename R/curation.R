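#' @title Curation of multi-source activity tables
#' @description Turns raw (source, SMILES, target, IC50) rows into a clean,
#'   deduplicated, pIC50-labelled multitask dataset with train/validation/test
#'   splits. The canonical SMILES string is the unique compound identity;
#'   duplicated measurements keep the lower (more potent) IC50 per target.
#' @name curation
NULL

#' Convert IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar concentration, so for
#' IC50 expressed in nM, `pIC50 = 9 - log10(IC50_nM)`. 1 nM maps to 9, the
#' common 1 uM activity threshold maps to 6.
#'
#' @param ic50_nM Positive numeric vector, nanomolar.
#' @return Numeric vector of pIC50 values (dimensionless).
#' @export
ic50_to_pic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("ic50_nM must be finite and > 0")
  }
  9 - log10(ic50_nM)
}

#' Inverse of [ic50_to_pic50()]
#' @param pic50 Numeric vector of pIC50 values.
#' @return IC50 in nM.
#' @export
pic50_to_ic50 <- function(pic50) {
  stopifnot(is.numeric(pic50), all(is.finite(pic50)))
  10^(9 - pic50)
}

#' Standardize raw SMILES, keeping a rejection log
#'
#' Thin wrapper over [chem_standardize()] that splits clean from rejected
#' rows. Rejections are reported, never silently dropped.
#'
#' @param smiles Character vector.
#' @return List with `canonical` (character, NA for rejected), and
#'   `rejections` (data.frame input/reason).
#' @export
standardize_smiles <- function(smiles) {
  std <- chem_standardize(smiles)
  rej <- std[is.na(std$canonical), c("input", "reason")]
  list(canonical = std$canonical, rejections = rej)
}

#' Merge duplicated measurements into one record per compound
#'
#' Groups standardized rows by canonical SMILES; within each compound and
#' target the minimum IC50 (the more potent, hence more conservative,
#' measurement) is retained and converted to pIC50.
#'
#' @param rows data.frame with columns `canonical_smiles`, `target`,
#'   `ic50_nM`.
#' @param targets Character vector of configured target names; rows with
#'   other targets raise an error.
#' @return data.frame of compound records: `canonical_smiles` plus one
#'   `<target>_pIC50` column per target (NA when unmeasured) and a `split`
#'   column initialized to `"unassigned"`.
#' @export
merge_duplicates <- function(rows, targets) {
  stopifnot(is.data.frame(rows),
            all(c("canonical_smiles", "target", "ic50_nM") %in% names(rows)))
  if (nrow(rows) == 0) {
    out <- data.frame(canonical_smiles = character(), stringsAsFactors = FALSE)
    for (t in targets) out[[paste0(t, "_pIC50")]] <- numeric()
    out$split <- character()
    return(out)
  }
  unknown <- setdiff(unique(rows$target), targets)
  if (length(unknown)) stop("unknown target(s): ", paste(unknown, collapse = ", "))
  if (any(rows$ic50_nM <= 0 | !is.finite(rows$ic50_nM))) {
    stop("all ic50_nM values must be finite and positive")
  }
  smi <- unique(rows$canonical_smiles)
  out <- data.frame(canonical_smiles = smi, stringsAsFactors = FALSE)
  for (t in targets) {
    sub <- rows[rows$target == t, ]
    best <- tapply(sub$ic50_nM, sub$canonical_smiles, min)
    col <- rep(NA_real_, length(smi))
    hit <- match(names(best), smi)
    col[hit] <- ic50_to_pic50(as.numeric(best))
    out[[paste0(t, "_pIC50")]] <- col
  }
  out$split <- "unassigned"
  out
}

#' Randomly split compound records into train/validation/test
#'
#' Validation and test sizes are the rounded ratio shares; the remainder goes
#' to training, so partitions are disjoint and exhaustive. The assignment is
#' a fixed permutation drawn from the seed and therefore reproducible.
#'
#' @param records Compound record data.frame (from [merge_duplicates()]).
#' @param ratios Numeric length 3 (train, valid, test) summing to 1.
#' @param seed Integer seed.
#' @return `records` with the `split` column filled.
#' @export
split_dataset <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  stopifnot(is.data.frame(records), length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  n <- nrow(records)
  if (n < 3) stop("need at least 3 records to split")
  n_valid <- round(n * ratios[2])
  n_test <- round(n * ratios[3])
  n_train <- n - n_valid - n_test
  if (n_train < 0) stop("ratios leave no training data")
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  lab <- rep(c("train", "valid", "test"), times = c(n_train, n_valid, n_test))
  records$split <- lab[order(ord)]
  records
}

#' Label and mask matrices for multitask training
#'
#' @param records Compound record data.frame.
#' @param targets Character vector of target names (column order of the
#'   matrices).
#' @return List with `labels` (n x T numeric, NA where unmeasured), `mask`
#'   (n x T logical, TRUE where a label exists), rownames = canonical SMILES.
#' @export
build_task_table <- function(records, targets) {
  cols <- paste0(targets, "_pIC50")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("unknown target column(s): ", paste(missing_cols, collapse = ", "))
  }
  labels <- as.matrix(records[, cols, drop = FALSE])
  colnames(labels) <- targets
  rownames(labels) <- records$canonical_smiles
  mask <- !is.na(labels)
  labels[!mask] <- 0
  list(labels = labels, mask = mask)
}

#' Read a wide activity CSV into raw rows
#'
#' Expected columns: `smiles` plus one `<target>_ic50_nM` per target; empty
#' cells mean "not measured".
#'
#' @param path CSV file path.
#' @param targets Character vector of target names.
#' @return Long data.frame with columns `smiles`, `target`, `ic50_nM`.
#' @export
read_activity_csv <- function(path, targets) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"smiles" %in% names(wide)) stop("CSV must contain a 'smiles' column")
  rows <- list()
  for (t in targets) {
    col <- paste0(t, "_ic50_nM")
    if (!col %in% names(wide)) stop("CSV lacks column ", col)
    keep <- !is.na(wide[[col]])
    if (any(keep)) {
      rows[[t]] <- data.frame(smiles = wide$smiles[keep], target = t,
                              ic50_nM = as.numeric(wide[[col]][keep]),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Full curation pipeline
#'
#' Standardizes structures, drops and logs rejected rows, merges duplicates
#' (minimum IC50 per compound and target), converts to pIC50 and assigns
#' 8:1:1 splits.
#'
#' @param raw Long data.frame (`smiles`, `target`, `ic50_nM`) or a path to a
#'   wide CSV readable by [read_activity_csv()].
#' @param targets Character vector of target names.
#' @param ratios Split ratios, see [split_dataset()].
#' @param seed Split seed.
#' @return List with `records` (curated data.frame), and `report` (counts
#'   and the rejection log).
#' @export
curate <- function(raw, targets, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (is.character(raw) && length(raw) == 1) raw <- read_activity_csv(raw, targets)
  stopifnot(is.data.frame(raw), all(c("smiles", "target", "ic50_nM") %in% names(raw)))
  bad_ic50 <- !is.finite(raw$ic50_nM) | raw$ic50_nM <= 0
  dropped_ic50 <- raw[bad_ic50, , drop = FALSE]
  raw <- raw[!bad_ic50, , drop = FALSE]
  std <- standardize_smiles(raw$smiles)
  ok <- !is.na(std$canonical)
  clean <- data.frame(canonical_smiles = std$canonical[ok],
                      target = raw$target[ok],
                      ic50_nM = raw$ic50_nM[ok],
                      stringsAsFactors = FALSE)
  records <- merge_duplicates(clean, targets)
  records <- split_dataset(records, ratios, seed)
  report <- list(
    n_rows_in = nrow(raw) + nrow(dropped_ic50),
    n_rows_dropped_ic50 = nrow(dropped_ic50),
    n_rows_rejected_structure = sum(!ok),
    rejections = std$rejections,
    n_compounds = nrow(records),
    per_target_counts = vapply(
      targets, function(t) sum(!is.na(records[[paste0(t, "_pIC50")]])), 0L),
    split_counts = table(records$split)
  )
  list(records = records, report = report)
}

#' Write curated records to CSV
#' @param records Curated record data.frame.
#' @param path Output file.
#' @export
write_curated_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read curated records from CSV
#' @param path File written by [write_curated_csv()].
#' @return Curated record data.frame.
#' @export
read_curated_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in grep("_pIC50$", names(rec), value = TRUE)) {
    rec[[col]] <- as.numeric(rec[[col]])
  }
  rec
}

#' Target names stored in a curated record table
#' @param records Curated record data.frame.
#' @return Character vector of targets.
#' @export
record_targets <- function(records) {
  sub("_pIC50$", "", grep("_pIC50$", names(records), value = TRUE))
}
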