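#' @title Chemical-space and task-relevance diagnostics
#' @description PCA of MACCS structural keys to visualize split overlap in
#'   chemical space, drug-likeness (QED) distributions per target with
#'   pairwise overlap areas, and inter-task activity correlations.
#' @name chemspace
NULL

#' PCA of the MACCS-key chemical space
#'
#' Fits a principal component analysis on the 167-bit MACCS keys of the
#' pooled set and reports the first three components. A bounding-box overlap
#' summary per split quantifies how completely validation/test chemistry is
#' covered by the training chemistry.
#'
#' @param smiles Character vector of molecules.
#' @param splits Optional character vector of split labels aligned with
#'   `smiles`.
#' @return `chemspace_pca` list: `coordinates` (n x 3), `explained_variance`
#'   (fractions, non-increasing), `splits`, `overlap` (per non-train split:
#'   fraction of points inside the training bounding box in PC1-3).
#' @export
pca_space <- function(smiles, splits = NULL) {
  stopifnot(length(smiles) >= 4)
  keys <- chem_fingerprints(smiles, "maccs")
  keep <- apply(keys, 2, stats::var) > 0
  if (!any(keep)) stop("degenerate input: all MACCS keys identical")
  pc <- stats::prcomp(keys[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ncomp <- min(3L, ncol(pc$x))
  coords <- pc$x[, seq_len(ncomp), drop = FALSE]
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncomp)]
  overlap <- NULL
  if (!is.null(splits)) {
    stopifnot(length(splits) == length(smiles))
    tr <- coords[splits == "train", , drop = FALSE]
    if (nrow(tr) > 0) {
      lo <- apply(tr, 2, min)
      hi <- apply(tr, 2, max)
      others <- setdiff(unique(splits), "train")
      overlap <- vapply(others, function(s) {
        pts <- coords[splits == s, , drop = FALSE]
        if (nrow(pts) == 0) return(NA_real_)
        inside <- apply(pts, 1, function(p) all(p >= lo & p <= hi))
        mean(inside)
      }, 0)
    }
  }
  structure(list(coordinates = coords, explained_variance = expl,
                 splits = splits, overlap = overlap),
            class = "chemspace_pca")
}

density_on_grid <- function(x, n_grid = 512L) {
  if (length(unique(x)) == 1) {
    # point mass: narrow kernel around the single value
    d <- stats::density(x, bw = 0.01, from = 0, to = 1, n = n_grid)
  } else {
    d <- stats::density(x, from = 0, to = 1, n = n_grid)
  }
  d$y / (sum(d$y) * diff(d$x[1:2]))  # renormalize to integrate to 1 on [0,1]
}

#' QED drug-likeness profiles per target
#'
#' Computes the quantitative estimate of drug-likeness for the compounds
#' labelled on each target and the pairwise overlap area of their kernel
#' density estimates on a shared 512-point grid over `[0, 1]`. Larger
#' overlap means more similar chemistry across tasks.
#'
#' @param smiles_by_target Named list: target -> character vector of SMILES.
#' @param n_grid Grid resolution.
#' @return `qed_profile` list: `qed` (named list of numeric vectors),
#'   `overlap` (T x T matrix in `[0, 1]`), `grid`, `densities`.
#' @export
qed_profile <- function(smiles_by_target, n_grid = 512L) {
  stopifnot(is.list(smiles_by_target), length(smiles_by_target) >= 1)
  empty <- vapply(smiles_by_target, length, 1L) == 0
  if (any(empty)) {
    warning("empty target set(s) skipped: ",
            paste(names(smiles_by_target)[empty], collapse = ", "))
    smiles_by_target <- smiles_by_target[!empty]
  }
  qed <- lapply(smiles_by_target, chem_qed)
  grid <- seq(0, 1, length.out = n_grid)
  dens <- lapply(qed, density_on_grid, n_grid = n_grid)
  T_ <- length(qed)
  ov <- matrix(1, T_, T_, dimnames = list(names(qed), names(qed)))
  dx <- diff(grid[1:2])
  for (i in seq_len(T_)) {
    for (j in seq_len(T_)) {
      ov[i, j] <- sum(pmin(dens[[i]], dens[[j]])) * dx
    }
  }
  structure(list(qed = qed, overlap = ov, grid = grid, densities = dens),
            class = "qed_profile")
}

#' Inter-task activity correlation
#'
#' Correlation of per-target pIC50 columns over pairwise-complete molecules
#' (those measured on both targets of a pair).
#'
#' @param labels n x T label matrix.
#' @param mask n x T logical mask.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_overlap Minimum co-labelled molecules per pair; sparser pairs
#'   get NA.
#' @return Symmetric T x T correlation matrix with unit diagonal.
#' @export
task_correlation <- function(labels, mask, method = c("pearson", "spearman"),
                             min_overlap = 3L) {
  method <- match.arg(method)
  stopifnot(all(dim(labels) == dim(mask)))
  T_ <- ncol(labels)
  out <- matrix(NA_real_, T_, T_, dimnames = list(colnames(labels), colnames(labels)))
  diag(out) <- 1
  for (i in seq_len(T_)) {
    for (j in seq_len(T_)) {
      if (i >= j) next
      sel <- mask[, i] & mask[, j]
      if (sum(sel) < min_overlap) next
      out[i, j] <- out[j, i] <- stats::cor(labels[sel, i], labels[sel, j],
                                           method = method)
    }
  }
  out
}
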