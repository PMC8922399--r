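#' @title Distance-to-model applicability domain
#' @description Fits a distance threshold `D_T = d_ave + Z * theta` from the
#'   nearest-neighbor distance distribution of the training fingerprints and
#'   classifies query molecules as inside/outside the domain with a
#'   k-nearest-neighbor rule: a compound is outside the domain as soon as
#'   one of its k nearest training distances exceeds `D_T`.
#' @name applicability-domain
NULL

fp_distance_matrix <- function(q, train, kind) {
  if (kind == "one_minus_tanimoto") {
    inter <- q %*% t(train)
    nq <- rowSums(q)
    nt <- rowSums(train)
    union <- outer(nq, nt, "+") - inter
    d <- 1 - inter / union
    d[union == 0] <- 0  # two empty fingerprints are identical
    d
  } else {
    # Euclidean normalized by sqrt(n_bits) so distances live in [0, 1]
    nb <- ncol(train)
    inter <- q %*% t(train)
    sq <- outer(rowSums(q), rowSums(train), "+") - 2 * inter
    sqrt(pmax(sq, 0)) / sqrt(nb)
  }
}

#' Applicability-domain threshold arithmetic
#'
#' `D_T = d_ave + Z * theta`: the mean nearest-neighbor distance of the
#' training set shifted by `Z` standard deviations.
#'
#' @param d_ave Mean nearest-neighbor distance.
#' @param theta Standard deviation of nearest-neighbor distances.
#' @param Z Significance multiplier (often negative, tightening the domain).
#' @return Numeric threshold(s).
#' @export
ad_threshold <- function(d_ave, theta, Z) {
  stopifnot(d_ave >= 0, theta >= 0)
  d_ave + Z * theta
}

#' Fit an applicability domain on training molecules
#'
#' Each training compound's distance to its nearest *other* training
#' compound is computed on binary Morgan fingerprints; `d_ave` and `theta`
#' are the mean and standard deviation of those distances.
#'
#' @param train Character vector of training SMILES, or a precomputed 0/1
#'   fingerprint matrix.
#' @param distance_kind `"one_minus_tanimoto"` (default) or
#'   `"euclidean_normalized"` (Euclidean divided by sqrt(n_bits)).
#' @param Z Threshold multiplier.
#' @param k Number of nearest neighbors checked at classification time.
#' @param radius,nbits Morgan fingerprint parameters.
#' @return `ad_model` list: `fingerprints`, `d_ave`, `theta`, `Z`, `k`,
#'   `D_T`, `distance_kind`, fingerprint settings.
#' @export
fit_ad <- function(train, distance_kind = c("one_minus_tanimoto",
                                            "euclidean_normalized"),
                   Z = -0.25, k = 3L, radius = 2L, nbits = 2048L) {
  distance_kind <- match.arg(distance_kind)
  fps <- if (is.matrix(train)) train else
    chem_fingerprints(train, "morgan", radius = radius, nbits = nbits)
  nbits <- ncol(fps)
  if (nrow(fps) < 2) stop("need at least 2 training molecules")
  if (k < 1 || k > nrow(fps)) stop("k must be in [1, n_train]")
  d <- fp_distance_matrix(fps, fps, distance_kind)
  diag(d) <- Inf  # self-exclusion
  nn <- apply(d, 1, min)
  d_ave <- mean(nn)
  theta <- stats::sd(nn)
  structure(list(fingerprints = fps, d_ave = d_ave, theta = theta,
                 Z = Z, k = as.integer(k),
                 D_T = ad_threshold(d_ave, theta, Z),
                 distance_kind = distance_kind,
                 radius = as.integer(radius), nbits = as.integer(nbits)),
            class = "ad_model")
}

#' Classify molecules against a fitted applicability domain
#'
#' @param ad `ad_model`.
#' @param molecules Character vector of SMILES or a fingerprint matrix with
#'   the model's bit length.
#' @param k,Z Optional overrides of the fitted values (the threshold is
#'   recomputed for a new `Z`).
#' @return data.frame with `in_domain` (logical), `max_k_distance`, and a
#'   `k_distances` list-column of the k ascending nearest distances.
#' @export
classify_ad <- function(ad, molecules, k = ad$k, Z = ad$Z) {
  stopifnot(inherits(ad, "ad_model"))
  if (k < 1 || k > nrow(ad$fingerprints)) stop("k exceeds training set size")
  fps <- if (is.matrix(molecules)) molecules else
    chem_fingerprints(molecules, "morgan", radius = ad$radius, nbits = ad$nbits)
  D_T <- ad_threshold(ad$d_ave, ad$theta, Z)
  d <- fp_distance_matrix(fps, ad$fingerprints, ad$distance_kind)
  kd <- t(apply(d, 1, function(row) sort(row, partial = k)[seq_len(k)]))
  if (k == 1) kd <- matrix(kd, ncol = 1)
  kd <- t(apply(kd, 1, sort))
  if (k == 1) kd <- matrix(kd, ncol = 1)
  mx <- kd[, k]
  data.frame(in_domain = mx <= D_T, max_k_distance = mx,
             k_distances = I(lapply(seq_len(nrow(kd)),
                                    function(i) as.numeric(kd[i, ]))))
}

#' Sweep the (k, Z) grid of an applicability domain
#'
#' For every combination: the threshold, the number of out-of-domain test
#' compounds, and (when predictions and labels are supplied) metric reports
#' for the inside- and outside-domain partitions.
#'
#' @param ad Fitted `ad_model`.
#' @param molecules Test SMILES or fingerprint matrix.
#' @param k_values,Z_values Non-empty grids.
#' @param pred,labels,mask Optional prediction/label/mask matrices aligned
#'   with `molecules` for partitioned metrics.
#' @return data.frame with one row per (k, Z): `k`, `Z`, `D_T`, `n_OD`, and
#'   when evaluable `r2_id`, `r2_od`, `mae_id`, `mae_od`, `rmse_id`,
#'   `rmse_od` (global metrics over targets; NA when a partition is too
#'   small).
#' @export
ad_sweep <- function(ad, molecules, k_values = 3:5,
                     Z_values = c(-0.25, -0.2, -0.15, -0.1),
                     pred = NULL, labels = NULL, mask = NULL) {
  if (!length(k_values) || !length(Z_values)) stop("empty sweep grid")
  fps <- if (is.matrix(molecules)) molecules else
    chem_fingerprints(molecules, "morgan", radius = ad$radius, nbits = ad$nbits)
  rows <- list()
  part_metric <- function(sel, which_) {
    if (is.null(pred) || sum(sel) < 2) return(c(NA_real_, NA_real_, NA_real_))
    rep_ <- tryCatch(
      metrics_report(pred[sel, , drop = FALSE], labels[sel, , drop = FALSE],
                     mask[sel, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(rep_)) return(c(NA_real_, NA_real_, NA_real_))
    g <- rep_[rep_$target == "global", ]
    c(g$r2, g$mae, g$rmse)
  }
  for (k in k_values) {
    for (Z in Z_values) {
      verdict <- classify_ad(ad, fps, k = k, Z = Z)
      id <- verdict$in_domain
      m_id <- part_metric(id, "id")
      m_od <- part_metric(!id, "od")
      rows[[length(rows) + 1]] <- data.frame(
        k = k, Z = Z, D_T = ad_threshold(ad$d_ave, ad$theta, Z),
        n_OD = sum(!id),
        r2_id = m_id[1], r2_od = m_od[1], mae_id = m_id[2], mae_od = m_od[2],
        rmse_id = m_id[3], rmse_od = m_od[3])
    }
  }
  do.call(rbind, rows)
}

#' Serialize / restore an applicability domain as JSON
#' @param ad `ad_model`.
#' @param path Output file.
#' @export
write_ad_json <- function(ad, path) {
  obj <- unclass(ad)
  obj$fingerprints <- apply(ad$fingerprints, 1, function(r) which(r == 1L),
                            simplify = FALSE)
  obj$n_train <- nrow(ad$fingerprints)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ad_json
#' @return `read_ad_json` returns the restored `ad_model`.
#' @export
read_ad_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fps <- matrix(0L, obj$n_train, obj$nbits)
  for (i in seq_len(obj$n_train)) fps[i, unlist(obj$fingerprints[[i]])] <- 1L
  structure(list(fingerprints = fps, d_ave = obj$d_ave, theta = obj$theta,
                 Z = obj$Z, k = as.integer(obj$k), D_T = obj$D_T,
                 distance_kind = obj$distance_kind,
                 radius = as.integer(obj$radius), nbits = as.integer(obj$nbits)),
            class = "ad_model")
}
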