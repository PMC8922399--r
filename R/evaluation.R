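#' @title Regression metrics and model evaluation
#' @description Per-task coefficient of determination, mean absolute error
#'   and root-mean-square error; global metrics as unweighted means across
#'   tasks; rank-based AUC after binarizing truth at an activity threshold;
#'   and a gradient-boosted fingerprint baseline sharing the same splits.
#' @name evaluation
NULL

#' Coefficient of determination
#'
#' `1 - sum((yhat - y)^2) / sum((mean(y) - y)^2)`.
#'
#' @param y Observed values (length >= 2, non-zero variance).
#' @param yhat Predicted values.
#' @return Scalar R2 (can be negative; at most 1).
#' @export
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (length(y) < 2) stop("need at least 2 observations")
  tss <- sum((mean(y) - y)^2)
  if (tss == 0) stop("zero variance in y: R2 undefined")
  1 - sum((yhat - y)^2) / tss
}

#' Mean absolute error
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Scalar MAE.
#' @export
mae <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  mean(abs(y - yhat))
}

#' Root-mean-square error
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return Scalar RMSE.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  sqrt(mean((y - yhat)^2))
}

#' Per-target and global metrics
#'
#' Computes R2/MAE/RMSE per target over the labelled entries, then appends a
#' `global` row of unweighted means across targets (the multitask summary
#' convention). Targets with fewer than 2 labels or zero label variance get
#' NA metrics and are excluded from the global mean.
#'
#' @param pred n x T prediction matrix.
#' @param labels n x T label matrix.
#' @param mask n x T logical mask.
#' @param targets Target names (default: column names).
#' @param pool Also append a `pooled` row computed over all masked entries
#'   at once (sample pooling instead of task averaging).
#' @return data.frame with columns `target`, `n`, `r2`, `mae`, `rmse`.
#' @export
metrics_report <- function(pred, labels, mask, targets = colnames(labels),
                           pool = FALSE) {
  stopifnot(all(dim(pred) == dim(labels)), all(dim(labels) == dim(mask)))
  rows <- lapply(seq_len(ncol(labels)), function(t) {
    sel <- mask[, t]
    n <- sum(sel)
    if (n < 2 || stats::var(labels[sel, t]) == 0) {
      return(data.frame(target = targets[t], n = n, r2 = NA_real_,
                        mae = NA_real_, rmse = NA_real_))
    }
    data.frame(target = targets[t], n = n,
               r2 = r2(labels[sel, t], pred[sel, t]),
               mae = mae(labels[sel, t], pred[sel, t]),
               rmse = rmse(labels[sel, t], pred[sel, t]))
  })
  rep_ <- do.call(rbind, rows)
  if (all(is.na(rep_$r2))) stop("no target has computable metrics")
  glob <- data.frame(target = "global", n = sum(rep_$n),
                     r2 = mean(rep_$r2, na.rm = TRUE),
                     mae = mean(rep_$mae, na.rm = TRUE),
                     rmse = mean(rep_$rmse, na.rm = TRUE))
  out <- rbind(rep_, glob)
  if (pool) {
    sel <- as.logical(mask)
    out <- rbind(out, data.frame(target = "pooled", n = sum(mask),
                                 r2 = r2(labels[sel], pred[sel]),
                                 mae = mae(labels[sel], pred[sel]),
                                 rmse = rmse(labels[sel], pred[sel])))
  }
  out
}

#' Unweighted global means from per-target reports
#'
#' @param reports data.frame of per-target rows (columns `target`, `n`,
#'   `r2`, `mae`, `rmse`), e.g. several outputs of [metrics_report()]
#'   stacked without their global rows.
#' @return Single-row data.frame of means across targets.
#' @export
global_metrics <- function(reports) {
  rep_ <- reports[!reports$target %in% c("global", "pooled"), , drop = FALSE]
  rep_ <- rep_[!is.na(rep_$r2), , drop = FALSE]
  if (nrow(rep_) == 0) stop("no valid per-target metrics")
  data.frame(target = "global", n = sum(rep_$n), r2 = mean(rep_$r2),
             mae = mean(rep_$mae), rmse = mean(rep_$rmse))
}

#' Rank-based AUC of continuous predictions at an activity threshold
#'
#' Truth is binarized at a pIC50 threshold (default 6, i.e. IC50 = 1 uM;
#' compounds at or below 1 uM count as active). The AUC is the
#' Mann-Whitney statistic of the continuous predictions with midrank tie
#' handling.
#'
#' @param y Observed pIC50 values.
#' @param yhat Predicted pIC50 (any strictly monotone score works).
#' @param threshold Activity threshold on the pIC50 scale.
#' @return AUC in `[0, 1]`.
#' @export
auc_at_threshold <- function(y, yhat, threshold = 6.0) {
  stopifnot(length(y) == length(yhat))
  pos <- y >= threshold
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present after thresholding")
  r <- rank(yhat)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gradient-boosted fingerprint baseline
#'
#' Fits one gradient-boosted tree regressor per target on 1024-bit radius-2
#' Morgan (ECFP4-style) fingerprints, using exactly the dataset's splits, and
#' evaluates it with [metrics_report()] on a chosen split. Targets with fewer
#' than 10 training labels are skipped with a warning.
#'
#' @param records Curated record data.frame with splits assigned.
#' @param targets Target names.
#' @param eval_split Split to evaluate on (default `"test"`).
#' @param fingerprint_bits Folded fingerprint length.
#' @param nrounds,max_depth,eta Boosting parameters.
#' @param seed Seed for the boosting fit.
#' @return List with `report` (metrics data.frame incl. global row) and
#'   `predictions` (matrix on the evaluation split).
#' @export
gbm_baseline <- function(records, targets = record_targets(records),
                         eval_split = "test", fingerprint_bits = 1024L,
                         nrounds = 200L, max_depth = 6L, eta = 0.1,
                         seed = 0L) {
  tab <- build_task_table(records, targets)
  fps <- chem_fingerprints(records$canonical_smiles, "morgan",
                           radius = 2L, nbits = fingerprint_bits)
  idx_tr <- which(records$split == "train")
  idx_ev <- which(records$split == eval_split)
  if (!length(idx_ev)) stop("no records in split ", eval_split)
  pred <- matrix(NA_real_, length(idx_ev), length(targets),
                 dimnames = list(NULL, targets))
  for (t in seq_along(targets)) {
    lab_tr <- idx_tr[tab$mask[idx_tr, t]]
    if (length(lab_tr) < 10) {
      warning("target ", targets[t], " has <10 training labels; skipped")
      next
    }
    set.seed(seed)
    booster <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(fps[lab_tr, , drop = FALSE],
                                  label = tab$labels[lab_tr, t]),
      nrounds = nrounds, verbose = 0)
    pred[, t] <- predict(booster, xgboost::xgb.DMatrix(fps[idx_ev, , drop = FALSE]))
  }
  fitted <- !is.na(pred[1, ])
  report <- metrics_report(pred[, fitted, drop = FALSE],
                           tab$labels[idx_ev, fitted, drop = FALSE],
                           tab$mask[idx_ev, fitted, drop = FALSE],
                           targets[fitted])
  list(report = report, predictions = pred)
}

#' Evaluate a trained model on one split of a dataset
#'
#' @param model `mt_model`.
#' @param data `mt_dataset`.
#' @param split Split name (`"train"`, `"valid"`, `"test"`).
#' @param pool See [metrics_report()].
#' @return Metrics data.frame.
#' @export
evaluate_model <- function(model, data, split = "test", pool = FALSE) {
  idx <- which(data$split == split)
  if (!length(idx)) stop("no records in split ", split)
  tsel <- match(model$config$targets, data$targets)
  pred <- mt_forward(batch_graphs(data$graphs[idx]), model)$pred
  metrics_report(pred, data$labels[idx, tsel, drop = FALSE],
                 data$mask[idx, tsel, drop = FALSE],
                 model$config$targets, pool = pool)
}
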