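#' @title Model training, hyperparameter search, Y-randomization
#' @name training
NULL

#' Training configuration
#'
#' Defaults follow common practice for this architecture family: Adam with
#' learning rate 1e-3 and weight decay 1e-6, batches of 256 molecules, at
#' most 1000 epochs with early stopping after 20 epochs without improvement
#' of the monitored validation metric (global R2).
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coupled into the Adam update.
#' @param batch_size Molecules per minibatch.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param monitor `"val_r2"` (maximized) or `"val_loss"` (minimized).
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print per-epoch progress.
#' @return `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-6,
                         batch_size = 256L, max_epochs = 1000L,
                         patience = 20L, monitor = c("val_r2", "val_loss"),
                         seed = 0L, verbose = FALSE) {
  monitor <- match.arg(monitor)
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1, patience < max_epochs)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), monitor = monitor,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Prepare a curated record table for training
#'
#' Featurizes every molecule once and assembles the label/mask matrices.
#'
#' @param records Curated record data.frame (with a filled `split` column).
#' @param targets Target names (default: all pIC50 columns present).
#' @param schema Feature schema.
#' @return `mt_dataset` list: `graphs`, `labels`, `mask`, `split`, `smiles`,
#'   `targets`, `schema`.
#' @export
prepare_dataset <- function(records, targets = record_targets(records),
                            schema = default_feature_schema()) {
  tab <- build_task_table(records, targets)
  graphs <- mol_to_graph(records$canonical_smiles, schema)
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  structure(list(graphs = graphs, labels = tab$labels, mask = tab$mask,
                 split = records$split, smiles = records$canonical_smiles,
                 targets = targets, schema = schema),
            class = "mt_dataset")
}

global_val_r2 <- function(pred, labels, mask) {
  vals <- vapply(seq_len(ncol(labels)), function(t) {
    sel <- mask[, t]
    if (sum(sel) < 2 || stats::var(labels[sel, t]) == 0) return(NA_real_)
    r2(labels[sel, t], pred[sel, t])
  }, 0)
  if (all(is.na(vals))) stop("no target has enough validation labels")
  mean(vals, na.rm = TRUE)
}

#' Train the multitask attentive network
#'
#' Minibatch Adam with early stopping; the returned model carries the
#' parameter snapshot of the best validation epoch, never a later one.
#'
#' @param data `mt_dataset` from [prepare_dataset()] (needs `train` and
#'   `valid` splits).
#' @param model_config `mt_model_config` (its `targets` must be a subset of
#'   the dataset's).
#' @param config `train_config`.
#' @return List with `model` (`mt_model` at the best epoch), `history`
#'   (per-epoch data.frame), `best_epoch`.
#' @export
mt_train <- function(data, model_config, config = train_config()) {
  stopifnot(inherits(data, "mt_dataset"))
  tsel <- match(model_config$targets, data$targets)
  if (anyNA(tsel)) stop("model targets absent from dataset")
  labels <- data$labels[, tsel, drop = FALSE]
  mask <- data$mask[, tsel, drop = FALSE]
  idx_train <- which(data$split == "train" & rowSums(mask) > 0)
  idx_valid <- which(data$split == "valid" & rowSums(mask) > 0)
  if (length(idx_train) == 0) stop("empty training split")
  if (length(idx_valid) == 0) stop("empty validation split")

  model <- mt_model(model_config, data$schema)
  opt <- adam_init(model$params)
  val_batch <- batch_graphs(data$graphs[idx_valid])
  best_metric <- -Inf
  best_params <- model$params
  best_epoch <- 0L
  history <- vector("list", config$max_epochs)

  set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    perm <- idx_train[sample.int(length(idx_train))]
    chunks <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    losses <- numeric(length(chunks))
    for (ci in seq_along(chunks)) {
      ids <- chunks[[ci]]
      batch <- batch_graphs(data$graphs[ids])
      lg <- mt_loss_grad(batch, labels[ids, , drop = FALSE],
                         mask[ids, , drop = FALSE], model, training = TRUE)
      if (!is.finite(lg$loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (learning rate ", config$learning_rate, ")")
      }
      upd <- adam_step(model$params, lg$grads, opt, config$learning_rate,
                       weight_decay = config$weight_decay)
      model$params <- upd$params
      opt <- upd$state
      losses[ci] <- lg$loss
    }
    vpred <- mt_forward(val_batch, model)$pred
    vlab <- labels[idx_valid, , drop = FALSE]
    vmask <- mask[idx_valid, , drop = FALSE]
    val_loss <- masked_mse_loss(vpred, vlab, vmask)
    val_r2 <- global_val_r2(vpred, vlab, vmask)
    metric <- if (config$monitor == "val_r2") val_r2 else -val_loss
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                   val_loss = val_loss, val_r2 = val_r2)
    if (config$verbose) {
      message(sprintf("epoch %4d  train %.4f  val %.4f  valR2 %.4f",
                      epoch, mean(losses), val_loss, val_r2))
    }
    if (is.finite(metric) && metric > best_metric) {
      best_metric <- metric
      best_params <- model$params
      best_epoch <- epoch
    } else if (epoch - best_epoch >= config$patience) {
      break
    }
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
       best_epoch = best_epoch)
}

#' Random hyperparameter search
#'
#' Draws trial configurations from candidate grids (learning rate, dropout,
#' batch size), trains each at a reduced epoch budget, and ranks trials by
#' validation R2.
#'
#' @param data `mt_dataset`.
#' @param model_config Base `mt_model_config`.
#' @param space List of candidate grids: `learning_rate`, `dropout`,
#'   `batch_size` (any may be a single value).
#' @param n_trials Number of random draws.
#' @param budget_epochs Epoch cap per trial.
#' @param patience Early-stopping patience per trial.
#' @param seed Seed for the draw and for each trial's training.
#' @return List with `trials` (ranked data.frame) and `best_config`
#'   (list of the winning learning_rate/dropout/batch_size).
#' @export
random_search <- function(data, model_config,
                          space = list(learning_rate = c(0.1, 0.01, 0.001, 1e-4),
                                       dropout = c(0.2, 0.3, 0.4, 0.5),
                                       batch_size = c(64L, 128L, 256L)),
                          n_trials = 8L, budget_epochs = 30L, patience = 10L,
                          seed = 0L) {
  stopifnot(n_trials >= 1, length(space$learning_rate) >= 1)
  set.seed(seed)
  pick <- function(v) v[sample.int(length(v), n_trials, replace = TRUE)]
  draws <- data.frame(
    trial = seq_len(n_trials),
    learning_rate = pick(space$learning_rate),
    dropout = pick(space$dropout),
    batch_size = pick(space$batch_size)
  )
  draws$val_r2 <- NA_real_
  draws$best_epoch <- NA_integer_
  for (i in seq_len(n_trials)) {
    mc <- model_config
    mc$dropout <- draws$dropout[i]
    tc <- train_config(learning_rate = draws$learning_rate[i],
                       batch_size = draws$batch_size[i],
                       max_epochs = budget_epochs,
                       patience = min(patience, budget_epochs - 1L),
                       seed = seed)
    fit <- tryCatch(mt_train(data, mc, tc), error = function(e) NULL)
    if (!is.null(fit)) {
      draws$val_r2[i] <- max(fit$history$val_r2, na.rm = TRUE)
      draws$best_epoch[i] <- fit$best_epoch
    }
  }
  ranked <- draws[order(-draws$val_r2), ]
  best <- ranked[1, ]
  list(trials = ranked,
       best_config = list(learning_rate = best$learning_rate,
                          dropout = best$dropout,
                          batch_size = best$batch_size))
}

shuffle_labels_within_targets <- function(labels, mask, idx_groups) {
  for (idx in idx_groups) {
    for (t in seq_len(ncol(labels))) {
      lab <- idx[mask[idx, t]]
      if (length(lab) > 1) {
        labels[lab, t] <- labels[sample(lab), t]
      }
    }
  }
  labels
}

#' Y-randomization (label scrambling) validation
#'
#' Permutes labels within each target column (separately inside the training
#' and validation splits, so the mask pattern and per-split label multisets
#' are preserved), retrains the model on the scrambled data for each round,
#' and records train/validation R2. A robust model scores far better than
#' every scrambled refit.
#'
#' @param data `mt_dataset`.
#' @param model_config `mt_model_config`.
#' @param config `train_config`.
#' @param n_rounds Number of scrambling rounds.
#' @param seed Base seed; round r permutes with `seed + r`.
#' @param baseline Optional pre-trained result of [mt_train()] on the
#'   unscrambled data (trained on identical budgets); computed when NULL.
#' @return List with `baseline` (train/valid R2 of the unscrambled model)
#'   and `rounds` (data.frame round, train_r2, valid_r2).
#' @export
y_randomize <- function(data, model_config, config = train_config(),
                        n_rounds = 10L, seed = 0L, baseline = NULL) {
  stopifnot(n_rounds >= 1)
  if (is.null(baseline)) baseline <- mt_train(data, model_config, config)
  eval_split <- function(fit, split) {
    idx <- which(data$split == split)
    tsel <- match(model_config$targets, data$targets)
    pred <- mt_forward(batch_graphs(data$graphs[idx]), fit$model)$pred
    global_val_r2(pred, data$labels[idx, tsel, drop = FALSE],
                  data$mask[idx, tsel, drop = FALSE])
  }
  base <- list(train_r2 = eval_split(baseline, "train"),
               valid_r2 = eval_split(baseline, "valid"))
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    set.seed(seed + r)
    shuf <- data
    shuf$labels <- shuffle_labels_within_targets(
      data$labels, data$mask,
      list(which(data$split == "train"), which(data$split == "valid")))
    fit <- mt_train(shuf, model_config, config)
    eval_shuf <- function(split) {
      idx <- which(shuf$split == split)
      tsel <- match(model_config$targets, shuf$targets)
      pred <- mt_forward(batch_graphs(shuf$graphs[idx]), fit$model)$pred
      global_val_r2(pred, shuf$labels[idx, tsel, drop = FALSE],
                    shuf$mask[idx, tsel, drop = FALSE])
    }
    rounds[[r]] <- data.frame(round = r, train_r2 = eval_shuf("train"),
                              valid_r2 = eval_shuf("valid"))
  }
  list(baseline = base, rounds = do.call(rbind, rounds))
}
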