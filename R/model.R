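#' @title Shared-trunk attentive graph network
#' @description A graph attention regressor for multitask pIC50 prediction:
#'   stacked attentive convolution layers (softmax neighbor attention feeding
#'   a gated recurrent state update per atom), an attentive readout that
#'   builds a molecule super-node over several timesteps, and one linear
#'   regression head per target on the shared molecule embedding. Training
#'   uses a masked mean-squared-error loss so molecules contribute gradient
#'   only for the targets they were measured on.
#' @name mtatfp
NULL

#' Model configuration
#'
#' @param targets Ordered character vector of target names (one regression
#'   head each); length 1 gives the single-task model.
#' @param graph_feat_size Hidden width of atom/molecule state vectors.
#' @param n_attentive_layers Number of attentive convolution layers.
#' @param n_readout_timesteps Readout iterations refining the super-node.
#' @param dropout Dropout rate applied to the molecule embedding during
#'   training.
#' @param leakyrelu_slope Negative slope of the LeakyReLU activations.
#' @param seed Seed for parameter initialization.
#' @return `mt_model_config` list.
#' @export
mt_model_config <- function(targets, graph_feat_size = 300L,
                            n_attentive_layers = 2L, n_readout_timesteps = 2L,
                            dropout = 0.2, leakyrelu_slope = 0.01, seed = 0L) {
  stopifnot(length(targets) >= 1, graph_feat_size >= 1, n_attentive_layers >= 1,
            n_readout_timesteps >= 1, dropout >= 0, dropout < 1)
  structure(list(targets = as.character(targets),
                 graph_feat_size = as.integer(graph_feat_size),
                 n_attentive_layers = as.integer(n_attentive_layers),
                 n_readout_timesteps = as.integer(n_readout_timesteps),
                 dropout = dropout, leakyrelu_slope = leakyrelu_slope,
                 seed = as.integer(seed)),
            class = "mt_model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

gru_init <- function(din, dh) {
  # update-gate bias starts at -1 so early training favors the candidate
  # state over the carry-over, which shortens the initial optimization
  # plateau of deep recurrent message passing
  list(Wz = glorot(din, dh), Uz = glorot(dh, dh), bz = rep(-1, dh),
       Wr = glorot(din, dh), Ur = glorot(dh, dh), br = numeric(dh),
       Wh = glorot(din, dh), Uh = glorot(dh, dh), bhx = numeric(dh),
       bhh = numeric(dh))
}

#' Initialize model parameters
#'
#' Glorot-uniform weights drawn from the config seed; the trunk (input
#' embedding, attentive layers, readout) is drawn before the heads, so two
#' configs differing only in their target list share identical trunk
#' parameters under the same seed.
#'
#' @param config `mt_model_config`.
#' @param schema Feature schema the model will consume.
#' @return Parameter list (`mt_model_state`).
#' @export
init_params <- function(config, schema) {
  set.seed(config$seed)
  D <- config$graph_feat_size
  Fa <- schema$atom_dim
  Fb <- schema$bond_dim
  # the input embedding carries a gain of 3 over plain Glorot: one-hot atom
  # features are sparse and low-magnitude, and a stronger initial contrast
  # between atom states speeds up differentiation of the attention weights
  p <- list(W_in = 3 * glorot(Fa, D), b_in = numeric(D))
  p$layers <- lapply(seq_len(config$n_attentive_layers), function(l) {
    list(Ws = glorot(D, D), Wn = glorot(D + Fb, D),
         a1 = stats::runif(D, -sqrt(3 / D), sqrt(3 / D)),
         a2 = stats::runif(D, -sqrt(3 / D), sqrt(3 / D)),
         gru = gru_init(D, D))
  })
  p$read <- list(Wrs = glorot(D, D), Wrh = glorot(D, D),
                 ar1 = stats::runif(D, -sqrt(3 / D), sqrt(3 / D)),
                 ar2 = stats::runif(D, -sqrt(3 / D), sqrt(3 / D)),
                 gru = gru_init(D, D))
  # heads are initialized one column at a time so that a single-task model
  # shares its head, bit for bit, with the first head of a multitask model
  # drawn from the same seed
  p$Wout <- do.call(cbind, lapply(config$targets, function(t) glorot(D, 1L)))
  p$bout <- numeric(length(config$targets))
  p$schema_id <- schema_id(schema)
  class(p) <- "mt_model_state"
  p
}

#' Assemble a model object
#' @param config `mt_model_config`.
#' @param schema Feature schema.
#' @param params Optional pre-built parameters (default: fresh init).
#' @return `mt_model` list with `config`, `schema`, `params`.
#' @export
mt_model <- function(config, schema = default_feature_schema(),
                     params = init_params(config, schema)) {
  if (!identical(params$schema_id, schema_id(schema))) {
    stop("parameter state was built for a different feature schema")
  }
  structure(list(config = config, schema = schema, params = params),
            class = "mt_model")
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

lrelu <- function(x, slope) ifelse(x > 0, x, slope * x)

gru_forward <- function(x, h, g) {
  z <- stats::plogis(add_bias(x %*% g$Wz + h %*% g$Uz, g$bz))
  r <- stats::plogis(add_bias(x %*% g$Wr + h %*% g$Ur, g$br))
  q <- add_bias(h %*% g$Uh, g$bhh)
  nn <- tanh(add_bias(x %*% g$Wh, g$bhx) + r * q)
  list(h = (1 - z) * nn + z * h, z = z, r = r, q = q, nn = nn, x = x, h_in = h)
}

seg_softmax <- function(logit, gf) {
  mx <- vapply(split(logit, gf), max, numeric(1))
  ex <- exp(logit - mx[as.integer(gf)])
  denom <- rowsum(ex, gf)
  as.numeric(ex / denom[as.integer(gf)])
}

seg_sum <- function(m, gf) {
  rowsum(m, gf)
}

#' Forward pass of the multitask attentive network
#'
#' @param batch A `graph_batch` built under the model's schema.
#' @param model `mt_model`.
#' @param training Logical; when TRUE, dropout is active (drawn from the
#'   current RNG stream).
#' @param keep_cache Keep intermediate activations (needed for gradients and
#'   attention extraction).
#' @return List with `pred` (n_molecules x T matrix, columns named by
#'   target) and, when requested, `cache`.
#' @export
mt_forward <- function(batch, model, training = FALSE, keep_cache = FALSE) {
  stopifnot(inherits(batch, "graph_batch"))
  if (!identical(batch$schema_id, model$params$schema_id)) {
    stop("batch featurized under a different schema than the model")
  }
  cfg <- model$config
  p <- model$params
  slope <- cfg$leakyrelu_slope
  A <- nrow(batch$x)
  M <- length(batch$n_atoms)
  # isolated atoms receive a zero-bond self-loop so every node has at least
  # one incoming message (single-heavy-atom molecules stay scorable)
  edge_src <- batch$edge_src
  edge_dst <- batch$edge_dst
  efeat <- batch$efeat
  lone <- which(tabulate(edge_dst, nbins = A) == 0)
  if (length(lone)) {
    edge_src <- c(edge_src, lone)
    edge_dst <- c(edge_dst, lone)
    efeat <- rbind(efeat, matrix(0, length(lone), ncol(efeat)))
  }
  gf_edge <- factor(edge_dst, levels = seq_len(A))
  gf_mol <- factor(batch$mol_index, levels = seq_len(M))

  h0_pre <- add_bias(batch$x %*% p$W_in, p$b_in)
  h <- lrelu(h0_pre, slope)
  layer_caches <- vector("list", length(p$layers))
  for (l in seq_along(p$layers)) {
    lp <- p$layers[[l]]
    P <- h %*% lp$Ws
    HE <- cbind(h[edge_src, , drop = FALSE], efeat)
    Nsrc <- HE %*% lp$Wn
    logit_pre <- as.numeric(P %*% lp$a1)[edge_dst] +
      as.numeric(Nsrc %*% lp$a2)
    logit <- lrelu(logit_pre, slope)
    align <- seg_softmax(logit, gf_edge)
    C <- seg_sum(align * Nsrc, gf_edge)
    gc_ <- gru_forward(C, h, lp$gru)
    layer_caches[[l]] <- list(h_in = h, P = P, HE = HE, Nsrc = Nsrc,
                              logit_pre = logit_pre, align = align, C = C,
                              gru = gc_)
    h <- gc_$h
  }

  Ph <- h %*% p$read$Wrh
  s <- seg_sum(h, gf_mol) / batch$n_atoms
  s0 <- s
  read_caches <- vector("list", cfg$n_readout_timesteps)
  for (t in seq_len(cfg$n_readout_timesteps)) {
    Ps <- s %*% p$read$Wrs
    logit_pre <- as.numeric(Ps %*% p$read$ar1)[batch$mol_index] +
      as.numeric(Ph %*% p$read$ar2)
    logit <- lrelu(logit_pre, slope)
    align <- seg_softmax(logit, gf_mol)
    cvec <- seg_sum(align * Ph, gf_mol)
    gc_ <- gru_forward(cvec, s, p$read$gru)
    read_caches[[t]] <- list(s_in = s, Ps = Ps, logit_pre = logit_pre,
                             align = align, cvec = cvec, gru = gc_)
    s <- gc_$h
  }

  if (training && cfg$dropout > 0) {
    keep <- matrix(stats::rbinom(length(s), 1, 1 - cfg$dropout) /
                     (1 - cfg$dropout), nrow(s), ncol(s))
    s_drop <- s * keep
  } else {
    keep <- NULL
    s_drop <- s
  }
  # heads are applied column by column: the same embedding then yields
  # identical head outputs whether the model carries one target or many
  pred <- do.call(cbind, lapply(seq_along(cfg$targets), function(t)
    s_drop %*% p$Wout[, t, drop = FALSE] + p$bout[t]))
  colnames(pred) <- cfg$targets

  out <- list(pred = pred)
  if (keep_cache) {
    out$cache <- list(h0_pre = h0_pre, h_final = h, layers = layer_caches,
                      Ph = Ph, s0 = s0, reads = read_caches, s = s,
                      keep = keep, s_drop = s_drop,
                      edge_src = edge_src, edge_dst = edge_dst,
                      gf_edge = gf_edge, gf_mol = gf_mol, batch = batch)
  }
  out
}

#' Neighbor attention weights for one atom
#'
#' Computes `softmax_j(LeakyReLU(a' [W_s h_k || W_n h_j]))` over the
#' neighbor states, the per-node attention used inside each attentive layer.
#' Exposed mainly for inspection and testing; [extract_attention()] returns
#' the same quantities for a whole batch from a forward cache.
#'
#' @param h_k Numeric state vector of the focal atom.
#' @param neighbor_states Matrix (one row per neighbor) of neighbor states,
#'   already concatenated with their bond features (width `D + bond_dim`),
#'   or plain states with `bond_dim = 0` columns padded by the caller.
#' @param layer_params One element of `params$layers` (fields `Ws`, `Wn`,
#'   `a1`, `a2`).
#' @param slope LeakyReLU negative slope.
#' @return Numeric vector of nonnegative weights summing to 1.
#' @export
attention_scores <- function(h_k, neighbor_states, layer_params, slope = 0.01) {
  if (is.null(dim(neighbor_states))) {
    neighbor_states <- matrix(neighbor_states, nrow = 1)
  }
  if (nrow(neighbor_states) < 1) stop("need at least one neighbor")
  pk <- sum((h_k %*% layer_params$Ws) * layer_params$a1)
  logits <- lrelu(pk + as.numeric((neighbor_states %*% layer_params$Wn) %*%
                                    layer_params$a2), slope)
  ex <- exp(logits - max(logits))
  ex / sum(ex)
}

#' Per-layer and readout attention weights from a forward cache
#'
#' @param forward Result of `mt_forward(..., keep_cache = TRUE)`.
#' @return List with `layers` (per layer: data.frame edge_src, edge_dst,
#'   weight) and `readout` (per timestep: data.frame atom, mol, weight).
#' @export
extract_attention <- function(forward) {
  stopifnot(!is.null(forward$cache))
  cache <- forward$cache
  b <- cache$batch
  list(
    layers = lapply(cache$layers, function(lc)
      data.frame(edge_src = cache$edge_src, edge_dst = cache$edge_dst,
                 weight = lc$align)),
    readout = lapply(cache$reads, function(rc)
      data.frame(atom = seq_along(b$mol_index), mol = b$mol_index,
                 weight = rc$align))
  )
}

#' Masked mean-squared-error loss
#'
#' Mean of squared errors over the (molecule, target) entries that carry an
#' experimental label; unlabeled entries contribute neither loss nor
#' gradient.
#'
#' @param pred n x T prediction matrix.
#' @param labels n x T label matrix.
#' @param mask n x T logical matrix, TRUE where a label exists.
#' @return Scalar loss.
#' @export
masked_mse_loss <- function(pred, labels, mask) {
  stopifnot(all(dim(pred) == dim(labels)), all(dim(pred) == dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("mask is all FALSE: no supervised signal")
  sum(((pred - labels)[mask])^2) / n
}

#' Predict pIC50 values for molecules
#'
#' @param model `mt_model`.
#' @param molecules Character vector of SMILES, a `molecular_graph`, a list
#'   of graphs, or a `graph_batch`.
#' @return n x T matrix of predicted pIC50, columns named by target.
#' @export
mt_predict <- function(model, molecules) {
  batch <- as_graph_batch(molecules, model$schema)
  mt_forward(batch, model)$pred
}

as_graph_batch <- function(molecules, schema) {
  if (inherits(molecules, "graph_batch")) return(molecules)
  if (inherits(molecules, "molecular_graph")) return(batch_graphs(list(molecules)))
  if (is.character(molecules)) {
    g <- mol_to_graph(molecules, schema)
    if (inherits(g, "molecular_graph")) g <- list(g)
    return(batch_graphs(g))
  }
  if (is.list(molecules)) return(batch_graphs(molecules))
  stop("cannot interpret 'molecules'")
}
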