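test_that("attention weights are a softmax over neighbors", {
  model <- toy_model()
  lp <- model$params$layers[[1]]
  D <- model$config$graph_feat_size
  Fb <- model$schema$bond_dim
  h_k <- rnorm(D)
  # single neighbor gets weight 1
  nb1 <- matrix(rnorm(D + Fb), 1)
  expect_equal(attention_scores(h_k, nb1, lp), 1)
  # identical neighbors share weight uniformly
  nb <- matrix(rep(nb1, 4), 4, byrow = TRUE)
  expect_equal(attention_scores(h_k, nb, lp), rep(0.25, 4))
  # two-neighbor toy reproduced by independent scalar arithmetic
  set.seed(9)
  nb2 <- matrix(rnorm(2 * (D + Fb)), 2)
  got <- attention_scores(h_k, nb2, lp, slope = 0.01)
  logit <- function(nbrow) {
    z <- sum((h_k %*% lp$Ws) * lp$a1) + sum((nbrow %*% lp$Wn) * lp$a2)
    if (z > 0) z else 0.01 * z
  }
  l <- c(logit(nb2[1, ]), logit(nb2[2, ]))
  expect_equal(got, exp(l) / sum(exp(l)), tolerance = 1e-12)
  expect_equal(sum(got), 1)
})

test_that("every node's attention normalizes at every layer, incl. readout", {
  model <- toy_model()
  batch <- batch_graphs(mol_to_graph(c("CCO", "c1ccncc1C(N)=O", "C"),
                                     model$schema))
  fw <- mt_forward(batch, model, keep_cache = TRUE)
  att <- extract_attention(fw)
  for (layer in att$layers) {
    sums <- tapply(layer$weight, layer$edge_dst, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
  for (step in att$readout) {
    sums <- tapply(step$weight, step$mol, sum)
    expect_true(all(abs(sums - 1) < 1e-6))
  }
})

test_that("masked loss averages only labelled entries", {
  pred <- matrix(c(1, 2), 1)
  lab <- matrix(c(0, 4), 1)
  expect_equal(masked_mse_loss(pred, lab, matrix(c(TRUE, FALSE), 1)), 1)
  expect_equal(masked_mse_loss(pred, lab, matrix(c(TRUE, TRUE), 1)), 2.5)
  expect_equal(masked_mse_loss(pred, pred, matrix(TRUE, 1, 2)), 0)
  expect_error(masked_mse_loss(pred, lab, matrix(FALSE, 1, 2)), "mask")
})

test_that("unlabelled heads receive zero gradient", {
  model <- toy_model()
  batch <- batch_graphs(mol_to_graph(c("CCO", "CCN"), model$schema))
  labels <- matrix(c(5, 6, 0, 0), 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)  # target B fully unlabelled
  lg <- mtqsar:::mt_loss_grad(batch, labels, mask, model, training = FALSE)
  expect_true(all(lg$grads$Wout[, 2] == 0))
  expect_equal(unname(lg$grads$bout[2]), 0)
  expect_true(any(lg$grads$Wout[, 1] != 0))
})

test_that("analytic gradients match central finite differences", {
  schema <- test_schema()
  batch <- batch_graphs(mol_to_graph(c("CCO", "c1ccncc1C(=O)N", "C"), schema))
  cfg <- mt_model_config(c("A", "B"), graph_feat_size = 7,
                         n_attentive_layers = 2, n_readout_timesteps = 2,
                         dropout = 0, seed = 42)
  model <- mt_model(cfg, schema)
  labels <- matrix(c(5.1, 6.2, 4.0, 7.0, 5.5, 6.6), 3, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 3, 2)
  lg <- mtqsar:::mt_loss_grad(batch, labels, mask, model, training = FALSE)
  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    masked_mse_loss(mt_forward(batch, m2)$pred, labels, mask)
  }
  set_leaf <- function(obj, keys, val) {
    k <- keys[[1]]
    if (length(keys) == 1) {
      obj[[k]] <- val
      return(obj)
    }
    obj[[k]] <- set_leaf(obj[[k]], keys[-1], val)
    obj
  }
  get_leaf <- function(obj, keys) {
    for (k in keys) obj <- obj[[k]]
    obj
  }
  paths <- list(list("W_in"), list("b_in"),
                list("layers", 1, "Ws"), list("layers", 1, "Wn"),
                list("layers", 1, "a1"), list("layers", 1, "a2"),
                list("layers", 1, "gru", "Wz"), list("layers", 2, "gru", "Uh"),
                list("layers", 2, "Ws"),
                list("read", "Wrh"), list("read", "ar2"),
                list("read", "gru", "Wh"), list("read", "gru", "bz"),
                list("Wout"), list("bout"))
  eps <- 1e-6
  set.seed(1)
  for (path in paths) {
    leaf <- get_leaf(model$params, path)
    gleaf <- get_leaf(lg$grads, path)
    for (i in sample(length(leaf), min(3, length(leaf)))) {
      v <- leaf
      v[i] <- leaf[i] + eps
      lp <- loss_at(set_leaf(model$params, path, v))
      v[i] <- leaf[i] - eps
      lm <- loss_at(set_leaf(model$params, path, v))
      num <- (lp - lm) / (2 * eps)
      expect_equal(as.numeric(gleaf[i]), num, tolerance = 1e-4,
                   label = paste(unlist(path), collapse = "$"))
    }
  }
})

test_that("predictions are invariant to atom reordering", {
  model <- toy_model()
  g <- mol_to_graph("c1ccncc1C(N)=O", model$schema)
  set.seed(5)
  perm <- sample(g$n_atoms)
  gp <- permute_graph(g, perm)
  p1 <- mt_forward(batch_graphs(list(g)), model)$pred
  p2 <- mt_forward(batch_graphs(list(gp)), model)$pred
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("batched and per-molecule forwards agree", {
  model <- toy_model()
  smiles <- c("CCO", "c1ccncc1", "CC(=O)Nc1ccccc1")
  gs <- mol_to_graph(smiles, model$schema)
  pb <- mt_forward(batch_graphs(gs), model)$pred
  for (i in seq_along(gs)) {
    pi <- mt_forward(batch_graphs(gs[i]), model)$pred
    expect_equal(unname(pb[i, ]), unname(pi[1, ]), tolerance = 1e-12)
  }
})

test_that("a single-target model is the multitask model's first head, bit for bit", {
  schema <- test_schema()
  st <- mt_model(mt_model_config("JAK1", graph_feat_size = 16, dropout = 0,
                                 seed = 11), schema)
  mt <- mt_model(mt_model_config(c("JAK1", "JAK2", "JAK3", "TYK2"),
                                 graph_feat_size = 16, dropout = 0, seed = 11),
                 schema)
  # shared seed: identical trunk, and the first head column coincides
  expect_identical(st$params$W_in, mt$params$W_in)
  expect_identical(st$params$layers, mt$params$layers)
  expect_identical(st$params$read, mt$params$read)
  expect_identical(unname(st$params$Wout[, 1]), unname(mt$params$Wout[, 1]))
  batch <- batch_graphs(mol_to_graph(c("CCO", "c1ccncc1"), schema))
  expect_identical(mt_forward(batch, st)$pred[, "JAK1"],
                   mt_forward(batch, mt)$pred[, "JAK1"])
})

test_that("checkpoints round-trip and refuse mismatched schemas", {
  model <- toy_model()
  path <- tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  batch <- batch_graphs(mol_to_graph("CCO", model$schema))
  expect_equal(mt_forward(batch, back)$pred, mt_forward(batch, model)$pred,
               tolerance = 1e-12)
  expect_error(load_checkpoint(path, default_feature_schema(elements = "C")),
               "schema")
})
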