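# Shared fixtures, built once per test run and cached in-process.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) assign(key, force(expr), envir = .test_cache)
  get(key, envir = .test_cache)
}

test_schema <- function() cached("schema", default_feature_schema())

# the reference fixture dataset: 400 molecules, 4 tasks, sparse third task
ref_fixture <- function() cached("fx", make_fixture_dataset(fixture_spec(seed = 7)))

ref_dataset <- function() cached("data", prepare_dataset(ref_fixture()$records,
                                                         schema = test_schema()))

# desk-scale training settings used across tests: small hidden width, higher
# learning rate and small batches so the optimization converges in seconds
desk_model_config <- function(targets, seed = 1L) {
  mt_model_config(targets, graph_feat_size = 32L, dropout = 0, seed = seed)
}

desk_train_config <- function(seed = 1L, max_epochs = 150L) {
  train_config(learning_rate = 3e-3, batch_size = 32L, max_epochs = max_epochs,
               patience = 60L, monitor = "val_loss", seed = seed)
}

# a small untrained model over the test schema (random but fixed parameters)
toy_model <- function(targets = c("A", "B"), seed = 42L) {
  cached(paste0("toy_model_", paste(targets, collapse = "_"), "_", seed),
         mt_model(mt_model_config(targets, graph_feat_size = 8L, dropout = 0,
                                  seed = seed),
                  test_schema()))
}

# reorder the atoms of a molecular graph: new atom i is old atom perm[i]
permute_graph <- function(g, perm) {
  inv <- integer(g$n_atoms)
  inv[perm] <- seq_len(g$n_atoms)
  src <- inv[g$edge_src]
  dst <- inv[g$edge_dst]
  out <- list(n_atoms = g$n_atoms,
              atom_features = g$atom_features[perm, , drop = FALSE],
              edge_src = src, edge_dst = dst,
              bond_features = g$bond_features,
              neighbor_sets = split(src, factor(dst, levels = seq_len(g$n_atoms))),
              schema_id = g$schema_id)
  class(out) <- "molecular_graph"
  out
}
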