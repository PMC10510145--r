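# The message-passing encoder: hand-computed aggregation examples, the
# scalar-loop oracle, permutation invariance and gradient correctness.

make_state <- function(h_atoms, h_bonds) {
  structure(list(h_atoms = dtakit:::ad_tensor(h_atoms),
                 h_bonds = dtakit:::ad_tensor(h_bonds),
                 layer_index = 0L),
            class = "layer_state")
}

zeroed_params <- function(d = 2, depth = 1) {
  p <- mol_encoder_params(hidden_dim = d, depth = depth, dropout_rate = 0)
  for (t in dtakit:::ad_flatten_params(p)) t$value[] <- 0
  p
}

test_that("initialization applies affine + ReLU rowwise", {
  g <- smiles_to_graph("CCO")
  p <- zeroed_params(d = 3, depth = 1)
  st <- init_hidden(g, p)
  expect_equal(dtakit:::ad_value(st$h_atoms), matrix(0, 3, 3))

  # identity-like map with bias -1: every one-hot coordinate clamps to 0
  p2 <- mol_encoder_params(d_atom = atom_feature_dim(),
                           hidden_dim = atom_feature_dim(), depth = 1,
                           dropout_rate = 0)
  p2$init_atom_w$value <- diag(atom_feature_dim())
  p2$init_atom_b$value[] <- -1
  st2 <- init_hidden(g, p2)
  expect_equal(dtakit:::ad_value(st2$h_atoms),
               matrix(0, 3, atom_feature_dim()))

  # random parameters match the scalar loop elementwise
  set.seed(11)
  p3 <- mol_encoder_params(hidden_dim = 4, depth = 1, dropout_rate = 0)
  st3 <- init_hidden(g, p3)
  manual <- t(apply(g$atom_features, 1, function(x) {
    pmax(as.numeric(x %*% dtakit:::ad_value(p3$init_atom_w)) +
           dtakit:::ad_value(p3$init_atom_b)[1, ], 0)
  }))
  expect_equal(dtakit:::ad_value(st3$h_atoms), manual, tolerance = 1e-12)

  expect_error(init_hidden(g, mol_encoder_params(d_atom = 5, hidden_dim = 4)),
               class = "dtakit_error_config")
})

test_that("neighborhood aggregations follow the max-times-sum rule", {
  # ethane: single incident bond with hidden [2, 3] -> [4, 9]
  g <- smiles_to_graph("CC")
  st <- make_state(matrix(1, 2, 2), matrix(c(2, 3), 1, 2))
  expect_equal(aggregate_bonds_to_atom(st, g, 1), c(4, 9))
  expect_equal(aggregate_bonds_to_bond(st, g, 1), c(0, 0))  # no neighbors

  # one neighbouring atom with hidden [-1, 2] -> [1, 4]
  st2 <- make_state(rbind(c(5, 5), c(-1, 2)), matrix(0, 1, 2))
  expect_equal(aggregate_atoms_to_atom(st2, g, 1), c(1, 4))

  # cyclopropane: atom 1 touches bonds with hiddens [1, 0] and [0, 1]
  g3 <- smiles_to_graph("C1CC1")
  hb <- matrix(0, 3, 2)
  hb[g3$incident_bonds[[1]][1], ] <- c(1, 0)
  hb[g3$incident_bonds[[1]][2], ] <- c(0, 1)
  st3 <- make_state(matrix(0, 3, 2), hb)
  expect_equal(aggregate_bonds_to_atom(st3, g3, 1), c(1, 1))

  # neighbours [1, 2] and [3, 0]: max [3,2] * sum [4,2] -> [12, 4]
  ha <- matrix(0, 3, 2)
  ha[g3$atom_neighbors[[1]][1], ] <- c(1, 2)
  ha[g3$atom_neighbors[[1]][2], ] <- c(3, 0)
  st4 <- make_state(ha, matrix(0, 3, 2))
  expect_equal(aggregate_atoms_to_atom(st4, g3, 1), c(12, 4))

  # cyclopropane bond with neighbour hiddens [1, 1], [2, 0] -> [6, 1]
  hb2 <- matrix(0, 3, 2)
  hb2[g3$bond_neighbors[[1]][1], ] <- c(1, 1)
  hb2[g3$bond_neighbors[[1]][2], ] <- c(2, 0)
  st5 <- make_state(matrix(0, 3, 2), hb2)
  expect_equal(aggregate_bonds_to_bond(st5, g3, 1), c(6, 1))

  # isolated atom: empty neighborhood yields zero
  g1 <- smiles_to_graph("C")
  st6 <- make_state(matrix(1, 1, 2), matrix(0, 0, 2))
  expect_equal(aggregate_bonds_to_atom(st6, g1, 1), c(0, 0))
  expect_equal(aggregate_atoms_to_atom(st6, g1, 1), c(0, 0))
})

test_that("a layer keeps zero states at zero and passes self term on edgeless graphs", {
  g <- smiles_to_graph("CC")
  p <- zeroed_params(d = 2, depth = 1)
  st <- make_state(matrix(0, 2, 2), matrix(0, 1, 2))
  out <- layer_forward(st, g, p)
  expect_equal(dtakit:::ad_value(out$h_atoms), matrix(0, 2, 2))
  expect_equal(out$layer_index, 1L)
  expect_error(layer_forward(out, g, p), class = "dtakit_error_state")

  # no bonds: h_v update reduces to the self term (empty aggregations)
  g1 <- smiles_to_graph("C")
  p1 <- mol_encoder_params(hidden_dim = 2, depth = 1, dropout_rate = 0)
  st1 <- make_state(matrix(1, 1, 2), matrix(0, 0, 2))
  out1 <- layer_forward(st1, g1, p1)
  expect_equal(dtakit:::ad_value(out1$h_atoms), matrix(1, 1, 2))
})

test_that("the full encoder matches the scalar-loop oracle", {
  set.seed(21)
  spec <- synthetic_spec(n_pairs = 20, mol_atom_range = c(1, 8), seed = 77)
  mols <- gen_molecules(spec)
  for (depth in c(1L, 3L)) {
    for (s in mols[1:10]) {
      p <- mol_encoder_params(hidden_dim = 6, depth = depth,
                              dropout_rate = 0)
      g <- smiles_to_graph(s)
      got <- encode_molecule(g, p)
      want <- scalar_encoder(g, p)
      expect_lt(rel_dev(got, want), 1e-6)
      expect_true(all(is.finite(got)))
    }
  }
})

test_that("molecule embeddings are invariant to atom renumbering", {
  set.seed(31)
  spellings <- random_spellings(fixture_smiles, n_per = 3L, seed = 5L)
  p <- mol_encoder_params(hidden_dim = 8, depth = 2, dropout_rate = 0)
  for (k in seq_along(fixture_smiles)) {
    ref <- encode_molecule(fixture_smiles[k], p)
    for (sp in spellings[[k]]) {
      expect_lt(rel_dev(encode_molecule(sp, p), ref), 1e-5)
    }
  }
})

test_that("readout pools by summation: disconnected duplicates double the embedding", {
  set.seed(41)
  p <- mol_encoder_params(hidden_dim = 6, depth = 2, dropout_rate = 0)
  one <- encode_molecule("CCO", p)
  two <- encode_molecule("CCO.CCO", p)
  expect_lt(rel_dev(two, 2 * one), 1e-8)

  # single atom: the pooled embedding equals that atom's communicated vector
  g1 <- smiles_to_graph("C")
  em <- encode_molecule(g1, p)
  expect_length(em, 6L)

  pz <- zeroed_params(d = 6, depth = 1)
  expect_equal(encode_molecule("CCO", pz), rep(0, 6))
})

test_that("batched encoding equals per-molecule encoding", {
  set.seed(51)
  p <- mol_encoder_params(hidden_dim = 5, depth = 2, dropout_rate = 0)
  graphs <- lapply(fixture_smiles[1:6], smiles_to_graph)
  batch <- dtakit:::ad_value(
    dtakit:::encode_molecules_batch_ad(graphs, p, training = FALSE))
  for (k in seq_along(graphs)) {
    expect_lt(rel_dev(batch[k, ], encode_molecule(graphs[[k]], p)), 1e-10)
  }
})

test_that("encoder gradients agree with finite differences", {
  set.seed(61)
  p <- mol_encoder_params(hidden_dim = 3, depth = 2, dropout_rate = 0)
  g <- smiles_to_graph("C=CO")
  tensors <- dtakit:::ad_flatten_params(p)
  # evaluate at a generic point: zero biases put ReLU kinks exactly at zero
  for (t in tensors) t$value <- t$value + rnorm(length(t$value), sd = 0.05)
  fn <- function() dtakit:::ad_sum(dtakit:::encode_molecule_ad(g, p))
  dtakit:::ad_zero_grad(p)
  expect_lt(finite_diff_check(fn, tensors), 1e-4)
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(mol_encoder_params(depth = 0), class = "dtakit_error_config")
  expect_error(mol_encoder_params(dropout_rate = 1),
               class = "dtakit_error_config")
})
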