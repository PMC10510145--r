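# Undirected cross-message-passing encoder for molecular graphs.
#
# Atoms and bonds carry hidden vectors of a shared width d.  Each layer runs
# three aggregations over the graph -- bonds-to-atom, atoms-to-atom and
# bonds-to-bond -- where every aggregation is the elementwise product of the
# neighborhood maximum and the neighborhood sum.  Atom states update by
# summing the two atom-directed messages with the previous state; bond states
# update through a learned linear map with a residual connection, ReLU and
# dropout.  The readout concatenates the final atom state with the two final
# atom-directed messages, passes them through a shared affine + ReLU
# "communicate" map, and sum-pools over atoms.

#' Create parameters for the molecular encoder
#'
#' @param d_atom Width of atom feature rows (default [atom_feature_dim()]).
#' @param d_bond Width of bond feature rows (default [bond_feature_dim()]).
#' @param hidden_dim Shared hidden width d of atom and bond states.
#' @param depth Number of message-passing layers L (>= 1).
#' @param dropout_rate Dropout probability on the bond update, in [0, 1).
#' @return An `encoder_params` list of parameter tensors.
#' @export
mol_encoder_params <- function(d_atom = atom_feature_dim(),
                               d_bond = bond_feature_dim(),
                               hidden_dim = 128L, depth = 3L,
                               dropout_rate = 0.1) {
  if (depth < 1L) {
    rlang::abort("`depth` must be at least 1", class = "dtakit_error_config")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    rlang::abort("`dropout_rate` must lie in [0, 1)",
                 class = "dtakit_error_config")
  }
  # The three message functions multiply a state by a neighborhood max and a
  # neighborhood sum, so state magnitudes grow cubically with depth; starting
  # the input maps small keeps the forward pass bounded at the stock depths.
  p <- list(
    init_atom_w = ad_param(d_atom, hidden_dim, gain = 0.25),
    init_atom_b = ad_param_zero(1L, hidden_dim),
    init_bond_w = ad_param(d_bond, hidden_dim, gain = 0.25),
    init_bond_b = ad_param_zero(1L, hidden_dim),
    bond_update_w = lapply(seq_len(depth), function(l) {
      ad_param(hidden_dim, hidden_dim)
    }),
    communicate_w = ad_param(3L * hidden_dim, hidden_dim),
    communicate_b = ad_param_zero(1L, hidden_dim),
    d_atom = d_atom, d_bond = d_bond,
    hidden_dim = hidden_dim, depth = as.integer(depth),
    dropout_rate = dropout_rate
  )
  class(p) <- "encoder_params"
  p
}

#' Initial hidden state of a molecular graph
#'
#' Applies the initial affine map + ReLU to every atom and bond feature row,
#' yielding the layer-0 state: `h = ReLU(Linear(x))` for both atoms and bonds.
#'
#' @param graph A [smiles_to_graph()] result.
#' @param params [mol_encoder_params()] output.
#' @return A `layer_state` list with `h_atoms`, `h_bonds` (autodiff tensors)
#'   and `layer_index = 0`.
#' @export
init_hidden <- function(graph, params) {
  if (ncol(graph$atom_features) != params$d_atom ||
      ncol(graph$bond_features) != params$d_bond) {
    rlang::abort("graph feature widths do not match encoder parameters",
                 class = "dtakit_error_config")
  }
  h_atoms <- ad_relu(ad_add_bias(
    ad_matmul(ad_tensor(graph$atom_features), params$init_atom_w),
    params$init_atom_b))
  h_bonds <- if (graph$n_bonds > 0L) {
    ad_relu(ad_add_bias(
      ad_matmul(ad_tensor(graph$bond_features), params$init_bond_w),
      params$init_bond_b))
  } else {
    ad_tensor(matrix(0, 0L, params$hidden_dim))
  }
  structure(list(h_atoms = h_atoms, h_bonds = h_bonds, layer_index = 0L),
            class = "layer_state")
}

agg_maxsum_numeric <- function(h, idx) {
  if (length(idx) == 0L) return(numeric(ncol(h)))
  block <- h[idx, , drop = FALSE]
  apply(block, 2L, max) * colSums(block)
}

#' Aggregate incident bond states onto one atom
#'
#' Elementwise `max * sum` over the hidden rows of the bonds touching atom
#' `v`; the zero vector when the atom has no bonds.
#'
#' @param state A `layer_state`.
#' @param graph The corresponding `molecular_graph`.
#' @param v Atom index (1-based).
#' @return Numeric vector of length `hidden_dim`.
#' @export
aggregate_bonds_to_atom <- function(state, graph, v) {
  agg_maxsum_numeric(ad_value(state$h_bonds), graph$incident_bonds[[v]])
}

#' Aggregate neighbouring atom states onto one atom
#' @inheritParams aggregate_bonds_to_atom
#' @return Numeric vector of length `hidden_dim`.
#' @export
aggregate_atoms_to_atom <- function(state, graph, v) {
  agg_maxsum_numeric(ad_value(state$h_atoms), graph$atom_neighbors[[v]])
}

#' Aggregate neighbouring bond states onto one bond
#'
#' Neighbours are the bonds sharing exactly one endpoint atom with bond `e`;
#' the bond's own state never participates.
#'
#' @param state A `layer_state`.
#' @param graph The corresponding `molecular_graph`.
#' @param e Bond index (1-based).
#' @return Numeric vector of length `hidden_dim`.
#' @export
aggregate_bonds_to_bond <- function(state, graph, e) {
  agg_maxsum_numeric(ad_value(state$h_bonds), graph$bond_neighbors[[e]])
}

# One message-passing layer on autodiff tensors; returns the new state plus
# the two atom-directed message terms (used by the readout at the top layer).
layer_forward_ad <- function(h_atoms, h_bonds, graph, params, layer,
                             training = FALSE) {
  f_ev <- ad_neighbor_maxsum(h_bonds, graph$incident_bonds)
  h_ev <- ad_mul(h_atoms, f_ev)
  f_vv <- ad_neighbor_maxsum(h_atoms, graph$atom_neighbors)
  h_vv <- ad_mul(h_atoms, f_vv)
  new_atoms <- ad_add(ad_add(h_ev, h_vv), h_atoms)
  new_bonds <- if (graph$n_bonds > 0L) {
    f_ee <- ad_neighbor_maxsum(h_bonds, graph$bond_neighbors)
    h_ee <- ad_mul(h_bonds, f_ee)
    ad_dropout(
      ad_relu(ad_add(ad_matmul(h_ee, params$bond_update_w[[layer]]), h_bonds)),
      params$dropout_rate, training)
  } else h_bonds
  list(h_atoms = new_atoms, h_bonds = new_bonds, h_ev = h_ev, h_vv = h_vv)
}

#' Advance the encoder state by one layer
#'
#' Computes the three neighborhood messages, updates every atom state by
#' summing the bond-to-atom message, the atom-to-atom message and the previous
#' state, and updates every bond state through the learned linear map with a
#' residual connection, ReLU and (training only) dropout.
#'
#' @param state `layer_state` at layer l - 1.
#' @param graph The corresponding `molecular_graph`.
#' @param params [mol_encoder_params()] output.
#' @param training Logical; enables dropout.
#' @return The `layer_state` at layer l.
#' @export
layer_forward <- function(state, graph, params, training = FALSE) {
  if (state$layer_index >= params$depth) {
    rlang::abort("state is already at the encoder depth",
                 class = "dtakit_error_state")
  }
  out <- layer_forward_ad(state$h_atoms, state$h_bonds, graph, params,
                          state$layer_index + 1L, training)
  structure(list(h_atoms = out$h_atoms, h_bonds = out$h_bonds,
                 layer_index = state$layer_index + 1L),
            class = "layer_state")
}

# Readout on autodiff tensors.  The two aggregated atom messages are
# recomputed from the final state, concatenated with it, passed through the
# shared communicate map, and sum-pooled over atoms.
readout_ad <- function(h_atoms, h_bonds, graph, params) {
  f_ev <- ad_neighbor_maxsum(h_bonds, graph$incident_bonds)
  h_ev <- ad_mul(h_atoms, f_ev)
  f_vv <- ad_neighbor_maxsum(h_atoms, graph$atom_neighbors)
  h_vv <- ad_mul(h_atoms, f_vv)
  comm <- ad_relu(ad_add_bias(
    ad_matmul(ad_cbind(list(h_atoms, h_vv, h_ev)), params$communicate_w),
    params$communicate_b))
  ad_colsums(comm)
}

#' Pool the final state into a molecule embedding
#'
#' Per atom, the final hidden state and the two atom-directed messages
#' recomputed at the final layer are concatenated (width 3d), mapped through
#' the shared communicate affine + ReLU (width d) and sum-pooled over atoms.
#' The result is invariant to atom reordering.
#'
#' @param state The depth-L `layer_state`.
#' @param graph The corresponding `molecular_graph`.
#' @param params [mol_encoder_params()] output.
#' @return Numeric vector of length `hidden_dim` (the molecule embedding).
#' @export
readout <- function(state, graph, params) {
  drop(ad_value(readout_ad(state$h_atoms, state$h_bonds, graph, params)))
}

# Full forward pass on autodiff tensors: 1 x d molecule embedding.
encode_molecule_ad <- function(graph, params, training = FALSE) {
  st <- init_hidden(graph, params)
  h_atoms <- st$h_atoms; h_bonds <- st$h_bonds
  for (l in seq_len(params$depth)) {
    out <- layer_forward_ad(h_atoms, h_bonds, graph, params, l, training)
    h_atoms <- out$h_atoms; h_bonds <- out$h_bonds
  }
  readout_ad(h_atoms, h_bonds, graph, params)
}

#' Encode a molecule into its embedding vector
#'
#' Runs the full message-passing encoder (initialization, `depth` layers,
#' readout) in evaluation mode.
#'
#' @param graph A `molecular_graph`, or a SMILES string.
#' @param params [mol_encoder_params()] output.
#' @return Numeric vector of length `hidden_dim`.
#' @examples
#' \dontrun{
#' p <- mol_encoder_params(hidden_dim = 8, depth = 2)
#' encode_molecule("CCO", p)
#' }
#' @export
encode_molecule <- function(graph, params) {
  if (is.character(graph)) graph <- smiles_to_graph(graph)
  drop(ad_value(encode_molecule_ad(graph, params, training = FALSE)))
}

# Combine several graphs into one disconnected graph (index offsets); the
# message passing is purely local, so encoding the union equals encoding each
# molecule separately.  `pool` maps combined atom rows to their molecule.
combine_graphs <- function(graphs) {
  n_at <- vapply(graphs, function(g) g$n_atoms, integer(1))
  n_bd <- vapply(graphs, function(g) g$n_bonds, integer(1))
  at_off <- cumsum(c(0L, n_at[-length(n_at)]))
  bd_off <- cumsum(c(0L, n_bd[-length(n_bd)]))
  shift <- function(lists, off) {
    do.call(c, lapply(seq_along(lists), function(k) {
      lapply(lists[[k]], function(v) v + off[k])
    }))
  }
  pool <- matrix(0, length(graphs), sum(n_at))
  for (k in seq_along(graphs)) {
    pool[k, at_off[k] + seq_len(n_at[k])] <- 1
  }
  list(
    n_atoms = sum(n_at), n_bonds = sum(n_bd),
    atom_features = do.call(rbind, lapply(graphs, `[[`, "atom_features")),
    bond_features = do.call(rbind, lapply(graphs, `[[`, "bond_features")),
    atom_neighbors = shift(lapply(graphs, `[[`, "atom_neighbors"), at_off),
    incident_bonds = shift(lapply(graphs, `[[`, "incident_bonds"), bd_off),
    bond_neighbors = shift(lapply(graphs, `[[`, "bond_neighbors"), bd_off),
    pool = pool
  )
}

# Batched encoder: one forward pass over the combined graph, sum-pooled per
# molecule.  Returns a (n molecules) x d tensor whose rows equal the
# individual encode_molecule_ad outputs.
encode_molecules_batch_ad <- function(graphs, params, training = FALSE) {
  cg <- combine_graphs(graphs)
  h_atoms <- ad_relu(ad_add_bias(
    ad_matmul(ad_tensor(cg$atom_features), params$init_atom_w),
    params$init_atom_b))
  h_bonds <- if (cg$n_bonds > 0L) {
    ad_relu(ad_add_bias(
      ad_matmul(ad_tensor(cg$bond_features), params$init_bond_w),
      params$init_bond_b))
  } else ad_tensor(matrix(0, 0L, params$hidden_dim))
  for (l in seq_len(params$depth)) {
    out <- layer_forward_ad(h_atoms, h_bonds, cg, params, l, training)
    h_atoms <- out$h_atoms; h_bonds <- out$h_bonds
  }
  f_ev <- ad_neighbor_maxsum(h_bonds, cg$incident_bonds)
  h_ev <- ad_mul(h_atoms, f_ev)
  f_vv <- ad_neighbor_maxsum(h_atoms, cg$atom_neighbors)
  h_vv <- ad_mul(h_atoms, f_vv)
  comm <- ad_relu(ad_add_bias(
    ad_matmul(ad_cbind(list(h_atoms, h_vv, h_ev)), params$communicate_w),
    params$communicate_b))
  ad_matmul(ad_tensor(cg$pool), comm)
}
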