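# Molecule-to-protein attention fusion and the MLP regression head.
#
# The molecule embedding queries the per-segment protein embedding: both are
# projected (affine-free linear maps + ReLU) into a shared attention width,
# their dot products squashed by tanh give one score per protein segment, and
# the score-weighted sum of projected protein rows, mapped through a further
# linear layer, is the attended protein summary.  The summary and the
# molecule embedding are concatenated and regressed to a single affinity by
# an MLP.  Attention runs from molecule to protein only.

#' Create fusion and regression-head parameters
#'
#' @param d_mol Width of the molecule embedding.
#' @param d_prot Width of one protein-embedding row.
#' @param d_att Shared attention width.
#' @param mlp_hidden Integer vector of hidden-layer widths of the MLP head.
#' @param l2_coeff L2 regularization coefficient of the training objective.
#' @return A `fusion_params` list of parameter tensors.
#' @export
fusion_params <- function(d_mol, d_prot, d_att = d_mol,
                          mlp_hidden = c(64L, 32L), l2_coeff = 1e-4) {
  if (l2_coeff < 0) {
    rlang::abort("`l2_coeff` must be non-negative",
                 class = "dtakit_error_config")
  }
  widths <- c(d_mol + d_att, mlp_hidden, 1L)
  p <- list(
    w_m = ad_param(d_mol, d_att),
    w_p = ad_param(d_prot, d_att),
    w_s = ad_param(d_att, d_att),
    mlp = lapply(seq_len(length(widths) - 1L), function(j) list(
      w = ad_param(widths[j], widths[j + 1L]),
      b = ad_param_zero(1L, widths[j + 1L])
    )),
    d_mol = d_mol, d_prot = d_prot, d_att = d_att,
    l2_coeff = l2_coeff
  )
  class(p) <- "fusion_params"
  p
}

#' Attention scores of a molecule over protein segments
#'
#' `Score = tanh( ReLU(W_m E_m) . ReLU(W_p E_p)^T )`: one score per protein
#' segment, each in (-1, 1) and non-negative given the ReLU pre-activations.
#'
#' @param e_m Molecule embedding (length-d_mol vector, 1-row matrix or
#'   tensor).
#' @param e_p Protein embedding matrix/tensor (x rows).
#' @param params [fusion_params()] output.
#' @return A 1-by-x autodiff tensor of scores.
#' @export
attention_score <- function(e_m, e_p, params) {
  e_m <- as_ad(rbind_vec(e_m)); e_p <- as_ad(e_p)
  if (ncol(e_m$value) != params$d_mol || ncol(e_p$value) != params$d_prot) {
    rlang::abort("embedding widths do not match fusion parameters",
                 class = "dtakit_error_config")
  }
  m <- ad_relu(ad_matmul(e_m, params$w_m))
  p <- ad_relu(ad_matmul(e_p, params$w_p))
  ad_tanh(ad_matmul(m, ad_t(p)))
}

#' Re-weight the protein embedding by attention scores
#'
#' The score-weighted sum of the projected protein rows, mapped through
#' `W_s`: a single fixed-width summary vector regardless of the number of
#' segments.
#'
#' @param score 1-by-x score tensor/matrix from [attention_score()].
#' @param e_p Protein embedding matrix/tensor.
#' @param params [fusion_params()] output.
#' @return A 1-by-d_att autodiff tensor.
#' @export
reweight_protein <- function(score, e_p, params) {
  score <- as_ad(rbind_vec(score)); e_p <- as_ad(e_p)
  if (ncol(score$value) != nrow(e_p$value)) {
    rlang::abort("score length must equal the number of protein rows",
                 class = "dtakit_error_config")
  }
  p <- ad_relu(ad_matmul(e_p, params$w_p))
  ad_matmul(ad_matmul(score, p), params$w_s)
}

#' Predict the binding affinity from the two embeddings
#'
#' Concatenates the molecule embedding and the attended protein summary and
#' passes them through the MLP head (ReLU between layers, linear output).
#'
#' @param e_m Molecule embedding.
#' @param e_p_att Attended protein summary from [reweight_protein()].
#' @param params [fusion_params()] output.
#' @return A 1-by-1 autodiff tensor (the predicted affinity).
#' @export
predict_affinity <- function(e_m, e_p_att, params) {
  e_m <- as_ad(rbind_vec(e_m)); e_p_att <- as_ad(rbind_vec(e_p_att))
  if (!all(is.finite(e_m$value)) || !all(is.finite(e_p_att$value))) {
    rlang::abort("non-finite values in the embeddings",
                 class = "dtakit_error_numeric")
  }
  h <- ad_cbind(list(e_m, e_p_att))
  n_layer <- length(params$mlp)
  for (j in seq_len(n_layer)) {
    h <- ad_add_bias(ad_matmul(h, params$mlp[[j]]$w), params$mlp[[j]]$b)
    if (j < n_layer) h <- ad_relu(h)
  }
  h
}

#' Regularized mean-squared-error training objective
#'
#' `mean((yhat - y)^2) + (lambda / 2) * ||Theta||^2`, where Theta collects
#' every learnable parameter passed in `theta`.
#'
#' @param y_hat Predictions (vector, matrix or tensor, one column).
#' @param y Observed affinities.
#' @param params [fusion_params()] output (supplies the L2 coefficient).
#' @param theta Nested list of all trainable tensors to penalize; defaults
#'   to `params`.
#' @return Scalar autodiff tensor.
#' @export
training_loss <- function(y_hat, y, params, theta = params) {
  y_hat <- as_ad(cbind_vec(y_hat))
  y <- ad_tensor(cbind_vec(y))
  diff <- ad_sub(y_hat, y)
  loss <- ad_mean(ad_mul(diff, diff))
  if (params$l2_coeff > 0) {
    pen <- NULL
    for (p in ad_flatten_params(theta)) {
      if (!p$requires_grad) next
      term <- ad_sum(ad_mul(p, p))
      pen <- if (is.null(pen)) term else ad_add(pen, term)
    }
    if (!is.null(pen)) {
      loss <- ad_add(loss, ad_scale(pen, params$l2_coeff / 2))
    }
  }
  loss
}

# coerce a bare vector to a 1 x d row (matrices/tensors pass through)
rbind_vec <- function(x) {
  if (is_ad(x)) return(x)
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

# coerce a bare vector to a d x 1 column
cbind_vec <- function(x) {
  if (is_ad(x)) return(x)
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}
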