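# Protein encoder combining a masked-language-model branch with a
# contrastive-predictive-coding branch.
#
# Sequences over the 20 amino-acid letters are tokenized against a 23-symbol
# vocabulary (residues + PAD, MASK, UNK).  The MLM branch is a small
# self-attention encoder trained to recover masked residues; its output is
# mean-pooled over non-PAD positions.  The CPC branch pads/discards to a fixed
# total length, cuts the sequence into equal segments, encodes each segment
# with a shared convolution stack, summarizes the segment sequence with a
# gated recurrent unit, and trains by discriminating each true future segment
# from segments of other proteins (InfoNCE).  The protein representation used
# downstream is the per-segment matrix of CPC features, each row concatenated
# with the pooled MLM vector.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PAD_ID <- 21L
MASK_ID <- 22L
UNK_ID <- 23L
VOCAB_SIZE <- 23L

#' Tokenize an amino-acid sequence
#'
#' Maps each residue letter to its integer id (1-20 in alphabet order);
#' unknown letters map to the UNK id.
#'
#' @param sequence Character scalar over the amino-acid alphabet.
#' @return Integer vector of token ids.
#' @export
tokenize_protein <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  ids <- match(chars, AA_LETTERS)
  ids[is.na(ids)] <- UNK_ID
  ids
}

#' Filter protein records by sequence length
#'
#' Keeps exactly the records whose sequence length lies inside the inclusive
#' bounds; emulates the corpus-selection rule used for pretraining.
#'
#' @param records A character vector of sequences, or a data frame with a
#'   `sequence` column.
#' @param min_len,max_len Inclusive length bounds.
#' @return The filtered records, same type as the input.
#' @export
length_filter <- function(records, min_len = 70L, max_len = 1000L) {
  if (min_len > max_len) {
    rlang::abort("`min_len` must not exceed `max_len`",
                 class = "dtakit_error_input")
  }
  seqs <- if (is.data.frame(records)) records$sequence else records
  keep <- nchar(seqs) >= min_len & nchar(seqs) <= max_len
  if (is.data.frame(records)) records[keep, , drop = FALSE] else records[keep]
}

#' Segment a protein to fixed-length windows
#'
#' Sequences longer than `l_total` are discarded; shorter ones are padded
#' with PAD tokens up to `l_total`, then cut into `l_total / l_segment`
#' consecutive non-overlapping windows.
#'
#' @param sequence Character scalar or an integer token-id vector.
#' @param l_segment Segment length (the conventional choice is 11).
#' @param l_total Padded total length; must be a multiple of `l_segment`.
#' @return A `segmented_protein` (list with `segments`, an x-by-`l_segment`
#'   integer matrix, `n_segments`, `total_length` and `raw_length`), or a
#'   `discarded_protein` marker when the sequence exceeds `l_total`.
#' @examples
#' sp <- segment_protein(strrep("A", 110), l_segment = 11, l_total = 110)
#' sp$n_segments  # 10
#' @export
segment_protein <- function(sequence, l_segment = 11L, l_total = 990L) {
  if (l_segment < 1L || l_total %% l_segment != 0L) {
    rlang::abort("`l_total` must be a positive multiple of `l_segment`",
                 class = "dtakit_error_config")
  }
  ids <- if (is.character(sequence)) tokenize_protein(sequence) else
    as.integer(sequence)
  n <- length(ids)
  if (n > l_total) {
    return(structure(list(raw_length = n), class = "discarded_protein"))
  }
  padded <- c(ids, rep(PAD_ID, l_total - n))
  x <- l_total %/% l_segment
  structure(
    list(segments = matrix(padded, nrow = x, ncol = l_segment, byrow = TRUE),
         token_ids = padded, n_segments = x, total_length = l_total,
         raw_length = n),
    class = "segmented_protein")
}

#' Corrupt tokens for masked-language-model training
#'
#' Selects `round(mask_rate * n)` of the non-PAD positions uniformly without
#' replacement (at least one) and replaces them with the MASK token.
#' Optionally, the BERT-style 80/10/10 mixing (mask / random residue /
#' unchanged) can be switched on; plain masking is the default.
#'
#' @param token_ids Integer token vector.
#' @param mask_rate Fraction of non-PAD positions to corrupt, in (0, 1).
#' @param seed Optional integer; when given the selection is deterministic.
#' @param bert_mixing Logical, off by default.
#' @return List with `corrupted` (token vector) and `positions` (sorted
#'   indices of the masked positions).
#' @export
mask_for_mlm <- function(token_ids, mask_rate = 0.15, seed = NULL,
                         bert_mixing = FALSE) {
  if (mask_rate <= 0 || mask_rate >= 1) {
    rlang::abort("`mask_rate` must lie strictly between 0 and 1",
                 class = "dtakit_error_input")
  }
  candidates <- which(token_ids != PAD_ID)
  if (length(candidates) == 0L) {
    rlang::abort("cannot mask an all-PAD sequence",
                 class = "dtakit_error_input")
  }
  n_mask <- max(1L, round(mask_rate * length(candidates)))
  pick <- function() sort(sample(candidates, n_mask))
  positions <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  corrupted <- token_ids
  if (bert_mixing) {
    draw <- function() stats::runif(n_mask)
    u <- if (is.null(seed)) draw() else withr::with_seed(seed + 1L, draw())
    rnd <- function() sample(20L, n_mask, replace = TRUE)
    rr <- if (is.null(seed)) rnd() else withr::with_seed(seed + 2L, rnd())
    corrupted[positions[u < 0.8]] <- MASK_ID
    swap <- u >= 0.8 & u < 0.9
    corrupted[positions[swap]] <- rr[swap]
  } else {
    corrupted[positions] <- MASK_ID
  }
  list(corrupted = corrupted, positions = positions)
}

## ---- MLM branch ----

#' Create parameters for the MLM encoder branch
#'
#' A compact self-attention encoder: learned token and position embeddings,
#' `n_layers` blocks of multi-head attention and a feed-forward sublayer
#' (each with residual connection and layer normalization), and a linear
#' vocabulary head.  `size = "base"` and `"large"` select the two stock
#' configurations; explicit arguments override either.
#'
#' @param size `"base"` or `"large"`.
#' @param d_model,n_layers,n_heads,d_ff,max_len Optional overrides.
#' @return An `mlm_params` list of parameter tensors.
#' @export
mlm_params <- function(size = c("base", "large"), d_model = NULL,
                       n_layers = NULL, n_heads = NULL, d_ff = NULL,
                       max_len = 1000L) {
  size <- match.arg(size)
  defaults <- if (size == "base") list(d = 16L, l = 1L, h = 2L, f = 32L)
  else list(d = 32L, l = 2L, h = 4L, f = 64L)
  d_model <- d_model %||% defaults$d
  n_layers <- n_layers %||% defaults$l
  n_heads <- n_heads %||% defaults$h
  d_ff <- d_ff %||% defaults$f
  if (d_model %% n_heads != 0L) {
    rlang::abort("`d_model` must be divisible by `n_heads`",
                 class = "dtakit_error_config")
  }
  dh <- d_model %/% n_heads
  layer <- function() list(
    wq = lapply(seq_len(n_heads), function(i) ad_param(d_model, dh)),
    wk = lapply(seq_len(n_heads), function(i) ad_param(d_model, dh)),
    wv = lapply(seq_len(n_heads), function(i) ad_param(d_model, dh)),
    wo = ad_param(d_model, d_model),
    ln1_g = ad_tensor(matrix(1, 1, d_model), requires_grad = TRUE),
    ln1_b = ad_param_zero(1L, d_model),
    w1 = ad_param(d_model, d_ff), b1 = ad_param_zero(1L, d_ff),
    w2 = ad_param(d_ff, d_model), b2 = ad_param_zero(1L, d_model),
    ln2_g = ad_tensor(matrix(1, 1, d_model), requires_grad = TRUE),
    ln2_b = ad_param_zero(1L, d_model)
  )
  p <- list(
    token_emb = ad_param(VOCAB_SIZE, d_model),
    pos_emb = ad_param(max_len, d_model),
    layers = lapply(seq_len(n_layers), function(i) layer()),
    out_w = ad_param(d_model, VOCAB_SIZE),
    out_b = ad_param_zero(1L, VOCAB_SIZE),
    d_model = d_model, n_layers = n_layers, n_heads = n_heads,
    d_ff = d_ff, max_len = as.integer(max_len), size = size
  )
  class(p) <- "mlm_params"
  p
}

#' Forward pass of the MLM encoder
#'
#' Token embeddings plus learned position embeddings run through the
#' self-attention blocks; a linear head produces per-position vocabulary
#' scores, and the pooled embedding is the mean of the final hidden states
#' over non-PAD positions.
#'
#' @param token_ids Integer token vector (possibly corrupted with MASK).
#' @param params [mlm_params()] output.
#' @return List with `scores` (length-by-vocab tensor), `pooled` (1-by-d
#'   tensor) and `hidden`.
#' @export
mlm_forward <- function(token_ids, params) {
  n <- length(token_ids)
  if (n > params$max_len) {
    rlang::abort("sequence longer than the configured position table",
                 class = "dtakit_error_config")
  }
  x <- ad_add(ad_rows(params$token_emb, token_ids),
              ad_rows(params$pos_emb, seq_len(n)))
  dh <- params$d_model %/% params$n_heads
  for (ly in params$layers) {
    heads <- lapply(seq_len(params$n_heads), function(h) {
      q <- ad_matmul(x, ly$wq[[h]])
      k <- ad_matmul(x, ly$wk[[h]])
      v <- ad_matmul(x, ly$wv[[h]])
      att <- ad_softmax_rows(ad_scale(ad_matmul(q, ad_t(k)), 1 / sqrt(dh)))
      ad_matmul(att, v)
    })
    a <- ad_matmul(ad_cbind(heads), ly$wo)
    x <- ad_add_bias(
      ad_mul_rowvec(ad_layernorm_rows(ad_add(x, a)), ly$ln1_g), ly$ln1_b)
    f <- ad_add_bias(ad_matmul(
      ad_relu(ad_add_bias(ad_matmul(x, ly$w1), ly$b1)), ly$w2), ly$b2)
    x <- ad_add_bias(
      ad_mul_rowvec(ad_layernorm_rows(ad_add(x, f)), ly$ln2_g), ly$ln2_b)
  }
  scores <- ad_add_bias(ad_matmul(x, params$out_w), params$out_b)
  non_pad <- which(token_ids != PAD_ID)
  if (length(non_pad) == 0L) {
    rlang::abort("cannot pool an all-PAD sequence",
                 class = "dtakit_error_input")
  }
  pooled <- ad_colmeans(ad_rows(x, non_pad))
  list(scores = scores, pooled = pooled, hidden = x)
}

#' Masked-language-model loss
#'
#' Mean cross-entropy of the vocabulary scores at the masked positions
#' against the original (uncorrupted) token ids.
#'
#' @param scores Score tensor/matrix from [mlm_forward()].
#' @param positions Masked position indices.
#' @param true_ids The uncorrupted token vector.
#' @return Scalar autodiff tensor.
#' @export
mlm_loss <- function(scores, positions, true_ids) {
  if (length(positions) == 0L) {
    rlang::abort("empty masked-position set", class = "dtakit_error_input")
  }
  logp <- ad_log_softmax_rows(ad_rows(as_ad(scores), positions))
  ad_scale(ad_mean(ad_pick(logp, true_ids[positions])), -1)
}

## ---- CPC branch ----

#' Create parameters for the CPC encoder branch
#'
#' A shared per-segment stack of (1-D convolution, layer normalization, ReLU)
#' blocks followed by mean pooling yields one local feature per segment; a
#' gated recurrent unit summarizes segments causally; `K` bilinear maps score
#' future segments for the contrastive task.
#'
#' @param d_emb Token embedding width inside the branch.
#' @param channels Integer vector of convolution output channels per layer;
#'   the last entry is the local feature width d_c.
#' @param kernel Convolution kernel width (odd).
#' @param prediction_steps K, number of future steps scored.
#' @return A `cpc_params` list of parameter tensors.
#' @export
cpc_params <- function(d_emb = 16L, channels = c(16L, 16L), kernel = 3L,
                       prediction_steps = 1L) {
  if (kernel %% 2L != 1L) {
    rlang::abort("`kernel` must be odd", class = "dtakit_error_config")
  }
  d_c <- channels[length(channels)]
  in_w <- c(d_emb, channels[-length(channels)])
  p <- list(
    token_emb = ad_param(VOCAB_SIZE, d_emb),
    conv = lapply(seq_along(channels), function(j) list(
      w = lapply(seq_len(kernel), function(t) ad_param(in_w[j], channels[j])),
      b = ad_param_zero(1L, channels[j])
    )),
    gru = list(
      wr = ad_param(d_c, d_c), ur = ad_param(d_c, d_c),
      br = ad_param_zero(1L, d_c),
      wu = ad_param(d_c, d_c), uu = ad_param(d_c, d_c),
      bu = ad_param_zero(1L, d_c),
      wn = ad_param(d_c, d_c), un = ad_param(d_c, d_c),
      bn = ad_param_zero(1L, d_c)
    ),
    pred_w = lapply(seq_len(prediction_steps), function(k) {
      ad_param(d_c, d_c)
    }),
    d_emb = d_emb, channels = channels, kernel = kernel,
    d_c = d_c, prediction_steps = as.integer(prediction_steps)
  )
  class(p) <- "cpc_params"
  p
}

#' Encode protein segments into local features
#'
#' Each segment runs independently (shared weights) through the convolution
#' stack and is mean-pooled to one d_c vector; identical segments map to
#' identical rows.
#'
#' @param seg A `segmented_protein`.
#' @param params [cpc_params()] output.
#' @return An x-by-d_c autodiff tensor of per-segment features.
#' @export
cpc_encode_segments <- function(seg, params) {
  if (inherits(seg, "discarded_protein")) {
    rlang::abort("cannot encode a discarded protein",
                 class = "dtakit_error_input")
  }
  x <- seg$n_segments
  ls <- ncol(seg$segments)
  flat <- as.integer(t(seg$segments))          # segment-major token order
  h <- ad_rows(params$token_emb, flat)
  n <- x * ls
  half <- (params$kernel - 1L) %/% 2L
  # Per-offset gather indices; positions outside the segment map to a zero
  # row appended below the real rows, so convolutions never cross segments.
  seg_of <- rep(seq_len(x), each = ls)
  pos_in <- rep(seq_len(ls), times = x)
  gather_idx <- lapply(seq_len(params$kernel), function(t) {
    off <- t - 1L - half
    tgt <- pos_in + off
    idx <- ifelse(tgt >= 1L & tgt <= ls, (seg_of - 1L) * ls + tgt, n + 1L)
    as.integer(idx)
  })
  for (ly in params$conv) {
    hz <- ad_rbind(list(h, ad_tensor(matrix(0, 1L, ncol(h$value)))))
    acc <- NULL
    for (t in seq_len(params$kernel)) {
      term <- ad_matmul(ad_rows(hz, gather_idx[[t]]), ly$w[[t]])
      acc <- if (is.null(acc)) term else ad_add(acc, term)
    }
    h <- ad_relu(ad_layernorm_rows(ad_add_bias(acc, ly$b)))
  }
  # mean-pool within each segment: constant x-by-n averaging matrix
  pool <- matrix(0, x, n)
  pool[cbind(seg_of, seq_len(n))] <- 1 / ls
  ad_matmul(ad_tensor(pool), h)
}

#' Causal segment summary via a gated recurrent unit
#'
#' Row t of the output summarizes segments 1..t; it never depends on later
#' segments.
#'
#' @param z x-by-d_c matrix/tensor of local features.
#' @param params [cpc_params()] output.
#' @return An x-by-d_c autodiff tensor of context vectors.
#' @export
cpc_autoregress <- function(z, params) {
  z <- as_ad(z)
  x <- nrow(z$value)
  d <- params$d_c
  g <- params$gru
  h <- ad_tensor(matrix(0, 1L, d))
  rows <- vector("list", x)
  for (t in seq_len(x)) {
    zt <- ad_rows(z, t)
    r <- ad_sigmoid(ad_add_bias(
      ad_add(ad_matmul(zt, g$wr), ad_matmul(h, g$ur)), g$br))
    u <- ad_sigmoid(ad_add_bias(
      ad_add(ad_matmul(zt, g$wu), ad_matmul(h, g$uu)), g$bu))
    nn <- ad_tanh(ad_add_bias(
      ad_add(ad_matmul(zt, g$wn), ad_mul(r, ad_matmul(h, g$un))), g$bn))
    one_minus_u <- ad_scale(ad_sub(u, ad_tensor(matrix(1, 1L, d))), -1)
    h <- ad_add(ad_mul(one_minus_u, h), ad_mul(u, nn))
    rows[[t]] <- h
  }
  ad_rbind(rows)
}

#' InfoNCE contrastive loss
#'
#' For every position t <= x - K and step k <= K, a bilinear map of the
#' context vector scores the true future segment z\[t+k\] against the supplied
#' negative rows; the loss is the mean cross-entropy of identifying the true
#' segment and the accuracy is the fraction of queries ranking it first.
#'
#' @param c_mat Context matrix/tensor from [cpc_autoregress()].
#' @param z Local feature matrix/tensor.
#' @param negatives Matrix of negative rows (segments of other proteins).
#' @param params [cpc_params()] output.
#' @param steps Number of prediction steps K (defaults to the parameter set).
#' @return List with `loss` (scalar tensor), `accuracy`, `n_queries`.
#' @export
infonce_loss <- function(c_mat, z, negatives, params, steps = NULL) {
  k_max <- steps %||% params$prediction_steps
  c_mat <- as_ad(c_mat); z <- as_ad(z)
  x <- nrow(z$value)
  if (x <= k_max) {
    rlang::abort("sequence has no positive pairs for the requested steps",
                 class = "dtakit_error_input")
  }
  neg <- as_ad(negatives)
  if (nrow(neg$value) < 1L) {
    rlang::abort("need at least one negative row",
                 class = "dtakit_error_input")
  }
  rows <- list()
  correct <- 0
  for (k in seq_len(k_max)) {
    for (t in seq_len(x - k)) {
      q <- ad_matmul(ad_rows(c_mat, t), params$pred_w[[k]])
      cand <- ad_rbind(list(ad_rows(z, t + k), neg))
      logits <- ad_matmul(q, ad_t(cand))
      rows[[length(rows) + 1L]] <- logits
      lv <- logits$value[1L, ]
      top <- which(lv == max(lv))   # ties share the credit
      if (1L %in% top) correct <- correct + 1 / length(top)
    }
  }
  logit_mat <- ad_rbind(rows)
  logp <- ad_log_softmax_rows(logit_mat)
  loss <- ad_scale(ad_mean(ad_rows(ad_t(logp), 1L)), -1)
  list(loss = loss, accuracy = correct / length(rows),
       n_queries = length(rows))
}

## ---- combined embedding ----

#' Combined protein embedding
#'
#' Segments the (possibly truncated) sequence, encodes the CPC local features
#' and the pooled MLM vector from the same padded token vector, and returns
#' the per-segment matrix with the pooled MLM vector concatenated onto every
#' row.
#'
#' @param sequence Amino-acid sequence.
#' @param mlm [mlm_params()] output.
#' @param cpc [cpc_params()] output.
#' @param l_segment,l_total Segmentation geometry; sequences longer than
#'   `l_total` are truncated to it.
#' @return List with `e_p` (x-by-(d_c + d_model) tensor), `z`, `pooled`,
#'   `segmented`.
#' @export
protein_embedding <- function(sequence, mlm, cpc, l_segment = 11L,
                              l_total = 990L) {
  ids <- if (is.character(sequence)) tokenize_protein(sequence) else
    as.integer(sequence)
  if (length(ids) > l_total) ids <- ids[seq_len(l_total)]
  seg <- segment_protein(ids, l_segment, l_total)
  z <- cpc_encode_segments(seg, cpc)
  fwd <- mlm_forward(seg$token_ids, mlm)
  x <- seg$n_segments
  e_p <- ad_cbind(list(z, ad_rows(fwd$pooled, rep(1L, x))))
  list(e_p = e_p, z = z, pooled = fwd$pooled, segmented = seg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
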