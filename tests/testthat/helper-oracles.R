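# Independent oracles and shared fixtures.  Every oracle here is a scalar
# loop (or an external toolkit) implemented without reference to the package
# internals it checks.

val <- dtakit:::ad_value

# relative deviation, guarded for small magnitudes
rel_dev <- function(a, b) {
  max(abs(a - b)) / max(1, max(abs(a)), max(abs(b)))
}

# Scalar-loop implementation of the full molecular encoder (initialization,
# L message-passing layers, readout), elementwise over features.
scalar_encoder <- function(graph, params) {
  relu <- function(x) pmax(x, 0)
  d <- params$hidden_dim
  agg <- function(h, idx) {
    if (length(idx) == 0L) return(numeric(d))
    out <- numeric(d)
    for (j in seq_len(d)) {
      m <- -Inf; s <- 0
      for (e in idx) { m <- max(m, h[e, j]); s <- s + h[e, j] }
      out[j] <- m * s
    }
    out
  }
  wa <- val(params$init_atom_w); ba <- val(params$init_atom_b)
  hv <- matrix(0, graph$n_atoms, d)
  for (v in seq_len(graph$n_atoms)) {
    hv[v, ] <- relu(as.numeric(graph$atom_features[v, ] %*% wa) + ba[1, ])
  }
  he <- matrix(0, graph$n_bonds, d)
  if (graph$n_bonds > 0L) {
    wb <- val(params$init_bond_w); bb <- val(params$init_bond_b)
    for (e in seq_len(graph$n_bonds)) {
      he[e, ] <- relu(as.numeric(graph$bond_features[e, ] %*% wb) + bb[1, ])
    }
  }
  for (l in seq_len(params$depth)) {
    hev <- matrix(0, graph$n_atoms, d); hvv <- matrix(0, graph$n_atoms, d)
    for (v in seq_len(graph$n_atoms)) {
      hev[v, ] <- hv[v, ] * agg(he, graph$incident_bonds[[v]])
      hvv[v, ] <- hv[v, ] * agg(hv, graph$atom_neighbors[[v]])
    }
    hee <- matrix(0, graph$n_bonds, d)
    if (graph$n_bonds > 0L) {
      for (e in seq_len(graph$n_bonds)) {
        hee[e, ] <- he[e, ] * agg(he, graph$bond_neighbors[[e]])
      }
    }
    hv_new <- hev + hvv + hv
    if (graph$n_bonds > 0L) {
      w <- val(params$bond_update_w[[l]])
      he_new <- matrix(0, graph$n_bonds, d)
      for (e in seq_len(graph$n_bonds)) {
        he_new[e, ] <- relu(as.numeric(hee[e, ] %*% w) + he[e, ])
      }
      he <- he_new
    }
    hv <- hv_new
  }
  hev <- matrix(0, graph$n_atoms, d); hvv <- matrix(0, graph$n_atoms, d)
  for (v in seq_len(graph$n_atoms)) {
    hev[v, ] <- hv[v, ] * agg(he, graph$incident_bonds[[v]])
    hvv[v, ] <- hv[v, ] * agg(hv, graph$atom_neighbors[[v]])
  }
  wc <- val(params$communicate_w); bc <- val(params$communicate_b)
  em <- numeric(d)
  for (v in seq_len(graph$n_atoms)) {
    em <- em + relu(as.numeric(c(hv[v, ], hvv[v, ], hev[v, ]) %*% wc) + bc[1, ])
  }
  em
}

# Brute-force concordance index: explicit double loop over ordered pairs.
brute_ci <- function(pred, labels) {
  num <- 0; z <- 0
  n <- length(pred)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (labels[i] > labels[j]) {
      z <- z + 1
      d <- pred[i] - pred[j]
      num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
    }
  }
  num / z
}

# Scalar-loop 1-D convolution stack oracle matching cpc_encode_segments for
# ONE segment: same-padded convolutions, per-position layer norm, ReLU, then
# mean pooling.
scalar_cpc_segment <- function(token_ids, params) {
  emb <- val(params$token_emb)
  h <- emb[token_ids, , drop = FALSE]
  ls <- length(token_ids)
  half <- (params$kernel - 1L) %/% 2L
  for (ly in params$conv) {
    ws <- lapply(ly$w, val)
    b <- val(ly$b)
    out <- matrix(0, ls, ncol(ws[[1]]))
    for (pos in seq_len(ls)) {
      acc <- b[1, ]
      for (t in seq_len(params$kernel)) {
        src <- pos + (t - 1L - half)
        if (src >= 1L && src <= ls) {
          acc <- acc + as.numeric(h[src, ] %*% ws[[t]])
        }
      }
      mu <- mean(acc); sdv <- sqrt(mean((acc - mu)^2) + 1e-5)
      out[pos, ] <- pmax((acc - mu) / sdv, 0)
    }
    h <- out
  }
  colMeans(h)
}

# Step-by-step scalar GRU oracle.
scalar_gru <- function(z, params) {
  g <- params$gru
  sig <- function(x) 1 / (1 + exp(-x))
  d <- params$d_c
  h <- numeric(d)
  out <- matrix(0, nrow(z), d)
  for (t in seq_len(nrow(z))) {
    zt <- z[t, ]
    r <- sig(as.numeric(zt %*% val(g$wr)) + as.numeric(h %*% val(g$ur)) +
               val(g$br)[1, ])
    u <- sig(as.numeric(zt %*% val(g$wu)) + as.numeric(h %*% val(g$uu)) +
               val(g$bu)[1, ])
    nn <- tanh(as.numeric(zt %*% val(g$wn)) +
                 r * as.numeric(h %*% val(g$un)) + val(g$bn)[1, ])
    h <- (1 - u) * h + u * nn
    out[t, ] <- h
  }
  out
}

# Central finite-difference gradient of `fn()` (a closure re-running the
# forward pass) with respect to tensor `p`, compared against `p$grad`.
finite_diff_check <- function(fn, tensors, eps = 1e-5) {
  loss <- fn()
  dtakit:::ad_backward(loss)
  worst <- 0
  for (p in tensors) {
    g_auto <- if (is.null(p$grad)) array(0, dim(p$value)) else p$grad
    for (idx in seq_len(length(p$value))) {
      v0 <- p$value[idx]
      p$value[idx] <- v0 + eps
      lp <- val(fn())[1L]
      p$value[idx] <- v0 - eps
      lm <- val(fn())[1L]
      p$value[idx] <- v0
      g_num <- (lp - lm) / (2 * eps)
      denom <- max(1e-4, abs(g_auto[idx]), abs(g_num))
      worst <- max(worst, abs(g_auto[idx] - g_num) / denom)
    }
  }
  worst
}

# Randomly renumbered SMILES spellings of the same molecules, generated with
# the Python RDKit toolkit (independent of the R-side parser).  One batched
# call; molecules RDKit cannot parse fall back to their input spelling.
random_spellings <- function(smiles, n_per = 3L, seed = 1L) {
  fin <- tempfile(fileext = ".txt"); fout <- tempfile(fileext = ".json")
  writeLines(smiles, fin)
  code <- sprintf(paste0(
    "import json, random\n",
    "from rdkit import Chem\n",
    "random.seed(%d)\n",
    "out = []\n",
    "for line in open(%s):\n",
    "    s = line.strip()\n",
    "    m = Chem.MolFromSmiles(s)\n",
    "    if m is None:\n",
    "        out.append([s] * %d)\n",
    "    else:\n",
    "        out.append([Chem.MolToSmiles(m, doRandom=True, canonical=False)\n",
    "                    for _ in range(%d)])\n",
    "json.dump(out, open(%s, 'w'))\n"),
    seed, deparse(fin), n_per, n_per, deparse(fout))
  fpy <- tempfile(fileext = ".py")
  writeLines(code, fpy)
  res <- system2("python", fpy, stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout)) {
    stop("python/rdkit spelling generation failed: ",
         paste(res, collapse = "\n"))
  }
  jsonlite::fromJSON(fout, simplifyVector = FALSE)
}

# shared small-molecule fixture set
fixture_smiles <- c("C", "CC", "CCO", "C1CC1", "c1ccccc1", "CC(=O)N",
                    "C1CCOC1", "C=CC#N", "c1ccncc1", "CC(C)O")
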