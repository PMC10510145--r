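# Reverse-mode automatic differentiation on dense matrices.
#
# Every tensor is an environment holding a numeric matrix plus the tape
# bookkeeping needed for backpropagation (parents and a backward closure that
# scatters the incoming gradient onto them).  The graph is rebuilt on every
# forward pass; leaf tensors (parameters) persist across passes.  All
# operations treat vectors as 1 x d or d x 1 matrices -- there is no implicit
# recycling beyond the explicitly provided bias/row-broadcast ops.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_next_id <- function() {
  .ad$counter <- .ad$counter + 1L
  .ad$counter
}

#' @noRd
ad_tensor <- function(value, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- as.matrix(value)
  storage.mode(e$value) <- "double"
  e$grad <- NULL
  e$parents <- list()
  e$backward <- NULL
  e$requires_grad <- isTRUE(requires_grad)
  e$id <- ad_next_id()
  class(e) <- "ad_tensor"
  e
}

is_ad <- function(x) inherits(x, "ad_tensor")

# Promote plain matrices to constant tensors so ops can mix both freely.
as_ad <- function(x) if (is_ad(x)) x else ad_tensor(x)

ad_value <- function(x) if (is_ad(x)) x$value else as.matrix(x)

ad_node <- function(value, parents, backward) {
  e <- ad_tensor(value)
  e$parents <- parents
  e$requires_grad <- any(vapply(parents, function(p) p$requires_grad, logical(1)))
  if (e$requires_grad) e$backward <- backward
  e
}

ad_accum <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar (or any) root.  `seed` defaults to ones.
ad_backward <- function(root, seed = NULL) {
  if (is.null(seed)) seed <- array(1, dim(root$value))
  # iterative DFS topological sort keyed on node ids
  topo <- vector("list", 256L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  assign(as.character(root$id), TRUE, envir = visited)
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    node <- top$node
    i <- top$i + 1L
    if (i <= length(node$parents)) {
      stack[[length(stack)]]$i <- i
      p <- node$parents[[i]]
      key <- as.character(p$id)
      if (p$requires_grad && !exists(key, envir = visited, inherits = FALSE)) {
        assign(key, TRUE, envir = visited)
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      stack[[length(stack)]] <- NULL
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- node
    }
  }
  root$grad <- seed
  for (k in seq_len(n_topo)) {
    node <- topo[[n_topo - k + 1L]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node$grad)
  }
  invisible(root)
}

ad_zero_grad <- function(params) {
  for (p in ad_flatten_params(params)) p$grad <- NULL
  invisible(NULL)
}

# Flatten an arbitrarily nested list of tensors into a flat list.
ad_flatten_params <- function(x) {
  if (is_ad(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, ad_flatten_params)))
  list()
}

## ---- elementwise and linear-algebra operations ----

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    ad_accum(a, g %*% t(b$value))
    ad_accum(b, t(a$value) %*% g)
  })
}

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  })
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value * b$value, list(a, b), function(g) {
    ad_accum(a, g * b$value)
    ad_accum(b, g * a$value)
  })
}

ad_scale <- function(a, s) {
  a <- as_ad(a)
  ad_node(a$value * s, list(a), function(g) ad_accum(a, g * s))
}

# Add a 1 x d bias row to every row of an n x d matrix.
ad_add_bias <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  stopifnot(ncol(a$value) == ncol(b$value), nrow(b$value) == 1L)
  ad_node(sweep(a$value, 2L, b$value[1L, ], "+"), list(a, b), function(g) {
    ad_accum(a, g)
    ad_accum(b, matrix(colSums(g), 1L))
  })
}

# Multiply every row of an n x d matrix by a 1 x d gain row.
ad_mul_rowvec <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  stopifnot(ncol(a$value) == ncol(b$value), nrow(b$value) == 1L)
  ad_node(sweep(a$value, 2L, b$value[1L, ], "*"), list(a, b), function(g) {
    ad_accum(a, sweep(g, 2L, b$value[1L, ], "*"))
    ad_accum(b, matrix(colSums(g * a$value), 1L))
  })
}

ad_relu <- function(a) {
  a <- as_ad(a)
  mask <- a$value > 0
  ad_node(a$value * mask, list(a), function(g) ad_accum(a, g * mask))
}

ad_tanh <- function(a) {
  a <- as_ad(a)
  y <- tanh(a$value)
  ad_node(y, list(a), function(g) ad_accum(a, g * (1 - y^2)))
}

ad_sigmoid <- function(a) {
  a <- as_ad(a)
  y <- 1 / (1 + exp(-a$value))
  ad_node(y, list(a), function(g) ad_accum(a, g * y * (1 - y)))
}

ad_sum <- function(a) {
  a <- as_ad(a)
  ad_node(matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    ad_accum(a, array(g[1L], dim(a$value)))
  })
}

ad_mean <- function(a) {
  a <- as_ad(a)
  n <- length(a$value)
  ad_node(matrix(mean(a$value), 1L, 1L), list(a), function(g) {
    ad_accum(a, array(g[1L] / n, dim(a$value)))
  })
}

# Column means over rows: n x d -> 1 x d.
ad_colmeans <- function(a) {
  a <- as_ad(a)
  n <- nrow(a$value)
  ad_node(matrix(colMeans(a$value), 1L), list(a), function(g) {
    ad_accum(a, matrix(g[1L, ], n, ncol(a$value), byrow = TRUE) / n)
  })
}

ad_colsums <- function(a) {
  a <- as_ad(a)
  n <- nrow(a$value)
  ad_node(matrix(colSums(a$value), 1L), list(a), function(g) {
    ad_accum(a, matrix(g[1L, ], n, ncol(a$value), byrow = TRUE))
  })
}

ad_t <- function(a) {
  a <- as_ad(a)
  ad_node(t(a$value), list(a), function(g) ad_accum(a, t(g)))
}

ad_rbind <- function(xs) {
  xs <- lapply(xs, as_ad)
  rows <- vapply(xs, function(x) nrow(x$value), integer(1))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  ad_node(do.call(rbind, lapply(xs, ad_value)), xs, function(g) {
    for (k in seq_along(xs)) {
      if (rows[k] > 0L) ad_accum(xs[[k]], g[starts[k]:ends[k], , drop = FALSE])
    }
  })
}

ad_cbind <- function(xs) {
  xs <- lapply(xs, as_ad)
  cols <- vapply(xs, function(x) ncol(x$value), integer(1))
  ends <- cumsum(cols)
  starts <- ends - cols + 1L
  ad_node(do.call(cbind, lapply(xs, ad_value)), xs, function(g) {
    for (k in seq_along(xs)) {
      if (cols[k] > 0L) ad_accum(xs[[k]], g[, starts[k]:ends[k], drop = FALSE])
    }
  })
}

# Row gather: out[k, ] = a[idx[k], ].  Duplicate indices accumulate on the
# way back (rowsum groups them).
ad_rows <- function(a, idx) {
  a <- as_ad(a)
  idx <- as.integer(idx)
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    acc <- rowsum(g, group = idx)
    da[as.integer(rownames(acc)), ] <- acc
    ad_accum(a, da)
  })
}

# Pick one entry per row: out[k, 1] = a[k, idx[k]].
ad_pick <- function(a, idx) {
  a <- as_ad(a)
  idx <- as.integer(idx)
  sel <- cbind(seq_along(idx), idx)
  ad_node(matrix(a$value[sel], ncol = 1L), list(a), function(g) {
    da <- matrix(0, nrow(a$value), ncol(a$value))
    da[sel] <- g[, 1L]
    ad_accum(a, da)
  })
}

ad_log <- function(a) {
  a <- as_ad(a)
  ad_node(log(a$value), list(a), function(g) ad_accum(a, g / a$value))
}

# Numerically stable per-row log-softmax.
ad_log_softmax_rows <- function(a) {
  a <- as_ad(a)
  m <- apply(a$value, 1L, max)
  z <- a$value - m
  lse <- log(rowSums(exp(z)))
  y <- z - lse
  p <- exp(y)
  ad_node(y, list(a), function(g) {
    ad_accum(a, g - p * rowSums(g))
  })
}

ad_softmax_rows <- function(a) {
  a <- as_ad(a)
  m <- apply(a$value, 1L, max)
  p <- exp(a$value - m)
  p <- p / rowSums(p)
  ad_node(p, list(a), function(g) {
    ad_accum(a, p * (g - rowSums(g * p)))
  })
}

# Per-row layer normalization (no gain/bias; compose with ad_mul_rowvec /
# ad_add_bias when an affine transform is wanted).
ad_layernorm_rows <- function(a, eps = 1e-5) {
  a <- as_ad(a)
  d <- ncol(a$value)
  mu <- rowMeans(a$value)
  xc <- a$value - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  ad_node(y, list(a), function(g) {
    gi <- g * inv
    ad_accum(a, gi - rowMeans(g * inv) - y * rowMeans(g * y * inv))
  })
}

# Dropout with inverted scaling; identity when not training.
ad_dropout <- function(a, rate, training) {
  a <- as_ad(a)
  if (!training || rate <= 0) return(a)
  keep <- (array(stats::runif(length(a$value)), dim(a$value)) >= rate) / (1 - rate)
  ad_node(a$value * keep, list(a), function(g) ad_accum(a, g * keep))
}

# Neighborhood max (.) sum aggregation: out[v, ] is the elementwise product of
# the per-column maximum and the per-column sum of the rows of `h` indexed by
# nbrs[[v]]; an empty neighborhood yields the zero row.  This is the shared
# aggregation of the three message-passing functions of the molecular encoder.
ad_neighbor_maxsum <- function(h, nbrs) {
  h <- as_ad(h)
  n <- length(nbrs)
  d <- ncol(h$value)
  out <- matrix(0, n, d)
  argmx <- matrix(NA_integer_, n, d)
  sums <- matrix(0, n, d)
  maxs <- matrix(0, n, d)
  for (v in seq_len(n)) {
    ii <- nbrs[[v]]
    if (length(ii) == 0L) next
    block <- h$value[ii, , drop = FALSE]
    wm <- max.col(t(block), ties.method = "first")  # per-column argmax
    mx <- block[cbind(wm, seq_len(d))]
    sm <- colSums(block)
    out[v, ] <- mx * sm
    argmx[v, ] <- ii[wm]
    sums[v, ] <- sm
    maxs[v, ] <- mx
  }
  ad_node(out, list(h), function(g) {
    dh <- matrix(0, nrow(h$value), d)
    for (v in seq_len(n)) {
      ii <- nbrs[[v]]
      if (length(ii) == 0L) next
      # d(out)/d h[e, j] = [e == argmax] * sum_j  +  max_j  (product rule)
      gv <- g[v, ]
      dh[ii, ] <- dh[ii, ] + matrix(gv * maxs[v, ], length(ii), d, byrow = TRUE)
      sel <- cbind(argmx[v, ], seq_len(d))
      dh[sel] <- dh[sel] + gv * sums[v, ]
    }
    ad_accum(h, dh)
  })
}

## ---- parameter initialisation and the Adam optimizer ----

# Glorot-uniform initial weights; biases start at zero.
ad_param <- function(nrow, ncol, gain = 1) {
  lim <- gain * sqrt(6 / (nrow + ncol))
  ad_tensor(matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol),
            requires_grad = TRUE)
}

ad_param_zero <- function(nrow, ncol) {
  ad_tensor(matrix(0, nrow, ncol), requires_grad = TRUE)
}

adam_state <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  flat <- ad_flatten_params(params)
  list(
    params = flat,
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(flat, function(p) array(0, dim(p$value))),
    v = lapply(flat, function(p) array(0, dim(p$value)))
  )
}

adam_step <- function(st) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (k in seq_along(st$params)) {
    p <- st$params[[k]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g^2
    p$value <- p$value -
      st$lr * (st$m[[k]] / corr1) / (sqrt(st$v[[k]] / corr2) + st$eps)
  }
  st
}

# Deep-copy parameter values (plain matrices) out of / into tensor trees;
# used for checkpointing and best-epoch snapshots.
ad_export_values <- function(x) {
  if (is_ad(x)) return(x$value)
  if (is.list(x)) return(lapply(x, ad_export_values))
  x
}

ad_import_values <- function(params, values) {
  if (is_ad(params)) {
    stopifnot(all(dim(params$value) == dim(as.matrix(values))))
    params$value <- as.matrix(values)
    return(invisible(params))
  }
  if (!is.list(params)) return(invisible(params))   # scalar metadata
  stopifnot(length(params) == length(values))
  for (k in seq_along(params)) ad_import_values(params[[k]], values[[k]])
  invisible(params)
}
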