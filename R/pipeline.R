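# Dataset IO, deterministic splits, pretraining and DTA training loops,
# checkpointing and prediction.

CHECKPOINT_VERSION <- 1L

#' Model configuration
#'
#' Collects every hyperparameter of the full model.  The defaults follow the
#' published working points where one exists (three message-passing layers,
#' segment length 11, 15 percent masking); everything else is an open knob
#' with a documented default.
#'
#' @param hidden_dim Hidden width of the molecular encoder.
#' @param depth Message-passing depth L.
#' @param dropout_rate Dropout on the bond update.
#' @param l_segment Protein segment length.
#' @param l_total Padded protein length; a multiple of `l_segment`.
#' @param mask_rate MLM corruption rate.
#' @param mlm_size `"base"` or `"large"`.
#' @param mlm_d_model,mlm_layers,mlm_heads,mlm_d_ff Optional MLM overrides.
#' @param cpc_d_emb,cpc_channels CPC encoder sizes.
#' @param cpc_steps Contrastive prediction steps K.
#' @param d_att Attention width.
#' @param mlp_hidden MLP head hidden widths.
#' @param l2_coeff L2 coefficient of the training objective.
#' @param learning_rate,batch_size,epochs Optimization knobs.
#' @param pretrain_steps,pretrain_batch Pretraining knobs.
#' @param min_len,max_len Pretraining corpus length filter (inclusive).
#' @param seed Integer seed.
#' @return A `dta_config` list.
#' @export
dta_config <- function(hidden_dim = 128L, depth = 3L, dropout_rate = 0.1,
                       l_segment = 11L, l_total = 990L, mask_rate = 0.15,
                       mlm_size = "base", mlm_d_model = NULL,
                       mlm_layers = NULL, mlm_heads = NULL, mlm_d_ff = NULL,
                       cpc_d_emb = 16L, cpc_channels = c(32L, 32L),
                       cpc_steps = 1L, d_att = 64L,
                       mlp_hidden = c(256L, 64L), l2_coeff = 1e-4,
                       learning_rate = 1e-3, batch_size = 32L, epochs = 30L,
                       pretrain_steps = 200L, pretrain_batch = 8L,
                       min_len = 70L, max_len = 1000L, seed = 1L) {
  if (l_total %% l_segment != 0L) {
    rlang::abort("`l_total` must be a multiple of `l_segment`",
                 class = "dtakit_error_config")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "dta_config")
}

#' Small configuration for examples and tests
#'
#' The same model at toy sizes: everything runs in seconds on one CPU while
#' exercising every component.
#'
#' @param ... Overrides passed on to [dta_config()].
#' @export
toy_config <- function(...) {
  defaults <- list(hidden_dim = 8L, depth = 2L, dropout_rate = 0.1,
                   l_segment = 11L, l_total = 66L, mlm_d_model = 16L,
                   mlm_layers = 1L, mlm_heads = 2L, mlm_d_ff = 32L,
                   cpc_d_emb = 16L, cpc_channels = c(16L, 16L), d_att = 16L,
                   mlp_hidden = c(32L, 16L), learning_rate = 3e-3,
                   batch_size = 16L, epochs = 8L, pretrain_batch = 6L,
                   min_len = 10L, max_len = 66L)
  args <- utils::modifyList(defaults, list(...))
  do.call(dta_config, args)
}

#' Read a DTA dataset from delimited text
#'
#' Expects a header with (at least) the three dataset columns.  Malformed
#' rows -- empty SMILES or sequence, missing or non-numeric affinity -- are
#' dropped with a warning naming their line numbers.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @param columns Names of the SMILES, sequence and affinity columns.
#' @return A tibble of validated rows with attribute `provenance`.
#' @export
read_dta <- function(path, delim = ",",
                     columns = c("smiles", "sequence", "affinity")) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  missing <- setdiff(columns, names(raw))
  if (length(missing) > 0L) {
    rlang::abort(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 class = "dtakit_error_schema")
  }
  out <- tibble::tibble(
    smiles = raw[[columns[1]]],
    sequence = raw[[columns[2]]],
    affinity = suppressWarnings(as.numeric(raw[[columns[3]]]))
  )
  bad <- is.na(out$smiles) | !nzchar(out$smiles) |
    is.na(out$sequence) | !nzchar(out$sequence) |
    !is.finite(out$affinity)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    lines <- which(bad) + 1L   # header is line 1
    rlang::warn(paste0("dropped ", sum(bad), " malformed row(s) at line(s): ",
                       paste(lines, collapse = ", ")),
                class = "dtakit_warning_rows")
    out <- out[!bad, , drop = FALSE]
  }
  attr(out, "provenance") <- path
  out
}

#' Write a DTA dataset as delimited text
#'
#' @param data Tibble with `smiles`, `sequence`, `affinity`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_dta <- function(data, path, delim = ",") {
  readr::write_delim(data[, c("smiles", "sequence", "affinity")], path,
                     delim = delim)
  invisible(path)
}

#' Deterministic train/validation/test split
#'
#' Shuffles `1:n` by the seed and partitions by the ratio.  The training
#' share is `round(ratio[1] * n)`; the remainder is split evenly between
#' validation and test, with an odd leftover sample going to training.
#'
#' @param n Number of rows.
#' @param ratio Length-3 ratio summing to 1 (default 8:1:1).
#' @param seed Integer seed.
#' @return A `split_indices` list with `train`, `valid`, `test`.
#' @examples
#' lengths(make_split(100, seed = 7))  # 80, 10, 10
#' @export
make_split <- function(n, ratio = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratio) != 3L || abs(sum(ratio) - 1) > 1e-8) {
    rlang::abort("`ratio` must be three fractions summing to 1",
                 class = "dtakit_error_config")
  }
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(ratio[1] * n)
  m <- n - n_train
  n_valid <- floor(m * ratio[2] / (ratio[2] + ratio[3]))
  n_test <- floor(m * ratio[3] / (ratio[2] + ratio[3]))
  n_train <- n - n_valid - n_test   # leftover goes to train
  structure(list(train = sort(perm[seq_len(n_train)]),
                 valid = sort(perm[n_train + seq_len(n_valid)]),
                 test = sort(perm[n_train + n_valid + seq_len(n_test)]),
                 ratio = ratio, seed = seed),
            class = "split_indices")
}

#' Assemble explicit split indices
#'
#' For protocols with fixed row assignments (an overfit run with no held-out
#' rows, or a train-first/test-last layout).  Indices must be disjoint.
#'
#' @param train,valid,test Integer row indices; `valid`/`test` may be empty.
#' @return A `split_indices` object.
#' @export
split_indices <- function(train, valid = integer(0), test = integer(0)) {
  if (anyDuplicated(c(train, valid, test)) > 0L) {
    rlang::abort("split indices must be disjoint",
                 class = "dtakit_error_config")
  }
  structure(list(train = as.integer(train), valid = as.integer(valid),
                 test = as.integer(test), ratio = NULL, seed = NULL),
            class = "split_indices")
}

# parameter bundles for the protein branches from a config
protein_params_from_config <- function(config) {
  list(
    mlm = mlm_params(size = config$mlm_size, d_model = config$mlm_d_model,
                     n_layers = config$mlm_layers, n_heads = config$mlm_heads,
                     d_ff = config$mlm_d_ff, max_len = config$l_total),
    cpc = cpc_params(d_emb = config$cpc_d_emb, channels = config$cpc_channels,
                     prediction_steps = config$cpc_steps)
  )
}

#' Initialize the full DTA model
#'
#' @param config A [dta_config()].
#' @param seed Seed for the weight initialization.
#' @return A `dta_params` list with `mol`, `mlm`, `cpc`, `fusion`.
#' @export
init_dta_model <- function(config, seed = config$seed) {
  withr::with_seed(seed, {
    prot <- protein_params_from_config(config)
    d_c <- config$cpc_channels[length(config$cpc_channels)]
    d_prot <- d_c + prot$mlm$d_model
    p <- list(
      mol = mol_encoder_params(hidden_dim = config$hidden_dim,
                               depth = config$depth,
                               dropout_rate = config$dropout_rate),
      mlm = prot$mlm,
      cpc = prot$cpc,
      fusion = fusion_params(d_mol = config$hidden_dim, d_prot = d_prot,
                             d_att = config$d_att,
                             mlp_hidden = config$mlp_hidden,
                             l2_coeff = config$l2_coeff)
    )
    class(p) <- "dta_params"
    p
  })
}

## ---- checkpointing ----

#' Save a checkpoint
#'
#' A single archive holding the weights (plain matrices), the full
#' configuration and a format version.
#'
#' @param object A `protein_pretrain` or `dta_model` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(object, path) {
  kind <- if (inherits(object, "protein_pretrain")) "pretrain"
  else if (inherits(object, "dta_model")) "dta"
  else rlang::abort("not a checkpointable object",
                    class = "dtakit_error_input")
  payload <- list(
    format_version = CHECKPOINT_VERSION,
    kind = kind,
    config = object$config,
    values = ad_export_values(object$params),
    history = object$history
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path Checkpoint path.
#' @return The restored `protein_pretrain` or `dta_model` object.
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format_version, CHECKPOINT_VERSION)) {
    rlang::abort("unsupported checkpoint format version",
                 class = "dtakit_error_load")
  }
  config <- payload$config
  if (payload$kind == "pretrain") {
    params <- withr::with_seed(0L, protein_params_from_config(config))
    ad_import_values(params, payload$values)
    structure(list(params = params, config = config,
                   history = payload$history),
              class = "protein_pretrain")
  } else {
    params <- init_dta_model(config, seed = 0L)
    ad_import_values(params, payload$values)
    structure(list(params = params, config = config,
                   history = payload$history),
              class = "dta_model")
  }
}

## ---- protein pretraining ----

#' Pretrain the protein encoder branches
#'
#' Filters the corpus by length, discards sequences longer than the padded
#' total, and optimizes the masked-language-model and contrastive objectives
#' -- in alternating batches by default, or as a joint weighted sum.  Both
#' losses and the contrastive accuracy are logged per step.
#'
#' @param corpus FASTA path or character vector of sequences.
#' @param config A [dta_config()].
#' @param steps Number of optimization steps (default from config).
#' @param mode `"alternating"` or `"joint"`.
#' @param seed Seed for masking, batching and initialization.
#' @param verbose Print a log line every 25 steps.
#' @return A `protein_pretrain` object (params, config, history tibble).
#' @export
pretrain_protein <- function(corpus, config = dta_config(),
                             steps = config$pretrain_steps,
                             mode = c("alternating", "joint"),
                             seed = config$seed, verbose = FALSE) {
  mode <- match.arg(mode)
  seqs <- if (is.character(corpus) && length(corpus) == 1L &&
              file.exists(corpus)) read_fasta_corpus(corpus) else corpus
  seqs <- length_filter(seqs, config$min_len, config$max_len)
  seqs <- seqs[nchar(seqs) <= config$l_total]
  if (length(seqs) == 0L) {
    rlang::abort("no sequences left after length filtering",
                 class = "dtakit_error_data")
  }
  segs <- lapply(seqs, segment_protein, l_segment = config$l_segment,
                 l_total = config$l_total)
  withr::with_seed(seed, {
    params <- protein_params_from_config(config)
    opt <- adam_state(params, lr = config$learning_rate)
    b <- min(config$pretrain_batch, length(segs))
    log <- vector("list", steps)
    for (step in seq_len(steps)) {
      idx <- sample.int(length(segs), b)
      do_mlm <- mode == "joint" || step %% 2L == 1L
      do_cpc <- mode == "joint" || step %% 2L == 0L
      ad_zero_grad(params)
      mlm_l <- NA_real_; cpc_l <- NA_real_; cpc_a <- NA_real_
      total <- NULL
      if (do_mlm) {
        terms <- lapply(idx, function(i) {
          ids <- segs[[i]]$token_ids
          msk <- mask_for_mlm(ids, config$mask_rate)
          fwd <- mlm_forward(msk$corrupted, params$mlm)
          mlm_loss(fwd$scores, msk$positions, ids)
        })
        l <- ad_scale(Reduce(ad_add, terms), 1 / length(terms))
        mlm_l <- ad_value(l)[1L]
        total <- if (is.null(total)) l else ad_add(total, l)
      }
      if (do_cpc) {
        zs <- lapply(idx, function(i) cpc_encode_segments(segs[[i]],
                                                          params$cpc))
        accs <- numeric(0)
        terms <- list()
        for (j in seq_along(idx)) {
          others <- setdiff(seq_along(idx), j)
          if (length(others) == 0L) break
          neg_rows <- ad_rbind(lapply(others, function(o) {
            ad_rows(zs[[o]], sample.int(nrow(zs[[o]]$value), 1L))
          }))
          cs <- cpc_autoregress(zs[[j]], params$cpc)
          nce <- infonce_loss(cs, zs[[j]], neg_rows, params$cpc)
          terms[[length(terms) + 1L]] <- nce$loss
          accs <- c(accs, nce$accuracy)
        }
        if (length(terms) > 0L) {
          l <- ad_scale(Reduce(ad_add, terms), 1 / length(terms))
          cpc_l <- ad_value(l)[1L]
          cpc_a <- mean(accs)
          total <- if (is.null(total)) l else ad_add(total, l)
        }
      }
      if (!is.null(total)) {
        if (!is.finite(ad_value(total)[1L])) {
          rlang::abort("pretraining loss diverged (non-finite)",
                       class = "dtakit_error_numeric")
        }
        ad_backward(total)
        opt <- adam_step(opt)
      }
      log[[step]] <- tibble::tibble(step = step, mlm_loss = mlm_l,
                                    cpc_loss = cpc_l, cpc_accuracy = cpc_a)
      if (verbose && step %% 25L == 0L) {
        message(sprintf("pretrain step %d: mlm=%.4f cpc=%.4f acc=%.3f",
                        step, mlm_l, cpc_l, cpc_a))
      }
    }
    structure(list(params = params, config = config,
                   history = dplyr::bind_rows(log)),
              class = "protein_pretrain")
  })
}

## ---- DTA training ----

# Forward pass for one (graph, protein-entry) pair.  `prot` is either a
# plain matrix (frozen, precomputed) or a token-id vector encoded on the fly.
forward_pair <- function(params, graph, prot, config, training = FALSE) {
  e_m <- encode_molecule_ad(graph, params$mol, training)
  e_p <- if (is.matrix(prot)) ad_tensor(prot) else {
    protein_embedding(prot, params$mlm, params$cpc,
                      l_segment = config$l_segment,
                      l_total = config$l_total)$e_p
  }
  score <- attention_score(e_m, e_p, params$fusion)
  att <- reweight_protein(score, e_p, params$fusion)
  predict_affinity(e_m, att, params$fusion)
}

# Precompute per-row molecule graphs and protein entries (shared across
# duplicate SMILES/sequences).
prepare_rows <- function(data, params, config, freeze_protein) {
  graphs_u <- lapply(unique(data$smiles), smiles_to_graph)
  names(graphs_u) <- unique(data$smiles)
  useq <- unique(data$sequence)
  prot_u <- if (freeze_protein) {
    lapply(useq, function(s) {
      ad_value(protein_embedding(s, params$mlm, params$cpc,
                                 l_segment = config$l_segment,
                                 l_total = config$l_total)$e_p)
    })
  } else {
    lapply(useq, function(s) {
      ids <- tokenize_protein(s)
      if (length(ids) > config$l_total) ids <- ids[seq_len(config$l_total)]
      ids
    })
  }
  names(prot_u) <- useq
  list(graphs = graphs_u[data$smiles], prots = prot_u[data$sequence])
}

# Batched forward: one combined-graph pass for the molecules, one shared
# projection for the stacked protein embeddings, per-sample attention, and a
# single MLP pass over the fused rows.  Equals forward_pair row by row.
forward_batch <- function(params, graphs, prots, config, training = FALSE) {
  b <- length(graphs)
  e_mol <- encode_molecules_batch_ad(graphs, params$mol, training)
  # encode each unique sequence once per batch when the branch is live
  p_list <- vector("list", b)
  enc_cache <- list()
  for (i in seq_len(b)) {
    pr <- prots[[i]]
    if (is.matrix(pr)) {
      p_list[[i]] <- ad_tensor(pr)
    } else {
      key <- paste(pr, collapse = ",")
      if (is.null(enc_cache[[key]])) {
        enc_cache[[key]] <- protein_embedding(
          pr, params$mlm, params$cpc,
          l_segment = config$l_segment, l_total = config$l_total)$e_p
      }
      p_list[[i]] <- enc_cache[[key]]
    }
  }
  x <- nrow(p_list[[1L]]$value)
  p_all <- ad_relu(ad_matmul(ad_rbind(p_list), params$fusion$w_p))
  m_all <- ad_relu(ad_matmul(e_mol, params$fusion$w_m))
  att_rows <- vector("list", b)
  for (i in seq_len(b)) {
    m_i <- ad_rows(m_all, i)
    p_i <- ad_rows(p_all, (i - 1L) * x + seq_len(x))
    sc <- ad_tanh(ad_matmul(m_i, ad_t(p_i)))
    att_rows[[i]] <- ad_matmul(ad_matmul(sc, p_i), params$fusion$w_s)
  }
  h <- ad_cbind(list(e_mol, ad_rbind(att_rows)))
  mlp <- params$fusion$mlp
  for (j in seq_along(mlp)) {
    h <- ad_add_bias(ad_matmul(h, mlp[[j]]$w), mlp[[j]]$b)
    if (j < length(mlp)) h <- ad_relu(h)
  }
  h
}

predict_rows <- function(params, rows, config, idx = seq_along(rows$graphs)) {
  if (length(idx) == 0L) return(numeric(0))
  out <- forward_batch(params, rows$graphs[idx], rows$prots[idx], config,
                       training = FALSE)
  ad_value(out)[, 1L]
}

#' Train the DTA model
#'
#' Minimizes the regularized mean-squared-error objective by mini-batch Adam,
#' tracks validation MSE each epoch, restores the best-epoch weights at the
#' end and reports test metrics.
#'
#' @param data Tibble with `smiles`, `sequence`, `affinity`.
#' @param config A [dta_config()].
#' @param split A [make_split()] result (default: 8:1:1 at the config seed).
#' @param pretrained Optional `protein_pretrain` object or checkpoint path;
#'   initializes the protein branches.
#' @param freeze_protein Freeze the protein branches (their embeddings are
#'   then precomputed once).
#' @param seed Training seed.
#' @param verbose Print one line per epoch.
#' @return A `dta_model` object with `params`, `config`, `history`,
#'   `best_epoch`, `metrics` (test MSE and CI) and `split`.
#' @export
train_dta <- function(data, config = dta_config(), split = NULL,
                      pretrained = NULL, freeze_protein = FALSE,
                      seed = config$seed, verbose = FALSE) {
  if (is.null(split)) split <- make_split(nrow(data), seed = seed)
  if (is.character(pretrained)) pretrained <- load_checkpoint(pretrained)
  withr::with_seed(seed, {
    params <- init_dta_model(config, seed = seed + 1L)
    if (!is.null(pretrained)) {
      ad_import_values(params$mlm, ad_export_values(pretrained$params$mlm))
      ad_import_values(params$cpc, ad_export_values(pretrained$params$cpc))
    }
    theta <- if (freeze_protein) params[c("mol", "fusion")] else params
    rows <- prepare_rows(data, params, config, freeze_protein)
    y <- data$affinity
    opt <- adam_state(theta, lr = config$learning_rate)
    best <- list(mse = Inf, epoch = 0L, values = NULL)
    log <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(split$train)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (bt in batches) {
        ad_zero_grad(theta)
        preds <- forward_batch(params, rows$graphs[bt], rows$prots[bt],
                               config, training = TRUE)
        loss <- training_loss(preds, y[bt], params$fusion, theta)
        lv <- ad_value(loss)[1L]
        if (!is.finite(lv)) {
          rlang::abort(sprintf("training diverged at epoch %d (loss %g)",
                               epoch, lv), class = "dtakit_error_numeric")
        }
        ad_backward(loss)
        opt <- adam_step(opt)
        epoch_loss <- epoch_loss + lv * length(bt)
      }
      epoch_loss <- epoch_loss / length(ord)
      if (length(split$valid) > 0L) {
        val_pred <- predict_rows(params, rows, config, split$valid)
        val_mse <- mse(val_pred, y[split$valid])
        val_ci <- tryCatch(concordance_index(val_pred, y[split$valid]),
                           error = function(e) NA_real_)
      } else {
        # no validation rows: track the training loss instead
        val_mse <- epoch_loss
        val_ci <- NA_real_
      }
      if (val_mse < best$mse) {
        best <- list(mse = val_mse, epoch = epoch,
                     values = ad_export_values(params))
      }
      log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = epoch_loss,
                                     valid_mse = val_mse, valid_ci = val_ci)
      if (verbose) {
        message(sprintf("epoch %d: train=%.4f valid_mse=%.4f valid_ci=%s",
                        epoch, epoch_loss, val_mse, format(val_ci)))
      }
    }
    if (!is.null(best$values)) ad_import_values(params, best$values)
    metrics <- if (length(split$test) > 0L) {
      test_pred <- predict_rows(params, rows, config, split$test)
      list(mse = mse(test_pred, y[split$test]),
           ci = tryCatch(concordance_index(test_pred, y[split$test]),
                         error = function(e) NA_real_))
    } else list(mse = NA_real_, ci = NA_real_)
    structure(list(params = params, config = config,
                   history = dplyr::bind_rows(log),
                   best_epoch = best$epoch, metrics = metrics,
                   split = split, freeze_protein = freeze_protein),
              class = "dta_model")
  })
}

#' Evaluate a trained model on a dataset
#'
#' Deterministic (dropout off).  The concordance index requires at least one
#' strictly ordered label pair and raises the undefined-CI error otherwise.
#'
#' @param model A `dta_model`.
#' @param data Tibble with `smiles`, `sequence`, `affinity`.
#' @param metrics Which metrics to compute.
#' @return Named list of the requested metrics plus `predictions`.
#' @export
evaluate_dta <- function(model, data, metrics = c("mse", "ci")) {
  rows <- prepare_rows(data, model$params, model$config,
                       freeze_protein = TRUE)
  pred <- predict_rows(model$params, rows, model$config)
  out <- list(predictions = pred)
  if ("mse" %in% metrics) out$mse <- mse(pred, data$affinity)
  if ("ci" %in% metrics) out$ci <- concordance_index(pred, data$affinity)
  out
}

#' Rank candidate molecules against one protein
#'
#' Predicts the affinity of every parseable SMILES against the sequence and
#' returns them in descending predicted order (ties keep input order).
#' Unparseable SMILES are collected in the `rejects` attribute; the run
#' continues past them.
#'
#' @param model A `dta_model`.
#' @param smiles Character vector of candidate SMILES.
#' @param sequence One protein sequence.
#' @return Tibble with `smiles`, `predicted_affinity`, `rank`, ordered by
#'   rank, with attribute `rejects`.
#' @export
predict_dta <- function(model, smiles, sequence) {
  stopifnot(length(sequence) == 1L)
  parsed <- lapply(smiles, function(s) {
    tryCatch(smiles_to_graph(s), error = function(e) NULL)
  })
  ok <- !vapply(parsed, is.null, logical(1))
  e_p <- ad_value(protein_embedding(sequence, model$params$mlm,
                                    model$params$cpc,
                                    l_segment = model$config$l_segment,
                                    l_total = model$config$l_total)$e_p)
  keep <- which(ok)
  pred <- if (length(keep) > 0L) {
    ad_value(forward_batch(model$params, parsed[keep],
                           rep(list(e_p), length(keep)), model$config,
                           training = FALSE))[, 1L]
  } else numeric(0)
  ord <- order(-pred, keep)
  out <- tibble::tibble(
    smiles = smiles[keep][ord],
    predicted_affinity = pred[ord],
    rank = seq_along(ord)
  )
  attr(out, "rejects") <- smiles[!ok]
  out
}

#' @export
print.dta_model <- function(x, ...) {
  cat("<dta_model> depth", x$config$depth, "hidden", x$config$hidden_dim,
      "| best epoch", x$best_epoch, "\n")
  if (!is.null(x$metrics)) {
    cat("  test MSE:", format(x$metrics$mse, digits = 4),
        " test CI:", format(x$metrics$ci, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
print.protein_pretrain <- function(x, ...) {
  n <- nrow(x$history)
  cat("<protein_pretrain>", n, "steps\n")
  invisible(x)
}
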