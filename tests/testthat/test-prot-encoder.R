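# Protein encoder: segmentation arithmetic, masking, both branches against
# scalar oracles, causality and the combined embedding.

tiny_mlm <- function(d = 8, max_len = 66) {
  mlm_params(d_model = d, n_layers = 1, n_heads = 2, d_ff = 16,
             max_len = max_len)
}
tiny_cpc <- function(d = 8) cpc_params(d_emb = d, channels = c(d, d))

test_that("length filtering keeps exactly the inclusive range", {
  seqs <- vapply(c(69, 70, 1000, 1001), function(n) strrep("A", n),
                 character(1))
  kept <- length_filter(seqs, 70, 1000)
  expect_equal(nchar(kept), c(70, 1000))
  expect_length(length_filter(character(0), 70, 1000), 0L)
  # count oracle on random lengths
  set.seed(3)
  lens <- sample(50:1050, 100, replace = TRUE)
  seqs <- vapply(lens, function(n) strrep("K", n), character(1))
  expect_length(length_filter(seqs, 70, 1000),
                sum(lens >= 70 & lens <= 1000))
  expect_error(length_filter(seqs, 10, 5), class = "dtakit_error_input")
})

test_that("segmentation pads, cuts and discards by the stated arithmetic", {
  sp <- segment_protein(strrep("A", 110), l_segment = 11, l_total = 110)
  expect_equal(sp$n_segments, 10L)
  expect_true(inherits(segment_protein(strrep("A", 111), 11, 110),
                       "discarded_protein"))
  sp95 <- segment_protein(strrep("A", 95), 11, 110)
  expect_equal(sum(sp95$token_ids == dtakit:::PAD_ID), 15L)
  expect_equal(sp95$n_segments, 10L)
  # the PAD tail sits at the end of the final segments
  expect_true(all(sp95$segments[10, 8:11] == dtakit:::PAD_ID))
  expect_error(segment_protein("AAA", l_segment = 11, l_total = 100),
               class = "dtakit_error_config")
})

test_that("masking selects the rounded budget without touching PAD", {
  ids <- rep(1L, 1000)
  m <- mask_for_mlm(ids, 0.15, seed = 4)
  expect_length(m$positions, 150L)
  expect_true(all(m$corrupted[m$positions] == dtakit:::MASK_ID))

  expect_length(mask_for_mlm(1L, 0.15, seed = 1)$positions, 1L)

  m1 <- mask_for_mlm(ids, 0.15, seed = 9)
  m2 <- mask_for_mlm(ids, 0.15, seed = 9)
  expect_identical(m1$positions, m2$positions)

  padded <- c(rep(2L, 40), rep(dtakit:::PAD_ID, 26))
  mp <- mask_for_mlm(padded, 0.15, seed = 2)
  expect_true(all(mp$positions <= 40))
  expect_length(mp$positions, round(0.15 * 40))

  expect_error(mask_for_mlm(rep(dtakit:::PAD_ID, 5), 0.15),
               class = "dtakit_error_input")
  expect_error(mask_for_mlm(ids, 0), class = "dtakit_error_input")

  # budget rule holds across random lengths
  set.seed(12)
  for (n in sample(1:500, 50)) {
    got <- length(mask_for_mlm(rep(3L, n), 0.15)$positions)
    expect_equal(got, max(1L, round(0.15 * n)))
  }
})

test_that("zero-weight MLM scores are uniform and cost ln V", {
  p <- tiny_mlm()
  for (t in dtakit:::ad_flatten_params(p)) t$value[] <- 0
  ids <- tokenize_protein(strrep("ACD", 10))
  fwd <- mlm_forward(ids, p)
  sc <- dtakit:::ad_value(fwd$scores)
  expect_equal(max(sc) - min(sc), 0)
  l <- mlm_loss(fwd$scores, 1:10, ids)
  expect_equal(dtakit:::ad_value(l)[1], log(23), tolerance = 1e-12)
})

test_that("MLM pooling is a mean over non-PAD positions only", {
  set.seed(14)
  p <- tiny_mlm()
  ids <- c(tokenize_protein("ACDEFGHIKL"), rep(dtakit:::PAD_ID, 12))
  fwd <- mlm_forward(ids, p)
  manual <- colMeans(dtakit:::ad_value(fwd$hidden)[1:10, ])
  expect_equal(dtakit:::ad_value(fwd$pooled)[1, ], manual, tolerance = 1e-12)
  expect_error(mlm_forward(rep(1L, 100), tiny_mlm(max_len = 66)),
               class = "dtakit_error_config")
})

test_that("the masked-position loss is a scalar-loop cross-entropy", {
  # perfect scores drive the loss to zero
  p <- tiny_mlm()
  ids <- tokenize_protein("ACDE")
  scores <- matrix(-50, 4, 23)
  scores[cbind(1:4, ids)] <- 50
  l <- mlm_loss(scores, 1:4, ids)
  expect_lt(dtakit:::ad_value(l)[1], 1e-6)

  # two-position hand example
  s2 <- rbind(c(1.0, rep(0.2, 22)), c(rep(-0.3, 22), 2.0))
  true_ids <- c(1L, 23L)
  want <- mean(c(
    -(s2[1, 1] - log(sum(exp(s2[1, ])))),
    -(s2[2, 23] - log(sum(exp(s2[2, ]))))
  ))
  expect_equal(dtakit:::ad_value(mlm_loss(s2, 1:2, true_ids))[1], want,
               tolerance = 1e-12)
  expect_error(mlm_loss(s2, integer(0), true_ids),
               class = "dtakit_error_input")
})

test_that("segment encoding is shared-weight and matches the convolution oracle", {
  set.seed(15)
  p <- tiny_cpc()
  # identical segments map to identical rows
  sp <- segment_protein(strrep("A", 33), 11, 33)
  z <- dtakit:::ad_value(cpc_encode_segments(sp, p))
  expect_equal(z[1, ], z[2, ], tolerance = 1e-12)
  expect_equal(z[1, ], z[3, ], tolerance = 1e-12)

  # scalar-loop oracle segment by segment on a random protein
  sq <- paste(sample(dtakit:::AA_LETTERS, 33, TRUE), collapse = "")
  sp2 <- segment_protein(sq, 11, 33)
  z2 <- dtakit:::ad_value(cpc_encode_segments(sp2, p))
  for (t in 1:3) {
    want <- scalar_cpc_segment(sp2$segments[t, ], p)
    expect_lt(rel_dev(z2[t, ], want), 1e-5)
  }

  # an all-PAD segment still yields finite features
  sp3 <- segment_protein("AC", 11, 22)
  z3 <- dtakit:::ad_value(cpc_encode_segments(sp3, p))
  expect_true(all(is.finite(z3)))
})

test_that("the autoregressor is causal and matches the scalar recurrence", {
  set.seed(16)
  p <- tiny_cpc()
  z <- matrix(rnorm(5 * 8), 5, 8)
  cm <- dtakit:::ad_value(cpc_autoregress(z, p))
  expect_equal(dim(cm), c(5L, 8L))
  expect_lt(rel_dev(cm, scalar_gru(z, p)), 1e-5)

  # perturbing the last segment leaves earlier context rows unchanged
  z2 <- z; z2[5, ] <- z2[5, ] + 10
  cm2 <- dtakit:::ad_value(cpc_autoregress(z2, p))
  expect_equal(cm2[1:4, ], cm[1:4, ], tolerance = 1e-12)

  c1 <- dtakit:::ad_value(cpc_autoregress(z[1, , drop = FALSE], p))
  expect_equal(c1[1, ], cm[1, ], tolerance = 1e-12)
})

test_that("the contrastive loss scores true future segments against negatives", {
  p <- tiny_cpc()
  # all-equal scores with one negative: chance level ln 2, accuracy one half
  for (t in dtakit:::ad_flatten_params(p$pred_w)) t$value[] <- 0
  z <- matrix(rnorm(16), 2, 8)
  cm <- dtakit:::ad_value(cpc_autoregress(z, p))
  nce <- infonce_loss(cm, z, matrix(rnorm(8), 1, 8), p)
  expect_equal(dtakit:::ad_value(nce$loss)[1], log(2), tolerance = 1e-12)
  expect_equal(nce$accuracy, 0.5)

  # a dominant true-segment score drives the loss toward zero
  p2 <- tiny_cpc()
  p2$pred_w[[1]]$value <- diag(8) * 50
  zz <- rbind(rep(1, 8), rep(1, 8))
  cc <- rbind(rep(1, 8), rep(1, 8))
  nce2 <- infonce_loss(cc, zz, matrix(-1, 3, 8), p2)
  expect_lt(dtakit:::ad_value(nce2$loss)[1], 1e-6)
  expect_equal(nce2$accuracy, 1)

  # fixed tiny instance against a hand-computed softmax cross-entropy
  set.seed(17)
  p3 <- tiny_cpc()
  z3 <- matrix(rnorm(32), 4, 8)
  c3 <- dtakit:::ad_value(cpc_autoregress(z3, p3))
  neg <- matrix(rnorm(24), 3, 8)
  nce3 <- infonce_loss(c3, z3, neg, p3)
  w <- dtakit:::ad_value(p3$pred_w[[1]])
  losses <- vapply(1:3, function(t) {
    q <- c3[t, ] %*% w
    logits <- as.numeric(q %*% t(rbind(z3[t + 1, ], neg)))
    -(logits[1] - log(sum(exp(logits))))
  }, numeric(1))
  expect_equal(dtakit:::ad_value(nce3$loss)[1], mean(losses),
               tolerance = 1e-10)

  expect_error(infonce_loss(c3[1, , drop = FALSE], z3[1, , drop = FALSE],
                            neg, p3),
               class = "dtakit_error_input")
})

test_that("the combined embedding concatenates CPC locals with the pooled MLM vector", {
  set.seed(18)
  mlm <- tiny_mlm(d = 8, max_len = 110)
  cpc <- tiny_cpc(d = 8)
  emb <- protein_embedding(strrep("ACDEF", 19), mlm, cpc,
                           l_segment = 11, l_total = 110)
  expect_equal(dim(dtakit:::ad_value(emb$e_p)), c(10L, 16L))
  # every row carries the same pooled MLM block
  ep <- dtakit:::ad_value(emb$e_p)
  expect_equal(ep[, 9:16],
               matrix(dtakit:::ad_value(emb$pooled)[1, ], 10, 8,
                      byrow = TRUE),
               tolerance = 1e-12)

  # identical sequences give identical embeddings; zero CPC weights give
  # segment-constant rows
  e1 <- dtakit:::ad_value(protein_embedding("ACDEACDE", mlm, cpc, 11, 110)$e_p)
  e2 <- dtakit:::ad_value(protein_embedding("ACDEACDE", mlm, cpc, 11, 110)$e_p)
  expect_identical(e1, e2)

  cpc0 <- tiny_cpc(d = 8)
  for (t in dtakit:::ad_flatten_params(cpc0$conv)) t$value[] <- 0
  for (t in dtakit:::ad_flatten_params(cpc0$token_emb)) t$value[] <- 0
  z0 <- dtakit:::ad_value(
    cpc_encode_segments(segment_protein("ACDEACDEAC", 11, 44), cpc0))
  expect_equal(z0[1, ], z0[4, ], tolerance = 1e-12)
})
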