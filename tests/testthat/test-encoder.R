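# Encoder: relative index, disentangled attention vs a naive double-loop
# oracle, feed-forward, layer plumbing, translation equivariance, gradients,
# and checkpoint round trips.

test_that("rel_index equals a brute-force clamp loop exhaustively", {
  for (k in c(1L, 2L, 128L)) {
    for (i in seq(0L, 299L, by = 7L)) {     # strided grid keeps this fast
      j <- 0:299
      brute <- vapply(j, function(jj) {
        d <- i - jj
        if (d < -k) d <- -k
        if (d > k) d <- k
        d + k
      }, numeric(1))
      expect_identical(rel_index(i, j, k), as.integer(brute))
    }
  }
  expect_identical(rel_index(5L, 5L, 128L), 128L)
  expect_identical(rel_index(0L, 300L, 128L), 0L)
  expect_identical(rel_index(5L, 2L, 128L), 131L)
})

# naive oracle: explicit loops over (i, j) computing the three dot products
oracle_scores <- function(H, P, w, k, variant) {
  N <- nrow(H)
  Qc <- H %*% w$W_qc; Kc <- H %*% w$W_kc; Kr <- P %*% w$W_kr
  Qr <- if (variant == "as_printed") H %*% w$W_qr else P %*% w$W_qr
  A <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    d1 <- sum(Qc[i, ] * Kc[j, ])
    d2 <- sum(Qc[i, ] * Kr[rel_index(i - 1L, j - 1L, k) + 1L, ])
    d3 <- if (variant == "as_printed") {
      sum(Qr[i, ] * Kc[j, ])
    } else {
      sum(Kc[j, ] * Qr[rel_index(j - 1L, i - 1L, k) + 1L, ])
    }
    A[i, j] <- d1 + d2 + d3
  }
  A
}

test_that("attention_scores matches the double-loop oracle on random instances", {
  rng <- new_rng(2024)
  for (variant in c("as_printed", "deberta_original")) {
    for (trial in 1:20) {
      N <- with_rng(rng, sample(2:8, 1))
      d <- with_rng(rng, sample(c(4L, 8L, 16L), 1))
      dk <- with_rng(rng, sample(c(2L, 4L), 1))
      k <- with_rng(rng, sample(1:4, 1))
      cfg <- encoder_config(n_layers = 1L, d_model = d, n_heads = d / dk,
                            k_max = k, p2c_variant = variant)
      H <- with_rng(rng, matrix(rnorm(N * d), N, d))
      P <- with_rng(rng, matrix(rnorm((2 * k + 1) * d), 2 * k + 1, d))
      w <- list(W_qc = with_rng(rng, matrix(rnorm(d * dk), d, dk)),
                W_kc = with_rng(rng, matrix(rnorm(d * dk), d, dk)),
                W_qr = with_rng(rng, matrix(rnorm(d * dk), d, dk)),
                W_kr = with_rng(rng, matrix(rnorm(d * dk), d, dk)))
      got <- attention_scores(H, P, w, cfg)
      want <- oracle_scores(H, P, w, k, variant)
      expect_lt(max(abs(got - want)) / max(1, max(abs(want))), 1e-6)
    }
  }
})

test_that("zero relative projections reduce scores to content attention", {
  rng <- new_rng(12)
  N <- 5L; d <- 8L; dk <- 4L; k <- 3L
  cfg <- encoder_config(n_layers = 1L, d_model = d, n_heads = 2L, k_max = k)
  H <- with_rng(rng, matrix(rnorm(N * d), N, d))
  P <- with_rng(rng, matrix(rnorm((2 * k + 1) * d), 2 * k + 1, d))
  w <- list(W_qc = with_rng(rng, matrix(rnorm(d * dk), d, dk)),
            W_kc = with_rng(rng, matrix(rnorm(d * dk), d, dk)),
            W_qr = matrix(0, d, dk), W_kr = matrix(0, d, dk))
  got <- attention_scores(H, P, w, cfg)
  expect_equal(got, (H %*% w$W_qc) %*% t(H %*% w$W_kc), tolerance = 1e-12)
})

test_that("attention_output scales by sqrt(3 dk), softmax rows sum to 1", {
  rng <- new_rng(13)
  cfg <- encoder_config(n_layers = 1L, d_model = 8L, n_heads = 2L, k_max = 4L)
  # all-equal scores -> uniform attention -> rows of output = column means of V
  V <- with_rng(rng, matrix(rnorm(6 * 4), 6, 4))
  O <- attention_output(matrix(1, 6, 6), V, cfg)
  expect_equal(O, matrix(colMeans(V), 6, 4, byrow = TRUE), tolerance = 1e-10)
  # saturation: one huge score picks out a single V row
  A <- matrix(0, 3, 3); A[1, 3] <- 1e4
  O2 <- attention_output(A, V[1:3, ], cfg)
  expect_equal(O2[1, ], V[3, ], tolerance = 1e-6)
  # random instance vs hand-computed softmax at the disentangled scale
  A3 <- with_rng(rng, matrix(rnorm(25), 5, 5))
  S <- A3 / sqrt(3 * cfg$d_k)
  W <- exp(S) / rowSums(exp(S))
  expect_equal(attention_output(A3, V[1:5, ], cfg), W %*% V[1:5, ], tolerance = 1e-10)
  expect_equal(rowSums(W), rep(1, 5), tolerance = 1e-6)
  # N = 1: softmax of a 1x1 matrix returns the single V row
  expect_equal(attention_output(matrix(2.7, 1, 1), V[1, , drop = FALSE], cfg),
               V[1, , drop = FALSE])
})

test_that("feed_forward implements Act(xW1+b1)W2+b2 exactly", {
  rng <- new_rng(14)
  x <- with_rng(rng, matrix(rnorm(3 * 4), 3, 4))
  zero <- list(W1 = matrix(0, 4, 6), b1 = rep(0, 6), W2 = matrix(0, 6, 4), b2 = rep(0, 4))
  expect_equal(feed_forward(x, zero, "gelu"), matrix(0, 3, 4))
  ffn <- list(W1 = with_rng(rng, matrix(rnorm(4 * 6), 4, 6)),
              b1 = with_rng(rng, rnorm(6)),
              W2 = with_rng(rng, matrix(rnorm(6 * 4), 6, 4)),
              b2 = with_rng(rng, rnorm(4)))
  # linear activation reproduces the affine composition
  want_lin <- sweep(sweep(x %*% ffn$W1, 2, ffn$b1, "+") %*% ffn$W2, 2, ffn$b2, "+")
  expect_equal(feed_forward(x, ffn, "linear"), want_lin, tolerance = 1e-12)
  # gelu oracle
  h <- sweep(x %*% ffn$W1, 2, ffn$b1, "+")
  want <- sweep((h * pnorm(h)) %*% ffn$W2, 2, ffn$b2, "+")
  expect_equal(feed_forward(x, ffn, "gelu"), want, tolerance = 1e-12)
})

test_that("transformer_layer preserves shape, is finite and deterministic", {
  cfg <- tiny_encoder_cfg()
  w <- init_encoder_weights(cfg, new_rng(3))
  x <- with_rng(new_rng(4), matrix(rnorm(10 * cfg$d_model), 10))
  y1 <- transformer_layer(x, w, 1L, cfg)
  y2 <- transformer_layer(x, w, 1L, cfg)
  expect_identical(dim(y1), dim(x))
  expect_true(all(is.finite(y1)))
  expect_identical(y1, y2)
})

test_that("encode is translation-equivariant in relative mode only", {
  ids <- c(2L, 10L, 12L, 7L, 20L, 9L, 3L)
  cfg_rel <- tiny_encoder_cfg()
  w_rel <- init_encoder_weights(cfg_rel, new_rng(5))
  H0 <- encode(ids, w_rel, cfg_rel, position_offset = 0L)
  H5 <- encode(ids, w_rel, cfg_rel, position_offset = 5L)
  expect_lt(max(abs(H0 - H5)), 1e-10)

  cfg_abs <- tiny_encoder_cfg(position_mode = "absolute_learned", max_abs_pos = 64L)
  w_abs <- init_encoder_weights(cfg_abs, new_rng(5))
  A0 <- encode(ids, w_abs, cfg_abs, position_offset = 0L)
  A5 <- encode(ids, w_abs, cfg_abs, position_offset = 5L)
  expect_gt(max(abs(A0 - A5)), 1e-4)
})

test_that("encode validates ids and mlm_logits is a single affine map", {
  cfg <- tiny_encoder_cfg()
  w <- init_encoder_weights(cfg, new_rng(6))
  expect_error(encode(c(2L, 99L, 3L), w, cfg), "vocabulary")
  H <- encode(c(2L, 8L, 9L, 3L), w, cfg)
  lg <- mlm_logits(H, w)
  expect_identical(dim(lg), c(4L, 25L))
  expect_equal(lg, sweep(H %*% w$lm_W, 2, w$lm_b, "+"), tolerance = 1e-12)
  # zero lm weights -> equal logits -> uniform softmax
  w0 <- w; w0$lm_W[] <- 0; w0$lm_b[] <- 0
  expect_true(all(mlm_logits(H, w0) == 0))
})

test_that("analytic gradients match central finite differences (tiny model)", {
  for (variant in c("as_printed", "deberta_original")) {
    cfg <- encoder_config(n_layers = 1L, d_model = 8L, n_heads = 2L, d_ff = 16L,
                          k_max = 3L, p2c_variant = variant)
    w <- init_encoder_weights(cfg, new_rng(7))
    ids <- c(2L, 10L, 7L, 9L, 23L, 3L)     # N=6 > k+1 exercises clamping
    labels <- c(NA, 12L, NA, 14L, 8L, NA)
    r <- mlm_loss_and_grads(ids, labels, w, cfg)
    f <- function(w) label_smoothed_ce(mlm_logits(encode(ids, w, cfg), w), labels)$loss
    h <- 1e-5
    rng <- new_rng(8)
    for (nm in names(w)) {
      for (cidx in with_rng(rng, sample(length(w[[nm]]), min(3, length(w[[nm]]))))) {
        wp <- w; wp[[nm]][cidx] <- wp[[nm]][cidx] + h
        wm <- w; wm[[nm]][cidx] <- wm[[nm]][cidx] - h
        g_num <- (f(wp) - f(wm)) / (2 * h)
        expect_lt(abs(g_num - r$grads[[nm]][cidx]), 1e-6)
      }
    }
  }
})

test_that("per-batch relative-projection caching leaves loss and gradients unchanged", {
  for (variant in c("as_printed", "deberta_original")) {
    cfg <- encoder_config(n_layers = 2L, d_model = 8L, n_heads = 2L, d_ff = 16L,
                          k_max = 4L, p2c_variant = variant)
    w <- init_encoder_weights(cfg, new_rng(31))
    ids <- c(2L, 10L, 7L, 9L, 23L, 11L, 3L)
    labels <- c(NA, 12L, NA, 14L, 8L, NA, NA)
    plain <- mlm_loss_and_grads(ids, labels, w, cfg)
    cached <- mlm_loss_and_grads(ids, labels, w, cfg,
                                 precomp = rel_precompute(w, cfg))
    expect_identical(plain$loss, cached$loss)
    for (nm in names(plain$grads)) {
      expect_identical(plain$grads[[nm]], cached$grads[[nm]])
    }
  }
})

test_that("checkpoints round-trip byte-identically and pin the vocabulary", {
  cfg <- tiny_encoder_cfg()
  w <- init_encoder_weights(cfg, new_rng(9))
  d1 <- file.path(tempdir(), "ck1"); d2 <- file.path(tempdir(), "ck2")
  save_checkpoint(w, cfg, d1, seed = 9L, step = 3L, epoch = 1L)
  ck <- load_checkpoint(d1)
  expect_equal(ck$weights$tok_emb, w$tok_emb)
  expect_identical(ck$cfg$d_model, cfg$d_model)
  expect_identical(unlist(ck$meta$vocabulary), residue_alphabet()$tokens)
  save_checkpoint(ck$weights, ck$cfg, d2, seed = 9L, step = 3L, epoch = 1L)
  expect_identical(readBin(file.path(d1, "params.bin"), "raw", 1e7),
                   readBin(file.path(d2, "params.bin"), "raw", 1e7))
  expect_identical(readLines(file.path(d1, "meta.json")),
                   readLines(file.path(d2, "meta.json")))
})
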