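# Transformer encoder with disentangled relative-position attention.
#
# Attention scores for one head sum three dot products: content-to-content
# Qc_i.Kc_j, content-to-position Qc_i.Kr_{delta(i,j)}, and position-to-content.
# The position-to-content term has two variants: "as_printed" takes
# Qr = H.Wqr (a content-derived query, exactly as the source formulation
# prints it) while "deberta_original" takes Qr = P.Wqr indexed by delta(j,i)
# (the original disentangled-attention formulation).  Scores are scaled by
# 1/sqrt(3*d_k) before the row softmax, accounting for the variance of the
# three-term sum; plain content attention (the absolute-position ablation)
# scales by 1/sqrt(d_k).
#
# delta(i,j) = clamp(i - j, -k, k) + k indexes the (2k+1) x d relative
# position table P, shared across layers.  Layers are post-LN:
# x' = LN(Attention(x) + x), x'' = LN(FFN(x') + x').
#
# Weights are stored as full d x d matrices (heads concatenated along
# columns); head h uses column block ((h-1)*d_k+1):(h*d_k).

#' Encoder configuration
#'
#' @param n_layers number of transformer layers (desk default 2).
#' @param d_model hidden width d (desk default 64).
#' @param n_heads attention heads (must divide d_model; default 4).
#' @param d_ff feed-forward inner width (default 4 * d_model).
#' @param k_max maximum relative distance k; offsets beyond it are clamped
#'   (default 128).
#' @param vocab_size token vocabulary size (25).
#' @param activation feed-forward nonlinearity: "gelu" (default), "relu", or
#'   "linear".
#' @param position_mode "relative_disentangled" (default) or
#'   "absolute_learned" (learned absolute embeddings added to the token
#'   embedding; attention reduces to plain content attention).
#' @param p2c_variant "as_printed" (default) or "deberta_original"; see file
#'   header.
#' @param max_abs_pos size of the absolute-position table (absolute mode
#'   only).
#' @param ln_eps layer-norm epsilon.
#' @return object of class \code{abmlm_encoder_config}.
#' @export
encoder_config <- function(n_layers = 2L, d_model = 64L, n_heads = 4L,
                           d_ff = 4L * d_model, k_max = 128L, vocab_size = 25L,
                           activation = c("gelu", "relu", "linear"),
                           position_mode = c("relative_disentangled", "absolute_learned"),
                           p2c_variant = c("as_printed", "deberta_original"),
                           max_abs_pos = 512L, ln_eps = 1e-5) {
  fail_if(d_model %% n_heads != 0L, "d_model (%d) must be divisible by n_heads (%d)",
          d_model, n_heads)
  fail_if(k_max < 1L, "k_max must be >= 1")
  out <- list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
              n_heads = as.integer(n_heads), d_k = as.integer(d_model / n_heads),
              d_ff = as.integer(d_ff), k_max = as.integer(k_max),
              vocab_size = as.integer(vocab_size),
              activation = match.arg(activation),
              position_mode = match.arg(position_mode),
              p2c_variant = match.arg(p2c_variant),
              max_abs_pos = as.integer(max_abs_pos), ln_eps = ln_eps)
  class(out) <- "abmlm_encoder_config"
  out
}

#' Initialize encoder weights
#'
#' Gaussian init (sd 0.02) for projection matrices and embedding tables;
#' layer-norm gains 1, all biases 0.
#'
#' @param cfg an [encoder_config()].
#' @param rng stream from [new_rng()].
#' @return named list of parameter arrays (class \code{abmlm_weights}).
#' @export
init_encoder_weights <- function(cfg, rng) {
  d <- cfg$d_model
  gauss <- function(nr, nc) with_rng(rng, matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc))
  w <- list(tok_emb = gauss(cfg$vocab_size, d))
  if (cfg$position_mode == "relative_disentangled") {
    w$pos_table <- gauss(2L * cfg$k_max + 1L, d)
  } else {
    w$abs_emb <- gauss(cfg$max_abs_pos, d)
  }
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d_", l)
    w[[paste0(pre, "Wqc")]] <- gauss(d, d)
    w[[paste0(pre, "Wkc")]] <- gauss(d, d)
    w[[paste0(pre, "Wvc")]] <- gauss(d, d)
    if (cfg$position_mode == "relative_disentangled") {
      w[[paste0(pre, "Wqr")]] <- gauss(d, d)
      w[[paste0(pre, "Wkr")]] <- gauss(d, d)
    }
    w[[paste0(pre, "ln1_g")]] <- rep(1, d)
    w[[paste0(pre, "ln1_b")]] <- rep(0, d)
    w[[paste0(pre, "W1")]] <- gauss(d, cfg$d_ff)
    w[[paste0(pre, "b1")]] <- rep(0, cfg$d_ff)
    w[[paste0(pre, "W2")]] <- gauss(cfg$d_ff, d)
    w[[paste0(pre, "b2")]] <- rep(0, d)
    w[[paste0(pre, "ln2_g")]] <- rep(1, d)
    w[[paste0(pre, "ln2_b")]] <- rep(0, d)
  }
  w$lm_W <- gauss(d, cfg$vocab_size)
  w$lm_b <- rep(0, cfg$vocab_size)
  class(w) <- "abmlm_weights"
  w
}

#' Clamped relative position index
#'
#' \code{delta(i, j) = clamp(i - j, -k, k) + k}, an integer in \[0, 2k\].
#'
#' @param i,j token positions (any integer-valued vectors, recycled).
#' @param k maximum relative distance.
#' @return integer index (vectorized).
#' @export
rel_index <- function(i, j, k) {
  fail_if(k < 1, "k must be >= 1")
  as.integer(pmin(pmax(i - j, -k), k) + k)
}

# N x N matrix of 1-based rows into the position table for positions pos
#' @noRd
.rel_index_matrix <- function(pos, k) {
  outer(pos, pos, function(i, j) rel_index(i, j, k)) + 1L
}

# Relative-position context shared by all heads and layers of one forward:
# Didx (N x N 1-based rows into P), linear gather indices into an
# N x (2k+1) matrix for the c2p term (lin) and its transpose for the
# original p2c variant (linT), and whether rows are collision-free (no two
# cells of a row share a Didx value; true whenever no clamping occurs, i.e.
# N <= k+1), which allows scatter by plain assignment.
#' @noRd
.rel_context <- function(pos, k, nP) {
  Didx <- .rel_index_matrix(pos, k)
  N <- length(pos)
  ri <- rep.int(seq_len(N), N)
  lin <- ri + N * (as.vector(Didx) - 1L)
  cj <- rep(seq_len(N), each = N)
  linT <- cj + N * (as.vector(t(Didx)) - 1L)
  list(Didx = Didx, lin = lin, linT = linT, N = N, nP = nP,
       collision_free = N <= k + 1L)
}

#' Single-head disentangled attention scores
#'
#' @param H N x d matrix of input hidden vectors.
#' @param P (2k+1) x d relative position table (ignored in absolute mode).
#' @param weights list with per-head projections \code{W_qc, W_kc, W_qr,
#'   W_kr}, each d x d_k.
#' @param cfg an [encoder_config()] (fields \code{k_max}, \code{p2c_variant},
#'   \code{position_mode} are honoured).
#' @param positions optional 0-based token positions (default 0..N-1).
#' @return N x N unscaled score matrix A'.
#' @export
attention_scores <- function(H, P, weights, cfg, positions = NULL) {
  N <- nrow(H)
  fail_if(ncol(H) != nrow(weights$W_qc), "H and W_qc disagree on d")
  Qc <- H %*% weights$W_qc
  Kc <- H %*% weights$W_kc
  S <- Qc %*% t(Kc)
  if (cfg$position_mode != "relative_disentangled") {
    return(S)
  }
  fail_if(nrow(P) != 2L * cfg$k_max + 1L, "P must have 2k+1 rows")
  if (is.null(positions)) positions <- seq_len(N) - 1L
  Didx <- .rel_index_matrix(positions, cfg$k_max)
  Kr <- P %*% weights$W_kr
  M1 <- Qc %*% t(Kr)                       # N x (2k+1)
  c2p <- matrix(M1[cbind(as.vector(row(Didx)), as.vector(Didx))], N, N)
  if (cfg$p2c_variant == "as_printed") {
    Qr <- H %*% weights$W_qr
    p2c <- Qr %*% t(Kc)
  } else {
    Qr <- P %*% weights$W_qr               # (2k+1) x d_k
    Mq <- Kc %*% t(Qr)                     # N x (2k+1)
    Dt <- t(Didx)                          # Dt[i,j] = delta(j,i)+1
    p2c <- matrix(Mq[cbind(as.vector(col(Dt)), as.vector(Dt))], N, N)
  }
  S + c2p + p2c
}

#' Attention output from unscaled scores
#'
#' Scales by \code{1/sqrt(3 d_k)} (disentangled) or \code{1/sqrt(d_k)}
#' (plain content attention), applies the row softmax, and multiplies by V.
#'
#' @param A_prime N x N unscaled scores.
#' @param V N x d_k value matrix.
#' @param cfg an [encoder_config()].
#' @return N x d_k output.
#' @export
attention_output <- function(A_prime, V, cfg) {
  fail_if(nrow(A_prime) != ncol(A_prime), "score matrix must be square")
  scale <- if (cfg$position_mode == "relative_disentangled") {
    sqrt(3 * cfg$d_k)
  } else {
    sqrt(cfg$d_k)
  }
  row_softmax(A_prime / scale) %*% V
}

#' Position-wise feed-forward network
#'
#' \code{FFN(x) = Act(x W1 + b1) W2 + b2}.
#'
#' @param x N x d input.
#' @param ffn list with \code{W1, b1, W2, b2}.
#' @param activation "gelu", "relu", or "linear".
#' @return N x d output.
#' @export
feed_forward <- function(x, ffn, activation = "gelu") {
  h <- sweep(x %*% ffn$W1, 2L, ffn$b1, "+")
  sweep(.act(h, activation) %*% ffn$W2, 2L, ffn$b2, "+")
}

#' @noRd
.act <- function(x, activation) {
  switch(activation,
         gelu = x * stats::pnorm(x),
         relu = pmax(x, 0),
         linear = x,
         stop("unknown activation"))
}

#' @noRd
.act_grad <- function(x, activation) {
  switch(activation,
         gelu = stats::pnorm(x) + x * stats::dnorm(x),
         relu = (x > 0) * 1,
         linear = array(1, dim = dim(x)))
}

# row-wise layer norm; returns y plus the cache needed for backward
#' @noRd
.layer_norm <- function(x, g, b, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  sd_ <- sqrt(v + eps)
  xhat <- xc / sd_
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(y = y, xhat = xhat, sd = sd_)
}

# Multi-head attention sublayer forward; returns output + cache.
#' @noRd
.attn_forward <- function(X, w, pre, cfg, rc, pc = NULL) {
  N <- nrow(X); d <- cfg$d_model; dk <- cfg$d_k
  rel <- cfg$position_mode == "relative_disentangled"
  Qc_f <- X %*% w[[paste0(pre, "Wqc")]]
  Kc_f <- X %*% w[[paste0(pre, "Wkc")]]
  V_f <- X %*% w[[paste0(pre, "Wvc")]]
  if (rel) {
    P <- w$pos_table
    # P-projections depend only on the weights; reuse across a batch if the
    # caller precomputed them
    Kr_f <- if (!is.null(pc)) pc$Kr_f else P %*% w[[paste0(pre, "Wkr")]]
    Qr_f <- if (cfg$p2c_variant == "as_printed") {
      X %*% w[[paste0(pre, "Wqr")]]
    } else if (!is.null(pc)) {
      pc$Qr_f
    } else {
      P %*% w[[paste0(pre, "Wqr")]]
    }
  }
  scale <- if (rel) sqrt(3 * dk) else sqrt(dk)
  O <- matrix(0, N, d)
  A_list <- vector("list", cfg$n_heads)
  for (h in seq_len(cfg$n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qc <- Qc_f[, cols, drop = FALSE]
    Kc <- Kc_f[, cols, drop = FALSE]
    S <- Qc %*% t(Kc)
    if (rel) {
      Kr <- Kr_f[, cols, drop = FALSE]
      M1 <- Qc %*% t(Kr)
      S <- S + matrix(M1[rc$lin], N, N)
      if (cfg$p2c_variant == "as_printed") {
        S <- S + Qr_f[, cols, drop = FALSE] %*% t(Kc)
      } else {
        Mq <- Kc %*% t(Qr_f[, cols, drop = FALSE])
        S <- S + matrix(Mq[rc$linT], N, N)
      }
    }
    A <- row_softmax(S / scale)
    O[, cols] <- A %*% V_f[, cols, drop = FALSE]
    A_list[[h]] <- A
  }
  list(O = O, A = A_list, Qc_f = Qc_f, Kc_f = Kc_f, V_f = V_f,
       Kr_f = if (rel) Kr_f else NULL, Qr_f = if (rel) Qr_f else NULL,
       X = X, scale = scale)
}

# One transformer layer forward with cache.
#' @noRd
.layer_forward <- function(X, w, l, cfg, rc, precomp = NULL) {
  pre <- sprintf("l%d_", l)
  att <- .attn_forward(X, w, pre, cfg, rc, pc = precomp[[pre]])
  res1 <- att$O + X
  ln1 <- .layer_norm(res1, w[[paste0(pre, "ln1_g")]], w[[paste0(pre, "ln1_b")]], cfg$ln_eps)
  X1 <- ln1$y
  Hpre <- sweep(X1 %*% w[[paste0(pre, "W1")]], 2L, w[[paste0(pre, "b1")]], "+")
  pn <- NULL
  if (cfg$activation == "gelu") {
    pn <- stats::pnorm(Hpre)
    Ha <- Hpre * pn
  } else {
    Ha <- .act(Hpre, cfg$activation)
  }
  ff <- sweep(Ha %*% w[[paste0(pre, "W2")]], 2L, w[[paste0(pre, "b2")]], "+")
  res2 <- ff + X1
  ln2 <- .layer_norm(res2, w[[paste0(pre, "ln2_g")]], w[[paste0(pre, "ln2_b")]], cfg$ln_eps)
  list(out = ln2$y,
       cache = list(att = att, ln1 = ln1, X1 = X1, Hpre = Hpre, Ha = Ha,
                    pn = pn, ln2 = ln2))
}

#' Apply one transformer layer
#'
#' Residual connections: \code{x' = LN(Attention(x) + x)},
#' \code{x'' = LN(FFN(x') + x')} (post-residual layer norm).
#'
#' @param x N x d input hidden states.
#' @param weights full weight list (from [init_encoder_weights()]).
#' @param layer layer number (1-based).
#' @param cfg an [encoder_config()].
#' @param positions optional 0-based token positions.
#' @return N x d output hidden states.
#' @export
transformer_layer <- function(x, weights, layer, cfg, positions = NULL) {
  N <- nrow(x)
  if (is.null(positions)) positions <- seq_len(N) - 1L
  rc <- if (cfg$position_mode == "relative_disentangled") {
    .rel_context(positions, cfg$k_max, 2L * cfg$k_max + 1L)
  } else {
    NULL
  }
  .layer_forward(x, weights, layer, cfg, rc)$out
}

#' Precompute the weight-only relative projections for a batch
#'
#' \code{Kr = P W_kr} (and \code{Qr = P W_qr} in the original variant) depend
#' only on the weights; computing them once per optimizer step instead of per
#' sequence saves a large share of the training matmuls.
#'
#' @param weights weight list.
#' @param cfg an [encoder_config()].
#' @return per-layer list to pass as \code{precomp} to [encode()], or NULL in
#'   absolute mode.
#' @export
rel_precompute <- function(weights, cfg) {
  if (cfg$position_mode != "relative_disentangled") return(NULL)
  pc <- list()
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("l%d_", l)
    pc[[pre]] <- list(
      Kr_f = weights$pos_table %*% weights[[paste0(pre, "Wkr")]],
      Qr_f = if (cfg$p2c_variant == "deberta_original") {
        weights$pos_table %*% weights[[paste0(pre, "Wqr")]]
      } else NULL)
  }
  pc
}

#' Encode a token sequence
#'
#' Embedding lookup (plus learned absolute embeddings in absolute mode),
#' followed by \code{n_layers} transformer layers.
#'
#' @param token_ids integer vector of 0-based token ids.
#' @param weights weight list.
#' @param cfg an [encoder_config()].
#' @param position_offset integer added to all token positions; in relative
#'   mode the output is invariant to it (translation equivariance within the
#'   clamp radius), in absolute mode it shifts the embedding lookup.
#' @param cache if TRUE, also return per-layer forward caches (needed for the
#'   backward pass).
#' @param precomp optional output of [rel_precompute()] (a per-batch cache of
#'   the weight-only relative projections).
#' @return N x d matrix of final hidden states, or a list
#'   \code{(H, caches, rc, positions, ids)} when \code{cache = TRUE}.
#' @export
encode <- function(token_ids, weights, cfg, position_offset = 0L, cache = FALSE,
                   precomp = NULL) {
  ids <- as.integer(token_ids)
  fail_if(any(ids < 0L | ids >= cfg$vocab_size), "token id out of vocabulary")
  N <- length(ids)
  positions <- position_offset + seq_len(N) - 1L
  X <- weights$tok_emb[ids + 1L, , drop = FALSE]
  if (cfg$position_mode == "absolute_learned") {
    fail_if(any(positions + 1L > cfg$max_abs_pos),
            "position exceeds the absolute-position table")
    X <- X + weights$abs_emb[positions + 1L, , drop = FALSE]
    rc <- NULL
  } else {
    rc <- .rel_context(positions, cfg$k_max, 2L * cfg$k_max + 1L)
  }
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    fl <- .layer_forward(X, weights, l, cfg, rc, precomp = precomp)
    X <- fl$out
    if (cache) caches[[l]] <- fl$cache
  }
  if (cache) {
    list(H = X, caches = caches, rc = rc, positions = positions, ids = ids)
  } else {
    X
  }
}

#' Token-prediction logits
#'
#' A single affine map from final hidden states to vocabulary scores; no
#' intermediate transform.
#'
#' @param H_final N x d matrix.
#' @param weights weight list (uses \code{lm_W}, \code{lm_b}).
#' @return N x vocab_size score matrix.
#' @export
mlm_logits <- function(H_final, weights) {
  sweep(H_final %*% weights$lm_W, 2L, weights$lm_b, "+")
}
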