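# Frozen-encoder downstream heads.
#
# Pairing head: mean-pooled chain representations pass through per-chain-type
# two-layer MLP projections, are L2-normalized, and compared by cosine
# similarity; training minimizes InfoNCE over one positive light chain and
# n_neg sampled negatives (identity < 0.85 to the true partner).  The
# encoder is frozen throughout; a parameter hash asserts it.
#
# Binding head: the hidden states of the CDR3 positions (zero-padded to a
# fixed length) pass through a single shared linear projection, are
# flattened, and classified by a two-layer MLP with softmax; training uses
# plain cross-entropy.

#' Mean-pool hidden states over residue tokens
#'
#' @param H N x d hidden-state matrix.
#' @param idx indices of the residue tokens ([CLS]/[SEP]/pad excluded).
#' @return length-d vector.
#' @export
mean_pool <- function(H, idx) {
  fail_if(length(idx) == 0L, "cannot pool an empty residue set")
  colMeans(H[idx, , drop = FALSE])
}

#' Pairing-head configuration
#'
#' @param d_proj projected dimension (default 32).
#' @param tau InfoNCE temperature (default 0.1); the loss uses raw cosine,
#'   the \[0, 1\] rescale of [pairing_score()] is for reporting only.
#' @param n_neg negatives per positive (default 15).
#' @param shared share one projection MLP between heavy and light (default
#'   FALSE: separate projections).
#' @param max_identity negative-filter identity ceiling (default 0.85,
#'   applied against the true partner light chain).
#' @param lr,epochs Adam learning rate and full-batch epochs.
#' @return object of class \code{abmlm_pairing_config}.
#' @export
pairing_config <- function(d_proj = 32L, tau = 0.1, n_neg = 15L, shared = FALSE,
                           max_identity = 0.85, lr = 5e-3, epochs = 150L) {
  fail_if(tau <= 0, "tau must be > 0")
  out <- list(d_proj = as.integer(d_proj), tau = tau, n_neg = as.integer(n_neg),
              shared = isTRUE(shared), max_identity = max_identity,
              lr = lr, epochs = as.integer(epochs))
  class(out) <- "abmlm_pairing_config"
  out
}

#' @noRd
.init_mlp2 <- function(d_in, d_out, rng, hidden = d_out) {
  g <- function(nr, nc) with_rng(rng, matrix(stats::rnorm(nr * nc, sd = 0.05), nr, nc))
  list(W1 = g(d_in, hidden), b1 = rep(0, hidden),
       W2 = g(hidden, d_out), b2 = rep(0, d_out))
}

# two-layer MLP forward on a row matrix; returns output + cache
#' @noRd
.mlp2_forward <- function(X, p) {
  H1pre <- sweep(X %*% p$W1, 2L, p$b1, "+")
  H1 <- pmax(H1pre, 0)
  Z <- sweep(H1 %*% p$W2, 2L, p$b2, "+")
  list(Z = Z, H1 = H1, H1pre = H1pre, X = X)
}

#' @noRd
.mlp2_backward <- function(dZ, cache, p) {
  dW2 <- t(cache$H1) %*% dZ
  db2 <- colSums(dZ)
  dH1 <- (dZ %*% t(p$W2)) * (cache$H1pre > 0)
  dW1 <- t(cache$X) %*% dH1
  db1 <- colSums(dH1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dX = dH1 %*% t(p$W1))
}

#' Heavy-light pairing score
#'
#' L2-normalizes both projected vectors and rescales their cosine similarity
#' to \[0, 1\]: \code{(cos + 1) / 2}.
#'
#' @param h_vec,l_vec projected heavy/light vectors.
#' @return score in \[0, 1\].
#' @export
pairing_score <- function(h_vec, l_vec) {
  nh <- sqrt(sum(h_vec^2)); nl <- sqrt(sum(l_vec^2))
  fail_if(nh == 0 || nl == 0, "zero-norm projected vector")
  (sum(h_vec * l_vec) / (nh * nl) + 1) / 2
}

#' InfoNCE loss
#'
#' \code{-log( exp(pos/tau) / (exp(pos/tau) + sum_i exp(neg_i/tau)) )}.
#'
#' @param pos_sim similarity of the positive pair.
#' @param neg_sims similarities of the negatives.
#' @param tau temperature (> 0).
#' @return scalar loss.
#' @export
info_nce <- function(pos_sim, neg_sims, tau = 0.1) {
  fail_if(tau <= 0, "tau must be > 0")
  z <- c(pos_sim, neg_sims) / tau
  m <- max(z)
  -(z[1] - (m + log(sum(exp(z - m)))))
}

#' Sample identity-filtered negative light chains
#'
#' Draws \code{n} lights uniformly without replacement from the pool members
#' whose identity to the true partner light chain is below
#' \code{max_identity}.
#'
#' @param true_light the positive partner (annotated chain).
#' @param light_pool list of candidate light chains.
#' @param n negatives to draw.
#' @param rng stream.
#' @param max_identity ceiling (default 0.85).
#' @param eligible optional precomputed logical vector over the pool (skips
#'   the alignment pass).
#' @return list of light chains.
#' @export
sample_negatives <- function(true_light, light_pool, n, rng,
                             max_identity = 0.85, eligible = NULL) {
  if (is.null(eligible)) {
    eligible <- vapply(light_pool, function(l) {
      pairwise_identity(l$sequence, true_light$sequence) < max_identity
    }, logical(1))
  }
  idx <- which(eligible)
  fail_if(length(idx) < n,
          "only %d eligible negatives (< %d requested) below identity %.2f",
          length(idx), n, max_identity)
  light_pool[with_rng(rng, sample(idx, n))]
}

# pooled frozen representation of a chain
#' @noRd
.pool_chain <- function(model, chain) {
  tok <- tokenize(chain)
  H <- encode(tok$token_ids, model$weights, model$cfg)
  mean_pool(H, residue_token_indices(tok))
}

#' @noRd
.pool_matrix <- function(model, chains) {
  do.call(rbind, lapply(chains, function(ch) .pool_chain(model, ch)))
}

# eligibility matrix pool-vs-positives under the identity filter
#' @noRd
.eligibility <- function(pairs, light_pool, max_identity) {
  do.call(rbind, lapply(pairs, function(pr) {
    vapply(light_pool, function(l) {
      pairwise_identity(l$sequence, pr$light$sequence) < max_identity
    }, logical(1))
  }))
}

#' Train the pairing head on a frozen encoder
#'
#' The encoder parameters are hashed before and after; any drift aborts.
#' Negatives are resampled once per epoch from the identity-filtered pool.
#'
#' @param model frozen \code{abmlm_model}.
#' @param pairs list of \code{list(heavy, light)} positives.
#' @param light_pool list of candidate negative lights.
#' @param head_cfg a [pairing_config()].
#' @param seed integer seed.
#' @return object of class \code{abmlm_pairing_head}: projection parameters
#'   (\code{heavy}, \code{light}), the config, and the training loss curve.
#' @export
train_pairing <- function(model, pairs, light_pool, head_cfg = pairing_config(),
                          seed = 1L) {
  hash_before <- object_hash(model$weights)
  rng <- new_rng(derive_seed(seed, "pairing"))
  d <- model$cfg$d_model
  Eh <- .pool_matrix(model, lapply(pairs, `[[`, "heavy"))
  El <- .pool_matrix(model, lapply(pairs, `[[`, "light"))
  Ep <- .pool_matrix(model, light_pool)
  elig <- .eligibility(pairs, light_pool, head_cfg$max_identity)

  ph <- .init_mlp2(d, head_cfg$d_proj, rng)
  pl <- if (head_cfg$shared) ph else .init_mlp2(d, head_cfg$d_proj, rng)
  params <- list(h = ph, l = pl)
  flat <- function(p) list(hW1 = p$h$W1, hb1 = p$h$b1, hW2 = p$h$W2, hb2 = p$h$b2,
                           lW1 = p$l$W1, lb1 = p$l$b1, lW2 = p$l$W2, lb2 = p$l$b2)
  unflat <- function(f) list(h = list(W1 = f$hW1, b1 = f$hb1, W2 = f$hW2, b2 = f$hb2),
                             l = list(W1 = f$lW1, b1 = f$lb1, W2 = f$lW2, b2 = f$lb2))
  fw <- flat(params)
  opt <- .adamw_init(fw)
  adam_cfg <- list(beta1 = 0.9, beta2 = 0.999, weight_decay = 0)
  n <- length(pairs)
  losses <- numeric(head_cfg$epochs)

  dp <- head_cfg$d_proj
  for (ep in seq_len(head_cfg$epochs)) {
    params <- unflat(fw)
    neg_idx <- with_rng(rng, t(vapply(seq_len(n), function(i) {
      sample(which(elig[i, ]), head_cfg$n_neg)
    }, integer(head_cfg$n_neg))))
    # project everything once per epoch, then accumulate per-positive InfoNCE
    fh <- .mlp2_forward(Eh, params$h)
    flp <- .mlp2_forward(El, params$l)
    fpool <- .mlp2_forward(Ep, params$l)
    nh <- sqrt(rowSums(fh$Z^2)); nl <- sqrt(rowSums(flp$Z^2))
    npo <- sqrt(rowSums(fpool$Z^2))
    fail_if(any(c(nh, nl, npo) == 0), "zero-norm projected vector")
    Uh <- fh$Z / nh; Ul <- flp$Z / nl; Up <- fpool$Z / npo
    dZh <- matrix(0, n, dp); dZl <- matrix(0, n, dp)
    dZp <- matrix(0, nrow(Ep), dp)
    total <- 0
    for (i in seq_len(n)) {
      uh <- Uh[i, ]
      rows <- neg_idx[i, ]
      Vh <- rbind(Ul[i, , drop = FALSE], Up[rows, , drop = FALSE])
      s <- as.vector(Vh %*% uh)
      p <- softmax_vec(s / head_cfg$tau)
      total <- total - log(p[1])
      dlog <- p; dlog[1] <- dlog[1] - 1
      ds <- dlog / head_cfg$tau
      dZh[i, ] <- colSums((Vh - outer(s, uh)) * ds) / nh[i]
      dV <- (matrix(uh, length(s), dp, byrow = TRUE) - Vh * s) * ds
      dZl[i, ] <- dV[1, ] / nl[i]
      dZp[rows, ] <- dZp[rows, ] + dV[-1, , drop = FALSE] / npo[rows]
    }
    bh <- .mlp2_backward(dZh, fh, params$h)
    bl1 <- .mlp2_backward(dZl, flp, params$l)
    bl2 <- .mlp2_backward(dZp, fpool, params$l)
    gh <- bh$grads
    gl <- Map(`+`, bl1$grads, bl2$grads)
    if (head_cfg$shared) {
      gh <- Map(`+`, gh, gl)
      gl <- gh
    }
    grads <- list(hW1 = gh$W1, hb1 = gh$b1, hW2 = gh$W2, hb2 = gh$b2,
                  lW1 = gl$W1, lb1 = gl$b1, lW2 = gl$W2, lb2 = gl$b2)
    grads <- lapply(grads, function(g) g / n)
    up <- .adamw_step(fw, grads, opt, head_cfg$lr, adam_cfg)
    fw <- up$weights
    opt <- up$state
    losses[ep] <- total / n
  }
  fail_if(object_hash(model$weights) != hash_before,
          "encoder parameters changed during head training (freeze contract)")
  params <- unflat(fw)
  out <- list(heavy = params$h, light = params$l, cfg = head_cfg,
              loss_curve = losses)
  class(out) <- "abmlm_pairing_head"
  out
}

#' Project a pooled representation through the pairing head
#'
#' @param head an \code{abmlm_pairing_head}.
#' @param x pooled d-vector (or row matrix).
#' @param side "heavy" or "light".
#' @return projected (un-normalized) vector(s).
#' @export
project_pairing <- function(head, x, side = c("heavy", "light")) {
  side <- match.arg(side)
  p <- head[[side]]
  X <- if (is.matrix(x)) x else matrix(x, 1L)
  .mlp2_forward(X, p)$Z
}

#' Area under the ROC curve (pairwise concordance, tie-corrected)
#'
#' @param pos,neg score vectors for positives / negatives.
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(pos, neg) {
  fail_if(length(pos) == 0L || length(neg) == 0L,
          "need at least one score of each class")
  r <- rank(c(pos, neg))
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Area under the precision-recall curve (step integration)
#'
#' Thresholds sweep the distinct scores from high to low; the area is the sum
#' over recall increments of the precision at each threshold.
#'
#' @param pos,neg score vectors for positives / negatives.
#' @return auPRC in \[0, 1\].
#' @export
auprc <- function(pos, neg) {
  fail_if(length(pos) == 0L || length(neg) == 0L,
          "need at least one score of each class")
  scores <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- length(pos)
  area <- 0
  prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    prec <- tp / sum(sel)
    rec <- tp / np
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

#' Evaluate the pairing head with repeated negative resampling
#'
#' Per repeat: fresh identity-filtered negatives for every positive, all
#' pairs scored with [pairing_score()], auROC and auPRC computed; means over
#' repeats reported.
#'
#' @param head trained \code{abmlm_pairing_head}.
#' @param model frozen encoder.
#' @param pairs test positives.
#' @param light_pool pool for negatives.
#' @param n_repeats number of resampling repeats (default 5).
#' @param rng stream.
#' @return list with \code{auroc}, \code{auprc} (means), and per-repeat
#'   vectors.
#' @export
eval_pairing <- function(head, model, pairs, light_pool, n_repeats = 5L, rng = new_rng(1L)) {
  fail_if(length(pairs) == 0L, "no test pairs")
  Eh <- .pool_matrix(model, lapply(pairs, `[[`, "heavy"))
  El <- .pool_matrix(model, lapply(pairs, `[[`, "light"))
  Ep <- .pool_matrix(model, light_pool)
  elig <- .eligibility(pairs, light_pool, head$cfg$max_identity)
  Zh <- project_pairing(head, Eh, "heavy")
  Zl <- project_pairing(head, El, "light")
  Zp <- project_pairing(head, Ep, "light")
  n <- length(pairs)
  roc <- prc <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    pos_scores <- vapply(seq_len(n), function(i) pairing_score(Zh[i, ], Zl[i, ]),
                         numeric(1))
    neg_scores <- unlist(lapply(seq_len(n), function(i) {
      pool_i <- which(elig[i, ])
      fail_if(length(pool_i) < head$cfg$n_neg,
              "only %d eligible negatives for pair %d", length(pool_i), i)
      js <- with_rng(rng, sample(pool_i, head$cfg$n_neg))
      vapply(js, function(j) pairing_score(Zh[i, ], Zp[j, ]), numeric(1))
    }))
    fail_if(length(pos_scores) == 0L || length(neg_scores) == 0L,
            "a repeat produced a single class")
    roc[rep_i] <- auroc(pos_scores, neg_scores)
    prc[rep_i] <- auprc(pos_scores, neg_scores)
  }
  list(auroc = mean(roc), auprc = mean(prc),
       auroc_repeats = roc, auprc_repeats = prc)
}

# ---------------------------------------------------------------------------
# binding head

#' Binding-head configuration
#'
#' @param cdr3_max_len pad/crop length for the CDR3 window (default 20).
#' @param d_proj per-position projected dimension (default 16).
#' @param hidden classifier hidden width (default 32).
#' @param crop "warn" (default: crop long CDR3s with a warning) or "reject".
#' @param lr,epochs Adam learning rate and epochs.
#' @return object of class \code{abmlm_binding_config}.
#' @export
binding_config <- function(cdr3_max_len = 20L, d_proj = 16L, hidden = 32L,
                           crop = c("warn", "reject"), lr = 5e-3, epochs = 80L) {
  out <- list(cdr3_max_len = as.integer(cdr3_max_len), d_proj = as.integer(d_proj),
              hidden = as.integer(hidden), crop = match.arg(crop),
              lr = lr, epochs = as.integer(epochs))
  class(out) <- "abmlm_binding_config"
  out
}

# CDR3 hidden-state stack (cdr3_max_len x d, zero-padded) for one example
#' @noRd
.binding_features <- function(model, example, cfg) {
  ch <- example$chain
  tok <- tokenize(ch)
  idx <- region_token_indices(tok, "CDR3")
  fail_if(length(idx) == 0L, "example '%s' has an empty CDR3", ch$id)
  if (length(idx) > cfg$cdr3_max_len) {
    fail_if(cfg$crop == "reject", "CDR3 longer than cdr3_max_len (%d > %d)",
            length(idx), cfg$cdr3_max_len)
    abmlm_log("CDR3 cropped to cdr3_max_len", level = "WARN")
    idx <- idx[seq_len(cfg$cdr3_max_len)]
  }
  H <- encode(tok$token_ids, model$weights, model$cfg)
  S <- matrix(0, cfg$cdr3_max_len, model$cfg$d_model)
  S[seq_along(idx), ] <- H[idx, , drop = FALSE]
  list(stack = S, n_real = length(idx))
}

#' @noRd
.init_binding_params <- function(d_model, cfg, rng) {
  g <- function(nr, nc) with_rng(rng, matrix(stats::rnorm(nr * nc, sd = 0.05), nr, nc))
  Fdim <- cfg$cdr3_max_len * cfg$d_proj
  list(Wp = g(d_model, cfg$d_proj), bp = rep(0, cfg$d_proj),
       W1 = g(Fdim, cfg$hidden), b1 = rep(0, cfg$hidden),
       W2 = g(cfg$hidden, 2L), b2 = rep(0, 2L))
}

# forward from a feature stack; returns class probabilities + cache
#' @noRd
.binding_head_forward <- function(feat, params, cfg) {
  Z <- sweep(feat$stack %*% params$Wp, 2L, params$bp, "+")
  if (feat$n_real < cfg$cdr3_max_len) {
    Z[(feat$n_real + 1L):cfg$cdr3_max_len, ] <- 0   # zero-vector pad convention
  }
  fvec <- as.vector(t(Z))                            # position-major flatten
  H1pre <- as.vector(fvec %*% params$W1) + params$b1
  H1 <- pmax(H1pre, 0)
  logits <- as.vector(H1 %*% params$W2) + params$b2
  p <- softmax_vec(logits)
  list(p = p, logits = logits, H1 = H1, H1pre = H1pre, fvec = fvec, Z = Z)
}

#' Binding probability for one example under a frozen encoder
#'
#' @param model frozen \code{abmlm_model}.
#' @param example list with \code{chain} (annotated VH) and CDR3 interval.
#' @param head trained \code{abmlm_binding_head}.
#' @return probability that the antibody binds (label 1).
#' @export
binding_forward <- function(model, example, head) {
  feat <- .binding_features(model, example, head$cfg)
  .binding_head_forward(feat, head$params, head$cfg)$p[2L]
}

# stack a feature list into one (n * maxlen) x d matrix plus a pad-row mask
#' @noRd
.binding_stack <- function(feats, cfg) {
  BigS <- do.call(rbind, lapply(feats, `[[`, "stack"))
  real <- unlist(lapply(feats, function(f) {
    c(rep(TRUE, f$n_real), rep(FALSE, cfg$cdr3_max_len - f$n_real))
  }))
  list(S = BigS, real = real, n = length(feats))
}

# full-batch forward over a stacked feature set; returns n x 2 probabilities
#' @noRd
.binding_batch_forward <- function(st, params, cfg) {
  Z <- sweep(st$S %*% params$Wp, 2L, params$bp, "+")
  Z[!st$real, ] <- 0
  # per-example position-major flatten: row i = as.vector(t(Z_i))
  A <- array(t(Z), dim = c(cfg$d_proj, cfg$cdr3_max_len, st$n))
  Fmat <- t(matrix(A, cfg$d_proj * cfg$cdr3_max_len, st$n))
  H1pre <- sweep(Fmat %*% params$W1, 2L, params$b1, "+")
  H1 <- pmax(H1pre, 0)
  logits <- sweep(H1 %*% params$W2, 2L, params$b2, "+")
  P <- row_softmax(logits)
  list(P = P, H1 = H1, H1pre = H1pre, Fmat = Fmat)
}

# train the binding head on precomputed feature stacks; full-batch Adam with
# cross-entropy; best-on-validation epoch selection
#' @noRd
.train_binding_head <- function(feats, labels, d_model, cfg, rng,
                                val_feats = NULL, val_labels = NULL) {
  params <- .init_binding_params(d_model, cfg, rng)
  opt <- .adamw_init(params)
  adam_cfg <- list(beta1 = 0.9, beta2 = 0.999, weight_decay = 0)
  st <- .binding_stack(feats, cfg)
  st_val <- if (!is.null(val_feats)) .binding_stack(val_feats, cfg) else NULL
  n <- st$n
  y1 <- labels + 1L
  best <- list(acc = -1, params = params, epoch = 0L)
  for (ep in seq_len(cfg$epochs)) {
    fwd <- .binding_batch_forward(st, params, cfg)
    dlogits <- fwd$P
    dlogits[cbind(seq_len(n), y1)] <- dlogits[cbind(seq_len(n), y1)] - 1
    dlogits <- dlogits / n
    grads <- list(Wp = NULL, bp = NULL, W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)
    grads$W2 <- t(fwd$H1) %*% dlogits
    grads$b2 <- colSums(dlogits)
    dH1 <- (dlogits %*% t(params$W2)) * (fwd$H1pre > 0)
    grads$W1 <- t(fwd$Fmat) %*% dH1
    grads$b1 <- colSums(dH1)
    dF <- dH1 %*% t(params$W1)
    # reverse the flatten: dZ rows grouped per example, position-major
    A <- array(t(dF), dim = c(cfg$d_proj, cfg$cdr3_max_len * n))
    dZ <- t(matrix(A, cfg$d_proj, cfg$cdr3_max_len * n))
    dZ[!st$real, ] <- 0
    grads$Wp <- t(st$S) %*% dZ
    grads$bp <- colSums(dZ[st$real, , drop = FALSE])
    up <- .adamw_step(params, grads, opt, cfg$lr, adam_cfg)
    params <- up$weights
    opt <- up$state
    if (!is.null(st_val)) {
      pv <- .binding_batch_forward(st_val, params, cfg)$P[, 2L]
      acc <- mean((pv > 0.5) == (val_labels == 1L))
      if (acc > best$acc) best <- list(acc = acc, params = params, epoch = ep)
    } else {
      best <- list(acc = NA_real_, params = params, epoch = ep)
    }
  }
  best
}

#' Subsample a training set
#'
#' @param ids vector of indices or ids.
#' @param fraction sampling rate (e.g. 0.01).
#' @param rng stream.
#' @return \code{round(fraction * length(ids))} elements, sampled uniformly
#'   without replacement.
#' @export
subsample_training <- function(ids, fraction, rng) {
  fail_if(fraction <= 0 || fraction > 1, "fraction must be in (0, 1]")
  n <- round(fraction * length(ids))
  fail_if(n < 1L, "subsample rounds to zero examples")
  with_rng(rng, sample(ids, n))
}

#' Train and evaluate the binding head over repeated random splits
#'
#' Per seed: random train/validation/test split, optional training-set
#' subsampling (the low-data protocol: rate 0.01 on 15,000 training examples
#' gives exactly 150), full-batch training with cross-entropy, best-on-
#' validation epoch selection, and test scoring.  Splits lacking both classes
#' in training are resampled with the next seed.
#'
#' @param model frozen \code{abmlm_model}.
#' @param dataset list from [sample_binding_dataset()] (or equivalent).
#' @param head_cfg a [binding_config()].
#' @param n_splits number of repeated splits (default 5).
#' @param seed base seed; split s uses \code{derive_seed(seed, paste0("split", s))}.
#' @param subsample optional training-set sampling rate.
#' @param fractions train/val/test fractions (default 0.7/0.15/0.15).
#' @return list with mean \code{accuracy}, \code{recall}, \code{precision}
#'   on test (and \code{val_accuracy}), per-split data.frame \code{splits},
#'   and the last trained head (class \code{abmlm_binding_head}).
#' @export
train_eval_binding <- function(model, dataset, head_cfg = binding_config(),
                               n_splits = 5L, seed = 1L, subsample = NULL,
                               fractions = c(0.7, 0.15, 0.15)) {
  labels_all <- vapply(dataset, function(e) e$label, integer(1))
  feats_all <- lapply(dataset, .binding_features, model = model, cfg = head_cfg)
  hash_before <- object_hash(model$weights)
  n <- length(dataset)
  rows <- list()
  head_out <- NULL
  s <- 0L
  done <- 0L
  while (done < n_splits) {
    s <- s + 1L
    fail_if(s > n_splits + 20L, "too many degenerate splits; check the dataset")
    sp <- split_dataset(as.character(seq_len(n)), fractions,
                        seed = derive_seed(seed, paste0("split", s)))
    tr <- as.integer(sp$train_ids)
    if (!is.null(subsample)) {
      rng_sub <- new_rng(derive_seed(seed, paste0("subsample", s)))
      tr <- subsample_training(tr, subsample, rng_sub)
    }
    if (length(unique(labels_all[tr])) < 2L) {
      abmlm_log("training split lacks a class; resampling with next seed",
                level = "WARN")
      next
    }
    va <- as.integer(sp$val_ids)
    te <- as.integer(sp$test_ids)
    rng_init <- new_rng(derive_seed(seed, paste0("init", s)))
    best <- .train_binding_head(feats_all[tr], labels_all[tr], model$cfg$d_model,
                                head_cfg, rng_init,
                                val_feats = feats_all[va],
                                val_labels = labels_all[va])
    pt <- .binding_batch_forward(.binding_stack(feats_all[te], head_cfg),
                                 best$params, head_cfg)$P[, 2L]
    pred <- as.integer(pt > 0.5)
    truth <- labels_all[te]
    tp <- sum(pred == 1L & truth == 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      split = s, n_train = length(tr),
      val_accuracy = best$acc, best_epoch = best$epoch,
      accuracy = mean(pred == truth),
      recall = if (sum(truth == 1L) > 0) tp / sum(truth == 1L) else NA_real_,
      precision = if (sum(pred == 1L) > 0) tp / sum(pred == 1L) else NA_real_)
    head_out <- structure(list(params = best$params, cfg = head_cfg),
                          class = "abmlm_binding_head")
    done <- done + 1L
  }
  fail_if(object_hash(model$weights) != hash_before,
          "encoder parameters changed during head training (freeze contract)")
  splits <- do.call(rbind, rows)
  list(accuracy = mean(splits$accuracy), recall = mean(splits$recall),
       precision = mean(splits$precision),
       val_accuracy = mean(splits$val_accuracy),
       splits = splits, head = head_out)
}
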