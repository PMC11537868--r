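# MLM pre-training: truncation augmentation, label-smoothed cross-entropy,
# cosine warmup schedule, AdamW, and the training loop.

#' Training configuration
#'
#' The full-scale preset mirrors the published configuration (AdamW,
#' beta = (0.9, 0.99), weight decay 0.01, base LR 3e-4, batch 784, cosine
#' decay with 15 warmup epochs out of 200, label smoothing 0.1, random
#' truncation augmentation).  Desk defaults shrink batch and epochs only.
#'
#' @param base_lr peak learning rate (default 3e-4).
#' @param batch_size sequences per optimizer step (desk default 32;
#'   full-scale 784).
#' @param epochs training epochs (desk default 3; full-scale 200).
#' @param warmup_epochs linear warmup epochs (desk default 1; full-scale 15).
#' @param beta1,beta2 AdamW momentum coefficients (0.9, 0.99).
#' @param weight_decay decoupled weight decay on weight matrices (0.01).
#' @param label_smoothing cross-entropy smoothing mass (0.1).
#' @param grad_clip global gradient-norm clip (1.0; set Inf to disable).
#' @param augment apply random 0-3 residue terminal truncation.
#' @param seed global seed; fans out to independent data/mask/init streams.
#' @return object of class \code{abmlm_train_config}.
#' @export
train_config <- function(base_lr = 3e-4, batch_size = 32L, epochs = 3L,
                         warmup_epochs = 1L, beta1 = 0.9, beta2 = 0.99,
                         weight_decay = 0.01, label_smoothing = 0.1,
                         grad_clip = 1.0, augment = TRUE, seed = 1L) {
  fail_if(warmup_epochs >= epochs, "warmup_epochs must be < epochs")
  fail_if(label_smoothing < 0 || label_smoothing >= 1,
          "label_smoothing must be in [0, 1)")
  out <- list(base_lr = base_lr, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), warmup_epochs = as.integer(warmup_epochs),
              beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
              label_smoothing = label_smoothing, grad_clip = grad_clip,
              augment = isTRUE(augment), seed = as.integer(seed))
  class(out) <- "abmlm_train_config"
  out
}

#' Random terminal-truncation augmentation
#'
#' Removes n ~ Uniform\{0..3\} residues from the N-terminus and independently
#' m ~ Uniform\{0..3\} from the C-terminus; region intervals are shifted and
#' clipped.  If the truncation would empty a region that was non-empty, the
#' augmentation is skipped for that sample and the chain returned unchanged.
#'
#' @param chain an [annotated_chain()] of length > 8.
#' @param rng stream.
#' @return the augmented (or original) chain.
#' @export
truncation_augment <- function(chain, rng) {
  L <- nchar(chain$sequence)
  fail_if(L <= 8L, "sequence too short for truncation augmentation (L <= 8)")
  nm <- with_rng(rng, sample(0:3, 2L, replace = TRUE))
  n <- nm[1]; m <- nm[2]
  if (n == 0L && m == 0L) return(chain)
  newL <- L - n - m
  new_seq <- substr(chain$sequence, n + 1L, L - m)
  out <- chain
  out$sequence <- new_seq
  if (!is.null(chain$regions)) {
    r <- chain$regions
    ns <- pmin(pmax(r$start - n, 0L), newL)
    ne <- pmin(pmax(r$end - n, 0L), newL)
    was_nonempty <- r$end > r$start
    if (any(was_nonempty & (ne <= ns))) {
      abmlm_log("truncation would empty a region; augmentation skipped",
                level = "WARN")
      return(chain)
    }
    out$regions <- region_annotation(ns, ne)
  }
  out
}

#' Label-smoothed cross-entropy over selected positions
#'
#' Mean over non-ignored positions of \code{-sum_c q_c log p_c} with
#' \code{q = (1 - eps) * onehot + eps / V}.
#'
#' @param logits N x V score matrix.
#' @param labels integer vector of 0-based class ids, NA = ignore.
#' @param eps smoothing mass (default 0.1).
#' @param grad if TRUE also return \code{dlogits} (gradient of the mean loss;
#'   exactly zero at ignored positions).
#' @return list \code{(loss, n_labels)} plus \code{dlogits} when requested.
#' @export
label_smoothed_ce <- function(logits, labels, eps = 0.1, grad = FALSE) {
  sel <- which(!is.na(labels))
  fail_if(length(sel) == 0L, "all labels are ignored; nothing to score")
  V <- ncol(logits)
  lg <- logits[sel, , drop = FALSE]
  m <- apply(lg, 1L, max)
  lse <- m + log(rowSums(exp(lg - m)))
  logp <- lg - lse
  y1 <- labels[sel] + 1L
  true_logp <- logp[cbind(seq_along(sel), y1)]
  loss_rows <- -((1 - eps) * true_logp + (eps / V) * rowSums(logp))
  out <- list(loss = mean(loss_rows), n_labels = length(sel))
  if (grad) {
    p <- exp(logp)
    q <- matrix(eps / V, length(sel), V)
    q[cbind(seq_along(sel), y1)] <- q[cbind(seq_along(sel), y1)] + (1 - eps)
    dsel <- (p - q) / length(sel)
    dlogits <- matrix(0, nrow(logits), V)
    dlogits[sel, ] <- dsel
    out$dlogits <- dlogits
  }
  out
}

#' Cosine learning-rate schedule with linear warmup
#'
#' Linear 0 -> base_lr over the warmup steps, then
#' \code{base_lr * 0.5 * (1 + cos(pi * t))} where t runs over the remaining
#' steps; the floor is 0 at the final step.
#'
#' @param step global step (0 at the start of training).
#' @param steps_per_epoch optimizer steps per epoch.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
cosine_warmup_lr <- function(step, steps_per_epoch, cfg) {
  fail_if(step < 0, "step must be >= 0")
  ws <- cfg$warmup_epochs * steps_per_epoch
  total <- cfg$epochs * steps_per_epoch
  if (ws > 0 && step <= ws) return(cfg$base_lr * step / ws)
  t <- (step - ws) / (total - ws)
  cfg$base_lr * 0.5 * (1 + cos(pi * min(t, 1)))
}

# ---------------------------------------------------------------------------
# AdamW

#' @noRd
.adamw_init <- function(weights) {
  list(m = .zero_grads(weights), v = .zero_grads(weights), t = 0L)
}

# decoupled weight decay is applied to weight matrices only (embeddings and
# projections); biases and layer-norm vectors are not decayed
#' @noRd
.adamw_step <- function(weights, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + 1e-8)
    if (is.matrix(weights[[nm]])) {
      upd <- upd + cfg$weight_decay * weights[[nm]]
    }
    weights[[nm]] <- weights[[nm]] - lr * upd
  }
  list(weights = weights, state = state)
}

#' @noRd
.clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (total > max_norm) {
    s <- max_norm / total
    grads <- lapply(grads, function(g) g * s)
  }
  grads
}

# ---------------------------------------------------------------------------
# training loop

# mask plan dispatch for one chain
#' @noRd
.plan_for_chain <- function(tok, masking_cfg, rng) {
  if (tok$chain_type == "heavy" && any(tok$region_labels == "CDR3")) {
    mask_plan_heavy(tok, masking_cfg, rng)
  } else if (tok$chain_type == "heavy" && masking_cfg$strategy == "region_aware") {
    stop(sprintf("heavy chain '%s' lacks a CDR3 annotation required by the region-aware mask",
                 tok$id), call. = FALSE)
  } else {
    mask_plan_light(tok, masking_cfg, rng)
  }
}

#' Train a masked language model
#'
#' Per sequence: truncation augmentation, tokenization, mask-plan selection
#' (heavy-chain region-aware rule for annotated heavy chains, untargeted span
#' masking for light chains), corruption, forward, label-smoothed
#' cross-entropy over the selected positions only, and an AdamW update per
#' batch under the cosine-warmup schedule.  Three independent RNG streams
#' (data order + augmentation, mask sampling, weight init) are derived from
#' the global seed so ablations that differ only in masking strategy see the
#' same data order.
#'
#' @param corpus list of [annotated_chain()].
#' @param masking_cfg a [masking_config()].
#' @param encoder_cfg an [encoder_config()].
#' @param train_cfg a [train_config()].
#' @param out_dir optional run directory: per-epoch checkpoints and
#'   \code{metrics.jsonl} are written there.
#' @param resume_from optional checkpoint directory to resume from; the
#'   resumed run reproduces the uninterrupted run exactly at equal step
#'   counts.
#' @param init_weights optional pre-initialized weights (otherwise drawn from
#'   the init stream).
#' @return object of class \code{abmlm_model}: \code{weights}, \code{cfg}
#'   (the encoder config), \code{metrics} (one row per optimizer step),
#'   plus the train and masking configs.
#' @export
train_mlm <- function(corpus, masking_cfg, encoder_cfg, train_cfg,
                      out_dir = NULL, resume_from = NULL, init_weights = NULL) {
  fail_if(length(corpus) == 0L, "empty corpus")
  min_L <- min(vapply(corpus, function(ch) nchar(ch$sequence), integer(1)))
  fail_if(round(masking_cfg$total_rate * (min_L - 6L)) < 1L,
          "masking rate too low: no position would be selected on the shortest chain")
  if (masking_cfg$strategy == "region_aware") {
    for (ch in corpus) {
      if (ch$chain_type == "heavy") {
        fail_if(is.null(ch$regions),
                "heavy chain '%s' lacks region annotations required by the region-aware mask",
                ch$id)
      }
    }
  }

  streams <- rng_streams(train_cfg$seed, c("data", "mask", "init"))
  n <- length(corpus)
  steps_per_epoch <- ceiling(n / train_cfg$batch_size)
  opt <- NULL
  weights <- init_weights
  start_epoch <- 1L
  step <- 0L
  metrics <- list()

  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    weights <- ck$weights
    opt <- ck$opt
    step <- ck$meta$step
    start_epoch <- ck$meta$epoch + 1L
    streams <- list(data = rng_restore(ck$meta$rng_states$data),
                    mask = rng_restore(ck$meta$rng_states$mask),
                    init = rng_restore(ck$meta$rng_states$init))
  }
  if (is.null(weights)) weights <- init_encoder_weights(encoder_cfg, streams$init)
  if (is.null(opt)) opt <- .adamw_init(weights)

  metrics_path <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.path(out_dir, "metrics.jsonl")
  } else NULL

  for (epoch in start_epoch:train_cfg$epochs) {
    order_ <- with_rng(streams$data, sample.int(n))
    for (b in seq_len(steps_per_epoch)) {
      lo <- (b - 1L) * train_cfg$batch_size + 1L
      hi <- min(b * train_cfg$batch_size, n)
      idx <- order_[lo:hi]
      grads <- .zero_grads(weights)
      precomp <- rel_precompute(weights, encoder_cfg)
      batch_loss <- 0
      sel_frac <- 0
      for (i in idx) {
        ch <- corpus[[i]]
        if (train_cfg$augment && nchar(ch$sequence) > 8L) {
          ch <- truncation_augment(ch, streams$data)
        }
        tok <- tokenize(ch)
        plan <- .plan_for_chain(tok, masking_cfg, streams$mask)
        masked <- apply_mask(tok, plan, policy = masking_cfg$policy,
                             rng = streams$mask)
        r <- mlm_loss_and_grads(masked$input_ids, masked$labels, weights,
                                encoder_cfg,
                                label_smoothing = train_cfg$label_smoothing,
                                grads = grads, precomp = precomp,
                                finalize = FALSE)
        grads <- r$grads
        batch_loss <- batch_loss + r$loss
        sel_frac <- sel_frac + length(plan$selected) / length(residue_token_indices(tok))
      }
      nb <- length(idx)
      batch_loss <- batch_loss / nb
      if (!is.finite(batch_loss)) {
        stop(sprintf("non-finite loss at step %d (epoch %d, batch %d); aborting",
                     step + 1L, epoch, b), call. = FALSE)
      }
      grads <- .finalize_rel_grads(grads, weights, encoder_cfg)
      grads <- lapply(grads, function(g) g / nb)
      grads <- .clip_global_norm(grads, train_cfg$grad_clip)
      step <- step + 1L
      lr <- cosine_warmup_lr(step, steps_per_epoch, train_cfg)
      up <- .adamw_step(weights, grads, opt, lr, train_cfg)
      weights <- up$weights
      opt <- up$state
      row <- list(step = step, epoch = epoch, lr = lr, loss = batch_loss,
                  mask_rate = sel_frac / nb)
      metrics[[length(metrics) + 1L]] <- row
      if (!is.null(metrics_path)) {
        cat(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), "\n",
            sep = "", file = metrics_path, append = TRUE)
      }
    }
    if (!is.null(out_dir)) {
      ckdir <- file.path(out_dir, sprintf("checkpoint_epoch_%03d", epoch))
      save_checkpoint(weights, encoder_cfg, ckdir, seed = train_cfg$seed,
                      step = step, epoch = epoch, opt = opt,
                      rng_states = list(data = rng_state(streams$data),
                                        mask = rng_state(streams$mask),
                                        init = rng_state(streams$init)))
    }
  }

  out <- list(weights = weights, cfg = encoder_cfg,
              metrics = do.call(rbind, lapply(metrics, as.data.frame)),
              train_cfg = train_cfg, masking_cfg = masking_cfg)
  class(out) <- "abmlm_model"
  out
}

#' @export
print.abmlm_model <- function(x, ...) {
  cat(sprintf("<abmlm_model: %d layers, d=%d, %s positions, %d steps trained>\n",
              x$cfg$n_layers, x$cfg$d_model, x$cfg$position_mode,
              if (is.null(x$metrics)) 0L else nrow(x$metrics)))
  invisible(x)
}
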