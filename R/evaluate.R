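# Evaluation protocols: whole-region restoration under optional terminal
# truncation, top-k accuracy, and CDR-H3 amino-acid distribution comparison
# grouped by (family, CDR3 length).

#' Truncate a sequence by slice notation
#'
#' \code{"a:b"} keeps residues \code{[a, L+b)}: \code{a} is a non-negative
#' start, \code{b} a non-positive offset from the end (empty means the
#' sequence end), e.g. \code{"10:-5"} drops the first 10 and last 5 residues.
#' Region annotations are re-clipped to the kept window.
#'
#' @param chain an [annotated_chain()].
#' @param spec slice string.
#' @return the truncated chain.
#' @export
truncate_spec <- function(chain, spec) {
  s <- .parse_slice(spec)
  L <- nchar(chain$sequence)
  start <- s$start
  end <- L + s$end
  fail_if(end <= start, "slice '%s' empties a length-%d sequence", spec, L)
  out <- chain
  out$sequence <- substr(chain$sequence, start + 1L, end)
  if (!is.null(chain$regions)) {
    r <- chain$regions
    newL <- end - start
    ns <- pmin(pmax(r$start - start, 0L), newL)
    ne <- pmin(pmax(r$end - start, 0L), newL)
    out$regions <- region_annotation(ns, ne)
  }
  out
}

#' @noRd
.parse_slice <- function(spec) {
  fail_if(!grepl("^\\d+:(-\\d+)?$", spec),
          "cannot parse slice '%s' (expected forms like '10:-5' or '0:')", spec)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  start <- as.integer(parts[1])
  end <- if (length(parts) < 2L || !nzchar(parts[2])) 0L else as.integer(parts[2])
  fail_if(end > 0L, "slice end must be <= 0 (counts from the sequence end)")
  list(start = start, end = end)
}

#' Mask whole regions and predict the hidden residues
#'
#' Every token of each requested region is replaced by [MASK]; the model's
#' ranked residue predictions (canonical residues only, ties broken by
#' alphabet order) are returned per masked position.
#'
#' @param model an \code{abmlm_model} (or list with \code{weights},
#'   \code{cfg}).
#' @param chain annotated chain.
#' @param regions character vector of region names to mask.
#' @param truncation optional slice string applied before masking.
#' @param topk how many ranked predictions to keep per position (default 3).
#' @return list with \code{pred} (n_masked x topk matrix of residue letters),
#'   \code{truth} (character vector), \code{region} (per-position region
#'   name).
#' @export
mask_region_predict <- function(model, chain, regions, truncation = NULL,
                                topk = 3L) {
  alphabet <- residue_alphabet()
  if (!is.null(truncation) && truncation != "none") {
    chain <- truncate_spec(chain, truncation)
  }
  tok <- tokenize(chain)
  idx <- integer(0)
  for (rg in regions) {
    ri <- region_token_indices(tok, rg)
    fail_if(length(ri) == 0L,
            "region %s is empty (possibly removed by truncation '%s')",
            rg, if (is.null(truncation)) "none" else truncation)
    idx <- c(idx, ri)
  }
  idx <- sort(idx)
  input_ids <- tok$token_ids
  input_ids[idx] <- alphabet$mask_id
  H <- encode(input_ids, model$weights, model$cfg)
  logits <- mlm_logits(H, model$weights)
  res_cols <- alphabet$residue_ids + 1L
  lg <- logits[idx, res_cols, drop = FALSE]
  pred_flat <- vapply(seq_along(idx), function(i) {
    AA_CANONICAL[order(-lg[i, ], seq_len(ncol(lg)))][seq_len(topk)]
  }, character(topk))
  pred <- if (topk == 1L) matrix(pred_flat, ncol = 1L) else t(pred_flat)
  list(pred = pred,
       truth = AA_CANONICAL[match(tok$token_ids[idx], alphabet$residue_ids)],
       region = tok$region_labels[idx])
}

#' Top-k restoration accuracy
#'
#' @param pred n x k matrix of ranked predictions (letters), best first.
#' @param truth character vector of true residues (length n).
#' @param k cutoff (>= 1).
#' @return fraction of positions whose true residue is among the k best.
#' @export
topk_accuracy <- function(pred, truth, k) {
  fail_if(k < 1L, "k must be >= 1")
  fail_if(nrow(pred) != length(truth), "predictions and truth disagree in length")
  k <- min(k, ncol(pred))
  hits <- vapply(seq_along(truth),
                 function(i) truth[i] %in% pred[i, seq_len(k)], logical(1))
  mean(hits)
}

#' Region-restoration report
#'
#' Mean top-k accuracy over a dataset for every combination of truncation
#' protocol and masked region set.  The default truncation grid is
#' none, 10:-5, 10:-10, 20:-5.
#'
#' @param model an \code{abmlm_model}.
#' @param chains list of annotated chains.
#' @param region_sets list of character vectors (each a set of regions masked
#'   jointly); default: each of the seven regions singly.
#' @param truncations character vector of slice protocols ("none" = identity).
#' @param topk integer vector of cutoffs (default c(1, 3)).
#' @return data.frame: truncation, regions, k, accuracy, n_positions.
#' @export
restoration_report <- function(model, chains,
                               region_sets = as.list(REGION_NAMES),
                               truncations = c("none", "10:-5", "10:-10", "20:-5"),
                               topk = c(1L, 3L)) {
  rows <- list()
  for (tr in truncations) {
    for (rs in region_sets) {
      hits <- stats::setNames(rep(0, length(topk)), topk)
      npos <- 0L
      for (ch in chains) {
        mp <- mask_region_predict(model, ch, rs, truncation = tr,
                                  topk = max(topk))
        n <- length(mp$truth)
        npos <- npos + n
        for (kk in seq_along(topk)) {
          hits[kk] <- hits[kk] + topk_accuracy(mp$pred, mp$truth, topk[kk]) * n
        }
      }
      for (kk in seq_along(topk)) {
        rows[[length(rows) + 1L]] <-
          data.frame(truncation = tr, regions = paste(rs, collapse = "+"),
                     k = topk[kk], accuracy = hits[kk] / npos,
                     n_positions = npos, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jensen-Shannon divergence (natural log)
#'
#' \code{JSD(p, q) = KL(p||m)/2 + KL(q||m)/2} with \code{m = (p+q)/2};
#' bounded by \code{ln 2}.
#'
#' @param p,q probability vectors on the same support (each sums to 1).
#' @return divergence in nats.
#' @export
js_divergence <- function(p, q) {
  fail_if(any(p < 0) || any(q < 0), "distributions must be non-negative")
  fail_if(length(p) != length(q), "p and q must share a support")
  fail_if(abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6,
          "distributions must each sum to 1")
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' CDR-H3 amino-acid distribution by (family, CDR3 length) group
#'
#' Pools residues over all CDR3 positions within each group and compares the
#' true composition with the model's top-1 reconstruction of a fully masked
#' CDR3.  Groups with fewer than \code{min_positions} pooled positions are
#' excluded.
#'
#' @param chains annotated heavy chains carrying a \code{family} label.
#' @param model optional \code{abmlm_model}; when NULL only the true
#'   distributions are computed.
#' @param min_positions exclusion threshold (default 10).
#' @return data.frame with one row per group: family, cdr3_len, n_positions,
#'   jsd (NA without a model), and the two frequency vectors in list columns
#'   \code{truth} and \code{predicted}.
#' @export
cdr3_distribution <- function(chains, model = NULL, min_positions = 10L) {
  fams <- vapply(chains, function(ch) ch$family, integer(1))
  lens <- vapply(chains, function(ch) {
    r <- ch$regions
    r$end[["CDR3"]] - r$start[["CDR3"]]
  }, integer(1))
  key <- paste(fams, lens, sep = "_")
  rows <- list()
  for (g in unique(key)) {
    members <- chains[key == g]
    truth_res <- unlist(lapply(members, function(ch) {
      r <- ch$regions
      strsplit(substr(ch$sequence, r$start[["CDR3"]] + 1L, r$end[["CDR3"]]), "")[[1]]
    }))
    if (length(truth_res) < min_positions) {
      abmlm_log(sprintf("group %s has %d CDR3 positions (<%d); excluded",
                        g, length(truth_res), min_positions), level = "WARN")
      next
    }
    count_freq <- function(res) {
      tab <- table(factor(res, levels = AA_CANONICAL))
      as.numeric(tab) / sum(tab)
    }
    truth <- count_freq(truth_res)
    predicted <- rep(NA_real_, 20L)
    jsd <- NA_real_
    if (!is.null(model)) {
      pred_res <- unlist(lapply(members, function(ch) {
        mask_region_predict(model, ch, "CDR3", topk = 1L)$pred[, 1L]
      }))
      predicted <- count_freq(pred_res)
      jsd <- js_divergence(truth, predicted)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(family = members[[1]]$family,
                 cdr3_len = lens[key == g][1],
                 n_positions = length(truth_res), jsd = jsd,
                 truth = I(list(truth)), predicted = I(list(predicted)),
                 stringsAsFactors = FALSE)
  }
  fail_if(length(rows) == 0L, "no group meets the minimum position count")
  do.call(rbind, rows)
}
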