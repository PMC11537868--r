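# Masking curricula for the MLM objective.
#
# The region-aware heavy-chain rule first selects round(0.70 * |CDR3|)
# positions inside CDR-H3 (a contiguous span with a uniform random offset by
# default), then span-masks the remaining regions until the total budget
# round(total_rate * L) is met.  Light chains get span masking over the whole
# residue range.  A uniform-random baseline and the classic BERT 80/10/10
# replacement policy are available for the 15%-rate ablation.
#
# All budgets are computed over residue tokens only; [CLS]/[SEP] are never
# selected.  round() is base R's round-half-to-even.

#' Masking configuration
#'
#' @param total_rate total fraction of residue tokens to select (the studied
#'   grid is 0.15/0.30/0.50/0.70/0.90; default 0.70).
#' @param cdr3_internal_rate fraction of CDR-H3 selected in step 1 of the
#'   heavy-chain rule (default 0.70).
#' @param cdr3_mode "contiguous_span" (default; one block with random offset)
#'   or "random_subset" (scattered positions).
#' @param span_mean mean of the geometric span-length law (default 3).
#' @param span_cap maximum span length (default 10).
#' @param policy "ALL_MASK" (every selected token becomes [MASK]; the
#'   high-rate default) or "BERT_80_10_10" (80% [MASK], 10% random residue,
#'   10% kept; the classic 15% setting).
#' @param strategy "region_aware" (CDR-H3-targeted rule for heavy chains) or
#'   "uniform_random" (the * baseline: plain random selection, no targeting).
#' @return object of class \code{abmlm_masking_config}.
#' @export
masking_config <- function(total_rate = 0.70, cdr3_internal_rate = 0.70,
                           cdr3_mode = c("contiguous_span", "random_subset"),
                           span_mean = 3, span_cap = 10L,
                           policy = c("ALL_MASK", "BERT_80_10_10"),
                           strategy = c("region_aware", "uniform_random")) {
  fail_if(total_rate <= 0 || total_rate > 1, "total_rate must be in (0, 1]")
  fail_if(cdr3_internal_rate <= 0 || cdr3_internal_rate > 1,
          "cdr3_internal_rate must be in (0, 1]")
  fail_if(span_cap < 1L, "span_cap must be >= 1")
  fail_if(span_mean < 1, "span_mean must be >= 1")
  out <- list(total_rate = total_rate,
              cdr3_internal_rate = cdr3_internal_rate,
              cdr3_mode = match.arg(cdr3_mode),
              span_mean = span_mean,
              span_cap = as.integer(span_cap),
              policy = match.arg(policy),
              strategy = match.arg(strategy))
  class(out) <- "abmlm_masking_config"
  out
}

#' Uniform random selection of maskable positions
#'
#' @param eligible integer vector of candidate token element indices.
#' @param rate selection fraction.
#' @param rng stream from [new_rng()].
#' @return integer vector of exactly \code{round(rate * length(eligible))}
#'   indices (sorted).
#' @export
select_random <- function(eligible, rate, rng) {
  fail_if(length(eligible) == 0L, "eligible set is empty")
  n <- round(rate * length(eligible))
  if (n == 0L) {
    abmlm_log("selection rounds to zero positions", level = "WARN")
    return(integer(0))
  }
  sort(with_rng(rng, sample(eligible, n)))
}

#' Span-based selection until a budget is met
#'
#' Repeatedly draws a run with probability proportional to its number of
#' still-unselected positions, a start uniform among those positions, and a
#' span length from a geometric law (1 + Geom(1/mean), capped), clipped to
#' the run end and to the remaining budget.  Stops when exactly \code{budget}
#' positions are selected; no position is selected twice.
#'
#' @param eligible_runs list of integer vectors, each a maximal contiguous run
#'   of token element indices.
#' @param budget number of positions to select.
#' @param cfg a [masking_config()].
#' @param rng stream.
#' @return sorted integer vector of selected indices.
#' @export
select_spans <- function(eligible_runs, budget, cfg, rng) {
  fail_if(budget < 0, "budget must be >= 0")
  budget <- as.integer(budget)
  if (budget == 0L) return(integer(0))
  avail <- unlist(eligible_runs, use.names = FALSE)
  if (budget >= length(avail)) {
    if (budget > length(avail)) {
      abmlm_log("span budget exceeds available positions; selecting all",
                level = "WARN")
    }
    return(sort(avail))
  }
  unsel <- lapply(eligible_runs, function(r) sort(as.integer(r)))
  p_geom <- 1 / cfg$span_mean
  selected <- with_rng(rng, {
    sel <- integer(0)
    while (length(sel) < budget) {
      counts <- vapply(unsel, length, integer(1))
      run_i <- sample.int(length(unsel), 1L, prob = counts)
      run <- unsel[[run_i]]
      start_pos <- run[sample.int(length(run), 1L)]
      len <- min(1L + stats::rgeom(1L, p_geom), cfg$span_cap)
      len <- min(len, budget - length(sel))
      # walk right from the start over contiguous token indices, taking the
      # still-unselected ones
      span <- start_pos:(start_pos + len - 1L)
      take <- intersect(span, run)
      take <- take[seq_len(min(length(take), budget - length(sel)))]
      sel <- c(sel, take)
      unsel[[run_i]] <- setdiff(run, take)
      unsel <- Filter(length, unsel)
    }
    sel
  })
  sort(selected)
}

# maximal contiguous runs of a sorted integer vector
#' @noRd
.contiguous_runs <- function(idx) {
  if (length(idx) == 0L) return(list())
  idx <- sort(idx)
  brk <- c(0L, which(diff(idx) != 1L), length(idx))
  lapply(seq_len(length(brk) - 1L), function(i) idx[(brk[i] + 1L):brk[i + 1L]])
}

#' Heavy-chain region-aware mask plan
#'
#' Step 1 selects \code{round(cdr3_internal_rate * |CDR3|)} positions inside
#' CDR-H3 (one contiguous block with uniform random offset, or a random
#' subset under \code{cdr3_mode = "random_subset"}).  Step 2 span-masks the
#' non-CDR3 residues with budget \code{round(total_rate * L) - |step 1|}; a
#' non-positive step-2 budget means step 1 already exceeds the total rate and
#' step 2 is skipped.
#'
#' @param tok tokenized heavy chain with a non-empty CDR3 annotation.
#' @param cfg a [masking_config()].
#' @param rng stream.
#' @return object of class \code{abmlm_mask_plan}: \code{selected} (sorted
#'   token element indices), \code{labels} (original 0-based ids at those
#'   positions), \code{n_cdr3} (step-1 count).
#' @export
mask_plan_heavy <- function(tok, cfg, rng) {
  cdr3 <- region_token_indices(tok, "CDR3")
  fail_if(length(cdr3) == 0L,
          paste0("chain '%s' has no CDR3 annotation; use mask_plan_light() ",
                 "or the uniform_random strategy"), tok$id)
  res_idx <- residue_token_indices(tok)
  L <- length(res_idx)

  if (cfg$strategy == "uniform_random") {
    sel <- select_random(res_idx, cfg$total_rate, rng)
    return(.mask_plan(tok, sel, n_cdr3 = length(intersect(sel, cdr3))))
  }

  n1 <- round(cfg$cdr3_internal_rate * length(cdr3))
  sel1 <- if (n1 == 0L) {
    integer(0)
  } else if (cfg$cdr3_mode == "contiguous_span") {
    off <- with_rng(rng, sample.int(length(cdr3) - n1 + 1L, 1L)) - 1L
    cdr3[(off + 1L):(off + n1)]
  } else {
    sort(with_rng(rng, sample(cdr3, n1)))
  }
  total_budget <- round(cfg$total_rate * L)
  budget2 <- total_budget - length(sel1)
  sel2 <- integer(0)
  if (budget2 > 0L) {
    runs <- .contiguous_runs(setdiff(res_idx, cdr3))
    sel2 <- select_spans(runs, budget2, cfg, rng)
  } else if (budget2 < 0L) {
    abmlm_log("CDR3 step exceeds the total budget; skipping span step",
              level = "WARN")
  }
  .mask_plan(tok, sort(c(sel1, sel2)), n_cdr3 = length(sel1))
}

#' Light-chain mask plan (untargeted span masking)
#'
#' @inheritParams mask_plan_heavy
#' @return an \code{abmlm_mask_plan}.
#' @export
mask_plan_light <- function(tok, cfg, rng) {
  res_idx <- residue_token_indices(tok)
  if (cfg$strategy == "uniform_random") {
    return(.mask_plan(tok, select_random(res_idx, cfg$total_rate, rng), 0L))
  }
  budget <- round(cfg$total_rate * length(res_idx))
  sel <- select_spans(.contiguous_runs(res_idx), budget, cfg, rng)
  .mask_plan(tok, sel, n_cdr3 = 0L)
}

#' @noRd
.mask_plan <- function(tok, selected, n_cdr3) {
  fail_if(any(tok$region_labels[selected] == "special"),
          "mask plan selected a special token (invariant breach)")
  out <- list(selected = as.integer(selected),
              labels = tok$token_ids[selected],
              n_cdr3 = as.integer(n_cdr3))
  class(out) <- "abmlm_mask_plan"
  out
}

#' Apply a mask plan to token ids
#'
#' Under ALL_MASK every selected token becomes [MASK].  Under BERT_80_10_10
#' each selected token independently becomes [MASK] (p=0.8), a uniformly
#' random canonical residue (p=0.1), or stays unchanged (p=0.1).  Labels
#' carry the original 0-based id at selected positions and NA elsewhere.
#'
#' @param tok tokenized sequence.
#' @param plan an \code{abmlm_mask_plan}.
#' @param policy overrides the policy (default: take it from \code{cfg}).
#' @param rng stream (used by the BERT policy only).
#' @param alphabet residue alphabet.
#' @return list with \code{input_ids} (corrupted 0-based ids), \code{labels}
#'   (integer with NA ignore marker), \code{actions} (per selected position).
#' @export
apply_mask <- function(tok, plan, policy = "ALL_MASK", rng = NULL,
                       alphabet = residue_alphabet()) {
  n <- length(tok$token_ids)
  fail_if(length(plan$selected) > 0L &&
            (min(plan$selected) < 1L || max(plan$selected) > n),
          "mask plan indices out of bounds")
  fail_if(any(tok$region_labels[plan$selected] == "special"),
          "mask plan selected a special token (invariant breach)")
  input_ids <- tok$token_ids
  labels <- rep(NA_integer_, n)
  labels[plan$selected] <- tok$token_ids[plan$selected]
  k <- length(plan$selected)
  if (k == 0L) {
    return(list(input_ids = input_ids, labels = labels, actions = character(0)))
  }
  if (policy == "ALL_MASK") {
    actions <- rep("mask", k)
    input_ids[plan$selected] <- alphabet$mask_id
  } else if (policy == "BERT_80_10_10") {
    fail_if(is.null(rng), "BERT_80_10_10 policy needs an rng stream")
    u <- with_rng(rng, stats::runif(k))
    actions <- ifelse(u < 0.8, "mask", ifelse(u < 0.9, "random_replace", "keep"))
    input_ids[plan$selected[actions == "mask"]] <- alphabet$mask_id
    n_rep <- sum(actions == "random_replace")
    if (n_rep > 0L) {
      input_ids[plan$selected[actions == "random_replace"]] <-
        with_rng(rng, sample(alphabet$residue_ids, n_rep, replace = TRUE))
    }
  } else {
    stop(sprintf("unknown replacement policy '%s'", policy), call. = FALSE)
  }
  list(input_ids = input_ids, labels = labels, actions = actions)
}

#' Realized masking-rate statistics over a corpus
#'
#' @param chains list of annotated chains.
#' @param cfg a [masking_config()].
#' @param rng stream.
#' @return data.frame with one row per chain: chain id, chain type, residue
#'   count, total selected, realized total rate, CDR3 length, CDR3 selected,
#'   realized CDR3 rate.
#' @export
mask_stats <- function(chains, cfg, rng) {
  rows <- lapply(chains, function(ch) {
    tok <- tokenize(ch)
    heavy <- ch$chain_type == "heavy" && !is.null(ch$regions)
    plan <- if (heavy) mask_plan_heavy(tok, cfg, rng) else mask_plan_light(tok, cfg, rng)
    res_n <- length(residue_token_indices(tok))
    cdr3 <- if (heavy) region_token_indices(tok, "CDR3") else integer(0)
    cdr3_sel <- length(intersect(plan$selected, cdr3))
    data.frame(id = ch$id, chain_type = ch$chain_type,
               n_residues = res_n, n_selected = length(plan$selected),
               total_rate = length(plan$selected) / res_n,
               cdr3_len = length(cdr3), cdr3_selected = cdr3_sel,
               cdr3_rate = if (length(cdr3)) cdr3_sel / length(cdr3) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
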