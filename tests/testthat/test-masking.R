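# Masking curricula: selection counts, span replay, the heavy-chain rule's
# budget arithmetic, and replacement policies.

test_that("select_random draws exactly round(rate * n) without replacement", {
  rng <- new_rng(3)
  sel <- select_random(1:100, 0.15, rng)
  expect_length(sel, 15L)
  expect_identical(anyDuplicated(sel), 0L)
  expect_length(select_random(1:37, 1.0, new_rng(1)), 37L)
  # determinism
  expect_identical(select_random(1:100, 0.3, new_rng(11)),
                   select_random(1:100, 0.3, new_rng(11)))
  # rounding to zero yields an empty selection
  expect_length(select_random(1:3, 0.1, new_rng(1)), 0L)
})

test_that("select_spans meets the budget exactly and replays deterministically", {
  cfg <- masking_config()
  expect_length(select_spans(list(1:20), 0L, cfg, new_rng(1)), 0L)
  expect_identical(select_spans(list(1:20), 20L, cfg, new_rng(1)), 1:20)
  s1 <- select_spans(list(1:20), 5L, cfg, new_rng(9))
  s2 <- select_spans(list(1:20), 5L, cfg, new_rng(9))
  expect_identical(s1, s2)
  expect_length(s1, 5L)
  expect_true(all(s1 %in% 1:20))
  # multiple runs, budget spanning them
  runs <- list(2:10, 15:40, 50:52)
  s3 <- select_spans(runs, 12L, cfg, new_rng(2))
  expect_length(s3, 12L)
  expect_true(all(s3 %in% unlist(runs)))
  expect_identical(anyDuplicated(s3), 0L)
})

test_that("heavy-chain rule follows the stated budget arithmetic", {
  rng <- new_rng(21)
  # L=120 residues, |CDR3|=10, total 0.70 -> 7 CDR3 + 77 others = 84
  lens <- c(25, 8, 17, 8, 41, 10, 11)  # sums to 120
  ends <- cumsum(lens)
  ch <- annotated_chain("a", rand_seq(120, rng), "heavy",
                        regions = region_annotation(ends - lens, ends))
  plan <- mask_plan_heavy(tokenize(ch), masking_config(total_rate = 0.70), rng)
  expect_identical(plan$n_cdr3, 7L)
  expect_length(plan$selected, 84L)

  # L=120, |CDR3|=20, total 0.15 -> 14 CDR3 + 4 span = 18
  lens2 <- c(25, 8, 17, 8, 31, 20, 11)
  ends2 <- cumsum(lens2)
  ch2 <- annotated_chain("b", rand_seq(120, rng), "heavy",
                         regions = region_annotation(ends2 - lens2, ends2))
  plan2 <- mask_plan_heavy(tokenize(ch2), masking_config(total_rate = 0.15), rng)
  expect_identical(plan2$n_cdr3, 14L)
  expect_length(plan2$selected, 18L)

  # L=30, |CDR3|=20: step-1 already exceeds round(0.15*30)=4 -> 14 selected
  lens3 <- c(2, 1, 2, 1, 2, 20, 2)
  ends3 <- cumsum(lens3)
  ch3 <- annotated_chain("c", rand_seq(30, rng), "heavy",
                         regions = region_annotation(ends3 - lens3, ends3))
  plan3 <- mask_plan_heavy(tokenize(ch3), masking_config(total_rate = 0.15), rng)
  expect_length(plan3$selected, 14L)
})

test_that("heavy rule rejects chains without CDR3 and light rule needs none", {
  rng <- new_rng(4)
  light <- annotated_chain("l", rand_seq(110, rng), "light")
  tokl <- tokenize(light)
  expect_error(mask_plan_heavy(tokl, masking_config(), rng), "CDR3")
  plan <- mask_plan_light(tokl, masking_config(total_rate = 0.70), rng)
  expect_length(plan$selected, 77L)
  plan_all <- mask_plan_light(tokl, masking_config(total_rate = 1.0), rng)
  expect_length(plan_all$selected, 110L)
  # fixed-seed reproducibility
  expect_identical(mask_plan_light(tokl, masking_config(), new_rng(8))$selected,
                   mask_plan_light(tokl, masking_config(), new_rng(8))$selected)
})

test_that("selection fraction is exact and specials are never selected (property)", {
  rng <- new_rng(55)
  cfgs <- list(masking_config(0.15), masking_config(0.30), masking_config(0.50),
               masking_config(0.70), masking_config(0.90),
               masking_config(0.70, cdr3_mode = "random_subset"),
               masking_config(0.50, strategy = "uniform_random"))
  for (i in 1:30) {
    ch <- rand_heavy(rng, id = paste0("p", i))
    tok <- tokenize(ch)
    L <- length(residue_token_indices(tok))
    cdr3_len <- length(region_token_indices(tok, "CDR3"))
    cfg <- cfgs[[(i %% length(cfgs)) + 1L]]
    plan <- mask_plan_heavy(tok, cfg, rng)
    expect_false(any(tok$region_labels[plan$selected] == "special"))
    expected_total <- max(round(cfg$total_rate * L),
                          if (cfg$strategy == "region_aware")
                            round(cfg$cdr3_internal_rate * cdr3_len) else 0L)
    expect_length(plan$selected, expected_total)
    if (cfg$strategy == "region_aware") {
      cdr3_sel <- length(intersect(plan$selected, region_token_indices(tok, "CDR3")))
      expect_gte(cdr3_sel, round(cfg$cdr3_internal_rate * cdr3_len))
    }
  }
})

test_that("apply_mask implements ALL_MASK and BERT 80/10/10", {
  rng <- new_rng(31)
  ab <- residue_alphabet()
  ch <- rand_heavy(rng, cdr3_len = 12)
  tok <- tokenize(ch)
  plan <- mask_plan_heavy(tok, masking_config(), rng)
  out <- apply_mask(tok, plan, policy = "ALL_MASK")
  expect_identical(sum(out$input_ids == ab$mask_id), length(plan$selected))
  expect_identical(which(!is.na(out$labels)), plan$selected)
  expect_identical(out$labels[plan$selected], tok$token_ids[plan$selected])

  # empty plan: corrupted == input, all labels ignored
  empty_plan <- structure(list(selected = integer(0), labels = integer(0),
                               n_cdr3 = 0L), class = "abmlm_mask_plan")
  out0 <- apply_mask(tok, empty_plan)
  expect_identical(out0$input_ids, tok$token_ids)
  expect_true(all(is.na(out0$labels)))

  # BERT policy action frequencies over many selections
  big <- annotated_chain("big", rand_seq(1250, rng), "light")
  tokb <- tokenize(big)
  planb <- mask_plan_light(tokb, masking_config(total_rate = 0.8,
                                                strategy = "uniform_random"), rng)
  outb <- apply_mask(tokb, planb, policy = "BERT_80_10_10", rng = rng)
  counts <- table(factor(outb$actions, levels = c("mask", "random_replace", "keep")))
  n <- length(planb$selected)
  expect_gt(counts[["mask"]], 0.8 * n - 4 * sqrt(n * 0.16))
  expect_lt(counts[["mask"]], 0.8 * n + 4 * sqrt(n * 0.16))
  expect_gt(counts[["random_replace"]], 0.1 * n - 4 * sqrt(n * 0.09))
  expect_lt(counts[["random_replace"]], 0.1 * n + 4 * sqrt(n * 0.09))
  # kept tokens unchanged
  keep_idx <- planb$selected[outb$actions == "keep"]
  expect_identical(outb$input_ids[keep_idx], tokb$token_ids[keep_idx])
})

test_that("mask_stats reports realized per-chain rates", {
  rng <- new_rng(6)
  chains <- lapply(1:5, function(i) rand_heavy(rng, id = paste0("m", i)))
  st <- mask_stats(chains, masking_config(), rng)
  expect_identical(nrow(st), 5L)
  expect_true(all(abs(st$total_rate - 0.7) < 0.01))
  expect_true(all(st$cdr3_rate >= 0.6 & st$cdr3_rate <= 0.8))
})
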