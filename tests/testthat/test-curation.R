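# Identity metric, greedy clustering, two-stage curation, dataset splitting.

test_that("pairwise_identity matches hand-derived global-alignment values", {
  expect_equal(pairwise_identity("QVQLVQSGAE", "QVQLVQSGAE"), 1.0)
  # equal lengths, one mismatch: 9 matched columns of 10
  expect_equal(pairwise_identity("QVQLVQSGAE", "QVQLVQSGAD"), 0.9)
  # one terminal gap: 3 matches over 4 alignment columns
  expect_equal(pairwise_identity("QVQ", "QVQL"), 0.75)
  expect_equal(pairwise_identity("QVQL", "QVQ"), 0.75)  # symmetry
  expect_error(pairwise_identity("", "QVQ"), "non-empty")
})

test_that("pairwise_identity agrees with the Biostrings alignment engine", {
  # independent oracle: Biostrings global alignment under the same scoring
  oracle <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = abmlm:::.identity_submat(),
      gapOpening = 0, gapExtension = 1, type = "global")
    c(score = Biostrings::score(aln),
      id = Biostrings::nmatch(aln) /
        nchar(as.character(Biostrings::alignedPattern(aln))))
  }
  rng <- new_rng(77)
  for (trial in 1:15) {
    la <- with_rng(rng, sample(5:40, 1)); lb <- with_rng(rng, sample(5:40, 1))
    a <- rand_seq(la, rng)
    b <- if (trial %% 2 == 0) {
      # related pair: mutate a few positions of a
      v <- strsplit(a, "")[[1]]
      p <- with_rng(rng, sample(la, min(3, la)))
      v[p] <- with_rng(rng, sample(AA_CANONICAL, length(p), replace = TRUE))
      paste(v, collapse = "")
    } else {
      rand_seq(lb, rng)
    }
    o <- oracle(a, b)
    expect_equal(pairwise_identity(a, b), unname(o["id"]), tolerance = 1e-9)
  }
})

test_that("greedy_cluster reproduces the hand-computed identity matrix case", {
  chains <- list(annotated_chain("A", "QVQLVQSGAE", "heavy"),
                 annotated_chain("B", "QVQLVQSGAD", "heavy"),
                 annotated_chain("C", "DIQMTQSPSS", "heavy"))
  cl <- greedy_cluster(chains, 0.8)
  expect_length(cl, 2L)
  sets <- lapply(cl, function(x) sort(x$member_ids))
  expect_true(any(vapply(sets, identical, logical(1), c("A", "B"))))
  expect_true(any(vapply(sets, identical, logical(1), "C")))
})

test_that("greedy_cluster trivial cases", {
  one <- greedy_cluster(list(annotated_chain("A", "QVQLV", "heavy")), 0.8)
  expect_length(one, 1L)
  expect_identical(one[[1]]$representative_id, "A")

  rng <- new_rng(5)
  distinct <- lapply(1:4, function(i) annotated_chain(paste0("s", i), rand_seq(12, rng), "heavy"))
  expect_length(greedy_cluster(distinct, 1.0), 4L)
  expect_error(greedy_cluster(distinct, 0), "threshold")
})

test_that("greedy_cluster agrees with an exhaustive oracle on random sets", {
  # oracle: all-pairs identity matrix + the same deterministic greedy rule,
  # coded independently of the package's single-pass implementation
  oracle_cluster <- function(seqs, ids, threshold) {
    M <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(i, j) pairwise_identity(seqs[i], seqs[j])))
    ord <- order(-nchar(seqs), seqs, seq_along(seqs))
    reps <- integer(0); assign_ <- integer(length(seqs))
    for (i in ord) {
      hit <- 0L
      for (r in reps) if (M[i, r] >= threshold) { hit <- r; break }
      if (hit == 0L) { reps <- c(reps, i); assign_[i] <- i } else assign_[i] <- hit
    }
    split(ids, assign_[seq_along(ids)])
  }
  rng <- new_rng(99)
  for (trial in 1:3) {
    n <- 30L
    # half the pool derived from two base sequences to force real clusters
    base1 <- rand_seq(20, rng); base2 <- rand_seq(14, rng)
    seqs <- character(n)
    for (i in seq_len(n)) {
      u <- with_rng(rng, stats::runif(1))
      seqs[i] <- if (u < 0.4) {
        v <- strsplit(base1, "")[[1]]
        p <- with_rng(rng, sample(20, 2))
        v[p] <- with_rng(rng, sample(AA_CANONICAL, 2, replace = TRUE))
        paste(v, collapse = "")
      } else if (u < 0.7) {
        v <- strsplit(base2, "")[[1]]
        p <- with_rng(rng, sample(14, 1))
        v[p] <- with_rng(rng, sample(AA_CANONICAL, 1))
        paste(v, collapse = "")
      } else {
        rand_seq(with_rng(rng, sample(10:20, 1)), rng)
      }
    }
    ids <- sprintf("s%02d", seq_len(n))
    chains <- lapply(seq_len(n), function(i) annotated_chain(ids[i], seqs[i], "heavy"))
    got <- greedy_cluster(chains, 0.8)
    got_sets <- sort(vapply(got, function(cl) paste(sort(cl$member_ids), collapse = ","),
                            character(1)))
    want <- oracle_cluster(seqs, ids, 0.8)
    want_sets <- sort(unname(vapply(want, function(m) paste(sort(m), collapse = ","),
                                    character(1))))
    expect_identical(got_sets, want_sets)
  }
})

test_that("curate follows the two-stage keep-longest rule", {
  # in-spec toy set: id(A,B)=0.9 >= 0.8 so {A,B} multi-member at stage 1;
  # C is a stage-1 singleton and stays one at stage 2 -> discarded
  chains <- list(annotated_chain("A", "QVQLVQSGAE", "heavy"),
                 annotated_chain("B", "QVQLVQSGAD", "heavy"),
                 annotated_chain("C", "DIQMTQSPSS", "heavy"))
  res <- curate(chains, 0.8, 0.5)
  expect_length(res$kept_ids, 1L)
  expect_true(res$kept_ids %in% c("A", "B"))

  # single input sequence stays a singleton at both stages -> empty output
  expect_length(curate(list(annotated_chain("A", "QVQLVQSGAE", "heavy")))$kept, 0L)

  # two identical sequences form one cluster -> one representative kept
  two <- list(annotated_chain("A", "QVQLVQSGAE", "heavy"),
              annotated_chain("B", "QVQLVQSGAE", "heavy"))
  expect_length(curate(two)$kept_ids, 1L)
})

test_that("curate output is a subset of input with one representative per cluster", {
  rng <- new_rng(17)
  base <- rand_seq(16, rng)
  chains <- lapply(1:12, function(i) {
    v <- strsplit(base, "")[[1]]
    p <- with_rng(rng, sample(16, sample(0:3, 1)))
    if (length(p)) v[p] <- with_rng(rng, sample(AA_CANONICAL, length(p), replace = TRUE))
    annotated_chain(sprintf("c%02d", i), paste(v, collapse = ""), "heavy")
  })
  res <- curate(chains, 0.8, 0.5)
  ids <- vapply(chains, function(ch) ch$id, character(1))
  expect_true(all(res$kept_ids %in% ids))
  # no two kept representatives from the same stage-1 multi-member cluster
  cl1 <- res$clusters[res$clusters$stage == 1L, ]
  counts <- table(cl1$cluster_id[cl1$member_id %in% res$kept_ids])
  multi <- names(which(table(cl1$cluster_id) > 1L))
  expect_true(all(counts[names(counts) %in% multi] <= 1L))
})

test_that("split_dataset is deterministic, size-exact, and validates fractions", {
  ids <- sprintf("id%02d", 1:10)
  sp <- split_dataset(ids, c(0.8, 0.1, 0.1), seed = 7L)
  expect_identical(lengths(sp[1:3]), c(train_ids = 8L, val_ids = 1L, test_ids = 1L))
  expect_setequal(c(sp$train_ids, sp$val_ids, sp$test_ids), ids)
  sp2 <- split_dataset(ids, c(0.8, 0.1, 0.1), seed = 7L)
  expect_identical(sp, sp2)
  expect_error(split_dataset(ids, c(0.5, 0.5, 0.5)), "summing to 1")
})
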