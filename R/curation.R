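# Identity-based redundancy reduction: pairwise identity, deterministic greedy
# clustering, the two-stage curation rule (cluster at 80% identity, keep the
# longest member of multi-member clusters, re-cluster the singletons at 50%
# and keep once more), and seeded dataset splitting.
#
# The identity metric is a global (Needleman-Wunsch) alignment with unit
# match, zero mismatch, and linear gap penalty 1, scored as
# matches / alignment columns.  Biostrings supplies the alignment engine.

# substitution matrix: +1 match, 0 mismatch over the canonical alphabet
# (used when cross-checking against the Biostrings alignment engine)
#' @noRd
.identity_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      n <- length(AA_CANONICAL)
      m <- matrix(0, n, n, dimnames = list(AA_CANONICAL, AA_CANONICAL))
      diag(m) <- 1
      cache <<- m
    }
    cache
  }
})

#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment with unit match, zero mismatch, and
#' linear gap penalty of one score unit; identity is the number of matched
#' columns divided by the total number of alignment columns (gaps included).
#' Symmetric, 1 iff the sequences are equal.  The DP fills anti-diagonals
#' (vectorized); the traceback breaks score ties deterministically
#' (diagonal, then up, then left).  The test suite cross-checks the result
#' against Biostrings::pairwiseAlignment under the same scoring.
#'
#' @param a,b non-empty amino-acid strings.
#' @return identity fraction in \[0, 1\].
#' @examples
#' pairwise_identity("QVQ", "QVQL")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  fail_if(!nzchar(a) || !nzchar(b), "sequences must be non-empty")
  if (a == b) return(1.0)
  x <- utf8ToInt(a); y <- utf8ToInt(b)
  n <- length(x); m <- length(y)
  eq <- outer(x, y, "==") * 1
  F <- matrix(0, n + 1L, m + 1L)
  F[, 1L] <- -(0:n)
  F[1L, ] <- -(0:m)
  for (k in 2L:(n + m)) {
    i <- max(1L, k - m):min(n, k - 1L)   # residue cells with i + j = k
    j <- k - i
    F[cbind(i + 1L, j + 1L)] <- pmax(F[cbind(i, j)] + eq[cbind(i, j)],
                                     F[cbind(i, j + 1L)] - 1,
                                     F[cbind(i + 1L, j)] - 1)
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L && F[i + 1L, j + 1L] == F[i, j] + eq[i, j]) {
      matches <- matches + (eq[i, j] == 1)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && F[i + 1L, j + 1L] == F[i, j + 1L] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  matches / cols
}

#' Deterministic greedy clustering at an identity threshold
#'
#' Sequences are visited in order of decreasing length, ties broken
#' lexicographically by sequence and then by input order.  Each sequence
#' joins the first existing cluster whose representative it matches at
#' \code{>= threshold}, otherwise it founds a new cluster with itself as the
#' representative.  Because visiting order is longest-first, representatives
#' are always at least as long as their members.
#'
#' @param chains list of [annotated_chain()] (or plain named character vector
#'   of sequences).
#' @param threshold identity threshold in (0, 1].
#' @return list of clusters, each \code{list(representative_id, member_ids,
#'   threshold)}.
#' @export
greedy_cluster <- function(chains, threshold) {
  fail_if(threshold <= 0 || threshold > 1, "threshold must be in (0, 1]")
  if (is.character(chains)) {
    ids <- names(chains)
    if (is.null(ids)) ids <- as.character(seq_along(chains))
    seqs <- unname(chains)
  } else {
    ids <- vapply(chains, function(ch) ch$id, character(1))
    seqs <- vapply(chains, function(ch) ch$sequence, character(1))
  }
  ord <- order(-nchar(seqs), seqs, seq_along(seqs))
  reps <- integer(0)              # indices (into input) of representatives
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (cl in seq_along(reps)) {
      if (pairwise_identity(seqs[i], seqs[reps[cl]]) >= threshold) {
        members[[cl]] <- c(members[[cl]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      members[[length(reps)]] <- i
    }
  }
  lapply(seq_along(reps), function(cl) {
    list(representative_id = ids[reps[cl]],
         member_ids = ids[members[[cl]]],
         threshold = threshold)
  })
}

# longest member of a cluster; ties broken lexicographically by sequence,
# then by position in member order
#' @noRd
.longest_member <- function(member_ids, seq_by_id) {
  s <- seq_by_id[member_ids]
  member_ids[order(-nchar(s), s, seq_along(s))[1]]
}

#' Two-stage identity curation
#'
#' Stage 1 clusters at \code{t1}; from every multi-member cluster the longest
#' member is kept.  Stage 2 re-clusters all stage-1 singletons at \code{t2}
#' and again keeps the longest member of multi-member clusters.  Sequences
#' that remain singletons after stage 2 are discarded.
#'
#' @param chains list of [annotated_chain()].
#' @param t1 stage-1 identity threshold (default 0.80).
#' @param t2 stage-2 identity threshold (default 0.50).
#' @return list with \code{kept} (the retained chains), \code{kept_ids}, and
#'   \code{clusters} (a data.frame: cluster_id, representative_id, member_id,
#'   stage).
#' @export
curate <- function(chains, t1 = 0.80, t2 = 0.50) {
  ids <- vapply(chains, function(ch) ch$id, character(1))
  seq_by_id <- stats::setNames(vapply(chains, function(ch) ch$sequence, character(1)), ids)
  chain_by_id <- stats::setNames(chains, ids)

  stage1 <- greedy_cluster(chains, t1)
  multi1 <- Filter(function(cl) length(cl$member_ids) > 1L, stage1)
  single1 <- Filter(function(cl) length(cl$member_ids) == 1L, stage1)
  kept_ids <- vapply(multi1, function(cl) .longest_member(cl$member_ids, seq_by_id),
                     character(1))

  singleton_ids <- vapply(single1, function(cl) cl$member_ids, character(1))
  stage2 <- list()
  if (length(singleton_ids) > 0L) {
    stage2 <- greedy_cluster(chain_by_id[singleton_ids], t2)
    multi2 <- Filter(function(cl) length(cl$member_ids) > 1L, stage2)
    kept_ids <- c(kept_ids,
                  vapply(multi2, function(cl) .longest_member(cl$member_ids, seq_by_id),
                         character(1)))
  }

  tab <- function(cls, stage) {
    if (length(cls) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(cls), function(i) {
      data.frame(cluster_id = sprintf("s%d_c%03d", stage, i),
                 representative_id = cls[[i]]$representative_id,
                 member_id = cls[[i]]$member_ids,
                 stage = stage,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  clusters <- rbind(tab(stage1, 1L), tab(stage2, 2L))
  list(kept = unname(chain_by_id[kept_ids]),
       kept_ids = unname(kept_ids),
       clusters = clusters)
}

#' Seeded random split into train/validation/test
#'
#' Partition sizes are \code{floor(frac * n)} with leftovers assigned one per
#' set in order, so each size differs from the exact fraction by less than
#' one item.
#'
#' @param ids character vector of ids.
#' @param fractions numeric length-3 vector summing to 1.
#' @param seed integer seed.
#' @return list with \code{train_ids}, \code{val_ids}, \code{test_ids},
#'   \code{seed}.
#' @export
split_dataset <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  fail_if(length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9,
          "fractions must be three numbers summing to 1")
  rng <- new_rng(derive_seed(seed, "split"))
  perm <- with_rng(rng, sample(ids))
  n <- length(ids)
  sizes <- floor(fractions * n)
  left <- n - sum(sizes)
  if (left > 0L) {
    for (i in seq_len(left)) sizes[i] <- sizes[i] + 1L
  }
  cuts <- cumsum(sizes)
  list(train_ids = perm[seq_len(sizes[1])],
       val_ids = if (sizes[2] > 0) perm[(cuts[1] + 1):cuts[2]] else character(0),
       test_ids = if (sizes[3] > 0) perm[(cuts[2] + 1):cuts[3]] else character(0),
       seed = as.integer(seed))
}
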