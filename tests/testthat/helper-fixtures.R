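# Shared fixtures, all built in code at test time.

# a hand-annotated heavy chain with simple region arithmetic:
# FR1 [0,25) CDR1 [25,33) FR2 [33,50) CDR2 [50,58) FR3 [58,96) CDR3 [96,107)
# FR4 [107,118)  => L = 118
make_test_heavy <- function(id = "h1") {
  seg <- function(letter, n) paste(rep(letter, n), collapse = "")
  seq_ <- paste0(seg("Q", 25), seg("A", 8), seg("V", 17), seg("S", 8),
                 seg("G", 38), seg("Y", 11), seg("W", 11))
  annotated_chain(id, seq_, "heavy",
                  regions = region_annotation(
                    starts = c(0, 25, 33, 50, 58, 96, 107),
                    ends   = c(25, 33, 50, 58, 96, 107, 118)))
}

# random canonical sequence of length n
rand_seq <- function(n, rng) {
  paste(with_rng(rng, sample(AA_CANONICAL, n, replace = TRUE)), collapse = "")
}

# a random annotated heavy chain with plausible region proportions
rand_heavy <- function(rng, id = "rh", cdr3_len = NULL) {
  if (is.null(cdr3_len)) cdr3_len <- with_rng(rng, sample(8:20, 1))
  lens <- c(25, 8, 17, 8, 38, cdr3_len, 11)
  ends <- cumsum(lens)
  annotated_chain(id, rand_seq(sum(lens), rng), "heavy",
                  regions = region_annotation(ends - lens, ends))
}

# small grammar/encoder presets shared across tests
tiny_grammar <- function(seed = 42L) build_grammar(grammar_config(seed = seed))

tiny_encoder_cfg <- function(...) {
  encoder_config(n_layers = 1L, d_model = 16L, n_heads = 2L, d_ff = 32L,
                 k_max = 8L, ...)
}

# session-level cache so expensive artifacts (the trained desk encoder) are
# built once per test run
.abmlm_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.abmlm_test_cache[[key]])) {
    .abmlm_test_cache[[key]] <- builder()
  }
  .abmlm_test_cache[[key]]
}
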