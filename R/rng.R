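# Named deterministic random-number streams.
#
# Every stochastic operation in the package takes an explicit stream object so
# that a single global seed fans out to independent, named sub-streams (data
# order, mask sampling, weight init, ...).  Adding a stream never perturbs the
# draws of an existing one because each stream's seed is derived from
# (global seed, stream name) alone.

#' Derive a child seed from a parent seed and a stream name
#'
#' Deterministic fold of the stream name's UTF-8 bytes into the parent seed,
#' modulo 2^31 - 1 so the result is always a valid 32-bit R integer.
#'
#' @param seed integer parent seed.
#' @param name character stream name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, name) {
  fail_if(!is.numeric(seed) || length(seed) != 1L, "seed must be a single number")
  s <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(name)) {
    s <- (s * 33 + b) %% 2147483647
  }
  as.integer(s)
}

#' Create a random-number stream
#'
#' A stream is an environment carrying its own copy of R's RNG state
#' (Mersenne-Twister).  Use [with_rng()] to draw from it; the global
#' \code{.Random.seed} is saved and restored around each use, so streams never
#' interfere with each other or with user code.
#'
#' @param seed integer seed for the stream.
#' @return an object of class \code{abmlm_rng}.
#' @export
new_rng <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  e$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "abmlm_rng"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' @param rng stream created by [new_rng()].
#' @param expr expression drawing random numbers.
#' @return the value of \code{expr}; the stream's state is advanced.
#' @export
with_rng <- function(rng, expr) {
  fail_if(!inherits(rng, "abmlm_rng"), "rng must be created by new_rng()")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  expr
}

#' Fan a global seed out to named streams
#'
#' @param seed integer global seed.
#' @param names character vector of stream names.
#' @return named list of \code{abmlm_rng} streams.
#' @export
rng_streams <- function(seed, names) {
  out <- lapply(names, function(nm) new_rng(derive_seed(seed, nm)))
  names(out) <- names
  out
}

# Snapshot / restore of a stream's internal state (for checkpoint resume).
#' @noRd
rng_state <- function(rng) as.integer(rng$state)

#' @noRd
rng_restore <- function(state) {
  e <- new.env(parent = emptyenv())
  e$state <- as.integer(state)
  class(e) <- "abmlm_rng"
  e
}
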