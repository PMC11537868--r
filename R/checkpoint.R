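# Checkpoint format: a directory with
#   meta.json    - format version, encoder config, vocabulary, seed, step,
#                  epoch, RNG stream states, and the parameter index
#                  (name, dimensions, offset into params.bin)
#   params.bin   - all parameters as little-endian doubles, concatenated in
#                  index order (column-major within each array)
#   opt.bin      - optional AdamW state (first moments then second moments,
#                  same layout as params.bin)
#
# save -> load -> save is byte-identical.

CHECKPOINT_FORMAT_VERSION <- 1L

#' Save an encoder checkpoint
#'
#' @param weights weight list.
#' @param cfg the [encoder_config()] the weights belong to.
#' @param dir output directory (created).
#' @param seed,step,epoch provenance fields stored in meta.json.
#' @param opt optional AdamW state (from the training loop).
#' @param rng_states optional named list of RNG stream states.
#' @return \code{dir}, invisibly.
#' @export
save_checkpoint <- function(weights, cfg, dir, seed = NA_integer_, step = 0L,
                            epoch = 0L, opt = NULL, rng_states = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- names(weights)
  index <- lapply(nms, function(nm) {
    p <- weights[[nm]]
    list(name = nm,
         dim = if (is.matrix(p)) dim(p) else length(p),
         length = length(p))
  })
  flat <- unlist(lapply(nms, function(nm) as.double(weights[[nm]])),
                 use.names = FALSE)
  con <- file(file.path(dir, "params.bin"), "wb")
  writeBin(flat, con, size = 8L, endian = "little")
  close(con)
  if (!is.null(opt)) {
    flat_opt <- c(unlist(lapply(nms, function(nm) as.double(opt$m[[nm]])),
                         use.names = FALSE),
                  unlist(lapply(nms, function(nm) as.double(opt$v[[nm]])),
                         use.names = FALSE))
    con <- file(file.path(dir, "opt.bin"), "wb")
    writeBin(flat_opt, con, size = 8L, endian = "little")
    close(con)
  }
  meta <- list(format_version = CHECKPOINT_FORMAT_VERSION,
               config = unclass(cfg),
               vocabulary = residue_alphabet()$tokens,
               seed = seed, step = step, epoch = epoch,
               opt_t = if (is.null(opt)) NULL else opt$t,
               rng_states = rng_states,
               params = index)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' Load an encoder checkpoint
#'
#' Rejects checkpoints whose stored vocabulary disagrees with the package's
#' alphabet (id stability contract).
#'
#' @param dir checkpoint directory.
#' @return list with \code{weights}, \code{cfg}, \code{meta}, and \code{opt}
#'   (NULL if absent).
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"), simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  fail_if(meta$format_version != CHECKPOINT_FORMAT_VERSION,
          "unsupported checkpoint format version %s", meta$format_version)
  fail_if(!identical(unlist(meta$vocabulary), residue_alphabet()$tokens),
          "checkpoint vocabulary differs from the package alphabet")
  cfg <- meta$config
  class(cfg) <- "abmlm_encoder_config"
  total <- sum(vapply(meta$params, function(p) p$length, numeric(1)))
  con <- file(file.path(dir, "params.bin"), "rb")
  flat <- readBin(con, "double", n = total, size = 8L, endian = "little")
  close(con)
  weights <- .unflatten(flat, meta$params)
  class(weights) <- "abmlm_weights"
  opt <- NULL
  opt_path <- file.path(dir, "opt.bin")
  if (file.exists(opt_path)) {
    con <- file(opt_path, "rb")
    flat_opt <- readBin(con, "double", n = 2L * total, size = 8L, endian = "little")
    close(con)
    opt <- list(m = .unflatten(flat_opt[seq_len(total)], meta$params),
                v = .unflatten(flat_opt[total + seq_len(total)], meta$params),
                t = as.integer(meta$opt_t))
  }
  list(weights = weights, cfg = cfg, meta = meta, opt = opt)
}

#' @noRd
.unflatten <- function(flat, index) {
  out <- list()
  off <- 0L
  for (p in index) {
    vals <- flat[(off + 1L):(off + p$length)]
    dm <- unlist(p$dim)
    out[[p$name]] <- if (length(dm) == 2L) matrix(vals, dm[1], dm[2]) else vals
    off <- off + p$length
  }
  out
}
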