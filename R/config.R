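# Run configuration: one nested JSON document covering every module, with
# strict unknown-key rejection and defaults taken from the module
# constructors.  (JSON rather than YAML: the deployment environment ships no
# R YAML parser, and jsonlite round-trips losslessly.)

#' Default run configuration
#'
#' @return nested list (class \code{abmlm_run_config}) with sections
#'   \code{grammar}, \code{masking}, \code{model}, \code{train},
#'   \code{heads} (\code{pairing}/\code{binding}), \code{eval}, plus global
#'   \code{seed}, \code{out}, \code{log_level}.
#' @export
default_run_config <- function() {
  strip <- function(x) unclass(x)
  out <- list(
    seed = 1L,
    out = "runs/run1",
    log_level = "INFO",
    grammar = strip(grammar_config()),
    masking = strip(masking_config()),
    model = strip(encoder_config()),
    train = strip(train_config()),
    heads = list(pairing = strip(pairing_config()),
                 binding = strip(binding_config())),
    eval = list(truncations = c("none", "10:-5", "10:-10", "20:-5"),
                regions = REGION_NAMES,
                topk = c(1L, 3L))
  )
  # d_k is derived, not a free key
  out$model$d_k <- NULL
  class(out) <- "abmlm_run_config"
  out
}

#' @noRd
.merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(defaults)) {
      stop(sprintf("unknown configuration key '%s'", key), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      fail_if(!is.list(user[[nm]]), "configuration key '%s' must be a section", key)
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]], key)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Parse a run configuration file
#'
#' Reads JSON, overlays it on the defaults, rejects unknown keys (naming the
#' key path), and validates every section by constructing the typed module
#' configs.  An empty file yields all defaults.
#'
#' @param path JSON file.
#' @return validated \code{abmlm_run_config}.
#' @export
parse_config <- function(path) {
  fail_if(!file.exists(path), "config file '%s' does not exist", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list() else {
    jsonlite::fromJSON(txt, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  cfg <- .merge_config(unclass(default_run_config()), user)
  # validation through the typed constructors
  resolve_configs(cfg)
  class(cfg) <- "abmlm_run_config"
  cfg
}

#' Materialize the typed module configs from a run configuration
#'
#' @param cfg an \code{abmlm_run_config} (or plain nested list).
#' @return list with \code{grammar}, \code{masking}, \code{model},
#'   \code{train}, \code{pairing}, \code{binding}, \code{eval}, \code{seed}.
#' @export
resolve_configs <- function(cfg) {
  cfg <- unclass(cfg)
  tr <- cfg$train
  tr$seed <- cfg$seed
  list(grammar = do.call(grammar_config, cfg$grammar),
       masking = do.call(masking_config, cfg$masking),
       model = do.call(encoder_config, cfg$model),
       train = do.call(train_config, tr),
       pairing = do.call(pairing_config, cfg$heads$pairing),
       binding = do.call(binding_config, cfg$heads$binding),
       eval = cfg$eval,
       seed = cfg$seed)
}

#' Write a run configuration to JSON
#'
#' \code{parse_config(write_config(cfg, path))} reproduces \code{cfg}.
#'
#' @param cfg an \code{abmlm_run_config}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             path)
  invisible(path)
}
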