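# Annotated antibody chains: the seven-region Fv partition, tokenization, and
# plain-text I/O (FASTA for sequences, TSV for region intervals).
#
# Coordinate convention: region intervals are 0-based, half-open [start, end)
# in residue coordinates, everywhere in the package and in the TSV format.
# Token vectors are ordinary R vectors (1-based element access); the [CLS]
# token sits at element 1, residue r (0-based residue coordinate) at element
# r + 2.  region_token_indices() is the single place where residue
# coordinates are converted to token element indices.

#' Region names of an Fv variable domain, in sequence order
#' @export
REGION_NAMES <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")

#' Construct a region annotation
#'
#' @param starts,ends integer vectors of length 7 giving 0-based half-open
#'   intervals for FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4 (in that order).
#' @return object of class \code{abmlm_regions}.
#' @export
region_annotation <- function(starts, ends) {
  fail_if(length(starts) != 7L || length(ends) != 7L,
          "region annotation needs exactly 7 start/end pairs")
  out <- list(start = stats::setNames(as.integer(starts), REGION_NAMES),
              end = stats::setNames(as.integer(ends), REGION_NAMES))
  class(out) <- "abmlm_regions"
  out
}

#' Construct an annotated chain
#'
#' @param id chain identifier.
#' @param sequence amino-acid string over the 20 canonical residues.
#' @param chain_type "heavy" or "light".
#' @param regions optional [region_annotation()]; required for heavy chains
#'   used with the region-targeted masking rule.
#' @param family optional integer family label (synthetic stand-in for the
#'   IGHV/IGLV germline gene family).
#' @return object of class \code{abmlm_chain}.
#' @export
annotated_chain <- function(id, sequence, chain_type = c("heavy", "light"),
                            regions = NULL, family = NA_integer_) {
  chain_type <- match.arg(chain_type)
  fail_if(!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L,
          "sequence must be a single non-empty string")
  out <- list(id = as.character(id), sequence = sequence, chain_type = chain_type,
              regions = regions, family = as.integer(family))
  class(out) <- "abmlm_chain"
  out
}

#' @export
print.abmlm_chain <- function(x, ...) {
  cat(sprintf("<abmlm_chain %s (%s), L=%d%s>\n", x$id, x$chain_type,
              nchar(x$sequence),
              if (is.null(x$regions)) ", unannotated" else ""))
  invisible(x)
}

#' Check a chain's region annotation against its invariants
#'
#' Reports (never throws).  The invariants: the seven intervals are in order,
#' contiguous, non-overlapping, and cover \code{[0, L)} exactly; on heavy
#' chains every CDR interval is non-empty.
#'
#' @param chain an [annotated_chain()].
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_annotation <- function(chain) {
  v <- character(0)
  L <- nchar(chain$sequence)
  bad <- !strsplit(chain$sequence, "")[[1]] %in% AA_CANONICAL
  if (any(bad)) {
    v <- c(v, sprintf("non-canonical residue at position %d",
                      which(bad)[1] - 1L))
  }
  r <- chain$regions
  if (is.null(r)) {
    return(c(v, "missing region annotation"))
  }
  if (r$start[["FR1"]] != 0L) {
    v <- c(v, sprintf("FR1 must start at 0, starts at %d", r$start[["FR1"]]))
  }
  for (i in seq_len(6L)) {
    a <- REGION_NAMES[i]; b <- REGION_NAMES[i + 1L]
    if (r$end[[a]] != r$start[[b]]) {
      v <- c(v, sprintf("gap or overlap between %s (ends %d) and %s (starts %d)",
                        a, r$end[[a]], b, r$start[[b]]))
    }
  }
  if (r$end[["FR4"]] != L) {
    v <- c(v, sprintf("FR4 must end at sequence length %d, ends at %d",
                      L, r$end[["FR4"]]))
  }
  for (nm in REGION_NAMES) {
    if (r$end[[nm]] < r$start[[nm]]) {
      v <- c(v, sprintf("%s has negative length", nm))
    }
  }
  if (chain$chain_type == "heavy") {
    for (nm in c("CDR1", "CDR2", "CDR3")) {
      if (r$end[[nm]] <= r$start[[nm]]) {
        v <- c(v, sprintf("%s is empty on a heavy chain", nm))
      }
    }
  }
  v
}

#' Tokenize an annotated chain
#'
#' Frames the residue sequence with [CLS] and [SEP].  Chain type is metadata
#' only and never enters the token ids; no chain-type marker token exists in
#' the vocabulary.
#'
#' @param chain an [annotated_chain()].
#' @param alphabet alphabet from [residue_alphabet()].
#' @param allow_unknown if TRUE, non-canonical residues map to [UNK]
#'   (inference-time convenience); the default FALSE rejects them, which is
#'   the required behaviour for training data.
#' @return object of class \code{abmlm_tokens}: \code{token_ids} (0-based
#'   integer ids, length L + 2), \code{region_labels} (per-token region name
#'   or "special"), \code{residue_offset} (always 1), plus chain metadata.
#' @export
tokenize <- function(chain, alphabet = residue_alphabet(), allow_unknown = FALSE) {
  letters_ <- strsplit(chain$sequence, "")[[1]]
  fail_if(length(letters_) == 0L, "cannot tokenize an empty sequence")
  ids <- alphabet$id_of[letters_]
  if (anyNA(ids)) {
    if (!allow_unknown) {
      pos <- which(is.na(ids))[1]
      stop(sprintf("non-canonical residue '%s' at position %d of '%s'",
                   letters_[pos], pos - 1L, chain$id), call. = FALSE)
    }
    ids[is.na(ids)] <- alphabet$unk_id
  }
  token_ids <- c(alphabet$cls_id, unname(ids), alphabet$sep_id)
  labels <- rep("special", length(token_ids))
  if (!is.null(chain$regions)) {
    r <- chain$regions
    for (nm in REGION_NAMES) {
      if (r$end[[nm]] > r$start[[nm]]) {
        labels[(r$start[[nm]] + 2L):(r$end[[nm]] + 1L)] <- nm
      }
    }
  } else {
    labels[seq_along(letters_) + 1L] <- "residue"
  }
  out <- list(token_ids = as.integer(token_ids),
              region_labels = labels,
              residue_offset = 1L,
              id = chain$id,
              chain_type = chain$chain_type,
              family = chain$family)
  class(out) <- "abmlm_tokens"
  out
}

#' Recover the residue string from a tokenized sequence
#'
#' @param tok an \code{abmlm_tokens} object (or a bare 0-based id vector).
#' @param alphabet alphabet from [residue_alphabet()].
#' @return the amino-acid string.
#' @export
detokenize <- function(tok, alphabet = residue_alphabet()) {
  ids <- if (inherits(tok, "abmlm_tokens")) tok$token_ids else as.integer(tok)
  fail_if(length(ids) < 2L, "token vector too short to contain [CLS]/[SEP]")
  inner <- ids[-c(1L, length(ids))]
  paste0(tokens_of(inner, alphabet), collapse = "")
}

#' Element indices of a region's tokens
#'
#' Converts a region's residue interval into indices into the token vector
#' (R 1-based element positions; [CLS] occupies element 1, so residue
#' coordinate r maps to element r + 2).  Special tokens are never included.
#'
#' @param tok an \code{abmlm_tokens} with region labels.
#' @param region one of FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4.
#' @return integer vector of token element indices (possibly empty).
#' @export
region_token_indices <- function(tok, region) {
  fail_if(!region %in% REGION_NAMES,
          "unknown region '%s' (expected one of %s)", region,
          paste(REGION_NAMES, collapse = ", "))
  which(tok$region_labels == region)
}

#' Indices of all residue tokens (everything but [CLS]/[SEP]/pad)
#' @param tok an \code{abmlm_tokens}.
#' @return integer vector of token element indices.
#' @export
residue_token_indices <- function(tok) {
  which(tok$region_labels != "special")
}

# ---------------------------------------------------------------------------
# I/O

#' Read antibody chains from FASTA
#'
#' The description line carries the id and an optional \code{chain=H|L}
#' key=value tag; chains without the tag default to heavy.
#'
#' @param path FASTA file.
#' @return list of [annotated_chain()] (regions unset; see
#'   [read_regions_tsv()] / [attach_regions()]).
#' @export
read_chain_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    desc <- names(ss)[i]
    parts <- strsplit(desc, "\\s+")[[1]]
    id <- parts[1]
    ctype <- "heavy"
    fam <- NA_integer_
    for (p in parts[-1]) {
      if (grepl("^chain=", p)) {
        ctype <- if (toupper(sub("^chain=", "", p)) == "L") "light" else "heavy"
      }
      if (grepl("^family=", p)) fam <- as.integer(sub("^family=", "", p))
    }
    out[[i]] <- annotated_chain(id, as.character(ss[[i]]), ctype, family = fam)
  }
  out
}

#' Write antibody chains to FASTA
#'
#' @param chains list of [annotated_chain()].
#' @param path output file.
#' @export
write_chain_fasta <- function(chains, path) {
  seqs <- vapply(chains, function(ch) ch$sequence, character(1))
  descs <- vapply(chains, function(ch) {
    d <- sprintf("%s chain=%s", ch$id, if (ch$chain_type == "light") "L" else "H")
    if (!is.na(ch$family)) d <- sprintf("%s family=%d", d, ch$family)
    d
  }, character(1))
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- descs
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read region annotations from TSV
#'
#' Expected columns: \code{id} plus the 14 integer columns
#' \code{fr1_start, fr1_end, cdr1_start, ..., fr4_end} (0-based half-open).
#'
#' @param path TSV file.
#' @return named list of [region_annotation()] keyed by id.
#' @export
read_regions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- as.vector(rbind(paste0(tolower(REGION_NAMES), "_start"),
                          paste0(tolower(REGION_NAMES), "_end")))
  missing <- setdiff(c("id", cols), names(df))
  fail_if(length(missing) > 0L, "regions TSV missing columns: %s",
          paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    region_annotation(
      starts = as.integer(df[i, paste0(tolower(REGION_NAMES), "_start")]),
      ends   = as.integer(df[i, paste0(tolower(REGION_NAMES), "_end")]))
  })
  names(out) <- df$id
  out
}

#' Write region annotations to TSV
#'
#' @param chains list of annotated chains (those without regions are skipped).
#' @param path output file.
#' @export
write_regions_tsv <- function(chains, path) {
  chains <- Filter(function(ch) !is.null(ch$regions), chains)
  rows <- lapply(chains, function(ch) {
    r <- ch$regions
    vals <- as.vector(rbind(r$start, r$end))
    names(vals) <- as.vector(rbind(paste0(tolower(REGION_NAMES), "_start"),
                                   paste0(tolower(REGION_NAMES), "_end")))
    c(list(id = ch$id), as.list(vals))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach region annotations to chains by id
#'
#' @param chains list of [annotated_chain()].
#' @param regions named list from [read_regions_tsv()].
#' @return chains with regions filled in where ids match.
#' @export
attach_regions <- function(chains, regions) {
  lapply(chains, function(ch) {
    if (!is.null(regions[[ch$id]])) ch$regions <- regions[[ch$id]]
    ch
  })
}
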