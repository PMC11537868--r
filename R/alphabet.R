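# Residue alphabet and token vocabulary.
#
# 20 canonical amino acids plus five special tokens.  Ids are 0-based and
# frozen: [PAD]=0, [UNK]=1, [CLS]=2, [SEP]=3, [MASK]=4, residues 5..24 in
# alphabetical one-letter order.  The vocabulary is serialized with every
# checkpoint so a saved model can assert id stability on load.

#' Canonical amino-acid letters (alphabetical one-letter codes)
#' @export
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Special tokens, in id order
#' @export
SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Build the residue alphabet
#'
#' @return an object of class \code{abmlm_alphabet} with components
#'   \code{tokens} (character, in id order), \code{id_of} (named integer map,
#'   0-based), \code{vocab_size} (25), and the ids of the special tokens.
#' @examples
#' ab <- residue_alphabet()
#' ab$vocab_size          # 25
#' ab$id_of[["[PAD]"]]    # 0
#' @export
residue_alphabet <- function() {
  tokens <- c(SPECIAL_TOKENS, AA_CANONICAL)
  id_of <- stats::setNames(seq_along(tokens) - 1L, tokens)
  out <- list(
    tokens = tokens,
    id_of = id_of,
    vocab_size = length(tokens),
    pad_id = id_of[["[PAD]"]],
    unk_id = id_of[["[UNK]"]],
    cls_id = id_of[["[CLS]"]],
    sep_id = id_of[["[SEP]"]],
    mask_id = id_of[["[MASK]"]],
    residue_ids = unname(id_of[AA_CANONICAL])
  )
  class(out) <- "abmlm_alphabet"
  out
}

#' Map 0-based token ids back to token strings
#'
#' @param ids integer vector of 0-based ids.
#' @param alphabet alphabet from [residue_alphabet()].
#' @return character vector of tokens.
#' @export
tokens_of <- function(ids, alphabet = residue_alphabet()) {
  fail_if(any(ids < 0L | ids >= alphabet$vocab_size),
          "token id out of vocabulary (valid range 0..%d)", alphabet$vocab_size - 1L)
  alphabet$tokens[ids + 1L]
}
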