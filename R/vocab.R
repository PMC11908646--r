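#' Residue vocabulary for window tokenization
#'
#' The tokenizer treats every residue symbol as one token. The vocabulary
#' covers the 20 standard amino acids, `X` (unknown residue), `-` (terminal
#' padding, distinct from unknown), and two special tokens: `[MASK]` used by
#' masked-language-model pretraining and `[CLS]` reserved as a
#' sequence-level token. Ids are contiguous integers starting at 0.
#'
#' @return A named integer vector mapping symbol to 0-based token id.
#' @examples
#' v <- aa_vocab()
#' v[["C"]]
#' @export
aa_vocab <- function() {
  symbols <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
               "X", "-", "[MASK]", "[CLS]")
  stats::setNames(seq_along(symbols) - 1L, symbols)
}

#' @rdname aa_vocab
#' @export
vocab_size <- function() length(aa_vocab())

# ids of the non-residue special tokens
mask_id <- function() aa_vocab()[["[MASK]"]]
pad_id  <- function() aa_vocab()[["-"]]

# token ids a random-replacement draw may use: real residues only
residue_ids <- function() unname(aa_vocab()[strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]])

#' Tokenize a residue string
#'
#' Converts a residue string into a vector of 0-based token ids, one id per
#' symbol with order preserved.
#'
#' @param residues Character scalar over the vocabulary alphabet
#'   (amino acids, `X`, `-`).
#' @param vocab Named integer vector as returned by [aa_vocab()].
#' @return Integer vector of token ids (length `nchar(residues)`).
#' @examples
#' tokenize("ACD-")
#' @export
tokenize <- function(residues, vocab = aa_vocab()) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (nchar(residues) == 0L) return(integer(0))
  chars <- strsplit(residues, "")[[1]]
  ids <- vocab[chars]
  if (anyNA(ids)) {
    bad <- unique(chars[is.na(ids)])
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(ids)
}

#' Convert token ids back to a residue string
#'
#' @param ids Integer vector of 0-based token ids.
#' @param vocab Named integer vector as returned by [aa_vocab()].
#' @return Character scalar.
#' @export
untokenize <- function(ids, vocab = aa_vocab()) {
  stopifnot(all(ids >= 0L), all(ids < length(vocab)))
  paste(names(vocab)[ids + 1L], collapse = "")
}
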