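#' Residue-level vocabulary
#'
#' The model treats each amino acid as a word. The vocabulary holds the 20
#' canonical residues in alphabetical order followed by the five special
#' tokens `[MASK]`, `[PAD]`, `[CLS]`, `[SEP]`, `[UNK]` — 25 tokens in all,
#' in a fixed, stable order so that token ids are portable across runs.
#'
#' @return An object of class `aa_vocabulary` with elements `tokens`
#'   (character vector of length 25) and `token_to_id` (named integer map).
#' @export
#' @examples
#' v <- aa_vocabulary()
#' v$token_to_id[["A"]]
aa_vocabulary <- function() {
  tokens <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
              "[MASK]", "[PAD]", "[CLS]", "[SEP]", "[UNK]")
  ids <- stats::setNames(seq_along(tokens), tokens)
  structure(list(tokens = tokens, token_to_id = ids), class = "aa_vocabulary")
}

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.vocab_size <- function() 25L

.special_id <- function(which) {
  switch(which, MASK = 21L, PAD = 22L, CLS = 23L, SEP = 24L, UNK = 25L,
         stop("unknown special token: ", which))
}

#' Tokenize an amino-acid sequence
#'
#' Maps a sequence to token ids, wrapping it in `[CLS]`/`[SEP]`.
#' Non-canonical residues (B, Z, J, X, U, O and anything else) map to
#' `[UNK]` with a warning.
#'
#' @param seq Character scalar, amino-acid sequence.
#' @param vocab An [aa_vocabulary()].
#' @return Integer vector of token ids of length `nchar(seq) + 2`.
#' @export
tokenize <- function(seq, vocab = aa_vocabulary()) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("`seq` must be a single non-empty string")
  chars <- strsplit(toupper(seq), "")[[1]]
  ids <- vocab$token_to_id[chars]
  bad <- is.na(ids)
  if (any(bad)) {
    warning("non-canonical residues mapped to [UNK]: ",
            paste(unique(chars[bad]), collapse = ", "))
    ids[bad] <- .special_id("UNK")
  }
  as.integer(c(.special_id("CLS"), ids, .special_id("SEP")))
}

#' Invert tokenization
#'
#' Drops special tokens and maps residue ids back to letters; `[UNK]`
#' becomes `X`.
#'
#' @param ids Integer token ids as returned by [tokenize()].
#' @param vocab An [aa_vocabulary()].
#' @return Character scalar.
#' @export
detokenize <- function(ids, vocab = aa_vocabulary()) {
  res <- ids[ids <= 20L | ids == .special_id("UNK")]
  paste(ifelse(res == .special_id("UNK"), "X", vocab$tokens[res]), collapse = "")
}

# Fast internal tokenizer for a set of equal-length sequences -> B x (L+2)
.tokenize_matrix <- function(seqs) {
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  m <- matrix(.special_id("UNK"), nrow = length(seqs), ncol = L)
  lookup <- stats::setNames(1:20, .AA)
  ch <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
               nrow = length(seqs), byrow = TRUE)
  idx <- lookup[ch]
  ok <- !is.na(idx)
  m[ok] <- idx[ok]
  cbind(.special_id("CLS"), m, .special_id("SEP"))
}
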